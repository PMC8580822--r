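#' Contact detection parameters
#'
#' Distance criteria for typed residue-residue contacts between heavy atoms.
#' A residue pair is a contact when at least one criterion holds; every
#' satisfied criterion is recorded as a contact type.
#'
#' * `vdw`: any heavy-atom pair closer than the sum of van der Waals radii
#'   plus `vdw_tolerance`.
#' * `hbond`: donor-acceptor heavy-atom (N/O/S) distance at most `hbond_max`.
#' * `ionic`: opposite-charge group nitrogen/oxygen distance at most
#'   `ionic_max` (Asp/Glu carboxylate O versus Lys NZ, Arg NE/NH, and
#'   optionally His ring N).
#' * `hydrophobic`: carbon-carbon distance at most `hydrophobic_max`.
#' * `aromatic`: ring-centroid distance at most `aromatic_centroid_max`
#'   (Phe/Tyr/Trp/His rings).
#'
#' Sequence-neighbour policy: within a chain, pairs with
#' `|seqnum difference| < min_seq_separation` are skipped, and pairs with
#' `|difference| <= 2` only count when a qualifying atom pair involves at
#' least one side-chain atom, so peptide-bond neighbours do not register via
#' backbone-backbone touching alone.
#'
#' @param vdw_tolerance Angstrom added to summed van der Waals radii.
#' @param hbond_max donor-acceptor heavy-atom cutoff, Angstrom.
#' @param ionic_max charged-group N/O cutoff, Angstrom.
#' @param hydrophobic_max carbon-carbon cutoff, Angstrom.
#' @param aromatic_centroid_max ring-centroid cutoff, Angstrom.
#' @param min_seq_separation minimum `|seqnum|` difference within a chain.
#' @param require_sidechain_adjacent suppress backbone-only contacts for
#'   `|seqnum difference| <= 2` (the adjacent rule).
#' @param his_charged treat His ring nitrogens as positively charged.
#' @return a `contact_params` list.
#' @export
contact_params <- function(vdw_tolerance = 0.6, hbond_max = 3.5,
                           ionic_max = 4.5, hydrophobic_max = 4.5,
                           aromatic_centroid_max = 5.5,
                           min_seq_separation = 1,
                           require_sidechain_adjacent = TRUE,
                           his_charged = FALSE) {
  p <- list(
    vdw_tolerance = vdw_tolerance, hbond_max = hbond_max,
    ionic_max = ionic_max, hydrophobic_max = hydrophobic_max,
    aromatic_centroid_max = aromatic_centroid_max,
    min_seq_separation = min_seq_separation,
    require_sidechain_adjacent = require_sidechain_adjacent,
    his_charged = his_charged
  )
  dists <- unlist(p[c("hbond_max", "ionic_max", "hydrophobic_max",
                      "aromatic_centroid_max")])
  if (any(dists <= 0) || vdw_tolerance < 0) {
    rlang::abort("Contact distance cutoffs must be positive.")
  }
  structure(p, class = "contact_params")
}

vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
backbone_atoms <- c("N", "CA", "C", "O", "OXT")

sidechain_donors <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", TRP = "NE1"
)
sidechain_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH"
)
positive_atoms <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)
negative_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)
aromatic_rings <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

element_radius <- function(el) {
  r <- vdw_radii[toupper(el)]
  r[is.na(r)] <- 1.70
  unname(r)
}

in_named_set <- function(resname, atom, set) {
  allowed <- set[resname]
  vapply(seq_along(atom),
         function(i) !is.null(allowed[[i]]) && atom[i] %in% allowed[[i]],
         logical(1))
}

# annotated atom table used by both detectors
contact_atom_table <- function(s) {
  res <- dplyr::filter(s$residues, !is.na(.data$generic))
  at <- dplyr::inner_join(
    s$atoms,
    dplyr::select(res, "chain", "seqnum", "aa", "resname", "generic"),
    by = c("chain", "seqnum")
  )
  at$is_backbone <- at$atom %in% backbone_atoms
  at$radius <- element_radius(at$element)
  at$is_carbon <- toupper(at$element) == "C"
  at$donor <- (at$atom == "N" & at$resname != "PRO") |
    in_named_set(at$resname, at$atom, sidechain_donors)
  at$acceptor <- at$atom %in% c("O", "OXT") |
    in_named_set(at$resname, at$atom, sidechain_acceptors)
  at$positive <- in_named_set(at$resname, at$atom, positive_atoms)
  at$negative <- in_named_set(at$resname, at$atom, negative_atoms)
  at$in_ring <- in_named_set(at$resname, at$atom, aromatic_rings)
  at
}

empty_contacts <- function() {
  tibble::tibble(
    pos_a = character(), pos_b = character(), aa_a = character(),
    aa_b = character(), types = character(), min_distance = numeric(),
    atom_a = character(), atom_b = character()
  )
}

new_contact_set <- function(structure_id, contacts, positions_resolved,
                            params = NULL) {
  structure(
    list(structure_id = structure_id, contacts = contacts,
         positions_resolved = positions_resolved, params = params),
    class = "contact_set"
  )
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact_set> ", x$structure_id, ": ", nrow(x$contacts),
      " contacts over ", length(x$positions_resolved),
      " resolved positions\n", sep = "")
  invisible(x)
}

# Aggregate qualifying atom pairs into typed residue-pair contacts.
# `ii`/`jj` index rows of `at`; `d` are their distances. Shared by both
# detectors: only the atom-pair *discovery* differs between them.
aggregate_atom_pairs <- function(s, at, ii, jj, d, params) {
  keep <- at$res_id[ii] != at$res_id[jj]
  ii <- ii[keep]; jj <- jj[keep]; d <- d[keep]
  contacts <- empty_contacts()
  if (length(ii)) {
    same_chain <- at$chain[ii] == at$chain[jj]
    dsep <- abs(at$seqnum[ii] - at$seqnum[jj])
    ok <- !(same_chain & dsep < params$min_seq_separation)
    admissible <- ok
    if (params$require_sidechain_adjacent) {
      adjacent <- same_chain & dsep <= 2
      admissible <- ok & !(adjacent & at$is_backbone[ii] & at$is_backbone[jj])
    }
    pos_v <- if (params$his_charged) at$positive else
      (at$positive & at$resname != "HIS")
    vdw_hit <- admissible & d <= at$radius[ii] + at$radius[jj] + params$vdw_tolerance
    hb_hit <- admissible & d <= params$hbond_max &
      ((at$donor[ii] & at$acceptor[jj]) | (at$acceptor[ii] & at$donor[jj]))
    ion_hit <- admissible & d <= params$ionic_max &
      ((pos_v[ii] & at$negative[jj]) | (at$negative[ii] & pos_v[jj]))
    phob_hit <- admissible & d <= params$hydrophobic_max &
      at$is_carbon[ii] & at$is_carbon[jj]

    any_hit <- vdw_hit | hb_hit | ion_hit | phob_hit
    if (any(any_hit) || any(ok)) {
      # orient each atom pair so ii belongs to the lower residue id
      flip <- at$res_id[ii] > at$res_id[jj]
      ii2 <- ifelse(flip, jj, ii)
      jj2 <- ifelse(flip, ii, jj)
      ra <- at$res_id[ii2]
      rb <- at$res_id[jj2]
      key <- paste0(ra, "_", rb)
      tab <- tibble::tibble(key = key, ra = ra, rb = rb, d = d, ii = ii2,
                            jj = jj2, vdw = vdw_hit, hb = hb_hit,
                            ion = ion_hit, phob = phob_hit, hit = any_hit)
      agg <- tab |>
        dplyr::group_by(.data$key, .data$ra, .data$rb) |>
        dplyr::summarise(
          vdw = any(.data$vdw), hydrophobic = any(.data$phob),
          hbond = any(.data$hb), ionic = any(.data$ion),
          hit = any(.data$hit),
          min_distance = min(.data$d),
          imin = .data$ii[which.min(.data$d)],
          jmin = .data$jj[which.min(.data$d)],
          .groups = "drop"
        )
      contacts <- agg
    }
  }

  # aromatic criterion on ring centroids, independent of atom-pair capture
  rings <- at[at$in_ring, , drop = FALSE]
  aro <- NULL
  if (nrow(rings) > 0 && length(unique(rings$res_id)) >= 2) {
    cen <- rings |>
      dplyr::group_by(res_id = .data$res_id) |>
      dplyr::summarise(x = mean(.data$x), y = mean(.data$y),
                       z = mean(.data$z), .groups = "drop")
    m <- as.matrix(cen[, c("x", "y", "z")])
    dd <- as.matrix(stats::dist(m))
    hit <- which(upper.tri(dd) & dd <= params$aromatic_centroid_max,
                 arr.ind = TRUE)
    if (nrow(hit)) {
      ra <- pmin(cen$res_id[hit[, 1]], cen$res_id[hit[, 2]])
      rb <- pmax(cen$res_id[hit[, 1]], cen$res_id[hit[, 2]])
      first_of <- match(ra, at$res_id); second_of <- match(rb, at$res_id)
      same_chain <- at$chain[first_of] == at$chain[second_of]
      dsep <- abs(at$seqnum[first_of] - at$seqnum[second_of])
      keep2 <- !(same_chain & dsep < params$min_seq_separation)
      if (any(keep2)) {
        aro <- tibble::tibble(key = paste0(ra, "_", rb)[keep2],
                              ra = ra[keep2], rb = rb[keep2],
                              aromatic = TRUE)
      }
    }
  }

  if (is.data.frame(contacts) && nrow(contacts)) {
    if (!is.null(aro)) {
      contacts <- dplyr::full_join(contacts, aro, by = c("key", "ra", "rb"))
    } else {
      contacts$aromatic <- FALSE
    }
  } else if (!is.null(aro)) {
    contacts <- aro
  } else {
    return(new_contact_set(s$structure_id, empty_contacts(),
                           positions_resolved(s), params))
  }
  for (cc in c("vdw", "hydrophobic", "hbond", "ionic", "aromatic", "hit")) {
    if (!cc %in% names(contacts)) contacts[[cc]] <- FALSE
    contacts[[cc]][is.na(contacts[[cc]])] <- FALSE
  }
  contacts <- contacts[contacts$hit | contacts$aromatic, , drop = FALSE]
  if (nrow(contacts) == 0) {
    return(new_contact_set(s$structure_id, empty_contacts(),
                           positions_resolved(s), params))
  }

  # aromatic-only pairs need distance/atom bookkeeping filled from geometry
  need <- which(is.na(contacts$min_distance))
  for (k in need) {
    a_idx <- which(at$res_id == contacts$ra[k])
    b_idx <- which(at$res_id == contacts$rb[k])
    dx <- outer(at$x[a_idx], at$x[b_idx], "-")
    dy <- outer(at$y[a_idx], at$y[b_idx], "-")
    dz <- outer(at$z[a_idx], at$z[b_idx], "-")
    dm <- sqrt(dx^2 + dy^2 + dz^2)
    w <- arrayInd(which.min(dm), dim(dm))
    contacts$min_distance[k] <- min(dm)
    contacts$imin[k] <- a_idx[w[1]]
    contacts$jmin[k] <- b_idx[w[2]]
  }

  first_a <- match(contacts$ra, at$res_id)
  first_b <- match(contacts$rb, at$res_id)
  gen_a <- at$generic[first_a]; gen_b <- at$generic[first_b]
  cp <- canonical_pair(gen_a, gen_b)
  swap <- cp$pos_a != gen_a
  type_str <- vapply(seq_len(nrow(contacts)), function(k) {
    paste(c("vdw", "hydrophobic", "hbond", "ionic", "aromatic")[
      c(contacts$vdw[k], contacts$hydrophobic[k], contacts$hbond[k],
        contacts$ionic[k], contacts$aromatic[k])], collapse = ",")
  }, "")
  out <- tibble::tibble(
    pos_a = cp$pos_a, pos_b = cp$pos_b,
    aa_a = ifelse(swap, at$aa[first_b], at$aa[first_a]),
    aa_b = ifelse(swap, at$aa[first_a], at$aa[first_b]),
    types = type_str,
    min_distance = contacts$min_distance,
    atom_a = ifelse(swap, at$atom[contacts$jmin], at$atom[contacts$imin]),
    atom_b = ifelse(swap, at$atom[contacts$imin], at$atom[contacts$jmin])
  )
  out <- out[order(generic_order_key(out$pos_a),
                   generic_order_key(out$pos_b)), ]
  new_contact_set(s$structure_id, out, positions_resolved(s), params)
}

atom_capture_radius <- function(at, params) {
  max(2 * max(element_radius(at$element)) + params$vdw_tolerance,
      params$hbond_max, params$ionic_max, params$hydrophobic_max)
}

prepare_contact_atoms <- function(s) {
  at <- contact_atom_table(s)
  if (nrow(at) == 0) return(NULL)
  at$res_key <- paste0(at$chain, ":", at$seqnum)
  at$res_id <- match(at$res_key, unique(at$res_key))
  at
}

#' Detect typed residue-residue contacts
#'
#' Finds all residue pairs (keyed by generic position) satisfying at least
#' one contact criterion. Uses a cell-list spatial index to gather candidate
#' atom pairs; correctness is defined by [detect_contacts_bruteforce()], the
#' exhaustive all-pairs reference the indexed version must match exactly.
#'
#' @param s an `annotated_structure` with generic numbers applied.
#' @param params a [contact_params()] object.
#' @return a `contact_set`: structure id, contact tibble (`pos_a`, `pos_b`,
#'   `aa_a`, `aa_b`, `types`, `min_distance`, `atom_a`, `atom_b`) and the
#'   set of generic positions resolved with at least one heavy atom.
#' @export
detect_contacts <- function(s, params = contact_params()) {
  stopifnot(inherits(s, "annotated_structure"))
  at <- prepare_contact_atoms(s)
  if (is.null(at)) {
    rlang::warn(paste0("Structure ", s$structure_id,
                       " has no residues with generic numbers; empty contact set."))
    return(new_contact_set(s$structure_id, empty_contacts(), character(), params))
  }
  cap <- atom_capture_radius(at, params)
  cell <- floor(cbind(at$x, at$y, at$z) / cap)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  cell_members <- split(seq_len(nrow(at)), key)
  cells <- do.call(rbind, strsplit(names(cell_members), ","))
  storage.mode(cells) <- "integer"
  cell_index <- stats::setNames(seq_along(cell_members), names(cell_members))
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ii <- list(); jj <- list(); dd <- list()
  for (ci in seq_along(cell_members)) {
    base <- cells[ci, ]
    ids_a <- cell_members[[ci]]
    for (oi in seq_len(nrow(offsets))) {
      nb_key <- paste(base[1] + offsets[oi, 1], base[2] + offsets[oi, 2],
                      base[3] + offsets[oi, 3], sep = ",")
      cj <- cell_index[nb_key]
      if (is.na(cj) || cj < ci) next
      ids_b <- cell_members[[cj]]
      dx <- outer(at$x[ids_a], at$x[ids_b], "-")
      dy <- outer(at$y[ids_a], at$y[ids_b], "-")
      dz <- outer(at$z[ids_a], at$z[ids_b], "-")
      d2 <- dx^2 + dy^2 + dz^2
      hit <- which(d2 <= cap^2, arr.ind = TRUE)
      if (ci == cj) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (nrow(hit) == 0) next
      ii[[length(ii) + 1]] <- ids_a[hit[, 1]]
      jj[[length(jj) + 1]] <- ids_b[hit[, 2]]
      dd[[length(dd) + 1]] <- sqrt(d2[hit])
    }
  }
  aggregate_atom_pairs(s, at, unlist(ii) %||% integer(),
                       unlist(jj) %||% integer(),
                       unlist(dd) %||% numeric(), params)
}

#' Exhaustive contact detection (reference implementation)
#'
#' Same contract as [detect_contacts()] but scans every atom pair with a
#' full O(n^2) distance computation and no spatial indexing. Serves as the
#' correctness oracle: both functions must return identical contact sets on
#' any input.
#'
#' @inheritParams detect_contacts
#' @return a `contact_set`.
#' @export
detect_contacts_bruteforce <- function(s, params = contact_params()) {
  stopifnot(inherits(s, "annotated_structure"))
  at <- prepare_contact_atoms(s)
  if (is.null(at)) {
    rlang::warn(paste0("Structure ", s$structure_id,
                       " has no residues with generic numbers; empty contact set."))
    return(new_contact_set(s$structure_id, empty_contacts(), character(), params))
  }
  cap <- atom_capture_radius(at, params)
  dm <- as.matrix(stats::dist(as.matrix(at[, c("x", "y", "z")])))
  hit <- which(upper.tri(dm) & dm <= cap, arr.ind = TRUE)
  aggregate_atom_pairs(s, at, hit[, 1], hit[, 2], dm[hit], params)
}

#' Write a per-structure contact table
#'
#' @param cs a `contact_set`.
#' @param path output TSV path; a provenance header records the parameters.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(cs, path) {
  hdr <- c(
    paste0("# structure_id=", cs$structure_id),
    paste0("# ", provenance_line(cs$params))
  )
  writeLines(hdr, path)
  out <- dplyr::mutate(cs$contacts, structure_id = cs$structure_id,
                       .before = 1)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

provenance_line <- function(params) {
  if (is.null(params)) return("params=default")
  paste(names(params), unlist(params), sep = "=", collapse = " ")
}
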