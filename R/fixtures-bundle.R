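#' Specification for an ideal transmembrane helix bundle
#'
#' Describes a synthetic receptor used as ground-truth input: `n_helices`
#' ideal alpha-helices (1.5 Angstrom rise, 100 degree twist per residue)
#' placed on a ring, with alternating up/down topology so that odd helices
#' run extracellular-to-intracellular. Residues carry generic numbers
#' centred on offset 50. Backbone N/CA/C/O plus a CB pseudo-side-chain are
#' built for every residue; residues listed in `sidechains` (by generic
#' label, with an amino acid) get full idealized side chains so that typed
#' contacts (ionic, aromatic, hydrogen bond) can be engineered.
#'
#' @param n_helices number of transmembrane helices (default 7).
#' @param residues_per_helix residues per helix (default 25).
#' @param bundle_radius ring radius for helix placement, Angstrom.
#' @param helix_radius alpha-helix CA radius, Angstrom.
#' @param rise axial rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param sidechains optional tibble with columns `generic`, `aa` and
#'   optionally `partner` naming residues built with full side chains; when
#'   a partner position is given, the side chain is aimed at it so the two
#'   functional tips meet ~3 Angstrom apart (engineered contact pairs).
#' @param include_h8 also build a short intracellular helix 8.
#' @param structure_id identifier for the generated structure.
#' @param seed integer seed (the construction is deterministic; the seed is
#'   recorded and used by downstream noise helpers).
#' @return a `bundle_spec` list.
#' @export
bundle_spec <- function(n_helices = 7, residues_per_helix = 25,
                        bundle_radius = 10, helix_radius = 2.3,
                        rise = 1.5, twist = 100,
                        sidechains = NULL, include_h8 = FALSE,
                        structure_id = "SYN1", seed = 1L) {
  if (n_helices < 2 || residues_per_helix < 7) {
    rlang::abort("Bundle needs at least 2 helices of at least 7 residues.")
  }
  # helices on a ring of radius R are separated by ~2 R sin(pi/n); they
  # overlap when that falls below twice the helix radius
  sep <- 2 * bundle_radius * sin(pi / n_helices)
  if (sep < 2 * helix_radius) {
    rlang::abort("Impossible geometry: helices overlap on the placement ring.")
  }
  structure(list(
    n_helices = n_helices, residues_per_helix = residues_per_helix,
    bundle_radius = bundle_radius, helix_radius = helix_radius,
    rise = rise, twist = twist, sidechains = sidechains,
    include_h8 = include_h8, structure_id = structure_id, seed = as.integer(seed)
  ), class = "bundle_spec")
}

# idealized side-chain templates: atom name, distance outward from CA along
# the radial direction, lateral (tangential) offset. Degenerate but
# deterministic geometry; only atom identity and rough distances matter.
sidechain_templates <- list(
  ASP = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("OD1", 3.8, 0.7), c("OD2", 3.8, -0.7)),
  GLU = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.1, 0), c("OE1", 5.0, 0.7), c("OE2", 5.0, -0.7)),
  ARG = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.1, 0), c("NE", 5.3, 0), c("CZ", 6.5, 0), c("NH1", 7.1, 0.7), c("NH2", 7.1, -0.7)),
  LYS = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.1, 0), c("CE", 5.3, 0), c("NZ", 6.4, 0)),
  ASN = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("OD1", 3.8, 0.7), c("ND2", 3.8, -0.7)),
  GLN = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.1, 0), c("OE1", 5.0, 0.7), c("NE2", 5.0, -0.7)),
  SER = list(c("CB", 1.5, 0), c("OG", 2.6, 0)),
  THR = list(c("CB", 1.5, 0), c("OG1", 2.5, 0.6), c("CG2", 2.5, -0.6)),
  LEU = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD1", 3.6, 0.7), c("CD2", 3.6, -0.7)),
  ILE = list(c("CB", 1.5, 0), c("CG1", 2.6, 0.6), c("CG2", 2.6, -0.6), c("CD1", 3.9, 0.6)),
  VAL = list(c("CB", 1.5, 0), c("CG1", 2.5, 0.6), c("CG2", 2.5, -0.6)),
  MET = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("SD", 4.2, 0), c("CE", 5.4, 0)),
  PHE = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("CD1", 3.6, 1.2), c("CD2", 3.6, -1.2), c("CE1", 5.0, 1.2), c("CE2", 5.0, -1.2), c("CZ", 5.7, 0)),
  TYR = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("CD1", 3.6, 1.2), c("CD2", 3.6, -1.2), c("CE1", 5.0, 1.2), c("CE2", 5.0, -1.2), c("CZ", 5.7, 0), c("OH", 7.1, 0)),
  TRP = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("CD1", 3.6, 1.1), c("CD2", 3.6, -1.1), c("NE1", 4.9, 1.1), c("CE2", 4.9, -0.2), c("CE3", 4.3, -2.1), c("CZ2", 6.1, -0.4), c("CZ3", 5.6, -2.3), c("CH2", 6.4, -1.5)),
  HIS = list(c("CB", 1.5, 0), c("CG", 2.9, 0), c("ND1", 3.7, 1.1), c("CD2", 3.7, -1.1), c("CE1", 5.0, 0.7), c("NE2", 5.0, -0.7))
)

#' Build an ideal helical bundle structure
#'
#' Constructs the synthetic receptor described by a [bundle_spec()], with
#' generic numbers already applied (offsets centred on 50) and the
#' corresponding mapping table attached as attribute `"mapping"`. The
#' construction is fully deterministic.
#'
#' @param spec a [bundle_spec()].
#' @return an `annotated_structure`; `attr(, "mapping")` holds the
#'   residue-to-generic mapping tibble.
#' @export
make_ideal_bundle <- function(spec = bundle_spec()) {
  stopifnot(inherits(spec, "bundle_spec"))
  m <- spec$residues_per_helix
  off0 <- 50L - (m - 1L) %/% 2L
  sidechains <- spec$sidechains
  if (!is.null(sidechains)) {
    sidechains <- tibble::as_tibble(sidechains)
    sidechains$generic <- parse_generic(sidechains$generic)$generic
    if ("partner" %in% names(sidechains)) {
      sidechains$partner <- parse_generic(sidechains$partner)$generic
    }
  }

  atom_rows <- list()
  res_rows <- list()
  twist_rad <- spec$twist * pi / 180
  # first pass: backbone geometry and per-residue frames
  res_info <- list()
  for (h in seq_len(spec$n_helices)) {
    phi <- 2 * pi * (h - 1) / spec$n_helices
    center <- c(spec$bundle_radius * cos(phi), spec$bundle_radius * sin(phi), 0)
    down <- (h %% 2 == 1) # odd helices run extracellular (+z) to intracellular
    for (j in seq_len(m)) {
      theta <- twist_rad * (j - 1)
      z_loc <- spec$rise * (j - 1) - spec$rise * (m - 1) / 2
      place <- function(r, dtheta, dz) {
        p <- c(r * cos(theta + dtheta), r * sin(theta + dtheta), z_loc + dz)
        if (down) p <- c(p[1], -p[2], -p[3]) # flip about x-axis
        p + center
      }
      generic <- paste0(h, "x", off0 + j - 1L)
      flipv <- function(v) if (down) c(v[1], -v[2], -v[3]) else v
      res_info[[generic]] <- list(
        h = h, seqnum = h * 100L + j, generic = generic,
        bb = list(
          N = place(1.83, -27.5 * pi / 180, -0.95),
          CA = place(spec$helix_radius, 0, 0),
          C = place(1.66, 24.0 * pi / 180, 1.05),
          O = place(2.00, 24.0 * pi / 180, 2.28)
        ),
        out_lab = flipv(c(cos(theta), sin(theta), 0)),
        tan_lab = flipv(c(-sin(theta), cos(theta), 0))
      )
    }
  }
  # second pass: side chains; designated residues with a partner are aimed
  # at that partner so the engineered pair meets within contact range
  for (generic in names(res_info)) {
    ri <- res_info[[generic]]
    aa3 <- "ALA"
    sc <- NULL
    dir <- ri$out_lab
    lat <- ri$tan_lab
    scale <- 1
    if (!is.null(sidechains) && generic %in% sidechains$generic) {
      k <- match(generic, sidechains$generic)
      aa3 <- aa_one_to_three(sidechains$aa[k])
      sc <- sidechain_templates[[aa3]]
      partner <- if ("partner" %in% names(sidechains)) sidechains$partner[k]
                 else NA_character_
      if (!is.na(partner) && partner %in% names(res_info)) {
        ca_self <- ri$bb$CA
        ca_partner <- res_info[[partner]]$bb$CA
        mid <- (ca_self + ca_partner) / 2
        v <- mid - ca_self
        reach <- sqrt(sum(v^2)) + 1.5 # functional tips end up ~3 A apart
        dir <- v / sqrt(sum(v^2))
        lat <- lat - sum(lat * dir) * dir
        lat <- lat / sqrt(sum(lat^2))
        tip <- max(vapply(sc, function(t) as.numeric(t[2]), 0))
        scale <- reach / tip
      }
    }
    ca_lab <- ri$bb$CA
    sc_atoms <- list()
    if (is.null(sc)) {
      sc_atoms$CB <- ca_lab + 1.53 * dir
    } else {
      for (t in sc) {
        sc_atoms[[t[1]]] <- ca_lab + scale * as.numeric(t[2]) * dir +
          as.numeric(t[3]) * lat
      }
    }
    all_atoms <- c(ri$bb, sc_atoms)
    el <- substr(gsub("[0-9]", "", names(all_atoms)), 1, 1)
    el[names(all_atoms) == "SD"] <- "S"
    atom_rows[[length(atom_rows) + 1]] <- tibble::tibble(
      chain = "A", seqnum = ri$seqnum, atom = names(all_atoms), element = el,
      x = vapply(all_atoms, `[`, 0, 1), y = vapply(all_atoms, `[`, 0, 2),
      z = vapply(all_atoms, `[`, 0, 3), altloc = "", occupancy = 1
    )
    res_rows[[length(res_rows) + 1]] <- tibble::tibble(
      chain = "A", seqnum = ri$seqnum, resname = aa3,
      aa = aa_three_to_one(aa3), generic = ri$generic,
      segment = segment_from_code(ri$h)
    )
  }
  if (spec$include_h8) {
    z8 <- -(spec$rise * (m - 1) / 2 + 4)
    for (j in 1:10) {
      theta <- twist_rad * (j - 1)
      # helix 8 lies roughly along x at the intracellular face
      pos <- c(spec$bundle_radius - 6 + 1.5 * (j - 1),
               2.3 * cos(theta) + 3, z8 + 2.3 * sin(theta) * 0.3)
      generic <- paste0("8x", 46L + j)
      seqnum <- 800L + j
      atom_rows[[length(atom_rows) + 1]] <- tibble::tibble(
        chain = "A", seqnum = seqnum,
        atom = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
        x = pos[1] + c(-0.6, 0, 0.6, 0.7, 0), y = pos[2] + c(0, 0, 0, 1.0, 1.4),
        z = pos[3] + c(-0.4, 0, 0.4, 0.5, -0.5), altloc = "", occupancy = 1
      )
      res_rows[[length(res_rows) + 1]] <- tibble::tibble(
        chain = "A", seqnum = seqnum, resname = "ALA", aa = "A",
        generic = generic, segment = "H8"
      )
    }
  }
  residues <- dplyr::bind_rows(res_rows)
  atoms <- dplyr::bind_rows(atom_rows)
  s <- new_annotated_structure(spec$structure_id, residues, atoms)
  s$n_mapped <- sum(!is.na(residues$generic))
  attr(s, "mapping") <- tibble::tibble(
    structure_id = spec$structure_id, chain = residues$chain,
    seqnum = residues$seqnum, generic = residues$generic
  )
  attr(s, "bundle_spec") <- spec
  s
}

#' Motion specification for synthetic activation
#'
#' Per-helix, per-region rigid motions imposed on a bundle to emulate an
#' active state: a translation vector and a rotation about the helix's own
#' axis. Regions blend smoothly along the helix: residues within a region's
#' plateau carry the full motion, with linear interpolation in between and
#' zero motion where no region is specified.
#'
#' @param tm helix label, e.g. `"TM6"`.
#' @param region one of `"ic_end"`, `"mid"`, `"ec_end"`, or `"all"` for a
#'   whole-helix rigid motion.
#' @param tx,ty,tz translation components, Angstrom (lab frame).
#' @param rot_deg rotation about the helix's own axis, degrees (positive =
#'   counterclockwise viewed from the extracellular side).
#' @return a one-row motion tibble; rows can be combined with
#'   [dplyr::bind_rows()].
#' @export
motion_spec <- function(tm, region = "all", tx = 0, ty = 0, tz = 0,
                        rot_deg = 0) {
  stopifnot(region %in% c("ic_end", "mid", "ec_end", "all"))
  tibble::tibble(tm = tm, region = region, tx = tx, ty = ty, tz = tz,
                 rot_deg = rot_deg)
}

# Region weight along the normalized intracellular->extracellular coordinate
# t. End motions plateau over the terminal window and decay to zero before
# the mid-membrane slab (|t - 0.5| < 1/6 for default 25-residue helices) so
# that an imposed end motion leaves the superposition core untouched.
region_weight <- function(region, t) {
  switch(region,
    all = rep(1, length(t)),
    ic_end = pmin(1, pmax(0, (0.32 - t) / 0.12)),
    ec_end = pmin(1, pmax(0, (t - 0.68) / 0.12)),
    mid = pmin(1, pmax(0, pmin((t - 0.3) / 0.11, (0.7 - t) / 0.11)))
  )
}

#' Apply an imposed motion to a bundle
#'
#' Produces the "active"-state structure by moving the named helices.
#' Rotation about the helix's own (inactive) axis is applied first, then the
#' translation. Ground-truth motion metadata is stored in attribute
#' `"imposed_motion"`.
#'
#' @param s an `annotated_structure` built by [make_ideal_bundle()].
#' @param motion tibble of [motion_spec()] rows.
#' @param structure_id id of the derived structure.
#' @return the moved `annotated_structure`.
#' @export
apply_motion <- function(s, motion, structure_id = paste0(s$structure_id, "A")) {
  stopifnot(inherits(s, "annotated_structure"))
  motion <- tibble::as_tibble(motion)
  missing_tm <- setdiff(motion$tm, unique(s$residues$segment))
  if (length(missing_tm)) {
    rlang::abort(paste0("Motion names segments absent from the structure: ",
                        paste(missing_tm, collapse = ", ")))
  }
  out <- s
  out$structure_id <- structure_id
  frame <- estimate_membrane_frame(s)
  for (tm in unique(motion$tm)) {
    span <- segment_span(s, tm)
    if (nrow(span) == 0) next
    ca <- atom_coords(s, "CA")
    ca <- ca[ca$segment == tm, , drop = FALSE]
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    centroid <- colMeans(xyz)
    ax <- principal_axis(xyz)
    if (sum(ax * frame$normal) < 0) ax <- -ax # orient extracellularly
    proj <- as.numeric((xyz - matrix(centroid, nrow(xyz), 3, byrow = TRUE)) %*% ax)
    tvals <- (proj - min(proj)) / (max(proj) - min(proj))
    names(tvals) <- paste0(ca$chain, ":", ca$seqnum)
    rows <- motion[motion$tm == tm, , drop = FALSE]
    idx <- out$atoms$seqnum %in% ca$seqnum & out$atoms$chain == ca$chain[1]
    atom_res_key <- paste0(out$atoms$chain[idx], ":", out$atoms$seqnum[idx])
    t_atom <- tvals[atom_res_key]
    xyz_atoms <- as.matrix(out$atoms[idx, c("x", "y", "z")])
    total_angle <- rep(0, sum(idx))
    total_shift <- matrix(0, sum(idx), 3)
    for (k in seq_len(nrow(rows))) {
      w <- region_weight(rows$region[k], t_atom)
      total_angle <- total_angle + w * rows$rot_deg[k]
      total_shift <- total_shift + w %o% c(rows$tx[k], rows$ty[k], rows$tz[k])
    }
    rel <- xyz_atoms - matrix(centroid, nrow(xyz_atoms), 3, byrow = TRUE)
    rotated <- rel
    for (i in seq_len(nrow(rel))) {
      R <- rotation_about_axis(ax, total_angle[i] * pi / 180)
      rotated[i, ] <- as.numeric(R %*% rel[i, ])
    }
    out$atoms[idx, c("x", "y", "z")] <-
      rotated + matrix(centroid, nrow(rel), 3, byrow = TRUE) + total_shift
  }
  attr(out, "imposed_motion") <- motion
  mapping <- attr(s, "mapping")
  if (!is.null(mapping)) mapping$structure_id <- structure_id
  attr(out, "mapping") <- mapping
  out
}

#' Add Gaussian coordinate noise to a structure
#'
#' @param s an `annotated_structure`.
#' @param sd noise standard deviation per coordinate, Angstrom.
#' @param seed integer seed.
#' @return the perturbed structure.
#' @export
perturb_structure <- function(s, sd = 0.3, seed = 1L) {
  n <- nrow(s$atoms)
  noise <- matrix(withr::with_seed(seed, stats::rnorm(3 * n, sd = sd)), n, 3)
  s$atoms[, c("x", "y", "z")] <- as.matrix(s$atoms[, c("x", "y", "z")]) + noise
  s
}

#' Apply one rigid transform to every atom
#'
#' @param s an `annotated_structure`.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation vector.
#' @return the transformed structure.
#' @export
transform_structure <- function(s, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  s$atoms[, c("x", "y", "z")] <- xyz %*% t(R) +
    matrix(t, nrow(xyz), 3, byrow = TRUE)
  if (nrow(s$hetero)) {
    hxyz <- as.matrix(s$hetero[, c("x", "y", "z")])
    s$hetero[, c("x", "y", "z")] <- hxyz %*% t(R) +
      matrix(t, nrow(hxyz), 3, byrow = TRUE)
  }
  s
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

principal_axis <- function(xyz) {
  c0 <- xyz - matrix(colMeans(xyz), nrow(xyz), 3, byrow = TRUE)
  sv <- svd(c0)
  sv$v[, 1]
}

#' Write a structure as mmCIF (plus mapping table and ground truth)
#'
#' Writes a minimal but standard-conformant `atom_site` loop. The companion
#' files `<id>_mapping.tsv` (generic-number mapping) and `<id>_truth.json`
#' (imposed-motion metadata, when present) are written next to it.
#'
#' @param s an `annotated_structure`.
#' @param dir output directory.
#' @param format `"cif"` or `"pdb"`.
#' @return path of the structure file, invisibly.
#' @export
write_structure <- function(s, dir, format = c("cif", "pdb")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, s$structure_id)
  path <- paste0(base, ".", format)
  at <- dplyr::left_join(s$atoms,
                         dplyr::select(s$residues, "chain", "seqnum", "resname"),
                         by = c("chain", "seqnum"))
  at$group <- "ATOM"
  if (nrow(s$hetero)) {
    het <- s$hetero
    het$group <- "HETATM"
    at <- dplyr::bind_rows(at, het)
  }
  if (format == "cif") {
    cols <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
              "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
              "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
    lines <- c(paste0("data_", s$structure_id), "#", "loop_",
               paste0("_atom_site.", cols))
    alt <- ifelse(is.na(at$altloc) | at$altloc == "", ".", at$altloc)
    lines <- c(lines, sprintf(
      "%s %d %s %s %s %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
      at$group, seq_len(nrow(at)), at$element, at$atom, alt, at$resname,
      at$chain, at$seqnum, at$x, at$y, at$z, at$occupancy, at$seqnum,
      at$resname, at$chain, at$atom
    ), "#")
    writeLines(lines, path)
  } else {
    alt <- ifelse(is.na(at$altloc) | at$altloc == "", " ", at$altloc)
    name4 <- ifelse(nchar(at$atom) < 4, paste0(" ", formatC(at$atom, width = -3)),
                    at$atom)
    writeLines(c(sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$group, seq_len(nrow(at)), name4, alt, at$resname, at$chain, at$seqnum,
      at$x, at$y, at$z, at$occupancy, 0, at$element
    ), "END"), path)
  }
  mapping <- attr(s, "mapping")
  if (!is.null(mapping)) {
    readr::write_tsv(mapping, paste0(base, "_mapping.tsv"))
  }
  truth <- attr(s, "imposed_motion")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(base, "_truth.json"), digits = NA)
  }
  invisible(path)
}
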