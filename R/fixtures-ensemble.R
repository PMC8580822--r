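#' Build a contact ensemble with programmed pair frequencies
#'
#' Generates lists of inactive/active contact sets in which every pair is
#' formed in exactly the programmed number of templates, with optional
#' per-position resolution dropout, so that downstream frequency
#' bookkeeping can be checked exactly (rational arithmetic on counts).
#' Which templates carry a contact is decided by a seeded shuffle; the
#' counts themselves are deterministic.
#'
#' @param n_inactive,n_active number of templates per state.
#' @param pairs tibble with columns `pos_a`, `pos_b`, `k_inactive`,
#'   `k_active` (template counts forming the contact in each state) and
#'   optionally `aa_a`, `aa_b` (default `A`-`A`).
#' @param dropout optional tibble with columns `position`, `k_inactive`,
#'   `k_active`: number of templates per state in which the position is
#'   unresolved.
#' @param gpcr_class class label.
#' @param seed integer seed for the template shuffles.
#' @return list with `inactive` and `active` lists of `contact_set`s and
#'   the `pairs` truth table.
#' @export
make_contact_ensemble <- function(n_inactive, n_active, pairs, dropout = NULL,
                                  gpcr_class = "A", seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  if (!"aa_a" %in% names(pairs)) pairs$aa_a <- "A"
  if (!"aa_b" %in% names(pairs)) pairs$aa_b <- "A"
  cp <- canonical_pair(pairs$pos_a, pairs$pos_b)
  pairs$pos_a <- cp$pos_a; pairs$pos_b <- cp$pos_b
  positions <- sort_generic(unique(c(pairs$pos_a, pairs$pos_b)))

  resolved_for <- function(n, state_col) {
    res <- replicate(n, positions, simplify = FALSE)
    if (!is.null(dropout)) {
      d <- tibble::as_tibble(dropout)
      kcol <- paste0("k_", state_col)
      for (i in seq_len(nrow(d))) {
        k <- d[[kcol]][i]
        if (is.null(k) || is.na(k) || k == 0) next
        if (k > n) rlang::abort("Dropout count exceeds template count.")
        drop_in <- withr::with_seed(seed + i, sample(n, k))
        for (t in drop_in) res[[t]] <- setdiff(res[[t]], d$position[i])
      }
    }
    res
  }
  res_i <- resolved_for(n_inactive, "inactive")
  res_a <- resolved_for(n_active, "active")

  assign_templates <- function(res, k, pos_a, pos_b, offset) {
    eligible <- which(vapply(res, function(r) pos_a %in% r && pos_b %in% r, TRUE))
    if (k > length(eligible)) {
      rlang::abort(paste0("Unrealizable frequency: pair ", pos_a, "-", pos_b,
                          " programmed in ", k, " templates but only ",
                          length(eligible), " have both positions resolved."))
    }
    if (k == 0) return(integer())
    withr::with_seed(seed + offset, sample(eligible, k))
  }

  build_sets <- function(res, state, n) {
    sets <- vector("list", n)
    formed <- vector("list", n)
    for (i in seq_len(n)) formed[[i]] <- integer()
    for (p in seq_len(nrow(pairs))) {
      k <- pairs[[paste0("k_", state)]][p]
      tpl <- assign_templates(res, k, pairs$pos_a[p], pairs$pos_b[p],
                              offset = 1000L * (state == "active") + p)
      for (t in tpl) formed[[t]] <- c(formed[[t]], p)
    }
    for (i in seq_len(n)) {
      pp <- pairs[formed[[i]], , drop = FALSE]
      contacts <- if (nrow(pp)) tibble::tibble(
        pos_a = pp$pos_a, pos_b = pp$pos_b, aa_a = pp$aa_a, aa_b = pp$aa_b,
        types = "vdw", min_distance = 3.5, atom_a = "CB", atom_b = "CB"
      ) else empty_contacts()
      sets[[i]] <- new_contact_set(
        paste0(gpcr_class, "_", state, "_", i), contacts, res[[i]]
      )
    }
    sets
  }
  list(
    inactive = build_sets(res_i, "inactive", n_inactive),
    active = build_sets(res_a, "active", n_active),
    pairs = pairs
  )
}

#' Build a class alignment with programmed conservation
#'
#' Produces a long alignment tibble (`receptor`, `position`, `aa`) in which
#' each position carries the programmed amino-acid fractions as exact
#' counts (largest-remainder allocation), shuffled across receptors with a
#' seeded permutation.
#'
#' @param n_receptors receptors in the class.
#' @param columns named list: position label -> named fraction vector, e.g.
#'   `list("3x50" = c(R = 0.8, K = 0.2))`.
#' @param seed integer seed.
#' @return long alignment tibble.
#' @export
make_class_alignment <- function(n_receptors, columns, seed = 1L) {
  receptors <- sprintf("R%02d", seq_len(n_receptors))
  rows <- purrr::imap_dfr(columns, function(freqs, pos) {
    counts <- floor(freqs * n_receptors)
    rem <- n_receptors - sum(counts)
    if (rem > 0) {
      frac <- freqs * n_receptors - counts
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[add] <- counts[add] + 1
    }
    aa <- rep(names(freqs), counts)
    aa <- withr::with_seed(seed + generic_order_key(pos),
                           sample(aa, n_receptors))
    tibble::tibble(receptor = receptors, position = pos, aa = aa)
  })
  rows
}

#' Emulated structure annotation catalog
#'
#' Builds a synthetic annotation catalog shaped like the published
#' 510-structure survey: per class, the representative-eligible rows are
#' planted so that selection yields the published per-class template counts
#' (A 33/14, B1 3/10, C 4/2, F 2/2 inactive/active), 13 receptors covered
#' in both states, heterodimer split entries sharing a parent structure
#' (YZ01 from 7C7Q, YZ02 from 7C7S) and 45 of the 68 distinct parent
#' structures at 3.0 Angstrom or better. The remaining rows fail at least
#' one filter (including rows placed exactly at, just above and just below
#' each threshold boundary) and pad the catalog to `n_rows`.
#'
#' @param n_rows total catalog size (default 510).
#' @param seed integer seed for the padding rows.
#' @return annotation tibble (see [load_annotation()] for the schema).
#' @export
make_annotation_catalog <- function(n_rows = 510, seed = 1L) {
  row <- function(structure_id, receptor, gpcr_class, state, resolution,
                  rc = 95, gc = NA, si = 98, da = NULL, lig = NULL,
                  gp = FALSE, parent = structure_id) {
    da <- da %||% if (state == "active") 95 else 5
    lig <- lig %||% if (state == "active") "agonist" else "antagonist"
    tibble::tibble(
      structure_id = structure_id, receptor = receptor,
      gpcr_class = gpcr_class, state_annotation = state,
      resolution = resolution, receptor_completeness = rc,
      gprotein_completeness = gc, seq_identity_human = si,
      degree_active = da, ligand_modality = lig,
      has_gprotein_complex = gp, parent_id = parent
    )
  }
  # resolutions for the distinct parent structures: 45 of 68 at <= 3.0
  res_good <- rep(c(2.4, 2.6, 2.8, 3.0), length.out = 45)
  res_poor <- rep(c(3.2, 3.4, 3.6), length.out = 23)
  res_all <- c(res_good, res_poor)
  ri <- 0L
  next_res <- function() { ri <<- ri + 1L; res_all[ri] }

  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- row(...)

  # class A: 33 inactive receptors, 14 active receptors, 8 with both states
  for (i in 1:33) {
    id <- if (i == 1) "2RH1" else sprintf("A%03dI", i)
    rec <- if (i == 1) "ADRB2" else sprintf("A_R%02d", i)
    add(id, rec, "A", "inactive", next_res())
  }
  for (i in c(1, 27:33, 34:39)) {
    id <- if (i == 1) "3SN6" else sprintf("A%03dA", i)
    rec <- if (i == 1) "ADRB2" else sprintf("A_R%02d", i)
    add(id, rec, "A", "active", next_res(), gc = 80, gp = TRUE)
  }
  # class B1: 3 inactive, 10 active, 2 receptors with both states
  b1_in <- c("GLP1R", "CRF1R", "B1_R03")
  for (i in 1:3) add(sprintf("B%03dI", i), b1_in[i], "B1", "inactive", next_res())
  b1_act <- c("GLP1R", "CRF1R", sprintf("B1_R%02d", 4:11))
  for (i in 1:10) add(sprintf("B%03dA", i), b1_act[i], "B1", "active",
                      next_res(), gc = 75, gp = TRUE)
  # class C: GABA_B heterodimer split entries share their parent structure
  r7c7s <- next_res(); r7c7q <- next_res()
  add("7C7S", "GABAB1", "C", "inactive", r7c7s)
  add("YZ02", "GABAB2", "C", "inactive", r7c7s, parent = "7C7S")
  add("C003I", "MGLU5", "C", "inactive", next_res())
  add("C004I", "MGLU2", "C", "inactive", next_res())
  add("7C7Q", "GABAB2", "C", "active", r7c7q, gc = 70, gp = TRUE)
  add("YZ01", "GABAB1", "C", "active", r7c7q, gc = 70, gp = TRUE,
      parent = "7C7Q")
  # class F: 2 inactive, 2 active, SMO covered in both states
  add("F001I", "SMO", "F", "inactive", next_res())
  add("F002I", "FZD4", "F", "inactive", next_res())
  add("F003A", "SMO", "F", "active", next_res(), gc = 60, gp = TRUE)
  add("F004A", "FZD7", "F", "active", next_res(), gc = 60, gp = TRUE)

  # boundary rows: straddle each filter threshold (the "just passing" ones
  # must lose the per-receptor tie-break, so they sit on covered receptors
  # at worse resolution than the planted representative)
  add("BND01", "A_R02", "A", "inactive", 3.60, rc = 83, si = 90.1) # at bounds
  add("BND02", "A_R02", "A", "inactive", 3.61)                      # res fail
  add("BND03", "A_R02", "A", "inactive", 3.5, rc = 82.9)            # compl fail
  add("BND04", "A_R02", "A", "inactive", 3.5, si = 90)              # identity fail (strict >)
  add("BND05", "A_R02", "A", "inactive", 3.5, da = 20)              # at degree bound
  add("BND06", "A_R02", "A", "inactive", 3.5, da = 20.1)            # degree fail
  add("BND07", "A_R02", "A", "inactive", 3.5, lig = "agonist")      # modality fail
  add("BND08", "A_R27", "A", "active", 3.5, gc = 43, gp = TRUE, da = 90)
  add("BND09", "A_R27", "A", "active", 3.5, gc = 42.9, gp = TRUE)   # G compl fail
  add("BND10", "A_R27", "A", "active", 3.5, gc = 80, gp = FALSE)    # no complex
  add("BND11", "A_R27", "A", "active", 3.5, gc = 80, gp = TRUE, da = 89.9)
  add("BND12", "A_R27", "A", "intermediate", 2.0, da = 50,
      lig = "agonist")                                              # never rep
  planted <- dplyr::bind_rows(rows)

  n_pad <- n_rows - nrow(planted)
  if (n_pad < 0) rlang::abort("n_rows smaller than the planted catalog.")
  pad <- withr::with_seed(seed, {
    cls <- sample(c("A", "B1", "C", "F"), n_pad, replace = TRUE,
                  prob = c(0.8, 0.1, 0.06, 0.04))
    tibble::tibble(
      structure_id = sprintf("PAD%03d", seq_len(n_pad)),
      receptor = paste0(cls, "_PADR", sample(40:99, n_pad, replace = TRUE)),
      gpcr_class = cls,
      state_annotation = sample(c("inactive", "active", "intermediate"),
                                n_pad, replace = TRUE),
      resolution = round(stats::runif(n_pad, 3.7, 6.0), 2),
      receptor_completeness = round(stats::runif(n_pad, 40, 82), 1),
      gprotein_completeness = NA_real_,
      seq_identity_human = round(stats::runif(n_pad, 30, 89), 1),
      degree_active = round(stats::runif(n_pad, 25, 85), 1),
      ligand_modality = sample(c("apo", "other", "antagonist", "agonist"),
                               n_pad, replace = TRUE),
      has_gprotein_complex = FALSE,
      parent_id = NA_character_
    )
  })
  out <- dplyr::bind_rows(planted, pad)
  out$parent_id[is.na(out$parent_id)] <- out$structure_id[is.na(out$parent_id)]
  out
}

#' Emulated mutant signaling table
#'
#' A two-group alanine-mutant table (six predicted state-changing, six
#' nonstate-changing positions, plus wild type) for epinephrine-induced
#' receptor activation of two G proteins, with triplicate rows per mutant.
#' The group means of the potency shifts are 1.07 versus 0.22 log units for
#' Gs and 1.25 versus 0.25 for G15, and the rank configurations place the
#' exact two-sided Wilcoxon p-values at 18/924 and 4/924 (potency) and
#' 646/924 and 286/924 (efficacy). Replicates are symmetric around each
#' mutant's value so replicate averaging is exact.
#'
#' @param seed integer seed (controls only the replicate jitter pattern).
#' @return mutant table tibble (see [read_mutant_table()] for the schema).
#' @export
make_mutant_table <- function(seed = 1L) {
  state_mut <- c("I3x40A", "I3x46A", "A6x34A", "F6x44A", "N7x49A", "Y7x53A")
  nons_mut <- c("V2x48A", "L3x36A", "T4x56A", "S5x63A", "L6x58A", "V7x40A")
  wt_log <- c(Gs = -7.60, G15 = -7.10)
  wt_emax <- c(Gs = 100, G15 = 100)
  # potency shifts (delta log EC50, positive = reduced potency)
  d_log <- list(
    Gs = list(state = c(0.20, 0.55, 0.90, 1.25, 1.55, 1.97),
              nonstate = c(0.02, 0.08, 0.20, 0.30, 0.30, 0.42)),
    G15 = list(state = c(0.55, 0.85, 1.15, 1.45, 1.65, 1.85),
               nonstate = c(0.00, 0.05, 0.15, 0.25, 0.30, 0.75))
  )
  # efficacy shifts (delta Emax, % of wild type): overlapping groups
  d_emax <- list(
    Gs = list(state = c(-12, -8, -6, -3, -1, 2),
              nonstate = c(-10, -7, -5, -2, 0, 4)),
    G15 = list(state = c(-15, -11, -8, -4, -2, 3),
               nonstate = c(-9, -6, -3, 0, 1, 5))
  )
  jit <- withr::with_seed(seed, stats::runif(1, 0.01, 0.03))
  rows <- list()
  for (gp in c("Gs", "G15")) {
    for (grp in c("state_changing", "nonstate_changing")) {
      key <- if (grp == "state_changing") "state" else "nonstate"
      muts <- if (grp == "state_changing") state_mut else nons_mut
      for (i in seq_along(muts)) {
        lv <- wt_log[[gp]] + d_log[[gp]][[key]][i]
        ev <- wt_emax[[gp]] + d_emax[[gp]][[key]][i]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          mutant = muts[i], group = grp, g_protein = gp,
          replicate = 1:3,
          log_ec50 = lv + c(-jit, 0, jit),
          emax = ev + c(-10 * jit, 0, 10 * jit)
        )
      }
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      mutant = "WT", group = "wt", g_protein = gp, replicate = 1:3,
      log_ec50 = wt_log[[gp]] + c(-jit, 0, jit),
      emax = wt_emax[[gp]] + c(-10 * jit, 0, 10 * jit)
    )
  }
  dplyr::bind_rows(rows)
}

#' Place a synthetic ligand against a receptor position
#'
#' Adds a compact hetero group of `n_atoms` heavy atoms at `distance` from
#' the named position's CA, displaced outward from the bundle centre, to
#' the structure's hetero side table. Used to engineer ligand-interface
#' fixtures.
#'
#' @param s an `annotated_structure`.
#' @param near generic position the ligand should touch.
#' @param n_atoms heavy atoms in the group (default 8).
#' @param distance target distance from the position's CA, Angstrom.
#' @param resname hetero residue name.
#' @return the structure with the ligand appended.
#' @export
add_synthetic_ligand <- function(s, near, n_atoms = 8, distance = 3.5,
                                 resname = "LIG") {
  ca <- atom_coords(s, "CA")
  hit <- ca[ca$generic == near, , drop = FALSE]
  if (nrow(hit) == 0) rlang::abort(paste0("Position ", near, " not in structure."))
  frame <- estimate_membrane_frame(s)
  p0 <- as.numeric(hit[1, c("x", "y", "z")])
  out_dir <- p0 - frame$center
  out_dir <- out_dir - sum(out_dir * frame$normal) * frame$normal
  out_dir <- out_dir / sqrt(sum(out_dir^2))
  base <- p0 + distance * out_dir
  offs <- expand.grid(x = 0:1, y = 0:1, z = 0:1)[seq_len(n_atoms), ] * 1.4
  lig <- tibble::tibble(
    chain = "L", seqnum = max(s$residues$seqnum) + 500L, resname = resname,
    atom = paste0("C", seq_len(n_atoms)), element = "C",
    x = base[1] + offs$x, y = base[2] + offs$y, z = base[3] + offs$z,
    altloc = "", occupancy = 1
  )
  s$hetero <- dplyr::bind_rows(s$hetero, lig)
  s
}

#' Build a decoy G-alpha probe touching given intracellular positions
#'
#' Returns a small synthetic protein chain whose CA/CB atoms sit within
#' contact range of the named positions of the receptor, emulating the
#' alpha5-helix engagement of a G protein.
#'
#' @param s the receptor `annotated_structure`.
#' @param touch generic positions the probe should contact.
#' @param distance probe-atom distance from each position's CA, Angstrom.
#' @return an `annotated_structure` for the probe chain.
#' @export
make_galpha_probe <- function(s, touch = c("3x50", "5x58"), distance = 3.8) {
  ca <- atom_coords(s, "CA")
  frame <- estimate_membrane_frame(s)
  rows_at <- list(); rows_res <- list()
  for (i in seq_along(touch)) {
    hit <- ca[ca$generic == touch[i], , drop = FALSE]
    if (nrow(hit) == 0) rlang::abort(paste0("Position ", touch[i], " missing."))
    p0 <- as.numeric(hit[1, c("x", "y", "z")])
    pos <- p0 - distance * frame$normal # approach from the intracellular side
    rows_at[[i]] <- tibble::tibble(
      chain = "G", seqnum = i, atom = c("CA", "CB"), element = "C",
      x = pos[1] + c(0, 0.8), y = pos[2] + c(0, 0.8), z = pos[3] + c(0, -0.8),
      altloc = "", occupancy = 1
    )
    rows_res[[i]] <- tibble::tibble(
      chain = "G", seqnum = i, resname = "ALA", aa = "A",
      generic = NA_character_, segment = "other"
    )
  }
  new_annotated_structure(paste0(s$structure_id, "_GA"),
                          dplyr::bind_rows(rows_res),
                          dplyr::bind_rows(rows_at))
}
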