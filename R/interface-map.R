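
# any-criterion heavy-atom contact between a residue's atoms and a partner
# atom table (ligand or G-protein): van der Waals overlap, carbon-carbon
# hydrophobic distance, or polar N/O pair at hydrogen-bond range
atoms_touch <- function(ra, pa, params) {
  dx <- outer(ra$x, pa$x, "-"); dy <- outer(ra$y, pa$y, "-")
  dz <- outer(ra$z, pa$z, "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  vdw <- d <= outer(element_radius(ra$element), element_radius(pa$element),
                    "+") + params$vdw_tolerance
  cc <- outer(toupper(ra$element) == "C", toupper(pa$element) == "C", "&") &
    d <= params$hydrophobic_max
  polar_r <- toupper(ra$element) %in% c("N", "O")
  polar_p <- toupper(pa$element) %in% c("N", "O")
  hb <- outer(polar_r, polar_p, "&") & d <= params$hbond_max
  any(vdw | cc | hb)
}

ligand_groups <- function(s, min_heavy_atoms) {
  if (nrow(s$hetero) == 0) return(list())
  groups <- dplyr::group_split(s$hetero,
                               .data$chain, .data$seqnum, .data$resname)
  groups[vapply(groups, nrow, 0L) >= min_heavy_atoms]
}

pocket_zone <- function(s, frame) {
  ca <- atom_coords(s, "CA")
  proj <- as.numeric(
    (as.matrix(ca[, c("x", "y", "z")]) -
       matrix(frame$center, nrow(ca), 3, byrow = TRUE)) %*% frame$normal
  )
  upper <- (proj > 0 & grepl("^TM", ca$segment)) | ca$segment == "ECL2"
  tibble::tibble(position = ca$generic,
                 zone = ifelse(upper, "upper7TM_ECL2", "other"))
}

interface_part <- function(structures, partner_atoms_fun, params) {
  per_structure <- purrr::map(structures, function(s) {
    partners <- partner_atoms_fun(s)
    if (length(partners) == 0) return(NULL)
    frame <- estimate_membrane_frame(s)
    res <- dplyr::filter(s$residues, !is.na(.data$generic))
    at <- dplyr::inner_join(
      s$atoms, dplyr::select(res, "chain", "seqnum", "generic"),
      by = c("chain", "seqnum")
    )
    touching <- vapply(split(at, at$generic), function(ra) {
      any(vapply(partners, function(pa) atoms_touch(ra, pa, params), TRUE))
    }, TRUE)
    list(
      resolved = positions_resolved(s),
      touching = names(touching)[touching],
      zone = pocket_zone(s, frame)
    )
  })
  per_structure[!vapply(per_structure, is.null, TRUE)]
}

summarise_interface <- function(parts) {
  if (length(parts) == 0) {
    return(tibble::tibble(position = character(), freq = numeric(),
                          n_structures = integer(), zone = character()))
  }
  all_pos <- sort_generic(unique(unlist(lapply(parts, `[[`, "resolved"))))
  freq <- vapply(all_pos, function(p) {
    denom <- sum(vapply(parts, function(x) p %in% x$resolved, TRUE))
    hits <- sum(vapply(parts, function(x) p %in% x$touching, TRUE))
    if (denom == 0) 0 else 100 * hits / denom
  }, 0)
  n_struct <- vapply(all_pos, function(p)
    sum(vapply(parts, function(x) p %in% x$resolved, TRUE)), 0L)
  zones <- dplyr::bind_rows(lapply(parts, `[[`, "zone")) |>
    dplyr::filter(!is.na(.data$position)) |>
    dplyr::count(.data$position, .data$zone) |>
    dplyr::group_by(.data$position) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("position", "zone")
  out <- tibble::tibble(position = all_pos, freq = unname(freq),
                        n_structures = unname(n_struct))
  dplyr::left_join(out, zones, by = "position")
}

#' Ligand-interacting positions across structures
#'
#' A receptor position is ligand-interacting in a structure when any of its
#' heavy atoms touches a ligand heavy atom (van der Waals overlap,
#' carbon-carbon hydrophobic range or polar N/O pair at hydrogen-bond
#' range). The frequency is taken over ligand-bearing structures in which
#' the position is resolved. Ligands are non-water hetero groups with at
#' least `min_heavy_atoms` heavy atoms. Positions outside the orthosteric
#' zone (upper transmembrane bundle above the membrane mid, plus ECL2) are
#' flagged `"other"` and dropped by default, as allosteric-site contacts.
#'
#' @param structures list of `annotated_structure`s with hetero side tables.
#' @param params a [contact_params()].
#' @param min_heavy_atoms minimum ligand heavy-atom count (default 6).
#' @param omit_allosteric drop positions outside the orthosteric zone.
#' @return tibble with `position`, `ligand_freq`, `n_structures`, `zone`.
#' @export
ligand_contact_positions <- function(structures, params = contact_params(),
                                     min_heavy_atoms = 6,
                                     omit_allosteric = TRUE) {
  parts <- interface_part(structures,
                          function(s) ligand_groups(s, min_heavy_atoms),
                          params)
  if (length(parts) == 0) {
    rlang::warn("No ligand-bearing structures; empty ligand profile.")
  }
  out <- summarise_interface(parts)
  names(out)[names(out) == "freq"] <- "ligand_freq"
  out <- out[out$ligand_freq > 0, , drop = FALSE]
  if (omit_allosteric) out <- out[out$zone == "upper7TM_ECL2", , drop = FALSE]
  out
}

#' G-protein-interacting positions across complex structures
#'
#' Same contact criterion as [ligand_contact_positions()], but against the
#' heavy atoms of a G-alpha chain supplied per receptor structure (plain
#' chain selection at load time). Frequencies are over complex structures
#' in which the position is resolved.
#'
#' @param structures list of `annotated_structure`s (receptor chains).
#' @param galpha list of `annotated_structure`s of the corresponding
#'   G-alpha chains; use `NULL` entries for structures without a complex.
#' @param params a [contact_params()].
#' @return tibble with `position`, `gprotein_freq`, `n_structures`, `zone`.
#' @export
gprotein_contact_positions <- function(structures, galpha,
                                       params = contact_params()) {
  stopifnot(length(structures) == length(galpha))
  keep <- !vapply(galpha, is.null, TRUE)
  parts <- purrr::map2(structures[keep], galpha[keep], function(s, g) {
    interface_part(list(s), function(.) list(g$atoms), params)[[1]]
  })
  out <- summarise_interface(parts)
  names(out)[names(out) == "freq"] <- "gprotein_freq"
  out[out$gprotein_freq > 0, , drop = FALSE]
}

#' Overlay determinant positions on the functional interfaces
#'
#' Assigns every determinant position of a class to the ligand site, the
#' G-protein site, both, or the transduction path between them, and reports
#' counts and percentages over the class's determinants.
#'
#' @param det a [classify_positions()] determinant map (one class).
#' @param ligand_profile output of [ligand_contact_positions()].
#' @param gprotein_profile output of [gprotein_contact_positions()].
#' @return a list: `assignments` tibble (`position`, `role`, `site`), and
#'   `summary` tibble with `n_determinants`, counts and percentages on
#'   ligand positions, G-protein positions and the transduction path.
#' @export
overlay_determinants <- function(det, ligand_profile, gprotein_profile) {
  lig_pos <- ligand_profile$position[ligand_profile$ligand_freq > 0]
  gp_pos <- gprotein_profile$position[gprotein_profile$gprotein_freq > 0]
  ass <- tibble::tibble(
    position = det$position, role = det$role,
    on_ligand = det$position %in% lig_pos,
    on_gprotein = det$position %in% gp_pos
  )
  ass$site <- dplyr::case_when(
    ass$on_ligand & ass$on_gprotein ~ "both",
    ass$on_ligand ~ "ligand",
    ass$on_gprotein ~ "gprotein",
    TRUE ~ "path"
  )
  n <- nrow(ass)
  summary <- tibble::tibble(
    gpcr_class = unique(det$gpcr_class)[1],
    n_determinants = n,
    n_ligand = sum(ass$on_ligand),
    n_gprotein = sum(ass$on_gprotein),
    n_path = sum(ass$site == "path"),
    pct_ligand = ifelse(n > 0, 100 * sum(ass$on_ligand) / n, NA_real_),
    pct_gprotein = ifelse(n > 0, 100 * sum(ass$on_gprotein) / n, NA_real_),
    pct_path = ifelse(n > 0, 100 * sum(ass$site == "path") / n, NA_real_)
  )
  list(assignments = ass, summary = summary)
}
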