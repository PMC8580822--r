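#' Template selection criteria
#'
#' Quality filters used to pick one representative inactive and one active
#' structure per receptor. Defaults follow the main selection protocol:
#' receptor completeness >= 83% and G-protein completeness >= 43% of generic
#' positions, sequence identity to human > 90%, resolution <= 3.6 Angstrom,
#' degree active <= 20% for inactive and >= 90% for active candidates,
#' state-consistent ligand modality (inverse agonist/antagonist for
#' inactive, agonist for active) and a required G-protein complex for active
#' templates. An alternative published variant of the completeness and
#' resolution cut-offs (>= 86%, <= 4.0 Angstrom) can be configured here; the
#' two variants are deliberately not reconciled.
#'
#' @param min_receptor_completeness percent of generic positions modelled.
#' @param min_gprotein_completeness percent, applied to active candidates.
#' @param min_seq_identity percent identity to the human receptor (strict
#'   `>`).
#' @param max_resolution Angstrom (inclusive `<=`).
#' @param max_degree_active_inactive percent (inclusive) for inactive
#'   candidates.
#' @param min_degree_active_active percent (inclusive) for active
#'   candidates.
#' @param require_gprotein_for_active logical.
#' @param inactive_modalities,active_modalities admissible ligand
#'   modalities per state.
#' @return a `selection_criteria` list.
#' @export
selection_criteria <- function(min_receptor_completeness = 83,
                               min_gprotein_completeness = 43,
                               min_seq_identity = 90,
                               max_resolution = 3.6,
                               max_degree_active_inactive = 20,
                               min_degree_active_active = 90,
                               require_gprotein_for_active = TRUE,
                               inactive_modalities = c("inverse agonist",
                                                       "antagonist"),
                               active_modalities = "agonist") {
  structure(list(
    min_receptor_completeness = min_receptor_completeness,
    min_gprotein_completeness = min_gprotein_completeness,
    min_seq_identity = min_seq_identity,
    max_resolution = max_resolution,
    max_degree_active_inactive = max_degree_active_inactive,
    min_degree_active_active = min_degree_active_active,
    require_gprotein_for_active = require_gprotein_for_active,
    inactive_modalities = inactive_modalities,
    active_modalities = active_modalities
  ), class = "selection_criteria")
}

annotation_required_cols <- c(
  "structure_id", "receptor", "gpcr_class", "state_annotation", "resolution",
  "receptor_completeness", "seq_identity_human", "degree_active",
  "ligand_modality", "has_gprotein_complex"
)

#' Load a structure annotation catalog
#'
#' Reads the annotation table (one row per structure) from TSV or CSV.
#' Optional columns `gprotein_completeness`, `parent_id` (source PDB entry
#' of artificial split entries, e.g. heterodimer monomers) and
#' `release_date` are filled with defaults when absent.
#'
#' @param path TSV/CSV file with the columns of the annotation schema.
#' @return typed tibble of annotation rows.
#' @export
load_annotation <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  rows <- reader(path, show_col_types = FALSE, comment = "#")
  validate_annotation(rows)
}

validate_annotation <- function(rows) {
  rows <- tibble::as_tibble(rows)
  miss <- setdiff(annotation_required_cols, names(rows))
  if (length(miss)) {
    rlang::abort(paste0("Annotation catalog lacks required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (!"gprotein_completeness" %in% names(rows)) {
    rows$gprotein_completeness <- NA_real_
  }
  if (!"parent_id" %in% names(rows)) rows$parent_id <- rows$structure_id
  rows$parent_id[is.na(rows$parent_id)] <- rows$structure_id[is.na(rows$parent_id)]
  num_cols <- c("resolution", "receptor_completeness", "gprotein_completeness",
                "seq_identity_human", "degree_active")
  for (cc in num_cols) rows[[cc]] <- as.numeric(rows[[cc]])
  rows$has_gprotein_complex <- as.logical(rows$has_gprotein_complex)
  pct <- c("receptor_completeness", "gprotein_completeness",
           "seq_identity_human", "degree_active")
  for (cc in pct) {
    bad <- !is.na(rows[[cc]]) & (rows[[cc]] < 0 | rows[[cc]] > 100)
    if (any(bad)) {
      rlang::abort(paste0("Column '", cc, "' outside [0, 100] for: ",
                          paste(rows$structure_id[bad], collapse = ", ")))
    }
  }
  if (any(!is.na(rows$resolution) & rows$resolution <= 0)) {
    rlang::abort("Resolution must be positive.")
  }
  rows
}

passes_criteria <- function(rows, criteria, state) {
  common <- !is.na(rows$resolution) & rows$resolution <= criteria$max_resolution &
    !is.na(rows$receptor_completeness) &
    rows$receptor_completeness >= criteria$min_receptor_completeness &
    !is.na(rows$seq_identity_human) &
    rows$seq_identity_human > criteria$min_seq_identity
  if (state == "inactive") {
    common &
      rows$state_annotation == "inactive" &
      !is.na(rows$degree_active) &
      rows$degree_active <= criteria$max_degree_active_inactive &
      rows$ligand_modality %in% criteria$inactive_modalities
  } else {
    ok <- common &
      rows$state_annotation == "active" &
      !is.na(rows$degree_active) &
      rows$degree_active >= criteria$min_degree_active_active &
      rows$ligand_modality %in% criteria$active_modalities
    if (criteria$require_gprotein_for_active) {
      ok <- ok & rows$has_gprotein_complex %in% TRUE &
        !is.na(rows$gprotein_completeness) &
        rows$gprotein_completeness >= criteria$min_gprotein_completeness
    }
    ok
  }
}

#' Select representative inactive/active templates
#'
#' Applies the [selection_criteria()] per receptor and state and picks one
#' representative among the passing rows: best (lowest) resolution, then
#' highest receptor completeness, then lexicographically smallest structure
#' id. "Intermediate" state annotations are never representative.
#'
#' @param rows annotation tibble (see [load_annotation()]).
#' @param criteria a [selection_criteria()].
#' @return a `template_catalog`: list with the input `rows`, the
#'   `representatives` tibble (`receptor`, `gpcr_class`, `state`,
#'   `structure_id`, `parent_id`, `resolution`, ...) and the `criteria`.
#' @export
select_representatives <- function(rows, criteria = selection_criteria()) {
  rows <- validate_annotation(rows)
  if (nrow(rows) == 0) rlang::abort("Annotation catalog is empty.")
  pick <- function(state) {
    cand <- rows[passes_criteria(rows, criteria, state), , drop = FALSE]
    if (nrow(cand) == 0) return(dplyr::mutate(cand, state = character()))
    cand |>
      dplyr::group_by(.data$receptor) |>
      dplyr::arrange(.data$resolution, dplyr::desc(.data$receptor_completeness),
                     .data$structure_id, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::mutate(state = state)
  }
  reps <- dplyr::bind_rows(pick("inactive"), pick("active"))
  reps <- dplyr::relocate(reps, "receptor", "gpcr_class", "state",
                          "structure_id", "parent_id", "resolution")
  structure(list(rows = rows, representatives = reps, criteria = criteria),
            class = "template_catalog")
}

#' @export
print.template_catalog <- function(x, ...) {
  s <- count_selection(x)
  cat("<template_catalog> ", nrow(x$rows), " annotated structures\n", sep = "")
  cat("  representatives: ", s$n_inactive, " inactive / ",
      s$n_active_entries, " active entries (",
      s$n_active_parents, " distinct active structures)\n", sep = "")
  cat("  receptors with both states: ", s$n_pairs, "\n", sep = "")
  invisible(x)
}

#' Summarise a representative template selection
#'
#' Exact bookkeeping of the selection: representative entry counts per state
#' and class, receptors covered in both states, distinct parent structures
#' (artificial split entries such as heterodimer monomers share a parent),
#' and a resolution tally of the distinct parents. Entry-level and
#' parent-level counts are both reported because split entries make them
#' differ legitimately.
#'
#' @param catalog a [select_representatives()] result.
#' @return a `selection_summary` list: `n_inactive`, `n_active_entries`,
#'   `n_active_parents`, `n_inactive_parents`, `n_templates_used` (distinct
#'   parents over both states), `n_pairs`, `n_le_3p0` (parents at <= 3.0
#'   Angstrom), `per_class` tibble and `resolution_histogram` tibble.
#' @export
count_selection <- function(catalog) {
  stopifnot(inherits(catalog, "template_catalog"))
  reps <- catalog$representatives
  ina <- reps[reps$state == "inactive", , drop = FALSE]
  act <- reps[reps$state == "active", , drop = FALSE]
  parents <- dplyr::distinct(reps, .data$parent_id, .keep_all = TRUE)
  per_class <- reps |>
    dplyr::count(.data$gpcr_class, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L, names_prefix = "n_")
  if (!"n_inactive" %in% names(per_class)) per_class$n_inactive <- 0L
  if (!"n_active" %in% names(per_class)) per_class$n_active <- 0L
  both <- intersect(unique(ina$receptor), unique(act$receptor))
  hist <- tibble::tibble(
    bin = c("<=2.5", "2.5-3.0", "3.0-3.5", ">3.5"),
    n = c(sum(parents$resolution <= 2.5),
          sum(parents$resolution > 2.5 & parents$resolution <= 3.0),
          sum(parents$resolution > 3.0 & parents$resolution <= 3.5),
          sum(parents$resolution > 3.5))
  )
  structure(list(
    n_inactive = nrow(ina),
    n_active_entries = nrow(act),
    n_inactive_parents = dplyr::n_distinct(ina$parent_id),
    n_active_parents = dplyr::n_distinct(act$parent_id),
    n_templates_used = dplyr::n_distinct(reps$parent_id),
    n_pairs = length(both),
    receptors_both_states = sort(both),
    n_le_3p0 = sum(parents$resolution <= 3.0),
    per_class = per_class,
    resolution_histogram = hist
  ), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, ...) {
  cat("Representative templates: ", x$n_inactive, " inactive, ",
      x$n_active_entries, " active entries\n", sep = "")
  cat("Distinct parent structures: ", x$n_templates_used,
      " (", x$n_inactive_parents, " inactive / ", x$n_active_parents,
      " active); ", x$n_le_3p0, " at <= 3.0 A\n", sep = "")
  cat("Receptors with both states: ", x$n_pairs, "\n", sep = "")
  print(x$per_class)
  invisible(x)
}

#' Crude TM6-opening proxy
#'
#' Reports the CA distance between positions 2x46 and 6x37 as a rough,
#' non-canonical indicator of how open the intracellular G-protein-coupling
#' interface is. This is *not* the published degree-active metric (which is
#' consumed as an annotation column, never recomputed here); it is provided
#' only as a sanity-check helper.
#'
#' @param s an `annotated_structure` with generic numbers.
#' @return distance in Angstrom, or `NA` when either position is missing.
#' @export
tm6_opening_proxy <- function(s) {
  ca <- atom_coords(s, "CA")
  a <- ca[ca$generic == "2x46", c("x", "y", "z")]
  b <- ca[ca$generic == "6x37", c("x", "y", "z")]
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}
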