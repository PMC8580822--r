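#' Tidy a template catalog
#'
#' @param x a [select_representatives()] result.
#' @param ... unused.
#' @return the representatives tibble (one row per receptor and state).
#' @export
tidy.template_catalog <- function(x, ...) x$representatives

#' One-row summary of a template selection
#'
#' @param x a [select_representatives()] result.
#' @param ... unused.
#' @return a one-row tibble with the headline selection counts.
#' @export
glance.template_catalog <- function(x, ...) {
  s <- count_selection(x)
  tibble::tibble(
    n_structures = nrow(x$rows),
    n_inactive = s$n_inactive,
    n_active_entries = s$n_active_entries,
    n_active_parents = s$n_active_parents,
    n_templates_used = s$n_templates_used,
    n_pairs = s$n_pairs,
    n_le_3p0 = s$n_le_3p0
  )
}

#' Tidy a mutant group comparison
#'
#' @param x a [compare_mutant_groups()] result.
#' @param ... unused.
#' @return long tibble: one row per G protein, measure and group with the
#'   mean shift, plus the test p-value.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$comparison |>
    tidyr::pivot_longer(
      cols = dplyr::starts_with("mean_"),
      names_to = c("measure", "group"),
      names_pattern = "mean_delta_(log_ec50|emax)_(state|nonstate)",
      values_to = "mean_shift"
    ) |>
    dplyr::mutate(
      measure = ifelse(.data$measure == "log_ec50", "potency", "efficacy"),
      p_value = ifelse(.data$measure == "potency", .data$p_potency,
                       .data$p_efficacy)
    ) |>
    dplyr::select("g_protein", "measure", "group", "mean_shift", "p_value")
}

#' One-row-per-G-protein summary of a mutant comparison
#'
#' @param x a [compare_mutant_groups()] result.
#' @param ... unused.
#' @return the wide comparison tibble.
#' @export
glance.group_comparison <- function(x, ...) x$comparison

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
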