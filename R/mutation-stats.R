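#' Exact two-sample Wilcoxon rank-sum test
#'
#' Rank-sum test on two independent samples using mid-ranks for ties. For
#' group sizes up to `exact_limit` the permutation distribution of the
#' rank-sum is computed exactly by dynamic programming over all
#' `choose(n, n_a)` group assignments (a shift-algorithm count over doubled
#' ranks, so tied mid-ranks stay integral); above it, a normal approximation
#' with tie correction and continuity correction is used. The two-sided
#' p-value doubles the smaller tail probability and caps at 1; under ties
#' the permutation distribution can be asymmetric, which this convention
#' handles deterministically.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (tail of the
#'   rank-sum of `a`).
#' @param exact_limit maximum per-group size for exact enumeration.
#' @return the p-value in (0, 1].
#' @export
wilcoxon_rank_sum_exact <- function(a, b,
                                    alternative = c("two.sided", "less",
                                                    "greater"),
                                    exact_limit = 10) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    rlang::abort("Each group needs at least 2 values.")
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a); nb <- length(b); n <- na + nb
  w <- sum(r[seq_len(na)])

  if (max(na, nb) <= exact_limit) {
    # DP over doubled ranks (integers even with mid-ranks): dp[k+1, s+1] =
    # number of size-k subsets of the pooled ranks with doubled-rank sum s
    r2 <- as.integer(round(2 * r))
    smax <- sum(r2)
    dp <- matrix(0, nrow = na + 1, ncol = smax + 1)
    dp[1, 1] <- 1
    seen <- 0L
    for (ri in r2) {
      seen <- seen + 1L
      for (k in seq(min(na, seen), 1)) {
        nz <- which(dp[k, ] > 0)
        if (length(nz)) dp[k + 1, nz + ri] <- dp[k + 1, nz + ri] + dp[k, nz]
      }
    }
    counts <- dp[na + 1, ]
    total <- sum(counts)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq(w2 + 1, smax + 1)]) / total
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      less = p_le,
      greater = p_ge
    )
    return(p)
  }

  # normal approximation with tie and continuity corrections
  mu <- na * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z_num <- w - mu
  cc <- 0.5
  p_le <- stats::pnorm((z_num + cc) / sqrt(sigma2))
  p_ge <- stats::pnorm((z_num - cc) / sqrt(sigma2), lower.tail = FALSE)
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    less = p_le,
    greater = p_ge
  )
}

#' Read a mutant signaling table
#'
#' @param path TSV with columns `mutant`, `group` (`state_changing`,
#'   `nonstate_changing` or `wt`), `g_protein`, `log_ec50`, `emax` and
#'   optionally `replicate`.
#' @return typed tibble.
#' @export
read_mutant_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("mutant", "group", "g_protein", "log_ec50", "emax")
  miss <- setdiff(req, names(tab))
  if (length(miss)) {
    rlang::abort(paste0("Mutant table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- 1L
  tab
}

#' Potency and efficacy shifts relative to wild type
#'
#' Averages replicates per mutant and G protein, then subtracts the
#' wild-type values: `delta_log_ec50 = log_ec50(mutant) - log_ec50(WT)`
#' (positive = reduced potency) and analogously `delta_emax`.
#'
#' @param records mutant table (see [read_mutant_table()]).
#' @return tibble with one row per mutant and G protein: `mutant`, `group`,
#'   `g_protein`, `delta_log_ec50`, `delta_emax`.
#' @export
delta_from_wt <- function(records) {
  records <- tibble::as_tibble(records)
  means <- records |>
    dplyr::group_by(.data$mutant, .data$group, .data$g_protein) |>
    dplyr::summarise(log_ec50 = mean(.data$log_ec50),
                     emax = mean(.data$emax), .groups = "drop")
  wt <- means[means$group == "wt", , drop = FALSE]
  muts <- means[means$group != "wt", , drop = FALSE]
  missing_wt <- setdiff(unique(muts$g_protein), unique(wt$g_protein))
  if (length(missing_wt)) {
    rlang::abort(paste0("No wild-type reference for G protein(s): ",
                        paste(missing_wt, collapse = ", ")))
  }
  wt <- dplyr::select(wt, "g_protein", wt_log_ec50 = "log_ec50",
                      wt_emax = "emax")
  muts |>
    dplyr::left_join(wt, by = "g_protein") |>
    dplyr::transmute(
      .data$mutant, .data$group, .data$g_protein,
      delta_log_ec50 = .data$log_ec50 - .data$wt_log_ec50,
      delta_emax = .data$emax - .data$wt_emax
    )
}

#' Compare state-changing and nonstate-changing mutant groups
#'
#' For each G protein, reports the group means of the potency and efficacy
#' shifts and the two-sided exact Wilcoxon rank-sum p-values comparing the
#' two groups.
#'
#' @param deltas output of [delta_from_wt()].
#' @return a `group_comparison` object wrapping a tibble with one row per
#'   G protein: mean shifts per group, `p_potency`, `p_efficacy`, `n_state`,
#'   `n_nonstate`.
#' @export
compare_mutant_groups <- function(deltas) {
  res <- deltas |>
    dplyr::group_by(.data$g_protein) |>
    dplyr::group_modify(function(d, key) {
      st <- d[d$group == "state_changing", , drop = FALSE]
      ns <- d[d$group == "nonstate_changing", , drop = FALSE]
      tibble::tibble(
        n_state = nrow(st), n_nonstate = nrow(ns),
        mean_delta_log_ec50_state = mean(st$delta_log_ec50),
        mean_delta_log_ec50_nonstate = mean(ns$delta_log_ec50),
        mean_delta_emax_state = mean(st$delta_emax),
        mean_delta_emax_nonstate = mean(ns$delta_emax),
        p_potency = wilcoxon_rank_sum_exact(st$delta_log_ec50,
                                            ns$delta_log_ec50),
        p_efficacy = wilcoxon_rank_sum_exact(st$delta_emax, ns$delta_emax)
      )
    }) |>
    dplyr::ungroup()
  structure(list(comparison = res, deltas = deltas),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> exact two-sided Wilcoxon rank-sum\n")
  print(x$comparison)
  invisible(x)
}
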