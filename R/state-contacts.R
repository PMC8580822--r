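#' Class frequency-difference thresholds
#'
#' State-specific contacts are residue pairs whose contact frequency differs
#' between the inactive and active representative sets by at least the class
#' threshold. The thresholds are calibrated to the structural coverage of
#' each class: A 40, B1 67, C 75, F 100 percentage points, together with a
#' 30% amino-acid-pair conservation cut-off.
#'
#' @param A,B1,C,F percentage-point thresholds per class.
#' @param conservation_min minimum fraction of class receptors carrying one
#'   of the observed amino-acid pairs.
#' @return a `class_thresholds` list.
#' @export
class_thresholds <- function(A = 40, B1 = 67, C = 75, F = 100,
                             conservation_min = 0.30) {
  th <- c(A = A, B1 = B1, C = C, F = F)
  if (any(th <= 0 | th > 100)) {
    rlang::abort("Class thresholds must lie in (0, 100].")
  }
  structure(list(thresholds = th, conservation_min = conservation_min),
            class = "class_thresholds")
}

contact_pair_table <- function(cs) {
  ct <- cs$contacts
  if (nrow(ct) == 0) {
    return(tibble::tibble(pos_a = character(), pos_b = character(),
                          aa_a = character(), aa_b = character()))
  }
  dplyr::distinct(ct, .data$pos_a, .data$pos_b, .data$aa_a, .data$aa_b)
}

#' Per-class inactive/active contact frequencies
#'
#' For every generic residue pair observed in at least one template, compute
#' the contact frequency (percent) separately over the inactive and active
#' representative sets. The denominator for a pair and state is, by default,
#' the number of templates in which both positions are resolved (present
#' with at least one heavy atom), so unmodelled loops do not deflate
#' frequencies; set `denominator = "all"` to divide by all templates of the
#' state. A pair contributes one count per template regardless of how many
#' interaction types it satisfies.
#'
#' @param inactive_sets,active_sets lists of `contact_set` objects, one
#'   representative per receptor.
#' @param gpcr_class class label carried into the records.
#' @param denominator `"resolved"` (default) or `"all"`.
#' @return tibble with columns `gpcr_class`, `pos_a`, `pos_b`,
#'   `freq_inactive`, `freq_active`, `diff` (= inactive - active, percentage
#'   points), `n_inactive_obs`, `n_active_obs`, and the list-column
#'   `observed_aa_pairs` of `"X-Y"` amino-acid pairs seen forming the
#'   contact.
#' @export
compute_pair_frequencies <- function(inactive_sets, active_sets, gpcr_class,
                                     denominator = c("resolved", "all")) {
  denominator <- match.arg(denominator)
  if (length(inactive_sets) == 0 || length(active_sets) == 0) {
    rlang::abort("Both states need at least one template; frequency undefined.")
  }
  gather <- function(sets, state) {
    purrr::imap_dfr(sets, function(cs, i) {
      pt <- contact_pair_table(cs)
      if (nrow(pt)) pt$template <- paste0(state, i)
      pt
    })
  }
  all_pairs <- dplyr::bind_rows(gather(inactive_sets, "i"), gather(active_sets, "a"))
  if (nrow(all_pairs) == 0) {
    return(tibble::tibble(
      gpcr_class = character(), pos_a = character(), pos_b = character(),
      freq_inactive = numeric(), freq_active = numeric(), diff = numeric(),
      n_inactive_obs = integer(), n_active_obs = integer(),
      observed_aa_pairs = list()
    ))
  }
  pairs <- dplyr::distinct(all_pairs, .data$pos_a, .data$pos_b)

  count_state <- function(sets) {
    resolved <- lapply(sets, function(cs) cs$positions_resolved)
    formed <- lapply(sets, function(cs) {
      pt <- contact_pair_table(cs)
      paste(pt$pos_a, pt$pos_b)
    })
    key <- paste(pairs$pos_a, pairs$pos_b)
    n_obs <- vapply(seq_len(nrow(pairs)), function(k) {
      if (denominator == "all") return(length(sets))
      sum(vapply(resolved, function(r)
        pairs$pos_a[k] %in% r && pairs$pos_b[k] %in% r, TRUE))
    }, 0L)
    n_formed <- vapply(key, function(k)
      sum(vapply(formed, function(f) k %in% f, TRUE)), 0L, USE.NAMES = FALSE)
    list(n_obs = n_obs, n_formed = n_formed)
  }
  ci <- count_state(inactive_sets)
  ca <- count_state(active_sets)

  aa_pairs <- all_pairs |>
    dplyr::mutate(aa_pair = paste0(.data$aa_a, "-", .data$aa_b)) |>
    dplyr::group_by(.data$pos_a, .data$pos_b) |>
    dplyr::summarise(observed_aa_pairs = list(sort(unique(.data$aa_pair))),
                     .groups = "drop")

  out <- pairs
  out$gpcr_class <- gpcr_class
  out$freq_inactive <- ifelse(ci$n_obs > 0, 100 * ci$n_formed / ci$n_obs, 0)
  out$freq_active <- ifelse(ca$n_obs > 0, 100 * ca$n_formed / ca$n_obs, 0)
  out$diff <- out$freq_inactive - out$freq_active
  out$n_inactive_obs <- ci$n_obs
  out$n_active_obs <- ca$n_obs
  out <- dplyr::left_join(out, aa_pairs, by = c("pos_a", "pos_b"))
  out <- out[out$freq_inactive > 0 | out$freq_active > 0, , drop = FALSE]
  dplyr::relocate(out, "gpcr_class")
}

#' Filter pair frequencies to state-specific contacts
#'
#' Keeps pairs whose absolute frequency difference reaches the class
#' threshold (inclusive) and labels them `inactivating` (more frequent in
#' the inactive state) or `activating`. Records are sorted by decreasing
#' `|diff|`, ties broken by canonical pair order.
#'
#' @param records output of [compute_pair_frequencies()] for one class.
#' @param thresholds a [class_thresholds()] object.
#' @return the retained records with an added `label` column.
#' @export
filter_state_specific <- function(records, thresholds = class_thresholds()) {
  cls <- unique(records$gpcr_class)
  if (length(cls) > 1) {
    rlang::abort("Records span several classes; filter one class at a time.")
  }
  if (nrow(records) == 0) {
    records$label <- character()
    return(records)
  }
  if (!cls %in% names(thresholds$thresholds)) {
    rlang::abort(paste0("No frequency-difference threshold configured for class '",
                        cls, "'."))
  }
  th <- thresholds$thresholds[[cls]]
  out <- records[abs(records$diff) >= th, , drop = FALSE]
  out$label <- ifelse(out$diff > 0, "inactivating", "activating")
  out[order(-abs(out$diff), generic_order_key(out$pos_a),
            generic_order_key(out$pos_b)), ]
}

#' Conservation filter on state-specific contacts
#'
#' A contact is kept when at least `min_fraction` of the class's receptors
#' carry one of the amino-acid pairs observed to form it in the structures.
#' Receptors missing either position in the alignment count as
#' non-matching. The computed fraction is attached as `conservation`.
#'
#' @param records state-specific records with `observed_aa_pairs`.
#' @param alignment class alignment tibble with columns `receptor`,
#'   `position` (generic label), `aa`.
#' @param min_fraction conservation cut-off (default 0.30, inclusive).
#' @return the retained records with a `conservation` column.
#' @export
conservation_filter <- function(records, alignment, min_fraction = 0.30) {
  alignment <- tibble::as_tibble(alignment)
  if (nrow(alignment) == 0) rlang::abort("Empty class alignment.")
  receptors <- unique(alignment$receptor)
  n_rec <- length(receptors)
  aln <- tidyr::pivot_wider(alignment, id_cols = "receptor",
                            names_from = "position", values_from = "aa")
  frac <- vapply(seq_len(nrow(records)), function(k) {
    pa <- records$pos_a[k]; pb <- records$pos_b[k]
    if (!pa %in% names(aln) || !pb %in% names(aln)) return(0)
    pair <- paste0(aln[[pa]], "-", aln[[pb]])
    sum(pair %in% records$observed_aa_pairs[[k]], na.rm = TRUE) / n_rec
  }, 0)
  records$conservation <- frac
  records[frac >= min_fraction, , drop = FALSE]
}

#' Classify determinant positions into inactivators, activators and switches
#'
#' Every position participating in a retained state-specific contact is a
#' state determinant. A position whose contacts are all inactivating is an
#' `inactivator`, all activating an `activator`, and one with at least one
#' contact of each kind a `switch` (contacts across both states).
#'
#' @param records thresholded and conservation-filtered records (with
#'   `label`).
#' @param alignment optional class alignment used to attach each position's
#'   consensus amino acid and its conservation percentage.
#' @return a `determinant_map` tibble: `gpcr_class`, `position`, `segment`,
#'   `role`, `n_inactivating`, `n_activating`, `consensus_aa`,
#'   `consensus_conservation`.
#' @export
classify_positions <- function(records, alignment = NULL) {
  long <- dplyr::bind_rows(
    dplyr::transmute(records, gpcr_class = .data$gpcr_class,
                     position = .data$pos_a, label = .data$label),
    dplyr::transmute(records, gpcr_class = .data$gpcr_class,
                     position = .data$pos_b, label = .data$label)
  )
  out <- long |>
    dplyr::group_by(.data$gpcr_class, .data$position) |>
    dplyr::summarise(
      n_inactivating = sum(.data$label == "inactivating"),
      n_activating = sum(.data$label == "activating"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      role = dplyr::case_when(
        .data$n_inactivating > 0 & .data$n_activating > 0 ~ "switch",
        .data$n_inactivating > 0 ~ "inactivator",
        TRUE ~ "activator"
      ),
      segment = generic_segment(.data$position)
    )
  if (!is.null(alignment)) {
    cons <- tibble::as_tibble(alignment) |>
      dplyr::group_by(position = .data$position) |>
      dplyr::count(.data$aa) |>
      dplyr::mutate(frac = .data$n / sum(.data$n)) |>
      dplyr::slice_max(.data$frac, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$position, consensus_aa = .data$aa,
                       consensus_conservation = 100 * .data$frac)
    out <- dplyr::left_join(out, cons, by = "position")
  } else {
    out$consensus_aa <- NA_character_
    out$consensus_conservation <- NA_real_
  }
  out <- out[order(generic_order_key(out$position)), ]
  out <- dplyr::relocate(out, "gpcr_class", "position", "segment", "role")
  class(out) <- c("determinant_map", class(out))
  out
}

#' Cross-class overlap of determinant positions
#'
#' Matches determinant positions by identical generic label across class
#' maps and counts positions unique to one class, shared by two, three or
#' four, overall and per role.
#'
#' @param maps list of [classify_positions()] results (one per class).
#' @return list with `total_positions`, tibble `by_sharing` (`n_classes`,
#'   `n_positions`) and tibble `by_role_sharing` (`role`, `n_classes`,
#'   `n_positions`, counting a position under each role it takes).
#' @export
cross_class_overlap <- function(maps) {
  if (length(maps) < 2) rlang::abort("Need at least two class maps.")
  all <- dplyr::bind_rows(maps)
  shared <- all |>
    dplyr::distinct(.data$gpcr_class, .data$position) |>
    dplyr::count(.data$position, name = "n_classes")
  by_sharing <- shared |>
    dplyr::count(.data$n_classes, name = "n_positions") |>
    dplyr::arrange(.data$n_classes)
  by_role <- all |>
    dplyr::distinct(.data$gpcr_class, .data$position, .data$role) |>
    dplyr::count(.data$position, .data$role, name = "n_classes") |>
    dplyr::count(.data$role, .data$n_classes, name = "n_positions")
  list(
    total_positions = nrow(shared),
    by_sharing = by_sharing,
    by_role_sharing = by_role
  )
}

#' Aggregate state-specific contacts into a segment network
#'
#' Collapses residue-pair records to receptor-segment edges (TM1-TM7, H8
#' and loops), counting inactivating and activating contacts per edge, and
#' flags segments holding contacts in both states ("segment switches").
#'
#' @param records thresholded (and typically conservation-filtered) records.
#' @return a list per the segment network: `edges` tibble (`gpcr_class`,
#'   `segment_a`, `segment_b`, `n_inactivating`, `n_activating`),
#'   `segments` tibble with per-segment tallies and `switch` flag, and
#'   `inactivating_fraction` tibble per class (overall and inter-segment
#'   only).
#' @export
aggregate_segment_network <- function(records) {
  if (nrow(records) == 0) {
    return(list(edges = tibble::tibble(), segments = tibble::tibble(),
                inactivating_fraction = tibble::tibble()))
  }
  rec <- dplyr::mutate(
    records,
    segment_a = generic_segment(.data$pos_a),
    segment_b = generic_segment(.data$pos_b)
  )
  edges <- rec |>
    dplyr::group_by(.data$gpcr_class, .data$segment_a, .data$segment_b) |>
    dplyr::summarise(
      n_inactivating = sum(.data$label == "inactivating"),
      n_activating = sum(.data$label == "activating"),
      .groups = "drop"
    )
  seg_long <- dplyr::bind_rows(
    dplyr::select(rec, "gpcr_class", segment = "segment_a", "label",
                  other = "segment_b"),
    dplyr::select(rec, "gpcr_class", segment = "segment_b", "label",
                  other = "segment_a")
  )
  segments <- seg_long |>
    dplyr::group_by(.data$gpcr_class, .data$segment) |>
    dplyr::summarise(
      n_inactivating = sum(.data$label == "inactivating"),
      n_activating = sum(.data$label == "activating"),
      n_inter_segment = sum(.data$other != .data$segment),
      switch = .data$n_inactivating > 0 & .data$n_activating > 0,
      .groups = "drop"
    )
  frac <- rec |>
    dplyr::group_by(.data$gpcr_class) |>
    dplyr::summarise(
      n_contacts = dplyr::n(),
      inactivating_fraction = 100 * sum(.data$label == "inactivating") / dplyr::n(),
      inactivating_fraction_inter = {
        inter <- .data$segment_a != .data$segment_b
        if (any(inter)) 100 * sum(.data$label[inter] == "inactivating") / sum(inter)
        else NA_real_
      },
      .groups = "drop"
    )
  list(edges = edges, segments = segments, inactivating_fraction = frac)
}
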