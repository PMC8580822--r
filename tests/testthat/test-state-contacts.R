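programmed_ensemble <- function(seed = 3) {
  pairs <- tibble::tibble(
    pos_a = c("1x49", "3x50", "6x48", "2x50", "5x58"),
    pos_b = c("7x50", "6x37", "7x53", "7x49", "7x53"),
    k_inactive = c(4L, 3L, 1L, 2L, 0L),
    k_active = c(0L, 0L, 2L, 2L, 2L),
    aa_a = c("L", "R", "W", "D", "Y"),
    aa_b = c("P", "A", "Y", "N", "Y")
  )
  make_contact_ensemble(
    n_inactive = 4, n_active = 2, pairs = pairs,
    dropout = tibble::tibble(position = "3x50", k_inactive = 1L, k_active = 0L),
    gpcr_class = "A", seed = seed
  )
}

test_that("programmed frequencies are recovered exactly, dropout shrinks denominators", {
  ens <- programmed_ensemble()
  fr <- compute_pair_frequencies(ens$inactive, ens$active, "A")
  get <- function(a, b) fr[fr$pos_a == a & fr$pos_b == b, ]
  expect_equal(get("1x49", "7x50")$freq_inactive, 100)
  expect_equal(get("1x49", "7x50")$freq_active, 0)
  expect_equal(get("1x49", "7x50")$diff, 100)
  # dropout of 3x50 in 1 of 4 inactive templates: denominator 3, formed 3
  expect_equal(get("3x50", "6x37")$n_inactive_obs, 3L)
  expect_equal(get("3x50", "6x37")$freq_inactive, 100)
  expect_equal(get("6x48", "7x53")$freq_inactive, 25)
  expect_equal(get("6x48", "7x53")$freq_active, 100)
  expect_equal(get("6x48", "7x53")$diff, -75)
  # diff is exactly freq_inactive - freq_active for every record
  expect_equal(fr$diff, fr$freq_inactive - fr$freq_active)
  # the "all templates" denominator deflates dropped-out pairs instead
  fr_all <- compute_pair_frequencies(ens$inactive, ens$active, "A",
                                     denominator = "all")
  expect_equal(fr_all[fr_all$pos_a == "3x50", ]$freq_inactive, 75)
})

test_that("frequencies are invariant to template order", {
  ens <- programmed_ensemble()
  fr1 <- compute_pair_frequencies(ens$inactive, ens$active, "A")
  fr2 <- compute_pair_frequencies(rev(ens$inactive), rev(ens$active), "A")
  expect_equal(dplyr::arrange(fr1, pos_a, pos_b),
               dplyr::arrange(fr2, pos_a, pos_b))
})

test_that("empty template lists are an error", {
  ens <- programmed_ensemble()
  expect_error(compute_pair_frequencies(list(), ens$active, "A"), "at least one")
})

test_that("threshold filter keeps |diff| at the class threshold inclusively", {
  rec <- tibble::tibble(
    gpcr_class = "A",
    pos_a = c("1x50", "2x50", "3x50", "4x50"),
    pos_b = c("7x50", "7x51", "7x52", "7x53"),
    freq_inactive = c(40, 39.9, 0, 100),
    freq_active = c(0, 0, 100, 0),
    diff = c(40, 39.9, -100, 100),
    n_inactive_obs = 10L, n_active_obs = 10L,
    observed_aa_pairs = list("A-A")
  )
  out <- filter_state_specific(rec, class_thresholds())
  expect_equal(sort(out$pos_a), c("1x50", "3x50", "4x50"))
  expect_equal(out$label[out$pos_a == "1x50"], "inactivating")
  expect_equal(out$label[out$pos_a == "3x50"], "activating")
  # sorted by |diff| descending
  expect_equal(abs(out$diff), sort(abs(out$diff), decreasing = TRUE))
  # class F keeps only full flips
  recF <- dplyr::mutate(rec, gpcr_class = "F")
  outF <- filter_state_specific(recF, class_thresholds())
  expect_equal(sort(abs(outF$diff)), c(100, 100))
  expect_error(filter_state_specific(dplyr::mutate(rec, gpcr_class = "Z")),
               "threshold")
})

test_that("conservation filter applies the 30% cut-off at the boundary", {
  rec <- tibble::tibble(
    gpcr_class = "A", pos_a = "3x50", pos_b = "6x37",
    freq_inactive = 100, freq_active = 0, diff = 100,
    n_inactive_obs = 4L, n_active_obs = 2L,
    observed_aa_pairs = list("R-A"), label = "inactivating"
  )
  aln_at <- tibble::tibble(
    receptor = rep(sprintf("R%02d", 1:10), each = 2),
    position = rep(c("3x50", "6x37"), 10),
    aa = c(rep(c("R", "A"), 3), rep(c("K", "A"), 7))
  )
  out <- conservation_filter(rec, aln_at, 0.30)
  expect_equal(nrow(out), 1)
  expect_equal(out$conservation, 0.30)
  # 2 of 10 matching drops the record
  aln_below <- aln_at
  aln_below$aa[aln_below$receptor == "R03" & aln_below$position == "3x50"] <- "K"
  expect_equal(nrow(conservation_filter(rec, aln_below, 0.30)), 0)
  # all matching keeps with fraction 1
  aln_full <- dplyr::mutate(aln_at, aa = rep(c("R", "A"), 10))
  expect_equal(conservation_filter(rec, aln_full, 0.30)$conservation, 1)
  # a position absent from the alignment counts as non-matching
  expect_equal(nrow(conservation_filter(
    rec, aln_at[aln_at$position == "3x50", ], 0.30)), 0)
  expect_error(conservation_filter(rec, aln_at[0, ], 0.30), "Empty")
})

test_that("roles partition determinants; switch iff both contact kinds", {
  rec <- tibble::tibble(
    gpcr_class = "A",
    pos_a = c("3x46", "7x53", "7x53"),
    pos_b = c("7x53", "7x54", "5x58"),
    freq_inactive = c(80, 100, 0), freq_active = c(0, 0, 70),
    diff = c(80, 100, -70),
    n_inactive_obs = 10L, n_active_obs = 10L,
    observed_aa_pairs = list("I-Y", "Y-A", "Y-Y"),
    label = c("inactivating", "inactivating", "activating")
  )
  dm <- classify_positions(rec)
  expect_equal(dm$role[dm$position == "7x53"], "switch")
  expect_equal(dm$role[dm$position == "3x46"], "inactivator")
  expect_equal(dm$role[dm$position == "5x58"], "activator")
  expect_true(all(dm$role %in% c("inactivator", "activator", "switch")))
  expect_false(anyDuplicated(dm$position) > 0)
  sw <- dm$n_inactivating > 0 & dm$n_activating > 0
  expect_equal(dm$role == "switch", sw)
})

test_that("roles partition holds on randomized programmed ensembles", {
  for (seed in 1:10) {
    labels <- withr::with_seed(seed, sample(c(1, -1), 8, replace = TRUE))
    pairs <- tibble::tibble(
      pos_a = paste0(1:8, "x45"),
      pos_b = paste0(rep(c(2, 5), 4), "x", 50:57),
      k_inactive = ifelse(labels > 0, 4L, 0L),
      k_active = ifelse(labels > 0, 0L, 2L)
    )
    ens <- make_contact_ensemble(4, 2, pairs, gpcr_class = "F", seed = seed)
    fr <- compute_pair_frequencies(ens$inactive, ens$active, "F")
    sp <- filter_state_specific(fr, class_thresholds())
    dm <- classify_positions(sp)
    expect_equal(dm$role == "switch",
                 dm$n_inactivating > 0 & dm$n_activating > 0)
    expect_true(all(dm$role[dm$n_activating == 0] == "inactivator"))
    expect_true(all(dm$role[dm$n_inactivating == 0] == "activator"))
  }
})

test_that("cross-class overlap counts shared generic positions", {
  mapA <- tibble::tibble(gpcr_class = "A",
                         position = c("3x50", "6x48", "7x53"),
                         role = c("switch", "activator", "switch"))
  mapB <- tibble::tibble(gpcr_class = "B1",
                         position = c("3x50", "6x48", "5x54"),
                         role = c("switch", "inactivator", "switch"))
  ov <- cross_class_overlap(list(mapA, mapB))
  expect_equal(ov$total_positions, 4)
  expect_equal(ov$by_sharing$n_positions[ov$by_sharing$n_classes == 2], 2)
  expect_equal(ov$by_sharing$n_positions[ov$by_sharing$n_classes == 1], 2)
  # disjoint maps are all unique
  mapC <- tibble::tibble(gpcr_class = "C", position = c("1x50", "2x50"),
                         role = "inactivator")
  ov2 <- cross_class_overlap(list(mapA, dplyr::mutate(mapC, gpcr_class = "C")))
  expect_equal(ov2$by_sharing$n_positions, 5)
  expect_error(cross_class_overlap(list(mapA)), "two class maps")
})

test_that("segment network aggregates edges and flags segment switches", {
  rec <- tibble::tibble(
    gpcr_class = "A",
    pos_a = c("3x46", "3x50", "6x30", "6x48"),
    pos_b = c("6x37", "6x34", "6x34", "7x45"),
    freq_inactive = c(100, 100, 100, 0), freq_active = c(0, 0, 0, 100),
    diff = c(100, 100, 100, -100),
    n_inactive_obs = 4L, n_active_obs = 2L,
    observed_aa_pairs = list("A-A"),
    label = c("inactivating", "inactivating", "inactivating", "activating")
  )
  net <- aggregate_segment_network(rec)
  e36 <- net$edges[net$edges$segment_a == "TM3" & net$edges$segment_b == "TM6", ]
  expect_equal(e36$n_inactivating, 2)
  intra6 <- net$edges[net$edges$segment_a == "TM6" &
                        net$edges$segment_b == "TM6", ]
  expect_equal(intra6$n_inactivating, 1)
  seg6 <- net$segments[net$segments$segment == "TM6", ]
  expect_true(seg6$switch)   # TM6 holds contacts in both states
  seg3 <- net$segments[net$segments$segment == "TM3", ]
  expect_false(seg3$switch)
  expect_equal(net$inactivating_fraction$inactivating_fraction, 75)
  # a class with only inactivating contacts has fraction 100
  net2 <- aggregate_segment_network(rec[rec$label == "inactivating", ])
  expect_equal(net2$inactivating_fraction$inactivating_fraction, 100)
  # edge counts conserve the number of underlying pairs
  expect_equal(sum(net$edges$n_inactivating) + sum(net$edges$n_activating),
               nrow(rec))
})
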