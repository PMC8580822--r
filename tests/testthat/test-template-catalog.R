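test_that("each selection criterion behaves correctly at its boundary", {
  crit <- selection_criteria()
  base <- function(...) annotation_row("X1", ...)

  at_bounds <- annotation_row("X1", resolution = 3.60, rc = 83, si = 90.1)
  tc <- select_representatives(at_bounds, crit)
  expect_equal(tc$representatives$structure_id, "X1")

  cases <- list(
    annotation_row("X1", resolution = 3.61),          # resolution above cutoff
    annotation_row("X1", rc = 82.9),                  # completeness below
    annotation_row("X1", si = 90),                    # identity strict >
    annotation_row("X1", da = 20.1),                  # degree active above
    annotation_row("X1", lig = "agonist"),            # wrong modality
    annotation_row("X1", state = "intermediate", da = 50, lig = "agonist")
  )
  for (rows in cases) {
    expect_equal(nrow(select_representatives(rows, crit)$representatives), 0)
  }
  # inclusive boundaries pass
  ok <- list(
    annotation_row("X1", resolution = 3.60),
    annotation_row("X1", rc = 83),
    annotation_row("X1", da = 20)
  )
  for (rows in ok) {
    expect_equal(nrow(select_representatives(rows, crit)$representatives), 1)
  }
})

test_that("active templates require an agonist-bound G-protein complex", {
  crit <- selection_criteria()
  no_gp <- annotation_row("A1", state = "active", gc = 80, gp = FALSE)
  expect_equal(nrow(select_representatives(no_gp, crit)$representatives), 0)
  low_gc <- annotation_row("A1", state = "active", gc = 42.9, gp = TRUE)
  expect_equal(nrow(select_representatives(low_gc, crit)$representatives), 0)
  at_gc <- annotation_row("A1", state = "active", gc = 43, gp = TRUE)
  expect_equal(nrow(select_representatives(at_gc, crit)$representatives), 1)
  low_da <- annotation_row("A1", state = "active", gc = 80, gp = TRUE, da = 89.9)
  expect_equal(nrow(select_representatives(low_da, crit)$representatives), 0)
})

test_that("tie-break picks best resolution, then completeness, then id", {
  rows <- dplyr::bind_rows(
    annotation_row("B1", resolution = 3.1),
    annotation_row("B2", resolution = 2.8)
  )
  tc <- select_representatives(rows)
  expect_equal(tc$representatives$structure_id, "B2")

  rows2 <- dplyr::bind_rows(
    annotation_row("C1", resolution = 2.8, rc = 90),
    annotation_row("C2", resolution = 2.8, rc = 95)
  )
  expect_equal(select_representatives(rows2)$representatives$structure_id, "C2")

  rows3 <- dplyr::bind_rows(
    annotation_row("D2", resolution = 2.8),
    annotation_row("D1", resolution = 2.8)
  )
  expect_equal(select_representatives(rows3)$representatives$structure_id, "D1")
})

test_that("relaxing any single threshold never shrinks the selection", {
  rows <- make_annotation_catalog(seed = 7)
  n_rep <- function(crit) {
    nrow(select_representatives(rows, crit)$representatives)
  }
  base <- n_rep(selection_criteria())
  expect_gte(n_rep(selection_criteria(max_resolution = 4.5)), base)
  expect_gte(n_rep(selection_criteria(min_receptor_completeness = 60)), base)
  expect_gte(n_rep(selection_criteria(min_seq_identity = 50)), base)
  expect_gte(n_rep(selection_criteria(max_degree_active_inactive = 40)), base)
  expect_gte(n_rep(selection_criteria(min_degree_active_active = 70)), base)
  expect_gte(n_rep(selection_criteria(require_gprotein_for_active = FALSE)),
             base)
})

test_that("selection is deterministic and the summary does exact bookkeeping", {
  rows <- make_annotation_catalog(seed = 1)
  t1 <- select_representatives(rows)
  t2 <- select_representatives(rows)
  expect_identical(t1$representatives, t2$representatives)

  s <- count_selection(t1)
  expect_equal(s$n_inactive, 42)
  expect_equal(s$n_active_entries, 28)       # entry-level count
  expect_equal(s$n_active_parents, 27)       # distinct parent structures
  expect_equal(s$n_templates_used, 68)
  expect_equal(s$n_pairs, 13)
  expect_equal(s$n_le_3p0, 45)
  pc <- s$per_class[order(s$per_class$gpcr_class), ]
  expect_equal(pc$n_inactive, c(33L, 3L, 4L, 2L))
  expect_equal(pc$n_active, c(14L, 10L, 2L, 2L))
})

test_that("annotation loading types columns and flags schema problems", {
  d <- withr::local_tempdir()
  rows <- make_annotation_catalog(seed = 2)
  f <- file.path(d, "cat.tsv")
  readr::write_tsv(rows, f)
  back <- load_annotation(f)
  expect_equal(nrow(back), 510)
  expect_type(back$resolution, "double")
  expect_type(back$has_gprotein_complex, "logical")

  bad <- rows[, setdiff(names(rows), "resolution")]
  f2 <- file.path(d, "bad.tsv")
  readr::write_tsv(bad, f2)
  expect_error(load_annotation(f2), "resolution")
})

test_that("tidy/glance expose the selection as tibbles", {
  tc <- select_representatives(make_annotation_catalog(seed = 1))
  td <- generics::tidy(tc)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("receptor", "state", "structure_id") %in% names(td)))
  g <- generics::glance(tc)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_pairs, 13)
})
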