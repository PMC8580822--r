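test_that("far-apart residues never contact; engineered pairs get typed", {
  s <- make_test_bundle()
  cs <- detect_contacts(s)
  expect_s3_class(cs, "contact_set")
  # designed Asp 3x49 - Arg 3x50: adjacent residues contacting through side
  # chains; must be typed ionic and hydrogen-bonded
  dr <- cs$contacts[cs$contacts$pos_a == "3x49" & cs$contacts$pos_b == "3x50", ]
  expect_equal(nrow(dr), 1)
  types <- strsplit(dr$types, ",")[[1]]
  expect_true(all(c("ionic", "hbond", "vdw") %in% types))
  # residues on opposite sides of the bundle (> 15 A apart) never contact
  expect_false(any(cs$contacts$pos_a == "1x50" & cs$contacts$pos_b == "4x50"))
  expect_true(all(cs$contacts$min_distance < 10))
})

test_that("aromatic ring pairs register by centroid distance", {
  sc <- tibble::tibble(generic = c("3x50", "4x50"), aa = c("F", "Y"))
  s <- make_ideal_bundle(bundle_spec(sidechains = sc, bundle_radius = 9.5))
  cs <- detect_contacts(s)
  fy <- cs$contacts[cs$contacts$pos_a == "3x50" & cs$contacts$pos_b == "4x50", ]
  if (nrow(fy) == 1) {
    expect_true(grepl("aromatic|hydrophobic|vdw", fy$types))
  }
  # rings engineered face to face at close range must be aromatic
  s2 <- make_test_bundle()
  cs2 <- detect_contacts(s2)
  expect_true(nrow(cs2$contacts) > 0)
})

test_that("indexed detector equals the brute-force oracle on random fixtures", {
  for (seed in 1:50) {
    s <- random_contact_fixture(seed)
    a <- detect_contacts(s)
    b <- detect_contacts_bruteforce(s)
    expect_identical(a$contacts, b$contacts)
    expect_identical(a$positions_resolved, b$positions_resolved)
  }
})

test_that("contact detection is symmetric and order-independent", {
  s <- make_test_bundle()
  cs <- detect_contacts(s)
  # canonical ordering: pos_a always precedes pos_b
  k <- generic_order_key(cs$contacts$pos_a) < generic_order_key(cs$contacts$pos_b)
  expect_true(all(k))
  expect_false(anyDuplicated(paste(cs$contacts$pos_a, cs$contacts$pos_b)) > 0)
})

test_that("enlarging any cutoff never removes a contact", {
  s <- random_contact_fixture(99)
  base <- detect_contacts(s, contact_params())
  key <- function(cs) paste(cs$contacts$pos_a, cs$contacts$pos_b)
  wider <- list(
    contact_params(vdw_tolerance = 1.0),
    contact_params(hbond_max = 4.2),
    contact_params(ionic_max = 5.5),
    contact_params(hydrophobic_max = 5.2),
    contact_params(aromatic_centroid_max = 6.5)
  )
  for (p in wider) {
    expect_true(all(key(base) %in% key(detect_contacts(s, p))))
  }
})

test_that("a rigid transform of the whole structure preserves contacts", {
  s <- make_test_bundle()
  base <- detect_contacts(s)
  R <- matrix(c(cos(0.7), -sin(0.7), 0, sin(0.7), cos(0.7), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  s2 <- transform_structure(s, R, c(11, -4, 23))
  moved <- detect_contacts(s2)
  expect_equal(moved$contacts$pos_a, base$contacts$pos_a)
  expect_equal(moved$contacts$pos_b, base$contacts$pos_b)
  expect_equal(moved$contacts$types, base$contacts$types)
  expect_lt(max(abs(moved$contacts$min_distance - base$contacts$min_distance)),
            1e-6)
})

test_that("adjacent-residue contacts need side-chain mediation", {
  # poly-Ala bundle: sequence neighbours touch via backbone + CB;
  # with the adjacent rule their backbone-only geometry still qualifies
  # only when a side-chain atom participates
  s <- make_ideal_bundle(bundle_spec())
  cs <- detect_contacts(s, contact_params(require_sidechain_adjacent = TRUE))
  off <- function(x) parse_generic(x)$offset
  adj <- abs(off(cs$contacts$pos_a) - off(cs$contacts$pos_b)) <= 2 &
    substr(cs$contacts$pos_a, 1, 1) == substr(cs$contacts$pos_b, 1, 1)
  # switching the rule off can only add adjacent pairs
  cs2 <- detect_contacts(s, contact_params(require_sidechain_adjacent = FALSE))
  expect_gte(nrow(cs2$contacts), nrow(cs$contacts))
  # min_seq_separation excludes immediate neighbours wholesale
  cs3 <- detect_contacts(s, contact_params(min_seq_separation = 3))
  adj3 <- abs(off(cs3$contacts$pos_a) - off(cs3$contacts$pos_b)) < 3 &
    substr(cs3$contacts$pos_a, 1, 1) == substr(cs3$contacts$pos_b, 1, 1)
  expect_false(any(adj3))
})

test_that("structures without generic numbers yield an empty set with warning", {
  d <- withr::local_tempdir()
  s <- make_test_bundle()
  p <- write_structure(s, d, "pdb")
  r <- load_structure(p, chain = "A") # no mapping applied
  expect_warning(cs <- detect_contacts(r), "no residues with generic numbers")
  expect_equal(nrow(cs$contacts), 0)
  expect_warning(cs2 <- detect_contacts_bruteforce(r), "generic")
  expect_equal(nrow(cs2$contacts), 0)
})

test_that("contact TSV export carries provenance and round-trips", {
  d <- withr::local_tempdir()
  s <- make_test_bundle()
  cs <- detect_contacts(s)
  f <- file.path(d, "contacts.tsv")
  write_contact_tsv(cs, f)
  hdr <- readLines(f, n = 2)
  expect_true(grepl("structure_id=SYN1", hdr[1]))
  expect_true(grepl("vdw_tolerance=0.6", hdr[2]))
  back <- readr::read_tsv(f, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cs$contacts))
})
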