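test_that("generic labels parse, render and order canonically", {
  p <- parse_generic(c("3x50", "45x51", "8x50", "3×50"))
  expect_equal(p$generic, c("3x50", "45x51", "8x50", "3x50"))
  expect_equal(p$segment, c("TM3", "ECL2", "H8", "TM3"))
  expect_equal(p$offset, c(50L, 51L, 50L, 50L))
  expect_error(parse_generic("9x50"), "Invalid generic")
  expect_error(parse_generic("3-50"), "Invalid generic")

  cp <- canonical_pair(c("7x50", "1x49"), c("1x49", "7x50"))
  expect_equal(cp$pos_a, c("1x49", "1x49"))
  expect_equal(cp$pos_b, c("7x50", "7x50"))
})

test_that("segment labels are a pure function of the segment code", {
  expect_equal(segment_from_code(c(1, 3, 7, 8)), c("TM1", "TM3", "TM7", "H8"))
  expect_equal(segment_from_code(c(12, 23, 34, 45, 56, 67)),
               c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3"))
  expect_equal(segment_from_code(78), "other")
})

test_that("fixture round-trips through mmCIF and PDB within 1e-3 A", {
  s <- make_test_bundle()
  for (fmt in c("cif", "pdb")) {
    d <- withr::local_tempdir()
    path <- write_structure(s, d, fmt)
    r <- load_structure(path, chain = "A")
    r <- apply_generic_numbers(
      r, read_generic_mapping(file.path(d, "SYN1_mapping.tsv")))
    expect_equal(nrow(r$residues), nrow(s$residues))
    expect_equal(r$residues$generic[order(r$residues$seqnum)],
                 s$residues$generic[order(s$residues$seqnum)])
    ra <- dplyr::arrange(r$atoms, seqnum, atom)
    sa <- dplyr::arrange(s$atoms, seqnum, atom)
    expect_equal(ra$atom, sa$atom)
    expect_lt(max(abs(as.matrix(ra[, c("x", "y", "z")]) -
                        as.matrix(sa[, c("x", "y", "z")]))), 1e-3)
    # loading is deterministic
    r2 <- load_structure(path, chain = "A")
    expect_identical(r$atoms, r2$atoms)
  }
})

test_that("altloc groups keep the highest occupancy, ties alphabetical", {
  d <- withr::local_tempdir()
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.60 10.00           C",
    "ATOM      4  CB BALA A   1       9.000   0.000   0.000  0.40 10.00           C",
    "ATOM      5  N   GLY A   2       0.000   3.000   0.000  1.00 10.00           N",
    "ATOM      6  CA CGLY A   2       1.000   3.000   0.000  0.50 10.00           C",
    "ATOM      7  CA DGLY A   2       8.000   3.000   0.000  0.50 10.00           C",
    "END"
  )
  f <- file.path(d, "alt.pdb")
  writeLines(lines, f)
  s <- load_structure(f, chain = "A")
  cb <- s$atoms[s$atoms$atom == "CB", ]
  expect_equal(nrow(cb), 1)
  expect_equal(cb$x, 3.0)        # occupancy 0.6 wins
  ca2 <- s$atoms[s$atoms$atom == "CA" & s$atoms$seqnum == 2, ]
  expect_equal(ca2$x, 1.0)       # tie -> alphabetically first altloc C
})

test_that("waters and hydrogens are dropped; hetero kept in the side table", {
  d <- withr::local_tempdir()
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00 10.00           C",
    "ATOM      3  H   ALA A   1       1.800   0.500   0.000  1.00 10.00           H",
    "HETATM    4  C1  LIG A 101       5.000   5.000   0.000  1.00 10.00           C",
    "HETATM    5  O   HOH A 201       8.000   8.000   0.000  1.00 10.00           O",
    "END"
  )
  f <- file.path(d, "het.pdb")
  writeLines(lines, f)
  s <- load_structure(f, chain = "A")
  expect_equal(nrow(s$atoms), 2)
  expect_false("H" %in% s$atoms$element)
  expect_equal(s$hetero$resname, "LIG")
})

test_that("load errors name the problem: missing file, missing chain", {
  expect_error(load_structure("no/such/file.pdb"), "does not exist")
  d <- withr::local_tempdir()
  s <- make_test_bundle()
  p <- write_structure(s, d, "pdb")
  expect_error(load_structure(p, chain = "Q"), "available chains: A")
})

test_that("apply_generic_numbers validates mapping uniqueness", {
  s <- make_test_bundle()
  m <- tibble::tibble(chain = "A", seqnum = c(131L, 132L),
                      generic = c("6x48", "6x48"))
  expect_error(apply_generic_numbers(s, m), "several residues")
  m2 <- tibble::tibble(chain = "A", seqnum = c(131L, 131L),
                       generic = c("6x48", "6x49"))
  expect_error(apply_generic_numbers(s, m2), "not unique")
  # remapping a fresh load: 45x51 derives ECL2
  d <- withr::local_tempdir()
  p <- write_structure(s, d, "pdb")
  r <- load_structure(p, chain = "A")
  r <- apply_generic_numbers(r, tibble::tibble(
    chain = "A", seqnum = c(301L, 302L), generic = c("3x50", "45x51")))
  expect_equal(r$n_mapped, 2)
  seg <- r$residues$segment[match(c(301L, 302L), r$residues$seqnum)]
  expect_equal(seg, c("TM3", "ECL2"))
  expect_true(all(r$residues$segment[!r$residues$seqnum %in% c(301L, 302L)] ==
                    "other"))
})

test_that("segment_span orders by offset and is empty for absent segments", {
  s <- make_test_bundle()
  tm6 <- segment_span(s, "TM6")
  expect_equal(nrow(tm6), 25)
  expect_equal(tm6$generic[1], "6x38")
  expect_equal(tm6$generic[25], "6x62")
  k <- generic_order_key(tm6$generic)
  expect_true(all(diff(k) > 0))
  i50 <- which(tm6$generic == "6x50")
  expect_equal(tm6$generic[c(i50 - 1, i50 + 1)], c("6x49", "6x51"))
  expect_equal(nrow(segment_span(s, "H8")), 0)
  s8 <- make_ideal_bundle(bundle_spec(include_h8 = TRUE))
  expect_equal(nrow(segment_span(s8, "H8")), 10)
})
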