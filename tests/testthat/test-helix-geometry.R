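test_that("identical structures give identity transform, zero movement", {
  s <- make_test_bundle()
  pair <- superpose_pair(s, s)
  expect_lt(pair$rmsd, 1e-10)
  expect_equal(pair$R, diag(3), tolerance = 1e-10)
  for (tm in c("TM1", "TM6")) {
    for (rg in c("ec_end", "mid", "ic_end")) {
      expect_lt(region_translation(pair, tm, rg), 1e-9)
      expect_lt(abs(region_rotation(pair, tm, rg)), 1e-9)
    }
  }
})

test_that("superposition recovers a known global rotation", {
  s <- make_test_bundle()
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  s2 <- transform_structure(s, R, c(5, -3, 2))
  pair <- superpose_pair(s, s2)
  expect_lt(pair$rmsd, 1e-8)
  # recovered transform inverts the applied one
  expect_equal(pair$R %*% R, diag(3), tolerance = 1e-6)
})

test_that("kabsch matches the bio3d reference superposition", {
  s <- make_test_bundle()
  ca <- dplyr::filter(s$atoms, atom == "CA")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  withr::with_seed(5, {
    ang <- runif(3, -pi, pi)
  })
  Rz <- matrix(c(cos(ang[1]), -sin(ang[1]), 0, sin(ang[1]), cos(ang[1]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- xyz %*% t(Rz) + matrix(c(1, 2, 3), nrow(xyz), 3, byrow = TRUE)
  fit <- gpcrstates:::kabsch(moved, xyz)
  # independent route: bio3d fit.xyz on the same coordinate sets
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(xyz)),
                                         mobile = as.numeric(t(moved))))
  ref_xyz <- matrix(ref, ncol = 3, byrow = TRUE)
  ours <- moved %*% t(fit$R) + matrix(fit$t, nrow(moved), 3, byrow = TRUE)
  expect_lt(max(abs(ours - ref_xyz)), 1e-6)
})

test_that("a rigid TM6 end move leaves the superposition core clean", {
  s <- make_test_bundle()
  a <- apply_motion(s, motion_spec("TM6", "ic_end", tx = 5))
  pair <- superpose_pair(s, a)
  expect_lt(pair$rmsd, 0.1)
})

test_that("imposed end translations and rotations are recovered (noiseless)", {
  s <- make_test_bundle()
  cases <- list(
    list(m = motion_spec("TM6", "ic_end", tx = 5), tm = "TM6",
         rg = "ic_end", tr = 5, ro = 0),
    list(m = motion_spec("TM6", "ic_end", ty = -7), tm = "TM6",
         rg = "ic_end", tr = 7, ro = 0),
    list(m = motion_spec("TM5", "ec_end", rot_deg = 25), tm = "TM5",
         rg = "ec_end", tr = 0.35, ro = 25),  # rotation swings the centroid
    list(m = motion_spec("TM3", "ic_end", rot_deg = -16), tm = "TM3",
         rg = "ic_end", tr = 0.25, ro = -16),
    list(m = motion_spec("TM2", "ec_end", tx = 2.8), tm = "TM2",
         rg = "ec_end", tr = 2.8, ro = 0)
  )
  for (cs in cases) {
    a <- apply_motion(s, cs$m)
    pair <- superpose_pair(s, a)
    tr <- region_translation(pair, cs$tm, cs$rg)
    ro <- region_rotation(pair, cs$tm, cs$rg)
    if (cs$ro == 0) {
      expect_lt(abs(tr - cs$tr), 0.05)
    } else {
      # pure own-axis rotation: centroid swing bounded by the off-axis lever
      expect_lt(tr, cs$tr)
    }
    expect_lt(abs(ro - cs$ro), 0.5)
    # untouched helices stay put
    expect_lt(region_translation(pair, "TM1", "mid"), 0.05)
    expect_lt(abs(region_rotation(pair, "TM1", "mid")), 0.5)
  }
})

test_that("composed rotation + translation are recovered independently", {
  s <- make_test_bundle()
  a <- apply_motion(s, motion_spec("TM6", "ic_end", tx = 4, rot_deg = 25))
  pair <- superpose_pair(s, a)
  ro <- region_rotation(pair, "TM6", "ic_end")
  expect_lt(abs(ro - 25), 0.5)
  # derived oracle for the centroid displacement: |T + (R - I) c_rel| with
  # c_rel the region centroid offset from the rotation axis
  ca <- dplyr::filter(as_tibble(s), segment == "TM6")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  helix_centroid <- colMeans(xyz)
  ax <- gpcrstates:::principal_axis(xyz)
  region <- xyz[order(xyz[, 3])[1:4], ]      # intracellular = lowest z
  c_rel <- colMeans(region) - helix_centroid
  c_perp <- c_rel - sum(c_rel * ax) * ax
  R <- gpcrstates:::rotation_about_axis(ax * sign(ax[3]), 25 * pi / 180)
  expected <- sqrt(sum((c(4, 0, 0) + as.numeric((R - diag(3)) %*% c_perp))^2))
  tr <- region_translation(pair, "TM6", "ic_end")
  expect_lt(abs(tr - expected), 0.05)
})

test_that("recovery degrades gracefully under 0.3 A coordinate noise", {
  s <- make_test_bundle()
  a <- apply_motion(s, dplyr::bind_rows(
    motion_spec("TM6", "ic_end", tx = 4, rot_deg = 25),
    motion_spec("TM5", "ec_end", ty = 3)
  ))
  pair <- superpose_pair(s, perturb_structure(a, sd = 0.3, seed = 42))
  expect_lt(abs(region_translation(pair, "TM5", "ec_end") - 3), 0.5)
  expect_lt(abs(region_rotation(pair, "TM6", "ic_end") - 25), 5)
  # averaged over several noise draws the rotation error is small
  errs <- vapply(1:6, function(sd_seed) {
    p <- superpose_pair(s, perturb_structure(a, sd = 0.3, seed = sd_seed))
    abs(region_rotation(p, "TM6", "ic_end") - 25)
  }, 0)
  expect_lt(mean(errs), 5)
})

test_that("a common rigid transform leaves all measurements unchanged", {
  s <- make_test_bundle()
  a <- apply_motion(s, motion_spec("TM6", "ic_end", tx = 4, rot_deg = -15))
  pair0 <- superpose_pair(s, a)
  R <- gpcrstates:::rotation_about_axis(c(1, 2, 2) / 3, 1.1)
  s2 <- transform_structure(s, R, c(13, -8, 4))
  a2 <- transform_structure(a, R, c(13, -8, 4))
  pair1 <- superpose_pair(s2, a2)
  for (tm in paste0("TM", c(1, 5, 6))) {
    for (rg in c("ec_end", "mid", "ic_end")) {
      expect_equal(region_translation(pair1, tm, rg),
                   region_translation(pair0, tm, rg), tolerance = 1e-6)
      expect_equal(region_rotation(pair1, tm, rg),
                   region_rotation(pair0, tm, rg), tolerance = 1e-6)
    }
  }
})

test_that("swapping state labels negates rotations, preserves translations", {
  s <- make_test_bundle()
  a <- apply_motion(s, motion_spec("TM6", "ic_end", tx = 3, rot_deg = 20))
  fw <- superpose_pair(s, a)
  bw <- superpose_pair(a, s)
  expect_equal(region_rotation(bw, "TM6", "ic_end"),
               -region_rotation(fw, "TM6", "ic_end"), tolerance = 0.2)
  expect_equal(region_translation(bw, "TM6", "ic_end"),
               region_translation(fw, "TM6", "ic_end"), tolerance = 0.1)
})

test_that("membrane frame orients toward the extracellular reference", {
  s <- make_test_bundle()
  f <- estimate_membrane_frame(s)
  expect_equal(sqrt(sum(f$normal^2)), 1, tolerance = 1e-9)
  expect_gt(f$normal[3], 0.99)   # bundle built along +z
  # flipping the structure flips the normal
  flip <- transform_structure(s, diag(c(1, -1, -1)), c(0, 0, 0))
  f2 <- estimate_membrane_frame(flip)
  expect_lt(f2$normal[3], -0.99)
  # external frames pass through unchanged
  ext <- estimate_membrane_frame(
    s, mode = "external", external = list(center = c(0, 0, 1),
                                          normal = c(0, 0, 2)))
  expect_equal(ext$normal, c(0, 0, 1))
  expect_equal(ext$center, c(0, 0, 1))
})

test_that("too few shared core positions is an error; short spans unmeasurable", {
  s <- make_test_bundle()
  tiny <- s
  keep <- tiny$residues$seqnum %in% c(101:125)  # one helix only
  tiny$residues <- tiny$residues[keep, ]
  tiny$atoms <- tiny$atoms[tiny$atoms$seqnum %in% 101:125, ]
  # a single shared helix leaves too few mid-membrane positions
  expect_error(superpose_pair(s, tiny), "mid-membrane positions")

  a <- apply_motion(s, motion_spec("TM6", "ic_end", tx = 5))
  pair <- superpose_pair(s, a)
  expect_true(is.na(region_translation(pair, "H8", "ic_end")))
})

test_that("class consensus counts strict movements over 1.0 A", {
  rep1 <- tibble::tibble(
    receptor = "R1", gpcr_class = "A", tm = "TM6",
    region = c("ic_end", "mid"), translation = c(7, 1.0),
    rotation = c(30, 0), measurable = TRUE
  )
  rep2 <- dplyr::mutate(rep1, receptor = "R2",
                        translation = c(2, 0.4))
  cons <- class_consensus_movements(list(rep1, rep2))
  ic <- cons[cons$region == "ic_end", ]
  expect_equal(ic$n_moving, 2L)
  expect_true(ic$consensus)
  mid <- cons[cons$region == "mid", ]
  expect_equal(mid$n_moving, 0L)   # exactly 1.0 A is NOT counted
  expect_false(mid$consensus)
})

test_that("full movement report covers every helix and region", {
  s <- make_test_bundle()
  a <- apply_motion(s, motion_spec("TM6", "ic_end", tx = 8, rot_deg = 30))
  rep <- helix_movement_report(s, a, receptor = "R1", gpcr_class = "A")
  expect_equal(nrow(rep), 21)  # 7 TMs x 3 regions
  expect_true(all(rep$measurable))
  tm6 <- rep[rep$tm == "TM6" & rep$region == "ic_end", ]
  expect_gt(tm6$translation, 7.5)
  expect_equal(tm6$rotation, 30, tolerance = 0.5)
  expect_true(all(rep$translation >= 0))
  expect_true(all(rep$rotation > -180 & rep$rotation <= 180))
})
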