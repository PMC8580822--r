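#' Estimate the membrane frame of a receptor
#'
#' The membrane frame is a point on the membrane mid-plane plus a unit
#' normal pointing extracellularly. In `bundle_axis` mode (the built-in
#' method) the normal is the first principal axis of all transmembrane CA
#' atoms and the centre is their centroid; the normal is oriented so that
#' the extracellular side is positive, using ECL2 residues when present and
#' otherwise the TM4 C-terminal / TM5 N-terminal ends (which flank ECL2) as
#' the extracellular reference. In `external` mode a supplied frame (for
#' example from a membrane-embedding server) is returned unchanged.
#'
#' @param s an `annotated_structure` with generic numbers.
#' @param mode `"bundle_axis"` or `"external"`.
#' @param external a list with `center` and `normal` (used when
#'   `mode = "external"`).
#' @return a `membrane_frame` list with unit `normal` and `center`.
#' @export
estimate_membrane_frame <- function(s, mode = c("bundle_axis", "external"),
                                    external = NULL) {
  mode <- match.arg(mode)
  if (mode == "external") {
    if (is.null(external)) rlang::abort("external mode needs a supplied frame.")
    external$normal <- external$normal / sqrt(sum(external$normal^2))
    return(structure(external, class = "membrane_frame"))
  }
  ca <- atom_coords(s, "CA")
  tm <- ca[grepl("^TM", ca$segment), , drop = FALSE]
  if (length(unique(tm$segment)) < 4) {
    rlang::abort("Too few transmembrane segments to estimate a membrane frame.")
  }
  xyz <- as.matrix(tm[, c("x", "y", "z")])
  center <- colMeans(xyz)
  normal <- principal_axis(xyz)

  ref <- NULL
  ecl2 <- ca[ca$segment == "ECL2", , drop = FALSE]
  if (nrow(ecl2)) {
    ref <- colMeans(as.matrix(ecl2[, c("x", "y", "z")]))
  } else {
    tm4 <- ca[ca$segment == "TM4", , drop = FALSE]
    tm5 <- ca[ca$segment == "TM5", , drop = FALSE]
    if (nrow(tm4) && nrow(tm5)) {
      tm4 <- tm4[order(generic_order_key(tm4$generic)), ]
      tm5 <- tm5[order(generic_order_key(tm5$generic)), ]
      a <- as.numeric(tm4[nrow(tm4), c("x", "y", "z")])
      b <- as.numeric(tm5[1, c("x", "y", "z")])
      ref <- (a + b) / 2
    }
  }
  if (is.null(ref)) {
    rlang::abort("Cannot orient the membrane normal: no ECL2 and no TM4/TM5 ends.")
  }
  if (sum((ref - center) * normal) < 0) normal <- -normal
  structure(list(center = center, normal = normal), class = "membrane_frame")
}

# least-squares rigid superposition (Kabsch): returns R, t minimizing
# || moving %*% t(R) + t - fixed ||
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  fit <- moving %*% t(R) + matrix(t, nrow(moving), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fit - fixed)^2)))
  list(R = R, t = t, rmsd = rmsd)
}

#' Superpose an active structure onto its inactive counterpart
#'
#' Least-squares (Kabsch) fit of the active structure onto the inactive one
#' using the CA atoms of shared transmembrane generic positions lying within
#' a slab of the membrane mid (default half-width 6 Angstrom, measured along
#' the inactive structure's membrane normal). Fitting on the mid-membrane
#' core measures end movements against the least mobile part of the bundle.
#'
#' @param inactive,active `annotated_structure`s of the same receptor.
#' @param frame optional [estimate_membrane_frame()] result for the inactive
#'   structure (computed when omitted).
#' @param slab_halfwidth half-width of the core slab, Angstrom.
#' @param min_shared minimum number of shared core positions required.
#' @return a `superposed_pair`: the inactive structure, the transformed
#'   active structure, the transform (`R`, `t`), the core `rmsd`, the core
#'   `positions` used, and the membrane `frame`.
#' @export
superpose_pair <- function(inactive, active, frame = NULL,
                           slab_halfwidth = 6, min_shared = 20) {
  stopifnot(inherits(inactive, "annotated_structure"),
            inherits(active, "annotated_structure"))
  frame <- frame %||% estimate_membrane_frame(inactive)
  ca_i <- atom_coords(inactive, "CA")
  ca_a <- atom_coords(active, "CA")
  ca_i <- ca_i[grepl("^TM", ca_i$segment), , drop = FALSE]
  shared <- intersect(ca_i$generic, ca_a$generic)
  ca_i <- ca_i[ca_i$generic %in% shared, , drop = FALSE]
  proj <- as.numeric(
    (as.matrix(ca_i[, c("x", "y", "z")]) -
       matrix(frame$center, nrow(ca_i), 3, byrow = TRUE)) %*% frame$normal
  )
  core <- ca_i$generic[abs(proj) <= slab_halfwidth]
  if (length(core) < min_shared) {
    rlang::abort(paste0("Only ", length(core), " shared mid-membrane positions; ",
                        "need at least ", min_shared, " for superposition."))
  }
  mi <- as.matrix(ca_i[match(core, ca_i$generic), c("x", "y", "z")])
  ma <- as.matrix(ca_a[match(core, ca_a$generic), c("x", "y", "z")])
  fit <- kabsch(ma, mi)
  active_fit <- transform_structure(active, fit$R, fit$t)
  structure(list(
    inactive = inactive, active = active_fit, R = fit$R, t = fit$t,
    rmsd = fit$rmsd, positions = core, frame = frame
  ), class = "superposed_pair")
}

#' Region window specification for helix measurements
#'
#' @param window_end residues per end region (default 4).
#' @param window_mid residues for the membrane-mid region (default 5).
#' @return a `region_spec` list.
#' @export
region_spec <- function(window_end = 4, window_mid = 5) {
  if (window_end < 3 || window_mid < 3) {
    rlang::abort("Region windows must hold at least 3 residues.")
  }
  structure(list(window_end = window_end, window_mid = window_mid),
            class = "region_spec")
}

# shared CA records of one TM in both states of a pair, with projections
# along the inactive membrane normal, ordered by projection
tm_shared_ca <- function(pair, tm) {
  ca_i <- atom_coords(pair$inactive, "CA")
  ca_a <- atom_coords(pair$active, "CA")
  ca_i <- ca_i[ca_i$segment == tm, , drop = FALSE]
  shared <- intersect(ca_i$generic, ca_a$generic)
  ca_i <- ca_i[ca_i$generic %in% shared, , drop = FALSE]
  if (nrow(ca_i) == 0) return(NULL)
  proj <- as.numeric(
    (as.matrix(ca_i[, c("x", "y", "z")]) -
       matrix(pair$frame$center, nrow(ca_i), 3, byrow = TRUE)) %*%
      pair$frame$normal
  )
  ord <- order(proj)
  list(
    generic = ca_i$generic[ord],
    xyz_i = as.matrix(ca_i[ord, c("x", "y", "z")]),
    xyz_a = as.matrix(ca_a[match(ca_i$generic[ord], ca_a$generic),
                           c("x", "y", "z")]),
    proj = proj[ord]
  )
}

region_positions <- function(shared, region, spec) {
  n <- length(shared$generic)
  w <- if (region == "mid") spec$window_mid else spec$window_end
  if (n < w) return(integer())
  switch(region,
    ic_end = seq_len(w),                 # lowest projections = intracellular
    ec_end = seq(n - w + 1, n),
    mid = order(abs(shared$proj))[seq_len(w)]
  )
}

#' Translation of a helix region between states
#'
#' Distance between the region's CA centroids in the inactive structure and
#' the superposed active structure. End regions are the terminal `window`
#' shared residues on the corresponding membrane side; the mid region is
#' the `window` shared residues nearest the membrane mid-plane.
#'
#' @param pair a [superpose_pair()] result.
#' @param tm helix label, e.g. `"TM6"`.
#' @param region `"ic_end"`, `"mid"` or `"ec_end"`.
#' @param spec a [region_spec()].
#' @return translation in Angstrom, or `NA` when fewer than 3 shared
#'   residues are available ("not measurable").
#' @export
region_translation <- function(pair, tm, region = c("ic_end", "mid", "ec_end"),
                               spec = region_spec()) {
  region <- match.arg(region)
  shared <- tm_shared_ca(pair, tm)
  if (is.null(shared)) return(NA_real_)
  idx <- region_positions(shared, region, spec)
  if (length(idx) < 3) return(NA_real_)
  ci <- colMeans(shared$xyz_i[idx, , drop = FALSE])
  ca <- colMeans(shared$xyz_a[idx, , drop = FALSE])
  sqrt(sum((ci - ca)^2))
}

#' Rotation of a helix region about its own axis between states
#'
#' Fits a local helix axis (principal component of a 7-residue window
#' centred on the region) in each state, removes the axis tilt by rotating
#' the active axis onto the inactive axis, and reports the circular mean of
#' the per-residue azimuthal shifts of the region CA atoms about the axis.
#' Positive rotation is counterclockwise viewed from the extracellular side.
#'
#' @inheritParams region_translation
#' @param axis_window residues in the axis-fitting window (default 7).
#' @return rotation in degrees in (-180, 180], or `NA` when not measurable
#'   (too few residues, or degenerate axis fit with < 1 Angstrom radial
#'   spread).
#' @export
region_rotation <- function(pair, tm, region = c("ic_end", "mid", "ec_end"),
                            spec = region_spec(), axis_window = 7) {
  region <- match.arg(region)
  shared <- tm_shared_ca(pair, tm)
  if (is.null(shared)) return(NA_real_)
  idx <- region_positions(shared, region, spec)
  if (length(idx) < 3 || length(shared$generic) < 5) return(NA_real_)
  n <- length(shared$generic)
  centre <- round(mean(idx))
  half <- axis_window %/% 2
  # centre the window on the region but keep its full length at the termini
  start <- min(max(1, centre - half), max(1, n - axis_window + 1))
  win <- start:min(n, start + axis_window - 1)
  if (length(win) < 5) win <- seq_len(n)

  ax_i <- local_helix_axis(shared$xyz_i[win, , drop = FALSE])
  if (sum(ax_i * pair$frame$normal) < 0) ax_i <- -ax_i

  # degenerate when the region CAs are nearly collinear with the axis
  rel_i <- shared$xyz_i[idx, , drop = FALSE]
  rel_i <- rel_i - matrix(colMeans(rel_i), nrow(rel_i), 3, byrow = TRUE)
  radial <- sqrt(rowSums((rel_i - (rel_i %*% ax_i) %*% t(ax_i))^2))
  if (stats::median(radial) < 1) return(NA_real_)

  # rigid transform of the region residues between states, then the twist
  # component of its rotation about the local axis (twist-swing
  # decomposition, which removes the axis tilt and is second-order
  # insensitive to axis estimation error). All backbone heavy atoms of the
  # region enter the fit: they move with the same rigid body and quarter
  # the variance under coordinate noise compared to CA-only fitting.
  region_gen <- shared$generic[idx]
  bb_i <- region_backbone_coords(pair$inactive, region_gen)
  bb_a <- region_backbone_coords(pair$active, region_gen)
  common <- intersect(rownames(bb_i), rownames(bb_a))
  if (length(common) >= 3 * length(idx)) {
    fit <- kabsch(bb_i[common, , drop = FALSE], bb_a[common, , drop = FALSE])
  } else {
    fit <- kabsch(shared$xyz_i[idx, , drop = FALSE],
                  shared$xyz_a[idx, , drop = FALSE])
  }
  rotation_twist_deg(fit$R, ax_i)
}

# Local helix axis: a raw principal component of a short CA window is
# strongly tilted by the helical spiral, so smooth with a running mean over
# ~one helical turn (4 residues) first; the smoothed points lie close to
# the axis and their principal component tracks it accurately.
local_helix_axis <- function(xyz) {
  n <- nrow(xyz)
  if (n >= 6) {
    sm <- vapply(seq_len(n - 3), function(i) colMeans(xyz[i:(i + 3), ]),
                 numeric(3))
    principal_axis(t(sm))
  } else {
    principal_axis(xyz)
  }
}

# backbone heavy-atom coordinates of the given generic positions, with
# "generic/atom" rownames so both states can be matched atom by atom
region_backbone_coords <- function(s, generics) {
  res <- s$residues[match(generics, s$residues$generic), , drop = FALSE]
  at <- dplyr::inner_join(
    dplyr::filter(s$atoms, .data$atom %in% c("N", "CA", "C", "O")),
    dplyr::select(res, "chain", "seqnum", "generic"),
    by = c("chain", "seqnum")
  )
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- paste0(at$generic, "/", at$atom)
  m
}

# twist angle of rotation matrix R about unit axis a, degrees in (-180, 180]
rotation_twist_deg <- function(R, a) {
  # quaternion of R
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    qw <- 0.25 * s
    qv <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / s
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    qv <- numeric(3)
    qv[i] <- 0.25 * s
    qw <- (R[k, j] - R[j, k]) / s
    qv[j] <- (R[j, i] + R[i, j]) / s
    qv[k] <- (R[k, i] + R[i, k]) / s
  }
  ang <- 2 * atan2(sum(qv * a), qw) * 180 / pi
  ((ang + 180) %% 360) - 180
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-helix movement report for one receptor pair
#'
#' Measures translation and rotation for every TM helix at the extracellular
#' end, membrane mid and intracellular end.
#'
#' @param inactive,active `annotated_structure`s of one receptor.
#' @param spec a [region_spec()].
#' @param receptor,gpcr_class labels carried into the report (default from
#'   the inactive structure).
#' @return a `helix_movement_report`: tibble with columns `receptor`,
#'   `gpcr_class`, `tm`, `region`, `translation`, `rotation`, `measurable`,
#'   plus attributes `rmsd` and `positions`.
#' @export
helix_movement_report <- function(inactive, active, spec = region_spec(),
                                  receptor = NULL, gpcr_class = NULL) {
  pair <- superpose_pair(inactive, active)
  receptor <- receptor %||% inactive$receptor
  gpcr_class <- gpcr_class %||% inactive$gpcr_class
  tms <- intersect(paste0("TM", 1:7), unique(inactive$residues$segment))
  grid <- tidyr::expand_grid(tm = tms, region = c("ec_end", "mid", "ic_end"))
  res <- purrr::pmap_dfr(grid, function(tm, region) {
    tr <- region_translation(pair, tm, region, spec)
    ro <- region_rotation(pair, tm, region, spec)
    tibble::tibble(
      receptor = receptor %||% NA_character_,
      gpcr_class = gpcr_class %||% NA_character_,
      tm = tm, region = region, translation = tr, rotation = ro,
      measurable = !is.na(tr)
    )
  })
  structure(res, class = c("helix_movement_report", class(res)),
            rmsd = pair$rmsd, positions = pair$positions)
}

#' Class consensus of helix movements
#'
#' Counts, per class, helix and region, the receptors whose translation
#' exceeds the threshold (strictly, "movements over 1.0 Angstrom"), and
#' flags a class consensus when a majority of that class's measured pairs
#' move.
#'
#' @param reports a list of [helix_movement_report()] results (or one bound
#'   tibble with the same columns).
#' @param threshold movement threshold in Angstrom (default 1.0, strict).
#' @return tibble with columns `gpcr_class`, `tm`, `region`, `n_measured`,
#'   `n_moving`, `consensus`.
#' @export
class_consensus_movements <- function(reports, threshold = 1.0) {
  tab <- if (inherits(reports, "data.frame")) tibble::as_tibble(reports)
         else dplyr::bind_rows(reports)
  tab |>
    dplyr::filter(.data$measurable) |>
    dplyr::group_by(.data$gpcr_class, .data$tm, .data$region) |>
    dplyr::summarise(
      n_measured = dplyr::n(),
      n_moving = sum(.data$translation > threshold),
      consensus = .data$n_moving > .data$n_measured / 2,
      .groups = "drop"
    )
}
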