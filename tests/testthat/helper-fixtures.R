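# shared fixture builders; everything is generated in code at test time

# small bundle with a designed ionic pair (Asp 3x49 - Arg 3x50 via templates)
# plus aromatic partners on facing helices
default_sidechains <- function() {
  tibble::tibble(
    generic = c("3x49", "3x50", "6x44", "7x53"),
    aa = c("D", "R", "F", "Y"),
    partner = c("3x50", "3x49", "7x53", "6x44")
  )
}

make_test_bundle <- function(structure_id = "SYN1", sidechains = default_sidechains(),
                             ...) {
  make_ideal_bundle(bundle_spec(sidechains = sidechains,
                                structure_id = structure_id, ...))
}

# random fixture for contact oracle equivalence: a bundle with randomly
# chosen side-chain residues and jittered coordinates
random_contact_fixture <- function(seed) {
  withr::with_seed(seed, {
    n_sc <- sample(3:8, 1)
    helices <- sample(1:7, n_sc, replace = TRUE)
    offsets <- sample(40:60, n_sc, replace = TRUE)
    generic <- unique(paste0(helices, "x", offsets))
    aa <- sample(c("D", "E", "R", "K", "F", "Y", "W", "H", "N", "Q", "S", "L"),
                 length(generic), replace = TRUE)
    s <- make_ideal_bundle(bundle_spec(
      sidechains = tibble::tibble(generic = generic, aa = aa),
      bundle_radius = runif(1, 9.5, 12), structure_id = paste0("RF", seed)
    ))
    # moderate coordinate jitter creates borderline distances
    s <- perturb_structure(s, sd = runif(1, 0.05, 0.4), seed = seed + 1)
    s
  })
}

# brute-force reference for the exact rank-sum p-value: enumerate every
# group assignment with utils::combn and recompute rank sums directly
wilcoxon_p_enumeration <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w <- sum(r[seq_len(na)])
  idx <- utils::combn(length(pooled), na)
  ws <- colSums(matrix(r[idx], nrow = na))
  p_le <- mean(ws <= w + 1e-9)
  p_ge <- mean(ws >= w - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# catalog row builder for boundary tests
annotation_row <- function(structure_id, receptor = "R", gpcr_class = "A",
                           state = "inactive", resolution = 2.5, rc = 95,
                           gc = NA_real_, si = 98, da = NULL, lig = NULL,
                           gp = FALSE, parent = structure_id) {
  da <- da %||% if (state == "active") 95 else 5
  lig <- lig %||% if (state == "active") "agonist" else "antagonist"
  tibble::tibble(
    structure_id = structure_id, receptor = receptor,
    gpcr_class = gpcr_class, state_annotation = state,
    resolution = resolution, receptor_completeness = rc,
    gprotein_completeness = gc, seq_identity_human = si,
    degree_active = da, ligand_modality = lig, has_gprotein_complex = gp,
    parent_id = parent
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

digest_file <- function(f) unname(tools::md5sum(f))
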