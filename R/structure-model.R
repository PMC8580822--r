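#' Load a receptor chain from a PDB or mmCIF file
#'
#' Reads one chain of one model into an annotated structure: a residue table,
#' a heavy-atom table and a side table of hetero groups (ligands, ions).
#' Hydrogens and waters are dropped. Alternate locations are resolved per
#' atom by keeping the highest-occupancy altloc, ties broken by the
#' alphabetically first altloc tag.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain chain identifier to extract. Required when the file holds
#'   several chains.
#' @param model model index (default 1).
#' @param structure_id identifier for the structure; defaults to the file
#'   base name.
#' @return an object of class `annotated_structure`: a list with fields
#'   `structure_id`, `receptor`, `gpcr_class`, `state`, `residues` (tibble:
#'   chain, seqnum, aa, resname, generic, segment), `atoms` (tibble: chain,
#'   seqnum, atom, element, x, y, z, altloc, occupancy) and `hetero` (same
#'   columns plus `resname`) holding non-water hetero groups of all chains.
#' @export
load_structure <- function(path, chain = NULL, model = 1, structure_id = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Cannot read structure file: '", path, "' does not exist."))
  }
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    {
      if (ext %in% c("cif", "mmcif")) {
        suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
      } else {
        bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE)
      }
    },
    error = function(e) {
      rlang::abort(paste0("Failed to parse '", path, "' as ",
                          ifelse(ext %in% c("cif", "mmcif"), "mmCIF", "PDB"),
                          ": ", conditionMessage(e)))
    }
  )
  at <- tibble::as_tibble(parsed$atom)
  if (nrow(at) == 0) rlang::abort(paste0("No atom records found in '", path, "'."))
  at$o[is.na(at$o)] <- 1
  at$alt[is.na(at$alt)] <- ""
  # infer element where the file lacks it
  at$elesy[is.na(at$elesy) | at$elesy == ""] <-
    substr(gsub("[0-9']", "", at$elety[is.na(at$elesy) | at$elesy == ""]), 1, 1)
  at <- at[at$elesy != "H" & at$elesy != "D", , drop = FALSE]
  at <- at[at$resid != "HOH" & at$resid != "DOD", , drop = FALSE]

  chains <- sort(unique(at$chain))
  if (is.null(chain)) {
    prot_chains <- sort(unique(at$chain[at$type == "ATOM"]))
    if (length(prot_chains) != 1) {
      rlang::abort(paste0("File holds chains ", paste(chains, collapse = ", "),
                          "; supply `chain` to select one."))
    }
    chain <- prot_chains
  }
  if (!chain %in% chains) {
    rlang::abort(paste0("Chain '", chain, "' not found; available chains: ",
                        paste(chains, collapse = ", "), "."))
  }

  # altloc resolution: per (chain, seqnum, atom name) keep highest occupancy,
  # ties -> alphabetically first tag ("" sorts first, i.e. unlabelled wins ties)
  at <- dplyr::arrange(at, .data$chain, .data$resno, .data$elety,
                       dplyr::desc(.data$o), .data$alt)
  at <- dplyr::distinct(at, .data$chain, .data$resno, .data$elety, .keep_all = TRUE)

  prot <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  het <- at[at$type == "HETATM", , drop = FALSE]

  atoms <- tibble::tibble(
    chain = prot$chain, seqnum = as.integer(prot$resno), atom = prot$elety,
    element = prot$elesy, x = prot$x, y = prot$y, z = prot$z,
    altloc = prot$alt, occupancy = prot$o
  )
  hetero <- tibble::tibble(
    chain = het$chain, seqnum = as.integer(het$resno), resname = het$resid,
    atom = het$elety, element = het$elesy, x = het$x, y = het$y, z = het$z,
    altloc = het$alt, occupancy = het$o
  )
  res <- dplyr::distinct(prot, .data$chain, .data$resno, .data$resid)
  residues <- tibble::tibble(
    chain = res$chain, seqnum = as.integer(res$resno),
    resname = res$resid, aa = aa_three_to_one(res$resid),
    generic = NA_character_, segment = "other"
  )
  if (is.null(structure_id)) {
    structure_id <- toupper(tools::file_path_sans_ext(basename(path)))
  }
  new_annotated_structure(structure_id, residues, atoms, hetero)
}

new_annotated_structure <- function(structure_id, residues, atoms,
                                    hetero = NULL, receptor = NA_character_,
                                    gpcr_class = NA_character_,
                                    state = "unknown") {
  if (anyDuplicated(residues[, c("chain", "seqnum")])) {
    rlang::abort("Duplicate (chain, seqnum) residue records.")
  }
  structure(
    list(
      structure_id = structure_id, receptor = receptor,
      gpcr_class = gpcr_class, state = state,
      residues = residues, atoms = atoms,
      hetero = hetero %||% tibble::tibble(
        chain = character(), seqnum = integer(), resname = character(),
        atom = character(), element = character(), x = numeric(),
        y = numeric(), z = numeric(), altloc = character(),
        occupancy = numeric()
      )
    ),
    class = "annotated_structure"
  )
}

#' @export
print.annotated_structure <- function(x, ...) {
  cat("<annotated_structure> ", x$structure_id,
      if (!is.na(x$receptor)) paste0(" (", x$receptor, ", class ", x$gpcr_class,
                                     ", ", x$state, ")"),
      "\n", sep = "")
  cat("  residues: ", nrow(x$residues),
      " (", sum(!is.na(x$residues$generic)), " with generic numbers)\n", sep = "")
  cat("  heavy atoms: ", nrow(x$atoms),
      "; hetero atoms: ", nrow(x$hetero), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.annotated_structure <- function(x, ...) {
  ca <- dplyr::filter(x$atoms, .data$atom == "CA")
  dplyr::left_join(x$residues,
                   dplyr::select(ca, "chain", "seqnum", "x", "y", "z"),
                   by = c("chain", "seqnum"))
}

three_one_table <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

aa_three_to_one <- function(resname) {
  out <- unname(three_one_table[toupper(resname)])
  out[is.na(out)] <- "X" # non-standard residues
  out
}

aa_one_to_three <- function(aa) {
  rev_tab <- stats::setNames(names(three_one_table), unname(three_one_table))
  out <- unname(rev_tab[toupper(aa)])
  out[is.na(out)] <- "UNK"
  out
}

#' Attach generic residue numbers to a structure
#'
#' Applies a `(chain, seqnum) -> generic` mapping to the residue table and
#' derives each mapped residue's segment label from its generic position.
#' Unmapped residues keep segment `"other"`.
#'
#' @param s an `annotated_structure`.
#' @param mapping data frame with columns `chain`, `seqnum`, `generic`
#'   (optionally `structure_id`, filtered to `s$structure_id` when present).
#' @return the structure with `generic`/`segment` filled in; the number of
#'   mapped residues is recorded in field `n_mapped`.
#' @export
apply_generic_numbers <- function(s, mapping) {
  stopifnot(inherits(s, "annotated_structure"))
  mapping <- tibble::as_tibble(mapping)
  req <- c("chain", "seqnum", "generic")
  miss <- setdiff(req, names(mapping))
  if (length(miss)) {
    rlang::abort(paste0("Mapping table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if ("structure_id" %in% names(mapping)) {
    mapping <- dplyr::filter(mapping, .data$structure_id == s$structure_id)
  }
  p <- parse_generic(mapping$generic)
  mapping$generic <- p$generic
  if (anyDuplicated(mapping[, c("chain", "seqnum")])) {
    d <- mapping[duplicated(mapping[, c("chain", "seqnum")]) |
                   duplicated(mapping[, c("chain", "seqnum")], fromLast = TRUE), ]
    rlang::abort(paste0("Mapping keys not unique: ",
                        paste(unique(paste0(d$chain, ":", d$seqnum)), collapse = ", ")))
  }
  if (anyDuplicated(mapping$generic)) {
    d <- mapping[mapping$generic %in% mapping$generic[duplicated(mapping$generic)], ]
    rlang::abort(paste0(
      "Generic position assigned to several residues: ",
      paste(apply(d, 1, function(r) paste0(r[["generic"]], " <- ",
                                           r[["chain"]], ":", r[["seqnum"]])),
            collapse = "; ")
    ))
  }
  res <- s$residues
  res$generic <- NULL
  res$segment <- NULL
  res <- dplyr::left_join(res, mapping[, req], by = c("chain", "seqnum"))
  res$segment <- ifelse(is.na(res$generic), "other", generic_segment(res$generic))
  s$residues <- res
  s$n_mapped <- sum(!is.na(res$generic))
  s
}

#' Read a residue-to-generic-number mapping table
#'
#' @param path TSV file with columns `structure_id`, `chain`, `seqnum`,
#'   `generic`.
#' @return tibble of the mapping rows.
#' @export
read_generic_mapping <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  req <- c("structure_id", "chain", "seqnum", "generic")
  miss <- setdiff(req, names(m))
  if (length(miss)) {
    rlang::abort(paste0("Mapping file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  m$seqnum <- as.integer(m$seqnum)
  m$generic <- parse_generic(m$generic)$generic
  m
}

#' Residues of one segment, in generic order
#'
#' @param s an `annotated_structure` with generic numbers applied.
#' @param segment a segment label such as `"TM6"` or `"ECL2"`.
#' @return tibble of the segment's residue records ordered by generic offset;
#'   zero rows when the segment is absent.
#' @export
segment_span <- function(s, segment) {
  stopifnot(inherits(s, "annotated_structure"))
  res <- dplyr::filter(s$residues, .data$segment == !!segment, !is.na(.data$generic))
  if (nrow(res) == 0) return(res)
  res[order(generic_order_key(res$generic)), ]
}

# generic positions with at least one heavy atom present
positions_resolved <- function(s) {
  res <- dplyr::filter(s$residues, !is.na(.data$generic))
  has_atom <- dplyr::semi_join(res, s$atoms, by = c("chain", "seqnum"))
  sort_generic(unique(has_atom$generic))
}

sort_generic <- function(x) x[order(generic_order_key(x))]

# coordinates of one named atom per residue, joined to generic labels
atom_coords <- function(s, atom = "CA", generic_only = TRUE) {
  a <- dplyr::filter(s$atoms, .data$atom == !!atom)
  r <- s$residues
  if (generic_only) r <- dplyr::filter(r, !is.na(.data$generic))
  dplyr::inner_join(
    dplyr::select(r, "chain", "seqnum", "aa", "generic", "segment"),
    dplyr::select(a, "chain", "seqnum", "x", "y", "z"),
    by = c("chain", "seqnum")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
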