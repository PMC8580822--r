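#' Generic residue numbers
#'
#' GPCR residues are indexed with class-independent generic numbers of the
#' form `<segment_code>x<offset>`, where the most conserved position of each
#' transmembrane helix carries offset 50 (e.g. `3x50` on TM3). Helices TM1-TM7
#' use codes 1-7 and helix 8 uses code 8; structurally conserved loops use the
#' two-digit code of the flanking helices (e.g. 45 is ECL2, between TM4 and
#' TM5). Both the ASCII `x` and the typographic multiplication sign are
#' accepted on input; the canonical rendered form uses `x`.
#'
#' @param x character vector of generic labels, e.g. `c("3x50", "45x51")`.
#' @return `parse_generic()` returns a tibble with columns `generic`
#'   (canonical label), `segment_code`, `offset` and `segment`.
#' @examples
#' parse_generic(c("3x50", "45x51", "8x50"))
#' @export
parse_generic <- function(x) {
  x <- gsub("×", "x", as.character(x))
  m <- regmatches(x, regexec("^([1-8]|12|23|34|45|56|67|78)x(-?[0-9]+)$", x))
  bad <- lengths(m) == 0 & !is.na(x)
  if (any(bad)) {
    rlang::abort(paste0(
      "Invalid generic residue label(s): ",
      paste(unique(x[bad]), collapse = ", "),
      ". Expected form '<segment_code>x<offset>', e.g. '3x50'."
    ))
  }
  code <- vapply(m, function(g) if (length(g)) as.integer(g[2]) else NA_integer_, 1L)
  off <- vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_, 1L)
  tibble::tibble(
    generic = ifelse(is.na(code), NA_character_, paste0(code, "x", off)),
    segment_code = code,
    offset = off,
    segment = segment_from_code(code)
  )
}

#' Segment label from a generic segment code
#'
#' Pure lookup: codes 1-7 map to TM1-TM7, 8 to H8, and the two-digit loop
#' codes to the named loops. Code 78 (the short TM7-H8 turn) has no named
#' loop in the segment vocabulary and maps to `"other"`.
#'
#' @param code integer vector of segment codes.
#' @return character vector of segment labels.
#' @export
segment_from_code <- function(code) {
  map <- c(
    "1" = "TM1", "2" = "TM2", "3" = "TM3", "4" = "TM4", "5" = "TM5",
    "6" = "TM6", "7" = "TM7", "8" = "H8",
    "12" = "ICL1", "23" = "ECL1", "34" = "ICL2", "45" = "ECL2",
    "56" = "ICL3", "67" = "ECL3", "78" = "other"
  )
  out <- unname(map[as.character(code)])
  out[is.na(code)] <- NA_character_
  out[!is.na(code) & is.na(out)] <- "other"
  out
}

#' @rdname parse_generic
#' @details `generic_segment()` returns just the segment label of each
#'   generic position; `generic_order_key()` returns an integer sort key so
#'   that positions order by segment code, then offset.
#' @export
generic_segment <- function(x) parse_generic(x)$segment

#' @rdname parse_generic
#' @export
generic_order_key <- function(x) {
  p <- parse_generic(x)
  p$segment_code * 1000L + p$offset
}

# Canonical ordering of a residue pair: smaller segment code first, then offset.
canonical_pair <- function(pos_a, pos_b) {
  ka <- generic_order_key(pos_a)
  kb <- generic_order_key(pos_b)
  swap <- kb < ka
  new_a <- ifelse(swap, pos_b, pos_a)
  new_b <- ifelse(swap, pos_a, pos_b)
  tibble::tibble(pos_a = new_a, pos_b = new_b)
}
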