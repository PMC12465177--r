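#' Parse a coding-DNA (c.) HGVS-like description
#'
#' Supports the subset of HGVS needed for the catalogued variants:
#' substitutions (`c.2908G>A`), deletions (`c.4432_4443del`,
#' `c.531_533delCCT`), insertions (`c.10_11insA`), deletion-insertions
#' (`c.4863_4864delinsAT`) and duplications (`c.10dup`). Intron-anchored
#' positions with offsets (`c.320-443G>C`, `c.2531-52G>A`) are parsed and
#' stored with their offset, but are excluded from codon arithmetic.
#'
#' @param x a single c. description string (the leading "c." is optional).
#' @return a list of class `cds_variant` with fields `cds_start`, `cds_end`,
#'   `offset_start`, `offset_end`, `kind` (substitution, deletion, insertion,
#'   delins, duplication), `ref`, `alt` and `intronic` (TRUE when either end
#'   carries a non-zero offset).
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(length(x) == 1)
  s <- sub("^c\\.", "", trimws(x))
  s <- gsub("[[:space:]]", "", s)
  pos_re <- "(\\d+)([+-]\\d+)?"
  one <- function(m) {
    list(pos = as.integer(m[1]),
         off = if (is.na(m[2]) || m[2] == "") 0L else as.integer(m[2]))
  }
  grab <- function(re, s) {
    m <- regmatches(s, regexec(re, s))[[1]]
    if (!length(m)) NULL else m[-1]
  }
  span_re <- paste0("^", pos_re, "(?:_", pos_re, ")?")
  m <- grab(paste0(span_re, "([ACGT]+)>([ACGT]+)$"), s)
  kind <- NULL
  if (!is.null(m)) {
    kind <- "substitution"; ref <- m[5]; alt <- m[6]
  } else if (!is.null(m <- grab(paste0(span_re, "delins([ACGT]+)$"), s))) {
    kind <- "delins"; ref <- NA_character_; alt <- m[5]
  } else if (!is.null(m <- grab(paste0(span_re, "del([ACGT]*)$"), s))) {
    kind <- "deletion"; ref <- if (nzchar(m[5])) m[5] else NA_character_
    alt <- NA_character_
  } else if (!is.null(m <- grab(paste0(span_re, "ins([ACGT]+)$"), s))) {
    kind <- "insertion"; ref <- NA_character_; alt <- m[5]
  } else if (!is.null(m <- grab(paste0(span_re, "dup([ACGT]*)$"), s))) {
    kind <- "duplication"; ref <- if (nzchar(m[5])) m[5] else NA_character_
    alt <- NA_character_
  } else {
    stop("unparseable c. description: ", x)
  }
  p1 <- one(m[1:2])
  p2 <- if (is.na(m[3]) || m[3] == "") p1 else one(m[3:4])
  if (p2$pos < p1$pos) stop("cds_end must be >= cds_start in ", x)
  if (kind == "substitution" && p2$pos != p1$pos) {
    stop("substitution must be a single position in ", x)
  }
  structure(list(cds_start = p1$pos, cds_end = p2$pos,
                 offset_start = p1$off, offset_end = p2$off,
                 kind = kind, ref = ref, alt = alt,
                 intronic = p1$off != 0L || p2$off != 0L),
            class = "cds_variant")
}

#' Codon index of a coding-DNA position
#'
#' Maps a 1-based CDS nucleotide position to its 1-based codon (protein
#' residue) index: `ceiling(cds_pos / 3)`. Intron-anchored offset positions
#' are not coding nucleotides and are rejected.
#'
#' @param cds_pos positive integer CDS position(s), or a `cds_variant` whose
#'   start position is used.
#' @return integer codon index (vectorised over positions).
#' @export
cds_to_codon <- function(cds_pos) {
  if (inherits(cds_pos, "cds_variant")) {
    if (cds_pos$intronic) {
      stop("intron-anchored (offset) position has no codon index")
    }
    cds_pos <- cds_pos$cds_start
  }
  if (!is.numeric(cds_pos) || any(is.na(cds_pos)) || any(cds_pos < 1) ||
      any(cds_pos != floor(cds_pos))) {
    stop("cds_pos must be positive integer coding position(s)")
  }
  as.integer(ceiling(cds_pos / 3))
}

#' Length in bp of a span event
#'
#' @param v a `cds_variant` of kind deletion, delins or duplication (span
#'   events); substitutions are rejected.
#' @return `cds_end - cds_start + 1`.
#' @export
span_length <- function(v) {
  stopifnot(inherits(v, "cds_variant"))
  if (v$kind %in% c("substitution")) {
    stop("span_length is undefined for a substitution")
  }
  v$cds_end - v$cds_start + 1L
}

#' Net coding-length change of a variant
#'
#' Deletions remove the span; insertions add the inserted allele; delins
#' removes the span and adds the inserted allele; duplications add the span.
#'
#' @param v a `cds_variant`.
#' @return integer net change in coding nucleotides (negative for loss).
#' @export
net_length_change <- function(v) {
  stopifnot(inherits(v, "cds_variant"))
  ins <- if (!is.na(v$alt)) nchar(v$alt) else 0L
  switch(v$kind,
         substitution = 0L,
         deletion = -span_length(v),
         insertion = ins,
         delins = ins - span_length(v),
         duplication = span_length(v))
}

#' In-frame or frameshift consequence of a length-changing variant
#'
#' @param v a `cds_variant` with a defined net length change (deletion,
#'   insertion, delins or duplication).
#' @return `"in_frame"` when the net change is a multiple of 3, else
#'   `"frameshift"`.
#' @export
frame_effect <- function(v) {
  stopifnot(inherits(v, "cds_variant"))
  if (v$kind == "substitution") {
    stop("frame_effect applies to length-changing variants")
  }
  if (net_length_change(v) %% 3L == 0L) "in_frame" else "frameshift"
}

#' Residue range spanned by an in-frame deletion
#'
#' Returns the first and last codon touched by the deleted span,
#' `(ceiling(cds_start/3), ceiling(cds_end/3))`. Non-codon-aligned in-frame
#' deletions report the spanned codon range as printed, without 3'-rule
#' re-normalisation.
#'
#' @param v an in-frame `cds_variant` deletion.
#' @return integer vector `c(first_codon, last_codon)`.
#' @export
inframe_residue_range <- function(v) {
  stopifnot(inherits(v, "cds_variant"))
  if (frame_effect(v) != "in_frame") {
    stop("residue range is undefined for a frameshift")
  }
  c(cds_to_codon(v$cds_start), cds_to_codon(v$cds_end))
}
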