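#' Coding-sequence coordinate
#'
#' A position in HGVS c. space: `base` is the 1-based position counted from
#' the A of the translation start codon along the spliced transcript;
#' `offset` is the signed intronic offset (`0` for exonic positions, `+n` for
#' the n-th base of the downstream intron counted from the donor, `-n` for
#' the n-th base upstream of the acceptor). 5'UTR (negative) and 3'UTR (`*`)
#' c. positions are not supported.
#'
#' @param base integer c. position, >= 1.
#' @param offset signed integer intron offset, default 0.
#' @return an object of class `coding_coord`.
#' @examples
#' coding_coord(2052, +3)
#' @export
coding_coord <- function(base, offset = 0L) {
  base <- as.integer(base)
  offset <- as.integer(offset)
  if (is.na(base) || base < 1L) stop("c. base position must be an integer >= 1")
  if (is.na(offset)) stop("intron offset must be an integer")
  structure(list(base = base, offset = offset), class = "coding_coord")
}

#' @export
print.coding_coord <- function(x, ...) {
  cat("c.", format_coding_coord(x), "\n", sep = "")
  invisible(x)
}

format_coding_coord <- function(x) {
  if (x$offset == 0L) as.character(x$base)
  else paste0(x$base, ifelse(x$offset > 0L, "+", "-"), abs(x$offset))
}

# transcript-order comparison key: -n sorts before the base, +n after
coord_key <- function(x) x$base + sign(x$offset) * (0.5 - 1 / (abs(x$offset) + 2))

coord_lte <- function(a, b) {
  if (a$base != b$base) return(a$base < b$base)
  a$offset <= b$offset
}

#' Variant descriptor in coding coordinates
#'
#' @param kind one of `substitution`, `deletion`, `duplication`, `insertion`,
#'   `delins`.
#' @param start,end [coding_coord()] bounds in transcript order.
#' @param ref_allele,alt_allele nucleotide strings; may be empty depending on
#'   `kind` (e.g. a `del` without stated bases).
#' @return an object of class `variant_descriptor`.
#' @export
variant_descriptor <- function(kind, start, end = start, ref_allele = "",
                               alt_allele = "") {
  kind <- match.arg(kind,
    c("substitution", "deletion", "duplication", "insertion", "delins"))
  stopifnot(inherits(start, "coding_coord"), inherits(end, "coding_coord"))
  if (!coord_lte(start, end))
    stop("variant start must not lie after end in transcript order")
  if (kind == "substitution" &&
      (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L))
    stop("substitution requires single-base ref and alt alleles")
  if (kind == "delins" && !nzchar(alt_allele))
    stop("delins requires a non-empty alt allele")
  if (kind == "insertion" && !nzchar(alt_allele))
    stop("insertion requires inserted bases")
  structure(
    list(kind = kind, start = start, end = end,
         ref_allele = ref_allele, alt_allele = alt_allele),
    class = "variant_descriptor")
}

#' Parse an HGVS c. variant string
#'
#' Supports the closed dialect used for panel reporting: substitutions
#' (`c.2052+3G>T`), deletions (`c.8440_8447del`), duplications
#' (`c.7833_7837dup`), insertions (`c.100_101insAT`) and deletion-insertions
#' (`c.198_200delinsCC`), with optional signed intron offsets on either
#' coordinate. Whitespace is ignored. Inversions, repeats, alleles and other
#' HGVS constructs are rejected with an explicit "unsupported" error rather
#' than silently misparsed.
#'
#' @param text an HGVS coding-DNA string beginning with `c.`.
#' @return a [variant_descriptor()].
#' @examples
#' parse_hgvs_c("c.2052+3G>T")
#' parse_hgvs_c("c.198_200delinsCC")
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- gsub("[[:space:]]+", "", text)
  if (!startsWith(txt, "c."))
    stop("not an HGVS c. string (must begin with 'c.'): ", text)
  body <- substring(txt, 3L)

  unsupported <- c("inv", "con", "\\[", "\\(", ";", "=", "\\^")
  for (pat in unsupported) {
    if (grepl(pat, body))
      stop("unsupported HGVS construct in '", text, "'")
  }

  pos_re <- "(\\d+)([+-]\\d+)?"
  mk <- function(base, off) {
    coding_coord(as.integer(base),
                 if (is.na(off) || off == "") 0L else as.integer(off))
  }

  # substitution: <pos><ref>><alt>
  m <- regmatches(body, regexec(paste0("^", pos_re, "([ACGT])>([ACGT])$"), body))[[1]]
  if (length(m)) {
    p <- mk(m[2], m[3])
    return(variant_descriptor("substitution", p, p,
                              ref_allele = m[4], alt_allele = m[5]))
  }

  # del / dup / delins / ins with optional range
  m <- regmatches(body, regexec(
    paste0("^", pos_re, "(?:_", pos_re, ")?(delins|del|dup|ins)([ACGT]*)$"),
    body))[[1]]
  if (length(m)) {
    start <- mk(m[2], m[3])
    end <- if (m[4] == "") start else mk(m[4], m[5])
    op <- m[6]
    seqs <- m[7]
    if (op == "del")
      return(variant_descriptor("deletion", start, end, ref_allele = seqs))
    if (op == "dup")
      return(variant_descriptor("duplication", start, end, ref_allele = seqs,
                                alt_allele = seqs))
    if (op == "delins") {
      if (!nzchar(seqs)) stop("delins without inserted bases in '", text, "'")
      return(variant_descriptor("delins", start, end, alt_allele = seqs))
    }
    if (op == "ins") {
      if (m[4] == "")
        stop("insertion requires a flanking-pair range, got '", text, "'")
      if (!nzchar(seqs)) stop("insertion without inserted bases in '", text, "'")
      return(variant_descriptor("insertion", start, end, alt_allele = seqs))
    }
  }

  stop("cannot parse HGVS c. string '", text, "': offending token '",
       body, "'")
}

#' Serialize a variant descriptor to canonical HGVS c. form
#'
#' Inverse of [parse_hgvs_c()]: `format_hgvs_c(parse_hgvs_c(x))` equals `x`
#' up to whitespace.
#'
#' @param v a [variant_descriptor()].
#' @return character scalar.
#' @export
format_hgvs_c <- function(v) {
  stopifnot(inherits(v, "variant_descriptor"))
  s <- format_coding_coord(v$start)
  e <- format_coding_coord(v$end)
  range <- if (identical(v$start, v$end)) s else paste0(s, "_", e)
  body <- switch(v$kind,
    substitution = paste0(s, v$ref_allele, ">", v$alt_allele),
    deletion     = paste0(range, "del", v$ref_allele),
    duplication  = paste0(range, "dup", v$ref_allele),
    insertion    = paste0(range, "ins", v$alt_allele),
    delins       = paste0(range, "delins", v$alt_allele))
  paste0("c.", body)
}

#' @export
print.variant_descriptor <- function(x, ...) {
  cat("<variant> ", format_hgvs_c(x), " [", x$kind, "]\n", sep = "")
  invisible(x)
}
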