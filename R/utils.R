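# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] returning a plain
#' character scalar.
#'
#' @param x single nucleotide string (A/C/G/T/N).
#' @return reverse-complemented string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# vectorized codon -> amino-acid lookup using the standard genetic code
.codon_table <- function() Biostrings::GENETIC_CODE

#' Translate a nucleotide string in frame 0
#'
#' Translates from the first position to the end of the last complete codon,
#' standard genetic code, stop rendered as `*`. Translation does NOT stop at
#' the first stop codon; callers decide how to truncate.
#'
#' @param nt nucleotide string.
#' @return character vector of one-letter amino acids (including `*`).
#' @keywords internal
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n < 3L) return(character(0))
  n_codon <- n %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(.codon_table()[codons])
  aa[is.na(aa)] <- "X"
  aa
}

# three-letter amino-acid codes, HGVS style
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", X = "Xaa", `*` = "*"
)

aa_three <- function(aa1) unname(AA3[aa1])

# run code with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
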