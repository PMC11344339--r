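#' Biallelic SNP genotype panel
#'
#' Container for a samples-by-SNPs matrix of alternate-allele dosages
#' (0/1/2, `NA` = missing call) with SNP metadata and per-SNP allele
#' frequencies. Positions must be strictly increasing within each
#' chromosome. Frequencies may be supplied (e.g. known simulation truth) or
#' estimated from the matrix with [estimate_freqs()].
#'
#' @param genotypes integer matrix, rows = samples, columns = SNPs.
#' @param snps data.frame with columns `chrom`, `pos` and optionally `id`.
#' @param samples sample identifiers (default rownames of `genotypes`).
#' @param freqs optional numeric vector of per-SNP allele frequencies.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, snps, samples = rownames(genotypes),
                           freqs = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(snps), all(c("chrom", "pos") %in% names(snps)))
  if (ncol(genotypes) != nrow(snps))
    stop("genotype matrix has ", ncol(genotypes), " SNP columns but ",
         nrow(snps), " SNP records")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  if (length(samples) != nrow(genotypes))
    stop("sample ids do not match genotype rows")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype dosages must be 0, 1, 2 or NA")
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (any(diff(p) <= 0))
      stop("SNP positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(snps$id))
    snps$id <- paste0(snps$chrom, ":", snps$pos)
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == nrow(snps))
    if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
      stop("frequencies must lie in [0,1]")
  }
  rownames(genotypes) <- samples
  structure(list(genotypes = genotypes, snps = snps,
                 samples = samples, freqs = freqs),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$samples), " samples x ", nrow(x$snps),
      " SNPs on ", length(unique(x$snps$chrom)), " chromosome(s)",
      if (!is.null(x$freqs)) ", frequencies attached" else "", "\n", sep = "")
  invisible(x)
}

#' Estimate per-SNP alternate-allele frequencies
#'
#' Frequency = (sum of dosages) / (2 x non-missing sample count). SNPs that
#' are monomorphic (frequency 0 or 1) or entirely missing are flagged; the
#' IBD estimator excludes them.
#'
#' @param panel a [genotype_panel()].
#' @return the panel with `freqs` filled in and a logical `monomorphic`
#'   attribute on the frequency vector.
#' @export
estimate_freqs <- function(panel) {
  g <- panel$genotypes
  n_obs <- colSums(!is.na(g))
  s <- colSums(g, na.rm = TRUE)
  f <- ifelse(n_obs > 0L, s / (2 * n_obs), NA_real_)
  mono <- is.na(f) | f <= 0 | f >= 1
  attr(f, "monomorphic") <- mono
  panel$freqs <- f
  panel
}

# conditional IBS-state probabilities given IBD state, per SNP with allele
# frequency p (all terms are symmetric in p <-> 1-p):
#   P(IBS0|Z0) = 2 p^2 q^2
#   P(IBS1|Z0) = 4 p^3 q + 4 p q^3
#   P(IBS1|Z1) = 2 p q
#   P(IBS2|Z0) = p^4 + q^4 + 4 p^2 q^2
#   P(IBS2|Z1) = p^2 + q^2
#   P(IBS2|Z2) = 1
ibd_expectation_terms <- function(p) {
  q <- 1 - p
  list(e00 = 2 * p^2 * q^2,
       e10 = 4 * p^3 * q + 4 * p * q^3,
       e11 = 2 * p * q,
       e20 = p^4 + q^4 + 4 * p^2 * q^2,
       e21 = p^2 + q^2)
}

# moment solve from observed IBS counts and summed expectation terms,
# followed by constraint enforcement (truncate to [0,1], renormalize)
.ibd_solve <- function(n0, n1, n2, s00, s10, s11, s20, s21, n) {
  z0 <- n0 / s00
  z1 <- (n1 - z0 * s10) / s11
  z2 <- (n2 - z0 * s20 - z1 * s21) / n
  z <- pmax(c(z0, z1, z2), 0)
  z <- pmin(z, 1)
  s <- sum(z)
  if (s == 0) z <- c(1, 0, 0) else z <- z / s
  z
}

#' Method-of-moments estimate of pairwise identity by descent
#'
#' Estimates the probabilities (Z0, Z1, Z2) that two individuals share 0, 1
#' or 2 alleles identical by descent at a locus, from observed
#' identity-by-state counts over a set of biallelic SNPs with known allele
#' frequencies, and reports `PI_HAT = Z2 + Z1/2` — the expected proportion
#' of alleles shared IBD. Identical genotype vectors give `PI_HAT = 1`
#' exactly; independently drawn individuals give values near 0;
#' parent-offspring pairs near 0.5.
#'
#' Moment equations are solved in IBS-count order (Z0 from IBS0, then Z1,
#' then Z2), after which estimates are truncated to `[0,1]` and renormalized
#' to sum to 1 (no small-sample bias-correction factors are applied). SNPs
#' that are monomorphic or missing in either sample are excluded pairwise.
#'
#' @param g_a,g_b integer dosage vectors (0/1/2/NA) on the same SNP list.
#' @param freqs per-SNP allele frequencies.
#' @param min_snps estimates using fewer informative SNPs are flagged
#'   low-confidence (default 20).
#' @return object of class `ibd_estimate`: `z0`, `z1`, `z2`, `pi_hat`,
#'   `n_snps_used`, `low_confidence`.
#' @export
ibd_mom_estimate <- function(g_a, g_b, freqs, min_snps = 20L) {
  stopifnot(length(g_a) == length(g_b), length(freqs) == length(g_a))
  use <- !is.na(g_a) & !is.na(g_b) & !is.na(freqs) & freqs > 0 & freqs < 1
  a <- g_a[use]; b <- g_b[use]; p <- freqs[use]
  n <- length(a)
  if (n == 0L)
    return(structure(list(z0 = NA_real_, z1 = NA_real_, z2 = NA_real_,
                          pi_hat = NA_real_, n_snps_used = 0L,
                          low_confidence = TRUE), class = "ibd_estimate"))
  d <- abs(a - b)
  n0 <- sum(d == 2L); n1 <- sum(d == 1L); n2 <- sum(d == 0L)
  e <- ibd_expectation_terms(p)
  z <- .ibd_solve(n0, n1, n2,
                  sum(e$e00), sum(e$e10), sum(e$e11),
                  sum(e$e20), sum(e$e21), n)
  structure(list(z0 = z[1], z1 = z[2], z2 = z[3],
                 pi_hat = z[3] + z[2] / 2, n_snps_used = n,
                 low_confidence = n < min_snps),
            class = "ibd_estimate")
}

#' @export
print.ibd_estimate <- function(x, ...) {
  cat(sprintf("<ibd_estimate> Z0=%.4f Z1=%.4f Z2=%.4f PI_HAT=%.4f (%d SNPs%s)\n",
              x$z0, x$z1, x$z2, x$pi_hat, x$n_snps_used,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' All pairwise PI_HAT values among a set of samples
#'
#' @param panel a [genotype_panel()] with frequencies.
#' @param samples sample ids (default all).
#' @param snp_idx optional SNP column subset.
#' @return data.frame with `sample_a`, `sample_b`, `pi_hat`, `n_snps_used`.
#' @export
pairwise_pihat <- function(panel, samples = panel$samples, snp_idx = NULL) {
  if (is.null(panel$freqs)) panel <- estimate_freqs(panel)
  idx <- snp_idx %||% seq_len(nrow(panel$snps))
  rows <- match(samples, panel$samples)
  if (anyNA(rows)) stop("unknown sample id(s): ",
                        paste(samples[is.na(rows)], collapse = ", "))
  g <- panel$genotypes[rows, idx, drop = FALSE]
  f <- panel$freqs[idx]
  pairs <- utils::combn(length(rows), 2)
  out <- apply(pairs, 2, function(pr) {
    est <- ibd_mom_estimate(g[pr[1], ], g[pr[2], ], f)
    c(est$pi_hat, est$n_snps_used)
  })
  data.frame(sample_a = samples[pairs[1, ]], sample_b = samples[pairs[2, ]],
             pi_hat = out[1, ], n_snps_used = as.integer(out[2, ]),
             stringsAsFactors = FALSE)
}
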