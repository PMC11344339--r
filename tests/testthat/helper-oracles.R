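# Independent oracles and shared toy fixtures. These deliberately avoid the
# package's own code paths: the IBD oracle is a per-SNP scalar loop, the
# translation oracle goes through Biostrings::translate on the whole tail.

# naive per-SNP loop implementation of the method-of-moments IBD estimate
naive_ibd_loop <- function(g_a, g_b, freqs) {
  n0 <- n1 <- n2 <- 0
  s00 <- s10 <- s11 <- s20 <- s21 <- 0
  n <- 0
  for (j in seq_along(g_a)) {
    if (is.na(g_a[j]) || is.na(g_b[j])) next
    p <- freqs[j]
    if (is.na(p) || p <= 0 || p >= 1) next
    n <- n + 1
    d <- abs(g_a[j] - g_b[j])
    if (d == 2) n0 <- n0 + 1 else if (d == 1) n1 <- n1 + 1 else n2 <- n2 + 1
    q <- 1 - p
    s00 <- s00 + 2 * p^2 * q^2
    s10 <- s10 + 4 * p^3 * q + 4 * p * q^3
    s11 <- s11 + 2 * p * q
    s20 <- s20 + p^4 + q^4 + 4 * p^2 * q^2
    s21 <- s21 + p^2 + q^2
  }
  z0 <- n0 / s00
  z1 <- (n1 - z0 * s10) / s11
  z2 <- (n2 - z0 * s20 - z1 * s21) / n
  z <- c(z0, z1, z2)
  z[z < 0] <- 0
  z[z > 1] <- 1
  if (sum(z) == 0) z <- c(1, 0, 0) else z <- z / sum(z)
  list(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[3] + z[2] / 2,
       n_snps_used = n)
}

# Biostrings-based translation of an mRNA from a start position to the
# first stop codon; returns one-letter residues without the stop
oracle_protein <- function(mrna, cds_start) {
  tail_nt <- substring(mrna, cds_start, nchar(mrna))
  tail_nt <- substring(tail_nt, 1L, 3L * (nchar(tail_nt) %/% 3L))
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(tail_nt))))
  aa_vec <- strsplit(aa, "")[[1]]
  stop_at <- match("*", aa_vec)
  list(protein = if (is.na(stop_at)) aa_vec else aa_vec[seq_len(stop_at - 1L)],
       has_stop = !is.na(stop_at))
}

# independent frameshift bookkeeping: novel residues after the last
# wild-type-matching residue, before the stop
oracle_novel_count <- function(wt_prot, alt_prot) {
  lim <- min(length(wt_prot), length(alt_prot))
  diffs <- which(wt_prot[seq_len(lim)] != alt_prot[seq_len(lim)])
  first_diff <- if (length(diffs)) diffs[1L] else lim + 1L
  max(length(alt_prot) - first_diff + 1L, 0L)
}

# plus-strand toy with exon boundaries matching the published splice cases:
# the last base of exon 14 is c.2052 and exon 24 starts at c.3599, so
# c.2052+3 sits in the intron-14 donor region and c.3599-2 at the
# intron-23 canonical acceptor
splice_case_model <- function() {
  lens <- c(rep(150L, 13L), 102L, rep(172L, 8L), 170L, 236L, 150L, 153L)
  starts <- 1L + (seq_along(lens) - 1L) * 10000L
  transcript_model("TOY_SPLICE", "chrT", "+",
                   data.frame(start = starts, end = starts + lens - 1L),
                   cds_start_tx = 1L, cds_end_tx = sum(lens))
}

# toy with the last base of exon 5 at c.510 (canonical-donor case)
donor_case_model <- function() {
  lens <- c(rep(102L, 5L), 138L, 150L, 150L)
  starts <- 1L + (seq_along(lens) - 1L) * 5000L
  transcript_model("TOY_DONOR", "chrT", "+",
                   data.frame(start = starts, end = starts + lens - 1L),
                   cds_start_tx = 1L, cds_end_tx = sum(lens))
}

# random valid splice event for a generated fixture's geometry
random_event <- function(n_exons) {
  kind <- sample(c("exon_skip", "partial_intron_retention_3prime",
                   "partial_intron_retention_5prime",
                   "exonic_acceptor_truncation"), 1L)
  if (kind == "exon_skip")
    splice_event(kind, sample(2:n_exons, 1L))
  else if (kind == "exonic_acceptor_truncation")
    splice_event(kind, sample(2:n_exons, 1L), length_nt = sample(10:80, 1L))
  else
    splice_event(kind, sample(1:(n_exons - 1L), 1L),
                 length_nt = sample(5:60, 1L))
}
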