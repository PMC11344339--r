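test_that("model construction enforces exon and CDS invariants", {
  ex <- data.frame(start = c(1001, 2001), end = c(1100, 2100))
  expect_s3_class(transcript_model("T", "chr1", "+", ex, 1, 198),
                  "transcript_model")
  # zero-length exon
  expect_error(transcript_model("T", "chr1", "+",
                                data.frame(start = 100, end = 99), 1, 3),
               "length >= 1")
  # overlap / wrong order on the plus strand
  expect_error(transcript_model("T", "chr1", "+",
                                data.frame(start = c(100, 150), end = c(160, 200)),
                                1, 99), "non-overlapping")
  # minus-strand exons must be genomically decreasing
  expect_error(transcript_model("T", "chr1", "-",
                                data.frame(start = c(100, 300), end = c(200, 400)),
                                1, 99), "decreasing")
  # CDS not a codon multiple
  expect_error(transcript_model("T", "chr1", "+", ex, 1, 100), "divisible")
  expect_error(transcript_model("T", "chr1", "+", ex, 0, 99), "CDS bounds")
})

test_that("coding positions map to hand-counted genomic coordinates", {
  # two exons of 100 nt starting at 1001 and 2001, CDS from tx position 1:
  # c.150 is the 50th base of exon 2 -> 2050
  tm <- transcript_model("T", "chr1", "+",
                         data.frame(start = c(1001, 2001), end = c(1100, 2100)),
                         1, 198)
  expect_identical(c_to_genomic(tm, coding_coord(150))$pos, 2050L)
  expect_identical(c_to_genomic(tm, coding_coord(1))$pos, 1001L)
  expect_identical(c_to_genomic(tm, coding_coord(100, +3))$pos, 1103L)
  expect_identical(c_to_genomic(tm, coding_coord(101, -2))$pos, 1999L)
  back <- genomic_to_c(tm, 1001L)
  expect_identical(c(back$base, back$offset), c(1L, 0L))
  # out of range
  expect_error(c_to_genomic(tm, coding_coord(300)), "outside")
  expect_error(c_to_genomic(tm, coding_coord(100, 1500)), "exceeds intron")
  # offsets must anchor at exon boundaries
  expect_error(c_to_genomic(tm, coding_coord(50, +3)), "last base")
})

test_that("coordinate mapping round-trips on random models, both strands", {
  for (seed in 1:10) {
    strand <- if (seed %% 2L == 0L) "+" else "-"
    fx <- gen_transcript_fixture(seed, n_exons = 6L, strand = strand)
    m <- fx$model
    set.seed(1000 + seed)
    # exonic: c -> genomic -> c is the identity
    for (b in sample.int(m$spliced_len, 50L)) {
      g <- c_to_genomic(m, coding_coord(b))
      back <- genomic_to_c(m, g$pos)
      expect_identical(c(back$base, back$offset), c(b, 0L))
    }
    # near-junction intronic coordinates round-trip exactly
    cum <- m$cum_len
    for (k in seq_len(length(m$exon_len) - 1L)) {
      for (d in c(1L, 2L, sample.int(6L, 1L))) {
        don <- coding_coord(cum[k], d)
        g <- c_to_genomic(m, don)
        back <- genomic_to_c(m, g$pos)
        expect_identical(c(back$base, back$offset), c(don$base, don$offset))
        acc <- coding_coord(cum[k] + 1L, -d)
        g <- c_to_genomic(m, acc)
        back <- genomic_to_c(m, g$pos)
        expect_identical(c(back$base, back$offset), c(acc$base, acc$offset))
      }
    }
    # arbitrary genomic positions (exonic or intronic): g -> c -> g identity
    lo <- min(m$exon_start); hi <- max(m$exon_end)
    for (g in sample(seq(lo, hi), 50L)) {
      cc <- genomic_to_c(m, g)
      expect_identical(c_to_genomic(m, cc)$pos, g)
    }
  }
})

test_that("splice-region classification reproduces the panel's intron calls", {
  m <- splice_case_model()
  # last base of exon 14 is c.2052: +3 is the donor region of intron 14
  r <- classify_splice_region(m, parse_hgvs_c("c.2052+3G>T"))
  expect_identical(r[c("region", "ordinal")],
                   list(region = "donor_region", ordinal = 14L))
  # exon 24 starts at c.3599: -2 is the canonical acceptor of intron 23
  r <- classify_splice_region(m, parse_hgvs_c("c.3599-2A>G"))
  expect_identical(r[c("region", "ordinal")],
                   list(region = "canonical_acceptor", ordinal = 23L))
  d <- donor_case_model()
  r <- classify_splice_region(d, parse_hgvs_c("c.510+1G>C"))
  expect_identical(r[c("region", "ordinal")],
                   list(region = "canonical_donor", ordinal = 5L))
  # exonic and deep-intronic labels
  expect_identical(classify_splice_region(m, coding_coord(2052))$region,
                   "exonic_near_junction")
  expect_identical(classify_splice_region(m, coding_coord(75))$region,
                   "exonic_internal")
  expect_identical(classify_splice_region(m, coding_coord(2052, 500))$region,
                   "deep_intronic")
  expect_identical(classify_splice_region(m, coding_coord(3599, -8))$region,
                   "acceptor_region")
})

test_that("spliced mRNA assembly is strand-aware and length-conserving", {
  # single-exon plus-strand model returns its sequence unchanged
  one <- transcript_model("ONE", "chr1", "+",
                          data.frame(start = 11, end = 22), 1, 12,
                          seq_genomic = "AAAATGCCCGGG", seq_offset = 11L)
  expect_identical(build_spliced_mrna(one), "AAAATGCCCGGG")
  # two-exon minus-strand toy, expected mRNA written out by hand:
  # genomic TTTTTCATGG (offset 101); exon1 = 107..110 -> revcomp(ATGG) =
  # CCAT; exon2 = 101..103 -> revcomp(TTT) = AAA
  mm <- transcript_model("MINUS", "chr1", "-",
                         data.frame(start = c(107, 101), end = c(110, 103)),
                         1, 6, seq_genomic = "TTTTTCATGG", seq_offset = 101L)
  expect_identical(build_spliced_mrna(mm), "CCATAAA")
  # length conservation over generated models
  for (seed in 21:25) {
    fx <- gen_transcript_fixture(seed, n_exons = 5L,
                                 strand = if (seed %% 2) "-" else "+")
    expect_identical(nchar(build_spliced_mrna(fx$model)),
                     sum(fx$model$exon_len))
  }
  # sequence-less model errors
  expect_error(build_spliced_mrna(splice_case_model()), "no sequence")
})

test_that("exon tables round-trip through the TSV reader and writer", {
  fx <- gen_transcript_fixture(31, n_exons = 4L, strand = "-")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_exon_table(fx$model, path)
  models <- read_exon_table(path, cds_start_tx = fx$model$cds_start_tx,
                            cds_end_tx = fx$model$cds_end_tx)
  m2 <- models[[fx$model$id]]
  expect_identical(m2$exon_start, fx$model$exon_start)
  expect_identical(m2$exon_end, fx$model$exon_end)
  expect_identical(m2$strand, "-")
  # FASTA attachment restores the spliced mRNA
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(paste0(">", fx$model$chrom), fx$model$seq_genomic), fa)
  m3 <- attach_sequence(m2, fa, seq_offset = fx$model$seq_offset)
  expect_identical(build_spliced_mrna(m3), build_spliced_mrna(fx$model))
})
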