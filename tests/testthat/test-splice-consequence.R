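test_that("splice events change the mRNA by exactly their declared extent", {
  # the four event geometries observed in the study's RT-PCR work:
  # a 322-nt exon skip, an 18-nt intron retention, a 59-nt exonic
  # truncation, a 138-nt exon skip
  cases <- list(
    list(fx = gen_transcript_fixture(101, n_exons = 10L,
           event = splice_event("exon_skip", 5L, 322L)), delta = -322L),
    list(fx = gen_transcript_fixture(102, n_exons = 10L,
           event = splice_event("partial_intron_retention_3prime", 7L, 18L)),
         delta = +18L),
    list(fx = gen_transcript_fixture(103, n_exons = 10L,
           event = splice_event("exonic_acceptor_truncation", 4L, 59L)),
         delta = -59L),
    list(fx = gen_transcript_fixture(104, n_exons = 10L,
           event = splice_event("exon_skip", 3L, 138L)), delta = -138L))
  for (cs in cases) {
    alt <- apply_splice_event(cs$fx$model, cs$fx$event)
    expect_identical(alt$delta_nt, cs$delta)
    expect_identical(nchar(alt$mrna) - nchar(build_spliced_mrna(cs$fx$model)),
                     as.integer(cs$delta))
    # the altered mRNA matches the generator's independent construction
    expect_identical(alt$mrna, cs$fx$truth$altered_mrna)
  }
})

test_that("event validation rejects impossible targets and lengths", {
  fx <- gen_transcript_fixture(105, n_exons = 4L)
  m <- fx$model
  expect_error(apply_splice_event(m, splice_event("exon_skip", 9L)),
               "no exon")
  expect_error(apply_splice_event(m, splice_event("exon_skip", 2L, 1L)),
               "does not match")
  expect_error(
    apply_splice_event(m, splice_event("partial_intron_retention_3prime",
                                       2L, 100000L)), "exceeds intron")
  expect_error(
    apply_splice_event(m, splice_event("exonic_acceptor_truncation", 2L,
                                       m$exon_len[2])), "exceeds exon")
})

test_that("frame consequence follows the mod-3 law", {
  expect_identical(frame_consequence(+18),
                   list(frame_class = "in_frame", aa_delta = 6L))
  expect_identical(frame_consequence(-138),
                   list(frame_class = "in_frame", aa_delta = -46L))
  expect_identical(frame_consequence(-322)$frame_class, "frameshift")
  expect_identical(frame_consequence(0),
                   list(frame_class = "in_frame", aa_delta = 0L))
  expect_identical(frame_consequence(-59)$frame_class, "frameshift")
})

test_that("frameshift translation matches the engineered novel-residue count", {
  # out-of-frame exon skip engineered to terminate after exactly 4 novel
  # residues, and an ectopic-acceptor truncation after exactly 11
  fx4 <- gen_transcript_fixture(111, n_exons = 10L,
                                event = splice_event("exon_skip", 3L, 322L),
                                novel_aa = 4L)
  pc <- translate_consequence(apply_splice_event(fx4$model, fx4$event),
                              fx4$model)
  expect_identical(pc$kind, "frameshift_with_PTC")
  expect_identical(pc$novel_aa_count, 4L)
  expect_match(pc$hgvs_p, "fs\\*5$")  # fs*N counts the stop: N = novel + 1

  fx11 <- gen_transcript_fixture(112, n_exons = 8L,
            event = splice_event("exonic_acceptor_truncation", 4L, 59L),
            novel_aa = 11L)
  pc <- translate_consequence(apply_splice_event(fx11$model, fx11$event),
                              fx11$model)
  expect_identical(pc$novel_aa_count, 11L)
  expect_match(pc$hgvs_p, "fs\\*12$")
})

test_that("a stop-gain substitution on a CGA arginine codon is nonsense", {
  # codon 20 is CGA (Arg); c.58C>T turns it into TGA
  codons <- c("ATG", rep("GGC", 18L), "CGA", rep("CTG", 29L), "TAA")
  cds <- paste(codons, collapse = "")
  m <- transcript_model("NONSENSE_TOY", "chr1", "+",
                        data.frame(start = c(1001, 2001),
                                   end = c(1001 + 119, 2001 + 29)),
                        1, 150,
                        seq_genomic = paste0(substring(cds, 1, 120),
                                             strrep("T", 880),
                                             substring(cds, 121, 150)),
                        seq_offset = 1001L)
  alt <- apply_variant(m, "c.58C>T")
  pc <- translate_consequence(alt, m)
  expect_identical(pc$kind, "nonsense")
  expect_identical(pc$hgvs_p, "p.Arg20*")
  # stop codon starts at tx 58, last junction at 120: 62 nt > 55 -> NMD
  expect_true(pc$nmd_predicted)
})

test_that("in-frame events report aa_delta without a premature stop", {
  # +18 retention extending the protein by 6 residues; seeds chosen so the
  # retained bases carry no in-frame stop
  fx <- gen_transcript_fixture(120, n_exons = 10L,
          event = splice_event("partial_intron_retention_3prime", 6L, 18L))
  pc <- translate_consequence(apply_splice_event(fx$model, fx$event), fx$model)
  expect_identical(pc$frame_class, "in_frame")
  expect_identical(pc$kind, "inframe_insertion")
  expect_identical(pc$aa_delta, 6L)
  # -138 skip shortening the protein by 46 residues
  fx <- gen_transcript_fixture(121, n_exons = 10L,
          event = splice_event("exon_skip", 6L, 138L))
  pc <- translate_consequence(apply_splice_event(fx$model, fx$event), fx$model)
  expect_identical(pc$kind, "inframe_deletion")
  expect_identical(pc$aa_delta, -46L)
})

test_that("translation agrees with a brute-force oracle on random fixtures", {
  for (seed in 200:240) {
    fx <- gen_transcript_fixture(seed, n_exons = 6L,
                                 exon_len_range = c(90L, 150L),
                                 strand = if (seed %% 2) "+" else "-")
    ev <- local({ set.seed(seed); random_event(6L) })
    alt <- apply_splice_event(fx$model, ev)
    pc <- translate_consequence(alt, fx$model)

    wt <- oracle_protein(build_spliced_mrna(fx$model), fx$model$cds_start_tx)
    ao <- oracle_protein(alt$mrna, alt$cds_start_tx)
    if (pc$kind == "frameshift_with_PTC") {
      if (ao$has_stop)
        expect_identical(pc$novel_aa_count,
                         oracle_novel_count(wt$protein, ao$protein))
      else  # shifted frame runs off the mRNA end: count undefined
        expect_identical(pc$novel_aa_count, NA_integer_)
    }
    if (!is.na(pc$protein_len))
      expect_identical(pc$protein_len, length(ao$protein))
    # termination position: stop codon starts right after the last residue
    if (ao$has_stop && !is.na(pc$ptc_tx_pos))
      expect_identical(pc$ptc_tx_pos,
                       alt$cds_start_tx + 3L * length(ao$protein))
  }
})

test_that("NMD follows the configurable last-junction distance rule", {
  lens <- c(200L, 200L, 200L)  # last junction at transcript position 400
  expect_true(predict_nmd(100L, lens))        # 300 nt upstream
  expect_false(predict_nmd(390L, lens))       # 10 nt upstream
  expect_false(predict_nmd(450L, lens))       # in the final exon
  expect_false(predict_nmd(100L, 600L))       # single exon: no junction
  expect_true(predict_nmd(344L, lens))        # 56 > 55
  expect_false(predict_nmd(345L, lens))       # exactly 55: escapes
  expect_true(predict_nmd(390L, lens, threshold = 5L))
})

test_that("amplicon sizes follow band arithmetic and report lost primers", {
  # WT amplicon of 472 nt spanning a 322-nt exon: mutant band at 150
  fx <- gen_transcript_fixture(130, n_exons = 15L,
                               event = splice_event("exon_skip", 14L, 322L))
  m <- fx$model
  f <- m$cum_len[13] - 74L   # 75 nt inside exon 13
  r <- m$cum_len[14] + 75L   # 75 nt into exon 15
  pr <- primer_pair(f, r)
  sizes <- predict_amplicon_sizes(m, pr, list(fx$event))
  expect_identical(sizes$size_nt, c(472L, 150L))
  expect_identical(sizes$allele[1], "WT")
  # no events: single WT band
  expect_identical(nrow(predict_amplicon_sizes(m, pr)), 1L)
  # WT 380 with a 138-nt skip -> 242
  fx2 <- gen_transcript_fixture(131, n_exons = 8L,
                                event = splice_event("exon_skip", 5L, 138L))
  f2 <- fx2$model$cum_len[4] - 120L
  pr2 <- primer_pair(f2, f2 + 379L)
  expect_true(fx2$model$cum_len[5] + 1L <= f2 + 379L)
  sizes2 <- predict_amplicon_sizes(fx2$model, pr2, list(fx2$event))
  expect_identical(sizes2$size_nt, c(380L, 242L))
  # mutant minus WT equals delta whenever both primers survive
  expect_identical(sizes2$size_nt[2] - sizes2$size_nt[1], -138L)
  # primer inside the skipped exon is reported lost
  inside <- primer_pair(fx2$model$cum_len[4] + 10L,
                        fx2$model$cum_len[5] + 50L)
  lost <- predict_amplicon_sizes(fx2$model, inside, list(fx2$event))
  expect_identical(lost$status[lost$allele != "WT"], "primer_lost")
  expect_true(is.na(lost$size_nt[lost$allele != "WT"]))
})

test_that("gel comparator accepts approximate band readings", {
  expect_true(gel_match(472, 470))
  expect_true(gel_match(380, 350))   # a ~350 reading of a 380-nt band
  expect_true(gel_match(242, 250))
  expect_false(gel_match(472, 150))
})

test_that("acceptor AG helper lists candidate cryptic sites", {
  fx <- gen_transcript_fixture(140, n_exons = 4L)
  hits <- find_acceptor_ag_sites(fx$model, 2L, window = 60L)
  expect_true(0L %in% hits)  # the canonical acceptor AG itself
  iseq <- foundersplice:::intron_sequence(fx$model, 2L)
  for (d in setdiff(hits, 0L)) {
    g_pos <- nchar(iseq) - d
    expect_identical(substring(iseq, g_pos - 1L, g_pos), "AG")
  }
})

test_that("consequence report tabulates events with amplicons", {
  fx <- gen_transcript_fixture(150, n_exons = 10L,
                               event = splice_event("exon_skip", 5L, 322L))
  pr <- primer_pair(fx$model$cum_len[4] - 50L, fx$model$cum_len[5] + 50L)
  rep1 <- consequence_report(fx$model, list(fx$event), pr)
  expect_identical(nrow(rep1), 1L)
  expect_identical(rep1$delta_nt, -322L)
  expect_identical(rep1$amplicon_nt, rep1$wt_amplicon_nt - 322L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_consequence_report(rep1, path)
  back <- read.delim(path)
  expect_identical(back$delta_nt, -322L)
})
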