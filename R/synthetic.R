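# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes, each paired with a ground-truth record computed by
# direct construction (naive string/arithmetic code paths, never the engine
# under test).

NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))

# naive translation used only for fixture truth: codon-by-codon while loop
.naive_translate <- function(nt) {
  gc <- Biostrings::GENETIC_CODE
  aa <- character(0)
  i <- 1L
  while (i + 2L <= nchar(nt)) {
    a <- unname(gc[substring(nt, i, i + 2L)])
    if (is.na(a)) a <- "X"
    aa <- c(aa, a)
    if (a == "*") break
    i <- i + 3L
  }
  aa
}

# truth for an event, computed from the generator's own exon/intron strings
.naive_event_truth <- function(exon_seqs, intron_seqs, event) {
  wt <- paste(unlist(exon_seqs), collapse = "")
  k <- event$target
  alt <- switch(event$kind,
    exon_skip = paste(unlist(exon_seqs[-k]), collapse = ""),
    exonic_acceptor_truncation = {
      es <- exon_seqs
      es[[k]] <- substring(es[[k]], event$length_nt + 1L, nchar(es[[k]]))
      paste(unlist(es), collapse = "")
    },
    partial_intron_retention_3prime = {
      iseq <- intron_seqs[[k]]
      ins <- substring(iseq, nchar(iseq) - event$length_nt + 1L, nchar(iseq))
      paste(c(unlist(exon_seqs[seq_len(k)]), ins,
              unlist(exon_seqs[(k + 1L):length(exon_seqs)])), collapse = "")
    },
    partial_intron_retention_5prime = {
      iseq <- intron_seqs[[k]]
      ins <- substring(iseq, 1L, event$length_nt)
      paste(c(unlist(exon_seqs[seq_len(k)]), ins,
              unlist(exon_seqs[(k + 1L):length(exon_seqs)])), collapse = "")
    })
  delta <- nchar(alt) - nchar(wt)
  wt_aa <- .naive_translate(wt)
  alt_aa <- .naive_translate(alt)
  strip <- function(a) if (length(a) && a[length(a)] == "*") a[-length(a)] else a
  wt_p <- strip(wt_aa); alt_p <- strip(alt_aa)
  lim <- min(length(wt_p), length(alt_p))
  diffs <- which(wt_p[seq_len(lim)] != alt_p[seq_len(lim)])
  first_diff <- if (length(diffs)) diffs[1L] else lim + 1L
  novel <- if (delta %% 3L == 0L) NA_integer_
    else max(length(alt_p) - first_diff + 1L, 0L)
  list(wt_mrna = wt, altered_mrna = alt, delta_nt = delta,
       frame_class = if (delta %% 3L == 0L) "in_frame" else "frameshift",
       aa_delta = if (delta %% 3L == 0L) delta %/% 3L else NA_integer_,
       novel_aa_count = novel,
       alt_has_stop = any(alt_aa == "*"))
}

#' Generate a synthetic transcript fixture with a planted splice event
#'
#' Builds a random multi-exon transcript (CDS spanning the whole spliced
#' transcript: ATG first codon, TAA last, no internal in-frame stop; introns
#' flanked by canonical GT..AG), plants the requested splice event and
#' derives the expected consequences by direct construction from the
#' generator's own exon/intron strings — independent of the consequence
#' engine.
#'
#' For a frameshift event, `novel_aa` requests that the shifted reading
#' frame meet its first stop after exactly that many novel residues; the
#' coding sequence downstream of the event is resampled until the
#' constraint holds (error if unreachable within `max_tries`).
#'
#' @param seed RNG seed; fixtures are byte-identical under the same seed.
#' @param n_exons number of exons (>= 2 for splice events).
#' @param exon_len_range,intron_len_range length ranges (nt).
#' @param event a [splice_event()] to plant, or NULL.
#' @param novel_aa optional exact novel-residue count for a frameshift
#'   event.
#' @param strand `"+"` or `"-"`.
#' @param chrom,genomic_start genomic placement of the transcript.
#' @param max_tries resampling budget for the `novel_aa` constraint.
#' @return list with `model` (a [transcript_model()] with sequence),
#'   `event`, and `truth` (delta, frame class, aa delta, novel residue
#'   count, wild-type and altered mRNA).
#' @export
gen_transcript_fixture <- function(seed, n_exons = 10L,
                                   exon_len_range = c(90L, 240L),
                                   intron_len_range = c(80L, 400L),
                                   event = NULL, novel_aa = NULL,
                                   strand = "+", chrom = "chrS",
                                   genomic_start = 1000L,
                                   max_tries = 5000L) {
  stopifnot(n_exons >= 1L)
  if (!is.null(event) && event$target > (if (event$kind %in%
      c("partial_intron_retention_3prime", "partial_intron_retention_5prime"))
      n_exons - 1L else n_exons))
    stop("event target exceeds the requested exon/intron count")
  if (!is.null(novel_aa) && is.null(event))
    stop("novel_aa requires a planted event")

  with_seed(seed, {
    # exon lengths; forced event length if the event pins one
    lens <- sample(seq(exon_len_range[1], exon_len_range[2]), n_exons,
                   replace = TRUE)
    if (!is.null(event) && event$kind == "exon_skip" &&
        !is.null(event$length_nt))
      lens[event$target] <- event$length_nt
    # make total CDS length a multiple of 3 by padding one exon (never the
    # exon whose length the event pins)
    pinned <- if (!is.null(event) && event$kind == "exon_skip" &&
                  !is.null(event$length_nt)) event$target else 0L
    pad_at <- if (pinned == n_exons) max(1L, n_exons - 1L) else n_exons
    rem <- sum(lens) %% 3L
    if (rem != 0L) lens[pad_at] <- lens[pad_at] + (3L - rem)
    total <- sum(lens)
    n_codons <- total %/% 3L
    ilens <- if (n_exons > 1L)
      sample(seq(intron_len_range[1], intron_len_range[2]), n_exons - 1L,
             replace = TRUE)
    else integer(0)

    gen_cds <- function() {
      paste(c("ATG", sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
              "TAA"), collapse = "")
    }
    split_cds <- function(cds) {
      ends <- cumsum(lens)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      mapply(function(s, e) substring(cds, s, e), starts, ends,
             SIMPLIFY = FALSE)
    }
    intron_seqs <- lapply(ilens, function(L)
      paste0("GT", random_dna(L - 4L), "AG"))

    tries <- 0L
    repeat {
      tries <- tries + 1L
      exon_seqs <- split_cds(gen_cds())
      if (is.null(event)) { truth <- NULL; break }
      truth <- .naive_event_truth(exon_seqs, intron_seqs, event)
      if (is.null(novel_aa)) break
      if (truth$frame_class != "frameshift")
        stop("novel_aa requested but the event is in-frame (delta = ",
             truth$delta_nt, ")")
      if (truth$alt_has_stop && identical(truth$novel_aa_count,
                                          as.integer(novel_aa))) break
      if (tries >= max_tries)
        stop("could not engineer a premature stop after exactly ", novel_aa,
             " novel residues in ", max_tries, " tries")
    }

    # genomic assembly in transcription order, then strand placement
    parts <- character(2L * n_exons - 1L)
    parts[seq(1L, by = 2L, length.out = n_exons)] <- unlist(exon_seqs)
    if (n_exons > 1L)
      parts[seq(2L, by = 2L, length.out = n_exons - 1L)] <- unlist(intron_seqs)
    txg <- paste(parts, collapse = "")
    ntot <- nchar(txg)
    seg_lens <- c(rbind(lens, c(ilens, NA)))[seq_len(2L * n_exons - 1L)]
    seg_ends <- cumsum(seg_lens)
    seg_starts <- c(1L, utils::head(seg_ends, -1L) + 1L)
    ex_idx <- seq(1L, by = 2L, length.out = n_exons)
    if (strand == "+") {
      seq_genomic <- txg
      ex_start <- genomic_start + seg_starts[ex_idx] - 1L
      ex_end <- genomic_start + seg_ends[ex_idx] - 1L
    } else {
      seq_genomic <- revcomp(txg)
      ex_start <- genomic_start + (ntot - seg_ends[ex_idx])
      ex_end <- genomic_start + (ntot - seg_starts[ex_idx])
    }
    model <- transcript_model(
      id = sprintf("SYN_%06d", seed), chrom = chrom, strand = strand,
      exons = data.frame(start = ex_start, end = ex_end),
      cds_start_tx = 1L, cds_end_tx = total,
      seq_genomic = seq_genomic, seq_offset = genomic_start)
    list(model = model, event = event, truth = truth)
  })
}

#' Generate a synthetic SNP cohort with a planted founder segment
#'
#' Simulates a biallelic genotype panel: allele frequencies drawn from
#' `Beta(shape1, shape2)` and clipped to `freq_clip` (avoiding monomorphic
#' SNPs), genotypes as Hardy–Weinberg draws, SNP positions spaced with
#' uniform jitter around `mean_spacing_bp` (the default spacing makes a
#' 275-SNP segment span about 6.25 Mb). A founder segment may be planted:
#' the carrier samples receive one shared, base-identical haplotype across
#' the segment plus an independently drawn second haplotype
#' (`mode = "haplotype"`); with `mode = "identical"` both haplotypes are
#' shared, making carriers' genotypes identical across the segment. The
#' shared haplotype carries the alternate allele at the central (index)
#' SNP. An optional `erosion_snps` shortens each carrier's segment
#' independently at both ends by a uniform amount, emulating recombination
#' edge decay.
#'
#' @param seed RNG seed.
#' @param n_samples cohort size (default 100).
#' @param n_chrom number of chromosomes (default 22).
#' @param snps_per_chrom SNPs per chromosome (default 16000, sized so the
#'   genome hosts 200 non-overlapping 500-SNP-flank control intervals under
#'   rejection sampling).
#' @param shape1,shape2 Beta parameters for allele frequencies (default
#'   2, 2).
#' @param freq_clip clipping bounds (default `c(0.05, 0.95)`).
#' @param founder NULL, or a list with `chrom` (default first), `n_carriers`
#'   (default 4), `segment_snps` (default 275), `mode`
#'   (`"haplotype"`/`"identical"`), `erosion_snps` (default 0).
#' @param mean_spacing_bp mean inter-SNP spacing (default 22727 bp).
#' @param spacing_jitter relative uniform jitter on spacing (default 0.5).
#' @param missing_rate per-genotype missingness (default 0).
#' @return list with `panel` (a [genotype_panel()] with truth frequencies
#'   attached) and `truth` (carrier ids, index SNP, segment rank interval
#'   and genomic span; NULL founder gives NULL fields).
#' @export
gen_cohort_fixture <- function(seed, n_samples = 100L, n_chrom = 22L,
                               snps_per_chrom = 16000L,
                               shape1 = 2, shape2 = 2,
                               freq_clip = c(0.05, 0.95),
                               founder = list(),
                               mean_spacing_bp = 22727L,
                               spacing_jitter = 0.5,
                               missing_rate = 0) {
  with_seed(seed, {
    n_snps <- n_chrom * snps_per_chrom
    chroms <- paste0("chr", rep(seq_len(n_chrom), each = snps_per_chrom))
    jit <- stats::runif(n_snps, 1 - spacing_jitter, 1 + spacing_jitter)
    gaps <- pmax(1L, as.integer(round(mean_spacing_bp * jit)))
    pos <- as.integer(unlist(lapply(split(gaps, rep(seq_len(n_chrom),
                                                    each = snps_per_chrom)),
                                    cumsum), use.names = FALSE))
    freqs <- stats::rbeta(n_snps, shape1, shape2)
    freqs <- pmin(pmax(freqs, freq_clip[1]), freq_clip[2])

    geno <- matrix(stats::rbinom(n_samples * n_snps, 2L,
                                 rep(freqs, each = n_samples)),
                   nrow = n_samples)
    samples <- sprintf("S%03d", seq_len(n_samples))

    truth <- list(carriers = NULL, index_chrom = NULL, index_pos = NULL,
                  segment_ranks = NULL, segment_span_bp = NULL, mode = NULL)
    if (!is.null(founder)) {
      fd <- utils::modifyList(
        list(chrom = "chr1", n_carriers = 4L, segment_snps = 275L,
             mode = "haplotype", erosion_snps = 0L), founder)
      if (fd$n_carriers > n_samples)
        stop("more carriers than samples")
      if (fd$segment_snps > snps_per_chrom)
        stop("founder segment does not fit on one chromosome")
      chr_cols <- which(chroms == fd$chrom)
      if (!length(chr_cols)) stop("founder chromosome not in panel")
      S <- fd$segment_snps
      center <- (length(chr_cols) + 1L) %/% 2L
      lo <- center - (S - 1L) %/% 2L
      hi <- lo + S - 1L
      if (lo < 1L || hi > length(chr_cols))
        stop("founder segment does not fit around the chromosome centre")
      seg <- chr_cols[lo:hi]
      pseg <- freqs[seg]
      hap1 <- stats::rbinom(S, 1L, pseg)
      hap1[center - lo + 1L] <- 1L  # founder allele at the index SNP
      carriers <- sort(sample.int(n_samples, fd$n_carriers))
      for (ci in carriers) {
        g <- if (fd$mode == "identical") {
          if (!exists("hap2", inherits = FALSE))
            hap2 <- stats::rbinom(S, 1L, pseg)
          hap1 + hap2
        } else {
          hap1 + stats::rbinom(S, 1L, pseg)
        }
        if (fd$erosion_snps > 0L) {
          eL <- sample.int(fd$erosion_snps + 1L, 1L) - 1L
          eR <- sample.int(fd$erosion_snps + 1L, 1L) - 1L
          keep <- rep(TRUE, S)
          if (eL > 0L) keep[seq_len(eL)] <- FALSE
          if (eR > 0L) keep[S - seq_len(eR) + 1L] <- FALSE
          g[!keep] <- stats::rbinom(sum(!keep), 2L, pseg[!keep])
        }
        geno[ci, seg] <- g
      }
      truth <- list(carriers = samples[carriers], index_chrom = fd$chrom,
                    index_pos = pos[chr_cols[center]],
                    segment_ranks = c(lo, hi),
                    segment_span_bp = pos[chr_cols[hi]] - pos[chr_cols[lo]],
                    mode = fd$mode)
    }

    if (missing_rate > 0) {
      nmiss <- stats::rbinom(1L, length(geno), missing_rate)
      geno[sample.int(length(geno), nmiss)] <- NA_integer_
    }
    panel <- genotype_panel(geno,
                            snps = data.frame(chrom = chroms, pos = pos,
                                              stringsAsFactors = FALSE),
                            samples = samples, freqs = freqs)
    list(panel = panel, truth = truth)
  })
}

#' Simulate a genotype pair with a known relationship
#'
#' Draws two individuals' dosage vectors with a planted pedigree
#' relationship: `unrelated` (independent Hardy–Weinberg draws),
#' `parent_offspring` (one allele transmitted per SNP), `full_sib`
#' (two shared parents), or `identical` (same genotypes).
#'
#' @param seed RNG seed.
#' @param n_snps number of SNPs (default 5000).
#' @param relationship one of the four relationships.
#' @param freqs optional frequency vector; defaults to Beta(2,2) clipped to
#'   `[0.05, 0.95]`.
#' @return list with `g_a`, `g_b`, `freqs`, `relationship` and the
#'   Mendelian expectation `expected_pihat`.
#' @export
gen_pair_genotypes <- function(seed, n_snps = 5000L,
                               relationship = c("unrelated",
                                                "parent_offspring",
                                                "full_sib", "identical"),
                               freqs = NULL) {
  relationship <- match.arg(relationship)
  with_seed(seed, {
    if (is.null(freqs)) {
      freqs <- stats::rbeta(n_snps, 2, 2)
      freqs <- pmin(pmax(freqs, 0.05), 0.95)
    }
    n_snps <- length(freqs)
    hap <- function() stats::rbinom(n_snps, 1L, freqs)
    res <- switch(relationship,
      unrelated = list(a = hap() + hap(), b = hap() + hap()),
      identical = { g <- hap() + hap(); list(a = g, b = g) },
      parent_offspring = {
        p1 <- hap(); p2 <- hap()
        transmit <- stats::rbinom(n_snps, 1L, 0.5)
        child <- ifelse(transmit == 1L, p1, p2) + hap()
        list(a = p1 + p2, b = child)
      },
      full_sib = {
        m1 <- hap(); m2 <- hap(); f1 <- hap(); f2 <- hap()
        pick <- function(h1, h2) {
          t <- stats::rbinom(n_snps, 1L, 0.5); ifelse(t == 1L, h1, h2)
        }
        list(a = pick(m1, m2) + pick(f1, f2),
             b = pick(m1, m2) + pick(f1, f2))
      })
    list(g_a = res$a, g_b = res$b, freqs = freqs,
         relationship = relationship,
         expected_pihat = switch(relationship, unrelated = 0,
                                 parent_offspring = 0.5, full_sib = 0.5,
                                 identical = 1))
  })
}

#' Generate an annotated variant table with known filter truth
#'
#' Emits records exercising every clause of the pre-curation filter. The
#' `"one_hot"` plan contains, for each of the seven clauses (genotype
#' quality; SNP depth; InDel depth; gnomAD frequency; CADD; ClinVar;
#' consequence), one record failing exactly that clause with all others
#' passing, plus all-pass SNP and InDel records; remaining records (up to
#' `n_records`) are drawn randomly. Expected labels come from a
#' straightforward independent application of the rule inside the
#' generator, never from [passes_filters()].
#'
#' @param seed RNG seed.
#' @param n_records total records (>= 9 for the one-hot plan; 0 gives an
#'   empty table).
#' @param plan `"one_hot"` or `"random"`.
#' @return list with `records` (data.frame) and `truth` (data.frame with
#'   `id`, `expected_pass`, `designed_failing_clause`).
#' @export
gen_variant_table <- function(seed, n_records = 30L, plan = "one_hot") {
  base_snp <- function(id) data.frame(
    id = id, variant_class = "SNP", genotype_quality = 45, depth = 30,
    gnomad_af = 1e-4, cadd = 28, clinvar = "VUS", consequence = "missense",
    stringsAsFactors = FALSE)
  base_indel <- function(id) {
    d <- base_snp(id); d$variant_class <- "InDel"; d$depth <- 40
    d$consequence <- "frameshift"; d
  }
  rows <- list(); truths <- list()
  add <- function(rec, pass, clause) {
    rows[[length(rows) + 1L]] <<- rec
    truths[[length(truths) + 1L]] <<- data.frame(
      id = rec$id, expected_pass = pass, designed_failing_clause = clause,
      stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    if (plan == "one_hot" && n_records > 0L) {
      if (n_records < 9L) stop("one-hot plan needs at least 9 records")
      r <- base_snp("pass_snp");   add(r, TRUE, NA_character_)
      r <- base_indel("pass_indel"); add(r, TRUE, NA_character_)
      r <- base_snp("fail_gq"); r$genotype_quality <- 12
      add(r, FALSE, "gq")
      r <- base_snp("fail_depth_snp"); r$depth <- 4
      add(r, FALSE, "depth_snp")
      r <- base_indel("fail_depth_indel"); r$depth <- 8
      add(r, FALSE, "depth_indel")
      r <- base_snp("fail_af"); r$gnomad_af <- 0.05
      add(r, FALSE, "af")
      r <- base_snp("fail_cadd"); r$cadd <- 6
      add(r, FALSE, "cadd")
      r <- base_snp("fail_clinvar"); r$clinvar <- "Benign"
      add(r, FALSE, "clinvar")
      r <- base_snp("fail_consequence"); r$consequence <- "synonymous"
      add(r, FALSE, "consequence")
    }
    n_random <- max(0L, n_records - length(rows))
    classes <- c("SNP", "InDel")
    clinvars <- c("Benign", "Likely_benign", "VUS", "Likely_pathogenic",
                  "Pathogenic", "Conflicting", NA)
    conseqs <- c("missense", "stop_gained", "frameshift", "splice_donor",
                 "splice_region", "synonymous", "intronic")
    altering <- c("missense", "stop_gained", "frameshift", "splice_donor",
                  "splice_region")
    for (i in seq_len(n_random)) {
      vc <- sample(classes, 1L)
      rec <- data.frame(
        id = sprintf("rand_%03d", i), variant_class = vc,
        genotype_quality = round(stats::runif(1, 0, 60), 1),
        depth = sample.int(40L, 1L),
        gnomad_af = if (stats::runif(1) < 0.3) NA_real_
          else signif(stats::runif(1, 0, 0.05), 3),
        cadd = if (stats::runif(1) < 0.3) NA_real_
          else round(stats::runif(1, 0, 40), 1),
        clinvar = sample(clinvars, 1L),
        consequence = paste(sample(conseqs, sample.int(2L, 1L)),
                            collapse = "&"),
        stringsAsFactors = FALSE)
      # independent straightforward application of the rule
      pass <- rec$genotype_quality > 20 &&
        rec$depth > (if (vc == "SNP") 5 else 10) &&
        (is.na(rec$gnomad_af) || rec$gnomad_af < 0.01) &&
        (is.na(rec$cadd) || rec$cadd > 20) &&
        (is.na(rec$clinvar) ||
           !(rec$clinvar %in% c("Benign", "Likely_benign"))) &&
        any(strsplit(rec$consequence, "&")[[1]] %in% altering)
      add(rec, pass, NA_character_)
    }
  })
  records <- if (length(rows)) do.call(rbind, rows) else
    base_snp("x")[0, ]
  truth <- if (length(truths)) do.call(rbind, truths) else
    data.frame(id = character(0), expected_pass = logical(0),
               designed_failing_clause = character(0))
  list(records = records, truth = truth)
}

#' Write a cohort fixture in the formats the pipeline reads
#'
#' Writes the panel as VCF and PED/MAP and the planted truth as a JSON
#' sidecar.
#'
#' @param fixture output of [gen_cohort_fixture()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_panel_vcf(fixture$panel, file.path(dir, "panel.vcf"))
  write_panel_ped_map(fixture$panel, file.path(dir, "panel.ped"),
                      file.path(dir, "panel.map"))
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
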