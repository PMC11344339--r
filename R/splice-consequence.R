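#' Declare an aberrant-splicing outcome
#'
#' Splice events are *declared* inputs — established experimentally (e.g. by
#' RT-PCR of patient cDNA) — not predicted from sequence motifs. Supported
#' kinds:
#' \describe{
#'   \item{exon_skip}{the target exon is absent from the mature mRNA.}
#'   \item{partial_intron_retention_3prime}{the 3'-terminal `length_nt` bases
#'     of the target intron stay in the mRNA (cryptic acceptor upstream of
#'     the canonical acceptor).}
#'   \item{partial_intron_retention_5prime}{the 5'-terminal `length_nt` bases
#'     of the target intron stay in the mRNA (cryptic donor).}
#'   \item{exonic_acceptor_truncation}{the first `length_nt` bases of the
#'     target exon are lost (ectopic acceptor inside the exon).}
#' }
#'
#' @param kind event kind, see Details.
#' @param target exon ordinal (for exon events) or intron ordinal (for
#'   retention events), counted in transcription direction from 1.
#' @param length_nt event length in nucleotides; for `exon_skip` it defaults
#'   to the exon length and is consistency-checked against the model.
#' @param label optional allele label used in reports.
#' @return an object of class `splice_event`.
#' @export
splice_event <- function(kind, target, length_nt = NULL, label = NULL) {
  kind <- match.arg(kind, c("exon_skip", "partial_intron_retention_3prime",
                            "partial_intron_retention_5prime",
                            "exonic_acceptor_truncation"))
  target <- as.integer(target)
  if (target < 1L) stop("event target ordinal must be >= 1")
  if (!is.null(length_nt)) {
    length_nt <- as.integer(length_nt)
    if (length_nt < 1L) stop("length_nt must be >= 1")
  }
  structure(list(kind = kind, target = target, length_nt = length_nt,
                 label = label %||% paste0(kind, "_", target)),
            class = "splice_event")
}

# wild-type transcript-coordinate range removed by a deletion-type event
event_removed_range <- function(model, event) {
  before <- c(0L, model$cum_len)
  switch(event$kind,
    exon_skip = c(before[event$target] + 1L, model$cum_len[event$target]),
    exonic_acceptor_truncation =
      c(before[event$target] + 1L, before[event$target] + event$length_nt),
    NULL)
}

#' Apply a splice event to a transcript model
#'
#' Produces the altered mature mRNA and its bookkeeping: the length change
#' `delta_nt` (altered minus wild-type), the transcript coordinate of the
#' 5'-most changed base, and the altered exon structure (used downstream for
#' the NMD last-junction rule). Retained intron fragments are merged into
#' the adjacent exon (a cryptic acceptor extends the downstream exon; a
#' cryptic donor extends the upstream exon), so the junction count is
#' unchanged.
#'
#' @param model a [transcript_model()] carrying sequence.
#' @param event a [splice_event()].
#' @return an object of class `altered_transcript` with fields `mrna`,
#'   `delta_nt`, `event`, `junction_tx_pos`, `altered_exon_len`,
#'   `cds_start_tx`.
#' @export
apply_splice_event <- function(model, event) {
  stopifnot(inherits(model, "transcript_model"), inherits(event, "splice_event"))
  wt <- build_spliced_mrna(model)
  nexon <- n_exons(model)
  before <- c(0L, model$cum_len)
  lens <- model$exon_len

  if (event$kind == "exon_skip") {
    k <- event$target
    if (k > nexon) stop("model has no exon ", k)
    L <- lens[k]
    if (!is.null(event$length_nt) && event$length_nt != L)
      stop("declared exon_skip length ", event$length_nt,
           " does not match exon ", k, " length ", L)
    rng <- event_removed_range(model, event)
    mrna <- paste0(substring(wt, 1L, rng[1] - 1L),
                   substring(wt, rng[2] + 1L, nchar(wt)))
    alt_lens <- lens[-k]
    delta <- -L
    junction <- rng[1]
  } else if (event$kind == "exonic_acceptor_truncation") {
    k <- event$target
    if (k > nexon) stop("model has no exon ", k)
    L <- event$length_nt
    if (is.null(L)) stop("exonic_acceptor_truncation requires length_nt")
    if (L >= lens[k])
      stop("truncation of ", L, " nt meets or exceeds exon ", k,
           " length ", lens[k])
    rng <- event_removed_range(model, event)
    mrna <- paste0(substring(wt, 1L, rng[1] - 1L),
                   substring(wt, rng[2] + 1L, nchar(wt)))
    alt_lens <- lens; alt_lens[k] <- alt_lens[k] - L
    delta <- -L
    junction <- rng[1]
  } else {
    k <- event$target  # intron ordinal
    if (k >= nexon) stop("model has no intron ", k)
    L <- event$length_nt
    if (is.null(L)) stop("intron retention requires length_nt")
    ilen <- intron_len(model, k)
    if (L > ilen)
      stop("retention of ", L, " nt exceeds intron ", k, " length ", ilen)
    iseq <- intron_sequence(model, k)
    ins <- if (event$kind == "partial_intron_retention_3prime")
      substring(iseq, nchar(iseq) - L + 1L, nchar(iseq))
    else
      substring(iseq, 1L, L)
    at <- model$cum_len[k]  # insert between exon k and exon k+1
    mrna <- paste0(substring(wt, 1L, at), ins,
                   substring(wt, at + 1L, nchar(wt)))
    alt_lens <- lens
    if (event$kind == "partial_intron_retention_3prime")
      alt_lens[k + 1L] <- alt_lens[k + 1L] + L
    else
      alt_lens[k] <- alt_lens[k] + L
    delta <- L
    junction <- at + 1L
  }

  cds_start <- model$cds_start_tx
  if (junction <= cds_start) {
    # alteration upstream of (or at) the start codon shifts its position
    if (delta < 0L && junction - delta > cds_start)
      cds_start <- NA_integer_  # start codon region removed
    else
      cds_start <- cds_start + delta
  }
  structure(
    list(mrna = mrna, delta_nt = as.integer(delta), event = event,
         junction_tx_pos = as.integer(junction),
         altered_exon_len = as.integer(alt_lens),
         cds_start_tx = cds_start, model_id = model$id),
    class = "altered_transcript")
}

#' Apply an exonic coding variant to the spliced mRNA
#'
#' Edits the spliced transcript with a small coding change (substitution,
#' deletion, duplication, insertion, delins) parsed from HGVS c. notation.
#' Intronic positions (non-zero offsets) act through splicing and must be
#' expressed as a [splice_event()] instead.
#'
#' @param model a [transcript_model()] carrying sequence.
#' @param v a [variant_descriptor()] or HGVS c. string.
#' @return an `altered_transcript`.
#' @export
apply_variant <- function(model, v) {
  if (is.character(v)) v <- parse_hgvs_c(v)
  stopifnot(inherits(v, "variant_descriptor"))
  if (v$start$offset != 0L || v$end$offset != 0L)
    stop("intronic variant ", format_hgvs_c(v),
         ": model its splicing outcome as a splice_event")
  wt <- build_spliced_mrna(model)
  s <- c_to_tx(model, v$start$base)
  e <- c_to_tx(model, v$end$base)
  ref <- substring(wt, s, e)
  if (nzchar(v$ref_allele) && !identical(ref, v$ref_allele))
    stop("reference mismatch at ", format_hgvs_c(v), ": model has ", ref)
  pre <- substring(wt, 1L, s - 1L)
  post <- substring(wt, e + 1L, nchar(wt))
  mrna <- switch(v$kind,
    substitution = paste0(pre, v$alt_allele, post),
    deletion     = paste0(pre, post),
    duplication  = paste0(pre, ref, ref, post),
    insertion    = paste0(substring(wt, 1L, s), v$alt_allele, post),
    delins       = paste0(pre, v$alt_allele, post))
  delta <- nchar(mrna) - nchar(wt)
  structure(
    list(mrna = mrna, delta_nt = as.integer(delta), event = v,
         junction_tx_pos = if (v$kind == "insertion") s + 1L else s,
         altered_exon_len = {
           al <- model$exon_len
           i <- tx_exon_index(model, s)
           al[i] <- al[i] + delta
           as.integer(al)
         },
         cds_start_tx = model$cds_start_tx, model_id = model$id),
    class = "altered_transcript")
}

#' Reading-frame consequence of an mRNA length change
#'
#' @param delta_nt signed length change of the mature mRNA.
#' @return list with `frame_class` (`"in_frame"` or `"frameshift"`) and
#'   `aa_delta` (`delta_nt / 3` when in frame, `NA` otherwise).
#' @examples
#' frame_consequence(+18)   # in frame, +6 residues
#' frame_consequence(-322)  # frameshift
#' @export
frame_consequence <- function(delta_nt) {
  delta_nt <- as.integer(delta_nt)
  if (delta_nt %% 3L == 0L)
    list(frame_class = "in_frame", aa_delta = delta_nt %/% 3L)
  else
    list(frame_class = "frameshift", aa_delta = NA_integer_)
}

#' Translate an altered transcript and derive the protein-level consequence
#'
#' Translates the altered mRNA with the standard genetic code from the
#' original start codon to the first stop (UAA/UAG/UGA) and compares it with
#' the wild-type protein. Frameshifts report `novel_aa_count` — residues
#' after the last wild-type-matching residue and before the premature stop —
#' and an HGVS p. string `p.Xaa#Yaafs*N` where `N = novel_aa_count + 1` (the
#' stop itself is counted, per HGVS). A substitution that directly creates a
#' stop is reported as nonsense, `p.Xaa#*`. In-frame events report
#' `aa_delta = delta_nt/3` and a descriptive (non-normalized) p. string.
#'
#' @param altered an `altered_transcript` from [apply_splice_event()] or
#'   [apply_variant()].
#' @param model the originating [transcript_model()].
#' @param nmd_threshold nucleotide distance for the NMD last-junction rule
#'   (see [predict_nmd()]), default 55.
#' @return an object of class `protein_consequence`: `frame_class`, `kind`,
#'   `novel_aa_count`, `aa_delta`, `hgvs_p`, `nmd_predicted`, `ptc_tx_pos`,
#'   `protein_len`.
#' @export
translate_consequence <- function(altered, model, nmd_threshold = 55L) {
  stopifnot(inherits(altered, "altered_transcript"),
            inherits(model, "transcript_model"))
  wt <- build_spliced_mrna(model)
  wt_aa <- translate_nt(substring(wt, model$cds_start_tx, model$cds_end_tx))
  wt_stop <- match("*", wt_aa)
  wt_prot <- if (is.na(wt_stop)) wt_aa else wt_aa[seq_len(wt_stop - 1L)]

  cds_start <- altered$cds_start_tx
  no_orf <- is.na(cds_start) ||
    !identical(substring(altered$mrna, cds_start, cds_start + 2L), "ATG")
  if (no_orf) {
    return(structure(list(
      frame_class = frame_consequence(altered$delta_nt)$frame_class,
      kind = "no_orf", novel_aa_count = NA_integer_, aa_delta = NA_integer_,
      hgvs_p = "p.?", nmd_predicted = NA, ptc_tx_pos = NA_integer_,
      protein_len = NA_integer_, delta_nt = altered$delta_nt),
      class = "protein_consequence"))
  }

  alt_aa <- translate_nt(substring(altered$mrna, cds_start,
                                   nchar(altered$mrna)))
  alt_stop <- match("*", alt_aa)
  no_stop <- is.na(alt_stop)
  alt_prot <- if (no_stop) alt_aa else alt_aa[seq_len(alt_stop - 1L)]

  fc <- frame_consequence(altered$delta_nt)
  nw <- length(wt_prot); na_ <- length(alt_prot)
  lim <- min(nw, na_)
  diff_at <- which(wt_prot[seq_len(lim)] != alt_prot[seq_len(lim)])
  first_diff <- if (length(diff_at)) diff_at[1L]
    else if (nw == na_ && altered$delta_nt == 0L) NA_integer_
    else lim + 1L

  ptc_tx <- if (no_stop) NA_integer_ else cds_start + 3L * na_
  nmd <- if (no_stop) NA else
    predict_nmd(ptc_tx, altered$altered_exon_len, nmd_threshold)

  if (is.na(first_diff)) {
    return(structure(list(frame_class = "in_frame", kind = "no_change",
      novel_aa_count = 0L, aa_delta = 0L, hgvs_p = "p.(=)",
      nmd_predicted = FALSE, ptc_tx_pos = ptc_tx, protein_len = na_,
      delta_nt = altered$delta_nt), class = "protein_consequence"))
  }

  wt_res <- if (first_diff <= nw) wt_prot[first_diff] else "*"
  if (fc$frame_class == "frameshift") {
    if (na_ < first_diff) {
      # the first changed codon is itself the stop
      kind <- "frameshift_with_PTC"; novel <- 0L
      hgvs_p <- paste0("p.", aa_three(wt_res), first_diff, "*")
    } else {
      kind <- "frameshift_with_PTC"
      novel <- na_ - first_diff + 1L
      hgvs_p <- if (no_stop)
        paste0("p.", aa_three(wt_res), first_diff,
               aa_three(alt_prot[first_diff]), "fs*?")
      else
        paste0("p.", aa_three(wt_res), first_diff,
               aa_three(alt_prot[first_diff]), "fs*", novel + 1L)
      if (no_stop) novel <- NA_integer_
    }
    return(structure(list(frame_class = "frameshift", kind = kind,
      novel_aa_count = novel, aa_delta = NA_integer_, hgvs_p = hgvs_p,
      nmd_predicted = nmd, ptc_tx_pos = ptc_tx, protein_len = na_,
      delta_nt = altered$delta_nt), class = "protein_consequence"))
  }

  # in frame
  if (altered$delta_nt == 0L && na_ < nw &&
      identical(alt_prot, wt_prot[seq_len(na_)])) {
    # direct stop gain
    return(structure(list(frame_class = "in_frame", kind = "nonsense",
      novel_aa_count = 0L, aa_delta = NA_integer_,
      hgvs_p = paste0("p.", aa_three(wt_prot[na_ + 1L]), na_ + 1L, "*"),
      nmd_predicted = nmd, ptc_tx_pos = ptc_tx, protein_len = na_,
      delta_nt = 0L), class = "protein_consequence"))
  }
  if (altered$delta_nt == 0L) {
    # same-length substitution: missense
    return(structure(list(frame_class = "in_frame", kind = "missense",
      novel_aa_count = 0L, aa_delta = 0L,
      hgvs_p = paste0("p.", aa_three(wt_res), first_diff,
                      aa_three(alt_prot[first_diff])),
      nmd_predicted = FALSE, ptc_tx_pos = ptc_tx, protein_len = na_,
      delta_nt = 0L), class = "protein_consequence"))
  }
  aa_delta <- fc$aa_delta
  if (aa_delta > 0L) {
    kind <- "inframe_insertion"
    hgvs_p <- paste0("p.", aa_three(wt_prot[max(first_diff - 1L, 1L)]),
                     max(first_diff - 1L, 1L), "_",
                     if (first_diff <= nw) aa_three(wt_prot[first_diff]) else "*",
                     first_diff, "ins", aa_delta)
  } else {
    kind <- "inframe_deletion"
    last_del <- min(first_diff - aa_delta - 1L, nw)
    hgvs_p <- paste0("p.", aa_three(wt_res), first_diff, "_",
                     aa_three(wt_prot[last_del]), last_del, "del")
  }
  structure(list(frame_class = "in_frame", kind = kind,
    novel_aa_count = 0L, aa_delta = aa_delta, hgvs_p = hgvs_p,
    nmd_predicted = nmd, ptc_tx_pos = ptc_tx, protein_len = na_,
    delta_nt = altered$delta_nt), class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat("<protein_consequence> ", x$hgvs_p, " [", x$kind, ", ", x$frame_class,
      "]", if (isTRUE(x$nmd_predicted)) ", NMD-predicted" else "", "\n",
      sep = "")
  invisible(x)
}

#' Predict nonsense-mediated decay by the last-junction rule
#'
#' A premature termination codon triggers NMD when it lies more than
#' `threshold` nucleotides (default 55, canonical 50–55 nt rule) upstream of
#' the last exon–exon junction of the mRNA it sits in. Transcripts with a
#' single exon — or a PTC in the final exon or within `threshold` nt of the
#' last junction — escape.
#'
#' @param ptc_tx_pos transcript coordinate of the first base of the stop
#'   codon (in the same transcript whose `exon_lengths` are given).
#' @param exon_lengths exon lengths of that transcript, 5' to 3'.
#' @param threshold rule distance in nucleotides, default 55.
#' @return logical.
#' @export
predict_nmd <- function(ptc_tx_pos, exon_lengths, threshold = 55L) {
  n <- length(exon_lengths)
  if (n < 2L) return(FALSE)
  last_junction <- sum(exon_lengths[seq_len(n - 1L)])
  (last_junction - ptc_tx_pos) > threshold
}

#' Primer pair on the wild-type transcript
#'
#' @param forward_tx_start transcript coordinate of the forward primer's
#'   5' end.
#' @param reverse_tx_end transcript coordinate of the reverse primer's 3'
#'   (transcript-distal) end; must exceed `forward_tx_start`.
#' @param label amplicon label.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward_tx_start, reverse_tx_end, label = "amplicon") {
  forward_tx_start <- as.integer(forward_tx_start)
  reverse_tx_end <- as.integer(reverse_tx_end)
  if (forward_tx_start >= reverse_tx_end)
    stop("forward_tx_start must be < reverse_tx_end")
  structure(list(forward_tx_start = forward_tx_start,
                 reverse_tx_end = reverse_tx_end, label = label),
            class = "primer_pair")
}

#' Predict RT-PCR amplicon sizes across alleles
#'
#' The wild-type band is `reverse_tx_end - forward_tx_start + 1` nt; each
#' splice event shifts its allele's band by `delta_nt`. A primer that falls
#' inside a region removed by an event cannot amplify that allele and yields
#' an explicit `primer_lost` row instead of a size.
#'
#' @param model a [transcript_model()] carrying sequence.
#' @param primers a [primer_pair()].
#' @param events list of [splice_event()] objects (possibly empty).
#' @return data.frame with columns `allele`, `size_nt`, `status`, sorted by
#'   decreasing size (lost alleles last).
#' @export
predict_amplicon_sizes <- function(model, primers, events = list()) {
  stopifnot(inherits(primers, "primer_pair"))
  if (inherits(events, "splice_event")) events <- list(events)
  if (primers$reverse_tx_end > model$spliced_len)
    stop("reverse primer beyond transcript end")
  wt_size <- primers$reverse_tx_end - primers$forward_tx_start + 1L
  out <- data.frame(allele = "WT", size_nt = wt_size, status = "ok",
                    stringsAsFactors = FALSE)
  for (ev in events) {
    alt <- apply_splice_event(model, ev)
    rng <- event_removed_range(model, ev)
    lost <- !is.null(rng) &&
      ((primers$forward_tx_start >= rng[1] && primers$forward_tx_start <= rng[2]) ||
       (primers$reverse_tx_end >= rng[1] && primers$reverse_tx_end <= rng[2]))
    out <- rbind(out, data.frame(
      allele = ev$label,
      size_nt = if (lost) NA_integer_ else wt_size + alt$delta_nt,
      status = if (lost) "primer_lost" else "ok",
      stringsAsFactors = FALSE))
  }
  out[order(is.na(out$size_nt), -ifelse(is.na(out$size_nt), 0L, out$size_nt)), ,
      drop = FALSE]
}

#' Compare an exact predicted size with an approximate gel estimate
#'
#' Agarose-gel size readings are approximate; bands within `tol` (default
#' 10%) of the predicted size are considered a match.
#'
#' @param predicted_nt exact predicted size.
#' @param observed_nt approximate size read off a gel.
#' @param tol relative tolerance.
#' @return logical.
#' @export
gel_match <- function(predicted_nt, observed_nt, tol = 0.10) {
  abs(observed_nt - predicted_nt) <= tol * predicted_nt
}

#' List AG dinucleotides near an acceptor site (exploration helper)
#'
#' Candidate cryptic acceptors are AG dinucleotides in the 3' part of an
#' intron. This helper only enumerates them for inspection; no splice-site
#' strength model is applied and no discovery is performed by the
#' consequence engine.
#'
#' @param model a [transcript_model()] carrying sequence.
#' @param intron intron ordinal.
#' @param window how many 3'-terminal intron bases to search (default 100).
#' @return integer vector: distances (nt) of each AG's G from the intron's
#'   3' end (0 = the canonical acceptor AG itself).
#' @export
find_acceptor_ag_sites <- function(model, intron, window = 100L) {
  iseq <- intron_sequence(model, intron)
  n <- nchar(iseq)
  tail_seq <- substring(iseq, max(1L, n - window + 1L), n)
  hits <- gregexpr("(?=AG)", tail_seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  nchar(tail_seq) - (as.integer(hits) + 1L)
}

#' Tabulate consequences for a set of splice events
#'
#' One row per event: mRNA length change, frame class, protein-level call,
#' HGVS p. string, NMD prediction, and (when primers are given) the
#' predicted amplicon size next to the wild-type band.
#'
#' @param model a [transcript_model()] carrying sequence.
#' @param events list of [splice_event()] objects.
#' @param primers optional [primer_pair()].
#' @param nmd_threshold passed to [translate_consequence()].
#' @return data.frame, one row per event.
#' @export
consequence_report <- function(model, events, primers = NULL,
                               nmd_threshold = 55L) {
  if (inherits(events, "splice_event")) events <- list(events)
  amp <- if (!is.null(primers))
    predict_amplicon_sizes(model, primers, events)
  rows <- lapply(events, function(ev) {
    alt <- apply_splice_event(model, ev)
    pc <- translate_consequence(alt, model, nmd_threshold)
    data.frame(
      transcript_id = model$id, event = ev$label, kind = ev$kind,
      target = ev$target, delta_nt = alt$delta_nt,
      frame_class = pc$frame_class, consequence = pc$kind,
      aa_delta = pc$aa_delta, novel_aa_count = pc$novel_aa_count,
      hgvs_p = pc$hgvs_p, nmd_predicted = pc$nmd_predicted,
      amplicon_nt = if (is.null(primers)) NA_integer_
        else amp$size_nt[match(ev$label, amp$allele)],
      wt_amplicon_nt = if (is.null(primers)) NA_integer_
        else amp$size_nt[match("WT", amp$allele)],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a consequence report as TSV or JSON
#'
#' @param report data.frame from [consequence_report()].
#' @param path output path; format chosen by extension (`.json` vs TSV).
#' @export
write_consequence_report <- function(report, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  else
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
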