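#' Transcript model
#'
#' The coordinate backbone for all splice arithmetic: an ordered set of exons
#' on a chromosome, a strand, and CDS bounds in spliced-transcript
#' coordinates. Exons are 1-based closed genomic intervals listed in
#' transcription direction, i.e. genomically decreasing for minus-strand
#' genes (axonemal dynein genes such as DNAH5 are minus-strand, and their c.
#' positions increase as the chromosome coordinate decreases).
#'
#' A genomic sequence slice may be attached so spliced mRNA, intron sequence
#' and translation are available; `seq_offset` is the genomic coordinate of
#' the first base of `seq_genomic`.
#'
#' @param id transcript identifier, e.g. `"NM_001369.3"`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based, closed
#'   genomic intervals), rows ordered in transcription direction.
#' @param cds_start_tx,cds_end_tx CDS bounds, 1-based positions in the
#'   spliced transcript. The CDS length must be a multiple of 3.
#' @param seq_genomic optional genomic nucleotide string covering all exons
#'   (plus any introns needed), in genome orientation.
#' @param seq_offset genomic coordinate of the first base of `seq_genomic`
#'   (default 1).
#' @return an object of class `transcript_model`.
#' @examples
#' tm <- transcript_model("TX1", "chr1", "+",
#'   exons = data.frame(start = c(1001, 2001), end = c(1100, 2100)),
#'   cds_start_tx = 1, cds_end_tx = 198)
#' @export
transcript_model <- function(id, chrom, strand, exons,
                             cds_start_tx, cds_end_tx,
                             seq_genomic = NULL, seq_offset = 1L) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L)
  start <- as.integer(exons$start); end <- as.integer(exons$end)
  if (any(end < start)) stop("every exon must have length >= 1")
  n <- length(start)
  if (n > 1L) {
    if (strand == "+") {
      if (any(start[-1] <= end[-n]))
        stop("exons must be non-overlapping and increasing on the + strand")
    } else {
      if (any(end[-1] >= start[-n]))
        stop("exons must be non-overlapping and decreasing on the - strand")
    }
  }
  lens <- end - start + 1L
  splen <- sum(lens)
  cds_start_tx <- as.integer(cds_start_tx)
  cds_end_tx <- as.integer(cds_end_tx)
  if (!(cds_start_tx >= 1L && cds_start_tx < cds_end_tx && cds_end_tx <= splen))
    stop("CDS bounds must satisfy 1 <= cds_start_tx < cds_end_tx <= spliced length")
  if ((cds_end_tx - cds_start_tx + 1L) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  if (!is.null(seq_genomic)) {
    seq_genomic <- toupper(as.character(seq_genomic))
    lo <- min(start); hi <- max(end)
    if (seq_offset > lo || seq_offset + nchar(seq_genomic) - 1L < hi)
      stop("seq_genomic does not cover the exon span")
  }
  structure(
    list(id = id, chrom = chrom, strand = strand,
         exon_start = start, exon_end = end, exon_len = lens,
         cum_len = cumsum(lens), spliced_len = splen,
         cds_start_tx = cds_start_tx, cds_end_tx = cds_end_tx,
         seq_genomic = seq_genomic, seq_offset = as.integer(seq_offset)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$id, " ", x$chrom, "(", x$strand, "), ",
      length(x$exon_len), " exons, spliced length ", x$spliced_len,
      " nt, CDS ", x$cds_start_tx, "..", x$cds_end_tx,
      if (!is.null(x$seq_genomic)) ", sequence attached" else "", "\n",
      sep = "")
  invisible(x)
}

n_exons <- function(model) length(model$exon_len)

# intron length between exon i and exon i+1 (transcription order)
intron_len <- function(model, i) {
  if (i < 1L || i >= n_exons(model)) stop("no intron ", i, " in model")
  if (model$strand == "+")
    model$exon_start[i + 1L] - model$exon_end[i] - 1L
  else
    model$exon_start[i] - model$exon_end[i + 1L] - 1L
}

# exon index containing a spliced-transcript position
tx_exon_index <- function(model, tx) {
  findInterval(tx - 1L, c(0L, model$cum_len), rightmost.closed = FALSE)
}

# spliced-transcript position -> genomic coordinate
tx_to_genomic <- function(model, tx) {
  if (tx < 1L || tx > model$spliced_len)
    stop("transcript position ", tx, " outside spliced transcript")
  i <- tx_exon_index(model, tx)
  k <- tx - c(0L, model$cum_len)[i] - 1L  # 0-based offset within exon i
  if (model$strand == "+") model$exon_start[i] + k else model$exon_end[i] - k
}

# genomic coordinate -> spliced-transcript position (exonic only, else NA)
genomic_to_tx <- function(model, g) {
  hit <- which(g >= model$exon_start & g <= model$exon_end)
  if (!length(hit)) return(NA_integer_)
  i <- hit[1L]
  before <- c(0L, model$cum_len)[i]
  if (model$strand == "+") before + (g - model$exon_start[i] + 1L)
  else before + (model$exon_end[i] - g + 1L)
}

c_to_tx <- function(model, base) {
  tx <- base + model$cds_start_tx - 1L
  if (tx < 1L || tx > model$spliced_len)
    stop("c.", base, " lies outside the spliced transcript")
  tx
}

#' Map a coding coordinate to its genomic position
#'
#' Strand-aware mapping of an HGVS c. position (with optional intron offset)
#' to a 1-based genomic coordinate. Exonic positions map through the spliced
#' transcript; a `+n` offset requires its anchor base to be the last base of
#' an exon (donor side) and an `-n` offset requires the first base of an
#' exon (acceptor side), per HGVS convention. The inverse is
#' [genomic_to_c()], and the two are mutually inverse on all valid inputs.
#'
#' @param model a [transcript_model()].
#' @param pos a [coding_coord()], or a string like `"2052+3"`.
#' @return list with `chrom` and `pos` (integer genomic coordinate).
#' @export
c_to_genomic <- function(model, pos) {
  if (is.character(pos)) {
    v <- parse_hgvs_c(paste0("c.", sub("^c\\.", "", pos), "A>C"))
    pos <- v$start
  }
  stopifnot(inherits(pos, "coding_coord"))
  tx <- c_to_tx(model, pos$base)
  off <- pos$offset
  if (off == 0L)
    return(list(chrom = model$chrom, pos = tx_to_genomic(model, tx)))
  i <- tx_exon_index(model, tx)
  if (off > 0L) {
    if (tx != model$cum_len[i])
      stop("'+' intron offset requires the anchor to be the last base of an exon")
    if (i >= n_exons(model) || off > intron_len(model, i))
      stop("intron offset +", off, " exceeds intron ", i, " extent")
    g <- if (model$strand == "+") model$exon_end[i] + off
         else model$exon_start[i] - off
  } else {
    if (tx != c(0L, model$cum_len)[i] + 1L)
      stop("'-' intron offset requires the anchor to be the first base of an exon")
    if (i <= 1L || -off > intron_len(model, i - 1L))
      stop("intron offset ", off, " exceeds intron ", i - 1L, " extent")
    g <- if (model$strand == "+") model$exon_start[i] + off
         else model$exon_end[i] - off
  }
  list(chrom = model$chrom, pos = g)
}

#' Map a genomic position to a coding coordinate
#'
#' Inverse of [c_to_genomic()]. Intronic positions are expressed relative to
#' the nearer splice site (donor `+n` / acceptor `-n`), with ties going to
#' the donor side.
#'
#' @param model a [transcript_model()].
#' @param g integer genomic coordinate on the model's chromosome.
#' @return a [coding_coord()].
#' @export
genomic_to_c <- function(model, g) {
  g <- as.integer(g)
  tx <- genomic_to_tx(model, g)
  if (!is.na(tx)) {
    base <- tx - model$cds_start_tx + 1L
    if (base < 1L) stop("position maps upstream of the CDS start (5'UTR c. ",
                        "numbering is not supported)")
    return(coding_coord(base, 0L))
  }
  # intronic: find the flanking exon pair in transcription order
  for (i in seq_len(n_exons(model) - 1L)) {
    inside <- if (model$strand == "+")
      g > model$exon_end[i] && g < model$exon_start[i + 1L]
    else
      g < model$exon_start[i] && g > model$exon_end[i + 1L]
    if (!inside) next
    d_don <- if (model$strand == "+") g - model$exon_end[i]
             else model$exon_start[i] - g
    d_acc <- intron_len(model, i) - d_don + 1L
    if (d_don <= d_acc) {
      base <- model$cum_len[i] - model$cds_start_tx + 1L
      return(coding_coord(base, d_don))
    } else {
      base <- model$cum_len[i] + 1L - model$cds_start_tx + 1L
      return(coding_coord(base, -d_acc))
    }
  }
  stop("genomic position ", g, " lies outside transcript ", model$id)
}

#' Classify a variant's position relative to splice sites
#'
#' Labels the 5'-most changed base of a variant with respect to the nearest
#' exon/intron junction, and reports the exon or intron ordinal (exon 1 =
#' first transcribed exon). Labels follow field convention: the invariant GT
#' donor dinucleotide is `canonical_donor` (+1/+2), the donor splice region
#' is +3..+6, the invariant AG acceptor is `canonical_acceptor` (-1/-2), the
#' acceptor region (polypyrimidine tract / branch area) is -3..-12; deeper
#' intronic positions are `deep_intronic`. Exonic positions within 3 nt of a
#' junction are `exonic_near_junction`, otherwise `exonic_internal`.
#'
#' @param model a [transcript_model()].
#' @param v a [variant_descriptor()] or a [coding_coord()].
#' @return list with `region`, `ordinal` and `ordinal_type` (`"exon"` or
#'   `"intron"`).
#' @export
classify_splice_region <- function(model, v) {
  pos <- if (inherits(v, "variant_descriptor")) v$start else v
  stopifnot(inherits(pos, "coding_coord"))
  tx <- c_to_tx(model, pos$base)
  i <- tx_exon_index(model, tx)
  off <- pos$offset
  if (off != 0L) {
    # validate anchoring and intron extent via the genomic mapping
    c_to_genomic(model, pos)
    intron <- if (off > 0L) i else i - 1L
    region <- if (off %in% c(1L, 2L)) "canonical_donor"
      else if (off >= 3L && off <= 6L) "donor_region"
      else if (off %in% c(-1L, -2L)) "canonical_acceptor"
      else if (off <= -3L && off >= -12L) "acceptor_region"
      else "deep_intronic"
    return(list(region = region, ordinal = intron, ordinal_type = "intron"))
  }
  exon_start_tx <- c(0L, model$cum_len)[i] + 1L
  exon_end_tx <- model$cum_len[i]
  dist <- min(tx - exon_start_tx, exon_end_tx - tx)
  region <- if (dist < 3L) "exonic_near_junction" else "exonic_internal"
  list(region = region, ordinal = i, ordinal_type = "exon")
}

#' Assemble the spliced mRNA of a transcript model
#'
#' Concatenates the exon sequences in transcription order, reverse-
#' complementing genomic slices for minus-strand models. The result length
#' always equals the sum of exon lengths.
#'
#' @param model a [transcript_model()] carrying `seq_genomic`.
#' @return nucleotide string of the spliced transcript.
#' @export
build_spliced_mrna <- function(model) {
  if (is.null(model$seq_genomic))
    stop("model ", model$id, " has no sequence attached")
  slices <- substring(model$seq_genomic,
                      model$exon_start - model$seq_offset + 1L,
                      model$exon_end - model$seq_offset + 1L)
  if (model$strand == "-") slices <- vapply(slices, revcomp, character(1))
  paste(slices, collapse = "")
}

# intron i sequence in transcription orientation
intron_sequence <- function(model, i) {
  if (is.null(model$seq_genomic))
    stop("model ", model$id, " has no sequence attached")
  if (i < 1L || i >= n_exons(model)) stop("no intron ", i, " in model")
  if (model$strand == "+") {
    lo <- model$exon_end[i] + 1L; hi <- model$exon_start[i + 1L] - 1L
    substring(model$seq_genomic, lo - model$seq_offset + 1L,
              hi - model$seq_offset + 1L)
  } else {
    lo <- model$exon_end[i + 1L] + 1L; hi <- model$exon_start[i] - 1L
    revcomp(substring(model$seq_genomic, lo - model$seq_offset + 1L,
                      hi - model$seq_offset + 1L))
  }
}

#' Read transcript models from an exon table
#'
#' The exon table is a TSV with header columns `transcript_id`, `chrom`,
#' `strand`, `exon_number`, `start`, `end`; exon numbers count in
#' transcription direction from 1.
#'
#' @param path path to the TSV file.
#' @param cds_start_tx,cds_end_tx CDS bounds applied to every transcript in
#'   the file, or a named list keyed by transcript id.
#' @return named list of [transcript_model()] objects (without sequence).
#' @export
read_exon_table <- function(path, cds_start_tx, cds_end_tx) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exon_number", "start", "end")
  if (!all(need %in% names(tab)))
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  get_bound <- function(b, id) if (is.list(b)) b[[id]] else b
  models <- lapply(split(tab, tab$transcript_id), function(d) {
    d <- d[order(d$exon_number), ]
    transcript_model(d$transcript_id[1], d$chrom[1], d$strand[1],
                     data.frame(start = d$start, end = d$end),
                     get_bound(cds_start_tx, d$transcript_id[1]),
                     get_bound(cds_end_tx, d$transcript_id[1]))
  })
  models
}

#' Write transcript models to an exon table
#'
#' @param models list of [transcript_model()] objects.
#' @param path output TSV path.
#' @export
write_exon_table <- function(models, path) {
  if (inherits(models, "transcript_model")) models <- list(models)
  rows <- do.call(rbind, lapply(models, function(m) {
    data.frame(transcript_id = m$id, chrom = m$chrom, strand = m$strand,
               exon_number = seq_along(m$exon_start),
               start = m$exon_start, end = m$exon_end)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach genomic sequence from a FASTA file to a transcript model
#'
#' The FASTA record matching the model's chromosome (or the model id) is
#' attached as `seq_genomic`; the record is assumed to start at genomic
#' coordinate `seq_offset`.
#'
#' @param model a [transcript_model()].
#' @param fasta path to a FASTA file (wrapped or unwrapped).
#' @param seq_offset genomic coordinate of the record's first base.
#' @return the model with sequence attached.
#' @export
attach_sequence <- function(model, fasta, seq_offset = 1L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*$", "", names(seqs))
  hit <- match(model$chrom, nm)
  if (is.na(hit)) hit <- match(model$id, nm)
  if (is.na(hit))
    stop("no FASTA record named '", model$chrom, "' or '", model$id, "'")
  transcript_model(model$id, model$chrom, model$strand,
                   data.frame(start = model$exon_start, end = model$exon_end),
                   model$cds_start_tx, model$cds_end_tx,
                   seq_genomic = as.character(seqs[[hit]]),
                   seq_offset = seq_offset)
}
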