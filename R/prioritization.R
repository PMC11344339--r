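#' Configuration of the pre-curation variant filter
#'
#' The default thresholds reproduce the panel study's pre-curation rule:
#' genotype quality > 20; coverage depth > 5 for SNPs and > 10 for InDels;
#' gnomAD allele frequency < 0.01; CADD score > 20; ClinVar classification
#' not Benign/Likely benign; and at least one protein-altering or
#' splice-altering consequence. Absent gnomAD or CADD annotations pass their
#' clause by default (novel variants carry no population frequency or
#' precomputed score); set `strict_absent = TRUE` to fail them instead.
#' "Conflicting" ClinVar interpretations are retained (treated as
#' non-Benign).
#'
#' @param gq_min,dp_min_snp,dp_min_indel,af_max,cadd_min numeric thresholds
#'   (all strict inequalities).
#' @param strict_absent fail records with absent AF/CADD annotations.
#' @param benign_classes ClinVar classes that fail the ClinVar clause.
#' @param altering_consequences consequence labels accepted as protein- or
#'   splice-altering.
#' @param splice_score_min optional: a record whose `splice_score` exceeds
#'   this value passes the consequence clause regardless of labels.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(gq_min = 20, dp_min_snp = 5, dp_min_indel = 10,
                          af_max = 0.01, cadd_min = 20,
                          strict_absent = FALSE,
                          benign_classes = c("Benign", "Likely_benign"),
                          altering_consequences = c(
                            "missense", "stop_gained", "stop_lost",
                            "start_lost", "frameshift", "inframe_deletion",
                            "inframe_insertion", "protein_altering",
                            "splice_donor", "splice_acceptor", "splice_region"),
                          splice_score_min = NULL) {
  structure(list(gq_min = gq_min, dp_min_snp = dp_min_snp,
                 dp_min_indel = dp_min_indel, af_max = af_max,
                 cadd_min = cadd_min, strict_absent = strict_absent,
                 benign_classes = benign_classes,
                 altering_consequences = altering_consequences,
                 splice_score_min = splice_score_min),
            class = "filter_config")
}

#' Apply the pre-curation filter to an annotated variant table
#'
#' Evaluates each clause of the filter on every record and returns the
#' table augmented with a per-clause audit (`gq_pass`, `depth_pass`,
#' `af_pass`, `cadd_pass`, `clinvar_pass`, `consequence_pass`) and the
#' overall `pass` verdict (the conjunction). Every failing record therefore
#' reports at least one failing clause. The filter is monotone: raising GQ,
#' DP or CADD, or lowering the allele frequency, can never turn a passing
#' record into a failing one.
#'
#' @param records data.frame with columns `variant_class` (`"SNP"` /
#'   `"InDel"`), `genotype_quality`, `depth`, `gnomad_af` (NA = absent),
#'   `cadd` (NA = absent), `clinvar` (NA = absent) and `consequence`
#'   (`&`- or comma-separated labels); optional `splice_score`.
#' @param config a [filter_config()].
#' @return `records` with the audit columns and `pass` appended.
#' @export
passes_filters <- function(records, config = filter_config()) {
  stopifnot(is.data.frame(records))
  need <- c("variant_class", "genotype_quality", "depth", "gnomad_af",
            "cadd", "clinvar", "consequence")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "))
  vc <- as.character(records$variant_class)
  bad <- !(vc %in% c("SNP", "InDel"))
  if (any(bad))
    stop("unknown variant_class: ", paste(unique(vc[bad]), collapse = ", "))

  gq_pass <- records$genotype_quality > config$gq_min
  dp_min <- ifelse(vc == "SNP", config$dp_min_snp, config$dp_min_indel)
  depth_pass <- records$depth > dp_min
  af <- records$gnomad_af
  af_pass <- ifelse(is.na(af), !config$strict_absent, af < config$af_max)
  cadd_pass <- ifelse(is.na(records$cadd), !config$strict_absent,
                      records$cadd > config$cadd_min)
  clin <- as.character(records$clinvar)
  clinvar_pass <- is.na(clin) | !(clin %in% config$benign_classes)

  cons_list <- strsplit(as.character(records$consequence), "[,&;]\\s*")
  cons_pass <- vapply(cons_list, function(cs)
    any(cs %in% config$altering_consequences), logical(1))
  if (!is.null(config$splice_score_min) && "splice_score" %in% names(records)) {
    ss <- records$splice_score
    cons_pass <- cons_pass | (!is.na(ss) & ss > config$splice_score_min)
  }

  records$gq_pass <- gq_pass
  records$depth_pass <- depth_pass
  records$af_pass <- af_pass
  records$cadd_pass <- cadd_pass
  records$clinvar_pass <- clinvar_pass
  records$consequence_pass <- cons_pass
  records$pass <- gq_pass & depth_pass & af_pass & cadd_pass &
    clinvar_pass & cons_pass
  records
}

#' Per-clause verdict report for a single record
#'
#' @param record one-row data.frame (same columns as [passes_filters()]).
#' @param config a [filter_config()].
#' @return named logical vector of clause verdicts plus `pass`.
#' @export
filter_report <- function(record, config = filter_config()) {
  out <- passes_filters(record[1, , drop = FALSE], config)
  unlist(out[1, c("gq_pass", "depth_pass", "af_pass", "cadd_pass",
                  "clinvar_pass", "consequence_pass", "pass")])
}

#' Trio genotypes at candidate variants
#'
#' Genotype calls (`"ref"`, `"het"`, `"hom_alt"`, `"hemi"`, `"missing"`)
#' for proband, mother and father at each candidate variant. `hemi` is only
#' valid for male probands on sex chromosomes.
#'
#' @param proband,mother,father named character vectors keyed by variant id.
#' @param proband_sex `"male"` or `"female"`.
#' @param chrom chromosome context per variant: named character vector, or
#'   a single value recycled.
#' @return object of class `trio_genotypes`.
#' @export
trio_genotypes <- function(proband, mother, father,
                           proband_sex = c("male", "female"),
                           chrom = "autosome") {
  proband_sex <- match.arg(proband_sex)
  calls <- c("ref", "het", "hom_alt", "hemi", "missing")
  chk <- function(x, who) {
    if (!all(x %in% calls))
      stop(who, " genotypes must be one of: ", paste(calls, collapse = ", "))
    x
  }
  ids <- names(proband)
  if (is.null(ids)) stop("proband genotypes must be named by variant id")
  if (length(chrom) == 1L) chrom <- stats::setNames(rep(chrom, length(ids)), ids)
  hemi_ids <- ids[proband[ids] == "hemi"]
  if (length(hemi_ids) &&
      (proband_sex != "male" || any(!chrom[hemi_ids] %in% c("X", "chrX", "Y", "chrY"))))
    stop("hemizygous calls require a male proband on a sex chromosome")
  structure(list(proband = chk(proband, "proband"),
                 mother = chk(mother, "mother"), father = chk(father, "father"),
                 proband_sex = proband_sex, chrom = chrom),
            class = "trio_genotypes")
}

carries <- function(gt) {
  if (is.na(gt) || gt == "missing") return(NA)
  gt %in% c("het", "hom_alt", "hemi")
}

#' Phase two heterozygous variants by parental origin
#'
#' Two variants heterozygous in the proband are *in trans* (compound
#' heterozygous) when one is carried by the mother only and the other by
#' the father only; *in cis* when both trace exclusively to the same
#' parent; otherwise *ambiguous* (a missing parent, both parents carrying a
#' variant, or an apparent de novo allele). Symmetric in the two variants.
#'
#' @param trio a [trio_genotypes()].
#' @param v1,v2 variant ids present in the trio.
#' @return `"in_trans"`, `"in_cis"` or `"ambiguous"`.
#' @export
phase_by_parents <- function(trio, v1, v2) {
  stopifnot(inherits(trio, "trio_genotypes"))
  for (v in c(v1, v2)) {
    if (!v %in% names(trio$proband)) stop("unknown variant id: ", v)
    if (trio$proband[[v]] != "het")
      stop("phase_by_parents requires the proband heterozygous at both ",
           "variants; ", v, " is ", trio$proband[[v]])
  }
  m1 <- carries(trio$mother[[v1]]); m2 <- carries(trio$mother[[v2]])
  f1 <- carries(trio$father[[v1]]); f2 <- carries(trio$father[[v2]])
  if (anyNA(c(m1, m2, f1, f2))) return("ambiguous")
  if ((m1 && !f1 && f2 && !m2) || (f1 && !m1 && m2 && !f2)) return("in_trans")
  if ((m1 && m2 && !f1 && !f2) || (f1 && f2 && !m1 && !m2)) return("in_cis")
  "ambiguous"
}

#' Check the inheritance model supported by trio genotypes
#'
#' Classifies candidate genotypes against recessive and X-linked models:
#' `AR_hom` — proband homozygous for the alternate allele with each typed
#' parent heterozygous; `XL_hemizygous` — male proband hemizygous on X with
#' a heterozygous (carrier) mother; `AR_comp_het` — two heterozygous
#' variants phased *in trans* by [phase_by_parents()]; `inconsistent` —
#' genotypes violating Mendelian transmission (e.g. a homozygous proband
#' with a homozygous-reference parent); otherwise `unresolved`.
#'
#' @param trio a [trio_genotypes()].
#' @param v1 variant id.
#' @param v2 optional second variant id (compound-heterozygous check).
#' @return character label.
#' @export
inheritance_model_check <- function(trio, v1, v2 = NULL) {
  stopifnot(inherits(trio, "trio_genotypes"))
  p <- trio$proband[[v1]]
  m <- trio$mother[[v1]]; f <- trio$father[[v1]]
  if (!is.null(v2)) {
    if (trio$proband[[v1]] == "het" && trio$proband[[v2]] == "het") {
      ph <- phase_by_parents(trio, v1, v2)
      if (ph == "in_trans") return("AR_comp_het")
      if (ph == "in_cis") return("unresolved")
      return("unresolved")
    }
  }
  if (p == "hom_alt") {
    typed <- c(mother = m, father = f)
    typed <- typed[typed != "missing"]
    if (any(typed == "ref")) return("inconsistent")
    if (all(typed %in% c("het", "hom_alt"))) return("AR_hom")
    return("unresolved")
  }
  if (p == "hemi") {
    if (trio$chrom[[v1]] %in% c("X", "chrX") &&
        m %in% c("het", "hom_alt"))
      return("XL_hemizygous")
    if (m == "ref") return("inconsistent")
    return("unresolved")
  }
  "unresolved"
}
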