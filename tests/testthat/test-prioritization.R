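rec <- function(...) {
  base <- data.frame(variant_class = "SNP", genotype_quality = 30,
                     depth = 20, gnomad_af = 0.001, cadd = 25,
                     clinvar = "VUS", consequence = "missense",
                     stringsAsFactors = FALSE)
  mod <- list(...)
  for (nm in names(mod)) base[[nm]] <- mod[[nm]]
  base
}

test_that("each filter clause acts as the pre-curation rule states", {
  expect_true(passes_filters(rec(depth = 6))$pass)              # SNP, DP>5
  expect_false(passes_filters(rec(variant_class = "InDel", depth = 8,
                                  consequence = "frameshift"))$pass)
  expect_true(passes_filters(rec(variant_class = "InDel", depth = 11,
                                 consequence = "frameshift"))$pass)
  expect_false(passes_filters(rec(genotype_quality = 15))$pass)
  expect_false(passes_filters(rec(genotype_quality = 20))$pass)  # strict >
  expect_false(passes_filters(rec(gnomad_af = 0.05))$pass)
  expect_false(passes_filters(rec(cadd = 12))$pass)
  expect_false(passes_filters(rec(clinvar = "Benign"))$pass)
  expect_false(passes_filters(rec(clinvar = "Likely_benign"))$pass)
  expect_true(passes_filters(rec(clinvar = "Conflicting"))$pass)
  expect_false(passes_filters(rec(consequence = "synonymous"))$pass)
  expect_true(passes_filters(rec(consequence = "synonymous&splice_region"))$pass)
  expect_error(passes_filters(rec(variant_class = "SV")), "variant_class")
})

test_that("absent annotations pass by default and fail in strict mode", {
  novel <- rec(gnomad_af = NA_real_, cadd = NA_real_,
               clinvar = NA_character_, consequence = "splice_donor")
  expect_true(passes_filters(novel)$pass)
  strict <- filter_config(strict_absent = TRUE)
  out <- passes_filters(novel, strict)
  expect_false(out$pass)
  expect_false(out$af_pass)
  expect_false(out$cadd_pass)
  expect_true(out$clinvar_pass)  # absent ClinVar is never disqualifying
})

test_that("failures always name at least one failing clause", {
  fx <- gen_variant_table(301, n_records = 40L)
  out <- passes_filters(fx$records)
  clauses <- c("gq_pass", "depth_pass", "af_pass", "cadd_pass",
               "clinvar_pass", "consequence_pass")
  for (i in seq_len(nrow(out))) {
    if (!out$pass[i]) expect_true(any(!unlist(out[i, clauses])))
    else expect_true(all(unlist(out[i, clauses])))
  }
})

test_that("the filter reproduces constructed truth labels exactly", {
  fx <- gen_variant_table(302, n_records = 60L)
  out <- passes_filters(fx$records)
  expect_identical(out$pass, fx$truth$expected_pass)
  # each one-hot record fails exactly its designed clause
  oh <- which(!is.na(fx$truth$designed_failing_clause))
  clause_col <- c(gq = "gq_pass", depth_snp = "depth_pass",
                  depth_indel = "depth_pass", af = "af_pass",
                  cadd = "cadd_pass", clinvar = "clinvar_pass",
                  consequence = "consequence_pass")
  for (i in oh) {
    col <- clause_col[[fx$truth$designed_failing_clause[i]]]
    expect_false(out[[col]][i])
    others <- setdiff(unname(clause_col), col)
    expect_true(all(unlist(out[i, others])))
  }
})

test_that("the filter is monotone in every quality metric", {
  set.seed(303)
  fx <- gen_variant_table(304, n_records = 30L)
  recs <- fx$records
  base <- passes_filters(recs)$pass
  for (rep in 1:40) {
    pert <- recs
    i <- sample(nrow(pert), 1)
    # improve one metric at random
    what <- sample(c("gq", "dp", "cadd", "af"), 1)
    if (what == "gq") pert$genotype_quality[i] <- pert$genotype_quality[i] + runif(1, 0, 50)
    if (what == "dp") pert$depth[i] <- pert$depth[i] + sample(1:30, 1)
    if (what == "cadd" && !is.na(pert$cadd[i]))
      pert$cadd[i] <- pert$cadd[i] + runif(1, 0, 20)
    if (what == "af" && !is.na(pert$gnomad_af[i]))
      pert$gnomad_af[i] <- pert$gnomad_af[i] * runif(1)
    newpass <- passes_filters(pert)$pass
    # pass -> fail flips are impossible; only fail -> pass allowed
    expect_true(all(newpass >= base))
  }
})

test_that("splice scores can rescue the consequence clause", {
  r <- rec(consequence = "intronic")
  r$splice_score <- 0.9
  expect_false(passes_filters(r)$pass)
  cfg <- filter_config(splice_score_min = 0.5)
  expect_true(passes_filters(r, cfg)$pass)
})

mk_trio <- function(p, m, f, sex = "male", chrom = "autosome") {
  trio_genotypes(proband = p, mother = m, father = f, proband_sex = sex,
                 chrom = chrom)
}

test_that("parental genotypes phase compound heterozygotes", {
  # one variant from each parent: in trans
  t1 <- mk_trio(c(v1 = "het", v2 = "het"),
                c(v1 = "ref", v2 = "het"),
                c(v1 = "het", v2 = "ref"))
  expect_identical(phase_by_parents(t1, "v1", "v2"), "in_trans")
  expect_identical(phase_by_parents(t1, "v2", "v1"), "in_trans")  # symmetric
  # both from the mother: in cis
  t2 <- mk_trio(c(v1 = "het", v2 = "het"),
                c(v1 = "het", v2 = "het"),
                c(v1 = "ref", v2 = "ref"))
  expect_identical(phase_by_parents(t2, "v1", "v2"), "in_cis")
  # missing father: cannot resolve
  t3 <- mk_trio(c(v1 = "het", v2 = "het"),
                c(v1 = "het", v2 = "ref"),
                c(v1 = "missing", v2 = "missing"))
  expect_identical(phase_by_parents(t3, "v1", "v2"), "ambiguous")
  # both parents carry v1: cannot resolve
  t4 <- mk_trio(c(v1 = "het", v2 = "het"),
                c(v1 = "het", v2 = "het"),
                c(v1 = "het", v2 = "ref"))
  expect_identical(phase_by_parents(t4, "v1", "v2"), "ambiguous")
  # proband must be het at both
  t5 <- mk_trio(c(v1 = "hom_alt", v2 = "het"),
                c(v1 = "het", v2 = "ref"),
                c(v1 = "het", v2 = "het"))
  expect_error(phase_by_parents(t5, "v1", "v2"), "heterozygous")
})

test_that("inheritance models are classified from trio genotypes", {
  # homozygous recessive with carrier parents
  hom <- mk_trio(c(v = "hom_alt"), c(v = "het"), c(v = "het"))
  expect_identical(inheritance_model_check(hom, "v"), "AR_hom")
  # Mendelian violation: hom proband with a ref/ref parent
  bad <- mk_trio(c(v = "hom_alt"), c(v = "het"), c(v = "ref"))
  expect_identical(inheritance_model_check(bad, "v"), "inconsistent")
  # X-linked hemizygous male with carrier mother
  xl <- mk_trio(c(v = "hemi"), c(v = "het"), c(v = "ref"),
                sex = "male", chrom = "X")
  expect_identical(inheritance_model_check(xl, "v"), "XL_hemizygous")
  # compound het via in-trans phase
  ch <- mk_trio(c(v1 = "het", v2 = "het"),
                c(v1 = "het", v2 = "ref"),
                c(v1 = "ref", v2 = "het"))
  expect_identical(inheritance_model_check(ch, "v1", "v2"), "AR_comp_het")
  # hemizygous calls are rejected for female probands
  expect_error(mk_trio(c(v = "hemi"), c(v = "het"), c(v = "ref"),
                       sex = "female", chrom = "X"), "male")
})
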