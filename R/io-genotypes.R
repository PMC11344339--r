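#' Read a biallelic SNP panel from a VCF file
#'
#' Uses the `vcfR` package to extract the GT field and convert it to
#' alternate-allele dosages (0/1/2, `NA` for missing). Multi-allelic
#' records are dropped with a message.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @return a [genotype_panel()] (frequencies not yet estimated).
#' @export
read_vcf_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_panel requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biall <- !grepl(",", fix[, "ALT"])
  if (!all(biall)) {
    message("dropping ", sum(!biall), " multi-allelic record(s)")
    v <- v[biall, ]
    fix <- fix[biall, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, 2, function(col) {
    a <- sub("[/|].*$", "", col)
    b <- sub("^.*[/|]", "", col)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out
  })
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
  genotype_panel(t(dos),
                 snps = data.frame(chrom = fix[, "CHROM"],
                                   pos = as.integer(fix[, "POS"]),
                                   id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                               paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                               fix[, "ID"]),
                                   stringsAsFactors = FALSE),
                 samples = colnames(gt))
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a valid VCFv4.2 with GT-only genotype columns; alleles are written
#' as A (reference) and C (alternate) placeholders unless the SNP table
#' carries `ref`/`alt` columns.
#'
#' @param panel a [genotype_panel()].
#' @param path output path (plain text).
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=foundersplice",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", panel$samples), collapse = "\t"), con)
  ref <- panel$snps$ref %||% rep("A", nrow(panel$snps))
  alt <- panel$snps$alt %||% rep("C", nrow(panel$snps))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[panel$genotypes + 1L],
                   nrow = nrow(panel$genotypes))
  gt_str[is.na(gt_str)] <- "./."
  for (j in seq_len(nrow(panel$snps))) {
    writeLines(paste(c(panel$snps$chrom[j], panel$snps$pos[j],
                       panel$snps$id[j], ref[j], alt[j], ".", "PASS", ".",
                       "GT", gt_str[, j]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype panel from PED/MAP text files
#'
#' Standard whitespace-delimited pedigree format: the MAP file lists
#' `chrom`, `id`, `cm`, `pos` per SNP; the PED file has six pedigree columns
#' followed by two allele calls per SNP (`0` = missing). Dosage is counted
#' for the minor allele at each SNP.
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_panel()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"))
  ped <- utils::read.table(ped_path, stringsAsFactors = FALSE)
  n_snp <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snp)
    stop("PED has ", ncol(ped) - 6L, " allele columns for ", n_snp,
         " MAP SNPs")
  samples <- as.character(ped[[2L]])
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * n_snp, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_snp, by = 2L), drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(ped), ncol = n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    alleles <- names(sort(table(obs)))  # minor allele first
    if (!length(alleles)) next
    minor <- alleles[1L]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    geno[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
    geno[miss, j] <- NA_integer_
  }
  genotype_panel(geno, snps = map[, c("chrom", "pos", "id")],
                 samples = samples)
}

#' Write a genotype panel as PED/MAP text files
#'
#' @param panel a [genotype_panel()].
#' @param ped_path,map_path output paths.
#' @export
write_panel_ped_map <- function(panel, ped_path, map_path) {
  map <- data.frame(chrom = panel$snps$chrom, id = panel$snps$id,
                    cm = 0, pos = panel$snps$pos)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- panel$genotypes
  # dosage counts allele "C" (alternate); reference allele "A"
  a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, "C", "A"))
  a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, "C", "A"))
  inter <- matrix("", nrow = nrow(g), ncol = 2L * ncol(g))
  inter[, seq(1L, 2L * ncol(g), 2L)] <- a1
  inter[, seq(2L, 2L * ncol(g), 2L)] <- a2
  ped <- cbind("FAM1", panel$samples, "0", "0", "0", "-9", inter)
  utils::write.table(ped, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}
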