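# VCF ingestion: biallelic sites only, genotypes as ALT-allele counts.

read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_raw <- vcfR::getFIX(v)
  if (is.null(dim(fix_raw))) {
    fix_raw <- matrix(fix_raw, nrow = 1, dimnames = list(NULL, names(fix_raw)))
  }
  fix <- as.data.frame(fix_raw, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    stop_mrf(paste0("Multi-allelic site(s) not supported: ",
                    fmt_names(paste0(fix$CHROM[multi], ":", fix$POS[multi]))),
             "mrf_validation_error")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # rows = sites, cols = samples; count ALT alleles from strings like 0/1, 1|1
  count_alt <- function(s) {
    ifelse(is.na(s) | grepl("\\.", s),
           NA_integer_,
           vapply(strsplit(s, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  counts <- apply(gt, 2, count_alt)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, colnames(gt)))
  snp_ids <- rownames(gt)
  if (is.null(snp_ids) || anyNA(snp_ids) || any(snp_ids == ".")) {
    snp_ids <- paste0(fix$CHROM, "_", fix$POS)
  }
  out <- as_tibble(t(counts), .name_repair = "minimal")
  names(out) <- snp_ids
  dplyr::bind_cols(tibble(sample = colnames(gt)), out)
}
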