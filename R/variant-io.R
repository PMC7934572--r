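#' Read a VCF into a genotype panel
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and converts the GT fields into
#' an alternate-allele dosage matrix.  Multiallelic records (comma in
#' ALT) are dropped and counted; half-calls (e.g. `./1`) and missing
#' genotypes become `NA`.  Phasing separators `|` and `/` are treated
#' identically.  Variants are classified as `SNP` when both alleles are
#' single bases and `INDEL` otherwise.
#'
#' @param path path to a VCF (optionally gzipped).
#' @return A [genotype_panel()]; the number of dropped multiallelic
#'   records is available as `attr(panel, "removed_multiallelic")`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2) stop("VCF has no sample columns")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == "."
  n_multi <- sum(multi)
  if (all(multi)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]

  gtv <- gsub("|", "/", as.vector(gt), fixed = TRUE)
  dos <- rep(NA_real_, length(gtv))
  dos[gtv %in% c("0/0", "0")] <- 0
  dos[gtv %in% c("0/1", "1/0")] <- 1
  dos[gtv %in% c("1/1", "1")] <- 2
  geno <- t(matrix(dos, nrow = nrow(gt), ncol = ncol(gt),
                   dimnames = dimnames(gt)))

  type <- ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "SNP", "INDEL")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, type = type, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = colnames(gt), group = NA_character_,
                        stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, variants, samples)
  attr(panel, "removed_multiallelic") <- n_multi
  panel
}

#' Write a genotype panel as VCF 4.2
#'
#' Emits a minimal genotype-only VCF (GT format field; missing calls as
#' `./.`).  Fractional (imputed) dosages cannot be represented and raise
#' an error; write before imputing.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  g <- panel$geno
  if (any(!is.na(g) & g != round(g)))
    stop("panel contains fractional dosages; VCF output requires hard calls")
  code <- function(x) {
    out <- rep("./.", length(x))
    out[!is.na(x) & x == 0] <- "0/0"
    out[!is.na(x) & x == 1] <- "0/1"
    out[!is.na(x) & x == 2] <- "1/1"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$samples$sample_id),
                     collapse = "\t")), con)
  v <- panel$variants
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", "GT", code(g[, j])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Filter variants on minor allele frequency and missingness
#'
#' Applies the association-side site filters: a variant is retained iff
#' its minor allele frequency (computed from non-missing dosages) is
#' `>= maf_min` and its missing-call fraction is `<= missing_max`.  The
#' printed thresholds are thus the edge of the retained region (a variant
#' at MAF exactly 0.025 survives).  Removal reasons are counted with
#' fixed precedence missingness before MAF, so the report partitions the
#' input exactly.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor-allele frequency in `[0, 0.5]`.
#' @param missing_max maximum missing fraction in `[0, 1]`.
#' @return A list with `panel` (filtered) and `report`, a `filter_report`
#'   with fields `input_count`, `removed_multiallelic`, `removed_missing`,
#'   `removed_maf`, `retained_count`.
#' @export
filter_variants <- function(panel, maf_min = 0.025, missing_max = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  g <- panel$geno
  n <- nrow(g)
  n_miss <- colSums(is.na(g))
  miss_frac <- n_miss / n
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[n_miss == n] <- 0          # all-missing: undefined MAF, fails either way

  fail_miss <- miss_frac > missing_max
  fail_maf <- !fail_miss & !(maf >= maf_min)   # NaN-safe: all-missing handled above
  keep <- !fail_miss & !fail_maf
  if (!any(keep))
    warning("all variants removed by the filters; returning an empty panel")
  report <- structure(
    list(input_count = ncol(g),
         removed_multiallelic = attr(panel, "removed_multiallelic") %||% 0L,
         removed_missing = sum(fail_miss),
         removed_maf = sum(fail_maf),
         retained_count = sum(keep)),
    class = "filter_report")
  list(panel = subset_panel(panel, variants = which(keep)), report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.filter_report <- function(x, ...) {
  cat("variant filter report\n")
  cat("  input:               ", x$input_count, "\n")
  cat("  removed multiallelic:", x$removed_multiallelic, "(at VCF read)\n")
  cat("  removed missingness: ", x$removed_missing, "\n")
  cat("  removed MAF:         ", x$removed_maf, "\n")
  cat("  retained:            ", x$retained_count, "\n")
  invisible(x)
}

#' Impute missing dosages
#'
#' Simple single-site imputation used to complete the dosage matrix
#' before kinship and association analysis (diversity statistics always
#' use the unimputed panel).  Mode `"mean"` replaces a missing call by
#' the per-variant mean dosage of the non-missing samples (fractional
#' values); mode `"major"` uses the most frequent observed hard call
#' (ties to the lower dosage).
#'
#' @param panel a [genotype_panel()].
#' @param mode `"mean"` or `"major"`.
#' @return The panel with no missing entries.
#' @export
impute_missing <- function(panel, mode = c("mean", "major")) {
  mode <- match.arg(mode)
  g <- panel$geno
  nm <- colSums(is.na(g))
  if (any(nm == nrow(g)))
    stop("variant(s) with all calls missing: ",
         paste(panel$variants$id[nm == nrow(g)], collapse = ", "))
  for (j in which(nm > 0)) {
    obs <- g[, j][!is.na(g[, j])]
    fill <- if (mode == "mean") mean(obs) else
      as.numeric(names(which.max(table(factor(obs, levels = 0:2)))))
    g[is.na(g[, j]), j] <- fill
  }
  panel$geno <- g
  panel
}

#' Read sample-to-subgroup and phenotype tables
#'
#' Tab-separated, with a header line.  The group table has columns
#' `sample_id` and `group`; the phenotype table `sample_id` and `value`.
#'
#' @param path TSV file path.
#' @return `read_group_table`: data.frame `sample_id`, `group`.
#'   `read_phenotype_table`: named numeric vector of phenotypes.
#' @export
read_group_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("group table must have columns sample_id and group")
  df[, c("sample_id", "group")]
}

#' @rdname read_group_table
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "value") %in% names(df)))
    stop("phenotype table must have columns sample_id and value")
  stats::setNames(as.numeric(df$value), df$sample_id)
}
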