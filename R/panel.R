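#' Construct a genotype panel
#'
#' A `genotype_panel` is the package's central container: a samples x
#' variants matrix of alternate-allele dosages (0, 1, 2 or `NA` for a
#' missing call) together with the variant table (chromosome, 1-based
#' position, ref/alt alleles, SNP/indel class) and the sample table with
#' optional subgroup labels.  All downstream statistics (diversity,
#' differentiation, LD, kinship, association) consume this object.
#'
#' Only biallelic variants are representable; multiallelic records must be
#' dropped (and counted) upstream, as [read_vcf()] does.
#'
#' @param geno numeric matrix, samples in rows, variants in columns;
#'   entries in `{0, 1, 2, NA}` (fractional dosages are allowed after
#'   imputation).
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`, `type` (`"SNP"` or `"INDEL"`); one row per column of `geno`.
#'   Positions must be non-decreasing within each chromosome.
#' @param samples data.frame with columns `sample_id` and `group`
#'   (subgroup label, may be `NA`); one row per row of `geno`.
#' @param chrom_lengths optional named numeric vector of chromosome
#'   lengths in bp; used to tile windows.  Defaults to the maximum
#'   observed position per chromosome.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, variants, samples, chrom_lengths = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "double"
  if (nrow(geno) != nrow(samples))
    stop("geno has ", nrow(geno), " rows but samples has ", nrow(samples))
  if (ncol(geno) != nrow(variants))
    stop("geno has ", ncol(geno), " columns but variants has ", nrow(variants))
  need <- c("id", "chrom", "pos", "ref", "alt", "type")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples must have columns sample_id and group")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample ids")
  ok <- geno >= 0 & geno <= 2
  if (any(!ok[!is.na(geno)]))
    stop("dosages must lie in [0, 2]")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("positions not sorted within chromosome ", ch)
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(variants$pos, variants$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  rownames(geno) <- samples$sample_id
  colnames(geno) <- variants$id
  structure(
    list(geno = geno,
         variants = as.data.frame(variants, stringsAsFactors = FALSE),
         samples = as.data.frame(samples, stringsAsFactors = FALSE),
         chrom_lengths = chrom_lengths),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  nm <- sum(is.na(x$geno))
  cat("genotype_panel: ", nrow(x$geno), " samples x ", ncol(x$geno),
      " variants\n", sep = "")
  cat("  chromosomes: ", paste(names(x$chrom_lengths), collapse = ", "), "\n",
      sep = "")
  cat("  missing calls: ", nm, " (",
      sprintf("%.2f%%", 100 * nm / length(x$geno)), ")\n", sep = "")
  grp <- x$samples$group
  if (!all(is.na(grp))) {
    tb <- table(grp, useNA = "no")
    cat("  groups: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Number of samples / variants in a panel
#' @param panel a [genotype_panel()]
#' @return integer count.
#' @export
n_samples <- function(panel) nrow(panel$geno)

#' @rdname n_samples
#' @export
n_variants <- function(panel) ncol(panel$geno)

#' Assign subgroup labels to panel samples
#'
#' @param panel a [genotype_panel()]
#' @param groups named character vector (names = sample ids) or a
#'   data.frame with columns `sample_id` and `group`, e.g. from
#'   [read_group_table()].
#' @return The panel with `samples$group` replaced.
#' @export
set_groups <- function(panel, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$sample_id)
  idx <- match(panel$samples$sample_id, names(groups))
  if (anyNA(idx))
    stop("no group label for sample(s): ",
         paste(panel$samples$sample_id[is.na(idx)], collapse = ", "))
  panel$samples$group <- unname(groups[idx])
  panel
}

#' Subset a genotype panel
#'
#' @param panel a [genotype_panel()]
#' @param samples,variants logical/integer/character index into samples or
#'   variants; `NULL` keeps everything.
#' @return A new `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(panel)) else samples
  if (is.character(si)) si <- match(si, panel$samples$sample_id)
  vi <- if (is.null(variants)) seq_len(n_variants(panel)) else variants
  if (is.character(vi)) vi <- match(vi, panel$variants$id)
  genotype_panel(panel$geno[si, vi, drop = FALSE],
                 panel$variants[vi, , drop = FALSE],
                 panel$samples[si, , drop = FALSE],
                 panel$chrom_lengths)
}

# group label -> list of row indices; errors on unassigned/empty groups
group_indices <- function(panel, groups = NULL) {
  g <- if (is.null(groups)) panel$samples$group else groups
  if (length(g) != n_samples(panel))
    stop("group vector length does not match sample count")
  if (anyNA(g)) stop("every sample must be assigned to exactly one group")
  idx <- split(seq_along(g), g)
  if (any(lengths(idx) == 0)) stop("group with zero samples")
  idx
}

# half-open 0-based windows [start, end) tiling a chromosome of length L
tile_windows <- function(L, W) {
  starts <- seq(0, max(0, L - 1), by = W)
  data.frame(start = starts, end = pmin(starts + W, L))
}
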