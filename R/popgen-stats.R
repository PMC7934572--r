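#' Per-group allele frequencies
#'
#' Alternate-allele frequency of every variant in every subgroup,
#' computed over non-missing alleles, together with the number of
#' genotyped alleles.  A variant with no genotyped sample in a group has
#' an undefined (`NA`) frequency there and is excluded downstream.
#'
#' @param panel a [genotype_panel()].
#' @param groups optional group label vector overriding
#'   `panel$samples$group`.
#' @return A list with matrices `freq` and `n_alleles` (variants x
#'   groups) plus the variant table.
#' @export
allele_frequencies <- function(panel, groups = NULL) {
  idx <- group_indices(panel, groups)
  g <- panel$geno
  m <- ncol(g)
  freq <- vapply(idx, function(i)
    colMeans(g[i, , drop = FALSE], na.rm = TRUE) / 2, numeric(m))
  nal <- vapply(idx, function(i)
    2 * colSums(!is.na(g[i, , drop = FALSE])), numeric(m))
  freq <- matrix(freq, m, length(idx), dimnames = list(colnames(g), names(idx)))
  nal <- matrix(nal, m, length(idx), dimnames = list(colnames(g), names(idx)))
  freq[nal == 0] <- NA_real_
  list(freq = freq, n_alleles = nal, variants = panel$variants)
}

#' Classify variants by subgroup sharing
#'
#' A variant is "observed" in a group iff its alternate-allele count
#' there is greater than zero (no frequency floor).  The exact set of
#' observing groups defines mutually exclusive, exhaustive categories:
#' `private-<G>` (one group), `shared-<G1>|<G2>` (a pair, sorted names),
#' `shared-all`, or `absent` (alt allele seen nowhere).
#'
#' @param af output of [allele_frequencies()].
#' @return A list of class `sharing_table`: per-variant `category`,
#'   `category_counts`, and `private_counts` per group.
#' @export
classify_sharing <- function(af) {
  if (ncol(af$freq) < 2) stop("sharing classification needs >= 2 groups")
  grp <- colnames(af$freq)
  cnt <- af$freq * af$n_alleles            # alt-allele counts; NA where n=0
  obs <- !is.na(cnt) & cnt > 0
  k <- rowSums(obs)
  category <- character(nrow(obs))
  category[k == 0] <- "absent"
  category[k == length(grp)] <- "shared-all"
  part <- which(k > 0 & k < length(grp))
  if (length(part)) {
    category[part] <- vapply(part, function(i) {
      who <- sort(grp[obs[i, ]])
      if (length(who) == 1) paste0("private-", who)
      else paste0("shared-", paste(who, collapse = "|"))
    }, character(1))
  }
  private_counts <- stats::setNames(
    vapply(grp, function(gn) sum(category == paste0("private-", gn)), numeric(1)),
    grp)
  structure(list(category = category,
                 category_counts = table(category),
                 private_counts = private_counts,
                 variants = af$variants),
            class = "sharing_table")
}

#' Private variants per accession
#'
#' Counts, for every accession, the variants whose alternate allele is
#' carried by that accession alone (dosage > 0 in exactly one sample).
#'
#' @param panel a [genotype_panel()].
#' @return Named integer vector of per-accession private-variant counts.
#' @export
private_variants_per_accession <- function(panel) {
  carrier <- !is.na(panel$geno) & panel$geno > 0
  n_carriers <- colSums(carrier)
  counts <- stats::setNames(integer(n_samples(panel)), panel$samples$sample_id)
  single <- which(n_carriers == 1)
  if (length(single)) {
    who <- apply(carrier[, single, drop = FALSE], 2, which.max)
    tb <- table(who)
    counts[as.integer(names(tb))] <- as.integer(tb)
  }
  counts
}

# per-site unbiased heterozygosity term n/(n-1) * 2 p (1-p); n = allele count
site_pi_terms <- function(g_rows) {
  nal <- 2 * colSums(!is.na(g_rows))
  p <- colMeans(g_rows, na.rm = TRUE) / 2
  term <- ifelse(nal >= 2, nal / (nal - 1) * 2 * p * (1 - p), NA_real_)
  list(term = term, nal = nal)
}

#' Windowed nucleotide diversity
#'
#' Per non-overlapping window of width `W` bp and per subgroup,
#' `pi = sum_sites [n/(n-1)] 2 p (1-p) / W`, where p and the allele
#' count n are group-local at each segregating site; monomorphic or
#' unobserved sites contribute 0.  The denominator is the full nominal
#' window width (resequencing convention), also for a short terminal
#' window (flagged by `partial`).  A window with variants but no site
#' genotyped in >= 2 alleles for a group gets `NA` there; a window with
#' no variants has `pi = 0`.
#'
#' @param panel a [genotype_panel()].
#' @param groups optional group label override.
#' @param W window width in bp (500 kb default).
#' @param include_indels include indel sites (default FALSE: SNPs only).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `n_variants`, `partial`, and one `pi_<group>` column per group.
#' @export
nucleotide_diversity_windows <- function(panel, groups = NULL, W = 500000,
                                         include_indels = FALSE) {
  idx <- group_indices(panel, groups)
  use <- if (include_indels) rep(TRUE, n_variants(panel)) else
    panel$variants$type == "SNP"
  terms <- lapply(idx, function(i) site_pi_terms(panel$geno[i, , drop = FALSE]))
  out <- list()
  for (ch in names(panel$chrom_lengths)) {
    win <- tile_windows(panel$chrom_lengths[[ch]], W)
    on_ch <- panel$variants$chrom == ch
    wi <- findInterval(panel$variants$pos - 1, win$start)  # 1-based window idx
    res <- data.frame(chrom = ch, start = win$start, end = win$end,
                      n_variants = tabulate(wi[on_ch], nbins = nrow(win)),
                      partial = (win$end - win$start) < W,
                      stringsAsFactors = FALSE)
    for (gn in names(idx)) {
      tt <- terms[[gn]]
      pi_col <- numeric(nrow(win))
      for (w in seq_len(nrow(win))) {
        sel <- on_ch & wi == w & use
        if (!any(sel)) { pi_col[w] <- 0; next }
        v <- tt$term[sel]
        pi_col[w] <- if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE) / W
      }
      res[[paste0("pi_", gn)]] <- pi_col
    }
    out[[ch]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Weir & Cockerham (1984) per-site variance components for r populations.
# n, p, h: sites x r matrices of genotyped individuals, alt frequency and
# observed heterozygote frequency.  Returns per-site a and a+b+c; sites
# unusable (any n_i < 1, nbar <= 1, or monomorphic across the set) are NA.
wc_site_components <- function(n, p, h) {
  r <- ncol(n)
  nbar <- rowMeans(n)
  nsum <- rowSums(n)
  nc <- (nsum - rowSums(n^2) / nsum) / (r - 1)
  pbar <- rowSums(n * p) / nsum
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / nsum
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- apply(n, 1, min) < 1 | nbar <= 1 | pbar <= 0 | pbar >= 1
  a[bad] <- NA_real_
  tot <- a + b + cc
  tot[bad] <- NA_real_
  list(a = a, tot = tot)
}

# sites x groups summaries needed by the WC estimator
wc_group_summaries <- function(panel, idx) {
  g <- panel$geno
  m <- ncol(g)
  as_mat <- function(x) matrix(x, m, length(idx),
                               dimnames = list(NULL, names(idx)))
  n <- as_mat(vapply(idx, function(i)
    colSums(!is.na(g[i, , drop = FALSE])), numeric(m)))
  p <- as_mat(vapply(idx, function(i)
    colMeans(g[i, , drop = FALSE], na.rm = TRUE) / 2, numeric(m)))
  h <- as_mat(vapply(idx, function(i) {
    gi <- g[i, , drop = FALSE]
    colSums(gi == 1, na.rm = TRUE) / pmax(colSums(!is.na(gi)), 1)
  }, numeric(m)))
  p[n == 0] <- 0
  list(n = n, p = p, h = h)
}

#' Windowed Weir-Cockerham F_ST
#'
#' The Weir & Cockerham (1984) theta estimator, aggregated per window as
#' a ratio of sums of the per-site variance components
#' `theta = sum(a) / sum(a + b + c)`.  The `total` column uses all
#' groups jointly; one pairwise column per group pair restricts the
#' estimator to that pair.  Sites monomorphic across the compared groups
#' (or with a group entirely missing) are skipped; a window with no
#' usable site gets `NA`.  Negative windowed theta is reported as-is,
#' not clamped.
#'
#' @inheritParams nucleotide_diversity_windows
#' @return data.frame with `chrom`, `start`, `end`, `n_variants`,
#'   `fst_total` and `fst_<G1>|<G2>` columns.
#' @export
fst_windows <- function(panel, groups = NULL, W = 500000,
                        include_indels = FALSE) {
  idx <- group_indices(panel, groups)
  if (length(idx) < 2) stop("F_ST needs >= 2 groups")
  if (any(lengths(idx) < 2)) stop("every group needs >= 2 samples")
  use <- if (include_indels) rep(TRUE, n_variants(panel)) else
    panel$variants$type == "SNP"
  sm <- wc_group_summaries(panel, idx)
  grp <- names(idx)
  sets <- c(list(total = grp),
            stats::setNames(combn(grp, 2, simplify = FALSE),
                            combn(grp, 2, function(x) paste(x, collapse = "|"))))
  comp <- lapply(sets, function(gs) {
    cols <- match(gs, grp)
    wc_site_components(sm$n[, cols, drop = FALSE], sm$p[, cols, drop = FALSE],
                       sm$h[, cols, drop = FALSE])
  })
  out <- list()
  for (ch in names(panel$chrom_lengths)) {
    win <- tile_windows(panel$chrom_lengths[[ch]], W)
    on_ch <- panel$variants$chrom == ch
    wi <- findInterval(panel$variants$pos - 1, win$start)
    res <- data.frame(chrom = ch, start = win$start, end = win$end,
                      n_variants = tabulate(wi[on_ch], nbins = nrow(win)),
                      stringsAsFactors = FALSE)
    for (nm in names(comp)) {
      cl <- numeric(nrow(win))
      for (w in seq_len(nrow(win))) {
        sel <- on_ch & wi == w & use
        a <- comp[[nm]]$a[sel]; tot <- comp[[nm]]$tot[sel]
        ok <- !is.na(a)
        cl[w] <- if (!any(ok) || sum(tot[ok]) == 0) NA_real_ else
          sum(a[ok]) / sum(tot[ok])
      }
      res[[if (nm == "total") "fst_total" else paste0("fst_", nm)]] <- cl
    }
    out[[ch]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Windowed mean linkage-disequilibrium r^2
#'
#' Mean squared Pearson correlation of unimputed dosage vectors
#' (pairwise-complete samples) over all intra-window variant pairs,
#' computed per subgroup.  When a window holds more than `max_pairs`
#' pairs, a seeded random subsample of pairs is used.  Pairs with a
#' zero-variance member (within the group) are skipped; a window with
#' fewer than two usable variants for a group gets `NA`.
#'
#' @inheritParams nucleotide_diversity_windows
#' @param max_pairs maximum variant pairs evaluated per window per group.
#' @param seed integer seed for pair subsampling.
#' @return data.frame with `chrom`, `start`, `end`, `n_variants` and
#'   `r2_<group>` columns.
#' @export
ld_r2_windows <- function(panel, groups = NULL, W = 500000,
                          max_pairs = 10000, seed = 1L,
                          include_indels = FALSE) {
  idx <- group_indices(panel, groups)
  use <- if (include_indels) rep(TRUE, n_variants(panel)) else
    panel$variants$type == "SNP"
  set.seed(as.integer(seed))
  out <- list()
  for (ch in names(panel$chrom_lengths)) {
    win <- tile_windows(panel$chrom_lengths[[ch]], W)
    on_ch <- panel$variants$chrom == ch
    wi <- findInterval(panel$variants$pos - 1, win$start)
    res <- data.frame(chrom = ch, start = win$start, end = win$end,
                      n_variants = tabulate(wi[on_ch], nbins = nrow(win)),
                      stringsAsFactors = FALSE)
    for (gn in names(idx)) {
      g <- panel$geno[idx[[gn]], , drop = FALSE]
      r2col <- rep(NA_real_, nrow(win))
      for (w in seq_len(nrow(win))) {
        vs <- which(on_ch & wi == w & use)
        if (length(vs) < 2) next
        npair <- choose(length(vs), 2)
        pairs <- if (npair <= max_pairs) {
          utils::combn(vs, 2)
        } else {
          # uniform random pairs (with replacement across draws)
          a <- sample(vs, max_pairs, replace = TRUE)
          b <- sample(vs, max_pairs, replace = TRUE)
          eq <- a == b
          while (any(eq)) {
            b[eq] <- sample(vs, sum(eq), replace = TRUE)
            eq <- a == b
          }
          rbind(pmin(a, b), pmax(a, b))
        }
        r2 <- mapply(function(i, j) {
          v <- suppressWarnings(stats::cor(g[, i], g[, j],
                                           use = "pairwise.complete.obs"))
          v^2
        }, pairs[1, ], pairs[2, ])
        r2col[w] <- if (all(is.na(r2))) NA_real_ else mean(r2, na.rm = TRUE)
      }
      res[[paste0("r2_", gn)]] <- r2col
    }
    out[[ch]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
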