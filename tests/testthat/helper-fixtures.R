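# Small deterministic fixtures shared across the suite.

# tiny panel from an explicit dosage matrix
make_panel <- function(geno, groups = NULL, chrom = "Chr01",
                       pos = NULL, type = "SNP", chrom_len = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100
  if (is.null(groups)) groups <- rep("A", n)
  variants <- data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                         pos = pos, ref = "A", alt = "T",
                         type = rep(type, length.out = m),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(n)), group = groups,
                        stringsAsFactors = FALSE)
  genotype_panel(geno, variants, samples,
                 if (is.null(chrom_len)) NULL else stats::setNames(chrom_len, chrom))
}

# random panel under Hardy-Weinberg, optional missingness
random_panel <- function(n, m, maf = NULL, missing_rate = 0, groups = NULL,
                         seed = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  geno <- sapply(maf, function(p) rbinom(n, 2, p))
  if (missing_rate > 0) geno[runif(n * m) < missing_rate] <- NA
  make_panel(geno, groups = groups, pos = sort(sample.int(m * 1000, m)),
             chrom_len = m * 1000)
}

# mean pairwise-difference brute-force oracle for nucleotide diversity:
# average over all sample pairs and sites of the per-site expected
# mismatch between one allele drawn from each diploid, normalized by W
pi_bruteforce <- function(geno, W) {
  n <- nrow(geno)
  tot <- 0
  # expected mismatch of two diploids d1,d2 under random allele draw:
  # p1(1-p2)+p2(1-p1) with p = dosage/2 -- but the unbiased estimator
  # sums over ordered allele pairs across individuals; equivalently
  # compute from the full allele list per site
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j]
    g <- g[!is.na(g)]
    if (length(g) < 1) next
    # allele multiset: dosage x -> x alt alleles, 2-x ref alleles
    alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    na <- length(alleles)
    if (na < 2) next
    diff <- 0
    for (a in seq_len(na - 1))
      for (b in (a + 1):na) diff <- diff + (alleles[a] != alleles[b])
    tot <- tot + diff / choose(na, 2)
  }
  unname(tot / W)
}

# brute-force Weir-Cockerham theta for two or more groups, one site at a
# time, from first principles (independent re-derivation used as oracle)
wc_theta_oracle <- function(geno, groups) {
  grp <- split(seq_len(nrow(geno)), groups)
  r <- length(grp)
  A <- 0; TOT <- 0
  for (j in seq_len(ncol(geno))) {
    n_i <- sapply(grp, function(i) sum(!is.na(geno[i, j])))
    if (any(n_i < 1)) next
    p_i <- sapply(grp, function(i) mean(geno[i, j], na.rm = TRUE) / 2)
    h_i <- sapply(grp, function(i) mean(geno[i, j] == 1, na.rm = TRUE))
    nbar <- mean(n_i)
    if (nbar <= 1) next
    nsum <- sum(n_i)
    pbar <- sum(n_i * p_i) / nsum
    if (pbar <= 0 || pbar >= 1) next
    nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / nsum
    a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    A <- A + a; TOT <- TOT + a + b + cc
  }
  A / TOT
}

# random additive (tree-metric) distance matrix from a random topology,
# by simulating a random rooted binary tree with positive branch lengths
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
  tr
}

# genomic positions covered by a gene's CDS
cds_positions <- function(models, gid) {
  cds <- models[models$gene_id == gid & models$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  unlist(lapply(seq_len(nrow(cds)), function(i) cds$start[i]:cds$end[i]))
}

# full-CDS translation-diff oracle for coding SNV effects
effect_oracle_snv <- function(models, genome, chrom, pos, ref, alt, gid) {
  rows <- models[models$gene_id == gid & models$type == "CDS", , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  strand <- rows$strand[1]
  # mutate the genome, rebuild the spliced CDS, translate both
  mut <- genome
  seqs <- as.character(mut[[chrom]])
  stopifnot(substr(seqs, pos, pos) == ref)
  substr(seqs, pos, pos) <- alt
  splice <- function(s) {
    pieces <- vapply(seq_len(nrow(rows)), function(i)
      substr(s, rows$start[i], rows$end[i]), character(1))
    if (strand == "-") {
      pieces <- rev(vapply(pieces, function(x)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))),
        character(1)))
    }
    paste(pieces, collapse = "")
  }
  cds_ref <- splice(as.character(genome[[chrom]]))
  cds_alt <- splice(seqs)
  aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(cds_ref),
                                               no.init.codon = TRUE))
  aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(cds_alt),
                                               no.init.codon = TRUE))
  if (aa_ref == aa_alt) return("synonymous")
  i <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])[1]
  r <- substr(aa_ref, i, i); a <- substr(aa_alt, i, i)
  if (a == "*") return("stop_gained")
  if (r == "*") return("stop_lost")
  if (i == 1 && substr(cds_ref, 1, 3) == "ATG") return("start_lost")
  "missense"
}
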