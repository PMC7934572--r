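#' Simulation configuration for structured genotype panels
#'
#' Bundles the parameters of the Balding-Nichols structured-population
#' generator.  Defaults emulate a three-subgroup panel shaped like a
#' soybean mini-core collection: 20 "Primitive", 58 "World" and 120
#' "Japan" accessions (198 in total), a single chromosome, and moderate
#' differentiation.
#'
#' @param n_per_group named integer vector, diploid samples per subgroup
#'   (each >= 2).
#' @param n_variants number of biallelic sites to simulate.
#' @param chrom_length chromosome length in bp; positions are drawn
#'   without replacement from `1:chrom_length`.
#' @param F differentiation parameter in (0, 1): the Balding-Nichols
#'   variance of subgroup allele frequencies around the ancestral
#'   frequency p is `F * p * (1 - p)`.  Scalar or one value per group.
#' @param maf_law function of `n` returning ancestral allele frequencies;
#'   default `runif(n, 0.05, 0.95)` guarantees polymorphism at desk scale.
#' @param rho adjacent-site copying probability in `[0, 1)`; each
#'   haplotype's latent uniform is copied from the previous site with
#'   probability `rho`, inducing LD that decays geometrically with site
#'   index distance.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param seed integer seed; all randomness is derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(Primitive = 20, World = 58, Japan = 120),
                       n_variants = 20000,
                       chrom_length = 5e7,
                       F = 0.1,
                       maf_law = function(n) stats::runif(n, 0.05, 0.95),
                       rho = 0,
                       missing_rate = 0,
                       seed = 1L) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("G", seq_along(n_per_group))
  if (any(n_per_group < 2)) stop("n_per_group must be >= 2 for every group")
  if (any(F <= 0 | F >= 1)) stop("F must lie strictly in (0, 1)")
  if (length(F) == 1) F <- rep(F, length(n_per_group))
  if (length(F) != length(n_per_group))
    stop("F must be scalar or one value per group")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  if (n_variants > chrom_length) stop("n_variants exceeds chrom_length")
  structure(list(n_per_group = n_per_group, n_variants = as.integer(n_variants),
                 chrom_length = chrom_length, F = F, maf_law = maf_law,
                 rho = rho, missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a structured-population genotype panel
#'
#' Draws, for each site, an ancestral frequency p from `config$maf_law`
#' and per-subgroup frequencies from the Balding-Nichols Beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (mean p, variance `F p (1-p)`),
#' clipped to `[0.001, 0.999]` to avoid degenerate draws.  Haplotypes are
#' sampled by a first-order copying chain on latent uniforms (probability
#' `rho` of copying the previous site's uniform), so that allele states at
#' nearby sites are correlated and r^2 decays with distance.  Diploid
#' dosages pair consecutive haplotypes; missingness is applied uniformly.
#'
#' The generator is deterministic under a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @param chrom chromosome name for the simulated sites.
#' @return A list with elements `panel` (a [genotype_panel()] with group
#'   labels set) and `truth` (class `sim_truth`: `group_labels`,
#'   `ancestral_freqs`, `subpop_freqs` (sites x groups), empty trait slots
#'   `causal_sites`/`effect_sizes`/`h2` to be filled before
#'   [simulate_phenotype()], and `cnv_segments = NULL`).
#' @export
simulate_structured_genotypes <- function(config, chrom = "Chr01") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_variants
  ngrp <- length(config$n_per_group)
  pos <- sort(sample.int(config$chrom_length, m))
  p_anc <- config$maf_law(m)
  if (any(p_anc <= 0 | p_anc >= 1)) stop("maf_law must return frequencies in (0,1)")

  subpop <- matrix(NA_real_, m, ngrp,
                   dimnames = list(NULL, names(config$n_per_group)))
  for (g in seq_len(ngrp)) {
    Fg <- config$F[g]
    a <- p_anc * (1 - Fg) / Fg
    b <- (1 - p_anc) * (1 - Fg) / Fg
    subpop[, g] <- pmin(pmax(stats::rbeta(m, a, b), 0.001), 0.999)
  }

  geno <- matrix(NA_real_, sum(config$n_per_group), m)
  row0 <- 0
  for (g in seq_len(ngrp)) {
    n_g <- config$n_per_group[g]
    H <- 2 * n_g
    U <- matrix(stats::runif(H * m), H, m)
    if (config$rho > 0 && m > 1) {
      cp <- matrix(stats::runif(H * m) < config$rho, H, m)
      for (j in 2:m) {
        k <- cp[, j]
        if (any(k)) U[k, j] <- U[k, j - 1]
      }
    }
    A <- U < rep(subpop[, g], each = H)  # H x m allele matrix
    geno[row0 + seq_len(n_g), ] <-
      A[seq(1, H, by = 2), , drop = FALSE] + A[seq(2, H, by = 2), , drop = FALSE]
    row0 <- row0 + n_g
  }

  if (config$missing_rate > 0) {
    drop <- stats::runif(length(geno)) < config$missing_rate
    geno[drop] <- NA_real_
  }

  labels <- rep(names(config$n_per_group), config$n_per_group)
  ids <- paste0(labels, "_", unlist(lapply(config$n_per_group, seq_len)))
  ref_alt <- matrix(sample(c("A", "C", "G", "T"), 2 * m, replace = TRUE), m, 2)
  same <- ref_alt[, 1] == ref_alt[, 2]
  ref_alt[same, 2] <- chartr("ACGT", "CGTA", ref_alt[same, 1])

  variants <- data.frame(id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
                         ref = ref_alt[, 1], alt = ref_alt[, 2], type = "SNP",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ids, group = labels, stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, variants, samples,
                          stats::setNames(config$chrom_length, chrom))
  truth <- structure(
    list(group_labels = stats::setNames(labels, ids),
         ancestral_freqs = p_anc,
         subpop_freqs = subpop,
         causal_sites = character(0),
         effect_sizes = numeric(0),
         h2 = NA_real_,
         cnv_segments = NULL),
    class = "sim_truth")
  list(panel = panel, truth = truth)
}

#' Attach quantitative-trait ground truth to a simulation
#'
#' @param truth a `sim_truth` from [simulate_structured_genotypes()].
#' @param causal_sites variant ids (or column indices) of causal sites.
#' @param effect_sizes additive effect per alternate allele, one per
#'   causal site (trait units).
#' @param h2 narrow-sense heritability in `[0, 1]` to realize.
#' @return The `sim_truth` with trait slots filled.
#' @export
set_trait_truth <- function(truth, causal_sites, effect_sizes, h2) {
  stopifnot(inherits(truth, "sim_truth"))
  if (length(causal_sites) != length(effect_sizes))
    stop("causal_sites and effect_sizes must have equal length")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  truth$causal_sites <- causal_sites
  truth$effect_sizes <- effect_sizes
  truth$h2 <- h2
  truth
}

#' Simulate a quantitative phenotype with known heritability
#'
#' Builds the genetic value `g = sum_j beta_j * dosage_j` over the causal
#' sites in `truth`, then adds Gaussian noise orthogonalized against `g`
#' and rescaled so the realized narrow-sense heritability
#' `var(g)/var(y)` matches `truth$h2` exactly in-sample.  With `h2 = 0`
#' the phenotype is pure noise; with `h2 = 1` it equals the genetic value
#' (noiseless limit).  Missing causal dosages are mean-imputed for trait
#' construction only.
#'
#' @param panel a [genotype_panel()].
#' @param truth a `sim_truth` whose `causal_sites`, `effect_sizes` and
#'   `h2` slots are set (see [set_trait_truth()]).
#' @param seed integer seed for the noise draw.
#' @return Named numeric vector of phenotypes (names = sample ids).
#' @export
simulate_phenotype <- function(panel, truth, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(truth, "sim_truth"))
  if (is.na(truth$h2)) stop("truth has no h2; call set_trait_truth() first")
  set.seed(as.integer(seed))
  n <- n_samples(panel)
  ids <- panel$samples$sample_id

  if (truth$h2 == 0)
    return(stats::setNames(stats::rnorm(n), ids))

  cs <- truth$causal_sites
  ci <- if (is.numeric(cs)) as.integer(cs) else match(cs, panel$variants$id)
  if (anyNA(ci) || any(ci < 1 | ci > n_variants(panel))) {
    bad <- if (is.numeric(cs)) cs[is.na(ci) | ci < 1 | ci > n_variants(panel)] else cs[is.na(ci)]
    stop("causal site(s) absent from panel: ", paste(bad, collapse = ", "))
  }
  X <- panel$geno[, ci, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  }
  g <- drop(X %*% truth$effect_sizes)
  vg <- stats::var(g)
  if (vg == 0) stop("causal sites carry no genetic variance")
  if (truth$h2 == 1)
    return(stats::setNames(g, ids))

  e <- stats::rnorm(n)
  e <- e - mean(e)
  e <- e - g * stats::cov(e, g) / vg      # orthogonal to g in-sample
  e <- e * sqrt(vg * (1 - truth$h2) / truth$h2) / stats::sd(e)
  stats::setNames(g + e, ids)
}
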