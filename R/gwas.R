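#' Genomic relationship matrix (VanRaden method 1)
#'
#' `K = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z` the column-centred
#' dosage matrix and `p_j` the alternate-allele frequency of marker j.
#' The panel must be complete (impute first); monomorphic markers
#' contribute nothing, and an all-monomorphic panel is an error (zero
#' denominator).
#'
#' @param x a complete [genotype_panel()] or numeric dosage matrix
#'   (samples x markers).
#' @return Symmetric kinship matrix with sample ids as dimnames.
#' @export
compute_grm <- function(x) {
  X <- if (inherits(x, "genotype_panel")) x$geno else as.matrix(x)
  if (anyNA(X)) stop("dosage matrix contains missing values; impute first")
  if (ncol(X) < 2) stop("need >= 2 markers")
  p <- colMeans(X) / 2
  den <- 2 * sum(p * (1 - p))
  if (den == 0) stop("all markers are monomorphic: zero GRM denominator")
  Z <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Z) / den
  dimnames(K) <- list(rownames(X), rownames(X))
  K
}

design_with_intercept <- function(n, covariates) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  X
}

#' Fit the null linear mixed model by REML
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by spectral decomposition of K and
#' one-dimensional REML maximization over `delta = sigma_e^2/sigma_g^2`:
#' a 100-point grid on `log10(delta) in [-5, 5]` followed by
#' golden-section refinement (via [stats::optimize()]) to 1e-6.  The fit
#' is deterministic.
#'
#' @param y numeric phenotype vector, no missing values.
#' @param covariates optional numeric matrix of fixed covariates
#'   (an intercept is always added).
#' @param K kinship matrix, symmetric positive semi-definite within
#'   numerical tolerance (eigenvalues >= -1e-8 relative).
#' @return A list of class `lmm_fit`: variance components `sigma_g2`,
#'   `sigma_e2`, ratio `lambda = sigma_e2/sigma_g2`, `h2`, restricted
#'   log-likelihood `loglik`, fixed-effect estimates `beta`, and the
#'   cached eigendecomposition used by [association_scan()].
#' @export
fit_null_lmm <- function(y, covariates = NULL, K) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("phenotype contains missing values")
  X <- design_with_intercept(n, covariates)
  if (nrow(X) != n || nrow(K) != n) stop("dimension mismatch among y, covariates, K")
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
  if (max(abs(K - t(K))) > 1e-8) stop("K is not symmetric")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(1, max(eg$values)))
    stop("K is not positive semi-definite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  q <- ncol(X)

  reml <- function(log10d) {
    delta <- 10^log10d
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - drop(Xt %*% beta)
    sg2 <- sum(w * r^2) / (n - q)
    -0.5 * ((n - q) * (log(2 * pi * sg2) + 1) + sum(log(d + delta)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  grid <- seq(-5, 5, length.out = 100)
  ll <- vapply(grid, reml, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(reml, interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  delta <- 10^opt$maximum

  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, Xt * w)
  beta <- drop(solve(XtWX, crossprod(Xt, yt * w)))
  names(beta) <- colnames(X)
  r <- yt - drop(Xt %*% beta)
  sg2 <- sum(w * r^2) / (n - q)
  structure(list(sigma_g2 = sg2, sigma_e2 = delta * sg2, lambda = delta,
                 h2 = 1 / (1 + delta), loglik = as.numeric(opt$objective),
                 beta = beta, eigen_values = d, eigen_vectors = U,
                 X = X),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("null LMM fit (REML)\n")
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g, lambda = %.4g\n",
              x$sigma_g2, x$sigma_e2, x$lambda))
  cat(sprintf("  h2 = %.3f, restricted logLik = %.2f\n", x$h2, x$loglik))
  invisible(x)
}

#' Mixed-model association scan (EMMAX / P3D)
#'
#' Per-marker generalized least squares with the variance components
#' fixed from the null fit: phenotype, covariates and dosages are
#' rotated by K's eigenvectors and scaled by
#' `(sigma_g2 * d_i + sigma_e2)^{-1/2}`, covariates are projected out,
#' and each marker's Wald statistic `(beta/se)^2` is referred to
#' chi-square(1) (two-sided p).  Markers with zero variance after
#' whitening get `p = 1` and are flagged.  Benjamini-Hochberg FDR
#' control at level `q` is applied to the scan (see [bh_fdr()]).
#'
#' @param panel a complete (imputed) [genotype_panel()].
#' @param y phenotype vector aligned with the panel's samples.
#' @param covariates optional fixed covariates (e.g. [panel_pcs()]).
#' @param fit an `lmm_fit` from [fit_null_lmm()] on the same data.
#' @param q FDR level for the significance call (default 0.01).
#' @return A data.frame of class `association_result`: `id`, `chrom`,
#'   `pos`, `beta`, `se`, `wald`, `p`, `flagged`, `significant`, with
#'   attributes `q` and `threshold` (largest significant p, `NA` when no
#'   marker passes).
#' @export
association_scan <- function(panel, y, covariates = NULL, fit, q = 0.01) {
  stopifnot(inherits(fit, "lmm_fit"))
  G <- panel$geno
  if (anyNA(G)) stop("panel contains missing dosages; impute first")
  y <- as.numeric(y)
  U <- fit$eigen_vectors
  s <- 1 / sqrt(fit$sigma_g2 * fit$eigen_values + fit$sigma_e2)
  X <- design_with_intercept(length(y), covariates)
  ys <- s * drop(crossprod(U, y))
  Xs <- s * crossprod(U, X)
  Gs <- s * crossprod(U, G)
  qrX <- qr(Xs)
  My <- qr.resid(qrX, ys)
  MG <- qr.resid(qrX, Gs)
  den <- colSums(MG^2)
  num <- drop(crossprod(MG, My))
  flagged <- den < 1e-12
  beta <- ifelse(flagged, NA_real_, num / den)
  se <- ifelse(flagged, NA_real_, sqrt(1 / den))
  wald <- ifelse(flagged, 0, num^2 / den)
  p <- ifelse(flagged, 1, stats::pchisq(wald, df = 1, lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)      # keep p in (0, 1]
  fdr <- bh_fdr(p, q = q)
  res <- data.frame(id = panel$variants$id, chrom = panel$variants$chrom,
                    pos = panel$variants$pos, beta = beta, se = se,
                    wald = wald, p = p, flagged = flagged,
                    significant = fdr$significant,
                    stringsAsFactors = FALSE)
  attr(res, "q") <- q
  attr(res, "threshold") <- fdr$threshold
  class(res) <- c("association_result", "data.frame")
  res
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Finds the largest i with `p_(i) <= i q / m`; all p-values at or below
#' `p_(i)` are declared significant.  With no passing p-value the
#' significant set is empty and the threshold `NA`.
#'
#' @param p vector of p-values in (0, 1].
#' @param q FDR level.
#' @return list with `significant` (logical vector), `threshold`
#'   (largest significant p or `NA`) and `n_significant`.
#' @export
bh_fdr <- function(p, q = 0.01) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * q / m)
  if (length(ok) == 0)
    return(list(significant = rep(FALSE, m), threshold = NA_real_,
                n_significant = 0L))
  thr <- ps[max(ok)]
  sig <- p <= thr
  list(significant = sig, threshold = thr, n_significant = sum(sig))
}

#' Tidy per-variant table for Manhattan-style display
#'
#' @param result an `association_result` from [association_scan()].
#' @return data.frame `chrom`, `pos`, `p`, `neglog10p`, `significant`,
#'   sorted by chromosome then position.
#' @export
manhattan_table <- function(result) {
  stopifnot(inherits(result, "association_result"))
  out <- data.frame(chrom = result$chrom, pos = result$pos, p = result$p,
                    neglog10p = -log10(result$p),
                    significant = result$significant,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
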