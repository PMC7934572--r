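#' Jukes-Cantor distances between panel samples
#'
#' For each sample pair the observed mismatch proportion p is computed
#' over variant sites non-missing in both samples, with per-site weights
#' reflecting expected allele sharing under a random allele draw:
#' opposite homozygotes count 1, heterozygote vs homozygote 0.5,
#' heterozygote vs heterozygote 0 (i.e. `|d_i - d_j| / 2` on dosages).
#' p is then corrected by the one-parameter Jukes-Cantor model,
#' `d = -(3/4) log(1 - (4/3) p)`; pairs with `p >= 0.75` are outside the
#' model's domain and get `Inf`.  An optional count of invariant sites
#' can be added to the denominator to emulate whole-genome (per-bp
#' diluted) distances.
#'
#' @param panel a [genotype_panel()].
#' @param n_invariant number of monomorphic sites added to the
#'   denominator of p (default 0: variant sites only).
#' @return A list of class `jc_dist` with symmetric matrices `d`
#'   (JC-corrected) and `p` (raw mismatch proportion).
#' @export
jc69_distances <- function(panel, n_invariant = 0) {
  if (n_samples(panel) < 2) stop("need >= 2 samples")
  M <- panel$geno / 2                      # 0, .5, 1
  n <- nrow(M)
  ids <- panel$samples$sample_id
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  if (!anyNA(M)) {
    mism <- as.matrix(stats::dist(M, method = "manhattan"))
    shared <- ncol(M)
    p <- mism / (shared + n_invariant)
  } else {
    obs <- !is.na(M)
    M0 <- M; M0[!obs] <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- obs[i, ] & obs[j, ]
        ns <- sum(ok)
        if (ns == 0)
          stop("no shared non-missing sites for pair ", ids[i], " / ", ids[j])
        p[i, j] <- p[j, i] <- sum(abs(M0[i, ok] - M0[j, ok])) /
          (ns + n_invariant)
      }
    }
  }
  d <- matrix(Inf, n, n, dimnames = dimnames(p))
  inside <- p < 0.75
  d[inside] <- -0.75 * log(1 - 4 * p[inside] / 3)
  diag(d) <- 0
  structure(list(d = d, p = p, sample_ids = ids), class = "jc_dist")
}

#' Neighbour-joining tree
#'
#' Canonical Saitou-Nei agglomeration on the Q criterion, O(n^3).  Ties
#' in Q are broken deterministically by the lexicographically lowest
#' original-index pair.  A negative branch length produced by the
#' two-point formulas is truncated to 0 and the deficit moved to the
#' sibling branch so the joined path length is preserved.  If an
#' outgroup is given the tree is rooted on its pendant edge.
#'
#' @param dist a `jc_dist` from [jc69_distances()], a symmetric numeric
#'   matrix, or a [stats::dist] object.
#' @param outgroup optional sample id to root on.
#' @return An [ape] `phylo` tree.
#' @export
neighbor_joining <- function(dist, outgroup = NULL) {
  D <- if (inherits(dist, "jc_dist")) dist$d else as.matrix(dist)
  if (any(is.na(D)) || any(is.nan(D))) stop("distance matrix contains NA/NaN")
  if (any(!is.finite(D))) stop("distance matrix contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3) stop("neighbour joining needs >= 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (!is.null(outgroup) && !outgroup %in% labels)
    stop("outgroup '", outgroup, "' not among the taxa")

  nwk <- labels                 # newick fragment per active node
  idx <- seq_len(n)             # original index for tie-breaking
  fmt <- function(x) sprintf("%.12g", x)

  while (length(nwk) > 3) {
    m <- nrow(D)
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(pmin(idx[cand[, 1]], idx[cand[, 2]]),
                 pmax(idx[cand[, 1]], idx[cand[, 2]]))
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]

    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)

    new_nwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    idx <- c(idx[keep], min(idx[c(i, j)]))
  }

  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lz <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- pmax(c(lx, ly, lz), 0)
  txt <- paste0("(", nwk[1], ":", fmt(bl[1]), ",", nwk[2], ":", fmt(bl[2]),
                ",", nwk[3], ":", fmt(bl[3]), ");")
  tree <- ape::read.tree(text = txt)
  if (!is.null(outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  tree
}

#' Principal coordinates (classical MDS) of a panel or distance matrix
#'
#' For a genotype panel, missing dosages are mean-imputed, columns are
#' centred, and Euclidean distances between samples are embedded by
#' classical multidimensional scaling (double-centring of squared
#' distances and eigendecomposition, via [stats::cmdscale()]).  Axes are
#' ordered by non-increasing eigenvalue; the percent variance per axis
#' is computed over positive eigenvalues only.  On Euclidean input the
#' coordinates reproduce the distances exactly, so the leading axes
#' equal the principal components of the dosage matrix up to sign.
#'
#' @param x a [genotype_panel()], symmetric distance matrix, or
#'   [stats::dist].
#' @param k number of axes requested (>= 1); truncated with a warning if
#'   fewer positive eigenvalues exist.
#' @return A list of class `ordination_result` with `points` (samples x
#'   axes), `eig` (all eigenvalues), and `percent_var` for the returned
#'   axes.
#' @export
pcoa <- function(x, k = 2) {
  stopifnot(k >= 1)
  d <- if (inherits(x, "genotype_panel")) {
    g <- x$geno
    if (anyNA(g)) g <- impute_missing(x)$geno
    g <- scale(g, center = TRUE, scale = FALSE)
    stats::dist(g)
  } else if (inherits(x, "dist")) x else stats::as.dist(as.matrix(x))
  n <- attr(d, "Size")
  fit <- stats::cmdscale(d, k = min(k, n - 1), eig = TRUE)
  eig <- fit$eig
  pos <- eig[eig > 1e-8 * max(abs(eig))]
  kk <- ncol(fit$points)
  if (kk < k)
    warning("only ", kk, " positive-eigenvalue axes available; truncating")
  pct <- 100 * eig[seq_len(kk)] / sum(pos)
  structure(list(points = fit$points, eig = eig, percent_var = pct),
            class = "ordination_result")
}

#' Leading principal-component covariates for association analysis
#'
#' Convenience wrapper returning the first `n_axes` ordination axes of a
#' (filtered, imputed) marker panel as a covariate matrix for
#' [fit_null_lmm()] / [association_scan()].
#'
#' @param panel a [genotype_panel()].
#' @param n_axes number of axes (default 2).
#' @return Numeric matrix samples x axes with column names `PC1..`.
#' @export
panel_pcs <- function(panel, n_axes = 2) {
  ord <- pcoa(panel, k = n_axes)
  pcs <- ord$points[, seq_len(min(n_axes, ncol(ord$points))), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  rownames(pcs) <- panel$samples$sample_id
  pcs
}
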