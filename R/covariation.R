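#' Escoufier's RV coefficient between two blocks of variables
#'
#' A multivariate generalization of the squared Pearson correlation:
#' `RV = tr(S_xy S_yx) / sqrt(tr(S_xx^2) tr(S_yy^2))` on column-centered
#' blocks.  Ranges over `[0, 1]`, equals `r^2` when both blocks are
#' one-dimensional, and is invariant to orthogonal rotation of either
#' block.
#'
#' @param X,Y numeric matrices with the same number of rows (individuals).
#' @return a scalar in `[0, 1]`.
#' @export
rv_coefficient <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same number of rows")
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  n1 <- nrow(X) - 1
  sxx <- crossprod(Xc) / n1
  syy <- crossprod(Yc) / n1
  sxy <- crossprod(Xc, Yc) / n1
  den <- sqrt(sum(sxx^2) * sum(syy^2))
  if (den == 0)
    stop("RV undefined: a block has zero within-block variance")
  sum(sxy^2) / den
}

#' Two-block partial least squares
#'
#' Singular value decomposition of the cross-covariance matrix between two
#' column-centered (never scaled) blocks, yielding paired axes ordered by
#' decreasing singular value, per-axis percentages of total squared
#' covariance, paired scores and their Pearson correlations, plus the RV
#' coefficient.  Significance of every statistic is assessed by randomly
#' permuting the rows of `Y` only, which breaks the between-block
#' covariance without altering the variance within blocks; p-values use the
#' `(count >= observed + 1) / (n_perm + 1)` convention (upper tail: larger
#' statistic = stronger association).
#'
#' @param X,Y numeric matrices, same row count `n >= 3`.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed recorded in the result.
#' @return an object of class `pls_result`.
#' @export
two_block_pls <- function(X, Y, n_perm = 10000L, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same number of rows")
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 individuals")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (any(apply(X, 2, var) == 0) || any(apply(Y, 2, var) == 0))
    warning("constant column(s) present; retained with zero covariance")
  if (!is.null(seed)) set.seed(seed)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  naxes <- min(ncol(X), ncol(Y))
  decomp <- function(Yc) {
    C <- crossprod(Xc, Yc) / (n - 1)
    svd(C, nu = naxes, nv = naxes)
  }
  sv_cors <- function(s, Yc) {
    xs <- Xc %*% s$u
    ys <- Yc %*% s$v
    r <- vapply(seq_len(naxes), function(a) {
      if (sd(xs[, a]) == 0 || sd(ys[, a]) == 0) 0 else cor(xs[, a], ys[, a])
    }, numeric(1))
    list(xs = xs, ys = ys, r = r)
  }
  s <- decomp(Yc)
  obs <- sv_cors(s, Yc)
  sv <- s$d[seq_len(naxes)]
  rv <- rv_coefficient(X, Y)

  ge_sv <- numeric(naxes); ge_r <- numeric(naxes); ge_rv <- 0
  for (b in seq_len(n_perm)) {
    Yp <- Yc[sample.int(n), , drop = FALSE]
    sp <- decomp(Yp)
    pr <- sv_cors(sp, Yp)
    ge_sv <- ge_sv + (sp$d[seq_len(naxes)] >= sv)
    ge_r <- ge_r + (abs(pr$r) >= abs(obs$r))
    syy <- crossprod(Yp) / (n - 1)
    sxx <- crossprod(Xc) / (n - 1)
    rv_p <- sum((crossprod(Xc, Yp) / (n - 1))^2) /
      sqrt(sum(sxx^2) * sum(syy^2))
    ge_rv <- ge_rv + (rv_p >= rv)
  }
  structure(list(
    singular_values = sv,
    pct_total_covariance = 100 * sv^2 / sum(s$d^2),
    x_loadings = s$u, y_loadings = s$v,
    x_scores = obs$xs, y_scores = obs$ys,
    axis_correlations = obs$r,
    rv = rv,
    p_rv = (ge_rv + 1) / (n_perm + 1),
    p_singular_values = (ge_sv + 1) / (n_perm + 1),
    p_correlations = (ge_r + 1) / (n_perm + 1),
    n_permutations = n_perm, seed = seed, n = n),
    class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat("<pls_result> ", length(x$singular_values), " axis pair(s), RV = ",
      signif(x$rv, 4), " (p = ", signif(x$p_rv, 4), "), PLS1: ",
      signif(x$pct_total_covariance[1], 4), "% of squared covariance, r = ",
      signif(x$axis_correlations[1], 4), "\n", sep = "")
  invisible(x)
}

#' Principal component analysis of one block
#'
#' Eigen-decomposition of the covariance matrix of the column-centered (not
#' scaled) block, with a deterministic sign convention: each axis is
#' oriented so that its largest-magnitude loading is positive.
#'
#' @param X numeric matrix, `n >= 2` rows.
#' @return an object of class `pca_result` with `eigenvalues`,
#'   `pct_variance`, `axes` (columns are unit vectors) and `scores`.
#' @export
pca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  axes <- pr$rotation
  for (j in seq_len(ncol(axes))) {
    top <- which.max(abs(axes[, j]))
    if (axes[top, j] < 0) {
      axes[, j] <- -axes[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(eigenvalues = ev,
                 pct_variance = 100 * ev / sum(ev),
                 axes = axes, scores = pr$x, center = pr$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", length(x$eigenvalues), " components; PC1 = ",
      signif(x$pct_variance[1], 4), "%, PC2 = ",
      if (length(x$pct_variance) > 1) signif(x$pct_variance[2], 4) else 0,
      "%\n", sep = "")
  invisible(x)
}

#' Angle and score correlation between two axes
#'
#' Axes are sign-indeterminate, so the angle is
#' `acos(|v1 . v2| / (||v1|| ||v2||))` in degrees (0..90).  The analytic
#' p-value is the probability that two independent uniformly random
#' directions in dimension `p` subtend an angle this small or smaller,
#' obtained from the Beta(1/2, (p-1)/2) law of the squared cosine.
#'
#' @param v1,v2 axis vectors of equal dimension.
#' @param scores1,scores2 optional paired score vectors; their Pearson
#'   correlation (sign-aligned to the axes) is reported.
#' @return a list with `angle_deg`, `score_correlation`, `p_angle`.
#' @export
compare_axes <- function(v1, v2, scores1 = NULL, scores2 = NULL) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) stop("axes must have equal dimension")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length axis vector")
  c_raw <- sum(v1 * v2) / (n1 * n2)
  cabs <- min(abs(c_raw), 1)
  angle <- acos(cabs) * 180 / pi
  p <- length(v1)
  p_angle <- if (p < 2L) NA_real_ else
    pbeta(cabs^2, 0.5, (p - 1) / 2, lower.tail = FALSE)
  r <- NA_real_
  if (!is.null(scores1) && !is.null(scores2)) {
    r <- cor(scores1, if (c_raw < 0) -scores2 else scores2)
  }
  list(angle_deg = angle, score_correlation = r, p_angle = p_angle)
}

#' Correlations between ordination scores and the hybrid index
#'
#' Reporting utility pairing score vectors (PLS, PCA or between-group PCA
#' axes, or centroid sizes) with per-individual hybrid indices; individuals
#' with missing HI are dropped.
#'
#' @param scores named list (or single vector) of per-individual scores.
#' @param hi hybrid indices aligned with the scores.
#' @return a data frame with `score`, `r`, `p`, `n`.
#' @export
hi_correlations <- function(scores, hi) {
  if (!is.list(scores)) scores <- list(score = scores)
  rows <- lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    ok <- !is.na(hi) & !is.na(s)
    ct <- stats::cor.test(s[ok], hi[ok])
    data.frame(score = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
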