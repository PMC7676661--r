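#' Classify individuals by hybrid index
#'
#' Three ancestry classes from the admixture proportion HI (0 = African,
#' 1 = European): `pure_african` when `HI < lower`, `pure_european` when
#' `HI > upper`, otherwise `hybrid` (boundary values are hybrids).  Missing
#' HI yields `NA` (unclassified).
#'
#' @param hi numeric vector in `[0, 1]` (NA allowed).
#' @param lower,upper class thresholds (defaults 0.1 and 0.9).
#' @return a factor with levels `pure_african`, `hybrid`, `pure_european`.
#' @export
classify_hybrid_index <- function(hi, lower = 0.1, upper = 0.9) {
  if (any(!is.na(hi) & (hi < 0 | hi > 1)))
    stop("hybrid index must lie in [0, 1]")
  out <- ifelse(is.na(hi), NA_character_,
                ifelse(hi < lower, "pure_african",
                       ifelse(hi > upper, "pure_european", "hybrid")))
  factor(out, levels = c("pure_african", "hybrid", "pure_european"))
}

#' One-way ANOVA on centroid size with Tukey and Games-Howell post-hocs
#'
#' Compares group mean wing sizes across ancestry classes: overall F test,
#' Tukey HSD (equal variances) and Games-Howell (equal variances not
#' assumed; studentized-range statistic with Welch-Satterthwaite degrees of
#' freedom) pairwise adjusted p-values, plus descriptive statistics per
#' group (mean, sd, se and the half-width of the t-based 95% CI).
#'
#' @param cs per-individual mean centroid sizes (micrometers).
#' @param classes factor of group labels aligned with `cs`; `NA`s dropped.
#' @return a list with `anova_F`, `p`, `tukey`, `games_howell` (data
#'   frames of pairwise comparisons) and `group_stats`.
#' @export
size_group_anova <- function(cs, classes) {
  ok <- !is.na(cs) & !is.na(classes)
  cs <- cs[ok]; classes <- droplevels(factor(classes[ok]))
  sizes <- table(classes)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("group(s) of size 1 excluded from post-hoc tests: ",
            paste(small, collapse = ", "))
  }
  if (sum(sizes >= 2L) < 2L) stop("need at least 2 groups with >= 2 members")
  fit <- aov(cs ~ classes)
  at <- anova(fit)
  tk <- TukeyHSD(fit)$classes
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  keep_pairs <- !grepl(paste0("\\b(", paste(small, collapse = "|"), ")\\b"),
                       tukey$comparison)
  if (length(small)) tukey <- tukey[keep_pairs, , drop = FALSE]

  lv <- names(sizes)[sizes >= 2L]
  stats_g <- lapply(levels(classes), function(g) {
    v <- cs[classes == g]
    n <- length(v)
    se <- sd(v) / sqrt(n)
    data.frame(group = g, n = n, mean = mean(v), sd = sd(v), se = se,
               ci95 = if (n > 1) qt(0.975, n - 1) * se else NA_real_,
               stringsAsFactors = FALSE)
  })
  group_stats <- do.call(rbind, stats_g)
  k <- length(lv)
  gh <- NULL
  if (k >= 2L) {
    pairs <- utils::combn(lv, 2)
    gh <- apply(pairs, 2, function(pr) {
      a <- cs[classes == pr[1]]; b <- cs[classes == pr[2]]
      na <- length(a); nb <- length(b)
      va <- var(a) / na; vb <- var(b) / nb
      se <- sqrt(va + vb)
      t_stat <- (mean(a) - mean(b)) / se
      df_w <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
      p_adj <- ptukey(abs(t_stat) * sqrt(2), k, df_w, lower.tail = FALSE)
      data.frame(comparison = paste(pr[2], pr[1], sep = "-"),
                 diff = mean(b) - mean(a), t = -t_stat, df = df_w,
                 p_adj = p_adj, stringsAsFactors = FALSE)
    })
    gh <- do.call(rbind, gh)
  }
  list(anova_F = at$`F value`[1], p = at$`Pr(>F)`[1], tukey = tukey,
       games_howell = gh, group_stats = group_stats)
}

# Group means (rows) of a shape matrix, in the order of factor levels.
.group_means <- function(X, classes) {
  lv <- levels(classes)
  m <- t(vapply(lv, function(g) colMeans(X[classes == g, , drop = FALSE]),
                numeric(ncol(X))))
  rownames(m) <- lv
  m
}

#' Between-group principal component analysis
#'
#' Ordination designed for strongly unbalanced groups in a high-dimensional
#' shape space: the axes are the eigenvectors of the covariance of the
#' (by default unweighted) group mean shapes about their unweighted grand
#' mean, and every individual is projected onto them.  With g groups there
#' are `g - 1` axes.
#'
#' @param shapes matrix of per-individual left-right mean Procrustes
#'   coordinates (rows = individuals).
#' @param classes factor of group labels; rows with `NA` are dropped.
#' @param weighted if `TRUE`, weight each group mean by its size when
#'   forming the grand mean and covariance (off by default so the large
#'   hybrid group cannot dominate the axes).
#' @return an object of class `bgpca_result` with `axes`, `scores`,
#'   `group_means`, `group_mean_scores`, `pct_between_variance`,
#'   `eigenvalues`, `classes` and `grand_mean`.
#' @export
between_group_pca <- function(shapes, classes, weighted = FALSE) {
  shapes <- as.matrix(shapes)
  ok <- !is.na(classes)
  shapes <- shapes[ok, , drop = FALSE]
  classes <- droplevels(factor(classes[ok]))
  g <- nlevels(classes)
  if (g < 2L) stop("need at least 2 groups")
  M <- .group_means(shapes, classes)
  w <- if (weighted) as.vector(table(classes)) / length(classes)
       else rep(1 / g, g)
  grand <- colSums(M * w)
  Mc <- sweep(M, 2, grand)
  B <- crossprod(Mc * sqrt(w * g)) / (g - 1)   # covariance of (weighted) means
  ev <- eigen(B, symmetric = TRUE)
  naxes <- g - 1L
  axes <- ev$vectors[, seq_len(naxes), drop = FALSE]
  for (j in seq_len(naxes)) {
    top <- which.max(abs(axes[, j]))
    if (axes[top, j] < 0) axes[, j] <- -axes[, j]
  }
  vals <- pmax(ev$values[seq_len(naxes)], 0)
  scores <- sweep(shapes, 2, grand) %*% axes
  colnames(scores) <- paste0("bgPC", seq_len(naxes))
  structure(list(axes = axes, scores = scores, group_means = M,
                 group_mean_scores = Mc %*% axes,
                 eigenvalues = vals,
                 pct_between_variance = 100 * vals / sum(vals),
                 classes = classes, grand_mean = grand,
                 weighted = weighted),
            class = "bgpca_result")
}

#' @export
print.bgpca_result <- function(x, ...) {
  cat("<bgpca_result> ", nlevels(x$classes), " groups, ",
      ncol(x$axes), " axes; bgPC1 = ",
      signif(x$pct_between_variance[1], 4), "% of between-group variance\n",
      sep = "")
  invisible(x)
}

#' Leave-one-out cross-validated classification to nearest group mean
#'
#' For each individual the group means — and, when `space =
#' "bg_subspace"`, the between-group PCA axes — are recomputed with that
#' individual removed, and the individual is assigned to the group whose
#' mean is nearest (Euclidean distance) in the chosen space.  Ties break to
#' the lowest group label in factor-level order.
#'
#' @param shapes matrix of per-individual shapes (rows = individuals).
#' @param classes factor of true group labels.
#' @param space `"bg_subspace"` (default) or `"full_shape"`.
#' @return a list with `confusion` (rows = true groups), `correct_rates`
#'   per group, `overall_correct_rate` and the `assigned` factor.
#' @export
loo_classification <- function(shapes, classes,
                               space = c("bg_subspace", "full_shape")) {
  space <- match.arg(space)
  shapes <- as.matrix(shapes)
  ok <- !is.na(classes)
  shapes <- shapes[ok, , drop = FALSE]
  classes <- droplevels(factor(classes[ok]))
  lv <- levels(classes)
  n <- nrow(shapes)
  assigned <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    cl_i <- classes[-i]
    if (!classes[i] %in% cl_i) {
      warning("individual ", i, " is the sole member of group '",
              classes[i], "'; skipped from cross-validation")
      next
    }
    M <- .group_means(shapes[-i, , drop = FALSE], droplevels(cl_i))
    x <- shapes[i, ]
    if (space == "bg_subspace" && nrow(M) > 2L) {
      grand <- colMeans(M)
      Mc <- sweep(M, 2, grand)
      evec <- eigen(crossprod(Mc) / (nrow(M) - 1),
                    symmetric = TRUE)$vectors[, seq_len(nrow(M) - 1L),
                                              drop = FALSE]
      Mp <- Mc %*% evec
      xp <- (x - grand) %*% evec
      d <- sqrt(rowSums(sweep(Mp, 2, as.vector(xp))^2))
    } else {
      d <- sqrt(rowSums(sweep(M, 2, x)^2))
    }
    assigned[i] <- rownames(M)[which.min(d)]  # which.min: first = lowest label
  }
  assigned <- factor(assigned, levels = lv)
  keep <- !is.na(assigned)
  confusion <- table(true = classes[keep], assigned = assigned[keep])
  correct <- diag(confusion) / rowSums(confusion)
  list(confusion = confusion, correct_rates = correct,
       overall_correct_rate = sum(diag(confusion)) / sum(confusion),
       assigned = assigned, space = space)
}

#' Permutation tests of pairwise distances between group mean shapes
#'
#' For each pair of groups, the observed Procrustes (Euclidean) distance
#' between the group mean shapes is compared with its null distribution
#' obtained by shuffling the class labels within that pair; p-values use
#' the `(count >= observed + 1) / (n_perm + 1)` convention.
#'
#' @param shapes matrix of per-individual shapes.
#' @param classes factor of group labels.
#' @param n_perm number of permutations (default 30000).
#' @param seed optional integer seed.
#' @return a data frame with `group1`, `group2`, `distance`, `p`.
#' @export
pairwise_mean_distance_test <- function(shapes, classes, n_perm = 30000L,
                                        seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  shapes <- as.matrix(shapes)
  ok <- !is.na(classes)
  shapes <- shapes[ok, , drop = FALSE]
  classes <- droplevels(factor(classes[ok]))
  lv <- levels(classes)
  if (length(lv) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(lv, 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    sel <- classes %in% pairs[, j]
    Xp <- shapes[sel, , drop = FALSE]
    lab <- droplevels(classes[sel])
    n1 <- sum(lab == pairs[1, j])
    dist_between <- function(labv) {
      m1 <- colMeans(Xp[labv == pairs[1, j], , drop = FALSE])
      m2 <- colMeans(Xp[labv == pairs[2, j], , drop = FALSE])
      sqrt(sum((m1 - m2)^2))
    }
    obs <- dist_between(lab)
    ge <- 0L
    nr <- nrow(Xp)
    for (b in seq_len(n_perm)) {
      perm <- lab[sample.int(nr)]
      if (dist_between(perm) >= obs) ge <- ge + 1L
    }
    rows[[j]] <- data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                            distance = obs, p = (ge + 1) / (n_perm + 1),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Phenotypic trajectory (vector-angle) analysis of the three clusters
#'
#' Tests whether hybrids deviate from the straight line between the two
#' parental mean shapes.  The angle at the African vertex between the
#' vectors to the hybrid mean and to the European mean is computed in shape
#' space; a zero angle means perfect intermediacy, a large angle
#' transgressive hybrid morphology.  The p-value permutes the class labels
#' and recomputes the angle (upper tail: larger angle = more
#' transgressive).  Pairwise mean distances (with their own permutation
#' tests) quantify the magnitudes.
#'
#' @param shapes matrix of per-individual shapes.
#' @param classes factor with levels containing `pure_african`, `hybrid`,
#'   `pure_european` (all non-empty).
#' @param n_perm permutations for the angle test (default 10000).
#' @param seed optional integer seed.
#' @param n_perm_distance permutations for the magnitude tests (default
#'   30000).
#' @return an object of class `trajectory_result` with `angle_deg`,
#'   `p_angle` and `magnitudes`.
#' @export
trajectory_angle <- function(shapes, classes, n_perm = 10000L, seed = NULL,
                             n_perm_distance = 30000L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  shapes <- as.matrix(shapes)
  ok <- !is.na(classes)
  shapes <- shapes[ok, , drop = FALSE]
  classes <- droplevels(factor(classes[ok]))
  need <- c("pure_african", "hybrid", "pure_european")
  if (!all(need %in% levels(classes)))
    stop("all three classes must be present; missing: ",
         paste(setdiff(need, levels(classes)), collapse = ", "))
  angle_of <- function(labv) {
    mA <- colMeans(shapes[labv == "pure_african", , drop = FALSE])
    mH <- colMeans(shapes[labv == "hybrid", , drop = FALSE])
    mE <- colMeans(shapes[labv == "pure_european", , drop = FALSE])
    v1 <- mH - mA; v2 <- mE - mA
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(max(-1, min(1, cosang))) * 180 / pi
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- angle_of(classes)
  ge <- 0L
  n <- nrow(shapes)
  for (b in seq_len(n_perm))
    if (angle_of(classes[sample.int(n)]) >= obs) ge <- ge + 1L
  mags <- pairwise_mean_distance_test(shapes, classes,
                                      n_perm = n_perm_distance, seed = seed)
  structure(list(angle_deg = obs, p_angle = (ge + 1) / (n_perm + 1),
                 magnitudes = mags, n_permutations = n_perm, seed = seed),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("<trajectory_result> angle at African vertex = ",
      signif(x$angle_deg, 4), " deg (p = ", signif(x$p_angle, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Size-correct FA scores by regression on centroid size
#'
#' Residuals of the ordinary least-squares regression of the FA score on
#' mean centroid size; used when asymmetry covaries with size so that
#' downstream FA-vs-ancestry regressions are not confounded by size.
#'
#' @param fa per-individual FA scores.
#' @param size per-individual mean centroid sizes.
#' @return residual (size-corrected) FA values, mean zero.
#' @export
size_correct_fa <- function(fa, size) {
  if (length(fa) != length(size)) stop("fa and size must be paired")
  if (var(size) == 0) stop("size has zero variance; correction undefined")
  as.numeric(resid(lm(fa ~ size)))
}

#' Linear vs quadratic regression of FA on a predictor, with model choice
#'
#' Fits `y = a + b x` and `y = a + b x + c x^2`, reports per model the
#' coefficients, R-squared, parametric slope p-value (the highest-order
#' term), residual sum of squares and the information criteria
#' `AIC = n log(RSS/n) + 2k`, `AICc = AIC + 2k(k+1)/(n-k-1)`,
#' `BIC = n log(RSS/n) + k log(n)` with `k` counting the intercept, the
#' slope(s) and the error variance.  The selected model is the one with
#' the lower AICc, ties (within 1e-8) breaking to the simpler (linear)
#' model.  The linear slope is additionally tested by permutation of the
#' predictor.
#'
#' @param fa response (FA values).
#' @param predictor covariate (hybrid index).
#' @param n_perm permutations for the slope test (default 10000).
#' @param seed optional integer seed.
#' @return an object of class `regression_comparison`.
#' @export
fa_vs_predictor <- function(fa, predictor, n_perm = 10000L, seed = NULL) {
  ok <- !is.na(fa) & !is.na(predictor)
  y <- fa[ok]; x <- predictor[ok]
  n <- length(y)
  if (n < 4L) stop("need at least 4 paired observations")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fit_one <- function(fml, k) {
    m <- lm(fml, data = data.frame(x = x, y = y))
    rss <- sum(resid(m)^2)
    if (n - k - 1 <= 0) stop("too few observations for AICc with k = ", k)
    aic <- n * log(rss / n) + 2 * k
    sm <- summary(m)
    cf <- coef(sm)
    list(coefficients = coef(m), r_squared = sm$r.squared,
         slope_p = cf[nrow(cf), 4], rss = rss, aic = aic,
         aicc = aic + 2 * k * (k + 1) / (n - k - 1),
         bic = n * log(rss / n) + k * log(n), k = k, model = m)
  }
  lin <- fit_one(y ~ x, 3L)
  quad <- fit_one(y ~ x + I(x^2), 4L)
  b_obs <- lin$coefficients[2]
  xc <- x - mean(x); yc <- y - mean(y)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    bp <- sum(xc[sample.int(n)] * yc) / sum(xc^2)
    if (abs(bp) >= abs(b_obs)) ge <- ge + 1L
  }
  selected <- if (quad$aicc < lin$aicc - 1e-8) "quadratic" else "linear"
  structure(list(linear = lin[-9], quadratic = quad[-9],
                 perm_slope_p = (ge + 1) / (n_perm + 1),
                 selected_model = selected, n = n,
                 n_permutations = n_perm, seed = seed),
            class = "regression_comparison")
}

#' @export
print.regression_comparison <- function(x, ...) {
  cat("<regression_comparison> selected: ", x$selected_model,
      " (AICc linear ", signif(x$linear$aicc, 6), ", quadratic ",
      signif(x$quadratic$aicc, 6), "); linear slope p = ",
      signif(x$linear$slope_p, 4), ", permutation p = ",
      signif(x$perm_slope_p, 4), "\n", sep = "")
  invisible(x)
}
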