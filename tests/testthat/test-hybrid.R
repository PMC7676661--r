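test_that("hybrid-index classification uses strict thresholds", {
  expect_equal(as.character(classify_hybrid_index(c(0.06, 0.5, 0.96))),
               c("pure_african", "hybrid", "pure_european"))
  # boundary values are hybrids ("smaller than"/"larger than" are strict)
  expect_equal(as.character(classify_hybrid_index(c(0.1, 0.9))),
               c("hybrid", "hybrid"))
  expect_true(is.na(classify_hybrid_index(NA_real_)))
  expect_error(classify_hybrid_index(1.1), "\\[0, 1\\]")
  expect_equal(as.character(classify_hybrid_index(c(0, 1))),
               c("pure_african", "pure_european"))
})

test_that("size group ANOVA handles identical and two-group designs", {
  g <- factor(rep(c("a", "b", "c"), each = 5))
  cs <- rep(c(1, 2, 3, 4, 5), 3)
  r <- size_group_anova(cs, g)
  expect_equal(r$anova_F, 0)
  expect_true(all(r$tukey$p_adj == 1))
  expect_true(all(r$games_howell$p_adj > 0.999))

  set.seed(51)
  cs2 <- c(rnorm(8, 10), rnorm(8, 12))
  g2 <- factor(rep(c("a", "b"), each = 8))
  r2 <- size_group_anova(cs2, g2)
  tt <- t.test(cs2 ~ g2, var.equal = TRUE)
  expect_equal(r2$tukey$p_adj, tt$p.value, tolerance = 1e-9)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-9)
})

test_that("group descriptive statistics match their definitions", {
  set.seed(52)
  cs <- rnorm(12, 6500, 100)
  g <- factor(rep(c("x", "y"), each = 6))
  st <- size_group_anova(cs, g)$group_stats
  v <- cs[g == "x"]
  expect_equal(st$mean[1], mean(v))
  expect_equal(st$se[1], sd(v) / sqrt(6))
  expect_equal(st$ci95[1], qt(0.975, 5) * sd(v) / sqrt(6))
})

test_that("singleton groups are excluded from post-hocs with a warning", {
  cs <- c(1, 2, 3, 4, 5, 9)
  g <- factor(c("a", "a", "b", "b", "b", "c"))
  expect_warning(r <- size_group_anova(cs, g), "size 1")
  expect_false(any(grepl("c", r$games_howell$comparison)))
})

test_that("between-group PCA recovers hand-computable axes for 3 groups", {
  # three group means in a 2-D plane embedded in 4-D
  M <- rbind(c(0, 0, 0, 0), c(2, 0, 0, 0), c(2, 1, 0, 0))
  shapes <- M[rep(1:3, each = 4), ] +
    matrix(rnorm(48, 0, 1e-6), 12, 4)
  cl <- factor(rep(c("a", "b", "c"), each = 4))
  bg <- between_group_pca(shapes, cl)
  expect_equal(ncol(bg$axes), 2)
  grand <- colMeans(M)
  B <- crossprod(sweep(M, 2, grand)) / 2
  ev <- eigen(B, symmetric = TRUE)
  expect_equal(bg$eigenvalues, ev$values[1:2], tolerance = 1e-4)
  expect_equal(abs(sum(bg$axes[, 1] * ev$vectors[, 1])), 1, tolerance = 1e-4)
  expect_equal(sum(bg$pct_between_variance), 100)
  # identical group means: all between-group eigenvalues vanish
  shapes0 <- matrix(rnorm(48), 12, 4)
  shapes0 <- shapes0[c(1:4, 1:4, 1:4), ]
  bg0 <- between_group_pca(shapes0, cl)
  expect_lt(max(bg0$eigenvalues), 1e-20)
})

test_that("bgPCA scores reproduce group-mean distances in the subspace", {
  set.seed(53)
  shapes <- matrix(rnorm(30 * 10), 30, 10)
  cl <- factor(rep(c("a", "b", "c"), each = 10))
  shapes[cl == "b", 1] <- shapes[cl == "b", 1] + 2
  shapes[cl == "c", 2] <- shapes[cl == "c", 2] + 1
  bg <- between_group_pca(shapes, cl)
  M <- bg$group_means
  proj <- bg$group_mean_scores
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    full_d <- sqrt(sum((M[pair[1], ] - M[pair[2], ])^2))
    sub_d <- sqrt(sum((proj[pair[1], ] - proj[pair[2], ])^2))
    expect_equal(sub_d, full_d, tolerance = 1e-9)  # 3 means span the plane
  }
})

test_that("leave-one-out classification separates distinct clusters", {
  set.seed(54)
  n <- 15
  shapes <- rbind(matrix(rnorm(n * 6, 0, 0.1), n, 6),
                  sweep(matrix(rnorm(n * 6, 0, 0.1), n, 6), 2,
                        c(5, 0, 0, 0, 0, 0), "+"),
                  sweep(matrix(rnorm(n * 6, 0, 0.1), n, 6), 2,
                        c(0, 5, 0, 0, 0, 0), "+"))
  cl <- factor(rep(c("a", "b", "c"), each = n))
  for (space in c("bg_subspace", "full_shape")) {
    r <- loo_classification(shapes, cl, space = space)
    expect_gte(r$overall_correct_rate, 0.99)
    expect_equal(rowSums(r$confusion), c(a = n, b = n, c = n))
  }
})

test_that("an overlapping middle group is misclassified far more often", {
  set.seed(55)
  n <- 40
  mk <- function(mu) sweep(matrix(rnorm(n * 8, 0, 1.2), n, 8), 2, mu, "+")
  shapes <- rbind(mk(rep(0, 8)), mk(c(1, rep(0, 7))), mk(c(2, rep(0, 7))))
  cl <- factor(rep(c("afr", "hyb", "eur"), each = n),
               levels = c("afr", "hyb", "eur"))
  r <- loo_classification(shapes, cl)
  expect_lt(r$correct_rates["hyb"],
            min(r$correct_rates["afr"], r$correct_rates["eur"]))
})

test_that("identical individuals break classification ties to the lowest label", {
  shapes <- matrix(1, 9, 4)
  cl <- factor(rep(c("a", "b", "c"), 3))
  expect_equal(as.character(loo_classification(shapes, cl)$assigned),
               rep("a", 9))
})

test_that("pairwise mean-distance permutation test saturates under separation", {
  set.seed(56)
  shapes <- rbind(matrix(rnorm(40, 0, 0.01), 10, 4),
                  matrix(rnorm(40, 8, 0.01), 10, 4))
  cl <- factor(rep(c("a", "b"), each = 10))
  r <- pairwise_mean_distance_test(shapes, cl, n_perm = 199, seed = 1)
  expect_equal(r$p, 1 / 200)       # minimum attainable p
  expect_equal(r$distance, sqrt(sum((colMeans(shapes[1:10, ]) -
                                     colMeans(shapes[11:20, ]))^2)))
  expect_error(pairwise_mean_distance_test(shapes, cl, n_perm = 0), "n_perm")
})

test_that("trajectory angle matches planar geometry and handles collinearity", {
  mk_groups <- function(means, n = 6, sd = 1e-9) {
    shapes <- do.call(rbind, lapply(means, function(m)
      sweep(matrix(rnorm(n * length(m), 0, sd), n, length(m)), 2, m, "+")))
    cl <- factor(rep(c("pure_african", "hybrid", "pure_european"), each = n),
                 levels = c("pure_african", "hybrid", "pure_european"))
    list(shapes = shapes, cl = cl)
  }
  # A=(0,0), H=(0.5,0.5), E=(1,0): 45 degrees at the African vertex
  g <- mk_groups(list(c(0, 0), c(0.5, 0.5), c(1, 0)))
  tr <- trajectory_angle(g$shapes, g$cl, n_perm = 9, seed = 1,
                         n_perm_distance = 9)
  expect_equal(tr$angle_deg, 45, tolerance = 1e-4)
  # hybrid mean exactly on the A-E segment: zero angle
  g0 <- mk_groups(list(c(0, 0), c(0.4, 0), c(1, 0)))
  tr0 <- trajectory_angle(g0$shapes, g0$cl, n_perm = 9, seed = 1,
                          n_perm_distance = 9)
  expect_equal(tr0$angle_deg, 0, tolerance = 0.01)
  # magnitudes obey the triangle inequality
  d <- tr$magnitudes$distance
  expect_lte(d[2], d[1] + d[3] + 1e-12)
  expect_error(trajectory_angle(g$shapes[1:12, ], droplevels(g$cl[1:12]),
                                n_perm = 9), "missing")
})

test_that("size correction returns OLS residuals", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.0, 9.8)
  r <- size_correct_fa(y, x)
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  expect_equal(r, y - (a + b * x))
  expect_equal(mean(r), 0)
  expect_equal(size_correct_fa(2 * x + 1, x), rep(0, 5), tolerance = 1e-12)
  set.seed(57)
  fa <- rnorm(30)
  expect_equal(size_correct_fa(fa, rnorm(30)), fa - mean(fa), tolerance = 0.5)
  expect_error(size_correct_fa(fa, rep(1, 30)), "zero variance")
})

test_that("model comparison prefers the true curvature and recovers slopes", {
  set.seed(58)
  x <- runif(50)
  y_quad <- 1 + 2 * x - 3 * x^2
  # noiseless response: lm warns about the perfect quadratic fit
  r <- suppressWarnings(fa_vs_predictor(y_quad, x, n_perm = 49, seed = 1))
  expect_equal(r$selected_model, "quadratic")
  expect_lt(r$quadratic$aic, r$linear$aic)
  expect_lt(r$quadratic$bic, r$linear$bic)
  # invariants: nested RSS ordering and the small-sample penalty
  expect_lte(r$quadratic$rss, r$linear$rss + 1e-12)
  expect_gte(r$linear$aicc, r$linear$aic)

  x2 <- runif(200)
  y2 <- 2 * x2 + rnorm(200, 0, 0.05)
  r2 <- fa_vs_predictor(y2, x2, n_perm = 49, seed = 2)
  expect_equal(unname(r2$linear$coefficients[2]), 2, tolerance = 0.05)
  expect_equal(r2$perm_slope_p, 1 / 50)
  expect_error(fa_vs_predictor(y2[1:3], x2[1:3]), "at least 4")
})

test_that("slope permutation p-values are calibrated under the null", {
  set.seed(59)
  nsim <- 300L; reject <- 0L
  for (i in seq_len(nsim)) {
    x <- runif(25); y <- rnorm(25)
    r <- fa_vs_predictor(y, x, n_perm = 99)
    if (r$perm_slope_p <= 0.05) reject <- reject + 1L
  }
  expect_gt(reject / nsim, 0.02)
  expect_lt(reject / nsim, 0.09)
})
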