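test_that("replicated-design ANOVA reproduces the balanced df bookkeeping", {
  sim <- simulate_population(generator_params(n_individuals = 36,
                                              n_replicated = 36, seed = 21))
  fit <- gpa(mirror_left(sim$dataset$landmarks))
  a_shape <- asymmetry_anova(fit, "shape", require_replicates = TRUE)
  a_size <- asymmetry_anova(fit, "size", require_replicates = TRUE)
  expect_equal(a_shape$df, c(1190L, 34L, 1190L, 2448L, 4896L))
  expect_equal(a_size$df, c(35L, 1L, 35L, 72L, 144L))
  expect_equal(a_shape$effect[4:5], c("ME1_imaging", "ME2_digitizing"))
  # SS additivity and %Var bookkeeping
  for (a in list(a_shape, a_size)) {
    expect_equal(sum(a$pct_var), 100)
    expect_equal(a$MS, a$SS / a$df)
  }
  # Goodall's F ratios follow the mixed-model denominators
  expect_equal(a_shape$F[1], a_shape$MS[1] / a_shape$MS[3])
  expect_equal(a_shape$F[2], a_shape$MS[2] / a_shape$MS[3])
  expect_equal(a_shape$F[3], a_shape$MS[3] / a_shape$MS[4])
  expect_equal(a_shape$F[4], a_shape$MS[4] / a_shape$MS[5])
})

test_that("shape SS decomposition equals summed per-coordinate ANOVA", {
  set.seed(31)
  for (design in list(c(4, 1, 1), c(3, 2, 1), c(3, 2, 2), c(5, 2, 3))) {
    ls <- random_landmarks(n_ind = design[1], r1 = design[2],
                           r2 = design[3], sd = 0.4)
    fit <- gpa(mirror_left(ls))
    a <- asymmetry_anova(fit, "shape")
    oracle <- aov_shape_ss(fit)
    expect_equal(a$SS, unname(oracle[seq_along(a$SS)]), tolerance = 1e-8)
    expect_equal(sum(a$SS),
                 sum(sweep(t(apply(fit$aligned, 3,
                                   function(m) as.vector(t(m)))), 2,
                           colMeans(t(apply(fit$aligned, 3,
                                            function(m) as.vector(t(m)))))) ^ 2),
                 tolerance = 1e-8)
  }
})

test_that("perfect bilateral symmetry yields zero side and interaction SS", {
  set.seed(32)
  base <- wing_template() + 6
  coords <- list(); info <- list(); idx <- 0
  for (i in 1:5) {
    shape <- base + matrix(rnorm(38, 0, 0.05), 19, 2)
    for (s in c("left", "right")) {
      idx <- idx + 1
      xy <- shape
      if (s == "left") xy[, 1] <- -xy[, 1]
      coords[[idx]] <- xy
      info[[idx]] <- data.frame(individual_id = paste0("i", i), side = s,
                                imaging_replicate = 1,
                                digitization_replicate = 1)
    }
  }
  ls <- landmark_set(coords, do.call(rbind, info))
  fit <- gpa(mirror_left(ls))
  a <- asymmetry_anova(fit, "shape")
  expect_lt(a$SS[a$effect == "sides"], 1e-12)
  expect_lt(a$SS[a$effect == "individuals_x_sides"], 1e-12)
  a_cs <- asymmetry_anova(fit, "size")
  expect_lt(a_cs$SS[2] + a_cs$SS[3], 1e-8)
})

test_that("measurement-error rows require genuine replicates", {
  set.seed(33)
  ls <- random_landmarks(n_ind = 4)
  fit <- gpa(mirror_left(ls))
  expect_error(asymmetry_anova(fit, "size", require_replicates = TRUE),
               "r1")
  a <- asymmetry_anova(fit, "size")
  expect_equal(a$effect, c("individuals", "sides", "individuals_x_sides"))
  expect_true(is.na(a$F[3]))  # no error stratum to test FA against
})

test_that("FA scores recover planted structure and match longhand norms", {
  set.seed(34)
  ls <- random_landmarks(n_ind = 6, sd = 0.3)
  fit <- gpa(mirror_left(ls))
  expect_warning(fa <- fa_scores(fit), "rank")
  im <- individual_means(fit)
  D <- sweep(im$asymmetry, 2, colMeans(im$asymmetry))
  expect_equal(fa$procrustes_fa, unname(sqrt(rowSums(D^2))))
  expect_equal(colMeans(D), rep(0, ncol(D)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(fa$cs_fa_signed, fa$cs_left - fa$cs_right)
  expect_equal(fa$cs_fa, abs(fa$cs_fa_signed))
})

test_that("a perfectly symmetric individual scores zero FA", {
  set.seed(35)
  base <- wing_template() + 6
  coords <- list(); info <- list(); idx <- 0
  for (i in 1:4) {
    shape <- base + matrix(rnorm(38, 0, 0.05), 19, 2)
    for (s in c("left", "right")) {
      idx <- idx + 1
      xy <- shape; if (s == "left") xy[, 1] <- -xy[, 1]
      coords[[idx]] <- xy
      info[[idx]] <- data.frame(individual_id = paste0("i", i), side = s,
                                imaging_replicate = 1,
                                digitization_replicate = 1)
    }
  }
  fit <- gpa(mirror_left(landmark_set(coords, do.call(rbind, info))))
  suppressWarnings(fa <- fa_scores(fit))
  expect_lt(max(fa$procrustes_fa), 1e-9)
  expect_lt(max(fa$cs_fa), 1e-6)
})

test_that("two antisymmetric individuals share their FA magnitude", {
  # left - right difference of one equals minus that of the other:
  # the DA vector vanishes and both Procrustes FA scores coincide
  base <- wing_template() + 6
  d <- matrix(c(0.02, rep(0, 37)), 19, 2)
  coords <- list(base + d, base - d, base - d, base + d)
  coords[c(1, 3)] <- lapply(coords[c(1, 3)], function(m) {
    m[, 1] <- -m[, 1]; m })
  info <- data.frame(individual_id = c("a", "a", "b", "b"),
                     side = c("left", "right", "left", "right"),
                     imaging_replicate = 1, digitization_replicate = 1)
  fit <- gpa(mirror_left(landmark_set(coords, info)))
  suppressWarnings(fa <- fa_scores(fit))
  expect_lt(max(abs(attr(fa, "da_vector"))), 1e-10)
  expect_equal(fa$procrustes_fa[1], fa$procrustes_fa[2], tolerance = 1e-9)
})

test_that("ICC(2,1) matches hand arithmetic and an independent reference", {
  # perfect repeatability
  x <- matrix(rep(c(3, 7, 1, 5), 2), ncol = 2)
  expect_equal(icc_2_1(x)$icc, 1)
  # 4 x 2 toy table checked against longhand mean squares
  y <- matrix(c(1, 2, 3, 5, 2, 1, 4, 6), ncol = 2)
  r <- icc_2_1(y)
  n <- 4; k <- 2
  grand <- mean(y)
  msr <- k * sum((rowMeans(y) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(y) - grand)^2) / (k - 1)
  mse <- (sum((y - grand)^2) - (n - 1) * msr / k * k - (k - 1) * msc / n * n) /
    ((n - 1) * (k - 1))
  expect_equal(r$icc,
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  # frozen reference: two-way random, absolute agreement, single measure
  # on a fixed 6 x 3 table (computed once with pingouin.intraclass_corr)
  z <- matrix(c(7.1, 7.3, 7.2, 5.1, 5.4, 5.0, 8.2, 8.0, 8.4,
                6.0, 6.1, 6.2, 4.9, 5.2, 5.1, 7.7, 7.4, 7.6),
              ncol = 3, byrow = TRUE)
  rz <- icc_2_1(z)
  expect_equal(rz$icc, 0.9854209, tolerance = 1e-6)
  expect_true(rz$ci95[1] > 0.935 && rz$ci95[1] < 0.945)
  expect_true(rz$ci95[2] > 0.99 && rz$ci95[2] <= 1)
  expect_error(icc_2_1(y[, 1, drop = FALSE]), "k = 2")
})

test_that("independent noise columns give near-zero ICC at large n", {
  set.seed(36)
  x <- matrix(rnorm(2000), ncol = 2)
  expect_lt(abs(icc_2_1(x)$icc), 0.08)
})

test_that("Goodall F tests hold their size with no planted DA or FA", {
  # only measurement error present: the sides and interaction tests must
  # reject at the nominal 5% rate, for both traits
  set.seed(12)
  nsim <- 800L
  rej <- matrix(0L, 2, 2, dimnames = list(c("sides", "int"),
                                          c("shape", "size")))
  for (i in seq_len(nsim)) {
    p <- generator_params(n_individuals = 5, n_replicated = 5,
                          fa_shape_sd = 0, fa_size_sd = 0, da_magnitude = 0,
                          cs_da = 0, me1_scale_sd = 0,
                          seed = sample.int(2^30, 1))
    sim <- simulate_population(p)
    fit <- gpa(mirror_left(sim$dataset$landmarks))
    ash <- asymmetry_anova(fit, "shape")
    asz <- asymmetry_anova(fit, "size")
    rej["sides", "shape"] <- rej["sides", "shape"] + (ash$p[2] <= 0.05)
    rej["int", "shape"] <- rej["int", "shape"] + (ash$p[3] <= 0.05)
    rej["sides", "size"] <- rej["sides", "size"] + (asz$p[2] <= 0.05)
    rej["int", "size"] <- rej["int", "size"] + (asz$p[3] <= 0.05)
  }
  rates <- rej / nsim
  expect_true(all(rates >= 0.03), info = paste(rates, collapse = ", "))
  expect_true(all(rates <= 0.07), info = paste(rates, collapse = ", "))
})

test_that("strong planted FA is detected essentially always", {
  # FA variance well above measurement error: the interaction test must
  # be significant in nearly every simulated dataset
  set.seed(13)
  hits <- 0L; nsim <- 40L
  for (i in seq_len(nsim)) {
    p <- generator_params(n_individuals = 8, n_replicated = 8,
                          fa_shape_sd = 0.003, me1_sd = 1, me2_sd = 1,
                          me1_scale_sd = 0, seed = sample.int(2^30, 1))
    sim <- simulate_population(p)
    fit <- gpa(mirror_left(sim$dataset$landmarks))
    ash <- asymmetry_anova(fit, "shape")
    if (ash$p[ash$effect == "individuals_x_sides"] < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / nsim, 0.95)
})

test_that("replicate-level FA scores form complete repeatability tables", {
  sim <- simulate_population(generator_params(n_individuals = 10,
                                              n_replicated = 10, seed = 37))
  fit <- gpa(mirror_left(sim$dataset$landmarks))
  rep_fa <- suppressWarnings(fa_scores_by_replicate(fit))  # rank warning
  expect_equal(dim(rep_fa$procrustes_fa), c(10, 4))
  expect_false(anyNA(rep_fa$procrustes_fa))
  # strong planted FA relative to ME: high repeatability of CSFA
  expect_gt(icc_2_1(rep_fa$cs_fa_signed)$icc, 0.5)
})
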