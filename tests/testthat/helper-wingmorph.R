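# Shared fixtures, all built in code.

# Random landmark set: n configurations of k landmarks, optionally a paired
# left/right design with r1 x r2 replicates per wing.
random_landmarks <- function(n_ind = 3, k = 19, r1 = 1, r2 = 1, sd = 1,
                             base = NULL) {
  if (is.null(base)) base <- matrix(runif(2 * k, 0, 10), k, 2)
  coords <- list(); info <- list(); idx <- 0
  for (i in seq_len(n_ind)) for (s in c("left", "right"))
    for (a in seq_len(r1)) for (b in seq_len(r2)) {
      idx <- idx + 1
      xy <- base + matrix(rnorm(2 * k, 0, sd), k, 2)
      if (s == "left") xy[, 1] <- -xy[, 1]   # stored as digitized
      coords[[idx]] <- xy
      info[[idx]] <- data.frame(individual_id = sprintf("ind%02d", i),
                                side = s, imaging_replicate = a,
                                digitization_replicate = b)
    }
  landmark_set(coords, do.call(rbind, info))
}

# Apply a random similarity transform (rotation + translation + scaling).
similarity_transform <- function(xy, angle = runif(1, -pi, pi),
                                 scale = runif(1, 0.5, 2),
                                 shift = runif(2, -5, 5)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * xy %*% R, 2, shift, "+")
}

# Conventional per-coordinate ANOVA SS via stats::aov with sequential sums
# of squares, summed over coordinates: the independent oracle for the
# Procrustes ANOVA decomposition.
aov_shape_ss <- function(fit) {
  X <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))
  info <- fit$info
  ind <- factor(info$individual_id)
  side <- factor(info$side)
  cell <- factor(paste(info$individual_id, info$side))
  img <- factor(paste(info$individual_id, info$side,
                      info$imaging_replicate))
  replicated <- max(table(cell)) > 1
  eff <- NULL
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    if (replicated) {
      # sequential SS with cell (= individual x side) fitted before the
      # imaging factor nested inside it, residual = digitization error;
      # aov warns on saturated fits (r2 = 1) but the SS are exact
      tab <- suppressWarnings(anova(aov(y ~ ind + side + cell + img)))
      ss <- tab[c("ind", "side", "cell", "img", "Residuals"), "Sum Sq"]
    } else {
      # saturated design: aov warns about the zero-residual fit, but the
      # sequential SS are exactly what the oracle needs
      tab <- suppressWarnings(anova(aov(y ~ ind * side)))
      ss <- tab[c("ind", "side", "ind:side"), "Sum Sq"]
    }
    eff <- if (is.null(eff)) ss else eff + ss
  }
  eff
}
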