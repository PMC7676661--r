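#' Two-way mixed-model (Procrustes) ANOVA for size and shape asymmetry
#'
#' Partitions the total variation of a paired-wing design into among-
#' individual variation (symmetric component), directional asymmetry
#' (sides), fluctuating asymmetry (individual-by-side interaction), and —
#' when the design carries replicates — two nested measurement-error
#' strata: re-imaging (ME1) and re-digitizing within image (ME2).
#'
#' Sums of squares are computed from marginal means of the balanced design:
#' the individual effect from left-right-replicate means, the side effect
#' from the mean left-right difference, the interaction from
#' individual-specific left-right deviations, ME1 from variation over
#' imaging sessions within individual-by-side, and ME2 as the residual over
#' digitizations.  For shape, squared deviations are summed over all `2k`
#' Procrustes coordinates and every conventional degree of freedom is
#' multiplied by the shape-space dimension `2k - 4` (34 for 19 landmarks).
#' Significance uses parametric Goodall's F with the ratios
#' `F_Ind = MS_Ind / MS_IndxSide`, `F_Side = MS_Side / MS_IndxSide`,
#' `F_IndxSide = MS_IndxSide / MS_ME1` (replicated designs only) and
#' `F_ME1 = MS_ME1 / MS_ME2`.
#'
#' @param fit a [gpa()] fit over all sides and replicates jointly.
#' @param trait `"shape"` (Procrustes coordinates) or `"size"` (centroid
#'   sizes, micrometers).
#' @param require_replicates if `TRUE`, error when the design has no
#'   imaging replicates and measurement-error strata were requested.
#' @return a `wing_anova` object: a data frame of effect rows with columns
#'   `effect`, `SS`, `df`, `pct_var`, `MS`, `F`, `p`, plus attributes
#'   `trait`, `design` and `shape_dim`.
#' @export
asymmetry_anova <- function(fit, trait = c("shape", "size"),
                            require_replicates = FALSE) {
  trait <- match.arg(trait)
  stopifnot(inherits(fit, "procrustes_fit"), !is.null(fit$info))
  design <- validate_rectangular(
    structure(list(coords = fit$aligned, info = fit$info),
              class = "landmark_set"))
  n <- design$n; r1 <- design$r1; r2 <- design$r2
  if (require_replicates && r1 < 2L)
    stop("measurement-error estimation requires imaging replicates ",
         "(r1 >= 2); this design has r1 = ", r1)
  if (require_replicates && r2 < 2L)
    stop("measurement-error estimation requires digitization replicates ",
         "(r2 >= 2); this design has r2 = ", r2)
  info <- fit$info
  Y <- if (trait == "shape") shape_matrix(fit) else
    matrix(fit$centroid_sizes, ncol = 1)
  mult <- if (trait == "shape") fit$shape_dim else 1L

  id <- info$individual_id
  side <- info$side
  img <- info$imaging_replicate
  grand <- colMeans(Y)
  Yc <- sweep(Y, 2, grand)

  mean_by <- function(key) {
    s <- rowsum(Yc, key)
    s / as.vector(table(key)[rownames(s)])
  }
  m_i <- mean_by(id)                                  # individual means
  m_s <- mean_by(side)                                # side means
  key_is <- paste(id, side, sep = "|")
  m_is <- mean_by(key_is)                             # cell means
  key_isj <- paste(id, side, img, sep = "|")
  m_isj <- mean_by(key_isj)                           # imaging-session means

  reps_cell <- r1 * r2
  ss_ind <- 2 * reps_cell * sum(m_i^2)
  ss_side <- n * reps_cell * sum(m_s^2)
  # interaction deviations: cell mean - individual mean - side mean
  dev_is <- m_is -
    m_i[sub("\\|.*$", "", rownames(m_is)), , drop = FALSE] -
    m_s[sub("^.*\\|", "", rownames(m_is)), , drop = FALSE]
  ss_int <- reps_cell * sum(dev_is^2)
  parts_isj <- strsplit(rownames(m_isj), "|", fixed = TRUE)
  cell_of_isj <- vapply(parts_isj, function(p) paste(p[1], p[2], sep = "|"), "")
  dev_isj <- m_isj - m_is[cell_of_isj, , drop = FALSE]
  ss_me1 <- r2 * sum(dev_isj^2)
  ss_me2 <- sum((Yc - m_isj[key_isj, , drop = FALSE])^2)

  effects <- c("individuals", "sides", "individuals_x_sides")
  ss <- c(ss_ind, ss_side, ss_int)
  df <- c(n - 1L, 1L, n - 1L)
  if (r1 > 1L) {
    effects <- c(effects, "ME1_imaging")
    ss <- c(ss, ss_me1)
    df <- c(df, 2L * n * (r1 - 1L))
  }
  if (r1 * r2 > 1L && r2 > 1L) {
    effects <- c(effects, "ME2_digitizing")
    ss <- c(ss, ss_me2)
    df <- c(df, 2L * n * r1 * (r2 - 1L))
  }
  df <- df * mult
  ms <- ss / df
  names(ms) <- effects

  F_ <- rep(NA_real_, length(effects))
  p <- rep(NA_real_, length(effects))
  names(F_) <- names(p) <- effects
  denom_int <- ms["individuals_x_sides"]
  F_["individuals"] <- ms["individuals"] / denom_int
  F_["sides"] <- ms["sides"] / denom_int
  p["individuals"] <- pf(F_["individuals"], df[1], df[3], lower.tail = FALSE)
  p["sides"] <- pf(F_["sides"], df[2], df[3], lower.tail = FALSE)
  if ("ME1_imaging" %in% effects) {
    F_["individuals_x_sides"] <- denom_int / ms["ME1_imaging"]
    p["individuals_x_sides"] <- pf(F_["individuals_x_sides"], df[3],
                                   df[effects == "ME1_imaging"],
                                   lower.tail = FALSE)
  }
  if (all(c("ME1_imaging", "ME2_digitizing") %in% effects)) {
    F_["ME1_imaging"] <- ms["ME1_imaging"] / ms["ME2_digitizing"]
    p["ME1_imaging"] <- pf(F_["ME1_imaging"],
                           df[effects == "ME1_imaging"],
                           df[effects == "ME2_digitizing"],
                           lower.tail = FALSE)
  }
  tab <- data.frame(effect = effects, SS = ss, df = as.integer(df),
                    pct_var = 100 * ss / sum(ss), MS = ms, F = F_, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(tab, class = c("wing_anova", "data.frame"), trait = trait,
            design = design,
            shape_dim = if (trait == "shape") fit$shape_dim else 1L)
}

#' @export
print.wing_anova <- function(x, ...) {
  cat("Asymmetry ANOVA (", attr(x, "trait"), "), n = ",
      attr(x, "design")$n, " individuals, replicates ",
      attr(x, "design")$r1, " x ", attr(x, "design")$r2, "\n", sep = "")
  print.data.frame(cbind(x[1], signif(x[-1], 6)), row.names = FALSE)
  invisible(x)
}

#' Fluctuating-asymmetry scores per individual
#'
#' Computes, per individual: the signed and absolute centroid-size
#' asymmetry (`CS_left - CS_right`, micrometers), the Procrustes FA score
#' (norm of the individual's left-minus-right shape vector after removing
#' the sample-wide directional asymmetry), and the Mahalanobis FA score
#' (same deviation measured in the metric of the sample covariance of the
#' asymmetry vectors, restricted to its non-null eigenspace).
#'
#' @param fit a [gpa()] fit (left wings mirrored before superimposition);
#'   replicates are averaged first.
#' @param rank_tol relative eigenvalue cutoff defining the retained
#'   eigenspace for the Mahalanobis metric.
#' @return a data frame with one row per individual (`individual_id`,
#'   `cs_left`, `cs_right`, `mean_cs`, `cs_fa_signed`, `cs_fa`,
#'   `procrustes_fa`, `mahalanobis_fa`) and attributes `da_vector` (the mean
#'   left-minus-right shape difference) and `retained_rank`.
#' @export
fa_scores <- function(fit, rank_tol = 1e-10) {
  im <- individual_means(fit)
  A <- im$asymmetry
  da <- colMeans(A)
  D <- sweep(A, 2, da)
  proc_fa <- sqrt(rowSums(D^2))
  n <- nrow(A); p <- ncol(A)
  S <- cov(A)
  ev <- eigen(S, symmetric = TRUE)
  keep <- ev$values > rank_tol * max(ev$values, 0)
  rank <- sum(keep)
  full_rank <- min(n - 1L, p - 4L)
  if (rank < p)
    warning("asymmetry covariance is rank-deficient (rank ", rank, " < ", p,
            "); Mahalanobis FA computed in the retained eigenspace")
  proj <- D %*% ev$vectors[, keep, drop = FALSE]
  mah_fa <- sqrt(rowSums(sweep(proj^2, 2, ev$values[keep], "/")))
  out <- data.frame(individual_id = im$individual_id,
                    cs_left = im$cs_left, cs_right = im$cs_right,
                    mean_cs = im$mean_cs,
                    cs_fa_signed = im$cs_left - im$cs_right,
                    cs_fa = abs(im$cs_left - im$cs_right),
                    procrustes_fa = proc_fa, mahalanobis_fa = mah_fa,
                    stringsAsFactors = FALSE)
  attr(out, "da_vector") <- da
  attr(out, "retained_rank") <- rank
  attr(out, "full_rank") <- full_rank
  out
}

#' Per-measurement FA scores for repeatability assessment
#'
#' Recomputes the FA scores once per replicate combination (matching
#' imaging and digitization replicates across sides), yielding the
#' individuals-by-measurements tables that [icc_2_1()] consumes.  The
#' directional-asymmetry vector and the Mahalanobis metric are estimated
#' from the replicate-averaged data so that all replicates of one
#' individual are scored against a common reference.
#'
#' @param fit a [gpa()] fit over a replicated, rectangular design.
#' @return a list of matrices (`cs_fa`, `cs_fa_signed`, `procrustes_fa`,
#'   `mahalanobis_fa`), each individuals x replicate-combinations.
#' @export
fa_scores_by_replicate <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"), !is.null(fit$info))
  design <- validate_rectangular(
    structure(list(coords = fit$aligned, info = fit$info),
              class = "landmark_set"))
  if (design$r1 * design$r2 < 2L)
    stop("repeatability needs at least two measurements per wing")
  base <- fa_scores(fit)
  da <- attr(base, "da_vector")
  im <- individual_means(fit)
  Sfull <- eigen(cov(im$asymmetry), symmetric = TRUE)
  keep <- Sfull$values > 1e-10 * max(Sfull$values, 0)
  X <- shape_matrix(fit)
  info <- fit$info
  ids <- sort(unique(info$individual_id))
  combos <- unique(info[, c("imaging_replicate", "digitization_replicate")])
  combos <- combos[order(combos$imaging_replicate,
                         combos$digitization_replicate), , drop = FALSE]
  m <- nrow(combos)
  mk <- function() matrix(NA_real_, length(ids), m,
                          dimnames = list(ids, paste0("m", seq_len(m))))
  out <- list(cs_fa = mk(), cs_fa_signed = mk(), procrustes_fa = mk(),
              mahalanobis_fa = mk())
  for (j in seq_len(m)) {
    sel <- info$imaging_replicate == combos$imaging_replicate[j] &
      info$digitization_replicate == combos$digitization_replicate[j]
    li <- match(paste(ids, "left"), paste(info$individual_id, info$side)[sel])
    ri <- match(paste(ids, "right"), paste(info$individual_id, info$side)[sel])
    Xs <- X[sel, , drop = FALSE]
    css <- fit$centroid_sizes[sel]
    a <- Xs[li, , drop = FALSE] - Xs[ri, , drop = FALSE]
    d <- sweep(a, 2, da)
    out$cs_fa_signed[, j] <- css[li] - css[ri]
    out$cs_fa[, j] <- abs(css[li] - css[ri])
    out$procrustes_fa[, j] <- sqrt(rowSums(d^2))
    proj <- d %*% Sfull$vectors[, keep, drop = FALSE]
    out$mahalanobis_fa[, j] <-
      sqrt(rowSums(sweep(proj^2, 2, Sfull$values[keep], "/")))
  }
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (the standard repeatability index for repeated measurements
#' of the same individuals by interchangeable sessions), with the F-based
#' 95% confidence interval.
#'
#' @param x an `n x k` matrix: n subjects, k >= 2 repeated measurements.
#' @param conf confidence level (default 0.95).
#' @return a list with `icc`, `ci95` (length-2 vector), and the mean
#'   squares (`ms_rows`, `ms_cols`, `ms_error`).  Negative estimates are
#'   returned as computed.
#' @export
icc_2_1 <- function(x, conf = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (k < 2L) stop("ICC(2,1) needs at least k = 2 repeated measurements")
  if (any(!is.finite(x))) stop("ICC table must be complete")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ms_r <- k * sum((row_m - grand)^2) / (n - 1)
  ms_c <- n * sum((col_m - grand)^2) / (k - 1)
  ss_e <- sum((x - outer(row_m, col_m, "+") + grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  # Shrout & Fleiss F-based interval
  alpha <- 1 - conf
  fj <- ms_c / ms_e
  vn <- (k - 1) * (n - 1) *
    ((k * icc * fj + n * (1 + (k - 1) * icc) - k * icc))^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  fo <- ms_r / ms_e
  lower <- n * (fo - f_l) / (f_l * (k * fj + k * n - k - n) + n * fo)
  upper <- n * (f_u * fo - 1) / (k * fj + k * n - k - n + n * f_u * fo)
  list(icc = icc, ci95 = c(lower = lower, upper = upper),
       ms_rows = ms_r, ms_cols = ms_c, ms_error = ms_e, n = n, k = k)
}
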