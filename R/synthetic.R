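#' Fixed 19-landmark forewing template
#'
#' A fixed, non-degenerate planar configuration of 19 landmarks with a
#' wing-like aspect ratio (about 3:1), centroid at the origin, standing in
#' for the vein-intersection landmarks of a worker honeybee forewing.  The
#' geometry is a package fixture: identical across calls, no three
#' consecutive landmarks collinear (so shape variation around it has full
#' rank), units arbitrary (the generator rescales to unit centroid size).
#'
#' @return a `19 x 2` matrix.
#' @export
wing_template <- function() {
  xy <- matrix(c(
    0.0, 1.4,   0.9, 2.0,   1.8, 2.4,   2.6, 1.9,   3.4, 2.5,
    4.2, 2.9,   5.1, 2.6,   5.9, 3.0,   6.8, 2.7,   7.7, 2.2,
    8.6, 1.6,   7.9, 1.0,   6.9, 0.7,   5.8, 0.5,   4.8, 0.9,
    3.9, 0.4,   2.9, 0.8,   1.9, 0.6,   1.0, 1.0), ncol = 2, byrow = TRUE)
  sweep(xy, 2, colMeans(xy))
}

# Orthonormal "shape directions" at the unit-size template: deterministic
# unit vectors (k x 2, flattened row-major) orthogonal to the translation,
# rotation and scaling directions (so they are genuine shape changes) and
# to each other.  Index 1 = ancestry cline, 2 = directional asymmetry,
# 3 = transgression.
.shape_directions <- function() {
  Tm <- wing_template()
  Tm <- Tm / sqrt(sum(Tm^2))
  k <- nrow(Tm)
  i <- seq_len(k)
  vec <- function(m) as.vector(t(m))
  null_dirs <- cbind(vec(cbind(rep(1, k), rep(0, k))),   # x translation
                     vec(cbind(rep(0, k), rep(1, k))),   # y translation
                     vec(Tm),                            # scaling
                     vec(cbind(-Tm[, 2], Tm[, 1])))      # rotation
  raw <- cbind(vec(cbind(sin(2 * pi * i / k), sin(4 * pi * i / k))),
               vec(cbind(cos(2 * pi * i / k), sin(6 * pi * i / k))),
               vec(cbind(sin(6 * pi * i / k), cos(4 * pi * i / k))))
  basis <- null_dirs
  out <- matrix(0, 2 * k, ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j]
    for (b in seq_len(ncol(basis)))
      v <- v - sum(v * basis[, b]) / sum(basis[, b]^2) * basis[, b]
    v <- v / sqrt(sum(v^2))
    out[, j] <- v
    basis <- cbind(basis, v)
  }
  colnames(out) <- c("cline", "da", "transgression")
  out
}

#' Generator parameters for synthetic admixed wing datasets
#'
#' Defaults describe a Mauritius-like admixed honeybee population: a
#' hybrid-index distribution with an African spike, a broad hybrid bulk and
#' a European spike; per-ancestry-class centroid-size distributions
#' (African 6453 +/- 145, hybrid 6560 +/- 176, European 6778 +/- 195
#' micrometers); a one-dimensional Afro-European shape cline; small
#' directional asymmetry; individual fluctuating asymmetry of size and
#' shape; and two nested measurement-error strata (re-imaging, which also
#' jitters the effective scale, and re-digitizing).
#'
#' @param n_individuals number of individuals.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param hi_weights mixture weights of the HI distribution components
#'   (African Beta(2,30) spike, Uniform(0.1,0.9) bulk, European Beta(30,2)
#'   spike).
#' @param cs_mean,cs_sd named numeric vectors (pure_african, hybrid,
#'   pure_european) of centroid-size means and sds in micrometers.
#' @param shape_cline_magnitude Procrustes-distance length of the shape
#'   cline over the full HI range 0 to 1.
#' @param within_individual_shape_sd isotropic per-coordinate sd of
#'   individual shape deviations (Procrustes units).
#' @param da_magnitude length of the directional-asymmetry shape vector
#'   (Procrustes units); `cs_da` its size analogue (micrometers).
#' @param fa_shape_sd per-coordinate sd of the individual fluctuating
#'   shape asymmetry (Procrustes units).
#' @param fa_size_sd sd of the individual signed left-minus-right centroid
#'   size difference (micrometers).
#' @param me1_sd,me2_sd per-coordinate imaging and digitization noise in
#'   micrometers; `me1_scale_sd` is the relative scale jitter per imaging
#'   session (slide remounting changes the effective magnification, which
#'   perturbs size but not shape).
#' @param transgression_magnitude hybrid-specific offset (Procrustes
#'   units) along a direction orthogonal to the cline, scaled by
#'   `4 HI (1 - HI)`; 0 (the default) simulates pure intermediacy.
#' @param n_loci,alleles_per_locus microsatellite panel layout.
#' @param fst_like separation of the ancestral allele-frequency profiles
#'   (0 = identical pools, 1 = fully distinct).
#' @param n_replicated number of individuals re-imaged and re-digitized;
#'   they receive the `r1 x r2` replicate grid, everyone else a single
#'   measurement per wing.
#' @param r1,r2 imaging and digitization replicate counts for the
#'   replicated subset.
#' @return a `generator_params` list.
#' @export
generator_params <- function(n_individuals = 283L, seed = 1L,
                             hi_weights = c(0.26, 0.62, 0.12),
                             cs_mean = c(pure_african = 6453, hybrid = 6560,
                                         pure_european = 6778),
                             cs_sd = c(pure_african = 145, hybrid = 176,
                                       pure_european = 195),
                             shape_cline_magnitude = 0.02,
                             within_individual_shape_sd = 0.0037,
                             da_magnitude = 0.003, cs_da = 0,
                             fa_shape_sd = 0.0021, fa_size_sd = 30,
                             me1_sd = 3, me2_sd = 2, me1_scale_sd = 1.5e-3,
                             transgression_magnitude = 0,
                             n_loci = 14L, alleles_per_locus = 4L,
                             fst_like = 0.75,
                             n_replicated = 36L, r1 = 2L, r2 = 2L) {
  p <- as.list(environment())
  stopifnot(p$n_individuals >= 1, length(p$hi_weights) == 3,
            all(p$hi_weights >= 0), all(p$cs_sd >= 0),
            p$within_individual_shape_sd >= 0, p$fa_shape_sd >= 0,
            p$fa_size_sd >= 0, p$me1_sd >= 0, p$me2_sd >= 0,
            p$shape_cline_magnitude >= 0, p$da_magnitude >= 0,
            p$n_loci >= 1, p$alleles_per_locus >= 2)
  if (p$n_replicated > 0 && (p$r1 < 2L || p$r2 < 2L))
    stop("measurement-error strata need r1 >= 2 and r2 >= 2 when ",
         "n_replicated > 0 (they are inestimable otherwise)")
  if (p$n_replicated > p$n_individuals)
    stop("n_replicated cannot exceed n_individuals")
  p$hi_weights <- p$hi_weights / sum(p$hi_weights)
  class(p) <- "generator_params"
  p
}

# Deterministic ancestral allele-frequency profiles for one locus.
# fst_like in [0,1] interpolates between a shared profile and two
# concentrated, opposed profiles; the dominant allele rotates with the
# locus index so loci are not exchangeable copies.
.ancestral_profiles <- function(n_alleles, locus, fst_like) {
  base <- (n_alleles:1)^1.5
  base <- base / sum(base)
  rot <- function(v, s) v[((seq_along(v) - 1 + s) %% length(v)) + 1]
  shared <- rot(base, locus %% n_alleles)
  pa <- (1 - fst_like) * shared + fst_like * rot(base, (locus + 1) %% n_alleles)
  pe <- (1 - fst_like) * shared + fst_like * rev(rot(base, locus %% n_alleles))
  list(p_A = pa / sum(pa), p_E = pe / sum(pe))
}

#' Simulate an admixed paired-wing population with known ground truth
#'
#' Draws, per individual: a hybrid index from the three-component mixture;
#' an ancestry class (HI thresholds 0.1/0.9); a mean centroid size from
#' that class's Normal; a true symmetric shape = unit template + HI x
#' cline + transgression x 4 HI (1-HI) + isotropic individual deviation;
#' a one-off developmental asymmetry (FA) and the population directional
#' asymmetry (DA), split half to each side (left +, right -); and a
#' 14-locus diploid genotype with alleles drawn from the HI-mixed
#' ancestral pools.  Every stored measurement then adds a per-imaging-
#' session scale jitter and coordinate noise (ME1) and per-digitization
#' noise (ME2), plus a random nuisance rotation and translation; left
#' wings are stored mirrored, as digitized.
#'
#' @param params a [generator_params] list.
#' @return an object of class `synthetic_dataset`: a list with `dataset`
#'   (a [wing_dataset]) and `ground_truth` (true HI, classes, sizes, FA
#'   draws, the planted cline/DA/transgression vectors and a parameter
#'   echo).
#' @export
simulate_population <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_individuals
  k <- WING_LANDMARKS
  Tm <- wing_template()
  Tm <- Tm / sqrt(sum(Tm^2))
  dirs <- .shape_directions()
  unvec <- function(v) matrix(v, ncol = 2, byrow = TRUE)
  cline <- unvec(dirs[, "cline"])
  da_dir <- unvec(dirs[, "da"])
  trans_dir <- unvec(dirs[, "transgression"])

  comp <- sample.int(3L, n, replace = TRUE, prob = p$hi_weights)
  hi <- numeric(n)
  hi[comp == 1L] <- rbeta(sum(comp == 1L), 2, 30)
  hi[comp == 2L] <- runif(sum(comp == 2L), 0.1, 0.9)
  hi[comp == 3L] <- rbeta(sum(comp == 3L), 30, 2)
  class <- classify_hybrid_index(hi)
  cs_true <- rnorm(n, p$cs_mean[as.character(class)],
                   p$cs_sd[as.character(class)])

  dev <- array(rnorm(k * 2 * n, 0, p$within_individual_shape_sd),
               dim = c(k, 2, n))
  fa_shape <- array(rnorm(k * 2 * n, 0, p$fa_shape_sd), dim = c(k, 2, n))
  fa_size <- rnorm(n, 0, p$fa_size_sd)
  da <- p$da_magnitude * da_dir

  ids <- sprintf("ind%04d", seq_len(n))
  reps <- data.frame(individual_id = ids,
                     r1 = ifelse(seq_len(n) <= p$n_replicated, p$r1, 1L),
                     r2 = ifelse(seq_len(n) <= p$n_replicated, p$r2, 1L))
  coords <- list(); info <- list(); idx <- 0L
  for (i in seq_len(n)) {
    shape_i <- Tm + hi[i] * p$shape_cline_magnitude * cline +
      p$transgression_magnitude * 4 * hi[i] * (1 - hi[i]) * trans_dir +
      dev[, , i]
    asym <- da + fa_shape[, , i]
    # exact unit centroid size per side so the drawn CS is the true size
    unit_cs <- function(m) {
      m <- sweep(m, 2, colMeans(m))
      m / sqrt(sum(m^2))
    }
    shape_side <- list(right = unit_cs(shape_i - asym / 2),
                       left = unit_cs(shape_i + asym / 2))
    cs_side <- c(right = cs_true[i] - (fa_size[i] + p$cs_da) / 2,
                 left = cs_true[i] + (fa_size[i] + p$cs_da) / 2)
    for (s in c("left", "right")) {
      for (j1 in seq_len(reps$r1[i])) {
        scale_jitter <- 1 + rnorm(1, 0, p$me1_scale_sd)
        e1 <- matrix(rnorm(2 * k, 0, p$me1_sd), k, 2)
        for (j2 in seq_len(reps$r2[i])) {
          e2 <- matrix(rnorm(2 * k, 0, p$me2_sd), k, 2)
          xy <- cs_side[s] * scale_jitter * shape_side[[s]] + e1 + e2
          th <- runif(1, -pi / 6, pi / 6)
          R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
          xy <- xy %*% R
          xy <- sweep(xy, 2, runif(2, -500, 500), "+")
          if (s == "left") xy[, 1] <- -xy[, 1]   # stored as digitized
          idx <- idx + 1L
          coords[[idx]] <- xy
          info[[idx]] <- data.frame(individual_id = ids[i], side = s,
                                    imaging_replicate = j1,
                                    digitization_replicate = j2,
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }
  landmarks <- landmark_set(coords, do.call(rbind, info), n_landmarks = k)

  mt <- ifelse(runif(n) < 1 - hi, "A", ifelse(runif(n) < 0.97, "C", "M"))
  geno <- matrix(0, n, p$n_loci * p$alleles_per_locus)
  cn <- character(0)
  for (l in seq_len(p$n_loci)) {
    prof <- .ancestral_profiles(p$alleles_per_locus, l, p$fst_like)
    cols <- (l - 1L) * p$alleles_per_locus + seq_len(p$alleles_per_locus)
    for (i in seq_len(n)) {
      pmix <- (1 - hi[i]) * prof$p_A + hi[i] * prof$p_E
      draw <- as.vector(stats::rmultinom(1, 2, pmix))
      geno[i, cols] <- draw / 2
    }
    cn <- c(cn, sprintf("L%02d.%d", l, seq_len(p$alleles_per_locus)))
  }
  colnames(geno) <- cn
  rownames(geno) <- ids
  individuals <- individual_table(ids, site = "SIM01", mt_lineage = mt,
                                  hybrid_index = hi)
  ds <- wing_dataset(landmarks, individuals, genotype_matrix(geno),
                     provenance = sprintf("simulate_population(seed = %d)",
                                          p$seed))
  structure(list(
    dataset = ds,
    ground_truth = list(hi = hi, class = class, cs_true = cs_true,
                        fa_size = fa_size, fa_shape = fa_shape,
                        da_vector = da, cline_vector = cline,
                        transgression_vector = trans_dir,
                        replicate_design = reps, params = p)),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  gt <- x$ground_truth
  cat("<synthetic_dataset> ", length(gt$hi), " individuals (",
      sum(gt$replicate_design$r1 > 1), " replicated), classes: ",
      paste(names(table(gt$class)), as.vector(table(gt$class)),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
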