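#' Per-site sampling summary of the Mauritius survey
#'
#' Published site-level counts for the 22 sampled Mauritian apiary sites:
#' maternal mtDNA lineage tallies (A / C / M), hybrid-index category tallies
#' (pure African, hybrid, pure European, missing) and the number of
#' morphologically characterized workers per site.
#'
#' @return a data frame with one row per site.
#' @export
mauritius_sites <- function() {
  utils::read.csv(system.file("extdata", "mauritius_sites.csv",
                              package = "wingmorph"),
                  stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]: either a `simulate`
#' block ([generator_params()]) or input paths, HI thresholds, permutation
#' settings and toggles.  Every stochastic step receives an explicit seed
#' derived from `seed` and recorded in the run manifest.
#'
#' @param simulate a [generator_params] object, or `NULL` when reading
#'   files.
#' @param landmarks_path,metadata_path input CSVs (used when `simulate` is
#'   `NULL`).
#' @param out_dir output directory (created if needed).
#' @param seed master integer seed.
#' @param hi_lower,hi_upper hybrid-index class thresholds.
#' @param n_perm permutations for PLS and regressions.
#' @param n_perm_pairwise permutations for the pairwise between-group mean
#'   distance tests.
#' @param tangent_projection,loo_space,signed_csfa analysis toggles: project
#'   to tangent space in the GPA; leave-one-out space (`"bg_subspace"` or
#'   `"full_shape"`); regress the signed instead of absolute CS asymmetry.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = generator_params(),
                            landmarks_path = NULL, metadata_path = NULL,
                            out_dir = tempfile("wingmorph_run_"),
                            seed = 1L, hi_lower = 0.1, hi_upper = 0.9,
                            n_perm = 10000L, n_perm_pairwise = 30000L,
                            tangent_projection = FALSE,
                            loo_space = c("bg_subspace", "full_shape"),
                            signed_csfa = FALSE) {
  loo_space <- match.arg(loo_space)
  cfg <- as.list(environment())
  if (is.null(simulate) && is.null(landmarks_path))
    stop("provide either a simulate block or landmark/metadata paths")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full wing-morphometrics analysis pipeline
#'
#' Orchestrates: data simulation or ingestion, mirroring of left wings and
#' joint generalized Procrustes superimposition, the replicated-design
#' measurement-error ANOVA and the full-sample asymmetry ANOVA (size and
#' shape), FA scores with ICC(2,1) repeatability, two-block PLS of size
#' and shape against microsatellite allele frequencies with PCAs and
#' PLS-PCA axis comparison, hybrid-index classification, group size ANOVA
#' with post-hocs, between-group PCA with leave-one-out classification and
#' permuted pairwise mean-shape tests, trajectory-angle analysis, and
#' linear-vs-quadratic FA regressions on HI.  Each stage writes a CSV/JSON
#' artifact to `config$out_dir`; a `run_manifest.json` echoes the
#' configuration and seeds.
#'
#' @param config a [pipeline_config].
#' @return invisibly, a named list with every stage result.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- list()
  stage <- "data"
  out <- function(...) file.path(config$out_dir, ...)
  wj <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                               digits = NA, na = "null")
  tryCatch({
    if (!is.null(config$simulate)) {
      sim <- simulate_population(config$simulate)
      ds <- sim$dataset
      res$ground_truth <- sim$ground_truth
    } else {
      ds <- read_long_csv(config$landmarks_path, config$metadata_path)
    }
    res$dataset <- ds

    stage <- "gpa"
    fit <- gpa(mirror_left(ds$landmarks),
               tangent_projection = config$tangent_projection)
    res$fit <- fit

    stage <- "asymmetry"
    info <- fit$info
    reps_per_wing <- table(paste(info$individual_id, info$side))
    replicated_ids <- unique(info$individual_id[
      paste(info$individual_id, info$side) %in%
        names(reps_per_wing)[reps_per_wing > 1]])
    write_anova <- function(a, path) {
      utils::write.csv(
        data.frame(Effect = a$effect, SS = a$SS, df = a$df,
                   pct_var = a$pct_var, MS = a$MS, F = a$F, P = a$p),
        path, row.names = FALSE)
    }
    if (length(replicated_ids) >= 2) {
      sub <- which(info$individual_id %in% replicated_ids)
      fit_rep <- gpa(mirror_left(ds$landmarks[sub]),
                     tangent_projection = config$tangent_projection)
      res$anova_me_size <- asymmetry_anova(fit_rep, "size",
                                           require_replicates = TRUE)
      res$anova_me_shape <- asymmetry_anova(fit_rep, "shape",
                                            require_replicates = TRUE)
      res$fa_replicated <- fa_scores_by_replicate(fit_rep)
      icc <- lapply(res$fa_replicated[c("cs_fa_signed", "procrustes_fa",
                                        "mahalanobis_fa")], icc_2_1)
      names(icc) <- c("cs_fa", "procrustes_fa", "mahalanobis_fa")
      res$icc <- icc
      wj(lapply(icc, function(z)
        list(icc = z$icc, ci95 = as.list(z$ci95), n = z$n, k = z$k)),
        out("icc.json"))
    }
    # full-sample ANOVA without replicates: replicate-average each wing
    sm <- side_means(fit)
    n_side <- nrow(sm$shapes)
    k_lm <- n_landmarks(ds$landmarks)
    fit_mean <- structure(list(
      aligned = array(apply(sm$shapes, 1,
                            function(v) matrix(v, ncol = 2, byrow = TRUE)),
                      dim = c(k_lm, 2, n_side)),
      centroid_sizes = sm$cs, consensus = fit$consensus,
      shape_dim = fit$shape_dim, n_iterations = fit$n_iterations,
      converged = fit$converged,
      info = data.frame(individual_id = sm$individual_id, side = sm$side,
                        imaging_replicate = 1L, digitization_replicate = 1L,
                        stringsAsFactors = FALSE)),
      class = "procrustes_fit")
    res$anova_size <- asymmetry_anova(fit_mean, "size")
    res$anova_shape <- asymmetry_anova(fit_mean, "shape")
    write_anova(res$anova_size, out("anova_size.csv"))
    write_anova(res$anova_shape, out("anova_shape.csv"))

    stage <- "fa_scores"
    fa <- fa_scores(fit)
    res$fa <- fa
    utils::write.csv(fa, out("fa_scores.csv"), row.names = FALSE)

    stage <- "pls"
    im <- individual_means(fit)
    md <- ds$individuals[match(im$individual_id, ds$individuals$individual_id), ]
    hi <- md$hybrid_index
    pls_summary <- function(p) list(
      singular_values = p$singular_values,
      pct_total_covariance = p$pct_total_covariance,
      axis_correlations = p$axis_correlations, rv = p$rv, p_rv = p$p_rv,
      p_singular_values = p$p_singular_values,
      p_correlations = p$p_correlations,
      n_permutations = p$n_permutations, seed = p$seed, n = p$n)
    if (!is.null(ds$genotypes)) {
      G <- ds$genotypes[im$individual_id, , drop = FALSE]
      res$pls_size <- two_block_pls(matrix(im$mean_cs, ncol = 1), G,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 1L)
      res$pls_shape <- two_block_pls(im$mean_shapes, G,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 2L)
      wj(pls_summary(res$pls_size), out("pls_size.json"))
      wj(pls_summary(res$pls_shape), out("pls_shape.json"))
      res$pca_shape <- pca(im$mean_shapes)
      res$pca_geno <- pca(G)
      res$axis_match <- list(
        shape = compare_axes(res$pls_shape$x_loadings[, 1],
                             res$pca_shape$axes[, 1],
                             res$pls_shape$x_scores[, 1],
                             res$pca_shape$scores[, 1]),
        genetic = compare_axes(res$pls_shape$y_loadings[, 1],
                               res$pca_geno$axes[, 1],
                               res$pls_shape$y_scores[, 1],
                               res$pca_geno$scores[, 1]))
      wj(list(shape_pc = list(pct_variance = res$pca_shape$pct_variance),
              genetic_pc = list(pct_variance = res$pca_geno$pct_variance),
              pls_vs_pca = res$axis_match),
         out("pca.json"))
    }

    stage <- "groups"
    classes <- classify_hybrid_index(hi, config$hi_lower, config$hi_upper)
    res$classes <- classes
    res$size_groups <- size_group_anova(im$mean_cs, classes)
    utils::write.csv(res$size_groups$group_stats, out("groups.csv"),
                     row.names = FALSE)

    stage <- "bgpca"
    keep <- !is.na(classes)
    res$bgpca <- between_group_pca(im$mean_shapes[keep, , drop = FALSE],
                                   classes[keep])
    res$loo <- loo_classification(im$mean_shapes[keep, , drop = FALSE],
                                  classes[keep], space = config$loo_space)
    set.seed(config$seed + 3L)
    res$pairwise <- pairwise_mean_distance_test(
      im$mean_shapes[keep, , drop = FALSE], classes[keep],
      n_perm = config$n_perm_pairwise)
    wj(list(pct_between_variance = res$bgpca$pct_between_variance,
            eigenvalues = res$bgpca$eigenvalues,
            correct_rates = as.list(res$loo$correct_rates),
            overall_correct_rate = res$loo$overall_correct_rate,
            pairwise = res$pairwise), out("bgpca.json"))
    cm <- as.data.frame.matrix(res$loo$confusion)
    cm <- cbind(cluster = rownames(cm), cm,
                correct_pct = 100 * res$loo$correct_rates)
    utils::write.csv(cm, out("confusion.csv"), row.names = FALSE)

    stage <- "trajectory"
    res$trajectory <- trajectory_angle(im$mean_shapes[keep, , drop = FALSE],
                                       classes[keep],
                                       n_perm = config$n_perm,
                                       seed = config$seed + 4L,
                                       n_perm_distance = config$n_perm_pairwise)
    wj(list(angle_deg = res$trajectory$angle_deg,
            p_angle = res$trajectory$p_angle,
            magnitudes = res$trajectory$magnitudes), out("trajectory.json"))

    stage <- "hi_correlations"
    bg1 <- rep(NA_real_, length(im$individual_id))
    bg1[keep] <- res$bgpca$scores[, 1]
    res$hi_cor <- hi_correlations(
      c(list(mean_cs = im$mean_cs, bgPC1 = bg1),
        if (!is.null(res$pls_shape))
          list(shape_pls1 = res$pls_shape$x_scores[, 1],
               genetic_pls1 = res$pls_shape$y_scores[, 1])), hi)

    stage <- "fa_regressions"
    fa_hi <- hi[match(fa$individual_id, im$individual_id)]
    csfa <- if (config$signed_csfa) fa$cs_fa_signed else fa$cs_fa
    res$reg_csfa <- fa_vs_predictor(csfa, fa_hi, n_perm = config$n_perm,
                                    seed = config$seed + 5L)
    proc_corr <- size_correct_fa(fa$procrustes_fa, fa$mean_cs)
    res$reg_shape_fa <- fa_vs_predictor(proc_corr, fa_hi,
                                        n_perm = config$n_perm,
                                        seed = config$seed + 6L)
    reg_summary <- function(r) list(
      linear = r$linear[c("coefficients", "r_squared", "slope_p", "rss",
                          "aic", "aicc", "bic")],
      quadratic = r$quadratic[c("coefficients", "r_squared", "slope_p",
                                "rss", "aic", "aicc", "bic")],
      perm_slope_p = r$perm_slope_p, selected_model = r$selected_model)
    wj(list(cs_fa = reg_summary(res$reg_csfa),
            size_corrected_procrustes_fa = reg_summary(res$reg_shape_fa)),
       out("regressions.json"))

    stage <- "manifest"
    cfg_echo <- config
    cfg_echo$simulate <- if (!is.null(config$simulate))
      unclass(config$simulate) else NULL
    wj(list(config = unclass(cfg_echo),
            seeds = config$seed + 0:6,
            package_version = as.character(utils::packageVersion("wingmorph")),
            r_version = R.version.string,
            wall_clock_sec = as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))),
       out("run_manifest.json"))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
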