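#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances between each landmark and
#' the centroid (barycenter) of the configuration — the standard
#' landmark-based size measure, homogeneous of degree one in the
#' coordinates.
#'
#' @param x a `k x 2` coordinate matrix (micrometers), or a `k x 2 x n`
#'   array / [landmark_set] for which per-configuration sizes are returned.
#' @return centroid size(s), in the units of the coordinates.
#' @export
centroid_size <- function(x) {
  if (inherits(x, "landmark_set")) x <- x$coords
  if (is.array(x) && length(dim(x)) == 3L)
    return(apply(x, 3, centroid_size))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 landmarks")
  cs <- sqrt(sum(scale(x, scale = FALSE)^2))
  if (cs == 0)
    warning("degenerate configuration: all landmarks coincide (CS = 0)")
  cs
}

#' Mirror left-side configurations
#'
#' Reflects left wings about the y-axis (x negated) so that left and right
#' configurations can be superimposed jointly (matching symmetry).  Centroid
#' size is unchanged (reflection is an isometry) and applying the reflection
#' twice restores the original coordinates.
#'
#' @param landmarks a [landmark_set].  All configurations with
#'   `side == "left"` and `mirrored == FALSE` are reflected and flagged.
#' @param strict if `TRUE`, error when the set contains a right-side
#'   configuration (use when mirroring a purported single left wing).
#' @return the landmark set with lefts mirrored.
#' @export
mirror_left <- function(landmarks, strict = FALSE) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (strict && any(landmarks$info$side == "right"))
    stop("mirror_left applied to a right-side configuration")
  todo <- which(landmarks$info$side == "left" & !landmarks$info$mirrored)
  if (length(todo)) {
    landmarks$coords[, 1, todo] <- -landmarks$coords[, 1, todo]
    landmarks$info$mirrored[todo] <- TRUE
  }
  landmarks
}

# Optimal rotation (det = +1) aligning X onto target C, both centered.
# Returns the 2x2 rotation matrix R such that X %*% R best matches C.
.opt_rotation <- function(X, C) {
  s <- svd(crossprod(X, C))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes superimposition
#'
#' Implements the three-step generalized least-squares fit: (1) every
#' configuration is centered on its centroid, (2) scaled to unit centroid
#' size (removing isometric size), and (3) iteratively rotated to minimize
#' the summed squared distances to the sample consensus, which is recomputed
#' as the arithmetic mean after each sweep and rescaled to unit size.  Left
#' wings must be mirrored beforehand ([mirror_left()]); the fit is joint
#' over all sides and replicates.  The algorithm is deterministic and
#' involves no randomness; the reported orientation is that of the mean of
#' the input configurations.
#'
#' @param landmarks a [landmark_set] (unmirrored left wings trigger an
#'   error) or a `k x 2 x n` array.
#' @param tol convergence tolerance on the relative decrease of the
#'   objective (summed squared distances to the consensus).
#' @param max_iter maximum number of rotation sweeps.
#' @param tangent_projection if `TRUE`, orthogonally project the aligned
#'   configurations onto the tangent space at the consensus.  Off by
#'   default: at within-species wing-variation scales (Procrustes radii of
#'   order 1e-2) the projection perturbs coordinates by only about the
#'   squared radius and leaves relative shape distances essentially
#'   unchanged; the flag exists for sensitivity checks.
#' @return an object of class `procrustes_fit` with elements `aligned`
#'   (`k x 2 x n`, dimensionless Procrustes coordinates), `centroid_sizes`
#'   (pre-scaling, micrometers), `consensus`, `n_iterations`, `converged`,
#'   `shape_dim` (`2k - 4`) and the provenance `info` table.
#' @export
gpa <- function(landmarks, tol = 1e-10, max_iter = 100L,
                tangent_projection = FALSE) {
  if (inherits(landmarks, "landmark_set")) {
    if (any(landmarks$info$side == "left" & !landmarks$info$mirrored))
      stop("left configurations must be mirrored (mirror_left) before GPA")
    info <- landmarks$info
    A <- landmarks$coords
  } else {
    A <- landmarks
    info <- NULL
  }
  stopifnot(length(dim(A)) == 3L, dim(A)[2] == 2L)
  k <- dim(A)[1]; n <- dim(A)[3]
  cs <- numeric(n)
  for (i in seq_len(n)) {
    x <- scale(A[, , i], scale = FALSE)           # (1) center
    cs[i] <- sqrt(sum(x^2))
    if (cs[i] == 0) stop("configuration ", i, " is degenerate (CS = 0)")
    A[, , i] <- x / cs[i]                          # (2) unit centroid size
  }
  # initial consensus: plain mean of the centered, scaled configurations
  # (order-independent, and a fixed point when the input is already
  # aligned); fall back to the first configuration if raw orientations
  # nearly cancel
  consensus <- apply(A, c(1, 2), mean)
  if (sqrt(sum(consensus^2)) < 0.1) consensus <- A[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  objective <- Inf
  trajectory <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n))                          # (3) rotate to consensus
      A[, , i] <- A[, , i] %*% .opt_rotation(A[, , i], consensus)
    consensus <- apply(A, c(1, 2), mean)
    consensus <- consensus / sqrt(sum(consensus^2))
    obj <- sum(sweep(A, c(1, 2), consensus)^2)
    trajectory <- c(trajectory, obj)
    if (is.finite(objective) && obj > objective + 1e-12)
      stop("GPA objective increased; this should not happen")
    if (is.finite(objective) && (objective - obj) <= tol * max(objective, 1e-300)) {
      converged <- TRUE
      break
    }
    objective <- obj
  }
  if (!converged && n > 1L)
    stop("GPA did not converge after ", max_iter,
         " iterations; objective trajectory: ",
         paste(signif(utils::head(trajectory, 20), 8), collapse = ", "))
  if (n == 1L) converged <- TRUE
  if (tangent_projection) {
    cvec <- as.vector(consensus)
    for (i in seq_len(n)) {
      v <- as.vector(A[, , i])
      A[, , i] <- A[, , i] - (sum(v * cvec) - 1) * consensus
    }
  }
  structure(list(aligned = A, centroid_sizes = cs, consensus = consensus,
                 n_iterations = iter, converged = converged,
                 shape_dim = 2L * k - 4L, objective = obj,
                 objective_trajectory = trajectory, info = info),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> ", dim(x$aligned)[3], " configurations, ",
      dim(x$aligned)[1], " landmarks, shape dim ", x$shape_dim,
      ", ", x$n_iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two superimposed shapes
#'
#' Square root of the summed squared coordinate differences between two
#' configurations aligned in a common fit; dimensionless.
#'
#' @param a,b `k x 2` matrices (or vectors of equal length).
#' @return a non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("configurations have mismatched landmark counts")
  sqrt(sum((a - b)^2))
}

# Flatten aligned configurations to an n x 2k matrix (x1,y1,x2,y2,...).
shape_matrix <- function(fit) {
  A <- fit$aligned
  t(apply(A, 3, function(m) as.vector(t(m))))
}

#' Per-individual, per-side mean shapes and sizes
#'
#' Averages Procrustes coordinates and centroid sizes over imaging and
#' digitization replicates within each individual-by-side cell.
#'
#' @param fit a [gpa()] fit carrying an `info` table.
#' @return a list with `shapes` (matrix, rows `individual|side`), `cs`,
#'   and the `individual_id` / `side` index vectors.
#' @export
side_means <- function(fit) {
  stopifnot(inherits(fit, "procrustes_fit"), !is.null(fit$info))
  X <- shape_matrix(fit)
  key <- paste(fit$info$individual_id, fit$info$side, sep = "|")
  sums <- rowsum(X, key)                       # sorted by key
  counts <- table(key)[rownames(sums)]
  shapes <- sums / as.vector(counts)
  cs <- tapply(fit$centroid_sizes, key, mean)[rownames(shapes)]
  parts <- strsplit(rownames(shapes), "|", fixed = TRUE)
  list(shapes = shapes, cs = as.numeric(cs),
       individual_id = vapply(parts, `[`, "", 1),
       side = vapply(parts, `[`, "", 2))
}

#' Per-individual left/right means and asymmetry vectors
#'
#' For each individual with both sides present, returns the left-right mean
#' shape (the symmetric component used by covariation and group analyses),
#' the asymmetry vector (left minus right, after superimposition with the
#' left mirrored), and the mean centroid sizes per side.
#'
#' @param fit a [gpa()] fit with provenance.
#' @return a list with `individual_id`, `mean_shapes`, `asymmetry`
#'   (matrices), `cs_left`, `cs_right`, `mean_cs`.
#' @export
individual_means <- function(fit) {
  sm <- side_means(fit)
  ids <- unique(sm$individual_id)
  keep <- ids[vapply(ids, function(id)
    all(sides_ok %in% sm$side[sm$individual_id == id]), logical(1))]
  if (!length(keep)) stop("no individual has both sides present")
  li <- match(paste(keep, "left"), paste(sm$individual_id, sm$side))
  ri <- match(paste(keep, "right"), paste(sm$individual_id, sm$side))
  list(individual_id = keep,
       mean_shapes = (sm$shapes[li, , drop = FALSE] +
                      sm$shapes[ri, , drop = FALSE]) / 2,
       asymmetry = sm$shapes[li, , drop = FALSE] - sm$shapes[ri, , drop = FALSE],
       cs_left = sm$cs[li], cs_right = sm$cs[ri],
       mean_cs = (sm$cs[li] + sm$cs[ri]) / 2)
}
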