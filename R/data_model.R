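#' Landmark configuration set
#'
#' Container for a collection of 2-D landmark configurations with side and
#' replicate provenance.  Coordinates are stored in physical units
#' (micrometers); any pixel-to-micrometer scale factor is applied by the
#' readers before construction.
#'
#' @param coords a `k x 2 x n` numeric array of landmark coordinates (k
#'   landmarks, n configurations), or a list of `k x 2` matrices.
#' @param info a data frame with one row per configuration and columns
#'   `individual_id` (character), `side` (`"left"` or `"right"`),
#'   `imaging_replicate` (integer >= 1), `digitization_replicate`
#'   (integer >= 1).  An optional logical column `mirrored` records whether a
#'   left configuration has already been reflected; it defaults to `FALSE`.
#' @param n_landmarks expected landmark count; the default `NULL` accepts any
#'   common count, while dataset-level code passes 19.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, info, n_landmarks = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    k <- unique(vapply(coords, nrow, integer(1)))
    if (length(k) != 1L)
      stop("all configurations must have the same number of landmarks; found counts: ",
           paste(sort(k), collapse = ", "))
    coords <- array(unlist(lapply(coords, function(m) as.matrix(m))),
                    dim = c(k, 2L, length(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 2L)
    stop("'coords' must be a k x 2 x n array of 2-D landmarks")
  if (!is.null(n_landmarks) && dim(coords)[1] != n_landmarks)
    stop("expected ", n_landmarks, " landmarks per configuration, got ",
         dim(coords)[1])
  if (!all(is.finite(coords)))
    stop("landmark coordinates must all be finite")
  info <- as.data.frame(info)
  required <- c("individual_id", "side", "imaging_replicate",
                "digitization_replicate")
  missing_cols <- setdiff(required, names(info))
  if (length(missing_cols))
    stop("'info' is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(info) != dim(coords)[3])
    stop("'info' rows (", nrow(info), ") must match the number of configurations (",
         dim(coords)[3], ")")
  if (!all(info$side %in% sides_ok))
    stop("'side' must be 'left' or 'right'")
  if (any(info$imaging_replicate < 1L) || any(info$digitization_replicate < 1L))
    stop("replicate indices must be >= 1")
  info$individual_id <- as.character(info$individual_id)
  info$imaging_replicate <- as.integer(info$imaging_replicate)
  info$digitization_replicate <- as.integer(info$digitization_replicate)
  if (is.null(info$mirrored)) info$mirrored <- FALSE
  structure(list(coords = coords, info = info), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", dim(x$coords)[3], " configurations, ",
      dim(x$coords)[1], " landmarks, ",
      length(unique(x$info$individual_id)), " individuals\n", sep = "")
  invisible(x)
}

#' @export
length.landmark_set <- function(x) dim(x$coords)[3]

#' Subset a landmark set by configuration index
#' @param x a `landmark_set`
#' @param i integer or logical index over configurations
#' @param ... unused
#' @export
`[.landmark_set` <- function(x, i, ...) {
  landmark_set(x$coords[, , i, drop = FALSE], x$info[i, , drop = FALSE])
}

n_landmarks <- function(x) dim(x$coords)[1]

#' Individual metadata table
#'
#' Validates per-individual metadata: site code, maternal mtDNA lineage and
#' hybrid index (admixture proportion, 0 = African, 1 = European ancestry).
#' Missing hybrid indices are allowed; such individuals are excluded from
#' HI-dependent analyses but retained elsewhere.
#'
#' @param individual_id character vector of unique identifiers.
#' @param site site codes (e.g. `"MUS01"`).
#' @param mt_lineage maternal lineage, one of `"A"`, `"C"`, `"M"` or `NA`.
#' @param hybrid_index numeric in `[0, 1]` or `NA`.
#' @return a validated data frame.
#' @export
individual_table <- function(individual_id, site = NA_character_,
                             mt_lineage = NA_character_,
                             hybrid_index = NA_real_) {
  individual_id <- as.character(individual_id)
  if (anyDuplicated(individual_id))
    stop("duplicated individual_id: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  df <- data.frame(individual_id = individual_id,
                   site = as.character(site),
                   mt_lineage = as.character(mt_lineage),
                   hybrid_index = as.numeric(hybrid_index),
                   stringsAsFactors = FALSE)
  bad_mt <- !is.na(df$mt_lineage) & !df$mt_lineage %in% c("A", "C", "M")
  if (any(bad_mt))
    stop("mt_lineage must be 'A', 'C', 'M' or missing")
  hi <- df$hybrid_index
  if (any(!is.na(hi) & (hi < 0 | hi > 1)))
    stop("hybrid_index must lie in [0, 1] (or be missing)")
  df
}

#' Genotype matrix of within-individual allele frequencies
#'
#' Rows are individuals, columns are alleles grouped by locus.  For a diploid
#' individual each entry is 0, 0.5 or 1 (number of copies / 2), and within
#' each locus the entries sum to 1.
#'
#' @param mat numeric matrix (individuals x alleles) with row names set to
#'   individual ids.
#' @param loci character or factor of length `ncol(mat)` assigning each
#'   allele column to its locus.  Defaults to the part of each column name
#'   before the last `"."`.
#' @param tol tolerance on the per-locus sum-to-one check.
#' @return the matrix with a `loci` attribute, validated.
#' @export
genotype_matrix <- function(mat, loci = NULL, tol = 1e-8) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    stop("genotype matrix must have individual ids as row names")
  if (is.null(loci)) {
    if (is.null(colnames(mat)))
      stop("provide 'loci' or name the allele columns '<locus>.<allele>'")
    loci <- sub("\\.[^.]*$", "", colnames(mat))
  }
  if (length(loci) != ncol(mat))
    stop("'loci' must have one entry per allele column")
  ok_vals <- is.na(mat) | abs(mat) < tol | abs(mat - 0.5) < tol | abs(mat - 1) < tol
  if (!all(ok_vals))
    stop("genotype entries must be 0, 0.5 or 1 (diploid allele frequencies)")
  for (loc in unique(loci)) {
    s <- rowSums(mat[, loci == loc, drop = FALSE])
    bad <- which(!is.na(s) & abs(s - 1) > tol)
    if (length(bad))
      stop("allele frequencies at locus '", loc, "' do not sum to 1 for: ",
           paste(rownames(mat)[utils::head(bad, 5)], collapse = ", "))
  }
  attr(mat, "loci") <- as.character(loci)
  mat
}

#' Assemble a wing dataset
#'
#' Bundles a landmark set with individual metadata and (optionally) a
#' genotype matrix, checking referential integrity: every configuration's
#' individual must resolve to exactly one metadata row.
#'
#' @param landmarks a [landmark_set].
#' @param individuals a data frame from [individual_table()].
#' @param genotypes optional matrix from [genotype_matrix()]; row names must
#'   cover all individuals.
#' @param provenance free-text provenance string.
#' @return an object of class `wing_dataset`.
#' @export
wing_dataset <- function(landmarks, individuals, genotypes = NULL,
                         provenance = "") {
  stopifnot(inherits(landmarks, "landmark_set"))
  individuals <- as.data.frame(individuals)
  unresolved <- setdiff(unique(landmarks$info$individual_id),
                        individuals$individual_id)
  if (length(unresolved))
    stop("configurations reference unknown individual ids: ",
         paste(utils::head(unresolved, 10), collapse = ", "))
  if (!is.null(genotypes)) {
    missing_g <- setdiff(individuals$individual_id, rownames(genotypes))
    if (length(missing_g))
      stop("genotype matrix lacks rows for: ",
           paste(utils::head(missing_g, 10), collapse = ", "))
    loci <- attr(genotypes, "loci")
    genotypes <- genotypes[individuals$individual_id, , drop = FALSE]
    attr(genotypes, "loci") <- loci
  }
  structure(list(landmarks = landmarks, individuals = individuals,
                 genotypes = genotypes, provenance = provenance),
            class = "wing_dataset")
}

#' @export
print.wing_dataset <- function(x, ...) {
  cat("<wing_dataset> ", nrow(x$individuals), " individuals, ",
      length(x$landmarks), " configurations",
      if (!is.null(x$genotypes))
        paste0(", ", length(unique(attr(x$genotypes, "loci"))), " loci"),
      "\n", sep = "")
  invisible(x)
}

#' Check that a landmark set forms a rectangular replicate design
#'
#' Every individual must contribute both sides, and every individual-by-side
#' cell must hold the same `r1 x r2` grid of imaging and digitization
#' replicates.  Required before the asymmetry ANOVA.
#'
#' @param landmarks a [landmark_set].
#' @return invisibly, a list with `n`, `r1`, `r2`.
#' @export
validate_rectangular <- function(landmarks) {
  info <- landmarks$info
  ids <- unique(info$individual_id)
  r1 <- sort(unique(info$imaging_replicate))
  r2 <- sort(unique(info$digitization_replicate))
  expected <- nrow(expand.grid(r1, r2)) # per side
  for (id in ids) {
    for (s in sides_ok) {
      cell <- info[info$individual_id == id & info$side == s, , drop = FALSE]
      key <- paste(cell$imaging_replicate, cell$digitization_replicate)
      full <- paste(rep(r1, times = length(r2)), rep(r2, each = length(r1)))
      if (nrow(cell) != expected || !setequal(key, full) || anyDuplicated(key))
        stop("non-rectangular replicate design at individual '", id,
             "', side '", s, "': expected ", length(r1), " x ", length(r2),
             " replicates, found ", nrow(cell))
    }
  }
  invisible(list(n = length(ids), r1 = length(r1), r2 = length(r2)))
}
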