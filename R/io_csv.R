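#' Read a long-format landmark CSV (plus optional metadata) into a dataset
#'
#' The landmark table has one row per digitized landmark with columns
#' `individual_id`, `side`, `imaging_replicate`, `digitization_replicate`,
#' `landmark_index` (1-based), `x`, `y` (micrometers).  `landmark_index` is
#' authoritative: rows may appear in any order and are never silently
#' reordered beyond sorting by that index.  The optional companion metadata
#' table carries `individual_id`, `site`, `mt_lineage`, `hybrid_index` and
#' allele-frequency columns named `<locus>.<allele>`.
#'
#' @param landmarks_path path to the long-format landmark CSV.
#' @param metadata_path optional path to the metadata CSV.
#' @param n_landmarks required landmark count (default 19).
#' @return a [wing_dataset] (with placeholder metadata when
#'   `metadata_path` is `NULL`).
#' @export
read_long_csv <- function(landmarks_path, metadata_path = NULL,
                          n_landmarks = WING_LANDMARKS) {
  lm <- utils::read.csv(landmarks_path, stringsAsFactors = FALSE)
  required <- c("individual_id", "side", "imaging_replicate",
                "digitization_replicate", "landmark_index", "x", "y")
  missing_cols <- setdiff(required, names(lm))
  if (length(missing_cols))
    stop("landmark CSV is missing columns: ",
         paste(missing_cols, collapse = ", "))
  key <- with(lm, paste(individual_id, side, imaging_replicate,
                        digitization_replicate, landmark_index, sep = "\r"))
  if (anyDuplicated(key)) {
    d <- lm[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate landmark rows, e.g. individual '", d$individual_id,
         "' side '", d$side, "' replicates ", d$imaging_replicate, "/",
         d$digitization_replicate, " landmark ", d$landmark_index)
  }
  cfg_key <- with(lm, paste(individual_id, side, imaging_replicate,
                            digitization_replicate, sep = "\r"))
  cfg_levels <- unique(cfg_key)
  coords <- vector("list", length(cfg_levels))
  info <- vector("list", length(cfg_levels))
  for (i in seq_along(cfg_levels)) {
    rows <- lm[cfg_key == cfg_levels[i], , drop = FALSE]
    rows <- rows[order(rows$landmark_index), , drop = FALSE]
    if (!identical(as.integer(rows$landmark_index), seq_len(n_landmarks)))
      stop("individual '", rows$individual_id[1], "' side '", rows$side[1],
           "' replicates ", rows$imaging_replicate[1], "/",
           rows$digitization_replicate[1], ": landmark_index must be exactly 1..",
           n_landmarks)
    coords[[i]] <- cbind(rows$x, rows$y)
    info[[i]] <- rows[1, c("individual_id", "side", "imaging_replicate",
                           "digitization_replicate"), drop = FALSE]
  }
  landmarks <- landmark_set(coords, do.call(rbind, info),
                            n_landmarks = n_landmarks)
  if (is.null(metadata_path)) {
    ids <- unique(landmarks$info$individual_id)
    return(wing_dataset(landmarks, individual_table(ids),
                        provenance = paste0("read_long_csv: ", landmarks_path)))
  }
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  base_cols <- c("individual_id", "site", "mt_lineage", "hybrid_index")
  missing_md <- setdiff(base_cols, names(md))
  if (length(missing_md))
    stop("metadata CSV is missing columns: ",
         paste(missing_md, collapse = ", "))
  individuals <- individual_table(md$individual_id, md$site, md$mt_lineage,
                                  md$hybrid_index)
  allele_cols <- setdiff(names(md), base_cols)
  genotypes <- NULL
  if (length(allele_cols)) {
    g <- as.matrix(md[, allele_cols, drop = FALSE])
    rownames(g) <- md$individual_id
    genotypes <- genotype_matrix(g)
  }
  wing_dataset(landmarks, individuals, genotypes,
               provenance = paste0("read_long_csv: ", landmarks_path, " + ",
                                   metadata_path))
}

#' Write a wing dataset as long-format landmark + metadata CSVs
#'
#' Emits exactly the dialect [read_long_csv()] accepts.
#'
#' @param dataset a [wing_dataset].
#' @param landmarks_path output path for the landmark table.
#' @param metadata_path optional output path for the metadata table
#'   (individuals + allele-frequency columns).
#' @return `landmarks_path`, invisibly.
#' @export
write_long_csv <- function(dataset, landmarks_path, metadata_path = NULL) {
  stopifnot(inherits(dataset, "wing_dataset"))
  ls <- dataset$landmarks
  k <- n_landmarks(ls)
  nconf <- length(ls)
  info <- ls$info
  out <- data.frame(
    individual_id = rep(info$individual_id, each = k),
    side = rep(info$side, each = k),
    imaging_replicate = rep(info$imaging_replicate, each = k),
    digitization_replicate = rep(info$digitization_replicate, each = k),
    landmark_index = rep(seq_len(k), times = nconf),
    x = as.vector(ls$coords[, 1, ]),
    y = as.vector(ls$coords[, 2, ]))
  utils::write.csv(out, landmarks_path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    md <- dataset$individuals[, c("individual_id", "site", "mt_lineage",
                                  "hybrid_index")]
    if (!is.null(dataset$genotypes)) {
      g <- dataset$genotypes[md$individual_id, , drop = FALSE]
      md <- cbind(md, as.data.frame(g, check.names = FALSE))
    }
    utils::write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  }
  invisible(landmarks_path)
}
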