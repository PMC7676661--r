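#' Read landmark configurations from a TPS file
#'
#' Parses `LM=` blocks of 2-D coordinates with optional `SCALE=` lines and an
#' `ID=` (or `IMAGE=`) identifier per block.  Identifiers follow the naming
#' convention `individual_side_imagingrep_digitizationrep`, e.g.
#' `bee007_left_1_2`; the individual id itself may contain underscores, the
#' last three fields are authoritative.  Coordinates are multiplied by the
#' scale factor so the returned configurations are in micrometers.
#'
#' @param path path to a TPS file.
#' @param n_landmarks required landmark count per block (default 19).
#' @param require_scale if `TRUE` (default) a block without a `SCALE=` line
#'   is an error: physical units were requested and no silent fallback to
#'   1.0 is made.  Set to `FALSE` for data already in physical units, in
#'   which case a missing scale means 1.0.
#' @return a [landmark_set] in file order.
#' @export
read_tps <- function(path, n_landmarks = WING_LANDMARKS, require_scale = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (!length(starts)) stop("no LM= blocks found in '", path, "'")
  ends <- c(starts[-1] - 1L, length(lines))
  coords <- vector("list", length(starts))
  info <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    lm <- as.integer(sub("^LM\\s*=\\s*", "", block[1]))
    if (is.na(lm) || lm != n_landmarks)
      stop("TPS block ", b, " (starting line ", starts[b], ") has LM=", lm,
           "; expected ", n_landmarks, " landmarks")
    coord_lines <- block[2:(1 + lm)]
    xy <- t(vapply(strsplit(coord_lines, "\\s+"),
                   function(f) as.numeric(f[1:2]), numeric(2)))
    if (!all(is.finite(xy)))
      stop("non-numeric coordinates in TPS block ", b)
    keyed <- block[-(1:(1 + lm))]
    get_field <- function(key) {
      hit <- grep(paste0("^", key, "\\s*="), keyed, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "\\s*=\\s*"), "", hit[1]) else NA_character_
    }
    id_str <- get_field("ID")
    if (is.na(id_str)) id_str <- get_field("IMAGE")
    if (is.na(id_str))
      stop("TPS block ", b, " has neither ID= nor IMAGE= identifier")
    scale_str <- get_field("SCALE")
    if (is.na(scale_str)) {
      if (require_scale)
        stop("TPS block ", b, " ('", id_str, "') has no SCALE= line but ",
             "physical units were requested; pass require_scale = FALSE ",
             "only if coordinates are already in micrometers")
      scale <- 1.0
    } else {
      scale <- as.numeric(scale_str)
      if (!is.finite(scale) || scale <= 0)
        stop("invalid SCALE in TPS block ", b)
    }
    parts <- strsplit(id_str, "_")[[1]]
    if (length(parts) < 4L)
      stop("TPS identifier '", id_str, "' does not follow ",
           "'individual_side_imagingrep_digitizationrep'")
    np <- length(parts)
    side <- parts[np - 2L]
    if (!side %in% sides_ok)
      stop("TPS identifier '", id_str, "': side field '", side,
           "' must be 'left' or 'right'")
    coords[[b]] <- xy * scale
    info[[b]] <- data.frame(
      individual_id = paste(parts[1:(np - 3L)], collapse = "_"),
      side = side,
      imaging_replicate = as.integer(parts[np - 1L]),
      digitization_replicate = as.integer(parts[np]),
      scale_um_per_px = scale,
      stringsAsFactors = FALSE)
  }
  landmark_set(coords, do.call(rbind, info), n_landmarks = n_landmarks)
}

#' Write a landmark set to a TPS file
#'
#' Emits exactly the dialect [read_tps()] accepts: one `LM=` block per
#' configuration with an `ID=individual_side_imagingrep_digitizationrep`
#' line and `SCALE=1.0` (coordinates are written in micrometers).
#'
#' @param landmarks a [landmark_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  info <- landmarks$info
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(length(landmarks))) {
    xy <- landmarks$coords[, , i]
    writeLines(c(
      sprintf("LM=%d", nrow(xy)),
      sprintf("%.10g %.10g", xy[, 1], xy[, 2]),
      sprintf("ID=%s_%s_%d_%d", info$individual_id[i], info$side[i],
              info$imaging_replicate[i], info$digitization_replicate[i]),
      "SCALE=1.0"), con)
  }
  invisible(path)
}
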