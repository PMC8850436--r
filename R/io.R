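#' Write an image series as a NIfTI volume plus a label sidecar
#'
#' Frames are stacked on the third (time) axis; pixel size is preserved in
#' the NIfTI header.  Per-frame condition labels go to a tab-separated
#' sidecar table \code{<stem>_labels.tsv}.
#'
#' @param series an \code{\link{image_series}}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return invisibly, the paths written (volume, labels).
#' @export
write_image_series <- function(series, path) {
  img <- RNifti::asNifti(series$frames)
  RNifti::pixdim(img) <- c(series$pixel_size_mm, series$pixel_size_mm, 1)
  RNifti::writeNifti(img, path)
  lab_path <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.tsv")
  utils::write.table(series$labels, lab_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(volume = path, labels = lab_path))
}

#' Read an image series written by \code{\link{write_image_series}}
#' @param path path to the NIfTI volume.
#' @return an \code{\link{image_series}}.
#' @export
read_image_series <- function(path) {
  img <- RNifti::readNifti(path)
  lab_path <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.tsv")
  labels <- if (file.exists(lab_path))
    utils::read.table(lab_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else NULL
  ps <- RNifti::pixdim(img)[1]
  arr <- array(as.vector(img), dim = dim(img))
  image_series(arr, pixel_size_mm = ps, labels = labels)
}

#' Write outlines as a long delimited-text contour table
#'
#' Columns: \code{frame_index}, \code{point_index}, \code{x_mm},
#' \code{y_mm}, \code{closed}.
#'
#' @param outlines list of \code{\link{vt_contour}}s.
#' @param path output path (TSV).
#' @return invisibly, the path.
#' @export
write_contours <- function(outlines, path) {
  rows <- lapply(outlines, function(o) {
    xy <- unclass(o)
    data.frame(frame_index = attr(o, "frame_index"),
               point_index = seq_len(nrow(xy)),
               x_mm = xy[, 1], y_mm = xy[, 2],
               closed = isTRUE(attr(o, "closed")))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a contour table written by \code{\link{write_contours}}
#' @param path TSV path.
#' @return list of \code{\link{vt_contour}}s in frame order.
#' @export
read_contours <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  lapply(split(d, d$frame_index), function(s) {
    s <- s[order(s$point_index), ]
    vt_contour(cbind(s$x_mm, s$y_mm), closed = s$closed[1L],
               frame_index = s$frame_index[1L])
  })
}

#' Write a pipeline table as tab-separated text
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tab-separated pipeline table
#' @param path TSV path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

## Table schemas: required columns and row-level invariant checks.
table_schemas <- function() {
  freq_cols <- c("f0_hz", "F1_hz", "F2_hz", "F3_hz", "F4_hz")
  list(
    acoustic_take = list(
      columns = c("speaker_id", "word", "condition", "vt_condition",
                  "take_index", freq_cols),
      checks = list(
        positive_frequencies = function(d)
          which(Reduce(`|`, lapply(freq_cols,
                                   function(cc) !is.finite(d[[cc]]) |
                                     d[[cc]] <= 0))),
        formants_ordered = function(d)
          which(!(d$F1_hz < d$F2_hz & d$F2_hz < d$F3_hz &
                    d$F3_hz < d$F4_hz)))),
    modulation_record = list(
      columns = c("speaker_id", "word", "condition", "vt_condition",
                  "measure", "modulation_st"),
      checks = list(
        finite_modulation = function(d) which(!is.finite(d$modulation_st)),
        known_measure = function(d)
          which(!d$measure %in% c("f0", "F1", "F2", "F3", "F4", "aVTL")))),
    score_table = list(
      columns = c("frame_index", "speaker_id", "word", "vt_condition",
                  "fPC1"),
      checks = list(
        finite_scores = function(d)
          which(!is.finite(d$fPC1)))),
    skill_record = list(
      columns = c("speaker_id", "sex", "vt_skill", "rank_within_sex",
                  "group"),
      checks = list(
        known_group = function(d)
          which(!d$group %in% c("good", "poor", "unassigned")))),
    perception_trial = list(
      columns = c("listener_id", "voice_sex", "speaker_id", "skill_group",
                  "vt_condition", "f0_shift_st", "rating_cm"),
      checks = list(
        rating_in_slider_range = function(d) {
          rng <- slider_range_cm(d$voice_sex)
          which(d$rating_cm < rng[, "lower"] | d$rating_cm > rng[, "upper"])
        })),
    contours = list(
      columns = c("frame_index", "point_index", "x_mm", "y_mm"),
      checks = list(
        finite_coordinates = function(d)
          which(!is.finite(d$x_mm) | !is.finite(d$y_mm))))
  )
}

#' Validate a delimited table against a pipeline schema
#'
#' Checks the header and the schema's row-level invariants (positive
#' frequencies, ordered formants, ratings within the slider range, ...).
#'
#' @param path TSV path.
#' @param schema_name one of \code{"acoustic_take"},
#'   \code{"modulation_record"}, \code{"score_table"},
#'   \code{"skill_record"}, \code{"perception_trial"}, \code{"contours"}.
#' @return data.frame report of violations (zero rows when the table is
#'   valid) with columns \code{check}, \code{row}, \code{detail}.
#' @export
validate_tables <- function(path, schema_name) {
  schemas <- table_schemas()
  if (!schema_name %in% names(schemas))
    stop("unknown schema '", schema_name, "'", call. = FALSE)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  sch <- schemas[[schema_name]]
  d <- read_table_tsv(path)
  report <- list()
  miss <- setdiff(sch$columns, names(d))
  if (length(miss))
    return(data.frame(check = "header", row = NA_integer_,
                      detail = paste("missing columns:",
                                     paste(miss, collapse = ", "))))
  for (cn in names(sch$checks)) {
    bad <- sch$checks[[cn]](d)
    if (length(bad))
      report[[cn]] <- data.frame(check = cn, row = bad,
                                 detail = paste("invariant", cn,
                                                "violated"))
  }
  if (!length(report))
    return(data.frame(check = character(0), row = integer(0),
                      detail = character(0)))
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  out
}
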