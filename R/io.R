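# Serialization: CSV trial/epoch tables, JSON sidecars, optional TIFF.

#' Write a lick session to CSV
#'
#' Column layout: `trial_id, type, level_db, pre_bin_00..pre_bin_34,
#' post_bin_00..post_bin_34`.
#'
#' @param session a [LickSession-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeLickSessionCSV <- function(session, path) {
  stopifnot(is(session, "LickSession"))
  pre <- session@preBins; post <- session@postBins
  colnames(pre) <- sprintf("pre_bin_%02d", 0:34)
  colnames(post) <- sprintf("post_bin_%02d", 0:34)
  df <- data.frame(trial_id = seq_along(session@type),
                   type = session@type, level_db = session@levelDb,
                   pre, post, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a lick session from CSV
#'
#' @param path file written by [writeLickSessionCSV()].
#' @param frequencyKHz session frequency metadata.
#' @return a [LickSession-class].
#' @export
readLickSessionCSV <- function(path, frequencyKHz = NA_real_) {
  df <- read.csv(path, check.names = FALSE)
  pre <- as.matrix(df[, sprintf("pre_bin_%02d", 0:34)])
  post <- as.matrix(df[, sprintf("post_bin_%02d", 0:34)])
  dimnames(pre) <- NULL; dimnames(post) <- NULL
  new("LickSession", frequencyKHz = frequencyKHz,
      type = as.character(df$type), levelDb = as.numeric(df$level_db),
      preBins = pre, postBins = post)
}

#' Write an epoch set to CSV
#'
#' Long format: one row per (epoch, sample) would be wasteful, so epochs
#' are stored wide (`epoch` id, then one column per sample) with stimulus
#' metadata in a JSON sidecar (`<path>.json`).
#'
#' @param epochSet an [EpochSet-class].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
writeEpochSetCSV <- function(epochSet, path) {
  stopifnot(is(epochSet, "EpochSet"))
  df <- data.frame(epoch = seq_len(nrow(epochSet@epochs)), epochSet@epochs)
  names(df) <- c("epoch", sprintf("s%04d", seq_len(ncol(epochSet@epochs))))
  write.csv(df, path, row.names = FALSE)
  meta <- list(stimulus = epochSet@stimulus,
               frequency_khz = epochSet@frequencyKHz,
               level_db = epochSet@levelDb,
               sample_rate_hz = epochSet@sampleRate,
               onset_index = epochSet@onsetIndex)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read an epoch set written by [writeEpochSetCSV()]
#'
#' @param path CSV file (its `.json` sidecar must sit next to it).
#' @return an [EpochSet-class].
#' @export
readEpochSetCSV <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ep <- as.matrix(df[, -1, drop = FALSE])
  dimnames(ep) <- NULL
  fk <- meta$frequency_khz
  fk <- if (is.null(fk) || length(fk) == 0) NA_real_ else as.numeric(fk)
  new("EpochSet", stimulus = meta$stimulus,
      frequencyKHz = fk,
      levelDb = meta$level_db, sampleRate = meta$sample_rate_hz,
      onsetIndex = as.integer(meta$onset_index), epochs = ep)
}

#' Write a section stack as multipage TIFF files
#'
#' Writes `<prefix>_sections.tif` (grayscale, 8-bit) and
#' `<prefix>_rois.tif` (binary masks) plus a JSON metadata sidecar.
#' Requires the optional `tiff` package.
#'
#' @param stack a [SectionStack-class].
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
writeSectionStackTIFF <- function(stack, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  stopifnot(is(stack, "SectionStack"))
  imgs <- lapply(stack@images, function(m) m / 255)
  rois <- lapply(stack@rois, function(m) m * 1)
  p1 <- paste0(prefix, "_sections.tif")
  p2 <- paste0(prefix, "_rois.tif")
  tiff::writeTIFF(imgs, p1, bits.per.sample = 8)
  tiff::writeTIFF(rois, p2, bits.per.sample = 8)
  jsonlite::write_json(
    list(pixel_size_um = stack@pixelSizeUm, spacing_um = stack@spacingUm,
         section_index = stack@sectionIndex,
         transforms = lapply(stack@transforms, function(m)
           as.vector(t(m)))),
    paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
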