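# Reading and writing the pipeline's on-disk formats: multi-channel TIFF
# stacks with a JSON metadata sidecar, ground truth as JSON, ABR series and
# ear-canal recordings as CSV + JSON, cohorts as CSV.

#' Write a confocal stack as per-channel TIFF files plus a JSON sidecar
#'
#' Each channel is written as a multi-page 32-bit float TIFF (one page per
#' z-slice), intensities rescaled to [0, 1]; the sidecar records voxel
#' dimensions, shape, channel names and the rescaling factor.
#'
#' @param stack a `"confocal_stack"`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  abort_if(!inherits(stack, "confocal_stack"),
           "`stack` must be a confocal_stack")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scale <- max(1, max(vapply(stack$channels, max, numeric(1))))
  for (ch in names(stack$channels)) {
    g <- stack$channels[[ch]] / scale
    slices <- lapply(seq_len(dim(g)[3]), function(z) t(g[, , z]))
    tiff::writeTIFF(slices, file.path(path, paste0(ch, ".tif")),
                    bits.per.sample = 32L)
  }
  meta <- list(voxel_dims_um = stack$voxel_dims,
               shape = dim(stack$channels[[1]]),
               channels = names(stack$channels),
               intensity_scale = scale,
               meta = stack$meta[setdiff(names(stack$meta), "noise")])
  jsonlite::write_json(meta, file.path(path, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a confocal stack written by [write_stack()]
#'
#' @param path directory containing the channel TIFFs and `stack.json`.
#' @return a `"confocal_stack"`.
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "stack.json"),
                              simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  channels <- lapply(meta$channels, function(ch) {
    slices <- tiff::readTIFF(file.path(path, paste0(ch, ".tif")), all = TRUE)
    g <- array(0, shape)
    for (z in seq_along(slices)) g[, , z] <- t(slices[[z]])
    g * meta$intensity_scale
  })
  names(channels) <- meta$channels
  structure(list(channels = channels,
                 voxel_dims = as.numeric(meta$voxel_dims_um),
                 meta = as.list(meta$meta)),
            class = "confocal_stack")
}

#' Write/read planted ground truth as JSON
#'
#' @param gt a `"ground_truth"`.
#' @param file JSON file path.
#' @return `file` (write) or a `"ground_truth"` (read).
#' @export
write_ground_truth <- function(gt, file) {
  jsonlite::write_json(
    list(puncta = gt$puncta, cells = gt$cells,
         field = gt$field, cleft_um = gt$cleft_um, seed = gt$seed),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(puncta = as.data.frame(x$puncta),
                 cells = as.data.frame(x$cells),
                 field = list(extent_um = as.numeric(x$field$extent_um)),
                 cleft_um = x$cleft_um, seed = x$seed),
            class = "ground_truth")
}

#' Write/read an ABR series as CSV + JSON metadata
#'
#' Long CSV with columns `level_db`, `t_ms`, `avg`, `half_a`, `half_b`; the
#' sidecar stores fs, frequency and epoch counts.
#'
#' @param series an `"abr_series"`.
#' @param path directory to write into.
#' @return `path` (write) or an `"abr_series"` (read).
#' @export
write_abr_series <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  rows <- do.call(rbind, lapply(series$waveforms, function(w) {
    data.frame(level_db = w$level_db, t_ms = w$t_ms, avg = w$samples,
               half_a = w$half_a, half_b = w$half_b)
  }))
  utils::write.csv(rows, file.path(path, "abr_series.csv"),
                   row.names = FALSE)
  w1 <- series$waveforms[[1]]
  jsonlite::write_json(
    list(fs = w1$fs, frequency_khz = series$frequency_khz,
         n_epochs_averaged = w1$n_epochs_averaged,
         levels = series$levels, seed = series$seed),
    file.path(path, "abr_series.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_abr_series
#' @export
read_abr_series <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "abr_series.json"),
                              simplifyVector = TRUE)
  rows <- utils::read.csv(file.path(path, "abr_series.csv"))
  waveforms <- lapply(sort(unique(rows$level_db)), function(L) {
    s <- rows[rows$level_db == L, ]
    structure(list(samples = s$avg, t_ms = s$t_ms, fs = meta$fs,
                   level_db = L, frequency_khz = meta$frequency_khz,
                   n_epochs_averaged = meta$n_epochs_averaged,
                   half_a = s$half_a, half_b = s$half_b),
              class = "abr_waveform")
  })
  structure(list(waveforms = waveforms,
                 levels = sort(unique(rows$level_db)),
                 threshold_db = NA_real_,
                 frequency_khz = meta$frequency_khz, seed = meta$seed),
            class = "abr_series")
}

#' Write/read an ear-canal recording as CSV + JSON metadata
#'
#' @param recording a `"pressure_recording"`.
#' @param path directory to write into.
#' @return `path` (write) or a `"pressure_recording"` (read).
#' @export
write_recording <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- length(recording$samples)
  utils::write.csv(
    data.frame(time_s = (seq_len(n) - 1) / recording$fs,
               pressure = recording$samples),
    file.path(path, "recording.csv"), row.names = FALSE)
  pp <- recording$primaries
  jsonlite::write_json(
    list(fs = recording$fs, p_ref = recording$p_ref,
         f1 = pp$f1, f2 = pp$f2, L1 = pp$L1, L2 = pp$L2,
         dp_frequency = pp$dp_frequency, ratio = pp$ratio),
    file.path(path, "recording.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "recording.json"),
                              simplifyVector = TRUE)
  rows <- utils::read.csv(file.path(path, "recording.csv"))
  structure(list(samples = rows$pressure, fs = meta$fs,
                 primaries = structure(
                   list(f1 = meta$f1, f2 = meta$f2, L1 = meta$L1,
                        L2 = meta$L2, dp_frequency = meta$dp_frequency,
                        ratio = meta$ratio), class = "primary_pair"),
                 p_ref = meta$p_ref, seed = NA),
            class = "pressure_recording")
}

#' Write/read a cohort table as CSV
#'
#' @param table a `"cohort_table"`.
#' @param file CSV path.
#' @return `file` (write) or a `"cohort_table"` (read).
#' @export
write_cohort <- function(table, file) {
  utils::write.csv(as.data.frame(table), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  tbl <- tibble::as_tibble(utils::read.csv(file, stringsAsFactors = FALSE))
  class(tbl) <- c("cohort_table", class(tbl))
  tbl
}
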