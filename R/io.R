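# Plain-text and TIFF I/O for the pipeline's data classes: tidy CSV for
# ATPase datasets, displacement traces and cell traces; TIFF plus JSON
# calibration sidecar for kymographs; TSV/JSON reports.

#' Write an ATPase dataset as tidy CSV
#'
#' Columns: `variant`, `mlck_treated`, `actin_uM`, `rate_per_s`, `replicate`.
#'
#' @param ds an [atpase_dataset()] (or a `data.frame` with those columns).
#' @param path output file.
#' @export
write_atpase_csv <- function(ds, path) {
  write.csv(as.data.frame(ds), path, row.names = FALSE)
  invisible(path)
}

#' Read an ATPase dataset from tidy CSV
#'
#' @param path CSV with columns `variant`, `mlck_treated`, `actin_uM`,
#'   `rate_per_s`, `replicate`.
#' @return an [atpase_dataset()] (multi-variant files keep all rows; split on
#'   `variant` / `mlck_treated` before fitting).
#' @export
read_atpase_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("variant", "mlck_treated", "actin_uM", "rate_per_s", "replicate")
  if (!all(req %in% names(df))) {
    stop_invalid("CSV must have columns ", paste(req, collapse = ", "))
  }
  class(df) <- c("atpase_dataset", "data.frame")
  df
}

#' Write a displacement trace as CSV
#'
#' Columns `time_s`, `displacement_um`; missing frames stay `NA`.
#' @param tr a [displacement_trace()].
#' @param path output file.
#' @export
write_trace_csv <- function(tr, path) {
  stopifnot(inherits(tr, "displacement_trace"))
  write.csv(data.frame(time_s = tr$times, displacement_um = tr$displacement),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a displacement trace from CSV
#' @param path CSV with columns `time_s`, `displacement_um`.
#' @return a [displacement_trace()].
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "displacement_um") %in% names(df))) {
    stop_invalid("CSV must have columns time_s, displacement_um")
  }
  displacement_trace(df$time_s, df$displacement_um)
}

#' Write a kymograph as TIFF with a JSON calibration sidecar
#'
#' The image is stored as 32-bit float TIFF rescaled to `[0, 1]`; the
#' rescaling and the physical calibration (pixel size, frame interval, cut
#' position, region width) go to `<path>.json`.
#'
#' @param k a [kymograph()].
#' @param path output TIFF file.
#' @export
write_kymograph_tiff <- function(k, path) {
  stopifnot(inherits(k, "kymograph"))
  rng <- range(k$image)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  tiff::writeTIFF((k$image - rng[1]) / scale, path, bits.per.sample = 32)
  sidecar <- list(pixel_size_um = k$pixel_size,
                  frame_interval_s = k$frame_interval,
                  cut_position_um = k$cut_position,
                  region_width_um = k$region_width,
                  intensity_offset = rng[1], intensity_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a kymograph written by [write_kymograph_tiff()]
#' @param path TIFF file with `<path>.json` sidecar alongside.
#' @return a [kymograph()].
#' @export
read_kymograph_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  kymograph(img * meta$intensity_scale + meta$intensity_offset,
            pixel_size = meta$pixel_size_um,
            frame_interval = meta$frame_interval_s,
            cut_position = meta$cut_position_um,
            region_width = meta$region_width_um)
}

#' Write embryo cell traces as tidy CSV
#'
#' Columns: `embryo_id`, `genotype`, `cell_id`, `time_min`, `area_um2`,
#' `myosin_au`.
#'
#' @param embryos list of [embryo_dataset()]s (or a single one).
#' @param path output file.
#' @export
write_cell_traces_csv <- function(embryos, path) {
  if (inherits(embryos, "embryo_dataset")) embryos <- list(embryos)
  rows <- lapply(embryos, function(e) {
    cbind(embryo_id = e$embryo_id, genotype = e$genotype, e$cells)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read embryo cell traces from tidy CSV
#'
#' @param path CSV as written by [write_cell_traces_csv()].
#' @param frame_interval acquisition interval (s); inferred from the time
#'   grid when omitted.
#' @return list of [embryo_dataset()]s, one per `embryo_id`.
#' @export
read_cell_traces_csv <- function(path, frame_interval = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("embryo_id", "genotype", "cell_id", "time_min", "area_um2",
           "myosin_au")
  if (!all(req %in% names(df))) {
    stop_invalid("CSV must have columns ", paste(req, collapse = ", "))
  }
  lapply(split(df, df$embryo_id), function(sub) {
    fi <- frame_interval
    if (is.null(fi)) {
      ts <- sort(unique(sub$time_min))
      fi <- if (length(ts) > 1) (ts[2] - ts[1]) * 60 else 1
    }
    embryo_dataset(sub[, c("cell_id", "time_min", "area_um2", "myosin_au")],
                   embryo_id = sub$embryo_id[1], genotype = sub$genotype[1],
                   frame_interval = fi)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
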