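#' @section File layout:
#' A movie on disk is a directory with one multi-page TIFF per channel
#' (pages ordered frame-major, then z: TZYX) and a `movie.json` sidecar
#' holding dimensions, physical calibration and the intensity scale of each
#' channel. Integer-valued movies (camera counts) are stored as 16-bit and
#' round-trip exactly; continuous-valued movies fall back to 32-bit float.
#' @name caosc-io
#' @keywords internal
NULL

MOVIE_SIDE_CAR_VERSION <- "1"

#' Write a movie to a directory (TIFF + JSON sidecar)
#'
#' @param movie A `ca_movie`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "ca_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acq <- movie$acquisition
  d <- dim(movie$nuclear)

  write_channel <- function(arr, file) {
    vals <- as.vector(arr)
    integerish <- all(vals == round(vals)) && min(vals) >= 0 &&
      max(vals) <= 65535
    if (integerish) {
      bits <- 16L
      scale <- 65535
    } else {
      bits <- 32L
      scale <- max(abs(vals), 1)
    }
    pages <- vector("list", d[4] * d[1])
    k <- 1L
    for (f in seq_len(d[4])) {
      for (z in seq_len(d[1])) {
        pages[[k]] <- arr[z, , , f] / scale
        k <- k + 1L
      }
    }
    tiff::writeTIFF(pages, file.path(dir, file), bits.per.sample = bits)
    list(file = file, bits = bits, scale = scale)
  }

  ch_n <- write_channel(movie$nuclear, "nuclear.tif")
  ch_i <- write_channel(movie$indicator, "indicator.tif")

  sidecar <- list(
    version = MOVIE_SIDE_CAR_VERSION,
    dims = list(z = d[1], y = d[2], x = d[3], t = d[4]),
    calibration = list(
      xy_pixel_um = acq$xy_pixel_um,
      z_step_um = acq$z_step_um,
      frame_interval_s = acq$frame_interval_s,
      duration_s = acq$duration_s
    ),
    channels = list(nuclear = ch_n, indicator = ch_i)
  )
  jsonlite::write_json(sidecar, file.path(dir, "movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a movie directory written by [write_movie()]
#'
#' Validates the sidecar (positive calibration, matching channel dimensions)
#' before loading voxel data.
#'
#' @param dir Directory containing `movie.json` and the channel TIFFs.
#' @return A `ca_movie`.
#' @export
read_movie <- function(dir) {
  side_path <- file.path(dir, "movie.json")
  if (!file.exists(side_path)) {
    abort(sprintf("missing calibration sidecar: %s", side_path))
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  cal <- side$calibration
  for (f in c("xy_pixel_um", "z_step_um", "frame_interval_s")) {
    if (is.null(cal[[f]]) || cal[[f]] <= 0) {
      abort(sprintf("sidecar calibration field `%s` must be > 0", f))
    }
  }
  d <- unlist(side$dims)
  if (any(d <= 0)) abort("sidecar dims must all be positive")

  read_channel <- function(ch) {
    pages <- tiff::readTIFF(file.path(dir, ch$file), all = TRUE)
    if (length(pages) != d["t"] * d["z"]) {
      abort(sprintf(
        "channel %s has %d pages, expected %d (t) x %d (z)",
        ch$file, length(pages), d["t"], d["z"]
      ))
    }
    page_dim <- dim(pages[[1]])
    if (page_dim[1] != d["y"] || page_dim[2] != d["x"]) {
      abort(sprintf(
        "channel %s pages are %d x %d, sidecar declares %d (y) x %d (x)",
        ch$file, page_dim[1], page_dim[2], d["y"], d["x"]
      ))
    }
    arr <- array(0, dim = unname(c(d["z"], d["y"], d["x"], d["t"])))
    k <- 1L
    for (f in seq_len(d["t"])) {
      for (z in seq_len(d["z"])) {
        arr[z, , , f] <- pages[[k]] * ch$scale
        k <- k + 1L
      }
    }
    if (ch$bits == 16) arr[] <- round(arr)
    arr
  }

  nuclear <- read_channel(side$channels$nuclear)
  indicator <- read_channel(side$channels$indicator)
  if (!identical(dim(nuclear), dim(indicator))) {
    abort(sprintf(
      "channel dims differ: nuclear %s vs indicator %s",
      paste(dim(nuclear), collapse = "x"),
      paste(dim(indicator), collapse = "x")
    ))
  }
  acq <- acquisition_config(
    frame_interval_s = cal$frame_interval_s,
    z_step_um = cal$z_step_um,
    xy_pixel_um = cal$xy_pixel_um,
    duration_s = if (!is.null(cal$duration_s)) cal$duration_s else
      (d["t"] - 1) * cal$frame_interval_s,
    volume_shape = d[c("z", "y", "x")]
  )
  structure(list(nuclear = nuclear, indicator = indicator, acquisition = acq),
            class = "ca_movie")
}

# stage table schemas ---------------------------------------------------------

table_schemas <- list(
  tracks = c("cell_id", "frame", "t_s", "x_um", "y_um", "z_um",
             "mitosis_flag", "excluded"),
  traces = c("cell_id", "frame", "t_s", "F"),
  dff = c("cell_id", "frame", "t_s", "F", "F0", "dff"),
  peaks = c("cell_id", "apex_frame", "apex_time_s", "apex_dff",
            "onset_time_s", "time_to_peak_s"),
  metrics = c("cell_id", "n_peaks", "frequency_per_min", "mean_dff",
              "observed_duration_s", "oscillating"),
  synchrony = c("cell_A", "cell_B", "pct_synchronous_A", "pct_synchronous_B",
                "window_s"),
  regions = c("cell_id", "region", "left_x_um", "right_x_um",
              "nucleus_x_at_t0_um"),
  boundary_counts = c("boundary_x_um", "n_oscillating", "category"),
  boundaries = c("x_um"),
  annotations = c("cell_id", "role"),
  spikes = c("cell_id", "spike_time_s", "amplitude_dff")
)

#' Write a stage table as CSV
#'
#' Column presence is checked against the named stage schema; columns are
#' reordered schema-first; missing values are written as empty fields; floats
#' are serialized at round-trip precision.
#'
#' @param records A data frame conforming to the schema.
#' @param path Output CSV path.
#' @param schema One of `r paste(names(table_schemas), collapse = ", ")`.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, schema) {
  if (!schema %in% names(table_schemas)) {
    abort(sprintf("unknown schema '%s'", schema))
  }
  cols <- table_schemas[[schema]]
  check_columns(records, cols, schema)
  records <- records[, c(cols, setdiff(names(records), cols)), drop = FALSE]
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read a stage table written by [write_table()]
#'
#' @param path CSV path.
#' @param schema Schema name (validated after reading).
#' @return A tibble.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(table_schemas)) {
    abort(sprintf("unknown schema '%s'", schema))
  }
  out <- readr::read_csv(path, show_col_types = FALSE, na = "",
                         progress = FALSE)
  check_columns(out, table_schemas[[schema]], schema)
  out
}
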