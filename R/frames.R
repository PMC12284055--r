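# Frames: 8 x 5 matrices of RMS differential voltages, their noisy
# acquisition, and the Frame<k>.txt text-file format.

#' Construct a measurement frame
#'
#' A frame is the complete set of RMS differential voltages for one
#' injection cycle, arranged drive-by-row: with 8 electrodes, 8 rows
#' (injections) by 5 columns (measurement slots).
#'
#' @param values Numeric matrix of non-negative voltages (volts), rows =
#'   injections, columns = measurement slots.
#' @param label `"homogeneous"` (reference) or `"inhomogeneous"`.
#' @param index Frame index; the homogeneous reference is frame 0.
#' @return An object of class `eit_frame`.
#' @export
eit_frame <- function(values, label = c("inhomogeneous", "homogeneous"),
                      index = 0L) {
  label <- match.arg(label)
  values <- as.matrix(values)
  if (!all(is.finite(values)) || any(values < 0))
    stop("frame values must be finite and non-negative")
  structure(list(values = values, label = label, index = as.integer(index)),
            class = "eit_frame")
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("<eit_frame %d> %s, %d x %d, mean %.4g V\n", x$index, x$label,
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' Flatten a frame to the protocol measurement vector
#'
#' Row-major flattening: drive 1 slots 1..5, then drive 2, and so on —
#' matching the row order of [adjacent_pattern()].
#'
#' @param frame An [eit_frame()] (or a bare matrix).
#' @return Numeric vector of length `rows * cols` (40 for 8 electrodes).
#' @export
frame_vector <- function(frame) {
  m <- if (inherits(frame, "eit_frame")) frame$values else as.matrix(frame)
  as.vector(t(m))
}

#' Measurement noise model
#'
#' Additive white Gaussian noise per measurement slot plus a slow random
#' drift accumulated across the slots of a frame — the statistical signature
#' of multiplexer switching transients at long switching times.
#'
#' @param additive_sd_v Standard deviation of the white component, volts.
#' @param drift_rate_v Standard deviation of the per-slot drift increment,
#'   volts per slot (0 disables drift).
#' @param seed Integer RNG seed for reproducible acquisition, or `NULL`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd_v = 0, drift_rate_v = 0, seed = NULL) {
  stopifnot(additive_sd_v >= 0, drift_rate_v >= 0)
  structure(list(additive_sd_v = additive_sd_v, drift_rate_v = drift_rate_v,
                 seed = seed), class = "noise_model")
}

#' Simulate repeated frame acquisition
#'
#' Each frame is the true measurement vector plus white noise plus a
#' cumulative random-walk drift over the measurement slots (so dispersion
#' grows with slot index when drift is active).  Voltages are RMS magnitudes
#' and are truncated at zero.  Deterministic under a fixed seed.
#'
#' @param truth_v True measurement vector (length = slots per frame, 40 for
#'   8 electrodes) in protocol order.
#' @param noise A [noise_model()].
#' @param n_frames Number of frames to acquire.
#' @param n_rows Injections per frame (default 8); slots per row inferred.
#' @param label Frame label for the acquired frames.
#' @param start_index Index given to the first acquired frame.
#' @return List of [eit_frame()] objects.
#' @export
acquire_frames <- function(truth_v, noise = noise_model(), n_frames = 1L,
                           n_rows = 8L, label = "inhomogeneous",
                           start_index = 1L) {
  if (n_frames < 1L) stop("n_frames must be at least 1")
  n <- length(truth_v)
  if (n %% n_rows != 0L) stop("truth length must be a multiple of n_rows")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  lapply(seq_len(n_frames), function(f) {
    eps <- stats::rnorm(n, 0, noise$additive_sd_v)
    drift <- if (noise$drift_rate_v > 0)
      cumsum(stats::rnorm(n, 0, noise$drift_rate_v)) else 0
    v <- pmax(truth_v + eps + drift, 0)
    eit_frame(matrix(v, nrow = n_rows, byrow = TRUE), label = label,
              index = start_index + f - 1L)
  })
}

#' Write frames as Frame<k>.txt files
#'
#' One whitespace-delimited text file per frame (`Frame0.txt`,
#' `Frame1.txt`, ...), each row of the matrix on its own line.  `Frame0.txt`
#' must hold the homogeneous reference.  Values are printed with 17
#' significant digits so a write/read round trip is exact.
#'
#' @param frames List of [eit_frame()] objects; the first must be labeled
#'   homogeneous.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, directory) {
  if (length(frames) == 0L) stop("no frames to write")
  if (frames[[1]]$label != "homogeneous")
    stop("the first frame must be the homogeneous reference (Frame0)")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- vapply(frames, function(fr) {
    path <- file.path(directory, sprintf("Frame%d.txt", fr$index))
    lines <- apply(fr$values, 1, function(row)
      paste(sprintf("%.17g", row), collapse = " "))
    writeLines(lines, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a directory of Frame<k>.txt files
#'
#' Frames are sorted by index; `Frame0.txt` is required and labeled
#' homogeneous, the rest inhomogeneous.  Blank lines and scientific
#' notation are tolerated.  Files may hold the `rows x slots` matrix or a
#' single column of `rows * slots` values (reshaped row-major).
#'
#' @param directory Directory containing the frame files.
#' @param n_rows Expected injections per frame (default 8).
#' @param n_cols Expected measurement slots per injection (default 5).
#' @return List of [eit_frame()] objects sorted by index.
#' @export
read_frames <- function(directory, n_rows = 8L, n_cols = 5L) {
  files <- list.files(directory, pattern = "^Frame[0-9]+\\.txt$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no Frame<k>.txt files in ", directory)
  idx <- as.integer(sub("^Frame([0-9]+)\\.txt$", "\\1", basename(files)))
  if (!0L %in% idx)
    stop("reference frame required: Frame0.txt missing from ", directory)
  ord <- order(idx)
  files <- files[ord]
  idx <- idx[ord]
  mapply(function(path, k) {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    rows <- lapply(seq_along(raw), function(i) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(raw[i]), "\\s+")[[1]]))
      if (any(is.na(v)))
        stop(sprintf("malformed row in %s, line %d", basename(path), i))
      v
    })
    lens <- lengths(rows)
    if (all(lens == n_cols) && length(rows) == n_rows) {
      m <- do.call(rbind, rows)
    } else if (all(lens == 1L) && length(rows) == n_rows * n_cols) {
      m <- matrix(unlist(rows), nrow = n_rows, byrow = TRUE)
    } else {
      stop(sprintf("%s: expected a %d x %d matrix or %d single values, got %d row(s) of width %s",
                   basename(path), n_rows, n_cols, n_rows * n_cols,
                   length(rows), paste(unique(lens), collapse = "/")))
    }
    eit_frame(m, label = if (k == 0L) "homogeneous" else "inhomogeneous",
              index = k)
  }, files, idx, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}
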