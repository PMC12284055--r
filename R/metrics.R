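# Channel statistics over repeated frames (SNR, accuracy) and the
# global-impedance volume index over reconstructed images.

#' Per-channel signal-to-noise ratio over repeated frames
#'
#' For each of the protocol channels (40 with 8 electrodes), the SNR over
#' repeated frames is `20 * log10(|mean| / dispersion)`.  The dispersion is
#' the square root of the unbiased variance by default; the raw variance
#' reading is exposed for comparison.  Channels with zero dispersion report
#' the `Inf` sentinel with a warning.
#'
#' @param frames List of [eit_frame()] objects (at least 2).
#' @param denominator `"sd"` (default) or `"variance"`.
#' @return An object of class `eit_channel_stats`: list with per-channel
#'   `mean_v`, `dispersion_v`, `snr_db`, and a `summary` (mean, median,
#'   min, max over channels).
#' @export
snr_stats <- function(frames, denominator = c("sd", "variance")) {
  denominator <- match.arg(denominator)
  if (length(frames) < 2L) stop("need at least 2 frames")
  M <- sapply(frames, frame_vector)           # channels x frames
  mu <- rowMeans(M)
  va <- apply(M, 1L, stats::var)
  disp <- if (denominator == "sd") sqrt(va) else va
  if (any(disp == 0))
    warning("zero dispersion on ", sum(disp == 0),
            " channel(s); SNR reported as Inf")
  snr <- ifelse(disp == 0, Inf, 20 * log10(abs(mu) / disp))
  fin <- snr[is.finite(snr)]
  structure(list(
    mean_v = mu, dispersion_v = disp, snr_db = snr,
    denominator = denominator,
    summary = c(mean = mean(snr), median = stats::median(snr),
                min = min(snr), max = max(snr))
  ), class = "eit_channel_stats")
}

#' Per-channel accuracy against a reference truth
#'
#' `Ac_i = (1 - |(mean_i - truth_i) / truth_i|) * 100` percent, where the
#' mean is taken over repeated frames.  In simulation the truth is the
#' noise-free forward-model voltage vector.
#'
#' @param frames List of [eit_frame()] objects.
#' @param truth_v True channel voltages (no zero entries).
#' @return An `eit_channel_stats` object with `accuracy_pct` per channel
#'   and the channel summary.
#' @export
accuracy_stats <- function(frames, truth_v) {
  if (length(frames) < 1L) stop("need at least 1 frame")
  if (any(truth_v == 0)) stop("truth vector must be nonzero elementwise")
  M <- sapply(frames, frame_vector)
  if (nrow(M) != length(truth_v))
    stop("truth length does not match frame channels")
  mu <- rowMeans(M)
  acc <- (1 - abs((mu - truth_v) / truth_v)) * 100
  structure(list(
    mean_v = mu, truth_v = truth_v, accuracy_pct = acc,
    summary = c(mean = mean(acc), median = stats::median(acc),
                min = min(acc), max = max(acc))
  ), class = "eit_channel_stats")
}

#' @export
print.eit_channel_stats <- function(x, ...) {
  what <- if (!is.null(x$snr_db)) "SNR (dB)" else "accuracy (%)"
  cat(sprintf("<eit_channel_stats> %s over %d channels:\n", what,
              length(x$mean_v)))
  print(round(x$summary, 3))
  invisible(x)
}

#' Global-impedance series over reconstructed frames
#'
#' The per-frame global impedance is the sum of the reconstructed pixel
#' values; the cumulative GI sums over frames as well.  The
#' inverse-magnitude transform `|GI|^-1`, reported per frame and
#' cumulatively, correlates with the fluid volume of the imaged inclusion.
#' Zero sums yield an `NA` sentinel for the inverse.
#'
#' @param images List of [apply_recon()] images (at least 1).
#' @return An object of class `gi_series`: list with `per_frame_sum`,
#'   `per_frame_inv` (`1/|sum|`), `cumulative` (running GI),
#'   `gi_total` and `inv_total`.
#' @export
global_impedance <- function(images) {
  if (length(images) < 1L) stop("need at least 1 image")
  sums <- vapply(images, function(im) {
    stopifnot(inherits(im, "eit_image"))
    sum(im$values)
  }, numeric(1))
  inv <- ifelse(sums == 0, NA_real_, 1 / abs(sums))
  total <- sum(sums)
  structure(list(per_frame_sum = sums, per_frame_inv = inv,
                 cumulative = cumsum(sums), gi_total = total,
                 inv_total = if (total == 0) NA_real_ else 1 / abs(total)),
            class = "gi_series")
}

#' @export
print.gi_series <- function(x, ...) {
  cat(sprintf("<gi_series> %d frame(s): GI total %.6g, median |GI|^-1 %.6g\n",
              length(x$per_frame_sum), x$gi_total,
              stats::median(x$per_frame_inv, na.rm = TRUE)))
  invisible(x)
}
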