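# Adjacent drive/measurement protocol on an electrode ring.

#' Electrode layout on the tank boundary
#'
#' @param n_electrodes Number of boundary electrodes (the tested device has 8).
#' @param angles Electrode angles in radians, strictly increasing in
#'   `[0, 2*pi)`; default equispaced with electrode 1 at angle 0,
#'   counterclockwise.
#' @param pin_permutation Bijection from electrode index (geometric order) to
#'   device pin; defaults to the identity.  Connector wirings that look
#'   non-adjacent in pin numbers are expressed here while the protocol stays
#'   canonical on electrode indices.
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(n_electrodes = 8L,
                             angles = 2 * pi * (seq_len(n_electrodes) - 1) /
                               n_electrodes,
                             pin_permutation = seq_len(n_electrodes)) {
  n_electrodes <- as.integer(n_electrodes)
  stopifnot(n_electrodes >= 1L, length(angles) == n_electrodes,
            length(pin_permutation) == n_electrodes)
  if (any(diff(angles) <= 0) || any(angles < 0) || any(angles >= 2 * pi))
    stop("angles must be strictly increasing within [0, 2*pi)")
  if (!setequal(pin_permutation, seq_len(n_electrodes)))
    stop("pin_permutation must be a bijection on electrode indices")
  structure(list(n_electrodes = n_electrodes, angles = angles,
                 pin_permutation = as.integer(pin_permutation)),
            class = "electrode_layout")
}

#' Adjacent injection/measurement pattern
#'
#' Current is driven through each pair of consecutive electrodes in turn;
#' for every drive, the differential voltage is read across each consecutive
#' electrode pair not touching a drive electrode, in ring order starting
#' just past the drive.  With `n` electrodes this yields `n * (n - 3)`
#' measurements per frame — 40 for the 8-electrode device, arranged as an
#' 8 x 5 frame.
#'
#' @param layout An [electrode_layout()].
#' @return A `data.frame` (class `eit_pattern`) with one row per
#'   measurement: `drive_a`, `drive_b`, `meas_a`, `meas_b` (1-based
#'   electrode indices), `drive_index` (1..n) and `meas_slot` (1..n-3).
#' @examples
#' p <- adjacent_pattern(electrode_layout(8))
#' nrow(p)  # 40
#' @export
adjacent_pattern <- function(layout = electrode_layout(8L)) {
  n <- layout$n_electrodes
  if (n < 4L) stop("adjacent protocol needs at least 4 electrodes")
  wrap <- function(i) ((i - 1L) %% n) + 1L
  rows <- vector("list", n)
  for (d in seq_len(n)) {
    da <- d
    db <- wrap(d + 1L)
    j <- wrap(d + 1L + seq_len(n - 3L))   # d+2 .. d+n-2
    rows[[d]] <- data.frame(drive_a = da, drive_b = db,
                            meas_a = j, meas_b = wrap(j + 1L),
                            drive_index = d, meas_slot = seq_len(n - 3L))
  }
  out <- do.call(rbind, rows)
  attr(out, "n_electrodes") <- n
  attr(out, "layout") <- layout
  class(out) <- c("eit_pattern", class(out))
  out
}

#' Differential voltage of the instrumentation stage
#'
#' Unity-gain contract of the matched-resistor differential amplifier:
#' the output is `V2 - V1`, rejecting common-mode offsets.
#'
#' @param v1,v2 Input voltages in volts (vectorized).
#' @return `v2 - v1`.
#' @export
differential_voltage <- function(v1, v2) v2 - v1
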