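# Once-per-period current-amplitude control, shunt sensing with SAR-ADC
# quantization, and RMS demodulation.

#' Load circuit seen by the synthesizer
#'
#' The synthesized voltage drives the load resistance in series with a shunt
#' resistor; the shunt voltage is digitized by a differential SAR ADC to
#' sense the load current.
#'
#' @param rl_ohm Load resistance in ohms.
#' @param shunt_ohm Shunt resistance in ohms (default 100).
#' @param adc_bits SAR ADC resolution in bits (default 10).
#' @param adc_range_v Differential ADC range in volts: the converter spans
#'   `[-adc_range_v, +adc_range_v]` (default 2.048).
#' @return An object of class `load_circuit`.
#' @export
load_circuit <- function(rl_ohm, shunt_ohm = 100, adc_bits = 10L,
                         adc_range_v = 2.048) {
  stopifnot(all(rl_ohm > 0), shunt_ohm > 0, adc_bits >= 1L, adc_range_v > 0)
  structure(list(rl_ohm = rl_ohm, shunt_ohm = shunt_ohm,
                 adc_bits = as.integer(adc_bits), adc_range_v = adc_range_v),
            class = "load_circuit")
}

#' Mid-rise uniform ADC quantization
#'
#' @param v Voltage(s) to digitize.
#' @param bits Resolution in bits.
#' @param range_v Differential range: input spans `[-range_v, range_v]`.
#' @return Quantized voltage(s); inputs beyond the range are clipped to the
#'   outermost code.
#' @export
adc_quantize <- function(v, bits = 10L, range_v = 2.048) {
  step <- 2 * range_v / 2^bits
  q <- (floor(v / step) + 0.5) * step
  pmin(pmax(q, -range_v + step / 2), range_v - step / 2)
}

#' Controller state of the amplitude loop
#'
#' @param amplitude_v Present voltage amplitude `a[k]` in volts; the loop
#'   starts from 1 V.
#' @param desired_current_a Current setpoint `Id` in amperes.
#' @param period_index Period counter `k`.
#' @return An object of class `control_state`.
#' @export
control_state <- function(amplitude_v = 1, desired_current_a, period_index = 0L) {
  stopifnot(amplitude_v > 0, desired_current_a > 0)
  structure(list(amplitude_v = amplitude_v,
                 desired_current_a = desired_current_a,
                 period_index = as.integer(period_index),
                 clipped = FALSE),
            class = "control_state")
}

#' One step of the once-per-period amplitude law
#'
#' The controller scales the voltage amplitude by the ratio of desired to
#' sensed current, `a[k] = a[k-1] * Id / IL[k]`.  The law needs no knowledge
#' of the load: after a single update the load current equals `Id` for any
#' resistive load (up to DAC/ADC quantization).  Amplitudes outside the
#' synthesizable span are clamped to the nearest autorange boundary and the
#' state is flagged `clipped`.
#'
#' @param state A [control_state()].
#' @param measured_current_a Sensed load-current amplitude `IL[k]` in amperes.
#' @param table Autorange table bounding the feasible amplitude span.
#' @return The updated `control_state`.
#' @export
update_amplitude <- function(state, measured_current_a,
                             table = feedback_table()) {
  stopifnot(inherits(state, "control_state"))
  if (!is.finite(measured_current_a) || measured_current_a <= 0)
    stop("no current sensed (IL <= 0): open circuit?")
  a_new <- state$amplitude_v * state$desired_current_a / measured_current_a
  lo <- table$lower_v[1]
  hi <- table$upper_v[nrow(table)]
  clipped <- FALSE
  if (a_new < lo) { a_new <- lo; clipped <- TRUE }
  if (a_new >= hi) { a_new <- hi - 1e-9; clipped <- TRUE }
  state$amplitude_v <- a_new
  state$period_index <- state$period_index + 1L
  state$clipped <- clipped
  state
}

#' Simulate the closed current-amplitude loop on a resistive load
#'
#' Per period: the requested amplitude selects a feedback resistance
#' (autorange), one quantized cosine period is synthesized, the true load
#' current follows Ohm's law through load plus shunt, the shunt voltage is
#' read at the sample of maximum `|S_i|` and digitized by the SAR ADC, and
#' the amplitude law is applied.
#'
#' @param desired_current_a Setpoint `Id` in amperes.
#' @param circuit A [load_circuit()]; `rl_ohm` may be a vector of length
#'   `n_periods` to change the load mid-run.
#' @param cfg A [dds_config()].
#' @param n_periods Number of periods to simulate (at least 2).
#' @param table Autorange table.
#' @return A `data.frame` (class `eit_loop_trace`) with one row per period:
#'   `period`, `amplitude_v` (requested, after clamping), `rf_kohm`,
#'   `current_true_a` (actual load-current amplitude), `current_meas_a`
#'   (ADC-sensed amplitude), `clipped`.
#' @examples
#' tr <- simulate_closed_loop(0.98e-3, load_circuit(1000), n_periods = 4)
#' tr$current_true_a[2] * 1e3  # ~0.98 mA from the second period on
#' @export
simulate_closed_loop <- function(desired_current_a, circuit,
                                 cfg = dds_config(), n_periods = 10L,
                                 table = feedback_table()) {
  stopifnot(inherits(circuit, "load_circuit"), n_periods >= 2L)
  rl <- rep_len(circuit$rl_ohm, n_periods)
  peak_idx <- which.max(abs(cos(2 * pi * (0:(cfg$samples_per_period - 1L)) /
                                  cfg$samples_per_period)))
  st <- control_state(1, desired_current_a)
  out <- data.frame(period = integer(n_periods), amplitude_v = numeric(n_periods),
                    rf_kohm = numeric(n_periods),
                    current_true_a = numeric(n_periods),
                    current_meas_a = numeric(n_periods),
                    clipped = logical(n_periods))
  for (k in seq_len(n_periods)) {
    a <- st$amplitude_v
    rf <- select_feedback_resistor(a, table)
    sp <- quantize_period(a, rf, cfg)
    r_tot <- rl[k] + circuit$shunt_ohm
    i_true <- sp$load_voltage_v[peak_idx] / r_tot
    v_shunt <- adc_quantize(i_true * circuit$shunt_ohm,
                            circuit$adc_bits, circuit$adc_range_v)
    i_meas <- v_shunt / circuit$shunt_ohm
    out$period[k] <- k - 1L
    out$amplitude_v[k] <- a
    out$rf_kohm[k] <- rf
    out$current_true_a[k] <- i_true
    out$current_meas_a[k] <- i_meas
    out$clipped[k] <- st$clipped
    st <- update_amplitude(st, i_meas, table)
  }
  if (all(c(out$clipped[-1], st$clipped)))
    stop("unreachable setpoint: requested amplitude outside the autorange span in every period")
  class(out) <- c("eit_loop_trace", class(out))
  out
}

#' RMS demodulation of a measured waveform
#'
#' Root of the mean squared sample value over whole signal periods — the
#' digital stand-in for the instrument's amplitude demodulator.
#'
#' @param waveform Numeric samples covering a positive whole number of
#'   periods.
#' @param samples_per_period Samples per period (default 55).
#' @return RMS value in the units of `waveform`.
#' @examples
#' rms_demodulate(cos(2 * pi * (0:54) / 55))  # ~1/sqrt(2)
#' @export
rms_demodulate <- function(waveform, samples_per_period = 55L) {
  n <- length(waveform)
  if (n == 0L) stop("empty waveform")
  if (n %% samples_per_period != 0L)
    stop("waveform length must be a whole number of periods")
  sqrt(mean(waveform^2))
}
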