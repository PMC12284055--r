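# Quantized direct digital synthesis: dual current-DAC cosine generation,
# trans-impedance conversion and feedback-resistor autoranging.

#' DDS configuration
#'
#' Settings of the dual-IDAC direct digital synthesizer: two 8-bit
#' current-output DACs generate the positive and negative half-waves of a
#' cosine, which trans-impedance amplifiers convert to a bipolar load voltage.
#'
#' @param samples_per_period Integer, register updates per signal period
#'   (default 55).
#' @param idac_full_scale_ua Full-scale IDAC output current in microamperes
#'   when the register holds `register_max` (default 31.875).
#' @param register_bits Width of the IDAC register in bits (default 8, so
#'   registers span 0..255).
#' @param signal_frequency_hz Synthesized signal frequency in Hz; the device
#'   operates between 2 Hz and 50 kHz (default 50000).
#' @param reference_voltage_v Optional fixed TIA reference voltage `Vr` in
#'   volts.  When `NULL` (default) `Vr` is chosen per period as
#'   `R_fb * idac_full_scale + 0.1 V`, which guarantees both amplifier
#'   outputs stay positive (single-supply feasibility).
#'
#' @return An object of class `dds_config`.
#' @examples
#' cfg <- dds_config()
#' cfg$register_max  # 255
#' @export
dds_config <- function(samples_per_period = 55L,
                       idac_full_scale_ua = 31.875,
                       register_bits = 8L,
                       signal_frequency_hz = 50000,
                       reference_voltage_v = NULL) {
  samples_per_period <- as.integer(samples_per_period)
  register_bits <- as.integer(register_bits)
  stopifnot(samples_per_period >= 2L,
            idac_full_scale_ua > 0,
            register_bits >= 1L)
  if (signal_frequency_hz < 2 || signal_frequency_hz > 50000)
    stop("signal_frequency_hz must lie in [2, 50000] Hz")
  structure(list(
    samples_per_period = samples_per_period,
    idac_full_scale_ua = idac_full_scale_ua,
    register_bits = register_bits,
    register_max = 2L^register_bits - 1L,
    signal_frequency_hz = signal_frequency_hz,
    reference_voltage_v = reference_voltage_v
  ), class = "dds_config")
}

#' Feedback-resistor autorange table
#'
#' The feedback resistance `R_fb` of the trans-impedance stage is switched
#' with the requested output amplitude so that the IDAC registers always use
#' their upper bits: small amplitudes at a fixed `R_fb` would exercise only
#' the low bits and distort the cosine.  Rows are half-open voltage intervals
#' `[lower_v, upper_v)` with the resistance (in kilo-ohms) used inside each.
#'
#' @return A `data.frame` with columns `lower_v`, `upper_v`, `rf_kohm`.
#' @export
feedback_table <- function() {
  tab <- data.frame(
    lower_v = c(0.15, 0.6375, 0.95625, 1.275, 2.55, 3.825),
    upper_v = c(0.6375, 0.95625, 1.275, 2.55, 3.825, 4.625),
    rf_kohm = c(20, 30, 40, 80, 120, 250)
  )
  tab
}

.validate_feedback_table <- function(tab) {
  stopifnot(is.data.frame(tab),
            all(c("lower_v", "upper_v", "rf_kohm") %in% names(tab)))
  if (any(diff(tab$lower_v) <= 0) || any(diff(tab$rf_kohm) <= 0))
    stop("feedback table rows must be sorted with strictly increasing R_fb")
  if (any(abs(tab$upper_v[-nrow(tab)] - tab$lower_v[-1]) > 1e-12))
    stop("feedback table intervals must be contiguous")
  invisible(tab)
}

#' Select the feedback resistance for a requested amplitude
#'
#' @param v_volts Requested load-voltage amplitude in volts.
#' @param table Autorange table, see [feedback_table()].
#' @return Feedback resistance in kilo-ohms.
#' @examples
#' select_feedback_resistor(0.5)  # 20
#' select_feedback_resistor(4.0)  # 250
#' @export
select_feedback_resistor <- function(v_volts, table = feedback_table()) {
  .validate_feedback_table(table)
  lo <- table$lower_v[1]
  hi <- table$upper_v[nrow(table)]
  if (length(v_volts) != 1L || !is.finite(v_volts) ||
      v_volts < lo || v_volts >= hi)
    stop(sprintf("amplitude %s V outside the autorange span [%g, %g) V",
                 format(v_volts), lo, hi))
  row <- which(v_volts >= table$lower_v & v_volts < table$upper_v)
  table$rf_kohm[row[1]]
}

# Floor with a one-part-per-billion guard: register scale factors such as
# 255*V/(31.875e-6*R) land exactly on integers for the tabulated interval
# bounds and must not be pushed down a step by binary rounding.
.floor_register <- function(x) floor(x + 1e-9)

#' IDAC output current for a register value
#'
#' Linear 8-bit DAC law: register 0 gives 0 uA, `register_max` gives the
#' full-scale current.
#'
#' @param register Integer register value(s) in `0..register_max`.
#' @param cfg A [dds_config()].
#' @return Current(s) in microamperes.
#' @examples
#' idac_current(255)  # 31.875
#' idac_current(128)  # 16
#' @export
idac_current <- function(register, cfg = dds_config()) {
  if (any(register != round(register)) ||
      any(register < 0) || any(register > cfg$register_max))
    stop(sprintf("register must be an integer in [0, %d]", cfg$register_max))
  register * cfg$idac_full_scale_ua / cfg$register_max
}

#' Quantize one cosine period into dual IDAC register sequences
#'
#' For a requested amplitude `V` and feedback resistance `R_fb`, the sample
#' table is `S_i = cos(2 i pi / n)` and the registers are
#' `D_i(+/-) = floor(register_max * V / (full_scale * R_fb) * max(0, +/-S_i))`,
#' one DAC carrying the positive half-wave and the other the negative.  The
#' synthesized load voltage follows the trans-impedance law
#' `VL_i = R_fb * (I2_i - I1_i)`.
#'
#' @param v_volts Requested amplitude in volts.
#' @param rf_kohm Feedback resistance in kilo-ohms (normally from
#'   [select_feedback_resistor()]).
#' @param cfg A [dds_config()].
#' @return An object of class `sampled_period`: list with integer vectors
#'   `registers_plus`, `registers_minus`, numeric `load_voltage_v`,
#'   `rf_kohm`, `scale` (the pre-floor register scale factor) and logical
#'   `saturated` (scale exceeded `register_max` by more than 1 LSB; registers
#'   are clipped).
#' @examples
#' sp <- quantize_period(0.6375, 20)
#' max(sp$registers_plus)  # 255
#' @export
quantize_period <- function(v_volts, rf_kohm, cfg = dds_config()) {
  stopifnot(v_volts > 0, rf_kohm > 0)
  n <- cfg$samples_per_period
  s <- cos(2 * pi * (0:(n - 1L)) / n)
  scale <- cfg$register_max * v_volts /
    (cfg$idac_full_scale_ua * 1e-6 * rf_kohm * 1e3)
  saturated <- scale > cfg$register_max + 1
  dp <- .floor_register(scale * pmax(0, s))
  dm <- .floor_register(scale * pmax(0, -s))
  dp <- pmin(dp, cfg$register_max)
  dm <- pmin(dm, cfg$register_max)
  i2 <- idac_current(dp, cfg) * 1e-6   # positive half-wave DAC, amperes
  i1 <- idac_current(dm, cfg) * 1e-6   # negative half-wave DAC
  vl <- rf_kohm * 1e3 * (i2 - i1)
  structure(list(
    registers_plus = as.integer(dp),
    registers_minus = as.integer(dm),
    load_voltage_v = vl,
    rf_kohm = rf_kohm,
    scale = scale,
    saturated = saturated
  ), class = "sampled_period")
}

#' @export
print.sampled_period <- function(x, ...) {
  cat(sprintf("<sampled_period> %d samples, R_fb = %g kOhm, peak register %d%s\n",
              length(x$registers_plus), x$rf_kohm,
              max(x$registers_plus, x$registers_minus),
              if (x$saturated) " (saturated)" else ""))
  invisible(x)
}

#' Trans-impedance stage output voltages
#'
#' Both amplifiers reference `Vr`; their outputs are `Va = Vr - R_fb * I1`
#' and `Vb = Vr - R_fb * I2`, and the bipolar load voltage is their
#' difference `VL = R_fb * (I2 - I1)`, independent of `Vr`.  The single
#' positive supply requires `Vr > R_fb * max(I1, I2)` so that both outputs
#' stay positive.
#'
#' @param i1_ua,i2_ua Currents of the two IDACs in microamperes.
#' @param rf_kohm Feedback resistance in kilo-ohms.
#' @param vr_volts Reference voltage in volts.
#' @return List with `va_v`, `vb_v`, `vl_v` (volts), vectorized over samples.
#' @examples
#' tia_output(31.875, 0, 20, 1.0)$vl_v  # -0.6375
#' @export
tia_output <- function(i1_ua, i2_ua, rf_kohm, vr_volts) {
  need <- rf_kohm * 1e3 * max(i1_ua, i2_ua) * 1e-6
  if (vr_volts <= need)
    stop(sprintf("Vr = %g V infeasible: needs Vr > %g V for positive outputs",
                 vr_volts, need))
  va <- vr_volts - rf_kohm * 1e3 * i1_ua * 1e-6
  vb <- vr_volts - rf_kohm * 1e3 * i2_ua * 1e-6
  list(va_v = va, vb_v = vb, vl_v = va - vb)
}

#' Total harmonic distortion of a sampled waveform
#'
#' Discrete Fourier decomposition of whole periods; distortion is the RMS of
#' all non-fundamental, non-DC content divided by the fundamental RMS.
#'
#' @param waveform Numeric samples covering an integer number of periods.
#' @param samples_per_period Samples per signal period.
#' @return THD as a dimensionless ratio.
#' @export
waveform_thd <- function(waveform, samples_per_period = 55L) {
  n <- length(waveform)
  if (n == 0L || n %% samples_per_period != 0L)
    stop("waveform length must be a positive multiple of samples_per_period")
  cycles <- n %/% samples_per_period
  x <- stats::fft(waveform)
  p <- Mod(x)^2
  fund_bin <- cycles + 1L                # 1 cycle per period
  half <- 2:ceiling((n + 1) / 2)         # skip DC, use unique spectrum half
  fund <- p[fund_bin]
  if (fund <= 0) stop("no fundamental component present")
  rest <- sum(p[setdiff(half, fund_bin)])
  sqrt(rest / fund)
}
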