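# Quantized synthesis chain: autoranging, register quantization, TIA law.

test_that("autorange table lookup returns the tabulated resistance", {
  expect_equal(select_feedback_resistor(0.5), 20)
  expect_equal(select_feedback_resistor(1.0), 40)
  expect_equal(select_feedback_resistor(4.0), 250)
  # interval bounds are half-open [lower, upper)
  expect_equal(select_feedback_resistor(0.6375), 30)
  expect_error(select_feedback_resistor(0.1), "autorange span")
  expect_error(select_feedback_resistor(4.625), "autorange span")
})

test_that("IDAC law is linear from 0 to full scale", {
  expect_equal(idac_current(0), 0)
  expect_equal(idac_current(255), 31.875)
  expect_equal(idac_current(128), 16.0)  # 128 * 31.875 / 255 by hand
  expect_error(idac_current(256), "register")
  expect_error(idac_current(-1), "register")
  expect_error(idac_current(2.5), "register")
})

test_that("quantizer reproduces the autorange register columns", {
  # lower and upper register bound of every autorange interval
  tab <- feedback_table()
  lower_regs <- c(60, 170, 191, 127, 170, 122)
  upper_regs <- c(255, 255, 255, 255, 255, 148)
  for (r in seq_len(nrow(tab))) {
    sp_lo <- quantize_period(tab$lower_v[r], tab$rf_kohm[r])
    sp_hi <- quantize_period(tab$upper_v[r] - 1e-12, tab$rf_kohm[r])
    expect_equal(max(sp_lo$registers_plus), lower_regs[r])
    expect_equal(max(sp_hi$registers_plus), upper_regs[r])
  }
  # the quantizer floors (1.275 V at 80 kOhm gives 127.5 -> 127, not 128)
  expect_equal(max(quantize_period(1.275, 80)$registers_plus), 127)
})

test_that("quantized period has one-sided registers and consistent voltage", {
  sp <- quantize_period(0.98, 40)
  n <- length(sp$registers_plus)
  expect_equal(n, 55L)
  expect_equal(length(sp$registers_minus), 55L)
  # cos(0) = 1: first sample fully on the positive DAC
  expect_equal(sp$registers_minus[1], 0L)
  expect_gt(sp$registers_plus[1], 0L)
  # at most one register nonzero per sample
  expect_true(all(sp$registers_plus == 0 | sp$registers_minus == 0))
  expect_true(all(sp$registers_plus >= 0 & sp$registers_plus <= 255))
  # load voltage follows the TIA law sample by sample
  vl <- 40e3 * (idac_current(sp$registers_plus) -
                  idac_current(sp$registers_minus)) * 1e-6
  expect_equal(sp$load_voltage_v, vl)
  expect_false(sp$saturated)
  # a request far beyond the interval saturates and clips
  sp_sat <- quantize_period(2.0, 20)
  expect_true(sp_sat$saturated)
  expect_true(all(sp_sat$registers_plus <= 255))
})

test_that("register ceiling below 0.16 V at 20 kOhm uses only 6 bits", {
  vs <- seq(0.15, 0.16 - 1e-9, by = 1e-4)
  ceiling_reg <- max(vapply(vs, function(v)
    max(quantize_period(v, 20)$registers_plus), numeric(1)))
  expect_equal(ceiling_reg, 63)
})

test_that("distortion falls as the register ceiling rises (autorange rationale)", {
  ceilings <- c(63, 127, 170, 191, 255)
  v <- ceilings / 255 * 0.6375
  thd <- vapply(v, function(vv)
    waveform_thd(quantize_period(vv, 20)$load_voltage_v), numeric(1))
  expect_true(all(diff(thd) < 0))
})

test_that("TIA outputs obey the subtraction law and feasibility bound", {
  out <- tia_output(31.875, 0, 20, 1.0)
  expect_equal(out$vl_v, -0.6375)           # Vl = Rf (I2 - I1), by hand
  expect_equal(tia_output(10, 10, 40, 1)$vl_v, 0)
  expect_true(out$va_v > 0 && out$vb_v > 0)
  expect_error(tia_output(31.875, 0, 20, 0.5), "infeasible")
})

test_that("config constructor enforces its invariants", {
  expect_equal(dds_config()$register_max, 255L)
  expect_error(dds_config(samples_per_period = 1))
  expect_error(dds_config(signal_frequency_hz = 1e6), "50000")
})
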