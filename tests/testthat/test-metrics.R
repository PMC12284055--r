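# Channel SNR/accuracy statistics and the global-impedance index.

test_that("SNR matches the Monte-Carlo closed form and is scale invariant", {
  set.seed(7)
  fr <- acquire_frames(rep(1, 40), noise_model(1e-3), 10000)
  st <- snr_stats(fr)
  # 20*log10(1 / 0.001) = 60 dB
  expect_equal(st$summary[["median"]], 60, tolerance = 0.5 / 60)
  fr10 <- lapply(fr, function(f) eit_frame(10 * f$values, f$label, f$index))
  expect_equal(snr_stats(fr10)$snr_db, st$snr_db, tolerance = 1e-10)
  expect_error(snr_stats(fr[1]), "at least 2")
})

test_that("variance-denominator reading is exposed alongside sd", {
  set.seed(8)
  fr <- acquire_frames(rep(1, 40), noise_model(1e-2), 200)
  s_sd <- snr_stats(fr, denominator = "sd")
  s_var <- snr_stats(fr, denominator = "variance")
  # the variance reading divides by sd^2 instead of sd
  expect_equal(s_var$snr_db,
               20 * log10(abs(s_sd$mean_v) / s_sd$dispersion_v^2),
               tolerance = 1e-10)
})

test_that("accuracy follows the relative-bias formula", {
  truth <- seq(0.5, 2, length.out = 40)
  exact <- acquire_frames(truth, noise_model(0), 5)
  expect_equal(accuracy_stats(exact, truth)$accuracy_pct, rep(100, 40))
  biased <- lapply(exact, function(f) eit_frame(1.05 * f$values, f$label, f$index))
  expect_equal(accuracy_stats(biased, truth)$accuracy_pct, rep(95, 40))
  expect_error(accuracy_stats(exact, c(0, truth[-1])), "nonzero")
})

test_that("noise-free end-to-end pipeline is 100 percent accurate", {
  st <- tw_saline_state(1024)
  fr <- acquire_frames(st$vh, noise_model(0), 3)
  expect_equal(accuracy_stats(fr, st$vh)$summary[["min"]], 100)
})

test_that("global impedance sums pixels per frame and cumulatively", {
  st <- tw_saline_state(200)
  op <- build_recon_operator(st$J, st$mesh)
  zero <- apply_recon(op, rep(0, 40))
  gz <- global_impedance(list(zero, zero))
  expect_equal(gz$per_frame_sum, c(0, 0))
  expect_true(all(is.na(gz$per_frame_inv)))
  # all-ones in-disk image: sum equals the in-disk pixel count
  ones <- zero
  ones$values[ones$mask] <- 1
  g1 <- global_impedance(list(ones))
  expect_equal(g1$per_frame_sum, sum(zero$mask))
  expect_equal(g1$inv_total, 1 / sum(zero$mask))
  # cumulative GI adds frames
  g2 <- global_impedance(list(ones, ones, ones))
  expect_equal(g2$cumulative, c(1, 2, 3) * sum(zero$mask))
})

test_that("|GI|^-1 is strictly monotone in cavity size and contrast", {
  # bigger or more conductive cavities perturb more channels more strongly,
  # so the image-sum magnitude grows and its inverse falls monotonically
  fine <- tw_mesh(4200)
  pat <- tw_pattern()
  vh <- protocol_voltages(fine, apply_phantom(make_phantom("agar-homog"), fine),
                          pat, 0.98e-3)
  st <- tw_agar_state(1024)
  op <- build_recon_operator(st$J, st$mesh)
  inv_gi <- function(name, cs) {
    v <- protocol_voltages(fine, apply_phantom(make_phantom(name, cs), fine),
                           pat, 0.98e-3)
    img <- apply_recon(op, normalized_difference(vh, v))
    1 / abs(sum(img$values))
  }
  for (cs in c(1.227, 2.07)) {
    series <- c(inv_gi("agar-small", cs), inv_gi("agar-medium", cs),
                inv_gi("agar-large", cs))
    expect_true(all(diff(series) < 0))
  }
  # contrast monotonicity at fixed area
  by_contrast <- vapply(c(1.227, 1.890, 2.07), inv_gi, numeric(1),
                        name = "agar-medium")
  expect_true(all(diff(by_contrast) < 0))
})
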