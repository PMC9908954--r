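test_that("section closed forms: hollow-square second moment and area", {
  sec <- segment_section(outer = 10, wall = 1)
  expect_equal(section_second_moment(sec), (0.01^4 - 0.008^4) / 12)
  expect_equal(section_area(sec), 0.01^2 - 0.008^2)
  expect_error(segment_section(outer = 10, wall = 6), "wall")
})

test_that("a free leg produces identically zero quasi-static strain", {
  leg <- leg_model(); sec <- segment_section()
  eps <- strain_at_gauges(c(0.2, -0.4, -1), load_state(contact = FALSE),
                          leg, sec)
  expect_true(all(eps == 0))
})

test_that("gauge strain is linear in the applied force", {
  leg <- leg_model(); sec <- segment_section()
  th <- c(0.1, -0.5, -1.1)
  f1 <- strain_at_gauges(th, load_state(contact_force = c(1, 2, 5)), leg, sec)
  f2 <- strain_at_gauges(th, load_state(contact_force = 2 * c(1, 2, 5)),
                         leg, sec)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  fa <- strain_at_gauges(th, load_state(contact_force = c(1, 0, 0)), leg, sec)
  fb <- strain_at_gauges(th, load_state(contact_force = c(0, 2, 5)), leg, sec)
  expect_equal(fa + fb, f1, tolerance = 1e-12)
})

test_that("a dorsal foot force compresses the dorsal gauges; transverse opposes axial", {
  leg <- leg_model(); sec <- segment_section()
  eps <- strain_at_gauges(c(0, -0.3, -1), load_state(contact_force = c(0, 0, 8)),
                          leg, sec, poisson = 0.35)
  expect_gt(eps["tf_axial"], 0)
  expect_equal(as.numeric(eps["tf_transverse"]),
               as.numeric(-0.35 * eps["tf_axial"]))
  expect_equal(as.numeric(eps["tib_transverse"]),
               as.numeric(-0.35 * eps["tib_axial"]))
})

test_that("zero signal maps to the constant mid-range ADC code", {
  ch <- sensor_chain_params(noise_sd = 0, drift_amp = 0)
  out <- sensor_chain(rep(0, 100), ch)
  expect_true(all(out$codes == 2^ch$adc_bits / 2))
  expect_true(all(out$strain == 0))
  expect_false(out$saturated)
})

test_that("quantization step equals vref over 2^bits", {
  ch <- sensor_chain_params(noise_sd = 0, drift_amp = 0)
  lsb_strain <- (ch$vref / 2^ch$adc_bits) / (ch$bridge_sens * ch$gain)
  # a ramp spanning a few LSBs digitizes into unit-code steps
  x <- seq(0, 10 * lsb_strain, length.out = 400)
  out <- sensor_chain(x, ch)
  steps <- unique(diff(sort(unique(out$codes))))
  expect_equal(steps, 1)
})

test_that("the median filter removes single-sample spikes and keeps ramps", {
  ch <- sensor_chain_params(noise_sd = 0, drift_amp = 0)
  lsb_strain <- (ch$vref / 2^ch$adc_bits) / (ch$bridge_sens * ch$gain)
  smooth <- seq(0, 100 * lsb_strain, length.out = 200)
  spiky <- smooth; spiky[100] <- spiky[100] + 50 * lsb_strain
  a <- sensor_chain(smooth, ch); b <- sensor_chain(spiky, ch)
  # the 50-LSB spike is knocked down to at most a one-code ripple
  expect_lte(max(abs(b$codes - a$codes)), 1)
  # a monotone ramp passes through the centred median untouched away from
  # the boundaries: filtered codes equal the raw quantized codes
  raw_codes <- floor((ch$vref / 2 + smooth * ch$bridge_sens * ch$gain) /
                       (ch$vref / 2^ch$adc_bits))
  mid <- 20:180
  expect_equal(a$codes[mid], raw_codes[mid])
  # and the filter is idempotent there
  expect_equal(stats::runmed(a$codes, ch$window)[mid], a$codes[mid],
               ignore_attr = TRUE)
})

test_that("saturation beyond the ADC range is clipped and flagged", {
  ch <- sensor_chain_params(noise_sd = 0, drift_amp = 0)
  big <- rep(1, 50)   # 1 unit strain -> 100 V, far past vref
  out <- sensor_chain(big, ch)
  expect_true(out$saturated)
  expect_true(all(out$codes <= 2^ch$adc_bits - 1))
})

test_that("sensor noise is deterministic under a seed and leaves the RNG alone", {
  ch <- sensor_chain_params()
  a <- sensor_chain(rep(0, 500), ch, seed = 5)
  set.seed(99); before <- stats::runif(1)
  b <- sensor_chain(rep(0, 500), ch, seed = 5)
  set.seed(99); after <- stats::runif(1)
  expect_identical(a$codes, b$codes)
  expect_identical(before, after)
})

test_that("stepping record structure, phases and ground-truth markers", {
  rec <- baseline_3step()
  expect_s3_class(rec, "strain_record")
  expect_equal(nrow(rec), 3 * 240)
  expect_equal(attr(rec, "onsets"), c(0, 4, 8))
  expect_equal(attr(rec, "offsets"), c(3, 7, 11))
  expect_false(attr(rec, "saturated"))
  # quasi-static silence in swing (pre-noise channel)
  raw <- attr(rec, "raw")
  expect_true(all(raw[rec$phase == "swing", ] == 0))
})

test_that("consecutive steps are identical when the chain is noiseless", {
  rec <- simulate_stepping(n_steps = 3, chain = quiet_chain())
  m <- as.matrix(rec[, c("tf_axial", "tf_transverse", "tib_axial",
                         "tib_transverse")])
  step1 <- m[1:240, ]; step2 <- m[241:480, ]; step3 <- m[481:720, ]
  expect_equal(step2, step1, ignore_attr = TRUE)
  expect_equal(step3, step1, ignore_attr = TRUE)
})

test_that("an unloaded leg steps with near-zero strain", {
  rec <- simulate_stepping(carriage_mass = 0, n_steps = 2,
                           chain = quiet_chain())
  expect_lt(max(abs(rec$tf_axial)), 1e-5)
})

test_that("added mass raises strain amplitude but preserves its shape", {
  base <- simulate_stepping(n_steps = 2, chain = quiet_chain())
  heavy <- simulate_stepping(n_steps = 2, added_mass = 1.0,
                             chain = quiet_chain())
  r <- max(heavy$tf_axial) / max(base$tf_axial)
  expect_equal(r, (0.8 + 1.0) / 0.8, tolerance = 0.05)
  # shape preserved over the loaded part of stance (the touchdown/lift-off
  # transfer ramps legitimately lengthen with mass and are excluded)
  tc <- base$t %% 4
  loaded <- base$phase == "stance" & tc > 0.3 & tc < 2.7
  expect_gt(stats::cor(base$tf_axial[loaded], heavy$tf_axial[loaded]), 0.98)
  expect_gt(stats::cor(base$tib_axial[loaded], heavy$tib_axial[loaded]),
            0.98)
})

test_that("the trochanterofemoral axial channel carries the largest strain", {
  rec <- baseline_3step()
  peaks <- vapply(c("tf_axial", "tf_transverse", "tib_axial",
                    "tib_transverse"),
                  function(ch) max(abs(rec[[ch]])), 0)
  expect_equal(names(which.max(peaks)), "tf_axial")
})

test_that("strain record validation catches malformed input", {
  expect_error(strain_record(1:5, rep("stance", 4), 1:5, 1:5, 1:5, 1:5),
               "length")
  expect_error(strain_record(1:4, rep("airborne", 4), 1:4, 1:4, 1:4, 1:4),
               "phase")
})
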