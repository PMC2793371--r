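test_that("principal projection recovers rank-one structure exactly", {
  w <- sin(2 * pi * 3 * seq(0, 2, by = 0.01))
  v <- c(0.5, 1, 2, 0.25)
  rec <- eeg_recording(v %o% w, 100)
  s <- principal_projection(rec)
  expect_equal(s$variance_explained, 1, tolerance = 1e-12)
  # series proportional to the temporal pattern (centred)
  wc <- w - mean(w)
  expect_gt(abs(cor(s$series, wc)), 1 - 1e-10)
  expect_equal(sqrt(sum(s$eigenvector^2)), 1, tolerance = 1e-12)
  # deterministic sign: largest-magnitude loading positive
  expect_gt(s$eigenvector[which.max(abs(s$eigenvector))], 0)
  expect_error(principal_projection(eeg_recording(matrix(0, 3, 10), 100)),
               "rank 0")
})

test_that("the first component loads on the simulated posterior topography", {
  s <- fx$scalp
  topo <- fx$params$topography
  expect_gt(abs(cor(abs(s$eigenvector), topo)), 0.9)
  post <- names(s$eigenvector) %in% eegbold:::posterior_channels
  expect_gt(min(abs(s$eigenvector[post])), max(abs(s$eigenvector[!post])))
})

test_that("no random projection beats the principal one (brute force)", {
  set.seed(31)
  Y <- matrix(rnorm(8 * 200), 8, 200) +
    c(1, 2, 1, 0, 0, 1, 3, 1) %o% rnorm(200, sd = 2)
  rec <- eeg_recording(Y, 100)
  s <- principal_projection(rec)
  Yc <- Y - rowMeans(Y)
  v_best <- var(s$series)
  for (i in 1:1000) {
    u <- rnorm(8); u <- u / sqrt(sum(u^2))
    expect_lte(var(drop(crossprod(u, Yc))), v_best + 1e-10)
  }
  # removing the first component strictly shrinks the Frobenius norm
  u1 <- s$eigenvector
  resid <- Yc - u1 %o% drop(crossprod(u1, Yc))
  expect_lt(sum(resid^2), sum(Yc^2))
})

test_that("Morlet power locates tones and obeys the amplitude-power law", {
  tt <- seq(0, 8, by = 1 / 250)
  P0 <- morlet_power(numeric(500), 250)
  expect_true(all(P0$power == 0))

  P1 <- morlet_power(sin(2 * pi * 10 * tt), 250)
  im <- eegbold:::interior_mean_power(P1)
  expect_equal(P1$freqs[which.max(im)], 10)
  # closed-form interior power of a unit tone: sqrt(pi) * sigma_t / 2
  expect_equal(im[10], sqrt(pi) * (7 / (2 * pi * 10)) / 2, tolerance = 1e-3)

  # unit-energy normalisation: equal-amplitude tones at 5 and 20 Hz have
  # power in ratio 20/5 = 4 (power scales as 1/f)
  P2 <- morlet_power(sin(2 * pi * 5 * tt) + sin(2 * pi * 20 * tt), 250)
  im2 <- eegbold:::interior_mean_power(P2)
  expect_equal(im2[P2$freqs == 5] / im2[P2$freqs == 20], 4, tolerance = 0.02)

  # scaling the signal by a scales power by a^2
  x <- rnorm(5000)
  Pa <- morlet_power(3 * x, 250)
  Pb <- morlet_power(x, 250)
  expect_equal(Pa$power, 9 * Pb$power, tolerance = 1e-10)
  # adding a DC offset leaves the power essentially unchanged away from
  # the record boundaries (the wavelets have near-zero DC gain; the
  # zero-padded edges see the offset as a step, hence the exclusion out
  # to the full kernel half-width)
  Pc <- morlet_power(x + 5, 250)
  n <- ncol(Pb$power)
  dmax <- 0
  for (j in seq_along(Pb$freqs)) {
    h <- min(ceiling(4 * (7 / (2 * pi * Pb$freqs[j])) * 250) + 1L, n %/% 3)
    idx <- (h + 1L):(n - h)
    dmax <- max(dmax, max(abs(Pc$power[j, idx] - Pb$power[j, idx])))
  }
  expect_lt(dmax, 0.005 * max(Pb$power))

  expect_error(morlet_power(x, 250, freqs = c(0, 5)), "invalid parameter")
  expect_error(morlet_power(x, 250, freqs = c(5, 130)), "invalid parameter")
})

test_that("global field power is reference-free and matches hand values", {
  Y <- rbind(c(1, 2, 0), c(-1, 2, 0))
  rec <- eeg_recording(Y, 100)
  expect_equal(global_field_power(rec), c(1, 0, 0))
  # identical electrodes -> zero everywhere
  rec2 <- eeg_recording(rbind(1:5, 1:5, 1:5) * 1.0, 100)
  expect_equal(global_field_power(rec2), rep(0, 5))
  # re-referencing invariance: any common per-sample offset
  set.seed(8)
  Y3 <- matrix(rnorm(4 * 50), 4, 50)
  off <- rnorm(50)
  g1 <- global_field_power(eeg_recording(Y3, 100))
  g2 <- global_field_power(eeg_recording(sweep(Y3, 2, off, "+"), 100))
  expect_equal(g1, g2, tolerance = 1e-12)
  expect_error(eeg_recording(matrix(1:5, 1), 100), "2 electrode")
})

test_that("steady-state spectra peak at the second harmonic", {
  sv <- compute_ssver(fx$rec, "O2")
  for (e in sv) {
    expect_lte(abs(e$peak_frequency - 2 * e$frequency), 0.5)
  }
  # zero-signal recording gives an all-zero response
  quiet <- simulate_eeg(fx$protocol, eeg_sim_params(
    ssver_amplitude = 0, alpha_power_rest = 0, alpha_power_task = 0,
    noise_sd = 0, seed = 1))
  sv0 <- compute_ssver(quiet, "O2")
  expect_true(all(vapply(sv0, function(e) max(abs(e$epoch)), 1) == 0))
  expect_error(compute_ssver(fx$rec, "O2", window = 20),
               "window")
  expect_error(compute_ssver(fx$rec, "nope"), "channel")
})

test_that("averaging across independent blocks suppresses noise like 1/N", {
  # same flicker frequency in every block, signal off, white background
  # noise: the averaged epoch is pure averaged noise, whose mean-square
  # falls as 1/(number of independent blocks) -- so going from 2 to 16
  # blocks should reduce it about 8-fold (a factor-2 band absorbs the
  # chi-square spread of single mean-square estimates)
  resid_power <- function(n_blocks, seed) {
    p <- stim_protocol(rep(10, n_blocks))
    rec <- simulate_eeg(p, eeg_sim_params(ssver_amplitude = 0,
                                          alpha_power_rest = 0,
                                          alpha_power_task = 0,
                                          noise_sd = 1,
                                          one_over_f_exponent = 0,
                                          seed = seed))
    sv <- compute_ssver(rec, "O2")
    mean(sv[["10"]]$epoch^2)
  }
  p2 <- mean(vapply(101:103, function(s) resid_power(2, s), 1))
  p16 <- mean(vapply(101:103, function(s) resid_power(16, s), 1))
  expect_gt(p2 / p16, 4)
  expect_lt(p2 / p16, 16)
})
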