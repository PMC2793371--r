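test_that("the canonical basis has the expected shape and orthogonality", {
  b <- canonical_hrf_basis(0.1)
  expect_equal(ncol(b$kernels), 3L)
  expect_equal(b$times[which.max(b$kernels[, 1])], 5, tolerance = 0.05)
  expect_gt(max(b$kernels[, 1]), 0)
  expect_lt(abs(sum(b$kernels[, 1] * b$kernels[, 2])), 1e-10)
  expect_lt(abs(sum(b$kernels[, 1] * b$kernels[, 3])), 1e-10)
  expect_true(all(is.finite(b$kernels)))
  # refinement: the dt/2 basis agrees with the dt basis on shared points
  b2 <- canonical_hrf_basis(0.05)
  shared <- seq(1, nrow(b2$kernels), by = 2)
  expect_equal(b2$kernels[shared, 1], b$kernels[, 1], tolerance = 0.01)
  expect_error(canonical_hrf_basis(0), "invalid parameter")
})

test_that("convolution reproduces impulse responses and a dense oracle", {
  rate <- 50
  basis <- canonical_hrf_basis(1 / rate)
  n_feat <- 100 * rate   # 100 s
  TR <- 2
  n_scans <- 50L

  # impulse at t0: the canonical column is the HRF shifted to t0
  t0 <- 10
  imp <- numeric(n_feat)
  imp[t0 * rate + 1] <- 1
  q <- regressor_set(imp, "M", rate)
  X <- convolve_and_downsample(q, basis, TR, n_scans, center = FALSE)
  tk <- (seq_len(n_scans) - 0.5) * TR
  expected <- numeric(n_scans)
  inside <- tk >= t0 & tk < t0 + 32
  expected[inside] <- basis$kernels[round((tk[inside] - t0) * rate) + 1, 1] / rate
  expect_equal(X[, "M.M.canonical"], expected, tolerance = 1e-8)

  # constant input: once past the causal onset transient (one kernel
  # length) the convolution is constant, so the steady-state portion of a
  # centred-on-steady-state column is zero
  qc <- regressor_set(rep(2.5, n_feat), "M", rate)
  Xc <- convolve_and_downsample(qc, basis, TR, n_scans, center = FALSE)
  ss <- tk > 32
  expect_lt(diff(range(Xc[ss, "M.M.canonical"])), 1e-10)
  expect_lt(max(abs(Xc[ss, ] - rep(colMeans(Xc[ss, , drop = FALSE]),
                                   each = sum(ss)))), 1e-10)

  # boxcar train against an independent direct-sum convolution
  tt <- (seq_len(n_feat) - 1) / rate
  box <- as.numeric(tt %% 30 < 15)
  qb <- regressor_set(box, "M", rate)
  Xb <- convolve_and_downsample(qb, basis, TR, n_scans, center = FALSE)
  dense <- numeric(n_feat)
  k <- basis$kernels[, 1]
  for (i in seq_along(k)) {
    idx <- seq_len(n_feat - i + 1)
    dense[idx + i - 1] <- dense[idx + i - 1] + box[idx] * k[i] / rate
  }
  oracle <- dense[round(tk * rate) + 1]
  expect_equal(Xb[, "M.M.canonical"], oracle, tolerance = 1e-6)

  expect_error(convolve_and_downsample(q, basis, TR, 1000L),
               "length mismatch")
})

test_that("halving the feature rate barely changes scan-rate regressors", {
  dur <- 200
  t250 <- seq(0, dur, by = 1 / 250)
  t125 <- seq(0, dur, by = 1 / 125)
  sig <- function(t) sin(2 * pi * 0.05 * t) + 0.5 * cos(2 * pi * 0.11 * t)
  q1 <- regressor_set(sig(t250), "M", 250)
  q2 <- regressor_set(sig(t125), "M", 125)
  X1 <- convolve_and_downsample(q1, canonical_hrf_basis(1 / 250), 3.06, 60L)
  X2 <- convolve_and_downsample(q2, canonical_hrf_basis(1 / 125), 3.06, 60L)
  rel <- sqrt(mean((X1[, 1] - X2[, 1])^2)) / sd(X1[, 1])
  expect_lt(rel, 0.01)
})

test_that("the high-pass projection removes slow and keeps fast components", {
  tk <- ((1:256) - 0.5) * 2   # 256 scans at TR 2 s
  slow <- cos(2 * pi * tk / 256)
  fast <- cos(2 * pi * tk / 32)
  expect_lt(max(abs(highpass(slow, TR = 2))), 1e-10)
  expect_equal(drop(highpass(fast, TR = 2)), fast, tolerance = 0.02)
  expect_lt(max(abs(highpass(rep(3, 256), TR = 2))), 1e-12)
  # cutoff boundary: the retained dimension count matches the period rule
  D <- dct_highpass_basis(256, 2, 128)
  expect_equal(ncol(D), 7L)   # periods 1024/k > 128 => k <= 7
  expect_equal(crossprod(D), diag(7), tolerance = 1e-12)
})

test_that("design assembly partitions columns and counts parameters", {
  regs <- transfer_functions(fx$P, c("TP", "FR3", "RMSF"))
  bold <- dummy_bold(fx$protocol$n_scans, n_sessions = 2)
  d <- assemble_design(regs, bold, fx$basis)
  expect_equal(ncol(d$X), ((1 + 3 + 1) * 3 + 7) * 2)
  # every column belongs to exactly one partition entry
  all_idx <- sort(unname(unlist(d$partition)))
  expect_identical(all_idx, seq_len(ncol(d$X)))
  expect_equal(length(d$partition$TP), 3L * 2L)
  expect_equal(length(d$partition$FR3), 9L * 2L)
  expect_equal(length(d$partition$confounds), 7L * 2L)
  expect_error(assemble_design(c(regs, regs["TP"]), bold, fx$basis),
               "duplicate model labels|named list")
  expect_error(assemble_design(list(), bold, fx$basis), "empty|named")
})

test_that("session blocks are independent of session order", {
  regs_a <- transfer_functions(fx$P, c("TP", "RMSF"))
  P2 <- fx$P
  P2$power <- fx$P$power[, rev(seq_len(ncol(fx$P$power)))]
  regs_b <- transfer_functions(P2, c("TP", "RMSF"))
  bold <- dummy_bold(fx$protocol$n_scans, n_sessions = 2)
  d_ab <- assemble_design(list(regs_a, regs_b), bold, fx$basis)
  d_ba <- assemble_design(list(regs_b, regs_a), bold, fx$basis)
  n <- fx$protocol$n_scans
  k <- ncol(d_ab$X) / 2
  # session 1 block of AB equals session 2 block of BA (same regressors,
  # same motion confounds are per-session so compare interest columns)
  int_cols <- 1:6   # 2 models x 3 basis functions
  expect_equal(unname(d_ab$X[1:n, int_cols]),
               unname(d_ba$X[(n + 1):(2 * n), k + int_cols]))
  expect_equal(unname(d_ab$X[(n + 1):(2 * n), k + int_cols]),
               unname(d_ba$X[1:n, int_cols]))
})
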