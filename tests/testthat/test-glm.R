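# shared fitted objects for the GLM tests
glm_fx <- local({
  regs <- transfer_functions(fx$P, c("TP", "RMSF"))
  bold <- dummy_bold(fx$protocol$n_scans, n_voxels = 8, seed = 42)
  design <- assemble_design(regs, bold, fx$basis)
  fit <- fit_glm(bold, design)
  list(regs = regs, bold = bold, design = design, fit = fit)
})

# a longer session (150 scans) where block-locked signals are detectable
fx150 <- local({
  protocol <- generate_protocol(15, seed = 15)
  rec <- simulate_eeg(protocol, eeg_sim_params(seed = 15))
  P <- morlet_power(principal_projection(rec))
  list(protocol = protocol,
       regs = transfer_functions(P, c("TP", "uRMSF", "RMSF")),
       basis = canonical_hrf_basis(1 / 250))
})

test_that("noiseless data reproduce their generating coefficients", {
  d <- glm_fx$design
  interest <- setdiff(seq_len(ncol(d$X)), d$partition$confounds)
  set.seed(1)
  beta <- numeric(ncol(d$X))
  beta[interest] <- rnorm(length(interest))
  bold0 <- glm_fx$bold
  bold0$Y <- cbind(d$X %*% beta, 2 * d$X %*% beta)
  fit0 <- fit_glm(bold0, d)
  expect_equal(unname(fit0$beta[interest, 1]), beta[interest],
               tolerance = 1e-8)
  expect_equal(unname(fit0$beta[interest, 2]), 2 * beta[interest],
               tolerance = 1e-8)
  expect_lt(max(fit0$residual_ss), 1e-16 * sum((bold0$Y)^2))
})

test_that("extra-sum-of-squares F equals an explicit reduced-model refit", {
  fit <- glm_fx$fit
  for (m in c("TP", "RMSF")) {
    fc <- f_contrast(fit, m)
    ii <- glm_fx$design$partition[[m]]
    for (v in seq_len(ncol(glm_fx$bold$Y))) {
      rss_f <- sum(lm.fit(fit$X_filtered, fit$Y_filtered[, v])$residuals^2)
      rss_r <- sum(lm.fit(fit$X_filtered[, -ii, drop = FALSE],
                          fit$Y_filtered[, v])$residuals^2)
      F_manual <- ((rss_r - rss_f) / fc$df[1]) / (rss_f / fc$df[2])
      expect_equal(fc$F[v], F_manual, tolerance = 1e-8)
    }
  }
})

test_that("a single-column F equals the squared t statistic", {
  fit <- glm_fx$fit
  col <- glm_fx$design$partition$RMSF[1]
  fc <- f_contrast(fit, col)
  expect_equal(fc$df[1], 1L)
  v <- 3
  # t statistic from lm on the filtered design, with the filter's lost
  # dimensions folded into the residual degrees of freedom
  lmfit <- lm(fit$Y_filtered[, v] ~ 0 + fit$X_filtered)
  sm <- summary(lmfit)
  tstat <- coef(sm)[paste0("fit$X_filtered",
                           colnames(fit$X_filtered)[col]), "t value"]
  scale_df <- sm$df[2] / fit$df_residual
  expect_equal(fc$F[v], tstat^2 / scale_df, tolerance = 1e-8)
})

test_that("F is invariant to reparameterisation of the tested set", {
  fit <- glm_fx$fit
  ii <- glm_fx$design$partition$TP
  f0 <- f_contrast(fit, ii)$F
  # invertibly remix the tested columns and refit
  set.seed(5)
  A <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
  d2 <- glm_fx$design
  d2$X[, ii] <- d2$X[, ii] %*% A
  f1 <- f_contrast(fit_glm(glm_fx$bold, d2), ii)$F
  expect_equal(f1, f0, tolerance = 1e-8)
})

test_that("rank deficiency is detected and degrees of freedom adjusted", {
  d <- glm_fx$design
  ii <- d$partition$TP
  d$X[, ii[2]] <- d$X[, ii[1]]   # duplicate a column
  fit <- fit_glm(glm_fx$bold, d)
  expect_equal(fit$rank, glm_fx$fit$rank - 1L)
  expect_equal(fit$df_residual, glm_fx$fit$df_residual + 1L)
  expect_true(any(fit$aliased))
  fc <- f_contrast(fit, "TP")
  expect_equal(fc$df[1], 2L)
})

test_that("testing confounds or empty sets is refused", {
  fit <- glm_fx$fit
  expect_error(f_contrast(fit, glm_fx$design$partition$confounds[1]),
               "confounds")
  expect_error(f_contrast(fit, integer(0)), "invalid parameter")
  expect_error(f_contrast(fit, 10000L), "out of range")
})

test_that("data orthogonal to the tested columns give F of zero", {
  d <- glm_fx$design
  bold0 <- glm_fx$bold
  # reduced-model span plus noise confined to the orthogonal complement of
  # the full design: the RMSF columns can explain exactly nothing
  set.seed(7)
  src <- cbind(d$X[, d$partition$confounds], d$X[, d$partition$TP])
  noise <- highpass(matrix(rnorm(nrow(src) * 2), ncol = 2),
                    d$TR, d$hp_cutoff, d$sessions)
  ortho <- qr.resid(qr(glm_fx$fit$X_filtered), noise)
  bold0$Y <- src %*% matrix(rnorm(ncol(src) * 2), ncol = 2) + ortho
  fit0 <- fit_glm(bold0, d)
  expect_lt(max(f_contrast(fit0, "RMSF")$F), 1e-8)
})

test_that("unique variance in a shared design never exceeds marginal variance", {
  # TP and the un-normalised Heuristic overlap heavily; with TP as the
  # generator both lose unique variance when placed in one design
  regs <- fx150$regs[c("TP", "uRMSF")]
  prm <- bold_sim_params("TP", n_voxels = 30, active_voxels = 1:10,
                         seed = 31)
  sim <- simulate_bold(regs$TP, fx150$protocol, prm, fx150$basis)
  shared <- compare_models(sim$bold, regs, mode = "shared")
  separate <- compare_models(sim$bold, regs, mode = "separate")
  ts_sh <- attr(shared, "tests")
  ts_se <- attr(separate, "tests")
  for (m in c("TP", "uRMSF"))
    expect_lt(max(ts_sh[[m]]$F[1:10]), max(ts_se[[m]]$F[1:10]))
  # the non-generating overlapping model retains almost nothing unique
  expect_lt(max(ts_sh$uRMSF$F[1:10]), 0.2 * max(ts_se$uRMSF$F[1:10]))
})

test_that("the activation mask finds active voxels and respects alpha", {
  prm <- bold_sim_params("RMSF", n_voxels = 60, active_voxels = 1:15,
                         seed = 17)
  sim <- simulate_bold(fx150$regs$RMSF, fx150$protocol, prm, fx150$basis)
  mask <- activation_mask(sim$bold, fx150$protocol)
  expect_gte(length(intersect(mask, 1:15)), 13)   # >= ~90% recall
  # essentially empty at a vanishing threshold
  expect_length(activation_mask(sim$bold, fx150$protocol, alpha = 1e-12), 0)
  # noise-only data: Bonferroni keeps family-wise errors near zero
  prm0 <- bold_sim_params("RMSF", coupling_gain = 0, n_voxels = 60,
                          active_voxels = integer(0), seed = 18)
  sim0 <- simulate_bold(fx150$regs$RMSF, fx150$protocol, prm0, fx150$basis)
  expect_lte(length(activation_mask(sim0$bold, fx150$protocol)), 1)
  expect_error(activation_mask(sim$bold, fx150$protocol, alpha = 2),
               "alpha")
})

test_that("AR(1) prewhitening leaves white residuals", {
  set.seed(23)
  q <- regressor_set(rnorm(round(fx150$protocol$duration * 250)), "TP", 250)
  prm <- bold_sim_params("TP", coupling_gain = 0, n_voxels = 40,
                         active_voxels = integer(0),
                         ar1_coefficient = 0.35, drift_amplitude = 0,
                         seed = 23)
  sim <- simulate_bold(q, fx150$protocol, prm)
  d <- assemble_design(list(TP = q), sim$bold)
  fit <- fit_glm(sim$bold, d, prewhiten = TRUE)
  # the pooled estimate is positive (shrunk toward zero by the projection
  # of the fit, as expected for residual-based estimators)
  expect_gt(fit$ar1_rho, 0.1)
  expect_lt(fit$ar1_rho, 0.5)
  res <- fit$Y_filtered - fit$X_filtered %*% fit$beta
  lag1 <- sum(colSums(res[-1, ] * res[-nrow(res), ])) / sum(res^2)
  expect_lt(abs(lag1), 0.08)
})
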