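# shared small fixtures, built once per test run

# 4-block protocol (40 scans, ~122 s) with a seeded low-noise EEG and its
# features; big enough for spectral structure, small enough to stay fast
fx <- local({
  protocol <- stim_protocol(c(10, 5, 7.5, 2))
  params <- eeg_sim_params(noise_sd = 1, seed = 7)
  rec <- simulate_eeg(protocol, params)
  scalp <- principal_projection(rec)
  P <- morlet_power(scalp)
  list(protocol = protocol, params = params, rec = rec,
       scalp = scalp, P = P, basis = canonical_hrf_basis(1 / 250))
})

# random tf_power matrix with positive entries on the standard grid
random_tf_power <- function(n_t = 50, freqs = 1:40, seed = 1) {
  set.seed(seed)
  structure(list(power = matrix(rexp(length(freqs) * n_t), length(freqs)),
                 freqs = freqs, times = (seq_len(n_t) - 1) / 10,
                 R = 7, sampling_rate = 10,
                 edge_half_width = rep(0L, length(freqs))),
            class = "tf_power")
}

# tf_power with all spectral mass on the rows listed in `at` (named weights)
point_mass_power <- function(at, n_t = 5, freqs = 1:40) {
  p <- matrix(0, length(freqs), n_t)
  for (f in names(at)) p[freqs == as.numeric(f), ] <- at[[f]]
  structure(list(power = p, freqs = freqs,
                 times = seq_len(n_t) - 1, R = 7, sampling_rate = 1,
                 edge_half_width = rep(0L, length(freqs))),
            class = "tf_power")
}

# quick multi-session BOLD container with seeded motion, for design tests
dummy_bold <- function(n_scans_per_session, n_sessions = 1, n_voxels = 3,
                       TR = 3.06, seed = 99) {
  set.seed(seed)
  n_total <- n_scans_per_session * n_sessions
  motion <- lapply(seq_len(n_sessions), function(i)
    matrix(rnorm(n_scans_per_session * 6, sd = 0.1),
           n_scans_per_session, 6))
  bold_dataset(matrix(rnorm(n_total * n_voxels), n_total, n_voxels),
               TR = TR, sessions = rep(seq_len(n_sessions),
                                       each = n_scans_per_session),
               motion = motion)
}
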