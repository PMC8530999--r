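# Shared fixtures, built in code.

popsd <- function(x) sqrt(mean((x - mean(x))^2))

# Small synthetic dataset with a planted component, ready for PLS.
# With noise_sd = 0 the planted support must cover every voxel, otherwise the
# unplanted columns are constant and cannot enter the PLS.
make_planted <- function(seed = 1, n_voxels = 300, effect_size = 0.5,
                         noise_sd = 1, deconfound = TRUE,
                         support_fraction = if (noise_sd == 0) 1 else 0.1) {
  coh <- generate_cohort(cohort_spec(), seed = seed)
  truth <- synthetic_truth(n_voxels, effect_size = effect_size,
                           support_fraction = support_fraction)
  sim <- generate_variability_maps(coh, truth, n_voxels,
                                   noise_sd = noise_sd, seed = seed + 1000)
  X <- if (deconfound) residualize(sim$X, encode_confounds(coh)) else sim$X
  list(cohort = coh, truth = truth, sim = sim,
       data = brain_behavior_data(X, sim$Y, coh$group))
}

# Brute-force scrubbing: expand a window around every excursion, frame by frame.
brute_scrub <- function(fd, threshold = 0.5, n_before = 1, n_after = 2) {
  T <- length(fd)
  keep <- rep(TRUE, T)
  for (t in seq_len(T)) {
    for (s in seq_len(T)) {
      if (fd[s] > threshold && t >= s - n_before && t <= s + n_after) {
        keep[t] <- FALSE
      }
    }
  }
  keep
}

# Brute-force BH: try every sorted p as the rejection threshold.
brute_bh <- function(p, q = 0.05) {
  m <- length(p)
  if (!m) return(logical(0))
  ord <- sort(p)
  ok <- which(ord <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= ord[max(ok)]
}
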