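# Small deterministic fixtures shared across the suite.  Everything is
# generated in code; nothing is read from disk except temp files a test
# writes itself.

# A tiny hemodynamic record: n_ch channels, n_t samples of seeded noise.
tiny_record <- function(n_t = 64L, n_ch = 2L, fs_hz = 25.7, seed = 42L) {
  set.seed(seed)
  hemodynamic_record(hbo = matrix(rnorm(n_t * n_ch), n_t, n_ch),
                     hbr = matrix(rnorm(n_t * n_ch), n_t, n_ch),
                     fs_hz = fs_hz, layout = default_layout(n_ch))
}

# Fast simulator settings: 2 experiments x 5 sessions x 4 blocks = 40
# blocks (20 rest / 10 right / 10 left), ~10k samples -- still deep enough
# for a 10-level decomposition.
fast_sim_config <- function(seed = 1L, ...) {
  simulation_config(n_experiments = 2L, seed = seed, ...)
}

# Simulate + denoise + segment, memoised per (seed, n_experiments) within
# a test run so several tests can share one small synthetic data set.
.sim_cache <- new.env(parent = emptyenv())
fast_trials <- function(seed = 1L, n_experiments = 2L) {
  key <- paste0("s", seed, "e", n_experiments)
  if (is.null(.sim_cache[[key]])) {
    sess <- simulate_session(simulation_config(n_experiments = n_experiments,
                                               seed = seed))
    den <- denoise_record(sess$record)
    .sim_cache[[key]] <- segment_trials(den, sess$onsets_s, sess$labels)
  }
  .sim_cache[[key]]
}

# Well-separated 3-class Gaussian feature clouds for classifier tests.
toy_clusters <- function(n_per_class = 30L, d = 8L, sep = 6, sd = 1,
                         seed = 1L) {
  set.seed(seed)
  centers <- matrix(0, 3, d)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  x <- do.call(rbind, lapply(1:3, function(cl)
    matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
      matrix(centers[cl, ], n_per_class, d, byrow = TRUE)))
  labels <- factor(rep(task_levels(), each = n_per_class),
                   levels = task_levels())
  list(x = x, labels = labels)
}
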