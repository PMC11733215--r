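# Programmatic fixtures shared across test files.

# a minimal valid meta
meta_fix <- function(id = "s1", infant = "i1", label = 1L) {
  snippet_meta(id, infant, session = "T5", label = label)
}

# constant-skeleton key-point snippet (no movement, optional offsets)
kp_fix <- function(offset = c(0, 0), meta = meta_fix()) {
  vals <- array(0, dim = c(250L, 15L, 2L))
  base <- fmfusion:::BASE_SKELETON
  for (k in 1:15) {
    vals[, k, 1L] <- base[k, 1L] + offset[1L]
    vals[, k, 2L] <- base[k, 2L] + offset[2L]
  }
  keypoint_snippet(vals, meta)
}

# pressure snippet with two moving Gaussian blobs via the simulator
sim_triple_fix <- function(label = 1L, seed = 42L, ...) {
  cfg <- sim_config(n_infants = 1L, snippets_per_infant = 1L,
                    seed = seed, ...)
  set.seed(seed)
  simulate_snippet(cfg, label, meta = meta_fix(label = label))
}

# pooled normalization stats from a handful of simulated snippets
stats_fix <- function(n = 3L, seed = 7L, ...) {
  cfg <- sim_config(n_infants = 1L, snippets_per_infant = n,
                    seed = seed, ...)
  set.seed(seed)
  triples <- lapply(seq_len(n), function(i) {
    simulate_snippet(cfg, i %% 2L, meta = meta_fix(sprintf("s%d", i)))
  })
  ds <- fm_dataset(triples)
  raw <- fmfusion:::precompute_raw(ds, c("VID", "IMU"))
  fmfusion:::fold_norm_stats(raw, seq_len(n), c("VID", "IMU"))
}

# small labeled dataset with controllable missingness
dataset_fix <- function(n_infants = 2L, snippets_per_infant = 2L,
                        seed = 5L, ...) {
  generate_dataset(sim_config(n_infants = n_infants,
                              snippets_per_infant = snippets_per_infant,
                              seed = seed, ...))
}
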