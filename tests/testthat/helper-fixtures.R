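# Shared fixtures, built in code. Small datasets are cached per session.

tiny_config <- function(...) {
  cstt_config(
    d = 8L, n_heads = 2L, n_temporal_layers = 1L, ffn_hidden = 10L,
    window = 3L, heatmap_patch = 32L, dropout = 0, ...
  )
}

random_skeleton <- function(t_f = 4L, seed = 1L) {
  withr::with_seed(seed, {
    kp <- array(runif(t_f * 17 * 2, 100, 500), c(t_f, 17L, 2L))
    skeleton_sequence(kp, matrix(runif(t_f * 17), t_f, 17L))
  })
}

random_heatmaps <- function(t_f = 4L, seed = 1L) {
  withr::with_seed(seed, heatmap_sequence(array(runif(t_f * 64 * 64), c(t_f, 64L, 64L))))
}

random_sample <- function(t_f = 6L, care_level = 2L, label = 0L, seed = 1L,
                          session_id = "s01", sample_id = "t001") {
  labeled_sample(
    random_skeleton(t_f, seed), random_heatmaps(t_f, seed + 1L),
    care_record(paste0("sub", seed), care_level), label, session_id, sample_id
  )
}

# small mixed dataset reused across file-level tests
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(generator_spec(
        n_subjects = 8L, frames = 12L, seed = 42L,
        care_level_distribution = c(0.25, 0.15, 0.3, 0.15, 0.15)
      ))
    }
    cache
  }
})
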