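# Small deterministic fixtures shared across test files.

tiny_windows <- function(n_subjects = 2L, epochs = 40L, N = 4L, Fd = 3L,
                         delta = 1.5, eta = 1.0, seed = 101L) {
  spec <- sg_synth_spec(n_subjects = n_subjects, epochs_per_subject = epochs,
                        N = N, Fd = Fd, delta = delta, eta = eta,
                        rho = 0.6, seed = seed)
  windows_from_cohort(generate_cohort(spec), d = 1L)
}

tiny_layer_input <- function(N = 4L, C = 2L, T = 3L, seed = 7L) {
  withr::with_seed(seed, array(rnorm(N * C * T), c(N, C, T)))
}
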