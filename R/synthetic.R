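#' Synthetic cohort specification
#'
#' Defines a multi-subject cohort in feature space with three controlled
#' ingredients: a class-discriminative signal shared by all subjects
#' (class mean patterns separated by `delta` within-class standard
#' deviations), a subject-specific nuisance offset (`eta`, same units)
#' that a subject-invariant model must ignore, and graph-coloured noise
#' whose channel correlations follow a known ground-truth graph. Stage
#' labels follow a first-order Markov chain with stay-probability `rho`
#' and uniform switching, emulating sleep-stage persistence.
#'
#' @param n_subjects,epochs_per_subject Cohort size.
#' @param N Channels. @param Fd Features per channel.
#' @param n_classes Stage classes (default 5).
#' @param delta Class effect size (separation of class mean patterns, in
#'   within-class sd units).
#' @param eta Subject effect size (separation of subject offsets, same
#'   units).
#' @param rho Stage persistence in `[0, 1)`.
#' @param ground_truth_graph Symmetric `N x N` adjacency shaping the noise
#'   correlation; default is a ring lattice.
#' @param seed Generation seed; the cohort is a pure function of the spec.
#' @return A list of class `sg_synth_spec`.
#' @export
sg_synth_spec <- function(n_subjects = 8L, epochs_per_subject = 400L,
                          N = 8L, Fd = 6L, n_classes = 5L,
                          delta = 2.0, eta = 1.5, rho = 0.7,
                          ground_truth_graph = NULL, seed = 20240101L) {
  if (delta < 0 || eta < 0) stopf("delta and eta must be >= 0")
  if (rho < 0 || rho >= 1) stopf("rho must be in [0, 1)")
  if (n_classes < 2L) stopf("need at least 2 classes")
  if (is.null(ground_truth_graph)) ground_truth_graph <- ring_graph(N)
  G <- as.matrix(ground_truth_graph)
  if (nrow(G) != N || max(abs(G - t(G))) > 1e-12)
    stopf("ground_truth_graph must be a symmetric %d x %d matrix", N, N)
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 N = as.integer(N), Fd = as.integer(Fd),
                 n_classes = as.integer(n_classes),
                 delta = delta, eta = eta, rho = rho,
                 ground_truth_graph = G, seed = as.integer(seed)),
            class = "sg_synth_spec")
}

ring_graph <- function(N) {
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    j <- i %% N + 1L
    A[i, j] <- A[j, i] <- 1
  }
  A
}

# Noise-colouring transform: symmetric square root of the complement of
# half the normalized Laplacian of the ground-truth graph, rescaled to
# unit channel variances. Neighbouring channels end up positively
# correlated; the implied correlation matrix is returned as an attribute.
colouring_transform <- function(G) {
  N <- nrow(G)
  dg <- rowSums(G)
  Dm <- diag(1 / sqrt(pmax(dg, 1e-12)))
  Ln <- diag(N) - Dm %*% G %*% Dm
  S <- diag(N) - 0.5 * Ln
  ev <- eigen(S, symmetric = TRUE)
  Cm <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  Sig <- Cm %*% t(Cm)
  Cm <- diag(1 / sqrt(diag(Sig))) %*% Cm
  attr(Cm, "correlation") <- stats::cov2cor(Sig)
  Cm
}

markov_labels <- function(L, n_classes, rho) {
  y <- integer(L)
  y[1] <- sample.int(n_classes, 1L) - 1L
  if (L > 1L) for (i in 2:L) {
    if (stats::runif(1) < rho) {
      y[i] <- y[i - 1L]
    } else {
      others <- setdiff(0:(n_classes - 1L), y[i - 1L])
      y[i] <- others[sample.int(length(others), 1L)]
    }
  }
  y
}

#' Generate a feature-space cohort
#'
#' Epoch features are `delta * M[class] + eta * O[subject] + C %*% noise`
#' where the class mean patterns `M` and subject offsets `O` are drawn
#' once from a standard normal under the spec seed, and the innovation
#' noise (unit sd) is mixed through the colouring transform of the
#' ground-truth graph so neighbouring channels correlate.
#'
#' @param spec An [sg_synth_spec()].
#' @return List of per-subject `sg_features` objects (class `sg_cohort`),
#'   with the spec and the implied noise correlation attached as
#'   attributes.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sg_synth_spec"))
  with_seed(spec$seed, {
    N <- spec$N; Fd <- spec$Fd
    Cm <- colouring_transform(spec$ground_truth_graph)
    Mcls <- lapply(seq_len(spec$n_classes),
                   function(i) matrix(stats::rnorm(N * Fd), N, Fd))
    cohort <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      Osub <- matrix(stats::rnorm(N * Fd), N, Fd)
      y <- markov_labels(spec$epochs_per_subject, spec$n_classes, spec$rho)
      feats <- lapply(seq_len(spec$epochs_per_subject), function(i) {
        E <- Cm %*% matrix(stats::rnorm(N * Fd), N, Fd)
        m <- spec$delta * Mcls[[y[i] + 1L]] + spec$eta * Osub + E
        rownames(m) <- paste0("ch", seq_len(N))
        colnames(m) <- paste0("f", seq_len(Fd))
        m
      })
      cohort[[s]] <- structure(feats, class = "sg_features", labels = y,
                               subject_id = sprintf("S%02d", s))
    }
    structure(cohort, class = "sg_cohort", spec = spec,
              noise_correlation = attr(Cm, "correlation"))
  })
}

#' Default stage-to-band mapping for raw simulation
#'
#' Wake -> beta, N1 -> theta, N2 -> sigma, N3 -> delta, REM -> alpha
#' (center frequencies 20, 6, 14, 2 and 10 Hz), echoing the dominant
#' rhythms of each stage.
#'
#' @return Numeric vector of 5 center frequencies in Hz.
#' @export
sg_default_band_map <- function() {
  c(Wake = 20, N1 = 6, N2 = 14, N3 = 2, REM = 10)
}

#' Generate a raw-signal cohort
#'
#' Produces epoched time-domain recordings in which each stage carries a
#' band-limited oscillation at its mapped frequency plus white noise, so
#' differential-entropy band features are class-separable by
#' construction. Exercises the full feature-extraction path.
#'
#' @param spec An [sg_synth_spec()] (`Fd` is ignored; features come from
#'   band extraction).
#' @param sampling_rate Hz (default 100).
#' @param band_map Stage center frequencies, length `n_classes`
#'   ([sg_default_band_map()]).
#' @param osc_amplitude Oscillation amplitude relative to unit noise sd;
#'   default `spec$delta`.
#' @param montage Montage (default [sg_default_montage()] with `spec$N`
#'   channels).
#' @return List of [sg_recording] objects.
#' @export
generate_raw_cohort <- function(spec, sampling_rate = 100,
                                band_map = sg_default_band_map(),
                                osc_amplitude = NULL, montage = NULL) {
  stopifnot(inherits(spec, "sg_synth_spec"))
  if (length(band_map) != spec$n_classes)
    stopf("band_map must give one frequency per class")
  if (any(band_map >= sampling_rate / 2)) stopf("band frequency above Nyquist")
  a <- osc_amplitude %||% spec$delta
  montage <- montage %||% sg_default_montage(spec$N)
  Ts <- as.integer(30 * sampling_rate)
  tt <- (seq_len(Ts) - 1L) / sampling_rate
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) {
      y <- markov_labels(spec$epochs_per_subject, spec$n_classes, spec$rho)
      gain <- 1 + spec$eta * 0.1 * stats::rnorm(spec$N)  # subject channel gains
      sig <- array(0, c(spec$N, Ts, spec$epochs_per_subject))
      for (i in seq_len(spec$epochs_per_subject)) {
        f0 <- band_map[y[i] + 1L]
        for (n in seq_len(spec$N)) {
          ph <- stats::runif(1, 0, 2 * pi)
          sig[n, , i] <- gain[n] * a * sin(2 * pi * f0 * tt + ph) +
            stats::rnorm(Ts)
        }
      }
      sg_recording(sig, sampling_rate, y, sprintf("S%02d", s), montage)
    })
  })
}

#' Build per-subject context windows from a feature-space cohort
#'
#' @param cohort Output of [generate_cohort()] (or a list of
#'   `sg_features`).
#' @param d Context radius.
#' @return List of `sg_windows`, one per subject.
#' @export
windows_from_cohort <- function(cohort, d = 2L) {
  out <- lapply(cohort, build_context_windows, d = d)
  names(out) <- vapply(out, function(w) w$subject[1], "")
  out
}
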