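#' Electrode montage
#'
#' A montage holds the channel names (10-20 convention) and their 3-D head
#' coordinates on (approximately) the unit sphere. Coordinates feed the
#' physical-distance brain graph; names label exported adjacency and
#' attention tables.
#'
#' @param names Character vector of unique channel labels (e.g. "F3", "C4").
#' @param coords Numeric matrix `[N x 3]`; each row should have norm within
#'   10% of 1 (unit-sphere head model).
#' @return An object of class `sg_montage`.
#' @export
sg_montage <- function(names, coords) {
  coords <- as.matrix(coords)
  if (anyDuplicated(names)) stopf("montage channel names must be unique")
  if (nrow(coords) != length(names) || ncol(coords) != 3L)
    stopf("coords must be a [%d x 3] matrix (one row per channel)", length(names))
  nrm <- sqrt(rowSums(coords^2))
  if (any(abs(nrm - 1) > 0.1))
    warnf("montage coordinates deviate from the unit sphere by more than 10%%")
  structure(list(names = as.character(names), coords = coords),
            class = "sg_montage")
}

#' A template 10-20 montage
#'
#' Unit-sphere coordinates for a small set of standard 10-20 electrode
#' positions, used as a default montage for synthetic cohorts.
#'
#' @param n Number of channels (2..10).
#' @return An `sg_montage`.
#' @export
sg_default_montage <- function(n = 8L) {
  pos <- list(
    F3  = c(-0.45,  0.65,  0.62), F4  = c(0.45,  0.65,  0.62),
    C3  = c(-0.65,  0.00,  0.76), C4  = c(0.65,  0.00,  0.76),
    O1  = c(-0.38, -0.80,  0.46), O2  = c(0.38, -0.80,  0.46),
    T3  = c(-0.99,  0.00,  0.13), T4  = c(0.99,  0.00,  0.13),
    Fz  = c( 0.00,  0.72,  0.69), Pz  = c(0.00, -0.72,  0.69))
  if (n < 2L || n > length(pos)) stopf("n must be in 2..%d", length(pos))
  cm <- do.call(rbind, pos[seq_len(n)])
  cm <- cm / sqrt(rowSums(cm^2))
  sg_montage(names(pos)[seq_len(n)], cm)
}

#' Epoched multi-channel recording
#'
#' Container for one subject's epoched signal: a `[N x Ts x L]` array of N
#' channels, Ts samples per 30-second epoch and L epochs, plus per-epoch
#' stage labels coded Wake=0, N1=1, N2=2, N3=3, REM=4.
#'
#' @param signal Numeric array `[N x Ts x L]`.
#' @param sampling_rate Sampling rate in Hz; `Ts` must equal
#'   `30 * sampling_rate`.
#' @param labels Integer vector of length L with values in 0..4.
#' @param subject_id Subject identifier (scalar).
#' @param montage An [sg_montage] with N channels.
#' @return An object of class `sg_recording`.
#' @export
sg_recording <- function(signal, sampling_rate, labels, subject_id, montage) {
  d <- dim(signal)
  if (length(d) != 3L) stopf("signal must be a 3-d array [N x Ts x L]")
  if (d[1] < 2L) stopf("need at least 2 channels, got %d", d[1])
  if (d[2] != 30 * sampling_rate)
    stopf("Ts = %d does not match 30 s at %g Hz (expected %d samples)",
          d[2], sampling_rate, 30 * sampling_rate)
  labels <- as.integer(labels)
  if (length(labels) != d[3])
    stopf("labels length %d != number of epochs %d", length(labels), d[3])
  if (any(labels < 0L | labels > 4L)) stopf("labels must be coded 0..4")
  if (!inherits(montage, "sg_montage")) stopf("montage must be an sg_montage")
  if (length(montage$names) != d[1])
    stopf("montage has %d channels but signal has %d", length(montage$names), d[1])
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 labels = labels, subject_id = subject_id, montage = montage),
            class = "sg_recording")
}

#' Default EEG frequency bands
#'
#' Six canonical bands: delta 0.5-4, theta 4-8, alpha 8-13, sigma 13-16,
#' beta 16-30 and gamma 30-45 Hz, giving the default feature dimension
#' Fd = 6.
#'
#' @return Named list of `c(low, high)` pairs in Hz.
#' @export
sg_default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
       sigma = c(13, 16), beta = c(16, 30), gamma = c(30, 45))
}

#' Differential-entropy features per epoch and band
#'
#' For each epoch, each channel is band-pass filtered (zero-phase
#' Butterworth) in each requested band and the differential entropy of the
#' band-limited signal is computed under a Gaussian assumption:
#' `DE = 0.5 * log(2 * pi * e * var)`.
#'
#' @param rec An [sg_recording].
#' @param bands List of `c(low, high)` Hz pairs; defaults to
#'   [sg_default_bands()].
#' @param filter_order Butterworth order (applied forward and backward, so
#'   effective order is doubled). Default 4.
#' @param var_floor Variance floor `eps` applied before the logarithm when a
#'   band-filtered signal is (numerically) constant. Default 1e-12.
#' @return List of L feature matrices, each `[N x Fd]` with band names as
#'   column names (class `sg_features`).
#' @export
extract_de_features <- function(rec, bands = sg_default_bands(),
                                filter_order = 4L, var_floor = 1e-12) {
  stopifnot(inherits(rec, "sg_recording"))
  fs <- rec$sampling_rate
  nyq <- fs / 2
  for (b in bands) {
    if (!(b[1] > 0 && b[1] < b[2] && b[2] <= nyq))
      stopf("band [%g, %g] Hz invalid for Nyquist %g Hz", b[1], b[2], nyq)
  }
  d <- dim(rec$signal)
  N <- d[1]; Ts <- d[2]; L <- d[3]
  Fd <- length(bands)
  # filter the whole recording per channel/band, then take per-epoch variance
  de <- array(NA_real_, c(N, Fd, L))
  for (j in seq_len(Fd)) {
    bf <- signal::butter(filter_order, bands[[j]] / nyq, type = "pass")
    for (n in seq_len(N)) {
      x <- as.vector(rec$signal[n, , ])
      xf <- signal::filtfilt(bf, x)
      xm <- matrix(xf, nrow = Ts, ncol = L)
      v <- pmax(apply(xm, 2L, stats::var), var_floor)
      de[n, j, ] <- 0.5 * log(2 * pi * exp(1) * v)
    }
  }
  nm <- names(bands) %||% paste0("band", seq_len(Fd))
  out <- lapply(seq_len(L), function(i) {
    m <- de[, , i, drop = FALSE]
    dim(m) <- c(N, Fd)
    colnames(m) <- nm
    rownames(m) <- rec$montage$names
    m
  })
  structure(out, class = "sg_features", labels = rec$labels,
            subject_id = rec$subject_id)
}

#' Assemble temporal context windows
#'
#' Each classified epoch is presented together with its `d` preceding and
#' `d` following epochs (Tn = 2d+1 consecutive feature matrices, ordered
#' oldest to newest). The first and last `d` epochs lack full context and
#' are dropped, leaving exactly `L - 2d` windows.
#'
#' @param feature_list List of L `[N x Fd]` feature matrices (or an
#'   `sg_features` object).
#' @param labels Integer stage labels, length L (taken from `feature_list`
#'   when it is an `sg_features`).
#' @param subject_id Subject identifier.
#' @param d Context radius (non-negative integer).
#' @return An `sg_windows` object: list with `x` `[N x Fd x Tn x W]`,
#'   `y` (center labels), `subject` (per window), `center` (1-based center
#'   epoch indices).
#' @export
build_context_windows <- function(feature_list, labels = NULL,
                                  subject_id = NULL, d = 2L) {
  if (inherits(feature_list, "sg_features")) {
    labels <- labels %||% attr(feature_list, "labels")
    subject_id <- subject_id %||% attr(feature_list, "subject_id")
  }
  d <- as.integer(d)
  if (d < 0L) stopf("context radius d must be >= 0")
  L <- length(feature_list)
  if (L <= 2L * d)
    stopf("cannot build context windows: L = %d epochs <= 2d = %d", L, 2L * d)
  N <- nrow(feature_list[[1]]); Fd <- ncol(feature_list[[1]])
  Tn <- 2L * d + 1L
  W <- L - 2L * d
  x <- array(NA_real_, c(N, Fd, Tn, W))
  centers <- (d + 1L):(L - d)
  for (w in seq_len(W)) {
    for (t in seq_len(Tn)) x[, , t, w] <- feature_list[[centers[w] + t - d - 1L]]
  }
  structure(list(x = x, y = as.integer(labels[centers]),
                 subject = rep(as.character(subject_id), W),
                 center = centers, d = d,
                 feature_names = colnames(feature_list[[1]]),
                 channel_names = rownames(feature_list[[1]])),
            class = "sg_windows")
}

#' @export
print.sg_windows <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<sg_windows> %d windows, %d channels x %d features x Tn=%d, %d subject(s)\n",
              d[4], d[1], d[2], d[3], length(unique(x$subject))))
  invisible(x)
}

#' Concatenate window sets from several subjects
#'
#' @param ... `sg_windows` objects (or one list of them).
#' @return A single `sg_windows`.
#' @export
bind_windows <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && !inherits(lst[[1]], "sg_windows")) lst <- lst[[1]]
  d <- dim(lst[[1]]$x)
  x <- array(NA_real_, c(d[1], d[2], d[3], sum(vapply(lst, function(w) dim(w$x)[4], 0))))
  off <- 0L
  for (w in lst) {
    k <- dim(w$x)[4]
    x[, , , off + seq_len(k)] <- w$x
    off <- off + k
  }
  structure(list(x = x, y = unlist(lapply(lst, `[[`, "y")),
                 subject = unlist(lapply(lst, `[[`, "subject")),
                 center = unlist(lapply(lst, `[[`, "center")),
                 d = lst[[1]]$d,
                 feature_names = lst[[1]]$feature_names,
                 channel_names = lst[[1]]$channel_names),
            class = "sg_windows")
}

#' Subset windows
#' @param windows An `sg_windows`.
#' @param idx Integer or logical index over windows.
#' @return An `sg_windows`.
#' @export
subset_windows <- function(windows, idx) {
  structure(list(x = windows$x[, , , idx, drop = FALSE],
                 y = windows$y[idx], subject = windows$subject[idx],
                 center = windows$center[idx], d = windows$d,
                 feature_names = windows$feature_names,
                 channel_names = windows$channel_names),
            class = "sg_windows")
}

#' Per-(channel, feature) standardization statistics
#'
#' Means and standard deviations computed over all epochs of a training set
#' of windows. Constant features (zero variance) are flagged and left
#' unscaled when applied.
#'
#' @param windows Training `sg_windows` (no held-out subjects).
#' @return A list with `mean`, `sd` (`[N x Fd]`) and `constant` mask.
#' @export
compute_feature_stats <- function(windows) {
  m <- apply(windows$x, c(1L, 2L), mean)
  s <- apply(windows$x, c(1L, 2L), stats::sd)
  const <- !is.finite(s) | s < 1e-12
  if (any(const)) {
    warnf("%d constant (zero-variance) channel/feature cells left unscaled",
          sum(const))
    s[const] <- 1
    m[const] <- 0
  }
  list(mean = m, sd = s, constant = const)
}

#' Standardize window features
#'
#' Applies the affine map `(x - mean) / sd` per (channel, feature) cell.
#' Statistics must come from training subjects only; the same map is then
#' applied to held-out windows, so no test information leaks into the
#' transform.
#'
#' @param windows An `sg_windows`.
#' @param stats Statistics from [compute_feature_stats()]; when `NULL` they
#'   are computed from `windows` itself (training use).
#' @return Standardized `sg_windows` with the stats attached as attribute
#'   `"stats"`.
#' @export
standardize_features <- function(windows, stats = NULL) {
  if (is.null(stats)) stats <- compute_feature_stats(windows)
  d <- dim(windows$x)
  mu <- array(stats$mean, c(d[1], d[2], d[3], d[4]))
  sd <- array(stats$sd, c(d[1], d[2], d[3], d[4]))
  windows$x <- (windows$x - mu) / sd
  attr(windows, "stats") <- stats
  windows
}
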