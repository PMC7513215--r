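#' Sample entropy of a signal epoch
#'
#' Sample entropy (SampEn) quantifies the irregularity of a time series as
#' the negative log of the conditional probability that two sequences which
#' match for `m` consecutive samples also match for `m + 1` samples, under a
#' Chebyshev tolerance `r = r_factor * SD(x)`. Self-matches are excluded and
#' template pairs are counted unordered (the Richman–Moorman convention).
#' Lower values indicate a more regular (e.g. oscillation-dominated) signal;
#' this is the core per-channel feature for fatigue-state recognition.
#'
#' The tolerance scales with the epoch's own standard deviation (population
#' convention, divide by N), so SampEn is invariant under affine amplitude
#' transforms of the epoch.
#'
#' @param x numeric vector, one channel's samples within one epoch.
#' @param m embedding dimension (template length), default 2.
#' @param r_factor tolerance as a multiple of the epoch SD, default 0.25.
#' @return a single non-negative number (nats).
#' @section Errors: a constant epoch (SD = 0) raises a condition of class
#'   `eegkpca_degenerate_epoch`; zero match counts at either template length
#'   raise `eegkpca_undefined_entropy` rather than returning `Inf`/`NaN`.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(200))
#' @export
sample_entropy <- function(x, m = 2L, r_factor = 0.25) {
  r <- .entropy_check(x, m, r_factor)
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (cnt[2] <= 0 || cnt[1] <= 0) {
    stop_eegkpca(
      sprintf("sample entropy undefined: %s-length template matches found (A=%g, B=%g)",
              if (cnt[2] <= 0) "no m" else "no (m+1)", cnt[1], cnt[2]),
      "eegkpca_undefined_entropy"
    )
  }
  -log(cnt[1] / cnt[2])
}

#' Raw template-match counts for sample entropy
#'
#' Exposes the pair counts `A` (length `m + 1`) and `B` (length `m`) behind
#' [sample_entropy()]; useful for diagnostics, e.g. both counts are
#' non-decreasing in the tolerance `r`.
#'
#' @inheritParams sample_entropy
#' @param r absolute Chebyshev tolerance (not a multiple of SD).
#' @return named numeric vector `c(A = , B = )`.
#' @export
sampen_counts <- function(x, m = 2L, r) {
  stopifnot(is.numeric(x), all(is.finite(x)), length(x) >= m + 2, r > 0)
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  c(A = cnt[1], B = cnt[2])
}

#' Fuzzy entropy of a signal epoch
#'
#' Like [sample_entropy()] but the hard match threshold is replaced by a
#' graded exponential membership `exp(-d^n / r)` computed on mean-centered
#' templates, which makes the estimate continuous in the data and finite for
#' any epoch with positive variance.
#'
#' @inheritParams sample_entropy
#' @param n membership gradient (exponent on the Chebyshev distance),
#'   default 2.
#' @return a single non-negative number (nats).
#' @export
fuzzy_entropy <- function(x, m = 2L, r_factor = 0.25, n = 2) {
  r <- .entropy_check(x, m, r_factor)
  ph <- .fuzzyen_sums_cpp(as.numeric(x), as.integer(m), r, n)
  log(ph[2]) - log(ph[1])
}

# shared validation; returns the absolute tolerance r
.entropy_check <- function(x, m, r_factor) {
  stopifnot(is.numeric(x), length(m) == 1L, m >= 1, r_factor > 0)
  if (!all(is.finite(x)))
    stop_eegkpca("epoch contains non-finite samples", "eegkpca_bad_input")
  if (length(x) < m + 2)
    stop_eegkpca(sprintf("epoch too short: N=%d < m+2=%d", length(x), m + 2),
                 "eegkpca_bad_input")
  sdx <- sqrt(mean((x - mean(x))^2))  # population SD
  if (sdx <= 0)
    stop_eegkpca("degenerate epoch: zero variance, tolerance r would be 0",
                 "eegkpca_degenerate_epoch")
  r_factor * sdx
}

## ---- combination-entropy registry ---------------------------------------

# The combination-entropy estimator is only cited in the source literature,
# never written out, so the slot is pluggable. The shipped default is a
# clearly labelled stand-in: the mean of sample and fuzzy entropy.
.default_combination_entropy <- function(x, m = 2L, r_factor = 0.25) {
  (sample_entropy(x, m, r_factor) + fuzzy_entropy(x, m, r_factor)) / 2
}

# the default stand-in is registered at build time; register_combination_entropy(NULL) clears it
.eegkpca_env$combination_entropy <- .default_combination_entropy

#' Register (or clear) the combination-entropy estimator
#'
#' @param fn a function `(x, m, r_factor)` returning a single number, or
#'   `NULL` to clear the slot (after which [combination_entropy()] errors
#'   until a new estimator is registered).
#' @return the previously registered function, invisibly.
#' @seealso [combination_entropy()]
#' @export
register_combination_entropy <- function(fn) {
  if (!is.null(fn) && !is.function(fn))
    stop_eegkpca("estimator must be a function or NULL", "eegkpca_bad_input")
  old <- .eegkpca_env$combination_entropy
  .eegkpca_env$combination_entropy <- fn
  invisible(old)
}

#' Combination entropy (pluggable slot)
#'
#' Dispatches to whatever estimator is registered via
#' [register_combination_entropy()]. The package ships with a stand-in
#' default, the mean of sample and fuzzy entropy, because the composite
#' estimator used in the driving-fatigue literature is cited there without a
#' formula; users holding that reference can register the real one.
#'
#' @inheritParams sample_entropy
#' @return a single number.
#' @export
combination_entropy <- function(x, m = 2L, r_factor = 0.25) {
  fn <- .eegkpca_env$combination_entropy
  if (is.null(fn))
    stop_eegkpca(paste0("no combination-entropy estimator registered; ",
                        "see register_combination_entropy()"),
                 "eegkpca_config_error")
  fn(x, m = m, r_factor = r_factor)
}

.entropy_fun <- function(estimator = c("sample", "fuzzy", "combination")) {
  switch(match.arg(estimator),
         sample = sample_entropy,
         fuzzy = fuzzy_entropy,
         combination = combination_entropy)
}

## ---- epoch feature matrix ------------------------------------------------

#' Entropy feature matrix from multichannel signals
#'
#' Splits each channel into consecutive whole epochs of `epoch_len` seconds
#' and computes one entropy value per epoch and channel, producing the
#' epochs-by-channels matrix that feeds the PCA/KPCA stage (e.g. 600 x 30
#' for ten 60-second subjects over 30 electrodes at 1 s epochs).
#'
#' @param signals numeric matrix, samples in rows and channels in columns
#'   (or a list of equal-length numeric vectors).
#' @param rate sampling rate in Hz.
#' @param epoch_len epoch length in seconds, default 1.
#' @param estimator `"sample"`, `"fuzzy"`, or `"combination"`.
#' @param m,r_factor entropy parameters, defaults 2 and 0.25.
#' @param labels optional per-epoch state labels (0 = alert, 1 = fatigue),
#'   recycled checks apply: length must equal the number of whole epochs.
#' @param on_degenerate `"error"` (default) stops on any zero-variance
#'   channel epoch; `"impute"` replaces such cells with the channel's median
#'   over its valid epochs and warns.
#' @return an object of class `feature_matrix`: a list with `values`
#'   (epochs x channels), `channels`, and optional `labels`.
#' @export
epoch_feature_matrix <- function(signals, rate, epoch_len = 1,
                                 estimator = "sample",
                                 m = 2L, r_factor = 0.25, labels = NULL,
                                 on_degenerate = c("error", "impute")) {
  on_degenerate <- match.arg(on_degenerate)
  if (is.list(signals) && !is.data.frame(signals)) {
    lens <- lengths(signals)
    if (length(unique(lens)) != 1L)
      stop_eegkpca("channels have unequal lengths", "eegkpca_bad_input")
    signals <- do.call(cbind, signals)
  }
  signals <- as.matrix(signals)
  storage.mode(signals) <- "double"
  stopifnot(rate > 0, epoch_len > 0)
  spe <- as.integer(round(rate * epoch_len))  # samples per epoch
  n_epochs <- nrow(signals) %/% spe
  if (n_epochs < 1L)
    stop_eegkpca("signal shorter than one epoch", "eegkpca_bad_input")
  if (nrow(signals) %% spe != 0L)
    warning(sprintf("dropping trailing partial epoch (%d samples)",
                    nrow(signals) %% spe))
  if (!is.null(labels) && length(labels) != n_epochs)
    stop_eegkpca("labels must have one entry per whole epoch",
                 "eegkpca_bad_input")
  fn <- .entropy_fun(estimator)
  n_ch <- ncol(signals)
  vals <- matrix(NA_real_, n_epochs, n_ch)
  for (q in seq_len(n_ch)) {
    for (p in seq_len(n_epochs)) {
      seg <- signals[((p - 1L) * spe + 1L):(p * spe), q]
      vals[p, q] <- tryCatch(
        fn(seg, m = m, r_factor = r_factor),
        eegkpca_degenerate_epoch = function(e) {
          if (on_degenerate == "error") stop(e)
          NA_real_
        })
    }
    if (anyNA(vals[, q])) {
      bad <- which(is.na(vals[, q]))
      vals[bad, q] <- stats::median(vals[, q], na.rm = TRUE)
      warning(sprintf("channel %d: imputed %d degenerate epoch(s) with the channel median",
                      q, length(bad)))
    }
  }
  channels <- colnames(signals)
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(n_ch))
  colnames(vals) <- channels
  feature_matrix(vals, labels = labels, channels = channels)
}

#' Construct a feature matrix object
#'
#' @param values numeric matrix, epochs in rows, channels/features in columns.
#' @param labels optional per-row binary labels (0/1).
#' @param channels optional feature names (defaults to column names).
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, labels = NULL, channels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop_eegkpca("feature matrix contains non-finite entries",
                 "eegkpca_bad_input")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values) || !all(labels %in% c(0L, 1L)))
      stop_eegkpca("labels must be one 0/1 value per row", "eegkpca_bad_input")
  }
  if (is.null(channels)) channels <- sprintf("f%02d", seq_len(ncol(values)))
  colnames(values) <- channels
  structure(list(values = values, labels = labels, channels = channels),
            class = "feature_matrix")
}

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d channels%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", labels: %d/%d (state 0/1)",
                        sum(x$labels == 0L), sum(x$labels == 1L))))
  invisible(x)
}

# accept either a feature_matrix or a bare matrix everywhere downstream
.fm_values <- function(X) {
  if (inherits(X, "feature_matrix")) X$values else {
    X <- as.matrix(X); storage.mode(X) <- "double"; X
  }
}
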