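#' Column standardization with stored centering state
#'
#' Centers each feature to mean 0 and scales to unit sample standard
#' deviation (the n-1 convention, matching the correlation-matrix PCA it
#' feeds). The returned object keeps the per-column means and SDs so unseen
#' rows can be transformed with the *training* statistics — required for a
#' leak-free cross-validation protocol.
#'
#' @param X numeric matrix or `feature_matrix`, samples in rows.
#' @return a list of class `standardizer` with elements `values` (the
#'   standardized matrix), `center` and `scale`.
#' @seealso [apply_standardizer()]
#' @export
standardize <- function(X) {
  X <- .fm_values(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  bad <- which(scl <= 0 | !is.finite(scl))
  if (length(bad))
    stop_eegkpca(sprintf("zero-variance column(s): %s",
                         paste(colnames(X)[bad] %||% bad, collapse = ", ")),
                 "eegkpca_degenerate_column")
  structure(list(values = sweep(sweep(X, 2L, ctr), 2L, scl, "/"),
                 center = ctr, scale = scl),
            class = "standardizer")
}

#' Apply stored standardization statistics to new rows
#' @param stats a `standardizer` from [standardize()].
#' @param X new rows with the same columns.
#' @return the transformed matrix.
#' @export
apply_standardizer <- function(stats, X) {
  stopifnot(inherits(stats, "standardizer"))
  X <- .fm_values(X)
  sweep(sweep(X, 2L, stats$center), 2L, stats$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reproducible eigenvector signs: first nonzero entry of each vector positive
.fix_signs <- function(V) {
  for (k in seq_len(ncol(V))) {
    nz <- which(abs(V[, k]) > 1e-12)
    if (length(nz) && V[nz[1L], k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Principal component analysis of a feature matrix
#'
#' Eigendecomposition of the feature *correlation* matrix (each entropy
#' channel standardized first), the convention of the fatigue-recognition
#' protocol; set `use_correlation = FALSE` for covariance PCA. Contribution
#' rates are the eigenvalue fractions used by [cvc_select()].
#'
#' @param X numeric matrix or `feature_matrix`.
#' @param use_correlation eigendecompose the correlation matrix (default)
#'   or the covariance matrix of the raw features.
#' @return a `decomposition_result` with `eigenvalues` (descending),
#'   `components` (unit-norm loading vectors in columns, signs fixed so the
#'   first nonzero loading is positive), `contribution_rates`, `scores` for
#'   the training rows, and the `centering_state` needed by [pca_project()].
#' @export
pca_fit <- function(X, use_correlation = TRUE) {
  X <- .fm_values(X)
  if (!all(is.finite(X)))
    stop_eegkpca("non-finite entries in feature matrix", "eegkpca_bad_input")
  if (nrow(X) < 2L)
    stop_eegkpca("need at least 2 samples", "eegkpca_bad_input")
  if (use_correlation) {
    std <- standardize(X)
    Y <- std$values
    M <- crossprod(Y) / (nrow(Y) - 1)  # correlation matrix
  } else {
    std <- list(center = colMeans(X), scale = rep(1, ncol(X)))
    class(std) <- "standardizer"
    Y <- sweep(X, 2L, std$center)
    M <- crossprod(Y) / (nrow(Y) - 1)
  }
  eg <- eigen(M, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- .fix_signs(eg$vectors)
  structure(list(
    method = "pca",
    eigenvalues = lam,
    components = V,
    contribution_rates = lam / sum(lam),
    scores = Y %*% V,
    centering_state = std,
    n_selected = length(lam)
  ), class = "decomposition_result")
}

#' Project new rows onto fitted principal components
#' @param fitted a `decomposition_result` from [pca_fit()].
#' @param X new rows (same features as the fit).
#' @param k number of leading components, default all retained.
#' @return an `nrow(X)` x `k` score matrix.
#' @export
pca_project <- function(fitted, X, k = fitted$n_selected) {
  stopifnot(inherits(fitted, "decomposition_result"), fitted$method == "pca")
  if (k > ncol(fitted$components))
    stop_eegkpca("k exceeds the number of fitted components", "eegkpca_bad_input")
  Y <- apply_standardizer(fitted$centering_state, X)
  Y %*% fitted$components[, seq_len(k), drop = FALSE]
}

#' Select components by cumulative variance contribution
#'
#' Returns the smallest `k` whose leading contribution rates sum to at least
#' `threshold`. The raw (unnormalized) cumulative sum of the supplied rates
#' is used, matching how published per-component contribution tables are
#' read; if the rates never reach the threshold all components are returned
#' with a warning.
#'
#' @param rates non-negative, non-increasing contribution rates.
#' @param threshold fraction in (0, 1], e.g. 0.90, 0.95, 0.99.
#' @return integer `k`.
#' @export
cvc_select <- function(rates, threshold = 0.90) {
  if (length(rates) == 0L)
    stop_eegkpca("empty contribution-rate vector", "eegkpca_bad_input")
  stopifnot(threshold > 0, threshold <= 1)
  if (any(rates < -1e-12) || is.unsorted(-rates, strictly = FALSE))
    stop_eegkpca("rates must be non-negative and non-increasing",
                 "eegkpca_bad_input")
  cs <- cumsum(rates)
  # small epsilon so exact decimal thresholds are not missed through
  # floating-point accumulation (e.g. 0.6 + 0.3 < 0.9 in binary)
  hit <- which(cs >= threshold - 1e-9)
  if (!length(hit)) {
    warning(sprintf("total contribution %.4f below threshold %.2f; keeping all %d components",
                    cs[length(cs)], threshold, length(rates)))
    return(length(rates))
  }
  hit[1L]
}

#' Double-center a kernel Gram matrix
#'
#' Centers the implicit feature-space images to zero mean. In fit mode
#' (`training_stats = NULL`, square `K`) computes
#' \eqn{\tilde K = K - 1_M K - K 1_M + 1_M K 1_M} with \eqn{(1_M)_{ij} = 1/M},
#' after which every row and column of \eqn{\tilde K} sums to zero; the
#' training column means and grand mean are attached as attribute
#' `"centering"`. In projection mode, pass the rectangular test-versus-train
#' Gram matrix plus those stored training statistics so test rows are
#' centered consistently with the fit (never with their own means).
#'
#' @param K Gram matrix: square in fit mode, `n_new` x `M` in projection
#'   mode (columns indexing training samples).
#' @param training_stats the `"centering"` attribute of a fit-mode result
#'   (a list with `col_means` and `grand_mean`), or `NULL` for fit mode.
#' @return the centered matrix; in fit mode with attribute `"centering"`.
#' @export
center_kernel <- function(K, training_stats = NULL) {
  K <- as.matrix(K)
  if (is.null(training_stats)) {
    if (nrow(K) != ncol(K))
      stop_eegkpca("fit-mode centering needs a square Gram matrix (pass training_stats for test rows)",
                   "eegkpca_bad_input")
    cm <- colMeans(K)
    g <- mean(K)
    Kc <- K - matrix(rowMeans(K), nrow(K), ncol(K)) -
      matrix(cm, nrow(K), ncol(K), byrow = TRUE) + g
    attr(Kc, "centering") <- list(col_means = cm, grand_mean = g)
    Kc
  } else {
    cm <- training_stats$col_means
    if (ncol(K) != length(cm))
      stop_eegkpca("test Gram matrix columns must index the training samples",
                   "eegkpca_bad_input")
    K - matrix(rowMeans(K), nrow(K), ncol(K)) -
      matrix(cm, nrow(K), ncol(K), byrow = TRUE) + training_stats$grand_mean
  }
}

#' Kernel principal component analysis
#'
#' Solves the dual eigenproblem \eqn{M \lambda a = \tilde K a} on the
#' double-centered Gram matrix of the training rows. Eigenvalues below
#' `tol * max(eigenvalue)` — including any negative ones produced by the
#' indefinite sigmoid (mlp) kernel — are truncated before contribution
#' rates are computed. Dual coefficient vectors are scaled so each
#' feature-space principal axis has unit length (\eqn{a_k^T K a_k = 1}).
#'
#' By default the features enter the kernel on their raw scale (nats):
#' the RBF bandwidth of the fatigue protocol (sigma = 0.2) is calibrated to
#' entropy units, and the KPCA procedure centers in feature space rather
#' than standardizing inputs. Set `standardize = TRUE` to standardize
#' columns first (stored and reapplied at projection time).
#'
#' @param X training feature matrix.
#' @param spec a [kernel_spec()].
#' @param standardize standardize columns before the kernel (default FALSE).
#' @param tol relative eigenvalue truncation threshold, default 1e-10.
#' @return a `decomposition_result` with feature-space `eigenvalues`
#'   (Gram eigenvalues divided by M, descending), normalized dual
#'   `coefficients`, `contribution_rates` over the retained spectrum,
#'   training `scores`, `n_dropped` (truncated eigenvalues, negatives
#'   included), and the `centering_state` for [kpca_project()].
#' @export
kpca_fit <- function(X, spec, standardize = FALSE, tol = 1e-10) {
  X <- .fm_values(X)
  if (nrow(X) < 2L)
    stop_eegkpca("need at least 2 samples", "eegkpca_bad_input")
  std <- NULL
  if (isTRUE(standardize)) {
    std <- standardize(X)
    X <- std$values
  }
  M <- nrow(X)
  K <- kernel_matrix(X, X, spec)
  Kc <- center_kernel(K)
  cstats <- attr(Kc, "centering")
  eg <- eigen(Kc, symmetric = TRUE)
  mu <- eg$values                      # Gram eigenvalues, descending
  keep <- which(mu > max(mu, 0) * tol & mu > 0)
  if (!length(keep))
    stop_eegkpca("degenerate kernel: no eigenvalue above tolerance",
                 "eegkpca_degenerate_kernel")
  mu_k <- mu[keep]
  A <- .fix_signs(eg$vectors[, keep, drop = FALSE])
  A <- sweep(A, 2L, sqrt(mu_k), "/")   # unit feature-space axes
  structure(list(
    method = "kpca",
    spec = spec,
    eigenvalues = mu_k / M,            # feature-space variances
    gram_eigenvalues = mu_k,
    coefficients = A,
    contribution_rates = mu_k / sum(mu_k),
    scores = Kc %*% A,
    n_dropped = length(mu) - length(keep),
    centering_state = list(kernel = cstats, standardizer = std),
    X_train = X,
    n_selected = length(keep)
  ), class = "decomposition_result")
}

#' Project new rows onto fitted kernel principal components
#'
#' Computes the test-versus-train Gram matrix, centers it with the stored
#' *training* statistics, and multiplies by the dual coefficients:
#' score(i, k) = sum_j a_jk ktilde(x_j_train, x_i_new).
#'
#' @param fitted a `decomposition_result` from [kpca_fit()].
#' @param X new rows in the same feature space.
#' @param k number of leading components, default all retained.
#' @return an `nrow(X)` x `k` score matrix.
#' @export
kpca_project <- function(fitted, X, k = fitted$n_selected) {
  stopifnot(inherits(fitted, "decomposition_result"), fitted$method == "kpca")
  if (k > fitted$n_selected)
    stop_eegkpca("k exceeds the number of retained components", "eegkpca_bad_input")
  X <- .fm_values(X)
  if (!is.null(fitted$centering_state$standardizer))
    X <- apply_standardizer(fitted$centering_state$standardizer, X)
  Kt <- kernel_matrix(X, fitted$X_train, fitted$spec)
  Ktc <- center_kernel(Kt, fitted$centering_state$kernel)
  Ktc %*% fitted$coefficients[, seq_len(k), drop = FALSE]
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> %s, %d component(s)%s\n", x$method,
              x$n_selected,
              if (x$method == "kpca")
                sprintf(" [%s kernel, %d eigenvalue(s) truncated]",
                        x$spec$family, x$n_dropped) else ""))
  cr <- x$contribution_rates
  cat(sprintf("  leading contribution rates: %s\n",
              paste(sprintf("%.4f", utils::head(cr, 5L)), collapse = " ")))
  invisible(x)
}
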