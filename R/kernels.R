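#' Kernel specification
#'
#' Defines one of the four kernel families used by the KPCA stage:
#' \describe{
#'   \item{linear}{\eqn{k(x, y) = x \cdot y}}
#'   \item{polynomial}{\eqn{k(x, y) = (x \cdot y + 1)^P} (fractional `P`
#'     such as 0.5 is allowed; the base must then be non-negative)}
#'   \item{rbf}{\eqn{k(x, y) = \exp(-\|x - y\|^2 / \delta^2)}, the standard
#'     squared-distance Gaussian with bandwidth `delta` (the sigma of the
#'     fatigue-recognition protocol, default choice there 0.2)}
#'   \item{mlp}{\eqn{k(x, y) = \tanh(v (x \cdot y) + c)}, the sigmoid
#'     kernel; not positive semidefinite in general, so its Gram matrix may
#'     have negative eigenvalues (truncated by [kpca_fit()])}
#' }
#'
#' @param family one of `"linear"`, `"polynomial"`, `"rbf"`, `"mlp"`.
#' @param P polynomial order (> 0), required for `"polynomial"`.
#' @param delta RBF bandwidth (> 0), required for `"rbf"`.
#' @param v,c sigmoid slope and offset, required for `"mlp"`.
#' @return an object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", delta = 0.2)
#' kernel_spec("polynomial", P = 2)
#' @export
kernel_spec <- function(family = c("linear", "polynomial", "rbf", "mlp"),
                        P = NULL, delta = NULL, v = NULL, c = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    linear = list(),
    polynomial = {
      if (is.null(P) || length(P) != 1L || !is.finite(P) || P <= 0)
        stop_eegkpca("polynomial kernel needs order P > 0", "eegkpca_bad_input")
      list(P = as.numeric(P))
    },
    rbf = {
      if (is.null(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
        stop_eegkpca("rbf kernel needs bandwidth delta > 0", "eegkpca_bad_input")
      list(delta = as.numeric(delta))
    },
    mlp = {
      if (is.null(v) || is.null(c) || !is.finite(v) || !is.finite(c))
        stop_eegkpca("mlp kernel needs finite slope v and offset c",
                     "eegkpca_bad_input")
      list(v = as.numeric(v), c = as.numeric(c))
    })
  structure(c(list(family = family), spec), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(sprintf("<kernel_spec> %s(%s)\n", x$family,
              paste(names(pars), unlist(pars), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Kernel (Gram) matrix between two sample sets
#'
#' Entry (i, j) is `k(x_i, y_j)` for row i of `X` and row j of `Y` under the
#' given [kernel_spec()]. With `Y = X` the result is symmetric, and positive
#' semidefinite up to rounding for the linear, polynomial and rbf families.
#'
#' @param X,Y numeric matrices (or `feature_matrix` objects) with samples in
#'   rows and the same number of columns.
#' @param spec a [kernel_spec()].
#' @return an `nrow(X)` x `nrow(Y)` matrix.
#' @export
kernel_matrix <- function(X, Y = X, spec = kernel_spec("linear")) {
  X <- .fm_values(X); Y <- .fm_values(Y)
  stopifnot(inherits(spec, "kernel_spec"))
  if (ncol(X) != ncol(Y))
    stop_eegkpca(sprintf("feature dimensions differ: %d vs %d",
                         ncol(X), ncol(Y)), "eegkpca_bad_input")
  G <- tcrossprod(X, Y)
  K <- switch(spec$family,
    linear = G,
    polynomial = {
      base <- G + 1
      if (spec$P != round(spec$P) && any(base < 0))
        stop_eegkpca("fractional-order polynomial kernel on negative base (x.y + 1 < 0)",
                     "eegkpca_bad_input")
      base^spec$P
    },
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      d2[d2 < 0] <- 0  # rounding guard
      exp(-d2 / spec$delta^2)
    },
    mlp = tanh(spec$v * G + spec$c))
  if (!all(is.finite(K)))
    stop_eegkpca("kernel matrix contains non-finite entries", "eegkpca_bad_input")
  K
}
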