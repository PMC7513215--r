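#' Support-vector classifier (built-in, kernelized)
#'
#' Soft-margin binary C-SVC trained with a deterministic SMO solver over a
#' precomputed Gram matrix. This is the classification stage of the fatigue
#' recognition pipeline; it is self-contained because no SVM library is
#' assumed. Defaults: RBF kernel with bandwidth `sqrt(ncol(X))`, i.e. a
#' kernel scale of 1/n_features on the squared distance, and unit
#' regularization `C = 1`.
#'
#' @param X numeric training matrix (samples x features).
#' @param y binary labels: 0/1, a two-level factor, or -1/+1.
#' @param kernel a [kernel_spec()]; default RBF with `delta = sqrt(ncol(X))`.
#' @param C box constraint (> 0), default 1.
#' @param tol KKT violation tolerance, default 1e-3.
#' @param max_passes cap on SMO sweeps, default 500.
#' @return an object of class `svc_model`.
#' @export
svc_fit <- function(X, y, kernel = NULL, C = 1, tol = 1e-3, max_passes = 500L) {
  X <- .fm_values(X)
  lv <- sort(unique(as.vector(y)))
  if (length(lv) != 2L)
    stop_eegkpca("training data must contain exactly two classes",
                 "eegkpca_single_class")
  ypm <- ifelse(y == lv[2L], 1, -1)
  if (is.null(kernel)) kernel <- kernel_spec("rbf", delta = sqrt(ncol(X)))
  K <- kernel_matrix(X, X, kernel)
  fit <- .svc_smo_cpp(K, as.numeric(ypm), C, tol, as.integer(max_passes))
  structure(list(alpha = fit$alpha, b = fit$b, X = X, y = ypm,
                 levels = lv, kernel = kernel, C = C),
            class = "svc_model")
}

#' @export
print.svc_model <- function(x, ...) {
  cat(sprintf("<svc_model> %s kernel, C=%g, %d support vector(s) of %d\n",
              x$kernel$family, x$C, sum(x$alpha > 1e-8), length(x$alpha)))
  invisible(x)
}

#' Decision values for a fitted SVC
#' @param model an `svc_model`.
#' @param newdata matrix of rows to score.
#' @return numeric decision values (positive = second class level).
#' @export
svc_decision <- function(model, newdata) {
  stopifnot(inherits(model, "svc_model"))
  Kt <- kernel_matrix(.fm_values(newdata), model$X, model$kernel)
  as.vector(Kt %*% (model$alpha * model$y)) + model$b
}

#' @export
predict.svc_model <- function(object, newdata, ...) {
  d <- svc_decision(object, newdata)
  ifelse(d >= 0, object$levels[2L], object$levels[1L])
}
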