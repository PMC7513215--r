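#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end runner: the entropy estimator
#' used upstream (recorded for reporting; feature extraction happens in
#' [epoch_feature_matrix()] / [simulate_features()]), the reduction stage,
#' the component-selection threshold, and the cross-validation and SVM
#' settings.
#'
#' The protocol default is stratified 3-fold cross-validation. A single
#' stratified 70/30 holdout is available as `protocol = "holdout"`; the two
#' protocols are alternatives (a 3-fold split tests on 1/3, a holdout on
#' 30%) and the report names which one was used.
#'
#' @param estimator `"sample"`, `"fuzzy"`, or `"combination"` (metadata).
#' @param reducer `"kpca"` (default), `"pca"`, or `"none"`.
#' @param kernel [kernel_spec()] for the KPCA stage; default RBF with
#'   `delta = 0.2`, the protocol's preferred kernel.
#' @param cvc cumulative variance contribution threshold, default 0.90.
#' @param protocol `"cv"` (stratified k-fold, default) or `"holdout"`.
#' @param folds number of CV folds, default 3.
#' @param train_fraction holdout training fraction, default 0.70.
#' @param standardize standardize features before reduction; `NULL`
#'   (default) means TRUE for PCA (built into correlation PCA) and FALSE
#'   for KPCA/none.
#' @param svc_kernel [kernel_spec()] for the classifier; `NULL` = RBF with
#'   bandwidth `sqrt(n_features_in)` (kernel scale 1/n_features).
#' @param svc_C SVM box constraint, default 1.
#' @param seed RNG seed controlling fold assignment, default 1.
#' @param label optional name for comparison tables.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(estimator = "sample",
                            reducer = c("kpca", "pca", "none"),
                            kernel = kernel_spec("rbf", delta = 0.2),
                            cvc = 0.90,
                            protocol = c("cv", "holdout"),
                            folds = 3L, train_fraction = 0.70,
                            standardize = NULL,
                            svc_kernel = NULL, svc_C = 1,
                            seed = 1L, label = NULL) {
  reducer <- match.arg(reducer)
  protocol <- match.arg(protocol)
  stopifnot(folds >= 2L, train_fraction > 0, train_fraction < 1,
            cvc > 0, cvc <= 1, svc_C > 0)
  if (is.null(label))
    label <- paste0(estimator, "_",
                    switch(reducer, none = "raw", pca = "pca",
                           kpca = paste0("kpca:", kernel$family)))
  structure(list(estimator = estimator, reducer = reducer, kernel = kernel,
                 cvc = cvc, protocol = protocol, folds = as.integer(folds),
                 train_fraction = train_fraction, standardize = standardize,
                 svc_kernel = svc_kernel, svc_C = svc_C,
                 seed = as.integer(seed), label = label),
            class = "pipeline_config")
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals rows round-robin, so the class
#' ratio of every fold matches the overall ratio to within one sample.
#'
#' @param labels per-row class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k, one per row.
#' @export
stratified_folds <- function(labels, k = 3L, seed = 1L) {
  stopifnot(k >= 2L, length(labels) >= k)
  .with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# fit the configured reducer on training rows, project both splits,
# returning the score matrices and number of components kept
.reduce_split <- function(Xtr, Xte, config) {
  std <- config$standardize
  switch(config$reducer,
    none = {
      if (isTRUE(std)) {
        s <- standardize(Xtr)
        list(train = s$values, test = apply_standardizer(s, Xte), k = ncol(Xtr))
      } else list(train = Xtr, test = Xte, k = ncol(Xtr))
    },
    pca = {
      fit <- pca_fit(Xtr)  # correlation PCA standardizes internally
      k <- cvc_select(fit$contribution_rates, config$cvc)
      list(train = fit$scores[, seq_len(k), drop = FALSE],
           test = pca_project(fit, Xte, k), k = k)
    },
    kpca = {
      fit <- kpca_fit(Xtr, config$kernel, standardize = isTRUE(std))
      k <- cvc_select(fit$contribution_rates, config$cvc)
      list(train = fit$scores[, seq_len(k), drop = FALSE],
           test = kpca_project(fit, Xte, k), k = k)
    })
}

.fit_eval_split <- function(Xtr, ytr, Xte, yte, config) {
  if (length(unique(ytr)) < 2L)
    stop_eegkpca("a training split contains a single class; use stratified splitting",
                 "eegkpca_single_class")
  red <- .reduce_split(Xtr, Xte, config)
  kern <- config$svc_kernel %||% kernel_spec("rbf", delta = sqrt(ncol(red$train)))
  model <- svc_fit(red$train, ytr, kernel = kern, C = config$svc_C)
  pred_tr <- predict(model, red$train)
  pred_te <- predict(model, red$test)
  list(
    n_components = red$k,
    train_accuracy = 100 * mean(pred_tr == ytr),
    test_accuracy = 100 * mean(pred_te == yte),
    confusion = table(truth = factor(yte, levels = model$levels),
                      predicted = factor(pred_te, levels = model$levels))
  )
}

#' Run the full classification pipeline
#'
#' Feature reduction is fitted on each training split only and the held-out
#' split is projected with the stored training statistics (feature means/SDs
#' for PCA, Gram-matrix means for KPCA), so no information leaks across the
#' split. The classifier is the built-in SVC ([svc_fit()]).
#'
#' @param features a labeled `feature_matrix`, or a numeric matrix plus
#'   `labels`.
#' @param config a [pipeline_config()].
#' @param labels per-row 0/1 labels (ignored if `features` carries them).
#' @param folds optional precomputed fold assignment (integer per row);
#'   default: stratified folds from `config$seed`. Ignored for the holdout
#'   protocol.
#' @return a `classification_report`: per-fold and mean test accuracy (%),
#'   components used per fold, confusion counts, and the config echo.
#' @export
run_pipeline <- function(features, config = pipeline_config(),
                         labels = NULL, folds = NULL) {
  X <- .fm_values(features)
  if (inherits(features, "feature_matrix") && !is.null(features$labels))
    labels <- features$labels
  if (is.null(labels))
    stop_eegkpca("labeled data required", "eegkpca_bad_input")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop_eegkpca("both classes must be present", "eegkpca_single_class")

  if (config$protocol == "holdout") {
    idx_tr <- .with_seed(config$seed, {
      unlist(lapply(split(seq_along(labels), labels), function(ix)
        sample(ix, round(config$train_fraction * length(ix)))))
    })
    splits <- list(list(train = sort(idx_tr),
                        test = setdiff(seq_along(labels), idx_tr)))
  } else {
    if (is.null(folds)) folds <- stratified_folds(labels, config$folds,
                                                  config$seed)
    stopifnot(length(folds) == length(labels))
    splits <- lapply(sort(unique(folds)), function(f)
      list(train = which(folds != f), test = which(folds == f)))
  }

  res <- lapply(splits, function(sp)
    .fit_eval_split(X[sp$train, , drop = FALSE], labels[sp$train],
                    X[sp$test, , drop = FALSE], labels[sp$test], config))
  conf <- Reduce(`+`, lapply(res, `[[`, "confusion"))
  structure(list(
    protocol = config$protocol,
    fold_accuracy = vapply(res, `[[`, numeric(1), "test_accuracy"),
    train_accuracy = vapply(res, `[[`, numeric(1), "train_accuracy"),
    mean_accuracy = mean(vapply(res, `[[`, numeric(1), "test_accuracy")),
    n_components = vapply(res, `[[`, numeric(1), "n_components"),
    confusion = conf,
    config = config,
    seed = config$seed
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s | %s\n", x$config$label,
              if (x$protocol == "cv")
                sprintf("stratified %d-fold CV", length(x$fold_accuracy))
              else sprintf("stratified %.0f/%.0f holdout",
                           100 * x$config$train_fraction,
                           100 * (1 - x$config$train_fraction))))
  cat(sprintf("  components per split: %s\n",
              paste(x$n_components, collapse = ", ")))
  cat(sprintf("  test accuracy per split (%%): %s\n",
              paste(sprintf("%.2f", x$fold_accuracy), collapse = ", ")))
  cat(sprintf("  mean accuracy: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}

#' Compare several pipeline configurations on shared folds
#'
#' Every configuration is evaluated on the *same* stratified fold
#' assignment (drawn from `seed`), so accuracy differences are paired, not
#' confounded by the split.
#'
#' @param features labeled `feature_matrix` (or matrix + `labels`).
#' @param configs list of [pipeline_config()] objects (at least 2).
#' @param labels per-row labels if `features` is a bare matrix.
#' @param seed seed for the shared fold assignment, default 1.
#' @param folds number of folds, default 3.
#' @return a list of class `method_comparison`: `table` (one row per
#'   config, in config order) and the full `reports`.
#' @export
compare_methods <- function(features, configs, labels = NULL,
                            seed = 1L, folds = 3L) {
  if (length(configs) < 2L)
    stop_eegkpca("need at least two configurations to compare",
                 "eegkpca_bad_input")
  bad <- which(!vapply(configs, inherits, logical(1), "pipeline_config"))
  if (length(bad))
    stop_eegkpca(sprintf("not pipeline_config objects: entries %s",
                         paste(bad, collapse = ", ")), "eegkpca_bad_input")
  if (inherits(features, "feature_matrix") && !is.null(features$labels))
    labels <- features$labels
  shared <- stratified_folds(as.integer(labels), folds, seed)
  reports <- lapply(configs, function(cf) {
    cf$protocol <- "cv"; cf$folds <- as.integer(folds)
    run_pipeline(features, cf, labels = labels, folds = shared)
  })
  tab <- data.frame(
    label = vapply(configs, `[[`, character(1), "label"),
    estimator = vapply(configs, `[[`, character(1), "estimator"),
    reducer = vapply(configs, `[[`, character(1), "reducer"),
    cvc = vapply(configs, `[[`, numeric(1), "cvc"),
    mean_components = vapply(reports, function(r) mean(r$n_components),
                             numeric(1)),
    mean_accuracy = vapply(reports, `[[`, numeric(1), "mean_accuracy"),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, reports = reports, seed = seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison> shared stratified folds, seed", x$seed, "\n")
  tab <- x$table
  tab$mean_accuracy <- sprintf("%.2f%%", tab$mean_accuracy)
  print(tab, row.names = FALSE)
  invisible(x)
}
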