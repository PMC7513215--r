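#' Read a multichannel signal matrix
#'
#' Delimited numeric text (comma, tab or whitespace separated, autodetected,
#' optional header naming the channels, one column per channel), or a
#' continuous EDF (European Data Format) recording via [read_edf()]. For
#' delimited input the sampling rate is not stored in the file and must be
#' supplied.
#'
#' @param path input file.
#' @param rate sampling rate in Hz (required for delimited input; for EDF
#'   it is read from the header and must not conflict if supplied).
#' @param format `"auto"` (by extension), `"delimited"`, or `"edf"`.
#' @return a list with `signals` (samples x channels matrix with channel
#'   names), `rate`, and `channels`.
#' @export
read_signal_matrix <- function(path, rate = NULL,
                               format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_eegkpca(sprintf("file not found: %s", path), "eegkpca_io_error")
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") {
    edf <- read_edf(path)
    if (!is.null(rate) && abs(rate - edf$rate) > 1e-9)
      stop_eegkpca(sprintf("supplied rate %g conflicts with EDF header rate %g",
                           rate, edf$rate), "eegkpca_io_error")
    return(edf)
  }
  if (is.null(rate))
    stop_eegkpca("sampling rate required for delimited input", "eegkpca_io_error")
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  header <- !grepl("^[-+0-9.eE \t,]+$", first)
  df <- tryCatch(
    read.table(path, sep = sep, header = header, colClasses = "numeric"),
    error = function(e) stop_eegkpca(
      sprintf("failed to parse %s (ragged or non-numeric?): %s",
              path, conditionMessage(e)), "eegkpca_io_error"))
  sig <- as.matrix(df)
  if (!is.numeric(sig) || !all(is.finite(sig)))
    stop_eegkpca("non-numeric or non-finite cells in signal file",
                 "eegkpca_io_error")
  channels <- if (header) colnames(df) else sprintf("ch%02d", seq_len(ncol(sig)))
  colnames(sig) <- channels
  list(signals = sig, rate = rate, channels = channels)
}

#' Minimal EDF reader
#'
#' Parses continuous EDF (not EDF+) recordings whose signals all share one
#' sampling rate, which covers standard multichannel EEG exports. Samples
#' are converted from the stored 16-bit integers to physical units via the
#' per-signal calibration fields. Written in-package because no EDF reader
#' is available in the supported dependency set.
#'
#' @param path an EDF file.
#' @return a list with `signals` (samples x channels), `rate`, `channels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8)                       # version
  hdr(80); hdr(80)             # patient / recording id
  hdr(8); hdr(8)               # start date / time
  header_bytes <- as.integer(hdr(8))
  hdr(44)                      # reserved
  n_records <- as.integer(hdr(8))
  record_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1L)
    stop_eegkpca("unparseable EDF header", "eegkpca_io_error")
  fld <- function(w) vapply(seq_len(ns), function(i) hdr(w), character(1))
  labels <- fld(16)
  fld(80); fld(8)              # transducer, physical dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                      # prefiltering
  nsamp <- as.integer(fld(8))  # samples per record per signal
  fld(32)                      # reserved
  if (length(unique(nsamp)) != 1L)
    stop_eegkpca("EDF signals have differing sampling rates; not supported",
                 "eegkpca_io_error")
  seek(con, header_bytes)
  spr <- nsamp[1L]
  gain <- (pmax - pmin) / (dmax - dmin)
  sig <- matrix(NA_real_, n_records * spr, ns)
  for (rec in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr, size = 2L, endian = "little")
      sig[((rec - 1L) * spr + 1L):(rec * spr), s] <-
        pmin[s] + gain[s] * (d - dmin[s])
    }
  }
  colnames(sig) <- labels
  list(signals = sig, rate = spr / record_dur, channels = labels)
}

#' Write / read a feature matrix as delimited text
#'
#' CSV with a header row of channel names and, when labels are present, a
#' trailing `label` column. Values round-trip at full double precision.
#'
#' @param fm a `feature_matrix`.
#' @param path output path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  if (!is.null(fm$labels)) df$label <- fm$labels
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, sep = ",", header = TRUE, colClasses = "numeric")
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  feature_matrix(as.matrix(df), labels = labels)
}

#' Write a classification report or comparison table
#'
#' Writes full-precision JSON at `path` and, alongside it, a delimited
#' summary (same path with a `.csv` extension) with accuracies rendered at
#' two decimals. Re-reading the JSON reproduces every numeric field
#' exactly.
#'
#' @param x a `classification_report` or `method_comparison`.
#' @param path output path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  csv <- sub("\\.json$", ".csv", path)
  if (identical(csv, path)) csv <- paste0(path, ".csv")
  if (inherits(x, "classification_report")) {
    payload <- list(
      kind = "classification_report",
      protocol = x$protocol,
      fold_accuracy = x$fold_accuracy,
      train_accuracy = x$train_accuracy,
      mean_accuracy = x$mean_accuracy,
      n_components = x$n_components,
      confusion = as.data.frame(x$confusion),
      seed = x$seed,
      config = .config_payload(x$config)
    )
    summary_df <- data.frame(
      split = seq_along(x$fold_accuracy),
      n_components = x$n_components,
      accuracy = sprintf("%.2f", x$fold_accuracy)
    )
  } else if (inherits(x, "method_comparison")) {
    payload <- list(kind = "method_comparison", seed = x$seed,
                    table = x$table)
    summary_df <- transform(x$table,
                            mean_accuracy = sprintf("%.2f", mean_accuracy))
  } else {
    stop_eegkpca("unsupported report object", "eegkpca_bad_input")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write.table(summary_df, csv, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

.config_payload <- function(cf) {
  out <- unclass(cf)
  out$kernel <- unclass(out$kernel)
  if (!is.null(out$svc_kernel)) out$svc_kernel <- unclass(out$svc_kernel)
  out
}

#' Serialize a fitted KPCA model to JSON
#'
#' Stores the kernel spec, eigenvalues, dual coefficients, training rows
#' and centering statistics at full precision so the model can be reloaded
#' and used to project new samples with [kpca_project()].
#'
#' @param fitted a `decomposition_result` from [kpca_fit()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_kpca_model <- function(fitted, path) {
  stopifnot(inherits(fitted, "decomposition_result"), fitted$method == "kpca")
  std <- fitted$centering_state$standardizer
  payload <- list(
    kind = "kpca_model",
    spec = unclass(fitted$spec),
    eigenvalues = fitted$eigenvalues,
    gram_eigenvalues = fitted$gram_eigenvalues,
    coefficients = fitted$coefficients,
    contribution_rates = fitted$contribution_rates,
    n_dropped = fitted$n_dropped,
    n_selected = fitted$n_selected,
    kernel_centering = fitted$centering_state$kernel,
    standardizer = if (is.null(std)) NULL else
      list(center = std$center, scale = std$scale),
    X_train = fitted$X_train
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_kpca_model
#' @export
read_kpca_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(kernel_spec, as.list(p$spec))
  std <- NULL
  if (!is.null(p$standardizer)) {
    std <- structure(list(center = unlist(p$standardizer$center),
                          scale = unlist(p$standardizer$scale)),
                     class = "standardizer")
  }
  structure(list(
    method = "kpca", spec = spec,
    eigenvalues = p$eigenvalues,
    gram_eigenvalues = p$gram_eigenvalues,
    coefficients = as.matrix(p$coefficients),
    contribution_rates = p$contribution_rates,
    scores = NULL,
    n_dropped = p$n_dropped,
    n_selected = p$n_selected,
    centering_state = list(
      kernel = list(col_means = unlist(p$kernel_centering$col_means),
                    grand_mean = p$kernel_centering$grand_mean),
      standardizer = std),
    X_train = as.matrix(p$X_train)
  ), class = "decomposition_result")
}
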