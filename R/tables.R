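#' Bundled per-component contribution-rate tables
#'
#' Example contribution-rate spectra for a 30-electrode entropy feature
#' matrix from a driving-fatigue recognition study, for linear PCA
#' (`"pca"`) and polynomial-kernel KPCA at orders 2, 1 and 0.5 (`"poly2"`,
#' `"poly1"`, `"poly05"`), each reported for two cohorts (experiment 1: a
#' 600-epoch / 10-subject matrix; experiment 2: 900 epochs / 15 subjects).
#' They serve as fixtures for [cvc_select()]: e.g. the experiment-1 PCA
#' spectrum reaches 90% cumulative contribution at 10 components.
#'
#' @param method `"pca"`, `"poly2"`, `"poly1"`, or `"poly05"`.
#' @param experiment cohort, 1 or 2.
#' @return numeric vector of 30 non-increasing contribution rates.
#' @export
contribution_rate_table <- function(method = c("pca", "poly2", "poly1", "poly05"),
                                    experiment = 1L) {
  method <- match.arg(method)
  stopifnot(experiment %in% c(1L, 2L))
  path <- system.file("extdata", "contribution_rates.csv",
                      package = "eegkpca", mustWork = TRUE)
  df <- read.table(path, sep = ",", header = TRUE)
  sel <- df[df$method == method & df$experiment == experiment, ]
  sel$rate[order(sel$component)]
}
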