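# Independent brute-force oracles, written directly from the estimator
# definitions and free of any package internals: every unordered template
# pair is enumerated (the j-loop is vectorized, nothing is pruned).

oracle_sampen <- function(x, m = 2L, r_factor = 0.25) {
  N <- length(x)
  r <- r_factor * sqrt(mean((x - mean(x))^2))
  nt <- N - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1L)) {
    js <- (i + 1L):nt
    dm <- abs(x[js] - x[i])
    for (k in seq_len(m - 1L)) dm <- pmax(dm, abs(x[js + k] - x[i + k]))
    B <- B + sum(dm < r)
    A <- A + sum(pmax(dm, abs(x[js + m] - x[i + m])) < r)
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

oracle_fuzzyen <- function(x, m = 2L, r_factor = 0.25, nf = 2) {
  N <- length(x)
  r <- r_factor * sqrt(mean((x - mean(x))^2))
  nt <- N - m
  centered <- function(len) {
    tm <- sapply(seq_len(len), function(k) x[seq_len(nt) + k - 1L])
    tm - rowMeans(tm)
  }
  phi <- function(len) {
    tm <- centered(len)
    tot <- 0
    for (i in seq_len(nt - 1L)) {
      js <- (i + 1L):nt
      d <- abs(tm[js, 1L] - tm[i, 1L])
      for (k in seq_len(len)[-1L]) d <- pmax(d, abs(tm[js, k] - tm[i, k]))
      tot <- tot + sum(exp(-d^nf / r))
    }
    tot / (nt * (nt - 1L) / 2)
  }
  log(phi(m)) - log(phi(m + 1L))
}

# scalar-loop kernel oracle
oracle_kernel <- function(X, Y, family, P = NULL, delta = NULL,
                          v = NULL, cc = NULL) {
  K <- matrix(0, nrow(X), nrow(Y))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(Y))) {
      dot <- sum(X[i, ] * Y[j, ])
      K[i, j] <- switch(family,
        linear = dot,
        polynomial = (dot + 1)^P,
        rbf = exp(-sum((X[i, ] - Y[j, ])^2) / delta^2),
        mlp = tanh(v * dot + cc))
    }
  }
  K
}

# epoch generators used across test files
make_epoch <- function(n, seed, kind = c("noise", "sine", "ar")) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    noise = rnorm(n),
    sine = sqrt(2) * sin(2 * pi * 8 * seq_len(n) / n + runif(1, 0, 2 * pi)),
    ar = as.numeric(stats::arima.sim(list(ar = 0.7), n)))
}

tiny_features <- function(n = 40, p = 5, seed = 1, gap = 0) {
  # two-class Gaussian blobs, `gap` = class mean separation
  set.seed(seed)
  lab <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + gap * lab
  list(X = X, labels = lab)
}

# run an expression in a fresh Rscript that can see the test library;
# used for command-line smoke tests
run_cli <- function(args) {
  script <- system.file("exec", "eegkpca", package = "eegkpca")
  stopifnot(nzchar(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
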