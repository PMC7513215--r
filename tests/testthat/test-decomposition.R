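test_that("standardize centers and scales with recoverable state", {
  set.seed(1)
  X <- matrix(rnorm(20 * 5, mean = 3, sd = 2), 20, 5)
  s <- standardize(X)
  expect_true(all(abs(colMeans(s$values)) <= 1e-12))
  expect_true(all(abs(apply(s$values, 2, sd) - 1) <= 1e-12))
  # idempotence: standardizing an already-standardized matrix changes nothing
  expect_equal(standardize(s$values)$values, s$values, tolerance = 1e-12)
  # stored state transforms new rows identically
  expect_equal(apply_standardizer(s, X), s$values, tolerance = 1e-12)
  expect_equal(standardize(cbind(a = c(1, 2, 3)))$values[, 1],
               c(-1, 0, 1), tolerance = 1e-12, ignore_attr = TRUE)
  Xz <- cbind(X, flat = 1)
  expect_error(standardize(Xz), "flat", class = "eegkpca_degenerate_column")
})

test_that("correlation PCA matches an independent SVD route", {
  set.seed(2)
  X <- matrix(rnorm(50 * 8), 50, 8)
  fit <- pca_fit(X)
  # oracle: singular values of the standardized matrix
  Y <- scale(X)
  lam_oracle <- svd(Y)$d^2 / (nrow(X) - 1)
  expect_equal(fit$eigenvalues, lam_oracle, tolerance = 1e-9)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_equal(sum(fit$contribution_rates), 1, tolerance = 1e-12)
  # unit-norm loadings
  expect_equal(colSums(fit$components^2), rep(1, 8), tolerance = 1e-9)
  # perfectly correlated pair: all variance on the first component
  Z <- cbind(rnorm(30))
  Z <- cbind(Z, 3 * Z[, 1] + 2)
  fit2 <- pca_fit(Z)
  expect_equal(fit2$contribution_rates, c(1, 0), tolerance = 1e-9)
  # independent columns at large m: near-uniform rates
  set.seed(3)
  W <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_true(all(abs(pca_fit(W)$contribution_rates - 0.25) < 0.04))
})

test_that("pca projection of training rows equals fit scores", {
  set.seed(4)
  X <- matrix(rnorm(30 * 6), 30, 6)
  fit <- pca_fit(X)
  expect_equal(pca_project(fit, X, 4), fit$scores[, 1:4], tolerance = 1e-10)
  expect_error(pca_project(fit, X, 7), class = "eegkpca_bad_input")
})

test_that("cvc_select reproduces the bundled contribution tables", {
  # stated component counts at thresholds 0.90 / 0.95 / 0.99
  expected <- list(
    pca_1 = c(10, 14, 23),    pca_2 = c(8, 13, 23),
    poly2_1 = c(8, 12, 26),   poly2_2 = c(7, 12, 25),
    poly1_1 = c(9, 14, 23),   poly1_2 = c(8, 13, 23),
    poly05_1 = c(10, 14, 22), poly05_2 = c(9, 13, 21))
  ths <- c(0.90, 0.95, 0.99)
  for (nm in names(expected)) {
    parts <- strsplit(nm, "_")[[1]]
    rates <- contribution_rate_table(parts[1], as.integer(parts[2]))
    got <- vapply(ths, function(th) as.numeric(cvc_select(rates, th)),
                  numeric(1))
    expect_equal(got, expected[[nm]], info = nm)
    # agreement with an exhaustive scan over k
    for (th in ths) {
      ok <- which(vapply(seq_along(rates),
                         function(k) sum(rates[1:k]) >= th, logical(1)))
      expect_identical(as.integer(cvc_select(rates, th)), min(ok), info = nm)
    }
  }
})

test_that("cvc_select edge cases", {
  expect_identical(cvc_select(1.0, 0.99), 1L)
  expect_identical(cvc_select(c(0.6, 0.3, 0.1), 0.9), 2L)
  expect_warning(k <- cvc_select(c(0.5, 0.2), 0.9), "below threshold")
  expect_identical(k, 2L)
  expect_error(cvc_select(numeric(0), 0.9), class = "eegkpca_bad_input")
  expect_error(cvc_select(c(0.2, 0.5), 0.9), class = "eegkpca_bad_input")
})

test_that("kernel matrices match a scalar-loop oracle", {
  set.seed(5)
  X <- matrix(rnorm(10 * 3), 10, 3)
  Y <- matrix(rnorm(7 * 3), 7, 3)
  specs <- list(
    list(spec = kernel_spec("linear"), fam = "linear"),
    list(spec = kernel_spec("polynomial", P = 2), fam = "polynomial", P = 2),
    list(spec = kernel_spec("rbf", delta = 0.7), fam = "rbf", delta = 0.7),
    list(spec = kernel_spec("mlp", v = 0.01, c = 0.1), fam = "mlp",
         v = 0.01, cc = 0.1))
  for (s in specs) {
    K <- kernel_matrix(X, Y, s$spec)
    Ko <- oracle_kernel(X, Y, s$fam, P = s$P, delta = s$delta,
                        v = s$v, cc = s$cc)
    expect_equal(K, Ko, tolerance = 1e-12, info = s$fam)
  }
  # fractional order needs a non-negative base: entropy-like positive data
  Xp <- abs(X) + 0.5; Yp <- abs(Y) + 0.5
  expect_equal(kernel_matrix(Xp, Yp, kernel_spec("polynomial", P = 0.5)),
               oracle_kernel(Xp, Yp, "polynomial", P = 0.5),
               tolerance = 1e-12)
  # and rejects a negative base rather than returning NaN
  expect_error(kernel_matrix(X, Y, kernel_spec("polynomial", P = 0.5)),
               class = "eegkpca_bad_input")
  # rbf self-Gram has a unit diagonal
  Kr <- kernel_matrix(X, X, kernel_spec("rbf", delta = 0.2))
  expect_equal(diag(Kr), rep(1, 10), tolerance = 1e-12)
  # order-1 polynomial is the linear Gram plus one
  expect_equal(kernel_matrix(X, X, kernel_spec("polynomial", P = 1)),
               kernel_matrix(X, X, kernel_spec("linear")) + 1,
               tolerance = 1e-12)
  expect_error(kernel_matrix(X, Y[, 1:2], kernel_spec("linear")),
               class = "eegkpca_bad_input")
  expect_error(kernel_spec("rbf"), class = "eegkpca_bad_input")
  expect_error(kernel_spec("polynomial", P = -1), class = "eegkpca_bad_input")
})

test_that("kernel centering zeroes row and column sums and is idempotent", {
  for (seed in 1:5) {
    set.seed(seed)
    K <- crossprod(matrix(rnorm(25), 5, 5))
    Kc <- center_kernel(K)
    expect_true(all(abs(rowSums(Kc)) <= 1e-10))
    expect_true(all(abs(colSums(Kc)) <= 1e-10))
    expect_equal(unname(center_kernel(Kc)), unname(Kc), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # rank-one all-ones kernel centers to exactly zero
  expect_equal(unname(center_kernel(matrix(1, 6, 6))), matrix(0, 6, 6),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(center_kernel(matrix(1, 2, 6)), class = "eegkpca_bad_input")
})

test_that("linear-kernel KPCA is equivalent to correlation PCA", {
  for (seed in 1:8) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 5), 25, 5)
    Y <- scale(X)  # same standardization the correlation PCA applies
    pfit <- pca_fit(X)
    kfit <- kpca_fit(Y, kernel_spec("linear"))
    nk <- kfit$n_selected
    # eigenvalue ratios agree on the retained spectrum
    expect_equal(kfit$eigenvalues / kfit$eigenvalues[1],
                 pfit$eigenvalues[1:nk] / pfit$eigenvalues[1],
                 tolerance = 1e-8, info = seed)
    # sample scores agree up to per-component sign
    expect_equal(abs(kfit$scores), abs(pfit$scores[, 1:nk]),
                 tolerance = 1e-8, ignore_attr = TRUE, info = seed)
    # projecting new rows agrees too
    set.seed(100 + seed)
    Xn <- matrix(rnorm(4 * 5), 4, 5)
    sp <- pca_project(pfit, Xn, nk)
    sk <- kpca_project(kfit, apply_standardizer(pfit$centering_state, Xn))
    expect_equal(abs(sk), abs(sp), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("kpca satisfies the dual eigen-relation on the centered Gram matrix", {
  set.seed(6)
  X <- matrix(rnorm(20 * 4), 20, 4)
  for (spec in list(kernel_spec("rbf", delta = 1.5),
                    kernel_spec("polynomial", P = 2),
                    kernel_spec("mlp", v = 0.5, c = 0.2))) {
    fit <- kpca_fit(X, spec)
    Kc <- center_kernel(kernel_matrix(X, X, spec))
    M <- nrow(X)
    for (k in seq_len(fit$n_selected)) {
      a <- fit$coefficients[, k]
      resid <- sqrt(sum((Kc %*% a - M * fit$eigenvalues[k] * a)^2))
      expect_lte(resid, 1e-8 * sqrt(sum(a^2)))
    }
    # unit feature-space axes: a' K~ a = 1
    q <- diag(t(fit$coefficients) %*% Kc %*% fit$coefficients)
    expect_equal(q, rep(1, fit$n_selected), tolerance = 1e-8)
    # contribution rates well-formed
    cr <- fit$contribution_rates
    expect_true(all(cr >= 0) && all(diff(cr) <= 1e-12))
    expect_lte(sum(cr), 1 + 1e-10)
  }
})

test_that("indefinite sigmoid kernels get their negative spectrum truncated", {
  set.seed(7)
  X <- matrix(rnorm(15 * 3, sd = 2), 15, 3)
  fit <- kpca_fit(X, kernel_spec("mlp", v = 1, c = -0.5))
  Kc <- center_kernel(kernel_matrix(X, X, kernel_spec("mlp", v = 1, c = -0.5)))
  expect_true(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values) < 0)
  expect_gt(fit$n_dropped, 0)
  expect_true(all(fit$eigenvalues > 0))
  expect_lte(sum(fit$contribution_rates), 1 + 1e-10)
})

test_that("kpca projection is consistent with the fit", {
  set.seed(8)
  X <- matrix(rnorm(18 * 4), 18, 4)
  spec <- kernel_spec("rbf", delta = 2)
  fit <- kpca_fit(X, spec)
  # the training set projects onto its own fit scores
  expect_equal(kpca_project(fit, X), fit$scores, tolerance = 1e-10)
  # a new sample identical to a training row reproduces that row's scores
  expect_equal(kpca_project(fit, X[3, , drop = FALSE]),
               fit$scores[3, , drop = FALSE], tolerance = 1e-10)
  expect_error(kpca_project(fit, X, k = fit$n_selected + 1),
               class = "eegkpca_bad_input")
  # constant input rows make every kernel row identical: degenerate
  expect_error(kpca_fit(matrix(1, 6, 3), kernel_spec("linear")),
               class = "eegkpca_degenerate_kernel")
})

test_that("kpca models survive a JSON round trip", {
  set.seed(9)
  X <- matrix(rnorm(12 * 3), 12, 3)
  fit <- kpca_fit(X, kernel_spec("rbf", delta = 1), standardize = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_kpca_model(fit, path)
  back <- read_kpca_model(path)
  Xn <- matrix(rnorm(5 * 3), 5, 3)
  expect_equal(kpca_project(back, Xn), kpca_project(fit, Xn),
               tolerance = 1e-12)
  expect_equal(back$contribution_rates, fit$contribution_rates,
               tolerance = 1e-12)
})
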