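test_that("sample and fuzzy entropy agree with brute-force oracles", {
  cases <- expand.grid(seed = 1:4, n = c(60, 150, 400),
                       kind = c("noise", "sine", "ar"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    x <- make_epoch(cases$n[i], cases$seed[i], cases$kind[i])
    expect_equal(sample_entropy(x), oracle_sampen(x), tolerance = 1e-12,
                 info = sprintf("sampen %s n=%d seed=%d", cases$kind[i],
                                cases$n[i], cases$seed[i]))
    expect_equal(fuzzy_entropy(x), oracle_fuzzyen(x), tolerance = 1e-12,
                 info = sprintf("fuzzyen %s n=%d seed=%d", cases$kind[i],
                                cases$n[i], cases$seed[i]))
  }
  # non-default parameters too
  x <- make_epoch(200, 11, "noise")
  expect_equal(sample_entropy(x, m = 3, r_factor = 0.4),
               oracle_sampen(x, m = 3, r_factor = 0.4), tolerance = 1e-12)
  expect_equal(fuzzy_entropy(x, m = 1, r_factor = 0.15, n = 3),
               oracle_fuzzyen(x, m = 1, r_factor = 0.15, nf = 3),
               tolerance = 1e-12)
})

test_that("a regular oscillation scores lower than noise of equal variance", {
  for (seed in 1:5) {
    s <- make_epoch(500, seed, "sine")
    w <- make_epoch(500, seed, "noise")
    expect_lt(sample_entropy(s), sample_entropy(w))
    expect_lt(fuzzy_entropy(s), fuzzy_entropy(w))
  }
})

test_that("degenerate and undefined inputs raise typed conditions", {
  konst <- rep(1, 100)
  expect_error(sample_entropy(konst), class = "eegkpca_degenerate_epoch")
  expect_error(fuzzy_entropy(konst), class = "eegkpca_degenerate_epoch")
  expect_error(combination_entropy(konst), class = "eegkpca_degenerate_epoch")
  # a strict ramp has no template matches at all: B = 0
  expect_error(sample_entropy(1:10), class = "eegkpca_undefined_entropy")
  expect_error(sample_entropy(rnorm(3)), class = "eegkpca_bad_input")
  expect_error(sample_entropy(c(rnorm(50), NA)), class = "eegkpca_bad_input")
})

test_that("sample entropy is invariant under affine amplitude transforms", {
  for (seed in 1:6) {
    x <- make_epoch(300, seed, "ar")
    ref <- sample_entropy(x)
    expect_equal(sample_entropy(2.5 * x - 7), ref, tolerance = 1e-10)
    expect_equal(sample_entropy(-0.3 * x + 100), ref, tolerance = 1e-10)
  }
})

test_that("template-match counts are non-decreasing in the tolerance r", {
  x <- make_epoch(250, 21, "noise")
  rs <- seq(0.05, 1, by = 0.05) * sd(x)
  cnt <- t(vapply(rs, function(r) sampen_counts(x, 2, r), numeric(2)))
  expect_true(all(diff(cnt[, "A"]) >= 0))
  expect_true(all(diff(cnt[, "B"]) >= 0))
})

test_that("combination-entropy slot: default stand-in, registration, clearing", {
  x <- make_epoch(200, 31, "noise")
  expect_equal(combination_entropy(x),
               (sample_entropy(x) + fuzzy_entropy(x)) / 2, tolerance = 1e-12)
  old <- register_combination_entropy(function(x, m, r_factor) 0)
  on.exit(register_combination_entropy(old), add = TRUE)
  expect_identical(combination_entropy(x), 0)
  register_combination_entropy(NULL)
  expect_error(combination_entropy(x), class = "eegkpca_config_error")
})

test_that("epoch feature matrix has epoch-by-channel layout", {
  set.seed(41)
  sig <- matrix(rnorm(6 * 100 * 4), ncol = 4)
  fm <- epoch_feature_matrix(sig, rate = 100, epoch_len = 1)
  expect_equal(dim(fm$values), c(6, 4))
  # single channel, single epoch reduces to sample_entropy
  one <- epoch_feature_matrix(sig[1:100, 1, drop = FALSE], rate = 100)
  expect_equal(unname(one$values[1, 1]), sample_entropy(sig[1:100, 1]),
               tolerance = 1e-15)
  # entry (p, q) is the entropy of channel q in epoch p
  expect_equal(unname(fm$values[3, 2]), sample_entropy(sig[201:300, 2]),
               tolerance = 1e-15)
  # trailing partial epoch dropped with a warning
  expect_warning(fm2 <- epoch_feature_matrix(sig[1:250, ], rate = 100),
                 "partial epoch")
  expect_equal(nrow(fm2$values), 2)
  expect_error(epoch_feature_matrix(sig, rate = 100, labels = c(0, 1)),
               class = "eegkpca_bad_input")
})

test_that("feature extraction is permutation-equivariant in channels", {
  set.seed(42)
  sig <- matrix(rnorm(4 * 100 * 5), ncol = 5)
  perm <- c(4, 1, 5, 3, 2)
  fm <- epoch_feature_matrix(sig, rate = 100)
  fmp <- epoch_feature_matrix(sig[, perm], rate = 100)
  expect_equal(unname(fmp$values), unname(fm$values[, perm]))
})

test_that("degenerate-channel policy: error by default, median imputation opt-in", {
  set.seed(43)
  sig <- matrix(rnorm(300 * 2), ncol = 2)
  sig[101:200, 2] <- 5  # one flat epoch in channel 2
  expect_error(epoch_feature_matrix(sig, rate = 100),
               class = "eegkpca_degenerate_epoch")
  expect_warning(fm <- epoch_feature_matrix(sig, rate = 100,
                                            on_degenerate = "impute"),
                 "imputed")
  expect_true(all(is.finite(fm$values)))
  expect_equal(unname(fm$values[2, 2]),
               median(fm$values[c(1, 3), 2]))
})
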