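test_that("GLM t-statistics match the pooled two-sample closed form", {
  y <- cbind(c(1, 2, 3, 3, 4, 5))
  x <- cbind(1, c(1, 1, 1, 0, 0, 0))  # intercept + group-1 indicator
  ct <- c(0, 1)                       # group1 - group2
  t_obs <- glm_tstat(y, x, ct)
  expect_equal(as.vector(t_obs), -sqrt(6), tolerance = 1e-12)  # = -2.449...
  # cross-check against the textbook pooled t
  tt <- t.test(y[1:3], y[4:6], var.equal = TRUE)
  expect_equal(as.vector(t_obs), unname(tt$statistic), tolerance = 1e-12)
})

test_that("t-statistics respect design invariances and degeneracies", {
  set.seed(2)
  x <- cbind(1, rep(c(0, 1), each = 4))
  y <- matrix(rnorm(8 * 5), 8)
  ct <- c(0, 1)
  base <- glm_tstat(y, x, ct)
  # adding a constant (absorbed by the intercept) leaves t unchanged
  expect_equal(as.vector(glm_tstat(y + 7, x, ct)), as.vector(base),
               tolerance = 1e-9)
  # contrast on the intercept of pure-noise-free constant data
  y0 <- matrix(1, 8, 2)
  t0 <- glm_tstat(y0, x, c(0, 1))
  expect_equal(as.vector(t0), c(0, 0))  # zero residual variance -> 0
  expect_equal(attr(t0, "degenerate"), 1:2)
  expect_error(glm_tstat(y, x, c(0, 0)), "all zero")
  expect_error(glm_tstat(y, cbind(x, x[, 2]), c(0, 1, 0)), "full column rank")
})

test_that("FWE p-values count as-or-more extreme null maxima", {
  # observed is the 5th largest of 1000: p = 5/1000
  null <- as.numeric(1:1000)
  expect_equal(fwe_pvalue(996, null), 0.005)
  # strictly greater than all others: p = 1/n
  expect_equal(fwe_pvalue(1000, null), 1 / 1000)
  # below all null values: p = 1
  expect_equal(fwe_pvalue(0.5, null), 1)
  # invariant to a strictly monotone joint transform
  obs <- c(0.5, 500.5, 996)
  expect_equal(fwe_pvalue(exp(obs / 100), exp(null / 100)), fwe_pvalue(obs, null))
})

test_that("significance thresholding is strict", {
  expect_equal(significant_fixels(c(0.05, 0.049, 1, 0.005)),
               c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(sum(significant_fixels(rep(1, 10))), 0)
})

test_that("permutation schedules are seeded, unique, and identity-first", {
  p1 <- permutation_schedule(8, 50, seed = 3)
  p2 <- permutation_schedule(8, 50, seed = 3)
  expect_identical(p1, p2)
  expect_equal(p1[1, ], 1:8)
  expect_equal(anyDuplicated(apply(p1, 1, paste, collapse = ",")), 0L)
  expect_false(identical(p1, permutation_schedule(8, 50, seed = 4)))
  # over-request: warn and enumerate
  expect_warning(pe <- permutation_schedule(4, 100, seed = 1), "exhaustively")
  expect_equal(nrow(pe), 24)
})

test_that("permutation p-values equal exhaustive relabelling enumeration at N = 6", {
  set.seed(13)
  n_fix <- 6
  co <- random_conn(n_fix)
  x <- cbind(1, rep(c(1, 0), each = 3))
  ct <- c(0, 1)
  y <- matrix(rnorm(6 * n_fix), 6)
  y[1:3, 1:2] <- y[1:3, 1:2] + 2  # plant an effect
  params <- cfe_params(dh = 0.1)
  fit <- cfe_permutation_test(y, x, ct, co, params = params,
                              n_permutations = 720, seed = 1)
  # oracle: every distinct 3-vs-3 assignment, pooled two-sample t,
  # brute-force CFE, max statistic
  combos <- combn(6, 3)
  null_max <- apply(combos, 2, function(g1) {
    tvec <- vapply(seq_len(n_fix), function(f) {
      unname(t.test(y[g1, f], y[-g1, f], var.equal = TRUE)$statistic)
    }, numeric(1))
    max(cfe_enhance_bruteforce(tvec, co, params))
  })
  p_oracle <- vapply(fit$enhanced, function(v) mean(null_max >= v - 1e-9),
                     numeric(1))
  expect_equal(fit$pvalue, p_oracle, tolerance = 1e-12)
})

test_that("the identity permutation floors p-values at 1/n_permutations", {
  set.seed(19)
  co <- random_conn(5)
  x <- cbind(1, rep(c(1, 0), each = 4))
  y <- matrix(rnorm(8 * 5), 8)
  y[1:4, 1] <- y[1:4, 1] + 5
  fit <- cfe_permutation_test(y, x, c(0, 1), co, n_permutations = 100, seed = 7)
  expect_true(all(fit$pvalue >= 1 / 100))
  expect_equal(fit$null_max[1], max(fit$enhanced))
  # a fixel whose enhanced value ties the identity maximum gets p >= 1/n
  expect_gte(fit$pvalue[which.max(fit$enhanced)], 1 / 100)
})

test_that("permutation tests are deterministic given the seed", {
  set.seed(29)
  co <- random_conn(6)
  x <- cbind(1, rep(c(1, 0), 4))
  y <- matrix(rnorm(8 * 6), 8)
  f1 <- cfe_permutation_test(y, x, c(0, 1), co, n_permutations = 60, seed = 11)
  f2 <- cfe_permutation_test(y, x, c(0, 1), co, n_permutations = 60, seed = 11)
  expect_identical(f1$pvalue, f2$pvalue)
  expect_identical(f1$null_max, f2$null_max)
})

test_that("tidy and glance summarise a fit", {
  set.seed(37)
  co <- random_conn(5)
  x <- cbind(1, rep(c(1, 0), each = 3))
  y <- matrix(rnorm(6 * 5), 6)
  fit <- cfe_permutation_test(y, x, c(0, 1), co, n_permutations = 20, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("fixel", "tstat", "enhanced", "pvalue", "significant"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_permutations, 20)
})
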