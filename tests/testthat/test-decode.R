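small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_iterations = 5, penalty_grid = c(1, 10),
         kernel_width_grid = c(NA, 0.1), n_shuffles = 100, seed = 1),
    list(...))
  do.call(decoder_config, args)
}

test_that("separable classes decode near-perfectly; permuted labels sit at chance", {
  b <- fx_blobs(n_per_class = 20, sep = 6)
  cfg <- small_cfg()
  fit <- fit_and_test(b$x, cfg, y = b$y)
  expect_gte(fit$mean_accuracy, 0.95)
  expect_equal(fit$mean_accuracy, mean(fit$iteration_accuracies))

  set.seed(2)
  yperm <- sample(b$y)
  null_fit <- empirical_null_and_p(fit_and_test(b$x, cfg, y = yperm), cfg)
  expect_gt(null_fit$mean_accuracy, 0.25)
  expect_lt(null_fit$mean_accuracy, 0.75)
  expect_false(null_fit$significant)

  expect_error(fit_and_test(matrix(1, 40, 3), cfg, y = b$y), "zero variance")
  expect_error(fit_and_test(b$x[c(1:5, 21:25), ], cfg, y = b$y[c(1:5, 21:25)]),
               "at least 10")
})

test_that("shuffle p equals the exhaustive permutation p on tiny test sets", {
  b <- fx_blobs(n_per_class = 10, sep = 1.5, seed = 5)
  cfg <- small_cfg(n_iterations = 1)
  fit <- empirical_null_and_p(fit_and_test(b$x, cfg, y = b$y), cfg)
  expect_true(fit$exact_null)

  # independent brute force over every assignment of the test-label multiset
  pr <- fit$preds[[1]]
  n <- length(pr$truth)
  lv <- sort(unique(pr$truth))
  pos_sets <- utils::combn(n, sum(pr$truth == lv[1]))
  null <- apply(pos_sets, 2, function(pos) {
    lab <- rep(lv[2], n); lab[pos] <- lv[1]
    mean(pr$pred == lab)
  })
  expect_equal(sort(fit$null_accuracies), sort(null))
  expect_equal(fit$p_value, mean(null >= fit$mean_accuracy))
  expect_lte(n, 8)  # the regime in which exhaustive enumeration must engage
})

test_that("a perfect decoder attains exactly the add-one permutation floor", {
  b <- fx_blobs(n_per_class = 30, sep = 10, seed = 6)
  cfg <- small_cfg(n_iterations = 2)
  fit <- empirical_null_and_p(fit_and_test(b$x, cfg, y = b$y), cfg)
  expect_equal(fit$mean_accuracy, 1)
  expect_false(fit$exact_null)
  expect_equal(fit$p_value, 1 / (cfg$n_shuffles + 1))
})

test_that("BH step-up matches the hand-computed oracle", {
  r <- bh_fdr(c(0.01, 0.02, 0.04, 0.5), q = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_false(any(bh_fdr(rep(1, 6))$reject))
  one <- bh_fdr(0.04)
  expect_equal(one$adjusted, 0.04)
  expect_true(one$reject)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("rank-sum contrast comparison is exact, monotone and guarded", {
  expect_warning(p <- compare_contrasts(rep(0.6, 5), rep(0.6, 5)), "identical")
  expect_equal(p, 1)
  # disjoint supports, n = 5 vs 5: exact two-sided minimum 2 / C(10,5)
  expect_equal(compare_contrasts(1:5, 11:15), 2 / choose(10, 5))
  set.seed(3)
  a <- rnorm(20, 0.65, 0.05)
  p_small <- compare_contrasts(a, rnorm(20, 0.63, 0.05))
  p_large <- compare_contrasts(a, rnorm(20, 0.45, 0.05))
  expect_lt(p_large, p_small)
  expect_error(compare_contrasts(numeric(0), 1), "non-empty")
})

test_that("group-level null is assembled per shuffle index and diluted by null datasets", {
  mk_sweep <- function(acc, null_mean, seed) {
    set.seed(seed)
    res <- lapply(c(-0.1, 0), function(off) {
      structure(list(offset = off, mean_accuracy = acc,
                     null_accuracies = rnorm(200, null_mean, 0.03),
                     p_value = NA_real_), class = "si_decode")
    })
    structure(list(offsets = c(-0.1, 0), results = res, contrast = "silence"),
              class = "si_sweep")
  }
  strong <- lapply(1:3, function(i) mk_sweep(0.9, 0.5, i))
  g <- group_significance(strong)
  expect_true(all(g$significant))

  # a modest signal dataset among nulls: the group mean dilutes its evidence
  modest <- mk_sweep(0.56, 0.5, 11)
  p_alone <- sapply(modest$results, function(r)
    (1 + sum(r$null_accuracies >= r$mean_accuracy)) / (1 + length(r$null_accuracies)))
  gm <- group_significance(c(list(modest), lapply(4:6, function(i) mk_sweep(0.5, 0.5, i))))
  expect_true(all(gm$p > p_alone))

  bad <- mk_sweep(0.9, 0.5, 9); bad$offsets <- c(0, 0.1)
  expect_error(group_significance(c(strong[1], list(bad))), "misaligned")
  expect_error(group_significance(strong[1]), "at least 2")
})

test_that("offset sweep on the signal fixture recovers causal intent and is deterministic", {
  fx <- fx_signal()
  cfg <- small_cfg(n_iterations = 3)
  sw <- offset_sweep(fx$env, fx$events, cfg, offsets = c(-1.2, -0.2, 0))
  expect_equal(sw$table$offset_s, c(-1.2, -0.2, 0))
  # strong planted signal: significant at and just before voice onset, not early
  expect_false(sw$table$significant[1])
  expect_true(sw$table$significant[3])
  expect_gt(sw$table$mean_accuracy[3], sw$table$mean_accuracy[1])
  expect_equal(sw$first_significant_offset, -0.2)

  sw2 <- offset_sweep(fx$env, fx$events, cfg, offsets = c(-1.2, -0.2, 0))
  expect_identical(sw$table, sw2$table)

  # single-electrode map: production channels informative, silent ones not
  # (no-CAR fixture: referencing would leak production signal into every channel)
  fxc <- fx_clean()
  cfg_e <- small_cfg(n_iterations = 3)
  map <- single_electrode_map(fxc$env, fxc$events, cfg_e)
  expect_equal(nrow(map), 8)
  prod <- grepl("production", map$label)
  silent <- grepl("silent", map$label)
  expect_true(all(map$significant[prod]))
  expect_false(any(map$significant[silent]))
  expect_gt(min(map$mean_accuracy[prod]), max(map$mean_accuracy[silent]))
})
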