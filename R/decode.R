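#' Decoder configuration
#'
#' Holds every tunable of the decoding machinery: the 80/20 outer resample,
#' 5-fold inner cross-validation, the RBF-SVM hyperparameter grids
#' (`penalty` = soft-margin cost C, `kernel_width` = RBF gamma; `NA` in the
#' width grid means `1/d` for feature dimension `d`), the 20 outer
#' iterations, the 500-shuffle empirical null and the significance level.
#'
#' @param outer_split Training fraction of the outer resample (0.8).
#' @param inner_folds Inner CV folds (5).
#' @param n_iterations Outer resample iterations (20).
#' @param penalty_grid Positive reals, grid for the SVM cost term.
#' @param kernel_width_grid Positive reals (or `NA` = 1/d), grid for gamma.
#' @param n_shuffles Label shuffles for the empirical chance distribution
#'   (at least 100; tiny test sets fall back to exhaustive enumeration).
#' @param alpha Significance level (0.05).
#' @param seed Integer seed; every random step derives a substream from it.
#' @return A validated list of class `si_decoderconfig`.
#' @export
decoder_config <- function(outer_split = 0.8, inner_folds = 5, n_iterations = 20,
                           penalty_grid = c(0.1, 1, 10, 100),
                           kernel_width_grid = c(0.01, 0.1, NA, 1, 10),
                           n_shuffles = 500, alpha = 0.05, seed = 1) {
  if (!(outer_split > 0 && outer_split < 1)) .stopf("outer_split must be in (0, 1)")
  if (!length(penalty_grid) || !length(kernel_width_grid)) .stopf("grids must be non-empty")
  if (any(penalty_grid <= 0)) .stopf("penalty grid values must be positive")
  if (any(!is.na(kernel_width_grid) & kernel_width_grid <= 0))
    .stopf("kernel width grid values must be positive")
  if (n_shuffles < 100) .stopf("n_shuffles must be at least 100")
  if (!.is_count(n_iterations) || !.is_count(inner_folds)) .stopf("counts must be positive integers")
  structure(list(outer_split = outer_split, inner_folds = inner_folds,
                 n_iterations = n_iterations, penalty_grid = sort(penalty_grid),
                 kernel_width_grid = kernel_width_grid, n_shuffles = n_shuffles,
                 alpha = alpha, seed = as.integer(seed)),
            class = "si_decoderconfig")
}

# Stratified index split: per class, `frac` of rows to train.
.strat_split <- function(y, frac) {
  train <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- round(frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  sort(train)
}

# Stratified fold ids 1..k.
.strat_folds <- function(y, k) {
  f <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

# Core nested-CV SVM evaluation on a plain matrix + factor. Returns
# per-iteration accuracies and the held-out predictions needed for the
# shuffle null.
.fit_svm_core <- function(x, y, cfg) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) .stopf("decoding needs exactly two classes")
  if (min(table(y)) < 10) .stopf("need at least 10 rows per class (have %d)", min(table(y)))
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) .stopf("degenerate features: zero variance in every column")
  widths <- cfg$kernel_width_grid
  widths[is.na(widths)] <- 1 / ncol(x)
  grid <- expand.grid(width = sort(unique(widths)), penalty = cfg$penalty_grid)
  grid <- grid[order(grid$penalty, grid$width), ]

  accs <- numeric(cfg$n_iterations)
  preds <- vector("list", cfg$n_iterations)
  for (it in seq_len(cfg$n_iterations)) {
    set.seed(.sub_seed(cfg$seed, 20, it))
    tr <- .strat_split(y, cfg$outer_split)
    te <- setdiff(seq_len(nrow(x)), tr)
    xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    mu <- colMeans(xtr); sg <- apply(xtr, 2, stats::sd); sg[sg == 0] <- 1
    xtr <- scale(xtr, mu, sg)
    xte <- scale(x[te, , drop = FALSE], mu, sg)
    folds <- .strat_folds(ytr, cfg$inner_folds)
    cv_acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      hit <- 0L; tot <- 0L
      for (fd in seq_len(cfg$inner_folds)) {
        va <- folds == fd
        if (!any(va) || length(unique(ytr[!va])) < 2) next
        m <- e1071::svm(xtr[!va, , drop = FALSE], ytr[!va], kernel = "radial",
                        cost = grid$penalty[g], gamma = grid$width[g], scale = FALSE)
        p <- predict(m, xtr[va, , drop = FALSE])
        hit <- hit + sum(p == ytr[va]); tot <- tot + sum(va)
      }
      cv_acc[g] <- if (tot > 0) hit / tot else 0
    }
    best <- which.max(cv_acc)  # first max: smallest penalty, then smallest width
    m <- e1071::svm(xtr, ytr, kernel = "radial",
                    cost = grid$penalty[best], gamma = grid$width[best], scale = FALSE)
    p <- predict(m, xte)
    accs[it] <- mean(p == y[te])
    preds[[it]] <- list(pred = as.character(p), truth = as.character(y[te]),
                        test_rows = te,
                        penalty = grid$penalty[best], width = grid$width[best])
  }
  list(iteration_accuracies = accs, mean_accuracy = mean(accs), preds = preds,
       labels = as.character(y))
}

#' Fit and test the speech-intent decoder at one offset
#'
#' Twenty (configurable) iterations of: stratified 80/20 resplit; 5-fold
#' cross-validated grid search over (penalty, kernel width) on the training
#' portion; refit of the winning hyperparameters on the full training set;
#' scoring on the held-out 20%. Features are standardised with training-set
#' mean/SD only. Held-out predictions are retained per iteration so the
#' empirical chance distribution can be computed by label shuffling.
#'
#' @param features An `si_features` object (or a plain numeric matrix, with
#'   labels in `y`).
#' @param cfg A [decoder_config()].
#' @param y Class factor when `features` is a plain matrix.
#' @return An `si_decode` object: `iteration_accuracies`, `mean_accuracy`,
#'   retained predictions, and (after [empirical_null_and_p()])
#'   `null_accuracies`, `p_value`, `p_adjusted`, `significant`.
#' @export
fit_and_test <- function(features, cfg, y = NULL) {
  if (inherits(features, "si_features")) {
    x <- features$x; y <- features$y; off <- features$offset
  } else {
    x <- features; off <- NA_real_
    if (is.null(y)) .stopf("labels `y` required with a plain feature matrix")
  }
  res <- .fit_svm_core(x, y, cfg)
  structure(list(
    offset = off, iteration_accuracies = res$iteration_accuracies,
    mean_accuracy = res$mean_accuracy, preds = res$preds, labels = res$labels,
    null_accuracies = NULL, p_value = NA_real_, p_adjusted = NA_real_,
    significant = NA, exact_null = FALSE
  ), class = "si_decode")
}

#' Empirical chance distribution and permutation p-value
#'
#' For each shuffle the trial labels are permuted once at the dataset level
#' and every iteration's stored test predictions are re-scored against the
#' permuted labels of its own test rows; the across-iteration mean of these
#' shuffled accuracies forms one sample of the empirical chance distribution
#' (`n_shuffles` samples). Permuting coherently across iterations matters:
#' the outer resamples share test rows, so their accuracies are positively
#' correlated, and a null built from per-iteration-independent shuffles
#' under-disperses and inflates the false-positive rate. The p-value is the
#' add-one permutation estimate
#' `(1 + #\{null >= observed\}) / (1 + n_shuffles)`.
#' The significance gate compares the observed mean against the 95th
#' percentile of the *pooled* chance distribution of single-iteration
#' shuffled accuracies (`null_pooled`), which is wider than the mean-null
#' and keeps borderline chance results from riding through the step-up
#' correction on the coattails of genuinely decodable ones.
#' When a single outer iteration is used (no cross-iteration correlation)
#' and the test set admits no more distinct label arrangements than
#' `n_shuffles`, the null is enumerated exhaustively over test-set label
#' permutations and the p-value is exact. A result is `significant` when the
#' observed mean accuracy exceeds the null's 95th percentile *and* the
#' (BH-adjusted, where applicable) p-value is below `alpha`.
#'
#' @param fit An `si_decode` from [fit_and_test()].
#' @param cfg The [decoder_config()] used for the fit.
#' @return The `si_decode` with `null_accuracies`, `p_value`, `p_adjusted`
#'   (set equal to `p_value` until a multiple-comparison pass overwrites it)
#'   and `significant` filled.
#' @export
empirical_null_and_p <- function(fit, cfg) {
  stopifnot(inherits(fit, "si_decode"))
  n_iter <- length(fit$preds)
  if (n_iter == 1) {
    truth <- fit$preds[[1]]$truth
    pred <- fit$preds[[1]]$pred
    n <- length(truth)
    lv <- sort(unique(truth))
    n1 <- sum(truth == lv[1])
    if (choose(n, n1) <= cfg$n_shuffles) {
      sets <- utils::combn(n, n1)
      null <- apply(sets, 2, function(pos) {
        lab <- rep(lv[2], n); lab[pos] <- lv[1]
        mean(pred == lab)
      })
      fit$null_accuracies <- null
      fit$p_value <- mean(null >= fit$mean_accuracy)
      fit$exact_null <- TRUE
    }
  }
  if (!fit$exact_null) {
    set.seed(.sub_seed(cfg$seed, 30))
    null <- numeric(cfg$n_shuffles)
    pooled <- matrix(0, cfg$n_shuffles, n_iter)
    nlab <- length(fit$labels)
    for (s in seq_len(cfg$n_shuffles)) {
      perm <- fit$labels[sample(nlab)]
      for (it in seq_len(n_iter))
        pooled[s, it] <- mean(fit$preds[[it]]$pred == perm[fit$preds[[it]]$test_rows])
      null[s] <- mean(pooled[s, ])
    }
    fit$null_accuracies <- null
    fit$null_pooled <- as.numeric(pooled)
    fit$p_value <- (1 + sum(null >= fit$mean_accuracy)) / (1 + cfg$n_shuffles)
  } else {
    fit$null_pooled <- fit$null_accuracies
  }
  fit$p_adjusted <- fit$p_value
  fit$significant <- (fit$mean_accuracy > .null_gate(fit)) &&
                     (fit$p_adjusted < cfg$alpha)
  fit
}

# The 95th percentile of the chance distribution of single-iteration shuffled
# test accuracies. Gating the observed across-iteration mean on this pooled
# (wide) distribution is deliberately strict: the mean-accuracy null alone is
# narrow enough that step-up correction across a sweep drags borderline
# chance offsets along with genuinely decodable ones.
.null_gate <- function(fit) {
  stats::quantile(fit$null_pooled, 0.95, names = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin, explicit surface over `stats::p.adjust(method = "BH")` returning
#' both the monotone adjusted p-values and the rejection mask at level `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return A list: `adjusted`, `reject` (logical, `adjusted <= q`).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) .stopf("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' Offset-swept decoding of speech intent
#'
#' Builds a balanced feature set and a full decode (fit, empirical null,
#' p-value) at every offset of the speech-intent window end relative to
#' voice onset — by default -1.5 to 0.7 s in 0.1 s steps against silence,
#' or -0.2/-0.1/0 s against the instructed-delay control. Contrast windows
#' are never offset. P-values are BH-corrected across offsets; the earliest
#' significant offset is reported. Offsets whose feature build fails (empty
#' class) are marked missing rather than fabricated.
#'
#' @param env Delay-corrected `si_envelope`.
#' @param events `si_events`.
#' @param cfg [decoder_config()].
#' @param contrast `"silence"` or `"delay"`.
#' @param offsets Optional numeric vector overriding the default grid.
#' @param n_windows,band,task_filter Passed to [build_feature_set()].
#' @return An `si_sweep`: per-offset results, a tidy `table`
#'   (offset_s, mean_accuracy, p, p_adj, significant), and
#'   `first_significant_offset` (NA when none).
#' @export
offset_sweep <- function(env, events, cfg, contrast = "silence", offsets = NULL,
                         n_windows = 4, band = "high_gamma", task_filter = NULL) {
  contrast <- match.arg(contrast, c("silence", "delay"))
  if (is.null(offsets))
    offsets <- if (contrast == "silence") seq(-1.5, 0.7, by = 0.1) else c(-0.2, -0.1, 0)
  offsets <- round(offsets, 6)
  results <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    cfg_k <- cfg
    cfg_k$seed <- .sub_seed(cfg$seed, 40, k)
    res <- tryCatch({
      fs <- build_feature_set(env, events, contrast = contrast, offset = offsets[k],
                              n_windows = n_windows, band = band,
                              task_filter = task_filter, seed = cfg_k$seed)
      empirical_null_and_p(fit_and_test(fs, cfg_k), cfg_k)
    }, error = function(e) structure(list(offset = offsets[k],
                                          message = conditionMessage(e)),
                                     class = "si_decode_missing"))
    results[[k]] <- res
  }
  ok <- !vapply(results, inherits, logical(1), "si_decode_missing")
  if (!any(ok)) .stopf("every offset failed: %s", results[[1]]$message)
  p <- vapply(results[ok], `[[`, numeric(1), "p_value")
  adj <- bh_fdr(p, cfg$alpha)$adjusted
  j <- 0
  for (k in which(ok)) {
    j <- j + 1
    results[[k]]$p_adjusted <- adj[j]
    results[[k]]$significant <-
      (results[[k]]$mean_accuracy > .null_gate(results[[k]])) &&
      (adj[j] < cfg$alpha)
  }
  tab <- data.frame(
    offset_s = offsets,
    mean_accuracy = vapply(results, function(r)
      if (inherits(r, "si_decode_missing")) NA_real_ else r$mean_accuracy, numeric(1)),
    p = vapply(results, function(r)
      if (inherits(r, "si_decode_missing")) NA_real_ else r$p_value, numeric(1)),
    p_adj = vapply(results, function(r)
      if (inherits(r, "si_decode_missing")) NA_real_ else r$p_adjusted, numeric(1)),
    significant = vapply(results, function(r)
      if (inherits(r, "si_decode_missing")) NA else r$significant, logical(1))
  )
  sig_off <- tab$offset_s[which(tab$significant)]
  structure(list(
    offsets = offsets, results = results, table = tab,
    first_significant_offset = if (length(sig_off)) min(sig_off) else NA_real_,
    contrast = contrast, n_windows = n_windows, band = band, cfg = cfg
  ), class = "si_sweep")
}

#' Group-level significance across datasets
#'
#' At each offset the s-th group-null sample is the mean, across datasets,
#' of their s-th shuffled accuracy; the observed group mean accuracy is
#' compared against this distribution (add-one permutation p, 95th-percentile
#' gate) and BH-corrected across offsets.
#'
#' @param sweeps List of two or more `si_sweep` objects on identical offset
#'   grids with sampled (non-exhaustive) nulls of equal size.
#' @param alpha Significance level.
#' @return Data frame: offset_s, group_mean_accuracy, p, p_adj, significant.
#' @export
group_significance <- function(sweeps, alpha = 0.05) {
  if (length(sweeps) < 2) .stopf("group significance needs at least 2 datasets")
  offs <- lapply(sweeps, `[[`, "offsets")
  if (!all(vapply(offs[-1], function(o) identical(o, offs[[1]]), logical(1))))
    .stopf("offset grids are misaligned across datasets")
  offsets <- offs[[1]]
  n_off <- length(offsets)
  p <- obs <- q95 <- numeric(n_off)
  for (k in seq_len(n_off)) {
    rs <- lapply(sweeps, function(s) s$results[[k]])
    if (any(vapply(rs, inherits, logical(1), "si_decode_missing")))
      .stopf("offset %.1f s missing in at least one dataset", offsets[k])
    nulls <- vapply(rs, `[[`, numeric(length(rs[[1]]$null_accuracies)), "null_accuracies")
    group_null <- rowMeans(nulls)
    obs[k] <- mean(vapply(rs, `[[`, numeric(1), "mean_accuracy"))
    p[k] <- (1 + sum(group_null >= obs[k])) / (1 + length(group_null))
    q95[k] <- stats::quantile(group_null, 0.95, names = FALSE)
  }
  adj <- bh_fdr(p, alpha)$adjusted
  data.frame(offset_s = offsets, group_mean_accuracy = obs, p = p, p_adj = adj,
             significant = obs > q95 & adj < alpha)
}

#' Per-electrode decoding map
#'
#' Fits a separate decoder for every good electrode using its own
#' `n_windows` feature windows at zero offset, with the same nested-CV and
#' empirical-null machinery, BH-corrected across electrodes.
#'
#' @param env Delay-corrected `si_envelope`.
#' @param events `si_events`.
#' @param cfg [decoder_config()].
#' @param contrast,n_windows Passed to [build_feature_set()].
#' @return Data frame keyed by channel name and anatomical label:
#'   mean_accuracy, p, p_adj, significant.
#' @export
single_electrode_map <- function(env, events, cfg, contrast = "silence", n_windows = 4) {
  fset <- build_feature_set(env, events, contrast = contrast, offset = 0,
                            n_windows = n_windows, seed = cfg$seed)
  nch <- length(fset$channel_names)
  out <- vector("list", nch)
  for (e in seq_len(nch)) {
    cols <- (e - 1L) * n_windows + seq_len(n_windows)
    cfg_e <- cfg
    cfg_e$seed <- .sub_seed(cfg$seed, 50, e)
    fit <- empirical_null_and_p(
      fit_and_test(fset$x[, cols, drop = FALSE], cfg_e, y = fset$y), cfg_e)
    out[[e]] <- c(acc = fit$mean_accuracy, p = fit$p_value, q95 = .null_gate(fit))
  }
  m <- do.call(rbind, out)
  adj <- bh_fdr(m[, "p"], cfg$alpha)$adjusted
  good <- env$channels$good
  data.frame(
    channel = fset$channel_names,
    label = env$channels$label[good],
    mean_accuracy = m[, "acc"], p = m[, "p"], p_adj = adj,
    significant = m[, "acc"] > m[, "q95"] & adj < cfg$alpha,
    stringsAsFactors = FALSE
  )
}

#' Compare decoding accuracy between two contrasts
#'
#' Two-sided Wilcoxon rank-sum test on accuracy samples (per participant or
#' per iteration) from e.g. the speech-vs-silence and speech-vs-delay
#' analyses. Identical constant samples yield p = 1 with a warning.
#'
#' @param acc_a,acc_b Numeric accuracy vectors.
#' @return The two-sided rank-sum p-value.
#' @export
compare_contrasts <- function(acc_a, acc_b) {
  if (!length(acc_a) || !length(acc_b)) .stopf("both accuracy samples must be non-empty")
  if (length(unique(c(acc_a, acc_b))) == 1) {
    warning("identical constant samples; rank-sum test is uninformative (p = 1)")
    return(1)
  }
  suppressWarnings(stats::wilcox.test(acc_a, acc_b, exact = NULL)$p.value)
}
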