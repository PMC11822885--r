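#' Prepare condition-mean input for dPCA
#'
#' Builds the two-condition (speech intent vs silence) trial-averaged,
#' Savitzky-Golay-smoothed high-gamma input: the speech condition is the
#' 500 ms before voice onset, silence is 1-1.5 s after voice offset, both on
#' the same per-channel time base.
#'
#' @param env Delay-corrected `si_envelope`.
#' @param events `si_events`.
#' @param speech_window Seconds pair relative to voice onset.
#' @param silence_window Seconds pair relative to voice offset.
#' @param sg_order,sg_length Savitzky-Golay polynomial order and kernel
#'   length in seconds (converted to the nearest odd sample count).
#' @return An `si_dpca_input`: `condition_means` (2 x channels x time array,
#'   conditions speech/silence), `time`, `sampling_rate`.
#' @export
dpca_prepare <- function(env, events, speech_window = c(-0.5, 0),
                         silence_window = c(1.0, 1.5),
                         sg_order = 4, sg_length = 0.201) {
  sp <- epoch(env, events, align = "voice_onset", window = speech_window)
  si <- epoch(env, events, align = "voice_offset", window = silence_window)
  if (dim(sp$data)[3] != dim(si$data)[3])
    .stopf("condition windows must have equal length")
  fs <- env$sampling_rate
  nsg <- round(sg_length * fs)
  if (nsg %% 2 == 0) nsg <- nsg + 1
  if (dim(sp$data)[3] < nsg) .stopf("epoch shorter than the smoothing kernel")
  avg <- function(ep) {
    m <- apply(ep$data, c(2, 3), mean)
    t(apply(m, 1, function(v) signal::sgolayfilt(v, p = sg_order, n = nsg)))
  }
  cm <- array(0, c(2, dim(sp$data)[2], dim(sp$data)[3]))
  cm[1, , ] <- avg(sp)
  cm[2, , ] <- avg(si)
  structure(list(condition_means = cm, time = sp$time, sampling_rate = fs,
                 conditions = c("speech_intent", "silence"),
                 sg = list(order = sg_order, n = nsg)),
            class = "si_dpca_input")
}

#' Demixed PCA of speech intent vs silence
#'
#' Two-factor demixed principal component analysis: channel-mean-centred
#' condition means are split into a condition-independent (time)
#' marginalization — the across-condition mean time course — and a
#' condition-dependent marginalization (the residual). For each
#' marginalization, a ridge-regularised reduced-rank regression of the
#' marginalized data on the full data yields paired decoder/encoder axes;
#' components are ordered by the fraction of total variance they capture.
#' The fit is deterministic (no random initialisation).
#'
#' @param input An `si_dpca_input` (or a plain 2 x channels x time array).
#' @param regularization Ridge penalty as a fraction of total variance
#'   (default 1e-2). Near-unregularised fits invert an ill-conditioned
#'   channel covariance and load the decoders heavily onto unmodulated
#'   channels; 1e-2 keeps decoders aligned with their encoders at a
#'   reconstruction cost well under 1%. Must be positive when the channel
#'   covariance is singular.
#' @param n_components Components to keep per marginalization (default 3;
#'   `NULL` keeps the full rank).
#' @return An `si_dpca`: per-component `marginalization`
#'   (`"condition"`/`"time"`), `explained_variance` fractions,
#'   `total_explained` (the reconstruction R-squared of the retained
#'   components, which the non-orthogonal per-component fractions need not
#'   sum to), `decoders` (components x channels), `encoders`
#'   (channels x components), `trajectories` (condition x time x component),
#'   `time`.
#' @export
dpca_fit <- function(input, regularization = 1e-2, n_components = 3) {
  cm <- if (inherits(input, "si_dpca_input")) input$condition_means else input
  if (length(dim(cm)) != 3 || dim(cm)[1] != 2)
    .stopf("dPCA input must be a 2 x channels x time array")
  nch <- dim(cm)[2]; nt <- dim(cm)[3]
  if (nch < 2) .stopf("dPCA needs at least 2 channels")
  X1 <- cm[1, , , drop = TRUE]; X2 <- cm[2, , , drop = TRUE]
  if (nch == 1) { X1 <- matrix(X1, 1); X2 <- matrix(X2, 1) }
  X <- cbind(X1, X2)
  X <- X - rowMeans(X)
  M <- (X[, 1:nt, drop = FALSE] + X[, nt + 1:nt, drop = FALSE]) / 2
  Xt <- cbind(M, M)         # condition-independent (time) marginalization
  Xc <- X - Xt              # condition-dependent marginalization
  totvar <- sum(X^2)
  if (totvar == 0) .stopf("input has zero variance")
  XXt <- X %*% t(X)
  lam <- regularization * totvar
  G <- tryCatch(solve(XXt + diag(lam, nch)),
                error = function(e) .stopf(
                  "channel covariance is singular; use a nonzero regularization"))
  if (is.null(n_components)) n_components <- nch
  comp <- list()
  for (marg in c("condition", "time")) {
    Xm <- if (marg == "condition") Xc else Xt
    A <- Xm %*% t(X) %*% G
    P <- A %*% X
    sv <- svd(P)
    q <- min(n_components, sum(sv$d > max(sv$d[1], 1) * 1e-12), nch)
    for (i in seq_len(q)) {
      d <- as.numeric(sv$u[, i] %*% A)      # decoder (row vector over channels)
      comp[[length(comp) + 1]] <- list(
        marginalization = marg,
        decoder = d, encoder = sv$u[, i],
        ev = sv$d[i]^2 / totvar,
        scores = as.numeric(d %*% X)
      )
    }
  }
  ev <- vapply(comp, `[[`, numeric(1), "ev")
  ord <- order(ev, decreasing = TRUE)
  comp <- comp[ord]; ev <- ev[ord]
  # components across marginalizations are not orthogonal, so per-component
  # fractions need not sum to the reconstruction R^2; report both
  xhat <- Reduce(`+`, lapply(comp, function(cc) outer(cc$encoder, cc$scores)))
  total_explained <- 1 - sum((X - xhat)^2) / totvar
  traj <- array(0, c(2, nt, length(comp)))
  for (i in seq_along(comp)) {
    traj[1, , i] <- comp[[i]]$scores[1:nt]
    traj[2, , i] <- comp[[i]]$scores[nt + 1:nt]
  }
  structure(list(
    marginalization = vapply(comp, `[[`, character(1), "marginalization"),
    explained_variance = ev,
    total_explained = total_explained,
    decoders = do.call(rbind, lapply(comp, `[[`, "decoder")),
    encoders = do.call(cbind, lapply(comp, `[[`, "encoder")),
    trajectories = traj,
    time = if (inherits(input, "si_dpca_input")) input$time else seq_len(nt),
    conditions = if (inherits(input, "si_dpca_input")) input$conditions
                 else c("condition1", "condition2"),
    total_variance = totvar, regularization = regularization,
    sg = if (inherits(input, "si_dpca_input")) input$sg else NULL
  ), class = "si_dpca")
}

#' Project single trials onto fitted dPCA axes
#'
#' @param fit An `si_dpca`.
#' @param epochs An `si_epochs` (trials x channels x time) on the same
#'   channel set.
#' @param smooth Apply the fit's Savitzky-Golay smoothing to each single
#'   trial before projecting (default `TRUE` when the fit carries smoothing
#'   parameters), so projections live on the same signal scale as the fit.
#' @return Array trials x time x components of dPC scores.
#' @export
dpca_project <- function(fit, epochs, smooth = !is.null(fit$sg)) {
  stopifnot(inherits(fit, "si_dpca"), inherits(epochs, "si_epochs"))
  d <- dim(epochs$data)
  out <- array(0, c(d[1], d[3], nrow(fit$decoders)))
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, , , drop = TRUE]
    if (d[2] == 1) x <- matrix(x, 1)
    if (smooth && d[3] >= fit$sg$n)
      x <- t(apply(x, 1, function(v) signal::sgolayfilt(v, p = fit$sg$order, n = fit$sg$n)))
    out[tr, , ] <- t(fit$decoders %*% x)
  }
  out
}
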