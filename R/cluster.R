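#' Cluster voice-onset-locked envelope dynamics across electrodes
#'
#' Each electrode's trial-averaged high-gamma envelope in a window around
#' voice onset (default -1 to +0.5 s) is Gaussian-smoothed (default SD
#' 25 ms), z-scored over the window, and clustered with k-means (Euclidean,
#' multiple restarts) for every k in `k_range`. The cluster count is chosen
#' at the elbow of the distortion curve — the k with the largest positive
#' second difference of mean within-cluster distance. Clusters are then
#' labelled production / perception / unmodulated from their centroid onset
#' relative to voice onset (see [label_clusters()]).
#'
#' @param epochs `si_epochs` aligned to voice onset.
#' @param k_range Candidate cluster counts (default 2:10; k exceeding the
#'   electrode count is skipped).
#' @param gaussian_sd Smoothing kernel SD in seconds (0.025).
#' @param n_restarts k-means restarts per k.
#' @param seed Integer seed (k-means initialisation).
#' @return An `si_clusters`: per-electrode `assignments`, `centroids`
#'   (k x time), `chosen_k`, `distortion_curve` (data frame k, distortion),
#'   `cluster_labels`, `onsets`, `time`.
#' @export
cluster_envelopes <- function(epochs, k_range = 2:10, gaussian_sd = 0.025,
                              n_restarts = 20, seed = 1) {
  stopifnot(inherits(epochs, "si_epochs"))
  if (!isTRUE(epochs$z_scored))
    warning("clustering is intended for z-scored epochs; pass epoch(..., z_score = TRUE)")
  fs <- epochs$sampling_rate
  # z-scoring happens per electrode at the single-trial envelope level (in
  # epoch()); averaging across trials then leaves unmodulated electrodes near
  # zero instead of renormalising their noise to unit variance
  avg <- apply(epochs$data, c(2, 3), mean)
  if (is.null(dim(avg))) avg <- matrix(avg, 1)
  z <- t(apply(avg, 1, .gauss_smooth, sd_samp = gaussian_sd * fs))
  nch <- nrow(z)
  n_distinct <- nrow(unique(z))
  if (n_distinct < 2) {
    # all electrodes share one time course: report the duplicate-centroid
    # degenerate solution rather than forcing k-means onto one point
    res <- structure(list(
      assignments = rep(1L, nch),
      centroids = rbind(z[1, ], z[1, ]),
      raw_centroids = rbind(avg[1, ], avg[1, ]),
      chosen_k = 2L,
      distortion_curve = data.frame(k = k_range, distortion = 0),
      time = epochs$time, channels = epochs$channels, z_courses = z
    ), class = "si_clusters")
    attr(res, "degenerate") <- TRUE
    return(label_clusters(res))
  }
  # k-means needs strictly fewer centres than (distinct) points
  k_range <- k_range[k_range >= 2 & k_range <= min(nch - 1L, n_distinct)]
  if (!length(k_range)) .stopf("need at least 2 electrodes to cluster")
  fits <- vector("list", length(k_range))
  distortion <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    set.seed(.sub_seed(seed, 60, k_range[i]))
    km <- stats::kmeans(z, centers = k_range[i], nstart = n_restarts, iter.max = 100)
    d <- sqrt(rowSums((z - km$centers[km$cluster, , drop = FALSE])^2))
    fits[[i]] <- km
    distortion[i] <- mean(d)
  }
  chosen_i <- .elbow(distortion)
  km <- fits[[chosen_i]]
  res <- structure(list(
    assignments = km$cluster,
    centroids = km$centers,
    raw_centroids = t(sapply(seq_len(k_range[chosen_i]), function(cl)
      colMeans(avg[km$cluster == cl, , drop = FALSE]))),
    chosen_k = k_range[chosen_i],
    distortion_curve = data.frame(k = k_range, distortion = distortion),
    time = epochs$time,
    channels = epochs$channels,
    z_courses = z
  ), class = "si_clusters")
  label_clusters(res)
}

# Largest positive second difference of the distortion curve; falls back to
# the first k when the curve is too short or has no concave corner.
.elbow <- function(d) {
  if (length(d) < 3) return(1L)
  d2 <- d[1:(length(d) - 2)] - 2 * d[2:(length(d) - 1)] + d[3:length(d)]
  if (max(d2) <= 0) return(1L)
  which.max(d2) + 1L
}

# Gaussian smoothing with edge renormalisation.
.gauss_smooth <- function(v, sd_samp) {
  if (sd_samp <= 0) return(v)
  hw <- max(1L, ceiling(4 * sd_samp))
  k <- stats::dnorm(-hw:hw, sd = sd_samp)
  n <- length(v)
  num <- stats::convolve(v, rev(k), type = "open")[(hw + 1):(hw + n)]
  den <- stats::convolve(rep(1, n), rev(k), type = "open")[(hw + 1):(hw + n)]
  num / den
}

#' Label clusters as production, perception or unmodulated
#'
#' Each centroid's onset is the first time it rises above its pre-window
#' baseline (the first `baseline` seconds of the epoch) mean + 2 SD and
#' stays there for at least `sustain` seconds (the sustain requirement keeps
#' brief noise excursions from registering as onsets). Onsets are measured
#' on the unsmoothed trial-averaged centroids when available
#' (`raw_centroids`): the Gaussian kernel used for the clustering distances
#' would otherwise smear a rising edge backward by roughly twice its width,
#' which matters exactly at the production/perception boundary. Clusters whose onset
#' precedes voice onset (t = 0) are labelled `production`, those at or after
#' it `perception`, and centroids that never cross the threshold
#' `unmodulated`.
#'
#' @param result An `si_clusters`.
#' @param baseline Baseline span in seconds at the start of the window.
#' @param sustain Minimum above-threshold duration in seconds.
#' @return The `si_clusters` with `cluster_labels` and `onsets` filled.
#' @export
label_clusters <- function(result, baseline = 0.25, sustain = 0.05) {
  stopifnot(inherits(result, "si_clusters"))
  tt <- result$time
  base_idx <- tt < (tt[1] + baseline)
  dt <- stats::median(diff(tt))
  min_run <- max(1L, as.integer(round(sustain / dt)))
  cen_mat <- if (!is.null(result$raw_centroids)) result$raw_centroids else result$centroids
  k <- nrow(cen_mat)
  onsets <- rep(NA_real_, k)
  labels <- character(k)
  for (i in seq_len(k)) {
    cen <- cen_mat[i, ]
    thr <- mean(cen[base_idx]) + 2 * stats::sd(cen[base_idx])
    above <- !base_idx & cen > thr
    r <- rle(above)
    run_end <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= min_run)
    if (!length(hit)) {
      labels[i] <- "unmodulated"
    } else {
      onsets[i] <- tt[run_end[hit[1]] - r$lengths[hit[1]] + 1L]
      labels[i] <- if (onsets[i] < 0) "production" else "perception"
    }
  }
  result$cluster_labels <- labels
  result$onsets <- onsets
  result
}
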