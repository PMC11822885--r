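# Print, summary and plot methods for the pipeline's result objects.

#' @export
print.si_simconfig <- function(x, ...) {
  cat(sprintf("<si_simconfig> %d ch @ %g Hz, %d trials, task %s, SNR %g, seed %d\n",
              x$n_channels, x$sampling_rate, x$n_trials, x$task,
              x$modulation_snr, x$seed))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$channel_roles)),
                                table(x$channel_roles)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.si_envelope <- function(x, ...) {
  cat(sprintf("<si_envelope> band %g-%g Hz, %d ch x %d samples @ %g Hz, %s (tau = %g s)\n",
              x$band[1], x$band[2], nrow(x$power), ncol(x$power), x$sampling_rate,
              if (x$delay_corrected) "delay-corrected" else "uncorrected",
              x$group_delay))
  invisible(x)
}

#' @export
print.si_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<si_epochs> %d trials x %d ch x %d samples, aligned to %s [%g, %g] s%s\n",
              d[1], d[2], d[3], x$alignment_event, x$window[1], x$window[2],
              if (x$z_scored) ", z-scored" else ""))
  invisible(x)
}

#' @export
print.si_features <- function(x, ...) {
  cat(sprintf("<si_features> %d x %d (%s vs %s, offset %+.1f s, %d x 100 ms, band %s)\n",
              nrow(x$x), ncol(x$x), levels(x$y)[1], levels(x$y)[2],
              x$offset, x$n_windows, x$band))
  invisible(x)
}

#' @export
print.si_decode <- function(x, ...) {
  cat(sprintf("<si_decode> offset %s: accuracy %.3f (%d iterations)",
              if (is.na(x$offset)) "n/a" else sprintf("%+.1f s", x$offset),
              x$mean_accuracy, length(x$iteration_accuracies)))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4g%s%s", x$p_value,
                if (x$exact_null) " (exact)" else "",
                if (isTRUE(x$significant)) " *" else ""))
  cat("\n")
  invisible(x)
}

#' @export
print.si_sweep <- function(x, ...) {
  cat(sprintf("<si_sweep> %s contrast, %d offsets [%g, %g] s, %d x 100 ms windows\n",
              x$contrast, length(x$offsets), min(x$offsets), max(x$offsets),
              x$n_windows))
  cat(sprintf("  first significant offset: %s\n",
              if (is.na(x$first_significant_offset)) "none"
              else sprintf("%+.1f s", x$first_significant_offset)))
  invisible(x)
}

#' @export
summary.si_sweep <- function(object, ...) {
  cat(sprintf("Offset sweep (%s contrast), BH-corrected at alpha = %g\n",
              object$contrast, object$cfg$alpha))
  print(transform(object$table,
                  mean_accuracy = round(mean_accuracy, 3),
                  p = signif(p, 3), p_adj = signif(p_adj, 3)),
        row.names = FALSE)
  invisible(object$table)
}

#' @export
plot.si_sweep <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$offset_s, tab$mean_accuracy, type = "b", pch = 16,
                 xlab = "offset of feature-window end re voice onset (s)",
                 ylab = "decoding accuracy", ylim = c(0.3, 1), ...)
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = 0, lty = 2)
  sig <- which(tab$significant)
  if (length(sig))
    graphics::points(tab$offset_s[sig], tab$mean_accuracy[sig], pch = 8, col = 2)
  invisible(x)
}

#' @export
print.si_dpca <- function(x, ...) {
  cat(sprintf("<si_dpca> %d components, reconstruction R2 %.1f%%\n",
              length(x$explained_variance), 100 * x$total_explained))
  df <- data.frame(component = seq_along(x$explained_variance),
                   marginalization = x$marginalization,
                   explained_variance_pct = round(100 * x$explained_variance, 2))
  print(utils::head(df, 6), row.names = FALSE)
  invisible(x)
}

#' @export
plot.si_dpca <- function(x, components = 1:2, ...) {
  components <- components[components <= dim(x$trajectories)[3]]
  old <- graphics::par(mfrow = c(1, length(components)))
  on.exit(graphics::par(old))
  for (ci in components) {
    rng <- range(x$trajectories[, , ci])
    graphics::plot(x$time, x$trajectories[1, , ci], type = "l", col = 2, ylim = rng,
                   xlab = "time (s)", ylab = sprintf("dPC%d (%s)", ci,
                                                     x$marginalization[ci]), ...)
    graphics::lines(x$time, x$trajectories[2, , ci], col = 4)
  }
  invisible(x)
}

#' @export
print.si_clusters <- function(x, ...) {
  cat(sprintf("<si_clusters> %d electrodes -> k = %d clusters\n",
              length(x$assignments), x$chosen_k))
  for (i in seq_len(nrow(x$centroids)))
    cat(sprintf("  cluster %d: %d electrodes, %s%s\n", i, sum(x$assignments == i),
                x$cluster_labels[i],
                if (is.na(x$onsets[i])) "" else sprintf(" (onset %+.3f s)", x$onsets[i])))
  invisible(x)
}

#' @export
plot.si_clusters <- function(x, ...) {
  rng <- range(x$centroids)
  graphics::plot(NULL, xlim = range(x$time), ylim = rng, xlab = "time re voice onset (s)",
                 ylab = "z-scored HG envelope", ...)
  for (i in seq_len(nrow(x$centroids)))
    graphics::lines(x$time, x$centroids[i, ], col = i, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topleft", bty = "n", lwd = 2, col = seq_len(nrow(x$centroids)),
                   legend = sprintf("%d: %s", seq_len(nrow(x$centroids)), x$cluster_labels))
  invisible(x)
}

#' Export cluster assignments and a sweep table
#'
#' @param x An `si_clusters` or `si_sweep`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "si_clusters")) {
    df <- data.frame(channel = x$channels$name, label = x$channels$label,
                     cluster = x$assignments,
                     cluster_label = x$cluster_labels[x$assignments],
                     stringsAsFactors = FALSE)
  } else if (inherits(x, "si_sweep")) {
    df <- x$table
  } else .stopf("no CSV export for class %s", class(x)[1])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
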