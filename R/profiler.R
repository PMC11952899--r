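# Per-residue propensity profiling: score sliding windows of one protein
# with a trained model, aggregate to per-residue tracks, and call peaks.

#' Sliding-window propensity profile of a single protein
#'
#' Cuts the sequence into overlapping windows (default 50 residues, step
#' 5), featurizes each window exactly as a full-length protein (so the
#' length feature equals the window length), scores it with the model, and
#' aggregates window scores into a per-residue track. A terminal leftover
#' window is included when it is at least half the window length; proteins
#' shorter than half a window are scored as one whole-sequence window with
#' a warning. Windowed GRAVY and cysteine-fraction tracks are carried
#' alongside, since low hydropathy and low cysteine content are the
#' hallmark of propensity peaks.
#'
#' @param model A `granule_model` fitted with a persisted vocabulary.
#' @param record Single named sequence (named character vector of length 1)
#'   or a plain string.
#' @param window Window length in residues (>= 10).
#' @param step Step between window starts.
#' @param aggregate Per-residue aggregation over covering windows:
#'   `"mean"` (default) or `"max"`.
#' @return Object of class `window_profile`: window table (`start`, `end`,
#'   `p`, `gravy`, `cys_fraction`) plus per-residue `residue_p`,
#'   `residue_gravy`, `residue_cys` tracks of length L.
#' @export
sliding_window_propensity <- function(model, record, window = 50L, step = 5L,
                                      aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (window < 10L) stop("`window` must be >= 10")
  if (is.null(model$vocabulary)) stop("model carries no k-mer vocabulary")
  accession <- if (!is.null(names(record))) names(record)[1L] else "protein"
  sequence <- unname(record[1L])
  check_sequence(sequence)
  L <- nchar(sequence)
  if (L < window / 2) {
    warning("sequence shorter than half a window; scoring one whole-sequence window")
    starts <- 1L; ends <- L
  } else {
    starts <- seq(1L, max(1L, L - window + 1L), by = step)
    ends <- pmin(starts + window - 1L, L)
    last_end <- max(ends)
    if (last_end < L) {
      tail_start <- starts[length(starts)] + step
      if (L - tail_start + 1L >= window / 2) {
        starts <- c(starts, tail_start)
        ends <- c(ends, L)
      }
    }
  }
  subseqs <- substring(sequence, starts, ends)
  names(subseqs) <- sprintf("w%04d", seq_along(subseqs))
  feats <- build_feature_table(subseqs, model$vocabulary)
  p <- stats::predict(model$forest,
                      feats[, model$feature_names, drop = FALSE],
                      type = "prob")[, "1"]
  gravy <- vapply(subseqs, compute_gravy, numeric(1L))
  cys <- vapply(subseqs, function(s) aa_composition(s)[["aa_C"]], numeric(1L))

  agg_track <- function(values) {
    if (aggregate == "mean") {
      acc <- numeric(L); cnt <- numeric(L)
      for (i in seq_along(starts)) {
        span <- starts[i]:ends[i]
        acc[span] <- acc[span] + values[i]
        cnt[span] <- cnt[span] + 1
      }
      ifelse(cnt > 0, acc / cnt, NA_real_)
    } else {
      acc <- rep(-Inf, L)
      for (i in seq_along(starts)) {
        span <- starts[i]:ends[i]
        acc[span] <- pmax(acc[span], values[i])
      }
      acc
    }
  }
  structure(list(accession = accession, length = L,
                 window = window, step = step, aggregate = aggregate,
                 windows = data.frame(start = starts, end = ends,
                                      p = as.numeric(p), gravy = gravy,
                                      cys_fraction = cys, row.names = NULL),
                 residue_p = agg_track(as.numeric(p)),
                 residue_gravy = agg_track(gravy),
                 residue_cys = agg_track(cys)),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat("Propensity profile of ", x$accession, " (L = ", x$length, ")\n",
      "  ", nrow(x$windows), " windows of ", x$window,
      " residues, step ", x$step, "\n",
      sprintf("  per-residue p: min %.3f, max %.3f\n",
              min(x$residue_p), max(x$residue_p)), sep = "")
  invisible(x)
}

#' @export
plot.window_profile <- function(x, min_p = 0.7, ...) {
  graphics::plot(seq_len(x$length), x$residue_p, type = "l", ylim = c(0, 1),
                 xlab = "residue", ylab = "granule propensity", ...)
  graphics::abline(h = min_p, lty = 2)
  invisible(x)
}

#' Call propensity peaks on a profile
#'
#' Maximal runs of the per-residue propensity track at or above `min_p`
#' with length at least `min_len`. Each peak is annotated with its maximal
#' propensity and the mean windowed GRAVY and cysteine fraction over its
#' span.
#'
#' @param profile A `window_profile`.
#' @param min_p Minimum per-residue propensity.
#' @param min_len Minimum peak length in residues.
#' @return Data frame (`start`, `end`, `max_p`, `mean_gravy`, `mean_cys`),
#'   peaks disjoint and sorted by start; zero rows when no peak qualifies.
#' @export
call_peaks <- function(profile, min_p = 0.7, min_len = 10L) {
  stopifnot(inherits(profile, "window_profile"))
  above <- profile$residue_p >= min_p
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(out) == 0L)
    return(cbind(out, data.frame(max_p = numeric(0), mean_gravy = numeric(0),
                                 mean_cys = numeric(0))))
  out$max_p <- vapply(seq_len(nrow(out)), function(i)
    max(profile$residue_p[out$start[i]:out$end[i]]), numeric(1L))
  out$mean_gravy <- vapply(seq_len(nrow(out)), function(i)
    mean(profile$residue_gravy[out$start[i]:out$end[i]]), numeric(1L))
  out$mean_cys <- vapply(seq_len(nrow(out)), function(i)
    mean(profile$residue_cys[out$start[i]:out$end[i]]), numeric(1L))
  out[order(out$start), ]
}
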