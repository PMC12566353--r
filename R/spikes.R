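#' Band-pass filter for action-potential extraction
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass, 200-3000 Hz
#' by default — the standard spike band.
#'
#' @param x voltage series
#' @param fs sampling rate (Hz); must exceed twice the upper corner
#' @param lo,hi corner frequencies (Hz)
#' @return filtered series
#' @export
bandpass <- function(x, fs, lo = 200, hi = 3000) {
  stopifnot(lo > 0, hi > lo)
  if (fs <= 2 * hi) stop("sampling rate must exceed twice the upper corner")
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Median-based adaptive detection threshold
#'
#' Robust noise estimate sigma_N = median(|x|)/0.6745 (the MAD consistency
#' constant for Gaussian noise; the median makes the estimate insensitive to
#' the spikes themselves) and threshold Thr = 4 sigma_N.
#'
#' @param x filtered voltage series
#' @return list with `sigma_n` and `thr = 4 * sigma_n`
#' @export
adaptive_threshold <- function(x) {
  if (length(x) == 0) stop("empty signal")
  sigma_n <- median(abs(x)) / 0.6745
  list(sigma_n = sigma_n, thr = 4 * sigma_n)
}

#' Detect spike events by threshold crossing
#'
#' Events are local extrema of the filtered signal beyond the threshold,
#' merged within a refractory window so each spike yields a single event.
#' Extracellular spikes are negative-going at the electrode, so the default
#' polarity detects local minima below `-thr`; `"both"` detects extrema of
#' `|x|`.
#'
#' @param x filtered voltage series
#' @param fs sampling rate (Hz)
#' @param thr detection threshold (V), > 0
#' @param refractory_ms merge window (ms); crossings closer than this are one
#'   event (default 1 ms)
#' @param polarity `"negative"` (default) or `"both"`
#' @return integer vector of event sample indices (ascending)
#' @export
detect_spikes <- function(x, fs, thr, refractory_ms = 1,
                          polarity = c("negative", "both")) {
  polarity <- match.arg(polarity)
  stopifnot(thr > 0, fs > 0)
  score <- if (polarity == "negative") -x else abs(x)
  over <- which(score > thr)
  if (length(over) == 0) return(integer(0))
  gap <- as.integer(round(refractory_ms / 1000 * fs))
  ## group contiguous/near crossings, keep the peak of each group
  brk <- c(0L, which(diff(over) > gap), length(over))
  events <- integer(length(brk) - 1L)
  for (i in seq_len(length(brk) - 1L)) {
    idx <- over[(brk[i] + 1L):brk[i + 1L]]
    events[i] <- idx[which.max(score[idx])]
  }
  ## enforce the merge window between group peaks as well
  if (length(events) > 1) {
    keep <- logical(length(events))
    last <- -Inf
    for (i in seq_along(events)) {
      if (events[i] - last > gap) {
        keep[i] <- TRUE
        last <- events[i]
      } else if (score[events[i]] > score[events[max(which(keep))]]) {
        keep[max(which(keep))] <- FALSE
        keep[i] <- TRUE
        last <- events[i]
      }
    }
    events <- events[keep]
  }
  sort(events)
}

#' Extract and peak-align spike waveforms
#'
#' Cuts a window of `window_ms` around each event, shifted so the absolute
#' peak sits exactly at the window midpoint (peak synchronization). Events
#' whose aligned window would run off the record are discarded and counted.
#'
#' @param x filtered voltage series
#' @param fs sampling rate (Hz)
#' @param events sorted event sample indices
#' @param window_ms extraction window (ms), default 5
#' @param search_ms half-width of the peak search around each event (ms)
#' @return object of class `waveform_matrix`: list with `waveforms`
#'   (n_spikes x N matrix), `peak_index` (midpoint), `events` (aligned peak
#'   indices of the kept spikes), `kept_input` (indices into the input event
#'   vector of the retained rows), `n_discarded`, `fs`, `window_ms`
#' @export
extract_align <- function(x, fs, events, window_ms = 5, search_ms = 0.5) {
  stopifnot(fs > 0, window_ms > 0)
  if (is.unsorted(events)) stop("events must be sorted")
  nwin <- as.integer(round(window_ms / 1000 * fs))
  if (nwin %% 2L == 1L) nwin <- nwin + 1L
  half <- nwin %/% 2L
  peak_index <- half + 1L  # midpoint of a window of nwin + 1 samples
  nsearch <- as.integer(round(search_ms / 1000 * fs))
  n <- length(x)
  rows <- list()
  kept <- integer(0)
  kept_input <- integer(0)
  discarded <- 0L
  for (k in seq_along(events)) {
    ev <- events[k]
    lo <- max(ev - nsearch, 1L)
    hi <- min(ev + nsearch, n)
    peak <- (lo:hi)[which.max(abs(x[lo:hi]))]
    if (peak - half < 1L || peak + half > n) {
      discarded <- discarded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- x[(peak - half):(peak + half)]
    kept <- c(kept, peak)
    kept_input <- c(kept_input, k)
  }
  wf <- if (length(rows)) do.call(rbind, rows) else {
    matrix(numeric(0), 0, nwin + 1L)
  }
  structure(list(waveforms = wf, peak_index = peak_index, events = kept,
                 kept_input = kept_input, n_discarded = discarded, fs = fs,
                 window_ms = window_ms),
            class = "waveform_matrix")
}

#' Principal-component feature scores for spike waveforms
#'
#' Principal components are the eigenvectors of the mean-centered waveform
#' covariance, ordered by decreasing explained variance; each spike's score
#' on component i is the inner product c_i = sum_n PC_i(n) s(n) of the raw
#' waveform with the component.
#'
#' @param wm a [extract_align()] result (or any list with a `waveforms`
#'   matrix)
#' @param k number of components to keep (default 2)
#' @return object of class `feature_scores`: list with `scores`
#'   (n_spikes x k), `components` (N x k), `explained_var` (length k)
#' @export
pca_features <- function(wm, k = 2) {
  wf <- if (is.matrix(wm)) wm else wm$waveforms
  if (nrow(wf) <= k) stop("need more spikes than components")
  pc <- prcomp(wf, center = TRUE, scale. = FALSE)
  comp <- pc$rotation[, seq_len(k), drop = FALSE]
  structure(list(scores = wf %*% comp, components = comp,
                 explained_var = pc$sdev[seq_len(k)]^2),
            class = "feature_scores")
}

#' Sort spikes by k-means on feature scores with waveform reassignment
#'
#' Lloyd k-means on the PCA scores (seeded random initialization, run to
#' centroid convergence), followed by one reassignment pass in waveform
#' space: each spike moves to the cluster whose mean waveform gives the
#' smaller RMS error. Spikes whose waveform RMS error exceeds
#' `outlier_factor` times their cluster's median RMS error are marked
#' unclustered (label 0) and subtracted from the sorted spike count.
#'
#' @param scores a [pca_features()] result or a numeric score matrix
#' @param k number of clusters
#' @param seed integer seed for centroid initialization
#' @param waveforms optional n_spikes x N waveform matrix enabling the RMS
#'   reassignment and outlier pass
#' @param outlier_factor multiple of the cluster median RMS error beyond
#'   which a spike is unclustered (default 3)
#' @return list with `labels` (0 = unclustered), `centroids` (k x k_scores),
#'   `n_unclustered`, `cluster_means` (k x N waveform means or NULL)
#' @export
kmeans_sort <- function(scores, k, seed = 0, waveforms = NULL,
                        outlier_factor = 3) {
  sc <- if (is.matrix(scores)) scores else scores$scores
  stopifnot(k >= 1)
  if (k > nrow(sc)) stop("more clusters than spikes")
  rng <- local_rng(seed)
  ## seeded Lloyd iterations: random distinct rows as initial centroids
  init <- sc[rng$sample(nrow(sc), k), , drop = FALSE]
  km <- suppressWarnings(kmeans(sc, centers = init, iter.max = 300,
                                algorithm = "Lloyd"))
  labels <- km$cluster
  cluster_means <- NULL
  n_unclustered <- 0L
  if (!is.null(waveforms) && k >= 1) {
    stopifnot(nrow(waveforms) == nrow(sc))
    for (pass in 1:2) {  # pass 1: reassign; pass 2: recompute means
      cluster_means <- t(vapply(seq_len(k), function(j) {
        rows <- waveforms[labels == j, , drop = FALSE]
        if (nrow(rows) == 0) rep(NA_real_, ncol(waveforms)) else colMeans(rows)
      }, numeric(ncol(waveforms))))
      if (pass == 2) break
      rmse_to <- vapply(seq_len(k), function(j) {
        if (anyNA(cluster_means[j, ])) return(rep(Inf, nrow(waveforms)))
        sqrt(rowMeans((waveforms - matrix(cluster_means[j, ],
                                          nrow(waveforms), ncol(waveforms),
                                          byrow = TRUE))^2))
      }, numeric(nrow(waveforms)))
      rmse_to <- matrix(rmse_to, nrow = nrow(waveforms))
      labels <- apply(rmse_to, 1, which.min)
    }
    ## outlier pass
    own_rmse <- vapply(seq_len(nrow(waveforms)), function(i) {
      sqrt(mean((waveforms[i, ] - cluster_means[labels[i], ])^2))
    }, numeric(1))
    for (j in seq_len(k)) {
      in_j <- which(labels == j)
      if (length(in_j) < 3) next
      med <- median(own_rmse[in_j])
      out <- in_j[own_rmse[in_j] > outlier_factor * med]
      labels[out] <- 0L
      n_unclustered <- n_unclustered + length(out)
    }
  }
  list(labels = labels, centroids = km$centers,
       n_unclustered = n_unclustered, cluster_means = cluster_means)
}

#' Score detected events against ground truth
#'
#' One-to-one matching of detected to true event times within `tol_ms`,
#' maximizing the number of matches (and among those, minimizing the total
#' time offset) by dynamic programming over the two sorted sequences.
#' Matched pairs are true positives; unmatched detections are false
#' positives; unmatched truth are false negatives. Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), Accuracy = TP/(TP+FP+FN).
#'
#' @param detected,truth sorted event sample indices
#' @param fs sampling rate (Hz)
#' @param tol_ms matching tolerance (ms), default 1
#' @return object of class `detection_report`: list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `accuracy`
#' @export
match_events <- function(detected, truth, fs, tol_ms = 1) {
  stopifnot(fs > 0, tol_ms >= 0)
  if (is.unsorted(detected) || is.unsorted(truth)) {
    stop("event lists must be sorted")
  }
  tol <- tol_ms / 1000 * fs
  nd <- length(detected)
  nt <- length(truth)
  if (nd == 0 || nt == 0) {
    tp <- 0L
  } else {
    ## Matches can only interact through chains of events closer than tol, so
    ## split the union of both sequences into components separated by gaps
    ## > tol and solve each component exactly by DP. Components are tiny for
    ## realistic (sparse) event trains.
    all_ev <- c(detected, truth)
    src <- rep(c(1L, 2L), c(nd, nt))
    ord <- order(all_ev)
    all_ev <- all_ev[ord]
    src <- src[ord]
    comp <- cumsum(c(1L, as.integer(diff(all_ev) > tol)))
    tp <- 0L
    for (cid in unique(comp)) {
      sel <- comp == cid
      dd <- all_ev[sel & src == 1L]
      tt <- all_ev[sel & src == 2L]
      tp <- tp + match_dp(dd, tt, tol)
    }
  }
  fp <- nd - tp
  fn <- nt - tp
  denom_p <- tp + fp
  denom_r <- tp + fn
  structure(list(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    precision = if (denom_p > 0) tp / denom_p else NA_real_,
    recall = if (denom_r > 0) tp / denom_r else NA_real_,
    accuracy = if (tp + fp + fn > 0) tp / (tp + fp + fn) else NA_real_),
    class = "detection_report")
}

## Exact max-cardinality (min total offset among ties) matching of two short
## sorted sequences, states indexed over (i, j) prefixes.
match_dp <- function(dd, tt, tol) {
  nd <- length(dd)
  nt <- length(tt)
  if (nd == 0 || nt == 0) return(0L)
  count <- matrix(0L, nd + 1L, nt + 1L)
  cost <- matrix(0, nd + 1L, nt + 1L)
  for (i in seq_len(nd)) {
    for (j in seq_len(nt)) {
      best_c <- count[i, j + 1L]
      best_w <- cost[i, j + 1L]
      if (count[i + 1L, j] > best_c ||
          (count[i + 1L, j] == best_c && cost[i + 1L, j] < best_w)) {
        best_c <- count[i + 1L, j]
        best_w <- cost[i + 1L, j]
      }
      d <- abs(dd[i] - tt[j])
      if (d <= tol) {
        c2 <- count[i, j] + 1L
        w2 <- cost[i, j] + d
        if (c2 > best_c || (c2 == best_c && w2 < best_w)) {
          best_c <- c2
          best_w <- w2
        }
      }
      count[i + 1L, j + 1L] <- best_c
      cost[i + 1L, j + 1L] <- best_w
    }
  }
  count[nd + 1L, nt + 1L]
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("TP %d, FP %d, FN %d | precision %.3f, recall %.3f, accuracy %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$accuracy))
  invisible(x)
}

#' Signed spike-count error relative to a baseline
#'
#' 100 * (n_level - n_baseline) / n_baseline, the percentage deviation of the
#' detected spike count at a distortion level from the level-0 baseline.
#'
#' @param n_level detected count at the distortion level
#' @param n_baseline detected count at level 0 (> 0)
#' @return signed percentage
#' @export
spike_count_error <- function(n_level, n_baseline) {
  if (n_baseline <= 0) stop("baseline count must be positive")
  100 * (n_level - n_baseline) / n_baseline
}
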