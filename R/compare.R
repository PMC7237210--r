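# Comparison with ground truth: tolerance-window matching and per-unit
# accuracy / precision / recall.

#' Comparison parameters
#'
#' @param delta_ms Timing tolerance in milliseconds; a sorted event matches a
#'   true event when their times differ by at most this tolerance. Default
#'   1 ms, to which results are rather insensitive.
#' @param sample_rate Sampling rate in Hz, used to convert the tolerance to
#'   integer samples: `delta_samples = round(delta_ms * sample_rate / 1000)`,
#'   floored at 1.
#' @return A list of class `comparison_params`.
#' @export
comparison_params <- function(delta_ms = 1.0, sample_rate = 30000) {
  stopifnot(delta_ms > 0, sample_rate > 0)
  delta_samples <- max(1L, as.integer(round(delta_ms * sample_rate / 1000)))
  structure(list(delta_ms = delta_ms, sample_rate = sample_rate,
                 delta_samples = delta_samples),
            class = "comparison_params")
}

#' Count tolerance-window matches between two spike trains
#'
#' Counts ground-truth events that have at least one sorted event within
#' `delta_samples`. Each ground-truth event contributes at most once, even if
#' several sorted events fall inside its window; under the refractory
#' assumption (true inter-spike gaps exceeding twice the tolerance) the
#' reverse multiplicity cannot occur.
#'
#' @param gt_times,sorted_times Nondecreasing event times in samples.
#' @param delta_samples Integer tolerance (>= 1) in samples.
#' @return Integer match count.
#' @export
count_matches <- function(gt_times, sorted_times, delta_samples) {
  stopifnot(delta_samples >= 1)
  if (is.unsorted(gt_times) || is.unsorted(sorted_times)) {
    stop("event times must be nondecreasing", call. = FALSE)
  }
  if (!length(gt_times) || !length(sorted_times)) return(0L)
  # For each t, the nearest sorted time at or below t + delta; match iff it
  # is also >= t - delta.
  idx <- findInterval(gt_times + delta_samples, sorted_times)
  sum(idx >= 1L & sorted_times[pmax(idx, 1L)] >= gt_times - delta_samples)
}

#' Match counts for every (ground-truth unit, sorted unit) pair
#'
#' @param gt,sorted [firings()] objects for ground truth and the sorter output.
#' @param params A [comparison_params()].
#' @return Data frame with one row per pair: `gt_label`, `sorted_label`,
#'   `n_match`, `n_miss`, `n_fp`, `N_l` (total true events of the unit) and
#'   `M_k` (total sorted events of the unit).
#' @export
match_counts_all <- function(gt, sorted, params) {
  stopifnot(inherits(gt, "firings"), inherits(sorted, "firings"),
            inherits(params, "comparison_params"))
  gl <- firings_labels(gt)
  if (!length(gl)) stop("ground truth has no events", call. = FALSE)
  sl <- firings_labels(sorted)
  delta <- params$delta_samples

  gt_trains <- lapply(gl, function(l) unit_times(gt, l))
  s_trains <- lapply(sl, function(k) unit_times(sorted, k))
  .warn_refractory(gt_trains, gl, delta)

  grid <- expand.grid(gi = seq_along(gl), si = seq_along(sl))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    gi <- grid$gi[r]; si <- grid$si[r]
    tg <- gt_trains[[gi]]; ts <- s_trains[[si]]
    nm <- count_matches(tg, ts, delta)
    data.frame(gt_label = gl[gi], sorted_label = sl[si], n_match = nm,
               n_miss = length(tg) - nm, n_fp = length(ts) - nm,
               N_l = length(tg), M_k = length(ts))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gt_label = numeric(), sorted_label = numeric(),
                      n_match = integer(), n_miss = integer(),
                      n_fp = integer(), N_l = integer(), M_k = integer())
  }
  out
}

.warn_refractory <- function(gt_trains, labels, delta) {
  bad <- vapply(gt_trains, function(t) {
    length(t) >= 2 && any(diff(t) < 2 * delta)
  }, logical(1))
  if (any(bad)) {
    warning("ground-truth unit(s) ", paste(labels[bad], collapse = ", "),
            " have inter-spike gaps < 2*delta; the matching assumes true ",
            "gaps exceed twice the tolerance", call. = FALSE)
  }
}

#' Accuracy of one (ground-truth, sorted) pair
#'
#' `a = n_match / (n_match + n_miss + n_fp)`: a balance of precision and
#' recall that penalizes both missed events and false positives.
#'
#' @param n_match,n_miss,n_fp Match counts (vectors recycle).
#' @return Accuracy in `[0, 1]`; `NA` where all three counts are zero.
#' @export
pair_accuracy <- function(n_match, n_miss, n_fp) {
  den <- n_match + n_miss + n_fp
  ifelse(den > 0, n_match / den, NA_real_)
}

#' Best-matching sorted unit for one ground-truth unit
#'
#' The sorted unit with the highest pair accuracy; ties broken by the
#' smallest sorted label. When the best accuracy is zero there is no match.
#'
#' @param accuracies Pair accuracies across sorted units.
#' @param sorted_labels Corresponding sorted unit labels.
#' @return List with `label` (or `NA` when nothing matches) and `accuracy`.
#' @export
best_match <- function(accuracies, sorted_labels) {
  stopifnot(length(accuracies) == length(sorted_labels),
            length(accuracies) >= 1)
  accuracies[is.na(accuracies)] <- 0
  ord <- order(-accuracies, sorted_labels)
  best <- ord[1L]
  if (accuracies[best] <= 0) {
    list(label = NA_real_, accuracy = 0)
  } else {
    list(label = sorted_labels[best], accuracy = accuracies[best])
  }
}

#' Compare a sorting against ground truth
#'
#' For each ground-truth unit, finds its best-matching sorted unit by pair
#' accuracy and reports accuracy, precision (penalizing only false positives)
#' and recall (penalizing only false negatives) restricted to that pair.
#' Multiple ground-truth units may share one best-matching sorted unit; this
#' is reported, not forbidden.
#'
#' @param gt,sorted [firings()] objects.
#' @param params A [comparison_params()].
#' @return An object of class `gt_comparison`: a list with `units` (one row
#'   per ground-truth unit: `gt_label`, `best_sorted_label`, `accuracy`,
#'   `precision`, `recall` and the pair's counts), `pairs` (the full
#'   [match_counts_all()] table with pair accuracies), `params`, and
#'   `shared_best` (sorted labels chosen by more than one ground-truth unit).
#' @export
compare_sorting <- function(gt, sorted, params) {
  pairs <- match_counts_all(gt, sorted, params)
  pairs$accuracy <- pair_accuracy(pairs$n_match, pairs$n_miss, pairs$n_fp)

  gl <- firings_labels(gt)
  units <- lapply(gl, function(l) {
    sub <- pairs[pairs$gt_label == l, , drop = FALSE]
    if (!nrow(sub)) {
      return(data.frame(gt_label = l, best_sorted_label = NA_real_,
                        accuracy = 0, precision = 0, recall = 0,
                        n_match = 0L, n_miss = sum(gt["label", ] == l),
                        n_fp = 0L, N_l = sum(gt["label", ] == l), M_k = 0L))
    }
    bm <- best_match(sub$accuracy, sub$sorted_label)
    if (is.na(bm$label)) {
      data.frame(gt_label = l, best_sorted_label = NA_real_, accuracy = 0,
                 precision = 0, recall = 0, n_match = 0L,
                 n_miss = sub$N_l[1L], n_fp = 0L, N_l = sub$N_l[1L],
                 M_k = 0L)
    } else {
      row <- sub[sub$sorted_label == bm$label, , drop = FALSE]
      data.frame(gt_label = l, best_sorted_label = bm$label,
                 accuracy = row$accuracy,
                 precision = row$n_match / (row$n_match + row$n_fp),
                 recall = row$n_match / (row$n_match + row$n_miss),
                 n_match = row$n_match, n_miss = row$n_miss,
                 n_fp = row$n_fp, N_l = row$N_l, M_k = row$M_k)
    }
  })
  units <- do.call(rbind, units)
  rownames(units) <- NULL

  bl <- units$best_sorted_label[!is.na(units$best_sorted_label)]
  shared <- unique(bl[duplicated(bl)])
  structure(list(units = units, pairs = pairs, params = params,
                 shared_best = shared),
            class = "gt_comparison")
}

#' @export
print.gt_comparison <- function(x, ...) {
  cat(sprintf("<gt_comparison> %d ground-truth units, delta = %g ms\n",
              nrow(x$units), x$params$delta_ms))
  print(x$units[, c("gt_label", "best_sorted_label", "accuracy",
                    "precision", "recall")], row.names = FALSE, digits = 4)
  if (length(x$shared_best)) {
    cat("note: sorted unit(s)", paste(x$shared_best, collapse = ", "),
        "are the best match of more than one ground-truth unit\n")
  }
  invisible(x)
}

#' @export
summary.gt_comparison <- function(object, ...) {
  u <- object$units
  out <- c(n_units = nrow(u),
           mean_accuracy = mean(u$accuracy),
           mean_precision = mean(u$precision),
           mean_recall = mean(u$recall))
  class(out) <- "summary.gt_comparison"
  out
}

#' @export
print.summary.gt_comparison <- function(x, ...) {
  cat(sprintf(
    "units: %d  mean accuracy: %.4f  precision: %.4f  recall: %.4f\n",
    x["n_units"], x["mean_accuracy"], x["mean_precision"], x["mean_recall"]))
  invisible(x)
}

#' @export
as.data.frame.gt_comparison <- function(x, ...) x$units

#' Categorize individual events as matched, missed or false positive
#'
#' Pairs events greedily one-to-one (each ground-truth event with the nearest
#' unused sorted event within the tolerance, in time order), so the matched
#' counts agree on both sides. Under the refractory assumption this equals
#' the existence count of [count_matches()].
#'
#' @param gt_times,sorted_times Nondecreasing event times in samples.
#' @param delta_samples Integer tolerance in samples.
#' @return List with `gt` (`"matched"`/`"missed"` per ground-truth event),
#'   `sorted` (`"matched"`/`"false_positive"` per sorted event) and
#'   `n_match`.
#' @export
categorize_events <- function(gt_times, sorted_times, delta_samples) {
  stopifnot(delta_samples >= 1)
  if (is.unsorted(gt_times) || is.unsorted(sorted_times)) {
    stop("event times must be nondecreasing", call. = FALSE)
  }
  n <- length(gt_times); m <- length(sorted_times)
  gt_cat <- rep("missed", n)
  s_cat <- rep("false_positive", m)
  used <- logical(m)
  for (i in seq_len(n)) {
    lo <- findInterval(gt_times[i] - delta_samples - 0.5, sorted_times) + 1L
    hi <- findInterval(gt_times[i] + delta_samples + 0.5, sorted_times)
    if (lo > hi) next
    cand <- lo:hi
    cand <- cand[!used[cand] &
                   abs(sorted_times[cand] - gt_times[i]) <= delta_samples]
    if (!length(cand)) next
    j <- cand[which.min(abs(sorted_times[cand] - gt_times[i]))]
    used[j] <- TRUE
    gt_cat[i] <- "matched"
    s_cat[j] <- "matched"
  }
  list(gt = gt_cat, sorted = s_cat, n_match = sum(used))
}
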