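# Sorter x study result tables: SNR-thresholded unweighted averages, counts
# of units above an accuracy cut-off, and linear-regression imputation of
# failed sorting runs.

#' Aggregation parameters
#'
#' @param snr_threshold Only ground-truth units with SNR at or above this
#'   enter the average metric (default 8). Counts of units above the accuracy
#'   threshold ignore it.
#' @param accuracy_threshold Cut-off for [count_above()] (default 0.8).
#' @param metric Which per-unit metric to average: `"accuracy"` (balances
#'   false positives and negatives), `"precision"` or `"recall"`.
#' @param impute Impute missing (failed/timed-out) sorting runs by linear
#'   regression before averaging (default `TRUE`). Counts are never imputed.
#' @return A list of class `aggregation_params`.
#' @export
aggregation_params <- function(snr_threshold = 8, accuracy_threshold = 0.8,
                               metric = c("accuracy", "precision", "recall"),
                               impute = TRUE) {
  stopifnot(snr_threshold >= 0, accuracy_threshold >= 0)
  structure(list(snr_threshold = snr_threshold,
                 accuracy_threshold = accuracy_threshold,
                 metric = match.arg(metric), impute = isTRUE(impute)),
            class = "aggregation_params")
}

#' Build a study result table
#'
#' Collects per-ground-truth-unit results of several sorters on several
#' recordings, plus the study structure and the mask of failed (missing)
#' sorter-recording runs.
#'
#' @param units Data frame with one row per (sorter, recording, ground-truth
#'   unit): columns `sorter`, `recording`, `gt_label`, `accuracy`,
#'   `precision`, `recall`, `snr`, `num_events`. Rows for missing runs must
#'   be absent.
#' @param studies Data frame mapping `recording` to `study` and `study_set`.
#' @param missing Data frame of failed runs with columns `sorter`,
#'   `recording` (default: none).
#' @return An object of class `study_results`.
#' @export
study_results <- function(units, studies,
                          missing = data.frame(sorter = character(),
                                               recording = character())) {
  need <- c("sorter", "recording", "gt_label", "accuracy", "precision",
            "recall", "snr", "num_events")
  stopifnot(all(need %in% names(units)),
            all(c("recording", "study", "study_set") %in% names(studies)),
            all(c("sorter", "recording") %in% names(missing)))
  if (nrow(units)) {
    m <- units[, c("accuracy", "precision", "recall")]
    stopifnot(all(m >= 0 & m <= 1), all(units$snr >= 0))
  }
  key <- function(s, r) paste(s, r, sep = "\r")
  if (any(key(units$sorter, units$recording) %in%
          key(missing$sorter, missing$recording))) {
    stop("missing runs must not carry unit results", call. = FALSE)
  }
  structure(list(units = units, studies = studies, missing = missing),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf(
    "<study_results> %d sorters, %d recordings in %d studies, %d missing runs\n",
    length(unique(x$units$sorter)), nrow(x$studies),
    length(unique(x$studies$study)), nrow(x$missing)))
  invisible(x)
}

# Per-recording mean of the chosen metric over qualifying units, one row per
# (sorter, recording); missing runs get NA.
.per_recording_means <- function(tab, params) {
  u <- tab$units
  u <- u[u$snr >= params$snr_threshold, , drop = FALSE]
  sorters <- sort(unique(c(tab$units$sorter, tab$missing$sorter)))
  recs <- tab$studies$recording
  m <- matrix(NA_real_, length(sorters), length(recs),
              dimnames = list(sorters, recs))
  nunits <- matrix(0L, length(sorters), length(recs),
                   dimnames = list(sorters, recs))
  for (s in sorters) {
    for (r in recs) {
      if (any(tab$missing$sorter == s & tab$missing$recording == r)) next
      sub <- u[u$sorter == s & u$recording == r, , drop = FALSE]
      if (nrow(sub)) {
        m[s, r] <- mean(sub[[params$metric]])
        nunits[s, r] <- nrow(sub)
      } else {
        m[s, r] <- NA_real_  # no qualifying units: flagged empty
      }
    }
  }
  miss <- matrix(FALSE, length(sorters), length(recs),
                 dimnames = list(sorters, recs))
  for (i in seq_len(nrow(tab$missing))) {
    miss[tab$missing$sorter[i], tab$missing$recording[i]] <- TRUE
  }
  list(means = m, missing = miss, nunits = nunits)
}

# Count of qualifying ground-truth units per recording (sorter-independent):
# taken as the max over sorters that ran, since ground truth is shared.
.gt_unit_counts <- function(nunits, missing) {
  counts <- integer(ncol(nunits))
  names(counts) <- colnames(nunits)
  for (r in colnames(nunits)) {
    ran <- !missing[, r]
    counts[r] <- if (any(ran)) max(nunits[ran, r]) else 0L
  }
  counts
}

#' Impute missing per-recording values by linear regression
#'
#' For each sorter with missing entries, fits ordinary least squares (with
#' intercept) of its observed entries on the entries of all sorters that have
#' no missing data, at the same recordings; the fitted model predicts the
#' missing entries, clipped to `[0, 1]`. Observed entries are never changed.
#' When no complete sorter exists, or the fit is under-determined, the
#' fallback is the mean of the sorter's observed values (logged as a message).
#'
#' @param values Sorter x recording numeric matrix (e.g. per-recording mean
#'   accuracies) with `NA` at missing runs, or explicit `missing_mask`.
#' @param missing_mask Logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return The filled matrix, with attribute `imputed` (logical matrix of
#'   cells that were filled).
#' @export
impute_missing <- function(values, missing_mask = is.na(values)) {
  stopifnot(is.matrix(values), identical(dim(values), dim(missing_mask)))
  filled <- values
  imputed <- missing_mask & FALSE
  complete <- rownames(values)[rowSums(missing_mask) == 0L]
  targets <- rownames(values)[rowSums(missing_mask) > 0L]
  for (s in targets) {
    obs <- !missing_mask[s, ]
    if (!any(obs)) next  # nothing observed: cell stays missing
    pred <- NULL
    if (length(complete)) {
      x_obs <- t(values[complete, obs, drop = FALSE])
      x_mis <- t(values[complete, !obs, drop = FALSE])
      y <- values[s, obs]
      if (sum(obs) >= length(complete) + 1L &&
          !anyNA(x_obs) && !anyNA(x_mis) && !anyNA(y)) {
        fit <- stats::lm.fit(cbind(1, x_obs), y)
        if (!anyNA(fit$coefficients)) {
          pred <- drop(cbind(1, x_mis) %*% fit$coefficients)
        }
      }
    }
    if (is.null(pred)) {
      message("imputation fallback for sorter '", s,
              "': mean of its observed values")
      pred <- rep(mean(values[s, obs], na.rm = TRUE), sum(!obs))
    }
    filled[s, !obs] <- pmin(1, pmax(0, pred))
    imputed[s, !obs] <- TRUE
  }
  attr(filled, "imputed") <- imputed
  filled
}

#' Average metric per sorter and study
#'
#' Per study: the unweighted mean of the chosen per-unit metric over
#' ground-truth units with SNR at or above the threshold (treating all units
#' equally, never weighting by event counts). Missing recordings are first
#' imputed at the per-recording-mean level when `params$impute`; an imputed
#' recording contributes its imputed mean weighted by that recording's count
#' of qualifying ground-truth units, which keeps the unit-level average exact
#' on complete data. Per study set: the unweighted mean of its study means.
#'
#' @param tab A [study_results()] table.
#' @param params An [aggregation_params()].
#' @return List of two data frames: `study` (`sorter`, `study`, `value`,
#'   `imputed` flag) and `study_set` (`sorter`, `study_set`, `value`).
#' @export
average_metric <- function(tab, params = aggregation_params()) {
  pr <- .per_recording_means(tab, params)
  means <- pr$means
  if (params$impute && any(pr$missing)) {
    means[pr$missing] <- NA_real_
    means <- impute_missing(means, pr$missing)
  }
  gt_counts <- .gt_unit_counts(pr$nunits, pr$missing)

  studies <- tab$studies
  sorters <- rownames(means)
  study_rows <- list()
  for (s in sorters) {
    for (st in unique(studies$study)) {
      recs <- studies$recording[studies$study == st]
      w <- ifelse(pr$missing[s, recs], gt_counts[recs], pr$nunits[s, recs])
      v <- means[s, recs]
      use <- if (params$impute) !is.na(v) else !pr$missing[s, recs] & !is.na(v)
      value <- if (any(use) && sum(w[use]) > 0) {
        sum(v[use] * w[use]) / sum(w[use])
      } else NA_real_
      study_rows[[length(study_rows) + 1L]] <- data.frame(
        sorter = s, study = st, value = value,
        imputed = any(pr$missing[s, recs]))
    }
  }
  study_df <- do.call(rbind, study_rows)

  set_map <- unique(studies[, c("study", "study_set")])
  set_rows <- list()
  for (s in sorters) {
    for (ss in unique(set_map$study_set)) {
      sts <- set_map$study[set_map$study_set == ss]
      v <- study_df$value[study_df$sorter == s & study_df$study %in% sts]
      set_rows[[length(set_rows) + 1L]] <- data.frame(
        sorter = s, study_set = ss, value = mean(v, na.rm = TRUE))
    }
  }
  list(study = study_df, study_set = do.call(rbind, set_rows))
}

#' Count units above an accuracy threshold
#'
#' Per sorter and study: the number of ground-truth units sorted with
#' accuracy at or above the threshold, regardless of SNR. Missing runs are
#' never imputed; they simply contribute no units, and the result row is
#' flagged with `incomplete = TRUE` (rendered as an asterisk in reports).
#'
#' @param tab A [study_results()] table.
#' @param params An [aggregation_params()].
#' @return Data frame with `sorter`, `study`, `count`, `incomplete`.
#' @export
count_above <- function(tab, params = aggregation_params()) {
  studies <- tab$studies
  sorters <- sort(unique(c(tab$units$sorter, tab$missing$sorter)))
  rows <- list()
  for (s in sorters) {
    for (st in unique(studies$study)) {
      recs <- studies$recording[studies$study == st]
      sub <- tab$units[tab$units$sorter == s &
                         tab$units$recording %in% recs, , drop = FALSE]
      n <- sum(sub$accuracy >= params$accuracy_threshold)
      inc <- any(tab$missing$sorter == s & tab$missing$recording %in% recs)
      rows[[length(rows) + 1L]] <- data.frame(
        sorter = s, study = st, count = n, incomplete = inc)
    }
  }
  do.call(rbind, rows)
}

#' Fit a linear predictor of accuracy from quality metrics
#'
#' Ordinary least squares of per-unit accuracy on SNR, firing rate and the
#' natural log of the ISI-violation ratio (zero ratios floored at half the
#' smallest positive observed value), with intercept. Useful for judging how
#' well quality metrics predict ground-truth accuracy when no ground truth is
#' available.
#'
#' @param units Data frame with columns `snr`, `firing_rate`,
#'   `isi_violation_ratio`, `accuracy`; at least 5 rows.
#' @return Object of class `accuracy_predictor`: list with `coefficients`,
#'   `fitted` (predictions for the training units), `correlation` (Pearson,
#'   predicted vs actual), `dropped` (collinear predictors removed, if any)
#'   and the underlying `lm` fit.
#' @export
fit_accuracy_predictor <- function(units) {
  need <- c("snr", "firing_rate", "isi_violation_ratio", "accuracy")
  stopifnot(all(need %in% names(units)), nrow(units) >= 5)
  ivr <- units$isi_violation_ratio
  pos <- ivr[ivr > 0]
  if (!length(pos)) stop("all ISI-violation ratios are zero", call. = FALSE)
  floor_val <- min(pos) * 0.5
  d <- data.frame(accuracy = units$accuracy, snr = units$snr,
                  firing_rate = units$firing_rate,
                  log_isi_vr = log(pmax(ivr, floor_val)))
  fit <- stats::lm(accuracy ~ snr + firing_rate + log_isi_vr, data = d)
  co <- stats::coef(fit)
  dropped <- names(co)[is.na(co)]
  if (length(dropped)) {
    warning("dropping collinear predictor(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    keep <- setdiff(c("snr", "firing_rate", "log_isi_vr"), dropped)
    fit <- stats::lm(stats::reformulate(keep, "accuracy"), data = d)
  }
  fitted <- unname(stats::fitted(fit))
  corr <- if (stats::sd(fitted) > 0 && stats::sd(d$accuracy) > 0) {
    stats::cor(fitted, d$accuracy)
  } else NA_real_
  structure(list(coefficients = stats::coef(fit), fitted = fitted,
                 correlation = corr, dropped = dropped,
                 isi_floor = floor_val, fit = fit),
            class = "accuracy_predictor")
}

#' @export
print.accuracy_predictor <- function(x, ...) {
  cat("<accuracy_predictor> OLS of accuracy on snr + firing_rate + log ISI-vr\n")
  print(round(x$coefficients, 5))
  cat(sprintf("correlation(predicted, actual) = %.4f\n", x$correlation))
  invisible(x)
}

#' @export
coef.accuracy_predictor <- function(object, ...) object$coefficients

#' @export
predict.accuracy_predictor <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nd <- data.frame(snr = newdata$snr, firing_rate = newdata$firing_rate,
                   log_isi_vr = log(pmax(newdata$isi_violation_ratio,
                                         object$isi_floor)))
  unname(stats::predict(object$fit, nd))
}
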