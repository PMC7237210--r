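# Synthetic ground-truth recordings and controlled pseudo-sortings.
#
# The generator emulates the phenomenological simulation style used for
# benchmark study sets: smooth biphasic templates placed on an electrode
# array, Poisson firing thinned to respect a refractory gap, per-event
# Gamma-distributed amplitude scaling (mean 1), iid Gaussian noise, and
# optional slow electrode drift realized by Gaussian-kernel interpolation of
# the spatial amplitude profile on a dense virtual grid.

# Run expr with a private RNG stream seeded by `seed`; the caller's RNG
# state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulation specification
#'
#' Parameters of the synthetic ground-truth recording generator. Defaults
#' describe a desk-scale tetrode-like recording: 4 channels at 20 um pitch,
#' 30 kHz, 60 s, Gaussian noise of 10 uV, per-unit firing around 5 Hz and
#' target SNR 8, with ~22% per-event amplitude jitter (Gamma shape 20).
#'
#' @param num_channels,num_units Counts (>= 1).
#' @param duration_s Recording duration in seconds.
#' @param sample_rate Hz.
#' @param firing_rates Per-unit mean firing rates in Hz (recycled).
#' @param target_snrs Per-unit target SNR: the template's peak absolute
#'   amplitude is `target_snr * noise_sd` (recycled).
#' @param noise_sd Gaussian noise standard deviation in uV.
#' @param amplitude_gamma_shape Shape `k` of the per-event amplitude scale
#'   `Gamma(k, scale = 1/k)` (mean 1, CV `1/sqrt(k)`).
#' @param spatial_decay_um Exponential decay constant of template amplitude
#'   with distance from the source, in um.
#' @param width1_ms,width2_ms Temporal widths (ms) of the two Gaussian lobes
#'   of the biphasic template kernel.
#' @param drift One of `"none"`, `"linear"`, `"sinusoidal"`.
#' @param drift_displacement_um Drift amplitude: total displacement for
#'   linear drift, plus/minus amplitude for sinusoidal (default 10).
#' @param drift_period_s Period of sinusoidal drift in seconds (default 600).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(num_channels = 4, num_units = 2,
                            duration_s = 60, sample_rate = 30000,
                            firing_rates = 5, target_snrs = 8,
                            noise_sd = 10, amplitude_gamma_shape = 20,
                            spatial_decay_um = 25,
                            width1_ms = 0.3, width2_ms = 0.6,
                            drift = c("none", "linear", "sinusoidal"),
                            drift_displacement_um = 10,
                            drift_period_s = 600, seed = 1L) {
  stopifnot(num_channels >= 1, num_units >= 1, duration_s > 0,
            sample_rate > 0, all(firing_rates > 0), all(target_snrs > 0),
            noise_sd >= 0, amplitude_gamma_shape > 0)
  structure(list(
    num_channels = as.integer(num_channels),
    num_units = as.integer(num_units),
    duration_s = duration_s, sample_rate = sample_rate,
    firing_rates = rep_len(firing_rates, num_units),
    target_snrs = rep_len(target_snrs, num_units),
    noise_sd = noise_sd, amplitude_gamma_shape = amplitude_gamma_shape,
    spatial_decay_um = spatial_decay_um,
    width1_ms = width1_ms, width2_ms = width2_ms,
    drift = match.arg(drift),
    drift_displacement_um = drift_displacement_um,
    drift_period_s = drift_period_s, seed = as.integer(seed)),
    class = "simulation_spec")
}

# Biphasic temporal kernel (difference of Gaussians), peak |amplitude| 1.
.template_kernel <- function(spec) {
  n1 <- round(0.001 * spec$sample_rate)  # 1 ms pre
  n2 <- round(0.002 * spec$sample_rate)  # 2 ms post
  t_ms <- (seq_len(n1 + n2) - n1 - 1) / spec$sample_rate * 1000
  k <- -exp(-0.5 * (t_ms / spec$width1_ms)^2) +
    0.6 * exp(-0.5 * ((t_ms - 0.6) / spec$width2_ms)^2)
  k / max(abs(k))
}

# Channel amplitude profile for a source at vertical offset dy (um):
# exponential decay with electrode distance, evaluated by Gaussian-kernel
# interpolation over a dense 0.5 um virtual grid of vertical positions.
.spatial_profile <- function(geom, src_xy, dy, decay_um, grid_um = 0.5) {
  src <- c(src_xy[1L], src_xy[2L] + dy)
  span <- range(geom[, 2L])
  grid <- seq(span[1L] - 4 * decay_um, span[2L] + 4 * decay_um, by = grid_um)
  dense <- exp(-sqrt((src[1L] - 0)^2 + (src[2L] - grid)^2) / decay_um)
  # Gaussian kernel (sd = 2 grid steps) interpolation from the virtual grid
  # to the actual electrode positions; x-offset handled by the dense profile
  # being computed at the electrodes' x = 0 column.
  sd_k <- 2 * grid_um
  vapply(seq_len(nrow(geom)), function(c) {
    w <- exp(-0.5 * ((geom[c, 2L] - grid) / sd_k)^2)
    sum(w * dense) / sum(w) *
      exp(-abs(geom[c, 1L] - src[1L]) / decay_um) /
      exp(-abs(0 - src[1L]) / decay_um)
  }, numeric(1))
}

#' Generate unit templates
#'
#' Each template is a smooth biphasic temporal kernel on a randomly placed
#' source, with per-channel amplitude decaying exponentially with electrode
#' distance, normalized so the peak absolute amplitude equals
#' `target_snr * noise_sd` (or `target_snr` when `noise_sd` is 0).
#'
#' @param spec A [simulation_spec()].
#' @return List with `templates` (units x channels x samples array),
#'   `sources` (unit source xy positions, um), `geometry`, `w_pre`
#'   (samples before the event time within the template).
#' @export
make_templates <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  geom <- cbind(0, (seq_len(spec$num_channels) - 1L) * 20)
  kern <- .template_kernel(spec)
  w_pre <- round(0.001 * spec$sample_rate)
  with_seed(spec$seed, {
    sources <- cbind(
      x = stats::runif(spec$num_units, 5, 15),
      y = stats::runif(spec$num_units, min(geom[, 2L]), max(geom[, 2L])))
    tmpl <- array(0, c(spec$num_units, spec$num_channels, length(kern)))
    for (u in seq_len(spec$num_units)) {
      prof <- .spatial_profile(geom, sources[u, ], 0, spec$spatial_decay_um)
      peak_target <- spec$target_snrs[u] *
        if (spec$noise_sd > 0) spec$noise_sd else 1
      m <- outer(prof, kern)
      tmpl[u, , ] <- m / max(abs(m)) * peak_target
    }
    list(templates = tmpl, sources = sources, geometry = geom,
         w_pre = w_pre)
  })
}

# Poisson event times (samples), thinned so consecutive kept events are at
# least min_gap samples apart.
.poisson_train <- function(rate, duration_s, sample_rate, min_gap) {
  n_exp <- stats::rpois(1L, rate * duration_s)
  if (n_exp == 0L) return(numeric(0))
  t <- sort(stats::runif(n_exp, 0, duration_s)) * sample_rate + 1
  keep <- numeric(0)
  last <- -Inf
  for (ti in t) {
    if (ti - last >= min_gap) {
      keep <- c(keep, ti)
      last <- ti
    }
  }
  if (length(keep) < 0.5 * n_exp) {
    stop("firing rate too high: refractory thinning removed > 50% of events",
         call. = FALSE)
  }
  keep
}

#' Simulate a ground-truth recording
#'
#' Per unit: Poisson event times thinned to enforce within-unit gaps of at
#' least twice the 1 ms matching tolerance; each event adds the unit's
#' template scaled by a Gamma(shape, scale = 1/shape) factor (mean 1); iid
#' Gaussian noise is added to every sample. With drift enabled, the unit's
#' spatial amplitude profile is re-derived per event from its displaced
#' source position via Gaussian-kernel interpolation on a 0.5 um grid.
#' Inserted amplitudes are calibrated so that [compute_snr()] (whose bandpass
#' attenuates the iid noise) recovers each unit's `target_snr`.
#' Identical specs (including seed) give bit-identical output.
#'
#' @param spec A [simulation_spec()].
#' @return List with `recording` (a [recording()]) and `firings` (the ground
#'   truth as a [firings()] object; primary channel is the template's peak
#'   channel).
#' @export
simulate_recording <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tm <- make_templates(spec)
  n_samp <- round(spec$duration_s * spec$sample_rate)
  min_gap <- 2 * round(0.001 * spec$sample_rate)  # 2 x default tolerance
  kern_len <- dim(tm$templates)[3L]
  # calibrate so compute_snr() on the result recovers target_snrs
  snr_cal <- if (spec$noise_sd > 0) {
    .noise_attenuation(spec$sample_rate) /
      .kernel_filter_gain(.template_kernel(spec), spec$sample_rate)
  } else 1

  with_seed(spec$seed + 1L, {
    trains <- lapply(seq_len(spec$num_units), function(u) {
      .poisson_train(spec$firing_rates[u], spec$duration_s,
                     spec$sample_rate, min_gap)
    })
    traces <- matrix(0, spec$num_channels, n_samp)
    ch <- integer(0); smp <- numeric(0); lab <- numeric(0)
    for (u in seq_len(spec$num_units)) {
      t_u <- trains[[u]]
      if (!length(t_u)) next
      scales <- stats::rgamma(length(t_u), shape = spec$amplitude_gamma_shape,
                              scale = 1 / spec$amplitude_gamma_shape)
      base <- tm$templates[u, , , drop = TRUE]
      if (is.null(dim(base))) base <- matrix(base, nrow = 1L)
      peak_ch <- which.max(apply(abs(base), 1L, max))
      base_prof <- apply(abs(base), 1L, max)
      for (e in seq_along(t_u)) {
        t0 <- floor(t_u[e]) - tm$w_pre
        idx <- t0:(t0 + kern_len - 1L)
        ok <- idx >= 1L & idx <= n_samp
        if (!any(ok)) next
        shape_e <- base
        if (spec$drift != "none" && spec$drift_displacement_um != 0) {
          dy <- .drift_offset(spec, (t_u[e] - 1) / spec$sample_rate)
          prof <- .spatial_profile(tm$geometry, tm$sources[u, ], dy,
                                   spec$spatial_decay_um)
          # rescale channel rows of the static template to the drifted profile
          ratio <- prof / .spatial_profile(tm$geometry, tm$sources[u, ], 0,
                                           spec$spatial_decay_um)
          shape_e <- base * ratio
        }
        traces[, idx[ok]] <- traces[, idx[ok]] +
          snr_cal * scales[e] * shape_e[, ok, drop = FALSE]
      }
      ch <- c(ch, rep(peak_ch, length(t_u)))
      smp <- c(smp, t_u)
      lab <- c(lab, rep(u, length(t_u)))
    }
    if (spec$noise_sd > 0) {
      traces <- traces + matrix(stats::rnorm(length(traces), 0,
                                             spec$noise_sd),
                                nrow(traces), ncol(traces))
    }
    list(recording = recording(traces, spec$sample_rate, tm$geometry),
         firings = firings(ch, smp, lab))
  })
}

# SNR-calibration factors. The SNR measurement bandpass attenuates iid
# Gaussian noise by r = sqrt(mean A(f)^2) over [0, Nyquist] and the template
# peak by g (the kernel is nearly in-band, g ~ 0.97). Scaling inserted
# templates by r / g makes the measured SNR match the requested target.
.noise_attenuation <- function(sample_rate, fspec = filter_spec()) {
  f <- seq(0, sample_rate / 2, length.out = 8192L)
  sqrt(mean(filter_gain(f, fspec)^2))
}

.kernel_filter_gain <- function(kern, sample_rate, fspec = filter_spec()) {
  n <- 8192L
  x <- c(kern, rep(0, n - length(kern)))
  f <- (seq_len(n) - 1L) / n * sample_rate
  f <- pmin(f, sample_rate - f)
  y <- Re(stats::fft(stats::fft(x) * filter_gain(f, fspec),
                     inverse = TRUE)) / n
  max(abs(y)) / max(abs(kern))
}

.drift_offset <- function(spec, t_s) {
  switch(spec$drift,
    none = 0,
    linear = spec$drift_displacement_um * t_s / spec$duration_s,
    sinusoidal = spec$drift_displacement_um *
      sin(2 * pi * t_s / spec$drift_period_s))
}

#' Perturbation specification for pseudo-sortings
#'
#' @param deletion_prob Per-event deletion probability (false negatives).
#' @param insertion_rate Rate (Hz) of spurious events inserted uniformly over
#'   the duration, per unit (false positives).
#' @param jitter_sd Standard deviation (samples) of rounded Gaussian timing
#'   jitter.
#' @param merge_pairs List of `c(from, into)` label pairs to merge.
#' @param split_fraction Named vector: fraction of each unit's events
#'   reassigned to a fresh label.
#' @param seed Integer seed.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(deletion_prob = 0, insertion_rate = 0,
                              jitter_sd = 0, merge_pairs = list(),
                              split_fraction = numeric(0), seed = 1L) {
  stopifnot(deletion_prob >= 0, deletion_prob <= 1, insertion_rate >= 0,
            jitter_sd >= 0)
  structure(list(deletion_prob = deletion_prob,
                 insertion_rate = insertion_rate, jitter_sd = jitter_sd,
                 merge_pairs = merge_pairs,
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Perturb a ground-truth firing set into a pseudo-sorting
#'
#' Applies independent per-event deletions, uniform spurious insertions,
#' rounded Gaussian timing jitter, merges and splits, returning a sorting
#' with analytically known expected metrics: for jitter well below the
#' matching tolerance, expected recall is `1 - deletion_prob` and expected
#' precision is `N_kept / (N_kept + N_inserted)` per unit.
#'
#' @param gt A [firings()] object (ground truth).
#' @param pspec A [perturbation_spec()].
#' @param duration_samples Recording length in samples (needed for
#'   insertions; defaults to the last event time).
#' @param sample_rate Hz; converts the insertion rate to expected counts.
#' @return List with `firings` (the pseudo-sorting) and `expected` (data
#'   frame per original unit: `label`, `recall`, `precision`).
#' @export
perturb_sorting <- function(gt, pspec, duration_samples = NULL,
                            sample_rate = 30000) {
  stopifnot(inherits(gt, "firings"), inherits(pspec, "perturbation_spec"))
  if (is.null(duration_samples)) duration_samples <- max(gt["sample", ])
  with_seed(pspec$seed, {
    ch <- gt["channel", ]; smp <- gt["sample", ]; lab <- gt["label", ]
    keep <- stats::runif(length(smp)) >= pspec$deletion_prob
    ch <- ch[keep]; smp <- smp[keep]; lab <- lab[keep]
    n_kept <- table(factor(lab, levels = firings_labels(gt)))

    if (pspec$jitter_sd > 0) {
      smp <- smp + round(stats::rnorm(length(smp), 0, pspec$jitter_sd))
      smp <- pmin(pmax(smp, 1), duration_samples)
    }

    n_ins <- integer(0)
    if (pspec$insertion_rate > 0) {
      dur_s <- duration_samples / sample_rate
      for (l in firings_labels(gt)) {
        k <- stats::rpois(1L, pspec$insertion_rate * dur_s)
        n_ins[as.character(l)] <- k
        if (k > 0) {
          smp <- c(smp, stats::runif(k, 1, duration_samples))
          ch <- c(ch, rep(0, k))
          lab <- c(lab, rep(l, k))
        }
      }
    }

    for (pair in pspec$merge_pairs) lab[lab == pair[1L]] <- pair[2L]

    if (length(pspec$split_fraction)) {
      next_label <- max(lab) + 1
      for (l in names(pspec$split_fraction)) {
        q <- pspec$split_fraction[[l]]
        idx <- which(lab == as.numeric(l))
        take <- idx[stats::runif(length(idx)) < q]
        if (length(take)) {
          lab[take] <- next_label
          next_label <- next_label + 1
        }
      }
    }

    exp_rows <- lapply(firings_labels(gt), function(l) {
      nk <- as.integer(n_kept[as.character(l)])
      ni <- if (length(n_ins)) n_ins[as.character(l)] else 0L
      ni <- ifelse(is.na(ni), 0L, ni)
      data.frame(label = l, recall = 1 - pspec$deletion_prob,
                 precision = if (nk + ni > 0) nk / (nk + ni) else NA_real_)
    })
    list(firings = firings(ch, smp, lab),
         expected = do.call(rbind, exp_rows))
  })
}
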