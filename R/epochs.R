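#' Epoched EEG container
#'
#' Holds feedback-locked epochs as a trials x electrodes x samples
#' voltage array (microvolts) with a millisecond time axis, per-trial
#' metadata, and (after [reject_artifacts()]) a rejection mask with
#' per-criterion flags.
#'
#' @param voltages Numeric array `[trial, electrode, sample]`.
#' @param times Numeric vector of sample times in ms (monotone
#'   increasing), length matching `dim(voltages)[3]`.
#' @param srate Sampling rate in Hz.
#' @param electrodes Electrode labels, length `dim(voltages)[2]`.
#' @param trials Tibble of per-trial metadata (one row per trial).
#' @param artifact_log Optional tibble of injected ground-truth
#'   artifacts (`trial`, `electrode`, `type`).
#' @return A list of class `epoch_set`.
#' @export
epoch_set <- function(voltages, times, srate, electrodes, trials,
                      artifact_log = NULL) {
  stopifnot(length(dim(voltages)) == 3L,
            dim(voltages)[2] == length(electrodes),
            dim(voltages)[3] == length(times),
            nrow(trials) == dim(voltages)[1],
            all(diff(times) > 0))
  structure(list(voltages = voltages, times = times, srate = srate,
                 electrodes = electrodes, trials = tibble::as_tibble(trials),
                 artifact_log = artifact_log, rejection = NULL),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$voltages)
  cat("<epoch_set>", d[1], "trials x", d[2], "electrodes x", d[3],
      "samples @", x$srate, "Hz,",
      sprintf("%.0f..%.0f ms\n", min(x$times), max(x$times)))
  if (!is.null(x$rejection)) {
    cat("  rejected:", sum(x$rejection$rejected), "trials\n")
  }
  invisible(x)
}

#' Waveform template for epoch synthesis
#'
#' Defines the epoch geometry and the deterministic component shapes
#' from which synthetic epochs are built. Each component is a Gaussian
#' bump (centre latency and width in ms); at synthesis time the bumps
#' are jointly rescaled so that the mean voltage in each component's
#' +/-30 ms quantification window equals the tabulated single-trial
#' amplitude exactly, which makes windowed-mean extraction unbiased by
#' construction.
#'
#' The default sampling rate is 500 Hz. At substantially lower rates
#' an isolated voltage-step artifact cannot be injected without also
#' exceeding the window-swing or amplitude-bound criteria (a step of
#' more than 70 uV/ms across one 4 ms sample interval already spans
#' more than 200 uV), so artifact attribution tests would be
#' impossible; 500 Hz leaves headroom for all four artifact classes.
#'
#' @param srate Sampling rate (Hz).
#' @param tmin,tmax Epoch span in ms relative to feedback onset.
#' @param components Named list; each element a list with `center`
#'   (ms), `width` (Gaussian SD, ms) and `polarity` (+1/-1).
#' @param noise_sd White-noise SD in microvolts.
#' @return A list of class `waveform_template`.
#' @export
waveform_template <- function(srate = 500,
                              tmin = -200, tmax = 800,
                              components = list(
                                frn = list(center = 300, width = 40,
                                           polarity = -1),
                                p300 = list(center = 380, width = 60,
                                            polarity = 1)),
                              noise_sd = 10) {
  stopifnot(srate > 0, tmax > tmin, noise_sd >= 0)
  for (nm in names(components)) {
    cmp <- components[[nm]]
    if (cmp$center <= tmin || cmp$center >= tmax) {
      stop("component '", nm, "' centre (", cmp$center,
           " ms) lies outside the epoch", call. = FALSE)
    }
  }
  structure(list(srate = srate, tmin = tmin, tmax = tmax,
                 components = components, noise_sd = noise_sd),
            class = "waveform_template")
}

# nearest-sample index of time t (ms) on axis `times`
.time_index <- function(times, t) which.min(abs(times - t))

# half-open [start, end) nearest-sample window indices
.window_index <- function(times, start, end) {
  i0 <- .time_index(times, start)
  i1 <- .time_index(times, end)
  if (times[i1] >= end) i1 <- i1 - 1L
  if (i1 < i0) stop("empty sample window", call. = FALSE)
  i0:i1
}

#' Synthesise noisy epochs embedding tabulated amplitudes
#'
#' Builds an [epoch_set] whose single-trial component amplitudes,
#' measured as the mean voltage in each component's +/-30 ms window,
#' equal the values of an amplitude table exactly (before noise).
#' Component shapes overlap in time, so the per-trial component scales
#' are obtained by solving the small linear system that equates each
#' window mean of the summed shapes to its target amplitude. A
#' controlled fraction of trials receives an injected artifact -- one
#' criterion violation per trial (voltage step, amplitude bound,
#' flatline, window swing), cycling through the four types, overlaid
#' on the ongoing signal (the flatline replaces it) -- and the
#' injections are recorded in `artifact_log` as ground truth for
#' [reject_artifacts()].
#'
#' @param amplitude_table Long tibble as returned by
#'   [generate_amplitude_table()]; must contain `trial` (or `.row`),
#'   `electrode`, `component`, `amplitude_uv`, and per-trial metadata.
#'   Components must match the template's component names (a subset is
#'   allowed; absent components get amplitude 0).
#' @param template A [waveform_template()].
#' @param seed Integer seed for noise and artifact placement.
#' @param artifact_rate Fraction of trials replaced by artifact
#'   waveforms, in `[0, 1]`.
#' @return An `epoch_set` with per-trial metadata and ground-truth
#'   `artifact_log`.
#' @export
generate_epochs <- function(amplitude_table, template, seed = 1L,
                            artifact_rate = 0) {
  stopifnot(inherits(template, "waveform_template"),
            artifact_rate >= 0, artifact_rate <= 1)
  tab <- amplitude_table
  if (!".row" %in% names(tab)) {
    tab$.row <- dplyr::dense_rank(tab$trial)
  }
  srate <- template$srate
  times <- seq(template$tmin, template$tmax, by = 1000 / srate)
  n_samp <- length(times)
  electrodes <- unique(tab$electrode)
  trial_meta <- dplyr::distinct(
    tab, dplyr::across(dplyr::any_of(c(
      ".row", "participant", "timing", "block", "trial", "reward",
      "pe_abs"))))
  trial_meta <- dplyr::arrange(trial_meta, .data$.row)
  trial_meta$epoch <- seq_len(nrow(trial_meta))
  n_trial <- nrow(trial_meta)

  comp_names <- names(template$components)
  used <- intersect(comp_names, unique(tab$component))
  if (length(setdiff(unique(tab$component), comp_names))) {
    stop("amplitude table has component(s) absent from the template",
         call. = FALSE)
  }

  # normalised shapes: window mean of own window = 1
  shapes <- list(); windows <- list()
  for (nm in comp_names) {
    cmp <- template$components[[nm]]
    g <- exp(-0.5 * ((times - cmp$center) / cmp$width)^2)
    win <- .window_index(times, cmp$center - 30, cmp$center + 30)
    shapes[[nm]] <- g / mean(g[win])
    windows[[nm]] <- win
  }
  # cross-window means of the normalised shapes
  M <- matrix(0, length(used), length(used),
              dimnames = list(used, used))
  for (i in used) for (j in used) {
    M[i, j] <- mean(shapes[[j]][windows[[i]]])
  }

  amp_wide <- tidyr::pivot_wider(
    dplyr::select(tab, ".row", "electrode", "component", "amplitude_uv"),
    names_from = "component", values_from = "amplitude_uv",
    values_fill = 0)

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  v <- array(rnorm(n_trial * length(electrodes) * n_samp, 0,
                   template$noise_sd),
             dim = c(n_trial, length(electrodes), n_samp))
  shape_mat <- do.call(rbind, shapes[used])      # used x samples
  Minv <- solve(M)
  for (r in seq_len(nrow(amp_wide))) {
    ti <- amp_wide$.row[r]
    ei <- match(amp_wide$electrode[r], electrodes)
    target <- as.numeric(amp_wide[r, used, drop = FALSE])
    scales <- drop(Minv %*% target)
    v[ti, ei, ] <- v[ti, ei, ] + drop(scales %*% shape_mat)
  }

  log <- NULL
  if (artifact_rate > 0) {
    n_art <- round(artifact_rate * n_trial)
    if (n_art > 0) {
      art_trials <- sort(sample(n_trial, n_art))
      types <- rep(c("step", "amplitude", "flatline", "swing"),
                   length.out = n_art)
      for (i in seq_len(n_art)) {
        w <- .artifact_waveform(types[i], times, srate)
        if (types[i] == "flatline") {
          v[art_trials[i], 1L, ] <- w   # dead channel: no residual activity
        } else {
          v[art_trials[i], 1L, ] <- v[art_trials[i], 1L, ] + w
        }
      }
      log <- tibble::tibble(trial = art_trials, electrode = electrodes[1],
                            type = types)
    }
  }

  es <- epoch_set(v, times, srate, electrodes,
                  dplyr::select(trial_meta, -".row"),
                  artifact_log = log)
  es
}

# one-violation artifact waveforms (thresholds 70 uV/ms step,
# 200 uV/100 ms swing, +/-150 uV bounds, 0.1 uV minimum activity)
.artifact_waveform <- function(type, times, srate) {
  dt <- 1000 / srate
  n <- length(times)
  switch(type,
    step = {
      jump <- 1.2 * 70 * dt
      if (jump >= 195 || jump / 2 > 145) {
        stop("sampling rate too low to inject an isolated voltage-step ",
             "artifact (needs > 70 uV/ms without exceeding the 200 uV ",
             "swing and +/-150 uV bounds)", call. = FALSE)
      }
      c(rep(-jump / 2, floor(n / 2)), rep(jump / 2, n - floor(n / 2)))
    },
    amplitude = 170 * exp(-0.5 * ((times - stats::median(times)) / 40)^2),
    flatline = rep(0, n),
    swing = 105 * sin(2 * pi * (times - times[1]) / 200)
  )
}
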