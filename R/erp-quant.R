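#' Baseline-correct epochs
#'
#' Subtracts, per trial and electrode, the mean voltage over the
#' baseline window (default the 200 ms before feedback onset) from the
#' whole epoch. Idempotent: correcting twice changes nothing.
#'
#' @param epochs An [epoch_set].
#' @param window Baseline window in ms, half-open `[start, end)`.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- .window_index(epochs$times, window[1], window[2])
  base <- apply(epochs$voltages[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$voltages <- sweep(epochs$voltages, c(1, 2), base)
  epochs
}

#' Zero-phase filter epochs
#'
#' Applies second-order Butterworth high-pass and low-pass filters and
#' a band-stop (notch) filter, each forward-backward
#' (`signal::filtfilt`) so the net phase response is zero. The epoch
#' mean is removed before filtering, so a pure DC input maps to zero.
#'
#' @param epochs An [epoch_set].
#' @param hp,lp High-/low-pass cutoffs in Hz (`NULL` disables).
#' @param order Butterworth order per pass (default 2).
#' @param notch Mains frequency in Hz (`NULL` disables); stop band is
#'   `notch` +/- 2 Hz.
#' @return The filtered `epoch_set`.
#' @export
filter_epochs <- function(epochs, hp = 0.1, lp = 30, order = 2,
                          notch = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$srate / 2
  edges <- c(hp, lp, if (!is.null(notch)) notch + 2)
  if (any(edges >= nyq)) {
    stop("filter edge at or above the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  filters <- list()
  if (!is.null(hp)) filters <- c(filters, list(
    signal::butter(order, hp / nyq, type = "high")))
  if (!is.null(lp)) filters <- c(filters, list(
    signal::butter(order, lp / nyq, type = "low")))
  if (!is.null(notch)) filters <- c(filters, list(
    signal::butter(order, c(notch - 2, notch + 2) / nyq, type = "stop")))
  d <- dim(epochs$voltages)
  for (t in seq_len(d[1])) for (e in seq_len(d[2])) {
    x <- epochs$voltages[t, e, ]
    x <- x - mean(x)
    for (f in filters) x <- signal::filtfilt(f, x)
    epochs$voltages[t, e, ] <- x
  }
  epochs
}

#' Artifact-rejection criteria
#'
#' Thresholds of the automatic artifact rejection: maximal voltage
#' step between adjacent samples (uV/ms), maximal peak-to-peak swing
#' within any 100 ms window (uV), absolute amplitude bounds (uV), and
#' the lowest allowed activity -- interpreted as peak-to-peak range --
#' within any 100 ms window (uV).
#'
#' @param max_step uV/ms (default 70).
#' @param max_swing uV per 100 ms (default 200).
#' @param amp_bound uV; samples outside `[-amp_bound, amp_bound]` are
#'   violations (default 150).
#' @param min_activity uV per 100 ms (default 0.1).
#' @return A list of class `rejection_criteria`.
#' @export
rejection_criteria <- function(max_step = 70, max_swing = 200,
                               amp_bound = 150, min_activity = 0.1) {
  vals <- c(max_step, max_swing, amp_bound, min_activity)
  if (any(vals <= 0)) stop("all thresholds must be > 0", call. = FALSE)
  structure(list(max_step = max_step, max_swing = max_swing,
                 amp_bound = amp_bound, min_activity = min_activity),
            class = "rejection_criteria")
}

# sliding-window range (max - min) over every `width`-sample window
.window_ranges <- function(x, width) {
  if (width > length(x)) stop("epoch shorter than the sliding window",
                              call. = FALSE)
  e <- stats::embed(x, width)
  apply(e, 1, max) - apply(e, 1, min)
}

#' Threshold-based artifact rejection
#'
#' Flags a trial as rejected when any electrode violates any
#' criterion: adjacent-sample voltage step above `max_step` uV/ms,
#' peak-to-peak swing above `max_swing` uV within a sliding 100 ms
#' window, any sample outside the amplitude bounds, or peak-to-peak
#' range below `min_activity` uV within any 100 ms window.
#'
#' @param epochs An [epoch_set].
#' @param criteria A [rejection_criteria()] object.
#' @param electrodes Electrode labels to evaluate (default all).
#' @return The `epoch_set` with `rejection`: a tibble (`trial`,
#'   `rejected`, `step`, `swing`, `bounds`, `activity`) of logical
#'   flags.
#' @export
reject_artifacts <- function(epochs, criteria = rejection_criteria(),
                             electrodes = NULL) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(criteria, "rejection_criteria"))
  if (is.null(electrodes)) electrodes <- epochs$electrodes
  eis <- match(electrodes, epochs$electrodes)
  if (anyNA(eis)) stop("unknown electrode label(s)", call. = FALSE)
  dt <- 1000 / epochs$srate
  width <- round(100 / dt) + 1L   # samples spanning 100 ms
  n_samp <- dim(epochs$voltages)[3]
  if (width > n_samp) stop("epochs shorter than 100 ms", call. = FALSE)
  d1 <- dim(epochs$voltages)[1]
  flags <- matrix(FALSE, d1, 4,
                  dimnames = list(NULL, c("step", "swing", "bounds",
                                          "activity")))
  for (t in seq_len(d1)) {
    for (e in eis) {
      x <- epochs$voltages[t, e, ]
      if (max(abs(diff(x))) / dt > criteria$max_step) {
        flags[t, "step"] <- TRUE
      }
      rng <- .window_ranges(x, width)
      if (max(rng) > criteria$max_swing) flags[t, "swing"] <- TRUE
      if (any(abs(x) > criteria$amp_bound)) flags[t, "bounds"] <- TRUE
      if (min(rng) < criteria$min_activity) flags[t, "activity"] <- TRUE
    }
  }
  epochs$rejection <- tibble::tibble(
    trial = seq_len(d1),
    rejected = rowSums(flags) > 0,
    step = flags[, "step"], swing = flags[, "swing"],
    bounds = flags[, "bounds"], activity = flags[, "activity"]
  )
  epochs
}

#' Electrode cluster specification
#'
#' The frontocentral cluster (Fz, FCz, Cz, FC1, FC2) is used for the
#' FRN/RewP; the parietal cluster (CP1, CP2, P3, Pz, P4) joins it for
#' the P300 analysis.
#'
#' @param name `"frontocentral"` or `"parietal"`.
#' @param electrodes Electrode labels (defaults per `name`).
#' @return A list of class `cluster_spec`.
#' @export
cluster_spec <- function(name = c("frontocentral", "parietal"),
                         electrodes = NULL) {
  name <- match.arg(name)
  if (is.null(electrodes)) {
    electrodes <- switch(name,
      frontocentral = c("Fz", "FCz", "Cz", "FC1", "FC2"),
      parietal = c("CP1", "CP2", "P3", "Pz", "P4"))
  }
  structure(list(name = name, electrodes = electrodes),
            class = "cluster_spec")
}

#' Average retained epochs over trials and electrodes
#'
#' Means the voltage over retained trials matching a selector and over
#' the cluster's electrodes, yielding one waveform (e.g. the grand
#' average for negative immediate feedback at the frontocentral
#' cluster).
#'
#' @param epochs An [epoch_set] (run [reject_artifacts()] first if a
#'   rejection mask should apply).
#' @param selector Logical vector over trials, or a one-sided formula
#'   evaluated in the trial metadata (e.g. `~ reward == 0`); `NULL`
#'   selects all trials.
#' @param cluster A [cluster_spec()], electrode label vector, or
#'   `NULL` for all electrodes.
#' @return A tibble of class `erp_waveform` with columns `time_ms` and
#'   `amplitude_uv`; attributes `n_trials`, `srate`.
#' @export
condition_average <- function(epochs, selector = NULL, cluster = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- rep(TRUE, nrow(epochs$trials))
  if (!is.null(epochs$rejection)) keep <- !epochs$rejection$rejected
  sel <- if (is.null(selector)) rep(TRUE, nrow(epochs$trials))
    else if (inherits(selector, "formula")) {
      rlang::eval_tidy(selector[[2]], data = epochs$trials,
                       env = environment(selector))
    } else as.logical(selector)
  keep <- keep & sel
  if (!any(keep)) stop("no retained trials match the selector", call. = FALSE)
  electrodes <- if (is.null(cluster)) epochs$electrodes
    else if (inherits(cluster, "cluster_spec")) cluster$electrodes
    else cluster
  eis <- match(electrodes, epochs$electrodes)
  if (anyNA(eis)) stop("cluster electrode(s) absent from the epochs",
                       call. = FALSE)
  w <- apply(epochs$voltages[keep, eis, , drop = FALSE], 3, mean)
  out <- tibble::new_tibble(
    tibble::tibble(time_ms = epochs$times, amplitude_uv = w),
    class = "erp_waveform")
  attr(out, "n_trials") <- sum(keep)
  attr(out, "srate") <- epochs$srate
  out
}

#' Punishment-minus-reward difference wave
#'
#' @param avg_negative,avg_positive `erp_waveform`s averaged over
#'   negative- and positive-feedback trials (same time axis).
#' @return An `erp_waveform` of the difference.
#' @export
difference_wave <- function(avg_negative, avg_positive) {
  stopifnot(isTRUE(all.equal(avg_negative$time_ms, avg_positive$time_ms)))
  out <- tibble::new_tibble(
    tibble::tibble(time_ms = avg_negative$time_ms,
                   amplitude_uv = avg_negative$amplitude_uv -
                     avg_positive$amplitude_uv),
    class = "erp_waveform")
  attr(out, "srate") <- attr(avg_negative, "srate")
  out
}

#' Locate a component peak in a waveform
#'
#' Finds the latency of the largest local extremum of the requested
#' polarity inside a search window (FRN: largest negative local peak
#' 180-350 ms of the difference wave; P300: largest local maximum
#' 300-500 ms of the pooled average). "Local" means strictly exceeding
#' both neighbouring samples; ties go to the earliest latency. If the
#' window contains no local extremum the windowed extremum is returned
#' with `fallback = TRUE` and a warning.
#'
#' @param waveform An `erp_waveform`.
#' @param window Search window in ms (inclusive).
#' @param polarity `"negative"` or `"positive"`.
#' @return A list: `latency_ms`, `amplitude_uv`, `fallback`.
#' @export
find_peak <- function(waveform, window, polarity = c("negative",
                                                     "positive")) {
  polarity <- match.arg(polarity)
  t <- waveform$time_ms
  if (window[1] < min(t) || window[2] > max(t)) {
    stop("search window outside the epoch", call. = FALSE)
  }
  y <- waveform$amplitude_uv
  if (polarity == "negative") y <- -y
  in_win <- which(t >= window[1] & t <= window[2])
  # strict local maxima of y (interior samples of the full waveform)
  cand <- in_win[in_win > 1 & in_win < length(y)]
  is_local <- y[cand] > y[cand - 1] & y[cand] > y[cand + 1]
  local <- cand[is_local]
  if (length(local)) {
    best <- local[which.max(y[local])]   # which.max: earliest on ties
    fallback <- FALSE
  } else {
    best <- in_win[which.max(y[in_win])]
    fallback <- TRUE
    warning("no local ", polarity, " peak in [", window[1], ", ",
            window[2], "] ms; using the windowed extremum", call. = FALSE)
  }
  list(latency_ms = t[best],
       amplitude_uv = waveform$amplitude_uv[best],
       fallback = fallback)
}

#' Extract single-trial windowed mean amplitudes
#'
#' For every retained trial and every cluster electrode, the mean
#' voltage over `[center - half_width, center + half_width)`
#' (nearest-sample, half-open). In the published procedure the centre
#' latency is the timing-condition-specific difference-wave peak (FRN)
#' or the valence- and cluster-pooled average peak (P300), and
#' `half_width` is 30 ms.
#'
#' @param epochs An [epoch_set].
#' @param center Window centre latency in ms.
#' @param half_width Half window width in ms (default 30).
#' @param cluster A [cluster_spec()], electrode labels, or `NULL` for
#'   all electrodes.
#' @param component Component label attached to the rows.
#' @return A long tibble: trial metadata plus `trial`, `electrode`,
#'   `cluster`, `component`, `amplitude_uv`. Rejected trials are
#'   dropped.
#' @export
extract_window_amplitudes <- function(epochs, center, half_width = 30,
                                      cluster = NULL, component = "frn") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (center - half_width < min(epochs$times) ||
      center + half_width > max(epochs$times) + 1000 / epochs$srate) {
    stop("amplitude window exceeds the epoch", call. = FALSE)
  }
  idx <- .window_index(epochs$times, center - half_width,
                       center + half_width)
  electrodes <- if (is.null(cluster)) epochs$electrodes
    else if (inherits(cluster, "cluster_spec")) cluster$electrodes
    else cluster
  cl_name <- if (inherits(cluster, "cluster_spec")) cluster$name
    else NA_character_
  eis <- match(electrodes, epochs$electrodes)
  if (anyNA(eis)) stop("cluster electrode(s) absent from the epochs",
                       call. = FALSE)
  keep <- if (is.null(epochs$rejection)) rep(TRUE, nrow(epochs$trials))
    else !epochs$rejection$rejected
  means <- apply(epochs$voltages[, eis, idx, drop = FALSE], c(1, 2), mean)
  meta <- epochs$trials
  if (!"trial" %in% names(meta)) meta$trial <- seq_len(nrow(meta))
  out <- tidyr::expand_grid(
    dplyr::mutate(meta, .row = dplyr::row_number()),
    tibble::tibble(electrode = electrodes, .e = seq_along(electrodes)))
  out$amplitude_uv <- means[cbind(out$.row, out$.e)]
  out$cluster <- cl_name
  out$component <- component
  out <- out[keep[out$.row], ]
  dplyr::select(out, -".e", -".row")
}
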