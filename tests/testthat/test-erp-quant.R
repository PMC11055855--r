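# small epoch fixture: known waveforms on a 500 Hz grid
flat_epochs <- function(n_trial = 2, n_elec = 2, srate = 500,
                        value = 0) {
  times <- seq(-200, 800, by = 1000 / srate)
  v <- array(value, dim = c(n_trial, n_elec, length(times)))
  epoch_set(v, times, srate, paste0("E", seq_len(n_elec)),
            tibble::tibble(trial = seq_len(n_trial),
                           reward = rep_len(c(0L, 1L), n_trial),
                           timing = "immediate",
                           participant = "p01"))
}

test_that("baseline correction removes offsets and is idempotent", {
  es <- flat_epochs(value = 3.7)
  bc <- baseline_correct(es)
  expect_equal(max(abs(bc$voltages)), 0)
  # ramp: subtracts the baseline-window mean, computed directly
  es2 <- flat_epochs(n_trial = 1, n_elec = 1)
  ramp <- seq_along(es2$times)
  es2$voltages[1, 1, ] <- ramp
  bc2 <- baseline_correct(es2)
  base_idx <- which(es2$times >= -200 & es2$times < 0)
  expect_equal(bc2$voltages[1, 1, ], ramp - mean(ramp[base_idx]))
  expect_equal(baseline_correct(bc2)$voltages, bc2$voltages)
})

test_that("zero-phase filtering removes DC, passes 10 Hz, notches 50 Hz", {
  es <- flat_epochs(n_trial = 3, n_elec = 1)
  t_s <- es$times / 1000
  es$voltages[1, 1, ] <- 5                       # DC
  es$voltages[2, 1, ] <- sin(2 * pi * 10 * t_s)  # passband
  es$voltages[3, 1, ] <- sin(2 * pi * 50 * t_s)  # mains
  f <- filter_epochs(es)
  core <- which(es$times > 0 & es$times < 600)   # avoid filter edges
  expect_lt(max(abs(f$voltages[1, 1, ])), 1e-8)
  gain10 <- sd(f$voltages[2, 1, core]) / sd(es$voltages[2, 1, core])
  expect_gt(gain10, 0.95)
  expect_lt(gain10, 1.05)
  gain50 <- sd(f$voltages[3, 1, core]) / sd(es$voltages[3, 1, core])
  expect_lt(gain50, 0.1)  # >= 20 dB attenuation
  expect_error(filter_epochs(flat_epochs(srate = 50)), "Nyquist")
})

test_that("each rejection criterion fires on its construction and only there", {
  es <- flat_epochs(n_trial = 5, n_elec = 1)
  n <- length(es$times)
  set.seed(1)
  jitter <- function() rnorm(n, 0, 0.5)  # keeps ongoing activity present
  # trial 1: step of 168 uV between adjacent samples (84 uV/ms at 500 Hz)
  es$voltages[1, 1, ] <- c(rep(-84, n %/% 2), rep(84, n - n %/% 2)) +
    jitter()
  # trial 2: slow bump exceeding the +/-150 uV bound
  es$voltages[2, 1, ] <- 170 * exp(-0.5 * ((es$times - 300) / 40)^2) +
    jitter()
  # trial 3: flatline
  es$voltages[3, 1, ] <- 0
  # trial 4: 210 uV swing inside 100 ms, slope and bounds safe
  es$voltages[4, 1, ] <- 105 * sin(2 * pi * (es$times + 200) / 200) +
    jitter()
  # trial 5: ordinary noise, no violation
  es$voltages[5, 1, ] <- rnorm(n, 0, 5)
  r <- reject_artifacts(es)$rejection
  expect_equal(r$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(r$step, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(r$bounds, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$activity, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(r$swing, c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("rejection is monotone in its thresholds", {
  set.seed(2)
  es <- flat_epochs(n_trial = 20, n_elec = 2)
  es$voltages <- array(rnorm(length(es$voltages), 0, 60),
                       dim = dim(es$voltages))
  strict <- reject_artifacts(es, rejection_criteria(
    max_step = 20, max_swing = 120, amp_bound = 90, min_activity = 0.1))
  loose <- reject_artifacts(es, rejection_criteria(
    max_step = 40, max_swing = 250, amp_bound = 160, min_activity = 0.05))
  expect_true(all(loose$rejection$rejected <= strict$rejection$rejected))
})

test_that("condition averages equal a direct nested-loop mean", {
  set.seed(3)
  es <- flat_epochs(n_trial = 12, n_elec = 2)
  es$voltages <- array(rnorm(length(es$voltages)), dim = dim(es$voltages))
  avg <- condition_average(es, ~ reward == 0, c("E1", "E2"))
  neg <- which(es$trials$reward == 0)
  manual <- rep(0, length(es$times))
  for (t in neg) for (e in 1:2) {
    manual <- manual + es$voltages[t, e, ]
  }
  manual <- manual / (length(neg) * 2)
  expect_equal(avg$amplitude_uv, manual, tolerance = 1e-12)
  expect_equal(attr(avg, "n_trials"), length(neg))
  # one trial, one electrode: the epoch itself
  one <- condition_average(es, es$trials$trial == 1, "E1")
  expect_equal(one$amplitude_uv, es$voltages[1, 1, ])
})

test_that("difference waves subtract reward from punishment averages", {
  es <- flat_epochs(n_trial = 2, n_elec = 1)
  es$voltages[1, 1, ] <- 2   # negative feedback trial
  es$voltages[2, 1, ] <- -1  # positive feedback trial
  d <- difference_wave(condition_average(es, ~ reward == 0),
                       condition_average(es, ~ reward == 1))
  expect_equal(unique(d$amplitude_uv), 3)
  z <- difference_wave(condition_average(es, ~ reward == 0),
                       condition_average(es, ~ reward == 0))
  expect_equal(max(abs(z$amplitude_uv)), 0)
})

test_that("peak finding returns local extrema, ties and fallbacks correctly", {
  times <- seq(-200, 800, by = 2)
  mk <- function(y) {
    w <- tibble::tibble(time_ms = times, amplitude_uv = y)
    class(w) <- c("erp_waveform", class(w))
    w
  }
  g <- -exp(-0.5 * ((times - 300) / 30)^2)
  pk <- find_peak(mk(g), c(180, 350), "negative")
  expect_lte(abs(pk$latency_ms - 300), 2)
  expect_false(pk$fallback)
  # two local minima, second deeper
  y2 <- -exp(-0.5 * ((times - 220) / 15)^2) -
    2 * exp(-0.5 * ((times - 320) / 15)^2)
  pk2 <- find_peak(mk(y2), c(180, 350), "negative")
  expect_lte(abs(pk2$latency_ms - 320), 2)
  # monotone ramp: fallback to the windowed extremum with a warning
  expect_warning(pk3 <- find_peak(mk(times * 0.01), c(300, 500),
                                  "positive"),
                 "windowed extremum")
  expect_true(pk3$fallback)
  expect_equal(pk3$latency_ms, 500)
  expect_error(find_peak(mk(g), c(-300, 100), "negative"),
               "outside the epoch")
})

test_that("windowed amplitudes recover embedded component values exactly", {
  tr <- tibble::tibble(participant = "p01", timing = "immediate",
                       trial = 1:8, reward = rep(c(0L, 1L), 4),
                       pe_abs = seq(.1, .8, by = .1))
  par <- amplitude_gen_params(
    coefs = c("(Intercept)" = 3, pe = 2),
    sd_participant = c("(Intercept)" = 0), sd_electrode = 0, sigma = 0)
  tab_frn <- generate_amplitude_table(tr, par, electrodes = c("Fz", "Cz"),
                                      seed = 4, component = "frn")
  tab_p3 <- generate_amplitude_table(tr, par, electrodes = c("Fz", "Cz"),
                                     seed = 5, component = "p300")
  tab_p3$amplitude_uv <- tab_p3$amplitude_uv + 2
  tab <- dplyr::bind_rows(tab_frn, tab_p3)
  tmpl <- waveform_template(noise_sd = 0)
  es <- generate_epochs(tab, tmpl, seed = 6, artifact_rate = 0)
  for (cmp in c("frn", "p300")) {
    ctr <- tmpl$components[[cmp]]$center
    ex <- extract_window_amplitudes(es, ctr, 30, component = cmp)
    truth <- tab[tab$component == cmp, ]
    m <- dplyr::inner_join(ex, truth,
                           by = c("epoch" = ".row", "electrode"))
    expect_equal(nrow(m), 16L)
    expect_lt(max(abs(m$amplitude_uv.x - m$amplitude_uv.y)), 1e-6)
  }
  # all-zero epochs extract to zero
  es0 <- flat_epochs()
  ex0 <- extract_window_amplitudes(es0, 300, 30)
  expect_true(all(ex0$amplitude_uv == 0))
  expect_error(extract_window_amplitudes(es0, 790, 30), "exceeds")
})

test_that("injected artifacts are flagged by exactly their criterion", {
  tr <- tibble::tibble(participant = "p01", timing = "immediate",
                       trial = 1:40, reward = rep(c(0L, 1L), 20),
                       pe_abs = runif(40))
  par <- amplitude_gen_params(
    coefs = c("(Intercept)" = 3, valence = -0.5),
    sd_participant = c("(Intercept)" = 0), sd_electrode = 0, sigma = 0)
  tab <- generate_amplitude_table(tr, par, electrodes = c("Fz", "Cz"),
                                  seed = 7)
  es <- generate_epochs(tab, waveform_template(noise_sd = 1), seed = 8,
                        artifact_rate = 0.2)
  expect_equal(nrow(es$artifact_log), 8L)
  rej <- reject_artifacts(es)$rejection
  expect_setequal(which(rej$rejected), es$artifact_log$trial)
  crit_of <- c(step = "step", amplitude = "bounds", flatline = "activity",
               swing = "swing")
  for (i in seq_len(nrow(es$artifact_log))) {
    tr_i <- es$artifact_log$trial[i]
    fired <- unlist(rej[tr_i, c("step", "swing", "bounds", "activity")])
    expect_equal(names(fired)[fired],
                 unname(crit_of[es$artifact_log$type[i]]))
  }
  # artifact_rate 0 flags nothing under default noise
  es0 <- generate_epochs(tab, waveform_template(), seed = 9,
                         artifact_rate = 0)
  expect_equal(sum(reject_artifacts(es0)$rejection$rejected), 0L)
})
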