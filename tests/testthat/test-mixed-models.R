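coded_fixture <- function(n_participants = 6, n_trials = 60,
                          electrodes = c("Fz", "Cz"), seed = 1,
                          coefs = c("(Intercept)" = 2, valence = -0.4,
                                    timing = -1, pe = 0.9,
                                    "valence:pe" = -0.7),
                          sigma = 2, re_sd = 0.5) {
  tr <- tibble::tibble(
    participant = rep(sprintf("p%02d", seq_len(n_participants)),
                      each = n_trials),
    timing = rep_len(c("immediate", "delayed"),
                     n_participants * n_trials),
    trial = rep(seq_len(n_trials), n_participants),
    reward = rep_len(c(0L, 1L, 1L, 0L), n_participants * n_trials),
    pe_abs = rep(seq(0.05, 0.95, length.out = n_trials), n_participants))
  par <- amplitude_gen_params(
    coefs = coefs,
    sd_participant = c("(Intercept)" = re_sd),
    sd_electrode = re_sd / 2, sigma = sigma)
  tab <- generate_amplitude_table(tr, par, electrodes = electrodes,
                                  seed = seed)
  encode_predictors(tab)
}

test_that("effect coding maps levels to -1/+1, centres the PE, round-trips", {
  tab <- tibble::tibble(
    amplitude_uv = rnorm(8), participant = "p01", electrode = "Cz",
    timing = rep(c("immediate", "delayed"), 4),
    reward = rep(c(0L, 1L), each = 4),
    pe_abs = c(0, 1, 0, 1, 0, 1, 0, 1),
    cluster = rep(c("frontocentral", "parietal"), 4))
  coded <- encode_predictors(tab)
  expect_equal(sum(coded$valence), 0)
  expect_equal(sum(coded$timing), 0)
  expect_equal(sort(unique(coded$pe)), c(-0.5, 0.5))
  expect_equal(diff(range(coded$pe)), diff(range(tab$pe_abs)))
  expect_equal(coded$valence[tab$reward == 0], rep(1, 4))
  expect_equal(coded$frontality[tab$cluster == "parietal"], rep(1, 4))
  dec <- decode_predictors(coded)
  expect_equal(dec$pe_abs, tab$pe_abs)
  expect_equal(dec$timing, tab$timing)
  expect_equal(dec$valence,
               ifelse(tab$reward == 1, "positive", "negative"))
  expect_equal(dec$cluster, tab$cluster)
})

test_that("noiseless data reproduce the generating coefficients (OLS oracle)", {
  coded <- coded_fixture(sigma = 0, re_sd = 0)
  fit <- fit_erp_lmm(amplitude ~ valence * pe + timing, coded)
  td <- tidy(fit)
  ols <- coef(lm(amplitude ~ valence * pe + timing, coded))
  expect_equal(setNames(td$estimate, td$term), ols, tolerance = 1e-6)
  expect_equal(unname(ols[c("valence", "timing", "pe", "valence:pe")]),
               c(-0.4, -1, 0.9, -0.7), tolerance = 1e-6)
})

test_that("mixed fits expose Satterthwaite df and sensible summaries", {
  coded <- coded_fixture(seed = 2)
  fit <- fit_erp_lmm(
    amplitude ~ valence * pe + timing + (1 | participant) +
      (1 | electrode), coded)
  td <- tidy(fit)
  expect_true(all(td$std.error > 0))
  expect_true(all(td$df > 0))
  expect_equal(fit$df_method, "satterthwaite")
  # intercept-only model: estimate is the sample mean
  fit0 <- fit_erp_lmm(amplitude ~ 1, coded)
  expect_equal(tidy(fit0)$estimate, mean(coded$amplitude),
               tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(coded))
  sds <- ranef_sds(fit)
  expect_setequal(sds$group, c("participant", "electrode", "Residual"))
  expect_error(
    fit_erp_lmm(amplitude ~ pe + (1 | participant),
                dplyr::filter(coded, participant == "p01")),
    ">= 2 participants")
})

test_that("stepwise selection keeps real structure and drops absent terms", {
  # strong valence effect, no timing effect anywhere
  coded <- coded_fixture(
    n_participants = 8, n_trials = 80, seed = 3,
    coefs = c("(Intercept)" = 1, valence = -2, pe = 1.5),
    sigma = 1.5, re_sd = 1)
  sel <- select_parsimonious(
    amplitude ~ valence * timing * pe +
      (valence + timing + pe | participant) + (1 | electrode),
    coded)
  kept <- attr(terms(lme4::nobars(sel$formula)), "term.labels")
  expect_true(all(c("valence", "pe") %in% kept))
  expect_false("timing:valence" %in% kept ||
                 "valence:timing" %in% kept)
  expect_true(all(sel$trace$action %in% c("added", "eliminated")))
  expect_s3_class(sel$fit, "erp_lmm")
  # an empty candidate set returns the intercept-only model
  sel0 <- select_parsimonious(amplitude ~ 1, coded)
  expect_equal(deparse1(sel0$formula), "amplitude ~ 1")
  expect_equal(nrow(sel0$trace), 0L)
})

test_that("simple slopes satisfy the interaction identity for any fit", {
  coded <- coded_fixture(seed = 4)
  fit <- fit_erp_lmm(
    amplitude ~ valence * timing * pe + (1 | participant) +
      (1 | electrode), coded)
  b <- lme4::fixef(fit$fit)
  ss <- simple_slopes(fit, "pe", "valence", correction = "none")
  expect_equal(ss$slope[ss$valence == -1],
               unname(b["pe"] - b["valence:pe"]), tolerance = 1e-12)
  expect_equal(ss$slope[ss$valence == 1],
               unname(b["pe"] + b["valence:pe"]), tolerance = 1e-12)
  # two moderators: slope includes the three-way product term
  ss2 <- simple_slopes(fit, "pe", c("valence", "timing"),
                       correction = "none")
  for (i in seq_len(nrow(ss2))) {
    v <- ss2$valence[i]; tm <- ss2$timing[i]
    expect_equal(ss2$slope[i],
                 unname(b["pe"] + v * b["valence:pe"] +
                          tm * b["timing:pe"] +
                          v * tm * b["valence:timing:pe"]),
                 tolerance = 1e-12)
  }
  # zero interaction: slopes collapse to the focal coefficient
  ssz <- simple_slopes(c(pe = 1.2, valence = 3), "pe", "valence")
  expect_equal(ssz$slope, c(1.2, 1.2))
})

test_that("Bonferroni adjustment is monotone and capped at 1", {
  set.seed(5)
  coded <- coded_fixture(seed = 6)
  fit <- fit_erp_lmm(
    amplitude ~ valence * pe + (1 | participant) + (1 | electrode),
    coded)
  raw <- simple_slopes(fit, "pe", "valence", correction = "none")
  adj <- simple_slopes(fit, "pe", "valence", correction = "bonferroni")
  expect_true(all(adj$p.value >= raw$p.value - 1e-15))
  expect_true(all(adj$p.value <= 1))
  expect_equal(adj$p.value, pmin(1, 2 * raw$p.value))
})

test_that("printed FRN/P300 fixed effects give the published simple slopes", {
  frn <- c(pe = 0.94, "valence:pe" = -0.77, "timing:pe" = -0.57)
  by_val <- simple_slopes(frn, "pe", "valence")
  expect_equal(by_val$slope[by_val$valence == -1], 1.71)  # positive feedback
  expect_equal(by_val$slope[by_val$valence == 1], 0.17)   # negative feedback
  by_tim <- simple_slopes(frn, "pe", "timing")
  expect_equal(by_tim$slope[by_tim$timing == -1], 1.51)   # immediate
  p300 <- c(pe = 1.02, "valence:pe" = -0.92)
  p3 <- simple_slopes(p300, "pe", "valence")
  expect_equal(p3$slope[p3$valence == 1], 0.10)           # negative feedback
})

test_that("null power simulations are calibrated near alpha", {
  tr <- tibble::tibble(
    participant = rep(sprintf("p%02d", 1:6), each = 40),
    timing = rep_len(c("immediate", "delayed"), 240),
    trial = rep(1:40, 6),
    reward = rep_len(c(0L, 1L), 240),
    pe_abs = runif(240))
  par <- amplitude_gen_params(
    coefs = c("(Intercept)" = 2, valence = -0.4, pe = 0.9,
              "valence:pe" = 0),
    sd_participant = c("(Intercept)" = 0.8), sd_electrode = 0.2,
    sigma = 3)
  pw <- power_simulation(tr, par, focal = "valence:pe", b = 0,
                         formula = amplitude ~ valence * pe +
                           (1 | participant) + (1 | electrode),
                         n_sims = 60, alpha = 0.05, seed = 11)
  se <- sqrt(0.05 * 0.95 / 60)
  expect_lt(pw$power, 0.05 + 4 * se)
  expect_gte(pw$power, 0)
  # a large effect with modest noise is detected essentially always
  pw2 <- power_simulation(tr, par, focal = "valence:pe", b = 2.5,
                          formula = amplitude ~ valence * pe +
                            (1 | participant) + (1 | electrode),
                          n_sims = 15, alpha = 0.05, seed = 12)
  expect_gt(pw2$power, 0.9)
  # deterministic under a fixed seed
  pw3 <- power_simulation(tr, par, focal = "valence:pe", b = 0,
                          formula = amplitude ~ valence * pe +
                            (1 | participant) + (1 | electrode),
                          n_sims = 10, alpha = 0.05, seed = 11)
  pw4 <- power_simulation(tr, par, focal = "valence:pe", b = 0,
                          formula = amplitude ~ valence * pe +
                            (1 | participant) + (1 | electrode),
                          n_sims = 10, alpha = 0.05, seed = 11)
  expect_identical(pw3$n_sig, pw4$n_sig)
})
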