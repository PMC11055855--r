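test_that("single-trial updates follow the delta rule from Q = 0.5", {
  p1 <- agent_params("M1", alpha = 0.1, beta = 5)
  u <- update_values("M1", rep(0.5, 5), chosen = 2, unchosen = 4,
                     reward = 1, params = p1)
  expect_equal(u$delta_chosen, 0.5)
  expect_equal(u$q[2], 0.55)
  expect_equal(u$q[-2], rep(0.5, 4))  # non-presented stimuli unchanged
  expect_true(is.na(u$delta_unchosen))

  p3 <- agent_params("M3", alpha_con = 0.1, alpha_dis = 0.3, beta = 5)
  u3 <- update_values("M3", rep(0.5, 5), chosen = 1, unchosen = 5,
                      reward = 1, params = p3)
  expect_equal(u3$delta_unchosen, -0.5)
  expect_equal(u3$q[5], 0.45)
  # punishment selects the disconfirmatory rate, for both stimuli
  u3n <- update_values("M3", rep(0.5, 5), chosen = 1, unchosen = 5,
                       reward = 0, params = p3)
  expect_equal(u3n$q[1], 0.5 + 0.3 * (-0.5))
  expect_equal(u3n$q[5], 0.5 + 0.3 * 0.5)
})

test_that("values stay in [0, 1] under arbitrary update sequences", {
  set.seed(31)
  for (rep in 1:20) {
    p <- agent_params("M3", alpha_con = runif(1), alpha_dis = runif(1),
                      beta = 5)
    q <- runif(5)
    for (t in 1:50) {
      pair <- sample(5, 2)
      u <- update_values("M3", q, pair[1], pair[2], rbinom(1, 1, .5), p)
      q <- u$q
      expect_true(all(q >= 0 & q <= 1))
    }
  }
})

test_that("M2 with equal rates reproduces M1 trajectories exactly", {
  d <- generate_task_design(seed = 8, n_blocks = 1, trials_per_block = 100)
  s <- simulate_agent(d, agent_params("M2", alpha_con = .25,
                                      alpha_dis = .25, beta = 4), seed = 9)
  nll1 <- negative_log_likelihood("M1", c(0.25, 4), s)
  nll2 <- negative_log_likelihood("M2", c(0.25, 0.25, 4), s)
  expect_equal(nll1, nll2, tolerance = 1e-12)
})

test_that("softmax probability is symmetric, stable, and degenerate at beta 0", {
  expect_equal(choice_probability(0.7, 0.7, 10), 0.5)
  expect_equal(choice_probability(0.9, 0.1, 0), 0.5)
  p <- choice_probability(1, 0, 100)
  expect_lt(abs(p - 1 / (1 + exp(-100))), 1e-15)
  expect_true(is.finite(p))
})

test_that("negative log-likelihood matches a straight-loop oracle", {
  d <- generate_task_design(seed = 10)
  s <- simulate_agent(d, agent_params("M3", alpha_con = .3,
                                      alpha_dis = .1, beta = 5), seed = 11)
  for (m in c("M1", "M2", "M3")) {
    pars <- if (m == "M1") c(0.22, 3.7) else c(0.31, 0.07, 6.4)
    expect_equal(negative_log_likelihood(m, pars, s),
                 oracle_nll(m, pars, s), tolerance = 1e-10)
  }
  # alpha = 0: every choice probability is 0.5
  expect_equal(negative_log_likelihood("M1", c(0, 50), s),
               nrow(s) * log(2), tolerance = 1e-10)
  one <- make_session(1, 2, 1)
  expect_equal(negative_log_likelihood("M1", c(0.1, 0), one), log(2),
               tolerance = 1e-4)
})

test_that("BIC follows k log n + 2 nll and is monotone in nll", {
  expect_equal(bic(0, 2, 1), 0)
  expect_equal(bic(100, 3, 300), 3 * log(300) + 200)
  expect_equal(round(bic(100, 3, 300), 2), 217.11)
  expect_lt(bic(99, 3, 300), bic(100, 3, 300))
})

test_that("fitting is seed-deterministic and never worse than any start", {
  d <- generate_task_design(seed = 12, n_blocks = 2, trials_per_block = 100)
  s <- simulate_agent(d, agent_params("M3", alpha_con = .3,
                                      alpha_dis = .1, beta = 5), seed = 13)
  f1 <- fit_rl_model("M3", s, n_starts = 20, seed = 99)
  f2 <- fit_rl_model("M3", s, n_starts = 20, seed = 99)
  expect_identical(f1$par, f2$par)
  expect_equal(f1$neg_ll, min(f1$start_neg_ll, na.rm = TRUE))
  expect_true(all(f1$par >= 0))
  expect_lte(f1$par[["alpha_con"]], 1)
  expect_lte(f1$par[["beta"]], 100)
})

test_that("likelihood nesting: M2 fits at least as well as M1, M3's PEs match", {
  d <- generate_task_design(seed = 14, n_blocks = 2, trials_per_block = 100)
  s <- simulate_agent(d, agent_params("M3", alpha_con = .35,
                                      alpha_dis = .05, beta = 6), seed = 15)
  f1 <- fit_rl_model("M1", s, n_starts = 20, seed = 1)
  f2 <- fit_rl_model("M2", s, n_starts = 20, seed = 1)
  expect_lte(f2$neg_ll, f1$neg_ll + 1e-3)

  f3 <- fit_rl_model("M3", s, n_starts = 20, seed = 1)
  pes <- extract_pes(f3, s)
  # oracle trajectory at the fitted optimum
  ref <- oracle_nll("M3", f3$par, s)
  expect_equal(f3$neg_ll, ref, tolerance = 1e-10)
  expect_equal(pes$pe_abs, abs(pes$pe))
  # first-ever trial with reward: |PE| = 0.5 from initial values
  first_rewarded <- which(s$reward == 1)[1]
  if (first_rewarded == 1) expect_equal(pes$pe_abs[1], 0.5)
})

test_that("a flat-learning session flags beta as unidentified", {
  d <- generate_task_design(seed = 16, n_blocks = 1, trials_per_block = 100)
  s <- simulate_agent(d, agent_params("M1", alpha = 0, beta = 0), seed = 17)
  f <- fit_rl_model("M1", s, n_starts = 20, seed = 2)
  # the optimum can only undercut coin-flipping by exploiting noise
  expect_lte(f$neg_ll, nrow(s) * log(2) + 1e-6)
  expect_gt(f$neg_ll, nrow(s) * log(2) - 5)
  # flag fires exactly when the fitted learning rate collapses to 0
  expect_equal(f$beta_unidentified, unname(f$par["alpha"] < 1e-6))
})

test_that("late-block values rank the 80% stimulus above the 20% stimulus", {
  d <- generate_task_design(seed = 18)
  s <- simulate_agent(d, agent_params("M3", alpha_con = .3,
                                      alpha_dis = .1, beta = 5), seed = 19)
  f <- fit_rl_model("M3", s, n_starts = 20, seed = 3)
  late <- s$block == 3
  expect_gt(mean(f$trajectories$Q5[late]), mean(f$trajectories$Q2[late]))
})

test_that("model comparison averages fits and breaks ties toward fewer parameters", {
  # a single trial from equal initial values is uninformative for every
  # model and parameter vector: p = 0.5, so all fits tie exactly
  s <- make_session(1, 2, 1)
  cmp <- compare_models(list(s), n_starts = 5, seed = 4)
  expect_equal(cmp$table$mean_neg_ll, rep(log(2), 3), tolerance = 1e-8)
  expect_equal(cmp$table$mean_bic, rep(2 * log(2), 3), tolerance = 1e-8)
  expect_equal(cmp$selected, "M1")  # fewest parameters wins the tie
  expect_equal(tidy(cmp), cmp$table)
})

test_that("rl_fit tidiers expose parameters and fit statistics", {
  d <- generate_task_design(seed = 22, n_blocks = 1, trials_per_block = 50)
  s <- simulate_agent(d, agent_params("M2", alpha_con = .3,
                                      alpha_dis = .1, beta = 5), seed = 23)
  f <- fit_rl_model("M2", s, n_starts = 5, seed = 5)
  td <- tidy(f)
  expect_equal(td$term, c("alpha_con", "alpha_dis", "beta"))
  gl <- glance(f)
  expect_equal(gl$bic, bic(f$neg_ll, 3, 50))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$model, "M2")
  expect_equal(back$neg_ll, f$neg_ll, tolerance = 1e-12)
})
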