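# Independent reference implementations used as oracles. These are
# deliberately plain straight-loop R code, written against the model
# definitions rather than against the package internals.

# forward-pass negative log-likelihood, straight loop
oracle_nll <- function(model, params, session) {
  if (model == "M1") {
    a_con <- params[1]; a_dis <- params[1]; beta <- params[2]
  } else {
    a_con <- params[1]; a_dis <- params[2]; beta <- params[3]
  }
  Q <- rep(0.5, 5)
  nll <- 0
  for (t in seq_len(nrow(session))) {
    c_t <- session$chosen[t]; u_t <- session$unchosen[t]
    r_t <- session$reward[t]
    p <- exp(Q[c_t] * beta) / (exp(Q[c_t] * beta) + exp(Q[u_t] * beta))
    nll <- nll - log(max(p, 1e-12))
    a <- if (model == "M1") a_con else if (r_t == 1) a_con else a_dis
    Q[c_t] <- Q[c_t] + a * (r_t - Q[c_t])
    if (model == "M3") Q[u_t] <- Q[u_t] + a * ((1 - r_t) - Q[u_t])
  }
  nll
}

# straight-loop forward simulation consuming the RNG exactly as the
# package does (one uniform for the choice, one for the feedback)
oracle_simulate <- function(design, a_con, a_dis, beta, seed,
                            counterfactual = TRUE) {
  probs <- attr(design, "probabilities")
  set.seed(seed)
  Q <- rep(0.5, 5)
  n <- nrow(design)
  chosen <- reward <- integer(n)
  for (t in seq_len(n)) {
    l <- design$stim_left[t]; r <- design$stim_right[t]
    p_left <- exp(Q[l] * beta) / (exp(Q[l] * beta) + exp(Q[r] * beta))
    pick_left <- runif(1) < p_left
    c_t <- if (pick_left) l else r
    u_t <- if (pick_left) r else l
    r_t <- as.integer(runif(1) < probs[c_t])
    a <- if (r_t == 1) a_con else a_dis
    Q[c_t] <- Q[c_t] + a * (r_t - Q[c_t])
    if (counterfactual) Q[u_t] <- Q[u_t] + a * ((1 - r_t) - Q[u_t])
    chosen[t] <- c_t; reward[t] <- r_t
  }
  list(chosen = chosen, reward = reward, Q = Q)
}

# hand-rolled session constructor for tiny fixed scenarios
make_session <- function(chosen, unchosen, reward,
                         probabilities = c(s1 = 0, s2 = .2, s3 = .4,
                                           s4 = .6, s5 = .8),
                         timing = "immediate", participant = "p01") {
  n <- length(chosen)
  out <- tibble::tibble(
    participant = participant, timing = timing,
    block = rep(1L, n), trial = seq_len(n),
    stim_left = chosen, stim_right = unchosen,
    chosen = chosen, unchosen = unchosen, reward = reward)
  out <- tibble::new_tibble(out, class = "session_data")
  attr(out, "probabilities") <- probabilities
  out
}

# textbook two-way within-subject ANOVA sums-of-squares decomposition
oracle_rm_anova <- function(df, dv = "accuracy") {
  y <- df[[dv]]
  A <- factor(df$timing); B <- factor(df$block); S <- factor(df$participant)
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  gm <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mS <- tapply(y, S, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, S), mean)
  mBS <- tapply(y, list(B, S), mean)
  ssA <- b * n * sum((mA - gm)^2)
  ssB <- a * n * sum((mB - gm)^2)
  ssAB <- n * sum((mAB - outer(mA - gm, mB - gm, `+`) - gm)^2)
  ssAS <- b * sum((mAS - outer(mA - gm, mS - gm, `+`) - gm)^2)
  ssBS <- a * sum((mBS - outer(mB - gm, mS - gm, `+`) - gm)^2)
  ssABS <- 0
  for (i in seq_len(a)) for (j in seq_len(b)) for (k in seq_len(n)) {
    fit <- gm + (mA[i] - gm) + (mB[j] - gm) + (mS[k] - gm) +
      (mAB[i, j] - mA[i] - mB[j] + gm) +
      (mAS[i, k] - mA[i] - mS[k] + gm) +
      (mBS[j, k] - mB[j] - mS[k] + gm)
    obs <- y[A == levels(A)[i] & B == levels(B)[j] & S == levels(S)[k]]
    ssABS <- ssABS + (obs - fit)^2
  }
  list(
    F_A = (ssA / (a - 1)) / (ssAS / ((a - 1) * (n - 1))),
    F_B = (ssB / (b - 1)) / (ssBS / ((b - 1) * (n - 1))),
    F_AB = (ssAB / ((a - 1) * (b - 1))) /
      (ssABS / ((a - 1) * (b - 1) * (n - 1))),
    df = c(A = a - 1, AS = (a - 1) * (n - 1),
           B = b - 1, BS = (b - 1) * (n - 1),
           AB = (a - 1) * (b - 1), ABS = (a - 1) * (b - 1) * (n - 1)),
    ss = c(A = ssA, AS = ssAS, B = ssB, BS = ssBS, AB = ssAB,
           ABS = ssABS)
  )
}

# exact signed-rank p by enumerating all 2^n sign assignments
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  V_all <- as.matrix(signs) %*% r
  mean(abs(V_all - mu) >= abs(V_obs - mu) - 1e-12)
}

# quick cohort of fitted-PE trial tables for generator/LMM tests
make_trial_table <- function(n_participants = 4, trials_per_block = 50,
                             n_blocks = 2, seed = 1) {
  ag <- agent_params("M3", alpha_con = 0.3, alpha_dis = 0.1, beta = 5)
  purrr::map_dfr(seq_len(n_participants), function(i) {
    purrr::map_dfr(c("immediate", "delayed"), function(tm) {
      off <- (tm == "delayed")
      d <- generate_task_design(seed = seed + 10L * i + off,
                                n_blocks = n_blocks,
                                trials_per_block = trials_per_block,
                                timing = tm)
      s <- simulate_agent(d, ag, seed = seed + 100L * i + off,
                          participant = sprintf("p%02d", i))
      f <- fit_rl_model("M3", s, n_starts = 5, seed = seed + i)
      extract_pes(f, s)
    })
  })
}
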