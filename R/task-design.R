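#' Generate a probabilistic selection task design
#'
#' Builds the trial list for the two-alternative probabilistic learning
#' task: five stimuli with distinct reward probabilities, all ten
#' unordered stimulus pairs, each pair shown equally often per block
#' with left/right screen positions counterbalanced, and trial order
#' randomised within block.
#'
#' @param seed Integer seed controlling trial-order and side
#'   randomisation.
#' @param n_blocks Number of learning blocks (default 3).
#' @param trials_per_block Trials per block; must be divisible by the
#'   number of stimulus pairs (default 100, i.e. ten presentations of
#'   each of the ten pairs).
#' @param probabilities Named or unnamed vector of 5 distinct reward
#'   probabilities in `[0, 1]` (default `c(0, .2, .4, .6, .8)`).
#' @param timing Timing-condition label carried through the pipeline,
#'   `"immediate"` or `"delayed"`. Feedback delay has no computational
#'   consequence in simulation; the label only tags the session.
#'
#' @return A tibble of class `task_design` with columns `block`,
#'   `trial`, `stim_left`, `stim_right`, `timing`, and attributes
#'   `probabilities` (named vector, stimuli `"s1"`..`"s5"`) and `seed`.
#' @examples
#' d <- generate_task_design(seed = 1)
#' nrow(d)                       # 300
#' table(pmin(d$stim_left, d$stim_right), pmax(d$stim_left, d$stim_right))
#' @export
generate_task_design <- function(seed = 1L, n_blocks = 3L,
                                 trials_per_block = 100L,
                                 probabilities = c(0, .2, .4, .6, .8),
                                 timing = c("immediate", "delayed")) {
  timing <- match.arg(timing)
  n_stim <- length(probabilities)
  if (n_stim != 5L || anyDuplicated(probabilities)) {
    stop("`probabilities` must contain 5 distinct reward probabilities",
         call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("`probabilities` must lie in [0, 1]", call. = FALSE)
  }
  pairs <- t(utils::combn(n_stim, 2L))
  n_pairs <- nrow(pairs)
  if (n_blocks < 1L || trials_per_block < n_pairs ||
      trials_per_block %% n_pairs != 0L) {
    stop("`trials_per_block` (", trials_per_block,
         ") must be a positive multiple of the number of stimulus pairs (",
         n_pairs, ")", call. = FALSE)
  }
  reps <- trials_per_block %/% n_pairs
  probs <- setNames(as.numeric(probabilities), paste0("s", seq_len(n_stim)))

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  blocks <- purrr::map(seq_len(n_blocks), function(b) {
    # reps presentations of each pair; first-listed stimulus shown left
    # in half of them (the extra one randomised when reps is odd)
    side_first_left <- purrr::map(seq_len(n_pairs), function(i) {
      sides <- rep(c(TRUE, FALSE), length.out = reps)
      sample(sides)
    })
    idx <- rep(seq_len(n_pairs), each = reps)
    left_first <- unlist(side_first_left)
    ord <- sample(length(idx))
    idx <- idx[ord]; left_first <- left_first[ord]
    tibble::tibble(
      block = b,
      trial = seq_along(idx),
      stim_left = ifelse(left_first, pairs[idx, 1L], pairs[idx, 2L]),
      stim_right = ifelse(left_first, pairs[idx, 2L], pairs[idx, 1L])
    )
  })
  out <- dplyr::bind_rows(blocks)
  out$timing <- timing
  out <- tibble::new_tibble(out, class = "task_design")
  attr(out, "probabilities") <- probs
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Agent parameters for forward simulation
#'
#' @param model One of `"M1"` (single learning rate), `"M2"`
#'   (valence-specific learning rates), `"M3"` (valence-specific rates
#'   plus counterfactual updating of the unchosen stimulus).
#' @param alpha Learning rate for M1, in `[0, 1]`.
#' @param alpha_con,alpha_dis Learning rates after confirmatory
#'   (positive) and disconfirmatory (negative) feedback for M2/M3.
#' @param beta Softmax exploration (inverse-temperature) parameter in
#'   `[0, 100]`.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(model = c("M3", "M1", "M2"), alpha = NULL,
                         alpha_con = NULL, alpha_dis = NULL, beta = 5) {
  model <- match.arg(model)
  if (model == "M1") {
    if (is.null(alpha)) stop("M1 requires `alpha`", call. = FALSE)
    if (!is.null(alpha_con) || !is.null(alpha_dis)) {
      stop("M1 carries exactly one learning rate", call. = FALSE)
    }
    alpha_con <- alpha_dis <- alpha
  } else {
    if (is.null(alpha_con) || is.null(alpha_dis)) {
      stop(model, " requires `alpha_con` and `alpha_dis`", call. = FALSE)
    }
  }
  rates <- c(alpha_con, alpha_dis)
  if (any(rates < 0 | rates > 1)) {
    stop("learning rates must lie in [0, 1]", call. = FALSE)
  }
  if (beta < 0 || beta > 100) stop("`beta` must lie in [0, 100]", call. = FALSE)
  structure(list(model = model, alpha_con = alpha_con,
                 alpha_dis = alpha_dis, beta = beta),
            class = "agent_params")
}

#' Simulate an agent performing the learning task
#'
#' Plays a [generate_task_design()] trial list forward under one of the
#' three Q-learning models: on every trial the agent chooses between the
#' two displayed stimuli with softmax probabilities over their current
#' values, receives binary feedback according to the chosen stimulus'
#' reward probability, and updates values with the model's rule
#' (initial values 0.5 for all five stimuli).
#'
#' @param design A `task_design`.
#' @param agent An [agent_params()] object.
#' @param seed Integer seed for choices and feedback.
#' @param reward_mode `"bernoulli"` draws feedback independently per
#'   choice; `"exact_proportion"` pre-schedules, per stimulus, reward
#'   sequences whose realised proportion matches the stimulus' reward
#'   probability as closely as choice counts allow (urn without
#'   replacement in units of 1/p granularity).
#' @param participant Participant identifier carried into the session.
#'
#' @return A tibble of class `session_data` with columns `participant`,
#'   `timing`, `block`, `trial`, `stim_left`, `stim_right`, `chosen`,
#'   `unchosen`, `reward`, and the design's `probabilities` attribute.
#' @export
simulate_agent <- function(design, agent, seed = 1L,
                           reward_mode = c("bernoulli", "exact_proportion"),
                           participant = "p01") {
  reward_mode <- match.arg(reward_mode)
  stopifnot(inherits(agent, "agent_params"))
  probs <- attr(design, "probabilities")
  if (is.null(probs)) stop("`design` lacks a probabilities attribute",
                           call. = FALSE)
  n <- nrow(design)
  model_id <- match(agent$model, c("M1", "M2", "M3"))

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  # pre-scheduled reward urns for exact_proportion mode
  urns <- NULL
  if (reward_mode == "exact_proportion") {
    urns <- purrr::map(probs, function(p) {
      # blocks of 5 outcomes realise multiples of 0.2 exactly
      denom <- 5L
      k <- round(p * denom)
      base <- c(rep(1L, k), rep(0L, denom - k))
      unlist(purrr::map(seq_len(ceiling(n / denom)), ~ sample(base)))
    })
    drawn <- integer(length(probs))
  }

  Q <- rep(0.5, 5)
  chosen <- unchosen <- reward <- integer(n)
  for (t in seq_len(n)) {
    l <- design$stim_left[t]; r <- design$stim_right[t]
    p_left <- .softmax2(Q[l], Q[r], agent$beta)
    pick_left <- runif(1) < p_left
    c_t <- if (pick_left) l else r
    u_t <- if (pick_left) r else l
    if (reward_mode == "bernoulli") {
      r_t <- as.integer(runif(1) < probs[c_t])
    } else {
      drawn[c_t] <- drawn[c_t] + 1L
      r_t <- urns[[c_t]][drawn[c_t]]
    }
    a <- if (model_id == 1L) agent$alpha_con else
      if (r_t == 1L) agent$alpha_con else agent$alpha_dis
    Q[c_t] <- Q[c_t] + a * (r_t - Q[c_t])
    if (model_id == 3L) Q[u_t] <- Q[u_t] + a * ((1 - r_t) - Q[u_t])
    chosen[t] <- c_t; unchosen[t] <- u_t; reward[t] <- r_t
  }

  out <- tibble::tibble(
    participant = participant,
    timing = design$timing,
    block = design$block,
    trial = design$trial,
    stim_left = design$stim_left,
    stim_right = design$stim_right,
    chosen = chosen,
    unchosen = unchosen,
    reward = reward
  )
  out <- tibble::new_tibble(out, class = "session_data")
  attr(out, "probabilities") <- probs
  out
}

# softmax choice probability of option 1 over option 2
.softmax2 <- function(q1, q2, beta) {
  m <- max(q1, q2) * beta
  e1 <- exp(q1 * beta - m); e2 <- exp(q2 * beta - m)
  e1 / (e1 + e2)
}

#' Read or write session data as CSV
#'
#' Sessions round-trip through plain CSV with columns `participant`,
#' `timing`, `block`, `trial`, `stim_left`, `stim_right`, `chosen`,
#' `unchosen`, `reward` plus one `prob_s1`..`prob_s5` header block
#' recording the reward probabilities.
#'
#' @param session A `session_data` tibble.
#' @param path File path.
#' @return `read_session()` returns a `session_data` tibble;
#'   `write_session()` returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  probs <- attr(session, "probabilities")
  df <- as.data.frame(session)
  for (i in seq_along(probs)) df[[paste0("prob_s", i)]] <- probs[i]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prob_cols <- grep("^prob_s", names(df), value = TRUE)
  probs <- setNames(as.numeric(df[1, prob_cols]),
                    sub("^prob_", "", prob_cols))
  out <- tibble::as_tibble(df[setdiff(names(df), prob_cols)])
  out <- tibble::new_tibble(out, class = "session_data")
  attr(out, "probabilities") <- probs
  out
}
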