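#' Softmax choice probability
#'
#' Probability of choosing the option with value `q_chosen` over the
#' alternative with value `q_unchosen` under inverse temperature
#' `beta`: `exp(q_c * beta) / (exp(q_c * beta) + exp(q_u * beta))`,
#' evaluated in max-subtracted form so it is stable for `beta` up to
#' the fitting bound of 100.
#'
#' @param q_chosen,q_unchosen Stimulus values.
#' @param beta Exploration parameter, `>= 0`.
#' @return Choice probability in `(0, 1)`.
#' @examples
#' choice_probability(0.8, 0.2, 5)
#' choice_probability(1, 0, 100)   # ~1, no overflow
#' @export
choice_probability <- function(q_chosen, q_unchosen, beta) {
  if (any(beta < 0)) stop("`beta` must be non-negative", call. = FALSE)
  .softmax2(q_chosen, q_unchosen, beta)
}

#' Single-trial value update
#'
#' Applies one trial's Rescorla-Wagner update. The chosen stimulus'
#' prediction error is `delta_c = r - Q_c`; its value moves by
#' `alpha * delta_c`, where `alpha` is the single rate (M1) or the
#' valence-selected rate (`alpha_con` after reward, `alpha_dis` after
#' punishment; M2/M3). M3 additionally updates the unchosen stimulus
#' with the counterfactual error `delta_u = (1 - r) - Q_u` using the
#' same valence-selected rate. Stimuli not shown are untouched.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param q Numeric vector of 5 stimulus values in `[0, 1]`.
#' @param chosen,unchosen Stimulus indices (1-5).
#' @param reward 0 or 1.
#' @param params An [agent_params()] object (or list with `alpha_con`,
#'   `alpha_dis`).
#' @return List with `q` (updated values), `delta_chosen`, and
#'   `delta_unchosen` (`NA` unless M3).
#' @examples
#' update_values("M1", rep(0.5, 5), chosen = 1, unchosen = 2, reward = 1,
#'               params = agent_params("M1", alpha = 0.1, beta = 5))
#' @export
update_values <- function(model, q, chosen, unchosen, reward, params) {
  if (length(q) != 5L || any(q < 0 | q > 1)) {
    stop("`q` must be 5 values in [0, 1]", call. = FALSE)
  }
  if (!reward %in% c(0, 1)) stop("`reward` must be 0 or 1", call. = FALSE)
  if (chosen == unchosen) stop("chosen and unchosen must differ", call. = FALSE)
  delta_c <- reward - q[chosen]
  a <- if (model == "M1") params$alpha_con else
    if (reward == 1) params$alpha_con else params$alpha_dis
  q[chosen] <- q[chosen] + a * delta_c
  delta_u <- NA_real_
  if (model == "M3") {
    delta_u <- (1 - reward) - q[unchosen]
    q[unchosen] <- q[unchosen] + a * delta_u
  }
  list(q = q, delta_chosen = delta_c, delta_unchosen = delta_u)
}

#' Negative log-likelihood of a session under a model
#'
#' Propagates values forward from 0.5 and sums `-log p` of the observed
#' choices under the softmax rule. Choice probabilities are floored at
#' 1e-12 inside the log so the result is always finite.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param params Numeric: `c(alpha, beta)` for M1, `c(alpha_con,
#'   alpha_dis, beta)` for M2/M3.
#' @param session A `session_data` tibble.
#' @return The negative summed log-likelihood (scalar).
#' @export
negative_log_likelihood <- function(model, params, session) {
  if (nrow(session) == 0L) stop("`session` is empty", call. = FALSE)
  model_id <- match(model, c("M1", "M2", "M3"))
  if (is.na(model_id)) stop("unknown model ", model, call. = FALSE)
  p <- .expand_params(model_id, params)
  .rl_nll_cpp(model_id, as.integer(session$chosen),
              as.integer(session$unchosen), as.integer(session$reward),
              p[1], p[2], p[3])
}

.expand_params <- function(model_id, params) {
  if (model_id == 1L) {
    stopifnot(length(params) == 2L)
    c(params[1], params[1], params[2])
  } else {
    stopifnot(length(params) == 3L)
    params
  }
}

#' Fit a reinforcement-learning model to one session
#'
#' Maximum-likelihood estimation by bounded quasi-Newton optimisation
#' (`optim(method = "L-BFGS-B")`) restarted from `n_starts` random
#' start vectors; the best start is returned. Start values for all
#' free parameters are drawn uniformly on `[0, 1]` by default (the
#' exploration parameter included, despite its `[0, 100]` bound);
#' `beta_start_max = 100` widens the beta starts instead. Learning
#' rates are bounded in `[0, 1]` and beta in `[0, 100]`.
#'
#' If the fitted learning rate(s) are numerically zero the likelihood
#' is flat in beta and `beta_unidentified` is flagged.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param session A `session_data` tibble.
#' @param n_starts Number of random restarts (default 50).
#' @param seed Integer seed making the restarts reproducible.
#' @param beta_start_max Upper end of the uniform start distribution
#'   for beta (default 1).
#' @return An object of class `rl_fit`: list with `model`, `par`
#'   (named estimates), `neg_ll`, `bic`, `n_trials`, `start_neg_ll`
#'   (per-start minima), `beta_unidentified`, `trajectories` (tibble
#'   with per-trial `Q1`..`Q5` before update, `p_chosen`,
#'   `delta_chosen`, `delta_unchosen`), `participant`, `timing`.
#' @export
fit_rl_model <- function(model, session, n_starts = 50L, seed = 1L,
                         beta_start_max = 1) {
  if (nrow(session) == 0L) stop("`session` is empty", call. = FALSE)
  model_id <- match(model, c("M1", "M2", "M3"))
  if (is.na(model_id)) stop("unknown model ", model, call. = FALSE)
  k <- if (model_id == 1L) 2L else 3L
  lower <- rep(0, k)
  upper <- c(rep(1, k - 1L), 100)
  ch <- as.integer(session$chosen); un <- as.integer(session$unchosen)
  rw <- as.integer(session$reward)

  obj <- function(par) {
    p <- .expand_params(model_id, par)
    .rl_nll_cpp(model_id, ch, un, rw, p[1], p[2], p[3])
  }

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  starts <- matrix(runif(n_starts * k), nrow = n_starts)
  starts[, k] <- starts[, k] * beta_start_max

  best <- NULL
  start_nll <- rep(NA_real_, n_starts)
  failures <- character(0)
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(factr = 1e9, maxit = 200L)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    start_nll[i] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("optimisation failed on all ", n_starts, " starts: ",
         paste(unique(failures), collapse = "; "), call. = FALSE)
  }

  par <- best$par
  names(par) <- if (model_id == 1L) c("alpha", "beta") else
    c("alpha_con", "alpha_dis", "beta")
  rates <- par[seq_len(k - 1L)]
  p_full <- .expand_params(model_id, par)
  traj <- .rl_traj_cpp(model_id, ch, un, rw, p_full[1], p_full[2], p_full[3])
  qmat <- traj$Q
  colnames(qmat) <- paste0("Q", 1:5)
  trajectories <- dplyr::bind_cols(
    tibble::as_tibble(qmat),
    tibble::tibble(p_chosen = traj$p_chosen,
                   delta_chosen = traj$delta_chosen,
                   delta_unchosen = traj$delta_unchosen)
  )
  structure(list(
    model = model,
    par = par,
    neg_ll = best$value,
    bic = bic(best$value, k, nrow(session)),
    n_trials = nrow(session),
    n_params = k,
    start_neg_ll = start_nll,
    beta_unidentified = all(rates < 1e-6),
    trajectories = trajectories,
    participant = session$participant[1],
    timing = session$timing[1]
  ), class = "rl_fit")
}

#' Bayesian information criterion
#'
#' `BIC = k * log(n) + 2 * (-LL)`, penalising the `k` free parameters
#' by the log of the number of fitted trials. Lower is better.
#'
#' @param neg_ll Negative log-likelihood at the optimum.
#' @param k Number of free parameters (`>= 1`).
#' @param n Number of trials (`>= 1`).
#' @return The BIC (scalar).
#' @examples
#' bic(100, 3, 300)  # 3 * log(300) + 200
#' @export
bic <- function(neg_ll, k, n) {
  stopifnot(k >= 1, n >= 1)
  k * log(n) + 2 * neg_ll
}

#' Fit and compare the three learning models across sessions
#'
#' Fits M1 (single learning rate), M2 (valence-specific rates) and M3
#' (valence-specific rates plus counterfactual updating) to every
#' session, then aggregates negative log-likelihood and BIC as means
#' across sessions. The selected model has the lowest mean BIC; exact
#' ties go to the model with fewer parameters.
#'
#' @param sessions A list of `session_data` tibbles (e.g. one per
#'   participant and timing condition).
#' @param n_starts,seed Passed to [fit_rl_model()]; each session/model
#'   pair gets a distinct deterministic seed derived from `seed`.
#' @return A list of class `model_comparison`: `table` (tibble with
#'   `model`, `k`, `mean_neg_ll`, `mean_bic`, `n_sessions`),
#'   `selected`, `fits` (nested list `fits[[model]][[session]]`), and
#'   `errors` (per-session fitting failures, if any).
#' @export
compare_models <- function(sessions, n_starts = 50L, seed = 1L) {
  stopifnot(length(sessions) >= 1L)
  models <- c("M1", "M2", "M3")
  fits <- list(); errors <- list()
  for (m in seq_along(models)) {
    fits[[models[m]]] <- purrr::imap(sessions, function(s, i) {
      idx <- if (is.character(i)) match(i, names(sessions)) else as.integer(i)
      tryCatch(
        fit_rl_model(models[m], s, n_starts = n_starts,
                     seed = seed + 1000L * m + idx),
        error = function(e) {
          errors[[paste(models[m], i)]] <<- conditionMessage(e)
          NULL
        }
      )
    })
  }
  tab <- purrr::map_dfr(models, function(m) {
    ok <- purrr::compact(fits[[m]])
    tibble::tibble(
      model = m,
      k = if (m == "M1") 2L else 3L,
      mean_neg_ll = mean(purrr::map_dbl(ok, "neg_ll")),
      mean_bic = mean(purrr::map_dbl(ok, "bic")),
      n_sessions = length(ok)
    )
  })
  # lowest mean BIC wins; ties broken toward fewer parameters
  ord <- order(tab$mean_bic, tab$k)
  structure(list(table = tab, selected = tab$model[ord[1]],
                 fits = fits, errors = errors),
            class = "model_comparison")
}

#' Extract per-trial prediction errors from a fit
#'
#' Returns the signed chosen-stimulus prediction error and its
#' absolute value (unsigned PE, the surprise measure used in the
#' single-trial ERP analyses) aligned with the session's trials.
#'
#' @param fit An `rl_fit`.
#' @param session The session the model was fitted to.
#' @return The session tibble with added columns `p_chosen`, `pe`
#'   (signed) and `pe_abs` (unsigned).
#' @export
extract_pes <- function(fit, session) {
  stopifnot(inherits(fit, "rl_fit"), nrow(session) == fit$n_trials)
  dplyr::mutate(session,
                p_chosen = fit$trajectories$p_chosen,
                pe = fit$trajectories$delta_chosen,
                pe_abs = abs(fit$trajectories$delta_chosen))
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit> model", x$model, "on", x$n_trials, "trials\n")
  cat("  ", paste(names(x$par), signif(x$par, 4), sep = " = ",
                  collapse = ", "), "\n")
  cat("  -LL =", format(x$neg_ll, digits = 6),
      " BIC =", format(x$bic, digits = 6), "\n")
  if (isTRUE(x$beta_unidentified)) {
    cat("  note: learning rate ~ 0; beta is unidentified\n")
  }
  invisible(x)
}

#' @describeIn fit_rl_model Tidy the fitted parameters (one row per
#'   parameter).
#' @param x An `rl_fit`.
#' @param ... Unused.
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @describeIn fit_rl_model One-row model summary (`neg_ll`, `bic`,
#'   `n_trials`, `beta_unidentified`).
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(model = x$model, neg_ll = x$neg_ll, bic = x$bic,
                 n_trials = x$n_trials, n_params = x$n_params,
                 beta_unidentified = x$beta_unidentified)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> selected:", x$selected, "\n")
  print(x$table)
  invisible(x)
}

#' @describeIn compare_models Tidy the comparison table.
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @export
tidy.model_comparison <- function(x, ...) x$table

#' Serialize a fit to JSON
#'
#' Writes parameters, fit statistics and (optionally) latent
#' trajectories to a JSON file.
#'
#' @param fit An `rl_fit`.
#' @param path Output path.
#' @param trajectories Include per-trial latent trajectories?
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, trajectories = FALSE) {
  obj <- list(model = fit$model, par = as.list(fit$par),
              neg_ll = fit$neg_ll, bic = fit$bic,
              n_trials = fit$n_trials,
              beta_unidentified = fit$beta_unidentified,
              participant = fit$participant, timing = fit$timing)
  if (trajectories) obj$trajectories <- as.list(fit$trajectories)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
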