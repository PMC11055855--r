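#' Score choice accuracy
#'
#' A choice is correct when the stimulus with the higher reward
#' probability of the displayed pair was selected. Accuracy is
#' aggregated per participant, timing condition and learning block.
#'
#' @param sessions A `session_data` tibble or a list of them.
#' @return A tibble (`accuracy_table`): `participant`, `timing`,
#'   `block`, `n_trials`, `n_correct`, `accuracy`.
#' @export
score_accuracy <- function(sessions) {
  if (inherits(sessions, "data.frame")) sessions <- list(sessions)
  purrr::map_dfr(sessions, function(s) {
    probs <- attr(s, "probabilities")
    if (is.null(probs)) stop("session lacks a probabilities attribute",
                             call. = FALSE)
    s$correct <- probs[s$chosen] > probs[s$unchosen]
    dplyr::summarise(
      dplyr::group_by(s, .data$participant, .data$timing, .data$block),
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      accuracy = mean(.data$correct),
      .groups = "drop")
  })
}

#' Per-trial correctness of a session
#'
#' @param session A `session_data` tibble.
#' @return The session with a logical `correct` column.
#' @export
score_trials <- function(session) {
  probs <- attr(session, "probabilities")
  if (is.null(probs)) stop("session lacks a probabilities attribute",
                           call. = FALSE)
  dplyr::mutate(session, correct = probs[.data$chosen] >
                  probs[.data$unchosen])
}

#' Repeated-measures ANOVA on accuracy
#'
#' Two-way within-subject ANOVA with factors Feedback Timing
#' (2 levels) and Learning Block (3 levels). Sphericity of the
#' block-related effects is assessed with Mauchly's test and
#' Greenhouse-Geisser epsilon-corrected degrees of freedom and
#' p-values are reported alongside the uncorrected ones; a two-level
#' factor has epsilon = 1 by construction. Partial eta squared is
#' computed from the effect and error sums of squares.
#'
#' @param accuracy An accuracy table from [score_accuracy()] with
#'   every participant observed in every timing x block cell.
#' @param dv Column used as dependent variable (default `accuracy`;
#'   `n_correct` mirrors the count-based analysis).
#' @return A tibble: `effect`, `df1`, `df2`, `statistic`, `p.value`,
#'   `gg_epsilon`, `df1_gg`, `df2_gg`, `p.value_gg`, `pes` (partial
#'   eta squared).
#' @export
rm_anova <- function(accuracy, dv = "accuracy") {
  need <- c("participant", "timing", "block", dv)
  stopifnot(all(need %in% names(accuracy)))
  if (length(unique(accuracy$timing)) < 2L ||
      length(unique(accuracy$block)) < 2L) {
    stop("rm_anova needs at least 2 timing conditions and 2 blocks",
         call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(accuracy, dplyr::all_of(c("participant", "timing",
                                            "block", dv))),
    names_from = c("timing", "block"), values_from = dplyr::all_of(dv),
    names_sort = TRUE)
  if (anyNA(wide)) stop("missing timing x block cells", call. = FALSE)
  timings <- sort(unique(accuracy$timing))
  blocks <- sort(unique(accuracy$block))
  cells <- tidyr::expand_grid(timing = timings, block = blocks)
  cols <- paste(cells$timing, cells$block, sep = "_")
  Y <- as.matrix(wide[, cols])
  idata <- data.frame(timing = factor(cells$timing),
                      block = factor(cells$block))
  mod <- stats::lm(Y ~ 1)
  av <- car::Anova(mod, idata = idata, idesign = ~ timing * block,
                   type = 3)
  s <- summary(av, multivariate = FALSE)
  ut <- s$univariate.tests
  adj <- s$pval.adjustments
  effects <- c("timing", "block", "timing:block")
  purrr::map_dfr(effects, function(ef) {
    row <- ut[ef, ]
    eps <- if (!is.null(adj) && ef %in% rownames(adj)) {
      adj[ef, "GG eps"]
    } else 1
    df1 <- row[["num Df"]]; df2 <- row[["den Df"]]
    Fv <- row[["F value"]]
    tibble::tibble(
      effect = ef, df1 = df1, df2 = df2, statistic = Fv,
      p.value = row[["Pr(>F)"]],
      gg_epsilon = eps, df1_gg = eps * df1, df2_gg = eps * df2,
      p.value_gg = pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
      pes = row[["Sum Sq"]] / (row[["Sum Sq"]] + row[["Error SS"]])
    )
  })
}

#' Exact binomial test against chance performance
#'
#' Tests whether a participant's number of correct choices is
#' significantly below a chance success probability of `p0` per
#' trial (one-sided exact binomial test).
#'
#' @param session A `session_data` tibble.
#' @param p0 Chance success probability (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `participant`, `timing`, `n_correct`,
#'   `n_trials`, `p.value`, `below_chance`.
#' @export
binomial_chance_test <- function(session, p0 = 0.5, alpha = 0.05) {
  s <- score_trials(session)
  x <- sum(s$correct); n <- nrow(s)
  p <- binom.test(x, n, p = p0, alternative = "less")$p.value
  tibble::tibble(participant = s$participant[1], timing = s$timing[1],
                 n_correct = x, n_trials = n, p.value = p,
                 below_chance = p < alpha)
}

#' Learning-rate table from fitted models
#'
#' @param fits List of `rl_fit` objects from a dual-learning-rate
#'   model (M2/M3), one per participant x timing condition.
#' @return Tibble: `participant`, `timing`, `alpha_con`, `alpha_dis`,
#'   `beta`.
#' @export
learning_rate_table <- function(fits) {
  purrr::map_dfr(fits, function(f) {
    stopifnot(inherits(f, "rl_fit"))
    if (!"alpha_con" %in% names(f$par)) {
      stop("learning-rate contrasts need a dual-learning-rate fit",
           call. = FALSE)
    }
    tibble::tibble(participant = f$participant, timing = f$timing,
                   alpha_con = f$par[["alpha_con"]],
                   alpha_dis = f$par[["alpha_dis"]],
                   beta = f$par[["beta"]])
  })
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences with the drop-zeros
#' convention. For 25 or fewer non-zero pairs without ties the exact
#' distribution is used; otherwise the normal approximation with
#' continuity correction. The standardised statistic `Z` (normal
#' approximation, tie-corrected) and the effect size r = Z/sqrt(N)
#' (N = non-zero pairs) are always reported.
#'
#' @param x,y Paired numeric vectors.
#' @param bonferroni_m Multiplicity for Bonferroni adjustment of the
#'   p-value (default 1 = none).
#' @return A one-row tibble: `n`, `n_nonzero`, `V`, `z`, `p.value`,
#'   `effect_r`, `method`, `degenerate` (all differences zero).
#' @export
wilcoxon_signed_rank <- function(x, y, bonferroni_m = 1) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d0 <- d[d != 0]
  n <- length(d0)
  if (n == 0L) {
    return(tibble::tibble(n = length(d), n_nonzero = 0L, V = NA_real_,
                          z = NA_real_, p.value = NA_real_,
                          effect_r = NA_real_, method = "degenerate",
                          degenerate = TRUE))
  }
  r <- rank(abs(d0))
  V <- sum(r[d0 > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  cc <- sign(V - mu) * 0.5
  z <- if (sig2 > 0) (V - mu - cc) / sqrt(sig2) else 0
  exact_ok <- n <= 25 && !any(duplicated(abs(d0)))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact_ok,
                       correct = TRUE)$p.value)
  method <- if (exact_ok) "exact" else "normal approximation"
  tibble::tibble(n = length(d), n_nonzero = n, V = V, z = z,
                 p.value = min(1, bonferroni_m * p),
                 effect_r = z / sqrt(n),
                 method = method, degenerate = FALSE)
}

#' Wilcoxon contrasts on estimated learning rates
#'
#' The three published contrasts on the dual learning rates:
#' * `feedback_type`: confirmatory vs disconfirmatory learning rate
#'   (per participant, averaged over timing conditions);
#' * `timing`: mean learning rate (average of the two rates) for
#'   immediate vs delayed feedback;
#' * `bias_by_timing`: the confirmation-bias difference
#'   `alpha_con - alpha_dis` compared between timing conditions.
#'
#' @param rates A [learning_rate_table()] tibble.
#' @param contrast One of `"feedback_type"`, `"timing"`,
#'   `"bias_by_timing"`.
#' @param bonferroni_m Bonferroni multiplicity (default 1).
#' @return A one-row tibble as from [wilcoxon_signed_rank()] plus a
#'   `contrast` column and the two condition medians.
#' @export
wilcoxon_learning_rates <- function(rates,
                                    contrast = c("feedback_type",
                                                 "timing",
                                                 "bias_by_timing"),
                                    bonferroni_m = 1) {
  contrast <- match.arg(contrast)
  if (contrast == "feedback_type") {
    per <- dplyr::summarise(dplyr::group_by(rates, .data$participant),
                            a = mean(.data$alpha_con),
                            b = mean(.data$alpha_dis), .groups = "drop")
  } else {
    wide <- tidyr::pivot_wider(
      dplyr::mutate(rates,
                    value = if (contrast == "timing") {
                      (.data$alpha_con + .data$alpha_dis) / 2
                    } else .data$alpha_con - .data$alpha_dis),
      id_cols = "participant", names_from = "timing",
      values_from = "value")
    if (!all(c("immediate", "delayed") %in% names(wide))) {
      stop("both timing conditions are required for contrast '",
           contrast, "'", call. = FALSE)
    }
    per <- tibble::tibble(participant = wide$participant,
                          a = wide$immediate, b = wide$delayed)
  }
  res <- wilcoxon_signed_rank(per$a, per$b, bonferroni_m = bonferroni_m)
  dplyr::bind_cols(tibble::tibble(contrast = contrast,
                                  median_a = median(per$a),
                                  median_b = median(per$b)), res)
}
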