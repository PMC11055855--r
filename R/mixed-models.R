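#' Effect-code predictors for single-trial mixed models
#'
#' Maps the two-level factors to -1/+1 with the package's fixed sign
#' map (negative feedback = +1, delayed = +1, parietal = +1) and
#' centres the unsigned PE on its grand mean over included trials
#' while preserving its range. The applied map and the PE centre are
#' recorded as attributes, so the coding round-trips.
#'
#' @param raw Long amplitude table with columns `amplitude_uv`,
#'   `participant`, `electrode`, `timing`, `pe_abs`, and either
#'   `reward` (0/1) or `valence` (`"negative"`/`"positive"`);
#'   optionally `cluster` for the frontality code.
#' @return A tibble of class `coded_table` with `amplitude`,
#'   `valence`, `timing`, `pe` (centred), optional `frontality`,
#'   `participant`, `electrode`; attributes `sign_map`, `pe_center`.
#' @export
encode_predictors <- function(raw) {
  need <- c("amplitude_uv", "participant", "electrode", "timing", "pe_abs")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  valence_raw <- if ("reward" %in% names(raw)) {
    ifelse(raw$reward == 1, "positive", "negative")
  } else if ("valence" %in% names(raw)) raw$valence else {
    stop("need a `reward` or `valence` column", call. = FALSE)
  }
  pe_center <- mean(raw$pe_abs)
  out <- tibble::tibble(
    amplitude = raw$amplitude_uv,
    valence = ifelse(valence_raw == "negative", 1, -1),
    timing = .code_timing(raw$timing),
    pe = raw$pe_abs - pe_center,
    participant = as.character(raw$participant),
    electrode = as.character(raw$electrode)
  )
  if ("cluster" %in% names(raw) && !all(is.na(raw$cluster))) {
    out$frontality <- .code_frontality(raw$cluster)
  }
  out <- tibble::new_tibble(out, class = "coded_table")
  attr(out, "sign_map") <- c(valence = "negative = +1",
                             timing = "delayed = +1",
                             frontality = "parietal = +1")
  attr(out, "pe_center") <- pe_center
  out
}

#' Decode effect-coded columns back to labels
#'
#' Inverse of [encode_predictors()] for the factor columns and the PE.
#'
#' @param coded A `coded_table`.
#' @return A tibble with `valence`, `timing`, optional `cluster`
#'   labels and `pe_abs` restored.
#' @export
decode_predictors <- function(coded) {
  out <- tibble::tibble(
    valence = ifelse(coded$valence > 0, "negative", "positive"),
    timing = ifelse(coded$timing > 0, "delayed", "immediate"),
    pe_abs = coded$pe + attr(coded, "pe_center")
  )
  if ("frontality" %in% names(coded)) {
    out$cluster <- ifelse(coded$frontality > 0, "parietal",
                          "frontocentral")
  }
  out
}

#' Fit a single-trial linear mixed model
#'
#' Gaussian LMM with crossed by-participant and by-electrode random
#' effects, estimated by REML (final inference) or ML (for
#' likelihood-ratio comparisons). Fixed-effect degrees of freedom use
#' the Satterthwaite approximation via \pkg{lmerTest}; if that fails,
#' residual degrees of freedom are used and the method is recorded. A
#' formula without random terms falls back to ordinary least squares.
#'
#' @param formula Model formula in \pkg{lme4} notation, e.g.
#'   `amplitude ~ valence * timing * pe + (valence * timing * pe |
#'   participant) + (1 | electrode)`.
#' @param data A `coded_table` (or any data frame with the variables).
#' @param reml Use REML (default `TRUE`).
#' @return An object of class `erp_lmm`: list with `fit`, `formula`,
#'   `reml`, `df_method`, `singular`, `convergence_messages`.
#' @export
fit_erp_lmm <- function(formula, data, reml = TRUE) {
  has_bars <- length(lme4::findbars(formula)) > 0
  msgs <- character(0)
  if (has_bars) {
    if (length(unique(data$participant)) < 2L &&
        grepl("participant", deparse1(formula))) {
      stop("mixed model requires >= 2 participants", call. = FALSE)
    }
    fit <- withCallingHandlers(
      lmerTest::lmer(formula, data = data, REML = reml,
                     control = lme4::lmerControl(calc.derivs = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    singular <- lme4::isSingular(fit)
    df_method <- "satterthwaite"
  } else {
    fit <- stats::lm(formula, data = data)
    singular <- FALSE
    df_method <- "residual"
  }
  structure(list(fit = fit, formula = formula, reml = reml,
                 df_method = df_method, singular = singular,
                 convergence_messages = msgs),
            class = "erp_lmm")
}

#' @export
print.erp_lmm <- function(x, ...) {
  cat("<erp_lmm> ", deparse1(x$formula), "\n",
      "  estimation: ", if (isTRUE(x$reml)) "REML" else "ML",
      ", df: ", x$df_method,
      if (x$singular) " (singular fit)" else "", "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_erp_lmm Fixed-effect table: `term`, `estimate`,
#'   `std.error`, `df`, `statistic`, `p.value`.
#' @param x An `erp_lmm`.
#' @param ... Unused.
#' @export
tidy.erp_lmm <- function(x, ...) {
  if (inherits(x$fit, "lmerModLmerTest") || inherits(x$fit, "lmerMod")) {
    co <- tryCatch(summary(x$fit)$coefficients, error = function(e) NULL)
    if (!is.null(co) && "df" %in% colnames(co)) {
      return(tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                            std.error = co[, "Std. Error"], df = co[, "df"],
                            statistic = co[, "t value"],
                            p.value = co[, "Pr(>|t|)"]))
    }
    # fallback: residual df
    co <- summary(x$fit)$coefficients
    df_res <- stats::nobs(x$fit) - nrow(co)
    tval <- co[, "t value"]
    return(tibble::tibble(term = rownames(co), estimate = co[, "Estimate"],
                          std.error = co[, "Std. Error"], df = df_res,
                          statistic = tval,
                          p.value = 2 * pt(-abs(tval), df_res)))
  }
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], df = x$fit$df.residual,
                 statistic = co[, 3], p.value = co[, 4])
}

#' @describeIn fit_erp_lmm One-row fit summary.
#' @export
glance.erp_lmm <- function(x, ...) {
  ll <- as.numeric(logLik(x$fit))
  tibble::tibble(logLik = ll,
                 sigma = stats::sigma(x$fit),
                 nobs = stats::nobs(x$fit),
                 reml = isTRUE(x$reml),
                 singular = x$singular,
                 df_method = x$df_method)
}

#' Random-effect standard deviations of a fit
#'
#' @param x An `erp_lmm` fitted with random effects.
#' @return Tibble with `group`, `term`, `sd`.
#' @export
ranef_sds <- function(x) {
  stopifnot(inherits(x, "erp_lmm"))
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(group = vc$grp, term = vc$var1, sd = vc$sdcor)[
    is.na(vc$var2), ]
}

# ---- parsimonious stepwise term selection ---------------------------

# canonical term label: components sorted so valence:pe == pe:valence
.canon_term <- function(term) {
  vapply(term, function(tt) {
    paste(sort(strsplit(tt, ":", fixed = TRUE)[[1]]), collapse = ":")
  }, character(1), USE.NAMES = FALSE)
}

# all sub-terms a term's marginality requires
.sub_terms <- function(term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  k <- length(parts)
  if (k == 1L) return(character(0))
  unlist(purrr::map(seq_len(k - 1L), function(m) {
    apply(utils::combn(parts, m), 2, function(x)
      paste(sort(x), collapse = ":"))
  }))
}

# assemble a fitting formula from selected fixed terms and random
# terms; random slopes use independent (diagonal) variance components
.build_formula <- function(response, fixed, random) {
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (nrow(random)) {
    groups <- unique(random$group)
    rterms <- vapply(groups, function(g) {
      tt <- random$term[random$group == g]
      has_int <- "(Intercept)" %in% tt
      slopes <- setdiff(tt, "(Intercept)")
      pieces <- character(0)
      if (has_int) pieces <- c(pieces, sprintf("(1 | %s)", g))
      if (length(slopes)) {
        pieces <- c(pieces, sprintf("(0 + %s | %s)", slopes, g))
      }
      paste(pieces, collapse = " + ")
    }, character(1))
    rhs <- paste(c(rhs, rterms), collapse = " + ")
  }
  as.formula(paste(response, "~", rhs))
}

.fit_ml_quiet <- function(formula, data) {
  has_bars <- length(lme4::findbars(formula)) > 0
  tryCatch(
    suppressMessages(suppressWarnings(
      if (has_bars) {
        lme4::lmer(formula, data = data, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      } else stats::lm(formula, data = data)
    )),
    error = function(e) NULL
  )
}

#' Select a parsimonious mixed-model structure
#'
#' Two-stage stepwise selection mirroring the published procedure.
#' Stage 1 builds up from an empty (intercept-only) model, at each
#' step adding -- among the terms whose marginality prerequisites are
#' already included -- the fixed or random term producing the most
#' significant likelihood-ratio improvement (ML fits, chi-square test,
#' alpha = 0.05), until no eligible term improves the fit or all
#' candidate fits fail. Stage 2 backward-eliminates random terms whose
#' removal does not significantly worsen the likelihood. The final
#' structure is refit with REML ([fit_erp_lmm()]). Random slopes are
#' treated as independent variance components, so each slope is one
#' candidate with one degree of freedom.
#'
#' @param formula Maximal model formula (fixed and random parts).
#' @param data A `coded_table`.
#' @param alpha Likelihood-ratio significance threshold (default
#'   0.05).
#' @return A list of class `lmm_selection`: `fit` (final `erp_lmm`),
#'   `formula`, and `trace` (tibble: `step`, `term`, `chisq`, `df`,
#'   `p.value`, `action`).
#' @export
select_parsimonious <- function(formula, data, alpha = 0.05) {
  response <- deparse1(formula[[2]])
  fixed_all <- .canon_term(attr(terms(lme4::nobars(formula)),
                                "term.labels"))
  bars <- lme4::findbars(formula)
  rand_all <- purrr::map_dfr(bars, function(b) {
    group <- deparse1(b[[3]])
    lhs <- as.formula(paste("~", deparse1(b[[2]])))
    labs <- attr(terms(lhs), "term.labels")
    has_int <- attr(terms(lhs), "intercept") == 1
    tibble::tibble(group = group,
                   term = c(if (has_int) "(Intercept)",
                            .canon_term(labs)))
  })

  trace <- tibble::tibble(step = integer(), term = character(),
                          chisq = numeric(), df = numeric(),
                          p.value = numeric(), action = character())
  fixed_in <- character(0)
  rand_in <- rand_all[0, ]
  cur_form <- .build_formula(response, fixed_in, rand_in)
  cur_fit <- .fit_ml_quiet(cur_form, data)
  if (is.null(cur_fit)) stop("intercept-only model failed", call. = FALSE)
  step_i <- 0L

  eligible <- function() {
    fx <- fixed_all[!fixed_all %in% fixed_in &
                      vapply(fixed_all, function(tt)
                        all(.sub_terms(tt) %in% fixed_in), logical(1))]
    rd <- rand_all[!paste(rand_all$group, rand_all$term) %in%
                     paste(rand_in$group, rand_in$term), , drop = FALSE]
    ok <- vapply(seq_len(nrow(rd)), function(i) {
      if (rd$term[i] == "(Intercept)") return(TRUE)
      ("(Intercept)" %in% rand_in$term[rand_in$group == rd$group[i]]) &&
        rd$term[i] %in% fixed_in
    }, logical(1))
    list(fixed = fx, random = rd[ok, , drop = FALSE])
  }

  repeat {
    el <- eligible()
    cands <- c(
      purrr::map(el$fixed, ~ list(kind = "fixed", term = .x)),
      purrr::map(seq_len(nrow(el$random)), function(i)
        list(kind = "random", term = el$random$term[i],
             group = el$random$group[i]))
    )
    if (!length(cands)) break
    lls <- purrr::map(cands, function(cd) {
      if (cd$kind == "fixed") {
        f <- .build_formula(response, c(fixed_in, cd$term), rand_in)
      } else {
        f <- .build_formula(response, fixed_in,
                            dplyr::bind_rows(rand_in,
                                             tibble::tibble(group = cd$group,
                                                            term = cd$term)))
      }
      fit <- .fit_ml_quiet(f, data)
      if (is.null(fit)) return(NULL)
      list(fit = fit, ll = as.numeric(logLik(fit)))
    })
    ll_cur <- as.numeric(logLik(cur_fit))
    stats_tbl <- purrr::map_dbl(lls, function(l)
      if (is.null(l)) NA_real_ else max(0, 2 * (l$ll - ll_cur)))
    pvals <- pchisq(stats_tbl, df = 1, lower.tail = FALSE)
    if (all(is.na(pvals))) break
    best <- which.min(pvals)
    step_i <- step_i + 1L
    cd <- cands[[best]]
    label <- if (cd$kind == "fixed") cd$term else
      sprintf("(%s | %s)", cd$term, cd$group)
    if (is.na(pvals[best]) || pvals[best] >= alpha) {
      break
    }
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step_i, term = label, chisq = stats_tbl[best], df = 1,
      p.value = pvals[best], action = "added"))
    if (cd$kind == "fixed") {
      fixed_in <- c(fixed_in, cd$term)
    } else {
      rand_in <- dplyr::bind_rows(rand_in,
                                  tibble::tibble(group = cd$group,
                                                 term = cd$term))
    }
    cur_fit <- lls[[best]]$fit
  }

  # stage 2: backward elimination of random terms
  repeat {
    removable <- rand_in[vapply(seq_len(nrow(rand_in)), function(i) {
      if (rand_in$term[i] != "(Intercept)") return(TRUE)
      # an intercept is removable only when its group has no slopes
      sum(rand_in$group == rand_in$group[i]) == 1L
    }, logical(1)), , drop = FALSE]
    if (!nrow(removable)) break
    ll_cur <- as.numeric(logLik(cur_fit))
    drops <- purrr::map(seq_len(nrow(removable)), function(i) {
      keep <- !(paste(rand_in$group, rand_in$term) ==
                  paste(removable$group[i], removable$term[i]))
      f <- .build_formula(response, fixed_in, rand_in[keep, , drop = FALSE])
      fit <- .fit_ml_quiet(f, data)
      if (is.null(fit)) return(NULL)
      list(fit = fit, ll = as.numeric(logLik(fit)), keep = keep)
    })
    stats_tbl <- purrr::map_dbl(drops, function(l)
      if (is.null(l)) NA_real_ else max(0, 2 * (ll_cur - l$ll)))
    pvals <- pchisq(stats_tbl, df = 1, lower.tail = FALSE)
    if (all(is.na(pvals))) break
    worst <- which.max(pvals)
    if (is.na(pvals[worst]) || pvals[worst] < alpha) break
    step_i <- step_i + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step_i,
      term = sprintf("(%s | %s)", removable$term[worst],
                     removable$group[worst]),
      chisq = stats_tbl[worst], df = 1, p.value = pvals[worst],
      action = "eliminated"))
    rand_in <- rand_in[drops[[worst]]$keep, , drop = FALSE]
    cur_fit <- drops[[worst]]$fit
  }

  final_form <- .build_formula(response, fixed_in, rand_in)
  final_fit <- fit_erp_lmm(final_form, data, reml = nrow(rand_in) > 0)
  structure(list(fit = final_fit, formula = final_form, trace = trace),
            class = "lmm_selection")
}

#' @export
print.lmm_selection <- function(x, ...) {
  cat("<lmm_selection> final:", deparse1(x$formula), "\n")
  print(x$trace)
  invisible(x)
}

# ---- simple slopes --------------------------------------------------

#' Simple slopes of a focal predictor at moderator levels
#'
#' Conditional slope of a focal variable at each -1/+1 level (or level
#' combination) of its moderators: with effect-coded moderators the
#' slope at levels `s` is the sum over all fixed-effect terms
#' containing the focal variable of the coefficient times the product
#' of the chosen moderator values, with variables outside the
#' moderator set averaged out at 0. Wald z tests with Bonferroni
#' correction (`p_adj = min(1, m * p)`, `m` = number of slopes).
#'
#' @param object An `erp_lmm`, a fitted `(g)lmerMod`/`lm`, or a named
#'   numeric vector of fixed-effect coefficients (then `vcov.` may be
#'   supplied for tests; without it only the slopes are returned).
#' @param focal Name of the focal variable (e.g. `"pe"`).
#' @param moderators Character vector of moderator names (e.g.
#'   `"valence"`).
#' @param levels Levels at which to evaluate each moderator (default
#'   `c(-1, 1)` for effect-coded factors).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @param vcov. Optional coefficient covariance matrix when `object`
#'   is a plain coefficient vector.
#' @return A tibble with one row per moderator-level combination:
#'   moderator columns, `slope`, `std.error`, `statistic` (z),
#'   `p.value` (adjusted).
#' @examples
#' simple_slopes(c(pe = 0.94, "valence:pe" = -0.77),
#'               focal = "pe", moderators = "valence")
#' @export
simple_slopes <- function(object, focal, moderators,
                          levels = c(-1, 1),
                          correction = c("bonferroni", "none"),
                          vcov. = NULL) {
  correction <- match.arg(correction)
  if (inherits(object, "erp_lmm")) object <- object$fit
  if (is.numeric(object)) {
    b <- object
    V <- vcov.
  } else {
    b <- lme4::fixef(object)
    if (is.null(b)) b <- coef(object)
    V <- as.matrix(vcov(object))
  }
  names(b) <- .canon_term(names(b))
  if (!is.null(V)) dimnames(V) <- list(names(b), names(b))

  grid <- do.call(tidyr::expand_grid,
                  setNames(rep(list(levels), length(moderators)),
                           moderators))
  m <- nrow(grid)
  res <- purrr::map_dfr(seq_len(m), function(i) {
    lv <- as.numeric(grid[i, ]); names(lv) <- moderators
    # contrast vector over coefficients: d(linear predictor)/d(focal)
    cvec <- setNames(numeric(length(b)), names(b))
    for (term in names(b)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (!(focal %in% parts)) next
      others <- setdiff(parts, focal)
      if (!all(others %in% moderators)) next  # averaged out at 0
      cvec[term] <- if (length(others)) prod(lv[others]) else 1
    }
    slope <- sum(cvec * b)
    if (!is.null(V)) {
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      z <- slope / se
      p <- 2 * pnorm(-abs(z))
    } else {
      se <- NA_real_; z <- NA_real_; p <- NA_real_
    }
    dplyr::bind_cols(grid[i, ],
                     tibble::tibble(slope = slope, std.error = se,
                                    statistic = z, p.value = p))
  })
  if (correction == "bonferroni") {
    res$p.value <- pmin(1, m * res$p.value)
  }
  res
}

# ---- simulation-based power -----------------------------------------

#' Simulation-based power for a mixed-model coefficient
#'
#' Repeatedly generates single-trial amplitudes from the generator
#' model with the focal fixed-effect coefficient set to `b`, refits
#' the analysis model, and counts significant focal tests
#' (Satterthwaite t, two-sided). Power is the significant fraction
#' with an exact (Clopper-Pearson) binomial confidence interval. With
#' `b = 0` the procedure estimates the type-I error rate and should
#' return approximately `alpha`.
#'
#' @param trials Per-trial covariate table (as for
#'   [generate_amplitude_table()]).
#' @param params An `amplitude_gen_params` whose focal coefficient is
#'   overridden.
#' @param focal Name of the focal fixed-effect term (canonical order,
#'   e.g. `"valence:timing:pe"`).
#' @param b Focal coefficient value under which data are simulated.
#' @param formula Analysis formula fitted to each simulated data set.
#' @param electrodes Electrode labels for the generator.
#' @param n_sims Number of simulations (default 200).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed; simulation `i` uses `seed + i`.
#' @param conf_level Confidence level of the binomial CI.
#' @return A list of class `power_result`: `power`, `conf_int`,
#'   `n_sig`, `n_sims`, `alpha`, `b`, `focal`.
#' @export
power_simulation <- function(trials, params, focal, b, formula,
                             electrodes = c("Fz", "Cz"),
                             n_sims = 200L, alpha = 0.05, seed = 1L,
                             conf_level = 0.95) {
  stopifnot(inherits(params, "amplitude_gen_params"))
  coefs <- params$coefs
  names(coefs) <- .canon_term(names(coefs))
  focal <- .canon_term(focal)
  coefs[focal] <- b
  params$coefs <- coefs
  n_sig <- 0L
  for (i in seq_len(n_sims)) {
    tab <- generate_amplitude_table(trials, params,
                                    electrodes = electrodes,
                                    seed = seed + i)
    coded <- encode_predictors(tab)
    fit <- fit_erp_lmm(formula, coded, reml = TRUE)
    tt <- tidy(fit)
    tt$term <- .canon_term(tt$term)
    p <- tt$p.value[tt$term == focal]
    if (length(p) != 1L) {
      stop("focal term '", focal, "' absent from the fitted model",
           call. = FALSE)
    }
    if (!is.na(p) && p < alpha) n_sig <- n_sig + 1L
  }
  ci <- binom.test(n_sig, n_sims, conf.level = conf_level)$conf.int
  structure(list(power = n_sig / n_sims, conf_int = as.numeric(ci),
                 n_sig = n_sig, n_sims = n_sims, alpha = alpha,
                 b = b, focal = focal),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "<power_result> %s = %.3g: power = %.2f%% (%d/%d, %.0f%% CI %.2f-%.2f%%)\n",
    x$focal, x$b, 100 * x$power, x$n_sig, x$n_sims, 95,
    100 * x$conf_int[1], 100 * x$conf_int[2]))
  invisible(x)
}
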