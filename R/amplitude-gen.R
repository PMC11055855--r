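#' Parameters of the single-trial amplitude generator
#'
#' Describes the linear mixed model from which synthetic single-trial
#' component amplitudes are drawn: fixed effects for Feedback Valence,
#' Feedback Timing, the unsigned prediction error (and Frontality for
#' P300-style tables) with all interactions, by-participant random
#' intercept and slopes, a by-electrode random intercept, and Gaussian
#' residual noise. Two-level factors are coded -1/+1 with the fixed
#' sign map *negative feedback = +1, delayed = +1, parietal = +1*.
#'
#' @param coefs Named numeric vector of fixed-effect coefficients.
#'   Recognised names: `"(Intercept)"`, `"valence"`, `"timing"`,
#'   `"pe"`, `"frontality"` and `:`-joined interactions thereof.
#' @param sd_participant Named numeric vector of by-participant random
#'   effect SDs (at least `"(Intercept)"`; slopes for any fixed term).
#' @param sd_electrode By-electrode random intercept SD.
#' @param sigma Residual SD (microvolts).
#' @return A list of class `amplitude_gen_params`.
#' @seealso [frn_gen_params()], [p300_gen_params()] for defaults whose
#'   fixed effects are the published FRN/RewP and P300 estimates.
#' @export
amplitude_gen_params <- function(coefs,
                                 sd_participant = c("(Intercept)" = 1.5),
                                 sd_electrode = 0.3,
                                 sigma = 8) {
  stopifnot(is.numeric(coefs), !is.null(names(coefs)))
  if (any(c(sd_participant, sd_electrode, sigma) < 0)) {
    stop("random-effect and residual SDs must be >= 0", call. = FALSE)
  }
  structure(list(coefs = coefs, sd_participant = sd_participant,
                 sd_electrode = sd_electrode, sigma = sigma),
            class = "amplitude_gen_params")
}

#' Generator defaults for FRN/RewP-style amplitudes
#'
#' Fixed effects default to the published single-trial FRN/RewP
#' estimates (valence -0.38, timing -1.01, |PE| 0.94,
#' valence:timing 0.20, timing:pe -0.57, valence:pe -0.77,
#' three-way -0.07) under the -1/+1 coding of
#' [amplitude_gen_params()]. Random-effect SDs and the residual SD are
#' not published; the defaults (participant intercept 1.5 and slopes
#' 0.4 microvolts, electrode intercept 0.3, residual 8) are typical of
#' single-trial frontocentral feedback ERPs.
#'
#' @param intercept Grand-mean amplitude (microvolts).
#' @param sigma Residual SD.
#' @param slope_sd By-participant slope SD applied to valence, timing
#'   and pe.
#' @return An `amplitude_gen_params` object.
#' @export
frn_gen_params <- function(intercept = 2, sigma = 8, slope_sd = 0.4) {
  amplitude_gen_params(
    coefs = c("(Intercept)" = intercept, valence = -0.38, timing = -1.01,
              pe = 0.94, "valence:timing" = 0.20, "timing:pe" = -0.57,
              "valence:pe" = -0.77, "valence:timing:pe" = -0.07),
    sd_participant = c("(Intercept)" = 1.5, valence = slope_sd,
                       timing = slope_sd, pe = slope_sd),
    sd_electrode = 0.3, sigma = sigma
  )
}

#' Generator defaults for P300-style amplitudes
#'
#' Published fixed effects for the P300 analysis (timing -0.80,
#' valence -0.19, |PE| 1.02, valence:pe -0.92, timing:frontality
#' -0.96, valence:timing:frontality -0.06, valence:frontality:pe
#' 0.18); remaining interactions default to zero.
#'
#' @inheritParams frn_gen_params
#' @return An `amplitude_gen_params` object.
#' @export
p300_gen_params <- function(intercept = 4, sigma = 8, slope_sd = 0.4) {
  amplitude_gen_params(
    coefs = c("(Intercept)" = intercept, valence = -0.19, timing = -0.80,
              frontality = 0, pe = 1.02, "valence:pe" = -0.92,
              "timing:frontality" = -0.96,
              "valence:timing:frontality" = -0.06,
              "valence:frontality:pe" = 0.18),
    sd_participant = c("(Intercept)" = 1.5, valence = slope_sd,
                       timing = slope_sd, pe = slope_sd),
    sd_electrode = 0.3, sigma = sigma
  )
}

# -1/+1 sign map used across the package:
# valence: negative feedback = +1; timing: delayed = +1;
# frontality: parietal = +1.
.code_valence <- function(reward) ifelse(reward == 1, -1, 1)
.code_timing <- function(timing) ifelse(timing == "delayed", 1, -1)
.code_frontality <- function(cluster) ifelse(cluster == "parietal", 1, -1)

#' Generate a single-trial amplitude table
#'
#' Draws one amplitude per retained trial and electrode from the
#' linear mixed model described by an [amplitude_gen_params()] object.
#' The linear predictor uses -1/+1 codes for the two-level factors and
#' the grand-mean-centred unsigned PE (so the coefficients carry the
#' same meaning as in the downstream mixed-model analysis); the output
#' column `pe_abs` keeps the PE on its original scale.
#'
#' @param trials A tibble with one row per trial, containing
#'   `participant`, `timing`, `reward` and `pe_abs` (e.g. the output
#'   of [extract_pes()], possibly row-bound across participants and
#'   conditions). An optional `trial` column is carried through.
#' @param params An `amplitude_gen_params` object.
#' @param electrodes Character vector of electrode labels; a
#'   `frontality` code is attached when `clusters` is given.
#' @param clusters Optional named list mapping cluster names
#'   (`"frontocentral"`, `"parietal"`) to electrode labels, needed
#'   when the generator coefficients involve `frontality`.
#' @param seed Integer seed.
#' @param component Component label stored in the table.
#' @return A tibble (long format): `participant`, `timing`, `trial`,
#'   `electrode`, `cluster`, `component`, `reward`, `pe_abs`,
#'   `amplitude_uv`, plus attribute `true_coefs`.
#' @export
generate_amplitude_table <- function(trials, params,
                                     electrodes = c("Fz", "FCz", "Cz",
                                                    "FC1", "FC2"),
                                     clusters = NULL, seed = 1L,
                                     component = "frn") {
  stopifnot(inherits(params, "amplitude_gen_params"))
  needed <- c("participant", "timing", "reward", "pe_abs")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    stop("`trials` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(electrodes) == 0L) stop("`electrodes` is empty", call. = FALSE)
  if (anyNA(trials$pe_abs)) stop("`pe_abs` contains NA", call. = FALSE)

  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  if (!"trial" %in% names(trials)) trials$trial <- seq_len(nrow(trials))
  trials$.row <- seq_len(nrow(trials))
  elec_tbl <- tibble::tibble(electrode = electrodes)
  if (!is.null(clusters)) {
    elec_tbl$cluster <- NA_character_
    for (nm in names(clusters)) {
      elec_tbl$cluster[elec_tbl$electrode %in% clusters[[nm]]] <- nm
    }
  } else {
    elec_tbl$cluster <- NA_character_
  }
  long <- tidyr::expand_grid(trials, elec_tbl)

  codes <- list(
    valence = .code_valence(long$reward),
    timing = .code_timing(long$timing),
    pe = long$pe_abs - mean(trials$pe_abs)
  )
  if (!all(is.na(elec_tbl$cluster))) {
    codes$frontality <- .code_frontality(long$cluster)
  }
  lp <- .linear_predictor(params$coefs, codes, nrow(long))

  # by-participant random intercept and slopes (independent normals)
  participants <- unique(long$participant)
  re_p <- matrix(rnorm(length(participants) * length(params$sd_participant)),
                 nrow = length(participants))
  re_p <- sweep(re_p, 2, params$sd_participant, `*`)
  colnames(re_p) <- names(params$sd_participant)
  rownames(re_p) <- participants
  pi <- match(long$participant, participants)
  for (term in names(params$sd_participant)) {
    z <- if (term == "(Intercept)") rep(1, nrow(long)) else
      .term_column(term, codes)
    lp <- lp + unname(re_p[pi, term]) * z
  }
  # by-electrode random intercept
  re_e <- rnorm(length(electrodes), 0, params$sd_electrode)
  lp <- lp + re_e[match(long$electrode, electrodes)]

  long$amplitude_uv <- as.numeric(lp) + rnorm(nrow(long), 0, params$sigma)
  long$component <- component
  out <- dplyr::select(long, dplyr::any_of(c(
    "participant", "timing", "block", "trial", ".row", "electrode",
    "cluster", "component", "reward", "pe_abs", "amplitude_uv")))
  attr(out, "true_coefs") <- params$coefs
  attr(out, "pe_center") <- mean(trials$pe_abs)
  out
}

# evaluate named-coefficient linear predictor on coded columns
.linear_predictor <- function(coefs, codes, n) {
  lp <- rep(0, n)
  for (term in names(coefs)) {
    lp <- lp + coefs[[term]] *
      (if (term == "(Intercept)") rep(1, n) else .term_column(term, codes))
  }
  lp
}

.term_column <- function(term, codes) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  unknown <- setdiff(parts, names(codes))
  if (length(unknown)) {
    stop("generator coefficient refers to unknown variable(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  Reduce(`*`, codes[parts])
}
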