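#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()]:
#' cohort size, task and agent parameters, amplitude-generator
#' coefficients, epoch synthesis, rejection criteria, component search
#' windows, and the maximal mixed-model formula. All values are
#' validated against the module preconditions when the pipeline runs.
#' Configurations round-trip through YAML ([read_pipeline_config()]).
#'
#' @param seed Master seed; every stochastic stage derives its own
#'   seed from it.
#' @param n_participants Cohort size (each participant performs both
#'   timing conditions).
#' @param n_blocks,trials_per_block Task dimensions per condition.
#' @param probabilities Stimulus reward probabilities.
#' @param agent List with `model`, `alpha_con`, `alpha_dis`, `beta`.
#' @param generator `"frn"` or `"p300"` default coefficient set.
#' @param generator_sigma Optional residual SD (microvolts) overriding
#'   the generator default.
#' @param mode `"amplitude"` relates generated amplitudes directly to
#'   the mixed model; `"epoch"` additionally synthesises noisy
#'   epochs, rejects artifacts, finds peaks and extracts windowed
#'   amplitudes before modelling.
#' @param artifact_rate Fraction of artifact trials in epoch mode.
#' @param epoch_noise_sd White-noise SD of synthesised epochs
#'   (microvolts; epoch mode only).
#' @param n_starts Random restarts per model fit.
#' @param max_formula Maximal mixed-model formula (character).
#' @param select_terms Run stepwise term selection (slower) instead of
#'   fitting `max_formula` directly.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_participants = 4L,
                            n_blocks = 3L,
                            trials_per_block = 100L,
                            probabilities = c(0, .2, .4, .6, .8),
                            agent = list(model = "M3", alpha_con = 0.3,
                                         alpha_dis = 0.1, beta = 5),
                            generator = "frn",
                            generator_sigma = NULL,
                            mode = c("amplitude", "epoch"),
                            artifact_rate = 0.05,
                            epoch_noise_sd = 10,
                            n_starts = 50L,
                            max_formula = paste(
                              "amplitude ~ valence * timing * pe",
                              "+ (1 | participant) + (1 | electrode)"),
                            select_terms = FALSE) {
  mode <- match.arg(mode)
  structure(list(seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 probabilities = probabilities, agent = agent,
                 generator = generator,
                 generator_sigma = generator_sigma, mode = mode,
                 artifact_rate = artifact_rate,
                 epoch_noise_sd = epoch_noise_sd,
                 n_starts = as.integer(n_starts),
                 max_formula = max_formula,
                 select_terms = isTRUE(select_terms)),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_pipeline_config()` returns a validated
#'   `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates the cohort (each participant performing the task under
#' immediate and delayed feedback), fits the three learning models and
#' selects one by mean BIC, extracts unsigned prediction errors from
#' the selected model's fits, generates single-trial amplitudes (and,
#' in epoch mode, noisy epochs that are baseline-corrected,
#' artifact-rejected, peak-searched and reduced to windowed mean
#' amplitudes), fits the mixed model, and computes the behavioural
#' statistics. Identical configuration and seed give identical
#' numeric results. Stage failures abort with the stage name; results
#' of completed stages are attached to the error condition.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, summary CSV/JSON
#'   artifacts are written there, each tagged with the configuration
#'   hash and seed.
#' @return A list of class `pipeline_result` with elements `sessions`,
#'   `comparison`, `trials` (per-trial table with PEs), `amplitudes`,
#'   `lmm` (`erp_lmm` or `lmm_selection`), `accuracy`, `anova`,
#'   `chance`, `wilcoxon`, `config_hash`, and in epoch mode `epochs`,
#'   `peaks`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg_hash <- .config_hash(config)
  result <- list(config = config, config_hash = cfg_hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  agent <- stage("config", do.call(agent_params, config$agent))

  sessions <- stage("simulate", {
    grid <- tidyr::expand_grid(
      participant = sprintf("p%02d", seq_len(config$n_participants)),
      timing = c("immediate", "delayed"))
    purrr::pmap(grid, function(participant, timing) {
      i <- which(grid$participant == participant &
                   grid$timing == timing)
      design <- generate_task_design(
        seed = config$seed + 17L * i, n_blocks = config$n_blocks,
        trials_per_block = config$trials_per_block,
        probabilities = config$probabilities, timing = timing)
      simulate_agent(design, agent, seed = config$seed + 31L * i,
                     participant = participant)
    })
  })
  result$sessions <- sessions

  result$comparison <- stage("compare_models",
    compare_models(sessions, n_starts = config$n_starts,
                   seed = config$seed))
  selected <- result$comparison$selected

  result$trials <- stage("extract_pes", {
    fits <- result$comparison$fits[[selected]]
    dplyr::bind_rows(purrr::map2(fits, sessions, extract_pes))
  })

  gen_params <- stage("generator_params", {
    maker <- switch(config$generator,
                    frn = frn_gen_params, p300 = p300_gen_params,
                    stop("unknown generator '", config$generator, "'"))
    if (is.null(config$generator_sigma)) maker()
    else maker(sigma = config$generator_sigma)
  })

  if (config$mode == "amplitude") {
    result$amplitudes <- stage("generate_amplitudes",
      generate_amplitude_table(result$trials, gen_params,
                               seed = config$seed + 101L))
  } else {
    result$epochs <- stage("generate_epochs", {
      tab <- generate_amplitude_table(result$trials, gen_params,
                                      seed = config$seed + 101L)
      es <- generate_epochs(tab,
                            waveform_template(noise_sd = config$epoch_noise_sd),
                            seed = config$seed + 103L,
                            artifact_rate = config$artifact_rate)
      es <- baseline_correct(es)
      reject_artifacts(es)
    })
    result$peaks <- stage("find_peaks", {
      purrr::map(c(immediate = "immediate", delayed = "delayed"),
                 function(tm) {
        neg <- condition_average(result$epochs,
                                 ~ reward == 0 & timing == tm,
                                 cluster_spec("frontocentral"))
        pos <- condition_average(result$epochs,
                                 ~ reward == 1 & timing == tm,
                                 cluster_spec("frontocentral"))
        find_peak(difference_wave(neg, pos), c(180, 350), "negative")
      })
    })
    result$amplitudes <- stage("extract_amplitudes", {
      purrr::map_dfr(c("immediate", "delayed"), function(tm) {
        keep <- result$epochs$trials$timing == tm
        sub <- result$epochs
        sub$voltages <- sub$voltages[keep, , , drop = FALSE]
        sub$trials <- sub$trials[keep, ]
        sub$rejection <- sub$rejection[keep, ]
        extract_window_amplitudes(
          sub, center = result$peaks[[tm]]$latency_ms,
          cluster = cluster_spec("frontocentral"))
      })
    })
  }

  # the mixed-model stage degrades gracefully (e.g. a single-participant
  # cohort cannot support by-participant random effects)
  result$lmm <- tryCatch({
    coded <- encode_predictors(result$amplitudes)
    f <- as.formula(config$max_formula)
    if (config$select_terms) select_parsimonious(f, coded)
    else fit_erp_lmm(f, coded)
  }, error = function(e) {
    structure(list(stage = "mixed_model", message = conditionMessage(e)),
              class = "pipeline_stage_error")
  })

  result$accuracy <- stage("behaviour", score_accuracy(sessions))
  # the accuracy ANOVA needs both factors at >= 2 levels; single-block
  # configurations carry on without it
  result$anova <- tryCatch(rm_anova(result$accuracy), error = function(e) {
    structure(list(stage = "rm_anova", message = conditionMessage(e)),
              class = "pipeline_stage_error")
  })
  result$chance <- stage("chance_tests",
                         purrr::map_dfr(sessions, binomial_chance_test))
  result$wilcoxon <- stage("wilcoxon", {
    fits <- result$comparison$fits[[
      if (selected == "M1") "M3" else selected]]
    rates <- learning_rate_table(fits)
    dplyr::bind_rows(
      wilcoxon_learning_rates(rates, "feedback_type"),
      wilcoxon_learning_rates(rates, "timing"),
      wilcoxon_learning_rates(rates, "bias_by_timing"))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(df) dplyr::mutate(df, config_hash = cfg_hash,
                                        seed = config$seed)
    utils::write.csv(stamp(result$comparison$table),
                     file.path(out_dir, "model_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(result$accuracy),
                     file.path(out_dir, "accuracy.csv"),
                     row.names = FALSE)
    if (inherits(result$anova, "data.frame")) {
      utils::write.csv(stamp(result$anova),
                       file.path(out_dir, "rm_anova.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(stamp(result$wilcoxon),
                     file.path(out_dir, "wilcoxon.csv"),
                     row.names = FALSE)
    lmm_fit <- if (inherits(result$lmm, "lmm_selection"))
      result$lmm$fit else result$lmm
    if (inherits(lmm_fit, "erp_lmm")) {
      utils::write.csv(stamp(tidy(lmm_fit)),
                       file.path(out_dir, "lmm_fixed_effects.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(config_hash = cfg_hash, seed = config$seed,
           selected_model = selected,
           package_version = as.character(utils::packageVersion("trialpe"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  structure(result, class = "pipeline_result")
}

.config_hash <- function(config) {
  # small stable fingerprint without extra dependencies
  s <- paste(deparse(unclass(config)), collapse = "")
  raw <- utils::head(charToRaw(s), 10000)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% 0xFFFFFFF)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> hash", x$config_hash, "\n")
  cat("  selected model:", x$comparison$selected, "\n")
  cat("  trials modelled:", nrow(x$amplitudes), "amplitude rows\n")
  invisible(x)
}
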