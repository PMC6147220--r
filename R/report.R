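# Summary surfaces: target-weight and response-variability curves versus
# level difference, identification-rate tables, and the end-to-end
# pipeline driver. Report tables are pure functions of fitted posteriors;
# re-reporting never re-samples.

#' Weight and variability curves per condition
#'
#' Extracts, for every (modulation frequency, level difference) cell, the
#' posterior mean and SD of the target weight `w` and double-sound SD
#' `sigma_d`, plus their 95% HDIs, from a (possibly pooled) localization
#' posterior.
#'
#' @param posterior A `wa_posterior` from [fit_localization()] or
#'   [pool_posteriors()].
#' @param require_full_grid If `TRUE` (default), error listing any of the
#'   15 standard (fm, level-difference) cells missing from the fit.
#' @return A tibble keyed by `fm_hz`, `delta_l_db` with columns `w_mean`,
#'   `w_sd`, `w_hdi_lo`, `w_hdi_hi`, `sigma_d_mean`, `sigma_d_sd`,
#'   `sigma_d_hdi_lo`, `sigma_d_hdi_hi`.
#' @export
weight_curves <- function(posterior, require_full_grid = TRUE) {
  conds <- posterior$conditions
  if (require_full_grid) {
    full <- expand.grid(fm_hz = FM_LEVELS, delta_l_db = DELTA_L_LEVELS)
    have <- paste(conds$fm_hz, conds$delta_l_db)
    miss <- !(paste(full$fm_hz, full$delta_l_db) %in% have)
    if (any(miss))
      stop("missing condition cell(s): ",
           paste(sprintf("(fm=%g, dL=%g)", full$fm_hz[miss],
                         full$delta_l_db[miss]), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    wd <- as.numeric(posterior$draws[[conds$w_param[i]]])
    sd_d <- as.numeric(posterior$draws[[conds$sigma_param[i]]])
    wh <- hdi(wd)
    sh <- hdi(sd_d)
    tibble::tibble(fm_hz = conds$fm_hz[i], delta_l_db = conds$delta_l_db[i],
                   w_mean = mean(wd), w_sd = stats::sd(wd),
                   w_hdi_lo = wh[1], w_hdi_hi = wh[2],
                   sigma_d_mean = mean(sd_d), sigma_d_sd = stats::sd(sd_d),
                   sigma_d_hdi_lo = sh[1], sigma_d_hdi_hi = sh[2])
  })
  out <- do.call(rbind, rows)
  out[order(out$fm_hz, out$delta_l_db), ]
}

#' Identification-rate table for discrimination conditions
#'
#' One row per condition: posterior mean and 95% HDI of the
#' identification rate, the Savage-Dickey Bayes factor against chance
#' (theta = 0.5) with its evidence label, and whether the HDI excludes
#' chance.
#'
#' @param results A list of `discrimination_result` objects (see
#'   [fit_discrimination()]).
#' @param conditions Optional tibble (one row per result) of condition
#'   descriptors to bind in front; defaults to the list names.
#' @return A tibble with `K`, `N`, `theta_mean`, `hdi_lo`, `hdi_hi`,
#'   `bf10`, `evidence`, `excludes_chance`.
#' @export
identification_table <- function(results, conditions = NULL) {
  rows <- lapply(results, function(r) {
    tibble::tibble(K = r$K, N = r$N, theta_mean = r$theta_mean,
                   hdi_lo = r$hdi[1], hdi_hi = r$hdi[2],
                   bf10 = as.numeric(r$bf10),
                   evidence = attr(r$bf10, "label"),
                   excludes_chance = r$hdi[1] > 0.5 | r$hdi[2] < 0.5)
  })
  out <- do.call(rbind, rows)
  if (is.null(conditions) && !is.null(names(results)))
    conditions <- tibble::tibble(condition = names(results))
  if (!is.null(conditions)) out <- cbind(tibble::as_tibble(conditions), out)
  tibble::as_tibble(out)
}

#' Run the full design-simulate-fit-report pipeline
#'
#' Executes design generation, behavioral simulation, model fitting and
#' reporting for one configuration, writing all artifacts (trial table,
#' responses, posterior summary or identification table, and a manifest
#' recording every seed) into `out_dir`. Reruns with the same
#' configuration reproduce the exact stage outputs.
#'
#' @param config A list with elements `design` (one of `"localization"`,
#'   `"discrim_freq"`, `"discrim_phase"`), `params` (a `behavior_params`;
#'   default [default_behavior_params()]), `model` (`"weighted_average"`
#'   or `"bistable"`, localization only), `seeds` (list with `design`,
#'   `simulate`, `fit`), and MCMC layout `n_chains`, `n_samples`,
#'   `n_burn`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design %||% "localization"
  params <- config$params %||% default_behavior_params()
  model <- config$model %||% "weighted_average"
  seeds <- config$seeds %||% list(design = 1L, simulate = 2L, fit = 3L)
  n_chains <- config$n_chains %||% 3L
  n_samples <- config$n_samples %||% 2000L
  n_burn <- config$n_burn %||% 1000L

  trials <- stop_stage("design", switch(design,
    localization = build_localization_trials(seeds$design),
    discrim_freq = build_discrim_freq_trials(seeds$design),
    discrim_phase = build_discrim_phase_trials(seeds$design),
    stop("unknown design: ", design)))
  paths <- list(trials = file.path(out_dir, "trials.csv"))
  write_trial_table(trials, paths$trials)

  if (design == "localization") {
    responses <- stop_stage("simulate", switch(model,
      weighted_average = simulate_localization(trials, params,
                                               seeds$simulate),
      bistable = simulate_bistable(trials, params, seeds$simulate),
      stop("unknown model: ", model)))
    paths$responses <- file.path(out_dir, "responses.csv")
    utils::write.csv(responses, paths$responses, row.names = FALSE)
    post <- stop_stage("fit", fit_localization(
      trials, responses, n_chains = n_chains, n_samples = n_samples,
      n_burn = n_burn, seed = seeds$fit))
    smry <- summary(post)
    paths$posterior_summary <- file.path(out_dir, "posterior_summary.csv")
    utils::write.csv(smry, paths$posterior_summary, row.names = FALSE)
    paths$weight_curves <- file.path(out_dir, "weight_curves.csv")
    utils::write.csv(weight_curves(post), paths$weight_curves,
                     row.names = FALSE)
  } else {
    theta <- if (design == "discrim_freq") params$theta_table else
      params$theta_phase
    responses <- stop_stage("simulate",
                            simulate_discrimination(trials, theta,
                                                    seeds$simulate))
    paths$responses <- file.path(out_dir, "responses.csv")
    utils::write.csv(responses, paths$responses, row.names = FALSE)
    key <- if (design == "discrim_freq") "fm_hz" else "phase_rad"
    tab <- stop_stage("fit", {
      d <- trials$trial_type == "double"
      cond_vals <- sort(unique(trials[[key]][d]))
      fits <- lapply(cond_vals, function(v) {
        sel <- d & trials[[key]] == v
        hit <- responses$correct[match(trials$index[sel], responses$index)]
        fit_discrimination(sum(hit), length(hit))
      })
      cond_tbl <- tibble::tibble(v = cond_vals)
      names(cond_tbl) <- key
      identification_table(fits, cond_tbl)
    })
    paths$identification <- file.path(out_dir, "identification.csv")
    utils::write.csv(tab, paths$identification, row.names = FALSE)
  }

  manifest <- list(design = design, model = model, seeds = seeds,
                   n_chains = n_chains, n_samples = n_samples,
                   n_burn = n_burn,
                   package_version =
                     as.character(utils::packageVersion("waloc")))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
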