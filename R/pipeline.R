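# End-to-end regional analysis: metrics -> detection scan -> scale
# profiles -> collinearity and model sets -> spatial check -> GOF ->
# all-subsets selection -> evaluation. Every stage is a pure function of
# (config, seed).

#' Regional analysis configuration
#'
#' Bundles the synthetic-scenario configuration with every analysis
#' threshold. All thresholds default to the standard values of the
#' patch-landscape workflow: Spearman 0.60, VIF 10, delta-AIC 2,
#' significance 0.05 for the spatial check, 0.01 steps for the kappa
#' threshold grid.
#'
#' @param sim a [sim_config()] for the synthetic region.
#' @param roster occupancy variable roster of the global models
#'   (scale-dependent names unsuffixed).
#' @param scale_vars variables measured at every buffer scale.
#' @param flagged_pairs correlated pairs kept via alternative model sets.
#' @param p_covariates detection covariates.
#' @param run_scales scale labels to run global models at: numeric scales
#'   and/or `"ms"`.
#' @param rs_threshold,vif_threshold,delta_threshold,alpha analysis
#'   thresholds.
#' @param gof_B bootstrap replicates for the goodness-of-fit stage.
#' @param use_aicc rank candidate subsets by AICc instead of AIC.
#' @return A `region_config` list.
#' @export
region_config <- function(sim = sim_config(),
                          roster = c(
                            "habitat", "crop_pas", "urban", "prox",
                            "np_dist", "dist_river", "area", "veg_str"
                          ),
                          scale_vars = c("habitat", "crop_pas", "urban", "prox"),
                          flagged_pairs = list(c("np_dist", "prox")),
                          p_covariates = c("veg_str", "day", "area"),
                          run_scales = c(as.list(sim$scales), list("ms")),
                          rs_threshold = 0.60, vif_threshold = 10,
                          delta_threshold = 2, alpha = 0.05,
                          gof_B = 200, use_aicc = FALSE) {
  structure(
    list(
      sim = sim, roster = roster, scale_vars = scale_vars,
      flagged_pairs = flagged_pairs, p_covariates = p_covariates,
      run_scales = run_scales,
      rs_threshold = rs_threshold, vif_threshold = vif_threshold,
      delta_threshold = delta_threshold, alpha = alpha,
      gof_B = gof_B, use_aicc = use_aicc
    ),
    class = "region_config"
  )
}

#' Run the full regional occupancy analysis
#'
#' Executes the workflow in order on a synthetic region generated from
#' `config$sim` (with `seed` substituted): landscape and covariate
#' simulation, detection-structure scan, univariate scale-of-effect
#' profiles, per-dataset collinearity screening and model-set
#' construction, residual spatial-autocorrelation check on each global
#' model (PCNM autocovariate entered as a fixed occupancy term when
#' significant), parametric-bootstrap goodness of fit of each global
#' model, all-subsets AIC selection, and confusion-matrix evaluation of
#' every selected model. Identical (config, seed) pairs give identical
#' output.
#'
#' @param config a [region_config()].
#' @param seed integer seed; replaces `config$sim$seed`.
#' @return A list of class `region_run`: `region` (synthetic data),
#'   `detection_scan`, `profiles` (named list of scale profiles),
#'   `scale_of_effect` (tibble), `globals` (per scale-label x set tibble
#'   with collinearity, SAC, GOF and selection results), `selected`
#'   (combined evaluation table), `config`, `seed`.
#' @export
run_region_analysis <- function(config = region_config(), seed = config$sim$seed) {
  sim <- config$sim
  sim$seed <- as.integer(seed)
  region <- simulate_region(sim)
  data <- region$detections
  centroids <- do.call(rbind, lapply(region$landscape$patches$polygon, poly_centroid))

  det_scan <- detection_model_scan(data, config$p_covariates)

  profiles <- lapply(config$scale_vars, function(v) {
    scale_profile_scan(data, v, sim$scales, config$p_covariates)
  })
  names(profiles) <- config$scale_vars
  soe <- tibble::tibble(
    variable = config$scale_vars,
    scale_of_effect = vapply(profiles, scale_of_effect, numeric(1))
  )

  # univariate strength (Nagelkerke R2) of the non-scale variables
  plain_vars <- setdiff(config$roster, config$scale_vars)
  null_fit <- fit_occupancy(data, character(), character(), compute_rn2 = FALSE)
  plain_rn2 <- vapply(plain_vars, function(v) {
    fit_occupancy(data, v, config$p_covariates, null_fit = null_fit)$rn2
  }, numeric(1))

  label_chr <- function(lab) if (identical(lab, "ms")) "ms" else as.character(lab)

  globals <- purrr::map(config$run_scales, function(lab) {
    terms_all <- assemble_global_model(config$roster, lab, profiles, config$scale_vars)
    names(terms_all) <- config$roster
    strengths <- stats::setNames(numeric(length(config$roster)), terms_all)
    for (v in config$roster) {
      strengths[terms_all[v]] <- if (v %in% config$scale_vars) {
        pr <- profiles[[v]]
        s <- if (identical(lab, "ms")) scale_of_effect(pr) else lab
        pr$rn2[match(as.numeric(s), pr$scale)]
      } else {
        plain_rn2[v]
      }
    }
    flagged_terms <- lapply(config$flagged_pairs, function(pr) unname(terms_all[pr]))
    screen <- collinearity_filter(
      data, unname(terms_all), strengths,
      rs_threshold = config$rs_threshold,
      vif_threshold = config$vif_threshold,
      flagged_pairs = flagged_terms
    )
    # flagged pairs survive screening only if both members were retained
    live_pairs <- purrr::keep(flagged_terms, function(pr) all(pr %in% screen$retained))
    sets <- build_model_sets(live_pairs, screen$retained)

    purrr::map(seq_len(nrow(sets)), function(i) {
      psi_terms <- sets$members[[i]]
      global_fit <- fit_occupancy(data, psi_terms, config$p_covariates,
        null_fit = null_fit
      )
      sac <- spatial_autocorrelation_check(global_fit, centroids,
        alpha = config$alpha, seed = sim$seed
      )
      dat <- data
      fixed <- character()
      if (sac$significant) {
        dat$pcnm_auto <- sac$autocovariate
        fixed <- "pcnm_auto"
        global_fit <- fit_occupancy(dat, c(psi_terms, fixed), config$p_covariates,
          null_fit = null_fit
        )
      }
      gof <- gof_parametric_bootstrap(global_fit, B = config$gof_B, seed = sim$seed)
      candidates <- all_subsets_selection(
        dat, psi_terms, config$p_covariates,
        delta_threshold = config$delta_threshold,
        use_aicc = config$use_aicc,
        fixed_psi = fixed, null_fit = null_fit
      )
      tibble::tibble(
        scale_label = label_chr(lab), set_id = sets$set_id[i],
        set_choice = sets$choice[i],
        psi_terms = list(psi_terms),
        retained = list(screen$retained),
        dropped = list(screen$dropped),
        morans_i = sac$morans_i, sac_p = sac$p_value,
        sac_significant = sac$significant,
        chi2_obs = gof$chi2_obs, gof_p = gof$p_value, c_hat = gof$c_hat,
        candidates = list(candidates)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  selected <- globals |>
    dplyr::mutate(sel = purrr::map(.data$candidates, function(cc) {
      cc |>
        dplyr::filter(.data$selected) |>
        dplyr::mutate(evaluation = purrr::map(.data$fit, evaluate_model))
    })) |>
    dplyr::select("scale_label", "set_id", "set_choice", "sel") |>
    tidyr::unnest("sel") |>
    tidyr::unnest("evaluation")

  structure(
    list(
      region = region, detection_scan = det_scan, profiles = profiles,
      scale_of_effect = soe, globals = globals, selected = selected,
      config = config, seed = sim$seed
    ),
    class = "region_run"
  )
}

#' @export
print.region_run <- function(x, ...) {
  cat(sprintf(
    "<region_run> seed %d: %d patches, %d scale labels, %d selected models\n",
    x$seed, nrow(x$region$detections),
    length(unique(x$globals$scale_label)), nrow(x$selected)
  ))
  invisible(x)
}

#' Write the artifacts of a regional run
#'
#' Emits the synthetic-region inputs plus the stage outputs: detection
#' scan, scale profiles, per-global diagnostics and the selected-model
#' table (CSV), and a JSON summary with seeds and selected models.
#'
#' @param run a `region_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_region_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_region(run$region, file.path(dir, "region"))
  utils::write.csv(
    dplyr::select(run$detection_scan, -"fit"),
    file.path(dir, "detection_scan.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    dplyr::bind_rows(lapply(run$profiles, tibble::as_tibble)),
    file.path(dir, "scale_profiles.csv"),
    row.names = FALSE
  )
  utils::write.csv(
    dplyr::select(
      run$globals, "scale_label", "set_id", "set_choice",
      "morans_i", "sac_p", "sac_significant", "chi2_obs", "gof_p", "c_hat"
    ),
    file.path(dir, "global_models.csv"),
    row.names = FALSE
  )
  sel <- dplyr::select(
    run$selected, "scale_label", "set_id", "set_choice",
    "psi_label", "p_label", "k", "logLik", "AIC", "AICc", "rn2", "delta",
    "pcc", "auc", "kappa_05", "kappa_opt", "opt_threshold"
  )
  utils::write.csv(sel, file.path(dir, "selected_models.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      seed = run$seed,
      scale_of_effect = run$scale_of_effect,
      selected_models = sel
    ),
    file.path(dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
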