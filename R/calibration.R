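#' Monte-Carlo calibration of the two-step framework
#'
#' Repeatedly simulates the landscape/outcome stage of a study under a
#' given configuration and refits the two-step model, returning one row
#' per simulated study. Used for type-I-error, power,
#' parameter-recovery and two-step-versus-plain-OLS concordance studies.
#'
#' Per study the single-predictor two-step model of pooled predator
#' counts on the standardized forest-edge proportion is always fitted
#' (`est_z`, `p_z` are the raw step-2 slope and its marginal F p-value;
#' the raw slope estimates the abundance slope of the generating
#' process). Optionally also fitted: the four-habitat land-cover model
#' (`fe_std`, `fe_p` for the forest-edge term), the aphid-growth model on
#' `log10(predators + 1)` (`aphid_coef`, `aphid_p`), and the plain
#' all-data OLS of `log10(predators + 1)` on forest edge (`ols_coef`),
#' whose sign can be compared with the step-2 slope.
#'
#' @param n_sims number of simulated studies.
#' @param config a [simulation_config()]; each study uses `seed + i` as
#'   its master seed.
#' @param seed base seed.
#' @param four_habitat,aphid,concordance switches for the optional fits.
#' @return Tibble with one row per study.
#' @export
simulate_recovery <- function(n_sims, config = simulation_config(),
                              seed = 1L, four_habitat = FALSE,
                              aphid = FALSE, concordance = FALSE) {
  props <- paste0("prop_", analysis_categories())
  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    land <- generate_landscapes(cfg)
    out <- generate_field_outcomes(land, cfg)
    gt <- out$ground_truth$landscapes
    d <- tibble(z = gt$forest_edge_z,
                predators = gt$predators,
                growth = gt$aphids_day14 - gt$aphids_day0)
    hs <- fit_two_step(d, "predators", "z")
    est_z <- p_z <- NA_real_
    if (!is.null(hs$step2)) {
      est_z <- hs$step2$coefficients$estimate[1]
      p_z <- hs$step2$coefficients$p_value[1]
    }
    fe_std <- fe_p <- NA_real_
    if (four_habitat) {
      lc <- summarize_landcover(land$patches, sectors = land$sectors)
      d4 <- dplyr::bind_cols(
        d, lc[match(gt$landscape_id, lc$landscape_id), props])
      h4 <- fit_two_step(d4, "predators", props)
      if (!is.null(h4$step2)) {
        co <- h4$step2$coefficients
        fe_std <- co$std_estimate[co$term == "prop_forest_edge"]
        fe_p <- co$p_value[co$term == "prop_forest_edge"]
      }
    }
    aphid_coef <- aphid_p <- NA_real_
    if (aphid) {
      d$log10_predators <- log10(d$predators + 1)
      fa <- fit_ols(d, "growth", "log10_predators")
      aphid_coef <- fa$coefficients$estimate[1]
      aphid_p <- fa$coefficients$p_value[1]
    }
    ols_coef <- NA_real_
    if (concordance) {
      d$log10_all <- log10(d$predators + 1)
      fo <- fit_ols(d, "log10_all", "z")
      ols_coef <- fo$coefficients$estimate[1]
    }
    rows[[i]] <- tibble(
      sim = i, n = nrow(d), zero_count = hs$zero_count,
      step2_ok = !is.null(hs$step2),
      est_z = est_z, p_z = p_z, fe_std = fe_std, fe_p = fe_p,
      aphid_coef = aphid_coef, aphid_p = aphid_p, ols_coef = ols_coef)
  }
  bind_rows(rows)
}
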