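suite_family_defs <- function() {
  lc4 <- paste0("prop_", c("crop", "grassland", "forest_edge", "semi_open"))
  fl4 <- paste0("flor_", c("crop", "grassland", "forest_edge", "semi_open"))
  list(
    pred_landcover_snh = list(response = "predators", type = "hurdle",
                              set = "snh_pooled", predictors = "snh_prop"),
    pred_floral_total = list(response = "predators", type = "hurdle",
                             set = "landscape_flower_total",
                             predictors = "flor_total"),
    pred_landcover_habitats = list(response = "predators", type = "hurdle",
                                   set = "four_habitats_landcover",
                                   predictors = lc4),
    pred_floral_habitats = list(response = "predators", type = "hurdle",
                                set = "four_habitats_floral",
                                predictors = fl4),
    aphid_landcover_snh = list(response = "growth", type = "ols",
                               set = "snh_pooled", predictors = "snh_prop"),
    aphid_floral_total = list(response = "growth", type = "ols",
                              set = "landscape_flower_total",
                              predictors = "flor_total"),
    aphid_landcover_habitats = list(response = "growth", type = "ols",
                                    set = "four_habitats_landcover",
                                    predictors = lc4),
    aphid_floral_habitats = list(response = "growth", type = "ols",
                                 set = "four_habitats_floral",
                                 predictors = fl4),
    aphid_predators = list(response = "growth", type = "ols",
                           set = "predators_log10",
                           predictors = "log10_predators"))
}

#' Assemble the per-landscape analysis frame
#'
#' Joins outcomes, land-cover proportions and pooled floral availability
#' (per habitat and per landscape) into one row per landscape, adds the
#' `log10(predators + offset)` predictor, and z-scores every predictor
#' column so reported coefficients are standardized.
#'
#' @param outcomes outcome table from [build_outcome_table()].
#' @param landcover summary from [summarize_landcover()].
#' @param floral_records availability records from [build_floral_map()].
#' @param predator_offset offset inside `log10(predators + offset)`, so
#'   zero-predator landscapes stay in the aphid model.
#' @return Tibble keyed by `landscape_id`.
#' @export
build_analysis_frame <- function(outcomes, landcover, floral_records,
                                 predator_offset = 1) {
  miss <- function(tbl, what) {
    m <- setdiff(outcomes$landscape_id, tbl$landscape_id)
    if (length(m) > 0) {
      abort(sprintf("landscape(s) missing from %s: %s", what,
                    paste(m, collapse = ", ")))
    }
  }
  miss(landcover, "the land-cover summary")
  miss(floral_records, "the floral map")
  fl_hab <- pool_availability(floral_records, "habitat") %>%
    tidyr::pivot_wider(names_from = "habitat",
                       values_from = "availability",
                       names_prefix = "flor_", values_fill = 0)
  for (ct in paste0("flor_", analysis_categories())) {
    if (!ct %in% names(fl_hab)) fl_hab[[ct]] <- 0
  }
  fl_tot <- pool_availability(floral_records, "landscape") %>%
    rename(flor_total = "availability")
  df <- outcomes %>%
    left_join(select(landcover, "landscape_id",
                     dplyr::starts_with("prop_"), "snh_prop"),
              by = "landscape_id") %>%
    left_join(fl_hab, by = "landscape_id") %>%
    left_join(fl_tot, by = "landscape_id") %>%
    mutate(dplyr::across(dplyr::starts_with("flor_"),
                         ~ coalesce(.x, 0)),
           log10_predators = log10(.data$predators + predator_offset))
  pred_cols <- c(paste0("prop_", analysis_categories()), "snh_prop",
                 paste0("flor_", analysis_categories()), "flor_total",
                 "log10_predators")
  for (cl in pred_cols) {
    s <- sd(df[[cl]])
    if (is.na(s) || s == 0) {
      warn(sprintf(
        "predictor `%s` has zero variance across landscapes; left unscaled",
        cl))
    } else {
      df[[cl]] <- as.numeric(scale(df[[cl]]))
    }
  }
  df
}

#' Fit the full suite of landscape models
#'
#' Mirrors the study's model families: the pooled predator count is
#' modelled with the two-step approach against (i) the pooled SNH
#' proportion, (ii) the landscape flower total, (iii) the four habitat
#' proportions from the land-cover map and (iv) the four habitat flower
#' availabilities; aphid population growth is modelled with plain linear
#' regressions against the same four predictor sets and against
#' `log10(predators + offset)`. Each family is a separate model — no
#' backwards selection. Multi-predictor designs are screened with variance
#' inflation factors (threshold 3).
#'
#' @inheritParams build_analysis_frame
#' @return A `model_suite`: `fits` (named list), `table` (tidy results),
#'   `vif` (screening per multi-predictor family), `data` (analysis
#'   frame).
#' @export
run_model_suite <- function(outcomes, landcover, floral_records,
                            predator_offset = 1) {
  df <- build_analysis_frame(outcomes, landcover, floral_records,
                             predator_offset)
  defs <- suite_family_defs()
  fits <- list()
  vifs <- list()
  for (nm in names(defs)) {
    d <- defs[[nm]]
    if (length(d$predictors) > 1) {
      vifs[[nm]] <- vif_screen(df[, d$predictors])
    }
    fits[[nm]] <- tryCatch(
      if (d$type == "hurdle") {
        fit_two_step(df, d$response, d$predictors)
      } else {
        fit_ols(df, d$response, d$predictors)
      },
      error = function(e) {
        structure(list(reason = conditionMessage(e)),
                  class = "unfit_family")
      })
  }
  structure(list(fits = fits, table = tidy_suite(fits, defs),
                 vif = vifs, data = df),
            class = "model_suite")
}

tidy_one_fit <- function(fr, model, response, set, step_label) {
  if (is.null(fr)) return(NULL)
  co <- fr$coefficients
  if (nrow(co) == 0) {
    co <- tibble(term = "(none)", estimate = NA_real_,
                 std_estimate = NA_real_, statistic = NA_real_,
                 stat_type = NA_character_, p_value = NA_real_)
  }
  tibble(
    model = model, response = response, predictor_set = set,
    step = step_label, n_used = fr$n_used, df = fr$df_residual,
    aicc = fr$aicc, gen_r2 = fr$gen_r2,
    term = co$term, std_coeff = co$std_estimate,
    statistic = co$statistic, stat_type = co$stat_type,
    p_value = co$p_value,
    significant = !is.na(co$p_value) & co$p_value < 0.05)
}

tidy_suite <- function(fits, defs) {
  rows <- list()
  for (nm in names(fits)) {
    d <- defs[[nm]]
    resp <- if (d$response == "predators") "predators" else "aphid_growth"
    f <- fits[[nm]]
    if (inherits(f, "unfit_family")) {
      rows[[nm]] <- tibble(
        model = nm, response = resp, predictor_set = d$set,
        step = "family_unfit", n_used = NA_integer_, df = NA_integer_,
        aicc = NA_real_, gen_r2 = NA_real_, term = NA_character_,
        std_coeff = NA_real_, statistic = NA_real_,
        stat_type = NA_character_, p_value = NA_real_, significant = NA)
    } else if (inherits(f, "hurdle_result")) {
      rows[[paste0(nm, "_1")]] <- tidy_one_fit(f$step1, nm, resp, d$set,
                                               "step1_binomial")
      rows[[paste0(nm, "_2")]] <- tidy_one_fit(f$step2, nm, resp, d$set,
                                               "step2_linear")
      for (st in names(f$unfit)) {
        rows[[paste0(nm, "_", st)]] <- tibble(
          model = nm, response = resp, predictor_set = d$set,
          step = paste0(st, "_unfit"), n_used = NA_integer_,
          df = NA_integer_, aicc = NA_real_, gen_r2 = NA_real_,
          term = NA_character_, std_coeff = NA_real_,
          statistic = NA_real_, stat_type = NA_character_,
          p_value = NA_real_, significant = NA)
      }
    } else {
      rows[[nm]] <- tidy_one_fit(f, nm, resp, d$set, "linear")
    }
  }
  bind_rows(rows)
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("Model suite: %d families, %d landscapes\n",
              length(x$fits), nrow(x$data)))
  sig <- filter(x$table, .data$significant)
  if (nrow(sig) > 0) {
    cat("significant terms (p < 0.05):\n")
    print(as.data.frame(select(sig, "model", "step", "term", "std_coeff",
                               "statistic", "p_value")), digits = 3)
  } else {
    cat("no term significant at p < 0.05\n")
  }
  invisible(x)
}

#' Compare land-cover and floral-map model families
#'
#' Side-by-side AICc and generalized R-squared of the four-habitat
#' land-cover family versus the four-habitat floral family, per response
#' and step, with the AICc difference (floral minus land cover; negative
#' favours the floral map).
#'
#' @param suite a `model_suite`.
#' @return Tibble with one row per response x step.
#' @export
compare_map_types <- function(suite) {
  pairs <- list(
    predators = c("pred_landcover_habitats", "pred_floral_habitats"),
    aphid_growth = c("aphid_landcover_habitats", "aphid_floral_habitats"))
  rows <- list()
  for (resp in names(pairs)) {
    lc <- suite$fits[[pairs[[resp]][1]]]
    fl <- suite$fits[[pairs[[resp]][2]]]
    steps <- if (resp == "predators") {
      list(step1_binomial = c("step1", "step1"),
           step2_linear = c("step2", "step2"))
    } else {
      list(linear = NULL)
    }
    for (st in names(steps)) {
      get_fit <- function(f) {
        if (inherits(f, "unfit_family")) return(NULL)
        if (inherits(f, "hurdle_result")) f[[steps[[st]][1]]] else f
      }
      a <- get_fit(lc); b <- get_fit(fl)
      rows[[paste(resp, st)]] <- tibble(
        response = resp, step = st,
        aicc_landcover = if (is.null(a)) NA_real_ else a$aicc,
        aicc_floral = if (is.null(b)) NA_real_ else b$aicc,
        delta_aicc = if (is.null(a) || is.null(b)) NA_real_ else
          b$aicc - a$aicc,
        gen_r2_landcover = if (is.null(a)) NA_real_ else a$gen_r2,
        gen_r2_floral = if (is.null(b)) NA_real_ else b$gen_r2,
        complete = !is.null(a) && !is.null(b))
    }
  }
  bind_rows(rows)
}
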