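#' Pipeline configuration
#'
#' Either a simulation block (a [simulation_config()]) or an input
#' directory of study files must be supplied — the pipeline then runs
#' generate/load -> land-cover summary -> floral map -> outcome table ->
#' model suite -> report.
#'
#' @param simulate a [simulation_config()], or `NULL` when reading files.
#' @param input_dir directory holding a study bundle (see
#'   [write_study()]), or `NULL` when simulating.
#' @param h_layer flower-bearing layer depth (m) for area-based habitats.
#' @param predator_offset offset in the `log10(predators + offset)`
#'   predictor of the aphid model.
#' @param n_perm permutations for the robustness permutation test.
#' @param seed optional integer overriding the simulation seed; also
#'   seeds the permutation stream.
#' @param outdir optional output directory for report artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = simulation_config(),
                            input_dir = NULL,
                            h_layer = 1,
                            predator_offset = 1,
                            n_perm = 500L,
                            seed = NULL,
                            outdir = NULL) {
  if (is.null(simulate) && is.null(input_dir)) {
    abort("either a simulation block or an input directory is required")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  if (!is.null(simulate) && !is.null(seed)) simulate$seed <- seed
  structure(list(simulate = simulate, input_dir = input_dir,
                 h_layer = h_layer, predator_offset = predator_offset,
                 n_perm = as.integer(n_perm), seed = seed,
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or file-based study and assembles a
#' study report: land-cover summary, floral-map summaries (landscape
#' totals, per-m2 values, diversity shares per habitat), the
#' Table-shaped model results with VIF screening, the land-cover versus
#' floral-map comparison, a permutation test of the aphid-versus-predators
#' relationship, and a provenance block. With a fixed configuration and
#' seed, two runs produce byte-identical output files.
#'
#' @param config a [pipeline_config()].
#' @return A `study_report`, invisibly when written to disk.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config")
  }
  study <- if (!is.null(config$input_dir)) {
    read_study(config$input_dir)
  } else {
    generate_study(config$simulate)
  }
  landcover <- summarize_landcover(study$patches, sectors = study$sectors)
  floral_map <- build_floral_map(study$surveys, study$species,
                                 study$patches, h_layer = config$h_layer)
  outcomes <- build_outcome_table(study$predator_obs, study$aphid_counts)
  suite <- run_model_suite(outcomes, landcover, floral_map,
                           predator_offset = config$predator_offset)
  comparison <- compare_map_types(suite)
  perm_seed <- (if (!is.null(config$seed)) config$seed
                else study$config$seed) + 505L
  perm <- permutation_test(
    y = outcomes$growth,
    x = log10(outcomes$predators + config$predator_offset),
    n_perm = config$n_perm, seed = perm_seed)

  hab_areas <- study$patches %>%
    group_by(.data$landscape_id, habitat = .data$category) %>%
    summarise(area_m2 = sum(.data$area_m2), .groups = "drop")
  radius <- study$sectors$radius_m[1]
  floral_landscape <- pool_availability(floral_map, "landscape",
                                        per_m2 = TRUE, radius = radius)
  floral_habitat <- pool_availability(floral_map, "habitat",
                                      per_m2 = TRUE, areas = hab_areas)
  diversity <- floral_diversity(floral_map, "habitat")

  report <- structure(
    list(landcover = landcover,
         floral_map = floral_map,
         floral_landscape = floral_landscape,
         floral_habitat = floral_habitat,
         diversity = diversity,
         outcomes = outcomes,
         suite = suite,
         comparison = comparison,
         permutation = perm,
         provenance = list(
           package = "aphidscape",
           package_version = as.character(utils::packageVersion("aphidscape")),
           seed = if (!is.null(config$seed)) config$seed else
             study$config$seed,
           n_landscapes = nrow(landcover),
           n_species = nrow(study$species),
           h_layer = config$h_layer,
           predator_offset = config$predator_offset,
           n_perm = config$n_perm)),
    class = "study_report")

  if (!is.null(config$outdir)) {
    write_report(report, config$outdir)
    return(invisible(report))
  }
  report
}

#' Write report artifacts as plain-text files
#'
#' @param report a `study_report`.
#' @param outdir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  readr::write_csv(report$landcover, p("landcover_summary.csv"))
  readr::write_csv(report$floral_map, p("floral_map.csv"))
  readr::write_csv(report$floral_landscape, p("floral_landscape.csv"))
  readr::write_csv(report$floral_habitat, p("floral_habitat.csv"))
  readr::write_csv(report$diversity$shares, p("floral_shares.csv"))
  readr::write_csv(report$outcomes, p("outcomes.csv"))
  readr::write_csv(report$suite$table, p("model_results.csv"))
  readr::write_csv(report$comparison, p("map_comparison.csv"))
  vif_tbl <- bind_rows(lapply(names(report$suite$vif), function(nm) {
    v <- report$suite$vif[[nm]]
    tibble(model = nm, predictor = names(v$vif), vif = unname(v$vif),
           pass = v$pass)
  }))
  readr::write_csv(vif_tbl, p("vif.csv"))
  jsonlite::write_json(
    list(provenance = report$provenance,
         permutation = unclass(report$permutation)),
    p("report.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Landscape study report\n")
  cat(sprintf("  %d landscapes; SNH proportion %.3f-%.3f\n",
              nrow(x$landcover), min(x$landcover$snh_prop),
              max(x$landcover$snh_prop)))
  cat(sprintf("  floral availability per landscape: %.3g-%.3g m3*days\n",
              min(x$floral_landscape$availability),
              max(x$floral_landscape$availability)))
  cat(sprintf("  predators present in %d/%d landscapes\n",
              sum(x$outcomes$present), nrow(x$outcomes)))
  print(x$suite)
  cat("map comparison (delta AICc = floral - land cover):\n")
  print(as.data.frame(x$comparison), digits = 4)
  print(x$permutation)
  invisible(x)
}
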