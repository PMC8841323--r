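#' Configuration for a synthetic landscape study
#'
#' Bundles every parameter of the synthetic data-generating process: the
#' layout of circular landscape sectors, the species pool and its floral
#' traits, the flower-density model per habitat, and the
#' presence/abundance/aphid-growth process observed on the phytometer
#' plants.
#'
#' The default values describe a study of 19 sectors of 500 m radius whose
#' habitat composition (forest edge, semi-open habitat, grassland, crop and
#' a residual "other" class) is drawn from a Dirichlet distribution with
#' mean shares of roughly 4 / 5 / 12 / 30 / 49 percent. Predator presence
#' follows a logistic model on the standardized forest-edge proportion and,
#' conditional on presence, pooled predator counts are log-normal on the
#' log10 scale; aphid population growth declines linearly in
#' `log10(predators + 1)`.
#'
#' @param n_landscapes number of circular landscape sectors (>= 1).
#' @param sector_radius sector radius in metres.
#' @param habitat_mix named Dirichlet concentration parameters over the five
#'   habitat categories; means are `habitat_mix / sum(habitat_mix)`.
#' @param n_species size of the flowering species pool (0 allowed).
#' @param trait_ranges list with elements `flower_size` (m^3 per flower,
#'   lower/upper) and `flowering_duration` (days, lower/upper). Flower sizes
#'   are drawn log-uniformly, durations uniformly.
#' @param density_model named vector of mean log10 flower density
#'   (flowers/m^3) for species whose primary habitat is each analysis
#'   category.
#' @param density_sd between-species standard deviation of log10 density.
#' @param presence_intercept,presence_slope logistic (logit-scale) intercept
#'   and slope of predator presence on the standardized forest-edge
#'   proportion.
#' @param abundance_intercept,abundance_slope,abundance_sd log10-scale
#'   intercept, slope and residual standard deviation of pooled predator
#'   counts conditional on presence.
#' @param aphid_intercept,aphid_slope,aphid_sd linear model of aphid
#'   population growth (aphids per landscape over 14 days) on
#'   `log10(predators + 1)`, plus its residual standard deviation.
#' @param start_aphids_per_plant expected starting aphid infestation per
#'   phytometer plant.
#' @param n_plants phytometer plants per landscape.
#' @param seed integer master seed; each generator uses a fixed offset of
#'   this seed so components can be regenerated independently.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_landscapes = 19L,
                              sector_radius = 500,
                              habitat_mix = c(forest_edge = 0.8,
                                              semi_open = 1.0,
                                              grassland = 2.4,
                                              crop = 6.0,
                                              other = 9.8),
                              n_species = 40L,
                              trait_ranges = list(
                                flower_size = c(1e-8, 1e-5),
                                flowering_duration = c(7, 42)),
                              density_model = c(forest_edge = 1.7,
                                                semi_open = 1.7,
                                                grassland = 1.0,
                                                crop = 1.5),
                              density_sd = 0.4,
                              presence_intercept = 1.3,
                              presence_slope = 1.0,
                              abundance_intercept = 0.9,
                              abundance_slope = 0.5,
                              abundance_sd = 0.3,
                              aphid_intercept = 1200,
                              aphid_slope = -300,
                              aphid_sd = 250,
                              start_aphids_per_plant = 20L,
                              n_plants = 10L,
                              seed = 1L) {
  cfg <- list(
    n_landscapes = as.integer(n_landscapes),
    sector_radius = sector_radius,
    habitat_mix = habitat_mix,
    n_species = as.integer(n_species),
    trait_ranges = trait_ranges,
    density_model = density_model,
    density_sd = density_sd,
    presence_intercept = presence_intercept,
    presence_slope = presence_slope,
    abundance_intercept = abundance_intercept,
    abundance_slope = abundance_slope,
    abundance_sd = abundance_sd,
    aphid_intercept = aphid_intercept,
    aphid_slope = aphid_slope,
    aphid_sd = aphid_sd,
    start_aphids_per_plant = as.integer(start_aphids_per_plant),
    n_plants = as.integer(n_plants),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_landscapes < 1L) abort("`n_landscapes` must be >= 1")
  if (cfg$n_species < 0L) abort("`n_species` must be >= 0")
  if (cfg$n_plants < 1L) abort("`n_plants` must be >= 1")
  if (cfg$start_aphids_per_plant < 1L) {
    abort("`start_aphids_per_plant` must be >= 1")
  }
  if (!is.numeric(cfg$sector_radius) || cfg$sector_radius <= 0) {
    abort("`sector_radius` must be > 0")
  }
  if (!setequal(names(cfg$habitat_mix), habitat_categories())) {
    abort("`habitat_mix` must be named by the five habitat categories")
  }
  if (any(cfg$habitat_mix <= 0)) {
    abort("`habitat_mix` concentrations must all be > 0")
  }
  for (nm in c("flower_size", "flowering_duration")) {
    b <- cfg$trait_ranges[[nm]]
    if (is.null(b) || length(b) != 2 || any(b <= 0) || b[1] > b[2]) {
      abort(sprintf(
        "`trait_ranges$%s` must be two positive, ordered bounds", nm))
    }
  }
  if (!all(analysis_categories() %in% names(cfg$density_model))) {
    abort("`density_model` must name all four analysis categories")
  }
  if (cfg$density_sd < 0) abort("`density_sd` must be >= 0")
  if (cfg$abundance_sd < 0 || cfg$aphid_sd < 0) {
    abort("residual standard deviations must be >= 0")
  }
  if (is.na(cfg$seed)) abort("`seed` must be a finite integer")
  invisible(cfg)
}

# fixed per-component seed offsets, so e.g. regenerating outcomes alone
# reproduces exactly what generate_study() produced
seed_offsets <- c(species = 101L, landscapes = 202L, surveys = 303L,
                  outcomes = 404L)

landscape_ids <- function(n) {
  sprintf("L%0*d", max(2L, nchar(n)), seq_len(n))
}

#' Draw a synthetic flowering species pool
#'
#' Each species gets a primary habitat affinity, floral traits (flower size
#' drawn log-uniformly, flowering duration uniformly within the configured
#' bounds), a growth form implied by its habitat (woody for forest edge and
#' semi-open habitat, crop plants for crops, herbaceous otherwise) and a
#' mean flower density in its primary habitat. A fraction of grassland
#' species are grasses, which are flagged for exclusion from floral-resource
#' mapping.
#'
#' @param config a [simulation_config()].
#' @return Tibble with one row per species: `species_id`, `flower_size_m3`,
#'   `flowering_duration_days`, `growth_form`, `is_grass`,
#'   `insect_pollinated`, `affinity`, `crop_type`, `mean_density`.
#' @export
generate_species_pool <- function(config) {
  validate_simulation_config(config)
  n <- config$n_species
  empty <- tibble(
    species_id = character(), flower_size_m3 = double(),
    flowering_duration_days = double(), growth_form = character(),
    is_grass = logical(), insect_pollinated = logical(),
    affinity = character(), crop_type = character(),
    mean_density = double())
  if (n == 0L) return(empty)
  set.seed(config$seed + seed_offsets[["species"]])
  affinity <- sample(c("grassland", "forest_edge", "semi_open", "crop"),
                     n, replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.2))
  growth_form <- case_when(
    affinity == "grassland" ~ "herbaceous",
    affinity == "crop" ~ "crop",
    TRUE ~ "woody")
  is_grass <- affinity == "grassland" & runif(n) < 0.15
  sb <- log10(config$trait_ranges$flower_size)
  size <- 10^runif(n, sb[1], sb[2])
  db <- config$trait_ranges$flowering_duration
  duration <- runif(n, db[1], db[2])
  crop_type <- ifelse(
    affinity == "crop",
    sample(insect_pollinated_crops(), n, replace = TRUE),
    NA_character_)
  mean_density <- 10^(config$density_model[affinity] +
                        rnorm(n, 0, config$density_sd))
  tibble(
    species_id = sprintf("sp%03d", seq_len(n)),
    flower_size_m3 = size,
    flowering_duration_days = duration,
    growth_form = growth_form,
    is_grass = is_grass,
    insect_pollinated = !is_grass,
    affinity = affinity,
    crop_type = crop_type,
    mean_density = unname(mean_density))
}

#' Draw synthetic landscape sectors and their habitat patches
#'
#' Habitat composition of each circular sector is a Dirichlet draw over the
#' five categories, scaled to the sector area `pi * radius^2`; each
#' category's area is then split among its sub-categories (again Dirichlet,
#' uniform concentrations) to yield a patch table in the same schema the
#' land-cover reader consumes.
#'
#' @param config a [simulation_config()].
#' @return List with `sectors` (tibble `landscape_id`, `radius_m`) and
#'   `patches` (tibble `landscape_id`, `category`, `sub_category`,
#'   `area_m2`).
#' @export
generate_landscapes <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed + seed_offsets[["landscapes"]])
  n <- config$n_landscapes
  cats <- habitat_categories()
  alpha <- config$habitat_mix[cats]
  g <- matrix(rgamma(n * length(cats), shape = rep(alpha, each = n)),
              nrow = n)
  props <- g / rowSums(g)
  areas <- props * sector_area_m2(config$sector_radius)
  ids <- landscape_ids(n)
  subs <- sub_category_table()
  patch_list <- lapply(seq_along(cats), function(j) {
    sc <- subs[[cats[j]]]
    k <- length(sc)
    if (k == 1L) {
      w <- matrix(1, n, 1)
    } else {
      gw <- matrix(rgamma(n * k, shape = 1), nrow = n)
      w <- gw / rowSums(gw)
    }
    tibble(
      landscape_id = rep(ids, times = k),
      category = cats[j],
      sub_category = rep(sc, each = n),
      area_m2 = as.vector(areas[, j] * w))
  })
  patches <- bind_rows(patch_list) %>%
    arrange(.data$landscape_id, .data$category, .data$sub_category)
  list(
    sectors = tibble(landscape_id = ids, radius_m = config$sector_radius),
    patches = patches)
}

#' Simulate the flower-survey field campaign
#'
#' Emulates the three survey protocols: grassland assessment cubes (10
#' cubes x 3 rounds per grassland sub-type per landscape, Poisson counts
#' around the species' habitat mean density), woody transects (a
#' flower-bearing volume per woody element and species) with a calibration
#' set of 10 individuals x 2 cubes per woody species, and crop field
#' surveys (10 fields per insect-pollinated crop type, cube protocol as in
#' grassland). Grasses are never surveyed.
#'
#' @param landscapes output of [generate_landscapes()].
#' @param species_pool output of [generate_species_pool()].
#' @param config a [simulation_config()].
#' @return List of tibbles: `grassland_cubes`, `woody_transects`,
#'   `woody_calibration`, `crop_fields`.
#' @export
generate_flower_surveys <- function(landscapes, species_pool, config) {
  validate_simulation_config(config)
  if (nrow(species_pool) == 0L) {
    abort("cannot simulate flower surveys from an empty species pool")
  }
  patches <- landscapes$patches
  if (is.null(patches) || nrow(patches) == 0L) {
    abort("`landscapes` must contain a non-empty patch table")
  }
  set.seed(config$seed + seed_offsets[["surveys"]])
  surveyable <- filter(species_pool, !.data$is_grass)

  # grassland: 10 cubes x 3 rounds per (landscape, sub-type, species)
  gr_species <- filter(surveyable, .data$affinity == "grassland")
  gr_patches <- patches %>%
    filter(.data$category == "grassland") %>%
    distinct(.data$landscape_id, .data$sub_category)
  grassland_cubes <- tidyr::crossing(
    gr_patches,
    select(gr_species, "species_id", "mean_density"),
    round = 1:3, cube_index = 1:10) %>%
    mutate(flower_count = rpois(n(), .data$mean_density)) %>%
    select("landscape_id", "sub_category", "species_id", "round",
           "cube_index", "flower_count")

  # woody elements: one transect volume per (element, woody species)
  wd_species <- filter(surveyable, .data$growth_form == "woody")
  elements <- patches %>%
    filter(.data$category %in% c("forest_edge", "semi_open")) %>%
    group_by(.data$landscape_id) %>%
    mutate(element_id = sprintf("%s_%s_%02d", .data$landscape_id,
                                .data$sub_category, row_number())) %>%
    ungroup()
  n_wd <- max(1L, nrow(wd_species))
  woody_transects <- tidyr::crossing(
    select(elements, "landscape_id", "element_id", "category",
           "sub_category", "area_m2"),
    species_id = wd_species$species_id) %>%
    mutate(flower_volume_m3 = .data$area_m2 *
             rlnorm(n(), meanlog = log(0.3 / n_wd), sdlog = 0.5)) %>%
    select("landscape_id", "element_id", "category", "sub_category",
           "species_id", "flower_volume_m3")

  woody_calibration <- tidyr::crossing(
    select(wd_species, "species_id", "mean_density"),
    individual = 1:10, cube_index = 1:2) %>%
    mutate(flower_count = rpois(n(), .data$mean_density)) %>%
    select("species_id", "individual", "cube_index", "flower_count")

  # crops: 10 fields per crop type, cube protocol as in grassland
  cr_species <- filter(surveyable, .data$affinity == "crop",
                       .data$insect_pollinated)
  crop_fields <- tidyr::crossing(
    select(cr_species, "crop_type", "species_id", "mean_density"),
    field_index = 1:10, round = 1:3, cube_index = 1:10) %>%
    mutate(flower_count = rpois(n(), .data$mean_density)) %>%
    select("crop_type", "field_index", "species_id", "round",
           "cube_index", "flower_count")

  list(grassland_cubes = grassland_cubes,
       woody_transects = woody_transects,
       woody_calibration = woody_calibration,
       crop_fields = crop_fields)
}

#' Simulate phytometer outcomes (predators and aphid growth)
#'
#' Predator presence per sector follows
#' `Bernoulli(plogis(a0 + a1 * z))`, with `z` the forest-edge proportion
#' standardized across sectors. Conditional on presence, the pooled
#' predator count is `max(1, round(10^(b0 + b1 * z + eps)))` with Gaussian
#' `eps`, so all zeros come from the presence step (an exact hurdle).
#' Starting aphids are Poisson around the intended infestation; growth is
#' `g0 + g1 * log10(P + 1)` plus Gaussian noise, and the day-14 census is
#' floored at zero. Counts are scattered over plants, sampling rounds,
#' taxa and life stages so the survey-pooling step has raw records to work
#' on; a small number of flagged non-target aphid records is added.
#'
#' @param landscapes output of [generate_landscapes()].
#' @param config a [simulation_config()].
#' @return List with `predator_obs`, `aphid_counts` (record tibbles) and
#'   `ground_truth` (realized parameters and per-landscape latent states).
#' @export
generate_field_outcomes <- function(landscapes, config) {
  validate_simulation_config(config)
  set.seed(config$seed + seed_offsets[["outcomes"]])
  patches <- landscapes$patches
  r <- config$sector_radius
  fe <- patches %>%
    filter(.data$category == "forest_edge") %>%
    group_by(.data$landscape_id) %>%
    summarise(fe_area = sum(.data$area_m2), .groups = "drop")
  sect <- landscapes$sectors %>%
    left_join(fe, by = "landscape_id") %>%
    mutate(fe_prop = coalesce(.data$fe_area, 0) / sector_area_m2(r))
  n <- nrow(sect)
  z <- if (n > 1 && sd(sect$fe_prop) > 0) {
    as.numeric(scale(sect$fe_prop))
  } else {
    rep(0, n)
  }
  present <- rbinom(n, 1, plogis(config$presence_intercept +
                                   config$presence_slope * z)) == 1
  eps <- rnorm(n, 0, config$abundance_sd)
  predators <- ifelse(
    present,
    pmax(1, round(10^(config$abundance_intercept +
                        config$abundance_slope * z + eps))),
    0)
  day0_plants <- matrix(
    rpois(n * config$n_plants, config$start_aphids_per_plant),
    nrow = n)
  day0 <- rowSums(day0_plants)
  growth_true <- config$aphid_intercept +
    config$aphid_slope * log10(predators + 1) +
    rnorm(n, 0, config$aphid_sd)
  day14 <- pmax(0, day0 + round(growth_true))

  ids <- sect$landscape_id

  # scatter pooled predator counts over plants x rounds x taxa x stages
  total <- sum(predators)
  predator_obs <- tibble(
    landscape_id = character(), plant = integer(), round = character(),
    taxon = character(), stage = character(), count = integer())
  if (total > 0) {
    obs <- tibble(
      landscape_id = rep(ids, times = predators),
      plant = sample.int(config$n_plants, total, replace = TRUE),
      round = sample(predator_rounds(), total, replace = TRUE),
      taxon = sample(predator_taxa(), total, replace = TRUE,
                     prob = c(0.63, 0.28, 0.09)),
      stage = sample(predator_stages(), total, replace = TRUE,
                     prob = c(0.3, 0.4, 0.3)))
    predator_obs <- obs %>%
      count(.data$landscape_id, .data$plant, .data$round, .data$taxon,
            .data$stage, name = "count") %>%
      ungroup()
  }

  # per-plant aphid censuses; day-14 totals scattered multinomially
  day0_rec <- tibble(
    landscape_id = rep(ids, each = config$n_plants),
    plant = rep(seq_len(config$n_plants), times = n),
    day = 0L,
    species_flag = "target",
    count = as.integer(t(day0_plants)))
  day14_counts <- lapply(seq_len(n), function(i) {
    if (day14[i] == 0) return(integer(config$n_plants))
    as.integer(stats::rmultinom(1, day14[i],
                                rep(1, config$n_plants))[, 1])
  })
  day14_rec <- tibble(
    landscape_id = rep(ids, each = config$n_plants),
    plant = rep(seq_len(config$n_plants), times = n),
    day = 14L,
    species_flag = "target",
    count = unlist(day14_counts))
  nontarget <- tibble(
    landscape_id = ids,
    plant = sample.int(config$n_plants, n, replace = TRUE),
    day = 14L,
    species_flag = "nontarget",
    count = rpois(n, 1))
  aphid_counts <- bind_rows(day0_rec, day14_rec, nontarget) %>%
    filter(.data$count > 0 | .data$species_flag == "target") %>%
    arrange(.data$landscape_id, .data$day, .data$plant)

  ground_truth <- list(
    parameters = list(
      presence_intercept = config$presence_intercept,
      presence_slope = config$presence_slope,
      abundance_intercept = config$abundance_intercept,
      abundance_slope = config$abundance_slope,
      abundance_sd = config$abundance_sd,
      aphid_intercept = config$aphid_intercept,
      aphid_slope = config$aphid_slope,
      aphid_sd = config$aphid_sd),
    landscapes = tibble(
      landscape_id = ids,
      forest_edge_prop = sect$fe_prop,
      forest_edge_z = z,
      present = present,
      predators = as.integer(predators),
      aphids_day0 = as.integer(day0),
      aphids_day14 = as.integer(day14),
      growth_latent = growth_true))

  list(predator_obs = predator_obs, aphid_counts = aphid_counts,
       ground_truth = ground_truth)
}

#' Generate a complete synthetic study
#'
#' One call produces a self-consistent bundle: species pool, landscape
#' sectors and patches, the three flower-survey tables, phytometer records
#' and the ground truth used to generate them.
#'
#' @param config a [simulation_config()].
#' @return An object of class `aphid_study`.
#' @export
generate_study <- function(config = simulation_config()) {
  validate_simulation_config(config)
  pool <- generate_species_pool(config)
  land <- generate_landscapes(config)
  surveys <- generate_flower_surveys(land, pool, config)
  out <- generate_field_outcomes(land, config)
  structure(
    list(config = config,
         species = pool,
         sectors = land$sectors,
         patches = land$patches,
         surveys = surveys,
         predator_obs = out$predator_obs,
         aphid_counts = out$aphid_counts,
         ground_truth = out$ground_truth),
    class = "aphid_study")
}

#' @export
print.aphid_study <- function(x, ...) {
  gt <- x$ground_truth$landscapes
  cat("Synthetic landscape study\n")
  cat(sprintf("  %d sectors of %g m radius, %d species\n",
              nrow(x$sectors), x$config$sector_radius, nrow(x$species)))
  cat(sprintf("  predators present in %d/%d landscapes (total %d)\n",
              sum(gt$present), nrow(gt), sum(gt$predators)))
  cat(sprintf("  mean aphid growth %.1f (day 0 mean %.1f, day 14 mean %.1f)\n",
              mean(gt$aphids_day14 - gt$aphids_day0),
              mean(gt$aphids_day0), mean(gt$aphids_day14)))
  invisible(x)
}

#' Write or read a study bundle as plain-text files
#'
#' The bundle is written as the same CSV schemas the pipeline readers
#' consume, plus the configuration and ground truth as JSON.
#'
#' @param study an `aphid_study`.
#' @param dir output directory (created if needed).
#' @return `write_study()` the directory, invisibly; `read_study()` an
#'   `aphid_study`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(study$species, p("species.csv"))
  readr::write_csv(study$sectors, p("sectors.csv"))
  readr::write_csv(study$patches, p("patches.csv"))
  readr::write_csv(study$surveys$grassland_cubes, p("grassland_cubes.csv"))
  readr::write_csv(study$surveys$woody_transects, p("woody_transects.csv"))
  readr::write_csv(study$surveys$woody_calibration,
                   p("woody_calibration.csv"))
  readr::write_csv(study$surveys$crop_fields, p("crop_fields.csv"))
  readr::write_csv(study$predator_obs, p("predator_observations.csv"))
  readr::write_csv(study$aphid_counts, p("aphid_counts.csv"))
  cfg <- study$config
  class(cfg) <- NULL
  # named vectors must become lists to keep their names in JSON
  cfg$habitat_mix <- as.list(cfg$habitat_mix)
  cfg$density_model <- as.list(cfg$density_model)
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  gt <- study$ground_truth
  jsonlite::write_json(gt, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("species.csv", "patches.csv", "sectors.csv", "config.json")) {
    if (!file.exists(p(f))) abort(sprintf("missing study file: %s", p(f)))
  }
  cfg_raw <- jsonlite::read_json(p("config.json"), simplifyVector = TRUE)
  cfg_raw$habitat_mix <- unlist(cfg_raw$habitat_mix)
  cfg_raw$density_model <- unlist(cfg_raw$density_model)
  config <- do.call(simulation_config, cfg_raw)
  rd <- function(f, types) readr::read_csv(p(f), col_types = types)
  gt_raw <- jsonlite::read_json(p("ground_truth.json"),
                                simplifyVector = TRUE)
  gt_raw$landscapes <- as_tibble(gt_raw$landscapes)
  structure(
    list(config = config,
         species = rd("species.csv", "cddcllccd"),
         sectors = rd("sectors.csv", "cd"),
         patches = rd("patches.csv", "cccd"),
         surveys = list(
           grassland_cubes = rd("grassland_cubes.csv", "ccciii"),
           woody_transects = rd("woody_transects.csv", "cccccd"),
           woody_calibration = rd("woody_calibration.csv", "ciii"),
           crop_fields = rd("crop_fields.csv", "ciciii")),
         predator_obs = rd("predator_observations.csv", "ciccci"),
         aphid_counts = rd("aphid_counts.csv", "ciici"),
         ground_truth = gt_raw),
    class = "aphid_study")
}
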