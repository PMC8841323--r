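#' Flower density from assessment cubes (herbaceous protocol)
#'
#' Density of one species in one grassland (or crop-field) survey unit:
#' the mean over sampling rounds of the per-round mean count across the
#' 1 m3 assessment cubes. Rounds are averaged, not summed — phenology is
#' carried by the flowering duration, not by repeated counting.
#'
#' @param cubes tibble of cube records with columns `round` and
#'   `flower_count` for a single landscape x sub-type x species group.
#' @return Flower density in flowers/m3.
#' @export
estimate_density_herb <- function(cubes) {
  if (is.null(cubes) || nrow(cubes) == 0) {
    abort("no cube records: cannot distinguish 'not surveyed' from zero")
  }
  round_means <- cubes %>%
    group_by(.data$round) %>%
    summarise(m = mean(.data$flower_count), .groups = "drop")
  mean(round_means$m)
}

#' Flower density from woody calibration cubes
#'
#' Density for a woody species: the mean over calibration individuals of
#' each individual's mean count across its (up to two) 1 m3 crown cubes.
#'
#' @param calib tibble of calibration records with columns `individual`
#'   and `flower_count` for a single species.
#' @return Flower density in flowers/m3.
#' @export
estimate_density_woody <- function(calib) {
  if (is.null(calib) || nrow(calib) == 0) {
    abort("no calibration records for this species")
  }
  ind_means <- calib %>%
    group_by(.data$individual) %>%
    summarise(m = mean(.data$flower_count), .groups = "drop")
  mean(ind_means$m)
}

#' Species flower number in a landscape
#'
#' Woody species: density times the summed flower-bearing transect volume.
#' Herbaceous and crop species: density times habitat area times the
#' flower-bearing layer depth `h_layer` (default 1 m, the assessment-cube
#' height), which closes the units of a per-m3 density applied to an area.
#'
#' @param density flowers/m3.
#' @param measure flower-bearing volume in m3 (woody) or habitat area in
#'   m2 (herbaceous/crop).
#' @param growth_form `"woody"`, `"herbaceous"` or `"crop"`.
#' @param h_layer flower-bearing layer depth in m for area-based habitats.
#' @return Number of flowers (vectorised).
#' @export
flower_number <- function(density, measure, growth_form, h_layer = 1) {
  if (any(density < 0) || any(measure < 0) || h_layer <= 0) {
    abort("densities, areas/volumes and `h_layer` must be non-negative")
  }
  ifelse(growth_form == "woody", density * measure,
         density * measure * h_layer)
}

#' Floral resource availability of a species
#'
#' Availability is flower number times flower size (bounding volume of one
#' open flower, m3) times flowering duration (days): the total
#' flower-volume-by-time offered. Grasses are excluded from floral mapping
#' and must not reach this computation.
#'
#' @param n flower number.
#' @param flower_size m3 per flower.
#' @param flowering_duration days.
#' @param is_grass logical exclusion flag (vectorised).
#' @return Availability F in m3 * days.
#' @export
flower_availability <- function(n, flower_size, flowering_duration,
                                is_grass = FALSE) {
  if (any(is_grass)) {
    abort("grass species must be excluded before computing availability")
  }
  if (any(n < 0) || any(flower_size <= 0) || any(flowering_duration <= 0)) {
    abort("flower numbers must be >= 0 and traits > 0")
  }
  n * flower_size * flowering_duration
}

two_stage_mean <- function(df, outer, value = "flower_count") {
  df %>%
    group_by(across(all_of(outer))) %>%
    summarise(m = mean(.data[[value]]), .groups = "drop") %>%
    pull(.data$m) %>%
    mean()
}

#' Build the floral resource map from survey records
#'
#' Combines the three survey protocols into per-(landscape, habitat,
#' species) availability records. Grassland densities estimated in the
#' representative patch of a management sub-type are applied to all area
#' of that sub-type in the landscape; a (landscape, sub-type, species)
#' combination without its own survey falls back to the across-landscape
#' mean density of that sub-type and is flagged `imputed`. Woody species
#' densities come from the calibration cubes and are applied to the summed
#' flower-bearing transect volumes per landscape and category; crop
#' densities are estimated per crop type across its surveyed fields and
#' applied to the crop-type area per landscape. Grasses never enter the
#' map.
#'
#' @param surveys list of survey tibbles (`grassland_cubes`,
#'   `woody_transects`, `woody_calibration`, `crop_fields`), as generated
#'   by [generate_flower_surveys()] or read from files.
#' @param species species trait table (`species_id`, `flower_size_m3`,
#'   `flowering_duration_days`, `growth_form`, `is_grass`).
#' @param patches habitat patch table.
#' @param h_layer flower-bearing layer depth (m) for area-based habitats.
#' @return Tibble of availability records: `landscape_id`, `habitat`,
#'   `sub_category`, `species_id`, `density`, `flower_number`,
#'   `availability`, `imputed`.
#' @export
build_floral_map <- function(surveys, species, patches, h_layer = 1) {
  traits <- species %>%
    select("species_id", "flower_size_m3", "flowering_duration_days",
           "growth_form", "is_grass")
  pieces <- list()

  # grassland cubes -> density per (landscape, sub-type, species)
  gc <- surveys$grassland_cubes
  if (!is.null(gc) && nrow(gc) > 0) {
    dens <- gc %>%
      group_by(.data$landscape_id, .data$sub_category, .data$species_id,
               .data$round) %>%
      summarise(m = mean(.data$flower_count), .groups = "drop") %>%
      group_by(.data$landscape_id, .data$sub_category, .data$species_id) %>%
      summarise(density = mean(.data$m), .groups = "drop")
    sub_means <- dens %>%
      group_by(.data$sub_category, .data$species_id) %>%
      summarise(density_pool = mean(.data$density), .groups = "drop")
    gr_areas <- patches %>%
      filter(.data$category == "grassland") %>%
      group_by(.data$landscape_id, .data$sub_category) %>%
      summarise(area_m2 = sum(.data$area_m2), .groups = "drop")
    grid <- inner_join(gr_areas, sub_means, by = "sub_category",
                       relationship = "many-to-many") %>%
      left_join(dens, by = c("landscape_id", "sub_category", "species_id")) %>%
      mutate(imputed = is.na(.data$density),
             density = coalesce(.data$density, .data$density_pool))
    n_imp <- sum(grid$imputed)
    if (n_imp > 0) {
      inform(sprintf(
        "%d grassland density value(s) imputed from sub-type means", n_imp))
    }
    pieces$grassland <- grid %>%
      mutate(habitat = "grassland",
             flower_number = .data$density * .data$area_m2 * h_layer) %>%
      select("landscape_id", "habitat", "sub_category", "species_id",
             "density", "flower_number", "imputed")
  }

  # woody calibration -> one density per species, applied to transect volumes
  wc <- surveys$woody_calibration
  wt <- surveys$woody_transects
  if (!is.null(wt) && nrow(wt) > 0) {
    if (is.null(wc) || nrow(wc) == 0) {
      abort("woody transects present but no calibration cubes")
    }
    wdens <- wc %>%
      group_by(.data$species_id, .data$individual) %>%
      summarise(m = mean(.data$flower_count), .groups = "drop") %>%
      group_by(.data$species_id) %>%
      summarise(density = mean(.data$m), .groups = "drop")
    missing <- setdiff(unique(wt$species_id), wdens$species_id)
    if (length(missing) > 0) {
      abort(sprintf("no calibration cubes for woody species: %s",
                    paste(missing, collapse = ", ")))
    }
    pieces$woody <- wt %>%
      group_by(.data$landscape_id, .data$category, .data$species_id) %>%
      summarise(volume_m3 = sum(.data$flower_volume_m3), .groups = "drop") %>%
      left_join(wdens, by = "species_id") %>%
      mutate(habitat = .data$category,
             sub_category = .data$category,
             flower_number = .data$density * .data$volume_m3,
             imputed = FALSE) %>%
      select("landscape_id", "habitat", "sub_category", "species_id",
             "density", "flower_number", "imputed")
  }

  # crop fields -> one density per (crop type, species), applied to crop area
  cf <- surveys$crop_fields
  if (!is.null(cf) && nrow(cf) > 0) {
    cdens <- cf %>%
      group_by(.data$crop_type, .data$species_id, .data$field_index,
               .data$round) %>%
      summarise(m = mean(.data$flower_count), .groups = "drop") %>%
      group_by(.data$crop_type, .data$species_id, .data$field_index) %>%
      summarise(m = mean(.data$m), .groups = "drop") %>%
      group_by(.data$crop_type, .data$species_id) %>%
      summarise(density = mean(.data$m), .groups = "drop")
    crop_areas <- patches %>%
      filter(.data$category == "crop") %>%
      group_by(.data$landscape_id, .data$sub_category) %>%
      summarise(area_m2 = sum(.data$area_m2), .groups = "drop")
    pieces$crop <- inner_join(
      crop_areas, cdens, by = c(sub_category = "crop_type"),
      relationship = "many-to-many") %>%
      mutate(habitat = "crop",
             flower_number = .data$density * .data$area_m2 * h_layer,
             imputed = FALSE) %>%
      select("landscape_id", "habitat", "sub_category", "species_id",
             "density", "flower_number", "imputed")
  }

  records <- bind_rows(pieces)
  if (nrow(records) == 0) {
    abort("no survey records: cannot build a floral resource map")
  }
  unknown <- setdiff(unique(records$species_id), traits$species_id)
  if (length(unknown) > 0) {
    abort(sprintf("surveyed species missing from the trait table: %s",
                  paste(unknown, collapse = ", ")))
  }
  records <- records %>%
    left_join(traits, by = "species_id") %>%
    filter(!.data$is_grass)
  records$availability <- flower_availability(
    records$flower_number, records$flower_size_m3,
    records$flowering_duration_days, records$is_grass)
  records %>%
    select("landscape_id", "habitat", "sub_category", "species_id",
           "density", "flower_number", "availability", "imputed") %>%
    arrange(.data$landscape_id, .data$habitat, .data$species_id)
}

#' Pool floral availability over landscapes or habitats
#'
#' @param records availability records from [build_floral_map()].
#' @param level `"landscape"` (one total per landscape) or `"habitat"`
#'   (one total per landscape x habitat category).
#' @param per_m2 divide totals by the corresponding area (sector area for
#'   the landscape level, habitat area for the habitat level).
#' @param areas required when `per_m2 = TRUE` at the habitat level: tibble
#'   `landscape_id`, `habitat`, `area_m2`.
#' @param radius sector radius in metres, used for the landscape-level
#'   per-m2 denominator.
#' @return Tibble of pooled availability (`availability`, plus
#'   `availability_per_m2` when requested).
#' @export
pool_availability <- function(records, level = c("landscape", "habitat"),
                              per_m2 = FALSE, areas = NULL, radius = 500) {
  level <- match.arg(level)
  keys <- if (level == "landscape") "landscape_id" else
    c("landscape_id", "habitat")
  out <- records %>%
    group_by(across(all_of(keys))) %>%
    summarise(availability = sum(.data$availability), .groups = "drop")
  if (per_m2) {
    if (level == "landscape") {
      denom <- sector_area_m2(radius)
      out$availability_per_m2 <- out$availability / denom
    } else {
      if (is.null(areas)) {
        abort("habitat-level per-m2 pooling needs an `areas` table")
      }
      out <- left_join(out, areas, by = keys)
      if (anyNA(out$area_m2) || any(out$area_m2 <= 0)) {
        abort("zero or missing area for a habitat-level normalization")
      }
      out$availability_per_m2 <- out$availability / out$area_m2
    }
  }
  out
}

#' Floral diversity and per-species shares
#'
#' @param records availability records from [build_floral_map()].
#' @param level `"landscape"` or `"habitat"`.
#' @return List with `richness` (distinct species with positive
#'   availability per group) and `shares` (per-species fraction of the
#'   group total availability).
#' @export
floral_diversity <- function(records, level = c("landscape", "habitat")) {
  level <- match.arg(level)
  if (nrow(records) == 0) abort("no availability records")
  keys <- if (level == "landscape") "landscape_id" else
    c("landscape_id", "habitat")
  richness <- records %>%
    group_by(across(all_of(keys))) %>%
    summarise(richness = n_distinct(.data$species_id[.data$availability > 0]),
              .groups = "drop")
  shares <- records %>%
    group_by(across(all_of(c(keys, "species_id")))) %>%
    summarise(availability = sum(.data$availability), .groups = "drop_last") %>%
    mutate(share = if (sum(.data$availability) > 0) {
      .data$availability / sum(.data$availability)
    } else {
      rep(NA_real_, n())
    }) %>%
    ungroup()
  list(richness = richness, shares = shares)
}
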