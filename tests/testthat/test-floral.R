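test_that("herbaceous density is the mean over rounds of per-round cube means", {
  cubes <- tibble::tibble(round = rep(1:3, each = 10),
                          cube_index = rep(1:10, 3),
                          flower_count = 4)
  expect_equal(estimate_density_herb(cubes), 4)
  cubes$flower_count <- rep(c(0, 3, 6), each = 10)
  expect_equal(estimate_density_herb(cubes), 3)
  # unbalanced rounds: random counts against a direct two-stage oracle
  set.seed(21)
  cubes2 <- tibble::tibble(round = sample(1:3, 23, replace = TRUE),
                           flower_count = rpois(23, 7))
  oracle <- mean(tapply(cubes2$flower_count, cubes2$round, mean))
  expect_equal(estimate_density_herb(cubes2), oracle)
  expect_error(estimate_density_herb(cubes2[0, ]), "not surveyed")
})

test_that("woody density is the nested mean over individuals and cubes", {
  calib <- tibble::tibble(individual = rep(1:10, each = 2),
                          cube_index = rep(1:2, 10), flower_count = 50)
  expect_equal(estimate_density_woody(calib), 50)
  calib2 <- tibble::tibble(individual = c(1, 1, 2, 2),
                           flower_count = c(10, 30, 20, 20))
  expect_equal(estimate_density_woody(calib2), 20)
  set.seed(22)
  calib3 <- tibble::tibble(individual = rep(1:7, times = c(2, 2, 1, 2, 2, 1, 2)),
                           flower_count = rpois(12, 40))
  oracle <- mean(tapply(calib3$flower_count, calib3$individual, mean))
  expect_equal(estimate_density_woody(calib3), oracle)
  expect_error(estimate_density_woody(calib3[0, ]), "calibration")
})

test_that("flower numbers combine density with volume or area", {
  expect_equal(flower_number(50, 2, "woody"), 100)
  expect_equal(flower_number(4, 250, "herbaceous"), 1000)
  expect_equal(flower_number(4, 250, "crop", h_layer = 0.5), 500)
  expect_equal(flower_number(0, 1e6, "herbaceous"), 0)
  expect_error(flower_number(-1, 10, "woody"), "non-negative")
})

test_that("availability is flower number x size x duration and excludes grasses", {
  expect_equal(flower_availability(1000, 5e-7, 14), 7e-3)
  expect_equal(flower_availability(0, 1e-6, 30), 0)
  set.seed(23)
  n <- runif(20, 0, 1e6); s <- runif(20, 1e-8, 1e-5); t <- runif(20, 5, 40)
  expect_equal(flower_availability(n, s, 2 * t),
               2 * flower_availability(n, s, t))
  expect_equal(flower_availability(2 * n, s, t),
               2 * flower_availability(n, s, t))
  expect_error(flower_availability(10, 1e-6, 14, is_grass = TRUE), "grass")
})

test_that("the floral map is additive and scale-equivariant", {
  st <- small_study(seed = 31)
  fm <- build_floral_map(st$surveys, st$species, st$patches)
  expect_true(all(fm$availability >= 0))
  total_rec <- sum(fm$availability)
  by_land <- pool_availability(fm, "landscape")
  by_hab <- pool_availability(fm, "habitat")
  expect_equal(sum(by_land$availability), total_rec, tolerance = 1e-12)
  hab_sums <- tapply(by_hab$availability, by_hab$landscape_id, sum)
  expect_equal(as.numeric(hab_sums[by_land$landscape_id]),
               by_land$availability, tolerance = 1e-12)
  # no grass species contributes
  expect_false(any(fm$species_id %in%
                     st$species$species_id[st$species$is_grass]))

  # tripling every raw count triples every availability value exactly
  sv <- st$surveys
  sv$grassland_cubes$flower_count <- 3L * sv$grassland_cubes$flower_count
  sv$woody_calibration$flower_count <- 3L * sv$woody_calibration$flower_count
  sv$crop_fields$flower_count <- 3L * sv$crop_fields$flower_count
  fm3 <- build_floral_map(sv, st$species, st$patches)
  expect_equal(fm3$availability, 3 * fm$availability, tolerance = 1e-12)
})

test_that("grassland densities fall back to sub-type means when unsurveyed", {
  patches <- tibble::tibble(
    landscape_id = c("A", "B"),
    category = "grassland", sub_category = "pasture", area_m2 = c(100, 200))
  cubes <- tibble::tibble(
    landscape_id = "A", sub_category = "pasture", species_id = "sp1",
    round = rep(1:3, each = 10), cube_index = rep(1:10, 3),
    flower_count = 6L)
  surveys <- list(grassland_cubes = cubes, woody_transects = NULL,
                  woody_calibration = NULL, crop_fields = NULL)
  expect_message(
    fm <- build_floral_map(surveys, trait_row("sp1"), patches),
    "imputed")
  expect_equal(nrow(fm), 2)
  expect_equal(fm$density, c(6, 6))
  expect_identical(fm$imputed, c(FALSE, TRUE))
  expect_equal(fm$flower_number, c(600, 1200))
})

test_that("grasses surveyed by mistake never reach the map", {
  patches <- tibble::tibble(landscape_id = "A", category = "grassland",
                            sub_category = "pasture", area_m2 = 100)
  cubes <- tibble::tibble(
    landscape_id = "A", sub_category = "pasture",
    species_id = rep(c("sp1", "grassy"), each = 30),
    round = rep(rep(1:3, each = 10), 2), cube_index = rep(1:10, 6),
    flower_count = 2L)
  traits <- dplyr::bind_rows(
    trait_row("sp1"),
    trait_row("grassy", is_grass = TRUE, insect_pollinated = FALSE))
  fm <- build_floral_map(
    list(grassland_cubes = cubes, woody_transects = NULL,
         woody_calibration = NULL, crop_fields = NULL),
    traits, patches)
  expect_identical(fm$species_id, "sp1")
})

test_that("pooled availability normalizes per square metre", {
  rec <- tibble::tibble(
    landscape_id = c("A", "A"), habitat = c("grassland", "crop"),
    sub_category = c("pasture", "oilseed_rape"),
    species_id = c("sp1", "sp2"), density = 1,
    flower_number = 1, availability = c(0.1, 0.3), imputed = FALSE)
  expect_equal(pool_availability(rec, "landscape")$availability, 0.4)
  rec2 <- dplyr::mutate(rec, availability = c(785.39816, 0))
  pm <- pool_availability(rec2, "landscape", per_m2 = TRUE, radius = 500)
  expect_equal(pm$availability_per_m2, 785.39816 / (pi * 500^2))
  areas <- tibble::tibble(landscape_id = "A",
                          habitat = c("grassland", "crop"),
                          area_m2 = c(50, 0))
  expect_error(
    pool_availability(rec, "habitat", per_m2 = TRUE, areas = areas),
    "zero or missing area")
})

test_that("diversity summaries count species and normalize shares", {
  rec1 <- tibble::tibble(landscape_id = "A", habitat = "crop",
                         species_id = "sp1", availability = 2)
  d1 <- floral_diversity(rec1, "landscape")
  expect_equal(d1$richness$richness, 1)
  expect_equal(d1$shares$share, 1)
  set.seed(24)
  rec <- tibble::tibble(
    landscape_id = sample(c("A", "B"), 40, replace = TRUE),
    habitat = sample(c("crop", "grassland"), 40, replace = TRUE),
    species_id = sample(paste0("sp", 1:8), 40, replace = TRUE),
    availability = runif(40))
  d <- floral_diversity(rec, "landscape")
  sums <- tapply(d$shares$share, d$shares$landscape_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  brute <- tapply(rec$species_id, rec$landscape_id,
                  function(s) length(unique(s)))
  expect_equal(d$richness$richness,
               as.vector(brute[d$richness$landscape_id]))
})

test_that("a habitat with boosted flower densities tops the per-m2 map", {
  cfg <- simulation_config(
    n_landscapes = 6, n_species = 24, seed = 55,
    density_model = c(forest_edge = 1, semi_open = 1, grassland = 3,
                      crop = 1))
  st <- generate_study(cfg)
  fm <- build_floral_map(st$surveys, st$species, st$patches)
  areas <- st$patches %>%
    dplyr::group_by(landscape_id, habitat = category) %>%
    dplyr::summarise(area_m2 = sum(area_m2), .groups = "drop")
  per_m2 <- pool_availability(fm, "habitat", per_m2 = TRUE, areas = areas)
  mean_by_hab <- tapply(per_m2$availability_per_m2, per_m2$habitat, mean)
  expect_equal(names(which.max(mean_by_hab)), "grassland")
})
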