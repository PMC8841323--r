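suppressPackageStartupMessages(library(dplyr))

# one-row species trait table for hand-built fixtures
trait_row <- function(species_id, flower_size_m3 = 1e-6,
                      flowering_duration_days = 14,
                      growth_form = "herbaceous", is_grass = FALSE,
                      insect_pollinated = TRUE, affinity = "grassland",
                      crop_type = NA_character_, mean_density = 5) {
  tibble::tibble(
    species_id = species_id, flower_size_m3 = flower_size_m3,
    flowering_duration_days = flowering_duration_days,
    growth_form = growth_form, is_grass = is_grass,
    insect_pollinated = insect_pollinated, affinity = affinity,
    crop_type = crop_type, mean_density = mean_density)
}

# all permutations of seq_len(n), rows of a matrix (n! must stay small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[j, ]])
    }
  }
  out
}

small_study <- function(seed = 42, n_landscapes = 6, n_species = 15) {
  generate_study(simulation_config(
    n_landscapes = n_landscapes, n_species = n_species, seed = seed))
}
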