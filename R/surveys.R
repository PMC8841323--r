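#' Pool predator observations per landscape
#'
#' Sums counts of ladybirds, hoverflies and lacewings over phytometer
#' plants, sampling rounds and life stages, per taxon and in total.
#' Pooling compensates for the low per-taxon numbers typical of phytometer
#' exposures.
#'
#' @param obs predator observation records: `landscape_id`, `plant`,
#'   `round` (one of 48h/96h/14d), `taxon`, `stage`, `count`.
#' @return Tibble per landscape: `predators` (total), one column per
#'   taxon, `present`.
#' @export
pool_predators <- function(obs) {
  template <- tibble(landscape_id = character(), predators = integer(),
                     ladybird = integer(), hoverfly = integer(),
                     lacewing = integer(), present = logical())
  if (is.null(obs) || nrow(obs) == 0) return(template)
  bad <- setdiff(unique(obs$taxon), predator_taxa())
  if (length(bad) > 0) {
    abort(sprintf("unknown predator taxon: %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(obs$stage), predator_stages())
  if (length(bad) > 0) {
    abort(sprintf("unknown life stage: %s", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(obs$round), predator_rounds())
  if (length(bad) > 0) {
    abort(sprintf("unknown sampling round: %s", paste(bad, collapse = ", ")))
  }
  if (any(obs$count < 0)) abort("counts must be >= 0")
  wide <- obs %>%
    group_by(.data$landscape_id, .data$taxon) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "taxon", values_from = "count",
                       values_fill = 0L)
  for (tx in setdiff(predator_taxa(), names(wide))) wide[[tx]] <- 0L
  wide %>%
    mutate(predators = .data$ladybird + .data$hoverfly + .data$lacewing,
           present = .data$predators > 0) %>%
    select("landscape_id", "predators", "ladybird", "hoverfly", "lacewing",
           "present") %>%
    arrange(.data$landscape_id)
}

#' Aphid population growth per landscape
#'
#' Growth is the pooled day-14 count minus the pooled day-0 count over all
#' phytometer plants of a landscape; negative growth (net suppression) is
#' legal. Records flagged as non-target aphid species (immigrants from the
#' surrounding landscape) are excluded. Parasitoid mummies are counted as
#' regular aphids at data entry, so no transformation happens here.
#'
#' @param counts aphid census records: `landscape_id`, `plant`, `day`
#'   (0 or 14), `species_flag` (`"target"`/`"nontarget"`), `count`.
#' @return Tibble per landscape: `aphids_day0`, `aphids_day14`, `growth`.
#' @export
aphid_growth <- function(counts) {
  if (is.null(counts) || nrow(counts) == 0) abort("no aphid census records")
  if (!all(counts$day %in% c(0L, 14L))) {
    abort("aphid census days must be 0 or 14")
  }
  if (any(counts$count < 0)) abort("counts must be >= 0")
  dup <- counts %>%
    count(.data$landscape_id, .data$plant, .data$day, .data$species_flag) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate census record(s), e.g. landscape %s plant %d day %d",
                  dup$landscape_id[1], dup$plant[1], dup$day[1]))
  }
  target <- filter(counts, .data$species_flag == "target")
  totals <- target %>%
    group_by(.data$landscape_id, .data$day) %>%
    summarise(total = sum(.data$count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "day", values_from = "total",
                       names_prefix = "day")
  for (cl in c("day0", "day14")) {
    if (!cl %in% names(totals)) totals[[cl]] <- NA_integer_
  }
  bad <- is.na(totals$day0) | is.na(totals$day14)
  if (any(bad)) {
    abort(sprintf("missing census time point for landscape(s): %s",
                  paste(totals$landscape_id[bad], collapse = ", ")))
  }
  totals %>%
    mutate(growth = .data$day14 - .data$day0) %>%
    rename(aphids_day0 = "day0", aphids_day14 = "day14") %>%
    arrange(.data$landscape_id)
}

#' Assemble the per-landscape outcome table
#'
#' Joins pooled predator counts and aphid growth into one row per
#' landscape. Landscapes with aphid censuses but no predator records get a
#' predator count of zero (absence); each landscape must appear exactly
#' once.
#'
#' @param predator_obs predator observation records (see
#'   [pool_predators()]).
#' @param aphid_counts aphid census records (see [aphid_growth()]).
#' @return Tibble sorted by `landscape_id`: `predators`, `present`,
#'   per-taxon counts, `aphids_day0`, `aphids_day14`, `growth`.
#' @export
build_outcome_table <- function(predator_obs, aphid_counts) {
  growth <- aphid_growth(aphid_counts)
  pred <- pool_predators(predator_obs)
  extra <- setdiff(pred$landscape_id, growth$landscape_id)
  if (length(extra) > 0) {
    abort(sprintf("predator records for landscape(s) without aphid census: %s",
                  paste(extra, collapse = ", ")))
  }
  growth %>%
    left_join(pred, by = "landscape_id") %>%
    mutate(predators = coalesce(.data$predators, 0L),
           ladybird = coalesce(.data$ladybird, 0L),
           hoverfly = coalesce(.data$hoverfly, 0L),
           lacewing = coalesce(.data$lacewing, 0L),
           present = .data$predators > 0) %>%
    select("landscape_id", "predators", "present", "ladybird", "hoverfly",
           "lacewing", "aphids_day0", "aphids_day14", "growth") %>%
    arrange(.data$landscape_id)
}
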