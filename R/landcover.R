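#' Read habitat patches from a table or a GeoJSON file
#'
#' Patch tables are CSV files with columns `landscape_id`, `category`,
#' `sub_category`, `area_m2`. Polygon inputs are GeoJSON FeatureCollections
#' whose features carry the same properties (minus `area_m2`); areas are
#' recomputed from the planar (projected, metric) geometry with the
#' shoelace formula, holes subtracted, and — when sector centres are
#' supplied — clipped to the sector circle first. Patches below the
#' minimal mapping unit (1 m2) are dropped with a message.
#'
#' @param source path to a `.csv` patch table or a `.geojson`/`.json`
#'   FeatureCollection.
#' @param sectors optional tibble (`landscape_id`, `center_x`, `center_y`,
#'   `radius_m`) used to clip polygons to their sector circle.
#' @param min_area minimal mapping unit in m2; smaller patches are dropped.
#' @return Tibble `landscape_id`, `category`, `sub_category`, `area_m2`.
#' @export
load_patches <- function(source, sectors = NULL, min_area = 1) {
  if (!file.exists(source)) abort(sprintf("file not found: %s", source))
  if (grepl("\\.(geojson|json)$", source, ignore.case = TRUE)) {
    patches <- load_patches_geojson(source, sectors)
  } else {
    patches <- readr::read_csv(source, col_types = "cccd")
    needed <- c("landscape_id", "category", "sub_category", "area_m2")
    if (!all(needed %in% names(patches))) {
      abort(sprintf("patch table must have columns: %s",
                    paste(needed, collapse = ", ")))
    }
  }
  bad <- which(!patches$category %in% habitat_categories())
  if (length(bad) > 0) {
    abort(sprintf("unknown habitat category '%s' in row %d of %s",
                  patches$category[bad[1]], bad[1], source))
  }
  if (anyNA(patches$landscape_id)) {
    abort("patch without a landscape assignment")
  }
  small <- patches$area_m2 < min_area
  if (any(small)) {
    inform(sprintf("dropped %d patch(es) below the %g m2 minimal mapping unit",
                   sum(small), min_area))
    patches <- patches[!small, , drop = FALSE]
  }
  as_tibble(patches)
}

load_patches_geojson <- function(source, sectors) {
  gj <- jsonlite::read_json(source)
  if (is.null(gj$features)) abort("GeoJSON input must be a FeatureCollection")
  rows <- lapply(gj$features, function(ft) {
    pr <- ft$properties
    if (is.null(pr$landscape_id)) {
      abort("GeoJSON feature has geometry without a landscape assignment")
    }
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      abort("only Polygon geometries are supported")
    }
    rings <- lapply(geom$coordinates, function(rg) {
      do.call(rbind, lapply(rg, function(xy) c(xy[[1]], xy[[2]])))
    })
    if (!is.null(sectors)) {
      sec <- sectors[sectors$landscape_id == pr$landscape_id, , drop = FALSE]
      if (nrow(sec) == 1) {
        circ <- circle_polygon(sec$center_x, sec$center_y, sec$radius_m)
        rings <- lapply(rings, clip_polygon_convex, clip = circ)
      }
    }
    areas <- vapply(rings, polygon_area, numeric(1))
    # first ring is the outer boundary; subsequent rings are holes
    area <- areas[1] - sum(areas[-1])
    tibble(landscape_id = pr$landscape_id,
           category = pr$category %||% NA_character_,
           sub_category = pr$sub_category %||% NA_character_,
           area_m2 = area)
  })
  bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Planar polygon area (shoelace formula)
#'
#' @param xy two-column matrix of vertex coordinates (metres), open or
#'   closed ring.
#' @return Area in m2 (non-negative).
#' @export
polygon_area <- function(xy) {
  if (is.null(xy) || nrow(xy) < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

circle_polygon <- function(cx, cy, r, n_vertices = 360L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Sutherland-Hodgman clipping of an arbitrary polygon against a convex,
# counter-clockwise clip polygon (here a many-sided circle approximation)
clip_polygon_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(out)
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    inside <- function(p) {
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    }
    intersect_pt <- function(p, q) {
      # intersection of segment p-q with the infinite line a-b
      d1 <- c(q[1] - p[1], q[2] - p[2])
      d2 <- c(b[1] - a[1], b[2] - a[2])
      denom <- d1[1] * d2[2] - d1[2] * d2[1]
      t <- ((a[1] - p[1]) * d2[2] - (a[2] - p[2]) * d2[1]) / denom
      c(p[1] + t * d1[1], p[2] + t * d1[2])
    }
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      cur <- inp[j, ]
      prev <- inp[if (j == 1L) np else j - 1L, ]
      if (inside(cur)) {
        if (!inside(prev)) out <- rbind(out, intersect_pt(prev, cur))
        out <- rbind(out, cur)
      } else if (inside(prev)) {
        out <- rbind(out, intersect_pt(prev, cur))
      }
    }
  }
  out
}

#' Summarise land cover of circular landscape sectors
#'
#' Sums patch areas per habitat category and converts them to proportions
#' of the full sector area `pi * radius^2` (so unmapped area dilutes
#' proportions). The three semi-natural categories (forest edge, semi-open
#' habitat, grassland) are additionally pooled into the SNH area and
#' proportion.
#'
#' @param patches patch tibble as returned by [load_patches()].
#' @param radius sector radius in metres (scalar, applied to all
#'   landscapes) — ignored when `sectors` is given.
#' @param sectors optional tibble (`landscape_id`, `radius_m`) with
#'   per-landscape radii.
#' @return Tibble with one row per landscape: `area_<category>`,
#'   `prop_<category>`, `snh_area`, `snh_prop`.
#' @export
summarize_landcover <- function(patches, radius = 500, sectors = NULL) {
  if (any(patches$area_m2 < 0)) abort("patch areas must be >= 0")
  bad <- setdiff(unique(patches$category), habitat_categories())
  if (length(bad) > 0) {
    abort(sprintf("unknown habitat category: %s", paste(bad, collapse = ", ")))
  }
  cats <- habitat_categories()
  wide <- patches %>%
    group_by(.data$landscape_id, .data$category) %>%
    summarise(area = sum(.data$area_m2), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "area",
                       values_fill = 0)
  for (ct in setdiff(cats, names(wide))) wide[[ct]] <- 0
  if (!is.null(sectors)) {
    wide <- left_join(wide, sectors, by = "landscape_id")
    if (anyNA(wide$radius_m)) abort("sector radius missing for some landscapes")
  } else {
    wide$radius_m <- radius
  }
  tot_area <- sector_area_m2(wide$radius_m)
  mapped <- rowSums(as.matrix(wide[, cats]))
  over <- mapped > tot_area * (1 + 1e-6)
  if (any(over)) {
    abort(sprintf("mapped area exceeds sector area in landscape(s): %s",
                  paste(wide$landscape_id[over], collapse = ", ")))
  }
  out <- tibble(landscape_id = wide$landscape_id)
  for (ct in cats) {
    out[[paste0("area_", ct)]] <- wide[[ct]]
    out[[paste0("prop_", ct)]] <- wide[[ct]] / tot_area
  }
  out$snh_area <- out$area_forest_edge + out$area_semi_open +
    out$area_grassland
  out$snh_prop <- out$snh_area / tot_area
  arrange(out, .data$landscape_id)
}

#' Pool the semi-natural habitat proportion
#'
#' Returns the summed proportions of forest edge, semi-open habitat and
#' grassland; crop and other area is excluded.
#'
#' @param summary a land-cover summary from [summarize_landcover()].
#' @return Named numeric vector of SNH proportions, one per landscape.
#' @export
pool_snh <- function(summary) {
  needed <- paste0("prop_", snh_categories())
  if (!all(needed %in% names(summary))) {
    abort("`summary` must carry the per-category proportion columns")
  }
  setNames(summary$prop_forest_edge + summary$prop_semi_open +
             summary$prop_grassland,
           summary$landscape_id)
}
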