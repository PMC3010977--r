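#' Sørensen similarity between regional assemblages
#'
#' For two regions a and b under a common partition: A and B are the
#' numbers of groups present in each region (a group is present where it
#' has at least one specimen), C the number of groups present in both, and
#' S = 2C / (A + B). Presence is always read off one pooled partition of
#' all the data, restricted to each region, so that "shared" is
#' well-defined.
#'
#' @param partition partition tibble (any kind: morphospecies, clusters,
#'   GMYC entities, ...).
#' @param region_map tibble with columns `specimen_id`, `region`.
#' @param regions optional character vector restricting/ordering the
#'   regions considered; default, all regions present.
#' @return A tibble per unordered region pair: `region_a`, `region_b`,
#'   `A`, `B`, `C`, `S` (`S` is `NA` when `A + B = 0`).
#' @export
sorensen <- function(partition, region_map, regions = NULL) {
  reg <- region_map$region[match(partition$specimen_id, region_map$specimen_id)]
  if (any(is.na(reg))) {
    bad <- partition$specimen_id[which(is.na(reg))[1L]]
    rlang::abort(paste0("region absent from map for specimen ", bad))
  }
  if (is.null(regions)) regions <- sort(unique(reg))
  if (length(regions) < 2L) rlang::abort("need at least two regions")
  pres <- unique(tibble::tibble(group = partition$group, region = reg))
  pairs <- utils::combn(regions, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    in_a <- unique(pres$group[pres$region == a])
    in_b <- unique(pres$group[pres$region == b])
    A <- length(in_a); B <- length(in_b)
    C <- length(intersect(in_a, in_b))
    tibble::tibble(
      region_a = a, region_b = b, A = A, B = B, C = C,
      S = if (A + B > 0) 2 * C / (A + B) else NA_real_
    )
  })
}

#' Distance decay of Sørensen similarity
#'
#' Ordinary least-squares fit of S on geographic distance across region
#' pairs; under distance decay of community similarity the slope is
#' negative.
#'
#' @param sorensen_tbl tibble from [sorensen()] joined with a
#'   `distance_km` column (see [region_distance_table()]).
#' @return A list with `slope`, `intercept`, `fit` (the `lm` object) and
#'   `pairs` (the input sorted by distance).
#' @export
distance_decay <- function(sorensen_tbl) {
  if (!all(c("S", "distance_km") %in% names(sorensen_tbl))) {
    rlang::abort("need columns S and distance_km")
  }
  df <- sorensen_tbl[!is.na(sorensen_tbl$S) & !is.na(sorensen_tbl$distance_km), ]
  if (nrow(df) < 3L) rlang::abort("need at least 3 region pairs with distances")
  fit <- stats::lm(S ~ distance_km, data = df)
  list(
    slope = unname(stats::coef(fit)[["distance_km"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    fit = fit,
    pairs = dplyr::arrange(df, .data$distance_km)
  )
}

#' Pairwise distances between regions on a line
#'
#' Synthetic regions sit on a one-dimensional coordinate line with fixed
#' spacing; this builds the region-pair distance table matching the
#' simulator's geography. For real data, supply your own table with the
#' same columns.
#'
#' @param regions character vector of region names, in spatial order.
#' @param spacing_km distance between adjacent regions.
#' @return A tibble: `region_a`, `region_b`, `distance_km` for all
#'   unordered pairs.
#' @export
region_distance_table <- function(regions, spacing_km = 500) {
  if (length(regions) < 2L) {
    return(tibble::tibble(region_a = character(), region_b = character(),
                          distance_km = numeric()))
  }
  pos <- stats::setNames(seq_along(regions), regions)
  pairs <- utils::combn(regions, 2L)
  tibble::tibble(
    region_a = pairs[1L, ],
    region_b = pairs[2L, ],
    distance_km = abs(pos[pairs[1L, ]] - pos[pairs[2L, ]]) * spacing_km
  )
}
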