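#' Round half away from zero
#'
#' Printed evaluation tables round percentages half-away-from-zero (68.47
#' -> 68, 68.5 -> 69), unlike base R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an estimated partition against the morphospecies truth
#'
#' Computes the evaluation statistics of threshold-clustering studies:
#' *agreement* (number of estimated groups as a percentage of the species
#' count; the species-richness-estimation success, which may exceed 100)
#' and *taxonomic accuracy* (percentage of species recovered as *perfect*
#' groups). A perfect group contains all sequenced individuals of exactly
#' one species and only those; a split species is spread over two or more
#' groups; a lumped group contains two or more species names.
#'
#' @param estimate partition tibble (clusters, GMYC entities, networks,
#'   PAA aggregates).
#' @param truth morphospecies partition over the same specimen set.
#' @return One-row tibble: `n_species`, `n_groups`, `n_perfect`,
#'   `n_species_split`, `n_groups_lumped`, `agreement_pct`, `accuracy_pct`
#'   (full precision) and rounded integer companions `agreement_pct_int`,
#'   `accuracy_pct_int`.
#' @export
evaluate_partition <- function(estimate, truth) {
  missing <- setdiff(truth$specimen_id, estimate$specimen_id)
  extra <- setdiff(estimate$specimen_id, truth$specimen_id)
  if (length(missing) || length(extra)) {
    rlang::abort(paste0(
      "partition coverage mismatch;",
      if (length(missing)) paste0(" missing: ", paste(utils::head(missing, 5), collapse = ", ")),
      if (length(extra)) paste0(" extra: ", paste(utils::head(extra, 5), collapse = ", "))
    ))
  }
  sp_sets <- partition_groups(truth)
  gr_sets <- partition_groups(estimate)
  n_species <- length(sp_sets)
  n_groups <- length(gr_sets)
  sp_key <- vapply(sp_sets, paste, "", collapse = "\r")
  gr_key <- vapply(gr_sets, paste, "", collapse = "\r")
  n_perfect <- sum(gr_key %in% sp_key)

  sp_of <- truth$group[match(estimate$specimen_id, truth$specimen_id)]
  # species spread over >= 2 groups
  by_species <- tapply(estimate$group, sp_of, function(g) length(unique(g)))
  n_species_split <- sum(by_species >= 2L)
  # groups containing >= 2 species names
  by_group <- tapply(sp_of, estimate$group, function(s) length(unique(s)))
  n_groups_lumped <- sum(by_group >= 2L)

  agreement <- 100 * n_groups / n_species
  accuracy <- 100 * n_perfect / n_species
  tibble::tibble(
    n_species = n_species,
    n_groups = n_groups,
    n_perfect = n_perfect,
    n_species_split = n_species_split,
    n_groups_lumped = n_groups_lumped,
    agreement_pct = agreement,
    accuracy_pct = accuracy,
    agreement_pct_int = round_half_up(agreement),
    accuracy_pct_int = round_half_up(accuracy)
  )
}

#' Shared groups between regions under a pooled partition
#'
#' For a partition computed on pooled data, a group is *shared* between two
#' regions when it contains at least one specimen from each. The
#' denominator is the number of groups with any member in either region of
#' the pair (for a partition of exactly the two regions' specimens, that is
#' the total group count).
#'
#' @param partition partition tibble of the pooled data.
#' @param region_map tibble with columns `specimen_id`, `region` covering
#'   all partitioned specimens.
#' @param regions optional character vector restricting which regions are
#'   paired; default, all regions present.
#' @return A tibble per unordered region pair: `region_a`, `region_b`,
#'   `n_groups`, `n_shared`, `shared_pct`, `shared_pct_int`.
#' @export
shared_group_pct <- function(partition, region_map, regions = NULL) {
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
    n_groups <- length(union(in_a, in_b))
    n_shared <- length(intersect(in_a, in_b))
    pct <- if (n_groups > 0) 100 * n_shared / n_groups else NA_real_
    tibble::tibble(
      region_a = a, region_b = b,
      n_groups = n_groups, n_shared = n_shared,
      shared_pct = pct, shared_pct_int = round_half_up(pct)
    )
  })
}

#' Mean, population SD and median of an evaluation column
#'
#' Summary rows of evaluation tables use the population standard deviation
#' (divisor n, not n - 1).
#'
#' @param reports tibble of evaluation rows (e.g. stacked
#'   [evaluate_partition()] outputs).
#' @param column column name to summarize (usually one of the rounded
#'   percentage columns).
#' @return One-row tibble: `column`, `n`, `mean`, `sd`, `median`.
#' @export
report_summary <- function(reports, column) {
  x <- reports[[column]]
  if (is.null(x)) rlang::abort(paste0("no column '", column, "'"))
  x <- x[!is.na(x)]
  if (length(x) == 0L) rlang::abort("no values to summarize")
  tibble::tibble(
    column = column, n = length(x),
    mean = mean(x), sd = sd_pop(x), median = stats::median(x)
  )
}
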