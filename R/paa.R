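#' Diagnostic sites between two specimen groups
#'
#' A site is diagnostic when the observed state sets of the two groups
#' (ignoring N) are both non-empty and disjoint, i.e. a fixed difference
#' separates the groups at that position. Two groups can be diagnosable
#' even when their overall divergence is far below any clustering
#' threshold.
#'
#' @param aln alignment tibble.
#' @param group_a,group_b disjoint, non-empty character vectors of
#'   specimen ids.
#' @param n_wildcard if `TRUE`, an N is treated as matching every state
#'   (so a column with an N in either group is never diagnostic); default
#'   `FALSE` excludes Ns from the state sets.
#' @return A tibble with one row per diagnostic site: `site` (0-based
#'   index), `states_a`, `states_b` (states collapsed with "/").
#' @export
diagnostic_sites <- function(aln, group_a, group_b, n_wildcard = FALSE) {
  validate_alignment(aln)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    rlang::abort("groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) {
    rlang::abort("groups must be disjoint")
  }
  m <- aln_matrix(aln)
  missing <- setdiff(c(group_a, group_b), rownames(m))
  if (length(missing)) {
    rlang::abort(paste0("specimens not in alignment: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  ma <- m[group_a, , drop = FALSE]
  mb <- m[group_b, , drop = FALSE]
  L <- ncol(m)
  rows <- lapply(seq_len(L), function(s) {
    sa <- unique(ma[, s])
    sb <- unique(mb[, s])
    if (n_wildcard) {
      if ("N" %in% sa || "N" %in% sb) return(NULL)
    } else {
      sa <- setdiff(sa, "N")
      sb <- setdiff(sb, "N")
    }
    if (length(sa) == 0L || length(sb) == 0L) return(NULL)
    if (length(intersect(sa, sb)) > 0L) return(NULL)
    tibble::tibble(
      site = s - 1L,
      states_a = paste(sort(sa), collapse = "/"),
      states_b = paste(sort(sb), collapse = "/")
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(site = integer(), states_a = character(),
                          states_b = character())
  }
  out
}

#' Population aggregation analysis
#'
#' Pairwise step addition: repeatedly merge the closest pair of groups
#' (smallest mean between-group p-distance) that lacks any diagnostic
#' site, until every remaining pair is mutually diagnosable (or one group
#' remains). Ties are broken by the alphabetically smallest pair of group
#' labels, and a merged group takes the smaller of the two labels, so the
#' procedure is deterministic.
#'
#' @param aln alignment tibble.
#' @param initial_groups partition tibble of starting populations (e.g.
#'   morphospecies, or populations within a cluster).
#' @param n_wildcard see [diagnostic_sites()].
#' @return Partition tibble (`kind = "paa_aggregate"`).
#' @export
paa_aggregate <- function(aln, initial_groups, n_wildcard = FALSE) {
  validate_alignment(aln)
  keep <- aln$specimen_id %in% initial_groups$specimen_id
  if (!all(keep)) rlang::abort("initial_groups must cover the alignment")
  groups <- partition_groups(initial_groups)
  dm <- if (nrow(aln) >= 2L) p_distance_matrix(aln) else NULL

  mean_dist <- function(a, b) mean(dm[a, b, drop = FALSE])
  diagnosable <- function(a, b) {
    nrow(diagnostic_sites(aln, a, b, n_wildcard = n_wildcard)) > 0L
  }

  repeat {
    if (length(groups) <= 1L) break
    labs <- names(groups)
    pairs <- utils::combn(seq_along(groups), 2L)
    cand <- NULL
    best <- Inf
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      if (diagnosable(groups[[i]], groups[[j]])) next
      d <- mean_dist(groups[[i]], groups[[j]])
      if (d < best - 1e-15) {
        best <- d; cand <- c(i, j)
      } else if (abs(d - best) <= 1e-15 && !is.null(cand)) {
        # tie: alphabetically smallest pair of labels
        if (paste(sort(labs[c(i, j)]), collapse = "\r") <
            paste(sort(labs[cand]), collapse = "\r")) cand <- c(i, j)
      } else if (is.null(cand) && is.finite(d)) {
        best <- d; cand <- c(i, j)
      }
    }
    if (is.null(cand)) break  # all remaining pairs diagnosable
    i <- cand[1L]; j <- cand[2L]
    merged <- sort(c(groups[[i]], groups[[j]]))
    new_lab <- min(labs[i], labs[j])
    groups <- groups[-c(i, j)]
    groups[[new_lab]] <- merged
    groups <- groups[order(names(groups))]
  }

  new_partition(
    unlist(groups, use.names = FALSE),
    rep(names(groups), lengths(groups)),
    kind = "paa_aggregate"
  )
}
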