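#' Screen an alignment for internal stop codons
#'
#' Translates each sequence under the invertebrate mitochondrial genetic
#' code and reports internal stop codons (a stop in the final codon of the
#' read is ignored, as protein-coding fragments may legitimately end on
#' one). A clean protein-coding barcode alignment should pass with zero
#' flags; internal stops indicate pseudogenes, frame errors or alignment
#' problems.
#'
#' @param aln alignment tibble.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @param code NCBI genetic-code number (default 5, invertebrate
#'   mitochondrial).
#' @return A tibble with one row per record: `specimen_id`, `species`,
#'   `n_internal_stops`, `stop_codons` (list column of 1-based codon
#'   indices) and `pass`.
#' @export
qc_translate <- function(aln, frame = 0L, code = 5L) {
  validate_alignment(aln)
  if (!frame %in% 0:2) rlang::abort("frame must be 0, 1 or 2")
  L <- alignment_length(aln)
  if (L - frame < 3L) rlang::abort("sequence too short to translate (need >= 3 sites)")
  stops <- lapply(aln$sequence, function(s) {
    chars <- strsplit(substring(s, frame + 1L), "")[[1L]]
    n_codon <- length(chars) %/% 3L
    chars <- chars[seq_len(n_codon * 3L)]
    aa <- seqinr::translate(tolower(chars), numcode = code, ambiguous = TRUE)
    idx <- which(aa == "*")
    idx[idx < n_codon]  # terminal stop ignored
  })
  tibble::tibble(
    specimen_id = aln$specimen_id,
    species = aln$species,
    n_internal_stops = lengths(stops),
    stop_codons = stops,
    pass = lengths(stops) == 0L
  )
}

#' Uncorrected p-distance matrix
#'
#' Pairwise proportion of differing sites, uncorrected for multiple hits.
#' Sites where either sequence carries an N are excluded for that pair
#' (pairwise deletion); the denominator is the number of sites unambiguous
#' in both sequences.
#'
#' @param aln alignment tibble with at least two records.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the specimen ids.
#' @export
p_distance_matrix <- function(aln) {
  validate_alignment(aln)
  if (nrow(aln) < 2L) rlang::abort("need at least 2 records for distances")
  m <- aln_matrix(aln)
  dnb <- ape::as.DNAbin(tolower(m))
  d <- ape::dist.dna(dnb, model = "raw", pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1L, ]
    rlang::abort(paste0(
      "no comparable sites between ", rownames(d)[bad[1L]], " and ",
      colnames(d)[bad[2L]]
    ))
  }
  diag(d) <- 0
  d
}

#' Cluster specimens at a fixed p-distance threshold
#'
#' Groups are the connected components of the graph with an edge wherever
#' the pairwise distance is at most `t` (single-linkage chaining): if A-B
#' and B-C are each within the threshold but A-C exceeds it, A, B and C
#' still fall into one cluster. Group labels are assigned in the order of
#' each cluster's smallest member id, so the result is invariant to input
#' record order.
#'
#' @param dm distance matrix from [p_distance_matrix()].
#' @param t threshold as a fraction in `[0, 1]`; values greater than 1 are
#'   interpreted as percent and divided by 100.
#' @return Partition tibble (`kind = "cluster"`).
#' @export
cluster_at_threshold <- function(dm, t) {
  t <- normalize_threshold(t)
  ids <- rownames(dm)
  ord <- order(ids)
  dm <- dm[ord, ord, drop = FALSE]
  ids <- ids[ord]
  g <- igraph::graph_from_adjacency_matrix(dm <= t, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # canonical labels: clusters ordered by their smallest member id
  first_member <- vapply(split(ids, comp), `[[`, "", 1L)
  lab_order <- order(first_member)
  relabel <- integer(length(lab_order))
  relabel[lab_order] <- seq_along(lab_order)
  new_partition(ids, sprintf("C%04d", relabel[comp]), kind = "cluster")
}

#' Normalize a clustering threshold
#'
#' Thresholds may be given as fractions (`0.03`) or percent (`3`); percent
#' values are divided by 100.
#'
#' @param t numeric scalar or vector in `[0, 1]` or `(1, 100]`.
#' @return Threshold(s) as fractions.
#' @export
normalize_threshold <- function(t) {
  if (any(t < 0 | t > 100)) rlang::abort("threshold out of range")
  ifelse(t > 1, t / 100, t)
}

#' Sweep clustering thresholds against the morphospecies truth
#'
#' Clusters the distance matrix at each threshold and evaluates the result
#' against the truth partition; the number of clusters is non-increasing in
#' the threshold.
#'
#' @param dm distance matrix.
#' @param truth morphospecies partition covering the same specimens.
#' @param thresholds numeric vector (fractions or percent), sorted
#'   ascending.
#' @return A tibble with one evaluation row per threshold, including
#'   `threshold`, `n_groups`, `agreement_pct`, `accuracy_pct` (see
#'   [evaluate_partition()]).
#' @export
threshold_sweep <- function(dm, truth, thresholds = seq(0.01, 0.10, by = 0.01)) {
  thresholds <- normalize_threshold(thresholds)
  if (is.unsorted(thresholds)) rlang::abort("thresholds must be sorted ascending")
  purrr::map_dfr(thresholds, function(t) {
    part <- cluster_at_threshold(dm, t)
    dplyr::bind_cols(
      tibble::tibble(threshold = t),
      evaluate_partition(part, truth)
    )
  })
}

#' Barcoding-gap table
#'
#' For every species: the largest intraspecific p-distance (undefined for
#' singletons) and the smallest interspecific p-distance to a congeneric
#' species (undefined for species whose genus is monotypic in the
#' dataset). The separation (or overlap) of these two distributions is the
#' barcoding gap.
#'
#' @param dm distance matrix.
#' @param truth morphospecies partition; genus is parsed from the species
#'   name.
#' @return A tibble with columns `species`, `genus`, `n`, `max_intra`,
#'   `min_inter_congeneric` (NA where undefined).
#' @export
barcoding_gap_table <- function(dm, truth) {
  ids <- rownames(dm)
  if (!setequal(ids, truth$specimen_id)) {
    rlang::abort("distance matrix and partition cover different specimens")
  }
  sp <- truth$group[match(ids, truth$specimen_id)]
  species <- sort(unique(sp))
  genus <- genus_of(species)
  max_intra <- vapply(species, function(s) {
    i <- which(sp == s)
    if (length(i) < 2L) return(NA_real_)
    max(dm[i, i])
  }, 0)
  min_inter <- vapply(seq_along(species), function(k) {
    congenerics <- species[genus == genus[k] & species != species[k]]
    if (length(congenerics) == 0L) return(NA_real_)
    i <- which(sp == species[k])
    j <- which(sp %in% congenerics)
    min(dm[i, j, drop = FALSE])
  }, 0)
  tibble::tibble(
    species = species,
    genus = genus,
    n = as.integer(table(sp)[species]),
    max_intra = max_intra,
    min_inter_congeneric = min_inter
  )
}

#' Summary statistics for a barcoding-gap table
#'
#' Median, mean and population standard deviation (divisor n) of the
#' largest-intraspecific and smallest-congeneric-interspecific distance
#' columns, over the species for which they are defined.
#'
#' @param gap tibble from [barcoding_gap_table()].
#' @return A two-row tibble (`statistic` = max_intra / min_inter) with
#'   columns `n`, `median`, `mean`, `sd`.
#' @export
gap_summary <- function(gap) {
  one <- function(x, label) {
    x <- x[!is.na(x)]
    tibble::tibble(
      statistic = label, n = length(x),
      median = stats::median(x), mean = mean(x), sd = sd_pop(x)
    )
  }
  dplyr::bind_rows(
    one(gap$max_intra, "max_intra"),
    one(gap$min_inter_congeneric, "min_inter_congeneric")
  )
}

# population standard deviation (divisor n)
sd_pop <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
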