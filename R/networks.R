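#' Collapse an alignment to distinct haplotypes
#'
#' Exact-sequence collapse; each haplotype is represented by its
#' lexicographically smallest member specimen id, which makes the result
#' deterministic and order-invariant.
#'
#' @param aln alignment tibble.
#' @return A tibble with one row per haplotype: `haplotype` (representative
#'   specimen id), `sequence`, `multiplicity`, `members` (list column of
#'   specimen ids).
#' @export
collapse_haplotypes <- function(aln) {
  validate_alignment(aln)
  groups <- split(aln$specimen_id, aln$sequence)
  groups <- lapply(groups, sort)
  reps <- vapply(groups, `[[`, "", 1L)
  ord <- order(reps)
  tibble::tibble(
    haplotype = unname(reps[ord]),
    sequence = names(groups)[ord],
    multiplicity = unname(lengths(groups)[ord]),
    members = unname(groups[ord])
  )
}

#' Parsimony connection limit for a sequence length
#'
#' The largest number of observed differences j between two haplotypes
#' such that, with probability at least `prob`, each of the j differing
#' sites arose from exactly one substitution (no hidden multiple hits), so
#' the mutational path between them is non-homoplastic. The per-site
#' substitution intensity is estimated from j/L by a Jukes-Cantor-style
#' multiple-hit correction; given at least one change at a site, the
#' probability that it was a single change comes from the Poisson hit
#' count, and independence across the j sites gives
#' `P(all single) = [mu exp(-mu) / (1 - exp(-mu))]^j`.
#'
#' @param seq_length alignment length L in sites.
#' @param prob parsimony probability (default 0.95).
#' @return Integer number of steps, in `[1, seq_length]`.
#' @export
connection_limit <- function(seq_length, prob = 0.95) {
  if (seq_length < 1L) rlang::abort("seq_length must be >= 1")
  if (prob <= 0 || prob >= 1) rlang::abort("prob must be in (0, 1)")
  j <- seq_len(seq_length)
  p_single <- single_hit_prob(j, seq_length)
  ok <- j * log(p_single) >= log(prob)   # log scale avoids underflow
  if (!any(ok)) return(1L)   # a single step is always allowed to connect
  max(which(ok))
}

# P(a differing site arose from exactly one substitution | >= one change),
# under Poisson(mu) hits per site with mu the JC-corrected divergence for
# j observed differences over L sites
single_hit_prob <- function(j, L) {
  phat <- pmin(j / L, 0.75 * (1 - 1e-9))
  mu <- -0.75 * log(1 - 4 / 3 * phat)
  ifelse(mu <= 0, 1, mu * exp(-mu) / (1 - exp(-mu)))
}

#' Build statistical-parsimony networks from haplotypes
#'
#' Networks are the connected components of the haplotype graph with an
#' edge wherever the Hamming distance (differing sites, sites with N in
#' either sequence excluded) is at most the connection limit. Network
#' membership is then expanded back to specimens. Long, presumably
#' homoplastic mutational paths are thereby cut, so components act as
#' species surrogates.
#'
#' @param haps haplotype tibble from [collapse_haplotypes()].
#' @param limit connection limit in substitution steps (`>= 1`).
#' @return Partition tibble (`kind = "network"`) over all member
#'   specimens, with attributes `"connection_limit"`.
#' @export
build_networks <- function(haps, limit) {
  if (limit < 1L) rlang::abort("connection limit must be >= 1")
  n <- nrow(haps)
  seqs <- strsplit(haps$sequence, "", fixed = TRUE)
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      si <- seqs[[i]]
      for (k in (i + 1L):n) {
        sk <- seqs[[k]]
        comparable <- si != "N" & sk != "N"
        dist <- sum(si[comparable] != sk[comparable])
        adj[i, k] <- adj[k, i] <- dist <= limit
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  first_member <- vapply(split(haps$haplotype, comp), `[[`, "", 1L)
  lab_order <- order(first_member)
  relabel <- integer(length(lab_order))
  relabel[lab_order] <- seq_along(lab_order)
  members <- haps$members
  part <- new_partition(
    unlist(members),
    rep(sprintf("N%04d", relabel[comp]), lengths(members)),
    kind = "network"
  )
  attr(part, "connection_limit") <- as.integer(limit)
  part
}

#' Delimit species surrogates by statistical-parsimony networks
#'
#' Convenience wrapper: collapse haplotypes, derive the connection limit
#' from the alignment length at the given parsimony probability (unless an
#' explicit `limit` is supplied, e.g. to match a published analysis), and
#' build networks.
#'
#' @param aln alignment tibble.
#' @param limit optional explicit connection limit in steps; overrides
#'   `prob`.
#' @param prob parsimony probability used to derive the limit (default
#'   0.95).
#' @return Partition tibble (`kind = "network"`).
#' @export
delimit_networks <- function(aln, limit = NULL, prob = 0.95) {
  haps <- collapse_haplotypes(aln)
  if (is.null(limit)) limit <- connection_limit(alignment_length(aln), prob)
  build_networks(haps, limit)
}
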