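# Independent oracles and tiny fixture builders used across the suite.
# These deliberately re-derive results with the most naive algorithm
# available (site loops, union-find, hand-expanded likelihood sums) and
# never call the package internals they are checking.

# ---- brute-force union-find clustering oracle -----------------------------

uf_cluster <- function(dm, t) {
  ids <- rownames(dm)
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (dm[i, j] <= t) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(ids, comp)
}

# canonical form of a partition for comparison: sorted list of sorted groups
canonical_groups <- function(groups) {
  g <- lapply(groups, sort)
  unname(g[order(vapply(g, `[[`, "", 1L))])
}

partition_as_groups <- function(partition) {
  canonical_groups(split(partition$specimen_id, partition$group))
}

# ---- naive per-site p-distance oracle -------------------------------------

p_dist_site_loop <- function(seq1, seq2) {
  a <- strsplit(seq1, "")[[1]]
  b <- strsplit(seq2, "")[[1]]
  comparable <- a != "N" & b != "N"
  sum(a[comparable] != b[comparable]) / sum(comparable)
}

# ---- single-process likelihood oracles for the GMYC limits ----------------

# pure diversification: events at all internal node heights (root included),
# counts 2..n below successive events, intervals down to `floor`
oracle_pure_yule <- function(tree, lambda, p, floor = 0) {
  n <- ape::Ntip(tree)
  h <- sort(barcodiv::node_heights(tree)[(n + 1):(n + tree$Nnode)],
            decreasing = TRUE)
  ll <- 0
  bounds <- c(h, floor)
  for (i in seq_along(h)) {
    d <- i + 1
    ll <- ll + log(lambda * d^p) - lambda * d^p * (bounds[i] - bounds[i + 1])
  }
  ll
}

# single-group coalescent: intervals with m = n..2 lineages from the tips,
# every interval terminated (at its older end) by a coalescence at total
# rate lambda * (m (m - 1))^p
oracle_pure_coal <- function(tree, lambda, p) {
  n <- ape::Ntip(tree)
  h <- sort(barcodiv::node_heights(tree)[(n + 1):(n + tree$Nnode)])
  x <- diff(c(0, h))
  m <- n:2
  sum(log(lambda * (m * (m - 1))^p) - lambda * (m * (m - 1))^p * x)
}

# ---- tiny alignments ------------------------------------------------------

toy_alignment <- function(seqs, species = NULL, region = "") {
  n <- length(seqs)
  if (is.null(species)) species <- paste0("Gen sp", seq_len(n))
  new_alignment(species, sprintf("T%02d", seq_len(n)), region, seqs)
}

# random gap-free test alignment (not via the simulator)
random_alignment <- function(n, L, n_frac = 0) {
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (n_frac > 0) {
      k <- rbinom(1, L, n_frac)
      if (k > 0) s[sample.int(L, k)] <- "N"
    }
    paste(s, collapse = "")
  }, "")
  toy_alignment(seqs)
}

# fabricate a truth/estimate partition pair realizing given evaluation
# counts: p perfect species, s species split into two groups each, and the
# remaining species lumped into `l` groups (each with >= 2 species)
fabricate_eval_case <- function(n_species, n_groups, n_perfect) {
  s <- n_species; g <- n_groups; p <- n_perfect
  for (l in 0:6) {
    spl <- g - p - l
    if (spl %% 2 != 0) next
    spl <- spl / 2
    if (spl < 0) next
    lumped_sp <- s - p - spl
    if (l == 0 && lumped_sp != 0) next
    if (l > 0 && lumped_sp < 2 * l) next
    truth_sp <- character(); truth_id <- character()
    est_id <- character(); est_gr <- character()
    add <- function(species, id, group) {
      truth_sp <<- c(truth_sp, species); truth_id <<- c(truth_id, id)
      est_id <<- c(est_id, id); est_gr <<- c(est_gr, group)
    }
    k <- 0
    for (i in seq_len(p)) {
      k <- k + 1
      add(sprintf("Gen perf%03d", i), sprintf("P%04d", k), sprintf("gP%03d", i))
    }
    for (i in seq_len(spl)) {
      k <- k + 1
      add(sprintf("Gen split%03d", i), sprintf("S%04da", k), sprintf("gSa%03d", i))
      add(sprintf("Gen split%03d", i), sprintf("S%04db", k), sprintf("gSb%03d", i))
    }
    if (l > 0) {
      sizes <- rep(2, l)
      extra <- lumped_sp - 2 * l
      sizes[1] <- sizes[1] + extra
      idx <- 0
      for (i in seq_len(l)) {
        for (j in seq_len(sizes[i])) {
          idx <- idx + 1; k <- k + 1
          add(sprintf("Gen lump%03d", idx), sprintf("L%04d", k),
              sprintf("gL%03d", i))
        }
      }
    }
    truth <- new_partition(truth_id, truth_sp, kind = "morphospecies")
    est <- new_partition(est_id, est_gr, kind = "cluster")
    return(list(truth = truth, estimate = est))
  }
  stop("cannot fabricate counts ", s, "/", g, "/", p)
}

# partition + region map with a prescribed number of pooled groups and
# groups shared between two regions
fabricate_shared_case <- function(n_groups, n_shared, regions = c("A", "B")) {
  ids <- character(); grp <- character(); reg <- character()
  k <- 0
  for (i in seq_len(n_groups)) {
    k <- k + 1
    in_both <- i <= n_shared
    ids <- c(ids, sprintf("X%04d", k)); grp <- c(grp, sprintf("g%04d", i))
    reg <- c(reg, regions[1 + (i %% 2) * (!in_both)])
    if (in_both) {
      k <- k + 1
      ids <- c(ids, sprintf("X%04d", k)); grp <- c(grp, sprintf("g%04d", i))
      reg <- c(reg, regions[2])
    }
  }
  list(
    partition = new_partition(ids, grp, kind = "cluster"),
    region_map = tibble::tibble(specimen_id = ids, region = reg)
  )
}

# fast well-separated simulation config for recovery-style tests
recovery_config <- function(seed, n_species = 20, ...) {
  sim_config(n_species = n_species, coal_depth = 0.1, min_split_age = 2,
             seed = seed, ...)
}

radiation_config <- function(seed, n_species = 20) {
  sim_config(n_species = n_species, coal_depth = 0.5, min_split_age = 3,
             radiation = list(n_species = 8, age = 0.3), seed = seed)
}
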