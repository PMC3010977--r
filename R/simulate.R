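#' Simulation configuration
#'
#' All knobs of the synthetic barcode-data generator. Defaults emulate a
#' continental beetle barcode survey: a few-dozen-species Yule radiation
#' over tens of millions of years, shallow within-species coalescence so
#' that most intraspecific divergence stays below 2%, an 828 bp
#' protein-coding fragment evolving at the standard insect mitochondrial
#' pairwise rate of 2.3% per Ma, skewed specimen sampling with singletons,
#' and species ranges spanning a handful of regions on a line, giving a
#' distance decay of shared species. An optional `radiation` block grafts a
#' clade of very recent species whose lineage sorting is incomplete, the
#' main error source for all delimitation methods.
#'
#' @param n_species number of species.
#' @param yule_rate per-Ma speciation rate used for tree shape (the tree is
#'   rescaled to `crown_age`).
#' @param crown_age age of the species-tree crown, Ma.
#' @param coal_depth expected within-species pairwise coalescence time, Ma.
#' @param samples_mean,samples_max,singleton_fraction specimen sampling:
#'   zero-truncated negative-binomial mean and cap, plus the fraction of
#'   species forced to a single specimen.
#' @param samples_size negative-binomial dispersion.
#' @param seq_length alignment length in sites; must be divisible by 3.
#' @param subst_rate pairwise divergence per Ma of separation (0.023 =
#'   2.3% per Ma; per-lineage branch rate is half of this).
#' @param kappa transition/transversion rate ratio of the K2P-style
#'   substitution process.
#' @param n_regions number of regions on the 1-D coordinate line.
#' @param region_spacing_km distance between adjacent regions.
#' @param range_geom_p geometric parameter of species range size (expected
#'   range about `1/range_geom_p` regions).
#' @param genus_age Ma; clades younger than this form one genus (used to
#'   name species and define "congeneric").
#' @param min_split_age Ma; when positive, speciation times of the base
#'   tree are linearly rescaled into `[min_split_age, crown_age]`,
#'   emulating a clade whose diversification slowed down so that all
#'   species are old and well separated (a grafted radiation is not
#'   affected). Default 0 (plain Yule ages).
#' @param radiation `NULL`, or `list(n_species =, age =)` forcing that many
#'   species into a clade whose internal divergences all postdate `age`
#'   (Ma); `age` must be below `crown_age`.
#' @param seed integer seed; [simulate_dataset()] sets it once up front.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 40,
                       yule_rate = 0.15,
                       crown_age = 35,
                       coal_depth = 0.5,
                       samples_mean = 4.8,
                       samples_max = 32,
                       samples_size = 1.5,
                       singleton_fraction = 0.1,
                       seq_length = 828,
                       subst_rate = 0.023,
                       kappa = 4,
                       n_regions = 6,
                       region_spacing_km = 500,
                       range_geom_p = 0.45,
                       genus_age = 10,
                       min_split_age = 0,
                       radiation = NULL,
                       seed = 1L) {
  if (n_species < 1) rlang::abort("n_species must be >= 1")
  if (yule_rate <= 0 || crown_age <= 0 || coal_depth <= 0 || subst_rate <= 0) {
    rlang::abort("all rates and ages must be > 0")
  }
  if (seq_length %% 3 != 0) rlang::abort("seq_length must be divisible by 3")
  if (!is.null(radiation)) {
    if (!all(c("n_species", "age") %in% names(radiation))) {
      rlang::abort("radiation must be list(n_species =, age =)")
    }
    if (radiation$age >= crown_age) {
      rlang::abort("radiation age must be below crown_age")
    }
    if (radiation$n_species < 2 || radiation$n_species >= n_species) {
      rlang::abort("radiation n_species must be in [2, n_species)")
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

# single-tip phylo (crown age is undefined; the tip sits at height 0)
single_tip_tree <- function(label) {
  structure(list(
    edge = matrix(c(2L, 1L), 1L, 2L),
    tip.label = label,
    edge.length = 0,
    Nnode = 1L
  ), class = "phylo")
}

#' Simulate a species tree
#'
#' Yule (pure-birth) tree conditioned on the species count, rescaled so the
#' crown sits at `crown_age`. With a `radiation` block, one randomly chosen
#' tip is replaced by a Yule subtree whose crown is at 90% of the
#' radiation age, so all divergences inside the radiation clade postdate
#' `radiation$age`. Tips are then named `"GenXX spYYY"`, genera being the
#' clades younger than `genus_age`; the radiation species are recorded in
#' attribute `"radiation_species"`.
#'
#' @param config `sim_config`.
#' @return Ultrametric `phylo` over species.
#' @export
simulate_species_tree <- function(config) {
  n <- config$n_species
  if (n == 1L) {
    tr <- single_tip_tree("sp001")
    tr$tip.label <- "Gen01 sp001"
    attr(tr, "radiation_species") <- character()
    return(tr)
  }
  rad <- config$radiation
  n_base <- if (is.null(rad)) n else n - rad$n_species + 1L
  if (n_base >= 2L) {
    tr <- ape::rphylo(n_base, birth = config$yule_rate, death = 0)
    tr$edge.length <- tr$edge.length * config$crown_age / max(node_heights(tr))
    if (config$min_split_age > 0) {
      # diversification slowdown: push all speciation times above the floor
      h <- node_heights(tr)
      ca <- config$crown_age
      fl <- config$min_split_age
      ntip <- ape::Ntip(tr)
      h_new <- h
      idx <- (ntip + 1L):(ntip + tr$Nnode)
      h_new[idx] <- fl + h[idx] * (ca - fl) / ca
      tr$edge.length <- h_new[tr$edge[, 1L]] - h_new[tr$edge[, 2L]]
    }
  } else {
    tr <- NULL  # radiation spans all but the stem: handled below
  }

  rad_tips <- character()
  if (!is.null(rad)) {
    rad_crown <- 0.9 * rad$age
    sub <- ape::rphylo(rad$n_species, birth = config$yule_rate, death = 0)
    sub$edge.length <- sub$edge.length * rad_crown / max(node_heights(sub))
    sub$tip.label <- sprintf("RADTIP%03d", seq_len(rad$n_species))
    rad_tips <- sub$tip.label
    if (is.null(tr)) {
      tr <- sub
    } else {
      # graft onto a terminal edge long enough to hold the radiation crown
      h <- node_heights(tr)
      parent <- node_parents(tr)
      ptip <- h[parent[seq_len(ape::Ntip(tr))]]
      eligible <- which(ptip > rad$age)
      tip_idx <- if (length(eligible)) {
        eligible[sample.int(length(eligible), 1L)]
      } else {
        which.max(ptip)
      }
      pos <- min(rad_crown, 0.9 * ptip[tip_idx])
      if (pos < rad_crown) {
        sub$edge.length <- sub$edge.length * pos / rad_crown
      }
      old_lab <- tr$tip.label[tip_idx]
      tr <- ape::bind.tree(tr, sub, where = tip_idx, position = pos)
      tr <- ape::drop.tip(tr, old_lab)
    }
  }

  # name species; genera = clades younger than genus_age
  h <- node_heights(tr)
  parent <- node_parents(tr)
  ntip <- ape::Ntip(tr)
  genus_root <- vapply(seq_len(ntip), function(v) {
    u <- v
    while (!is.na(parent[u]) && h[parent[u]] < config$genus_age) u <- parent[u]
    u
  }, 0L)
  genera <- split(seq_len(ntip), genus_root)
  genera <- genera[order(vapply(genera, min, 0L))]
  old_labels <- tr$tip.label
  new_labels <- character(ntip)
  for (g in seq_along(genera)) {
    for (v in genera[[g]]) {
      new_labels[v] <- sprintf("Gen%02d sp%03d", g, v)
    }
  }
  tr$tip.label <- new_labels
  attr(tr, "radiation_species") <- new_labels[match(rad_tips, old_labels)]
  tr
}

# lineages in one population coalesce backward in time at rate
# choose(k, 2) / coal_depth between t_start and t_end
coalesce_interval <- function(lineages, t_start, t_end, coal_depth, state) {
  t <- t_start
  while (length(lineages) >= 2L) {
    k <- length(lineages)
    t <- t + stats::rexp(1L, rate = k * (k - 1) / 2 / coal_depth)
    if (t >= t_end) break
    pick <- sample.int(k, 2L)
    state$n_internal <- state$n_internal + 1L
    id <- -state$n_internal  # negative ids for internal gene nodes
    state$children[[state$n_internal]] <- lineages[pick]
    state$heights[state$n_internal] <- t
    lineages <- c(lineages[-pick], id)
  }
  lineages
}

#' Simulate a gene tree under the multispecies coalescent
#'
#' Within each species, the sampled lineages coalesce backward in time at
#' rate `choose(k, 2) / coal_depth` (so the expected pairwise
#' within-species coalescence time is `coal_depth`); lineages that fail to
#' coalesce before a speciation time enter the ancestral species. When
#' `coal_depth` is much smaller than the species divergences every species
#' is monophyletic in the gene tree; when a radiation is younger than
#' `coal_depth`, incomplete lineage sorting makes species
#' non-monophyletic.
#'
#' @param species_tree ultrametric `phylo` over species.
#' @param config `sim_config`.
#' @param samples optional named integer vector (per species) of specimen
#'   counts; default drawn from the config's sampling distribution.
#' @return Ultrametric `phylo` over specimens; tip labels are specimen
#'   ids, and attribute `"specimen_species"` maps them to species.
#' @export
simulate_gene_tree <- function(species_tree, config, samples = NULL) {
  sp <- species_tree$tip.label
  if (is.null(samples)) samples <- draw_sample_sizes(length(sp), config)
  if (is.null(names(samples))) names(samples) <- sp

  specimen_species <- rep(sp, samples[sp])
  specimen_id <- sprintf("S%04d", seq_along(specimen_species))
  names(specimen_id) <- NULL

  ntip_sp <- length(sp)
  single <- ntip_sp == 1L
  h <- if (single) 0 else node_heights(species_tree)
  parent <- if (single) NA_integer_ else node_parents(species_tree)
  root <- ntip_sp + 1L

  state <- new.env()
  state$n_internal <- 0L
  state$children <- list()
  state$heights <- numeric()

  # positive ids are specimen (gene-tip) indices
  pops <- split(seq_along(specimen_id), match(specimen_species, sp))

  if (single) {
    lin <- coalesce_interval(pops[[1L]], 0, Inf, config$coal_depth, state)
  } else {
    ord <- order(h[1:(ntip_sp + species_tree$Nnode)])
    pending <- vector("list", ntip_sp + species_tree$Nnode)
    for (i in seq_along(pops)) {
      pending[[as.integer(names(pops)[i])]] <- pops[[i]]
    }
    for (v in ord) {
      if (v > ntip_sp || !is.null(pending[[v]])) {
        lineages <- pending[[v]]
        if (is.null(lineages)) lineages <- integer()
        t_start <- if (v <= ntip_sp) 0 else h[v]
        t_end <- if (is.na(parent[v])) Inf else h[parent[v]]
        surv <- coalesce_interval(lineages, t_start, t_end,
                                  config$coal_depth, state)
        if (is.na(parent[v])) {
          lin <- surv
        } else {
          pending[[parent[v]]] <- c(pending[[parent[v]]], surv)
        }
      }
    }
  }
  stopifnot(length(lin) == 1L)

  gt <- build_gene_phylo(lin, specimen_id, state)
  attr(gt, "specimen_species") <- stats::setNames(specimen_species, specimen_id)
  gt
}

# assemble a phylo from the coalescent event records
build_gene_phylo <- function(root_lineage, specimen_id, state) {
  n <- length(specimen_id)
  if (n == 1L) return(single_tip_tree(specimen_id))
  newick_of <- function(node, parent_h) {
    if (node > 0) {
      paste0(specimen_id[node], ":", format(parent_h, digits = 17))
    } else {
      k <- -node
      ch <- state$children[[k]]
      hk <- state$heights[k]
      paste0("(", newick_of(ch[1L], hk), ",", newick_of(ch[2L], hk), "):",
             format(parent_h - hk, digits = 17))
    }
  }
  k <- -root_lineage
  hk <- state$heights[k]
  ch <- state$children[[k]]
  txt <- paste0("(", newick_of(ch[1L], hk), ",", newick_of(ch[2L], hk), ");")
  ape::read.tree(text = txt)
}

# zero-truncated negative binomial sampling with singleton inflation
draw_sample_sizes <- function(n_sp, config) {
  out <- integer(n_sp)
  for (i in seq_len(n_sp)) {
    if (stats::runif(1L) < config$singleton_fraction) {
      out[i] <- 1L
    } else {
      k <- 0L
      while (k < 1L) {
        k <- stats::rnbinom(1L, size = config$samples_size,
                            mu = config$samples_mean)
      }
      out[i] <- min(k, config$samples_max)
    }
  }
  out
}

#' Evolve protein-coding sequences down a gene tree
#'
#' The root sequence is drawn codon-wise from the stop-free codons of the
#' invertebrate mitochondrial code; sites then evolve under a K2P-style
#' process (transition/transversion ratio `kappa`) with per-lineage rate
#' `subst_rate / 2` per Ma, so two tips whose most recent common ancestor
#' sits `t` Ma back are expected to differ by about `subst_rate * t`
#' before multiple-hit saturation. Proposed mutations creating an in-frame
#' stop codon (TAA/TAG) are rejected and redrawn, so the output always
#' passes the stop-codon QC screen. No indels are generated.
#'
#' @param gene_tree ultrametric `phylo` over specimens (attribute
#'   `"specimen_species"` as produced by [simulate_gene_tree()]).
#' @param config `sim_config`.
#' @param region_map optional tibble (`specimen_id`, `region`) to fill the
#'   region column; default empty regions.
#' @return Alignment tibble.
#' @export
evolve_sequences <- function(gene_tree, config, region_map = NULL) {
  bases <- c("A", "C", "G", "T")
  L <- config$seq_length
  r <- config$subst_rate / 2
  kappa <- config$kappa
  p_ts <- kappa / (kappa + 2)
  transition <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T
  stops <- c("TAA", "TAG")  # invertebrate mitochondrial code

  codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                            function(ab, c) paste0(ab, c)))
  ok_codons <- setdiff(codons, stops)
  root_codons <- sample(ok_codons, L / 3, replace = TRUE)
  root_seq <- match(unlist(strsplit(root_codons, "")), bases)

  n <- ape::Ntip(gene_tree)
  labels <- gene_tree$tip.label
  seqs <- vector("list", n + gene_tree$Nnode)

  if (n == 1L) {
    seqs[[1L]] <- root_seq
  } else {
    tr <- ape::reorder.phylo(gene_tree, "cladewise")
    root <- n + 1L
    seqs[[root]] <- root_seq
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]
      child <- tr$edge[e, 2L]
      s <- seqs[[par]]
      M <- stats::rpois(1L, r * tr$edge.length[e] * L)
      m <- 0L
      attempts <- 0L
      while (m < M && attempts < 50L * M + 100L) {
        attempts <- attempts + 1L
        site <- sample.int(L, 1L)
        old <- s[site]
        new <- if (stats::runif(1L) < p_ts) {
          transition[old]
        } else {
          tv <- setdiff(1:4, c(old, transition[old]))
          tv[sample.int(2L, 1L)]
        }
        cod <- (site - 1L) %/% 3L
        pos <- cod * 3L + 1:3
        trial <- s[pos]
        trial[site - cod * 3L] <- new
        if (paste(bases[trial], collapse = "") %in% stops) next
        s[site] <- new
        m <- m + 1L
      }
      seqs[[child]] <- s
    }
  }

  sequence <- vapply(seq_len(n), function(i) {
    paste(bases[seqs[[i]]], collapse = "")
  }, "")
  sp_map <- attr(gene_tree, "specimen_species")
  species <- if (is.null(sp_map)) rep("unknown", n) else unname(sp_map[labels])
  region <- rep("", n)
  if (!is.null(region_map)) {
    region <- region_map$region[match(labels, region_map$specimen_id)]
    region[is.na(region)] <- ""
  }
  new_alignment(species, labels, region, sequence)
}

#' Assign species to regions with distance decay
#'
#' Regions sit on a one-dimensional line. Each species occupies a
#' contiguous run of regions: a uniform-random center and a geometric range
#' size (clipped to the line), so nearby regions share more species than
#' distant ones and Sorensen similarity decays with distance.
#'
#' @param species character vector of species names.
#' @param config `sim_config`.
#' @return A list: `species_regions` (tibble `species`, `region`, one row
#'   per occupied region), `regions` (character vector in spatial order)
#'   and `distances` (region-pair distance tibble).
#' @export
assign_regions <- function(species, config) {
  R <- config$n_regions
  regions <- sprintf("R%d", seq_len(R))
  rows <- lapply(species, function(s) {
    center <- sample.int(R, 1L)
    size <- min(1L + stats::rgeom(1L, config$range_geom_p), R)
    lo <- center - (size - 1L) %/% 2L
    hi <- lo + size - 1L
    if (lo < 1L) { hi <- hi + (1L - lo); lo <- 1L }
    if (hi > R) { lo <- lo - (hi - R); hi <- R }
    tibble::tibble(species = s, region = regions[lo:hi])
  })
  list(
    species_regions = dplyr::bind_rows(rows),
    regions = regions,
    distances = region_distance_table(regions, config$region_spacing_km)
  )
}

#' Simulate a complete synthetic barcode dataset
#'
#' Runs the full generator under one seed: species tree, region
#' assignment, specimen sampling, multispecies-coalescent gene tree,
#' sequence evolution and labeling. Identical config and seed give a
#' bit-identical result.
#'
#' @param config `sim_config`.
#' @return An object of class `sim_dataset`: list with `config`,
#'   `species_tree`, `gene_tree`, `alignment`, `truth` (morphospecies
#'   partition), `region_map` (tibble `specimen_id`, `region`),
#'   `species_regions`, `region_distances` and `radiation_species`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  sp_tree <- simulate_species_tree(config)
  geo <- assign_regions(sp_tree$tip.label, config)
  gene_tree <- simulate_gene_tree(sp_tree, config)
  sp_map <- attr(gene_tree, "specimen_species")
  region_map <- tibble::tibble(
    specimen_id = names(sp_map),
    region = vapply(unname(sp_map), function(s) {
      occ <- geo$species_regions$region[geo$species_regions$species == s]
      occ[sample.int(length(occ), 1L)]
    }, "")
  )
  aln <- evolve_sequences(gene_tree, config, region_map)
  structure(list(
    config = config,
    species_tree = sp_tree,
    gene_tree = gene_tree,
    alignment = aln,
    truth = morphospecies_partition(aln),
    region_map = region_map,
    species_regions = geo$species_regions,
    region_distances = geo$distances,
    radiation_species = attr(sp_tree, "radiation_species")
  ), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic barcode dataset\n")
  cat(sprintf("  species: %d  specimens: %d  sites: %d\n",
              length(unique(x$alignment$species)), nrow(x$alignment),
              alignment_length(x$alignment)))
  cat(sprintf("  regions: %d  seed: %s\n",
              length(unique(x$region_map$region)), x$config$seed))
  if (length(x$radiation_species)) {
    cat(sprintf("  recent-radiation species: %d\n",
                length(x$radiation_species)))
  }
  invisible(x)
}

#' Is each species monophyletic in the gene tree?
#'
#' @param gene_tree `phylo` with attribute `"specimen_species"`.
#' @return Named logical vector over species (singletons are trivially
#'   monophyletic).
#' @export
species_monophyly <- function(gene_tree) {
  sp_map <- attr(gene_tree, "specimen_species")
  species <- unique(unname(sp_map))
  n <- ape::Ntip(gene_tree)
  tips_of <- clade_tips(gene_tree)
  clade_keys <- vapply(tips_of, function(i) {
    paste(sort(gene_tree$tip.label[i]), collapse = "\r")
  }, "")
  vapply(stats::setNames(species, species), function(s) {
    members <- sort(names(sp_map)[sp_map == s])
    if (length(members) <= 1L) return(TRUE)
    paste(members, collapse = "\r") %in% clade_keys
  }, TRUE)
}
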