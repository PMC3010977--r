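#' Build a labeled barcode alignment
#'
#' The central data structure of the package is a plain tibble with one row
#' per sequenced specimen and columns `species`, `specimen_id`, `region` and
#' `sequence`. All sequences must be equal-length, gap-free and drawn from
#' the alphabet A, C, G, T, N; this mirrors a quality-screened, indel-free
#' protein-coding barcode alignment.
#'
#' @param species character vector of species names ("Genus epithet" or an
#'   operational name); the genus is taken as the first whitespace token.
#' @param specimen_id character vector of unique specimen identifiers.
#' @param region character vector of region codes (may be `NA` or `""`).
#' @param sequence character vector of aligned nucleotide sequences.
#' @return A tibble with columns `species`, `specimen_id`, `region`,
#'   `sequence`, validated against the alignment invariants.
#' @export
new_alignment <- function(species, specimen_id, region, sequence) {
  aln <- tibble::tibble(
    species = as.character(species),
    specimen_id = as.character(specimen_id),
    region = as.character(region),
    sequence = toupper(as.character(sequence))
  )
  validate_alignment(aln)
  aln
}

#' Validate alignment invariants
#'
#' Checks equal sequence lengths, the A/C/G/T/N alphabet (no gaps or
#' ambiguity codes other than N), non-empty species names and uniqueness of
#' (species, specimen_id).
#'
#' @param aln alignment tibble as returned by [new_alignment()] or
#'   [read_fasta()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_alignment <- function(aln) {
  req <- c("species", "specimen_id", "region", "sequence")
  if (!all(req %in% names(aln))) {
    rlang::abort(paste0(
      "alignment must have columns ",
      paste(req, collapse = ", ")
    ))
  }
  if (nrow(aln) == 0L) return(invisible(aln))
  if (any(!nzchar(aln$species) | is.na(aln$species))) {
    rlang::abort("alignment error: empty species name")
  }
  if (anyDuplicated(aln$specimen_id)) {
    dup <- unique(aln$specimen_id[duplicated(aln$specimen_id)])
    rlang::abort(paste0(
      "alignment error: duplicated specimen ids: ",
      paste(utils::head(dup, 5), collapse = ", ")
    ))
  }
  len <- nchar(aln$sequence)
  if (length(unique(len)) != 1L) {
    rlang::abort(paste0(
      "alignment error: unequal sequence lengths (",
      paste(unique(len), collapse = ", "), ")"
    ))
  }
  bad <- grepl("[^ACGTN]", aln$sequence)
  if (any(bad)) {
    rlang::abort(paste0(
      "alignment error: sequence of ", aln$specimen_id[which(bad)[1]],
      " contains characters outside A/C/G/T/N (gaps are not allowed)"
    ))
  }
  invisible(aln)
}

#' Alignment length in sites
#' @param aln alignment tibble.
#' @return Integer number of aligned sites.
#' @export
alignment_length <- function(aln) {
  if (nrow(aln) == 0L) return(0L)
  nchar(aln$sequence[[1]])
}

# character matrix (specimens x sites), rownames = specimen ids
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(m) <- aln$specimen_id
  m
}

#' Extract the genus from species names
#'
#' The genus of a species is its first whitespace-separated token; needed
#' for congeneric-distance statistics.
#'
#' @param species character vector of species names.
#' @return Character vector of genus names.
#' @export
genus_of <- function(species) {
  sub("\\s.*$", "", species)
}

# ---- FASTA with structured labels -----------------------------------------

parse_labels <- function(headers, label_scheme = c("pipe", "spaces")) {
  label_scheme <- match.arg(label_scheme)
  if (label_scheme == "pipe") {
    parts <- strsplit(headers, "|", fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad)) {
      rlang::abort(paste0(
        "label error: header '", headers[which(bad)[1]],
        "' does not parse as species|specimen[|region]"
      ))
    }
    tibble::tibble(
      species = trimws(vapply(parts, `[[`, "", 1L)),
      specimen_id = trimws(vapply(parts, `[[`, "", 2L)),
      region = trimws(vapply(parts, function(p) {
        if (length(p) >= 3L) p[[3L]] else ""
      }, ""))
    )
  } else {
    # "Genus species" or "Genus species ID": first two tokens are the
    # binomial, an optional third token the specimen id
    parts <- strsplit(trimws(headers), "\\s+")
    bad <- lengths(parts) < 2L
    if (any(bad)) {
      rlang::abort(paste0(
        "label error: header '", headers[which(bad)[1]],
        "' does not parse as 'Genus species [ID]'"
      ))
    }
    tibble::tibble(
      species = vapply(parts, function(p) paste(p[1:2], collapse = " "), ""),
      specimen_id = vapply(parts, function(p) {
        if (length(p) >= 3L) paste(p[-(1:2)], collapse = "_") else
          paste(p[1:2], collapse = "_")
      }, ""),
      region = ""
    )
  }
}

#' Read a labeled FASTA alignment
#'
#' Headers carry the specimen label in one of two schemes: `"pipe"`
#' (`species|specimenID|region`, the canonical internal form) or `"spaces"`
#' (`Genus species [ID]`, the loose convention of distance-clustering
#' tools that recognize a priori species from the sequence name).
#'
#' @param path FASTA file path.
#' @param label_scheme `"pipe"` (default) or `"spaces"`.
#' @return Alignment tibble (see [new_alignment()]); record order preserved.
#' @export
read_fasta <- function(path, label_scheme = c("pipe", "spaces")) {
  label_scheme <- match.arg(label_scheme)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) rlang::abort("alignment error: no FASTA records")
  headers <- sub("^>\\s*", "", lines[hdr_idx])
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, "")
  seqs <- toupper(gsub("\\s", "", seqs))
  if (any(grepl("-", seqs, fixed = TRUE))) {
    rlang::abort("alignment error: gap characters present (alignment must be free of indels)")
  }
  labs <- parse_labels(headers, label_scheme)
  new_alignment(labs$species, labs$specimen_id, labs$region, seqs)
}

#' Write a labeled FASTA alignment
#'
#' @param aln alignment tibble.
#' @param path output path.
#' @param label_scheme header scheme; see [read_fasta()].
#' @param width sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, label_scheme = c("pipe", "spaces"),
                        width = 70L) {
  label_scheme <- match.arg(label_scheme)
  validate_alignment(aln)
  hdr <- if (label_scheme == "pipe") {
    paste0(">", aln$species, "|", aln$specimen_id, "|",
           ifelse(is.na(aln$region), "", aln$region))
  } else {
    paste0(">", aln$species, " ", aln$specimen_id)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(hdr[i], con)
    s <- aln$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- Newick trees ---------------------------------------------------------

#' Node heights of a rooted tree
#'
#' Heights are times before the present: tips sit at (approximately) zero,
#' the root at the crown age. Entries are ordered as in `ape`'s internal
#' node numbering (tips `1..n`, then internal nodes).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return Numeric vector of length `n + Nnode`.
#' @export
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Relative ultrametricity deviation
#'
#' Maximum spread of root-to-tip path lengths divided by the tree height.
#'
#' @param tree a rooted `phylo`.
#' @return Non-negative scalar; 0 for a perfectly ultrametric tree.
#' @export
ultrametric_deviation <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_len(ape::Ntip(tree))]
  if (max(tipd) == 0) return(0)
  (max(tipd) - min(tipd)) / max(tipd)
}

#' Read a rooted tree with branch lengths from Newick
#'
#' Polytomies are resolved arbitrarily into zero-length branches (they are
#' later perturbed by the GMYC preprocessing). Ultrametricity is *not*
#' enforced here -- the GMYC entry point checks it against its tolerance --
#' but branch lengths and rootedness are.
#'
#' @param path Newick file path.
#' @return A rooted, fully dichotomous `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) rlang::abort("format error: expected a single tree")
    tree <- tree[[1L]]
  }
  if (is.null(tree)) rlang::abort("format error: could not parse Newick")
  if (is.null(tree$edge.length)) {
    rlang::abort("format error: tree has no branch lengths")
  }
  if (!ape::is.rooted(tree)) rlang::abort("format error: tree is unrooted")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  tree
}

#' Write a tree to Newick
#' @param tree a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 17)
  invisible(path)
}

# ---- partitions -----------------------------------------------------------

#' Construct a specimen partition
#'
#' A partition is a tibble with columns `specimen_id` and `group`; every
#' specimen belongs to exactly one group. `kind` records what the grouping
#' is (morphospecies truth, distance cluster, GMYC entity, parsimony
#' network, PAA aggregate).
#'
#' @param specimen_id character vector.
#' @param group character vector, same length.
#' @param kind one of `"morphospecies"`, `"cluster"`, `"gmyc_entity"`,
#'   `"network"`, `"paa_aggregate"`.
#' @return A tibble with attribute `"kind"`.
#' @export
new_partition <- function(specimen_id, group,
                          kind = c("morphospecies", "cluster", "gmyc_entity",
                                   "network", "paa_aggregate")) {
  kind <- match.arg(kind)
  if (length(specimen_id) != length(group)) {
    rlang::abort("partition error: specimen_id and group lengths differ")
  }
  if (anyDuplicated(specimen_id)) {
    rlang::abort("partition error: a specimen appears in more than one group")
  }
  if (any(is.na(group) | !nzchar(group))) {
    rlang::abort("partition error: empty group label")
  }
  out <- tibble::tibble(
    specimen_id = as.character(specimen_id),
    group = as.character(group)
  )
  attr(out, "kind") <- kind
  out
}

#' Morphospecies truth partition of an alignment
#'
#' @param aln alignment tibble.
#' @return Partition tibble (`kind = "morphospecies"`) mapping each
#'   specimen to its a priori species name.
#' @export
morphospecies_partition <- function(aln) {
  new_partition(aln$specimen_id, aln$species, kind = "morphospecies")
}

# list of specimen-id character vectors, named by group, ordered by the
# smallest member id of each group (canonical order)
partition_groups <- function(partition) {
  g <- split(partition$specimen_id, partition$group)
  g <- lapply(g, sort)
  g[order(vapply(g, `[[`, "", 1L))]
}
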