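#' Write an evaluation report (or any tibble) as TSV
#'
#' Deterministic formatting: fixed column order as given, tab-separated,
#' no quoting, full precision for numeric cells.
#'
#' @param report tibble or data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  # list columns cannot round-trip through TSV
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV report back
#' @param path TSV path written by [write_report()].
#' @return A tibble.
#' @export
read_report <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Write / read a partition as a two-column TSV
#'
#' Format: `specimen_id <tab> group`, one row per specimen.
#'
#' @param partition partition tibble.
#' @param path file path.
#' @return `path` (write) or a partition tibble (read).
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition[, c("specimen_id", "group")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @param kind partition kind to stamp on the read result.
#' @export
read_partition <- function(path, kind = "cluster") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  new_partition(df$specimen_id, df$group, kind = kind)
}

#' Subsample an alignment by genus, region or region set
#'
#' Mirrors the two subsampling axes of regional barcode surveys:
#' phylogenetic subsampling (all specimens of each genus, capturing sister
#' species) and regional subsampling (all specimens from an area or a
#' pooled set of areas).
#'
#' @param aln alignment tibble.
#' @param by `"genus"`, `"region"` or `"region_set"`.
#' @param region_sets for `by = "region_set"`: a list of character vectors
#'   of regions to pool (each set yields one alignment).
#' @return Named list of alignment tibbles; empty subsets are dropped with
#'   a warning.
#' @export
subsample_alignment <- function(aln, by = c("genus", "region", "region_set"),
                                region_sets = NULL) {
  by <- match.arg(by)
  validate_alignment(aln)
  out <- switch(by,
    genus = split(aln, genus_of(aln$species)),
    region = split(aln, aln$region),
    region_set = {
      if (is.null(region_sets)) rlang::abort("region_sets required")
      nm <- vapply(region_sets, paste, "", collapse = "+")
      stats::setNames(lapply(region_sets, function(rs) {
        aln[aln$region %in% rs, , drop = FALSE]
      }), nm)
    }
  )
  empty <- vapply(out, nrow, 0L) == 0L
  if (any(empty)) {
    rlang::warn(paste0("dropping empty subsets: ",
                       paste(names(out)[empty], collapse = ", ")))
    out <- out[!empty]
  }
  lapply(out, tibble::as_tibble)
}

# deterministic content hash of a tibble
table_hash <- function(df) {
  rlang::hash(lapply(as.data.frame(df), function(x) {
    if (is.numeric(x)) format(x, digits = 15) else as.character(x)
  }))
}

drop_gene_subtree <- function(gene_tree, keep_ids) {
  sp_map <- attr(gene_tree, "specimen_species")
  drop <- setdiff(gene_tree$tip.label, keep_ids)
  tr <- if (length(drop)) ape::drop.tip(gene_tree, drop) else gene_tree
  attr(tr, "specimen_species") <- sp_map[tr$tip.label]
  tr
}

#' Run the full delimitation-and-evaluation pipeline
#'
#' Orchestrates one end-to-end analysis over a dataset (typically a
#' [simulate_dataset()] result): for the whole data and each requested
#' subset, delimit by the requested methods, evaluate against the
#' morphospecies truth, and compute Sorensen beta-diversity across
#' regions. The GMYC stage consumes the supplied gene tree directly (for
#' synthetic data, the simulator's true gene tree; tree inference is out
#' of scope here), pruned to each subset.
#'
#' @param data a `sim_dataset`, or a list with elements `alignment`,
#'   `truth`, `region_map` and (for GMYC) `gene_tree` /
#'   `region_distances`.
#' @param methods subset of `"cluster"`, `"gmyc"`, `"network"`, `"paa"`.
#' @param thresholds clustering thresholds (fractions or percent).
#' @param subsets subset axes to analyze in addition to the pooled data:
#'   any of `"genus"`, `"region"`.
#' @param out_dir optional directory; when given, every partition and
#'   report is also written as TSV.
#' @return An object of class `pipeline_run`: list with `reports` (one
#'   evaluation row per subset x method x threshold), `partitions` (named
#'   list), `sorensen` (per partition kind, with distances), and
#'   `manifest` (tibble naming every artifact with row counts and content
#'   hashes).
#' @export
run_pipeline <- function(data,
                         methods = c("cluster", "gmyc", "network"),
                         thresholds = 0.03,
                         subsets = c("region"),
                         out_dir = NULL) {
  methods <- match.arg(methods, c("cluster", "gmyc", "network", "paa"),
                       several.ok = TRUE)
  thresholds <- normalize_threshold(thresholds)
  aln <- data$alignment
  truth <- data$truth
  validate_alignment(aln)

  units <- list(all = aln)
  for (ax in subsets) {
    sub <- subsample_alignment(aln, by = ax)
    names(sub) <- paste0(ax, ":", names(sub))
    units <- c(units, sub)
  }

  partitions <- list()
  reports <- list()
  for (u in names(units)) {
    sub_aln <- units[[u]]
    sub_truth <- morphospecies_partition(sub_aln)
    dm <- if (nrow(sub_aln) >= 2L) p_distance_matrix(sub_aln) else NULL
    for (m in methods) {
      parts <- list()
      if (m == "cluster") {
        if (is.null(dm)) next
        for (t in thresholds) {
          parts[[paste0("cluster@", format(t))]] <- cluster_at_threshold(dm, t)
        }
      } else if (m == "gmyc") {
        if (is.null(data$gene_tree) || nrow(sub_aln) < 4L) next
        tr <- drop_gene_subtree(data$gene_tree, sub_aln$specimen_id)
        fit <- try(fit_gmyc(tr), silent = TRUE)
        if (inherits(fit, "try-error")) {
          rlang::abort(paste0("stage gmyc failed on subset '", u, "': ",
                              attr(fit, "condition")$message))
        }
        parts[["gmyc"]] <- fit$entities
      } else if (m == "network") {
        if (nrow(sub_aln) < 2L) next
        parts[["network"]] <- delimit_networks(sub_aln)
      } else if (m == "paa") {
        if (nrow(sub_aln) < 2L) next
        parts[["paa"]] <- paa_aggregate(sub_aln, sub_truth)
      }
      for (pn in names(parts)) {
        key <- paste0(u, "/", pn)
        partitions[[key]] <- parts[[pn]]
        reports[[key]] <- dplyr::bind_cols(
          tibble::tibble(subset = u, method = pn),
          evaluate_partition(parts[[pn]], sub_truth)
        )
      }
    }
  }
  reports <- dplyr::bind_rows(reports)

  # beta diversity on the pooled partitions, per method
  sor <- list()
  if (!is.null(data$region_map) &&
      length(unique(data$region_map$region)) >= 2L) {
    keys <- grep("^all/", names(partitions), value = TRUE)
    sor_parts <- c(list(`morphospecies` = truth), partitions[keys])
    names(sor_parts) <- c("morphospecies", sub("^all/", "", keys))
    for (pn in names(sor_parts)) {
      s <- sorensen(sor_parts[[pn]], data$region_map)
      if (!is.null(data$region_distances)) {
        s <- dplyr::left_join(s, data$region_distances,
                              by = c("region_a", "region_b"))
      }
      sor[[pn]] <- dplyr::bind_cols(tibble::tibble(partition = pn), s)
    }
  }
  sor <- dplyr::bind_rows(sor)

  manifest <- dplyr::bind_rows(
    purrr::imap_dfr(partitions, function(p, nm) {
      tibble::tibble(artifact = paste0("partition/", nm), kind = "partition",
                     n_rows = nrow(p), hash = table_hash(p))
    }),
    tibble::tibble(artifact = "reports", kind = "report",
                   n_rows = nrow(reports), hash = table_hash(reports)),
    if (nrow(sor)) {
      tibble::tibble(artifact = "sorensen", kind = "report",
                     n_rows = nrow(sor), hash = table_hash(sor))
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(partitions)) {
      write_partition(partitions[[nm]],
                      file.path(out_dir, paste0(gsub("[/@:]", "_", nm), ".tsv")))
    }
    write_report(reports, file.path(out_dir, "reports.tsv"))
    if (nrow(sor)) write_report(sor, file.path(out_dir, "sorensen.tsv"))
    write_report(manifest, file.path(out_dir, "manifest.tsv"))
  }

  structure(list(reports = reports, partitions = partitions,
                 sorensen = sor, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run:", nrow(x$reports), "evaluation rows,",
      length(x$partitions), "partitions\n")
  print(utils::head(as.data.frame(
    x$reports[, c("subset", "method", "n_species", "n_groups",
                  "agreement_pct_int", "accuracy_pct_int")]
  ), 12))
  invisible(x)
}
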