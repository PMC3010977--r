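#' Preprocess an ultrametric tree for GMYC
#'
#' GMYC needs a fully dichotomous ultrametric tree with strictly positive
#' branch lengths. This (1) resolves polytomies arbitrarily with zero-length
#' branches, (2) verifies ultrametricity within a relative tolerance,
#' (3) collapses zero-height clades -- tips carrying identical haplotypes --
#' down to one representative tip (lexicographically smallest id),
#' recording an alias map so entities can later be re-expanded to all
#' specimens, and (4) pushes any residual zero-length internal branch apart
#' by a tiny relative offset so all branching times are distinct and
#' positive.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tol relative ultrametricity tolerance (default `1e-6`).
#' @param epsilon relative offset used to separate coincident node heights;
#'   default `1e-8` of the root height.
#' @return An object of class `gmyc_tree`: list with `tree` (cleaned
#'   `phylo`), `aliases` (tibble `alias`, `representative`) and `epsilon`.
#' @export
preprocess_tree <- function(tree, tol = 1e-6, epsilon = NULL) {
  if (!inherits(tree, "phylo")) rlang::abort("tree must be a 'phylo'")
  if (is.null(tree$edge.length)) rlang::abort("tree has no branch lengths")
  if (!ape::is.rooted(tree)) rlang::abort("tree must be rooted")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (ultrametric_deviation(tree) > tol) {
    rlang::abort(paste0(
      "tree is not ultrametric within tolerance (relative deviation ",
      format(ultrametric_deviation(tree), digits = 3), ")"
    ))
  }
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  H <- max(h)
  if (H <= 0) rlang::abort("tree has zero height")
  zero_tol <- 1e-9 * H

  # collapse clades of identical haplotypes (clade height ~ 0)
  aliases <- tibble::tibble(alias = character(), representative = character())
  internal <- (n + 1L):(n + tree$Nnode)
  zero_nodes <- internal[h[internal] <= zero_tol]
  if (length(zero_nodes)) {
    tips_of <- clade_tips(tree)
    parent <- node_parents(tree)
    # maximal zero-height clades only
    maximal <- zero_nodes[vapply(zero_nodes, function(v) {
      p <- parent[v]
      is.na(p) || h[p] > zero_tol
    }, TRUE)]
    drop <- character()
    for (v in maximal) {
      tips <- sort(tree$tip.label[tips_of[[v]]])
      rep_tip <- tips[1L]
      aliases <- dplyr::bind_rows(aliases, tibble::tibble(
        alias = tips[-1L], representative = rep_tip
      ))
      drop <- c(drop, tips[-1L])
    }
    if (length(drop)) {
      if (length(drop) >= n - 1L) {
        rlang::abort("all tips are identical haplotypes; nothing to delimit")
      }
      tree <- ape::drop.tip(tree, drop)
      n <- ape::Ntip(tree)
      h <- node_heights(tree)
      H <- max(h)
    }
  }

  # separate coincident internal heights, working down from the root
  shrink <- if (is.null(epsilon)) 1e-8 else epsilon / H
  parent <- node_parents(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  h_new <- h
  for (v in internal[order(h[internal], decreasing = TRUE)]) {
    p <- parent[v]
    if (!is.na(p) && h_new[v] >= h_new[p] * (1 - shrink)) {
      h_new[v] <- h_new[p] * (1 - shrink)
    }
  }
  tree$edge.length <- h_new[tree$edge[, 1L]] - h_new[tree$edge[, 2L]]
  if (any(tree$edge.length <= 0)) {
    rlang::abort("could not resolve zero-length branches")
  }
  structure(list(tree = tree, aliases = aliases, epsilon = shrink * H),
            class = "gmyc_tree")
}

# parent node id of every node (NA for the root)
node_parents <- function(tree) {
  parent <- rep(NA_integer_, ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

# tip indices under every node (list indexed by node id)
clade_tips <- function(tree) {
  n <- ape::Ntip(tree)
  out <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) out[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ed))) {
    out[[ed[k, 1L]]] <- c(out[[ed[k, 1L]]], out[[ed[k, 2L]]])
  }
  out
}

# Sufficient statistics of the mixed model at threshold height T.
# Intervals run between successive branching events, ordered from the
# tips; the event terminating an interval sits at its older end, and all
# rates are evaluated with the lineage counts during that interval (the
# coalescent convention). Yule side: branch segments above T, rate
# lambda1 * d^p1; coalescent side: below-T subtrees ("groups"), rate
# lambda2 * sum_j [m_j (m_j - 1)]^p2. T splits the interval it falls in;
# the piece below T carries coalescent rates only, the piece above Yule
# rates only. Each side is stored as interval durations `x`, per-interval
# count values `vals` (a vector per interval on the coalescent side), and
# a logical `has_event` marking intervals terminated by an event of that
# side. Also returns the tip composition of each below-T group.
gmyc_stats <- function(tree, T) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  h[seq_len(n)] <- 0
  root <- n + 1L
  H <- h[root]
  internal <- (n + 1L):(n + tree$Nnode)
  parent <- node_parents(tree)

  yule_nodes <- internal[h[internal] >= T]
  coal_nodes <- if (T > 0) internal[h[internal] < T] else integer()

  # ---- Yule side: from T (or 0) up to and including the root event
  e <- sort(h[yule_nodes], decreasing = TRUE)
  m <- length(e)
  y_floor <- min(T, H)
  if (m > 0L) {
    bounds <- c(e, y_floor)               # descending: root ... T
    yule <- list(
      x = -diff(bounds),
      vals = as.list(seq_len(m) + 1),     # 2 below the root, ..., m+1 above T
      has_event = rep(TRUE, m)            # every interval ends at an event
    )
  } else {
    yule <- list(x = numeric(), vals = list(), has_event = logical())
  }

  # ---- coalescent side: groups = subtrees hanging below T
  groups <- list()
  if (T > 0) {
    # group root of a node: topmost ancestor with height < T
    group_root <- integer(n + tree$Nnode)
    for (v in c(seq_len(n), coal_nodes)) {
      u <- v
      while (!is.na(parent[u]) && h[parent[u]] < T) u <- parent[u]
      group_root[v] <- u
    }
    g_of_tip <- group_root[seq_len(n)]
    groups <- split(seq_len(n), g_of_tip)
    sizes <- lengths(groups)
    g_ids <- as.integer(names(groups))
    g_index <- stats::setNames(seq_along(g_ids), g_ids)

    ev_h <- h[coal_nodes]
    ev_g <- g_index[as.character(group_root[coal_nodes])]
    ord <- order(ev_h)
    ev_h <- ev_h[ord]; ev_g <- ev_g[ord]
    q <- length(ev_h)
    top <- min(T, H)
    bounds <- c(0, ev_h, top)              # ascending: present ... T
    mcur <- sizes
    wg <- vector("list", q + 1L)
    wx <- numeric(q + 1L)
    for (k in seq_len(q + 1L)) {
      wx[k] <- bounds[k + 1L] - bounds[k]
      active <- mcur[mcur >= 2L]
      wg[[k]] <- active * (active - 1)     # counts during interval k, whose
      if (k <= q) {                        # top (if any) is event k
        g <- ev_g[k]
        mcur[g] <- mcur[g] - 1L
      }
    }
    coal <- list(
      x = wx,
      vals = wg,
      has_event = c(rep(TRUE, q), FALSE)   # the piece touching T has none
    )
  } else {
    coal <- list(x = numeric(), vals = list(), has_event = logical())
  }

  # below T the diversification process persists without events: the K
  # entities' subtending stems lie above T, so d = K throughout [0, T)
  if (T > 0 && length(groups)) {
    yule$x <- c(yule$x, min(T, H))
    yule$vals <- c(yule$vals, list(length(groups)))
    yule$has_event <- c(yule$has_event, FALSE)
  }

  list(yule = yule, coal = coal,
       group_tips = lapply(groups, function(i) tree$tip.label[i]))
}

# log-likelihood of one side given rate lambda and exponent p:
# sum over intervals of [has_event] * log(lambda * S) - lambda * S * x,
# with S = sum of the interval's count values each raised to p
side_loglik <- function(stats, lambda, p) {
  if (length(stats$x) == 0L) return(0)
  S <- vapply(stats$vals, function(v) sum(v^p), 0)
  if (any(stats$has_event & S <= 0)) return(-Inf)
  sum(log(lambda * S[stats$has_event])) - lambda * sum(S * stats$x)
}

#' GMYC mixed-model log-likelihood at a threshold
#'
#' Branching events on an ultrametric gene tree are split at the threshold
#' height `T`: nodes at or above `T` are speciation events of a Yule-type
#' diversification process with rate `lambda1 * d^p1` (`d` = number of
#' lineages whose branch segment lies above `T`), nodes below `T` are
#' coalescent events of a within-group coalescent process with total rate
#' `lambda2 * sum_j (m_j (m_j - 1))^p2` over the below-threshold subtrees
#' `j` (`m_j` = lineages currently inside group `j`; singleton groups
#' contribute zero). `d` counts lineages whose subtending branch segment
#' lies above `T`: the full lineage count above the threshold, and the
#' constant number of entities below it (their stems cross `T`), where the
#' diversification process persists without observed events. Inter-event intervals are taken between successive
#' branching events ordered from the tips; each interval of duration `x`
#' contributes `log b(event) - b x`, where `b` is evaluated with the
#' lineage counts during the interval and the event-rate term is the
#' component belonging to the process in which the terminating event
#' occurs (the interval adjoining the present has no event term, and `T`
#' splits the interval it falls in). `T = 0` gives the pure
#' diversification model over the whole tree; `T` at or above the root
#' height gives the pure single-group coalescent.
#'
#' @param tree ultrametric `phylo` (preprocessed; see
#'   [preprocess_tree()]).
#' @param T threshold height (time before present), `>= 0`.
#' @param lambda1,p1 diversification rate and scaling exponent.
#' @param lambda2,p2 coalescent rate and scaling exponent.
#' @return Log-likelihood (scalar; `-Inf` for invalid parameter points).
#' @export
gmyc_loglik <- function(tree, T, lambda1, p1, lambda2, p2) {
  if (T < 0) rlang::abort("T must be >= 0")
  if (lambda1 <= 0 || lambda2 <= 0) rlang::abort("rates must be > 0")
  st <- gmyc_stats(tree, T)
  side_loglik(st$yule, lambda1, p1) + side_loglik(st$coal, lambda2, p2)
}

# profile fit of one side: lambda has a closed-form MLE given p, p is
# maximized on a grid over [0, 3] refined by optimize()
fit_side <- function(stats, lambda_bounds = c(1e-8, 1e4), p_bounds = c(0, 3)) {
  E <- sum(stats$has_event)
  if (E == 0L) {
    W0 <- if (length(stats$x)) {
      sum(stats$x * vapply(stats$vals, sum, 0))
    } else 0
    return(list(lambda = lambda_bounds[1L], p = 1,
                loglik = -lambda_bounds[1L] * W0))
  }
  ll_of_p <- function(p) {
    S <- vapply(stats$vals, function(v) sum(v^p), 0)
    if (any(stats$has_event & S <= 0)) return(-Inf)
    W <- sum(S * stats$x)
    lam <- min(max(E / W, lambda_bounds[1L]), lambda_bounds[2L])
    E * log(lam) + sum(log(S[stats$has_event])) - lam * W
  }
  grid <- seq(p_bounds[1L], p_bounds[2L], length.out = 31L)
  vals <- vapply(grid, ll_of_p, 0)
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(ll_of_p, interval = c(lo, hi), maximum = TRUE)
  if (opt$objective >= vals[i]) {
    p_hat <- opt$maximum; ll <- opt$objective
  } else {
    p_hat <- grid[i]; ll <- vals[i]
  }
  S <- vapply(stats$vals, function(v) sum(v^p_hat), 0)
  W <- sum(S * stats$x)
  lam <- min(max(E / W, lambda_bounds[1L]), lambda_bounds[2L])
  list(lambda = lam, p = p_hat, loglik = ll)
}

#' Fit the single-threshold GMYC model
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' branching heights (including a candidate below the youngest node, where
#' every tip is its own entity, and one just below the root, where the two
#' basal subtrees are the entities). For each candidate the two process
#' parameter pairs are profile-optimized; the fitted threshold is the
#' profile maximum (ties broken toward the older threshold). The null
#' model is a single branching process `b = lambda * n^p` over the whole
#' tree, and the likelihood-ratio test compares the two with a chi-squared
#' reference distribution (df = 3 by default: four parameters against two,
#' the threshold itself not counted). Entities are the below-threshold
#' subtrees plus the singleton branches crossing the threshold, re-expanded
#' with the identical-haplotype alias map from preprocessing.
#'
#' @param tree rooted ultrametric `phylo`, or a `gmyc_tree` from
#'   [preprocess_tree()].
#' @param alpha significance level reported in the summary (the test
#'   itself returns a p-value).
#' @param df degrees of freedom of the likelihood-ratio test.
#' @return An object of class `gmyc_fit`; see [tidy.gmyc_fit()] and
#'   [glance.gmyc_fit()].
#' @export
fit_gmyc <- function(tree, alpha = 0.05, df = 3) {
  pre <- if (inherits(tree, "gmyc_tree")) tree else preprocess_tree(tree)
  tr <- pre$tree
  n <- ape::Ntip(tr)
  if (n < 3L) rlang::abort("need at least 3 distinct haplotypes for GMYC")
  h <- node_heights(tr)
  hs <- sort(unique(h[(n + 1L):(n + tr$Nnode)]))
  bounds <- c(0, hs)
  candidates <- (bounds[-1L] + bounds[-length(bounds)]) / 2

  prof <- lapply(candidates, function(T) {
    st <- gmyc_stats(tr, T)
    fy <- fit_side(st$yule)
    fc <- fit_side(st$coal)
    list(T = T, loglik = fy$loglik + fc$loglik, yule = fy, coal = fc,
         n_entities = length(st$group_tips))
  })
  ll <- vapply(prof, `[[`, 0, "loglik")

  # null: one process over the whole timeline (the T -> 0 limit)
  st0 <- gmyc_stats(tr, 0)
  f0 <- fit_side(st0$yule)
  logL_null <- f0$loglik

  best_ll <- max(ll)
  i_hat <- max(which(ll >= best_ll - 1e-9))  # tie-break toward older T
  T_hat <- candidates[i_hat]
  fit <- prof[[i_hat]]
  LR <- 2 * (fit$loglik - logL_null)
  p_value <- stats::pchisq(LR, df = df, lower.tail = FALSE)

  st_hat <- gmyc_stats(tr, T_hat)
  groups <- st_hat$group_tips
  first <- vapply(lapply(groups, sort), `[[`, "", 1L)
  groups <- groups[order(first)]
  ent <- tibble::tibble(
    specimen_id = unlist(groups, use.names = FALSE),
    group = rep(sprintf("E%04d", seq_along(groups)), lengths(groups))
  )
  if (nrow(pre$aliases)) {
    extra <- tibble::tibble(
      specimen_id = pre$aliases$alias,
      group = ent$group[match(pre$aliases$representative, ent$specimen_id)]
    )
    ent <- dplyr::bind_rows(ent, extra)
  }
  entities <- new_partition(ent$specimen_id, ent$group, kind = "gmyc_entity")

  structure(list(
    T_hat = T_hat,
    params = tibble::tibble(
      lambda1 = fit$yule$lambda, p1 = fit$yule$p,
      lambda2 = fit$coal$lambda, p2 = fit$coal$p
    ),
    logL_model = fit$loglik,
    logL_null = logL_null,
    LR = LR,
    p_value = p_value,
    df = df,
    alpha = alpha,
    entities = entities,
    n_entities = fit$n_entities,
    ci_thresholds = candidates[ll >= best_ll - 2],
    profile = tibble::tibble(
      threshold = candidates, loglik = ll,
      n_entities = vapply(prof, `[[`, 0L, "n_entities")
    ),
    n_tips = n,
    aliases = pre$aliases,
    tree = tr
  ), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat("Single-threshold GMYC fit\n")
  cat(sprintf("  tips (distinct haplotypes): %d\n", x$n_tips))
  cat(sprintf("  threshold T_hat: %.6g (CI: %d candidate heights)\n",
              x$T_hat, length(x$ci_thresholds)))
  cat(sprintf("  entities: %d\n", x$n_entities))
  cat(sprintf("  logL model %.3f, null %.3f, LR %.3f, p = %.4g (df = %d)\n",
              x$logL_model, x$logL_null, x$LR, x$p_value, x$df))
  invisible(x)
}

#' Tidy a GMYC fit into its entity partition
#'
#' @param x `gmyc_fit` object.
#' @param ... unused.
#' @return Partition tibble (`kind = "gmyc_entity"`), one row per
#'   specimen including re-expanded identical haplotypes.
#' @method tidy gmyc_fit
#' @export
tidy.gmyc_fit <- function(x, ...) {
  x$entities
}

#' One-row summary of a GMYC fit
#'
#' @param x `gmyc_fit` object.
#' @param ... unused.
#' @return One-row tibble with tip and entity counts, the fitted
#'   threshold, log-likelihoods, likelihood ratio and p-value, and the
#'   2-log-likelihood confidence range of the threshold.
#' @method glance gmyc_fit
#' @export
glance.gmyc_fit <- function(x, ...) {
  tibble::tibble(
    n_tips = x$n_tips,
    n_entities = x$n_entities,
    threshold = x$T_hat,
    logL = x$logL_model,
    logL_null = x$logL_null,
    LR = x$LR,
    p_value = x$p_value,
    ci_n = length(x$ci_thresholds),
    ci_min = min(x$ci_thresholds),
    ci_max = max(x$ci_thresholds)
  )
}

#' Profile plot of a GMYC fit
#'
#' Log-likelihood profile over candidate thresholds, with the fitted
#' threshold and the 2-log-likelihood confidence band marked.
#'
#' @param object `gmyc_fit` object.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gmyc_fit
#' @export
autoplot.gmyc_fit <- function(object, ...) {
  prof <- object$profile
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$threshold, y = .data$loglik)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$T_hat, color = "#d95f02") +
    ggplot2::geom_hline(yintercept = object$logL_model - 2,
                        linetype = "dashed", color = "grey60") +
    ggplot2::labs(
      x = "threshold height (time before present)",
      y = "profile log-likelihood",
      title = sprintf("GMYC profile: %d entities at T = %.4g",
                      object$n_entities, object$T_hat)
    ) +
    ggplot2::theme_minimal()
}
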