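#' Simulate guild-targeted random extinctions
#'
#' Per trial, `round(f * guild size)` uniformly chosen nodes of the target
#' guild are removed (banker's rounding), then any node left with zero
#' edges is removed iteratively (secondary extinction). Robustness is the
#' proportion of the original network's nodes that survive.
#'
#' @param net bipartite_network
#' @param target_guild guild label to remove from, or `"both"` for removal
#'   from the whole node set.
#' @param f removal fraction in (0, 1].
#' @param n_trials number of random trials (default 100).
#' @param seed integer RNG seed.
#' @return object of class `extinction_experiment`: vector `robustness`
#'   (one value per trial), `mean`, `sd`, and the settings.
#' @export
simulate_extinctions <- function(net, target_guild, f, n_trials = 100, seed = 1) {
  if (f <= 0 || f > 1) stop("removal fraction f must be in (0, 1]")
  pool <- if (identical(target_guild, "both")) net$nodes$id else
    net$nodes$id[net$nodes$guild == target_guild]
  if (length(pool) == 0)
    stop("target guild '", target_guild, "' has no nodes in this network")
  k <- round(f * length(pool))
  n0 <- nrow(net$nodes)
  if (k == 0) {
    warning("removal fraction rounds to 0 nodes; robustness is 1 by definition")
    rb <- rep(1, n_trials)
    return(structure(list(robustness = rb, mean = 1, sd = 0,
                          target_guild = target_guild, f = f,
                          n_trials = n_trials, removed_per_trial = 0L,
                          seed = seed),
                     class = "extinction_experiment"))
  }
  set.seed(seed)
  rb <- numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    removed <- sample(pool, k)
    rb[tr] <- length(.surviving_nodes(net, removed)) / n0
  }
  structure(list(robustness = rb, mean = mean(rb), sd = stats::sd(rb),
                 target_guild = target_guild, f = f, n_trials = n_trials,
                 removed_per_trial = as.integer(k), seed = seed),
            class = "extinction_experiment")
}

# nodes surviving after removing `removed` plus the secondary-extinction
# cascade (a node survives iff it keeps >= 1 edge)
.surviving_nodes <- function(net, removed) {
  alive <- setdiff(net$nodes$id, removed)
  ed <- net$edges
  repeat {
    keep <- ed$from %in% alive & ed$to %in% alive
    deg <- table(c(ed$from[keep], ed$to[keep]))
    with_edge <- names(deg)
    dead <- setdiff(alive, with_edge)
    if (length(dead) == 0) break
    alive <- with_edge
  }
  alive
}

#' @export
print.extinction_experiment <- function(x, ...) {
  cat(sprintf("extinction_experiment: remove %.0f%% of %s (%d nodes) x %d trials -> robustness %.3f +/- %.3f\n",
              100 * x$f, x$target_guild, x$removed_per_trial, x$n_trials,
              x$mean, x$sd))
  invisible(x)
}

#' Robustness curve and least-squares slope
#'
#' Runs [simulate_extinctions()] across a grid of removal fractions and
#' fits an ordinary least-squares line to mean robustness versus fraction;
#' a more negative slope indicates a more drastic decline in structural
#' robustness.
#'
#' @param net bipartite_network
#' @param target_guild guild to remove from (or `"both"`)
#' @param fractions strictly increasing removal fractions in (0,1);
#'   at least 3.
#' @param n_trials trials per fraction
#' @param seed integer seed; fraction i uses sub-seed seed + i.
#' @return object of class `robustness_curve`: data.frame `curve`
#'   (fraction, mean, sd, n), `slope`, `intercept`, and the per-fraction
#'   trial matrix `trials` (n_trials x length(fractions)).
#' @export
robustness_curve <- function(net, target_guild, fractions, n_trials = 100,
                             seed = 1) {
  if (length(fractions) < 3) stop("need at least 3 removal fractions")
  if (any(diff(fractions) <= 0)) stop("fractions must be strictly increasing")
  trials <- matrix(NA_real_, n_trials, length(fractions))
  colnames(trials) <- as.character(fractions)
  for (i in seq_along(fractions)) {
    ex <- simulate_extinctions(net, target_guild, fractions[i],
                               n_trials = n_trials, seed = seed + i)
    trials[, i] <- ex$robustness
  }
  mu <- colMeans(trials)
  fit <- stats::lm(mu ~ fractions)
  structure(list(
    curve = data.frame(fraction = fractions, mean = mu,
                       sd = apply(trials, 2, stats::sd), n = n_trials),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    trials = trials, target_guild = target_guild, seed = seed),
    class = "robustness_curve")
}

#' Permutation test for a difference between two robustness curves
#'
#' Tests whether mean robustness differs between two networks across a
#' shared removal-fraction grid. The statistic is the mean over fractions of
#' the difference in mean robustness; trial labels are permuted within each
#' fraction (999 permutations by default).
#'
#' @param curve_a,curve_b robustness_curve objects over identical fractions
#' @param n_permutations number of label permutations (default 999)
#' @param seed integer seed
#' @return list with `statistic` (mean difference a - b), `p` (two-sided,
#'   add-one smoothed), `n_permutations`.
#' @export
compare_robustness_curves <- function(curve_a, curve_b, n_permutations = 999,
                                      seed = 1) {
  if (!isTRUE(all.equal(curve_a$curve$fraction, curve_b$curve$fraction)))
    stop("curves must share the same removal-fraction grid")
  A <- curve_a$trials
  B <- curve_b$trials
  stat <- mean(colMeans(A) - colMeans(B))
  na <- nrow(A)
  pooled <- rbind(A, B)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(nrow(pooled))
    Ap <- pooled[perm[seq_len(na)], , drop = FALSE]
    Bp <- pooled[perm[-seq_len(na)], , drop = FALSE]
    if (abs(mean(colMeans(Ap) - colMeans(Bp))) >= abs(stat))
      exceed <- exceed + 1L
  }
  list(statistic = stat, p = (1 + exceed) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Global efficiency of a network
#'
#' E = 1/(n(n-1)) * sum over ordered pairs of 1/d(i,j), with hop-count
#' shortest paths and 1/d = 0 for disconnected pairs.
#'
#' @param net bipartite_network (or igraph graph)
#' @return scalar efficiency in [0, 1]
#' @export
global_efficiency <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Node and network vulnerability
#'
#' Node vulnerability is the relative contribution of the node to global
#' efficiency, (E - E_i)/E, where E_i is the efficiency of the network with
#' node i removed; it can be negative for redundant peripheral nodes. The
#' network vulnerability is the maximum over nodes.
#'
#' @param net bipartite_network or igraph graph
#' @return object of class `vulnerability_report`: named vector `node`,
#'   scalars `network` and `global_efficiency`.
#' @export
vulnerability <- function(net) {
  g <- if (inherits(net, "igraph")) net else as_igraph(net)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
  n <- igraph::vcount(g)
  if (n < 3) stop("vulnerability needs at least 3 nodes")
  E <- global_efficiency(g)
  if (E == 0) stop("global efficiency is 0; vulnerability undefined")
  vuln <- vapply(igraph::V(g)$name, function(v) {
    Ei <- global_efficiency(igraph::delete_vertices(g, v))
    (E - Ei) / E
  }, numeric(1))
  structure(list(node = vuln, network = max(vuln), global_efficiency = E),
            class = "vulnerability_report")
}

#' @export
print.vulnerability_report <- function(x, ...) {
  cat(sprintf("vulnerability_report: E = %.4f, network vulnerability = %.4f (max of %d nodes)\n",
              x$global_efficiency, x$network, length(x$node)))
  invisible(x)
}

#' Extract the subnetwork anchored on one phytoplankton taxon group
#'
#' Keeps the phytoplankton nodes of the given taxon group, every zooplankton
#' node sharing an edge with them, and the edges between those sets. All
#' stability metrics apply unchanged to the result.
#'
#' @param net bipartite_network whose phytoplankton nodes carry taxon_group
#'   labels (e.g. `"diatom"`, `"dinoflagellate"`).
#' @param phyto_group taxon-group label to anchor on.
#' @param min_nodes subnetworks below this size are flagged `small = TRUE`
#'   (default 20).
#' @return bipartite_network with attributes `small` and (when the group is
#'   absent) `empty = TRUE`.
#' @export
extract_subnetwork <- function(net, phyto_group, min_nodes = 20) {
  phyto <- net$nodes$id[net$nodes$guild == "phytoplankton" &
                          !is.na(net$nodes$taxon_group) &
                          net$nodes$taxon_group == phyto_group]
  keep <- net$edges$from %in% phyto | net$edges$to %in% phyto
  edges <- net$edges[keep, , drop = FALSE]
  guilds <- stats::setNames(net$nodes$guild, net$nodes$id)
  tg <- stats::setNames(net$nodes$taxon_group, net$nodes$id)
  sub <- bipartite_network(edges, guilds = guilds, taxon_group = tg)
  sub$small <- nrow(sub$nodes) < min_nodes
  sub
}
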