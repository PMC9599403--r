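#' Detect modules by greedy modularity maximization
#'
#' Partitions the networked nodes into modules maximizing modularity on
#' |r|-weighted edges (fast-greedy agglomeration; deterministic for a given
#' network, the seed is recorded for provenance). Modules with at most
#' `small_cutoff` nodes are flagged.
#'
#' @param net bipartite_network (nonempty)
#' @param seed integer recorded in the result (the algorithm itself is
#'   deterministic).
#' @param small_cutoff flag modules with <= this many nodes (default 5).
#' @return object of class `module_partition`: named integer vector
#'   `membership` (node -> dense module id), `modularity`, `algorithm`,
#'   `small_modules` (integer ids), `seed`.
#' @export
detect_modules <- function(net, seed = 1, small_cutoff = 5) {
  if (net$empty) stop("cannot detect modules in an empty network")
  g <- as_igraph(net)
  set.seed(seed)
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  Q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  # guard against the degenerate all-singleton cut on tiny graphs: the
  # connected-component partition is a valid coarser candidate
  comp <- igraph::components(g)$membership
  Qc <- igraph::modularity(g, comp, weights = igraph::E(g)$weight)
  if (Qc > Q) { memb <- comp; Q <- Qc }
  membership <- stats::setNames(as.integer(memb), names(memb))
  sizes <- table(membership)
  structure(list(membership = membership,
                 modularity = Q,
                 algorithm = "fast_greedy",
                 small_modules = as.integer(names(sizes)[sizes <= small_cutoff]),
                 seed = seed),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes in %d modules (Q = %.3f, %s)\n",
              length(x$membership), length(unique(x$membership)),
              x$modularity, x$algorithm))
  invisible(x)
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' Zi is the z-score of a node's within-module degree relative to the other
#' members of its module (0 when the module's within-degree standard
#' deviation is 0). Pi = 1 - sum_s (k_is/k_i)^2, where k_is is the node's
#' degree into module s and k_i its total degree. Nodes are classified as
#' module hubs (Zi > 2.5, Pi <= 0.62), network hubs (Zi > 2.5, Pi > 0.62),
#' connectors (Zi <= 2.5, Pi > 0.62) or peripherals (Zi <= 2.5, Pi <= 0.62);
#' all non-peripherals are network keystones.
#'
#' @param net bipartite_network
#' @param partition module_partition covering every node.
#' @param zi_threshold,pi_threshold classification thresholds
#'   (defaults 2.5 and 0.62).
#' @return data.frame with columns node, module, degree, within_degree,
#'   Zi, Pi, role, keystone.
#' @export
zi_pi <- function(net, partition, zi_threshold = 2.5, pi_threshold = 0.62) {
  memb <- partition$membership
  missing <- setdiff(net$nodes$id, names(memb))
  if (length(missing) > 0)
    stop("partition does not cover nodes: ", paste(missing, collapse = ", "))
  ids <- net$nodes$id
  deg <- node_connectivity(net)
  mods <- sort(unique(memb[ids]))
  # k_is: node x module degree counts
  kis <- matrix(0L, length(ids), length(mods),
                dimnames = list(ids, as.character(mods)))
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]
    kis[f, as.character(memb[t])] <- kis[f, as.character(memb[t])] + 1L
    kis[t, as.character(memb[f])] <- kis[t, as.character(memb[f])] + 1L
  }
  within <- kis[cbind(ids, as.character(memb[ids]))]
  names(within) <- ids
  zi <- numeric(length(ids))
  names(zi) <- ids
  for (m in mods) {
    members <- ids[memb[ids] == m]
    mu <- mean(within[members])
    s <- stats::sd(within[members])
    zi[members] <- if (is.na(s) || s == 0) 0 else (within[members] - mu) / s
  }
  pi_ <- 1 - rowSums((kis / deg[ids])^2)
  role <- classify_node_role(zi, pi_, zi_threshold, pi_threshold)
  data.frame(node = ids, module = unname(memb[ids]), degree = unname(deg[ids]),
             within_degree = unname(within), Zi = unname(zi), Pi = unname(pi_),
             role = role, keystone = role != "peripheral",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify node roles from Zi and Pi
#'
#' Four-way classification: module hubs (Zi > 2.5, Pi <= 0.62), network
#' hubs (Zi > 2.5, Pi > 0.62), connectors (Zi <= 2.5, Pi > 0.62),
#' peripherals (Zi <= 2.5, Pi <= 0.62). Boundary values (Zi = 2.5 or
#' Pi = 0.62) fall to the non-hub / non-connector side.
#'
#' @param zi,pi_ numeric vectors of within-module degree z-scores and
#'   among-module connectivities.
#' @param zi_threshold,pi_threshold thresholds (defaults 2.5, 0.62).
#' @return character vector of roles
#' @export
classify_node_role <- function(zi, pi_, zi_threshold = 2.5,
                               pi_threshold = 0.62) {
  ifelse(zi > zi_threshold,
         ifelse(pi_ > pi_threshold, "network hub", "module hub"),
         ifelse(pi_ > pi_threshold, "connector", "peripheral"))
}

#' Module eigenvalue (eigengene) series
#'
#' The first principal component of the per-species z-scored abundance
#' profiles of the module's members across samples, scaled to unit variance
#' and sign-oriented to correlate positively with the mean member profile.
#'
#' @param members character vector of module member species.
#' @param abundance abundance_table containing every member.
#' @return object of class `module_eigen`: numeric `series` (one value per
#'   sample, unit variance), `variance_explained` in (0,1], `members`.
#' @export
module_eigenvalue <- function(members, abundance) {
  missing <- setdiff(members, species_ids(abundance))
  if (length(missing) > 0)
    stop("module members absent from abundance table: ",
         paste(missing, collapse = ", "))
  x <- abundance$density[, members, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all module members have constant abundance")
  x <- x[, sds > 0, drop = FALSE]
  xz <- scale(x)
  if (ncol(xz) == 1) {
    series <- xz[, 1]
    ve <- 1
  } else {
    pc <- stats::prcomp(xz, center = FALSE, scale. = FALSE)
    series <- pc$x[, 1]
    series <- series / stats::sd(series)
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  if (stats::cor(series, rowMeans(xz)) < 0) series <- -series
  structure(list(series = stats::setNames(as.numeric(series), rownames(x)),
                 variance_explained = ve, members = colnames(x)),
            class = "module_eigen")
}

#' Correlate a module eigenvalue series with environmental factors
#'
#' Pearson correlation and two-sided p-value per factor, with the usual
#' star convention (*** p < 0.001, ** p < 0.01, * p < 0.05).
#'
#' @param eigen module_eigen
#' @param env environment_table aligned to the same samples.
#' @return data.frame with columns factor, r, p, stars, undefined (TRUE for
#'   constant factors).
#' @export
module_env_correlation <- function(eigen, env) {
  shared <- intersect(names(eigen$series), rownames(env$factors))
  if (length(shared) < 4) stop("fewer than 4 shared samples")
  s <- eigen$series[shared]
  rows <- lapply(colnames(env$factors), function(f) {
    v <- env$factors[shared, f]
    if (stats::sd(v) == 0)
      return(data.frame(factor = f, r = NA_real_, p = NA_real_, stars = "",
                        undefined = TRUE))
    ct <- stats::cor.test(s, v)
    p <- ct$p.value
    stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
      if (p < 0.05) "*" else ""
    data.frame(factor = f, r = unname(ct$estimate), p = p, stars = stars,
               undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' Pair preserved modules across two partitions
#'
#' Two modules form a preserved pair when they share at least half of the
#' smaller module's nodes: overlap(A, B) = |A n B| / min(|A|, |B|) >= 0.5
#' (inclusive). Candidate pairs are matched greedily by descending overlap,
#' each module used at most once; ties break deterministically on module
#' ids.
#'
#' @param partition_small,partition_big module_partition objects over
#'   (partially) overlapping node sets, e.g. from the smaller- and
#'   bigger-fraction networks of one site.
#' @param threshold minimum overlap for pairing (default 0.5).
#' @param method `"min"` for the smaller-module denominator (default) or
#'   `"jaccard"`.
#' @return data.frame with columns module_small, module_big, overlap,
#'   paired (all TRUE; empty data.frame when nothing pairs).
#' @export
pair_preserved_modules <- function(partition_small, partition_big,
                                   threshold = 0.5, method = c("min", "jaccard")) {
  method <- match.arg(method)
  ms <- split(names(partition_small$membership), partition_small$membership)
  mb <- split(names(partition_big$membership), partition_big$membership)
  cand <- expand.grid(module_small = names(ms), module_big = names(mb),
                      stringsAsFactors = FALSE)
  cand$overlap <- mapply(function(a, b) {
    A <- ms[[a]]; B <- mb[[b]]
    inter <- length(intersect(A, B))
    denom <- if (method == "min") min(length(A), length(B)) else
      length(union(A, B))
    inter / denom
  }, cand$module_small, cand$module_big)
  cand <- cand[cand$overlap >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$overlap, as.integer(cand$module_small),
                     as.integer(cand$module_big)), , drop = FALSE]
  used_s <- character(); used_b <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$module_small[i] %in% used_s || cand$module_big[i] %in% used_b)
      next
    keep[i] <- TRUE
    used_s <- c(used_s, cand$module_small[i])
    used_b <- c(used_b, cand$module_big[i])
  }
  out <- cand[keep, , drop = FALSE]
  out$module_small <- as.integer(out$module_small)
  out$module_big <- as.integer(out$module_big)
  out$paired <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Mantel test: node connectivity versus environmental-factor significance
#'
#' For the networked species of one guild, species significance is the
#' squared Pearson correlation of each species' density profile with each
#' factor of the queried group. The Mantel statistic correlates the
#' Euclidean distance matrix of node connectivity with that of the
#' significance profiles; the p-value comes from matrix permutations.
#'
#' @param net bipartite_network
#' @param abundance abundance_table containing the networked species.
#' @param env environment_table aligned to the abundance samples.
#' @param factor_group one of `"temperature"`, `"salinity"`, `"pH"`, `"N"`,
#'   `"metal"`.
#' @param guild which guild's species to test (`"zooplankton"` or
#'   `"phytoplankton"`; any guild label present in the network).
#' @param n_permutations Mantel permutations (default 999).
#' @param seed integer seed for the permutation test.
#' @return list with `R` (Mantel statistic), `p`, `n_species`,
#'   `factor_group`, `guild`, `undefined` (TRUE when connectivity is
#'   constant).
#' @export
mantel_connectivity_significance <- function(net, abundance, env, factor_group,
                                             guild = "zooplankton",
                                             n_permutations = 999, seed = 1) {
  cols <- mantel_factor_columns(factor_group, env)
  sp <- net$nodes$id[net$nodes$guild == guild]
  sp <- intersect(sp, species_ids(abundance))
  if (length(sp) < 5)
    stop("need at least 5 networked species of guild '", guild, "'")
  shared <- intersect(sample_ids(abundance), rownames(env$factors))
  if (length(shared) < 4) stop("fewer than 4 shared samples")
  x <- abundance$density[shared, sp, drop = FALSE]
  f <- env$factors[shared, cols, drop = FALSE]
  sig <- matrix(NA_real_, length(sp), length(cols),
                dimnames = list(sp, cols))
  for (j in seq_along(cols)) {
    sig[, j] <- suppressWarnings(stats::cor(x, f[, j]))^2
  }
  sig[is.na(sig)] <- 0  # constant species profile: no explainable variance
  deg <- node_connectivity(net)[sp]
  if (stats::sd(deg) == 0)
    return(list(R = NA_real_, p = NA_real_, n_species = length(sp),
                factor_group = factor_group, guild = guild, undefined = TRUE))
  d_conn <- stats::dist(deg)
  d_sig <- stats::dist(sig)
  set.seed(seed)
  mt <- vegan::mantel(d_conn, d_sig, method = "pearson",
                      permutations = n_permutations)
  list(R = unname(mt$statistic), p = mt$signif, n_species = length(sp),
       factor_group = factor_group, guild = guild, undefined = FALSE)
}

#' Zi/Pi partition table export
#' @param net bipartite_network
#' @param partition module_partition
#' @param path output TSV path
#' @return path invisibly
#' @export
write_partition <- function(net, partition, path) {
  df <- zi_pi(net, partition)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
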