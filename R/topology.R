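#' Per-node connectivity (degree)
#' @param net bipartite_network
#' @return named integer vector, node -> number of links
#' @export
node_connectivity <- function(net) {
  ids <- net$nodes$id
  deg <- integer(length(ids))
  names(deg) <- ids
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

# neighbor sets as a named list of character vectors
.adjacency_list <- function(net) {
  ids <- net$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  adj
}

#' Bipartite (pairwise) clustering coefficient
#'
#' Triangles cannot exist in a bipartite graph, so clustering is measured on
#' same-side node pairs at distance two: for nodes u, v of the same guild,
#' cc(u,v) = |N(u) ∩ N(v)| / |N(u) ∪ N(v)|. A node's coefficient is the
#' mean of cc(u,v) over all v sharing at least one neighbor with u (0 when
#' there are none), and the network coefficient is the mean over all nodes.
#'
#' @param net bipartite_network
#' @return list with `per_node` (named vector) and `network` (scalar)
#' @export
bipartite_clustering <- function(net) {
  adj <- .adjacency_list(net)
  ids <- net$nodes$id
  cc <- stats::setNames(numeric(length(ids)), ids)
  for (u in ids) {
    nu <- adj[[u]]
    second <- setdiff(unique(unlist(adj[nu], use.names = FALSE)), u)
    if (length(second) == 0) { cc[u] <- 0; next }
    vals <- vapply(second, function(v) {
      nv <- adj[[v]]
      length(intersect(nu, nv)) / length(union(nu, nv))
    }, numeric(1))
    cc[u] <- mean(vals)
  }
  list(per_node = cc, network = if (length(cc)) mean(cc) else NA_real_)
}

#' Quantitative (Shannon) linkage density
#'
#' Weighted linkage density of a bipartite network on |r| edge weights:
#' for each node, the effective number of partners is exp(H) with H the
#' Shannon entropy of its edge-weight distribution; linkage density is half
#' the sum, over both guilds, of each node's share of total weight times its
#' effective partner number.
#'
#' @param net bipartite_network
#' @return scalar linkage density
#' @export
linkage_density <- function(net) {
  if (net$empty) return(NA_real_)
  w <- abs(net$edges$r)
  total <- sum(w)
  s <- 0
  for (u in net$nodes$id) {
    wi <- w[net$edges$from == u | net$edges$to == u]
    pi_ <- wi / sum(wi)
    H <- -sum(pi_ * log(pi_))
    s <- s + (sum(wi) / total) * exp(H)
  }
  s / 2
}

#' Network-level topological indices
#'
#' The standard descriptor set for a bipartite co-occurrence network:
#' network size (networked taxa), links, proportion of negative links,
#' links per species, bipartite clustering coefficient, quantitative
#' linkage density, and weighted connectance (linkage density / size).
#'
#' @param net bipartite_network
#' @return object of class `topology_report` (a list); `empty = TRUE` with
#'   all-NA metrics for an empty network.
#' @export
network_level_metrics <- function(net) {
  if (net$empty) {
    return(structure(list(empty = TRUE, network_size = 0L, links = 0L),
                     class = "topology_report"))
  }
  size <- nrow(net$nodes)
  links <- nrow(net$edges)
  ld <- linkage_density(net)
  structure(list(
    empty = FALSE,
    network_size = size,
    links = links,
    nodes_per_guild = vapply(split(net$nodes$id, net$nodes$guild), length,
                             integer(1)),
    prop_negative = mean(net$edges$r < 0),
    links_per_species = links / size,
    cluster_coefficient = bipartite_clustering(net)$network,
    linkage_density = ld,
    weighted_connectance = ld / size),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  if (isTRUE(x$empty)) { cat("topology_report: empty network\n"); return(invisible(x)) }
  cat(sprintf(paste0("topology_report: size %d, links %d (%.1f%% negative)\n",
                     "  links/species %.3f, clustering %.4f,",
                     " linkage density %.3f, weighted connectance %.3f\n"),
              x$network_size, x$links, 100 * x$prop_negative,
              x$links_per_species, x$cluster_coefficient,
              x$linkage_density, x$weighted_connectance))
  invisible(x)
}
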