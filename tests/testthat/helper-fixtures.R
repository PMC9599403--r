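# shared fixture builders and independent oracles

# bipartite network from a two-column edge matrix; guilds derived from
# node-name prefixes "p" (phytoplankton) and "z" (zooplankton)
net_from_pairs <- function(pairs, r = NULL, p = 0.01, taxon_group = NULL) {
  if (!is.matrix(pairs)) pairs <- matrix(pairs, ncol = 2, byrow = TRUE)
  ids <- unique(as.vector(pairs))
  guilds <- stats::setNames(
    ifelse(substr(ids, 1, 1) == "p", "phytoplankton", "zooplankton"), ids)
  if (is.null(r)) r <- rep(0.5, nrow(pairs))
  bipartite_network(data.frame(from = pairs[, 1], to = pairs[, 2],
                               r = r, p = rep(p, nrow(pairs)),
                               stringsAsFactors = FALSE),
                    guilds = guilds, taxon_group = taxon_group)
}

# complete bipartite K(na, nb)
k_bipartite <- function(na = 4, nb = 4, r = 0.5) {
  pairs <- as.matrix(expand.grid(paste0("p", seq_len(na)),
                                 paste0("z", seq_len(nb)),
                                 stringsAsFactors = FALSE))
  net_from_pairs(pairs, r = rep(r, nrow(pairs)))
}

star_net <- function(n_leaves = 4) {
  net_from_pairs(as.vector(rbind("p1", paste0("z", seq_len(n_leaves)))))
}

# random bipartite network with every node connected (edges sampled until
# no isolated side-node remains)
random_bipartite <- function(na = 5, nb = 6, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    grid <- expand.grid(a = paste0("p", seq_len(na)), b = paste0("z", seq_len(nb)),
                        stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < p_edge
    if (sum(keep) >= 2) {
      ed <- grid[keep, ]
      return(net_from_pairs(as.vector(t(as.matrix(ed))),
                            r = stats::runif(sum(keep), -1, 1)))
    }
  }
}

# --- independent oracles ----------------------------------------------------

# all-pairs hop distances by BFS on an edge data.frame (no igraph)
oracle_distances <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$from[i]]] <- c(adj[[edges$from[i]]], edges$to[i])
    adj[[edges$to[i]]] <- c(adj[[edges$to[i]]], edges$from[i])
  }
  d <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in ids) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                     ids[is.finite(d[s, ])])
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

oracle_global_efficiency <- function(ids, edges) {
  n <- length(ids)
  d <- oracle_distances(ids, edges)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_vulnerability <- function(ids, edges) {
  E <- oracle_global_efficiency(ids, edges)
  v <- vapply(ids, function(i) {
    keep <- edges$from != i & edges$to != i
    Ei <- oracle_global_efficiency(setdiff(ids, i), edges[keep, , drop = FALSE])
    (E - Ei) / E
  }, numeric(1))
  list(node = v, network = max(v), E = E)
}

# brute-force survivor set: prune zero-degree nodes via adjacency matrix
oracle_survivors <- function(net, removed) {
  ids <- setdiff(net$nodes$id, removed)
  repeat {
    deg <- vapply(ids, function(u)
      sum((net$edges$from == u & net$edges$to %in% ids) |
            (net$edges$to == u & net$edges$from %in% ids)), integer(1))
    if (all(deg > 0) || length(ids) == 0) break
    ids <- ids[deg > 0]
  }
  ids
}

# brute-force Zi/Pi from scratch
oracle_zipi <- function(net, membership) {
  ids <- net$nodes$id
  deg <- vapply(ids, function(u)
    sum(net$edges$from == u | net$edges$to == u), numeric(1))
  mods <- sort(unique(membership[ids]))
  k_to_mod <- function(u, m) {
    nb <- c(net$edges$to[net$edges$from == u], net$edges$from[net$edges$to == u])
    sum(membership[nb] == m)
  }
  within <- vapply(ids, function(u) k_to_mod(u, membership[u]), numeric(1))
  zi <- numeric(length(ids)); names(zi) <- ids
  for (m in mods) {
    mem <- ids[membership[ids] == m]
    s <- stats::sd(within[mem])
    zi[mem] <- if (is.na(s) || s == 0) 0 else
      (within[mem] - mean(within[mem])) / s
  }
  pi_ <- vapply(ids, function(u) {
    1 - sum(vapply(mods, function(m) (k_to_mod(u, m) / deg[u])^2, numeric(1)))
  }, numeric(1))
  list(zi = zi, pi = pi_)
}

# small synthetic benchmark shared by SparCC tests: 15 phyto + 15 zoo,
# 10 planted cross-guild pairs at the given strength
benchmark_truth <- function(strength = 0.9, n_planted = 10) {
  gs <- c(phytoplankton = 15, zoo_shared = 15, zoo_smaller_only = 0,
          zoo_bigger_only = 0)
  nm <- species_names(gs)
  pe <- if (n_planted == 0) NULL else
    data.frame(species_a = nm$phytoplankton[seq_len(n_planted)],
               species_b = nm$zoo_shared[seq_len(n_planted)],
               sign = rep(c(1, -1), length.out = n_planted),
               strength = strength)
  synthetic_truth(gs, planted_edges = pe, density_ratio = 3)
}

benchmark_tables <- function(truth = benchmark_truth(), n_samples = 200,
                             seed = 7, ...) {
  cfg <- generator_config(n_samples = n_samples, n_sites = 4, seed = seed,
                          zero_inflation = 0.05, ...)
  comm <- generate_community(cfg, truth)
  list(comm = comm,
       x = cbind(comm$phytoplankton$density, comm$zoo_smaller$density),
       guilds = c(comm$phytoplankton$guild, comm$zoo_smaller$guild),
       truth = truth)
}

planted_keys <- function(truth) {
  pe <- truth$planted_edges
  paste(pmin(pe$species_a, pe$species_b), pmax(pe$species_a, pe$species_b))
}

edge_keys <- function(net) {
  paste(pmin(net$edges$from, net$edges$to), pmax(net$edges$from, net$edges$to))
}
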