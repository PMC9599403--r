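#' Network inference configuration
#'
#' Thresholds and SparCC settings used to build co-occurrence networks:
#' associations with basis correlation |r| below `r_threshold` (default 0.3)
#' or permutation p-value at or above `p_threshold` (default 0.05) are
#' discarded.
#'
#' @param r_threshold correlation magnitude threshold, in (0,1); edges
#'   require |r| >= r_threshold (inclusive).
#' @param p_threshold significance threshold, in (0,1); edges require
#'   p < p_threshold (strict).
#' @param n_permutations permutation count for p-values (>= 20).
#' @param sparcc_iterations maximum strongly-correlated-pair exclusion
#'   rounds in the basis-variance estimation.
#' @param exclusion_threshold |r| above which the strongest pair is excluded
#'   from the basis-variance system in each round.
#' @param pseudocount positive count added to every virtual count before
#'   closure to fractions, so zeros do not break the log-ratio transform.
#' @param virtual_depth every sample is first rescaled to this total
#'   (a virtual counting depth) before the pseudocount is added; the
#'   estimate therefore depends on relative abundances only and is exactly
#'   invariant to any per-sample closure of the input.
#' @param seed RNG seed for the permutation test.
#' @return object of class `network_config`
#' @export
network_config <- function(r_threshold = 0.3, p_threshold = 0.05,
                           n_permutations = 100, sparcc_iterations = 10,
                           exclusion_threshold = 0.1, pseudocount = 1,
                           virtual_depth = 1000, seed = 1) {
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must be in (0,1)")
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0,1)")
  if (n_permutations < 20) stop("n_permutations must be >= 20")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (virtual_depth <= 0) stop("virtual_depth must be positive")
  structure(list(r_threshold = r_threshold, p_threshold = p_threshold,
                 n_permutations = as.integer(n_permutations),
                 sparcc_iterations = as.integer(sparcc_iterations),
                 exclusion_threshold = exclusion_threshold,
                 pseudocount = pseudocount, virtual_depth = virtual_depth,
                 seed = as.integer(seed)),
            class = "network_config")
}

# Core basis-correlation estimate from a density matrix (samples x species).
# Steps: pseudocount, closure to fractions, log, covariance; log-ratio
# variances t_ij = v_i + v_j - 2*c_ij; basis variances from the linear
# system ((D-2)I + J) w = t_row, refined by excluding the strongest
# remaining pair while |r| exceeds the exclusion threshold.
.sparcc_basis_r <- function(x, config) {
  # work on relative abundances only: rescale each sample to a common
  # virtual depth, then add the pseudocount, so per-sample closure of the
  # input cannot change the estimate
  tot <- rowSums(x)
  tot[tot == 0] <- 1
  frac <- (x / tot) * config$virtual_depth + config$pseudocount
  frac <- frac / rowSums(frac)
  lf <- log(frac)
  C <- stats::cov(lf)
  v <- diag(C)
  Tm <- outer(v, v, "+") - 2 * C
  D <- ncol(Tm)
  M <- matrix(1, D, D)
  diag(M) <- D - 1
  excl <- matrix(FALSE, D, D)
  R <- NULL
  for (iter in 0:config$sparcc_iterations) {
    Tuse <- Tm
    Tuse[excl] <- 0
    ti <- rowSums(Tuse)
    w <- tryCatch(solve(M, ti), error = function(e) NULL)
    if (is.null(w)) break
    w[w < .Machine$double.eps] <- .Machine$double.eps
    Rnew <- (outer(w, w, "+") - Tm) / (2 * sqrt(outer(w, w)))
    Rnew[Rnew > 1] <- 1
    Rnew[Rnew < -1] <- -1
    diag(Rnew) <- 1
    R <- Rnew
    if (iter == config$sparcc_iterations) break
    cand <- abs(R)
    cand[excl] <- 0
    diag(cand) <- 0
    m <- max(cand)
    if (m <= config$exclusion_threshold) break
    idx <- which(cand == m, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    # removing a pair from the system: drop its t contribution and counts
    if (M[i, i] <= 2 || M[j, j] <= 2) break
    excl[i, j] <- excl[j, i] <- TRUE
    M[i, j] <- M[j, i] <- 0
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
  }
  dimnames(R) <- dimnames(Tm)
  R
}

#' SparCC basis correlations for a density table
#'
#' Estimates correlations between the unobserved basis abundances from the
#' observed (possibly composition-distorted) densities via log-ratio
#' variances, following the sparse compositional correlation approach:
#' t_ij = var(log(x_i/x_j)) depends only on relative abundances, basis
#' variances are solved from a linear system under the sparsity assumption,
#' and strongly correlated pairs are iteratively excluded from that system.
#'
#' @param table abundance_table (or plain numeric matrix, samples x species).
#' @param config [network_config()]
#' @return object of class `correlation_result`: list with symmetric matrix
#'   `r`, matrix `p` (NA until [permutation_pvalues()] is run), `species`,
#'   `dropped` (all-zero species removed), and `config`.
#' @export
sparcc_correlations <- function(table, config = network_config()) {
  x <- if (inherits(table, "abundance_table")) table$density else as.matrix(table)
  if (nrow(x) < 4) stop("need at least 4 samples")
  zero <- colSums(x) == 0
  if (any(zero)) {
    warning("dropping all-zero species: ",
            paste(colnames(x)[zero], collapse = ", "))
    x <- x[, !zero, drop = FALSE]
  }
  if (ncol(x) < 4)
    stop("need at least 4 species with nonzero counts for basis-variance estimation")
  R <- .sparcc_basis_r(x, config)
  p <- matrix(NA_real_, ncol(x), ncol(x), dimnames = dimnames(R))
  structure(list(r = R, p = p, species = colnames(x),
                 dropped = colnames(x)[zero], config = config,
                 .data = x),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("correlation_result: %d species, permutation p-values %s\n",
              length(x$species),
              if (all(is.na(x$p[upper.tri(x$p)]))) "not computed" else "computed"))
  invisible(x)
}

#' Permutation p-values for SparCC correlations
#'
#' Each permuted dataset shuffles every species column independently across
#' samples, destroying all pairwise association while preserving marginals;
#' the SparCC estimate is recomputed on each. Two-sided p-values use add-one
#' smoothing: p = (1 + #\{|r_perm| >= |r_obs|\}) / (1 + n_permutations), so
#' the attainable floor is 1/(1 + n_permutations).
#'
#' @param observed correlation_result from [sparcc_correlations()]
#' @param config [network_config()]; `n_permutations` and `seed` are used.
#' @return the correlation_result with `p` filled in.
#' @export
permutation_pvalues <- function(observed, config = observed$config) {
  if (config$n_permutations < 20) stop("n_permutations must be >= 20")
  x <- observed$.data
  robs <- abs(observed$r)
  exceed <- matrix(0, nrow(robs), ncol(robs))
  set.seed(config$seed)
  n <- nrow(x)
  for (b in seq_len(config$n_permutations)) {
    xp <- apply(x, 2, function(col) col[sample.int(n)])
    rp <- abs(.sparcc_basis_r(xp, config))
    exceed <- exceed + (rp >= robs)
  }
  p <- (1 + exceed) / (1 + config$n_permutations)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(observed$r)
  observed$p <- p
  observed
}

#' Build a signed bipartite co-occurrence network
#'
#' Keeps exactly the cross-guild pairs whose correlation magnitude and
#' permutation significance pass the thresholds (|r| >= r_threshold,
#' p < p_threshold); within-guild pairs are never edges. Species left
#' without any surviving edge are excluded from the node set, so network
#' size counts networked taxa only.
#'
#' @param corr correlation_result with p-values computed.
#' @param guilds named character vector species -> guild label (exactly two
#'   distinct labels among the correlated species).
#' @param config [network_config()]
#' @param taxon_group optional named character vector species -> taxon group.
#' @return object of class `bipartite_network`: list with data.frames
#'   `nodes` (id, guild, taxon_group) and `edges` (from, to, r, p), logical
#'   `empty`, and a `report` (node counts per guild, edges, proportion of
#'   negative edges).
#' @export
build_bipartite_network <- function(corr, guilds, config = corr$config,
                                    taxon_group = NULL) {
  sp <- corr$species
  missing <- setdiff(sp, names(guilds))
  if (length(missing) > 0)
    stop("species without guild label: ", paste(missing, collapse = ", "))
  g <- guilds[sp]
  lv <- sort(unique(g))
  if (length(lv) != 2)
    stop("need exactly two guilds among the correlated species, got: ",
         paste(lv, collapse = ", "))
  if (all(is.na(corr$p[upper.tri(corr$p)])))
    stop("permutation p-values not computed; run permutation_pvalues() first")
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  a <- sp[ut[, 1]]; b <- sp[ut[, 2]]
  r <- corr$r[ut]; p <- corr$p[ut]
  cross <- g[a] != g[b]
  keep <- cross & abs(r) >= config$r_threshold & p < config$p_threshold
  edges <- data.frame(from = a[keep], to = b[keep], r = r[keep], p = p[keep],
                      stringsAsFactors = FALSE)
  bipartite_network(edges, guilds = g, taxon_group = taxon_group)
}

#' Construct a bipartite_network from an edge list
#'
#' @param edges data.frame with columns from, to, r, p.
#' @param guilds named character vector covering every endpoint.
#' @param taxon_group optional named character vector.
#' @return bipartite_network (with `empty = TRUE` flag when no edges).
#' @export
bipartite_network <- function(edges, guilds, taxon_group = NULL) {
  stopifnot(all(c("from", "to", "r", "p") %in% names(edges)))
  ids <- sort(unique(c(edges$from, edges$to)))
  missing <- setdiff(ids, names(guilds))
  if (length(missing) > 0)
    stop("edge endpoints without guild label: ", paste(missing, collapse = ", "))
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    if (any(guilds[edges$from] == guilds[edges$to]))
      stop("within-guild edges are not allowed in a bipartite network")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) stop("parallel edges are not allowed")
    # orient every edge from the first guild level so that double-edge
    # swaps on the 'to' endpoints stay cross-guild by construction
    lv <- sort(unique(guilds[ids]))
    flip <- guilds[edges$from] != lv[1]
    if (any(flip)) {
      tmp <- edges$from[flip]
      edges$from[flip] <- edges$to[flip]
      edges$to[flip] <- tmp
    }
  }
  tg <- rep(NA_character_, length(ids))
  names(tg) <- ids
  if (!is.null(taxon_group))
    tg[intersect(ids, names(taxon_group))] <-
      taxon_group[intersect(ids, names(taxon_group))]
  nodes <- data.frame(id = ids, guild = unname(guilds[ids]),
                      taxon_group = unname(tg), stringsAsFactors = FALSE)
  report <- list(
    nodes_per_guild = if (nrow(nodes)) table(nodes$guild) else table(character()),
    edges = nrow(edges),
    prop_negative = if (nrow(edges)) mean(edges$r < 0) else NA_real_)
  structure(list(nodes = nodes, edges = edges, empty = nrow(edges) == 0,
                 report = report),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  if (x$empty) {
    cat("bipartite_network: empty (no surviving edges)\n")
  } else {
    gl <- paste(sprintf("%s=%d", names(x$report$nodes_per_guild),
                        as.integer(x$report$nodes_per_guild)), collapse = ", ")
    cat(sprintf("bipartite_network: %d nodes (%s), %d edges (%.1f%% negative)\n",
                nrow(x$nodes), gl, nrow(x$edges), 100 * x$report$prop_negative))
  }
  invisible(x)
}

#' Cross-fraction zooplankton network
#'
#' Builds a bipartite network between the smaller and bigger zooplankton
#' size fractions: the two fraction tables are column-bound over shared
#' samples with fraction-suffixed species names, correlations are estimated
#' jointly, and size fractions take the role of guilds.
#'
#' @param smaller,bigger abundance_table objects (already intersected).
#' @param config [network_config()]
#' @return bipartite_network whose guild labels are `smaller` / `bigger`.
#' @export
build_zoozoo_network <- function(smaller, bigger, config = network_config()) {
  shared_samples <- intersect(sample_ids(smaller), sample_ids(bigger))
  if (length(shared_samples) < 4) stop("need >= 4 shared samples")
  xs <- smaller$density[shared_samples, , drop = FALSE]
  xb <- bigger$density[shared_samples, , drop = FALSE]
  colnames(xs) <- paste0(colnames(xs), "|smaller")
  colnames(xb) <- paste0(colnames(xb), "|bigger")
  x <- cbind(xs, xb)
  fraction <- stats::setNames(
    c(rep("smaller", ncol(xs)), rep("bigger", ncol(xb))), colnames(x))
  corr <- sparcc_correlations(x, config)
  corr <- permutation_pvalues(corr, config)
  build_bipartite_network(corr, guilds = fraction, config = config)
}

#' Export a network as GraphML and TSV edge list
#' @param net bipartite_network
#' @param graphml_path,edges_path output file paths (NULL to skip either)
#' @return invisibly, the paths written
#' @export
export_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  written <- character()
  if (!is.null(graphml_path)) {
    g <- as_igraph(net)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path)) {
    ed <- net$edges
    ed$sign <- ifelse(ed$r >= 0, "positive", "negative")
    utils::write.table(ed, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edges_path)
  }
  invisible(written)
}

#' Convert a bipartite_network to an igraph graph
#'
#' Nodes carry `guild` and `taxon_group` attributes; edges carry `r`, `p`
#' and `weight` = |r|.
#' @param net bipartite_network
#' @return igraph graph
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = net$nodes)
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  g
}

#' Read a network back from a GraphML file
#' @param path GraphML path
#' @return bipartite_network
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ed <- igraph::as_data_frame(g, what = "edges")
  vs <- igraph::as_data_frame(g, what = "vertices")
  id <- if ("name" %in% names(vs)) vs$name else as.character(seq_len(nrow(vs)))
  guilds <- stats::setNames(vs$guild, id)
  tg <- if ("taxon_group" %in% names(vs)) stats::setNames(vs$taxon_group, id) else NULL
  bipartite_network(ed[, c("from", "to", "r", "p")], guilds = guilds,
                    taxon_group = tg)
}
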