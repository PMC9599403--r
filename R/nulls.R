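#' Maslov-Sneppen degree-preserving rewiring
#'
#' Repeated double-edge swaps (a-b, c-d -> a-d, c-b) on the bipartite edge
#' list. Because every edge is oriented from one guild to the other, swapped
#' edges remain cross-guild automatically; a swap is accepted only when
#' neither proposed edge already exists. Node degrees, the guild
#' bipartition, the edge count, and the multiset of edge weights are all
#' conserved. Rewired edges carry the attributes (r, p) of the first parent
#' edge.
#'
#' @param net bipartite_network
#' @param n_swaps number of accepted-or-rejected swap attempts; defaults to
#'   10 x number of edges (standard mixing heuristic).
#' @param seed integer RNG seed (NULL to use the current RNG state).
#' @return rewired bipartite_network
#' @export
rewire <- function(net, n_swaps = 10 * nrow(net$edges), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(net$edges)
  if (m < 2) {
    warning("fewer than 2 edges; returning network unchanged")
    return(net)
  }
  from <- net$edges$from
  to <- net$edges$to
  r <- net$edges$r
  p <- net$edges$p
  keys <- paste(from, to, sep = "\r")
  for (s in seq_len(n_swaps)) {
    e <- sample.int(m, 2)
    i <- e[1]; j <- e[2]
    if (to[i] == to[j] || from[i] == from[j]) next
    k1 <- paste(from[i], to[j], sep = "\r")
    k2 <- paste(from[j], to[i], sep = "\r")
    if (k1 %in% keys || k2 %in% keys) next
    tmp <- to[i]; to[i] <- to[j]; to[j] <- tmp
    keys[i] <- k1; keys[j] <- k2
  }
  guilds <- stats::setNames(net$nodes$guild, net$nodes$id)
  tg <- stats::setNames(net$nodes$taxon_group, net$nodes$id)
  bipartite_network(data.frame(from = from, to = to, r = r, p = p,
                               stringsAsFactors = FALSE),
                    guilds = guilds, taxon_group = tg)
}

#' Null distributions of network metrics over a rewired ensemble
#'
#' Generates `n_networks` independently rewired networks and evaluates each
#' metric on every one. Metric failures on individual null networks are
#' recorded and excluded.
#'
#' @param net empirical bipartite_network
#' @param metric_fns named list of functions `bipartite_network -> numeric(1)`
#' @param n_networks ensemble size (>= 100; 1000 for full runs)
#' @param seed integer seed; network k uses sub-seed seed + k.
#' @return object of class `null_ensemble`: per metric the empirical value,
#'   the vector of null values, mean, sd, and the failure count.
#' @export
null_metric_distribution <- function(net, metric_fns, n_networks = 1000,
                                     seed = 1) {
  stopifnot(is.list(metric_fns), length(names(metric_fns)) == length(metric_fns))
  empirical <- vapply(metric_fns, function(f) as.numeric(f(net)), numeric(1))
  vals <- matrix(NA_real_, n_networks, length(metric_fns),
                 dimnames = list(NULL, names(metric_fns)))
  failures <- stats::setNames(integer(length(metric_fns)), names(metric_fns))
  for (k in seq_len(n_networks)) {
    nullnet <- rewire(net, seed = seed + k)
    for (mname in names(metric_fns)) {
      v <- tryCatch(as.numeric(metric_fns[[mname]](nullnet)),
                    error = function(e) NA_real_)
      if (is.na(v)) failures[mname] <- failures[mname] + 1L
      vals[k, mname] <- v
    }
  }
  metrics <- lapply(names(metric_fns), function(mname) {
    v <- vals[, mname]
    ok <- v[!is.na(v)]
    list(empirical = empirical[[mname]], null = v,
         null_mean = mean(ok), null_sd = stats::sd(ok),
         n_valid = length(ok), n_failed = failures[[mname]])
  })
  names(metrics) <- names(metric_fns)
  structure(list(metrics = metrics, n_networks = n_networks, seed = seed),
            class = "null_ensemble")
}

#' Compare empirical metrics against their null distributions
#'
#' One-sample Student's t-test of each metric's null vector against the
#' empirical value (two-sided). A null distribution with zero standard
#' deviation (a conserved metric such as the link count) is flagged as
#' degenerate instead of producing a t-statistic.
#'
#' @param ensemble null_ensemble from [null_metric_distribution()]
#' @param alpha significance flag level (default 0.05)
#' @return data.frame with one row per metric: empirical, null_mean,
#'   null_sd, t, p, significant, degenerate, n_valid.
#' @export
compare_empirical_to_null <- function(ensemble, alpha = 0.05) {
  rows <- lapply(names(ensemble$metrics), function(mname) {
    m <- ensemble$metrics[[mname]]
    ok <- m$null[!is.na(m$null)]
    tt <- if (length(ok) < 2) NULL else
      tryCatch(stats::t.test(ok, mu = m$empirical), error = function(e) NULL)
    degenerate <- is.null(tt)  # constant (or near-constant) null vector
    if (degenerate) {
      data.frame(metric = mname, empirical = m$empirical,
                 null_mean = m$null_mean, null_sd = m$null_sd,
                 t = NA_real_, p = NA_real_, significant = NA,
                 degenerate = TRUE, n_valid = m$n_valid)
    } else {
      data.frame(metric = mname, empirical = m$empirical,
                 null_mean = m$null_mean, null_sd = m$null_sd,
                 t = unname(tt$statistic), p = tt$p.value,
                 significant = tt$p.value < alpha,
                 degenerate = FALSE, n_valid = m$n_valid)
    }
  })
  do.call(rbind, rows)
}

#' Serialize a null-ensemble comparison as JSON
#' @param ensemble null_ensemble
#' @param path output path
#' @return path invisibly
#' @export
write_null_summary <- function(ensemble, path) {
  df <- compare_empirical_to_null(ensemble)
  jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
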