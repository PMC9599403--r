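# independent log-normal table: no true associations
indep_table <- function(n = 200, d = 30, seed = 1, meanlog = 3, sdlog = 1) {
  set.seed(seed)
  x <- matrix(stats::rlnorm(n * d, meanlog, sdlog), n, d,
              dimnames = list(paste0("s", seq_len(n)), paste0("sp", seq_len(d))))
  x
}

test_that("a perfectly proportional pair has basis correlation near 1", {
  # x_i = 2 x_j implies var(log(x_i/x_j)) = var(log 2) = 0, hence r = 1
  x <- indep_table(150, 20, seed = 2, meanlog = 5)
  x[, "sp2"] <- 2 * x[, "sp1"]
  r <- sparcc_correlations(x, network_config())$r
  expect_gt(r["sp1", "sp2"], 0.95)
  # and the direct log-ratio variance oracle confirms the mechanism
  expect_lt(stats::var(log(x[, "sp1"] / x[, "sp2"])), 1e-20)
})

test_that("independent species yield near-zero basis correlations", {
  r <- sparcc_correlations(indep_table(200, 30, seed = 3), network_config())$r
  expect_lt(stats::median(abs(r[upper.tri(r)])), 0.1)
})

test_that("all-zero species are dropped with a warning", {
  x <- indep_table(50, 8, seed = 4)
  x[, "sp5"] <- 0
  expect_warning(res <- sparcc_correlations(x, network_config()), "sp5")
  expect_false("sp5" %in% res$species)
  expect_equal(dim(res$r), c(7, 7))
})

test_that("size contracts are enforced", {
  x <- indep_table(3, 10)
  expect_error(sparcc_correlations(x), "at least 4 samples")
  expect_error(sparcc_correlations(indep_table(50, 3)), "at least 4 species")
  expect_error(network_config(n_permutations = 10), "n_permutations")
})

test_that("correlations are symmetric and invariant to species order", {
  x <- indep_table(100, 12, seed = 6)
  r1 <- sparcc_correlations(x, network_config())$r
  expect_identical(r1, t(r1))
  perm <- sample(ncol(x))
  r2 <- sparcc_correlations(x[, perm], network_config())$r
  expect_equal(r2[colnames(x), colnames(x)], r1, tolerance = 1e-12)
})

test_that("permutation p-values hit the smoothing floor for proportional pairs", {
  x <- indep_table(100, 12, seed = 7, meanlog = 5)
  x[, "sp2"] <- 3 * x[, "sp1"]
  cfg <- network_config(n_permutations = 49, seed = 5)
  res <- permutation_pvalues(sparcc_correlations(x, cfg), cfg)
  expect_equal(res$p["sp1", "sp2"], 1 / 50)
  # reproducible under the same seed
  res2 <- permutation_pvalues(sparcc_correlations(x, cfg), cfg)
  expect_identical(res$p, res2$p)
})

test_that("permutation p-values are roughly uniform under independence", {
  # pooled upper-triangle p-values over independent draws should spread
  # across the unit interval rather than concentrate
  ps <- c()
  for (s in 1:6) {
    x <- indep_table(60, 8, seed = 20 + s)
    cfg <- network_config(n_permutations = 39, seed = s)
    res <- permutation_pvalues(sparcc_correlations(x, cfg), cfg)
    ps <- c(ps, res$p[upper.tri(res$p)])
  }
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.1), 0.25)
})

test_that("network building applies the guild, r and p filters exactly", {
  species <- c("pA", "pB", "zA", "zB")
  r <- diag(4); dimnames(r) <- list(species, species)
  p <- matrix(1, 4, 4, dimnames = dimnames(r)); diag(p) <- NA
  fill <- function(m, a, b, v) { m[a, b] <- v; m[b, a] <- v; m }
  r <- fill(r, "pA", "zA", 0.5);  p <- fill(p, "pA", "zA", 0.01)
  r <- fill(r, "pA", "pB", 0.9);  p <- fill(p, "pA", "pB", 0.001) # within-guild
  r <- fill(r, "pB", "zB", 0.25); p <- fill(p, "pB", "zB", 0.001) # |r| < 0.3
  r <- fill(r, "zA", "zB", 0.9);  p <- fill(p, "zA", "zB", 0.001) # within-guild
  corr <- structure(list(r = r, p = p, species = species,
                         dropped = character(), config = network_config()),
                    class = "correlation_result")
  guilds <- c(pA = "phytoplankton", pB = "phytoplankton",
              zA = "zooplankton", zB = "zooplankton")
  net <- build_bipartite_network(corr, guilds)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes$id, c("pA", "zA"))  # isolated species dropped

  # boundary: |r| = 0.3 is kept (inclusive), p = 0.05 is dropped (strict)
  r2 <- fill(r, "pB", "zB", 0.3)
  c2 <- corr; c2$r <- r2
  expect_equal(nrow(build_bipartite_network(c2, guilds)$edges), 2)
  p3 <- fill(p, "pA", "zA", 0.05)
  c3 <- corr; c3$p <- p3
  net3 <- build_bipartite_network(c3, guilds)
  expect_true(net3$empty)
})

test_that("planted cross-guild structure is recovered end to end", {
  tb <- benchmark_tables(benchmark_truth(strength = 0.9, n_planted = 5),
                         n_samples = 200, seed = 9)
  cfg <- network_config(seed = 4)
  corr <- permutation_pvalues(sparcc_correlations(tb$x, cfg), cfg)
  net <- build_bipartite_network(corr, tb$guilds)
  keys <- planted_keys(tb$truth)
  found <- edge_keys(net)
  expect_equal(sum(keys %in% found), 5)
  expect_lte(sum(!found %in% keys), 1)
  # sign bookkeeping
  expect_equal(net$report$prop_negative, mean(net$edges$r < 0))
})

test_that("closure leaves SparCC unchanged but shifts naive Pearson", {
  tb <- benchmark_tables(benchmark_truth(strength = 0.9, n_planted = 10),
                         n_samples = 200, seed = 7)
  x <- tb$x
  closed <- x / rowSums(x) * 1e4
  cfg <- network_config()
  delta <- abs(sparcc_correlations(x, cfg)$r -
                 sparcc_correlations(closed, cfg)$r)
  expect_lt(max(delta), 0.05)
  # naive Pearson on proportions is distorted for truly null pairs
  shift <- abs(cor(x) - cor(x / rowSums(x)))
  keys <- planted_keys(tb$truth)
  ut <- which(upper.tri(shift), arr.ind = TRUE)
  pairkey <- paste(pmin(rownames(shift)[ut[, 1]], colnames(shift)[ut[, 2]]),
                   pmax(rownames(shift)[ut[, 1]], colnames(shift)[ut[, 2]]))
  cross <- tb$guilds[rownames(shift)[ut[, 1]]] !=
    tb$guilds[colnames(shift)[ut[, 2]]]
  null_shift <- shift[ut][cross & !(pairkey %in% keys)]
  expect_gt(max(null_shift), 0.1)
})

test_that("cross-fraction zooplankton networks recover same-species coupling", {
  gs <- c(phytoplankton = 4, zoo_shared = 12, zoo_smaller_only = 0,
          zoo_bigger_only = 0)
  nm <- species_names(gs)
  # the same species planted to covary between its two size fractions
  pe <- data.frame(species_a = nm$zoo_shared[1], species_b = nm$zoo_shared[1],
                   sign = 1, strength = 0.9)
  tr <- synthetic_truth(gs, planted_edges = pe)
  cfg <- generator_config(n_samples = 150, n_sites = 3, seed = 15,
                          zero_inflation = 0.05)
  comm <- generate_community(cfg, tr)
  net <- build_zoozoo_network(comm$zoo_smaller, comm$zoo_bigger,
                              network_config(seed = 6))
  want <- paste0(nm$zoo_shared[1], "|smaller")
  partner <- paste0(nm$zoo_shared[1], "|bigger")
  hit <- (net$edges$from == want & net$edges$to == partner) |
    (net$edges$from == partner & net$edges$to == want)
  expect_true(any(hit))
  expect_gt(net$edges$r[hit], 0)  # positive cross-fraction link
  # few spurious links under the thresholds
  expect_lte(sum(!hit), ceiling(0.05 * (12 * 12 - 1)))
})
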