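# two dense bipartite blocks joined by a single bridge edge
two_block_net <- function() {
  blockA <- as.matrix(expand.grid(paste0("p", 1:4), paste0("z", 1:4),
                                  stringsAsFactors = FALSE))
  blockB <- as.matrix(expand.grid(paste0("p", 5:8), paste0("z", 5:8),
                                  stringsAsFactors = FALSE))
  net_from_pairs(rbind(blockA, blockB, c("p1", "z5")))
}

test_that("module detection recovers planted blocks", {
  net <- two_block_net()
  part <- detect_modules(net, seed = 1)
  memb <- part$membership
  blockA <- c(paste0("p", 1:4), paste0("z", 1:4))
  blockB <- c(paste0("p", 5:8), paste0("z", 5:8))
  expect_equal(length(unique(memb[blockA])), 1)
  expect_equal(length(unique(memb[blockB])), 1)
  expect_false(memb[blockA[1]] == memb[blockB[1]])
  expect_gt(part$modularity, 0.3)
})

test_that("module detection is deterministic and flags small modules", {
  net <- two_block_net()
  expect_identical(detect_modules(net, seed = 1)$membership,
                   detect_modules(net, seed = 2)$membership)
  single <- net_from_pairs(c("p1", "z1"))
  part <- detect_modules(single)
  expect_equal(length(unique(part$membership)), 1)
  expect_true(1 %in% part$small_modules)  # 2 nodes <= 5
})

test_that("Zi and Pi satisfy their closed-form cases", {
  net <- two_block_net()
  part <- detect_modules(net, seed = 1)
  zp <- zi_pi(net, part)
  # all edges of z1 stay inside its module -> Pi = 0
  expect_equal(zp$Pi[zp$node == "z1"], 0)
  # complete blocks: every member of z-block has the same within-degree
  # except the bridge endpoints; p2 has within-degree equal to p3, p4
  expect_equal(zp$Zi[zp$node == "z2"], zp$Zi[zp$node == "z3"])
  # bridge endpoint p1 splits its edges across modules -> Pi in (0, 1)
  p1 <- zp[zp$node == "p1", ]
  expect_equal(p1$Pi, 1 - (4 / 5)^2 - (1 / 5)^2)
  expect_true(all(zp$Pi >= 0 & zp$Pi < 1))
  # Pi = 0 iff all edges within own module
  all_within <- vapply(zp$node, function(u) {
    nb <- c(net$edges$to[net$edges$from == u], net$edges$from[net$edges$to == u])
    all(part$membership[nb] == part$membership[u])
  }, logical(1))
  expect_identical(unname(zp$Pi == 0), unname(all_within))
})

test_that("zi_pi equals a brute-force recomputation on random partitioned graphs", {
  for (s in 1:100) {
    net <- random_bipartite(sample(3:6, 1), sample(3:6, 1), p_edge = 0.5,
                            seed = 500 + s)
    ids <- net$nodes$id
    set.seed(s)
    memb <- stats::setNames(sample(1:3, length(ids), replace = TRUE), ids)
    part <- structure(list(membership = memb, modularity = NA,
                           algorithm = "random", small_modules = integer(),
                           seed = s), class = "module_partition")
    zp <- zi_pi(net, part)
    orc <- oracle_zipi(net, memb)
    expect_equal(stats::setNames(zp$Zi, zp$node), orc$zi[zp$node])
    expect_equal(stats::setNames(zp$Pi, zp$node), orc$pi[zp$node])
  }
})

test_that("role classification follows the four-way rule with boundaries", {
  expect_equal(classify_node_role(3.0, 0.5), "module hub")
  expect_equal(classify_node_role(3.0, 0.7), "network hub")
  expect_equal(classify_node_role(2.0, 0.7), "connector")
  expect_equal(classify_node_role(2.0, 0.5), "peripheral")
  # boundaries: Zi = 2.5 is not a hub; Pi = 0.62 is not a connector
  expect_equal(classify_node_role(2.5, 0.62), "peripheral")
  expect_equal(classify_node_role(2.5, 0.6200001), "connector")
  expect_equal(classify_node_role(2.5000001, 0.62), "module hub")
})

test_that("module eigenvalues reduce correctly for degenerate modules", {
  set.seed(3)
  x <- matrix(exp(rnorm(60)), 20, 3,
              dimnames = list(paste0("s", 1:20), c("a", "b", "c")))
  x[, "b"] <- 2 * x[, "a"]   # perfectly correlated pair
  at <- abundance_table(x, guild = stats::setNames(rep("phytoplankton", 3),
                                                   c("a", "b", "c")))
  one <- module_eigenvalue("a", at)
  expect_equal(unname(one$series), unname(scale(x[, "a"])[, 1]))
  two <- module_eigenvalue(c("a", "b"), at)
  expect_equal(two$variance_explained, 1)
  expect_gt(abs(cor(two$series, x[, "a"])), 0.9999)
  expect_equal(stats::sd(two$series), 1)
  expect_error(module_eigenvalue(c("a", "zz"), at), "zz")
})

test_that("a temperature-coupled module's eigenvalue tracks temperature", {
  gs <- c(phytoplankton = 8, zoo_shared = 8, zoo_smaller_only = 0,
          zoo_bigger_only = 0)
  nm <- species_names(gs)
  ec <- data.frame(species = nm$phytoplankton[1:4], factor = "temperature",
                   coef = 0.8)
  tr <- synthetic_truth(gs, env_coupling = ec)
  cfg <- generator_config(n_samples = 200, n_sites = 4, seed = 21,
                          zero_inflation = 0)
  comm <- generate_community(cfg, tr)
  env <- generate_environment(cfg, tr)
  me <- module_eigenvalue(nm$phytoplankton[1:4], comm$phytoplankton)
  expect_gt(abs(cor(me$series, env$factors[names(me$series), "temperature"])),
            0.5)
  mc <- module_env_correlation(me, env)
  expect_true(mc$stars[mc$factor == "temperature"] == "***")
})

test_that("module-environment correlations keep signs and flag constants", {
  set.seed(9)
  f <- matrix(rnorm(40), 20, 2,
              dimnames = list(paste0("s", 1:20), c("temperature", "pH")))
  f[, "pH"] <- 5  # constant factor
  env <- environment_table(f)
  eig <- structure(list(series = stats::setNames(f[, "temperature"],
                                                 rownames(f)),
                        variance_explained = 1, members = "m"),
                   class = "module_eigen")
  mc <- module_env_correlation(eig, env)
  expect_equal(mc$r[mc$factor == "temperature"], 1)
  expect_equal(mc$stars[mc$factor == "temperature"], "***")
  expect_true(mc$undefined[mc$factor == "pH"])
  eig$series <- -eig$series
  mc2 <- module_env_correlation(eig, env)
  expect_equal(mc2$r[mc2$factor == "temperature"], -1)
})

test_that("preserved-module pairing obeys overlap, boundary and one-to-one rules", {
  mk_part <- function(memb) structure(
    list(membership = memb, modularity = NA, algorithm = "fixed",
         small_modules = integer(), seed = 0), class = "module_partition")
  # identical partitions pair completely at overlap 1
  memb <- stats::setNames(c(1, 1, 1, 2, 2, 2), paste0("n", 1:6))
  pairs <- pair_preserved_modules(mk_part(memb), mk_part(memb))
  expect_equal(nrow(pairs), 2)
  expect_true(all(pairs$overlap == 1))
  # disjoint node sets: no pairs
  memb2 <- stats::setNames(c(1, 1, 2, 2), paste0("m", 1:4))
  expect_equal(nrow(pair_preserved_modules(mk_part(memb), mk_part(memb2))), 0)
  # boundary: overlap exactly 0.5 pairs (inclusive threshold)
  a <- stats::setNames(rep(1, 4), paste0("n", 1:4))
  b <- stats::setNames(rep(1, 6), c("n1", "n2", paste0("x", 1:4)))
  pb <- pair_preserved_modules(mk_part(a), mk_part(b))
  expect_equal(pb$overlap, 0.5)
  expect_true(pb$paired)
  # greedy one-to-one, invariant to module relabeling
  m_small <- stats::setNames(c(1, 1, 1, 2, 2), paste0("n", 1:5))
  m_big <- stats::setNames(c(7, 7, 7, 7, 9), paste0("n", 1:5))
  p1 <- pair_preserved_modules(mk_part(m_small), mk_part(m_big))
  expect_true(!anyDuplicated(p1$module_small) && !anyDuplicated(p1$module_big))
  relab <- m_small; relab[] <- c(5, 5, 5, 3, 3)
  p2 <- pair_preserved_modules(mk_part(relab), mk_part(m_big))
  expect_equal(sort(p2$overlap), sort(p1$overlap))
})

test_that("the connectivity-significance Mantel test is exact on a proportional construction", {
  # build abundance profiles whose factor correlations are exactly
  # controlled: x_i = w_i * t + sqrt(1 - w_i^2) * e with t, e orthonormal
  n <- 24
  t_raw <- sin(seq_len(n)); e_raw <- cos(7 * seq_len(n))
  t_v <- scale(t_raw)[, 1]
  e_v <- stats::residuals(stats::lm(e_raw ~ t_v))
  e_v <- scale(e_v)[, 1]
  # nested bipartite graph: p_i linked to z_1..z_i, so phyto degrees 1..8
  pairs <- do.call(rbind, lapply(1:8, function(i)
    cbind(paste0("p", i), paste0("z", seq_len(i)))))
  net <- net_from_pairs(pairs)
  deg <- node_connectivity(net)[paste0("p", 1:8)]
  w <- sqrt(deg / 20)
  x <- sapply(seq_along(w), function(i) {
    5 + w[i] * t_v + sqrt(1 - w[i]^2) * e_v
  })
  x <- x - min(x) + 0.1
  colnames(x) <- paste0("p", 1:8)
  rownames(x) <- paste0("s", 1:n)
  at <- abundance_table(x, guild = stats::setNames(rep("phytoplankton", 8),
                                                   paste0("p", 1:8)))
  f <- matrix(t_v, n, 1, dimnames = list(rownames(x), "temperature"))
  env <- environment_table(f)
  mt <- mantel_connectivity_significance(net, at, env, "temperature",
                                         guild = "phytoplankton",
                                         n_permutations = 999, seed = 4)
  # significance = cor^2 = w^2 = deg/20, exactly proportional to
  # connectivity, so both Euclidean distance matrices are proportional
  expect_equal(mt$R, 1, tolerance = 1e-10)
  expect_lte(mt$p, 0.005)
})

test_that("Mantel R is invariant to joint species relabeling and flags degenerate input", {
  set.seed(12)
  n <- 20
  x <- matrix(exp(rnorm(n * 6)), n, 6,
              dimnames = list(paste0("s", 1:n), paste0("p", 1:6)))
  at <- abundance_table(x, guild = stats::setNames(rep("phytoplankton", 6),
                                                   paste0("p", 1:6)))
  f <- matrix(rnorm(n), n, 1, dimnames = list(rownames(x), "temperature"))
  env <- environment_table(f)
  net <- net_from_pairs(rbind(
    as.matrix(expand.grid(paste0("p", 1:6), "z1", stringsAsFactors = FALSE)),
    c("p1", "z2"), c("p2", "z2"), c("p3", "z2"), c("p1", "z3")))
  m1 <- mantel_connectivity_significance(net, at, env, "temperature",
                                         guild = "phytoplankton", seed = 2)
  # relabel species consistently in network and table
  perm <- c(p1 = "p3", p2 = "p1", p3 = "p2", p4 = "p6", p5 = "p4", p6 = "p5")
  ed <- net$edges
  ed$from <- ifelse(ed$from %in% names(perm), perm[ed$from], ed$from)
  ed$to <- ifelse(ed$to %in% names(perm), perm[ed$to], ed$to)
  guilds <- stats::setNames(net$nodes$guild, ifelse(
    net$nodes$id %in% names(perm), perm[net$nodes$id], net$nodes$id))
  net2 <- bipartite_network(ed, guilds = guilds)
  x2 <- x[, names(perm)]
  colnames(x2) <- unname(perm)
  at2 <- abundance_table(x2, guild = stats::setNames(rep("phytoplankton", 6),
                                                     unname(perm)))
  m2 <- mantel_connectivity_significance(net2, at2, env, "temperature",
                                         guild = "phytoplankton", seed = 2)
  expect_equal(m1$R, m2$R)

  # constant connectivity -> undefined flag
  star <- net_from_pairs(as.matrix(expand.grid(paste0("p", 1:6), "z1",
                                               stringsAsFactors = FALSE)))
  m3 <- mantel_connectivity_significance(star, at, env, "temperature",
                                         guild = "phytoplankton")
  expect_true(m3$undefined)
  # unknown factor group errors
  expect_error(mantel_connectivity_significance(net, at, env, "sulfate"),
               "unknown factor group")
})
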