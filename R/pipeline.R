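#' Pipeline configuration
#'
#' @param out_dir output directory for all stage artifacts.
#' @param phytoplankton,zoo_smaller,zoo_bigger paths to abundance tables
#'   (NULL to simulate instead; see `simulate`).
#' @param taxonomy path to the taxonomy table (required when reading).
#' @param environment_path path to the environment table (optional; enables
#'   the module-environment and Mantel stages).
#' @param simulate NULL, or a list with elements `config`
#'   ([generator_config()]) and `truth` ([synthetic_truth()]): generate the
#'   input tables instead of reading them.
#' @param network [network_config()]
#' @param fractions removal-fraction grid for robustness curves.
#' @param n_trials extinction trials per fraction.
#' @param n_null_networks Maslov-Sneppen ensemble size.
#' @param per_site also build one network per sampling site (regional
#'   networks) with the same thresholds.
#' @param seed master seed; every stochastic stage derives its sub-seed
#'   from it.
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            phytoplankton = NULL, zoo_smaller = NULL,
                            zoo_bigger = NULL, taxonomy = NULL,
                            environment_path = NULL, simulate = NULL,
                            network = network_config(),
                            fractions = seq(0.1, 0.9, by = 0.2),
                            n_trials = 100, n_null_networks = 1000,
                            per_site = FALSE, seed = 1) {
  if (is.null(simulate)) {
    paths <- c(phytoplankton, zoo_smaller, zoo_bigger, taxonomy)
    if (length(paths) < 4)
      stop("either provide all three abundance paths plus taxonomy, ",
           "or a 'simulate' specification")
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  if (!is.null(environment_path) && !file.exists(environment_path))
    stop("environment path does not exist: ", environment_path)
  structure(list(out_dir = out_dir, phytoplankton = phytoplankton,
                 zoo_smaller = zoo_smaller, zoo_bigger = zoo_bigger,
                 taxonomy = taxonomy, environment_path = environment_path,
                 simulate = simulate, network = network,
                 fractions = fractions, n_trials = n_trials,
                 n_null_networks = n_null_networks, per_site = per_site,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.infer_network <- function(phyto, zoo, netcfg) {
  shared <- intersect(sample_ids(phyto), sample_ids(zoo))
  x <- cbind(phyto$density[shared, , drop = FALSE],
             zoo$density[shared, , drop = FALSE])
  guilds <- c(phyto$guild[species_ids(phyto)], zoo$guild[species_ids(zoo)])
  tg <- c(phyto$taxon_group, zoo$taxon_group)
  corr <- sparcc_correlations(x, netcfg)
  corr <- permutation_pvalues(corr, netcfg)
  build_bipartite_network(corr, guilds = guilds, config = netcfg,
                          taxon_group = tg)
}

#' Run the full analysis pipeline
#'
#' Stages, per zooplankton size fraction: load or simulate the density
#' tables; intersect the zooplankton fractions; infer the SparCC bipartite
#' network; topology report; Maslov-Sneppen null ensemble with t tests;
#' robustness curves (zooplankton and phytoplankton removal) and
#' vulnerability; module detection, Zi/Pi roles, preserved-module pairing;
#' and, when an environment table is available, module-eigenvalue
#' correlations and connectivity-significance Mantel tests. All outputs are
#' written under `config$out_dir`; the returned manifest records inputs,
#' seeds, stage outcomes and counts.
#'
#' @param config [pipeline_config()]
#' @return run manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   thresholds = list(r = config$network$r_threshold,
                                     p = config$network$p_threshold))
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    message(sprintf("[pznet] %s: %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  # --- inputs -------------------------------------------------------------
  env <- NULL
  if (!is.null(config$simulate)) {
    comm <- generate_community(config$simulate$config, config$simulate$truth)
    env <- generate_environment(config$simulate$config, config$simulate$truth)
    phyto <- comm$phytoplankton
    zs <- comm$zoo_smaller
    zb <- comm$zoo_bigger
    log_stage("simulate", samples = nrow(phyto$density),
              phyto = ncol(phyto$density), zoo_smaller = ncol(zs$density),
              zoo_bigger = ncol(zb$density))
  } else {
    phyto <- read_abundance_table(config$phytoplankton, config$taxonomy)
    zs <- read_abundance_table(config$zoo_smaller, config$taxonomy)
    zb <- read_abundance_table(config$zoo_bigger, config$taxonomy)
    if (!is.null(config$environment_path))
      env <- read_environment_table(config$environment_path)
    log_stage("read", samples = nrow(phyto$density))
  }

  # --- intersection -------------------------------------------------------
  ix <- intersect_size_fractions(zs, zb)
  zs <- ix$smaller; zb <- ix$bigger
  log_stage("intersect", shared = ix$report$shared,
            only_smaller = ix$report$only_smaller,
            only_bigger = ix$report$only_bigger)

  nets <- list()
  for (frac in c("PSZN", "PBZN")) {
    zoo <- if (frac == "PSZN") zs else zb
    netcfg <- config$network
    netcfg$seed <- config$seed + if (frac == "PSZN") 11L else 22L
    net <- .infer_network(phyto, zoo, netcfg)
    nets[[frac]] <- net
    prefix <- file.path(config$out_dir, frac)
    if (!net$empty)
      export_network(net, paste0(prefix, ".graphml"), paste0(prefix, "_edges.tsv"))
    log_stage(paste0("infer_", frac), nodes = nrow(net$nodes),
              edges = nrow(net$edges))
    if (net$empty) next

    topo <- network_level_metrics(net)
    jsonlite::write_json(unclass(topo), paste0(prefix, "_topology.json"),
                         auto_unbox = TRUE, digits = NA)

    ens <- null_metric_distribution(
      net,
      metric_fns = list(
        cluster_coefficient = function(n) bipartite_clustering(n)$network,
        linkage_density = linkage_density,
        weighted_connectance = function(n) linkage_density(n) / nrow(n$nodes)),
      n_networks = config$n_null_networks, seed = config$seed + 100L)
    write_null_summary(ens, paste0(prefix, "_null_tests.json"))
    log_stage(paste0("nulls_", frac), n_networks = config$n_null_networks)

    for (target in c("zooplankton", "phytoplankton")) {
      rc <- robustness_curve(net, target, config$fractions,
                             n_trials = config$n_trials,
                             seed = config$seed + 200L)
      utils::write.table(rc$curve,
                         paste0(prefix, "_robustness_", target, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage(paste0("robustness_", frac, "_", target),
                slope = round(rc$slope, 4))
    }
    if (nrow(net$nodes) >= 3) {
      vr <- vulnerability(net)
      jsonlite::write_json(list(global_efficiency = vr$global_efficiency,
                                network_vulnerability = vr$network),
                           paste0(prefix, "_vulnerability.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    part <- detect_modules(net, seed = config$seed)
    write_partition(net, part, paste0(prefix, "_modules.tsv"))
    log_stage(paste0("modules_", frac),
              n_modules = length(unique(part$membership)),
              modularity = round(part$modularity, 3))

    if (!is.null(env)) {
      zoo_tab <- if (frac == "PSZN") zs else zb
      al <- align_samples(phyto, env)
      combined_density <- cbind(al$abundance$density,
                                zoo_tab$density[sample_ids(al$abundance), ,
                                                drop = FALSE])
      combined <- abundance_table(
        combined_density,
        guild = c(phyto$guild, zoo_tab$guild),
        size_fraction = zoo_tab$size_fraction,
        taxon_group = c(phyto$taxon_group, zoo_tab$taxon_group),
        site = phyto$site)
      # module eigenvalues x environment
      memb <- part$membership
      rows <- list()
      for (m in sort(unique(memb))) {
        members <- intersect(names(memb)[memb == m], species_ids(combined))
        if (length(members) == 0) next
        me <- tryCatch(module_eigenvalue(members, combined),
                       error = function(e) NULL)
        if (is.null(me)) next
        mc <- module_env_correlation(me, al$env)
        mc$module <- m
        rows[[length(rows) + 1]] <- mc
      }
      if (length(rows) > 0)
        utils::write.table(do.call(rbind, rows),
                           paste0(prefix, "_module_env.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      # Mantel tests per guild x factor group
      mrows <- list()
      for (gld in c("zooplankton", "phytoplankton")) {
        for (fg in c("temperature", "salinity", "N", "pH", "metal")) {
          mt <- tryCatch(
            mantel_connectivity_significance(net, combined, al$env, fg,
                                             guild = gld,
                                             seed = config$seed + 300L),
            error = function(e) NULL)
          if (!is.null(mt))
            mrows[[length(mrows) + 1]] <-
              data.frame(guild = gld, factor_group = fg, R = mt$R, p = mt$p)
        }
      }
      if (length(mrows) > 0) {
        jsonlite::write_json(do.call(rbind, mrows),
                             paste0(prefix, "_mantel.json"),
                             auto_unbox = TRUE, digits = NA, na = "null")
        log_stage(paste0("mantel_", frac), tests = length(mrows))
      }
    }
  }

  # preserved-module pairing across fractions
  if (!nets$PSZN$empty && !nets$PBZN$empty) {
    ps <- detect_modules(nets$PSZN, seed = config$seed)
    pb <- detect_modules(nets$PBZN, seed = config$seed)
    pairs <- pair_preserved_modules(ps, pb)
    utils::write.table(pairs, file.path(config$out_dir, "module_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("module_pairs", n_pairs = nrow(pairs))
  }

  manifest$networks <- lapply(nets, function(n)
    list(nodes = nrow(n$nodes), edges = nrow(n$edges), empty = n$empty))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}
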