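#' Ground-truth association structure for the synthetic generator
#'
#' Describes the "world" the generator emulates: guild inventories, planted
#' cross-guild (or cross-fraction) associations with latent strengths, species
#' coupled to environmental factors, and the ratio of mean density between the
#' smaller and bigger zooplankton size fractions.
#'
#' @param guild_sizes named integer vector with entries `phytoplankton`,
#'   `zoo_shared` (zooplankton caught by both nets), `zoo_smaller_only`,
#'   `zoo_bigger_only`. Defaults mirror a coastal survey in which the bigger
#'   net caught 240 species (40 exclusive), the smaller net 282 (82
#'   exclusive), 200 shared, with 307 phytoplankton.
#' @param planted_edges data.frame with columns `species_a`, `species_b`,
#'   `sign` (+1/-1) and `strength` in [0,1]: pairs that share a latent
#'   log-normal factor. Species names must refer to generated names (see
#'   [species_names()]). An optional `fraction` column
#'   (`"both"`/`"smaller"`/`"bigger"`, default `"both"`) restricts which
#'   zooplankton size-fraction table receives the association, so the two
#'   fraction networks can be given different planted signal.
#' @param env_coupling data.frame with columns `species`, `factor`,
#'   `coef` in (-1,1): the target correlation between the species'
#'   log-density and the named environmental factor.
#' @param density_ratio ratio (>0) of mean smaller-fraction to
#'   bigger-fraction zooplankton density; the default 3 encodes the stylized
#'   fact that zooplankton density declines steeply with body size.
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(guild_sizes = c(phytoplankton = 307, zoo_shared = 200,
                                            zoo_smaller_only = 82, zoo_bigger_only = 40),
                            planted_edges = NULL, env_coupling = NULL,
                            density_ratio = 3) {
  need <- c("phytoplankton", "zoo_shared", "zoo_smaller_only", "zoo_bigger_only")
  if (!all(need %in% names(guild_sizes)))
    stop("guild_sizes needs entries: ", paste(need, collapse = ", "))
  guild_sizes <- guild_sizes[need]
  storage.mode(guild_sizes) <- "integer"
  density_ratio <- as.numeric(density_ratio)
  if (any(guild_sizes[c("phytoplankton", "zoo_shared")] < 1))
    stop("phytoplankton and zoo_shared counts must be >= 1")
  if (any(guild_sizes < 0)) stop("guild sizes must be nonnegative")
  if (density_ratio <= 0) stop("density_ratio must be > 0")
  if (is.null(planted_edges))
    planted_edges <- data.frame(species_a = character(), species_b = character(),
                                sign = numeric(), strength = numeric())
  if (is.null(env_coupling))
    env_coupling <- data.frame(species = character(), factor = character(),
                               coef = numeric())
  if (is.null(planted_edges$fraction) && nrow(planted_edges) > 0)
    planted_edges$fraction <- "both"
  if (nrow(planted_edges) > 0) {
    if (any(planted_edges$strength < 0 | planted_edges$strength > 1))
      stop("latent strength must lie in [0,1]")
    if (!all(planted_edges$sign %in% c(-1, 1)))
      stop("edge sign must be -1 or +1")
    if (!all(planted_edges$fraction %in% c("both", "smaller", "bigger")))
      stop("edge fraction must be 'both', 'smaller' or 'bigger'")
    nm <- species_names(guild_sizes)
    known <- unlist(nm, use.names = FALSE)
    unknown <- setdiff(c(planted_edges$species_a, planted_edges$species_b), known)
    if (length(unknown) > 0)
      stop("planted edge references unknown species: ",
           paste(unknown, collapse = ", "))
    side <- function(s) ifelse(s %in% nm$phytoplankton, "phyto", "zoo")
    same <- side(planted_edges$species_a) == side(planted_edges$species_b) &
      side(planted_edges$species_a) == "phyto"
    if (any(same))
      stop("planted edges must join species of different guilds or size fractions")
  }
  structure(list(guild_sizes = guild_sizes, planted_edges = planted_edges,
                 env_coupling = env_coupling, density_ratio = density_ratio),
            class = "synthetic_truth")
}

#' Deterministic species names for a given guild-size configuration
#'
#' Shared zooplankton species keep the same name in both fraction tables so
#' the size-fraction intersection behaves as in a real matched survey.
#' @param guild_sizes as in [synthetic_truth()]
#' @return list with character vectors `phytoplankton`, `zoo_shared`,
#'   `zoo_smaller_only`, `zoo_bigger_only`
#' @export
species_names <- function(guild_sizes) {
  pad <- function(prefix, n) if (n == 0) character() else
    sprintf("%s_%03d", prefix, seq_len(n))
  list(phytoplankton = pad("phyto", guild_sizes[["phytoplankton"]]),
       zoo_shared = pad("zoo", guild_sizes[["zoo_shared"]]),
       zoo_smaller_only = pad("zoosm", guild_sizes[["zoo_smaller_only"]]),
       zoo_bigger_only = pad("zoobg", guild_sizes[["zoo_bigger_only"]]))
}

#' Generator configuration
#'
#' @param n_samples number of water samples (>= 4); default 251.
#' @param n_sites number of sampling sites; samples are split into
#'   contiguous site blocks; default 12.
#' @param seed integer RNG seed; a fixed seed gives bit-identical output.
#' @param zero_inflation probability in [0,1] of independently zeroing a
#'   density cell (Bernoulli thinning), emulating sparse plankton counts.
#' @param noise_sd standard deviation of the residual log-scale noise.
#' @param compositional_total if not `NULL`, each sample's densities within
#'   a table are rescaled to sum to this total (closure), creating the
#'   compositional artifacts SparCC is designed to remove.
#' @param species_logmean_sd spread of per-species mean log-densities;
#'   values >1 yield the strongly uneven abundance distributions (few
#'   dominant bloom taxa) typical of plankton communities.
#' @param site_effect_sd standard deviation of per-site, per-species mean
#'   shifts generating regional structure.
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_samples = 251, n_sites = 12, seed = 1,
                             zero_inflation = 0.1, noise_sd = 1,
                             compositional_total = NULL,
                             species_logmean_sd = 1.5, site_effect_sd = 0.5) {
  if (n_samples < 4) stop("n_samples must be >= 4")
  if (n_sites < 1 || n_sites > n_samples) stop("invalid n_sites")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must lie in [0,1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.null(compositional_total) && compositional_total <= 0)
    stop("compositional_total must be positive")
  structure(list(n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
                 seed = as.integer(seed), zero_inflation = zero_inflation,
                 noise_sd = noise_sd, compositional_total = compositional_total,
                 species_logmean_sd = species_logmean_sd,
                 site_effect_sd = site_effect_sd),
            class = "generator_config")
}

# contiguous site blocks: sample i belongs to site ceil(i * n_sites / n)
.sample_sites <- function(config) {
  sites <- sprintf("site%02d", ceiling(seq_len(config$n_samples) *
                                         config$n_sites / config$n_samples))
  stats::setNames(sites, sprintf("S%04d", seq_len(config$n_samples)))
}

# Environmental matrix, deterministic in config$seed alone so that
# generate_community() and generate_environment() see the same factors.
.env_matrix <- function(config) {
  set.seed(config$seed + 777L)
  n <- config$n_samples
  site <- .sample_sites(config)
  site_idx <- as.integer(factor(site, levels = unique(site)))
  ns <- max(site_idx)
  # latitudinal temperature gradient across sites plus local noise
  temp_site <- seq(29, 15, length.out = ns)
  f <- cbind(
    temperature = temp_site[site_idx] + stats::rnorm(n, 0, 1.2),
    salinity = 31 + 0.15 * site_idx + stats::rnorm(n, 0, 0.8),
    pH = 8.1 + stats::rnorm(n, 0, 0.12),
    DO = 7.5 + stats::rnorm(n, 0, 0.9),
    NO3N = exp(stats::rnorm(n, log(0.25), 0.6)),
    NO2N = exp(stats::rnorm(n, log(0.02), 0.6)),
    NH4N = exp(stats::rnorm(n, log(0.05), 0.6)),
    COD = exp(stats::rnorm(n, log(1.5), 0.4)),
    Zn = exp(stats::rnorm(n, log(20), 0.5)),
    Pb = exp(stats::rnorm(n, log(1.5), 0.5)),
    As = exp(stats::rnorm(n, log(2), 0.5)),
    Cu = exp(stats::rnorm(n, log(3), 0.5)),
    Hg = exp(stats::rnorm(n, log(0.05), 0.5)))
  rownames(f) <- names(site)
  list(factors = f, site = site)
}

#' Generate synthetic plankton community density tables
#'
#' Species log-densities are latent log-normals: a per-species mean, a
#' per-site shift, loadings on shared latent factors for planted pairs,
#' loadings on environmental factors for coupled species, and residual
#' Gaussian noise. A planted pair with latent strength `s` has expected
#' log-scale Pearson correlation `s`; an environmental coupling with
#' coefficient `c` has expected log-scale correlation `c` with the factor.
#' Smaller-fraction zooplankton densities are shifted up by
#' `log(density_ratio)`. Zeros are injected by independent Bernoulli
#' thinning; optional closure rescales each sample to a fixed total.
#'
#' @param config [generator_config()]
#' @param truth [synthetic_truth()]
#' @return object of class `plankton_community`: list with abundance_table
#'   elements `phytoplankton`, `zoo_smaller`, `zoo_bigger`, plus `taxonomy`
#'   (data.frame), `truth`, and `config`.
#' @export
generate_community <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"), inherits(truth, "synthetic_truth"))
  nm <- species_names(truth$guild_sizes)
  all_unique <- c(nm$phytoplankton, nm$zoo_shared, nm$zoo_smaller_only,
                  nm$zoo_bigger_only)
  if (anyDuplicated(all_unique))
    stop("species names not disjoint across guilds")
  env <- .env_matrix(config)
  envz <- scale(env$factors)
  n <- config$n_samples
  set.seed(config$seed)

  sigma <- config$noise_sd
  # latent loadings giving target correlations on the log scale
  edge_load <- function(s) {
    s <- min(s, 0.995)
    sigma * sqrt(s / (1 - s))
  }
  env_load <- function(c0) {
    a <- min(abs(c0), 0.995)
    sign(c0) * sigma * a / sqrt(1 - a^2)
  }

  site_idx <- as.integer(factor(env$site, levels = unique(env$site)))
  ns <- max(site_idx)

  # per-species baselines are drawn once and shared across tables, so a
  # zooplankton species caught by both nets keeps its abundance level and
  # the smaller-fraction shift is exactly log(density_ratio)
  all_species <- c(nm$phytoplankton, nm$zoo_shared, nm$zoo_smaller_only,
                   nm$zoo_bigger_only)
  mu <- stats::setNames(
    stats::rnorm(length(all_species), 2, config$species_logmean_sd),
    all_species)
  site_eff <- matrix(stats::rnorm(ns * length(all_species), 0,
                                  config$site_effect_sd),
                     ns, length(all_species),
                     dimnames = list(NULL, all_species))

  gen_logmat <- function(species, mu_shift = 0) {
    p <- length(species)
    lx <- matrix(rep(mu[species] + mu_shift, each = n), n, p) +
      site_eff[site_idx, species, drop = FALSE] +
      matrix(stats::rnorm(n * p, 0, sigma), n, p)
    dimnames(lx) <- list(names(env$site), species)
    lx
  }

  # latent factors for planted pairs, one per edge
  pe <- truth$planted_edges
  latents <- if (nrow(pe) > 0)
    matrix(stats::rnorm(n * nrow(pe)), n, nrow(pe)) else NULL

  lp <- gen_logmat(nm$phytoplankton)
  lzs <- gen_logmat(c(nm$zoo_shared, nm$zoo_smaller_only),
                    mu_shift = log(truth$density_ratio))
  lzb <- gen_logmat(c(nm$zoo_shared, nm$zoo_bigger_only))

  add_latent <- function(lx, species, load) {
    if (species %in% colnames(lx)) lx[, species] <- lx[, species] + load
    lx
  }
  if (nrow(pe) > 0) {
    for (e in seq_len(nrow(pe))) {
      lam <- edge_load(pe$strength[e])
      la <- latents[, e] * lam
      frac <- pe$fraction[e]
      add_all <- function(sp, load) {
        lp <<- add_latent(lp, sp, load)
        if (frac %in% c("both", "smaller")) lzs <<- add_latent(lzs, sp, load)
        if (frac %in% c("both", "bigger")) lzb <<- add_latent(lzb, sp, load)
      }
      add_all(pe$species_a[e], la)
      if (pe$species_b[e] == pe$species_a[e]) next  # cross-fraction self-pair
      add_all(pe$species_b[e], la * pe$sign[e])
    }
  }
  ec <- truth$env_coupling
  if (nrow(ec) > 0) {
    unknown <- setdiff(ec$factor, colnames(envz))
    if (length(unknown) > 0)
      stop("unknown environmental factor in coupling: ",
           paste(unknown, collapse = ", "))
    for (e in seq_len(nrow(ec))) {
      la <- envz[, ec$factor[e]] * env_load(ec$coef[e])
      lp  <- add_latent(lp,  ec$species[e], la)
      lzs <- add_latent(lzs, ec$species[e], la)
      lzb <- add_latent(lzb, ec$species[e], la)
    }
  }

  finish <- function(lx) {
    x <- exp(lx)
    if (config$zero_inflation > 0) {
      drop <- matrix(stats::runif(length(x)) < config$zero_inflation,
                     nrow(x), ncol(x))
      x[drop] <- 0
    }
    if (!is.null(config$compositional_total)) {
      tot <- rowSums(x)
      tot[tot == 0] <- 1
      x <- x / tot * config$compositional_total
    }
    x
  }
  xp <- finish(lp); xzs <- finish(lzs); xzb <- finish(lzb)

  taxonomy <- data.frame(
    species = c(nm$phytoplankton, nm$zoo_shared, nm$zoo_smaller_only,
                nm$zoo_bigger_only),
    guild = c(rep("phytoplankton", length(nm$phytoplankton)),
              rep("zooplankton", length(nm$zoo_shared) +
                    length(nm$zoo_smaller_only) + length(nm$zoo_bigger_only))),
    size_fraction = c(rep(NA, length(nm$phytoplankton)),
                      rep("both", length(nm$zoo_shared)),
                      rep("smaller", length(nm$zoo_smaller_only)),
                      rep("bigger", length(nm$zoo_bigger_only))),
    taxon_group = NA_character_, stringsAsFactors = FALSE)
  # simple taxon-group assignment: alternating dominant groups per guild
  pg <- c("diatom", "dinoflagellate", "Ochrophyta")
  zg <- c("Arthropoda", "Chaetognatha", "Tunicata", "Gastropoda")
  taxonomy$taxon_group[taxonomy$guild == "phytoplankton"] <-
    pg[(seq_len(sum(taxonomy$guild == "phytoplankton")) - 1) %% length(pg) + 1]
  taxonomy$taxon_group[taxonomy$guild == "zooplankton"] <-
    zg[(seq_len(sum(taxonomy$guild == "zooplankton")) - 1) %% length(zg) + 1]

  guild <- stats::setNames(taxonomy$guild, taxonomy$species)
  tg <- stats::setNames(taxonomy$taxon_group, taxonomy$species)
  sf_small <- stats::setNames(rep("smaller", ncol(xzs)), colnames(xzs))
  sf_big <- stats::setNames(rep("bigger", ncol(xzb)), colnames(xzb))

  structure(list(
    phytoplankton = abundance_table(xp, guild = guild, taxon_group = tg,
                                    site = env$site),
    zoo_smaller = abundance_table(xzs, guild = guild, size_fraction = sf_small,
                                  taxon_group = tg, site = env$site),
    zoo_bigger = abundance_table(xzb, guild = guild, size_fraction = sf_big,
                                 taxon_group = tg, site = env$site),
    taxonomy = taxonomy, truth = truth, config = config),
    class = "plankton_community")
}

#' Generate the synthetic environment table
#'
#' Deterministic in `config$seed`; the same factor realizations are used
#' inside [generate_community()] for environmentally coupled species, so the
#' two outputs are mutually consistent.
#' @param config [generator_config()]
#' @param truth [synthetic_truth()] (checked for unknown factor names)
#' @return environment_table
#' @export
generate_environment <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"))
  env <- .env_matrix(config)
  if (nrow(truth$env_coupling) > 0) {
    unknown <- setdiff(truth$env_coupling$factor, colnames(env$factors))
    if (length(unknown) > 0)
      stop("unknown environmental factor in coupling: ",
           paste(unknown, collapse = ", "))
  }
  environment_table(env$factors, site = env$site)
}

#' Write a synthetic fixture to disk
#'
#' Writes the three abundance TSVs, taxonomy TSV, environment TSV and the
#' ground truth as JSON; returns a manifest of files with row/column counts.
#' @param community plankton_community from [generate_community()]
#' @param env environment_table from [generate_environment()]
#' @param directory output directory (created if needed)
#' @return manifest: data.frame with columns file, rows, cols
#' @export
write_fixture <- function(community, env, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  wt <- function(name, df) {
    path <- file.path(directory, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[name]] <<- c(rows = nrow(df), cols = ncol(df))
    path
  }
  for (tab in c("phytoplankton", "zoo_smaller", "zoo_bigger")) {
    at <- community[[tab]]
    wt(paste0(tab, ".tsv"),
       data.frame(sample = sample_ids(at), at$density, check.names = FALSE))
  }
  wt("taxonomy.tsv", community$taxonomy)
  wt("environment.tsv",
     data.frame(sample = rownames(env$factors), site = env$site,
                env$factors, check.names = FALSE))
  truth <- community$truth
  tr <- list(guild_sizes = as.list(truth$guild_sizes),
             planted_edges = truth$planted_edges,
             env_coupling = truth$env_coupling,
             density_ratio = truth$density_ratio)
  jsonlite::write_json(tr, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  files[["truth.json"]] <- c(rows = nrow(truth$planted_edges), cols = 4)
  manifest <- data.frame(file = names(files),
                         rows = vapply(files, `[`, numeric(1), 1),
                         cols = vapply(files, `[`, numeric(1), 2),
                         row.names = NULL)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Reload a truth JSON written by [write_fixture()]
#' @param path truth.json path
#' @return synthetic_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  pe <- as.data.frame(tr$planted_edges)
  if (nrow(pe) == 0)
    pe <- NULL
  ec <- as.data.frame(tr$env_coupling)
  if (nrow(ec) == 0)
    ec <- NULL
  synthetic_truth(guild_sizes = unlist(tr$guild_sizes),
                  planted_edges = pe, env_coupling = ec,
                  density_ratio = tr$density_ratio)
}
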