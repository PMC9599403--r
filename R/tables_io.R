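#' Construct an abundance table
#'
#' The central data container of the package: a samples-by-species density
#' matrix (ind/L) with per-species guild, size-fraction and taxon-group
#' annotations and per-sample site labels.
#'
#' @param density numeric matrix, samples in rows, species in columns.
#'   Row names are sample ids, column names species ids. All values must be
#'   nonnegative and finite.
#' @param guild named character vector mapping every species to
#'   `"phytoplankton"` or `"zooplankton"`.
#' @param size_fraction named character vector mapping zooplankton species to
#'   `"smaller"` or `"bigger"`. May be empty for pure phytoplankton tables.
#' @param taxon_group named character vector mapping species to a taxon-group
#'   label (e.g. `"diatom"`, `"Arthropoda"`). Unlisted species get `NA`.
#' @param site named character vector mapping sample ids to site labels.
#'   Unlisted samples get `"site1"`.
#' @return An object of class `abundance_table`: a list with elements
#'   `density`, `guild`, `size_fraction`, `taxon_group`, `site`.
#' @export
abundance_table <- function(density, guild, size_fraction = character(),
                            taxon_group = character(), site = character()) {
  density <- as.matrix(density)
  if (is.null(rownames(density)))
    rownames(density) <- paste0("sample", seq_len(nrow(density)))
  if (is.null(colnames(density)))
    stop("density matrix must have species column names")
  if (anyDuplicated(rownames(density)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(density)))
    stop("duplicate species ids")
  bad <- which(!is.finite(density) | density < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative or non-finite density at sample '%s', species '%s'",
                 rownames(density)[bad[1, 1]], colnames(density)[bad[1, 2]]))
  }
  sp <- colnames(density)
  missing_guild <- setdiff(sp, names(guild))
  if (length(missing_guild) > 0)
    stop("species without guild annotation: ",
         paste(missing_guild, collapse = ", "))
  guild <- guild[sp]
  if (!all(guild %in% c("phytoplankton", "zooplankton")))
    stop("guild must be 'phytoplankton' or 'zooplankton'")
  zoo <- sp[guild == "zooplankton"]
  missing_frac <- setdiff(zoo, names(size_fraction))
  if (length(missing_frac) > 0)
    stop("zooplankton species without size fraction: ",
         paste(missing_frac, collapse = ", "))
  tg <- rep(NA_character_, length(sp))
  names(tg) <- sp
  tg[intersect(sp, names(taxon_group))] <-
    taxon_group[intersect(sp, names(taxon_group))]
  st <- rep("site1", nrow(density))
  names(st) <- rownames(density)
  st[intersect(rownames(density), names(site))] <-
    site[intersect(rownames(density), names(site))]
  structure(list(density = density, guild = guild,
                 size_fraction = size_fraction[intersect(zoo, names(size_fraction))],
                 taxon_group = tg, site = st),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d species (%d phyto, %d zoo), %d sites\n",
              nrow(x$density), ncol(x$density),
              sum(x$guild == "phytoplankton"), sum(x$guild == "zooplankton"),
              length(unique(x$site))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$density)

sample_ids <- function(x) rownames(x$density)
species_ids <- function(x) colnames(x$density)

#' Restrict an abundance table to a subset of species and/or samples
#' @param x abundance_table
#' @param species,samples character vectors of ids to keep (default all)
#' @return abundance_table
#' @export
subset_abundance <- function(x, species = species_ids(x), samples = sample_ids(x)) {
  abundance_table(x$density[samples, species, drop = FALSE],
                  guild = x$guild, size_fraction = x$size_fraction,
                  taxon_group = x$taxon_group[!is.na(x$taxon_group)],
                  site = x$site)
}

#' Construct an environment table
#'
#' @param factors numeric matrix, samples in rows, environmental factors in
#'   columns (temperature, salinity, pH, DO, NO3N, NO2N, NH4N, COD, Zn, Pb,
#'   As, Cu, Hg or a subset).
#' @param site optional named character vector of site labels per sample.
#' @param factor_groups named character vector mapping factor names to the
#'   groups `"water"`, `"N"` or `"metal"`; defaults to the standard grouping
#'   via [default_factor_groups()].
#' @return object of class `environment_table`.
#' @export
environment_table <- function(factors, site = character(), factor_groups = NULL) {
  factors <- as.matrix(factors)
  if (is.null(rownames(factors)))
    rownames(factors) <- paste0("sample", seq_len(nrow(factors)))
  if (is.null(colnames(factors))) stop("factors must have column names")
  if (is.null(factor_groups)) {
    fg <- default_factor_groups()
    factor_groups <- fg[intersect(colnames(factors), names(fg))]
  }
  st <- rep("site1", nrow(factors))
  names(st) <- rownames(factors)
  st[intersect(rownames(factors), names(site))] <-
    site[intersect(rownames(factors), names(site))]
  structure(list(factors = factors, site = st, factor_groups = factor_groups),
            class = "environment_table")
}

#' Default environmental factor grouping
#'
#' Water traits, nitrogen species, and dissolved heavy metals.
#' @return named character vector factor -> group
#' @export
default_factor_groups <- function() {
  c(temperature = "water", salinity = "water", pH = "water", DO = "water",
    COD = "water",
    NO3N = "N", NO2N = "N", NH4N = "N",
    Zn = "metal", Pb = "metal", As = "metal", Cu = "metal", Hg = "metal")
}

#' Resolve a Mantel factor-group name to factor columns
#'
#' The factor groups used for connectivity-significance Mantel tests:
#' `temperature`, `salinity` and `pH` are single factors; `N` covers the
#' three nitrogen species; `metal` covers Zn, Pb, As, Cu and Hg.
#' @param group one of `"temperature"`, `"salinity"`, `"pH"`, `"N"`, `"metal"`.
#' @param env environment_table (used to check availability).
#' @return character vector of factor column names
#' @export
mantel_factor_columns <- function(group, env) {
  cols <- switch(group,
    temperature = "temperature",
    salinity    = "salinity",
    pH          = "pH",
    N           = c("NO3N", "NO2N", "NH4N"),
    metal       = c("Zn", "Pb", "As", "Cu", "Hg"),
    stop("unknown factor group '", group,
         "'; must be one of temperature, salinity, pH, N, metal"))
  missing <- setdiff(cols, colnames(env$factors))
  if (length(missing) > 0)
    stop("environment table lacks factor(s): ", paste(missing, collapse = ", "))
  cols
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an abundance table with its taxonomy
#'
#' Expects a delimited file (tab or comma, auto-detected) with a header of
#' species names and a first column of sample ids, plus a taxonomy file with
#' columns `species`, `guild`, `size_fraction`, `taxon_group` and optionally
#' a site file embedded as a `site` column keyed by sample in the taxonomy
#' directory. Species missing from the taxonomy raise an error listing the
#' offenders.
#'
#' @param path abundance file path.
#' @param taxonomy_path taxonomy file path.
#' @param site optional named character vector of per-sample site labels.
#' @return abundance_table
#' @export
read_abundance_table <- function(path, taxonomy_path, site = character()) {
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df[[1]])
  tax <- utils::read.table(taxonomy_path, header = TRUE,
                           sep = .detect_sep(taxonomy_path),
                           stringsAsFactors = FALSE)
  need <- c("species", "guild")
  if (!all(need %in% names(tax)))
    stop("taxonomy file must have columns: species, guild")
  sp <- .normalize_species(colnames(mat))
  colnames(mat) <- sp
  tax$species <- .normalize_species(tax$species)
  missing <- setdiff(sp, tax$species)
  if (length(missing) > 0)
    stop("species absent from taxonomy: ", paste(missing, collapse = ", "))
  guild <- stats::setNames(tax$guild, tax$species)
  sf <- if ("size_fraction" %in% names(tax)) {
    keep <- !is.na(tax$size_fraction) & tax$size_fraction != ""
    stats::setNames(tax$size_fraction[keep], tax$species[keep])
  } else character()
  tg <- if ("taxon_group" %in% names(tax)) {
    stats::setNames(tax$taxon_group, tax$species)
  } else character()
  abundance_table(mat, guild = guild, size_fraction = sf, taxon_group = tg,
                  site = site)
}

#' Read an environment table
#' @param path delimited file, first column sample id; remaining columns
#'   numeric factors, optional `site` column of site labels.
#' @return environment_table
#' @export
read_environment_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  site <- character()
  if ("site" %in% names(df)) {
    site <- stats::setNames(as.character(df$site), rn)
    df$site <- NULL
  }
  mat <- as.matrix(df)
  storage.mode(mat) <- "double"
  rownames(mat) <- rn
  env <- environment_table(mat, site = site)
  impute_environment(env)
}

#' Impute missing environmental values by per-site median
#'
#' Remaining NAs (a whole site missing a factor) fall back to the global
#' median of the factor.
#' @param env environment_table
#' @return environment_table without missing values
#' @export
impute_environment <- function(env) {
  f <- env$factors
  for (j in seq_len(ncol(f))) {
    if (!anyNA(f[, j])) next
    for (s in unique(env$site)) {
      idx <- env$site == s
      nas <- idx & is.na(f[, j])
      if (any(nas))
        f[nas, j] <- stats::median(f[idx, j], na.rm = TRUE)
    }
    f[is.na(f[, j]), j] <- stats::median(f[, j], na.rm = TRUE)
  }
  env$factors <- f
  env
}

# exact matching after trimming and case-folding; taxonomic resolution is
# out of scope
.normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  tolower(x)
}

#' Intersect zooplankton inventories of two size fractions
#'
#' Before any network analysis the two zooplankton fraction tables are
#' restricted to the species caught in both nets, removing fraction-exclusive
#' species so that community-composition differences do not drive the
#' comparison of networks.
#'
#' @param smaller,bigger abundance_table objects for the smaller and bigger
#'   zooplankton size fractions.
#' @return list with elements `smaller` and `bigger` (tables restricted to
#'   the shared species, original sample sets) and `report`: counts
#'   `n_smaller`, `n_bigger`, `only_smaller`, `only_bigger`, `shared`.
#' @export
intersect_size_fractions <- function(smaller, bigger) {
  sp_s <- .normalize_species(species_ids(smaller))
  sp_b <- .normalize_species(species_ids(bigger))
  shared <- intersect(sp_s, sp_b)
  if (length(shared) == 0)
    stop("empty intersection: the two size fractions share no species; ",
         "cross-fraction networks are impossible")
  report <- list(n_smaller = length(sp_s), n_bigger = length(sp_b),
                 only_smaller = length(setdiff(sp_s, sp_b)),
                 only_bigger = length(setdiff(sp_b, sp_s)),
                 shared = length(shared))
  keep_s <- species_ids(smaller)[sp_s %in% shared]
  keep_b <- species_ids(bigger)[sp_b %in% shared]
  list(smaller = subset_abundance(smaller, species = keep_s),
       bigger = subset_abundance(bigger, species = keep_b),
       report = report)
}

#' Align an abundance table and an environment table on shared samples
#'
#' @param abundance abundance_table
#' @param env environment_table
#' @return list `abundance`, `env` restricted to the shared samples in
#'   identical order, and `dropped`: count of samples dropped from either.
#' @export
align_samples <- function(abundance, env) {
  shared <- intersect(sample_ids(abundance), rownames(env$factors))
  if (length(shared) < 4)
    stop("fewer than 4 shared samples between abundance and environment tables")
  dropped <- (nrow(abundance$density) - length(shared)) +
    (nrow(env$factors) - length(shared))
  env2 <- environment_table(env$factors[shared, , drop = FALSE],
                            site = env$site, factor_groups = env$factor_groups)
  list(abundance = subset_abundance(abundance, samples = shared),
       env = env2, dropped = dropped)
}

#' Write an abundance table (densities only) as TSV
#' @param x abundance_table
#' @param path output path
#' @return path, invisibly
#' @export
write_abundance_table <- function(x, path) {
  df <- data.frame(sample = sample_ids(x), x$density, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
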