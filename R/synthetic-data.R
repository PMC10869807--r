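#' Configuration for the synthetic study generator
#'
#' Defaults describe the simulated study conditions used throughout the test
#' suite: 100 species over 3 realms x 2 countries x 8 basins, a pure-birth
#' ultrametric tree, Brownian-motion habitat traits filtered by basin
#' environments, and establishment driven by nonnative-native relatedness
#' (beta_mpd on the z-scale) plus native richness and Gaussian random
#' intercepts for species, country, and basin.
#'
#' @param n_species number of tips / species.
#' @param n_realms,countries_per_realm,basins_per_country geography sizes.
#' @param birth_rate,death_rate birth-death rates for the tree.
#' @param sigma2_bm Brownian-motion rate of the habitat trait.
#' @param tau environmental-filter width, in units of the realized trait SD.
#' @param baseline_occupancy maximal probability a species is native to a
#'   basin (attained when its trait matches the basin environment).
#' @param beta0 establishment intercept on the link scale.
#' @param beta_mpd coefficient of z-scored relatedness (MPD by default).
#' @param beta_richness coefficient of z-scored native richness.
#' @param sd_species,sd_country,sd_basin random-intercept SDs.
#' @param intro_rate fraction of (species, country) pairs proposed for
#'   introduction.
#' @param driver `"mpd"` or `"mntd"`: which relatedness metric drives
#'   establishment.
#' @param seed integer seed; stage streams (tree / traits / assembly /
#'   establishment) are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 100, n_realms = 3, countries_per_realm = 2,
                       basins_per_country = 8, birth_rate = 1, death_rate = 0,
                       sigma2_bm = 1, tau = 1.5, baseline_occupancy = 0.35,
                       beta0 = -1.0, beta_mpd = -0.5, beta_richness = 0.2,
                       sd_species = 0.5, sd_country = 0.3, sd_basin = 0.3,
                       intro_rate = 0.5, driver = c("mpd", "mntd"), seed = 1) {
  driver <- match.arg(driver)
  stopifnot(n_species >= 2, n_realms >= 1, countries_per_realm >= 1,
            basins_per_country >= 1, birth_rate > 0, death_rate >= 0,
            sigma2_bm > 0, tau > 0,
            baseline_occupancy > 0, baseline_occupancy <= 1,
            sd_species >= 0, sd_country >= 0, sd_basin >= 0,
            intro_rate >= 0, intro_rate <= 1)
  if (n_realms > length(VALID_REALMS))
    stop("at most ", length(VALID_REALMS), " realms")
  structure(as.list(environment()), class = "sim_config")
}

# derive a per-stage seed, keeping well inside 32-bit range
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 101L + stage
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' @param n_species number of extant tips.
#' @param birth_rate,death_rate per-lineage rates (death < birth).
#' @param seed integer seed.
#' @return an `ape::phylo` with tips `sp_001`, `sp_002`, ...
#' @export
simulate_tree <- function(n_species, birth_rate = 1, death_rate = 0,
                          seed = 1) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (death_rate >= birth_rate)
    stop("death_rate must be less than birth_rate")
  set.seed(stage_seed(seed, 1L))
  tree <- ape::rphylo(n_species, birth = birth_rate, death = death_rate,
                      fossils = FALSE)
  tree$tip.label <- sprintf("sp_%03d", seq_len(n_species))
  tree
}

#' Simulate an occurrence database with known establishment truth
#'
#' Generates the full synthetic study: (1) a birth-death tree; (2) a 1-D
#' habitat trait evolving by Brownian motion; (3) native assembly — each
#' basin draws an environment around its country's optimum and species become
#' native with probability `baseline_occupancy * exp(-(trait - env)^2 /
#' (2 tau_eff^2))` (Gaussian environmental filter, `tau_eff` scaled by the
#' realized trait SD); (4) introduction proposals for a fraction of (species,
#' country) pairs — translocated when the species is native somewhere in the
#' country (candidate basins exclude its native basins), exotic otherwise
#' (all basins); (5) establishment of each proposed (species, basin) by a
#' Bernoulli draw on the logit scale with the programmed coefficients and
#' random intercepts, where the relatedness driver is z-scored over the
#' proposal set (the record-builder convention, so `beta_mpd` is recoverable
#' on the same scale). Successes become non-native occurrence records.
#'
#' @param config a [sim_config()].
#' @return list with `db` (an [occurrence_db()]), `tree`, and `truth` (the
#'   config, realized random intercepts, and the proposal table with true
#'   establishment probabilities).
#' @export
simulate_database <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tree <- simulate_tree(cfg$n_species, cfg$birth_rate, cfg$death_rate,
                        cfg$seed)
  species <- tree$tip.label

  set.seed(stage_seed(cfg$seed, 2L))
  traits <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(cfg$sigma2_bm))

  # geography: realms > countries > basins, with lognormal areas (km^2)
  set.seed(stage_seed(cfg$seed, 3L))
  realms <- VALID_REALMS[seq_len(cfg$n_realms)]
  n_countries <- cfg$n_realms * cfg$countries_per_realm
  countries <- sprintf("country_%02d", seq_len(n_countries))
  country_realm <- rep(realms, each = cfg$countries_per_realm)
  n_basins <- n_countries * cfg$basins_per_country
  basins <- data.frame(
    basin_id = sprintf("basin_%03d", seq_len(n_basins)),
    country = rep(countries, each = cfg$basins_per_country),
    realm = rep(country_realm, each = cfg$basins_per_country),
    area_km2 = stats::rlnorm(n_basins, meanlog = 8, sdlog = 1.5),
    lat = stats::runif(n_basins, -60, 70),
    lon = stats::runif(n_basins, -180, 180),
    stringsAsFactors = FALSE)

  trait_sd <- stats::sd(traits)
  country_opt <- stats::rnorm(n_countries, 0, trait_sd)
  names(country_opt) <- countries
  basin_env <- country_opt[basins$country] +
    stats::rnorm(n_basins, 0, 0.3 * trait_sd)
  tau_eff <- cfg$tau * trait_sd
  p_native <- cfg$baseline_occupancy *
    exp(-outer(traits, basin_env, "-")^2 / (2 * tau_eff^2))
  native <- matrix(stats::runif(length(p_native)) < p_native,
                   nrow = cfg$n_species,
                   dimnames = list(species, basins$basin_id))
  nat_idx <- which(native, arr.ind = TRUE)
  if (nrow(nat_idx) == 0) stop("configuration produced zero native records")
  native_records <- data.frame(species = species[nat_idx[, 1]],
                               basin_id = basins$basin_id[nat_idx[, 2]],
                               status = "native", stringsAsFactors = FALSE)

  # introduction proposals and establishment
  set.seed(stage_seed(cfg$seed, 4L))
  D <- cophenetic_distances(tree)
  natives_by_basin <- split(native_records$species, native_records$basin_id)
  native_countries <- lapply(species, function(s)
    unique(basins$country[basins$basin_id %in%
                            native_records$basin_id[native_records$species == s]]))
  names(native_countries) <- species

  pairs <- expand.grid(species = species, country = countries,
                       stringsAsFactors = FALSE)
  proposed <- pairs[stats::runif(nrow(pairs)) < cfg$intro_rate, , drop = FALSE]
  prop_rows <- list()
  for (i in seq_len(nrow(proposed))) {
    s <- proposed$species[i]; co <- proposed$country[i]
    translocated <- co %in% native_countries[[s]]
    cand <- basins$basin_id[basins$country == co]
    if (translocated)
      cand <- setdiff(cand,
                      native_records$basin_id[native_records$species == s])
    if (length(cand) == 0) next
    for (b in cand) {
      nat <- setdiff(natives_by_basin[[b]] %||% character(0), s)
      if (length(nat) == 0) next
      d <- D[s, nat]
      prop_rows[[length(prop_rows) + 1L]] <- data.frame(
        species = s, country = co, basin_id = b,
        type = if (translocated) "translocated" else "exotic",
        mpd = mean(d), mntd = min(d), native_richness = length(nat),
        stringsAsFactors = FALSE)
    }
  }
  prop <- do.call(rbind, prop_rows)
  u_species <- stats::rnorm(cfg$n_species, 0, cfg$sd_species)
  names(u_species) <- species
  u_country <- stats::rnorm(n_countries, 0, cfg$sd_country)
  names(u_country) <- countries
  u_basin <- stats::rnorm(n_basins, 0, cfg$sd_basin)
  names(u_basin) <- basins$basin_id
  if (is.null(prop) || nrow(prop) == 0) {
    # no proposals (e.g. intro_rate = 0): a fully native world is legal
    prop <- data.frame(species = character(0), country = character(0),
                       basin_id = character(0), type = character(0),
                       mpd = numeric(0), mntd = numeric(0),
                       native_richness = integer(0), driver_z = numeric(0),
                       richness_z = numeric(0), p_true = numeric(0),
                       established = integer(0), stringsAsFactors = FALSE)
    nonnative_records <- native_records[0, , drop = FALSE]
  } else {
    z <- function(x) (x - mean(x)) / stats::sd(x)
    prop$driver_z <- z(prop[[cfg$driver]])
    prop$richness_z <- z(prop$native_richness)
    eta <- cfg$beta0 + cfg$beta_mpd * prop$driver_z +
      cfg$beta_richness * prop$richness_z +
      u_species[prop$species] + u_country[prop$country] +
      u_basin[prop$basin_id]
    prop$p_true <- stats::plogis(eta)
    prop$established <- as.integer(stats::runif(nrow(prop)) < prop$p_true)
    est <- prop[prop$established == 1, , drop = FALSE]
    nonnative_records <- data.frame(species = est$species,
                                    basin_id = est$basin_id,
                                    status = "nonnative",
                                    stringsAsFactors = FALSE)
  }
  db <- occurrence_db(rbind(native_records, nonnative_records), basins)

  list(db = db, tree = tree,
       truth = list(config = cfg, traits = traits, basin_env = basin_env,
                    u_species = u_species, u_country = u_country,
                    u_basin = u_basin, proposals = prop))
}

#' Write a hand-auditable fixture bundle
#'
#' A small registry of fixed datasets used across the test suite:
#' \describe{
#'   \item{tiny}{3 species on the worked tree `((A:1,B:1):1,C:2);`, 2 basins.}
#'   \item{toy-country}{one country, 3 basins, 1 exotic + 1 translocated
#'     species (modeling record counts 3 and 2).}
#'   \item{realm-scope}{two countries in one realm plus one in another, so a
#'     species exotic at country scope is translocated at realm scope.}
#'   \item{single-native-basin}{a basin with exactly one native, exercising
#'     undefined native MPD/MNTD handling.}
#' }
#'
#' @param name registry key.
#' @param dir output directory (created if needed).
#' @return named list of file paths (`occurrences`, `basins`, `tree`).
#' @export
make_fixture <- function(name, dir = tempfile("fixture")) {
  registry <- c("tiny", "toy-country", "realm-scope", "single-native-basin")
  if (!name %in% registry)
    stop("unknown fixture '", name, "'; registry: ",
         paste(registry, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bs <- function(id, country, realm, area = 100)
    data.frame(basin_id = id, country = country, realm = realm,
               area_km2 = area, lat = 0, lon = 0, stringsAsFactors = FALSE)
  oc <- function(sp, b, st)
    data.frame(species = sp, basin_id = b, status = st,
               stringsAsFactors = FALSE)
  if (name == "tiny") {
    tree <- "((A:1,B:1):1,C:2);"
    basins <- rbind(bs("b1", "X", "Palearctic"), bs("b2", "X", "Palearctic"))
    occ <- rbind(oc("B", "b1", "native"), oc("C", "b1", "native"),
                 oc("A", "b1", "nonnative"), oc("A", "b2", "native"))
  } else if (name == "toy-country") {
    # exotic E present in b1 only; translocated T native in b1, nonnative b2
    tree <- "(((A:1,B:1):1,(E:1,T:1):1):1,C:3);"
    basins <- rbind(bs("b1", "X", "Palearctic", 50),
                    bs("b2", "X", "Palearctic", 150),
                    bs("b3", "X", "Palearctic", 400))
    occ <- rbind(oc("A", "b1", "native"), oc("T", "b1", "native"),
                 oc("B", "b2", "native"), oc("C", "b2", "native"),
                 oc("A", "b3", "native"), oc("C", "b3", "native"),
                 oc("E", "b1", "nonnative"), oc("T", "b2", "nonnative"))
  } else if (name == "realm-scope") {
    # S native in country Y, nonnative in country X; X,Y share a realm, Z not
    tree <- "((S:1,A:1):1,(B:1.5,C:1.5):0.5);"
    basins <- rbind(bs("b1", "X", "Palearctic"), bs("b2", "Y", "Palearctic"),
                    bs("b3", "Z", "Nearctic"))
    occ <- rbind(oc("S", "b2", "native"), oc("A", "b1", "native"),
                 oc("B", "b1", "native"), oc("B", "b3", "native"),
                 oc("C", "b3", "native"),
                 oc("S", "b1", "nonnative"), oc("S", "b3", "nonnative"))
  } else { # single-native-basin
    tree <- "((A:1,B:1):1,(C:1,E:1):1);"
    basins <- rbind(bs("b1", "X", "Palearctic"), bs("b2", "X", "Palearctic"))
    occ <- rbind(oc("A", "b1", "native"), oc("B", "b1", "native"),
                 oc("C", "b2", "native"),  # b2: exactly one native
                 oc("E", "b1", "nonnative"), oc("E", "b2", "nonnative"))
  }
  paths <- list(occurrences = file.path(dir, "occurrences.csv"),
                basins = file.path(dir, "basins.csv"),
                tree = file.path(dir, "tree.nwk"))
  utils::write.csv(occ, paths$occurrences, row.names = FALSE, quote = FALSE)
  utils::write.csv(basins, paths$basins, row.names = FALSE, quote = FALSE)
  writeLines(tree, paths$tree)
  paths
}
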