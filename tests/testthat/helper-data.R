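# Shared builders for in-code fixtures and independent simulation oracles.

basin_row <- function(id, country, realm, area = 100) {
  data.frame(basin_id = id, country = country, realm = realm,
             area_km2 = area, lat = 0, lon = 0, stringsAsFactors = FALSE)
}

occ_row <- function(species, basin, status) {
  data.frame(species = species, basin_id = basin, status = status,
             stringsAsFactors = FALSE)
}

# the worked 3-tip tree used in hand-derived examples
worked_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# Direct simulation from the Bernoulli mixed model (independent of
# simulate_database): a species x basin grid with a standard-normal
# relatedness covariate and Gaussian random intercepts.
sim_glmm_direct <- function(n_sp, n_ba, n_co, beta0, beta1,
                            sds = c(0.5, 0.3, 0.3), seed = 1) {
  set.seed(seed)
  sp <- sprintf("s%03d", seq_len(n_sp))
  ba <- sprintf("b%03d", seq_len(n_ba))
  co <- stats::setNames(rep(sprintf("c%02d", seq_len(n_co)),
                            length.out = n_ba), ba)
  g <- expand.grid(species = sp, basin_id = ba, stringsAsFactors = FALSE)
  g$country <- unname(co[g$basin_id])
  g$mpd_z <- stats::rnorm(nrow(g))
  us <- stats::setNames(stats::rnorm(n_sp, 0, sds[1]), sp)
  uc <- stats::setNames(stats::rnorm(n_co, 0, sds[2]), unique(co))
  ub <- stats::setNames(stats::rnorm(n_ba, 0, sds[3]), ba)
  eta <- beta0 + beta1 * g$mpd_z + us[g$species] + uc[g$country] +
    ub[g$basin_id]
  g$presence <- stats::rbinom(nrow(g), 1, stats::plogis(eta))
  g
}

# Direct simulation of the mediation structure: basin-level richness and
# diversity, relatedness = a_rich*rich + a_div*div + noise, presence from the
# latent logit with the relatedness, direct paths and REs. Covariates and the
# noise are constructed with exactly unit row-level sample SD and exact
# orthogonality, so the programmed paths are exactly the z-scale estimands
# that fit_sem recovers (its per-fit z-scoring divides by 1).
sim_sem_direct <- function(n_sp, n_ba, n_co, a_rich, a_div, b_rel,
                           d_rich = 0, d_div = 0, beta0 = -0.5,
                           sds = c(0.4, 0.2, 0.2), seed = 1) {
  set.seed(seed)
  sp <- sprintf("s%03d", seq_len(n_sp))
  ba <- sprintf("b%03d", seq_len(n_ba))
  co <- stats::setNames(rep(sprintf("c%02d", seq_len(n_co)),
                            length.out = n_ba), ba)
  g <- expand.grid(species = sp, basin_id = ba, stringsAsFactors = FALSE)
  g$country <- unname(co[g$basin_id])
  unit <- function(x) (x - mean(x)) / stats::sd(x)
  rich <- stats::setNames(stats::rnorm(n_ba), ba)
  div <- stats::setNames(stats::rnorm(n_ba), ba)
  g$native_richness <- unit(unname(rich[g$basin_id]))
  # orthogonalize diversity against richness at row level, unit SD
  g$native_mpd <- unit(stats::residuals(
    stats::lm(unname(div[g$basin_id]) ~ g$native_richness)))
  g$native_mntd <- g$native_mpd
  s_res <- sqrt(max(1 - a_rich^2 - a_div^2, 0.1))
  e <- unit(stats::residuals(stats::lm(
    stats::rnorm(nrow(g)) ~ g$native_richness + g$native_mpd))) * s_res
  g$mpd <- a_rich * g$native_richness + a_div * g$native_mpd + e
  g$mntd <- g$mpd
  us <- stats::setNames(stats::rnorm(n_sp, 0, sds[1]), sp)
  uc <- stats::setNames(stats::rnorm(n_co, 0, sds[2]), unique(co))
  ub <- stats::setNames(stats::rnorm(n_ba, 0, sds[3]), ba)
  eta <- beta0 + b_rel * g$mpd + d_rich * g$native_richness +
    d_div * g$native_mpd + us[g$species] + uc[g$country] + ub[g$basin_id]
  g$presence <- stats::rbinom(nrow(g), 1, stats::plogis(eta))
  g
}

# Brute-force oracle for the number of modeling records: a plain triple loop
# over (species, unit, basin) re-deriving labels and candidate sets from the
# raw tables, independent of classify_nonnatives/build_records internals.
oracle_record_count <- function(db, scope, group) {
  rec <- db$records
  unit_of <- stats::setNames(db$basins[[scope]], db$basins$basin_id)
  n <- 0L
  for (s in unique(rec$species)) {
    nat_b <- rec$basin_id[rec$species == s & rec$status == "native"]
    nn_b <- rec$basin_id[rec$species == s & rec$status == "nonnative"]
    for (u in unique(unname(unit_of[nn_b]))) {
      translocated <- any(unname(unit_of[nat_b]) == u)
      if ((group == "translocated") != translocated) next
      for (b in db$basins$basin_id[db$basins[[scope]] == u]) {
        if (translocated && b %in% nat_b) next
        natives <- setdiff(
          rec$species[rec$basin_id == b & rec$status == "native"], s)
        if (length(natives) >= 1) n <- n + 1L
      }
    }
  }
  n
}
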