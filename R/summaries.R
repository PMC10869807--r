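# half-up rounding to 2 decimals, matching conventional percentage reporting
round_pct <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Per-realm colonization percentages
#'
#' For every biogeographical realm: the percentage of its river basins
#' containing at least one non-native, at least one exotic, and at least one
#' translocated record. Denominators are all basins of the realm in the
#' supplied (uncleaned) database.
#'
#' @param db an [occurrence_db()].
#' @param assignment a `status_assignment` from [classify_nonnatives()].
#' @return data.frame: realm, n_basins, and count/percentage columns for
#'   nonnative, exotic, translocated.
#' @export
realm_colonization <- function(db, assignment) {
  stopifnot(inherits(db, "occurrence_db"),
            inherits(assignment, "status_assignment"))
  lab <- assignment$labels
  realm_of <- basin_realm(db)
  basins_with <- function(lbls)
    unique(lab$basin_id[lab$label %in% lbls])
  tab <- function(ids) table(factor(unname(realm_of[ids]),
                                    levels = sort(unique(db$basins$realm))))
  n_basins <- tab(db$basins$basin_id)
  res <- data.frame(realm = names(n_basins),
                    n_basins = as.integer(n_basins),
                    stringsAsFactors = FALSE)
  for (set in list(c(nonnative = list(c("exotic", "translocated"))),
                   list(exotic = "exotic"),
                   list(translocated = "translocated"))) {
    nm <- names(set)
    cnt <- tab(basins_with(set[[1]]))
    res[[paste0("n_", nm)]] <- as.integer(cnt)
    res[[paste0("pct_", nm)]] <- round_pct(100 * as.integer(cnt) /
                                             res$n_basins)
  }
  res
}

#' Per-basin non-native richness and percentage
#'
#' Exotic and translocated species richness per basin, each also as a
#' percentage of the basin's total species richness (natives + non-natives).
#' Basins with zero recorded species get `NA` percentages and are flagged.
#'
#' @inheritParams realm_colonization
#' @return data.frame keyed by basin_id.
#' @export
basin_summary <- function(db, assignment) {
  stopifnot(inherits(db, "occurrence_db"),
            inherits(assignment, "status_assignment"))
  lab <- assignment$labels
  ids <- db$basins$basin_id
  cnt <- function(lbl) {
    t <- table(factor(lab$basin_id[lab$label == lbl], levels = ids))
    as.integer(t)
  }
  total <- as.integer(table(factor(lab$basin_id, levels = ids)))
  res <- data.frame(basin_id = ids, total_richness = total,
                    exotic_richness = cnt("exotic"),
                    translocated_richness = cnt("translocated"),
                    stringsAsFactors = FALSE)
  res$pct_exotic <- ifelse(total == 0, NA_real_,
                           round_pct(100 * res$exotic_richness / total))
  res$pct_translocated <- ifelse(total == 0, NA_real_,
                                 round_pct(100 * res$translocated_richness /
                                             total))
  res$flag_empty <- total == 0
  res
}

#' Per-country non-native species tallies
#'
#' Distinct non-native species per country, plus exotic and translocated
#' species counts as percentages of all species recorded in the country.
#'
#' @inheritParams realm_colonization
#' @return data.frame sorted by descending non-native species count.
#' @export
country_summary <- function(db, assignment) {
  stopifnot(inherits(db, "occurrence_db"),
            inherits(assignment, "status_assignment"))
  if (assignment$scope != "country")
    stop("country_summary requires a country-scope assignment")
  lab <- assignment$labels
  lab$country <- unname(basin_country(db)[lab$basin_id])
  per <- function(d) length(unique(d))
  countries <- sort(unique(db$basins$country))
  res <- do.call(rbind, lapply(countries, function(co) {
    l <- lab[lab$country == co, , drop = FALSE]
    n_all <- per(l$species)
    n_nn <- per(l$species[l$label != "native"])
    n_ex <- per(l$species[l$label == "exotic"])
    n_tr <- per(l$species[l$label == "translocated"])
    data.frame(country = co, n_species = n_all, n_nonnative = n_nn,
               n_exotic = n_ex, n_translocated = n_tr,
               pct_exotic = if (n_all) round_pct(100 * n_ex / n_all) else NA_real_,
               pct_translocated = if (n_all) round_pct(100 * n_tr / n_all)
                                  else NA_real_,
               stringsAsFactors = FALSE)
  }))
  res[order(-res$n_nonnative, res$country), , drop = FALSE]
}

#' Spread of non-native species across countries and basins
#'
#' For every species with at least one non-native record: the number of
#' countries and basins where it has established, sorted descending (the
#' "most widespread invaders" table).
#'
#' @param db an [occurrence_db()].
#' @return data.frame: species, n_countries, n_basins.
#' @export
species_spread <- function(db) {
  stopifnot(inherits(db, "occurrence_db"))
  rec <- db$records[db$records$status == "nonnative", , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(species = character(0), n_countries = integer(0),
                      n_basins = integer(0), stringsAsFactors = FALSE))
  rec$country <- unname(basin_country(db)[rec$basin_id])
  sp <- split(rec, rec$species)
  res <- data.frame(species = names(sp),
                    n_countries = vapply(sp, function(d)
                      length(unique(d$country)), integer(1)),
                    n_basins = vapply(sp, function(d)
                      length(unique(d$basin_id)), integer(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(-res$n_basins, -res$n_countries, res$species), , drop = FALSE]
}
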