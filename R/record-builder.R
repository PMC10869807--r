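#' Apply the modeling-stage cleaning rules
#'
#' Two rules precede record construction: (1) administrative units (countries
#' or realms, matching the assignment scope) with no non-native record are
#' removed wholesale — relatedness of non-natives to natives cannot be
#' evaluated there; (2) species absent from the phylogeny are removed, since
#' their pairwise distances are unavailable.
#'
#' @param db an [occurrence_db()].
#' @param assignment a `status_assignment` computed on `db`.
#' @param tree an `ape::phylo` covering the species pool.
#' @return list with `db` (cleaned `occurrence_db`) and `report` (counts of
#'   units/basins/species/records dropped at each step).
#' @export
clean_database <- function(db, assignment, tree) {
  stopifnot(inherits(db, "occurrence_db"),
            inherits(assignment, "status_assignment"))
  tree <- validate_phylogeny(tree)
  unit_of <- basin_unit(db, assignment$scope)

  rec <- db$records
  nn_units <- unique(unname(unit_of[rec$basin_id[rec$status == "nonnative"]]))
  all_units <- unique(db$basins[[assignment$scope]])
  drop_units <- setdiff(all_units, nn_units)

  keep_basin <- unname(unit_of[db$basins$basin_id]) %in% nn_units
  basins2 <- db$basins[keep_basin, , drop = FALSE]
  rec2 <- rec[rec$basin_id %in% basins2$basin_id, , drop = FALSE]
  n_rec_unit_drop <- nrow(rec) - nrow(rec2)

  in_tree <- rec2$species %in% tree$tip.label
  drop_species <- sort(unique(rec2$species[!in_tree]))
  rec3 <- rec2[in_tree, , drop = FALSE]

  if (nrow(rec3) == 0) stop("cleaning removed every record")
  list(db = occurrence_db(rec3, basins2),
       report = list(units_dropped = sort(drop_units),
                     n_units_dropped = length(drop_units),
                     n_basins_dropped = sum(!keep_basin),
                     n_records_dropped_units = n_rec_unit_drop,
                     species_dropped = drop_species,
                     n_species_dropped = length(drop_species),
                     n_records_dropped_species = nrow(rec2) - nrow(rec3)))
}

#' Build the establishment success/failure modeling table
#'
#' For every species carrying the requested label (exotic or translocated) in
#' at least one basin of an administrative unit, one row is emitted per
#' candidate basin of that unit: all basins for exotics, all basins minus the
#' species' origin (native) basins for translocations. `presence` is 1 where
#' the species is recorded non-native and 0 elsewhere, so the absences are
#' the inferred establishment failures. Each row carries the nonnative-native
#' relatedness (MPD, MNTD) of the focal species to the basin's natives, the
#' basin's native diversity (richness, native MPD/MNTD), basin area and its
#' log. Rows where relatedness is undefined (no natives in the basin) are
#' dropped.
#'
#' @param db_clean cleaned `occurrence_db` (see [clean_database()]).
#' @param assignment `status_assignment` matching `db_clean`.
#' @param D cophenetic distance matrix covering the database species.
#' @param group `"exotic"` or `"translocated"`.
#' @return data.frame with columns species, basin_id, country, realm, group,
#'   presence, mpd, mntd, native_richness, native_mpd, native_mntd,
#'   basin_area, log_area.
#' @export
build_records <- function(db_clean, assignment, D,
                          group = c("exotic", "translocated")) {
  group <- match.arg(group)
  stopifnot(inherits(db_clean, "occurrence_db"),
            inherits(assignment, "status_assignment"))
  scope <- assignment$scope
  unit_of <- basin_unit(db_clean, scope)
  country_of <- basin_country(db_clean)
  realm_of <- basin_realm(db_clean)
  area_of <- stats::setNames(db_clean$basins$area_km2, db_clean$basins$basin_id)

  lab <- assignment$labels
  lab <- lab[lab$basin_id %in% db_clean$basins$basin_id &
               paste(lab$species, lab$basin_id) %in%
                 paste(db_clean$records$species, db_clean$records$basin_id), ,
             drop = FALSE]
  lab$unit <- unname(unit_of[lab$basin_id])
  focal <- unique(lab[lab$label == group, c("species", "unit")])
  if (nrow(focal) == 0)
    stop("no records labeled '", group, "' under ", scope, " scope")

  rec <- db_clean$records
  natives_by_basin <- split(rec$species[rec$status == "native"],
                            rec$basin_id[rec$status == "native"])
  # native community metrics are a per-basin quantity; compute each basin once
  basin_ids <- db_clean$basins$basin_id
  div <- lapply(basin_ids, function(b) {
    native_diversity(natives_by_basin[[b]] %||% character(0), D)
  })
  names(div) <- basin_ids
  basins_of_unit <- split(basin_ids, unname(unit_of[basin_ids]))

  nn_key <- paste(rec$species[rec$status == "nonnative"],
                  rec$basin_id[rec$status == "nonnative"], sep = "\r")
  nat_key <- paste(rec$species[rec$status == "native"],
                   rec$basin_id[rec$status == "native"], sep = "\r")

  out <- vector("list", nrow(focal))
  for (i in seq_len(nrow(focal))) {
    s <- focal$species[i]; u <- focal$unit[i]
    cand <- basins_of_unit[[u]]
    if (group == "translocated")
      cand <- setdiff(cand, rec$basin_id[rec$species == s &
                                           rec$status == "native" &
                                           unname(unit_of[rec$basin_id]) == u])
    stopifnot(!any(paste(s, cand, sep = "\r") %in% nat_key))
    rows <- lapply(cand, function(b) {
      nat <- setdiff(natives_by_basin[[b]] %||% character(0), s)
      rel <- relatedness_to_natives(s, nat, D)
      if (is.na(rel$mpd)) return(NULL)
      dv <- div[[b]]
      data.frame(species = s, basin_id = b,
                 country = unname(country_of[b]), realm = unname(realm_of[b]),
                 group = group,
                 presence = as.integer(paste(s, b, sep = "\r") %in% nn_key),
                 mpd = rel$mpd, mntd = rel$mntd,
                 native_richness = dv$richness,
                 native_mpd = dv$native_mpd, native_mntd = dv$native_mntd,
                 basin_area = unname(area_of[b]),
                 log_area = log(unname(area_of[b])),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0)
    stop("no modeling records could be built (no basins with natives?)")
  res <- res[order(res$species, res$basin_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append z-scored copies of numeric columns
#'
#' Standardizes each named column with the sample (n-1) standard deviation
#' computed over the table's non-missing values and appends it as
#' `<column>_z`; originals are retained. z-scores are recomputed for each fit
#' (global, per-realm, per-country) so coefficients are comparable within a
#' fit.
#'
#' @param records data.frame of modeling records.
#' @param columns character vector of column names to standardize.
#' @return the table with `_z` columns appended.
#' @export
standardize_records <- function(records,
                                columns = c("mpd", "mntd", "native_richness",
                                            "native_mpd", "native_mntd",
                                            "log_area")) {
  columns <- intersect(columns, names(records))
  for (col in columns) {
    x <- records[[col]]
    if (!is.numeric(x)) stop("column '", col, "' is not numeric")
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("column '", col, "' has zero standard deviation")
    records[[paste0(col, "_z")]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  records
}
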