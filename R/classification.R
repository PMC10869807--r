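#' Classify non-native records as exotic or translocated
#'
#' A non-native species in basin b is *translocated* within the administrative
#' unit U containing b (country or biogeographical realm, per `scope`) when it
#' is also recorded as native in at least one other basin of U; otherwise it
#' is *exotic* (introduced from outside U). Classification is computed per
#' unit independently, so the same species may be exotic in one country and
#' translocated in another. Because countries nest within realms, every
#' country-scope translocation is also a realm-scope translocation.
#'
#' @param db an [occurrence_db()].
#' @param scope `"country"` (default) or `"realm"`.
#' @return an object of class `status_assignment`: list with `scope` and a
#'   data.frame `labels` (`species`, `basin_id`, `label` in
#'   native/exotic/translocated) covering every occurrence record.
#' @export
classify_nonnatives <- function(db, scope = c("country", "realm")) {
  scope <- match.arg(scope)
  stopifnot(inherits(db, "occurrence_db"))
  unit_of <- basin_unit(db, scope)
  rec <- db$records
  rec$unit <- unname(unit_of[rec$basin_id])

  native_units <- unique(rec[rec$status == "native", c("species", "unit")])
  native_key <- paste(native_units$species, native_units$unit, sep = "\r")

  label <- rep("native", nrow(rec))
  nn <- rec$status == "nonnative"
  nn_key <- paste(rec$species[nn], rec$unit[nn], sep = "\r")
  label[nn] <- ifelse(nn_key %in% native_key, "translocated", "exotic")

  structure(list(scope = scope,
                 labels = data.frame(species = rec$species,
                                     basin_id = rec$basin_id,
                                     label = label,
                                     stringsAsFactors = FALSE)),
            class = "status_assignment")
}

#' @export
print.status_assignment <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("Status assignment (%s scope): %d native, %d exotic, %d translocated\n",
              x$scope,
              if ("native" %in% names(tab)) tab[["native"]] else 0L,
              if ("exotic" %in% names(tab)) tab[["exotic"]] else 0L,
              if ("translocated" %in% names(tab)) tab[["translocated"]] else 0L))
  invisible(x)
}

#' Origin basins of a translocated species
#'
#' The basins of an administrative unit where a translocated species is
#' recorded as native; these are excluded from its candidate basin set when
#' building establishment records (a translocation cannot "establish" where
#' it already natively occurs).
#'
#' @param db an [occurrence_db()].
#' @param assignment a `status_assignment` from [classify_nonnatives()].
#' @param species species name (any whitespace/underscore form).
#' @param unit administrative unit identifier (a country or realm matching
#'   the assignment's scope).
#' @return character vector of basin ids.
#' @export
origin_basins <- function(db, assignment, species, unit) {
  stopifnot(inherits(db, "occurrence_db"),
            inherits(assignment, "status_assignment"))
  species <- normalize_species(species)
  unit_of <- basin_unit(db, assignment$scope)
  lab <- assignment$labels
  in_unit <- unname(unit_of[lab$basin_id]) == unit
  if (!any(lab$species == species & in_unit & lab$label == "translocated"))
    stop("species '", species, "' is not translocated in unit '", unit, "'")
  rec <- db$records
  sel <- rec$species == species & rec$status == "native" &
    unname(unit_of[rec$basin_id]) == unit
  sort(unique(rec$basin_id[sel]))
}
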