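#' @keywords internal
"_PACKAGE"

VALID_REALMS <- c("Afrotropic", "Australasia", "Indo-Malay", "Nearctic",
                  "Neotropic", "Oceania", "Palearctic")

#' Normalize species names
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace,
#' and replaces spaces with underscores so that occurrence-table names and
#' Newick tip labels compare equal ("Homo sapiens" == "Homo_sapiens").
#'
#' @param x character vector of species names.
#' @return character vector of canonical names (underscore form).
#' @export
normalize_species <- function(x) {
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  gsub(" ", "_", x, fixed = TRUE)
}

#' Construct and validate an occurrence database
#'
#' Bundles a species-by-basin occurrence table with basin metadata
#' (basin -> country -> biogeographical realm hierarchy, surface area,
#' centroid) and enforces the structural invariants: unique (species, basin)
#' records, no species both native and non-native in one basin, every basin
#' present in the metadata, one country per basin and one realm per country.
#'
#' @param records data.frame with columns `species`, `basin_id`, `status`
#'   (values `"native"` or `"nonnative"`).
#' @param basins data.frame with columns `basin_id`, `country`, `realm`,
#'   `area_km2`, `lat`, `lon`.
#' @return an object of class `occurrence_db` (list with elements `records`
#'   and `basins`).
#' @export
occurrence_db <- function(records, basins) {
  req_rec <- c("species", "basin_id", "status")
  req_bas <- c("basin_id", "country", "realm", "area_km2", "lat", "lon")
  miss <- setdiff(req_rec, names(records))
  if (length(miss))
    stop("occurrence table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_bas, names(basins))
  if (length(miss))
    stop("basin table is missing column(s): ", paste(miss, collapse = ", "))

  records <- as.data.frame(records)[req_rec]
  basins <- as.data.frame(basins)[req_bas]
  records$species <- normalize_species(as.character(records$species))
  records$basin_id <- as.character(records$basin_id)
  records$status <- as.character(records$status)
  basins$basin_id <- as.character(basins$basin_id)
  basins$country <- as.character(basins$country)
  basins$realm <- as.character(basins$realm)

  bad <- setdiff(unique(records$status), c("native", "nonnative"))
  if (length(bad))
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         " (must be 'native' or 'nonnative')")
  if (anyDuplicated(basins$basin_id))
    stop("duplicate basin_id in basin metadata")
  bad <- setdiff(unique(basins$realm), VALID_REALMS)
  if (length(bad))
    stop("unknown realm(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(basins$area_km2)) || any(basins$area_km2 <= 0))
    stop("basin area must be positive")
  if (any(basins$lat < -90 | basins$lat > 90))
    stop("basin centroid latitude outside [-90, 90]")
  if (any(basins$lon < -180 | basins$lon > 180))
    stop("basin centroid longitude outside [-180, 180]")
  cr <- unique(basins[, c("country", "realm")])
  dup <- cr$country[duplicated(cr$country)]
  if (length(dup))
    stop("country assigned to more than one realm: ",
         paste(unique(dup), collapse = ", "))

  key <- paste(records$species, records$basin_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[duplicated(key), , drop = FALSE]
    stop("duplicate (species, basin) record(s), e.g. (",
         d$species[1], ", ", d$basin_id[1], ")")
  }
  # a species cannot be simultaneously native and non-native in one basin:
  # duplicates across statuses are already duplicates of the (species, basin)
  # key above, so reaching here guarantees the invariant.
  orphan <- setdiff(unique(records$basin_id), basins$basin_id)
  if (length(orphan))
    stop("basin(s) in occurrence table absent from metadata: ",
         paste(orphan, collapse = ", "))

  structure(list(records = records, basins = basins), class = "occurrence_db")
}

#' Load an occurrence database from delimited text
#'
#' Reads the occurrence table (`species,basin_id,status`) and basin metadata
#' (`basin_id,country,realm,area_km2,lat,lon`) and returns a validated
#' [occurrence_db()].
#'
#' @param occurrence_path,basin_path paths to delimited text files with
#'   headers.
#' @param sep field delimiter; `","` (default) or `"\t"`.
#' @return an `occurrence_db`.
#' @export
load_occurrence_database <- function(occurrence_path, basin_path, sep = ",") {
  if (!file.exists(occurrence_path))
    stop("occurrence file not found: ", occurrence_path)
  if (!file.exists(basin_path))
    stop("basin file not found: ", basin_path)
  rec <- utils::read.table(occurrence_path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8")
  bas <- utils::read.table(basin_path, header = TRUE, sep = sep,
                           quote = "\"", fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  for (col in c("area_km2", "lat", "lon"))
    if (col %in% names(bas)) bas[[col]] <- as.numeric(bas[[col]])
  occurrence_db(rec, bas)
}

#' Write an occurrence database to delimited text
#'
#' Emits the same two-file schema consumed by [load_occurrence_database()].
#'
#' @param db an `occurrence_db`.
#' @param occurrence_path,basin_path output paths.
#' @param sep field delimiter.
#' @return invisibly, the two paths.
#' @export
write_occurrence_database <- function(db, occurrence_path, basin_path,
                                      sep = ",") {
  stopifnot(inherits(db, "occurrence_db"))
  utils::write.table(db$records, occurrence_path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(db$basins, basin_path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(occurrence_path, basin_path))
}

#' @export
print.occurrence_db <- function(x, ...) {
  s <- db_summary(x)
  cat("Occurrence database:\n")
  cat(sprintf("  basins:    %d (%d countries, %d realms)\n",
              s$n_basins, s$n_countries, s$n_realms))
  cat(sprintf("  species:   %d\n", s$n_species))
  cat(sprintf("  records:   %d native, %d non-native\n",
              s$n_native, s$n_nonnative))
  invisible(x)
}

#' Summary counts for an occurrence database
#'
#' @param db an `occurrence_db`.
#' @return list of counts: basins, countries, realms, species, native and
#'   non-native records.
#' @export
db_summary <- function(db) {
  stopifnot(inherits(db, "occurrence_db"))
  list(n_basins = nrow(db$basins),
       n_countries = length(unique(db$basins$country)),
       n_realms = length(unique(db$basins$realm)),
       n_species = length(unique(db$records$species)),
       n_native = sum(db$records$status == "native"),
       n_nonnative = sum(db$records$status == "nonnative"))
}

#' Drop non-native records of selected families
#'
#' Removes non-native records whose species belong to any family in
#' `drop_families` (e.g. Cyprinidae and Salmonidae, the families dominating
#' the global non-native pool); native records are untouched, as is the basin
#' table.
#'
#' @param db an `occurrence_db`.
#' @param drop_families character vector of family names to drop.
#' @param family_map named character vector or two-column data.frame
#'   (`species`, `family`) mapping species to families; must cover every
#'   species whose family is dropped.
#' @return a new `occurrence_db`.
#' @export
subset_database <- function(db, drop_families, family_map) {
  stopifnot(inherits(db, "occurrence_db"))
  if (length(drop_families) == 0) return(db)
  if (is.data.frame(family_map)) {
    fm <- stats::setNames(as.character(family_map$family),
                          normalize_species(family_map$species))
  } else {
    fm <- stats::setNames(as.character(family_map),
                          normalize_species(names(family_map)))
  }
  nn <- db$records$status == "nonnative"
  fam <- fm[db$records$species]
  # every non-native species must be resolvable before we can decide drops
  unknown <- unique(db$records$species[nn & is.na(fam)])
  if (length(unknown))
    stop("species without a family assignment: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  keep <- !(nn & fam %in% drop_families)
  occurrence_db(db$records[keep, , drop = FALSE], db$basins)
}

# basin_id -> country / realm lookup vectors (internal)
basin_country <- function(db) {
  stats::setNames(db$basins$country, db$basins$basin_id)
}
basin_realm <- function(db) {
  stats::setNames(db$basins$realm, db$basins$basin_id)
}

# basin_id -> administrative unit under a scope (internal)
basin_unit <- function(db, scope) {
  switch(scope, country = basin_country(db), realm = basin_realm(db),
         stop("scope must be 'country' or 'realm'"))
}
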