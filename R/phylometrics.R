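#' Read a Newick phylogeny
#'
#' Parses a Newick file with `ape`, normalizes tip labels to the underscore
#' form used throughout the package (so occurrence-table names and tree tips
#' compare equal) and validates the result: unique tips, at least two tips,
#' non-negative branch lengths present.
#'
#' @param path path to a Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  validate_phylogeny(tree)
}

#' Validate a phylogeny for use in relatedness metrics
#'
#' @param tree an `ape::phylo`.
#' @return the tree, tips normalized, invisibly checked.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  tree$tip.label <- normalize_species(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (length(tree$tip.label) < 2) stop("tree has fewer than 2 tips")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tree
}

#' Cophenetic (patristic) distance matrix
#'
#' Sum of branch lengths along the tree path between every pair of tips,
#' as a dense symmetric matrix with tip labels as dimnames.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return numeric matrix, tips x tips.
#' @export
cophenetic_distances <- function(tree) {
  tree <- validate_phylogeny(tree)
  as.matrix(stats::cophenetic(tree))
}

#' Relatedness of a focal species to a basin's native community
#'
#' MPD is the mean patristic distance from the focal (non-native) species to
#' all native species of the basin; MNTD is the distance to its closest
#' native relative. With an empty native set both are undefined (`NA`), and
#' callers decide the disposition (the record builder drops such rows).
#'
#' @param species focal species name (must be a tip of `D`).
#' @param native_set character vector of native species names.
#' @param D cophenetic distance matrix from [cophenetic_distances()].
#' @return list with elements `mpd` and `mntd`.
#' @export
relatedness_to_natives <- function(species, native_set, D) {
  species <- normalize_species(species)
  native_set <- normalize_species(native_set)
  if (!species %in% rownames(D))
    stop("focal species '", species, "' absent from distance matrix")
  if (species %in% native_set)
    stop("focal species '", species, "' is in the native set")
  if (length(native_set) == 0)
    return(list(mpd = NA_real_, mntd = NA_real_))
  missing <- setdiff(native_set, colnames(D))
  if (length(missing))
    stop("native species absent from distance matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  d <- D[species, native_set]
  list(mpd = mean(d), mntd = min(d))
}

#' Native community phylogenetic diversity
#'
#' Richness, native MPD (mean patristic distance over unordered pairs of
#' natives) and native MNTD (mean distance of each native to its nearest
#' native neighbor). With fewer than two natives both distance metrics are
#' undefined and reported as `NA`, never 0.
#'
#' @param native_set character vector of native species names.
#' @param D cophenetic distance matrix.
#' @return list with `richness`, `native_mpd`, `native_mntd`.
#' @export
native_diversity <- function(native_set, D) {
  native_set <- normalize_species(native_set)
  missing <- setdiff(native_set, colnames(D))
  if (length(missing))
    stop("native species absent from distance matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  n <- length(native_set)
  if (n < 2)
    return(list(richness = n, native_mpd = NA_real_, native_mntd = NA_real_))
  sub <- D[native_set, native_set, drop = FALSE]
  mpd <- mean(sub[lower.tri(sub)])
  diag(sub) <- Inf
  mntd <- mean(apply(sub, 1, min))
  list(richness = n, native_mpd = mpd, native_mntd = mntd)
}

#' Phylogenetic covariance matrix
#'
#' C(i, j) is the shared branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds tip depths. Satisfies
#' d(i, j) = C(i, i) + C(j, j) - 2 C(i, j) against the cophenetic matrix.
#' Exposed for phylogenetic mixed models that accept a covariance structure.
#'
#' @param tree a rooted `ape::phylo`.
#' @return numeric matrix, tips x tips.
#' @export
phylo_covariance_matrix <- function(tree) {
  tree <- validate_phylogeny(tree)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::vcv.phylo(tree)
}

#' Prune a phylogeny to the species of a database
#'
#' Restricts the tree to species present in the occurrence database and
#' reports which database species are absent from the tree (those species'
#' records must be dropped before modeling; see [clean_database()]).
#'
#' @param tree an `ape::phylo`.
#' @param db an [occurrence_db()].
#' @return list with `tree` (pruned phylogeny) and `dropped` (character
#'   vector of database species absent from the tree).
#' @export
prune_to_database <- function(tree, db) {
  tree <- validate_phylogeny(tree)
  stopifnot(inherits(db, "occurrence_db"))
  db_species <- unique(db$records$species)
  keep <- intersect(tree$tip.label, db_species)
  if (length(keep) < 2)
    stop("fewer than 2 database species present in the tree")
  list(tree = ape::keep.tip(tree, keep),
       dropped = sort(setdiff(db_species, tree$tip.label)))
}
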