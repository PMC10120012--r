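#' Read a species table
#'
#' Expects CSV columns `species_id, genus, life_history, ploidy, hectads,
#' has_barcode`. `hectads` is a semicolon-separated list of grid-cell ids;
#' `ploidy` may hold several semicolon-separated cytotypes or be empty
#' (unknown). Biennials are collapsed into perennials; empty life history is
#' an error.
#'
#' @param path CSV file path.
#' @return data.frame of class `species_table`: one row per species with list
#'   columns `hectads` (character vectors) and `ploidy` (integer vectors,
#'   length 0 = unknown).
#' @export
read_species_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species_id", "genus", "life_history", "ploidy", "hectads",
            "has_barcode")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("species table missing columns: ",
                         paste(miss, collapse = ", "))
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup)) stop("duplicate species_id: ",
                        paste(unique(dup), collapse = ", "))
  lh <- tolower(trimws(df$life_history))
  lh[lh == "biennial"] <- "perennial"   # few biennials; folded into perennial
  bad <- which(!lh %in% c("annual", "perennial"))
  if (length(bad))
    stop("unknown life_history in row(s) ", paste(bad, collapse = ", "),
         " (species ", paste(df$species_id[bad], collapse = ", "), ")")
  ploidy <- lapply(strsplit(df$ploidy, ";", fixed = TRUE), function(p) {
    p <- trimws(p[nzchar(trimws(p))])
    if (!length(p)) return(integer(0))
    v <- suppressWarnings(as.integer(p))
    if (anyNA(v) || any(v <= 0)) stop("non-positive or non-integer ploidy: ",
                                      paste(p, collapse = ";"))
    v
  })
  hect <- lapply(strsplit(df$hectads, ";", fixed = TRUE), function(h) {
    unique(trimws(h[nzchar(trimws(h))]))
  })
  out <- data.frame(species_id = df$species_id, genus = df$genus,
                    life_history = lh,
                    has_barcode = tolower(df$has_barcode) %in%
                      c("true", "t", "1", "yes"),
                    stringsAsFactors = FALSE)
  out$ploidy <- ploidy
  out$hectads <- hect
  class(out) <- c("species_table", "data.frame")
  out
}

#' Read a hybrid table
#'
#' Expects CSV columns `parent1, parent2, origin_flag, rank_flag,
#' certainty_flag, parent_count, intergeneric` and optionally `cytotype1,
#' cytotype2` (the parental cytotypes known to have contributed, for species
#' with multiple ploidy levels). Records are keyed on the unordered parent
#' pair: repeated origins of the same combination collapse to one record.
#'
#' @param path CSV file path.
#' @return data.frame of class `hybrid_table`.
#' @export
read_hybrid_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("parent1", "parent2", "origin_flag", "rank_flag",
            "certainty_flag", "parent_count", "intergeneric")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hybrid table missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$parent1 == df$parent2))
    stop("hybrid with identical parents: ",
         paste(df$parent1[df$parent1 == df$parent2], collapse = ", "))
  if (!"cytotype1" %in% names(df)) df$cytotype1 <- ""
  if (!"cytotype2" %in% names(df)) df$cytotype2 <- ""
  df$parent_count <- as.integer(df$parent_count)
  df$intergeneric <- tolower(df$intergeneric) %in% c("true", "t", "1", "yes")
  # canonical unordered key; first record of a combination wins
  swap <- df$parent1 > df$parent2
  tmp <- df$parent1[swap]; df$parent1[swap] <- df$parent2[swap]
  df$parent2[swap] <- tmp
  tmp <- df$cytotype1[swap]; df$cytotype1[swap] <- df$cytotype2[swap]
  df$cytotype2[swap] <- tmp
  df <- df[!duplicated(paste(df$parent1, df$parent2, sep = "\r")), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hybrid_table", "data.frame")
  df
}

#' Read a rooted newick tree
#'
#' @param path newick file with a single rooted tree, branch lengths on all
#'   edges and labelled tips.
#' @param species optional character vector of valid species ids; tips not in
#'   it raise an error naming the offenders.
#' @return an `ape::phylo` tree with attributes `ultrametric` (within 1e-6 of
#'   max depth) and `depth`.
#' @export
read_newick <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo"))
    stop("expected a single tree, found ", length(tree))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("tree has unlabeled tips")
  if (!is.null(species)) {
    extra <- setdiff(tree$tip.label, species)
    if (length(extra))
      stop("tree tips absent from the species table: ",
           paste(extra, collapse = ", "))
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  attr(tree, "depth") <- max(depths)
  attr(tree, "ultrametric") <- (max(depths) - min(depths)) <= 1e-6 * max(depths)
  tree
}

#' Write a species table back to CSV (round-trips [read_species_table()])
#' @param species a `species_table`.
#' @param path output CSV path.
#' @export
write_species_table <- function(species, path) {
  df <- data.frame(
    species_id = species$species_id, genus = species$genus,
    life_history = species$life_history,
    ploidy = vapply(species$ploidy, paste, character(1), collapse = ";"),
    hectads = vapply(species$hectads, paste, character(1), collapse = ";"),
    has_barcode = ifelse(species$has_barcode, "true", "false"),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dyad table to CSV
#' @param dyads a `dyad_table` from [build_dyads()].
#' @param path output CSV path.
#' @export
write_dyad_table <- function(dyads, path) {
  utils::write.csv(as.data.frame(dyads), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dyad table written by [write_dyad_table()]
#' @param path CSV path.
#' @export
read_dyad_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_a", "species_b", "genus", "hybridizes", "branch_length",
            "hectad_overlap", "genus_size", "life_history_pair",
            "ploidy_match")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("dyad table missing columns: ",
                         paste(miss, collapse = ", "))
  class(df) <- c("dyad_table", "data.frame")
  df
}
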