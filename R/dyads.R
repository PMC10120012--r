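#' Apply hybrid-record exclusion filters
#'
#' Removes, in order: (a) hybrids formed abroad, (b) triple hybrids,
#' (c) dubious records, (d) crosses below specific rank, then intergeneric
#' crosses, then hybrids whose parents lack barcode data (and so are absent
#' from the phylogeny). Each record is counted against the first filter that
#' removes it, so the audit counts sum to the total removed.
#'
#' @param hybrids a `hybrid_table`.
#' @param species a `species_table`; all parents must be present.
#' @return list with `hybrids` (surviving records) and `audit` (named integer
#'   vector of removal counts per filter, plus `retained`).
#' @export
apply_exclusion_filters <- function(hybrids, species) {
  parents <- unique(c(hybrids$parent1, hybrids$parent2))
  unknown <- setdiff(parents, species$species_id)
  if (length(unknown))
    stop("hybrid references unknown species: ",
         paste(unknown, collapse = ", "))
  barcode <- stats::setNames(species$has_barcode, species$species_id)
  filters <- list(
    formed_abroad  = hybrids$origin_flag == "formed-abroad",
    triple_hybrid  = hybrids$parent_count != 2L,
    dubious        = hybrids$certainty_flag != "accepted",
    infraspecific  = hybrids$rank_flag != "species",
    intergeneric   = hybrids$intergeneric,
    no_barcode     = !(barcode[hybrids$parent1] & barcode[hybrids$parent2])
  )
  removed <- rep(FALSE, nrow(hybrids))
  audit <- integer(0)
  for (nm in names(filters)) {
    hit <- filters[[nm]] & !removed
    audit[nm] <- sum(hit)
    removed <- removed | hit
  }
  audit["retained"] <- sum(!removed)
  keep <- hybrids[!removed, , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- class(hybrids)
  list(hybrids = keep, audit = audit)
}

#' Resolve per-species ploidy
#'
#' Species with a single recorded ploidy keep it. Species with multiple
#' cytotypes are unknown at the species level, but a hybrid record annotated
#' with the contributing cytotype resolves the pair it names.
#'
#' @param species a `species_table`.
#' @param hybrids a filtered `hybrid_table` (columns `cytotype1`,
#'   `cytotype2` may annotate contributing cytotypes).
#' @return list with `species_ploidy` (named integer, `NA` = unknown) and
#'   `pair_ploidy` (data.frame `parent1, parent2, ploidy1, ploidy2` of
#'   pair-specific resolutions, `NA` where unresolved).
#' @export
ploidy_assignment <- function(species, hybrids = NULL) {
  bad <- vapply(species$ploidy, function(p) any(p <= 0), logical(1))
  if (any(bad))
    stop("non-positive ploidy for species: ",
         paste(species$species_id[bad], collapse = ", "))
  pl <- vapply(species$ploidy, function(p) {
    if (length(p) == 1L) p else NA_integer_
  }, integer(1))
  names(pl) <- species$species_id
  pool <- stats::setNames(species$ploidy, species$species_id)
  pair <- NULL
  if (!is.null(hybrids) && nrow(hybrids)) {
    resolve <- function(sp, cyt) {
      if (!is.na(pl[sp])) return(pl[[sp]])
      v <- suppressWarnings(as.integer(cyt))
      if (is.na(v) || !v %in% pool[[sp]]) return(NA_integer_)
      v
    }
    pair <- data.frame(
      parent1 = hybrids$parent1, parent2 = hybrids$parent2,
      ploidy1 = mapply(resolve, hybrids$parent1, hybrids$cytotype1),
      ploidy2 = mapply(resolve, hybrids$parent2, hybrids$cytotype2),
      stringsAsFactors = FALSE)
  }
  list(species_ploidy = pl, pair_ploidy = pair)
}

#' Build the congeneric dyad table
#'
#' Enumerates every unordered within-genus species pair and attaches the
#' binary response (does a surviving hybrid record name this pair?) and the
#' five covariates: cophenetic branch length, hectad overlap, genus size
#' (tips of the genus in the phylogeny), life-history pair and ploidy match.
#'
#' @param species a `species_table` (filtered to analysis species).
#' @param hybrids a filtered `hybrid_table`, or `NULL` for none (all
#'   responses 0; used when outcomes are simulated afterwards).
#' @param tree a `phylo` tree containing every species as a tip.
#' @param cophenetic optional precomputed matrix from
#'   [cophenetic_distance()]; computed from `tree` if missing.
#' @param hectad_policy for species with no distribution data: `"drop"`
#'   removes their dyads, `"zero"` scores their overlaps as 0.
#' @return data.frame of class `dyad_table`, rows sorted by
#'   (genus, species_a, species_b) with `species_a < species_b`.
#' @export
build_dyads <- function(species, hybrids, tree, cophenetic = NULL,
                        hectad_policy = c("drop", "zero")) {
  hectad_policy <- match.arg(hectad_policy)
  if (is.null(hybrids)) hybrids <- .empty_hybrids()
  missing_tip <- setdiff(species$species_id, tree$tip.label)
  if (length(missing_tip))
    stop("species absent from the tree: ", paste(missing_tip, collapse = ", "))
  if (is.null(cophenetic)) cophenetic <- cophenetic_distance(tree)

  pa <- ploidy_assignment(species, hybrids)
  sp_pl <- pa$species_ploidy
  lh <- stats::setNames(species$life_history, species$species_id)
  hect <- stats::setNames(species$hectads, species$species_id)
  has_hect <- vapply(hect, length, integer(1)) > 0

  genus_size <- table(species$genus[species$species_id %in% tree$tip.label])
  hyb_key <- character(0)
  if (nrow(hybrids))
    hyb_key <- paste(pmin(hybrids$parent1, hybrids$parent2),
                     pmax(hybrids$parent1, hybrids$parent2), sep = "\r")

  pair_pl <- pa$pair_ploidy
  pair_key <- if (is.null(pair_pl)) character(0) else
    paste(pmin(pair_pl$parent1, pair_pl$parent2),
          pmax(pair_pl$parent1, pair_pl$parent2), sep = "\r")

  rows <- list()
  for (g in sort(unique(species$genus))) {
    ids <- sort(species$species_id[species$genus == g])
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      if (hectad_policy == "drop" && (!has_hect[[a]] || !has_hect[[b]]))
        next
      key <- paste(min(a, b), max(a, b), sep = "\r")
      p1 <- sp_pl[[a]]; p2 <- sp_pl[[b]]
      if ((is.na(p1) || is.na(p2)) && key %in% pair_key) {
        hit <- pair_pl[match(key, pair_key), ]
        q1 <- if (hit$parent1 == a) hit$ploidy1 else hit$ploidy2
        q2 <- if (hit$parent1 == a) hit$ploidy2 else hit$ploidy1
        if (is.na(p1)) p1 <- q1
        if (is.na(p2)) p2 <- q2
      }
      pm <- if (is.na(p1) || is.na(p2)) "unknown"
            else if (p1 == p2) "homoploid" else "heteroploid"
      lhp <- paste(sort(c(lh[[a]], lh[[b]])), collapse = "-")
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = a, species_b = b, genus = g,
        hybridizes = as.integer(key %in% hyb_key),
        branch_length = cophenetic[a, b],
        hectad_overlap = length(intersect(hect[[a]], hect[[b]])),
        genus_size = as.integer(genus_size[[g]]),
        life_history_pair = lhp, ploidy_match = pm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    out <- data.frame(species_a = character(0), species_b = character(0),
                      genus = character(0), hybridizes = integer(0),
                      branch_length = numeric(0), hectad_overlap = integer(0),
                      genus_size = integer(0),
                      life_history_pair = character(0),
                      ploidy_match = character(0), stringsAsFactors = FALSE)
  else out <- do.call(rbind, rows)
  out <- out[order(out$genus, out$species_a, out$species_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dyad_table", "data.frame")
  out
}
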