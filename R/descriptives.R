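#' Descriptive counts for a dyad table
#'
#' Totals, hybridizing fraction, genus-level concentration of hybrids and the
#' share captured by the top-k genera, plus the cross-ploidy share among
#' hybridizing dyads with known ploidy.
#'
#' @param dyads a `dyad_table`.
#' @param top_k genera to report in the concentration summary.
#' @return list of class `descriptive_report`.
#' @export
summarize_counts <- function(dyads, top_k = 5) {
  if (!nrow(dyads)) stop("empty dyad table")
  n <- nrow(dyads)
  nh <- sum(dyads$hybridizes)
  per_genus <- tapply(dyads$hybridizes, dyads$genus, sum)
  n_genera <- length(per_genus)
  with_h <- sum(per_genus > 0)
  topg <- sort(per_genus, decreasing = TRUE)[seq_len(min(top_k,
                                                         length(per_genus)))]
  hyb_known <- dyads$hybridizes == 1 & dyads$ploidy_match != "unknown"
  cross <- sum(dyads$hybridizes == 1 & dyads$ploidy_match == "heteroploid")
  structure(list(
    n_dyads = n, n_hybridizing = nh, pct_hybridizing = 100 * nh / n,
    n_genera = n_genera, genera_with_hybrids = with_h,
    pct_genera_with_hybrids = 100 * with_h / n_genera,
    genera_without_hybrids = n_genera - with_h,
    top_genera = topg,
    top_share_pct = if (nh > 0) 100 * sum(topg) / nh else NA_real_,
    cross_ploidy_hybrids = cross,
    cross_ploidy_share_pct = if (sum(hyb_known) > 0)
      100 * cross / sum(hyb_known) else NA_real_),
    class = "descriptive_report")
}

#' @export
print.descriptive_report <- function(x, ...) {
  cat(sprintf("Dyads: %d, hybridizing %d (%.1f%%)\n", x$n_dyads,
              x$n_hybridizing, x$pct_hybridizing))
  cat(sprintf("Multi-species genera: %d; with hybrids %d (%.1f%%), without %d (%.1f%%)\n",
              x$n_genera, x$genera_with_hybrids, x$pct_genera_with_hybrids,
              x$genera_without_hybrids, 100 - x$pct_genera_with_hybrids))
  cat(sprintf("Top %d genera hold %.1f%% of hybridizing dyads\n",
              length(x$top_genera), x$top_share_pct))
  if (!is.na(x$cross_ploidy_share_pct))
    cat(sprintf("Cross-ploidy: %d hybrids (%.1f%% of those with known ploidy)\n",
                x$cross_ploidy_hybrids, x$cross_ploidy_share_pct))
  invisible(x)
}

#' Life-history cross-tabulation of hybridization
#'
#' Per life-history pair level: dyad count and hybridizing percentage, with a
#' second tabulation after excluding the named genera (sensitivity to genera
#' that dominate a level).
#'
#' @param dyads a `dyad_table`.
#' @param exclude_genera character vector of genera for the sensitivity
#'   recomputation (may be empty).
#' @return data.frame: level, n, n_hybridizing, pct, and the same after
#'   exclusion (`n_excl`, `pct_excl`).
#' @export
life_history_crosstab <- function(dyads, exclude_genera = character(0)) {
  lev <- c("annual-annual", "annual-perennial", "perennial-perennial")
  bad <- setdiff(unique(dyads$life_history_pair), lev)
  if (length(bad)) stop("unknown life_history_pair level: ",
                        paste(bad, collapse = ", "))
  tab1 <- function(dd) {
    vapply(lev, function(l) {
      sel <- dd$life_history_pair == l
      c(n = sum(sel), nh = sum(dd$hybridizes[sel]),
        pct = if (sum(sel)) 100 * sum(dd$hybridizes[sel]) / sum(sel)
              else NA_real_)
    }, numeric(3))
  }
  full <- tab1(dyads)
  red <- tab1(dyads[!dyads$genus %in% exclude_genera, , drop = FALSE])
  data.frame(level = lev, n = full["n", ], n_hybridizing = full["nh", ],
             pct = full["pct", ], n_excl = red["n", ],
             n_hybridizing_excl = red["nh", ], pct_excl = red["pct", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-species hybrid load
#'
#' Number of unique hybrid combinations a species parents, divided by the
#' size of its genus.
#'
#' @param species a `species_table`.
#' @param hybrids a filtered `hybrid_table`.
#' @param genus_sizes named integer vector of genus sizes; defaults to the
#'   census of the species table.
#' @return data.frame: species_id, genus, n_hybrids, genus_size, load.
#' @export
hybrid_load <- function(species, hybrids, genus_sizes = NULL) {
  if (is.null(genus_sizes)) {
    gs <- table(species$genus)
    genus_sizes <- stats::setNames(as.integer(gs), names(gs))
  }
  key <- paste(pmin(hybrids$parent1, hybrids$parent2),
               pmax(hybrids$parent1, hybrids$parent2), sep = "\r")
  uniq <- !duplicated(key)
  counts <- table(c(hybrids$parent1[uniq], hybrids$parent2[uniq]))
  n_h <- as.integer(counts[species$species_id])
  n_h[is.na(n_h)] <- 0L
  gsz <- as.integer(genus_sizes[species$genus])
  data.frame(species_id = species$species_id, genus = species$genus,
             n_hybrids = n_h, genus_size = gsz, load = n_h / gsz,
             stringsAsFactors = FALSE)
}

#' Distance comparison between hybridizing and non-hybridizing dyads
#'
#' Group mean and standard error per distance type, with a two-sided Wilcoxon
#' rank-sum test: exact enumeration when both groups have at most 12
#' observations and no ties, normal approximation with tie correction
#' otherwise.
#'
#' @param dyads a `dyad_table`.
#' @param distances named list; each element either a symmetric species-by-
#'   species matrix (looked up per dyad) or a per-dyad numeric vector aligned
#'   with `dyads` rows.
#' @return data.frame: one row per distance type with group means, SEs,
#'   group sizes, the rank-sum W statistic and the p-value.
#' @export
distance_comparison <- function(dyads, distances) {
  stopifnot(is.list(distances), length(names(distances)) == length(distances))
  g1 <- dyads$hybridizes == 1
  if (!any(g1) || all(g1)) stop("both dyad groups must be non-empty")
  res <- lapply(names(distances), function(nm) {
    d <- distances[[nm]]
    v <- if (is.matrix(d)) d[cbind(dyads$species_a, dyads$species_b)]
         else as.numeric(d)
    if (length(v) != nrow(dyads))
      stop("distance '", nm, "' does not align with the dyad table")
    x <- v[g1]; y <- v[!g1]
    exact <- length(x) <= 12 && length(y) <= 12 && !anyDuplicated(c(x, y))
    wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
    se <- function(z) stats::sd(z) / sqrt(length(z))
    data.frame(distance = nm,
               mean_hybridizing = mean(x), se_hybridizing = se(x),
               n_hybridizing = length(x),
               mean_other = mean(y), se_other = se(y), n_other = length(y),
               W = unname(wt$statistic), p.value = wt$p.value,
               exact = exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Dyad divergence times from a dated tree
#'
#' Half the cophenetic distance: the node height of the pair's most recent
#' common ancestor on an ultrametric tree.
#'
#' @param dyads a `dyad_table`.
#' @param cophenetic matrix from [cophenetic_distance()].
#' @return numeric vector aligned with `dyads` rows.
#' @export
divergence_time <- function(dyads, cophenetic) {
  cophenetic[cbind(dyads$species_a, dyads$species_b)] / 2
}
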