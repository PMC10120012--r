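#' Tip-to-tip cophenetic distances
#'
#' Sum of branch lengths along the path between every pair of tips. On a
#' dated ultrametric tree this equals twice the divergence time of the pair.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, dimnames = tip labels.
#' @export
cophenetic_distance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  # fixed tip order for downstream joins
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Phylogenetic covariance matrix A
#'
#' A[i, j] is the shared root-to-tip path length of tips i and j, i.e. the
#' depth of their most recent common ancestor; A[i, i] is the root-to-tip
#' length. The tree is used unscaled (no rescaling of A to a unit diagonal).
#'
#' @param tree a rooted `phylo` tree with branch lengths >= 0.
#' @return an object of class `relatedness` with elements `A` (covariance),
#'   `species` (tip labels), `depth` (max root-to-tip length), `ultrametric`
#'   (logical, within 1e-6 of depth) and `A_inv` (`NULL` until
#'   [inverse_relatedness()] is called).
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  A <- ape::vcv.phylo(tree)
  A <- A[tree$tip.label, tree$tip.label, drop = FALSE]
  depth <- max(diag(A))
  structure(
    list(A = A, species = tree$tip.label, depth = depth,
         ultrametric = (depth - min(diag(A))) <= 1e-6 * depth,
         A_inv = NULL),
    class = "relatedness")
}

#' @export
print.relatedness <- function(x, ...) {
  cat(sprintf("Phylogenetic relatedness structure: %d species, depth %.4g%s%s\n",
              length(x$species), x$depth,
              if (x$ultrametric) ", ultrametric" else ", non-ultrametric",
              if (is.null(x$A_inv)) "" else ", inverse available"))
  invisible(x)
}

#' Inverse of the phylogenetic covariance matrix
#'
#' Dense inversion of A. Near-singular matrices (e.g. zero-length terminal
#' branches duplicating rows) trigger a warning and, if `jitter = TRUE`, a
#' diagonal jitter of 1e-10 before inverting.
#'
#' @param structure a `relatedness` object from [phylo_covariance()].
#' @param jitter add 1e-10 to the diagonal if A is computationally singular.
#' @return the `relatedness` object with `A_inv` filled.
#' @export
inverse_relatedness <- function(structure, jitter = FALSE) {
  stopifnot(inherits(structure, "relatedness"))
  A <- structure$A
  inv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(inv)) {
    if (!jitter)
      stop("relatedness matrix is singular; re-run with jitter = TRUE ",
           "(adds 1e-10 to the diagonal)")
    warning("relatedness matrix near-singular; adding 1e-10 diagonal jitter")
    inv <- chol2inv(chol(A + diag(1e-10, nrow(A))))
  }
  dimnames(inv) <- dimnames(A)
  structure$A_inv <- inv
  structure
}

#' Dyad phylogenetic variance statistics
#'
#' A dyad built from species a and b receives the sum of the two parental
#' phylogenetic effects, whose prior variance is
#' \eqn{\sigma_p^2 (A_{aa} + A_{bb} + 2A_{ab})}. Averaging the bracket over a
#' dyad set gives the multiplier that puts \eqn{\sigma_p^2} on the dyad
#' liability scale: `B_bar` averages over all unordered species pairs
#' (equivalently \eqn{2\bar d + 2\bar o}), and `B_bar_S` averages only over
#' within-genus (congeneric) pairs, which is the set the model is fitted to.
#'
#' @param structure a `relatedness` object.
#' @param genus_map named character vector (or factor) mapping species id to
#'   genus; must cover all species in `structure`.
#' @return a `dyad_variance_stats` list: `d_bar`, `o_bar`, `B_bar`,
#'   `B_bar_S`, per-genus vectors `d_i`, `o_i`, `n_i`, `n_ci`, and
#'   `B_bar_S_literal`, a diagnostic recomputation weighting the d-term by
#'   species counts rather than pair counts.
#' @export
dyad_variance_stats <- function(structure, genus_map) {
  stopifnot(inherits(structure, "relatedness"))
  A <- structure$A
  sp <- structure$species
  n <- length(sp)
  if (n < 2L) stop("need at least two species")
  genus_map <- vapply(genus_map, as.character, character(1))
  if (!all(sp %in% names(genus_map)))
    stop("genus_map is missing species: ",
         paste(setdiff(sp, names(genus_map)), collapse = ", "))
  genus <- unname(genus_map[sp])

  dg <- diag(A)
  d_bar <- mean(dg)
  npair <- n * (n - 1) / 2
  off_sum <- (sum(A) - sum(dg)) / 2          # sum over unordered pairs
  o_bar <- off_sum / npair
  # mean over all unordered dyads of A_aa + A_bb + 2 A_ab; each species
  # appears in (n-1) pairs, so the diagonal term averages to 2*d_bar.
  B_bar <- 2 * d_bar + 2 * o_bar

  gl <- split(seq_len(n), genus)
  n_i <- vapply(gl, length, integer(1))
  multi <- n_i >= 2L
  if (!any(multi))
    stop("B_bar_S undefined: no genus has two or more species")
  d_i <- vapply(gl, function(ix) mean(dg[ix]), numeric(1))
  o_i <- vapply(gl, function(ix) {
    if (length(ix) < 2L) return(NA_real_)
    Ag <- A[ix, ix, drop = FALSE]
    (sum(Ag) - sum(diag(Ag))) / (length(ix) * (length(ix) - 1))
  }, numeric(1))
  n_ci <- n_i * (n_i - 1) / 2

  # genus-constrained dyad mean: within each genus g with n_i >= 2 the mean
  # of (A_aa + A_bb + 2 A_ab) over its pairs is 2 d_i + 2 o_i; pool weighted
  # by pair counts.
  keep <- which(multi)
  B_bar_S <- sum((2 * d_i[keep] + 2 * o_i[keep]) * n_ci[keep]) / sum(n_ci[keep])
  # literal printed form (d-term weighted by species counts) kept as a
  # diagnostic only; inconsistent with the dyad-mean reading.
  B_literal <- (2 * sum(o_i[keep] * n_ci[keep]) + 2 * sum(d_i[keep] * n_i[keep])) /
    sum(n_ci[keep])

  structure(
    list(d_bar = d_bar, o_bar = o_bar, B_bar = B_bar, B_bar_S = B_bar_S,
         d_i = d_i, o_i = o_i, n_i = n_i, n_ci = n_ci,
         B_bar_S_literal = B_literal),
    class = "dyad_variance_stats")
}

#' @export
print.dyad_variance_stats <- function(x, ...) {
  cat(sprintf(
    "Dyad phylogenetic variance multipliers\n  B_bar   (all pairs):          %.6g\n  B_bar_S (within-genus pairs): %.6g\n  d_bar = %.6g, o_bar = %.6g; %d genera (%d with >= 2 species)\n",
    x$B_bar, x$B_bar_S, x$d_bar, x$o_bar,
    length(x$n_i), sum(x$n_i >= 2)))
  invisible(x)
}

#' Pairwise sequence distances from an alignment
#'
#' Distance = sqrt(1 - identity fraction), where the identity fraction is the
#' proportion of matching positions among those where neither sequence has a
#' gap (`-`) or `N` (pairwise deletion). `NaN` when a pair shares no
#' comparable positions.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   length), or a `Biostrings`-style list coercible with `as.character`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
sequence_distance <- function(alignment) {
  seqs <- toupper(vapply(alignment, as.character, character(1)))
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  n <- length(seqs)
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- mat != "-" & mat != "N"
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[i, ] & ok[j, ]
    nc <- sum(comp)
    if (nc == 0L) { d[i, j] <- d[j, i] <- NaN; next }
    ident <- sum(mat[i, comp] == mat[j, comp]) / nc
    d[i, j] <- d[j, i] <- sqrt(1 - ident)
  }
  d
}
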