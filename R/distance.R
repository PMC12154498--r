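# Per-individual per-locus "allele frequencies": 1/0 for homozygotes,
# 0.5/0.5 for heterozygotes (the only frequencies computable from a single
# diploid genotype). Returns ref-allele frequency matrix, NA = missing.
individual_ref_freq <- function(x) {
  al <- x$calls
  out <- matrix(NA_real_, nrow(al), ncol(al), dimnames = dimnames(al))
  for (j in seq_len(ncol(al))) {
    r <- x$markers$ref[j]
    cj <- al[, j]
    out[, j] <- ((substr(cj, 1, 1) == r) + (substr(cj, 2, 2) == r)) / 2
  }
  out
}

# shared-locus count and the Bhattacharyya-type numerator
# sum_l sum_a sqrt(p_x,a p_y,a), both as N x N matrices
pairwise_sqrt_terms <- function(pref) {
  m <- !is.na(pref)
  sref <- sqrt(ifelse(m, pref, 0))
  salt <- sqrt(ifelse(m, 1 - pref, 0))
  list(num = tcrossprod(sref) + tcrossprod(salt),
       shared = tcrossprod(m * 1))
}

#' Nei (1983) DA genetic distance between all sample pairs
#'
#' \eqn{D_A = 1 - (1/L') \sum_l \sum_a \sqrt{p_{x,a} p_{y,a}}} with
#' per-individual frequencies of 1/0 (homozygote) or 0.5/0.5 (heterozygote);
#' loci missing in either sample of a pair are skipped and L' is the count
#' of shared non-missing loci (pairwise deletion).
#'
#' @param x a \code{\link{genotype_matrix}} with >= 2 samples
#' @return symmetric distance matrix with zero diagonal
#' @export
nei_da_dist <- function(x) {
  if (nrow(x$calls) < 2L) stop_param("need >= 2 samples")
  pt <- pairwise_sqrt_terms(individual_ref_freq(x))
  check_shared(pt$shared, sample_ids(x))
  d <- 1 - pt$num / pt$shared
  finish_dist(d, sample_ids(x))
}

#' Modified Rogers and Cavalli-Sforza--Edwards distances
#'
#' \code{rogers_dist}: \eqn{MR = \sqrt{(1/2L') \sum_l \sum_a (p_x - p_y)^2}};
#' \code{cavalli_dist}: the same form on square-root frequencies,
#' \eqn{CE = \sqrt{(1/2L') \sum_l \sum_a (\sqrt{p_x} - \sqrt{p_y})^2}}.
#' Both lie in [0, 1], use per-individual frequencies and pairwise deletion
#' as in \code{\link{nei_da_dist}}.
#'
#' @inheritParams nei_da_dist
#' @return symmetric distance matrix with zero diagonal
#' @export
rogers_dist <- function(x) {
  if (nrow(x$calls) < 2L) stop_param("need >= 2 samples")
  pref <- individual_ref_freq(x)
  m <- !is.na(pref)
  a <- ifelse(m, 1 - pref, 0)      # alt frequency; ref diff is its negative
  shared <- tcrossprod(m * 1)
  check_shared(shared, sample_ids(x))
  a2m <- tcrossprod(a^2, m * 1)
  ss <- a2m + t(a2m) - 2 * tcrossprod(a)  # sum over shared loci of (ax-ay)^2
  d <- sqrt(pmax(2 * ss / (2 * shared), 0))
  finish_dist(d, sample_ids(x))
}

#' @rdname rogers_dist
#' @export
cavalli_dist <- function(x) {
  if (nrow(x$calls) < 2L) stop_param("need >= 2 samples")
  pt <- pairwise_sqrt_terms(individual_ref_freq(x))
  check_shared(pt$shared, sample_ids(x))
  # sum_l sum_a (sqrt px - sqrt py)^2 = 2 L' - 2 sum sqrt-products
  d <- sqrt(pmax(1 - pt$num / pt$shared, 0))
  finish_dist(d, sample_ids(x))
}

check_shared <- function(shared, ids) {
  diag(shared) <- 1
  if (any(shared == 0)) {
    bad <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop_param("samples %s and %s share no non-missing loci",
               ids[bad[1]], ids[bad[2]])
  }
}

finish_dist <- function(d, ids) {
  d <- pmin(pmax(d, 0), 1)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Locus-wise modified Rogers / Cavalli-Sforza--Edwards distance between
#' two frequency profiles
#'
#' Operates on allele-frequency matrices (loci x alleles, rows summing
#' to 1); loci with any missing frequency in either profile are skipped.
#'
#' @param px,py numeric matrices, loci x alleles
#' @param method "mr" or "ce"
#' @return a single distance in [0, 1]
#' @export
profile_distance <- function(px, py, method = c("mr", "ce")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(px) & stats::complete.cases(py)
  if (!any(ok)) stop_param("no shared non-missing loci")
  px <- px[ok, , drop = FALSE]; py <- py[ok, , drop = FALSE]
  if (method == "ce") { px <- sqrt(px); py <- sqrt(py) }
  sqrt(sum((px - py)^2) / (2 * nrow(px)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining (via \pkg{ape}); negative branch-length
#' estimates are clamped to zero, with the total clamped deficit recorded
#' in the \code{"nj_negative_deficit"} attribute. Exactly recovers additive
#' trees.
#'
#' @param d symmetric distance matrix (N >= 3) with labelled rows
#' @return an unrooted \code{ape::phylo} tree
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop_param("neighbor joining needs >= 3 taxa")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop_param("distance matrix must be symmetric with zero diagonal")
  tree <- ape::nj(as.dist(d))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "nj_negative_deficit") <- deficit
  tree
}

#' Write a phylogenetic tree in Newick format
#'
#' Branch lengths are rendered with 6 significant digits; the written file
#' re-parses to the same topology and path lengths.
#'
#' @param tree an \code{ape::phylo} with labelled leaves and branch lengths
#' @param path output path, or NULL to return the Newick string
#' @return the Newick string (invisibly when written to \code{path})
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop_param("all leaves must be labelled")
  txt <- ape::write.tree(tree, digits = 6)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a distance matrix as PHYLIP-compatible TSV
#' @param d square distance matrix with labelled rows
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_distance_matrix <- function(d, path) {
  lines <- c(as.character(nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(c(rownames(d)[i],
                       format(d[i, ], trim = TRUE, digits = 6)),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}
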