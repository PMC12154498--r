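#' Can one marker discriminate a pair of samples?
#'
#' TRUE iff both calls are non-missing and the genotype classes differ.
#' A missing call never discriminates: an empty KASP well is not evidence
#' of difference.
#'
#' @param call_a,call_b two-letter calls (\code{NA} = missing), vectorized
#' @return logical
#' @export
pair_discriminated <- function(call_a, call_b) {
  !is.na(call_a) & !is.na(call_b) & call_a != call_b
}

# pairs-by-markers resolution matrix for all N(N-1)/2 sample pairs
pair_resolution_matrix <- function(x) {
  n <- nrow(x$calls)
  pr <- utils::combn(n, 2L)
  res <- matrix(FALSE, ncol(pr), ncol(x$calls),
                dimnames = list(NULL, x$markers$id))
  for (j in seq_len(ncol(x$calls))) {
    cj <- x$calls[, j]
    res[, j] <- pair_discriminated(cj[pr[1, ]], cj[pr[2, ]])
  }
  list(pairs = pr, res = res)
}

#' Greedy minimal discriminating-marker set
#'
#' Maximum-coverage greedy set cover on sample pairs: iteratively add the
#' marker resolving the most currently-unresolved pairs, ties broken by
#' higher PIC then by (chrom, pos); stop when no marker resolves another
#' pair. Samples whose fingerprints over the chosen markers are still
#' identical are reported as unresolved groups.
#'
#' @param x a \code{\link{genotype_matrix}} with >= 2 samples
#' @return list of class \code{marker_set}: \code{chosen} (ordered marker
#'   IDs), \code{steps} (per-step cumulative pairs resolved),
#'   \code{pairs_resolved}, \code{pairs_total}, \code{unresolved_groups}
#'   (sample-ID sets sharing a fingerprint over the chosen markers)
#' @export
greedy_min_marker_set <- function(x) {
  n <- nrow(x$calls)
  if (n < 2L) stop_param("need >= 2 samples")
  prm <- pair_resolution_matrix(x)
  res <- prm$res
  pic <- vapply(seq_len(ncol(x$calls)), function(j)
    marker_stats(x$calls[, j])$pic, numeric(1))
  ord_rank <- order(x$markers$chrom, x$markers$pos)
  pos_rank <- match(seq_along(ord_rank), ord_rank)

  unresolved <- rep(TRUE, nrow(res))
  chosen <- integer(0)
  steps <- integer(0)
  repeat {
    gain <- colSums(res[unresolved, , drop = FALSE])
    gain[chosen] <- -1L
    if (max(gain) <= 0L) break
    best <- which(gain == max(gain))
    best <- best[order(-pic[best], pos_rank[best])][1L]
    chosen <- c(chosen, best)
    unresolved <- unresolved & !res[, best]
    steps <- c(steps, sum(!unresolved))
  }
  pairs_resolved <- sum(!unresolved)
  structure(list(chosen = x$markers$id[chosen], steps = steps,
                 pairs_resolved = pairs_resolved, pairs_total = nrow(res),
                 unresolved_groups = duplicate_groups(
                   x, x$markers$id[chosen], strict = FALSE)),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers resolve %d / %d sample pairs\n",
              length(x$chosen), x$pairs_resolved, x$pairs_total))
  if (length(x$unresolved_groups))
    cat(sprintf("  %d unresolved group(s): %s\n", length(x$unresolved_groups),
                paste(vapply(x$unresolved_groups, paste, character(1),
                             collapse = "/"), collapse = "; ")))
  invisible(x)
}

#' Exact minimal discriminating-marker set by exhaustive search
#'
#' Brute-force oracle for small instances: enumerates marker subsets by
#' increasing size and returns a smallest subset achieving the maximum
#' achievable number of resolved pairs (that of the full marker set).
#'
#' @param x a \code{\link{genotype_matrix}} with at most \code{max_markers}
#'   markers
#' @param max_markers guard on instance size (default 20)
#' @return list: \code{chosen} marker IDs, \code{pairs_resolved},
#'   \code{pairs_total}
#' @export
brute_force_min_set <- function(x, max_markers = 20L) {
  L <- ncol(x$calls)
  if (L > max_markers)
    stop_param("instance too large for exhaustive search (%d > %d markers)",
               L, max_markers)
  prm <- pair_resolution_matrix(x)
  res <- prm$res
  target <- sum(apply(res, 1L, any))
  if (target == 0L)
    return(list(chosen = character(0), pairs_resolved = 0L,
                pairs_total = nrow(res)))
  for (k in seq_len(L)) {
    subsets <- utils::combn(L, k)
    for (ci in seq_len(ncol(subsets))) {
      sel <- subsets[, ci]
      if (sum(apply(res[, sel, drop = FALSE], 1L, any)) == target)
        return(list(chosen = x$markers$id[sel], pairs_resolved = target,
                    pairs_total = nrow(res)))
    }
  }
  stop("unreachable")
}

#' Groups of samples with identical fingerprints
#'
#' Returns groups of >= 2 samples whose call vectors over the given markers
#' are identical. With \code{strict = TRUE} (the default) a missing call is
#' a distinct symbol, matching how identical fingerprints are read off a
#' plate report; with \code{strict = FALSE} groups are the unresolved
#' partition under the conservative rule that missing never discriminates
#' (transitively closed).
#'
#' @param x a \code{\link{genotype_matrix}}
#' @param markers marker IDs to fingerprint over (default: all)
#' @param strict see above
#' @return list of character vectors of sample IDs (possibly empty)
#' @export
duplicate_groups <- function(x, markers = marker_ids(x), strict = TRUE) {
  sub <- x[, markers]
  calls <- sub$calls
  if (strict) {
    code <- apply(calls, 1L, function(r)
      paste(ifelse(is.na(r), MISSING_CODE, r), collapse = "-"))
    grp <- split(rownames(calls), code)
  } else {
    # union-find over pairs not discriminated by any chosen marker
    n <- nrow(calls)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n >= 2L) {
      pr <- utils::combn(n, 2L)
      disc <- rep(FALSE, ncol(pr))
      for (j in seq_len(ncol(calls))) {
        cj <- calls[, j]
        disc <- disc | pair_discriminated(cj[pr[1, ]], cj[pr[2, ]])
      }
      for (pidx in which(!disc)) {
        ri <- find(pr[1, pidx]); rj <- find(pr[2, pidx])
        if (ri != rj) parent[rj] <- ri
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    grp <- split(rownames(calls), roots)
  }
  grp <- grp[lengths(grp) >= 2L]
  names(grp) <- NULL
  lapply(grp, sort)
}
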