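#' Select a core germplasm subset
#'
#' Chooses \code{round(fraction * N)} samples (round half away from zero)
#' maximizing a distance-based diversity objective: \code{"EN"}, the mean
#' entry-to-nearest-entry modified Rogers distance; \code{"MR"} /
#' \code{"CE"}, the mean pairwise modified Rogers / Cavalli-Sforza--Edwards
#' distance among core entries. Optimization is greedy seeding (start from
#' the pair at maximal distance, repeatedly add the sample maximizing the
#' objective) followed by steepest-ascent swap local search, with
#' \code{restarts} additional random restarts; the best set found wins.
#' With \code{enforce_coverage}, any allele present in the full collection
#' but absent from the core triggers a repair swap inserting a carrier, so
#' allele coverage reaches 100\% whenever carriers exist. Deterministic
#' under \code{seed}.
#'
#' @param x a \code{\link{genotype_matrix}}
#' @param fraction sampling intensity in (0, 1); default 0.20
#' @param objective one of "EN", "MR", "CE"
#' @param enforce_coverage repair the core to carry every allele
#' @param restarts number of random restarts after the greedy start
#' @param seed integer seed
#' @return list of class \code{core_selection}: \code{core} (sample IDs),
#'   \code{objective_value}, \code{objective}, \code{n_core}
#' @export
select_core <- function(x, fraction = 0.20,
                        objective = c("EN", "MR", "CE"),
                        enforce_coverage = TRUE, restarts = 5L, seed = 1L) {
  objective <- match.arg(objective)
  if (fraction <= 0 || fraction >= 1) stop_param("fraction must be in (0, 1)")
  N <- nrow(x$calls)
  n_core <- as.integer(sign(fraction * N) * floor(abs(fraction * N) + 0.5))
  if (n_core < 2L) stop_param("fraction yields a core of < 2 entries")

  d <- if (objective == "CE") cavalli_dist(x) else rogers_dist(x)
  obj_fun <- if (objective == "EN") obj_nearest_entry else obj_mean_dist

  carriers <- if (enforce_coverage) allele_carriers(x) else NULL

  run_one <- function(init) {
    set <- local_search(init, d, objective)
    if (enforce_coverage) set <- coverage_repair(set, d, obj_fun, carriers)
    set
  }
  best <- run_one(greedy_seed(d, n_core, objective))
  best_val <- obj_fun(d, best)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      set.seed(derive_seed(seed, 300L + r))
      cand <- run_one(sort(sample.int(N, n_core)))
      val <- obj_fun(d, cand)
      if (val > best_val + 1e-12) { best <- cand; best_val <- val }
    }
  }
  structure(list(core = sort(rownames(x$calls)[best]),
                 objective_value = best_val, objective = objective,
                 n_core = n_core, n_original = N),
            class = "core_selection")
}

#' @export
print.core_selection <- function(x, ...) {
  cat(sprintf("core_selection: %d of %d entries, %s objective = %.4f\n",
              x$n_core, x$n_original, x$objective, x$objective_value))
  invisible(x)
}

obj_mean_dist <- function(d, idx) {
  sub <- d[idx, idx]
  sum(sub) / (length(idx) * (length(idx) - 1L))
}

obj_nearest_entry <- function(d, idx) {
  sub <- d[idx, idx]
  diag(sub) <- Inf
  mean(row_mins(sub))
}

col_mins <- function(m) m[cbind(max.col(-t(m), ties.method = "first"),
                                seq_len(ncol(m)))]

greedy_seed <- function(d, n_core, objective) {
  start <- which(d == max(d), arr.ind = TRUE)[1, ]
  set <- sort(as.integer(start))
  n <- nrow(d)
  while (length(set) < n_core) {
    rest <- setdiff(seq_len(n), set)
    if (objective == "EN") {
      sub <- d[set, set, drop = FALSE]; diag(sub) <- Inf
      nn <- row_mins(sub)
      D_out <- d[set, rest, drop = FALSE]
      vals <- (colSums(pmin(D_out, nn)) + col_mins(D_out)) /
        (length(set) + 1L)
    } else {
      vals <- colSums(d[set, rest, drop = FALSE])   # maximizes mean distance
    }
    set <- sort(c(set, rest[which.max(vals)]))
  }
  set
}

# steepest-ascent swap local search; never decreases the objective.
# Swap deltas are evaluated incrementally (vectorized over all candidate
# insertions for each candidate removal), not by re-scoring subsets.
local_search <- function(set, d, objective, max_passes = 50L) {
  n <- nrow(d)
  k <- length(set)
  obj_fun <- if (objective == "EN") obj_nearest_entry else obj_mean_dist
  cur <- obj_fun(d, set)
  for (pass in seq_len(max_passes)) {
    outside <- setdiff(seq_len(n), set)
    if (length(outside) == 0L) break     # core == full collection
    best_val <- cur
    best_swap <- NULL
    if (objective == "EN") {
      sub <- d[set, set, drop = FALSE]; diag(sub) <- Inf
      # top-2 nearest neighbours within the set, per member
      nn1_j <- max.col(-sub, ties.method = "first")
      nn1 <- sub[cbind(seq_len(k), nn1_j)]
      sub2 <- sub; sub2[cbind(seq_len(k), nn1_j)] <- Inf
      nn2 <- row_mins(sub2)
      for (m in seq_len(k)) {
        keep <- setdiff(seq_len(k), m)
        # nearest neighbour among the remaining members
        nn_m <- ifelse(nn1_j[keep] == m, nn2[keep], nn1[keep])
        D_out <- d[set[keep], outside, drop = FALSE]
        vals <- (colSums(pmin(D_out, nn_m)) + col_mins(D_out)) / k
        i <- which.max(vals)
        if (vals[i] > best_val + 1e-12) {
          best_val <- vals[i]
          best_swap <- c(m, outside[i])
        }
      }
    } else {
      s_all <- as.vector(d[, set, drop = FALSE] %*% rep(1, k))
      tot <- sum(s_all[set])                  # twice the pairwise sum
      # delta(m, c) on the pair-sum: -2 s[m] + 2 s[c] - 2 d[c, m]
      delta <- outer(-2 * s_all[set], 2 * s_all[outside], "+") -
        2 * d[set, outside, drop = FALSE]
      i <- arrayInd(which.max(delta), dim(delta))
      val <- (tot + delta[i[1], i[2]]) / (k * (k - 1L))
      if (val > best_val + 1e-12) {
        best_val <- val
        best_swap <- c(i[1], outside[i[2]])
      }
    }
    if (is.null(best_swap)) break
    set[best_swap[1]] <- best_swap[2]
    set <- sort(set)
    cur <- obj_fun(d, set)
  }
  set
}

# per-allele carrier lists: which samples carry each (marker, base) allele
allele_carriers <- function(x) {
  out <- list()
  for (j in seq_len(ncol(x$calls))) {
    cj <- x$calls[, j]
    for (b in c(x$markers$ref[j], x$markers$alt[j])) {
      has <- which(!is.na(cj) &
                     (substr(cj, 1, 1) == b | substr(cj, 2, 2) == b))
      if (length(has))
        out[[paste0(x$markers$id[j], ":", b)]] <- has
    }
  }
  out
}

# swap in a carrier of each missing allele, removing the entry whose loss
# hurts the objective least among removable (non-essential) entries
coverage_repair <- function(set, d, obj_fun, carriers) {
  repeat {
    covered <- vapply(carriers, function(h) any(h %in% set), logical(1))
    if (all(covered)) break
    h <- carriers[[names(carriers)[!covered][1]]]
    cand_in <- h[!(h %in% set)][1]
    # entries that are the sole in-set carrier of some allele are essential
    sole <- unique(unlist(lapply(carriers, function(cc) {
      inset <- intersect(cc, set)
      if (length(inset) == 1L) inset else integer(0)
    })))
    removable <- setdiff(set, sole)
    if (length(removable) == 0L) removable <- set
    vals <- vapply(removable, function(m)
      obj_fun(d, c(setdiff(set, m), cand_in)), numeric(1))
    set <- sort(c(setdiff(set, removable[which.max(vals)]), cand_in))
  }
  set
}

#' Evaluate a core subset against the full collection
#'
#' Computes the standard core-collection quality indices, allele
#' frequencies taken within the core: mean pairwise modified Rogers (MR)
#' and Cavalli-Sforza--Edwards (CE) distance among core entries; Shannon
#' index SH (per-locus mean of \eqn{-\sum_a p_a \ln p_a}, with the
#' across-locus sum also reported); expected heterozygosity HE (mean gene
#' diversity over loci); mean effective allele number NE
#' (\eqn{1/\sum p^2} per locus); mean PIC; and allele coverage CV, the
#' percentage of the full collection's alleles present in the core.
#'
#' @param x a \code{\link{genotype_matrix}} (the full collection)
#' @param core character vector of core sample IDs (or a
#'   \code{core_selection})
#' @return list of class \code{core_evaluation} with fields n_original,
#'   n_core, MR, CE, SH (per-locus mean), SH_total (across-locus sum), HE,
#'   NE, PIC, CV
#' @export
evaluate_core <- function(x, core) {
  if (inherits(core, "core_selection")) core <- core$core
  if (!all(core %in% rownames(x$calls)))
    stop_param("core contains unknown sample IDs")
  if (length(core) < 2L) stop_param("core must have >= 2 entries")
  sub <- x[core, ]

  mr <- rogers_dist(sub); ce <- cavalli_dist(sub)
  up <- upper.tri(mr)

  per_locus <- lapply(seq_len(ncol(sub$calls)), function(j)
    allele_frequencies(sub$calls[, j]))
  sh <- vapply(per_locus, function(p) -sum(p * log(p)), numeric(1))
  gd <- vapply(per_locus, function(p) 1 - sum(p^2), numeric(1))
  ne <- vapply(per_locus, function(p) 1 / sum(p^2), numeric(1))
  pic <- vapply(seq_len(ncol(sub$calls)), function(j)
    marker_stats(sub$calls[, j])$pic, numeric(1))

  alleles_of <- function(g) {
    unlist(lapply(seq_len(ncol(g$calls)), function(j)
      paste0(g$markers$id[j], ":",
             names(allele_frequencies(g$calls[, j])))))
  }
  full_alleles <- alleles_of(x)
  cv <- 100 * mean(full_alleles %in% alleles_of(sub))

  structure(list(n_original = nrow(x$calls), n_core = length(core),
                 MR = mean(mr[up]), CE = mean(ce[up]),
                 SH = mean(sh), SH_total = sum(sh),
                 HE = mean(gd), NE = mean(ne), PIC = mean(pic), CV = cv),
            class = "core_evaluation")
}

#' @export
print.core_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("core_evaluation: %d/%d entries\n",
           "  MR %.3f  CE %.3f  SH %.3f (total %.2f)  HE %.3f  NE %.3f",
           "  PIC %.3f  CV %.1f%%\n"),
    x$n_core, x$n_original, x$MR, x$CE, x$SH, x$SH_total, x$HE, x$NE,
    x$PIC, x$CV))
  invisible(x)
}
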