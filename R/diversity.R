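#' Allele frequencies at one marker
#'
#' Each non-missing diploid call contributes two allele observations;
#' missing calls are excluded entirely (never counted as an allele).
#'
#' @param calls character vector of two-letter calls (\code{NA} = missing)
#' @return named numeric vector of allele frequencies, summing to 1
#' @examples
#' allele_frequencies(c("AA", "AG", "GG")) # A 0.5, G 0.5
#' @export
allele_frequencies <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) stop_param("all calls missing at this marker")
  al <- c(substr(calls, 1, 1), substr(calls, 2, 2))
  tab <- table(al)
  p <- as.numeric(tab) / length(al)
  names(p) <- names(tab)
  p
}

#' Per-marker diversity statistics
#'
#' PowerMarker-style statistics computed from genotype counts (no
#' Hardy-Weinberg assumption): gene diversity \eqn{GD = 1 - \sum_i p_i^2},
#' observed heterozygosity He (fraction of non-missing calls that are
#' heterozygous), polymorphic information content
#' \eqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}, minor- and
#' major-allele frequencies. For biallelic markers PIC <= GD <= 0.5, with
#' PIC maximal (0.375) at p = 0.5.
#'
#' @param calls character vector of two-letter calls (\code{NA} = missing)
#' @return one-row data.frame: maf, major_freq, gd, he, pic, n_nonmissing
#' @export
marker_stats <- function(calls) {
  p <- allele_frequencies(calls)
  nonmiss <- calls[!is.na(calls)]
  het <- substr(nonmiss, 1, 1) != substr(nonmiss, 2, 2)
  gd <- 1 - sum(p^2)
  # sum over unordered allele pairs of 2 p_i^2 p_j^2
  pp <- outer(p^2, p^2)
  pic <- gd - sum(pp[upper.tri(pp)]) * 2
  data.frame(maf = if (length(p) > 1L) min(p) else 0,
             major_freq = max(p),
             gd = gd, he = mean(het), pic = pic,
             n_nonmissing = length(nonmiss))
}

#' Panel-level diversity summary
#'
#' Per-marker statistics for every marker plus column means and ranges.
#' Both the minor-allele frequency and the major/alternate allele
#' frequencies are reported as separate labelled columns: published "MAF"
#' ranges exceeding 0.5 can only refer to a major or alternate frequency,
#' so all candidates are emitted rather than guessed between.
#'
#' @param x a \code{\link{genotype_matrix}}
#' @return list of class \code{panel_summary}: \code{per_marker} data.frame
#'   (one row per marker, including alt_freq) and \code{overall}
#'   (mean/min/max per statistic)
#' @export
panel_summary <- function(x) {
  if (ncol(x$calls) == 0L) stop_param("no markers in panel")
  rows <- lapply(seq_len(ncol(x$calls)), function(j) {
    st <- marker_stats(x$calls[, j])
    p <- allele_frequencies(x$calls[, j])
    st$alt_freq <- if (x$markers$alt[j] %in% names(p))
      p[[x$markers$alt[j]]] else 0
    cbind(data.frame(id = x$markers$id[j], chrom = x$markers$chrom[j],
                     pos = x$markers$pos[j], stringsAsFactors = FALSE), st)
  })
  per_marker <- do.call(rbind, rows)
  stats_cols <- c("maf", "major_freq", "alt_freq", "gd", "he", "pic")
  overall <- data.frame(
    statistic = stats_cols,
    mean = vapply(stats_cols, function(k) mean(per_marker[[k]]), numeric(1)),
    min = vapply(stats_cols, function(k) min(per_marker[[k]]), numeric(1)),
    max = vapply(stats_cols, function(k) max(per_marker[[k]]), numeric(1)),
    row.names = NULL)
  structure(list(per_marker = per_marker, overall = overall),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel_summary: %d markers\n", nrow(x$per_marker)))
  print(x$overall, digits = 3)
  invisible(x)
}
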