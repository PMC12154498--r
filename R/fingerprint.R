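#' Fingerprint colour map
#'
#' The genotype-class colour encoding of the fingerprint barcode figure:
#' homozygotes AA yellow, CC green, GG blue, TT purple; every heterozygote
#' gray; missing (NN) white. Total and mutually exclusive over genotype
#' classes.
#' @return named character vector of colours
#' @export
fingerprint_colormap <- function() {
  c(AA = "#F4D03F", CC = "#2ECC71", GG = "#3498DB", TT = "#8E44AD",
    het = "#95A5A6", NN = "#FFFFFF")
}

#' Encode one sample's genotype vector as a fingerprint string
#'
#' Markers are taken in fixed (chrom, pos) order so codes are comparable
#' across runs; heterozygotes are canonicalized alphabetically and missing
#' calls rendered as NN. Encoding is injective on genotype vectors.
#'
#' @param x a \code{\link{genotype_matrix}}
#' @param sample one sample ID
#' @param markers marker IDs defining the panel (default: all markers of
#'   \code{x}); every requested marker must exist
#' @return a single string like \code{"AA-AG-NN"}
#' @export
encode_fingerprint <- function(x, sample, markers = NULL) {
  if (is.null(markers)) {
    ord <- marker_order(x)
    markers <- x$markers$id[ord]
  }
  missing_mk <- setdiff(markers, x$markers$id)
  if (length(missing_mk))
    stop_param("marker(s) absent from the matrix: %s",
               paste(missing_mk, collapse = ", "))
  if (!sample %in% rownames(x$calls))
    stop_param("unknown sample: %s", sample)
  calls <- x$calls[sample, markers]
  paste(ifelse(is.na(calls), MISSING_CODE, calls), collapse = "-")
}

#' Fingerprints for every sample of a panel
#'
#' @inheritParams encode_fingerprint
#' @return data.frame with columns \code{sample} and \code{code}
#' @export
fingerprints <- function(x, markers = NULL) {
  data.frame(sample = rownames(x$calls),
             code = vapply(rownames(x$calls), function(s)
               encode_fingerprint(x, s, markers), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two fingerprints marker by marker
#'
#' @param a,b fingerprint strings over the same marker order
#' @return list with disjoint counts \code{matches}, \code{mismatches},
#'   \code{incomparable} (either side NN), summing to the code length
#' @export
compare_fingerprints <- function(a, b) {
  va <- strsplit(a, "-", fixed = TRUE)[[1]]
  vb <- strsplit(b, "-", fixed = TRUE)[[1]]
  if (length(va) != length(vb))
    stop_param("fingerprints have different marker counts (%d vs %d)",
               length(va), length(vb))
  inc <- va == MISSING_CODE | vb == MISSING_CODE
  list(matches = sum(!inc & va == vb),
       mismatches = sum(!inc & va != vb),
       incomparable = sum(inc))
}

#' Plot the fingerprint matrix
#'
#' Renders the barcode figure: one row per marker, one column per sample,
#' cells coloured by genotype class (\code{\link{fingerprint_colormap}}).
#' Returns the underlying code table invisibly; pass \code{file} to write
#' the sidecar TSV of codes alongside.
#'
#' @param x a \code{\link{genotype_matrix}}
#' @param markers marker IDs to plot (default: all, in (chrom, pos) order)
#' @param file optional path for the sidecar TSV of fingerprint codes
#' @param colormap named colours as in \code{\link{fingerprint_colormap}}
#' @return the \code{\link{fingerprints}} data.frame, invisibly
#' @export
plot_fingerprint_matrix <- function(x, markers = NULL, file = NULL,
                                    colormap = fingerprint_colormap()) {
  if (is.null(markers)) markers <- x$markers$id[marker_order(x)]
  sub <- x[, markers]
  calls <- sub$calls
  classes <- c("AA", "CC", "GG", "TT", "het", "NN")
  cls <- matrix("NN", nrow(calls), ncol(calls))
  cls[!is.na(calls)] <- ifelse(
    substr(calls[!is.na(calls)], 1, 1) == substr(calls[!is.na(calls)], 2, 2),
    calls[!is.na(calls)], "het")
  z <- matrix(match(cls, classes), nrow(calls), ncol(calls))
  # image(): rows of z run along x; transpose so markers are rows on screen
  graphics::image(x = seq_len(nrow(calls)), y = seq_len(ncol(calls)),
                  z = z[, rev(seq_len(ncol(calls))), drop = FALSE],
                  col = colormap[classes], zlim = c(1, 6), axes = FALSE,
                  xlab = "sample", ylab = "marker")
  graphics::axis(2, at = seq_len(ncol(calls)), labels = rev(markers),
                 las = 2, cex.axis = 0.5)
  graphics::box()
  fp <- fingerprints(x, markers)
  if (!is.null(file))
    utils::write.table(fp, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(fp)
}

#' Read a fingerprint TSV written by \code{\link{plot_fingerprint_matrix}}
#' @param path TSV with columns sample, code
#' @return data.frame with columns sample, code
#' @export
read_fingerprints <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
}
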