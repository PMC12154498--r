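#' Genotype matrix of diploid base-pair calls
#'
#' The central data container of the pipeline: an N sample x L marker matrix
#' of unordered diploid base-pair calls ("AA", "AG", ...; \code{NA} = missing),
#' together with per-marker metadata (chromosome, 1-based position, ref and alt
#' alleles). Calls are canonicalized so the two bases of a heterozygote are in
#' alphabetical order, reflecting that KASP reports a genotype class, not a
#' phase. Every call at a marker must use only that marker's ref/alt alleles.
#'
#' @param calls character matrix (samples x markers) of two-letter calls;
#'   \code{NA} or \code{"NN"} denote missing. Row names are sample IDs, column
#'   names marker IDs (defaulted if absent).
#' @param markers data.frame with columns \code{id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, one row per column of \code{calls}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{calls} (canonicalized character matrix) and \code{markers}.
#' @examples
#' mk <- data.frame(id = "m1", chrom = "chr1", pos = 100L, ref = "A", alt = "G")
#' gm <- genotype_matrix(matrix(c("AA", "GA", NA), ncol = 1,
#'                              dimnames = list(c("s1", "s2", "s3"), "m1")), mk)
#' gm$calls[2, 1] # "AG" -- canonicalized
#' @export
genotype_matrix <- function(calls, markers) {
  if (!is.matrix(calls) || !is.character(calls))
    stop_param("`calls` must be a character matrix")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop_param("`markers` must have columns %s", paste(need, collapse = ", "))
  if (nrow(markers) != ncol(calls))
    stop_param("markers (%d) and call columns (%d) disagree",
               nrow(markers), ncol(calls))
  if (anyDuplicated(markers$id)) stop_param("marker IDs must be unique")
  if (any(markers$ref == markers$alt)) stop_param("ref and alt must differ")
  if (any(markers$pos < 1L)) stop_param("positions are 1-based, must be >= 1")
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (anyDuplicated(rownames(calls))) stop_param("sample IDs must be unique")
  colnames(calls) <- markers$id

  calls[calls %in% c(MISSING_CODE, "")] <- NA_character_
  ok <- is.na(calls) | nchar(calls) == 2L
  if (!all(ok))
    stop_param("malformed calls (need two bases): %s",
               paste(unique(calls[!ok]), collapse = ", "))
  al <- call_alleles(calls)
  calls[] <- ifelse(is.na(calls), NA_character_,
                    canonical_call(al[, 1], al[, 2]))

  # allele-domain validation: each call restricted to its marker's ref/alt
  bad <- character(0)
  for (j in seq_len(ncol(calls))) {
    allowed <- c(markers$ref[j], markers$alt[j])
    cj <- calls[, j]
    viol <- !is.na(cj) &
      !(substr(cj, 1, 1) %in% allowed & substr(cj, 2, 2) %in% allowed)
    if (any(viol))
      bad <- c(bad, paste0(rownames(calls)[viol], "/", markers$id[j],
                           "=", cj[viol]))
  }
  if (length(bad))
    stop_param("calls outside the marker's ref/alt alleles: %s",
               paste(bad, collapse = "; "))

  structure(list(calls = calls, markers = markers), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls), 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param x a \code{genotype_matrix}
#' @param i sample index (integer, logical or sample-ID character vector)
#' @param j marker index (integer, logical or marker-ID character vector)
#' @param ... unused
#' @return a \code{genotype_matrix}
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(j)) j <- match(j, x$markers$id)
  calls <- x$calls[i, j, drop = FALSE]
  structure(list(calls = calls,
                 markers = x$markers[j, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Sample and marker accessors
#' @param x a \code{genotype_matrix}
#' @return character vector of IDs
#' @export
sample_ids <- function(x) rownames(x$calls)

#' @rdname sample_ids
#' @export
marker_ids <- function(x) x$markers$id

#' Alternate-allele dosage matrix
#'
#' Converts base-pair calls to counts of the alt allele (0, 1, 2; \code{NA}
#' for missing), the encoding used by the admixture model and PCA.
#'
#' @param x a \code{genotype_matrix}
#' @return integer matrix, samples x markers
#' @export
gt_dosage <- function(x) {
  al <- x$calls
  out <- matrix(NA_integer_, nrow(al), ncol(al), dimnames = dimnames(al))
  for (j in seq_len(ncol(al))) {
    alt <- x$markers$alt[j]
    cj <- al[, j]
    out[, j] <- (substr(cj, 1, 1) == alt) + (substr(cj, 2, 2) == alt)
  }
  out
}

# order markers by (chrom, pos): the canonical fingerprint order
marker_order <- function(x) order(x$markers$chrom, x$markers$pos)
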