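#' Read and write genotype-call tables
#'
#' The canonical interchange table: CSV/TSV with the first column holding
#' sample IDs and one column per marker; cells are two-letter base calls
#' ("AA", "AG"), with "NN" or an empty cell meaning missing. Heterozygote
#' order is irrelevant on input ("GA" == "AG"). Marker metadata (chrom, pos,
#' ref, alt) can be supplied as a sidecar table; without it, ref/alt are
#' inferred from the observed alleles (major allele as ref) and positions
#' default to the column index.
#'
#' @param path file path; the delimiter is inferred from the extension
#'   (".csv" = comma, otherwise tab).
#' @param markers optional marker metadata: a data.frame or a path to a
#'   TSV/CSV with columns id, chrom, pos, ref, alt.
#' @return \code{read_genotype_table}: a \code{\link{genotype_matrix}}.
#' @export
read_genotype_table <- function(path, markers = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NN", "NA", ""))
  calls <- as.matrix(df)
  if (!is.null(markers)) {
    if (is.character(markers)) {
      msep <- if (grepl("\\.csv$", markers, ignore.case = TRUE)) "," else "\t"
      markers <- utils::read.table(markers, header = TRUE, sep = msep,
                                   stringsAsFactors = FALSE)
    }
    markers <- markers[match(colnames(calls), markers$id), , drop = FALSE]
  } else {
    markers <- infer_marker_meta(calls)
  }
  genotype_matrix(calls, markers)
}

# infer ref/alt from observed alleles; positions fall back to column index
infer_marker_meta <- function(calls) {
  meta <- lapply(seq_len(ncol(calls)), function(j) {
    cj <- calls[!is.na(calls[, j]), j]
    al <- c(substr(cj, 1, 1), substr(cj, 2, 2))
    tab <- sort(table(factor(al, levels = DNA_BASES)), decreasing = TRUE)
    tab <- tab[tab > 0]
    if (length(tab) > 2L)
      stop_param("marker %s has >2 observed alleles", colnames(calls)[j])
    ref <- names(tab)[1] %||% "A"
    alt <- if (length(tab) >= 2L) names(tab)[2] else setdiff(DNA_BASES, ref)[1]
    data.frame(id = colnames(calls)[j], chrom = "un", pos = j,
               ref = ref, alt = alt, stringsAsFactors = FALSE)
  })
  do.call(rbind, meta)
}

#' @rdname read_genotype_table
#' @param x a \code{genotype_matrix}
#' @param markers_path optional path for a sidecar marker-metadata TSV
#' @return \code{write_genotype_table}: the input, invisibly.
#' @export
write_genotype_table <- function(x, path, markers_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- x$calls
  out[is.na(out)] <- MISSING_CODE
  df <- data.frame(sample = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(markers_path))
    utils::write.table(x$markers, markers_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(x)
}

#' Export a genotype matrix in STRUCTURE's two-row-per-sample format
#'
#' Alleles are recoded A,C,G,T -> 1..4 and missing calls as -9, two data rows
#' per sample (one allele per row), the layout STRUCTURE-family programs read.
#'
#' @param x a \code{genotype_matrix}
#' @param path optional output file; when NULL the lines are returned
#' @return character vector of lines, invisibly when written to \code{path}
#' @export
export_structure_format <- function(x, path = NULL) {
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  n <- nrow(x$calls)
  lines <- character(2L * n)
  for (i in seq_len(n)) {
    ci <- x$calls[i, ]
    a1 <- ifelse(is.na(ci), -9L, code[substr(ci, 1, 1)])
    a2 <- ifelse(is.na(ci), -9L, code[substr(ci, 2, 2)])
    lines[2L * i - 1L] <- paste(c(rownames(x$calls)[i], a1), collapse = "\t")
    lines[2L * i] <- paste(c(rownames(x$calls)[i], a2), collapse = "\t")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
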