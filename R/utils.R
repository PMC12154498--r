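# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

MISSING_CODE <- "NN"

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation from one master seed; kept < 2^31 - 1
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 7919 + offset * 104729) %% 2147483646) + 1L
}

# canonical unordered diploid call: two bases, alphabetically sorted ("GA" -> "AG")
canonical_call <- function(a1, a2) {
  swap <- a1 > a2
  paste0(ifelse(swap, a2, a1), ifelse(swap, a1, a2))
}

call_alleles <- function(calls) {
  calls <- as.vector(calls)
  cbind(substr(calls, 1L, 1L), substr(calls, 2L, 2L))
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", vapply(seq, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# all permutations of 1..n as a matrix (n! rows); used for ancestry label matching
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    m <- cbind(k, sub + (sub >= k))
    out[[k]] <- m
  }
  do.call(rbind, out)
}

# row-wise minimum of a numeric matrix (fast path via max.col)
row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
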