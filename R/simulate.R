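#' Population model for synthetic genotype panels
#'
#' Describes an admixed diploid panel: K ancestral populations whose per-locus
#' allele frequencies are drawn from a Beta prior (optionally truncated to a
#' frequency range), sample ancestries drawn from a symmetric Dirichlet, and
#' i.i.d. missingness applied per call. This is the statistical structure the
#' downstream stages (diversity statistics, admixture EM, Evanno selection,
#' core selection) assume, so every stage can be exercised without real data.
#'
#' @param n_pops K, number of ancestral populations (>= 1)
#' @param n_loci L, number of biallelic markers
#' @param n_samples N, number of samples
#' @param freq_prior Beta(a, b) shape parameters for ancestral allele
#'   frequencies; the default Beta(0.2, 0.2) yields strongly diverged
#'   populations (frequencies piled near 0 and 1)
#' @param freq_range optional truncation interval for the frequency prior,
#'   e.g. \code{c(0.3, 0.7)} for mid-frequency markers
#' @param admix_alpha symmetric Dirichlet concentration for ancestry rows;
#'   small values (default 0.05) give near-pure ancestry
#' @param missing_rate per-call missingness probability in [0, 1)
#' @param seed master seed; all sub-stage seeds derive from it
#' @return an object of class \code{population_model}
#' @export
population_model <- function(n_pops = 8L, n_loci = 32L, n_samples = 280L,
                             freq_prior = c(0.2, 0.2), freq_range = c(0, 1),
                             admix_alpha = 0.05, missing_rate = 0,
                             seed = 1L) {
  if (n_pops < 1L || n_loci < 1L || n_samples < 1L)
    stop_param("n_pops, n_loci, n_samples must all be >= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_param("missing_rate must lie in [0, 1)")
  if (admix_alpha <= 0) stop_param("admix_alpha must be > 0")
  if (any(freq_prior <= 0)) stop_param("freq_prior shapes must be > 0")
  if (freq_range[1] < 0 || freq_range[2] > 1 || freq_range[1] >= freq_range[2])
    stop_param("freq_range must be an interval within [0, 1]")
  structure(list(n_pops = as.integer(n_pops), n_loci = as.integer(n_loci),
                 n_samples = as.integer(n_samples), freq_prior = freq_prior,
                 freq_range = freq_range, admix_alpha = admix_alpha,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "population_model")
}

# Beta(a,b) truncated to [lo, hi] via the inverse-CDF
rbeta_trunc <- function(n, a, b, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, a, b), stats::pbeta(hi, a, b))
  stats::qbeta(u, a, b)
}

rdirichlet <- function(n, alpha, k) {
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n)
  # guard against all-zero rows at tiny alpha (numerically possible)
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, sample.int(k, sum(zero), replace = TRUE)] <- 1
  g / rowSums(g)
}

# the 12 ordered ref/alt base pairs ("A/C", "A/G", ..., "T/G")
ordered_base_pairs <- function() {
  pairs <- expand.grid(alt = DNA_BASES, ref = DNA_BASES,
                       stringsAsFactors = FALSE)[, 2:1]
  pairs <- pairs[pairs$ref != pairs$alt, ]
  rownames(pairs) <- NULL
  pairs
}

#' Simulate an admixed genotype panel
#'
#' Ancestral frequencies P (K x L) are drawn from the model's Beta prior,
#' ancestry rows Q (N x K) from a symmetric Dirichlet, and each genotype as
#' two Bernoulli allele draws with success probability
#' \eqn{f_{ij} = \sum_k Q_{ik} P_{kj}}. Ref/alt bases are assigned per locus
#' uniformly from the 12 ordered base pairs; missingness is applied i.i.d.
#' per call. Fully reproducible under the model's seed.
#'
#' @param model a \code{\link{population_model}}
#' @return an object of class \code{simulated_panel}: list with
#'   \code{genotypes} (a \code{\link{genotype_matrix}}), \code{true_Q},
#'   \code{true_P}, \code{duplicate_groups}, plus the pre-missingness calls
#'   and the missingness mask (used by \code{\link{plant_duplicates}}).
#' @examples
#' panel <- simulate_panel(population_model(n_pops = 2, n_loci = 6,
#'                                          n_samples = 10, seed = 7))
#' panel$genotypes
#' @export
simulate_panel <- function(model) {
  stopifnot(inherits(model, "population_model"))
  K <- model$n_pops; L <- model$n_loci; N <- model$n_samples

  set.seed(derive_seed(model$seed, 1L))
  P <- matrix(rbeta_trunc(K * L, model$freq_prior[1], model$freq_prior[2],
                          model$freq_range[1], model$freq_range[2]),
              nrow = K)
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)

  set.seed(derive_seed(model$seed, 2L))
  Q <- if (K == 1L) matrix(1, N, 1L) else rdirichlet(N, model$admix_alpha, K)

  set.seed(derive_seed(model$seed, 3L))
  f <- Q %*% P
  dosage <- matrix(stats::rbinom(N * L, size = 2L, prob = f), nrow = N)

  set.seed(derive_seed(model$seed, 4L))
  pairs <- ordered_base_pairs()
  pick <- sample.int(12L, L, replace = TRUE)
  markers <- data.frame(id = sprintf("M%03d", seq_len(L)),
                        chrom = sprintf("chr%02d", ((seq_len(L) - 1L) %% 12L) + 1L),
                        pos = 1000L * seq_len(L),
                        ref = pairs$ref[pick], alt = pairs$alt[pick],
                        stringsAsFactors = FALSE)

  calls <- dosage_to_calls(dosage, markers)
  rownames(calls) <- sprintf("S%03d", seq_len(N))

  set.seed(derive_seed(model$seed, 5L))
  mask <- matrix(stats::runif(N * L) < model$missing_rate, nrow = N)

  panel <- structure(list(calls_complete = calls, missing_mask = mask,
                          true_Q = Q, true_P = P, markers = markers,
                          duplicate_groups = list(), model = model),
                     class = "simulated_panel")
  panel$genotypes <- apply_missing(panel)
  panel
}

dosage_to_calls <- function(dosage, markers) {
  N <- nrow(dosage); L <- ncol(dosage)
  calls <- matrix(NA_character_, N, L)
  for (j in seq_len(L)) {
    r <- markers$ref[j]; a <- markers$alt[j]
    lv <- c(paste0(r, r), canonical_call(r, a), paste0(a, a))
    calls[, j] <- lv[dosage[, j] + 1L]
  }
  colnames(calls) <- markers$id
  calls
}

apply_missing <- function(panel) {
  calls <- panel$calls_complete
  calls[panel$missing_mask] <- NA_character_
  genotype_matrix(calls, panel$markers)
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf("simulated_panel: N=%d, L=%d, K=%d, %d duplicate group(s)\n",
              nrow(x$true_Q), ncol(x$true_P), ncol(x$true_Q),
              length(x$duplicate_groups)))
  invisible(x)
}

#' Plant duplicate samples into a simulated panel
#'
#' Within each group, every sample's pre-missingness call vector is copied
#' from the group's first member, then the panel's original missingness mask
#' is re-applied. Emulates accessions deposited under several names whose
#' genotyping results are identical.
#'
#' @param panel a \code{\link{simulate_panel}} result
#' @param groups list of integer vectors of sample indices; groups must be
#'   disjoint
#' @return the panel with duplicates planted and \code{duplicate_groups} set
#' @export
plant_duplicates <- function(panel, groups) {
  stopifnot(inherits(panel, "simulated_panel"))
  if (length(groups) == 0L) return(panel)
  idx <- unlist(groups)
  if (anyDuplicated(idx)) stop_param("duplicate groups must be disjoint")
  if (any(idx < 1L | idx > nrow(panel$calls_complete)))
    stop_param("sample index out of range")
  for (g in groups) {
    g <- sort(as.integer(g))
    panel$calls_complete[g[-1L], ] <-
      rep(panel$calls_complete[g[1L], ], each = length(g) - 1L)
  }
  panel$duplicate_groups <- lapply(groups, function(g) sort(as.integer(g)))
  panel$genotypes <- apply_missing(panel)
  panel
}

#' Simulate a toy VCF variant set for screening tests
#'
#' Sites are placed uniformly over the given chromosome lengths except a
#' \code{clustered_fraction} planted within 100 bp of another site (to
#' exercise flank isolation). Annotations (QD, MQ, MQRankSum,
#' ReadPosRankSum, DP, QUAL) are drawn from comfortable passing ranges,
#' with \code{n_violate[field]} sites per field planted below/above its
#' hard-filter threshold. Genotypes are drawn binomially at per-site alt
#' frequencies uniform in \code{maf_range}.
#'
#' @param n_sites number of SNP sites
#' @param n_samples number of samples
#' @param chrom_lengths named numeric vector, chromosome -> length in bp
#' @param n_violate named integer vector: how many sites violate each of
#'   QD, MQ, MQRankSum, ReadPosRankSum, DP, QUAL (disjoint site sets)
#' @param clustered_fraction fraction of sites planted within 100 bp of
#'   another site
#' @param maf_range range of per-site alt-allele frequencies
#' @param missing_rate per-call missing probability
#' @param seed integer seed
#' @return a \code{\link{variant_set}} with attribute \code{"planted"}
#'   recording the planted violations and clustered sites
#' @export
simulate_vcf <- function(n_sites, n_samples,
                         chrom_lengths = c(chr01 = 1e6, chr02 = 1e6),
                         n_violate = c(), clustered_fraction = 0,
                         maf_range = c(0.05, 0.95), missing_rate = 0,
                         seed = 1L) {
  if (length(chrom_lengths) == 0L) stop_param("chrom_lengths must be non-empty")
  set.seed(derive_seed(seed, 11L))
  chrom <- sample(names(chrom_lengths), n_sites, replace = TRUE,
                  prob = chrom_lengths / sum(chrom_lengths))
  pos <- floor(stats::runif(n_sites, 1, chrom_lengths[chrom])) + 0

  n_clust <- round(clustered_fraction * n_sites)
  clustered <- integer(0)
  if (n_clust > 0L) {
    clustered <- sample.int(n_sites, n_clust)
    anchors <- sample(setdiff(seq_len(n_sites), clustered), n_clust,
                      replace = TRUE)
    chrom[clustered] <- chrom[anchors]
    pos[clustered] <- pmax(1, pos[anchors] +
                             sample(c(-1, 1), n_clust, TRUE) *
                             sample.int(100L, n_clust, TRUE))
  }

  pairs <- ordered_base_pairs()
  pick <- sample.int(12L, n_sites, replace = TRUE)

  ann <- data.frame(
    QD = stats::runif(n_sites, 5, 35),
    MQ = stats::runif(n_sites, 50, 60),
    MQRankSum = stats::runif(n_sites, -2, 2),
    ReadPosRankSum = stats::runif(n_sites, -2, 2),
    DP = round(stats::runif(n_sites, 10, 40) * n_samples),
    QUAL = stats::runif(n_sites, 100, 2000))
  viol_vals <- list(QD = c(0.1, 1.9), MQ = c(10, 39.9),
                    MQRankSum = c(-20, -12.6), ReadPosRankSum = c(-15, -8.1),
                    DP = c(0, 3) , QUAL = c(1, 29))
  planted <- list()
  avail <- seq_len(n_sites)
  for (k in names(n_violate)) {
    m <- n_violate[[k]]
    if (m == 0L) next
    sel <- sort(sample(avail, m))
    avail <- setdiff(avail, sel)
    lohi <- viol_vals[[k]]
    ann[[k]][sel] <- stats::runif(m, lohi[1], lohi[2])
    if (k == "DP") ann$DP[sel] <- round(stats::runif(m, 0, 3) * n_samples)
    planted[[k]] <- sel
  }

  # genotypes: binomial at uniform alt frequency
  set.seed(derive_seed(seed, 12L))
  p_alt <- stats::runif(n_sites, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n_sites * n_samples, 2L, rep(p_alt, n_samples)),
                nrow = n_sites)
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = n_sites)
  if (missing_rate > 0)
    gt[matrix(stats::runif(length(gt)) < missing_rate, nrow = n_sites)] <-
      NA_character_
  samples <- sprintf("S%03d", seq_len(n_samples))
  colnames(gt) <- samples
  dp_per_sample <- pmax(matrix(stats::rpois(n_sites * n_samples,
                                            ann$DP / n_samples),
                               nrow = n_sites), 1L)
  colnames(dp_per_sample) <- samples

  ord <- order(chrom, pos)
  sites <- data.frame(chrom = chrom, pos = as.integer(pos),
                      id = sprintf("snp%05d", seq_len(n_sites)),
                      ref = pairs$ref[pick], alt = pairs$alt[pick],
                      qual = ann$QUAL, QD = ann$QD, MQ = ann$MQ,
                      MQRankSum = ann$MQRankSum,
                      ReadPosRankSum = ann$ReadPosRankSum, DP = ann$DP,
                      stringsAsFactors = FALSE)
  vs <- variant_set(sites[ord, ], gt[ord, , drop = FALSE],
                    dp_per_sample[ord, , drop = FALSE], samples)
  attr(vs, "planted") <- list(
    violations = lapply(planted, function(s) sites$id[s]),
    clustered = sites$id[clustered])
  vs
}

#' Simulate a flanking-sequence template for assay design
#'
#' Returns a sequence of length \code{2 * flank_len + 1} with a biallelic SNP
#' at the centre and base composition targeting \code{gc_target}.
#'
#' @param flank_len flank length in bp on each side (>= 20)
#' @param gc_target target GC fraction in [0, 1]
#' @param alleles optional length-2 vector of SNP alleles (ref, alt)
#' @param seed integer seed
#' @return list with \code{seq} (character), \code{snp_pos} (centre, 1-based),
#'   \code{ref}, \code{alt}
#' @export
simulate_flank_template <- function(flank_len = 100L, gc_target = 0.4,
                                    alleles = NULL, seed = 1L) {
  if (flank_len < 20L) stop_param("flank_len must be >= 20")
  set.seed(derive_seed(seed, 21L))
  n <- 2L * flank_len + 1L
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, T = (1 - gc_target) / 2)
  bases <- sample(DNA_BASES, n, replace = TRUE, prob = probs)
  if (is.null(alleles)) {
    pairs <- ordered_base_pairs()
    alleles <- unlist(pairs[sample.int(12L, 1L), ], use.names = FALSE)
  }
  bases[flank_len + 1L] <- alleles[1]
  list(seq = paste(bases, collapse = ""), snp_pos = flank_len + 1L,
       ref = alleles[1], alt = alleles[2])
}

#' Write flank templates as FASTA
#' @param templates named list of \code{\link{simulate_flank_template}} results
#' @param path output FASTA path
#' @return \code{path}, invisibly
#' @export
write_template_fasta <- function(templates, path) {
  lines <- unlist(lapply(names(templates), function(nm) {
    t <- templates[[nm]]
    c(sprintf(">%s pos=%d ref=%s alt=%s", nm, t$snp_pos, t$ref, t$alt), t$seq)
  }))
  writeLines(lines, path)
  invisible(path)
}
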