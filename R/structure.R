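#' Maximum-likelihood admixture model fitted by EM
#'
#' Fits the classic admixture likelihood for diploid biallelic genotypes:
#' with dosage \eqn{g_{ij} \in \{0,1,2\}} and
#' \eqn{f_{ij} = \sum_k Q_{ik} P_{kj}},
#' \deqn{LL = \sum_{ij} g_{ij} \ln f_{ij} + (2 - g_{ij}) \ln (1 - f_{ij}),}
#' maximized over ancestry proportions Q (N x K, rows on the simplex) and
#' ancestral allele frequencies P (K x L) by EM block updates from random
#' initialization (Dirichlet(1,...,1) rows for Q, Uniform(0.2, 0.8) for P).
#' Missing dosages are excluded from every sum. The best of
#' \code{n_restarts} random restarts is returned; all replicate final
#' log-likelihoods are retained for Evanno-style model selection. The EM
#' log-likelihood is non-decreasing at every iteration (asserted).
#'
#' @param x a \code{\link{genotype_matrix}} of biallelic markers
#' @param K number of ancestral populations (1 <= K <= N)
#' @param n_restarts number of random restarts
#' @param max_iter maximum EM iterations per restart
#' @param tol absolute log-likelihood convergence tolerance
#' @param seed integer seed (restart seeds derive from it)
#' @return object of class \code{admix_fit}: Q, P, loglik, n_iter,
#'   converged, seed, K, and \code{replicate_logliks}
#' @examples
#' panel <- simulate_panel(population_model(n_pops = 2, n_loci = 24,
#'                                          n_samples = 40, seed = 3))
#' fit <- fit_admixture(panel$genotypes, K = 2, n_restarts = 2, seed = 1)
#' fit
#' @export
fit_admixture <- function(x, K, n_restarts = 5L, max_iter = 2000L,
                          tol = 1e-6, seed = 1L) {
  G <- gt_dosage(x)
  N <- nrow(G); L <- ncol(G)
  if (K < 1L) stop_param("K must be >= 1")
  if (K > N) stop_param("K (%d) exceeds the number of samples (%d)", K, N)
  fits <- lapply(seq_len(n_restarts), function(r)
    admix_em_once(G, K, max_iter, tol, derive_seed(seed, 100L * K + r)))
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- fits[[which.max(lls)]]
  structure(c(best, list(K = K, seed = as.integer(seed),
                         replicate_logliks = lls,
                         samples = rownames(G), markers = colnames(G))),
            class = "admix_fit")
}

admix_em_once <- function(G, K, max_iter, tol, seed) {
  set.seed(seed)
  N <- nrow(G); L <- ncol(G)
  eps <- 1e-6
  miss <- is.na(G)
  G0 <- ifelse(miss, 0, G)          # zero-filled for matrix algebra
  G2 <- ifelse(miss, 0, 2 - G)
  Li <- rowSums(!miss)
  if (any(Li == 0L)) stop_param("a sample has no non-missing genotypes")

  Q <- if (K == 1L) matrix(1, N, 1L) else rdirichlet(N, 1, K)
  P <- matrix(stats::runif(K * L, 0.2, 0.8), nrow = K)

  loglik_of <- function(th) {
    f <- pmin(pmax(th$Q %*% th$P, eps), 1 - eps)
    sum(G0 * log(f) + G2 * log(1 - f))
  }
  # one EM block update of (Q, P); jointly valid M-step of the
  # complete-data model with latent per-allele ancestries
  em_step <- function(th) {
    f <- pmin(pmax(th$Q %*% th$P, eps), 1 - eps)
    R1 <- G0 / f
    R0 <- G2 / (1 - f)
    A <- th$P * crossprod(th$Q, R1)      # K x L expected alt-copy counts
    B <- (1 - th$P) * crossprod(th$Q, R0)
    Qn <- th$Q * (R1 %*% t(th$P) + R0 %*% t(1 - th$P)) / (2 * Li)
    list(Q = Qn / rowSums(Qn), P = pmin(pmax(A / (A + B), eps), 1 - eps))
  }
  project <- function(th) {
    th$Q <- pmax(th$Q, 1e-9); th$Q <- th$Q / rowSums(th$Q)
    th$P <- pmin(pmax(th$P, eps), 1 - eps)
    th
  }

  # SQUAREM-accelerated EM with a monotone safeguard: every accepted step
  # has log-likelihood >= the plain double-EM step it replaces
  th <- list(Q = Q, P = P)
  ll <- loglik_of(th)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    th1 <- em_step(th)
    th2 <- em_step(th1)
    ll2 <- loglik_of(th2)
    r_q <- th1$Q - th$Q;  v_q <- th2$Q - th1$Q - r_q
    r_p <- th1$P - th$P;  v_p <- th2$P - th1$P - r_p
    vnorm <- sqrt(sum(v_q^2) + sum(v_p^2))
    cand <- th2
    ll_new <- ll2
    if (vnorm > 0) {
      alpha <- -sqrt(sum(r_q^2) + sum(r_p^2)) / vnorm
      alpha <- min(alpha, -1)
      acc <- project(list(Q = th$Q - 2 * alpha * r_q + alpha^2 * v_q,
                          P = th$P - 2 * alpha * r_p + alpha^2 * v_p))
      acc <- em_step(acc)   # stabilization step keeps us in the EM flow
      ll_acc <- loglik_of(acc)
      if (is.finite(ll_acc) && ll_acc > ll2) { cand <- acc; ll_new <- ll_acc }
    }
    if (ll_new < ll - 1e-6)
      stop("internal error: EM log-likelihood decreased")  # invariant guard
    delta <- ll_new - ll
    th <- cand; ll <- ll_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(Q = th$Q, P = th$P, loglik = ll, n_iter = it, converged = converged)
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf(
    "admix_fit: K=%d, N=%d, L=%d, logLik=%.2f (%d iter%s, %d restarts)\n",
    x$K, nrow(x$Q), ncol(x$P), x$loglik, x$n_iter,
    if (x$converged) ", converged" else "", length(x$replicate_logliks)))
  invisible(x)
}

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(object$loglik, df = (nrow(object$Q) * (object$K - 1) +
                                   object$K * ncol(object$P)),
            class = "logLik")
}

#' @export
coef.admix_fit <- function(object, ...) object$Q

#' Match ancestry labels between two Q matrices
#'
#' Finds the column permutation of \code{Q_est} minimizing the mean
#' row-wise maximum absolute error against \code{Q_true} (exhaustive over
#' permutations, feasible for K <= 8).
#'
#' @param Q_est,Q_true N x K ancestry matrices
#' @return list: \code{perm}, \code{Q_matched}, \code{mean_row_max_err}
#' @export
match_ancestry_labels <- function(Q_est, Q_true) {
  K <- ncol(Q_true)
  stopifnot(ncol(Q_est) == K, K <= 8L)
  perms <- all_perms(K)
  errs <- apply(perms, 1L, function(pm)
    mean(apply(abs(Q_est[, pm, drop = FALSE] - Q_true), 1L, max)))
  best <- which.min(errs)
  list(perm = perms[best, ], Q_matched = Q_est[, perms[best, ], drop = FALSE],
       mean_row_max_err = errs[best])
}

#' Evanno delta-K model selection table
#'
#' From replicate log-likelihoods over a consecutive range of K:
#' \eqn{L'(K) = \bar L(K) - \bar L(K-1)},
#' \eqn{|L''(K)| = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)|}, and
#' \eqn{\Delta K = |L''(K)| / sd_L(K)}, defined for interior K only.
#' \code{best_K} is the interior argmax of delta-K, ties broken toward
#' smaller K (preferring the smallest K with the highest support); K values
#' with zero replicate standard deviation are flagged and excluded.
#'
#' Replicate log-likelihoods from a converged optimizer can agree to within
#' its convergence tolerance, where the sample sd measures numerical noise
#' rather than run-to-run variability; the denominator is therefore floored
#' at \code{sd_floor} (default 1 log-likelihood unit, about one genotype
#' call's contribution) so that delta-K is not dominated by sd values below
#' the optimizer's resolution. The table always reports the raw sd.
#'
#' @param logliks named list (or matrix with rownames) mapping each K to a
#'   numeric vector of replicate log-likelihoods (>= 2 per K, >= 3
#'   consecutive K values)
#' @param sd_floor minimum effective replicate sd used in the delta-K
#'   denominator
#' @return list of class \code{evanno_table}: \code{table} data.frame (K,
#'   mean_L, sd_L, Lp, Lpp_abs, delta_K, flagged) and \code{best_K}
#' @export
evanno_delta_k <- function(logliks, sd_floor = 1) {
  if (is.matrix(logliks))
    logliks <- stats::setNames(asplit(logliks, 1L), rownames(logliks))
  Ks <- as.integer(names(logliks))
  if (length(Ks) < 3L || any(diff(Ks) != 1L))
    stop_param("need >= 3 consecutive K values")
  if (any(lengths(logliks) < 2L))
    stop_param("need >= 2 replicates per K")
  mean_L <- vapply(logliks, mean, numeric(1))
  sd_L <- vapply(logliks, stats::sd, numeric(1))
  n <- length(Ks)
  Lp <- c(NA, diff(mean_L))
  Lpp <- c(NA, abs(mean_L[-(1:2)] - 2 * mean_L[2:(n - 1)] +
                     mean_L[1:(n - 2)]), NA)
  delta <- Lpp / pmax(sd_L, sd_floor)
  flagged <- sd_L == 0
  delta[flagged] <- NA_real_
  tab <- data.frame(K = Ks, mean_L = mean_L, sd_L = sd_L, Lp = Lp,
                    Lpp_abs = Lpp, delta_K = delta, flagged = flagged,
                    row.names = NULL)
  interior <- tab[!is.na(tab$delta_K), ]
  best_K <- if (nrow(interior)) {
    top <- interior$delta_K == max(interior$delta_K)
    min(interior$K[top])
  } else NA_integer_
  structure(list(table = tab, best_K = best_K), class = "evanno_table")
}

#' @export
print.evanno_table <- function(x, ...) {
  print(x$table, digits = 4)
  cat(sprintf("best K by delta-K: %s\n", x$best_K))
  invisible(x)
}

#' Admixture fits over a range of K plus Evanno selection
#'
#' Runs \code{n_replicates} independent replicate fits per K (the analogue
#' of replicate clustering runs) and feeds their log-likelihoods to the
#' Evanno calculation. Each replicate is itself the best of
#' \code{inner_restarts} EM starts, so that every replicate log-likelihood
#' is a reliable estimate of the maximized likelihood at that K rather
#' than an artefact of one bad starting point; the replicate-to-replicate
#' spread then reflects genuine optimization variability.
#'
#' @param x a \code{\link{genotype_matrix}}
#' @param k_range inclusive range of K values
#' @param n_replicates replicate fits per K for the Evanno table
#' @param inner_restarts EM starts within each replicate fit
#' @param seed integer seed
#' @param ... passed to \code{\link{fit_admixture}}
#' @return list: \code{fits} (the best \code{admix_fit} per K),
#'   \code{replicate_logliks} (K x replicate matrix), \code{evanno}
#'   (an \code{evanno_table}), \code{best_K}
#' @export
structure_scan <- function(x, k_range = c(2L, 10L), n_replicates = 10L,
                           inner_restarts = 3L, seed = 1L, ...) {
  Ks <- seq(k_range[1], k_range[2])
  fits <- vector("list", length(Ks))
  names(fits) <- Ks
  rep_ll <- matrix(NA_real_, length(Ks), n_replicates,
                   dimnames = list(Ks, NULL))
  for (ki in seq_along(Ks)) {
    K <- Ks[ki]
    reps <- lapply(seq_len(n_replicates), function(r)
      fit_admixture(x, K, n_restarts = inner_restarts,
                    seed = derive_seed(seed, 1000L * K + r), ...))
    rep_ll[ki, ] <- vapply(reps, function(f) f$loglik, numeric(1))
    fits[[ki]] <- reps[[which.max(rep_ll[ki, ])]]
  }
  ev <- evanno_delta_k(rep_ll)
  list(fits = fits, replicate_logliks = rep_ll, evanno = ev,
       best_K = ev$best_K)
}

#' Genotype principal component analysis
#'
#' Dosage matrix, column mean-imputed for missing calls, column-centered
#' and scaled by \eqn{\sqrt{p(1-p)}} (Patterson-style SNP scaling), then
#' decomposed by SVD. Zero-variance (monomorphic) columns are dropped with
#' a warning. Scores are deterministic up to sign.
#'
#' @param x a \code{\link{genotype_matrix}} (>= 2 samples, >= 2 markers)
#' @param n_components number of components to return
#' @return list of class \code{genotype_pca}: \code{scores} (N x
#'   n_components), \code{explained} (variance fractions, non-increasing)
#' @export
genotype_pca <- function(x, n_components = 3L) {
  G <- gt_dosage(x)
  if (nrow(G) < 2L || ncol(G) < 2L) stop_param("need >= 2 samples and markers")
  p <- colMeans(G, na.rm = TRUE) / 2
  for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- 2 * p[j]
  keep <- p > 0 & p < 1
  if (!all(keep)) {
    warning(sprintf("dropping %d zero-variance marker(s)", sum(!keep)))
    G <- G[, keep, drop = FALSE]; p <- p[keep]
  }
  X <- sweep(G, 2L, 2 * p)
  X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
  sv <- svd(X)
  n_components <- min(n_components, length(sv$d))
  ev <- sv$d^2
  scores <- sv$u[, seq_len(n_components), drop = FALSE] *
    rep(sv$d[seq_len(n_components)], each = nrow(X))
  rownames(scores) <- rownames(G)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 explained = ev[seq_len(n_components)] / sum(ev)),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples, explained %s\n", nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}
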