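#' Pipeline configuration
#'
#' One list of every tunable of the end-to-end pipeline, defaulting to the
#' published assay and analysis settings where one exists (flank isolation
#' 100 bp, frequency window 0.30--0.70, product <= 120 bp, GC < 60\%,
#' Tm 55--62 \eqn{\degree}C, K range 2--10 with 10 replicates, core
#' sampling intensity 0.20) and to the study-scale panel (280 samples, 32
#' markers, 8 ancestral populations) elsewhere. Serializable to JSON.
#'
#' @param ... overrides for any default field
#' @return a list of class \code{pipeline_config}
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # synthetic panel (the study conditions)
    n_samples = 280L, n_loci = 32L, k_true = 8L,
    freq_prior = c(0.2, 0.2), admix_alpha = 0.05, missing_rate = 0.02,
    duplicate_groups = list(c(19L, 20L, 21L, 48L)),
    # toy VCF + screening
    n_sites = 400L, n_vcf_samples = 49L, clustered_fraction = 0.1,
    thresholds = filter_thresholds(), n_target = 224L,
    # assay design
    max_product = 120L, gc_max = 0.60, tm_range = c(55, 62),
    n_assays = 8L, flank_len = 100L,
    # marker QC
    marker_missing_threshold = 0.20, sample_missing_threshold = 0.50,
    # structure / Evanno
    k_range = c(2L, 10L), n_restarts = 10L, em_max_iter = 2000L,
    em_tol = 1e-6,
    # PCA, core markers, core collection
    n_components = 3L, core_fraction = 0.20, core_objective = "EN",
    core_restarts = 5L, enforce_coverage = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_param("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end demonstration pipeline
#'
#' Exercises every stage on synthetic data: simulate a toy VCF and screen it
#' (funnel report), design KASP assays on simulated flank templates,
#' simulate an admixed genotype panel with planted duplicates, run marker
#' QC, diversity statistics, Nei DA neighbor-joining tree, the admixture
#' K-scan with Evanno selection, PCA, greedy core-marker selection, core
#' collection selection/evaluation and fingerprint encoding. All artifacts
#' are written under \code{out_dir} together with a manifest of MD5 hashes;
#' re-running with the same config and seed reproduces the hashes.
#'
#' @param config a \code{\link{pipeline_config}}
#' @param out_dir writable output directory (created if needed)
#' @param seed master seed for every stage
#' @return list of class \code{demo_run} with the in-memory stage results
#'   and \code{manifest} (file -> MD5)
#' @export
run_demo <- function(config = pipeline_config(), out_dir = tempfile("demo"),
                     seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  res <- list()

  # 1. variant screening on a toy VCF
  vs <- simulate_vcf(config$n_sites, config$n_vcf_samples,
                     n_violate = c(QD = 10L, MQ = 10L),
                     clustered_fraction = config$clustered_fraction,
                     maf_range = c(0.1, 0.9), seed = derive_seed(seed, 1L))
  write_vcf(vs, path("input.vcf"))
  screen <- screen_snps(vs, config$thresholds,
                        n_target = min(config$n_target, length(vs)))
  write_screen_report(screen, path("screen_report.json"))
  write_vcf(screen$kept, path("candidates.vcf"))
  utils::write.table(screen$kept$sites, path("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res$screen <- screen

  # 2. KASP assay design on simulated flank templates
  n_assay <- min(config$n_assays, length(screen$kept))
  assays <- lapply(seq_len(n_assay), function(i) {
    tpl <- simulate_flank_template(config$flank_len, gc_target = 0.45,
                                   alleles = c(screen$kept$sites$ref[i],
                                               screen$kept$sites$alt[i]),
                                   seed = derive_seed(seed, 40L + i))
    design_assay(tpl, config$max_product, config$gc_max, config$tm_range,
                 marker_id = screen$kept$sites$id[i])
  })
  ok <- vapply(assays, inherits, logical(1), "kasp_assay")
  if (any(ok)) {
    sheet <- do.call(rbind, lapply(assays[ok], function(a)
      data.frame(marker = a$marker, fam_primer = a$fam_primer,
                 hex_primer = a$hex_primer, common_primer = a$common_primer,
                 product = a$product_size, tm_fam = a$tm[["fam"]],
                 tm_hex = a$tm[["hex"]], tm_common = a$tm[["common"]])))
    utils::write.table(sheet, path("assays.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  jsonlite::write_json(lapply(assays[!ok], unclass), path("assay_failures.json"),
                       auto_unbox = TRUE, digits = NA)
  res$assays <- assays

  # 3. genotype panel with planted duplicates
  model <- population_model(config$k_true, config$n_loci, config$n_samples,
                            freq_prior = config$freq_prior,
                            admix_alpha = config$admix_alpha,
                            missing_rate = config$missing_rate,
                            seed = derive_seed(seed, 2L))
  panel <- simulate_panel(model)
  dup <- Filter(function(g) all(g <= config$n_samples),
                config$duplicate_groups)
  panel <- plant_duplicates(panel, dup)
  gm <- panel$genotypes
  write_genotype_table(gm, path("genotypes.csv"), path("markers.tsv"))
  export_structure_format(gm, path("genotypes.structure.txt"))
  res$panel <- panel

  # 4. marker QC + diversity statistics
  qc <- marker_qc(gm, config$marker_missing_threshold,
                  config$sample_missing_threshold)
  utils::write.table(qc$markers, path("marker_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- panel_summary(gm)
  utils::write.table(summ$per_marker, path("diversity_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$qc <- qc; res$summary <- summ

  # 5. distance + NJ tree
  d <- nei_da_dist(gm)
  write_distance_matrix(d, path("nei_da.tsv"))
  tree <- neighbor_joining(d)
  write_newick(tree, path("nj_tree.nwk"))
  res$tree <- tree

  # 6. structure scan + Evanno, PCA
  scan <- structure_scan(gm, config$k_range,
                         n_replicates = config$n_restarts,
                         seed = derive_seed(seed, 3L),
                         max_iter = config$em_max_iter, tol = config$em_tol)
  utils::write.table(scan$evanno$table, path("evanno.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bestQ <- scan$fits[[as.character(scan$best_K)]]$Q
  utils::write.csv(data.frame(sample = sample_ids(gm), bestQ),
                   path("ancestry_Q.csv"), row.names = FALSE)
  pca <- genotype_pca(gm, config$n_components)
  utils::write.csv(data.frame(sample = rownames(pca$scores), pca$scores),
                   path("pca_scores.csv"), row.names = FALSE)
  res$scan <- scan; res$pca <- pca

  # 7. core markers, core collection, fingerprints
  ms <- greedy_min_marker_set(gm)
  utils::write.table(data.frame(step = seq_along(ms$chosen),
                                marker = ms$chosen,
                                pairs_resolved = ms$steps),
                     path("core_markers.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(ms$unresolved_groups, path("unresolved_groups.json"))
  core <- select_core(gm, config$core_fraction,
                      objective = config$core_objective,
                      enforce_coverage = config$enforce_coverage,
                      restarts = config$core_restarts,
                      seed = derive_seed(seed, 4L))
  ev <- evaluate_core(gm, core)
  jsonlite::write_json(c(list(core = core$core), unclass(ev)),
                       path("core_collection.json"), auto_unbox = TRUE,
                       digits = NA)
  fp <- fingerprints(gm, ms$chosen)
  utils::write.table(fp, path("fingerprints.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  grDevices::pdf(path("fingerprint_matrix.pdf"), width = 8, height = 6)
  plot_fingerprint_matrix(gm, ms$chosen)
  grDevices::dev.off()
  res$core_markers <- ms; res$core <- core; res$core_eval <- ev

  # manifest: hashes of every text artifact (the determinism contract);
  # PDF output embeds a creation timestamp and is excluded
  files <- sort(setdiff(list.files(out_dir),
                        c("manifest.json",
                          grep("\\.pdf$", list.files(out_dir), value = TRUE))))
  manifest <- list(seed = seed,
                   files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  res$manifest <- manifest$files
  res$out_dir <- out_dir
  structure(res, class = "demo_run")
}

#' @export
print.demo_run <- function(x, ...) {
  cat(sprintf("demo_run: %d artifacts in %s; best K = %s; core %d/%d\n",
              length(x$manifest), x$out_dir, x$scan$best_K,
              x$core_eval$n_core, x$core_eval$n_original))
  invisible(x)
}
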