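#' Read a cohort CSV
#'
#' Reads and validates a cohort table with columns
#' `subject_id,sex,age,etiology,thr,disc,ident` (optional trailing
#' `latent_profile`). Malformed rows are rejected with their line numbers
#' (line 1 is the header). CRLF and LF files parse identically.
#'
#' @param path CSV path.
#' @param etiologies Allowed etiology labels.
#' @return An `olf_cohort` data.frame.
#' @export
read_cohort <- function(path, etiologies = olf_etiologies()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "etiology", "thr", "disc", "ident")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop("cohort file misses column(s): ", paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(d)) + 1L
  fail <- function(col, bad, why) {
    if (any(bad))
      stop(sprintf("invalid '%s' (%s) at line(s) %s", col, why,
                   paste(utils::head(line[bad], 10L), collapse = ", ")))
  }
  fail("sex", !(d$sex %in% c("M", "F")), "must be M or F")
  fail("etiology", !(d$etiology %in% etiologies), "unknown label")
  fail("age", !is.finite(d$age) | d$age < 0 | d$age > 120, "implausible age")
  fail("thr", !is.finite(d$thr) | d$thr < 1 | d$thr > 16 |
         abs(d$thr * 4 - round(d$thr * 4)) > 1e-9,
       "must lie in [1, 16] on the 0.25 grid")
  fail("disc", !is.finite(d$disc) | d$disc < 0 | d$disc > 16 |
         d$disc != round(d$disc), "must be an integer in [0, 16]")
  fail("ident", !is.finite(d$ident) | d$ident < 0 | d$ident > 16 |
         d$ident != round(d$ident), "must be an integer in [0, 16]")
  class(d) <- c("olf_cohort", "data.frame")
  d
}

#' Write a cohort CSV
#'
#' @param cohort Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / read mixture models as JSON
#'
#' @param models Named list of `olf_gmm` models.
#' @param path JSON path.
#' @return `write_models()`: `path` invisibly; `read_models()`: named list of
#'   `olf_gmm` models (parameters only).
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m)
    list(subtest = m$subtest, w = m$w, mu = m$mu, sigma = m$sigma))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_models
#' @export
read_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(m)
    structure(list(w = m$w, mu = m$mu, sigma = m$sigma, m = length(m$w),
                   subtest = m$subtest), class = "olf_gmm"))
}

#' Pipeline configuration
#'
#' One configuration object drives every stage of [run_pipeline()]. Defaults
#' follow the reference analysis: 3 Gaussians per subtest, a 50 x 80 toroidal
#' grid (4,000 units), 30 training epochs.
#'
#' @param n_subjects Synthetic cohort size (ignored when `cohort_path` set).
#' @param cohort_path Optional path of a cohort CSV to analyze instead of
#'   simulating one.
#' @param seed Global seed; per-stage seeds default to `seed`, `seed + 1`,
#'   `seed + 2`, `seed + 3` (cohort, mixture, ESOM, radius subsample).
#' @param seeds Optional named list overriding the per-stage seeds
#'   (`cohort`, `gmm`, `esom`, `radius`).
#' @param m_gaussians Mixture components per subtest.
#' @param pde_quantile Pareto-radius quantile.
#' @param rows,cols,epochs ESOM grid dimensions and training epochs.
#' @param lr,kernel ESOM learning-rate range and neighborhood kernel.
#' @param radius ESOM neighborhood radius range (default `c(rows/2, 1)`).
#' @param threshold_quantile,min_basin_units Watershed parameters, see
#'   [cluster_landscape()].
#' @param tdi_cutoffs TDI diagnosis cutoffs, see [classify_tdi()].
#' @param sign_convention relDiff sign convention, see [rel_diff()].
#' @param exclude Etiologies excluded from the association analysis
#'   (e.g. `"Healthy"`).
#' @param out_dir Optional directory; when set, all intermediate artifacts
#'   are written there as CSV/JSON.
#' @return A list of class `olf_config`.
#' @export
olf_config <- function(n_subjects = 10714L, cohort_path = NULL, seed = 1L,
                       seeds = NULL, m_gaussians = 3L, pde_quantile = 0.18,
                       rows = 50L, cols = 80L, epochs = 30L,
                       lr = c(0.5, 0.05), radius = NULL,
                       kernel = "gaussian",
                       threshold_quantile = 0.5, min_basin_units = 5L,
                       tdi_cutoffs = c(anosmia = 16.5, normosmia = 30.5),
                       sign_convention = "exp_minus_obs",
                       exclude = NULL, out_dir = NULL) {
  seed <- as.integer(seed)
  default_seeds <- list(cohort = seed, gmm = seed + 1L, esom = seed + 2L,
                        radius = seed + 3L)
  if (!is.null(seeds)) default_seeds[names(seeds)] <- lapply(seeds, as.integer)
  structure(list(
    n_subjects = as.integer(n_subjects), cohort_path = cohort_path,
    seed = seed, seeds = default_seeds,
    m_gaussians = as.integer(m_gaussians), pde_quantile = pde_quantile,
    rows = as.integer(rows), cols = as.integer(cols),
    epochs = as.integer(epochs), lr = lr, radius = radius, kernel = kernel,
    threshold_quantile = threshold_quantile,
    min_basin_units = as.integer(min_basin_units),
    tdi_cutoffs = tdi_cutoffs, sign_convention = sign_convention,
    exclude = exclude, out_dir = out_dir
  ), class = "olf_config")
}

write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full pattern-discovery pipeline
#'
#' Executes, in order: cohort simulation (or loading), sex-specific age
#' correction and TDI diagnosis, per-subtest Pareto density estimation and
#' Gaussian-mixture featurization into Bayesian posteriors, toroidal ESOM
#' training, U-/P-/U*-matrix computation, watershed cluster extraction, and
#' the cluster-versus-etiology association statistics. Identical
#' configuration (including seeds) yields identical artifacts.
#'
#' @param config An [olf_config()].
#' @param keep_objects Keep the heavyweight intermediates (features, grid,
#'   landscapes) in the returned report.
#' @return A list of class `olf_report`; see the package vignette for the
#'   fields.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(olf_config(n_subjects = 500, rows = 12, cols = 18,
#'                                epochs = 10, seed = 7))
#' rep$k
#' rep$cluster_medians
#' }
run_pipeline <- function(config = olf_config(), keep_objects = TRUE) {
  stopifnot(inherits(config, "olf_config"))
  say <- function(...) message(sprintf(...))

  if (!is.null(config$cohort_path)) {
    say("stage cohort: reading %s", config$cohort_path)
    cohort <- read_cohort(config$cohort_path)
  } else {
    say("stage cohort: simulating n = %d (seed %d)",
        config$n_subjects, config$seeds$cohort)
    cohort <- generate_cohort(default_cohort_config(
      n_subjects = config$n_subjects, seed = config$seeds$cohort))
  }

  say("stage preprocess: sex-specific linear age correction; TDI cutoffs %.1f / %.1f",
      config$tdi_cutoffs[["anosmia"]], config$tdi_cutoffs[["normosmia"]])
  corrected <- age_sex_correct(cohort)
  diagnosis <- classify_tdi(cohort$thr, cohort$disc, cohort$ident,
                            cutoffs = config$tdi_cutoffs)

  say("stage mixture: m = %d Gaussians per subtest, PDE quantile %.2f (seed %d)",
      config$m_gaussians, config$pde_quantile, config$seeds$gmm)
  models <- fit_subtest_models(corrected, m = config$m_gaussians,
                               seed = config$seeds$gmm, q = config$pde_quantile)
  features <- build_feature_matrix(corrected, models)

  say("stage esom: %d x %d toroidal grid, %d epochs (seed %d)",
      config$rows, config$cols, config$epochs, config$seeds$esom)
  grid <- train_esom(features, rows = config$rows, cols = config$cols,
                     epochs = config$epochs, seed = config$seeds$esom,
                     lr = config$lr, radius = config$radius,
                     kernel = config$kernel)
  bmus <- bmu(grid, features)
  U <- umatrix(grid)
  r <- pareto_radius(features, q = config$pde_quantile,
                     seed = config$seeds$radius)
  P <- pmatrix(grid, features, r)
  Ust <- ustar(U, P)

  say("stage cluster: valley threshold quantile %.2f, min basin %d units",
      config$threshold_quantile, config$min_basin_units)
  clusters <- cluster_landscape(grid, Ust, bmus,
                                threshold_quantile = config$threshold_quantile,
                                min_basin_units = config$min_basin_units)

  if (clusters$k >= 2L) {
    say("stage associate: chi-squared + relDiff (%s)%s", config$sign_convention,
        if (length(config$exclude))
          paste0(", excluding ", paste(config$exclude, collapse = ", ")) else "")
    assoc <- associate(cohort, clusters, exclude = config$exclude,
                       sign_convention = config$sign_convention)
  } else {
    say("stage associate: skipped (single cluster, no contingency structure)")
    assoc <- NULL
  }
  correlations <- spearman_by_group(cohort, by = "cluster", clusters = clusters)

  cl <- clusters$subject_cluster[match(cohort$subject_id,
                                       names(clusters$subject_cluster))]
  med <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    i <- which(cl == k)
    maj <- if ("latent_profile" %in% names(cohort))
      names(which.max(table(cohort$latent_profile[i]))) else NA_character_
    data.frame(cluster = k, n = length(i),
               thr_median = stats::median(cohort$thr[i]),
               disc_median = stats::median(cohort$disc[i]),
               ident_median = stats::median(cohort$ident[i]),
               majority_profile = maj, stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    config = config,
    n = nrow(cohort),
    diagnosis_counts = table(diagnosis$diagnosis),
    correction = correction_metadata(corrected),
    models = lapply(models, function(m) m[c("w", "mu", "sigma")]),
    pareto_radius = r$r,
    quantization_error = quantization_error(grid, features),
    k = clusters$k,
    cluster_sizes = clusters$sizes,
    cluster_medians = med,
    association = assoc,
    correlations = correlations,
    objects = if (keep_objects)
      list(cohort = cohort, corrected = corrected, models = models,
           features = features, grid = grid, bmus = bmus,
           U = U, P = P, Ustar = Ust, clusters = clusters)
  ), class = "olf_report")

  if (!is.null(config$out_dir)) write_artifacts(report, config$out_dir,
                                                cohort, corrected, models,
                                                features, U, P, Ust,
                                                clusters, assoc, correlations)
  report
}

write_artifacts <- function(report, dir, cohort, corrected, models, features,
                            U, P, Ust, clusters, assoc, correlations) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_cohort(cohort, fp("cohort.csv"))
  utils::write.csv(corrected, fp("corrected.csv"), row.names = FALSE, quote = FALSE)
  write_models(models, fp("models.json"))
  utils::write.csv(data.frame(subject_id = rownames(features), features,
                              check.names = FALSE),
                   fp("features.csv"), row.names = FALSE, quote = FALSE)
  write_matrix_csv(unclass(U), fp("umatrix.csv"))
  write_matrix_csv(unclass(P), fp("pmatrix.csv"))
  write_matrix_csv(unclass(Ust), fp("ustar.csv"))
  utils::write.csv(data.frame(subject_id = names(clusters$subject_cluster),
                              cluster = unname(clusters$subject_cluster)),
                   fp("clusters.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(assoc)) {
    utils::write.csv(as.data.frame(assoc$table$observed), fp("contingency.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(etiology = rownames(assoc$reldiff), assoc$reldiff,
                                check.names = FALSE),
                     fp("reldiff.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(chi2 = assoc$chi2, df = assoc$df, p = assoc$p),
                         fp("association.json"), auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(correlations, fp("correlations.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(dir)
}

#' @export
print.olf_report <- function(x, ...) {
  cat(sprintf("Olfactory subtest pattern discovery: n = %d subjects\n", x$n))
  cat("Diagnoses:", paste(sprintf("%s %d", names(x$diagnosis_counts),
                                  x$diagnosis_counts), collapse = ", "), "\n")
  cat(sprintf("ESOM %d x %d, %d epochs; quantization error %.4f\n",
              x$config$rows, x$config$cols, x$config$epochs,
              x$quantization_error))
  cat(sprintf("Clusters: k = %d\n", x$k))
  print(x$cluster_medians, row.names = FALSE)
  if (!is.null(x$association))
    cat(sprintf("Association: chi-squared = %.4g, df = %d, p %s\n",
                x$association$chi2, x$association$df,
                format.pval(x$association$p, digits = 3, eps = 2.2e-16)))
  invisible(x)
}
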