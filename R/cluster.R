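# toroidal 8-connected component labelling of a logical matrix
label_components <- function(mask) {
  rows <- nrow(mask); cols <- ncol(mask)
  comp <- matrix(NA_integer_, rows, cols)
  offs <- expand.grid(dr = -1:1, dc = -1:1)[-5L, ]
  cid <- 0L
  for (r0 in seq_len(rows)) for (c0 in seq_len(cols)) {
    if (!mask[r0, c0] || !is.na(comp[r0, c0])) next
    cid <- cid + 1L
    stack_r <- r0; stack_c <- c0
    comp[r0, c0] <- cid
    while (length(stack_r)) {
      r <- stack_r[length(stack_r)]; c <- stack_c[length(stack_c)]
      stack_r <- stack_r[-length(stack_r)]; stack_c <- stack_c[-length(stack_c)]
      nr <- torus_shift(r, offs$dr, rows)
      nc <- torus_shift(c, offs$dc, cols)
      for (k in seq_along(nr)) {
        if (mask[nr[k], nc[k]] && is.na(comp[nr[k], nc[k]])) {
          comp[nr[k], nc[k]] <- cid
          stack_r <- c(stack_r, nr[k]); stack_c <- c(stack_c, nc[k])
        }
      }
    }
  }
  comp
}

#' Extract clusters from the U*-matrix landscape
#'
#' Watershed-style surrogate for reading clusters off the landscape: units
#' whose U* height is at or below the `threshold_quantile` of all heights are
#' "valley" units; clusters are the toroidally 8-connected components of the
#' valley set. Components smaller than `min_basin_units` are merged into the
#' component with the nearest mean weight vector. Every subject inherits the
#' cluster of its best matching unit; subjects whose BMU lies on a ridge are
#' assigned to the valley component containing the valley unit nearest in
#' weight space. Cluster ids 1..k are ordered by descending subject count.
#'
#' @param grid An `olf_esom`.
#' @param ustar Height matrix from [ustar()] (any height matrix works).
#' @param bmus BMU table from [bmu()]; row names are subject ids.
#' @param threshold_quantile Valley threshold as a quantile of the heights.
#' @param min_basin_units Minimum basin size before merging.
#' @return A list of class `olf_clusters`: `k`, `unit_cluster` (rows x cols
#'   matrix, `NA` on ridge units), `subject_cluster` (integer vector named by
#'   subject id), `sizes` (subjects per cluster), `threshold`,
#'   `threshold_quantile`.
#' @export
cluster_landscape <- function(grid, ustar, bmus, threshold_quantile = 0.5,
                              min_basin_units = 5L) {
  rows <- nrow(ustar); cols <- ncol(ustar)
  stopifnot(rows == grid$rows, cols == grid$cols)
  thr <- stats::quantile(as.numeric(ustar), threshold_quantile, names = FALSE)
  mask <- unclass(ustar) <= thr
  if (all(mask))
    warning("all units are valley at this threshold; a single cluster results")
  comp <- label_components(mask)
  W <- grid$weights
  # unit index (row-major) per matrix cell
  unit_of <- matrix(seq_len(rows * cols), nrow = rows, byrow = TRUE)

  # merge undersized basins into the component with the nearest mean weight
  repeat {
    ids <- sort(unique(stats::na.omit(as.integer(comp))))
    if (length(ids) <= 1L) break
    usize <- vapply(ids, function(i) sum(comp == i, na.rm = TRUE), integer(1))
    small <- ids[usize < min_basin_units]
    if (!length(small)) break
    tgt <- small[which.min(usize[match(small, ids)])]
    means <- t(vapply(ids, function(i)
      colMeans(W[unit_of[which(comp == i)], , drop = FALSE]), numeric(ncol(W))))
    me <- means[ids == tgt, ]
    others <- ids[ids != tgt]
    d2 <- rowSums((means[match(others, ids), , drop = FALSE] -
                     matrix(me, length(others), ncol(W), byrow = TRUE))^2)
    comp[comp == tgt] <- others[which.min(d2)]
  }

  ids <- sort(unique(stats::na.omit(as.integer(comp))))
  comp_vec <- as.integer(t(comp))  # by unit index, NA for ridge

  # subjects inherit the BMU component; ridge BMUs go to the nearest valley unit
  subj_comp <- comp_vec[bmus$unit]
  if (anyNA(subj_comp)) {
    valley_units <- which(!is.na(comp_vec))
    Wv <- W[valley_units, , drop = FALSE]
    ridge_units <- unique(bmus$unit[is.na(subj_comp)])
    nearest <- vapply(ridge_units, function(u) {
      d2 <- rowSums((Wv - matrix(W[u, ], nrow(Wv), ncol(Wv), byrow = TRUE))^2)
      comp_vec[valley_units[which.min(d2)]]
    }, integer(1))
    subj_comp[is.na(subj_comp)] <- nearest[match(bmus$unit[is.na(subj_comp)], ridge_units)]
  }

  # relabel 1..k by descending subject count (ties: unit count, then old id)
  n_subj <- vapply(ids, function(i) sum(subj_comp == i), integer(1))
  n_unit <- vapply(ids, function(i) sum(comp_vec == i, na.rm = TRUE), integer(1))
  ord <- ids[order(-n_subj, -n_unit, ids)]
  relab <- stats::setNames(seq_along(ord), ord)
  subject_cluster <- unname(relab[as.character(subj_comp)])
  names(subject_cluster) <- rownames(bmus)
  unit_cluster <- matrix(relab[as.character(comp_vec)], nrow = rows, byrow = TRUE)

  structure(list(
    k = length(ids),
    unit_cluster = unit_cluster,
    subject_cluster = subject_cluster,
    sizes = table(cluster = subject_cluster),
    threshold = thr, threshold_quantile = threshold_quantile,
    min_basin_units = min_basin_units
  ), class = "olf_clusters")
}

#' @export
print.olf_clusters <- function(x, ...) {
  cat(sprintf("U*-landscape clustering: k = %d (valley threshold at the %.0f%% height quantile)\n",
              x$k, 100 * x$threshold_quantile))
  print(x$sizes)
  invisible(x)
}

#' Etiology-by-cluster contingency table
#'
#' Cross-tabulates etiology against cluster membership, with optional
#' exclusion of etiologies (e.g. healthy subjects) before margins and
#' expected counts are computed.
#'
#' @param cohort Cohort data.frame with `subject_id` and `etiology`.
#' @param clusters An `olf_clusters` object, or an integer vector of cluster
#'   ids named by subject id.
#' @param exclude Optional character vector of etiology labels to drop.
#' @return A list of class `olf_contingency`: `observed`, `expected`
#'   (`row_total * col_total / grand_total`), `row_totals`, `col_totals`,
#'   `total`.
#' @export
contingency <- function(cohort, clusters, exclude = NULL) {
  cl <- if (inherits(clusters, "olf_clusters")) clusters$subject_cluster else clusters
  idx <- match(cohort$subject_id, names(cl))
  if (anyNA(idx)) stop("every subject needs a cluster assignment")
  keep <- !(cohort$etiology %in% exclude)
  if (!any(keep)) stop("no subjects left after etiology exclusion")
  obs <- table(etiology = cohort$etiology[keep], cluster = cl[idx][keep])
  obs <- unclass(obs)
  rt <- rowSums(obs); ct <- colSums(obs); tot <- sum(obs)
  structure(list(observed = obs, expected = outer(rt, ct) / tot,
                 row_totals = rt, col_totals = ct, total = tot),
            class = "olf_contingency")
}

as_contingency <- function(x) {
  if (inherits(x, "olf_contingency")) return(x)
  obs <- as.matrix(x)
  rt <- rowSums(obs); ct <- colSums(obs)
  structure(list(observed = obs, expected = outer(rt, ct) / sum(obs),
                 row_totals = rt, col_totals = ct, total = sum(obs)),
            class = "olf_contingency")
}

#' Chi-squared test of an etiology-by-cluster table
#'
#' Pearson chi-squared statistic `sum((obs - exp)^2 / exp)` without
#' continuity correction, `df = (r - 1)(c - 1)`, upper-tail p-value.
#'
#' @param table An `olf_contingency` or a plain count matrix.
#' @return A list of class `olf_chisq` with `chi2`, `df`, `p`.
#' @export
chi_square <- function(table) {
  tab <- as_contingency(table)
  if (nrow(tab$observed) < 2L || ncol(tab$observed) < 2L)
    stop("association test needs at least a 2 x 2 table")
  if (any(tab$expected <= 0))
    stop("zero expected count; merge sparse rows or columns before testing")
  ct <- suppressWarnings(stats::chisq.test(tab$observed, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value), class = "olf_chisq")
}

#' @export
print.olf_chisq <- function(x, ...) {
  cat(sprintf("chi-squared = %.4g, df = %d, p %s\n", x$chi2, x$df,
              format.pval(x$p, digits = 3, eps = 2.2e-16)))
  invisible(x)
}

#' Relative difference overrepresentation matrix
#'
#' Cellwise bounded overrepresentation metric
#' `relDiff = (n_expected - n_observed) / (0.5 (n_expected + n_observed))`,
#' with values in \[-2, 2\]. The default sign convention (`"exp_minus_obs"`)
#' is the formula as written, under which overrepresented cells are negative;
#' `"obs_minus_exp"` flips the sign so overrepresentation is positive. Cells
#' with `expected + observed = 0` yield 0 (with a note).
#'
#' @param table An `olf_contingency` or plain count matrix.
#' @param sign_convention `"exp_minus_obs"` (default) or `"obs_minus_exp"`.
#' @return Numeric matrix, same shape as the table.
#' @export
rel_diff <- function(table, sign_convention = c("exp_minus_obs", "obs_minus_exp")) {
  sign_convention <- match.arg(sign_convention)
  tab <- as_contingency(table)
  num <- tab$expected - tab$observed
  den <- 0.5 * (tab$expected + tab$observed)
  out <- num / den
  if (any(den == 0)) {
    message("relDiff: cell(s) with expected + observed = 0 set to 0")
    out[den == 0] <- 0
  }
  if (sign_convention == "obs_minus_exp") out <- -out
  out
}

#' Spearman correlations of the subtest pairs, by subgroup
#'
#' Spearman's rho (average-rank ties) for discrimination/identification,
#' discrimination/threshold and threshold/identification, for the whole
#' cohort ("global") and per group (etiology or cluster). Groups smaller
#' than `min_n` are omitted with a warning.
#'
#' @param cohort Cohort data.frame with `thr`, `disc`, `ident` columns.
#' @param by `"none"` (global only), `"etiology"`, or `"cluster"`.
#' @param clusters Required when `by = "cluster"`: an `olf_clusters` object
#'   or named cluster vector.
#' @param min_n Minimum group size.
#' @return A data.frame with columns `group`, `pair`, `rho`, `n`.
#' @export
spearman_by_group <- function(cohort, by = c("none", "etiology", "cluster"),
                              clusters = NULL, min_n = 3L) {
  by <- match.arg(by)
  pairs <- list(`disc/ident` = c("disc", "ident"),
                `disc/thr` = c("disc", "thr"),
                `thr/ident` = c("thr", "ident"))
  rho_rows <- function(d, label) {
    do.call(rbind, lapply(names(pairs), function(p) {
      v <- pairs[[p]]
      data.frame(group = label, pair = p,
                 rho = stats::cor(d[[v[1]]], d[[v[2]]], method = "spearman"),
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
  }
  out <- rho_rows(cohort, "global")
  if (by != "none") {
    g <- if (by == "etiology") cohort$etiology else {
      cl <- if (inherits(clusters, "olf_clusters")) clusters$subject_cluster else clusters
      if (is.null(cl)) stop("'clusters' required when by = \"cluster\"")
      paste0("cluster ", cl[match(cohort$subject_id, names(cl))])
    }
    for (grp in sort(unique(g))) {
      d <- cohort[g == grp, , drop = FALSE]
      if (nrow(d) < min_n) {
        warning(sprintf("group '%s' has fewer than %d subjects; omitted", grp, min_n))
        next
      }
      out <- rbind(out, rho_rows(d, grp))
    }
  }
  rownames(out) <- NULL
  out
}

#' Cluster-versus-etiology association analysis
#'
#' Combines the contingency table, the chi-squared test and the relDiff
#' overrepresentation matrix into one result.
#'
#' @inheritParams contingency
#' @inheritParams rel_diff
#' @return A list of class `olf_association`: `table` (`olf_contingency`),
#'   `chi2`, `df`, `p`, `reldiff`.
#' @export
associate <- function(cohort, clusters, exclude = NULL,
                      sign_convention = c("exp_minus_obs", "obs_minus_exp")) {
  tab <- contingency(cohort, clusters, exclude = exclude)
  cs <- chi_square(tab)
  structure(list(table = tab, chi2 = cs$chi2, df = cs$df, p = cs$p,
                 reldiff = rel_diff(tab, sign_convention)),
            class = "olf_association")
}

#' @export
print.olf_association <- function(x, ...) {
  cat(sprintf("Etiology x cluster association (%d x %d table)\n",
              nrow(x$table$observed), ncol(x$table$observed)))
  cat(sprintf("chi-squared = %.4g, df = %d, p %s\n", x$chi2, x$df,
              format.pval(x$p, digits = 3, eps = 2.2e-16)))
  invisible(x)
}
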