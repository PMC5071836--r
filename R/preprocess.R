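#' Sex-specific linear age correction of subtest scores
#'
#' Within each sex stratum an ordinary least-squares line `score ~ age` is
#' fitted per subtest; the corrected score is the residual plus the overall
#' (both-sex) mean of that subtest, so corrected scores stay on the clinical
#' scale and carry no linear age trend within either sex. Strata with fewer
#' than two subjects or constant age degenerate to mean-centering (with a
#' warning). Corrected scores are continuous and are not re-rounded.
#'
#' @param cohort A data.frame with columns `sex`, `age` and the subtest
#'   columns named in `subtests`.
#' @param subtests Character vector of score columns to correct.
#' @return `cohort` with appended columns `<subtest>_c` and an attribute
#'   `"correction"`: per subtest the grand mean and per-sex slope/intercept,
#'   retrievable with [correction_metadata()].
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_config(n_subjects = 300, seed = 1))
#' corrected <- age_sex_correct(cohort)
#' correction_metadata(corrected)$thr$fits$M["slope"]
age_sex_correct <- function(cohort, subtests = c("thr", "disc", "ident")) {
  stopifnot(all(c("sex", "age") %in% names(cohort)),
            all(subtests %in% names(cohort)))
  meta <- list()
  for (s in subtests) {
    y <- cohort[[s]]
    grand <- mean(y)
    corrected <- numeric(length(y))
    fits <- list()
    for (sx in unique(cohort$sex)) {
      idx <- which(cohort$sex == sx)
      if (length(idx) < 2L || length(unique(cohort$age[idx])) < 2L) {
        warning(sprintf(
          "sex stratum '%s' has <2 subjects or constant age; '%s' correction degenerates to mean-centering",
          sx, s))
        corrected[idx] <- y[idx] - mean(y[idx]) + grand
        fits[[sx]] <- c(slope = 0, intercept = mean(y[idx]))
      } else {
        fit <- stats::lm(y[idx] ~ cohort$age[idx])
        corrected[idx] <- stats::residuals(fit) + grand
        fits[[sx]] <- c(slope = unname(stats::coef(fit)[2L]),
                        intercept = unname(stats::coef(fit)[1L]))
      }
    }
    cohort[[paste0(s, "_c")]] <- corrected
    meta[[s]] <- list(grand_mean = grand, fits = fits)
  }
  attr(cohort, "correction") <- meta
  cohort
}

#' @rdname age_sex_correct
#' @param corrected A data.frame returned by [age_sex_correct()].
#' @export
correction_metadata <- function(corrected) attr(corrected, "correction")

#' TDI-based olfactory diagnosis
#'
#' The TDI composite is the sum of the threshold, discrimination and
#' identification scores. Subjects with TDI at or below the low cutoff are
#' labelled `anosmia`, at or above the high cutoff `normosmia`, and
#' `hyposmia` in between. Defaults (16.5 / 30.5) follow the established
#' convention for the 16-item three-subtest battery.
#'
#' @param thr,disc,ident Raw subtest scores (threshold in \[1,16\],
#'   discrimination/identification in \[0,16\]).
#' @param cutoffs Numeric vector `c(anosmia = ..., normosmia = ...)`.
#' @return A data.frame with columns `tdi` and `diagnosis` (factor with
#'   levels anosmia < hyposmia < normosmia).
#' @export
#' @examples
#' classify_tdi(16, 16, 16)            # normosmia
#' classify_tdi(1, 2, 3)$diagnosis     # anosmia
classify_tdi <- function(thr, disc, ident,
                         cutoffs = c(anosmia = 16.5, normosmia = 30.5)) {
  if (any(!is.finite(thr)) || any(!is.finite(disc)) || any(!is.finite(ident)))
    stop("scores must be finite")
  if (any(thr < 1 | thr > 16)) stop("'thr' out of range [1, 16]")
  if (any(disc < 0 | disc > 16)) stop("'disc' out of range [0, 16]")
  if (any(ident < 0 | ident > 16)) stop("'ident' out of range [0, 16]")
  if (cutoffs[["anosmia"]] >= cutoffs[["normosmia"]])
    stop("anosmia cutoff must be below the normosmia cutoff")
  tdi <- thr + disc + ident
  label <- ifelse(tdi <= cutoffs[["anosmia"]], "anosmia",
                  ifelse(tdi >= cutoffs[["normosmia"]], "normosmia", "hyposmia"))
  data.frame(tdi = tdi,
             diagnosis = factor(label, levels = c("anosmia", "hyposmia", "normosmia")))
}
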