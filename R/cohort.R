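#' Etiology labels of the reference cohort
#'
#' The nine physiological/pathological conditions used throughout the package,
#' in the order of the reference demographic table.
#'
#' @return Character vector of length 9.
#' @export
olf_etiologies <- function() {
  c("Healthy", "Sinunasal disease", "Congenital", "Neurodegenerative",
    "Idiopathic", "Infectious", "Head trauma", "Toxic", "Tumor/apoplectic")
}

#' Reference cohort demographics
#'
#' Demographic composition of a large (n = 10,714) tertiary smell-clinic
#' cohort covering nine etiologies of normal or altered olfactory function:
#' per-etiology subject counts and age summaries, separately by sex. These
#' counts define the default etiology weights of [default_cohort_config()].
#'
#' @return A data.frame with one row per etiology and columns
#'   `etiology`, `n_men`, `age_mean_men`, `age_sd_men`, `n_women`,
#'   `age_mean_women`, `age_sd_women`.
#' @export
#' @examples
#' d <- reference_demographics()
#' sum(d$n_men + d$n_women)  # 10714
reference_demographics <- function() {
  data.frame(
    etiology      = olf_etiologies(),
    n_men         = c(928L, 852L, 79L, 91L, 928L, 961L, 801L, 52L, 18L),
    age_mean_men  = c(35.9, 56.2, 30.8, 64.4, 61.4, 58.8, 46.9, 60.8, 61.1),
    age_sd_men    = c(16.4, 12.7, 16.3, 10.8, 13.6, 12.6, 15.0, 12.4, 13.1),
    n_women       = c(1171L, 785L, 124L, 67L, 1021L, 2092L, 690L, 38L, 16L),
    age_mean_women = c(35.0, 54.4, 28.9, 64.7, 58.4, 59.8, 51.1, 59.6, 58.0),
    age_sd_women  = c(16.2, 12.8, 16.4, 11.3, 13.9, 11.2, 15.1, 14.6, 14.7),
    stringsAsFactors = FALSE
  )
}

#' Latent olfactory performance profiles
#'
#' The three latent profiles planted by the synthetic generator, mirroring the
#' archetypes seen in clinical three-subtest data: `good` (low threshold
#' dilution detected, i.e. high threshold score, with good discrimination and
#' identification), `abolished` (threshold score at the test floor, near-chance
#' discrimination/identification), and `reduced` (medium threshold, reduced
#' but preserved discrimination/identification).
#'
#' Centers: threshold 13.5 / 1 / 5 dilution steps; discrimination and
#' identification for `abolished` sit at the chance level of the forced-choice
#' tests (16/3 and 16/4 items respectively).
#'
#' @return A data.frame with one row per profile and columns `profile`,
#'   `thr_center`, `thr_sd`, `disc_center`, `disc_sd`, `ident_center`,
#'   `ident_sd`.
#' @export
latent_profiles <- function() {
  data.frame(
    profile      = c("good", "abolished", "reduced"),
    thr_center   = c(13.5, 1.0, 5.0),
    thr_sd       = c(1.5, 0.75, 1.5),
    disc_center  = c(13.5, 16 / 3, 10.0),
    disc_sd      = c(1.5, 2.0, 2.0),
    ident_center = c(13.5, 4.0, 9.0),
    ident_sd     = c(1.5, 2.0, 2.0),
    stringsAsFactors = FALSE
  )
}

default_profile_map <- function() {
  m <- rbind(
    "Healthy"           = c(good = 0.88, abolished = 0.02, reduced = 0.10),
    "Sinunasal disease" = c(good = 0.20, abolished = 0.20, reduced = 0.60),
    "Congenital"        = c(good = 0.01, abolished = 0.95, reduced = 0.04),
    "Neurodegenerative" = c(good = 0.10, abolished = 0.30, reduced = 0.60),
    "Idiopathic"        = c(good = 0.10, abolished = 0.35, reduced = 0.55),
    "Infectious"        = c(good = 0.12, abolished = 0.25, reduced = 0.63),
    "Head trauma"       = c(good = 0.08, abolished = 0.50, reduced = 0.42),
    "Toxic"             = c(good = 0.10, abolished = 0.40, reduced = 0.50),
    "Tumor/apoplectic"  = c(good = 0.10, abolished = 0.45, reduced = 0.45)
  )
  m
}

#' Cohort generator configuration
#'
#' Builds and validates the configuration consumed by [generate_cohort()].
#'
#' @param n_subjects Number of subjects to simulate.
#' @param etiology_weights Named numeric vector of etiology sampling
#'   probabilities; must sum to 1 (within 1e-9).
#' @param profile_map Numeric matrix (etiology x profile) of conditional
#'   probabilities of the latent profiles given the etiology; every row must
#'   sum to 1 (within 1e-9). Column names must match `profiles$profile`.
#' @param profiles Latent profile parameter table, see [latent_profiles()].
#' @param age_range Two-element vector, minimum and maximum age in years;
#'   must lie within \[6, 95\].
#' @param age_mean,age_sd Moments of the (truncated) normal age distribution.
#' @param sex_ratio Probability that a subject is male.
#' @param age_slope_per_subtest Linear age effect in score units per year
#'   applied to all three subtests (negative = decline), relative to the
#'   midpoint of `age_range`.
#' @param seed Integer seed; the same seed yields an identical cohort.
#'
#' @return A list of class `olf_cohort_config`.
#' @seealso [default_cohort_config()], [generate_cohort()]
#' @export
cohort_config <- function(n_subjects,
                          etiology_weights,
                          profile_map,
                          profiles = latent_profiles(),
                          age_range = c(6, 95),
                          age_mean = 52.2,
                          age_sd = 17,
                          sex_ratio = 0.5,
                          age_slope_per_subtest = -0.05,
                          seed = 1L) {
  if (!is_count(n_subjects)) stop("'n_subjects' must be a positive integer count")
  if (is.null(names(etiology_weights)) || any(!nzchar(names(etiology_weights))))
    stop("configuration error in 'etiology_weights': weights must be a named vector")
  if (any(etiology_weights < 0) || abs(sum(etiology_weights) - 1) > 1e-9)
    stop("configuration error in 'etiology_weights': probabilities must be nonnegative and sum to 1")
  profile_map <- as.matrix(profile_map)
  if (is.null(rownames(profile_map)) ||
      !setequal(rownames(profile_map), names(etiology_weights)))
    stop("configuration error in 'profile_map': row names must match names(etiology_weights)")
  if (!setequal(colnames(profile_map), profiles$profile))
    stop("configuration error in 'profile_map': column names must match the profile table")
  bad <- rownames(profile_map)[abs(rowSums(profile_map) - 1) > 1e-9 |
                                 apply(profile_map < 0, 1L, any)]
  if (length(bad))
    stop("configuration error in 'profile_map': row(s) ", paste(bad, collapse = ", "),
         " must be nonnegative and sum to 1")
  if (length(age_range) != 2L || age_range[1] >= age_range[2] ||
      age_range[1] < 6 || age_range[2] > 95)
    stop("configuration error in 'age_range': need [min, max] within [6, 95]")
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("configuration error in 'sex_ratio': must be a probability")
  stopifnot(all(profiles$thr_center >= 1 & profiles$thr_center <= 16),
            all(profiles$disc_center >= 0 & profiles$disc_center <= 16),
            all(profiles$ident_center >= 0 & profiles$ident_center <= 16))
  structure(list(
    n_subjects = as.integer(n_subjects),
    etiology_weights = etiology_weights,
    profile_map = profile_map[names(etiology_weights), profiles$profile, drop = FALSE],
    profiles = profiles,
    age_range = as.numeric(age_range),
    age_mean = age_mean, age_sd = age_sd,
    sex_ratio = sex_ratio,
    age_slope_per_subtest = age_slope_per_subtest,
    seed = as.integer(seed)
  ), class = "olf_cohort_config")
}

#' Default cohort configuration
#'
#' Etiology weights proportional to the reference demographic counts (e.g.
#' Healthy (928+1171)/10714 ~= 0.196), sex ratio equal to the reference male
#' fraction, and a per-etiology latent profile mix in which healthy subjects
#' are mostly `good`, congenital anosmia is almost surely `abolished`, and
#' postinfectious dysfunction is mostly `reduced`.
#'
#' @param n_subjects Cohort size (default: the reference total, 10,714).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [cohort_config()].
#' @return An `olf_cohort_config` object.
#' @export
#' @examples
#' cfg <- default_cohort_config(n_subjects = 500, seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$etiology)
default_cohort_config <- function(n_subjects = 10714L, seed = 1L, ...) {
  d <- reference_demographics()
  counts <- d$n_men + d$n_women
  w <- stats::setNames(counts / sum(counts), d$etiology)
  cohort_config(
    n_subjects = n_subjects,
    etiology_weights = w,
    profile_map = default_profile_map(),
    sex_ratio = sum(d$n_men) / sum(counts),
    seed = seed,
    ...
  )
}

#' Simulate a synthetic olfactory cohort
#'
#' Draws subjects with demographics, etiology, a latent performance profile,
#' and the three raw subtest scores. Scores are drawn from the latent
#' profile's truncated normals, shifted linearly with age relative to the age
#' midpoint, then clipped to the legal range and rounded to the legal grid:
#' threshold to quarter dilution steps in \[1, 16\] (the staircase estimate is
#' a mean of four integer-step reversals), discrimination and identification
#' to integers in \[0, 16\] (16-item forced-choice tests).
#'
#' @param config An `olf_cohort_config`, see [cohort_config()].
#' @return A data.frame of class `olf_cohort` with columns `subject_id`,
#'   `sex` ("M"/"F"), `age` (years), `etiology`, `thr`, `disc`, `ident`,
#'   and `latent_profile` (the planted profile, kept for recovery checks).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "olf_cohort_config"))
    stop("'config' must be created by cohort_config()")
  n <- config$n_subjects
  set.seed(config$seed)

  etiology <- sample(names(config$etiology_weights), n, replace = TRUE,
                     prob = config$etiology_weights)
  sex <- ifelse(stats::runif(n) < config$sex_ratio, "M", "F")
  age <- as.integer(round(rtruncnorm(n, config$age_mean, config$age_sd,
                                     config$age_range[1], config$age_range[2])))

  # latent profile: inverse-CDF draw against the etiology's profile row
  pm <- config$profile_map
  cum <- pm
  if (ncol(pm) > 1L)
    for (j in 2:ncol(pm)) cum[, j] <- cum[, j - 1L] + pm[, j]
  u <- stats::runif(n)
  prof_idx <- rowSums(u > cum[etiology, , drop = FALSE]) + 1L
  latent_profile <- colnames(pm)[prof_idx]

  prof <- config$profiles
  pi <- match(latent_profile, prof$profile)
  mid <- mean(config$age_range)
  shift <- config$age_slope_per_subtest * (age - mid)

  thr <- rtruncnorm(n, prof$thr_center[pi], prof$thr_sd[pi], 1, 16) + shift
  disc <- rtruncnorm(n, prof$disc_center[pi], prof$disc_sd[pi], 0, 16) + shift
  ident <- rtruncnorm(n, prof$ident_center[pi], prof$ident_sd[pi], 0, 16) + shift

  thr <- round_to_step(pmin(pmax(thr, 1), 16), 0.25)
  disc <- as.integer(round(pmin(pmax(disc, 0), 16)))
  ident <- as.integer(round(pmin(pmax(ident, 0), 16)))

  out <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    sex = sex, age = age, etiology = etiology,
    thr = thr, disc = disc, ident = ident,
    latent_profile = latent_profile,
    stringsAsFactors = FALSE
  )
  class(out) <- c("olf_cohort", "data.frame")
  out
}
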