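#' Pareto radius of a data set
#'
#' The hypersphere radius used for Pareto density estimation and for the
#' P-matrix: the `q`-quantile (default 18%) of the empirical pairwise
#' Euclidean distance distribution. For more than `max_points` observations
#' the distance distribution is computed on a seeded subsample (the global
#' RNG state is left untouched).
#'
#' @param x Numeric vector or matrix (rows = observations).
#' @param q Quantile of the pairwise distance distribution.
#' @param max_points Subsample size cap for the pairwise computation.
#' @param seed Seed for the subsample draw.
#' @return A list of class `olf_pareto_radius` with elements `r`, `q`,
#'   `n_used`, `subsampled`.
#' @export
#' @examples
#' pareto_radius(c(0, 1, 2, 4))$r
pareto_radius <- function(x, q = 0.18, max_points = 2000L, seed = 77L) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  if (!all(is.finite(x))) stop("'x' must be finite")
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 points")
  subsampled <- n > max_points
  if (subsampled) {
    rng <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
    set.seed(seed)
    x <- x[sample.int(n, max_points), , drop = FALSE]
    if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  d <- as.numeric(stats::dist(x))
  if (all(d == 0)) stop("zero spread: all points identical")
  r <- unname(stats::quantile(d, q))
  # discretized data can put >q of the pair mass at distance zero; the radius
  # must stay positive whenever the data have spread
  if (r <= 0) r <- min(d[d > 0])
  structure(list(r = r, q = q, n_used = nrow(x), subsampled = subsampled),
            class = "olf_pareto_radius")
}

as_radius <- function(r) {
  if (inherits(r, "olf_pareto_radius")) r$r else as.numeric(r)
}

#' Pareto density estimate
#'
#' Sphere-count density estimate of a univariate sample: the raw density at a
#' grid point is the number of observations within the Pareto radius, which is
#' then normalized so the trapezoidal integral over the grid equals 1.
#'
#' @param x Numeric vector.
#' @param grid Evaluation points; default 200 equally spaced points spanning
#'   the data range extended by one radius on each side.
#' @param r Radius (number or [pareto_radius()] result); computed from `x`
#'   when omitted.
#' @param n_grid Number of default grid points.
#' @param q Quantile passed to [pareto_radius()] when `r` is omitted.
#' @return A list of class `olf_pde` with elements `grid`, `density`
#'   (normalized), `raw` (sphere counts) and `r`.
#' @export
pde <- function(x, grid = NULL, r = NULL, n_grid = 200L, q = 0.18) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("'x' must be finite")
  rr <- as_radius(r %||% pareto_radius(x, q = q))
  if (is.null(grid)) grid <- seq(min(x) - rr, max(x) + rr, length.out = n_grid)
  if (length(grid) == 0L) stop("empty evaluation grid")
  raw <- vapply(grid, function(g) sum(abs(x - g) <= rr), numeric(1))
  dens <- raw
  if (length(grid) > 1L) {
    area <- sum(diff(grid) * (raw[-1L] + raw[-length(raw)]) / 2)
    if (area > 0) dens <- raw / area
  }
  structure(list(grid = grid, density = dens, raw = raw, r = rr),
            class = "olf_pde")
}

gmm_pdf <- function(grid, w, mu, sigma) {
  rowSums(vapply(seq_along(w),
                 function(j) w[j] * stats::dnorm(grid, mu[j], sigma[j]),
                 numeric(length(grid))))
}

#' Fit a univariate Gaussian mixture against the Pareto density estimate
#'
#' Two-phase fit. Phase 1 is expectation-maximization on the raw data with
#' quantile-based initialization of the means; the log-likelihood trace is
#' recorded and is non-decreasing. Phase 2 refines all parameters by
#' least squares between the mixture pdf and the Pareto density estimate on
#' its grid; the refinement is kept only if it does not increase the sum of
#' squared residuals. Components are returned sorted by ascending mean
#' (ties broken by SD).
#'
#' @param x Numeric data vector, `length(x) >= 10 * m`.
#' @param m Number of Gaussian components (3 accommodates low / medium / high
#'   scores in each olfactory subtest).
#' @param seed Seed used when a degenerate component must be re-seeded.
#' @param tol Relative log-likelihood convergence tolerance of the EM phase.
#' @param max_iter EM iteration cap.
#' @param refine Run the least-squares refinement phase.
#' @param q Pareto-radius quantile for the PDE target curve.
#' @param n_grid PDE grid size.
#' @return A list of class `olf_gmm` with `w`, `mu`, `sigma` (each length
#'   `m`, weights summing to 1), `m`, `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `refined`, `ssr` (named: em, refined), `pde`, `subtest`.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(300, 0), rnorm(300, 8))
#' fit <- fit_gmm(x, m = 2)
#' fit$mu
fit_gmm <- function(x, m = 3L, seed = 1L, tol = 1e-8, max_iter = 500L,
                    refine = TRUE, q = 0.18, n_grid = 200L) {
  x <- as.numeric(x)
  n <- length(x)
  if (!all(is.finite(x))) stop("'x' must be finite")
  if (n < 10L * m) stop(sprintf("need at least %d observations for m = %d", 10L * m, m))
  sdx <- stats::sd(x)
  if (sdx == 0) stop("zero spread: all observations identical")
  sigma_floor <- 1e-3 * sdx

  w <- rep(1 / m, m)
  mu <- unname(stats::quantile(x, (2 * seq_len(m) - 1) / (2 * m)))
  sigma <- rep(sdx, m)

  reseeded <- FALSE
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    logd <- vapply(seq_len(m),
                   function(j) log(w[j]) + stats::dnorm(x, mu[j], sigma[j], log = TRUE),
                   numeric(n))
    lse <- row_logsumexp(logd)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) / nk)
    if (any(sigma < sigma_floor)) {
      if (reseeded)
        stop("degenerate mixture component (SD collapsed below 1e-3 of the data SD) after re-seeding")
      reseeded <- TRUE
      bad <- which(sigma < sigma_floor)
      rng <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv())
      set.seed(seed)
      mu[bad] <- sample(x, length(bad))
      if (!is.null(rng)) assign(".Random.seed", rng, envir = globalenv())
      sigma[bad] <- sdx
      w <- rep(1 / m, m)
      ll_old <- -Inf
      next
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  dens <- pde(x, q = q, n_grid = n_grid)
  ssr_em <- sum((gmm_pdf(dens$grid, w, mu, sigma) - dens$density)^2)
  ssr_ref <- ssr_em
  refined <- FALSE
  if (refine) {
    obj <- function(theta) {
      lw <- theta[seq_len(m)]
      mu2 <- theta[m + seq_len(m)]
      sg2 <- exp(theta[2 * m + seq_len(m)])
      w2 <- exp(lw - max(lw)); w2 <- w2 / sum(w2)
      sum((gmm_pdf(dens$grid, w2, mu2, sg2) - dens$density)^2)
    }
    theta0 <- c(log(w), mu, log(sigma))
    opt <- tryCatch(stats::optim(theta0, obj, method = "BFGS",
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && opt$value <= ssr_em) {
      lw <- opt$par[seq_len(m)]
      mu2 <- opt$par[m + seq_len(m)]
      sg2 <- exp(opt$par[2 * m + seq_len(m)])
      if (all(sg2 >= sigma_floor)) {
        w <- exp(lw - max(lw)); w <- w / sum(w)
        mu <- mu2; sigma <- sg2
        ssr_ref <- opt$value
        refined <- TRUE
      }
    }
  }

  ord <- order(mu, sigma)
  structure(list(
    w = unname(w[ord]), mu = unname(mu[ord]), sigma = unname(sigma[ord]),
    m = as.integer(m),
    loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
    iterations = it, converged = converged,
    refined = refined, ssr = c(em = ssr_em, refined = ssr_ref),
    pde = dens, subtest = NA_character_
  ), class = "olf_gmm")
}

#' Bayesian posterior component probabilities
#'
#' For each value `x`, the posterior probability of each mixture component:
#' `p_j = w_j f(x; mu_j, sigma_j) / sum_k w_k f(x; mu_k, sigma_k)`, evaluated
#' in log space with log-sum-exp stabilization. The result is invariant to a
#' common rescaling of the component weights.
#'
#' @param model An `olf_gmm`.
#' @param x Numeric vector.
#' @return Matrix `length(x)` x `m`; rows sum to 1. For `m = 3` the columns
#'   are named `low`, `mid`, `high` (components are stored by ascending mean).
#' @export
#' @examples
#' g <- structure(list(w = c(.5, .5), mu = c(0, 4), sigma = c(1, 1), m = 2L),
#'                class = "olf_gmm")
#' posterior(g, 2)   # (0.5, 0.5) by symmetry
posterior <- function(model, x) {
  if (!inherits(model, "olf_gmm")) stop("'model' must be an olf_gmm")
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("'x' must be finite")
  m <- model$m
  logd <- vapply(seq_len(m),
                 function(j) log(model$w[j]) +
                   stats::dnorm(x, model$mu[j], model$sigma[j], log = TRUE),
                 numeric(length(x)))
  if (length(x) == 1L) logd <- matrix(logd, nrow = 1L)
  p <- exp(logd - row_logsumexp(logd))
  colnames(p) <- if (m == 3L) c("low", "mid", "high") else paste0("comp", seq_len(m))
  p
}

#' Fit the three per-subtest mixture models
#'
#' Convenience wrapper fitting one `m`-component [fit_gmm()] model to each
#' corrected subtest column (`thr_c`, `disc_c`, `ident_c`).
#'
#' @param corrected Output of [age_sex_correct()].
#' @param m Components per subtest.
#' @param ... Passed on to [fit_gmm()].
#' @return Named list of `olf_gmm` models (`thr`, `disc`, `ident`).
#' @export
fit_subtest_models <- function(corrected, m = 3L, ...) {
  cols <- c(thr = "thr_c", disc = "disc_c", ident = "ident_c")
  if (!all(cols %in% names(corrected)))
    stop("corrected scores missing; run age_sex_correct() first")
  out <- lapply(names(cols), function(s) {
    fit <- fit_gmm(corrected[[cols[[s]]]], m = m, ...)
    fit$subtest <- s
    fit
  })
  names(out) <- names(cols)
  out
}

#' Posterior feature matrix
#'
#' Builds the n x 3m matrix of Bayesian posterior probabilities that is the
#' ESOM input space: for each subject the posterior vectors of the corrected
#' threshold, discrimination and identification scores are concatenated, in
#' the column order thr low/mid/high, disc low/mid/high, ident low/mid/high
#' (for m = 3, giving the nine-dimensional feature space).
#'
#' @param corrected Output of [age_sex_correct()].
#' @param models Named list of `olf_gmm` models as from [fit_subtest_models()].
#' @return Numeric matrix with subjects as (named) rows; each subtest block of
#'   `m` columns sums to 1 per row. Rows with missing scores are dropped with
#'   a warning naming the subject ids.
#' @export
build_feature_matrix <- function(corrected, models) {
  cols <- c(thr = "thr_c", disc = "disc_c", ident = "ident_c")
  if (!all(names(cols) %in% names(models)))
    stop("'models' must contain elements thr, disc, ident")
  if (!all(cols %in% names(corrected)))
    stop("corrected scores missing; run age_sex_correct() first")
  scores <- as.matrix(corrected[, cols])
  ok <- stats::complete.cases(scores)
  if (!all(ok)) {
    warning("dropping subject(s) with missing scores: ",
            paste(corrected$subject_id[!ok], collapse = ", "))
    corrected <- corrected[ok, , drop = FALSE]
    scores <- scores[ok, , drop = FALSE]
  }
  blocks <- lapply(seq_along(cols), function(k) {
    p <- posterior(models[[names(cols)[k]]], scores[, k])
    colnames(p) <- paste(names(cols)[k], colnames(p), sep = "_")
    p
  })
  feat <- do.call(cbind, blocks)
  rownames(feat) <- corrected$subject_id
  feat
}
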