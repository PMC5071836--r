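test_that("Pareto radius equals the distance-quantile computed by brute force", {
  x <- c(0, 1, 2, 4)
  d <- as.numeric(dist(x))  # {1, 2, 4, 1, 3, 2}
  expect_equal(sort(d), c(1, 1, 2, 2, 3, 4))
  expect_equal(pareto_radius(x)$r, unname(quantile(d, 0.18)), tolerance = 1e-12)
  expect_equal(pareto_radius(x, q = 0.5)$r, unname(quantile(d, 0.5)),
               tolerance = 1e-12)
})

test_that("Pareto radius is scale-equivariant and positive-definite", {
  set.seed(10)
  x <- rnorm(60)
  for (c in c(0.5, 3, 10))
    expect_equal(pareto_radius(c * x)$r, c * pareto_radius(x)$r,
                 tolerance = 1e-10)
  expect_equal(pareto_radius(c(2, 7))$r, 5)  # single-distance multiset
  expect_error(pareto_radius(rep(3, 10)), "zero spread")
})

test_that("PDE sphere counts match a brute-force double loop exactly", {
  expect_equal(pde(c(0, 1, 2, 4), grid = 1, r = 1)$raw, 3)  # points 0,1,2
  set.seed(11)
  for (rep in 1:3) {
    x <- runif(150, 0, 10)
    est <- pde(x, q = 0.3)
    oracle <- vapply(est$grid,
                     function(g) sum(vapply(x, function(xi) abs(xi - g) <= est$r,
                                            logical(1))),
                     numeric(1))
    expect_identical(est$raw, oracle)
  }
})

test_that("PDE is flat under an all-inclusive radius and integrates to 1", {
  x <- c(0, 1, 2, 4)
  est <- pde(x, grid = seq(0, 4, length.out = 50), r = 100)
  expect_true(all(est$raw == 4))
  set.seed(12)
  y <- rnorm(500)
  est2 <- pde(y)
  area <- sum(diff(est2$grid) *
                (est2$density[-1] + est2$density[-length(est2$density)]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_true(all(est2$density >= 0))
  expect_error(pde(y, grid = numeric(0)), "empty")
})

test_that("EM recovers a single Gaussian at n = 5000", {
  set.seed(20)
  x <- rnorm(5000, mean = 5, sd = 1)
  fit <- fit_gmm(x, m = 1)
  expect_equal(fit$mu, 5, tolerance = 0.1)
  expect_equal(fit$sigma, 1, tolerance = 0.1)
  expect_equal(fit$w, 1, tolerance = 1e-9)
})

test_that("EM log-likelihood is non-decreasing and refinement never hurts the PDE fit", {
  set.seed(21)
  x <- c(rnorm(600, 0), rnorm(600, 6))
  fit <- fit_gmm(x, m = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * (1 + abs(fit$loglik))))
  expect_lte(fit$ssr[["refined"]], fit$ssr[["em"]])
  expect_equal(sum(fit$w), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$mu) > 0))  # sorted by ascending mean
})

test_that("posterior matches hand-computed Bayes ratios", {
  g <- fake_gmm(c(0.5, 0.5), c(0, 4), c(1, 1))
  expect_equal(as.numeric(posterior(g, 2)), c(0.5, 0.5), tolerance = 1e-12)
  # x = 1: w phi(1;0,1) vs w phi(1;4,1), normalized -> 1/(1+e^-4)
  p <- as.numeric(posterior(g, 1))
  byhand <- dnorm(1, 0, 1) / (dnorm(1, 0, 1) + dnorm(1, 4, 1))
  expect_equal(p[1], byhand, tolerance = 1e-12)
  expect_equal(round(p, 3), c(0.982, 0.018))
  set.seed(22)
  xs <- rnorm(50, 2, 3)
  pm <- posterior(fake_gmm(c(0.2, 0.3, 0.5), c(-1, 2, 5), c(1, 2, 1)), xs)
  expect_equal(rowSums(pm), rep(1, 50), tolerance = 1e-12)
})

test_that("posterior is invariant to a common rescaling of the weights", {
  set.seed(23)
  xs <- rnorm(30)
  g1 <- fake_gmm(c(0.2, 0.8), c(0, 3), c(1, 2))
  g2 <- fake_gmm(10 * c(0.2, 0.8), c(0, 3), c(1, 2))
  expect_equal(posterior(g1, xs), posterior(g2, xs), tolerance = 1e-12)
  expect_error(posterior(g1, NaN), "finite")
})

test_that("the feature matrix has nine columns of block-normalized posteriors", {
  co <- age_sex_correct(small_cohort(n = 400, seed = 6))
  models <- fit_subtest_models(co, m = 3, seed = 1)
  feat <- build_feature_matrix(co, models)
  expect_equal(ncol(feat), 9L)
  expect_equal(colnames(feat)[1:3], c("thr_low", "thr_mid", "thr_high"))
  expect_equal(rowSums(feat), setNames(rep(3, nrow(feat)), rownames(feat)),
               tolerance = 1e-8)
  expect_true(all(feat >= 0 & feat <= 1))
  for (blk in list(1:3, 4:6, 7:9))
    expect_equal(unname(rowSums(feat[, blk])), rep(1, nrow(feat)),
                 tolerance = 1e-9)
})

test_that("a subject at an isolated component mean loads >0.99 on that component", {
  models <- list(thr = fake_gmm(c(1, 1, 1) / 3, c(0, 10, 20), c(1, 1, 1)),
                 disc = fake_gmm(c(1, 1, 1) / 3, c(0, 10, 20), c(1, 1, 1)),
                 ident = fake_gmm(c(1, 1, 1) / 3, c(0, 10, 20), c(1, 1, 1)))
  d <- data.frame(subject_id = "s1", thr_c = 0, disc_c = 0, ident_c = 0)
  feat <- build_feature_matrix(d, models)
  expect_true(all(feat[1, c("thr_low", "disc_low", "ident_low")] > 0.99))
})

test_that("rows with missing scores are dropped and named", {
  models <- list(thr = fake_gmm(1, 0, 1), disc = fake_gmm(1, 0, 1),
                 ident = fake_gmm(1, 0, 1))
  d <- data.frame(subject_id = c("keep", "drop1"),
                  thr_c = c(1, NA), disc_c = c(1, 1), ident_c = c(1, 1))
  expect_warning(feat <- build_feature_matrix(d, models), "drop1")
  expect_equal(rownames(feat), "keep")
})
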