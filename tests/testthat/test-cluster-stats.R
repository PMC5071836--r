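# toy 6x8 toroidal landscape: ridge columns `ridges` at height 5, rest 0;
# weights separate the two valley strips in feature space
toy_landscape <- function(ridges) {
  rows <- 6; cols <- 8
  H <- matrix(0, rows, cols); H[, ridges] <- 5
  colof <- function(u) (u - 1) %% cols + 1
  w <- numeric(rows * cols)
  for (u in seq_len(rows * cols)) {
    cc <- colof(u)
    w[u] <- if (cc %in% c(4, 5)) 0 else if (cc %in% c(7, 8, 1, 2)) 10 else 5
  }
  list(grid = fake_grid(matrix(w, ncol = 1), rows, cols), H = H)
}

unit_at <- function(r, c, cols = 8) (r - 1) * cols + c

test_that("a flat landscape yields a single cluster holding every subject", {
  g <- fake_grid(matrix(0, 24, 1), 4, 6)
  H <- matrix(0, 4, 6)
  bm <- data.frame(unit = c(1L, 8L, 20L), row = 1, col = 1,
                   row.names = c("a", "b", "c"))
  expect_warning(cl <- cluster_landscape(g, H, bm), "single cluster")
  expect_equal(cl$k, 1L)
  expect_true(all(cl$subject_cluster == 1L))
})

test_that("two full ridge columns split the torus into exactly two basins; one cannot", {
  toy <- toy_landscape(c(3, 6))
  bunits <- c(unit_at(1, 7), unit_at(2, 8), unit_at(3, 1), unit_at(4, 2),
              unit_at(5, 7),                      # strip B (cols 7,8,1,2)
              unit_at(1, 4), unit_at(2, 5), unit_at(3, 4))  # strip A (cols 4,5)
  bm <- data.frame(unit = bunits, row = 1, col = 1,
                   row.names = paste0("s", seq_along(bunits)))
  cl <- cluster_landscape(toy$grid, toy$H, bm)
  expect_equal(cl$k, 2L)
  expect_equal(unname(cl$subject_cluster[paste0("s", 1:5)]), rep(1L, 5))  # larger strip first
  expect_equal(unname(cl$subject_cluster[paste0("s", 6:8)]), rep(2L, 3))
  # a single ridge column cannot separate a torus
  toy1 <- toy_landscape(3)
  cl1 <- cluster_landscape(toy1$grid, toy1$H, bm)
  expect_equal(cl1$k, 1L)
})

test_that("ridge-resident BMUs join the valley component nearest in weight space", {
  toy <- toy_landscape(c(3, 6))
  toy$grid$weights[unit_at(1, 3), 1] <- 1  # ridge unit close to strip A (weight 0)
  bm <- data.frame(unit = c(unit_at(1, 7), unit_at(2, 8), unit_at(1, 4),
                            unit_at(1, 3)),
                   row = 1, col = 1, row.names = c("b1", "b2", "a1", "ridge"))
  cl <- cluster_landscape(toy$grid, toy$H, bm)
  expect_equal(cl$k, 2L)
  expect_equal(cl$subject_cluster[["ridge"]], cl$subject_cluster[["a1"]])
})

test_that("cluster extraction commutes with toroidal rolls of the landscape", {
  toy <- toy_landscape(c(3, 6))
  bunits <- c(unit_at(1, 7), unit_at(2, 8), unit_at(3, 1), unit_at(1, 4),
              unit_at(2, 5))
  bm <- data.frame(unit = bunits, row = 1, col = 1,
                   row.names = paste0("s", 1:5))
  cl <- cluster_landscape(toy$grid, toy$H, bm)
  dr <- 2; dc <- 3
  g2 <- roll_grid(toy$grid, dr, dc)
  H2 <- roll2(toy$H, dr, dc)
  rows <- 6; cols <- 8
  rr <- ((bunits - 1) %/% cols + dr) %% rows
  cc <- ((bunits - 1) %% cols + dc) %% cols
  bm2 <- bm; bm2$unit <- rr * cols + cc + 1
  cl2 <- cluster_landscape(g2, H2, bm2)
  expect_identical(cl2$subject_cluster, cl$subject_cluster)
})

test_that("chi-squared agrees with the closed-form 2x2 expression", {
  set.seed(40)
  for (i in 1:100) {
    m <- matrix(sample(5:80, 4, TRUE), 2, 2)
    res <- chi_square(m)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    n <- sum(m)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$chi2, closed, tolerance = 1e-9)
    expect_equal(res$df, 1L)
  }
  res <- chi_square(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(round(res$chi2, 3), 6.667)
})

test_that("df follows the table shape and the null table gives chi2 = 0", {
  set.seed(41)
  m <- matrix(sample(10:60, 27, TRUE), 9, 3)
  expect_equal(chi_square(m)$df, 16L)
  null_tab <- outer(c(1, 2), c(3, 3))  # equals its own expected counts
  res <- chi_square(null_tab)
  expect_equal(res$chi2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(5, 0, 7, 0), 2, 2)), "expected")
})

test_that("relDiff reproduces the worked cells and is sign-antisymmetric", {
  tab <- fake_table(observed = matrix(c(10, 30, 0), 1, 3),
                    expected = matrix(c(10, 10, 8), 1, 3))
  rd <- rel_diff(tab)
  expect_equal(rd[1, 1], 0)        # obs = exp
  expect_equal(rd[1, 2], -1)       # (10 - 30) / (0.5 * 40)
  expect_equal(rd[1, 3], 2)        # obs = 0, exp > 0: attainable extreme
  swapped <- fake_table(observed = tab$expected, expected = tab$observed)
  expect_equal(rel_diff(swapped), -rd, ignore_attr = TRUE)
  expect_equal(rel_diff(tab, sign_convention = "obs_minus_exp"), -rd)
  set.seed(42)
  rnd <- matrix(sample(0:50, 30, TRUE), 5, 6)
  expect_true(all(abs(rel_diff(rnd)) <= 2))
  zero <- fake_table(matrix(0, 1, 1), matrix(0, 1, 1))
  expect_message(rz <- rel_diff(zero), "0")
  expect_equal(rz[1, 1], 0)
})

test_that("Spearman rho matches the rank-difference formula on worked triplets", {
  co <- data.frame(subject_id = c("a", "b", "c"), etiology = "Healthy",
                   thr = c(1, 2, 3), disc = c(3, 1, 2), ident = c(3, 2, 1))
  rho <- spearman_by_group(co)
  get <- function(p) rho$rho[rho$group == "global" & rho$pair == p]
  expect_equal(get("disc/thr"), -0.5, tolerance = 1e-12)   # 1 - 6*6/(3*8)
  expect_equal(get("thr/ident"), -1, tolerance = 1e-12)    # reversed order
  co2 <- co; co2$disc <- c(2, 4, 6)
  expect_equal(spearman_by_group(co2)$rho[
    spearman_by_group(co2)$pair == "disc/thr"][1], 1, tolerance = 1e-12)
})

test_that("per-group correlations omit undersized groups with a warning", {
  co <- small_cohort(n = 300, seed = 2)
  co$etiology[1] <- "Tumor/apoplectic"
  co$etiology[-1][co$etiology[-1] == "Tumor/apoplectic"] <- "Healthy"
  ws <- capture_warnings(rho <- spearman_by_group(co, by = "etiology"))
  expect_true(any(grepl("Tumor/apoplectic.*omitted", ws)))
  expect_false("Tumor/apoplectic" %in% rho$group)
  expect_true(all(rho$rho >= -1 & rho$rho <= 1))
})

test_that("contingency tables have the right shape, margins and exclusions", {
  co <- small_cohort(n = 4000, seed = 3)
  cl <- setNames(as.integer(factor(co$latent_profile)), co$subject_id)
  tab <- contingency(co, cl)
  expect_equal(dim(tab$observed), c(9L, 3L))
  expect_equal(unname(tab$row_totals), unname(rowSums(tab$observed)))
  expect_equal(unname(tab$col_totals), unname(colSums(tab$observed)))
  expect_equal(sum(tab$expected), sum(tab$observed), tolerance = 1e-9)
  tab2 <- contingency(co, cl, exclude = "Healthy")
  expect_equal(dim(tab2$observed), c(8L, 3L))
  expect_equal(tab2$total, sum(co$etiology != "Healthy"))
  expect_error(contingency(co, cl, exclude = olf_etiologies()), "no subjects")
})
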