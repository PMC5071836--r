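# shared fixture builders

small_cohort <- function(n = 300, seed = 1, ...) {
  generate_cohort(default_cohort_config(n_subjects = n, seed = seed, ...))
}

# single mid-scale profile, far from the score bounds, so clipping and
# rounding cannot distort linear-trend estimates
flat_profile_config <- function(n, seed = 1, slope = -0.05) {
  prof <- data.frame(profile = "mid",
                     thr_center = 8, thr_sd = 1.5,
                     disc_center = 8, disc_sd = 1.5,
                     ident_center = 8, ident_sd = 1.5,
                     stringsAsFactors = FALSE)
  cohort_config(n_subjects = n,
                etiology_weights = c(Healthy = 1),
                profile_map = matrix(1, 1, 1, dimnames = list("Healthy", "mid")),
                profiles = prof,
                age_slope_per_subtest = slope,
                seed = seed)
}

# hand-built map object (bypasses training) for oracle tests
fake_grid <- function(W, rows, cols) {
  structure(list(weights = W, rows = rows, cols = cols, dim = ncol(W)),
            class = "olf_esom")
}

# hand-built mixture model for posterior/feature tests
fake_gmm <- function(w, mu, sigma) {
  structure(list(w = w, mu = mu, sigma = sigma, m = length(w)),
            class = "olf_gmm")
}

# hand-built contingency with explicit expected counts (formula checks)
fake_table <- function(observed, expected) {
  structure(list(observed = observed, expected = expected,
                 row_totals = rowSums(observed), col_totals = colSums(observed),
                 total = sum(observed)),
            class = "olf_contingency")
}

# toroidal roll of a matrix by (dr, dc)
roll2 <- function(m, dr, dc) {
  r <- nrow(m); c <- ncol(m)
  m[((seq_len(r) - 1 - dr) %% r) + 1, ((seq_len(c) - 1 - dc) %% c) + 1,
    drop = FALSE]
}

# roll a trained grid's units by (dr, dc) on the torus
roll_grid <- function(grid, dr, dc) {
  rows <- grid$rows; cols <- grid$cols
  rc <- cbind((seq_len(rows * cols) - 1) %/% cols, (seq_len(rows * cols) - 1) %% cols)
  src_r <- (rc[, 1] - dr) %% rows
  src_c <- (rc[, 2] - dc) %% cols
  src <- src_r * cols + src_c + 1
  g2 <- grid
  g2$weights <- grid$weights[src, , drop = FALSE]
  g2
}
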