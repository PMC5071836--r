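#' Train an emergent self-organizing map on a toroidal grid
#'
#' Online (sample-by-sample) SOM training: for every presented feature vector
#' the best matching unit (BMU) is located and all units are moved toward the
#' sample, weighted by a neighborhood kernel of the toroidal grid distance to
#' the BMU. The learning rate decays linearly from `lr[1]` to `lr[2]` and the
#' neighborhood radius from `radius[1]` to `radius[2]` over the epochs; the
#' presentation order is reshuffled every epoch from the seed, so a fixed
#' seed yields bit-identical weights. The grid is emergent: the number of
#' units (default 50 x 80 = 4,000) far exceeds the expected cluster count.
#'
#' Initial weights are drawn uniformly per dimension from the range of the
#' data variables.
#'
#' @param features Numeric matrix (subjects x feature dimensions), e.g. from
#'   [build_feature_matrix()].
#' @param rows,cols Grid dimensions.
#' @param epochs Number of sweeps through the data.
#' @param seed Integer seed (initialization and presentation order).
#' @param lr Learning rate at the first and last epoch.
#' @param radius Neighborhood radius at the first and last epoch; defaults to
#'   `c(rows / 2, 1)`.
#' @param kernel `"gaussian"` (`exp(-d^2 / (2 radius^2))`) or `"cone"`
#'   (linear to zero at the radius).
#' @return A list of class `olf_esom`: `weights` ((rows*cols) x D matrix,
#'   row-major unit order), `rows`, `cols`, `epochs`, `seed`, `lr`, `radius`,
#'   `kernel`, `dim`, `feature_names`.
#' @export
#' @examples
#' x <- matrix(rnorm(60), ncol = 3)
#' g <- train_esom(x, rows = 4, cols = 5, epochs = 3, seed = 1)
#' dim(g$weights)
train_esom <- function(features, rows = 50L, cols = 80L, epochs = 30L,
                       seed = 1L, lr = c(0.5, 0.05), radius = NULL,
                       kernel = c("gaussian", "cone")) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("'features' must be finite")
  if (!is_count(rows) || !is_count(cols) || !is_count(epochs))
    stop("'rows', 'cols' and 'epochs' must be positive integers")
  kernel <- match.arg(kernel)
  n <- nrow(features); D <- ncol(features)
  units <- as.integer(rows) * as.integer(cols)
  radius <- radius %||% c(rows / 2, 1)
  if (any(radius <= 0)) stop("'radius' must be positive")

  set.seed(seed)
  mn <- apply(features, 2L, min)
  mx <- apply(features, 2L, max)
  W <- vapply(seq_len(D), function(d) stats::runif(units, mn[d], mx[d]),
              numeric(units))
  orders <- matrix(vapply(seq_len(epochs), function(e) sample.int(n),
                          integer(n)), nrow = n)

  lr_sched <- if (epochs == 1L) lr[1] else seq(lr[1], lr[2], length.out = epochs)
  rad_sched <- if (epochs == 1L) radius[1] else
    seq(radius[1], radius[2], length.out = epochs)

  W <- esom_train_cpp(features, W, as.integer(rows), as.integer(cols),
                      orders - 1L, lr_sched, rad_sched,
                      if (kernel == "gaussian") 0L else 1L)
  colnames(W) <- colnames(features)
  structure(list(weights = W, rows = as.integer(rows), cols = as.integer(cols),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr = lr, radius = radius, kernel = kernel, dim = D,
                 feature_names = colnames(features)),
            class = "olf_esom")
}

#' @export
print.olf_esom <- function(x, ...) {
  cat(sprintf("Toroidal ESOM: %d x %d units (%d), %d-dimensional weights, %d epochs, seed %d\n",
              x$rows, x$cols, x$rows * x$cols, x$dim, x$epochs, x$seed))
  invisible(x)
}

unit_to_rc <- function(unit, cols) {
  cbind(row = (unit - 1L) %/% cols + 1L, col = (unit - 1L) %% cols + 1L)
}

#' Best matching units
#'
#' For each feature vector, the grid unit whose weight vector minimizes the
#' Euclidean distance; ties are broken toward the smallest row-major linear
#' index (row 1, col 1 first).
#'
#' @param grid An `olf_esom`.
#' @param x Feature vector or matrix (rows = subjects) of dimension
#'   `grid$dim`.
#' @return A data.frame with columns `unit`, `row`, `col` (1-based) and one
#'   row per input vector; row names carry the input row names.
#' @export
bmu <- function(grid, x) {
  X <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  if (ncol(X) != grid$dim)
    stop(sprintf("dimension mismatch: features have %d columns, grid weights %d",
                 ncol(X), grid$dim))
  if (!all(is.finite(X))) stop("'x' must be finite")
  W <- grid$weights
  w2 <- rowSums(W * W)
  n <- nrow(X)
  idx <- integer(n)
  chunk <- 2000L
  for (start in seq(1L, n, by = chunk)) {
    jj <- start:min(start + chunk - 1L, n)
    Xb <- X[jj, , drop = FALSE]
    D2 <- w2 - 2 * (W %*% t(Xb))  # + |x|^2, constant per column
    idx[jj] <- max.col(-t(D2), ties.method = "first")
  }
  rc <- unit_to_rc(idx, grid$cols)
  data.frame(unit = idx, row = rc[, "row"], col = rc[, "col"],
             row.names = rownames(X))
}

#' Mean quantization error
#'
#' Mean Euclidean distance between each feature vector and the weight of its
#' best matching unit.
#'
#' @inheritParams bmu
#' @return A single number.
#' @export
quantization_error <- function(grid, x) {
  X <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else as.matrix(x)
  b <- bmu(grid, X)
  mean(sqrt(rowSums((X - grid$weights[b$unit, , drop = FALSE])^2)))
}

# weights as rows x cols x D array (unit order is row-major)
weight_array <- function(grid) {
  A <- array(0, dim = c(grid$rows, grid$cols, grid$dim))
  for (d in seq_len(grid$dim))
    A[, , d] <- matrix(grid$weights[, d], nrow = grid$rows, byrow = TRUE)
  A
}

torus_shift <- function(idx, delta, size) ((idx - 1L + delta) %% size) + 1L

#' U-matrix of a trained map
#'
#' Per unit, the mean Euclidean distance (in feature space) between its
#' weight vector and those of its toroidal Moore (8-)neighbors. Large
#' heights mark gaps in the data space, low heights mark dense similarity
#' regions.
#'
#' @param grid An `olf_esom`.
#' @param neighborhood `"moore"` (8 neighbors, default) or `"vonneumann"`
#'   (4 neighbors).
#' @return A `rows x cols` numeric matrix with attribute `kind = "U"`.
#' @export
umatrix <- function(grid, neighborhood = c("moore", "vonneumann")) {
  neighborhood <- match.arg(neighborhood)
  offs <- if (neighborhood == "moore") {
    expand.grid(dr = -1:1, dc = -1:1)[-5L, ]  # drop (0,0)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  A <- weight_array(grid)
  U <- matrix(0, grid$rows, grid$cols)
  for (k in seq_len(nrow(offs))) {
    ri <- torus_shift(seq_len(grid$rows), offs$dr[k], grid$rows)
    ci <- torus_shift(seq_len(grid$cols), offs$dc[k], grid$cols)
    d2 <- matrix(0, grid$rows, grid$cols)
    for (d in seq_len(grid$dim))
      d2 <- d2 + (A[, , d] - A[ri, ci, d])^2
    U <- U + sqrt(d2)
  }
  U <- U / nrow(offs)
  attr(U, "kind") <- "U"
  U
}

#' P-matrix: data density at each unit
#'
#' Per unit, the number of subjects whose feature vector lies within the
#' Pareto radius of the unit's weight vector (a sphere-count density
#' landscape over the map).
#'
#' @param grid An `olf_esom`.
#' @param features Feature matrix the map was trained on.
#' @param r Pareto radius (number or [pareto_radius()] result); computed
#'   from `features` when omitted.
#' @return A `rows x cols` integer matrix with attributes `kind = "P"` and
#'   `r` (the radius used).
#' @export
pmatrix <- function(grid, features, r = NULL) {
  X <- as.matrix(features)
  if (ncol(X) != grid$dim) stop("dimension mismatch between features and grid")
  rr <- as_radius(r %||% pareto_radius(X))
  W <- grid$weights
  x2 <- rowSums(X * X)
  counts <- integer(nrow(W))
  chunk <- 500L
  r2 <- rr^2
  for (start in seq(1L, nrow(W), by = chunk)) {
    jj <- start:min(start + chunk - 1L, nrow(W))
    Wb <- W[jj, , drop = FALSE]
    D2 <- outer(rowSums(Wb * Wb), x2, "+") - 2 * (Wb %*% t(X))
    counts[jj] <- rowSums(D2 <= r2)
  }
  P <- matrix(as.integer(counts), nrow = grid$rows, byrow = TRUE)
  attr(P, "kind") <- "P"
  attr(P, "r") <- rr
  P
}

#' U*-matrix: density-weighted distance landscape
#'
#' Combines the distance structure (U-matrix) with the density structure
#' (P-matrix): `Ustar = U * scale` with
#' `scale = (P - mean(P)) / (mean(P) - max(P)) + 1`, clamped below at 0.
#' The scale equals 1 at mean density, 0 at maximum density and exceeds 1 in
#' sparse regions, so ridges inside dense regions are suppressed while gaps
#' in sparse regions are emphasized. A constant P-matrix (mean = max) is a
#' documented degenerate case with `scale = 1`, i.e. `Ustar = U`.
#'
#' @param U U-matrix from [umatrix()].
#' @param P P-matrix from [pmatrix()].
#' @return Matrix of the same shape with attribute `kind = "Ustar"`.
#' @export
ustar <- function(U, P) {
  if (!all(dim(U) == dim(P))) stop("'U' and 'P' must have the same shape")
  mp <- mean(P); mx <- max(P)
  scale <- if (mx == mp) matrix(1, nrow(P), ncol(P)) else (P - mp) / (mp - mx) + 1
  out <- unclass(U) * pmax(scale, 0)
  attr(out, "kind") <- "Ustar"
  attr(out, "r") <- attr(P, "r")
  out
}

#' Export a height matrix as a terrain-colored PNG
#'
#' Optional static heightmap export for visual inspection of the landscape
#' (top view; row 1 of the matrix is the top row of the image).
#'
#' @param height A matrix from [umatrix()], [pmatrix()] or [ustar()].
#' @param file Output PNG path.
#' @param pixels_per_unit Image scale.
#' @return `file`, invisibly.
#' @export
save_heightmap <- function(height, file, pixels_per_unit = 8L) {
  grDevices::png(file, width = ncol(height) * pixels_per_unit,
                 height = nrow(height) * pixels_per_unit)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(t(height)[, nrow(height):1, drop = FALSE],
                  col = grDevices::terrain.colors(64), axes = FALSE,
                  useRaster = TRUE)
  invisible(file)
}
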