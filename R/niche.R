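#' Greedy correlation pruning of environmental variables
#'
#' Variables are scanned in input order; a variable is dropped when its
#' absolute Pearson correlation with any already-retained variable exceeds
#' \code{r_max}. Constant variables (undefined correlation) are dropped with
#' a warning.
#'
#' @param env locations x variables numeric matrix (or data.frame).
#' @param r_max retention threshold on |r| (default 0.75).
#' @return character vector of retained variable names.
#' @export
pruneEnvCorrelated <- function(env, r_max = 0.75) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("need >= 2 variables")
  if (is.null(colnames(env))) colnames(env) <- paste0("V", seq_len(ncol(env)))
  keep <- character(0)
  for (v in colnames(env)) {
    if (stats::sd(env[, v]) == 0) {
      warning("variable ", v, " is constant; dropped")
      next
    }
    ok <- TRUE
    for (u in keep) {
      if (abs(stats::cor(env[, v], env[, u])) > r_max) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, v)
  }
  keep
}

#' Schoener's D niche overlap
#'
#' D = 1 - 0.5 sum |a - b| over the shared valid cells of two normalized
#' suitability rasters; 1 for identical niches, 0 for disjoint supports.
#' @param a,b \linkS4class{SuitabilityRaster} objects on the same extent.
#' @export
schoenerD <- function(a, b) {
  .check_extent(a, b)
  m <- a@mask & b@mask
  pa <- .renorm(a@grid, m); pb <- .renorm(b@grid, m)
  .snap01(1 - 0.5 * sum(abs(pa - pb)))
}

# overlap statistics live in [0, 1] with hard endpoints at identity and
# disjointness; clamp and snap away floating-point dust at the endpoints
.snap01 <- function(x, tol = 1e-12) {
  x <- min(max(x, 0), 1)
  if (x < tol) 0 else if (x > 1 - tol) 1 else x
}

#' Hellinger-based I niche overlap
#'
#' I = 1 - 0.5 sum (sqrt(a) - sqrt(b))^2 (one minus half the squared
#' Hellinger distance); shares the [0, 1] range and endpoints of Schoener's D.
#' @inheritParams schoenerD
#' @export
hellingerI <- function(a, b) {
  .check_extent(a, b)
  m <- a@mask & b@mask
  pa <- .renorm(a@grid, m); pb <- .renorm(b@grid, m)
  .snap01(1 - 0.5 * sum((sqrt(pa) - sqrt(pb))^2))
}

.check_extent <- function(a, b) {
  if (!identical(dim(a@grid), dim(b@grid)) ||
      !isTRUE(all.equal(a@xcoords, b@xcoords)) ||
      !isTRUE(all.equal(a@ycoords, b@ycoords)))
    stop("raster extents do not match")
}

# joint renormalization over a shared mask
.renorm <- function(grid, mask) {
  v <- grid[mask]
  s <- sum(v)
  if (s <= 0) return(v)
  v / s
}

#' Kernel-density suitability model in 2-D environment space
#'
#' The default pluggable suitability model for the identity test: a Gaussian
#' kernel density (MASS::kde2d) of the occurrences' positions in a fixed 2-D
#' environmental projection, evaluated over a shared grid. A deliberately
#' simple stand-in for full ecological-niche model fitting, adequate for
#' overlap statistics and their permutation null.
#'
#' @param xy two-column matrix of occurrence coordinates in the projected
#'   environment space.
#' @param xlim,ylim shared grid extent.
#' @param n grid cells per axis.
#' @return a \linkS4class{SuitabilityRaster}
#' @export
kdeSuitability <- function(xy, xlim, ylim, n = 50) {
  bw <- c(max(MASS::bandwidth.nrd(xy[, 1]), diff(xlim) / 25),
          max(MASS::bandwidth.nrd(xy[, 2]), diff(ylim) / 25))
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = bw, n = n, lims = c(xlim, ylim))
  SuitabilityRaster(kd$z, xcoords = kd$x, ycoords = kd$y)
}

#' Niche identity (equivalency) test
#'
#' Observed D and I come from per-species suitability models; the null
#' distribution re-splits the pooled occurrences at random, preserving the
#' two sample sizes, and recomputes both statistics \code{n_perm} times.
#' One-sided p-values use the add-one rule p = (1 + #(null <= observed)) /
#' (n_perm + 1), so p is never zero. Deterministic given \code{seed}.
#'
#' @param envA,envB occurrences x 2 matrices: the two species' positions in a
#'   shared 2-D environmental projection.
#' @param n_perm number of permutations (0 = observed values only; < 20
#'   draws a warning).
#' @param suitability_model function(xy) -> \linkS4class{SuitabilityRaster};
#'   defaults to \code{\link{kdeSuitability}} on the pooled extent.
#' @param seed RNG seed.
#' @param grid_n grid cells per axis for the default model.
#' @return list(d, i, p_d, p_i, null_d, null_i)
#' @export
identityTest <- function(envA, envB, n_perm = 99, suitability_model = NULL,
                         seed = 1, grid_n = 50) {
  envA <- as.matrix(envA); envB <- as.matrix(envB)
  if (n_perm > 0 && n_perm < 20)
    warning("n_perm < 20 gives a very coarse null")
  pool <- rbind(envA, envB)
  pad <- function(r) c(r[1] - 0.1 * diff(r), r[2] + 0.1 * diff(r))
  xlim <- pad(range(pool[, 1])); ylim <- pad(range(pool[, 2]))
  if (is.null(suitability_model))
    suitability_model <- function(xy) kdeSuitability(xy, xlim, ylim, n = grid_n)
  obs_stats <- function(a, b) {
    ra <- suitability_model(a); rb <- suitability_model(b)
    c(d = schoenerD(ra, rb), i = hellingerI(ra, rb))
  }
  obs <- obs_stats(envA, envB)
  if (n_perm == 0)
    return(list(d = obs[["d"]], i = obs[["i"]], p_d = NA_real_,
                p_i = NA_real_, null_d = numeric(0), null_i = numeric(0)))
  nA <- nrow(envA)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(nrow(pool), nA)
    obs_stats(pool[idx, , drop = FALSE], pool[-idx, , drop = FALSE])
  }, numeric(2))
  p_d <- (1 + sum(null["d", ] <= obs[["d"]])) / (n_perm + 1)
  p_i <- (1 + sum(null["i", ] <= obs[["i"]])) / (n_perm + 1)
  list(d = obs[["d"]], i = obs[["i"]], p_d = p_d, p_i = p_i,
       null_d = null["d", ], null_i = null["i", ])
}
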