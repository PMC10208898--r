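## Folded SFS construction, Poisson composite likelihood, model fitting.

# lexicographic "less or equal" of two count configurations
.lex_le <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  TRUE
}

# all cell configurations of an SFS with per-pop sizes `dims`
.sfs_cells <- function(dims) {
  as.matrix(expand.grid(lapply(dims, function(n) 0:n)))
}

# fold mask: TRUE where a cell carries no mass after folding
.fold_mask <- function(dims) {
  cells <- .sfs_cells(dims)
  ntot <- sum(dims)
  apply(cells, 1, function(d) {
    t <- sum(d); conj <- dims - d
    t == 0 || t > ntot - t || (t == ntot - t && !.lex_le(d, conj))
  })
}

# fold an unfolded array (same shape); returns list(counts, mask)
.fold_array <- function(arr, dims) {
  cells <- .sfs_cells(dims)
  ntot <- sum(dims)
  res <- array(0, dim = dims + 1)
  msk <- array(.fold_mask(dims), dim = dims + 1)
  for (i in seq_len(nrow(cells))) {
    d <- cells[i, ]
    t <- sum(d); conj <- dims - d
    if (t == 0 || t > ntot - t) next
    ci <- 1 + sum(conj * cumprod(c(1, dims[-length(dims)] + 1)))
    if (t < ntot - t) res[i] <- arr[i] + arr[ci]
    else if (identical(as.integer(d), as.integer(conj))) res[i] <- arr[i]
    else if (.lex_le(d, conj)) res[i] <- arr[i] + arr[ci]
  }
  res[msk] <- 0
  list(counts = res, mask = msk)
}

#' Build a folded joint SFS from genotypes
#'
#' Complete-case sites only: any missing call in a selected sample excludes
#' the site. Each retained polymorphic site contributes one count to the cell
#' of its joint minor-allele configuration, folded by the total minor allele
#' (ties resolved to the lexicographically smaller configuration).
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param pops a \linkS4class{PopulationMap}
#' @param which character vector of 1-3 population labels.
#' @return a \linkS4class{FoldedSFS}
#' @export
buildFoldedSfs <- function(vm, pops, which) {
  sets <- lapply(which, function(p) popSamples(pops, p))
  g <- genotypes(vm)
  sub <- do.call(rbind, lapply(sets, function(s) g[s, , drop = FALSE]))
  complete <- colSums(is.na(sub)) == 0
  if (!any(complete)) stop("no complete-case site for the selected samples")
  dims <- vapply(sets, function(s) 2L * length(s), integer(1))
  ntot <- sum(dims)
  counts <- array(0, dim = dims + 1)
  offs <- cumprod(c(1, dims[-length(dims)] + 1))
  dmat <- vapply(sets, function(s)
    colSums(g[s, , drop = FALSE]), numeric(ncol(g)))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1)
  for (j in which(complete)) {
    d <- as.integer(dmat[j, ])
    t <- sum(d)
    if (t == 0 || t == ntot) next
    conj <- dims - d
    if (t > ntot - t || (t == ntot - t && !.lex_le(d, conj))) d <- conj
    idx <- 1 + sum(d * offs)
    counts[idx] <- counts[idx] + 1
  }
  if (sum(counts) == 0) stop("no polymorphic complete-case site")
  new("FoldedSFS", counts = counts,
      mask = array(.fold_mask(dims), dim = dims + 1), dims = dims)
}

#' Monte-Carlo expected folded SFS under a demographic model
#'
#' Averages branch lengths subtending each joint descendant configuration
#' over seeded structured-coalescent replicates and scales so that the
#' expected SNP count per cell is theta times the returned value
#' (theta = 4 Nref mu L). Deterministic given the seed.
#'
#' @param model a \linkS4class{DemographicModel}
#' @param dims integer allele-copy sample sizes per deme (length 3 for the
#'   three-population models; zeros mark unsampled demes).
#' @param n_reps number of coalescent replicates (>= 10000 recommended).
#' @param seed RNG seed.
#' @param params named parameter vector (defaults to the model defaults).
#' @param fold fold the expectation (default TRUE).
#' @return a \linkS4class{FoldedSFS} holding the per-unit-theta expectation
#'   (unfolded array with a fixed-cells-only mask when fold = FALSE).
#' @export
expectedSfs <- function(model, dims, n_reps = 10000, seed = 1,
                        params = model@params, fold = TRUE) {
  epochs <- modelEpochs(model, params)
  ends <- vapply(epochs, function(e) e$end, numeric(1))
  if (any(diff(ends) < 0) || any(ends <= 0))
    stop("invalid model: epoch end times must be positive and nested")
  dims <- as.integer(dims)
  sampled <- dims > 0
  set.seed(seed)
  raw <- .coal_expected_sfs(epochs, dims, as.integer(n_reps)) / 2
  arr <- array(raw, dim = dims + 1)
  if (any(!sampled)) {
    # drop singleton axes of unsampled demes
    arr <- array(arr, dim = (dims + 1)[sampled])
  }
  d2 <- dims[sampled]
  if (fold) {
    f <- .fold_array(arr, d2)
    new("FoldedSFS", counts = f$counts, mask = f$mask, dims = d2)
  } else {
    msk <- array(FALSE, dim = d2 + 1)
    new("FoldedSFS", counts = arr, mask = msk, dims = d2)
  }
}

#' Closed-form profile estimate of theta
#'
#' The Poisson composite likelihood is maximized in theta by
#' sum(obs) / sum(expected) over unmasked cells.
#' @param obs,expd matching \linkS4class{FoldedSFS} objects (observed counts
#'   and per-unit-theta expectation).
#' @export
thetaHat <- function(obs, expd) {
  stopifnot(identical(obs@dims, expd@dims))
  keep <- !(obs@mask | expd@mask)
  sum(obs@counts[keep]) / sum(expd@counts[keep])
}

#' Poisson composite log-likelihood of an observed SFS
#'
#' sum over unmasked cells of obs * log(theta * exp) - theta * exp -
#' log(obs!). Expected cells that are zero where the observation is positive
#' are floored at \code{eps} with a warning.
#'
#' @inheritParams thetaHat
#' @param theta the scaling of the expectation (see \code{\link{thetaHat}}).
#' @param eps floor for empty expectation cells.
#' @export
compositeLoglik <- function(obs, expd, theta, eps = 1e-8) {
  stopifnot(identical(obs@dims, expd@dims))
  keep <- !(obs@mask | expd@mask)
  o <- obs@counts[keep]
  e <- expd@counts[keep]
  bad <- e <= 0 & o > 0
  if (any(bad)) {
    warning(sum(bad), " expectation cell(s) floored at eps")
    e[bad] <- eps
  }
  lt <- ifelse(o > 0, o * log(theta * e), 0)
  sum(lt - theta * e - lfactorial(o))
}

#' Akaike information criterion
#' @param loglik log-likelihood at the optimum.
#' @param k free-parameter count (>= 1).
#' @return 2k - 2 loglik
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 1)
  2 * k - 2 * loglik
}

#' Fit a demographic model to an observed folded SFS
#'
#' Multi-start bounded Nelder-Mead on log-parameters: each start multiplies
#' the model defaults by independent log-uniform factors in
#' [1/perturb_fold, perturb_fold], runs at most \code{maxiter} simplex
#' iterations and the best start by composite log-likelihood wins. theta is
#' profiled analytically at every evaluation, so it is not a simplex
#' dimension; the AIC parameter count is length(params) + 1. The Monte-Carlo
#' expectation uses common random numbers (one simulation seed shared by all
#' evaluations), making the objective deterministic given \code{seed}.
#'
#' @param model a \linkS4class{DemographicModel}
#' @param obs observed \linkS4class{FoldedSFS}
#' @param n_starts number of perturbed starts (default 50).
#' @param perturb_fold multiplicative perturbation range (default 3).
#' @param maxiter Nelder-Mead iteration cap per start (default 20; small by
#'   design, raise for tighter optima).
#' @param seed RNG seed governing starts and the simulation stream.
#' @param n_reps coalescent replicates per objective evaluation.
#' @param dims per-deme allele-copy sample sizes (default: the observed dims
#'   mapped onto demes 1..k).
#' @return a \linkS4class{FitResult}
#' @export
fitModel <- function(model, obs, n_starts = 50, perturb_fold = 3,
                     maxiter = 20, seed = 1, n_reps = 5000, dims = NULL) {
  if (is.null(dims)) {
    dims <- rep(0L, 3)
    dims[seq_along(obs@dims)] <- obs@dims
    if (model@npop == 1L) dims <- obs@dims[1]
  }
  p0 <- model@params
  np <- length(p0)
  lw <- log(model@lower); up <- log(model@upper)
  set.seed(seed)
  sim_seed <- sample.int(.Machine$integer.max - 1, 1)
  starts <- replicate(n_starts,
    pmin(pmax(log(p0) + stats::runif(np, -log(perturb_fold), log(perturb_fold)),
              lw), up),
    simplify = FALSE)
  objective <- function(lp) {
    if (any(lp < lw - 1e-9) || any(lp > up + 1e-9)) return(1e12)
    par <- exp(lp); names(par) <- names(p0)
    expd <- suppressWarnings(
      expectedSfs(model, dims, n_reps = n_reps, seed = sim_seed, params = par))
    th <- thetaHat(obs, expd)
    if (!is.finite(th) || th <= 0) return(1e12)
    -suppressWarnings(compositeLoglik(obs, expd, th))
  }
  best <- NULL
  for (s in starts) {
    fit <- suppressWarnings(
      stats::optim(s, objective, method = "Nelder-Mead",
                   control = list(maxit = maxiter)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- exp(best$par); names(par) <- names(p0)
  expd <- suppressWarnings(
    expectedSfs(model, dims, n_reps = n_reps, seed = sim_seed, params = par))
  th <- thetaHat(obs, expd)
  ll <- suppressWarnings(compositeLoglik(obs, expd, th))
  k <- np + 1L
  new("FitResult", model = model@id, family = model@family, params = par,
      theta = th, loglik = ll, k = k, aic = aic(ll, k), converted = list())
}

#' Re-score a fit on a common high-precision expectation
#'
#' Composite log-likelihoods carry a Monte-Carlo offset that depends on the
#' simulation seed and replicate count used during optimization. Before
#' comparing models by AIC, every fit should be re-scored at its fitted
#' parameters on one shared, high-replicate evaluation (same seed, same
#' n_reps), which makes the residual offset common across models.
#'
#' @param fit a \linkS4class{FitResult}
#' @param model the model that produced it.
#' @param obs the observed \linkS4class{FoldedSFS}
#' @param n_reps evaluation replicates (default 50000).
#' @param seed shared evaluation seed.
#' @param dims per-deme sample sizes (as in \code{\link{fitModel}}).
#' @return the FitResult with loglik, theta and aic re-evaluated.
#' @export
rescoreFit <- function(fit, model, obs, n_reps = 50000, seed = 1,
                       dims = NULL) {
  if (is.null(dims)) {
    dims <- rep(0L, 3)
    dims[seq_along(obs@dims)] <- obs@dims
    if (model@npop == 1L) dims <- obs@dims[1]
  }
  expd <- suppressWarnings(
    expectedSfs(model, dims, n_reps = n_reps, seed = seed,
                params = fit@params))
  th <- thetaHat(obs, expd)
  ll <- suppressWarnings(compositeLoglik(obs, expd, th))
  initialize(fit, theta = th, loglik = ll, aic = aic(ll, fit@k))
}

#' Parametric-bootstrap confidence intervals for a fitted model
#'
#' Draws \code{n_boot} Poisson replicates of the observed SFS from the
#' fitted expectation (theta-hat times the per-unit-theta spectrum at the
#' fitted parameters) and refits each, reporting per-parameter quantile
#' intervals. Off by default in every pipeline because it multiplies the
#' fitting cost by \code{n_boot}; 100 replicates is the conventional choice.
#'
#' @param model the fitted \linkS4class{DemographicModel}
#' @param fit its \linkS4class{FitResult}
#' @param obs the observed \linkS4class{FoldedSFS} (for dims)
#' @param n_boot bootstrap replicates (default 100).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @param n_starts,maxiter,n_reps refit effort per replicate (kept modest:
#'   refits start from the fitted optimum).
#' @return matrix with parameters in rows, columns lower / estimate / upper.
#' @export
bootstrapFit <- function(model, fit, obs, n_boot = 100, level = 0.95,
                         seed = 1, n_starts = 4, maxiter = 40,
                         n_reps = 3000) {
  dims3 <- rep(0L, 3)
  dims3[seq_along(obs@dims)] <- obs@dims
  if (model@npop == 1L) dims3 <- obs@dims[1]
  expd <- suppressWarnings(
    expectedSfs(model, dims3, n_reps = max(n_reps, 20000), seed = seed,
                params = fit@params))
  lam <- fit@theta * sfsCounts(expd)
  m_at_opt <- initialize(model, params = fit@params)
  set.seed(seed)
  boot_seeds <- sample.int(2^20, n_boot)
  draws <- vapply(seq_len(n_boot), function(b) {
    set.seed(boot_seeds[b])
    oc <- array(stats::rpois(length(lam), lam), dim = dim(lam))
    oc[sfsMask(expd)] <- 0
    ob <- new("FoldedSFS", counts = oc, mask = sfsMask(expd),
              dims = obs@dims)
    fb <- fitModel(m_at_opt, ob, n_starts = n_starts, perturb_fold = 1.5,
                   maxiter = maxiter, seed = boot_seeds[b], n_reps = n_reps)
    fb@params
  }, fit@params)
  alpha <- (1 - level) / 2
  dm <- matrix(draws, nrow = length(fit@params),
               dimnames = list(names(fit@params), NULL))
  ci <- t(apply(dm, 1, function(x)
    c(lower = unname(stats::quantile(x, alpha)),
      estimate = NA_real_,
      upper = unname(stats::quantile(x, 1 - alpha)))))
  ci[, "estimate"] <- fit@params
  ci
}

#' Physical-unit constants
#' @param mu per-base per-generation mutation rate.
#' @param gen_time generation time in years.
#' @param L callable genome length in bp.
#' @export
unitConstants <- function(mu = 3.75e-8, gen_time = 15, L) {
  stopifnot(mu > 0, gen_time > 0, L > 0)
  list(mu = mu, gen_time = gen_time, L = L)
}

#' Convert a fit to physical units
#'
#' Nref = theta / (4 mu L); per-population Ne = nu * Nref; times in years are
#' 2 Nref T g (T in 2 Nref generations); migration parameters (2 Nref m
#' convention) convert to the per-generation replacement fraction
#' m / (2 Nref).
#'
#' @param fit a \linkS4class{FitResult}
#' @param const a \code{\link{unitConstants}} list.
#' @return the FitResult with its converted slot filled.
#' @export
convertUnits <- function(fit, const) {
  nref <- fit@theta / (4 * const$mu * const$L)
  conv <- list(N_ref = nref)
  p <- fit@params
  for (nm in names(p)) {
    if (startsWith(nm, "nu")) conv[[paste0("Ne_", nm)]] <- p[[nm]] * nref
    if (startsWith(nm, "m")) conv[[paste0("frac_", nm)]] <- p[[nm]] / (2 * nref)
  }
  tg <- function(t) 2 * nref * t * const$gen_time
  if ("T2" %in% names(p)) {
    conv$T2_years <- tg(p[["T2"]])
    if ("dT" %in% names(p)) conv$T1_years <- tg(p[["T2"]] + p[["dT"]])
  }
  if ("T" %in% names(p)) conv$T_years <- tg(p[["T"]])
  initialize(fit, converted = conv)
}

#' Rank fitted models by AIC
#'
#' Ascending AIC; ties broken by fewer parameters, then model id.
#' @param fits list of \linkS4class{FitResult}
#' @return data.frame(model, family, k, loglik, aic, delta_aic)
#' @export
selectModel <- function(fits) {
  stopifnot(length(fits) >= 2)
  df <- data.frame(
    model = vapply(fits, function(f) f@model, character(1)),
    family = vapply(fits, function(f) f@family, character(1)),
    k = vapply(fits, function(f) f@k, integer(1)),
    loglik = vapply(fits, function(f) f@loglik, numeric(1)),
    aic = vapply(fits, function(f) f@aic, numeric(1)))
  df <- df[order(df$aic, df$k, df$model), ]
  df$delta_aic <- df$aic - df$aic[1]
  rownames(df) <- NULL
  df
}

#' Write / read a folded SFS as a small text format
#'
#' Line 1: the array shape (dims + 1) and the word "folded"; line 2 the
#' flattened counts (R column-major); line 3 the flattened mask as 0/1.
#' @param sfs a \linkS4class{FoldedSFS}
#' @param path file path
#' @export
writeSfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(sfs@dims + 1L, "folded"), collapse = " "), con)
  writeLines(paste(as.numeric(sfs@counts), collapse = " "), con)
  writeLines(paste(as.integer(sfs@mask), collapse = " "), con)
  invisible(path)
}

#' @rdname writeSfs
#' @export
readSfs <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  shape <- as.integer(hdr[hdr != "folded"])
  cnt <- array(as.numeric(strsplit(trimws(ln[2]), "\\s+")[[1]]), dim = shape)
  msk <- array(as.logical(as.integer(strsplit(trimws(ln[3]), "\\s+")[[1]])),
               dim = shape)
  new("FoldedSFS", counts = cnt, mask = msk, dims = shape - 1L)
}
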