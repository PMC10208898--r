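#' Site QC filter configuration
#'
#' Defaults reproduce a strict resequencing QC: minor allele frequency >= 0.05,
#' per-site missing rate <= 20%, and mean depth within [1/3, 2] times the
#' across-site mean depth (applied only when depth is available).
#'
#' @param min_maf minimum minor allele frequency (on non-missing calls).
#' @param max_missing maximum fraction of missing calls per site.
#' @param depth_low_factor,depth_high_factor multipliers on the mean site depth
#'   bounding acceptable coverage.
#' @return a list of class "FilterConfig"
#' @export
filterConfig <- function(min_maf = 0.05, max_missing = 0.20,
                         depth_low_factor = 1 / 3, depth_high_factor = 2.0) {
  stopifnot(min_maf >= 0, min_maf < 0.5, max_missing >= 0, max_missing <= 1,
            depth_low_factor < depth_high_factor)
  structure(list(min_maf = min_maf, max_missing = max_missing,
                 depth_low_factor = depth_low_factor,
                 depth_high_factor = depth_high_factor),
            class = "FilterConfig")
}

#' Per-site minor allele frequency on non-missing calls
#' @param vm a VariantMatrix
#' @return numeric vector (NaN for all-missing sites)
#' @export
siteMaf <- function(vm) {
  g <- genotypes(vm)
  nonmiss <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * nonmiss)
  pmin(p, 1 - p)
}

#' Filter sites of a VariantMatrix
#'
#' Retains exactly the sites with MAF >= min_maf, missing fraction
#' <= max_missing and, when depth is present, mean depth within
#' [mean * depth_low_factor, mean * depth_high_factor]. Sites with all calls
#' missing are removed (counted in a message). The sample set is unchanged
#' and the operation is idempotent.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param cfg a \code{\link{filterConfig}}
#' @return the filtered VariantMatrix
#' @export
filterVariants <- function(vm, cfg = filterConfig()) {
  if (nSites(vm) == 0) return(vm)
  g <- genotypes(vm)
  nonmiss <- colSums(!is.na(g))
  all_missing <- nonmiss == 0
  if (any(all_missing))
    message(sum(all_missing), " site(s) with all calls missing removed")
  missfrac <- 1 - nonmiss / nrow(g)
  maf <- siteMaf(vm)
  keep <- !all_missing & missfrac <= cfg$max_missing & maf >= cfg$min_maf
  d <- siteDepth(vm)
  if (any(!is.na(d))) {
    mu <- mean(d, na.rm = TRUE)
    dep_ok <- is.na(d) | (d >= mu * cfg$depth_low_factor &
                            d <= mu * cfg$depth_high_factor)
    keep <- keep & dep_ok
  }
  vm[, which(keep)]
}

# one pruning pass over the current site sequence of one chromosome;
# returns logical keep vector
.ld_prune_pass <- function(g, window_snps, step_snps, r2_max) {
  m <- ncol(g)
  alive <- rep(TRUE, m)
  starts <- seq(1, m, by = step_snps)
  for (s in starts) {
    idx <- s:min(s + window_snps - 1, m)
    idx <- idx[alive[idx]]
    if (length(idx) < 2) next
    r2 <- suppressWarnings(stats::cor(g[, idx, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    for (a in seq_len(length(idx) - 1)) {
      if (!alive[idx[a]]) next
      for (b in (a + 1):length(idx)) {
        if (!alive[idx[b]]) next
        if (!is.na(r2[a, b]) && r2[a, b] > r2_max) alive[idx[b]] <- FALSE
      }
    }
  }
  alive
}

#' Greedy LD pruning of a VariantMatrix
#'
#' Sliding windows of \code{window_snps} sites advanced by \code{step_snps};
#' within a window, pairs are scanned left to right and the later (higher
#' index) site of any pair with squared genotype correlation above
#' \code{r2_max} is removed. Passes repeat on the surviving sites until no
#' further removal occurs, so no within-window pair of the output exceeds the
#' threshold. Deterministic; output sites keep their original order.
#'
#' @param vm a filtered \linkS4class{VariantMatrix}
#' @param window_snps,step_snps window size and step in SNP counts.
#' @param r2_max removal threshold on r squared.
#' @export
ldPrune <- function(vm, window_snps = 50, step_snps = 10, r2_max = 0.2) {
  if (step_snps < 1) stop("step_snps must be >= 1")
  if (nSites(vm) < 2) return(vm)
  keep_global <- rep(TRUE, nSites(vm))
  for (ch in unique(siteChrom(vm))) {
    sel <- which(siteChrom(vm) == ch)
    cur <- sel
    repeat {
      g <- genotypes(vm)[, cur, drop = FALSE]
      alive <- .ld_prune_pass(g, window_snps, step_snps, r2_max)
      if (all(alive)) break
      cur <- cur[alive]
      if (length(cur) < 2) break
    }
    keep_global[setdiff(sel, cur)] <- FALSE
  }
  vm[, which(keep_global)]
}
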