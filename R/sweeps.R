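#' Configuration of the cross-population composite-likelihood scan
#'
#' Defaults follow common practice for XP-CLR-style scans: 0.05-cM windows,
#' 100-bp grid steps, at most 200 SNPs assayed per window, and a uniform
#' genetic map of 1 cM/Mb (a per-chromosome map being rarely available for
#' non-model plants; the uniform scaling preserves score ranking).
#'
#' @param window_cM window size in centimorgans.
#' @param grid_step_bp spacing of score grid points in bp.
#' @param max_snps_per_window cap on SNPs entering one window.
#' @param cm_per_mb genetic-map scale.
#' @param quantile empirical top-quantile used downstream (in (0.5, 1)).
#' @param lambda_grid candidate sweep scales (cM) for the alternative model.
#' @param boundary_eps allele frequency standing in for "carried to the
#'   boundary by the sweep" in the likelihood (hard sweeps rarely reach
#'   exact fixation in a sample).
#' @export
sweepScanConfig <- function(window_cM = 0.05, grid_step_bp = 100,
                            max_snps_per_window = 200, cm_per_mb = 1.0,
                            quantile = 0.95,
                            lambda_grid = c(0.001, 0.002, 0.005, 0.01,
                                            0.02, 0.05),
                            boundary_eps = 0.05) {
  stopifnot(window_cM > 0, grid_step_bp > 0, max_snps_per_window > 0,
            cm_per_mb > 0, quantile > 0.5, quantile < 1)
  structure(list(window_cM = window_cM, grid_step_bp = grid_step_bp,
                 max_snps_per_window = max_snps_per_window,
                 cm_per_mb = cm_per_mb, quantile = quantile,
                 lambda_grid = lambda_grid, boundary_eps = boundary_eps),
            class = "SweepScanConfig")
}

# log P(k | n, q ~ truncnorm(p1, omega p1 (1-p1)) on (0,1)) per SNP,
# integrated on a fixed q grid
.neutral_loglik <- function(k2, n2, p1, omega, nq = 101) {
  q <- (seq_len(nq) - 0.5) / nq
  sd <- sqrt(pmax(omega * p1 * (1 - p1), 1e-12))
  # weights: truncated normal density on (0,1), renormalized on the grid
  w <- vapply(q, function(qq) stats::dnorm(qq, p1, sd), numeric(length(p1)))
  w <- w / pmax(rowSums(w), 1e-300)
  lik <- vapply(seq_along(q), function(i)
    stats::dbinom(k2, n2, q[i]), numeric(length(k2)))
  log(pmax(rowSums(w * lik), 1e-300))
}

#' Cross-population composite-likelihood sweep scan (simplified XP-CLR)
#'
#' At each grid point the object-population allele counts within the genetic
#' window are modelled either as neutral drift away from the reference
#' frequency (truncated normal with variance omega p (1-p), omega estimated
#' genome-wide) or as a sweep centred at the grid point: a SNP at genetic
#' distance d escapes the sweep with probability c = 1 - exp(-d / lambda)
#' and otherwise rides the swept haplotype to a boundary frequency. The score
#' is 2 (max over lambda - neutral) composite log-likelihood, non-negative by
#' construction. This variant omits the original XP-CLR's LD-based SNP
#' down-weighting; it is validated by planted-sweep power, not score equality
#' with the original tool.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param ref_samples,obj_samples sample ids of reference and object
#'   populations (>= 4 each).
#' @param cfg a \code{\link{sweepScanConfig}}
#' @return data.frame(chrom, pos, n_snps, xpclr); NA score where a window
#'   holds fewer than 5 usable SNPs.
#' @export
xpclrScan <- function(vm, ref_samples, obj_samples, cfg = sweepScanConfig()) {
  if (length(ref_samples) < 4 || length(obj_samples) < 4)
    stop("need >= 4 samples in each population")
  gR <- genotypes(vm)[ref_samples, , drop = FALSE]
  gO <- genotypes(vm)[obj_samples, , drop = FALSE]
  nR <- 2 * colSums(!is.na(gR)); nO <- 2 * colSums(!is.na(gO))
  p1 <- colSums(gR, na.rm = TRUE) / nR
  k2 <- colSums(gO, na.rm = TRUE)
  use <- !is.na(p1) & p1 > 0 & p1 < 1 & nO > 0
  p1 <- p1[use]; k2 <- k2[use]; n2 <- nO[use]
  chrom <- siteChrom(vm)[use]; pos <- sitePos(vm)[use]
  p2 <- k2 / n2
  omega <- max(mean((p2 - p1)^2 / (p1 * (1 - p1))), 1e-4)
  ln_neu <- .neutral_loglik(k2, n2, p1, omega)
  lb1 <- stats::dbinom(k2, n2, 1 - cfg$boundary_eps, log = TRUE)
  lb0 <- stats::dbinom(k2, n2, cfg$boundary_eps, log = TRUE)
  sweep_mix <- log(p1 * exp(lb1) + (1 - p1) * exp(lb0))
  gcm <- pos * cfg$cm_per_mb / 1e6
  half <- cfg$window_cM / 2
  out <- list()
  for (ch in unique(siteChrom(vm))) {
    allpos <- sitePos(vm)[siteChrom(vm) == ch]
    grid <- seq(min(allpos), max(allpos), by = cfg$grid_step_bp)
    sel <- which(chrom == ch)
    sp <- gcm[sel]
    score <- rep(NA_real_, length(grid))
    nsnp <- integer(length(grid))
    for (gi in seq_along(grid)) {
      gpos <- grid[gi] * cfg$cm_per_mb / 1e6
      j <- sel[sp >= gpos - half & sp <= gpos + half]
      if (length(j) > cfg$max_snps_per_window) {
        d0 <- abs(gcm[j] - gpos)
        j <- j[order(d0)[seq_len(cfg$max_snps_per_window)]]
      }
      nsnp[gi] <- length(j)
      if (length(j) < 5) next
      d <- abs(gcm[j] - gpos)
      ll_n <- sum(ln_neu[j])
      best <- ll_n
      for (lam in cfg$lambda_grid) {
        cc <- -expm1(-d / lam)
        ll_s <- sum(log(pmax((1 - cc) * exp(sweep_mix[j]) +
                               cc * exp(ln_neu[j]), 1e-300)))
        if (ll_s > best) best <- ll_s
      }
      score[gi] <- 2 * (best - ll_n)
    }
    out[[ch]] <- data.frame(chrom = ch, pos = grid, n_snps = nsnp,
                            xpclr = score)
  }
  do.call(rbind, out)
}

#' Reduce grid-point scores to a window grid (max within window)
#' @param scan output of \code{\link{xpclrScan}}
#' @param windows data.frame(chrom, start, end) window grid.
#' @return the window data.frame with column xpclr (NA for empty windows).
#' @export
xpclrToWindows <- function(scan, windows) {
  v <- rep(NA_real_, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- scan$chrom == ch & !is.na(scan$xpclr)
    p <- scan$pos[si]; s <- scan$xpclr[si]
    if (!length(p)) next
    o <- order(p); p <- p[o]; s <- s[o]
    lo <- findInterval(windows$start[wi] - 1, p)
    hi <- findInterval(windows$end[wi], p)
    v[wi] <- vapply(seq_along(wi), function(k) {
      if (hi[k] <= lo[k]) NA_real_ else max(s[(lo[k] + 1):hi[k]])
    }, numeric(1))
  }
  data.frame(windows[c("chrom", "start", "end")], xpclr = v)
}

#' Empirical top-quantile threshold and flags
#'
#' Cutoff is the type-7 empirical quantile of the non-missing values; flagged
#' entries are those at or above the cutoff. Missing values are excluded
#' from both the quantile and the flags.
#'
#' @param values numeric vector (>= 20 non-missing).
#' @param q quantile (default 0.95).
#' @return list(cutoff, flags logical aligned with values)
#' @export
quantileThreshold <- function(values, q = 0.95) {
  ok <- !is.na(values)
  if (sum(ok) < 20) stop("need >= 20 non-missing values")
  if (length(unique(values[ok])) == 1) {
    warning("degenerate distribution: all values identical; all flagged")
    return(list(cutoff = values[which(ok)[1]], flags = ok))
  }
  cutoff <- unname(stats::quantile(values[ok], q, type = 7))
  list(cutoff = cutoff, flags = ok & values >= cutoff)
}

#' Intersect per-metric flagged windows into sweep regions
#'
#' Windows flagged by all supplied metrics are merged (overlapping or
#' book-ended windows, gap 0) into maximal regions.
#'
#' @param windows data.frame(chrom, start, end), the shared window grid.
#' @param ... logical flag vectors aligned with \code{windows} (one per
#'   metric, e.g. fst, pi_ratio, xpclr).
#' @return data.frame(chrom, start, end) of designated regions (possibly
#'   empty).
#' @export
intersectSweeps <- function(windows, ...) {
  flags <- list(...)
  stopifnot(length(flags) >= 1)
  joint <- Reduce(`&`, flags)
  joint[is.na(joint)] <- FALSE
  if (!any(joint))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  gr <- GenomicRanges::GRanges(windows$chrom[joint],
                               IRanges::IRanges(windows$start[joint],
                                                windows$end[joint]))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red),
             end = GenomicRanges::end(red))
}

#' Three-metric selective-sweep caller
#'
#' Computes windowed Weir-Cockerham FST, ln(pi_ref / pi_obj) and the
#' composite-likelihood scan (reduced to the same window grid by
#' max-within-window), flags the empirical top quantile of each metric and
#' designates the windows flagged by all three, merged into maximal regions.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param ref_samples,obj_samples reference and object (candidate-swept)
#'   population sample ids.
#' @param ws window grid (default 100 kb / 10 kb).
#' @param cfg scan configuration.
#' @param q top quantile (default 0.95).
#' @param chrom_lengths optional named chromosome lengths.
#' @return list(windows, cutoffs, regions); windows carries the three metric
#'   columns and their flags.
#' @export
callSweeps <- function(vm, ref_samples, obj_samples, ws = windowSpec(),
                       cfg = sweepScanConfig(), q = 0.95,
                       chrom_lengths = NULL) {
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sitePos(vm), siteChrom(vm), max)
  fst <- wcFst(vm, ref_samples, obj_samples, ws, chrom_lengths)
  pi_ref <- windowPi(vm, ref_samples, ws, chrom_lengths)
  pi_obj <- windowPi(vm, obj_samples, ws, chrom_lengths)
  lpr <- lnPiRatio(pi_ref, pi_obj)
  xp <- xpclrToWindows(xpclrScan(vm, ref_samples, obj_samples, cfg),
                       fst[c("chrom", "start", "end")])
  t_fst <- quantileThreshold(fst$fst, q)
  t_lpr <- quantileThreshold(lpr$ln_pi_ratio, q)
  t_xp <- quantileThreshold(xp$xpclr, q)
  win <- data.frame(fst[c("chrom", "start", "end")],
                    fst = fst$fst, ln_pi_ratio = lpr$ln_pi_ratio,
                    xpclr = xp$xpclr,
                    flag_fst = t_fst$flags, flag_pi = t_lpr$flags,
                    flag_xpclr = t_xp$flags)
  regions <- intersectSweeps(win, t_fst$flags, t_lpr$flags, t_xp$flags)
  list(windows = win,
       cutoffs = c(fst = t_fst$cutoff, ln_pi_ratio = t_lpr$cutoff,
                   xpclr = t_xp$cutoff),
       regions = regions)
}

#' Genes overlapping sweep regions
#'
#' A gene supports a region when the spans overlap by at least 1 bp.
#' @param regions data.frame(chrom, start, end)
#' @param ann a \linkS4class{GeneAnnotation}
#' @return list with per-region gene id vectors (\code{genes}) and the
#'   unique union (\code{psg}).
#' @export
regionsToGenes <- function(regions, ann) {
  if (!nrow(regions))
    return(list(genes = list(), psg = character(0)))
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(gr, ann@genes, ignore.strand = TRUE)
  per <- lapply(seq_len(nrow(regions)), function(i)
    ann@genes$gene_id[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
  list(genes = per, psg = unique(unlist(per)))
}
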