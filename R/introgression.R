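## ABBA-BABA (Patterson's D) and f4-ratio for the fixed topology (((P1,P2)P3)O)

# outgroup-polarized derived allele frequencies for a trio + outgroup.
# Returns data.frame(chrom, pos, p1, p2, p3) over usable sites: the outgroup
# must be fixed (consensus = ancestral) and every population must have at
# least one non-missing call.
.derived_freqs <- function(vm, pops, trio) {
  stopifnot(length(trio) == 4)
  sets <- lapply(trio, function(p) popSamples(pops, p))
  g <- genotypes(vm)
  fr <- lapply(sets, function(s) {
    gs <- g[s, , drop = FALSE]
    n <- colSums(!is.na(gs))
    colSums(gs, na.rm = TRUE) / (2 * n)
  })
  pO <- fr[[4]]
  usable <- !is.na(pO) & (pO == 0 | pO == 1) &
    !is.na(fr[[1]]) & !is.na(fr[[2]]) & !is.na(fr[[3]])
  flip <- pO == 1
  d <- data.frame(chrom = siteChrom(vm), pos = sitePos(vm),
                  p1 = ifelse(flip, 1 - fr[[1]], fr[[1]]),
                  p2 = ifelse(flip, 1 - fr[[2]], fr[[2]]),
                  p3 = ifelse(flip, 1 - fr[[3]], fr[[3]]))
  d[usable, , drop = FALSE]
}

.block_ids <- function(chrom, pos, block_size) {
  paste(chrom, (pos - 1) %/% block_size, sep = ":")
}

# delete-one block jackknife of a ratio statistic num/den given per-block sums
.jackknife_ratio <- function(num_b, den_b) {
  B <- length(num_b)
  tot_n <- sum(num_b); tot_d <- sum(den_b)
  est <- tot_n / tot_d
  loo <- (tot_n - num_b) / (tot_d - den_b)
  loo <- loo[is.finite(loo)]
  B <- length(loo)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(est = est, se = se, n_blocks = B)
}

#' Patterson's D (ABBA-BABA) with block-jackknife significance
#'
#' Sites are polarized by the outgroup consensus (outgroup-polymorphic or
#' missing sites dropped). With derived-allele frequencies p1, p2, p3,
#' ABBA = sum (1-p1) p2 p3 and BABA = sum p1 (1-p2) p3;
#' D = (ABBA - BABA) / (ABBA + BABA). The standard error comes from a
#' delete-one block jackknife over physical blocks, Z = D / SE and the
#' p-value from the standard normal (two-sided).
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param pops a \linkS4class{PopulationMap}
#' @param trio character(4): labels of P1, P2, P3 and the outgroup.
#' @param block_size jackknife block size in bp (default 1 Mb).
#' @return list of class "IntrogressionResult" with d, jackknife_se, z, p,
#'   abba, baba, n_sites_used, n_blocks, trio.
#' @export
abbaBaba <- function(vm, pops, trio, block_size = 1000000) {
  fr <- .derived_freqs(vm, pops, trio)
  abba <- (1 - fr$p1) * fr$p2 * fr$p3
  baba <- fr$p1 * (1 - fr$p2) * fr$p3
  if (sum(abba) + sum(baba) == 0)
    stop("ABBA + BABA is zero: D undefined")
  blk <- .block_ids(fr$chrom, fr$pos, block_size)
  num_b <- tapply(abba - baba, blk, sum)
  den_b <- tapply(abba + baba, blk, sum)
  jk <- .jackknife_ratio(as.numeric(num_b), as.numeric(den_b))
  if (jk$n_blocks < 20)
    warning("fewer than 20 non-empty jackknife blocks: SE may be unstable")
  z <- jk$est / jk$se
  structure(list(d = jk$est, jackknife_se = jk$se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 abba = sum(abba), baba = sum(baba),
                 n_sites_used = nrow(fr), n_blocks = jk$n_blocks,
                 trio = trio),
            class = "IntrogressionResult")
}

#' @export
print.IntrogressionResult <- function(x, ...) {
  cat(sprintf("D = %.4f (SE %.4f, Z = %.2f, p = %.3g) over %d sites / %d blocks\n",
              x$d, x$jackknife_se, x$z, x$p, x$n_sites_used, x$n_blocks))
  invisible(x)
}

#' f4-ratio admixture-fraction estimate
#'
#' Estimates the fraction of P2 ancestry derived from the P3 lineage under
#' the topology (((P1,P2)P3)O), by splitting the P3 samples into two halves
#' (a, b; first/second half in sample order, documented and deterministic):
#' alpha = f4(P3a, O; P2, P1) / f4(P3a, O; P3b, P1), evaluated with
#' outgroup-polarized frequencies and block-jackknifed for a standard error.
#'
#' @inheritParams abbaBaba
#' @return list with f4_ratio, jackknife_se, z, n_blocks.
#' @export
f4Ratio <- function(vm, pops, trio, block_size = 1000000) {
  p3_samples <- popSamples(pops, trio[3])
  if (length(p3_samples) < 2)
    stop("P3 must have >= 2 samples to split")
  half <- length(p3_samples) %/% 2
  a_id <- paste0(trio[3], ".a"); b_id <- paste0(trio[3], ".b")
  asg <- pops@assignments
  asg[p3_samples[seq_len(half)]] <- a_id
  asg[p3_samples[(half + 1):length(p3_samples)]] <- b_id
  pops2 <- PopulationMap(asg)
  frA <- .derived_freqs(vm, pops2, c(trio[1], trio[2], a_id, trio[4]))
  g <- genotypes(vm)
  b_samp <- popSamples(pops2, b_id)
  gb <- g[b_samp, , drop = FALSE]
  nb <- colSums(!is.na(gb))
  p3b_all <- colSums(gb, na.rm = TRUE) / (2 * nb)
  key <- paste(siteChrom(vm), sitePos(vm))
  p3b <- p3b_all[match(paste(frA$chrom, frA$pos), key)]
  # re-polarize p3b consistently with frA's outgroup flip
  sO <- popSamples(pops, trio[4])
  gO <- g[sO, , drop = FALSE]
  pO_all <- colSums(gO, na.rm = TRUE) / (2 * colSums(!is.na(gO)))
  flip <- pO_all[match(paste(frA$chrom, frA$pos), key)] == 1
  p3b <- ifelse(flip, 1 - p3b, p3b)
  ok <- !is.na(p3b)
  frA <- frA[ok, ]; p3b <- p3b[ok]
  num <- frA$p3 * (frA$p2 - frA$p1)
  den <- frA$p3 * (p3b - frA$p1)
  if (abs(sum(den)) < 1e-12) stop("denominator f4 is ~0: ratio undefined")
  blk <- .block_ids(frA$chrom, frA$pos, block_size)
  jk <- .jackknife_ratio(as.numeric(tapply(num, blk, sum)),
                         as.numeric(tapply(den, blk, sum)))
  list(f4_ratio = jk$est, jackknife_se = jk$se,
       z = jk$est / jk$se, n_blocks = jk$n_blocks)
}
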