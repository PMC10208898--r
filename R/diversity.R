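#' Sliding-window specification
#'
#' Defaults follow the common resequencing convention of 100 kb windows
#' advanced in 10 kb steps.
#' @param size window size in bp.
#' @param step step in bp (<= size).
#' @param min_sites minimum informative sites for a window value.
#' @export
windowSpec <- function(size = 100000, step = 10000, min_sites = 1) {
  stopifnot(size > 0, step > 0, step <= size, min_sites >= 0)
  structure(list(size = size, step = step, min_sites = min_sites),
            class = "WindowSpec")
}

#' Sliding windows over chromosomes
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param ws a \code{\link{windowSpec}}
#' @return data.frame(chrom, start, end), 1-based inclusive coordinates.
#' @export
makeWindows <- function(chrom_lengths, ws = windowSpec()) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, len, by = ws$step)
    starts <- starts[starts <= len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + ws$size - 1, len))
  })
  do.call(rbind, out)
}

# sum of per-site values over windows (sites and windows on one chrom grid);
# returns matrix cbind(n_sites, total) aligned with `win`
.window_sums <- function(win, chrom, pos, values) {
  n <- nrow(win)
  tot <- numeric(n); cnt <- integer(n)
  for (ch in unique(win$chrom)) {
    wi <- which(win$chrom == ch)
    si <- which(chrom == ch & !is.na(values))
    if (!length(si)) next
    p <- pos[si]; v <- values[si]
    o <- order(p); p <- p[o]; v <- v[o]
    cs <- c(0, cumsum(v))
    lo <- findInterval(win$start[wi] - 1, p)        # sites strictly before start
    hi <- findInterval(win$end[wi], p)              # sites at or before end
    tot[wi] <- cs[hi + 1] - cs[lo + 1]
    cnt[wi] <- hi - lo
  }
  cbind(n_sites = cnt, total = tot)
}

# per-site unbiased heterozygosity within a sample subset
.site_pi <- function(g) {
  m <- 2 * colSums(!is.na(g))
  j <- colSums(g, na.rm = TRUE)
  pi <- ifelse(m >= 2, 2 * j * (m - j) / (m * (m - 1)), NA_real_)
  pi
}

#' Windowed nucleotide diversity
#'
#' Per-site pi is the unbiased expected heterozygosity
#' 2 j (m - j) / (m (m - 1)) over m non-missing allele copies carrying j
#' alternate alleles; the window value is the sum of per-site pi divided by
#' the window span in bp (per-bp units). Windows with fewer informative sites
#' than \code{ws$min_sites} are reported as NA.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param samples sample ids of one population (>= 2).
#' @param ws a \code{\link{windowSpec}}
#' @param chrom_lengths named chromosome lengths; defaults to the largest
#'   observed position per chromosome.
#' @return data.frame(chrom, start, end, n_sites, pi)
#' @export
windowPi <- function(vm, samples, ws = windowSpec(), chrom_lengths = NULL) {
  if (length(samples) < 2) stop("need >= 2 samples for pi")
  g <- genotypes(vm)[samples, , drop = FALSE]
  ps <- .site_pi(g)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sitePos(vm), siteChrom(vm), max)
  win <- makeWindows(chrom_lengths, ws)
  s <- .window_sums(win, siteChrom(vm), sitePos(vm), ps)
  pi <- s[, "total"] / (win$end - win$start + 1)
  pi[s[, "n_sites"] < ws$min_sites] <- NA_real_
  data.frame(win, n_sites = s[, "n_sites"], pi = pi)
}

#' Per-sample heterozygosity
#'
#' Count of heterozygous calls divided by total genome length.
#' @param vm a \linkS4class{VariantMatrix}
#' @param genome_length total genome length in bp (> 0).
#' @return named numeric per sample
#' @export
sampleHeterozygosity <- function(vm, genome_length) {
  stopifnot(genome_length > 0)
  g <- genotypes(vm)
  rowSums(g == 1L, na.rm = TRUE) / genome_length
}

#' Per-site Weir-Cockerham variance components for two populations
#'
#' Returns the a (among-population), b (among-individual) and c
#' (within-individual) components of Weir & Cockerham's 1984 estimator,
#' computed from genotype counts with per-site complete cases.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param samplesA,samplesB sample id vectors of the two populations.
#' @return matrix with columns a, b, c (NA at uninformative sites).
#' @export
wcFstComponents <- function(vm, samplesA, samplesB) {
  gA <- genotypes(vm)[samplesA, , drop = FALSE]
  gB <- genotypes(vm)[samplesB, , drop = FALSE]
  n1 <- colSums(!is.na(gA)); n2 <- colSums(!is.na(gB))
  p1 <- colSums(gA, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gB, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(gA == 1L, na.rm = TRUE) / n1
  h2 <- colSums(gB == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- n1 < 1 | n2 < 1 | nbar <= 1 | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  cbind(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham FST (ratio of sums)
#'
#' Window FST = sum(a) / sum(a + b + c) over informative sites in the window.
#' Raw values are reported without clamping: slightly negative estimates are
#' legitimate and empirical top-quantile thresholds operate on raw values.
#'
#' @inheritParams windowPi
#' @param samplesA,samplesB the two populations (>= 2 samples each).
#' @return data.frame(chrom, start, end, n_sites, fst)
#' @export
wcFst <- function(vm, samplesA, samplesB, ws = windowSpec(),
                  chrom_lengths = NULL) {
  if (length(samplesA) < 2 || length(samplesB) < 2)
    stop("need >= 2 samples per population")
  comp <- wcFstComponents(vm, samplesA, samplesB)
  denom_site <- rowSums(comp)
  informative <- !is.na(denom_site) & denom_site != 0
  aa <- ifelse(informative, comp[, "a"], NA_real_)
  dd <- ifelse(informative, denom_site, NA_real_)
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(sitePos(vm), siteChrom(vm), max)
  win <- makeWindows(chrom_lengths, ws)
  sa <- .window_sums(win, siteChrom(vm), sitePos(vm), aa)
  sd_ <- .window_sums(win, siteChrom(vm), sitePos(vm), dd)
  fst <- sa[, "total"] / sd_[, "total"]
  fst[sd_[, "n_sites"] == 0 | sd_[, "n_sites"] < ws$min_sites] <- NA_real_
  data.frame(win, n_sites = sd_[, "n_sites"], fst = fst)
}

#' Genome-wide Weir-Cockerham FST (single ratio of sums)
#' @inheritParams wcFst
#' @export
wcFstOverall <- function(vm, samplesA, samplesB) {
  comp <- wcFstComponents(vm, samplesA, samplesB)
  denom <- rowSums(comp)
  ok <- !is.na(denom)
  sum(comp[ok, "a"]) / sum(denom[ok])
}

#' Log ratio of windowed diversities
#'
#' ln(pi_num / pi_den) on a shared window grid; windows where either pi is
#' zero or missing are NA.
#' @param pi_num,pi_den outputs of \code{\link{windowPi}} on identical grids.
#' @return the window data.frame with column ln_pi_ratio
#' @export
lnPiRatio <- function(pi_num, pi_den) {
  if (!identical(pi_num[c("chrom", "start", "end")],
                 pi_den[c("chrom", "start", "end")]))
    stop("window grids do not match")
  v <- ifelse(!is.na(pi_num$pi) & !is.na(pi_den$pi) &
                pi_num$pi > 0 & pi_den$pi > 0,
              log(pi_num$pi / pi_den$pi), NA_real_)
  data.frame(pi_num[c("chrom", "start", "end")], ln_pi_ratio = v)
}

#' Half-decay distance of a binned LD curve
#'
#' The curve is first made monotone non-increasing by an isotonic fit; the
#' half-decay distance is the smallest distance at which the smoothed curve
#' reaches half of its maximum.
#' @param distance bin-centre distances (bp, increasing).
#' @param mean_r2 binned mean r-squared values.
#' @return list(max_r2, half_decay_distance, smoothed)
#' @export
halfDecayDistance <- function(distance, mean_r2) {
  ok <- !is.na(mean_r2)
  d <- distance[ok]; r <- mean_r2[ok]
  if (!length(d)) stop("empty LD curve")
  iso <- stats::isoreg(d, -r)
  sm <- -iso$yf[order(order(d))]
  mx <- sm[1]
  idx <- which(sm <= mx / 2 + 1e-12)
  half <- if (length(idx)) d[idx[1]] else NA_real_
  list(max_r2 = mx, half_decay_distance = half,
       smoothed = data.frame(distance = d, r2 = sm))
}

#' LD decay curve within one population
#'
#' r-squared is the squared Pearson correlation of genotype dosage over
#' pairwise-complete samples, for all site pairs up to \code{max_dist} apart
#' on the same chromosome; sites are pre-filtered at MAF >= 0.05 and missing
#' rate <= 0.2 within the population. Binned means use \code{bin_width} bp
#' bins and the half-decay distance comes from \code{\link{halfDecayDistance}}.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param samples population sample ids.
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return list of class "LDDecayCurve": bins (data.frame distance, mean_r2,
#'   n_pairs), max_r2, half_decay_distance.
#' @export
ldDecay <- function(vm, samples, max_dist = 500000, bin_width = 100) {
  sub <- vm[samples, ]
  sub <- filterVariants(sub, filterConfig(min_maf = 0.05, max_missing = 0.2))
  g <- genotypes(sub)
  chrom <- siteChrom(sub); pos <- sitePos(sub)
  dists <- integer(0); r2s <- numeric(0)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    for (ii in seq_along(idx)) {
      jj <- which(p > p[ii] & p - p[ii] <= max_dist)
      if (!length(jj)) next
      r <- suppressWarnings(
        stats::cor(g[, idx[ii]], g[, idx[jj], drop = FALSE],
                   use = "pairwise.complete.obs"))
      dists <- c(dists, p[jj] - p[ii])
      r2s <- c(r2s, as.numeric(r)^2)
    }
  }
  ok <- !is.na(r2s)
  dists <- dists[ok]; r2s <- r2s[ok]
  if (!length(dists)) stop("no SNP pair within max_dist")
  bin <- pmin(ceiling(dists / bin_width), ceiling(max_dist / bin_width))
  mean_r2 <- tapply(r2s, bin, mean)
  n_pairs <- tapply(r2s, bin, length)
  centre <- (as.integer(names(mean_r2)) - 0.5) * bin_width
  hd <- halfDecayDistance(centre, as.numeric(mean_r2))
  structure(list(bins = data.frame(distance = centre,
                                   mean_r2 = as.numeric(mean_r2),
                                   n_pairs = as.integer(n_pairs)),
                 max_r2 = hd$max_r2,
                 half_decay_distance = hd$half_decay_distance),
            class = "LDDecayCurve")
}
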