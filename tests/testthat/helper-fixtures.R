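# Small deterministic fixture builders shared across test files.

# VariantMatrix from a genotype matrix with evenly spaced positions
toy_vm <- function(g, chrom = "chr1", pos = NULL, ref = NULL, alt = NULL,
                   depth = NULL) {
  g <- as.matrix(g)
  storage.mode(g) <- "integer"
  if (is.null(rownames(g))) rownames(g) <- paste0("s", seq_len(nrow(g)))
  ns <- ncol(g)
  if (is.null(pos)) pos <- seq_len(ns) * 100L
  if (is.null(ref)) ref <- rep("A", ns)
  if (is.null(alt)) alt <- rep("T", ns)
  VariantMatrix(g, rep(chrom, ns), pos, ref, alt, depth)
}

# literal scalar transcription of the Weir & Cockerham (1984) a, b, c
# variance components for two populations at one biallelic site
wc_oracle_site <- function(gA, gB) {
  r <- 2
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n <- c(length(gA), length(gB))
  p <- c(sum(gA) / (2 * n[1]), sum(gB) / (2 * n[2]))
  h <- c(mean(gA == 1), mean(gB == 1))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Hudson-style FST from allele frequencies: 1 - Hw / Hb, ratio of averages
hudson_fst <- function(vm, sA, sB) {
  g <- genotypes(vm)
  fA <- colMeans(g[sA, , drop = FALSE], na.rm = TRUE) / 2
  fB <- colMeans(g[sB, , drop = FALSE], na.rm = TRUE) / 2
  nA <- 2 * colSums(!is.na(g[sA, , drop = FALSE]))
  nB <- 2 * colSums(!is.na(g[sB, , drop = FALSE]))
  hw <- fA * (1 - fA) * nA / (nA - 1) + fB * (1 - fB) * nB / (nB - 1)
  hb <- fA * (1 - fB) + fB * (1 - fA)
  1 - sum(hw) / sum(hb)
}

# independent greedy LD-prune trace used as oracle on tiny inputs:
# windows are laid over the surviving site sequence, pairs scanned left to
# right removing the later site; passes repeat until stable
ld_prune_oracle <- function(g, window_snps, step_snps, r2_max) {
  surv <- seq_len(ncol(g))
  repeat {
    alive <- rep(TRUE, length(surv))
    for (s in seq(1, length(surv), by = step_snps)) {
      idx <- s:min(s + window_snps - 1, length(surv))
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        i <- idx[a]; j <- idx[b]
        if (!alive[i] || !alive[j]) next
        r2 <- suppressWarnings(cor(g[, surv[i]], g[, surv[j]],
                                   use = "pairwise.complete.obs"))^2
        if (!is.na(r2) && r2 > r2_max) alive[j] <- FALSE
      }
    }
    if (all(alive)) break
    surv <- surv[alive]
    if (length(surv) < 2) break
  }
  surv
}

write_mini_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB\tsampC",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t0/1",
    "chr1\t300\t.\tG\tA,T\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"),
    path)
  path
}
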