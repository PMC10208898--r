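## Seeded generators for every input the pipeline consumes.

#' Simulate genotypes under a demographic model
#'
#' Coalescent genotypes over a chromosome tiled with independent
#' non-recombining loci of \code{locus_len} bp (free recombination between
#' loci, complete linkage within; an internal Hudson-style engine with no
#' external simulator dependency). Mutations follow the infinite-sites model
#' at rate theta_site = 4 Nref mu per bp. The generating parameters are
#' returned as the truth record. Deterministic given \code{seed}.
#'
#' @param model a \linkS4class{DemographicModel}
#' @param n_dip named integer: diploid sample count per population, in deme
#'   order (names become population labels).
#' @param L chromosome length in bp.
#' @param theta_site population-scaled mutation rate per bp.
#' @param locus_len independent-locus length in bp.
#' @param chrom chromosome label.
#' @param seed RNG seed.
#' @param params model parameters (defaults to the model defaults).
#' @return list(vm = \linkS4class{VariantMatrix}, pops =
#'   \linkS4class{PopulationMap}, truth = generating parameters)
#' @export
simulateGenotypes <- function(model, n_dip, L, theta_site = 0.001,
                              locus_len = 2000, chrom = "chr1", seed = 1,
                              params = model@params) {
  stopifnot(!is.null(names(n_dip)), all(n_dip >= 0), L > 0, theta_site >= 0)
  epochs <- modelEpochs(model, params)
  ndeme <- length(epochs[[1]]$nu)
  samp <- rep(0L, ndeme)
  samp[seq_along(n_dip)] <- 2L * as.integer(n_dip)
  ntot_dip <- sum(n_dip)
  sample_ids <- unlist(lapply(names(n_dip), function(p)
    paste0(p, "_", seq_len(n_dip[[p]]))))
  set.seed(seed)
  n_loci <- ceiling(L / locus_len)
  geno_cols <- list(); pos_all <- integer(0)
  for (lo in seq_len(n_loci)) {
    start <- (lo - 1) * locus_len + 1
    len <- min(locus_len, L - start + 1)
    muts <- .coal_sim_locus(epochs, samp, theta_site * len)
    if (!length(muts)) next
    # unique integer positions within the locus
    pos <- sort(sample.int(len, min(length(muts), len))) + start - 1L
    muts <- muts[seq_along(pos)]
    for (m in seq_along(muts)) {
      carriers <- muts[[m]] + 1L              # 1-based allele-copy ids
      gcol <- tabulate((carriers + 1L) %/% 2L, nbins = ntot_dip)
      geno_cols[[length(geno_cols) + 1L]] <- gcol
    }
    pos_all <- c(pos_all, pos)
  }
  if (!length(geno_cols)) {
    warning("zero mutations simulated: empty matrix")
    g <- matrix(integer(0), nrow = ntot_dip, ncol = 0,
                dimnames = list(sample_ids, NULL))
    vm <- VariantMatrix(g, character(0), integer(0), character(0), character(0))
  } else {
    g <- do.call(cbind, geno_cols)
    rownames(g) <- sample_ids
    nsnp <- ncol(g)
    ref <- sample(c("A", "C", "G", "T"), nsnp, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    vm <- VariantMatrix(g, chrom = rep(chrom, nsnp), pos = pos_all,
                        ref = ref, alt = unname(alt))
  }
  asg <- rep(names(n_dip), times = n_dip)
  names(asg) <- sample_ids
  list(vm = vm, pops = PopulationMap(asg),
       truth = list(model = model@id, params = params,
                    theta_site = theta_site, L = L, locus_len = locus_len,
                    seed = seed))
}

#' Plant a hard selective sweep into a genotype matrix
#'
#' Within \code{region}, one randomly chosen donor's genotype vector is
#' copied into target-population samples until the copied state reaches
#' \code{final_freq} of the population, mimicking (selection-free) the
#' diversity collapse and frequency shift of a hard sweep. Diversity inside
#' the region strictly decreases whenever recipients existed.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param samples target-population sample ids.
#' @param region list or vector (chrom, start, end).
#' @param final_freq fraction of target samples carrying the swept genotype.
#' @param seed RNG seed (donor and recipient choice).
#' @return the modified VariantMatrix
#' @export
plantSweep <- function(vm, samples, region, final_freq = 0.9, seed = 1) {
  chrom <- as.character(region[[1]])
  start <- as.numeric(region[[2]]); end <- as.numeric(region[[3]])
  sel <- which(siteChrom(vm) == chrom & sitePos(vm) >= start &
                 sitePos(vm) <= end)
  if (!length(sel)) {
    warning("region holds no SNP: nothing planted")
    return(vm)
  }
  set.seed(seed)
  donor <- sample(samples, 1)
  ncarry <- ceiling(final_freq * length(samples))
  if (ncarry <= 1) return(vm)
  g <- genotypes(vm)
  # donor pseudo-haplotype: homozygous sites resolve directly, heterozygous
  # sites get a seeded random phase; carriers become homozygous for it
  gd <- g[donor, sel]
  hap <- ifelse(is.na(gd), 0L, as.integer(gd == 2L))
  het <- !is.na(gd) & gd == 1L
  hap[het] <- as.integer(stats::runif(sum(het)) < 0.5)
  carriers <- c(donor, sample(setdiff(samples, donor), ncarry - 1))
  g[carriers, sel] <- rep(2L * hap, each = length(carriers))
  VariantMatrix(g, siteChrom(vm), sitePos(vm), siteRef(vm), siteAlt(vm),
                siteDepth(vm))
}

# genome position of CDS (translation-order) base q for the toy gene layout:
# two exons [s, s+e-1], [s+e+i, s+2e+i-1], strand-aware
.toy_cds_pos <- function(q, s, e, i, strand) {
  if (strand == "+") {
    if (q <= e) s + q - 1 else s + e + i + (q - e) - 1
  } else {
    if (q <= e) (s + 2 * e + i - 1) - (q - 1) else (s + e - 1) - (q - e - 1)
  }
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Toy annotated genome with a placed-SNP truth table
#'
#' Builds a single chromosome of random sequence carrying \code{n_genes}
#' two-exon genes on alternating strands. Coding sequences are constructed
#' codon-wise (TGC repeats closed by TGA) so that placed SNPs have effect
#' classes known by construction, independent of any translation code:
#' per gene one upstream, splice-site, intronic, synonymous, nonsynonymous,
#' stop-gain, stop-lost and downstream SNP, plus two intergenic SNPs on the
#' leading gap. Writes FASTA and GFF3 into \code{dir}.
#'
#' @param n_genes number of genes (0 allowed: truth is all-intergenic).
#' @param exon_len exon length in bp (multiple of 3).
#' @param intron_len intron length in bp.
#' @param dir output directory for fasta/gff files.
#' @param seed RNG seed for the background sequence.
#' @return list(fasta, gff, truth = data.frame(chrom, pos, ref, alt, class),
#'   chrom_len)
#' @export
makeToyGenome <- function(n_genes = 2, exon_len = 150, intron_len = 90,
                          dir = tempdir(), seed = 1) {
  stopifnot(exon_len %% 3 == 0, intron_len >= 10)
  set.seed(seed)
  gap0 <- 12000; gap <- 12000
  glen <- 2 * exon_len + intron_len
  total <- gap0 + max(n_genes, 0) * (glen + gap)
  seqv <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ncod <- 2 * exon_len / 3
  cds <- c(rep(c("T", "G", "C"), ncod - 1), c("T", "G", "A"))
  gff <- c("##gff-version 3")
  truth <- list()
  add_truth <- function(pos, alt, cls)
    truth[[length(truth) + 1]] <<- data.frame(pos = pos, alt = alt, class = cls)
  starts <- integer(0)
  for (k in seq_len(n_genes)) {
    s <- gap0 + (k - 1) * (glen + gap) + 1
    starts <- c(starts, s)
    strand <- if (k %% 2 == 1) "+" else "-"
    ex1 <- c(s, s + exon_len - 1)
    intr <- c(s + exon_len, s + exon_len + intron_len - 1)
    ex2 <- c(s + exon_len + intron_len, s + glen - 1)
    # write CDS into the genome (strand-aware)
    for (q in seq_along(cds)) {
      p <- .toy_cds_pos(q, s, exon_len, intron_len, strand)
      seqv[p] <- if (strand == "+") cds[q] else .COMP[[cds[q]]]
    }
    gid <- sprintf("gene%02d", k); tid <- paste0(gid, ".t1")
    att <- function(id, parent = NULL)
      paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent))
    row <- function(type, a, b, ph, attr)
      paste("toychr", "toy", type, a, b, ".", strand, ph, attr, sep = "\t")
    gff <- c(gff,
             row("gene", s, s + glen - 1, ".", att(gid)),
             row("mRNA", s, s + glen - 1, ".", att(tid, gid)),
             row("exon", ex1[1], ex1[2], ".", att(paste0(tid, ".e1"), tid)),
             row("exon", ex2[1], ex2[2], ".", att(paste0(tid, ".e2"), tid)),
             row("CDS", ex1[1], ex1[2], "0", att(paste0(tid, ".c1"), tid)),
             row("CDS", ex2[1], ex2[2], "0", att(paste0(tid, ".c2"), tid)))
    # coding SNPs, positions in translation order; classes by construction
    snp_cds <- function(q, cds_alt, cls) {
      p <- .toy_cds_pos(q, s, exon_len, intron_len, strand)
      a <- if (strand == "+") cds_alt else .COMP[[cds_alt]]
      add_truth(p, a, cls)
    }
    snp_cds(2 * 3, "T", "synonymous")        # codon 2: TGC -> TGT
    snp_cds(3 * 3, "A", "stop_gain")         # codon 3: TGC -> TGA
    snp_cds(4 * 3 - 1, "C", "nonsynonymous") # codon 4: TGC -> TCC (Ser)
    snp_cds(length(cds), "C", "stop_lost")   # final TGA -> TGC (Cys)
    # non-coding SNPs
    up_pos <- if (strand == "+") s - 100 else s + glen - 1 + 100
    dn_pos <- if (strand == "+") s + glen - 1 + 100 else s - 100
    imid <- intr[1] + intron_len %/% 2
    add_truth(up_pos, NA, "upstream")
    add_truth(dn_pos, NA, "downstream")
    add_truth(intr[1], NA, "splice_site")
    add_truth(imid, NA, "intronic")
  }
  add_truth(1000, NA, "intergenic")
  add_truth(2000, NA, "intergenic")
  tr <- do.call(rbind, truth)
  tr <- tr[order(tr$pos), ]
  tr$ref <- seqv[tr$pos]
  # fill alt for non-coding SNPs with any differing base
  need <- is.na(tr$alt)
  tr$alt[need] <- vapply(tr$ref[need], function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1))
  tr <- data.frame(chrom = "toychr", pos = tr$pos, ref = tr$ref,
                   alt = tr$alt, class = tr$class,
                   stringsAsFactors = FALSE)
  fasta <- file.path(dir, "toy_genome.fa")
  gfff <- file.path(dir, "toy_genome.gff3")
  gseq <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(gseq) <- "toychr"
  Biostrings::writeXStringSet(gseq, fasta)
  writeLines(gff, gfff)
  list(fasta = fasta, gff = gfff, truth = tr, chrom_len = total)
}

#' Occurrence/environment fixture with controllable niche separation
#'
#' Two species' occurrences drawn from 2-D Gaussians in environment space
#' whose means are \code{separation} apart (Euclidean); additional noise
#' variables pad the environmental matrix. Optionally writes deterministic
#' CSVs (species, lon, lat, env columns).
#'
#' @param separation distance between niche centres in environment space.
#' @param n_per_species occurrences per species.
#' @param seed RNG seed.
#' @param n_env total environmental variables (>= 2).
#' @param dir optional output directory for CSV files.
#' @return list(envA, envB, occ, files)
#' @export
makeNicheFixture <- function(separation = 0, n_per_species = 50, seed = 1,
                             n_env = 4, dir = NULL) {
  stopifnot(separation >= 0, n_env >= 2)
  set.seed(seed)
  shift <- separation / sqrt(2)
  mkenv <- function(n, mu) {
    cbind(stats::rnorm(n, mu[1]), stats::rnorm(n, mu[2]),
          matrix(stats::rnorm(n * (n_env - 2)), n))
  }
  envA <- mkenv(n_per_species, c(0, 0))
  envB <- mkenv(n_per_species, c(shift, shift))
  colnames(envA) <- colnames(envB) <- paste0("env", seq_len(n_env))
  occ <- data.frame(
    species = rep(c("A", "B"), each = n_per_species),
    lon = stats::runif(2 * n_per_species, 90, 120),
    lat = stats::runif(2 * n_per_species, 20, 45),
    rbind(envA, envB))
  files <- NULL
  if (!is.null(dir)) {
    files <- file.path(dir, c("occurrences_A.csv", "occurrences_B.csv"))
    utils::write.csv(occ[occ$species == "A", ], files[1], row.names = FALSE)
    utils::write.csv(occ[occ$species == "B", ], files[2], row.names = FALSE)
  }
  list(envA = envA[, 1:2], envB = envB[, 1:2], occ = occ, files = files)
}
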