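test_that("readVcfMatrix keeps only biallelic SNPs and maps genotype codes", {
  path <- write_mini_vcf(tempfile(fileext = ".vcf"))
  vm <- readVcfMatrix(path)
  expect_s4_class(vm, "VariantMatrix")
  expect_equal(nSamples(vm), 3)
  expect_equal(nSites(vm), 2)          # multiallelic and indel dropped
  expect_equal(sampleIds(vm), c("sampA", "sampB", "sampC"))
  expect_equal(unname(genotypes(vm)[, 1]), c(0L, 1L, 2L))
  expect_true(is.na(genotypes(vm)["sampA", 2]))
  expect_equal(sitePos(vm), c(100L, 200L))
})

test_that("VariantMatrix validity rejects malformed objects", {
  g <- matrix(0L, 2, 2)
  expect_error(VariantMatrix(g, c("c1", "c1"), c(20L, 10L),
                             c("A", "A"), c("T", "T")),
               "increasing")
  expect_error(VariantMatrix(g, c("c1", "c1"), c(10L, 20L),
                             c("A", "A"), c("A", "T")),
               "distinct")
  gbad <- matrix(c(0L, 3L, 1L, 2L), 2, 2)
  expect_error(VariantMatrix(gbad, c("c1", "c1"), c(10L, 20L),
                             c("A", "A"), c("T", "G")))
})

test_that("filterVariants applies MAF, missingness and depth rules exactly", {
  # 20 samples, single heterozygote: MAF 0.025 < 0.05 -> removed
  g <- matrix(0L, 20, 1); g[1, 1] <- 1L
  expect_equal(nSites(filterVariants(toy_vm(g))), 0)
  # 5/20 missing (25% > 20%) -> removed even though MAF fine
  g2 <- matrix(c(rep(NA_integer_, 5), rep(0L, 7), rep(1L, 8)), 20, 1)
  expect_equal(nSites(filterVariants(toy_vm(g2))), 0)

  # 10-site toy matrix, 3 sites violating exactly one rule each (hand check):
  # site 2 low MAF, site 5 high missingness, site 8 depth out of range
  set.seed(1)
  n <- 10
  g3 <- matrix(1L, n, 10)
  g3[, ] <- rep(c(0L, 1L), length.out = n * 10)   # MAF 0.25 everywhere
  g3[2:n, 2] <- 0L; g3[1, 2] <- 0L                 # site 2 monomorphic
  g3[1:3, 5] <- NA_integer_                        # 30% missing
  depth <- rep(10, 10); depth[8] <- 100            # mean ~19; 100 > 2 * mean
  vm3 <- toy_vm(g3, depth = depth)
  out <- filterVariants(vm3)
  expect_equal(nSites(out), 7)
  expect_false(any(sitePos(out) %in% sitePos(vm3)[c(2, 5, 8)]))
  # idempotency
  expect_identical(genotypes(filterVariants(out)), genotypes(out))
  expect_identical(sitePos(filterVariants(out)), sitePos(out))
})

test_that("all-missing sites are removed with a message, not an error", {
  g <- cbind(rep(NA_integer_, 6), rep(c(0L, 1L), 3))
  expect_message(out <- filterVariants(toy_vm(g), filterConfig(min_maf = 0)),
                 "all calls missing")
  expect_equal(nSites(out), 1)
})

test_that("ldPrune removes the later site of high-LD pairs", {
  set.seed(42)
  base <- sample(0:2, 30, replace = TRUE)
  # two identical adjacent sites -> exactly one removed
  g <- cbind(base, base)
  out <- ldPrune(toy_vm(g))
  expect_equal(nSites(out), 1)
  expect_equal(sitePos(out), 100L)     # the earlier site survives
  # mutually uncorrelated sites -> untouched
  g2 <- replicate(6, sample(0:2, 200, replace = TRUE))
  vm2 <- toy_vm(g2)
  out2 <- ldPrune(vm2, r2_max = 0.2)
  expect_equal(nSites(out2), nSites(vm2))
})

test_that("ldPrune matches an exhaustive greedy-rule trace and its invariant", {
  set.seed(7)
  base <- sample(0:2, 40, replace = TRUE)
  g <- cbind(base, sample(0:2, 40, TRUE), base, sample(0:2, 40, TRUE),
             base, sample(0:2, 40, TRUE), sample(0:2, 40, TRUE),
             sample(0:2, 40, TRUE))      # correlated triple at 1, 3, 5
  vm <- toy_vm(g)
  out <- ldPrune(vm, window_snps = 4, step_snps = 2, r2_max = 0.2)
  expect_equal(sitePos(out),
               sitePos(vm)[ld_prune_oracle(g, 4, 2, 0.2)])
  # invariant: no surviving within-window pair exceeds the threshold
  go <- genotypes(out)
  for (s in seq(1, ncol(go), by = 2)) {
    idx <- s:min(s + 3, ncol(go))
    if (length(idx) < 2) next
    r2 <- suppressWarnings(cor(go[, idx]))^2
    expect_true(all(r2[upper.tri(r2)] <= 0.2 + 1e-12, na.rm = TRUE))
  }
  expect_error(ldPrune(vm, step_snps = 0), "step")
})

test_that("SNP effect classification reproduces the generator truth table", {
  toy <- makeToyGenome(n_genes = 2, seed = 3)
  genome <- readGenomeFasta(toy$fasta)
  ann <- readGeneAnnotation(toy$gff)
  tr <- toy$truth
  vm <- VariantMatrix(matrix(1L, 1, nrow(tr), dimnames = list("s1", NULL)),
                      tr$chrom, tr$pos, tr$ref, tr$alt)
  eff <- classifySnpEffects(vm, genome, ann)
  expect_equal(as.character(eff$effect), tr$class)
  fr <- effectSummary(eff)
  expect_equal(sum(fr), 1)
})

test_that("classification is invariant under reverse-complementing the fixture", {
  toy <- makeToyGenome(n_genes = 2, seed = 11)
  genome <- readGenomeFasta(toy$fasta)
  ann <- readGeneAnnotation(toy$gff)
  tr <- toy$truth
  L <- toy$chrom_len
  # reverse-complement the chromosome; remap features and SNPs
  rc <- Biostrings::reverseComplement(genome[[1]])
  genome_rc <- Biostrings::DNAStringSet(rc); names(genome_rc) <- "toychr"
  flip_gr <- function(gr) {
    st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
    GenomicRanges::ranges(gr) <- IRanges::IRanges(L - en + 1, L - st + 1)
    str <- as.character(GenomicRanges::strand(gr))
    GenomicRanges::strand(gr) <- ifelse(str == "+", "-",
                                        ifelse(str == "-", "+", str))
    gr
  }
  ann_rc <- new("GeneAnnotation", genes = flip_gr(ann@genes),
                exons = flip_gr(ann@exons), cds = flip_gr(ann@cds))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  o <- order(L - tr$pos + 1)
  tr_rc <- data.frame(chrom = tr$chrom, pos = L - tr$pos + 1,
                      ref = unname(comp[tr$ref]), alt = unname(comp[tr$alt]),
                      class = tr$class)[o, ]
  vm_rc <- VariantMatrix(matrix(1L, 1, nrow(tr_rc),
                                dimnames = list("s1", NULL)),
                         tr_rc$chrom, tr_rc$pos, tr_rc$ref, tr_rc$alt)
  eff_rc <- classifySnpEffects(vm_rc, genome_rc, ann_rc)
  # upstream/downstream swap orientation with the flip; both map to flanks
  got <- as.character(eff_rc$effect)
  want <- tr_rc$class
  flank <- want %in% c("upstream", "downstream")
  expect_equal(got[!flank], want[!flank])
  expect_true(all(got[flank] %in% c("upstream", "downstream")))
})

test_that("population map round-trips through its TSV format", {
  pm <- PopulationMap(c(s1 = "A", s2 = "A", s3 = "B"))
  path <- tempfile(fileext = ".tsv")
  writePopulationMap(pm, path)
  pm2 <- readPopulationMap(path)
  expect_equal(pm2@assignments, pm@assignments)
  expect_equal(popSamples(pm2, "B"), "s3")
  expect_error(popSamples(pm2, "absent"), "empty or unknown")
})
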