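#' Read biallelic SNPs from a VCF file into a VariantMatrix
#'
#' Multiallelic records, indels and other non-SNP records are dropped.
#' Genotype calls are mapped to alternate-allele dosage (0/0 -> 0,
#' 0/1 or 1/0 -> 1, 1/1 -> 2); missing calls (./.) map to NA. Per-site mean
#' depth is taken from the per-sample DP FORMAT field when present.
#'
#' @param path path to a VCF v4.x file (plain or gzipped).
#' @return a \linkS4class{VariantMatrix}; zero biallelic SNPs yields an empty
#'   matrix with a warning, not an error.
#' @export
readVcfMatrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  if (!any(keep)) {
    warning("no biallelic SNP records in ", path)
    samples <- colnames(v@gt)[-1]
    g <- matrix(integer(0), nrow = length(samples), ncol = 0,
                dimnames = list(samples, NULL))
    return(VariantMatrix(g, character(0), integer(0), character(0), character(0)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  # normalize separators, count alt alleles
  core <- substr(gsub("\\|", "/", gt), 1, 3)
  dos <- matrix(NA_integer_, nrow = nrow(core), ncol = ncol(core))
  dos[core == "0/0"] <- 0L
  dos[core %in% c("0/1", "1/0")] <- 1L
  dos[core == "1/1"] <- 2L
  depth <- rep(NA_real_, sum(keep))
  if (grepl("DP", v@gt[1, "FORMAT"], fixed = TRUE)) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    depth <- rowMeans(dp[keep, , drop = FALSE], na.rm = TRUE)
    depth[is.nan(depth)] <- NA_real_
  }
  g <- t(dos)
  rownames(g) <- colnames(gt)
  VariantMatrix(g, chrom = fix[keep, "CHROM"],
                pos = as.integer(fix[keep, "POS"]),
                ref = ref[keep], alt = alt[keep], depth = depth)
}

#' Write a VariantMatrix to a minimal VCF v4.2 file
#'
#' Emits GT (and DP in INFO as the site mean when available). The written file
#' round-trips through \code{readVcfMatrix} to the identical genotype matrix.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param path output path (plain text)
#' @export
writeVcfMatrix <- function(vm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##INFO=<ID=MDP,Number=1,Type=Float,Description=\"Mean sample depth\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(vm)), collapse = "\t"), con)
  if (nSites(vm) == 0) return(invisible(path))
  g <- genotypes(vm)
  gt_str <- matrix("./.", nrow = nrow(g), ncol = ncol(g))
  gt_str[!is.na(g) & g == 0L] <- "0/0"
  gt_str[!is.na(g) & g == 1L] <- "0/1"
  gt_str[!is.na(g) & g == 2L] <- "1/1"
  info <- ifelse(is.na(siteDepth(vm)), ".",
                 sprintf("MDP=%.6g", siteDepth(vm)))
  lines <- paste(siteChrom(vm), sitePos(vm), ".", siteRef(vm), siteAlt(vm),
                 ".", "PASS", info, "GT",
                 apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a tab-separated population map (sample<TAB>population)
#' @param path two-column headerless TSV
#' @return a \linkS4class{PopulationMap}
#' @export
readPopulationMap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  a <- df$population
  names(a) <- df$sample
  PopulationMap(a)
}

#' @rdname readPopulationMap
#' @param pm a PopulationMap
#' @export
writePopulationMap <- function(pm, path) {
  utils::write.table(data.frame(names(pm@assignments), unname(pm@assignments)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
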