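#' GeneAnnotation: gene models for SNP effect classification
#'
#' @slot genes GRanges of gene spans with mcols gene_id.
#' @slot exons GRanges of exons with mcols transcript_id, gene_id.
#' @slot cds GRanges of CDS segments with mcols transcript_id, gene_id, phase.
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
  representation(genes = "GRanges", exons = "GRanges", cds = "GRanges"))

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA / exon / CDS features with ID and Parent attributes.
#' @param path GFF3 file
#' @return a \linkS4class{GeneAnnotation}
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path)
  ty <- as.character(gr$type)
  genes <- gr[ty == "gene"]
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = genes$ID)
  tx <- gr[ty %in% c("mRNA", "transcript")]
  tx2gene <- structure(as.character(unlist(tx$Parent)), names = tx$ID)
  exons <- gr[ty == "exon"]
  cds <- gr[ty == "CDS"]
  tid_ex <- as.character(unlist(exons$Parent))
  tid_cds <- as.character(unlist(cds$Parent))
  ph <- if (!is.null(cds$phase)) as.integer(cds$phase) else rep(0L, length(cds))
  ph[is.na(ph)] <- 0L
  S4Vectors::mcols(exons) <- S4Vectors::DataFrame(
    transcript_id = tid_ex, gene_id = unname(tx2gene[tid_ex]))
  S4Vectors::mcols(cds) <- S4Vectors::DataFrame(
    transcript_id = tid_cds, gene_id = unname(tx2gene[tid_cds]), phase = ph)
  new("GeneAnnotation", genes = genes, exons = exons, cds = cds)
}

#' Read a genome FASTA into a named DNAStringSet
#' @param path FASTA file
#' @export
readGenomeFasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

EFFECT_CLASSES <- c("intergenic", "upstream", "downstream", "intronic",
                    "synonymous", "splice_site", "nonsynonymous",
                    "stop_lost", "stop_gain")
# severity used by the most-severe rule:
# stop_gain > stop_lost > nonsynonymous > splice_site > synonymous >
# intronic > upstream/downstream > intergenic
.EFFECT_SEVERITY <- c(intergenic = 0, upstream = 1, downstream = 1,
                      intronic = 2, synonymous = 3, splice_site = 4,
                      nonsynonymous = 5, stop_lost = 6, stop_gain = 7)

#' Classify SNP effects against gene models and a reference genome
#'
#' Each site receives exactly one class; where several transcripts overlap a
#' site the most severe class wins (stop_gain > stop_lost > nonsynonymous >
#' splice_site > synonymous > intronic > upstream/downstream > intergenic).
#' CDS sites are translated through the standard genetic code with strand
#' handling; transcripts whose phase-adjusted CDS length is not a multiple of
#' three are skipped with a warning. Untranslated gene-body sites (introns and
#' non-coding exon parts) fall back to the intronic class. Reference-allele
#' mismatches against the genome are reported via message and classified from
#' the genome base context.
#'
#' @param vm a \linkS4class{VariantMatrix}
#' @param genome named DNAStringSet (one entry per chromosome).
#' @param ann a \linkS4class{GeneAnnotation}
#' @param upstream_bp,downstream_bp flank extent around gene bodies (default
#'   5 kb each side).
#' @param splice_bp intronic bases at each exon boundary called splice_site
#'   (default 2).
#' @return data.frame with chrom, pos, effect (factor over the class
#'   enumeration).
#' @export
classifySnpEffects <- function(vm, genome, ann, upstream_bp = 5000,
                               downstream_bp = 5000, splice_bp = 2) {
  ns <- nSites(vm)
  snps <- GenomicRanges::GRanges(siteChrom(vm),
                                 IRanges::IRanges(sitePos(vm), width = 1))
  sev <- rep(0, ns)
  cls <- rep("intergenic", ns)
  assign_cls <- function(idx, what) {
    s <- .EFFECT_SEVERITY[[what]]
    upd <- idx[sev[idx] < s]
    cls[upd] <<- what
    sev[upd] <<- s
  }
  # reference mismatch check
  gbase <- vapply(seq_len(ns), function(i) {
    as.character(Biostrings::subseq(genome[[siteChrom(vm)[i]]],
                                    sitePos(vm)[i], sitePos(vm)[i]))
  }, character(1))
  nmis <- sum(gbase != siteRef(vm))
  if (nmis > 0)
    message(nmis, " site(s) whose REF does not match the genome base")

  genes <- ann@genes
  if (length(genes)) {
    up <- GenomicRanges::trim(GenomicRanges::flank(genes, upstream_bp, start = TRUE))
    dn <- GenomicRanges::trim(GenomicRanges::flank(genes, downstream_bp, start = FALSE))
    assign_cls(S4Vectors::queryHits(GenomicRanges::findOverlaps(snps, up)), "upstream")
    assign_cls(S4Vectors::queryHits(GenomicRanges::findOverlaps(snps, dn)), "downstream")
    assign_cls(S4Vectors::queryHits(GenomicRanges::findOverlaps(snps, genes)), "intronic")
  }
  # splice sites: first/last splice_bp bases of each intron, per transcript
  if (length(ann@exons)) {
    ex_by_tx <- S4Vectors::split(ann@exons, ann@exons$transcript_id)
    for (tx in names(ex_by_tx)) {
      ex <- GenomicRanges::reduce(ex_by_tx[[tx]])
      if (length(ex) < 2) next
      introns <- GenomicRanges::setdiff(range(ex), ex, ignore.strand = TRUE)
      if (!length(introns)) next
      donors <- GenomicRanges::resize(introns, splice_bp, fix = "start",
                                      ignore.strand = TRUE)
      accept <- GenomicRanges::resize(introns, splice_bp, fix = "end",
                                      ignore.strand = TRUE)
      ss <- c(donors, accept)
      assign_cls(S4Vectors::queryHits(GenomicRanges::findOverlaps(snps, ss,
                                                                  ignore.strand = TRUE)),
                 "splice_site")
    }
  }
  # coding classification per transcript
  if (length(ann@cds)) {
    cds_by_tx <- S4Vectors::split(ann@cds, ann@cds$transcript_id)
    code <- Biostrings::GENETIC_CODE
    for (tx in names(cds_by_tx)) {
      cd <- cds_by_tx[[tx]]
      minus <- as.character(GenomicRanges::strand(cd)[1]) == "-"
      cd <- cd[order(GenomicRanges::start(cd))]
      segs <- if (minus) rev(seq_along(cd)) else seq_along(cd)
      phase0 <- cd$phase[segs[1]]
      total_len <- sum(GenomicRanges::width(cd)) - phase0
      if (total_len %% 3 != 0) {
        warning("CDS length of transcript ", tx,
                " is not a multiple of 3; transcript skipped")
        next
      }
      # spliced CDS sequence in translation order
      chrom <- as.character(GenomicRanges::seqnames(cd))[1]
      pieces <- lapply(seq_along(cd), function(k)
        Biostrings::subseq(genome[[chrom]], GenomicRanges::start(cd)[k],
                           GenomicRanges::end(cd)[k]))
      spliced <- do.call(Biostrings::xscat, pieces)   # genomic (+) order
      hits <- GenomicRanges::findOverlaps(snps, cd)
      if (!length(hits)) next
      starts <- GenomicRanges::start(cd)
      cum <- cumsum(c(0, GenomicRanges::width(cd)))
      for (h in seq_along(hits)) {
        i <- S4Vectors::queryHits(hits)[h]
        k <- S4Vectors::subjectHits(hits)[h]
        off_plus <- cum[k] + (sitePos(vm)[i] - starts[k]) + 1  # 1-based in spliced
        seq_plus <- spliced
        alt_plus <- Biostrings::replaceLetterAt(seq_plus, off_plus,
                                                siteAlt(vm)[i])
        if (minus) {
          refseq <- Biostrings::reverseComplement(seq_plus)
          altseq <- Biostrings::reverseComplement(alt_plus)
          off <- length(seq_plus) - off_plus + 1
        } else {
          refseq <- seq_plus; altseq <- alt_plus; off <- off_plus
        }
        off <- off - phase0
        if (off < 1) next   # inside the phase-trimmed stub
        ci <- (off - 1) %/% 3
        cstart <- phase0 + ci * 3 + 1
        if (cstart + 2 > length(refseq)) next
        ref_cod <- as.character(Biostrings::subseq(refseq, cstart, cstart + 2))
        alt_cod <- as.character(Biostrings::subseq(altseq, cstart, cstart + 2))
        ref_aa <- code[[ref_cod]]
        alt_aa <- code[[alt_cod]]
        what <- if (ref_aa == alt_aa) "synonymous"
          else if (alt_aa == "*") "stop_gain"
          else if (ref_aa == "*") "stop_lost"
          else "nonsynonymous"
        assign_cls(i, what)
      }
    }
  }
  data.frame(chrom = siteChrom(vm), pos = sitePos(vm),
             effect = factor(cls, levels = EFFECT_CLASSES))
}

#' Fraction of classified SNPs per effect class
#' @param effects output of \code{\link{classifySnpEffects}}
#' @return named numeric summing to one
#' @export
effectSummary <- function(effects) {
  tab <- table(effects$effect)
  as.numeric(tab) / sum(tab) -> fr
  names(fr) <- names(tab)
  fr
}
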