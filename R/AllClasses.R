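#' @import methods
NULL

MISSING_GT <- NA_integer_

#' VariantMatrix: biallelic SNP genotypes with site metadata
#'
#' The central container of the package: a samples x sites matrix of
#' alternate-allele dosages (0, 1, 2, or \code{NA} for a missing call)
#' together with per-site chromosome, 1-based position, reference and
#' alternate alleles and (optionally) mean sequencing depth.
#'
#' @slot genotypes integer matrix, samples in rows (rownames = sample ids),
#'   sites in columns; entries in \{0, 1, 2, NA\}.
#' @slot chrom character vector, one chromosome label per site.
#' @slot pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @slot ref,alt single-character alleles from \{A, C, G, T\}.
#' @slot depth numeric vector of per-site mean depths (NA when absent).
#' @exportClass VariantMatrix
setClass("VariantMatrix",
  representation(genotypes = "matrix", chrom = "character", pos = "integer",
                 ref = "character", alt = "character", depth = "numeric"))

setValidity("VariantMatrix", function(object) {
  g <- object@genotypes
  ns <- ncol(g)
  msg <- character()
  if (length(object@chrom) != ns || length(object@pos) != ns ||
      length(object@ref) != ns || length(object@alt) != ns ||
      length(object@depth) != ns)
    msg <- c(msg, "site metadata lengths must equal ncol(genotypes)")
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (ns) {
    ok_allele <- object@ref %in% c("A", "C", "G", "T") &
      object@alt %in% c("A", "C", "G", "T") & object@ref != object@alt
    if (!all(ok_allele))
      msg <- c(msg, "ref/alt must be distinct single bases from {A,C,G,T}")
    for (ch in unique(object@chrom)) {
      p <- object@pos[object@chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0)) {
        msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VariantMatrix
#'
#' @param genotypes samples x sites integer matrix of alt-allele dosages
#'   (NA = missing call); rownames are taken as sample ids.
#' @param chrom,pos,ref,alt per-site metadata.
#' @param depth optional per-site mean depth.
#' @return a \linkS4class{VariantMatrix}
#' @export
VariantMatrix <- function(genotypes, chrom, pos, ref, alt, depth = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- paste0("S", seq_len(nrow(genotypes)))
  if (is.null(depth)) depth <- rep(NA_real_, ncol(genotypes))
  new("VariantMatrix", genotypes = genotypes,
      chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      depth = as.numeric(depth))
}

#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("siteChrom", function(x) standardGeneric("siteChrom"))
#' @export
setGeneric("sitePos", function(x) standardGeneric("sitePos"))
#' @export
setGeneric("siteRef", function(x) standardGeneric("siteRef"))
#' @export
setGeneric("siteAlt", function(x) standardGeneric("siteAlt"))
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname VariantMatrix
setMethod("nSites", "VariantMatrix", function(x) ncol(x@genotypes))
#' @rdname VariantMatrix
setMethod("nSamples", "VariantMatrix", function(x) nrow(x@genotypes))
#' @rdname VariantMatrix
setMethod("sampleIds", "VariantMatrix", function(x) rownames(x@genotypes))
#' @rdname VariantMatrix
setMethod("siteChrom", "VariantMatrix", function(x) x@chrom)
#' @rdname VariantMatrix
setMethod("sitePos", "VariantMatrix", function(x) x@pos)
#' @rdname VariantMatrix
setMethod("siteRef", "VariantMatrix", function(x) x@ref)
#' @rdname VariantMatrix
setMethod("siteAlt", "VariantMatrix", function(x) x@alt)
#' @rdname VariantMatrix
setMethod("siteDepth", "VariantMatrix", function(x) x@depth)
#' @rdname VariantMatrix
setMethod("genotypes", "VariantMatrix", function(x) x@genotypes)

#' Subset a VariantMatrix by samples (i) and/or sites (j)
#' @param x a VariantMatrix
#' @param i sample index (integer, logical or sample ids)
#' @param j site index
#' @export
setMethod("[", "VariantMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  if (is.character(i)) i <- match(i, rownames(x@genotypes))
  g <- x@genotypes[i, j, drop = FALSE]
  new("VariantMatrix", genotypes = g, chrom = x@chrom[j], pos = x@pos[j],
      ref = x@ref[j], alt = x@alt[j], depth = x@depth[j])
})

setMethod("show", "VariantMatrix", function(object) {
  cat(sprintf("VariantMatrix: %d samples x %d biallelic SNPs on %d chromosome(s)\n",
              nSamples(object), nSites(object),
              length(unique(object@chrom))))
  miss <- mean(is.na(object@genotypes))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
})

#' PopulationMap: sample-to-population assignments
#'
#' @slot assignments named character: names are sample ids, values population
#'   labels.
#' @slot populations ordered unique population labels.
#' @exportClass PopulationMap
setClass("PopulationMap",
  representation(assignments = "character", populations = "character"))

setValidity("PopulationMap", function(object) {
  if (is.null(names(object@assignments)) || any(names(object@assignments) == ""))
    return("assignments must be named by sample id")
  if (!setequal(unique(unname(object@assignments)), object@populations))
    return("populations must be the unique values of assignments")
  TRUE
})

#' @param assignments named character vector (sample id -> population label)
#' @rdname PopulationMap-class
#' @export
PopulationMap <- function(assignments) {
  new("PopulationMap", assignments = assignments,
      populations = unique(unname(assignments)))
}

#' Sample ids belonging to one population
#' @export
setGeneric("popSamples", function(x, pop) standardGeneric("popSamples"))
setMethod("popSamples", "PopulationMap", function(x, pop) {
  s <- names(x@assignments)[x@assignments == pop]
  if (!length(s)) stop("population '", pop, "' is empty or unknown")
  s
})

setMethod("show", "PopulationMap", function(object) {
  tab <- table(object@assignments)
  cat("PopulationMap:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

#' FoldedSFS: joint minor-allele-count spectrum
#'
#' Counts over cells of joint derived/minor allele counts across one to three
#' populations, folded by the total minor allele and masked at fixed and
#' fold-redundant cells.
#'
#' @slot counts numeric array with dim = sample sizes + 1 per population.
#' @slot mask logical array, TRUE where the cell carries no mass (fixed cells
#'   and the redundant half of the fold).
#' @slot dims integer vector of per-population allele-copy sample sizes.
#' @exportClass FoldedSFS
setClass("FoldedSFS",
  representation(counts = "array", mask = "array", dims = "integer"))

setValidity("FoldedSFS", function(object) {
  if (!identical(dim(object@counts), dim(object@mask)))
    return("counts and mask must share dimensions")
  if (!identical(as.integer(dim(object@counts)), object@dims + 1L))
    return("dim(counts) must equal dims + 1")
  if (any(object@counts[object@mask] != 0))
    return("masked cells must carry zero mass")
  TRUE
})

#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
setMethod("nSnps", "FoldedSFS", function(x) sum(x@counts))

#' @export
setGeneric("sfsCounts", function(x) standardGeneric("sfsCounts"))
setMethod("sfsCounts", "FoldedSFS", function(x) x@counts)

#' @export
setGeneric("sfsMask", function(x) standardGeneric("sfsMask"))
setMethod("sfsMask", "FoldedSFS", function(x) x@mask)

setMethod("show", "FoldedSFS", function(object) {
  cat(sprintf("FoldedSFS over %d population(s), sample sizes (%s); %g SNPs\n",
              length(object@dims), paste(object@dims, collapse = ", "),
              sum(object@counts)))
})

#' DemographicModel: parameterized multi-population history
#'
#' A named scenario from one of five three-population families
#' (divergence with gene flow, ancient migration, secondary contact,
#' simultaneous split, hybrid origin). The \code{builder} maps a named
#' parameter vector to the epoch list consumed by the coalescent engine;
#' sizes are relative to the ancestral reference, times in units of
#' 2 Nref generations, migration in units of 2 Nref m.
#'
#' @slot id model identifier, e.g. "m09_sc_adjacent_sym".
#' @slot family scenario family name.
#' @slot params named numeric defaults (also the multi-start centre).
#' @slot lower,upper named box bounds.
#' @slot builder function(params) -> epoch list.
#' @slot npop number of contemporary populations.
#' @exportClass DemographicModel
setClass("DemographicModel",
  representation(id = "character", family = "character",
                 params = "numeric", lower = "numeric", upper = "numeric",
                 builder = "function", npop = "integer"))

setValidity("DemographicModel", function(object) {
  pn <- names(object@params)
  if (is.null(pn)) return("params must be named")
  if (!identical(names(object@lower), pn) || !identical(names(object@upper), pn))
    return("bounds must be named like params")
  if (any(object@lower >= object@upper)) return("lower must be < upper")
  TRUE
})

setMethod("show", "DemographicModel", function(object) {
  cat(sprintf("DemographicModel '%s' [%s], %d parameter(s): %s\n",
              object@id, object@family, length(object@params),
              paste(names(object@params), collapse = ", ")))
})

#' FitResult: one fitted demographic model
#'
#' @slot model model id.
#' @slot family scenario family.
#' @slot params fitted named parameters (genetic units).
#' @slot theta profiled ancestral effective mutation rate.
#' @slot loglik Poisson composite log-likelihood at the optimum.
#' @slot k free-parameter count entering AIC (simplex parameters + 1 for theta).
#' @slot aic 2k - 2 loglik.
#' @slot converted named list of physical-unit conversions (may be empty).
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "character", family = "character",
                 params = "numeric", theta = "numeric", loglik = "numeric",
                 k = "integer", aic = "numeric", converted = "list"))

setValidity("FitResult", function(object) {
  if (abs(object@aic - (2 * object@k - 2 * object@loglik)) > 1e-8 * max(1, abs(object@aic)))
    return("aic must equal 2k - 2 loglik")
  TRUE
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult %s [%s]: loglik = %.3f, k = %d, AIC = %.3f, theta = %.4g\n",
              object@model, object@family, object@loglik, object@k,
              object@aic, object@theta))
  print(round(object@params, 4))
})

#' SuitabilityRaster: normalized habitat-suitability grid
#'
#' A non-negative grid over a shared extent, normalized so that values on the
#' valid-cell mask sum to one.
#'
#' @slot grid numeric matrix of suitabilities.
#' @slot mask logical matrix of valid cells.
#' @slot xcoords,ycoords cell-centre coordinates of the grid axes.
#' @exportClass SuitabilityRaster
setClass("SuitabilityRaster",
  representation(grid = "matrix", mask = "matrix",
                 xcoords = "numeric", ycoords = "numeric"))

setValidity("SuitabilityRaster", function(object) {
  if (!identical(dim(object@grid), dim(object@mask)))
    return("grid and mask must share dimensions")
  if (any(object@grid[object@mask] < 0)) return("suitabilities must be >= 0")
  s <- sum(object@grid[object@mask])
  if (s > 0 && abs(s - 1) > 1e-8) return("grid must be normalized over the mask")
  TRUE
})

#' @param grid non-negative matrix; normalized over \code{mask} on construction.
#' @rdname SuitabilityRaster-class
#' @export
SuitabilityRaster <- function(grid, mask = NULL, xcoords = NULL, ycoords = NULL) {
  grid <- as.matrix(grid)
  if (is.null(mask)) mask <- !is.na(grid)
  grid[!mask] <- 0
  s <- sum(grid[mask])
  if (s > 0) grid[mask] <- grid[mask] / s
  if (is.null(xcoords)) xcoords <- seq_len(nrow(grid))
  if (is.null(ycoords)) ycoords <- seq_len(ncol(grid))
  new("SuitabilityRaster", grid = grid, mask = mask,
      xcoords = as.numeric(xcoords), ycoords = as.numeric(ycoords))
}

setMethod("show", "SuitabilityRaster", function(object) {
  cat(sprintf("SuitabilityRaster %d x %d (%d valid cells)\n",
              nrow(object@grid), ncol(object@grid), sum(object@mask)))
})
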