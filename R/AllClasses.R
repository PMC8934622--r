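#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols mcols<-
#' @importFrom IRanges IRanges
NULL

REGION_TYPES <- c("bivalent", "enhancer", "insulator", "promoter", "silencer")
GENELINK_EVIDENCE <- c("direct", "closest_gene", "closest_tss", "eqtl")
PHENO_PROVENANCE <- c("gwas", "hpo", "curated")

#' GenomeModel: chromosome sizes plus excluded intervals
#'
#' Minimal genome description used throughout the package: named chromosome
#' lengths and a set of excluded intervals (e.g. mock centromeres/telomeres)
#' that control-region sampling must avoid and over which coverage fractions
#' are computed.
#'
#' @slot chromLengths named numeric vector, chromosome -> length in bp.
#' @slot excluded GRanges of intervals unavailable for control placement.
#' @export
setClass("GenomeModel",
  representation(chromLengths = "numeric", excluded = "GRanges"))

setValidity("GenomeModel", function(object) {
  msg <- character()
  cl <- object@chromLengths
  if (length(cl) == 0) msg <- c(msg, "at least one chromosome required")
  if (is.null(names(cl)) || anyDuplicated(names(cl)) || any(!nzchar(names(cl))))
    msg <- c(msg, "chromosome names must be unique and non-empty")
  if (any(!is.finite(cl)) || any(cl <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  ex <- object@excluded
  if (length(ex) > 0) {
    chr <- as.character(GenomicRanges::seqnames(ex))
    if (!all(chr %in% names(cl))) {
      msg <- c(msg, "excluded intervals on unknown chromosomes")
    } else if (any(GenomicRanges::start(ex) < 1) ||
               any(GenomicRanges::end(ex) > cl[chr])) {
      msg <- c(msg, "excluded intervals must lie within their chromosome")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeModel
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param excluded GRanges (1-based closed) of excluded intervals, or NULL.
#' @return A \linkS4class{GenomeModel}.
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e6, chr2 = 5e5))
#' @export
GenomeModel <- function(chromLengths, excluded = NULL) {
  if (is.null(excluded)) excluded <- GenomicRanges::GRanges()
  new("GenomeModel", chromLengths = chromLengths, excluded = excluded)
}

#' @describeIn GenomeModel-class total genome length in bp
#' @param x,object a GenomeModel
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname GenomeModel-class
#' @export
setMethod("genomeLength", "GenomeModel", function(x) sum(x@chromLengths))

#' @rdname GenomeModel-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeModel-class
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

#' @rdname GenomeModel-class
#' @export
setGeneric("excludedRegions", function(x) standardGeneric("excludedRegions"))

#' @rdname GenomeModel-class
#' @export
setMethod("excludedRegions", "GenomeModel", function(x) x@excluded)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", length(object@chromLengths), "chromosome(s),",
      format(sum(object@chromLengths), big.mark = ","), "bp,",
      length(object@excluded), "excluded interval(s)\n")
})

#' RegulatoryDB: a database of regulatory regions with gene and phenotype links
#'
#' Central container tying together normalized regulatory regions (a GRanges
#' with type, provenance, constraint and closest gene/TSS metadata), a
#' region-to-gene link table with evidence classes, a region-to-phenotype
#' link table, the gene models used for closest-gene assignment, and the
#' genome the regions live on.
#'
#' Region coordinates are held as 1-based closed GRanges; all text interfaces
#' (extended BED, the SQLite store) use 0-based half-open coordinates.
#'
#' @slot regions GRanges with mcols: region_id, region_type, sources,
#'   methods, tissues, closest_gene, closest_gene_dist, closest_tss_gene,
#'   closest_tss_dist, constraint.
#' @slot geneLinks DataFrame with region_id, gene_id, evidence, tissues.
#' @slot phenoLinks DataFrame with region_id, phenotype, provenance.
#' @slot genes DataFrame of gene models (gene_id, chrom, start, end, strand,
#'   tss, biotype), 1-based closed.
#' @slot genome GenomeModel.
#' @export
setClass("RegulatoryDB",
  representation(regions = "GRanges", geneLinks = "DataFrame",
                 phenoLinks = "DataFrame", genes = "DataFrame",
                 genome = "GenomeModel"))

setValidity("RegulatoryDB", function(object) {
  msg <- character()
  mc <- GenomicRanges::mcols(object@regions)
  need <- c("region_id", "region_type", "sources", "methods", "tissues",
            "closest_gene", "closest_gene_dist", "closest_tss_gene",
            "closest_tss_dist", "constraint")
  miss <- setdiff(need, colnames(mc))
  if (length(miss)) {
    msg <- c(msg, paste("regions missing mcols:", paste(miss, collapse = ", ")))
  } else {
    if (anyDuplicated(mc$region_id))
      msg <- c(msg, "region_id must be unique")
    if (!all(mc$region_type %in% REGION_TYPES))
      msg <- c(msg, paste("region_type must be one of:",
                          paste(REGION_TYPES, collapse = ", ")))
    cv <- mc$constraint
    if (any(!is.na(cv) & (cv < 0 | cv > 1)))
      msg <- c(msg, "constraint must lie in [0,1] where defined")
    gl <- object@geneLinks
    if (nrow(gl)) {
      if (!all(gl$evidence %in% GENELINK_EVIDENCE))
        msg <- c(msg, "gene link evidence outside vocabulary")
      dangling <- setdiff(gl$region_id, mc$region_id)
      if (length(dangling))
        msg <- c(msg, paste("gene links reference unknown regions:",
                            paste(utils::head(dangling, 5), collapse = ", ")))
    }
    pl <- object@phenoLinks
    if (nrow(pl)) {
      if (!all(pl$provenance %in% PHENO_PROVENANCE))
        msg <- c(msg, "phenotype link provenance outside vocabulary")
      dangling <- setdiff(pl$region_id, mc$region_id)
      if (length(dangling))
        msg <- c(msg, paste("phenotype links reference unknown regions:",
                            paste(utils::head(dangling, 5), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegulatoryDB", function(object) {
  tab <- table(GenomicRanges::mcols(object@regions)$region_type)
  cat("RegulatoryDB:", length(object@regions), "regions (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  cat("  gene links:", nrow(object@geneLinks),
      "| phenotype links:", nrow(object@phenoLinks),
      "| genes:", nrow(object@genes), "\n")
  nc <- sum(!is.na(GenomicRanges::mcols(object@regions)$constraint))
  cat("  constraint set for", nc, "regions\n")
})

#' @rdname RegulatoryDB-class
#' @param x a RegulatoryDB
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname RegulatoryDB-class
#' @export
setMethod("regions", "RegulatoryDB", function(x) x@regions)

#' @rdname RegulatoryDB-class
#' @export
setGeneric("geneLinks", function(x) standardGeneric("geneLinks"))

#' @rdname RegulatoryDB-class
#' @export
setMethod("geneLinks", "RegulatoryDB", function(x) x@geneLinks)

#' @rdname RegulatoryDB-class
#' @export
setGeneric("phenotypeLinks", function(x) standardGeneric("phenotypeLinks"))

#' @rdname RegulatoryDB-class
#' @export
setMethod("phenotypeLinks", "RegulatoryDB", function(x) x@phenoLinks)

#' @rdname RegulatoryDB-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))

#' @rdname RegulatoryDB-class
#' @export
setMethod("geneModels", "RegulatoryDB", function(x) x@genes)

#' @rdname RegulatoryDB-class
#' @export
setGeneric("genomeModel", function(x) standardGeneric("genomeModel"))

#' @rdname RegulatoryDB-class
#' @export
setMethod("genomeModel", "RegulatoryDB", function(x) x@genome)

#' ConstraintFit: expectation model and per-region constraint values
#'
#' Result of regressing observed variant counts on region covariates
#' (length, GC fraction, segmental-duplication / low-complexity / exonic
#' overlap fractions) by ordinary least squares, together with the derived
#' constraint value: the mid-rank empirical CDF of the residual
#' expected - observed, so regions with fewer variants than expected get
#' values near 1.
#'
#' @slot coefficients named numeric: intercept + 5 covariate coefficients.
#' @slot covariates DataFrame of the fitted covariates (one row per region).
#' @slot expected numeric, model-expected variant count per region.
#' @slot observed numeric, observed variant count per region.
#' @slot residuals numeric, expected - observed.
#' @slot constraint numeric in [0,1].
#' @slot flagged logical, TRUE above the flag percentile.
#' @slot percentile numeric scalar, the flagging percentile (default 99).
#' @export
setClass("ConstraintFit",
  representation(coefficients = "numeric", covariates = "DataFrame",
                 expected = "numeric", observed = "numeric",
                 residuals = "numeric", constraint = "numeric",
                 flagged = "logical", percentile = "numeric"))

setValidity("ConstraintFit", function(object) {
  msg <- character()
  n <- length(object@observed)
  if (length(object@expected) != n || length(object@residuals) != n ||
      length(object@constraint) != n || length(object@flagged) != n)
    msg <- c(msg, "per-region slots must have equal length")
  if (any(object@constraint < 0 | object@constraint > 1))
    msg <- c(msg, "constraint values must lie in [0,1]")
  if (object@percentile < 0 || object@percentile > 100)
    msg <- c(msg, "percentile must lie in [0,100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConstraintFit", function(object) {
  cat("ConstraintFit:", length(object@observed), "regions;",
      sum(object@flagged), "flagged above the", object@percentile,
      "th percentile\n")
  cat("  coefficients:\n")
  print(round(object@coefficients, 6))
})

#' @rdname ConstraintFit-class
#' @param x a ConstraintFit
#' @export
setGeneric("constraintValues", function(x) standardGeneric("constraintValues"))

#' @rdname ConstraintFit-class
#' @export
setMethod("constraintValues", "ConstraintFit", function(x) x@constraint)

#' @rdname ConstraintFit-class
#' @export
setGeneric("constrainedFlags", function(x) standardGeneric("constrainedFlags"))

#' @rdname ConstraintFit-class
#' @export
setMethod("constrainedFlags", "ConstraintFit", function(x) x@flagged)

#' @rdname ConstraintFit-class
#' @export
setGeneric("expectedCounts", function(x) standardGeneric("expectedCounts"))

#' @rdname ConstraintFit-class
#' @export
setMethod("expectedCounts", "ConstraintFit", function(x) x@expected)

#' @rdname ConstraintFit-class
#' @export
setMethod("coef", "ConstraintFit", function(object, ...) object@coefficients)

#' @rdname ConstraintFit-class
#' @export
setMethod("residuals", "ConstraintFit", function(object, ...) object@residuals)
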