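#' @importFrom stats lm coef quantile setNames
NULL

#' Count observed variant sites per region
#'
#' One count per VCF site falling inside the region span; multi-allelic
#' sites count once. Sites on chromosomes absent from the genome are
#' ignored with a warning.
#'
#' @param gr region GRanges.
#' @param sites either a GRanges/data.frame of site positions
#'   (\code{chrom}, \code{pos}, 1-based) or a path to a VCF file.
#' @param genome optional \linkS4class{GenomeModel} used to screen unknown
#'   chromosomes.
#' @return integer vector of counts, one per region.
#' @export
countObserved <- function(gr, sites, genome = NULL) {
  if (is.character(sites) && length(sites) == 1) {
    v <- VariantAnnotation::readVcf(sites)
    rr <- SummarizedExperiment::rowRanges(v)
    sites <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(rr)),
                                    IRanges::IRanges(GenomicRanges::start(rr),
                                                     width = 1))
  } else if (is.data.frame(sites)) {
    sites <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, width = 1))
  }
  # a site is its POS only, regardless of REF length
  sites <- GenomicRanges::resize(sites, width = 1, fix = "start",
                                 ignore.strand = TRUE)
  sites <- unique(sites)
  if (!is.null(genome)) {
    known <- as.character(GenomicRanges::seqnames(sites)) %in%
      names(chromLengths(genome))
    if (any(!known))
      warning(sum(!known), " site(s) on unknown chromosomes ignored")
    sites <- sites[known]
  }
  GenomicRanges::countOverlaps(gr, sites, ignore.strand = TRUE)
}

mergedOverlapFraction <- function(gr, features) {
  if (is.null(features) || length(features) == 0)
    return(numeric(length(gr)))
  features <- GenomicRanges::reduce(features, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(gr, features, ignore.strand = TRUE)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    gr[S4Vectors::queryHits(hits)], features[S4Vectors::subjectHits(hits)]))
  tot <- numeric(length(gr))
  agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  tot / GenomicRanges::width(gr)
}

#' Compute per-region covariates for the expectation model
#'
#' Length, GC fraction and overlap fractions with segmental duplications,
#' low-complexity regions and exonic regions. Overlap fractions are
#' computed on merged feature intervals (overlapped bases / region length).
#'
#' @param gr region GRanges.
#' @param sequence named character vector or \code{DNAStringSet} of
#'   chromosome sequences; alternatively supply a precomputed
#'   \code{gc} numeric vector per region.
#' @param segdup,lcr,exons GRanges of the respective feature sets (NULL =
#'   no overlap).
#' @param observed optional observed variant counts to carry along.
#' @param gc precomputed GC fractions (used when \code{sequence} is NULL).
#' @return DataFrame with region_id, length, gc, segdup, lcr, exonic and
#'   (when given) observed columns.
#' @export
computeCovariates <- function(gr, sequence = NULL, segdup = NULL, lcr = NULL,
                              exons = NULL, observed = NULL, gc = NULL) {
  n <- length(gr)
  if (!is.null(sequence)) {
    if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
    seqs <- Biostrings::DNAStringSet(lapply(seq_len(n), function(i) {
      ch <- as.character(GenomicRanges::seqnames(gr[i]))
      Biostrings::subseq(sequence[[ch]], GenomicRanges::start(gr[i]),
                         GenomicRanges::end(gr[i]))
    }))
    gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC",
                                                 as.prob = TRUE))
  } else if (is.null(gc)) {
    gc <- rep(NA_real_, n)
  }
  out <- S4Vectors::DataFrame(
    region_id = GenomicRanges::mcols(gr)$region_id,
    length = GenomicRanges::width(gr),
    gc = gc,
    segdup = mergedOverlapFraction(gr, segdup),
    lcr = mergedOverlapFraction(gr, lcr),
    exonic = mergedOverlapFraction(gr, exons))
  if (!is.null(observed)) out$observed <- as.integer(observed)
  out
}

#' Fit the variant-count expectation model
#'
#' Ordinary least squares of observed variant counts on region length, GC
#' fraction and segmental-duplication / low-complexity / exonic overlap
#' fractions (plus intercept). The per-region residual is
#' expected - observed, so variant-depleted regions have positive
#' residuals; the constraint value is the mid-rank empirical CDF of that
#' residual, and regions strictly above the flag percentile of the
#' constraint distribution are flagged as constrained.
#'
#' @param covariates DataFrame from \code{\link{computeCovariates}} with an
#'   \code{observed} column (or pass \code{observed} separately).
#' @param observed observed counts (overrides the column).
#' @param percentile flagging percentile, default 99.
#' @param studentized rank studentized rather than raw residuals
#'   (off by default).
#' @return A \linkS4class{ConstraintFit}.
#' @export
fitExpectation <- function(covariates, observed = NULL, percentile = 99,
                           studentized = FALSE) {
  covariates <- S4Vectors::DataFrame(covariates)
  if (is.null(observed)) observed <- covariates$observed
  if (is.null(observed)) stop("observed counts required")
  vars <- c("length", "gc", "segdup", "lcr", "exonic")
  df <- as.data.frame(covariates[, vars])
  if (nrow(df) < 10 * (length(vars) + 1))
    stop("need at least ", 10 * (length(vars) + 1),
         " regions to fit the expectation model")
  if (!all(vapply(df, function(x) all(is.finite(x)), logical(1))))
    stop("covariates must be finite")
  df$observed <- as.numeric(observed)
  # constant columns carry no information; fit without them (coefficient 0)
  active <- vars[vapply(df[vars], function(x) stats::var(x) > 0, logical(1))]
  form <- stats::reformulate(if (length(active)) active else "1",
                             response = "observed")
  fit <- stats::lm(form, data = df)
  cf0 <- stats::coef(fit)
  if (anyNA(cf0)) {
    dropped <- names(cf0)[is.na(cf0)]
    # name the columns each dropped term is collinear with
    partners <- vapply(dropped, function(d) {
      others <- setdiff(active, d)
      cors <- vapply(others, function(o)
        suppressWarnings(abs(stats::cor(df[[d]], df[[o]]))), numeric(1))
      paste(others[which(cors > 1 - 1e-8)], collapse = ",")
    }, character(1))
    stop("rank-deficient design; collinear columns: ",
         paste(sprintf("%s~%s", dropped, partners), collapse = "; "))
  }
  cf <- stats::setNames(numeric(length(vars) + 1), c("(Intercept)", vars))
  cf[names(cf0)] <- cf0
  expected <- as.numeric(stats::fitted(fit))
  resid <- expected - df$observed
  ranked <- if (studentized) {
    as.numeric(-stats::rstudent(fit))   # sign matches expected - observed
  } else resid
  constraint <- midrankECDF(ranked)
  flags <- flagConstrained(constraint, percentile)
  new("ConstraintFit",
      coefficients = cf, covariates = covariates,
      expected = expected, observed = df$observed, residuals = resid,
      constraint = constraint, flagged = flags,
      percentile = as.numeric(percentile))
}

#' Mid-rank empirical CDF
#'
#' \code{(number smaller + 0.5 * number equal) / n}; strictly monotone in
#' its argument with ties mapped to identical values.
#'
#' @param x numeric vector.
#' @return numeric vector in (0, 1).
#' @export
midrankECDF <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Flag constrained regions above a percentile
#'
#' A region is flagged when its constraint value is strictly greater than
#' the empirical percentile (inverse-ECDF quantile) of the constraint
#' distribution. At the default 99th percentile and distinct residuals the
#' flagged fraction is exactly 1% up to integer rounding.
#'
#' @param constraint numeric constraint values in [0, 1].
#' @param percentile percentile in [0, 100], default 99.
#' @return logical vector.
#' @export
flagConstrained <- function(constraint, percentile = 99) {
  thr <- stats::quantile(constraint, percentile / 100, type = 1, names = FALSE)
  constraint > thr
}

#' Write constraint values back into a RegulatoryDB
#'
#' @param db a \linkS4class{RegulatoryDB}.
#' @param fit a \linkS4class{ConstraintFit} whose covariate region_ids match
#'   database regions.
#' @return the updated database.
#' @export
setConstraint <- function(db, fit) {
  mc <- GenomicRanges::mcols(db@regions)
  m <- match(mc$region_id, fit@covariates$region_id)
  mc$constraint <- ifelse(is.na(m), mc$constraint, fit@constraint[m])
  GenomicRanges::mcols(db@regions) <- mc
  methods::validObject(db)
  db
}
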