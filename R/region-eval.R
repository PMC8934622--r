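#' @importFrom stats fisher.test median pnorm cor fitted model.matrix rstudent
#' @importFrom utils combn head read.table write.table
NULL

## run code under a temporary RNG state so callers' streams are untouched
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

usableIntervals <- function(genome) {
  cl <- chromLengths(genome)
  full <- GenomicRanges::GRanges(names(cl), IRanges::IRanges(1, unname(cl)))
  GenomicRanges::setdiff(full, GenomicRanges::reduce(excludedRegions(genome)),
                         ignore.strand = TRUE)
}

#' Sample matched control regions
#'
#' For each chromosome, draws as many control regions as the source set has
#' there, reusing the source regions' exact size multiset (sizes are
#' re-placed, not re-drawn), uniformly over the chromosome with excluded
#' intervals (mock centromeres/telomeres) avoided entirely. Identical seeds
#' give identical output.
#'
#' @param genome \linkS4class{GenomeModel} with excluded intervals.
#' @param gr source region GRanges.
#' @param seed integer seed.
#' @return GRanges of control regions (with a \code{size} metadata column).
#' @export
sampleControls <- function(genome, gr, seed = 1) {
  if (!length(gr)) return(GenomicRanges::GRanges())
  usable <- usableIntervals(genome)
  uchrom <- as.character(GenomicRanges::seqnames(usable))
  rchrom <- as.character(GenomicRanges::seqnames(gr))
  withSeed(seed, {
    out <- lapply(unique(rchrom), function(ch) {
      sizes <- GenomicRanges::width(gr[rchrom == ch])
      iv <- usable[uchrom == ch]
      if (!length(iv))
        stop("no usable space on chromosome ", ch)
      ivs <- GenomicRanges::start(iv); ivw <- GenomicRanges::width(iv)
      starts <- integer(length(sizes))
      for (k in seq_along(sizes)) {
        L <- sizes[k]
        nstart <- pmax(ivw - L + 1L, 0L)
        if (sum(nstart) == 0)
          stop("cannot place a ", L, " bp control on chromosome ", ch)
        pick <- sample.int(length(iv), 1, prob = nstart / sum(nstart))
        starts[k] <- ivs[pick] + sample.int(nstart[pick], 1) - 1L
      }
      data.frame(chrom = rep(ch, length(sizes)), start = starts,
                 size = sizes)
    })
    df <- do.call(rbind, out)
    GenomicRanges::sort(
      GenomicRanges::GRanges(df$chrom,
                             IRanges::IRanges(df$start, width = df$size),
                             size = df$size),
      ignore.strand = TRUE)
  })
}

#' Fisher-exact enrichment of a feature in regions versus controls
#'
#' Counts at region level (a region "hits" when it overlaps at least one
#' feature base), builds the 2x2 table regions-vs-controls by hit/no-hit,
#' and tests it with the exact hypergeometric two-sided test. The odds
#' ratio is the sample OR (a*d)/(b*c); the 0.5 Haldane correction is
#' applied (and flagged) only when a zero cell occurs.
#'
#' @param gr region GRanges.
#' @param controls control GRanges from \code{\link{sampleControls}}.
#' @param feature feature GRanges.
#' @param name feature label carried into the result.
#' @return one-row data.frame: feature, the four counts, odds_ratio,
#'   p_value, haldane flag, side.
#' @export
fisherEnrichment <- function(gr, controls, feature, name = "feature") {
  if (!length(controls)) stop("control set is empty")
  a <- sum(IRanges::overlapsAny(gr, feature, ignore.strand = TRUE))
  b <- length(gr) - a
  c_ <- sum(IRanges::overlapsAny(controls, feature, ignore.strand = TRUE))
  d <- length(controls) - c_
  haldane <- any(c(a, b, c_, d) == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2))$p.value
  data.frame(feature = name, hits = a, misses = b, control_hits = c_,
             control_misses = d, odds_ratio = or, p_value = p,
             haldane = haldane, side = "two.sided",
             stringsAsFactors = FALSE)
}

trackToGRanges <- function(track) {
  GenomicRanges::GRanges(track$chrom, IRanges::IRanges(track$pos, width = 1),
                         score = track$score)
}

#' Per-region conservation/score summaries over a partial track
#'
#' For each region, the fraction of covered bases whose track value is
#' strictly above each threshold, plus the median and maximum value. Bases
#' without a track value are excluded from denominators; regions with no
#' covered base get an undefined (NA) summary and are counted in
#' \code{metadata(.)$uncovered}.
#'
#' @param gr region GRanges.
#' @param track data.frame with chrom, pos (1-based), score; may cover only
#'   part of the genome.
#' @param thresholds numeric thresholds, default c(1, 1.5, 2).
#' @return DataFrame, one row per region: n_covered, frac_gt_<t> columns,
#'   median, max.
#' @export
conservationSummary <- function(gr, track, thresholds = c(1, 1.5, 2)) {
  tg <- trackToGRanges(track)
  hits <- GenomicRanges::findOverlaps(gr, tg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  vals <- split(tg$score[S4Vectors::subjectHits(hits)],
                factor(qh, levels = seq_along(gr)))
  n <- lengths(vals)
  rid <- GenomicRanges::mcols(gr)$region_id
  if (is.null(rid)) rid <- as.character(seq_along(gr))
  out <- S4Vectors::DataFrame(region_id = rid, n_covered = as.integer(n))
  for (t in thresholds)
    out[[sprintf("frac_gt_%g", t)]] <- vapply(seq_along(gr), function(i)
      if (n[i] == 0) NA_real_ else mean(vals[[i]] > t), numeric(1))
  out$median <- vapply(seq_along(gr), function(i)
    if (n[i] == 0) NA_real_ else stats::median(vals[[i]]), numeric(1))
  out$max <- vapply(seq_along(gr), function(i)
    if (n[i] == 0) NA_real_ else max(vals[[i]]), numeric(1))
  S4Vectors::metadata(out)$uncovered <- sum(n == 0)
  out
}

#' Mann-Whitney U test with mid-rank ties
#'
#' U is computed from the rank sum of the first sample with mid-ranks for
#' ties. The two-sided p-value uses exact enumeration over all rank
#' assignments when both samples have at most 8 observations, and the
#' normal approximation with tie and continuity correction otherwise. If
#' every value is identical across both samples, p = 1.
#'
#' @param a,b numeric samples (non-empty).
#' @param method "auto" (default), "exact" or "normal".
#' @return list with \code{U} (for sample \code{a}), \code{p} and
#'   \code{method} used.
#' @export
mannWhitneyU <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled, ties.method = "average")
  Ustat <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  U <- Ustat(seq_len(na))
  if (length(unique(pooled)) == 1)
    return(list(U = U, p = 1, method = "degenerate"))
  mu <- na * nb / 2
  if (method == "auto") method <- if (na <= 8 && nb <= 8) "exact" else "normal"
  if (method == "exact") {
    sets <- utils::combn(N, na)
    Us <- apply(sets, 2, Ustat)
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p, method = method)
}

#' Evaluate a region set against functional features and score tracks
#'
#' Convenience wrapper: samples matched controls, runs
#' \code{\link{fisherEnrichment}} for each supplied feature set, and
#' compares region-vs-control conservation fractions with
#' \code{\link{mannWhitneyU}} per threshold.
#'
#' @param db a \linkS4class{RegulatoryDB}.
#' @param features named list of feature GRanges.
#' @param tracks named list of score-track data.frames.
#' @param seed seed for control sampling.
#' @param thresholds thresholds for conservation fractions.
#' @return list with \code{controls}, \code{enrichment} (data.frame) and
#'   \code{conservation} (data.frame of U and p per track/threshold).
#' @export
evaluateRegions <- function(db, features = list(), tracks = list(),
                            seed = 1, thresholds = c(1, 1.5, 2)) {
  gr <- regions(db)
  controls <- sampleControls(genomeModel(db), gr, seed = seed)
  enr <- do.call(rbind, lapply(names(features), function(nm)
    fisherEnrichment(gr, controls, features[[nm]], name = nm)))
  cons <- NULL
  for (nm in names(tracks)) {
    sr <- conservationSummary(gr, tracks[[nm]], thresholds)
    sc <- conservationSummary(controls, tracks[[nm]], thresholds)
    for (t in thresholds) {
      col <- sprintf("frac_gt_%g", t)
      aa <- sr[[col]][!is.na(sr[[col]])]
      bb <- sc[[col]][!is.na(sc[[col]])]
      if (!length(aa) || !length(bb)) next
      mw <- mannWhitneyU(aa, bb)
      cons <- rbind(cons, data.frame(track = nm, threshold = t,
                                     U = mw$U, p_value = mw$p,
                                     stringsAsFactors = FALSE))
    }
  }
  list(controls = controls, enrichment = enr, conservation = cons)
}
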