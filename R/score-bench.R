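#' ROC area under the curve by pair counting
#'
#' AUC as the Mann-Whitney probability that a random positive outscores a
#' random negative, with ties counting one half:
#' (concordant + 0.5 * tied) / (n_pos * n_neg). Higher scores are taken as
#' more pathogenic; variants with a missing score are excluded.
#'
#' @param scores numeric score values.
#' @param labels logical (TRUE = positive) or character
#'   "positive"/"negative".
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  lab <- normalizeLabels(labels)
  keep <- !is.na(scores)
  scores <- scores[keep]; lab <- lab[keep]
  npos <- sum(lab); nneg <- sum(!lab)
  if (npos == 0 || nneg == 0)
    stop("need both positive and negative examples with scores")
  r <- rank(scores, ties.method = "average")
  (sum(r[lab]) - npos * (npos + 1) / 2) / (npos * nneg)
}

normalizeLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  l <- tolower(as.character(labels))
  if (!all(l %in% c("positive", "negative")))
    stop("labels must be positive/negative")
  l == "positive"
}

confusionAt <- function(scores, lab, t) {
  called <- scores >= t
  tp <- sum(called & lab); fp <- sum(called & !lab)
  fn <- sum(!called & lab); tn <- sum(!called & !lab)
  c(tpr = if (tp + fn) tp / (tp + fn) else 0,
    fdr = if (tp + fp) fp / (tp + fp) else 0,
    accuracy = (tp + tn) / length(scores))
}

#' Calibrate operating thresholds for an impact score
#'
#' Sweeps the finite set of observed score values as candidate cutoffs
#' (a variant is called positive when score >= threshold) and reports:
#' the largest threshold retaining TPR >= 0.9 (with its FDR), the smallest
#' threshold achieving FDR <= 0.5 (with its TPR; undefined and flagged
#' when no cutoff reaches it), and the maximum-accuracy threshold (ties
#' broken toward the higher cutoff), together with the AUC.
#'
#' @param scores numeric score values (missing excluded, counted).
#' @param labels positive/negative labels.
#' @return one-row data.frame of thresholds and attained metrics.
#' @export
calibrateThresholds <- function(scores, labels) {
  lab <- normalizeLabels(labels)
  n_missing <- sum(is.na(scores))
  keep <- !is.na(scores)
  scores <- scores[keep]; lab <- lab[keep]
  if (!sum(lab) || !sum(!lab))
    stop("need both positive and negative examples with scores")
  cand <- sort(unique(scores))
  met <- t(vapply(cand, confusionAt, numeric(3), scores = scores, lab = lab))

  ok_tpr <- which(met[, "tpr"] >= 0.9)
  thr_tpr90 <- if (length(ok_tpr)) cand[max(ok_tpr)] else NA_real_
  fdr_at_tpr90 <- if (length(ok_tpr)) met[max(ok_tpr), "fdr"] else NA_real_

  ok_fdr <- which(met[, "fdr"] <= 0.5)
  fdr50_defined <- length(ok_fdr) > 0
  thr_fdr50 <- if (fdr50_defined) cand[min(ok_fdr)] else NA_real_
  tpr_at_fdr50 <- if (fdr50_defined) met[min(ok_fdr), "tpr"] else NA_real_

  best <- max(met[, "accuracy"])
  thr_maxacc <- cand[max(which(met[, "accuracy"] >= best - 1e-12))]
  data.frame(
    auc = rocAuc(scores, lab),
    thr_tpr90 = thr_tpr90, fdr_at_tpr90 = fdr_at_tpr90,
    thr_fdr50 = thr_fdr50, tpr_at_fdr50 = tpr_at_fdr50,
    fdr50_defined = fdr50_defined,
    thr_maxacc = thr_maxacc, accuracy = best,
    n_pos = sum(lab), n_neg = sum(!lab), n_missing = n_missing)
}

#' Fraction of the genome covered by a score track
#'
#' @param track data.frame with chrom and pos (1-based) columns.
#' @param genome \linkS4class{GenomeModel}.
#' @return covered positions / genome length.
#' @export
coverageFraction <- function(track, genome) {
  if (is.null(track) || nrow(track) == 0) return(0)
  nrow(unique(track[, c("chrom", "pos")])) / genomeLength(genome)
}

lookupTrack <- function(track, chrom, pos) {
  key <- paste(track$chrom, track$pos)
  m <- match(paste(chrom, pos), key)
  track$score[m]
}

#' Benchmark impact scores on a labeled variant set
#'
#' Looks up each score track at the labeled variant positions, calibrates
#' thresholds per score, and attaches the track's genome coverage. An
#' optional composite metric (the mean of AUC and maximum accuracy,
#' clearly labeled as this package's own composite) can be added for
#' ranking convenience.
#'
#' @param labeled data.frame with chrom, pos, ref, alt, label columns.
#' @param tracks named list of score-track data.frames (chrom, pos, score).
#' @param genome \linkS4class{GenomeModel} for coverage fractions.
#' @param composite add the composite column (default FALSE).
#' @return data.frame, one row per score.
#' @export
benchmarkScores <- function(labeled, tracks, genome = NULL,
                            composite = FALSE) {
  rows <- lapply(names(tracks), function(nm) {
    vals <- lookupTrack(tracks[[nm]], labeled$chrom, labeled$pos)
    out <- calibrateThresholds(vals, labeled$label)
    out <- cbind(data.frame(score = nm, stringsAsFactors = FALSE), out)
    out$coverage <- if (is.null(genome)) NA_real_ else
      coverageFraction(tracks[[nm]], genome)
    out
  })
  res <- do.call(rbind, rows)
  if (composite) res$composite <- (res$auc + res$accuracy) / 2
  res
}
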