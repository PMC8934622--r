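#' Build a gene rank table from HPO-driven Z-scores
#'
#' Takes a table of per-gene Z-scores (as produced by HPO-profile gene
#' prioritization tools) and attaches the mid-rank percentile of each gene
#' within the table. Percentiles are computed over all genes present in
#' the supplied table; absent genes are never silently assigned one.
#'
#' @param x data.frame with \code{gene} and \code{z} columns, or a path to
#'   a two-column TSV (header \code{gene<TAB>z}).
#' @return data.frame with gene, z and percentile columns.
#' @export
geneRankTable <- function(x) {
  if (is.character(x) && length(x) == 1)
    x <- utils::read.table(x, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "z") %in% colnames(x)))
  if (nrow(x) == 0) stop("empty gene rank table")
  x$percentile <- midrankECDF(x$z)
  x[order(-x$z), , drop = FALSE]
}

#' Percentile rank of genes in a rank table
#'
#' @param table data.frame from \code{\link{geneRankTable}}.
#' @param gene character vector of gene ids.
#' @return numeric percentiles in [0, 1]; NA for genes absent from the
#'   table (reported via a warning).
#' @export
genePercentile <- function(table, gene) {
  if (nrow(table) == 0) stop("empty gene rank table")
  p <- table$percentile[match(gene, table$gene)]
  if (anyNA(p))
    warning("gene(s) absent from rank table: ",
            paste(gene[is.na(p)], collapse = ", "))
  p
}

extractGeneSet <- function(genesEntry, closest) {
  g <- sub(":.*$", "", genesEntry)
  unique(c(g, closest[!is.na(closest)]))
}

#' HPO-driven candidate selection from an annotated VCF
#'
#' Keeps variants whose prioritization level reaches \code{levelMin} and
#' that are linked (controlled or closest gene) to at least one gene at or
#' above \code{percentileMin} in the rank table; candidates are sorted by
#' their best linked gene Z-score, descending, ties in genomic order.
#' Presets mirror common practice: 0.90 for level gating, 0.95 for likely
#' and 0.99 for strongly disease-related genes.
#'
#' @param vcf annotated VCF object or path (must carry RV_LEVEL/RV_GENES).
#' @param rankTable data.frame from \code{\link{geneRankTable}}.
#' @param levelMin minimum prioritization level, default 1.
#' @param percentileMin minimum gene percentile, default 0.90.
#' @return data.frame of candidates: variant id, chrom, pos, level,
#'   best_gene, z, percentile.
#' @export
hpoPrioritize <- function(vcf, rankTable, levelMin = 1,
                          percentileMin = 0.90) {
  if (is.character(vcf)) vcf <- VariantAnnotation::readVcf(vcf)
  ii <- VariantAnnotation::info(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- nrow(vcf)
  lev <- vapply(seq_len(n), function(i) {
    l <- ii$RV_LEVEL[[i]]
    if (!length(l)) NA_integer_ else max(l)
  }, integer(1))
  rows <- lapply(seq_len(n), function(i) {
    if (is.na(lev[i]) || lev[i] < levelMin) return(NULL)
    genes <- extractGeneSet(ii$RV_GENES[[i]], ii$RV_CLOSEST[i])
    if (!length(genes)) return(NULL)
    p <- suppressWarnings(genePercentile(rankTable, genes))
    ok <- !is.na(p) & p >= percentileMin
    if (!any(ok)) return(NULL)
    z <- rankTable$z[match(genes, rankTable$gene)]
    best <- which(ok)[order(-z[ok])[1]]
    data.frame(variant = rownames(ii)[i] %||% as.character(i),
               chrom = as.character(GenomicRanges::seqnames(rr[i])),
               pos = GenomicRanges::start(rr[i]), level = lev[i],
               best_gene = genes[best], z = z[best],
               percentile = p[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(variant = character(0), chrom = character(0),
                      pos = integer(0), level = integer(0),
                      best_gene = character(0), z = numeric(0),
                      percentile = numeric(0)))
  out <- out[order(-out$z, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a 6-column PED pedigree file
#'
#' @param path PED file (family, id, father, mother, sex, affected; 0 =
#'   missing parent, affected 2 = affected).
#' @return data.frame with those columns.
#' @export
readPed <- function(path) {
  ped <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  colnames(ped) <- c("family", "id", "father", "mother", "sex", "affected")
  ped
}

#' Extract complete trios from a pedigree
#'
#' @param ped data.frame from \code{\link{readPed}}.
#' @return data.frame with proband, father, mother ids (probands are
#'   affected samples with both parents present in the pedigree).
#' @export
pedTrios <- function(ped) {
  sel <- ped$father != "0" & ped$mother != "0" &
    ped$father %in% ped$id & ped$mother %in% ped$id & ped$affected == 2
  data.frame(proband = ped$id[sel], father = ped$father[sel],
             mother = ped$mother[sel], stringsAsFactors = FALSE)
}

## alt-allele dosage from a diploid genotype string; NA when missing,
## NaN when ploidy != 2
gtDosage <- function(gt) {
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (any(a == ".")) return(NA_real_)
    if (length(a) != 2) return(NaN)
    sum(a != "0")
  }, numeric(1))
}

#' Trio segregation filter
#'
#' Recessive model: the proband is homozygous for the alternate allele and
#' both parents are heterozygous. Dominant model: every affected sample
#' carries the alternate allele (het or hom) and unaffected parents are
#' homozygous reference. Missing genotypes fail the variant (fail-safe)
#' and are counted; non-diploid genotypes on autosomes are skipped with a
#' warning.
#'
#' @param gt character matrix of genotypes, rows = variants, columns named
#'   by sample (e.g. \code{geno(vcf)$GT}).
#' @param trio one-row data.frame (proband, father, mother), e.g. from
#'   \code{\link{pedTrios}}.
#' @param model "recessive" or "dominant".
#' @return logical vector per variant; counts of missing/skipped in
#'   attributes \code{n_missing} and \code{n_skipped}.
#' @export
segregationFilter <- function(gt, trio, model = c("recessive", "dominant")) {
  model <- match.arg(model)
  p <- gtDosage(gt[, trio$proband])
  f <- gtDosage(gt[, trio$father])
  m <- gtDosage(gt[, trio$mother])
  bad_ploidy <- is.nan(p) | is.nan(f) | is.nan(m)
  if (any(bad_ploidy))
    warning(sum(bad_ploidy), " record(s) with non-diploid genotypes skipped")
  missing <- (is.na(p) | is.na(f) | is.na(m)) & !bad_ploidy
  pass <- if (model == "recessive") {
    p == 2 & f == 1 & m == 1
  } else {
    p >= 1 & f == 0 & m == 0
  }
  pass[missing | bad_ploidy] <- FALSE
  pass[is.na(pass)] <- FALSE
  attr(pass, "n_missing") <- sum(missing)
  attr(pass, "n_skipped") <- sum(bad_ploidy)
  pass
}

#' Compound-heterozygote candidate pairs in a trio
#'
#' Pairs of variants in the same gene for which the proband is
#' heterozygous at both and the two alternate alleles are inherited in
#' trans (one from each parent, inferred from parental genotypes only).
#' Pairs whose phase cannot be resolved (a variant carried by both
#' parents) are kept and flagged \code{phase_ambiguous}; certain-cis pairs
#' and alleles carried by neither parent are excluded. Pairs are
#' classified by composition: coding+coding, coding+regulatory or
#' regulatory+regulatory.
#'
#' @param variants data.frame with columns id, gene, class ("coding" or
#'   "regulatory"), gt_proband, gt_father, gt_mother.
#' @return data.frame: gene, id1, id2, class1, class2, composition,
#'   phase_ambiguous.
#' @export
compoundHetPairs <- function(variants) {
  p <- gtDosage(variants$gt_proband)
  f <- gtDosage(variants$gt_father)
  m <- gtDosage(variants$gt_mother)
  het <- !is.na(p) & p == 1 & !is.na(f) & !is.na(m)
  origin <- rep(NA_character_, nrow(variants))
  origin[het & f >= 1 & m == 0] <- "paternal"
  origin[het & m >= 1 & f == 0] <- "maternal"
  origin[het & f >= 1 & m >= 1] <- "ambiguous"
  # het alleles carried by neither parent have no transmitted origin
  out <- NULL
  for (g in unique(variants$gene)) {
    idx <- which(variants$gene == g & !is.na(origin))
    if (length(idx) < 2) next
    for (i in seq_along(idx)[-length(idx)]) for (j in (i + 1):length(idx)) {
      a <- idx[i]; b <- idx[j]
      oa <- origin[a]; ob <- origin[b]
      trans <- (oa == "paternal" && ob == "maternal") ||
        (oa == "maternal" && ob == "paternal")
      amb <- (oa == "ambiguous" || ob == "ambiguous") &&
        !(oa == ob && oa != "ambiguous")
      if (!trans && !amb) next   # certain cis
      cls <- sort(c(variants$class[a], variants$class[b]))
      out <- rbind(out, data.frame(
        gene = g, id1 = variants$id[a], id2 = variants$id[b],
        class1 = variants$class[a], class2 = variants$class[b],
        composition = paste(cls, collapse = "+"),
        phase_ambiguous = !trans, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(gene = character(0), id1 = character(0),
                      id2 = character(0), class1 = character(0),
                      class2 = character(0), composition = character(0),
                      phase_ambiguous = logical(0))
  out
}
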