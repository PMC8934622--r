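## shared fixtures and independent brute-force oracles

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(VariantAnnotation)
})

tinyGenome <- function(len = c(chr1 = 1e5, chr2 = 1e5), excluded = NULL) {
  GenomeModel(len, excluded)
}

## a GRanges of regions with full metadata, ready for buildDatabase
tinyRegions <- function(chrom, start, end, type, source = "src",
                        genes = "", tissues = "") {
  n <- length(start)
  df <- data.frame(chrom = rep_len(chrom, n), start = start, end = end,
                   type = rep_len(type, n), gene = rep_len(genes, n),
                   tissue = rep_len(tissues, n), stringsAsFactors = FALSE)
  normalizeSource(df, source,
                  columns = c(chrom = "chrom", start = "start", end = "end",
                              type = "type", gene = "gene",
                              tissue = "tissue"),
                  coords = "one_based")
}

## one-region database fixture with configurable constraint
oneRegionDb <- function(start = 5001, end = 6000, type = "enhancer",
                        constraint = NA_real_, gene = "G0001") {
  gm <- tinyGenome()
  gr <- tinyRegions("chr1", start, end, type, genes = gene)
  genes <- geneModelTable(gene, "chr1", end + 1000, end + 2000, "+")
  db <- buildDatabase(gr, gm, genes = genes)
  mc <- mcols(regions(db))
  mc$constraint <- constraint
  gr2 <- regions(db)
  mcols(gr2) <- mc
  methods::slot(db, "regions") <- gr2
  db
}

## minimal single-sample VCF writer for targeted fixtures
writeTestVcf <- function(path, chrom, pos, ref = "A", alt = "T", af = NULL,
                         info = NULL, contigs = c(chr1 = 1e5, chr2 = 1e5),
                         gt = NULL, samples = "S1") {
  n <- length(pos)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  chrom <- rep_len(chrom, n)
  infoStr <- rep("", n)
  if (!is.null(af))
    infoStr <- sprintf("AF=%s", format(af, trim = TRUE,
                                       scientific = FALSE))
  if (!is.null(info))
    infoStr <- ifelse(nzchar(infoStr), paste(infoStr, info, sep = ";"), info)
  infoStr[!nzchar(infoStr)] <- "."
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
           "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Len\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt)) cols <- c(cols, "FORMAT", samples)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", chrom, pos, ref, alt,
                  infoStr)
  if (!is.null(gt)) {
    gtm <- matrix(gt, nrow = n)
    body <- paste(body, "GT", apply(gtm, 1, paste, collapse = "\t"),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
  path
}

## ---- independent oracles ---------------------------------------------------

bfIntervalQuery <- function(regStart, regEnd, qStart, qEnd) {
  which(regStart <= qEnd & regEnd >= qStart)
}

bfClosestGene <- function(rs, re, gs, ge, ids) {
  d <- numeric(length(gs))
  for (k in seq_along(gs)) {
    if (ge[k] >= rs && gs[k] <= re) d[k] <- 0
    else if (gs[k] > re) d[k] <- gs[k] - re - 1
    else d[k] <- rs - ge[k] - 1
  }
  ord <- order(d, ids)
  list(gene = ids[ord[1]], dist = d[ord[1]])
}

bfCountSites <- function(rs, re, pos) {
  vapply(seq_along(rs), function(i) sum(pos >= rs[i] & pos <= re[i]),
         integer(1))
}

## exact two-sided Fisher p via hypergeometric enumeration
bfFisherP <- function(a, b, c_, d) {
  m <- a + b; n_ <- c_ + d; k <- a + c_
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_, k)
  pa <- dhyper(a, m, n_, k)
  sum(probs[probs <= pa * (1 + 1e-7)])
}

bfAUC <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

## trapezoidal integration of the empirical ROC curve
trapezoidAUC <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

## exhaustive threshold sweep, written independently of calibrateThresholds
bfSweep <- function(scores, labels) {
  cand <- sort(unique(scores))
  stats <- lapply(cand, function(t) {
    tp <- sum(scores >= t & labels); fp <- sum(scores >= t & !labels)
    fn <- sum(scores < t & labels); tn <- sum(scores < t & !labels)
    list(t = t, tpr = tp / (tp + fn),
         fdr = if (tp + fp > 0) fp / (tp + fp) else 0,
         acc = (tp + tn) / length(scores))
  })
  tprs <- vapply(stats, `[[`, 0, "tpr")
  fdrs <- vapply(stats, `[[`, 0, "fdr")
  accs <- vapply(stats, `[[`, 0, "acc")
  list(
    tpr90 = if (any(tprs >= 0.9)) cand[max(which(tprs >= 0.9))] else NA_real_,
    fdr50 = if (any(fdrs <= 0.5)) cand[min(which(fdrs <= 0.5))] else NA_real_,
    maxacc = cand[max(which(accs >= max(accs) - 1e-12))])
}

## exhaustive compound-het pairing oracle
bfCompHet <- function(v) {
  out <- list()
  for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
    if (v$gene[i] != v$gene[j]) next
    ok <- TRUE
    orig <- character(2)
    for (kk in 1:2) {
      r <- v[c(i, j)[kk], ]
      pd <- sum(strsplit(r$gt_proband, "/")[[1]] != "0")
      fd <- sum(strsplit(r$gt_father, "/")[[1]] != "0")
      md <- sum(strsplit(r$gt_mother, "/")[[1]] != "0")
      if (pd != 1) { ok <- FALSE; break }
      if (fd >= 1 && md == 0) orig[kk] <- "P"
      else if (md >= 1 && fd == 0) orig[kk] <- "M"
      else if (fd >= 1 && md >= 1) orig[kk] <- "A"
      else { ok <- FALSE; break }
    }
    if (!ok) next
    trans <- (orig[1] == "P" && orig[2] == "M") ||
      (orig[1] == "M" && orig[2] == "P")
    cis <- orig[1] == orig[2] && orig[1] != "A"
    if (cis || (!trans && !any(orig == "A"))) next
    out[[length(out) + 1]] <- data.frame(
      gene = v$gene[i], id1 = v$id[i], id2 = v$id[j],
      phase_ambiguous = !trans, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(0), id1 = character(0),
                      id2 = character(0), phase_ambiguous = logical(0)))
  do.call(rbind, out)
}

## standard test fixture: collapsed database with genes over a small genome
standardDb <- function(seed = 11, nPerType = 60) {
  cfg <- simConfig(seed = seed,
                   regionCounts = c(bivalent = nPerType, enhancer = nPerType,
                                    insulator = nPerType,
                                    promoter = nPerType,
                                    silencer = nPerType),
                   chromLengths = c(chr1 = 2e5, chr2 = 2e5),
                   geneCount = 40)
  gm <- simGenome(cfg)
  tab <- simRegions(cfg, gm)
  gr <- normalizeSource(tab, "sim",
                        columns = c(chrom = "chrom", start = "start",
                                    end = "end", type = "type",
                                    tissue = "tissue", method = "method"),
                        coords = "one_based", genome = gm)
  grc <- collapseRegions(gr, 0.8)
  buildDatabase(grc, gm, genes = simGenes(cfg, gm))
}
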