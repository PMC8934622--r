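#' @importFrom VariantAnnotation readVcf writeVcf info info<- header header<- ref alt
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom IRanges CharacterList IntegerList NumericList
#' @importFrom S4Vectors elementNROWS
NULL

RV_FIELDS <- c("RV_ID", "RV_TYPE", "RV_CONSTRAINT", "RV_GENES", "RV_CLOSEST",
               "RV_DIST", "RV_FE", "RV_SCORES", "RV_LEVEL", "RV_VOI",
               "RV_AFMISS")

#' Prioritization-level configuration
#'
#' Bundles the tunables of the four-level classification: the population
#' allele-frequency gate (strict, AF < af_max), the functional-element
#' classes counted at level 2, the per-score FDR50 thresholds used at level
#' 3, the region-constraint gate (inclusive, >= constraint_min) at level 4,
#' and the HPO-ranking percentile used downstream. Variants with no AF
#' annotation pass the rarity gate by default (absence from a population
#' database is itself evidence of rarity) and are flagged RV_AFMISS;
#' \code{missing_af = "strict"} fails them instead.
#'
#' @param af_max maximum population AF, exclusive; default 0.01.
#' @param fe_classes functional-element class names; default
#'   TFBS/DNase/UCNE.
#' @param score_thresholds named numeric vector of per-score FDR50
#'   thresholds (e.g. from \code{\link{calibrateThresholds}}).
#' @param constraint_min minimum region constraint for level 4, inclusive;
#'   default 0.7.
#' @param gado_percentile HPO-ranking percentile gate; default 0.90.
#' @param af_field INFO field holding the population AF; default "AF".
#' @param missing_af "rare" (default) or "strict".
#' @return a LevelConfig list.
#' @export
levelConfig <- function(af_max = 0.01,
                        fe_classes = c("TFBS", "DNase", "UCNE"),
                        score_thresholds = numeric(0),
                        constraint_min = 0.7, gado_percentile = 0.90,
                        af_field = "AF",
                        missing_af = c("rare", "strict")) {
  stopifnot(af_max > 0, af_max <= 1, constraint_min >= 0, constraint_min <= 1)
  structure(list(af_max = af_max, fe_classes = fe_classes,
                 score_thresholds = score_thresholds,
                 constraint_min = constraint_min,
                 gado_percentile = gado_percentile, af_field = af_field,
                 missing_af = match.arg(missing_af)),
            class = "LevelConfig")
}

#' Assign the prioritization level of one annotated allele
#'
#' Level 1: rare (AF below the gate) and overlapping at least one database
#' region. Level 2: level 1 plus at least one functional-element class hit.
#' Level 3: level 2 plus at least one prediction score at or above its
#' FDR50 threshold. Level 4: level 3 plus maximum region constraint at or
#' above the constraint gate. Levels are nested by construction; the
#' highest satisfied level is returned (0 when level 1 fails).
#'
#' @param af population allele frequency (NA = missing).
#' @param hasRegion does the allele overlap any database region?
#' @param feHits character vector of functional-element classes hit.
#' @param scoreValues named numeric score values at the variant.
#' @param maxConstraint maximum constraint over overlapping regions (NA ok).
#' @param config a \code{\link{levelConfig}}.
#' @return integer level 0..4.
#' @export
classifyLevel <- function(af, hasRegion, feHits = character(0),
                          scoreValues = numeric(0), maxConstraint = NA,
                          config = levelConfig()) {
  rare <- if (is.na(af)) config$missing_af == "rare" else af < config$af_max
  if (!rare || !hasRegion) return(0L)
  lvl <- 1L
  if (!any(feHits %in% config$fe_classes)) return(lvl)
  lvl <- 2L
  thr <- config$score_thresholds
  common <- intersect(names(scoreValues), names(thr))
  pass <- length(common) > 0 &&
    any(!is.na(scoreValues[common]) & scoreValues[common] >= thr[common])
  if (!pass) return(lvl)
  lvl <- 3L
  if (!is.na(maxConstraint) && maxConstraint >= config$constraint_min)
    lvl <- 4L
  lvl
}

rvHeaderRows <- function() {
  S4Vectors::DataFrame(
    Number = c(".", ".", "1", ".", "1", "1", ".", ".", ".", "0", "0"),
    Type = c("String", "String", "Float", "String", "String", "Integer",
             "String", "String", "Integer", "Flag", "Flag"),
    Description = c(
      "Overlapping regulatory region ids",
      "Overlapping regulatory region types",
      "Maximum constraint over overlapping regulatory regions",
      "Controlled genes as gene:evidence entries",
      "Closest gene of the overlapping regulatory regions",
      "Distance (bp) of the closest gene",
      "Functional element classes hit",
      "Score values at the variant as name:value entries",
      "Prioritization level per ALT allele (absent for SVs)",
      "Variant linked to a gene of interest",
      "Population AF missing; treated as rare"),
    row.names = RV_FIELDS)
}

isSymbolicAlt <- function(altList) {
  if (is(altList, "DNAStringSetList"))
    return(list(sv = logical(length(altList)), bnd = logical(length(altList))))
  ch <- as.list(altList)
  sym <- vapply(ch, function(a) any(grepl("^<.*>$", a)), logical(1))
  bnd <- vapply(ch, function(a) any(grepl("\\[|\\]", a)), logical(1))
  list(sv = sym | bnd, bnd = bnd & !sym)
}

infoNumeric <- function(v, field, n) {
  ii <- VariantAnnotation::info(v)
  if (!field %in% colnames(ii)) return(rep(list(NA_real_), n))
  x <- ii[[field]]
  if (is.numeric(x)) as.list(as.numeric(x)) else
    lapply(as.list(x), function(e) if (length(e)) as.numeric(e) else NA_real_)
}

#' Annotate a VCF with regulatory evidence and prioritization levels
#'
#' Adds the RV_* INFO fields: overlapping region ids/types and their
#' maximum constraint, controlled genes (union over regions with evidence
#' class retained), closest gene and distance, functional-element hits,
#' per-score values, per-allele prioritization level, gene-of-interest and
#' AF-missing flags. The overlap span of a small variant is its affected
#' reference bases (POS..POS+len(REF)-1); indel score lookup takes the
#' maximum over affected positions, insertions using the two flanking
#' bases. Structural variants (symbolic ALT) are annotated with span
#' POS..END (or SVLEN), breakends at the breakend position only, and
#' receive regions and genes but no level. Record count and genotypes are
#' never modified; existing RV_* fields are replaced, making annotation
#' idempotent.
#'
#' @param vcf path to a VCF file or a VCF object.
#' @param db a \linkS4class{RegulatoryDB}.
#' @param functionalElements named list of GRanges (e.g. TFBS, DNase,
#'   UCNE).
#' @param scoreTracks named list of score-track data.frames (chrom, pos,
#'   score).
#' @param config a \code{\link{levelConfig}}.
#' @param genesOfInterest optional character vector for the RV_VOI flag.
#' @param out optional output VCF path.
#' @return the annotated VCF object (invisibly when written to file);
#'   skipped-record counts in \code{metadata(.)$RV_skipped}.
#' @export
annotateVcf <- function(vcf, db, functionalElements = list(),
                        scoreTracks = list(), config = levelConfig(),
                        genesOfInterest = NULL, out = NULL) {
  if (is.character(vcf)) vcf <- VariantAnnotation::readVcf(vcf)
  n <- nrow(vcf)
  hdr <- VariantAnnotation::header(vcf)
  ih <- VariantAnnotation::info(hdr)
  ih <- ih[!(rownames(ih) %in% RV_FIELDS), , drop = FALSE]
  VariantAnnotation::info(hdr) <- rbind(ih, rvHeaderRows())
  VariantAnnotation::header(vcf) <- hdr
  ii <- VariantAnnotation::info(vcf)
  ii <- ii[, !(colnames(ii) %in% RV_FIELDS), drop = FALSE]

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refw <- Biostrings::width(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(altList)
  sym <- isSymbolicAlt(altList)
  isSV <- sym$sv; isBND <- sym$bnd

  # affected span per record
  spanEnd <- pos + refw - 1L
  skipped <- 0L
  if (any(isSV)) {
    endField <- infoNumeric(vcf, "END", n)
    svlenField <- infoNumeric(vcf, "SVLEN", n)
    for (i in which(isSV)) {
      if (isBND[i]) { spanEnd[i] <- pos[i]; next }
      e <- endField[[i]][1]; sl <- svlenField[[i]][1]
      if (!is.na(e)) spanEnd[i] <- as.integer(e)
      else if (!is.na(sl)) spanEnd[i] <- pos[i] + abs(as.integer(sl)) - 1L
      else { spanEnd[i] <- pos[i] - 1L; skipped <- skipped + 1L }  # empty span
    }
  }
  valid <- spanEnd >= pos
  spans <- GenomicRanges::GRanges(chrom, IRanges::IRanges(
    ifelse(valid, pos, 1L), ifelse(valid, spanEnd, 0L)))

  # region overlaps
  gr <- regions(db)
  mc <- GenomicRanges::mcols(gr)
  gl <- as.data.frame(geneLinks(db))
  geneEntries <- split(paste(gl$gene_id, gl$evidence, sep = ":"),
                       factor(gl$region_id, levels = mc$region_id))
  hits <- GenomicRanges::findOverlaps(spans, gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  f <- factor(qh, levels = seq_len(n))
  idL <- split(mc$region_id[sh], f)
  typeL <- lapply(split(mc$region_type[sh], f), function(x) sort(unique(x)))
  consV <- vapply(split(mc$constraint[sh], f), function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE), numeric(1))
  genesL <- lapply(split(sh, f), function(idx)
    sort(unique(unlist(geneEntries[idx], use.names = FALSE))))
  closest <- lapply(split(sh, f), function(idx) {
    if (!length(idx)) return(c(NA_character_, NA_character_))
    d <- mc$closest_gene_dist[idx]; g <- mc$closest_gene[idx]
    ok <- !is.na(g)
    if (!any(ok)) return(c(NA_character_, NA_character_))
    b <- which(ok)[order(d[ok], g[ok])][1]
    c(g[b], as.character(d[b]))
  })

  # functional elements
  feL <- rep(list(character(0)), n)
  for (cls in names(functionalElements)) {
    hit <- IRanges::overlapsAny(spans, functionalElements[[cls]],
                                ignore.strand = TRUE)
    for (i in which(hit & valid)) feL[[i]] <- c(feL[[i]], cls)
  }

  # score lookup: max over affected positions; insertions use the flanks
  maxAltW <- rep(0L, n)
  if (sum(nalt) > 0) {
    aw <- nchar(as.character(unlist(altList)))
    agg <- tapply(aw, rep(seq_len(n), nalt), max)
    maxAltW[as.integer(names(agg))] <- as.integer(agg)
  }
  ins <- !isSV & refw == 1 & maxAltW > refw
  scoreVals <- matrix(NA_real_, n, length(scoreTracks),
                      dimnames = list(NULL, names(scoreTracks)))
  for (nm in names(scoreTracks)) {
    tr <- scoreTracks[[nm]]
    key <- paste(tr$chrom, tr$pos)
    simple <- valid & (spanEnd == pos) & !ins
    scoreVals[simple, nm] <- tr$score[match(paste(chrom, pos)[simple], key)]
    for (i in which(valid & !simple)) {
      p <- pos[i]:max(spanEnd[i], pos[i] + as.integer(ins[i]))
      v <- tr$score[match(paste(chrom[i], p), key)]
      scoreVals[i, nm] <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }
  }

  # allele frequency (per ALT or scalar)
  afL <- infoNumeric(vcf, config$af_field, n)
  afmiss <- vapply(afL, function(a) all(is.na(a)), logical(1))

  levels <- vector("list", n)
  for (i in seq_len(n)) {
    if (isSV[i]) { levels[[i]] <- integer(0); next }
    afs <- rep_len(afL[[i]], max(nalt[i], 1L))
    sv <- scoreVals[i, ]
    levels[[i]] <- vapply(afs, function(a)
      classifyLevel(a, length(idL[[i]]) > 0, feL[[i]], sv, consV[i], config),
      integer(1))
  }

  allGenes <- lapply(seq_len(n), function(i) {
    g <- sub(":.*$", "", genesL[[i]])
    cg <- closest[[i]][1]
    unique(c(g, cg[!is.na(cg)]))
  })
  voi <- if (is.null(genesOfInterest)) rep(FALSE, n) else
    vapply(allGenes, function(g) length(intersect(g, genesOfInterest)) > 0,
           logical(1))

  scoreEntries <- lapply(seq_len(n), function(i) {
    v <- scoreVals[i, ]
    v <- v[!is.na(v)]
    if (!length(v)) character(0) else
      sprintf("%s:%s", names(v), format(v, trim = TRUE, digits = 6))
  })

  ii$RV_ID <- IRanges::CharacterList(idL)
  ii$RV_TYPE <- IRanges::CharacterList(typeL)
  ii$RV_CONSTRAINT <- unname(consV)
  ii$RV_GENES <- IRanges::CharacterList(genesL)
  ii$RV_CLOSEST <- vapply(closest, `[`, "", 1)
  ii$RV_DIST <- suppressWarnings(as.integer(vapply(closest, `[`, "", 2)))
  ii$RV_FE <- IRanges::CharacterList(feL)
  ii$RV_SCORES <- IRanges::CharacterList(scoreEntries)
  ii$RV_LEVEL <- IRanges::IntegerList(levels)
  ii$RV_VOI <- voi
  ii$RV_AFMISS <- afmiss & !isSV
  VariantAnnotation::info(vcf) <- ii
  S4Vectors::metadata(vcf)$RV_skipped <- skipped
  if (!is.null(out)) {
    VariantAnnotation::writeVcf(vcf, out)
    return(invisible(vcf))
  }
  vcf
}

#' Update a snpEff/bcftools consequence field with regulatory genes
#'
#' For every regulatory controlled gene absent from the existing
#' annotation entries, appends a \code{regulatory_region_variant} entry
#' naming that gene; existing entries are untouched. With no existing
#' field, a new one listing all regulatory genes is created. Unparseable
#' fields are returned unchanged with a warning.
#'
#' @param existing existing ANN/BCSQ string (comma-separated entries) or
#'   NA/empty for none.
#' @param genes character vector of regulatory controlled genes.
#' @param format "ANN" (snpEff; gene at pipe-field 4) or "BCSQ"
#'   (bcftools csq; gene at pipe-field 2).
#' @param allele ALT allele symbol used in new ANN entries.
#' @return the updated field string.
#' @export
updateConsequence <- function(existing, genes, format = c("ANN", "BCSQ"),
                              allele = ".") {
  format <- match.arg(format)
  gidx <- if (format == "ANN") 4L else 2L
  newEntry <- function(g) {
    if (format == "ANN")
      paste(c(allele, "regulatory_region_variant", "MODIFIER", g), collapse = "|")
    else paste(c("regulatory_region_variant", g), collapse = "|")
  }
  if (is.null(existing) || length(existing) == 0 || is.na(existing) ||
      !nzchar(existing))
    return(paste(vapply(genes, newEntry, ""), collapse = ","))
  entries <- strsplit(existing, ",", fixed = TRUE)[[1]]
  parts <- strsplit(entries, "|", fixed = TRUE)
  if (any(lengths(parts) < gidx)) {
    warning("unparseable consequence field left unchanged")
    return(existing)
  }
  have <- vapply(parts, `[`, "", gidx)
  add <- setdiff(genes, have)
  paste(c(entries, vapply(add, newEntry, "")), collapse = ",")
}

#' Flag variants linked to genes of interest
#'
#' @param annotatedGenes character vector of a variant's controlled and
#'   closest genes.
#' @param genesOfInterest non-empty character vector.
#' @return TRUE when the two sets intersect.
#' @export
tagGenesOfInterest <- function(annotatedGenes, genesOfInterest) {
  stopifnot(length(genesOfInterest) > 0)
  length(intersect(annotatedGenes, genesOfInterest)) > 0
}
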