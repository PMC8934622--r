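#' Configuration for the synthetic-data generators
#'
#' Desk-scale defaults: two 1-Mb chromosomes, ~2000 regions with sizes
#' log-uniform between 100 and 1000 bp, 200 genes, 5000 variants with a
#' common/rare AF mixture, labeled score sets at a 1:10 positive:negative
#' ratio, and partially covered score tracks. All generators are
#' deterministic under \code{seed}: the same configuration yields
#' byte-identical files.
#'
#' @param seed master seed.
#' @param chromLengths named chromosome lengths (bp).
#' @param regionCounts named integer vector per region type.
#' @param sizeRange log-uniform size bounds (bp) for regions.
#' @param duplicateFraction fraction of regions re-emitted as high-overlap
#'   near-duplicates (exercises collapsing).
#' @param geneCount number of genes.
#' @param variantCount background variants in trio VCFs.
#' @param afCommonFraction fraction of background variants drawn from the
#'   common-AF component.
#' @param nPositives,nNegatives labeled-set class sizes (default 72/720,
#'   a 1:10 ratio).
#' @param aucShift mean shift of positive score values (in SD units).
#' @param trackCoverage fraction of positions covered per score track.
#' @param depletionFraction,depletionFactor fraction of regions with
#'   planted variant depletion, and the factor applied to their expected
#'   count.
#' @return a SimConfig list.
#' @export
simConfig <- function(seed = 42,
                      chromLengths = c(chr1 = 1e6, chr2 = 1e6),
                      regionCounts = c(bivalent = 100, enhancer = 800,
                                       insulator = 200, promoter = 700,
                                       silencer = 200),
                      sizeRange = c(100, 1000),
                      duplicateFraction = 0.05,
                      geneCount = 200,
                      variantCount = 5000,
                      afCommonFraction = 0.7,
                      nPositives = 72, nNegatives = 720,
                      aucShift = 1.5,
                      trackCoverage = 0.9,
                      depletionFraction = 0.1, depletionFactor = 0.2) {
  structure(as.list(environment()), class = "SimConfig")
}

#' Generate a synthetic genome
#'
#' Chromosome lengths from the configuration, with mock telomeres (10 kb
#' at each end) and a mock centromere (50 kb at the middle) as excluded
#' intervals. Optionally also generates uniform-random chromosome
#' sequences.
#'
#' @param config a \code{\link{simConfig}}.
#' @param sequence also generate DNA sequences (DNAStringSet)?
#' @return a \linkS4class{GenomeModel}; with \code{sequence = TRUE}, a
#'   list \code{(genome, sequence)}.
#' @export
simGenome <- function(config, sequence = FALSE) {
  cl <- config$chromLengths
  exdf <- do.call(rbind, lapply(names(cl), function(ch) {
    L <- cl[[ch]]
    telo <- min(10000, floor(L / 10))
    centro <- min(50000, floor(L / 10))
    cstart <- floor(L / 2) - floor(centro / 2)
    data.frame(ch = ch, s = c(1, cstart, L - telo + 1),
               e = c(telo, cstart + centro - 1, L))
  }))
  ex <- GenomicRanges::GRanges(exdf$ch, IRanges::IRanges(exdf$s, exdf$e))
  gm <- GenomeModel(cl, ex)
  if (!sequence) return(gm)
  seqs <- withSeed(config$seed + 101L, {
    Biostrings::DNAStringSet(vapply(names(cl), function(ch)
      paste(sample(c("A", "C", "G", "T"), cl[[ch]], replace = TRUE),
            collapse = ""), character(1)))
  })
  list(genome = gm, sequence = seqs)
}

#' Generate a raw region table emulating one catalog source
#'
#' Emits the configured number of regions per type with log-uniform sizes
#' (default 100-1000 bp, matching typical regulatory-element catalogs),
#' spread over three synthetic sources, plus a configurable fraction of
#' planted near-duplicates (small coordinate jitter, reciprocal overlap
#' above 0.9) that region collapsing should remove.
#'
#' @param config a \code{\link{simConfig}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @return data.frame (chrom, start, end, type, source, tissue, method)
#'   with 1-based inclusive coordinates.
#' @export
simRegions <- function(config, genome) {
  cl <- chromLengths(genome)
  withSeed(config$seed + 202L, {
    rows <- lapply(names(config$regionCounts), function(ty) {
      k <- config$regionCounts[[ty]]
      if (k == 0) return(NULL)
      sz <- round(10^stats::runif(k, log10(config$sizeRange[1]),
                                  log10(config$sizeRange[2])))
      ch <- sample(names(cl), k, replace = TRUE,
                   prob = unname(cl) / sum(cl))
      st <- floor(stats::runif(k, 1, unname(cl[ch]) - sz))
      data.frame(chrom = ch, start = st, end = st + sz - 1, type = ty,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$source <- sample(paste0("source", 1:3), nrow(tab), replace = TRUE)
    tab$tissue <- sample(c("brain", "liver", "heart", "blood"), nrow(tab),
                         replace = TRUE)
    tab$method <- sample(c("chip", "cage", "predicted"), nrow(tab),
                         replace = TRUE)
    ndup <- round(config$duplicateFraction * nrow(tab))
    if (ndup > 0) {
      pick <- sample.int(nrow(tab), ndup)
      dup <- tab[pick, ]
      jitter <- pmax(1, round((dup$end - dup$start + 1) * 0.04))
      dup$start <- pmax(1, dup$start + jitter)
      dup$end <- dup$end + jitter
      dup$source <- "source_dup"
      tab <- rbind(tab, dup)
    }
    rownames(tab) <- NULL
    tab
  })
}

#' Generate synthetic gene models
#'
#' @param config a \code{\link{simConfig}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @return DataFrame from \code{\link{geneModelTable}}.
#' @export
simGenes <- function(config, genome) {
  cl <- chromLengths(genome)
  withSeed(config$seed + 303L, {
    k <- config$geneCount
    len <- round(10^stats::runif(k, log10(2000), log10(20000)))
    ch <- sample(names(cl), k, replace = TRUE, prob = unname(cl) / sum(cl))
    st <- floor(stats::runif(k, 1, unname(cl[ch]) - len))
    geneModelTable(sprintf("G%04d", seq_len(k)), ch, st, st + len - 1,
                   sample(c("+", "-"), k, replace = TRUE))
  })
}

#' Generate synthetic functional-element tracks
#'
#' @param config a \code{\link{simConfig}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @param counts named element counts, default 400 TFBS, 300 DNase,
#'   100 UCNE.
#' @return named list of GRanges.
#' @export
simFunctionalElements <- function(config, genome,
                                  counts = c(TFBS = 400, DNase = 300,
                                             UCNE = 100)) {
  cl <- chromLengths(genome)
  withSeed(config$seed + 404L, {
    out <- lapply(names(counts), function(nm) {
      k <- counts[[nm]]
      sz <- round(stats::runif(k, 20, 500))
      ch <- sample(names(cl), k, replace = TRUE, prob = unname(cl) / sum(cl))
      st <- floor(stats::runif(k, 1, unname(cl[ch]) - sz))
      GenomicRanges::sort(GenomicRanges::GRanges(
        ch, IRanges::IRanges(st, width = sz)), ignore.strand = TRUE)
    })
    names(out) <- names(counts)
    out
  })
}

#' Generate a labeled variant set with per-score values
#'
#' Positions are uniform over the genome; negative scores are standard
#' normal, positives are shifted by \code{aucShift} standard deviations so
#' the expected AUC is pnorm(shift / sqrt(2)). Each variant's score is
#' observed with probability \code{trackCoverage} per score, missing
#' otherwise.
#'
#' @param config a \code{\link{simConfig}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @param scores character vector of score names.
#' @return list: \code{labeled} data.frame (chrom, pos, ref, alt, label
#'   and one value column per score) and \code{tracks}, a named list of
#'   per-score track data.frames restricted to covered variants.
#' @export
simLabeledScores <- function(config, genome,
                             scores = c("ncER", "FATHMM_MKL", "ReMM")) {
  cl <- chromLengths(genome)
  withSeed(config$seed + 505L, {
    n <- config$nPositives + config$nNegatives
    lab <- rep(c("positive", "negative"),
               c(config$nPositives, config$nNegatives))
    ch <- sample(names(cl), n, replace = TRUE, prob = unname(cl) / sum(cl))
    pos <- floor(stats::runif(n, 1, unname(cl[ch])))
    df <- data.frame(chrom = ch, pos = pos,
                     ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     label = lab, stringsAsFactors = FALSE)
    tracks <- list()
    for (s in scores) {
      val <- stats::rnorm(n) + ifelse(lab == "positive", config$aucShift, 0)
      covered <- stats::runif(n) < config$trackCoverage
      val[!covered] <- NA
      df[[s]] <- val
      tracks[[s]] <- data.frame(chrom = ch[covered], pos = pos[covered],
                                score = val[covered],
                                stringsAsFactors = FALSE)
    }
    list(labeled = df, tracks = tracks)
  })
}

#' Generate a genome-wide partial score track
#'
#' Covers each genomic position independently with the given probability;
#' values are standard normal.
#'
#' @param config a \code{\link{simConfig}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @param coverage coverage probability (default from config).
#' @param seedOffset offset added to the master seed (distinct tracks).
#' @return data.frame (chrom, pos, score).
#' @export
simScoreTrack <- function(config, genome, coverage = config$trackCoverage,
                          seedOffset = 0L) {
  cl <- chromLengths(genome)
  withSeed(config$seed + 606L + seedOffset, {
    out <- lapply(names(cl), function(ch) {
      pos <- which(stats::runif(cl[[ch]]) < coverage)
      data.frame(chrom = ch, pos = pos, score = stats::rnorm(length(pos)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate variant sites with planted depletion in some regions
#'
#' Per-region site counts are Poisson with mean
#' \code{rate * region length}, multiplied by \code{depletionFactor} for a
#' randomly chosen \code{depletionFraction} of regions; site positions are
#' uniform within their region. Used to exercise the constraint model with
#' known truth.
#'
#' @param config a \code{\link{simConfig}}.
#' @param gr region GRanges.
#' @param rate per-base expected variant rate (default 0.02).
#' @return list: \code{sites} data.frame (chrom, pos) and \code{depleted}
#'   logical per region.
#' @export
simVariantSites <- function(config, gr, rate = 0.02) {
  withSeed(config$seed + 707L, {
    n <- length(gr)
    depleted <- stats::runif(n) < config$depletionFraction
    lam <- rate * GenomicRanges::width(gr) *
      ifelse(depleted, config$depletionFactor, 1)
    counts <- stats::rpois(n, lam)
    rows <- lapply(which(counts > 0), function(i) {
      w <- GenomicRanges::width(gr[i])
      k <- min(counts[i], w)
      data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr[i])),
        pos = GenomicRanges::start(gr[i]) + sample.int(w, k) - 1L,
        stringsAsFactors = FALSE)
    })
    sites <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), pos = integer(0))
    list(sites = sites, depleted = depleted)
  })
}

formatGT <- function(a1, a2) paste(a1, a2, sep = "/")

hwTrioGenotypes <- function(af) {
  draw <- function() c(stats::rbinom(1, 1, af), stats::rbinom(1, 1, af))
  fa <- draw(); mo <- draw()
  ch <- c(sample(fa, 1), sample(mo, 1))
  c(formatGT(fa[1], fa[2]), formatGT(mo[1], mo[2]), formatGT(ch[1], ch[2]))
}

#' Generate a trio VCF with an inheritance scenario spiked in
#'
#' Background variants get allele frequencies from a common/rare mixture
#' and Hardy-Weinberg trio genotypes (child alleles drawn from the
#' parents). The scenario then spikes variants with genotypes consistent
#' with it and AF below 1%: \code{recessive} (proband 1/1, parents 0/1),
#' \code{dominant} (proband 0/1, parents 0/0), \code{comphet} (one
#' paternal-only and one maternal-only heterozygous variant inside the
#' target region), or \code{null} (no spike). Files are written
#' deterministically: identical configurations give byte-identical VCF and
#' PED output.
#'
#' @param config a \code{\link{simConfig}}.
#' @param genome a \linkS4class{GenomeModel}.
#' @param scenario one of "recessive", "dominant", "comphet", "null".
#' @param spikeRegion optional GRanges of length 1; spiked variants are
#'   placed inside it (default: mid-chromosome positions).
#' @param dir output directory (created).
#' @param prefix file name prefix.
#' @return list: vcf path, ped path, samples, spiked data.frame
#'   (chrom, pos, id) of spiked records.
#' @export
simTrioVcf <- function(config, genome,
                       scenario = c("recessive", "dominant", "comphet",
                                    "null"),
                       spikeRegion = NULL, dir = tempdir(),
                       prefix = "trio") {
  scenario <- match.arg(scenario)
  cl <- chromLengths(genome)
  samples <- c("FATHER", "MOTHER", "PROBAND")
  withSeed(config$seed + 808L, {
    n <- config$variantCount
    ch <- sample(names(cl), n, replace = TRUE, prob = unname(cl) / sum(cl))
    pos <- floor(stats::runif(n, 1, unname(cl[ch])))
    common <- stats::runif(n) < config$afCommonFraction
    af <- ifelse(common, stats::runif(n, 0.05, 0.5),
                 10^stats::runif(n, -4, -2))
    gts <- t(vapply(af, hwTrioGenotypes, character(3)))
    tab <- data.frame(chrom = ch, pos = pos,
                      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                      af = af, gt_father = gts[, 1], gt_mother = gts[, 2],
                      gt_proband = gts[, 3], id = ".",
                      stringsAsFactors = FALSE)
    tab$alt <- vapply(tab$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")

    spikePos <- function(k) {
      if (!is.null(spikeRegion)) {
        s <- GenomicRanges::start(spikeRegion)[1]
        w <- GenomicRanges::width(spikeRegion)[1]
        data.frame(chrom = as.character(
          GenomicRanges::seqnames(spikeRegion))[1],
          pos = s + sort(sample.int(w, k)) - 1L)
      } else {
        data.frame(chrom = names(cl)[1],
                   pos = floor(cl[[1]] / 4) + seq_len(k) * 10L)
      }
    }
    spiked <- NULL
    mkSpike <- function(k, gtf, gtm, gtp, idstem) {
      sp <- spikePos(k)
      data.frame(chrom = sp$chrom, pos = sp$pos,
                 ref = "A", af = 0.001, gt_father = gtf, gt_mother = gtm,
                 gt_proband = gtp, id = paste0(idstem, seq_len(k)),
                 alt = "T", stringsAsFactors = FALSE)
    }
    if (scenario == "recessive") {
      spiked <- mkSpike(1, "0/1", "0/1", "1/1", "SPIKE_REC")
    } else if (scenario == "dominant") {
      spiked <- mkSpike(1, "0/0", "0/0", "0/1", "SPIKE_DOM")
    } else if (scenario == "comphet") {
      spiked <- mkSpike(2, c("0/1", "0/0"), c("0/0", "0/1"),
                        c("0/1", "0/1"), "SPIKE_CH")
    }
    if (!is.null(spiked)) tab <- rbind(tab, spiked)
    tab <- tab[order(match(tab$chrom, names(cl)), tab$pos), ]

    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vcfPath <- file.path(dir, paste0(prefix, ".vcf"))
    pedPath <- file.path(dir, paste0(prefix, ".ped"))
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(cl),
                     as.integer(unname(cl))),
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%s\tGT\t%s\t%s\t%s",
                    tab$chrom, tab$pos, tab$id, tab$ref, tab$alt,
                    format(tab$af, trim = TRUE, scientific = FALSE,
                           digits = 6),
                    tab$gt_father, tab$gt_mother, tab$gt_proband)
    writeLines(c(hdr, body), vcfPath)
    ped <- c("FAM1\tFATHER\t0\t0\t1\t1",
             "FAM1\tMOTHER\t0\t0\t2\t1",
             "FAM1\tPROBAND\tFATHER\tMOTHER\t1\t2")
    writeLines(ped, pedPath)
    list(vcf = vcfPath, ped = pedPath, samples = samples,
         spiked = if (is.null(spiked)) NULL else
           spiked[, c("chrom", "pos", "id")])
  })
}
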