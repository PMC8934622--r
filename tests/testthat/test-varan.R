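mkConfig <- function(...) levelConfig(score_thresholds = c(ncER = 0.5), ...)

test_that("classifyLevel implements the nested four-level criteria", {
  cfg <- mkConfig()
  # rare variant in a region, nothing else -> level 1
  expect_equal(classifyLevel(0.005, TRUE, config = cfg), 1L)
  # + DNase hit, scores below thresholds -> level 2
  expect_equal(classifyLevel(0.005, TRUE, feHits = "DNase",
                             scoreValues = c(ncER = 0.1), config = cfg), 2L)
  # + score above its threshold -> level 3
  expect_equal(classifyLevel(0.005, TRUE, feHits = "TFBS",
                             scoreValues = c(ncER = 0.9), config = cfg), 3L)
  # + constraint 0.75 >= 0.7 -> level 4
  expect_equal(classifyLevel(0.005, TRUE, feHits = "TFBS",
                             scoreValues = c(ncER = 0.9),
                             maxConstraint = 0.75, config = cfg), 4L)
  # AF gate is strict: AF exactly 0.01 fails
  expect_equal(classifyLevel(0.01, TRUE, config = cfg), 0L)
  # constraint gate is inclusive: exactly 0.7 passes
  expect_equal(classifyLevel(0.005, TRUE, "TFBS", c(ncER = 0.9), 0.7, cfg),
               4L)
  # no region -> 0 regardless
  expect_equal(classifyLevel(0.001, FALSE, "TFBS", c(ncER = 0.9), 1, cfg), 0L)
  # missing AF: rare by default, strict mode fails it
  expect_equal(classifyLevel(NA, TRUE, config = cfg), 1L)
  strict <- levelConfig(score_thresholds = c(ncER = 0.5),
                        missing_af = "strict")
  expect_equal(classifyLevel(NA, TRUE, config = strict), 0L)
})

test_that("annotateVcf attaches regions, scores and per-allele levels", {
  db <- oneRegionDb(start = 5001, end = 6000, constraint = 0.8)
  vcfPath <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1",
                          c(5500, 50000), af = c(0.005, 0.005))
  v <- annotateVcf(vcfPath, db, config = mkConfig())
  ii <- info(v)
  expect_equal(as.character(ii$RV_ID[[1]]), "RDB000001")
  expect_equal(ii$RV_CONSTRAINT[1], 0.8)
  expect_equal(ii$RV_LEVEL[[1]], 1L)
  expect_true("G0001:direct" %in% ii$RV_GENES[[1]])
  # SNV overlapping nothing: empty annotation, level 0
  expect_equal(length(ii$RV_ID[[2]]), 0)
  expect_equal(ii$RV_LEVEL[[2]], 0L)
})

test_that("deletions span multiple regions and take the max constraint", {
  gm <- tinyGenome()
  gr <- c(tinyRegions("chr1", 1000, 1004, "enhancer"),
          tinyRegions("chr1", 1006, 1010, "promoter"))
  db <- buildDatabase(gr, gm)
  mc <- mcols(regions(db)); mc$constraint <- c(0.3, 0.9)
  gr2 <- regions(db); mcols(gr2) <- mc
  methods::slot(db, "regions") <- gr2
  # 10-bp deletion REF spanning 1000..1009 covers both regions
  vcfPath <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", 1000,
                          ref = paste(rep("A", 10), collapse = ""),
                          alt = "A", af = 0.001)
  v <- annotateVcf(vcfPath, db, config = mkConfig())
  ii <- info(v)
  expect_setequal(as.character(ii$RV_ID[[1]]), c("RDB000001", "RDB000002"))
  expect_equal(ii$RV_CONSTRAINT[1], 0.9)
})

test_that("indel score lookup is the max over affected positions, insertions use flanks", {
  db <- oneRegionDb(start = 1001, end = 2000)
  tracks <- list(ncER = data.frame(chrom = "chr1", pos = c(1500, 1501, 1502),
                                   score = c(0.2, 0.9, 0.4)))
  # deletion affecting 1500-1502
  del <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", 1500, ref = "AAA",
                      alt = "A", af = 0.001)
  v <- annotateVcf(del, db, scoreTracks = tracks, config = mkConfig())
  expect_equal(as.character(info(v)$RV_SCORES[[1]]), "ncER:0.9")
  # insertion at 1500: flanking positions 1500 and 1501
  ins <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", 1500, ref = "A",
                      alt = "ATTT", af = 0.001)
  v2 <- annotateVcf(ins, db, scoreTracks = tracks, config = mkConfig())
  expect_equal(as.character(info(v2)$RV_SCORES[[1]]), "ncER:0.9")
})

test_that("structural variants get regions and genes but no level", {
  db <- standardDb()
  gr <- regions(db)
  # symbolic deletion spanning a large window
  s <- 1000; e <- 101000
  del <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", s, ref = "N",
                      alt = "<DEL>", info = sprintf("SVTYPE=DEL;END=%d", e),
                      contigs = c(chr1 = 2e5, chr2 = 2e5))
  v <- annotateVcf(del, db)
  ii <- info(v)
  onSpan <- which(as.character(seqnames(gr)) == "chr1" &
                  start(gr) <= e & end(gr) >= s)
  expect_setequal(as.character(ii$RV_ID[[1]]),
                  mcols(gr)$region_id[onSpan])
  expect_equal(length(ii$RV_LEVEL[[1]]), 0)   # no level for SVs
  gl <- as.data.frame(geneLinks(db))
  expGenes <- sort(unique(paste(gl$gene_id, gl$evidence, sep = ":")
                          [gl$region_id %in% mcols(gr)$region_id[onSpan]]))
  expect_equal(sort(as.character(ii$RV_GENES[[1]])), expGenes)

  # missing END and SVLEN on a non-BND SV: skipped and counted
  bad <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", 5000, ref = "N",
                      alt = "<DUP>", info = "SVTYPE=DUP",
                      contigs = c(chr1 = 2e5, chr2 = 2e5))
  v2 <- annotateVcf(bad, db)
  expect_equal(S4Vectors::metadata(v2)$RV_skipped, 1)
  expect_equal(length(info(v2)$RV_ID[[1]]), 0)

  # breakends are annotated at the breakend position only
  bndPos <- start(gr)[1] + 1
  bnd <- writeTestVcf(tempfile(fileext = ".vcf"),
                      as.character(seqnames(gr))[1], bndPos, ref = "N",
                      alt = "N]chr2:3000]", info = "SVTYPE=BND",
                      contigs = c(chr1 = 2e5, chr2 = 2e5))
  v3 <- annotateVcf(bnd, db)
  expect_true(mcols(gr)$region_id[1] %in%
              as.character(info(v3)$RV_ID[[1]]))
})

test_that("consequence updates append only missing regulatory genes", {
  ann <- "T|missense_variant|MODERATE|GENEA|x|y"
  expect_equal(updateConsequence(ann, "GENEA"), ann)
  upd <- updateConsequence(ann, c("GENEA", "GENEB"))
  expect_match(upd, "^T\\|missense_variant")
  expect_match(upd, "regulatory_region_variant\\|MODIFIER\\|GENEB")
  expect_equal(length(strsplit(upd, ",")[[1]]), 2)
  # no existing field: create one listing all genes
  fresh <- updateConsequence(NA, c("G1", "G2"))
  expect_equal(length(strsplit(fresh, ",")[[1]]), 2)
  # BCSQ dialect
  expect_equal(updateConsequence("missense|GENEA", "GENEA",
                                 format = "BCSQ"), "missense|GENEA")
  expect_warning(updateConsequence("noseparators", "G1"), "unparseable")
})

test_that("genes of interest are flagged by set intersection", {
  expect_true(tagGenesOfInterest(c("G1", "G2"), "G1"))
  expect_false(tagGenesOfInterest(c("G1", "G2"), "G3"))
  expect_false(tagGenesOfInterest(character(0), "G1"))
  db <- oneRegionDb()
  vcfPath <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", 5500,
                          af = 0.001)
  v <- annotateVcf(vcfPath, db, genesOfInterest = "G0001")
  expect_true(info(v)$RV_VOI[1])
  v2 <- annotateVcf(vcfPath, db, genesOfInterest = "ZZZ")
  expect_false(info(v2)$RV_VOI[1])
})

test_that("level sets are nested and annotation preserves the VCF", {
  cfg <- simConfig(seed = 19, variantCount = 400,
                   chromLengths = c(chr1 = 2e5, chr2 = 2e5))
  db <- standardDb()
  gm <- genomeModel(db)
  fe <- simFunctionalElements(cfg, gm)
  tracks <- list(ncER = simScoreTrack(cfg, gm, 0.5, 1),
                 ReMM = simScoreTrack(cfg, gm, 0.5, 2))
  trio <- simTrioVcf(cfg, gm, "null", dir = tempdir(), prefix = "nest")
  conf <- levelConfig(score_thresholds = c(ncER = 0.8, ReMM = 0.8))
  out <- tempfile(fileext = ".vcf")
  v <- annotateVcf(trio$vcf, db, fe, tracks, conf, out = out)

  lev <- vapply(info(v)$RV_LEVEL, max, integer(1))
  counts <- vapply(1:4, function(k) sum(lev >= k), integer(1))
  expect_true(all(diff(counts) <= 0))
  # levels nest: every level-k variant satisfies all lower criteria
  ii <- info(v)
  expect_true(all(lengths(ii$RV_ID[lev >= 1]) > 0))
  expect_true(all(lengths(ii$RV_FE[lev >= 2]) > 0))

  # record count and genotypes identical; header declares all RV_* fields
  vin <- readVcf(trio$vcf); vout <- readVcf(out)
  expect_equal(nrow(vout), nrow(vin))
  expect_identical(geno(vout)$GT, geno(vin)$GT)
  expect_true(all(c("RV_ID", "RV_TYPE", "RV_CONSTRAINT", "RV_GENES",
                    "RV_CLOSEST", "RV_DIST", "RV_FE", "RV_SCORES",
                    "RV_LEVEL", "RV_VOI", "RV_AFMISS") %in%
                  rownames(info(header(vout)))))

  # idempotence: re-annotating the annotated file replaces RV_* fields
  v2 <- annotateVcf(out, db, fe, tracks, conf)
  expect_equal(as.list(info(v2)$RV_ID), as.list(info(v)$RV_ID))
  expect_equal(vapply(info(v2)$RV_LEVEL, max, integer(1)), lev)
  expect_equal(sum(grepl("RV_LEVEL", rownames(info(header(v2))))), 1)
})

test_that("a variant built for level k is retrieved at exactly level k", {
  db <- standardDb()
  gm <- genomeModel(db)
  gr <- regions(db)
  fe <- simFunctionalElements(simConfig(seed = 77,
                                        chromLengths = chromLengths(gm)), gm)
  # find a position inside a region AND a TFBS
  ov <- findOverlaps(gr, fe$TFBS)
  stopifnot(length(ov) > 0)
  ri <- queryHits(ov)[1]; ti <- subjectHits(ov)[1]
  p <- max(start(gr)[ri], start(fe$TFBS)[ti])
  chrom <- as.character(seqnames(gr))[ri]
  # constraint high for level 4
  mc <- mcols(gr); mc$constraint <- 0.95; mcols(gr) <- mc
  methods::slot(db, "regions") <- gr
  conf <- levelConfig(score_thresholds = c(ncER = 0.5))
  tracks <- list(ncER = data.frame(chrom = chrom, pos = p, score = 0.9))

  spikeFor <- function(level) {
    # degrade evidence stepwise
    feUse <- fe; trUse <- tracks; dbUse <- db
    if (level < 4) {
      mc$constraint <- NA_real_; mcols(gr) <- mc
      methods::slot(dbUse, "regions") <- gr
    }
    if (level < 3) trUse <- list()
    if (level < 2) feUse <- list()
    vcfPath <- writeTestVcf(tempfile(fileext = ".vcf"), chrom, p,
                            af = 0.001, contigs = chromLengths(gm))
    v <- annotateVcf(vcfPath, dbUse, feUse, trUse, conf)
    max(info(v)$RV_LEVEL[[1]])
  }
  for (k in 1:4) expect_equal(spikeFor(k), k)
})
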