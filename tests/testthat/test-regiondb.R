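test_that("normalizeSource converts coordinate conventions and rejects bad records", {
  raw <- data.frame(chrom = c("chr1", "chr1", "chrUn", "chr1"),
                    start = c(101, 300, 10, 500),
                    end = c(200, 250, 20, 600),
                    type = c("Enhancer", "promoter", "enhancer", "mystery"))
  gr <- normalizeSource(raw, "srcA",
                        columns = c(chrom = "chrom", start = "start",
                                    end = "end", type = "type"),
                        coords = "one_based", genome = tinyGenome())
  # 1-based record (101, 200) spans internal coordinates [100, 200) half-open
  expect_equal(start(gr)[1], 101)
  expect_equal(end(gr)[1], 200)
  expect_equal(width(gr)[1], 100)
  expect_equal(mcols(gr)$region_type[1], "enhancer")
  expect_true(all(mcols(gr)$sources == "srcA"))
  rej <- S4Vectors::metadata(gr)$rejected
  expect_setequal(rej$reason,
                  c("non-positive span", "unmappable region type",
                    "unknown chromosome"))
  expect_equal(sum(rej$count), 3)
  expect_equal(length(gr), 1)

  # BED-dialect input shifts start by one
  grb <- normalizeSource(data.frame(chrom = "chr1", start = 100, end = 200,
                                    type = "enhancer"),
                         "srcB", coords = "bed")
  expect_equal(c(start(grb), end(grb)), c(101, 200))

  expect_error(
    normalizeSource(data.frame(chrom = "chr1", begin = 1, end = 2,
                               type = "enhancer"), "srcC"),
    "missing mandatory column")
})

test_that("regions from multiple sources keep their provenance", {
  grs <- lapply(1:3, function(k)
    tinyRegions("chr1", c(1000, 3000) + 5000 * k, c(1500, 3500) + 5000 * k,
                "enhancer", source = paste0("src", k)))
  gr <- do.call(c, grs)
  expect_equal(length(gr), 6)
  expect_equal(sort(unique(mcols(gr)$sources)), paste0("src", 1:3))
})

test_that("collapseRegions merges by reciprocal overlap with set-union provenance", {
  # (0,100) and (10,110) in 0-based half-open: overlap 90, RO = 0.9 >= 0.8
  a <- tinyRegions("chr1", 1, 100, "enhancer", source = "A")
  b <- tinyRegions("chr1", 11, 110, "enhancer", source = "B")
  out <- collapseRegions(c(a, b), 0.8)
  expect_equal(length(out), 1)
  expect_equal(c(start(out), end(out)), c(1, 110))
  expect_equal(mcols(out)$sources, "A,B")

  # just below threshold: untouched
  out2 <- collapseRegions(c(a, b), 0.95)
  expect_equal(length(out2), 2)

  # different types are never merged, even at identical coordinates
  enh <- tinyRegions("chr1", 1000, 2000, "enhancer")
  pro <- tinyRegions("chr1", 1000, 2000, "promoter")
  both <- collapseRegions(c(enh, pro), 0.8)
  expect_equal(length(both), 2)
  expect_setequal(mcols(both)$region_type, c("enhancer", "promoter"))

  # disjoint regions unchanged
  dis <- tinyRegions("chr1", c(100, 5000), c(200, 6000), "silencer")
  expect_equal(length(collapseRegions(dis, 0.5)), 2)
})

test_that("collapse is idempotent and never loses covered bases or gains regions", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 80
    st <- sample.int(5e4, n)
    gr <- tinyRegions("chr1", st, st + sample(50:500, n, replace = TRUE),
                      sample(c("enhancer", "promoter"), n, replace = TRUE))
    c1 <- collapseRegions(gr, 0.8)
    c2 <- collapseRegions(c1, 0.8)
    expect_equal(length(c2), length(c1))
    expect_equal(start(c2), start(c1))
    expect_equal(end(c2), end(c1))
    expect_lte(length(c1), length(gr))
    for (ty in unique(mcols(gr)$region_type)) {
      covIn <- sum(width(reduce(gr[mcols(gr)$region_type == ty])))
      covOut <- sum(width(reduce(c1[mcols(c1)$region_type == ty])))
      expect_gte(covOut, covIn)
    }
  }
})

test_that("assignClosest matches containment, tie-break and brute force", {
  gm <- tinyGenome()
  genes <- geneModelTable(c("A", "B"), "chr1", c(10000, 14000),
                          c(11000, 15000), c("+", "+"))
  # region inside gene body -> distance 0
  inside <- assignClosest(tinyRegions("chr1", 10200, 10300, "promoter"),
                          genes)
  expect_equal(mcols(inside)$closest_gene, "A")
  expect_equal(mcols(inside)$closest_gene_dist, 0L)

  # equidistant (1 kb gap each side) -> lexicographically smaller gene
  tie <- assignClosest(tinyRegions("chr1", 12001, 12999, "promoter"), genes)
  expect_equal(mcols(tie)$closest_gene, "A")

  # brute-force oracle over random gene sets
  for (seed in 1:20) {
    set.seed(seed)
    gs <- sort(sample.int(9e4, 20))
    ge <- gs + sample(100:2000, 20, replace = TRUE)
    ids <- sprintf("G%02d", sample(99, 20))
    gtab <- geneModelTable(ids, "chr1", gs, ge,
                           sample(c("+", "-"), 20, replace = TRUE))
    rs <- sample.int(9e4, 1); re <- rs + 500
    got <- assignClosest(tinyRegions("chr1", rs, re, "enhancer"), gtab)
    exp <- bfClosestGene(rs, re, gs, ge, ids)
    expect_equal(mcols(got)$closest_gene, exp$gene)
    expect_equal(mcols(got)$closest_gene_dist, as.integer(exp$dist))
    # closest TSS by midpoint against direct scan
    mid <- rs + floor((re - rs) / 2)
    dd <- abs(mid - gtab$tss)
    ord <- order(dd, gtab$gene_id)
    expect_equal(mcols(got)$closest_tss_gene, gtab$gene_id[ord[1]])
    expect_equal(mcols(got)$closest_tss_dist, as.integer(dd[ord[1]]))
  }

  expect_warning(assignClosest(tinyRegions("chr1", 1, 10, "enhancer"),
                               geneModelTable(character(0), character(0),
                                              integer(0), integer(0),
                                              character(0))),
                 "no gene models")
})

test_that("database round-trips through SQLite and answers queries", {
  db <- standardDb()
  path <- tempfile(fileext = ".sqlite")
  writeDatabase(db, path)
  db2 <- readDatabase(path)
  expect_equal(as.data.frame(mcols(regions(db))),
               as.data.frame(mcols(regions(db2))))
  expect_equal(start(regions(db)), start(regions(db2)))
  expect_equal(as.data.frame(geneLinks(db)), as.data.frame(geneLinks(db2)))
  expect_equal(as.data.frame(phenotypeLinks(db)),
               as.data.frame(phenotypeLinks(db2)))
  expect_equal(chromLengths(genomeModel(db)), chromLengths(genomeModel(db2)))

  # self-retrieval by a region's own interval
  r1 <- regions(db)[1]
  got <- queryDetails(db, interval = sprintf("%s:%d-%d",
                                             seqnames(r1), start(r1),
                                             end(r1)))
  expect_true(mcols(r1)$region_id %in% got$records$region_id)

  # gene query equals the link table
  gl <- as.data.frame(geneLinks(db))
  g <- gl$gene_id[1]
  got <- queryDetails(db, gene = g)
  expect_setequal(got$records$region_id,
                  unique(gl$region_id[gl$gene_id == g]))

  # unknown region id reported, not fatal
  got <- queryDetails(db, ids = c(mcols(r1)$region_id, "RDB999999"))
  expect_equal(got$notFound, "RDB999999")
  expect_equal(nrow(got$records), 1)

  # interval overlapping nothing
  empty <- queryDetails(db, interval = GRanges("chr2", IRanges(1, 2)))
  expect_equal(nrow(empty$records), 0)
})

test_that("dangling links abort the build with the offending ids", {
  gr <- tinyRegions("chr1", 1000, 2000, "enhancer")
  expect_error(
    buildDatabase(gr, tinyGenome(),
                  geneLinks = data.frame(region_id = "RDBnope",
                                         gene_id = "G1",
                                         evidence = "eqtl")),
    "RDBnope")
  # empty phenotype table is fine and phenotype queries return empty
  db <- buildDatabase(gr, tinyGenome())
  expect_equal(nrow(phenotypeLinks(db)), 0)
  rec <- queryDetails(db, ids = mcols(regions(db))$region_id)$records
  expect_equal(rec$phenotypes, "")
})

test_that("extended BED export is lossless and byte-stable", {
  db <- standardDb()
  b1 <- tempfile(); b2 <- tempfile()
  exportBed(db, b1)
  gr <- importBed(b1)
  exportBed(gr, b2)
  expect_identical(readLines(b1), readLines(b2))
  # half-open convention and missing constraint as "."
  one <- oneRegionDb(start = 101, end = 200)
  f <- tempfile(); exportBed(one, f)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(fields[2:3]), c(100L, 200L))
  expect_equal(fields[5], ".")
  # coverage identical computed from store and from the exported BED
  expect_equal(genomeCoverage(db),
               genomeCoverage(importBed(b1), genomeModel(db)))
})

test_that("interval queries equal a brute-force linear scan", {
  db <- standardDb()
  gr <- regions(db)
  rs <- start(gr); re <- end(gr)
  onChr1 <- as.character(seqnames(gr)) == "chr1"
  set.seed(99)
  for (k in 1:25) {
    qs <- sample.int(2e5, 1); qe <- qs + sample.int(5e3, 1)
    got <- queryDetails(db, interval = GRanges("chr1", IRanges(qs, qe)))
    exp_idx <- intersect(bfIntervalQuery(rs, re, qs, qe), which(onChr1))
    expect_setequal(got$records$region_id,
                    mcols(gr)$region_id[exp_idx])
  }
})

test_that("VCF selectors equal the union of per-variant interval queries", {
  db <- standardDb()
  set.seed(3)
  pos <- sample.int(19e4, 30)
  vcfPath <- writeTestVcf(tempfile(fileext = ".vcf"), "chr1", sort(pos),
                          contigs = c(chr1 = 2e5, chr2 = 2e5))
  got <- queryDetails(db, vcf = vcfPath)
  perVariant <- unique(unlist(lapply(pos, function(p)
    queryDetails(db, interval = GRanges("chr1",
                                        IRanges(p, p)))$records$region_id)))
  expect_setequal(got$records$region_id, perVariant)
})
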