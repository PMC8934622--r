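#' @importFrom GenomicRanges findOverlaps pintersect reduce distanceToNearest
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom IRanges overlapsAny
NULL

## --- set columns: sets of labels are carried as sorted, comma-joined strings

packSet <- function(x) {
  vapply(x, function(v) {
    v <- unique(v[!is.na(v) & nzchar(v) & v != "."])
    if (!length(v)) "" else paste(sort(v), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

unpackSet <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s) || s == ".") character(0)
    else strsplit(s, ",", fixed = TRUE)[[1]]
  })
}

unionSets <- function(x) {
  packSet(list(unlist(unpackSet(x), use.names = FALSE)))
}

emptyRegionMcols <- function(n) {
  S4Vectors::DataFrame(
    region_id = rep(NA_character_, n), region_type = rep(NA_character_, n),
    sources = rep("", n), methods = rep("", n), tissues = rep("", n),
    direct_genes = rep("", n),
    closest_gene = rep(NA_character_, n),
    closest_gene_dist = rep(NA_integer_, n),
    closest_tss_gene = rep(NA_character_, n),
    closest_tss_dist = rep(NA_integer_, n),
    constraint = rep(NA_real_, n))
}

#' Normalize a raw region table into regulatory regions
#'
#' Converts one heterogeneous source table (with a declared column mapping
#' and coordinate convention) into a GRanges of regulatory regions in the
#' package's internal representation, attaching the source name to every
#' region. Records with an unknown chromosome, a non-positive span, or a
#' region type that cannot be mapped onto the five-type vocabulary
#' (bivalent, enhancer, insulator, promoter, silencer) are dropped and
#' counted in the attached rejection report.
#'
#' @param raw data.frame with at least chromosome, start, end and type
#'   columns.
#' @param source single source name attached to all regions.
#' @param columns named character vector mapping the roles
#'   \code{chrom,start,end,type} (optionally \code{gene,tissue,method}) to
#'   column names of \code{raw}.
#' @param coords coordinate convention of the table: \code{"bed"}
#'   (0-based half-open) or \code{"one_based"} (1-based inclusive).
#' @param typeMap named character vector mapping raw type labels
#'   (case-insensitive) to the vocabulary; by default raw labels are
#'   lower-cased and matched directly.
#' @param genome optional \linkS4class{GenomeModel}; when supplied, records
#'   on chromosomes absent from it are rejected.
#' @return GRanges (1-based closed) with region metadata columns; the
#'   rejection report is in \code{metadata(.)$rejected}, a data.frame of
#'   reason/count.
#' @export
normalizeSource <- function(raw, source,
                            columns = c(chrom = "chrom", start = "start",
                                        end = "end", type = "type"),
                            coords = c("bed", "one_based"),
                            typeMap = NULL, genome = NULL) {
  coords <- match.arg(coords)
  mandatory <- c("chrom", "start", "end", "type")
  if (!all(mandatory %in% names(columns)))
    stop("column mapping must define: ", paste(mandatory, collapse = ", "))
  missing_cols <- setdiff(unname(columns[mandatory]), colnames(raw))
  if (length(missing_cols))
    stop("source '", source, "' rejected: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "))

  chrom <- as.character(raw[[columns[["chrom"]]]])
  start <- as.numeric(raw[[columns[["start"]]]])
  end <- as.numeric(raw[[columns[["end"]]]])
  rawtype <- tolower(as.character(raw[[columns[["type"]]]]))
  type <- if (is.null(typeMap)) rawtype else {
    names(typeMap) <- tolower(names(typeMap))
    unname(typeMap[rawtype])
  }

  # to 1-based closed
  if (coords == "bed") start <- start + 1

  reasons <- rep(NA_character_, nrow(raw))
  bad_span <- !is.finite(start) | !is.finite(end) | end < start
  reasons[bad_span] <- "non-positive span"
  bad_type <- is.na(type) | !(type %in% REGION_TYPES)
  reasons[is.na(reasons) & bad_type] <- "unmappable region type"
  if (!is.null(genome)) {
    bad_chrom <- !(chrom %in% names(chromLengths(genome)))
    reasons[is.na(reasons) & bad_chrom] <- "unknown chromosome"
  }
  keep <- is.na(reasons)

  gr <- GenomicRanges::GRanges(chrom[keep],
                               IRanges::IRanges(start[keep], end[keep]))
  mc <- emptyRegionMcols(sum(keep))
  mc$region_type <- type[keep]
  mc$sources <- rep(source, sum(keep))
  grab <- function(role) {
    if (role %in% names(columns) && columns[[role]] %in% colnames(raw))
      packSet(as.list(as.character(raw[[columns[[role]]]][keep])))
    else rep("", sum(keep))
  }
  mc$direct_genes <- grab("gene")
  mc$tissues <- grab("tissue")
  mc$methods <- grab("method")
  GenomicRanges::mcols(gr) <- mc

  rej <- table(reasons[!keep])
  S4Vectors::metadata(gr)$rejected <-
    data.frame(reason = names(rej), count = as.integer(rej),
               stringsAsFactors = FALSE)
  gr
}

reciprocalOverlap <- function(gr) {
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
  if (!length(hits)) return(cbind(i = integer(0), j = integer(0), ro = numeric(0)))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[i], gr[j]))
  ro <- pmin(ov / GenomicRanges::width(gr[i]), ov / GenomicRanges::width(gr[j]))
  cbind(i = i, j = j, ro = ro)
}

#' Collapse redundant regions of the same type
#'
#' Regions of identical type whose reciprocal overlap
#' (min(overlap/len_A, overlap/len_B)) reaches the threshold are merged into
#' their union span; provenance columns (sources, methods, tissues, direct
#' genes) become set unions. Merging is transitive via connected components
#' and is iterated until a fixed point, so the operation is idempotent.
#' Regions of different types are never merged, even at identical
#' coordinates.
#'
#' @param gr GRanges from \code{\link{normalizeSource}} (possibly
#'   concatenated across sources).
#' @param threshold reciprocal-overlap fraction in (0, 1]; default 0.8.
#' @return collapsed GRanges with merged provenance.
#' @export
collapseRegions <- function(gr, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!length(gr)) return(gr)
  mc <- GenomicRanges::mcols(gr)
  out <- lapply(split(seq_along(gr), mc$region_type), function(idx) {
    sub <- gr[idx]
    repeat {
      pairs <- reciprocalOverlap(sub)
      pairs <- pairs[pairs[, "ro"] >= threshold, , drop = FALSE]
      if (!nrow(pairs)) break
      # union-find over qualifying pairs
      parent <- seq_along(sub)
      find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(as.integer(pairs[k, "i"]))
        rb <- find(as.integer(pairs[k, "j"]))
        if (ra != rb) parent[ra] <- rb
      }
      comp <- vapply(seq_along(sub), find, integer(1))
      smc <- GenomicRanges::mcols(sub)
      st0 <- GenomicRanges::start(sub); en0 <- GenomicRanges::end(sub)
      chr0 <- as.character(GenomicRanges::seqnames(sub))
      byComp <- unname(split(seq_along(sub), comp))
      first <- vapply(byComp, `[`, integer(1), 1)
      st <- vapply(byComp, function(m) min(st0[m]), integer(1))
      en <- vapply(byComp, function(m) max(en0[m]), integer(1))
      nm <- emptyRegionMcols(length(byComp))
      nm$region_type <- smc$region_type[first]
      for (col in c("sources", "methods", "tissues", "direct_genes")) {
        v <- smc[[col]]
        nm[[col]] <- vapply(byComp, function(m)
          if (length(m) == 1) v[m] else unionSets(v[m]), character(1))
      }
      cons0 <- smc$constraint
      nm$constraint <- vapply(byComp, function(m) {
        cv <- cons0[m]
        if (all(is.na(cv))) NA_real_ else max(cv, na.rm = TRUE)
      }, numeric(1))
      sub <- GenomicRanges::GRanges(chr0[first], IRanges::IRanges(st, en))
      GenomicRanges::mcols(sub) <- nm
    }
    sub
  })
  res <- do.call(c, unname(out))
  res <- GenomicRanges::sort(res, ignore.strand = TRUE)
  S4Vectors::metadata(res) <- S4Vectors::metadata(gr)
  res
}

#' Build a gene-model table
#'
#' @param gene_id,chrom,start,end,strand,biotype vectors describing genes;
#'   coordinates 1-based closed. The TSS is the strand-dependent end:
#'   \code{start} on '+', \code{end} on '-'.
#' @return DataFrame of gene models with a computed \code{tss} column.
#' @export
geneModelTable <- function(gene_id, chrom, start, end, strand,
                           biotype = "protein_coding") {
  stopifnot(all(strand %in% c("+", "-")), all(end >= start))
  S4Vectors::DataFrame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    tss = as.integer(ifelse(strand == "+", start, end)),
    biotype = rep_len(as.character(biotype), length(gene_id)))
}

#' Assign closest gene and closest TSS to each region
#'
#' The closest gene minimizes the gap distance between the region span and
#' the gene span (0 when they overlap); the closest TSS minimizes the
#' distance between the region midpoint and the gene's transcription start
#' site. Ties are broken toward the lexicographically smaller gene id.
#' Regions on chromosomes without genes keep undefined fields (with a
#' warning).
#'
#' @param gr region GRanges.
#' @param genes DataFrame from \code{\link{geneModelTable}}.
#' @return \code{gr} with closest_gene/closest_gene_dist and
#'   closest_tss_gene/closest_tss_dist metadata filled.
#' @export
assignClosest <- function(gr, genes) {
  if (!length(gr)) return(gr)
  mc <- GenomicRanges::mcols(gr)
  if (is.null(genes) || nrow(genes) == 0) {
    warning("no gene models supplied; closest fields left undefined")
    return(gr)
  }
  # gap distance region-to-gene per chromosome (0 when overlapping), with
  # lexicographic gene-id tie-break; midpoint-to-TSS for the closest TSS
  rs <- GenomicRanges::start(gr); re <- GenomicRanges::end(gr)
  mid <- rs + floor((re - rs) / 2)
  rchrom <- as.character(GenomicRanges::seqnames(gr))
  for (ch in unique(rchrom)) {
    gsel <- which(genes$chrom == ch)
    if (!length(gsel)) next
    gsel <- gsel[order(genes$gene_id[gsel])]  # lexicographic tie-break
    rsel <- which(rchrom == ch)
    gap <- pmax(outer(rs[rsel], genes$end[gsel], "-") - 1,
                outer(-re[rsel], -genes$start[gsel], "-") - 1, 0)
    best <- max.col(-gap, ties.method = "first")
    mc$closest_gene[rsel] <- genes$gene_id[gsel[best]]
    mc$closest_gene_dist[rsel] <-
      as.integer(gap[cbind(seq_along(rsel), best)])
    dd <- abs(outer(mid[rsel], genes$tss[gsel], "-"))
    best <- max.col(-dd, ties.method = "first")
    mc$closest_tss_gene[rsel] <- genes$gene_id[gsel[best]]
    mc$closest_tss_dist[rsel] <- as.integer(dd[cbind(seq_along(rsel), best)])
  }
  if (any(is.na(mc$closest_gene)))
    warning(sum(is.na(mc$closest_gene)),
            " region(s) on chromosomes without genes; closest fields undefined")
  GenomicRanges::mcols(gr) <- mc
  gr
}

#' Assemble a RegulatoryDB
#'
#' Assigns stable region ids (sorted genomic order), derives gene links from
#' the regions' own annotations (evidence classes \code{direct},
#' \code{closest_gene}, \code{closest_tss}) and merges user-supplied link
#' tables (e.g. eQTL-based links and phenotype links computed upstream).
#' Supplied links referencing unknown region ids abort the build.
#'
#' @param gr region GRanges (after collapsing and closest assignment).
#' @param genome \linkS4class{GenomeModel}.
#' @param genes optional DataFrame from \code{\link{geneModelTable}}; when
#'   given and closest fields are unset, \code{\link{assignClosest}} is run.
#' @param geneLinks optional data.frame/DataFrame (region_id, gene_id,
#'   evidence, tissues) of pre-computed links; region_id may also be given
#'   as the integer index of the region in \code{gr}.
#' @param phenoLinks optional data.frame/DataFrame (region_id, phenotype,
#'   provenance).
#' @param path optional file path; when supplied the database is also
#'   serialized to SQLite via \code{\link{writeDatabase}}.
#' @return A \linkS4class{RegulatoryDB}.
#' @export
buildDatabase <- function(gr, genome, genes = NULL, geneLinks = NULL,
                          phenoLinks = NULL, path = NULL) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  mc <- GenomicRanges::mcols(gr)
  mc$region_id <- sprintf("RDB%06d", seq_along(gr))
  GenomicRanges::mcols(gr) <- mc
  if (!is.null(genes) && all(is.na(mc$closest_gene))) {
    gr <- assignClosest(gr, genes)
    mc <- GenomicRanges::mcols(gr)
  }
  if (is.null(genes)) genes <- geneModelTable(character(0), character(0),
                                              integer(0), integer(0),
                                              character(0))
  resolveIds <- function(tab) {
    if (is.numeric(tab$region_id)) mc$region_id[tab$region_id]
    else as.character(tab$region_id)
  }
  links <- list()
  dg <- unpackSet(mc$direct_genes)
  n_direct <- lengths(dg)
  if (any(n_direct > 0))
    links[[length(links) + 1L]] <- data.frame(
      region_id = rep(mc$region_id, n_direct),
      gene_id = unlist(dg, use.names = FALSE),
      evidence = "direct", tissues = rep(mc$tissues, n_direct),
      stringsAsFactors = FALSE)
  for (ev in c("closest_gene", "closest_tss")) {
    col <- if (ev == "closest_gene") mc$closest_gene else mc$closest_tss_gene
    ok <- !is.na(col)
    if (any(ok))
      links[[length(links) + 1L]] <- data.frame(
        region_id = mc$region_id[ok], gene_id = col[ok], evidence = ev,
        tissues = "", stringsAsFactors = FALSE)
  }
  if (!is.null(geneLinks) && nrow(geneLinks)) {
    geneLinks <- as.data.frame(geneLinks)
    geneLinks$region_id <- resolveIds(geneLinks)
    bad <- setdiff(geneLinks$region_id, mc$region_id)
    if (length(bad))
      stop("gene links reference unknown region ids: ",
           paste(bad, collapse = ", "))
    if (is.null(geneLinks$tissues)) geneLinks$tissues <- ""
    links[[length(links) + 1L]] <-
      geneLinks[, c("region_id", "gene_id", "evidence", "tissues")]
  }
  gl <- if (length(links)) do.call(rbind, links) else
    data.frame(region_id = character(0), gene_id = character(0),
               evidence = character(0), tissues = character(0))
  gl <- gl[!duplicated(gl[, c("region_id", "gene_id", "evidence")]), ]
  gl <- gl[order(gl$region_id, gl$gene_id, gl$evidence), ]
  rownames(gl) <- NULL

  if (is.null(phenoLinks))
    phenoLinks <- data.frame(region_id = character(0),
                             phenotype = character(0),
                             provenance = character(0))
  phenoLinks <- as.data.frame(phenoLinks)
  if (nrow(phenoLinks)) {
    phenoLinks$region_id <- resolveIds(phenoLinks)
    bad <- setdiff(phenoLinks$region_id, mc$region_id)
    if (length(bad))
      stop("phenotype links reference unknown region ids: ",
           paste(bad, collapse = ", "))
    phenoLinks <- phenoLinks[order(phenoLinks$region_id,
                                   phenoLinks$phenotype), ]
    rownames(phenoLinks) <- NULL
  }

  db <- new("RegulatoryDB", regions = gr,
            geneLinks = S4Vectors::DataFrame(gl),
            phenoLinks = S4Vectors::DataFrame(phenoLinks),
            genes = genes, genome = genome)
  if (!is.null(path)) writeDatabase(db, path)
  db
}

## --- SQLite serialization ---------------------------------------------------

regionsAsTable <- function(db) {
  gr <- db@regions
  mc <- GenomicRanges::mcols(gr)
  data.frame(
    region_id = mc$region_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 0-based half-open on disk
    end = GenomicRanges::end(gr),
    region_type = mc$region_type, sources = mc$sources,
    methods = mc$methods, tissues = mc$tissues,
    direct_genes = mc$direct_genes,
    closest_gene = mc$closest_gene,
    closest_gene_dist = mc$closest_gene_dist,
    closest_tss_gene = mc$closest_tss_gene,
    closest_tss_dist = mc$closest_tss_dist,
    constraint = mc$constraint, stringsAsFactors = FALSE)
}

#' Serialize a RegulatoryDB to a single-file SQLite store
#'
#' Schema: tables \code{regions} (0-based half-open coordinates),
#' \code{gene_links}, \code{phenotype_links}, \code{genes},
#' \code{genome} and \code{excluded}. \code{\link{readDatabase}} inverts it
#' exactly.
#'
#' @param db a \linkS4class{RegulatoryDB}.
#' @param path file path for the SQLite database (overwritten).
#' @return \code{path}, invisibly.
#' @export
writeDatabase <- function(db, path) {
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbWriteTable(con, "regions", regionsAsTable(db))
  DBI::dbWriteTable(con, "gene_links", as.data.frame(db@geneLinks))
  DBI::dbWriteTable(con, "phenotype_links", as.data.frame(db@phenoLinks))
  DBI::dbWriteTable(con, "genes", as.data.frame(db@genes))
  cl <- chromLengths(db@genome)
  DBI::dbWriteTable(con, "genome",
                    data.frame(chrom = names(cl), length = unname(cl)))
  ex <- excludedRegions(db@genome)
  DBI::dbWriteTable(con, "excluded", data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L, end = GenomicRanges::end(ex)))
  DBI::dbExecute(con, "CREATE INDEX idx_regions ON regions(chrom, start, end)")
  DBI::dbExecute(con, "CREATE INDEX idx_links ON gene_links(gene_id)")
  invisible(path)
}

#' Load a RegulatoryDB from its SQLite store
#'
#' @param path SQLite file written by \code{\link{writeDatabase}}.
#' @return A \linkS4class{RegulatoryDB}.
#' @export
readDatabase <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  reg <- DBI::dbReadTable(con, "regions")
  gr <- GenomicRanges::GRanges(reg$chrom,
                               IRanges::IRanges(reg$start + 1L, reg$end))
  mc <- emptyRegionMcols(nrow(reg))
  for (col in colnames(mc)) mc[[col]] <- reg[[col]]
  mc$closest_gene_dist <- as.integer(mc$closest_gene_dist)
  mc$closest_tss_dist <- as.integer(mc$closest_tss_dist)
  GenomicRanges::mcols(gr) <- mc
  gen <- DBI::dbReadTable(con, "genome")
  ex <- DBI::dbReadTable(con, "excluded")
  gm <- GenomeModel(stats::setNames(gen$length, gen$chrom),
                    if (nrow(ex)) GenomicRanges::GRanges(
                      ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end))
                    else NULL)
  new("RegulatoryDB", regions = gr,
      geneLinks = S4Vectors::DataFrame(DBI::dbReadTable(con, "gene_links")),
      phenoLinks = S4Vectors::DataFrame(
        DBI::dbReadTable(con, "phenotype_links")),
      genes = S4Vectors::DataFrame(DBI::dbReadTable(con, "genes")),
      genome = gm)
}

## --- extended BED -----------------------------------------------------------

#' Export database regions as an extended BED file
#'
#' BED6+3: chrom, start, end (0-based half-open), region_id, constraint
#' (\code{"."} when unset), strand \code{"."}, then region_type, sources and
#' the direct-gene set. Sorted by chromosome then start;
#' \code{\link{importBed}} reads it back losslessly and
#' export-import-export is byte-identical.
#'
#' @param db a \linkS4class{RegulatoryDB} (or a GRanges carrying the same
#'   metadata columns).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
exportBed <- function(db, path) {
  gr <- if (is(db, "RegulatoryDB")) db@regions else db
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  mc <- GenomicRanges::mcols(gr)
  fmtNum <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                     scientific = FALSE))
  fmtSet <- function(x) ifelse(nzchar(x), x, ".")
  tab <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = mc$region_id,
    score = fmtNum(mc$constraint),
    strand = ".",
    type = mc$region_type,
    sources = fmtSet(mc$sources),
    genes = fmtSet(mc$direct_genes), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Import an extended BED written by \code{\link{exportBed}}
#'
#' @param path extended BED file.
#' @return GRanges with region_id, constraint, region_type, sources and
#'   direct_genes metadata.
#' @export
importBed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "integer",
                                          "character", "character",
                                          "character", "character",
                                          "character", "character"))
  gr <- GenomicRanges::GRanges(tab[[1]],
                               IRanges::IRanges(tab[[2]] + 1L, tab[[3]]))
  mc <- emptyRegionMcols(nrow(tab))
  mc$region_id <- tab[[4]]
  mc$constraint <- suppressWarnings(
    ifelse(tab[[5]] == ".", NA_real_, as.numeric(tab[[5]])))
  mc$region_type <- tab[[7]]
  mc$sources <- ifelse(tab[[8]] == ".", "", tab[[8]])
  mc$direct_genes <- ifelse(tab[[9]] == ".", "", tab[[9]])
  GenomicRanges::mcols(gr) <- mc
  gr
}

#' Read a plain feature BED (BED3+) as a GRanges
#'
#' Thin wrapper around \code{rtracklayer::import} for functional-element
#' tracks (TFBS, DNase clusters, UCNE, segmental duplications, ...).
#'
#' @param path BED file path.
#' @return GRanges (1-based closed, as usual in Bioconductor).
#' @export
readFeatureBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::granges(gr)
}

#' Fraction of the genome covered by region spans
#'
#' Union of region spans divided by total genome length.
#'
#' @param x a RegulatoryDB or GRanges.
#' @param genome GenomeModel (taken from \code{x} when it is a database).
#' @return numeric fraction in [0, 1].
#' @export
genomeCoverage <- function(x, genome = NULL) {
  gr <- if (is(x, "RegulatoryDB")) x@regions else x
  if (is.null(genome) && is(x, "RegulatoryDB")) genome <- x@genome
  sum(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))) /
    genomeLength(genome)
}

## --- queries ----------------------------------------------------------------

parseInterval <- function(s) {
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4) stop("malformed interval selector: ", s)
  GenomicRanges::GRanges(m[2], IRanges::IRanges(as.integer(m[3]),
                                                as.integer(m[4])))
}

regionDetails <- function(db, idx) {
  gr <- db@regions[idx]
  mc <- GenomicRanges::mcols(gr)
  gl <- as.data.frame(db@geneLinks)
  pl <- as.data.frame(db@phenoLinks)
  genesBy <- function(rid, ev) {
    g <- gl$gene_id[gl$region_id == rid & gl$evidence == ev]
    packSet(list(g))
  }
  data.frame(
    region_id = mc$region_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    region_type = mc$region_type, sources = mc$sources,
    methods = mc$methods, tissues = mc$tissues,
    constraint = mc$constraint,
    genes_direct = vapply(mc$region_id, genesBy, "", ev = "direct"),
    genes_closest_gene = vapply(mc$region_id, genesBy, "", ev = "closest_gene"),
    genes_closest_tss = vapply(mc$region_id, genesBy, "", ev = "closest_tss"),
    genes_eqtl = vapply(mc$region_id, genesBy, "", ev = "eqtl"),
    phenotypes = vapply(mc$region_id, function(rid)
      packSet(list(pl$phenotype[pl$region_id == rid])), ""),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Query the database for detailed region records
#'
#' Exactly one selector is used: a genomic interval (GRanges or
#' \code{"chr:start-end"} string, 1-based inclusive), a gene id (regions
#' linked by any evidence class), a vector of region ids, or a VCF file
#' whose variant positions select overlapping regions.
#'
#' @param db a \linkS4class{RegulatoryDB}.
#' @param interval,gene,ids,vcf selectors (supply one).
#' @return list with \code{records} (one detail row per matching region,
#'   including tissues, sources, genes by evidence class, phenotypes and
#'   constraint) and \code{notFound} (unknown region ids, never fatal).
#' @export
queryDetails <- function(db, interval = NULL, gene = NULL, ids = NULL,
                         vcf = NULL) {
  mc <- GenomicRanges::mcols(db@regions)
  notFound <- character(0)
  if (!is.null(interval)) {
    if (is.character(interval)) interval <- parseInterval(interval)
    idx <- which(IRanges::overlapsAny(db@regions, interval,
                                      ignore.strand = TRUE))
  } else if (!is.null(gene)) {
    gl <- as.data.frame(db@geneLinks)
    rid <- unique(gl$region_id[gl$gene_id %in% gene])
    idx <- which(mc$region_id %in% rid)
  } else if (!is.null(ids)) {
    notFound <- setdiff(ids, mc$region_id)
    idx <- which(mc$region_id %in% ids)
  } else if (!is.null(vcf)) {
    v <- VariantAnnotation::readVcf(vcf)
    idx <- which(IRanges::overlapsAny(db@regions,
                                      SummarizedExperiment::rowRanges(v),
                                      ignore.strand = TRUE))
  } else {
    stop("supply one selector: interval, gene, ids or vcf")
  }
  list(records = regionDetails(db, idx), notFound = notFound)
}
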