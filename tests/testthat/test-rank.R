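# guide scoring, ranking, bidirectional assignment, multiplex selection

promoterOf <- function(chrom = "chr1", start, end) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$bidirectional <- FALSE
  gr
}

nfrOf <- function(start, end, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

test_that("a guide in an NFR, inside the activation window and genome-unique scores cleanly", {
  gene <- makeGene("chr1", 5001, 6000, "+", chromLength = 10000)  # tss0 = 5000
  prom <- promoterOf(start = 4400, end = 5000)
  # spacer centre 100 bp upstream: center0 = 4900 -> start0 4890, 1-based 4891
  site <- makeSite("chr1", 4891)
  nfrs <- nfrOf(4501, 4990)
  sc <- scoreGuide(site, prom, gene, nfrs,
                   report = list(counts = c("0" = 0L, "1" = 0L, "2" = 0L)))
  expect_equal(sc$tss_distance, 100)
  expect_equal(sc$nfr_component, 1)
  expect_equal(sc$distance_component, 1)
  expect_false(sc$crispri_flag)
  expect_equal(sc$offtarget_component, 1)
  expect_equal(sc$total, 1)
})

test_that("a spacer overlapping the TSS raises the CRISPRi flag and zeroes the total", {
  gene <- makeGene("chr1", 5001, 6000, "+", chromLength = 10000)
  prom <- promoterOf(start = 4400, end = 5020)
  site <- makeSite("chr1", 4995)  # spans the TSS at 5001
  sc <- scoreGuide(site, prom, gene, nfrOf(4401, 5010))
  expect_true(sc$crispri_flag)
  expect_equal(sc$total, 0)
})

test_that("NFR membership is the fraction of spacer bases inside NFRs", {
  gene <- makeGene("chr1", 5001, 6000, "+", chromLength = 10000)
  prom <- promoterOf(start = 4400, end = 5000)
  site <- makeSite("chr1", 4891)  # spacer 4891-4910
  expect_equal(scoreGuide(site, prom, gene, nfrOf(3000, 3100))$nfr_component, 0)
  expect_equal(scoreGuide(site, prom, gene, nfrOf(4891, 4900))$nfr_component, 0.5)
  expect_equal(scoreGuide(site, prom, gene,
                          GenomicRanges::GRanges())$nfr_component, 0)
})

test_that("scoring errors when the site lies outside the promoter", {
  gene <- makeGene("chr1", 5001, 6000, "+", chromLength = 10000)
  prom <- promoterOf(start = 4400, end = 5000)
  expect_error(scoreGuide(makeSite("chr1", 3000), prom, gene,
                          GenomicRanges::GRanges()), "outside")
})

test_that("distance component is monotone in windowMax and off-target burden never helps", {
  gene <- makeGene("chr1", 5001, 6000, "+", chromLength = 10000)
  prom <- promoterOf(start = 4200, end = 5000)
  site <- makeSite("chr1", 4691)  # 300 bp upstream
  nfrs <- nfrOf(4201, 5000)
  for (wmax in c(210, 260, 310, 360)) {
    cfg <- rankingConfig(windowMax = wmax)
    sc <- scoreGuide(site, prom, gene, nfrs, config = cfg)
    if (wmax > 210) {
      prev <- scoreGuide(site, prom, gene, nfrs,
                         config = rankingConfig(windowMax = wmax - 50))
      expect_gte(sc$distance_component, prev$distance_component)
    }
  }
  offs <- vapply(0:5, function(k)
    scoreGuide(site, prom, gene, nfrs,
               report = list(counts = c("0" = 0L, "1" = k)))$offtarget_component,
    numeric(1))
  expect_true(all(diff(offs) < 0))
})

test_that("rankGuides orders by the documented key and matches the oracle sort", {
  base <- data.frame(
    gene_id = "g", chrom = "chr1", strand = "+", spacer = "X", pam = "NGG",
    nfr_component = 1, distance_component = 1, crispri_flag = FALSE,
    offtarget_component = 1, preferred = TRUE, stringsAsFactors = FALSE)
  two <- rbind(cbind(base, start = 100L, end = 119L, tss_distance = 50, total = 0.9),
               cbind(base, start = 200L, end = 219L, tss_distance = 60, total = 0.5))
  r <- rankGuides(two)
  expect_equal(r$total, c(0.9, 0.5))

  tie <- rbind(cbind(base, start = 100L, end = 119L, tss_distance = 150, total = 0.7),
               cbind(base, start = 200L, end = 219L, tss_distance = 100, total = 0.7))
  expect_equal(rankGuides(tie)$tss_distance, c(100, 150))

  set.seed(401)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    sc <- do.call(rbind, lapply(seq_len(n), function(j)
      cbind(base[, setdiff(names(base), "strand")],
            strand = sample(c("+", "-"), 1),
            start = sample(1:500, 1), end = 520L,
            tss_distance = sample(c(-50:400), 1),
            total = sample(c(0.2, 0.5, 0.5, 0.9), 1))))
    got <- rankGuides(sc)
    want <- sc[oracleRankOrder(sc), ]
    expect_equal(got$start, want$start)
    expect_equal(got$total, want$total)
  }
})

test_that("ranking identical inputs is byte-deterministic", {
  set.seed(402)
  base <- data.frame(
    gene_id = "g", chrom = "chr1", strand = "+", spacer = "X", pam = "NGG",
    nfr_component = 1, distance_component = 1, crispri_flag = FALSE,
    offtarget_component = 1, preferred = TRUE, stringsAsFactors = FALSE)
  sc <- do.call(rbind, lapply(1:8, function(j)
    cbind(base, start = sample(1:500, 1), end = 520L,
          tss_distance = sample(1:300, 1), total = runif(1))))
  f1 <- tempfile(); f2 <- tempfile()
  writeRankedGuides(rankGuides(sc), f1)
  writeRankedGuides(rankGuides(sc), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("assignBidirectional scores both flanking genes and labels a primary", {
  genes <- c(makeGene("chr1", 1001, 2000, "-", id = "gl", chromLength = 20000),
             makeGene("chr1", 2305, 3300, "+", id = "gr", chromLength = 20000))
  prom <- detectBidirectional(genes, maxGap = 600)
  nfrs <- nfrOf(2001, 2304)
  # spacer centre 100 bp from the left TSS (2000): center0 = 2099 -> start 2090
  site <- makeSite("chr1", 2090)
  sc <- assignBidirectional(site, prom, genes, nfrs)
  expect_identical(nrow(sc), 2L)
  expect_identical(sum(sc$primary), 1L)
  expect_equal(sc$tss_distance[sc$gene_id == "gl"], 100)
  expect_equal(sc$tss_distance[sc$gene_id == "gr"], 205)
  # both in window and NFR: equal totals, tie falls to the smaller distance
  expect_true(sc$primary[sc$gene_id == "gl"])

  # inside one gene's exclusion zone only
  siteNear <- makeSite("chr1", 2010)  # within 30 bp of left TSS
  scn <- assignBidirectional(siteNear, prom, genes, nfrs)
  expect_equal(scn$total[scn$gene_id == "gl"], 0)
  expect_gt(scn$total[scn$gene_id == "gr"], 0)

  notBid <- promoterOf(start = 2001, end = 2304)
  expect_error(assignBidirectional(site, notBid, genes, nfrs), "bidirectional")
})

test_that("selectMultiplex is greedy in rank order and matches the exhaustive oracle", {
  mkRanked <- function(starts, totals) {
    df <- data.frame(start = starts, end = starts + 19L, total = totals)
    df <- df[order(-df$total), ]
    rownames(df) <- NULL
    cbind(rank = seq_len(nrow(df)), df)
  }
  r1 <- mkRanked(c(100, 200, 300, 400), c(0.9, 0.8, 0.7, 0.6))
  expect_warning(one <- selectMultiplex(r1, 1), "single-guide")
  expect_identical(nrow(one$guides), 1L)
  expect_equal(one$guides$total, 0.9)

  all4 <- selectMultiplex(r1, 4)
  expect_identical(nrow(all4$guides), 4L)
  expect_equal(all4$combined, sum(r1$total))

  set.seed(403)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    ranked <- mkRanked(sample(seq(100, 400, by = 10), n), runif(n))
    k <- sample(2:4, 1)
    minSp <- sample(c(30, 60, 100), 1)
    got <- suppressWarnings(selectMultiplex(ranked, k, minSpacing = minSp))
    centers <- (ranked$start - 1) + 10
    want <- oracleMultiplex(centers, k, minSp)
    expect_identical(got$guides$rank, ranked$rank[want])
    # feasibility invariant
    selC <- (got$guides$start - 1) + 10
    if (nrow(got$guides) > 1)
      expect_true(all(dist(selC) >= minSp))
  }
})

test_that("NFR condition sets combine by intersection (default) or union", {
  a <- nfrOf(c(100, 500), c(200, 600))
  b <- nfrOf(c(150, 800), c(250, 900))
  inter <- combineNfrConditions(a, b)
  expect_identical(GenomicRanges::start(inter), 150L)
  expect_identical(GenomicRanges::end(inter), 200L)
  uni <- combineNfrConditions(a, b, mode = "union")
  expect_identical(length(uni), 3L)
})
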