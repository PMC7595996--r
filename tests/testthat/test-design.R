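# protospacer enumeration and off-target vetting

regionOf <- function(genome, chrom = "chr1", start = 1,
                     end = Biostrings::width(genome)[1]) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

test_that("scanProtospacers finds constructed single sites on either strand", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("A", 20), "TGG")))
  s <- scanProtospacers(regionOf(g), g)
  expect_length(s, 1L)
  expect_identical(as.character(GenomicRanges::strand(s)), "+")
  expect_identical(s$spacer, strrep("A", 20))
  expect_identical(s$pam, "TGG")
  expect_identical(GenomicRanges::start(s), 1L)

  gm <- Biostrings::DNAStringSet(c(chr1 = paste0("CCA", strrep("T", 20))))
  sm <- scanProtospacers(regionOf(gm), gm)
  expect_length(sm, 1L)
  expect_identical(as.character(GenomicRanges::strand(sm)), "-")
  expect_identical(sm$spacer, strrep("A", 20))
  expect_identical(sm$pam, "TGG")
})

test_that("spacers containing N are excluded and short regions warn", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0("AAAAANAAAAAAAAAAAAAA", "TGG")))
  expect_length(scanProtospacers(regionOf(g), g), 0L)
  g2 <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 60)))
  expect_warning(out <- scanProtospacers(regionOf(g2, end = 20), g2), "shorter")
  expect_length(out, 0L)
})

test_that("scanProtospacers matches the per-offset oracle on random sequences", {
  set.seed(301)
  for (i in 1:100) {
    seq <- randomDna(300)
    g <- Biostrings::DNAStringSet(c(chr1 = seq))
    got <- scanProtospacers(regionOf(g), g)
    want <- oracleScan(seq)
    expect_identical(length(got), nrow(want))
    if (nrow(want)) {
      expect_identical(GenomicRanges::start(got), as.integer(want$start))
      expect_identical(as.character(GenomicRanges::strand(got)), want$strand)
      expect_identical(got$spacer, want$spacer)
      expect_identical(got$pam, want$pam)
    }
  }
})

test_that("site sequence/coordinate invariants hold against the genome string", {
  set.seed(302)
  seq <- randomDna(2000)
  g <- Biostrings::DNAStringSet(c(chr1 = seq))
  sites <- scanProtospacers(regionOf(g), g)
  expect_gt(length(sites), 20)
  for (i in seq_along(sites)) {
    s <- sites[i]
    sub <- substr(seq, GenomicRanges::start(s), GenomicRanges::end(s))
    if (as.character(GenomicRanges::strand(s)) == "+") {
      expect_identical(sub, s$spacer)
      expect_identical(s$pam_start, GenomicRanges::end(s) + 1L)
    } else {
      expect_identical(sub, revComp(s$spacer))
      expect_identical(s$pam_end, GenomicRanges::start(s) - 1L)
    }
    expect_match(s$pam, "^[ACGT]GG$")
  }
})

test_that("designing on the reverse-complemented genome mirrors the site set", {
  set.seed(303)
  seq <- randomDna(400)
  g <- Biostrings::DNAStringSet(c(chr1 = seq))
  grc <- Biostrings::DNAStringSet(c(chr1 = revComp(seq)))
  a <- scanProtospacers(regionOf(g), g)
  b <- scanProtospacers(regionOf(grc), grc)
  expect_identical(sort(a$spacer), sort(b$spacer))
  L <- nchar(seq)
  mirroredStarts <- sort(L - GenomicRanges::end(a) + 1L)
  expect_identical(sort(GenomicRanges::start(b)), mirroredStarts)
  # strands flip 1-to-1
  expect_identical(sum(GenomicRanges::strand(a) == "+"),
                   sum(GenomicRanges::strand(b) == "-"))
})

test_that("countOfftargets tallies planted duplicates and unique sites", {
  spacer <- "GATTACAGATTACAGGATTC"
  filler1 <- randomDna(50)
  filler2 <- randomDna(50)
  seq <- paste0(filler1, spacer, "TGG", filler2, spacer, "AGG", filler1)
  g <- Biostrings::DNAStringSet(c(chr1 = seq))
  region <- regionOf(g, start = 51, end = 73)  # the first planted copy
  sites <- scanProtospacers(region, g)
  site <- sites[sites$spacer == spacer][1]
  rep_ <- countOfftargets(site, g, maxMismatches = 0)
  expect_identical(unname(rep_$counts[["0"]]), 1L)  # the other copy only
  expect_identical(rep_$examples$start[1], 124L)

  set.seed(304)
  g2 <- Biostrings::DNAStringSet(c(chr1 = randomDna(2000)))
  s2 <- scanProtospacers(regionOf(g2), g2)[1]
  rep2 <- countOfftargets(s2, g2, maxMismatches = 0)
  expect_identical(unname(rep2$counts[["0"]]), 0L)
})

test_that("off-target counts match the exhaustive Hamming oracle", {
  set.seed(305)
  for (i in 1:100) {
    nChrom <- sample(1:2, 1)
    gs <- setNames(lapply(seq_len(nChrom), function(j) randomDna(600)),
                   paste0("chr", seq_len(nChrom)))
    g <- Biostrings::DNAStringSet(unlist(gs))
    sites <- scanProtospacers(regionOf(g), g)
    if (!length(sites)) next
    k <- sample(length(sites), 1)
    site <- sites[k]
    requirePam <- i %% 4 != 0
    got <- countOfftargets(site, g, maxMismatches = 3, requirePam = requirePam)
    want <- oracleOfftargets(
      site$spacer, gs, 3, requirePam,
      site = list(chrom = as.character(GenomicRanges::seqnames(site)),
                  strand = as.character(GenomicRanges::strand(site)),
                  start = GenomicRanges::start(site)))
    expect_identical(got$counts, want)
  }
})

test_that("off-target symmetry: counting at a duplicate locus equals the direct spacer distance", {
  set.seed(306)
  spacerA <- randomDna(20)
  spacerB <- paste0(substr(spacerA, 1, 17), revComp(substr(spacerA, 18, 20)))
  seq <- paste0(randomDna(30), spacerA, "TGG", randomDna(30), spacerB, "CGG",
                randomDna(30))
  g <- Biostrings::DNAStringSet(c(chr1 = seq))
  sites <- scanProtospacers(regionOf(g), g)
  sa <- sites[sites$spacer == spacerA][1]
  d <- oracleHamming(spacerA, spacerB)
  rep_ <- countOfftargets(sa, g, maxMismatches = 19)
  expect_gte(unname(rep_$counts[[as.character(d)]]), 1L)
})

test_that("maxMismatches above the spacer length is a configuration error", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("A", 20), "TGG")))
  s <- scanProtospacers(regionOf(g), g)
  expect_error(countOfftargets(s[1], g, maxMismatches = 21), "spacer length")
})

test_that("filterCandidates applies the per-tier ceilings in order", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("A", 20), "TGG")))
  sites <- rep(scanProtospacers(regionOf(g), g), 10)
  set.seed(307)
  reports <- lapply(1:10, function(i)
    list(counts = setNames(sample(0:2, 4, replace = TRUE),
                           as.character(0:3))))
  got <- filterCandidates(sites, reports, maxTier0 = 0, maxTier1 = 0,
                          maxTier2 = 1)
  manual <- vapply(reports, function(r)
    r$counts[["0"]] <= 0 && r$counts[["1"]] <= 0 && r$counts[["2"]] <= 1,
    logical(1))
  expect_identical(length(got), sum(manual))
  # unique site retained, exact duplicate removed under the default ceilings
  keep <- filterCandidates(sites[1], list(list(counts = c("0" = 0L, "1" = 0L))))
  expect_length(keep, 1L)
  drop <- filterCandidates(sites[1], list(list(counts = c("0" = 1L, "1" = 0L))))
  expect_length(drop, 0L)
})

test_that("candidate tables round-trip through TSV", {
  set.seed(308)
  g <- Biostrings::DNAStringSet(c(chr1 = randomDna(500)))
  sites <- scanProtospacers(regionOf(g), g)
  reports <- countOfftargetsAll(sites, g, maxMismatches = 2)
  tsv <- tempfile(fileext = ".tsv")
  writeCandidates(sites, reports, tsv)
  back <- readCandidates(tsv)
  expect_identical(length(back), length(sites))
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(sites))
  expect_identical(back$spacer, sites$spacer)
  expect_identical(back$mm0,
                   vapply(reports, function(r) unname(r$counts[["0"]]), 1L))
})
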