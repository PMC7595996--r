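# fragment reading and occupancy profiles

test_that("coverageProfile matches the definition and a brute-force oracle", {
  # single fragment [10, 20) in BED terms = 1-based [11, 20]
  fs <- makeFragments(11, 20, chromLength = 50)
  p <- coverageProfile(fs, "chr1", 50)
  expect_equal(profileValues(p)[11:20], rep(1, 10))
  expect_equal(sum(profileValues(p)), 10)

  # additivity on the overlap
  fs2 <- makeFragments(c(11, 16), c(20, 25), chromLength = 50)
  expect_equal(profileValues(coverageProfile(fs2, "chr1", 50))[16:20], rep(2, 5))

  # 100 random fragment sets against the per-base oracle
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    s <- sample(1:1800, n, replace = TRUE)
    e <- pmin(s + sample(99:199, n, replace = TRUE), 2000)
    fs <- makeFragments(s, e, chromLength = 2000)
    expect_equal(profileValues(coverageProfile(fs, "chr1", 2000)),
                 oracleCoverage(s, e, 2000))
  }
})

test_that("coverage mass equals total fragment length; dyad mass equals fragment count", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    s <- sample(1:1800, n, replace = TRUE)
    e <- pmin(s + sample(99:199, n, replace = TRUE), 2000)
    fs <- makeFragments(s, e, chromLength = 2000)
    expect_identical(sum(profileValues(coverageProfile(fs, "chr1", 2000))),
                     sum(e - s + 1))
    expect_identical(sum(profileValues(dyadDensity(fs, "chr1", 2000))),
                     as.numeric(n))
  }
})

test_that("dyadDensity places midpoints by the floor rule and matches the oracle", {
  # fragment [100, 250) in BED terms -> 0-based midpoint 174 (1-based 175)
  fs <- makeFragments(101, 250, chromLength = 400)
  v <- profileValues(dyadDensity(fs, "chr1", 400))
  expect_equal(which(v == 1), 175L)

  # even-length fragment [10, 12) -> 0-based midpoint 10 (1-based 11)
  fs2 <- makeFragments(11, 12, chromLength = 20)
  expect_equal(which(profileValues(dyadDensity(fs2, "chr1", 20)) == 1), 11L)

  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:150, 1)
    s <- sample(1:1800, n, replace = TRUE)
    e <- pmin(s + sample(99:199, n, replace = TRUE), 2000)
    fs <- makeFragments(s, e, chromLength = 2000)
    expect_equal(profileValues(dyadDensity(fs, "chr1", 2000)),
                 oracleDyadDensity(s, e, 2000))
  }
})

test_that("profiles mirror when fragment coordinates are reverse-complemented", {
  set.seed(12)
  L <- 1500L
  s <- sample(1:1300, 50, replace = TRUE)
  e <- pmin(s + sample(99:199, 50, replace = TRUE), L)
  fwd <- coverageProfile(makeFragments(s, e, chromLength = L), "chr1", L)
  rev_ <- coverageProfile(makeFragments(L - e + 1L, L - s + 1L, chromLength = L),
                          "chr1", L)
  expect_equal(profileValues(rev_), rev(profileValues(fwd)))
})

test_that("smoothProfile: identity at bandwidth 0, constant fixed point, closed-form kernel", {
  fs <- makeFragments(c(101, 301), c(250, 450), chromLength = 1000)
  p <- coverageProfile(fs, "chr1", 1000)
  expect_identical(profileValues(smoothProfile(p, 0)), profileValues(p))

  flat <- methods::new("OccupancyProfile", chrom = "chr1",
                       values = rep(3.5, 800), mode = "coverage", bandwidth = 0)
  expect_equal(profileValues(smoothProfile(flat, 25)), rep(3.5, 800),
               tolerance = 1e-9)

  # single interior impulse reproduces the normalised Gaussian exactly
  imp <- methods::new("OccupancyProfile", chrom = "chr1",
                      values = replace(numeric(1001), 501, 1),
                      mode = "coverage", bandwidth = 0)
  sm <- smoothProfile(imp, 20)
  h <- ceiling(4 * 20)
  kern <- dnorm(seq(-h, h), sd = 20); kern <- kern / sum(kern)
  expect_equal(profileValues(sm)[(501 - h):(501 + h)], kern, tolerance = 1e-12)
  # interior mass conserved within 0.1%
  expect_lt(abs(sum(profileValues(sm)) - 1), 1e-3)
  expect_equal(profileBandwidth(sm), 20)
})

test_that("readFragments handles BED, applies the length filter and counts drops", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t250", "chr1\t10\t100", "chr1\t500\t590"), bed)
  fs <- readFragments(bed, lengthRange = c(100, 200))
  gr <- fragmentRanges(fs)
  # "chr1 100 250" -> 1-based [101, 250]; the 90-bp fragments are dropped
  expect_length(gr, 1L)
  expect_identical(GenomicRanges::start(gr), 101L)
  expect_identical(GenomicRanges::end(gr), 250L)
  expect_identical(fragmentsDropped(fs), 2L)
})

test_that("paired-end SAM fragments round-trip through writeFragmentsSam/readFragments", {
  locus <- simulateLocus(seed = 21, length = 8000, nGenes = 2)
  fr <- simulateFragments(locus, 4, seed = 21)
  sam <- tempfile(fileext = ".sam")
  writeFragmentsSam(fr, locusGenome(locus), sam)
  back <- readFragments(sam, genome = locusGenome(locus))
  expect_identical(GenomicRanges::ranges(fragmentRanges(back)),
                   GenomicRanges::ranges(fragmentRanges(fr)))
  expect_identical(back@source, "paired-end")
})

test_that("unpaired SAM input fails with advice to use BED", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000",
               sprintf("r1\t0\tchr1\t100\t60\t50M\t*\t0\t0\t%s\t%s",
                       strrep("A", 50), strrep("I", 50))), sam)
  expect_error(readFragments(sam), "BED")
})

test_that("bedGraph output round-trips a profile", {
  fs <- makeFragments(c(101, 301, 320), c(250, 450, 460), chromLength = 1000)
  p <- coverageProfile(fs, "chr1", 1000)
  bg <- tempfile(fileext = ".bedGraph")
  writeProfileBedGraph(p, bg)
  back <- readProfileBedGraph(bg)
  expect_equal(profileValues(back), profileValues(p))
  expect_identical(profileChrom(back), "chr1")
})
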