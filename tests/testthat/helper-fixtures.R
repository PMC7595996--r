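# small in-code fixtures shared across test files

writeFasta <- function(records, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  for (nm in names(records)) writeLines(c(paste0(">", nm), records[[nm]]), con)
  close(con)
  path
}

writeGff3 <- function(rows, path = tempfile(fileext = ".gff3")) {
  # rows: data.frame(seqid, start, end, strand, id) in 1-based GFF3 terms
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(rows)))
    writeLines(sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       rows$seqid[i], rows$start[i], rows$end[i],
                       rows$strand[i], rows$id[i]), con)
  close(con)
  path
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# a FragmentSet built directly from interval vectors (1-based inclusive)
makeFragments <- function(starts, ends, chrom = "chr1", chromLength = NA) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  if (!is.na(chromLength)) {
    GenomeInfoDb::seqlevels(gr) <- chrom
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(chromLength, chrom)
  }
  methods::new("FragmentSet", fragments = gr, source = "bed", dropped = 0L)
}

# a bare protospacer site GRanges row without scanning (for score tiling)
makeSite <- function(chrom, start, strand = "+", spacer = strrep("A", 20),
                     pam = "AGG") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, width = nchar(spacer)),
                         strand = strand, spacer = spacer, pam = pam,
                         pam_start = if (strand == "+") start + nchar(spacer)
                                     else start - 3L,
                         pam_end = if (strand == "+") start + nchar(spacer) + 2L
                                   else start - 1L)
}

makeGene <- function(chrom, start, end, strand, id = "g1", chromLength = NA,
                     tss = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand, gene_id = id,
                               tss = as.integer(
                                 if (is.null(tss)) ifelse(strand == "+", start, end)
                                 else tss))
  if (!is.na(chromLength)) {
    GenomeInfoDb::seqlevels(gr) <- chrom
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(chromLength, chrom)
  }
  gr
}

# run the full simulate -> profile -> smooth -> dyad-call -> NFR pipeline on
# one synthetic world and score recovery of the planted NFRs
nfrRecovery <- function(seed, fragmentsPerNucleosome = 30, borderTol = 20,
                        minTruthWidth = 80) {
  locus <- simulateLocus(seed = seed, length = 40000, nGenes = 8)
  frags <- simulateFragments(locus, fragmentsPerNucleosome, seed = seed)
  prof <- smoothProfile(coverageProfile(frags, "chr1", 40000), 20)
  called <- delineateNfrs(callDyads(prof), offset = 75, minWidth = 20)
  truth <- truthNfrs(locus)
  truth <- truth[GenomicRanges::width(truth) >= minTruthWidth]
  hit <- vapply(seq_along(truth), function(j) {
    errs <- pmax(abs(GenomicRanges::start(called) - GenomicRanges::start(truth[j])),
                 abs(GenomicRanges::end(called) - GenomicRanges::end(truth[j])))
    length(errs) && min(errs) <= borderTol
  }, logical(1))
  list(n = length(truth), recovered = sum(hit))
}

# a synthetic smoothed-looking profile: Gaussian bumps on a flat floor
bumpProfile <- function(len, centers, height = 10, sd = 30, chrom = "chr1") {
  x <- numeric(len)
  for (c0 in centers) x <- x + height * exp(-((seq_len(len) - c0)^2) / (2 * sd^2))
  methods::new("OccupancyProfile", chrom = chrom, values = x,
               mode = "coverage", bandwidth = 20)
}
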