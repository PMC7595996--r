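# MNase-seq fragment handling and per-base occupancy profiles

#' Read MNase-seq fragments from SAM/BAM or BED
#'
#' Reconstructs sequenced fragments from paired-end alignments (one fragment
#' per properly paired read pair, spanning from the leftmost mate's start over
#' the absolute template length) or takes explicit intervals from a BED file.
#' Fragments outside `lengthRange` -- the mononucleosome window around the
#' ~147 bp of nucleosome-protected DNA -- are discarded and counted.
#' Secondary, supplementary and unmapped records are skipped.
#'
#' @param path Path to a `.sam`, `.bam` or `.bed` file.
#' @param lengthRange Two-element numeric, inclusive fragment-length window in
#'   bp (default `c(100, 200)`).
#' @param genome Optional genome ([loadGenome()]); when given, `seqlengths`
#'   are attached and out-of-bounds fragments are an error.
#' @param extendTo For BED input holding single-end 5' read positions instead
#'   of full fragments: extend every interval to this fixed length from its 5'
#'   end (strand-aware; default `NULL` = intervals are full fragments).
#' @return A [FragmentSet-class].
#' @export
readFragments <- function(path, lengthRange = c(100L, 200L), genome = NULL,
                          extendTo = NULL) {
  if (!file.exists(path)) stop("fragment file not found: ", path)
  stopifnot(length(lengthRange) == 2L, lengthRange[1] <= lengthRange[2])
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    src <- "bed"
    if (!is.null(extendTo)) {
      str <- as.character(GenomicRanges::strand(gr))
      s <- ifelse(str == "-", GenomicRanges::end(gr) - extendTo + 1L,
                  GenomicRanges::start(gr))
      gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                   IRanges::IRanges(pmax(s, 1L), width = extendTo))
      src <- "single-end-extended"
    }
  } else if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam")
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("rname", "pos", "isize", "flag"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE))
    rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
    paired <- bitwAnd(rec$flag, 1L) == 1L
    if (!any(paired))
      stop("no paired records in ", path,
           "; for single-end data supply fragment intervals as BED instead")
    keep <- paired & !is.na(rec$isize) & rec$isize > 0L & !is.na(rec$pos)
    gr <- GenomicRanges::GRanges(as.character(rec$rname[keep]),
                                 IRanges::IRanges(rec$pos[keep],
                                                  width = rec$isize[keep]))
    src <- "paired-end"
  } else {
    stop("unrecognised fragment file extension: .", ext,
         " (expected .sam, .bam or .bed)")
  }
  GenomicRanges::strand(gr) <- "*"
  S4Vectors::mcols(gr) <- NULL
  inRange <- GenomicRanges::width(gr) >= lengthRange[1] &
    GenomicRanges::width(gr) <= lengthRange[2]
  dropped <- sum(!inRange)
  gr <- gr[inRange]
  if (!is.null(genome)) {
    sl <- Biostrings::width(genome)
    names(sl) <- names(genome)
    GenomeInfoDb::seqlevels(gr) <- union(names(genome),
                                         GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr)[names(sl)] <- sl
  }
  methods::new("FragmentSet", fragments = gr, source = src,
               dropped = as.integer(dropped))
}

# coerce FragmentSet / GRanges input to a per-chromosome GRanges
.fragGr <- function(fragments, chrom) {
  gr <- if (methods::is(fragments, "FragmentSet")) fragmentRanges(fragments)
        else fragments
  gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
}

#' Fragment-coverage occupancy profile
#'
#' The nucleosome occupancy representation used throughout the package:
#' `values[i]` is the number of fragments overlapping base `i` (coverage per
#' base pair).
#'
#' @param fragments A [FragmentSet-class] or fragment `GRanges`.
#' @param chrom Chromosome name.
#' @param chromLength Chromosome length in bp.
#' @return An [OccupancyProfile-class] with `mode = "coverage"`.
#' @export
coverageProfile <- function(fragments, chrom, chromLength) {
  .assertScalarNum(chromLength, "chromLength", 1)
  gr <- .fragGr(fragments, chrom)
  if (length(gr) && any(GenomicRanges::end(gr) > chromLength))
    stop("fragments extend past chromosome length on ", chrom)
  cov <- IRanges::coverage(IRanges::ranges(gr), width = chromLength)
  methods::new("OccupancyProfile", chrom = chrom, values = as.numeric(cov),
               mode = "coverage", bandwidth = 0)
}

#' Fragment-midpoint (dyad-density) occupancy profile
#'
#' Alternative occupancy estimator: `values[i]` counts fragments whose
#' midpoint falls on base `i`. The midpoint of a fragment occupying 1-based
#' bases `[s, e]` is `floor((s + e) / 2)` (for even-length fragments the
#' left-of-centre base).
#'
#' @inheritParams coverageProfile
#' @return An [OccupancyProfile-class] with `mode = "dyad-density"`.
#' @export
dyadDensity <- function(fragments, chrom, chromLength) {
  .assertScalarNum(chromLength, "chromLength", 1)
  gr <- .fragGr(fragments, chrom)
  if (length(gr) && any(GenomicRanges::end(gr) > chromLength))
    stop("fragments extend past chromosome length on ", chrom)
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
  vals <- numeric(chromLength)
  if (length(mid)) {
    tab <- tabulate(mid, nbins = chromLength)
    vals <- as.numeric(tab)
  }
  methods::new("OccupancyProfile", chrom = chrom, values = vals,
               mode = "dyad-density", bandwidth = 0)
}

#' Gaussian smoothing of an occupancy profile
#'
#' Convolves the profile with a normalised Gaussian kernel of standard
#' deviation `bandwidth` bp (truncated at 4 standard deviations). Near the
#' chromosome ends the kernel is truncated and renormalised, so a constant
#' profile is a fixed point and total signal away from the edges is conserved.
#' A bandwidth of 0 returns the profile unchanged.
#'
#' @param profile An [OccupancyProfile-class].
#' @param bandwidth Kernel standard deviation in bp (>= 0; default 20, narrow
#'   enough to resolve dyads of adjacent nucleosomes >= 147 bp apart).
#' @return A smoothed [OccupancyProfile-class] with `bandwidth` recorded.
#' @export
smoothProfile <- function(profile, bandwidth = 20) {
  .assertScalarNum(bandwidth, "bandwidth", 0)
  if (bandwidth == 0) return(profile)
  x <- profileValues(profile)
  h <- as.integer(ceiling(4 * bandwidth))
  k <- stats::dnorm(seq(-h, h), sd = bandwidth)
  k <- k / sum(k)
  n <- length(x)
  padded <- c(numeric(h), x, numeric(h))
  num <- stats::filter(padded, k, sides = 2)[(h + 1L):(h + n)]
  den <- stats::filter(c(numeric(h), rep(1, n), numeric(h)), k,
                       sides = 2)[(h + 1L):(h + n)]
  methods::new("OccupancyProfile", chrom = profileChrom(profile),
               values = as.numeric(num / den), mode = profileMode(profile),
               bandwidth = bandwidth)
}

#' Scale a profile by its mean
#'
#' Optional depth normalisation for cross-condition display: divides every
#' value by the profile mean. Dyad calling uses relative prominence and is
#' insensitive to global scale, so this is never applied implicitly.
#'
#' @param profile An [OccupancyProfile-class].
#' @return The rescaled profile.
#' @export
meanScaleProfile <- function(profile) {
  m <- mean(profileValues(profile))
  if (m == 0) return(profile)
  methods::new("OccupancyProfile", chrom = profileChrom(profile),
               values = profileValues(profile) / m, mode = profileMode(profile),
               bandwidth = profileBandwidth(profile))
}

#' Write / read an occupancy profile as bedGraph
#'
#' `writeProfileBedGraph()` emits the profile as a 4-column bedGraph
#' (0-based half-open intervals, run-length collapsed, zero runs included so
#' the chromosome length round-trips). `readProfileBedGraph()` parses such a
#' file back into an [OccupancyProfile-class].
#'
#' @param profile An [OccupancyProfile-class].
#' @param path Output / input file path.
#' @param chromLength Optional chromosome length for reading; defaults to the
#'   largest interval end in the file.
#' @return `writeProfileBedGraph()` returns `path` invisibly;
#'   `readProfileBedGraph()` returns an [OccupancyProfile-class].
#' @export
writeProfileBedGraph <- function(profile, path) {
  r <- rle(profileValues(profile))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based half-open
  df <- data.frame(chrom = profileChrom(profile), start = starts, end = ends,
                   value = format(r$values, trim = TRUE, digits = 10,
                                  scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeProfileBedGraph
#' @export
readProfileBedGraph <- function(path, chromLength = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) stop("empty bedGraph: ", path)
  chrom <- as.character(GenomicRanges::seqnames(gr))[1L]
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  n <- if (is.null(chromLength)) max(GenomicRanges::end(gr)) else chromLength
  vals <- numeric(n)
  for (i in seq_along(gr))
    vals[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- gr$score[i]
  methods::new("OccupancyProfile", chrom = chrom, values = vals,
               mode = "coverage", bandwidth = 0)
}
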