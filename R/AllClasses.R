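#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- Rle runValue
#' @importFrom IRanges IRanges coverage
#' @importFrom GenomicRanges GRanges start end width strand seqnames
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom tools file_ext
#' @importFrom stats setNames
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Per-base nucleosome occupancy signal for one chromosome
#'
#' An `OccupancyProfile` holds one non-negative real value per base of a
#' chromosome. The signal is either fragment *coverage* (number of
#' mononucleosome-sized fragments overlapping each base, the representation
#' used for nucleosome maps derived from MNase-seq) or *dyad density*
#' (fragment-midpoint counts). A Gaussian smoothing bandwidth of 0 denotes a
#' raw, unsmoothed profile.
#'
#' @slot chrom Chromosome name.
#' @slot values Numeric vector, one value per base, all `>= 0`; its length is
#'   the chromosome length.
#' @slot mode Either `"coverage"` or `"dyad-density"`.
#' @slot bandwidth Gaussian smoothing bandwidth in bp (standard deviation);
#'   0 means unsmoothed.
#' @export
setClass("OccupancyProfile",
  representation(
    chrom = "character",
    values = "numeric",
    mode = "character",
    bandwidth = "numeric"
  ),
  prototype(mode = "coverage", bandwidth = 0)
)

setValidity("OccupancyProfile", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@values) < 1L)
    msg <- c(msg, "'values' must be non-empty")
  if (anyNA(object@values) || any(object@values < 0))
    msg <- c(msg, "'values' must be non-negative and free of NA")
  if (!object@mode %in% c("coverage", "dyad-density"))
    msg <- c(msg, "'mode' must be \"coverage\" or \"dyad-density\"")
  if (length(object@bandwidth) != 1L || object@bandwidth < 0)
    msg <- c(msg, "'bandwidth' must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Set of MNase-seq fragments on one chromosome
#'
#' Fragment intervals (1-based inclusive, as a [GenomicRanges::GRanges])
#' recovered from paired-end alignments, a fragment BED file, or single-end
#' reads extended to a fixed length. `dropped` counts fragments discarded by
#' the mononucleosome length filter.
#'
#' @slot fragments `GRanges` of fragment intervals (strand ignored).
#' @slot source One of `"paired-end"`, `"bed"`, `"single-end-extended"`,
#'   `"simulated"`.
#' @slot dropped Number of fragments discarded by the length filter.
#' @export
setClass("FragmentSet",
  representation(
    fragments = "GRanges",
    source = "character",
    dropped = "integer"
  ),
  prototype(source = "bed", dropped = 0L)
)

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (length(object@fragments) && any(GenomicRanges::width(object@fragments) < 1L))
    msg <- c(msg, "all fragments must be non-empty intervals")
  if (length(object@fragments) && any(GenomicRanges::start(object@fragments) < 1L))
    msg <- c(msg, "fragment starts must be >= 1")
  sl <- GenomeInfoDb::seqlengths(object@fragments)
  if (length(object@fragments) && !all(is.na(sl))) {
    ends <- GenomicRanges::end(object@fragments)
    lim <- sl[as.character(GenomicRanges::seqnames(object@fragments))]
    if (any(!is.na(lim) & ends > lim))
      msg <- c(msg, "fragments extend past chromosome end")
  }
  if (!object@source %in% c("paired-end", "bed", "single-end-extended", "simulated"))
    msg <- c(msg, "unknown fragment source")
  if (length(object@dropped) != 1L || object@dropped < 0L)
    msg <- c(msg, "'dropped' must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Synthetic locus with planted ground truth
#'
#' Container returned by [simulateLocus()]: a synthetic genome plus gene
#' models, together with the planted truth used to validate the nucleosome
#' mapping and NFR calling pipeline (realized dyad positions and the
#' nucleosome-free regions they delimit).
#'
#' @slot genome `DNAStringSet`, one entry per chromosome.
#' @slot genes `GRanges` of gene models with `gene_id` and `tss` metadata.
#' @slot truthDyads `GRanges` (width 1) of planted nucleosome dyad axes.
#' @slot truthNfrs `GRanges` of planted nucleosome-free regions.
#' @slot offset Dyad-axis border offset (bp) used to record the truth NFRs.
#' @slot seed Integer seed the simulation was run with.
#' @export
setClass("SimulatedLocus",
  representation(
    genome = "DNAStringSet",
    genes = "GRanges",
    truthDyads = "GRanges",
    truthNfrs = "GRanges",
    offset = "integer",
    seed = "integer"
  )
)

setValidity("SimulatedLocus", function(object) {
  msg <- character()
  sl <- GenomeInfoDb::seqlengths(object@truthDyads)
  for (gr in list(object@genes, object@truthDyads, object@truthNfrs)) {
    if (length(gr)) {
      lim <- Biostrings::width(object@genome)[match(
        as.character(GenomicRanges::seqnames(gr)), names(object@genome))]
      if (anyNA(lim) || any(GenomicRanges::end(gr) > lim) ||
          any(GenomicRanges::start(gr) < 1L))
        msg <- c(msg, "truth features must lie within genome bounds")
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn OccupancyProfile-class Display a short summary.
#' @param object An `OccupancyProfile`.
#' @export
setMethod("show", "OccupancyProfile", function(object) {
  cat(sprintf(
    "OccupancyProfile on %s: %d bp, mode=%s, bandwidth=%g bp, total signal %.4g\n",
    object@chrom, length(object@values), object@mode, object@bandwidth,
    sum(object@values)))
})

#' @describeIn FragmentSet-class Display a short summary.
#' @param object A `FragmentSet`.
#' @export
setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet: %d fragments (source=%s, %d dropped by length filter)\n",
    length(object@fragments), object@source, object@dropped))
})

#' @describeIn SimulatedLocus-class Display a short summary.
#' @param object A `SimulatedLocus`.
#' @export
setMethod("show", "SimulatedLocus", function(object) {
  cat(sprintf(
    "SimulatedLocus: %d chromosome(s) (%d bp total), %d genes, %d truth dyads, %d truth NFRs, seed %d\n",
    length(object@genome), sum(Biostrings::width(object@genome)),
    length(object@genes), length(object@truthDyads), length(object@truthNfrs),
    object@seed))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `profileChrom()`, `profileValues()`, `profileMode()`, `profileBandwidth()`
#' for [OccupancyProfile-class]; `fragmentRanges()`, `fragmentsDropped()` for
#' [FragmentSet-class]; `locusGenome()`, `locusGenes()`, `truthDyads()`,
#' `truthNfrs()` for [SimulatedLocus-class].
#'
#' @param x The object to access.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
profileChrom <- function(x) x@chrom
#' @rdname accessors
#' @export
profileValues <- function(x) x@values
#' @rdname accessors
#' @export
profileMode <- function(x) x@mode
#' @rdname accessors
#' @export
profileBandwidth <- function(x) x@bandwidth
#' @rdname accessors
#' @export
fragmentRanges <- function(x) x@fragments
#' @rdname accessors
#' @export
fragmentsDropped <- function(x) x@dropped
#' @rdname accessors
#' @export
locusGenome <- function(x) x@genome
#' @rdname accessors
#' @export
locusGenes <- function(x) x@genes
#' @rdname accessors
#' @export
truthDyads <- function(x) x@truthDyads
#' @rdname accessors
#' @export
truthNfrs <- function(x) x@truthNfrs
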