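# guide scoring and ranking: NFR membership, TSS-distance window, CRISPRi
# proximity exclusion, off-target burden; bidirectional promoters; multiplex
# guide sets

#' Ranking configuration
#'
#' Tunable parameters of the guide score. The activation window defaults
#' (42-210 bp upstream of the TSS, with a preference for distances below
#' 110 bp) reflect reported dCas9-activator positioning optima from systematic
#' promoter-walking experiments; they are defaults, not constants, since their
#' transferability between organisms is uncertain. `crispriExclusion` keeps
#' the dCas9 footprint clear of the TSS, where bound dCas9 blocks rather than
#' activates transcription (CRISPRi).
#'
#' @param windowMin,windowMax Closed activation window bounds, bp upstream of
#'   the TSS measured TSS to spacer centre (defaults 42 and 210).
#' @param preferredMax Preferred upper distance in bp (default 110); does not
#'   alter the distance component, only the `preferred` annotation.
#' @param crispriExclusion Exclusion radius around/downstream of the TSS in
#'   bp (default 30).
#' @param weights Named non-negative weights for the `nfr`, `distance` and
#'   `offtarget` components; must sum to 1.
#' @param tierWeights Weights applied to off-target tier counts 0..k in the
#'   off-target component `1 / (1 + sum(tierWeights * counts))`.
#' @return A list of validated ranking parameters.
#' @export
rankingConfig <- function(windowMin = 42, windowMax = 210, preferredMax = 110,
                          crispriExclusion = 30,
                          weights = c(nfr = 0.4, distance = 0.4, offtarget = 0.2),
                          tierWeights = c(1, 0.5, 0.2, 0.1)) {
  if (!(0 < windowMin && windowMin < preferredMax && preferredMax <= windowMax))
    stop("require 0 < windowMin < preferredMax <= windowMax")
  if (crispriExclusion < 0) stop("'crispriExclusion' must be >= 0")
  if (!all(c("nfr", "distance", "offtarget") %in% names(weights)))
    stop("'weights' must name nfr, distance and offtarget")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must be non-negative and sum to 1")
  if (any(tierWeights < 0)) stop("'tierWeights' must be non-negative")
  list(windowMin = windowMin, windowMax = windowMax,
       preferredMax = preferredMax, crispriExclusion = crispriExclusion,
       weights = weights, tierWeights = tierWeights)
}

# signed distance (bp) from the TSS to the spacer centre, positive upstream,
# in 0-based boundary coordinates (strand-symmetric for even spacer lengths)
.tssDistance <- function(site, gene) {
  center0 <- (GenomicRanges::start(site) - 1) + GenomicRanges::width(site) / 2
  tss0 <- gene$tss - 1
  if (as.character(GenomicRanges::strand(gene)) == "+") tss0 - center0
  else center0 - tss0
}

# distance component: 1 on the closed activation window, linear taper to 0
# over one window width on either side
.distanceComponent <- function(d, config) {
  tw <- config$windowMax - config$windowMin
  if (d >= config$windowMin && d <= config$windowMax) return(1)
  if (d > config$windowMax) return(max(0, 1 - (d - config$windowMax) / tw))
  max(0, 1 - (config$windowMin - d) / tw)
}

#' Score a candidate guide against one target gene
#'
#' Combines four considerations into a single `[0, 1]` score:
#' * `nfr_component`: fraction of spacer bases lying inside nucleosome-free
#'   regions (1 when fully contained) -- the activator should not be buried in
#'   positioned nucleosomes;
#' * `distance_component`: 1 when the TSS-to-spacer-centre distance lies in
#'   the activation window, tapering linearly to 0 over one window width
#'   outside it;
#' * `crispri_flag`: `TRUE` when any spacer base lies within
#'   `crispriExclusion` bp of the TSS or downstream of it -- such guides risk
#'   transcriptional interference and their total is forced to 0;
#' * `offtarget_component`: `1 / (1 + sum(tierWeights * counts))` from the
#'   off-target report.
#'
#' The total is the configured weighted sum of the three components (0 when
#' the CRISPRi flag is set).
#'
#' @param site A single site from [scanProtospacers()].
#' @param promoter Promoter region `GRanges` containing the site.
#' @param gene Single-row gene `GRanges` (metadata `gene_id`, `tss`).
#' @param nfrs NFR `GRanges` from [delineateNfrs()] (may be empty).
#' @param report Off-target report from [countOfftargets()], or `NULL` for a
#'   neutral off-target component of 1.
#' @param config Parameters from [rankingConfig()].
#' @return A one-row `data.frame` with the site coordinates, spacer, target
#'   gene, signed `tss_distance`, the four score pieces, a `preferred` flag
#'   (distance within `[windowMin, preferredMax]`) and the `total`.
#' @export
scoreGuide <- function(site, promoter, gene, nfrs,
                       report = NULL, config = rankingConfig()) {
  stopifnot(length(site) == 1L, length(gene) == 1L)
  if (as.character(GenomicRanges::seqnames(site)) !=
        as.character(GenomicRanges::seqnames(promoter)) ||
      GenomicRanges::start(site) < GenomicRanges::start(promoter) ||
      GenomicRanges::end(site) > GenomicRanges::end(promoter))
    stop("site lies outside the promoter region")
  L <- GenomicRanges::width(site)
  d <- .tssDistance(site, gene)
  distComp <- .distanceComponent(d, config)
  nfrComp <- 0
  if (length(nfrs)) {
    nfrsC <- nfrs[as.character(GenomicRanges::seqnames(nfrs)) ==
                    as.character(GenomicRanges::seqnames(site))]
    if (length(nfrsC)) {
      ov <- GenomicRanges::intersect(
        GenomicRanges::granges(site),
        GenomicRanges::reduce(GenomicRanges::granges(nfrsC)),
        ignore.strand = TRUE)
      nfrComp <- sum(GenomicRanges::width(ov)) / L
    }
  }
  # nearest spacer base to the TSS along the gene's upstream axis
  tss0 <- gene$tss - 1
  bases0 <- (GenomicRanges::start(site) - 1L):(GenomicRanges::end(site) - 1L)
  baseDist <- if (as.character(GenomicRanges::strand(gene)) == "+")
    tss0 - bases0 else bases0 - tss0
  crispri <- min(baseDist) < config$crispriExclusion
  offComp <- 1
  if (!is.null(report)) {
    cnt <- as.numeric(report$counts)
    tw <- config$tierWeights[seq_along(cnt)]
    offComp <- 1 / (1 + sum(tw * cnt, na.rm = TRUE))
  }
  total <- if (crispri) 0 else unname(
    config$weights["nfr"] * nfrComp +
    config$weights["distance"] * distComp +
    config$weights["offtarget"] * offComp)
  data.frame(
    gene_id = gene$gene_id,
    chrom = as.character(GenomicRanges::seqnames(site)),
    start = GenomicRanges::start(site), end = GenomicRanges::end(site),
    strand = as.character(GenomicRanges::strand(site)),
    spacer = site$spacer, pam = site$pam,
    tss_distance = d,
    nfr_component = nfrComp, distance_component = distComp,
    crispri_flag = crispri, offtarget_component = offComp,
    preferred = d >= config$windowMin & d <= config$preferredMax,
    total = total,
    stringsAsFactors = FALSE)
}

#' Rank scored guides
#'
#' Deterministic stable ordering: descending total, ties broken by smaller
#' absolute TSS distance, then `+` strand before `-`, then leftmost genomic
#' coordinate.
#'
#' @param scores `data.frame` of rows from [scoreGuide()].
#' @return The reordered `data.frame` with a `rank` column prepended.
#' @export
rankGuides <- function(scores) {
  if (!nrow(scores)) return(cbind(rank = integer(), scores))
  ord <- order(-scores$total, abs(scores$tss_distance),
               scores$strand != "+", scores$start)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Score a guide against both genes of a bidirectional promoter
#'
#' In a divergent gene pair sharing one control region a single dCas9-bound
#' guide faces two TSSs; the same site is scored independently against each
#' flanking gene. The higher-scoring gene is labelled the *primary* predicted
#' target (ties: smaller absolute TSS distance, then the leftmost-coordinate
#' gene), but both scores are always reported -- observed activation in such
#' promoters does not reliably follow guide proximity, so the secondary score
#' is not a prediction of inactivity.
#'
#' @param site A single site from [scanProtospacers()].
#' @param promoter A bidirectional promoter from [detectBidirectional()].
#' @param genes Gene `GRanges` from [loadAnnotation()] containing both target
#'   genes.
#' @param nfrs NFR `GRanges`.
#' @param report Off-target report for the site (or `NULL`).
#' @param config Parameters from [rankingConfig()].
#' @return A two-row `data.frame` of [scoreGuide()] rows with a logical
#'   `primary` column.
#' @export
assignBidirectional <- function(site, promoter, genes, nfrs,
                                report = NULL, config = rankingConfig()) {
  if (!isTRUE(S4Vectors::mcols(promoter)$bidirectional[1L]))
    stop("promoter is not bidirectional")
  ids <- unlist(S4Vectors::mcols(promoter)$target_genes)
  stopifnot(length(ids) == 2L)
  idx <- match(ids, genes$gene_id)
  if (anyNA(idx)) stop("target gene(s) missing from annotation: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  sc <- do.call(rbind, lapply(idx, function(i)
    scoreGuide(site, promoter, genes[i], nfrs, report, config)))
  gStart <- GenomicRanges::start(genes)[idx]
  ord <- order(-sc$total, abs(sc$tss_distance), gStart)
  sc$primary <- seq_len(2L) == 0L
  sc$primary[ord[1L]] <- TRUE
  sc
}

#' Select a multiplex guide set
#'
#' Greedy selection in rank order, skipping any guide whose spacer centre
#' lies closer than `minSpacing` bp to an already selected guide, until `k`
#' guides are chosen or the candidates are exhausted (with a warning when
#' fewer than `k` remain). Combining several guides on one promoter is often
#' required for activation -- single guides can be completely inactive where
#' pairs or quadruples activate strongly -- hence a warning is also issued
#' when a single-guide design (`k = 1`) is requested.
#'
#' @param ranked Ranked `data.frame` from [rankGuides()].
#' @param k Number of guides requested (>= 1).
#' @param minSpacing Minimum pairwise spacer-centre distance in bp (default
#'   30, exceeding the dCas9/sgRNA footprint so multiplexed guides do not
#'   compete).
#' @return A list with `guides` (the selected rows, rank order),
#'   `pairwise_min_distance` (`minSpacing`) and `combined` (sum of totals).
#' @export
selectMultiplex <- function(ranked, k, minSpacing = 30L) {
  if (k < 1L) stop("'k' must be >= 1")
  if (k == 1L)
    warning("single-guide designs frequently fail to activate; ",
            "consider multiplexing (k >= 2)")
  centers <- (ranked$start - 1) + (ranked$end - ranked$start + 1) / 2
  sel <- integer()
  for (i in seq_len(nrow(ranked))) {
    if (length(sel) >= k) break
    if (!length(sel) || all(abs(centers[sel] - centers[i]) >= minSpacing))
      sel <- c(sel, i)
  }
  if (length(sel) < k)
    warning("only ", length(sel), " of ", k,
            " requested guides satisfy the spacing constraint")
  guides <- ranked[sel, , drop = FALSE]
  rownames(guides) <- NULL
  list(guides = guides, pairwise_min_distance = minSpacing,
       combined = sum(guides$total))
}

#' Combine NFR sets from two conditions for ranking
#'
#' Guides are best supported by a nucleosome-free region present under the
#' conditions of the planned activation; when maps from two conditions are
#' available the conservative default is their intersection (guide valid
#' under both), with the union available for permissive designs.
#'
#' @param nfrsA,nfrsB NFR `GRanges` for the two conditions.
#' @param mode `"intersection"` (default) or `"union"`.
#' @return A `GRanges` of combined regions.
#' @export
combineNfrConditions <- function(nfrsA, nfrsB,
                                 mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  a <- GenomicRanges::reduce(GenomicRanges::granges(nfrsA))
  b <- GenomicRanges::reduce(GenomicRanges::granges(nfrsB))
  if (mode == "intersection") GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  else GenomicRanges::reduce(c(a, b))
}

#' Write a ranked guide table
#'
#' Emits the ranked score table as TSV with 0-based half-open coordinates.
#'
#' @param ranked `data.frame` from [rankGuides()] (or the `guides` element of
#'   [selectMultiplex()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeRankedGuides <- function(ranked, path) {
  out <- ranked
  out$start <- out$start - 1L  # emit 0-based half-open
  .writeTsv(out, path)
}
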