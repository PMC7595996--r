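# synthetic loci with planted ground truth: genomes with annotated (including
# divergent) genes, phased nucleosome arrays flanking promoter NFRs, sampled
# mononucleosome fragments, and Ct tables with planted fold changes

# run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a genome with annotated genes
#'
#' Draws i.i.d. bases at the requested GC content and places gene models on
#' the first chromosome with configurable spacing, always including one
#' divergently transcribed pair whose TSS separation is drawn uniformly from
#' `divergentSepRange` (default a fixed 305 bp, the size of the compact
#' bidirectional control regions this toolkit is designed around).
#'
#' @param nChrom Number of chromosomes (default 1).
#' @param length Chromosome length in bp (>= 5000; default 20000).
#' @param gc GC fraction (default 0.5).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param nGenes Number of genes (>= 2; default 4).
#' @param geneLength Gene body length in bp (default 1000).
#' @param spacing Intergenic spacing in bp (default 2000; must leave room for
#'   promoter windows).
#' @param divergentSepRange Two-element range the divergent pair's TSS
#'   separation is drawn from (default `c(305, 305)`).
#' @return A list with `genome` (named `DNAStringSet`) and `genes`
#'   (`GRanges` with `gene_id` and `tss`, `seqlengths` set).
#' @export
simulateGenome <- function(nChrom = 1L, length = 20000L, gc = 0.5, seed = 1L,
                           nGenes = 4L, geneLength = 1000L, spacing = 2000L,
                           divergentSepRange = c(305L, 305L)) {
  if (length < 5000L) stop("'length' must be >= 5000")
  if (nGenes < 2L) stop("'nGenes' must be >= 2 (the divergent pair)")
  .withSeed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(seq_len(nChrom), function(i)
      paste(sample(names(probs), length, replace = TRUE, prob = probs),
            collapse = ""), character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- sprintf("chr%d", seq_len(nChrom))
    sep <- if (divergentSepRange[1] == divergentSepRange[2])
      divergentSepRange[1]
    else sample(seq(divergentSepRange[1], divergentSepRange[2]), 1L)
    rows <- list()
    cursor <- spacing
    i <- 1L
    pairAt <- if (nGenes >= 3L) 2L else 1L
    while (i <= nGenes) {
      if (i == pairAt) {  # divergent pair: minus-strand gene, gap = sep, plus-strand gene
        mEnd <- cursor + geneLength - 1L
        rows[[i]] <- data.frame(start = cursor, end = mEnd, strand = "-")
        pStart <- mEnd + sep
        rows[[i + 1L]] <- data.frame(start = pStart,
                                     end = pStart + geneLength - 1L,
                                     strand = "+")
        cursor <- pStart + geneLength - 1L + spacing
        i <- i + 2L
      } else {
        rows[[i]] <- data.frame(start = cursor, end = cursor + geneLength - 1L,
                                strand = "+")
        cursor <- cursor + geneLength - 1L + spacing
        i <- i + 1L
      }
    }
    df <- do.call(rbind, rows)[seq_len(nGenes), , drop = FALSE]
    if (max(df$end) + spacing %/% 2L > length)
      stop("infeasible gene packing: ", nGenes, " genes of ", geneLength,
           " bp at spacing ", spacing, " exceed chromosome length ", length)
    genes <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(df$start, df$end), strand = df$strand,
      gene_id = sprintf("gene%d", seq_len(nGenes)),
      tss = as.integer(ifelse(df$strand == "+", df$start, df$end)))
    sl <- stats::setNames(rep(length, nChrom), names(genome))
    GenomeInfoDb::seqlevels(genes) <- names(genome)
    GenomeInfoDb::seqlengths(genes) <- sl
    list(genome = genome, genes = genes)
  })
}

# strand-aware planted NFR window upstream of a gene's TSS (1-based interval)
.nfrWindow <- function(gene, nfrWidth, proximal) {
  tss <- gene$tss
  if (as.character(GenomicRanges::strand(gene)) == "+")
    c(tss - proximal - nfrWidth, tss - proximal - 1L)
  else
    c(tss + proximal + 1L, tss + proximal + nfrWidth)
}

#' Plant phased nucleosome arrays with promoter NFRs
#'
#' Places nucleosome dyads on a regular lattice of `repeatLength` bp spacing
#' outside the promoter NFR windows, with the two dyads flanking each window
#' anchored exactly `offset` bp outside its borders (overlapping windows of
#' divergent gene pairs are merged into one shared NFR). Optional Gaussian
#' jitter perturbs every dyad; the recorded truth NFRs are always recomputed
#' from the *realized* flanking dyads with the configured offset, so truth
#' NFR borders are exactly `offset` bp from their flanking dyads by
#' construction.
#'
#' @param sim A list with `genome` and `genes` from [simulateGenome()].
#' @param repeatLength Nucleosome repeat length in bp (default 165).
#' @param nfrWidth Planted NFR width in bp (default 150).
#' @param nfrProximal Distance from the TSS to the NFR's proximal border in
#'   bp (default 30).
#' @param offset Dyad-to-border offset in bp (default 75).
#' @param jitterSd Dyad position jitter standard deviation in bp (default 0).
#' @param seed Integer seed (used only when `jitterSd > 0`).
#' @return A [SimulatedLocus-class].
#' @export
plantNucleosomes <- function(sim, repeatLength = 165L, nfrWidth = 150L,
                             nfrProximal = 30L, offset = 75L, jitterSd = 0,
                             seed = 1L) {
  genome <- sim$genome
  genes <- sim$genes
  if (nfrWidth < 2L * 1L) warning("nfr window too small to exclude a dyad")
  dyadL <- list(); nfrL <- list()
  for (chrom in names(genome)) {
    chromLen <- Biostrings::width(genome)[match(chrom, names(genome))]
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == chrom]
    win <- if (length(g))
      GenomicRanges::reduce(GenomicRanges::GRanges(chrom, IRanges::IRanges(
        t(vapply(seq_along(g), function(i) .nfrWindow(g[i], nfrWidth, nfrProximal),
                 integer(2)))[, 1L],
        t(vapply(seq_along(g), function(i) .nfrWindow(g[i], nfrWidth, nfrProximal),
                 integer(2)))[, 2L])))
    else GenomicRanges::GRanges()
    ws <- GenomicRanges::start(win); we <- GenomicRanges::end(win)
    margin <- 101L  # keep whole fragments on-chromosome around edge dyads
    dy <- integer()
    anchors <- list()
    if (length(win) == 0L) {
      dy <- seq(margin, chromLen - margin, by = repeatLength)
    } else {
      # left flank of the first window
      dy <- if (ws[1L] - offset >= margin)
        rev(seq(ws[1L] - offset, margin, by = -repeatLength))
      else integer()
      for (j in seq_along(win)) {
        # right flanking dyad of window j sits at we + offset + 1, so the
        # recorded truth NFR [dl + offset, dr - offset - 1] equals the window;
        # the lattice between windows is evenly respaced (both anchors
        # included) so the last step is never a short remainder
        if (j < length(win)) {
          a <- we[j] + offset + 1L; b <- ws[j + 1L] - offset
          n <- max(1L, round((b - a) / repeatLength))
          dy <- c(dy, round(a + (b - a) * (0:n) / n))
        } else {
          dy <- c(dy, seq(we[j] + offset + 1L, chromLen - margin,
                          by = repeatLength))
        }
      }
    }
    dy <- sort(unique(as.integer(dy)))
    if (jitterSd > 0)
      dy <- .withSeed(seed + match(chrom, names(genome)),
                      sort(unique(as.integer(dy + round(stats::rnorm(length(dy),
                                                        0, jitterSd))))))
    # drop any dyad that fell inside a window, then record truth NFRs from the
    # realized flanking dyads
    if (length(win)) {
      inWin <- GenomicRanges::countOverlaps(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(dy, width = 1L)), win) > 0L
      dy <- dy[!inWin]
      for (j in seq_along(win)) {
        dl <- suppressWarnings(max(dy[dy < ws[j]]))
        dr <- suppressWarnings(min(dy[dy > we[j]]))
        if (!is.finite(dl) || !is.finite(dr)) {
          warning("window on ", chrom, " lacks a flanking dyad; truth NFR skipped")
          next
        }
        w <- dr - dl - 2L * offset
        if (w < 1L) { warning("nfr window too small to exclude a dyad"); next }
        nfrL[[length(nfrL) + 1L]] <- GenomicRanges::GRanges(
          chrom, IRanges::IRanges(dl + offset, width = w),
          left_dyad = dl, right_dyad = dr)
      }
    }
    dyadL[[length(dyadL) + 1L]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(dy, width = 1L))
  }
  dyads <- do.call(c, dyadL)
  nfrs <- if (length(nfrL)) do.call(c, nfrL) else
    GenomicRanges::GRanges(left_dyad = integer(), right_dyad = integer())
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  GenomeInfoDb::seqlevels(dyads) <- names(genome)
  GenomeInfoDb::seqlengths(dyads) <- sl
  GenomeInfoDb::seqlevels(nfrs) <- names(genome)
  GenomeInfoDb::seqlengths(nfrs) <- sl
  methods::new("SimulatedLocus", genome = genome, genes = genes,
               truthDyads = dyads, truthNfrs = nfrs,
               offset = as.integer(offset), seed = as.integer(seed))
}

#' Convenience: simulate a genome and plant nucleosomes in one call
#'
#' @param seed Integer seed.
#' @param ... Passed on to [simulateGenome()] and [plantNucleosomes()]
#'   (arguments are routed by name).
#' @return A [SimulatedLocus-class].
#' @export
simulateLocus <- function(seed = 1L, ...) {
  args <- list(...)
  gArgs <- args[names(args) %in% names(formals(simulateGenome))]
  pArgs <- args[names(args) %in% setdiff(names(formals(plantNucleosomes)), "sim")]
  sim <- do.call(simulateGenome, c(list(seed = seed), gArgs))
  do.call(plantNucleosomes, c(list(sim = sim, seed = seed), pArgs))
}

#' Sample mononucleosome fragments around planted dyads
#'
#' For every truth dyad, draws `fragmentsPerNucleosome` fragments whose
#' centres are the dyad position plus Gaussian jitter (MNase trimming
#' variability) and whose lengths are Gaussian around `fragMean`, clipped to
#' the mononucleosome window `[100, 200]` bp. Deterministic under a fixed
#' seed.
#'
#' @param locus A [SimulatedLocus-class].
#' @param fragmentsPerNucleosome Fragments drawn per dyad (>= 1; default 30).
#' @param fragMean,fragSd Fragment length distribution in bp (defaults 147
#'   and 15).
#' @param centerJitterSd Fragment-centre jitter standard deviation in bp
#'   (default 10).
#' @param seed Integer seed.
#' @return A [FragmentSet-class] (`source = "simulated"`).
#' @export
simulateFragments <- function(locus, fragmentsPerNucleosome = 30L,
                              fragMean = 147, fragSd = 15,
                              centerJitterSd = 10, seed = 1L) {
  if (fragmentsPerNucleosome < 1L) stop("'fragmentsPerNucleosome' must be >= 1")
  dyads <- truthDyads(locus)
  sl <- stats::setNames(Biostrings::width(locusGenome(locus)),
                        names(locusGenome(locus)))
  .withSeed(seed, {
    n <- length(dyads) * fragmentsPerNucleosome
    pos <- rep(GenomicRanges::start(dyads), each = fragmentsPerNucleosome)
    chrom <- rep(as.character(GenomicRanges::seqnames(dyads)),
                 each = fragmentsPerNucleosome)
    centers <- pos + round(stats::rnorm(n, 0, centerJitterSd))
    lens <- pmin(pmax(round(stats::rnorm(n, fragMean, fragSd)), 100L), 200L)
    starts <- centers - lens %/% 2L
    ends <- starts + lens - 1L
    lim <- sl[chrom]
    shift <- pmax(0L, 1L - starts) - pmax(0L, ends - lim)
    starts <- starts + shift
    ends <- ends + shift
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    methods::new("FragmentSet", fragments = gr, source = "simulated",
                 dropped = 0L)
  })
}

#' Simulate a qPCR Ct table with a planted fold change
#'
#' Builds a long-format Ct table (see [readCtTable()]) for one target gene
#' and two reference genes across calibrator and treated biological samples,
#' in technical duplicate. The treated samples' target Ct is shifted by
#' `-log2(trueFold)` plus Gaussian noise, so with zero noise [foldChange()]
#' recovers `trueFold` exactly.
#'
#' @param trueFold Planted fold change (> 0; default 30).
#' @param nBio Biological replicates per group (default 3).
#' @param ctNoiseSd Ct noise standard deviation (default 0).
#' @param seed Integer seed.
#' @param target Target gene name (default `"mdpE"`).
#' @param refs Reference gene names (default `c("actA", "benA")`).
#' @param nTech Technical replicates (default 2).
#' @return A `data.frame` in the [readCtTable()] layout, with attributes
#'   `treated` and `calibrator` naming the sample groups.
#' @export
simulateQpcr <- function(trueFold = 30, nBio = 3L, ctNoiseSd = 0, seed = 1L,
                         target = "mdpE", refs = c("actA", "benA"),
                         nTech = 2L) {
  if (trueFold <= 0) stop("'trueFold' must be > 0")
  .withSeed(seed, {
    calSamples <- sprintf("ctrl_%d", seq_len(nBio))
    trtSamples <- sprintf("act_%d", seq_len(nBio))
    baseCt <- stats::setNames(c(30, 20, 22), c(target, refs[1],
                                               refs[min(2L, length(refs))]))
    rows <- list()
    for (s in c(calSamples, trtSamples)) {
      treated <- s %in% trtSamples
      for (g in c(target, refs)) {
        ct <- baseCt[[g]]
        if (treated && g == target)
          ct <- ct - log2(trueFold) + stats::rnorm(1, 0, ctNoiseSd)
        for (r in seq_len(nTech))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s, gene_id = g, replicate = r, Ct = ct,
            efficiency = 100, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "treated") <- trtSamples
    attr(out, "calibrator") <- calSamples
    out
  })
}

#' Write simulator outputs to files
#'
#' `writeSimulatedGenome()` writes the genome FASTA and gene GFF3;
#' `writeFragmentsBed()` writes fragments as BED3; `writeFragmentsSam()`
#' writes fully specified paired-end records (proper-pair flags, correct
#' template lengths, genome-derived read sequences) so that alignment-based
#' fragment recovery can be validated against the ground-truth fragment set.
#'
#' @param sim List from [simulateGenome()] or a [SimulatedLocus-class].
#' @param fastaPath,gffPath,path Output paths.
#' @param fragments A [FragmentSet-class].
#' @param genome Named `DNAStringSet`.
#' @param readLength Read length for SAM output (default 50, paired-end).
#' @return The written path(s), invisibly.
#' @export
writeSimulatedGenome <- function(sim, fastaPath, gffPath) {
  genome <- if (methods::is(sim, "SimulatedLocus")) locusGenome(sim) else sim$genome
  genes <- if (methods::is(sim, "SimulatedLocus")) locusGenes(sim) else sim$genes
  Biostrings::writeXStringSet(genome, fastaPath)
  gff <- GenomicRanges::granges(genes)
  S4Vectors::mcols(gff)$source <- "nucleoguide"
  S4Vectors::mcols(gff)$type <- "gene"
  S4Vectors::mcols(gff)$ID <- genes$gene_id
  S4Vectors::mcols(gff)$Name <- genes$gene_id
  rtracklayer::export(gff, gffPath, format = "gff3")
  invisible(c(fastaPath, gffPath))
}

#' @rdname writeSimulatedGenome
#' @export
writeFragmentsBed <- function(fragments, path) {
  bed <- .toBed(fragmentRanges(fragments))
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname writeSimulatedGenome
#' @export
writeFragmentsSam <- function(fragments, genome, path, readLength = 50L) {
  gr <- fragmentRanges(fragments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       Biostrings::width(genome)[match(nm, names(genome))]), con)
  if (!length(gr)) return(invisible(path))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  len <- GenomicRanges::width(gr)
  rl <- pmin(readLength, len)
  p2 <- e - rl + 1L
  seq1 <- vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], s[i], s[i] + rl[i] - 1L)),
    character(1))
  seq2 <- vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], p2[i], e[i])),
    character(1))
  qual <- vapply(rl, function(l) strrep("I", l), character(1))
  cig <- sprintf("%dM", rl)
  qname <- sprintf("frag_%06d", seq_along(gr))
  l1 <- sprintf("%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                qname, chrom, s, cig, p2, len, seq1, qual)
  l2 <- sprintf("%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t%s",
                qname, chrom, p2, cig, s, -len, seq2, qual)
  writeLines(c(rbind(l1, l2)), con)
  invisible(path)
}

#' @rdname writeSimulatedGenome
#' @param ct A Ct table from [simulateQpcr()].
#' @export
writeCtTable <- function(ct, path) {
  .writeTsv(ct, path)
}
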