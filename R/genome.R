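# genome and annotation model: FASTA/GFF3 loading, TSS derivation, promoter
# regions, bidirectional (divergent-pair) promoter detection

#' Load a genome from FASTA
#'
#' Reads every FASTA record as one chromosome and normalises the sequence to
#' uppercase. Record names are truncated at the first whitespace. Only the
#' alphabet A/C/G/T/N is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (the genome), one entry per
#'   chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- loadGenome(fa)
#' as.character(g$chr1)
#' @export
loadGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome names in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence record in FASTA: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0L], collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE]) > 0
  if (any(bad))
    stop("record(s) with characters outside A/C/G/T/N: ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Load gene models from GFF3
#'
#' Imports `gene` features from a GFF3 file, keeping the standard 1-based
#' inclusive coordinates, and derives each gene's transcriptional start site
#' (TSS) from its strand: the annotated gene start on `+`, the annotated gene
#' end on `-`. Predicted TSSs from other evidence (e.g. RNA-seq) can be
#' injected with `tssOverride`, a two-column `gene_id`/`tss` table
#' (1-based positions).
#'
#' @param path Path to a GFF3 file.
#' @param genome Genome as returned by [loadGenome()]; used for bounds checks.
#' @param tssOverride Optional `data.frame` (or path to a two-column TSV) with
#'   columns `gene_id` and `tss` overriding the annotation-derived TSS.
#' @return A [GenomicRanges::GRanges] of gene spans with metadata columns
#'   `gene_id` and `tss`, with `seqlengths` set from the genome.
#' @export
loadAnnotation <- function(path, genome, tssOverride = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  if (length(genes) == 0L) stop("no 'gene' features in ", path)
  chr <- as.character(GenomicRanges::seqnames(genes))
  unknown <- setdiff(unique(chr), names(genome))
  if (length(unknown))
    stop("GFF3 seqid(s) absent from genome: ", paste(unknown, collapse = ", "))
  lens <- Biostrings::width(genome)[match(chr, names(genome))]
  if (any(GenomicRanges::end(genes) > lens) || any(GenomicRanges::start(genes) < 1L))
    stop("gene(s) extend past chromosome bounds: ",
         paste(genes$ID[GenomicRanges::end(genes) > lens |
                        GenomicRanges::start(genes) < 1L], collapse = ", "))
  if (any(!as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
    stop("gene(s) without explicit +/- strand")
  ids <- genes$ID
  if (is.null(ids)) ids <- genes$Name
  if (is.null(ids) || anyNA(ids)) stop("gene features must carry an ID attribute")
  tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                GenomicRanges::start(genes), GenomicRanges::end(genes))
  out <- GenomicRanges::GRanges(
    seqnames = chr,
    ranges = IRanges::IRanges(GenomicRanges::start(genes), GenomicRanges::end(genes)),
    strand = GenomicRanges::strand(genes),
    gene_id = ids, tss = as.integer(tss))
  if (!is.null(tssOverride)) {
    if (is.character(tssOverride))
      tssOverride <- utils::read.delim(tssOverride, header = TRUE,
                                       stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "tss") %in% names(tssOverride)))
    idx <- match(out$gene_id, tssOverride$gene_id)
    hit <- !is.na(idx)
    out$tss[hit] <- as.integer(tssOverride$tss[idx[hit]])
  }
  sl <- Biostrings::width(genome)
  names(sl) <- names(genome)
  GenomeInfoDb::seqlevels(out) <- names(genome)
  GenomeInfoDb::seqlengths(out) <- sl
  out[order(as.character(GenomicRanges::seqnames(out)), GenomicRanges::start(out))]
}

#' Promoter region of a gene
#'
#' Returns the interval extending `upstream` bp 5' of the TSS and
#' `downstream` bp 3' of it, strand-aware, clipped to the chromosome bounds
#' (clipping raises a warning, not an error).
#'
#' @param gene A single-row gene `GRanges` from [loadAnnotation()] (metadata
#'   `gene_id`, `tss`; `seqlengths` set).
#' @param upstream,downstream Number of bp 5'/3' of the TSS (>= 0).
#' @return A `GRanges` of length 1 with metadata columns `target_genes`
#'   (CharacterList), `bidirectional` (FALSE), `tss_positions` (IntegerList)
#'   and `clipped` (logical).
#' @export
promoterRegion <- function(gene, upstream = 800L, downstream = 0L) {
  stopifnot(length(gene) == 1L)
  .assertScalarNum(upstream, "upstream", 0)
  .assertScalarNum(downstream, "downstream", 0)
  tss <- gene$tss
  str <- as.character(GenomicRanges::strand(gene))
  chrom <- as.character(GenomicRanges::seqnames(gene))
  chromLen <- GenomeInfoDb::seqlengths(gene)[chrom]
  if (str == "+") {
    s <- tss - upstream
    e <- tss + downstream - 1L
    if (downstream == 0L) e <- tss - 1L  # pure upstream window ends at TSS
  } else {
    s <- tss - downstream + 1L
    if (downstream == 0L) s <- tss + 1L
    e <- tss + upstream
  }
  clipped <- FALSE
  if (s < 1L) { s <- 1L; clipped <- TRUE }
  if (!is.na(chromLen) && e > chromLen) { e <- chromLen; clipped <- TRUE }
  if (clipped)
    warning("promoter region for ", gene$gene_id, " clipped to chromosome bounds")
  if (e < s) stop("degenerate promoter region for ", gene$gene_id)
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e), strand = "*")
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(gene)
  GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(gene)
  S4Vectors::mcols(out)$target_genes <- IRanges::CharacterList(list(gene$gene_id))
  S4Vectors::mcols(out)$bidirectional <- FALSE
  S4Vectors::mcols(out)$tss_positions <- IRanges::IntegerList(list(stats::setNames(
    as.integer(tss), gene$gene_id)))
  S4Vectors::mcols(out)$clipped <- clipped
  out
}

#' Detect bidirectional (divergent-pair) promoters
#'
#' Scans genes in coordinate order and reports every pair of adjacent,
#' divergently transcribed genes (`-` then `+` along the chromosome) whose
#' TSS separation is at most `maxGap` bp. Each such pair yields one
#' bidirectional promoter region spanning from the minus-strand gene's TSS to
#' the plus-strand gene's TSS (half-open at the plus TSS, so the region width
#' equals the TSS separation; the 305-bp divergent control regions typical of
#' compact fungal genomes motivate the default gap).
#'
#' @param genes Gene `GRanges` from [loadAnnotation()].
#' @param maxGap Maximum TSS separation in bp (default 600).
#' @return `GRanges` of bidirectional promoter regions with metadata columns
#'   `target_genes`, `bidirectional` (TRUE), `tss_positions` and `clipped`.
#' @export
detectBidirectional <- function(genes, maxGap = 600L) {
  .assertScalarNum(maxGap, "maxGap", 0)
  out <- GenomicRanges::GRanges()
  GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(genes)
  GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(genes)
  hits <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(genes)))) {
    g <- genes[as.character(GenomicRanges::seqnames(genes)) == chrom]
    g <- g[order(GenomicRanges::start(g))]
    if (length(g) < 2L) next
    for (i in seq_len(length(g) - 1L)) {
      left <- g[i]; right <- g[i + 1L]
      if (as.character(GenomicRanges::strand(left)) != "-" ||
          as.character(GenomicRanges::strand(right)) != "+") next
      sep <- right$tss - left$tss
      if (sep <= 0L || sep > maxGap) next
      region <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(left$tss, right$tss - 1L), strand = "*")
      GenomeInfoDb::seqlevels(region) <- GenomeInfoDb::seqlevels(genes)
      GenomeInfoDb::seqlengths(region) <- GenomeInfoDb::seqlengths(genes)
      S4Vectors::mcols(region)$target_genes <-
        IRanges::CharacterList(list(c(left$gene_id, right$gene_id)))
      S4Vectors::mcols(region)$bidirectional <- TRUE
      S4Vectors::mcols(region)$tss_positions <- IRanges::IntegerList(list(
        stats::setNames(c(left$tss, right$tss), c(left$gene_id, right$gene_id))))
      S4Vectors::mcols(region)$clipped <- FALSE
      hits[[length(hits) + 1L]] <- region
    }
  }
  if (length(hits)) out <- do.call(c, hits)
  out
}
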