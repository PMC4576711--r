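#' Assign transcripts to genes
#'
#' A transcript is assigned iff its genomic span overlaps exactly one
#' annotated gene on the same strand. Transcripts overlapping no gene are
#' discarded (`no_gene`), transcripts overlapping two or more genes are
#' discarded (`ambiguous`) — intergenic and unresolvable alignments carry no
#' usable event information.
#'
#' @param alignments List of `spliced_alignment` objects.
#' @param catalog Gene catalog from [read_gene_annotation()].
#' @return List with `assigned` (named list gene_id -> list of alignments,
#'   genes with no transcripts omitted) and `discarded` (`data.frame` with
#'   `transcript_id`, `reason`).
#' @export
assign_transcripts <- function(alignments, catalog) {
  if (!nrow(catalog)) stop("gene catalog is empty")
  genes <- GenomicRanges::GRanges(
    catalog$chrom,
    IRanges::IRanges(catalog$start + 1L, catalog$end),
    strand = catalog$strand)
  spans <- GenomicRanges::GRanges(
    vapply(alignments, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(alignments, function(a) a$blocks[1, 1], 0L) + 1L,
                     vapply(alignments, function(a) a$blocks[nrow(a$blocks), 2], 0L)),
    strand = vapply(alignments, `[[`, "", "strand"))
  hits <- GenomicRanges::findOverlaps(spans, genes)
  n_hits <- tabulate(S4Vectors::queryHits(hits), nbins = length(alignments))
  gene_of <- rep(NA_integer_, length(alignments))
  uniq <- which(n_hits == 1L)
  gene_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  assigned <- list()
  disc_id <- character(0); disc_reason <- character(0)
  for (i in seq_along(alignments)) {
    if (n_hits[i] == 1L) {
      gid <- catalog$gene_id[gene_of[i]]
      assigned[[gid]] <- c(assigned[[gid]], list(alignments[[i]]))
    } else {
      disc_id <- c(disc_id, alignments[[i]]$transcript_id)
      disc_reason <- c(disc_reason, if (n_hits[i] == 0L) "no_gene" else "ambiguous")
    }
  }
  list(assigned = assigned,
       discarded = data.frame(transcript_id = disc_id, reason = disc_reason,
                              stringsAsFactors = FALSE))
}

#' Build a gene's exon-intron template from its transcripts
#'
#' The template exons are the union of all transcript exon blocks, merged
#' where overlapping or bookended; template introns are the complementary
#' gaps within the template span, so exons and introns alternate and tile the
#' span. The template additionally records the set of distinct introns
#' observed across the contributing transcripts: a retained intron is covered
#' by the retaining transcript's block and therefore absent from the gap
#' structure, but remains visible as an observed intron, which is what
#' intron-retention calling needs.
#'
#' @param gene_id Gene identifier the transcripts were assigned to.
#' @param transcripts List of `spliced_alignment` objects for one gene.
#' @return A list of class `gene_template`: `gene_id`, `chrom`, `strand`,
#'   `exons` (merged union, 2-col matrix), `introns` (gaps, 2-col matrix),
#'   `observed_introns` (distinct transcript introns, 2-col matrix).
#' @export
build_gene_template <- function(gene_id, transcripts) {
  if (!length(transcripts)) stop("no transcripts supplied for gene ", gene_id)
  chroms <- unique(vapply(transcripts, `[[`, "", "chrom"))
  strands <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(chroms) != 1 || length(strands) != 1)
    stop("transcripts for gene ", gene_id, " on mixed chromosomes/strands")
  blocks <- do.call(rbind, lapply(transcripts, `[[`, "blocks"))
  exons <- merge_intervals(blocks)
  n <- nrow(exons)
  introns <- if (n > 1) cbind(start = exons[-n, 2], end = exons[-1, 1]) else
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  obs <- do.call(rbind, lapply(transcripts, alignment_introns))
  obs <- unique(obs)
  obs <- obs[order(obs[, 1], obs[, 2]), , drop = FALSE]
  structure(list(gene_id = gene_id, chrom = chroms, strand = strands,
                 exons = exons, introns = introns, observed_introns = obs),
            class = "gene_template")
}

# Union of possibly overlapping/bookended intervals; returns sorted,
# disjoint, non-adjacent intervals.
merge_intervals <- function(m) {
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  starts <- m[, 1]; ends <- m[, 2]
  keep_start <- c(TRUE, starts[-1] > cummax(ends[-length(ends)]))
  grp <- cumsum(keep_start)
  out <- cbind(start = as.integer(tapply(starts, grp, min)),
               end = as.integer(tapply(ends, grp, max)))
  rownames(out) <- NULL
  out
}
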