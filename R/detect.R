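#' Detect and classify AS events for one transcript against a gene template
#'
#' Compares the transcript's introns and blocks with the gene template and
#' emits zero or more events of the five types:
#'
#' * **ES** (exon skipping): a transcript intron fully contains one or more
#'   template exons; one event per skipped exon, event interval = the skipped
#'   exon.
#' * **IR** (intron retention): a transcript block fully contains a template
#'   intron (gap) or an observed intron, extending at least one base beyond
#'   it on both sides; event interval = the retained intron.
#' * **5S** (alternative 5'-donor): a transcript intron shares its
#'   acceptor-side boundary with a template intron but not its donor-side
#'   boundary; event interval = the transcript intron.
#' * **3S** (alternative 3'-acceptor): donor-side boundary shared, acceptor
#'   side not; event interval = the transcript intron.
#' * **3S5S**: the intron overlaps a template intron but shares neither
#'   boundary and contains no complete template exon; event interval = the
#'   transcript intron.
#'
#' Donor and acceptor are strand-aware: the donor is the intron end abutting
#' the transcript-5' exon (the left boundary on `+`, the right on `-`).
#' A transcript intron exactly matching a template intron, an intron lying
#' strictly within a merged template exon, and a block lying inside a
#' template exon all emit nothing.
#'
#' When a skipping intron also has a shifted boundary, the ES event(s) are
#' emitted and, if `emit_side_with_es` is `TRUE` (default), the 5S/3S event
#' for the shifted boundary is emitted as well.
#'
#' @param aln A `spliced_alignment` assigned to the template's gene.
#' @param template A `gene_template` from [build_gene_template()].
#' @param emit_side_with_es Also emit the boundary-shift event when an intron
#'   both skips exon(s) and has one moved boundary.
#' @return `data.frame` with columns `gene_id`, `event_type`, `chrom`,
#'   `start`, `end`, `ecotype`, `transcript_id`; zero rows if the transcript
#'   is template-concordant.
#' @export
detect_events <- function(aln, template, emit_side_with_es = TRUE) {
  stopifnot(inherits(aln, "spliced_alignment"), inherits(template, "gene_template"))
  exons <- template$exons
  gaps <- template$introns
  plus <- template$strand == "+"
  gap_donor <- if (nrow(gaps)) (if (plus) gaps[, 1] else gaps[, 2]) else integer(0)
  gap_accep <- if (nrow(gaps)) (if (plus) gaps[, 2] else gaps[, 1]) else integer(0)

  type <- character(0); ev_s <- integer(0); ev_e <- integer(0)
  emit <- function(t, s, e) {
    type <<- c(type, t); ev_s <<- c(ev_s, s); ev_e <<- c(ev_e, e)
  }

  introns <- alignment_introns(aln)
  for (i in seq_len(nrow(introns))) {
    s <- introns[i, 1]; e <- introns[i, 2]
    if (nrow(gaps) && any(gaps[, 1] == s & gaps[, 2] == e)) next
    if (any(exons[, 1] <= s & e <= exons[, 2])) next  # splice inside merged exon
    donor_pos <- if (plus) s else e
    accep_pos <- if (plus) e else s
    donor_shared <- donor_pos %in% gap_donor
    accep_shared <- accep_pos %in% gap_accep
    skipped <- which(exons[, 1] >= s & exons[, 2] <= e)
    if (length(skipped)) {
      for (k in skipped) emit("ES", exons[k, 1], exons[k, 2])
      if (emit_side_with_es && xor(donor_shared, accep_shared))
        emit(if (accep_shared) "5S" else "3S", s, e)
    } else if (donor_shared && !accep_shared) {
      emit("3S", s, e)
    } else if (accep_shared && !donor_shared) {
      emit("5S", s, e)
    } else if (nrow(gaps) && any(gaps[, 1] < e & s < gaps[, 2])) {
      emit("3S5S", s, e)
    }
    # else: intron outside any template intron's reach -> nothing
  }

  # intron retention: block strictly covers a (gap or observed) intron
  cand <- unique(rbind(gaps, template$observed_introns))
  blocks <- aln$blocks
  for (j in seq_len(nrow(cand))) {
    js <- cand[j, 1]; je <- cand[j, 2]
    if (any(blocks[, 1] < js & blocks[, 2] > je)) emit("IR", js, je)
  }

  data.frame(gene_id = rep(template$gene_id, length(type)),
             event_type = type,
             chrom = rep(template$chrom, length(type)),
             start = ev_s, end = ev_e,
             ecotype = rep(aln$ecotype, length(type)),
             transcript_id = rep(aln$transcript_id, length(type)),
             stringsAsFactors = FALSE)
}

#' Detect events for all transcripts of one gene
#'
#' Builds the gene template from the supplied transcripts and runs
#' [detect_events()] for each transcript against it.
#'
#' @inheritParams build_gene_template
#' @inheritParams detect_events
#' @return Raw (pre-deduplication) events `data.frame` as in
#'   [detect_events()].
#' @export
detect_gene_events <- function(gene_id, transcripts, emit_side_with_es = TRUE) {
  template <- build_gene_template(gene_id, transcripts)
  out <- lapply(transcripts, detect_events, template = template,
                emit_side_with_es = emit_side_with_es)
  do.call(rbind, out)
}

#' Deduplicate raw events into distinct events with per-ecotype support
#'
#' Event identity is the tuple `(gene_id, event_type, start, end)`; raw
#' events sharing an identity are merged and their per-ecotype transcript
#' support summed. Multiple raw events from the same transcript count once.
#'
#' @param raw Raw events `data.frame` from [detect_gene_events()] (possibly
#'   row-bound over genes).
#' @param ecotypes Character vector of ecotype labels defining the support
#'   columns (order preserved in the output).
#' @return `data.frame` with one row per distinct event: `gene_id`,
#'   `event_type`, `chrom`, `start`, `end`, `support_<ecotype>` counts, and
#'   `confirmed` (initialised `NA`), sorted by `(chrom, start, end,
#'   event_type)`.
#' @export
deduplicate_events <- function(raw, ecotypes = c("head", "body")) {
  sup_cols <- paste0("support_", ecotypes)
  if (is.null(raw) || !nrow(raw)) {
    out <- data.frame(gene_id = character(0), event_type = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
    for (sc in sup_cols) out[[sc]] <- integer(0)
    out$confirmed <- logical(0)
    return(out)
  }
  raw <- unique(raw)  # one count per (event, transcript)
  key <- paste(raw$gene_id, raw$event_type, raw$start, raw$end, sep = "\r")
  first <- !duplicated(key)
  out <- raw[first, c("gene_id", "event_type", "chrom", "start", "end")]
  rownames(out) <- NULL
  idx <- match(key, key[first])
  for (k in seq_along(ecotypes)) {
    cnt <- tabulate(idx[raw$ecotype == ecotypes[k]], nbins = nrow(out))
    out[[sup_cols[k]]] <- cnt
  }
  out$confirmed <- NA
  out <- out[order(out$chrom, out$start, out$end, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
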