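# Brute-force definitional classifier: enumerates every (intron, template
# feature) and (block, candidate intron) pair with plain loops and applies
# the five event definitions literally. Kept deliberately naive and separate
# from the package's vectorised classifier; detect_events must agree with it
# on every instance.
oracle_detect <- function(aln, template, emit_side_with_es = TRUE) {
  exons <- template$exons
  gaps <- template$introns
  plus <- template$strand == "+"
  res <- list()
  emit <- function(t, s, e) res[[length(res) + 1]] <<- c(t, s, e)

  introns <- alignment_introns(aln)
  for (i in seq_len(nrow(introns))) {
    s <- introns[i, 1]; e <- introns[i, 2]
    exact <- FALSE
    for (g in seq_len(nrow(gaps)))
      if (gaps[g, 1] == s && gaps[g, 2] == e) exact <- TRUE
    if (exact) next
    inside <- FALSE
    for (x in seq_len(nrow(exons)))
      if (exons[x, 1] <= s && e <= exons[x, 2]) inside <- TRUE
    if (inside) next
    donor_pos <- if (plus) s else e
    accep_pos <- if (plus) e else s
    donor_shared <- FALSE; accep_shared <- FALSE; overlaps <- FALSE
    for (g in seq_len(nrow(gaps))) {
      gd <- if (plus) gaps[g, 1] else gaps[g, 2]
      ga <- if (plus) gaps[g, 2] else gaps[g, 1]
      if (gd == donor_pos) donor_shared <- TRUE
      if (ga == accep_pos) accep_shared <- TRUE
      if (gaps[g, 1] < e && s < gaps[g, 2]) overlaps <- TRUE
    }
    skipped <- integer(0)
    for (x in seq_len(nrow(exons)))
      if (exons[x, 1] >= s && exons[x, 2] <= e) skipped <- c(skipped, x)
    if (length(skipped) > 0) {
      for (x in skipped) emit("ES", exons[x, 1], exons[x, 2])
      if (emit_side_with_es && (donor_shared != accep_shared))
        emit(if (accep_shared) "5S" else "3S", s, e)
    } else if (donor_shared && !accep_shared) emit("3S", s, e)
    else if (accep_shared && !donor_shared) emit("5S", s, e)
    else if (!donor_shared && !accep_shared && overlaps) emit("3S5S", s, e)
  }

  cand <- unique(rbind(gaps, template$observed_introns))
  for (j in seq_len(nrow(cand))) {
    covered <- FALSE
    for (b in seq_len(nrow(aln$blocks)))
      if (aln$blocks[b, 1] < cand[j, 1] && aln$blocks[b, 2] > cand[j, 2])
        covered <- TRUE
    if (covered) emit("IR", cand[j, 1], cand[j, 2])
  }

  if (!length(res)) return(data.frame(event_type = character(0),
                                      start = integer(0), end = integer(0)))
  m <- do.call(rbind, res)
  data.frame(event_type = m[, 1], start = as.integer(m[, 2]),
             end = as.integer(m[, 3]), stringsAsFactors = FALSE)
}

# Canonical sorted event-key representation for comparing two classifiers.
event_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$event_type, df$start, df$end))
}
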