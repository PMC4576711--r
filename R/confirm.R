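#' Confirm AS events against short-read splice junctions
#'
#' An event is confirmed iff some junction end (donor or acceptor position,
#' same chromosome) equals the event's start or end exactly. Matching is
#' coordinate-only; junction strand is ignored. All events are returned with
#' the `confirmed` flag set.
#'
#' @param events Distinct-events `data.frame` from [deduplicate_events()].
#' @param jset A `junction_set` from [read_junctions()] / [junction_set()].
#' @return `events` with `confirmed` filled in.
#' @export
confirm_events <- function(events, jset) {
  events$confirmed <- junction_site_lookup(jset, events$chrom, events$start) |
    junction_site_lookup(jset, events$chrom, events$end)
  events
}

#' Confirmation rate as a percentage
#'
#' @param n_confirmed,n_total Confirmed and total distinct event counts.
#' @return `100 * n_confirmed / n_total`.
#' @export
confirmation_rate <- function(n_confirmed, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  100 * n_confirmed / n_total
}

#' Partition counts from per-ecotype observation totals
#'
#' Inclusion-exclusion arithmetic over confirmed events: given how many
#' confirmed events were observed in each ecotype and the total number of
#' confirmed events, derive the shared and ecotype-specific counts. The
#' identities `shared = observed_A + observed_B - total`,
#' `specific_A = total - observed_B`, `specific_B = total - observed_A`, and
#' `specific_A + specific_B + shared = total` are asserted.
#'
#' @param observed_A,observed_B Confirmed events with support in ecotype A
#'   (resp. B).
#' @param total Total confirmed events (the union).
#' @return List with `total_confirmed`, `observed_A`, `observed_B`, `shared`,
#'   `specific_A`, `specific_B`.
#' @export
partition_counts <- function(observed_A, observed_B, total) {
  shared <- observed_A + observed_B - total
  specific_A <- total - observed_B
  specific_B <- total - observed_A
  if (shared < 0 || specific_A < 0 || specific_B < 0)
    stop("inconsistent partition inputs (negative derived count)")
  stopifnot(specific_A + specific_B + shared == total)
  list(total_confirmed = total, observed_A = observed_A, observed_B = observed_B,
       shared = shared, specific_A = specific_A, specific_B = specific_B)
}

#' Partition confirmed events by ecotype specificity
#'
#' Labels every confirmed event `shared` (support in both ecotypes),
#' `A_only`, or `B_only` (support in exactly one), and computes the partition
#' counts. Specificity is presence/absence of support, not a differential
#' test. Unconfirmed events must be filtered out by the caller
#' ([confirmed_only()]).
#'
#' @param events Confirmed distinct-events `data.frame`.
#' @param ecotypes Length-2 character vector naming the support columns
#'   (`ecotypes[1]` is "A").
#' @return List with `events` (input plus a `specificity` column using the
#'   actual ecotype labels, e.g. `"head_only"`) and `counts`
#'   (see [partition_counts()]).
#' @export
partition_specificity <- function(events, ecotypes = c("head", "body")) {
  sup_a <- events[[paste0("support_", ecotypes[1])]]
  sup_b <- events[[paste0("support_", ecotypes[2])]]
  if (any(sup_a + sup_b == 0)) stop("event with zero total support")
  lab <- ifelse(sup_a > 0 & sup_b > 0, "shared",
                ifelse(sup_a > 0, paste0(ecotypes[1], "_only"),
                       paste0(ecotypes[2], "_only")))
  counts <- partition_counts(sum(sup_a > 0), sum(sup_b > 0), nrow(events))
  stopifnot(counts$shared == sum(lab == "shared"),
            counts$specific_A == sum(lab == paste0(ecotypes[1], "_only")),
            counts$specific_B == sum(lab == paste0(ecotypes[2], "_only")))
  events$specificity <- lab
  list(events = events, counts = counts)
}

#' Keep only confirmed events
#'
#' @param events Events `data.frame` with a `confirmed` column.
#' @return The confirmed subset.
#' @export
confirmed_only <- function(events) {
  ev <- events[!is.na(events$confirmed) & events$confirmed, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Gene sets by ecotype-specific AS
#'
#' A gene enters the A-specific set iff at least one of its events is labeled
#' A-only (similarly for B). The union identity
#' `|union| = |A| + |B| - |both|` is asserted.
#'
#' @param labeled_events Events `data.frame` with a `specificity` column from
#'   [partition_specificity()].
#' @param ecotypes Length-2 character vector of ecotype labels.
#' @return List with `genes_specific_A`, `genes_specific_B`, `genes_both`,
#'   `genes_union` (character vectors of gene ids).
#' @export
gene_specificity_sets <- function(labeled_events, ecotypes = c("head", "body")) {
  a <- unique(labeled_events$gene_id[
    labeled_events$specificity == paste0(ecotypes[1], "_only")])
  b <- unique(labeled_events$gene_id[
    labeled_events$specificity == paste0(ecotypes[2], "_only")])
  both <- intersect(a, b)
  un <- union(a, b)
  stopifnot(length(un) == length(a) + length(b) - length(both))
  list(genes_specific_A = sort(a), genes_specific_B = sort(b),
       genes_both = sort(both), genes_union = sort(un))
}

#' Gene-union count from printed set sizes
#'
#' Inclusion-exclusion on gene counts: `n_A + n_B - n_both`.
#'
#' @param n_A,n_B Genes with events specific to ecotype A (resp. B).
#' @param n_both Genes in both sets.
#' @return The union count.
#' @export
gene_union_count <- function(n_A, n_B, n_both) {
  if (n_both > min(n_A, n_B)) stop("n_both exceeds a set size")
  n_A + n_B - n_both
}
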