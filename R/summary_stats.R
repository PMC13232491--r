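#' Nx contiguity statistic
#'
#' Length of the scaffold at which the cumulative sum of descending-sorted
#' scaffold lengths first reaches `x` percent of the total span (the
#' threshold is inclusive: cumulative length >= x% of span).
#'
#' @param sorted_lengths Numeric vector of scaffold lengths, non-increasing.
#' @param x Percentage in (0, 100].
#' @return The Nx length in bases.
#' @examples
#' compute_nx(c(50, 40, 30, 20, 10), 50) # 40
#' compute_nx(c(50, 40, 30, 20, 10), 90) # 20
#' @export
compute_nx <- function(sorted_lengths, x) {
  if (length(sorted_lengths) == 0) stop("empty length vector")
  if (is.unsorted(rev(sorted_lengths))) {
    stop("lengths must be sorted in non-increasing order")
  }
  if (x <= 0 || x > 100) stop("x must be in (0, 100]")
  span <- sum(sorted_lengths)
  cum <- cumsum(sorted_lengths)
  # tolerance absorbs binary rounding of x/100 * span at exact thresholds
  threshold <- x / 100 * span - 1e-9 * span
  sorted_lengths[which(cum >= threshold)[1]]
}

#' auN (E-size) contiguity statistic
#'
#' auN is the sum of squared scaffold lengths divided by the assembly span:
#' the expected length of the scaffold containing a randomly chosen base.
#' The adjusted variant substitutes the squared count of ACGT (non-N) bases
#' per scaffold into the numerator while keeping the full span, including
#' Ns, as the denominator, penalising assemblies whose contiguity rests on
#' long runs of N.
#'
#' @param records A `snail_records` data frame.
#' @param adjusted Use the N-adjusted numerator?
#' @return auN in bases.
#' @export
compute_aun <- function(records, adjusted = FALSE) {
  len <- records$length
  span <- sum(len)
  if (length(len) == 0 || span <= 0) stop("zero assembly span")
  num <- if (adjusted) (len - records$n_count)^2 else len^2
  sum(num) / span
}

#' Whole-assembly summary statistics
#'
#' @param records A `snail_records` data frame.
#' @return An `assembly_summary` list: `span`, `scaffold_count`, `longest`,
#'   `n50`, `n90`, `aun`, `adjusted_aun`, `gc_fraction`, `at_fraction`,
#'   `n_fraction`, and `sorted_lengths` (descending). GC and AT fractions
#'   are proportions of ATGC bases; the N fraction is a proportion of span.
#' @export
summarize_assembly <- function(records) {
  stopifnot(nrow(records) > 0)
  # explicit secondary key: ties keep input order
  ord <- order(-records$length, seq_len(nrow(records)))
  sorted <- records$length[ord]
  span <- sum(sorted)
  atgc <- sum(records$gc_count) + sum(records$at_count)
  structure(list(
    span = span,
    scaffold_count = nrow(records),
    longest = sorted[1],
    n50 = compute_nx(sorted, 50),
    n90 = compute_nx(sorted, 90),
    aun = compute_aun(records, adjusted = FALSE),
    adjusted_aun = compute_aun(records, adjusted = TRUE),
    gc_fraction = if (atgc > 0) sum(records$gc_count) / atgc else 0,
    at_fraction = if (atgc > 0) sum(records$at_count) / atgc else 0,
    n_fraction = sum(records$n_count) / span,
    sorted_lengths = sorted
  ), class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Assembly summary: span %s, %d scaffolds\n",
           "  longest %s, N50 %s, N90 %s\n",
           "  auN %s, adjusted auN %s\n",
           "  GC %.2f%%, N %.2f%%\n"),
    format(x$span, big.mark = ","), x$scaffold_count,
    format(x$longest, big.mark = ","), format(x$n50, big.mark = ","),
    format(x$n90, big.mark = ","),
    format(round(x$aun), big.mark = ","),
    format(round(x$adjusted_aun), big.mark = ","),
    100 * x$gc_fraction, 100 * x$n_fraction))
  invisible(x)
}

#' Per-segment bin series for the circular axis
#'
#' Scaffolds are laid end-to-end in descending length order (stable for
#' ties) along a cumulative-span axis divided into `segments` equal bins of
#' width `max_span / segments`. A scaffold overlaps a bin iff its half-open
#' `[start, end)` interval intersects the bin's half-open interval. Bins
#' entirely beyond the assembly span (possible when `max_span` exceeds the
#' span) are flagged `empty`.
#'
#' @param records A `snail_records` data frame.
#' @param segments Number of bins (>= 1); the plot's polygon side count.
#' @param max_span Cumulative axis extent in bases; defaults to the span.
#' @return Data frame with one row per bin: `index` (0-based),
#'   `span_start`, `span_end`, `min_length`, `max_length`, `gc_mean`,
#'   `gc_min`, `gc_max`, `n_fraction_mean`, `cumulative_count`, `empty`.
#' @export
bin_assembly <- function(records, segments = 1000, max_span = NULL) {
  if (!is.numeric(segments) || segments < 1) {
    stop("segments must be an integer >= 1")
  }
  segments <- as.integer(segments)
  ord <- order(-records$length, seq_len(nrow(records)))
  len <- records$length[ord]
  gc_count <- records$gc_count[ord]
  at_count <- records$at_count[ord]
  n_count <- records$n_count[ord]
  atgc <- gc_count + at_count
  gc_prop <- ifelse(atgc > 0, gc_count / atgc, 0)
  n_prop <- n_count / len

  span <- sum(len)
  if (is.null(max_span)) max_span <- span
  if (max_span < span) max_span <- span
  ends <- cumsum(len)
  starts <- ends - len
  width <- max_span / segments

  idx <- seq_len(segments) - 1L
  bin_start <- idx * width
  bin_end <- bin_start + width
  # scaffolds overlap a contiguous index range per bin
  first <- findInterval(bin_start, ends) + 1L
  last <- findInterval(bin_end, starts, left.open = TRUE)

  n_bins <- segments
  min_length <- max_length <- gc_mean <- gc_min <- gc_max <-
    n_fraction_mean <- rep(NA_real_, n_bins)
  cumulative_count <- pmin(last, length(len))
  empty <- first > length(len) | first > last
  for (b in which(!empty)) {
    i <- first[b]:last[b]
    min_length[b] <- len[last[b]]
    max_length[b] <- len[first[b]]
    g <- gc_prop[i]
    gc_mean[b] <- mean(g)
    gc_min[b] <- min(g)
    gc_max[b] <- max(g)
    n_fraction_mean[b] <- mean(n_prop[i])
  }
  cumulative_count <- cummax(cumulative_count)
  data.frame(index = idx, span_start = bin_start, span_end = bin_end,
             min_length = min_length, max_length = max_length,
             gc_mean = gc_mean, gc_min = gc_min, gc_max = gc_max,
             n_fraction_mean = n_fraction_mean,
             cumulative_count = cumulative_count, empty = empty)
}

#' Summarize BUSCO completeness
#'
#' Resolves each distinct marker to a single status from its retained hits:
#' Duplicated when two or more Complete/Duplicated hits remain, Complete
#' (single) when exactly one remains, Fragmented when only fragmented hits
#' remain, Missing otherwise. `complete` includes both single and
#' duplicated markers (BUSCO convention). When `filter_scaffolds` is given,
#' hits on excluded scaffolds are dropped before status resolution, so a
#' duplicated marker can resolve to Complete-single after filtering.
#'
#' @param genes Data frame of BUSCO hits (see [parse_busco_table()]).
#' @param filter_scaffolds Optional character vector of retained scaffold
#'   identifiers.
#' @param lineage Lineage label carried through to the summary.
#' @return A `busco_summary` list: `lineage`, `total`, per-status counts,
#'   and `complete_fraction`, `single_fraction`, `duplicated_fraction`,
#'   `fragmented_fraction`, `missing_fraction` over distinct markers.
#' @export
summarize_busco <- function(genes, filter_scaffolds = NULL,
                            lineage = "unknown") {
  stopifnot(nrow(genes) > 0)
  ids <- unique(genes$busco_id)
  retained <- genes[!is.na(genes$scaffold_id), , drop = FALSE]
  if (!is.null(filter_scaffolds)) {
    retained <- retained[retained$scaffold_id %in% filter_scaffolds, ,
                         drop = FALSE]
  }
  complete_hits <- retained[retained$status %in% c("Complete", "Duplicated"), ]
  n_complete_hits <- table(factor(complete_hits$busco_id, levels = ids))
  any_frag <- ids %in% retained$busco_id[retained$status == "Fragmented"]

  status <- ifelse(n_complete_hits >= 2, "Duplicated",
            ifelse(n_complete_hits == 1, "Complete",
            ifelse(any_frag, "Fragmented", "Missing")))
  total <- length(ids)
  n_single <- sum(status == "Complete")
  n_dup <- sum(status == "Duplicated")
  n_frag <- sum(status == "Fragmented")
  n_miss <- sum(status == "Missing")
  structure(list(
    lineage = lineage, total = total,
    single = n_single, duplicated = n_dup, fragmented = n_frag,
    missing = n_miss,
    complete_fraction = (n_single + n_dup) / total,
    single_fraction = n_single / total,
    duplicated_fraction = n_dup / total,
    fragmented_fraction = n_frag / total,
    missing_fraction = n_miss / total
  ), class = "busco_summary")
}
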