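#' Relative auN
#'
#' auN divided by the longest scaffold length: a scale-independent
#' contiguity value in (0, 1]. It equals 1 only when the assembly is a
#' single scaffold or all scaffolds have equal length.
#'
#' @param aun auN in bases.
#' @param longest Longest scaffold length in bases.
#' @return Unitless value in (0, 1].
#' @examples
#' relative_aun(185.42, 260.32) # ~0.71
#' @export
relative_aun <- function(aun, longest) {
  if (longest <= 0) stop("longest scaffold length must be positive")
  if (aun <= 0) stop("auN must be positive")
  if (aun > longest * (1 + 1e-9)) stop("auN cannot exceed the longest scaffold")
  min(aun / longest, 1)
}

#' Snail score (adjusted relative auN)
#'
#' The N-adjusted auN divided by the longest scaffold length (including
#' Ns). Equal to the relative auN for assemblies with no Ns, and below it
#' when contiguity rests on N runs.
#'
#' @param adjusted_aun Adjusted auN in bases (see [compute_aun()]).
#' @param longest Longest scaffold length in bases, including Ns.
#' @return Unitless score in (0, 1].
#' @examples
#' snail_score(24.82, 32.08) # ~0.77
#' @export
snail_score <- function(adjusted_aun, longest) {
  relative_aun(adjusted_aun, longest)
}

#' Expected-size corrections of the snail score
#'
#' Four corrected variants guard against inflation of the base score:
#' \describe{
#'   \item{g}{`base * min(1, span / expected_span)` — penalises assemblies
#'     shorter than the expected genome size (over-filtering, incomplete
#'     assembly).}
#'   \item{gs}{`g * min(1, longest / expected_longest)` — additionally
#'     penalises a longest scaffold shorter than the expected longest
#'     chromosome.}
#'   \item{ag}{absolute variant of g: when the span ratio exceeds one the
#'     inverse ratio is applied instead of clamping, penalising spans
#'     larger than expected (non-target data, uncollapsed heterozygosity).}
#'   \item{ags}{absolute variant of gs, chained from the clamped g:
#'     `g * f(longest / expected_longest)` where `f` takes the inverse of
#'     ratios above one.}
#' }
#' Variants whose expectation is absent are returned as `NA`.
#'
#' @param base Base snail score in (0, 1].
#' @param span Assembly span in bases.
#' @param longest Longest scaffold length in bases.
#' @param expected_span Expected genome size in bases, or `NULL`.
#' @param expected_longest Expected longest scaffold length, or `NULL`.
#' @param relative_aun Optional unadjusted relative auN carried into the
#'   returned set for reporting.
#' @return A `snail_scores` list: `relative_aun`, `base`, `g`, `gs`, `ag`,
#'   `ags`, `expected_span`, `expected_longest`.
#' @examples
#' correct_scores(0.237, span = 38.0, longest = 0.5,
#'                expected_span = 43.3, expected_longest = 8.9)
#' @export
correct_scores <- function(base, span, longest, expected_span = NULL,
                           expected_longest = NULL, relative_aun = NA_real_) {
  if (base <= 0 || base > 1) stop("base score must be in (0, 1]")
  if (!is.null(expected_span) && expected_span <= 0) {
    stop("expected_span must be positive")
  }
  if (!is.null(expected_longest) && expected_longest <= 0) {
    stop("expected_longest must be positive")
  }
  clamp <- function(r) min(1, r)
  absf <- function(r) if (r <= 1) r else 1 / r

  g <- gs <- ag <- ags <- NA_real_
  if (!is.null(expected_span)) {
    r_g <- span / expected_span
    g <- base * clamp(r_g)
    ag <- base * absf(r_g)
    if (!is.null(expected_longest)) {
      r_s <- longest / expected_longest
      gs <- g * clamp(r_s)
      ags <- g * absf(r_s)
    }
  }
  structure(list(
    relative_aun = relative_aun, base = base,
    g = g, gs = gs, ag = ag, ags = ags,
    expected_span = expected_span %||% NA_real_,
    expected_longest = expected_longest %||% NA_real_
  ), class = "snail_scores")
}

#' Score an assembly, optionally against a reference
#'
#' Convenience wrapper computing the relative auN, base snail score, and
#' corrected variants from an [summarize_assembly()] result. Expectations
#' default to the reference assembly's span and longest scaffold; explicit
#' `expected_span` / `expected_longest` values override the
#' reference-derived ones.
#'
#' @param summary An `assembly_summary`.
#' @param reference Optional `assembly_summary` of a reference (e.g. T2T)
#'   assembly.
#' @param expected_span,expected_longest Optional explicit expectations in
#'   bases.
#' @return A `snail_scores` list (see [correct_scores()]).
#' @export
score_assembly <- function(summary, reference = NULL, expected_span = NULL,
                           expected_longest = NULL) {
  if (!is.null(reference)) {
    expected_span <- expected_span %||% reference$span
    expected_longest <- expected_longest %||% reference$longest
  }
  correct_scores(
    base = snail_score(summary$adjusted_aun, summary$longest),
    span = summary$span, longest = summary$longest,
    expected_span = expected_span, expected_longest = expected_longest,
    relative_aun = relative_aun(summary$aun, summary$longest)
  )
}

#' @export
print.snail_scores <- function(x, ...) {
  cat(sprintf("Snail score: %.3f (relative auN %.3f)\n", x$base,
              x$relative_aun))
  for (v in c("g", "gs", "ag", "ags")) {
    if (!is.na(x[[v]])) cat(sprintf("  snail-%s: %.3f\n", toupper(v), x[[v]]))
  }
  invisible(x)
}
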