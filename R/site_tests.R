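## Per-site exact statistics for RDD calling.
##
## Two independent per-site tests gate every call, mirroring the practice of
## cross-checking editing candidates with two variant-calling suites:
##   * a one-sided binomial test against a fixed sequencing-error rate
##     (REDItools-style error model), and
##   * a one-sided Fisher's exact test of the observed alt support against
##     the expected error count at the site's depth (VarScan-style).
## Multiple testing across candidate sites is controlled by the
## Benjamini-Hochberg step-up on the per-site maximum of the two p-values.

#' One-sided binomial test of alt support against the error model
#'
#' Computes `P(X >= alt_count)` for `X ~ Binomial(depth, error_rate)`: the
#' probability of observing at least the seen variant support if every
#' variant base were a sequencing error.
#'
#' @param alt_count reads supporting the variant (vectorized).
#' @param depth quality-passing depth at the site (vectorized).
#' @param error_rate assumed per-base error probability.
#' @return p-value(s) in \[0, 1\].
#' @examples
#' binomial_site_test(3, 10, 0.01)   # ~1.14e-4
#' binomial_site_test(0, 10, 0.01)   # 1: no evidence at zero support
#' @export
binomial_site_test <- function(alt_count, depth, error_rate) {
  check_that(all(depth >= 1), "depth must be >= 1")
  check_that(all(alt_count >= 0 & alt_count <= depth),
             "alt_count must lie in [0, depth]")
  check_that(error_rate > 0 && error_rate < 1, "error_rate must be in (0, 1)")
  stats::pbinom(alt_count - 1, depth, error_rate, lower.tail = FALSE)
}

#' One-sided Fisher's exact test of alt support against expected errors
#'
#' Tests enrichment of the variant in the observed counts relative to the
#' expectation under the error model, on the 2x2 table
#' `[[alt_count, depth - alt_count], [e, depth - e]]` with
#' `e = round(error_rate * depth)`. The one-sided (enrichment) p-value is
#' the hypergeometric upper tail with the table's margins fixed. At minimal
#' depth `e` is 0 and the test is weak; this is a property of the design,
#' not corrected for.
#'
#' @inheritParams binomial_site_test
#' @return p-value(s) in \[0, 1\].
#' @examples
#' fisher_site_test(3, 10, 0.01)    # ~0.105: weak at low depth
#' fisher_site_test(10, 10, 0.01)   # ~5.4e-6
#' @export
fisher_site_test <- function(alt_count, depth, error_rate) {
  check_that(all(depth >= 1), "depth must be >= 1")
  check_that(all(alt_count >= 0 & alt_count <= depth),
             "alt_count must lie in [0, depth]")
  check_that(error_rate > 0 && error_rate < 1, "error_rate must be in (0, 1)")
  e <- round(error_rate * depth)
  ## P(X >= alt_count) for X ~ Hypergeom drawing `alt_count + e` successes
  ## out of two rows of size `depth`; identical to
  ## fisher.test(matrix(c(a, e, depth-a, depth-e), 2), alternative="greater")
  stats::phyper(alt_count - 1, depth, depth, alt_count + e,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values in the input order (wrapper over
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in \[0, 1\]; may be empty.
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  check_that(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
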