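# Independent enumeration oracles for the per-site exact tests, built from
# log-factorials only (no pbinom/phyper) so they can vouch for the
# implementation.

binom_tail_oracle <- function(alt, depth, eps) {
  if (alt <= 0) return(1)
  k <- alt:depth
  sum(exp(lchoose(depth, k) + k * log(eps) + (depth - k) * log1p(-eps)))
}

fisher_tail_oracle <- function(alt, depth, eps) {
  # one-sided enrichment p over all admissible 2x2 tables with row sums
  # (depth, depth) and first-column sum alt + e
  e <- round(eps * depth)
  draws <- alt + e
  lo <- max(0, draws - depth)
  hi <- min(depth, draws)
  k <- lo:hi
  probs <- exp(lchoose(depth, k) + lchoose(depth, draws - k) -
                 lchoose(2 * depth, draws))
  sum(probs[k >= alt])
}
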