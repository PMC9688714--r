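## RDD calling from a quality-filtered pileup.

## Filter labels, in attrition (first-failure) order.
CALL_FILTERS <- c("snp_mask", "min_depth", "min_alt_support", "min_freq",
                  "p_binomial", "p_fisher", "q_value")

#' Call RNA:DNA difference sites from a pileup
#'
#' Every pileup position carrying at least one non-reference base is a
#' candidate. The variant base is the most abundant non-reference base
#' (ties broken lexicographically A < C < G < T for determinism). Each
#' candidate gets both per-site exact tests: the binomial error-model test
#' is FDR-controlled (Benjamini-Hochberg q-values across all candidates,
#' the usual pairing for REDItools-style per-site statistics), while the
#' Fisher's exact test is thresholded at its raw p-value
#' (VarScan-style). A site must be significant under both, the conservative
#' intersection of the two suites.
#'
#' A candidate passes iff all of the following hold: it is not in the SNP
#' mask, `depth >= min_depth`, `alt_count >= min_alt_support`,
#' `frequency >= min_freq`, both p-values `<= alpha`, and
#' `q_value <= alpha`. All candidates are retained with per-filter failure
#' flags for audit.
#'
#' @param pileup a `pileup` data.frame from [build_pileup()].
#' @param snp_mask `NULL`, a VCF path, or a data.frame with chrom/pos
#'   columns (e.g. from [read_snp_mask()]). Masked positions never pass.
#'   Mask entries on contigs unknown to the pileup's reference are ignored
#'   with a warning.
#' @param config a [filter_config()].
#' @return a data.frame of class `rdd_calls`: chrom, pos, ref, alt, depth,
#'   alt_count, frequency, p_binomial, p_fisher, q_value, passed, flags
#'   (comma-joined failed filters, "" when passed).
#' @export
call_rdd_sites <- function(pileup, snp_mask = NULL,
                           config = filter_config()) {
  validate_filter_config(config)
  check_that(inherits(pileup, "pileup") ||
               all(c("chrom", "pos", "ref", BASES, "depth") %in% names(pileup)),
             "pileup must come from build_pileup()")

  mask <- snp_mask
  if (is.character(mask)) mask <- read_snp_mask(mask)
  if (!is.null(mask) && nrow(mask)) {
    contigs <- attr(pileup, "contigs")
    if (!is.null(contigs)) {
      unknown <- setdiff(unique(mask$chrom), contigs)
      if (length(unknown)) {
        warning("SNP mask entries on unknown contigs ignored: ",
                paste(unknown, collapse = ", "), call. = FALSE)
        mask <- mask[!mask$chrom %in% unknown, , drop = FALSE]
      }
    }
  }

  empty <- data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), depth = integer(), alt_count = integer(),
    frequency = numeric(), p_binomial = numeric(), p_fisher = numeric(),
    q_value = numeric(), passed = logical(), flags = character(),
    stringsAsFactors = FALSE)
  if (!nrow(pileup)) {
    class(empty) <- c("rdd_calls", "data.frame")
    return(empty)
  }

  cm <- as.matrix(pileup[, BASES])
  ref_idx <- match(pileup$ref, BASES)
  alt_counts <- cm
  alt_counts[cbind(seq_len(nrow(cm)), ref_idx)] <- -1L  # exclude ref base
  ## most abundant non-reference base; which.max on the row takes the first
  ## (lexicographically smallest) base on ties
  alt_idx <- max.col(alt_counts, ties.method = "first")
  alt_count <- cm[cbind(seq_len(nrow(cm)), alt_idx)]

  cand <- which(alt_count > 0 & !is.na(ref_idx))
  if (!length(cand)) {
    class(empty) <- c("rdd_calls", "data.frame")
    return(empty)
  }

  calls <- data.frame(
    chrom = pileup$chrom[cand],
    pos = pileup$pos[cand],
    ref = pileup$ref[cand],
    alt = BASES[alt_idx[cand]],
    depth = pileup$depth[cand],
    alt_count = alt_count[cand],
    stringsAsFactors = FALSE)
  calls$frequency <- calls$alt_count / calls$depth
  calls$p_binomial <- binomial_site_test(calls$alt_count, calls$depth,
                                         config$error_rate)
  calls$p_fisher <- fisher_site_test(calls$alt_count, calls$depth,
                                     config$error_rate)
  calls$q_value <- fdr_adjust(calls$p_binomial)

  in_mask <- rep(FALSE, nrow(calls))
  if (!is.null(mask) && nrow(mask)) {
    in_mask <- paste(calls$chrom, calls$pos) %in% paste(mask$chrom, mask$pos)
  }
  fails <- cbind(
    snp_mask = in_mask,
    min_depth = calls$depth < config$min_depth,
    min_alt_support = calls$alt_count < config$min_alt_support,
    min_freq = calls$frequency < config$min_freq,
    p_binomial = calls$p_binomial > config$alpha,
    p_fisher = calls$p_fisher > config$alpha,
    q_value = calls$q_value > config$alpha)
  calls$passed <- rowSums(fails) == 0L
  calls$flags <- apply(fails, 1L, function(f)
    paste(CALL_FILTERS[f], collapse = ","))
  class(calls) <- c("rdd_calls", "data.frame")
  calls
}

#' Per-filter attrition of RDD candidates
#'
#' Counts candidates removed at each filter, attributing every failing
#' candidate to its first failing filter in the order snp_mask, min_depth,
#' min_alt_support, min_freq, p_binomial, p_fisher, q_value, so that counts
#' telescope: `n_candidates = n_passed + sum(removed per filter)`.
#'
#' @param calls an `rdd_calls` data.frame.
#' @return named list: n_candidates, n_passed, removed (named integer
#'   vector over filters).
#' @export
call_attrition <- function(calls) {
  first_fail <- vapply(strsplit(calls$flags, ",", fixed = TRUE),
                       function(f) if (length(f)) f[[1]] else NA_character_,
                       "")
  removed <- vapply(CALL_FILTERS,
                    function(f) sum(first_fail == f, na.rm = TRUE), 0L)
  list(n_candidates = nrow(calls),
       n_passed = sum(calls$passed),
       removed = removed)
}

#' Write RDD calls as TSV and as a minimal VCF
#'
#' @param calls an `rdd_calls` data.frame.
#' @param tsv_path output TSV path, or `NULL` to skip.
#' @param vcf_path output VCF path for passing calls, or `NULL` to skip.
#' @return invisibly, a list of the written paths.
#' @export
write_rdd_calls <- function(calls, tsv_path = NULL, vcf_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    pass <- calls[calls$passed, , drop = FALSE]
    header <- c("##fileformat=VCFv4.2",
                "##source=editomeR-rdd-caller",
                paste0('##INFO=<ID=DP,Number=1,Type=Integer,',
                       'Description="Quality-passing depth">'),
                paste0('##INFO=<ID=AF,Number=1,Type=Float,',
                       'Description="Editing frequency">'),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- character(0)
    if (nrow(pass)) {
      body <- paste(pass$chrom, pass$pos, ".", pass$ref, pass$alt, ".",
                    "PASS",
                    sprintf("DP=%d;AF=%.4f", pass$depth, pass$frequency),
                    sep = "\t")
    }
    writeLines(c(header, body), vcf_path)
  }
  invisible(list(tsv = tsv_path, vcf = vcf_path))
}
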