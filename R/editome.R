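## Editome classification, annotation, summary and comparison.

#' The 12 reference-strand mismatch types
#'
#' Ordered vector of the twelve possible ref->alt mismatch classes on the
#' reference strand.
#' @export
RDD_TYPES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
               "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Genomic feature classes, in annotation precedence order
#'
#' A site overlapping several features receives the highest-precedence one;
#' a site overlapping nothing is `intergenic`.
#' @export
FEATURE_CLASSES <- c("exonic", "utr5", "utr3", "ncRNA_exonic", "intronic",
                     "ncRNA_intronic", "updownstream", "intergenic")

EDITING_CLASSES <- c("A-to-I", "C-to-U", "other")

#' Classify a mismatch into one of the 12 RDD types
#'
#' @param ref_base,alt_base character vectors of A/C/G/T; `ref != alt`.
#' @return character vector of types (e.g. `"A>G"`), factor levels
#'   [RDD_TYPES].
#' @examples
#' classify_mismatch("A", "G")
#' @export
classify_mismatch <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  check_that(all(ref_base %in% BASES) && all(alt_base %in% BASES),
             "bases must be A/C/G/T")
  check_that(all(ref_base != alt_base),
             "reference and alternate base must differ")
  paste0(ref_base, ">", alt_base)
}

#' Resolve the biological editing class of a mismatch
#'
#' A-to-I (ADAR) editing reads as A>G on the edited strand, C-to-U (APOBEC)
#' as C>T; on a minus-strand gene these appear as T>C and G>A on the
#' reference strand. With unknown strand (`"*"`), A>G and C>T are classified
#' on the plus-strand reading (flag such calls low-confidence downstream)
#' while T>C and G>A are left `other`. All remaining mismatches are `other`:
#' they carry no deamination signature.
#'
#' @param rdd_type character vector of types from [classify_mismatch()].
#' @param gene_strand character vector in `+`, `-`, `*` (unknown).
#' @return character vector in `A-to-I`, `C-to-U`, `other`.
#' @examples
#' resolve_editing_class("T>C", "-")   # A-to-I on the opposite strand
#' @export
resolve_editing_class <- function(rdd_type, gene_strand) {
  check_that(all(rdd_type %in% RDD_TYPES), "unknown RDD type")
  gene_strand[gene_strand %in% c("unknown", ".", NA)] <- "*"
  check_that(all(gene_strand %in% c("+", "-", "*")),
             "gene_strand must be one of +, -, *")
  out <- rep("other", length(rdd_type))
  out[(rdd_type == "A>G" & gene_strand %in% c("+", "*")) |
        (rdd_type == "T>C" & gene_strand == "-")] <- "A-to-I"
  out[(rdd_type == "C>T" & gene_strand %in% c("+", "*")) |
        (rdd_type == "G>A" & gene_strand == "-")] <- "C-to-U"
  out
}

#' Annotate genomic positions with feature class, gene and strand
#'
#' Overlaps positions with the feature annotation and resolves multiple
#' overlaps by precedence `exonic > utr5 > utr3 > ncRNA_exonic > intronic >
#' ncRNA_intronic > updownstream`; remaining ties (same class in several
#' genes) go to the lexicographically smallest gene identifier. Positions
#' overlapping nothing are `intergenic` with empty gene and `*` strand.
#'
#' @param chrom,pos character / integer vectors (1-based positions).
#' @param features annotation data.frame (chrom, start, end, strand, gene,
#'   feature) as from [simulate_reference()] or [read_features()].
#' @return data.frame with columns feature, gene, gene_strand, parallel to
#'   the input.
#' @export
annotate_region <- function(chrom, pos, features) {
  check_that(all(features$start <= features$end),
             "malformed annotation interval: start > end")
  check_that(all(features$feature %in% setdiff(FEATURE_CLASSES, "intergenic")),
             "unknown feature class in annotation")
  n <- length(pos)
  out <- data.frame(feature = rep("intergenic", n),
                    gene = rep("", n),
                    gene_strand = rep("*", n),
                    stringsAsFactors = FALSE)
  if (!n || !nrow(features)) return(out)

  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  gr <- features_to_granges(features)
  hits <- GenomicRanges::findOverlaps(sites, gr, ignore.strand = TRUE)
  if (!length(hits)) return(out)

  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  prec <- match(features$feature[sh], FEATURE_CLASSES)
  ord <- order(qh, prec, features$gene[sh])
  best <- ord[!duplicated(qh[ord])]
  out$feature[qh[best]] <- features$feature[sh[best]]
  out$gene[qh[best]] <- features$gene[sh[best]]
  out$gene_strand[qh[best]] <- features$strand[sh[best]]
  out
}

#' Annotate RDD calls with mismatch type, editing class and genomic feature
#'
#' @param calls an `rdd_calls` data.frame (all rows are annotated; filter on
#'   `passed` first if only accepted calls are wanted).
#' @param features annotation data.frame.
#' @return data.frame of class `annotated_edits`: the call columns plus
#'   rdd_type, feature, gene, gene_strand, editing_class and
#'   strand_confidence (`"low"` for intergenic/unknown-strand sites whose
#'   class is assigned on the plus-strand reading).
#' @export
annotate_edits <- function(calls, features) {
  ann <- annotate_region(calls$chrom, calls$pos, features)
  out <- calls
  out$rdd_type <- if (nrow(calls)) classify_mismatch(calls$ref, calls$alt)
                  else character(0)
  out$feature <- ann$feature
  out$gene <- ann$gene
  out$gene_strand <- ann$gene_strand
  out$editing_class <- if (nrow(out))
    resolve_editing_class(out$rdd_type, out$gene_strand) else character(0)
  out$strand_confidence <- ifelse(out$gene_strand == "*", "low", "high")
  class(out) <- c("annotated_edits", "data.frame")
  out
}

#' Summarize an editome
#'
#' Per-condition totals, counts by editing class, counts and percentages by
#' genomic feature (percentages of the total, rounded to 0.1, so they close
#' to 100 only up to rounding), and the 12-type mismatch histogram.
#'
#' @param edits an `annotated_edits` data.frame for one condition.
#' @param label condition label.
#' @return list of class `editome_summary`: label, n_total, n_by_class,
#'   n_by_feature, pct_by_feature, type_hist.
#' @export
summarize_editome <- function(edits, label = "condition") {
  n_total <- nrow(edits)
  n_by_class <- setNames(integer(length(EDITING_CLASSES)), EDITING_CLASSES)
  n_by_feature <- setNames(integer(length(FEATURE_CLASSES)), FEATURE_CLASSES)
  type_hist <- setNames(integer(length(RDD_TYPES)), RDD_TYPES)
  if (n_total == 0) {
    warning("empty editome for condition '", label,
            "'; percentages reported as zero", call. = FALSE)
    pct <- setNames(numeric(length(FEATURE_CLASSES)), FEATURE_CLASSES)
  } else {
    tc <- table(factor(edits$editing_class, levels = EDITING_CLASSES))
    n_by_class[] <- as.integer(tc)
    tf <- table(factor(edits$feature, levels = FEATURE_CLASSES))
    n_by_feature[] <- as.integer(tf)
    th <- table(factor(edits$rdd_type, levels = RDD_TYPES))
    type_hist[] <- as.integer(th)
    pct <- round(100 * n_by_feature / n_total, 1)
  }
  structure(list(label = label, n_total = n_total, n_by_class = n_by_class,
                 n_by_feature = n_by_feature, pct_by_feature = pct,
                 type_hist = type_hist),
            class = "editome_summary")
}

#' @export
print.editome_summary <- function(x, ...) {
  cat(sprintf("Editome '%s': %d events (A-to-I %d, C-to-U %d, other %d)\n",
              x$label, x$n_total, x$n_by_class[["A-to-I"]],
              x$n_by_class[["C-to-U"]], x$n_by_class[["other"]]))
  feats <- x$pct_by_feature[x$n_by_feature > 0]
  if (length(feats)) {
    cat("  features:",
        paste(sprintf("%s %.1f%%", names(feats), feats), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Compare two editomes
#'
#' Percent reductions of the case relative to the baseline (total and per
#' editing class; `100 * (n_base - n_case) / n_base`, `NA` when the
#' baseline count is zero) and per-feature shifts in percentage points
#' (case minus baseline).
#'
#' @param base,case `editome_summary` objects ([summarize_editome()]).
#' @return list of class `editome_comparison`: labels, reduction_total_pct,
#'   reduction_total_pct_rounded, reduction_by_class_pct, feature_shift_pp.
#' @export
compare_editomes <- function(base, case) {
  check_that(inherits(base, "editome_summary") &&
               inherits(case, "editome_summary"),
             "inputs must be editome_summary objects")
  red <- function(nb, nc) if (nb > 0) 100 * (nb - nc) / nb else NA_real_
  reduction_total <- red(base$n_total, case$n_total)
  reduction_class <- mapply(red, base$n_by_class, case$n_by_class)
  structure(list(
    baseline = base$label, case = case$label,
    n_baseline = base$n_total, n_case = case$n_total,
    reduction_total_pct = reduction_total,
    reduction_total_pct_rounded = if (is.na(reduction_total)) NA_real_
                                  else round(reduction_total),
    reduction_by_class_pct = reduction_class,
    feature_shift_pp = case$pct_by_feature - base$pct_by_feature),
    class = "editome_comparison")
}

#' @export
print.editome_comparison <- function(x, ...) {
  cat(sprintf("Editome comparison %s -> %s: %d -> %d events", x$baseline,
              x$case, x$n_baseline, x$n_case))
  if (!is.na(x$reduction_total_pct)) {
    cat(sprintf(" (%.1f%% reduction, ~%d%%)", x$reduction_total_pct,
                x$reduction_total_pct_rounded))
  }
  cat("\n")
  shifts <- x$feature_shift_pp[abs(x$feature_shift_pp) >= 0.05]
  if (length(shifts)) {
    cat("  feature shifts (pp):",
        paste(sprintf("%s %+0.1f", names(shifts), shifts), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Tabular view of an editome summary (ring-table layout)
#'
#' Flattens an `editome_summary` into a data.frame with one row per
#' statistic: per-class counts, per-feature counts and per-feature
#' percentages.
#'
#' @param x an `editome_summary`.
#' @param ... unused.
#' @return data.frame with columns condition, ring (`class` / `feature_n` /
#'   `feature_pct`), category, value.
#' @export
as.data.frame.editome_summary <- function(x, ...) {
  rbind(
    data.frame(condition = x$label, ring = "class",
               category = names(x$n_by_class),
               value = as.numeric(x$n_by_class)),
    data.frame(condition = x$label, ring = "feature_n",
               category = names(x$n_by_feature),
               value = as.numeric(x$n_by_feature)),
    data.frame(condition = x$label, ring = "feature_pct",
               category = names(x$pct_by_feature),
               value = as.numeric(x$pct_by_feature)))
}
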