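test_that("mismatch classification is a total function onto 12 distinct types", {
  expect_equal(classify_mismatch("A", "G"), "A>G")
  expect_equal(classify_mismatch("T", "C"), "T>C")
  all_pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                           alt = c("A", "C", "G", "T"),
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$ref != all_pairs$alt, ]
  types <- classify_mismatch(all_pairs$ref, all_pairs$alt)
  expect_setequal(types, RDD_TYPES)
  expect_equal(length(unique(types)), 12)
  expect_error(classify_mismatch("A", "A"), "differ")
})

test_that("editing classes follow the deamination signatures and strand", {
  expect_equal(resolve_editing_class("A>G", "+"), "A-to-I")
  expect_equal(resolve_editing_class("T>C", "-"), "A-to-I")
  expect_equal(resolve_editing_class("C>T", "+"), "C-to-U")
  expect_equal(resolve_editing_class("G>A", "-"), "C-to-U")
  expect_equal(resolve_editing_class("A>C", "+"), "other")
  expect_equal(resolve_editing_class("A>G", "-"), "other")
  # unknown strand: plus-strand reading for A>G / C>T, "other" for their
  # reverse-strand signatures
  expect_equal(resolve_editing_class("A>G", "*"), "A-to-I")
  expect_equal(resolve_editing_class("C>T", "*"), "C-to-U")
  expect_equal(resolve_editing_class("T>C", "*"), "other")
  expect_equal(resolve_editing_class("G>A", "*"), "other")
})

test_that("editing-class resolution has complement symmetry over all 12 types", {
  complement_type <- function(tp) {
    b <- strsplit(tp, ">", fixed = TRUE)[[1]]
    paste0(complement_base(b[1]), ">", complement_base(b[2]))
  }
  for (tp in RDD_TYPES) {
    expect_equal(resolve_editing_class(tp, "-"),
                 resolve_editing_class(complement_type(tp), "+"),
                 label = paste("complement symmetry for", tp))
  }
})

test_that("feature annotation follows precedence, windows, and intergenic default", {
  features <- data.frame(
    chrom = "chr1",
    start = c(1000, 1000, 3000, 5000),
    end = c(1999, 1999, 3999, 5999),
    strand = c("+", "+", "-", "+"),
    gene = c("gA", "gB", "gC", "gD"),
    feature = c("exonic", "intronic", "utr3", "updownstream"),
    tx_type = "coding", stringsAsFactors = FALSE)
  ann <- annotate_region(rep("chr1", 4), c(1500, 3500, 5500, 9000), features)
  # exon of gA beats intron of gB at the same position
  expect_equal(ann$feature[1], "exonic")
  expect_equal(ann$gene[1], "gA")
  expect_equal(ann$feature[2], "utr3")
  expect_equal(ann$gene_strand[2], "-")
  expect_equal(ann$feature[3], "updownstream")
  expect_equal(ann$feature[4], "intergenic")
  expect_equal(ann$gene[4], "")
  expect_equal(ann$gene_strand[4], "*")

  # same class in two genes: smallest gene identifier wins
  tie <- data.frame(chrom = "chr1", start = 10, end = 20, strand = "+",
                    gene = c("gZ", "gA"), feature = "intronic",
                    tx_type = "coding", stringsAsFactors = FALSE)
  expect_equal(annotate_region("chr1", 15, tie)$gene, "gA")

  bad <- data.frame(chrom = "chr1", start = 10, end = 5, strand = "+",
                    gene = "g", feature = "exonic", tx_type = "coding",
                    stringsAsFactors = FALSE)
  expect_error(annotate_region("chr1", 7, bad), "start > end")
})

test_that("positions upstream of a transcript fall in the flank window", {
  ds <- make_dataset()
  feats <- ds$genome$features
  tx <- feats[feats$gene == "gene_01" & feats$feature != "updownstream", ]
  tss <- min(tx$start)
  ann <- annotate_region("chrS", tss - 500, feats)
  expect_equal(ann$feature, "updownstream")
  expect_equal(ann$gene, "gene_01")
})

test_that("editome summaries conserve counts and close percentages", {
  edits <- make_edits(775, 450)
  s <- summarize_editome(edits, "naive")
  expect_equal(s$n_total, 1225)
  expect_equal(s$n_by_class[["A-to-I"]], 775)
  expect_equal(s$n_by_class[["C-to-U"]], 450)
  expect_equal(s$n_total, sum(s$n_by_class))
  expect_equal(s$n_total, sum(s$n_by_feature))
  expect_equal(s$n_total, sum(s$type_hist))
  expect_lte(abs(sum(s$pct_by_feature) - 100), 0.2 + 1e-9)

  # a single edit in a 3'UTR: that feature carries 100%
  single <- summarize_editome(make_edits(1, 0, feature = "utr3"), "one")
  expect_equal(single$pct_by_feature[["utr3"]], 100.0)
  expect_equal(sum(single$pct_by_feature), 100)

  expect_warning(s0 <- summarize_editome(make_edits(0, 0), "empty"), "empty")
  expect_equal(s0$n_total, 0)
  expect_equal(sum(s0$pct_by_feature), 0)
})

test_that("percentage closure holds to the per-category rounding bound", {
  # plain rounding to 0.1 per category bounds the total drift by
  # 0.05 * (number of occupied categories)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(50:2000, 1)
    edits <- make_edits(n, 0)
    edits$feature <- sample(setdiff(FEATURE_CLASSES, "intergenic"), n,
                            replace = TRUE)
    s <- summarize_editome(edits, "x")
    bound <- 0.05 * sum(s$n_by_feature > 0)
    expect_lte(abs(sum(s$pct_by_feature) - 100), bound + 1e-9)
  }
})

test_that("editome comparisons reproduce percent reductions and shifts", {
  naive <- summarize_editome(make_edits(775, 450), "naive")
  pre <- summarize_editome(make_edits(717, 417), "pre")    # 1134 total
  acute <- summarize_editome(make_edits(564, 327), "acute") # 891 total

  cmp_acute <- compare_editomes(naive, acute)
  expect_equal(cmp_acute$reduction_total_pct, 100 * (1225 - 891) / 1225)
  expect_equal(cmp_acute$reduction_total_pct_rounded, 27)

  cmp_pre <- compare_editomes(naive, pre)
  expect_equal(cmp_pre$reduction_total_pct_rounded, 7)

  ident <- compare_editomes(naive, naive)
  expect_equal(ident$reduction_total_pct, 0)
  expect_true(all(ident$feature_shift_pp == 0))

  # feature shift in percentage points (case - baseline)
  base <- summarize_editome(make_edits(50, 50, feature = "utr3"), "b")
  mixed <- make_edits(40, 40)
  mixed$feature <- rep(c("utr3", "intronic"), each = 40)
  case <- summarize_editome(mixed, "c")
  cmp <- compare_editomes(base, case)
  expect_equal(cmp$feature_shift_pp[["utr3"]], 50 - 100)
  expect_equal(cmp$feature_shift_pp[["intronic"]], 50)
})

test_that("annotated recovery: planted classes, genes and features round-trip", {
  ds <- make_dataset()
  calls <- call_rdd_sites(ds$pileup, ds$snps, filter_config())
  # annotate with the GFF3 read back from disk: exercises the writer/reader
  gff <- tempfile(fileext = ".gff3")
  write_features(ds$genome$features, gff)
  edits <- annotate_edits(calls[calls$passed, , drop = FALSE],
                          read_features(gff))
  m <- merge(edits, ds$truth, by = "pos")
  expect_equal(nrow(m), nrow(edits))
  expect_identical(m$editing_class.x, m$editing_class.y)
  expect_identical(m$feature, m$feature_label)
  expect_identical(m$gene.x, m$gene.y)
  expect_identical(m$gene_strand.x, m$gene_strand.y)

  # with only A-to-I and C-to-U planted and low error, the deamination
  # signatures dominate the 12-type histogram
  s <- summarize_editome(edits, "sim")
  sig <- sum(s$type_hist[c("A>G", "T>C", "C>T", "G>A")])
  expect_gte(sig / s$n_total, 0.95)
})
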