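test_that("simulated annotation contains every feature class and respects strand geometry", {
  cfg <- sim_config(seed = 3, genome_length = 10000, n_transcripts = 2)
  g <- simulate_reference(cfg)
  expect_equal(Biostrings::width(g$reference)[[1]], 10000)
  expect_setequal(unique(g$features$feature),
                  c("utr5", "exonic", "intronic", "utr3",
                    "ncRNA_exonic", "ncRNA_intronic", "updownstream"))
  expect_true(all(g$features$start <= g$features$end))

  # minus-strand coding transcript: 3'UTR is 5'-most in genome coordinates
  cfg4 <- sim_config(seed = 3, genome_length = 20000, n_transcripts = 4)
  g4 <- simulate_reference(cfg4)
  minus_coding <- g4$features[g4$features$strand == "-" &
                                g4$features$tx_type == "coding" &
                                g4$features$feature != "updownstream", ]
  expect_gt(nrow(minus_coding), 0)
  for (gene in unique(minus_coding$gene)) {
    tx <- minus_coding[minus_coding$gene == gene, ]
    expect_equal(tx$feature[which.min(tx$start)], "utr3")
    expect_equal(tx$feature[which.max(tx$start)], "utr5")
  }
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, genome_length = 10000, n_transcripts = 2,
                    mean_depth = 10)
  run <- function() {
    g <- simulate_reference(cfg)
    p <- plant_sites(cfg, g$reference, g$features)
    r <- simulate_alignments(cfg, g$reference, p$truth, p$snps)
    fa <- tempfile(fileext = ".fasta"); sam <- tempfile(fileext = ".sam")
    vcf <- tempfile(fileext = ".vcf"); tsv <- tempfile(fileext = ".tsv")
    Biostrings::writeXStringSet(g$reference, fa)
    write_sam(r, sam); write_vcf(p$snps, vcf, cfg$genome_length)
    write_truth_table(p$truth, tsv)
    lapply(c(fa, sam, vcf, tsv), function(f) readLines(f))
  }
  expect_identical(run(), run())
})

test_that("layout exceeding the genome is rejected with a sizing error", {
  cfg <- sim_config(seed = 1, genome_length = 1000, n_transcripts = 2,
                    flank_window = 100)
  expect_error(simulate_reference(cfg), "exceeds genome length")
})

test_that("planted sites respect counts, base/strand invariants and SNP disjointness", {
  ds <- make_dataset()
  truth <- ds$truth
  expect_equal(nrow(truth), sum(ds$cfg$n_edit_sites))
  expect_equal(sum(truth$editing_class == "A-to-I"),
               ds$cfg$n_edit_sites[["a_to_i"]])
  expect_equal(sum(truth$editing_class == "C-to-U"),
               ds$cfg$n_edit_sites[["c_to_u"]])

  # base/strand rule: A-to-I sits on A (+) or T (-); C-to-U on C (+) or G (-)
  ai <- truth[truth$editing_class == "A-to-I", ]
  expect_true(all(ifelse(ai$gene_strand == "+", ai$ref_base == "A",
                         ai$ref_base == "T")))
  expect_true(all(ifelse(ai$gene_strand == "+", ai$alt_base == "G",
                         ai$alt_base == "C")))
  cu <- truth[truth$editing_class == "C-to-U", ]
  expect_true(all(ifelse(cu$gene_strand == "+", cu$ref_base == "C",
                         cu$ref_base == "G")))
  expect_true(all(ifelse(cu$gene_strand == "+", cu$alt_base == "T",
                         cu$alt_base == "A")))

  # planted bases match the reference sequence
  g <- strsplit(as.character(ds$genome$reference[[1]]), "")[[1]]
  expect_identical(g[truth$pos], truth$ref_base)

  # distinct positions; SNPs disjoint from edit sites
  expect_false(anyDuplicated(truth$pos) > 0)
  expect_equal(nrow(ds$snps), ds$cfg$n_snp_sites)
  expect_length(intersect(ds$snps$pos, truth$pos), 0)
  expect_true(all(truth$planted_frequency > 0 & truth$planted_frequency <= 1))

  # the VCF round-trips the mask
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(ds$snps, vcf, ds$cfg$genome_length)
  mask <- read_snp_mask(vcf)
  expect_equal(mask$pos, ds$snps$pos)
  expect_equal(mask$ref, ds$snps$ref)
})

test_that("requesting more sites than eligible bases fails loudly", {
  cfg <- sim_config(seed = 5, genome_length = 10000, n_transcripts = 2,
                    n_edit_sites = c(a_to_i = 100000L, c_to_u = 0L))
  g <- simulate_reference(cfg)
  expect_error(plant_sites(cfg, g$reference, g$features),
               "eligible reference bases")
})

test_that("reads carry planted alleles at the planted frequency", {
  # frequency 1, zero error: every overlapping read carries the alt base
  cfg <- sim_config(seed = 9, genome_length = 10000, n_transcripts = 2,
                    mean_depth = 30, error_rate = 1e-12,
                    edit_freq_range = c(1, 1), n_snp_sites = 0L,
                    multimap_fraction = 0)
  g <- simulate_reference(cfg)
  p <- plant_sites(cfg, g$reference, g$features)
  r <- simulate_alignments(cfg, g$reference, p$truth, p$snps)
  site <- p$truth[1, ]
  cover <- r[r$pos <= site$pos & r$pos > site$pos - cfg$read_length, ]
  expect_gt(nrow(cover), 0)
  obs <- substr(cover$seq, site$pos - cover$pos + 1, site$pos - cover$pos + 1)
  expect_true(all(obs == site$alt_base))

  # empirical alt fraction converges to the planted frequency at high depth
  cfg2 <- sim_config(seed = 10, genome_length = 8000, n_transcripts = 2,
                     flank_window = 300, mean_depth = 2000,
                     error_rate = 1e-12, edit_freq_range = c(0.35, 0.35),
                     n_edit_sites = c(a_to_i = 3L, c_to_u = 2L),
                     n_snp_sites = 0L, multimap_fraction = 0)
  g2 <- simulate_reference(cfg2)
  p2 <- plant_sites(cfg2, g2$reference, g2$features)
  r2 <- simulate_alignments(cfg2, g2$reference, p2$truth, p2$snps)
  per_site <- vapply(seq_len(nrow(p2$truth)), function(k) {
    site <- p2$truth[k, ]
    cover <- r2[r2$pos <= site$pos & r2$pos > site$pos - cfg2$read_length, ]
    obs <- substr(cover$seq, site$pos - cover$pos + 1,
                  site$pos - cover$pos + 1)
    mean(obs == site$alt_base)
  }, numeric(1))
  # pooled over ~10k overlapping reads: within +/-0.02 of the planted
  # frequency; each site individually inside a generous binomial envelope
  expect_equal(mean(per_site), 0.35, tolerance = 0.02 / 0.35)
  expect_true(all(abs(per_site - 0.35) < 0.05))
})

test_that("multimapper fraction matches the binomial expectation", {
  cfg <- sim_config(seed = 21, genome_length = 8000, n_transcripts = 2,
                    flank_window = 300, mean_depth = 15,
                    multimap_fraction = 0.2)
  g <- simulate_reference(cfg)
  p <- plant_sites(cfg, g$reference, g$features)
  r <- simulate_alignments(cfg, g$reference, p$truth, p$snps)
  n <- nrow(r)
  expect_gt(n, 800)
  n_mm <- sum(r$mapq == 0)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.2)
  expect_gte(n_mm, ci[1])
  expect_lte(n_mm, ci[2])
  expect_identical(r$mapq == 0, r$multimap)
})

test_that("a zero-depth configuration produces an empty, valid SAM", {
  cfg <- sim_config(seed = 2, genome_length = 10000, n_transcripts = 2,
                    mean_depth = 0)
  g <- simulate_reference(cfg)
  p <- plant_sites(cfg, g$reference, g$features)
  r <- simulate_alignments(cfg, g$reference, p$truth, p$snps)
  expect_equal(nrow(r), 0)
  sam <- tempfile(fileext = ".sam")
  write_sam(r, sam)
  lines <- readLines(sam)
  expect_length(lines, 2)
  expect_match(lines[2], "^@SQ")
  pu <- build_pileup(sam, g$reference, filter_config())
  expect_equal(nrow(pu), 0)
})

test_that("feature annotation round-trips through BED and GFF3", {
  ds <- make_dataset()
  for (ext in c("bed", "gff3")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_features(ds$genome$features, path)
    back <- read_features(path)
    orig <- ds$genome$features[order(ds$genome$features$start,
                                     ds$genome$features$feature), ]
    back <- back[order(back$start, back$feature), ]
    rownames(orig) <- rownames(back) <- NULL
    expect_equal(back[, c("chrom", "start", "end", "strand", "gene",
                          "feature")],
                 orig[, c("chrom", "start", "end", "strand", "gene",
                          "feature")])
  }
})
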