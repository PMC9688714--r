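# Shared fixtures built in code. Datasets are cached per test run so that
# several test files can reuse the same simulated library without paying the
# pileup cost repeatedly.

.ds_cache <- new.env(parent = emptyenv())

# A complete simulated dataset: genome + annotation + planted sites + reads
# written as SAM + quality-filtered pileup.
make_dataset <- function(seed = 11, genome_length = 20000, n_transcripts = 4,
                         mean_depth = 50, error_rate = 0.005, ...) {
  key <- paste(seed, genome_length, n_transcripts, mean_depth, error_rate,
               ..., sep = "_")
  if (!is.null(.ds_cache[[key]])) return(.ds_cache[[key]])
  cfg <- sim_config(seed = seed, genome_length = genome_length,
                    n_transcripts = n_transcripts, mean_depth = mean_depth,
                    error_rate = error_rate, ...)
  genome <- simulate_reference(cfg)
  planted <- plant_sites(cfg, genome$reference, genome$features)
  reads <- simulate_alignments(cfg, genome$reference, planted$truth,
                               planted$snps)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, sam)
  pileup <- build_pileup(sam, genome$reference, filter_config())
  ds <- list(cfg = cfg, genome = genome, truth = planted$truth,
             snps = planted$snps, reads = reads, sam = sam, pileup = pileup)
  .ds_cache[[key]] <- ds
  ds
}

# Write a tiny hand-specified SAM file (ungapped reads on `chrom`).
write_test_sam <- function(reads, chrom = "chrT", chrom_len = 200L) {
  path <- tempfile(fileext = ".sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(reads, function(r) {
    paste(r$qname, r$flag %||% 0L, chrom, r$pos, r$mapq %||% 60L,
          paste0(nchar(r$seq), "M"), "*", 0L, 0L, r$seq, r$qual, sep = "\t")
  }, "")
  writeLines(c(header, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Phred quality string of length n at constant quality q.
qual_str <- function(q, n) strrep(rawToChar(as.raw(q + 33L)), n)

# A reference for the hand-specified SAM: deterministic repeated pattern.
test_reference <- function(chrom = "chrT", len = 200L) {
  seq <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- chrom
  ref
}

# Minimal annotated-edits data.frame for editome summaries.
make_edits <- function(n_ai, n_cu, feature = "utr3") {
  n <- n_ai + n_cu
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      rdd_type = character(), feature = character(),
                      gene = character(), gene_strand = character(),
                      editing_class = character(),
                      strand_confidence = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = "chr1", pos = seq_len(n),
    ref = c(rep("A", n_ai), rep("C", n_cu)),
    alt = c(rep("G", n_ai), rep("T", n_cu)),
    rdd_type = c(rep("A>G", n_ai), rep("C>T", n_cu)),
    feature = feature, gene = "g1", gene_strand = "+",
    editing_class = c(rep("A-to-I", n_ai), rep("C-to-U", n_cu)),
    strand_confidence = "high",
    stringsAsFactors = FALSE)
}

extdata <- function(name) {
  system.file("extdata", name, package = "editomeR", mustWork = TRUE)
}

read_clone_table <- function(name) {
  utils::read.table(extdata(name), header = TRUE, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE)
}
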