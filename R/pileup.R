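#' Filtering configuration for RDD calling
#'
#' Thresholds applied when building pileups and calling RNA:DNA differences.
#' Defaults are the stringent settings used for high-confidence editing-site
#' detection in bulk RNA-seq: base quality 25, read depth 10, at least 3
#' reads supporting the variant, editing frequency 0.1, and significance
#' level 0.05 for both per-site exact tests and the BH-adjusted q-value.
#'
#' @param min_base_quality minimum Phred base quality for a read base to be
#'   counted in the pileup.
#' @param min_depth minimum quality-passing read depth at a site.
#' @param min_alt_support minimum number of reads supporting the variant.
#' @param min_freq minimum editing frequency (alt / depth).
#' @param alpha significance level applied to both per-site exact-test
#'   p-values and the BH q-value.
#' @param error_rate assumed per-base sequencing error rate for the null
#'   models of [binomial_site_test()] and [fisher_site_test()]. 0.01 is a
#'   typical post-Q25 error ceiling.
#' @param end_trim bases ignored at each read end when building the pileup,
#'   to suppress false RDDs from random-hexamer mispriming near read ends.
#' @param exclude_multimapped drop reads with mapping quality at or below
#'   `max_multimap_mapq` (multimappers are conventionally MAPQ 0).
#' @param max_multimap_mapq MAPQ floor used when `exclude_multimapped`.
#' @return a validated list of class `filter_config`.
#' @examples
#' filter_config()                      # published defaults
#' filter_config(min_depth = 20)        # stricter depth
#' @export
filter_config <- function(min_base_quality = 25L,
                          min_depth = 10L,
                          min_alt_support = 3L,
                          min_freq = 0.1,
                          alpha = 0.05,
                          error_rate = 0.01,
                          end_trim = 6L,
                          exclude_multimapped = TRUE,
                          max_multimap_mapq = 0L) {
  cfg <- list(
    min_base_quality = as.integer(min_base_quality),
    min_depth = as.integer(min_depth),
    min_alt_support = as.integer(min_alt_support),
    min_freq = as.numeric(min_freq),
    alpha = as.numeric(alpha),
    error_rate = as.numeric(error_rate),
    end_trim = as.integer(end_trim),
    exclude_multimapped = isTRUE(exclude_multimapped),
    max_multimap_mapq = as.integer(max_multimap_mapq))
  class(cfg) <- "filter_config"
  validate_filter_config(cfg)
  cfg
}

validate_filter_config <- function(cfg) {
  check_that(cfg$min_alt_support >= 1, "min_alt_support must be >= 1")
  check_that(cfg$min_depth >= cfg$min_alt_support,
             "min_depth must be >= min_alt_support")
  check_that(cfg$min_freq > 0 && cfg$min_freq <= 1,
             "min_freq must lie in (0, 1]")
  check_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  check_that(cfg$error_rate > 0 && cfg$error_rate < cfg$min_freq,
             "error_rate must lie in (0, min_freq)")
  check_that(cfg$min_base_quality >= 0, "min_base_quality must be >= 0")
  check_that(cfg$end_trim >= 0, "end_trim must be >= 0")
  invisible(cfg)
}

#' Build a quality-filtered per-site pileup from aligned reads
#'
#' Reads a coordinate-sorted SAM/BAM of ungapped alignments and tallies
#' quality-passing bases per reference position. Bases with Phred quality
#' below `min_base_quality`, bases within `end_trim` bases of either read
#' end, and (optionally) reads with multimapper mapping quality are
#' excluded. Positions with zero surviving depth are omitted.
#'
#' Only ungapped alignments (CIGAR `<n>M`) are supported: the simulator
#' emits full-match alignments and mismatch calling is insensitive to
#' soft-clip conventions at this scale.
#'
#' @param alignments path to a SAM or BAM file, coordinate-sorted.
#' @param reference reference genome ([Biostrings::DNAStringSet] or FASTA
#'   path); every contig in the alignments must be present.
#' @param config a [filter_config()].
#' @return a data.frame of class `pileup`: chrom, pos (1-based), ref, A, C,
#'   G, T, depth; attribute `contigs` lists the reference contigs.
#' @export
build_pileup <- function(alignments, reference, config = filter_config()) {
  validate_filter_config(config)
  ref <- as_reference(reference)

  path <- alignments
  check_that(is.character(path) && file.exists(path),
             paste0("alignment file not found: ", path))
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  ga <- GenomicAlignments::readGAlignments(path, param = param,
                                           use.names = FALSE)
  seqs <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]

  contigs <- names(ref)
  chr_aln <- as.character(GenomicAlignments::seqnames(ga))
  missing <- setdiff(unique(chr_aln), contigs)
  if (length(missing)) {
    stop("contig absent from reference: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  keep <- rep(TRUE, length(ga))
  if (config$exclude_multimapped) {
    mq <- S4Vectors::mcols(ga)$mapq
    keep <- keep & (is.na(mq) | mq > config$max_multimap_mapq)
  }
  cig <- GenomicAlignments::cigar(ga)
  if (!all(grepl("^[0-9]+M$", cig))) {
    stop("only ungapped alignments (CIGAR <n>M) are supported", call. = FALSE)
  }

  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) {
    attr(empty, "contigs") <- contigs
    class(empty) <- c("pileup", "data.frame")
    return(empty)
  }

  widths <- GenomicAlignments::qwidth(ga)[keep]
  starts <- GenomicAlignments::start(ga)[keep]
  chroms <- chr_aln[keep]
  seqchar <- as.character(seqs$seq)[keep]
  qualchar <- as.character(seqs$qual)[keep]

  n <- length(starts)
  total <- sum(widths)
  posvec <- unlist(mapply(seq.int, starts, starts + widths - 1L,
                          SIMPLIFY = FALSE), use.names = FALSE)
  cyc <- unlist(lapply(widths, seq_len), use.names = FALSE)
  rlen <- rep(widths, widths)
  basevec <- unlist(strsplit(seqchar, "", fixed = TRUE), use.names = FALSE)
  qvec <- as.integer(charToRaw(paste(qualchar, collapse = ""))) - 33L
  chromvec <- rep(chroms, widths)

  pass <- qvec >= config$min_base_quality &
    cyc > config$end_trim & cyc <= rlen - config$end_trim &
    basevec %in% BASES
  dt <- data.table::data.table(chrom = chromvec[pass], pos = posvec[pass],
                               base = basevec[pass])
  if (!nrow(dt)) {
    attr(empty, "contigs") <- contigs
    class(empty) <- c("pileup", "data.frame")
    return(empty)
  }
  counts <- dt[, .N, by = c("chrom", "pos", "base")]
  wide <- data.table::dcast(counts, chrom + pos ~ base, value.var = "N",
                            fill = 0L)
  for (b in BASES) {
    if (!b %in% names(wide)) wide[[b]] <- 0L
  }
  data.table::setorderv(wide, c("chrom", "pos"))
  out <- as.data.frame(wide[, c("chrom", "pos", BASES), with = FALSE])
  out$depth <- out$A + out$C + out$G + out$T

  ## vectorized reference lookup per contig
  out$ref <- NA_character_
  for (chr in unique(out$chrom)) {
    sel <- out$chrom == chr
    v <- Biostrings::extractAt(ref[[chr]],
                               IRanges::IRanges(out$pos[sel], width = 1L))
    out$ref[sel] <- as.character(v)
  }
  out <- out[, c("chrom", "pos", "ref", BASES, "depth")]
  attr(out, "contigs") <- contigs
  class(out) <- c("pileup", "data.frame")
  out
}

#' Read a VCF SNP mask
#'
#' Extracts masked positions from a VCF file (e.g. a dbSNP subset or the
#' mask written by [write_vcf()]).
#'
#' @param path VCF path.
#' @return data.frame with columns chrom, pos (1-based), ref, alt.
#' @export
read_snp_mask <- function(path) {
  check_that(file.exists(path), paste0("VCF not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)) || nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]),
    stringsAsFactors = FALSE)
}
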