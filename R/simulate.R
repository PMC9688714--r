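## Synthetic editome datasets: reference + annotation, planted sites, reads.
##
## The generator emits a miniature single-chromosome genome with alternating
## coding / non-coding transcript models (so that every feature class used by
## the editome annotator is represented), plants A-to-I and C-to-U editing
## sites on strand-appropriate reference bases, plants SNPs that are written
## to a VCF mask, and emits pre-aligned ungapped reads (SAM) carrying the
## planted alleles, multimappers and end-biased sequencing errors.

## Transcript templates, in transcript 5'->3' order.
.coding_template <- function() {
  data.frame(feature = c("utr5", "exonic", "intronic", "exonic", "utr3"),
             len = c(200L, 400L, 600L, 400L, 800L))
}
.ncrna_template <- function() {
  data.frame(feature = c("ncRNA_exonic", "ncRNA_intronic", "ncRNA_exonic"),
             len = c(300L, 500L, 300L))
}

GENIC_FEATURES <- c("utr5", "exonic", "intronic", "utr3",
                    "ncRNA_exonic", "ncRNA_intronic")

#' Simulate a reference genome with transcript annotation
#'
#' Generates a random single-chromosome genome and lays out alternating
#' coding and non-coding transcript models along it, on alternating strands.
#' Coding models carry 5'UTR / CDS exon / intron / CDS exon / 3'UTR blocks;
#' non-coding models carry exon / intron / exon. Each transcript also gets a
#' merged upstream/downstream flank feature of `flank_window` bases on both
#' sides. Regions covered by no feature are intergenic by definition.
#'
#' On a minus-strand transcript the template order maps to descending genome
#' coordinates, so e.g. its 3'UTR is the left-most (5'-most in genome
#' coordinates) block.
#'
#' @param config a [sim_config()].
#' @return a list with elements `reference` (named [Biostrings::DNAStringSet])
#'   and `features` (data.frame: chrom, start, end, strand, gene, feature,
#'   tx_type; 1-based inclusive coordinates).
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  glen <- config$genome_length
  ntx <- config$n_transcripts
  block <- glen %/% ntx

  feats <- vector("list", ntx)
  for (i in seq_len(ntx)) {
    coding <- (i %% 2L) == 1L
    tmpl <- if (coding) .coding_template() else .ncrna_template()
    span <- sum(tmpl$len)
    need <- span + 2L * config$flank_window + 100L
    if (need > block) {
      stop(sprintf(paste0("transcript layout exceeds genome length: ",
                          "transcript %d needs %d bases but only %d are ",
                          "available per transcript block"), i, need, block),
           call. = FALSE)
    }
    strand <- if ((i %% 2L) == 1L) "+" else "-"
    ## alternate coding strand too, so both (-)-strand coding and ncRNA exist
    if (coding && (i %% 4L) == 3L) strand <- "-"
    tx_start <- (i - 1L) * block + config$flank_window + 51L
    order_in_genome <- if (strand == "+") seq_len(nrow(tmpl)) else rev(seq_len(nrow(tmpl)))
    lens <- tmpl$len[order_in_genome]
    ends <- tx_start - 1L + cumsum(lens)
    starts <- ends - lens + 1L
    gene <- sprintf("gene_%02d", i)
    tx <- data.frame(
      chrom = config$chrom_name,
      start = starts, end = ends, strand = strand, gene = gene,
      feature = tmpl$feature[order_in_genome],
      tx_type = if (coding) "coding" else "ncRNA",
      stringsAsFactors = FALSE)
    tx_end <- max(ends)
    flank <- data.frame(
      chrom = config$chrom_name,
      start = c(max(1L, tx_start - config$flank_window), tx_end + 1L),
      end = c(tx_start - 1L, min(glen, tx_end + config$flank_window)),
      strand = strand, gene = gene, feature = "updownstream",
      tx_type = if (coding) "coding" else "ncRNA",
      stringsAsFactors = FALSE)
    flank <- flank[flank$start <= flank$end, , drop = FALSE]
    feats[[i]] <- rbind(tx, flank)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL

  seq <- with_rng(config$seed, paste(
    sample(BASES, glen, replace = TRUE), collapse = ""))
  reference <- Biostrings::DNAStringSet(seq)
  names(reference) <- config$chrom_name
  list(reference = reference, features = features)
}

#' Plant editing sites and SNPs in a simulated genome
#'
#' Selects strand-appropriate genic positions for A-to-I sites (reference A
#' on `+` genes, T on `-` genes; edited allele G / C) and C-to-U sites
#' (reference C on `+`, G on `-`; edited allele T / A), draws each site's
#' true editing frequency uniformly from `edit_freq_range`, and plants SNP
#' positions disjoint from the editing sites anywhere on the genome.
#'
#' @param config a [sim_config()].
#' @param reference,features output of [simulate_reference()].
#' @return a list with `truth` (the ground-truth table: chrom, pos, ref_base,
#'   alt_base, editing_class, gene, gene_strand, planted_frequency,
#'   feature_label) and `snps` (chrom, pos, ref, alt, genotype).
#' @export
plant_sites <- function(config, reference, features) {
  validate_sim_config(config)
  ref <- as_reference(reference)
  g <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  glen <- length(g)

  genic <- features[features$feature %in% GENIC_FEATURES, , drop = FALSE]
  pos_all <- unlist(mapply(seq.int, genic$start, genic$end, SIMPLIFY = FALSE))
  strand_all <- rep(genic$strand, genic$end - genic$start + 1L)
  ## transcripts do not overlap by construction; positions are unique
  base_all <- g[pos_all]

  pick_sites <- function(n, class) {
    if (class == "a_to_i") {
      ok <- (strand_all == "+" & base_all == "A") |
            (strand_all == "-" & base_all == "T")
    } else {
      ok <- (strand_all == "+" & base_all == "C") |
            (strand_all == "-" & base_all == "G")
    }
    idx <- which(ok)
    if (length(idx) < n) {
      stop(sprintf("only %d eligible reference bases for %d requested %s sites",
                   length(idx), n, class), call. = FALSE)
    }
    idx[sample.int(length(idx), n)]
  }

  res <- with_rng(config$seed + 1L, {
    ai_idx <- pick_sites(config$n_edit_sites[["a_to_i"]], "a_to_i")
    cu_idx <- pick_sites(config$n_edit_sites[["c_to_u"]], "c_to_u")
    ## an A/T position can never satisfy the C/G condition, so the two draws
    ## are disjoint by construction
    idx <- c(ai_idx, cu_idx)
    cls <- rep(c("A-to-I", "C-to-U"), c(length(ai_idx), length(cu_idx)))
    pos <- pos_all[idx]
    strand <- strand_all[idx]
    refb <- base_all[idx]
    altb <- ifelse(cls == "A-to-I",
                   ifelse(strand == "+", "G", "C"),
                   ifelse(strand == "+", "T", "A"))
    freq <- runif(length(idx), config$edit_freq_range[1], config$edit_freq_range[2])

    snp_pool <- setdiff(seq_len(glen), pos)
    if (length(snp_pool) < config$n_snp_sites) {
      stop("insufficient positions for requested SNP count", call. = FALSE)
    }
    snp_pos <- sort(sample(snp_pool, config$n_snp_sites))
    snp_ref <- g[snp_pos]
    snp_alt <- vapply(snp_ref, function(b) sample(setdiff(BASES, b), 1L), "")
    snp_gt <- ifelse(runif(config$n_snp_sites) < config$snp_hom_fraction,
                     "1/1", "0/1")
    list(pos = pos, strand = strand, refb = refb, altb = altb, cls = cls,
         freq = freq, snp_pos = snp_pos, snp_ref = snp_ref, snp_alt = snp_alt,
         snp_gt = snp_gt)
  })

  ord <- order(res$pos)
  ann <- annotate_region(rep(config$chrom_name, length(res$pos)),
                         res$pos, features)
  truth <- data.frame(
    chrom = rep(config$chrom_name, length(res$pos)),
    pos = res$pos,
    ref_base = res$refb,
    alt_base = res$altb,
    editing_class = res$cls,
    gene = ann$gene,
    gene_strand = res$strand,
    planted_frequency = res$freq,
    feature_label = ann$feature,
    stringsAsFactors = FALSE)[ord, ]
  rownames(truth) <- NULL

  snps <- data.frame(
    chrom = rep(config$chrom_name, length(res$snp_pos)),
    pos = res$snp_pos,
    ref = unname(res$snp_ref),
    alt = unname(res$snp_alt),
    genotype = res$snp_gt,
    stringsAsFactors = FALSE)
  list(truth = truth, snps = snps)
}

#' Simulate aligned reads over a genome with planted sites
#'
#' Places ungapped reads uniformly along the genome at the configured mean
#' depth. Each read overlapping a planted editing site carries the edited
#' base with probability equal to the site's planted frequency (independent
#' per read); heterozygous SNPs show the alternate allele in ~50% of reads
#' and homozygous SNPs in all reads. Per-base substitution errors are then
#' applied at `error_rate`, boosted by `end_error_boost` within
#' `end_error_window` bases of either read end (mimicking random-hexamer
#' mispriming artifacts). A `multimap_fraction` of reads is emitted with
#' mapping quality 0 and tag `ZM:i:1`; the rest get mapping quality 60.
#'
#' @param config a [sim_config()].
#' @param reference reference genome ([Biostrings::DNAStringSet] or path).
#' @param truth ground-truth table from [plant_sites()] (may have 0 rows).
#' @param snps SNP table from [plant_sites()] or `NULL`.
#' @return a data.frame of class `sim_reads` (one row per read: qname, flag,
#'   rname, pos, mapq, cigar, seq, qual, multimap), coordinate-sorted, with
#'   attributes `chrom` and `genome_length`. Write with [write_sam()].
#' @export
simulate_alignments <- function(config, reference, truth, snps = NULL) {
  validate_sim_config(config)
  ref <- as_reference(reference)
  g <- strsplit(as.character(ref[[1]]), "", fixed = TRUE)[[1]]
  glen <- length(g)
  L <- config$read_length
  check_that(glen >= L, "genome shorter than read length")
  n <- max(0L, as.integer(round(glen * config$mean_depth / L)))

  empty <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), multimap = logical(),
                      stringsAsFactors = FALSE)
  make_out <- function(df) {
    attr(df, "chrom") <- config$chrom_name
    attr(df, "genome_length") <- glen
    class(df) <- c("sim_reads", "data.frame")
    df
  }
  if (n == 0L) return(make_out(empty))

  with_rng(config$seed + 2L, {
    starts <- sort(sample.int(glen - L + 1L, n, replace = TRUE))
    ## base matrix, L rows x n reads (column-major = per-read columns)
    posvec <- rep(starts, each = L) + seq_len(L) - 1L
    mat <- matrix(g[posvec], nrow = L)

    plant <- function(pos, alt, prob) {
      idx <- which(starts <= pos & starts > pos - L)
      if (!length(idx)) return(invisible(NULL))
      row <- pos - starts[idx] + 1L
      hit <- runif(length(idx)) < prob
      if (any(hit)) mat[cbind(row[hit], idx[hit])] <<- alt
      invisible(NULL)
    }
    if (!is.null(truth) && nrow(truth)) {
      for (k in seq_len(nrow(truth))) {
        plant(truth$pos[k], truth$alt_base[k], truth$planted_frequency[k])
      }
    }
    if (!is.null(snps) && nrow(snps)) {
      for (k in seq_len(nrow(snps))) {
        plant(snps$pos[k], snps$alt[k],
              if (snps$genotype[k] == "1/1") 1 else 0.5)
      }
    }

    ## sequencing errors, elevated near read ends
    perr <- rep(config$error_rate, L)
    w <- config$end_error_window
    if (w > 0) {
      zone <- c(seq_len(w), (L - w + 1L):L)
      perr[zone] <- pmin(1, perr[zone] * config$end_error_boost)
    }
    err <- matrix(runif(L * n) < perr, nrow = L)  # perr recycles per column
    ne <- sum(err)
    if (ne) {
      cur <- match(mat[err], BASES)
      mat[err] <- BASES[((cur - 1L + sample.int(3L, ne, replace = TRUE)) %% 4L) + 1L]
    }

    ## base qualities: high around Q35, a low tail below the Q25 threshold
    low <- runif(L * n) < config$low_qual_fraction
    q <- integer(L * n)
    q[low] <- sample(10:24, sum(low), replace = TRUE)
    q[!low] <- sample(33:40, sum(!low), replace = TRUE)
    qlookup <- strsplit(rawToChar(as.raw(33L + 0:60)), "", fixed = TRUE)[[1]]
    qmat <- matrix(qlookup[q + 1L], nrow = L)

    mm <- runif(n) < config$multimap_fraction

    seqs <- do.call(paste0, as.data.frame(t(mat), stringsAsFactors = FALSE))
    quals <- do.call(paste0, as.data.frame(t(qmat), stringsAsFactors = FALSE))
    reads <- data.frame(
      qname = sprintf("read_%06d", seq_len(n)),
      flag = 0L,
      rname = config$chrom_name,
      pos = starts,
      mapq = ifelse(mm, 0L, 60L),
      cigar = paste0(L, "M"),
      seq = seqs,
      qual = quals,
      multimap = mm,
      stringsAsFactors = FALSE)
    make_out(reads)
  })
}

#' Write simulated reads as a coordinate-sorted SAM file
#'
#' @param reads a `sim_reads` data.frame from [simulate_alignments()].
#' @param path output path (`.sam`).
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, path) {
  chrom <- attr(reads, "chrom")
  glen <- attr(reads, "genome_length")
  check_that(!is.null(chrom) && !is.null(glen),
             "reads must come from simulate_alignments()")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, glen))
  body <- character(0)
  if (nrow(reads)) {
    tag <- ifelse(reads$multimap, "\tZM:i:1", "")
    body <- paste0(reads$qname, "\t", reads$flag, "\t", reads$rname, "\t",
                   reads$pos, "\t", reads$mapq, "\t", reads$cigar,
                   "\t*\t0\t0\t", reads$seq, "\t", reads$qual, tag)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a SNP table as a VCF 4.2 mask
#'
#' @param snps SNP table from [plant_sites()].
#' @param path output path (`.vcf`).
#' @param genome_length contig length for the VCF header.
#' @return the path, invisibly.
#' @export
write_vcf <- function(snps, path, genome_length = NA_integer_) {
  header <- c("##fileformat=VCFv4.2",
              "##source=editomeR-simulator",
              '##INFO=<ID=GT,Number=1,Type=String,Description="Simulated genotype">')
  if (!is.na(genome_length) && nrow(snps)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                unique(snps$chrom)[1], genome_length))
  }
  header <- c(header,
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(snps)) {
    body <- paste(snps$chrom, snps$pos, ".", snps$ref, snps$alt, ".", "PASS",
                  paste0("GT=", snps$genotype), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the planted-site ground truth as TSV
#' @param truth truth table from [plant_sites()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## features data.frame <-> GRanges
features_to_granges <- function(features) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand)
  S4Vectors::mcols(gr)$gene <- features$gene
  S4Vectors::mcols(gr)$feature <- features$feature
  S4Vectors::mcols(gr)$tx_type <- features$tx_type
  gr
}

granges_to_features <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene = as.character(S4Vectors::mcols(gr)$gene),
    feature = as.character(S4Vectors::mcols(gr)$feature),
    tx_type = as.character(S4Vectors::mcols(gr)$tx_type),
    stringsAsFactors = FALSE)
}

#' Write feature annotation as BED or GFF3
#'
#' BED records are 0-based half-open with `name = gene|feature|tx_type`;
#' GFF3 records carry the feature class in the type column and `gene` /
#' `tx_type` attributes. [read_features()] round-trips both.
#'
#' @param features annotation data.frame from [simulate_reference()].
#' @param path output path ending in `.bed`, `.gff3` or `.gff`.
#' @return the path, invisibly.
#' @export
write_features <- function(features, path) {
  gr <- features_to_granges(features)
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = paste(features$gene, features$feature, features$tx_type,
                   sep = "|"))
    rtracklayer::export(gr, path, format = "bed")
  } else if (ext %in% c("gff3", "gff")) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = features$feature, gene = features$gene,
      tx_type = features$tx_type, source = "editomeR")
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    stop("unsupported annotation format: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' Read feature annotation from BED or GFF3
#'
#' @param path annotation path written by [write_features()] (or any BED with
#'   `gene|feature|tx_type` names / GFF3 with `gene` attributes).
#' @return annotation data.frame (chrom, start, end, strand, gene, feature,
#'   tx_type), 1-based inclusive.
#' @export
read_features <- function(path) {
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  if (ext == "bed") {
    parts <- strsplit(as.character(S4Vectors::mcols(gr)$name), "|", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad)) {
      stop("BED name field must be gene|feature|tx_type", call. = FALSE)
    }
    S4Vectors::mcols(gr)$gene <- vapply(parts, `[`, "", 1L)
    S4Vectors::mcols(gr)$feature <- vapply(parts, `[`, "", 2L)
    S4Vectors::mcols(gr)$tx_type <- vapply(parts, `[`, "", 3L)
  } else if (ext %in% c("gff3", "gff")) {
    S4Vectors::mcols(gr)$feature <- as.character(S4Vectors::mcols(gr)$type)
  } else {
    stop("unsupported annotation format: ", ext, call. = FALSE)
  }
  feats <- granges_to_features(gr)
  if (any(feats$start > feats$end)) {
    stop("malformed annotation interval: start > end", call. = FALSE)
  }
  feats
}
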