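#' Per-position base counts over kept reads
#'
#' Lays each read's bases into reference space along its CIGAR
#' (insertions contribute nothing, deletion gaps contribute nothing,
#' soft-clipped bases are dropped), discards calls below `min_base_quality`,
#' and tallies A/C/G/T/N per covered reference position.
#'
#' @param kept An `edit_filter` (its `$kept` is used) or an alignments tibble
#'   with `contig`, `pos` (0-based), `cigar`, `seq`, `qual` columns.
#' @param genome Reference genome: `edit_reference`, named `DNAStringSet`, or
#'   FASTA path.
#' @param min_base_quality Phred cutoff for individual base calls (default
#'   20).
#' @return Tibble with one row per covered position: `contig`, `pos`
#'   (0-based), `ref_base`, counts `A`, `C`, `G`, `T`, `N`, and `coverage`
#'   (their sum).
#' @export
build_pileup <- function(kept, genome, min_base_quality = 20L) {
  if (inherits(kept, "edit_filter")) {
    min_base_quality <- kept$params$min_base_quality
    kept <- kept$kept
  }
  kept <- as_tibble(kept)
  assert_cols(kept, c("contig", "pos", "cigar", "seq", "qual"), "kept alignments")
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  genome <- as_genome(genome)
  empty <- tibble(contig = character(), pos = integer(), ref_base = character(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  N = integer(), coverage = integer())
  if (nrow(kept) == 0L) return(empty)

  contig_len <- setNames(Biostrings::width(genome), names(genome))
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(kept$cigar)
  over <- kept$pos + rw > contig_len[kept$contig] | kept$pos < 0L
  if (any(over, na.rm = TRUE)) {
    bad <- which(over)[1L]
    abort(sprintf("alignment extends past contig end: read %s (%s:%d, CIGAR %s)",
                  if (!is.null(kept$qname)) kept$qname[bad] else bad,
                  kept$contig[bad], kept$pos[bad] + 1L, kept$cigar[bad]))
  }

  laid <- GenomicAlignments::sequenceLayer(Biostrings::DNAStringSet(kept$seq),
                                           kept$cigar)

  # mask base calls below the quality cutoff to '.', which the tally below
  # ignores (deletion gaps are already '-' and ignored the same way)
  low_q <- if (min_base_quality > 0L) {
    # any Phred+33 character strictly below the cutoff
    pat <- sprintf("[\\x21-\\x%02X]", 32L + min_base_quality)
    which(grepl(pat, kept$qual, perl = TRUE))
  } else integer(0)
  if (length(low_q) > 0L) {
    laid_q <- GenomicAlignments::sequenceLayer(
      Biostrings::BStringSet(kept$qual[low_q]), kept$cigar[low_q])
    masked <- vapply(seq_along(low_q), function(j) {
      chars <- strsplit(as.character(laid[[low_q[j]]]), "")[[1L]]
      at <- utf8ToInt(as.character(laid_q[[j]])) - 33L < min_base_quality
      chars[at] <- "."
      paste(chars, collapse = "")
    }, character(1))
    laid[low_q] <- Biostrings::DNAStringSet(masked)
  }

  # per-contig pileup via consensusMatrix (C-level per-position counting)
  res <- list()
  for (cn in unique(kept$contig)) {
    i <- which(kept$contig == cn)
    cm <- Biostrings::consensusMatrix(laid[i], shift = kept$pos[i],
                                      width = contig_len[[cn]])
    m <- t(cm[c("A", "C", "G", "T", "N"), , drop = FALSE])
    cov <- as.integer(rowSums(m))
    covered <- which(cov > 0L)
    if (length(covered) == 0L) next
    ref_base <- as.character(
      Biostrings::extractAt(genome[[cn]],
                            IRanges::IRanges(covered, width = 1L)))
    res[[cn]] <- tibble(contig = cn, pos = covered - 1L, ref_base = ref_base,
                        A = as.integer(m[covered, 1L]),
                        C = as.integer(m[covered, 2L]),
                        G = as.integer(m[covered, 3L]),
                        T = as.integer(m[covered, 4L]),
                        N = as.integer(m[covered, 5L]),
                        coverage = cov[covered])
  }
  if (length(res) == 0L) return(empty)
  arrange(bind_rows(res), .data$contig, .data$pos)
}

#' Per-site editing statistics in transcript space
#'
#' Joins pileup columns to the gene they fall in and rotates counts into
#' transcript orientation: for a `-` strand gene each reference base count is
#' complemented (reference T calls are transcript A calls, etc.). The A-to-G
#' editing class therefore reads out as (ref A, alt G) on `+` strand genes
#' and (ref T, alt C) on `-` strand genes. `editing_fraction` is
#' `n_alt / (n_ref + n_alt)` at transcript adenosines (`NA` elsewhere); N
#' calls enter neither numerator nor denominator.
#'
#' @param pileup Tibble from [build_pileup()].
#' @param genes Gene model table, `edit_reference`, or annotation path.
#' @return Tibble with one row per gene-covered position: `gene_id`,
#'   `contig`, `pos` (0-based genomic), `strand`, `biotype`,
#'   `transcript_offset`, `transcript_base`, transcript-space counts
#'   `tx_A`, `tx_C`, `tx_G`, `tx_T`, `tx_N`, `coverage`, and for the A-to-G
#'   class `n_ref`, `n_alt`, `editing_fraction`.
#' @export
site_stats <- function(pileup, genes) {
  genes <- resolve_genes(genes)
  pileup <- as_tibble(pileup)
  if (nrow(pileup) == 0L || nrow(genes) == 0L) {
    return(tibble(gene_id = character(), contig = character(), pos = integer(),
                  strand = character(), biotype = character(),
                  transcript_offset = integer(), transcript_base = character(),
                  tx_A = integer(), tx_C = integer(), tx_G = integer(),
                  tx_T = integer(), tx_N = integer(), coverage = integer(),
                  n_ref = integer(), n_alt = integer(),
                  editing_fraction = double()))
  }
  pos_gr <- GenomicRanges::GRanges(pileup$contig,
                                   IRanges::IRanges(pileup$pos + 1L, width = 1L))
  ov <- GenomicRanges::findOverlaps(pos_gr, gr_from_genes(genes),
                                    ignore.strand = TRUE)
  p <- pileup[S4Vectors::queryHits(ov), ]
  g <- genes[S4Vectors::subjectHits(ov), ]
  minus <- g$strand == "-"
  out <- tibble(
    gene_id = g$gene_id,
    contig = p$contig,
    pos = p$pos,
    strand = g$strand,
    biotype = g$biotype,
    transcript_offset = as.integer(genomic_to_offset(p$pos, g$start, g$end,
                                                     g$strand)),
    transcript_base = if_else(minus, complement_base(p$ref_base), p$ref_base),
    tx_A = if_else(minus, p$T, p$A),
    tx_C = if_else(minus, p$G, p$C),
    tx_G = if_else(minus, p$C, p$G),
    tx_T = if_else(minus, p$A, p$T),
    tx_N = p$N,
    coverage = p$coverage
  )
  out %>%
    mutate(
      n_ref = dplyr::case_when(
        .data$transcript_base == "A" ~ .data$tx_A,
        .data$transcript_base == "C" ~ .data$tx_C,
        .data$transcript_base == "G" ~ .data$tx_G,
        .data$transcript_base == "T" ~ .data$tx_T,
        TRUE ~ NA_integer_),
      n_alt = if_else(.data$transcript_base == "A", .data$tx_G, NA_integer_),
      editing_fraction = if_else(
        .data$transcript_base == "A" & (.data$tx_A + .data$tx_G) > 0L,
        .data$tx_G / (.data$tx_A + .data$tx_G),
        NA_real_)
    ) %>%
    arrange(.data$gene_id, .data$transcript_offset)
}
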