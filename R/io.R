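# File-format boundaries. Internally everything is 0-based half-open;
# 1-based coordinates appear only inside these readers/writers.

#' Write the reference genome as FASTA
#'
#' @param reference An `edit_reference` (or named `DNAStringSet`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(as_genome(reference), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' The feature `type` carries the biotype (`mRNA`/`rRNA`/`tRNA`); `ID` and
#' `expression_weight` are written as attributes.
#'
#' @param genes Gene model table (or an `edit_reference`).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  if (inherits(genes, "edit_reference")) genes <- genes$genes
  gr <- gr_from_genes(genes)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "editscan",
    type = genes$biotype,
    ID = genes$gene_id,
    expression_weight = genes$expression_weight
  )
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3: the biotype comes from the feature `type` (or a `biotype`
#' attribute), the gene id from `ID` or `Name`. BED: standard six columns
#' plus a seventh `biotype` column (and optional eighth `expression_weight`).
#' Unknown biotypes are kept as mRNA with a warning; a missing strand is an
#' error, because the antisense rule cannot be applied without it.
#'
#' @param path Path to a `.gff`/`.gff3` or `.bed` file.
#' @return A gene model tibble (see [gene_models()]).
#' @export
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "GFF3")
    md <- as.data.frame(S4Vectors::mcols(gr))
    gene_id <- if (!is.null(md$ID)) md$ID else md$Name
    if (is.null(gene_id)) gene_id <- sprintf("feature%04d", seq_along(gr))
    biotype <- if (!is.null(md$biotype)) as.character(md$biotype)
               else as.character(md$type)
    w <- if (!is.null(md$expression_weight)) {
      as.numeric(as.character(md$expression_weight))
    } else 1
    genes <- tibble(
      gene_id = as.character(gene_id),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = biotype,
      expression_weight = w
    )
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED",
                              extraCols = c(biotype = "character",
                                            expression_weight = "numeric"))
    md <- as.data.frame(S4Vectors::mcols(gr))
    genes <- tibble(
      gene_id = as.character(md$name),
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      biotype = md$biotype,
      expression_weight = if (!is.null(md$expression_weight) &&
                              !all(is.na(md$expression_weight)))
        md$expression_weight else 1
    )
  } else {
    abort(sprintf("unsupported annotation format '.%s' (use GFF3 or BED)", ext))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    bad <- which(!genes$strand %in% c("+", "-"))
    abort(sprintf("annotation record(s) without strand: %s",
                  paste(genes$gene_id[bad], collapse = ", ")))
  }
  gene_models(genes)
}

#' Write simulated reads as FASTQ
#'
#' @param sim An `edit_sim` (or its `reads` tibble).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "edit_sim")) sim$reads else as_tibble(sim)
  assert_cols(reads, c("qname", "seq", "qual"), "reads table")
  lines <- as.vector(rbind(paste0("@", reads$qname), reads$seq,
                           "+", reads$qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write truth alignments as SAM
#'
#' Multi-mapping evidence is encoded both ways common aligners do it: MAPQ 0
#' and an `NH` hit-count tag of 2 or more; unique reads carry MAPQ 60, NH 1.
#'
#' @param sim An `edit_sim`, or an alignments tibble.
#' @param path Output SAM path.
#' @param contigs Contig table (`name`, `length`); taken from the simulation's
#'   reference when `sim` is an `edit_sim`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path, contigs = NULL) {
  if (inherits(sim, "edit_sim")) {
    aln <- sim$alignments
    contigs <- sim$reference$contigs
  } else {
    aln <- as_tibble(sim)
    if (is.null(contigs)) abort("`contigs` required when writing a bare alignment table")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs$name, contigs$length))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tNH:i:%d",
                  aln$qname, aln$flag, aln$contig, aln$pos + 1L, aln$mapq,
                  aln$cigar, aln$seq, aln$qual, aln$nh)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read aligned reads from SAM or BAM into a tibble
#'
#' SAM text is converted with [Rsamtools::asBam()] and scanned; each record
#' becomes one row with 0-based `pos`, the `NH` hit-count tag (1 when
#' absent), and the alignment `strand`.
#'
#' @param path Path to a `.sam` or `.bam` file, or an alignments tibble
#'   (returned unchanged, so simulator output can skip the round-trip).
#' @return Tibble with columns `qname`, `flag`, `contig`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `nh`, `strand`.
#' @export
read_alignments <- function(path) {
  if (is.data.frame(path)) {
    return(assert_cols(as_tibble(path),
                       c("qname", "flag", "contig", "pos", "mapq", "cigar",
                         "seq", "qual", "nh"),
                       "alignments table"))
  }
  ext <- tolower(tools::file_ext(path))
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else if (ext == "bam") {
    path
  } else {
    abort(sprintf("unsupported alignment format '.%s'", ext))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(res$qname))
  tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    contig = as.character(res$rname),
    pos = as.integer(res$pos) - 1L,
    mapq = as.integer(res$mapq),
    cigar = res$cigar,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    nh = if_else(is.na(nh), 1L, as.integer(nh)),
    strand = if_else(bitwAnd(as.integer(res$flag), 16L) > 0L, "-", "+")
  )
}

#' Read a target-locus list
#'
#' Tab-separated with header: `contig`, `pos` (1-based), `strand`, `label`.
#'
#' @param path TSV path.
#' @return Tibble with the columns above plus 0-based `pos0`.
#' @export
read_loci <- function(path) {
  loci <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(loci, c("contig", "pos", "strand", "label"), "loci list")
  mutate(loci, pos0 = as.integer(.data$pos) - 1L)
}
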