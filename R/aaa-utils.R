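# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Vectorised reverse complement on plain character vectors. Biostrings does
# the heavy lifting; this wrapper keeps the tibble columns as characters.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  unname(COMPLEMENT[x])
}

# transcript offset <-> genomic position (0-based), given gene start/end
# (0-based half-open) and strand; all arguments broadcast to common length.
offset_to_genomic <- function(offset, start, end, strand) {
  n <- max(length(offset), length(start), length(strand))
  ifelse(rep_len(strand, n) == "+",
         rep_len(start, n) + rep_len(offset, n),
         rep_len(end, n) - 1L - rep_len(offset, n))
}

genomic_to_offset <- function(pos, start, end, strand) {
  n <- max(length(pos), length(start), length(strand))
  ifelse(rep_len(strand, n) == "+",
         rep_len(pos, n) - rep_len(start, n),
         rep_len(end, n) - 1L - rep_len(pos, n))
}

# Phred+33 quality string of constant Q30, by read length.
const_qual <- function(widths, q = 30L) {
  strrep(rawToChar(as.raw(33L + q)), widths)
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# The genome travels as a named Biostrings::DNAStringSet; accept a named
# character vector too.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  if (is.list(genome) && !is.null(genome$genome)) return(as_genome(genome$genome))
  abort("`genome` must be a named DNAStringSet, a named character vector, or a reference object")
}

gr_from_genes <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
}
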