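#' Validate a tibble of gene models
#'
#' A gene model table has one row per gene: `gene_id`, `contig`, `start`,
#' `end` (0-based half-open), `strand` (`"+"`/`"-"`), `biotype`
#' (`mRNA`/`rRNA`/`tRNA`) and a non-negative `expression_weight`. Intervals of
#' distinct genes on the same strand of the same contig must not overlap.
#'
#' @param genes A data frame of gene models.
#' @return The validated genes as a tibble (invisibly usable in a pipe).
#' @export
gene_models <- function(genes) {
  genes <- as_tibble(genes)
  assert_cols(genes,
              c("gene_id", "contig", "start", "end", "strand", "biotype",
                "expression_weight"),
              "gene model table")
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("duplicated gene_id(s): %s",
                  paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                        collapse = ", ")))
  }
  bad <- genes$start >= genes$end
  if (any(bad)) {
    abort(sprintf("gene(s) with start >= end: %s",
                  paste(genes$gene_id[bad], collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-'")
  }
  if (any(genes$expression_weight < 0)) {
    abort("expression_weight must be non-negative")
  }
  unknown <- !genes$biotype %in% c("mRNA", "rRNA", "tRNA")
  if (any(unknown)) {
    warn(sprintf("unknown biotype for %s; treating as mRNA",
                 paste(genes$gene_id[unknown], collapse = ", ")))
    genes$biotype[unknown] <- "mRNA"
  }
  # same-strand overlap check, naming both offenders
  by_cs <- split(genes, paste(genes$contig, genes$strand))
  for (grp in by_cs) {
    if (nrow(grp) < 2L) next
    grp <- arrange(grp, .data$start)
    prev_end <- grp$end[-nrow(grp)]
    nxt_start <- grp$start[-1L]
    hit <- which(nxt_start < prev_end)
    if (length(hit) > 0L) {
      abort(sprintf("same-strand genes overlap: %s and %s",
                    grp$gene_id[hit[1L]], grp$gene_id[hit[1L] + 1L]))
    }
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes
}

#' Generate a random reference genome for a set of gene models
#'
#' Draws random contig sequences at the requested GC content, then patches
#' each gene so its transcript contains at least one adenosine (a requirement
#' of the editing simulator). Deterministic under `seed`.
#'
#' @param genes Gene model table (see [gene_models()]).
#' @param contigs A data frame with columns `name`, `length` (bp, >= 1000)
#'   and `gc` (GC fraction in `[0, 1]`).
#' @param seed Integer seed; identical inputs and seed give byte-identical
#'   sequence.
#' @return An object of class `edit_reference`: a list with `genome` (named
#'   [Biostrings::DNAStringSet]), `genes`, `contigs`, and `decoys` (regions
#'   added later by [plant_decoy()]).
#' @examples
#' layout <- design_genome(n_mrna = 5, n_phage = 2, seed = 1)
#' ref <- generate_reference(layout$genes, layout$contigs, seed = 1)
#' ref
#' @export
generate_reference <- function(genes, contigs, seed = 1L) {
  contigs <- as_tibble(contigs)
  assert_cols(contigs, c("name", "length", "gc"), "contig table")
  if (anyDuplicated(contigs$name)) abort("contig names must be unique")
  if (any(contigs$length < 1000L)) abort("contig lengths must be >= 1000 bp")
  if (any(contigs$gc < 0 | contigs$gc > 1)) abort("gc must be in [0, 1]")
  genes <- gene_models(genes)
  if (!all(genes$contig %in% contigs$name)) {
    abort("gene(s) reference unknown contig(s)")
  }
  lims <- setNames(as.integer(contigs$length), contigs$name)
  out_of_bounds <- genes$end > lims[genes$contig] | genes$start < 0L
  if (any(out_of_bounds)) {
    abort(sprintf("gene(s) outside contig bounds: %s",
                  paste(genes$gene_id[out_of_bounds], collapse = ", ")))
  }

  seqs <- withr::with_seed(seed, {
    lapply(seq_len(nrow(contigs)), function(i) {
      gc <- contigs$gc[i]
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(BASES, contigs$length[i], replace = TRUE, prob = p),
            collapse = "")
    })
  })
  genome <- Biostrings::DNAStringSet(setNames(unlist(seqs), contigs$name))

  # guarantee >=1 A per transcript: a '+' gene needs an A in its genomic
  # slice, a '-' gene needs a T; patch the middle base deterministically.
  slices <- extract_gene_slices(genome, genes)
  need <- ifelse(genes$strand == "+", "A", "T")
  lacking <- which(!vapply(seq_along(slices),
                           function(i) grepl(need[i], slices[i], fixed = TRUE),
                           logical(1)))
  for (i in lacking) {
    g <- genes[i, ]
    mid <- g$start + ((g$end - g$start) %/% 2L) + 1L
    Biostrings::subseq(genome[[g$contig]], mid, mid) <-
      Biostrings::DNAString(need[i])
  }

  structure(
    list(genome = genome, genes = genes, contigs = contigs,
         decoys = tibble(source_gene = character(), contig = character(),
                         start = integer(), end = integer()),
         seed = as.integer(seed)),
    class = "edit_reference"
  )
}

#' @export
print.edit_reference <- function(x, ...) {
  cat("<edit_reference>\n")
  cat(sprintf("  contigs: %s\n",
              paste(sprintf("%s (%d bp)", x$contigs$name, x$contigs$length),
                    collapse = ", ")))
  cat(sprintf("  genes:   %d (%s)\n", nrow(x$genes),
              paste(sprintf("%d %s", table(x$genes$biotype),
                            names(table(x$genes$biotype))), collapse = ", ")))
  if (nrow(x$decoys) > 0L) {
    cat(sprintf("  decoys:  %d planted segment(s)\n", nrow(x$decoys)))
  }
  invisible(x)
}

#' Duplicate a gene's sequence into unannotated space to create multi-mappers
#'
#' Copies the genomic sequence of `source_gene` into intergenic regions, so
#' reads simulated from that gene align equally well to several positions.
#' The copies are not annotated as genes; the simulator marks reads from the
#' source gene as multi-mapping (MAPQ 0, `NH` = copies + 1), which the
#' alignment filter must discard.
#'
#' @param reference An `edit_reference` from [generate_reference()].
#' @param source_gene `gene_id` of the gene to duplicate.
#' @param copies Number of extra copies to plant (>= 1).
#' @return The modified `edit_reference`; `$decoys` gains one row per copy.
#' @export
plant_decoy <- function(reference, source_gene, copies = 1L) {
  stopifnot(inherits(reference, "edit_reference"))
  if (copies < 1L) abort("`copies` must be >= 1")
  g <- reference$genes[reference$genes$gene_id == source_gene, ]
  if (nrow(g) != 1L) abort(sprintf("unknown source gene '%s'", source_gene))
  seg <- as.character(Biostrings::subseq(reference$genome[[g$contig]],
                                         g$start + 1L, g$end))
  len <- nchar(seg)

  # occupied = genes plus previously planted decoys, any strand
  occ <- bind_rows(
    select(reference$genes, "contig", "start", "end"),
    select(reference$decoys, "contig", "start", "end")
  )
  placed <- 0L
  new_rows <- list()
  for (ci in seq_len(nrow(reference$contigs))) {
    if (placed >= copies) break
    cname <- reference$contigs$name[ci]
    clen <- reference$contigs$length[ci]
    occ_c <- occ[occ$contig == cname, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = occ_c$start + 1L,
                                           end = occ_c$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, clen), ir)
    # 1 bp of padding each side so planted copies never abut annotation
    gaps <- gaps[IRanges::width(gaps) >= len + 2L]
    for (gi in seq_along(gaps)) {
      gstart <- IRanges::start(gaps)[gi] + 1L  # 1-based, padded
      while (placed < copies &&
             gstart + len - 1L <= IRanges::end(gaps)[gi] - 1L) {
        Biostrings::subseq(reference$genome[[cname]],
                           gstart, gstart + len - 1L) <- Biostrings::DNAString(seg)
        new_rows[[length(new_rows) + 1L]] <- tibble(
          source_gene = source_gene, contig = cname,
          start = gstart - 1L, end = gstart + len - 1L)
        occ <- bind_rows(occ, new_rows[[length(new_rows)]][, c("contig", "start", "end")])
        placed <- placed + 1L
        gstart <- gstart + len + 1L
      }
      if (placed >= copies) break
    }
  }
  if (placed < copies) {
    abort(sprintf("not enough intergenic space to plant %d copies of '%s' (placed %d)",
                  copies, source_gene, placed))
  }
  reference$decoys <- bind_rows(reference$decoys, bind_rows(new_rows))
  reference
}

#' Lay out a miniature host + phage genome design
#'
#' Builds the contig and gene tables for a compact two-contig community: a
#' bacterial host chromosome carrying mRNA, rRNA and tRNA genes, and a phage
#' contig carrying mRNA genes. Genes are placed sequentially with random
#' intergenic gaps and random strands. Expression weights emulate a real
#' transcriptome: log-normal for mRNAs, heavy constant weights for rRNA
#' (the rRNA load the filter must discard) and moderate weights for tRNA.
#'
#' @param n_mrna Host mRNA gene count.
#' @param n_rrna Host rRNA gene count (the filter's discard targets).
#' @param n_trna Host tRNA gene count.
#' @param n_phage Phage mRNA gene count.
#' @param mrna_length Two-vector range of mRNA gene lengths (bp).
#' @param trna_length Two-vector range of tRNA gene lengths (bp).
#' @param rrna_length rRNA gene length (bp).
#' @param host_gc,phage_gc GC fraction per contig.
#' @param rrna_weight,trna_weight Expression weights for structural RNAs,
#'   relative to the log-normal (meanlog 0, sdlog 1) mRNA weights.
#' @param phage_weight_factor Multiplier on phage mRNA weights (phage
#'   transcripts dominate late infection; 1 = host-like).
#' @param seed Integer seed.
#' @return A list with `contigs` and `genes` tibbles for
#'   [generate_reference()].
#' @export
design_genome <- function(n_mrna = 200L, n_rrna = 2L, n_trna = 3L,
                          n_phage = 20L,
                          mrna_length = c(200L, 400L),
                          trna_length = c(76L, 90L),
                          rrna_length = 500L,
                          host_gc = 0.5, phage_gc = 0.4,
                          rrna_weight = 50, trna_weight = 5,
                          phage_weight_factor = 1,
                          seed = 1L) {
  withr::with_seed(seed, {
    lay_contig <- function(contig, prefix, biotypes, lengths, weights) {
      n <- length(lengths)
      gaps <- sample(50:150, n, replace = TRUE)
      starts <- cumsum(gaps + c(0L, lengths[-n])) # gap before each gene
      tibble(
        gene_id = sprintf("%s%03d", prefix, seq_len(n)),
        contig = contig,
        start = as.integer(starts),
        end = as.integer(starts + lengths),
        strand = sample(c("+", "-"), n, replace = TRUE),
        biotype = biotypes,
        expression_weight = weights
      )
    }
    host_len <- c(sample(mrna_length[1]:mrna_length[2], n_mrna, replace = TRUE),
                  rep(rrna_length, n_rrna),
                  sample(trna_length[1]:trna_length[2], n_trna, replace = TRUE))
    host_bio <- c(rep("mRNA", n_mrna), rep("rRNA", n_rrna), rep("tRNA", n_trna))
    host_w <- c(stats::rlnorm(n_mrna), rep(rrna_weight, n_rrna),
                rep(trna_weight, n_trna))
    ord <- sample(length(host_len))  # interleave biotypes along the contig
    host <- lay_contig("host", "g", host_bio[ord], host_len[ord], host_w[ord])
    host$gene_id <- sprintf("%s%03d",
                            c(mRNA = "g", rRNA = "rrn", tRNA = "trn")[host$biotype],
                            stats::ave(seq_len(nrow(host)), host$biotype,
                                       FUN = seq_along))
    # tail margin leaves intergenic room for plant_decoy() copies
    margin <- 3L * (max(mrna_length) + 2L)
    genes <- host
    contigs <- tibble(name = "host",
                      length = max(1000L, max(host$end) + margin),
                      gc = host_gc)
    if (n_phage > 0L) {
      ph_len <- sample(mrna_length[1]:mrna_length[2], n_phage, replace = TRUE)
      phage <- lay_contig("phage", "p", rep("mRNA", n_phage), ph_len,
                          stats::rlnorm(n_phage) * phage_weight_factor)
      genes <- bind_rows(genes, phage)
      contigs <- bind_rows(contigs,
                           tibble(name = "phage",
                                  length = max(1000L, max(phage$end) + margin),
                                  gc = phage_gc))
    }
    list(contigs = contigs, genes = gene_models(genes))
  })
}

#' Extract transcript sequences (5'->3') for each gene
#'
#' @param reference An `edit_reference`.
#' @return Named character vector of transcript sequences, one per gene.
#' @export
transcript_seqs <- function(reference) {
  stopifnot(inherits(reference, "edit_reference"))
  genes <- reference$genes
  out <- extract_gene_slices(reference$genome, genes)
  minus <- genes$strand == "-"
  if (any(minus)) out[minus] <- revcomp(out[minus])
  setNames(out, genes$gene_id)
}

# genomic-strand sequence of every gene interval, batched per contig
extract_gene_slices <- function(genome, genes) {
  out <- character(nrow(genes))
  for (cn in unique(genes$contig)) {
    i <- which(genes$contig == cn)
    out[i] <- as.character(Biostrings::extractAt(
      genome[[cn]],
      IRanges::IRanges(genes$start[i] + 1L, genes$end[i])))
  }
  out
}
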