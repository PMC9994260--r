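#' Transcript offsets of adenosines in a gene
#'
#' Convenience for choosing valid edit-site positions: returns the 0-based
#' transcript-space offsets whose base is A.
#'
#' @param reference An `edit_reference`.
#' @param gene_id Gene to inspect.
#' @return Integer vector of 0-based offsets.
#' @export
adenosine_offsets <- function(reference, gene_id) {
  tx <- transcript_seqs(reference)
  if (!gene_id %in% names(tx)) abort(sprintf("unknown gene '%s'", gene_id))
  as.integer(gregexpr("A", tx[[gene_id]], fixed = TRUE)[[1L]]) - 1L
}

validate_edit_sites <- function(edit_sites, tx) {
  if (is.null(edit_sites) || nrow(edit_sites) == 0L) {
    return(tibble(gene_id = character(), offset = integer(),
                  true_rate = double(), label = character()))
  }
  edit_sites <- as_tibble(edit_sites)
  assert_cols(edit_sites, c("gene_id", "offset", "true_rate"), "edit site table")
  if (!"label" %in% names(edit_sites)) edit_sites$label <- NA_character_
  for (i in seq_len(nrow(edit_sites))) {
    s <- edit_sites[i, ]
    if (!s$gene_id %in% names(tx)) {
      abort(sprintf("edit site %d references unknown gene '%s'", i, s$gene_id))
    }
    if (s$true_rate < 0 || s$true_rate > 1) {
      abort(sprintf("edit site %s:%d has true_rate outside [0, 1]",
                    s$gene_id, s$offset))
    }
    if (s$offset < 0L || s$offset >= nchar(tx[[s$gene_id]])) {
      abort(sprintf("edit site %s:%d is outside the transcript",
                    s$gene_id, s$offset))
    }
    base <- substr(tx[[s$gene_id]], s$offset + 1L, s$offset + 1L)
    if (base != "A") {
      abort(sprintf("edit site %s:%d is not an adenosine in transcript space (found %s)",
                    s$gene_id, s$offset, base))
    }
  }
  edit_sites$offset <- as.integer(edit_sites$offset)
  edit_sites
}

#' Simulate strand-specific RNA-seq reads with injected A-to-I editing
#'
#' Emulates a dUTP-type (first-strand) protocol: reads are sequenced
#' antisense to their gene, so a read from a `+` strand gene aligns on the
#' `-` strand and vice versa. Editing is Bernoulli per transcript *molecule*
#' per site (A->G in transcript space) before fragmentation, so reads that
#' share a molecule share its edits and the per-site editing-fraction
#' estimator targets exactly `true_rate`. Uniform substitution errors (each
#' of the three alternate bases equally likely, so any one mismatch class has
#' background rate `error_rate / 3`) are applied after fragmentation.
#' Constant base quality Q30 is written. Reads from genes duplicated with
#' [plant_decoy()] are flagged multi-mapping (MAPQ 0, `NH` >= 2); all other
#' reads get MAPQ 60, `NH` 1.
#'
#' @param reference An `edit_reference`.
#' @param edit_sites `NULL` or a data frame with `gene_id`, `offset` (0-based
#'   transcript coordinate of an A), `true_rate` in `[0, 1]`, and optional
#'   `label`.
#' @param read_length Read length (bp); must not exceed the shortest
#'   transcript.
#' @param mean_depth Mean fold-coverage over expressed transcripts; per-gene
#'   coverage scales with `expression_weight`.
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer seed; identical inputs give byte-identical output.
#' @param indel_read_fraction Fraction of reads given a 1-bp insertion or
#'   deletion in their CIGAR (the filter's indel-discard targets).
#' @param reads_per_molecule Reads drawn from each transcript molecule.
#' @return An object of class `edit_sim`: list with tibbles `reads` (FASTQ
#'   orientation), `alignments` (truth alignments, reference orientation,
#'   0-based `pos`), `truth` (per injected site: realized edited/total
#'   molecule tallies), plus the `reference` and the call parameters.
#' @examples
#' layout <- design_genome(n_mrna = 4, n_phage = 0, n_rrna = 1, seed = 2)
#' ref <- generate_reference(layout$genes, layout$contigs, seed = 2)
#' sites <- tibble::tibble(gene_id = "g001",
#'                         offset = adenosine_offsets(ref, "g001")[5],
#'                         true_rate = 0.4, label = "positive-control")
#' sim <- simulate_reads(ref, sites, mean_depth = 20, seed = 3)
#' sim$truth
#' @export
simulate_reads <- function(reference, edit_sites = NULL,
                           read_length = 50L, mean_depth = 50,
                           error_rate = 0.001, seed = 1L,
                           indel_read_fraction = 0,
                           reads_per_molecule = 1L) {
  stopifnot(inherits(reference, "edit_reference"))
  if (error_rate < 0 || error_rate >= 0.25) {
    abort("`error_rate` must be in [0, 0.25)")
  }
  if (indel_read_fraction < 0 || indel_read_fraction > 1) {
    abort("`indel_read_fraction` must be in [0, 1]")
  }
  genes <- reference$genes
  tx <- transcript_seqs(reference)
  tlen <- nchar(tx)
  if (read_length > min(tlen)) {
    abort(sprintf("read_length %d exceeds shortest transcript (%d bp)",
                  read_length, min(tlen)))
  }
  edit_sites <- validate_edit_sites(edit_sites, tx)

  empty <- function() {
    structure(list(
      reads = tibble(qname = character(), seq = character(), qual = character()),
      alignments = tibble(qname = character(), flag = integer(),
                          contig = character(), pos = integer(),
                          mapq = integer(), cigar = character(),
                          seq = character(), qual = character(),
                          nh = integer(), gene_id = character(),
                          strand = character()),
      truth = tibble(gene_id = character(), contig = character(),
                     genomic_pos = integer(), transcript_offset = integer(),
                     true_rate = double(), label = character(),
                     n_edited = integer(), n_total = integer()),
      reference = reference,
      config = list(read_length = read_length, mean_depth = mean_depth,
                    error_rate = error_rate, seed = seed,
                    indel_read_fraction = indel_read_fraction,
                    reads_per_molecule = reads_per_molecule)),
      class = "edit_sim")
  }
  if (mean_depth <= 0) {
    warn("mean_depth is 0; returning empty simulation")
    return(empty())
  }

  decoy_genes <- unique(reference$decoys$source_gene)
  w <- genes$expression_weight
  mean_w <- mean(w[w > 0])

  withr::with_seed(seed, {
    per_gene <- vector("list", nrow(genes))
    truth_rows <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$expression_weight <= 0) next
      cov_g <- mean_depth * g$expression_weight / mean_w
      n_mol <- as.integer(round(cov_g * tlen[i] /
                                  (read_length * reads_per_molecule)))
      if (n_mol < 1L) next
      sites_g <- edit_sites[edit_sites$gene_id == g$gene_id, ]
      k <- nrow(sites_g)

      # molecule-level Bernoulli edits; group molecules by edit pattern so
      # only distinct edited sequences are materialised
      if (k > 0L) {
        edits <- matrix(rbinom(n_mol * k, 1L, rep(sites_g$true_rate,
                                                  each = n_mol)),
                        nrow = n_mol)
        key <- apply(edits, 1L, paste, collapse = "")
        upat <- unique(key)
        pat_seq <- vapply(upat, function(p) {
          s <- tx[[i]]
          on <- sites_g$offset[strsplit(p, "")[[1L]] == "1"]
          for (o in on) substr(s, o + 1L, o + 1L) <- "G"
          s
        }, character(1))
        pat_of_mol <- match(key, upat)
        truth_rows[[i]] <- mutate(sites_g,
          contig = g$contig,
          genomic_pos = as.integer(offset_to_genomic(.data$offset, g$start,
                                                     g$end, g$strand)),
          transcript_offset = .data$offset,
          n_edited = as.integer(colSums(edits)),
          n_total = n_mol) %>%
          select("gene_id", "contig", "genomic_pos", "transcript_offset",
                 "true_rate", "label", "n_edited", "n_total")
      } else {
        pat_seq <- tx[[i]]
        pat_of_mol <- rep(1L, n_mol)
      }

      n_reads <- n_mol * as.integer(reads_per_molecule)
      mol <- rep(seq_len(n_mol), each = reads_per_molecule)
      start <- sample.int(tlen[i] - read_length + 1L, n_reads,
                          replace = TRUE) - 1L
      frag <- substring(pat_seq[pat_of_mol[mol]], start + 1L,
                        start + read_length)

      # uniform substitution errors in fragment space (the error model is
      # invariant under complementation, so this equals sequencing-space noise)
      n_err <- rbinom(n_reads, read_length, error_rate)
      for (r in which(n_err > 0L)) {
        chars <- strsplit(frag[r], "")[[1L]]
        at <- sample.int(read_length, n_err[r])
        chars[at] <- vapply(chars[at],
                            function(b) sample(setdiff(BASES, b), 1L),
                            character(1))
        frag[r] <- paste(chars, collapse = "")
      }

      per_gene[[i]] <- tibble(
        gene_idx = i, mol = mol, start = start, frag = frag)
    }

    reads <- bind_rows(per_gene)
    if (nrow(reads) == 0L) {
      warn("no reads generated (all weights/depths too low)")
      empty()
    } else {
    g <- genes[reads$gene_idx, ]
    from_plus <- g$strand == "+"
    aln <- tibble(
      qname = sprintf("%s_m%d_r%06d", g$gene_id, reads$mol,
                      seq_len(nrow(reads))),
      flag = ifelse(from_plus, 16L, 0L),
      contig = g$contig,
      pos = as.integer(ifelse(from_plus, g$start + reads$start,
                              g$end - reads$start - read_length)),
      mapq = ifelse(g$gene_id %in% decoy_genes, 0L, 60L),
      cigar = sprintf("%dM", read_length),
      seq = ifelse(from_plus, reads$frag, NA_character_),
      qual = const_qual(read_length),
      nh = 1L,
      gene_id = g$gene_id,
      strand = ifelse(from_plus, "-", "+")
    )
    if (any(!from_plus)) aln$seq[!from_plus] <- revcomp(reads$frag[!from_plus])
    if (length(decoy_genes) > 0L) {
      cnt <- table(reference$decoys$source_gene)
      hit <- aln$gene_id %in% decoy_genes
      aln$nh[hit] <- as.integer(cnt[aln$gene_id[hit]]) + 1L
    }

    # inject 1-bp indels into a fraction of reads (reference orientation;
    # flanking matches preserved so CIGARs stay canonical)
    n_indel <- round(indel_read_fraction * nrow(aln))
    if (n_indel > 0L) {
      idx <- sample.int(nrow(aln), n_indel)
      is_del <- runif(n_indel) < 0.5
      for (j in seq_len(n_indel)) {
        r <- idx[j]
        if (is_del[j]) {
          kpos <- sample(2:(read_length - 1L), 1L)
          aln$seq[r] <- paste0(substr(aln$seq[r], 1L, kpos - 1L),
                               substr(aln$seq[r], kpos + 1L, read_length))
          aln$cigar[r] <- sprintf("%dM1D%dM", kpos - 1L, read_length - kpos)
          aln$qual[r] <- const_qual(read_length - 1L)
        } else {
          kpos <- sample(1:(read_length - 1L), 1L)
          aln$seq[r] <- paste0(substr(aln$seq[r], 1L, kpos),
                               sample(BASES, 1L),
                               substr(aln$seq[r], kpos + 1L, read_length))
          aln$cigar[r] <- sprintf("%dM1I%dM", kpos, read_length - kpos)
          aln$qual[r] <- const_qual(read_length + 1L)
        }
      }
    }

    # FASTQ orientation: reverse complement of the reference-oriented SEQ for
    # reverse-strand alignments, identity otherwise
    fq_seq <- aln$seq
    rev <- aln$flag == 16L
    if (any(rev)) fq_seq[rev] <- revcomp(fq_seq[rev])
    fastq <- tibble(qname = aln$qname, seq = fq_seq,
                    qual = const_qual(nchar(fq_seq)))

    truth <- bind_rows(truth_rows)
    if (nrow(truth) == 0L) {
      truth <- tibble(gene_id = character(), contig = character(),
                      genomic_pos = integer(), transcript_offset = integer(),
                      true_rate = double(), label = character(),
                      n_edited = integer(), n_total = integer())
    }

    structure(list(
      reads = fastq, alignments = aln, truth = truth, reference = reference,
      config = list(read_length = read_length, mean_depth = mean_depth,
                    error_rate = error_rate, seed = seed,
                    indel_read_fraction = indel_read_fraction,
                    reads_per_molecule = reads_per_molecule)),
      class = "edit_sim")
    }
  })
}

#' @export
print.edit_sim <- function(x, ...) {
  cat("<edit_sim>\n")
  cat(sprintf("  reads: %d x %d bp, error rate %g\n", nrow(x$reads),
              x$config$read_length, x$config$error_rate))
  cat(sprintf("  injected sites: %d\n", nrow(x$truth)))
  invisible(x)
}
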