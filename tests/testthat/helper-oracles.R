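# Independent oracles and fixture builders. These deliberately use naive
# nested loops and manual parsing so they share no code path with the
# package implementation they check.

# A compact reference with unit expression weights, so mean_depth equals the
# per-gene coverage directly.
flat_ref <- function(n_genes = 4L, gene_len = 300L, n_rrna = 1L, seed = 1L,
                     contig_len = NULL) {
  starts <- 100L + (seq_len(n_genes + n_rrna) - 1L) * (gene_len + 120L)
  genes <- tibble::tibble(
    gene_id = c(sprintf("g%02d", seq_len(n_genes)),
                if (n_rrna > 0L) sprintf("rrn%02d", seq_len(n_rrna))),
    contig = "chr",
    start = starts,
    end = starts + gene_len,
    strand = rep(c("+", "-"), length.out = n_genes + n_rrna),
    biotype = c(rep("mRNA", n_genes), rep("rRNA", n_rrna)),
    expression_weight = 1
  )
  contigs <- tibble::tibble(
    name = "chr",
    length = max(max(genes$end) + 1500L, contig_len %||% 0L, 1000L),
    gc = 0.5)
  generate_reference(genes, contigs, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive per-read nested-loop pileup: manual CIGAR walk, one base at a time.
naive_pileup <- function(kept, genome, min_base_quality = 20L) {
  genome <- as.character(genome)
  tally <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(kept))) {
    ops <- regmatches(kept$cigar[r],
                      gregexpr("[0-9]+[MIDNSHP=X]", kept$cigar[r]))[[1L]]
    rpos <- kept$pos[r]
    qpos <- 1L
    seqc <- strsplit(kept$seq[r], "")[[1L]]
    qualc <- utf8ToInt(kept$qual[r]) - 33L
    for (op in ops) {
      len <- as.integer(substr(op, 1L, nchar(op) - 1L))
      typ <- substr(op, nchar(op), nchar(op))
      if (typ %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          if (qualc[qpos] >= min_base_quality &&
              seqc[qpos] %in% c("A", "C", "G", "T", "N")) {
            key <- paste0(kept$contig[r], ":", rpos)
            cur <- tally[[key]]
            if (is.null(cur)) cur <- c(A = 0L, C = 0L, G = 0L, T = 0L, N = 0L)
            cur[seqc[qpos]] <- cur[seqc[qpos]] + 1L
            tally[[key]] <- cur
          }
          rpos <- rpos + 1L
          qpos <- qpos + 1L
        }
      } else if (typ == "I" || typ == "S") {
        qpos <- qpos + len
      } else if (typ == "D" || typ == "N") {
        rpos <- rpos + len
      }
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L) {
    return(tibble::tibble(contig = character(), pos = integer(),
                          A = integer(), C = integer(), G = integer(),
                          T = integer(), N = integer(), coverage = integer()))
  }
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- tibble::tibble(
    contig = vapply(parts, `[[`, "", 1L),
    pos = as.integer(vapply(parts, `[[`, "", 2L)),
    A = vapply(keys, function(k) tally[[k]][["A"]], 0L),
    C = vapply(keys, function(k) tally[[k]][["C"]], 0L),
    G = vapply(keys, function(k) tally[[k]][["G"]], 0L),
    T = vapply(keys, function(k) tally[[k]][["T"]], 0L),
    N = vapply(keys, function(k) tally[[k]][["N"]], 0L)
  )
  out$coverage <- out$A + out$C + out$G + out$T + out$N
  out[order(out$contig, out$pos), ]
}

# Random small pileup instance: hand-built alignments over a short genome,
# mixing plain, indel-bearing, soft-clipped, low-quality and N-containing
# reads.
random_pileup_instance <- function(seed) {
  set.seed(seed)
  glen <- 120L
  genome <- Biostrings::DNAStringSet(
    setNames(paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                   collapse = ""), "ctg"))
  n <- sample.int(50L, 1L)
  reads <- lapply(seq_len(n), function(i) {
    kind <- sample(c("plain", "ins", "del", "clip"), 1L,
                   prob = c(0.6, 0.15, 0.15, 0.1))
    core <- 20L
    pos <- sample.int(glen - core - 2L, 1L) - 1L
    bases <- sample(c("A", "C", "G", "T", "N"), core + 2L, replace = TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    quals <- sample(10:40, core + 2L, replace = TRUE)
    if (kind == "plain") {
      len <- core
      cigar <- sprintf("%dM", len)
    } else if (kind == "ins") {
      len <- core + 1L
      cigar <- sprintf("%dM1I%dM", 8L, core - 8L)
    } else if (kind == "del") {
      len <- core
      cigar <- sprintf("%dM1D%dM", 8L, core - 8L)
    } else {
      len <- core + 2L
      cigar <- sprintf("1S%dM1S", core)
    }
    tibble::tibble(
      qname = sprintf("r%03d", i), flag = 0L, contig = "ctg", pos = pos,
      mapq = 60L, cigar = cigar,
      seq = paste(bases[seq_len(len)], collapse = ""),
      qual = intToUtf8(33L + quals[seq_len(len)], multiple = FALSE),
      nh = 1L)
  })
  list(genome = genome, kept = dplyr::bind_rows(reads))
}

# Brute-force read classifier: applies the exclusion rules in the documented
# order with plain loops over genes.
naive_classify <- function(aln, genes, expect_policy = "any_overlap") {
  ref_width <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
    w <- 0L
    for (op in ops) {
      typ <- substr(op, nchar(op), nchar(op))
      if (typ %in% c("M", "D", "N", "=", "X")) {
        w <- w + as.integer(substr(op, 1L, nchar(op) - 1L))
      }
    }
    w
  }
  vapply(seq_len(nrow(aln)), function(r) {
    a <- aln[r, ]
    if (bitwAnd(a$flag, 4L) > 0L || is.na(a$pos)) return("unmapped")
    lo <- a$pos
    hi <- a$pos + ref_width(a$cigar)   # half-open
    overlaps <- function(g) g$start < hi && lo < g$end
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$biotype == "rRNA" && identical(g$contig, a$contig) &&
          overlaps(g)) return("rrna")
    }
    if (a$nh > 1L || a$mapq == 0L) return("multimapper")
    if (grepl("[ID]", a$cigar)) return("indel")
    n_any <- 0L
    cand <- character(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (!identical(g$contig, a$contig) || !overlaps(g)) next
      n_any <- n_any + 1L
      fits <- if (expect_policy == "full_overlap") {
        lo >= g$start && hi <= g$end
      } else TRUE
      if (g$strand != a$strand && fits) cand <- c(cand, g$gene_id)
    }
    if (n_any == 0L) return("unassigned")
    if (length(cand) == 0L) {
      any_anti <- FALSE
      for (i in seq_len(nrow(genes))) {
        g <- genes[i, ]
        if (identical(g$contig, a$contig) && overlaps(g) &&
            g$strand != a$strand) any_anti <- TRUE
      }
      return(if (any_anti) "unassigned" else "wrong_strand")
    }
    if (length(cand) == 1L) return("kept")
    "ambiguous"
  }, character(1))
}

# Exact upper-tail binomial probability by direct summation with choose().
naive_binom_upper <- function(n_alt, n, p) {
  if (n_alt <= 0L) return(1)
  sum(vapply(n_alt:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k), 0))
}

# Mirror a dataset: reverse-complement genome, flip annotation and
# alignments. Editing summaries must be invariant under this transform.
revcomp_dataset <- function(reference, alignments) {
  lens <- setNames(Biostrings::width(reference$genome),
                   names(reference$genome))
  genome2 <- Biostrings::reverseComplement(reference$genome)
  names(genome2) <- names(reference$genome)
  genes2 <- reference$genes
  L <- lens[genes2$contig]
  new_start <- as.integer(L - genes2$end)
  genes2$end <- as.integer(L - genes2$start)
  genes2$start <- new_start
  genes2$strand <- ifelse(genes2$strand == "+", "-", "+")
  ref2 <- reference
  ref2$genome <- genome2
  ref2$genes <- genes2

  rev_cigar <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
    paste(rev(ops), collapse = "")
  }
  ref_width <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
    sum(vapply(ops, function(op) {
      typ <- substr(op, nchar(op), nchar(op))
      if (typ %in% c("M", "D", "N", "=", "X"))
        as.integer(substr(op, 1L, nchar(op) - 1L)) else 0L
    }, 0L))
  }
  aln2 <- alignments
  w <- vapply(aln2$cigar, ref_width, 0L, USE.NAMES = FALSE)
  aln2$pos <- as.integer(lens[aln2$contig] - (aln2$pos + w))
  aln2$flag <- bitwXor(aln2$flag, 16L)
  aln2$strand <- ifelse(aln2$strand == "+", "-", "+")
  aln2$seq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(aln2$seq)))
  aln2$qual <- vapply(aln2$qual, function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, "", USE.NAMES = FALSE)
  aln2$cigar <- vapply(aln2$cigar, rev_cigar, "", USE.NAMES = FALSE)
  list(reference = ref2, alignments = aln2)
}
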