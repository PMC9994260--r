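#' Filtering parameters for the read-exclusion rules
#'
#' Defaults reproduce the published exclusion set: discard reads overlapping
#' rRNA genes (either strand), reads mapping equally well to multiple
#' positions, reads whose CIGAR contains an insertion or deletion, and reads
#' that are not antisense to an annotated gene (dUTP first-strand protocol:
#' the sequenced strand is the cDNA, so informative reads align opposite to
#' the gene). Soft-clipped reads are not discarded; soft-clipped bases simply
#' never enter the pileup.
#'
#' @param drop_rrna Discard reads overlapping annotated rRNA genes.
#' @param drop_multimappers Discard multi-mapping reads.
#' @param multimapper_hit_count_above Reads with hit-count tag (`NH`) above
#'   this are multi-mappers.
#' @param multimapper_mapq_below Reads with MAPQ strictly below this are
#'   multi-mappers (default 1, i.e. MAPQ 0). Both criteria apply (OR), which
#'   covers the common aligner dialects.
#' @param drop_indels Discard reads with `I`/`D` CIGAR operations.
#' @param strand_rule Only `"antisense_only"` is defined: a kept read must be
#'   antisense to its assigned gene.
#' @param min_base_quality Minimum base quality for pileup inclusion (applied
#'   by [build_pileup()], carried here so one object configures the run).
#' @param assigned_gene_policy `"any_overlap"` (default; a read partially
#'   overhanging a gene end still counts) or `"full_overlap"` (read fully
#'   contained in the gene).
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(drop_rrna = TRUE,
                          drop_multimappers = TRUE,
                          multimapper_hit_count_above = 1L,
                          multimapper_mapq_below = 1L,
                          drop_indels = TRUE,
                          strand_rule = c("antisense_only"),
                          min_base_quality = 20L,
                          assigned_gene_policy = c("any_overlap", "full_overlap")) {
  strand_rule <- match.arg(strand_rule)
  assigned_gene_policy <- match.arg(assigned_gene_policy)
  if (min_base_quality < 0L) abort("min_base_quality must be >= 0")
  structure(list(drop_rrna = drop_rrna,
                 drop_multimappers = drop_multimappers,
                 multimapper_hit_count_above = multimapper_hit_count_above,
                 multimapper_mapq_below = multimapper_mapq_below,
                 drop_indels = drop_indels,
                 strand_rule = strand_rule,
                 min_base_quality = min_base_quality,
                 assigned_gene_policy = assigned_gene_policy),
            class = "filter_params")
}

FILTER_CATEGORIES <- c("unmapped", "rrna", "multimapper", "indel",
                       "wrong_strand", "unassigned", "ambiguous", "kept")

resolve_genes <- function(genes) {
  if (inherits(genes, "edit_reference")) return(genes$genes)
  if (is.character(genes) && length(genes) == 1L) return(read_annotation(genes))
  gene_models(genes)
}

#' Classify each aligned read by the first failing exclusion rule
#'
#' Rules apply in a fixed, documented order — unmapped, rRNA overlap,
#' multi-mapper, indel, then strand/gene assignment — so each read lands in
#' exactly one audit category. The order only affects the tally, never which
#' reads survive. A read antisense to two or more genes (possible when it
#' spans an intergenic gap) is `ambiguous` and not kept.
#'
#' @param alignments Alignments tibble from [read_alignments()] (or an
#'   `edit_sim`'s `$alignments`).
#' @param genes Gene model table, `edit_reference`, or annotation path.
#' @param params A [filter_params()] object.
#' @return The alignments tibble with `category` and assigned `gene_id`
#'   (`NA` unless kept) columns added.
#' @export
classify_reads <- function(alignments, genes, params = filter_params()) {
  aln <- read_alignments(alignments)
  genes <- resolve_genes(genes)
  n <- nrow(aln)
  category <- rep(NA_character_, n)
  gene_id <- rep(NA_character_, n)
  if (n == 0L) {
    return(mutate(aln, category = character(0), gene_id = character(0)))
  }

  unmapped <- bitwAnd(aln$flag, 4L) > 0L | is.na(aln$pos) | is.na(aln$contig) |
    aln$cigar == "*" | is.na(aln$cigar)
  category[unmapped] <- "unmapped"

  mapped <- which(!unmapped)
  if (length(mapped) > 0L) {
    rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar[mapped])
    read_gr <- GenomicRanges::GRanges(
      seqnames = aln$contig[mapped],
      ranges = IRanges::IRanges(start = aln$pos[mapped] + 1L,
                                width = rw))

    if (params$drop_rrna && any(genes$biotype == "rRNA")) {
      rg <- genes[genes$biotype == "rRNA", ]
      hit <- IRanges::overlapsAny(read_gr, gr_from_genes(rg),
                                  ignore.strand = TRUE)
      idx <- mapped[hit & is.na(category[mapped])]
      category[idx] <- "rrna"
    }

    if (params$drop_multimappers) {
      multi <- aln$nh[mapped] > params$multimapper_hit_count_above |
        aln$mapq[mapped] < params$multimapper_mapq_below
      idx <- mapped[multi & is.na(category[mapped])]
      category[idx] <- "multimapper"
    }

    if (params$drop_indels) {
      indel <- grepl("[ID]", aln$cigar[mapped])
      idx <- mapped[indel & is.na(category[mapped])]
      category[idx] <- "indel"
    }

    rest <- which(is.na(category))
    if (length(rest) > 0L && nrow(genes) > 0L) {
      sub <- match(rest, mapped)        # rows of read_gr
      gene_gr <- gr_from_genes(genes)
      ov_any <- GenomicRanges::findOverlaps(read_gr[sub], gene_gr,
                                            ignore.strand = TRUE)
      ov_with <- if (params$assigned_gene_policy == "full_overlap") {
        GenomicRanges::findOverlaps(read_gr[sub], gene_gr, type = "within",
                                    ignore.strand = TRUE)
      } else ov_any

      anti <- function(ov) {
        q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
        keep <- genes$strand[s] != aln$strand[rest[q]]
        list(q = q[keep], s = s[keep])
      }
      n_any <- tabulate(S4Vectors::queryHits(ov_any), nbins = length(sub))
      aa <- anti(ov_any)
      n_anti_any <- tabulate(aa$q, nbins = length(sub))
      aw <- anti(ov_with)
      n_cand <- tabulate(aw$q, nbins = length(sub))

      category[rest[n_any == 0L]] <- "unassigned"
      category[rest[n_any > 0L & n_anti_any == 0L]] <- "wrong_strand"
      category[rest[n_anti_any > 0L & n_cand == 0L]] <- "unassigned"
      category[rest[n_cand == 1L]] <- "kept"
      category[rest[n_cand > 1L]] <- "ambiguous"

      one <- aw$q %in% which(n_cand == 1L)
      gene_id[rest[aw$q[one]]] <- genes$gene_id[aw$s[one]]
    } else if (length(rest) > 0L) {
      category[rest] <- "unassigned"
    }
  }

  aln$category <- category
  aln$gene_id <- gene_id
  aln
}

#' Apply the read-exclusion rules and tally the audit
#'
#' @inheritParams classify_reads
#' @param alignments Alignments tibble, `edit_sim`, or SAM/BAM path.
#' @return An object of class `edit_filter`: list with `kept` (the surviving
#'   alignments, gene-assigned) and `stats` (tibble of per-category counts;
#'   the categories partition the input exactly).
#' @examples
#' layout <- design_genome(n_mrna = 4, n_phage = 0, seed = 1)
#' ref <- generate_reference(layout$genes, layout$contigs, seed = 1)
#' sim <- simulate_reads(ref, mean_depth = 10, seed = 1)
#' flt <- filter_alignments(sim, ref)
#' flt$stats
#' @export
filter_alignments <- function(alignments, genes, params = filter_params()) {
  if (inherits(alignments, "edit_sim")) {
    if (missing(genes)) genes <- alignments$reference
    alignments <- alignments$alignments
  }
  cls <- classify_reads(alignments, genes, params)
  counts <- table(factor(cls$category, levels = FILTER_CATEGORIES))
  stats <- bind_rows(
    tibble(category = "input", n = nrow(cls)),
    tibble(category = FILTER_CATEGORIES, n = as.integer(counts))
  )
  structure(list(
    kept = filter(cls, .data$category == "kept"),
    stats = stats,
    params = params
  ), class = "edit_filter")
}

#' @export
print.edit_filter <- function(x, ...) {
  cat("<edit_filter>\n")
  w <- x$stats
  total <- w$n[w$category == "input"]
  for (i in seq_len(nrow(w))) {
    cat(sprintf("  %-12s %8d%s\n", w$category[i], w$n[i],
                if (w$category[i] == "input") "" else
                  sprintf("  (%.1f%%)", 100 * w$n[i] / max(total, 1L))))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.edit_filter <- function(x, ...) x$stats

#' @exportS3Method generics::glance
glance.edit_filter <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$stats, names_from = "category", values_from = "n")
  mutate(wide, fraction_kept = .data$kept / pmax(.data$input, 1L))
}
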