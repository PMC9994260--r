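MISMATCH_CLASSES <- local({
  x <- expand.grid(ref_base = BASES, alt_base = BASES,
                   stringsAsFactors = FALSE)
  x <- x[x$ref_base != x$alt_base, ]
  x$class <- paste0(x$ref_base, ">", x$alt_base)
  tibble::as_tibble(x[order(x$ref_base, x$alt_base), ])
})

#' Transcriptome-wide mismatch-class rates
#'
#' Aggregates per-site transcript-space counts into the twelve substitution
#' classes X>Y over all expressed positions of non-rRNA genes. The headline
#' quantity is the A>G class: the rate of mismatches at all expressed
#' adenosine positions, the transcriptome-wide readout of A-to-I editing.
#' The coverage-weighted rate `sum(n_alt) / sum(n_ref + n_alt)` is the
#' primary statistic; an unweighted per-position mean is reported alongside.
#'
#' @param sites Tibble from [site_stats()].
#' @param expressed_threshold Minimum coverage for a position to count as
#'   expressed (default 10 kept reads).
#' @return Tibble with one row per class: `ref_base`, `alt_base`, `class`,
#'   `n_positions`, `n_alt`, `n_total`, `rate`, `rate_mean`.
#' @export
transcriptome_rates <- function(sites, expressed_threshold = 10L) {
  sites <- as_tibble(sites)
  q <- filter(sites, .data$biotype != "rRNA",
              .data$coverage >= expressed_threshold,
              .data$transcript_base %in% BASES)
  if (nrow(q) == 0L) {
    warn("no positions pass the expressed threshold; rates are undefined")
    return(mutate(MISMATCH_CLASSES, n_positions = 0L, n_alt = NA_integer_,
                  n_total = NA_integer_, rate = NA_real_,
                  rate_mean = NA_real_))
  }
  cnt <- function(df, base) df[[paste0("tx_", base)]]
  purrr::pmap_dfr(MISMATCH_CLASSES, function(ref_base, alt_base, class) {
    d <- q[q$transcript_base == ref_base, ]
    n_alt <- cnt(d, alt_base)
    n_pair <- cnt(d, ref_base) + n_alt
    ok <- n_pair > 0L
    tot_alt <- sum(n_alt)
    tot_pair <- sum(n_pair)
    rmean <- if (any(ok)) mean(n_alt[ok] / n_pair[ok]) else NA_real_
    tibble(ref_base = ref_base, alt_base = alt_base, class = class,
           n_positions = nrow(d),
           n_alt = tot_alt,
           n_total = tot_pair,
           rate = if (tot_pair > 0L) tot_alt / tot_pair else NA_real_,
           rate_mean = rmean)
  })
}

#' Estimate the background mismatch rate from the non-editing classes
#'
#' Median of the eleven non-A>G class rates; under a uniform sequencing-error
#' model each class has background `error_rate / 3`, so this self-calibrates
#' without knowing the error rate.
#'
#' @param rates Tibble from [transcriptome_rates()].
#' @return A single background rate.
#' @export
background_rate <- function(rates) {
  r <- rates$rate[rates$class != "A>G"]
  r <- r[!is.na(r)]
  if (length(r) == 0L) {
    warn("no non-A>G classes with data; background set to 0")
    return(0)
  }
  median(r)
}

#' Call edited sites with an exact binomial test
#'
#' At each expressed transcript adenosine, tests whether the alternate (G)
#' call count exceeds the background mismatch rate: upper-tail exact binomial
#' p for `n_alt` successes in `n_ref + n_alt` trials, Benjamini-Hochberg
#' adjusted across all tested sites. A site is called edited when its
#' adjusted q is at most `q_threshold` and its editing fraction exceeds the
#' background. The published analysis reports raw frequencies without a
#' formal test; this calling rule is this package's own operational
#' definition of "edited", needed to state "fraction of adenosines left
#' unedited" reproducibly.
#'
#' @param sites Tibble from [site_stats()].
#' @param background Background per-class mismatch rate; default estimated
#'   with [background_rate()] from the same data.
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @param expressed_threshold Minimum coverage to test a site.
#' @return The tested sites with `background`, `p_value`, `q_value`,
#'   `called_edited` columns added.
#' @export
call_sites <- function(sites, background = NULL, q_threshold = 0.05,
                       expressed_threshold = 10L) {
  sites <- as_tibble(sites)
  if (is.null(background)) {
    background <- background_rate(transcriptome_rates(sites,
                                                      expressed_threshold))
  }
  tested <- filter(sites, .data$transcript_base == "A",
                   .data$biotype != "rRNA",
                   .data$coverage >= expressed_threshold,
                   (.data$tx_A + .data$tx_G) > 0L)
  if (nrow(tested) == 0L) {
    return(mutate(tested, background = double(0), p_value = double(0),
                  q_value = double(0), called_edited = logical(0)))
  }
  n <- tested$tx_A + tested$tx_G
  p <- pbinom(tested$tx_G - 1L, n, background, lower.tail = FALSE)
  tested %>%
    mutate(background = background,
           p_value = p,
           q_value = p.adjust(p, method = "BH"),
           called_edited = .data$q_value <= q_threshold &
             .data$editing_fraction > background)
}

#' Compare editing between control and treatment samples
#'
#' Joins per-site editing fractions from a control and a treatment sample
#' (optionally across timepoints, via a `timepoint` column in each input),
#' computes per-site deltas, per-class rate deltas, and the headline summary:
#' the fraction of expressed adenosine positions in the treatment sample
#' *not* called edited.
#'
#' @param control,treatment [site_stats()] tibbles, each optionally with a
#'   `timepoint` column (minutes; 0 = uninfected).
#' @param background Background rate override for [call_sites()].
#' @param q_threshold,expressed_threshold Passed to [call_sites()].
#' @return An object of class `edit_comparison`: list with `sites` (per-site
#'   `f_control`, `f_treatment`, `delta_f`, `direction`, `called_edited`),
#'   `class_rates` (per-class control/treatment rates and delta), and
#'   `summary` (per timepoint: expressed adenosines, called count, fraction
#'   unedited).
#' @export
compare_conditions <- function(control, treatment, background = NULL,
                               q_threshold = 0.05, expressed_threshold = 10L) {
  control <- as_tibble(control)
  treatment <- as_tibble(treatment)
  if (!"timepoint" %in% names(control)) control$timepoint <- 0
  if (!"timepoint" %in% names(treatment)) treatment$timepoint <- 0
  if (length(intersect(unique(control$contig),
                       unique(treatment$contig))) == 0L) {
    abort("control and treatment share no contigs; mismatched references?")
  }
  chk <- inner_join(
    select(control, "contig", "pos", "gene_id", cb = "transcript_base"),
    select(treatment, "contig", "pos", "gene_id", tb = "transcript_base"),
    by = c("contig", "pos", "gene_id"),
    relationship = "many-to-many")
  if (any(chk$cb != chk$tb)) {
    abort("transcript base disagrees between control and treatment; mismatched references")
  }

  tps <- sort(unique(treatment$timepoint))
  per_tp <- lapply(tps, function(tp) {
    tr <- filter(treatment, .data$timepoint == tp)
    # match the control timepoint when available, else pool the control
    ct <- if (tp %in% control$timepoint) {
      filter(control, .data$timepoint == tp)
    } else control
    calls <- call_sites(tr, background = background,
                        q_threshold = q_threshold,
                        expressed_threshold = expressed_threshold)
    a_tr <- filter(tr, .data$transcript_base == "A", .data$biotype != "rRNA",
                   .data$coverage >= expressed_threshold)
    joined <- a_tr %>%
      select("gene_id", "contig", "pos", "strand",
             f_treatment = "editing_fraction",
             coverage_treatment = "coverage") %>%
      left_join(select(ct, "gene_id", "contig", "pos",
                       f_control = "editing_fraction",
                       coverage_control = "coverage"),
                by = c("gene_id", "contig", "pos")) %>%
      left_join(select(calls, "gene_id", "contig", "pos", "q_value",
                       "called_edited"),
                by = c("gene_id", "contig", "pos")) %>%
      mutate(timepoint = tp,
             delta_f = .data$f_treatment - .data$f_control,
             direction = dplyr::case_when(
               is.na(.data$delta_f) ~ NA_character_,
               .data$delta_f > 0 ~ "up",
               .data$delta_f < 0 ~ "down",
               TRUE ~ "none"))
    rates_c <- transcriptome_rates(ct, expressed_threshold)
    rates_t <- transcriptome_rates(tr, expressed_threshold)
    cls <- inner_join(select(rates_c, "class", rate_control = "rate"),
                      select(rates_t, "class", rate_treatment = "rate"),
                      by = "class") %>%
      mutate(timepoint = tp,
             delta_rate = .data$rate_treatment - .data$rate_control)
    n_expressed <- nrow(a_tr)
    n_called <- sum(joined$called_edited, na.rm = TRUE)
    list(sites = joined, class_rates = cls,
         summary = tibble(timepoint = tp,
                          n_expressed_adenosines = n_expressed,
                          n_called_edited = n_called,
                          fraction_unedited =
                            if (n_expressed > 0L)
                              1 - n_called / n_expressed else NA_real_))
  })
  structure(list(
    sites = bind_rows(lapply(per_tp, `[[`, "sites")),
    class_rates = bind_rows(lapply(per_tp, `[[`, "class_rates")),
    summary = bind_rows(lapply(per_tp, `[[`, "summary")),
    q_threshold = q_threshold,
    expressed_threshold = expressed_threshold
  ), class = "edit_comparison")
}

#' @export
print.edit_comparison <- function(x, ...) {
  cat("<edit_comparison>\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.edit_comparison <- function(x, ...) x$sites

#' @exportS3Method generics::glance
glance.edit_comparison <- function(x, ...) x$summary

#' Report editing at a user-supplied list of target loci
#'
#' For each locus the editing fraction comes from the strand-appropriate
#' base pair: (ref A, alt G) for `+` strand loci, (ref T, alt C) for `-`.
#' Loci under the expressed threshold are flagged `low_coverage` rather than
#' omitted; loci outside the genome are flagged `invalid_locus` without
#' aborting the rest of the report.
#'
#' @param pileup A [build_pileup()] tibble, optionally carrying `sample`
#'   and/or `timepoint` columns, or a named list of pileups (names become
#'   the `sample` column).
#' @param loci Loci tibble (`contig`, `pos` 1-based, `strand`, `label`) or a
#'   TSV path for [read_loci()].
#' @param expressed_threshold Coverage below this flags `low_coverage`.
#' @param genome Optional genome (for bounds checking of loci).
#' @return Tibble with one row per locus per sample/timepoint: counts,
#'   coverage, `f`, and `status`.
#' @export
targeted_report <- function(pileup, loci, expressed_threshold = 10L,
                            genome = NULL) {
  if (is.list(pileup) && !is.data.frame(pileup)) {
    pileup <- bind_rows(pileup, .id = "sample")
  }
  pileup <- as_tibble(pileup)
  if (is.character(loci) && length(loci) == 1L) loci <- read_loci(loci)
  loci <- as_tibble(loci)
  assert_cols(loci, c("contig", "pos", "strand", "label"), "loci list")
  if (!"pos0" %in% names(loci)) loci$pos0 <- as.integer(loci$pos) - 1L
  if (!all(loci$strand %in% c("+", "-"))) abort("loci strand must be '+' or '-'")

  grp_cols <- intersect(c("sample", "timepoint"), names(pileup))
  groups <- if (length(grp_cols) > 0L) distinct(pileup[grp_cols]) else tibble(.dummy = 1L)
  grid <- tidyr::crossing(loci, groups)
  if (".dummy" %in% names(grid)) grid$.dummy <- NULL

  joined <- left_join(grid, pileup,
                      by = c("contig", pos0 = "pos", grp_cols))

  invalid <- rep(FALSE, nrow(joined))
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    lens <- setNames(Biostrings::width(genome), names(genome))
    invalid <- !(joined$contig %in% names(lens)) |
      joined$pos0 < 0L | joined$pos0 >= lens[joined$contig]
    invalid[is.na(invalid)] <- TRUE
  }

  plus <- joined$strand == "+"
  zero <- function(x) if_else(is.na(x), 0L, x)
  n_ref <- if_else(plus, zero(joined$A), zero(joined$T))
  n_alt <- if_else(plus, zero(joined$G), zero(joined$C))
  coverage <- zero(joined$coverage)
  status <- dplyr::case_when(
    invalid ~ "invalid_locus",
    coverage < expressed_threshold ~ "low_coverage",
    TRUE ~ "ok")
  f <- if_else(status == "ok" & (n_ref + n_alt) > 0L,
               n_alt / (n_ref + n_alt), NA_real_)
  out <- tibble(label = joined$label, contig = joined$contig,
                pos = joined$pos0 + 1L, strand = joined$strand)
  for (gc in grp_cols) out[[gc]] <- joined[[gc]]
  out$n_ref <- n_ref
  out$n_alt <- n_alt
  out$coverage <- coverage
  out$f <- f
  out$status <- status
  arrange(out, .data$label)
}
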