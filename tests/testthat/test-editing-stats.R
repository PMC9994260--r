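# Synthetic site-stat rows for arithmetic checks, plus simulation-backed
# statistical properties of the calling and comparison layers.

mk_sites <- function(n_alt, n_pair, base = "A", biotype = "mRNA",
                     coverage = NULL) {
  n <- length(n_alt)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)), contig = "chr",
    pos = seq_len(n) * 10L, strand = "+", biotype = biotype,
    transcript_offset = seq_len(n), transcript_base = base,
    tx_A = if (base == "A") n_pair - n_alt else 0L,
    tx_C = 0L,
    tx_G = if (base == "A") n_alt else 0L,
    tx_T = 0L, tx_N = 0L,
    coverage = coverage %||% n_pair,
    n_ref = n_pair - n_alt, n_alt = n_alt,
    editing_fraction = n_alt / n_pair)
}

test_that("class rates aggregate by coverage weighting, with rRNA excluded", {
  ss <- mk_sites(n_alt = c(1L, 3L), n_pair = c(10L, 30L))
  rates <- transcriptome_rates(ss, expressed_threshold = 10L)
  expect_equal(rates$rate[rates$class == "A>G"], 4 / 40)
  expect_equal(rates$rate_mean[rates$class == "A>G"], mean(c(0.1, 0.1)))
  expect_equal(rates$n_positions[rates$class == "A>G"], 2L)

  # rRNA positions never enter, even if present in the site table
  with_rrna <- dplyr::bind_rows(
    ss, dplyr::mutate(mk_sites(50L, 100L), gene_id = "rrnX",
                      biotype = "rRNA"))
  rates2 <- transcriptome_rates(with_rrna, expressed_threshold = 10L)
  expect_equal(rates2$rate[rates2$class == "A>G"], 4 / 40)

  # positions under the expressed threshold are excluded
  rates3 <- transcriptome_rates(ss, expressed_threshold = 20L)
  expect_equal(rates3$rate[rates3$class == "A>G"], 3 / 30)

  expect_warning(transcriptome_rates(ss, expressed_threshold = 1000L),
                 "no positions")
})

test_that("the transcriptome A>G rate is the coverage-weighted mean of site fractions", {
  ref <- flat_ref(n_genes = 4, seed = 91)
  sim <- simulate_reads(ref, NULL, mean_depth = 30, error_rate = 0.01,
                        seed = 92)
  ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
  rates <- transcriptome_rates(ss, expressed_threshold = 10L)
  q <- dplyr::filter(ss, biotype != "rRNA", coverage >= 10L,
                     transcript_base == "A", (tx_A + tx_G) > 0L)
  w <- q$tx_A + q$tx_G
  expect_equal(rates$rate[rates$class == "A>G"],
               sum(w * q$editing_fraction) / sum(w))
})

test_that("null A>G rate matches the uniform error model closed form e/3", {
  ref <- flat_ref(n_genes = 6, seed = 101)
  e <- 0.003
  sim <- simulate_reads(ref, NULL, mean_depth = 40, error_rate = e, seed = 102)
  ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
  rates <- transcriptome_rates(ss, expressed_threshold = 10L)
  ag <- rates[rates$class == "A>G", ]
  se <- sqrt((e / 3) * (1 - e / 3) / ag$n_total)
  expect_lt(abs(ag$rate - e / 3), 3 * se)
})

test_that("binomial tail p-values equal direct summation; calling behaves at the edges", {
  # zero alternate calls: p = 1, never called
  ss0 <- mk_sites(0L, 100L)
  calls0 <- call_sites(ss0, background = 0.001, expressed_threshold = 10L)
  expect_true(all(calls0$p_value == 1))
  expect_false(any(calls0$called_edited))

  # exact tail against an independent choose()-based summation
  cases <- list(c(10L, 100L, 0.001), c(3L, 50L, 0.01), c(1L, 20L, 0.05),
                c(80L, 200L, 0.3))
  for (cs in cases) {
    ss <- mk_sites(cs[1], cs[2])
    got <- call_sites(ss, background = cs[3], expressed_threshold = 1L)
    expect_equal(got$p_value, naive_binom_upper(cs[1], cs[2], cs[3]),
                 tolerance = 1e-12)
  }
  # the spec-style strong case is called
  ss <- mk_sites(10L, 100L)
  got <- call_sites(ss, background = 0.001, expressed_threshold = 10L)
  expect_true(got$called_edited)

  # coverage below the expressed threshold is skipped entirely
  low <- mk_sites(5L, 8L)
  expect_equal(nrow(call_sites(low, background = 0.001,
                               expressed_threshold = 10L)), 0L)
})

test_that("background self-calibrates to the median non-A>G class rate", {
  ref <- flat_ref(n_genes = 5, seed = 111)
  e <- 0.006
  sim <- simulate_reads(ref, NULL, mean_depth = 40, error_rate = e, seed = 112)
  ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
  bg <- background_rate(transcriptome_rates(ss, 10L))
  expect_lt(abs(bg - e / 3), e / 3)   # right order, self-estimated
})

test_that("false-discovery rate holds on fully-null simulations", {
  ref <- flat_ref(n_genes = 3, seed = 121)
  tested <- 0L
  called <- 0L
  for (seed in 1:20) {
    sim <- simulate_reads(ref, NULL, mean_depth = 25, error_rate = 0.002,
                          seed = 200 + seed)
    ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
    calls <- call_sites(ss, q_threshold = 0.05, expressed_threshold = 10L)
    tested <- tested + nrow(calls)
    called <- called + sum(calls$called_edited)
  }
  expect_gt(tested, 1000L)
  # Monte-Carlo slack: 3 binomial SEs above the nominal level
  expect_lte(called / tested, 0.05 + 3 * sqrt(0.05 * 0.95 / tested))
})

test_that("median editing-fraction estimate is monotone in the injected rate", {
  ref <- flat_ref(n_genes = 2, seed = 131)
  offset <- adenosine_offsets(ref, "g01")[8]
  med <- vapply(c(0.02, 0.1, 0.4), function(rate) {
    f <- vapply(1:5, function(s) {
      site <- tibble::tibble(gene_id = "g01", offset = offset,
                             true_rate = rate, label = "m")
      sim <- simulate_reads(ref, site, mean_depth = 120, error_rate = 0,
                            seed = 300 + s)
      ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
      tr <- sim$truth
      ss$editing_fraction[ss$gene_id == "g01" & ss$pos == tr$genomic_pos]
    }, 0)
    median(f)
  }, 0)
  expect_true(all(diff(med) >= 0))
})

test_that("per-site estimates recover the injected rates within binomial error", {
  ref <- flat_ref(n_genes = 6, gene_len = 400L, seed = 141)
  mrna <- ref$genes$gene_id[ref$genes$biotype == "mRNA"]
  sites <- dplyr::bind_rows(lapply(mrna, function(g) {
    offs <- adenosine_offsets(ref, g)
    tibble::tibble(gene_id = g, offset = offs[seq(5, length(offs) - 5, by = 12)],
                   true_rate = rep(c(0.05, 0.2, 0.5),
                                   length.out = length(seq(5, length(offs) - 5,
                                                           by = 12))),
                   label = "recovery")
  }))
  inside <- 0L
  total <- 0L
  for (s in 1:4) {
    sim <- simulate_reads(ref, sites, mean_depth = 150, error_rate = 0,
                          seed = 400 + s)
    ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
    j <- dplyr::inner_join(
      sim$truth, ss[, c("gene_id", "pos", "tx_A", "tx_G")],
      by = c(gene_id = "gene_id", genomic_pos = "pos"))
    n <- j$tx_A + j$tx_G
    lo <- qbinom(0.005, n, j$true_rate)
    hi <- qbinom(0.995, n, j$true_rate)
    ok <- j$tx_G >= lo & j$tx_G <= hi
    inside <- inside + sum(ok)
    total <- total + length(ok)
  }
  expect_gt(total, 150L)
  expect_gte(inside / total, 0.99)
})

test_that("condition comparison: identical inputs give zero deltas everywhere", {
  ref <- flat_ref(n_genes = 3, seed = 151)
  sim <- simulate_reads(ref, NULL, mean_depth = 25, error_rate = 0.002,
                        seed = 152)
  ss <- site_stats(build_pileup(filter_alignments(sim, ref), ref), ref)
  cmp <- compare_conditions(ss, ss)
  expect_true(all(cmp$sites$delta_f[!is.na(cmp$sites$delta_f)] == 0))
  expect_true(all(cmp$class_rates$delta_rate == 0))
  expect_s3_class(generics::tidy(cmp), "tbl_df")
  expect_identical(generics::glance(cmp), cmp$summary)
})

test_that("a treatment-only editing site tops the per-site delta ranking", {
  ref <- flat_ref(n_genes = 4, seed = 161)
  site <- tibble::tibble(gene_id = "g02",
                         offset = adenosine_offsets(ref, "g02")[6],
                         true_rate = 0.04, label = "weak")
  ctl <- simulate_reads(ref, NULL, mean_depth = 400, error_rate = 0.001,
                        seed = 162)
  trt <- simulate_reads(ref, site, mean_depth = 400, error_rate = 0.001,
                        seed = 163)
  ss_c <- site_stats(build_pileup(filter_alignments(ctl, ref), ref), ref)
  ss_t <- site_stats(build_pileup(filter_alignments(trt, ref), ref), ref)
  cmp <- compare_conditions(ss_c, ss_t)
  top <- cmp$sites[which.max(cmp$sites$delta_f), ]
  expect_equal(top$gene_id, "g02")
  expect_equal(top$pos, trt$truth$genomic_pos)
  # mismatched references are refused
  ss_t2 <- dplyr::mutate(ss_t, contig = "other")
  expect_error(compare_conditions(ss_c, ss_t2), "contigs")
})

test_that("targeted loci report editing fractions by strand with coverage flags", {
  ref <- flat_ref(n_genes = 4, seed = 171)
  plus_gene <- ref$genes[ref$genes$strand == "+" & ref$genes$biotype == "mRNA", ][1, ]
  minus_gene <- ref$genes[ref$genes$strand == "-" & ref$genes$biotype == "mRNA", ][1, ]
  mid <- function(g) {   # central adenosine, clear of coverage ramp-down
    offs <- adenosine_offsets(ref, g)
    offs[which.min(abs(offs - 150L))]
  }
  sites <- tibble::tibble(
    gene_id = c(plus_gene$gene_id, minus_gene$gene_id),
    offset = c(mid(plus_gene$gene_id), mid(minus_gene$gene_id)),
    true_rate = 0.04, label = "tmRNA-like")
  sim <- simulate_reads(ref, sites, mean_depth = 1100, error_rate = 0.001,
                        seed = 172)
  pl <- build_pileup(filter_alignments(sim, ref), ref)
  gpos <- sim$truth$genomic_pos
  loci <- tibble::tibble(
    contig = "chr", pos = c(gpos + 1L, 5L),
    strand = c(plus_gene$strand, minus_gene$strand, "+"),
    label = c("site_plus", "site_minus", "uncovered"))
  rep <- targeted_report(pl, loci, expressed_threshold = 10L,
                         genome = ref$genome)
  rep <- rep[order(rep$label), ]
  ok <- rep[rep$label != "uncovered", ]
  expect_true(all(ok$status == "ok"))
  expect_true(all(ok$coverage >= 1000L))
  for (i in seq_len(nrow(ok))) {
    n <- ok$n_ref[i] + ok$n_alt[i]
    lim <- qbinom(c(0.005, 0.995), n, 0.04)
    expect_gte(ok$n_alt[i], lim[1])
    expect_lte(ok$n_alt[i], lim[2])
  }
  un <- rep[rep$label == "uncovered", ]
  expect_equal(un$status, "low_coverage")
  expect_true(is.na(un$f))
  # a locus beyond the contig is reported as invalid, others still present
  bad <- tibble::tibble(contig = "chr", pos = 10^7L, strand = "+",
                        label = "outside")
  rep2 <- targeted_report(pl, dplyr::bind_rows(loci, bad),
                          genome = ref$genome)
  expect_equal(rep2$status[rep2$label == "outside"], "invalid_locus")
  expect_equal(nrow(rep2), 4L)
})
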