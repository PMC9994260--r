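# Orchestration: simulate -> filter -> pileup -> summarize -> compare -> loci,
# with deterministic TSV outputs and a run manifest. Positions are 1-based in
# every TSV written here; conversion happens only at this boundary.

write_tsv_out <- function(df, path) {
  readr::write_tsv(df, path, na = ".")
  nrow(df)
}

read_tsv_in <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("missing artifact '%s'; run the '%s' stage first",
                  path, stage))
  }
  readr::read_tsv(path, show_col_types = FALSE, na = ".")
}

#' Assemble a pipeline configuration
#'
#' @param simulate `NULL`, or a list of simulator settings: genome design
#'   arguments for [design_genome()] (`n_mrna`, `n_rrna`, `n_trna`,
#'   `n_phage`, ...), `mean_depth`, `error_rate`, `read_length`,
#'   `indel_read_fraction`, `decoy_copies`, and `edit_sites` (data frame;
#'   injected into `radar`-condition samples only — the control arm is
#'   always editing-free).
#' @param samples Sample sheet: tibble with `sample_id`, `condition`
#'   (`control`/`radar`), `timepoint` (minutes, 0 = uninfected) and, when not
#'   simulating, `alignments` (SAM/BAM path).
#' @param genome,annotation Paths to FASTA/GFF3 when running on real
#'   alignments instead of the simulator.
#' @param loci Optional loci list (TSV path or tibble) for the targeted
#'   report.
#' @param filter A [filter_params()] object.
#' @param expressed_threshold,q_threshold,background Analysis settings.
#' @param seed Integer master seed; per-sample simulator seeds are derived
#'   as `seed + sample index`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, samples = NULL,
                            genome = NULL, annotation = NULL, loci = NULL,
                            filter = filter_params(),
                            expressed_threshold = 10L, q_threshold = 0.05,
                            background = NULL, seed = 1L) {
  if (is.null(samples)) {
    samples <- tibble(sample_id = c("control_t0", "radar_t0"),
                      condition = c("control", "radar"),
                      timepoint = c(0, 0))
  }
  samples <- as_tibble(samples)
  assert_cols(samples, c("sample_id", "condition", "timepoint"), "sample sheet")
  if (!all(samples$condition %in% c("control", "radar"))) {
    abort("sample sheet condition must be 'control' or 'radar'")
  }
  if (is.null(simulate) && !"alignments" %in% names(samples)) {
    abort("sample sheet needs an 'alignments' column when not simulating")
  }
  structure(list(simulate = simulate, samples = samples, genome = genome,
                 annotation = annotation, loci = loci, filter = filter,
                 expressed_threshold = expressed_threshold,
                 q_threshold = q_threshold, background = background,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    raw <- yaml::read_yaml(config)
    fp <- do.call(filter_params, raw$filter %||% list())
    samples <- if (!is.null(raw$samples)) bind_rows(raw$samples) else NULL
    sim <- raw$simulate
    if (!is.null(sim$edit_sites)) sim$edit_sites <- bind_rows(sim$edit_sites)
    return(pipeline_config(
      simulate = sim, samples = samples, genome = raw$genome,
      annotation = raw$annotation, loci = raw$loci, filter = fp,
      expressed_threshold = raw$expressed_threshold %||% 10L,
      q_threshold = raw$q_threshold %||% 0.05,
      background = raw$background, seed = raw$seed %||% 1L))
  }
  if (is.list(config)) return(do.call(pipeline_config, config))
  abort("`config` must be a pipeline_config, a list, or a YAML path")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simulate_stage <- function(cfg, out_dir) {
  sim <- cfg$simulate
  design_args <- sim[intersect(names(sim),
                               names(formals(design_genome)))]
  design_args$seed <- design_args$seed %||% cfg$seed
  layout <- do.call(design_genome, design_args)
  ref <- generate_reference(layout$genes, layout$contigs,
                            seed = design_args$seed)
  decoy_copies <- sim$decoy_copies %||% 0L
  if (decoy_copies > 0L) {
    src <- sim$decoy_gene %||% ref$genes$gene_id[ref$genes$biotype == "mRNA"][1L]
    ref <- plant_decoy(ref, src, decoy_copies)
  }
  write_fasta(ref, file.path(out_dir, "reference.fasta"))
  write_gff3(ref, file.path(out_dir, "annotation.gff3"))

  # edit sites may name the k-th adenosine of a transcript (`offset_index`)
  # instead of a literal offset, since the genome is drawn at run time
  sites_cfg <- sim$edit_sites
  if (!is.null(sites_cfg) && !"offset" %in% names(sites_cfg) &&
      "offset_index" %in% names(sites_cfg)) {
    sites_cfg$offset <- vapply(seq_len(nrow(sites_cfg)), function(i) {
      offs <- adenosine_offsets(ref, sites_cfg$gene_id[i])
      offs[min(sites_cfg$offset_index[i], length(offs))]
    }, integer(1))
    sites_cfg$offset_index <- NULL
  }

  sims <- list()
  for (i in seq_len(nrow(cfg$samples))) {
    s <- cfg$samples[i, ]
    sites <- if (identical(s$condition, "radar")) sites_cfg else NULL
    this <- simulate_reads(
      ref, sites,
      read_length = sim$read_length %||% 50L,
      mean_depth = sim$mean_depth %||% 50,
      error_rate = sim$error_rate %||% 0.001,
      seed = cfg$seed + i,
      indel_read_fraction = sim$indel_read_fraction %||% 0,
      reads_per_molecule = sim$reads_per_molecule %||% 1L)
    write_fastq(this, file.path(out_dir, paste0(s$sample_id, ".fastq")))
    write_sam(this, file.path(out_dir, paste0(s$sample_id, ".truth.sam")))
    truth_out <- mutate(this$truth, genomic_pos = .data$genomic_pos + 1L)
    write_tsv_out(truth_out,
                  file.path(out_dir, paste0(s$sample_id, ".truth_table.tsv")))
    sims[[s$sample_id]] <- this
  }
  list(reference = ref, sims = sims)
}

#' Run the editing-quantification pipeline
#'
#' Stages: `simulate` (when the config carries simulator settings),
#' `filter`, `pileup`, `summarize` (site stats, class rates, site calls),
#' `compare` (control vs radar across timepoints), `loci` (targeted report,
#' when a loci list is configured), or `all`. Each stage writes TSV
#' artifacts into `out_dir` (1-based positions, `.` for missing values) and
#' the run ends with a `manifest.json` recording the config hash, seed and
#' per-stage row counts. Re-running with an identical config reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()], a plain list of its arguments, or a
#'   YAML path.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a list with the in-memory results (`filters`,
#'   `pileups`, `site_stats`, `rates`, `calls`, `comparison`, `loci_report`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "filter", "pileup", "summarize", "compare", "loci")
  if (identical(stages, "all")) {
    stages <- all_stages
    if (is.null(cfg$simulate)) stages <- setdiff(stages, "simulate")
    if (is.null(cfg$loci)) stages <- setdiff(stages, "loci")
  }
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) abort(sprintf("unknown stage(s): %s",
                                      paste(bad, collapse = ", ")))
  needs <- list(pileup = "filter", summarize = c("filter", "pileup"),
                compare = c("filter", "pileup", "summarize"),
                loci = c("filter", "pileup"))
  for (st in intersect(stages, names(needs))) {
    missing_dep <- setdiff(needs[[st]], stages)
    if (length(missing_dep) > 0L) {
      abort(sprintf("stage '%s' is missing upstream artifact(s); include stage(s) %s in the same run",
                    st, paste(sprintf("'%s'", missing_dep), collapse = ", ")))
    }
  }
  manifest <- list(config_hash = rlang::hash(unclass(cfg)), seed = cfg$seed,
                   stages = list())
  res <- list()

  sims <- NULL
  reference <- NULL
  if ("simulate" %in% stages) {
    if (is.null(cfg$simulate)) abort("config has no simulator settings")
    st <- simulate_stage(cfg, out_dir)
    sims <- st$sims
    reference <- st$reference
    manifest$stages$simulate <- list(
      n_samples = length(sims),
      n_reads = vapply(sims, function(s) nrow(s$reads), 0L))
  }

  genes <- if (!is.null(reference)) reference$genes
           else if (!is.null(cfg$annotation)) read_annotation(cfg$annotation)
           else abort("no annotation available; configure `annotation` or simulate")
  genome <- if (!is.null(reference)) reference$genome
            else if (!is.null(cfg$genome)) {
              g <- Biostrings::readDNAStringSet(cfg$genome)
              names(g) <- sub("\\s.*$", "", names(g))
              g
            } else abort("no genome available; configure `genome` or simulate")

  sample_aln <- function(s) {
    if (!is.null(sims)) return(sims[[s$sample_id]]$alignments)
    read_alignments(s$alignments)
  }

  if ("filter" %in% stages) {
    res$filters <- lapply(seq_len(nrow(cfg$samples)), function(i) {
      filter_alignments(sample_aln(cfg$samples[i, ]), genes, cfg$filter)
    })
    names(res$filters) <- cfg$samples$sample_id
    stats <- bind_rows(lapply(res$filters, tidy), .id = "sample_id")
    n <- write_tsv_out(stats, file.path(out_dir, "filter_stats.tsv"))
    manifest$stages$filter <- list(rows = n)
  }

  if ("pileup" %in% stages) {
    if (is.null(res$filters)) abort("missing filtered alignments; run the 'filter' stage first")
    res$pileups <- lapply(res$filters, build_pileup, genome = genome)
    combined <- bind_rows(res$pileups, .id = "sample_id") %>%
      mutate(pos = .data$pos + 1L)
    n <- write_tsv_out(combined, file.path(out_dir, "pileup.tsv"))
    manifest$stages$pileup <- list(rows = n)
  }

  if ("summarize" %in% stages) {
    if (is.null(res$pileups)) abort("missing pileups; run the 'pileup' stage first")
    res$site_stats <- lapply(res$pileups, site_stats, genes = genes)
    ss_out <- bind_rows(res$site_stats, .id = "sample_id") %>%
      mutate(pos = .data$pos + 1L)
    n1 <- write_tsv_out(ss_out, file.path(out_dir, "site_stats.tsv"))
    res$rates <- lapply(res$site_stats, transcriptome_rates,
                        expressed_threshold = cfg$expressed_threshold)
    n2 <- write_tsv_out(bind_rows(res$rates, .id = "sample_id"),
                        file.path(out_dir, "class_rates.tsv"))
    res$calls <- lapply(res$site_stats, call_sites,
                        background = cfg$background,
                        q_threshold = cfg$q_threshold,
                        expressed_threshold = cfg$expressed_threshold)
    calls_out <- bind_rows(res$calls, .id = "sample_id") %>%
      mutate(pos = .data$pos + 1L)
    n3 <- write_tsv_out(calls_out, file.path(out_dir, "site_calls.tsv"))
    manifest$stages$summarize <- list(site_rows = n1, class_rows = n2,
                                      call_rows = n3)
  }

  if ("compare" %in% stages) {
    if (is.null(res$site_stats)) abort("missing site stats; run the 'summarize' stage first")
    sheet <- cfg$samples
    with_tp <- function(cond) {
      ids <- sheet$sample_id[sheet$condition == cond]
      bind_rows(lapply(ids, function(id) {
        mutate(res$site_stats[[id]],
               timepoint = sheet$timepoint[sheet$sample_id == id])
      }))
    }
    ctl <- with_tp("control"); trt <- with_tp("radar")
    if (nrow(ctl) == 0L || nrow(trt) == 0L) {
      warn("compare stage needs both control and radar samples; skipping")
    } else {
      res$comparison <- compare_conditions(
        ctl, trt, background = cfg$background,
        q_threshold = cfg$q_threshold,
        expressed_threshold = cfg$expressed_threshold)
      sites_out <- mutate(res$comparison$sites, pos = .data$pos + 1L)
      n1 <- write_tsv_out(sites_out, file.path(out_dir, "comparison.tsv"))
      n2 <- write_tsv_out(res$comparison$summary,
                          file.path(out_dir, "comparison_summary.tsv"))
      manifest$stages$compare <- list(site_rows = n1, summary_rows = n2)
    }
  }

  if ("loci" %in% stages) {
    if (is.null(cfg$loci)) abort("no loci list configured")
    if (is.null(res$pileups)) abort("missing pileups; run the 'pileup' stage first")
    pl <- bind_rows(res$pileups, .id = "sample")
    res$loci_report <- targeted_report(pl, cfg$loci,
                                       expressed_threshold = cfg$expressed_threshold,
                                       genome = genome)
    n <- write_tsv_out(res$loci_report, file.path(out_dir, "loci_report.tsv"))
    manifest$stages$loci <- list(rows = n)
  }

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
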