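#' Pipeline configuration
#'
#' Paths and thresholds for [run_pipeline()]. Stages are enabled by the
#' presence of their inputs: differential expression always runs; enrichment
#' needs `term_gmt`; TFBS analysis needs `genome_fasta`, `gene_coords` and
#' `motif_file`; network assembly needs `edge_table`.
#'
#' @param data_dir directory with the expression TSVs (see
#'   [write_dataset_tsv()]).
#' @param out_dir output directory for the report bundle.
#' @param genome_fasta,gene_coords,motif_file,term_gmt,edge_table optional
#'   input paths (see [read_genome_fasta()], [extract_upstream()],
#'   [read_motifs()], [read_gmt()]).
#' @param seed_nodes extra network seed nodes (default the metal-ion node
#'   `"Zn"` and `"MTF1"`).
#' @param fc_threshold,fdr_threshold differential-expression thresholds.
#' @param alpha significance level of the TFBS z-test.
#' @param window promoter window in bp.
#' @param cohort_size control-cohort size for the TFBS comparison.
#' @param min_replicates minimum replicates per group per time point.
#' @param span lowess span; `skip_lowess` disables normalization.
#' @param skip_lowess logical.
#' @param enrich_mode `"ease"` or `"fisher"`.
#' @param seed master seed for the run (control-cohort sampling).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            genome_fasta = NULL, gene_coords = NULL,
                            motif_file = NULL, term_gmt = NULL,
                            edge_table = NULL,
                            seed_nodes = c("Zn", "MTF1"),
                            fc_threshold = 1.8, fdr_threshold = 0.1,
                            alpha = 0.05, window = 2000L,
                            cohort_size = 198L, min_replicates = 3L,
                            span = 0.3, skip_lowess = FALSE,
                            enrich_mode = "ease", seed = 1L) {
  if (fc_threshold <= 0 || fdr_threshold <= 0 || alpha <= 0)
    stopf("thresholds must be positive")
  structure(list(
    data_dir = data_dir, out_dir = out_dir, genome_fasta = genome_fasta,
    gene_coords = gene_coords, motif_file = motif_file, term_gmt = term_gmt,
    edge_table = edge_table, seed_nodes = seed_nodes,
    fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
    alpha = alpha, window = check_count(window, "window", 1),
    cohort_size = check_count(cohort_size, "cohort_size"),
    min_replicates = check_count(min_replicates, "min_replicates"),
    span = span, skip_lowess = isTRUE(skip_lowess),
    enrich_mode = enrich_mode, seed = as.integer(seed)
  ), class = "pipeline_config")
}

validate_pipeline_inputs <- function(config) {
  chk <- function(path, stage) {
    if (!is.null(path) && !file.exists(path))
      stopf("stage '%s': input not found: %s", stage, path)
  }
  for (f in c("M.tsv", "A.tsv", "confidence.tsv", "design.tsv"))
    chk(file.path(config$data_dir, f), "preprocess")
  tfbs_in <- list(config$genome_fasta, config$gene_coords, config$motif_file)
  if (any(!vapply(tfbs_in, is.null, logical(1))) &&
      any(vapply(tfbs_in, is.null, logical(1))))
    stopf(paste("stage 'tfbs': needs genome_fasta, gene_coords and",
                "motif_file together"))
  for (p in tfbs_in) chk(p, "tfbs")
  chk(config$term_gmt, "enrich")
  chk(config$edge_table, "network")
  invisible(config)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing (MA data are read pre-transformed as M/A TSVs),
#' lowess normalization, confidence/replicate filtering, per-time-point
#' differential-expression calling, then the optional enrichment, TFBS and
#' network stages, writing a report bundle to `config$out_dir`:
#' `de_calls.tsv`, `temporal_summary.json`, `enrichment.tsv`,
#' `tfbs_comparison.tsv`, `tfbs_scans.tsv`, `network_nodes.tsv`,
#' `network_edges.tsv`, `network.graphml`, and `run_log.txt`. Identical
#' config and seed reproduce byte-identical analysis outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results (`calls`, `summary`,
#'   `enrichment`, `tfbs`, `network`, `paths`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_inputs(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  dataset <- run_stage("preprocess", {
    d <- read_dataset_tsv(config$data_dir)
    if (!config$skip_lowess) d <- normalize_dataset(d, span = config$span)
    filter_expressed(d, min_replicates = config$min_replicates)
  })

  calls <- run_stage("diffexpr", {
    call_regulated(dataset, fc_threshold = config$fc_threshold,
                   fdr_threshold = config$fdr_threshold)
  })
  summary <- temporal_summary(calls)
  regulated <- sort(unique(calls$reporter[calls$called]))
  expressed <- rownames(dataset$retained)[rowSums(dataset$retained) > 0]
  p <- file.path(config$out_dir, "de_calls.tsv")
  write_tsv(calls, p); paths <- c(paths, p)
  p <- file.path(config$out_dir, "temporal_summary.json")
  jsonlite::write_json(list(
    per_time = summary$per_time, pct_up = summary$pct_up,
    pct_down = summary$pct_down, n_events = summary$n_events,
    n_regulated = length(regulated), persistent = summary$persistent),
    p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, p)

  enrichment <- NULL
  if (!is.null(config$term_gmt)) {
    enrichment <- run_stage("enrich", {
      tm <- read_gmt(config$term_gmt)
      tm <- lapply(tm, intersect, expressed)
      if (!length(regulated)) stopf("no regulated genes to test")
      fisher_enrichment(regulated, expressed, tm, mode = config$enrich_mode)
    })
    p <- file.path(config$out_dir, "enrichment.tsv")
    write_tsv(enrichment, p); paths <- c(paths, p)
  }

  tfbs <- NULL
  if (!is.null(config$genome_fasta)) {
    tfbs <- run_stage("tfbs", {
      genome <- read_genome_fasta(config$genome_fasta)
      coords <- read_tsv(config$gene_coords)
      motifs <- read_motifs(config$motif_file)
      promoters <- extract_upstream(coords, genome, window = config$window)
      fg_ids <- intersect(regulated, names(promoters$seqs))
      if (!length(fg_ids)) stopf("no regulated genes with promoter sequence")
      cohort <- select_control_cohort(names(promoters$seqs), regulated,
                                      size = config$cohort_size,
                                      seed = config$seed)
      subset_ps <- function(ids) promoter_set(
        promoters$seqs[ids], promoters$window, promoters$truncated[ids])
      fg <- subset_ps(fg_ids); bg <- subset_ps(cohort)
      comp <- do.call(rbind, lapply(motifs, function(m) {
        compare_tfbs_frequency(scan_promoters(fg, m), scan_promoters(bg, m),
                               alpha = config$alpha)
      }))
      scans <- do.call(rbind, lapply(motifs, function(m) {
        s <- rbind(cbind(scan_promoters(fg, m), cohort = "regulated"),
                   cbind(scan_promoters(bg, m), cohort = "control"))
        cbind(motif = m$name, s)
      }))
      list(comparison = comp, scans = scans)
    })
    p <- file.path(config$out_dir, "tfbs_comparison.tsv")
    write_tsv(tfbs$comparison, p); paths <- c(paths, p)
    p <- file.path(config$out_dir, "tfbs_scans.tsv")
    write_tsv(tfbs$scans, p); paths <- c(paths, p)
  }

  network <- NULL
  if (!is.null(config$edge_table)) {
    network <- run_stage("network", {
      edges <- read_tsv(config$edge_table)
      build_direct_interaction_network(regulated, config$seed_nodes, edges)
    })
    paths <- c(paths, write_network(network,
                                    file.path(config$out_dir, "network")))
  }

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(c(
    sprintf("gillzinc %s / R %s", as.character(utils::packageVersion("gillzinc")),
            getRversion()),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", config$seed),
    "parameters:",
    sprintf("  %s = %s", names(config),
            vapply(config, function(v) paste(format(v), collapse = ","),
                   character(1))),
    sprintf("stages run: %s", paste(c("preprocess", "diffexpr",
      if (!is.null(enrichment)) "enrich", if (!is.null(tfbs)) "tfbs",
      if (!is.null(network)) "network"), collapse = ", "))),
    log_path)
  paths <- c(paths, log_path)

  invisible(list(calls = calls, summary = summary, enrichment = enrichment,
                 tfbs = tfbs, network = network, regulated = regulated,
                 expressed = expressed, paths = paths))
}

#' Summarize a regulated-gene fold-change table
#'
#' Counts per-time-point regulation calls from a wide table of signed fold
#' changes (one row per gene, one column per time point, `NA` where the gene
#' was not called at that time point), the overall percentages of up- and
#' down-regulation events, and the genes called in the same direction at
#' every time point.
#'
#' @param x data frame (first column gene id, remaining columns signed fold
#'   changes) or path to such a TSV.
#' @return list as in [temporal_summary()], with `per_time` keyed by the
#'   fold-change column names.
#' @export
summarize_regulated_table <- function(x) {
  if (is.character(x)) x <- read_tsv(x)
  fc <- as.matrix(x[, -1, drop = FALSE])
  n_up <- colSums(fc > 0, na.rm = TRUE)
  n_down <- colSums(fc < 0, na.rm = TRUE)
  n_events <- sum(n_up) + sum(n_down)
  sgn <- sign(fc)
  persistent <- x[[1]][apply(sgn, 1, function(s)
    !anyNA(s) && all(s != 0) && length(unique(s)) == 1)]
  list(per_time = data.frame(time = colnames(fc), n_up = unname(n_up),
                             n_down = unname(n_down),
                             n_total = unname(n_up + n_down)),
       pct_up = if (n_events) 100 * sum(n_up) / n_events else NA_real_,
       pct_down = if (n_events) 100 * sum(n_down) / n_events else NA_real_,
       n_events = n_events, persistent = sort(persistent))
}

# Wrap simulated promoters into synthetic contigs so that extract_upstream()
# recovers them: plus-strand genes get [pad][promoter][start codon...],
# minus-strand genes the reverse-complement layout.
promoters_to_genome <- function(promoters, strands = NULL, seed = 1L) {
  ids <- names(promoters$seqs)
  w <- promoters$window
  if (is.null(strands))
    strands <- rep(c("+", "-"), length.out = length(ids))
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  withr::with_seed(sub_seed(seed, "genome"), {
    contigs <- character(length(ids)); starts <- integer(length(ids))
    for (i in seq_along(ids)) {
      p <- promoters$seqs[[ids[i]]]
      if (strands[i] == "+") {
        contigs[i] <- paste0(pad(10), p, "ATG", pad(10))
        starts[i] <- 10L + nchar(p) + 1L
      } else {
        contigs[i] <- paste0(pad(10), "CAT", revcomp(p), pad(10))
        starts[i] <- 13L
      }
    }
  })
  names(contigs) <- paste0("ctg_", ids)
  list(genome = contigs,
       coords = data.frame(id = ids, contig = names(contigs),
                           start = starts, strand = strands))
}

#' Write a complete synthetic study to disk
#'
#' Generates every input the pipeline consumes — expression TSVs, a genome
#' FASTA with gene coordinates whose upstream windows contain planted motif
#' sites, a motif file, a GMT annotation table with a term planted among the
#' regulated genes, and a curated edge table wired around the regulated
#' genes plus the `Zn` and `MTF1` seed nodes — together with the ground
#' truth tables.
#'
#' @param dir output directory.
#' @param config a [sim_config()]; its seed drives all sub-generators.
#' @param n_promoter_genes number of genes given promoter sequence (the
#'   regulated genes first, then never-regulated fillers for the control
#'   cohort pool).
#' @param fg_presence,bg_presence planted presence fractions of the enriched
#'   demonstration motif in regulated vs non-regulated promoters.
#' @return invisibly, a list with the truth tables and file paths.
#' @export
simulate_study <- function(dir, config = sim_config(),
                           n_promoter_genes = 320L,
                           fg_presence = 0.5, bg_presence = 0.05) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_expression_dataset(config)
  write_dataset_tsv(sim$dataset, dir)
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))

  reg_ids <- sim$truth$reporter[sim$truth$regulated]
  nonreg <- setdiff(sim$truth$reporter, reg_ids)
  n_prom <- min(n_promoter_genes, nrow(sim$truth))
  prom_ids <- c(reg_ids, nonreg)[seq_len(n_prom)]
  fg_ids <- intersect(reg_ids, prom_ids)

  # motifs: an HNF4A-like direct repeat planted enriched in the foreground,
  # and an MRE-like consensus (fixture-only) planted at equal frequency
  motifs <- list(
    list(name = "HNF4A", motif = "RGGNCAAAGGTCA", fg = fg_presence,
         bg = bg_presence),
    list(name = "MRE", motif = "TGCRCNCGGCCC", fg = 0.2, bg = 0.2))
  ps <- simulate_promoter_set(
    n_genes = n_prom, length = 2000L, gc = 0.4, planted = motifs,
    foreground_ids = fg_ids, ids = prom_ids, seed = config$seed)
  gen <- promoters_to_genome(ps$promoters, seed = config$seed)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(gen$genome),
                              file.path(dir, "genome.fasta"), width = 60)
  write_tsv(gen$coords, file.path(dir, "gene_coords.tsv"))
  writeLines(c("# name\tIUPAC consensus",
               vapply(motifs, function(m) paste(m$name, m$motif, sep = "\t"),
                      character(1))),
             file.path(dir, "motifs.tsv"))
  write_tsv(ps$truth, file.path(dir, "promoter_truth.tsv"))

  n_planted <- min(30L, length(reg_ids))
  tm <- simulate_annotation_table(
    n_genes = nrow(sim$truth), n_terms = 100L, term_size_range = c(10L, 60L),
    planted = list(list(term = "T001", genes = reg_ids[seq_len(n_planted)])),
    ids = sim$truth$reporter, seed = config$seed)
  write_gmt(tm, file.path(dir, "terms.gmt"))

  edges <- simulate_interaction_table(
    nodes = c(utils::head(reg_ids, 60), "Zn", "MTF1"),
    edge_density = 0.08, seed = config$seed)
  write_tsv(edges, file.path(dir, "edges.tsv"))

  invisible(list(truth = sim$truth, promoter_truth = ps$truth,
                 foreground_ids = fg_ids, dir = dir))
}
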