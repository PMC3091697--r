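#' Simulation configuration for a two-channel time-course experiment
#'
#' Describes the study design emulated by [simulate_expression_dataset()]:
#' two conditions (zinc `depleted` vs `control`) sampled at five time points
#' with five biological replicates each, one control replicate missing at
#' day 4, ~16K reporters of which a small minority carry a planted expression
#' effect at one or more time points, with down-regulation dominating from
#' day 4 onwards.
#'
#' @param n_reporters number of array reporters (spots).
#' @param time_points sampled time points, in days.
#' @param n_replicates biological replicates per condition per time point.
#' @param dropout list of `list(condition =, time =)` entries each losing one
#'   replicate (default: one control fish at day 4).
#' @param frac_regulated fraction of reporters carrying a true effect at one
#'   or more time points.
#' @param tp_weights relative probability that a regulated reporter is active
#'   at each time point; the default peaks at day 7 and nearly vanishes by
#'   day 14, mirroring a transient acclimation response.
#' @param frac_down_late probability that a planted effect at time points
#'   >= `late_from` days is a down-regulation (earlier effects are
#'   symmetric); the default 0.75 encodes a three-to-one dominance of
#'   down-regulation at later time points.
#' @param late_from first time point (days) at which `frac_down_late`
#'   applies.
#' @param effect_log2 magnitude of every planted effect, in log2 units.
#' @param noise_sd standard deviation of the log-ratio measurement noise.
#' @param bias_coeffs polynomial coefficients `c(b0, b1, b2, b3)` of the
#'   intensity-dependent dye bias `b(z) = b0 + b1*z + b2*z^2 + b3*z^3`
#'   evaluated at `z = (A - 10)/5`; the default gives a visible but removable
#'   trend bounded by about 0.5 log2 units over the bulk of the intensity
#'   range.
#' @param baseline_sd standard deviation of reporter-specific baseline
#'   log-ratios (shared between conditions).
#' @param low_confidence_rate fraction of spots flagged as unreliable by the
#'   image quantification.
#' @param seed master seed; every stochastic sub-task draws from a named
#'   stream derived from it.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reporters = 16000L,
                       time_points = c(0.3, 1, 4, 7, 14),
                       n_replicates = 5L,
                       dropout = list(list(condition = "control", time = 4)),
                       frac_regulated = 0.03,
                       tp_weights = c(0.10, 0.16, 0.29, 0.40, 0.05),
                       frac_down_late = 0.75,
                       late_from = 4,
                       effect_log2 = 1.5,
                       noise_sd = 0.4,
                       bias_coeffs = c(0, 0.1, -0.15, 0.25),
                       baseline_sd = 0.25,
                       low_confidence_rate = 0.05,
                       seed = 1L) {
  n_reporters <- check_count(n_reporters, "n_reporters", min = 1)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1)
  check_fraction(frac_regulated, "frac_regulated")
  check_fraction(frac_down_late, "frac_down_late")
  check_fraction(low_confidence_rate, "low_confidence_rate")
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!is.numeric(effect_log2) || effect_log2 <= 0)
    stopf("'effect_log2' must be > 0")
  if (length(tp_weights) != length(time_points) || any(tp_weights < 0))
    stopf("'tp_weights' must be non-negative, one per time point")
  for (d in dropout) {
    if (!is.list(d) || is.null(d$condition) || is.null(d$time))
      stopf("'dropout' entries must be list(condition =, time =)")
    if (!d$condition %in% c("depleted", "control"))
      stopf("'dropout' condition must be 'depleted' or 'control'")
    if (!d$time %in% time_points) stopf("'dropout' time not a design time point")
  }
  structure(list(
    n_reporters = n_reporters, time_points = time_points,
    n_replicates = n_replicates, dropout = dropout,
    frac_regulated = frac_regulated, tp_weights = tp_weights,
    frac_down_late = frac_down_late, late_from = late_from,
    effect_log2 = effect_log2, noise_sd = noise_sd,
    bias_coeffs = bias_coeffs, baseline_sd = baseline_sd,
    low_confidence_rate = low_confidence_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_reporters, "reporters;",
      length(x$time_points), "time points x 2 conditions x",
      x$n_replicates, "replicates;",
      length(x$dropout), "dropout(s);",
      sprintf("%.1f%% regulated; seed %d\n",
              100 * x$frac_regulated, x$seed))
  invisible(x)
}

# Design table implied by a sim_config: one row per array.
sim_design <- function(config) {
  g <- expand.grid(replicate = seq_len(config$n_replicates),
                   time = config$time_points,
                   condition = c("depleted", "control"),
                   stringsAsFactors = FALSE)
  drop <- rep(FALSE, nrow(g))
  for (d in config$dropout) {
    drop <- drop | (g$condition == d$condition & g$time == d$time &
                      g$replicate == config$n_replicates)
  }
  g <- g[!drop, , drop = FALSE]
  g$array_id <- sprintf("%s_d%s_r%d", g$condition,
                        sub("\\.", "p", format(g$time)), g$replicate)
  rownames(g) <- NULL
  g[, c("array_id", "condition", "time", "replicate")]
}

# Dye-bias polynomial b(A); A is mean log2 intensity, centred and scaled so
# the default coefficients act on roughly [-1, 1].
dye_bias <- function(A, coeffs) {
  z <- (A - 10) / 5
  b <- 0
  for (i in seq_along(coeffs)) b <- b + coeffs[i] * z^(i - 1)
  b
}

#' Simulate a two-channel time-course expression dataset with planted truth
#'
#' Generates log2-ratio measurements `M = baseline + effect + b(A) + noise`
#' per spot: a reporter-specific baseline shared between conditions, a
#' planted log2 effect for regulated reporters on depleted arrays at their
#' active time points, an intensity-dependent dye bias `b(A)` (cubic
#' polynomial by default), and Gaussian noise. Per-spot mean log2 intensities
#' `A` are drawn from a normal distribution (log-normal intensities) spanning
#' roughly three orders of magnitude. A configurable fraction of spots is
#' flagged low-confidence.
#'
#' @param config a [sim_config()].
#' @return a list with elements `dataset` (an [expression_dataset()]) and
#'   `truth`, a data frame with one row per reporter: the per-time-point true
#'   log2 effects (columns `effect_<t>`, 0 when unregulated), `regulated`
#'   (any nonzero effect) and `persistent` (same nonzero sign at every time
#'   point).
#' @export
simulate_expression_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  design <- sim_design(config)
  nr <- config$n_reporters
  na <- nrow(design)
  tps <- config$time_points
  reporters <- sprintf("R%05d", seq_len(nr))

  # planted truth
  truth_eff <- matrix(0, nr, length(tps),
                      dimnames = list(reporters, paste0("effect_", tps)))
  withr::with_seed(sub_seed(config$seed, "truth"), {
    n_reg <- round(config$frac_regulated * nr)
    reg_idx <- sample.int(nr, n_reg)
    w <- config$tp_weights / sum(config$tp_weights)
    for (i in reg_idx) {
      # mostly single-time-point regulation: little temporal continuity
      n_active <- min(sample(1:3, 1, prob = c(0.80, 0.15, 0.05)),
                      length(tps))
      active <- sample(seq_along(tps), n_active, prob = w)
      for (j in active) {
        p_down <- if (tps[j] >= config$late_from) config$frac_down_late else 0.5
        sgn <- if (runif(1) < p_down) -1 else 1
        truth_eff[i, j] <- sgn * config$effect_log2
      }
    }
  })

  withr::with_seed(sub_seed(config$seed, "measure"), {
    baseline <- rnorm(nr, 0, config$baseline_sd)
    A <- matrix(rnorm(nr * na, mean = 10, sd = 1.7), nr, na,
                dimnames = list(reporters, design$array_id))
    mu <- matrix(baseline, nr, na)
    dep <- design$condition == "depleted"
    for (j in which(dep)) {
      tj <- match(design$time[j], tps)
      mu[, j] <- mu[, j] + truth_eff[, tj]
    }
    M <- mu + dye_bias(A, config$bias_coeffs) +
      matrix(rnorm(nr * na, 0, config$noise_sd), nr, na)
    dimnames(M) <- dimnames(A)
    confidence <- matrix(runif(nr * na) >= config$low_confidence_rate, nr, na,
                         dimnames = dimnames(A))
  })

  signs <- sign(truth_eff)
  persistent <- apply(signs, 1, function(s) all(s != 0) && length(unique(s)) == 1)
  truth <- data.frame(reporter = reporters, truth_eff,
                      regulated = rowSums(truth_eff != 0) > 0,
                      persistent = persistent, row.names = NULL,
                      check.names = FALSE)

  list(dataset = expression_dataset(M, A, confidence, design), truth = truth)
}

#' Simulate a promoter set with planted motif sites
#'
#' Generates random upstream sequences at a given GC content and implants
#' concrete realizations of IUPAC consensus motifs into chosen fractions of a
#' foreground gene set and of the remaining (background) genes. The realized
#' number of carriers is `round(fraction * group size)`.
#'
#' @param n_genes total number of genes; ids are `G0001`, ...
#' @param length promoter window length in bp.
#' @param gc GC content of the random background sequence.
#' @param planted list of `list(motif =, name =, fg = fraction, bg = fraction)`
#'   entries; `name` defaults to the motif string.
#' @param foreground_ids character vector of foreground gene ids (subset of
#'   the generated ids); defaults to the first quarter of genes.
#' @param ids optional custom gene ids (length `n_genes`), e.g. to reuse
#'   reporter ids from an expression simulation.
#' @param seed integer seed.
#' @return list with `promoters` (a [promoter_set()]) and `truth`, a data
#'   frame of planted insertions (gene, motif name, realized site sequence,
#'   1-based position).
#' @export
simulate_promoter_set <- function(n_genes, length = 2000L, gc = 0.4,
                                  planted = list(), foreground_ids = NULL,
                                  ids = NULL, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  length <- check_count(length, "length", min = 1)
  check_fraction(gc, "gc")
  if (is.null(ids)) ids <- sprintf("G%04d", seq_len(n_genes))
  if (length(ids) != n_genes || anyDuplicated(ids))
    stopf("'ids' must be %d unique gene ids", n_genes)
  if (is.null(foreground_ids)) foreground_ids <- ids[seq_len(max(1, n_genes %/% 4))]
  if (!all(foreground_ids %in% ids)) stopf("unknown foreground gene ids")
  for (p in planted) {
    if (!is_iupac(p$motif)) stopf("invalid IUPAC motif '%s'", p$motif)
    if (nchar(p$motif) > length) stopf("motif longer than promoter window")
    check_fraction(p$fg, "planted fg fraction")
    check_fraction(p$bg, "planted bg fraction")
  }

  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  withr::with_seed(sub_seed(seed, "promoters"), {
    seqs <- vapply(ids, function(id) {
      paste(sample(names(base_prob), length, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))

    truth <- list()
    bg_ids <- setdiff(ids, foreground_ids)
    for (p in planted) {
      nm <- p$name %||% p$motif
      carriers <- c(
        sample(foreground_ids, round(p$fg * length(foreground_ids))),
        if (length(bg_ids)) sample(bg_ids, round(p$bg * length(bg_ids)))
      )
      for (g in carriers) {
        site <- paste(vapply(strsplit(toupper(p$motif), "")[[1]],
                             function(ch) sample(IUPAC_SETS[[ch]], 1),
                             character(1)), collapse = "")
        pos <- sample.int(length - nchar(site) + 1L, 1)
        substr(seqs[g], pos, pos + nchar(site) - 1L) <- site
        truth[[length(truth) + 1L]] <- data.frame(
          gene = g, motif = nm, site = site, position = pos)
      }
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(), motif = character(),
               site = character(), position = integer())
  list(promoters = promoter_set(seqs, window = length),
       truth = truth, foreground_ids = foreground_ids)
}

#' Simulate a gene-to-term annotation table
#'
#' Builds a GMT-style term map over a synthetic gene universe, optionally
#' forcing chosen genes into chosen terms (planted overlaps are reproduced
#' exactly); other term members are drawn uniformly.
#'
#' @param n_genes universe size; ids are `G0001`, ...
#' @param n_terms number of terms, named `T001`, ...
#' @param term_size_range inclusive range of term sizes.
#' @param planted list of `list(term =, genes = character vector)` forcing
#'   membership; an error is raised if a forced set exceeds the sampled term
#'   size (the term is grown to fit if needed, capped at the universe).
#' @param ids optional custom gene ids (length `n_genes`).
#' @param seed integer seed.
#' @return named list of character vectors (term -> gene ids), class
#'   `gene_term_map`, with the gene universe in `attr(, "universe")`.
#' @export
simulate_annotation_table <- function(n_genes, n_terms,
                                      term_size_range = c(5L, 50L),
                                      planted = list(), ids = NULL,
                                      seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1)
  n_terms <- check_count(n_terms, "n_terms", min = 1)
  if (is.null(ids)) ids <- sprintf("G%04d", seq_len(n_genes))
  if (length(ids) != n_genes || anyDuplicated(ids))
    stopf("'ids' must be %d unique gene ids", n_genes)
  term_ids <- sprintf("T%03d", seq_len(n_terms))
  forced <- setNames(vector("list", n_terms), term_ids)
  for (p in planted) {
    if (!p$term %in% term_ids) stopf("planted term '%s' not among terms", p$term)
    if (!all(p$genes %in% ids)) stopf("planted genes outside the universe")
    if (length(p$genes) > n_genes) stopf("impossible planted overlap")
    forced[[p$term]] <- unique(p$genes)
  }
  withr::with_seed(sub_seed(seed, "annotation"), {
    tm <- lapply(term_ids, function(t) {
      size <- sample(seq(term_size_range[1], min(term_size_range[2], n_genes)), 1)
      size <- max(size, length(forced[[t]]))
      extra <- setdiff(ids, forced[[t]])
      members <- c(forced[[t]], sample(extra, size - length(forced[[t]])))
      sort(members)
    })
  })
  structure(setNames(tm, term_ids), class = "gene_term_map", universe = ids)
}

#' Simulate a curated interaction edge table
#'
#' Draws typed, optionally directed edges among a node set (plus optional
#' anonymous extra nodes) with a given per-pair density. Self-loops are
#' excluded unless requested.
#'
#' @param nodes character vector of node ids.
#' @param extra_nodes number of additional nodes `X001`, ...
#' @param edge_density probability that an unordered node pair is connected.
#' @param types interaction-type vocabulary to sample from.
#' @param directed fraction of edges marked directed.
#' @param self_loops allow self edges.
#' @param seed integer seed.
#' @return data frame with columns `source`, `target`, `type`, `directed`.
#' @export
simulate_interaction_table <- function(nodes, extra_nodes = 0L,
                                       edge_density = 0.1,
                                       types = c("binding", "expression",
                                                 "regulation", "metabolism",
                                                 "promoter binding"),
                                       directed = 0.3, self_loops = FALSE,
                                       seed = 1L) {
  check_fraction(edge_density, "edge_density")
  extra_nodes <- check_count(extra_nodes, "extra_nodes")
  all_nodes <- c(nodes, if (extra_nodes) sprintf("X%03d", seq_len(extra_nodes)))
  n <- length(all_nodes)
  pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(integer(), ncol = 2)
  if (self_loops) pairs <- rbind(pairs, cbind(seq_len(n), seq_len(n)))
  withr::with_seed(sub_seed(seed, "edges"), {
    keep <- runif(nrow(pairs)) < edge_density
    pairs <- pairs[keep, , drop = FALSE]
    out <- data.frame(
      source = all_nodes[pairs[, 1]], target = all_nodes[pairs[, 2]],
      type = if (nrow(pairs)) sample(types, nrow(pairs), replace = TRUE)
             else character(0),
      directed = if (nrow(pairs)) runif(nrow(pairs)) < directed else logical(0),
      stringsAsFactors = FALSE)
  })
  out
}
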