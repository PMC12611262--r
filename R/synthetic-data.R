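#' Simulation configuration
#'
#' Collects every tunable of the synthetic multi-cell-type generator.
#' The generator plants three kinds of structure on top of an alternating
#' A/B block baseline: (i) organ divergence — for each secondary organ a
#' disjoint set of bins where that organ's normal epithelium holds the
#' opposite compartment from the primary-organ epithelium; (ii) EMT bins —
#' bins that tilt monotonically from the baseline state as a cell line's
#' epithelial-to-mesenchymal parameter grows; (iii) free bins, where cancer
#' lines pick up idiosyncratic compartment switches. Metastatic (and, at a
#' lower rate, localized) cancer lines additionally flip organ-divergent
#' bins toward the target organ's state: the organ-permissive switches the
#' downstream statistic is designed to detect.
#'
#' @param n_bins Bins per synthetic chromosome.
#' @param bin_size Bin width in bp.
#' @param n_chromosomes Number of synthetic chromosomes (concatenated
#'   genome-wide analyses use several).
#' @param compartment_block_length Mean A/B block length in bins
#'   (geometric).
#' @param decay_exponent Contact distance-decay exponent `alpha`
#'   (P ~ d^-alpha).
#' @param checkerboard_strength Compartment contrast `delta` in (0,1):
#'   same-state contacts are scaled by `1+delta`, cross-state by `1-delta`.
#' @param depth Expected total contacts per chromosome (upper triangle).
#' @param organ_divergence Fraction of bins at which each secondary organ's
#'   normal state differs from the primary organ's.
#' @param switch_rate_cancer Per-bin probability that a cancer line flips a
#'   free bin.
#' @param permissive_switch_rate_metastatic,permissive_switch_rate_localized
#'   Probability that a metastatic (localized) line flips an
#'   organ-divergent bin toward the target organ's state.
#' @param emt_bin_fraction Fraction of bins on the EMT tilt gradient.
#' @param de_gene_fraction Fraction of simulated genes that are
#'   differential (the epithelial/mesenchymal signature genes); sets the
#'   total gene count given the signature sizes.
#' @param effect_size_log2 log2 expression shift of signature genes across
#'   the full EMT gradient.
#' @param dispersion Negative-binomial dispersion of simulated counts
#'   (0 = Poisson).
#' @param baseline_log2_mean,baseline_log2_sd Log-normal baseline of gene
#'   expression (log2 scale).
#' @param n_localized,n_metastatic Number of primary-organ localized and
#'   metastatic cancer lines (at least 2 cancer lines in total).
#' @param n_secondary_cancers Localized cancer lines per secondary organ.
#' @param primary_organ,secondary_organs Organ names; the first secondary
#'   organ is the metastatic target, any further ones are decoys that
#'   receive no permissive flips.
#' @param seed Integer master seed; all randomness derives from it through
#'   named substreams.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_bins = 400L,
                              bin_size = 250000L,
                              n_chromosomes = 1L,
                              compartment_block_length = 8,
                              decay_exponent = 1.0,
                              checkerboard_strength = 0.3,
                              depth = 1e6,
                              organ_divergence = 0.05,
                              switch_rate_cancer = 0.05,
                              permissive_switch_rate_metastatic = 0.5,
                              permissive_switch_rate_localized = 0.1,
                              emt_bin_fraction = 0.1,
                              de_gene_fraction = 0.2,
                              effect_size_log2 = 2,
                              dispersion = 0.1,
                              baseline_log2_mean = 6,
                              baseline_log2_sd = 1.5,
                              n_localized = 2L,
                              n_metastatic = 2L,
                              n_secondary_cancers = 2L,
                              primary_organ = "breast",
                              secondary_organs = "lung",
                              seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(organ_divergence, switch_rate_cancer,
             permissive_switch_rate_metastatic,
             permissive_switch_rate_localized, emt_bin_fraction,
             de_gene_fraction)
  if (any(rates < 0 | rates > 1)) {
    stop("rates and fractions must lie in [0, 1]")
  }
  if (depth <= 0) stop("depth must be positive")
  if (decay_exponent <= 0) stop("decay_exponent must be positive")
  if (checkerboard_strength <= 0 || checkerboard_strength >= 1) {
    stop("checkerboard_strength must lie in (0, 1)")
  }
  if (n_localized + n_metastatic < 2L) {
    stop("need at least 2 primary-organ cancer lines")
  }
  if (length(secondary_organs) < 1L) stop("need >= 1 secondary organ")
  if (n_chromosomes * n_bins * (organ_divergence * length(secondary_organs) +
                                emt_bin_fraction) > n_chromosomes * n_bins) {
    stop("organ divergence and EMT fractions exceed the genome")
  }
  structure(cfg, class = "SimulationConfig")
}

# Deterministic substream seed derived from the master seed and a label.
# Keeps every draw reproducible from one integer while decoupling the
# streams of different cell types / stages.
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483123
  as.integer((abs(as.numeric(seed)) %% 2147483123 * 7919 + h) %% 2147483123)
}

geometric_blocks <- function(n_bins, mean_len) {
  states <- character(0)
  cur <- "A"
  while (length(states) < n_bins) {
    len <- stats::rgeom(1L, prob = 1 / mean_len) + 1L
    states <- c(states, rep(cur, len))
    cur <- if (cur == "A") "B" else "A"
  }
  states[seq_len(n_bins)]
}

flip_states <- function(states, at) {
  states[at] <- ifelse(states[at] == "A", "B", "A")
  states
}

#' Simulate a multi-cell-type compartment panel
#'
#' Builds ground-truth A/B state vectors for a panel of cell types sharing
#' an epithelial lineage: normal epithelium for the primary organ and for
#' each secondary organ, localized and metastatic primary-organ cancer
#' lines carrying an EMT gradient, and localized secondary-organ cancer
#' lines. See [simulation_config()] for the planted structure.
#'
#' @param config A [simulation_config()].
#' @return A `CellTypePanel`: list with `bins`, `cell_types` (data.frame of
#'   name/organ/status/emt_parameter), `states` (bins x cell types matrix
#'   of "A"/"B"), `partition` (per-bin planted class:
#'   `free` / `emt` / `eligible_<organ>`), `emt_threshold` (per-bin tilt
#'   threshold, NA off the EMT set), `planted` (bins x primary-cancer-lines
#'   matrix recording, for each (normal, cancer) pair, the planted class of
#'   every bin: `background`, `cancer_switch`, `emt`, `eligible_<organ>` or
#'   `permissive_<organ>`), and `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  n <- cfg$n_bins * cfg$n_chromosomes
  bins <- bind_bins(lapply(seq_len(cfg$n_chromosomes), function(i) {
    make_bins(sprintf("chrS%d", i), cfg$n_bins, cfg$bin_size)
  }))

  set.seed(substream_seed(cfg$seed, "baseline"))
  baseline <- unlist(lapply(seq_len(cfg$n_chromosomes), function(i) {
    geometric_blocks(cfg$n_bins, cfg$compartment_block_length)
  }), use.names = FALSE)

  # disjoint partition of bins into planted classes
  set.seed(substream_seed(cfg$seed, "partition"))
  partition <- rep("free", n)
  avail <- seq_len(n)
  n_div <- round(cfg$organ_divergence * n)
  for (org in cfg$secondary_organs) {
    pick <- sort(sample(avail, min(n_div, length(avail))))
    partition[pick] <- paste0("eligible_", org)
    avail <- setdiff(avail, pick)
  }
  n_emt <- round(cfg$emt_bin_fraction * n)
  emt_bins <- sort(sample(avail, min(n_emt, length(avail))))
  partition[emt_bins] <- "emt"
  emt_threshold <- rep(NA_real_, n)
  if (length(emt_bins) > 0L) {
    emt_threshold[emt_bins] <- stats::runif(length(emt_bins))
  }
  free_bins <- which(partition == "free")

  # normal epithelium per organ: secondary organs differ from the primary
  # exactly at their own eligible bins
  organ_normals <- list()
  organ_normals[[cfg$primary_organ]] <- baseline
  for (org in cfg$secondary_organs) {
    organ_normals[[org]] <- flip_states(baseline,
                                        which(partition == paste0("eligible_", org)))
  }

  target <- cfg$secondary_organs[1L]
  n_cancer <- cfg$n_localized + cfg$n_metastatic
  emt_values <- seq_len(n_cancer) / n_cancer

  cell_types <- data.frame(name = character(0), organ = character(0),
                           status = character(0),
                           emt_parameter = numeric(0),
                           stringsAsFactors = FALSE)
  states <- list()
  add_cell <- function(name, organ, status, emt, st) {
    cell_types[nrow(cell_types) + 1L, ] <<- list(name, organ, status, emt)
    states[[name]] <<- st
  }

  add_cell(paste0(cfg$primary_organ, "_normal"), cfg$primary_organ,
           "normal", 0, baseline)

  make_cancer <- function(name, emt, permissive_rate) {
    set.seed(substream_seed(cfg$seed, name))
    st <- baseline
    planted <- rep("background", n)
    planted[partition == "emt"] <- "emt"
    tilted <- emt_bins[emt_threshold[emt_bins] <= emt]
    st <- flip_states(st, tilted)
    sw <- free_bins[stats::runif(length(free_bins)) < cfg$switch_rate_cancer]
    st <- flip_states(st, sw)
    planted[sw] <- "cancer_switch"
    for (org in cfg$secondary_organs) {
      elig <- which(partition == paste0("eligible_", org))
      planted[elig] <- paste0("eligible_", org)
      rate <- if (org == target) permissive_rate else 0
      if (rate > 0 && length(elig) > 0L) {
        flip <- elig[stats::runif(length(elig)) < rate]
        st[flip] <- organ_normals[[org]][flip]
        planted[flip] <- paste0("permissive_", org)
      }
    }
    list(states = st, planted = planted)
  }

  planted <- list()
  k <- 0L
  for (i in seq_len(cfg$n_localized)) {
    k <- k + 1L
    nm <- sprintf("%s_localized_%d", cfg$primary_organ, i)
    cc <- make_cancer(nm, emt_values[k], cfg$permissive_switch_rate_localized)
    add_cell(nm, cfg$primary_organ, "localized", emt_values[k], cc$states)
    planted[[nm]] <- cc$planted
  }
  for (i in seq_len(cfg$n_metastatic)) {
    k <- k + 1L
    nm <- sprintf("%s_metastatic_%d", cfg$primary_organ, i)
    cc <- make_cancer(nm, emt_values[k], cfg$permissive_switch_rate_metastatic)
    add_cell(nm, cfg$primary_organ, "metastatic", emt_values[k], cc$states)
    planted[[nm]] <- cc$planted
  }

  for (org in cfg$secondary_organs) {
    add_cell(paste0(org, "_normal"), org, "normal", 0, organ_normals[[org]])
    for (i in seq_len(cfg$n_secondary_cancers)) {
      nm <- sprintf("%s_localized_%d", org, i)
      set.seed(substream_seed(cfg$seed, nm))
      sw <- free_bins[stats::runif(length(free_bins)) < cfg$switch_rate_cancer]
      add_cell(nm, org, "localized", 0,
               flip_states(organ_normals[[org]], sw))
    }
  }

  structure(list(
    bins = bins,
    cell_types = cell_types,
    states = do.call(cbind, states),
    partition = partition,
    emt_threshold = emt_threshold,
    planted = if (length(planted) > 0L) do.call(cbind, planted) else NULL,
    config = cfg
  ), class = "CellTypePanel")
}

#' @export
print.CellTypePanel <- function(x, ...) {
  cat(sprintf("CellTypePanel: %d cell types x %d bins (%d chromosomes)\n",
              nrow(x$cell_types), nrow(x$bins), x$config$n_chromosomes))
  print(x$cell_types)
  invisible(x)
}

#' Simulate a binned contact matrix from a compartment state vector
#'
#' Expected contacts follow a power-law distance decay modulated by a
#' compartment checkerboard: `E[i,j] = C * (|i-j|+1)^-alpha * (1+delta)`
#' when bins i and j share a state and `(1-delta)` otherwise (i != j), with
#' C chosen so the upper-triangle expectation sums to `depth`. Observed
#' counts are Poisson draws around the expectation, mirrored to a symmetric
#' matrix with a zero diagonal.
#'
#' @param states Character vector of "A"/"B" states, one per bin.
#' @param config A [simulation_config()] supplying `decay_exponent`,
#'   `checkerboard_strength` and `depth`.
#' @param bins Optional bin table (defaults to one chromosome of
#'   `config$bin_size` bins named "chrS1").
#' @param seed Seed for the Poisson draw (defaults to `config$seed`).
#' @param expected If TRUE, return the noiseless expectation instead of a
#'   Poisson draw.
#' @return A [contact_matrix()].
#' @export
simulate_contact_matrix <- function(states, config, bins = NULL,
                                    seed = config$seed, expected = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  delta <- config$checkerboard_strength
  n <- length(states)
  if (is.null(bins)) bins <- make_bins("chrS1", n, config$bin_size)
  if (nrow(bins) != n) stop("bins do not match states length")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  same <- outer(states, states, "==")
  mu <- (d + 1)^(-config$decay_exponent) * ifelse(same, 1 + delta, 1 - delta)
  diag(mu) <- 0
  mu <- mu * (config$depth / sum(mu[upper.tri(mu)]))
  if (expected) {
    return(contact_matrix(mu, bins, mask = rep(FALSE, n)))
  }
  set.seed(seed)
  up <- which(upper.tri(mu))
  counts <- matrix(0, n, n)
  counts[up] <- stats::rpois(length(up), mu[up])
  counts <- counts + t(counts)
  contact_matrix(counts, bins)
}

#' Placeholder epithelial/mesenchymal signature gene sets
#'
#' Generates synthetic gene-symbol sets sized like the curated signatures
#' used for E/M scoring (232 epithelial, 193 mesenchymal genes by default).
#'
#' @param n_epithelial,n_mesenchymal Set sizes.
#' @return A `GeneSetCollection` with sets `E` and `M`.
#' @export
simulate_gene_sets <- function(n_epithelial = 232L, n_mesenchymal = 193L) {
  structure(list(E = sprintf("EPI%04d", seq_len(n_epithelial)),
                 M = sprintf("MES%04d", seq_len(n_mesenchymal))),
            class = "GeneSetCollection")
}

#' Simulate a gene annotation tied to a panel's compartment structure
#'
#' Signature (differential) genes are placed inside bins that are A in
#' every cell type of the panel — mirroring the observation that the genes
#' whose transcription most distinguishes epithelial from mesenchymal cells
#' sit in constitutively active chromatin — while expression-flat filler
#' genes are spread uniformly, so compartment-switching bins carry only
#' flat genes. Each gene lies entirely within one bin.
#'
#' @param panel A [simulate_panel()] result.
#' @param gene_sets A `GeneSetCollection` whose members become the
#'   differential genes.
#' @param config The panel's [simulation_config()]; `de_gene_fraction`
#'   fixes the total gene count as `n_signature / de_gene_fraction`.
#' @return Gene annotation data.frame (see [read_bed_genes()]) with
#'   attribute `de_status` naming each gene's set ("E", "M" or "flat").
#' @export
simulate_gene_annotation <- function(panel, gene_sets, config = panel$config) {
  set.seed(substream_seed(config$seed, "genes"))
  bins <- panel$bins
  const_a <- which(rowSums(panel$states == "A") == ncol(panel$states) &
                     panel$partition == "free")
  if (length(const_a) == 0L) stop("no constitutive-A bins to place genes in")
  set_genes <- unlist(gene_sets, use.names = FALSE)
  set_label <- rep(names(gene_sets), lengths(gene_sets))
  n_total <- max(length(set_genes) + 1L,
                 round(length(set_genes) / max(config$de_gene_fraction, 1e-9)))
  n_flat <- n_total - length(set_genes)
  ids <- c(set_genes, sprintf("FLAT%05d", seq_len(n_flat)))
  status <- c(set_label, rep("flat", n_flat))
  bin_of <- c(sample(const_a, length(set_genes), replace = TRUE),
              sample(nrow(bins), n_flat, replace = TRUE))
  width <- bins$end - bins$start
  len <- pmax(1000, round(stats::runif(n_total) * width[bin_of] / 5))
  offset <- floor(stats::runif(n_total) * (width[bin_of] - len))
  genes <- data.frame(
    gene_id = ids, gene_name = ids,
    chrom = bins$chrom[bin_of],
    start = bins$start[bin_of] + offset,
    end = bins$start[bin_of] + offset + len,
    strand = sample(c("+", "-"), n_total, replace = TRUE),
    stringsAsFactors = FALSE
  )
  attr(genes, "de_status") <- status
  attr(genes, "bin_index") <- bin_of
  genes
}

#' Simulate an expression count table for a panel
#'
#' Baseline expression is log-normal per gene; epithelial-signature genes
#' decrease and mesenchymal-signature genes increase linearly (on the log2
#' scale, by `effect_size_log2` over the full gradient) with each cell
#' type's EMT parameter. Counts carry negative-binomial noise. Signature
#' genes missing from the annotation are skipped with a warning.
#'
#' @param panel A [simulate_panel()] result.
#' @param gene_annotation Gene annotation data.frame.
#' @param gene_sets `GeneSetCollection` with sets `E` and `M`.
#' @param config The panel's [simulation_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return Integer matrix genes x cell types with attribute `truth`
#'   (data.frame gene / de_status).
#' @export
simulate_expression <- function(panel, gene_annotation, gene_sets,
                                config = panel$config, seed = config$seed) {
  ids <- gene_annotation$gene_id
  e_set <- intersect(gene_sets$E, ids)
  m_set <- intersect(gene_sets$M, ids)
  missing <- setdiff(c(gene_sets$E, gene_sets$M), ids)
  if (length(missing) > 0L) {
    warning(sprintf("%d signature genes absent from annotation; skipped",
                    length(missing)))
  }
  if (length(ids) == 0L || (length(e_set) + length(m_set) == 0L &&
                            length(c(gene_sets$E, gene_sets$M)) > 0L &&
                            length(missing) == length(c(gene_sets$E, gene_sets$M)))) {
    stop("all genes skipped; annotation and gene sets are disjoint")
  }
  set.seed(substream_seed(seed, "expr_baseline"))
  base_log2 <- stats::rnorm(length(ids), config$baseline_log2_mean,
                            config$baseline_log2_sd)
  dir <- numeric(length(ids))
  dir[ids %in% m_set] <- 1
  dir[ids %in% e_set] <- -1
  samples <- panel$cell_types$name
  emt <- panel$cell_types$emt_parameter
  expr <- matrix(0L, nrow = length(ids), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    set.seed(substream_seed(seed, paste0("expr_", samples[j])))
    mu <- 2^(base_log2 + dir * config$effect_size_log2 * emt[j])
    expr[, j] <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  status <- rep("flat", length(ids))
  status[ids %in% e_set] <- "E"
  status[ids %in% m_set] <- "M"
  attr(expr, "truth") <- data.frame(gene = ids, de_status = status,
                                    stringsAsFactors = FALSE)
  expr
}

#' Truth-state compartment tracks for a panel
#'
#' Converts planted A/B states into oriented compartment tracks (+1 for A,
#' -1 for B), the idealized output of a perfect compartment caller. Useful
#' for isolating statistic error from caller noise.
#'
#' @param panel A [simulate_panel()] result.
#' @return Named list of oriented `CompartmentTrack`s, one per cell type.
#' @export
truth_tracks <- function(panel) {
  out <- lapply(colnames(panel$states), function(nm) {
    compartment_track(ifelse(panel$states[, nm] == "A", 1, -1), panel$bins,
                      oriented = TRUE, orientation_cor = 1)
  })
  names(out) <- colnames(panel$states)
  out
}

#' Truth-state A/B tracks for a panel
#' @param panel A [simulate_panel()] result.
#' @return Named list of per-bin "A"/"B" character vectors.
#' @export
truth_states <- function(panel) {
  out <- lapply(colnames(panel$states), function(nm) panel$states[, nm])
  names(out) <- colnames(panel$states)
  out
}
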