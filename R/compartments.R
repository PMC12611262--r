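#' Iterative correction (ICE) of a contact matrix
#'
#' Symmetric Sinkhorn-style balancing over unmasked bins: the matrix is
#' repeatedly divided by the outer product of its row marginals (normalized
#' to mean 1) until the coefficient of variation of the unmasked row sums
#' drops below `tol`. Before iterating, bins whose marginal falls below
#' `sparsity_fraction` of the median marginal are added to the mask. The
#' balanced matrix is rescaled to preserve the original total count over
#' unmasked bins.
#'
#' @param x A `ContactMatrix` (symmetric).
#' @param tol Convergence tolerance on the row-sum coefficient of
#'   variation.
#' @param max_iter Maximum number of iterations; non-convergence is
#'   reported with a warning and flagged in the result.
#' @param sparsity_fraction Bins with marginal below this fraction of the
#'   median unmasked marginal are masked before iteration.
#' @return List with `matrix` (balanced `ContactMatrix`, mask possibly
#'   enlarged), `bias` (per-bin accumulated correction factor, NA on masked
#'   bins), `converged`, `n_iter`.
#' @export
ice_normalize <- function(x, tol = 1e-6, max_iter = 200L,
                          sparsity_fraction = 0.1) {
  stopifnot(inherits(x, "ContactMatrix"))
  mask <- x$mask
  marg <- rowSums(x$counts)
  med <- stats::median(marg[!mask])
  mask <- mask | marg < sparsity_fraction * med
  keep <- which(!mask)
  if (length(keep) < 2L) stop("fewer than 2 unmasked bins; cannot balance")
  w <- x$counts[keep, keep, drop = FALSE]
  total0 <- sum(w)
  if (total0 <= 0) stop("all unmasked contacts are zero")
  bias <- rep(1, length(keep))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    s <- rowSums(w)
    cv <- stats::sd(s) / mean(s)
    if (is.finite(cv) && cv < tol) {
      converged <- TRUE
      iter <- iter - 1L
      break
    }
    b <- s / mean(s)
    b[b == 0] <- 1  # all-zero rows should have been masked; leave untouched
    w <- w / outer(b, b)
    bias <- bias * b
  }
  if (!converged) {
    s <- rowSums(w)
    if (is.finite(stats::sd(s) / mean(s)) && stats::sd(s) / mean(s) < tol) {
      converged <- TRUE
    } else {
      warning(sprintf("ICE did not converge within %d iterations", max_iter))
    }
  }
  w <- w * (total0 / sum(w))
  counts <- matrix(0, n_bins(x), n_bins(x))
  counts[keep, keep] <- w
  full_bias <- rep(NA_real_, n_bins(x))
  full_bias[keep] <- bias
  list(matrix = contact_matrix(counts, x$bins, mask = mask),
       bias = full_bias, converged = converged, n_iter = iter)
}

#' Scale a chromosome's contacts to a target total
#'
#' Multiplies every entry so the sum over the unmasked upper triangle
#' (diagonal included) equals `target_total` (1M by default, putting all
#' chromosomes on a common footing before eigenvector analysis).
#'
#' @param x A `ContactMatrix`.
#' @param target_total Desired total.
#' @return A rescaled `ContactMatrix`.
#' @export
scale_chromosome <- function(x, target_total = 1e6) {
  stopifnot(inherits(x, "ContactMatrix"))
  keep <- !x$mask
  sub <- x$counts[keep, keep, drop = FALSE]
  total <- sum(sub[upper.tri(sub, diag = TRUE)])
  if (total <= 0) stop("zero total over unmasked bins; cannot scale")
  contact_matrix(x$counts * (target_total / total), x$bins, mask = x$mask)
}

#' Observed-over-expected distance normalization
#'
#' Divides each entry by the mean contact value at its genomic distance
#' (mean over unmasked pairs at that |i-j|), flattening the distance decay
#' so compartment structure stands out. Distances whose mean is zero yield
#' NA; masked bins stay NA throughout.
#'
#' @param x A balanced `ContactMatrix`.
#' @return A `ContactMatrix`-shaped list whose `counts` hold O/E ratios
#'   (NA on masked rows/columns).
#' @export
observed_over_expected <- function(x) {
  stopifnot(inherits(x, "ContactMatrix"))
  keep <- which(!x$mask)
  sub <- x$counts[keep, keep, drop = FALSE]
  # genomic distance comes from bin ordinals, not storage order, so
  # permuting bin order permutes the output identically
  ord <- x$bins$ordinal[keep]
  d <- abs(outer(ord, ord, "-"))
  mean_by_d <- tapply(c(sub), c(d), mean)
  expected <- matrix(mean_by_d[as.character(c(d))], nrow = length(keep))
  oe_sub <- sub / expected
  oe_sub[!is.finite(oe_sub)] <- NA_real_
  oe <- matrix(NA_real_, n_bins(x), n_bins(x))
  oe[keep, keep] <- oe_sub
  out <- x
  out$counts <- oe
  dimnames(out$counts) <- list(bin_labels(x$bins), bin_labels(x$bins))
  out
}

#' Leading eigenvector of the compartment correlation matrix
#'
#' Computes the Pearson correlation matrix of the O/E columns over unmasked
#' bins and returns the requested principal component of that correlation
#' matrix (PC1 by default) as a unit-norm per-bin track. The sign is
#' arbitrary at this stage; see [orient_track()].
#'
#' @param x An O/E `ContactMatrix` (see [observed_over_expected()]).
#' @param pc Which principal component to return (1 by default).
#' @return An unoriented `CompartmentTrack` (NA on masked bins).
#' @export
compartment_eigenvector <- function(x, pc = 1L) {
  stopifnot(inherits(x, "ContactMatrix"))
  keep <- which(!x$mask)
  if (length(keep) < 10L) stop("fewer than 10 unmasked bins")
  sub <- x$counts[keep, keep, drop = FALSE]
  # undefined O/E entries (zero-mean distance diagonals) carry no signal;
  # treat them as the O/E null value 1 for the correlation step
  sub[is.na(sub)] <- 1
  v <- apply(sub, 2L, stats::var)
  if (any(v == 0)) {
    stop(sprintf("degenerate correlation: constant O/E column(s) at bin(s) %s",
                 paste(keep[v == 0], collapse = ", ")))
  }
  cc <- stats::cor(sub)
  p <- stats::prcomp(cc, center = TRUE, scale. = FALSE)
  if (pc > ncol(p$rotation)) stop("requested PC not available")
  ev <- p$rotation[, pc]
  ev <- ev / sqrt(sum(ev^2))
  values <- rep(NA_real_, n_bins(x))
  values[keep] <- ev
  compartment_track(values, x$bins, oriented = FALSE)
}

#' Orient a compartment track against a covariate
#'
#' Fixes the eigenvector's global sign so that its Pearson correlation with
#' an A-compartment covariate (typically gene density per bin) is
#' non-negative, matching the A-positive / B-negative convention.
#'
#' @param track An unoriented `CompartmentTrack`.
#' @param covariate Per-bin numeric covariate expected to be higher in the
#'   A compartment.
#' @return The oriented track, with the (non-negative) orientation
#'   correlation recorded; a correlation below 0.1 in magnitude triggers an
#'   ambiguous-orientation warning.
#' @export
orient_track <- function(track, covariate) {
  stopifnot(inherits(track, "CompartmentTrack"))
  if (length(covariate) != length(track$values)) {
    stop("covariate length does not match track")
  }
  ok <- !is.na(track$values) & !is.na(covariate)
  if (sum(ok) < 10L) stop("covariate defined on fewer than 10 unmasked bins")
  r <- stats::cor(track$values[ok], covariate[ok])
  if (is.na(r)) stop("orientation correlation undefined (constant input)")
  values <- if (r < 0) -track$values else track$values
  if (abs(r) < 0.1) {
    warning(sprintf("ambiguous orientation: |correlation| = %.3f < 0.1",
                    abs(r)))
  }
  compartment_track(values, track$bins, oriented = TRUE,
                    orientation_cor = abs(r))
}

#' Discrete A/B compartment calls from an oriented track
#'
#' Positive values map to A, negative to B; masked bins and exact zeros
#' (sign undefined) map to NA.
#'
#' @param track An oriented `CompartmentTrack`.
#' @return Character per-bin vector of "A"/"B"/NA (a state track).
#' @export
call_states <- function(track) {
  stopifnot(inherits(track, "CompartmentTrack"))
  if (!isTRUE(track$oriented)) {
    stop("track must be oriented before calling states")
  }
  states <- rep(NA_character_, length(track$values))
  states[!is.na(track$values) & track$values > 0] <- "A"
  states[!is.na(track$values) & track$values < 0] <- "B"
  states
}

#' Per-bin gene density
#'
#' Number of annotated genes overlapping each bin (half-open interval
#' overlap); the default orientation covariate, gene-dense bins being
#' A-compartment-prone.
#'
#' @param bins Bin table.
#' @param genes Gene annotation data.frame (see [read_bed_genes()]).
#' @return Integer per-bin gene counts.
#' @export
gene_density <- function(bins, genes) {
  gr_bins <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start + 1, bins$end))
  gr_genes <- GenomicRanges::GRanges(genes$chrom,
                                     IRanges::IRanges(genes$start + 1, genes$end))
  GenomicRanges::countOverlaps(gr_bins, gr_genes)
}

#' Full per-chromosome compartment calling pipeline
#'
#' Runs iterative correction, scaling to a common total, O/E
#' normalization, eigenvector extraction, covariate orientation and
#' discrete A/B calling in sequence.
#'
#' @param x A raw `ContactMatrix` for one chromosome.
#' @param covariate Per-bin orientation covariate (e.g. [gene_density()]).
#' @param pc Principal component to use: an integer, or `"auto"` to pick,
#'   among the first 3, the one best correlated (absolutely) with the
#'   covariate.
#' @param target_total Scaling target (1M).
#' @param tol,max_iter ICE parameters.
#' @return List with `track` (oriented `CompartmentTrack`), `states`,
#'   `pc_used`, `ice` (the [ice_normalize()] result).
#' @export
call_compartments <- function(x, covariate, pc = 1L, target_total = 1e6,
                              tol = 1e-6, max_iter = 200L) {
  ice <- ice_normalize(x, tol = tol, max_iter = max_iter)
  oe <- observed_over_expected(scale_chromosome(ice$matrix, target_total))
  if (identical(pc, "auto")) {
    cand <- lapply(1:3, function(k) compartment_eigenvector(oe, pc = k))
    cors <- vapply(cand, function(tr) {
      ok <- !is.na(tr$values) & !is.na(covariate)
      abs(stats::cor(tr$values[ok], covariate[ok]))
    }, 0)
    pc_used <- which.max(cors)
    track <- cand[[pc_used]]
  } else {
    pc_used <- pc
    track <- compartment_eigenvector(oe, pc = pc)
  }
  track <- orient_track(track, covariate)
  list(track = track, states = call_states(track), pc_used = pc_used,
       ice = ice)
}
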