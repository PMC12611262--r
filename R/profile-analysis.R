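#' Assemble a multi-cell-type profile matrix
#'
#' Stacks per-cell-type compartment tracks (which must share one bin list,
#' typically genome-wide concatenations) into a cell-types x bins matrix,
#' dropping every bin that is NA in at least one cell type so downstream
#' clustering and PCA see a complete matrix.
#'
#' @param tracks Named list of `CompartmentTrack`s.
#' @return A `ProfileMatrix`: list with `values` (entities x features),
#'   `entity_names`, `feature_ids` (bin labels), `feature_bins` (the
#'   retained bin table), `feature_kind = "bin"`, `n_dropped`.
#' @export
assemble_profile <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L)
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("tracks must be a named list")
  }
  bins <- tracks[[1L]]$bins
  for (tr in tracks) {
    if (!same_bins(tr$bins, bins)) stop("tracks do not share the same bins")
  }
  values <- do.call(rbind, lapply(tracks, function(tr) tr$values))
  keep <- colSums(is.na(values)) == 0L
  if (length(tracks) < 3L) {
    warning("fewer than 3 cell types: clustering/PCA downstream will fail")
  }
  structure(list(
    values = values[, keep, drop = FALSE],
    entity_names = names(tracks),
    feature_ids = bin_labels(bins)[keep],
    feature_bins = bins[keep, , drop = FALSE],
    feature_kind = "bin",
    n_dropped = sum(!keep)
  ), class = "ProfileMatrix")
}

#' Expression profile matrix (cell types x genes)
#'
#' log2(count+1)-transforms a genes x samples count table, drops
#' zero-variance genes and returns samples as entities, mirroring
#' [assemble_profile()] for the transcriptome.
#'
#' @param expr Numeric genes x samples matrix.
#' @return A `ProfileMatrix` with `feature_kind = "gene"`.
#' @export
expression_profile <- function(expr) {
  stopifnot(is.matrix(expr))
  lg <- log2(expr + 1)
  v <- apply(lg, 1L, stats::var)
  keep <- v > 0
  structure(list(
    values = t(lg[keep, , drop = FALSE]),
    entity_names = colnames(expr),
    feature_ids = rownames(expr)[keep],
    feature_bins = NULL,
    feature_kind = "gene",
    n_dropped = sum(!keep)
  ), class = "ProfileMatrix")
}

#' @export
print.ProfileMatrix <- function(x, ...) {
  cat(sprintf("ProfileMatrix: %d entities x %d %s features (%d dropped)\n",
              nrow(x$values), ncol(x$values), x$feature_kind, x$n_dropped))
  invisible(x)
}

#' Pearson-correlation distance between entities
#'
#' Pairwise similarity is Pearson's r across features; distance is `1 - r`,
#' ranging over `[0, 2]` with 0 on the diagonal.
#'
#' @param profile A `ProfileMatrix`.
#' @return Symmetric entity x entity distance matrix.
#' @export
pearson_distance <- function(profile) {
  v <- profile$values
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance entity: %s",
                 paste(profile$entity_names[sds == 0], collapse = ", ")))
  }
  d <- 1 - stats::cor(t(v))
  d[d < 0] <- 0  # clip numerical noise below exact-correlation zero
  diag(d) <- 0
  dimnames(d) <- list(profile$entity_names, profile$entity_names)
  d
}

#' Ward-linkage hierarchical clustering on a precomputed distance matrix
#'
#' Agglomerative Ward clustering (ward.D2, i.e. Ward's criterion applied to
#' the supplied distances) of the entity distance matrix.
#'
#' @param distance Symmetric distance matrix, e.g. [pearson_distance()].
#' @return List with `merge`, `height`, `order`, `labels` and the
#'   underlying `hclust` object.
#' @export
ward_cluster <- function(distance) {
  if (any(is.na(distance)) || any(!is.finite(distance))) {
    stop("distance matrix contains NaN/NA")
  }
  hc <- stats::hclust(stats::as.dist(distance), method = "ward.D2")
  list(merge = hc$merge, height = hc$height, order = hc$order,
       labels = hc$labels, hclust = hc)
}

#' PCA of a profile matrix
#'
#' Feature-wise mean-centered PCA without unit-variance scaling
#' (compartment values share a common scale; scaling would inflate noisy
#' bins). Component signs are fixed deterministically: the largest-|value|
#' element of each loading vector is made positive.
#'
#' @param profile A `ProfileMatrix` with >= 3 entities.
#' @param n_components Number of components to keep (clipped with a
#'   warning to `min(n_entities - 1, n_features)`).
#' @return List with `scores` (entities x PCs), `loadings` (features x
#'   PCs), `explained_variance` (fractions), `center`.
#' @export
profile_pca <- function(profile, n_components = 2L) {
  v <- profile$values
  if (nrow(v) < 3L) stop("PCA needs at least 3 entities")
  max_pc <- min(nrow(v) - 1L, ncol(v))
  if (n_components > max_pc) {
    warning(sprintf("n_components clipped from %d to %d", n_components,
                    max_pc))
    n_components <- max_pc
  }
  p <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  loadings <- p$rotation[, k, drop = FALSE]
  scores <- p$x[, k, drop = FALSE]
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- profile$entity_names
  rownames(loadings) <- profile$feature_ids
  list(scores = scores, loadings = loadings,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[k],
       center = p$center)
}

#' Top positive and negative loading features of a component
#'
#' Selects the `k` most-positive and `k` most-negative loading features
#' (e.g. the 100 strongest bins at each extreme of compartment PC1), each
#' list sorted by |loading| descending, ties broken by feature ordinal.
#'
#' @param loadings Features x PCs loading matrix from [profile_pca()].
#' @param component Component index.
#' @param k Number of features per sign (default 100).
#' @return List with `positive_features`, `negative_features`,
#'   `component`, `k`.
#' @export
top_loading_bins <- function(loadings, component = 1L, k = 100L) {
  if (component > ncol(loadings)) stop("component not computed")
  l <- loadings[, component]
  ids <- rownames(loadings)
  if (is.null(ids)) ids <- as.character(seq_along(l))
  ord_pos <- order(-l, seq_along(l))
  pos <- ord_pos[l[ord_pos] > 0]
  ord_neg <- order(l, seq_along(l))
  neg <- ord_neg[l[ord_neg] < 0]
  if (length(pos) < k || length(neg) < k) {
    warning(sprintf("only %d positive / %d negative loadings available",
                    length(pos), length(neg)))
  }
  list(positive_features = ids[utils::head(pos, k)],
       negative_features = ids[utils::head(neg, k)],
       component = component, k = k)
}

#' Genes overlapping a set of selected bins
#'
#' Maps selected bin features (labels `chrom:start-end`) to the genes whose
#' intervals overlap them, using strand-agnostic half-open overlap; a gene
#' abutting a bin end (gene start == bin end) does not overlap. Results are
#' deduplicated and sorted.
#'
#' @param selection Character vector of bin labels (e.g.
#'   `positive_features` from [top_loading_bins()]).
#' @param annotation Gene annotation data.frame (see [read_bed_genes()]).
#' @param bins Bin table the labels refer to.
#' @return Sorted character vector of gene identifiers.
#' @export
bins_to_genes <- function(selection, annotation, bins) {
  idx <- match(selection, bin_labels(bins))
  if (anyNA(idx)) stop("selection contains labels not present in bins")
  b <- bins[idx, , drop = FALSE]
  gr_bins <- GenomicRanges::GRanges(b$chrom,
                                    IRanges::IRanges(b$start + 1, b$end))
  gr_genes <- GenomicRanges::GRanges(annotation$chrom,
                                     IRanges::IRanges(annotation$start + 1,
                                                      annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_bins)
  sort(unique(annotation$gene_id[S4Vectors::queryHits(hits)]))
}

#' Bins overlapped by a set of genes
#'
#' Reverse of [bins_to_genes()]: the unique bin labels whose intervals
#' overlap any of the named genes (half-open, strand-agnostic). Used to
#' place top expression-PC genes on the compartment bin grid.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param annotation Gene annotation data.frame.
#' @param bins Bin table.
#' @return Sorted character vector of bin labels.
#' @export
genes_to_bins <- function(gene_ids, annotation, bins) {
  g <- annotation[annotation$gene_id %in% gene_ids, , drop = FALSE]
  gr_genes <- GenomicRanges::GRanges(g$chrom,
                                     IRanges::IRanges(g$start + 1, g$end))
  gr_bins <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start + 1, bins$end))
  hits <- GenomicRanges::findOverlaps(gr_bins, gr_genes)
  sort(unique(bin_labels(bins)[S4Vectors::queryHits(hits)]))
}

#' Fraction of a reference feature set found in a query set
#'
#' `|reference intersect query| / |reference|`; the overlap statistic used
#' to compare top compartment-PC regions against organotropic switch
#' regions or expression-PC gene bins.
#'
#' @param reference Non-empty character vector (the denominator set).
#' @param query Character vector.
#' @return A number in `[0, 1]`.
#' @export
overlap_fraction <- function(reference, query) {
  reference <- unique(reference)
  if (length(reference) == 0L) stop("reference set is empty")
  length(intersect(reference, unique(query))) / length(reference)
}
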