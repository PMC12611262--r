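#' Single-sample gene-set enrichment score
#'
#' A Kolmogorov-Smirnov-style random-walk statistic: genes are ranked by
#' expression (descending, ties broken by gene identifier so the walk is
#' deterministic); a running sum gains `1/n` at each of the `n` set genes
#' and loses `1/(N-n)` at each of the other `N-n` genes. The score is the
#' maximum-magnitude deviation of the walk, signed: +1 when the set sits
#' entirely at the top of the ranking, -1 entirely at the bottom. Because
#' it depends only on ranks, the score is invariant under any strictly
#' monotone transform of the expression values.
#'
#' @param expression_sample Named numeric vector of per-gene expression for
#'   one sample.
#' @param gene_set Character vector of set members; members absent from
#'   `expression_sample` are ignored (at least one must be present, and the
#'   present set must not exhaust all genes).
#' @return Signed score in `[-1, 1]`.
#' @export
enrichment_score <- function(expression_sample, gene_set) {
  ids <- names(expression_sample)
  if (is.null(ids)) stop("expression_sample must be named by gene")
  present <- intersect(unique(gene_set), ids)
  n <- length(present)
  N <- length(expression_sample)
  if (n == 0L) stop("no gene-set member present among expressed genes")
  if (n == N) stop("gene set covers every expressed gene; score undefined")
  ord <- order(-expression_sample, ids)
  in_set <- ids[ord] %in% present
  step <- ifelse(in_set, 1 / n, -1 / (N - n))
  walk <- cumsum(step)
  walk[which.max(abs(walk))]
}

#' Epithelial/mesenchymal enrichment scores for a panel
#'
#' Applies [enrichment_score()] per sample to the epithelial (`E`) and
#' mesenchymal (`M`) signature sets and reports the combined EMT axis
#' `M_score - E_score` (more positive = more mesenchymal).
#'
#' @param expression Genes x samples numeric matrix.
#' @param sets A `GeneSetCollection` containing sets named `E` and `M`.
#' @return An `EMTScores` data.frame: `sample`, `E_score`, `M_score`,
#'   `combined`, with attribute `method = "enrichment"`.
#' @export
score_panel <- function(expression, sets) {
  stopifnot(is.matrix(expression))
  if (!all(c("E", "M") %in% names(sets))) {
    stop("gene set collection must contain sets named E and M")
  }
  scores <- vapply(seq_len(ncol(expression)), function(j) {
    v <- expression[, j]
    names(v) <- rownames(expression)
    c(E = enrichment_score(v, sets$E), M = enrichment_score(v, sets$M))
  }, c(E = 0, M = 0))
  out <- data.frame(sample = colnames(expression),
                    E_score = scores["E", ], M_score = scores["M", ],
                    combined = scores["M", ] - scores["E", ],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- "enrichment"
  out
}

#' Non-negative principal axes of a gene-set expression submatrix
#'
#' Finds axes of maximal projection variance subject to non-negative,
#' unit-norm gene loadings, by projected power iteration on the
#' gene-centered log2(count+1) submatrix: multiply by the covariance, clip
#' negative loadings to zero, renormalize, until the update falls below
#' `tol`. Later axes are computed after Hotelling deflation of the fitted
#' axis; projections are taken against the original centered data.
#' Initialization is deterministic (leading standard principal axis,
#' clipped to its dominant sign).
#'
#' @param expression Genes x samples count matrix.
#' @param gene_set Genes to restrict to (members absent from the matrix are
#'   ignored).
#' @param n_axes Number of axes (default 1).
#' @param tol Convergence tolerance on the loading update.
#' @param max_iter Iteration cap per axis.
#' @return A `NonNegativeAxes`: list with `loadings` (genes x axes, >= 0,
#'   unit columns), `projections` (samples x axes), `axis_variance`,
#'   `cosines` (upper-triangle |cosine| between axes), `n_axes`.
#' @export
nnpca_axes <- function(expression, gene_set, n_axes = 1L, tol = 1e-8,
                       max_iter = 500L) {
  present <- intersect(unique(gene_set), rownames(expression))
  if (length(present) < 2L) stop("fewer than 2 gene-set members expressed")
  g <- log2(expression[present, , drop = FALSE] + 1)
  g <- g - rowMeans(g)
  g0 <- g
  p <- nrow(g)
  loadings <- matrix(0, p, n_axes, dimnames = list(present, NULL))
  for (ax in seq_len(n_axes)) {
    sv <- svd(g, nu = 1L, nv = 0L)
    w <- sv$u[, 1L]
    if (sum(pmax(w, 0)) < sum(pmax(-w, 0))) w <- -w
    w <- pmax(w, 0)
    if (sum(w) == 0) stop(sprintf("axis %d collapsed; try fewer axes", ax))
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      w_new <- g %*% (crossprod(g, w))
      w_new <- pmax(as.vector(w_new), 0)
      nrm <- sqrt(sum(w_new^2))
      if (nrm == 0) stop(sprintf("axis %d collapsed; try fewer axes", ax))
      w_new <- w_new / nrm
      if (sqrt(sum((w_new - w)^2)) < tol) {
        w <- w_new
        break
      }
      w <- w_new
    }
    loadings[, ax] <- w
    g <- g - w %*% crossprod(w, g)  # Hotelling deflation
  }
  projections <- crossprod(g0, loadings)  # samples x axes
  rownames(projections) <- colnames(expression)
  cosines <- if (n_axes > 1L) {
    cc <- abs(crossprod(loadings))
    cc[upper.tri(cc)]
  } else {
    numeric(0)
  }
  structure(list(loadings = loadings, projections = projections,
                 axis_variance = apply(projections, 2L, stats::var),
                 cosines = cosines, n_axes = n_axes),
            class = "NonNegativeAxes")
}

#' Epithelial/mesenchymal scores by non-negative PCA
#'
#' The E score of a sample is its projection on the first non-negative
#' axis of the epithelial-set submatrix (gene-centered log2 counts); the M
#' score likewise for the mesenchymal set; `combined = M_score - E_score`.
#' Because loadings are non-negative, each score rises with the overall
#' expression of its signature.
#'
#' @param expression Genes x samples count matrix.
#' @param sets A `GeneSetCollection` with sets `E` and `M`.
#' @return An `EMTScores` data.frame with attribute `method = "nnpca"`.
#' @export
nnpca_scores <- function(expression, sets) {
  if (!all(c("E", "M") %in% names(sets))) {
    stop("gene set collection must contain sets named E and M")
  }
  e_ax <- nnpca_axes(expression, sets$E, n_axes = 1L)
  m_ax <- nnpca_axes(expression, sets$M, n_axes = 1L)
  out <- data.frame(sample = colnames(expression),
                    E_score = e_ax$projections[, 1L],
                    M_score = m_ax$projections[, 1L],
                    combined = m_ax$projections[, 1L] - e_ax$projections[, 1L],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- "nnpca"
  out
}
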