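#' Construct a ContactMatrix
#'
#' A `ContactMatrix` holds a symmetric, non-negative, per-chromosome (or
#' concatenated) binned Hi-C contact map together with its bin coordinates
#' and a per-bin mask. Masked bins (typically unmappable or ultra-sparse
#' regions) are retained in the matrix so bin coordinates stay genome-wide,
#' but every downstream operation ignores them.
#'
#' @param counts Square numeric matrix of non-negative contact values.
#' @param bins Bin table (see [make_bins()]) with one row per matrix row.
#' @param mask Logical per-bin vector, `TRUE` = excluded. Defaults to
#'   flagging all-zero rows/columns.
#' @return An object of class `ContactMatrix`: a list with elements
#'   `counts`, `bins`, `mask`.
#' @export
contact_matrix <- function(counts, bins, mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("contact matrix must be square")
  if (nrow(counts) != nrow(bins)) stop("bins do not match matrix dimension")
  if (any(counts < 0)) stop("negative contact values")
  if (is.null(mask)) {
    mask <- rowSums(counts) == 0 & colSums(counts) == 0
  }
  stopifnot(is.logical(mask), length(mask) == nrow(counts))
  dimnames(counts) <- list(bin_labels(bins), bin_labels(bins))
  structure(list(counts = counts, bins = bins, mask = mask),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bins (%d masked), %s, total %.4g\n",
              n_bins(x), sum(x$mask),
              paste(unique(x$bins$chrom), collapse = ","),
              sum(x$counts)))
  invisible(x)
}

#' Number of bins of a ContactMatrix
#' @param x A `ContactMatrix`.
#' @export
n_bins <- function(x) nrow(x$counts)

# Check symmetry within a relative tolerance; average the two triangles if
# acceptable, otherwise report the worst cell.
symmetrize <- function(counts, rel_tol = 1e-6, context = "matrix") {
  d <- abs(counts - t(counts))
  scale <- max(abs(counts), 1e-300)
  worst <- max(d)
  if (worst > rel_tol * scale) {
    ij <- which(d == worst, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s asymmetric beyond tolerance: cells [%d,%d]/[%d,%d] differ by %g",
      context, ij[1L], ij[2L], ij[2L], ij[1L], worst))
  }
  (counts + t(counts)) / 2
}

#' Construct a compartment track
#'
#' Per-bin signed eigenvector values; positive = A (euchromatic), negative =
#' B (heterochromatic) once the track is oriented. Masked bins carry `NA`.
#'
#' @param values Numeric per-bin values (NA allowed).
#' @param bins Bin table.
#' @param oriented Whether the global sign has been fixed against a
#'   covariate (see [orient_track()]).
#' @param orientation_cor Correlation with the orientation covariate,
#'   recorded by [orient_track()].
#' @return An object of class `CompartmentTrack`.
#' @export
compartment_track <- function(values, bins, oriented = FALSE,
                              orientation_cor = NA_real_) {
  stopifnot(length(values) == nrow(bins))
  if (any(!is.finite(values) & !is.na(values))) {
    stop("compartment track values must be finite or NA")
  }
  structure(list(values = as.numeric(values), bins = bins,
                 oriented = oriented, orientation_cor = orientation_cor),
            class = "CompartmentTrack")
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  cat(sprintf("CompartmentTrack: %d bins (%d NA), %soriented\n",
              length(x$values), sum(is.na(x$values)),
              if (x$oriented) "" else "un"))
  invisible(x)
}
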