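#' @name io_formats
#' @title On-disk formats used by the pipeline
#' @description
#' The pipeline exchanges data through plain-text formats: dense
#' tab-delimited contact matrices with `chrom:start-end` headers on the
#' first row and column (the per-chromosome interchange format at 250 kb
#' resolution), bedGraph for compartment tracks, BED6 for gene annotations,
#' GMT for gene sets, and TSV (genes x samples) for expression tables.
#' Readers validate strictly and writers serialize numbers at 6 significant
#' digits so that write/read round trips are reproducible byte for byte.
NULL

fmt6g <- function(x) {
  out <- sprintf("%.6g", x)
  out[out == "-0"] <- "0"
  out
}

#' Read a dense contact matrix
#'
#' Reads a tab-delimited square matrix whose first row and first column
#' carry `chrom:start-end` bin headers. The body must be numeric and
#' non-negative; row and column headers must agree. Mild numerical
#' asymmetry (at most 1e-6 of the largest entry) is repaired by averaging
#' the two triangles; anything larger is treated as a corrupt file.
#'
#' @param path Path to the matrix file.
#' @param expected_bin_size If non-NULL, bin widths are checked against it
#'   (last bin of a chromosome may be shorter).
#' @return A [contact_matrix()]; all-zero bins are flagged in the mask.
#' @export
read_dense_matrix <- function(path, expected_bin_size = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("dense matrix file too short")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  # allow an optional empty corner cell before the column headers
  if (header[1L] == "") header <- header[-1L]
  n <- length(header)
  if (length(fields) != n + 1L) {
    stop(sprintf("dense matrix not square: %d column headers, %d data rows",
                 n, length(fields) - 1L))
  }
  row_names <- vapply(fields[-1L], `[`, "", 1L)
  if (!identical(row_names, header)) {
    stop("row and column bin headers disagree")
  }
  body <- vapply(fields[-1L], function(f) {
    if (length(f) != n + 1L) stop("dense matrix row with wrong field count")
    as.numeric(f[-1L])
  }, numeric(n))
  counts <- t(body)
  if (any(is.na(counts))) stop("non-numeric value in dense matrix body")
  if (any(counts < 0)) stop("negative value in dense matrix body")
  bins <- parse_bin_labels(header)
  validate_bins(bins, expected_bin_size)
  counts <- symmetrize(counts, context = basename(path))
  contact_matrix(counts, bins)
}

#' Write a dense contact matrix
#'
#' Inverse of [read_dense_matrix()]; numbers are serialized at 6
#' significant digits, so `write(read(write(m)))` is byte-identical.
#'
#' @param x A `ContactMatrix`.
#' @param path Output path.
#' @export
write_dense_matrix <- function(x, path) {
  labs <- bin_labels(x$bins)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("", labs), collapse = "\t"), con)
  body <- matrix(fmt6g(x$counts), nrow = n_bins(x))
  writeLines(paste(labs, apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a bedGraph compartment track
#'
#' Intervals must coincide exactly with bins of `bins`; bins absent from
#' the file become `NA`. Duplicate intervals for the same bin are rejected.
#'
#' @param path Path to a 4-column bedGraph file.
#' @param bins Bin table defining the expected intervals.
#' @return A [compartment_track()] (unoriented).
#' @export
read_bedgraph_track <- function(path, bins) {
  values <- rep(NA_real_, nrow(bins))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(compartment_track(values, bins))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) != 4L)) {
    stop("bedGraph line without exactly 4 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- as.numeric(vapply(fields, `[`, "", 2L))
  end <- as.numeric(vapply(fields, `[`, "", 3L))
  val <- as.numeric(vapply(fields, `[`, "", 4L))
  if (any(is.na(start)) || any(is.na(end)) || any(is.na(val))) {
    stop("non-numeric field in bedGraph")
  }
  key <- paste(chrom, start, end)
  bin_key <- paste(bins$chrom, bins$start, bins$end)
  idx <- match(key, bin_key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("bedGraph interval %s:%g-%g does not align to any bin",
                 chrom[bad], start[bad], end[bad]))
  }
  if (anyDuplicated(idx)) {
    stop("overlapping/duplicate bedGraph intervals for the same bin")
  }
  values[idx] <- val
  compartment_track(values, bins)
}

#' Write a compartment track as bedGraph
#'
#' `NA` bins are omitted; values are written with 6 decimal places.
#'
#' @param track A `CompartmentTrack`.
#' @param path Output path.
#' @export
write_bedgraph_track <- function(track, path) {
  keep <- !is.na(track$values)
  b <- track$bins[keep, , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (any(keep)) {
    writeLines(sprintf("%s\t%.0f\t%.0f\t%.6f", b$chrom, b$start, b$end,
                       track$values[keep]), con)
  }
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' Standard GMT: one set per line, tab-delimited `name`, `description`,
#' then members. Member order is preserved.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (class `GeneSetCollection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1L]))
  }
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene set name '%s'", nm[duplicated(nm)][1L]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  for (i in seq_along(sets)) {
    dup <- sets[[i]][duplicated(sets[[i]])]
    if (length(dup) > 0L) {
      stop(sprintf("gene '%s' repeated in set '%s'", dup[1L], nm[i]))
    }
    if (length(sets[[i]]) == 0L) stop(sprintf("empty gene set '%s'", nm[i]))
  }
  names(sets) <- nm
  structure(sets, class = "GeneSetCollection")
}

#' Write a GMT gene set collection
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column (defaults to the
#'   set name).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, ""), con)
  invisible(path)
}

#' Read a BED6 gene annotation
#'
#' BED convention: 0-based half-open coordinates; the name column carries
#' the gene identifier (also used as gene name).
#'
#' @param path Path to a BED6 file.
#' @return data.frame with columns `gene_id`, `gene_name`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
read_bed_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, 1L) < 6L)) {
    stop("BED6 line with fewer than 6 fields")
  }
  out <- data.frame(
    gene_id = vapply(fields, `[`, "", 4L),
    gene_name = vapply(fields, `[`, "", 4L),
    chrom = vapply(fields, `[`, "", 1L),
    start = as.numeric(vapply(fields, `[`, "", 2L)),
    end = as.numeric(vapply(fields, `[`, "", 3L)),
    strand = vapply(fields, `[`, "", 6L),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    stop("non-numeric coordinate in BED file")
  }
  if (any(out$end <= out$start)) stop("gene with end <= start")
  if (any(!out$strand %in% c("+", "-"))) stop("strand must be + or -")
  out
}

#' Write genes as BED6
#' @param genes Gene annotation data.frame (see [read_bed_genes()]).
#' @param path Output path.
#' @export
write_bed_genes <- function(genes, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t0\t%s", genes$chrom, genes$start,
                     genes$end, genes$gene_id, genes$strand), con)
  invisible(path)
}

#' Read an expression table (genes x samples TSV)
#'
#' First column holds gene identifiers, remaining columns one sample each.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >= 1 sample column")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicate gene identifier in expression table")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- ids
  m
}

#' Write an expression table as TSV
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @export
write_expression_tsv <- function(expr, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  writeLines(paste(rownames(expr),
                   apply(matrix(fmt6g(expr), nrow = nrow(expr)), 1L,
                         paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}
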