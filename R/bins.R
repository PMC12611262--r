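#' Build a per-chromosome bin table
#'
#' Bins are 0-based half-open `[start, end)` intervals of constant width
#' (`bin_size`), except possibly the last bin of a chromosome, which is
#' truncated at `chrom_length`. The `ordinal` column is the 1-based position
#' of the bin within its chromosome.
#'
#' @param chrom Chromosome name.
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp (default 250 kb, the working resolution
#'   of the compartment pipeline).
#' @param chrom_length Optional chromosome length in bp; the last bin is
#'   clipped to it.
#' @return A data.frame with columns `chrom`, `start`, `end`, `ordinal`.
#' @export
make_bins <- function(chrom, n_bins, bin_size = 250000L, chrom_length = NULL) {
  stopifnot(length(chrom) == 1L, n_bins >= 1L, bin_size >= 1L)
  start <- as.numeric(bin_size) * (seq_len(n_bins) - 1)
  end <- start + bin_size
  if (!is.null(chrom_length)) {
    if (chrom_length <= start[n_bins]) {
      stop("chrom_length smaller than the start of the last bin")
    }
    end[n_bins] <- min(end[n_bins], chrom_length)
  }
  data.frame(
    chrom = rep(as.character(chrom), n_bins),
    start = start, end = end, ordinal = seq_len(n_bins),
    stringsAsFactors = FALSE
  )
}

#' Concatenate per-chromosome bin tables genome-wide
#'
#' @param ... Bin tables as produced by [make_bins()], or a single list of
#'   them.
#' @return A single bin table; ordinals restart within each chromosome.
#' @export
bind_bins <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) && !is.data.frame(parts[[1L]])) {
    parts <- parts[[1L]]
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Format bins as `chrom:start-end` labels
#' @param bins A bin table.
#' @return Character vector of labels.
#' @export
bin_labels <- function(bins) {
  sprintf("%s:%.0f-%.0f", bins$chrom, bins$start, bins$end)
}

# Parse "chrom:start-end" labels back into a bin table; used by the dense
# matrix reader. Coordinates must be non-negative integers with start < end.
parse_bin_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+):([0-9]+)-([0-9]+)$", labels))
  bad <- which(vapply(m, length, 1L) != 4L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed bin header '%s'", labels[bad[1L]]))
  }
  chrom <- vapply(m, `[`, "", 2L)
  start <- as.numeric(vapply(m, `[`, "", 3L))
  end <- as.numeric(vapply(m, `[`, "", 4L))
  if (any(end <= start)) stop("bin header with end <= start")
  bins <- data.frame(
    chrom = chrom, start = start, end = end,
    ordinal = stats::ave(seq_along(chrom), chrom, FUN = seq_along),
    stringsAsFactors = FALSE
  )
  bins
}

validate_bins <- function(bins, expected_bin_size = NULL) {
  stopifnot(is.data.frame(bins),
            all(c("chrom", "start", "end", "ordinal") %in% names(bins)))
  if (any(bins$end <= bins$start)) stop("bin with end <= start")
  if (!is.null(expected_bin_size)) {
    for (ch in unique(bins$chrom)) {
      b <- bins[bins$chrom == ch, , drop = FALSE]
      w <- b$end - b$start
      n <- nrow(b)
      if (n > 1L && any(w[-n] != expected_bin_size)) {
        stop(sprintf("bin width differs from expected %d on %s",
                     expected_bin_size, ch))
      }
      if (w[n] > expected_bin_size) {
        stop(sprintf("last bin of %s wider than expected bin size", ch))
      }
      if (any(diff(b$ordinal) != 1L) || b$ordinal[1L] != 1L) {
        stop(sprintf("bin ordinals not consecutive on %s", ch))
      }
      if (n > 1L && any(b$start[-1L] != b$end[-n])) {
        stop(sprintf("bins not contiguous on %s", ch))
      }
    }
  }
  invisible(bins)
}

same_bins <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(a$chrom == b$chrom) && all(a$start == b$start) && all(a$end == b$end)
}
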