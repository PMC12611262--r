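#' Simulate Hi-C and call compartments for panel cell types
#'
#' For each requested cell type, simulates one contact matrix per synthetic
#' chromosome from the planted states, runs the full compartment caller
#' ([call_compartments()]) per chromosome, and concatenates the results
#' genome-wide. The orientation covariate is the planted-truth gene-density
#' proxy: the indicator of bins that are A in every cell type of the panel
#' (the generator concentrates genes in constitutively active chromatin, and
#' gene density is a property of the genome, not of the cell type, so one
#' covariate serves every track).
#'
#' @param panel A [simulate_panel()] result.
#' @param cell_types Character vector of cell type names (default: all).
#' @param seed Seed for the contact-matrix noise (defaults to the panel
#'   config seed); each (cell type, chromosome) gets its own substream.
#' @param pc Principal component policy passed to [call_compartments()].
#' @return List with `tracks` (named list of oriented genome-wide
#'   `CompartmentTrack`s) and `states` (named list of called A/B state
#'   vectors).
#' @export
panel_called_tracks <- function(panel, cell_types = colnames(panel$states),
                                seed = panel$config$seed, pc = 1L) {
  stopifnot(inherits(panel, "CellTypePanel"))
  bad <- setdiff(cell_types, colnames(panel$states))
  if (length(bad) > 0L) {
    stop(sprintf("unknown cell type(s): %s", paste(bad, collapse = ", ")))
  }
  covariate_all <- as.numeric(rowSums(panel$states == "A") ==
                                ncol(panel$states))
  chroms <- unique(panel$bins$chrom)
  tracks <- lapply(cell_types, function(ct) {
    values <- rep(NA_real_, nrow(panel$bins))
    for (ch in chroms) {
      sel <- which(panel$bins$chrom == ch)
      b <- panel$bins[sel, , drop = FALSE]
      b$ordinal <- seq_along(sel)
      m <- simulate_contact_matrix(panel$states[sel, ct], panel$config,
                                   bins = b,
                                   seed = substream_seed(seed,
                                                         paste0(ct, "|", ch)))
      res <- call_compartments(m, covariate_all[sel], pc = pc)
      values[sel] <- res$track$values
    }
    compartment_track(values, panel$bins, oriented = TRUE)
  })
  names(tracks) <- cell_types
  list(tracks = tracks,
       states = lapply(tracks, call_states))
}
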