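#' @name organotropism_statistic
#' @title Organ-permissive compartment-switch statistic
#' @description
#' Each genomic bin is labelled by a pair state per organ system — the
#' normal-cell compartment followed by the cancer-cell compartment (AA, AB,
#' BA or BB) — and the primary and secondary organ pair states are crossed
#' into one of 16 categories such as `AB_BB`. Two categories are
#' organ-permissive: `AB_BB` (primary cancer switches A to B where the
#' secondary organ is constitutively B) and `BA_AA` (B to A where the
#' secondary organ is constitutively A); in both, the primary cancer
#' abandons its tissue-of-origin state for the state held by the target
#' organ. The permissive fraction asks how much of the primary cancer's
#' compartment remodelling points at the target organ, and a
#' conditional-probability adjustment removes the bias introduced by
#' differing compartment stability of different secondary organs' cancers.
NULL

PAIR_LEVELS <- c("AA", "AB", "BA", "BB")
CROSS_LEVELS <- as.vector(outer(PAIR_LEVELS, PAIR_LEVELS,
                                function(a, b) paste(a, b, sep = "_")))

check_states <- function(x, what = "state track") {
  if (!is.character(x)) stop(sprintf("%s must be a character vector", what))
  if (any(!x %in% c("A", "B") & !is.na(x))) {
    stop(sprintf("%s may only contain A, B or NA", what))
  }
  x
}

#' Per-bin normal-vs-cancer pair states
#'
#' Concatenates the normal and cancer compartment letters per bin (first
#' letter = normal, second = cancer); any NA input propagates.
#'
#' @param normal,cancer Per-bin "A"/"B"/NA state tracks of equal length.
#' @return Character vector over `AA`/`AB`/`BA`/`BB`/NA.
#' @export
pair_states <- function(normal, cancer) {
  check_states(normal, "normal")
  check_states(cancer, "cancer")
  if (length(normal) != length(cancer)) stop("state tracks differ in length")
  out <- paste0(normal, cancer)
  out[is.na(normal) | is.na(cancer)] <- NA_character_
  out
}

#' Consensus pair states across a group of cancer lines
#'
#' A bin keeps its pair state only if every cancer line of the group gives
#' the identical, non-NA pair state against the common normal; otherwise
#' the bin is NA. With a single cancer line this reduces to
#' [pair_states()]. A looser majority rule is available.
#'
#' @param normal Per-bin normal state track.
#' @param cancers Non-empty list of cancer state tracks.
#' @param rule `"unanimous"` (default) or `"majority"` (strict majority of
#'   non-NA pair states, NA if no strict majority or any line is NA).
#' @return Character pair-state vector.
#' @export
consensus_pair_states <- function(normal, cancers, rule = c("unanimous", "majority")) {
  rule <- match.arg(rule)
  if (!is.list(cancers) || length(cancers) == 0L) {
    stop("cancers must be a non-empty list of state tracks")
  }
  pairs <- vapply(cancers, function(cc) pair_states(normal, cc),
                  character(length(normal)))
  pairs <- matrix(pairs, nrow = length(normal))
  apply(pairs, 1L, function(p) {
    if (anyNA(p)) return(NA_character_)
    if (rule == "unanimous") {
      if (all(p == p[1L])) p[1L] else NA_character_
    } else {
      tab <- table(p)
      top <- names(tab)[which.max(tab)]
      if (tab[top] * 2L > length(p)) top else NA_character_
    }
  })
}

#' Cross-organ compartment-change categories
#'
#' Combines the primary-organ and secondary-organ pair states per bin into
#' one of the 16 `XY_ZW` categories; NA propagates.
#'
#' @param primary_pairs,secondary_pairs Pair-state vectors of equal length.
#' @return Character vector over the 16 cross labels / NA.
#' @export
cross_states <- function(primary_pairs, secondary_pairs) {
  if (length(primary_pairs) != length(secondary_pairs)) {
    stop("pair-state tracks differ in length")
  }
  out <- paste(primary_pairs, secondary_pairs, sep = "_")
  out[is.na(primary_pairs) | is.na(secondary_pairs)] <- NA_character_
  out
}

#' Summarize permissive compartment changes
#'
#' Tabulates the 16 cross categories and computes the permissive fraction:
#' the share of primary-organ compartment alterations (primary pair AB or
#' BA) that are organ-permissive (`AB_BB` or `BA_AA` by default).
#' Per-category percentages of informative (non-NA) bins are reported too;
#' these feed the cross-organ adjustment.
#'
#' @param cross Cross-state vector from [cross_states()].
#' @param permissive_labels The categories counted as permissive;
#'   substituting `c("AB_AB", "BA_BA")` yields the cancer-shared fraction
#'   instead.
#' @param denominator `"primary-changed"` (default: bins whose primary pair
#'   is AB or BA) or `"informative"` (all non-NA bins).
#' @return A `PermissiveSummary`: list with `category_counts` (all 16),
#'   `n_informative_bins`, `permissive_fraction`, `percent` (per-category
#'   percentages of informative bins), `percent_of_changed`,
#'   `permissive_labels`, `denominator`.
#' @export
permissive_summary <- function(cross,
                               permissive_labels = c("AB_BB", "BA_AA"),
                               denominator = c("primary-changed", "informative")) {
  denominator <- match.arg(denominator)
  ok <- !is.na(cross)
  if (any(!cross[ok] %in% CROSS_LEVELS)) stop("invalid cross-state label")
  counts <- table(factor(cross[ok], levels = CROSS_LEVELS))
  counts <- stats::setNames(as.integer(counts), CROSS_LEVELS)
  n_inf <- sum(ok)
  primary_of <- substr(CROSS_LEVELS, 1L, 2L)
  changed <- counts[primary_of %in% c("AB", "BA")]
  denom <- if (denominator == "primary-changed") sum(changed) else n_inf
  if (denom == 0L) {
    stop("no-changes: zero bins in the permissive-fraction denominator")
  }
  frac <- sum(counts[permissive_labels]) / denom
  structure(list(
    category_counts = counts,
    n_informative_bins = n_inf,
    permissive_fraction = frac,
    percent = 100 * counts / max(n_inf, 1L),
    percent_of_changed = if (sum(changed) > 0L) {
      100 * counts / sum(changed)
    } else {
      counts * NA_real_
    },
    permissive_labels = permissive_labels,
    denominator = denominator
  ), class = "PermissiveSummary")
}

#' @export
print.PermissiveSummary <- function(x, ...) {
  cat(sprintf("PermissiveSummary: %d informative bins, permissive fraction %.4f (%s of %s)\n",
              x$n_informative_bins, x$permissive_fraction,
              paste(x$permissive_labels, collapse = "+"), x$denominator))
  nz <- x$category_counts[x$category_counts > 0]
  if (length(nz)) print(nz)
  if (!is.null(x$adjusted_BA_AA_percent)) {
    cat(sprintf("adjusted: BA_AA %.4f%%, AB_BB %.4f%%\n",
                x$adjusted_BA_AA_percent, x$adjusted_AB_BB_percent))
  }
  invisible(x)
}

#' Compartment stability probabilities of a secondary organ
#'
#' For each secondary-organ localized cancer line, the probability that a
#' bin in compartment A (resp. B) in that organ's normal cells is still A
#' (resp. B) in the cancer line: p(TA|NA) and p(TB|NB). The reported values
#' are the minima over cell lines; per-line values and denominators are
#' retained.
#'
#' @param secondary_normal Normal-cell state track of the secondary organ.
#' @param secondary_cancers Non-empty list of that organ's localized cancer
#'   state tracks.
#' @return A `StabilityProbabilities`: list with `p_TA_given_NA`,
#'   `p_TB_given_NB` (minima), `per_line` (data.frame) and denominators.
#' @export
stability_probabilities <- function(secondary_normal, secondary_cancers) {
  check_states(secondary_normal, "secondary_normal")
  if (!is.list(secondary_cancers) || length(secondary_cancers) == 0L) {
    stop("secondary_cancers must be a non-empty list")
  }
  per <- lapply(secondary_cancers, function(cc) {
    check_states(cc, "secondary cancer")
    if (length(cc) != length(secondary_normal)) {
      stop("cancer track length differs from normal")
    }
    ok <- !is.na(secondary_normal) & !is.na(cc)
    nA <- sum(ok & secondary_normal == "A")
    nB <- sum(ok & secondary_normal == "B")
    if (nA == 0L) stop("denominator 0 for compartment A (no normal-A bins)")
    if (nB == 0L) stop("denominator 0 for compartment B (no normal-B bins)")
    c(p_TA = sum(ok & secondary_normal == "A" & cc == "A") / nA,
      p_TB = sum(ok & secondary_normal == "B" & cc == "B") / nB,
      n_A = nA, n_B = nB)
  })
  per <- as.data.frame(do.call(rbind, per))
  if (!is.null(names(secondary_cancers))) {
    rownames(per) <- names(secondary_cancers)
  }
  structure(list(
    p_TA_given_NA = min(per$p_TA),
    p_TB_given_NB = min(per$p_TB),
    per_line = per,
    n_normal_A = per$n_A[1L],
    n_normal_B = per$n_B[1L]
  ), class = "StabilityProbabilities")
}

#' Adjust permissive percentages for secondary-organ compartment stability
#'
#' Applies the cross-organ bias correction: the stability probabilities are
#' subtracted from one and multiplied with the corresponding organ-specific
#' permissive percentages — `(1 - p(TA|NA))` with the `BA_AA` percentage
#' and `(1 - p(TB|NB))` with the `AB_BB` percentage. A sensitivity flag can
#' swap to weighting by `p` itself.
#'
#' @param summary A `PermissiveSummary`.
#' @param probs A `StabilityProbabilities`.
#' @param percent_basis `"informative"` (default: per-category percentages
#'   of informative bins) or `"primary-changed"`.
#' @param weighting `"one-minus-p"` (default, the published form) or `"p"`.
#' @return The summary with `adjusted_BA_AA_percent`,
#'   `adjusted_AB_BB_percent`, `stability` filled in.
#' @export
adjusted_permissive <- function(summary, probs,
                                percent_basis = c("informative", "primary-changed"),
                                weighting = c("one-minus-p", "p")) {
  stopifnot(inherits(summary, "PermissiveSummary"),
            inherits(probs, "StabilityProbabilities"))
  percent_basis <- match.arg(percent_basis)
  weighting <- match.arg(weighting)
  pct <- if (percent_basis == "informative") {
    summary$percent
  } else {
    summary$percent_of_changed
  }
  wA <- if (weighting == "one-minus-p") 1 - probs$p_TA_given_NA else probs$p_TA_given_NA
  wB <- if (weighting == "one-minus-p") 1 - probs$p_TB_given_NB else probs$p_TB_given_NB
  summary$adjusted_BA_AA_percent <- wA * pct[["BA_AA"]]
  summary$adjusted_AB_BB_percent <- wB * pct[["AB_BB"]]
  summary$stability <- probs
  summary$percent_basis <- percent_basis
  summary$weighting <- weighting
  summary
}

#' Compare permissive changes across candidate target organs
#'
#' Runs the full classification chain — consensus pair states, cross
#' categories, permissive summary, stability probabilities, adjustment —
#' once per candidate organ, on the common set of bins informative in
#' every track involved, so the per-organ numbers share one denominator
#' basis.
#'
#' @param primary_normal Primary-organ normal state track.
#' @param primary_cancers Non-empty named list of primary cancer state
#'   tracks (one consensus group).
#' @param organ_panels Named list (>= 2 organs) of lists with elements
#'   `normal` (state track) and `cancers` (list of state tracks).
#' @param ... Passed to [permissive_summary()] / [adjusted_permissive()]
#'   (`denominator`, `percent_basis`, `weighting`).
#' @return List with `table` (one row per organ: permissive fraction, raw
#'   and adjusted percentages, stability probabilities), `summaries`
#'   (per-organ `PermissiveSummary`), `common_bins` (logical per bin).
#' @export
compare_target_organs <- function(primary_normal, primary_cancers,
                                  organ_panels, ...) {
  if (length(organ_panels) < 2L) stop("need >= 2 organ panels to compare")
  all_tracks <- c(list(primary_normal), primary_cancers,
                  unlist(lapply(organ_panels, function(p) {
                    c(list(p$normal), p$cancers)
                  }), recursive = FALSE))
  common <- Reduce(`&`, lapply(all_tracks, function(tr) !is.na(tr)))
  if (!any(common)) stop("empty common bin set across organ panels")
  sub <- function(tr) tr[common]
  p_pairs <- consensus_pair_states(sub(primary_normal),
                                   lapply(primary_cancers, sub))
  summaries <- lapply(names(organ_panels), function(org) {
    panel <- organ_panels[[org]]
    s_pairs <- consensus_pair_states(sub(panel$normal),
                                     lapply(panel$cancers, sub))
    cross <- cross_states(p_pairs, s_pairs)
    sm <- permissive_summary(cross, ...)
    probs <- stability_probabilities(sub(panel$normal),
                                     lapply(panel$cancers, sub))
    adjusted_permissive(sm, probs)
  })
  names(summaries) <- names(organ_panels)
  tab <- do.call(rbind, lapply(names(summaries), function(org) {
    sm <- summaries[[org]]
    data.frame(
      organ = org,
      n_informative_bins = sm$n_informative_bins,
      permissive_fraction = sm$permissive_fraction,
      percent_BA_AA = sm$percent[["BA_AA"]],
      percent_AB_BB = sm$percent[["AB_BB"]],
      p_TA_given_NA = sm$stability$p_TA_given_NA,
      p_TB_given_NB = sm$stability$p_TB_given_NB,
      adjusted_BA_AA_percent = sm$adjusted_BA_AA_percent,
      adjusted_AB_BB_percent = sm$adjusted_AB_BB_percent,
      adjusted_permissive_percent = sm$adjusted_BA_AA_percent +
        sm$adjusted_AB_BB_percent,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  list(table = tab, summaries = summaries, common_bins = common)
}
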