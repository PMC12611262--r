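# Independent oracles, implemented with different algorithms than the
# package code paths they check.

# Classic alternating Sinkhorn balancing: scale rows to a common sum, then
# columns, repeatedly; finally rescale to the input total. For symmetric
# positive matrices the balanced matrix is unique up to a scalar, so after
# total-matching it must agree with the package's symmetric iteration.
oracle_sinkhorn <- function(m, n_iter = 5000, tol = 1e-14) {
  total0 <- sum(m)
  for (i in seq_len(n_iter)) {
    rs <- rowSums(m)
    m <- m / rs
    cs <- colSums(m)
    m <- sweep(m, 2, cs, "/")
    if (max(abs(rowSums(m) - 1)) < tol && max(abs(colSums(m) - 1)) < tol) break
  }
  m * (total0 / sum(m))
}

# Exhaustive per-bin enumeration of the normal/cancer pair-state table.
oracle_pair <- function(normal, cancer) {
  out <- character(length(normal))
  for (i in seq_along(normal)) {
    n <- normal[i]; c <- cancer[i]
    out[i] <-
      if (is.na(n) || is.na(c)) NA_character_
      else if (n == "A" && c == "A") "AA"
      else if (n == "A" && c == "B") "AB"
      else if (n == "B" && c == "A") "BA"
      else "BB"
  }
  out
}

oracle_consensus <- function(normal, cancers) {
  out <- character(length(normal))
  for (i in seq_along(normal)) {
    labs <- vapply(cancers, function(cc) oracle_pair(normal[i], cc[i]), "")
    out[i] <- if (anyNA(labs) || length(unique(labs)) != 1L) {
      NA_character_
    } else {
      labs[1L]
    }
  }
  out
}

oracle_cross <- function(p, s) {
  out <- character(length(p))
  for (i in seq_along(p)) {
    out[i] <- if (is.na(p[i]) || is.na(s[i])) NA_character_
              else paste0(p[i], "_", s[i])
  }
  out
}

# Permissive fraction straight from its definition, by looping.
oracle_permissive_fraction <- function(cross,
                                       permissive = c("AB_BB", "BA_AA")) {
  num <- 0L; den <- 0L
  for (lab in cross) {
    if (is.na(lab)) next
    prim <- substr(lab, 1, 2)
    if (prim %in% c("AB", "BA")) {
      den <- den + 1L
      if (lab %in% permissive) num <- num + 1L
    }
  }
  if (den == 0L) stop("oracle: zero denominator")
  num / den
}

# Direct KS walk, computed with an explicit data.frame sort.
oracle_walk_score <- function(expr, set) {
  df <- data.frame(gene = names(expr), value = unname(expr),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$value, df$gene), ]
  inset <- df$gene %in% set
  n <- sum(inset); N <- nrow(df)
  running <- 0; best <- 0
  for (i in seq_len(N)) {
    running <- running + if (inset[i]) 1 / n else -1 / (N - n)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Quadratic all-pairs half-open overlap scan.
oracle_overlap_genes <- function(sel_bins, genes) {
  hits <- character(0)
  for (k in seq_len(nrow(sel_bins))) {
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] == sel_bins$chrom[k] &&
          genes$start[g] < sel_bins$end[k] &&
          genes$end[g] > sel_bins$start[k]) {
        hits <- c(hits, genes$gene_id[g])
      }
    }
  }
  sort(unique(hits))
}

# 1 - Pearson r from the raw sum formula, pair by pair.
oracle_pearson_distance <- function(v) {
  n <- nrow(v)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- v[i, ]; y <- v[j, ]
      xm <- x - mean(x); ym <- y - mean(y)
      r <- sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
      d[i, j] <- 1 - r
    }
  }
  d
}

random_state_track <- function(n, p_na = 0.15) {
  sample(c("A", "B", NA_character_), n, replace = TRUE,
         prob = c((1 - p_na) / 2, (1 - p_na) / 2, p_na))
}
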