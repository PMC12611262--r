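test_that("pair states enumerate the four combinations and propagate NA", {
  expect_identical(pair_states(c("A", "A", "B", "B"), c("A", "B", "A", "B")),
                   c("AA", "AB", "BA", "BB"))
  expect_identical(pair_states(c("A", NA, "B"), c(NA, "B", "A")),
                   c(NA, NA, "BA"))
  expect_error(pair_states(c("A"), c("A", "B")), "length")
  expect_error(pair_states(c("A", "C"), c("A", "B")), "A, B or NA")

  # exhaustive over the full 3x3 alphabet
  alphabet <- c("A", "B", NA_character_)
  grid <- expand.grid(n = alphabet, c = alphabet, stringsAsFactors = FALSE)
  expect_identical(pair_states(grid$n, grid$c), oracle_pair(grid$n, grid$c))
})

test_that("consensus keeps only unanimous non-NA pair labels", {
  normal <- c("A", "A", "A", "B")
  c1 <- c("B", "B", "A", NA)
  c2 <- c("B", "A", "A", "A")
  got <- consensus_pair_states(normal, list(c1, c2))
  expect_identical(got, c("AB", NA, "AA", NA))
  # single cancer track degenerates to pair_states
  expect_identical(consensus_pair_states(normal, list(c1)),
                   pair_states(normal, c1))
  expect_error(consensus_pair_states(normal, list()), "non-empty")
})

test_that("cross states form the 16 categories; permissive labels verified", {
  expect_identical(cross_states("AB", "BB"), "AB_BB")
  expect_identical(cross_states("AA", "AA"), "AA_AA")
  expect_identical(cross_states(c("AB", NA), c(NA, "BB")),
                   c(NA_character_, NA_character_))
  levels <- c("AA", "AB", "BA", "BB")
  grid <- expand.grid(p = levels, s = levels, stringsAsFactors = FALSE)
  expect_equal(length(unique(cross_states(grid$p, grid$s))), 16L)
})

test_that("permissive summary counts, fractions and substitutions are exact", {
  cross <- c(rep("AB_BB", 2), "BA_AA", "AB_AB", rep("AA_AA", 6))
  sm <- permissive_summary(cross)
  expect_equal(sm$permissive_fraction, 3 / 4)
  expect_equal(sum(sm$category_counts), sm$n_informative_bins)
  expect_equal(sm$n_informative_bins, 10L)
  expect_equal(unname(sm$percent[["AB_BB"]]), 20)

  # only permissive changes -> fraction 1
  expect_equal(permissive_summary(c("AB_BB", "BA_AA"))$permissive_fraction, 1)

  # definitional substitution: cancer-shared labels
  shared <- permissive_summary(cross,
                               permissive_labels = c("AB_AB", "BA_BA"))
  expect_equal(shared$permissive_fraction, 1 / 4)

  expect_error(permissive_summary(rep("AA_AA", 5)), "no-changes")
  expect_error(permissive_summary("XY_ZW"), "invalid")

  # alternative denominator: all informative bins
  sm_inf <- permissive_summary(cross, denominator = "informative")
  expect_equal(sm_inf$permissive_fraction, 3 / 10)
})

test_that("classification chain equals exhaustive enumeration on random tracks", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    p_norm <- random_state_track(n)
    cancers <- lapply(1:sample(1:3, 1), function(i) random_state_track(n))
    s_norm <- random_state_track(n)
    s_cancers <- lapply(1:2, function(i) random_state_track(n))
    pp <- consensus_pair_states(p_norm, cancers)
    sp <- consensus_pair_states(s_norm, s_cancers)
    expect_identical(pp, oracle_consensus(p_norm, cancers))
    cross <- cross_states(pp, sp)
    expect_identical(cross, oracle_cross(pp, sp))
    ok <- !is.na(cross) & substr(cross, 1, 2) %in% c("AB", "BA")
    if (any(ok)) {
      sm <- permissive_summary(cross)
      expect_equal(sm$permissive_fraction, oracle_permissive_fraction(cross))
      # conservation: 16 category counts + NA count = total bins
      expect_equal(sum(sm$category_counts) + sum(is.na(cross)), n)
    }
  }
})

test_that("stability probabilities use the minimum across cell lines", {
  normal <- c("A", "A", "B", "B")
  t1 <- c("A", "B", "B", "B")
  t2 <- c("A", "A", "B", "A")
  probs <- stability_probabilities(normal, list(t1 = t1, t2 = t2))
  expect_equal(probs$p_TA_given_NA, 0.5)
  expect_equal(probs$p_TB_given_NB, 0.5)
  expect_equal(probs$per_line$p_TA, c(0.5, 1.0))
  expect_equal(probs$per_line$p_TB, c(1.0, 0.5))

  same <- stability_probabilities(normal, list(normal))
  expect_equal(same$p_TA_given_NA, 1)
  expect_equal(same$p_TB_given_NB, 1)
  flipped <- stability_probabilities(normal, list(c("B", "B", "A", "A")))
  expect_equal(flipped$p_TA_given_NA, 0)
  expect_equal(flipped$p_TB_given_NB, 0)
  expect_error(stability_probabilities(c("A", "A"), list(c("A", "A"))),
               "compartment B")
})

test_that("the adjustment multiplies (1-p) with the matching percentages", {
  cross <- c(rep("BA_AA", 1), rep("AB_BB", 2), rep("AA_AA", 7))
  sm <- permissive_summary(cross)  # BA_AA 10%, AB_BB 20% of informative
  mk <- function(pa, pb) {
    structure(list(p_TA_given_NA = pa, p_TB_given_NB = pb,
                   per_line = data.frame(p_TA = pa, p_TB = pb),
                   n_normal_A = 1L, n_normal_B = 1L),
              class = "StabilityProbabilities")
  }
  adj <- adjusted_permissive(sm, mk(0.8, 0.5))
  expect_equal(adj$adjusted_BA_AA_percent, (1 - 0.8) * 10)
  expect_equal(adj$adjusted_AB_BB_percent, (1 - 0.5) * 20)

  # limits: p = 1 zeroes the adjusted values; p = 0 leaves them unadjusted
  adj1 <- adjusted_permissive(sm, mk(1, 1))
  expect_equal(adj1$adjusted_BA_AA_percent, 0)
  expect_equal(adj1$adjusted_AB_BB_percent, 0)
  adj0 <- adjusted_permissive(sm, mk(0, 0))
  expect_equal(adj0$adjusted_BA_AA_percent, unname(sm$percent[["BA_AA"]]))
  expect_equal(adj0$adjusted_AB_BB_percent, unname(sm$percent[["AB_BB"]]))

  # monotone: adjusted percentages never increase with stability
  vals <- sapply(seq(0, 1, 0.25), function(p) {
    adjusted_permissive(sm, mk(p, p))$adjusted_BA_AA_percent
  })
  expect_true(all(diff(vals) <= 0))

  # sensitivity flag swaps to p-weighting
  adj_p <- adjusted_permissive(sm, mk(0.8, 0.5), weighting = "p")
  expect_equal(adj_p$adjusted_BA_AA_percent, 0.8 * 10)
})

test_that("organ comparison is reproducible and per-organ independent", {
  panel <- small_panel(seed = 12, n_chromosomes = 2,
                       secondary_organs = c("lung", "brain"),
                       organ_divergence = 0.1)
  ps <- panel_organ_states(panel)
  res <- compare_target_organs(ps$primary_normal, ps$metastatic,
                               ps$organ_panels)
  expect_equal(nrow(res$table), 2L)

  # identical organ panels give identical summaries
  twin_panels <- list(lung = ps$organ_panels$lung,
                      lung2 = ps$organ_panels$lung)
  twin <- compare_target_organs(ps$primary_normal, ps$metastatic, twin_panels)
  expect_equal(twin$table$adjusted_permissive_percent[1],
               twin$table$adjusted_permissive_percent[2])

  # removing the decoy does not change the target numbers once the common
  # bin set is fixed (truth tracks have no NA, so the set is all bins)
  solo <- compare_target_organs(ps$primary_normal, ps$metastatic,
                                c(ps$organ_panels,
                                  list(dummy = ps$organ_panels$lung)))
  expect_equal(solo$table[solo$table$organ == "lung", -1],
               res$table[res$table$organ == "lung", -1])
  expect_error(compare_target_organs(ps$primary_normal, ps$metastatic,
                                     ps$organ_panels["lung"]), ">= 2")
})
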