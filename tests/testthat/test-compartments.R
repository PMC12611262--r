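test_that("ICE leaves already-balanced matrices unchanged", {
  # circulant matrix: all row sums equal by construction
  n <- 6
  base <- c(0, 5, 3, 2, 3, 5)
  counts <- outer(1:n, 1:n, function(i, j) base[((j - i) %% n) + 1])
  cm <- contact_matrix(counts, make_bins("chr1", n))
  res <- ice_normalize(cm)
  expect_true(res$converged)
  expect_equal(res$matrix$counts, cm$counts, tolerance = 1e-12)
  expect_equal(unname(res$bias), rep(1, n))

  cm2 <- contact_matrix(matrix(c(0, 4, 4, 0), 2), make_bins("chr1", 2))
  res2 <- ice_normalize(cm2)
  expect_equal(res2$matrix$counts, cm2$counts, tolerance = 1e-12)
})

test_that("ICE agrees with an independent Sinkhorn oracle and equalizes rows", {
  set.seed(123)
  for (rep in 1:5) {
    m <- matrix(runif(50 * 50, 0.5, 5), 50)
    m <- (m + t(m)) / 2
    cm <- contact_matrix(m, make_bins("chr1", 50))
    res <- ice_normalize(cm)
    s <- rowSums(res$matrix$counts)
    expect_lt(sd(s) / mean(s), 1e-6)
    oracle <- oracle_sinkhorn(m)
    expect_lt(max(abs(res$matrix$counts - oracle) / oracle), 1e-5)
  }
})

test_that("ICE masks sparse bins and errors when nothing is left", {
  set.seed(5)
  m <- random_contact_counts(30, lambda = 40)
  m[3, ] <- 0; m[, 3] <- 0          # dead bin
  m[7, ] <- m[7, ] * 0.001; m[, 7] <- m[, 7] * 0.001  # ultra-sparse bin
  cm <- contact_matrix(m, make_bins("chr1", 30))
  res <- ice_normalize(cm)
  expect_true(res$matrix$mask[3])
  expect_true(res$matrix$mask[7])
  expect_true(all(res$matrix$counts[3, ] == 0))
  expect_error(ice_normalize(contact_matrix(matrix(0, 2, 2),
                                            make_bins("chr1", 2),
                                            mask = c(FALSE, FALSE))),
               "unmasked|zero")
})

test_that("chromosome scaling is a plain rescale: idempotent and symmetric", {
  set.seed(8)
  cm <- contact_matrix(random_contact_counts(40, 60), make_bins("chr1", 40))
  total <- function(x) {
    s <- x$counts[!x$mask, !x$mask]
    sum(s[upper.tri(s, diag = TRUE)])
  }
  doubled <- contact_matrix(cm$counts * (2e6 / total(cm)), cm$bins)
  sc <- scale_chromosome(doubled, 1e6)
  expect_equal(sc$counts, doubled$counts / 2)
  expect_equal(total(sc), 1e6, tolerance = 1e-9)
  expect_equal(scale_chromosome(sc, 1e6)$counts, sc$counts)
  expect_equal(sc$counts, t(sc$counts))
  expect_error(scale_chromosome(contact_matrix(matrix(0, 2, 2),
                                               make_bins("chr1", 2),
                                               mask = c(FALSE, FALSE))),
               "zero total")
})

test_that("O/E flattens pure distance decay and propagates the mask", {
  n <- 30
  d <- abs(outer(1:n, 1:n, "-"))
  cm <- contact_matrix(100 / (d + 1), make_bins("chr1", n))
  oe <- observed_over_expected(cm)
  expect_equal(oe$counts, matrix(1, n, n), ignore_attr = TRUE)

  counts <- 100 / (d + 1)
  counts[4, ] <- 0; counts[, 4] <- 0
  cm2 <- contact_matrix(counts, make_bins("chr1", n))
  oe2 <- observed_over_expected(cm2)
  expect_true(all(is.na(oe2$counts[4, ])))
  expect_true(all(is.na(oe2$counts[, 4])))
  expect_equal(oe2$counts[-4, -4], matrix(1, n - 1, n - 1),
               ignore_attr = TRUE)
})

test_that("O/E shows the planted checkerboard above and below 1", {
  cfg <- simulation_config(n_bins = 200L, checkerboard_strength = 0.3,
                           seed = 3)
  st <- rep(rep(c("A", "B"), each = 10), 10)
  e <- simulate_contact_matrix(st, cfg, expected = TRUE)
  oe <- observed_over_expected(e)
  same <- outer(st, st, "==")
  off <- abs(outer(1:200, 1:200, "-")) > 0
  expect_gt(mean(oe$counts[same & off]), 1)
  expect_lt(mean(oe$counts[!same & off]), 1)
})

test_that("eigenvector recovers a noiseless checkerboard exactly", {
  cfg <- simulation_config(n_bins = 60L, checkerboard_strength = 0.3,
                           seed = 1)
  st <- rep(rep(c("A", "B"), each = 6), 5)
  e <- simulate_contact_matrix(st, cfg, expected = TRUE)
  tr <- compartment_eigenvector(observed_over_expected(e))
  expect_false(tr$oriented)
  expect_equal(sqrt(sum(tr$values^2)), 1, tolerance = 1e-8)
  signs <- sign(tr$values)
  agree <- mean(signs == ifelse(st == "A", 1, -1))
  expect_true(agree %in% c(0, 1))  # exact block recovery up to global sign

  # the negated eigenvector is an equally valid solution until orientation
  cov <- as.numeric(st == "A")
  o1 <- orient_track(tr, cov)
  o2 <- orient_track(compartment_track(-tr$values, tr$bins), cov)
  expect_equal(o1$values, o2$values)
  expect_identical(call_states(o1), st)
})

test_that("orientation is an involution with a recorded non-negative correlation", {
  set.seed(21)
  bins <- make_bins("chr1", 50)
  cov <- rnorm(50)
  v <- cov + rnorm(50, sd = 0.3)
  tr <- compartment_track(v, bins)
  o <- orient_track(tr, cov)
  expect_identical(o$values, v)           # already positively correlated
  expect_gte(o$orientation_cor, 0)
  o_neg <- orient_track(compartment_track(-v, bins), cov)
  expect_identical(o_neg$values, o$values)  # flipped back
  # a track orthogonal to the covariate cannot be oriented confidently
  v_orth <- as.numeric(resid(lm(rnorm(50) ~ cov)))
  expect_warning(orient_track(compartment_track(v_orth, bins), cov),
                 "ambiguous")
})

test_that("state calls follow the sign convention and require orientation", {
  bins <- make_bins("chr1", 3)
  tr <- compartment_track(c(0.4, -0.1, NA), bins, oriented = TRUE)
  expect_identical(call_states(tr), c("A", "B", NA))
  expect_identical(call_states(compartment_track(c(1, 2, 3), bins,
                                                 oriented = TRUE)),
                   c("A", "A", "A"))
  expect_identical(call_states(compartment_track(c(0, 1, -1), bins,
                                                 oriented = TRUE))[1],
                   NA_character_)
  expect_error(call_states(compartment_track(c(1, 2, 3), bins)), "oriented")
})

test_that("the pipeline is equivariant under bin permutation", {
  cfg <- simulation_config(n_bins = 120L, seed = 14)
  panel <- simulate_panel(cfg)
  st <- panel$states[, "breast_normal"]
  m <- simulate_contact_matrix(st, cfg, seed = 14)
  cov <- as.numeric(st == "A")
  res <- call_compartments(m, cov)

  set.seed(99)
  perm <- sample(120)
  pm <- contact_matrix(m$counts[perm, perm], m$bins[perm, ],
                       mask = m$mask[perm])
  res_p <- call_compartments(pm, cov[perm])
  agree <- suppressWarnings(cor(res_p$track$values, res$track$values[perm]))
  expect_equal(abs(res_p$track$values), abs(res$track$values[perm]),
               tolerance = 1e-6)
  expect_gt(agree, 1 - 1e-9)
})

test_that("recovery accuracy rises with depth and contrast", {
  accuracy <- function(depth, delta, seed) {
    cfg <- simulation_config(n_bins = 200L, depth = depth,
                             checkerboard_strength = delta, seed = seed)
    panel <- simulate_panel(cfg)
    st <- panel$states[, "breast_normal"]
    m <- simulate_contact_matrix(st, cfg, seed = seed + 1000)
    # at the lowest depths orientation is legitimately ambiguous
    res <- suppressWarnings(call_compartments(m, as.numeric(st == "A")))
    mean(res$states == st, na.rm = TRUE)
  }
  grid <- sapply(c(3e4, 3e5, 3e6), function(depth) {
    mean(sapply(1:3, function(s) accuracy(depth, 0.15, s)))
  })
  expect_true(all(diff(grid) >= 0))
  lowhigh <- sapply(c(0.1, 0.3), function(delta) {
    mean(sapply(1:3, function(s) accuracy(1e5, delta, s)))
  })
  expect_true(diff(lowhigh) >= 0)
  # deep sequencing recovers the planted states essentially perfectly
  expect_gte(accuracy(1e7, 0.3, 42), 0.99)
})
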