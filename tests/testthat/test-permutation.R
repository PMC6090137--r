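test_that("exhaustive sign-flip p-values match brute-force enumeration", {
  # worked examples first
  expect_equal(median_location_test(c(5, 5, 6, 6))$p_value, 2 / 16)
  expect_equal(median_location_test(4)$p_value, 1)
  deg <- median_location_test(c(0, 0, 0))
  expect_equal(deg$p_value, 1)
  expect_equal(deg$estimate, 0)
  expect_true(deg$degenerate)
  expect_error(median_location_test(numeric(0)), "nonempty")

  # random vectors with ties and zeros, against explicit enumeration
  set.seed(13)
  for (i in 1:25) {
    g <- sample(-6:6, sample(2:8, 1), replace = TRUE)
    res <- median_location_test(g, method = "exhaustive")
    expect_equal(res$p_value, brute_force_signflip_p(g),
                 info = paste(g, collapse = ","))
    expect_equal(res$estimate, median(g))
  }
})

test_that("tie-free inputs agree with the exact Wilcoxon signed-rank test", {
  cases <- list(c(1, -2, 3, 4, -5, 6, 7),
                c(2, 3, 5, -7, 11),
                c(-1, -4, 9, 10, -12, 15),
                c(3, 1, -6, 2, 7, -10, 12, 4))
  for (g in cases) {
    mine <- median_location_test(g, method = "exhaustive")
    ref <- stats::wilcox.test(g, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12,
                 info = paste(g, collapse = ","))
  }
})

test_that("the location test is sign-symmetric and MC mode tracks exhaustive mode", {
  g <- c(5, 5, 6, 6, -3, 2, 0, -1)
  a <- median_location_test(g)
  b <- median_location_test(-g)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$estimate, -b$estimate)

  for (g in list(c(5, 5, 6, 6), c(1, -2, 3, 3, 4), c(2, 2, 2, -2, 5, 6, -1))) {
    exact <- median_location_test(g, method = "exhaustive")$p_value
    mc <- median_location_test(g, n_perm = 10000, seed = 1,
                               method = "monte_carlo")$p_value
    se <- sqrt(exact * (1 - exact) / 10000)
    expect_lt(abs(mc - exact), 3 * se + 1e-4)
  }
  # MC mode is seeded and never returns p = 0
  m1 <- median_location_test(c(5, 5, 6, 6), n_perm = 500, seed = 9,
                             method = "monte_carlo")
  m2 <- median_location_test(c(5, 5, 6, 6), n_perm = 500, seed = 9,
                             method = "monte_carlo")
  expect_identical(m1$p_value, m2$p_value)
  expect_gt(median_location_test(rep(6, 12), n_perm = 500, seed = 1,
                                 method = "monte_carlo")$p_value, 0)
})

test_that("type-I error of the location test under a symmetric null stays at level", {
  set.seed(2024)
  n_rep <- 10000
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    g <- sample(1:6, 12, replace = TRUE) * sample(c(-1, 1), 12, replace = TRUE)
    p <- median_location_test(g, method = "exhaustive")$p_value
    rejections <- rejections + (p < 0.05)
  }
  expect_lte(rejections / n_rep, 0.06)
})

test_that("dominance verdicts follow the median sign and the threshold", {
  fungi <- paste0("F", 1:4); bacteria <- paste0("B", 1:5)
  mk <- function(medium, direction, w) {
    fbinet:::new_fbi_network(medium, direction,
                             if (direction == "fungi_to_bacteria") fungi else bacteria,
                             if (direction == "fungi_to_bacteria") bacteria else fungi,
                             w)
  }
  nets <- tibble::tibble(
    medium = c("MM", "PDA", "LB"),
    direction = "fungi_to_bacteria",
    network = list(mk("MM", "fungi_to_bacteria", matrix(6L, 4, 5)),
                   mk("PDA", "fungi_to_bacteria", matrix(-5L, 4, 5)),
                   mk("LB", "fungi_to_bacteria", matrix(0L, 4, 5)))
  )
  dom <- dominance_test(nets)
  expect_identical(dom$verdict,
                   c("inductions dominate", "repressions dominate",
                     "no dominance"))
  expect_equal(dom$median, c(6, -5, 0))
  # verdict never contradicts the median sign
  set.seed(5)
  for (i in 1:20) {
    w <- matrix(sample(-6:6, 20, TRUE), 4)
    nets1 <- tibble::tibble(medium = "MM", direction = "fungi_to_bacteria",
                            network = list(mk("MM", "fungi_to_bacteria", w)))
    d <- dominance_test(nets1)
    if (d$verdict == "inductions dominate") expect_gt(d$median, 0)
    if (d$verdict == "repressions dominate") expect_lt(d$median, 0)
  }
})

test_that("QAP self- and anti-correlation and permutation invariance", {
  set.seed(17)
  w <- random_weight_matrix()
  expect_equal(qap_correlation(w, w, n_perm = 50, seed = 1)$estimate, 1)
  expect_equal(qap_correlation(w, -w, n_perm = 50, seed = 1)$estimate, -1)
  expect_error(qap_correlation(w, matrix(3, 4, 5), n_perm = 10), "constant")
  expect_error(qap_correlation(w, w[, 1:4], n_perm = 10), "shape")

  w2 <- random_weight_matrix()
  r0 <- qap_correlation(w, w2, n_perm = 10, seed = 1)$estimate
  pr <- sample(4); pc <- sample(5)
  r1 <- qap_correlation(w[pr, pc], w2[pr, pc], n_perm = 10, seed = 1)$estimate
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("QAP Monte-Carlo p matches exhaustive relabelling on small matrices", {
  set.seed(23)
  for (i in 1:3) {
    w1 <- matrix(sample(-6:6, 9, TRUE), 3)
    w2 <- matrix(sample(-6:6, 9, TRUE), 3)
    if (sd(w1) == 0 || sd(w2) == 0) next
    p_exact <- brute_force_qap_p(w1, w2)
    n_perm <- 4000
    p_mc <- qap_correlation(w1, w2, n_perm = n_perm, seed = i)$p_value
    se <- sqrt(p_exact * (1 - p_exact) / n_perm)
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-3)
  }
})

test_that("qap_all_pairs covers every media pair and survives constant matrices", {
  set.seed(41)
  fungi <- paste0("F", 1:4); bacteria <- paste0("B", 1:5)
  media <- c("CP", "LB", "MM", "PDA")
  nets <- tibble::tibble(
    medium = media, direction = "fungi_to_bacteria",
    network = purrr::map(media, ~ fbinet:::new_fbi_network(
      .x, "fungi_to_bacteria", fungi, bacteria, random_weight_matrix()))
  )
  res <- qap_all_pairs(nets, "fungi_to_bacteria", n_perm = 100, seed = 1)
  expect_equal(nrow(res), 6)   # choose(4, 2)
  expect_false(anyNA(res$r))

  # a duplicated network pair correlates perfectly
  nets$network[[2]] <- nets$network[[1]]
  nets$network[[2]]$medium <- "LB"
  res_dup <- qap_all_pairs(nets, "fungi_to_bacteria", n_perm = 100, seed = 1)
  expect_equal(res_dup$r[res_dup$medium1 == "CP" & res_dup$medium2 == "LB"], 1)

  # one constant network poisons only its own pairs
  nets$network[[3]]$weights[] <- 0L
  res_na <- qap_all_pairs(nets, "fungi_to_bacteria", n_perm = 100, seed = 1)
  bad <- res_na$medium1 == "MM" | res_na$medium2 == "MM"
  expect_true(all(is.na(res_na$r[bad])))
  expect_true(all(!is.na(res_na$r[!bad])))
  expect_match(res_na$note[bad][1], "constant")

  expect_error(qap_all_pairs(nets[1, ], "fungi_to_bacteria"), "at least 2")
})

test_that("permutation results expose broom-style tidy and glance views", {
  res <- median_location_test(c(5, 5, 6, 6))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p.value, 0.125)
  expect_equal(td$method, "exhaustive")
  expect_identical(glance(res), td)
})
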