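new_fbi_permtest <- function(test, estimate, statistic, p_value, method,
                             n_perm, seed = NULL, degenerate = FALSE,
                             note = NA_character_) {
  structure(
    list(test = test, estimate = estimate, statistic = statistic,
         p_value = p_value, method = method, n_perm = n_perm,
         seed = seed, degenerate = degenerate, note = note,
         alternative = "two.sided"),
    class = "fbi_permtest"
  )
}

#' @export
print.fbi_permtest <- function(x, ...) {
  cat(sprintf("<fbi_permtest> %s (%s, %s permutations)\n", x$test, x$method,
              format(x$n_perm, big.mark = ",")))
  cat(sprintf("  estimate = %.4g, statistic = %.4g, two-sided p = %.4g\n",
              x$estimate, x$statistic, x$p_value))
  if (isTRUE(x$degenerate)) cat("  note: degenerate input\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fbi_permtest <- function(x, ...) {
  tibble::tibble(
    test = x$test, estimate = x$estimate, statistic = x$statistic,
    p.value = x$p_value, method = x$method, n_perm = x$n_perm,
    alternative = x$alternative, degenerate = x$degenerate
  )
}

#' @exportS3Method generics::glance
glance.fbi_permtest <- function(x, ...) tidy(x)

# Exact null distribution of the signed-rank statistic under independent
# sign flips, as counts over the doubled-rank support (mid-ranks are
# half-integers, so doubling makes the support integer). Returns
# P(|T| >= |t_obs|) computed without enumeration: a convolution over
# 2^m equally likely assignments.
signflip_exhaustive_p <- function(ranks2, t2_obs) {
  s <- sum(ranks2)
  counts <- numeric(2 * s + 1)  # support -s..s, index offset s + 1
  counts[s + 1] <- 1
  for (r in ranks2) {
    new <- numeric(2 * s + 1)
    idx <- seq_len(2 * s + 1)
    lo <- idx - r; hi <- idx + r
    ok_lo <- lo >= 1; ok_hi <- hi <= 2 * s + 1
    new[idx[ok_lo]] <- new[idx[ok_lo]] + counts[lo[ok_lo]]
    new[idx[ok_hi]] <- new[idx[ok_hi]] + counts[hi[ok_hi]]
    counts <- new
  }
  support <- (-s):s
  sum(counts[abs(support) >= abs(t2_obs)]) / 2^length(ranks2)
}

#' Sign-flip permutation test for median zero
#'
#' One-sample location test applied to the interaction grades of a network:
#' the null hypothesis is that the grades are symmetrically signed around a
#' median of 0, i.e. inductions and repressions are exchangeable. Zeros
#' (absent links) are dropped, tied magnitudes receive mid-ranks, and the
#' statistic is the sum of signed ranks; the null distribution is generated
#' by independently flipping the sign of each rank, which is exact for tied
#' data. The reported estimate is the median of the grade list exactly as
#' supplied (zeros included).
#'
#' With `method = "auto"` the test enumerates all `2^m` sign assignments
#' exactly whenever at most 20 nonzero grades are present (always true for
#' a 20-link network), and otherwise falls back to `n_perm` Monte-Carlo
#' sign flips with an add-one correction, so Monte-Carlo p-values are never
#' zero.
#'
#' @param grades Numeric vector of interaction grades (zeros allowed).
#' @param n_perm Monte-Carlo permutation count (default 500).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param method `"auto"`, `"exhaustive"` or `"monte_carlo"`.
#' @return An `fbi_permtest` object; see [tidy()] for a tibble view.
#' @examples
#' median_location_test(c(5, 5, 6, 6))  # exhaustive p = 2/16
#' @export
median_location_test <- function(grades, n_perm = 500, seed = NULL,
                                 method = c("auto", "exhaustive", "monte_carlo")) {
  method <- match.arg(method)
  grades <- as.numeric(grades)
  if (length(grades) == 0) abort("`grades` must be nonempty.")
  if (anyNA(grades)) abort("`grades` must not contain NA.")

  est <- median(grades)
  nz <- grades[grades != 0]
  m <- length(nz)
  if (m == 0) {
    return(new_fbi_permtest("median_location", est, 0, 1, "exhaustive",
                            n_perm = 1, degenerate = TRUE,
                            note = "all grades zero"))
  }

  ranks <- rank(abs(nz))               # mid-ranks for tied magnitudes
  ranks2 <- as.integer(round(2 * ranks))
  t2_obs <- sum(sign(nz) * ranks2)
  t_obs <- t2_obs / 2

  if (method == "auto") {
    method <- if (m <= 20) "exhaustive" else "monte_carlo"
  }

  if (method == "exhaustive") {
    p <- signflip_exhaustive_p(ranks2, t2_obs)
    new_fbi_permtest("median_location", est, t_obs, p, "exhaustive",
                     n_perm = 2^m, seed = NULL)
  } else {
    t2_perm <- local_seed(seed, {
      signs <- matrix(sample(c(-1L, 1L), m * n_perm, replace = TRUE),
                      nrow = n_perm)
      as.vector(signs %*% ranks2)
    })
    p <- (1 + sum(abs(t2_perm) >= abs(t2_obs))) / (1 + n_perm)
    new_fbi_permtest("median_location", est, t_obs, p, "monte_carlo",
                     n_perm = n_perm, seed = seed)
  }
}

#' Dominance of inductions vs repressions per network
#'
#' Applies [median_location_test()] to the grades of every network in a
#' bundle and calls a verdict: a significant positive median means
#' inductions dominate on that medium and direction, a significant negative
#' median means repressions dominate, anything else is no dominance.
#'
#' @param networks Network tibble from [build_networks()].
#' @param alpha Significance threshold for a dominance verdict.
#' @param n_perm,seed,method Passed to [median_location_test()]; the default
#'   `"auto"` method is exhaustive for networks of up to 20 links.
#' @return Tibble: `medium`, `direction`, `median`, `statistic`, `p_value`,
#'   `method`, `n_perm`, `verdict`.
#' @export
dominance_test <- function(networks, alpha = 0.05, n_perm = 500, seed = NULL,
                           method = "auto") {
  res <- purrr::imap(networks$network, function(net, i) {
    tst <- median_location_test(as.vector(net$weights), n_perm = n_perm,
                                seed = if (is.null(seed)) NULL else seed + i,
                                method = method)
    tibble::tibble(median = tst$estimate, statistic = tst$statistic,
                   p_value = tst$p_value, method = tst$method,
                   n_perm = tst$n_perm)
  })
  out <- dplyr::bind_cols(networks[c("medium", "direction")],
                          dplyr::bind_rows(res))
  out$verdict <- dplyr::case_when(
    out$p_value < alpha & out$median > 0 ~ "inductions dominate",
    out$p_value < alpha & out$median < 0 ~ "repressions dominate",
    .default = "no dominance"
  )
  out
}

#' QAP correlation between two networks
#'
#' Quadratic Assignment Procedure test for the correlation between two
#' weight matrices over the same node sets (e.g. the same direction on two
#' media). The estimate is the Pearson correlation across all cells; the
#' null distribution is generated by relabelling the strains of the second
#' network -- permuting its row labels and, independently, its column
#' labels -- so that the bipartite structure is preserved while strain
#' identities are broken. The two-sided p-value uses an add-one correction.
#'
#' @param w1,w2 Numeric matrices of identical shape and node order; neither
#'   may be constant.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return An `fbi_permtest` object with `estimate` = Pearson r.
#' @examples
#' m <- matrix(c(1, -2, 0, 3, 5, 0, -1, 2), 2)
#' qap_correlation(m, m, n_perm = 99, seed = 1)$estimate  # r = 1
#' @export
qap_correlation <- function(w1, w2, n_perm = 1000, seed = NULL) {
  if (inherits(w1, "fbi_network")) w1 <- w1$weights
  if (inherits(w2, "fbi_network")) w2 <- w2$weights
  if (!all(dim(w1) == dim(w2))) abort("Matrices must have identical shape.")
  v1 <- as.vector(w1); v2 <- as.vector(w2)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Correlation undefined: at least one matrix is constant.")
  }
  r_obs <- cor(v1, v2)
  nr <- nrow(w1); nc <- ncol(w1)
  r_perm <- local_seed(seed, vapply(seq_len(n_perm), function(b) {
    cor(v1, as.vector(w2[sample.int(nr), sample.int(nc)]))
  }, numeric(1)))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_perm)
  new_fbi_permtest("qap", r_obs, r_obs, p, "monte_carlo", n_perm, seed)
}

#' QAP tests over all media pairs of one direction
#'
#' Runs [qap_correlation()] on every unordered pair of media networks of the
#' requested direction, mirroring the upper-triangular media-by-media report
#' layout. A pair whose correlation is undefined (constant matrix) is
#' reported with `NA` and a note; the remaining pairs still run.
#'
#' @param networks Network tibble from [build_networks()].
#' @param direction `"fungi_to_bacteria"` or `"bacteria_to_fungi"`.
#' @param n_perm,seed Passed to [qap_correlation()]; each pair uses a
#'   deterministic sub-seed derived from `seed`.
#' @return Tibble: `direction`, `medium1`, `medium2`, `r`, `p_value`,
#'   `n_perm`, `note`.
#' @export
qap_all_pairs <- function(networks, direction, n_perm = 1000, seed = NULL) {
  sub <- networks[networks$direction == direction, ]
  if (nrow(sub) < 2) abort("Need at least 2 networks of the requested direction.")
  pairs <- utils::combn(seq_len(nrow(sub)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    res <- tryCatch(
      qap_correlation(sub$network[[i]], sub$network[[j]], n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + k),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      tibble::tibble(direction = direction, medium1 = sub$medium[i],
                     medium2 = sub$medium[j], r = NA_real_,
                     p_value = NA_real_, n_perm = n_perm,
                     note = conditionMessage(res))
    } else {
      tibble::tibble(direction = direction, medium1 = sub$medium[i],
                     medium2 = sub$medium[j], r = res$estimate,
                     p_value = res$p_value, n_perm = n_perm,
                     note = NA_character_)
    }
  })
}
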