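# Shared fixtures and independent oracles, built in code.

# Null study design: default roster/media/days, lognormal replicate noise.
null_config <- function(seed, noise_cv = 0.1) {
  fbi_sim_config(noise_cv = noise_cv, seed = seed)
}

# Stress-gradient scenario: every interaction induced on the low-nutrient
# medium (MM, +50%) and repressed on the rich medium (PDA, -50%), from day 3.
stress_gradient_config <- function(seed, noise_cv = 0.1,
                                   media = c("CP", "LB", "MM", "PDA")) {
  strains <- fbi_strains()
  eff <- dplyr::bind_rows(
    fbi_uniform_effects(strains, "MM", 0.5),
    fbi_uniform_effects(strains, "PDA", -0.5)
  )
  fbi_sim_config(media = media, noise_cv = noise_cv,
                 effects = eff[eff$medium %in% media, ], seed = seed)
}

# Brute-force oracle for the sign-flip location test: enumerate every sign
# assignment of the nonzero values explicitly.
brute_force_signflip_p <- function(grades) {
  nz <- grades[grades != 0]
  m <- length(nz)
  if (m == 0) return(1)
  ranks <- rank(abs(nz))
  t_obs <- sum(sign(nz) * ranks)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), m)))
  t_perm <- as.vector(signs %*% ranks)
  mean(abs(t_perm) >= abs(t_obs) - 1e-9)
}

# All permutations of 1..n (tiny n only), for the exhaustive QAP oracle.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = k - 1)
    }
  }
  out
}

# Exhaustive QAP null: proportion of |r| under ALL row x column relabellings
# of w2 at least as extreme as observed.
brute_force_qap_p <- function(w1, w2) {
  v1 <- as.vector(w1)
  r_obs <- stats::cor(v1, as.vector(w2))
  rs <- unlist(lapply(all_perms(nrow(w2)), function(pr) {
    vapply(all_perms(ncol(w2)),
           function(pc) stats::cor(v1, as.vector(w2[pr, pc])), numeric(1))
  }))
  mean(abs(rs) >= abs(r_obs) - 1e-12)
}

random_weight_matrix <- function(nr = 4, nc = 5) {
  repeat {
    w <- matrix(sample(-6:6, nr * nc, replace = TRUE), nr)
    if (stats::sd(w) > 0) return(w)
  }
}
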