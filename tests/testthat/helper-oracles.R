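# Independent oracles and small fixture builders used across the suite.

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# dense random model without planted structure, over the first q AA symbols
random_model <- function(L, q, seed, field_sd = 1, coupling_sd = 0.5) {
  set.seed(seed)
  alphabet <- aa_alphabet(gap = FALSE)[seq_len(q)]
  h <- matrix(rnorm(L * q, sd = field_sd), L, q)
  J <- array(rnorm(L * L * q * q, sd = coupling_sd), dim = c(L, L, q, q))
  potts_model(h, J, alphabet = alphabet)  # symmetrized on construction
}

# brute-force EVH: triple loop, no shared code with the package kernel
oracle_evh <- function(model, s) {
  s <- encode_seq(s, model$alphabet)
  e <- 0
  for (i in seq_len(model$L)) e <- e + model$h[i, s[i]]
  for (i in seq_len(model$L - 1))
    for (j in (i + 1):model$L)
      e <- e + model$J[i, j, s[i], s[j]]
  e
}

# exhaustive greedy hill climb: recompute EVH of every single amino-acid
# mutant from scratch each step; accept the first-maximal strictly positive
# move (position, then alphabet order)
oracle_hill_climb <- function(model, start) {
  s <- encode_seq(start, model$alphabet)
  aa_states <- sort(match(aa_alphabet(gap = FALSE), model$alphabet))
  aa_states <- aa_states[!is.na(aa_states)]
  repeat {
    e0 <- oracle_evh(model, s)
    best_gain <- 0; best <- NULL
    for (i in seq_len(model$L)) {
      for (a in aa_states) {
        if (a == s[i]) next
        cand <- s; cand[i] <- a
        gain <- oracle_evh(model, cand) - e0
        if (gain > best_gain + 1e-12) { best_gain <- gain; best <- cand }
      }
    }
    if (is.null(best)) return(decode_seq(s, model$alphabet))
    s <- best
  }
}

# Spearman via explicit average ranks and the explicit product-moment formula
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exact single-member equilibrium of the penalized design energy by
# enumeration: p(s) proportional to exp(-beta * U(s)) over amino-acid states
oracle_penalized_boltzmann <- function(model, beta, cfg, target_chr) {
  X <- enumerate_states(model)
  U <- vapply(seq_len(nrow(X)), function(r) {
    s <- decode_seq(X[r, ], model$alphabet)
    pen <- penalty_terms(s, character(), target_chr, NULL, cfg,
                         alphabet = model$alphabet)
    -evh(model, s) + sum(pen)
  }, numeric(1))
  w <- exp(-beta * (U - min(U)))
  w / sum(w)
}

# a rugged two-state landscape: strong chain couplings create aligned-A and
# aligned-C basins; a small field tilt makes all-C the unique global optimum
two_basin_model <- function(L = 8, coupling = 1.5, tilt = 0.1) {
  q <- 2
  h <- matrix(0, L, q)
  h[, 2] <- tilt
  J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1)) {
    B <- matrix(0, q, q); B[1, 1] <- coupling; B[2, 2] <- coupling
    J[i, i + 1, , ] <- B
    J[i + 1, i, , ] <- t(B)
  }
  potts_model(h, J, alphabet = c("A", "C"), enforce = FALSE)
}
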