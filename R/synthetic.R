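#' Generate a planted Potts model
#'
#' Draws a random site-and-pairwise landscape with a known interaction
#' graph: fields i.i.d. `N(0, field_scale^2)` and, on each planted edge, a
#' `q x q` coupling block with entries i.i.d. `N(0, coupling_strength^2)`
#' (the array is completed by the symmetry `J[i,j,a,b] = J[j,i,b,a]`; all
#' other blocks are zero). With the default random-graph topology, edges
#' are drawn among position pairs at least `min_sep` apart in sequence, so
#' contact-ranking evaluations exercise the usual primary-sequence
#' separation filter. Reproducible from `seed`.
#'
#' @param L number of positions.
#' @param q alphabet size; `q = 21` uses the amino-acid alphabet with gap,
#'   `q = 20` without, smaller `q` uses the first `q` amino-acid symbols
#'   (the default 8 keeps enumeration-based tests fast).
#' @param n_edges number of planted coupling edges
#'   (`<=` available pairs).
#' @param coupling_strength,field_scale standard deviations of coupling and
#'   field entries.
#' @param topology `"random"` (pairs at least `min_sep` apart) or `"chain"`
#'   (consecutive pairs).
#' @param min_sep minimum |i - j| for random-graph edges (default 5; reduce
#'   for small `L`).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return an `evh_planted` (also an `evh_potts`) with an `edges` tibble and
#'   the generation parameters in `metadata`.
#' @export
planted_model <- function(L, q = 8L, n_edges = L, coupling_strength = 1,
                          field_scale = 1, topology = c("random", "chain"),
                          min_sep = 5L, seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(L >= 2L, q >= 2L, n_edges >= 0L)
  if (!is.null(seed)) set.seed(seed)
  alphabet <- if (q == 21L) aa_alphabet() else aa_alphabet(gap = FALSE)[seq_len(q)]
  if (q > 21L) stop("q must be at most 21", call. = FALSE)
  if (topology == "chain") {
    cand <- cbind(seq_len(L - 1L), 2:L)
  } else {
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
    cand <- idx[abs(idx[, 2] - idx[, 1]) >= min_sep, , drop = FALSE]
    if (nrow(cand) == 0L)
      cand <- idx  # tiny L: fall back to all pairs
  }
  if (n_edges > nrow(cand))
    stop("n_edges = ", n_edges, " exceeds the ", nrow(cand),
         " available pairs", call. = FALSE)
  pick <- if (n_edges > 0) sort(sample.int(nrow(cand), n_edges)) else integer()
  edges <- cand[pick, , drop = FALSE]
  h <- matrix(stats::rnorm(L * q, sd = field_scale), L, q)
  J <- array(0, dim = c(L, L, q, q))
  if (n_edges > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      B <- matrix(stats::rnorm(q * q, sd = coupling_strength), q, q)
      J[i, j, , ] <- B
      J[j, i, , ] <- t(B)
    }
  }
  m <- potts_model(h, J, alphabet = alphabet,
                   metadata = list(topology = topology, min_sep = min_sep,
                                   coupling_strength = coupling_strength,
                                   field_scale = field_scale,
                                   n_edges = n_edges, seed = seed),
                   enforce = FALSE)
  m$edges <- tibble::tibble(i = as.integer(edges[, 1]),
                            j = as.integer(edges[, 2]))
  class(m) <- c("evh_planted", class(m))
  m
}

#' Planted edges of a synthetic model
#' @param model an `evh_planted`.
#' @return tibble (i, j).
#' @export
planted_contacts <- function(model) {
  stopifnot(inherits(model, "evh_planted"))
  model$edges
}

#' Exact Boltzmann distribution of a small model
#'
#' Enumerates all `q^L` sequences and returns
#' `p(sigma) = exp(beta * EVH(sigma)) / Z`. The state index uses position 1
#' as the fastest-varying digit (`state = 1 + sum_i (s_i - 1) * q^(i-1)`),
#' matching the visit-count ordering of the samplers. Guarded to
#' `q^L <= 1e6`.
#'
#' @param model an [potts_model()].
#' @param beta inverse temperature.
#' @return tibble (state, evh, prob); probabilities sum to 1 within 1e-12.
#' @export
enumerate_boltzmann <- function(model, beta = 1) {
  n_states <- model$q^model$L
  if (n_states > 1e6)
    stop("q^L = ", n_states, " exceeds the enumeration guard (1e6)",
         call. = FALSE)
  X <- as.matrix(expand.grid(rep(list(seq_len(model$q)), model$L)))
  storage.mode(X) <- "integer"
  e <- evh_many(model, X)
  lw <- beta * e
  p <- exp(lw - max(lw))
  p <- p / sum(p)
  tibble::tibble(state = seq_len(nrow(X)), evh = e, prob = p)
}

#' Encoded sequences of all enumerated states
#'
#' Companion to [enumerate_boltzmann()]: the `q^L x L` matrix of encoded
#' sequences in state order.
#' @inheritParams enumerate_boltzmann
#' @export
enumerate_states <- function(model) {
  n_states <- model$q^model$L
  if (n_states > 1e6)
    stop("q^L exceeds the enumeration guard (1e6)", call. = FALSE)
  X <- as.matrix(expand.grid(rep(list(seq_len(model$q)), model$L)))
  storage.mode(X) <- "integer"
  X
}

#' Sample an alignment from a Potts model
#'
#' `method = "exact"` draws i.i.d. sequences from the enumerated Boltzmann
#' distribution (small models only); `method = "gibbs"` runs a single Gibbs
#' chain over the full alphabet with the stated burn-in and thinning.
#' Sequences are i.i.d. (exact) or approximately so (gibbs, for adequate
#' thinning); no phylogenetic correlation is simulated.
#'
#' @param model an [potts_model()].
#' @param n number of sequences.
#' @param beta inverse temperature.
#' @param method `"exact"` or `"gibbs"`.
#' @param burn_in,thin Gibbs chain settings (sweeps).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return an [new_alignment()] whose first record is the target.
#' @export
sample_msa <- function(model, n, beta = 1, method = c("exact", "gibbs"),
                       burn_in = 500L, thin = 10L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (method == "exact") {
    bz <- enumerate_boltzmann(model, beta)
    X <- enumerate_states(model)[
      sample.int(nrow(bz), n, replace = TRUE, prob = bz$prob), , drop = FALSE]
  } else {
    init <- sample.int(model$q, model$L, replace = TRUE)
    X <- cpp_gibbs_chain(model$h, model$J, beta, as.integer(n),
                         as.integer(burn_in), as.integer(thin), init - 1L) + 1L
  }
  rows <- apply(X, 1, decode_seq, alphabet = model$alphabet)
  new_alignment(sprintf("seq_%d", seq_len(n)), rows,
                target_index = 1L, alphabet = model$alphabet)
}

#' Generate a synthetic deep mutational scan
#'
#' Emulates the replicate structure of an experimental scan: each
#' replicate's score for a substitution is the model's predicted effect
#' plus independent Gaussian noise, `score = delta_evh + N(0, noise_sd^2)`.
#'
#' @param model an [potts_model()].
#' @param wt background sequence (defaults to the model target).
#' @param noise_sd measurement noise standard deviation (>= 0).
#' @param n_replicates number of replicate score columns.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return tibble (position, wt, mut, score_1, ..., score_k).
#' @export
synthetic_dms <- function(model, wt = NULL, noise_sd = 1, n_replicates = 2L,
                          seed = NULL) {
  stopifnot(noise_sd >= 0, n_replicates >= 1L)
  if (is.null(wt)) wt <- model$target_seq
  if (!is.null(seed)) set.seed(seed)
  scan <- mutation_matrix(model, wt)
  out <- dplyr::select(scan, "position", "wt", "mut")
  for (r in seq_len(n_replicates)) {
    out[[sprintf("score_%d", r)]] <-
      scan$delta_evh + stats::rnorm(nrow(scan), sd = noise_sd)
  }
  out
}
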