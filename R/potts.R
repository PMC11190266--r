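#' Potts model objects
#'
#' A site-and-pairwise (Potts) model over `L` focus positions and a `q`-state
#' alphabet: site terms `h[i, a]` and coupling terms `J[i, j, a, b]` with
#' `J[i, j, a, b] == J[j, i, b, a]` and zero diagonal blocks. The statistical
#' energy of a sequence, `EVH`, is the sum of its site terms plus the coupling
#' terms over all position pairs; higher EVH means better agreement with the
#' evolutionary record of the family.
#'
#' @param h `L x q` numeric matrix of site terms.
#' @param J `L x L x q x q` numeric array of couplings; symmetrized and
#'   diagonal-zeroed on construction if `enforce = TRUE`.
#' @param alphabet ordered symbol set (length `q`).
#' @param index_map integer vector mapping focus position to residue number
#'   in the target sequence's own numbering; defaults to `1:L`.
#' @param target_seq optional target sequence (string or encoded).
#' @param metadata named list (theta, n_eff, regularization, seed, ...).
#' @param enforce symmetrize J and zero its diagonal blocks (default TRUE).
#' @return an object of class `evh_potts`.
#' @export
potts_model <- function(h, J, alphabet = aa_alphabet(), index_map = NULL,
                        target_seq = NULL, metadata = list(), enforce = TRUE) {
  h <- as.matrix(h)
  L <- nrow(h); q <- ncol(h)
  stopifnot(length(alphabet) == q, length(dim(J)) == 4L,
            all(dim(J) == c(L, L, q, q)))
  if (!all(is.finite(h)) || !all(is.finite(J)))
    stop("model parameters must be finite", call. = FALSE)
  if (enforce) {
    J <- (J + aperm(J, c(2, 1, 4, 3))) / 2
    for (i in seq_len(L)) J[i, i, , ] <- 0
  }
  if (is.null(index_map)) index_map <- seq_len(L)
  index_map <- as.integer(index_map)
  if (length(index_map) != L || is.unsorted(index_map, strictly = TRUE))
    stop("index_map must be strictly increasing with length L", call. = FALSE)
  if (!is.null(target_seq)) target_seq <- encode_seq(target_seq, alphabet)
  structure(
    list(L = L, q = q, alphabet = alphabet, h = h, J = J,
         index_map = index_map, target_seq = target_seq, metadata = metadata),
    class = "evh_potts"
  )
}

#' @export
print.evh_potts <- function(x, ...) {
  cat("<evh_potts> L = ", x$L, ", q = ", x$q,
      " (alphabet: ", paste(x$alphabet, collapse = ""), ")\n", sep = "")
  if (!is.null(x$metadata$n_eff))
    cat("  n_eff = ", format(x$metadata$n_eff, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics glance
glance.evh_potts <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    L = x$L, q = x$q,
    n_eff = md$n_eff %||% NA_real_,
    theta = md$theta %||% NA_real_,
    lambda_h = md$lambda_h %||% NA_real_,
    lambda_J = md$lambda_J %||% NA_real_,
    converged = md$converged %||% NA
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Statistical energy (EVH) of a sequence
#'
#' `EVH(sigma) = sum_i h_i(sigma_i) + sum_{i<j} J_ij(sigma_i, sigma_j)`.
#'
#' @param model an [potts_model()].
#' @param seq a sequence of length `L` (string or encoded integer vector).
#' @return a single number.
#' @export
#' @examples
#' m <- planted_model(L = 5, q = 4, n_edges = 3, seed = 1)
#' evh(m, sample_msa(m, n = 1, method = "gibbs", seed = 1)$rows[[1]])
evh <- function(model, seq) {
  s <- encode_seq(seq, model$alphabet)
  if (length(s) != model$L)
    stop("sequence length ", length(s), " != model L = ", model$L, call. = FALSE)
  cpp_evh(model$h, model$J, s - 1L)
}

# EVH for each row of an encoded n x L matrix
evh_many <- function(model, X) {
  stopifnot(ncol(X) == model$L)
  cpp_evh_many(model$h, model$J, X - 1L)
}

#' Effect of substitutions on EVH
#'
#' The change in statistical energy caused by one or more substitutions in a
#' stated background, computed incrementally from only the terms touching the
#' mutated positions (identical to a full recomputation up to floating-point
#' roundoff below 1e-9 relative).
#'
#' @param model an [potts_model()].
#' @param background background sequence of length `L`.
#' @param mutations either a list of `c(position, symbol)` pairs, or a
#'   two-column data frame / matrix with columns (position, symbol); symbols
#'   may be characters or state indices. Positions must be distinct and the
#'   new symbol must differ from the background.
#' @return the scalar `EVH(mutant) - EVH(background)`.
#' @export
delta_evh <- function(model, background, mutations) {
  bg <- encode_seq(background, model$alphabet)
  mu <- normalize_mutations(model, bg, mutations)
  if (nrow(mu) == 0L) return(0)
  cpp_delta_evh(model$h, model$J, bg - 1L, mu$pos - 1L, mu$state - 1L)
}

normalize_mutations <- function(model, bg, mutations) {
  if (is.null(mutations) || (is.list(mutations) && length(mutations) == 0L))
    return(data.frame(pos = integer(), state = integer()))
  if (is.data.frame(mutations) || is.matrix(mutations)) {
    pos <- as.integer(mutations[[1]]); sym <- mutations[[2]]
  } else if (is.list(mutations)) {
    pos <- vapply(mutations, function(x) as.integer(x[[1]]), integer(1))
    sym <- sapply(mutations, function(x) x[[2]])  # symbols or state indices
  } else {  # single c(pos, sym)
    pos <- as.integer(mutations[[1]]); sym <- mutations[[2]]
  }
  state <- if (is.character(sym)) match(toupper(sym), model$alphabet) else as.integer(sym)
  if (anyNA(state)) stop("mutation symbol outside the alphabet", call. = FALSE)
  if (any(pos < 1L | pos > model$L)) stop("mutation position out of range", call. = FALSE)
  if (anyDuplicated(pos)) stop("mutation positions must be distinct", call. = FALSE)
  if (any(state == bg[pos]))
    stop("mutation symbol equals the background symbol", call. = FALSE)
  data.frame(pos = pos, state = state)
}

#' Full single-substitution scan
#'
#' The change in EVH for every possible amino-acid substitution in a
#' background sequence: `L x 19` rows for a 20-letter alphabet (the gap state
#' is not proposed as a mutation).
#'
#' @inheritParams delta_evh
#' @param background_id label recorded in the output (default "background").
#' @return a tibble with columns `position`, `wt`, `mut`, `delta_evh`,
#'   `background_id`.
#' @export
mutation_matrix <- function(model, background, background_id = "background") {
  bg <- encode_seq(background, model$alphabet)
  aas <- aa_alphabet(gap = FALSE)
  aa_states <- match(aas, model$alphabet)
  aa_states <- aa_states[!is.na(aa_states)]
  out <- cpp_mutation_scan(model$h, model$J, bg - 1L, aa_states - 1L)
  tibble::tibble(
    position = out$pos + 1L,
    wt = model$alphabet[bg[out$pos + 1L]],
    mut = model$alphabet[out$state + 1L],
    delta_evh = out$delta,
    background_id = background_id
  )
}

#' Predicted epistasis between two substitutions
#'
#' The non-additivity of a double mutant:
#' `delta_evh({A, B}) - delta_evh({A}) - delta_evh({B})`, which for a
#' pairwise model reduces to the closed form
#' `J_ij(a', b') - J_ij(a', b) - J_ij(a, b') + J_ij(a, b)`.
#'
#' @inheritParams delta_evh
#' @param mutA,mutB `c(position, symbol)` pairs at distinct positions.
#' @return a single number.
#' @export
epistasis <- function(model, background, mutA, mutB) {
  bg <- encode_seq(background, model$alphabet)
  a <- normalize_mutations(model, bg, list(mutA))
  b <- normalize_mutations(model, bg, list(mutB))
  if (a$pos == b$pos)
    stop("epistasis is not defined for two mutations at the same position",
         call. = FALSE)
  delta_evh(model, bg, list(mutA, mutB)) -
    delta_evh(model, bg, list(mutA)) -
    delta_evh(model, bg, list(mutB))
}
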