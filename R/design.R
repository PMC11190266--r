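#' Design configuration
#'
#' Bundles the hyperparameters of the penalized batch design sampler: the
#' batch size, the target-identity distance band, the diversity and homolog
#' distance floors, the penalty weights, and the annealing schedule. The
#' defaults are the settings used throughout the package: a batch of 6
#' sequences, `lambda_target = 1000`, `lambda_diversity = lambda_alignment
#' = 10`, `d_max = d_min + 0.05` (a small margin of tolerated target
#' distances), `d_diversity = d_alignment = d_min`, and a linear inverse-
#' temperature ramp from 0.5 to 10 over 1000 batch sweeps. A target identity
#' of, say, 70% corresponds to `d_min = 0.30`.
#'
#' @param M batch size.
#' @param d_min lower edge of the target normalized-Hamming-distance band.
#' @param d_max upper edge (default `d_min + 0.05`).
#' @param d_diversity batch members closer than this to each other are
#'   penalized (default `d_min`).
#' @param d_alignment designs closer than this to any alignment record are
#'   penalized (default `d_min`).
#' @param lambda_target,lambda_diversity,lambda_alignment penalty weights.
#' @param beta_start,beta_end,n_sweeps linear annealing schedule of the
#'   inverse temperature; one sweep is `M * L` random single-site updates.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @param mode `"gibbs"`, `"greedy"` or `"tempering"` (used by the CLI;
#'   the R functions are called directly).
#' @return a list of class `evh_design_config`.
#' @export
design_config <- function(M = 6L, d_min = 0.30, d_max = d_min + 0.05,
                          d_diversity = d_min, d_alignment = d_min,
                          lambda_target = 1000, lambda_diversity = 10,
                          lambda_alignment = 10,
                          beta_start = 0.5, beta_end = 10, n_sweeps = 1000L,
                          seed = NULL, mode = c("gibbs", "greedy", "tempering")) {
  mode <- match.arg(mode)
  stopifnot(M >= 1L, n_sweeps >= 1L,
            lambda_target >= 0, lambda_diversity >= 0, lambda_alignment >= 0,
            d_min >= 0, d_max <= 1, beta_start > 0, beta_end > 0)
  if (d_min >= d_max) stop("d_min must be strictly below d_max", call. = FALSE)
  structure(list(M = as.integer(M), d_min = d_min, d_max = d_max,
                 d_diversity = d_diversity, d_alignment = d_alignment,
                 lambda_target = lambda_target,
                 lambda_diversity = lambda_diversity,
                 lambda_alignment = lambda_alignment,
                 beta_start = beta_start, beta_end = beta_end,
                 n_sweeps = as.integer(n_sweeps), seed = seed, mode = mode),
            class = "evh_design_config")
}

#' @export
print.evh_design_config <- function(x, ...) {
  cat("<evh_design_config> M = ", x$M,
      ", D(target) in [", x$d_min, ", ", x$d_max, "]",
      ", lambda = (", x$lambda_target, ", ", x$lambda_diversity, ", ",
      x$lambda_alignment, ")",
      ", beta ", x$beta_start, " -> ", x$beta_end,
      " over ", x$n_sweeps, " sweeps\n", sep = "")
  invisible(x)
}

as_char_vec <- function(seq, alphabet) {
  if (is.character(seq) && length(seq) == 1L)
    return(alphabet[encode_seq(seq, alphabet)])
  if (is.numeric(seq)) return(alphabet[as.integer(seq)])
  as.character(seq)
}

#' Penalty terms of the design energy for one sequence
#'
#' The three constraint penalties entering a batch member's energy:
#' a target-band term `lambda_target * I(D(s, target) outside band) *
#' |D(s, target) - d_min|`, a batch-diversity term `lambda_diversity *`
#' (number of other batch members closer than `d_diversity`), and an
#' alignment term `lambda_alignment *` (number of alignment records closer
#' than `d_alignment`). Distances are normalized Hamming distances over the
#' focus columns.
#'
#' @param seq the sequence being scored (string or encoded).
#' @param batch_others other batch members: character vector (or list) of
#'   sequences; may be empty.
#' @param target_seq the target sequence; `NULL` drops the target term.
#' @param msa an [new_alignment()] (or character vector of rows); `NULL`
#'   drops the alignment term.
#' @param cfg a [design_config()].
#' @param alphabet symbol set used to encode string inputs.
#' @return named numeric vector `c(target, diversity, alignment)`.
#' @export
penalty_terms <- function(seq, batch_others = character(), target_seq = NULL,
                          msa = NULL, cfg = design_config(),
                          alphabet = aa_alphabet()) {
  s <- as_char_vec(seq, alphabet)
  tol <- 1e-9
  target <- 0
  if (!is.null(target_seq) && cfg$lambda_target > 0) {
    D <- normalized_hamming(s, as_char_vec(target_seq, alphabet))
    outside <- D < cfg$d_min - tol || D > cfg$d_max + tol
    target <- cfg$lambda_target * as.numeric(outside) * abs(D - cfg$d_min)
  }
  diversity <- 0
  if (length(batch_others) > 0 && cfg$lambda_diversity > 0) {
    dd <- vapply(batch_others,
                 function(b) normalized_hamming(s, as_char_vec(b, alphabet)),
                 numeric(1))
    diversity <- cfg$lambda_diversity * sum(dd < cfg$d_diversity - tol)
  }
  alignment <- 0
  if (!is.null(msa) && cfg$lambda_alignment > 0) {
    rows <- if (inherits(msa, "evh_alignment")) msa$rows else as.character(msa)
    da <- vapply(rows, function(b) normalized_hamming(s, as_char_vec(b, alphabet)),
                 numeric(1))
    alignment <- cfg$lambda_alignment * sum(da < cfg$d_alignment - tol)
  }
  c(target = target, diversity = diversity, alignment = alignment)
}

#' Batch design energy
#'
#' Per-member energy `U(s_a) = -EVH(s_a) + penalties` and the total batch
#' energy `sum_a U(s_a)`. Because the diversity penalty of a pair of batch
#' members appears in both members' `U`, each offending unordered pair
#' contributes twice to the total, matching the joint objective the sampler
#' targets.
#'
#' @param batch character vector (or list) of `M` sequences of length `L`.
#' @param model an [potts_model()].
#' @inheritParams penalty_terms
#' @return a list with `members` (a tibble: member, evh, target_pen,
#'   diversity_pen, alignment_pen, U) and `total`.
#' @export
batch_energy <- function(batch, model, target_seq = NULL, msa = NULL,
                         cfg = design_config()) {
  batch <- lapply(batch, as_char_vec, alphabet = model$alphabet)
  rows <- lapply(seq_along(batch), function(a) {
    pen <- penalty_terms(batch[[a]], batch[-a], target_seq, msa, cfg,
                         alphabet = model$alphabet)
    e <- evh(model, paste(batch[[a]], collapse = ""))
    tibble::tibble(member = a, evh = e,
                   target_pen = pen[["target"]],
                   diversity_pen = pen[["diversity"]],
                   alignment_pen = pen[["alignment"]],
                   U = -e + sum(pen))
  })
  members <- dplyr::bind_rows(rows)
  list(members = members, total = sum(members$U))
}

prep_design_inputs <- function(model, cfg, target_seq, msa) {
  if (cfg$d_min >= 1)
    stop("infeasible constraints: d_min must be below 1", call. = FALSE)
  tgt <- if (is.null(target_seq)) model$target_seq
         else encode_seq(target_seq, model$alphabet)
  if (is.null(tgt) && cfg$lambda_target > 0)
    stop("a target sequence is required when lambda_target > 0", call. = FALSE)
  if (!is.null(tgt) && length(tgt) != model$L)
    stop("target sequence length != model L", call. = FALSE)
  msaX <- matrix(integer(), 0L, model$L)
  if (!is.null(msa)) {
    rows <- if (inherits(msa, "evh_alignment")) msa$rows else as.character(msa)
    msaX <- encode_rows(rows, model$alphabet)
    if (ncol(msaX) != model$L)
      stop("alignment width != model L", call. = FALSE)
  }
  aa_states <- match(aa_alphabet(gap = FALSE), model$alphabet)
  aa_states <- sort(aa_states[!is.na(aa_states)])
  if (length(aa_states) < 2L)
    stop("model alphabet contains fewer than two amino-acid states", call. = FALSE)
  list(target = tgt, msaX = msaX, propose = aa_states)
}

random_batch <- function(M, L, propose) {
  matrix(propose[sample.int(length(propose), M * L, replace = TRUE)], M, L)
}

#' Generate a batch of designs by annealed penalized Gibbs sampling
#'
#' Each of the `M` batch members starts from an independent uniformly random
#' amino-acid sequence of length `L`. The sampler then performs `n_sweeps`
#' batch sweeps (one sweep = `M * L` single-site updates at random (member,
#' position) pairs), resampling the chosen site from the conditional
#' distribution `p(x) proportional to exp(-beta * U_total)` over the 20
#' amino acids, while the inverse temperature ramps linearly from
#' `beta_start` to `beta_end`. Runs are fully reproducible from `cfg$seed`.
#'
#' @param model an [potts_model()].
#' @param cfg a [design_config()].
#' @param target_seq target sequence; defaults to the model's stored target.
#' @param msa an [new_alignment()] of known homologs for the alignment
#'   penalty; `NULL` disables that term.
#' @return an object of class `evh_design`: sequences, per-member energies
#'   and penalty breakdown, per-sweep traces, constraint flags, and the
#'   config/seed snapshot.
#' @export
design_batch <- function(model, cfg = design_config(), target_seq = NULL,
                         msa = NULL) {
  stopifnot(inherits(model, "evh_potts"), inherits(cfg, "evh_design_config"))
  inp <- prep_design_inputs(model, cfg, target_seq, msa)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  init <- random_batch(cfg$M, model$L, inp$propose)
  beta_sched <- seq(cfg$beta_start, cfg$beta_end, length.out = cfg$n_sweeps)
  res <- cpp_gibbs_design(
    model$h, model$J,
    if (is.null(inp$target)) integer() else inp$target - 1L,
    inp$msaX - 1L, init - 1L, inp$propose - 1L, beta_sched,
    cfg$d_min, cfg$d_max, cfg$d_diversity, cfg$d_alignment,
    cfg$lambda_target, cfg$lambda_diversity, cfg$lambda_alignment,
    FALSE
  )
  finalize_design(model, cfg, inp, res, beta_sched)
}

finalize_design <- function(model, cfg, inp, res, beta_sched) {
  seqs <- apply(res$batch + 1L, 1, decode_seq, alphabet = model$alphabet)
  names(seqs) <- sprintf("design_%d", seq_along(seqs))
  tgt_chr <- if (is.null(inp$target)) NULL else decode_seq(inp$target, model$alphabet)
  msa_rows <- if (nrow(inp$msaX) > 0)
    apply(inp$msaX, 1, decode_seq, alphabet = model$alphabet) else NULL
  en <- batch_energy(seqs, model, tgt_chr, msa_rows, cfg)
  flags <- design_flags(seqs, tgt_chr, msa_rows, cfg)
  structure(
    list(sequences = seqs,
         energies = en$members,
         total_U = en$total,
         trace = tibble::tibble(sweep = seq_along(beta_sched),
                                beta = beta_sched, total_U = res$trace_U),
         flags = flags, config = cfg, seed = cfg$seed),
    class = "evh_design"
  )
}

design_flags <- function(seqs, target, msa_rows, cfg) {
  tol <- 1e-9
  d_t <- if (is.null(target)) rep(NA_real_, length(seqs))
         else vapply(seqs, normalized_hamming, numeric(1), b = target)
  d_b <- vapply(seq_along(seqs), function(a) {
    if (length(seqs) == 1L) return(NA_real_)
    min(vapply(seqs[-a], normalized_hamming, numeric(1), a = seqs[[a]]))
  }, numeric(1))
  d_m <- if (is.null(msa_rows)) rep(NA_real_, length(seqs))
         else vapply(seqs, function(s)
           min(vapply(msa_rows, normalized_hamming, numeric(1), a = s)),
           numeric(1))
  tibble::tibble(
    member = seq_along(seqs),
    dist_target = d_t,
    min_dist_batch = d_b,
    min_dist_msa = d_m,
    target_band_ok = is.na(d_t) |
      (d_t >= cfg$d_min - tol & d_t <= cfg$d_max + tol),
    batch_diverse_ok = is.na(d_b) | d_b >= cfg$d_diversity - tol,
    msa_distant_ok = is.na(d_m) | d_m >= cfg$d_alignment - tol
  )
}

#' @export
print.evh_design <- function(x, ...) {
  cat("<evh_design> batch of ", length(x$sequences), " sequences, ",
      nrow(x$trace), " sweeps\n", sep = "")
  print(dplyr::left_join(x$energies, x$flags, by = "member"))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.evh_design <- function(x, ...) {
  dplyr::mutate(
    dplyr::left_join(x$energies, x$flags, by = "member"),
    id = names(x$sequences), sequence = unname(x$sequences),
    .before = 1
  )
}

#' @export
#' @importFrom generics glance
glance.evh_design <- function(x, ...) {
  tibble::tibble(
    M = length(x$sequences), n_sweeps = nrow(x$trace),
    total_U = x$total_U,
    all_constraints_ok = all(x$flags$target_band_ok &
                             x$flags$batch_diverse_ok &
                             x$flags$msa_distant_ok),
    seed = x$seed %||% NA_integer_
  )
}

#' Exact Gibbs conditional at one site (reference path)
#'
#' The conditional distribution the batch sampler draws from, computed by
#' brute force: for each candidate amino acid at `(member, position)` the
#' full batch energy is recomputed and `p(x) proportional to
#' exp(-beta * U_total(x))`. This is the slow reference implementation used
#' to verify the incremental sampler; `gibbs_update()` draws one symbol from
#' it and returns the updated batch.
#'
#' @param model an [potts_model()].
#' @param batch character vector of current batch sequences.
#' @param member,position the site being resampled (1-based).
#' @param beta inverse temperature (> 0).
#' @inheritParams design_batch
#' @return `gibbs_conditional()`: named probability vector over the 20 amino
#'   acids; `gibbs_update()`: the batch with the resampled symbol.
#' @export
gibbs_conditional <- function(model, batch, member, position, beta = 1,
                              cfg = design_config(), target_seq = NULL,
                              msa = NULL) {
  stopifnot(beta > 0)
  aas <- intersect(aa_alphabet(gap = FALSE), model$alphabet)
  U <- vapply(aas, function(x) {
    b <- vapply(batch, as_char_vec, character(model$L), alphabet = model$alphabet)
    b <- t(b)  # members in rows
    b[member, position] <- x
    batch_energy(apply(b, 1, paste, collapse = ""), model,
                 target_seq, msa, cfg)$total
  }, numeric(1))
  p <- exp(-beta * (U - min(U)))
  p / sum(p)
}

#' @rdname gibbs_conditional
#' @export
gibbs_update <- function(model, batch, member, position, beta = 1,
                         cfg = design_config(), target_seq = NULL,
                         msa = NULL) {
  p <- gibbs_conditional(model, batch, member, position, beta, cfg,
                         target_seq, msa)
  sym <- sample(names(p), 1L, prob = p)
  ch <- as_char_vec(batch[[member]], model$alphabet)
  ch[position] <- sym
  batch[[member]] <- paste(ch, collapse = "")
  batch
}

#' Greedy EVH maximization
#'
#' Starting from `start_seq`, repeatedly evaluates all `L x 19` single
#' amino-acid substitutions and applies the one with the largest strictly
#' positive EVH gain, stopping at a local optimum (no substitution improves
#' EVH). Ties are broken by position, then alphabet order. Deterministic.
#'
#' @param model an [potts_model()].
#' @param start_seq starting sequence (default: the model's target).
#' @param max_steps safety cap on accepted mutations (default `10 * L`).
#' @return a list with `sequence`, `evh`, `n_steps`, and the accepted-move
#'   `path` tibble.
#' @export
greedy_design <- function(model, start_seq = NULL, max_steps = NULL) {
  if (is.null(start_seq)) start_seq <- model$target_seq
  if (is.null(start_seq)) stop("no start sequence given", call. = FALSE)
  s <- encode_seq(start_seq, model$alphabet)
  if (length(s) != model$L) stop("start sequence length != model L", call. = FALSE)
  if (is.null(max_steps)) max_steps <- 10L * model$L
  aa_states <- sort(match(aa_alphabet(gap = FALSE), model$alphabet))
  aa_states <- aa_states[!is.na(aa_states)]
  path <- list()
  for (step in seq_len(max_steps)) {
    scan <- cpp_mutation_scan(model$h, model$J, s - 1L, aa_states - 1L)
    best <- which.max(scan$delta)  # first maximum: (position, alphabet) order
    if (scan$delta[best] <= 0) break
    pos <- scan$pos[best] + 1L
    path[[step]] <- tibble::tibble(
      step = step, position = pos,
      wt = model$alphabet[s[pos]],
      mut = model$alphabet[scan$state[best] + 1L],
      delta_evh = scan$delta[best])
    s[pos] <- scan$state[best] + 1L
  }
  list(sequence = decode_seq(s, model$alphabet),
       evh = evh(model, s),
       n_steps = length(path),
       path = if (length(path)) dplyr::bind_rows(path)
              else tibble::tibble(step = integer(), position = integer(),
                                  wt = character(), mut = character(),
                                  delta_evh = numeric()))
}

#' Global EVH maximization by annealed parallel tempering
#'
#' Runs coupled Gibbs chains ("replicas") at a ladder of inverse
#' temperatures, by default 19 replicas initialized with linear spacing on
#' `[0.1, 1.0]`; after sweep `i` every replica's inverse temperature is its
#' initial value times `growth^i` (default `1.002`). Adjacent replicas
#' attempt a Metropolis configuration swap each sweep. Chains are
#' unconstrained — they target `exp(beta * EVH)` over the 20 amino acids —
#' and the best-EVH sequence ever visited is returned.
#'
#' @param model an [potts_model()].
#' @param n_replicas number of replicas (>= 2 for swaps; 1 reduces to a
#'   plain Gibbs chain).
#' @param beta_range initial inverse-temperature range, linearly spaced.
#' @param growth per-sweep multiplicative schedule on all betas.
#' @param n_sweeps number of Gibbs sweeps (one sweep = `L` updates per
#'   replica).
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return a list of class `evh_tempering`: `sequence`, `evh`,
#'   `trace_best_evh`, plus the final replica states.
#' @export
tempering_design <- function(model, n_replicas = 19L, beta_range = c(0.1, 1.0),
                             growth = 1.002, n_sweeps = 1000L, seed = NULL) {
  stopifnot(inherits(model, "evh_potts"), n_replicas >= 1L, n_sweeps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  aa_states <- sort(match(aa_alphabet(gap = FALSE), model$alphabet))
  aa_states <- aa_states[!is.na(aa_states)]
  init <- random_batch(n_replicas, model$L, aa_states)
  beta0 <- if (n_replicas == 1L) beta_range[1]
           else seq(beta_range[1], beta_range[2], length.out = n_replicas)
  res <- cpp_tempering(model$h, model$J, init - 1L, beta0, growth,
                       as.integer(n_sweeps), aa_states - 1L)
  structure(
    list(sequence = decode_seq(res$best_seq + 1L, model$alphabet),
         evh = res$best_evh,
         trace_best_evh = as.numeric(res$trace_best_evh),
         final_replicas = apply(res$final + 1L, 1, decode_seq,
                                alphabet = model$alphabet),
         final_evh = as.numeric(res$final_evh),
         n_replicas = n_replicas, growth = growth, seed = seed),
    class = "evh_tempering"
  )
}

#' @export
print.evh_tempering <- function(x, ...) {
  cat("<evh_tempering> ", x$n_replicas, " replicas, best EVH = ",
      format(x$evh, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Write designed sequences as FASTA
#'
#' Headers carry `evh=`, `identity_to_target=` (when a target is known) and
#' `seed=` fields.
#'
#' @param design an `evh_design` from [design_batch()].
#' @param path output FASTA path.
#' @param target_seq target used for the identity field (optional).
#' @export
write_designs <- function(design, path, target_seq = NULL) {
  ids <- vapply(seq_along(design$sequences), function(a) {
    id <- sprintf("%s evh=%.6g", names(design$sequences)[a],
                  design$energies$evh[a])
    if (!is.null(target_seq)) {
      idy <- 1 - normalized_hamming(design$sequences[[a]], target_seq)
      id <- sprintf("%s identity_to_target=%.4f", id, idy)
    }
    if (!is.null(design$seed)) id <- sprintf("%s seed=%d", id, design$seed)
    id
  }, character(1))
  writeLines(as.vector(rbind(paste0(">", ids), unname(design$sequences))), path)
  invisible(path)
}

#' Write a design-run manifest (JSON) and trace (TSV)
#'
#' @param design an `evh_design`.
#' @param manifest_path JSON output path.
#' @param trace_path optional TSV output path for the per-sweep trace.
#' @export
write_design_manifest <- function(design, manifest_path, trace_path = NULL) {
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("evhdesign")),
         config = unclass(design$config),
         seed = design$seed,
         sequences = as.list(design$sequences),
         flags = design$flags),
    manifest_path, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(trace_path))
    utils::write.table(design$trace, trace_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(manifest_path)
}
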