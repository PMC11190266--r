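#' Coupling-strength scores and average-product correction
#'
#' `coupling_scores()` summarizes each coupling block as the Frobenius norm
#' of `J_ij` over the amino-acid (non-gap) states; `correction = "apc"`
#' additionally applies the average-product correction,
#' `S_ij - rowmean_i * rowmean_j / grandmean`, the standard background
#' correction before contact ranking. `apc()` applies the correction to any
#' square matrix and annihilates rank-one matrices exactly.
#'
#' @param model an [potts_model()].
#' @param correction `"apc"` (default) or `"none"`.
#' @return an `L x L` symmetric matrix with zero diagonal and a
#'   `score` attribute (`"fn"` or `"fn_apc"`).
#' @export
coupling_scores <- function(model, correction = c("apc", "none")) {
  correction <- match.arg(correction)
  aa_states <- match(aa_alphabet(gap = FALSE), model$alphabet)
  aa_states <- aa_states[!is.na(aa_states)]
  if (length(aa_states) == 0L) aa_states <- seq_len(model$q)
  L <- model$L
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      S[i, j] <- S[j, i] <- sqrt(sum(model$J[i, j, aa_states, aa_states]^2))
    }
  }
  if (correction == "apc") S <- apc(S)
  attr(S, "score") <- if (correction == "apc") "fn_apc" else "fn"
  S
}

#' @rdname coupling_scores
#' @param S a square numeric matrix of raw scores.
#' @export
apc <- function(S) {
  gm <- mean(S)
  if (gm == 0) return(S)
  rm <- rowMeans(S); cm <- colMeans(S)
  S - outer(rm, cm) / gm
}

#' Tidy pair scores
#'
#' @param scores matrix from [coupling_scores()].
#' @param min_sep keep pairs at least this far apart in sequence.
#' @return tibble (i, j, score) with `i < j`, sorted by decreasing score.
#' @export
pair_score_table <- function(scores, min_sep = 1L) {
  L <- nrow(scores)
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  out <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                        score = scores[idx])
  out <- dplyr::filter(out, abs(.data$j - .data$i) >= min_sep)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$i, .data$j)
}

#' Precision of top-ranked couplings against known contacts
#'
#' Takes the `top_n` highest-scoring position pairs separated by at least
#' `min_sep` positions in primary sequence and reports the fraction present
#' in the supplied contact set.
#'
#' @param scores matrix from [coupling_scores()].
#' @param contacts two-column matrix/data frame of unordered focus-position
#'   pairs (1-based).
#' @param top_n number of top pairs to evaluate (often `L`).
#' @param min_sep minimum primary-sequence separation (default 5).
#' @return a fraction in `[0, 1]`.
#' @export
contact_precision <- function(scores, contacts, top_n, min_sep = 5L) {
  tab <- pair_score_table(scores, min_sep = min_sep)
  if (top_n > nrow(tab))
    stop("top_n = ", top_n, " exceeds the ", nrow(tab),
         " available pairs at min_sep = ", min_sep, call. = FALSE)
  top <- tab[seq_len(top_n), ]
  ckey <- pair_key(contacts[[1]], contacts[[2]])
  mean(pair_key(top$i, top$j) %in% ckey)
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Compare a mutation-effect scan with a deep mutational scan
#'
#' Spearman rank correlation between predicted effects and each
#' replicate's measured fitness scores over the intersection of
#' (position, mutant) keys. Tied values receive average ranks.
#'
#' @param scan a tibble from [mutation_matrix()].
#' @param dms a DMS table: columns `position`, `wt`, `mut`, plus one numeric
#'   column per replicate.
#' @return tibble (replicate, spearman, n).
#' @export
dms_compare <- function(scan, dms) {
  reps <- setdiff(names(dms), c("position", "wt", "mut"))
  if (length(reps) == 0L) stop("DMS table has no replicate columns", call. = FALSE)
  merged <- dplyr::inner_join(
    dplyr::select(scan, "position", "mut", "delta_evh"),
    dms, by = c("position", "mut"))
  if (nrow(merged) == 0L)
    stop("no (position, mut) keys shared between scan and DMS table",
         call. = FALSE)
  if (nrow(merged) < 3L)
    stop("need at least 3 matched mutations, found ", nrow(merged),
         call. = FALSE)
  dplyr::bind_rows(lapply(reps, function(r) {
    ok <- stats::complete.cases(merged$delta_evh, merged[[r]])
    tibble::tibble(
      replicate = r,
      spearman = stats::cor(merged$delta_evh[ok], merged[[r]][ok],
                            method = "spearman"),
      n = sum(ok))
  }))
}

#' Flag mutations with a measured fitness defect
#'
#' A mutation is flagged when its fitness score is strictly below `cutoff`
#' in at least one replicate (the conventional rule: a score below -1 in any
#' replicate marks a roughly tenfold fitness drop).
#'
#' @inheritParams dms_compare
#' @param cutoff defect threshold (default -1).
#' @return the DMS table with a logical `flagged` column.
#' @export
fitness_defect_flags <- function(dms, cutoff = -1.0) {
  reps <- setdiff(names(dms), c("position", "wt", "mut"))
  scores <- as.matrix(dms[reps])
  dplyr::mutate(dms,
                flagged = apply(scores < cutoff, 1, any, na.rm = TRUE))
}

#' Summary table of a set of designs
#'
#' Per design: mutation count versus the wild type over focus columns,
#' percent identity to the wild type, maximum percent identity over the
#' alignment records, EVH, and EVH difference from the wild type.
#'
#' @param model an [potts_model()].
#' @param designs named character vector of design sequences (length `L`).
#' @param wt wild-type sequence; defaults to the model's stored target.
#' @param msa optional [new_alignment()] of natural homologs.
#' @return a tibble, one row per design.
#' @export
design_summary <- function(model, designs, wt = NULL, msa = NULL) {
  if (is.null(wt)) wt <- decode_seq(model$target_seq, model$alphabet)
  wt_chr <- as_char_vec(wt, model$alphabet)
  L <- model$L
  evh_wt <- evh(model, wt)
  ids <- names(designs) %||% sprintf("design_%d", seq_along(designs))
  dplyr::bind_rows(lapply(seq_along(designs), function(k) {
    d <- normalized_hamming(designs[[k]], wt)
    max_id <- if (is.null(msa)) NA_real_ else
      1 - min(vapply(msa$rows, normalized_hamming, numeric(1),
                     a = designs[[k]]))
    e <- evh(model, designs[[k]])
    tibble::tibble(
      id = ids[k],
      n_mutations = as.integer(round(d * L)),
      identity_wt = 100 * (1 - d),
      max_identity_msa = 100 * max_id,
      evh = e,
      delta_evh_wt = e - evh_wt)
  }))
}

#' Background dependence of design mutations (quadrant analysis)
#'
#' For every position where a design differs from the wild type, the same
#' substitution (wild-type symbol to design symbol) is scored in both
#' backgrounds: its EVH change when introduced into the wild type, and its
#' EVH change when introduced into the design-with-that-site-reverted (i.e.
#' the effect of the design symbol in the design background). Each mutation
#' is then assigned a quadrant by the sign pair: Q1 positive in the design
#' background and negative in the wild type, Q2 positive in both, Q3
#' negative in the design and positive in the wild type, Q4 negative in
#' both ("positive" means strictly greater than zero).
#'
#' @param model an [potts_model()].
#' @param wt,design sequences of length `L`.
#' @return a list of class `evh_quadrants`: `mutations` (per-mutation
#'   tibble) and `percentages` (per-quadrant tibble; percentages sum to 100
#'   when any mutations exist). `design == wt` yields empty tables.
#' @export
quadrant_analysis <- function(model, wt, design) {
  w <- encode_seq(wt, model$alphabet)
  d <- encode_seq(design, model$alphabet)
  stopifnot(length(w) == model$L, length(d) == model$L)
  pos <- which(w != d)
  mut_tbl <- dplyr::bind_rows(lapply(pos, function(i) {
    dw <- delta_evh(model, w, list(c(i, d[i])))
    dd <- -delta_evh(model, d, list(c(i, w[i])))
    tibble::tibble(position = i,
                   wt = model$alphabet[w[i]], mut = model$alphabet[d[i]],
                   delta_wt_background = dw,
                   delta_design_background = dd,
                   quadrant = quadrant_of(dw, dd))
  }))
  if (length(pos) == 0L)
    mut_tbl <- tibble::tibble(position = integer(), wt = character(),
                              mut = character(),
                              delta_wt_background = numeric(),
                              delta_design_background = numeric(),
                              quadrant = character())
  counts <- table(factor(mut_tbl$quadrant, levels = paste0("Q", 1:4)))
  pct <- tibble::tibble(
    quadrant = names(counts),
    n = as.integer(counts),
    percent = if (length(pos)) 100 * as.integer(counts) / length(pos)
              else rep(NA_real_, 4))
  structure(list(mutations = mut_tbl, percentages = pct),
            class = "evh_quadrants")
}

quadrant_of <- function(delta_wt, delta_design) {
  pos_w <- delta_wt > 0; pos_d <- delta_design > 0
  if (pos_d && !pos_w) "Q1"
  else if (pos_d && pos_w) "Q2"
  else if (!pos_d && pos_w) "Q3"
  else "Q4"
}

#' @export
print.evh_quadrants <- function(x, ...) {
  cat("<evh_quadrants> ", nrow(x$mutations), " mutations\n", sep = "")
  print(x$percentages)
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.evh_quadrants <- function(x, ...) x$mutations

#' Reversion scan of a design
#'
#' For every mutated position, the EVH change of reverting the design
#' symbol back to the wild-type symbol in the design background. For a
#' well-optimized design these reversions are predominantly unfavorable.
#'
#' @inheritParams quadrant_analysis
#' @return a tibble (position, wt, mut, delta_evh, background_id) where
#'   `wt` is the design's symbol (the scan background) and `mut` the
#'   wild-type symbol being restored.
#' @export
reversion_scan <- function(model, wt, design) {
  w <- encode_seq(wt, model$alphabet)
  d <- encode_seq(design, model$alphabet)
  stopifnot(length(w) == model$L, length(d) == model$L)
  pos <- which(w != d)
  if (length(pos) == 0L)
    return(tibble::tibble(position = integer(), wt = character(),
                          mut = character(), delta_evh = numeric(),
                          background_id = character()))
  dplyr::bind_rows(lapply(pos, function(i) {
    tibble::tibble(position = i,
                   wt = model$alphabet[d[i]],
                   mut = model$alphabet[w[i]],
                   delta_evh = delta_evh(model, d, list(c(i, w[i]))),
                   background_id = "design")
  }))
}

#' EVH of random mutants of a sequence
#'
#' Draws `n` sequences, each carrying `k` substitutions at distinct random
#' positions to random non-wild-type amino acids, and returns their EVH.
#' This is the random-mutagenesis baseline against which designed sequences
#' are compared.
#'
#' @param model an [potts_model()].
#' @param wt background sequence.
#' @param k number of mutations per sample (`0 <= k <= L`).
#' @param n number of samples.
#' @param seed RNG seed; `NULL` leaves the RNG state untouched.
#' @return tibble (sample, n_mutations, evh).
#' @export
random_mutation_baseline <- function(model, wt, k, n = 100L, seed = NULL) {
  w <- encode_seq(wt, model$alphabet)
  stopifnot(k >= 0, k <= model$L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  aa_states <- sort(match(aa_alphabet(gap = FALSE), model$alphabet))
  aa_states <- aa_states[!is.na(aa_states)]
  X <- matrix(rep(w, each = n), nrow = n)
  if (k > 0) {
    for (r in seq_len(n)) {
      pos <- sample.int(model$L, k)
      for (i in pos) {
        choices <- setdiff(aa_states, w[i])
        X[r, i] <- choices[sample.int(length(choices), 1L)]
      }
    }
  }
  tibble::tibble(sample = seq_len(n), n_mutations = as.integer(k),
                 evh = evh_many(model, X))
}

#' Reverse-translate a designed protein with codon-usage matching
#'
#' Unchanged residues keep the wild-type codon. Changed residues receive the
#' synonymous codon for the new amino acid whose usage frequency is closest
#' to the wild-type codon's frequency (minimizing the translation-efficiency
#' perturbation); ties are broken by alphabetical codon order.
#'
#' @param protein designed protein sequence (no gaps).
#' @param wt_dna wild-type coding DNA; must translate to a protein of the
#'   same length as `protein`.
#' @param usage codon usage table: a data frame with columns `codon` (DNA,
#'   e.g. "CTG") and `frequency`.
#' @return a DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, wt_dna, usage) {
  protein <- toupper(protein)
  wt_dna <- toupper(gsub("U", "T", wt_dna))
  p <- strsplit(protein, "", fixed = TRUE)[[1]]
  if (nchar(wt_dna) != 3L * length(p))
    stop("wt_dna length (", nchar(wt_dna), ") != 3 x protein length (",
         3L * length(p), ")", call. = FALSE)
  codons <- substring(wt_dna, seq(1, nchar(wt_dna), 3), seq(3, nchar(wt_dna), 3))
  gc <- Biostrings::GENETIC_CODE
  wt_aa <- unname(gc[codons])
  if (anyNA(wt_aa) || any(wt_aa == "*"))
    stop("wt_dna contains an invalid or stop codon", call. = FALSE)
  freq <- stats::setNames(usage$frequency, toupper(gsub("U", "T", usage$codon)))
  out <- character(length(p))
  for (i in seq_along(p)) {
    if (p[i] == wt_aa[i]) {
      out[i] <- codons[i]
    } else {
      syn <- sort(names(gc)[gc == p[i]])  # alphabetical for the tie rule
      syn <- syn[syn %in% names(freq)]    # restrict to the supplied table
      if (length(syn) == 0L)
        stop("usage table has no codon for residue '", p[i], "'",
             call. = FALSE)
      fs <- freq[syn]
      wt_f <- freq[codons[i]]
      if (is.na(wt_f))
        stop("usage table is missing wild-type codon ", codons[i], call. = FALSE)
      out[i] <- syn[which.min(abs(fs - wt_f))]
    }
  }
  paste(out, collapse = "")
}

#' Read a codon usage table (TSV: codon, frequency)
#' @param path file path.
#' @return tibble (codon, frequency).
#' @export
read_codon_usage <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read a contact list (TSV: i, j; 1-based focus numbering)
#' @param path file path.
#' @return tibble (i, j).
#' @export
read_contacts <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Read a DMS table (TSV: position, wt, mut, one column per replicate)
#' @param path file path.
#' @return tibble.
#' @export
read_dms <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}
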