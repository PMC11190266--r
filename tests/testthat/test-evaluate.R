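test_that("coupling scores are symmetric, non-negative, and rank constructions correctly", {
  z <- potts_model(matrix(0, 6, 4), array(0, dim = c(6, 6, 4, 4)),
                   alphabet = c("A", "C", "D", "E"))
  expect_true(all(coupling_scores(z, correction = "none") == 0))

  m <- random_model(L = 8, q = 4, seed = 70)
  S <- coupling_scores(m, correction = "none")
  expect_identical(S, t(S))
  expect_true(all(S >= 0))
  expect_true(all(diag(S) == 0))

  # a single nonzero block dominates the ranking
  q <- 4
  J <- array(0, dim = c(6, 6, q, q))
  J[1, 2, , ] <- matrix(rnorm(q * q), q, q); J[2, 1, , ] <- t(J[1, 2, , ])
  m1 <- potts_model(matrix(0, 6, q), J, alphabet = c("A", "C", "D", "E"),
                    enforce = FALSE)
  tab <- pair_score_table(coupling_scores(m1, correction = "none"))
  expect_equal(c(tab$i[1], tab$j[1]), c(1, 2))
})

test_that("the average-product correction annihilates rank-one matrices", {
  set.seed(71)
  u <- abs(rnorm(12)) + 0.1
  S <- outer(u, u)
  expect_lt(max(abs(apc(S))), 1e-9)
})

test_that("contact precision counts top-ranked pairs inside the contact set", {
  set.seed(72)
  L <- 20
  S <- matrix(0, L, L)
  planted <- cbind(c(1, 2, 3), c(8, 12, 15))
  for (k in 1:3) S[planted[k, 1], planted[k, 2]] <-
      S[planted[k, 2], planted[k, 1]] <- 10 - k
  expect_equal(contact_precision(S, as.data.frame(planted), top_n = 3), 1)
  disjoint <- data.frame(i = c(4, 5), j = c(11, 13))
  expect_equal(contact_precision(S, disjoint, top_n = 3), 0)
  expect_error(contact_precision(S, disjoint, top_n = 1e6), "exceeds")
  # pairs closer than min_sep never enter the ranking
  S2 <- S; S2[1, 2] <- S2[2, 1] <- 100
  expect_equal(contact_precision(S2, as.data.frame(planted), top_n = 3,
                                 min_sep = 5), 1)
})

test_that("DMS comparison is a rank correlation, invariant to monotone transforms", {
  m <- random_model(L = 8, q = 4, seed = 73)
  wt <- rep(1L, 8)
  scan <- mutation_matrix(m, wt)
  dms <- dplyr::mutate(dplyr::select(scan, position, wt, mut),
                       r1 = exp(scan$delta_evh / 2),        # monotone up
                       r2 = -rank(scan$delta_evh))          # monotone down
  out <- dms_compare(scan, dms)
  expect_equal(out$spearman, c(1, -1))
  expect_equal(out$n, rep(nrow(scan), 2))

  # noisy scores: agrees with an independent rank/product-moment oracle
  set.seed(74)
  noisy <- dplyr::mutate(dplyr::select(dms, position, wt, mut),
                         r1 = scan$delta_evh + rnorm(nrow(scan), sd = 1))
  rho_pkg <- dms_compare(scan, noisy)$spearman
  merged <- dplyr::inner_join(scan, noisy, by = c("position", "mut"))
  expect_equal(rho_pkg, oracle_spearman(merged$delta_evh, merged$r1),
               tolerance = 1e-12)
  expect_gt(rho_pkg, 0)

  expect_error(dms_compare(scan, dms[0, ]), "shared")
})

test_that("fitness defects require a score strictly below the cutoff in some replicate", {
  dms <- tibble::tibble(position = 1:3, wt = "A", mut = c("C", "D", "E"),
                        r1 = c(-1.5, -0.9, -1.0),
                        r2 = c(0.2, -0.99, -0.5))
  out <- fitness_defect_flags(dms)
  expect_equal(out$flagged, c(TRUE, FALSE, FALSE))
})

test_that("design summaries report mutation counts, identities and EVH", {
  m <- random_model(L = 20, q = 4, seed = 75)
  wt <- strrep("A", 20)
  msa <- sample_msa(m, 10, method = "gibbs", seed = 76)
  d1 <- paste0(strrep("C", 5), strrep("A", 15))  # 5 mutations, 75% identity
  out <- design_summary(m, c(wt = wt, d1 = d1), wt = wt, msa = msa)
  expect_equal(out$n_mutations, c(0L, 5L))
  expect_equal(out$identity_wt, c(100, 75))
  expect_equal(out$delta_evh_wt, c(0, evh(m, d1) - evh(m, wt)))
  # max identity over the alignment equals the brute-force scan
  brute <- 100 * (1 - min(vapply(msa$rows, normalized_hamming, numeric(1),
                                 a = d1)))
  expect_equal(out$max_identity_msa[2], brute)
  # mutation counts are L x normalized Hamming distance, exactly
  expect_equal(out$n_mutations,
               as.integer(20 * vapply(c(wt, d1), normalized_hamming,
                                      numeric(1), b = wt)))
})

test_that("quadrant analysis scores the same substitution in both backgrounds", {
  # constructed sign epistasis: mutation 1:A->C is bad in the wt background
  # but good when position 3 carries the design residue D
  q <- 3
  h <- matrix(0, 4, q)
  J <- array(0, dim = c(4, 4, q, q))
  J[1, 3, 2, 3] <- 2;  J[3, 1, 3, 2] <- 2    # C at 1 with D at 3: favorable
  J[1, 3, 2, 1] <- -1; J[3, 1, 1, 2] <- -1   # C at 1 with wt A at 3: bad
  J[1, 3, 1, 3] <- -0.5; J[3, 1, 3, 1] <- -0.5
  m <- potts_model(h, J, alphabet = c("A", "C", "D"), enforce = FALSE)
  wt <- "AAAA"; design <- "CADA"
  qa <- quadrant_analysis(m, wt, design)
  expect_equal(nrow(qa$mutations), 2)
  m1 <- qa$mutations[qa$mutations$position == 1, ]
  # verified by direct EVH arithmetic
  expect_equal(m1$delta_wt_background, evh(m, "CAAA") - evh(m, "AAAA"))
  expect_equal(m1$delta_design_background, evh(m, "CADA") - evh(m, "AADA"))
  expect_lt(m1$delta_wt_background, 0)
  expect_gt(m1$delta_design_background, 0)
  expect_equal(m1$quadrant, "Q1")
  expect_equal(sum(qa$percentages$percent), 100)

  # design == wt: empty summary, not an error
  empty <- quadrant_analysis(m, wt, wt)
  expect_equal(nrow(empty$mutations), 0)
})

test_that("reversion deltas match delta_evh in the design background", {
  m <- random_model(L = 6, q = 4, seed = 77)
  wt <- "AAAAAA"; design <- "ACADAC"
  rev <- reversion_scan(m, wt, design)
  expect_equal(nrow(rev), 3)
  d <- encode_seq(design, m$alphabet)
  for (r in seq_len(nrow(rev))) {
    expect_equal(rev$delta_evh[r],
                 delta_evh(m, d, list(c(rev$position[r], rev$mut[r]))),
                 tolerance = 1e-12)
  }
  # field-only model: reversion delta is minus the forward delta
  mf <- potts_model(m$h, array(0, dim = dim(m$J)), alphabet = m$alphabet)
  revf <- reversion_scan(mf, wt, design)
  fwd <- vapply(revf$position, function(i)
    delta_evh(mf, encode_seq(wt, mf$alphabet),
              list(c(i, encode_seq(design, mf$alphabet)[i]))), numeric(1))
  expect_equal(revf$delta_evh, -fwd, tolerance = 1e-12)
  expect_equal(nrow(reversion_scan(m, wt, wt)), 0)
})

test_that("quadrant assignment and reversion scan are mutually consistent", {
  m <- random_model(L = 8, q = 4, seed = 78)
  wt <- strrep("A", 8)
  design <- "CCAADDAA"
  qa <- quadrant_analysis(m, wt, design)
  rev <- reversion_scan(m, wt, design)
  merged <- dplyr::inner_join(qa$mutations, rev, by = "position",
                              suffix = c("", "_rev"))
  q2 <- merged[merged$quadrant %in% c("Q1", "Q2"), ]
  expect_true(all(q2$delta_evh < 0))  # reverting a design-favorable site hurts
  expect_equal(merged$delta_evh, -merged$delta_design_background,
               tolerance = 1e-9)
})

test_that("random mutant baselines are seeded and degrade a fitted optimum", {
  m <- planted_model(L = 12, q = 8, n_edges = 0, field_scale = 2, seed = 79)
  wt <- greedy_design(m, strrep("A", 12))$sequence  # field optimum
  b0 <- random_mutation_baseline(m, wt, k = 0, n = 20, seed = 1)
  expect_equal(b0$evh, rep(evh(m, wt), 20))
  b1 <- random_mutation_baseline(m, wt, k = 10, n = 50, seed = 2)
  b2 <- random_mutation_baseline(m, wt, k = 10, n = 50, seed = 2)
  expect_identical(b1, b2)
  expect_lt(mean(b1$evh), evh(m, wt))
  # never mutates to the background symbol
  expect_true(all(b1$n_mutations == 10))
})

test_that("reverse translation keeps wild-type codons and matches usage frequency", {
  usage <- tibble::tibble(
    codon = c("CTG", "GTG", "GTT", "GTC", "GTA", "GCG", "GCC"),
    frequency = c(0.50, 0.37, 0.26, 0.22, 0.15, 0.30, 0.70))
  # unchanged protein: DNA returned verbatim
  expect_equal(reverse_translate("LV", "CTGGTG", usage), "CTGGTG")
  # Leu(CTG, 0.50) -> Val: GTG has the closest frequency (0.37)
  expect_equal(reverse_translate("VV", "CTGGTG", usage), "GTGGTG")
  # tie broken by alphabetical codon order
  usage2 <- tibble::tibble(codon = c("AAA", "GGA", "GGG"),
                           frequency = c(0.5, 0.4, 0.6))
  expect_equal(reverse_translate("G", "AAA", usage2), "GGA")
  expect_error(reverse_translate("LVX", "CTGGTG", usage), "protein length")
})
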