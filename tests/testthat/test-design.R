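test_that("design config validates its bounds", {
  cfg <- design_config()
  expect_equal(cfg$M, 6L)                # default batch size
  expect_equal(cfg$d_max, cfg$d_min + 0.05)
  expect_equal(cfg$d_diversity, cfg$d_min)
  expect_error(design_config(d_min = 0.5, d_max = 0.4), "d_min")
  expect_error(design_config(d_min = 1), "d_max|d_min")
  expect_error(design_config(M = 0))
})

test_that("penalty terms reproduce the stated arithmetic", {
  cfg <- design_config(d_min = 0.30)
  tgt <- strrep("A", 10)
  # sequence equal to the target: outside the band, |0 - 0.30| * 1000
  p1 <- penalty_terms(tgt, character(), tgt, NULL, cfg)
  expect_equal(unname(p1["target"]), 300)
  # two identical batch members: 10 per offending neighbor
  p2 <- penalty_terms(tgt, c(tgt, tgt), NULL, NULL, cfg)
  expect_equal(unname(p2["diversity"]), 20)
  # inside the band, far from batch and alignment: all zero
  s <- paste0(strrep("C", 3), strrep("A", 7))  # D = 0.3 to target
  p3 <- penalty_terms(s, strrep("D", 10), tgt, strrep("E", 10), cfg)
  expect_equal(unname(p3), c(0, 0, 0))
  # D = 0.32-band membership via a 25-long sequence: 8/25 = 0.32
  tgt25 <- strrep("A", 25)
  s25 <- paste0(strrep("C", 8), strrep("A", 17))
  expect_equal(unname(penalty_terms(s25, character(), tgt25, NULL, cfg)["target"]), 0)
})

test_that("batch energy combines EVH and penalties, double-counting pairs", {
  m <- random_model(L = 8, q = 4, seed = 1)
  seqs <- c("ACDAACDA", "CCDDAACD")
  cfg0 <- design_config(lambda_target = 0, lambda_diversity = 0,
                        lambda_alignment = 0)
  en0 <- batch_energy(seqs, m, cfg = cfg0)
  expect_equal(en0$members$U, -en0$members$evh)
  expect_equal(en0$total, -sum(en0$members$evh))

  # zero model, zero penalties: U identically zero
  z <- potts_model(matrix(0, 8, 21), array(0, dim = c(8, 8, 21, 21)))
  expect_equal(batch_energy(seqs, z, cfg = cfg0)$members$U, c(0, 0))

  # member equal to the target with a band that includes zero distance
  cfg_in <- design_config(d_min = 0, d_max = 0.05, lambda_diversity = 0,
                          lambda_alignment = 0)
  en1 <- batch_energy(seqs[1], m, target_seq = seqs[1], cfg = cfg_in)
  expect_equal(en1$total, -evh(m, seqs[1]))

  # identical members are mutually penalized: pair counted in both U's
  cfgd <- design_config(lambda_target = 0, lambda_alignment = 0,
                        lambda_diversity = 10, d_min = 0.3)
  en2 <- batch_energy(c(seqs[1], seqs[1]), m, cfg = cfgd)
  expect_equal(en2$members$diversity_pen, c(10, 10))
  expect_equal(en2$total, -2 * evh(m, seqs[1]) + 20)
})

test_that("the incremental sampler energy equals recomputation from scratch", {
  m <- planted_model(L = 12, q = 8, n_edges = 10, min_sep = 2, seed = 3)
  tgt <- sample_msa(m, 1, method = "gibbs", seed = 4)$rows[[1]]
  msa <- sample_msa(m, 8, method = "gibbs", seed = 5)
  cfg <- design_config(M = 3, d_min = 0.25, n_sweeps = 40, seed = 6)
  d <- design_batch(m, cfg, target_seq = tgt, msa = msa)
  en <- batch_energy(d$sequences, m, target_seq = tgt, msa = msa$rows, cfg = cfg)
  expect_equal(d$trace$total_U[cfg$n_sweeps], en$total, tolerance = 1e-9)
  expect_equal(d$total_U, en$total, tolerance = 1e-9)
})

test_that("the Gibbs conditional is the softmax of the batch energy", {
  # flat energy: uniform over the 20 amino acids
  z <- potts_model(matrix(0, 4, 21), array(0, dim = c(4, 4, 21, 21)))
  cfg0 <- design_config(lambda_target = 0, lambda_diversity = 0,
                        lambda_alignment = 0)
  p <- gibbs_conditional(z, c("AAAA", "CCCC"), member = 1, position = 2,
                         beta = 1, cfg = cfg0)
  expect_equal(unname(p), rep(1 / 20, 20))

  # L = 1, two states, h = (0, log 2): probabilities (1/3, 2/3)
  m1 <- potts_model(matrix(c(0, log(2)), 1, 2),
                    array(0, dim = c(1, 1, 2, 2)), alphabet = c("A", "C"))
  p1 <- gibbs_conditional(m1, "A", member = 1, position = 1, beta = 1,
                          cfg = cfg0)
  expect_equal(unname(p1), c(1 / 3, 2 / 3))

  # gibbs_update only changes the chosen site
  set.seed(1)
  out <- gibbs_update(m1, "A", 1, 1, beta = 1, cfg = cfg0)
  expect_true(out[[1]] %in% c("A", "C"))
})

test_that("pooled sampler frequencies match the exact penalized equilibrium", {
  # two batch members under a diversity penalty at fixed beta: the exact
  # joint is enumerable and the factor-2 pair convention is observable
  m <- random_model(L = 3, q = 3, seed = 7, coupling_sd = 0.3)
  cfg <- design_config(M = 2, lambda_target = 0, lambda_alignment = 0,
                       lambda_diversity = 3, d_diversity = 0.4,
                       beta_start = 1, beta_end = 1, n_sweeps = 30000, seed = 8)
  X <- enumerate_states(m)
  e <- apply(X, 1, function(s) evh(m, s))
  n_st <- nrow(X)
  # joint energy with the pair penalty counted in both members
  D <- outer(seq_len(n_st), seq_len(n_st), Vectorize(function(a, b)
    mean(X[a, ] != X[b, ])))
  Uj <- outer(-e, -e, "+") + 2 * cfg$lambda_diversity * (D < cfg$d_diversity - 1e-9)
  Pj <- exp(-(Uj - min(Uj))); Pj <- Pj / sum(Pj)
  marg <- rowSums(Pj)

  inp <- evhdesign:::prep_design_inputs(m, cfg, NULL, NULL)
  set.seed(cfg$seed)
  init <- evhdesign:::random_batch(cfg$M, m$L, inp$propose)
  res <- evhdesign:::cpp_gibbs_design(
    m$h, m$J, integer(), matrix(integer(), 0, m$L) - 1L, init - 1L,
    inp$propose - 1L, rep(1, cfg$n_sweeps),
    cfg$d_min, cfg$d_max, cfg$d_diversity, cfg$d_alignment,
    0, cfg$lambda_diversity, 0, TRUE)
  emp <- res$state_counts / sum(res$state_counts)
  expect_lt(tv_dist(emp, marg), 0.05)
})

test_that("raising the target penalty cannot favor band violations", {
  m <- random_model(L = 4, q = 3, seed = 9)
  tgt <- "AAAA"
  prob_violation <- function(lt) {
    cfg <- design_config(d_min = 0.25, d_max = 0.5, lambda_target = lt,
                         lambda_diversity = 0, lambda_alignment = 0)
    p <- oracle_penalized_boltzmann(m, beta = 1, cfg, tgt)
    X <- enumerate_states(m)
    d <- apply(X, 1, function(s) mean(m$alphabet[s] != strsplit(tgt, "")[[1]]))
    sum(p[d < 0.25 - 1e-9 | d > 0.5 + 1e-9])
  }
  pv <- vapply(c(0, 1, 5, 20), prob_violation, numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
})

test_that("design runs are reproducible from seed and feasibility is checked", {
  m <- planted_model(L = 15, q = 8, n_edges = 10, min_sep = 2, seed = 10)
  tgt <- sample_msa(m, 1, method = "gibbs", seed = 11)$rows[[1]]
  cfg <- design_config(M = 4, d_min = 0.2, n_sweeps = 60, seed = 123)
  d1 <- design_batch(m, cfg, target_seq = tgt)
  d2 <- design_batch(m, cfg, target_seq = tgt)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$trace$total_U, d2$trace$total_U)
  expect_equal(nrow(d1$trace), 60)
  expect_error(design_batch(m, design_config(M = 2)), "target")
  # designs propose only amino acids, never gaps
  expect_false(any(grepl("-", d1$sequences, fixed = TRUE)))
})

test_that("greedy design equals the exhaustive hill-climb oracle", {
  for (seed in 1:10) {
    m <- random_model(L = 5, q = 3, seed = 400 + seed)
    start <- decode_seq(sample.int(3, 5, replace = TRUE), m$alphabet)
    g <- greedy_design(m, start)
    expect_identical(g$sequence, oracle_hill_climb(m, start))
  }
})

test_that("greedy design stops at local optima and on flat landscapes", {
  m <- random_model(L = 4, q = 3, seed = 500)
  bz <- enumerate_boltzmann(m, beta = 1)
  opt <- decode_seq(enumerate_states(m)[which.max(bz$evh), ], m$alphabet)
  g <- greedy_design(m, opt)
  expect_identical(g$sequence, opt)
  expect_equal(g$n_steps, 0L)

  z <- potts_model(matrix(0, 4, 21), array(0, dim = c(4, 4, 21, 21)))
  expect_identical(greedy_design(z, "ACDE")$sequence, "ACDE")
})

test_that("tempering is seed-reproducible and a single replica samples the chain", {
  m <- two_basin_model(L = 6)
  t1 <- tempering_design(m, n_replicas = 4, n_sweeps = 100, seed = 2)
  t2 <- tempering_design(m, n_replicas = 4, n_sweeps = 100, seed = 2)
  expect_identical(t1$sequence, t2$sequence)
  expect_identical(t1$trace_best_evh, t2$trace_best_evh)

  # one replica at fixed beta reduces to plain Gibbs on exp(beta * EVH):
  # final states across independent runs follow the Boltzmann distribution
  ms <- random_model(L = 3, q = 2, seed = 600, coupling_sd = 0.5)
  bz <- enumerate_boltzmann(ms, beta = 1)
  X <- enumerate_states(ms)
  key <- apply(X, 1, paste, collapse = "")
  set.seed(7)
  finals <- vapply(1:600, function(k) {
    td <- tempering_design(ms, n_replicas = 1, beta_range = c(1, 1),
                           growth = 1, n_sweeps = 60)
    paste(encode_seq(td$final_replicas[[1]], ms$alphabet), collapse = " ")
  }, character(1))
  emp <- as.numeric(table(factor(finals, levels = apply(X, 1, paste, collapse = " ")))) / 600
  expect_lt(tv_dist(emp, bz$prob), 0.12)
})

test_that("design outputs serialize as FASTA, manifest and trace", {
  m <- planted_model(L = 10, q = 8, n_edges = 5, min_sep = 2, seed = 20)
  tgt <- sample_msa(m, 1, method = "gibbs", seed = 21)$rows[[1]]
  cfg <- design_config(M = 2, d_min = 0.2, n_sweeps = 30, seed = 22)
  d <- design_batch(m, cfg, target_seq = tgt)
  fa <- tempfile(fileext = ".fa"); js <- tempfile(fileext = ".json")
  tr <- tempfile(fileext = ".tsv")
  write_designs(d, fa, target_seq = tgt)
  lines <- readLines(fa)
  expect_true(all(grepl("evh=", lines[c(1, 3)])))
  expect_true(all(grepl("identity_to_target=", lines[c(1, 3)])))
  write_design_manifest(d, js, tr)
  man <- jsonlite::fromJSON(js)
  expect_equal(man$seed, 22)
  expect_equal(nrow(read.table(tr, header = TRUE, sep = "\t")), 30)
  # tidy/glance surfaces
  td <- generics::tidy(d)
  expect_true(all(c("id", "sequence", "evh", "U", "target_band_ok") %in% names(td)))
  expect_equal(nrow(td), 2)
  expect_s3_class(generics::glance(d), "tbl_df")
})
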