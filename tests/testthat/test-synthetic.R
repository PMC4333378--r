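ref64 <- fixture_reference()

test_that("an all-zero model copies the template faithfully", {
  m0 <- polymerase_error_model(matrix(0, 4, 4))
  pool <- simulate_synthesis(m0, ref64, 30, seed = 1)
  expect_equal(nrow(pool$events), 0)
  expect_true(all(pool_reads(pool)$sequence == ref64$sequence))
})

test_that("seed determinism: identical inputs give identical outputs", {
  m <- primpol_lacz_model(total_rate = 1e-3)
  p1 <- simulate_synthesis(m, ref64, 5000, seed = 42)
  p2 <- simulate_synthesis(m, ref64, 5000, seed = 42)
  expect_identical(p1$events, p2$events)
  expect_identical(pool_reads(p1, 1:50), pool_reads(p2, 1:50))
  cfg <- assay_sim_config(expression_p = 0.3, background_mf = 1e-4,
                          n_sequenced = 20, seed = 7)
  r1 <- simulate_colony_assay(p1, cfg)
  r2 <- simulate_colony_assay(p2, cfg)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$reads, r2$reads)
})

test_that("substitution-only mutant fraction matches 1-(1-r)^L", {
  r <- 1e-3
  L <- nchar(ref64$sequence)
  m <- polymerase_error_model(matrix(r / 3, 4, 4))
  n <- 20000
  pool <- simulate_synthesis(m, ref64, n, seed = 5)
  frac <- length(unique(pool$events$molecule)) / n
  p_true <- 1 - (1 - r)^L
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(frac - p_true), 3 * se)
})

test_that("slippage concentrates indels in the homopolymer run", {
  growth <- 1.5
  base <- 1e-4
  m <- polymerase_error_model(matrix(0, 4, 4), indel_rate = base,
                              slippage_base = base,
                              slippage_growth = growth,
                              insertion_fraction = 0.5)
  n <- 50000
  pool <- simulate_synthesis(m, ref64, n, seed = 9)
  runs <- polfid:::homopolymer_runs(ref64$sequence)
  t8 <- runs[runs$length == 8L, ]
  in_run <- pool$events$position >= t8$start & pool$events$position <= t8$end
  # compare per-site observed rates; configured ratio is growth^(8-2)
  short_runs <- runs[runs$length >= 2 & runs$length < 8, ]
  in_short <- rep(FALSE, nrow(pool$events))
  for (k in seq_len(nrow(short_runs)))
    in_short <- in_short | (pool$events$position >= short_runs$start[k] &
                              pool$events$position <= short_runs$end[k])
  k_run <- sum(in_run)
  k_out <- sum(!in_run & !in_short)
  sites_out <- nchar(ref64$sequence) - 8L - sum(short_runs$length)
  rate_run <- k_run / (8 * n)
  rate_out <- k_out / (sites_out * n)
  ratio <- rate_run / rate_out
  true_ratio <- growth^6
  # Poisson-propagated 3-SE band on the log ratio
  se_log <- sqrt(1 / k_run + 1 / k_out)
  expect_lt(abs(log(ratio) - log(true_ratio)), 3 * se_log)
})

test_that("scrunching injects complex events inside hairpin regions", {
  hp <- data.frame(start = 20L, end = 30L)
  m <- polymerase_error_model(matrix(0, 4, 4), scrunch_rate = 0.2,
                              hairpin_regions = hp)
  pool <- simulate_synthesis(m, ref64, 2000, seed = 13)
  expect_true(all(pool$events$scrunch))
  expect_true(all(pool$events$position >= 20 & pool$events$position <= 30))
  # each affected molecule carries >= 2 sub-events within <= 10 nt,
  # so the calling pipeline labels the group complex
  ids <- unique(pool$events$molecule)
  expect_true(length(ids) > 0)
  reads <- pool_reads(pool, ids[1:20])
  ev <- call_mutations(ref64, reads)
  expect_true(all(ev$is_complex))
  # frequency of affected molecules matches scrunch_rate within 3 SE
  frac <- length(ids) / 2000
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
})

test_that("colony screening implements the phenotype and background model", {
  # zero-error products, zero background: no mutants
  m0 <- polymerase_error_model(matrix(0, 4, 4))
  p0 <- simulate_synthesis(m0, ref64, 500, seed = 2)
  r0 <- simulate_colony_assay(p0, assay_sim_config(expression_p = 1,
                                                   background_mf = 0))
  expect_equal(r0$counts$mutant_colonies, 0)
  expect_equal(r0$counts$total_colonies, 500)

  # every product with a detectable event, expression 1: all score mutant
  ev_all <- data.frame(molecule = 1:200, kind = "substitution",
                       position = 5L, ref_allele = "C", alt_allele = "T",
                       length = 1L, scrunch = FALSE,
                       stringsAsFactors = FALSE)
  pool_all <- structure(list(reference = ref64, n = 200L, events = ev_all,
                             model = m0), class = "mutant_pool")
  r_all <- simulate_colony_assay(pool_all,
                                 assay_sim_config(expression_p = 1))
  expect_equal(r_all$counts$mutant_colonies, 200)

  # events outside the detectable mask never score
  r_mask <- simulate_colony_assay(pool_all,
                                  assay_sim_config(expression_p = 1,
                                                   detectable = 40:64))
  expect_equal(r_mask$counts$mutant_colonies, 0)

  # oversampling requests fall back to all phenotypic mutants, with warning
  expect_warning(simulate_colony_assay(pool_all,
                                       assay_sim_config(expression_p = 1,
                                                        n_sequenced = 999)),
                 "phenotypic")
})

test_that("simulated mutant frequency matches q*P + (1-q*P)*background", {
  r <- 2e-3
  L <- nchar(ref64$sequence)
  m <- polymerase_error_model(matrix(r / 3, 4, 4))
  n <- 200000
  P <- 0.5; bg <- 1e-3
  pool <- simulate_synthesis(m, ref64, n, seed = 17)
  res <- simulate_colony_assay(pool, assay_sim_config(expression_p = P,
                                                      background_mf = bg,
                                                      seed = 18))
  q <- 1 - (1 - r)^L
  # phenotypic term qP plus background over the (1 - qP) remainder
  p_exp <- q * P + (1 - q * P) * bg
  obs <- res$counts$mutant_colonies / n
  expect_lt(abs(obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("recovered error rate is unbiased over repeat simulations", {
  # scaled-down version of the full recovery harness: 20 runs at n = 1e5
  true_rate <- 1e-4
  D <- 147L
  refD <- reference_target(random_seq(D))
  m <- polymerase_error_model(matrix(true_rate / 3, 4, 4))
  params <- gap_assay_params(D = D, P = 0.3, NiN = 1)
  n <- 100000
  est <- vapply(1:20, function(k) {
    pool <- simulate_synthesis(m, refD, n, seed = 1000 + k)
    res <- simulate_colony_assay(pool, assay_sim_config(
      expression_p = 0.3, background_mf = 1.7e-5, seed = 2000 + k))
    recover_error_rate(res, params)
  }, 0)
  expect_lt(abs(mean(est) - true_rate) / true_rate, 0.05)
  # empirical SD within a factor 2 of the binomial prediction
  pm <- (1 - (1 - true_rate)^D) * 0.3 + 1.7e-5
  sd_pred <- sqrt(pm * (1 - pm) / n) / (D * 0.3)
  expect_lt(sd(est) / sd_pred, 2)
  expect_gt(sd(est) / sd_pred, 0.5)
  # doubling the rate doubles the estimate in expectation
  m2 <- polymerase_error_model(matrix(2 * true_rate / 3, 4, 4))
  est2 <- vapply(1:5, function(k) {
    pool <- simulate_synthesis(m2, refD, n, seed = 3000 + k)
    res <- simulate_colony_assay(pool, assay_sim_config(
      expression_p = 0.3, background_mf = 1.7e-5, seed = 4000 + k))
    recover_error_rate(res, params)
  }, 0)
  expect_lt(abs(mean(est2) / mean(est) - 2), 0.3)
})

test_that("zero-rate simulation recovers zero after background correction", {
  m0 <- polymerase_error_model(matrix(0, 4, 4))
  pool <- simulate_synthesis(m0, ref64, 50000, seed = 6)
  res <- simulate_colony_assay(pool, assay_sim_config(
    expression_p = 0.3, background_mf = 1.7e-5, seed = 7))
  est <- recover_error_rate(res, gap_assay_params(64, 0.3, 1))
  # only background colonies arise; after correction the estimate stays
  # below the 99.99% binomial envelope of pure background
  k_max <- stats::qbinom(0.9999, 50000, 1.7e-5)
  expect_lte(est, (k_max / 50000 - 1.7e-5) / (64 * 0.3))
})

test_that("model validation rejects bad parameters", {
  expect_error(polymerase_error_model(matrix(2, 4, 4)), "\\[0, 1\\]")
  expect_error(polymerase_error_model(matrix(0, 4, 4),
                                      slippage_growth = 0.5), ">= 1")
  expect_error(polymerase_error_model(matrix(0, 2, 2)), "4x4")
  # per-site total probability must stay < 1 on the concrete reference
  m <- polymerase_error_model(matrix(0.4, 4, 4))
  expect_error(simulate_synthesis(m, ref64, 10), "< 1")
  expect_error(assay_sim_config(expression_p = 0), "expression_p")
})
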