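test_that("rate matrix has GY structure, zero row sums and detailed balance", {
  f <- equal_freqs()
  Q <- build_rate_matrix(f, kappa = 1, omega = 1)
  off <- Q[row(Q) != col(Q)]
  expect_true(all(abs(off[off > 0] - off[off > 0][1]) < 1e-12))
  expect_equal(-sum(f * diag(Q)), 1, tolerance = 1e-12)

  set.seed(21)
  for (i in 1:5) {
    kappa <- runif(1, 0.3, 10)
    omega <- runif(1, 0.01, 5)
    fr <- protamine_like_freqs()
    Q <- build_rate_matrix(fr, kappa, omega)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # reversibility: pi_i q_ij == pi_j q_ji
    flux <- fr * Q
    expect_lt(max(abs(flux - t(flux))), 1e-15)
    # multi-nucleotide changes have zero rate
    pt <- protsel:::.code_env$pair_type
    expect_true(all(Q[pt == 0L & row(Q) != col(Q)] == 0))
  }
})

test_that("transition probabilities are a stochastic semigroup", {
  f <- protamine_like_freqs()
  Q <- build_rate_matrix(f, 2, 0.4)
  P0 <- transition_probabilities(Q, 0, f)
  expect_equal(P0, diag(61), ignore_attr = TRUE, tolerance = 1e-10)
  P <- transition_probabilities(Q, 0.3, f)
  expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-12)
  expect_true(all(P >= 0))
  P2 <- transition_probabilities(Q, 0.6, f)
  expect_lt(max(abs(P %*% P - P2)), 1e-10)
  Pinf <- transition_probabilities(Q, 500, f)
  expect_lt(max(abs(sweep(Pinf, 2, f))), 1e-8)
  expect_error(transition_probabilities(Q, NA_real_, f), "finite")
  expect_error(transition_probabilities(Q, -1, f), ">= 0")
})

test_that("pruning likelihood equals brute-force enumeration on small cases", {
  tr <- toy_tree3()
  f <- equal_freqs()
  spec <- codon_model_spec(2.5, f, 0.6)
  sim <- simulate_codon_alignment(tr, spec, 5, seed = 42)
  expect_lt(abs(log_likelihood(sim$alignment, tr, spec) -
                brute_force_loglik(sim$alignment, tr, spec)), 1e-10)

  # mixture model, different frequencies
  spec2 <- codon_model_spec(1.5, protamine_like_freqs(),
                            m1a_spec(0.7, 0.2))
  sim2 <- simulate_codon_alignment(tr, spec2, 4, seed = 43)
  expect_lt(abs(log_likelihood(sim2$alignment, tr, spec2) -
                brute_force_loglik(sim2$alignment, tr, spec2)), 1e-10)
})

test_that("single-taxon likelihood reduces to log equilibrium frequencies", {
  f <- protamine_like_freqs()
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- codon_alignment(c(A = "ATGAAA", B = "ATGAAA"))
  spec <- codon_model_spec(2, f, 0.5)
  # two identical tips at distance 0 from each other behave like one tip
  tr0 <- ape::read.tree(text = "(A:0,B:0);")
  ll <- log_likelihood(aln, tr0, spec)
  cods <- c("ATG", "AAA")
  expect_equal(ll, sum(log(f[cods])), tolerance = 1e-9)
})

test_that("site independence and taxon order invariance hold", {
  tr <- toy_tree4()
  f <- protamine_like_freqs()
  spec <- codon_model_spec(2, f, 0.7)
  sim <- simulate_codon_alignment(tr, spec, 20, seed = 7)
  aln <- sim$alignment
  ll <- log_likelihood(aln, tr, spec)
  # duplicating every column doubles lnL exactly
  dup <- codon_alignment(stats::setNames(apply(
    cbind(aln$codons, aln$codons), 1, paste0, collapse = ""), aln$taxa))
  expect_equal(log_likelihood(dup, tr, spec), 2 * ll, tolerance = 1e-8)
  # reordering taxa leaves lnL unchanged
  perm <- subset_taxa(aln, rev(aln$taxa))
  expect_equal(log_likelihood(perm, tr, spec), ll, tolerance = 1e-9)
})

test_that("expected branch dN/dS behaves like the neutral normalization says", {
  f <- protamine_like_freqs()
  for (kappa in c(1, 3)) {
    nd <- branch_expected_subs(f, kappa, 1, 0.37)
    expect_equal(unname(nd["dN"]), unname(nd["dS"]), tolerance = 1e-12)
    expect_equal(unname(nd["dN"]), 0.37, tolerance = 1e-12)
  }
  expect_equal(unname(branch_expected_subs(f, 2, 0.7, 0)), c(0, 0))
  # realized Gillespie counts match expectations within sampling error
  t <- 0.8; omega <- 0.5; kappa <- 2; n <- 1500
  counts <- simulate_branch_counts(f, kappa, omega, t, n, seed = 99)
  fc <- protsel:::.flux_consts(f)
  # expected raw counts per codon: t * flux fractions
  fluxS <- (fc["T1"] + kappa * fc["T2"])
  fluxN <- omega * (fc["T3"] + kappa * fc["T4"])
  tot <- fluxS + fluxN
  expS <- n * t * fluxS / tot
  expN <- n * t * fluxN / tot
  expect_lt(abs(counts$syn - expS), 3 * sqrt(expS))
  expect_lt(abs(counts$nonsyn - expN), 3 * sqrt(expN))
})

test_that("M0 fit recovers simulation truth and nesting holds", {
  tr <- toy_tree4()
  f <- protamine_like_freqs()
  spec <- codon_model_spec(2, f, 0.5)
  sim <- simulate_codon_alignment(tr, spec, 2000, seed = 13)
  m0 <- fit(sim$alignment, tr, "M0", branch_mode = "scale")
  expect_true(m0$converged)
  expect_lt(abs(m0$mles["omega"] - 0.5) / 0.5, 0.10)
  expect_lt(abs(m0$mles["kappa"] - 2) / 2, 0.10)
  # pinning omega at 1 can never beat the free fit
  m0_pin <- fit(sim$alignment, tr, "M0", branch_mode = "scale",
                fixed = list(omega = 1))
  expect_lte(m0_pin$lnL, m0$lnL + 1e-6)
  expect_equal(m0_pin$n_params + 1L, m0$n_params)
})

test_that("three optimizer starts agree in lnL on well-behaved data", {
  tr <- toy_tree4()
  spec <- codon_model_spec(2, protamine_like_freqs(), 0.4)
  sim <- simulate_codon_alignment(tr, spec, 300, seed = 17)
  f1 <- fit(sim$alignment, tr, "M0", branch_mode = "scale", n_starts = 1)
  f3 <- fit(sim$alignment, tr, "M0", branch_mode = "scale", n_starts = 3)
  expect_lt(abs(f1$lnL - f3$lnL), 1e-4)
})

test_that("data simulated under omega = 1 gives M0 estimates near 1", {
  tr <- toy_tree6()
  spec <- codon_model_spec(2, protamine_like_freqs(), 1)
  sim <- simulate_codon_alignment(tr, spec, 1500, seed = 19)
  m0 <- fit(sim$alignment, tr, "M0", branch_mode = "scale")
  expect_lt(abs(m0$mles["omega"] - 1), 0.1)
})
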