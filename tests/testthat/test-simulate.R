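test_that("simulation is deterministic given the seed", {
  tr <- toy_tree4()
  spec <- codon_model_spec(2, protamine_like_freqs(), 0.5)
  s1 <- simulate_codon_alignment(tr, spec, 50, seed = 81)
  s2 <- simulate_codon_alignment(tr, spec, 50, seed = 81)
  s3 <- simulate_codon_alignment(tr, spec, 50, seed = 82)
  expect_identical(s1$alignment$codons, s2$alignment$codons)
  expect_false(identical(s1$alignment$codons, s3$alignment$codons))
  expect_identical(s1$truth$site_class, s2$truth$site_class)

  t1 <- simulate_traits(tr, 2, -1, 0.5, 1, seed = 83)
  t2 <- simulate_traits(tr, 2, -1, 0.5, 1, seed = 83)
  expect_identical(t1, t2)
})

test_that("omega = 0 forbids amino-acid change", {
  tr <- toy_tree6()
  spec <- codon_model_spec(2, protamine_like_freqs(), 0)
  sim <- simulate_codon_alignment(tr, spec, 120, seed = 85)
  aa <- apply(sim$alignment$codons, c(1, 2), translate_codons)
  expect_true(all(apply(aa, 2, function(col) length(unique(col)) == 1)))
  # but synonymous change still happens
  expect_gt(sum(apply(sim$alignment$codons, 2,
                      function(col) length(unique(col)) > 1)), 0)
})

test_that("no stop codon is ever emitted and truth records the regime", {
  tr <- toy_tree4()
  mix <- m8_spec(0.8, 0.5, 1, 3, K = 6)
  spec <- codon_model_spec(3, protamine_like_freqs(), mix)
  sim <- simulate_codon_alignment(tr, spec, 200, seed = 87)
  expect_true(all(sim$alignment$codons %in% sense_codons()))
  expect_equal(sim$truth$model_id, "M8")
  expect_equal(length(sim$truth$site_class), 200)
  expect_equal(sim$truth$seed, 87)
})

test_that("simulator and likelihood are mutually consistent", {
  # average per-site lnL at the generating parameters beats perturbed ones
  tr <- toy_tree6()
  spec <- codon_model_spec(2, protamine_like_freqs(), 0.5)
  sim <- simulate_codon_alignment(tr, spec, 1200, seed = 89)
  ll_true <- log_likelihood(sim$alignment, tr, spec)
  for (om in c(0.2, 1.2)) {
    ll_pert <- log_likelihood(sim$alignment, tr,
                              codon_model_spec(2, protamine_like_freqs(), om))
    expect_gt(ll_true, ll_pert)
  }
})

test_that("trait simulation has the advertised covariance structure", {
  tr <- ape::drop.tip(cricetidae_tree(), c("MMU", "CGR", "SHI"))
  # huge alpha: noise is effectively independent across species
  xs <- sapply(1:300, function(i)
    simulate_traits(tr, 1e4, 0, 0, 1, seed = 90000 + i)$y[1:2])
  expect_lt(abs(stats::cor(xs[1, ], xs[2, ])), 0.15)
  # slope zero: mean fitted slope across replicates is near zero
  sl <- vapply(1:200, function(i) {
    td <- simulate_traits(tr, 10, 0, 0, 1, seed = 91000 + i)
    f <- pgls_fit(tr, stats::setNames(td$x, td$species),
                  stats::setNames(td$y, td$species))
    f$slope
  }, numeric(1))
  expect_lt(abs(mean(sl)), 0.05)
})

test_that("the fixture bundle round-trips and the positive fixture classifies", {
  d <- file.path(tempdir(), "fixtures_test")
  p <- make_fixture_set(d, seed = 4, Lc = 240)
  tr <- ape::read.tree(p$clade_tree)
  expect_equal(length(tr$tip.label), 16)
  site_tr <- ape::read.tree(p$site_tree)
  expect_equal(length(site_tr$tip.label), 17)
  for (nm in c("clade_positive", "clade_relaxed", "one_ratio")) {
    a <- read_fasta(p[[nm]])
    expect_equal(n_codons(a), 240)
    expect_equal(length(a$taxa), 16)
    truth <- jsonlite::read_json(p[[paste0(nm, "_truth")]])
    expect_equal(truth$Lc, 240)
  }
  traits <- utils::read.table(p$traits, header = TRUE, sep = "\t")
  expect_true(all(c("species", "body_mass_g", "testes_mass_g") %in%
                  names(traits)))
  expect_true(all(traits$body_mass_g > 0 & traits$testes_mass_g > 0))

  # end-to-end: the positive-regime fixture is labelled Positive
  aln <- read_fasta(p$clade_positive)
  suite <- fit_clade_suite(aln, tr, clade_fixture_foreground(),
                           branch_mode = "scale")
  dec <- classify_clade(suite$m1, suite$m2, suite$m3)
  expect_equal(dec$label, "Positive")
  expect_gt(dec$foreground_omega, 1)
})
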