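test_that("LRT verdicts follow the chi-square at 0.05 / 0.01", {
  v <- lrt_verdict(9.71, 2)
  expect_lt(v$p_value, 0.01)
  expect_equal(v$verdict, "**")
  v2 <- lrt_verdict(7.34, 2)
  expect_lt(v2$p_value, 0.05)
  expect_gte(v2$p_value, 0.01)
  expect_equal(v2$verdict, "*")
  v3 <- lrt_verdict(0, 2)
  expect_equal(v3$verdict, "ns")
  # small negative statistics clamp to zero
  expect_equal(lrt_verdict(-1e-8, 1)$two_delta_l, 0)
  expect_warning(lrt_verdict(-2, 1), "worse")
})

test_that("lrt() requires nested fits with more parameters in the alternative", {
  fake <- function(model_id, lnL, np) {
    structure(list(model_id = model_id, lnL = lnL, n_params = np),
              class = "codon_fit")
  }
  expect_error(lrt(fake("M1a", -100, 4), fake("M7", -99, 4)), "not nested")
  expect_error(lrt(fake("two_ratio", -100, 5), fake("two_ratio", -99, 5)),
               "more free parameters")
  r <- lrt(fake("M1a", -100, 4), fake("M2a", -95.145, 6))
  expect_equal(r$df, 2)
  expect_equal(r$two_delta_l, 9.71, tolerance = 1e-9)
  expect_equal(r$verdict, "**")
  # identical fits: ns
  expect_equal(lrt(fake("M7", -50, 4), fake("M8", -50, 6))$verdict, "ns")
})

test_that("the clade decision table is exhaustive and mutually exclusive", {
  combos <- expand.grid(sig13 = c(TRUE, FALSE), sig23 = c(TRUE, FALSE),
                        omega_gt1 = c(TRUE, FALSE))
  labels <- mapply(function(s1, s2, o)
    clade_rule(s1, s2, if (o) 2.4 else 0.4),
    combos$sig13, combos$sig23, combos$omega_gt1)
  expect_true(all(labels %in% c("Positive", "Relaxation", "None")))
  # the three printed cases
  expect_equal(clade_rule(TRUE, TRUE, 2.44), "Positive")
  expect_equal(clade_rule(TRUE, FALSE, 2.75), "Relaxation")
  expect_equal(clade_rule(TRUE, FALSE, 1.66), "Relaxation")
  # rule table corners
  expect_equal(clade_rule(FALSE, TRUE, 0.4), "None")
  expect_equal(clade_rule(TRUE, TRUE, 0.4), "None")
  expect_equal(clade_rule(FALSE, FALSE, 3), "None")
})

test_that("clade suite fits are nested and a null simulation shows no split", {
  tr <- toy_tree6()
  fg <- c("A", "B", "C", "D")
  spec <- codon_model_spec(2, protamine_like_freqs(), 0.4)
  sim <- simulate_codon_alignment(tr, spec, 400, seed = 23)
  suite <- fit_clade_suite(sim$alignment, tr, fg, branch_mode = "scale")
  expect_lte(suite$m1$lnL, suite$m3$lnL + 1e-6)
  expect_lte(suite$m2$lnL, suite$m3$lnL + 1e-6)
  # both omegas near the shared truth on one-ratio data
  expect_lt(abs(suite$m3$mles["omega_background"] -
                suite$m3$mles["omega_foreground"]), 0.35)
  dec <- classify_clade(suite$m1, suite$m2, suite$m3)
  expect_s3_class(dec, "clade_decision")
  expect_true(dec$label %in% c("None", "Relaxation"))
})

test_that("foreground = all branches collapses model 2 to the global omega-1 model", {
  tr <- toy_tree4()
  spec <- codon_model_spec(2, protamine_like_freqs(), 0.6)
  sim <- simulate_codon_alignment(tr, spec, 200, seed = 29)
  m2 <- fit(sim$alignment, tr, "two_ratio", foreground = tr$tip.label,
            fixed = list(omega_foreground = 1, omega_background = 0.123),
            branch_mode = "scale")
  m_global1 <- fit(sim$alignment, tr, "M0", fixed = list(omega = 1),
                   branch_mode = "scale")
  expect_equal(m2$lnL, m_global1$lnL, tolerance = 1e-4)
})

test_that("site posteriors normalize and class-3 flags obey model capability", {
  tr <- toy_tree6()
  spec <- codon_model_spec(2, protamine_like_freqs(),
                           m2a_spec(0.6, 0.35, 0.1, 3))
  sim <- simulate_codon_alignment(tr, spec, 150, seed = 31)
  f1 <- fit(sim$alignment, tr, "M1a", branch_mode = "scale")
  f2 <- fit(sim$alignment, tr, "M2a", branch_mode = "scale")
  p2 <- beb_classify(sim$alignment, tr, f2)
  s <- p2$sites
  expect_equal(s$p_class1 + s$p_class2 + s$p_class3, rep(1, nrow(s)),
               tolerance = 1e-8)
  expect_true(p2$class3_allowed)
  p1 <- beb_classify(sim$alignment, tr, f1)
  expect_false(p1$class3_allowed)
  expect_true(all(is.na(p1$sites$pp_class3)))
  expect_true(all(p1$sites$class %in% 1:2))
  summ1 <- summarize_site_classes(p1)
  expect_identical(summ1$pss, "not allowed")
  # BEB with a single grid point is exactly NEB
  neb <- beb_classify(sim$alignment, tr, f2, method = "neb")
  beb1 <- beb_classify(sim$alignment, tr, f2, grid_points = 1)
  expect_equal(beb1$sites$p_class3, neb$sites$p_class3, tolerance = 1e-12)
  expect_equal(beb1$sites$mean_omega, neb$sites$mean_omega,
               tolerance = 1e-12)
})

test_that("site class summaries count hand-assigned classes exactly", {
  mk_post <- function(classes, pp3 = NULL) {
    n <- length(classes)
    sites <- data.frame(
      site = seq_len(n),
      p_class1 = as.numeric(classes == 1),
      p_class2 = as.numeric(classes == 2),
      p_class3 = as.numeric(classes == 3),
      class = classes, mean_omega = 1, se_omega = 0,
      pp_class3 = if (is.null(pp3)) as.numeric(classes == 3) else pp3)
    sites$pp95 <- sites$pp_class3 > 0.95
    sites$pp99 <- sites$pp_class3 > 0.99
    structure(list(sites = sites, model_id = "M2a", method = "beb",
                   class3_allowed = TRUE), class = "site_posterior")
  }
  post <- mk_post(c(1, 1, 2, 2, 2, 3, 1, 2, 2, 1))
  summ <- summarize_site_classes(post)
  expect_equal(unname(summ$overall), c(40, 50, 10))
  # a 4-site region with classes 1,1,2,3 -> 50/25/25
  regions <- data.frame(type = "anchoring", start = 0L, end = 4L,
                        source = "configured")
  post2 <- mk_post(c(1, 1, 2, 3, 2, 2, 2, 2, 2, 2))
  s2 <- summarize_site_classes(post2, regions)
  expect_equal(s2$by_region$class1, 50)
  expect_equal(s2$by_region$class2, 25)
  expect_equal(s2$by_region$class3, 25)
  expect_error(summarize_site_classes(post2,
    data.frame(type = "x", start = 0L, end = 40L, source = "configured")),
    "outside")
  # the printed overall split is reproduced from a matching assignment
  cls <- rep(c(1, 2, 3), times = c(41, 51, 8))
  expect_equal(unname(summarize_site_classes(mk_post(cls))$overall),
               c(41, 51, 8))
  # positively selected sites get residue labels
  post3 <- mk_post(c(rep(1, 9), 3), pp3 = c(rep(0, 9), 0.995))
  s3 <- summarize_site_classes(post3, ref_aa = "MARRRRYYYV")
  expect_equal(s3$pss, "10V**")
})

test_that("site suite designates neutral models when selection is absent", {
  tr <- toy_tree6()
  spec <- codon_model_spec(2, protamine_like_freqs(), m1a_spec(0.63, 0.05))
  sim <- simulate_codon_alignment(tr, spec, 200, seed = 37)
  suite <- fit_site_suite(sim$alignment, tr, K = 8, branch_mode = "scale")
  expect_named(suite$fits, c("M0", "M1a", "M2a", "M7", "M8"))
  expect_equal(suite$lrt_m1a_m2a$df, 2)
  expect_equal(suite$lrt_m7_m8$df, 2)
  # within the optimizer lnL tolerance the alternative never falls below
  expect_gte(suite$fits$M2a$lnL, suite$fits$M1a$lnL - 5e-3)
  expect_gte(suite$fits$M8$lnL, suite$fits$M7$lnL - 5e-3)
  expect_true(grepl("neutral|beta", suite$designation))
})
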