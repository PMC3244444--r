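# ---- simulation-recovery study protocols -----------------------------------
# These functions define the package's recovery and calibration studies: data
# are simulated under a known regime seeded with the published point
# estimates, the corresponding model is refitted, and the recovered
# quantities are returned. They are the computational core of the
# analysis/ drivers and of scripts/acceptance.R.

#' Clade-model recovery study
#'
#' Simulates replicate codon alignments on the 16-taxon clade fixture tree
#' under the two-ratio model (all focal-clade branches at `omega_fg`,
#' background at `omega_bg`), refits the two-ratio model, and collects the
#' foreground omega MLEs.
#'
#' @param omega_fg true foreground (focal clade) omega.
#' @param omega_bg true background omega.
#' @param kappa true transition/transversion ratio.
#' @param Lc codons per alignment.
#' @param n_rep replicates.
#' @param seed base seed; replicate i uses `seed * 1000 + i`.
#' @param freqs generating codon frequencies (protamine-like by default).
#' @return List: `estimates` (length `n_rep`), `mean`, `truth`.
#' @export
recover_clade_omega <- function(omega_fg, omega_bg = 0.3, kappa = 2,
                                Lc = 800, n_rep = 20, seed = 1,
                                freqs = protamine_like_freqs()) {
  tr <- clade_fixture_tree()
  fg <- clade_fixture_foreground()
  part <- edge_partition(tr, fg)
  spec <- codon_model_spec(kappa, freqs,
                           c(background = omega_bg, foreground = omega_fg))
  est <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_codon_alignment(tr, spec, Lc, seed = seed * 1000 + i,
                                    edge_partition = part)
    f <- fit(sim$alignment, tr, "two_ratio", freq_model = "F3X4",
             foreground = fg, branch_mode = "scale",
             init = list(omega_background = 0.4, omega_foreground = 1))
    unname(f$mles["omega_foreground"])
  }, numeric(1))
  list(estimates = est, mean = mean(est), truth = omega_fg)
}

#' Site-model recovery studies (M8 selection omega, M1a proportions)
#'
#' Simulates alignments on the 17-taxon tree under M8 (or M1a), refits the
#' model, and collects the parameter of interest. Replicates after the first
#' are warm-started from the previous replicate's MLEs (same truth), which
#' speeds convergence without changing the estimator.
#'
#' @param p0,p,q,omega_s generating M8 parameters.
#' @param Lc codons per alignment.
#' @param n_rep replicates.
#' @param seed base seed.
#' @param K beta categories.
#' @return List: `estimates`, `mean`, `truth`.
#' @name site_recovery
NULL

#' @rdname site_recovery
#' @export
recover_m8_omega_s <- function(p0 = 0.58495, p = 0.0050, q = 0.04910,
                               omega_s = 2.65844, Lc = 500, n_rep = 10,
                               seed = 1, K = 10) {
  tr <- cricetidae_tree()
  spec <- codon_model_spec(2, protamine_like_freqs(),
                           m8_spec(p0, p, q, omega_s, K))
  warm <- list()
  est <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_codon_alignment(tr, spec, Lc, seed = seed * 2000 + i)
    f <- suppressWarnings(fit(sim$alignment, tr, "M8", K = K,
                              branch_mode = "scale", init = warm))
    warm <<- as.list(f$mles[c("kappa", "p0", "p", "q", "omega_s")])
    unname(f$mles["omega_s"])
  }, numeric(1))
  list(estimates = est, mean = mean(est), truth = omega_s)
}

#' @rdname site_recovery
#' @param omega0 generating M1a purifying-class omega.
#' @export
recover_m1a_p0 <- function(p0 = 0.63016, omega0 = 0.05, Lc = 500,
                           n_rep = 10, seed = 1) {
  tr <- cricetidae_tree()
  spec <- codon_model_spec(2, protamine_like_freqs(), m1a_spec(p0, omega0))
  warm <- list()
  est <- vapply(seq_len(n_rep), function(i) {
    sim <- simulate_codon_alignment(tr, spec, Lc, seed = seed * 3000 + i)
    f <- fit(sim$alignment, tr, "M1a", branch_mode = "scale", init = warm)
    warm <<- as.list(f$mles[c("kappa", "p0", "omega0")])
    unname(f$mles["p0"])
  }, numeric(1))
  list(estimates = est, mean = mean(est), truth = p0)
}

#' Type-I error calibration of the M1a-vs-M2a LRT
#'
#' Simulates null (M1a) data, fits M1a cold (a sloppy null fit would inflate
#' the statistic) and M2a warm-started from it, refitting the alternative
#' cold if it lands below the null, and reports the rejection rate at the
#' nominal level. The chi-square reference is expected to be conservative
#' here because the null pins parameters at the boundary of the
#' alternative's space.
#'
#' @param n_rep null replicates.
#' @param Lc codons per replicate.
#' @param p0,omega0 generating M1a parameters.
#' @param level nominal significance level.
#' @param seed base seed.
#' @return List: `rejections`, `n_rep`, `rate`.
#' @export
lrt_calibration_m1a_m2a <- function(n_rep = 200, Lc = 60, p0 = 0.63016,
                                    omega0 = 0.05, level = 0.05, seed = 1) {
  tr <- ape::read.tree(text = paste0(
    "(((A:0.05,B:0.05):0.03,C:0.07):0.03,(D:0.08,E:0.08):0.03);"))
  spec <- codon_model_spec(2, protamine_like_freqs(), m1a_spec(p0, omega0))
  rej <- 0L
  for (i in seq_len(n_rep)) {
    sim <- simulate_codon_alignment(tr, spec, Lc, seed = seed * 4000 + i)
    f1 <- suppressWarnings(fit(sim$alignment, tr, "M1a",
                               branch_mode = "scale"))
    f2 <- suppressWarnings(fit(
      sim$alignment, tr, "M2a", branch_mode = "scale",
      init = list(kappa = unname(f1$mles["kappa"]),
                  p0 = unname(f1$mles["p0"]),
                  omega0 = unname(f1$mles["omega0"]),
                  r1 = 0.95, omega2 = 1.2)))
    f2 <- .retry_if_below(f2, f1, sim$alignment, branch_mode = "scale")
    l <- suppressWarnings(lrt(f1, f2))
    if (l$p_value < level) rej <- rej + 1L
  }
  list(rejections = rej, n_rep = n_rep, rate = rej / n_rep)
}

#' pGLS correlation recovery study
#'
#' Simulates bivariate species data on a 14-taxon tree under the exponential
#' phylogenetic covariance with the standardized slope set so the true
#' whitened-space correlation equals `r`, fits the pGLS, and averages the
#' estimated correlations.
#'
#' @param r true correlation.
#' @param alpha true (and generating) covariance decay.
#' @param n_rep replicates.
#' @param seed base seed.
#' @return List: `estimates`, `mean`, `truth`.
#' @export
recover_pgls_correlation <- function(r, alpha, n_rep = 500, seed = 1) {
  tr <- ape::drop.tip(cricetidae_tree(), c("MMU", "CGR", "SHI"))
  sl <- slope_for_correlation(r)
  est <- vapply(seq_len(n_rep), function(i) {
    td <- simulate_traits(tr, alpha, sl, intercept = 1, noise_sd = 1,
                          seed = seed * 5000 + i)
    f <- pgls_fit(tr, stats::setNames(td$x, td$species),
                  stats::setNames(td$y, td$species))
    f$correlation
  }, numeric(1))
  list(estimates = est, mean = mean(est), truth = r)
}

#' False-flag rate of BEB positive-selection calls
#'
#' Simulates M2a data with a small class of truly positively selected sites,
#' refits M2a, flags sites with class-3 posterior above 0.95, and reports
#' what fraction of flags fall on sites that are not truly class 3.
#'
#' @param n_rep replicates.
#' @param Lc codons per replicate.
#' @param p0,p1,omega0,omega2 generating M2a parameters (default: 5% of
#'   sites at omega = 3).
#' @param seed base seed.
#' @return List: `n_flagged`, `n_false`, `rate` (0 when nothing is flagged).
#' @export
beb_false_flag_rate <- function(n_rep = 4, Lc = 300, p0 = 0.70, p1 = 0.25,
                                omega0 = 0.1, omega2 = 3, seed = 1) {
  tr <- cricetidae_tree()
  spec <- codon_model_spec(2, protamine_like_freqs(),
                           m2a_spec(p0, p1, omega0, omega2))
  n_flagged <- 0L; n_false <- 0L
  for (i in seq_len(n_rep)) {
    sim <- simulate_codon_alignment(tr, spec, Lc, seed = seed * 6000 + i)
    suite <- fit_site_suite(sim$alignment, tr,
                            models = c("M0", "M1a", "M2a"),
                            branch_mode = "scale")
    post <- beb_classify(sim$alignment, tr, suite$fits$M2a)
    fl <- post$sites$site[post$sites$pp95 %in% TRUE]
    truth3 <- which(sim$truth$site_class == 3)
    n_flagged <- n_flagged + length(fl)
    n_false <- n_false + sum(!fl %in% truth3)
  }
  list(n_flagged = n_flagged, n_false = n_false,
       rate = if (n_flagged) n_false / n_flagged else 0)
}
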