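#' Site-mixture omega structures (M0, M1a, M2a, M7, M8)
#'
#' Constructors for the standard site-class models of variable dN/dS among
#' codons. `M1a` (nearly neutral) has a purifying class `omega0 in [0,1)` and
#' a neutral class pinned at 1; `M2a` adds a selection class `omega2 >= 1`.
#' `M7` draws omega from a beta(p, q) on (0, 1), discretized into `K`
#' equal-probability categories represented by their medians; `M8` adds an
#' extra class at `omega_s >= 1` with weight `1 - p0`.
#'
#' @param p0,p1 class proportions.
#' @param omega0 purifying-class omega in `[0, 1)`.
#' @param omega2,omega_s selection-class omega `>= 1`.
#' @param p,q beta shape parameters (> 0).
#' @param K number of discrete beta categories (default 10).
#' @return A `site_mixture` object.
#' @name site_mixture
NULL

.new_mixture <- function(model_id, pars, K = NA_integer_) {
  structure(list(model_id = model_id, pars = pars, K = K),
            class = "site_mixture")
}

.sc <- function(x) unname(as.numeric(x)) # scalar, stripped of inherited names

#' @rdname site_mixture
#' @export
m1a_spec <- function(p0, omega0) {
  p0 <- .sc(p0); omega0 <- .sc(omega0)
  stopifnot(p0 >= 0, p0 <= 1, omega0 >= 0, omega0 < 1)
  .new_mixture("M1a", c(p0 = p0, omega0 = omega0))
}

#' @rdname site_mixture
#' @export
m2a_spec <- function(p0, p1, omega0, omega2) {
  p0 <- .sc(p0); p1 <- .sc(p1); omega0 <- .sc(omega0); omega2 <- .sc(omega2)
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, omega0 >= 0, omega0 < 1,
            omega2 >= 1)
  .new_mixture("M2a", c(p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2))
}

#' @rdname site_mixture
#' @export
m7_spec <- function(p, q, K = 10) {
  p <- .sc(p); q <- .sc(q)
  stopifnot(p > 0, q > 0, K >= 2)
  .new_mixture("M7", c(p = p, q = q), as.integer(K))
}

#' @rdname site_mixture
#' @export
m8_spec <- function(p0, p, q, omega_s, K = 10) {
  p0 <- .sc(p0); p <- .sc(p); q <- .sc(q); omega_s <- .sc(omega_s)
  stopifnot(p0 >= 0, p0 <= 1, p > 0, q > 0, omega_s >= 1, K >= 2)
  .new_mixture("M8", c(p0 = p0, p = p, q = q, omega_s = omega_s),
               as.integer(K))
}

# equal-probability beta categories represented by category medians.
# For very small shapes (near two-point-mass betas) qbeta can be inaccurate,
# which would make the likelihood discontinuous in (p, q) and break line
# searches; inaccurate quantiles are recomputed by root-finding on the CDF
# over the logit scale.
.beta_categories <- function(p, q, K) {
  probs <- (2 * seq_len(K) - 1) / (2 * K)
  x <- suppressWarnings(stats::qbeta(probs, p, q))
  err <- abs(suppressWarnings(stats::pbeta(x, p, q)) - probs)
  bad <- which(!is.finite(x) | err > 1e-6)
  for (i in bad) {
    g <- function(u) stats::pbeta(stats::plogis(u), p, q) - probs[i]
    x[i] <- tryCatch(
      stats::plogis(stats::uniroot(g, c(-700, 700), tol = 1e-10)$root),
      error = function(e) x[i])
  }
  x
}

#' Discrete class representation of a site mixture
#'
#' @param mix a `site_mixture`.
#' @return List with `props` and `omegas`, both numeric vectors; proportions
#'   sum to 1.
#' @export
mixture_classes <- function(mix) {
  stopifnot(inherits(mix, "site_mixture"))
  p <- mix$pars
  out <- switch(mix$model_id,
    M1a = list(props = c(p["p0"], 1 - p["p0"]),
               omegas = c(p["omega0"], 1)),
    M2a = list(props = c(p["p0"], p["p1"], 1 - p["p0"] - p["p1"]),
               omegas = c(p["omega0"], 1, p["omega2"])),
    M7 = list(props = rep(1 / mix$K, mix$K),
              omegas = .beta_categories(p["p"], p["q"], mix$K)),
    M8 = list(props = c(rep(p["p0"] / mix$K, mix$K), 1 - p["p0"]),
              omegas = c(.beta_categories(p["p"], p["q"], mix$K),
                         p["omega_s"])),
    stop("unknown mixture model ", mix$model_id))
  out$props <- unname(out$props)
  out$omegas <- pmax(unname(out$omegas), 1e-8)
  out
}

#' Codon substitution model specification
#'
#' Bundles the transition/transversion ratio `kappa`, equilibrium codon
#' frequencies and an omega structure: a single omega (M0 / one-ratio), a
#' named omega per branch partition (e.g. `c(background = .3,
#' foreground = 2)`), or a [site_mixture].
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param freqs numeric length-61 equilibrium distribution, see
#'   [codon_freqs()].
#' @param omega numeric scalar, named numeric vector (branch partitions), or
#'   `site_mixture` object.
#' @return A `codon_model_spec`.
#' @export
codon_model_spec <- function(kappa, freqs, omega) {
  stopifnot(kappa > 0, length(freqs) == 61, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-6)
  if (is.numeric(omega)) stopifnot(all(omega >= 0))
  structure(list(kappa = kappa, freqs = freqs / sum(freqs), omega = omega),
            class = "codon_model_spec")
}

# Resolve a spec into per-class scaled generators sharing one time scale.
# Mixtures are scaled by the mixture-average rate so branch lengths are
# expected substitutions per codon averaged over site classes; scalar and
# branch-partition omegas are scaled per generator.
.class_generators <- function(spec) {
  freqs <- spec$freqs
  if (inherits(spec$omega, "site_mixture")) {
    cl <- mixture_classes(spec$omega)
    raw <- lapply(cl$omegas, function(om)
      build_rate_matrix(freqs, spec$kappa, om, scale = FALSE))
    rates <- vapply(raw, function(Q) attr(Q, "rate"), numeric(1))
    cbar <- sum(cl$props * rates)
    decomps <- lapply(raw, function(Q)
      .decompose_generator(Q / cbar, freqs))
    list(type = "mixture", props = cl$props, omegas = cl$omegas,
         decomps = decomps, scale = cbar, raw_rates = rates)
  } else if (length(spec$omega) == 1L && is.null(names(spec$omega))) {
    Q <- build_rate_matrix(freqs, spec$kappa, spec$omega, scale = TRUE)
    list(type = "single", props = 1, omegas = unname(spec$omega),
         decomps = list(.decompose_generator(Q, freqs)), scale = attr(Q, "rate"))
  } else {
    if (is.null(names(spec$omega))) stop("partition omegas must be named")
    decomps <- lapply(spec$omega, function(om) {
      Q <- build_rate_matrix(freqs, spec$kappa, om, scale = TRUE)
      .decompose_generator(Q, freqs)
    })
    list(type = "partition", omegas = spec$omega, decomps = decomps)
  }
}
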