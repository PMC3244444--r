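# ---- Bayes empirical Bayes site classification ----------------------------

# log-likelihood per site pattern under each omega in `omegas`, holding
# kappa, frequencies and branch lengths at their fitted values. Branch
# lengths are supplied in raw generator time so the scaling matches the fit.
.site_loglik_matrix <- function(prep, freqs, kappa, omegas, elen_raw) {
  out <- matrix(0, length(omegas), prep$S)
  ones <- rep(1L, nrow(prep$edge))
  for (i in seq_along(omegas)) {
    Q <- build_rate_matrix(freqs, kappa, omegas[i], scale = FALSE)
    d <- .decompose_generator(Q, freqs)
    out[i, ] <- .prune_loglik(prep, list(d), ones, elen_raw, freqs)
  }
  out
}

.grid_mid <- function(n, lo, hi) lo + (hi - lo) * (2 * seq_len(n) - 1) / (2 * n)

# map mixture-component omegas to selective classes
.class_of_omega <- function(om, tol = 1e-8) {
  ifelse(om > 1 + tol, 3L, ifelse(om < 1 - tol, 1L, 2L))
}

#' Bayes empirical Bayes (BEB) classification of sites
#'
#' Computes per-site posterior probabilities over the selective classes of a
#' fitted site-mixture model. The empirical-Bayes posterior is averaged over
#' a discrete grid prior on the mixture parameters (proportions and class
#' omegas; `grid_points` values per free dimension, uniform prior), weighted
#' by each grid point's integrated likelihood — this accounts for the
#' sampling error in the mixture MLEs that plain (naive) empirical Bayes
#' ignores. `method = "neb"` gives the plug-in alternative; a 1-point grid
#' reduces BEB to NEB exactly. Selection-class omega grids span (1, 11);
#' proportion grids span (0, 1); M7/M8 beta-shape grids span (0, 2), with
#' beta categories snapped to a fixed omega lattice on (0, 1).
#'
#' Positively-selected flags (posterior of the omega > 1 class above 0.95 /
#' 0.99) are only available for models with such a class (M2a, M8); for M1a
#' and M7 the flags are marked not allowed.
#'
#' @param alignment the [codon_alignment()] the model was fitted to.
#' @param tree the tree used for the fit (the fitted tree inside `fit` is
#'   used for branch lengths).
#' @param fit a `codon_fit` for M1a, M2a, M7 or M8.
#' @param method `"beb"` (default) or `"neb"`.
#' @param grid_points grid values per free mixture-parameter dimension.
#' @return A `site_posterior`: data.frame `sites` with per-site class
#'   posteriors (`p_class1`, `p_class2`, `p_class3`), maximum-posterior
#'   `class`, posterior `mean_omega` and `se_omega`, class-3 posterior and
#'   0.95/0.99 flags; plus `model_id`, `method`, `class3_allowed`.
#' @export
beb_classify <- function(alignment, tree, fit, method = c("beb", "neb"),
                         grid_points = 10) {
  method <- match.arg(method)
  if (!fit$model_id %in% c("M1a", "M2a", "M7", "M8")) {
    stop("site classification requires a site-mixture fit (M1a/M2a/M7/M8)")
  }
  kept <- seq_len(n_codons(alignment))
  if (fit$cleandata) {
    cd <- drop_incomplete_columns(alignment)
    alignment <- cd$alignment
    kept <- cd$kept
  }
  prep <- .prep_likelihood(alignment, fit$tree)
  freqs <- fit$spec$freqs
  kappa <- unname(fit$mles["kappa"])
  mix <- fit$spec$omega
  cl <- mixture_classes(mix)
  fc <- .flux_consts(freqs)
  cbar <- sum(cl$props * .rate_of(fc, kappa, cl$omegas))
  elen_raw <- fit$tree$edge.length / cbar

  if (method == "neb" || grid_points == 1) {
    res <- .neb_posteriors(prep, freqs, kappa, cl, elen_raw)
  } else {
    res <- switch(fit$model_id,
      M1a = .beb_m1a(prep, freqs, kappa, elen_raw, grid_points),
      M2a = .beb_m2a(prep, freqs, kappa, elen_raw, grid_points),
      M7 = .beb_m7(prep, freqs, kappa, elen_raw, grid_points, fit$K),
      M8 = .beb_m8(prep, freqs, kappa, elen_raw, grid_points, fit$K))
  }
  class3_allowed <- fit$model_id %in% c("M2a", "M8")

  idx <- prep$pattern_of_site # expand patterns to sites
  p1 <- res$post[1, idx]; p2 <- res$post[2, idx]; p3 <- res$post[3, idx]
  mo <- res$mean_omega[idx]
  so <- sqrt(pmax(res$mean_omega2[idx] - mo^2, 0))
  cls <- max.col(cbind(p1, p2, p3), ties.method = "first")
  sites <- data.frame(
    site = kept, p_class1 = p1, p_class2 = p2, p_class3 = p3,
    class = cls, mean_omega = mo, se_omega = so,
    pp_class3 = if (class3_allowed) p3 else NA_real_)
  sites$pp95 <- if (class3_allowed) sites$pp_class3 > 0.95 else NA
  sites$pp99 <- if (class3_allowed) sites$pp_class3 > 0.99 else NA
  structure(list(sites = sites, model_id = fit$model_id, method =
                   if (grid_points == 1) "neb" else method,
                 grid_points = grid_points,
                 class3_allowed = class3_allowed),
            class = "site_posterior")
}

#' @export
print.site_posterior <- function(x, ...) {
  cat("site_posterior [", x$model_id, ",", x$method, "]:",
      nrow(x$sites), "sites;",
      if (x$class3_allowed) paste(sum(x$sites$pp95), "flagged at PP>0.95")
      else "class-3 flags not allowed", "\n")
  invisible(x)
}

# plug-in (naive empirical Bayes) posteriors at the fitted mixture
.neb_posteriors <- function(prep, freqs, kappa, cl, elen_raw) {
  LL <- .site_loglik_matrix(prep, freqs, kappa, cl$omegas, elen_raw)
  off <- apply(LL, 2, max)
  EL <- exp(LL - rep(off, each = nrow(LL)))
  num <- cl$props * EL
  f <- colSums(num)
  postk <- num / rep(f, each = nrow(EL)) # class-k posterior per pattern
  ko <- .class_of_omega(cl$omegas)
  post <- rbind(colSums(postk[ko == 1L, , drop = FALSE]),
                colSums(postk[ko == 2L, , drop = FALSE]),
                colSums(postk[ko == 3L, , drop = FALSE]))
  list(post = post,
       mean_omega = colSums(cl$omegas * postk),
       mean_omega2 = colSums(cl$omegas^2 * postk))
}

# shared accumulator: given a list of "blocks", each block being a set of
# grid rows sharing class likelihood vectors (rows of EL per class), compute
# grid posterior weights then per-site class posteriors and omega moments.
# blocks[[b]]$P: R x K proportions; $L: K x S class likelihoods;
# $W: K x S class omega values (omega of class k, recycled per site).
.beb_accumulate <- function(blocks, w) {
  nb <- length(blocks)
  logm <- vector("list", nb)
  for (b in seq_len(nb)) {
    F <- blocks[[b]]$P %*% blocks[[b]]$L
    logm[[b]] <- as.vector(log(F) %*% w)
  }
  mx <- max(unlist(logm))
  Wg <- lapply(logm, function(v) exp(v - mx))
  tot <- sum(unlist(Wg))
  S <- ncol(blocks[[1]]$L)
  post <- matrix(0, 3, S)
  mo <- numeric(S); mo2 <- numeric(S)
  for (b in seq_len(nb)) {
    bl <- blocks[[b]]
    invF <- 1 / (bl$P %*% bl$L)
    Wr <- Wg[[b]] / tot
    for (k in seq_len(ncol(bl$P))) {
      # sum over grid rows r of W_r * p_rk / f_rs, shared by all moments
      g <- as.vector(crossprod(Wr * bl$P[, k], invF))
      post[bl$class[k], ] <- post[bl$class[k], ] + g * bl$L[k, ]
      mo <- mo + g * bl$omega_mom1[k, ]
      mo2 <- mo2 + g * bl$omega_mom2[k, ]
    }
  }
  list(post = post, mean_omega = mo, mean_omega2 = mo2)
}

.beb_m1a <- function(prep, freqs, kappa, elen_raw, n) {
  g_p0 <- .grid_mid(n, 0, 1)
  g_w0 <- .grid_mid(n, 0, 1)
  LL <- .site_loglik_matrix(prep, freqs, kappa, c(g_w0, 1), elen_raw)
  off <- apply(LL, 2, max)
  EL <- exp(LL - rep(off, each = nrow(LL)))
  L1 <- EL[n + 1, ]
  P <- cbind(g_p0, 1 - g_p0)
  blocks <- lapply(seq_len(n), function(i0) {
    L <- rbind(EL[i0, ], L1)
    list(P = P, L = L, class = c(1L, 2L),
         omega_mom1 = rbind(g_w0[i0] * L[1, ], 1 * L[2, ]),
         omega_mom2 = rbind(g_w0[i0]^2 * L[1, ], 1 * L[2, ]))
  })
  .beb_accumulate(blocks, prep$weights)
}

.beb_m2a <- function(prep, freqs, kappa, elen_raw, n) {
  g1 <- .grid_mid(n, 0, 1) # p0
  g2 <- .grid_mid(n, 0, 1) # stick fraction for p1
  g_w0 <- .grid_mid(n, 0, 1)
  g_w2 <- .grid_mid(n, 1, 11)
  LL <- .site_loglik_matrix(prep, freqs, kappa, c(g_w0, 1, g_w2), elen_raw)
  off <- apply(LL, 2, max)
  EL <- exp(LL - rep(off, each = nrow(LL)))
  L1 <- EL[n + 1, ]
  gg <- expand.grid(g1 = g1, g2 = g2)
  P <- cbind(gg$g1, (1 - gg$g1) * gg$g2,
             (1 - gg$g1) * (1 - gg$g2))
  blocks <- list()
  for (i0 in seq_len(n)) {
    for (i2 in seq_len(n)) {
      L <- rbind(EL[i0, ], L1, EL[n + 1 + i2, ])
      blocks[[length(blocks) + 1]] <- list(
        P = P, L = L, class = c(1L, 2L, 3L),
        omega_mom1 = rbind(g_w0[i0] * L[1, ], L[2, ], g_w2[i2] * L[3, ]),
        omega_mom2 = rbind(g_w0[i0]^2 * L[1, ], L[2, ],
                           g_w2[i2]^2 * L[3, ]))
    }
  }
  .beb_accumulate(blocks, prep$weights)
}

# fixed omega lattice on (0,1) used to approximate beta categories
.beta_lattice <- function() {
  c(1e-5, 0.0025, 0.01, 0.025, seq(0.05, 0.95, by = 0.05),
    0.975, 0.99, 0.9975, 0.99995)
}

.snap <- function(x, lattice) {
  vapply(x, function(v) which.min(abs(lattice - v)), integer(1))
}

.beb_m7 <- function(prep, freqs, kappa, elen_raw, n, K) {
  lat <- .beta_lattice()
  g_p <- .grid_mid(n, 0, 2)
  g_q <- .grid_mid(n, 0, 2)
  LL <- .site_loglik_matrix(prep, freqs, kappa, lat, elen_raw)
  off <- apply(LL, 2, max)
  EL <- exp(LL - rep(off, each = nrow(LL)))
  blocks <- list()
  P <- matrix(1, 1, 1)
  for (ip in seq_len(n)) {
    for (iq in seq_len(n)) {
      idx <- .snap(.beta_categories(g_p[ip], g_q[iq], K), lat)
      Lb <- colMeans(EL[idx, , drop = FALSE])
      m1 <- colMeans(lat[idx] * EL[idx, , drop = FALSE])
      m2 <- colMeans(lat[idx]^2 * EL[idx, , drop = FALSE])
      blocks[[length(blocks) + 1]] <- list(
        P = P, L = matrix(Lb, 1), class = 1L,
        omega_mom1 = matrix(m1, 1), omega_mom2 = matrix(m2, 1))
    }
  }
  .beb_accumulate(blocks, prep$weights)
}

.beb_m8 <- function(prep, freqs, kappa, elen_raw, n, K) {
  lat <- .beta_lattice()
  g_p0 <- .grid_mid(n, 0, 1)
  g_p <- .grid_mid(n, 0, 2)
  g_q <- .grid_mid(n, 0, 2)
  g_ws <- .grid_mid(n, 1, 11)
  LL <- .site_loglik_matrix(prep, freqs, kappa, c(lat, g_ws), elen_raw)
  off <- apply(LL, 2, max)
  EL <- exp(LL - rep(off, each = nrow(LL)))
  nl <- length(lat)
  P <- cbind(g_p0, 1 - g_p0)
  blocks <- list()
  for (ip in seq_len(n)) {
    for (iq in seq_len(n)) {
      idx <- .snap(.beta_categories(g_p[ip], g_q[iq], K), lat)
      Lb <- colMeans(EL[idx, , drop = FALSE])
      bm1 <- colMeans(lat[idx] * EL[idx, , drop = FALSE])
      bm2 <- colMeans(lat[idx]^2 * EL[idx, , drop = FALSE])
      for (is in seq_len(n)) {
        Ls <- EL[nl + is, ]
        blocks[[length(blocks) + 1]] <- list(
          P = P, L = rbind(Lb, Ls), class = c(1L, 3L),
          omega_mom1 = rbind(bm1, g_ws[is] * Ls),
          omega_mom2 = rbind(bm2, g_ws[is]^2 * Ls))
      }
    }
  }
  .beb_accumulate(blocks, prep$weights)
}
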