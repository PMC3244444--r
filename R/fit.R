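# ---- parameter transforms -------------------------------------------------
# Optimization runs on an unconstrained-ish transformed scale under
# L-BFGS-B boxes: log for positive parameters, logit for proportions and
# omega0 in (0,1), log(x - 1) for selection-class omegas bounded below by 1.

.tr_fwd <- function(x, trans, lb, ub) {
  switch(trans,
    log = log(pmin(pmax(x, lb), ub)),
    logit = stats::qlogis(pmin(pmax((x - lb) / (ub - lb), 1e-7), 1 - 1e-7)),
    logp1 = log(pmax(x - 1, 1e-9)))
}

.tr_bwd <- function(th, trans, lb, ub) {
  switch(trans,
    log = exp(th),
    logit = lb + (ub - lb) * stats::plogis(th),
    logp1 = 1 + exp(th))
}

.tr_lo <- function(trans, lb, ub) {
  switch(trans, log = log(lb), logit = -16, logp1 = -20)
}

.tr_hi <- function(trans, lb, ub) {
  switch(trans, log = log(ub), logit = 16, logp1 = log(ub - 1))
}

.par_row <- function(name, trans, lb, ub, init) {
  data.frame(name = name, trans = trans, lb = lb, ub = ub, init = init,
             stringsAsFactors = FALSE)
}

# search bounds: omega in [1e-6, 50], kappa in [0.1, 20]
.model_param_table <- function(model_id, nedge = 0) {
  kap <- .par_row("kappa", "log", 0.1, 20, 2)
  om <- function(nm, init = 0.5) .par_row(nm, "log", 1e-6, 50, init)
  switch(model_id,
    M0 = rbind(kap, om("omega", 0.4)),
    two_ratio = rbind(kap, om("omega_background", 0.4),
                      om("omega_foreground", 0.8)),
    free_ratio = rbind(kap, do.call(rbind, lapply(seq_len(nedge), function(e)
      om(paste0("omega_e", e), 0.4)))),
    M1a = rbind(kap,
                .par_row("p0", "logit", 1e-6, 1 - 1e-6, 0.7),
                .par_row("omega0", "logit", 1e-6, 1 - 1e-6, 0.2)),
    M2a = rbind(kap,
                .par_row("p0", "logit", 1e-6, 1 - 1e-6, 0.6),
                .par_row("r1", "logit", 1e-6, 1 - 1e-6, 0.7),
                .par_row("omega0", "logit", 1e-6, 1 - 1e-6, 0.2),
                .par_row("omega2", "logp1", 1, 50, 2.5)),
    M7 = rbind(kap,
               .par_row("p", "log", 0.005, 99, 0.5),
               .par_row("q", "log", 0.005, 99, 1)),
    M8 = rbind(kap,
               .par_row("p0", "logit", 1e-6, 1 - 1e-6, 0.9),
               .par_row("p", "log", 0.005, 99, 0.5),
               .par_row("q", "log", 0.005, 99, 1),
               .par_row("omega_s", "logp1", 1, 50, 2.5)),
    stop("unknown model_id: ", model_id))
}

# natural parameter vector -> omega structure for the spec
.omega_structure <- function(model_id, v, K, nedge) {
  switch(model_id,
    M0 = unname(v["omega"]),
    two_ratio = c(background = unname(v["omega_background"]),
                  foreground = unname(v["omega_foreground"])),
    free_ratio = stats::setNames(v[paste0("omega_e", seq_len(nedge))],
                                 paste0("e", seq_len(nedge))),
    M1a = m1a_spec(v["p0"], min(v["omega0"], 1 - 1e-7)),
    M2a = m2a_spec(v["p0"], (1 - v["p0"]) * v["r1"],
                   min(v["omega0"], 1 - 1e-7), max(v["omega2"], 1)),
    M7 = m7_spec(v["p"], v["q"], K),
    M8 = m8_spec(v["p0"], v["p"], v["q"], max(v["omega_s"], 1), K))
}

#' Maximum-likelihood fit of a codon model
#'
#' Fits the Goldman-Yang codon model under one of the supported omega
#' structures by bounded quasi-Newton optimization (L-BFGS-B on transformed
#' parameters): `M0` (one ratio), `two_ratio` (branch partition:
#' foreground clade vs background), `free_ratio` (independent omega per
#' branch), and the site mixtures `M1a`, `M2a`, `M7`, `M8`. Equilibrium codon
#' frequencies are empirical (not optimized, and not counted as free
#' parameters). Parameters can be pinned through `fixed` — e.g.
#' `fixed = list(omega_foreground = 1)` gives the relaxation null in which the
#' focal clade is constrained to neutral evolution.
#'
#' @param alignment a [codon_alignment()].
#' @param tree rooted `phylo` with branch lengths (used as starting values).
#' @param model_id one of `"M0"`, `"two_ratio"`, `"free_ratio"`, `"M1a"`,
#'   `"M2a"`, `"M7"`, `"M8"`.
#' @param freq_model codon frequency model passed to [codon_freqs()].
#' @param foreground tip labels of the focal clade (required for
#'   `two_ratio`).
#' @param include_stem include the clade's stem branch in the foreground.
#' @param fixed named list of parameters to pin (natural scale). Branch
#'   lengths are controlled by `branch_mode`.
#' @param branch_mode `"free"` (every branch length optimized), `"scale"`
#'   (one multiplier of the input tree's lengths) or `"fixed"` (input
#'   lengths kept).
#' @param cleandata drop alignment columns containing gaps/ambiguities before
#'   fitting (default TRUE); with FALSE they are treated as missing data.
#' @param K discrete beta categories for M7/M8.
#' @param n_starts number of deterministic optimizer starts; later starts
#'   perturb the first and the best fit is kept.
#' @param init named list of starting values (natural scale) overriding the
#'   defaults — used to warm-start nested model ladders.
#' @param optim_control passed to [stats::optim()] control.
#' @return A `codon_fit` with elements `lnL`, `mles`, `spec`, `tree` (fitted
#'   branch lengths), `branch_table`, `n_params`, `converged`, `model_id`.
#' @export
fit <- function(alignment, tree, model_id = "M0",
                freq_model = c("F3X4", "F1X4", "F61", "equal"),
                foreground = NULL, include_stem = TRUE, fixed = list(),
                branch_mode = c("free", "scale", "fixed"), cleandata = TRUE,
                K = 10, n_starts = 1, init = list(), optim_control = list()) {
  freq_model <- match.arg(freq_model)
  branch_mode <- match.arg(branch_mode)
  if (cleandata) {
    cd <- drop_incomplete_columns(alignment)
    alignment <- cd$alignment
  }
  freqs <- codon_freqs(alignment, freq_model)
  prep <- .prep_likelihood(alignment, tree)
  ptree <- prep$tree
  nedge <- nrow(ptree$edge)
  tree_len <- ptree$edge.length
  if (is.null(tree_len)) tree_len <- rep(0.1, nedge)
  tree_len <- pmin(pmax(tree_len, 1e-6), 19)

  labels <- NULL
  if (model_id == "two_ratio") {
    if (is.null(foreground)) stop("two_ratio model needs `foreground` tips")
    labels <- edge_partition(ptree, foreground, include_stem)
  } else if (model_id == "free_ratio") {
    labels <- paste0("e", seq_len(nedge))
  }

  ptab <- .model_param_table(model_id, nedge)
  if (branch_mode == "free") {
    bt <- do.call(rbind, lapply(seq_len(nedge), function(e)
      .par_row(paste0("t", e), "log", 1e-8, 20, tree_len[e])))
    ptab <- rbind(ptab, bt)
  } else if (branch_mode == "scale") {
    ptab <- rbind(ptab, .par_row("bscale", "log", 1e-3, 100, 1))
  }
  for (nm in names(init)) {
    if (nm %in% ptab$name) ptab$init[ptab$name == nm] <- init[[nm]]
  }
  is_fixed <- ptab$name %in% names(fixed)
  fixed_vals <- unlist(fixed[ptab$name[is_fixed]])
  free_tab <- ptab[!is_fixed, , drop = FALSE]
  np <- nrow(free_tab)

  natural_of <- function(theta) {
    v <- vapply(seq_len(np), function(i)
      .tr_bwd(theta[i], free_tab$trans[i], free_tab$lb[i], free_tab$ub[i]),
      numeric(1))
    names(v) <- free_tab$name
    c(v, fixed_vals)
  }
  edge_len_of <- function(v) {
    switch(branch_mode,
      free = unname(v[paste0("t", seq_len(nedge))]),
      scale = tree_len * unname(v["bscale"]),
      fixed = tree_len)
  }

  # Site mixtures are optimized with branch lengths in raw generator time:
  # the per-class pattern log-likelihood then depends only on
  # (kappa, omega_k, edge lengths), so passes are memoized across the
  # optimizer's gradient evaluations. The fitted time scale is converted back
  # to expected substitutions per codon (mixture-average rate) afterwards.
  is_mixture <- model_id %in% c("M1a", "M2a", "M7", "M8")
  fc <- .flux_consts(freqs)
  parts <- .rate_matrix_parts(freqs)
  cache <- new.env(parent = emptyenv()) # per-class pattern log-likelihoods
  dcache <- new.env(parent = emptyenv()) # spectral decompositions by (k, w)
  dcache_n <- 0L
  get_decomp <- function(kappa, omega) {
    key <- paste(sprintf("%.17g", kappa), sprintf("%.17g", omega))
    d <- dcache[[key]]
    if (is.null(d)) {
      d <- .decompose_generator(.q_from_parts(parts, kappa, omega), freqs)
      d$rate <- .rate_of(fc, kappa, omega) # raw mean rate, for rescaling
      if (dcache_n > 400) {
        rm(list = ls(dcache), envir = dcache)
        dcache_n <<- 0L
      }
      dcache[[key]] <- d
      dcache_n <<- dcache_n + 1L
    }
    d
  }
  scaled <- function(d) list(values = d$values / d$rate, left = d$left,
                             right = d$right)
  ones_idx <- rep(1L, nedge)
  mixture_negll <- function(v) {
    mix <- .omega_structure(model_id, v, K, nedge)
    cl <- mixture_classes(mix)
    kap <- unname(v["kappa"])
    elen <- edge_len_of(v)
    if (branch_mode == "fixed") {
      cbar <- sum(cl$props * .rate_of(fc, kap, cl$omegas))
      elen <- elen / cbar
    }
    # full-precision keys: only bitwise-identical evaluations are reused
    elkey <- paste(sprintf("%.17g", elen), collapse = ",")
    M <- matrix(0, length(cl$omegas), prep$S)
    for (k in seq_along(cl$omegas)) {
      key <- paste(sprintf("%.17g", kap), sprintf("%.17g", cl$omegas[k]),
                   elkey, sep = "|")
      ll <- cache[[key]]
      if (is.null(ll)) {
        d <- get_decomp(kap, cl$omegas[k])
        ll <- .prune_loglik(prep, list(d), ones_idx, elen, freqs)
        cache[[key]] <- ll
      }
      M[k, ] <- ll
    }
    site_ll <- .logsumexp_rows(M + log(pmax(cl$props, 1e-300)))
    sum(prep$weights * site_ll)
  }
  plain_negll <- function(v) {
    kap <- unname(v["kappa"])
    elen <- edge_len_of(v)
    om <- .omega_structure(model_id, v, K, nedge)
    if (is.null(labels)) { # single omega (M0)
      d <- scaled(get_decomp(kap, unname(om)))
      ll <- .prune_loglik(prep, list(d), ones_idx, elen, freqs)
    } else { # branch partition / free ratio
      dlist <- lapply(om, function(o) scaled(get_decomp(kap, o)))
      ll <- .prune_loglik(prep, dlist, match(labels, names(dlist)), elen,
                          freqs)
    }
    sum(prep$weights * ll)
  }
  negll <- function(theta) {
    v <- natural_of(theta)
    ll <- try(if (is_mixture) mixture_negll(v) else plain_negll(v),
              silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }

  theta0 <- vapply(seq_len(np), function(i)
    .tr_fwd(free_tab$init[i], free_tab$trans[i], free_tab$lb[i],
            free_tab$ub[i]), numeric(1))
  lo <- vapply(seq_len(np), function(i)
    .tr_lo(free_tab$trans[i], free_tab$lb[i], free_tab$ub[i]), numeric(1))
  hi <- vapply(seq_len(np), function(i)
    .tr_hi(free_tab$trans[i], free_tab$lb[i], free_tab$ub[i]), numeric(1))
  theta0 <- pmin(pmax(theta0, lo + 1e-6), hi - 1e-6)

  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e8), optim_control)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    th <- theta0
    if (s > 1L) {
      # deterministic perturbation, no RNG involved
      th <- theta0 + 0.4 * sin(seq_len(np) * s * 1.7)
      th <- pmin(pmax(th, lo + 1e-6), hi - 1e-6)
    }
    o <- stats::optim(th, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = ctrl)
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization failed")
  converged <- best$convergence == 0
  if (!converged) {
    warning("fit (", model_id, ") did not report convergence: ",
            best$message)
  }

  v <- natural_of(best$par)
  om <- .omega_structure(model_id, v, K, nedge)
  spec <- codon_model_spec(unname(v["kappa"]), freqs, om)
  elen <- edge_len_of(v)
  if (is_mixture && branch_mode != "fixed") {
    # convert raw generator time to expected substitutions per codon
    cl <- mixture_classes(om)
    cbar <- sum(cl$props * .rate_of(fc, unname(v["kappa"]), cl$omegas))
    elen <- elen * cbar
    tn <- grepl("^t[0-9]+$", names(v)) | names(v) == "bscale"
    v[tn] <- v[tn] * cbar
  }
  ftree <- ptree
  ftree$edge.length <- elen
  bt <- .branch_table(ftree, spec, labels)
  structure(list(
    lnL = -best$value, model_id = model_id, mles = v, spec = spec,
    tree = ftree, freq_model = freq_model, K = K,
    edge_partition = labels, branch_table = bt,
    n_params = np, converged = converged, counts = best$counts,
    cleandata = cleandata, foreground = foreground,
    include_stem = include_stem),
    class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon_fit [", x$model_id, "]  lnL =", format(x$lnL, digits = 8),
      " np =", x$n_params, if (!x$converged) " (NOT converged)", "\n")
  mp <- x$mles[!grepl("^t[0-9]+$", names(x$mles))]
  cat(paste(names(mp), "=", signif(mp, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Choose a codon frequency model by AIC
#'
#' Fits the one-ratio model under each candidate frequency parameterization
#' and compares AIC, counting the empirical frequency parameters (equal: 0,
#' F1X4: 3, F3X4: 9, F61: 60) on top of the model's free parameters — the
#' candidates are not nested, so AIC rather than an LRT ladder decides.
#'
#' @inheritParams fit
#' @param models candidate frequency models.
#' @param ... passed to [fit()].
#' @return List with `best` (the winning model name) and `table`
#'   (model, lnL, n_params, AIC).
#' @export
select_freq_model <- function(alignment, tree,
                              models = c("F3X4", "F1X4", "F61", "equal"),
                              ...) {
  extra <- c(equal = 0, F1X4 = 3, F3X4 = 9, F61 = 60)
  rows <- lapply(models, function(m) {
    f <- fit(alignment, tree, "M0", freq_model = m, ...)
    k <- f$n_params + extra[[m]]
    data.frame(model = m, lnL = f$lnL, n_params = k,
               AIC = 2 * k - 2 * f$lnL)
  })
  tab <- do.call(rbind, rows)
  list(best = tab$model[which.min(tab$AIC)], table = tab)
}

# expected dN/dS per unit branch time for a site mixture sharing one scale
.mixture_flux <- function(freqs, kappa, props, omegas) {
  pt <- .code_env$pair_type
  syn <- nonsyn <- 0
  rates <- numeric(length(omegas))
  for (k in seq_along(omegas)) {
    Q <- build_rate_matrix(freqs, kappa, omegas[k], scale = FALSE)
    fx <- freqs * Q
    syn <- syn + props[k] * sum(fx[pt == 1L | pt == 2L])
    nonsyn <- nonsyn + props[k] * sum(fx[pt == 3L | pt == 4L])
    rates[k] <- attr(Q, "rate")
  }
  cbar <- sum(props * rates)
  c(syn = syn / cbar, nonsyn = nonsyn / cbar)
}

# per-branch (t, omega, dN, dS) table for a fitted model
.branch_table <- function(tree, spec, labels = NULL) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  child_lab <- ifelse(edge[, 2] <= ntip, tree$tip.label[edge[, 2]],
                      paste0("node", edge[, 2]))
  freqs <- spec$freqs
  kappa <- spec$kappa
  n <- nrow(edge)
  if (inherits(spec$omega, "site_mixture")) {
    cl <- mixture_classes(spec$omega)
    fx <- .mixture_flux(freqs, kappa, cl$props, cl$omegas)
    f1 <- .mixture_flux(freqs, kappa, 1, 1)
    rho <- f1 / sum(f1)
    t <- tree$edge.length
    dN <- t * fx["nonsyn"] / rho["nonsyn"]
    dS <- t * fx["syn"] / rho["syn"]
    om <- rep(if (dS[1] > 0 || t[1] == 0) unname(fx["nonsyn"] / max(fx["syn"], 1e-12)) else NA_real_, n)
    tab <- data.frame(parent = edge[, 1], child = edge[, 2],
                      label = child_lab, t = t, omega = om,
                      dN = unname(dN), dS = unname(dS))
  } else {
    om_edge <- if (length(spec$omega) == 1L && is.null(names(spec$omega))) {
      rep(unname(spec$omega), n)
    } else {
      unname(spec$omega[labels])
    }
    sub <- t(vapply(seq_len(n), function(e)
      branch_expected_subs(freqs, kappa, om_edge[e], tree$edge.length[e]),
      numeric(2)))
    tab <- data.frame(parent = edge[, 1], child = edge[, 2],
                      label = child_lab, t = tree$edge.length,
                      omega = om_edge, dN = sub[, 1], dS = sub[, 2])
  }
  rownames(tab) <- NULL
  tab
}
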