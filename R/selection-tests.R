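#' Likelihood-ratio test verdict
#'
#' Compares twice the log-likelihood difference between a nested null and
#' alternative model to a chi-square with degrees of freedom equal to the
#' difference in the number of free parameters. Verdicts: `**` for p < 0.01,
#' `*` for p < 0.05, `ns` otherwise.
#'
#' @param two_delta_l the statistic `2 * (lnL_alt - lnL_null)`; small negative
#'   values (optimizer noise) are clamped to 0.
#' @param df degrees of freedom (>= 1).
#' @return List with `two_delta_l`, `df`, `p_value`, `verdict`.
#' @export
lrt_verdict <- function(two_delta_l, df) {
  stopifnot(df >= 1)
  if (two_delta_l < 0) {
    if (two_delta_l < -0.05) {
      warning("alternative fit worse than null by ", -two_delta_l / 2,
              " log-units; check convergence")
    }
    two_delta_l <- 0
  }
  p <- stats::pchisq(two_delta_l, df, lower.tail = FALSE)
  verdict <- if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  list(two_delta_l = two_delta_l, df = df, p_value = p, verdict = verdict)
}

# nesting relationships the LRT accepts (null -> alternatives)
.nested_alternatives <- list(
  M0 = c("two_ratio", "free_ratio", "M1a", "M2a", "M8"),
  two_ratio = "two_ratio",
  M1a = "M2a",
  M7 = "M8")

#' Likelihood-ratio test between two fitted codon models
#'
#' @param fit_null,fit_alt `codon_fit` objects from [fit()]; the models must
#'   be nested and the alternative must have more free parameters (e.g. the
#'   two-ratio model with the focal clade pinned at omega = 1 vs the free
#'   two-ratio model).
#' @return An `lrt_result`: model ids, log-likelihoods, `two_delta_l`, `df`,
#'   `p_value` and `verdict`.
#' @export
lrt <- function(fit_null, fit_alt) {
  ok <- fit_alt$model_id %in% .nested_alternatives[[fit_null$model_id]]
  if (!isTRUE(ok)) {
    stop("models not nested: ", fit_null$model_id, " vs ", fit_alt$model_id)
  }
  df <- fit_alt$n_params - fit_null$n_params
  if (df < 1) {
    stop("alternative must have more free parameters than the null (",
         fit_alt$n_params, " vs ", fit_null$n_params, ")")
  }
  v <- lrt_verdict(2 * (fit_alt$lnL - fit_null$lnL), df)
  structure(c(list(model_null = fit_null$model_id,
                   model_alt = fit_alt$model_id,
                   lnL_null = fit_null$lnL, lnL_alt = fit_alt$lnL), v),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: 2dl = %.4f (df %d), p = %.4g %s\n",
              x$model_null, x$model_alt, x$two_delta_l, x$df, x$p_value,
              x$verdict))
  invisible(x)
}

#' Fit the three clade models
#'
#' Model 1 ("one ratio"): every branch shares one omega. Model 2 ("two
#' ratio, focal clade fixed"): the background omega is free while the focal
#' clade is pinned at omega = 1 (the relaxation null). Model 3 ("two
#' ratio"): foreground and background omegas both free. Models 2 and 3 are
#' warm-started from the one-ratio fit.
#'
#' @inheritParams fit
#' @param ... further arguments passed to [fit()] (e.g. `branch_mode`,
#'   `freq_model`).
#' @return List with elements `m1`, `m2`, `m3` (codon fits) and `foreground`.
#' @export
fit_clade_suite <- function(alignment, tree, foreground, include_stem = TRUE,
                            ...) {
  m1 <- fit(alignment, tree, "M0", ...)
  om <- unname(m1$mles["omega"])
  kap <- unname(m1$mles["kappa"])
  m3 <- fit(alignment, m1$tree, "two_ratio", foreground = foreground,
            include_stem = include_stem,
            init = list(kappa = kap, omega_background = om,
                        omega_foreground = om), ...)
  m2 <- fit(alignment, m3$tree, "two_ratio", foreground = foreground,
            include_stem = include_stem,
            fixed = list(omega_foreground = 1),
            init = list(kappa = unname(m3$mles["kappa"]),
                        omega_background =
                          unname(m3$mles["omega_background"])), ...)
  list(m1 = m1, m2 = m2, m3 = m3, foreground = foreground)
}

#' Decision rule separating positive selection from relaxation
#'
#' A focal clade is called under *positive selection* when (i) it evolves at
#' a rate significantly different from the background (one-ratio vs two-ratio
#' LRT), (ii) the two-ratio model also beats the null in which the clade is
#' pinned at omega = 1, and (iii) the estimated clade omega exceeds 1. It is
#' a candidate for *relaxation* when condition (i) holds but the clade omega
#' is not significantly different from 1 (condition (ii) fails). Otherwise no
#' call is made.
#'
#' @param sig_m1_vs_m3 logical, one-ratio vs two-ratio LRT significant.
#' @param sig_m2_vs_m3 logical, fixed-omega-1 vs two-ratio LRT significant.
#' @param foreground_omega estimated omega of the focal clade.
#' @return `"Positive"`, `"Relaxation"` or `"None"`.
#' @export
clade_rule <- function(sig_m1_vs_m3, sig_m2_vs_m3, foreground_omega) {
  if (sig_m1_vs_m3 && sig_m2_vs_m3 && foreground_omega > 1) return("Positive")
  if (sig_m1_vs_m3 && !sig_m2_vs_m3) return("Relaxation")
  "None"
}

#' Classify a focal clade from the three clade-model fits
#'
#' @param m1,m2,m3 fits from [fit_clade_suite()].
#' @param alpha significance level for both LRTs (default 0.05).
#' @return A `clade_decision`: foreground omega, both LRTs and the label.
#' @export
classify_clade <- function(m1, m2, m3, alpha = 0.05) {
  lrt13 <- lrt(m1, m3)
  lrt23 <- lrt(m2, m3)
  fg <- unname(m3$spec$omega["foreground"])
  label <- clade_rule(lrt13$p_value < alpha, lrt23$p_value < alpha, fg)
  structure(list(foreground_omega = fg, lrt_m1_vs_m3 = lrt13,
                 lrt_m2_vs_m3 = lrt23, alpha = alpha, label = label),
            class = "clade_decision")
}

#' @export
print.clade_decision <- function(x, ...) {
  cat(sprintf("clade decision: %s (foreground omega = %.3f)\n", x$label,
              x$foreground_omega))
  print(x$lrt_m1_vs_m3); print(x$lrt_m2_vs_m3)
  invisible(x)
}

#' Fit the site-model suite (M0, M1a, M2a, M7, M8) with its two LRTs
#'
#' Fits the nearly-neutral vs selection pairs M1a/M2a and M7/M8 (both df 2)
#' plus the one-ratio baseline. Fits are warm-started along the ladder
#' (M0 -> M1a -> M2a, M0 -> M7 -> M8). The designation mirrors the reporting
#' convention of selection scans: if a selection model is significantly
#' better it is named (`"M2a (selection)"` / `"M8 (beta and omega)"`, the
#' larger statistic winning when both are significant); otherwise the
#' better-scoring neutral model is named (`"M1a (neutral)"` / `"M7 (beta)"`).
#'
#' @inheritParams fit
#' @param models subset of models to fit (the two LRTs require their pair).
#' @param ... passed to [fit()].
#' @return List with `fits` (named list), `lrt_m1a_m2a`, `lrt_m7_m8`,
#'   `designation`.
#' @export
fit_site_suite <- function(alignment, tree, K = 10,
                           models = c("M0", "M1a", "M2a", "M7", "M8"), ...) {
  fits <- list()
  fits$M0 <- fit(alignment, tree, "M0", ...)
  kap <- unname(fits$M0$mles["kappa"])
  om <- unname(fits$M0$mles["omega"])
  btree <- fits$M0$tree
  if ("M1a" %in% models) {
    fits$M1a <- fit(alignment, btree, "M1a",
                    init = list(kappa = kap, omega0 = min(om, 0.9)), ...)
  }
  if ("M2a" %in% models) {
    fits$M2a <- fit(alignment, fits$M1a$tree, "M2a",
                    init = list(kappa = unname(fits$M1a$mles["kappa"]),
                                p0 = unname(fits$M1a$mles["p0"]),
                                omega0 = unname(fits$M1a$mles["omega0"]),
                                r1 = 0.8, omega2 = 2), ...)
    fits$M2a <- .retry_if_below(fits$M2a, fits$M1a, alignment, ...)
  }
  if ("M7" %in% models) {
    fits$M7 <- fit(alignment, btree, "M7", K = K,
                   init = list(kappa = kap), ...)
  }
  if ("M8" %in% models) {
    fits$M8 <- fit(alignment, fits$M7$tree, "M8", K = K,
                   init = list(kappa = unname(fits$M7$mles["kappa"]),
                               p = unname(fits$M7$mles["p"]),
                               q = unname(fits$M7$mles["q"]),
                               p0 = 0.9, omega_s = 2), ...)
    fits$M8 <- .retry_if_below(fits$M8, fits$M7, alignment, K = K, ...)
  }
  lrt12 <- if (all(c("M1a", "M2a") %in% names(fits)))
    lrt(fits$M1a, fits$M2a) else NULL
  lrt78 <- if (all(c("M7", "M8") %in% names(fits)))
    lrt(fits$M7, fits$M8) else NULL
  sig12 <- !is.null(lrt12) && lrt12$p_value < 0.05
  sig78 <- !is.null(lrt78) && lrt78$p_value < 0.05
  designation <- if (sig12 || sig78) {
    if (sig12 && (!sig78 || lrt12$two_delta_l >= lrt78$two_delta_l)) {
      "M2a (selection)"
    } else {
      "M8 (beta and omega)"
    }
  } else {
    neut <- c(M1a = if (!is.null(fits$M1a)) fits$M1a$lnL else -Inf,
              M7 = if (!is.null(fits$M7)) fits$M7$lnL else -Inf)
    if (which.max(neut) == 1L) "M1a (neutral)" else "M7 (beta)"
  }
  list(fits = fits, lrt_m1a_m2a = lrt12, lrt_m7_m8 = lrt78,
       designation = designation)
}

# An alternative that ends below its nested null has been trapped by the
# warm start; refit from the default (cold) start and keep the better fit.
.retry_if_below <- function(fit_alt, fit_null, alignment, ...) {
  if (fit_alt$lnL >= fit_null$lnL - 1e-4) return(fit_alt)
  cold <- suppressWarnings(fit(alignment, fit_null$tree, fit_alt$model_id,
                               ...))
  if (cold$lnL > fit_alt$lnL) cold else fit_alt
}

#' Summarize per-site selective classes
#'
#' Tabulates the percentage of sites assigned (by maximum posterior) to the
#' three selective classes — 1: purifying (omega < 1), 2: neutral
#' (omega = 1), 3: positive selection / relaxation (omega > 1) — overall and,
#' if a domain annotation is given, within each functional region type.
#' Positively selected sites are listed as position + reference residue
#' (e.g. `"33C"`).
#'
#' @param posterior a `site_posterior` from [beb_classify()].
#' @param regions optional domain annotation (`data.frame` with `type`,
#'   `start`, `end` in 0-based half-open codon/residue coordinates), e.g.
#'   from [scan_anchoring()] / [scan_phospho()] / [map_configured_sites()].
#' @param ref_aa optional reference amino-acid sequence (character vector or
#'   string) used to label positively selected sites.
#' @return A `site_class_summary`: `overall` percentages, optional
#'   `by_region` table, and `pss` (positively selected site labels with
#'   posterior probabilities, or `"not allowed"` for class-3-incapable
#'   models).
#' @export
summarize_site_classes <- function(posterior, regions = NULL, ref_aa = NULL) {
  stopifnot(inherits(posterior, "site_posterior"))
  tab <- posterior$sites
  pct <- function(rows) {
    if (!length(rows)) return(c(class1 = NA, class2 = NA, class3 = NA))
    cl <- factor(tab$class[rows], levels = 1:3)
    as.numeric(100 * table(cl) / length(rows))
  }
  overall <- stats::setNames(pct(seq_len(nrow(tab))),
                             c("class1", "class2", "class3"))
  by_region <- NULL
  if (!is.null(regions) && nrow(regions)) {
    if (any(regions$end > max(tab$site))) {
      stop("region outside alignment (end beyond last site)")
    }
    by_region <- do.call(rbind, lapply(split(regions, regions$type),
      function(rr) {
        cols <- unique(unlist(Map(function(s, e) seq.int(s + 1L, e),
                                  rr$start, rr$end)))
        rows <- which(tab$site %in% cols)
        p <- pct(rows)
        data.frame(type = rr$type[1], n_sites = length(rows),
                   class1 = p[1], class2 = p[2], class3 = p[3])
      }))
    rownames(by_region) <- NULL
  }
  if (!posterior$class3_allowed) {
    pss <- "not allowed"
  } else {
    flagged <- which(!is.na(tab$pp_class3) & tab$pp_class3 > 0.95)
    lab <- vapply(flagged, function(i) {
      s <- tab$site[i]
      res <- if (!is.null(ref_aa)) {
        aa <- if (length(ref_aa) == 1L) strsplit(ref_aa, "")[[1]] else ref_aa
        if (s <= length(aa)) aa[s] else "?"
      } else ""
      paste0(s, res, if (tab$pp_class3[i] > 0.99) "**" else "*")
    }, character(1))
    pss <- if (length(lab)) lab else character(0)
  }
  structure(list(overall = overall, by_region = by_region, pss = pss,
                 model_id = posterior$model_id),
            class = "site_class_summary")
}

#' @export
print.site_class_summary <- function(x, ...) {
  cat("site classes (%):", paste(names(x$overall),
      round(x$overall, 2), sep = "=", collapse = "  "), "\n")
  if (!is.null(x$by_region)) print(x$by_region)
  cat("positively selected sites:",
      if (identical(x$pss, "not allowed")) "not allowed"
      else if (!length(x$pss)) "none" else paste(x$pss, collapse = ", "),
      "\n")
  invisible(x)
}
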