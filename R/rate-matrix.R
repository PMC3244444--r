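#' Equilibrium codon frequencies
#'
#' Builds the stationary distribution over the 61 sense codons from an
#' alignment under one of the standard empirical parameterizations:
#' `equal` (1/61), `F1X4` (pooled nucleotide frequencies), `F3X4`
#' (position-specific nucleotide frequencies) or `F61` (observed codon
#' counts with add-one smoothing). Frequencies over stop codons are excluded
#' and the vector renormalized, so all 61 entries are strictly positive.
#'
#' @param aln a `codon_alignment`; may be `NULL` for `model = "equal"`.
#' @param model frequency model.
#' @return Numeric vector of length 61, named by codon, summing to 1.
#' @export
codon_freqs <- function(aln = NULL,
                        model = c("F3X4", "F1X4", "F61", "equal")) {
  model <- match.arg(model)
  codons <- .code_env$codons
  if (model == "equal") {
    return(stats::setNames(rep(1 / 61, 61), codons))
  }
  if (is.null(aln)) stop("alignment required for model ", model)
  cod <- as.vector(aln$codons)
  cod <- cod[cod %in% codons] # usable sense codons only
  if (!length(cod)) stop("no complete sense codons in alignment")
  cmat <- do.call(rbind, strsplit(cod, ""))
  bases <- c("A", "C", "G", "T")
  pi_codon <- switch(model,
    F61 = {
      counts <- table(factor(cod, levels = codons)) + 1 # add-one smoothing
      as.numeric(counts)
    },
    F1X4 = {
      f <- table(factor(as.vector(cmat), levels = bases))
      f <- (as.numeric(f) + 1) / (sum(f) + 4)
      names(f) <- bases
      cm <- .code_env$codon_mat
      f[cm[, 1]] * f[cm[, 2]] * f[cm[, 3]]
    },
    F3X4 = {
      cm <- .code_env$codon_mat
      fp <- sapply(1:3, function(p) {
        f <- table(factor(cmat[, p], levels = bases))
        (as.numeric(f) + 1) / (sum(f) + 4)
      })
      rownames(fp) <- bases
      fp[cm[, 1], 1] * fp[cm[, 2], 2] * fp[cm[, 3], 3]
    })
  pi_codon <- pi_codon / sum(pi_codon)
  stats::setNames(pi_codon, codons)
}

#' Goldman-Yang codon rate matrix
#'
#' Instantaneous rate generator over the 61 sense codons. Only
#' single-nucleotide changes have nonzero rate; the rate from codon i to j is
#' `pi_j` times 1, `kappa`, `omega` or `omega * kappa` for synonymous
#' transversions, synonymous transitions, nonsynonymous transversions and
#' nonsynonymous transitions respectively. Rows sum to zero. With
#' `scale = TRUE` the generator is normalized so the expected number of
#' substitutions per codon per unit time, `sum_i pi_i * (-q_ii)`, equals 1.
#'
#' @param freqs equilibrium codon frequencies (length 61).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param scale normalize mean rate to 1 (default) or leave raw.
#' @return 61 x 61 generator matrix; attribute `"rate"` carries the raw mean
#'   rate before scaling.
#' @export
build_rate_matrix <- function(freqs, kappa, omega, scale = TRUE) {
  stopifnot(length(freqs) == 61, abs(sum(freqs) - 1) < 1e-8,
            all(freqs > 0), kappa > 0, omega >= 0)
  pt <- .code_env$pair_type
  mult <- matrix(0, 61, 61)
  mult[pt == 1L] <- 1
  mult[pt == 2L] <- kappa
  mult[pt == 3L] <- omega
  mult[pt == 4L] <- omega * kappa
  Q <- mult * rep(freqs, each = 61) # column j scaled by pi_j
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  if (scale) Q <- Q / rate
  attr(Q, "rate") <- rate
  dimnames(Q) <- list(.code_env$codons, .code_env$codons)
  Q
}

# Spectral decomposition of a reversible generator for fast repeated
# exponentials: Q = D^{-1/2} A D^{1/2} with A symmetric, D = diag(freqs).
.decompose_generator <- function(Q, freqs) {
  sp <- sqrt(freqs)
  A <- Q * (sp %o% (1 / sp))
  A <- (A + t(A)) / 2 # enforce exact symmetry
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors * (1 / sp),  # diag(1/sp) %*% U
       right = t(e$vectors * sp))    # t(U) %*% diag(sp)
}

.ptrans <- function(decomp, t) {
  P <- decomp$left %*% (exp(decomp$values * t) * decomp$right)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix exp(Qt)
#'
#' @param Q generator from [build_rate_matrix()].
#' @param t branch length (expected substitutions per codon), `t >= 0`.
#' @param freqs the equilibrium frequencies used to build `Q`.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_probabilities <- function(Q, t, freqs) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  d <- .decompose_generator(Q, freqs)
  P <- .ptrans(d, t)
  dimnames(P) <- dimnames(Q)
  P
}

# Additive decomposition of the GY generator for fast reassembly:
# Q(kappa, omega) = A1 + kappa*A2 + omega*A3 + omega*kappa*A4 (off-diagonal),
# with A_k holding pi_j at the positions of change type k.
.rate_matrix_parts <- function(freqs) {
  pt <- .code_env$pair_type
  base <- rep(freqs, each = 61)
  lapply(1:4, function(k) {
    M <- matrix(0, 61, 61)
    M[pt == k] <- base[pt == k]
    M
  })
}

.q_from_parts <- function(parts, kappa, omega) {
  Q <- parts[[1]] + kappa * parts[[2]] + omega * parts[[3]] +
    (omega * kappa) * parts[[4]]
  diag(Q) <- -rowSums(Q)
  Q
}

# Frequency-dependent flux constants of the GY generator. The raw mean rate
# decomposes as (T1 + kappa*T2) + omega*(T3 + kappa*T4) for synonymous
# transversions/transitions and nonsynonymous transversions/transitions.
.flux_consts <- function(freqs) {
  pt <- .code_env$pair_type
  pij <- freqs %o% freqs
  c(T1 = sum(pij[pt == 1L]), T2 = sum(pij[pt == 2L]),
    T3 = sum(pij[pt == 3L]), T4 = sum(pij[pt == 4L]))
}

# raw mean rate(s) of the unscaled generator at given kappa and omega(s)
.rate_of <- function(fc, kappa, omega) {
  unname((fc["T1"] + kappa * fc["T2"]) + omega * (fc["T3"] + kappa * fc["T4"]))
}

#' Expected dN and dS along a branch
#'
#' Partitions the substitution flux of the scaled generator into synonymous
#' and nonsynonymous parts and normalizes each by the corresponding site
#' proportion evaluated at the mutational null (`omega = 1`), giving expected
#' nonsynonymous substitutions per nonsynonymous site and synonymous
#' substitutions per synonymous site over a branch of length `t`. Under
#' `omega = 1` the two are equal for any `kappa` and frequency vector.
#'
#' @param freqs equilibrium codon frequencies.
#' @param kappa transition/transversion ratio.
#' @param omega dN/dS of the branch.
#' @param t branch length in expected substitutions per codon.
#' @return Named numeric vector `c(dN =, dS =)`; `dS` is 0 (with a warning
#'   suppressed into an attribute) when the synonymous flux vanishes.
#' @export
branch_expected_subs <- function(freqs, kappa, omega, t) {
  stopifnot(t >= 0)
  flux <- function(om) {
    Q <- build_rate_matrix(freqs, kappa, om, scale = FALSE)
    pt <- .code_env$pair_type
    fx <- freqs * Q # pi_i * q_ij
    syn <- sum(fx[pt == 1L | pt == 2L])
    nonsyn <- sum(fx[pt == 3L | pt == 4L])
    c(syn = syn, nonsyn = nonsyn)
  }
  f <- flux(omega)
  tot <- sum(f)
  f1 <- flux(1)
  rho <- f1 / sum(f1) # site proportions at the mutational null
  dN <- t * (f["nonsyn"] / tot) / rho["nonsyn"]
  dS <- if (f["syn"] > 0) t * (f["syn"] / tot) / rho["syn"] else 0
  out <- c(dN = unname(dN), dS = unname(dS))
  if (f["syn"] <= 0) attr(out, "zero_synonymous_flux") <- TRUE
  out
}
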