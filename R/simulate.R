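#' Simulate a codon alignment along a phylogeny
#'
#' Generative twin of the pruning likelihood: root codons are drawn from the
#' equilibrium distribution, each site is independently assigned a mixture
#' class (site models), and child states are drawn from the exact transition
#' probabilities `exp(Qt)` per branch, using the branch's partition omega for
#' clade models. The generators and their scaling are shared with
#' [log_likelihood()], so branch lengths mean the same thing to the simulator
#' and to the fitted models. No stop codon can ever be emitted (61-state
#' space).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param spec a [codon_model_spec()]; for branch-partition omegas also pass
#'   `edge_partition`.
#' @param Lc number of codon sites (>= 1).
#' @param seed integer seed; the same seed reproduces the alignment exactly.
#' @param edge_partition character vector per postorder edge (see
#'   [edge_partition()]) for branch-partition omega structures.
#' @param gene_label label stored on the alignment.
#' @return List with `alignment` (a [codon_alignment()] over the tips) and
#'   `truth`, a `simulation_truth` record holding every generative parameter,
#'   the per-site true class, the tree and the seed.
#' @export
simulate_codon_alignment <- function(tree, spec, Lc, seed,
                                     edge_partition = NULL,
                                     gene_label = "sim") {
  stopifnot(Lc >= 1)
  tree <- ape::reorder.phylo(tree, "postorder")
  gens <- .class_generators(spec)
  set.seed(seed)

  site_class <- if (gens$type == "mixture") {
    sample.int(length(gens$props), Lc, replace = TRUE, prob = gens$props)
  } else {
    rep(1L, Lc)
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  root <- edge[nrow(edge), 1]
  states <- matrix(NA_integer_, nnode, Lc)
  states[root, ] <- sample.int(61, Lc, replace = TRUE, prob = spec$freqs)

  # preorder = reverse postorder: parent states exist before children
  for (e in rev(seq_len(nrow(edge)))) {
    pa <- edge[e, 1]; ch <- edge[e, 2]
    t <- tree$edge.length[e]
    dec_of_class <- function(k) {
      if (gens$type == "partition") gens$decomps[[edge_partition[e]]]
      else gens$decomps[[k]]
    }
    child <- integer(Lc)
    for (k in unique(site_class)) {
      P <- .ptrans(dec_of_class(k), t)
      sites_k <- which(site_class == k)
      par_states <- states[pa, sites_k]
      for (s in unique(par_states)) {
        idx <- sites_k[par_states == s]
        child[idx] <- sample.int(61, length(idx), replace = TRUE,
                                 prob = P[s, ])
      }
    }
    states[ch, ] <- child
  }

  codons <- .code_env$codons
  seqs <- stats::setNames(vapply(seq_len(ntip), function(i)
    paste0(codons[states[i, ]], collapse = ""), character(1)),
    tree$tip.label)
  aln <- codon_alignment(seqs, gene_label)
  truth <- structure(list(
    model_id = if (inherits(spec$omega, "site_mixture"))
      spec$omega$model_id else if (gens$type == "partition") "branch" else "M0",
    kappa = spec$kappa, freqs = spec$freqs, omega = spec$omega,
    site_class = site_class, class_omegas = gens$omegas,
    edge_partition = edge_partition, tree = tree, Lc = Lc, seed = seed),
    class = "simulation_truth")
  list(alignment = aln, truth = truth)
}

#' Simulate a codon substitution path along one branch (Gillespie)
#'
#' Event-by-event simulation used to count realized synonymous and
#' nonsynonymous substitutions, e.g. to check [branch_expected_subs()]
#' against realized counts.
#'
#' @param freqs,kappa,omega model parameters.
#' @param t branch length (expected substitutions per codon; scaled
#'   generator).
#' @param n_sites number of independent codon sites.
#' @param seed integer seed.
#' @return List with `syn` and `nonsyn` total substitution counts and
#'   `end_state` integer vector.
#' @export
simulate_branch_counts <- function(freqs, kappa, omega, t, n_sites, seed) {
  Q <- build_rate_matrix(freqs, kappa, omega, scale = TRUE)
  pt <- .code_env$pair_type
  set.seed(seed)
  syn <- nonsyn <- 0L
  state <- sample.int(61, n_sites, replace = TRUE, prob = freqs)
  for (i in seq_len(n_sites)) {
    s <- state[i]
    time <- 0
    repeat {
      rate <- -Q[s, s]
      time <- time + stats::rexp(1, rate)
      if (time > t) break
      probs <- Q[s, ]
      probs[s] <- 0
      s2 <- sample.int(61, 1, prob = probs)
      if (pt[s, s2] %in% c(1L, 2L)) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      s <- s2
    }
    state[i] <- s
  }
  list(syn = syn, nonsyn = nonsyn, end_state = state)
}

#' Protamine-like equilibrium codon frequencies
#'
#' A fixed F3X4-style codon distribution built from position-specific
#' nucleotide frequencies skewed the way arginine-rich protamine coding
#' sequences are (G/A-heavy second positions from AGA/AGG/CGN arginine
#' codons). Used as the generating distribution in simulations so that the
#' empirical frequency models have something non-uniform to estimate.
#'
#' @return Named numeric vector of length 61 summing to 1.
#' @export
protamine_like_freqs <- function() {
  p1 <- c(A = .35, C = .25, G = .30, T = .10)
  p2 <- c(A = .25, C = .15, G = .45, T = .15)
  p3 <- c(A = .30, C = .20, G = .30, T = .20)
  cm <- .code_env$codon_mat
  fr <- p1[cm[, 1]] * p2[cm[, 2]] * p3[cm[, 3]]
  fr <- fr / sum(fr)
  stats::setNames(unname(fr), .code_env$codons)
}

#' Simulate phylogenetically correlated species traits
#'
#' Generative twin of [pgls_fit()]: the predictor is drawn with covariance
#' `exp(-alpha * d_ij)` across species (`d` = patristic distance), and the
#' response is `intercept + slope * x` plus phylogenetic noise with the same
#' exponential correlation and marginal standard deviation `noise_sd`.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param alpha exponential decay of the phylogenetic correlation (>= 0).
#' @param slope,intercept regression truth.
#' @param noise_sd marginal standard deviation of the phylogenetic noise.
#' @param seed integer seed.
#' @return `data.frame` with columns `species`, `x` (predictor, e.g.
#'   relative testes mass on the analysis scale) and `y` (response, e.g.
#'   root-to-tip omega).
#' @export
simulate_traits <- function(tree, alpha, slope, intercept, noise_sd, seed) {
  stopifnot(alpha >= 0)
  D <- ape::cophenetic.phylo(tree)
  C <- exp(-alpha * D)
  n <- nrow(C)
  L <- t(chol(C + diag(1e-10, n)))
  set.seed(seed)
  x <- as.vector(L %*% stats::rnorm(n))
  y <- intercept + slope * x + noise_sd * as.vector(L %*% stats::rnorm(n))
  data.frame(species = rownames(C), x = x, y = y, stringsAsFactors = FALSE)
}

#' Slope giving a target pGLS correlation
#'
#' With the predictor whitened to unit variance and noise of standard
#' deviation `noise_sd`, the standardized slope (GLS correlation) equals
#' `slope / sqrt(slope^2 + noise_sd^2)`; this helper inverts that relation.
#'
#' @param r target correlation in (-1, 1).
#' @param noise_sd noise standard deviation.
#' @return Slope on the raw scale.
#' @export
slope_for_correlation <- function(r, noise_sd = 1) {
  stopifnot(abs(r) < 1)
  r * noise_sd / sqrt(1 - r^2)
}

#' Write a self-contained fixture bundle
#'
#' Emits, under `out_dir`: the 17-taxon tree (Newick), the 16-taxon clade
#' tree, three codon alignments (FASTA) simulated under the three regimes of
#' the clade analysis — positive selection in the focal clade, relaxation
#' (focal omega ~ 1), and a one-ratio null — a species trait table (TSV) and
#' a truth JSON per alignment. Every file parses with the package's readers.
#'
#' @param out_dir writable directory (created if missing).
#' @param seed integer master seed.
#' @param Lc codons per simulated alignment.
#' @return Invisibly, a named list of written paths.
#' @export
make_fixture_set <- function(out_dir, seed = 1, Lc = 300) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  site_tree <- cricetidae_tree()
  clade_tree <- clade_fixture_tree()
  fg <- clade_fixture_foreground()
  freqs <- codon_freqs(model = "equal")
  part <- edge_partition(clade_tree, fg)

  regimes <- list(
    clade_positive = c(background = 0.3, foreground = 2.44),
    clade_relaxed = c(background = 0.1, foreground = 1.0),
    one_ratio = 0.3)
  paths <- list()
  p <- file.path(out_dir, "site_tree.nwk")
  ape::write.tree(site_tree, p); paths$site_tree <- p
  p <- file.path(out_dir, "clade_tree.nwk")
  ape::write.tree(clade_tree, p); paths$clade_tree <- p

  for (i in seq_along(regimes)) {
    nm <- names(regimes)[i]
    om <- regimes[[i]]
    spec <- codon_model_spec(2, freqs, om)
    sim <- simulate_codon_alignment(
      clade_tree, spec, Lc, seed = seed + i,
      edge_partition = if (length(om) > 1) part else NULL, gene_label = nm)
    fa <- file.path(out_dir, paste0(nm, ".fasta"))
    write_fasta(sim$alignment, fa)
    tj <- file.path(out_dir, paste0(nm, "_truth.json"))
    tr <- sim$truth
    jsonlite::write_json(list(
      model_id = tr$model_id, kappa = tr$kappa, omega = as.list(tr$omega),
      Lc = tr$Lc, seed = tr$seed,
      foreground = if (length(om) > 1) fg else NULL), tj,
      auto_unbox = TRUE, digits = NA)
    paths[[nm]] <- fa
    paths[[paste0(nm, "_truth")]] <- tj
  }

  traits <- simulate_traits(site_tree, alpha = 8, slope = -1,
                            intercept = 1.2, noise_sd = 0.5,
                            seed = seed + 100)
  # present as masses: body mass around 30 g, testes mass from predictor
  traits_tab <- data.frame(
    species = traits$species,
    body_mass_g = round(30 * exp(0.1 * seq_len(nrow(traits))), 2),
    testes_mass_g = round(0.4 * exp(0.3 * traits$x), 4))
  p <- file.path(out_dir, "traits.tsv")
  utils::write.table(traits_tab, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$traits <- p
  invisible(paths)
}
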