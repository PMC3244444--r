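#' @importFrom ape reorder.phylo drop.tip
NULL

# Precompute everything that does not depend on parameters: postorder tree,
# encoded tip states, site-pattern compression.
.prep_likelihood <- function(alignment, tree) {
  if (!all(alignment$taxa %in% tree$tip.label)) {
    stop("taxon mismatch: alignment taxa not all present in tree: ",
         paste(setdiff(alignment$taxa, tree$tip.label), collapse = ", "))
  }
  extra <- setdiff(tree$tip.label, alignment$taxa)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree <- ape::reorder.phylo(tree, "postorder")
  st <- matrix(.encode_codons(alignment$codons), nrow = length(alignment$taxa))
  rownames(st) <- alignment$taxa
  st <- st[tree$tip.label, , drop = FALSE]
  key <- apply(st, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- st[, first, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[first])))
  tipstate <- pat
  tipstate[is.na(tipstate)] <- 0L # 0 encodes missing for the C kernel
  storage.mode(tipstate) <- "integer"
  edge <- tree$edge
  storage.mode(edge) <- "integer"
  list(tree = tree, weights = w, S = ncol(pat), L = n_codons(alignment),
       edge = edge, ntip = length(tree$tip.label), nnode = tree$Nnode,
       tipstate = tipstate, pattern_of_site = match(key, key[first]))
}

# Felsenstein pruning, one site class, via the compiled kernel. `decomps` is
# a list of spectral decompositions and `didx` maps each postorder edge to
# one of them (a branch-partition model uses several; site classes use one).
# Returns per-pattern log-likelihoods.
.prune_loglik <- function(prep, decomps, didx, elen, freqs) {
  prune_loglik_cpp(prep$edge, prep$ntip, prep$nnode,
                   lapply(decomps, `[[`, "left"),
                   lapply(decomps, `[[`, "right"),
                   lapply(decomps, `[[`, "values"),
                   as.integer(didx), as.numeric(elen), prep$tipstate,
                   as.numeric(freqs))
}

.logsumexp_rows <- function(M) {
  # M: K x S of logs; returns length-S log(sum_k exp(M[k, ]))
  mx <- apply(M, 2, max)
  mx + log(colSums(exp(M - rep(mx, each = nrow(M)))))
}

# Per-pattern log-likelihood matrix, one row per site class.
# edge_partition: character per edge row for branch-partition structures.
# cache: optional environment memoizing single-class passes by
# (kappa | omega | edge lengths); used by the fitter.
.class_pattern_logliks <- function(prep, spec, gens, edge_len,
                                   edge_partition = NULL) {
  if (gens$type == "partition") {
    if (is.null(edge_partition)) {
      stop("branch-partition model needs an edge partition")
    }
    didx <- match(edge_partition, names(gens$decomps))
    ll <- .prune_loglik(prep, gens$decomps, didx, edge_len, spec$freqs)
    matrix(ll, nrow = 1)
  } else {
    K <- length(gens$decomps)
    out <- matrix(0, K, prep$S)
    ones <- rep(1L, nrow(prep$edge))
    for (k in seq_len(K)) {
      out[k, ] <- .prune_loglik(prep, gens$decomps[k], ones, edge_len,
                                spec$freqs)
    }
    out
  }
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over the 61-codon state space. For site mixtures the
#' per-site likelihood is the proportion-weighted sum over classes; codons
#' with gaps or ambiguities at a tip sum over all compatible states (treated
#' as missing data). Computation is done on compressed site patterns in
#' log space with per-node rescaling, so long alignments do not underflow.
#' Branch lengths are expected substitutions per codon (averaged over site
#' classes for mixtures).
#'
#' @param alignment a [codon_alignment()]; its taxa must be a subset of the
#'   tree's tips (extra tips are pruned).
#' @param tree rooted `phylo` with branch lengths in expected substitutions
#'   per codon.
#' @param spec a [codon_model_spec()].
#' @param edge_partition for branch-partition omega structures, a character
#'   vector along `reorder(tree, "postorder")$edge` rows naming the partition
#'   of each branch; see [edge_partition()].
#' @param per_site return per-site log-likelihoods as an attribute.
#' @return Total log-likelihood (numeric scalar). With `per_site = TRUE`, the
#'   attribute `"site_loglik"` holds the per-column values.
#' @export
log_likelihood <- function(alignment, tree, spec, edge_partition = NULL,
                           per_site = FALSE) {
  prep <- .prep_likelihood(alignment, tree)
  if (is.null(prep$tree$edge.length)) stop("tree must have branch lengths")
  gens <- .class_generators(spec)
  M <- .class_pattern_logliks(prep, spec, gens, prep$tree$edge.length,
                              edge_partition)
  site_ll <- if (nrow(M) == 1L) M[1, ] else .logsumexp_rows(M + log(gens$props))
  lnl <- sum(prep$weights * site_ll)
  if (per_site) attr(lnl, "site_loglik") <- site_ll[prep$pattern_of_site]
  lnl
}

#' Label tree branches as foreground clade vs background
#'
#' Marks every branch inside the clade spanned by `foreground_tips` (and, by
#' default, the clade's stem branch) as `"foreground"`, everything else as
#' `"background"`. The returned labels follow the edge rows of
#' `reorder(tree, "postorder")`, the ordering used by the likelihood engine.
#'
#' @param tree rooted `phylo`.
#' @param foreground_tips tip labels spanning the focal clade.
#' @param include_stem include the branch subtending the clade (default TRUE).
#' @return Character vector, one entry per postorder edge.
#' @export
edge_partition <- function(tree, foreground_tips, include_stem = TRUE) {
  tree <- ape::reorder.phylo(tree, "postorder")
  stopifnot(all(foreground_tips %in% tree$tip.label))
  ntip <- length(tree$tip.label)
  tipno <- match(foreground_tips, tree$tip.label)
  mrca <- if (length(tipno) == 1L) tipno else ape::getMRCA(tree, tipno)
  desc <- if (length(tipno) == 1L) tipno
          else c(mrca, .descendants(tree, mrca))
  clade_tips <- intersect(desc, seq_len(ntip))
  if (!setequal(clade_tips, tipno)) {
    stop("foreground tips do not form a connected clade (MRCA spans ",
         length(clade_tips), " tips)")
  }
  lab <- rep("background", nrow(tree$edge))
  inside <- tree$edge[, 1] %in% desc # parent inside clade
  lab[inside] <- "foreground"
  if (include_stem) lab[tree$edge[, 2] == mrca] <- "foreground"
  lab
}

# all descendants of a node (internal + tips), plain traversal
.descendants <- function(tree, node) {
  out <- integer(0)
  todo <- node
  while (length(todo)) {
    kids <- tree$edge[tree$edge[, 1] %in% todo, 2]
    out <- c(out, kids)
    todo <- kids[kids > length(tree$tip.label)]
  }
  unique(out)
}
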