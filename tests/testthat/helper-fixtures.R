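# small shared fixtures, all generated in code

toy_tree3 <- function() {
  ape::read.tree(text = "((A:0.2,B:0.3):0.1,C:0.4);")
}

toy_tree4 <- function() {
  ape::read.tree(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
}

toy_tree6 <- function() {
  ape::read.tree(text = paste0(
    "(((A:0.05,B:0.05):0.03,(C:0.05,D:0.05):0.03):0.03,",
    "(E:0.08,F:0.08):0.03);"))
}

equal_freqs <- function() codon_freqs(model = "equal")

# brute-force pruning oracle: enumerate all internal-node states
brute_force_loglik <- function(aln, tree, spec) {
  tree <- ape::reorder.phylo(tree, "postorder")
  gens <- protsel:::.class_generators(spec)
  st <- matrix(match(as.vector(aln$codons), sense_codons()),
               nrow = length(aln$taxa))
  rownames(st) <- aln$taxa
  st <- st[tree$tip.label, , drop = FALSE]
  ntip <- nrow(st)
  nnode <- tree$Nnode
  edge <- tree$edge
  total <- 0
  for (s in seq_len(ncol(st))) {
    sitelik <- 0
    for (k in seq_along(gens$props)) {
      P <- lapply(seq_len(nrow(edge)), function(e)
        protsel:::.ptrans(gens$decomps[[k]], tree$edge.length[e]))
      # enumerate internal states
      combos <- as.matrix(expand.grid(rep(list(1:61), nnode)))
      lik <- 0
      root <- edge[nrow(edge), 1]
      for (r in seq_len(nrow(combos))) {
        states <- c(st[, s], combos[r, ])
        pr <- spec$freqs[states[root]]
        for (e in seq_len(nrow(edge))) {
          pr <- pr * P[[e]][states[edge[e, 1]], states[edge[e, 2]]]
        }
        lik <- lik + pr
      }
      sitelik <- sitelik + gens$props[k] * lik
    }
    total <- total + log(sitelik)
  }
  total
}
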