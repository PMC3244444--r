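#' Fixture phylogenies
#'
#' `cricetidae_tree()` is a rooted 17-taxon tree shaped like the study
#' system: 16 cricetid rodents — subfamilies Arvicolinae (10 species),
#' Cricetinae (5) and Sigmodontinae (1) — with *Mus musculus* as outgroup,
#' the input used for branch and site analyses. `clade_fixture_tree()` is a
#' rooted 16-taxon tree holding an 8-taxon focal ("Cricetidae-shaped") clade
#' against a murid background plus outgroup, the input shape used for clade
#' tests. Branch lengths are plausible values in expected substitutions per
#' codon for rodent protamines (tens of millions of years of divergence on a
#' fast-evolving short gene).
#'
#' @return A rooted `phylo` with branch lengths.
#' @name fixture_trees
NULL

#' @rdname fixture_trees
#' @export
cricetidae_tree <- function() {
  arv <- paste0(
    "((((((MAR:0.02,MCA:0.02):0.01,MAG:0.03):0.01,(MGE:0.02,",
    "(PDU:0.015,PLU:0.015):0.01):0.015):0.01,CNI:0.05):0.01,",
    "(ASA:0.02,ATE:0.02):0.04):0.02,CGL:0.08):0.06")
  cri <- paste0(
    "(((PSU:0.02,PCM:0.02):0.02,PRO:0.04):0.04,",
    "(MAU:0.07,CGR:0.07):0.02):0.06")
  nwk <- paste0("(((", arv, ",", cri, "):0.03,SHI:0.17):0.05,MMU:0.22);")
  ape::read.tree(text = nwk)
}

#' @rdname fixture_trees
#' @param foreground_size unused placeholder kept for clarity; the focal
#'   clade has 8 tips labelled `FG1..FG8`.
#' @export
clade_fixture_tree <- function(foreground_size = 8) {
  fg <- paste0(
    "((((FG1:0.02,FG2:0.02):0.02,(FG3:0.03,FG4:0.03):0.01):0.02,",
    "(FG5:0.04,FG6:0.04):0.02):0.02,(FG7:0.05,FG8:0.05):0.03):0.04")
  bg <- paste0(
    "((((BG1:0.04,BG2:0.04):0.03,BG3:0.07):0.03,",
    "(BG4:0.06,BG5:0.06):0.04):0.03,(BG6:0.08,BG7:0.08):0.05):0.03")
  nwk <- paste0("((", fg, ",", bg, "):0.05,OUT:0.25);")
  ape::read.tree(text = nwk)
}

#' Tips of the focal clade in [clade_fixture_tree()]
#' @return Character vector of foreground tip labels.
#' @export
clade_fixture_foreground <- function() paste0("FG", 1:8)
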