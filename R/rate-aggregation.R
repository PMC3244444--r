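#' Free-ratio fit: an independent omega on every branch
#'
#' Convenience wrapper around [fit()] with `model_id = "free_ratio"`; the
#' resulting `branch_table` carries per-branch `(t, dN, dS, omega)` used for
#' root-to-tip aggregation.
#'
#' @inheritParams fit
#' @param ... passed to [fit()].
#' @return A `codon_fit`.
#' @export
free_ratio_fit <- function(alignment, tree, ...) {
  fit(alignment, tree, model_id = "free_ratio", ...)
}

#' Cumulative root-to-tip omega for one species
#'
#' Sums the expected nonsynonymous (`dN`) and synonymous (`dS`) substitutions
#' per site over every branch on the unique path from the root to the
#' species' tip, and takes the ratio of the sums (not the mean of per-branch
#' ratios). This measures the total accumulated selective pressure along a
#' lineage, the quantity related to sperm-competition levels downstream.
#'
#' @param fit a `codon_fit` (typically from [free_ratio_fit()]).
#' @param species tip label.
#' @return A one-row `data.frame`: `species`, `sum_dN`, `sum_dS`,
#'   `omega_path` (`NA` with a warning when `sum_dS` is 0).
#' @export
root_to_tip_omega <- function(fit, species) {
  tree <- fit$tree
  if (!species %in% tree$tip.label) stop("unknown species: ", species)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  path <- ape::nodepath(tree, root, match(species, tree$tip.label))
  bt <- fit$branch_table
  sum_dN <- 0; sum_dS <- 0
  for (i in seq_len(length(path) - 1L)) {
    row <- which(bt$parent == path[i] & bt$child == path[i + 1L])
    if (length(row) != 1L) stop("path edge not found in branch table")
    sum_dN <- sum_dN + bt$dN[row]
    sum_dS <- sum_dS + bt$dS[row]
  }
  omega_path <- if (sum_dS > 0) sum_dN / sum_dS else NA_real_
  if (is.na(omega_path)) {
    warning("sum of dS is zero for ", species,
            "; omega_path undefined (species should be dropped downstream)")
  }
  data.frame(species = species, sum_dN = sum_dN, sum_dS = sum_dS,
             omega_path = omega_path, stringsAsFactors = FALSE)
}

#' Root-to-tip omega table for all species
#'
#' @param fit a `codon_fit` from [free_ratio_fit()].
#' @return `data.frame` with one row per tip: `species`, `sum_dN`, `sum_dS`,
#'   `omega_path`.
#' @export
path_omega_table <- function(fit) {
  do.call(rbind, lapply(fit$tree$tip.label,
                        function(sp) suppressWarnings(
                          root_to_tip_omega(fit, sp))))
}
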