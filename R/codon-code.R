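#' @importFrom Biostrings GENETIC_CODE
NULL

# Universal genetic code over the 61 sense codons. The state space is fixed:
# stop codons are excluded and never appear in alignments or simulations.
.code_env <- new.env(parent = emptyenv())

.build_code_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons) # 61
  cmat <- do.call(rbind, strsplit(codons, ""))

  purines <- c("A", "G")
  is_transition <- function(a, b) {
    (a %in% purines) == (b %in% purines)
  }

  # pair_type[i, j]: 0 = not a single-nucleotide change; 1 = syn transversion,
  # 2 = syn transition, 3 = nonsyn transversion, 4 = nonsyn transition
  pt <- matrix(0L, n, n)
  diff_pos <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(cmat[i, ] != cmat[j, ])
      if (length(d) != 1L) next
      ts <- is_transition(cmat[i, d], cmat[j, d])
      syn <- aa[i] == aa[j]
      pt[i, j] <- if (syn) (if (ts) 2L else 1L) else (if (ts) 4L else 3L)
      diff_pos[i, j] <- d
    }
  }
  dimnames(pt) <- list(codons, codons)

  assign("codons", codons, envir = .code_env)
  assign("codon_aa", stats::setNames(aa, codons), envir = .code_env)
  assign("codon_mat", cmat, envir = .code_env)
  assign("pair_type", pt, envir = .code_env)
  assign("stop_codons", names(gc)[gc == "*"], envir = .code_env)
  invisible(NULL)
}

.build_code_tables()

#' The 61 sense codons of the universal genetic code
#'
#' @return Character vector of length 61, the fixed codon state order used
#'   throughout the package.
#' @export
sense_codons <- function() .code_env$codons

#' Translate codon strings to amino acids (universal code)
#'
#' @param codons character vector of codon strings.
#' @return Character vector of one-letter amino acids; `"*"` for stop codons,
#'   `NA` for codons containing gaps or ambiguity characters.
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[toupper(codons)])
  out
}

# codon string -> integer state in 1..61; NA for gap / ambiguity; error on stop
.encode_codons <- function(codons, allow_stop = FALSE) {
  codons <- toupper(codons)
  idx <- match(codons, .code_env$codons)
  is_stop <- codons %in% .code_env$stop_codons
  if (!allow_stop && any(is_stop)) {
    stop("alignment contains stop codon(s): ",
         paste(unique(codons[is_stop]), collapse = ", "))
  }
  idx
}

# IUPAC nucleotide ambiguity codes keyed by the sorted base set they cover
.iupac_from_set <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)
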