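#' In-frame codon alignments
#'
#' A `codon_alignment` holds an in-frame nucleotide alignment as an N x Lc
#' matrix of codon strings over the 61 sense codons plus gap / IUPAC-ambiguity
#' states. Stop codons are rejected: a sequence whose reading frame contains a
#' sense stop is not a valid member of a coding alignment (use
#' [integrity_check()] to diagnose such sequences first).
#'
#' All coordinates used on alignments are 0-based, half-open intervals in
#' codon units.
#'
#' @param seqs named character vector of aligned nucleotide sequences
#'   (IUPAC, `-` for gaps). Names are taxon identifiers and must be unique.
#' @param gene_label optional text label carried through reports.
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `codons` (N x Lc character matrix) and `gene_label`.
#' @export
codon_alignment <- function(seqs, gene_label = "") {
  if (length(seqs) < 1L) stop("empty alignment")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique taxon names")
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  }
  if (lens[1] %% 3L != 0L) {
    stop("frame error: alignment length ", lens[1], " not divisible by 3")
  }
  lc <- lens[1] %/% 3L
  cod <- matrix("", length(seqs), lc, dimnames = list(names(seqs), NULL))
  starts <- seq(1L, by = 3L, length.out = lc)
  for (i in seq_along(seqs)) {
    cod[i, ] <- substring(seqs[i], starts, starts + 2L)
  }
  bad <- matrix(cod %in% .code_env$stop_codons, nrow = nrow(cod))
  if (any(bad)) {
    stop("frame/stop error: sense stop codon(s) in alignment (e.g. taxon '",
         rownames(cod)[which(bad, arr.ind = TRUE)[1, 1]], "')")
  }
  structure(list(taxa = names(seqs), codons = cod, gene_label = gene_label),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", ncol(x$codons), "codons",
      if (nzchar(x$gene_label)) paste0("[", x$gene_label, "]") else "", "\n")
  invisible(x)
}

#' Number of codon columns
#' @param aln a `codon_alignment`.
#' @return Integer count of codon columns.
#' @export
n_codons <- function(aln) ncol(aln$codons)

# flat nucleotide strings, one per taxon
.aln_strings <- function(aln) {
  stats::setNames(apply(aln$codons, 1, paste0, collapse = ""), aln$taxa)
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path path to an aligned FASTA file of in-frame coding sequences.
#' @param gene_label optional label stored on the alignment.
#' @return A [codon_alignment()].
#' @export
read_fasta <- function(path, gene_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(ss), names(ss)), gene_label)
}

#' Write a codon alignment to FASTA
#'
#' Round-tripping through [read_fasta()] preserves taxa order and sequence
#' content exactly.
#'
#' @param aln a `codon_alignment`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  seqs <- .aln_strings(aln)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Majority-rule consensus of individual sequences
#'
#' Column-wise majority base; ties are encoded as the IUPAC ambiguity code
#' covering the tied bases. Non-ACGT characters (gaps, ambiguities) are
#' ignored in the vote; a column with no ACGT observations yields `N`.
#'
#' @param individual_seqs character vector of >= 2 equal-length nucleotide
#'   sequences (e.g. from several individuals of one species).
#' @return Single consensus sequence string.
#' @export
consensus_sequence <- function(individual_seqs) {
  if (length(individual_seqs) < 2L) stop("need at least 2 sequences")
  individual_seqs <- toupper(individual_seqs)
  lens <- nchar(individual_seqs)
  if (length(unique(lens)) != 1L) stop("sequences have unequal lengths")
  m <- do.call(rbind, strsplit(individual_seqs, ""))
  bases <- c("A", "C", "G", "T")
  out <- apply(m, 2, function(col) {
    tab <- table(factor(col[col %in% bases], levels = bases))
    mx <- max(tab)
    if (mx == 0L) return("N")
    winners <- sort(bases[tab == mx])
    .iupac_from_set[[paste0(winners, collapse = "")]]
  })
  paste0(out, collapse = "")
}

#' Domain boundary for a precursor coding region
#'
#' Half-open, 0-based codon intervals for the proteolytically cleaved
#' N-terminal domain and the mature domain of a precursor. The two ranges
#' must be disjoint, contiguous and jointly cover the precursor.
#'
#' @param cleaved_end first codon column of the mature domain (also the length
#'   of the cleaved domain).
#' @param total total codon columns of the precursor alignment.
#' @return A `domain_boundary` list with `cleaved_range` and `mature_range`.
#' @export
domain_boundary <- function(cleaved_end, total) {
  if (cleaved_end < 0 || cleaved_end > total) {
    stop("range error: boundary ", cleaved_end, " outside [0, ", total, "]")
  }
  structure(list(cleaved_range = c(0L, as.integer(cleaved_end)),
                 mature_range = c(as.integer(cleaved_end), as.integer(total))),
            class = "domain_boundary")
}

#' Split a precursor alignment into cleaved and mature domains
#'
#' Protamine 2 is translated as a precursor whose N-terminal ("cleaved")
#' domain is removed by proteolysis; the two domains are analysed separately.
#' Concatenating the two returned sub-alignments restores the input.
#'
#' @param alignment a `codon_alignment` of the full precursor.
#' @param boundary a [domain_boundary()] in alignment codon columns.
#' @return List with elements `cleaved` and `mature`, both `codon_alignment`s.
#' @export
split_prm2 <- function(alignment, boundary) {
  lc <- n_codons(alignment)
  if (boundary$mature_range[2] != lc) {
    stop("range error: boundary covers ", boundary$mature_range[2],
         " codons but alignment has ", lc)
  }
  take <- function(rng, lab) {
    cols <- if (rng[2] > rng[1]) seq.int(rng[1] + 1L, rng[2]) else integer(0)
    cod <- alignment$codons[, cols, drop = FALSE]
    seqs <- stats::setNames(apply(cod, 1, paste0, collapse = ""),
                            alignment$taxa)
    if (all(nchar(seqs) == 0)) {
      # degenerate empty part: keep a valid, zero-column alignment
      return(structure(list(taxa = alignment$taxa,
                            codons = cod, gene_label = lab),
                       class = "codon_alignment"))
    }
    codon_alignment(seqs, lab)
  }
  lab <- alignment$gene_label
  list(cleaved = take(boundary$cleaved_range, paste0(lab, "_cleaved")),
       mature = take(boundary$mature_range, paste0(lab, "_mature")))
}

#' Percent identity between two protein sequences
#'
#' Identical residues / compared positions x 100. Columns with a gap (`-`) in
#' either sequence are excluded from the denominator. Unaligned inputs are
#' first globally aligned (Needleman-Wunsch with BLOSUM62 via Biostrings).
#'
#' @param seq_a,seq_b amino-acid sequences.
#' @param aligned if `TRUE` (default) the inputs are already aligned and must
#'   have equal length.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seq_a, seq_b, aligned = TRUE) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!aligned) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    seq_a <- as.character(Biostrings::alignedPattern(pa))
    seq_b <- as.character(Biostrings::alignedSubject(pa))
  }
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length")
  }
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) stop("undefined identity: no comparable positions")
  100 * sum(a[keep] == b[keep]) / sum(keep)
}

#' Flag pseudogenized coding sequences
#'
#' A sequence is called dysfunctional if any of: it contains a premature stop
#' codon, its length is not a multiple of 3, or its best protein identity
#' against a panel of orthologues falls below `identity_floor`. This mirrors
#' the diagnosis of a degenerate protamine 2 orthologue that accumulated
#' defective mutations and lost expression.
#'
#' @param seq nucleotide coding sequence (a terminal stop codon is allowed).
#' @param reference_orthologues character vector of amino-acid sequences to
#'   compare against (may be `NULL` to skip the identity criterion).
#' @param identity_floor percent identity below which the identity criterion
#'   triggers; ignored when no references are given.
#' @return List with `status` (`"intact"` or `"dysfunctional"`), `criteria`
#'   (character vector of triggered criteria) and `best_identity`.
#' @export
integrity_check <- function(seq, reference_orthologues = NULL,
                            identity_floor = NULL) {
  seq <- toupper(seq)
  criteria <- character(0)
  n <- nchar(seq)
  if (n %% 3L != 0L) criteria <- c(criteria, "length_not_multiple_of_3")
  n_cod <- n %/% 3L
  best_id <- NA_real_
  if (n_cod >= 1L) {
    cods <- substring(seq, seq(1L, by = 3L, length.out = n_cod),
                      seq(3L, by = 3L, length.out = n_cod))
    aa <- translate_codons(cods)
    stops <- which(!is.na(aa) & aa == "*")
    if (any(stops < n_cod)) criteria <- c(criteria, "premature_stop")
    if (!is.null(identity_floor)) {
      if (is.null(reference_orthologues) || !length(reference_orthologues)) {
        stop("config error: identity criterion requested with no references")
      }
      prot <- paste0(aa[!is.na(aa) & aa != "*"], collapse = "")
      ids <- vapply(reference_orthologues, function(ref) {
        tryCatch(pairwise_identity(prot, ref, aligned = FALSE),
                 error = function(e) 0)
      }, numeric(1))
      best_id <- max(ids)
      if (best_id < identity_floor) {
        criteria <- c(criteria, "identity_below_floor")
      }
    }
  }
  list(status = if (length(criteria)) "dysfunctional" else "intact",
       criteria = criteria, best_identity = best_id)
}

#' Subset an alignment to a set of taxa
#'
#' @param aln a `codon_alignment`.
#' @param taxa taxon names to keep (order preserved as given).
#' @return A `codon_alignment` with the selected rows.
#' @export
subset_taxa <- function(aln, taxa) {
  stopifnot(all(taxa %in% aln$taxa))
  cod <- aln$codons[match(taxa, aln$taxa), , drop = FALSE]
  seqs <- stats::setNames(apply(cod, 1, paste0, collapse = ""), taxa)
  codon_alignment(seqs, aln$gene_label)
}

#' Drop alignment columns containing gaps or ambiguities
#'
#' Likelihood computations can either treat gap/ambiguous codons as missing
#' data or remove those columns entirely (`cleandata`); removal is the
#' default in the model-fitting layer and is applied through this helper.
#'
#' @param aln a `codon_alignment`.
#' @return List with the filtered `alignment` and `kept`, the 1-based indices
#'   of retained columns.
#' @export
drop_incomplete_columns <- function(aln) {
  st <- matrix(.encode_codons(aln$codons, allow_stop = FALSE),
               nrow = nrow(aln$codons))
  keep <- colSums(is.na(st)) == 0L
  cod <- aln$codons[, keep, drop = FALSE]
  seqs <- stats::setNames(apply(cod, 1, paste0, collapse = ""), aln$taxa)
  list(alignment = codon_alignment(seqs, aln$gene_label), kept = which(keep))
}
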