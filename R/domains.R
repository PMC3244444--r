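# region tables are BED-like: 0-based half-open residue intervals
.region_df <- function(type, start, end, source) {
  data.frame(type = type, start = as.integer(start), end = as.integer(end),
             source = source, stringsAsFactors = FALSE)
}

.empty_regions <- function() {
  .region_df(character(0), integer(0), integer(0), character(0))
}

#' Scan for DNA-anchoring domains
#'
#' Protamine DNA-anchoring domains are runs of 3 or more consecutive
#' arginine/lysine residues flanked by short peptide segments containing
#' cysteine. A maximal `[RK]{3,}` run qualifies if a cysteine occurs within
#' `flank_window` residues on at least one side; the reported interval is the
#' run extended to include each qualifying cysteine. Overlapping qualifying
#' intervals are merged.
#'
#' @param seq amino-acid sequence (string).
#' @param flank_window residues searched on each side for a cysteine
#'   (default 5).
#' @return BED-like `data.frame` (`type`, `start`, `end`, `source`), 0-based
#'   half-open coordinates.
#' @export
scan_anchoring <- function(seq, flank_window = 5) {
  seq <- toupper(seq)
  aa <- strsplit(seq, "")[[1]]
  m <- gregexpr("[RK]{3,}", seq)[[1]]
  if (m[1] == -1) return(.empty_regions())
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  keep <- logical(length(starts))
  rs <- re <- integer(length(starts))
  for (i in seq_along(starts)) {
    lwin <- seq.int(max(1L, starts[i] - flank_window + 1L),
                    length.out = min(flank_window, starts[i]))
    rwin <- seq.int(ends[i] + 1L,
                    length.out = min(flank_window, length(aa) - ends[i]))
    lc <- lwin[aa[lwin] == "C"]
    rc <- rwin[aa[rwin] == "C"]
    if (length(lc) || length(rc)) {
      keep[i] <- TRUE
      rs[i] <- if (length(lc)) min(lc) - 1L else starts[i]
      re[i] <- if (length(rc)) max(rc) else ends[i]
    }
  }
  if (!any(keep)) return(.empty_regions())
  out <- .region_df("anchoring", rs[keep], re[keep], "scanned")
  .merge_regions(out)
}

.merge_regions <- function(df) {
  df <- df[order(df$start), , drop = FALSE]
  keep <- list()
  cur <- df[1, ]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= cur$end) {
      cur$end <- max(cur$end, df$end[i])
    } else {
      keep[[length(keep) + 1]] <- cur
      cur <- df[i, ]
    }
  }
  keep[[length(keep) + 1]] <- cur
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

# consensus phosphorylation patterns (ProSite-style)
.kinase_patterns <- c(
  PKC = "[ST].[RK]",      # protein kinase C: [ST]-x-[RK]
  PKA = "[RK][RK].[ST]",  # protein kinase A: [RK]-[RK]-x-[ST]
  CK2 = "[ST]..[DE]")     # casein kinase II: [ST]-x-x-[DE]

#' Scan for phosphorylation motifs
#'
#' Matches consensus kinase target patterns on a protein sequence: PKC
#' `[ST]-x-[RK]`, PKA `[RK]-[RK]-x-[ST]`, CK2 `[ST]-x-x-[DE]`. All
#' overlapping matches are reported.
#'
#' @param seq amino-acid sequence (string).
#' @param kinases subset of `c("PKC", "PKA", "CK2")`.
#' @return BED-like `data.frame` with types `phospho_PKC` etc.
#' @export
scan_phospho <- function(seq, kinases = c("PKC", "PKA", "CK2")) {
  seq <- toupper(seq)
  bad <- setdiff(kinases, names(.kinase_patterns))
  if (length(bad)) stop("unknown kinase id(s): ", paste(bad, collapse = ", "))
  span <- c(PKC = 3L, PKA = 4L, CK2 = 4L)
  out <- lapply(kinases, function(k) {
    # lookahead finds overlapping matches
    m <- gregexpr(paste0("(?=", .kinase_patterns[[k]], ")"), seq,
                  perl = TRUE)[[1]]
    if (m[1] == -1) return(.empty_regions())
    starts <- as.integer(m) - 1L
    .region_df(paste0("phospho_", k), starts, starts + span[[k]], "scanned")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Map reference-sequence positions to alignment columns
#'
#' Converts positions given in the coordinates of one (ungapped) reference
#' sequence — e.g. experimentally determined cleavage sites of the protamine
#' 2 precursor — to columns of the alignment, accounting for gaps in the
#' reference row.
#'
#' @param alignment a [codon_alignment()].
#' @param site_list integer vector of 0-based reference residue positions.
#' @param type region type label (e.g. `"cleavage"`).
#' @param reference taxon name of the reference row.
#' @return BED-like `data.frame`, one single-column region per site, with
#'   `source = "configured"`.
#' @export
map_configured_sites <- function(alignment, site_list, type, reference) {
  if (!reference %in% alignment$taxa) {
    stop("reference taxon not in alignment: ", reference)
  }
  row <- alignment$codons[match(reference, alignment$taxa), ]
  ungapped_cols <- which(row != "---" & !grepl("-", row))
  if (any(site_list >= length(ungapped_cols)) || any(site_list < 0)) {
    stop("position beyond reference length (", length(ungapped_cols),
         " residues)")
  }
  cols <- ungapped_cols[site_list + 1L] - 1L # to 0-based columns
  .region_df(type, cols, cols + 1L, "configured")
}

#' Profile selective classes within functional regions
#'
#' Intersects per-site selective-class assignments with a domain annotation:
#' for each region type, the percentage of covered sites in classes 1/2/3,
#' and the positively selected sites falling inside regions of that type.
#' Empty region types are omitted with a note.
#'
#' @param posterior a `site_posterior` from [beb_classify()].
#' @param annotation BED-like region `data.frame` (rows from the scanners
#'   and/or [map_configured_sites()]).
#' @return List: `table` (`type`, `n_sites`, `class1`, `class2`, `class3`
#'   percentages), `ps_by_type` (positively selected site numbers per type),
#'   `notes`.
#' @export
profile_regions <- function(posterior, annotation) {
  stopifnot(inherits(posterior, "site_posterior"))
  tab <- posterior$sites
  types <- unique(annotation$type)
  rows <- list(); ps <- list(); notes <- character(0)
  flagged <- if (posterior$class3_allowed) {
    tab$site[!is.na(tab$pp_class3) & tab$pp_class3 > 0.95]
  } else integer(0)
  for (ty in types) {
    rr <- annotation[annotation$type == ty, , drop = FALSE]
    cols <- unique(unlist(Map(function(s, e) seq.int(s + 1L, e),
                              rr$start, rr$end)))
    idx <- which(tab$site %in% cols)
    if (!length(idx)) {
      notes <- c(notes, paste0("type '", ty,
                               "' covers no analysed sites; omitted"))
      next
    }
    cl <- factor(tab$class[idx], levels = 1:3)
    p <- as.numeric(100 * table(cl) / length(idx))
    rows[[ty]] <- data.frame(type = ty, n_sites = length(idx),
                             class1 = p[1], class2 = p[2], class3 = p[3])
    ps[[ty]] <- intersect(flagged, cols)
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out)) rownames(out) <- NULL
  list(table = out, ps_by_type = ps, notes = notes)
}
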