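test_that("anchoring scanner finds R/K runs with cysteine flanks", {
  r <- scan_anchoring("CYRRRRSC", flank_window = 3)
  expect_equal(nrow(r), 1)
  expect_lte(r$start, 2); expect_gte(r$end, 6) # covers the RRRR run
  expect_equal(r$type, "anchoring")
  expect_equal(nrow(scan_anchoring("ARRRA")), 0) # no cysteine anywhere
  expect_equal(nrow(scan_anchoring("CARKAC")), 0) # run too short
  # scanning twice yields identical regions (idempotence)
  expect_identical(scan_anchoring("CYRRRRSCAAKKKC", 4),
                   scan_anchoring("CYRRRRSCAAKKKC", 4))
})

test_that("phospho scanner matches kinase consensus patterns, overlaps included", {
  r <- scan_phospho("ASRK", "PKC")
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 1) # S at position 1 (0-based)
  expect_equal(r$end, 4)
  r2 <- scan_phospho("RRAS", "PKA")
  expect_equal(r2$start, 0); expect_equal(r2$end, 4)
  expect_equal(nrow(scan_phospho("AAAA")), 0)
  expect_error(scan_phospho("ASRK", "PKQ"), "unknown kinase")
  # overlapping PKC matches are all reported
  r3 <- scan_phospho("SSRKR", "PKC") # S-S-R (no), S at 0: S S R? pattern [ST].[RK]
  expect_gte(nrow(r3), 2)
})

test_that("scanners agree with a brute-force pattern oracle on random peptides", {
  set.seed(71)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  brute_phospho <- function(aa, pat_fun, span) {
    hits <- integer(0)
    for (i in seq_len(max(0, length(aa) - span + 1))) {
      if (pat_fun(aa[i:(i + span - 1)])) hits <- c(hits, i - 1L)
    }
    hits
  }
  pkc <- function(w) w[1] %in% c("S", "T") && w[3] %in% c("R", "K")
  pka <- function(w) all(w[1:2] %in% c("R", "K")) && w[4] %in% c("S", "T")
  ck2 <- function(w) w[1] %in% c("S", "T") && w[4] %in% c("D", "E")
  brute_anchor <- function(aa, win) {
    n <- length(aa)
    runs <- list(); i <- 1
    while (i <= n) {
      if (aa[i] %in% c("R", "K")) {
        j <- i
        while (j < n && aa[j + 1] %in% c("R", "K")) j <- j + 1
        if (j - i + 1 >= 3) runs[[length(runs) + 1]] <- c(i, j)
        i <- j + 1
      } else i <- i + 1
    }
    if (!length(runs)) return(0L)
    keep <- vapply(runs, function(rg) {
      lw <- if (rg[1] > 1) seq.int(max(1, rg[1] - win), rg[1] - 1)
            else integer(0)
      rw <- if (rg[2] < n) seq.int(rg[2] + 1, min(n, rg[2] + win))
            else integer(0)
      any(aa[lw] == "C") || any(aa[rw] == "C")
    }, logical(1))
    sum(keep)
  }
  for (rep in 1:200) {
    len <- sample(10:200, 1)
    aa <- sample(aas, len, replace = TRUE)
    pep <- paste0(aa, collapse = "")
    sc <- scan_phospho(pep)
    expect_equal(sort(sc$start[sc$type == "phospho_PKC"]),
                 sort(brute_phospho(aa, pkc, 3)))
    expect_equal(sort(sc$start[sc$type == "phospho_PKA"]),
                 sort(brute_phospho(aa, pka, 4)))
    expect_equal(sort(sc$start[sc$type == "phospho_CK2"]),
                 sort(brute_phospho(aa, ck2, 4)))
    # anchoring: every qualifying run is covered by a reported region
    an <- scan_anchoring(pep, 5)
    nq <- brute_anchor(aa, 5)
    if (nq == 0) expect_equal(nrow(an), 0) else expect_gte(nrow(an), 1)
  }
})

test_that("configured sites map through reference gaps to alignment columns", {
  aln <- codon_alignment(c(ref = "ATGAAACCCGGG", oth = "ATGAAACCCGGG"))
  r <- map_configured_sites(aln, c(0, 2), "cleavage", "ref")
  expect_equal(r$start, c(0L, 2L)) # ungapped reference: identity mapping
  # a 2-column gap before position 5 shifts the mapping by 2
  aln2 <- codon_alignment(c(
    ref = paste0("ATGATG", "------", strrep("AAA", 5)),
    oth = paste0("ATGATG", "CCCGGG", strrep("AAA", 5))))
  r2 <- map_configured_sites(aln2, 5, "cleavage", "ref")
  expect_equal(r2$start, 7L) # residue 5 of the reference sits in column 7
  expect_error(map_configured_sites(aln2, 10, "cleavage", "ref"), "beyond")
  expect_error(map_configured_sites(aln2, 0, "cleavage", "nope"),
               "reference taxon")
  # 14 configured cleavage positions produce 14 single-column regions
  aln3 <- codon_alignment(c(ref = strrep("AGA", 50), oth = strrep("AGG", 50)))
  r3 <- map_configured_sites(aln3, 0:13, "cleavage", "ref")
  expect_equal(nrow(r3), 14)
  expect_true(all(r3$source == "configured"))
})

test_that("regional profiles count classes exactly and sum to 100", {
  mk_post <- function(classes) {
    n <- length(classes)
    sites <- data.frame(site = seq_len(n),
                        p_class1 = as.numeric(classes == 1),
                        p_class2 = as.numeric(classes == 2),
                        p_class3 = as.numeric(classes == 3),
                        class = classes, mean_omega = 1, se_omega = 0,
                        pp_class3 = as.numeric(classes == 3))
    sites$pp95 <- sites$pp_class3 > 0.95
    sites$pp99 <- FALSE
    structure(list(sites = sites, model_id = "M2a", method = "beb",
                   class3_allowed = TRUE), class = "site_posterior")
  }
  post <- mk_post(c(1, 1, 2, 3, 2, 2, 1, 2, 2, 2))
  ann <- data.frame(type = c("anchoring", "phospho_PKC"),
                    start = c(0L, 6L), end = c(4L, 9L),
                    source = "scanned")
  prof <- profile_regions(post, ann)
  anch <- prof$table[prof$table$type == "anchoring", ]
  expect_equal(anch$class1, 50); expect_equal(anch$class2, 25)
  expect_equal(anch$class3, 25)
  expect_equal(sum(unlist(anch[, c("class1", "class2", "class3")])), 100)
  # the positively selected site 4 falls inside the anchoring region
  expect_equal(prof$ps_by_type$anchoring, 4)
  # all-class-2 posterior: every type reports 0/100/0
  post2 <- mk_post(rep(2, 10))
  prof2 <- profile_regions(post2, ann)
  expect_true(all(prof2$table$class2 == 100))
  expect_true(all(prof2$table$class1 == 0 & prof2$table$class3 == 0))
  # an anchoring split like 70/16.6/13.3 is reproduced from matching counts
  cls <- rep(c(1, 2, 3), times = c(21, 5, 4))
  prof3 <- profile_regions(mk_post(cls),
    data.frame(type = "anchoring", start = 0L, end = 30L, source = "scanned"))
  expect_equal(prof3$table$class1, 70)
  expect_equal(prof3$table$class2, 16.6, tolerance = 0.05)
  expect_equal(prof3$table$class3, 13.3, tolerance = 0.05)
  # empty region types are omitted with a note
  prof4 <- profile_regions(post,
    data.frame(type = "cleavage", start = 11L, end = 12L, source = "conf"))
  expect_null(prof4$table)
  expect_match(prof4$notes, "omitted")
})
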