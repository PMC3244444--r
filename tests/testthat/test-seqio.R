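test_that("FASTA parsing builds codon alignments and enforces the frame", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">t1", "ATGAAA", ">t2", "ATGAAG"), f)
  a <- read_fasta(f)
  expect_s3_class(a, "codon_alignment")
  expect_equal(a$taxa, c("t1", "t2"))
  expect_equal(dim(a$codons), c(2L, 2L))

  expect_error(codon_alignment(c(a = "ATGAA", b = "ATGAA")), "frame")
  expect_error(codon_alignment(c(a = "ATGAAA", b = "ATG")), "unequal")
  expect_error(codon_alignment(c(a = "ATGTAAAAA", b = "ATGAAAAAA")),
               "stop")
  expect_error(codon_alignment(c("ATGAAA", "ATGAAG")), "unique")
})

test_that("FASTA round trip is byte-preserving on a synthetic alignment", {
  sim <- simulate_codon_alignment(
    cricetidae_tree(),
    codon_model_spec(2, protamine_like_freqs(), 0.5), 153, seed = 101)
  f <- tempfile(fileext = ".fa")
  write_fasta(sim$alignment, f)
  back <- read_fasta(f)
  expect_identical(back$taxa, sim$alignment$taxa)
  expect_identical(back$codons, sim$alignment$codons)
})

test_that("consensus takes the column majority with IUPAC ties", {
  expect_equal(consensus_sequence(c("ATG", "ATG", "ATG", "ATG")), "ATG")
  expect_equal(consensus_sequence(c("ATG", "ATG", "ACG", "ATG")), "ATG")
  expect_equal(consensus_sequence(c("AT", "AC")), "AY")
  expect_error(consensus_sequence(character(0)), "at least 2")
  expect_error(consensus_sequence("ATG"), "at least 2")
  # consensus of k identical sequences equals that sequence, for several k
  for (k in 2:5) {
    expect_equal(consensus_sequence(rep("ACGTAC", k)), "ACGTAC")
  }
})

test_that("precursor split returns the two domains and concatenation is the identity", {
  set.seed(3)
  codons <- sense_codons()
  seqs <- vapply(1:4, function(i)
    paste0(sample(codons, 100, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0("t", 1:4)
  aln <- codon_alignment(seqs, "prm2")
  sp <- split_prm2(aln, domain_boundary(40, 100))
  expect_equal(n_codons(sp$cleaved), 40)
  expect_equal(n_codons(sp$mature), 60)
  expect_identical(cbind(sp$cleaved$codons, sp$mature$codons), aln$codons)

  # mouse-like precursor numbers: 105 codons, mature domain of 63
  aln105 <- codon_alignment(stats::setNames(vapply(1:2, function(i)
    paste0(sample(codons, 105, replace = TRUE), collapse = ""), ""),
    c("a", "b")))
  sp105 <- split_prm2(aln105, domain_boundary(105 - 63, 105))
  expect_equal(n_codons(sp105$mature), 63)

  # degenerate boundary at 0
  sp0 <- split_prm2(aln, domain_boundary(0, 100))
  expect_equal(n_codons(sp0$cleaved), 0)
  expect_identical(sp0$mature$codons, aln$codons)
  expect_error(domain_boundary(120, 100), "range")
})

test_that("pairwise identity counts matches over gap-free compared positions", {
  expect_equal(pairwise_identity("ARRK", "ARRK"), 100)
  expect_equal(pairwise_identity("ARRK", "ARRR"), 75)
  expect_equal(pairwise_identity("A-RK", "AQRK"), 100)
  expect_error(pairwise_identity("--", "AQ"), "undefined")
  # symmetry and range on random pairs
  set.seed(11)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:20) {
    a <- paste0(sample(c(aas, "-"), 30, replace = TRUE), collapse = "")
    b <- paste0(sample(c(aas, "-"), 30, replace = TRUE), collapse = "")
    if (!any(strsplit(a, "")[[1]] != "-" & strsplit(b, "")[[1]] != "-")) next
    ab <- pairwise_identity(a, b)
    expect_equal(ab, pairwise_identity(b, a))
    expect_gte(ab, 0); expect_lte(ab, 100)
  }
})

test_that("integrity check flags pseudogenized sequences", {
  intact <- "ATGGCTAGAAGAAGAAGATAG" # M A R R R R stop
  self_aa <- "MARRRR"
  expect_equal(integrity_check(intact, self_aa, 40)$status, "intact")

  with_stop <- paste0("ATG", strrep("AGA", 8), "TAA", strrep("AGA", 5), "TAG")
  chk <- integrity_check(with_stop)
  expect_equal(chk$status, "dysfunctional")
  expect_true("premature_stop" %in% chk$criteria)

  chk2 <- integrity_check("ATGAA")
  expect_true("length_not_multiple_of_3" %in% chk2$criteria)

  # null homology against an orthologue panel
  set.seed(5)
  junk <- paste0(sample(c("GGG", "GGC"), 40, replace = TRUE), collapse = "")
  refs <- c("MARYRCCRRRRRRCCRRRRRCYTVIRCTRCR", "MARYRCCRRRRRCCRRRRRCYTRRRSRCRYR")
  chk3 <- integrity_check(junk, refs, 40)
  expect_equal(chk3$status, "dysfunctional")
  expect_true("identity_below_floor" %in% chk3$criteria)

  expect_error(integrity_check("ATG", NULL, 40), "config")
})

test_that("gap/ambiguity columns can be removed before model fitting", {
  aln <- codon_alignment(c(a = "ATGAAANNNCCC", b = "ATG---AAACCC"))
  cd <- drop_incomplete_columns(aln)
  expect_equal(cd$kept, c(1L, 4L))
  expect_equal(n_codons(cd$alignment), 2)
})
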