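test_that("apply_outcome edits sequences and does mass bookkeeping", {
  a <- wildtype_allele("ACGTACGT")

  del <- apply_outcome(a, "gA", indel_outcome("deletion", 3, 2, freq = 0.5))
  expect_equal(del$seq, "ACGCGT")
  expect_equal(nchar(del$seq), nchar(a$seq) - 2L)
  expect_equal(del$level, 1L)

  ins <- apply_outcome(a, "gA", indel_outcome("insertion", 4, 1, "T",
                                              freq = 1))
  expect_equal(ins$seq, "ACGTTACGT")
  expect_equal(nchar(ins$seq), nchar(a$seq) + 1L)

  parent <- allele("ACGTACGTAC", mass = 0.8)
  child <- apply_outcome(parent, "g", indel_outcome("deletion", 2, 1,
                                                    freq = 0.5))
  expect_equal(child$mass, 0.4)

  expect_error(apply_outcome(a, "g", indel_outcome("deletion", 7, 5)),
               "coordinate")
})

test_that("child length changes by the indel length for random outcomes", {
  set.seed(101)
  for (i in 1:300) {
    L <- sample(30:80, 1)
    a <- wildtype_allele(rand_dna(L))
    if (runif(1) < 0.5) {
      d <- sample(1:10, 1)
      s <- sample(0:(L - d), 1)
      child <- apply_outcome(a, "g", indel_outcome("deletion", s, d))
      expect_equal(nchar(child$seq), L - d)
    } else {
      n <- sample(1:5, 1)
      s <- sample(0:L, 1)
      child <- apply_outcome(a, "g", indel_outcome("insertion", s, n,
                                                   rand_dna(n)))
      expect_equal(nchar(child$seq), L + n)
    }
  }
})

test_that("deletions canonicalize to the leftmost equivalent alignment", {
  seq <- "AACCAACCGG"
  o1 <- canonicalize_deletion(seq, indel_outcome("deletion", 4, 4))
  o2 <- canonicalize_deletion(seq, indel_outcome("deletion", 0, 4))
  expect_equal(o1$start, 0L)
  expect_equal(o2$start, 0L)
  # both alignments produce the identical child
  a <- wildtype_allele(seq)
  expect_equal(apply_outcome(a, "g", indel_outcome("deletion", 4, 4))$seq,
               apply_outcome(a, "g", indel_outcome("deletion", 0, 4))$seq)

  # no flanking homology: unchanged; idempotent in general
  set.seed(7)
  for (i in 1:50) {
    s <- rand_dna(50)
    o <- indel_outcome("deletion", sample(0:40, 1), sample(1:8, 1))
    c1 <- canonicalize_deletion(s, o)
    expect_identical(canonicalize_deletion(s, c1), c1)
  }
})

test_that("canonical deletions of one length have pairwise distinct children", {
  set.seed(13)
  for (i in 1:20) {
    seq <- rand_dna(50)
    d <- sample(2:6, 1)
    canon <- vapply(0:(50 - d), function(s)
      canonicalize_deletion(seq, indel_outcome("deletion", s, d))$start, 0L)
    child_of <- function(s) paste0(substr(seq, 1, s),
                                   substr(seq, s + d + 1, 50))
    reps <- unique(canon)
    expect_equal(anyDuplicated(vapply(reps, child_of, "")), 0L)
    # equal canonical start means equal child
    for (s in 0:(50 - d))
      expect_equal(child_of(s), child_of(canon[s + 1]))
  }
})

test_that("microhomology length matches direct flank comparison", {
  expect_equal(microhomology_length("TAGCTAGC",
                                    indel_outcome("deletion", 0, 4)), 4L)
  expect_equal(microhomology_length("ACGTTTTACGG",
                                    indel_outcome("deletion", 2, 3)), 0L)
  set.seed(17)
  for (i in 1:100) {
    seq <- rand_dna(40)
    s <- sample(0:30, 1); d <- sample(1:8, 1)
    if (s + d > 40) next
    m <- microhomology_length(seq, indel_outcome("deletion", s, d))
    expect_lte(m, 40 - (s + d))
    if (m > 0)
      expect_equal(substr(seq, s + 1, s + m),
                   substr(seq, s + d + 1, s + d + m))
    if (s + d + m < 40)
      expect_false(substr(seq, s + m + 1, s + m + 1) ==
                   substr(seq, s + d + m + 1, s + d + m + 1))
  }
})

test_that("allele merging sums mass over convergent lineages", {
  a <- wildtype_allele("ACGTACGTACGTACGTACGTACGTACGTAC")
  o <- indel_outcome("deletion", 10, 2, freq = 0.3)
  c1 <- apply_outcome(a, "g1", o)
  c2 <- apply_outcome(a, "g2", indel_outcome("deletion", 10, 2, freq = 0.2))
  c3 <- apply_outcome(a, "g1", indel_outcome("deletion", 5, 1, freq = 0.1))
  merged <- merge_alleles(list(c1, c2, c3))
  expect_length(merged, 2L)
  expect_equal(merged[[1]]$seq, c1$seq)
  expect_equal(merged[[1]]$mass, 0.5)
  expect_equal(merged[[2]]$mass, 0.1)
})

test_that("donor specifications derive the HDR allele from the edit", {
  wt <- "ACGTACGTACGTACGTACGT"
  d1 <- donor_spec(wt, indel_outcome("insertion", 10, 3, "GAT"))
  expect_equal(d1$hdr_allele, paste0(substr(wt, 1, 10), "GAT",
                                     substr(wt, 11, 20)))
  d2 <- donor_spec(wt, substitution(4, "A", "C"))
  expect_equal(substr(d2$hdr_allele, 5, 5), "C")
  expect_equal(nchar(d2$hdr_allele), nchar(wt))
  expect_error(donor_spec(wt, substitution(4, "G", "C")), "ref")
  expect_equal(d1$homology_arm_length, 45L)
})

test_that("degenerate bases are rejected for design sequences", {
  expect_error(wildtype_allele("ACGTN"), "A,C,G,T")
  expect_error(sequence_window("c", 0, "acgt"), "uppercase")
})
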