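test_that("outcome frequencies and truncated mass always sum to one", {
  set.seed(23)
  for (i in 1:60) {
    w <- rand_dna(sample(40:140, 1))
    cut <- sample(5:(nchar(w) - 5), 1)
    d <- predict_outcomes(w, cut)
    expect_equal(sum(d$freqs) + d$truncated_mass, 1, tolerance = 1e-9)
    expect_false(is.unsorted(rev(d$freqs)))
    # parent mass splits exactly over children + truncated mass
    a <- allele(w, mass = 0.8)
    kids <- vapply(d$outcomes,
                   function(o) apply_outcome(a, "g", o)$mass, 0)
    expect_equal(sum(kids) + 0.8 * d$truncated_mass, 0.8, tolerance = 1e-9)
  }
})

test_that("an engineered 3-bp microhomology deletion dominates the +1 ins", {
  w <- mh_worked_window()
  d <- predict_outcomes(w, 50)
  top <- d$outcomes[[1]]
  expect_equal(top$kind, "deletion")
  expect_equal(top$start, 47L)
  expect_equal(top$length, 6L)
  expect_equal(microhomology_length(w, top), 3L)
  # its raw score is (1+3)^2 * exp(-0.6) = 8.78 > beta_ins1 = 3.0
  oracle <- oracle_del_scores(w, 50)
  expect_equal(max(oracle$w), 16 * exp(-0.6), tolerance = 1e-12)
  Z <- sum(oracle$w) + 3.0 + 0.3
  expect_equal(d$freqs[1], 16 * exp(-0.6) / Z, tolerance = 1e-9)
})

test_that("in repeat-free context the +1 duplication is the top outcome", {
  w <- plus1_window()
  d <- predict_outcomes(w, 50)
  top <- d$outcomes[[1]]
  expect_equal(top$kind, "insertion")
  expect_equal(top$length, 1L)
  expect_equal(top$inserted_seq, substr(w, 50, 50))  # duplicates base 5' of cut
  oracle <- oracle_del_scores(w, 50)
  expect_lt(max(oracle$w), 3.0)
  expect_equal(d$freqs[1], 3.0 / (sum(oracle$w) + 3.3), tolerance = 1e-9)
})

test_that("deletion enumeration agrees with the exhaustive oracle", {
  set.seed(29)
  for (i in 1:10) {
    w <- rand_dna(90)
    cut <- sample(20:70, 1)
    oracle <- oracle_del_scores(w, cut)
    p <- predictor_params(min_report_freq = 0)     # keep everything
    d <- predict_outcomes(w, cut, p)
    dels <- Filter(function(o) o$kind == "deletion", d$outcomes)
    expect_equal(length(dels), nrow(oracle))
    got <- sort(paste(vapply(dels, `[[`, 0L, "start"),
                      vapply(dels, `[[`, 0L, "length")))
    want <- sort(paste(oracle$start, oracle$length))
    expect_identical(got, want)
    Z <- sum(oracle$w) + 3.3
    for (o in dels) {
      ow <- oracle$w[oracle$start == o$start & oracle$length == o$length]
      expect_equal(o$freq, ow / Z, tolerance = 1e-9)
    }
  }
})

test_that("prediction is shift-equivariant under added flanks", {
  # flanks engineered to contribute no microhomology partner in range:
  # extend with bases that never equal the window edge alphabetically
  w <- mh_worked_window()
  d0 <- predict_outcomes(w, 50, predictor_params(d_max = 10))
  set.seed(31)
  for (i in 1:10) {
    wide <- paste0(rand_dna(10), w, rand_dna(10))
    d1 <- predict_outcomes(wide, 60, predictor_params(d_max = 10))
    k0 <- paste(vapply(d0$outcomes, `[[`, "", "kind"),
                vapply(d0$outcomes, `[[`, 0L, "start"),
                vapply(d0$outcomes, `[[`, 0L, "length"))
    k1 <- paste(vapply(d1$outcomes, `[[`, "", "kind"),
                vapply(d1$outcomes, `[[`, 0L, "start") - 10L,
                vapply(d1$outcomes, `[[`, 0L, "length"))
    # d_max = 10 keeps all spans >= 40 bp from the window edge, so no new
    # partner can enter range and the top of the distribution must agree
    n <- min(length(d0$outcomes), length(d1$outcomes), 10L)
    expect_identical(k1[1:n], k0[1:n])
    expect_equal(d1$freqs[1:n], d0$freqs[1:n], tolerance = 1e-6)
  }
})

test_that("deletion enumeration is reverse-complement symmetric", {
  set.seed(37)
  for (i in 1:10) {
    w <- rand_dna(80)
    cut <- sample(20:60, 1)
    p <- predictor_params(min_report_freq = 0)
    d <- predict_outcomes(w, cut, p)
    dr <- predict_outcomes(revcomp(w), 80 - cut, p)
    dels <- Filter(function(o) o$kind == "deletion", d$outcomes)
    delsr <- Filter(function(o) o$kind == "deletion", dr$outcomes)
    expect_equal(length(dels), length(delsr))
    # mirrored deletion spans carry equal frequencies; compare multisets of
    # (length, freq) since canonical starts mirror to rightmost alignments
    key <- function(os) sort(paste(vapply(os, `[[`, 0L, "length"),
                                   signif(vapply(os, `[[`, 0, "freq"), 9)))
    expect_identical(key(dels), key(delsr))
  }
})

test_that("outcomes below the reporting cutoff pool into truncated mass", {
  w <- plus1_window()
  d_all <- predict_outcomes(w, 50, predictor_params(min_report_freq = 0))
  d <- predict_outcomes(w, 50)
  expect_lt(length(d$outcomes), length(d_all$outcomes))
  expect_equal(d$truncated_mass,
               sum(d_all$freqs[d_all$freqs < 0.01]), tolerance = 1e-9)
  expect_true(all(d$freqs >= 0.01))
})

test_that("ranking and concentration follow the stated tie rules", {
  fake <- structure(list(
    cut_index = 50L,
    outcomes = list(indel_outcome("deletion", 1, 2, freq = 0.5),
                    indel_outcome("deletion", 4, 1, freq = 0.3),
                    indel_outcome("insertion", 5, 1, "A", freq = 0.2)),
    freqs = c(0.5, 0.3, 0.2), truncated_mass = 0),
    class = "outcome_distribution")
  expect_equal(concentration(fake, 2), 0.8)
  expect_equal(concentration(fake, 10), 1 - fake$truncated_mass)
  expect_length(rank_outcomes(fake, 2), 2L)
  expect_length(rank_outcomes(fake, 10), 3L)
  # monotone nondecreasing in n
  cs <- vapply(1:3, function(n) concentration(fake, n), 0)
  expect_false(is.unsorted(cs))
  # exact tie: shorter indel sorts first
  w <- chain_window()
  d <- predict_outcomes(w, chain_cut(), predictor_params(min_report_freq = 0))
  lens <- vapply(d$outcomes, `[[`, 0L, "length")
  fr <- d$freqs
  for (i in seq_len(length(fr) - 1L))
    if (fr[i] == fr[i + 1]) expect_lte(lens[i], lens[i + 1])
})

test_that("cut sites too close to the window edge are rejected", {
  expect_error(predict_outcomes(rand_dna(40), 2), "window error")
  expect_error(predict_outcomes(rand_dna(40), 38), "window error")
})

test_that("the adapter seam validates external predictors", {
  bad <- function(allele_seq, cut_index, params) {
    structure(list(cut_index = cut_index,
                   outcomes = list(indel_outcome("deletion", 1, 1,
                                                 freq = 0.4)),
                   freqs = 0.4, truncated_mass = 0.1),
              class = "outcome_distribution")
  }
  register_predictor("broken", bad)
  expect_error(get_predictor("broken")(rand_dna(40), 20,
                                       predictor_params()),
               "contract")
  expect_error(get_predictor("nonexistent"), "unknown predictor")
  ok <- get_predictor("bundled")
  expect_s3_class(ok(rand_dna(40), 20, predictor_params()),
                  "outcome_distribution")
})
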