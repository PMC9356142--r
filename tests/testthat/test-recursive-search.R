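test_that("retarget score is the product of targeted mass and look-ahead", {
  w <- chain_window()
  # two frontier alleles matched by the same guide (distant base changed
  # outside every protospacer), plus one unmatched allele
  w2 <- w
  substr(w2, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(w2, 3, 3))[1]
  other <- chain_window("ACG")   # same flanks, different repeat unit
  g <- Filter(function(x) x$cut_index == chain_cut(),
              enumerate_guides(w))[[1]]
  frontier <- list(allele(w, mass = 0.6), allele(w2, mass = 0.1),
                   allele(other, mass = 0.3))
  sc <- retarget_score(g, frontier)
  expect_equal(attr(sc, "M"), 0.7)
  expect_equal(as.numeric(sc), 0.7 * attr(sc, "R"), tolerance = 1e-12)
  expect_lte(as.numeric(sc), attr(sc, "M"))
  expect_gt(attr(sc, "R"), 0)

  # a guide matching nothing scores zero; empty frontier is a domain error
  miss <- Filter(function(x) x$cut_index == chain_cut(),
                 enumerate_guides(other))[[1]]   # repeat-spanning, ACG unit
  expect_equal(as.numeric(retarget_score(miss, list(allele(w, mass = 1)))), 0)
  expect_error(retarget_score(g, list()), "domain error")
})

test_that("the tandem-repeat chain yields a three-level A1/B1/C1 cascade", {
  w <- chain_window()
  casc <- run_recursion(w, donor = chain_donor(w))
  expect_equal(n_levels(casc), 3L)
  labels <- lapply(casc$levels, function(lv) vapply(lv, `[[`, "", "label"))
  expect_equal(labels[[1]], "A1")
  expect_equal(labels[[2]][1], "B1")
  expect_equal(labels[[3]][1], "C1")
  # within a level, numbers follow targeted mass, descending
  for (lv in casc$levels) {
    tm <- vapply(lv, `[[`, 0, "targeted_mass")
    expect_false(is.unsorted(rev(tm)))
  }
  # successive 3-bp microhomology deletions dominate each level
  d <- predict_outcomes(w, chain_cut())
  expect_equal(d$outcomes[[1]]$label, "-3 bp del")
  expect_gte(concentration(d, 2), 0.5)
})

test_that("selected retargeting guides match frontier but never WT or donor", {
  w <- chain_window()
  donor <- chain_donor(w)
  casc <- run_recursion(w, donor = donor)
  wt <- wildtype_allele(w)
  for (lev in seq_along(casc$levels)) {
    if (lev == 1L) next
    frontier <- casc$frontiers[[lev]]
    for (e in casc$levels[[lev]]) {
      expect_false(matches_allele(e$guide, wt))
      expect_false(matches_allele(e$guide, donor))
      hits <- vapply(frontier, function(a) matches_allele(e$guide, a), TRUE)
      expect_gte(sum(hits), 1L)
      expect_equal(e$targeted_mass,
                   sum(vapply(frontier, `[[`, 0, "mass")[hits]),
                   tolerance = 1e-12)
    }
  }
})

test_that("a +1-duplication site recurses onto the duplicated base", {
  # the insertion class carries ~3% outcome mass under default parameters,
  # below the default targeted-mass cutoff, so a relaxed threshold is used
  # to exercise the retargeting mechanics on insertion-led sites
  w <- plus1_window()
  donor <- donor_spec(w, indel_outcome("insertion", 50, 3,
                                       inserted_seq = "GAT"))
  casc <- run_recursion(w, donor = donor,
                        cfg = search_config(max_levels = 2,
                                            min_targeted_mass = 0.02))
  expect_equal(n_levels(casc), 2L)
  b1 <- casc$levels[[2]][[1]]
  d <- predict_outcomes(w, casc$levels[[1]][[1]]$guide$cut_index)
  plus1 <- apply_outcome(wildtype_allele(w), "A1", d$outcomes[[1]])
  expect_true(matches_allele(b1$guide, plus1))
  expect_false(matches_allele(b1$guide, wildtype_allele(w)))
  # B1's protospacer spans the duplicated base
  site <- find_guide_sites(b1$guide, plus1$seq)
  spans <- any(site$position <= 50 & site$position + 23 > 50)
  expect_true(spans)
})

test_that("stopping criteria and degenerate inputs end the search cleanly", {
  w <- chain_window()
  one <- run_recursion(w, donor = chain_donor(w),
                       cfg = search_config(max_levels = 1))
  expect_equal(n_levels(one), 1L)
  expect_equal(one$levels[[1]][[1]]$label, "A1")

  # no qualifying entry guide: empty cascade with a reason
  no_pam <- run_recursion(paste(rep("AT", 20), collapse = ""))
  expect_equal(n_levels(no_pam), 0L)
  expect_match(no_pam$reason, "no qualifying entry guide")
})

test_that("retargeting efficiency is the covered share of the cut mass", {
  w <- chain_window()
  casc <- run_recursion(w, donor = chain_donor(w))
  eff0 <- retargeting_efficiency(casc, 0)
  tsets <- lapply(casc$levels[[2]], `[[`, "targeted_alleles")
  expect_equal(anyDuplicated(unlist(tsets)), 0L)  # disjoint target sets
  covered <- sum(vapply(casc$levels[[2]], `[[`, 0, "targeted_mass"))
  expect_equal(eff0, covered, tolerance = 1e-9)
  expect_gte(eff0, 0); expect_lte(eff0, 1)
  expect_equal(retargeting_efficiency(casc, n_levels(casc) - 1L), 0)
})

test_that("site classification applies a strict 20% efficiency boundary", {
  fake_report <- function(eff) {
    structure(list(cascade = list(config = list(cfg = search_config())),
                   retargeting_efficiency_per_level = eff,
                   is_recursive = NA, overall_rank_score = 0),
              class = "site_report")
  }
  expect_false(classify_site(fake_report(0.20)))
  expect_true(classify_site(fake_report(0.21)))
  expect_false(classify_site(fake_report(0)))
  expect_true(classify_site(fake_report(1)))

  w <- chain_window()
  rep <- site_report(run_recursion(w, donor = chain_donor(w)))
  expect_true(rep$is_recursive)
  expect_gt(rep$retargeting_efficiency_per_level[1], 0.2)
})

test_that("two runs on identical inputs serialize byte-identically", {
  w <- chain_window()
  c1 <- run_recursion(w, donor = chain_donor(w))
  c2 <- run_recursion(w, donor = chain_donor(w))
  expect_identical(cascade_json(c1), cascade_json(c2))
  df <- as.data.frame(c1)
  expect_equal(nrow(df), sum(lengths(c1$levels)))
  expect_named(df, c("site", "level", "label", "protospacer", "pam",
                     "strand", "cut", "on_target", "offtarget_hits",
                     "targeted_mass", "retarget_score", "efficiency"))
})
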