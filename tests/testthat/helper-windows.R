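# Engineered design windows shared across tests, plus a lazily generated,
# cached synthetic fixture set (one generation per test run).

# 101-bp window, cut 50: engineered so the only deletion outweighing the
# +1 duplication is the planted 3-bp microhomology pair (ACG at [47,50) and
# [53,56)), giving the -6 bp deletion (start 47) score (1+3)^2*e^-0.6.
mh_worked_window <- function() {
  paste0("AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTACG",
         "TGAACGGAGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCC")
}

# 101-bp window, cut 50: engineered repeat-free context in which no
# deletion reaches the +1 duplication weight, so the +1 duplication is the
# rank-1 predicted outcome.
plus1_window <- function() {
  paste0("AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCA",
         "TGAAACGAGAACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCC")
}

# deterministic tandem-repeat chain window: 18-bp period-3 repeat at
# [50, 68), PAM TGG at [68, 71), entry cut 65; supports an A1/B1/B2/C1
# three-level cascade under default configuration
chain_window <- function(unit = "AGC") {
  withr::with_seed(11, {
    flL <- rand_dna(50)
    flR <- rand_dna(47)
  })
  paste0(flL, strrep(unit, 6L), "TGG", flR)
}

chain_cut <- function() 65L

chain_donor <- function(window = chain_window()) {
  donor_spec(window, indel_outcome("insertion", chain_cut(), 3L,
                                   inserted_seq = "GAT"))
}

# ---- cached fixture set ----------------------------------------------------

.fx_cache <- new.env(parent = emptyenv())

cached_fixtures <- function() {
  if (is.null(.fx_cache$fx)) {
    dir <- file.path(tempdir(), "editcascade-fixtures")
    .fx_cache$fx <- generate_fixtures(fixture_spec(seed = 20260921L),
                                      out_dir = dir)
  }
  .fx_cache$fx
}
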