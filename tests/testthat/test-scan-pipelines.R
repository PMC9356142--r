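# Scans run on the cached synthetic mini-genome (generated once per test
# run; every planted construct was verified at generation time).

test_that("the genome scan recovers exactly the planted Recursive sites", {
  fx <- cached_fixtures()
  rec <- scan_genome(scan_job("genome", genome = fx$fasta))
  truth <- fx$truth
  planted <- truth[truth$expected_recursive, ]
  expect_equal(nrow(rec), nrow(planted))
  # each record's entry cut coincides with a planted cut
  key_rec <- paste(rec$contig, rec$a_cut)
  key_truth <- paste(planted$contig, planted$a_cut0)
  expect_setequal(key_rec, key_truth)
  expect_true(all(rec$is_recursive))
  expect_true(all(rec$n_levels == 3L))
  # sorted by rank score, descending
  expect_false(is.unsorted(rev(rec$overall_rank_score)))
})

test_that("scan records equal direct per-site recursion runs bit-for-bit", {
  fx <- cached_fixtures()
  rec <- scan_genome(scan_job("genome", genome = fx$fasta))
  cascades <- attr(rec, "cascades")
  expect_length(cascades, nrow(rec))
  r <- rec[1, ]
  casc <- cascades[[1]]
  window <- substr(fx$genome[[r$contig]], r$window_start + 1L, r$window_end)
  lcut <- r$a_cut - r$window_start
  a_proto <- sub("^A1=([A-Z]+)\\|.*$", "\\1", r$guides)
  a_guide <- Filter(function(g) g$cut_index == lcut &&
                      g$protospacer == a_proto,
                    enumerate_guides(window))[[1]]
  donor <- donor_spec(window, indel_outcome("insertion", lcut, 3,
                                            inserted_seq = "GAT"))
  direct <- run_recursion(sequence_window(r$contig, r$window_start, window),
                          donor = donor, a_guide = a_guide,
                          background = fx$genome)
  expect_identical(cascade_json(direct), cascade_json(casc))
})

test_that("scan output files are deterministic across repeated runs", {
  fx <- cached_fixtures()
  job <- scan_job("genome", genome = fx$fasta)
  r1 <- scan_genome(job)
  r2 <- scan_genome(job)
  d1 <- file.path(tempdir(), "scanout1"); d2 <- file.path(tempdir(), "scanout2")
  write_records(r1, d1)
  write_records(r2, d2)
  for (ext in c(".tsv", ".json"))
    expect_identical(readLines(paste0(d1, ext)), readLines(paste0(d2, ext)))
})

test_that("codon scan deduplicates isoforms and tags every planted gene", {
  fx <- cached_fixtures()
  gr <- read_gff3(fx$gff3)
  stops <- gr[gr$type == "stop_codon"]
  # the annotation carries a duplicated stop codon from an isoform pair
  key <- paste(GenomicRanges::seqnames(stops), GenomicRanges::start(stops))
  expect_gt(length(stops), length(unique(key)))

  rec <- scan_cds_ends(scan_job("cds_ends", genome = fx$fasta,
                                annotation = fx$gff3))
  expect_equal(nrow(rec), fx$spec$gene_count)  # one record per unique codon
  expect_setequal(rec$gene, unique(stops$gene_id))
  expect_true(all(rec$feature_type == "stop_codon"))
  expect_true(all(rec$is_recursive))
})

test_that("variant scan applies the 50-bp filter and finds planted SNVs", {
  fx <- cached_fixtures()
  rec <- scan_variants(scan_job("variants", genome = fx$fasta,
                                variants = fx$vcf))
  vdf <- read_vcf_df(fx$vcf)
  independent <- sum(abs(nchar(vdf$REF) - nchar(vdf$ALT)) <= 50)
  expect_equal(attr(rec, "n_retained"), independent)
  expect_lt(independent, nrow(vdf))       # the long deletion is excluded

  planted <- fx$truth[!is.na(fx$truth$variant_id), ]
  expect_equal(sort(rec$variant_id), sort(planted$variant_id))
  # each record's HDR allele differs from wildtype at exactly one position
  cascades <- attr(rec, "cascades")
  for (casc in cascades) {
    wt <- casc$site$seq; hdr <- casc$donor$hdr_allele
    expect_equal(nchar(wt), nchar(hdr))
    expect_equal(sum(strsplit(wt, "")[[1]] != strsplit(hdr, "")[[1]]), 1L)
  }
})

test_that("malformed variant records are skipped with a logged id", {
  fx <- cached_fixtures()
  vdf <- data.frame(
    CHROM = names(fx$genome)[1],
    POS = c(600L, 700L),
    ID = c("bad_same", "bad_alpha"),
    REF = c("A", "A"),
    ALT = c("A", "X"), stringsAsFactors = FALSE)
  vdf$REF[1] <- substr(fx$genome[[1]], 600, 600)
  vdf$ALT[1] <- vdf$REF[1]                      # REF == ALT: malformed
  rec <- scan_variants(scan_job("variants", genome = fx$fasta,
                                variants = vdf))
  expect_equal(nrow(rec), 0L)
  expect_setequal(attr(rec, "skipped"), c("bad_same", "bad_alpha"))
  expect_equal(attr(rec, "n_retained"), 0L)
})

test_that("an empty genome or missing features yield empty results", {
  expect_equal(nrow(scan_genome(scan_job("genome",
                                         genome = c(ctg = strrep("AT", 40))))),
               0L)
  fx <- cached_fixtures()
  gr <- read_gff3(fx$gff3)
  expect_warning(
    rec <- scan_cds_ends(scan_job("cds_ends", genome = fx$fasta,
                                  annotation = gr[gr$type == "gene"])),
    "no start_codon")
  expect_equal(nrow(rec), 0L)
})
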