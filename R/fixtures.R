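# Seeded synthetic fixture generator: a mini-genome with planted constructs
# of known cascade structure, a matching GFF3 of genes with start/stop
# codons, a VCF of SNVs and short indels, HDR donor specifications, and a
# machine-readable truth table.
#
# Construct types
#   mh_deletion_chain : an 18-bp period-3 tandem repeat (six copies of a
#     3-mer unit) with an NGG PAM placed immediately 3' of the repeat, so
#     the entry cut falls inside the repeat. Successive 3-bp
#     microhomology-mediated deletions dominate each round, supporting a
#     three-level A1/B1/C1 cascade with high retargeting efficiency.
#   plus1_dup : a planted PAM in engineered repeat-free context, so the
#     rank-1 predicted outcome is the +1 duplication of the cut-adjacent
#     base. Under the bundled model the insertion class carries only a few
#     percent of the outcome mass, so these sites do not reach the default
#     targeted-mass threshold and classify non-Recursive; the retargeting
#     mechanics (a B guide spanning the duplicated base) are still verified
#     at a relaxed threshold.
#   non_recursive : a planted PAM in repeat-free context with a dispersed
#     outcome spectrum; classifies non-Recursive by construction.
#
# Background sequence is rejection-sampled to be free of unintended 23-mer
# duplicates (including reverse complements), and each plant is verified by
# actually running the recursion before it is accepted.

#' Specify a synthetic fixture set
#'
#' @param seed Integer seed; generation is byte-for-byte reproducible.
#' @param n_contigs Number of contigs. Default 4.
#' @param contig_length Length of each contig, bp. Default 5000.
#' @param planted_constructs List of `list(type=, count=)` with types
#'   `"plus1_dup"`, `"mh_deletion_chain"`, `"non_recursive"`.
#' @param gene_count Genes (each with start/stop codons; stop codons are
#'   placed adjacent to a planted repeat so the gene is taggable). Default 4.
#' @param variant_count VCF records: two qualifying SNVs planted next to
#'   repeat constructs, one >50-bp deletion (excluded by the variant scan's
#'   length filter), the rest plain background SNVs. Default 6.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 4L, contig_length = 5000L,
                         planted_constructs = list(
                           list(type = "plus1_dup", count = 1L),
                           list(type = "mh_deletion_chain", count = 2L),
                           list(type = "non_recursive", count = 1L)),
                         gene_count = 4L, variant_count = 6L) {
  stopifnot(n_contigs >= 1L, contig_length >= 1000L, gene_count >= 0L,
            variant_count >= 0L)
  types <- vapply(planted_constructs, `[[`, "", "type")
  if (!all(types %in% c("plus1_dup", "mh_deletion_chain", "non_recursive")))
    stop("unknown construct type", call. = FALSE)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 planted_constructs = planted_constructs,
                 gene_count = as.integer(gene_count),
                 variant_count = as.integer(variant_count)),
            class = "fixture_spec")
}

# 3-mer repeat units whose tandem repetition creates no PAM (GG/CC) and no
# homopolymer; deterministic order
.unit_pool <- function() {
  b <- c("A", "C", "G", "T")
  units <- apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1, paste,
                 collapse = "")
  ok <- vapply(units, function(u) {
    uu <- strrep(u, 2L)
    !grepl("GG|CC", uu) && length(unique(strsplit(u, "")[[1]])) >= 2L &&
      !grepl("AAAA|TTTT", strrep(u, 3L)) &&
      !startsWith(u, "T")   # keep the PAM "T" from extending the repeat period
  }, TRUE)
  units[ok]
}

# all 23-mers of the genome (both strands); used to enforce uniqueness
.kmers23 <- function(genome) {
  out <- character(0)
  for (seq in genome) {
    L <- nchar(seq)
    if (L < 23L) next
    fw <- substring(seq, 1:(L - 22L), 23:L)
    out <- c(out, fw, revcomp(fw))
  }
  out
}

.dedupe_background <- function(genome, protect = NULL, max_iter = 40L) {
  for (iter in seq_len(max_iter)) {
    km <- .kmers23(genome)
    dup <- unique(km[duplicated(km)])
    if (length(dup) == 0L) return(genome)
    for (contig in names(genome)) {
      seq <- genome[[contig]]
      for (k in dup) {
        hits <- find_all0(k, seq)
        for (h in hits) {
          p <- h + sample.int(23L, 1L) - 1L
          if (!is.null(protect) && any(p >= protect$lo[protect$contig == contig] &
                                       p < protect$hi[protect$contig == contig]))
            next
          base <- substr(seq, p + 1L, p + 1L)
          substr(seq, p + 1L, p + 1L) <- sample(setdiff(c("A","C","G","T"),
                                                        base), 1L)
        }
      }
      genome[[contig]] <- seq
    }
  }
  stop("generation error: could not make background 23-mer unique",
       call. = FALSE)
}

# Engineer repeat-free context around a cut: iteratively break the
# strongest microhomology pair until the +1 duplication is the rank-1
# outcome. Mutations stay within +/-35 bp of the cut and never touch the
# planted PAM. Returns the modified contig sequence, or NULL.
.engineer_plus1 <- function(seq, a_cut, pam0, params) {
  wstart <- a_cut - 50L
  tries <- new.env(parent = emptyenv())       # per-MH-pair retry counter
  for (iter in seq_len(400L)) {
    window <- subseq0(seq, wstart, a_cut + 50L)
    dist <- predict_outcomes(window, 50L, params)
    o1 <- dist$outcomes[[1]]
    if (o1$kind == "insertion" && o1$length == 1L) return(seq)
    if (o1$kind != "deletion") return(NULL)
    m <- microhomology_length(window, o1)
    s0 <- o1$start + wstart                  # genomic canonical start
    partner <- s0 + o1$length                # first base of the MH partner
    key <- paste(s0, o1$length)
    k <- tries[[key]] %||% 0L
    tries[[key]] <- k + 1L
    # walk along the MH tract (and rotate the replacement base) on repeat
    # visits so overlapping pairs cannot trap the loop in a 2-cycle
    t <- partner + (k %% max(1L, m))
    if (t >= pam0 && t < pam0 + 3L) t <- s0 + (k %% max(1L, m))
    if ((t >= pam0 && t < pam0 + 3L) ||
        abs(t - a_cut) > 40L) return(NULL)
    cur <- substr(seq, t + 1L, t + 1L)
    other <- substr(seq, s0 + (t - partner) + 1L, s0 + (t - partner) + 1L)
    choices <- setdiff(c("A", "C", "G", "T"), c(cur, other))
    repl <- choices[1L + ((k %/% max(1L, m)) %% length(choices))]
    substr(seq, t + 1L, t + 1L) <- repl
  }
  NULL
}

# splice `core` into contig sequence at 0-based position
.splice <- function(seq, pos, core) {
  paste0(subseq0(seq, 0L, pos), core, subseq0(seq, pos + nchar(core),
                                              nchar(seq)))
}

#' Generate the synthetic fixture set
#'
#' Writes a mini-genome FASTA, a GFF3 with gene/start_codon/stop_codon
#' features (including a duplicated stop-codon isoform pair to exercise
#' deduplication), a VCF of variants, HDR donor specifications (JSON), and
#' a truth table (TSV) recording the expected cascade structure of every
#' planted construct. Same seed, same bytes.
#'
#' @param spec A [fixture_spec].
#' @param out_dir Output directory (created if needed).
#' @param verify Verify each plant by running the recursion (default TRUE).
#' @return List with paths (`fasta`, `gff3`, `vcf`, `donors`, `truth_tsv`),
#'   the in-memory `genome`, the `truth` data frame, and the `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec(), out_dir = tempfile("fix"),
                              verify = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, {
    res <- .generate_fixtures_impl(spec, out_dir, verify)
  })
  res
}

.generate_fixtures_impl <- function(spec, out_dir, verify) {
  filters <- filter_config()
  cfg <- search_config()
  params <- predictor_params()
  pred <- get_predictor("bundled")

  genome <- stats::setNames(
    vapply(seq_len(spec$n_contigs), function(i) .random_dna(spec$contig_length),
           ""),
    sprintf("ctg%02d", seq_len(spec$n_contigs)))
  genome <- .dedupe_background(genome)

  # plant plan: construct list in deterministic order
  plants <- list()
  for (pc in spec$planted_constructs)
    for (k in seq_len(pc$count))
      plants[[length(plants) + 1L]] <- list(type = pc$type, role = "construct")
  for (k in seq_len(spec$gene_count))
    plants[[length(plants) + 1L]] <- list(type = "mh_deletion_chain",
                                          role = "gene")
  n_qual_var <- min(2L, spec$variant_count)
  for (k in seq_len(n_qual_var))
    plants[[length(plants) + 1L]] <- list(type = "mh_deletion_chain",
                                          role = "variant")

  # slot allocation: evenly spaced, round-robin over contigs
  slots_per_contig <- ceiling(length(plants) / spec$n_contigs)
  if (slots_per_contig * 420L + 400L > spec$contig_length)
    stop("generation error: construct collision (too many plants per contig)",
         call. = FALSE)
  slot <- function(i) {
    contig_i <- ((i - 1L) %% spec$n_contigs) + 1L
    rank <- (i - 1L) %/% spec$n_contigs
    list(contig = names(genome)[contig_i], pos = 400L + rank * 420L)
  }

  units <- .unit_pool()
  unit_i <- 0L
  truth <- list(); donors <- list(); gff <- list(); vcf_rows <- list()
  gene_i <- 0L; var_i <- 0L

  for (pi in seq_along(plants)) {
    plant <- plants[[pi]]
    sl <- slot(pi)
    contig <- sl$contig
    planted <- FALSE

    for (attempt in seq_len(60L)) {
      seq0 <- genome[[contig]]
      pos <- sl$pos

      if (plant$type == "mh_deletion_chain") {
        if (attempt == 1L) unit_i <- unit_i + 1L
        unit <- units[((unit_i - 1L) %% length(units)) + 1L]
        core <- paste0(strrep(unit, 6L), "TGG")
        if (plant$role == "gene") core <- paste0(core, "TGA")
        rs <- pos; re <- pos + 18L                 # repeat [rs, re)
        a_cut <- re - 3L
      } else {
        core <- "TGG"                              # just the PAM
        re <- pos
        a_cut <- pos - 3L
      }
      # refresh local flanks on retry so rejection sampling can progress
      if (attempt > 1L) {
        lo <- max(0L, pos - 30L)
        hi <- min(nchar(seq0), pos + nchar(core) + 30L)
        seq0 <- paste0(subseq0(seq0, 0L, lo),
                       .random_dna(pos - lo), core,
                       .random_dna(hi - pos - nchar(core)),
                       subseq0(seq0, hi, nchar(seq0)))
      } else {
        seq0 <- .splice(seq0, pos, core)
      }
      trial <- genome; trial[[contig]] <- seq0

      check <- .check_plant(plant, trial, contig, pos, a_cut, re,
                            if (plant$type == "mh_deletion_chain") unit else NA,
                            pred, params, filters, cfg, verify)
      if (is.null(check)) next

      genome <- check$genome
      site_id <- sprintf("site%02d", pi)
      tr <- data.frame(
        site_id = site_id, type = plant$type, role = plant$role,
        contig = contig, pam_pos0 = if (plant$type == "mh_deletion_chain")
          re else pos,
        a_cut0 = a_cut,
        unit = if (plant$type == "mh_deletion_chain") unit else NA_character_,
        expected_levels = check$levels,
        expected_recursive = check$recursive,
        expected_rank1_label = check$rank1,
        stop_codon0 = NA_integer_, variant_id = NA_character_,
        stringsAsFactors = FALSE)

      if (plant$role == "gene") {
        gene_i <- gene_i + 1L
        gname <- sprintf("GENE%d", gene_i)
        stop0 <- re + 3L                          # TGA right after the PAM
        gstart0 <- pos - 300L
        # plant an ATG at the gene start
        s <- genome[[contig]]
        substr(s, gstart0 + 1L, gstart0 + 3L) <- "ATG"
        genome[[contig]] <- s
        tr$stop_codon0 <- stop0
        iso <- if (gene_i == 1L) 2L else 1L       # isoform pair for dedup
        gff[[length(gff) + 1L]] <- data.frame(
          seqid = contig, source = "editcascade", type = "gene",
          start = gstart0 + 1L, end = stop0 + 3L, strand = "+",
          ID = gname, gene_id = gname, transcript_id = NA_character_,
          stringsAsFactors = FALSE)
        for (t in seq_len(iso)) {
          tid <- sprintf("%s.t%d", gname, t)
          gff[[length(gff) + 1L]] <- data.frame(
            seqid = contig, source = "editcascade", type = "start_codon",
            start = gstart0 + 1L, end = gstart0 + 3L, strand = "+",
            ID = paste0(tid, ".start"), gene_id = gname, transcript_id = tid,
            stringsAsFactors = FALSE)
          gff[[length(gff) + 1L]] <- data.frame(
            seqid = contig, source = "editcascade", type = "stop_codon",
            start = stop0 + 1L, end = stop0 + 3L, strand = "+",
            ID = paste0(tid, ".stop"), gene_id = gname, transcript_id = tid,
            stringsAsFactors = FALSE)
        }
      }

      if (plant$role == "variant") {
        var_i <- var_i + 1L
        vid <- sprintf("var_q%d", var_i)
        v0 <- check$variant_pos
        vcf_rows[[length(vcf_rows) + 1L]] <- data.frame(
          CHROM = contig, POS = v0 + 1L, ID = vid,
          REF = check$variant_ref, ALT = check$variant_alt,
          stringsAsFactors = FALSE)
        tr$variant_id <- vid
      }

      if (check$recursive) {
        donors[[length(donors) + 1L]] <- list(
          site_id = site_id, contig = contig, a_cut0 = a_cut,
          edit = "+3 bp ins GAT at the entry cut",
          homology_arm_length = 45L)
      }
      truth[[length(truth) + 1L]] <- tr
      planted <- TRUE
      break
    }
    if (!planted)
      stop("generation error: could not plant construct ", pi, " (",
           plant$type, ")", call. = FALSE)
  }

  # non-qualifying variants: plain SNVs + one long deletion
  n_extra <- max(0L, spec$variant_count - n_qual_var)
  extra_pos <- 150L
  for (k in seq_len(n_extra)) {
    contig <- names(genome)[((k - 1L) %% spec$n_contigs) + 1L]
    seq <- genome[[contig]]
    if (k == n_extra && n_extra >= 1L) {
      p0 <- nchar(seq) - 220L                     # >50 bp deletion variant
      ref <- subseq0(seq, p0, p0 + 60L)
      vcf_rows[[length(vcf_rows) + 1L]] <- data.frame(
        CHROM = contig, POS = p0 + 1L, ID = sprintf("var_long%d", k),
        REF = ref, ALT = substr(ref, 1L, 1L), stringsAsFactors = FALSE)
    } else {
      p0 <- extra_pos + 17L * k
      ref <- substr(seq, p0 + 1L, p0 + 1L)
      alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
      vcf_rows[[length(vcf_rows) + 1L]] <- data.frame(
        CHROM = contig, POS = p0 + 1L, ID = sprintf("var_bg%d", k),
        REF = ref, ALT = alt, stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, truth)
  vcf <- if (length(vcf_rows)) do.call(rbind, vcf_rows) else
    data.frame(CHROM = character(0), POS = integer(0), ID = character(0),
               REF = character(0), ALT = character(0))
  vcf <- vcf[order(vcf$CHROM, vcf$POS), , drop = FALSE]

  paths <- list(fasta = file.path(out_dir, "genome.fa"),
                gff3 = file.path(out_dir, "annotation.gff3"),
                vcf = file.path(out_dir, "variants.vcf"),
                donors = file.path(out_dir, "donors.json"),
                truth_tsv = file.path(out_dir, "truth.tsv"))
  write_genome(genome, paths$fasta)
  if (length(gff)) write_gff3(do.call(rbind, gff), paths$gff3)
  write_vcf_df(vcf, paths$vcf,
               contig_lengths = stats::setNames(nchar(genome), names(genome)))
  writeLines(as.character(jsonlite::toJSON(donors, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             paths$donors)
  utils::write.table(truth, paths$truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  c(paths, list(genome = genome, truth = truth, spec = spec,
                dir = out_dir))
}

# verify one plant; returns NULL to reject, else expectations (with the
# possibly engineered genome in $genome)
.check_plant <- function(plant, genome, contig, pos, a_cut, re, unit,
                         pred, params, filters, cfg, verify) {
  seq <- genome[[contig]]
  hw <- 50L
  wstart <- a_cut - hw
  if (wstart < 0L || a_cut + hw > nchar(seq)) return(NULL)
  if (plant$type == "plus1_dup") {
    seq <- .engineer_plus1(seq, a_cut, pos, params)
    if (is.null(seq)) return(NULL)
    genome[[contig]] <- seq
  }
  window <- subseq0(seq, wstart, a_cut + hw)
  lcut <- hw

  # the planted guide: protospacer immediately 5' of the planted PAM
  pam0 <- if (plant$type == "mh_deletion_chain") re else pos
  if (subseq0(seq, pam0 + 1L, pam0 + 3L) != "GG") return(NULL)
  proto <- subseq0(seq, pam0 - 20L, pam0)
  if (!grepl("^[ACGT]+$", proto)) return(NULL)
  g <- .new_guide(proto, subseq0(seq, pam0, pam0 + 3L), "+",
                  cut_index = a_cut, position = pam0 - 20L)
  if (g$on_target < filters$min_on_target) return(NULL)
  if (count_offtargets(g, genome, filters$mm_max) >
      filters$max_offtarget_hits) return(NULL)

  # the planted cut must be the only candidate entry cut in or near the
  # repeat, and the flanks must break the repeat period so that no
  # equivalent high-microhomology deletion covers a cut outside the repeat
  if (plant$type == "mh_deletion_chain") {
    rs <- re - 18L
    if (substr(seq, rs, rs) == substr(seq, rs + 3L, rs + 3L)) return(NULL)
    for (cand in enumerate_guides(window)) {
      gcut <- cand$cut_index + wstart
      if (gcut >= rs - 8L && gcut <= re + 8L && gcut != a_cut) return(NULL)
    }
  }

  dist <- pred(window, lcut, params)
  conc <- concentration(dist, cfg$top_outcomes_per_allele)
  rank1 <- dist$outcomes[[1]]$label

  if (plant$type == "mh_deletion_chain") {
    if (conc < cfg$entry_concentration_min) return(NULL)
    if (dist$outcomes[[1]]$kind != "deletion" ||
        dist$outcomes[[1]]$length != 3L) return(NULL)
  } else {
    if (conc >= cfg$entry_concentration_min) return(NULL)
    if (plant$type == "plus1_dup" &&
        !(dist$outcomes[[1]]$kind == "insertion" &&
          dist$outcomes[[1]]$length == 1L)) return(NULL)
  }

  donor <- donor_spec(window, indel_outcome("insertion", start = lcut,
                                            length = 3L,
                                            inserted_seq = "GAT"))
  lg <- .new_guide(proto, g$pam, "+", cut_index = lcut,
                   position = (pam0 - 20L) - wstart)
  site <- sequence_window(contig, wstart, window)

  out <- list(levels = 1L, recursive = FALSE, rank1 = rank1,
              variant_pos = NA_integer_, variant_ref = NA_character_,
              variant_alt = NA_character_, genome = genome)

  if (!verify) {
    out$levels <- switch(plant$type, mh_deletion_chain = 3L, plus1_dup = 1L,
                         non_recursive = 1L)
    out$recursive <- plant$type == "mh_deletion_chain"
    if (plant$role == "variant") {
      v0 <- a_cut - 2L
      out$variant_pos <- v0
      out$variant_ref <- substr(seq, v0 + 1L, v0 + 1L)
      out$variant_alt <- setdiff(c("A", "C", "G", "T"), out$variant_ref)[1]
    }
    return(out)
  }

  casc <- run_recursion(site, donor = donor, predictor = pred,
                        params = params, filters = filters, cfg = cfg,
                        a_guide = lg, background = genome)
  if (n_levels(casc) == 0L) return(NULL)
  rep <- site_report(casc)
  out$levels <- n_levels(casc)
  out$recursive <- rep$is_recursive

  if (plant$type == "mh_deletion_chain") {
    if (n_levels(casc) < 3L || !rep$is_recursive) return(NULL)
  }
  if (plant$type == "non_recursive" && rep$is_recursive) return(NULL)
  if (plant$type == "plus1_dup") {
    if (rep$is_recursive) return(NULL)
    # mechanics check at a relaxed targeted-mass threshold: a B guide must
    # exist that spans the duplicated base and avoids wildtype and donor
    relaxed <- search_config(max_levels = 2L, min_targeted_mass = 0.02)
    c2 <- run_recursion(site, donor = donor, predictor = pred,
                        params = params, filters = filters, cfg = relaxed,
                        a_guide = lg, background = genome)
    if (n_levels(c2) < 2L) return(NULL)
    b1 <- c2$levels[[2]][[1]]
    plus1 <- apply_outcome(wildtype_allele(window), "A1",
                           dist$outcomes[[1]])
    if (!matches_allele(b1$guide, plus1) ||
        matches_allele(b1$guide, window) ||
        matches_allele(b1$guide, donor)) return(NULL)
  }

  if (plant$role == "variant") {
    # SNV inside the repeat, 2 bp 5' of the cut; donor installs it
    v0 <- a_cut - 2L
    ref <- substr(seq, v0 + 1L, v0 + 1L)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      edit <- substitution(v0 - wstart, ref, alt)
      dn <- tryCatch(donor_spec(window, edit), error = function(e) NULL)
      if (is.null(dn)) next
      cv <- run_recursion(site, donor = dn, predictor = pred,
                          params = params, filters = filters, cfg = cfg,
                          a_guide = lg, background = genome,
                          target_pos = v0 - wstart)
      if (n_levels(cv) >= 2L && site_report(cv)$is_recursive) {
        out$variant_pos <- v0; out$variant_ref <- ref; out$variant_alt <- alt
        out$levels <- n_levels(cv); out$recursive <- TRUE
        return(out)
      }
    }
    return(NULL)
  }
  out
}
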