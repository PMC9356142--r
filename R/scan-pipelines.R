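# Database-generation scans: genome-wide site scan, start/stop-codon
# (tagging) scan, and variant-window scan. Every record a scan emits is
# exactly the result of running `run_recursion` on that window, so scan
# output and per-site runs agree bit-for-bit.

#' Describe a scan job
#'
#' @param mode `"genome"`, `"cds_ends"` or `"variants"`.
#' @param genome Genome FASTA path or named character vector of contigs.
#' @param annotation GFF3 path or `GRanges` (cds_ends mode).
#' @param variants VCF path or variant data frame (variants mode).
#' @param window_half_width Half-width of the search window, bp; defaults to
#'   50 (genome, variants) or 30 (cds_ends).
#' @param step Genome-mode coarse tiling step over candidate entry guides
#'   (1 = every guide).
#' @param search_config,filter_config,predictor_params Module configurations.
#' @param predictor Predictor name or function.
#' @param donor_insertion Insertion installed by the default HDR donor at
#'   the entry cut (genome / cds_ends modes). Default `"GAT"` (3 bp).
#' @param variant_direction `"install"` (donor installs the ALT allele into
#'   a REF genome) or `"revert"` (donor restores REF; genome carries ALT).
#' @param dedup_radius Genome-mode records whose entry cuts lie within this
#'   many bp collapse to the best-scoring. Default 5.
#' @return An object of class `scan_job`.
#' @export
scan_job <- function(mode = c("genome", "cds_ends", "variants"), genome,
                     annotation = NULL, variants = NULL,
                     window_half_width = NULL, step = 1L,
                     search_config = editcascade::search_config(),
                     filter_config = editcascade::filter_config(),
                     predictor_params = editcascade::predictor_params(),
                     predictor = "bundled", donor_insertion = "GAT",
                     variant_direction = c("install", "revert"),
                     dedup_radius = 5L) {
  mode <- match.arg(mode)
  variant_direction <- match.arg(variant_direction)
  if (is.null(window_half_width))
    window_half_width <- if (mode == "cds_ends") 30L else 50L
  if (mode == "cds_ends" && is.null(annotation))
    stop("cds_ends mode requires an annotation", call. = FALSE)
  if (mode == "variants" && is.null(variants))
    stop("variants mode requires a variant list", call. = FALSE)
  structure(list(mode = mode, genome = genome, annotation = annotation,
                 variants = variants,
                 window_half_width = as.integer(window_half_width),
                 step = as.integer(step), search_config = search_config,
                 filter_config = filter_config,
                 predictor_params = predictor_params, predictor = predictor,
                 donor_insertion = donor_insertion,
                 variant_direction = variant_direction,
                 dedup_radius = as.integer(dedup_radius)),
            class = "scan_job")
}

.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)))
    read_genome(genome)                 # errors with the path when unreadable
  else if (is.character(genome) && !is.null(names(genome))) toupper(genome)
  else stop("I/O error: genome must be a FASTA path or named contig vector",
            call. = FALSE)
}

.empty_records <- function() {
  data.frame(locus_id = character(0), mode = character(0),
             contig = character(0), window_start = integer(0),
             window_end = integer(0), a_cut = integer(0),
             n_levels = integer(0), is_recursive = logical(0),
             eff_level0 = numeric(0), overall_rank_score = numeric(0),
             guides = character(0), gene = character(0),
             feature_type = character(0), variant_id = character(0),
             stringsAsFactors = FALSE)
}

.guides_field <- function(cascade) {
  parts <- character(0)
  for (lev in seq_along(cascade$levels))
    for (e in cascade$levels[[lev]])
      parts <- c(parts, sprintf("%s=%s|%s", e$label, e$guide$protospacer,
                                e$guide$pam))
  paste(parts, collapse = ";")
}

.record_row <- function(job, contig, wstart, wend, a_cut, report,
                        gene = NA_character_, feature_type = NA_character_,
                        variant_id = NA_character_) {
  cascade <- report$cascade
  data.frame(
    locus_id = sprintf("%s:%d-%d", contig, wstart, wend), mode = job$mode,
    contig = contig, window_start = wstart, window_end = wend,
    a_cut = a_cut, n_levels = n_levels(cascade),
    is_recursive = report$is_recursive,
    eff_level0 = report$retargeting_efficiency_per_level[1],
    overall_rank_score = report$overall_rank_score,
    guides = .guides_field(cascade), gene = gene,
    feature_type = feature_type, variant_id = variant_id,
    stringsAsFactors = FALSE)
}

# evaluate one candidate entry guide; returns list(row=, cascade=) or NULL
.scan_site <- function(job, genome, idx, contig, g, pred, donor_edit = NULL,
                       target_pos = NULL, gene = NA_character_,
                       feature_type = NA_character_,
                       variant_id = NA_character_) {
  hw <- job$window_half_width
  seq <- genome[[contig]]
  cut <- g$cut_index
  wstart <- cut - hw; wend <- cut + hw
  if (wstart < 0L || wend > nchar(seq)) return(NULL)   # window crosses edge
  window <- subseq0(seq, wstart, wend)
  lcut <- hw
  cfg <- job$search_config

  dist <- tryCatch(pred(window, lcut, job$predictor_params),
                   error = function(e) NULL)
  if (is.null(dist)) return(NULL)
  if (concentration(dist, cfg$top_outcomes_per_allele) <
      cfg$entry_concentration_min) return(NULL)

  local_guide <- .new_guide(g$protospacer, g$pam, g$strand,
                            cut_index = lcut,
                            position = g$position - wstart,
                            on_target = g$on_target)
  edit <- if (is.null(donor_edit)) {
    indel_outcome("insertion", start = lcut,
                  length = nchar(job$donor_insertion),
                  inserted_seq = job$donor_insertion)
  } else donor_edit
  donor <- tryCatch(donor_spec(window, edit), error = function(e) NULL)
  if (is.null(donor)) return(NULL)

  site <- sequence_window(contig, wstart, window)
  cascade <- run_recursion(site, donor = donor, predictor = pred,
                           params = job$predictor_params,
                           filters = job$filter_config, cfg = cfg,
                           a_guide = local_guide, background = idx,
                           target_pos = target_pos)
  if (n_levels(cascade) == 0L) return(NULL)
  report <- site_report(cascade)
  list(row = .record_row(job, contig, wstart, wend, cut, report, gene,
                         feature_type, variant_id),
       cascade = cascade)
}

.finalize_records <- function(rows, cascades) {
  if (length(rows) == 0L) {
    rec <- .empty_records()
    attr(rec, "cascades") <- list()
    return(rec)
  }
  rec <- do.call(rbind, rows)
  ord <- order(-rec$overall_rank_score, rec$contig, rec$a_cut)
  rec <- rec[ord, , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "cascades") <- cascades[ord]
  rec
}

#' Genome-wide scan for Recursive-Editing-amenable sites
#'
#' Every enumerated guide is a candidate entry point: its window passes the
#' entry-concentration check, then the full recursion runs with a default
#' donor installing a short insertion at the entry cut. Sites classified
#' Recursive are emitted; overlapping records (entry cuts within
#' `dedup_radius`) collapse to the best-scoring. Records are sorted by
#' overall rank score, descending.
#'
#' @param job A [scan_job] with `mode = "genome"`.
#' @return Data frame of database records, one per qualifying site, with the
#'   corresponding `cascade` objects in `attr(, "cascades")`.
#' @export
scan_genome <- function(job) {
  stopifnot(inherits(job, "scan_job"), job$mode == "genome")
  genome <- .load_genome(job$genome)
  idx <- bg_index(genome)
  pred <- if (is.function(job$predictor)) job$predictor
          else get_predictor(job$predictor)
  rows <- list(); cascades <- list()

  for (contig in names(genome)) {
    guides <- enumerate_guides(genome[[contig]])
    if (job$step > 1L)
      guides <- Filter(function(g) g$position %% job$step == 0L, guides)
    for (g in guides) {
      hit <- .scan_site(job, genome, idx, contig, g, pred)
      if (is.null(hit) || !hit$row$is_recursive) next
      rows[[length(rows) + 1L]] <- hit$row
      cascades[[length(cascades) + 1L]] <- hit$cascade
    }
  }

  # deduplicate overlapping records, keeping the higher-scoring
  if (length(rows) > 1L) {
    keep <- rep(TRUE, length(rows))
    sc <- vapply(rows, function(r) r$overall_rank_score, 0)
    for (i in seq_along(rows)) {
      if (!keep[i]) next
      for (j in seq_along(rows)) {
        if (i == j || !keep[j]) next
        if (rows[[i]]$contig == rows[[j]]$contig &&
            abs(rows[[i]]$a_cut - rows[[j]]$a_cut) <= job$dedup_radius) {
          drop <- if (sc[i] < sc[j]) i else j
          keep[drop] <- FALSE
        }
      }
    }
    rows <- rows[keep]; cascades <- cascades[keep]
  }
  .finalize_records(rows, cascades)
}

#' Scan start/stop codons for taggable Recursive-Editing sites
#'
#' Extracts `start_codon` / `stop_codon` features from the annotation,
#' drops redundant entries that overlap the same codon (different gene or
#' isoform names), builds one search window per deduplicated codon, and
#' requires the entry cut to be proximal to the codon. The best Recursive
#' cascade per codon is emitted.
#'
#' @param job A [scan_job] with `mode = "cds_ends"`.
#' @return Data frame of database records (see [scan_genome]).
#' @export
scan_cds_ends <- function(job) {
  stopifnot(inherits(job, "scan_job"), job$mode == "cds_ends")
  genome <- .load_genome(job$genome)
  idx <- bg_index(genome)
  pred <- if (is.function(job$predictor)) job$predictor
          else get_predictor(job$predictor)
  gr <- if (methods::is(job$annotation, "GRanges")) job$annotation
        else read_gff3(job$annotation)
  feats <- gr[as.character(gr$type) %in% c("start_codon", "stop_codon")]
  if (length(feats) == 0L) {
    warning("no start_codon/stop_codon features in annotation")
    return(.finalize_records(list(), list()))
  }
  key <- paste(GenomicRanges::seqnames(feats), GenomicRanges::start(feats),
               GenomicRanges::end(feats), GenomicRanges::strand(feats),
               feats$type)
  feats <- feats[!duplicated(key)]

  rows <- list(); cascades <- list()
  for (i in seq_along(feats)) {
    contig <- as.character(GenomicRanges::seqnames(feats))[i]
    if (!contig %in% names(genome)) next
    c0 <- GenomicRanges::start(feats)[i] - 1L       # 0-based codon start
    c1 <- GenomicRanges::end(feats)[i]              # 0-based exclusive end
    gene <- if (!is.null(feats$gene_id)) feats$gene_id[i] else NA_character_
    ftype <- as.character(feats$type[i])

    best <- NULL
    for (g in enumerate_guides(genome[[contig]])) {
      if (.edit_distance(g$cut_index, c(c0, c1)) >
          job$filter_config$proximity_bp) next
      hit <- .scan_site(job, genome, idx, contig, g, pred,
                        target_pos = c(c0, c1) - (g$cut_index -
                                                  job$window_half_width),
                        gene = gene, feature_type = ftype)
      if (is.null(hit) || !hit$row$is_recursive) next
      if (is.null(best) ||
          hit$row$overall_rank_score > best$row$overall_rank_score)
        best <- hit
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- best$row
      cascades[[length(cascades) + 1L]] <- best$cascade
    }
  }
  .finalize_records(rows, cascades)
}

# classify a trimmed REF/ALT pair as a donor edit in window coordinates
.variant_edit <- function(ref, alt, local_pos) {
  # trim shared prefix (VCF anchor base convention)
  n <- 0L
  while (n < nchar(ref) && n < nchar(alt) &&
         substr(ref, n + 1L, n + 1L) == substr(alt, n + 1L, n + 1L)) n <- n + 1L
  r <- substr(ref, n + 1L, nchar(ref))
  a <- substr(alt, n + 1L, nchar(alt))
  pos <- local_pos + n
  if (nchar(r) == 0L && nchar(a) > 0L)
    indel_outcome("insertion", start = pos, length = nchar(a),
                  inserted_seq = a)
  else if (nchar(a) == 0L && nchar(r) > 0L)
    indel_outcome("deletion", start = pos, length = nchar(r))
  else if (nchar(r) >= 1L && nchar(r) == nchar(a))
    substitution(pos, r, a)
  else NULL                                   # complex MNV: unsupported
}

#' Scan variant windows for Recursive-Editing sites
#'
#' Variants with `|len(REF) - len(ALT)| > 50` are excluded; for each
#' retained variant a window of `window_half_width` bp either side of the
#' variant is searched, the HDR donor installs (or, in revert mode,
#' corrects) the variant, and the entry cut must be proximal to the variant.
#' Malformed records (REF == ALT, non-DNA alleles, REF not matching the
#' genome) are skipped with a logged id.
#'
#' @param job A [scan_job] with `mode = "variants"`.
#' @return Data frame of database records (see [scan_genome]); the number
#'   of retained/skipped variants is in `attr(, "n_retained")` /
#'   `attr(, "skipped")`.
#' @export
scan_variants <- function(job) {
  stopifnot(inherits(job, "scan_job"), job$mode == "variants")
  genome <- .load_genome(job$genome)
  idx <- bg_index(genome)
  pred <- if (is.function(job$predictor)) job$predictor
          else get_predictor(job$predictor)
  vdf <- if (is.data.frame(job$variants)) job$variants
         else read_vcf_df(job$variants)

  skipped <- character(0)
  ok <- rep(TRUE, nrow(vdf))
  for (i in seq_len(nrow(vdf))) {
    bad <- is.na(vdf$REF[i]) || is.na(vdf$ALT[i]) ||
      !grepl("^[ACGT]+$", vdf$REF[i]) || !grepl("^[ACGT]+$", vdf$ALT[i]) ||
      vdf$REF[i] == vdf$ALT[i]
    if (bad) {
      skipped <- c(skipped, vdf$ID[i] %||% sprintf("row%d", i))
      ok[i] <- FALSE
    }
  }
  vdf <- vdf[ok, , drop = FALSE]
  retained <- abs(nchar(vdf$REF) - nchar(vdf$ALT)) <= 50L
  vdf <- vdf[retained, , drop = FALSE]

  rows <- list(); cascades <- list()
  hw <- job$window_half_width
  for (i in seq_len(nrow(vdf))) {
    contig <- vdf$CHROM[i]
    if (!contig %in% names(genome)) { skipped <- c(skipped, vdf$ID[i]); next }
    seq <- genome[[contig]]
    v0 <- vdf$POS[i] - 1L                       # 0-based variant start
    ref <- vdf$REF[i]; alt <- vdf$ALT[i]
    if (job$variant_direction == "revert") { tmp <- ref; ref <- alt; alt <- tmp }
    if (v0 + nchar(ref) > nchar(seq) ||
        subseq0(seq, v0, v0 + nchar(ref)) != ref) {
      skipped <- c(skipped, vdf$ID[i]); next
    }
    vint <- c(v0, v0 + nchar(ref))              # genomic edit interval

    best <- NULL
    for (g in enumerate_guides(seq)) {
      if (.edit_distance(g$cut_index, vint) >
          job$filter_config$proximity_bp) next
      wstart <- g$cut_index - hw
      edit <- .variant_edit(ref, alt, v0 - wstart)
      if (is.null(edit)) { next }
      hit <- .scan_site(job, genome, idx, contig, g, pred,
                        donor_edit = edit,
                        target_pos = vint - wstart,
                        variant_id = vdf$ID[i])
      if (is.null(hit) || !hit$row$is_recursive) next
      if (is.null(best) ||
          hit$row$overall_rank_score > best$row$overall_rank_score)
        best <- hit
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- best$row
      cascades[[length(cascades) + 1L]] <- best$cascade
    }
  }
  rec <- .finalize_records(rows, cascades)
  attr(rec, "n_retained") <- nrow(vdf)
  attr(rec, "skipped") <- skipped
  rec
}

#' Write scan records as a TSV database plus JSON cascades
#'
#' @param records Records from a scan, with cascades attached.
#' @param path_prefix Output path without extension.
#' @return Invisibly, the two paths.
#' @export
write_records <- function(records, path_prefix) {
  tp <- paste0(path_prefix, ".tsv"); jp <- paste0(path_prefix, ".json")
  utils::write.table(records, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cascades <- attr(records, "cascades") %||% list()
  json <- vapply(cascades, cascade_json, "")
  writeLines(paste0("[", paste(json, collapse = ",\n"), "]"), jp)
  invisible(c(tsv = tp, json = jp))
}
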