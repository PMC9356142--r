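# The recursive cascade search: build the recursion tree of edited alleles,
# score candidate guides per level, select cascades, classify sites.
#
# Levels are lettered A (entry, wildtype-targeting), B, C, ...; within a
# level guides are numbered by the predicted abundance of the alleles they
# target, so "B2" targets the second most abundant outcome of the first
# round of editing.

#' Search configuration for cascade design
#'
#' @param max_levels Maximum recursion depth (3 = A/B/C). Default 3.
#' @param top_outcomes_per_allele Children expanded per frontier allele.
#'   Default 2.
#' @param min_targeted_mass Minimum summed frontier mass a retargeting guide
#'   must cover to qualify. Default 0.05.
#' @param entry_concentration_min Minimum summed frequency of the top
#'   outcomes required at the entry level for a site to be considered in
#'   scans. Default 0.5.
#' @param guides_per_level_max Guides kept per retargeting level. Default 2.
#' @param recursive_threshold Sites whose level-0 retargeting efficiency
#'   strictly exceeds this are classified Recursive. Default 0.20.
#' @return An object of class `search_config`.
#' @export
search_config <- function(max_levels = 3L, top_outcomes_per_allele = 2L,
                          min_targeted_mass = 0.05,
                          entry_concentration_min = 0.5,
                          guides_per_level_max = 2L,
                          recursive_threshold = 0.20) {
  stopifnot(max_levels >= 1L, top_outcomes_per_allele >= 1L,
            min_targeted_mass >= 0, min_targeted_mass <= 1,
            entry_concentration_min >= 0, entry_concentration_min <= 1,
            guides_per_level_max >= 1L,
            recursive_threshold >= 0, recursive_threshold <= 1)
  structure(list(max_levels = as.integer(max_levels),
                 top_outcomes_per_allele = as.integer(top_outcomes_per_allele),
                 min_targeted_mass = min_targeted_mass,
                 entry_concentration_min = entry_concentration_min,
                 guides_per_level_max = as.integer(guides_per_level_max),
                 recursive_threshold = recursive_threshold),
            class = "search_config")
}

# cached off-target counting (keyed by protospacer)
.ot_hits <- function(g, idx, mm_max, cache) {
  key <- g$protospacer
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  n <- count_offtargets(g, idx, mm_max)
  if (!is.null(cache)) cache[[key]] <- n
  n
}

# edit interval of an outcome in CHILD coordinates
.child_edit_interval <- function(parent_seq, outcome) {
  if (outcome$kind == "deletion") {
    m <- microhomology_length(parent_seq, outcome)
    c(outcome$start, outcome$start + m)
  } else {
    c(outcome$start, outcome$start + outcome$length)
  }
}

# does any next-level candidate on `child` pass the filters?
.has_next_level_guide <- function(child, edit_interval, filters, wt, donor,
                                  idx, cache) {
  for (cand in enumerate_guides(child$seq)) {
    if (cand$on_target < filters$min_on_target) next
    if (.edit_distance(cand$cut_index, edit_interval) > filters$proximity_bp) next
    if (!is.null(wt) && matches_allele(cand, wt)) next
    if (!is.null(donor) && matches_allele(cand, donor)) next
    if (.ot_hits(cand, idx, filters$mm_max, cache) > filters$max_offtarget_hits) next
    return(TRUE)
  }
  FALSE
}

#' Retarget score of a candidate guide
#'
#' The priority metric for retargeting guides: `M(g) * R(g)`, where `M(g)`
#' is the summed mass of frontier alleles the guide targets (abundance of
#' the newly targeted indels) and `R(g)` is the fraction of the guide's own
#' predicted outcomes for which a qualifying next-level guide exists (the
#' retargetable fraction, a one-step look-ahead). Both factors lie in
#' `[0, 1]`. The score ranks reagents at a locus; it is not a quantitative
#' predictor of HDR improvement.
#'
#' @param g A `guide_candidate`.
#' @param frontier Non-empty list of [allele]s with masses conditional on
#'   the indel channel.
#' @param predictor Predictor name (see [get_predictor]) or function.
#' @param params [predictor_params] for the predictor.
#' @param filters [filter_config] applied to look-ahead candidates.
#' @param wt,donor Wildtype allele and [donor_spec] for avoidance clauses.
#' @param background Background sequences for off-target counting (defaults
#'   to none, i.e. zero off-target hits in look-ahead).
#' @param cache Optional environment for off-target memoisation.
#' @return Numeric score with attributes `M` and `R`.
#' @export
retarget_score <- function(g, frontier, predictor = "bundled",
                           params = predictor_params(),
                           filters = filter_config(), wt = NULL, donor = NULL,
                           background = NULL, cache = NULL) {
  if (length(frontier) == 0L)
    stop("domain error: empty frontier", call. = FALSE)
  pred <- if (is.function(predictor)) predictor else get_predictor(predictor)
  idx <- if (is.null(background)) NULL else bg_index(background)

  matched <- Filter(function(a) matches_allele(g, a), frontier)
  M <- sum(vapply(matched, `[[`, 0, "mass"))
  if (M == 0) return(structure(0, M = 0, R = 0))

  masses <- vapply(matched, `[[`, 0, "mass")
  seqs <- vapply(matched, `[[`, "", "seq")
  target <- matched[[order(-masses, seqs)[1]]]
  sites <- find_guide_sites(g, target$seq)
  cut <- sites$cut_index[1]
  dist <- pred(target$seq, cut, params)

  if (is.null(idx)) idx <- bg_index(target$seq)
  R <- 0
  for (o in dist$outcomes) {
    child <- apply_outcome(target, g$guide_id, o)
    edit <- .child_edit_interval(target$seq, o)
    if (.has_next_level_guide(child, edit, filters, wt, donor, idx, cache))
      R <- R + o$freq
  }
  structure(M * R, M = M, R = R)
}

# deterministic ranking helpers
.rank_by_score <- function(entries) {
  sc <- vapply(entries, function(e) as.numeric(e$retarget_score), 0)
  ot <- vapply(entries, function(e) e$guide$on_target, 0)
  pos <- vapply(entries, function(e) e$guide$position, 0L)
  str <- vapply(entries, function(e) e$guide$strand, "")
  entries[order(-sc, -ot, pos, str != "+")]
}

.rank_by_efficacy <- function(entries) {
  ot <- vapply(entries, function(e) e$guide$on_target, 0)
  oh <- vapply(entries, function(e) e$guide$offtarget_hits, 0L)
  pos <- vapply(entries, function(e) e$guide$position, 0L)
  str <- vapply(entries, function(e) e$guide$strand, "")
  entries[order(-ot, oh, pos, str != "+")]
}

#' Run the recursive cascade search on a site
#'
#' Breadth-wise per level: predict outcomes for each frontier allele, expand
#' the top outcomes into child alleles (merging alleles that converge to the
#' same sequence), enumerate candidate guides proximal to the new edits,
#' score them with [retarget_score], and keep the highest-scoring qualifying
#' candidates (`targeted_mass >= min_targeted_mass`). At the final level,
#' qualifying candidates are re-ranked solely by efficacy and specificity
#' (on-target descending, off-target hits ascending). The entry guide can be
#' designed (highest retarget score) or supplied by the user. Deterministic.
#'
#' @param site A [sequence_window] (>= 30 bp) or DNA string.
#' @param donor Optional [donor_spec]; the HDR allele is never targeted.
#' @param predictor Predictor name or function.
#' @param params [predictor_params].
#' @param filters [filter_config].
#' @param cfg [search_config].
#' @param a_guide Optional user-supplied entry `guide_candidate` (window
#'   coordinates).
#' @param background Background sequences for off-target counting; defaults
#'   to the site window itself.
#' @param target_pos Optional position/interval (window coordinates) the
#'   entry cut must be proximal to (codon or variant scans).
#' @return An object of class `cascade`; when no entry guide qualifies, an
#'   empty cascade whose `reason` field explains why.
#' @export
run_recursion <- function(site, donor = NULL, predictor = "bundled",
                          params = predictor_params(),
                          filters = filter_config(), cfg = search_config(),
                          a_guide = NULL, background = NULL,
                          target_pos = NULL) {
  if (is.character(site)) site <- sequence_window("window", 0L, site)
  stopifnot(inherits(site, "sequence_window"))
  if (nchar(site$seq) < 30L)
    stop("site window must be at least 30 bp for design", call. = FALSE)
  pred <- if (is.function(predictor)) predictor else get_predictor(predictor)
  idx <- bg_index(background %||% stats::setNames(site$seq, site$contig_id))
  cache <- new.env(parent = emptyenv())
  wt <- wildtype_allele(site$seq)

  empty <- function(reason) {
    structure(list(site = site, donor = donor, levels = list(),
                   frontiers = list(), cut_mass = numeric(0),
                   config = list(params = params, filters = filters, cfg = cfg),
                   reason = reason),
              class = "cascade")
  }

  # ---- entry level (A) ----
  cands <- if (!is.null(a_guide)) list(a_guide) else enumerate_guides(wt$seq)
  entries <- list()
  for (g in cands) {
    if (nrow(find_guide_sites(g, wt$seq)) == 0L) next
    g$offtarget_hits <- .ot_hits(g, idx, filters$mm_max, cache)
    if (!passes_filters(g, filters, wt = NULL, donor = donor,
                        prior_edit_pos = target_pos, level = 0L)) next
    sc <- retarget_score(g, list(wt), pred, params, filters, wt = wt,
                         donor = donor, background = idx, cache = cache)
    entries[[length(entries) + 1L]] <-
      list(guide = g, label = "A1", retarget_score = as.numeric(sc),
           targeted_alleles = wt$seq, targeted_mass = attr(sc, "M"))
  }
  if (length(entries) == 0L) return(empty("no qualifying entry guide"))
  a_entry <- .rank_by_score(entries)[[1]]

  levels <- list(list(a_entry))
  frontiers <- list(list(wt))
  cut_mass <- 1
  chosen_protos <- a_entry$guide$protospacer

  # ---- expand children of the entry guide ----
  expand <- function(parents, guides) {
    kids <- list()
    for (g in guides) {
      for (a in parents) {
        if (!matches_allele(g, a)) next
        sites <- find_guide_sites(g, a$seq)
        cut <- sites$cut_index[1]
        if (cut < 5L || cut > nchar(a$seq) - 5L) next
        dist <- pred(a$seq, cut, params)
        for (o in rank_outcomes(dist, cfg$top_outcomes_per_allele))
          kids[[length(kids) + 1L]] <- apply_outcome(a, g$guide_id, o)
      }
    }
    merge_alleles(kids)
  }
  frontier <- expand(list(wt), list(a_entry$guide))

  # ---- retargeting levels (B, C, ...) ----
  lev <- 2L
  while (lev <= cfg$max_levels && length(frontier) > 0L) {
    pool <- list(); seen <- character(0)
    for (a in frontier) {
      for (g in enumerate_guides(a$seq)) {
        key <- paste0(g$protospacer, g$pam)
        if (key %in% seen || g$protospacer %in% chosen_protos) next
        if (.edit_distance(g$cut_index, a$last_edit) > filters$proximity_bp) next
        if (g$on_target < filters$min_on_target) next
        if (matches_allele(g, wt)) next
        if (!is.null(donor) && matches_allele(g, donor)) next
        if (.ot_hits(g, idx, filters$mm_max, cache) >
            filters$max_offtarget_hits) next
        seen <- c(seen, key)
        g$offtarget_hits <- .ot_hits(g, idx, filters$mm_max, cache)
        sc <- retarget_score(g, frontier, pred, params, filters, wt = wt,
                             donor = donor, background = idx, cache = cache)
        if (attr(sc, "M") < cfg$min_targeted_mass) next
        tseqs <- vapply(Filter(function(x) matches_allele(g, x), frontier),
                        `[[`, "", "seq")
        pool[[length(pool) + 1L]] <-
          list(guide = g, label = NA_character_,
               retarget_score = as.numeric(sc),
               targeted_alleles = tseqs, targeted_mass = attr(sc, "M"))
      }
    }
    if (length(pool) == 0L) break
    ranked <- if (lev == cfg$max_levels) .rank_by_efficacy(pool)
              else .rank_by_score(pool)
    sel <- utils::head(ranked, cfg$guides_per_level_max)

    # number labels within the level by targeted mass, descending
    tm <- vapply(sel, `[[`, 0, "targeted_mass")
    pos <- vapply(sel, function(e) e$guide$position, 0L)
    sel <- sel[order(-tm, pos)]
    for (i in seq_along(sel))
      sel[[i]]$label <- sprintf("%s%d", LETTERS[lev], i)

    levels[[lev]] <- sel
    frontiers[[lev]] <- frontier
    covered <- unique(unlist(lapply(sel, `[[`, "targeted_alleles")))
    fmass <- vapply(frontier, `[[`, 0, "mass")
    fseq <- vapply(frontier, `[[`, "", "seq")
    cut_mass[lev] <- sum(fmass[fseq %in% covered])
    chosen_protos <- c(chosen_protos,
                       vapply(sel, function(e) e$guide$protospacer, ""))

    frontier <- expand(frontier, lapply(sel, `[[`, "guide"))
    lev <- lev + 1L
  }

  structure(list(site = site, donor = donor, levels = levels,
                 frontiers = frontiers, cut_mass = cut_mass,
                 config = list(params = params, filters = filters, cfg = cfg),
                 reason = NULL),
            class = "cascade")
}

#' Number of levels in a cascade
#' @param cascade A `cascade`.
#' @return Integer.
#' @export
n_levels <- function(cascade) length(cascade$levels)

#' Retargeting efficiency between cascade levels
#'
#' The fraction of the indel mass generated at `level` that is targeted by
#' the guides of the next level: `(union mass of frontier alleles matched at
#' level+1) / (mass cut at level)`. Returns 0 when there is no next level.
#'
#' @param cascade A `cascade`.
#' @param level 0-based level index (0 = entry level A).
#' @return Numeric in `[0, 1]`.
#' @export
retargeting_efficiency <- function(cascade, level) {
  stopifnot(inherits(cascade, "cascade"), level >= 0L)
  if (level + 2L > n_levels(cascade)) return(0)
  cascade$cut_mass[level + 2L] / cascade$cut_mass[level + 1L]
}

#' Build a site report from a cascade
#'
#' @param cascade A `cascade`.
#' @return An object of class `site_report` with per-level retargeting
#'   efficiencies, the Recursive classification and an overall rank score
#'   (the entry guide's retarget score).
#' @export
site_report <- function(cascade) {
  stopifnot(inherits(cascade, "cascade"))
  nl <- n_levels(cascade)
  effs <- if (nl <= 1L) 0
          else vapply(0:(nl - 2L), function(L) retargeting_efficiency(cascade, L), 0)
  rank <- if (nl >= 1L) cascade$levels[[1]][[1]]$retarget_score else 0
  rep <- structure(list(cascade = cascade,
                        retargeting_efficiency_per_level = effs,
                        is_recursive = NA, overall_rank_score = rank),
                   class = "site_report")
  rep$is_recursive <- classify_site(rep)
  rep
}

#' Classify a site as Recursive
#'
#' Recursive sites are defined by a level-0 retargeting efficiency strictly
#' greater than the threshold (default 20%): enough of the first round's
#' indel mass must be retargetable for additional guides to pay off.
#'
#' @param report A `site_report`.
#' @param threshold Strict lower bound; defaults to the cascade's configured
#'   `recursive_threshold`.
#' @return Logical.
#' @export
classify_site <- function(report, threshold = NULL) {
  stopifnot(inherits(report, "site_report"),
            length(report$retargeting_efficiency_per_level) >= 1L)
  thr <- threshold %||% report$cascade$config$cfg$recursive_threshold
  report$retargeting_efficiency_per_level[1] > thr
}

# ---- serialization ---------------------------------------------------------

.cascade_to_list <- function(cascade) {
  rep <- site_report(cascade)
  list(
    site = list(contig = cascade$site$contig_id, start = cascade$site$start,
                length = nchar(cascade$site$seq), seq = cascade$site$seq),
    donor = if (is.null(cascade$donor)) NULL else list(
      edit = unclass(cascade$donor$edit),
      homology_arm_length = cascade$donor$homology_arm_length,
      hdr_allele = cascade$donor$hdr_allele),
    reason = cascade$reason,
    n_levels = n_levels(cascade),
    retargeting_efficiency_per_level = rep$retargeting_efficiency_per_level,
    is_recursive = rep$is_recursive,
    overall_rank_score = rep$overall_rank_score,
    levels = lapply(cascade$levels, function(entries) {
      lapply(entries, function(e) {
        list(label = e$label, guide_id = e$guide$guide_id,
             protospacer = e$guide$protospacer, pam = e$guide$pam,
             strand = e$guide$strand, cut_index = e$guide$cut_index,
             position = e$guide$position, on_target = e$guide$on_target,
             offtarget_hits = e$guide$offtarget_hits,
             retarget_score = e$retarget_score,
             targeted_mass = e$targeted_mass,
             targeted_alleles = as.list(e$targeted_alleles))
      })
    }))
}

#' Serialize a cascade to a JSON string
#'
#' Deterministic (byte-identical for identical inputs).
#'
#' @param cascade A `cascade`.
#' @return A JSON character scalar.
#' @export
cascade_json <- function(cascade) {
  as.character(jsonlite::toJSON(.cascade_to_list(cascade), auto_unbox = TRUE,
                                digits = NA, pretty = TRUE, null = "null"))
}

#' Flatten a cascade to one row per guide
#'
#' Columns: site, level, label, protospacer, pam, strand, cut, on_target,
#' offtarget_hits, targeted_mass, retarget_score, efficiency (the
#' retargeting efficiency from the guide's level into the next).
#'
#' @param x A `cascade`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.cascade <- function(x, ...) {
  rows <- list()
  site_id <- sprintf("%s:%d-%d", x$site$contig_id, x$site$start,
                     x$site$start + nchar(x$site$seq))
  for (lev in seq_along(x$levels)) {
    eff <- retargeting_efficiency(x, lev - 1L)
    for (e in x$levels[[lev]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = site_id, level = LETTERS[lev], label = e$label,
        protospacer = e$guide$protospacer, pam = e$guide$pam,
        strand = e$guide$strand, cut = e$guide$cut_index,
        on_target = e$guide$on_target,
        offtarget_hits = e$guide$offtarget_hits,
        targeted_mass = e$targeted_mass,
        retarget_score = e$retarget_score,
        efficiency = eff, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(data.frame())
  do.call(rbind, rows)
}

#' Write a cascade as JSON and flat TSV
#'
#' @param cascade A `cascade`.
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.json` and `<prefix>.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_cascade <- function(cascade, path_prefix) {
  jp <- paste0(path_prefix, ".json")
  tp <- paste0(path_prefix, ".tsv")
  writeLines(cascade_json(cascade), jp)
  utils::write.table(as.data.frame(cascade), tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = jp, tsv = tp))
}

#' @export
print.cascade <- function(x, ...) {
  if (n_levels(x) == 0L) {
    cat("<cascade> empty:", x$reason %||% "no levels", "\n")
    return(invisible(x))
  }
  cat(sprintf("<cascade> %s, %d level(s)\n", x$site$contig_id, n_levels(x)))
  for (lev in seq_along(x$levels)) {
    for (e in x$levels[[lev]]) {
      cat(sprintf("  %s %s|%s (%s) mass %.3f score %.3f\n", e$label,
                  e$guide$protospacer, e$guide$pam, e$guide$strand,
                  e$targeted_mass, e$retarget_score))
    }
  }
  invisible(x)
}

#' @export
print.site_report <- function(x, ...) {
  cat(sprintf("<site_report> %s, levels %d, eff[0] %.3f, recursive %s\n",
              x$cascade$site$contig_id, n_levels(x$cascade),
              x$retargeting_efficiency_per_level[1], x$is_recursive))
  invisible(x)
}
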