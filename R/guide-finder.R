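# SpCas9 guide candidate enumeration, scoring and filtering.
#
# Convention: 20-nt protospacer immediately 5' of an NGG PAM; blunt cut 3 nt
# 5' of the PAM, i.e. between protospacer positions 17 and 18. `cut_index`
# is the 0-based allele coordinate of the base immediately 3' of the cut on
# the `+` strand, so a 23-nt window that is exactly one protospacer+NGG on
# the `+` strand has `cut_index = 17`.

.new_guide <- function(protospacer, pam, strand, cut_index, position,
                       on_target = NULL, offtarget_hits = NA_integer_,
                       guide_id = NULL) {
  if (is.null(on_target)) on_target <- score_on_target(protospacer)
  if (is.null(guide_id))
    guide_id <- sprintf("g%s%d", if (strand == "+") "p" else "m", position)
  structure(list(guide_id = guide_id, protospacer = protospacer, pam = pam,
                 strand = strand, cut_index = as.integer(cut_index),
                 position = as.integer(position), on_target = on_target,
                 offtarget_hits = offtarget_hits),
            class = "guide_candidate")
}

#' Filtering thresholds for guide candidates
#'
#' @param min_on_target Minimum on-target efficacy score. Default 0.5.
#' @param max_offtarget_hits Maximum allowed off-target sites (counted at up
#'   to `mm_max` mismatches, intended site excluded). Default 0.
#' @param mm_max Mismatch radius for off-target counting. Default 2.
#' @param proximity_bp Maximum distance from a retargeting guide's cut to
#'   the prior edit, bp. Default 10.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_on_target = 0.5, max_offtarget_hits = 0L,
                          mm_max = 2L, proximity_bp = 10L) {
  stopifnot(min_on_target >= 0, min_on_target <= 1,
            max_offtarget_hits >= 0L, mm_max >= 0L, proximity_bp >= 0L)
  structure(list(min_on_target = min_on_target,
                 max_offtarget_hits = as.integer(max_offtarget_hits),
                 mm_max = as.integer(mm_max),
                 proximity_bp = as.integer(proximity_bp)),
            class = "filter_config")
}

#' Enumerate all SpCas9 guide candidates on an allele
#'
#' Finds every 20-mer followed by an NGG PAM on both strands, with the cut
#' site mapped to `+`-strand allele coordinates. Candidates are ordered by
#' position, then strand (`+` before `-`).
#'
#' @param allele_seq Allele DNA sequence (or an [allele] / [sequence_window]).
#' @return List of `guide_candidate` objects (possibly empty).
#' @export
enumerate_guides <- function(allele_seq) {
  if (inherits(allele_seq, "allele") || inherits(allele_seq, "sequence_window"))
    allele_seq <- allele_seq$seq
  .check_dna(allele_seq)
  L <- nchar(allele_seq)
  out <- list()
  if (L < 23L) return(out)

  for (p1 in find_all0("GG", allele_seq)) {     # 0-based GG start = pam+1
    p0 <- p1 - 1L                               # 0-based PAM start
    if (p0 < 20L || p0 + 3L > L) next
    out[[length(out) + 1L]] <- .new_guide(
      protospacer = subseq0(allele_seq, p0 - 20L, p0),
      pam = subseq0(allele_seq, p0, p0 + 3L),
      strand = "+", cut_index = p0 - 3L, position = p0 - 20L)
  }
  for (q in find_all0("CC", allele_seq)) {      # PAM as CCN on + strand
    if (q + 23L > L) next
    out[[length(out) + 1L]] <- .new_guide(
      protospacer = revcomp(subseq0(allele_seq, q + 3L, q + 23L)),
      pam = revcomp(subseq0(allele_seq, q, q + 3L)),
      strand = "-", cut_index = q + 6L, position = q)
  }
  pos <- vapply(out, `[[`, 0L, "position")
  strand <- vapply(out, `[[`, "", "strand")
  out[order(pos, strand != "+")]
}

#' On-target efficacy heuristic
#'
#' Bundled heuristic in `[0, 1]`:
#' `0.6 + 0.2*[0.40 <= GC <= 0.70] - 0.2*[homopolymer >= 5]
#'  - 0.2*[protospacer ends "TT" before the PAM]`, clipped to `[0, 1]`.
#' Pluggable: any scorer taking a protospacer and returning `[0, 1]` can be
#' substituted where guides are constructed.
#'
#' @param g A `guide_candidate` or a 20-nt protospacer string.
#' @return Numeric score in `[0, 1]`.
#' @export
score_on_target <- function(g) {
  s <- if (inherits(g, "guide_candidate")) g$protospacer else g
  .check_dna(s, "protospacer")
  gc <- gc_fraction(s)
  score <- 0.6 +
    0.2 * (gc >= 0.40 && gc <= 0.70) -
    0.2 * has_homopolymer(s, 5L) -
    0.2 * endsWith(s, "TT")
  min(max(score, 0), 1)
}

# ---- background index for off-target search --------------------------------

#' Build a background index for off-target counting
#'
#' @param background Named character vector of contig sequences, a
#'   `DNAStringSet`, or an existing index (returned unchanged).
#' @return An object of class `bg_index`.
#' @export
bg_index <- function(background) {
  if (inherits(background, "bg_index")) return(background)
  if (methods::is(background, "DNAStringSet")) {
    seqs <- as.character(background)
  } else {
    stopifnot(is.character(background))
    seqs <- toupper(background)
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  structure(list(seqs = seqs,
                 dss = Biostrings::DNAStringSet(seqs)),
            class = "bg_index")
}

#' Count off-target sites of a guide in a background
#'
#' Exhaustively counts positions on both strands of the background whose
#' 20-mer lies within `mm_max` mismatches (Hamming distance, no bulges) of
#' the protospacer and is followed by an NGG PAM. One perfect-match
#' occurrence (the intended on-target site) is excluded when present.
#'
#' @param g A `guide_candidate`.
#' @param background Background sequences (see [bg_index]).
#' @param mm_max Maximum mismatches counted.
#' @return Integer count of off-target sites.
#' @export
count_offtargets <- function(g, background, mm_max = 2L) {
  idx <- bg_index(background)
  proto <- Biostrings::DNAString(g$protospacer)
  hits <- 0L; perfect <- 0L

  plus <- Biostrings::vmatchPattern(proto, idx$dss, max.mismatch = mm_max,
                                    fixed = TRUE)
  for (ci in seq_along(plus)) {
    seq <- idx$seqs[[ci]]; L <- nchar(seq)
    for (st in BiocGenerics::start(plus[[ci]])) {   # 1-based protospacer start
      pam0 <- st + 19L                              # 0-based PAM start
      if (pam0 + 3L > L) next
      if (subseq0(seq, pam0 + 1L, pam0 + 3L) != "GG") next
      hits <- hits + 1L
      if (subseq0(seq, st - 1L, st + 19L) == g$protospacer)
        perfect <- perfect + 1L
    }
  }
  rcproto <- Biostrings::reverseComplement(proto)
  minus <- Biostrings::vmatchPattern(rcproto, idx$dss, max.mismatch = mm_max,
                                     fixed = TRUE)
  rcp <- as.character(rcproto)
  for (ci in seq_along(minus)) {
    seq <- idx$seqs[[ci]]
    for (st in BiocGenerics::start(minus[[ci]])) {  # 1-based rc(proto) start
      q <- st - 4L                                  # 0-based CCN PAM start
      if (q < 0L) next
      if (subseq0(seq, q, q + 2L) != "CC") next
      hits <- hits + 1L
      if (subseq0(seq, st - 1L, st + 19L) == rcp)
        perfect <- perfect + 1L
    }
  }
  hits - min(perfect, 1L)
}

#' Locate exact guide target sites on a sequence
#'
#' @param g A `guide_candidate` (or protospacer string).
#' @param seq DNA sequence to search.
#' @return Data frame with columns `position`, `strand`, `cut_index`
#'   (0-based allele coordinates), one row per exact protospacer+NGG site.
#' @export
find_guide_sites <- function(g, seq) {
  proto <- if (inherits(g, "guide_candidate")) g$protospacer else g
  L <- nchar(seq)
  pat <- paste0(proto, "[ACGT]GG")
  plus <- find_all0(pat, seq, fixed = FALSE)
  rcpat <- paste0("CC[ACGT]", revcomp(proto))
  minus <- find_all0(rcpat, seq, fixed = FALSE)
  data.frame(
    position = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    cut_index = c(plus + 17L, minus + 6L),
    stringsAsFactors = FALSE)[order(c(plus, minus)), , drop = FALSE]
}

#' Does a guide target an allele?
#'
#' Targeting is defined by sequence: `TRUE` iff the protospacer followed by
#' an NGG PAM occurs exactly (0 mismatches) in the allele on either strand.
#'
#' @param g A `guide_candidate`.
#' @param allele An [allele], [sequence_window], [donor_spec] (its HDR
#'   allele), or DNA string.
#' @return Logical.
#' @export
matches_allele <- function(g, allele) {
  seq <- if (inherits(allele, "allele") || inherits(allele, "sequence_window"))
    allele$seq
  else if (inherits(allele, "donor_spec")) allele$hdr_allele
  else allele
  nrow(find_guide_sites(g, seq)) > 0L
}

# distance from a cut to an edit position or interval (0 when inside)
.edit_distance <- function(cut, edit) {
  if (length(edit) == 1L) edit <- c(edit, edit)
  if (cut >= edit[1] && cut <= edit[2]) return(0L)
  min(abs(cut - edit[1]), abs(cut - edit[2]))
}

#' Apply candidate filters to a guide
#'
#' A guide passes iff its on-target score and off-target count meet the
#' thresholds, it does not target the wildtype allele (retargeting levels
#' only; entry-level guides are exempt since they must cut wildtype), it
#' does not target the HDR donor allele, and its cut lies within
#' `proximity_bp` of the prior edit (when one is given).
#'
#' @param g A `guide_candidate` (with `on_target` and `offtarget_hits` set;
#'   `NA` off-target counts are treated as 0).
#' @param cfg A [filter_config].
#' @param wt Wildtype [allele] (or sequence) for the avoidance clause.
#' @param donor A [donor_spec]; its HDR allele must not be targeted.
#' @param prior_edit_pos Position or `c(lo, hi)` interval of the prior edit
#'   in the coordinates of the allele the guide was enumerated from.
#' @param level Recursion level of the guide, 0 = entry (wildtype-targeting).
#' @return Logical.
#' @export
passes_filters <- function(g, cfg = filter_config(), wt = NULL, donor = NULL,
                           prior_edit_pos = NULL, level = 1L) {
  ot <- g$on_target %||% score_on_target(g)
  if (ot < cfg$min_on_target) return(FALSE)
  oh <- g$offtarget_hits
  if (is.null(oh) || is.na(oh)) oh <- 0L
  if (oh > cfg$max_offtarget_hits) return(FALSE)
  if (level >= 1L && !is.null(wt) && matches_allele(g, wt)) return(FALSE)
  if (!is.null(donor) && matches_allele(g, donor)) return(FALSE)
  if (!is.null(prior_edit_pos) &&
      .edit_distance(g$cut_index, prior_edit_pos) > cfg$proximity_bp)
    return(FALSE)
  TRUE
}

#' @export
print.guide_candidate <- function(x, ...) {
  cat(sprintf("<guide> %s %s|%s (%s) cut %d on_target %.2f offtargets %s\n",
              x$guide_id, x$protospacer, x$pam, x$strand, x$cut_index,
              x$on_target, as.character(x$offtarget_hits)))
  invisible(x)
}
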