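# Domain types and the allele algebra: sequence windows, indel outcomes,
# alleles with lineage and frequency mass, and HDR donor specifications.

#' Create a sequence window
#'
#' A window of genomic sequence, the unit of input for cascade design.
#' Coordinates are 0-based half-open on the `+` strand of the source contig.
#'
#' @param contig_id Contig / chromosome name.
#' @param start 0-based start of the window on the contig.
#' @param seq Uppercase DNA string over `{A,C,G,T}`.
#' @param origin_strand `"+"` or `"-"`; strand the window was taken from.
#' @return An object of class `sequence_window`.
#' @export
sequence_window <- function(contig_id, start, seq, origin_strand = "+") {
  .check_dna(seq, "window sequence")
  stopifnot(is.character(contig_id), length(contig_id) == 1L,
            start >= 0, origin_strand %in% c("+", "-"))
  structure(list(contig_id = contig_id, start = as.integer(start),
                 seq = seq, origin_strand = origin_strand),
            class = "sequence_window")
}

#' Create an indel outcome
#'
#' One predicted repair product: a deletion span or an insertion sequence,
#' in 0-based allele coordinates. Insertions are anchored before `start`.
#'
#' @param kind `"deletion"` or `"insertion"`.
#' @param start 0-based start (deletion) or anchor (insertion) coordinate.
#' @param length Indel length in bp (`>= 1`).
#' @param inserted_seq Inserted bases; empty for deletions.
#' @param freq Predicted frequency in `(0, 1]`, conditional on the indel
#'   (non-HDR) repair channel.
#' @param label Display label; defaults to e.g. `"-4 bp del"` / `"+1 bp ins"`.
#' @return An object of class `indel_outcome`.
#' @export
indel_outcome <- function(kind = c("deletion", "insertion"), start, length,
                          inserted_seq = "", freq = 1, label = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start); length <- as.integer(length)
  stopifnot(start >= 0L, length >= 1L, freq > 0, freq <= 1)
  if (kind == "deletion" && nzchar(inserted_seq))
    stop("a deletion carries no inserted sequence", call. = FALSE)
  if (kind == "insertion") {
    .check_dna(inserted_seq, "inserted_seq")
    if (nchar(inserted_seq) != length)
      stop("insertion length must equal nchar(inserted_seq)", call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (kind == "deletion") sprintf("-%d bp del", length)
             else sprintf("+%d bp ins", length)
  }
  structure(list(kind = kind, start = start, length = length,
                 inserted_seq = inserted_seq, freq = freq, label = label),
            class = "indel_outcome")
}

#' Create an allele
#'
#' A concrete DNA sequence together with its lineage (ordered guide/outcome
#' events) and frequency mass, the product of conditional outcome
#' frequencies along the lineage (conditional on the indel channel).
#'
#' @param seq Allele DNA sequence.
#' @param lineage List of `list(guide_id=, outcome=)` events.
#' @param mass Mass in `[0, 1]`; the wildtype allele has mass 1.
#' @param last_edit Optional `c(lo, hi)` interval (allele coordinates) of the
#'   most recent edit; used for proximity filtering of retargeting guides.
#' @return An object of class `allele`.
#' @export
allele <- function(seq, lineage = list(), mass = 1, last_edit = NULL) {
  .check_dna(seq, "allele sequence")
  stopifnot(mass >= 0, mass <= 1)
  structure(list(seq = seq, lineage = lineage, level = length(lineage),
                 mass = mass, last_edit = last_edit),
            class = "allele")
}

#' @rdname allele
#' @export
wildtype_allele <- function(seq) allele(seq, lineage = list(), mass = 1)

# apply an indel to a bare sequence; shared by apply_outcome and donor_spec
.apply_indel <- function(seq, outcome) {
  L <- nchar(seq)
  if (outcome$kind == "deletion") {
    if (outcome$start + outcome$length > L)
      stop("coordinate error: deletion exceeds allele length", call. = FALSE)
    paste0(subseq0(seq, 0L, outcome$start),
           subseq0(seq, outcome$start + outcome$length, L))
  } else {
    if (outcome$start > L)
      stop("coordinate error: insertion anchor beyond allele length", call. = FALSE)
    paste0(subseq0(seq, 0L, outcome$start), outcome$inserted_seq,
           subseq0(seq, outcome$start, L))
  }
}

#' Apply an indel outcome to an allele
#'
#' Returns the child allele: edited sequence, extended lineage, incremented
#' level, and mass equal to `parent mass * outcome frequency`.
#'
#' @param allele Parent [allele].
#' @param guide_id Identifier of the guide whose cut produced the outcome.
#' @param outcome An [indel_outcome] with coordinates valid on the parent.
#' @return The child [allele].
#' @export
apply_outcome <- function(allele, guide_id, outcome) {
  stopifnot(inherits(allele, "allele"), inherits(outcome, "indel_outcome"))
  child_seq <- .apply_indel(allele$seq, outcome)
  if (outcome$kind == "deletion") {
    m <- microhomology_length(allele$seq, outcome)
    edit <- c(outcome$start, outcome$start + m)
  } else {
    edit <- c(outcome$start, outcome$start + outcome$length)
  }
  structure(list(seq = child_seq,
                 lineage = c(allele$lineage,
                             list(list(guide_id = guide_id, outcome = outcome))),
                 level = allele$level + 1L,
                 mass = allele$mass * outcome$freq,
                 last_edit = edit),
            class = "allele")
}

#' Canonicalize a deletion
#'
#' Microhomology makes deletions ambiguous: several equal-length spans can
#' yield the same child sequence. Returns the leftmost-aligned deletion that
#' produces the identical child; idempotent.
#'
#' @param seq Parent DNA sequence.
#' @param outcome A deletion [indel_outcome].
#' @return The canonical (leftmost) equivalent [indel_outcome].
#' @export
canonicalize_deletion <- function(seq, outcome) {
  stopifnot(inherits(outcome, "indel_outcome"), outcome$kind == "deletion")
  x <- charToRaw(seq)
  s <- outcome$start; d <- outcome$length
  if (s + d > length(x))
    stop("coordinate error: deletion exceeds sequence length", call. = FALSE)
  while (s > 0L && x[s] == x[s + d]) s <- s - 1L  # raw index i+1 <-> base i
  if (s == outcome$start) return(outcome)
  indel_outcome("deletion", start = s, length = d, freq = outcome$freq,
                label = outcome$label)
}

#' Microhomology length of a deletion
#'
#' The longest `m` such that the `m`-mer starting at the deletion start
#' equals the `m`-mer starting just past the deleted span:
#' `seq[start+i] == seq[start+length+i]` for all `i < m`. Deletions with
#' `m >= 3` bp correspond to the alt-EJ (microhomology-mediated) class.
#'
#' @inheritParams canonicalize_deletion
#' @return Integer microhomology length (0 for non-matching flanks).
#' @export
microhomology_length <- function(seq, outcome) {
  stopifnot(inherits(outcome, "indel_outcome"), outcome$kind == "deletion")
  x <- charToRaw(seq)
  s <- outcome$start; d <- outcome$length; L <- length(x)
  m <- 0L
  while (s + d + m < L && x[s + m + 1L] == x[s + d + m + 1L]) m <- m + 1L
  m
}

#' Merge alleles that converge to the same sequence
#'
#' Alleles are compared by exact sequence identity; lineages that converge
#' to the same sequence are merged by summing mass (a guide targets
#' sequences, not histories). The representative lineage is the one of the
#' highest-mass constituent. Result is ordered by mass descending, ties by
#' sequence, for determinism.
#'
#' @param alleles List of [allele] objects.
#' @return List of merged alleles.
#' @export
merge_alleles <- function(alleles) {
  if (length(alleles) == 0L) return(alleles)
  seqs <- vapply(alleles, `[[`, "", "seq")
  masses <- vapply(alleles, `[[`, 0, "mass")
  out <- lapply(split(seq_along(alleles), seqs), function(idx) {
    rep_i <- idx[which.max(masses[idx])]
    a <- alleles[[rep_i]]
    a$mass <- sum(masses[idx])
    a
  })
  m <- vapply(out, `[[`, 0, "mass")
  out[order(-m, names(out))]
}

#' Specify an HDR donor
#'
#' Describes an ssODN-style donor as the edit it installs relative to the
#' wildtype window, with homology arms flanking the edit. The derived
#' `hdr_allele` (wildtype with the edit applied) is what retargeting guides
#' are required to avoid.
#'
#' @param wt_seq Wildtype window sequence the donor edits.
#' @param edit An [indel_outcome] or a [substitution].
#' @param homology_arm_length Homology arm length in bp (default 45; donors
#'   are typically designed with 40-50 bp arms).
#' @return An object of class `donor_spec`.
#' @export
donor_spec <- function(wt_seq, edit, homology_arm_length = 45L) {
  .check_dna(wt_seq, "wildtype sequence")
  stopifnot(homology_arm_length >= 10L)
  if (inherits(edit, "indel_outcome")) {
    hdr <- .apply_indel(wt_seq, edit)
  } else if (inherits(edit, "substitution")) {
    if (subseq0(wt_seq, edit$position, edit$position + nchar(edit$ref)) != edit$ref)
      stop("substitution ref does not match the wildtype sequence", call. = FALSE)
    hdr <- paste0(subseq0(wt_seq, 0L, edit$position), edit$alt,
                  subseq0(wt_seq, edit$position + nchar(edit$ref), nchar(wt_seq)))
  } else stop("edit must be an indel_outcome or a substitution", call. = FALSE)
  structure(list(edit = edit,
                 homology_arm_length = as.integer(homology_arm_length),
                 hdr_allele = hdr),
            class = "donor_spec")
}

#' Single-base or multi-base substitution edit
#'
#' @param position 0-based position of the first substituted base.
#' @param ref Reference bases replaced.
#' @param alt Replacement bases (same length class not required).
#' @return An object of class `substitution`.
#' @export
substitution <- function(position, ref, alt) {
  .check_dna(ref, "ref"); .check_dna(alt, "alt")
  stopifnot(position >= 0L)
  structure(list(position = as.integer(position), ref = ref, alt = alt),
            class = "substitution")
}

#' @export
print.allele <- function(x, ...) {
  cat(sprintf("<allele> level %d, mass %.4g, %d bp\n", x$level, x$mass,
              nchar(x$seq)))
  if (x$level > 0L) {
    ev <- x$lineage[[x$level]]
    cat(sprintf("  last edit: %s by %s\n", ev$outcome$label, ev$guide_id))
  }
  invisible(x)
}
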