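# Bundled indel-outcome model and the predictor adapter seam.
#
# The bundled model is deterministic and hand-computable: deletions are
# enumerated exhaustively around the cut and scored by microhomology and
# length, and cut-adjacent duplications supply the insertion classes. It is
# a documented stand-in, at desk scale, for machine-learned repair-outcome
# predictors; any external predictor can be registered by name and must
# return a distribution satisfying the same invariants.

#' Parameters of the bundled outcome model
#'
#' @param lambda_del Deletion-length decay scale in bp: a deletion of length
#'   `d` is down-weighted by `exp(-d/lambda_del)`. Default 10.
#' @param beta_ins1 Raw weight of the +1 duplication of the base 5' of the
#'   cut. Default 3.0.
#' @param beta_ins2 Raw weight of the +2 duplication of the dinucleotide 5'
#'   of the cut. Default 0.3.
#' @param d_max Maximum deletion length enumerated, bp. Default 30.
#' @param mh_max Microhomology length cap used in scoring. Default 15.
#' @param min_report_freq Outcomes below this frequency are pooled into
#'   `truncated_mass`. Default 0.01.
#' @return An object of class `predictor_params`.
#' @export
predictor_params <- function(lambda_del = 10, beta_ins1 = 3.0, beta_ins2 = 0.3,
                             d_max = 30L, mh_max = 15L, min_report_freq = 0.01) {
  stopifnot(lambda_del > 0, beta_ins1 > 0, beta_ins2 >= 0,
            d_max >= 1L, mh_max >= 1L,
            min_report_freq >= 0, min_report_freq < 1)
  structure(list(lambda_del = lambda_del, beta_ins1 = beta_ins1,
                 beta_ins2 = beta_ins2, d_max = as.integer(d_max),
                 mh_max = as.integer(mh_max), min_report_freq = min_report_freq),
            class = "predictor_params")
}

# run lengths of TRUE ending at / starting at each index of a logical vector
.true_runs <- function(M) {
  r <- rle(M)
  ends <- cumsum(r$lengths)
  E <- integer(length(M)); S <- integer(length(M))
  pos <- 1L
  for (k in seq_along(r$lengths)) {
    idx <- pos:ends[k]
    if (r$values[k]) {
      E[idx] <- seq_along(idx)
      S[idx] <- rev(seq_along(idx))
    }
    pos <- ends[k] + 1L
  }
  list(ending = E, starting = S)
}

#' Predict the indel outcome distribution at a cut site
#'
#' Bundled model: (a) all canonical deletions of length `d <= d_max` whose
#' span covers or abuts the cut (`s <= cut <= s+d`) are enumerated and scored
#' `w = (1+m)^2 * exp(-d/lambda_del)`, where `m` is the microhomology length
#' of the canonical (leftmost) alignment, capped at `mh_max`; (b) the +1 and
#' +2 duplications of the sequence 5' of the cut are added with weights
#' `beta_ins1` and `beta_ins2`; (c) weights are normalized to frequencies;
#' (d) outcomes below `min_report_freq` are pooled into `truncated_mass`.
#' Frequencies are conditional on the indel (non-HDR) repair channel.
#' Deterministic.
#'
#' @param allele_seq Allele DNA sequence (the full design window).
#' @param cut_index 0-based cut position: the blunt cut falls between bases
#'   `cut_index - 1` and `cut_index`. Must be at least 5 bp from each edge.
#' @param params A [predictor_params] object.
#' @return An object of class `outcome_distribution` with fields
#'   `cut_index`, `outcomes` (list of [indel_outcome], frequency-sorted),
#'   `freqs`, and `truncated_mass`.
#' @export
predict_outcomes <- function(allele_seq, cut_index,
                             params = predictor_params()) {
  .check_dna(allele_seq)
  L <- nchar(allele_seq)
  cut_index <- as.integer(cut_index)
  if (cut_index < 5L || cut_index > L - 5L)
    stop("window error: cut site must be at least 5 bp from the window edge",
         call. = FALSE)
  x <- charToRaw(allele_seq)
  starts <- integer(0); dels <- integer(0); mhs <- integer(0)

  for (d in seq_len(min(params$d_max, L - 1L))) {
    lo <- max(0L, cut_index - d)
    hi <- min(cut_index, L - d)
    if (lo > hi) next
    M <- x[seq_len(L - d)] == x[seq.int(1L + d, L)]  # M[i+1]: seq[i]==seq[i+d]
    runs <- .true_runs(M)
    s_all <- lo:hi
    ext <- ifelse(s_all >= 1L, runs$ending[pmax(s_all, 1L)], 0L)
    s0 <- s_all - ext                         # leftmost-equivalent start
    keep <- !duplicated(s0)
    s0 <- s0[keep]
    m <- ifelse(s0 + 1L <= L - d, runs$starting[pmin(s0 + 1L, L - d)], 0L)
    m[s0 + 1L > L - d] <- 0L
    starts <- c(starts, s0)
    dels <- c(dels, rep.int(d, length(s0)))
    mhs <- c(mhs, m)
  }

  w_del <- (1 + pmin(mhs, params$mh_max))^2 * exp(-dels / params$lambda_del)

  ins_seq1 <- subseq0(allele_seq, cut_index - 1L, cut_index)
  ins_seq2 <- subseq0(allele_seq, cut_index - 2L, cut_index)
  kind <- c(rep("deletion", length(starts)), "insertion", "insertion")
  start_all <- c(starts, cut_index, cut_index)
  len_all <- c(dels, 1L, 2L)
  ins_all <- c(rep("", length(starts)), ins_seq1, ins_seq2)
  w_all <- c(w_del, params$beta_ins1, params$beta_ins2)

  keep <- w_all > 0
  kind <- kind[keep]; start_all <- start_all[keep]; len_all <- len_all[keep]
  ins_all <- ins_all[keep]; w_all <- w_all[keep]

  freq <- w_all / sum(w_all)
  retained <- freq >= params$min_report_freq
  truncated_mass <- sum(freq[!retained])

  kind <- kind[retained]; start_all <- start_all[retained]
  len_all <- len_all[retained]; ins_all <- ins_all[retained]
  freq <- freq[retained]

  # deterministic order: freq desc, shorter indel first, then child sequence
  child <- character(length(freq))
  for (i in seq_along(freq)) {
    child[i] <- if (kind[i] == "deletion")
      paste0(subseq0(allele_seq, 0L, start_all[i]),
             subseq0(allele_seq, start_all[i] + len_all[i], L))
    else
      paste0(subseq0(allele_seq, 0L, start_all[i]), ins_all[i],
             subseq0(allele_seq, start_all[i], L))
  }
  ord <- order(-freq, len_all, child)

  outcomes <- vector("list", length(ord))
  for (j in seq_along(ord)) {
    i <- ord[j]
    outcomes[[j]] <- indel_outcome(kind[i], start_all[i], len_all[i],
                                   inserted_seq = ins_all[i], freq = freq[i])
  }
  structure(list(cut_index = cut_index, outcomes = outcomes,
                 freqs = freq[ord], truncated_mass = truncated_mass),
            class = "outcome_distribution")
}

#' Validate an outcome distribution at the adapter seam
#'
#' Checks the invariants every predictor (bundled or external) must satisfy:
#' frequencies plus truncated mass sum to 1, outcomes are sorted by
#' frequency descending, and all deletions are canonical (leftmost-aligned)
#' on the given allele sequence.
#'
#' @param dist An `outcome_distribution`.
#' @param allele_seq Optional allele sequence for canonicality checks.
#' @param tol Numeric tolerance for the mass sum.
#' @return `dist`, invisibly; errors on violation.
#' @export
validate_distribution <- function(dist, allele_seq = NULL, tol = 1e-9) {
  stopifnot(inherits(dist, "outcome_distribution"))
  total <- sum(dist$freqs) + dist$truncated_mass
  if (abs(total - 1) > tol)
    stop("predictor contract violated: frequencies + truncated_mass != 1",
         call. = FALSE)
  if (is.unsorted(rev(dist$freqs)))
    stop("predictor contract violated: outcomes not sorted by frequency",
         call. = FALSE)
  if (!is.null(allele_seq)) {
    for (o in dist$outcomes) {
      if (o$kind == "deletion" &&
          canonicalize_deletion(allele_seq, o)$start != o$start)
        stop("predictor contract violated: non-canonical deletion", call. = FALSE)
    }
  }
  invisible(dist)
}

#' Take the top-k outcomes of a distribution
#'
#' Ties are broken deterministically: shorter indel first, then
#' lexicographic child sequence (the order the distribution is stored in).
#'
#' @param dist An `outcome_distribution`.
#' @param top_k Number of outcomes to return (`>= 1`).
#' @return List of [indel_outcome] objects.
#' @export
rank_outcomes <- function(dist, top_k) {
  stopifnot(inherits(dist, "outcome_distribution"), top_k >= 1L)
  utils::head(dist$outcomes, top_k)
}

#' Concentration of an outcome distribution
#'
#' Sum of the top-`n` outcome frequencies. Positions where initial editing
#' is predicted to yield a small number of highly abundant indels (high
#' concentration) are the entry points for retargeting.
#'
#' @inheritParams rank_outcomes
#' @param n Number of top outcomes to sum (`>= 1`).
#' @return Numeric in `[0, 1]`.
#' @export
concentration <- function(dist, n) {
  stopifnot(inherits(dist, "outcome_distribution"), n >= 1L)
  sum(utils::head(dist$freqs, n))
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat(sprintf("<outcome_distribution> cut %d: %d outcomes, truncated %.3f\n",
              x$cut_index, length(x$outcomes), x$truncated_mass))
  for (o in utils::head(x$outcomes, 6L))
    cat(sprintf("  %-12s freq %.3f\n", o$label, o$freq))
  invisible(x)
}

# ---- predictor registry ----------------------------------------------------

.predictors <- new.env(parent = emptyenv())

#' Register or fetch an outcome predictor by name
#'
#' A predictor is a function `f(allele_seq, cut_index, params)` returning an
#' `outcome_distribution`; its output is validated at the seam on every
#' call. `"bundled"` is always available. Adapters for external tools can be
#' registered under names such as `"lindel"` or `"indelphi"`.
#'
#' @param name Predictor name.
#' @param fun Predictor function (for `register_predictor`).
#' @return `get_predictor` returns a validated wrapper function.
#' @export
register_predictor <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = .predictors)
  invisible(name)
}

#' @rdname register_predictor
#' @export
get_predictor <- function(name = "bundled") {
  if (!exists(name, envir = .predictors))
    stop("unknown predictor: ", name, call. = FALSE)
  fun <- get(name, envir = .predictors)
  function(allele_seq, cut_index, params) {
    validate_distribution(fun(allele_seq, cut_index, params), allele_seq)
  }
}
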