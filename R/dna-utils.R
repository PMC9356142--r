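# Low-level DNA string helpers. All package-internal coordinates are
# 0-based half-open; insertions are anchored "before index start".

`%||%` <- function(x, y) if (is.null(x)) y else x

.check_dna <- function(seq, what = "sequence", allow_n = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (!grepl(pat, seq))
    stop(what, " must be an uppercase DNA string over {A,C,G,T}",
         if (allow_n) " (N allowed)" else "", call. = FALSE)
  invisible(seq)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of uppercase DNA strings (N allowed).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) chartr("ACGTN", "TGCAN", rawToChar(rev(charToRaw(s)))),
         character(1), USE.NAMES = FALSE)
}

# substring in 0-based half-open coordinates
subseq0 <- function(seq, start, end) substr(seq, start + 1L, end)

gc_fraction <- function(seq) {
  n <- nchar(seq)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / n
}

has_homopolymer <- function(seq, len = 5L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}", len, len, len, len), seq)
}

# overlapping occurrences (0-based start positions) of a fixed pattern
find_all0 <- function(pattern, seq, fixed = TRUE) {
  pat <- if (fixed) paste0("(?=", pattern, ")") else pattern
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
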