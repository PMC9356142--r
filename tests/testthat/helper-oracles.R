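# Independent brute-force oracles. These stay deliberately naive (nested
# loops, no shared code with the implementation) so they can vouch for it.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# every 20-mer + NGG on both strands, by direct inspection of each offset
oracle_enumerate <- function(seq) {
  L <- nchar(seq)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  rows <- list()
  for (i in seq_len(L - 22L)) {               # 1-based 23-mer start
    w <- substr(seq, i, i + 22L)
    if (substr(w, 22L, 23L) == "GG")
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
        strand = "+", position = i - 1L, cut_index = i - 1L + 17L,
        stringsAsFactors = FALSE)
    wr <- rc(w)
    if (substr(wr, 22L, 23L) == "GG")
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer = substr(wr, 1L, 20L), pam = substr(wr, 21L, 23L),
        strand = "-", position = i - 1L, cut_index = i - 1L + 6L,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), position = integer(0),
                      cut_index = integer(0)))
  df <- do.call(rbind, rows)
  df[order(df$position, df$strand != "+"), , drop = FALSE]
}

guides_as_df <- function(guides) {
  if (length(guides) == 0L)
    return(data.frame(protospacer = character(0), pam = character(0),
                      strand = character(0), position = integer(0),
                      cut_index = integer(0)))
  data.frame(
    protospacer = vapply(guides, `[[`, "", "protospacer"),
    pam = vapply(guides, `[[`, "", "pam"),
    strand = vapply(guides, `[[`, "", "strand"),
    position = vapply(guides, `[[`, 0L, "position"),
    cut_index = vapply(guides, `[[`, 0L, "cut_index"),
    stringsAsFactors = FALSE)
}

# Hamming-distance off-target scan, one position at a time
oracle_offtargets <- function(proto, background, mm_max) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  pv <- strsplit(proto, "")[[1]]
  hits <- 0L; perfect <- 0L
  for (seq in background) {
    L <- nchar(seq)
    for (i in seq_len(max(0L, L - 22L))) {
      w <- substr(seq, i, i + 22L)
      if (substr(w, 22L, 23L) == "GG") {
        mm <- sum(strsplit(substr(w, 1L, 20L), "")[[1]] != pv)
        if (mm <= mm_max) {
          hits <- hits + 1L
          if (mm == 0L) perfect <- perfect + 1L
        }
      }
      wr <- rc(w)
      if (substr(wr, 22L, 23L) == "GG") {
        mm <- sum(strsplit(substr(wr, 1L, 20L), "")[[1]] != pv)
        if (mm <= mm_max) {
          hits <- hits + 1L
          if (mm == 0L) perfect <- perfect + 1L
        }
      }
    }
  }
  hits - min(perfect, 1L)
}

# exhaustive deletion-score enumeration: every (start, length) span covering
# or abutting the cut, grouped by identical child sequence
oracle_del_scores <- function(seq, cut, lambda = 10, dmax = 30, mhmax = 15) {
  L <- nchar(seq)
  x <- strsplit(seq, "")[[1]]
  seen <- character(0)
  out <- list()
  for (d in seq_len(min(dmax, L - 1L))) {
    for (s in max(0L, cut - d):min(cut, L - d)) {
      child <- paste0(substr(seq, 1L, s), substr(seq, s + d + 1L, L))
      key <- paste0(d, ":", child)
      if (key %in% seen) next
      seen <- c(seen, key)
      s0 <- s
      while (s0 > 0L && x[s0] == x[s0 + d]) s0 <- s0 - 1L
      m <- 0L
      while (s0 + d + m < L && x[s0 + m + 1L] == x[s0 + d + m + 1L]) m <- m + 1L
      out[[length(out) + 1L]] <- data.frame(
        start = s0, length = d, mh = m,
        w = (1 + min(m, mhmax))^2 * exp(-d / lambda))
    }
  }
  do.call(rbind, out)
}
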