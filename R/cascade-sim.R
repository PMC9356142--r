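# Mass-flow simulator of multi-round editing for a cascade.
#
# Deterministic expectation dynamics over an allele population: no cell
# sampling, no RNP degradation, no target-site blocking. Each round, every
# allele targeted by an active guide loses `cut_efficiency` of its mass; a
# `hdr_fraction` share of the removed mass enters the absorbing HDR pool and
# the remainder is redistributed over the predictor's outcome distribution
# for that allele. Mass below the reporting cutoff of the predictor flows
# into an inert residual indel pool, so every round conserves total mass.

#' Simulator configuration
#'
#' @param cut_efficiency Probability a matched allele is cut in a round.
#'   Default 0.9.
#' @param hdr_fraction Fraction of repair events resolved by HDR when the
#'   donor is present. Default 0.25.
#' @param schedule `"sequential"` (one cascade level active per round, in
#'   order) or `"simultaneous"` (all levels active every round).
#' @param rounds_max Maximum number of rounds. Default 10.
#' @param min_mass Simultaneous schedule stops when the total targetable
#'   mass falls below this. Default 1e-4.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cut_efficiency = 0.9, hdr_fraction = 0.25,
                       schedule = c("sequential", "simultaneous"),
                       rounds_max = 10L, min_mass = 1e-4) {
  schedule <- match.arg(schedule)
  if (cut_efficiency < 0 || cut_efficiency > 1 ||
      hdr_fraction < 0 || hdr_fraction > 1 || rounds_max < 1L || min_mass < 0)
    stop("config error: probabilities must lie in [0,1] and rounds_max >= 1",
         call. = FALSE)
  structure(list(cut_efficiency = cut_efficiency, hdr_fraction = hdr_fraction,
                 schedule = schedule, rounds_max = as.integer(rounds_max),
                 min_mass = min_mass),
            class = "sim_config")
}

#' Simulate multi-round editing of a cascade
#'
#' @param cascade A non-empty `cascade` from [run_recursion].
#' @param cfg A [sim_config].
#' @param predictor Predictor name or function (defaults to the cascade's).
#' @return An object of class `sim_result`: a per-round `trajectory` data
#'   frame (`round`, `pool`, `mass`), final pool masses, and summary fields
#'   `hdr_mass`, `wt_mass`, `indel_mass`, `hdr_indel_ratio`.
#' @export
simulate_cascade <- function(cascade, cfg = sim_config(),
                             predictor = "bundled") {
  stopifnot(inherits(cascade, "cascade"))
  if (n_levels(cascade) == 0L)
    stop("cascade is empty; nothing to simulate", call. = FALSE)
  pred <- if (is.function(predictor)) predictor else get_predictor(predictor)
  params <- cascade$config$params

  guides <- list()
  for (lev in seq_along(cascade$levels))
    for (e in cascade$levels[[lev]])
      guides[[length(guides) + 1L]] <- list(guide = e$guide, level = lev,
                                            label = e$label)

  wt_seq <- cascade$site$seq
  HDR <- ".HDR"; RES <- ".RESIDUAL"
  pools <- stats::setNames(c(1, 0, 0), c(wt_seq, HDR, RES))
  display <- stats::setNames(c("WT", "HDR", "residual"), c(wt_seq, HDR, RES))
  n_named <- 0L

  label_of <- function(seq) {
    if (is.na(display[seq])) {
      n_named <<- n_named + 1L
      display[seq] <<- sprintf("allele%02d", n_named)
    }
    display[seq]
  }

  rows <- list()
  snapshot_rows <- function(round) {
    for (seq in names(pools)) {
      if (pools[[seq]] <= 0 && round > 0L) next
      rows[[length(rows) + 1L]] <<- data.frame(
        round = round, pool = label_of(seq), mass = pools[[seq]],
        stringsAsFactors = FALSE)
    }
  }
  snapshot_rows(0L)

  n_rounds <- if (cfg$schedule == "sequential")
    min(length(cascade$levels), cfg$rounds_max) else cfg$rounds_max

  for (r in seq_len(n_rounds)) {
    active <- if (cfg$schedule == "sequential")
      Filter(function(gi) gi$level == r, guides) else guides
    if (length(active) == 0L) break

    snap <- pools
    allele_seqs <- setdiff(names(snap)[snap > 0], c(HDR, RES))
    allele_seqs <- allele_seqs[order(display[allele_seqs])]

    targetable <- 0
    cut_plan <- list()
    for (seq in allele_seqs) {
      hit <- Filter(function(gi) matches_allele(gi$guide, seq), active)
      if (length(hit) == 0L) next
      targetable <- targetable + snap[[seq]]
      cut_plan[[seq]] <- hit[[1]]$guide        # first by level/label order
    }
    if (cfg$schedule == "simultaneous" && targetable < cfg$min_mass) break

    for (seq in names(cut_plan)) {
      g <- cut_plan[[seq]]
      mass <- snap[[seq]]
      removed <- cfg$cut_efficiency * mass
      if (removed <= 0) next
      pools[[seq]] <- pools[[seq]] - removed
      pools[[HDR]] <- pools[[HDR]] + cfg$hdr_fraction * removed
      rem <- (1 - cfg$hdr_fraction) * removed
      if (rem <= 0) next
      cut <- find_guide_sites(g, seq)$cut_index[1]
      if (cut < 5L || cut > nchar(seq) - 5L) {
        pools[[RES]] <- pools[[RES]] + rem
        next
      }
      dist <- pred(seq, cut, params)
      for (o in dist$outcomes) {
        child <- .apply_indel(seq, o)
        if (is.na(pools[child])) pools[child] <- 0
        pools[[child]] <- pools[[child]] + rem * o$freq
      }
      pools[[RES]] <- pools[[RES]] + rem * dist$truncated_mass
    }
    snapshot_rows(r)
  }

  traj <- do.call(rbind, rows)
  hdr <- pools[[HDR]]
  wt <- if (is.na(pools[wt_seq])) 0 else pools[[wt_seq]]
  indel <- max(0, sum(pools) - hdr - wt)
  ratio <- if (indel > 0) hdr / indel else if (hdr > 0) Inf else 0
  structure(list(trajectory = traj,
                 final = stats::setNames(as.numeric(pools),
                                         display[names(pools)]),
                 hdr_mass = hdr, wt_mass = wt, indel_mass = indel,
                 hdr_indel_ratio = ratio,
                 rounds = max(traj$round), config = cfg),
            class = "sim_result")
}

#' HDR:indel ratio of a simulation
#'
#' HDR mass divided by total indel mass at the final round; `Inf` when the
#' indel mass is zero but HDR mass is positive, 0 when HDR mass is zero.
#'
#' @param result A `sim_result`.
#' @return Numeric ratio.
#' @export
hdr_indel_ratio <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  result$hdr_indel_ratio
}

#' Write a simulation result as TSV (round, pool, mass) and JSON summary
#'
#' @param result A `sim_result`.
#' @param path_prefix Output path without extension.
#' @return Invisibly, the two paths.
#' @export
write_sim_result <- function(result, path_prefix) {
  tp <- paste0(path_prefix, ".tsv"); jp <- paste0(path_prefix, ".json")
  utils::write.table(result$trajectory, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summary <- list(rounds = result$rounds, hdr_mass = result$hdr_mass,
                  wt_mass = result$wt_mass, indel_mass = result$indel_mass,
                  hdr_indel_ratio = result$hdr_indel_ratio)
  writeLines(as.character(jsonlite::toJSON(summary, auto_unbox = TRUE,
                                           digits = NA)), jp)
  invisible(c(tsv = tp, json = jp))
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d round(s): HDR %.3f, WT %.3f, indels %.3f, HDR:indel %.3g\n",
    x$rounds, x$hdr_mass, x$wt_mass, x$indel_mass, x$hdr_indel_ratio))
  invisible(x)
}
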