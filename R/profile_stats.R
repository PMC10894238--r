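#' Editing-window, selectivity and context summary statistics
#'
#' Per-position profiles average the target-position efficiency over all
#' members whose target base sits at that position (replicates having been
#' averaged first). The editing window is the set of positions whose average
#' clears a fraction (default 20%) of the peak average; the C-versus-A
#' selectivity is the geometric mean over a position range (default 4-8) of
#' the ratio of average C->T to average A->G editing, with denominators
#' below the sequencing limit of detection floored at the LOD (0.1%) so
#' undetectable adenine editing yields a lower bound rather than infinity.
#'
#' @name profile_stats
NULL

#' Per-position average editing profile
#'
#' @param edits A `PositionEditMatrix` (replicate-aggregated).
#' @param library The `LibraryTable` the matrix was called against.
#' @param conversion Directed substitution, e.g. "C>T".
#' @param target_base Members whose target base equals this are averaged;
#'   defaults to the conversion's reference base.
#' @return An `AggregateProfile` data.frame: position, mean_pct, n_members.
#'   Positions with no members are omitted; an empty profile warns.
#' @export
position_profile <- function(edits, library, conversion = "C>T",
                             target_base = substr(conversion, 1L, 1L)) {
  members <- library[library$target_base == target_base, , drop = FALSE]
  if (nrow(members) == 0L) {
    warning(sprintf("no members with target base %s", target_base))
    out <- data.frame(position = integer(0), mean_pct = numeric(0),
                      n_members = integer(0))
    class(out) <- c("AggregateProfile", "data.frame")
    attr(out, "conversion") <- conversion
    return(out)
  }
  sel <- edits[edits$conversion == conversion &
                 edits$member_id %in% members$member_id &
                 !edits$low_coverage, , drop = FALSE]
  tp <- members$target_position[match(sel$member_id, members$member_id)]
  sel <- sel[sel$position == tp, , drop = FALSE]
  sel <- sel[!is.na(sel$efficiency_pct), , drop = FALSE]
  agg <- stats::aggregate(efficiency_pct ~ position, data = sel, FUN = mean)
  cnt <- stats::aggregate(efficiency_pct ~ position, data = sel, FUN = length)
  out <- data.frame(position = agg$position, mean_pct = agg$efficiency_pct,
                    n_members = cnt$efficiency_pct)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("AggregateProfile", "data.frame")
  attr(out, "conversion") <- conversion
  out
}

#' Build an AggregateProfile from bare position/value pairs
#'
#' Convenience for analytic inputs (ground-truth rates, worked examples).
#'
#' @param positions Integer protospacer positions.
#' @param values Average efficiencies (percent).
#' @param n_members Optional member counts.
#' @return An `AggregateProfile`.
#' @export
aggregate_profile <- function(positions, values, n_members = NA_integer_) {
  out <- data.frame(position = as.integer(positions), mean_pct = as.numeric(values),
                    n_members = n_members)
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  class(out) <- c("AggregateProfile", "data.frame")
  out
}

#' Editing window from a position profile
#'
#' The peak is the position with the highest average (ties to the smallest
#' position); positions whose average is at least `threshold` times the peak
#' average are above threshold; the reported window is the maximal contiguous
#' run of above-threshold positions containing the peak (contiguity over the
#' profile's scored positions).
#'
#' @param profile An `AggregateProfile`.
#' @param threshold Fraction of peak (default 0.20).
#' @return An `EditingWindow` list: threshold, peak_position, peak_value,
#'   window (contiguous positions), above_threshold (all qualifying
#'   positions).
#' @export
editing_window <- function(profile, threshold = 0.20) {
  if (nrow(profile) == 0L || all(is.na(profile$mean_pct)) ||
      max(profile$mean_pct, na.rm = TRUE) <= 0) {
    bep_data_error("editing window undefined: profile has no positive average")
  }
  pos <- profile$position
  val <- profile$mean_pct
  peak_i <- which(val == max(val, na.rm = TRUE))[1L]
  above <- which(!is.na(val) & val >= threshold * val[peak_i])
  # contiguous run (in protospacer coordinates) containing the peak
  above_pos <- pos[above]
  run <- pos[peak_i]
  repeat {
    lo <- min(run); hi <- max(run)
    grew <- FALSE
    if ((lo - 1L) %in% above_pos) { run <- c(lo - 1L, run); grew <- TRUE }
    if ((hi + 1L) %in% above_pos) { run <- c(run, hi + 1L); grew <- TRUE }
    if (!grew) break
  }
  structure(
    list(threshold = threshold,
         peak_position = pos[peak_i],
         peak_value = val[peak_i],
         window = sort(unique(run)),
         above_threshold = sort(above_pos)),
    class = "EditingWindow"
  )
}

#' @export
print.EditingWindow <- function(x, ...) {
  cat(sprintf("EditingWindow: positions %d-%d (peak %d at %.1f%%, threshold %.0f%% of peak)\n",
              min(x$window), max(x$window), x$peak_position, x$peak_value,
              100 * x$threshold))
  invisible(x)
}

#' C-versus-A selectivity: geometric mean of per-position ratios
#'
#' At each position the ratio of the average C->T efficiency to the average
#' A->G efficiency is formed; A-averages below the limit of detection are
#' floored at the LOD and flagged censored, making the geometric mean a
#' lower bound. A zero C-average makes that ratio 0 and the reported mean 0
#' with a warning.
#'
#' @param c_profile,a_profile `AggregateProfile`s for C->T and A->G.
#' @param positions Position range (default 4:8).
#' @param lod Limit of detection in percent (default 0.1).
#' @return A `SelectivityResult` list: positions, ratio (per position),
#'   censored (per position), geometric_mean, lower_bound flag.
#' @export
selectivity_ratio <- function(c_profile, a_profile, positions = 4:8,
                              lod = 0.1) {
  cpos <- match(positions, c_profile$position)
  apos <- match(positions, a_profile$position)
  if (any(is.na(cpos)) || any(is.na(apos))) {
    bep_validation_error("profiles do not cover requested positions %s",
                         paste(positions[is.na(cpos) | is.na(apos)], collapse = ","))
  }
  cv <- c_profile$mean_pct[cpos]
  av <- a_profile$mean_pct[apos]
  censored <- av < lod
  av_f <- pmax(av, lod)
  ratio <- cv / av_f
  if (any(ratio == 0)) {
    warning("zero C average at some position; geometric mean reported as 0")
    gm <- 0
  } else {
    gm <- exp(mean(log(ratio)))
  }
  structure(
    list(positions = positions, c_avg = cv, a_avg = av, ratio = ratio,
         censored = censored, lod = lod, geometric_mean = gm,
         lower_bound = any(censored)),
    class = "SelectivityResult"
  )
}

#' @export
print.SelectivityResult <- function(x, ...) {
  cat(sprintf("SelectivityResult: geometric mean C/A = %s%.1f-fold over positions %d-%d%s\n",
              if (x$lower_bound) ">= " else "", x$geometric_mean,
              min(x$positions), max(x$positions),
              if (x$lower_bound) " (LOD-censored lower bound)" else ""))
  invisible(x)
}

#' Per-context (5' x 3') efficiency matrix at one target position
#'
#' @param edits Replicate-aggregated `PositionEditMatrix`.
#' @param library `LibraryTable`.
#' @param position Target position to summarise.
#' @param conversion Directed substitution (default "C>T"); only members with
#'   the matching target base at `position` contribute.
#' @param normalize Divide by the maximum entry (default FALSE).
#' @return A `ContextMatrix` data.frame: flank5, flank3, efficiency (or
#'   normalized value), missing flag for absent contexts.
#' @export
context_matrix <- function(edits, library, position, conversion = "C>T",
                           normalize = FALSE) {
  tb <- substr(conversion, 1L, 1L)
  members <- library[library$target_base == tb &
                       library$target_position == position, , drop = FALSE]
  alphabet <- sort(unique(c(library$flank5, library$flank3)))
  grid <- expand.grid(flank3 = alphabet, flank5 = alphabet,
                      stringsAsFactors = FALSE)[, c("flank5", "flank3")]
  sel <- edits[edits$conversion == conversion & edits$position == position &
                 edits$member_id %in% members$member_id &
                 !edits$low_coverage & !is.na(edits$efficiency_pct), ,
               drop = FALSE]
  mi <- match(sel$member_id, members$member_id)
  key <- paste(members$flank5[mi], members$flank3[mi])
  eff <- tapply(sel$efficiency_pct, key, mean)
  grid$efficiency <- as.numeric(eff[paste(grid$flank5, grid$flank3)])
  grid$missing <- is.na(grid$efficiency)
  if (normalize) {
    mx <- max(grid$efficiency, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) grid$efficiency <- grid$efficiency / mx
  }
  class(grid) <- c("ContextMatrix", "data.frame")
  attr(grid, "position") <- position
  attr(grid, "conversion") <- conversion
  attr(grid, "normalized") <- normalize
  grid
}
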