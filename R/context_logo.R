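#' Kullback-Leibler context-preference logos
#'
#' For each side (5', 3') of the edited base, editing efficiency is summed
#' over all members whose flank on that side is a given base, across all
#' positions in the editing window, then normalised by the total editing over
#' all contexts, yielding a frequency per base. Letter heights are the
#' signed per-base information content f_b * log2(f_b / 0.25); their sum is
#' the Kullback-Leibler divergence from the uniform background and is
#' non-negative.
#'
#' @name context_logo
NULL

#' Editing-weighted flank-base frequencies over a window
#'
#' @param edits Replicate-aggregated `PositionEditMatrix`.
#' @param library `LibraryTable`.
#' @param window An `EditingWindow` or integer vector of positions.
#' @param side "5p" or "3p".
#' @param conversion Directed substitution (default "C>T"); only members with
#'   the matching target base contribute, via their own target-position
#'   efficiency.
#' @return Named numeric vector of frequencies over A, C, G, T summing to 1.
#' @export
context_frequencies <- function(edits, library, window, side = c("5p", "3p"),
                                conversion = "C>T") {
  side <- match.arg(side)
  positions <- if (inherits(window, "EditingWindow")) window$window else as.integer(window)
  if (length(positions) == 0L) bep_validation_error("window is empty")
  tb <- substr(conversion, 1L, 1L)
  members <- library[library$target_base == tb &
                       library$target_position %in% positions, , drop = FALSE]
  sel <- edits[edits$conversion == conversion &
                 edits$member_id %in% members$member_id &
                 !edits$low_coverage & !is.na(edits$efficiency_pct), ,
               drop = FALSE]
  mi <- match(sel$member_id, members$member_id)
  sel <- sel[sel$position == members$target_position[mi], , drop = FALSE]
  mi <- match(sel$member_id, members$member_id)
  flank <- if (side == "5p") members$flank5[mi] else members$flank3[mi]
  total <- sum(sel$efficiency_pct)
  if (!is.finite(total) || total <= 0) {
    bep_data_error("total editing over the window is zero; frequencies undefined")
  }
  sums <- vapply(DNA_BASES, function(b) sum(sel$efficiency_pct[flank == b]),
                 numeric(1))
  sums / total
}

#' Information content of flank-base frequencies
#'
#' @param frequencies Named numeric vector over A, C, G, T summing to 1
#'   (tolerance 1e-9).
#' @param background Background frequency per base (default 0.25).
#' @param log_base Logarithm base (default 2, bits).
#' @return A `LogoMatrix` data.frame: base, frequency, ic (signed letter
#'   height); `sum(ic)` is the KL divergence from background.
#' @export
information_content <- function(frequencies, background = 0.25, log_base = 2) {
  if (abs(sum(frequencies) - 1) > 1e-9) {
    bep_validation_error("frequencies must sum to 1 (got %.12f)", sum(frequencies))
  }
  if (background <= 0 || background >= 1) {
    bep_validation_error("background must lie in (0,1)")
  }
  f <- as.numeric(frequencies)
  ic <- ifelse(f > 0, f * log(f / background, base = log_base), 0)
  out <- data.frame(base = names(frequencies), frequency = f, ic = ic,
                    stringsAsFactors = FALSE)
  class(out) <- c("LogoMatrix", "data.frame")
  attr(out, "background") <- background
  attr(out, "log_base") <- log_base
  out
}

#' Two-sided context logo for a window
#'
#' Convenience wrapper computing [context_frequencies()] and
#' [information_content()] for both flanks.
#'
#' @inheritParams context_frequencies
#' @param background,log_base See [information_content()].
#' @return A `LogoMatrix` data.frame with a `side` column ("5p"/"3p").
#' @export
context_logo <- function(edits, library, window, conversion = "C>T",
                         background = 0.25, log_base = 2) {
  out <- do.call(rbind, lapply(c("5p", "3p"), function(s) {
    f <- context_frequencies(edits, library, window, s, conversion)
    m <- information_content(f, background, log_base)
    cbind(side = s, as.data.frame(m), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("LogoMatrix", "data.frame")
  attr(out, "background") <- background
  attr(out, "log_base") <- log_base
  out
}
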