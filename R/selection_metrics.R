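#' Directed-evolution bookkeeping: titers, enrichment, cumulative dilution
#'
#' Plaque-assay titers follow the quadrant formula
#' titer (PFU/ml) = plaques x dilution factor x 100; fold enrichment is the
#' output titer over the input titer after overnight propagation; cumulative
#' fold-dilution multiplies per-passage factors (discrete serial passaging)
#' and exp(rate x time) terms (continuous well-mixed lagoon washout),
#' accumulated in log10 space so campaign totals around 10^61 do not
#' overflow.
#'
#' @name selection_metrics
NULL

#' Plaque-assay titer
#' @param plaque_count Non-negative plaque count in the quadrant.
#' @param dilution_factor Positive dilution factor of that quadrant.
#' @return Titer in PFU/ml: `plaque_count * dilution_factor * 100`.
#' @examples
#' plaque_titer(5, 1e4)  # 5e6
#' @export
plaque_titer <- function(plaque_count, dilution_factor) {
  if (any(plaque_count < 0)) bep_validation_error("plaque_count must be >= 0")
  if (any(dilution_factor <= 0)) bep_validation_error("dilution_factor must be > 0")
  plaque_count * dilution_factor * 100
}

#' Phage fold enrichment
#' @param output_titer Titer of propagated phage (PFU/ml).
#' @param input_titer Titer of input phage (PFU/ml), must be > 0.
#' @return `output_titer / input_titer`.
#' @export
fold_enrichment <- function(output_titer, input_titer) {
  if (any(input_titer <= 0)) {
    bep_stop("fold enrichment undefined for input titer <= 0",
             "bep_validation_error")
  }
  output_titer / input_titer
}

#' Define a dilution campaign
#'
#' @param segments List of segments; each is a list with `type` "discrete"
#'   (field `factors`: per-passage fold dilutions, all >= 1) or "continuous"
#'   (fields `rate`: lagoon volumes/hour, `duration`: hours, both >= 0;
#'   vectors describe a piecewise-constant schedule).
#' @param label Campaign label.
#' @return A `DilutionCampaign` object.
#' @export
dilution_campaign <- function(segments, label = "") {
  for (s in segments) {
    if (!is.list(s) || is.null(s$type)) {
      bep_validation_error("each segment needs a 'type' field")
    }
    if (s$type == "discrete") {
      if (is.null(s$factors) || any(s$factors < 1)) {
        bep_validation_error("discrete segment fold dilutions must all be >= 1")
      }
    } else if (s$type == "continuous") {
      if (is.null(s$rate) || is.null(s$duration) ||
          any(s$rate < 0) || any(s$duration < 0) ||
          length(s$rate) != length(s$duration)) {
        bep_validation_error("continuous segment needs rate, duration >= 0 of equal length")
      }
    } else {
      bep_validation_error("segment type must be 'discrete' or 'continuous'")
    }
  }
  structure(list(segments = segments, label = label),
            class = "DilutionCampaign")
}

segment_log10_fold <- function(s) {
  if (s$type == "discrete") sum(log10(s$factors))
  else sum(s$rate * s$duration) / log(10)
}

#' Cumulative fold-dilution across campaigns
#'
#' @param campaigns A `DilutionCampaign`, or a list of them (e.g. the serial
#'   passaging phases and continuous-evolution segments of one evolution
#'   effort).
#' @return List: `log10_total`, `total` (may be Inf if > ~1e308; use the
#'   log), and `per_campaign` data.frame (label, log10_fold).
#' @export
cumulative_fold_dilution <- function(campaigns) {
  if (inherits(campaigns, "DilutionCampaign")) campaigns <- list(campaigns)
  logs <- vapply(campaigns, function(cmp) {
    stopifnot(inherits(cmp, "DilutionCampaign"))
    sum(vapply(cmp$segments, segment_log10_fold, numeric(1)))
  }, numeric(1))
  labels <- vapply(campaigns, `[[`, character(1), "label")
  list(log10_total = sum(logs),
       total = 10^sum(logs),
       per_campaign = data.frame(label = labels, log10_fold = logs,
                                 stringsAsFactors = FALSE))
}

#' Read a dilution campaign YAML file
#'
#' Expected structure: a top-level `campaigns` list, each with `label` and
#' `segments` as in [dilution_campaign()].
#'
#' @param path YAML file path.
#' @return List of `DilutionCampaign` objects.
#' @export
read_campaign_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$campaigns)) bep_validation_error("campaign file lacks 'campaigns'")
  lapply(y$campaigns, function(cmp) {
    dilution_campaign(cmp$segments, label = if (is.null(cmp$label)) "" else cmp$label)
  })
}
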