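#' Synthetic amplicon read simulation with known ground truth
#'
#' Reads are full-amplicon, single-end and fixed length. Per read, the target
#' conversion (C->T on C members, A->G on A members) is an independent
#' Bernoulli(p_target) event at the member's target position; residual
#' cross-conversions (A->G on C members and vice versa) are independent
#' Bernoulli(p_cross) events at every protospacer position carrying the
#' opposite base; sequencing substitution errors are Bernoulli(e) per base
#' with a uniform alternative base. Base qualities are constant so that
#' quality filtering is exercised by explicit fixtures rather than noise.
#'
#' @name synthetic_reads
NULL

#' Create a read-simulation configuration
#'
#' @param p_target Target conversion rate in \[0,1\]; either a scalar applied
#'   to every member or a named vector of per-member rates (names are
#'   member_ids; unnamed members fall back to the scalar default 0).
#' @param p_cross Cross-conversion (opposite-base) rate in \[0,1\].
#' @param error_rate Per-base sequencing substitution error rate in \[0,1\].
#' @param depth Reads per member per replicate (>= 0).
#' @param replicates Number of replicates (>= 1).
#' @param quality Constant Phred base quality (default 30).
#' @param indel_rate Per-read probability of a 1-base deletion, to exercise
#'   the caller's indel-exclusion path (default 0).
#' @param seed Integer seed governing all randomness.
#' @return A `ReadSimConfig` object.
#' @export
read_sim_config <- function(p_target = 0.9, p_cross = 0, error_rate = 0,
                            depth = 100L, replicates = 1L, quality = 30L,
                            indel_rate = 0, seed = 1L) {
  for (nm in c("p_cross", "error_rate", "indel_rate")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      bep_validation_error("%s must be a single value in [0,1]", nm)
    }
  }
  if (any(is.na(p_target)) || any(p_target < 0) || any(p_target > 1)) {
    bep_validation_error("p_target values must lie in [0,1]")
  }
  if (depth < 0L) bep_validation_error("depth must be >= 0")
  if (replicates < 1L) bep_validation_error("replicates must be >= 1")
  structure(
    list(p_target = p_target, p_cross = p_cross, error_rate = error_rate,
         depth = as.integer(depth), replicates = as.integer(replicates),
         quality = as.integer(quality), indel_rate = indel_rate,
         seed = as.integer(seed)),
    class = "ReadSimConfig"
  )
}

member_p_target <- function(config, member_ids) {
  p <- config$p_target
  if (is.null(names(p))) {
    if (length(p) == 1L) return(rep(p, length(member_ids)))
    if (length(p) == length(member_ids)) return(as.numeric(p))
    bep_validation_error("unnamed p_target must be scalar or one per member")
  }
  out <- rep(0, length(member_ids))
  hit <- match(member_ids, names(p))
  out[!is.na(hit)] <- p[hit[!is.na(hit)]]
  out
}

#' Expand a simulation config into an explicit ground-truth rate table
#'
#' One row per (member, protospacer position, conversion) with the generating
#' rate the simulator uses: the target conversion at the target position, and
#' the cross conversion at every protospacer position carrying the opposite
#' base (rows only emitted when p_cross > 0).
#'
#' @param config A [read_sim_config()].
#' @param library A `LibraryTable`.
#' @return `GroundTruth` data.frame: member_id, position, conversion
#'   ("C>T"/"A>G"), rate.
#' @export
expand_ground_truth <- function(config, library) {
  stopifnot(inherits(config, "ReadSimConfig"))
  p_tgt <- member_p_target(config, library$member_id)
  rows <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    tb <- library$target_base[i]
    conv <- if (tb == "C") "C>T" else "A>G"
    df <- data.frame(member_id = library$member_id[i],
                     position = library$target_position[i],
                     conversion = conv, rate = p_tgt[i],
                     stringsAsFactors = FALSE)
    if (config$p_cross > 0) {
      opp <- if (tb == "C") "A" else "C"
      opp_conv <- if (tb == "C") "A>G" else "C>T"
      pos <- which(str_chars(library$protospacer[i]) == opp)
      if (length(pos)) {
        df <- rbind(df, data.frame(member_id = library$member_id[i],
                                   position = pos, conversion = opp_conv,
                                   rate = config$p_cross,
                                   stringsAsFactors = FALSE))
      }
    }
    rows[[i]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("GroundTruth", "data.frame")
  out
}

converted_base <- function(from) c(C = "T", A = "G")[[from]]

#' Simulate amplicon sequencing reads from a library
#'
#' @param library A `LibraryTable` (nonempty).
#' @param config A [read_sim_config()].
#' @param outdir Optional directory; when given, one FASTQ per replicate plus
#'   a ground-truth TSV and a YAML config echo are written there.
#' @return List with `reads` (one `read_set` per replicate: seq, qual, id
#'   character vectors), `truth` (the [expand_ground_truth()] table) and
#'   `files` (paths, when written).
#' @export
simulate_reads <- function(library, config, outdir = NULL) {
  stopifnot(inherits(config, "ReadSimConfig"))
  if (nrow(library) == 0L) bep_validation_error("library is empty")
  layout <- attr(library, "layout")
  if (is.null(layout)) bep_data_error("library table carries no amplicon layout")
  truth <- expand_ground_truth(config, library)
  set.seed(config$seed)
  qchar <- rawToChar(as.raw(config$quality + 33L))
  reps <- vector("list", config$replicates)
  for (rep_i in seq_len(config$replicates)) {
    seqs <- vector("list", nrow(library))
    ids <- vector("list", nrow(library))
    for (i in seq_len(nrow(library))) {
      amp <- str_chars(library$amplicon[i])
      L <- length(amp)
      n <- config$depth
      if (n == 0L) { seqs[[i]] <- character(0); ids[[i]] <- character(0); next }
      mat <- matrix(amp, nrow = n, ncol = L, byrow = TRUE)
      tr <- truth[truth$member_id == library$member_id[i], , drop = FALSE]
      for (k in seq_len(nrow(tr))) {
        off <- layout$protospacer_offset + tr$position[k] - 1L
        from <- substr(tr$conversion[k], 1L, 1L)
        stopifnot(amp[off] == from)
        edited <- stats::runif(n) < tr$rate[k]
        mat[edited, off] <- converted_base(from)
      }
      if (config$error_rate > 0) {
        err <- matrix(stats::runif(n * L) < config$error_rate, n, L)
        idx <- which(err)
        if (length(idx)) {
          cur <- mat[idx]
          # uniform over the three alternatives: shift by 1..3 in base order
          shift <- sample.int(3L, length(idx), replace = TRUE)
          mat[idx] <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift) %% 4L) + 1L]
        }
      }
      rs <- apply(mat, 1L, paste, collapse = "")
      if (config$indel_rate > 0) {
        del <- which(stats::runif(n) < config$indel_rate)
        for (j in del) {
          cut <- sample.int(L, 1L)
          rs[j] <- paste0(substr(rs[j], 1L, cut - 1L), substr(rs[j], cut + 1L, L))
        }
      }
      seqs[[i]] <- rs
      ids[[i]] <- sprintf("%s/rep%d/%d", library$member_id[i], rep_i, seq_len(n))
    }
    seq_v <- unlist(seqs, use.names = FALSE)
    reps[[rep_i]] <- list(
      seq = seq_v,
      qual = vapply(nchar(seq_v), function(l) strrep(qchar, l), character(1)),
      id = unlist(ids, use.names = FALSE)
    )
    class(reps[[rep_i]]) <- "read_set"
  }
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fq <- character(config$replicates)
    for (rep_i in seq_len(config$replicates)) {
      fq[rep_i] <- file.path(outdir, sprintf("reads_rep%d.fastq", rep_i))
      write_fastq(reps[[rep_i]], fq[rep_i])
    }
    truth_path <- file.path(outdir, "ground_truth.tsv")
    write_tsv(truth, truth_path)
    cfg_path <- file.path(outdir, "sim_config.yaml")
    writeLines(yaml::as.yaml(unclass(config)), cfg_path)
    files <- c(fastq = fq, truth = truth_path, config = cfg_path)
  }
  list(reads = reps, truth = truth, files = files)
}

#' Write a read set as FASTQ
#' @param reads A `read_set` (seq, qual, id).
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  # writeXStringSet stores the qualities as a metadata column and then warns
  # about dropping metadata columns; that warning is spurious here
  withCallingHandlers(
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual)),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ path.
#' @return A `read_set` list (seq, qual, id).
#' @export
read_fastq <- function(path) {
  # the reader re-attaches qualities from the metadata column it warns about
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  out <- list(seq = as.character(x),
              qual = as.character(Biostrings::quality(x)),
              id = names(x))
  names(out$seq) <- names(out$qual) <- NULL
  class(out) <- "read_set"
  out
}

#' Position-tapered target conversion rates
#'
#' Gaussian taper of the target conversion rate around a peak protospacer
#' position, emulating an editor whose activity falls off away from the
#' window centre. Returns a named per-member p_target vector for
#' [read_sim_config()].
#'
#' @param library A `LibraryTable`.
#' @param peak Rate at the centre position.
#' @param center Peak protospacer position (default 6).
#' @param sd Gaussian width in positions (default 1.5).
#' @return Named numeric vector (names are member_ids).
#' @export
position_tapered_rates <- function(library, peak = 0.9, center = 6, sd = 1.5) {
  r <- peak * exp(-(library$target_position - center)^2 / (2 * sd^2))
  names(r) <- library$member_id
  r
}
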