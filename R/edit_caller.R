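#' Demultiplexing and per-position substitution quantification
#'
#' Reads are assigned to library members by the UMI barcode embedded at a
#' fixed amplicon offset, then compared gaplessly to the member's reference
#' amplicon. Reads whose length differs from the amplicon (the signature of
#' an indel in this fixed-length, single-end read model) are excluded from
#' substitution counting and reported as an indel fraction; positions with
#' base quality below Qmin are masked out of both numerator and denominator.
#' Efficiencies are percentages of contributing reads carrying a given
#' directed substitution at a given protospacer position.
#'
#' @name edit_caller
NULL

#' Demultiplex reads to library members by UMI
#'
#' Each read's UMI field is compared to all member UMIs; the read is assigned
#' to the unique member within `max_umi_mismatch`, and left unassigned (or
#' flagged ambiguous on a tie) otherwise. Exact matches are resolved by hash
#' lookup; only inexact UMIs fall back to a full Hamming scan, which the
#' brute-force oracle in the test-suite mirrors.
#'
#' @param reads A `read_set`.
#' @param library A `LibraryTable` with UMIs assigned.
#' @param max_umi_mismatch Maximum Hamming distance for assignment
#'   (default 1).
#' @return List: `member` (member_id per read, NA when unassigned), and
#'   counts `n_total`, `n_assigned`, `n_unassigned`, `n_ambiguous`
#'   (ambiguous reads are also counted in `n_unassigned`).
#' @export
demultiplex <- function(reads, library, max_umi_mismatch = 1L) {
  umis <- library$umi
  min_d <- if (nrow(library) > 1L) {
    min(hamming_to_refs(umis, umis)[upper.tri(diag(nrow(library)))])
  } else Inf
  if (min_d <= 2L * max_umi_mismatch) {
    bep_config_error(
      "UMI min pairwise distance %d must exceed 2 x max_umi_mismatch = %d",
      min_d, 2L * max_umi_mismatch)
  }
  layout <- attr(library, "layout")
  if (is.null(layout)) bep_data_error("library table carries no amplicon layout")
  k <- layout$umi_length
  umi_end <- layout$umi_offset + k - 1L
  n <- length(reads$seq)
  member <- rep(NA_character_, n)
  ambiguous <- logical(n)
  long_enough <- nchar(reads$seq) >= umi_end
  read_umi <- substr(reads$seq[long_enough], layout$umi_offset, umi_end)
  idx <- match(read_umi, umis)
  if (max_umi_mismatch > 0L) {
    inexact <- which(is.na(idx))
    if (length(inexact)) {
      d <- hamming_to_refs(read_umi[inexact], umis)
      best <- apply(d, 1L, min)
      for (r in seq_along(inexact)) {
        if (best[r] <= max_umi_mismatch) {
          hits <- which(d[r, ] == best[r])
          if (length(hits) == 1L) idx[inexact[r]] <- hits
          else ambiguous[which(long_enough)[inexact[r]]] <- TRUE
        }
      }
    }
  }
  member[long_enough] <- library$member_id[idx]
  list(member = member,
       n_total = n,
       n_assigned = sum(!is.na(member)),
       n_unassigned = sum(is.na(member)),
       n_ambiguous = sum(ambiguous))
}

#' Classify one read against its member's reference amplicon
#'
#' @param read_seq Read sequence.
#' @param read_qual Phred+33 quality string (same length), or NULL for
#'   no masking.
#' @param member One-row slice of a `LibraryTable`.
#' @param layout The library's amplicon layout.
#' @param qmin Minimum base quality; lower-quality positions are masked.
#' @param lowq_read_frac A read with more than this fraction of its bases
#'   below qmin is discarded as low-quality.
#' @return List with `status` ("ok", "indel" or "lowq") and, for ok reads,
#'   `calls`: data.frame (position, conversion) of protospacer substitutions,
#'   and `masked`: protospacer positions removed from the denominator.
#' @export
classify_read <- function(read_seq, read_qual = NULL, member, layout,
                          qmin = 20L, lowq_read_frac = 0.5) {
  if (!nzchar(read_seq)) bep_data_error("empty read")
  amp <- member$amplicon
  if (nchar(read_seq) != nchar(amp)) {
    return(list(status = "indel", calls = NULL, masked = integer(0)))
  }
  qual_ok <- rep(TRUE, nchar(read_seq))
  if (!is.null(read_qual)) {
    q <- utf8ToInt(read_qual) - 33L
    qual_ok <- q >= qmin
    if (mean(!qual_ok) > lowq_read_frac) {
      return(list(status = "lowq", calls = NULL, masked = integer(0)))
    }
  }
  rc <- utf8ToInt(read_seq)
  ac <- utf8ToInt(amp)
  plen <- nchar(member$protospacer)
  off <- layout$protospacer_offset
  proto_idx <- off:(off + plen - 1L)
  mism <- proto_idx[rc[proto_idx] != ac[proto_idx] & qual_ok[proto_idx]]
  calls <- if (length(mism)) {
    data.frame(
      position = mism - off + 1L,
      conversion = paste0(intToUtf8(ac[mism], multiple = TRUE), ">",
                          intToUtf8(rc[mism], multiple = TRUE)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(position = integer(0), conversion = character(0),
               stringsAsFactors = FALSE)
  }
  list(status = "ok", calls = calls,
       masked = which(!qual_ok[proto_idx]))
}

# Vectorised classification and counting for one member's read group.
# Returns per-position edited counts by conversion, denominators, and the
# read accounting.
classify_group <- function(seqs, quals, member, layout, qmin, lowq_read_frac) {
  plen <- nchar(member$protospacer)
  amp <- member$amplicon
  L <- nchar(amp)
  is_indel <- nchar(seqs) != L
  seqs_ok <- seqs[!is_indel]
  quals_ok <- quals[!is_indel]
  n_lowq <- 0L
  qual_pass <- NULL
  if (length(seqs_ok)) {
    qmat <- matrix(utf8ToInt(paste(quals_ok, collapse = "")) - 33L,
                   nrow = length(seqs_ok), ncol = L, byrow = TRUE)
    qual_pass <- qmat >= qmin
    lowq <- rowMeans(!qual_pass) > lowq_read_frac
    n_lowq <- sum(lowq)
    seqs_ok <- seqs_ok[!lowq]
    qual_pass <- qual_pass[!lowq, , drop = FALSE]
  }
  off <- layout$protospacer_offset
  proto_cols <- off:(off + plen - 1L)
  ref <- str_chars(member$protospacer)
  edited <- matrix(0L, nrow = plen, ncol = 3L)  # per position x alt rank
  alt_base <- matrix("", nrow = plen, ncol = 3L)
  for (p in seq_len(plen)) alt_base[p, ] <- setdiff(DNA_BASES, ref[p])
  denom <- integer(plen)
  if (length(seqs_ok)) {
    smat <- matrix(strsplit(paste(seqs_ok, collapse = ""), "", fixed = TRUE)[[1]],
                   nrow = length(seqs_ok), ncol = L, byrow = TRUE)
    pm <- smat[, proto_cols, drop = FALSE]
    qp <- qual_pass[, proto_cols, drop = FALSE]
    denom <- colSums(qp)
    for (p in seq_len(plen)) {
      obs <- pm[qp[, p], p]
      if (!length(obs)) next
      for (a in 1:3) edited[p, a] <- sum(obs == alt_base[p, a])
    }
  }
  list(edited = edited, alt_base = alt_base, denom = denom, ref = ref,
       n_indel = sum(is_indel), n_lowq = n_lowq,
       n_classified = length(seqs_ok))
}

#' Quantify per-position substitution frequencies for one member
#'
#' @param seqs,quals Character vectors of the member's assigned reads.
#' @param member One-row slice of a `LibraryTable`.
#' @param layout Amplicon layout.
#' @param qmin Minimum base quality.
#' @param min_reads Members with fewer classified reads are flagged
#'   low-coverage.
#' @param lod Efficiencies below this percentage are flagged below the
#'   sequencing limit of detection (default 0.1).
#' @param lowq_read_frac See [classify_read()].
#' @return List: `edits` long data.frame (member_id, position, conversion,
#'   edited, aligned, efficiency_pct, low_coverage, below_lod) and `counts`
#'   (total, indel, lowq, classified, indel_fraction).
#' @export
quantify <- function(seqs, quals, member, layout, qmin = 20L,
                     min_reads = 100L, lod = 0.1, lowq_read_frac = 0.5) {
  g <- classify_group(seqs, quals, member, layout, qmin, lowq_read_frac)
  plen <- length(g$ref)
  low_cov <- g$n_classified < min_reads
  rows <- data.frame(
    member_id = member$member_id,
    position = rep(seq_len(plen), each = 3L),
    conversion = paste0(rep(g$ref, each = 3L), ">", as.vector(t(g$alt_base))),
    edited = as.vector(t(g$edited)),
    aligned = rep(g$denom, each = 3L),
    stringsAsFactors = FALSE
  )
  rows$efficiency_pct <- ifelse(rows$aligned > 0,
                                100 * rows$edited / rows$aligned, NA_real_)
  rows$low_coverage <- low_cov
  rows$below_lod <- !is.na(rows$efficiency_pct) & rows$efficiency_pct < lod
  counts <- list(total = length(seqs), indel = g$n_indel, lowq = g$n_lowq,
                 classified = g$n_classified,
                 indel_fraction = if (length(seqs)) g$n_indel / length(seqs) else NA_real_)
  list(edits = rows, counts = counts)
}

#' Demultiplex, classify and quantify a read set against a library
#'
#' The one-call path from FASTQ-level reads to a long-format position/edit
#' matrix, with full read accounting.
#'
#' @param reads A `read_set` (or FASTQ path).
#' @param library A `LibraryTable`.
#' @param qmin,min_reads,lod,lowq_read_frac See [quantify()].
#' @param max_umi_mismatch See [demultiplex()].
#' @return A `PositionEditMatrix`: long data.frame over all members, with a
#'   `summary` attribute holding the read accounting (assigned, unassigned,
#'   ambiguous, indel, lowq per member and in total).
#' @export
call_edits <- function(reads, library, qmin = 20L, min_reads = 100L,
                       lod = 0.1, max_umi_mismatch = 1L,
                       lowq_read_frac = 0.5) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  layout <- attr(library, "layout")
  dmx <- demultiplex(reads, library, max_umi_mismatch)
  per_member <- vector("list", nrow(library))
  accounting <- data.frame(member_id = library$member_id,
                           assigned = 0L, indel = 0L, lowq = 0L,
                           classified = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(library))) {
    sel <- which(!is.na(dmx$member) & dmx$member == library$member_id[i])
    q <- quantify(reads$seq[sel], reads$qual[sel], library[i, ], layout,
                  qmin, min_reads, lod, lowq_read_frac)
    per_member[[i]] <- q$edits
    accounting$assigned[i] <- q$counts$total
    accounting$indel[i] <- q$counts$indel
    accounting$lowq[i] <- q$counts$lowq
    accounting$classified[i] <- q$counts$classified
  }
  edits <- do.call(rbind, per_member)
  rownames(edits) <- NULL
  class(edits) <- c("PositionEditMatrix", "data.frame")
  attr(edits, "summary") <- list(
    n_total = dmx$n_total, n_assigned = dmx$n_assigned,
    n_unassigned = dmx$n_unassigned, n_ambiguous = dmx$n_ambiguous,
    per_member = accounting,
    parameters = list(qmin = qmin, min_reads = min_reads, lod = lod,
                      max_umi_mismatch = max_umi_mismatch))
  edits
}

#' Average per-replicate edit matrices
#'
#' Unweighted mean of per-replicate efficiencies per (member, position,
#' conversion). Replicates in which a member is flagged low-coverage are
#' excluded from that member's mean and the member is flagged; members with
#' no valid replicate are dropped with a warning.
#'
#' @param matrices List of `PositionEditMatrix` objects sharing a library.
#' @return A `PositionEditMatrix` with `efficiency_pct` the replicate mean,
#'   `edited`/`aligned` summed over retained replicates, and
#'   `n_replicates`/`replicates_dropped` columns.
#' @export
aggregate_replicates <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  if (length(matrices) == 1L) {
    out <- matrices[[1]]
    out$n_replicates <- 1L
    out$replicates_dropped <- 0L
    return(out)
  }
  key0 <- with(matrices[[1]], paste(member_id, position, conversion))
  for (m in matrices[-1]) {
    if (!identical(with(m, paste(member_id, position, conversion)), key0)) {
      bep_data_error("replicate matrices do not share a library layout")
    }
  }
  eff <- do.call(cbind, lapply(matrices, `[[`, "efficiency_pct"))
  low <- do.call(cbind, lapply(matrices, `[[`, "low_coverage"))
  keep <- !low & !is.na(eff)
  n_kept <- rowSums(keep)
  eff[!keep] <- NA
  out <- matrices[[1]]
  out$efficiency_pct <- rowMeans(eff, na.rm = TRUE)
  out$efficiency_pct[n_kept == 0L] <- NA_real_
  out$edited <- rowSums(do.call(cbind, lapply(matrices, `[[`, "edited")) * keep)
  out$aligned <- rowSums(do.call(cbind, lapply(matrices, `[[`, "aligned")) * keep)
  out$low_coverage <- n_kept == 0L
  lodv <- attr(matrices[[1]], "summary")$parameters$lod
  if (is.null(lodv)) lodv <- 0.1
  out$below_lod <- !is.na(out$efficiency_pct) & out$efficiency_pct < lodv
  out$n_replicates <- n_kept
  out$replicates_dropped <- length(matrices) - n_kept
  dropped <- unique(out$member_id[n_kept == 0L])
  if (length(dropped)) {
    warning(sprintf("%d member(s) had no valid replicate and were excluded: %s",
                    length(dropped), paste(utils::head(dropped, 5L), collapse = ", ")))
    out <- out[!(out$member_id %in% dropped), ]
    rownames(out) <- NULL
  }
  class(out) <- c("PositionEditMatrix", "data.frame")
  out
}

#' Write an edit matrix as long-format TSV plus a JSON run summary
#' @param edits A `PositionEditMatrix` from [call_edits()].
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Invisibly, the file paths.
#' @export
write_edit_matrix <- function(edits, dir, prefix = "edits") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  write_tsv(as.data.frame(edits), tsv)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  s <- attr(edits, "summary")
  if (!is.null(s)) {
    jsonlite::write_json(s, js, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(c(tsv = tsv, summary = js))
}
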