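#' Combinatorial sequence-context substrate library design
#'
#' A context library places a target base (C or A) at chosen protospacer
#' positions and varies the bases immediately 5' and 3' of it over a flank
#' alphabet, one substrate per combination. Positions are 1-based along the
#' 20-nt protospacer with the PAM occupying positions 21-23. Each member is
#' tagged with a unique molecular identifier (UMI) barcode embedded in the
#' constant region of its amplicon, which is what the demultiplexer reads.
#'
#' @name library_design
NULL

#' Create a context library specification
#'
#' @param target_bases Character vector, subset of `c("A", "C")`: which target
#'   bases to enumerate.
#' @param positions Integer vector of 1-based protospacer positions (1..20) at
#'   which the target base is placed. May be empty (empty library).
#' @param flank_alphabet Ordered bases used for the variable 5' and 3'
#'   contexts. Default all four bases.
#' @param umi_length UMI barcode length in nt (default 10).
#' @param protospacer_length Protospacer length (fixed at 20 for SpCas9).
#' @param pam Three-base PAM placed immediately 3' of the protospacer
#'   (default "TGG", an NGG representative with an A/C-free N).
#' @return A `ContextLibrarySpec` object.
#' @examples
#' context_library_spec(target_bases = c("A", "C"), positions = 6)
#' @export
context_library_spec <- function(target_bases = c("A", "C"),
                                 positions = 6L,
                                 flank_alphabet = c("A", "C", "G", "T"),
                                 umi_length = 10L,
                                 protospacer_length = 20L,
                                 pam = "TGG") {
  target_bases <- unique(as.character(target_bases))
  if (!all(target_bases %in% c("A", "C"))) {
    bep_validation_error("target_bases must be a subset of {A, C}")
  }
  positions <- as.integer(positions)
  if (length(positions) && (any(is.na(positions)) ||
                            any(positions < 1L | positions > protospacer_length))) {
    bep_validation_error("positions must lie in [1, %d]", protospacer_length)
  }
  flank_alphabet <- as.character(flank_alphabet)
  if (length(flank_alphabet) == 0L) {
    bep_validation_error("flank_alphabet must be nonempty")
  }
  if (anyDuplicated(flank_alphabet)) {
    bep_validation_error("flank_alphabet must not contain duplicates")
  }
  if (!all(flank_alphabet %in% DNA_BASES)) {
    bep_validation_error("flank_alphabet must consist of DNA bases")
  }
  if (umi_length < 0L) bep_validation_error("umi_length must be >= 0")
  if (nchar(pam) != 3L || !is_dna(pam)) {
    bep_validation_error("pam must be a 3-base DNA sequence")
  }
  structure(
    list(target_bases = target_bases,
         positions = sort(unique(positions)),
         flank_alphabet = flank_alphabet,
         umi_length = as.integer(umi_length),
         protospacer_length = as.integer(protospacer_length),
         pam = pam),
    class = "ContextLibrarySpec"
  )
}

#' @export
print.ContextLibrarySpec <- function(x, ...) {
  cat("ContextLibrarySpec:",
      length(x$target_bases), "target base(s) x",
      length(x$positions), "position(s) x",
      length(x$flank_alphabet), "^2 flank contexts =",
      length(x$target_bases) * length(x$positions) * length(x$flank_alphabet)^2,
      "members\n")
  invisible(x)
}

#' Default amplicon layout
#'
#' The amplicon backbone is: left constant | UMI | mid constant | protospacer
#' (20 nt) | PAM | right constant. The filler 20-mer supplies every
#' protospacer position not overwritten by the member's target base or
#' flanks; the default alternating G/T filler keeps the protospacer free of
#' A and C apart from the member-specific bases, so bystander substitution
#' calls are unambiguous. When the target sits at position 1 its 5' flank
#' replaces the last base of the mid constant; when it sits at position 20
#' its 3' flank replaces the first (N) base of the PAM.
#'
#' @param umi_length UMI barcode length (determines offsets only).
#' @param left_const,mid_const,right_const Constant sequences around the UMI
#'   and protospacer.
#' @param filler 20-nt protospacer backbone.
#' @param pam Three-base PAM.
#' @return An `AmpliconLayout` list with sequence parts and 1-based offsets
#'   `umi_offset` and `protospacer_offset`.
#' @export
amplicon_layout <- function(umi_length = 10L,
                            left_const = "GTTTGG",
                            mid_const = "TGGTG",
                            right_const = "TGGTT",
                            filler = "GTGTGTGTGTGTGTGTGTGT",
                            pam = "TGG") {
  for (s in c(left_const, mid_const, right_const, filler, pam)) {
    if (!is_dna(s)) bep_validation_error("layout sequences must be DNA")
  }
  if (nchar(mid_const) < 1L) {
    bep_validation_error("mid_const must have length >= 1 (holds the 5' flank of a position-1 target)")
  }
  structure(
    list(umi_length = as.integer(umi_length),
         left_const = left_const, mid_const = mid_const,
         right_const = right_const, filler = filler, pam = pam,
         umi_offset = nchar(left_const) + 1L,
         protospacer_offset = nchar(left_const) + as.integer(umi_length) +
           nchar(mid_const) + 1L),
    class = "AmpliconLayout"
  )
}

#' Build one member amplicon
#'
#' Overwrites the filler protospacer with the member's target base and flanks,
#' then assembles the full amplicon around the UMI. Flanks that fall outside
#' the protospacer are written into the adjacent constant sequence (see
#' [amplicon_layout()]).
#'
#' @param target_base "A" or "C".
#' @param target_position 1-based protospacer position of the target.
#' @param flank5,flank3 Single bases immediately 5' and 3' of the target.
#' @param umi UMI barcode sequence (length must equal `layout$umi_length`).
#' @param layout An [amplicon_layout()].
#' @param protospacer_length Protospacer length; the filler must be at least
#'   this long.
#' @return List with `amplicon` and `protospacer` strings.
#' @export
build_amplicon <- function(target_base, target_position, flank5, flank3, umi,
                           layout = amplicon_layout(nchar(umi)),
                           protospacer_length = 20L) {
  if (nchar(layout$filler) < protospacer_length) {
    bep_validation_error("filler (%d nt) shorter than protospacer (%d nt)",
                         nchar(layout$filler), protospacer_length)
  }
  if (nchar(umi) != layout$umi_length) {
    bep_validation_error("umi length %d does not match layout umi_length %d",
                         nchar(umi), layout$umi_length)
  }
  proto <- str_chars(layout$filler)[seq_len(protospacer_length)]
  mid <- str_chars(layout$mid_const)
  pam <- str_chars(layout$pam)
  proto[target_position] <- target_base
  if (target_position - 1L >= 1L) {
    proto[target_position - 1L] <- flank5
  } else {
    mid[length(mid)] <- flank5
  }
  if (target_position + 1L <= protospacer_length) {
    proto[target_position + 1L] <- flank3
  } else {
    pam[1L] <- flank3
  }
  proto_seq <- paste(proto, collapse = "")
  amplicon <- paste0(layout$left_const, umi, paste(mid, collapse = ""),
                     proto_seq, paste(pam, collapse = ""), layout$right_const)
  n_occ <- length(gregexpr(proto_seq, amplicon, fixed = TRUE)[[1]])
  if (n_occ != 1L || gregexpr(proto_seq, amplicon, fixed = TRUE)[[1]][1] == -1L) {
    bep_validation_error("protospacer does not occur exactly once in the amplicon")
  }
  list(amplicon = amplicon, protospacer = proto_seq)
}

#' Assign unique, well-separated UMIs to a library table
#'
#' Samples fixed-length barcodes uniformly and keeps one per member subject to
#' a minimum pairwise Hamming distance (greedy rejection). With the default
#' distance 3 a single sequencing error cannot move a read's UMI closer to a
#' wrong member than to its own.
#'
#' @param table A `LibraryTable` from [enumerate_context_library()].
#' @param umi_length Barcode length.
#' @param min_pairwise_distance Minimum Hamming distance between any two UMIs.
#' @param seed Integer seed; assignment is reproducible.
#' @return The table with `umi` and `amplicon` columns (re)filled.
#' @export
assign_umis <- function(table, umi_length = 10L, min_pairwise_distance = 3L,
                        seed = 1L) {
  n <- nrow(table)
  if (n == 0L) return(table)
  if (4^umi_length < n) {
    bep_capacity_error("4^%d = %g barcodes cannot cover %d members",
                       umi_length, 4^umi_length, n)
  }
  set.seed(seed)
  accepted <- character(0)
  max_attempts <- 2000L * n
  attempts <- 0L
  while (length(accepted) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      bep_capacity_error(
        "could not place %d UMIs of length %d at pairwise distance >= %d",
        n, umi_length, min_pairwise_distance)
    }
    cand <- paste(sample(DNA_BASES, umi_length, replace = TRUE), collapse = "")
    if (length(accepted) == 0L ||
        min(hamming_to_refs(cand, accepted)) >= min_pairwise_distance) {
      accepted <- c(accepted, cand)
    }
  }
  table$umi <- accepted
  layout <- attr(table, "layout")
  if (is.null(layout) || layout$umi_length != umi_length) {
    layout <- amplicon_layout(umi_length, pam = attr(table, "spec")$pam)
  }
  spec <- attr(table, "spec")
  plen <- if (is.null(spec)) 20L else spec$protospacer_length
  for (i in seq_len(n)) {
    built <- build_amplicon(table$target_base[i], table$target_position[i],
                            table$flank5[i], table$flank3[i], table$umi[i],
                            layout, plen)
    table$amplicon[i] <- built$amplicon
    table$protospacer[i] <- built$protospacer
  }
  attr(table, "layout") <- layout
  attr(table, "seed") <- as.integer(seed)
  table
}

#' Enumerate a combinatorial context library
#'
#' Produces one member per (target base, position, 5' flank, 3' flank)
#' combination, in deterministic order (target base, then position, then 5'
#' flank, then 3' flank in alphabet order), with UMIs assigned and amplicons
#' built. The classic designs are the 32-member single-position library
#' (both target bases at position 6, 16 contexts each) and the 448-member
#' window-profiling library (positions 1-14).
#'
#' @param spec A [context_library_spec()].
#' @param seed Seed for UMI assignment.
#' @param layout Amplicon layout; defaults to [amplicon_layout()] with the
#'   spec's UMI length and PAM.
#' @param min_umi_distance Minimum pairwise UMI Hamming distance.
#' @return A `LibraryTable`: a data.frame with one row per member and columns
#'   member_id, target_base, target_position, flank5, flank3, umi,
#'   protospacer, amplicon; the spec, layout and seed ride along as
#'   attributes.
#' @examples
#' lib <- enumerate_context_library(context_library_spec(positions = 6))
#' nrow(lib)  # 32
#' @export
enumerate_context_library <- function(spec, seed = 1L,
                                      layout = amplicon_layout(spec$umi_length,
                                                               pam = spec$pam),
                                      min_umi_distance = 3L) {
  stopifnot(inherits(spec, "ContextLibrarySpec"))
  grid <- expand.grid(flank3 = spec$flank_alphabet,
                      flank5 = spec$flank_alphabet,
                      target_position = spec$positions,
                      target_base = sort(spec$target_bases),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("target_base", "target_position", "flank5", "flank3")]
  n <- nrow(grid)
  table <- data.frame(
    member_id = if (n) sprintf("%s%02d_%s%s", grid$target_base,
                               grid$target_position, grid$flank5, grid$flank3)
                else character(0),
    grid,
    umi = character(n),
    protospacer = character(n),
    amplicon = character(n),
    stringsAsFactors = FALSE
  )
  class(table) <- c("LibraryTable", "data.frame")
  attr(table, "spec") <- spec
  attr(table, "layout") <- layout
  if (n > 0L) {
    table <- assign_umis(table, spec$umi_length, min_umi_distance, seed)
  }
  stopifnot(!anyDuplicated(table$member_id), !anyDuplicated(table$umi))
  table
}

#' Write a library as FASTA plus TSV manifest
#'
#' @param table A `LibraryTable`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the two file paths.
#' @export
write_library <- function(table, dir, prefix = "library") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fasta"))
  manifest <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  seqs <- Biostrings::DNAStringSet(table$amplicon)
  names(seqs) <- table$member_id
  Biostrings::writeXStringSet(seqs, fasta)
  cols <- c("member_id", "target_base", "target_position", "flank5", "flank3",
            "umi", "protospacer", "amplicon")
  write_tsv(as.data.frame(table)[, cols], manifest)
  invisible(c(fasta = fasta, manifest = manifest))
}

#' Read a library manifest TSV back into a LibraryTable
#'
#' Layout offsets are re-derived from the UMI length and the position of the
#' protospacer within the first amplicon, so a manifest written by
#' [write_library()] round-trips.
#'
#' @param path Manifest TSV path.
#' @return A `LibraryTable`.
#' @export
read_library_manifest <- function(path) {
  char_cols <- c("member_id", "target_base", "flank5", "flank3", "umi",
                 "protospacer", "amplicon")
  table <- read_tsv(path, colClasses = stats::setNames(
    rep("character", length(char_cols)), char_cols))
  class(table) <- c("LibraryTable", "data.frame")
  if (nrow(table)) {
    umi_len <- nchar(table$umi[1])
    off <- as.integer(regexpr(table$protospacer[1], table$amplicon[1],
                              fixed = TRUE))
    if (off < 1L) bep_data_error("manifest amplicon does not contain its protospacer")
    layout <- amplicon_layout(umi_len)
    layout$protospacer_offset <- off
    at_default <- substr(table$amplicon[1], layout$umi_offset,
                         layout$umi_offset + umi_len - 1L)
    if (!identical(at_default, table$umi[1])) {
      layout$umi_offset <- as.integer(regexpr(table$umi[1], table$amplicon[1],
                                              fixed = TRUE))
    }
    attr(table, "layout") <- layout
  }
  table
}
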