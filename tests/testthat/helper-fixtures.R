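# Shared fixtures and independent oracles, built in code at test time.

lib32 <- function(seed = 11L) {
  enumerate_context_library(context_library_spec(positions = 6L), seed = seed)
}

lib448 <- function(seed = 11L) {
  enumerate_context_library(context_library_spec(positions = 1:14), seed = seed)
}

# Brute-force nearest-UMI assignment: for each read UMI, scan every member
# UMI with a character-by-character Hamming count; unique nearest within
# max_mismatch wins. Oracle for demultiplex().
brute_force_demux <- function(read_umis, member_umis, member_ids, max_mismatch) {
  vapply(read_umis, function(u) {
    d <- vapply(member_umis, function(m) {
      sum(strsplit(u, "")[[1]] != strsplit(m, "")[[1]])
    }, numeric(1))
    best <- min(d)
    hits <- which(d == best)
    if (best <= max_mismatch && length(hits) == 1L) member_ids[hits]
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force geometric mean via repeated multiplication and an n-th root.
brute_force_geomean <- function(x) prod(x)^(1 / length(x))

# Minimal single-member read set built by hand around a member's amplicon.
manual_reads <- function(seqs, quality = 30L) {
  q <- rawToChar(as.raw(quality + 33L))
  structure(list(seq = seqs,
                 qual = vapply(nchar(seqs), function(l) strrep(q, l), character(1)),
                 id = sprintf("r%d", seq_along(seqs))),
            class = "read_set")
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
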