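test_that("demultiplexing assigns clean reads and conserves totals", {
  lib <- lib32(seed = 6)
  sim <- simulate_reads(lib, read_sim_config(p_target = 0.5, depth = 10, seed = 2))
  r <- sim$reads[[1]]
  dmx <- demultiplex(r, lib, max_umi_mismatch = 0)
  expect_equal(dmx$n_assigned, length(r$seq))
  expect_equal(dmx$n_assigned + dmx$n_unassigned, dmx$n_total)
  truth_member <- sub("/.*", "", r$id)
  expect_identical(dmx$member, truth_member)
})

test_that("UMI mismatches are handled per the distance rule", {
  lib <- lib32(seed = 6)
  layout <- attr(lib, "layout")
  amp <- lib$amplicon[3]
  # corrupt one base of the UMI
  bad <- mutate_at(amp, layout$umi_offset,
                   setdiff(c("A", "C", "G", "T"),
                           substr(amp, layout$umi_offset, layout$umi_offset))[1])
  reads <- manual_reads(c(amp, bad))
  d0 <- demultiplex(reads, lib, max_umi_mismatch = 0)
  expect_identical(d0$member, c(lib$member_id[3], NA))
  d1 <- demultiplex(reads, lib, max_umi_mismatch = 1)
  expect_identical(d1$member, rep(lib$member_id[3], 2))
  # precondition: distance must exceed 2 x max mismatch
  expect_error(demultiplex(reads, lib, max_umi_mismatch = 2),
               class = "bep_config_error")
})

test_that("demultiplexer matches the brute-force nearest-UMI oracle", {
  lib <- lib448(seed = 6)
  layout <- attr(lib, "layout")
  set.seed(99)
  n <- 400
  src <- sample.int(nrow(lib), n, replace = TRUE)
  seqs <- lib$amplicon[src]
  # corrupt 0-2 random UMI bases per read
  for (k in seq_len(n)) {
    nmut <- sample(0:2, 1)
    if (nmut == 0) next
    pos <- sample(seq(layout$umi_offset, layout$umi_offset + 9), nmut)
    for (p in pos) {
      seqs[k] <- mutate_at(seqs[k], p,
                           sample(setdiff(c("A", "C", "G", "T"),
                                          substr(seqs[k], p, p)), 1))
    }
  }
  reads <- manual_reads(seqs)
  dmx <- demultiplex(reads, lib, max_umi_mismatch = 1)
  read_umis <- substr(seqs, layout$umi_offset, layout$umi_offset + 9)
  oracle <- brute_force_demux(read_umis, lib$umi, lib$member_id, 1)
  expect_identical(dmx$member, oracle)
})

test_that("classify_read calls substitutions, indels and low quality", {
  lib <- lib32(seed = 6)
  layout <- attr(lib, "layout")
  m <- lib[lib$target_base == "C", ][1, ]
  off <- layout$protospacer_offset + m$target_position - 1L
  # identical read: no calls
  r0 <- classify_read(m$amplicon, NULL, m, layout)
  expect_identical(r0$status, "ok")
  expect_equal(nrow(r0$calls), 0)
  # one C->T at the target position
  r1 <- classify_read(mutate_at(m$amplicon, off, "T"), NULL, m, layout)
  expect_equal(r1$calls, data.frame(position = m$target_position,
                                    conversion = "C>T",
                                    stringsAsFactors = FALSE))
  # 1-base deletion: indel flag (edit-distance oracle: lengths differ => gap)
  del <- paste0(substr(m$amplicon, 1, off - 1),
                substr(m$amplicon, off + 1, nchar(m$amplicon)))
  expect_lt(nchar(del), nchar(m$amplicon))
  expect_identical(classify_read(del, NULL, m, layout)$status, "indel")
  # low-quality base masked; mostly-low-quality read discarded
  qual <- strrep(rawToChar(as.raw(30 + 33)), nchar(m$amplicon))
  lowq_one <- qual
  substr(lowq_one, off, off) <- rawToChar(as.raw(2 + 33))
  r2 <- classify_read(mutate_at(m$amplicon, off, "T"), lowq_one, m, layout,
                      qmin = 20)
  expect_equal(nrow(r2$calls), 0)
  expect_true(m$target_position %in% r2$masked)
  all_low <- strrep(rawToChar(as.raw(2 + 33)), nchar(m$amplicon))
  expect_identical(classify_read(m$amplicon, all_low, m, layout)$status, "lowq")
  expect_error(classify_read("", NULL, m, layout), class = "bep_data_error")
})

test_that("quantify counts reads per position and conversion independently", {
  lib <- lib32(seed = 6)
  layout <- attr(lib, "layout")
  m <- lib[lib$target_base == "C", ][1, ]
  off <- layout$protospacer_offset + m$target_position - 1L
  # 4 reads, 3 with the target C->T: 75%
  seqs <- c(rep(mutate_at(m$amplicon, off, "T"), 3), m$amplicon)
  reads <- manual_reads(seqs)
  q <- quantify(reads$seq, reads$qual, m, layout, min_reads = 1)
  row <- q$edits[q$edits$position == m$target_position &
                   q$edits$conversion == "C>T", ]
  expect_equal(row$edited, 3)
  expect_equal(row$aligned, 4)
  expect_equal(row$efficiency_pct, 75)
  # independent tallies at different positions; protospacer pos 4 is G here
  pos4_off <- layout$protospacer_offset + 3L
  ref4 <- substr(m$amplicon, pos4_off, pos4_off)
  seqs2 <- c(rep(mutate_at(m$amplicon, off, "T"), 2),
             mutate_at(m$amplicon, pos4_off, "A"),
             rep(m$amplicon, 7))
  q2 <- quantify(seqs2, manual_reads(seqs2)$qual, m, layout, min_reads = 1)
  r_t <- q2$edits[q2$edits$position == m$target_position &
                    q2$edits$conversion == "C>T", ]
  r_4 <- q2$edits[q2$edits$position == 4 &
                    q2$edits$conversion == paste0(ref4, ">A"), ]
  expect_equal(r_t$efficiency_pct, 20)
  expect_equal(r_4$efficiency_pct, 10)
  # zero reads: low-coverage flag, no efficiency
  q0 <- quantify(character(0), character(0), m, layout, min_reads = 1)
  expect_true(all(q0$edits$low_coverage))
  expect_true(all(is.na(q0$edits$efficiency_pct)))
})

test_that("raising Qmin never increases a denominator", {
  lib <- lib32(seed = 6)
  layout <- attr(lib, "layout")
  m <- lib[1, ]
  set.seed(3)
  n <- 50
  seqs <- rep(m$amplicon, n)
  quals <- vapply(seq_len(n), function(i) {
    intToUtf8(33L + sample(0:40, nchar(m$amplicon), replace = TRUE))
  }, character(1))
  qs <- c(0, 10, 20, 30, 40)
  denom <- lapply(qs, function(qm) {
    quantify(seqs, quals, m, layout, qmin = qm, min_reads = 1,
             lowq_read_frac = 1)$edits$aligned
  })
  for (k in 2:length(qs)) expect_true(all(denom[[k]] <= denom[[k - 1]]))
})

test_that("simulate -> call round trip recovers rates; accounting conserved", {
  lib <- lib32(seed = 6)
  sim <- simulate_reads(lib, read_sim_config(p_target = 0.6, depth = 400,
                                             indel_rate = 0.05, seed = 17))
  edits <- call_edits(sim$reads[[1]], lib, min_reads = 10)
  s <- attr(edits, "summary")
  expect_equal(s$n_assigned + s$n_unassigned, s$n_total)
  pm <- s$per_member
  expect_equal(sum(pm$assigned), s$n_assigned)
  expect_true(all(pm$classified + pm$indel + pm$lowq == pm$assigned))
  # e=0: recovered efficiency equals the simulated edited-read fraction
  layout <- attr(lib, "layout")
  for (i in c(2L, 20L)) {
    off <- layout$protospacer_offset + lib$target_position[i] - 1L
    member_sel <- grepl(paste0("^", lib$member_id[i], "/"), sim$reads[[1]]$id)
    kept <- sim$reads[[1]]$seq[member_sel]
    kept <- kept[nchar(kept) == nchar(lib$amplicon[i])]  # caller drops indels
    want <- if (lib$target_base[i] == "C") "T" else "G"
    conv <- paste0(lib$target_base[i], ">", want)
    frac <- 100 * mean(substr(kept, off, off) == want)
    got <- edits$efficiency_pct[edits$member_id == lib$member_id[i] &
                                  edits$position == lib$target_position[i] &
                                  edits$conversion == conv]
    expect_equal(got, frac)
  }
})

test_that("replicate aggregation averages efficiencies and flags dropouts", {
  lib <- lib32(seed = 6)
  mk <- function(eff, low = FALSE) {
    m <- data.frame(member_id = lib$member_id[1], position = 6,
                    conversion = "C>T", edited = eff, aligned = 100,
                    efficiency_pct = eff, low_coverage = low,
                    below_lod = FALSE, stringsAsFactors = FALSE)
    class(m) <- c("PositionEditMatrix", "data.frame")
    m
  }
  agg <- aggregate_replicates(list(mk(70), mk(80), mk(90)))
  expect_equal(agg$efficiency_pct, 80)
  expect_equal(agg$n_replicates, 3L)
  # single replicate passes through
  one <- aggregate_replicates(list(mk(55)))
  expect_equal(one$efficiency_pct, 55)
  # one low-coverage replicate: mean of the other two, drop flagged
  agg2 <- aggregate_replicates(list(mk(70), mk(80, low = TRUE), mk(90)))
  expect_equal(agg2$efficiency_pct, 80)
  expect_equal(agg2$replicates_dropped, 1L)
  # all replicates low-coverage: member excluded with a warning
  expect_warning(agg3 <- aggregate_replicates(list(mk(70, TRUE), mk(80, TRUE))),
                 "no valid replicate")
  expect_equal(nrow(agg3), 0)
})
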