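test_that("position_profile averages members per position", {
  lib <- lib32(seed = 8)
  cm <- lib[lib$target_base == "C", ]
  mk_edits <- function(ids, eff) {
    m <- data.frame(member_id = ids, position = 6, conversion = "C>T",
                    edited = 0, aligned = 100, efficiency_pct = eff,
                    low_coverage = FALSE, below_lod = FALSE,
                    stringsAsFactors = FALSE)
    class(m) <- c("PositionEditMatrix", "data.frame")
    m
  }
  # singleton mean
  p1 <- position_profile(mk_edits(cm$member_id[1], 88), lib, "C>T")
  expect_equal(p1$mean_pct, 88)
  # 16 members all at 50
  p2 <- position_profile(mk_edits(cm$member_id, rep(50, 16)), lib, "C>T")
  expect_equal(p2$mean_pct, 50)
  expect_equal(p2$n_members, 16)
  # arithmetic mean of 80/90/100
  p3 <- position_profile(mk_edits(cm$member_id[1:3], c(80, 90, 100)), lib, "C>T")
  expect_equal(p3$mean_pct, 90)
  # no members for requested base -> empty profile with warning
  libC <- enumerate_context_library(
    context_library_spec(target_bases = "C", positions = 6), seed = 1)
  expect_warning(p4 <- position_profile(mk_edits(cm$member_id[1], 10), libC, "A>G"),
                 "no members")
  expect_equal(nrow(p4), 0)
})

test_that("editing_window matches the 20%-of-peak definition", {
  prof <- aggregate_profile(4:9, c(50, 80, 100, 70, 30, 15))
  w <- editing_window(prof, 0.20)
  expect_equal(w$peak_position, 6)
  expect_equal(w$window, 4:8)           # 15 < 20 drops position 9
  expect_equal(w$above_threshold, 4:8)
  # flat profile: whole scored range
  wf <- editing_window(aggregate_profile(1:10, rep(5, 10)))
  expect_equal(wf$window, 1:10)
  # all zeros: undefined
  expect_error(editing_window(aggregate_profile(1:5, rep(0, 5))),
               class = "bep_data_error")
  # ties break to the smallest position
  wt <- editing_window(aggregate_profile(3:5, c(10, 50, 50)))
  expect_equal(wt$peak_position, 4)
  # non-contiguous above-threshold set: window is the run containing the peak
  wn <- editing_window(aggregate_profile(1:7, c(30, 1, 1, 50, 100, 50, 1)), 0.2)
  expect_equal(wn$window, 4:6)
  expect_equal(wn$above_threshold, c(1, 4, 5, 6))
})

test_that("window set shrinks monotonically with threshold", {
  set.seed(7)
  for (i in 1:50) {
    prof <- aggregate_profile(1:12, runif(12, 0, 100))
    prev <- NULL
    for (th in c(0.05, 0.2, 0.5, 0.8, 1.0)) {
      ab <- editing_window(prof, th)$above_threshold
      if (!is.null(prev)) expect_true(all(ab %in% prev))
      prev <- ab
    }
  }
})

test_that("selectivity geometric mean matches its definition and oracle", {
  # constant ratio 16 at every position
  s <- selectivity_ratio(aggregate_profile(4:8, rep(80, 5)),
                         aggregate_profile(4:8, rep(5, 5)))
  expect_equal(s$geometric_mean, 16)
  expect_false(s$lower_bound)
  # identity
  p <- aggregate_profile(4:8, c(10, 20, 30, 40, 50))
  expect_equal(selectivity_ratio(p, p)$geometric_mean, 1)
  # censoring: A below LOD floored at 0.1 -> 99/0.1 = 990 lower bound
  s990 <- selectivity_ratio(aggregate_profile(6, 99), aggregate_profile(6, 0),
                            positions = 6)
  expect_equal(s990$geometric_mean, 990)
  expect_true(s990$lower_bound)
  expect_true(s990$censored)
  # random profiles: equals exp(mean log ratio) and brute-force product root,
  # and is permutation-invariant
  set.seed(123)
  for (i in 1:25) {
    cv <- runif(5, 1, 100)
    av <- runif(5, 0.2, 50)
    s <- selectivity_ratio(aggregate_profile(4:8, cv), aggregate_profile(4:8, av))
    r <- cv / av
    expect_equal(s$geometric_mean, exp(mean(log(r))))
    expect_equal(s$geometric_mean, brute_force_geomean(r))
    perm <- sample(5)
    s2 <- selectivity_ratio(aggregate_profile(4:8, cv[perm]),
                            aggregate_profile(4:8, av[perm]))
    expect_equal(s2$geometric_mean, s$geometric_mean)
  }
  # zero C average: reported 0 with warning
  expect_warning(
    s0 <- selectivity_ratio(aggregate_profile(4:8, c(0, 10, 10, 10, 10)),
                            aggregate_profile(4:8, rep(5, 5))),
    "zero C average")
  expect_equal(s0$geometric_mean, 0)
})

test_that("censored selectivity lower-bounds the uncensored value", {
  set.seed(5)
  for (i in 1:25) {
    cv <- runif(5, 1, 100)
    av_true <- runif(5, 0.1, 2)  # all at or above LOD
    s_unc <- selectivity_ratio(aggregate_profile(4:8, cv),
                               aggregate_profile(4:8, av_true))
    # censor by zeroing some A averages (observed below LOD)
    av_obs <- av_true
    av_obs[sample(5, 2)] <- 0
    s_cen <- selectivity_ratio(aggregate_profile(4:8, cv),
                               aggregate_profile(4:8, av_obs))
    expect_true(s_cen$lower_bound)
    expect_gte(s_cen$geometric_mean, s_unc$geometric_mean)
  }
})

test_that("context_matrix tabulates and normalizes the 16 contexts", {
  lib <- lib32(seed = 8)
  cm <- lib[lib$target_base == "C", ]
  mk <- function(ids, eff) {
    m <- data.frame(member_id = ids, position = 6, conversion = "C>T",
                    edited = 0, aligned = 100, efficiency_pct = eff,
                    low_coverage = FALSE, below_lod = FALSE,
                    stringsAsFactors = FALSE)
    class(m) <- c("PositionEditMatrix", "data.frame")
    m
  }
  m_uniform <- context_matrix(mk(cm$member_id, rep(90, 16)), lib, 6,
                              normalize = TRUE)
  expect_equal(nrow(m_uniform), 16)
  expect_true(all(m_uniform$efficiency == 1))
  eff <- c(100, rep(50, 15))
  m_peaked <- context_matrix(mk(cm$member_id, eff), lib, 6, normalize = TRUE)
  got <- m_peaked$efficiency[match(paste(cm$flank5, cm$flank3),
                                   paste(m_peaked$flank5, m_peaked$flank3))]
  expect_equal(got, eff / 100)
  expect_equal(max(m_peaked$efficiency), 1)
  # missing context flagged
  m_gap <- context_matrix(mk(cm$member_id[-1], rep(50, 15)), lib, 6)
  expect_equal(sum(m_gap$missing), 1)
})
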