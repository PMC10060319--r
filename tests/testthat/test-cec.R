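test_that("boundary frequencies count every exon boundary once per side", {
  rs <- reads_from_chains("100-200", 10)
  f <- boundary_frequencies(rs)
  expect_equal(f$total_reads, 10)
  expect_equal(f$starts, data.frame(pos = 100L, count = 10L, percent = 100))
  expect_equal(f$ends, data.frame(pos = 200L, count = 10L, percent = 100))

  rs2 <- reads_from_chains("100-150;200-250", 1)
  f2 <- boundary_frequencies(rs2)
  expect_equal(f2$starts$pos, c(100L, 200L))
  expect_equal(f2$ends$pos, c(150L, 250L))
  expect_equal(f2$starts$count, c(1L, 1L))

  rs3 <- reads_from_chains(c("100-200", "103-200"), c(6, 4))
  f3 <- boundary_frequencies(rs3)
  expect_equal(f3$starts$percent, c(60, 40))
  expect_error(boundary_frequencies(rs3[0, ]), "no reads")
})

test_that("candidate selection is strictly above the threshold", {
  rs <- reads_from_chains(c("100-300", "103-300", "100-177"),
                          c(59, 40, 1))
  f <- boundary_frequencies(rs)
  expect_equal(select_candidates(f, 2)$starts, c(100L, 103L))
  expect_equal(select_candidates(f, 0)$starts, sort(unique(rs$start)))
  expect_length(select_candidates(f, 100)$starts, 0)  # strict >
})

test_that("close candidates chain-merge into the most frequent one", {
  mk_freq <- function(pos, count) {
    total <- sum(count)
    list(starts = data.frame(pos = pos, count = count,
                             percent = 100 * count / total),
         ends = data.frame(pos = integer(0), count = integer(0),
                           percent = numeric(0)),
         total_reads = total)
  }
  f <- mk_freq(c(100L, 102L), c(60L, 40L))
  m <- merge_close_candidates(list(starts = c(100L, 102L), ends = integer(0)),
                              f, 3)
  expect_equal(m$starts, 100L)

  f2 <- mk_freq(c(100L, 110L), c(5L, 5L))
  m2 <- merge_close_candidates(list(starts = c(100L, 110L),
                                    ends = integer(0)), f2, 3)
  expect_equal(m2$starts, c(100L, 110L))

  # chained cluster collapses to its most frequent member
  f3 <- mk_freq(c(100L, 102L, 104L), c(30L, 30L, 40L))
  m3 <- merge_close_candidates(list(starts = c(100L, 102L, 104L),
                                    ends = integer(0)), f3, 3)
  expect_equal(m3$starts, 104L)

  # frequency tie inside a cluster goes to the smaller coordinate
  f4 <- mk_freq(c(100L, 102L), c(50L, 50L))
  m4 <- merge_close_candidates(list(starts = c(100L, 102L),
                                    ends = integer(0)), f4, 3)
  expect_equal(m4$starts, 100L)

  # exclusive mode: distance == merge_distance no longer merges
  m5 <- merge_close_candidates(list(starts = c(100L, 103L),
                                    ends = integer(0)),
                               mk_freq(c(100L, 103L), c(6L, 4L)),
                               3, inclusive = FALSE)
  expect_equal(m5$starts, c(100L, 103L))
})

test_that("windows collect nearby counts and truncate at the midpoint", {
  rs <- reads_from_chains(c("118-300", "120-300", "124-300"), c(1, 8, 1))
  f <- boundary_frequencies(rs)
  cs <- build_windows(list(starts = 120L, ends = 300L), f, 5)
  expect_equal(cs$starts$lower, 115L)
  expect_equal(cs$starts$upper, 125L)
  expect_equal(cs$starts$reads_at_breakpoint, 8L)
  expect_equal(cs$starts$reads_in_interval, 10L)

  # adjacent candidates: equidistant midpoint joins the more frequent one
  rs2 <- reads_from_chains(c("100-300", "108-300"), c(6, 4))
  f2 <- boundary_frequencies(rs2)
  cs2 <- build_windows(list(starts = c(100L, 108L), ends = 300L), f2, 5)
  expect_equal(cs2$starts$lower, c(95L, 105L))
  expect_equal(cs2$starts$upper, c(104L, 113L))
  # frequency reversed: midpoint 104 moves to the right window
  rs3 <- reads_from_chains(c("100-300", "108-300"), c(4, 6))
  cs3 <- build_windows(list(starts = c(100L, 108L), ends = 300L),
                       boundary_frequencies(rs3), 5)
  expect_equal(cs3$starts$upper[1], 103L)
  expect_equal(cs3$starts$lower[2], 104L)

  # window 0: degenerate windows at the breakpoints
  cs0 <- build_windows(list(starts = c(100L, 108L), ends = 300L), f2, 0)
  expect_equal(cs0$starts$lower, cs0$starts$breakpoint)
  expect_equal(cs0$starts$upper, cs0$starts$breakpoint)
})

test_that("detection matches the literal brute-force oracle on random data", {
  set.seed(42)
  for (rep in 1:60) {
    inst <- random_instance()
    freq <- structure(list(starts = inst$df,
                           ends = inst$df[0, ],
                           total_reads = inst$total),
                      class = "boundary_freq")
    params <- detection_params(
      read_threshold_percent = sample(c(0, 1, 2, 5, 10), 1),
      window_nt = sample(0:6, 1),
      merge_distance_nt = sample(0:4, 1))
    got <- isoquantr:::detect_from_freq(freq, params)$starts
    want <- oracle_detect_side(inst$df, inst$total,
                               params$read_threshold_percent,
                               params$window_nt, params$merge_distance_nt)
    rownames(got) <- NULL
    expect_equal(got, want,
                 info = sprintf("rep %d params %s", rep,
                                paste(unlist(params), collapse = "/")))
  }
})

test_that("detection is deterministic and monotone in the threshold", {
  sim <- simulate_reads(three_isoform_config(seed = 3, noise_reads = 10))
  a <- detect_cecs(sim$reads)
  b <- detect_cecs(sim$reads)
  expect_identical(a, b)
  n_cecs <- vapply(c(0.25, 0.5, 1, 2, 3), function(th) {
    cs <- detect_cecs(sim$reads, detection_params(th))
    c(nrow(cs$starts), nrow(cs$ends))
  }, numeric(2))
  expect_true(all(diff(n_cecs[1, ]) <= 0))
  expect_true(all(diff(n_cecs[2, ]) <= 0))
})

test_that("count conservation holds per side and windows stay disjoint", {
  sim <- simulate_reads(three_isoform_config(seed = 11, noise_reads = 15))
  f <- boundary_frequencies(sim$reads)
  cs <- detect_cecs(sim$reads)
  expect_lte(sum(cs$starts$reads_in_interval), sum(f$starts$count))
  expect_lte(sum(cs$ends$reads_in_interval), sum(f$ends$count))
  expect_no_error(validate_cec_set(cs))
})

test_that("custom coordinates replace or merge, overriding on overlap", {
  rs <- reads_from_chains(c("100-200;301-400", "100-200"), c(6, 4))
  f <- boundary_frequencies(rs)
  auto <- detect_cecs(rs)
  none <- list(starts = auto$starts[0, 1:3], ends = auto$ends[0, 1:3])
  repl <- apply_custom_cecs(auto, none, "replace", f)
  expect_equal(nrow(repl$starts), 0)

  far <- list(starts = data.frame(breakpoint = 500L, lower = 495L,
                                  upper = 505L),
              ends = auto$ends[0, 1:3])
  merged <- apply_custom_cecs(auto, far, "merge", f)
  expect_equal(nrow(merged$starts), nrow(auto$starts) + 1)
  expect_equal(nrow(merged$ends), nrow(auto$ends))

  # overlapping custom window evicts the auto coordinate
  near <- list(starts = data.frame(breakpoint = 98L, lower = 93L,
                                   upper = 103L),
               ends = auto$ends[0, 1:3])
  over <- apply_custom_cecs(auto, near, "merge", f)
  expect_true(98L %in% over$starts$breakpoint)
  expect_false(100L %in% over$starts$breakpoint)
  expect_equal(over$starts$reads_in_interval[
    over$starts$breakpoint == 98L], 10L)  # counts recomputed

  clash <- list(starts = data.frame(breakpoint = c(100L, 104L),
                                    lower = c(95L, 103L),
                                    upper = c(105L, 109L)),
                ends = auto$ends[0, 1:3])
  expect_error(apply_custom_cecs(auto, clash, "merge", f), "overlap")
})

test_that("editing a coordinate set is reversible and recounts windows", {
  rs <- reads_from_chains(c("100-200", "100-250"), c(6, 4))
  f <- boundary_frequencies(rs)
  cs <- detect_cecs(rs)
  added <- edit_cec_set(cs, "add", "start", 500L, 495L, 505L, freq = f)
  back <- edit_cec_set(added, "delete", "start", 500L, freq = f)
  expect_equal(back$starts, cs$starts)

  # widening a window never decreases its interval count
  before <- cs$ends$reads_in_interval[cs$ends$breakpoint == 200L]
  upd <- edit_cec_set(cs, "update", "end", 200L, lower = 190L,
                      upper = 210L, freq = f)
  expect_gte(upd$ends$reads_in_interval[upd$ends$breakpoint == 200L],
             before)

  expect_error(edit_cec_set(cs, "delete", "start", 999L), "no start")
  expect_error(edit_cec_set(cs, "add", "end", 205L, 195L, 215L),
               "overlap")

  # deleting a used coordinate makes its reads unassignable downstream
  gone <- edit_cec_set(cs, "delete", "end", 250L, freq = f)
  asn <- assign_reads(rs, gone)
  expect_equal(sum(asn$status == "rejected"), 4)
  expect_equal(unique(asn$reason[asn$status == "rejected"]),
               "unmatched_boundary")
})
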