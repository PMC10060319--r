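test_that("region restriction drops, clips and flags exons", {
  rs <- reads_from_chains("100-200;300-400", 1)
  expect_equal(restrict_region(rs)$start, rs$start)

  r1 <- restrict_region(rs, 250, 500)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(300L, 400L))
  expect_false(any(r1$start_clipped))

  r2 <- restrict_region(reads_from_chains("100-200", 1), 150, 500)
  expect_equal(c(r2$start, r2$end), c(150L, 200L))
  expect_true(r2$start_clipped)
  expect_false(r2$end_clipped)

  # read entirely outside is reported, not silently dropped
  mix <- reads_from_chains(c("100-200", "600-700"), c(1, 1))
  r3 <- restrict_region(mix, 50, 300)
  expect_equal(attr(r3, "rejected"), "r002")
})

test_that("boundary assignment uses unique window containment", {
  rs <- reads_from_chains(c("120-300", "122-300", "130-300"), c(5, 3, 1))
  cecs <- build_windows(list(starts = 120L, ends = 300L),
                        boundary_frequencies(rs), 5)
  asn <- assign_reads(rs, cecs)
  expect_equal(asn$status[asn$read_id == "r001"], "assigned")
  expect_equal(asn$chain[asn$read_id == "r006"], "120-300")  # 122 -> 120
  r9 <- asn[asn$read_id == "r009", ]  # start 130 outside all windows
  expect_equal(r9$status, "rejected")
  expect_equal(r9$reason, "unmatched_boundary")

  # assignment agrees with a literal window-containment lookup
  set.seed(9)
  sim <- simulate_reads(three_isoform_config(seed = 9))
  cs <- detect_cecs(sim$reads)
  asn2 <- assign_reads(sim$reads, cs)
  for (rid in sample(unique(sim$reads$read_id), 20)) {
    ex <- sim$reads[sim$reads$read_id == rid, ]
    s <- vapply(ex$start, oracle_assign_one, 1L, cec = cs$starts)
    e <- vapply(ex$end, oracle_assign_one, 1L, cec = cs$ends)
    want <- if (anyNA(s) || anyNA(e)) NA_character_
            else paste(paste0(s, "-", e), collapse = ";")
    expect_equal(asn2$chain[asn2$read_id == rid], want)
  }
})

test_that("full-length filtering anchors to the outermost coordinates", {
  rs <- reads_from_chains(c("100-200;300-400", "300-400", "100-200"),
                          c(5, 3, 2))
  cecs <- build_windows(list(starts = c(100L, 300L), ends = c(200L, 400L)),
                        boundary_frequencies(rs), 5)
  asn <- assign_reads(rs, cecs)
  ff <- filter_full_length(asn, cecs)
  # spanning reads kept; internal starts or ends rejected
  expect_equal(sum(ff$status == "assigned"), 5)
  expect_equal(sort(unique(ff$reason[ff$status == "rejected"])),
               "not_full_length")
})

test_that("grouping keys on the exact chain and ranks deterministically", {
  rs <- reads_from_chains(c("100-200;300-400", "100-400"), c(9, 1))
  iso <- group_and_quantify(assign_reads(rs, build_windows(
    list(starts = c(100L, 300L), ends = c(200L, 400L)),
    boundary_frequencies(rs), 5)))
  expect_equal(iso$isoforms$percent, c(90, 10))
  expect_equal(iso$isoforms$isoform_id, c("Iso1", "Iso2"))

  one <- reads_from_chains("100-200", 7)
  iso1 <- group_and_quantify(assign_reads(one, build_windows(
    list(starts = 100L, ends = 200L), boundary_frequencies(one), 5)))
  expect_equal(iso1$isoforms$percent, 100)

  # count tie broken by length (longer first)
  tie <- reads_from_chains(c("100-400", "100-200"), c(5, 5))
  isot <- group_and_quantify(assign_reads(tie, build_windows(
    list(starts = 100L, ends = c(200L, 400L)),
    boundary_frequencies(tie), 5)))
  expect_equal(isot$isoforms$chain, c("100-400", "100-200"))

  # zero assigned reads is an explicit error carrying the breakdown
  asn0 <- data.frame(read_id = "r1", status = "rejected",
                     reason = "unmatched_boundary", chain = NA_character_)
  expect_error(group_and_quantify(asn0), "unmatched_boundary=1")
})

test_that("abundances sum to 100 and assignment partitions the reads", {
  sim <- simulate_reads(three_isoform_config(
    seed = 5, truncation_fraction = 0.2, noise_reads = 10))
  fit <- run_locus(sim$reads, full_length_only = TRUE)
  expect_equal(sum(fit$isoforms$percent), 100, tolerance = 1e-9)
  expect_equal(fit$n_assigned + fit$n_rejected,
               length(unique(sim$reads$read_id)))
  expect_equal(sum(fit$isoforms$read_count), fit$n_assigned)
  rej <- fit$assignments[fit$assignments$status == "rejected", ]
  expect_true(all(rej$reason %in%
                  c("unmatched_boundary", "not_full_length",
                    "outside_region")))
})

test_that("results are invariant under read order permutation", {
  sim <- simulate_reads(three_isoform_config(seed = 13, noise_reads = 5))
  fit1 <- run_locus(sim$reads)
  shuffled <- sim$reads[sample(nrow(sim$reads)), ]
  fit2 <- run_locus(as_read_set(shuffled))
  expect_equal(fit1$isoforms, fit2$isoforms)
  expect_equal(fit1$cecs$starts, fit2$cecs$starts)
  expect_equal(fit1$assignments[order(fit1$assignments$read_id), ],
               fit2$assignments[order(fit2$assignments$read_id), ],
               ignore_attr = TRUE)
})

test_that("exon summary aggregates shared exons across isoforms", {
  rs <- reads_from_chains(c("100-200;300-400", "100-200"), c(6, 4))
  fit <- run_locus(rs)
  es <- exon_summary(fit)
  shared <- es[es$start == 100, ]
  expect_equal(shared$n_isoforms, 2L)
  expect_equal(shared$read_support, 10L)
  expect_equal(shared$length, 101L)
  expect_equal(nrow(exon_summary(fit$isoforms[0, ])), 0)
})

test_that("region clipping anchors reads to a sentinel coordinate", {
  # vector exon at 100-200 to be excluded; biological exons from 300
  rs <- reads_from_chains(c("100-400;500-600", "100-400"), c(6, 4))
  fit <- run_locus(rs, region = c(250, 700))
  expect_true(250L %in% fit$cecs$starts$breakpoint)
  expect_equal(sort(unique(fit$isoforms$chain)),
               sort(c("250-400;500-600", "250-400")))
  expect_equal(fit$n_assigned, 10)
})

test_that("rerunning after an edit yields no stale chains", {
  rs <- reads_from_chains(c("100-200;300-400", "100-200"), c(6, 4))
  fit <- run_locus(rs)
  f <- boundary_frequencies(rs)
  edited <- edit_cec_set(fit$cecs, "delete", "end", 400L, freq = f)
  asn <- assign_reads(rs, edited)
  iso <- group_and_quantify(asn)
  expect_false("100-200;300-400" %in% iso$isoforms$chain)
  expect_equal(iso$n_assigned, 4)
  used_ends <- unlist(lapply(iso$isoforms$chain, function(ch)
    chain_to_exons(ch)[, "end"]))
  expect_true(all(used_ends %in% edited$ends$breakpoint))
})
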