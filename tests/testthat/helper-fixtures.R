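# shared synthetic fixtures built in code

# three isoforms sharing outer exons: 50/30/20% of n = 200 reads
three_isoform_config <- function(jitter = 2, seed = 1, ...) {
  simulation_config(
    truth = list(
      A = list(chain = cbind(c(101, 301, 501, 701), c(200, 400, 600, 800)),
               count = 100),
      B = list(chain = cbind(c(101, 301, 701), c(200, 400, 800)),
               count = 60),
      C = list(chain = cbind(c(101, 301, 701), c(200, 360, 800)),
               count = 40)),
    jitter = jitter, seed = seed, ...)
}

truth_chains <- function(config) {
  vapply(config$truth, function(t)
    paste(paste0(t$chain[, 1], "-", t$chain[, 2]), collapse = ";"), "")
}

# tiny deterministic read set: counts per distinct chain, no jitter
reads_from_chains <- function(chains, counts, reference_id = "amp") {
  rows <- list()
  idx <- 0
  for (i in seq_along(chains)) {
    ex <- chain_to_exons(chains[i])
    for (r in seq_len(counts[i])) {
      idx <- idx + 1
      rows[[idx]] <- data.frame(
        read_id = sprintf("r%03d", idx), reference_id = reference_id,
        start = ex[, "start"], end = ex[, "end"])
    }
  }
  as_read_set(do.call(rbind, rows))
}

# one-transcript exon table for overlap tests
tx <- function(starts, ends, id = "t1", gene = "g1", ref = "amp",
               abundance = NA_real_) {
  as_transcript_set(data.frame(
    transcript_id = id, gene_id = gene, reference_id = ref,
    start = starts, end = ends, abundance = abundance))
}
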