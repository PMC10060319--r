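#' Configuration for the amplicon read simulator
#'
#' Describes a ground-truth set of isoforms (exon chains on one reference)
#' and the distortions the simulator applies: small bounded jitter on exon
#' boundaries, a fraction of truncated (non-full-length) reads, and random
#' noise reads whose boundaries stay well away from every true boundary.
#'
#' Jitter: each boundary is perturbed with probability `jitter_prob`; a
#' perturbed boundary moves by a uniform non-zero integer offset in
#' `[-jitter, +jitter]`. Offsets are therefore bounded by `jitter` and the
#' true position remains the modal observed position, which is what makes
#' exact recovery of the true chains provable when `jitter <= window_nt`.
#'
#' @param truth named list of isoforms, each a list with `chain` (two-column
#'   matrix of exon `start`,`end`) and `count` (number of reads).
#' @param reference_id reference name, default `"amplicon"`.
#' @param jitter maximum absolute boundary offset (nt).
#' @param jitter_prob probability that any one boundary is jittered.
#' @param truncation_fraction fraction of reads with 5' and/or 3' exons
#'   removed (requires multi-exon chains).
#' @param noise_reads number of random single-exon reads whose boundaries
#'   are at least `noise_margin` away from every true boundary.
#' @param noise_margin minimum distance of noise boundaries from truth.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(truth, reference_id = "amplicon", jitter = 2,
                              jitter_prob = 0.35, truncation_fraction = 0,
                              noise_reads = 0, noise_margin = 8,
                              seed = NULL) {
  stopifnot(is.list(truth), length(truth) > 0,
            truncation_fraction >= 0, truncation_fraction <= 1,
            jitter >= 0, jitter_prob >= 0, jitter_prob <= 1,
            noise_reads >= 0)
  if (is.null(names(truth)) || any(names(truth) == ""))
    names(truth) <- paste0("iso", seq_along(truth))
  for (nm in names(truth)) {
    ch <- truth[[nm]]$chain
    if (is.null(dim(ch)) || ncol(ch) != 2)
      stop("truth chain for ", nm, " must be a two-column matrix")
    if (truth[[nm]]$count < 0) stop("negative read count for ", nm)
    if (any(ch[, 2] - ch[, 1] + 1 <= 2 * jitter))
      stop("exon of ", nm, " shorter than 2*jitter+1; jitter could ",
           "invert its boundaries")
    if (nrow(ch) > 1 && any(ch[-1, 1] <= ch[-nrow(ch), 2]))
      stop("truth chain for ", nm, " has unordered/overlapping exons")
  }
  structure(list(truth = truth, reference_id = reference_id,
                 jitter = as.integer(jitter), jitter_prob = jitter_prob,
                 truncation_fraction = truncation_fraction,
                 noise_reads = as.integer(noise_reads),
                 noise_margin = as.integer(noise_margin), seed = seed),
            class = "simulation_config")
}

draw_offsets <- function(n, j, p) {
  off <- integer(n)
  if (j > 0 && p > 0) {
    hit <- stats::runif(n) < p
    nz <- c(seq(-j, -1), seq(1, j))
    off[hit] <- sample(nz, sum(hit), replace = TRUE)
  }
  off
}

#' Simulate amplicon-style long-read alignments with known truth
#'
#' Draws reads from the configured true isoforms, applies boundary jitter
#' (redrawn when it would break exon ordering), removes terminal exons from
#' the truncated fraction, and appends noise reads. Reproducible for a
#' fixed seed.
#'
#' @param config a [simulation_config()].
#' @return list with `reads` (a [read_set]) and `truth` (data.frame
#'   `read_id`, `isoform`, `truncated`, `offsets` — comma-separated applied
#'   boundary offsets in chain order).
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  j <- config$jitter
  rows <- list(); truth_rows <- list()
  idx <- 0L
  for (nm in names(config$truth)) {
    ch <- config$truth[[nm]]$chain
    for (r in seq_len(config$truth[[nm]]$count)) {
      idx <- idx + 1L
      rid <- sprintf("read%05d", idx)
      ex <- ch
      truncated <- FALSE
      if (config$truncation_fraction > 0 && nrow(ex) > 1 &&
          stats::runif(1) < config$truncation_fraction) {
        truncated <- TRUE
        mode <- sample(c("5p", "3p", "both"), 1)
        if (mode %in% c("5p", "both")) ex <- ex[-1, , drop = FALSE]
        if (mode %in% c("3p", "both") && nrow(ex) > 1)
          ex <- ex[-nrow(ex), , drop = FALSE]
      }
      nb <- 2 * nrow(ex)
      repeat {
        off <- draw_offsets(nb, j, config$jitter_prob)
        s <- ex[, 1] + off[seq(1, nb, by = 2)]
        e <- ex[, 2] + off[seq(2, nb, by = 2)]
        ok <- all(s >= 1) && all(s <= e) &&
          (nrow(ex) == 1 || all(s[-1] > e[-nrow(ex)]))
        if (ok) break
      }
      rows[[idx]] <- data.frame(read_id = rid,
                                reference_id = config$reference_id,
                                start = s, end = e,
                                stringsAsFactors = FALSE)
      truth_rows[[idx]] <- data.frame(read_id = rid, isoform = nm,
                                      truncated = truncated,
                                      offsets = paste(off, collapse = ","),
                                      stringsAsFactors = FALSE)
    }
  }
  if (config$noise_reads > 0) {
    bnd <- unlist(lapply(config$truth, function(t) as.vector(t$chain)))
    lo <- max(1, min(bnd) - 50)
    hi <- max(bnd) + 50
    m <- config$noise_margin
    allowed <- setdiff(seq(lo, hi),
                       unlist(lapply(bnd, function(b) seq(b - m, b + m))))
    for (r in seq_len(config$noise_reads)) {
      idx <- idx + 1L
      rid <- sprintf("read%05d", idx)
      repeat {
        p <- sort(sample(allowed, 2))
        if (p[2] - p[1] >= 20) break
      }
      rows[[idx]] <- data.frame(read_id = rid,
                                reference_id = config$reference_id,
                                start = p[1], end = p[2],
                                stringsAsFactors = FALSE)
      truth_rows[[idx]] <- data.frame(read_id = rid, isoform = "noise",
                                      truncated = FALSE, offsets = "",
                                      stringsAsFactors = FALSE)
    }
  }
  list(reads = as_read_set(do.call(rbind, rows)),
       truth = do.call(rbind, truth_rows))
}

#' Export simulated reads as an alignment fixture
#'
#' Writes a [read_set] as BED6, GFF3 or BAM so it round-trips through
#' [load_alignments()]. BAM is produced by writing SAM text (CIGAR built
#' from the exon chain with `N` gaps, `*` sequence) and converting with
#' Rsamtools.
#'
#' @param reads a [read_set].
#' @param path output file path (for `bam`, the final `.bam` path).
#' @param format `"bed6"`, `"gff3"` or `"bam"`.
#' @return The path written, invisibly.
#' @export
export_fixture <- function(reads, path, format = c("bed6", "gff3", "bam")) {
  format <- match.arg(format)
  if (format == "bed6") {
    gr <- GenomicRanges::GRanges(
      reads$reference_id, IRanges::IRanges(reads$start, reads$end),
      strand = "+", name = reads$read_id, score = 0L)
    rtracklayer::export(gr, path, format = "bed")
  } else if (format == "gff3") {
    ids <- unique(reads$read_id)
    first <- reads[!duplicated(reads$read_id), , drop = FALSE]
    span <- data.frame(
      read_id = ids,
      reference_id = first$reference_id[match(ids, first$read_id)],
      start = vapply(ids, function(i) min(reads$start[reads$read_id == i]),
                     integer(1)),
      end = vapply(ids, function(i) max(reads$end[reads$read_id == i]),
                   integer(1)))
    parents <- GenomicRanges::GRanges(
      span$reference_id, IRanges::IRanges(span$start, span$end),
      strand = "+", type = "match", ID = span$read_id)
    exons <- GenomicRanges::GRanges(
      reads$reference_id, IRanges::IRanges(reads$start, reads$end),
      strand = "+", type = "exon", ID = NA_character_)
    exons$Parent <- methods::as(as.list(reads$read_id), "CharacterList")
    parents$Parent <- methods::as(vector("list", length(parents)),
                                  "CharacterList")
    rtracklayer::export(c(parents, exons), path, format = "gff3")
  } else {
    sam <- tempfile(fileext = ".sam")
    write_sam(reads, sam)
    dest <- sub("\\.bam$", "", path)
    Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
    unlink(sam)
  }
  invisible(path)
}

# minimal SAM writer: one primary record per read, CIGAR M/N from exons
write_sam <- function(reads, path) {
  refs <- unique(reads$reference_id)
  reflen <- vapply(refs, function(r)
    max(reads$end[reads$reference_id == r]) + 100L, integer(1))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", refs, reflen))
  ids <- unique(reads$read_id)
  recs <- vapply(ids, function(i) {
    ex <- reads[reads$read_id == i, , drop = FALSE]
    m <- ex$end - ex$start + 1L
    cigar <- paste0(m[1], "M")
    if (nrow(ex) > 1) {
      gaps <- ex$start[-1] - ex$end[-nrow(ex)] - 1L
      cigar <- paste0(m[1], "M",
                      paste0(gaps, "N", m[-1], "M", collapse = ""))
    }
    sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
            i, ex$reference_id[1], ex$start[1], cigar)
  }, character(1))
  # SAM is coordinate-sorted for indexing
  first_pos <- vapply(ids, function(i)
    min(reads$start[reads$read_id == i]), integer(1))
  writeLines(c(hdr, recs[order(first_pos)]), path)
}
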