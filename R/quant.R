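# chain encoding: "start-end;start-end;..." with exons in coordinate order

exons_to_chain <- function(starts, ends) {
  paste(paste0(starts, "-", ends), collapse = ";")
}

#' Decode an exon chain string
#'
#' @param chain a chain string `"start-end;start-end;..."` as used in
#'   isoform tables.
#' @return integer matrix with `start` and `end` columns.
#' @export
chain_to_exons <- function(chain) {
  parts <- strsplit(strsplit(chain, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p), integer(2)))
  colnames(m) <- c("start", "end")
  m
}

chain_length_nt <- function(chain) {
  ex <- chain_to_exons(chain)
  sum(ex[, "end"] - ex[, "start"] + 1L)
}

#' Restrict reads to an analysis region
#'
#' Exons entirely outside `[region_start, region_end]` are dropped; exons
#' straddling an edge are clipped to the edge and the clipped boundary is
#' flagged so that a sentinel consensus coordinate at the region limit can
#' absorb it downstream (the typical use is cutting away vector-derived
#' exons of a minigene while keeping the biological remainder of the read).
#' Reads left with no exons are recorded in the `"rejected"` attribute.
#'
#' @param reads a [read_set].
#' @param region_start,region_end region limits (either may be `NULL` for
#'   an open end; both `NULL` returns the input unchanged).
#' @return A [read_set] with attribute `rejected` (character vector of read
#'   ids that fell entirely outside the region).
#' @export
restrict_region <- function(reads, region_start = NULL, region_end = NULL) {
  if (is.null(region_start) && is.null(region_end)) {
    attr(reads, "rejected") <- character(0)
    return(reads)
  }
  lo <- if (is.null(region_start)) -Inf else region_start
  hi <- if (is.null(region_end)) Inf else region_end
  if (lo > hi) stop("region_start must be <= region_end")
  all_ids <- unique(reads$read_id)
  keep <- reads$end >= lo & reads$start <= hi
  out <- reads[keep, , drop = FALSE]
  clip_lo <- out$start < lo
  clip_hi <- out$end > hi
  out$start[clip_lo] <- as.integer(lo)
  out$end[clip_hi] <- as.integer(hi)
  out$start_clipped <- out$start_clipped | clip_lo
  out$end_clipped <- out$end_clipped | clip_hi
  out <- as_read_set(out)
  attr(out, "rejected") <- setdiff(all_ids, unique(out$read_id))
  out
}

# add degenerate sentinel coordinates at clipped region limits when no
# existing window already covers the limit
ensure_sentinels <- function(cecs, reads, freq) {
  add_if_needed <- function(cecs, side, pos) {
    key <- if (side == "start") "starts" else "ends"
    df <- cecs[[key]]
    covered <- any(df$lower <= pos & df$upper >= pos)
    if (!covered)
      cecs <- edit_cec_set(cecs, "add", side, breakpoint = pos,
                           lower = pos, upper = pos, freq = freq)
    cecs
  }
  for (pos in unique(reads$start[reads$start_clipped]))
    cecs <- add_if_needed(cecs, "start", pos)
  for (pos in unique(reads$end[reads$end_clipped]))
    cecs <- add_if_needed(cecs, "end", pos)
  cecs
}

# map positions to the window containing them; NA where uncovered
match_windows <- function(pos, cec) {
  if (nrow(cec) == 0) return(rep(NA_integer_, length(pos)))
  idx <- findInterval(pos, cec$lower)
  ok <- idx >= 1 & idx <= nrow(cec)
  ok[ok] <- pos[ok] <= cec$upper[idx[ok]]
  idx[!ok] <- NA_integer_
  idx
}

#' Assign read boundaries to consensus coordinates
#'
#' Each exon start of a read must fall inside the window of exactly one
#' start coordinate (windows are disjoint, so containment is unique), and
#' likewise each end; the read's chain is then rewritten with the consensus
#' breakpoints. Reads with any boundary outside all windows, or whose
#' rewritten chain is not a valid ordered exon chain, are rejected with
#' reason `unmatched_boundary`.
#'
#' @param reads a [read_set].
#' @param cecs a `cec_set`.
#' @return data.frame with `read_id`, `status` (`assigned`/`rejected`),
#'   `reason` (`NA` or a rejection reason) and `chain` (consensus chain
#'   string, `NA` when rejected).
#' @export
assign_reads <- function(reads, cecs) {
  ids <- unique(reads$read_id)
  si <- match_windows(reads$start, cecs$starts)
  ei <- match_windows(reads$end, cecs$ends)
  bp_s <- cecs$starts$breakpoint[si]
  bp_e <- cecs$ends$breakpoint[ei]
  res <- lapply(split(seq_len(nrow(reads)), reads$read_id)[ids],
                function(rows) {
    s <- bp_s[rows]; e <- bp_e[rows]
    if (anyNA(s) || anyNA(e) || any(s > e) ||
        (length(s) > 1 && any(s[-1] <= e[-length(e)])))
      return(list(status = "rejected", reason = "unmatched_boundary",
                  chain = NA_character_))
    list(status = "assigned", reason = NA_character_,
         chain = exons_to_chain(s, e))
  })
  data.frame(read_id = ids,
             status = vapply(res, `[[`, "", "status"),
             reason = vapply(res, `[[`, "", "reason"),
             chain = vapply(res, `[[`, "", "chain"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep only full-length reads
#'
#' A read is full length when its first boundary is assigned to the 5'-most
#' start coordinate and its last boundary to the 3'-most end coordinate —
#' in an amplicon design these are the PCR primer positions. Other assigned
#' reads are re-flagged `rejected` with reason `not_full_length`.
#'
#' @param assignments output of [assign_reads()].
#' @param cecs the `cec_set` used for assignment.
#' @return The assignments data.frame with non-full-length reads rejected.
#' @export
filter_full_length <- function(assignments, cecs) {
  if (nrow(cecs$starts) == 0 || nrow(cecs$ends) == 0) return(assignments)
  first_bp <- min(cecs$starts$breakpoint)
  last_bp <- max(cecs$ends$breakpoint)
  is_asn <- assignments$status == "assigned"
  full <- vapply(assignments$chain[is_asn], function(ch) {
    ex <- chain_to_exons(ch)
    ex[1, "start"] == first_bp && ex[nrow(ex), "end"] == last_bp
  }, logical(1))
  drop <- which(is_asn)[!full]
  assignments$status[drop] <- "rejected"
  assignments$reason[drop] <- "not_full_length"
  assignments$chain[drop] <- NA_character_
  assignments
}

#' Group assigned reads into isoforms and quantify them
#'
#' Reads with the identical consensus exon chain form one isoform. Isoforms
#' are ranked by read count (ties: longer first, then leftmost start) and
#' named `Iso1`, `Iso2`, ... in rank order; abundance is the percentage of
#' assigned reads.
#'
#' @param assignments output of [assign_reads()] (optionally after
#'   [filter_full_length()]).
#' @param display_min_percent abundance cut used by display methods only;
#'   never enters the quantification denominator.
#' @return A list of class `isoform_set`: `isoforms` data.frame
#'   (`isoform_id`, `chain`, `n_exons`, `length`, `read_count`, `percent`),
#'   `assignments` (input with an `isoform_id` column added), `n_assigned`,
#'   `n_rejected`, `rejections` (table of reasons), `display_min_percent`.
#' @export
group_and_quantify <- function(assignments, display_min_percent = 1) {
  asn <- assignments[assignments$status == "assigned", , drop = FALSE]
  n_assigned <- nrow(asn)
  n_rejected <- sum(assignments$status == "rejected")
  rejections <- table(assignments$reason[assignments$status == "rejected"])
  if (n_assigned == 0) {
    stop("no reads assigned to isoforms; rejections: ",
         paste(names(rejections), as.integer(rejections), sep = "=",
               collapse = ", "))
  }
  counts <- table(asn$chain)
  iso <- data.frame(chain = names(counts),
                    read_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  iso$n_exons <- vapply(iso$chain,
                        function(ch) nrow(chain_to_exons(ch)), integer(1))
  iso$length <- vapply(iso$chain, chain_length_nt, integer(1))
  first_start <- vapply(iso$chain,
                        function(ch) chain_to_exons(ch)[1, "start"],
                        integer(1))
  o <- order(-iso$read_count, -iso$length, first_start, iso$chain)
  iso <- iso[o, , drop = FALSE]
  iso$isoform_id <- paste0("Iso", seq_len(nrow(iso)))
  iso$percent <- 100 * iso$read_count / n_assigned
  iso <- iso[, c("isoform_id", "chain", "n_exons", "length", "read_count",
                 "percent")]
  rownames(iso) <- NULL
  assignments$isoform_id <- iso$isoform_id[match(assignments$chain,
                                                 iso$chain)]
  structure(list(isoforms = iso, assignments = assignments,
                 n_assigned = n_assigned, n_rejected = n_rejected,
                 rejections = rejections,
                 display_min_percent = display_min_percent),
            class = "isoform_set")
}

#' @export
print.isoform_set <- function(x, ...) {
  cat("Isoform set:", nrow(x$isoforms), "isoforms from", x$n_assigned,
      "assigned reads (", x$n_rejected, "rejected )\n")
  show <- x$isoforms[x$isoforms$percent >= x$display_min_percent, ,
                     drop = FALSE]
  print(show, row.names = FALSE)
  invisible(x)
}

#' Summarise distinct exons across isoforms
#'
#' @param isoforms an `isoform_set` or `locus_fit`.
#' @return data.frame with one row per distinct consensus exon: `start`,
#'   `end`, `length`, `n_isoforms` containing it and `read_support`
#'   (summed read counts of those isoforms).
#' @export
exon_summary <- function(isoforms) {
  if (inherits(isoforms, "locus_fit")) iso <- isoforms$isoforms
  else if (inherits(isoforms, "isoform_set")) iso <- isoforms$isoforms
  else iso <- isoforms
  if (nrow(iso) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_isoforms = integer(0),
                      read_support = integer(0)))
  rows <- do.call(rbind, lapply(seq_len(nrow(iso)), function(i) {
    ex <- chain_to_exons(iso$chain[i])
    data.frame(start = ex[, "start"], end = ex[, "end"],
               read_count = iso$read_count[i])
  }))
  key <- paste(rows$start, rows$end)
  agg <- do.call(rbind, lapply(split(rows, key), function(d) {
    data.frame(start = d$start[1], end = d$end[1],
               length = d$end[1] - d$start[1] + 1L,
               n_isoforms = nrow(d), read_support = sum(d$read_count))
  }))
  agg <- agg[order(agg$start, agg$end), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Detect and quantify isoforms at a locus
#'
#' The package's fitting function: runs the whole workflow on the aligned
#' reads of one reference — region restriction, consensus exon coordinate
#' detection, optional custom-coordinate injection, boundary assignment,
#' optional full-length filtering, and isoform grouping/quantification.
#' Fully deterministic for fixed input.
#'
#' @param reads a [read_set] (see [load_alignments()], [simulate_reads()]).
#' @param reference_id analyse only reads on this reference; required when
#'   the read set spans several references.
#' @param region optional `c(start, end)` analysis bounds; exons straddling
#'   an edge are clipped and anchored to a sentinel coordinate at the limit.
#' @param full_length_only keep only reads spanning from the outermost
#'   start coordinate to the outermost end coordinate.
#' @param params [detection_params()].
#' @param custom_cecs optional custom coordinates ([load_custom_cecs()]).
#' @param custom_mode `"merge"` or `"replace"` (see [apply_custom_cecs()]).
#' @param display_min_percent abundance cut used by print/plot only.
#' @return An object of class `locus_fit` with components `isoforms`,
#'   `cecs`, `assignments`, `freq`, `n_assigned`, `n_rejected`,
#'   `rejections`, `reference_id`, `region`, `params`. Methods: `print`,
#'   `summary`, `plot`, `coef` (named abundance percentages).
#' @export
#' @examples
#' sim <- simulate_reads(simulation_config(
#'   truth = list(A = list(chain = cbind(c(101, 301), c(200, 400)),
#'                         count = 30)),
#'   jitter = 0, seed = 1))
#' fit <- run_locus(sim$reads)
#' coef(fit)
run_locus <- function(reads, reference_id = NULL, region = NULL,
                      full_length_only = FALSE,
                      params = detection_params(),
                      custom_cecs = NULL, custom_mode = "merge",
                      display_min_percent = 1) {
  reads <- filter_reference(as_read_set(reads), reference_id)
  ref <- single_reference(reads)
  reads <- restrict_region(reads,
                           region_start = if (!is.null(region)) region[1],
                           region_end = if (!is.null(region)) region[2])
  outside <- attr(reads, "rejected")
  freq <- boundary_frequencies(reads)
  cecs <- detect_from_freq(freq, params)
  if (!is.null(custom_cecs))
    cecs <- apply_custom_cecs(cecs, custom_cecs, custom_mode, freq)
  cecs <- ensure_sentinels(cecs, reads, freq)
  asn <- assign_reads(reads, cecs)
  if (full_length_only) asn <- filter_full_length(asn, cecs)
  if (length(outside) > 0) {
    asn <- rbind(asn, data.frame(read_id = outside, status = "rejected",
                                 reason = "outside_region",
                                 chain = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  iso <- group_and_quantify(asn, display_min_percent)
  structure(list(
    isoforms = iso$isoforms, assignments = iso$assignments,
    cecs = cecs, freq = freq,
    n_assigned = iso$n_assigned, n_rejected = iso$n_rejected,
    rejections = iso$rejections,
    reference_id = ref, region = region,
    full_length_only = full_length_only, params = params,
    display_min_percent = display_min_percent,
    call = match.call()), class = "locus_fit")
}

#' @export
print.locus_fit <- function(x, ...) {
  cat("Locus isoform fit:", x$reference_id, "\n")
  cat(" ", x$n_assigned, "reads assigned,", x$n_rejected, "rejected",
      if (x$n_rejected > 0)
        paste0("(", paste(names(x$rejections), as.integer(x$rejections),
                          sep = "=", collapse = ", "), ")"), "\n")
  cat(" ", nrow(x$cecs$starts), "start /", nrow(x$cecs$ends),
      "end consensus coordinates;", nrow(x$isoforms), "isoforms\n")
  show <- x$isoforms[x$isoforms$percent >= x$display_min_percent, ,
                     drop = FALSE]
  print(show, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.locus_fit <- function(object, ...) {
  structure(list(fit = object, exons = exon_summary(object)),
            class = "summary.locus_fit")
}

#' @export
print.summary.locus_fit <- function(x, ...) {
  print(x$fit)
  cat("\nDistinct exons:\n")
  print(x$exons, row.names = FALSE)
  invisible(x)
}

#' @export
coef.locus_fit <- function(object, ...) {
  stats::setNames(object$isoforms$percent, object$isoforms$isoform_id)
}

#' Plot a locus fit
#'
#' Draws the detected isoform models (top) above the boundary frequency
#' peaks (bottom): exon starts in blue, exon ends in red, consensus
#' breakpoints marked with points. Only isoforms at or above
#' `display_min_percent` are drawn.
#'
#' @param x a `locus_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.locus_fit <- function(x, ...) {
  iso <- x$isoforms[x$isoforms$percent >= x$display_min_percent, ,
                    drop = FALSE]
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 8, 2, 1))
  on.exit(graphics::par(old))
  xlim <- range(c(x$freq$starts$pos, x$freq$ends$pos))
  graphics::plot(NA, xlim = xlim, ylim = c(0, nrow(iso) + 1), yaxt = "n",
                 xlab = "", ylab = "", main = x$reference_id, ...)
  if (nrow(iso) > 0) {
    for (i in seq_len(nrow(iso))) {
      ex <- chain_to_exons(iso$chain[i])
      y <- nrow(iso) - i + 1
      graphics::segments(min(ex[, "start"]), y, max(ex[, "end"]), y,
                         col = "grey60")
      graphics::rect(ex[, "start"], y - 0.3, ex[, "end"], y + 0.3,
                     col = "grey30", border = NA)
    }
    graphics::axis(2, at = rev(seq_len(nrow(iso))), las = 1,
                   labels = sprintf("%s (%.1f%%)", iso$isoform_id,
                                    iso$percent))
  }
  graphics::plot(NA, xlim = xlim,
                 ylim = c(0, max(x$freq$starts$percent,
                                 x$freq$ends$percent)),
                 xlab = "position", ylab = "% reads")
  graphics::segments(x$freq$starts$pos, 0, x$freq$starts$pos,
                     x$freq$starts$percent, col = "blue")
  graphics::segments(x$freq$ends$pos, 0, x$freq$ends$pos,
                     x$freq$ends$percent, col = "red")
  bp_pct <- function(cec, df) df$percent[match(cec$breakpoint, df$pos)]
  graphics::points(x$cecs$starts$breakpoint,
                   bp_pct(x$cecs$starts, x$freq$starts), col = "blue",
                   pch = 19)
  graphics::points(x$cecs$ends$breakpoint,
                   bp_pct(x$cecs$ends, x$freq$ends), col = "red", pch = 19)
  invisible(x)
}

#' Detected isoforms as a transcript set
#'
#' Converts a fit's isoforms to the `transcript_set` layout used by the
#' comparison functions, with `abundance` as a fraction of assigned reads.
#'
#' @param fit a `locus_fit`.
#' @param gene_id gene key for the comparison report; defaults to the
#'   reference id.
#' @return A `transcript_set`.
#' @export
as_transcript_set_fit <- function(fit, gene_id = fit$reference_id) {
  iso <- fit$isoforms
  if (nrow(iso) == 0)
    return(as_transcript_set(data.frame(
      transcript_id = character(0), gene_id = character(0),
      reference_id = character(0), start = integer(0), end = integer(0))))
  rows <- do.call(rbind, lapply(seq_len(nrow(iso)), function(i) {
    ex <- chain_to_exons(iso$chain[i])
    data.frame(transcript_id = iso$isoform_id[i], gene_id = gene_id,
               reference_id = fit$reference_id,
               start = ex[, "start"], end = ex[, "end"],
               abundance = iso$percent[i] / 100,
               stringsAsFactors = FALSE)
  }))
  as_transcript_set(rows)
}
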