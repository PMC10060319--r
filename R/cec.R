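#' Detection parameters for consensus exon coordinates
#'
#' Defaults mirror the standard configuration of locus-targeted long-read
#' isoform analysis: a boundary position seeds a candidate when more than 2%
#' of reads share it, candidates closer than 3 bases are merged into the
#' most frequent one, and each surviving candidate collects nearby
#' off-by-a-few boundaries within a window of 5 nt on both sides.
#'
#' @param read_threshold_percent minimum percentage of reads sharing a
#'   boundary position for it to become a candidate (strictly above).
#' @param window_nt half-width, in nucleotides, of the assignment window
#'   around each consensus breakpoint.
#' @param merge_distance_nt candidates at distance `<= merge_distance_nt`
#'   are merged into the most frequent one (set `merge_inclusive = FALSE`
#'   for a strict `<` comparison).
#' @param merge_inclusive logical; whether the merge distance is inclusive.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(read_threshold_percent = 2, window_nt = 5,
                             merge_distance_nt = 3, merge_inclusive = TRUE) {
  stopifnot(read_threshold_percent >= 0, window_nt >= 0,
            merge_distance_nt >= 0, is.logical(merge_inclusive))
  structure(list(read_threshold_percent = read_threshold_percent,
                 window_nt = as.integer(window_nt),
                 merge_distance_nt = as.integer(merge_distance_nt),
                 merge_inclusive = merge_inclusive),
            class = "detection_params")
}

#' Boundary frequency table
#'
#' Counts, separately for exon starts and exon ends, how many reads have a
#' boundary at each reference position; percentages are relative to the
#' number of reads analysed. A read with k exons contributes k start and k
#' end positions.
#'
#' @param reads a [read_set].
#' @return A list of class `boundary_freq` with elements `starts` and `ends`
#'   (data.frames `pos`, `count`, `percent`, position-sorted) and
#'   `total_reads`.
#' @export
boundary_frequencies <- function(reads) {
  if (nrow(reads) == 0) stop("no reads to analyse")
  total <- n_reads(reads)
  tab <- function(pos) {
    t <- table(pos)
    df <- data.frame(pos = as.integer(names(t)), count = as.integer(t))
    df <- df[order(df$pos), , drop = FALSE]
    df$percent <- 100 * df$count / total
    rownames(df) <- NULL
    df
  }
  structure(list(starts = tab(reads$start), ends = tab(reads$end),
                 total_reads = total),
            class = "boundary_freq")
}

#' Select candidate consensus positions by frequency
#'
#' A position is a candidate iff its percentage of reads is strictly above
#' the threshold, independently per side.
#'
#' @param freq a `boundary_freq` table.
#' @param threshold percentage of reads.
#' @return list with integer vectors `starts` and `ends`.
#' @export
select_candidates <- function(freq, threshold = 2) {
  pick <- function(df) df$pos[df$percent > threshold]
  list(starts = pick(freq$starts), ends = pick(freq$ends))
}

# single-linkage clusters of sorted positions with gaps <= / < d;
# representative = most frequent member, ties to the smaller coordinate
merge_side <- function(pos, counts, d, inclusive) {
  if (length(pos) <= 1) return(pos)
  o <- order(pos)
  pos <- pos[o]; counts <- counts[o]
  gap <- diff(pos)
  brk <- if (inclusive) gap > d else gap >= d
  grp <- cumsum(c(TRUE, brk))
  out <- vapply(split(seq_along(pos), grp), function(idx) {
    cmax <- max(counts[idx])
    min(pos[idx][counts[idx] == cmax])
  }, integer(1))
  unname(sort(out))
}

#' Merge close candidate positions
#'
#' Candidate positions on one side that form a chain with consecutive gaps
#' at most `merge_distance` apart collapse to the most frequent member of
#' the chain (frequency ties go to the smaller coordinate).
#'
#' @param candidates list with `starts` and `ends` position vectors.
#' @param freq the `boundary_freq` the candidates came from.
#' @param merge_distance distance in nt.
#' @param inclusive whether `|a-b| == merge_distance` triggers merging.
#' @return list with merged `starts` and `ends`.
#' @export
merge_close_candidates <- function(candidates, freq, merge_distance = 3,
                                   inclusive = TRUE) {
  cnt <- function(df, pos) df$count[match(pos, df$pos)]
  list(
    starts = merge_side(candidates$starts, cnt(freq$starts, candidates$starts),
                        merge_distance, inclusive),
    ends = merge_side(candidates$ends, cnt(freq$ends, candidates$ends),
                      merge_distance, inclusive)
  )
}

# windows [b-w, b+w], truncated at the midpoint where neighbours collide;
# an exactly equidistant position joins the more frequent candidate,
# frequency ties go to the left one
window_side <- function(bp, counts, w) {
  k <- length(bp)
  if (k == 0)
    return(data.frame(breakpoint = integer(0), lower = integer(0),
                      upper = integer(0)))
  lower <- bp - w
  upper <- bp + w
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      if (upper[i] >= lower[i + 1]) {
        s <- bp[i] + bp[i + 1]
        if (s %% 2 == 1) {
          u1 <- (s - 1) %/% 2
        } else {
          m <- s %/% 2
          u1 <- if (counts[i] >= counts[i + 1]) m else m - 1L
        }
        upper[i] <- min(upper[i], u1)
        lower[i + 1] <- max(lower[i + 1], u1 + 1L)
      }
    }
  }
  data.frame(breakpoint = as.integer(bp), lower = as.integer(lower),
             upper = as.integer(upper))
}

#' Build consensus coordinate windows around merged candidates
#'
#' Each candidate becomes a consensus exon coordinate (CEC) with an
#' assignment window of `window` nt on both sides. Overlapping windows of
#' adjacent candidates are truncated at their midpoint so that windows stay
#' pairwise disjoint; an exactly equidistant position is given to the more
#' frequent candidate, with frequency ties going to the left one.
#' `reads_at_breakpoint` is the boundary count at the breakpoint itself and
#' `reads_in_interval` the summed counts over the final window.
#'
#' @param candidates list with `starts`/`ends` merged candidate positions.
#' @param freq the `boundary_freq` table.
#' @param window half-width in nt.
#' @param params optional `detection_params` to record on the result.
#' @return A `cec_set`.
#' @export
build_windows <- function(candidates, freq, window = 5, params = NULL) {
  cnt <- function(df, pos) {
    x <- df$count[match(pos, df$pos)]
    x[is.na(x)] <- 0L
    x
  }
  side <- function(pos, df) {
    cec <- window_side(pos, cnt(df, pos), window)
    recount_side(cec, df)
  }
  if (is.null(params))
    params <- detection_params(window_nt = window)
  new_cec_set(side(candidates$starts, freq$starts),
              side(candidates$ends, freq$ends), params)
}

# fill count columns of one side from a frequency data.frame
recount_side <- function(cec, df) {
  if (nrow(cec) == 0) {
    cec$reads_at_breakpoint <- integer(0)
    cec$reads_in_interval <- integer(0)
    return(cec)
  }
  atbp <- df$count[match(cec$breakpoint, df$pos)]
  atbp[is.na(atbp)] <- 0L
  cec$reads_at_breakpoint <- atbp
  cec$reads_in_interval <- vapply(seq_len(nrow(cec)), function(i) {
    sum(df$count[df$pos >= cec$lower[i] & df$pos <= cec$upper[i]])
  }, integer(1))
  cec
}

new_cec_set <- function(starts, ends, params) {
  x <- structure(list(starts = starts, ends = ends, params = params),
                 class = "cec_set")
  validate_cec_set(x)
}

#' Validate a consensus coordinate set
#'
#' Checks, per side, that `lower <= breakpoint <= upper`, breakpoints are
#' strictly increasing and windows are pairwise disjoint.
#'
#' @param x a `cec_set`.
#' @return `x`, invisibly on success; error otherwise.
#' @export
validate_cec_set <- function(x) {
  for (s in c("starts", "ends")) {
    cec <- x[[s]]
    cec <- cec[order(cec$breakpoint), , drop = FALSE]
    rownames(cec) <- NULL
    if (nrow(cec) > 0) {
      if (any(cec$lower > cec$breakpoint | cec$upper < cec$breakpoint))
        stop("window does not contain its breakpoint (", s, ")")
      if (any(duplicated(cec$breakpoint)))
        stop("duplicate breakpoints on side ", s)
      if (nrow(cec) > 1 && any(cec$lower[-1] <= cec$upper[-nrow(cec)]))
        stop("overlapping windows on side ", s)
    }
    x[[s]] <- cec
  }
  x
}

#' @export
print.cec_set <- function(x, ...) {
  cat("Consensus exon coordinates:", nrow(x$starts), "starts,",
      nrow(x$ends), "ends\n")
  cat("Starts:\n"); print(x$starts)
  cat("Ends:\n"); print(x$ends)
  invisible(x)
}

#' Detect consensus exon coordinates from reads
#'
#' The full three-rule procedure: boundary frequencies, strict frequency
#' threshold, single-linkage merging of close candidates into the most
#' frequent one, and construction of disjoint assignment windows.
#' Deterministic for fixed input.
#'
#' @param reads a [read_set].
#' @param params a [detection_params()] list.
#' @return A `cec_set`.
#' @export
#' @examples
#' r <- read_set(rep(c("a","b","c"), each = 1), "amp",
#'               start = c(100, 100, 102), end = c(200, 200, 200))
#' detect_cecs(r)
detect_cecs <- function(reads, params = detection_params()) {
  detect_from_freq(boundary_frequencies(reads), params)
}

detect_from_freq <- function(freq, params) {
  cand <- select_candidates(freq, params$read_threshold_percent)
  cand <- merge_close_candidates(cand, freq, params$merge_distance_nt,
                                 params$merge_inclusive)
  build_windows(cand, freq, params$window_nt, params)
}

#' Inject custom consensus coordinates
#'
#' In `replace` mode the result contains only the custom coordinates. In
#' `merge` mode automatically detected coordinates whose window overlaps a
#' custom window are dropped in favour of the custom one, and the rest are
#' kept. Counts are recomputed from the frequency table when given.
#'
#' @param auto a `cec_set` from [detect_cecs()].
#' @param custom list with `starts`/`ends` data.frames
#'   (`breakpoint`, `lower`, `upper`), e.g. from [load_custom_cecs()].
#' @param mode `"merge"` or `"replace"`.
#' @param freq optional `boundary_freq` used to recompute counts.
#' @return A `cec_set`.
#' @export
apply_custom_cecs <- function(auto, custom, mode = c("merge", "replace"),
                              freq = NULL) {
  mode <- match.arg(mode)
  side_cols <- c("breakpoint", "lower", "upper")
  combine <- function(auto_df, cust_df) {
    cust_df <- cust_df[order(cust_df$breakpoint), , drop = FALSE]
    if (nrow(cust_df) > 1 &&
        any(cust_df$lower[-1] <= cust_df$upper[-nrow(cust_df)]))
      stop("custom windows overlap each other")
    if (mode == "replace" || nrow(auto_df) == 0) {
      out <- cust_df[, side_cols, drop = FALSE]
    } else {
      keep <- vapply(seq_len(nrow(auto_df)), function(i) {
        !any(auto_df$lower[i] <= cust_df$upper &
             auto_df$upper[i] >= cust_df$lower)
      }, logical(1))
      out <- rbind(auto_df[keep, side_cols, drop = FALSE],
                   cust_df[, side_cols, drop = FALSE])
    }
    out <- out[order(out$breakpoint), , drop = FALSE]
    rownames(out) <- NULL
    out$reads_at_breakpoint <- rep(NA_integer_, nrow(out))
    out$reads_in_interval <- rep(NA_integer_, nrow(out))
    out
  }
  res <- new_cec_set(combine(auto$starts, custom$starts),
                     combine(auto$ends, custom$ends), auto$params)
  if (!is.null(freq)) res <- recount_cecs(res, freq)
  res
}

recount_cecs <- function(cecs, freq) {
  cecs$starts <- recount_side(cecs$starts, freq$starts)
  cecs$ends <- recount_side(cecs$ends, freq$ends)
  cecs
}

#' Edit a consensus coordinate set programmatically
#'
#' Adds, deletes or updates one consensus coordinate. Any edit invalidates
#' downstream isoforms: rerun assignment/quantification (e.g. [run_locus()])
#' on the edited set.
#'
#' @param set a `cec_set`.
#' @param action `"add"`, `"delete"` or `"update"`.
#' @param side `"start"` or `"end"`.
#' @param breakpoint position of the coordinate to add/delete/update.
#' @param lower,upper window limits (default: degenerate window at the
#'   breakpoint for `add`; unchanged for `update` when omitted).
#' @param freq optional `boundary_freq` used to recompute counts.
#' @return A new, validated `cec_set`.
#' @export
edit_cec_set <- function(set, action = c("add", "delete", "update"),
                         side = c("start", "end"), breakpoint,
                         lower = NULL, upper = NULL, freq = NULL) {
  action <- match.arg(action)
  side <- match.arg(side)
  key <- if (side == "start") "starts" else "ends"
  df <- set[[key]]
  i <- match(breakpoint, df$breakpoint)
  if (action == "add") {
    if (!is.na(i)) stop("breakpoint ", breakpoint, " already present")
    if (is.null(lower)) lower <- breakpoint
    if (is.null(upper)) upper <- breakpoint
    df <- rbind(df, data.frame(breakpoint = as.integer(breakpoint),
                               lower = as.integer(lower),
                               upper = as.integer(upper),
                               reads_at_breakpoint = NA_integer_,
                               reads_in_interval = NA_integer_))
  } else {
    if (is.na(i)) stop("no ", side, " coordinate at breakpoint ", breakpoint)
    if (action == "delete") {
      df <- df[-i, , drop = FALSE]
    } else {
      if (!is.null(lower)) df$lower[i] <- as.integer(lower)
      if (!is.null(upper)) df$upper[i] <- as.integer(upper)
      df$reads_at_breakpoint[i] <- NA_integer_
      df$reads_in_interval[i] <- NA_integer_
    }
  }
  set[[key]] <- df
  res <- new_cec_set(set$starts, set$ends, set$params)
  if (!is.null(freq)) res <- recount_cecs(res, freq)
  res
}
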