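#' Construct a read set
#'
#' A read set is the package's container for aligned long reads at a single
#' locus: one row per exon, reads identified by `read_id` and kept in exon
#' coordinate order. Coordinates are 1-based inclusive on the forward strand
#' of the reference (GFF3 convention); BED input is converted on load.
#'
#' @param read_id character vector, one entry per exon row.
#' @param reference_id character vector (typically a single repeated value).
#' @param start,end integer vectors of 1-based inclusive exon coordinates.
#' @param start_clipped,end_clipped logical; whether the boundary was created
#'   by clipping an exon at an analysis-region edge (see [restrict_region()]).
#'
#' @return A `data.frame` of class `read_set` with columns `read_id`,
#'   `reference_id`, `start`, `end`, `start_clipped`, `end_clipped`.
#' @seealso [load_alignments()], [simulate_reads()]
#' @export
#' @examples
#' read_set(read_id = c("r1", "r1"), reference_id = "amp",
#'          start = c(100L, 300L), end = c(200L, 400L))
read_set <- function(read_id, reference_id, start, end,
                     start_clipped = FALSE, end_clipped = FALSE) {
  df <- data.frame(
    read_id = as.character(read_id),
    reference_id = as.character(reference_id),
    start = as.integer(start),
    end = as.integer(end),
    start_clipped = rep_len(as.logical(start_clipped), length(read_id)),
    end_clipped = rep_len(as.logical(end_clipped), length(read_id)),
    stringsAsFactors = FALSE
  )
  as_read_set(df)
}

#' Coerce a data frame to a read set, validating invariants
#'
#' Checks that every read's exons are non-empty, have `start <= end`, and are
#' strictly ordered and non-overlapping along the reference.
#'
#' @param x a data.frame with at least `read_id`, `reference_id`, `start`,
#'   `end` columns.
#' @return The input with class `read_set`, rows sorted by read and start.
#' @export
as_read_set <- function(x) {
  req <- c("read_id", "reference_id", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("read set is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(x$start_clipped)) x$start_clipped <- FALSE
  if (is.null(x$end_clipped)) x$end_clipped <- FALSE
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x <- x[order(x$read_id, x$start), , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) > 0) {
    if (any(x$start > x$end))
      stop("exon with start > end for read ",
           x$read_id[which(x$start > x$end)[1]])
    same <- x$read_id[-1] == x$read_id[-nrow(x)]
    bad <- which(same & x$start[-1] <= x$end[-nrow(x)])
    if (length(bad) > 0)
      stop("overlapping or unordered exons for read ", x$read_id[bad[1] + 1])
  }
  class(x) <- unique(c("read_set", class(x)))
  x
}

#' @export
print.read_set <- function(x, ...) {
  n_reads <- length(unique(x$read_id))
  cat("Read set:", n_reads, "reads,", nrow(x), "exons on",
      paste(unique(x$reference_id), collapse = ", "), "\n")
  NextMethod()
}

# number of distinct reads
n_reads <- function(reads) length(unique(reads$read_id))

# keep reads mapped to one reference; error with the available ones if absent
filter_reference <- function(reads, reference_id) {
  if (is.null(reference_id)) return(reads)
  keep <- reads$reference_id == reference_id
  if (!any(keep)) {
    stop("no reads on reference '", reference_id, "'; available: ",
         paste(unique(reads$reference_id), collapse = ", "))
  }
  as_read_set(reads[keep, , drop = FALSE])
}

# single reference or error (analysis is one locus at a time)
single_reference <- function(reads) {
  refs <- unique(reads$reference_id)
  if (length(refs) != 1)
    stop("reads span several references (", paste(refs, collapse = ", "),
         "); select one with reference_id")
  refs
}
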