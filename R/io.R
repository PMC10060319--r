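#' Convert a CIGAR string to exon intervals
#'
#' Walks the reference cursor of an alignment and splits it into exons at `N`
#' (intron/skip) operations only. `M`, `=`, `X` and `D` consume reference
#' without opening a new exon — spliced aligners run with splice-aware
#' presets encode introns as `N`, so a deletion of any length stays inside
#' its exon. `I`, `S` and `H` consume no reference.
#'
#' @param alignment_start 1-based leftmost reference position of the
#'   alignment.
#' @param cigar CIGAR string using operations `M/I/D/N/S/H/=/X`.
#' @return Integer matrix with columns `start`, `end` (1-based inclusive),
#'   one row per exon.
#' @export
#' @examples
#' cigar_to_exons(100, "20M100N30M")  # two exons split at the N gap
cigar_to_exons <- function(alignment_start, cigar) {
  if (!is.character(cigar) || length(cigar) != 1 || is.na(cigar) ||
      !grepl("^([0-9]+[MIDNSHX=])+$", cigar))
    stop("malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHX=]", cigar))[[1]]
  pos <- as.integer(alignment_start)
  exon_start <- NA_integer_
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_along(ops)) {
    op <- ops[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(exon_start)) exon_start <- pos
      pos <- pos + lens[i]
    } else if (op == "N") {
      if (!is.na(exon_start)) {
        starts <- c(starts, exon_start)
        ends <- c(ends, pos - 1L)
        exon_start <- NA_integer_
      }
      pos <- pos + lens[i]
    }
    # I/S/H: no reference consumed
  }
  if (!is.na(exon_start)) {
    starts <- c(starts, exon_start)
    ends <- c(ends, pos - 1L)
  }
  cbind(start = starts, end = ends)
}

#' Load aligned reads for a locus
#'
#' Reads pre-aligned long reads from BAM, GFF3 or BED6 into a [read_set].
#' For BAM, only primary mapped alignments are kept (unmapped, secondary and
#' supplementary records are dropped) and exon chains are derived from the
#' CIGAR by splitting at `N` operations. For GFF3, `exon` features are
#' grouped into one read per `Parent` (or `ID`/`transcript_id`) value. For
#' BED6 (0-based half-open, converted on input), lines sharing the name
#' column are the exons of one read.
#'
#' @param path input file.
#' @param format one of `"bam"`, `"gff3"`, `"bed6"`; defaults to a guess
#'   from the file extension.
#' @param reference_id optional: keep only reads mapped to this reference.
#' @return A [read_set].
#' @export
load_alignments <- function(path, format = c("bam", "gff3", "bed6"),
                            reference_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bam = "bam", sam = "bam", bed = "bed6",
                     bed6 = "bed6", gff = "gff3", gff3 = "gff3",
                     stop("cannot guess alignment format from extension '",
                          ext, "'"))
  }
  format <- match.arg(format)
  reads <- switch(format,
    bam = load_alignments_bam(path),
    gff3 = load_alignments_gff3(path),
    bed6 = load_alignments_bed6(path)
  )
  filter_reference(reads, reference_id)
}

load_alignments_bam <- function(path) {
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "cigar"))
  rec <- Rsamtools::scanBam(path, param = param)[[1]]
  if (length(rec$qname) == 0)
    return(read_set(character(0), character(0), integer(0), integer(0)))
  chunks <- lapply(seq_along(rec$qname), function(i) {
    ex <- cigar_to_exons(rec$pos[i], rec$cigar[i])
    data.frame(read_id = rec$qname[i],
               reference_id = as.character(rec$rname[i]),
               start = ex[, "start"], end = ex[, "end"],
               stringsAsFactors = FALSE)
  })
  as_read_set(do.call(rbind, chunks))
}

load_alignments_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("cannot parse GFF3 '", path,
                                          "': ", conditionMessage(e)))
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0)
    return(read_set(character(0), character(0), integer(0), integer(0)))
  id <- gff_group_id(gr)
  as_read_set(data.frame(
    read_id = id,
    reference_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

load_alignments_bed6 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) stop("cannot parse BED '", path,
                                          "': ", conditionMessage(e)))
  if (length(gr) == 0)
    return(read_set(character(0), character(0), integer(0), integer(0)))
  nm <- gr$name
  if (is.null(nm) || anyNA(nm))
    nm <- paste0("read", seq_along(gr))
  as_read_set(data.frame(
    read_id = as.character(nm),
    reference_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

# grouping id for exon features: Parent, else transcript_id, else ID
gff_group_id <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$Parent)) {
    p <- as.character(S4Vectors::unstrsplit(
      methods::as(mc$Parent, "CharacterList"), ","))
    if (!all(p == "" | is.na(p))) return(p)
  }
  if (!is.null(mc$transcript_id)) return(as.character(mc$transcript_id))
  if (!is.null(mc$ID)) return(as.character(mc$ID))
  stop("exon features carry no Parent/transcript_id/ID attribute to group by")
}

#' Construct or validate a transcript set
#'
#' A transcript set holds reference transcript models (e.g. a GTF/GFF3
#' annotation, or this package's detected isoforms) as one row per exon with
#' `transcript_id`, `gene_id`, optional `label` and optional `abundance`
#' (fraction of its gene).
#'
#' @param x data.frame with columns `transcript_id`, `gene_id`,
#'   `reference_id`, `start`, `end` and optionally `label`, `abundance`.
#' @return `x` with class `transcript_set`, exons coordinate-sorted within
#'   transcript.
#' @export
as_transcript_set <- function(x) {
  req <- c("transcript_id", "reference_id", "start", "end")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop("transcript set is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(x$gene_id)) x$gene_id <- NA_character_
  if (is.null(x$label)) x$label <- NA_character_
  if (is.null(x$abundance)) x$abundance <- NA_real_
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x <- x[order(x$transcript_id, x$start), , drop = FALSE]
  rownames(x) <- NULL
  if (nrow(x) > 0) {
    if (any(x$start > x$end)) stop("transcript exon with start > end")
    same <- x$transcript_id[-1] == x$transcript_id[-nrow(x)]
    if (any(same & x$start[-1] <= x$end[-nrow(x)]))
      stop("overlapping exons within one transcript")
  }
  class(x) <- unique(c("transcript_set", class(x)))
  x
}

#' Load a transcript annotation (GTF or GFF3)
#'
#' Exon features are grouped into transcripts by `transcript_id` (GTF) or
#' `Parent` (GFF3); exons are returned coordinate-sorted regardless of line
#' order in the file. A free-text `label` attribute, when present, is kept
#' for display.
#'
#' @param path GTF or GFF3 file.
#' @param format `"gtf"` or `"gff3"`; guessed from the extension by default.
#' @return A `transcript_set` data.frame (one row per exon).
#' @export
load_transcript_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "gtf") "gtf" else "gff3"
  }
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e) stop("cannot parse ", format, " '",
                                          path, "': ", conditionMessage(e)))
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0)
    return(as_transcript_set(data.frame(
      transcript_id = character(0), gene_id = character(0),
      reference_id = character(0), start = integer(0), end = integer(0))))
  mc <- S4Vectors::mcols(gr)
  tid <- if (!is.null(mc$transcript_id) && !anyNA(mc$transcript_id))
    as.character(mc$transcript_id) else gff_group_id(gr)
  gid <- if (!is.null(mc$gene_id)) as.character(mc$gene_id) else NA_character_
  lab <- if (!is.null(mc$label)) as.character(mc$label) else NA_character_
  ab <- if (!is.null(mc$abundance))
    suppressWarnings(as.numeric(mc$abundance)) else NA_real_
  as_transcript_set(data.frame(
    transcript_id = tid, gene_id = gid,
    reference_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    label = lab, abundance = ab, stringsAsFactors = FALSE))
}

#' Load custom consensus coordinates from a TSV file
#'
#' The file must have columns `side` (`start` or `end`), `breakpoint`,
#' `lower`, `upper`. Windows may overlap at load time; overlap resolution
#' happens in [apply_custom_cecs()].
#'
#' @param path TSV file.
#' @return A list with `starts` and `ends` data.frames of consensus
#'   coordinates (counts unset; they are recomputed against the data).
#' @export
load_custom_cecs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("side", "breakpoint", "lower", "upper")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("custom coordinate table is missing columns: ",
         paste(miss, collapse = ", "))
  if (!all(tab$side %in% c("start", "end")))
    stop("side must be 'start' or 'end' (row ",
         which(!tab$side %in% c("start", "end"))[1], ")")
  bad <- which(tab$lower > tab$breakpoint | tab$upper < tab$breakpoint)
  if (length(bad) > 0)
    stop("row ", bad[1], ": window [", tab$lower[bad[1]], ",",
         tab$upper[bad[1]], "] does not contain breakpoint ",
         tab$breakpoint[bad[1]])
  mk <- function(side) {
    d <- tab[tab$side == side, , drop = FALSE]
    data.frame(breakpoint = as.integer(d$breakpoint),
               lower = as.integer(d$lower), upper = as.integer(d$upper),
               reads_at_breakpoint = NA_integer_,
               reads_in_interval = NA_integer_)
  }
  list(starts = mk("start"), ends = mk("end"))
}

#' Write result tables for a fitted locus
#'
#' Emits `<prefix>_isoforms.gtf` (one transcript plus exon features per
#' isoform, with read count and abundance attributes),
#' `<prefix>_cec_start.tsv` / `<prefix>_cec_end.tsv` (consensus coordinate
#' tables), `<prefix>_read_assignments.tsv` (per-read isoform or rejection
#' reason) and `<prefix>_isoform_table.tsv`.
#'
#' @param fit a `locus_fit` from [run_locus()].
#' @param prefix output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(fit, prefix) {
  stopifnot(inherits(fit, "locus_fit"))
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("cannot write to directory: ", dir)
  files <- c(
    gtf = paste0(prefix, "_isoforms.gtf"),
    cec_start = paste0(prefix, "_cec_start.tsv"),
    cec_end = paste0(prefix, "_cec_end.tsv"),
    assignments = paste0(prefix, "_read_assignments.tsv"),
    table = paste0(prefix, "_isoform_table.tsv")
  )
  write_isoform_gtf(fit, files[["gtf"]])
  cec_cols <- c("breakpoint", "lower", "upper", "reads_at_breakpoint",
                "reads_in_interval")
  utils::write.table(fit$cecs$starts[, cec_cols], files[["cec_start"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$cecs$ends[, cec_cols], files[["cec_end"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  asn <- fit$assignments[, c("read_id", "isoform_id", "status", "reason")]
  utils::write.table(asn, files[["assignments"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  iso <- fit$isoforms[, c("isoform_id", "chain", "n_exons", "length",
                          "read_count", "percent")]
  utils::write.table(iso, files[["table"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(files)
}

write_isoform_gtf <- function(fit, path) {
  iso <- fit$isoforms
  if (nrow(iso) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ref <- fit$reference_id
  rows <- lapply(seq_len(nrow(iso)), function(i) {
    ex <- chain_to_exons(iso$chain[i])
    data.frame(
      seqnames = ref,
      start = c(min(ex[, "start"]), ex[, "start"]),
      end = c(max(ex[, "end"]), ex[, "end"]),
      type = c("transcript", rep("exon", nrow(ex))),
      transcript_id = iso$isoform_id[i],
      gene_id = ref,
      read_count = iso$read_count[i],
      abundance = iso$percent[i] / 100,
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    df$seqnames, IRanges::IRanges(df$start, df$end), strand = "+",
    type = df$type, source = "isoquantr",
    transcript_id = df$transcript_id, gene_id = df$gene_id,
    read_count = df$read_count, abundance = df$abundance)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
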