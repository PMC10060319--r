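# exonic base set of one transcript as a reduced IRanges
transcript_ranges <- function(x) {
  IRanges::reduce(IRanges::IRanges(x$start, x$end))
}

#' Reciprocal base overlap of two transcripts
#'
#' The intersection of the two exonic base sets, expressed as a fraction of
#' each transcript's own exonic bases.
#'
#' @param a,b exon tables for one transcript each (data.frames with
#'   `start`/`end`, e.g. one transcript's rows of a `transcript_set`).
#' @return numeric `c(frac_a, frac_b)`, both in `[0, 1]`.
#' @export
#' @examples
#' a <- data.frame(start = 1, end = 100)
#' b <- data.frame(start = c(1, 201), end = c(100, 210))
#' reciprocal_overlap(a, b)  # 1.0 and 100/110
reciprocal_overlap <- function(a, b) {
  ra <- if (!is.null(a$reference_id)) unique(a$reference_id) else NULL
  rb <- if (!is.null(b$reference_id)) unique(b$reference_id) else NULL
  if (!is.null(ra) && !is.null(rb) && !identical(ra, rb))
    stop("transcripts are on different references: ", ra, " vs ", rb)
  ia <- transcript_ranges(a)
  ib <- transcript_ranges(b)
  inter <- sum(IRanges::width(IRanges::intersect(ia, ib)))
  c(frac_a = inter / sum(IRanges::width(ia)),
    frac_b = inter / sum(IRanges::width(ib)))
}

#' Match detected isoforms against a gold annotation
#'
#' Gold transcripts whose mutual reciprocal overlap is strictly above
#' `min_frac` on both fractions are first merged into indistinguishable
#' groups (the comparison cannot tell them apart). A detected isoform is a
#' true positive when both reciprocal overlap fractions with some member of
#' a gold group exceed `min_frac`; matching is one-to-one, greedy by best
#' mean overlap.
#'
#' @param detected,gold `transcript_set` data.frames on one reference
#'   (or per-gene slices of one).
#' @param min_frac reciprocal overlap threshold (strict `>`), default 0.99.
#' @return A list of class `match_result`: `matches` (data.frame
#'   `detected_id`, `gold_group`, `frac_detected`, `frac_gold`),
#'   `gold_groups` (named list of member transcript ids),
#'   `unmatched_detected`, `unmatched_gold`.
#' @export
match_isoforms <- function(detected, gold, min_frac = 0.99) {
  stopifnot(min_frac > 0, min_frac <= 1)
  # strict "more than min_frac"; at min_frac = 1 only base-identity passes
  qualifies <- function(ov) {
    all(ov > min_frac) || (min_frac == 1 && all(ov == 1))
  }
  gsplit <- split(gold, gold$transcript_id)
  dsplit <- split(detected, detected$transcript_id)
  gid <- names(gsplit)
  # merge indistinguishable gold transcripts (union-find components)
  parent <- seq_along(gid)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(gid) > 1) {
    for (i in seq_len(length(gid) - 1)) {
      for (j in seq(i + 1, length(gid))) {
        same_ref <- identical(unique(gsplit[[i]]$reference_id),
                              unique(gsplit[[j]]$reference_id))
        if (same_ref) {
          ov <- reciprocal_overlap(gsplit[[i]], gsplit[[j]])
          if (qualifies(ov)) {
            a <- find(i); b <- find(j)
            if (a != b) parent[max(a, b)] <- min(a, b)
          }
        }
      }
    }
  }
  comp <- vapply(seq_along(gid), find, integer(1))
  groups <- lapply(split(gid, comp), sort)
  names(groups) <- vapply(groups, paste, "", collapse = "+")

  # candidate (detected, group) pairs: best qualifying member overlap
  cand <- list()
  for (d in names(dsplit)) {
    for (g in names(groups)) {
      best <- NULL
      for (m in groups[[g]]) {
        same_ref <- identical(unique(dsplit[[d]]$reference_id),
                              unique(gsplit[[m]]$reference_id))
        if (!same_ref) next
        ov <- reciprocal_overlap(dsplit[[d]], gsplit[[m]])
        if (qualifies(ov) &&
            (is.null(best) || mean(ov) > best$score))
          best <- list(score = mean(ov), ov = ov)
      }
      if (!is.null(best))
        cand[[length(cand) + 1]] <- list(d = d, g = g, score = best$score,
                                         ov = best$ov)
    }
  }
  matches <- data.frame(detected_id = character(0), gold_group = character(0),
                        frac_detected = numeric(0), frac_gold = numeric(0))
  if (length(cand) > 0) {
    ord <- order(-vapply(cand, `[[`, 0, "score"),
                 vapply(cand, `[[`, "", "d"))
    used_d <- character(0); used_g <- character(0)
    for (k in ord) {
      ck <- cand[[k]]
      if (ck$d %in% used_d || ck$g %in% used_g) next
      used_d <- c(used_d, ck$d); used_g <- c(used_g, ck$g)
      matches <- rbind(matches, data.frame(
        detected_id = ck$d, gold_group = ck$g,
        frac_detected = unname(ck$ov[1]), frac_gold = unname(ck$ov[2])))
    }
  }
  structure(list(
    matches = matches, gold_groups = groups,
    unmatched_detected = setdiff(names(dsplit), matches$detected_id),
    unmatched_gold = setdiff(names(groups), matches$gold_group)),
    class = "match_result")
}

#' Cosine similarity of two nonnegative abundance vectors
#'
#' @param u,v numeric vectors of equal length, not both zero.
#' @return `u.v / (|u||v|)`, in `[0, 1]` for nonnegative inputs.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' Compare detected isoforms with an equimolar gold standard
#'
#' For each gene, gold transcripts are merged into indistinguishable groups
#' (see [match_isoforms()]) and given equimolar shares (a merged group's
#' share is the sum of its members'). Matched detected isoforms place their
#' abundance at the gold group's index; unmatched gold groups get 0. The
#' report carries per-gene cosine similarities, an overall cosine over the
#' concatenated per-gene vectors, and detection counts under both group and
#' transcript-unit conventions.
#'
#' @param detected a `transcript_set` with `gene_id` and `abundance`
#'   (fraction of its gene).
#' @param gold a `transcript_set` with `gene_id`; treated as equimolar
#'   unless it carries its own `abundance` values.
#' @param min_frac reciprocal overlap threshold, default 0.99.
#' @return A list of class `comparison_report`: `per_gene` data.frame
#'   (`gene_id`, `n_gold`, `n_groups`, `n_detected`, `cosine`),
#'   `overall_cosine`, `detection_count` (matched gold groups),
#'   `detection_count_units` (transcripts inside matched groups),
#'   `n_gold_groups`, `n_gold_transcripts`, `matches` (per-gene
#'   `match_result`s).
#' @export
build_report <- function(detected, gold, min_frac = 0.99) {
  genes <- unique(gold$gene_id)
  per_gene <- list()
  match_list <- list()
  gold_all <- numeric(0)
  det_all <- numeric(0)
  for (g in genes) {
    gg <- gold[gold$gene_id == g, , drop = FALSE]
    dd <- detected[detected$gene_id == g, , drop = FALSE]
    mr <- match_isoforms(dd, gg, min_frac)
    match_list[[g]] <- mr
    n_tx <- length(unique(gg$transcript_id))
    grp <- mr$gold_groups
    # per-transcript gold shares: stated abundances when present,
    # equimolar otherwise; a merged group's share is the sum of members'
    first <- gg[!duplicated(gg$transcript_id), , drop = FALSE]
    share <- first$abundance[match(unlist(grp), first$transcript_id)]
    if (anyNA(share)) share <- rep(1 / n_tx, length(unlist(grp)))
    gold_vec <- vapply(split(share, rep(seq_along(grp), lengths(grp))),
                       sum, 0)
    names(gold_vec) <- names(grp)
    det_vec <- rep(0, length(grp))
    names(det_vec) <- names(grp)
    if (nrow(mr$matches) > 0) {
      ab <- vapply(mr$matches$detected_id, function(d) {
        a <- dd$abundance[dd$transcript_id == d][1]
        if (is.na(a)) 0 else a
      }, 0)
      det_vec[mr$matches$gold_group] <- ab
    }
    cos <- if (sum(det_vec) > 0) cosine_similarity(gold_vec, det_vec)
           else NA_real_
    per_gene[[g]] <- data.frame(
      gene_id = g, n_gold = n_tx, n_groups = length(grp),
      n_detected = nrow(mr$matches), cosine = cos,
      stringsAsFactors = FALSE)
    gold_all <- c(gold_all, gold_vec)
    det_all <- c(det_all, det_vec)
  }
  per_gene <- do.call(rbind, per_gene)
  rownames(per_gene) <- NULL
  overall <- if (sum(det_all) > 0) cosine_similarity(gold_all, det_all)
             else NA_real_
  matched_units <- sum(vapply(match_list, function(mr) {
    sum(lengths(mr$gold_groups[mr$matches$gold_group]))
  }, 0L))
  structure(list(
    per_gene = per_gene, overall_cosine = overall,
    detection_count = sum(per_gene$n_detected),
    detection_count_units = matched_units,
    n_gold_groups = sum(per_gene$n_groups),
    n_gold_transcripts = sum(per_gene$n_gold),
    matches = match_list), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Isoform comparison report\n")
  cat(" detected", x$detection_count, "of", x$n_gold_groups,
      "gold groups (", x$detection_count_units, "of",
      x$n_gold_transcripts, "transcript units )\n")
  cat(" overall cosine similarity:",
      format(x$overall_cosine, digits = 3), "\n")
  print(x$per_gene, row.names = FALSE, digits = 3)
  invisible(x)
}
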