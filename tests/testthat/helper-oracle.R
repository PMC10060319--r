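# Independent brute-force reference for consensus coordinate detection:
# literal rule application by position enumeration. Deliberately written
# with double loops and per-position ownership, unlike the package's
# sorted-sweep implementation.

oracle_detect_side <- function(df, total, threshold, window, merge_d,
                               inclusive = TRUE) {
  empty <- data.frame(breakpoint = integer(0), lower = integer(0),
                      upper = integer(0), reads_at_breakpoint = integer(0),
                      reads_in_interval = integer(0))
  cand <- df$pos[100 * df$count / total > threshold]
  k <- length(cand)
  if (k == 0) return(empty)
  # transitive closure of the "closer than merge distance" relation
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        close <- if (inclusive) abs(cand[i] - cand[j]) <= merge_d
                 else abs(cand[i] - cand[j]) < merge_d
        if (close && comp[i] != comp[j]) {
          nc <- min(comp[i], comp[j])
          comp[comp == comp[i] | comp == comp[j]] <- nc
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cnt_at <- function(p) {
    x <- df$count[match(p, df$pos)]
    ifelse(is.na(x), 0L, as.integer(x))
  }
  reps <- sort(vapply(unique(comp), function(cc) {
    mem <- cand[comp == cc]
    cnts <- cnt_at(mem)
    as.integer(min(mem[cnts == max(cnts)]))
  }, integer(1)))
  # per-position ownership: nearest covering rep; equidistance goes to the
  # more frequent rep, frequency ties to the left one
  owner_of <- function(p) {
    inwin <- which(abs(p - reps) <= window)
    if (length(inwin) == 0) return(NA_integer_)
    dist <- abs(p - reps[inwin])
    best <- inwin[dist == min(dist)]
    if (length(best) > 1) {
      cb <- cnt_at(reps[best])
      best <- best[cb == max(cb)]
    }
    best[1]
  }
  positions <- seq(min(reps) - window, max(reps) + window)
  owner <- vapply(positions, owner_of, integer(1))
  out <- do.call(rbind, lapply(seq_along(reps), function(i) {
    mine <- positions[!is.na(owner) & owner == i]
    data.frame(breakpoint = reps[i], lower = min(mine), upper = max(mine),
               reads_at_breakpoint = cnt_at(reps[i]),
               reads_in_interval = sum(cnt_at(mine)))
  }))
  rownames(out) <- NULL
  out
}

# random boundary-count instance for oracle-equivalence tests
random_instance <- function(max_positions = 50, span = 60) {
  npos <- sample(1:max_positions, 1)
  pos <- sort(sample(seq_len(span), npos))
  counts <- sample(1:30, npos, replace = TRUE)
  total <- sum(counts)
  df <- data.frame(pos = as.integer(pos), count = as.integer(counts))
  df$percent <- 100 * df$count / total
  list(df = df, total = total)
}

# literal window-containment assignment of one boundary position
oracle_assign_one <- function(pos, cec) {
  hit <- NA_integer_
  for (i in seq_len(nrow(cec))) {
    if (cec$lower[i] <= pos && pos <= cec$upper[i]) hit <- i
  }
  if (is.na(hit)) NA_integer_ else cec$breakpoint[hit]
}
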