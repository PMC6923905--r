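#' Global (Needleman-Wunsch) alignment of two sequences
#'
#' Optimal global alignment under linear gap penalties (defaults: match +1,
#' mismatch -1, gap -2), computed with `Biostrings::pairwiseAlignment`.
#'
#' @param a,b Non-empty sequences; `a` is the reference side, `b` the read
#'   side.
#' @param match,mismatch,gap Alignment scores.
#' @return A list with `score`, the gapped strings `a_aln`/`b_aln`, and
#'   `identity` (matching columns / alignment columns).
#' @examples
#' global_align("ACGT", "ACT")
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0L || nchar(b) == 0L)
    stop("sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(b),
                                      Biostrings::DNAString(a),
                                      type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = -gap)
  a_aln <- as.character(Biostrings::alignedSubject(pa))
  b_aln <- as.character(Biostrings::alignedPattern(pa))
  list(score = Biostrings::score(pa), a_aln = a_aln, b_aln = b_aln,
       identity = alignment_identity(a_aln, b_aln))
}

# Fast banded global alignment with band doubling until the optimal path no
# longer touches the band edge (validated against pairwiseAlignment in the
# test suite); used for bulk evaluation of multi-kilobase reads.
banded_align <- function(a, b, match = 1, mismatch = -1, gap = -2,
                         band = NULL) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) stop("sequences must be non-empty")
  if (is.null(band)) band <- max(48L, abs(na - nb) + 32L)
  repeat {
    res <- cpp_banded_align(a, b, match, mismatch, gap, as.integer(band))
    if (!isTRUE(res$edge_hit) || band >= max(na, nb)) break
    band <- band * 2L
  }
  res$identity <- alignment_identity(res$a_aln, res$b_aln)
  res
}

alignment_identity <- function(a_aln, b_aln) {
  ac <- strsplit(a_aln, "")[[1L]]
  bc <- strsplit(b_aln, "")[[1L]]
  sum(ac == bc & ac != "-") / length(ac)
}

# Extract error events from an alignment of read `b_aln` against reference
# `a_aln`, keyed by reference coordinate (ref_offset = 1-based reference
# position of the first aligned reference base).  Gap placement is
# normalized by left-shifting indels through equal bases so that equivalent
# alignments yield identical keys.
alignment_events <- function(a_aln, b_aln, ref_offset = 1L) {
  ac <- strsplit(a_aln, "")[[1L]]
  bc <- strsplit(b_aln, "")[[1L]]
  n <- length(ac)
  ref_pos <- cumsum(ac != "-") + ref_offset - 1L  # position of ref base at col
  out <- list()
  i <- 1L
  while (i <= n) {
    if (ac[i] != "-" && bc[i] != "-") {
      if (ac[i] != bc[i])
        out[[length(out) + 1L]] <-
          data.frame(ref_pos = ref_pos[i], type = "sub", base = bc[i],
                     stringsAsFactors = FALSE)
      i <- i + 1L
    } else if (bc[i] == "-") {  # deletion of the reference base
      out[[length(out) + 1L]] <-
        data.frame(ref_pos = ref_pos[i], type = "del", base = "",
                   stringsAsFactors = FALSE)
      i <- i + 1L
    } else {                    # insertion before the next reference base
      p <- if (i <= n && any(ac[i:n] != "-"))
        ref_pos[i] + 1L else ref_pos[n] + 1L
      out[[length(out) + 1L]] <-
        data.frame(ref_pos = p, type = "ins", base = bc[i],
                   stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  if (!length(out))
    return(data.frame(ref_pos = integer(0), type = character(0),
                      base = character(0)))
  do.call(rbind, out)
}

# Left-normalize indel events against the reference so that equivalent
# placements inside repeated context compare equal: a deletion shifts left
# through a homopolymer of the deleted base; an insertion of base x shifts
# left while the reference base before it is x.
normalize_events <- function(events, ref, lower = 1L) {
  if (nrow(events) == 0L) return(events)
  for (j in seq_len(nrow(events))) {
    p <- events$ref_pos[j]
    if (events$type[j] == "del") {
      b <- substr(ref, p, p)
      while (p > lower && substr(ref, p - 1L, p - 1L) == b) p <- p - 1L
    } else if (events$type[j] == "ins") {
      b <- events$base[j]
      while (p > lower && substr(ref, p - 1L, p - 1L) == b) p <- p - 1L
    }
    events$ref_pos[j] <- p
  }
  events
}

event_keys <- function(events) {
  if (nrow(events) == 0L) return(character(0))
  key0 <- paste(events$ref_pos, events$type, events$base, sep = ":")
  # identical co-located events get deterministic occurrence suffixes so that
  # e.g. two deletions normalized into one homopolymer stay distinct
  occ <- stats::ave(seq_along(key0), key0, FUN = seq_along)
  unique(paste(key0, occ, sep = ":"))
}

#' Ground-truth error set of a read
#'
#' Converts the simulation log of one read into the set `E_m` of real
#' sequencing errors, keyed by reference coordinate, event type and read
#' base.  Indel keys are left-normalized against the reference
#' (indels shifted left through equal bases) so that they compare against
#' alignment-derived keys; co-located duplicate events merge
#' deterministically.
#'
#' @param truth An `error_log`.
#' @param read_id Read identifier.
#' @param ref Reference sequence (used for normalization; when `NULL` the
#'   raw logged coordinates are used).
#' @return Character vector of unique `"pos:type:base"` keys.
#' @export
error_set_from_truth <- function(truth, read_id, ref = NULL) {
  iv <- truth$intervals[truth$intervals$read_id == read_id, , drop = FALSE]
  if (nrow(iv) != 1L) stop("unknown read id: ", read_id)
  ev <- truth$events[truth$events$read_id == read_id, , drop = FALSE]
  events <- data.frame(ref_pos = ev$ref_pos, type = ev$type,
                       base = ev$read_base, stringsAsFactors = FALSE)
  if (!is.null(ref))
    events <- normalize_events(events, ref, lower = iv$ref_start)
  event_keys(events)
}

#' Error set remaining in a (corrected) read
#'
#' Globally aligns the read against the reference interval it derives from
#' and extracts the set `E_r` of differences (mismatches, insertions,
#' deletions), keyed like [error_set_from_truth()] with left-normalized
#' indel placement.
#'
#' @param read_seq The (corrected) read sequence.
#' @param ref Reference sequence.
#' @param ref_start,ref_end 1-based inclusive interval the read derives
#'   from.
#' @param method `"banded"` (fast, default) or `"exact"`
#'   (`pairwiseAlignment`).
#' @return A list with `keys` (character vector) and `identity`.
#' @export
error_set_from_alignment <- function(read_seq, ref, ref_start, ref_end,
                                     method = c("banded", "exact")) {
  method <- match.arg(method)
  interval <- substring(ref, ref_start, ref_end)
  al <- if (method == "banded") banded_align(interval, read_seq) else
    global_align(interval, read_seq)
  ev <- alignment_events(al$a_aln, al$b_aln, ref_offset = ref_start)
  ev <- normalize_events(ev, ref, lower = ref_start)
  list(keys = event_keys(ev), identity = al$identity)
}

#' Correction gain from error-set comparison
#'
#' Set algebra over the real error set `E_m` and the remaining error set
#' `E_r`: `TP = |E_m \ E_r|` (errors removed), `FP = |E_r \ E_m|` (true
#' bases wrongly changed), `FN = |E_r intersect E_m|` (errors remaining),
#' and `gain = (TP - FP) / (TP + FN)`.  When `TP + FN == 0` (error-free
#' input) the gain is reported as 1 if `FP == 0`, else as the sentinel -1,
#' with `degenerate = TRUE`.
#'
#' @param e_m,e_r Character vectors of error keys (any set representation
#'   with well-defined equality works).
#' @return A list with `TP`, `FP`, `FN`, `gain`, `degenerate`.
#' @examples
#' compute_gain(c("a", "b", "c", "d"), c("c", "e"))  # gain 0.5
#' @export
compute_gain <- function(e_m, e_r) {
  e_m <- unique(e_m); e_r <- unique(e_r)
  tp <- length(setdiff(e_m, e_r))
  fp <- length(setdiff(e_r, e_m))
  fn <- length(intersect(e_r, e_m))
  degenerate <- (tp + fn) == 0L
  gain <- if (!degenerate) (tp - fp) / (tp + fn)
          else if (fp == 0L) 1 else -1
  list(TP = tp, FP = fp, FN = fn, gain = gain, degenerate = degenerate)
}

gain_from_counts <- function(tp, fp, fn) {
  if (tp + fn > 0) (tp - fp) / (tp + fn) else if (fp == 0) 1 else -1
}

#' N50 of a set of read lengths
#'
#' The largest length `L` such that reads of length at least `L` together
#' contain at least half of all bases.
#'
#' @param lengths Non-empty vector of positive integers.
#' @return An integer length.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  if (any(lengths <= 0)) stop("lengths must be positive")
  x <- sort(as.numeric(lengths), decreasing = TRUE)
  as.integer(x[which(cumsum(x) >= sum(x) / 2)[1L]])
}

#' Fraction of reads aligning to their true source intervals
#'
#' A read counts as aligned when its global alignment to the reference
#' interval it was simulated from reaches at least `min_identity`.
#'
#' @param reads A read set `data.frame`.
#' @param truth The `error_log` carrying the source intervals.
#' @param ref Reference sequence.
#' @param min_identity Identity cutoff (default 0.7).
#' @return A list with `pct_reads`, `pct_bases` (percentages) and the
#'   per-read `identity` vector.
#' @export
aligned_fraction <- function(reads, truth, ref, min_identity = 0.7) {
  stopifnot(is.data.frame(reads))
  idx <- match(reads$id, truth$intervals$read_id)
  if (anyNA(idx)) stop("missing truth interval for read(s): ",
                       paste(head(reads$id[is.na(idx)]), collapse = ", "))
  iv <- truth$intervals[idx, , drop = FALSE]
  identity <- vapply(seq_len(nrow(reads)), function(i) {
    banded_align(substring(ref, iv$ref_start[i], iv$ref_end[i]),
                 reads$seq[i])$identity
  }, numeric(1))
  aligned <- identity >= min_identity
  lens <- nchar(reads$seq)
  list(pct_reads = 100 * mean(aligned),
       pct_bases = 100 * sum(lens[aligned]) / sum(lens),
       identity = identity)
}

#' Evaluate a correction run against simulation ground truth
#'
#' For every read, the ground-truth error set `E_m` comes from the
#' simulation log and the remaining error set `E_r` from global alignment
#' of the corrected read to its true source interval; TP/FP/FN are summed
#' over reads and the gain computed from the totals.  Also reports N50
#' before/after, aligned fractions and mean identity.
#'
#' @param original_reads,corrected_reads Read sets before and after
#'   correction (same ids, same order).
#' @param truth The simulation `error_log`.
#' @param ref Reference sequence.
#' @param min_identity Identity cutoff for the aligned fractions.
#' @return A list with `TP`, `FP`, `FN`, `gain`, `n50_before`, `n50_after`,
#'   `pct_aligned_reads`, `pct_aligned_bases`, `mean_identity` and the
#'   `per_read` data frame.
#' @export
evaluate_correction <- function(original_reads, corrected_reads, truth, ref,
                                min_identity = 0.7) {
  stopifnot(identical(original_reads$id, corrected_reads$id))
  n <- nrow(corrected_reads)
  idx <- match(corrected_reads$id, truth$intervals$read_id)
  if (anyNA(idx)) stop("missing truth interval for read(s): ",
                       paste(head(corrected_reads$id[is.na(idx)]),
                             collapse = ", "))
  iv <- truth$intervals[idx, , drop = FALSE]
  per <- vector("list", n)
  for (i in seq_len(n)) {
    e_m <- error_set_from_truth(truth, corrected_reads$id[i], ref)
    er <- error_set_from_alignment(corrected_reads$seq[i], ref,
                                   iv$ref_start[i], iv$ref_end[i])
    g <- compute_gain(e_m, er$keys)
    per[[i]] <- data.frame(id = corrected_reads$id[i], TP = g$TP, FP = g$FP,
                           FN = g$FN, identity = er$identity,
                           stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  tp <- sum(per$TP); fp <- sum(per$FP); fn <- sum(per$FN)
  aligned <- per$identity >= min_identity
  lens <- nchar(corrected_reads$seq)
  list(TP = tp, FP = fp, FN = fn, gain = gain_from_counts(tp, fp, fn),
       n50_before = n50(nchar(original_reads$seq)),
       n50_after = n50(lens),
       pct_aligned_reads = 100 * mean(aligned),
       pct_aligned_bases = 100 * sum(lens[aligned]) / sum(lens),
       mean_identity = mean(per$identity),
       per_read = per)
}
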