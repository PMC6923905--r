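#' Split a long read into fixed-length fragments
#'
#' Consecutive non-overlapping windows of `frag_len` bases; a final window
#' shorter than `frag_len` is labeled `ignored_tail` and never used for
#' substitution correction (too short to gather coverage statistics).  The
#' default fragment length mirrors a typical short-read length.
#'
#' @param read A single sequence string or one-row read set `data.frame`.
#' @param frag_len Fragment length in bases (at least k).
#' @param k K-mer length (only used to validate `frag_len`).
#' @return A `data.frame` with columns `start`, `end` (0-based half-open
#'   base coordinates) and `klass` (`"unclassified"` or `"ignored_tail"`).
#' @export
fragment_read <- function(read, frag_len = 100L, k = 2L) {
  if (frag_len < k) stop("frag_len must be at least k = ", k)
  seq <- read_seq(read)
  n <- nchar(seq)
  n_full <- n %/% frag_len
  starts <- seq_len(n_full) * frag_len - frag_len
  ends <- starts + frag_len
  klass <- rep("unclassified", n_full)
  if (n %% frag_len != 0L) {
    starts <- c(starts, n_full * frag_len)
    ends <- c(ends, n)
    klass <- c(klass, "ignored_tail")
  }
  data.frame(start = as.integer(starts), end = as.integer(ends),
             klass = klass, stringsAsFactors = FALSE)
}

#' Pearson's median skew coefficient
#'
#' `3 * (mean - median) / sd` with the *population* standard deviation (the
#' fragment is the full population of its windows); defined as 0 when the
#' standard deviation is 0.  Near zero for coverage-balanced fragments;
#' strongly negative when a few low-coverage outliers sit below a
#' high-coverage bulk.
#'
#' @param coverages Non-empty numeric vector of k-mer coverages.
#' @return A number.
#' @examples
#' pearson_median_skew(c(1, 1, 1, 10))
#' @export
pearson_median_skew <- function(coverages) {
  if (length(coverages) == 0L) stop("coverages must be non-empty")
  x <- as.numeric(coverages)
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(0)
  3 * (mean(x) - median(x)) / s
}

#' Classify a fragment by its k-mer coverage skew
#'
#' Implements the three coverage regimes used to decide whether a fragment
#' contains substitution errors:
#' * `true_low` — the fragment median is well below the spectrum median
#'   (below `low_factor * graph_median`): a genuinely low-coverage genomic
#'   region, never flagged as error regardless of its skew (the skew of
#'   small discrete counts is too noisy to be meaningful).
#' * `true_balanced` — skew inside `[skew_low, skew_high]`: balanced low and
#'   high coverages, no error.
#' * otherwise the fragment is an error fragment — its histogram is skewed
#'   towards high-coverage k-mers with low-coverage outliers — split into
#'   `error_high` (fragment median above the spectrum median) and
#'   `error_low`.
#'
#' @param coverages K-mer coverage vector of the fragment's windows
#'   (negative values from invalid windows are clamped to 0).
#' @param graph_median Median coverage of the entire k-mer spectrum (see
#'   [spectrum_median()]).
#' @param skew_low,skew_high The "true" skew interval (defaults -0.3, 0.3).
#' @param low_factor A fragment only counts as a low-coverage genomic
#'   region when its median falls below this fraction of the spectrum
#'   median (default 0.5); this keeps high-coverage fragments whose median
#'   is dragged slightly below the spectrum median by error k-mers
#'   correctable.
#' @return One of `"true_balanced"`, `"true_low"`, `"error_high"`,
#'   `"error_low"`.
#' @export
classify_fragment <- function(coverages, graph_median, skew_low = -0.3,
                              skew_high = 0.3, low_factor = 0.5) {
  x <- pmax(as.numeric(coverages), 0)
  skew <- pearson_median_skew(x)
  frag_median <- median(x)
  if (frag_median < low_factor * graph_median) return("true_low")
  if (skew >= skew_low && skew <= skew_high) return("true_balanced")
  if (frag_median > graph_median) "error_high" else "error_low"
}

#' Locate candidate substitution positions within an error fragment
#'
#' A fragment owns the k-mer windows *starting* inside it (each window
#' extends up to k-1 bases past the fragment end, so every read window
#' belongs to exactly one fragment and none is lost at fragment
#' boundaries).  Windows with coverage below `tau_low` are error k-mers.  A
#' base position is flagged when every owned window overlapping it is an
#' error k-mer; additionally, for a maximal run of at most k consecutive
#' error windows — the footprint of an isolated substitution — the
#' positions in the intersection of all windows of the run are flagged.
#' For an isolated substitution both rules coincide and name exactly the
#' substituted base.
#'
#' @param read A single sequence string or one-row read set `data.frame`.
#' @param frag_start,frag_end Fragment base coordinates (0-based half-open).
#' @param graph A `dbg_graph`.
#' @param tau_low Error k-mer coverage cutoff (coverage `< tau_low`).
#' @return Sorted integer vector of 0-based read positions.
#' @export
locate_error_positions <- function(read, frag_start, frag_end, graph,
                                   tau_low = 3L, profile = NULL) {
  seq <- toupper(read_seq(read))
  k <- graph$k
  n <- nchar(seq)
  w0 <- frag_start                      # first owned window (0-based start)
  w1 <- min(frag_end - 1L, n - k)       # last owned window
  if (w1 < w0) return(integer(0))
  if (is.null(profile)) profile <- cpp_profile(graph$ptr, seq)
  err <- profile[(w0:w1) + 1L] < tau_low
  if (!any(err)) return(integer(0))
  base0 <- w0                           # first base covered by owned windows
  base1 <- w1 + k - 1L                  # last base covered
  flagged <- logical(base1 - base0 + 1L)
  # rule 1: every owned window overlapping the base is an error window
  for (p in base0:base1) {
    a <- max(w0, p - k + 1L)
    b <- min(p, w1)
    if (a > b) next
    if (all(err[(a:b) - w0 + 1L])) flagged[p - base0 + 1L] <- TRUE
  }
  # rule 2: isolated-substitution runs (length <= k): intersection of the run
  r <- rle(err)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths            # run starts, relative to w0
  for (j in which(r$values)) {
    L <- r$lengths[j]
    if (L > k) next
    i0 <- w0 + starts[j]                # absolute start of first run window
    lo <- i0 + L - 1L                   # start of the last run window
    hi <- min(i0 + k - 1L, base1)       # last base of the first run window
    if (lo <= hi) flagged[(lo:hi) - base0 + 1L] <- TRUE
  }
  base0 + which(flagged) - 1L
}

#' Vote for the base at a position using k-mer coverage
#'
#' Substitutes each of A, C, G, T at `pos` and computes the coverage of
#' every k-mer window overlapping the position (clipped to the read).  A
#' candidate qualifies when all those coverages are at least `threshold`;
#' among qualifying candidates the one maximizing the minimum window
#' coverage wins (ties towards the alphabetically smaller base).
#'
#' @param read A single sequence string or one-row read set `data.frame`.
#' @param pos 0-based position in the read.
#' @param graph A `dbg_graph`.
#' @param threshold Minimum acceptable window coverage.
#' @return A single base, or `NULL` when no candidate qualifies (the base is
#'   then left unchanged).
#' @export
vote_base <- function(read, pos, graph, threshold) {
  seq <- toupper(read_seq(read))
  k <- graph$k
  n <- nchar(seq)
  stopifnot(pos >= 0L, pos < n)
  ctx_start <- max(0L, pos - k + 1L)              # 0-based
  ctx_end <- min(n, pos + k)                      # 0-based exclusive
  ctx <- substr(seq, ctx_start + 1L, ctx_end)
  rel <- pos - ctx_start + 1L                     # 1-based within context
  best <- NULL
  best_min <- -Inf
  for (base in c("A", "C", "G", "T")) {
    cand <- ctx
    substr(cand, rel, rel) <- base
    prof <- cpp_profile(graph$ptr, cand)
    if (length(prof) == 0L) next
    m <- min(prof)
    if (m >= threshold && m > best_min) {
      best <- base
      best_min <- m
    }
  }
  best
}

#' Correct the substitution errors of one long read
#'
#' The read is cut into fragments ([fragment_read()]), each fragment is
#' classified by the Pearson median skew of its k-mer coverages
#' ([classify_fragment()]), candidate positions are located only inside
#' error fragments ([locate_error_positions()]), and each candidate base is
#' re-voted from the k-mer spectrum ([vote_base()]) with an area-specific
#' threshold: `thresh_high` in high-coverage (`error_high`) fragments and
#' `thresh_low` in low-coverage (`error_low`) ones.  Corrections are applied
#' left to right on the evolving sequence.  Output length always equals
#' input length.
#'
#' @param read A single sequence string or one-row read set `data.frame`.
#' @param graph A `dbg_graph`.
#' @param frag_len Fragment length (default 100, a typical short-read
#'   length).
#' @param skew_low,skew_high "True fragment" skew interval.
#' @param tau_low Error k-mer cutoff inside fragments.
#' @param thresh_high Voting threshold in high-coverage areas; default
#'   `max(tau_low, ceiling(graph_median / 4))`.
#' @param thresh_low Voting threshold in low-coverage areas; default
#'   `tau_low`.
#' @param graph_median Precomputed spectrum median; defaults to the
#'   instance-weighted [spectrum_median()], which tracks the typical
#'   genomic coverage even when distinct error k-mers outnumber true ones.
#' @return A list with `seq` (same length as the input) and `report` (a
#'   list: `n_fragments`, `n_error_fragments`, `n_positions_flagged`,
#'   `n_positions_corrected`, `skipped`, and a per-position `data.frame`
#'   `edits` with columns `pos`, `old`, `new`).
#' @export
correct_read_substitutions <- function(read, graph, frag_len = 100L,
                                       skew_low = -0.3, skew_high = 0.3,
                                       tau_low = 3L, thresh_high = NULL,
                                       thresh_low = NULL,
                                       graph_median = NULL) {
  stopifnot(inherits(graph, "dbg_graph"))
  k <- graph$k
  if (frag_len < k) stop("frag_len must be at least k = ", k)
  seq <- toupper(read_seq(read))
  if (is.null(graph_median))
    graph_median <- spectrum_median(graph, weighted = TRUE)
  if (is.null(thresh_high))
    thresh_high <- max(tau_low, ceiling(graph_median / 4))
  if (is.null(thresh_low)) thresh_low <- tau_low
  frags <- fragment_read(seq, frag_len, k)
  usable <- frags[frags$klass != "ignored_tail", , drop = FALSE]
  no_edits <- data.frame(pos = integer(0), old = character(0),
                         new = character(0))
  if (nrow(usable) == 0L) {
    return(list(seq = seq,
                report = list(n_fragments = nrow(frags),
                              n_error_fragments = 0L,
                              n_positions_flagged = 0L,
                              n_positions_corrected = 0L, skipped = TRUE,
                              edits = no_edits)))
  }
  prof <- cpp_profile(graph$ptr, seq)
  n_err <- 0L
  flagged_all <- integer(0)
  thresholds <- integer(0)
  n <- nchar(seq)
  for (i in seq_len(nrow(usable))) {
    fs <- usable$start[i]; fe <- usable$end[i]
    # the fragment owns the windows starting inside it
    wl <- min(fe - 1L, n - graph$k)
    if (wl < fs) next
    cov <- prof[(fs:wl) + 1L]
    klass <- classify_fragment(cov, graph_median, skew_low, skew_high)
    # Sensitivity fallback: a handful of sub-solid windows (e.g. a single
    # substitution near a read end) barely moves the skew of a fragment
    # that is otherwise solidly covered, yet in a well-covered area such
    # windows are near-certain errors.  Route those fragments into
    # localization too; the voting step remains the precision guard.
    if (klass == "true_balanced" && any(cov < tau_low))
      klass <- if (median(pmax(cov, 0)) > graph_median) "error_high" else
        "error_low"
    if (!klass %in% c("error_high", "error_low")) next
    n_err <- n_err + 1L
    pos <- locate_error_positions(seq, fs, fe, graph, tau_low,
                                  profile = prof)
    if (length(pos)) {
      flagged_all <- c(flagged_all, pos)
      thresholds <- c(thresholds,
                      rep(if (klass == "error_high") thresh_high else
                            thresh_low, length(pos)))
    }
  }
  edits <- no_edits
  cur <- seq
  if (length(flagged_all)) {
    o <- order(flagged_all)
    flagged_all <- flagged_all[o]
    thresholds <- thresholds[o]
    keep <- !duplicated(flagged_all)  # a position can be flagged by two
    flagged_all <- flagged_all[keep]  # fragments near a boundary
    thresholds <- thresholds[keep]
    for (i in seq_along(flagged_all)) {
      p <- flagged_all[i]
      old <- substr(cur, p + 1L, p + 1L)
      new <- vote_base(cur, p, graph, thresholds[i])
      if (!is.null(new) && new != old) {
        substr(cur, p + 1L, p + 1L) <- new
        edits <- rbind(edits, data.frame(pos = p, old = old, new = new,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  list(seq = cur,
       report = list(n_fragments = nrow(frags), n_error_fragments = n_err,
                     n_positions_flagged = length(flagged_all),
                     n_positions_corrected = nrow(edits), skipped = FALSE,
                     edits = edits))
}

#' Correct the substitution errors of a set of long reads
#'
#' Applies [correct_read_substitutions()] to every read (typically the
#' output of [correct_indels()]).  Read length is never changed.
#'
#' @param long_reads A read set `data.frame`.
#' @param graph A `dbg_graph`.
#' @inheritParams correct_read_substitutions
#' @param workers Number of parallel workers (forked; default 1).
#' @return A list with `reads` (corrected read set) and `report` (one row
#'   per read).
#' @export
correct_substitutions <- function(long_reads, graph, frag_len = 100L,
                                  skew_low = -0.3, skew_high = 0.3,
                                  tau_low = 3L, thresh_high = NULL,
                                  thresh_low = NULL, workers = 1L) {
  stopifnot(is.data.frame(long_reads))
  gm <- spectrum_median(graph, weighted = TRUE)
  res <- apply_per_read(long_reads$seq, workers, function(s)
    correct_read_substitutions(s, graph, frag_len = frag_len,
                               skew_low = skew_low, skew_high = skew_high,
                               tau_low = tau_low, thresh_high = thresh_high,
                               thresh_low = thresh_low, graph_median = gm))
  reads <- data.frame(id = long_reads$id,
                      seq = vapply(res, `[[`, character(1), "seq"),
                      qual = if ("qual" %in% names(long_reads))
                        long_reads$qual else NA_character_,
                      stringsAsFactors = FALSE)
  report <- data.frame(
    id = long_reads$id,
    n_fragments = vapply(res, function(x) x$report$n_fragments, 1L),
    n_error_fragments =
      vapply(res, function(x) x$report$n_error_fragments, 1L),
    n_positions_flagged =
      vapply(res, function(x) x$report$n_positions_flagged, 1L),
    n_positions_corrected =
      vapply(res, function(x) x$report$n_positions_corrected, 1L),
    skipped = vapply(res, function(x) x$report$skipped, TRUE),
    stringsAsFactors = FALSE)
  list(reads = reads, report = report)
}
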