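#' Partition a long read into strong and weak regions
#'
#' Every k-mer window of the read is looked up in the short-read de Bruijn
#' graph; window `i` (0-based, in k-mer index space) is *weak* when its
#' coverage is below `tau` (windows containing non-ACGT characters count as
#' weak), *strong* otherwise.  Maximal runs of equal label form the regions.
#' Weak regions are presumed indel-error regions; strong regions are trusted
#' verbatim.
#'
#' @param read A single sequence string, or a one-row read set `data.frame`.
#' @param graph A `dbg_graph` built from the short reads.
#' @param tau Weak-coverage threshold (coverage `< tau` is weak); default 3.
#' @return A `data.frame` with columns `start`, `end` (0-based half-open, in
#'   k-mer index space) and `label` (`"strong"`/`"weak"`), tiling
#'   `[0, n_kmers)` with alternating labels.  Zero rows for reads shorter
#'   than `k` (such reads are passed through untouched, never dropped).
#' @export
partition_read <- function(read, graph, tau = 3L) {
  stopifnot(inherits(graph, "dbg_graph"))
  seq <- read_seq(read)
  if (tau < 1) stop("tau must be a positive integer")
  prof <- cpp_profile(graph$ptr, toupper(seq))
  if (length(prof) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = character(0)))
  weak <- prof < tau  # invalid windows are -1, hence weak
  r <- rle(weak)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts, end = ends,
             label = ifelse(r$values, "weak", "strong"),
             stringsAsFactors = FALSE)
}

read_seq <- function(read) {
  if (is.data.frame(read)) {
    stopifnot(nrow(read) == 1L)
    return(read$seq)
  }
  stopifnot(is.character(read), length(read) == 1L)
  read
}

new_assembly_path <- function(kmers, width) {
  structure(list(kmers = kmers, width = as.integer(width),
                 length = length(kmers), seq = spell_kmers(kmers)),
            class = "assembly_path")
}

#' @export
print.assembly_path <- function(x, ...) {
  cat(sprintf("assembly path: %d k-mers, width %d, spells %d bases\n",
              x$length, x$width, nchar(x$seq)))
  invisible(x)
}

path_search_result <- function(res) {
  if (!isTRUE(res$found)) return(NULL)
  new_assembly_path(res$kmers, res$width)
}

check_endpoints <- function(graph, source, dest) {
  source <- toupper(source); dest <- toupper(dest)
  if (nchar(source) != graph$k || nchar(dest) != graph$k)
    stop("source and destination must be k-mers of length ", graph$k)
  cov <- cpp_coverage(graph$ptr, c(source, dest))
  if (any(cov == 0L))
    stop("k-mer not present in graph: ",
         paste(c(source, dest)[cov == 0L], collapse = ", "))
  c(source, dest)
}

#' Bottleneck (widest) path between two k-mers
#'
#' Returns a path from `source` to `dest` of at most `max_len` k-mers that
#' maximizes the path *width* — the minimum vertex coverage along the path,
#' endpoints included.  Among equal-width paths a shortest one is returned,
#' with ties broken towards the lexicographically smaller next k-mer.  The
#' search is a Dijkstra variant on a max-priority queue keyed by
#' (width descending, length ascending), `O(E log V)`.
#'
#' @param graph A `dbg_graph`.
#' @param source,dest K-mers present in the graph (absent k-mers are an
#'   error).
#' @param max_len Maximum path length in k-mers.
#' @return An `assembly_path` (fields `kmers`, `width`, `length`, `seq`), or
#'   `NULL` when no path of at most `max_len` k-mers exists.
#' @export
widest_path <- function(graph, source, dest, max_len) {
  stopifnot(inherits(graph, "dbg_graph"), max_len >= 1)
  ep <- check_endpoints(graph, source, dest)
  path_search_result(cpp_widest_path(graph$ptr, ep[1L], ep[2L],
                                     as.integer(max_len)))
}

#' Shortest path between two k-mers
#'
#' Unweighted breadth-first search minimizing the number of k-mers on the
#' path; the bottleneck width of the returned path is still reported for
#' diagnostics.  Used by the `"shortest"` traversal strategy.
#'
#' @inheritParams widest_path
#' @return An `assembly_path` or `NULL`.
#' @export
shortest_path <- function(graph, source, dest, max_len) {
  stopifnot(inherits(graph, "dbg_graph"), max_len >= 1)
  ep <- check_endpoints(graph, source, dest)
  path_search_result(cpp_shortest_path(graph$ptr, ep[1L], ep[2L],
                                       as.integer(max_len)))
}

#' Greedy maximum-coverage path between two k-mers
#'
#' Depth-first descent that always prefers the successor with the highest
#' coverage, backtracking after `b` successive vertices without reaching the
#' destination, and aborting once every vertex reachable from the source has
#' been visited.  Used by the `"greedy"` traversal strategy.
#'
#' @inheritParams widest_path
#' @param b Branching factor: maximum number of successive vertices explored
#'   down one branch before backtracking (default 100).
#' @return An `assembly_path` or `NULL`.
#' @export
greedy_path <- function(graph, source, dest, b = 100L, max_len = b) {
  stopifnot(inherits(graph, "dbg_graph"), max_len >= 1, b >= 1)
  ep <- check_endpoints(graph, source, dest)
  path_search_result(cpp_greedy_path(graph$ptr, ep[1L], ep[2L],
                                     as.integer(b), as.integer(max_len)))
}

#' Spell the sequence of a k-mer path
#'
#' Concatenates the first k-mer with the last character of each subsequent
#' k-mer; consecutive k-mers must overlap by k-1 characters.
#'
#' @param path An `assembly_path` or a character vector of k-mers.
#' @return A single string of length `k + length - 1`.
#' @export
spell_path <- function(path) {
  kmers <- if (inherits(path, "assembly_path")) path$kmers else
    as.character(path)
  if (length(kmers) == 0L) stop("empty path")
  k <- nchar(kmers[1L])
  if (length(kmers) > 1L) {
    ok <- substring(kmers[-length(kmers)], 2L, k) ==
      substring(kmers[-1L], 1L, k - 1L)
    if (!all(ok))
      stop("internal consistency error: consecutive k-mers do not overlap ",
           "by k-1 at step ", which(!ok)[1L])
  }
  spell_kmers(kmers)
}

spell_kmers <- function(kmers) {
  if (length(kmers) == 1L) return(kmers)
  k <- nchar(kmers[1L])
  paste0(kmers[1L],
         paste(substring(kmers[-1L], k, k), collapse = ""))
}

#' Correct the indel errors of one long read
#'
#' Partitions the read into strong and weak regions and replaces each weak
#' region that is flanked by strong regions on both sides with the spelled
#' path found between the boundary k-mers (the last k-mer of the left strong
#' region and the first k-mer of the right strong region).  The search is
#' bounded at `ceiling(max_len_factor * (weak span in k-mers + 2))` k-mers.
#' Weak regions with no qualifying path, or at a read end (only one
#' boundary), are left unchanged — the read is never trimmed.  Bases inside
#' strong regions are preserved verbatim.
#'
#' @param read A single sequence string or one-row read set `data.frame`.
#' @param graph A `dbg_graph`.
#' @param tau Weak-coverage threshold (see [partition_read()]).
#' @param search Traversal strategy: `"widest"` (default), `"shortest"` or
#'   `"greedy"`.
#' @param max_len_factor Path length bound relative to the weak-region span
#'   (default 2).
#' @param b Branching factor for the greedy strategy.
#' @return A list with `seq` (the corrected sequence) and `report` (a list
#'   with counts `n_weak_regions`, `n_replaced`, `n_unchanged`, a logical
#'   `skipped` for reads shorter than k, and a per-region outcome
#'   `data.frame` `regions` with columns `start`, `end`, `outcome` in
#'   `{"replaced", "no_path", "missing_boundary"}`).
#' @export
correct_read_indels <- function(read, graph, tau = 3L,
                                search = c("widest", "shortest", "greedy"),
                                max_len_factor = 2.0, b = 100L) {
  search <- match.arg(search)
  stopifnot(inherits(graph, "dbg_graph"))
  seq <- toupper(read_seq(read))
  k <- graph$k
  n <- nchar(seq)
  empty_regions <- data.frame(start = integer(0), end = integer(0),
                              outcome = character(0))
  if (n < k) {
    return(list(seq = seq,
                report = list(n_weak_regions = 0L, n_replaced = 0L,
                              n_unchanged = 0L, skipped = TRUE,
                              regions = empty_regions)))
  }
  regions <- partition_read(seq, graph, tau)
  weak <- regions[regions$label == "weak", , drop = FALSE]
  n_kmers <- n - k + 1L
  if (nrow(weak) == 0L) {
    return(list(seq = seq,
                report = list(n_weak_regions = 0L, n_replaced = 0L,
                              n_unchanged = 0L, skipped = FALSE,
                              regions = empty_regions)))
  }
  out_pieces <- character(0)
  opos <- 0L  # bases of the original read emitted so far (1-based prefix)
  outcome <- character(nrow(weak))
  for (i in seq_len(nrow(weak))) {
    ws <- weak$start[i]; we <- weak$end[i]
    if (ws == 0L || we == n_kmers) {  # read-end weak region: single boundary
      outcome[i] <- "missing_boundary"
      next
    }
    source <- substr(seq, ws, ws + k - 1L)        # k-mer index ws - 1
    dest <- substr(seq, we + 1L, we + k)          # k-mer index we
    max_len <- as.integer(ceiling(max_len_factor * ((we - ws) + 2L)))
    res <- switch(search,
      widest = cpp_widest_path(graph$ptr, source, dest, max_len),
      shortest = cpp_shortest_path(graph$ptr, source, dest, max_len),
      greedy = cpp_greedy_path(graph$ptr, source, dest, as.integer(b),
                               max_len))
    if (!isTRUE(res$found)) {
      outcome[i] <- "no_path"
      next
    }
    spelled <- spell_kmers(res$kmers)
    out_pieces <- c(out_pieces,
                    substr(seq, opos + 1L, ws + k - 1L),  # through source k-mer
                    substr(spelled, k + 1L, nchar(spelled)))
    opos <- we + k  # emitted through the end of the destination k-mer
    outcome[i] <- "replaced"
  }
  out_pieces <- c(out_pieces, substr(seq, opos + 1L, n))
  corrected <- paste(out_pieces, collapse = "")
  weak_out <- data.frame(start = weak$start, end = weak$end,
                         outcome = outcome, stringsAsFactors = FALSE)
  list(seq = corrected,
       report = list(n_weak_regions = nrow(weak),
                     n_replaced = sum(outcome == "replaced"),
                     n_unchanged = sum(outcome != "replaced"),
                     skipped = FALSE, regions = weak_out))
}

#' Correct the indel errors of a set of long reads
#'
#' Applies [correct_read_indels()] to every read.  Per-read corrections are
#' independent, so results do not depend on processing order or worker
#' count.
#'
#' @param long_reads A read set `data.frame` (columns `id`, `seq`).
#' @param graph A `dbg_graph`.
#' @inheritParams correct_read_indels
#' @param workers Number of parallel workers (forked; default 1).
#' @return A list with `reads` (corrected read set; qualities are dropped
#'   because indel splices change coordinates) and `report` (one row per
#'   read: `id`, `n_weak_regions`, `n_replaced`, `n_unchanged`, `skipped`).
#' @export
correct_indels <- function(long_reads, graph, tau = 3L,
                           search = c("widest", "shortest", "greedy"),
                           max_len_factor = 2.0, b = 100L, workers = 1L) {
  search <- match.arg(search)
  stopifnot(is.data.frame(long_reads))
  res <- apply_per_read(long_reads$seq, workers, function(s)
    correct_read_indels(s, graph, tau = tau, search = search,
                        max_len_factor = max_len_factor, b = b))
  reads <- data.frame(id = long_reads$id,
                      seq = vapply(res, `[[`, character(1), "seq"),
                      qual = NA_character_, stringsAsFactors = FALSE)
  report <- data.frame(
    id = long_reads$id,
    n_weak_regions = vapply(res, function(x) x$report$n_weak_regions, 1L),
    n_replaced = vapply(res, function(x) x$report$n_replaced, 1L),
    n_unchanged = vapply(res, function(x) x$report$n_unchanged, 1L),
    skipped = vapply(res, function(x) x$report$skipped, TRUE),
    stringsAsFactors = FALSE)
  list(reads = reads, report = report)
}

apply_per_read <- function(seqs, workers, fun) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seqs, fun, mc.cores = workers)
  } else {
    lapply(seqs, fun)
  }
}
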