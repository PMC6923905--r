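#' Extract k-mers from a sequence
#'
#' Returns every length-`k` window of `sequence` whose characters are all in
#' `{A,C,G,T}`, with its 0-based start position.  Windows containing any
#' other character (e.g. `N`) are omitted.
#'
#' @param sequence A single character string.
#' @param k Window length (integer, at least 2).
#' @return A `data.frame` with columns `pos` (0-based start) and `kmer`.
#' @examples
#' extract_kmers("ACNGT", 2)
#' @export
extract_kmers <- function(sequence, k) {
  k <- check_k(k)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < k) return(data.frame(pos = integer(0), kmer = character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  keep <- !grepl("[^ACGT]", kmers)
  data.frame(pos = starts[keep] - 1L, kmer = kmers[keep],
             stringsAsFactors = FALSE)
}

check_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2)
    stop("k must be a single integer >= 2")
  k <- as.integer(k)
  if (k > 32L) stop("k must be <= 32")
  k
}

new_dbg <- function(ptr, k, canonical) {
  g <- new.env(parent = emptyenv())
  g$ptr <- ptr
  g$k <- as.integer(k)
  g$canonical <- isTRUE(canonical)
  class(g) <- "dbg_graph"
  g
}

#' Build a coverage-annotated de Bruijn graph from short reads
#'
#' Counts every valid k-mer window over the input reads and records the
#' single-character in/out edges observed between consecutive windows.  Each
#' vertex stores the k-mer occurrence count (its coverage), the central
#' signal used by both correction phases.
#'
#' In canonical mode (the default) a k-mer and its reverse complement are
#' merged into one vertex keyed by the lexicographically smaller of the two,
#' so that reads sampled from either genomic strand contribute to the same
#' count; edges are recorded in the canonical orientation and presented in
#' whichever literal orientation a query uses.  `canonical = FALSE` keeps the
#' literal single-strand spelling of every window.
#'
#' @param short_reads A read set `data.frame` (see [read_sequences()]) or a
#'   character vector of sequences.
#' @param k K-mer length (default 21).
#' @param canonical Merge reverse-complement k-mers (default `TRUE`).
#' @return A `dbg_graph` object.
#' @examples
#' g <- build_graph("ACGT", k = 3, canonical = FALSE)
#' coverage(g, c("ACG", "CGT", "TTT"))
#' @export
build_graph <- function(short_reads, k = 21L, canonical = TRUE) {
  k <- check_k(k)
  seqs <- if (is.data.frame(short_reads)) short_reads$seq else
    as.character(short_reads)
  seqs <- toupper(seqs)
  if (!any(nchar(seqs) >= k))
    stop("no input read is at least k = ", k,
         " bases long; cannot build a graph")
  ptr <- cpp_build_graph(seqs, k, canonical)
  g <- new_dbg(ptr, k, canonical)
  if (n_vertices(g) == 0L)
    stop("no valid k-mer windows in the input reads (all windows contain ",
         "non-ACGT characters)")
  g
}

#' Number of vertices in the graph
#' @param graph A `dbg_graph`.
#' @return Integer count of distinct stored k-mers.
#' @export
n_vertices <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  as.integer(cpp_graph_info(graph$ptr)$n_vertices)
}

#' Total number of k-mer instances counted
#' @param graph A `dbg_graph`.
#' @return The sum of all vertex counts (number of valid windows seen).
#' @export
total_instances <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  cpp_graph_info(graph$ptr)$total_instances
}

#' @export
print.dbg_graph <- function(x, ...) {
  cat(sprintf("de Bruijn graph: k = %d, %s, %d vertices, %.0f k-mer instances\n",
              x$k, if (x$canonical) "canonical" else "single-strand",
              n_vertices(x), total_instances(x)))
  invisible(x)
}

#' Coverage of k-mers in the graph
#'
#' Looks up the occurrence count of each query k-mer; absent k-mers have
#' coverage 0.  In canonical graphs a k-mer and its reverse complement
#' return the same (merged) count.  Lookup is a constant-time hash access.
#'
#' @param graph A `dbg_graph`.
#' @param kmer Character vector of k-mers, each of length `graph$k`.
#' @return Integer vector of coverages.
#' @export
coverage <- function(graph, kmer) {
  stopifnot(inherits(graph, "dbg_graph"))
  kmer <- toupper(as.character(kmer))
  if (any(nchar(kmer) != graph$k))
    stop("all query k-mers must have length k = ", graph$k)
  cpp_coverage(graph$ptr, kmer)
}

#' Graph neighborhood queries
#'
#' Successors (predecessors) of a k-mer are reconstructed by appending
#' (prepending) each recorded out-edge (in-edge) character to the k-1 suffix
#' (prefix), with the neighbor's coverage attached.
#'
#' @param graph A `dbg_graph`.
#' @param kmer A single k-mer present in the graph.
#' @return A `data.frame` with columns `kmer` and `coverage`, in `A < C < G
#'   < T` edge-character order.
#' @export
successors <- function(graph, kmer) neighbor_df(graph, kmer, TRUE)

#' @rdname successors
#' @export
predecessors <- function(graph, kmer) neighbor_df(graph, kmer, FALSE)

neighbor_df <- function(graph, kmer, forward) {
  stopifnot(inherits(graph, "dbg_graph"))
  kmer <- toupper(as.character(kmer))
  stopifnot(length(kmer) == 1L)
  if (nchar(kmer) != graph$k)
    stop("query k-mer must have length k = ", graph$k)
  if (cpp_coverage(graph$ptr, kmer) == 0L)
    stop("k-mer not present in graph: ", kmer)
  nb <- cpp_neighbors(graph$ptr, kmer, forward)
  data.frame(kmer = nb$kmer, coverage = nb$coverage, stringsAsFactors = FALSE)
}

#' Median coverage of the k-mer spectrum
#'
#' The median of the counts of the distinct stored k-mers (default), or the
#' median over k-mer instances (every occurrence counted) when
#' `weighted = TRUE`.  An even number of values yields the arithmetic mean of
#' the two middle values.
#'
#' @param graph A `dbg_graph`.
#' @param weighted Median over instances instead of distinct k-mers.
#' @return A number.
#' @export
spectrum_median <- function(graph, weighted = FALSE) {
  stopifnot(inherits(graph, "dbg_graph"))
  counts <- cpp_counts(graph$ptr)
  if (length(counts) == 0L) stop("graph is empty")
  if (weighted) weighted_median(counts) else median(as.numeric(counts))
}

weighted_median <- function(counts) {
  x <- sort(as.numeric(counts))
  # median over instances: each count value repeated count times
  w <- x
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  i <- which(cw >= tot / 2)[1L]
  if (cw[i] == tot / 2 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

#' Vertex table of a de Bruijn graph
#'
#' A deterministic (lexicographically sorted) tabular view of the graph:
#' one row per vertex with its count and in/out edge characters (`-` when
#' empty).  This is also the serialization payload of [serialize_graph()].
#'
#' @param graph A `dbg_graph`.
#' @return A `data.frame` with columns `kmer`, `count`, `in_chars`,
#'   `out_chars`.
#' @export
graph_table <- function(graph) {
  stopifnot(inherits(graph, "dbg_graph"))
  cpp_graph_table(graph$ptr)
}

#' Reconstruct a de Bruijn graph from a vertex table
#'
#' Inverse of [graph_table()]; mainly used by [deserialize_graph()] and for
#' constructing small fixture graphs with chosen coverages.
#'
#' @param table A `data.frame` with columns `kmer`, `count`, `in_chars`,
#'   `out_chars`.
#' @param k K-mer length.
#' @param canonical Whether the stored k-mers are strand-canonicalized.
#' @param total_instances Total instance count; defaults to `sum(count)`.
#' @return A `dbg_graph`.
#' @export
graph_from_table <- function(table, k, canonical = FALSE,
                             total_instances = sum(table$count)) {
  k <- check_k(k)
  ptr <- cpp_graph_from_table(as.character(table$kmer),
                              as.integer(table$count),
                              as.character(table$in_chars),
                              as.character(table$out_chars),
                              k, canonical, as.numeric(total_instances))
  new_dbg(ptr, k, canonical)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
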