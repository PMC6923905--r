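GRAPH_FORMAT_VERSION <- 1L

#' Serialize a de Bruijn graph to a tab-separated text dump
#'
#' The format is a versioned header line followed by one tab-separated line
#' per vertex: `kmer  count  in-chars  out-chars` (edge-character sets, `-`
#' when empty), sorted lexicographically by k-mer.  A `.gz` path suffix
#' triggers gzip compression.  `deserialize_graph(serialize_graph(g))`
#' reproduces the graph exactly.
#'
#' @param graph A `dbg_graph`.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
serialize_graph <- function(graph, path) {
  stopifnot(inherits(graph, "dbg_graph"))
  tab <- graph_table(graph)
  header <- sprintf("#dbg\t%d\tk=%d\tcanonical=%d\ttotal=%.0f",
                    GRAPH_FORMAT_VERSION, graph$k,
                    as.integer(graph$canonical), total_instances(graph))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header,
               if (nrow(tab)) paste(tab$kmer, tab$count, tab$in_chars,
                                    tab$out_chars, sep = "\t")),
             con)
  invisible(path)
}

#' @rdname serialize_graph
#' @return `deserialize_graph` returns the reconstructed `dbg_graph`.
#' @export
deserialize_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)  # file() handles gzip transparently
  if (length(lines) == 0L) stop("graph format error: empty file ", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) < 5L || hdr[1L] != "#dbg")
    stop("graph format error in ", path, ": unrecognized header")
  version <- suppressWarnings(as.integer(hdr[2L]))
  if (is.na(version) || version != GRAPH_FORMAT_VERSION)
    stop("graph format error in ", path, ": unsupported version '", hdr[2L],
         "' (expected ", GRAPH_FORMAT_VERSION, ")")
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(hit) != 1L)
      stop("graph format error in ", path, ": missing header field '", key, "'")
    sub(paste0("^", key, "="), "", hit)
  }
  k <- suppressWarnings(as.integer(get_field("k")))
  canonical <- identical(get_field("canonical"), "1")
  total <- suppressWarnings(as.numeric(get_field("total")))
  if (is.na(k) || is.na(total))
    stop("graph format error in ", path, ": malformed header fields")
  body <- lines[-1L]
  if (length(body) == 0L) {
    tab <- data.frame(kmer = character(0), count = integer(0),
                      in_chars = character(0), out_chars = character(0))
    return(graph_from_table(tab, k, canonical, total_instances = total))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop("graph format error in ", path, " at line ",
         which(nf != 4L)[1L] + 1L, ": expected 4 tab-separated fields")
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  counts <- suppressWarnings(as.integer(m[, 2L]))
  if (anyNA(counts) || any(counts < 1L))
    stop("graph format error in ", path, " at line ",
         which(is.na(counts) | counts < 1L)[1L] + 1L,
         ": count is not a positive integer")
  tab <- data.frame(kmer = m[, 1L], count = counts, in_chars = m[, 3L],
                    out_chars = m[, 4L], stringsAsFactors = FALSE)
  tryCatch(graph_from_table(tab, k, canonical, total_instances = total),
           error = function(e)
             stop("graph format error in ", path, ": ",
                  conditionMessage(e), call. = FALSE))
}
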