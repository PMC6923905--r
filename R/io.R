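#' Read sequences from a FASTA or FASTQ file
#'
#' Reads a (possibly gzip-compressed) FASTA or FASTQ file into a read set: a
#' `data.frame` with one row per record and columns `id`, `seq` and `qual`
#' (`NA` when the input carries no qualities).  Sequences are upper-cased on
#' ingest; quality strings are preserved verbatim and never interpreted.
#'
#' @param path Path to the input file.  Files ending in `.gz` are
#'   decompressed transparently.
#' @param format One of `"fasta"`, `"fastq"` or `"auto"` (detect from the
#'   file extension, falling back to the first byte).
#' @return A `data.frame` with columns `id` (character, unique), `seq`
#'   (character over `A,C,G,T,N`), `qual` (character or `NA`).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT", ">r2", "ggtt"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- sniff_format(path)
  if (format == "fastq") validate_fastq(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format,
                                 with.qualities = (format == "fastq")),
    error = function(e) {
      stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  ids <- names(x)
  seqs <- toupper(as.character(x))
  if (anyNA(ids) || any(ids == ""))
    stop("parse error in ", path, ": record without an identifier")
  if (anyDuplicated(ids))
    stop("duplicate read id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("parse error in ", path, ": empty sequence for record ",
         ids[which(nchar(seqs) == 0L)[1L]])
  qual <- rep(NA_character_, length(x))
  if (format == "fastq") {
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad))
      stop("parse error in ", path, ": quality length does not match ",
           "sequence length for record ", ids[bad[1L]])
  }
  data.frame(id = unname(ids), seq = unname(seqs), qual = unname(qual),
             stringsAsFactors = FALSE)
}

sniff_format <- function(path) {
  base <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", base))
  if (ext %in% c("fa", "fasta", "fna", "ffn")) return("fasta")
  if (ext %in% c("fq", "fastq")) return("fastq")
  con <- file(path, "rb")  # file() decompresses gzip transparently
  on.exit(close(con))
  first <- readChar(con, 1L)
  if (identical(first, ">")) "fasta"
  else if (identical(first, "@")) "fastq"
  else stop("cannot detect sequence format of ", path)
}

# Structural pre-validation of 4-line FASTQ (Biostrings mis-slices records
# whose quality length disagrees with the sequence length instead of
# erroring, so the contract check happens here).
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible())
  if (length(lines) %% 4L != 0L)
    stop("parse error in ", path, ": truncated FASTQ record at end of file")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  seps <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(ids, "@")) || !all(startsWith(seps, "+")))
    stop("parse error in ", path, ": malformed FASTQ record structure")
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad))
    stop("parse error in ", path, ": quality length does not match ",
         "sequence length for record ", sub("^@", "", ids[bad[1L]]))
  invisible()
}

#' Write sequences to a FASTA or FASTQ file
#'
#' Inverse of [read_sequences()]: `read_sequences(write_sequences(x))`
#' reproduces ids and sequences exactly.  Writing FASTQ requires every record
#' to carry a quality string; otherwise the records are emitted as FASTA with
#' a warning (per-base qualities cannot be invented).
#'
#' @param records A read set `data.frame` with columns `id`, `seq` and
#'   optionally `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param format `"fasta"` or `"fastq"`.
#' @return Invisibly, the path written.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  qual <- if ("qual" %in% names(records)) records$qual else
    rep(NA_character_, nrow(records))
  if (format == "fastq" && (nrow(records) > 0L) && anyNA(qual)) {
    warning("records lack quality strings; writing FASTA instead")
    format <- "fasta"
  }
  x <- Biostrings::DNAStringSet(setNames(as.character(records$seq),
                                         records$id))
  compress <- grepl("\\.gz$", path, ignore.case = TRUE)
  if (format == "fastq") {
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(qual),
                                compress = compress)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 20000L,
                                compress = compress)
  }
  invisible(path)
}
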