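#' Stream a FASTQ file in chunks
#'
#' Reads standard 4-line FASTQ records, plain or gzip-compressed (compression
#' is detected transparently), and calls \code{callback} on successive chunks
#' so arbitrarily large files are processed in bounded memory. A file whose
#' line count is not a multiple of 4 is rejected with the index of the
#' truncated record.
#'
#' @param path FASTQ(.gz) path.
#' @param callback function called as \code{callback(chunk)} where
#'   \code{chunk} is a data frame with columns \code{read_id},
#'   \code{sequence}, \code{quality}.
#' @param chunk_size records per chunk.
#' @return total number of records streamed, invisibly.
#' @export
stream_fastq <- function(path, callback, chunk_size = 50000L) {
  if (!file.exists(path)) stop(sprintf("FASTQ file not found: %s", path))
  con <- gzfile(path, "r")
  on.exit(close(con))
  total <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L)
      stop(sprintf("truncated FASTQ record %d in %s (file is not a multiple of 4 lines)",
                   total + length(lines) %/% 4L + 1L, path))
    n <- length(lines) %/% 4L
    at <- lines[seq(1L, length(lines), by = 4L)]
    seqs <- lines[seq(2L, length(lines), by = 4L)]
    qual <- lines[seq(4L, length(lines), by = 4L)]
    bad <- which(substr(at, 1L, 1L) != "@")
    if (length(bad))
      stop(sprintf("malformed FASTQ record %d in %s: header does not start with '@'",
                   total + bad[1L], path))
    bad_q <- which(nchar(seqs) != nchar(qual))
    if (length(bad_q))
      stop(sprintf("FASTQ record %d in %s: sequence and quality lengths differ",
                   total + bad_q[1L], path))
    callback(data.frame(read_id = sub("^@", "", at), sequence = seqs,
                        quality = qual, stringsAsFactors = FALSE))
    total <- total + n
  }
  invisible(total)
}

#' Read an entire FASTQ file into a data frame
#'
#' @param path FASTQ(.gz) path.
#' @return data frame with columns \code{read_id}, \code{sequence},
#'   \code{quality}, in file order.
#' @export
read_fastq <- function(path) {
  chunks <- list()
  stream_fastq(path, function(chunk) chunks[[length(chunks) + 1L]] <<- chunk)
  if (length(chunks) == 0L)
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  do.call(rbind, chunks)
}

#' Write reads to a FASTQ file
#'
#' @param reads data frame with columns \code{read_id}, \code{sequence},
#'   \code{quality}.
#' @param path output path; written gzip-compressed if it ends in \code{.gz}.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
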