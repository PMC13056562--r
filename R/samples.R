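#' Read and validate a sample sheet
#'
#' The sample sheet describes the experiment layout: one row per sequencing
#' library with columns \code{sample_id}, \code{model}, \code{capsid},
#' \code{fraction} (\code{premix}, \code{gDNA} or \code{cDNA}),
#' \code{replicate} and \code{reads_path}. Validation enforces the pairing
#' the Expression Index needs: every (model, capsid, replicate) with a cDNA
#' library must also have a gDNA library, and each capsid batch has exactly
#' one premix library (the pre-transduction mix it is normalised to).
#'
#' @param path path to the TSV sample sheet.
#' @param check_files if TRUE, error when a referenced reads file is missing.
#' @return a \code{sample_sheet} data frame.
#' @export
read_sample_sheet <- function(path, check_files = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "model", "capsid", "fraction", "replicate",
            "reads_path")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("sample sheet %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  # relative reads paths are taken relative to the sheet's directory
  rel <- !is.na(tab$reads_path) & !grepl("^(/|[A-Za-z]:)", tab$reads_path)
  tab$reads_path[rel] <- file.path(dirname(path), tab$reads_path[rel])
  sample_sheet(tab, check_files = check_files)
}

#' Construct and validate a sample sheet from a data frame
#'
#' @param records data frame with columns \code{sample_id}, \code{model},
#'   \code{capsid}, \code{fraction}, \code{replicate}, \code{reads_path}.
#' @param check_files if TRUE, error when a referenced reads file is missing.
#' @return a \code{sample_sheet} data frame.
#' @export
sample_sheet <- function(records, check_files = FALSE) {
  if (nrow(records) == 0L) stop("no samples in sample sheet")
  for (col in c("sample_id", "model", "capsid", "fraction", "reads_path"))
    records[[col]] <- trimws(as.character(records[[col]]))
  records$replicate <- as.integer(records$replicate)

  dup <- which(duplicated(records$sample_id))
  if (length(dup))
    stop(sprintf("duplicate sample_id '%s'", records$sample_id[dup[1L]]))
  bad_frac <- which(!records$fraction %in% c("premix", "gDNA", "cDNA"))
  if (length(bad_frac))
    stop(sprintf("unknown fraction '%s' for sample '%s'",
                 records$fraction[bad_frac[1L]],
                 records$sample_id[bad_frac[1L]]))
  if (any(!is.na(records$replicate) & records$replicate < 1L))
    stop("replicate numbers must be >= 1")

  # every cDNA library needs its gDNA partner
  key <- function(d) paste(d$model, d$capsid, d$replicate, sep = "\r")
  cdna <- records[records$fraction == "cDNA", , drop = FALSE]
  gdna <- records[records$fraction == "gDNA", , drop = FALSE]
  orphan <- which(!key(cdna) %in% key(gdna))
  if (length(orphan))
    stop(sprintf("cDNA sample '%s' (%s/%s replicate %d) has no matching gDNA sample",
                 cdna$sample_id[orphan[1L]], cdna$model[orphan[1L]],
                 cdna$capsid[orphan[1L]], cdna$replicate[orphan[1L]]))

  pre <- records[records$fraction == "premix", , drop = FALSE]
  dup_pre <- which(duplicated(pre$capsid))
  if (length(dup_pre))
    stop(sprintf("more than one premix sample for capsid '%s'",
                 pre$capsid[dup_pre[1L]]))
  no_pre <- setdiff(records$capsid, pre$capsid)
  if (length(no_pre))
    stop(sprintf("capsid '%s' has samples but no premix library", no_pre[1L]))

  if (check_files) {
    missing <- records$reads_path[!file.exists(records$reads_path)]
    if (length(missing))
      stop(sprintf("reads file not found: %s", missing[1L]))
  }
  class(records) <- c("sample_sheet", "data.frame")
  records
}

#' Write a sample sheet to TSV
#' @param sheet a \code{sample_sheet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  cols <- c("sample_id", "model", "capsid", "fraction", "replicate",
            "reads_path")
  utils::write.table(as.data.frame(sheet)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# premix sample_id for a capsid batch
premix_sample <- function(sheet, capsid) {
  id <- sheet$sample_id[sheet$fraction == "premix" & sheet$capsid == capsid]
  if (length(id) != 1L)
    stop(sprintf("expected exactly one premix sample for capsid '%s', found %d",
                 capsid, length(id)))
  id
}
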