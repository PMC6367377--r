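#' Read a protein FASTA file
#'
#' Thin wrapper around \code{Biostrings::readAAStringSet} that returns a
#' plain data frame. Record order is preserved and sequences are
#' uppercased; gap (\code{-}, \code{.}) and stop (\code{*}) characters are
#' stripped when \code{strip_gaps} is \code{TRUE}.
#'
#' @param path Path to a FASTA file.
#' @param strip_gaps Remove gap and stop characters from sequences.
#' @return A data frame with columns \code{id} and \code{sequence}.
#' @export
read_fasta <- function(path, strip_gaps = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("empty FASTA file (no records): ", path)
  }
  seqs <- toupper(as.character(set))
  if (strip_gaps) {
    seqs <- gsub("[-.*]", "", seqs)
  }
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(seqs),
    stringsAsFactors = FALSE
  )
}

#' Write a protein FASTA file
#'
#' Inverse of \code{\link{read_fasta}}: writing then reading restores the
#' same records.
#'
#' @param records Data frame with columns \code{id} and \code{sequence}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a TSV table with header
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A data frame; character columns are never converted to factors.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a TSV table with header
#'
#' Exact inverse of \code{\link{read_tsv}} on valid inputs.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
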