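#' Load the curated tomato nsLTP reference table
#'
#' The package ships a machine-readable transcription of the 64-gene
#' curated tomato nsLTP census: gene identifier, genomic position
#' (chromosome, start, stop, strand; 1-based inclusive), exon count,
#' intron position (nucleotides downstream of the last ECM cysteine;
#' blank for single-exon genes), sub-family labels under two published
#' classification schemes, protein lengths (full, signal peptide, mature)
#' and the ECM descriptor string. The Edstam-scheme column
#' (\code{type_edstam}) is stored verbatim but never recomputed by this
#' package (its assignment rules are not defined here).
#'
#' Every load re-validates the table: exactly 64 rows, unique gene IDs,
#' every descriptor parses into a 5-gap spacing vector whose implied ECM
#' length matches the stored \code{ecm_length}, and
#' \code{full_length == signal_length + mature_length} row-wise.
#'
#' Columns of \code{inst/extdata/table1_nsltp.tsv}:
#' \describe{
#'   \item{gene_id}{Solyc gene identifier (chromosome encoded in the
#'     prefix).}
#'   \item{chromosome}{Chromosome number, 1--12.}
#'   \item{start, stop}{Genomic gene bounds, 1-based inclusive.}
#'   \item{strand}{\code{+} or \code{-}.}
#'   \item{n_exons}{Exon count of the gene model.}
#'   \item{intron_position}{Nucleotides downstream of the last ECM
#'     cysteine (blank/NA for single-exon genes; stored as printed).}
#'   \item{type_edstam}{Sub-family label under the Edstam scheme
#'     (\code{1}, \code{2}, \code{C}, \code{D} or \code{n.d.}); stored,
#'     never computed.}
#'   \item{type_boutrot}{Sub-family label under the spacing-rule scheme
#'     (I, II, III, IV, X, XI); reproducible via
#'     \code{\link{classify_spacings}}.}
#'   \item{full_length, signal_length, mature_length}{Protein lengths in
#'     residues; full = signal + mature.}
#'   \item{ecm_length}{ECM span in residues; equals 9 + sum of gaps.}
#'   \item{ecm_descriptor}{Canonical motif descriptor, see
#'     \code{\link{ecm_descriptor}}.}
#' }
#'
#' @return A data frame of 64 rows with attribute \code{provenance_note}.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_nsltp.tsv", package = "nsltpscan",
                      mustWork = TRUE)
  t1 <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE,
                   colClasses = list(intron_position = "character"))
  req <- c("gene_id", "chromosome", "start", "stop", "strand", "n_exons",
           "intron_position", "type_edstam", "type_boutrot", "full_length",
           "signal_length", "mature_length", "ecm_length", "ecm_descriptor")
  if (!identical(names(t1), req)) {
    stop("reference table corrupted: unexpected column layout")
  }
  if (nrow(t1) != 64L) {
    stop("reference table corrupted: expected 64 rows, found ", nrow(t1))
  }
  if (anyDuplicated(t1$gene_id)) {
    stop("reference table corrupted: duplicated gene IDs")
  }
  sp <- lapply(t1$ecm_descriptor, parse_ecm_descriptor)
  implied <- vapply(sp, ecm_length, numeric(1L))
  if (!all(implied == t1$ecm_length)) {
    stop("reference table corrupted: ECM length identity violated for ",
         paste(t1$gene_id[implied != t1$ecm_length], collapse = ", "))
  }
  if (!all(t1$full_length == t1$signal_length + t1$mature_length)) {
    stop("reference table corrupted: full != signal + mature")
  }
  t1$intron_position[t1$intron_position == ""] <- NA_character_
  attr(t1, "provenance_note") <- paste(
    "Curated 64-gene tomato nsLTP census; intron position stored exactly",
    "as printed (blank/NA for single-exon genes); all rows reconcile with",
    "the internal identities full = signal + mature and",
    "ECM length = 9 + sum(gaps)."
  )
  t1
}

#' Spacing vectors for every reference-table row
#'
#' Convenience accessor: parses each stored ECM descriptor into its
#' five-gap spacing vector.
#'
#' @param fixture Data frame from \code{\link{load_table1_fixture}}.
#' @return A 64 x 5 integer matrix with columns a--e and gene IDs as row
#'   names.
#' @export
fixture_spacings <- function(fixture = load_table1_fixture()) {
  m <- t(vapply(fixture$ecm_descriptor, parse_ecm_descriptor, integer(5L)))
  dimnames(m) <- list(fixture$gene_id, c("a", "b", "c", "d", "e"))
  m
}
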