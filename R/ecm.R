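#' Default inter-cysteine gap bounds for ECM scanning
#'
#' Elementwise envelope of the published tomato sub-family spacing ranges,
#' widened by two residues on each side so that every catalogued type fits
#' while pathological cysteine arrangements are rejected.
#'
#' @return Named list of length-2 integer vectors \code{(min, max)} for
#'   gaps \code{a}--\code{e}.
#' @export
default_ecm_bounds <- function() {
  list(a = c(5L, 12L), b = c(10L, 24L), c = c(6L, 27L),
       d = c(10L, 27L), e = c(4L, 16L))
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.check_protein <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L) {
    stop("sequence must be a single non-empty amino-acid string")
  }
  res <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(unique(res), c(AA_LETTERS, "X"))
  if (length(bad)) {
    stop("non-amino-acid characters in sequence: ",
         paste(bad, collapse = ", "))
  }
  res
}

#' Locate the eight-cysteine motif in a protein sequence
#'
#' Scans for the skeleton \code{C Xa C Xb C C Xc C X C Xd C Xe C}: eight
#' cysteines, the third and fourth adjacent (CC), the fifth and sixth
#' separated by exactly one non-cysteine residue (CXC), with the five free
#' gaps constrained to \code{search_bounds}. Because no gap may contain a
#' cysteine, any match uses eight consecutive cysteines of the sequence;
#' the scanner therefore slides an eight-cysteine window across the
#' cysteine positions. Ambiguity is resolved deterministically: leftmost
#' start first, then smallest total span. The ambiguity code \code{X} in
#' the sequence never matches a motif cysteine.
#'
#' @param sequence Amino-acid string (standard letters plus \code{X}).
#' @param search_bounds Per-gap \code{(min, max)} ranges, as
#'   \code{\link{default_ecm_bounds}}.
#' @param protein_id Identifier carried into the result.
#' @return An object of class \code{ecm_match} (fields \code{protein_id},
#'   \code{start}, \code{end}, \code{spacings}, \code{descriptor}), or
#'   \code{NULL} if no arrangement fits.
#' @export
find_ecm <- function(sequence, search_bounds = default_ecm_bounds(),
                     protein_id = NA_character_) {
  res <- .check_protein(sequence)
  cpos <- which(res == "C")
  if (length(cpos) < 8L) return(NULL)
  hits <- list()
  for (i in seq_len(length(cpos) - 7L)) {
    p <- cpos[i:(i + 7L)]
    # skeleton: CC block at cysteines 3-4, CXC at 5-6
    if (p[4L] != p[3L] + 1L) next
    if (p[6L] != p[5L] + 2L) next
    gaps <- c(a = p[2L] - p[1L] - 1L, b = p[3L] - p[2L] - 1L,
              c = p[5L] - p[4L] - 1L, d = p[7L] - p[6L] - 1L,
              e = p[8L] - p[7L] - 1L)
    ok <- all(vapply(seq_len(5L), function(k) {
      b <- search_bounds[[k]]
      gaps[k] >= b[1L] && gaps[k] <= b[2L]
    }, logical(1L)))
    if (!ok) next
    hits[[length(hits) + 1L]] <- list(start = p[1L], end = p[8L],
                                      spacings = gaps)
  }
  if (!length(hits)) return(NULL)
  starts <- vapply(hits, `[[`, integer(1L), "start")
  spans <- vapply(hits, function(h) h$end - h$start + 1L, integer(1L))
  best <- hits[[order(starts, spans)[1L]]]
  structure(
    list(protein_id = protein_id, start = best$start, end = best$end,
         spacings = best$spacings,
         descriptor = ecm_descriptor(best$spacings)),
    class = "ecm_match"
  )
}

#' @export
print.ecm_match <- function(x, ...) {
  cat(sprintf("<ecm_match> %s  [%d-%d]  %s\n",
              if (is.na(x$protein_id)) "(unnamed)" else x$protein_id,
              x$start, x$end, x$descriptor))
  invisible(x)
}

#' Canonical ECM descriptor string from a spacing vector
#'
#' @param spacings Five non-negative integers (gaps a--e).
#' @return The string \code{"C-Xa-C-Xb-CC-Xc-CXC-Xd-C-Xe-C"}.
#' @export
ecm_descriptor <- function(spacings) {
  spacings <- .check_spacings(spacings)
  sprintf("C-X%d-C-X%d-CC-X%d-CXC-X%d-C-X%d-C",
          spacings[1L], spacings[2L], spacings[3L], spacings[4L],
          spacings[5L])
}

#' Parse a canonical ECM descriptor back into its spacing vector
#'
#' Inverse of \code{\link{ecm_descriptor}}.
#'
#' @param descriptor Descriptor string.
#' @return Named integer vector \code{c(a, b, c, d, e)}.
#' @export
parse_ecm_descriptor <- function(descriptor) {
  m <- regmatches(descriptor,
                  regexec("^C-X(\\d+)-C-X(\\d+)-CC-X(\\d+)-CXC-X(\\d+)-C-X(\\d+)-C$",
                          descriptor))[[1L]]
  if (length(m) != 6L) {
    stop("not a canonical ECM descriptor: '", descriptor, "'")
  }
  setNames(as.integer(m[-1L]), c("a", "b", "c", "d", "e"))
}

.check_spacings <- function(spacings) {
  spacings <- as.integer(spacings)
  if (length(spacings) != 5L || anyNA(spacings) || any(spacings < 0L)) {
    stop("spacings must be 5 non-negative integers")
  }
  spacings
}

#' ECM span implied by a spacing vector
#'
#' The motif holds 8 cysteines plus the single X of the CXC block, so the
#' span is \code{9 + a + b + c + d + e} residues.
#'
#' @param spacings Five non-negative integers (gaps a--e).
#' @return Integer span in residues.
#' @export
ecm_length <- function(spacings) {
  spacings <- .check_spacings(spacings)
  9L + sum(spacings)
}

#' Per-column information content of an alignment column, in bits
#'
#' Sequence-logo information content over the 20-letter amino-acid
#' alphabet: \code{log2(20)} minus the Shannon entropy of the empirical
#' residue frequencies. A fully conserved column scores
#' \code{log2(20) ~ 4.32} bits, a uniform column 0 bits. The optional
#' small-sample correction subtracts \code{(K - 1) / (2 ln(2) n)} with
#' \code{K = 20}.
#'
#' @param residue_counts Non-negative counts; names are residue letters
#'   (unnamed vectors are taken as already tabulated counts).
#' @param small_sample_correction Apply the approximate small-n correction
#'   (default off; results are then clamped at 0).
#' @return Information content in bits (non-negative).
#' @export
column_information <- function(residue_counts, small_sample_correction = FALSE) {
  counts <- as.numeric(residue_counts)
  if (anyNA(counts) || any(counts < 0)) {
    stop("residue_counts must be non-negative numbers")
  }
  n <- sum(counts)
  if (n <= 0) stop("residue_counts sums to zero: no observations")
  p <- counts[counts > 0] / n
  h <- -sum(p * log2(p))
  ic <- log2(20) - h
  if (small_sample_correction) {
    ic <- ic - 19 / (2 * log(2) * n)
  }
  max(ic, 0)
}
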