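#' Published tomato sub-family spacing rules
#'
#' The allowed inter-cysteine gap sets per Boutrot-style type, as
#' catalogued for the tomato family. Each entry gives, for gaps a--e, the
#' exact set of admissible residue counts.
#'
#' @return Named list (types I, II, III, IV, X, XI) of named lists of
#'   integer vectors.
#' @export
boutrot_rules <- function() {
  list(
    I   = list(a = 9L, b = c(12L, 13L, 14L, 16L), c = 19L,
               d = c(21L, 22L, 23L), e = c(13L, 14L)),
    II  = list(a = c(7L, 8L), b = c(13L, 14L, 17L), c = 8L,
               d = 23L, e = 6L),
    III = list(a = 9L, b = c(14L, 16L), c = 9L, d = 12L, e = 6L),
    IV  = list(a = 9L, b = 15L, c = 9L, d = 24L, e = c(6L, 7L)),
    X   = list(a = c(9L, 10L), b = c(14L, 17L), c = c(19L, 20L, 21L),
               d = c(20L, 21L), e = c(12L, 13L)),
    XI  = list(a = 9L, b = c(18L, 19L, 20L, 22L), c = 13L,
               d = c(24L, 25L), e = 9L)
  )
}

.matches_rule <- function(spacings, rule) {
  all(vapply(seq_len(5L), function(k) spacings[k] %in% rule[[k]],
             logical(1L)))
}

#' Assign a sub-family type from an ECM spacing vector
#'
#' Strict mode checks the tuple against each type's exact published gap
#' sets; tuples matching no type are labelled \code{"n.d."} (not
#' determined). The published type I and type X gap sets overlap on one
#' corner of their ranges (e.g. the tuple \code{(9,14,19,21,13)} satisfies
#' both), so ambiguity handling is explicit: the default resolves by
#' canonical type precedence (I, II, III, IV, X, XI; first match wins),
#' which reproduces the published per-gene assignments;
#' \code{on_ambiguous = "error"} raises a configuration error listing the
#' colliding types instead.
#'
#' Nearest-pattern mode (\code{mode = "nearest"}) assigns the type whose
#' gap sets minimize the summed absolute deviation, provided that
#' deviation does not exceed \code{max_deviation}; beyond the cap the
#' tuple is labelled \code{"n.d."}. This mode is meant for surveying novel
#' motifs and is off by default.
#'
#' @param spacings Five non-negative integers (gaps a--e).
#' @param rules Rule table, as \code{\link{boutrot_rules}}.
#' @param mode \code{"strict"} (default) or \code{"nearest"}.
#' @param on_ambiguous \code{"first"} (default) or \code{"error"}.
#' @param max_deviation Cap on the summed gap deviation in nearest mode.
#' @return A type label (\code{"I"}, \code{"II"}, ..., \code{"XI"}) or
#'   \code{"n.d."}.
#' @export
classify_spacings <- function(spacings, rules = boutrot_rules(),
                              mode = c("strict", "nearest"),
                              on_ambiguous = c("first", "error"),
                              max_deviation = 3L) {
  spacings <- .check_spacings(spacings)
  mode <- match.arg(mode)
  on_ambiguous <- match.arg(on_ambiguous)
  if (mode == "strict") {
    hit <- names(rules)[vapply(rules, .matches_rule, logical(1L),
                               spacings = spacings)]
    if (length(hit) == 0L) return("n.d.")
    if (length(hit) > 1L && on_ambiguous == "error") {
      stop("rule-table ambiguity: spacing tuple (",
           paste(spacings, collapse = ","), ") matches types ",
           paste(hit, collapse = ", "))
    }
    return(hit[1L])
  }
  dev <- vapply(rules, function(rule) {
    sum(vapply(seq_len(5L), function(k) min(abs(spacings[k] - rule[[k]])),
               numeric(1L)))
  }, numeric(1L))
  if (min(dev) > max_deviation) return("n.d.")
  names(rules)[which.min(dev)]
}

#' Curate annotated nsLTP candidates
#'
#' Applies the census curation filters in their canonical order: drop
#' candidates lacking an N-terminal signal peptide, drop candidates with a
#' chloroplast or mitochondrial transit peptide, set aside (not delete)
#' candidates with a C-terminal GPI anchor signal, drop members of related
#' but distinct families (alpha-amylase/trypsin inhibitors, proline-rich,
#' hybrid proline-rich, glycine-rich proteins). Each candidate receives
#' exactly one disposition; the retained set is the classification input.
#'
#' @param candidates Data frame with columns \code{id},
#'   \code{has_signal_peptide} (logical), \code{transit_peptide}
#'   (\code{"none"}, \code{"chloroplast"} or \code{"mitochondrial"}),
#'   \code{has_gpi_anchor} (logical) and \code{family_outlier}
#'   (\code{"none"} or a family label).
#' @return An object of class \code{curation_ledger}: counts per
#'   disposition plus the per-candidate disposition table.
#' @export
curate <- function(candidates) {
  req <- c("id", "has_signal_peptide", "transit_peptide", "has_gpi_anchor",
           "family_outlier")
  if (!is.data.frame(candidates)) stop("candidates must be a data frame")
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols)) {
    stop("candidates lack annotation column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in req[-1L]) {
    bad <- which(is.na(candidates[[col]]))
    if (length(bad)) {
      stop("missing annotation '", col, "' for candidate ",
           candidates$id[bad[1L]])
    }
  }
  n <- nrow(candidates)
  disposition <- character(n)
  for (i in seq_len(n)) {
    disposition[i] <-
      if (!candidates$has_signal_peptide[i]) "removed_no_signal"
      else if (candidates$transit_peptide[i] != "none") "removed_transit"
      else if (candidates$has_gpi_anchor[i]) "gpi_set_aside"
      else if (candidates$family_outlier[i] != "none") "removed_family_outlier"
      else "retained"
  }
  transit <- candidates$transit_peptide[disposition == "removed_transit"]
  structure(
    list(
      n_input = n,
      n_removed_no_signal = sum(disposition == "removed_no_signal"),
      n_removed_transit = sum(disposition == "removed_transit"),
      n_removed_transit_chloroplast = sum(transit == "chloroplast"),
      n_removed_transit_mitochondrial = sum(transit == "mitochondrial"),
      n_gpi_set_aside = sum(disposition == "gpi_set_aside"),
      n_removed_family_outlier = sum(disposition == "removed_family_outlier"),
      n_retained = sum(disposition == "retained"),
      dispositions = data.frame(id = candidates$id,
                                disposition = disposition,
                                stringsAsFactors = FALSE)
    ),
    class = "curation_ledger"
  )
}

#' @export
print.curation_ledger <- function(x, ...) {
  cat("<curation_ledger>\n")
  cat(sprintf("  input:                %4d\n", x$n_input))
  cat(sprintf("  no signal peptide:   -%4d\n", x$n_removed_no_signal))
  cat(sprintf("  transit peptide:     -%4d (chloroplast %d, mitochondrial %d)\n",
              x$n_removed_transit, x$n_removed_transit_chloroplast,
              x$n_removed_transit_mitochondrial))
  cat(sprintf("  GPI anchor (aside):  -%4d\n", x$n_gpi_set_aside))
  cat(sprintf("  family outliers:     -%4d\n", x$n_removed_family_outlier))
  cat(sprintf("  retained:             %4d\n", x$n_retained))
  invisible(x)
}

#' Count classified records per sub-family type
#'
#' @param types Character vector of type labels (including \code{"n.d."}).
#' @return Named integer vector over I, II, III, IV, X, XI and
#'   \code{"n.d."}.
#' @export
census_by_type <- function(types) {
  levels <- c("I", "II", "III", "IV", "X", "XI", "n.d.")
  unknown <- setdiff(unique(types), levels)
  if (length(unknown)) {
    stop("unknown type label(s): ", paste(unknown, collapse = ", "))
  }
  table(factor(types, levels = levels)) |> as.integer() |>
    setNames(levels)
}
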