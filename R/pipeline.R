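#' Run the full nsLTP census pipeline
#'
#' Orchestrates scan, curation, classification, structure and census
#' reporting as one reproducible run. Two input modes are supported
#' through the \code{config} list:
#' \itemize{
#'   \item \strong{records mode} (\code{config$records}): a
#'     Table-shaped data frame (as \code{\link{load_table1_fixture}})
#'     whose ECM descriptors are classified directly;
#'   \item \strong{fasta mode} (\code{config$fasta}): a protein FASTA is
#'     scanned with \code{\link{find_ecm}}; an optional
#'     \code{config$annotations} TSV (curation columns, see
#'     \code{\link{curate}}) is applied first, and only retained
#'     candidates are scanned.
#' }
#' Recognized config entries: \code{records}, \code{fasta},
#' \code{annotations}, \code{bounds} (default
#' \code{\link{default_ecm_bounds}}), \code{max_gap} (default 200000),
#' \code{same_type_required} (default FALSE), \code{out_dir} (optional;
#' where typed.tsv, ledger.json, census.json and run.log are written).
#' All thresholds and the rule table are echoed into the report so every
#' reported number is traceable to its configuration.
#'
#' @param config Named list, see Details.
#' @return Report list (schema version, config echo, typed table, ledger,
#'   census), invisibly when \code{out_dir} is set.
#' @export
run_census <- function(config = list()) {
  bounds <- config$bounds %||% default_ecm_bounds()
  max_gap <- config$max_gap %||% 200000L
  same_type <- isTRUE(config$same_type_required)
  log_lines <- c(sprintf("nsltpscan run_census  schema 1.0  package %s",
                         as.character(utils::packageVersion("nsltpscan"))),
                 sprintf("max_gap=%d same_type_required=%s", max_gap,
                         same_type))
  ledger <- NULL

  if (!is.null(config$records)) {
    typed <- config$records
    sp <- t(vapply(typed$ecm_descriptor, parse_ecm_descriptor, integer(5L)))
    typed$type <- apply(sp, 1L, classify_spacings)
    typed[c("a", "b", "c", "d", "e")] <- as.data.frame(sp)
    log_lines <- c(log_lines,
                   sprintf("records mode: %d input records", nrow(typed)))
  } else if (!is.null(config$fasta)) {
    proteins <- tryCatch(read_fasta(config$fasta), error = function(e) {
      warning("no usable FASTA records (", conditionMessage(e),
              "); emitting an empty report")
      NULL
    })
    if (!is.null(config$annotations) && !is.null(proteins)) {
      ann <- read_tsv(config$annotations)
      ledger <- curate(ann)
      keep <- ledger$dispositions$id[ledger$dispositions$disposition ==
                                       "retained"]
      proteins <- proteins[proteins$id %in% keep, , drop = FALSE]
      log_lines <- c(log_lines,
                     sprintf("curation: %d/%d retained", ledger$n_retained,
                             ledger$n_input))
    }
    if (is.null(proteins) || nrow(proteins) == 0L) {
      typed <- data.frame(id = character(), type = character(),
                          ecm_descriptor = character(),
                          stringsAsFactors = FALSE)
    } else {
      rows <- lapply(seq_len(nrow(proteins)), function(i) {
        hit <- find_ecm(proteins$sequence[i], bounds,
                        protein_id = proteins$id[i])
        if (is.null(hit)) {
          data.frame(id = proteins$id[i], type = "n.d.",
                     ecm_descriptor = NA_character_, a = NA_integer_,
                     b = NA_integer_, c = NA_integer_, d = NA_integer_,
                     e = NA_integer_, stringsAsFactors = FALSE)
        } else {
          data.frame(id = proteins$id[i],
                     type = classify_spacings(hit$spacings),
                     ecm_descriptor = hit$descriptor,
                     a = hit$spacings[1L], b = hit$spacings[2L],
                     c = hit$spacings[3L], d = hit$spacings[4L],
                     e = hit$spacings[5L], stringsAsFactors = FALSE)
        }
      })
      typed <- do.call(rbind, rows)
    }
    log_lines <- c(log_lines,
                   sprintf("fasta mode: %d sequences typed", nrow(typed)))
  } else {
    stop("config must provide either 'records' or 'fasta'")
  }

  census <- list(type_counts = as.list(census_by_type(typed$type)))
  if ("n_exons" %in% names(typed) && nrow(typed)) {
    census$exon_histogram <- as.list(table(typed$n_exons))
  }
  if (all(c("full_length", "mature_length") %in% names(typed)) &&
      nrow(typed)) {
    census$length_stats <- list(
      full = family_length_stats(typed$full_length),
      mature = family_length_stats(typed$mature_length))
  }
  if ("chromosome" %in% names(typed) && nrow(typed)) {
    census$chromosome_census <-
      as.list(chromosome_census(typed$chromosome))
  }
  if (all(c("chromosome", "start") %in% names(typed)) && nrow(typed)) {
    id_col <- if ("gene_id" %in% names(typed)) "gene_id" else "id"
    cl <- detect_clusters(
      data.frame(gene_id = typed[[id_col]],
                 chromosome = typed$chromosome, start = typed$start,
                 type = typed$type, stringsAsFactors = FALSE),
      max_gap = max_gap, same_type_required = same_type)
    census$clusters <- list(
      clusters = cl$clusters, pairs = cl$pairs,
      n_singletons = length(cl$singletons),
      grouped_fraction = grouped_fraction(cl),
      max_gap = max_gap, same_type_required = same_type)
  }

  report <- list(
    schema_version = "1.0",
    config = list(mode = if (!is.null(config$records)) "records" else "fasta",
                  bounds = bounds, rules = boutrot_rules(),
                  max_gap = max_gap, same_type_required = same_type),
    typed = typed,
    ledger = if (!is.null(ledger)) ledger[setdiff(names(ledger),
                                                  "dispositions")],
    census = census
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(typed, file.path(config$out_dir, "typed.tsv"))
    jsonlite::write_json(report$census,
                         file.path(config$out_dir, "census.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$ledger)) {
      jsonlite::write_json(report$ledger,
                           file.path(config$out_dir, "ledger.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    return(invisible(report))
  }
  report
}

.flatten_report <- function(x, prefix = "") {
  if (is.data.frame(x)) {
    out <- list()
    for (nm in names(x)) {
      out[[paste0(prefix, "$", nm)]] <- x[[nm]]
    }
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      out <- c(out, .flatten_report(x[[i]], paste0(prefix, "$", nms[i])))
    }
    return(out)
  }
  setNames(list(x), prefix)
}

#' Field-level difference between two census reports
#'
#' @param report_a,report_b Two \code{\link{run_census}} reports of the
#'   same schema version.
#' @return Data frame with columns \code{field}, \code{a}, \code{b}; zero
#'   rows when the reports are identical.
#' @export
diff_reports <- function(report_a, report_b) {
  if (!identical(report_a$schema_version, report_b$schema_version)) {
    stop("report schema mismatch: ", report_a$schema_version, " vs ",
         report_b$schema_version)
  }
  fa <- .flatten_report(report_a)
  fb <- .flatten_report(report_b)
  fields <- union(names(fa), names(fb))
  rows <- lapply(fields, function(f) {
    va <- fa[[f]]; vb <- fb[[f]]
    if (identical(va, vb)) return(NULL)
    data.frame(field = f,
               a = paste(deparse(va), collapse = " "),
               b = paste(deparse(vb), collapse = " "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out %||% data.frame(field = character(), a = character(),
                      b = character(), stringsAsFactors = FALSE)
}
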