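#' Construct a gene model
#'
#' A gene model holds the genomic footprint of one mRNA and its CDS
#' segments. Coordinates are GFF3-native: 1-based, inclusive. CDS segments
#' are stored in transcript orientation (5' to 3' of the mRNA), i.e. in
#' decreasing genomic order for minus-strand genes.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome label.
#' @param strand \code{"+"} or \code{"-"}.
#' @param start,stop Genomic gene bounds (1-based inclusive).
#' @param cds Data frame with columns \code{start}, \code{stop}; one row
#'   per CDS segment, any order (sorted internally).
#' @param protein_id Optional identifier of the encoded protein.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, chromosome, strand, start, stop, cds,
                       protein_id = gene_id) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(cds),
            all(c("start", "stop") %in% names(cds)), nrow(cds) >= 1L)
  if (start > stop) stop("gene_model '", gene_id, "': start > stop")
  if (any(cds$start > cds$stop)) {
    stop("gene_model '", gene_id, "': CDS segment with start > stop")
  }
  cds <- cds[order(cds$start), c("start", "stop"), drop = FALSE]
  if (nrow(cds) > 1L && any(cds$start[-1L] <= cds$stop[-nrow(cds)])) {
    stop("gene_model '", gene_id, "': overlapping CDS segments")
  }
  if (min(cds$start) < start || max(cds$stop) > stop) {
    stop("gene_model '", gene_id, "': CDS outside gene bounds")
  }
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  rownames(cds) <- NULL
  structure(
    list(gene_id = gene_id, protein_id = protein_id,
         chromosome = as.character(chromosome), strand = strand,
         start = as.integer(start), stop = as.integer(stop), cds = cds),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  chr%s:%d-%d(%s)  %d CDS segment(s)\n",
              x$gene_id, x$chromosome, x$start, x$stop, x$strand,
              nrow(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features (via \code{rtracklayer::readGFF}) and
#' returns one \code{\link{gene_model}} per mRNA. mRNAs without any CDS
#' feature are skipped with a warning; CDS segments outside the parent
#' gene's bounds raise a consistency error.
#'
#' @param path Path to a GFF3 file.
#' @return A list of \code{gene_model} objects, named by mRNA ID.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$type <- as.character(g$type)
  g$ID <- as.character(g$ID)
  parent <- vapply(g$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }, character(1L))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_parent <- parent[g$type %in% c("mRNA", "transcript")]
  cds <- g[g$type == "CDS", , drop = FALSE]
  cds_parent <- parent[g$type == "CDS"]

  models <- list()
  for (i in seq_len(nrow(mrnas))) {
    m <- mrnas[i, ]
    seg <- cds[cds_parent == m$ID, , drop = FALSE]
    if (nrow(seg) == 0L) {
      warning("mRNA '", m$ID, "' has no CDS features; skipped")
      next
    }
    gi <- which(genes$ID == mrna_parent[i])
    gene_id <- if (length(gi) == 1L) genes$ID[gi] else m$ID
    bounds <- if (length(gi) == 1L) {
      c(genes$start[gi], genes$end[gi])
    } else {
      c(m$start, m$end)
    }
    if (min(seg$start) < bounds[1L] || max(seg$end) > bounds[2L]) {
      stop("GFF3 consistency error: CDS of '", m$ID,
           "' outside parent gene bounds")
    }
    models[[m$ID]] <- gene_model(
      gene_id = gene_id, chromosome = as.character(m$seqid),
      strand = as.character(m$strand), start = bounds[1L], stop = bounds[2L],
      cds = data.frame(start = seg$start, stop = seg$end),
      protein_id = m$ID
    )
  }
  models
}

#' Serialize gene models to GFF3 text
#'
#' Emits gene, mRNA and CDS features with ID/Parent attributes; the output
#' round-trips through \code{\link{read_gff3}}.
#'
#' @param models List of \code{gene_model} objects.
#' @return Character vector of GFF3 lines (including the version pragma).
#' @export
format_gff3 <- function(models) {
  lines <- "##gff-version 3"
  for (m in models) {
    row <- function(type, start, stop, attrs) {
      sprintf("%s\tnsltpscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$chromosome, type, start, stop, m$strand, attrs)
    }
    gid <- m$gene_id
    tid <- m$protein_id
    lines <- c(lines,
               row("gene", m$start, m$stop, sprintf("ID=%s", gid)),
               row("mRNA", m$start, m$stop,
                   sprintf("ID=%s;Parent=%s", tid, gid)))
    cds <- m$cds[order(m$cds$start), , drop = FALSE]
    for (j in seq_len(nrow(cds))) {
      lines <- c(lines, row("CDS", cds$start[j], cds$stop[j],
                            sprintf("ID=%s.cds%d;Parent=%s", tid, j, tid)))
    }
  }
  lines
}
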