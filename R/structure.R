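#' Exon count of a gene model
#'
#' @param model A \code{\link{gene_model}}.
#' @return Number of CDS segments.
#' @export
exon_count <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  nrow(model$cds)
}

#' CDS offsets of a gene model's exon/intron junctions
#'
#' For each intron, the number of coding nucleotides 5' of the junction
#' (cumulative CDS segment lengths in transcript orientation). A model
#' with k CDS segments has k - 1 junctions.
#'
#' @param model A \code{\link{gene_model}}.
#' @return Integer vector of junction offsets (empty for single-exon
#'   genes).
#' @export
intron_cds_offsets <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  w <- model$cds$stop - model$cds$start + 1L
  if (length(w) < 2L) return(integer(0L))
  cumsum(w)[-length(w)]
}

#' Intron position relative to the last ECM cysteine
#'
#' For each intron the offset is the junction's CDS position minus the
#' CDS position of the final nucleotide of the eighth (last) ECM
#' cysteine's codon. Downstream (toward the C-terminus, in transcript
#' orientation) is positive; 0 means the junction sits immediately at that
#' codon boundary. The protein is assumed to map residue i onto CDS
#' nucleotides 3i-2..3i.
#'
#' @param model A \code{\link{gene_model}}.
#' @param ecm An \code{ecm_match} for the encoded protein, or the 1-based
#'   residue index of the last ECM cysteine.
#' @return Integer vector, one offset per intron.
#' @export
intron_offset_from_ecm <- function(model, ecm) {
  end_residue <- if (inherits(ecm, "ecm_match")) ecm$end else ecm
  if (is.null(end_residue) || is.na(end_residue)) {
    stop("gene '", model$gene_id,
         "': no ECM on the encoded protein; offset undefined")
  }
  cds_len <- sum(model$cds$stop - model$cds$start + 1L)
  anchor <- 3L * as.integer(end_residue)
  if (anchor > cds_len) {
    stop("gene '", model$gene_id, "': ECM cysteine codon beyond CDS")
  }
  intron_cds_offsets(model) - anchor
}

#' Intron phase from a junction's CDS offset
#'
#' Phase 0 introns fall between codons; phase 1 and 2 fall after the first
#' and second codon nucleotide respectively.
#'
#' @param cds_offset Non-negative junction offset(s) in coding
#'   nucleotides.
#' @return \code{cds_offset mod 3}.
#' @export
intron_phase <- function(cds_offset) {
  if (any(cds_offset < 0)) stop("cds_offset must be non-negative")
  as.integer(cds_offset %% 3)
}

#' Per-chromosome gene counts
#'
#' @param chromosomes Vector of chromosome labels, integers 1..n.
#' @param n_chromosomes Number of chromosomes in the karyotype
#'   (default 12, the tomato complement); zero-count chromosomes are
#'   included.
#' @return Named integer vector of length \code{n_chromosomes}.
#' @export
chromosome_census <- function(chromosomes, n_chromosomes = 12L) {
  chromosomes <- suppressWarnings(as.integer(chromosomes))
  if (anyNA(chromosomes) ||
      (length(chromosomes) &&
       (min(chromosomes) < 1L || max(chromosomes) > n_chromosomes))) {
    stop("chromosome labels must be integers in 1..", n_chromosomes)
  }
  counts <- tabulate(chromosomes, nbins = n_chromosomes)
  setNames(as.integer(counts), as.character(seq_len(n_chromosomes)))
}

#' Detect tandem clusters and pairs of genes
#'
#' Genes are grouped into maximal runs in which consecutive genes on the
#' same chromosome are separated by at most \code{max_gap} (start-to-start
#' genomic distance) and, when \code{same_type_required}, carry the same
#' type label. Runs of three or more genes are clusters, runs of exactly
#' two are pairs; clusters, pairs and singletons partition the input. The
#' result is invariant to the input row order.
#'
#' @param records Data frame with columns \code{gene_id},
#'   \code{chromosome}, \code{start} and (if \code{same_type_required})
#'   \code{type}.
#' @param max_gap Maximum start-to-start distance in bp (default 200 kb).
#' @param same_type_required Restrict runs to a single type label.
#' @return Object of class \code{cluster_set}: lists \code{clusters},
#'   \code{pairs}, \code{singletons} (character vectors of gene IDs) plus
#'   the parameters used.
#' @export
detect_clusters <- function(records, max_gap = 200000L,
                            same_type_required = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "chromosome", "start") %in% names(records)))
  if (max_gap <= 0) stop("max_gap must be positive")
  if (same_type_required && !"type" %in% names(records)) {
    stop("same_type_required needs a 'type' column")
  }
  ord <- order(records$chromosome, records$start)
  r <- records[ord, , drop = FALSE]
  n <- nrow(r)
  groups <- list()
  if (n > 0L) {
    run <- 1L
    for (i in seq_len(n)[-1L]) {
      linked <- r$chromosome[i] == r$chromosome[i - 1L] &&
        (r$start[i] - r$start[i - 1L]) <= max_gap &&
        (!same_type_required || r$type[i] == r$type[i - 1L])
      if (linked) {
        run <- c(run, i)
      } else {
        groups[[length(groups) + 1L]] <- r$gene_id[run]
        run <- i
      }
    }
    groups[[length(groups) + 1L]] <- r$gene_id[run]
  }
  sizes <- lengths(groups)
  structure(
    list(clusters = groups[sizes >= 3L],
         pairs = groups[sizes == 2L],
         singletons = unlist(groups[sizes == 1L], use.names = FALSE),
         max_gap = max_gap, same_type_required = same_type_required),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d pair(s), %d singleton(s) (max_gap = %d bp)\n",
              length(x$clusters), length(x$pairs), length(x$singletons),
              x$max_gap))
  invisible(x)
}

#' Fraction of genes organized in groups of two or more
#'
#' @param cluster_set A \code{\link{detect_clusters}} result.
#' @return Fraction in [0, 1].
#' @export
grouped_fraction <- function(cluster_set) {
  grouped <- sum(lengths(cluster_set$clusters)) +
    sum(lengths(cluster_set$pairs))
  total <- grouped + length(cluster_set$singletons)
  if (total == 0L) return(0)
  grouped / total
}
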