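# Seeded synthetic-data generators. One integer seed is threaded through
# documented substreams (one per generated entity), so adding entities
# never perturbs the ones already generated and regeneration under the
# same seed is byte-identical.

NONCYS <- setdiff(AA_LETTERS, "C")

.substream <- function(seed, index) {
  set.seed((as.integer(seed) %% 100000L) * 20011L + as.integer(index))
}

.random_residues <- function(n) {
  if (n <= 0L) return("")
  paste(sample(NONCYS, n, replace = TRUE), collapse = "")
}

# Assemble signal + pad + planted ECM + tail; everything outside the
# motif cysteines is cysteine-free, so the planted motif is the only
# eight-cysteine arrangement in the sequence.
.plant_protein <- function(spacings, signal_length, nterm_pad, tail) {
  motif <- paste0("C", .random_residues(spacings[1L]),
                  "C", .random_residues(spacings[2L]),
                  "CC", .random_residues(spacings[3L]),
                  "C", .random_residues(1L),
                  "C", .random_residues(spacings[4L]),
                  "C", .random_residues(spacings[5L]), "C")
  seq <- paste0(.random_residues(signal_length), .random_residues(nterm_pad),
                motif, .random_residues(tail))
  list(sequence = seq,
       ecm_start = signal_length + nterm_pad + 1L,
       ecm_end = signal_length + nterm_pad + ecm_length(spacings))
}

.sample_spacings <- function(type, rules = boutrot_rules()) {
  rule <- rules[[type]]
  if (is.null(rule)) stop("unknown type: ", type)
  repeat {
    sp <- vapply(rule, function(set) {
      if (length(set) == 1L) set else sample(set, 1L)
    }, integer(1L))
    # plant only unambiguous tuples: the published type I and X gap sets
    # share one corner tuple, which is redrawn so planted-type recovery
    # stays exact
    if (classify_spacings(sp) == type) return(sp)
  }
}

#' Generate a synthetic proteome with planted eight-cysteine motifs
#'
#' Each planted sequence carries exactly one ECM whose gaps are drawn
#' uniformly from the named type's published gap sets, preceded by a
#' cysteine-free N-terminal signal region of 20--29 residues and followed
#' by a cysteine-free tail. Decoy sequences contain fewer than eight
#' cysteines and can never match the motif skeleton.
#'
#' @param n_per_type Named integer vector of sequences per type
#'   (names from \code{\link{boutrot_rules}}).
#' @param decoy_fraction Fraction of the emitted proteome made of decoys
#'   (0 <= f < 1).
#' @param seed Integer seed.
#' @return List with \code{proteins} (data frame \code{id},
#'   \code{sequence}) and \code{truth} (planted type, gaps a--e, ECM
#'   start/end, signal length per planted sequence).
#' @export
gen_proteome <- function(n_per_type = setNames(rep(10L, 6L),
                                               names(boutrot_rules())),
                         decoy_fraction = 0, seed = 1L) {
  stopifnot(!is.null(names(n_per_type)), all(n_per_type >= 0L),
            decoy_fraction >= 0, decoy_fraction < 1)
  rules <- boutrot_rules()
  proteins <- list()
  truth <- list()
  idx <- 0L
  for (type in names(n_per_type)) {
    for (j in seq_len(n_per_type[[type]])) {
      idx <- idx + 1L
      .substream(seed, idx)
      spac <- .sample_spacings(type, rules)
      planted <- .plant_protein(spac, sample(20:29, 1L), sample(0:5, 1L),
                                sample(5:15, 1L))
      id <- sprintf("SYNT_%s_%03d", type, j)
      proteins[[idx]] <- data.frame(id = id, sequence = planted$sequence,
                                    stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(
        id = id, type = type, a = spac[1L], b = spac[2L], c = spac[3L],
        d = spac[4L], e = spac[5L], ecm_start = planted$ecm_start,
        ecm_end = planted$ecm_end, stringsAsFactors = FALSE)
    }
  }
  n_planted <- idx
  n_decoys <- if (decoy_fraction > 0) {
    round(decoy_fraction / (1 - decoy_fraction) * max(n_planted, 1L))
  } else 0L
  for (j in seq_len(n_decoys)) {
    .substream(seed, 100000L + j)
    n_c <- sample(0:7, 1L)
    body <- strsplit(.random_residues(sample(80:140, 1L)), "")[[1L]]
    if (n_c > 0L) {
      body[sample(seq_along(body), n_c)] <- "C"
    }
    proteins[[n_planted + j]] <- data.frame(
      id = sprintf("DECOY_%03d", j),
      sequence = paste(body, collapse = ""), stringsAsFactors = FALSE)
  }
  list(proteins = do.call(rbind, proteins) %||%
         data.frame(id = character(), sequence = character()),
       truth = do.call(rbind, truth) %||%
         data.frame(id = character(), type = character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate synthetic gene models with planted intron geometry
#'
#' Builds, per requested gene, a protein with a planted ECM and a gene
#' model whose exon/intron junctions realize the requested offsets from
#' the last ECM cysteine (downstream positive, in transcript orientation)
#' on either strand. Intron phases follow from the junction arithmetic.
#'
#' @param genes_spec Data frame with columns \code{chromosome},
#'   \code{strand}, \code{start}, \code{type} and \code{intron_offsets}
#'   (comma-separated offsets from the last ECM cysteine; empty string or
#'   NA for single-exon genes). An optional \code{gene_id} column names
#'   the genes.
#' @param seed Integer seed.
#' @return List with \code{models} (list of \code{\link{gene_model}}),
#'   \code{gff3} (character lines), \code{proteins} (data frame) and
#'   \code{truth} (planted offsets, phases, ECM end, spacing gaps).
#' @export
gen_gff3 <- function(genes_spec, seed = 1L) {
  stopifnot(is.data.frame(genes_spec),
            all(c("chromosome", "strand", "start", "type",
                  "intron_offsets") %in% names(genes_spec)))
  if (!"gene_id" %in% names(genes_spec)) {
    genes_spec$gene_id <- sprintf("SYNGENE%03d", seq_len(nrow(genes_spec)))
  }
  rules <- boutrot_rules()
  models <- list()
  proteins <- list()
  truth <- list()
  for (i in seq_len(nrow(genes_spec))) {
    g <- genes_spec[i, ]
    .substream(seed, 200000L + i)
    offs <- g$intron_offsets
    offs <- if (is.na(offs) || offs == "") integer(0L) else
      as.integer(strsplit(offs, ",")[[1L]])
    spac <- .sample_spacings(g$type, rules)
    signal_length <- sample(20:29, 1L)
    tail_needed <- if (length(offs)) ceiling(max(offs) / 3) + 3L else 0L
    if (tail_needed > 60L) {
      stop("infeasible gene spec '", g$gene_id,
           "': intron offset beyond a plausible CDS tail")
    }
    tail <- max(8L, tail_needed)
    planted <- .plant_protein(spac, signal_length, sample(0:4, 1L), tail)
    prot_len <- nchar(planted$sequence)
    cds_total <- 3L * prot_len + 3L  # includes the stop codon
    cds_offsets <- sort(3L * planted$ecm_end + offs)
    if (length(cds_offsets) &&
        (min(cds_offsets) < 1L || max(cds_offsets) >= cds_total)) {
      stop("infeasible gene spec '", g$gene_id,
           "': junction outside the CDS")
    }
    seg_len <- diff(c(0L, cds_offsets, cds_total))
    introns <- if (length(offs)) sample(100:500, length(offs),
                                        replace = TRUE) else integer(0L)
    span <- sum(seg_len) + sum(introns)
    gstart <- as.integer(g$start)
    gstop <- gstart + span - 1L
    # genomic CDS segments; transcript order maps to descending genomic
    # coordinates on the minus strand
    if (g$strand == "+") {
      s <- gstart + c(0L, cumsum(seg_len + c(introns, 0L))[-length(seg_len)])
      segs <- data.frame(start = s, stop = s + seg_len - 1L)
    } else {
      e <- gstop - c(0L, cumsum(seg_len + c(introns, 0L))[-length(seg_len)])
      segs <- data.frame(start = e - seg_len + 1L, stop = e)
    }
    models[[g$gene_id]] <- gene_model(
      gene_id = g$gene_id, chromosome = g$chromosome, strand = g$strand,
      start = gstart, stop = gstop, cds = segs,
      protein_id = paste0(g$gene_id, ".1"))
    proteins[[i]] <- data.frame(id = paste0(g$gene_id, ".1"),
                                sequence = planted$sequence,
                                stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      gene_id = g$gene_id, type = g$type, chromosome = g$chromosome,
      strand = g$strand, start = gstart, stop = gstop,
      n_exons = length(seg_len), ecm_end = planted$ecm_end,
      intron_offsets = paste(offs, collapse = ","),
      intron_phases = paste(intron_phase(cds_offsets), collapse = ","),
      stringsAsFactors = FALSE)
  }
  list(models = models, gff3 = format_gff3(models),
       proteins = do.call(rbind, proteins),
       truth = do.call(rbind, truth))
}

#' Generate an RPKM expression matrix with planted tissue patterns
#'
#' Background expression is low (mean 0.05 RPKM, well below the default
#' call threshold of 1) with multiplicative log-normal noise; planted
#' patterns sit at 10 RPKM, ten times the design threshold. The first
#' \code{n_specific} genes are each strongly expressed in exactly one
#' non-fruit tissue (cycled over the non-fruit tissues); the next
#' \code{n_fruit_all_stages} genes are strongly expressed in every fruit
#' ripening stage.
#'
#' @param n_genes Total number of genes.
#' @param tissues Tissue column labels.
#' @param fruit_stages Subset of \code{tissues} forming the ripening
#'   series.
#' @param n_specific Number of planted single-tissue genes.
#' @param n_fruit_all_stages Number of planted all-stage fruit genes.
#' @param noise_sd Log-scale standard deviation of the multiplicative
#'   noise (0 gives the planted means exactly).
#' @param seed Integer seed.
#' @return List with \code{matrix} (genes x tissues RPKM) and
#'   \code{truth} (pattern per gene).
#' @export
gen_expression <- function(n_genes = 64L,
                           tissues = c("root", "leaf", "bud", "flower",
                                       "fruit_MG", "fruit_B", "fruit_RR"),
                           fruit_stages = c("fruit_MG", "fruit_B",
                                            "fruit_RR"),
                           n_specific = 13L, n_fruit_all_stages = 5L,
                           noise_sd = 0.2, seed = 1L) {
  stopifnot(n_specific + n_fruit_all_stages <= n_genes,
            all(fruit_stages %in% tissues), noise_sd >= 0)
  non_fruit <- setdiff(tissues, fruit_stages)
  if (n_specific > 0L && length(non_fruit) == 0L) {
    stop("planting tissue-specific genes needs a non-fruit tissue")
  }
  background <- 0.05
  planted <- 10
  ids <- sprintf("GENE%03d", seq_len(n_genes))
  mat <- matrix(0, n_genes, length(tissues),
                dimnames = list(ids, tissues))
  pattern <- character(n_genes)
  for (i in seq_len(n_genes)) {
    .substream(seed, 300000L + i)
    mean_row <- rep(background, length(tissues))
    if (i <= n_specific) {
      tissue <- non_fruit[(i - 1L) %% length(non_fruit) + 1L]
      mean_row[match(tissue, tissues)] <- planted
      pattern[i] <- paste0("specific:", tissue)
    } else if (i <= n_specific + n_fruit_all_stages) {
      mean_row[match(fruit_stages, tissues)] <- planted
      pattern[i] <- "fruit_all_stages"
    } else {
      pattern[i] <- "background"
    }
    mat[i, ] <- mean_row * exp(rnorm(length(tissues), 0, noise_sd))
  }
  list(matrix = mat,
       truth = data.frame(gene_id = ids, pattern = pattern,
                          stringsAsFactors = FALSE))
}

#' Generate a ligand titration series from a one-site Hill model
#'
#' Concentrations are log-spaced over two decades up to \code{conc_max};
#' responses follow \code{A x^n / (K_D^n + x^n)} with multiplicative
#' Gaussian noise.
#'
#' @param K_D Dissociation constant (uM).
#' @param hill_n Hill coefficient.
#' @param amplitude Saturating relative-fluorescence amplitude.
#' @param n_points Number of titration points (>= 5).
#' @param conc_max Highest ligand concentration (uM).
#' @param noise_sd Standard deviation of the multiplicative noise (0 for
#'   points exactly on the curve).
#' @param seed Integer seed.
#' @return List with \code{curve} (data frame \code{concentration_uM},
#'   \code{rel_fluorescence}) and \code{truth}.
#' @export
gen_titration <- function(K_D = 85.5, hill_n = 1, amplitude = 1,
                          n_points = 12L, conc_max = 500, noise_sd = 0.02,
                          seed = 1L) {
  stopifnot(K_D > 0, n_points >= 5L, conc_max > 0, noise_sd >= 0)
  .substream(seed, 400001L)
  x <- 10^seq(log10(conc_max) - 2, log10(conc_max), length.out = n_points)
  y <- amplitude * x^hill_n / (K_D^hill_n + x^hill_n)
  y <- y * (1 + rnorm(n_points, 0, noise_sd))
  list(curve = data.frame(concentration_uM = x, rel_fluorescence = y),
       truth = list(K_D = K_D, hill_n = hill_n, amplitude = amplitude,
                    noise_sd = noise_sd))
}

#' Generate an annotated candidate set for curation
#'
#' Realizes a curation scenario: so many candidates lacking the signal
#' peptide, carrying chloroplast/mitochondrial transit peptides, GPI
#' anchor signals or belonging to related outlier families, plus clean
#' nsLTP candidates (which carry a planted ECM). The default scenario is
#' 107 candidates resolving to 64 retained (4 without signal peptide,
#' 3 chloroplast + 1 mitochondrial transit, 23 GPI-anchored, 12 family
#' outliers).
#'
#' @param scenario Named list of counts: \code{n_no_signal},
#'   \code{n_chloroplast}, \code{n_mitochondrial}, \code{n_gpi},
#'   \code{n_outlier}, \code{n_clean}.
#' @param seed Integer seed.
#' @return List with \code{candidates} (annotation data frame ready for
#'   \code{\link{curate}}) and \code{truth} (expected disposition per
#'   candidate).
#' @export
gen_candidate_set <- function(scenario = list(n_no_signal = 4L,
                                              n_chloroplast = 3L,
                                              n_mitochondrial = 1L,
                                              n_gpi = 23L,
                                              n_outlier = 12L,
                                              n_clean = 64L),
                              seed = 1L) {
  req <- c("n_no_signal", "n_chloroplast", "n_mitochondrial", "n_gpi",
           "n_outlier", "n_clean")
  if (!all(req %in% names(scenario)) ||
      any(unlist(scenario[req]) < 0L)) {
    stop("scenario must give non-negative counts for: ",
         paste(req, collapse = ", "))
  }
  outlier_families <- c("alpha-amylase/trypsin-inhibitor", "proline-rich",
                        "hybrid-proline-rich", "glycine-rich")
  dispositions <- c(rep("removed_no_signal", scenario$n_no_signal),
                    rep("removed_transit_chloroplast", scenario$n_chloroplast),
                    rep("removed_transit_mitochondrial", scenario$n_mitochondrial),
                    rep("gpi_set_aside", scenario$n_gpi),
                    rep("removed_family_outlier", scenario$n_outlier),
                    rep("retained", scenario$n_clean))
  n <- length(dispositions)
  .substream(seed, 500001L)
  ord <- sample(n)
  dispositions <- dispositions[ord]
  ids <- sprintf("CAND%03d", seq_len(n))
  rows <- vector("list", n)
  types <- names(boutrot_rules())
  for (i in seq_len(n)) {
    .substream(seed, 500001L + i)
    d <- dispositions[i]
    has_ecm <- d %in% c("retained", "gpi_set_aside")
    seqn <- if (has_ecm) {
      .plant_protein(.sample_spacings(sample(types, 1L)),
                     sample(20:29, 1L), sample(0:4, 1L),
                     sample(5:15, 1L))$sequence
    } else {
      .random_residues(sample(80:140, 1L))
    }
    rows[[i]] <- data.frame(
      id = ids[i], sequence = seqn,
      has_signal_peptide = d != "removed_no_signal",
      signal_length = if (d == "removed_no_signal") NA_integer_
                      else sample(20:29, 1L),
      transit_peptide = switch(d,
        removed_transit_chloroplast = "chloroplast",
        removed_transit_mitochondrial = "mitochondrial",
        "none"),
      has_gpi_anchor = d == "gpi_set_aside",
      family_outlier = if (d == "removed_family_outlier") {
        outlier_families[(i - 1L) %% length(outlier_families) + 1L]
      } else "none",
      stringsAsFactors = FALSE)
  }
  truth_disp <- sub("removed_transit_(chloroplast|mitochondrial)",
                    "removed_transit", dispositions)
  empty <- data.frame(id = character(), sequence = character(),
                      has_signal_peptide = logical(),
                      signal_length = integer(),
                      transit_peptide = character(),
                      has_gpi_anchor = logical(),
                      family_outlier = character(),
                      stringsAsFactors = FALSE)
  list(candidates = if (n) do.call(rbind, rows) else empty,
       truth = data.frame(id = ids, disposition = truth_disp,
                          stringsAsFactors = FALSE))
}
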