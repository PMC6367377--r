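toy_model <- function(strand = "+", seg_len = c(150, 150), intron = 200,
                      start = 1000) {
  n <- length(seg_len)
  if (strand == "+") {
    s <- start + c(0, cumsum(seg_len + c(rep(intron, n - 1), 0))[-n])
    cds <- data.frame(start = s, stop = s + seg_len - 1)
  } else {
    stop_pos <- start + sum(seg_len) + intron * (n - 1) - 1
    e <- stop_pos - c(0, cumsum(seg_len + c(rep(intron, n - 1), 0))[-n])
    cds <- data.frame(start = e - seg_len + 1, stop = e)
  }
  gene_model("toy", "1", strand, min(cds$start), max(cds$stop), cds)
}

test_that("exon counts come straight from the CDS segments", {
  expect_equal(exon_count(toy_model(seg_len = 300, intron = 0)), 1)
  expect_equal(exon_count(toy_model(seg_len = c(100, 100, 100))), 3)
  t1 <- load_table1_fixture()
  expect_equal(as.integer(table(t1$n_exons)), c(47L, 15L, 2L))
})

test_that("synthetic gene models recover their planted exon counts", {
  spec <- data.frame(chromosome = "1", strand = c("+", "-", "+"),
                     start = c(1000, 10000, 50000),
                     type = c("I", "X", "XI"),
                     intron_offsets = c("5", "4,100", ""))
  g <- gen_gff3(spec, seed = 17)
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(g$gff3, path)
  models <- read_gff3(path)
  got <- vapply(g$truth$gene_id, function(id) {
    exon_count(models[[paste0(id, ".1")]])
  }, integer(1))
  expect_equal(unname(got), g$truth$n_exons)
})

test_that("intron offsets from the last ECM cysteine follow the convention", {
  # junction planted o nt downstream of the last nucleotide of the eighth
  # cysteine codon, on both strands
  for (strand in c("+", "-")) {
    for (o in c(5L, 4L, 0L)) {
      spec <- data.frame(chromosome = "1", strand = strand, start = 5000,
                         type = "I", intron_offsets = as.character(o))
      g <- gen_gff3(spec, seed = 23 + o)
      model <- g$models[[1]]
      expect_equal(intron_offset_from_ecm(model, g$truth$ecm_end), o,
                   info = sprintf("strand %s offset %d", strand, o))
    }
  }
})

test_that("minus-strand genes mirror plus-strand intron arithmetic", {
  spec <- data.frame(chromosome = "1", strand = c("+", "-"),
                     start = c(1000, 1000), type = "I",
                     intron_offsets = "5")
  g <- gen_gff3(spec, seed = 31)
  offsets <- vapply(seq_len(2), function(i) {
    intron_offset_from_ecm(g$models[[i]], g$truth$ecm_end[i])
  }, numeric(1))
  expect_equal(offsets[1], offsets[2])
  phases <- g$truth$intron_phases
  expect_equal(phases[1], phases[2])
})

test_that("an ECM-less protein has no defined intron offset", {
  model <- toy_model()
  expect_error(intron_offset_from_ecm(model, NA), "undefined|no ECM")
})

test_that("intron phase is the junction offset modulo three", {
  expect_equal(intron_phase(300), 0L)
  expect_equal(intron_phase(301), 1L)
  expect_equal(intron_phase(302), 2L)
  expect_error(intron_phase(-1), "non-negative")
  # planted phases match the generator truth
  spec <- data.frame(chromosome = "1", strand = "+",
                     start = c(1000, 9000, 20000), type = "XI",
                     intron_offsets = c("5", "7", "3,60"))
  g <- gen_gff3(spec, seed = 41)
  for (i in seq_len(nrow(g$truth))) {
    got <- intron_phase(intron_cds_offsets(g$models[[i]]))
    expect_equal(paste(got, collapse = ","), g$truth$intron_phases[i])
  }
})

test_that("chromosome census covers the full karyotype including zeros", {
  t1 <- load_table1_fixture()
  counts <- chromosome_census(t1$chromosome)
  expect_length(counts, 12)
  # the reference table places genes on chromosomes 1,2,3,6,8,9,10,12
  expect_equal(names(counts)[counts > 0],
               c("1", "2", "3", "6", "8", "9", "10", "12"))
  expect_equal(max(counts), 15)
  expect_equal(names(counts)[counts == 15], c("3", "8"))
  expect_equal(counts[["12"]], 1L)
  expect_true(all(chromosome_census(integer(0)) == 0))
  expect_error(chromosome_census(c(1, 13)), "1..12")
  set.seed(3)
  random <- sample(1:12, 100, replace = TRUE)
  expect_equal(unname(chromosome_census(random)),
               vapply(1:12, function(k) sum(random == k), integer(1)))
})

test_that("cluster detection groups genes by gap rule", {
  recs <- data.frame(gene_id = c("a", "b", "c"), chromosome = "1",
                     start = c(0, 50000, 90000))
  cl <- detect_clusters(recs, max_gap = 100000)
  expect_length(cl$clusters, 1)
  expect_equal(cl$clusters[[1]], c("a", "b", "c"))
  lone <- data.frame(gene_id = c("a", "b"), chromosome = c("1", "2"),
                     start = c(0, 0))
  cl2 <- detect_clusters(lone, max_gap = 100000)
  expect_length(cl2$clusters, 0)
  expect_length(cl2$pairs, 0)
  expect_equal(sort(cl2$singletons), c("a", "b"))
})

test_that("cluster detection recovers planted layouts and is order-invariant", {
  # six-gene cluster at 50 kb spacing plus a pair and a singleton
  recs <- data.frame(
    gene_id = sprintf("g%02d", 1:9),
    chromosome = c(rep("3", 6), "8", "8", "10"),
    start = c(seq(1e6, by = 50000, length.out = 6), 2e6, 2.003e6, 5e6))
  cl <- detect_clusters(recs, max_gap = 200000)
  expect_equal(cl$clusters, list(sprintf("g%02d", 1:6)))
  expect_equal(cl$pairs, list(c("g07", "g08")))
  expect_equal(cl$singletons, "g09")
  set.seed(77)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(detect_clusters(shuffled, max_gap = 200000), cl)
})

test_that("widening the gap never reduces the grouped fraction", {
  set.seed(19)
  recs <- data.frame(gene_id = sprintf("g%03d", 1:40),
                     chromosome = as.character(sample(1:4, 40, TRUE)),
                     start = sample(1:5e6, 40))
  gaps <- c(5e4, 1e5, 2e5, 5e5, 1e6)
  fracs <- vapply(gaps, function(g) {
    grouped_fraction(detect_clusters(recs, max_gap = g))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("most census genes sit in chromosome groups at the default gap", {
  t1 <- load_table1_fixture()
  cl <- detect_clusters(data.frame(gene_id = t1$gene_id,
                                   chromosome = t1$chromosome,
                                   start = t1$start,
                                   type = t1$type_boutrot))
  expect_gte(grouped_fraction(cl), 0.6)
})

test_that("intron presence by sub-family matches the census", {
  t1 <- load_table1_fixture()
  expect_equal(sum(t1$type_boutrot == "I" & t1$n_exons >= 2), 13)
  single_only <- t1$type_boutrot %in% c("II", "IV", "XI")
  expect_true(all(t1$n_exons[single_only] == 1))
})
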