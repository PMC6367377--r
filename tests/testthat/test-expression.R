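test_that("Spearman distance spans [0, 2] with rank semantics", {
  x <- c(1, 5, 3, 8, 2)
  expect_equal(spearman_distance(x, x), 0)
  expect_equal(spearman_distance(x, -x), 2)
  expect_error(spearman_distance(x, rep(1, 5)), "constant")
  expect_error(spearman_distance(1:2, 1:2), "length")
})

test_that("Spearman distance matches the rank-then-Pearson oracle", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:30, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    expect_equal(spearman_distance(a, b), spearman_oracle(a, b))
    # symmetry and invariance under strictly monotone transforms
    expect_equal(spearman_distance(a, b), spearman_distance(b, a))
    expect_equal(spearman_distance(exp(a), b), spearman_distance(a, b))
    expect_equal(spearman_distance(a, 3 * b + 2), spearman_distance(a, b))
  }
})

test_that("identical profiles merge first and at height zero", {
  m <- rbind(g1 = c(1, 4, 2, 9, 3), g2 = c(1, 4, 2, 9, 3),
             g3 = c(9, 2, 8, 1, 7))
  hc <- hierarchical_cluster(m)
  expect_equal(hc$height[1], 0)
  first <- rownames(m)[-hc$merge[1, ]]
  expect_setequal(first, c("g1", "g2"))
})

test_that("a planted two-block matrix splits into its blocks", {
  set.seed(61)
  base_a <- c(10, 9, 8, 1, 1, 1)
  base_b <- c(1, 1, 1, 8, 9, 10)
  m <- rbind(
    t(replicate(4, base_a + runif(6, 0, 0.3))),
    t(replicate(4, base_b + runif(6, 0, 0.3))))
  rownames(m) <- sprintf("g%d", 1:8)
  hc <- hierarchical_cluster(m)
  blocks <- stats::cutree(hc, k = 2)
  expect_length(unique(blocks[1:4]), 1)
  expect_length(unique(blocks[5:8]), 1)
  expect_true(blocks[1] != blocks[5])
})

test_that("zero-variance profiles are excluded with a warning", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1), g3 = rep(5, 4))
  expect_warning(hc <- hierarchical_cluster(m), "zero-variance")
  expect_setequal(hc$labels, c("g1", "g2"))
})

test_that("tissue-specific filter returns exactly the planted genes", {
  e <- gen_expression(n_genes = 40, n_specific = 13,
                      n_fruit_all_stages = 5, seed = 10)
  got <- tissue_specific_genes(e$matrix)
  want <- e$truth$gene_id[startsWith(e$truth$pattern, "specific:")]
  expect_setequal(got, want)
  expect_length(got, 13)
  zeros <- matrix(0, 3, 4, dimnames = list(c("a", "b", "c"), NULL))
  expect_length(tissue_specific_genes(zeros), 0)
})

test_that("fruit all-stage filter returns exactly the planted genes", {
  e <- gen_expression(n_genes = 40, n_specific = 13,
                      n_fruit_all_stages = 5, seed = 10)
  stages <- c("fruit_MG", "fruit_B", "fruit_RR")
  got <- fruit_expressed_genes(e$matrix, stages)
  expect_setequal(got, e$truth$gene_id[e$truth$pattern == "fruit_all_stages"])
  expect_length(got, 5)
  expect_error(fruit_expressed_genes(e$matrix, c("fruit_MG", "nope")),
               "absent")
  # a gene on in only two of three stages is excluded
  m <- matrix(c(5, 5, 0.2), 1, 3,
              dimnames = list("g", stages))
  expect_length(fruit_expressed_genes(m, stages), 0)
  # threshold 0 means strictly positive in all stages
  m2 <- matrix(c(0.01, 0.02, 0.03, 0, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("pos", "zero"), stages))
  expect_equal(fruit_expressed_genes(m2, stages, expressed_threshold = 0),
               "pos")
})

test_that("expression filters are monotone in the threshold", {
  e <- gen_expression(n_genes = 30, n_specific = 8, n_fruit_all_stages = 4,
                      noise_sd = 0.5, seed = 3)
  stages <- c("fruit_MG", "fruit_B", "fruit_RR")
  thresholds <- c(0.1, 0.5, 1, 2, 5)
  prev_ts <- NULL
  prev_fr <- NULL
  for (th in thresholds) {
    ts <- tissue_specific_genes(e$matrix, th)
    fr <- fruit_expressed_genes(e$matrix, stages, th)
    if (!is.null(prev_fr)) {
      # raising the threshold never adds fruit-expressed genes
      expect_true(all(fr %in% prev_fr))
    }
    prev_fr <- fr
    prev_ts <- ts
  }
})

test_that("relative quantification follows the comparative-CT identity", {
  expect_equal(relative_quantity(25, 20, 25, 20), 1)
  expect_equal(relative_quantity(25, 20, 28, 20), 8)
  set.seed(40)
  for (rep in 1:15) {
    ct <- runif(4, 15, 35)
    rq <- relative_quantity(ct[1], ct[2], ct[3], ct[4])
    ddct <- (ct[1] - ct[2]) - (ct[3] - ct[4])
    expect_equal(log2(rq), -ddct)
    expect_gt(rq, 0)
  }
  expect_error(relative_quantity(25, NA, 28, 20), "finite")
})
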