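test_that("spacing tuples classify to their published types", {
  expect_equal(classify_spacings(c(9, 13, 19, 22, 13)), "I")
  expect_equal(classify_spacings(c(9, 19, 13, 24, 9)), "XI")
  expect_equal(classify_spacings(c(7, 13, 8, 23, 6)), "II")
  expect_equal(classify_spacings(c(9, 15, 9, 24, 7)), "IV")
  expect_equal(classify_spacings(c(1, 1, 1, 1, 1)), "n.d.")
})

test_that("the type I / type X rule overlap is resolved by precedence", {
  # this corner tuple satisfies both published rule rows
  expect_equal(classify_spacings(c(9, 14, 19, 21, 13)), "I")
  expect_error(classify_spacings(c(9, 14, 19, 21, 13),
                                 on_ambiguous = "error"),
               "matches types I, X")
})

test_that("classification reproduces the reference type column 64/64", {
  t1 <- load_table1_fixture()
  types <- apply(fixture_spacings(t1), 1, classify_spacings)
  expect_equal(unname(types), t1$type_boutrot)
  counts <- census_by_type(types)
  expect_equal(counts[c("I", "II", "III", "IV", "X", "XI")],
               c(I = 24L, II = 6L, III = 2L, IV = 3L, X = 6L, XI = 23L))
  expect_equal(counts[["n.d."]], 0L)
})

test_that("classification is a pure function of the tuple", {
  t1 <- load_table1_fixture()
  sp <- fixture_spacings(t1)
  set.seed(8)
  perm <- sample(nrow(sp))
  shuffled <- apply(sp[perm, ], 1, classify_spacings)
  expect_equal(unname(shuffled), t1$type_boutrot[perm])
})

test_that("planted types are recovered perfectly from synthetic proteomes", {
  p <- gen_proteome(setNames(rep(12L, 6),
                             c("I", "II", "III", "IV", "X", "XI")),
                    seed = 21)
  expect_gte(nrow(p$truth), 60)
  got <- vapply(seq_len(nrow(p$proteins)), function(i) {
    hit <- find_ecm(p$proteins$sequence[i])
    classify_spacings(hit$spacings)
  }, character(1))
  expect_equal(got, p$truth$type)
})

test_that("nearest-pattern mode caps the allowed deviation", {
  # one off a type XI tuple
  expect_equal(classify_spacings(c(9, 19, 13, 26, 9)), "n.d.")
  expect_equal(classify_spacings(c(9, 19, 13, 26, 9), mode = "nearest"),
               "XI")
  expect_equal(classify_spacings(c(1, 1, 1, 1, 1), mode = "nearest",
                                 max_deviation = 3), "n.d.")
})

test_that("curation applies the filters in order with exhaustive dispositions", {
  cs <- gen_candidate_set(seed = 5)
  ledger <- curate(cs$candidates)
  expect_equal(ledger$n_input, 107)
  expect_equal(ledger$n_removed_no_signal, 4)
  expect_equal(ledger$n_removed_transit, 4)
  expect_equal(ledger$n_removed_transit_chloroplast, 3)
  expect_equal(ledger$n_removed_transit_mitochondrial, 1)
  expect_equal(ledger$n_gpi_set_aside, 23)
  expect_equal(ledger$n_removed_family_outlier, 12)
  expect_equal(ledger$n_retained, 64)
  # ledger arithmetic: input = retained + removals + set-asides
  expect_equal(ledger$n_input,
               ledger$n_retained + ledger$n_removed_no_signal +
                 ledger$n_removed_transit + ledger$n_gpi_set_aside +
                 ledger$n_removed_family_outlier)
  # dispositions mirror the generator truth
  merged <- merge(ledger$dispositions, cs$truth, by = "id")
  expect_equal(merged$disposition.x, merged$disposition.y)
})

test_that("curation handles the empty and malformed inputs", {
  empty <- gen_candidate_set(scenario = list(n_no_signal = 0,
                                             n_chloroplast = 0,
                                             n_mitochondrial = 0,
                                             n_gpi = 0, n_outlier = 0,
                                             n_clean = 0), seed = 1)
  ledger <- curate(empty$candidates)
  expect_equal(ledger$n_input, 0)
  expect_equal(ledger$n_retained, 0)
  bad <- data.frame(id = "x", has_signal_peptide = TRUE)
  expect_error(curate(bad), "annotation column")
  na_row <- gen_candidate_set(seed = 2)$candidates[1:3, ]
  na_row$transit_peptide[2] <- NA
  expect_error(curate(na_row), na_row$id[2])
})

test_that("type census equals a brute-force tally on random labels", {
  set.seed(30)
  labels <- sample(c("I", "II", "III", "IV", "X", "XI", "n.d."), 200,
                   replace = TRUE, prob = c(4, 1, 1, 1, 1, 4, 2))
  counts <- census_by_type(labels)
  for (type in names(counts)) {
    expect_equal(counts[[type]], sum(labels == type))
  }
  expect_equal(sum(counts), length(labels))
  expect_true(all(census_by_type(character(0)) == 0))
  expect_error(census_by_type("V"), "unknown type")
})
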