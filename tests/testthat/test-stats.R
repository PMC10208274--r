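test_that("fisher_exact handles degenerate and extreme tables", {
  expect_equal(fisher_exact(c(0, 10, 0, 10))$p_two_tailed, 1)
  r <- fisher_exact(c(5, 0, 0, 5))
  expect_equal(r$p_two_tailed, 2 / 252, tolerance = 1e-12)
  expect_equal(r$odds_ratio, Inf)
  expect_equal(fisher_exact(c(2, 3, 4, 5))$odds_ratio, 10 / 12)
  expect_error(fisher_exact(c(-1, 2, 3, 4)), "non-negative")
})

test_that("fisher_exact matches enumeration on random tables and is swap invariant", {
  set.seed(42)
  for (i in 1:200) {
    tab <- sample(0:12, 4, replace = TRUE)
    if (sum(tab) == 0) next
    p <- fisher_exact(tab)$p_two_tailed
    expect_equal(p, fisher_enumerate(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-10)
    # simultaneous row and column swap leaves p unchanged
    swapped <- c(tab[4], tab[3], tab[2], tab[1])
    expect_equal(fisher_exact(swapped)$p_two_tailed, p, tolerance = 1e-12)
  }
})

test_that("carrier frequency reproduces the recording-threshold conversions", {
  expect_equal(carrier_frequency(0.10), 0.19)
  expect_equal(carrier_frequency(0.02), 0.0396)
  expect_equal(carrier_frequency(0), 0)
  expect_equal(carrier_frequency(1), 1)
  q <- seq(0.001, 0.999, by = 0.001)
  cf <- carrier_frequency(q)
  expect_true(all(diff(cf) > 0))   # strictly increasing
  expect_true(all(cf >= q))        # carriers at least as common as alleles
  expect_error(carrier_frequency(1.2), "\\[0, 1\\]")
})

test_that("recurrent variant tests apply the 3-participant threshold and allele counting", {
  v <- make_variants(
    make_variant(participant_id = "S001", variant_id = "v1", af_nfe = 0.05),
    make_variant(participant_id = "S002", variant_id = "v1", af_nfe = 0.05),
    make_variant(participant_id = "S003", variant_id = "v1", af_nfe = 0.05,
                 zygosity = "hom"),
    make_variant(participant_id = "S004", variant_id = "v2", af_nfe = 0.05),
    make_variant(participant_id = "S005", variant_id = "v2", af_nfe = 0.05)
  )
  pop <- data.frame(variant_id = "v1", allele_count = 500,
                    allele_number = 10000, stringsAsFactors = FALSE)
  res <- recurrent_variant_tests(v, pop, n_participants = 80)
  expect_equal(nrow(res), 1)        # v2 in only 2 participants -> skipped
  expect_equal(res$variant_id, "v1")
  expect_equal(res$cohort_alleles, 4)  # 2 het + 1 hom
  # cohort frequency equal to population frequency -> p near 1
  pop_null <- data.frame(variant_id = "v1", allele_count = 2500,
                         allele_number = 100000, stringsAsFactors = FALSE)
  res_null <- recurrent_variant_tests(v, pop_null, n_participants = 80)
  expect_gt(res_null$p_two_tailed, 0.5)
  expect_error(recurrent_variant_tests(v[1:3, ],
                                       pop[0, , drop = FALSE], 80),
               "population")
})

test_that("enrichment power: 10-fold enriched variant detected as often as the simulation oracle predicts", {
  # Oracle: simulate the sampling distribution of carrier draws at the
  # enriched frequency and measure how often the Fisher test rejects.
  q_pop <- 0.005; fold <- 10; n <- 80
  pop <- data.frame(variant_id = "e1", allele_count = round(q_pop * 2e5),
                    allele_number = 2e5, stringsAsFactors = FALSE)
  reps <- 400
  set.seed(7)
  rejected <- logical(reps)
  for (r in seq_len(reps)) {
    k <- rbinom(1, 2 * n, q_pop * fold)
    if (k < 3) { rejected[r] <- FALSE; next }   # below recurrence threshold
    carriers <- make_variants(
      do.call(rbind, lapply(seq_len(min(k, n)), function(i) {
        make_variant(participant_id = sprintf("S%03d", i),
                     variant_id = "e1", af_nfe = q_pop)
      })))
    res <- recurrent_variant_tests(carriers, pop, n_participants = n)
    rejected[r] <- res$p_two_tailed < 0.05
  }
  expect_gt(mean(rejected), 0.8)  # 10-fold enrichment at this n is well powered
})

test_that("categorize_recorded partitions recorded variants exhaustively", {
  v <- make_variants(
    make_variant(consequence = "intronic", af_nfe = 0.05),
    make_variant(consequence = "missense", af_nfe = 0.05),
    make_variant(consequence = "missense", af_nfe = 0.001, phylop = 0.3),
    make_variant(consequence = "missense", af_nfe = 0.001, phylop = 3),
    make_variant(consequence = "utr", af_nfe = 0.001)
  )
  counts <- categorize_recorded(v)
  expect_equal(unname(counts), c(2L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(counts), nrow(v))
  expect_equal(attr(counts, "class_of")[2], "coding_2_10pct")
  # random recorded pools always sum to the input size
  r <- random_variants(300, seed = 5)
  r <- r[is_recorded(r), ]
  expect_equal(sum(categorize_recorded(r)), nrow(r))
})

test_that("mixed-population frequency is the weighted average", {
  expect_equal(mixed_population_frequency(c(nfe = 0.2), c(nfe = 1)), 0.2)
  expect_equal(
    mixed_population_frequency(c(nfe = 0.14, aa = 0.03),
                               c(nfe = 0.91, aa = 0.09)),
    0.1301)
  expect_equal(mixed_population_frequency(c(a = 0.07, b = 0.07),
                                          c(a = 0.5, b = 0.5)), 0.07)
  expect_error(mixed_population_frequency(c(nfe = 0.1), c(nfe = 0.9)),
               "sum to 1")
  cnt <- mixed_population_counts(c(nfe = 0.14, aa = 0.03),
                                 c(nfe = 7756, aa = 9102))
  expect_equal(unname(cnt["allele_number"]), 2L * (7756L + 9102L))
  expect_equal(unname(cnt["allele_count"]),
               as.integer(round(2 * (7756 * 0.14 + 9102 * 0.03))))
})

test_that("panel burden comparison reproduces the Key-carrier contrast", {
  # 27 of 75 participants with a hit in the 35-gene panel vs 2 of 75 in the
  # 20-gene control panel: significant far below 1e-4 even uncorrected
  plain <- panel_burden_comparison(27, 2, 35, 20, 75, correction = "none")
  expect_lt(plain$p_two_tailed, 1e-4)
  corrected <- panel_burden_comparison(27, 2, 35, 20, 75,
                                       correction = "gene_count_rescale")
  expect_equal(corrected$correction, "gene_count_rescale")
  expect_equal(corrected$table[1, 1], round(27 * 20 / 35))  # 15 rescaled hits
  expect_lt(corrected$p_two_tailed, 0.01)
  expect_equal(corrected$uncorrected$p_two_tailed, plain$p_two_tailed)
  # equal panels: rescaling is a no-op
  same <- panel_burden_comparison(10, 10, 20, 20, 75,
                                  correction = "gene_count_rescale")
  expect_gt(same$p_two_tailed, 0.99)
  expect_equal(same$table,
               panel_burden_comparison(10, 10, 20, 20, 75)$table)
})
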