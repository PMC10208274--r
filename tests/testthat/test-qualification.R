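t_def <- qualification_thresholds()

test_that("coding predicate follows consequence and splice evidence", {
  v <- make_variants(
    make_variant(consequence = "missense"),
    make_variant(consequence = "intronic", splice_ada = 0.7),
    make_variant(consequence = "utr"),
    make_variant(consequence = "synonymous"),
    make_variant(consequence = "intronic", splice_rf = 0.6),  # strict >
    make_variant(consequence = "frameshift")
  )
  expect_equal(is_coding(v, t_def), c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("recording threshold is strict and absent frequency counts as rare", {
  v <- make_variants(
    make_variant(af_nfe = 0.05),
    make_variant(af_nfe = 0.10),
    make_variant()                       # absent -> 0
  )
  expect_equal(is_recorded(v, t_def), c(TRUE, FALSE, TRUE))
})

test_that("qualifying needs coding, rarity and conservation", {
  v <- make_variants(
    make_variant(af_nfe = 0.001, phylop = 2.3),
    make_variant(af_nfe = 0.03, phylop = 2.3),
    make_variant(af_nfe = 0.001, phylop = 0.2, mammal_match_pct = 95),
    make_variant(af_nfe = 0.001, phylop = 0.2),
    make_variant(af_nfe = 0.02, phylop = 2.3),   # boundary, strict <
    make_variant(af_nfe = 0.001, phylop = 1.5),  # boundary, inclusive >=
    make_variant(af_nfe = 0.001, phylop = 0.2, mammal_match_pct = 90)
  )
  expect_equal(is_qualifying(v, t_def),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("repeat/structural records qualify only via the explicit flag", {
  v <- make_variants(
    make_variant(consequence = "repeat_expansion", variant_id = "CAG_7"),
    make_variant(consequence = "repeat_expansion", variant_id = "CAG_7")
  )
  v$coding_equivalent <- c(TRUE, FALSE)
  expect_equal(is_qualifying(v, t_def), c(TRUE, FALSE))
  expect_false(is_qualifying(v[2, , drop = FALSE], t_def))
})

test_that("ClinVar majority rule and loss-of-function shortcut", {
  expect_true(aggregate_clinvar("P,VUS"))          # exactly half
  expect_false(aggregate_clinvar("VUS,VUS,LP"))    # 1/3 < 1/2
  expect_true(aggregate_clinvar(NA, lof_predicted = TRUE))
  expect_false(aggregate_clinvar(NA))
  expect_equal(aggregate_clinvar(c("P", "B,LB", "LP,P,VUS")),
               c(TRUE, FALSE, TRUE))
})

test_that("clinical match uses panel phenotypes and never CVS", {
  panel <- load_fixture("paroxysmal_panel")
  ph <- make_phenotypes(c("S001", "S002", "S003", "S004"),
                        diagnoses = c("EAx", NA, "PP", "CVS"))
  v <- make_variants(
    make_variant(participant_id = "S001", gene = "CACNA1A"),
    make_variant(participant_id = "S002", gene = "CACNA1A"),
    make_variant(participant_id = "S003", gene = "SCN4A"),
    make_variant(participant_id = "S004", gene = "RYR2")  # RYR2 lists CVS
  )
  expect_equal(is_clinical(v, ph, panel), c(TRUE, FALSE, TRUE, FALSE))
  expect_error(
    is_clinical(make_variant(gene = "NOT_A_GENE"), ph, panel), "NOT_A_GENE")
})

test_that("co-segregation collapsing groups shared identifiers only", {
  v <- make_variants(
    make_variant(participant_id = "S029", gene = "SCN1A",
                 variant_id = "a", coseg_group = "g"),
    make_variant(participant_id = "S029", gene = "SCN1A",
                 variant_id = "b", coseg_group = "g"),
    make_variant(participant_id = "S029", gene = "SCN1A",
                 variant_id = "c", coseg_group = "g")
  )
  expect_length(collapse_cosegregating(v), 1)
  v2 <- make_variants(
    make_variant(participant_id = "S039", gene = "TRAP1", variant_id = "a"),
    make_variant(participant_id = "S039", gene = "TRAP1", variant_id = "b")
  )
  expect_length(collapse_cosegregating(v2), 2)
  expect_length(collapse_cosegregating(v[0, ]), 0)
  expect_error(collapse_cosegregating(rbind(v, v2)), "share")
})

test_that("qualify_cohort categorises and errors on unknown participants", {
  panel <- load_fixture("paroxysmal_panel")
  ph <- make_phenotypes("S001", diagnoses = "EAx")
  v <- make_variants(
    make_variant(participant_id = "S001", gene = "MEFV", af_nfe = 0.001,
                 phylop = 3, clinvar_calls = "P"),
    make_variant(participant_id = "S001", gene = "TRAP1", af_nfe = 0.001,
                 phylop = 3, variant_id = "x"),
    make_variant(participant_id = "S001", gene = "TRAP1", af_nfe = 0.5,
                 variant_id = "y"),
    make_variant(participant_id = "S001", gene = "SCN4A", af_nfe = 0.05,
                 phylop = 3, variant_id = "z")
  )
  res <- qualify_cohort(v, ph, panel)
  expect_equal(res$category[res$gene == "MEFV"], "key")
  expect_setequal(res$category[res$gene == "TRAP1"],
                  c("other", "not_recorded"))
  expect_equal(res$category[res$gene == "SCN4A"], "recorded_only")
  expect_error(qualify_cohort(v, make_phenotypes("S999"), panel), "S001")

  common <- v
  common$af_nfe <- 0.5
  expect_equal(sum(qualify_cohort(common, ph, panel)$recorded), 0)
})

test_that("nesting key => qualifying => recorded holds on random cohorts", {
  panel <- load_fixture("paroxysmal_panel")
  for (seed in 1:5) {
    v <- random_variants(200, seed = seed)
    ph <- make_phenotypes(unique(v$participant_id),
                          diagnoses = sample(c(NA, "EAx", "PP", "FMF"),
                                             length(unique(v$participant_id)),
                                             replace = TRUE))
    res <- qualify_cohort(v, ph, panel)
    expect_true(all(res$qualifying[res$category == "key"]))
    expect_true(all(res$recorded[res$qualifying]))
    expect_true(all(res$category[res$plp & res$qualifying] == "key"))
  }
})

test_that("qualifying set shrinks monotonically with stricter thresholds", {
  v <- random_variants(1000, seed = 11)
  base <- is_qualifying(v, qualification_thresholds())
  tighter_af <- is_qualifying(v, qualification_thresholds(af_qualify_max = 0.005))
  tighter_cons <- is_qualifying(
    v, qualification_thresholds(phylop_min = 3, mammal_match_min_pct = 99))
  expect_true(all(tighter_af <= base))
  expect_true(all(tighter_cons <= base))
})

test_that("qualification is invariant to input permutation", {
  panel <- load_fixture("paroxysmal_panel")
  v <- random_variants(150, seed = 3)
  ph <- make_phenotypes(unique(v$participant_id), diagnoses = "PP")
  res1 <- qualify_cohort(v, ph, panel)
  set.seed(99)
  res2 <- qualify_cohort(v[sample(nrow(v)), ], ph, panel)
  key <- function(r) r[order(r$participant_id, r$gene, r$variant_ids), ]
  expect_equal(key(res1)$category, key(res2)$category)
  expect_equal(nrow(res1), nrow(res2))
})

test_that("vectorised predicates match scalar brute-force re-evaluation", {
  v <- random_variants(200, seed = 17)
  rec <- is_recorded(v, t_def)
  qual <- is_qualifying(v, t_def)
  plp <- aggregate_clinvar(v$clinvar_calls, v$lof_predicted)
  for (i in seq_len(nrow(v))) {
    oracle <- brute_force_qualify(v[i, ], t_def)
    expect_equal(rec[i], oracle$recorded)
    expect_equal(qual[i], oracle$qualifying)
    expect_equal(plp[i], oracle$plp)
  }
})

test_that("recessive detection counts collapsed occurrence groups", {
  panel <- gene_panel("test", c("GLS2", "OTHER"))
  ph <- make_phenotypes(c("S040", "S041"))
  v <- make_variants(
    make_variant(participant_id = "S040", gene = "GLS2", variant_id = "a",
                 af_nfe = 0.001, phylop = 3),
    make_variant(participant_id = "S040", gene = "GLS2", variant_id = "b",
                 af_nfe = 0.001, phylop = 3),
    make_variant(participant_id = "S041", gene = "GLS2", variant_id = "c",
                 af_nfe = 0.001, phylop = 3),
    make_variant(participant_id = "S041", gene = "OTHER", variant_id = "d",
                 af_nfe = 0.001, phylop = 3)
  )
  res <- qualify_cohort(v, ph, panel)
  cand <- detect_recessive_candidates(res)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$participant_id, "S040")
  expect_equal(cand$n_occurrences, 2)
  expect_equal(cand$phase, "unknown")

  # three co-segregating variants are one occurrence, hence no candidate;
  # brute-force check: raw rows would give 3, collapsed gives 1
  v2 <- make_variants(
    make_variant(participant_id = "S029", gene = "GLS2", variant_id = "a",
                 af_nfe = 0.001, phylop = 3, coseg_group = "g"),
    make_variant(participant_id = "S029", gene = "GLS2", variant_id = "b",
                 af_nfe = 0.001, phylop = 3, coseg_group = "g"),
    make_variant(participant_id = "S029", gene = "GLS2", variant_id = "c",
                 af_nfe = 0.001, phylop = 3, coseg_group = "g")
  )
  res2 <- qualify_cohort(v2, make_phenotypes("S029"), panel)
  expect_equal(sum(is_qualifying(v2, t_def)), 3)  # raw count
  expect_equal(nrow(res2), 1)                     # collapsed count
  expect_equal(nrow(detect_recessive_candidates(res2)), 0)
})
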