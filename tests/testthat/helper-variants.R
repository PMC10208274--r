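# Build variant-table rows from a compact spec for tests.
make_variant <- function(participant_id = "S001", gene = "SCN4A",
                         genome = "nuclear", variant_id = "p.Test1Xyz",
                         consequence = "missense", zygosity = "het",
                         af_nfe = NA_real_, af_afr = NA_real_,
                         af_global = NA_real_, phylop = NA_real_,
                         mammal_match_pct = NA_real_, splice_rf = NA_real_,
                         splice_ada = NA_real_, clinvar_calls = NA_character_,
                         lof_predicted = FALSE, heteroplasmy_pct = NA_real_,
                         structure_exception = FALSE,
                         coseg_group = NA_character_) {
  data.frame(participant_id = participant_id, gene = gene, genome = genome,
             variant_id = variant_id, consequence = consequence,
             zygosity = zygosity, af_nfe = af_nfe, af_afr = af_afr,
             af_global = af_global, phylop = phylop,
             mammal_match_pct = mammal_match_pct, splice_rf = splice_rf,
             splice_ada = splice_ada, clinvar_calls = clinvar_calls,
             lof_predicted = lof_predicted,
             heteroplasmy_pct = heteroplasmy_pct,
             structure_exception = structure_exception,
             coseg_group = coseg_group, stringsAsFactors = FALSE)
}

make_variants <- function(...) {
  do.call(rbind, list(...))
}

make_phenotypes <- function(ids, diagnoses = NA_character_,
                            mito_domains = NA_character_) {
  data.frame(participant_id = ids,
             paroxysmal_diagnoses = rep_len(diagnoses, length(ids)),
             mito_domains = rep_len(mito_domains, length(ids)),
             ancestry_label = rep("nfe", length(ids)),
             stringsAsFactors = FALSE)
}

# Random valid variant records for property tests (annotations span the
# rule boundaries; not all records qualify).
random_variants <- function(n, seed = 1) {
  set.seed(seed)
  cons <- sample(c("missense", "nonsense", "synonymous", "intronic", "utr",
                   "inframe_indel", "frameshift"), n, replace = TRUE)
  af <- ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 0.15))
  tab <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_variant(
      participant_id = sprintf("S%03d", sample(1:40, 1)),
      gene = sample(c("SCN4A", "RYR2", "MEFV", "TRAP1", "CACNA1A"), 1),
      variant_id = sprintf("v%04d", i), consequence = cons[i],
      af_nfe = af[i],
      phylop = ifelse(runif(1) < 0.15, NA_real_, runif(1, -2, 6)),
      mammal_match_pct = ifelse(runif(1) < 0.7, NA_real_, runif(1, 50, 100)),
      splice_ada = ifelse(runif(1) < 0.8, NA_real_, runif(1)),
      clinvar_calls = sample(c(NA, "P", "P,VUS", "VUS,VUS,LP", "B,LB", "LP,P"),
                             1),
      lof_predicted = cons[i] %in% c("nonsense", "frameshift") && runif(1) < 0.5
    )
  }))
  rownames(tab) <- NULL
  tab
}

# Independent single-record re-evaluation of the three nuclear predicates,
# written directly from the rule statements (scalar, no shared code path
# with the vectorised implementation).
brute_force_qualify <- function(row, t = qualification_thresholds()) {
  af <- row[[paste0("af_", t$comparison_population)]]
  if (is.na(af)) af <- 0
  coding <- row$consequence %in% c("missense", "nonsense", "frameshift",
                                   "inframe_indel") ||
    (!is.na(row$splice_rf) && row$splice_rf > t$splice_min) ||
    (!is.na(row$splice_ada) && row$splice_ada > t$splice_min)
  conserved <- (!is.na(row$phylop) && row$phylop >= t$phylop_min) ||
    (!is.na(row$mammal_match_pct) &&
       row$mammal_match_pct >= t$mammal_match_min_pct)
  recorded <- af < t$af_record_max
  qualifying <- coding && af < t$af_qualify_max && conserved
  calls <- if (is.na(row$clinvar_calls)) character(0) else
    strsplit(row$clinvar_calls, ",")[[1]]
  plp <- isTRUE(row$lof_predicted) ||
    (length(calls) > 0 && sum(calls %in% c("P", "LP")) >= length(calls) / 2)
  list(recorded = recorded, qualifying = qualifying, plp = plp)
}

# Exhaustive hypergeometric enumeration of the two-tailed Fisher p-value:
# sum of point probabilities <= that of the observed table, margins fixed.
fisher_enumerate <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
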