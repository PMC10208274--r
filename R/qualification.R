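#' Qualification thresholds
#'
#' Cutoffs for the nuclear variant rules. Defaults are the study settings:
#' variants below 10% allele frequency in the comparison population are
#' *recorded*; *Qualifying* variants are coding, below 2% allele frequency and
#' conserved (PhyloP >= 1.5, or a reference-allele match in >= 90% of
#' mammalian species); predicted splice sites need a score above 0.6 on
#' either splice classifier. Frequency comparisons are strict (`<`),
#' conservation inclusive (`>=`), splice strict (`>`).
#'
#' @param af_record_max recording cutoff on allele frequency (strict `<`).
#' @param af_qualify_max qualifying rarity cutoff (strict `<`); must not
#'   exceed `af_record_max`.
#' @param phylop_min PhyloP conservation cutoff (inclusive `>=`).
#' @param mammal_match_min_pct mammalian-species match percentage cutoff
#'   (inclusive `>=`).
#' @param splice_min splice-classifier score cutoff (strict `>`).
#' @param comparison_population population whose gnomAD frequency is compared;
#'   one of `"nfe"`, `"afr"`, `"global"`. A frequency absent from gnomAD is
#'   treated as 0 (absence is the strongest rarity evidence).
#' @return object of class `qualification_thresholds`.
#' @export
qualification_thresholds <- function(af_record_max = 0.10,
                                     af_qualify_max = 0.02,
                                     phylop_min = 1.5,
                                     mammal_match_min_pct = 90,
                                     splice_min = 0.6,
                                     comparison_population = "nfe") {
  stopifnot(af_record_max >= 0, af_record_max <= 1,
            af_qualify_max >= 0, af_qualify_max <= af_record_max,
            splice_min >= 0, splice_min <= 1,
            mammal_match_min_pct >= 0, mammal_match_min_pct <= 100,
            comparison_population %in% c("nfe", "afr", "global"))
  structure(list(af_record_max = af_record_max,
                 af_qualify_max = af_qualify_max,
                 phylop_min = phylop_min,
                 mammal_match_min_pct = mammal_match_min_pct,
                 splice_min = splice_min,
                 comparison_population = comparison_population),
            class = "qualification_thresholds")
}

#' @export
print.qualification_thresholds <- function(x, ...) {
  cat("Qualification thresholds:\n")
  cat(sprintf("  recorded:   %s allele frequency < %g\n",
              x$comparison_population, x$af_record_max))
  cat(sprintf("  qualifying: allele frequency < %g, coding, conserved\n",
              x$af_qualify_max))
  cat(sprintf("  conserved:  PhyloP >= %g or mammal match >= %g%%\n",
              x$phylop_min, x$mammal_match_min_pct))
  cat(sprintf("  splice:     score > %g on either classifier\n", x$splice_min))
  invisible(x)
}

# Comparison-population allele frequency, absent -> 0.
resolved_af <- function(variants, t) {
  af <- variants[[paste0("af_", t$comparison_population)]]
  ifelse(is.na(af), 0, af)
}

#' Per-variant predicates: coding, recorded, qualifying
#'
#' `is_coding()` is true for amino-acid-altering consequences (missense,
#' nonsense, frameshift, in-frame indel) and for variants with a predicted
#' splice-altering score above the cutoff on either classifier.
#' `is_recorded()` is true below the recording frequency cutoff.
#' `is_qualifying()` requires coding, rarity below the qualifying cutoff, and
#' conservation (PhyloP or mammalian match). Repeat-expansion and structural
#' records are not derivable from these annotations; they qualify iff the
#' optional `coding_equivalent` flag is set on the record.
#'
#' All three are vectorised over the rows of the variant table.
#'
#' @param variants variant table (see [read_variant_table()]).
#' @param t [qualification_thresholds()].
#' @return logical vector, one element per row.
#' @export
is_coding <- function(variants, t = qualification_thresholds()) {
  aa_altering <- variants$consequence %in%
    c("missense", "nonsense", "frameshift", "inframe_indel")
  splice <- (!is.na(variants$splice_rf) & variants$splice_rf > t$splice_min) |
    (!is.na(variants$splice_ada) & variants$splice_ada > t$splice_min)
  aa_altering | splice
}

#' @rdname is_coding
#' @export
is_recorded <- function(variants, t = qualification_thresholds()) {
  resolved_af(variants, t) < t$af_record_max
}

#' @rdname is_coding
#' @export
is_qualifying <- function(variants, t = qualification_thresholds()) {
  special <- variants$consequence %in%
    c("repeat_expansion", "structural_deletion", "structural_duplication")
  flag <- if ("coding_equivalent" %in% names(variants)) {
    !is.na(variants$coding_equivalent) & variants$coding_equivalent
  } else rep(FALSE, nrow(variants))
  conserved <- (!is.na(variants$phylop) & variants$phylop >= t$phylop_min) |
    (!is.na(variants$mammal_match_pct) &
       variants$mammal_match_pct >= t$mammal_match_min_pct)
  rare <- resolved_af(variants, t) < t$af_qualify_max
  ifelse(special, flag, is_coding(variants, t) & rare & conserved)
}

#' Aggregate ClinVar calls into a P/LP verdict
#'
#' A variant is P/LP when it has a high prediction of loss of function
#' (nonsense, frameshift, large deletion, ...), or when at least half of its
#' ClinVar interpretations are Pathogenic or Likely Pathogenic.
#'
#' @param calls a character vector of comma-separated call strings (one per
#'   variant), or a list of token vectors; tokens among `P, LP, VUS, LB, B`.
#' @param lof_predicted logical vector, recycled to the length of `calls`.
#' @return logical vector.
#' @export
aggregate_clinvar <- function(calls, lof_predicted = FALSE) {
  if (!is.list(calls)) calls <- parse_token_sets(as.character(calls))
  lof_predicted <- rep_len(!is.na(lof_predicted) & lof_predicted,
                           length(calls))
  majority <- vapply(calls, function(tok) {
    tok <- tok[nzchar(tok)]
    length(tok) > 0 && sum(tok %in% c("P", "LP")) >= length(tok) / 2
  }, logical(1))
  lof_predicted | majority
}

#' Clinical phenotype match
#'
#' A qualifying variant is *Clinical* when its carrier holds a clinical
#' diagnosis of a non-CVS paroxysmal disease associated with the gene: the
#' panel's phenotype codes for the gene intersect the participant's
#' diagnoses. CVS itself never matches (it is excluded to avoid a circular
#' argument).
#'
#' @param variants variant table rows to test (requires `gene`,
#'   `participant_id`).
#' @param phenotypes phenotype table (see [read_phenotype_table()]).
#' @param panel [gene_panel()] providing `gene_phenotypes`.
#' @return logical vector.
#' @export
is_clinical <- function(variants, phenotypes, panel) {
  missing_genes <- setdiff(unique(variants$gene), panel$genes)
  if (length(missing_genes)) {
    stop(sprintf("gene(s) absent from panel '%s': %s", panel$name,
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  diag_by_pt <- parse_token_sets(phenotypes$paroxysmal_diagnoses)
  names(diag_by_pt) <- phenotypes$participant_id
  mapply(function(g, pt) {
    gene_ph <- setdiff(panel$gene_phenotypes[[g]], "CVS")
    pt_ph <- setdiff(diag_by_pt[[pt]], "CVS")
    length(intersect(gene_ph, pt_ph)) > 0
  }, variants$gene, variants$participant_id, USE.NAMES = FALSE)
}

#' Collapse co-segregating variants into occurrence groups
#'
#' Closely-spaced variants with identical prevalence data co-segregate and
#' count as a single scoring occurrence; they are marked by a shared
#' `coseg_group` identifier (groups are given in the data, never inferred
#' from positions). Ungrouped records are singleton occurrences, and a
#' homozygous record is one occurrence.
#'
#' @param records rows of a variant table for one participant and gene.
#' @return list of integer vectors, each the row indices of one occurrence.
#' @export
collapse_cosegregating <- function(records) {
  n <- nrow(records)
  if (n == 0) return(list())
  if (length(unique(records$participant_id)) > 1 ||
      length(unique(records$gene)) > 1) {
    stop("records must share one participant and one gene", call. = FALSE)
  }
  key <- occurrence_key(records)
  unname(split(seq_len(n), factor(key, levels = unique(key))))
}

# Occurrence grouping key for arbitrary tables: participant x gene x
# coseg_group, with ungrouped rows unique.
occurrence_key <- function(records) {
  cg <- if ("coseg_group" %in% names(records)) records$coseg_group else
    rep(NA_character_, nrow(records))
  singleton <- is.na(cg) | !nzchar(cg)
  grp <- ifelse(singleton, paste0(".row", seq_len(nrow(records))), cg)
  paste(records$participant_id, records$gene, grp, sep = "\r")
}

#' Qualify a cohort of nuclear variants
#'
#' Applies the full nuclear rule set: recording threshold, the Qualifying
#' definition (coding, rare, conserved), ClinVar P/LP aggregation, Clinical
#' phenotype matching, and co-segregation collapsing. Returns one row per
#' occurrence group; a group is Key Qualifying when it is qualifying and any
#' member is P/LP or Clinical, Other Qualifying when qualifying but neither.
#'
#' @param variants variant table; only `genome == "nuclear"` rows are
#'   processed (mitochondrial records go through [classify_mito()]).
#' @param phenotypes phenotype table covering every participant in
#'   `variants`.
#' @param panel [gene_panel()]; genes outside the panel are dropped with a
#'   warning.
#' @param t [qualification_thresholds()].
#' @return data frame with one row per occurrence group: `participant_id`,
#'   `gene`, `variant_ids` (semicolon-joined), `n_variants`, `recorded`,
#'   `qualifying`, `plp`, `clinical`, and `category` among
#'   `key, other, recorded_only, not_recorded`.
#' @export
qualify_cohort <- function(variants, phenotypes, panel,
                           t = qualification_thresholds()) {
  v <- variants[variants$genome == "nuclear", , drop = FALSE]
  unknown <- setdiff(unique(v$participant_id), phenotypes$participant_id)
  if (length(unknown)) {
    stop(sprintf("participant_id(s) missing from phenotype table: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  off_panel <- !(v$gene %in% panel$genes)
  if (any(off_panel)) {
    warning(sprintf("dropping %d record(s) in gene(s) outside panel '%s'",
                    sum(off_panel), panel$name))
    v <- v[!off_panel, , drop = FALSE]
  }
  if (nrow(v) == 0) return(empty_qualification())
  rec <- is_recorded(v, t)
  qual <- is_qualifying(v, t)
  plp <- aggregate_clinvar(v$clinvar_calls, v$lof_predicted)
  clin <- is_clinical(v, phenotypes, panel)
  key <- occurrence_key(v)
  groups <- split(seq_len(nrow(v)), factor(key, levels = unique(key)))
  res <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(
      participant_id = v$participant_id[idx[1]],
      gene = v$gene[idx[1]],
      variant_ids = paste(v$variant_id[idx], collapse = ";"),
      n_variants = length(idx),
      recorded = any(rec[idx]),
      qualifying = any(qual[idx]),
      plp = any(plp[idx] & qual[idx]),
      clinical = any(clin[idx] & qual[idx]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  res$category <- ifelse(!res$recorded, "not_recorded",
                    ifelse(!res$qualifying, "recorded_only",
                      ifelse(res$plp | res$clinical, "key", "other")))
  res
}

empty_qualification <- function() {
  data.frame(participant_id = character(0), gene = character(0),
             variant_ids = character(0), n_variants = integer(0),
             recorded = logical(0), qualifying = logical(0),
             plp = logical(0), clinical = logical(0),
             category = character(0), stringsAsFactors = FALSE)
}

#' Detect recessive (two-hit) candidates
#'
#' Reports every participant x gene combination carrying two or more
#' qualifying occurrence groups, as candidates for compound-heterozygous
#' (phase-unknown) recessive disease. Co-segregating variants were collapsed
#' beforehand, so one co-segregating cluster never triggers a candidate.
#' No filtering by gene function is applied; that judgement is downstream.
#'
#' @param results output of [qualify_cohort()].
#' @return data frame with `participant_id`, `gene`, `n_occurrences` (>= 2),
#'   and `phase` (always `"unknown"`).
#' @export
detect_recessive_candidates <- function(results) {
  q <- results[results$qualifying, , drop = FALSE]
  if (nrow(q) == 0) {
    return(data.frame(participant_id = character(0), gene = character(0),
                      n_occurrences = integer(0), phase = character(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_occurrences = q$qualifying),
                          by = list(participant_id = q$participant_id,
                                    gene = q$gene), FUN = length)
  agg <- agg[agg$n_occurrences >= 2, , drop = FALSE]
  agg <- agg[order(agg$participant_id, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  if (nrow(agg)) agg$phase <- "unknown" else agg$phase <- character(0)
  agg
}
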