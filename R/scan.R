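#' Score candidate genes for CVS association in a cohort
#'
#' The main entry point: composes the full analysis on an annotated variant
#' table. Nuclear variants go through the qualification rules
#' ([qualify_cohort()]): recording threshold, Qualifying definition (coding,
#' rare, conserved), ClinVar P/LP aggregation, Clinical phenotype matching
#' and co-segregation collapsing. Mitochondrial variants are classified by
#' the heteroplasmy, structure-exception and clinical-domain rules
#' ([classify_mito()]) and pooled under the single gene `"mtDNA"`. Gene
#' scores (3 points per Key, 1 per Other Qualifying occurrence) become
#' evidence tiers, combined with literature family counts into composite
#' tiers, yielding the ordered candidate list; participants with two or more
#' qualifying occurrences in one gene are flagged as recessive candidates.
#'
#' @param variants annotated variant table ([read_variant_table()]).
#' @param phenotypes phenotype table ([read_phenotype_table()]) covering all
#'   participants in `variants`.
#' @param panel [gene_panel()]; defaults to the packaged 35-gene paroxysmal
#'   panel.
#' @param literature data frame with `gene` and `literature_families`, or
#'   `TRUE` for the packaged literature table, or `NULL` for study-only
#'   scoring.
#' @param thresholds [qualification_thresholds()].
#' @return object of class `cvs_scan` with components `qualification`
#'   (per-occurrence results), `mito` (per-record mitochondrial
#'   classifications), `gene_scores`, `candidates`, `recessive`,
#'   `thresholds`, `panel`, and `summary` (carrier counts with explicit
#'   denominators).
#' @export
score_candidates <- function(variants, phenotypes,
                             panel = load_fixture("paroxysmal_panel"),
                             literature = NULL,
                             thresholds = qualification_thresholds()) {
  if (isTRUE(literature)) literature <- load_fixture("literature_points")
  nuclear <- qualify_cohort(variants, phenotypes, panel, thresholds)
  mrec <- variants[variants$genome == "mitochondrial", , drop = FALSE]
  mito <- if (nrow(mrec)) classify_mito(mrec, phenotypes) else NULL
  results <- nuclear
  if (!is.null(mito) && isTRUE(panel$mito_as_single_gene)) {
    results <- rbind(results, mito_as_qualification(mito))
  }
  scores <- score_panel(results, panel, literature)
  candidates <- build_candidate_list(scores)
  recessive <- detect_recessive_candidates(nuclear)
  n_pt <- nrow(phenotypes)
  cand_genes <- candidates$gene
  in_cand <- results$gene %in% cand_genes
  structure(list(
    qualification = nuclear,
    mito = mito,
    results = results,
    gene_scores = scores,
    candidates = candidates,
    recessive = recessive,
    thresholds = thresholds,
    panel = panel,
    summary = list(
      n_participants = n_pt,
      key_carriers = length(unique(
        results$participant_id[results$category == "key" & in_cand])),
      qualifying_carriers = length(unique(
        results$participant_id[results$category %in% c("key", "other") &
                                 in_cand])),
      n_candidates = nrow(candidates)
    )
  ), class = "cvs_scan")
}

# Nearest-integer percentage, half away from zero.
pct <- function(num, den) {
  if (den == 0) return(0)
  as.integer(round_half_away(100 * num / den))
}

#' @export
print.cvs_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("CVS candidate-gene scan: %d genes in panel '%s', %d participants\n",
              length(x$panel$genes), x$panel$name, s$n_participants))
  cat(sprintf("  candidate genes (composite tier >= likely): %d\n",
              s$n_candidates))
  cat(sprintf("  participants with a Key Qualifying variant in a candidate gene: %d/%d (%d%%)\n",
              s$key_carriers, s$n_participants,
              pct(s$key_carriers, s$n_participants)))
  cat(sprintf("  participants with any Qualifying variant in a candidate gene: %d/%d (%d%%)\n",
              s$qualifying_carriers, s$n_participants,
              pct(s$qualifying_carriers, s$n_participants)))
  invisible(x)
}

#' @export
summary.cvs_scan <- function(object, ...) {
  print(object)
  cat("\nTop candidate genes:\n")
  top <- utils::head(object$candidates[, c("gene", "key_occurrences",
                                           "other_occurrences", "study_points",
                                           "study_tier", "literature_points",
                                           "composite_tier")], 12)
  print(top, row.names = FALSE)
  if (nrow(object$recessive)) {
    cat(sprintf("\nRecessive (2+ qualifying occurrences) candidates: %d\n",
                nrow(object$recessive)))
  }
  invisible(object)
}

#' @export
plot.cvs_scan <- function(x, ...) {
  sc <- x$gene_scores[order(-x$gene_scores$study_points), , drop = FALSE]
  sc <- sc[sc$study_points > 0, , drop = FALSE]
  cols <- c(no_evidence = "grey80", possibly = "khaki",
            likely = "orange", highly_likely = "firebrick")
  graphics::barplot(sc$study_points, names.arg = sc$gene, las = 2,
                    col = cols[as.character(sc$study_tier)],
                    ylab = "study points", cex.names = 0.7, ...)
  graphics::abline(h = c(3, 6, 12), lty = 3)
  invisible(x)
}

#' Convert a labeled occurrence table to qualification results
#'
#' Replays a table in the shape of the packaged `table2_occurrences` fixture
#' (one row per variant occurrence per participant with its Key/Other label,
#' zygosity and co-segregation group) into occurrence-collapsed
#' qualification results suitable for [score_gene()]/[score_panel()]:
#' co-segregating rows collapse to one occurrence which is Key when any
#' member is Key, and a homozygous row still counts once.
#'
#' @param occurrences data frame with columns `gene`, `variant_id`,
#'   `participant_id`, `category` (`key`/`other`), `zygosity`,
#'   `coseg_group`.
#' @return data frame in the [qualify_cohort()] result shape.
#' @export
occurrences_as_qualification <- function(occurrences) {
  key <- occurrence_key(occurrences)
  groups <- split(seq_len(nrow(occurrences)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(idx) {
    data.frame(
      participant_id = occurrences$participant_id[idx[1]],
      gene = occurrences$gene[idx[1]],
      variant_ids = paste(occurrences$variant_id[idx], collapse = ";"),
      n_variants = length(idx),
      recorded = TRUE, qualifying = TRUE,
      plp = NA, clinical = NA,
      category = if (any(occurrences$category[idx] == "key")) "key" else "other",
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Replay the packaged study tables as a scan
#'
#' Builds a `cvs_scan` from the packaged fixtures alone: the transcribed
#' nuclear occurrence table, the mitochondrial variant table, and (by
#' default) the literature family counts, with the study denominator of 80
#' participants. This is the fixtures-only run that reproduces the printed
#' per-gene points, tier counts and the 22-gene candidate list.
#'
#' @param literature as in [score_candidates()].
#' @param n_participants cohort denominator for the summary counts.
#' @return a `cvs_scan` object.
#' @export
fixture_scan <- function(literature = TRUE, n_participants = 80) {
  if (isTRUE(literature)) literature <- load_fixture("literature_points")
  panel <- load_fixture("paroxysmal_panel")
  nuclear <- occurrences_as_qualification(load_fixture("table2_occurrences"))
  mito <- classify_mito(load_fixture("mtdna_table"))
  results <- rbind(nuclear, mito_as_qualification(mito))
  scores <- score_panel(results, panel, literature)
  candidates <- build_candidate_list(scores)
  in_cand <- results$gene %in% candidates$gene
  structure(list(
    qualification = nuclear, mito = mito, results = results,
    gene_scores = scores, candidates = candidates,
    recessive = detect_recessive_candidates(nuclear),
    thresholds = qualification_thresholds(), panel = panel,
    summary = list(
      n_participants = n_participants,
      key_carriers = length(unique(
        results$participant_id[results$category == "key" & in_cand])),
      qualifying_carriers = length(unique(
        results$participant_id[results$category %in% c("key", "other") &
                                 in_cand])),
      n_candidates = nrow(candidates)
    )
  ), class = "cvs_scan")
}

#' Run the full pipeline and write its report bundle
#'
#' Runs qualification, mitochondrial classification, scoring and the
#' candidate list on a configuration, writing each stage's table plus a
#' JSON summary whose every number is recomputable from the stage tables.
#' Identical inputs (and seed, when the cohort is simulated) produce
#' byte-identical outputs.
#'
#' @param config a named list (or path to a YAML file with the same keys):
#'   `variants` and `phenotypes` (paths to TSVs, or data frames), `panel`
#'   (fixture name, default `"paroxysmal_panel"`), `literature` (default
#'   `TRUE` = packaged table; `FALSE` = study-only scoring), `thresholds` (named list of
#'   [qualification_thresholds()] arguments), `out_dir` (required),
#'   `format` (`"tsv"`, with a JSON mirror of the gene scores).
#' @return the `cvs_scan` object, invisibly; the report paths are in
#'   attribute `"paths"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the 'yaml' package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  literature <- if (is.null(config$literature)) TRUE else config$literature
  if (isFALSE(literature)) literature <- NULL   # study-only scoring
  if (isTRUE(config$fixtures_only)) {
    scan <- fixture_scan(literature = literature)
  } else {
    variants <- if (is.character(config$variants)) {
      read_variant_table(config$variants)
    } else config$variants
    phenotypes <- if (is.character(config$phenotypes)) {
      read_phenotype_table(config$phenotypes)
    } else config$phenotypes
    panel <- if (is.null(config$panel)) {
      load_fixture("paroxysmal_panel")
    } else if (is.character(config$panel)) {
      load_fixture(config$panel)
    } else config$panel
    thresholds <- do.call(qualification_thresholds,
                          if (is.null(config$thresholds)) list() else
                            config$thresholds)
    scan <- score_candidates(variants, phenotypes, panel = panel,
                             literature = literature, thresholds = thresholds)
  }
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".tsv"))
    out <- df
    for (col in names(out)) if (is.factor(out[[col]])) {
      out[[col]] <- as.character(out[[col]])
    }
    utils::write.table(out, p, sep = "\t", quote = FALSE, na = "",
                       row.names = FALSE)
    p
  }
  paths["qualification"] <- wt(scan$qualification, "qualification")
  if (!is.null(scan$mito)) paths["mito"] <- wt(scan$mito, "mito")
  paths["gene_scores"] <- wt(scan$gene_scores, "gene_scores")
  paths["candidates"] <- wt(scan$candidates, "candidates")
  paths["recessive"] <- wt(scan$recessive, "recessive")
  scores_json <- scan$gene_scores
  for (col in names(scores_json)) if (is.factor(scores_json[[col]])) {
    scores_json[[col]] <- as.character(scores_json[[col]])
  }
  paths["gene_scores_json"] <- file.path(config$out_dir, "gene_scores.json")
  jsonlite::write_json(scores_json, paths["gene_scores_json"],
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  s <- scan$summary
  summary_list <- list(
    n_participants = s$n_participants,
    n_candidate_genes = s$n_candidates,
    candidate_genes = scan$candidates$gene,
    key_carriers = s$key_carriers,
    key_carrier_pct = pct(s$key_carriers, s$n_participants),
    qualifying_carriers = s$qualifying_carriers,
    qualifying_carrier_pct = pct(s$qualifying_carriers, s$n_participants),
    recessive_candidates = nrow(scan$recessive)
  )
  paths["summary"] <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary_list, paths["summary"], auto_unbox = TRUE,
                       digits = NA)
  attr(scan, "paths") <- paths
  invisible(scan)
}
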