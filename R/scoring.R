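TIER_LEVELS <- c("no_evidence", "possibly", "likely", "highly_likely")

#' Convert points to an evidence tier
#'
#' The threshold map: >= 12 points "highly_likely", 6-11 "likely", 3-5
#' "possibly", <= 2 "no_evidence". Monotone non-decreasing in points.
#'
#' @param points non-negative integer vector.
#' @return ordered factor with levels
#'   `no_evidence < possibly < likely < highly_likely`.
#' @export
assign_tier <- function(points) {
  stopifnot(all(points >= 0, na.rm = TRUE))
  cut(points, breaks = c(-Inf, 2, 5, 11, Inf), labels = TIER_LEVELS,
      ordered_result = TRUE)
}

#' Composite of two evidence tiers
#'
#' The composite tier is the higher of the study-derived and
#' literature-derived tiers (commutative maximum under
#' `no_evidence < possibly < likely < highly_likely`).
#'
#' @param study,literature tiers as returned by [assign_tier()] (character
#'   input is coerced).
#' @return ordered factor of composite tiers.
#' @export
composite_tier <- function(study, literature) {
  s <- as.integer(as_tier(study))
  l <- as.integer(as_tier(literature))
  s[is.na(s)] <- 1L
  l[is.na(l)] <- 1L
  as_tier(TIER_LEVELS[pmax(s, l)])
}

as_tier <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  factor(x, levels = TIER_LEVELS, ordered = TRUE)
}

#' Score one gene from its qualification results
#'
#' Each Key Qualifying occurrence earns the gene 3 points and each Other
#' Qualifying occurrence 1 point. An occurrence that is both P/LP and
#' Clinical still earns 3 points, once. Input rows must already be
#' occurrence-collapsed (one row per occurrence group, as produced by
#' [qualify_cohort()]).
#'
#' @param results qualification-result rows for a single gene.
#' @param gene gene symbol; defaults to the one present in `results`.
#' @param literature_families count of literature families with reported
#'   paroxysmal vomiting for this gene (1 point each), `NA` when unknown.
#' @return one-row data frame: `gene`, `key_occurrences`,
#'   `other_occurrences`, `study_points`, `study_tier`,
#'   `literature_families`, `literature_points`, `literature_tier`,
#'   `composite_tier`.
#' @export
score_gene <- function(results, gene = NULL, literature_families = NA_integer_) {
  if (is.null(gene)) {
    gene <- if (nrow(results)) unique(results$gene) else NA_character_
  }
  if (length(gene) != 1) {
    stop("score_gene expects results for exactly one gene", call. = FALSE)
  }
  key <- sum(results$category == "key")
  other <- sum(results$category == "other")
  study_points <- 3L * key + other
  lit_points <- if (is.na(literature_families)) NA_integer_ else
    as.integer(literature_families)
  out <- data.frame(
    gene = gene,
    key_occurrences = key,
    other_occurrences = other,
    study_points = study_points,
    study_tier = assign_tier(study_points),
    literature_families = lit_points,
    literature_points = lit_points,
    literature_tier = assign_tier(ifelse(is.na(lit_points), 0L, lit_points)),
    stringsAsFactors = FALSE
  )
  out$composite_tier <- composite_tier(out$study_tier, out$literature_tier)
  out
}

#' Score every gene of a panel
#'
#' Applies [score_gene()] across a panel, including genes with no qualifying
#' occurrences (0 points), and optionally pools mitochondrial results under
#' the reserved symbol `"mtDNA"`.
#'
#' @param results occurrence-collapsed qualification results (nuclear; may
#'   already include pooled `"mtDNA"` rows from [mito_as_qualification()]).
#' @param panel [gene_panel()]; scored genes are the panel genes plus
#'   `"mtDNA"` when the panel pools the mitochondrial genome and
#'   mitochondrial results are present.
#' @param literature data frame with `gene` and `literature_families`
#'   columns, or `NULL` when no literature evidence is used.
#' @return data frame with one [score_gene()] row per gene.
#' @export
score_panel <- function(results, panel, literature = NULL) {
  genes <- panel$genes
  if (isTRUE(panel$mito_as_single_gene) && any(results$gene == "mtDNA")) {
    genes <- c(genes, "mtDNA")
  }
  lit_for <- function(g) {
    if (is.null(literature)) return(NA_integer_)
    i <- match(g, literature$gene)
    if (is.na(i)) 0L else literature$literature_families[i]
  }
  scores <- do.call(rbind, lapply(genes, function(g) {
    score_gene(results[results$gene == g, , drop = FALSE], gene = g,
               literature_families = lit_for(g))
  }))
  rownames(scores) <- NULL
  scores
}

#' Build the ordered candidate-gene list
#'
#' Genes whose composite tier is at least "likely", ordered by study points
#' (descending) and then gene symbol. With full study and literature
#' evidence for the paroxysmal panel plus the pooled mitochondrial genome,
#' this reproduces the 22-gene candidate list.
#'
#' @param scores output of [score_panel()] (rows may span several panels).
#' @return data frame of candidate genes with their scores and tiers.
#' @export
build_candidate_list <- function(scores) {
  keep <- as_tier(scores$composite_tier) >= "likely"
  out <- scores[keep, , drop = FALSE]
  out <- out[order(-out$study_points, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
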