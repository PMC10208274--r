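#' Mitochondrial exclusion rule
#'
#' Mitochondrial variants with heteroplasmy (minor-allele proportion) below
#' 20% are excluded as likely of recent somatic origin. Absent heteroplasmy
#' means homoplasmic, which is kept. Exclusion is absorbing: an excluded
#' record contributes to no downstream count or score.
#'
#' @param heteroplasmy_pct numeric vector of heteroplasmy percentages
#'   (0-100), `NA` = homoplasmic.
#' @return logical vector: `TRUE` = excluded.
#' @export
mito_exclude <- function(heteroplasmy_pct) {
  check_percentage(heteroplasmy_pct, "heteroplasmy_pct")
  !is.na(heteroplasmy_pct) & heteroplasmy_pct < 20
}

#' Mitochondrial P/LP rule
#'
#' A retained mitochondrial variant is labeled P/LP when its heteroplasmy
#' lies in the 40-98% band (inclusive at both ends; above 98% is effectively
#' homoplasmic and does not trigger the band), when ClinVar lists it as
#' likely pathogenic, or when it carries the secondary-structure
#' conservation exception flag (very high conservation of tRNA stem
#' Watson-Crick binding across mammals; the flag is an input, not computed).
#'
#' @param heteroplasmy_pct numeric, `NA` = homoplasmic.
#' @param clinvar_lp logical ClinVar P/LP flag.
#' @param structure_exception logical structure-conservation exception flag.
#' @return logical vector.
#' @export
mito_plp <- function(heteroplasmy_pct, clinvar_lp = FALSE,
                     structure_exception = FALSE) {
  n <- max(length(heteroplasmy_pct), length(clinvar_lp),
           length(structure_exception))
  h <- rep_len(heteroplasmy_pct, n)
  in_band <- !is.na(h) & h >= 40 & h <= 98
  in_band | rep_len(!is.na(clinvar_lp) & clinvar_lp, n) |
    rep_len(!is.na(structure_exception) & structure_exception, n)
}

#' Mitochondrial Clinical rule: four or more affected domains
#'
#' Mitochondrial phenotypes are protean, so the Clinical label requires
#' mitochondrial-related clinical findings in at least four of the eight
#' domains: neuromuscular, neurodevelopmental, neuropsychiatric, functional,
#' endocrine, immunological, metabolic, enzymological.
#'
#' @param domains a character vector of domain labels (one participant) or a
#'   list of such vectors; alternatively a numeric vector of domain counts.
#' @return logical vector.
#' @export
mito_clinical <- function(domains) {
  if (is.numeric(domains)) return(!is.na(domains) & domains >= 4)
  if (!is.list(domains)) domains <- list(domains)
  counts <- vapply(domains, function(d) {
    d <- unique(d[nzchar(d)])
    bad <- setdiff(d, MITO_DOMAINS)
    if (length(bad)) {
      stop(sprintf("unknown mitochondrial domain label(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    length(d)
  }, integer(1))
  counts >= 4
}

#' Enzymological domain from respiratory-chain complex activities
#'
#' The enzymological domain counts as affected when complex I or complex IV
#' activity is below 30% of control in muscle or buccal cells (strict `<`).
#'
#' @param complex_i_pct,complex_iv_pct percent of control activity, `NA` when
#'   not measured.
#' @return logical vector.
#' @export
enzymological_domain <- function(complex_i_pct = NA_real_,
                                 complex_iv_pct = NA_real_) {
  n <- max(length(complex_i_pct), length(complex_iv_pct))
  ci <- rep_len(complex_i_pct, n)
  civ <- rep_len(complex_iv_pct, n)
  (!is.na(ci) & ci < 30) | (!is.na(civ) & civ < 30)
}

#' Classify mitochondrial variant records
#'
#' Applies the mitochondrial rule set in order: somatic exclusion
#' (heteroplasmy < 20%), then P/LP (heteroplasmy band, ClinVar flag,
#' structure exception) and Clinical (>= 4 domains). A retained record is
#' Key Qualifying when P/LP or Clinical, otherwise Other Qualifying. For
#' scoring, the whole mitochondrial genome is treated as a single gene.
#'
#' @param records a data frame with columns `gene`, `variant_id`,
#'   `participant_id`, `heteroplasmy_pct`, `clinvar_lp`,
#'   `structure_exception`, and either `n_domains` or `domain_labels`
#'   (comma-separated), as in the packaged `mtdna_table` fixture; or a
#'   variant table restricted to `genome == "mitochondrial"` combined with
#'   `phenotypes`.
#' @param phenotypes optional phenotype table supplying `mito_domains` when
#'   `records` lacks domain information.
#' @return data frame with one row per record: identifiers plus
#'   `excluded_somatic`, `plp`, `clinical`, and `category` among
#'   `key, other, excluded`.
#' @export
classify_mito <- function(records, phenotypes = NULL) {
  if ("genome" %in% names(records)) {
    if (any(records$genome != "mitochondrial")) {
      stop("classify_mito expects mitochondrial records only", call. = FALSE)
    }
  }
  clinvar_lp <- if ("clinvar_lp" %in% names(records)) records$clinvar_lp else
    aggregate_clinvar(records$clinvar_calls, records$lof_predicted)
  n_domains <- if ("n_domains" %in% names(records)) {
    records$n_domains
  } else if ("domain_labels" %in% names(records)) {
    lengths(parse_token_sets(records$domain_labels))
  } else if (!is.null(phenotypes)) {
    doms <- parse_token_sets(phenotypes$mito_domains)
    names(doms) <- phenotypes$participant_id
    lengths(doms[records$participant_id])
  } else {
    stop("no domain information: provide n_domains/domain_labels or phenotypes",
         call. = FALSE)
  }
  excluded <- mito_exclude(records$heteroplasmy_pct)
  plp <- mito_plp(records$heteroplasmy_pct, clinvar_lp,
                  records$structure_exception) & !excluded
  clinical <- mito_clinical(as.numeric(n_domains)) & !excluded
  data.frame(
    gene = records$gene,
    variant_id = records$variant_id,
    participant_id = records$participant_id,
    excluded_somatic = excluded,
    plp = plp,
    clinical = clinical,
    category = ifelse(excluded, "excluded",
                      ifelse(plp | clinical, "key", "other")),
    stringsAsFactors = FALSE
  )
}

#' Convert mitochondrial classifications to pooled qualification results
#'
#' Re-expresses [classify_mito()] output in the shape of [qualify_cohort()]
#' results under the reserved gene symbol `"mtDNA"`, so mitochondrial Key and
#' Other occurrences score into a single gene.
#'
#' @param mito output of [classify_mito()].
#' @return data frame in the [qualify_cohort()] result shape.
#' @export
mito_as_qualification <- function(mito) {
  kept <- mito[mito$category != "excluded", , drop = FALSE]
  if (nrow(kept) == 0) return(empty_qualification())
  data.frame(
    participant_id = kept$participant_id,
    gene = "mtDNA",
    variant_ids = kept$variant_id,
    n_variants = 1L,
    recorded = TRUE,
    qualifying = TRUE,
    plp = kept$plp,
    clinical = kept$clinical,
    category = kept$category,
    stringsAsFactors = FALSE
  )
}
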