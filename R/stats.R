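#' Two-tailed Fisher exact test on a 2x2 table
#'
#' The two-tailed p-value follows the minimum-likelihood convention (the sum
#' of point probabilities of all tables with the observed margins that are no
#' more probable than the observed table), the convention of common
#' statistical tools; the doubling convention is not used. The odds ratio is
#' the sample odds ratio `a*d / (b*c)` (infinite when `b*c = 0` and
#' `a*d > 0`), not the conditional maximum-likelihood estimate.
#'
#' @param tab a 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(a, b, c, d)` filled by row (rows = groups, columns =
#'   outcome/non-outcome).
#' @return list of class `fisher_result` with elements `p_two_tailed`,
#'   `odds_ratio`, `table`, and `correction` (`"none"`).
#' @export
fisher_exact <- function(tab) {
  m <- as_2x2(tab)
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  p <- if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) 1
    else stats::fisher.test(m)$p.value
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  structure(list(p_two_tailed = min(p, 1), odds_ratio = or, table = m,
                 correction = "none"),
            class = "fisher_result")
}

as_2x2 <- function(tab) {
  m <- if (is.matrix(tab)) tab else matrix(as.numeric(tab), nrow = 2,
                                           byrow = TRUE)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(is.na(m)) || any(m < 0)) {
    stop("table entries must be non-negative counts", call. = FALSE)
  }
  if (sum(m) > 0 && (all(rowSums(m) == 0) || all(colSums(m) == 0))) {
    stop("need at least one positive margin", call. = FALSE)
  }
  m
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Two-tailed Fisher exact test\n")
  print(x$table)
  cat(sprintf("p = %.4g, odds ratio = %.4g (correction: %s)\n",
              x$p_two_tailed, x$odds_ratio, x$correction))
  invisible(x)
}

#' Hardy-Weinberg carrier frequency
#'
#' Converts an allele frequency `q` into the frequency of carriers of at
#' least one copy under Hardy-Weinberg equilibrium: `1 - (1 - q)^2`. An
#' allele frequency of 10% corresponds to 19% carriers, and the 2% rarity
#' cutoff to a carrier frequency near 4% (3.96%).
#'
#' @param q allele frequency in `[0, 1]` (vectorised).
#' @return carrier frequency in `[0, 1]`.
#' @export
carrier_frequency <- function(q) {
  if (any(is.na(q)) || any(q < 0 | q > 1)) {
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - q)^2
}

# Cohort allele count per occurrence: hom = 2, het/hemi = 1.
allele_count <- function(zygosity) {
  ifelse(zygosity == "hom", 2L, 1L)
}

#' Test recurrent recorded variants against population allele counts
#'
#' Every recorded variant carried by at least `min_participants` study
#' participants is tested for enrichment against supplied population allele
#' counts (never fetched): a 2x2 table of cohort alternate/reference alleles
#' (hom = 2 alleles, het or hemizygous = 1; cohort denominator = 2 x
#' participants) versus population counts, by [fisher_exact()].
#'
#' @param variants variant table of recorded variants (per participant).
#' @param population data frame with columns `variant_id`, `allele_count`,
#'   `allele_number` (counts in the comparison population).
#' @param n_participants number of participants sequenced (cohort allele
#'   denominator is `2 * n_participants`).
#' @param min_participants recurrence threshold; variants carried by fewer
#'   participants are skipped.
#' @return data frame with one row per tested variant: `variant_id`,
#'   `n_carriers`, `cohort_alleles`, `p_two_tailed`, `odds_ratio`.
#' @export
recurrent_variant_tests <- function(variants, population, n_participants,
                                    min_participants = 3) {
  by_var <- split(seq_len(nrow(variants)), variants$variant_id)
  by_var <- by_var[vapply(by_var, function(i) {
    length(unique(variants$participant_id[i])) >= min_participants
  }, logical(1))]
  if (!length(by_var)) {
    return(data.frame(variant_id = character(0), n_carriers = integer(0),
                      cohort_alleles = integer(0), p_two_tailed = numeric(0),
                      odds_ratio = numeric(0), stringsAsFactors = FALSE))
  }
  res <- lapply(names(by_var), function(vid) {
    idx <- by_var[[vid]]
    pop <- population[population$variant_id == vid, , drop = FALSE]
    if (nrow(pop) == 0) {
      stop(sprintf("no population allele counts for variant %s", vid),
           call. = FALSE)
    }
    alt <- sum(allele_count(variants$zygosity[idx]))
    total <- 2L * n_participants
    ft <- fisher_exact(c(alt, total - alt,
                         pop$allele_count[1],
                         pop$allele_number[1] - pop$allele_count[1]))
    data.frame(variant_id = vid,
               n_carriers = length(unique(variants$participant_id[idx])),
               cohort_alleles = alt,
               p_two_tailed = ft$p_two_tailed,
               odds_ratio = ft$odds_ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Categorize recorded variants
#'
#' Partitions recorded variants into the four exhaustive, disjoint classes
#' used to describe the recurrent-variant pool: non-coding; uncommon coding
#' (allele frequency 2%-10%); rare, lesser-conserved coding; and rare,
#' highly-conserved coding.
#'
#' @param variants variant table rows (recorded variants).
#' @param t [qualification_thresholds()].
#' @return named integer vector of class sizes (`non_coding`,
#'   `coding_2_10pct`, `coding_rare_nonconserved`, `coding_rare_conserved`),
#'   with the per-row class as attribute `"class_of"`.
#' @export
categorize_recorded <- function(variants, t = qualification_thresholds()) {
  coding <- is_coding(variants, t)
  af <- resolved_af(variants, t)
  conserved <- (!is.na(variants$phylop) & variants$phylop >= t$phylop_min) |
    (!is.na(variants$mammal_match_pct) &
       variants$mammal_match_pct >= t$mammal_match_min_pct)
  cls <- ifelse(!coding, "non_coding",
           ifelse(af >= t$af_qualify_max, "coding_2_10pct",
             ifelse(conserved, "coding_rare_conserved",
                    "coding_rare_nonconserved")))
  lv <- c("non_coding", "coding_2_10pct", "coding_rare_nonconserved",
          "coding_rare_conserved")
  counts <- table(factor(cls, levels = lv))
  out <- stats::setNames(as.integer(counts), lv)
  attr(out, "class_of") <- cls
  out
}

#' Mixed-population allele frequency
#'
#' Constructs the allele frequency of a synthetic population mixing source
#' populations at given proportions (e.g. 91% NFE + 9% AA to match a
#' mixed-ancestry cohort), as the weighted average of per-population
#' frequencies.
#'
#' @param freqs named numeric vector of per-population allele frequencies.
#' @param weights named numeric vector of population proportions over the
#'   same names; must sum to 1 (tolerance 1e-9).
#' @return the mixed allele frequency.
#' @export
mixed_population_frequency <- function(freqs, weights) {
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("population weights must sum to 1", call. = FALSE)
  }
  if (is.null(names(weights)) || is.null(names(freqs))) {
    stopifnot(length(freqs) == length(weights))
    return(sum(freqs * weights))
  }
  missing_pop <- setdiff(names(weights), names(freqs))
  if (length(missing_pop)) {
    stop(sprintf("no frequency for population(s): %s",
                 paste(missing_pop, collapse = ", ")), call. = FALSE)
  }
  sum(freqs[names(weights)] * weights)
}

#' @describeIn mixed_population_frequency companion helper: mixed allele
#'   counts given per-population individual counts. Returns `allele_count`
#'   and `allele_number` for the pooled population (2 alleles per
#'   individual, counts rounded to integers).
#' @param n_individuals named numeric vector of per-population individual
#'   counts.
#' @export
mixed_population_counts <- function(freqs, n_individuals) {
  missing_pop <- setdiff(names(n_individuals), names(freqs))
  if (length(missing_pop)) {
    stop(sprintf("no frequency for population(s): %s",
                 paste(missing_pop, collapse = ", ")), call. = FALSE)
  }
  an <- 2 * sum(n_individuals)
  ac <- round(sum(2 * n_individuals * freqs[names(n_individuals)]))
  c(allele_count = as.integer(ac), allele_number = as.integer(an))
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Compare qualifying-variant burden between two gene panels
#'
#' Tests whether the number of participants carrying at least one hit
#' (e.g. at least one Key Qualifying variant) differs between two gene
#' panels, by a two-tailed Fisher exact test on participants with/without a
#' hit per panel. Because the panels may contain different numbers of genes,
#' an optional labeled correction (`"gene_count_rescale"`) rescales the
#' larger panel's hit count by the gene-count ratio (rounded half away from
#' zero) before testing; the plain uncorrected test is always computed
#' alongside and the applied correction is recorded in the result.
#'
#' @param panel_a_hits,panel_b_hits participants with >= 1 hit per panel.
#' @param n_a_genes,n_b_genes panel sizes (genes).
#' @param n_participants participants examined for each panel.
#' @param correction `"none"` or `"gene_count_rescale"`.
#' @return `fisher_result` with the applied correction recorded; when a
#'   correction is applied, the uncorrected result is attached as
#'   `$uncorrected`.
#' @export
panel_burden_comparison <- function(panel_a_hits, panel_b_hits,
                                    n_a_genes, n_b_genes, n_participants,
                                    correction = c("none",
                                                   "gene_count_rescale")) {
  correction <- match.arg(correction)
  stopifnot(panel_a_hits >= 0, panel_b_hits >= 0,
            panel_a_hits <= n_participants, panel_b_hits <= n_participants,
            n_a_genes > 0, n_b_genes > 0)
  plain <- fisher_exact(c(panel_a_hits, n_participants - panel_a_hits,
                          panel_b_hits, n_participants - panel_b_hits))
  if (correction == "none") return(plain)
  a <- panel_a_hits; b <- panel_b_hits
  if (n_a_genes > n_b_genes) {
    a <- min(n_participants, round_half_away(a * n_b_genes / n_a_genes))
  } else if (n_b_genes > n_a_genes) {
    b <- min(n_participants, round_half_away(b * n_a_genes / n_b_genes))
  }
  out <- fisher_exact(c(a, n_participants - a, b, n_participants - b))
  out$correction <- "gene_count_rescale"
  out$uncorrected <- plain
  out
}
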