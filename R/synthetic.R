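#' Synthetic cohort configuration
#'
#' Generative parameters for seeded cohorts with the statistical structure
#' the analysis assumes, used to exercise every stage without access to the
#' protected cohort data. Defaults mirror the study's composition: 80
#' participants, the 35-gene paroxysmal panel, a per-gene qualifying
#' occurrence rate of 0.04 (about 119 qualifying occurrences over 35 genes x
#' 80 participants), 26% of qualifying occurrences Key, 32% of Key
#' occurrences P/LP (the rest Clinical), and a mitochondrial variant rate of
#' 0.19 per participant.
#'
#' @param n_participants cohort size.
#' @param panels list of [gene_panel()] objects to simulate over.
#' @param per_gene_qualifying_rate probability a participant carries a
#'   qualifying occurrence in a given gene; a single value or a named vector
#'   per gene.
#' @param key_fraction probability a qualifying occurrence is Key.
#' @param plp_given_key probability a Key occurrence is Key via P/LP (the
#'   complement is Key via Clinical; a gene without panel phenotype codes
#'   falls back to P/LP).
#' @param af_lognormal_params `c(meanlog, sdlog)` of the rare allele
#'   frequency distribution (draws above the qualifying cutoff are
#'   resampled by inverse-CDF truncation).
#' @param novel_af_rate probability a qualifying variant is absent from the
#'   population reference (frequency recorded as absent, treated as 0).
#' @param phylop_mixture list with `conserved` and `nonconserved`
#'   `c(mean, sd)` pairs for the two conservation components.
#' @param noncoding_rate probability a participant carries a recorded
#'   non-coding (intronic) variant in a given gene.
#' @param mito list: `variants_per_participant` (Poisson rate),
#'   `heteroplasmy_absent_prob` (homoplasmic fraction; otherwise uniform
#'   5-99%), `domain_count_probs` (distribution of per-participant affected
#'   domain counts over 0..8), `clinvar_lp_prob`, `structure_exception_prob`.
#' @param seed integer seed; a fixed seed yields byte-identical output.
#'   Per-gene random streams are split off the seed by gene symbol, so
#'   adding a gene does not perturb other genes' draws.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 80,
                          panels = list(load_fixture("paroxysmal_panel")),
                          per_gene_qualifying_rate = 0.04,
                          key_fraction = 0.26,
                          plp_given_key = 0.32,
                          af_lognormal_params = c(meanlog = -9, sdlog = 2),
                          novel_af_rate = 0.15,
                          phylop_mixture = list(conserved = c(mean = 4, sd = 1.2),
                                                nonconserved = c(mean = 0.2, sd = 0.6)),
                          noncoding_rate = 0.05,
                          mito = list(variants_per_participant = 0.19,
                                      heteroplasmy_absent_prob = 0.6,
                                      domain_count_probs = c(0.25, 0.2, 0.15,
                                                             0.1, 0.1, 0.08,
                                                             0.06, 0.04, 0.02),
                                      clinvar_lp_prob = 0.05,
                                      structure_exception_prob = 0.05),
                          seed = 1L) {
  probs <- c(per_gene_qualifying_rate, key_fraction, plp_given_key,
             novel_af_rate, noncoding_rate)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_participants >= 0, length(panels) >= 1,
            abs(sum(mito$domain_count_probs) - 1) < 1e-9)
  structure(list(n_participants = as.integer(n_participants), panels = panels,
                 per_gene_qualifying_rate = per_gene_qualifying_rate,
                 key_fraction = key_fraction, plp_given_key = plp_given_key,
                 af_lognormal_params = af_lognormal_params,
                 novel_af_rate = novel_af_rate,
                 phylop_mixture = phylop_mixture,
                 noncoding_rate = noncoding_rate, mito = mito,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic 31-bit stream seed for (seed, label): polynomial string hash.
stream_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 2654435) %% 2147483647)
}

gene_rate <- function(config, gene) {
  r <- config$per_gene_qualifying_rate
  if (!is.null(names(r))) {
    if (!gene %in% names(r)) stop(sprintf("no rate for gene %s", gene))
    unname(r[gene])
  } else r
}

# Truncated lognormal below `upper` via inverse CDF.
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  pmax_u <- stats::plnorm(upper, meanlog, sdlog)
  u <- stats::runif(n, 0, pmax_u)
  pmin(stats::qlnorm(u, meanlog, sdlog), upper * (1 - 1e-12))
}

# ClinVar call multisets of size 1-5: majority P/LP or not, as requested.
draw_clinvar <- function(n, majority_plp) {
  vapply(seq_len(n), function(i) {
    size <- sample(1:5, 1)
    n_plp <- if (majority_plp[i]) {
      sample(ceiling(size / 2):size, 1)
    } else {
      if (size == 1) 0 else sample(0:(ceiling(size / 2) - 1L), 1)
    }
    calls <- c(sample(c("P", "LP"), n_plp, replace = TRUE),
               sample(c("VUS", "LB", "B"), size - n_plp, replace = TRUE))
    paste(sample(calls), collapse = ",")
  }, character(1))
}

#' Generate a synthetic cohort
#'
#' Draws an annotated variant table and a matching phenotype table from a
#' [cohort_config()]. Per participant and gene, a qualifying occurrence is
#' drawn at the configured rate; annotations (consequence, allele frequency,
#' conservation, ClinVar call mixture, carrier diagnoses, heteroplasmy,
#' domain counts) are drawn so that the qualification predicates recover the
#' configured rates. Output is deterministic under the config seed.
#'
#' @param config a [cohort_config()].
#' @return list with elements `variants` (canonical variant table) and
#'   `phenotypes` (phenotype table covering all participants).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  pts <- sprintf("S%03d", seq_len(n))
  diagnoses <- stats::setNames(vector("list", n), pts)
  tables <- list()
  for (panel in config$panels) {
    for (gene in panel$genes) {
      set.seed(stream_seed(config$seed, paste0("gene:", gene)))
      tab <- generate_gene_records(config, panel, gene, pts)
      if (!is.null(tab$diag_pts) && length(tab$diag_pts)) {
        for (p in tab$diag_pts) {
          diagnoses[[p]] <- union(diagnoses[[p]], tab$diag_code)
        }
      }
      tables[[length(tables) + 1L]] <- tab$records
    }
  }
  set.seed(stream_seed(config$seed, "mito"))
  mito <- generate_mito_records(config, pts)
  tables[[length(tables) + 1L]] <- mito$records
  variants <- do.call(rbind, tables)
  rownames(variants) <- NULL
  phenotypes <- data.frame(
    participant_id = pts,
    paroxysmal_diagnoses = vapply(diagnoses, function(d) {
      if (length(d)) paste(sort(d), collapse = ",") else NA_character_
    }, character(1), USE.NAMES = FALSE),
    mito_domains = mito$domain_labels,
    ancestry_label = rep("nfe", n),
    stringsAsFactors = FALSE
  )
  rownames(phenotypes) <- NULL
  list(variants = variants, phenotypes = phenotypes)
}

generate_gene_records <- function(config, panel, gene, pts) {
  n <- length(pts)
  rate <- gene_rate(config, gene)
  hit <- stats::runif(n) < rate
  nonc <- stats::runif(n) < config$noncoding_rate
  n_hit <- sum(hit)
  recs <- list()
  diag_pts <- character(0); diag_code <- NA_character_
  if (n_hit > 0) {
    is_key <- stats::runif(n_hit) < config$key_fraction
    gene_codes <- setdiff(panel$gene_phenotypes[[gene]], "CVS")
    can_clinical <- length(gene_codes) > 0
    via_plp <- is_key & (stats::runif(n_hit) < config$plp_given_key |
                           !can_clinical)
    via_clin <- is_key & !via_plp
    ml <- config$af_lognormal_params[[1]]; sl <- config$af_lognormal_params[[2]]
    af <- rlnorm_trunc(n_hit, ml, sl,
                       qualification_thresholds()$af_qualify_max)
    af[stats::runif(n_hit) < config$novel_af_rate] <- NA_real_
    cons <- config$phylop_mixture$conserved
    phylop <- pmax(1.5, stats::rnorm(n_hit, cons[[1]], cons[[2]]))
    lof <- via_plp & stats::runif(n_hit) < 0.3
    tab <- empty_variant_table(n_hit)
    tab$participant_id <- pts[hit]
    tab$gene <- gene
    tab$genome <- "nuclear"
    tab$variant_id <- sprintf("%s:v%03d", gene, seq_len(n_hit))
    tab$consequence <- ifelse(lof, "nonsense", "missense")
    tab$zygosity <- "het"
    tab$af_nfe <- af
    tab$af_afr <- af
    tab$af_global <- af
    tab$phylop <- phylop
    tab$mammal_match_pct <- NA_real_
    tab$splice_rf <- NA_real_
    tab$splice_ada <- NA_real_
    tab$clinvar_calls <- ifelse(via_plp & !lof, draw_clinvar(n_hit, via_plp),
                                ifelse(stats::runif(n_hit) < 0.4,
                                       draw_clinvar(n_hit, rep(FALSE, n_hit)),
                                       NA_character_))
    tab$lof_predicted <- lof
    tab$heteroplasmy_pct <- NA_real_
    tab$structure_exception <- FALSE
    tab$coseg_group <- NA_character_
    recs[[1]] <- tab
    if (any(via_clin)) {
      diag_code <- gene_codes[1]
      diag_pts <- pts[hit][via_clin]
    }
  }
  if (any(nonc)) {
    m <- sum(nonc)
    ncons <- config$phylop_mixture$nonconserved
    tab <- empty_variant_table(m)
    tab$participant_id <- pts[nonc]
    tab$gene <- gene
    tab$genome <- "nuclear"
    tab$variant_id <- sprintf("%s:nc%03d", gene, seq_len(m))
    tab$consequence <- "intronic"
    tab$zygosity <- "het"
    af <- stats::runif(m, 0, qualification_thresholds()$af_record_max)
    tab$af_nfe <- af; tab$af_afr <- af; tab$af_global <- af
    tab$phylop <- stats::rnorm(m, ncons[[1]], ncons[[2]])
    tab$mammal_match_pct <- NA_real_
    tab$splice_rf <- NA_real_; tab$splice_ada <- NA_real_
    tab$clinvar_calls <- NA_character_
    tab$lof_predicted <- FALSE
    tab$heteroplasmy_pct <- NA_real_
    tab$structure_exception <- FALSE
    tab$coseg_group <- NA_character_
    recs[[length(recs) + 1L]] <- tab
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_variant_table(0)
  list(records = records, diag_pts = diag_pts, diag_code = diag_code)
}

MITO_GENES <- c("ATP6", "COX1", "COX2", "COX3", "CYB", "ND1", "ND5",
                "TA", "TG", "TM", "TR", "TT")

generate_mito_records <- function(config, pts) {
  n <- length(pts)
  m <- config$mito
  domain_counts <- sample(0:8, n, replace = TRUE,
                          prob = m$domain_count_probs)
  domain_labels <- vapply(domain_counts, function(k) {
    if (k == 0) NA_character_ else
      paste(MITO_DOMAINS[seq_len(k)], collapse = ",")
  }, character(1))
  n_var <- stats::rpois(n, m$variants_per_participant)
  total <- sum(n_var)
  tab <- empty_variant_table(total)
  if (total > 0) {
    carrier <- rep(pts, n_var)
    tab$participant_id <- carrier
    tab$gene <- sample(MITO_GENES, total, replace = TRUE)
    tab$genome <- "mitochondrial"
    tab$variant_id <- sprintf("m.%d%s>%s",
                              sample(1000:16000, total, replace = TRUE),
                              sample(c("A", "C", "G", "T"), total, TRUE),
                              sample(c("A", "C", "G", "T"), total, TRUE))
    tab$consequence <- "missense"
    tab$zygosity <- "het"
    tab$af_nfe <- NA_real_; tab$af_afr <- NA_real_; tab$af_global <- NA_real_
    tab$phylop <- NA_real_; tab$mammal_match_pct <- NA_real_
    tab$splice_rf <- NA_real_; tab$splice_ada <- NA_real_
    het <- ifelse(stats::runif(total) < m$heteroplasmy_absent_prob, NA_real_,
                  stats::runif(total, 5, 99))
    tab$heteroplasmy_pct <- het
    lp <- stats::runif(total) < m$clinvar_lp_prob
    tab$clinvar_calls <- ifelse(lp, "LP", NA_character_)
    tab$lof_predicted <- FALSE
    tab$structure_exception <- stats::runif(total) < m$structure_exception_prob
    tab$coseg_group <- NA_character_
  }
  list(records = tab, domain_labels = domain_labels)
}

#' Generate a null two-panel cohort
#'
#' Builds two synthetic panels with identical per-gene generative rates and
#' draws one cohort over both, so any burden difference between the panels
#' is sampling noise. Used as the null for [panel_burden_comparison()]
#' calibration.
#'
#' @param config a [cohort_config()]; its `panels` entry is replaced by the
#'   two synthetic panels.
#' @param n_genes_a,n_genes_b panel sizes.
#' @return list with `variants`, `phenotypes`, `panel_a`, `panel_b`.
#' @export
generate_null_pair <- function(config, n_genes_a = 35, n_genes_b = 20) {
  panel_a <- synthetic_panel("null_a", n_genes_a, prefix = "A")
  panel_b <- synthetic_panel("null_b", n_genes_b, prefix = "B")
  config$panels <- list(panel_a, panel_b)
  out <- generate_cohort(config)
  out$panel_a <- panel_a
  out$panel_b <- panel_b
  out
}

#' @describeIn generate_null_pair a synthetic panel of `n` genes, each with
#'   a unique phenotype code (so Clinical matches never cross genes).
#' @param name,n,prefix panel name, size and gene-symbol prefix.
#' @export
synthetic_panel <- function(name, n, prefix = "G") {
  genes <- sprintf("%s%03d", prefix, seq_len(n))
  phen <- stats::setNames(lapply(genes, function(g) paste0("PH_", g)), genes)
  gene_panel(name, genes, phen)
}
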