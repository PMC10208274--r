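#' @keywords internal
"_PACKAGE"

# Controlled vocabularies used across the package.
CONSEQUENCES <- c(
  "missense", "nonsense", "frameshift", "inframe_indel",
  "splice_site_predicted", "synonymous", "utr", "intronic", "intergenic",
  "repeat_expansion", "structural_deletion", "structural_duplication"
)
ZYGOSITIES <- c("het", "hom", "hemi")
GENOMES <- c("nuclear", "mitochondrial")
CLINVAR_TOKENS <- c("P", "LP", "VUS", "LB", "B")
MITO_DOMAINS <- c(
  "neuromuscular", "neurodevelopmental", "neuropsychiatric", "functional",
  "endocrine", "immunological", "metabolic", "enzymological"
)

#' Column header of the canonical variant TSV dialect
#'
#' One row per participant x variant. Empty cells are absent values, never
#' zero. `clinvar_calls` holds comma-separated tokens among
#' `P, LP, VUS, LB, B`; `lof_predicted` and `structure_exception` are 0/1;
#' `heteroplasmy_pct` and `structure_exception` are meaningful only for
#' mitochondrial records.
#' @export
variant_table_columns <- function() {
  c(
    "participant_id", "gene", "genome", "variant_id", "consequence",
    "zygosity", "af_nfe", "af_afr", "af_global", "phylop",
    "mammal_match_pct", "splice_rf", "splice_ada", "clinvar_calls",
    "lof_predicted", "heteroplasmy_pct", "structure_exception", "coseg_group"
  )
}

phenotype_table_columns <- function() {
  c("participant_id", "paroxysmal_diagnoses", "mito_domains", "ancestry_label")
}

check_unit_interval <- function(x, name) {
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) {
    stop(sprintf("column '%s' outside [0, 1] at row(s) %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_percentage <- function(x, name) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop(sprintf("column '%s' outside [0, 100] at row(s) %s", name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_enum <- function(x, allowed, name, allow_na = FALSE) {
  bad <- which(!(x %in% allowed) & !(allow_na & is.na(x)))
  if (length(bad)) {
    stop(sprintf("column '%s' has invalid value(s) %s at row(s) %s", name,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

validate_variant_table <- function(x) {
  check_enum(x$genome, GENOMES, "genome")
  check_enum(x$consequence, CONSEQUENCES, "consequence")
  check_enum(x$zygosity, ZYGOSITIES, "zygosity")
  for (col in c("af_nfe", "af_afr", "af_global", "splice_rf", "splice_ada")) {
    check_unit_interval(x[[col]], col)
  }
  check_percentage(x$mammal_match_pct, "mammal_match_pct")
  check_percentage(x$heteroplasmy_pct, "heteroplasmy_pct")
  nuc <- x$genome == "nuclear"
  if (any(nuc & !is.na(x$heteroplasmy_pct))) {
    stop("heteroplasmy_pct present on nuclear record(s)", call. = FALSE)
  }
  if (any(nuc & !is.na(x$structure_exception) & x$structure_exception)) {
    stop("structure_exception set on nuclear record(s)", call. = FALSE)
  }
  tokens <- strsplit(x$clinvar_calls[!is.na(x$clinvar_calls)], ",", fixed = TRUE)
  bad_tok <- setdiff(trimws(unlist(tokens)), c(CLINVAR_TOKENS, ""))
  if (length(bad_tok)) {
    stop(sprintf("unknown ClinVar token(s): %s", paste(bad_tok, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

empty_variant_table <- function(n = 0) {
  data.frame(
    participant_id = character(n), gene = character(n),
    genome = character(n), variant_id = character(n),
    consequence = character(n), zygosity = character(n),
    af_nfe = numeric(n), af_afr = numeric(n), af_global = numeric(n),
    phylop = numeric(n), mammal_match_pct = numeric(n),
    splice_rf = numeric(n), splice_ada = numeric(n),
    clinvar_calls = character(n), lof_predicted = logical(n),
    heteroplasmy_pct = numeric(n), structure_exception = logical(n),
    coseg_group = character(n), stringsAsFactors = FALSE
  )
}

#' Read an annotated variant table
#'
#' Reads the canonical per-participant variant table, either from the TSV
#' dialect (see [variant_table_columns()]) or from a VCF whose INFO field
#' carries the annotation keys `GENOMAD_AF`-style keys, `PHYLOP`, `CLNSIG`,
#' `CSQ`, `SPLICE_RF`, `SPLICE_ADA` (and optionally `GENE`/`GENOME`).
#' Multi-sample VCF records are exploded to one row per carrier, with
#' zygosity derived from the genotype.
#'
#' Absent optional fields are `NA`, never zero-filled; validation rejects
#' allele frequencies outside `[0, 1]` and percentages outside `[0, 100]`,
#' reporting the offending row.
#'
#' @param path file to read.
#' @param dialect `"tsv"` (canonical) or `"vcf"`.
#' @return A data frame with the columns of [variant_table_columns()] (extra
#'   TSV columns, e.g. `coding_equivalent` for repeat/structural records, are
#'   preserved).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "vcf") return(read_variant_vcf(path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  missing_cols <- setdiff(variant_table_columns(), names(x))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("af_nfe", "af_afr", "af_global", "phylop", "mammal_match_pct",
                "splice_rf", "splice_ada", "heteroplasmy_pct")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  for (col in c("lof_predicted", "structure_exception")) {
    x[[col]] <- !is.na(x[[col]]) & x[[col]] %in% c("1", "TRUE", "true")
  }
  if ("coding_equivalent" %in% names(x)) {
    x$coding_equivalent <- !is.na(x$coding_equivalent) &
      x$coding_equivalent %in% c("1", "TRUE", "true")
  }
  validate_variant_table(x)
  x
}

#' Write an annotated variant table in the canonical TSV dialect
#'
#' Inverse of [read_variant_table()]: absent values become empty cells and
#' logical flags become 0/1, so a write/read round trip reproduces all
#' populated fields exactly.
#'
#' @param x variant table data frame.
#' @param path output file.
#' @export
write_variant_table <- function(x, path) {
  out <- x
  for (col in intersect(c("lof_predicted", "structure_exception",
                          "coding_equivalent"), names(out))) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_integer_, as.integer(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a participant phenotype table
#'
#' Columns: `participant_id`, `paroxysmal_diagnoses` (comma-separated non-CVS
#' paroxysmal diagnosis codes), `mito_domains` (comma-separated labels among
#' the eight mitochondrial clinical domains), `ancestry_label`.
#'
#' @param path file to read.
#' @return data frame with one row per participant.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  missing_cols <- setdiff(phenotype_table_columns(), names(x))
  if (length(missing_cols)) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  doms <- parse_token_sets(x$mito_domains)
  bad <- setdiff(unlist(doms), MITO_DOMAINS)
  if (length(bad)) {
    stop(sprintf("unknown mitochondrial domain label(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

# Comma-separated token cells -> list of character vectors ("" / NA -> empty).
parse_token_sets <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
  })
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m)   # single-record VCF
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(v, element = key)
  gt <- vcfR::extract.gt(v, element = "GT")
  n <- nrow(fix)
  gene <- info_get("GENE")
  genome <- info_get("GENOME")
  genome[is.na(genome)] <- "nuclear"
  rows <- list()
  for (i in seq_len(n)) {
    carriers <- character(0); zyg <- character(0)
    for (s in colnames(gt)) {
      g <- gt[i, s]
      if (is.na(g)) next
      alleles <- strsplit(g, "[/|]")[[1]]
      n_alt <- sum(alleles == "1")
      if (n_alt == 0) next
      carriers <- c(carriers, s)
      zyg <- c(zyg, if (length(alleles) == 1) "hemi"
               else if (n_alt == 2) "hom" else "het")
    }
    if (!length(carriers)) next
    vid <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i] else
      paste0(fix$CHROM[i], ":", fix$POS[i], fix$REF[i], ">", fix$ALT[i])
    clnsig <- info_get("CLNSIG")[i]
    if (!is.na(clnsig)) clnsig <- gsub("|", ",", clnsig, fixed = TRUE)
    tab <- empty_variant_table(length(carriers))
    tab$participant_id <- carriers
    tab$gene <- gene[i]
    tab$genome <- genome[i]
    tab$variant_id <- vid
    tab$consequence <- info_get("CSQ")[i]
    tab$zygosity <- zyg
    tab$af_nfe <- as.numeric(info_get("GNOMAD_AF_NFE")[i])
    tab$af_afr <- as.numeric(info_get("GNOMAD_AF_AFR")[i])
    tab$af_global <- as.numeric(info_get("GNOMAD_AF")[i])
    tab$phylop <- as.numeric(info_get("PHYLOP")[i])
    tab$mammal_match_pct <- NA_real_
    tab$splice_rf <- as.numeric(info_get("SPLICE_RF")[i])
    tab$splice_ada <- as.numeric(info_get("SPLICE_ADA")[i])
    tab$clinvar_calls <- clnsig
    tab$lof_predicted <- FALSE
    tab$heteroplasmy_pct <- NA_real_
    tab$structure_exception <- FALSE
    tab$coseg_group <- NA_character_
    rows[[length(rows) + 1L]] <- tab
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_variant_table(0)
  validate_variant_table(out)
  out
}

#' Construct a gene panel
#'
#' @param name panel identifier.
#' @param genes character vector of gene symbols (order preserved).
#' @param gene_phenotypes named list mapping gene symbol to a character vector
#'   of associated non-CVS paroxysmal phenotype codes.
#' @param mito_as_single_gene should mitochondrial records be pooled under the
#'   reserved symbol `"mtDNA"` when scoring?
#' @return object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes, gene_phenotypes = list(),
                       mito_as_single_gene = FALSE) {
  stopifnot(is.character(genes), !anyDuplicated(genes))
  extra <- setdiff(names(gene_phenotypes), genes)
  if (length(extra)) {
    stop(sprintf("gene_phenotypes for gene(s) not in panel: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  structure(list(name = name, genes = genes,
                 gene_phenotypes = gene_phenotypes,
                 mito_as_single_gene = isTRUE(mito_as_single_gene)),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel '%s': %d genes\n", x$name, length(x$genes)))
  cat(strwrap(paste(x$genes, collapse = ", "), width = 70, prefix = "  "),
      sep = "\n")
  invisible(x)
}

#' Load a packaged fixture
#'
#' Packaged transcriptions of the study's printed tables:
#' \describe{
#'   \item{`paroxysmal_panel`}{35 paroxysmal genes with their associated
#'     non-CVS paroxysmal phenotype codes, as a [gene_panel()].}
#'   \item{`dntr_panel`}{the 20 dominant neurotransmitter-receptor
#'     control genes.}
#'   \item{`table2_occurrences`}{one row per nuclear qualifying-variant
#'     occurrence per participant with its Key/Other label, zygosity and
#'     co-segregation group.}
#'   \item{`mtdna_table`}{the 15 mitochondrial variant records with
#'     heteroplasmy, clinical-domain count, ClinVar likely-pathogenic flag and
#'     secondary-structure conservation-exception flag. Domain labels are
#'     deterministic placeholders for the printed counts; the unnumbered
#'     large-deletion carrier has the reserved participant id `"unnumbered"`.}
#'   \item{`literature_points`}{per-gene counts of literature families with
#'     reported paroxysmal vomiting.}
#' }
#'
#' @param name fixture name.
#' @return a `gene_panel` or a data frame, depending on the fixture.
#' @export
load_fixture <- function(name = c("table2_occurrences", "mtdna_table",
                                  "literature_points", "paroxysmal_panel",
                                  "dntr_panel")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cvscan",
                      mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  switch(name,
    paroxysmal_panel = ,
    dntr_panel = {
      phen <- parse_token_sets(x$phenotypes)
      names(phen) <- x$gene
      gene_panel(name, x$gene, phen[lengths(phen) > 0],
                 mito_as_single_gene = name == "paroxysmal_panel")
    },
    table2_occurrences = {
      check_enum(x$category, c("key", "other"), "category")
      check_enum(x$zygosity, ZYGOSITIES, "zygosity")
      x
    },
    mtdna_table = {
      x$heteroplasmy_pct <- as.numeric(x$heteroplasmy_pct)
      x$n_domains <- as.integer(x$n_domains)
      x$clinvar_lp <- x$clinvar_lp == "1"
      x$structure_exception <- x$structure_exception == "1"
      x
    },
    literature_points = {
      x$literature_families <- as.integer(x$literature_families)
      x
    }
  )
}
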