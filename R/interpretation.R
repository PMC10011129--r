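#' Path to the bundled antigen-presentation ("escape") gene list
#'
#' A reconstructed list of 88 antigen processing and presentation genes
#' (KEGG pathway hsa04612 members plus ERAP1, ERAP2, IRF1, PDIA3, FAS and
#' MEX3B). The file is a synthetic reconstruction assembled from the public
#' pathway membership, shipped as a sensible default; analyses of real
#' cohorts should supply their own curated list via `escape_genes`.
#'
#' @return Path to a plain-text file, one gene symbol per line.
#' @export
default_escape_genes_file <- function() {
  system.file("extdata", "escape_genes_synthetic.txt",
              package = "immunodnds", mustWork = TRUE)
}

#' Read an escape-gene list (one symbol per line)
#' @param path File path; defaults to the bundled list.
#' @return Character vector of gene symbols.
#' @export
read_escape_genes <- function(path = default_escape_genes_file()) {
  genes <- trimws(readLines(path))
  genes[nzchar(genes) & !startsWith(genes, "#")]
}

#' Classify a patient's immune-escape status
#'
#' A patient is escaped+ if any nonsynonymous or truncating mutation
#' (missense, start loss, stop gain, stop loss, frameshift; splice
#' optionally) falls in a listed escape gene — synonymous mutations never
#' count — or if an HLA loss-of-heterozygosity / full-homozygosity flag is
#' set.
#'
#' @param mutations A `mutation_table` for one patient.
#' @param escape_genes Character vector of gene symbols (error if empty).
#' @param transcript2gene Optional named character vector mapping
#'   transcript IDs to gene symbols; when `NULL` the transcript IDs are
#'   matched against the gene list directly.
#' @param hla_loh,hla_homozygous Optional logical flags OR-ed into the
#'   call.
#' @param include_splice Count splice mutations as escape evidence
#'   (default FALSE).
#' @return List of class `escape_status`: `escaped`, `evidence` (data
#'   frame of gene/class pairs), `flags`.
#' @export
classify_escape <- function(mutations, escape_genes, transcript2gene = NULL,
                            hla_loh = NA, hla_homozygous = NA,
                            include_splice = FALSE) {
  if (!length(escape_genes)) stop("escape-gene list is empty")
  classes <- c("missense", "start_loss", "stop_gain", "stop_loss", "frameshift")
  if (include_splice) classes <- c(classes, "splice")
  gene <- if (is.null(transcript2gene)) mutations$transcript_id
          else unname(transcript2gene[mutations$transcript_id])
  hit <- !is.na(gene) & gene %in% escape_genes &
    mutations$consequence %in% classes
  evidence <- unique(data.frame(gene = gene[hit],
                                consequence = mutations$consequence[hit],
                                stringsAsFactors = FALSE))
  out <- list(
    escaped = nrow(evidence) > 0 || isTRUE(hla_loh) || isTRUE(hla_homozygous),
    evidence = evidence,
    flags = c(hla_loh = hla_loh, hla_homozygous = hla_homozygous))
  class(out) <- "escape_status"
  out
}

#' Fraction of nonsynonymous mutations removed by immune selection
#'
#' Under the neutral-expectation relation, an immune dN/dS of `x <= 1`
#' means a fraction `1 - x` of the expected antigenic nonsynonymous
#' mutations were removed; an immune dN/dS of 0.6 means 40% were removed.
#' Values above 1 indicate enrichment, not removal, and return 0 with the
#' `enrichment` flag set.
#'
#' @param immune_dnds Immune dN/dS point estimate.
#' @return List: `fraction` (0-1), `percent` (0-100), `enrichment`.
#' @export
edited_fraction <- function(immune_dnds) {
  if (is.null(immune_dnds) || !is.finite(immune_dnds))
    return(list(fraction = NA_real_, percent = NA_real_, enrichment = NA))
  if (immune_dnds < 0) stop("immune dN/dS cannot be negative")
  if (immune_dnds > 1)
    return(list(fraction = 0, percent = 0, enrichment = TRUE))
  list(fraction = 1 - immune_dnds, percent = 100 * (1 - immune_dnds),
       enrichment = FALSE)
}

#' Edited-neoantigen count from observed mutation counts
#'
#' The signed difference between the observed nonsynonymous count and the
#' neutral expectation (`n_s_obs` scaled by the mutation-rate ratio
#' `mu_ratio = L_N / L_S` of the same region):
#' `signed = n_a_obs - n_s_obs * mu_ratio`. Under immune editing the
#' signed value is negative; `removed = max(0, -signed)` is reported as
#' the (lower-bound) number of edited neoantigens.
#'
#' @param n_a_obs Observed nonsynonymous count in the region.
#' @param n_s_obs Observed synonymous count in the region (>= 1).
#' @param mu_ratio Neutral nonsynonymous:synonymous rate ratio for the
#'   region (`site_counts$mu_ratio`).
#' @return List: `signed`, `removed`, `neutral_expectation`.
#' @export
edited_neoantigens <- function(n_a_obs, n_s_obs, mu_ratio) {
  if (!is.finite(mu_ratio)) stop("mu_ratio is undefined for this region")
  if (n_s_obs < 1) stop("need at least one observed synonymous mutation")
  expectation <- n_s_obs * mu_ratio
  signed <- n_a_obs - expectation
  list(signed = signed, removed = max(0, -signed),
       neutral_expectation = expectation)
}

#' Immune-selection category and distance to neutrality
#'
#' Classifies an immune dN/dS estimate as `low` (< 0.82), `neutral`
#' (0.82-1.21 inclusive) or `high` (> 1.21), and reports the distance to
#' neutrality `d_immune = |value - 1|`. The default neutral band is
#' 0.82 to its (rounded) reciprocal 1.21; both bounds are configurable.
#'
#' @param immune_dnds Immune dN/dS point estimate (may be `NA`).
#' @param low Lower neutral bound (default 0.82).
#' @param high Upper neutral bound (default 1.21).
#' @return List of class `selection_call`: `immune_dnds`, `category`,
#'   `d_immune`.
#' @export
categorize_selection <- function(immune_dnds, low = 0.82, high = 1.21) {
  category <- if (is.null(immune_dnds) || !is.finite(immune_dnds)) "undefined"
  else if (immune_dnds < low) "low"
  else if (immune_dnds > high) "high"
  else "neutral"
  out <- list(immune_dnds = immune_dnds, category = category,
              d_immune = if (category == "undefined") NA_real_
                         else abs(immune_dnds - 1))
  class(out) <- "selection_call"
  out
}

#' Filter patient estimates by confidence-interval width
#'
#' Convenience filter mirroring the exclusion of patients whose immune
#' dN/dS confidence interval is too wide (few synonymous events) for
#' category-level analyses.
#'
#' @param patient_table Output of [run_patient()].
#' @param max_ci_width Maximum allowed `ci_high - ci_low` (default 5).
#' @param exclude_high Also drop patients with immune dN/dS above
#'   `high_threshold`.
#' @param high_threshold Upper neutral bound (default 1.21).
#' @return The filtered patient table.
#' @export
filter_patient_estimates <- function(patient_table, max_ci_width = 5,
                                     exclude_high = FALSE,
                                     high_threshold = 1.21) {
  width <- patient_table$ci_high - patient_table$ci_low
  keep <- patient_table$estimable & !is.na(width) & width <= max_ci_width
  if (exclude_high)
    keep <- keep & patient_table$immune_dnds <= high_threshold
  out <- patient_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
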