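#' Enumerate all overlapping 9-mer peptide windows of a CDS
#'
#' A protein of length P yields P - 8 overlapping 9-mers; each window spans
#' 27 nucleotides and steps by one codon (3 nt). Windows containing a stop
#' codon (internal or terminal) are excluded and reported in the
#' `"excluded_stop"` attribute.
#'
#' @param seq CDS sequence (length divisible by 3, >= 27 nt).
#' @param transcript_id Identifier attached to the output rows.
#' @return Data frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open nucleotide coordinates) and `peptide`.
#' @export
enumerate_9mers <- function(seq, transcript_id = "tx") {
  L <- nchar(seq)
  if (L %% 3 != 0) stop("CDS length must be divisible by 3")
  if (L < 27) stop("CDS too short for a 9-mer window (need >= 27 nt)")
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(seq), no.init.codon = TRUE)), "")[[1]]
  P <- length(aa)
  starts_aa <- 0:(P - 9)
  pep <- vapply(starts_aa, function(i) paste(aa[(i + 1):(i + 9)], collapse = ""),
                "")
  has_stop <- grepl("*", pep, fixed = TRUE)
  out <- data.frame(transcript_id = transcript_id,
                    start = starts_aa * 3L,
                    end = starts_aa * 3L + 27L,
                    peptide = pep,
                    stringsAsFactors = FALSE)[!has_stop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_stop") <- sum(has_stop)
  out
}

#' HLA class I genotype (up to six alleles)
#'
#' Normalizes and deduplicates a patient's class I alleles. Duplicated
#' alleles at a locus collapse to one entry with the locus flagged
#' homozygous (set semantics: a homozygous locus contributes its allele
#' once).
#'
#' @param alleles Character vector of 1-6 allele names in any common
#'   spelling (see [normalize_hla()]).
#' @return List of class `hla_genotype`: `alleles` (unique, normalized) and
#'   `homozygous` (named logical by locus A/B/C).
#' @export
hla_genotype <- function(alleles) {
  if (!length(alleles)) stop("empty HLA genotype")
  norm <- normalize_hla(alleles)
  if (anyNA(norm))
    stop("malformed HLA allele(s): ",
         paste(alleles[is.na(norm)], collapse = ", "))
  if (length(norm) > 6) stop("a class I genotype has at most 6 alleles")
  locus <- substr(norm, 1, 1)
  homozygous <- vapply(c("A", "B", "C"), function(l) {
    a <- norm[locus == l]
    length(a) >= 2 && length(unique(a)) == 1
  }, logical(1))
  out <- list(alleles = unique(norm), homozygous = homozygous)
  class(out) <- "hla_genotype"
  out
}

#' Build an immunopeptidome region set from a binder table
#'
#' Keeps binder records whose allele belongs to the genotype and whose
#' binding percentile rank is strictly below the threshold (default 0.5,
#' strong binders; 2.0 selects strong plus weak binders), projects the
#' surviving 27-nt windows to intervals, and merges them per transcript.
#'
#' @param binders A `binder_table`.
#' @param genotype An [hla_genotype()] (or character vector of alleles).
#' @param rank_threshold Strict upper bound on `percent_rank`
#'   (default 0.5).
#' @param label Label for the resulting region set.
#' @return A `target_regions` object. Empty (with a warning) when no
#'   binder survives; an empty genotype is an error.
#' @export
build_immunopeptidome <- function(binders, genotype, rank_threshold = 0.5,
                                  label = "immunopeptidome") {
  if (is.character(genotype)) genotype <- hla_genotype(genotype)
  if (!length(genotype$alleles)) stop("empty HLA genotype")
  keep <- binders$allele %in% genotype$alleles &
    binders$percent_rank < rank_threshold
  if (!any(keep)) {
    warning("no binders match the genotype at rank < ", rank_threshold)
    return(target_regions(label = label))
  }
  target_regions(binders[keep, c("transcript_id", "start", "end")],
                 label = label)
}

#' Keep binders whose peptide matches a positive-assay list
#'
#' A binder is retained iff its 9-mer is an exact substring of any
#' positive-assay peptide of length 9 or more; shorter assay peptides are
#' ignored with a warning.
#'
#' @param binders A `binder_table` with a `peptide` column.
#' @param assay_peptides Character vector of amino-acid strings.
#' @return The filtered `binder_table`.
#' @export
filter_by_positive_assays <- function(binders, assay_peptides) {
  assay_peptides <- toupper(assay_peptides)
  short <- nchar(assay_peptides) < 9
  if (any(short)) {
    warning(sum(short), " assay peptide(s) shorter than 9 aa ignored")
    assay_peptides <- assay_peptides[!short]
  }
  if (!length(assay_peptides)) {
    warning("no usable assay peptides; all binders removed")
    return(binders[0, , drop = FALSE])
  }
  if (anyNA(binders$peptide))
    stop("binder table has no peptide sequences; cannot apply assay filter")
  keep <- vapply(binders$peptide, function(p)
    any(grepl(p, assay_peptides, fixed = TRUE)), logical(1))
  out <- binders[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove transcripts below an expression threshold
#'
#' Keeps only transcripts expressed strictly above `threshold` FPKM
#' (default 1; set 0 to drop only non-expressed transcripts, as in
#' patient-specific filtering). Works on a binder table or a region set;
#' the failing transcripts are removed entirely.
#'
#' @param x A `binder_table` or `target_regions`.
#' @param expression Named numeric vector of FPKM by transcript.
#' @param threshold Strict lower bound (keep iff FPKM > threshold).
#' @param missing Policy for transcripts absent from `expression`:
#'   `"keep"` (default, with a warning) or `"drop"`.
#' @return Filtered object of the same class.
#' @export
filter_by_expression <- function(x, expression, threshold = 1,
                                 missing = c("keep", "drop")) {
  missing <- match.arg(missing)
  fpkm <- expression[x$transcript_id]
  unknown <- is.na(fpkm)
  if (any(unknown) && missing == "keep")
    warning(length(unique(x$transcript_id[unknown])),
            " transcript(s) missing from the expression table were kept")
  keep <- if (missing == "keep") unknown | (!unknown & fpkm > threshold)
          else !unknown & fpkm > threshold
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (inherits(x, "target_regions")) {
    out <- target_regions(as.data.frame(out), label = attr(x, "label"))
  }
  out
}
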