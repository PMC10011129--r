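#' Canonical somatic consequence classes
#'
#' The closed set of mutation classes used throughout the package. Annotation
#' vocabularies (VEP-style terms) are mapped onto this set by
#' [consequence_policy()]; unmapped terms become `"other"` and are retained
#' but flagged.
#'
#' @return Character vector of the nine canonical class names.
#' @export
mutation_classes <- function() {
  c("synonymous", "missense", "start_loss", "stop_gain", "stop_loss",
    "frameshift", "splice", "intronic", "other")
}

#' Consequence-mapping policy
#'
#' Maps annotation-consequence strings (VEP-style, but configurable because
#' vocabularies drift across annotator versions) onto the canonical
#' [mutation_classes()]. Canonical names map to themselves, so reading a
#' table the package wrote is the identity.
#'
#' @param extra Named character vector of additional `term -> class`
#'   mappings, merged over the defaults (later wins).
#' @return Named character vector: names are annotation terms (lower case),
#'   values are canonical classes.
#' @export
consequence_policy <- function(extra = NULL) {
  map <- c(
    synonymous_variant       = "synonymous",
    missense_variant         = "missense",
    start_lost               = "start_loss",
    start_loss               = "start_loss",
    stop_gained              = "stop_gain",
    stop_gain                = "stop_gain",
    stop_lost                = "stop_loss",
    stop_loss                = "stop_loss",
    frameshift_variant       = "frameshift",
    frameshift               = "frameshift",
    splice_acceptor_variant  = "splice",
    splice_donor_variant     = "splice",
    splice_region_variant    = "splice",
    splice                   = "splice",
    intron_variant           = "intronic",
    intronic                 = "intronic",
    synonymous               = "synonymous",
    missense                 = "missense",
    other                    = "other"
  )
  if (length(extra)) {
    stopifnot(!is.null(names(extra)), all(extra %in% mutation_classes()))
    map[tolower(names(extra))] <- unname(extra)
  }
  map
}

map_consequence <- function(terms, policy = consequence_policy()) {
  cls <- unname(policy[tolower(terms)])
  cls[is.na(cls)] <- "other"
  cls
}

#' Read a table of annotated somatic point mutations
#'
#' Reads a tab-separated mutation table (one row per mutation) with a header
#' naming sample, transcript, CDS position, reference allele, alternate
#' allele and consequence columns. Consequence strings are mapped through
#' the supplied policy; rows whose consequence is unknown are kept with
#' class `"other"` and `flagged = TRUE`. Rows failing record-level
#' validation (non-ACGT allele, `ref == alt`, non-positive CDS position)
#' are dropped and collected in the `"rejects"` attribute.
#'
#' @param path Path to a TSV file (or a connection).
#' @param columns Named character vector mapping the required roles
#'   `sample`, `transcript`, `cds_pos`, `ref`, `alt`, `consequence` to the
#'   column names present in the file.
#' @param policy Consequence map from [consequence_policy()].
#' @return A `data.frame` of class `mutation_table` with columns
#'   `sample_id`, `transcript_id`, `cds_pos`, `ref`, `alt`, `consequence`,
#'   `clonality`, `flagged`, and attribute `rejects` (a data.frame with a
#'   `reason` column, possibly empty).
#' @export
read_annotated_mutations <- function(path,
                                     columns = c(sample = "sample",
                                                 transcript = "transcript",
                                                 cds_pos = "cds_pos",
                                                 ref = "ref", alt = "alt",
                                                 consequence = "consequence"),
                                     policy = consequence_policy()) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  required <- c("sample", "transcript", "cds_pos", "ref", "alt", "consequence")
  missing_roles <- setdiff(required, names(columns))
  if (length(missing_roles))
    stop("column mapping is missing roles: ", paste(missing_roles, collapse = ", "))
  absent <- setdiff(unname(columns[required]), names(raw))
  if (length(absent))
    stop("mutation table is missing required column(s): ",
         paste(absent, collapse = ", "))
  df <- data.frame(
    sample_id     = raw[[columns[["sample"]]]],
    transcript_id = raw[[columns[["transcript"]]]],
    cds_pos       = suppressWarnings(as.integer(raw[[columns[["cds_pos"]]]])),
    ref           = toupper(raw[[columns[["ref"]]]]),
    alt           = toupper(raw[[columns[["alt"]]]]),
    consequence   = map_consequence(raw[[columns[["consequence"]]]], policy),
    stringsAsFactors = FALSE
  )
  df$clonality <- if ("clonality" %in% names(raw)) raw$clonality else "unknown"
  df$flagged <- df$consequence == "other"

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  is_snv <- !(df$consequence %in% c("frameshift", "intronic"))
  bad_allele <- is_snv & !(df$ref %in% bases & df$alt %in% bases)
  reason[bad_allele] <- "non-ACGT allele"
  same <- is_snv & !bad_allele & df$ref == df$alt
  reason[same] <- "ref equals alt"
  bad_pos <- is.na(df$cds_pos) | df$cds_pos < 1
  reason[bad_pos & is.na(reason)] <- "invalid CDS position"

  rejects <- cbind(df[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  class(out) <- c("mutation_table", class(out))
  out
}

#' Write a mutation table
#'
#' Writes the canonical TSV dialect that [read_annotated_mutations()] reads
#' back unchanged (round-trip identity on canonicalized tables).
#'
#' @param mutations A `mutation_table` (or compatible data.frame).
#' @param path Output path.
#' @export
write_annotated_mutations <- function(mutations, path) {
  out <- data.frame(sample = mutations$sample_id,
                    transcript = mutations$transcript_id,
                    cds_pos = mutations$cds_pos,
                    ref = mutations$ref, alt = mutations$alt,
                    consequence = mutations$consequence,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a merged target-region set
#'
#' A target-region set holds, per transcript, sorted non-overlapping
#' intervals in CDS nucleotide coordinates, 0-based half-open (BED
#' convention). Overlapping and bookended intervals are merged on
#' construction, so the representation is canonical: constructing from its
#' own rows is the identity.
#'
#' @param df Data frame with columns `transcript_id`, `start`, `end`.
#' @param label Optional label describing the region set.
#' @return A `data.frame` of class `target_regions`, sorted by transcript
#'   then start.
#' @export
target_regions <- function(df = data.frame(transcript_id = character(),
                                           start = integer(),
                                           end = integer()),
                           label = "") {
  stopifnot(all(c("transcript_id", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("target regions need 0 <= start < end")
  if (nrow(df)) {
    parts <- split(df, df$transcript_id)
    merged <- lapply(names(parts), function(tx) {
      ir <- IRanges::reduce(IRanges::IRanges(start = parts[[tx]]$start + 1L,
                                             end = parts[[tx]]$end))
      data.frame(transcript_id = tx,
                 start = IRanges::start(ir) - 1L,
                 end = IRanges::end(ir),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, merged)
    df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "label") <- label
  class(df) <- c("target_regions", "data.frame")
  df
}

#' Total length of a target-region set, in nucleotides
#' @param regions A `target_regions` object.
#' @return Integer total width.
#' @export
region_width <- function(regions) {
  if (!nrow(regions)) return(0L)
  sum(regions$end - regions$start)
}

#' Read transcript-coordinate target regions from BED text
#'
#' Three-or-more-column BED where column 1 is a transcript identifier and
#' columns 2-3 are 0-based half-open interval bounds within that
#' transcript's CDS. Intervals are merged per transcript; reading the
#' written output of [write_target_regions()] is the identity.
#'
#' @param path Path to a BED file.
#' @param label Optional label.
#' @return A `target_regions` object.
#' @export
read_target_regions <- function(path, label = basename(as.character(path)[1])) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(target_regions(label = label))
  fields <- strsplit(lines, "\t")
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("BED line ", short[1], " has fewer than 3 columns")
  tx <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad))
    stop("BED line ", bad[1], ": invalid interval (start must be < end, both >= 0)")
  target_regions(data.frame(transcript_id = tx, start = start, end = end,
                            stringsAsFactors = FALSE), label = label)
}

#' Write a target-region set as BED text
#' @param regions A `target_regions` object.
#' @param path Output path.
#' @export
write_target_regions <- function(regions, path) {
  utils::write.table(as.data.frame(regions)[, c("transcript_id", "start", "end")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read CDS sequences from a FASTA file
#'
#' Headers are truncated at the first whitespace to give the transcript ID.
#' Sequences are upper-cased. Duplicate IDs and empty sequences are errors.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of CDS sequences (alphabet A/C/G/T/N).
#' @export
read_transcript_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate transcript ID in FASTA: ",
         ids[duplicated(ids)][1])
  if (any(Biostrings::width(set) == 0))
    stop("empty sequence for transcript ", ids[Biostrings::width(set) == 0][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write CDS sequences to FASTA
#' @param transcripts Named character vector of sequences.
#' @param path Output path.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  set <- Biostrings::DNAStringSet(transcripts)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Normalize HLA class I allele names
#'
#' Collapses the common spellings of a 4-digit class I allele --
#' `"HLA-A*02:01"`, `"A*02:01"`, `"A02:01"`, `"A0201"` -- to the canonical
#' compact form `"A0201"`. Higher-resolution fields beyond 4 digits are
#' truncated. Strings that do not resolve to locus A/B/C plus four digits
#' return `NA`.
#'
#' @param x Character vector of allele names.
#' @return Character vector of normalized alleles (`NA` where malformed).
#' @export
normalize_hla <- function(x) {
  y <- toupper(trimws(x))
  y <- sub("^HLA-", "", y)
  y <- gsub("[*:]", "", y)
  ok <- grepl("^[ABC][0-9]{4}", y)
  out <- ifelse(ok, substr(y, 1, 5), NA_character_)
  out
}

#' Read a precomputed MHC-binder table
#'
#' Tab-separated with header columns `transcript`, `start`, `end`,
#' `allele`, `percent_rank` and optionally `peptide`. Windows are stored in
#' nucleotide space: each 9-mer peptide spans 27 nt, so `end - start` must
#' be 27. A peptide-space dialect (`end - start == 9`, amino-acid
#' coordinates) is accepted with `dialect = "peptide"` and converted on
#' read. Records with malformed alleles or wrong window widths are dropped
#' into the `"rejects"` attribute. No rank filtering happens here; that is
#' [build_immunopeptidome()]'s job.
#'
#' @param path Path to the TSV.
#' @param dialect `"nucleotide"` (default) or `"peptide"`.
#' @return Data frame of class `binder_table` with columns `transcript_id`,
#'   `start`, `end`, `allele`, `percent_rank`, `peptide` and a `rejects`
#'   attribute.
#' @export
read_binder_table <- function(path, dialect = c("nucleotide", "peptide")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "start", "end", "allele", "percent_rank")
  absent <- setdiff(need, names(raw))
  if (length(absent))
    stop("binder table is missing required column(s): ",
         paste(absent, collapse = ", "))
  df <- data.frame(
    transcript_id = raw$transcript,
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    allele = normalize_hla(raw$allele),
    percent_rank = as.numeric(raw$percent_rank),
    peptide = if ("peptide" %in% names(raw)) toupper(raw$peptide) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (dialect == "peptide") {
    df$start <- df$start * 3L
    df$end <- df$end * 3L
  }
  reason <- rep(NA_character_, nrow(df))
  reason[is.na(df$allele)] <- "malformed allele"
  wrong_width <- is.na(reason) & (df$end - df$start != 27L)
  reason[wrong_width] <- "window is not 27 nt (9 aa)"
  reason[is.na(reason) & (is.na(df$percent_rank) | df$percent_rank < 0)] <-
    "invalid percent_rank"
  rejects <- cbind(df[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  class(out) <- c("binder_table", class(out))
  out
}

#' Write a binder table
#' @param binders A `binder_table` data frame.
#' @param path Output path.
#' @export
write_binder_table <- function(binders, path) {
  out <- data.frame(transcript = binders$transcript_id,
                    start = binders$start, end = binders$end,
                    allele = binders$allele,
                    percent_rank = binders$percent_rank,
                    peptide = binders$peptide,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript expression table
#'
#' Tab-separated with header columns `transcript` and `fpkm`.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of FPKM values.
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript", "fpkm") %in% names(raw)))
    stop("expression table needs columns 'transcript' and 'fpkm'")
  stats::setNames(as.numeric(raw$fpkm), raw$transcript)
}
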