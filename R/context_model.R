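BASES <- c("A", "C", "G", "T")

# standard nuclear code; named by codon, stops are "*"
genetic_code <- function() Biostrings::GENETIC_CODE

#' All 192 trinucleotide substitution classes
#'
#' 64 trinucleotide contexts (upstream base, reference base, downstream
#' base) times the 3 possible alternative middle bases.
#'
#' @return Data frame with columns `context` (3-mer) and `alt`, 192 rows in
#'   a fixed lexicographic order.
#' @export
context_classes <- function() {
  ctx <- expand.grid(up = BASES, ref = BASES, down = BASES,
                     stringsAsFactors = FALSE)
  ctx <- ctx[order(ctx$up, ctx$ref, ctx$down), ]
  rows <- lapply(seq_len(nrow(ctx)), function(i) {
    alts <- setdiff(BASES, ctx$ref[i])
    data.frame(context = paste0(ctx$up[i], ctx$ref[i], ctx$down[i]),
               alt = alts, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

class_key <- function(context, alt) paste(context, alt, sep = ">")

#' Enumerate and classify all single-nucleotide changes in a CDS
#'
#' For every CDS position except the first and last (which lack an
#' in-CDS flanking base for the trinucleotide context), classifies the 3
#' possible substitutions as synonymous or nonsynonymous under the standard
#' genetic code in the codon frame. Changes that create or destroy a stop
#' codon are nonsynonymous and additionally marked `stop_relevant`.
#' Positions whose context window contains an N are skipped and counted in
#' the `"skipped_sites"` attribute.
#'
#' @param seq A CDS sequence (character scalar, A/C/G/T/N), length >= 3 and
#'   divisible by 3.
#' @return Data frame with one row per classified change: `pos` (1-based
#'   CDS position), `context`, `ref`, `alt`, `key` (context class),
#'   `impact` (`"synonymous"`/`"nonsynonymous"`) and `stop_relevant`;
#'   attribute `skipped_sites` gives the number of positions skipped for N
#'   context.
#' @export
enumerate_site_classes <- function(seq) {
  L <- nchar(seq)
  if (L < 3 || L %% 3 != 0)
    stop("CDS length must be >= 3 and divisible by 3")
  s <- strsplit(seq, "")[[1]]
  pos <- 2:(L - 1)
  ctx_ok <- s[pos - 1] %in% BASES & s[pos] %in% BASES & s[pos + 1] %in% BASES
  skipped <- sum(!ctx_ok)
  pos <- pos[ctx_ok]
  if (!length(pos)) {
    out <- data.frame(pos = integer(), context = character(),
                      ref = character(), alt = character(),
                      key = character(), impact = character(),
                      stop_relevant = logical())
    attr(out, "skipped_sites") <- skipped
    return(out)
  }
  ref <- s[pos]
  context <- paste0(s[pos - 1], ref, s[pos + 1])
  # 3 alternative bases per position, vectorized over an n x 3 layout
  alt_mat <- rbind(
    ifelse(ref == "A", "C", "A"),
    ifelse(ref %in% c("A", "C"), "G", "C"),
    ifelse(ref == "T", "G", "T")
  )
  n <- length(pos)
  pos3 <- rep(pos, each = 3)
  ref3 <- rep(ref, each = 3)
  ctx3 <- rep(context, each = 3)
  alt3 <- as.vector(alt_mat)

  codon_idx <- (pos3 - 1L) %/% 3L        # 0-based codon
  offset <- (pos3 - 1L) %% 3L            # 0-based within codon
  c1 <- s[codon_idx * 3L + 1L]
  c2 <- s[codon_idx * 3L + 2L]
  c3 <- s[codon_idx * 3L + 3L]
  codon <- paste0(c1, c2, c3)
  m1 <- ifelse(offset == 0L, alt3, c1)
  m2 <- ifelse(offset == 1L, alt3, c2)
  m3 <- ifelse(offset == 2L, alt3, c3)
  mutated <- paste0(m1, m2, m3)

  gc <- genetic_code()
  aa_ref <- unname(gc[codon])
  aa_alt <- unname(gc[mutated])
  codon_ok <- !is.na(aa_ref) & !is.na(aa_alt)  # N elsewhere in the codon
  impact <- ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous")
  stop_relevant <- (aa_ref == "*") != (aa_alt == "*")

  out <- data.frame(pos = pos3, context = ctx3, ref = ref3, alt = alt3,
                    key = class_key(ctx3, alt3), impact = impact,
                    stop_relevant = stop_relevant,
                    stringsAsFactors = FALSE)[codon_ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_sites") <- skipped
  out
}

#' Enumerate classified changes for a set of transcripts
#'
#' Convenience wrapper over [enumerate_site_classes()] that adds a
#' `transcript_id` column and concatenates. The result is the site universe
#' used by rate estimation and site counting; compute it once and reuse.
#'
#' @param transcripts Named character vector of CDS sequences.
#' @return Data frame of classified changes across all transcripts.
#' @export
enumerate_transcriptome <- function(transcripts) {
  stopifnot(!is.null(names(transcripts)))
  parts <- lapply(names(transcripts), function(tx) {
    e <- enumerate_site_classes(transcripts[[tx]])
    if (nrow(e)) cbind(transcript_id = tx, e, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# logical index of enumerated changes whose 0-based position lies in regions
in_regions <- function(enum, regions) {
  if (!nrow(enum)) return(logical(0))
  if (!nrow(regions)) return(rep(FALSE, nrow(enum)))
  inside <- rep(FALSE, nrow(enum))
  for (tx in unique(regions$transcript_id)) {
    r <- regions[regions$transcript_id == tx, , drop = FALSE]
    sel <- which(enum$transcript_id == tx)
    if (!length(sel)) next
    p0 <- enum$pos[sel] - 1L
    idx <- findInterval(p0, r$start)
    inside[sel] <- idx > 0 & p0 < r$end[pmax(idx, 1L)]
  }
  inside
}

availability_by_class <- function(enum) {
  cls <- context_classes()
  keys <- class_key(cls$context, cls$alt)
  counts <- table(factor(enum$key, levels = keys))
  data.frame(context = cls$context, alt = cls$alt,
             availability = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Estimate relative per-class substitution rates (192-class model)
#'
#' Estimates the relative rate of each of the 192 trinucleotide
#' substitution classes from observed mutations, as observed count divided
#' by the number of available sites of that class in the estimation region,
#' then normalized so that the availability-weighted mean rate is 1.
#' The estimation set defaults to all single-nucleotide substitutions
#' supplied (synonymous and nonsynonymous); `subset = "synonymous"`
#' restricts to synonymous mutations for a purer neutrality assumption at
#' the cost of fewer counts. Zero-count classes get rate 0 unless a
#' pseudocount is requested.
#'
#' @param mutations A `mutation_table` restricted by the caller to the
#'   estimation region (typically OFF-target mutations).
#' @param transcripts Named character vector of CDS sequences.
#' @param regions Optional `target_regions` giving the estimation region;
#'   `NULL` means the full classified CDS space of `transcripts`.
#' @param subset `"all"` (default) or `"synonymous"`.
#' @param pseudocount Added to every class's observed count (default 0).
#' @param enum Optional precomputed [enumerate_transcriptome()] result.
#' @return Data frame of class `context_rate_model` with columns `context`,
#'   `alt`, `availability`, `observed`, `rate`.
#' @export
estimate_context_rates <- function(mutations, transcripts, regions = NULL,
                                   subset = c("all", "synonymous"),
                                   pseudocount = 0, enum = NULL) {
  subset <- match.arg(subset)
  if (is.null(enum)) enum <- enumerate_transcriptome(transcripts)
  if (!is.null(regions)) enum <- enum[in_regions(enum, regions), , drop = FALSE]
  avail <- availability_by_class(enum)

  snv_classes <- c("synonymous", "missense", "start_loss", "stop_gain", "stop_loss")
  if (subset == "synonymous") snv_classes <- "synonymous"
  mut <- mutations[mutations$consequence %in% snv_classes, , drop = FALSE]
  keys <- classify_mutations(mut, transcripts)
  keys <- keys[!is.na(keys)]
  if (!length(keys) && pseudocount == 0)
    stop("cannot estimate spectrum: no usable mutations in the estimation set")
  lev <- class_key(avail$context, avail$alt)
  observed <- as.integer(table(factor(keys, levels = lev)))

  if (any(observed > 0 & avail$availability == 0))
    stop("internal consistency error: observed mutations in a class with zero available sites")

  obs <- observed + pseudocount
  rate <- ifelse(avail$availability > 0, obs / avail$availability, 0)
  w <- sum(rate * avail$availability) / sum(avail$availability)
  if (w <= 0) stop("cannot estimate spectrum: all observed rates are zero")
  model <- data.frame(context = avail$context, alt = avail$alt,
                      availability = avail$availability,
                      observed = observed, rate = rate / w,
                      stringsAsFactors = FALSE)
  class(model) <- c("context_rate_model", "data.frame")
  model
}

#' Uniform-rate model (no context correction)
#'
#' All 192 classes get rate 1; site counting then reduces to naive counting
#' of synonymous and nonsynonymous changes.
#'
#' @param transcripts Named character vector of CDS sequences.
#' @param regions Optional estimation region for the availability column.
#' @param enum Optional precomputed enumeration.
#' @return A `context_rate_model`.
#' @export
uniform_rate_model <- function(transcripts = NULL, regions = NULL, enum = NULL) {
  if (is.null(enum)) {
    enum <- if (is.null(transcripts)) NULL else enumerate_transcriptome(transcripts)
  }
  if (!is.null(enum) && !is.null(regions))
    enum <- enum[in_regions(enum, regions), , drop = FALSE]
  avail <- if (is.null(enum)) {
    cls <- context_classes()
    data.frame(context = cls$context, alt = cls$alt, availability = 1L)
  } else availability_by_class(enum)
  model <- data.frame(context = avail$context, alt = avail$alt,
                      availability = avail$availability,
                      observed = NA_integer_, rate = 1,
                      stringsAsFactors = FALSE)
  class(model) <- c("context_rate_model", "data.frame")
  model
}

# map each mutation to its 192-class key using the transcript sequence;
# NA where not classifiable (edge position, context N, transcript unknown,
# or ref mismatch with the sequence)
classify_mutations <- function(mutations, transcripts) {
  n <- nrow(mutations)
  keys <- rep(NA_character_, n)
  if (!n) return(keys)
  for (tx in unique(mutations$transcript_id)) {
    if (!tx %in% names(transcripts)) next
    s <- strsplit(transcripts[[tx]], "")[[1]]
    L <- length(s)
    sel <- which(mutations$transcript_id == tx)
    p <- mutations$cds_pos[sel]
    ok <- p >= 2 & p <= L - 1
    okp <- sel[ok]
    pp <- p[ok]
    ctx <- paste0(s[pp - 1], s[pp], s[pp + 1])
    valid <- s[pp] == mutations$ref[okp] &
      !grepl("N", ctx, fixed = TRUE) &
      mutations$alt[okp] %in% BASES
    keys[okp[valid]] <- class_key(ctx[valid], mutations$alt[okp][valid])
  }
  keys
}

#' Context-weighted expected site counts for a region set
#'
#' Sums the model rate over every classified change whose position falls in
#' the region set: nonsynonymous changes contribute to `L_N`, synonymous to
#' `L_S`. `mu_ratio = L_N / L_S` is the neutral expectation for the ratio
#' of nonsynonymous to synonymous mutation counts in that region. With
#' uniform rates this reduces to naive change counting.
#'
#' @param regions A `target_regions` object (or `NULL` for the full
#'   classified CDS space).
#' @param transcripts Named character vector of CDS sequences.
#' @param model A `context_rate_model`.
#' @param enum Optional precomputed enumeration.
#' @return List of class `site_counts`: `L_N`, `L_S`, `mu_ratio`,
#'   `degenerate` (TRUE when `L_S` is 0 and downstream dN/dS is undefined).
#' @export
compute_site_counts <- function(regions, transcripts, model, enum = NULL) {
  if (is.null(enum)) enum <- enumerate_transcriptome(transcripts)
  if (!is.null(regions)) enum <- enum[in_regions(enum, regions), , drop = FALSE]
  lev <- class_key(model$context, model$alt)
  r <- model$rate[match(enum$key, lev)]
  r[is.na(r)] <- 0
  L_N <- sum(r[enum$impact == "nonsynonymous"])
  L_S <- sum(r[enum$impact == "synonymous"])
  out <- list(L_N = L_N, L_S = L_S,
              mu_ratio = if (L_S > 0) L_N / L_S else NA_real_,
              degenerate = L_S <= 0)
  class(out) <- "site_counts"
  out
}

#' Write a context-rate model as a 192-row TSV for audit
#' @param model A `context_rate_model`.
#' @param path Output path.
#' @export
write_rate_model <- function(model, path) {
  utils::write.table(as.data.frame(model), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a context-rate model written by [write_rate_model()]
#' @param path Path to the TSV.
#' @return A `context_rate_model`.
#' @export
read_rate_model <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("context", "alt", "availability", "rate")
  if (!all(need %in% names(df)))
    stop("rate-model table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) != 192) stop("rate-model table must have exactly 192 rows")
  if (!"observed" %in% names(df)) df$observed <- NA_integer_
  df <- df[, c("context", "alt", "availability", "observed", "rate")]
  class(df) <- c("context_rate_model", "data.frame")
  df
}
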