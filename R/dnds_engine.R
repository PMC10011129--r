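#' Analysis configuration for immune dN/dS runs
#'
#' Bundles the knobs shared by [run_cohort()] and [run_patient()].
#'
#' @param mode `"exonic-only"` (default for patient-level runs) or
#'   `"exonic-intronic"`, which averages the OFF-target synonymous per-site
#'   rate with the intronic per-base rate before computing OFF-dN/dS.
#' @param nonsyn_classes Mutation classes counted as nonsynonymous.
#'   Default: missense plus truncating substitutions (start loss, stop
#'   gain, stop loss). Frameshift and splice events can be added but are
#'   excluded by default (a frameshift is not a single-nucleotide
#'   substitution).
#' @param min_on_mutations Cohort-level exclusion: groups with fewer than
#'   this many ON-target mutations are reported as not estimable
#'   (default 10).
#' @param min_on_synonymous Patient-level exclusion: patients with fewer
#'   than this many ON-target synonymous mutations are reported as not
#'   estimable (default 1; 2-4 for sensitivity analyses).
#' @param exclude_transcripts Transcripts (e.g. driver genes) whose
#'   mutations are removed before any counting.
#' @param spectrum_subset Passed to [estimate_context_rates()]: `"all"` or
#'   `"synonymous"`.
#' @param intronic_averaging `"rate-averaged"` (default) averages the
#'   intronic and OFF-synonymous per-base rates in exonic-intronic mode;
#'   `"off-only"` ignores intronic mutations even in that mode.
#' @return List of class `dnds_config`.
#' @export
dnds_config <- function(mode = c("exonic-only", "exonic-intronic"),
                        nonsyn_classes = c("missense", "start_loss",
                                           "stop_gain", "stop_loss"),
                        min_on_mutations = 10L,
                        min_on_synonymous = 1L,
                        exclude_transcripts = character(),
                        spectrum_subset = c("all", "synonymous"),
                        intronic_averaging = c("rate-averaged", "off-only")) {
  out <- list(mode = match.arg(mode),
              nonsyn_classes = nonsyn_classes,
              min_on_mutations = as.integer(min_on_mutations),
              min_on_synonymous = as.integer(min_on_synonymous),
              exclude_transcripts = exclude_transcripts,
              spectrum_subset = match.arg(spectrum_subset),
              intronic_averaging = match.arg(intronic_averaging))
  class(out) <- "dnds_config"
  out
}

#' Count mutations inside and outside a target-region set
#'
#' A substitution is ON-target iff its transcript's interval set contains
#' its 0-based CDS position (`cds_pos - 1`); all other coding
#' substitutions are OFF-target. Intronic mutations are tallied
#' separately; classes outside the synonymous/nonsynonymous policy
#' (frameshift, splice, other by default) are excluded from the N/S
#' counts. Mutations beyond the CDS length are rejected when CDS lengths
#' are available.
#'
#' @param mutations A `mutation_table`.
#' @param regions A `target_regions` object (the ON target).
#' @param nonsyn_classes Classes counted as nonsynonymous.
#' @param cds_lengths Optional named integer vector for bounds checking.
#' @return List of class `mutation_counts`: `n_N_on`, `n_S_on`, `n_N_off`,
#'   `n_S_off`, `n_intronic`, `n_excluded`, and attribute `rejects`.
#' @export
count_mutations <- function(mutations, regions,
                            nonsyn_classes = c("missense", "start_loss",
                                               "stop_gain", "stop_loss"),
                            cds_lengths = NULL) {
  keep <- rep(TRUE, nrow(mutations))
  if (!is.null(cds_lengths)) {
    L <- cds_lengths[mutations$transcript_id]
    keep <- is.na(L) | mutations$consequence == "intronic" | mutations$cds_pos <= L
  }
  rejects <- mutations[!keep, , drop = FALSE]
  mutations <- mutations[keep, , drop = FALSE]

  is_syn <- mutations$consequence == "synonymous"
  is_non <- mutations$consequence %in% nonsyn_classes
  is_intr <- mutations$consequence == "intronic"
  on <- mutation_in_regions(mutations, regions)

  out <- list(n_N_on = sum(is_non & on),
              n_S_on = sum(is_syn & on),
              n_N_off = sum(is_non & !on),
              n_S_off = sum(is_syn & !on),
              n_intronic = sum(is_intr),
              n_excluded = sum(!(is_syn | is_non | is_intr)))
  attr(out, "rejects") <- rejects
  class(out) <- "mutation_counts"
  out
}

# TRUE where mutation's 0-based position lies inside its transcript's intervals
mutation_in_regions <- function(mutations, regions) {
  n <- nrow(mutations)
  on <- rep(FALSE, n)
  if (!n || !nrow(regions)) return(on)
  for (tx in intersect(unique(mutations$transcript_id),
                       unique(regions$transcript_id))) {
    r <- regions[regions$transcript_id == tx, , drop = FALSE]
    sel <- which(mutations$transcript_id == tx)
    p0 <- mutations$cds_pos[sel] - 1L
    idx <- findInterval(p0, r$start)
    on[sel] <- idx > 0 & p0 < r$end[pmax(idx, 1L)]
  }
  on
}

#' Point estimate and 95% CI for dN/dS from counts and site counts
#'
#' `dN/dS = (n_N / L_N) / (n_S / L_S)`. The confidence interval is the
#' Katz log-ratio normal approximation,
#' `exp(log(value) +/- 1.96 * sqrt(1/n_N + 1/n_S))`. The estimate is
#' undefined when `n_S = 0` or the site counts are degenerate
#' (`L_S = 0` or `L_N = 0`). With `n_N = 0` the value is 0 and the CI is
#' one-sided (lower bound 0, upper bound `NA`).
#'
#' @param n_N,n_S Observed nonsynonymous / synonymous mutation counts.
#' @param sites A `site_counts` object for the same region.
#' @param conf_z Normal quantile for the interval (default 1.96 for 95%).
#' @return List of class `dnds_estimate`: `value`, `ci_low`, `ci_high`,
#'   `n_N`, `n_S`, `defined`.
#' @export
compute_dnds <- function(n_N, n_S, sites, conf_z = 1.96) {
  est <- list(value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n_N = n_N, n_S = n_S, defined = FALSE)
  class(est) <- "dnds_estimate"
  if (sites$degenerate || sites$L_N <= 0 || n_S == 0) return(est)
  rate_N <- n_N / sites$L_N
  rate_S <- n_S / sites$L_S
  est$value <- rate_N / rate_S
  est$defined <- TRUE
  if (n_N == 0) {
    est$ci_low <- 0
    est$ci_high <- NA_real_
  } else {
    se <- sqrt(1 / n_N + 1 / n_S)
    est$ci_low <- est$value * exp(-conf_z * se)
    est$ci_high <- est$value * exp(conf_z * se)
  }
  est
}

#' Immune dN/dS: the ratio of ON-target to OFF-target dN/dS
#'
#' The CI propagates all four counts on the log scale:
#' `exp(log(value) +/- 1.96 * sqrt(1/n_N_on + 1/n_S_on + 1/n_N_off +
#' 1/n_S_off))`.
#'
#' @param on,off `dnds_estimate` objects for the ON and OFF regions.
#' @param conf_z Normal quantile (default 1.96).
#' @return A `dnds_estimate` for the ratio; `n_N`/`n_S` carry the ON
#'   counts.
#' @export
compute_immune_dnds <- function(on, off, conf_z = 1.96) {
  est <- list(value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              n_N = on$n_N, n_S = on$n_S, defined = FALSE)
  class(est) <- "dnds_estimate"
  if (!isTRUE(on$defined) || !isTRUE(off$defined) || off$value <= 0) return(est)
  est$value <- on$value / off$value
  est$defined <- TRUE
  if (on$n_N == 0) {
    est$ci_low <- 0
    est$ci_high <- NA_real_
  } else {
    se <- sqrt(1 / on$n_N + 1 / on$n_S + 1 / off$n_N + 1 / off$n_S)
    est$ci_low <- est$value * exp(-conf_z * se)
    est$ci_high <- est$value * exp(conf_z * se)
  }
  est
}

#' OFF-target dN/dS with the intronic background correction
#'
#' In exonic-intronic mode the per-base intronic mutation rate
#' (`n_intronic / intronic_length`) is averaged (arithmetic mean) with the
#' OFF-target synonymous per-site rate, and OFF-dN/dS is recomputed with
#' the averaged rate in the denominator. The CI uses the observed OFF
#' counts (the averaging changes the point estimate, not the counting
#' uncertainty model).
#'
#' @param counts A `mutation_counts` object.
#' @param off_sites `site_counts` for the OFF region.
#' @param intronic_length Total intronic length in bases.
#' @param conf_z Normal quantile (default 1.96).
#' @return A `dnds_estimate` for the corrected OFF-dN/dS.
#' @export
apply_intronic_correction <- function(counts, off_sites, intronic_length,
                                      conf_z = 1.96) {
  if (intronic_length <= 0) {
    if (counts$n_intronic > 0)
      stop("intronic mutations present but intronic_length is 0")
    return(compute_dnds(counts$n_N_off, counts$n_S_off, off_sites, conf_z))
  }
  est <- compute_dnds(counts$n_N_off, counts$n_S_off, off_sites, conf_z)
  if (!est$defined) return(est)
  r_intron <- counts$n_intronic / intronic_length
  r_syn <- counts$n_S_off / off_sites$L_S
  r_bg <- mean(c(r_intron, r_syn))
  scale <- r_syn / r_bg
  est$value <- est$value * scale
  if (counts$n_N_off > 0) {
    est$ci_low <- est$ci_low * scale
    est$ci_high <- est$ci_high * scale
  }
  est
}

#' Complement of a region set within the full CDS space
#'
#' @param regions A `target_regions` object.
#' @param transcripts Named character vector of CDS sequences; every
#'   transcript contributes its full `[0, length)` span.
#' @return A `target_regions` object covering everything not in `regions`.
#' @export
complement_regions <- function(regions, transcripts) {
  rows <- lapply(names(transcripts), function(tx) {
    L <- nchar(transcripts[[tx]])
    r <- regions[regions$transcript_id == tx, , drop = FALSE]
    full <- IRanges::IRanges(start = 1L, end = L)
    if (nrow(r)) {
      used <- IRanges::IRanges(start = r$start + 1L, end = r$end)
      gap <- IRanges::setdiff(full, used)
    } else gap <- full
    if (!length(gap)) return(NULL)
    data.frame(transcript_id = tx, start = IRanges::start(gap) - 1L,
               end = IRanges::end(gap), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(transcript_id = character(),
                                    start = integer(), end = integer())
  target_regions(df, label = paste0("complement(", attr(regions, "label"), ")"))
}

immune_result <- function(on, off, immune, counts, sites_on, sites_off,
                          scope, sample_id = NA_character_,
                          estimable = TRUE, reason = NA_character_) {
  out <- list(on = on, off = off, immune = immune, counts = counts,
              sites_on = sites_on, sites_off = sites_off, scope = scope,
              sample_id = sample_id, estimable = estimable, reason = reason)
  class(out) <- "immune_dnds_result"
  out
}

#' @export
print.immune_dnds_result <- function(x, ...) {
  cat(sprintf("immune dN/dS result (%s%s)\n", x$scope,
              if (!is.na(x$sample_id)) paste0(", ", x$sample_id) else ""))
  if (!x$estimable) {
    cat("  not estimable:", x$reason, "\n")
    return(invisible(x))
  }
  fmt <- function(e, lab)
    cat(sprintf("  %-7s %6.3f [%.3f, %.3f]  (n_N=%d, n_S=%d)\n", lab,
                e$value, e$ci_low, e$ci_high, e$n_N, e$n_S))
  fmt(x$on, "ON"); fmt(x$off, "OFF"); fmt(x$immune, "immune")
  invisible(x)
}

#' Cohort-level immune dN/dS
#'
#' Pools mutations across samples, optionally removes driver transcripts,
#' fits (or accepts) a 192-class context model from the OFF-target
#' mutations, computes context-weighted site counts for the ON target and
#' its complement, and returns ON-, OFF- and immune dN/dS with 95% CIs.
#' Cohorts with fewer than `config$min_on_mutations` ON-target mutations
#' are reported as not estimable.
#'
#' @param mutations A `mutation_table` (all samples pooled).
#' @param regions The ON-target `target_regions` (the immunopeptidome).
#' @param transcripts Named character vector of CDS sequences.
#' @param config A [dnds_config()].
#' @param model Optional `context_rate_model`; `NULL` fits one from the
#'   OFF-target substitutions.
#' @param intronic_length Total intronic length (bases) for
#'   exonic-intronic mode.
#' @param enum Optional precomputed [enumerate_transcriptome()] result.
#' @return An `immune_dnds_result`.
#' @export
run_cohort <- function(mutations, regions, transcripts,
                       config = dnds_config(), model = NULL,
                       intronic_length = 0, enum = NULL) {
  if (length(config$exclude_transcripts))
    mutations <- mutations[!(mutations$transcript_id %in%
                               config$exclude_transcripts), , drop = FALSE]
  mutations <- mutations[mutations$transcript_id %in% names(transcripts) |
                           mutations$consequence == "intronic", , drop = FALSE]
  if (!nrow(mutations)) stop("empty cohort after filters")
  if (is.null(enum)) enum <- enumerate_transcriptome(transcripts)

  cds_len <- vapply(transcripts, nchar, 1L)
  counts <- count_mutations(mutations, regions,
                            nonsyn_classes = config$nonsyn_classes,
                            cds_lengths = cds_len)
  n_on <- counts$n_N_on + counts$n_S_on
  if (n_on < config$min_on_mutations) {
    return(immune_result(NULL, NULL, NULL, counts, NULL, NULL, "cohort",
                         estimable = FALSE,
                         reason = sprintf(
                           "fewer than %d mutations in the target region (%d)",
                           config$min_on_mutations, n_on)))
  }

  off_regions <- complement_regions(regions, transcripts)
  if (is.null(model)) {
    on <- mutation_in_regions(mutations, regions)
    off_mut <- mutations[!on & mutations$consequence != "intronic", , drop = FALSE]
    model <- estimate_context_rates(off_mut, transcripts, regions = off_regions,
                                    subset = config$spectrum_subset, enum = enum)
  }
  sites_on <- compute_site_counts(regions, transcripts, model, enum = enum)
  sites_off <- compute_site_counts(off_regions, transcripts, model, enum = enum)

  on_est <- compute_dnds(counts$n_N_on, counts$n_S_on, sites_on)
  off_est <- if (config$mode == "exonic-intronic" &&
                 config$intronic_averaging == "rate-averaged") {
    apply_intronic_correction(counts, sites_off, intronic_length)
  } else {
    compute_dnds(counts$n_N_off, counts$n_S_off, sites_off)
  }
  immune <- compute_immune_dnds(on_est, off_est)
  res <- immune_result(on_est, off_est, immune, counts, sites_on, sites_off,
                       "cohort")
  res$model <- model
  res
}

#' Patient-level immune dN/dS
#'
#' Runs one immune dN/dS estimate per sample. Patients with fewer than
#' `config$min_on_synonymous` ON-target synonymous mutations are reported
#' as not estimable (immune editing and escape cannot be distinguished
#' without synonymous events inside the target). The context model is
#' fitted once from the pooled OFF-target mutations of the whole cohort
#' (per-patient spectra are too sparse) unless one is supplied.
#'
#' @param mutations A `mutation_table` with a `sample_id` column.
#' @param regions Either one shared `target_regions`, or a named list of
#'   per-patient `target_regions` keyed by `sample_id`.
#' @param transcripts Named character vector of CDS sequences.
#' @param config A [dnds_config()] (mode defaults to exonic-only).
#' @param model Optional shared `context_rate_model`.
#' @param enum Optional precomputed enumeration.
#' @return Data frame with one row per patient (counts, estimates, CIs,
#'   `estimable`, `reason`) and attribute `results` holding the full
#'   `immune_dnds_result` objects.
#' @export
run_patient <- function(mutations, regions, transcripts,
                        config = dnds_config(), model = NULL, enum = NULL) {
  samples <- unique(mutations$sample_id)
  per_patient <- is.list(regions) && !inherits(regions, "data.frame")
  if (is.null(enum)) enum <- enumerate_transcriptome(transcripts)

  if (is.null(model)) {
    pooled_regions <- if (per_patient) regions[[1]] else regions
    on <- mutation_in_regions(mutations, pooled_regions)
    off_mut <- mutations[!on & mutations$consequence != "intronic", , drop = FALSE]
    model <- estimate_context_rates(
      off_mut, transcripts,
      regions = complement_regions(pooled_regions, transcripts),
      subset = config$spectrum_subset, enum = enum)
  }

  site_cache <- new.env(parent = emptyenv())
  results <- vector("list", length(samples))
  names(results) <- samples
  cds_len <- vapply(transcripts, nchar, 1L)
  for (s in samples) {
    mut_s <- mutations[mutations$sample_id == s, , drop = FALSE]
    reg_s <- if (per_patient) regions[[s]] else regions
    if (is.null(reg_s)) {
      results[[s]] <- immune_result(NULL, NULL, NULL, NULL, NULL, NULL,
                                    "patient", sample_id = s,
                                    estimable = FALSE,
                                    reason = "no target-region set for patient")
      next
    }
    counts <- count_mutations(mut_s, reg_s,
                              nonsyn_classes = config$nonsyn_classes,
                              cds_lengths = cds_len)
    if (counts$n_S_on < config$min_on_synonymous) {
      results[[s]] <- immune_result(NULL, NULL, NULL, counts, NULL, NULL,
                                    "patient", sample_id = s,
                                    estimable = FALSE,
                                    reason = sprintf(
        "not estimable - edited vs escape indistinguishable (%d < %d ON synonymous)",
        counts$n_S_on, config$min_on_synonymous))
      next
    }
    key <- digest_regions(reg_s)
    if (is.null(site_cache[[key]])) {
      off_reg <- complement_regions(reg_s, transcripts)
      site_cache[[key]] <- list(
        on = compute_site_counts(reg_s, transcripts, model, enum = enum),
        off = compute_site_counts(off_reg, transcripts, model, enum = enum))
    }
    sc <- site_cache[[key]]
    on_est <- compute_dnds(counts$n_N_on, counts$n_S_on, sc$on)
    off_est <- compute_dnds(counts$n_N_off, counts$n_S_off, sc$off)
    immune <- compute_immune_dnds(on_est, off_est)
    results[[s]] <- immune_result(on_est, off_est, immune, counts,
                                  sc$on, sc$off, "patient", sample_id = s)
  }
  df <- do.call(rbind, lapply(results, patient_row))
  rownames(df) <- NULL
  attr(df, "results") <- results
  df
}

digest_regions <- function(regions) {
  paste(regions$transcript_id, regions$start, regions$end,
        sep = ":", collapse = ";")
}

patient_row <- function(r) {
  g <- function(e, f) if (is.null(e) || !isTRUE(e$defined)) NA_real_ else e[[f]]
  data.frame(
    sample_id = r$sample_id,
    n_N_on = if (is.null(r$counts)) NA_integer_ else r$counts$n_N_on,
    n_S_on = if (is.null(r$counts)) NA_integer_ else r$counts$n_S_on,
    n_N_off = if (is.null(r$counts)) NA_integer_ else r$counts$n_N_off,
    n_S_off = if (is.null(r$counts)) NA_integer_ else r$counts$n_S_off,
    dnds_on = g(r$on, "value"), dnds_off = g(r$off, "value"),
    immune_dnds = g(r$immune, "value"),
    ci_low = g(r$immune, "ci_low"), ci_high = g(r$immune, "ci_high"),
    estimable = r$estimable, reason = r$reason,
    stringsAsFactors = FALSE
  )
}

#' Bootstrap the immune dN/dS
#'
#' Resamples mutations (or patients) with replacement, recomputes the
#' pooled immune dN/dS per replicate with a fixed context model, and
#' reports the percentile interval. Replicates with no OFF or ON
#' synonymous mutations are dropped and counted.
#'
#' @param mutations A `mutation_table`.
#' @param regions ON-target `target_regions`.
#' @param transcripts Named character vector of CDS sequences.
#' @param unit `"mutation"` or `"patient"`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer RNG seed (required for reproducibility).
#' @param config A [dnds_config()].
#' @param model Optional `context_rate_model`; `NULL` fits one once from
#'   the original OFF-target mutations and reuses it across replicates.
#' @param level Confidence level for the percentile interval.
#' @param enum Optional precomputed enumeration.
#' @return List: `values` (replicate estimates), `ci_low`, `ci_high`,
#'   `n_dropped`.
#' @export
bootstrap_resample <- function(mutations, regions, transcripts,
                               unit = c("mutation", "patient"), B = 200,
                               seed, config = dnds_config(), model = NULL,
                               level = 0.95, enum = NULL) {
  unit <- match.arg(unit)
  stopifnot(B >= 1)
  set.seed(seed)
  if (is.null(enum)) enum <- enumerate_transcriptome(transcripts)
  off_regions <- complement_regions(regions, transcripts)
  if (is.null(model)) {
    on <- mutation_in_regions(mutations, regions)
    off_mut <- mutations[!on & mutations$consequence != "intronic", , drop = FALSE]
    model <- estimate_context_rates(off_mut, transcripts, regions = off_regions,
                                    subset = config$spectrum_subset, enum = enum)
  }
  sites_on <- compute_site_counts(regions, transcripts, model, enum = enum)
  sites_off <- compute_site_counts(off_regions, transcripts, model, enum = enum)

  values <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (unit == "mutation") {
      sample.int(nrow(mutations), replace = TRUE)
    } else {
      ids <- unique(mutations$sample_id)
      picked <- sample(ids, length(ids), replace = TRUE)
      unlist(lapply(picked, function(s) which(mutations$sample_id == s)),
             use.names = FALSE)
    }
    counts <- count_mutations(mutations[idx, , drop = FALSE], regions,
                              nonsyn_classes = config$nonsyn_classes)
    on_est <- compute_dnds(counts$n_N_on, counts$n_S_on, sites_on)
    off_est <- compute_dnds(counts$n_N_off, counts$n_S_off, sites_off)
    imm <- compute_immune_dnds(on_est, off_est)
    if (isTRUE(imm$defined)) values[b] <- imm$value
  }
  ok <- values[!is.na(values)]
  alpha <- (1 - level) / 2
  list(values = values,
       ci_low = if (length(ok)) unname(stats::quantile(ok, alpha)) else NA_real_,
       ci_high = if (length(ok)) unname(stats::quantile(ok, 1 - alpha)) else NA_real_,
       n_dropped = sum(is.na(values)))
}

#' Randomize a target-region set within a universe
#'
#' Returns a region set with the same number of intervals and identical
#' interval lengths, placed uniformly at random (without overlap) inside
#' the universe. Used as a negative control: on neutral data the immune
#' dN/dS on a randomized target should average 1.
#'
#' @param regions The `target_regions` to re-place.
#' @param universe A `target_regions` giving the allowed space (typically
#'   the full exonic space of the analyzed transcripts).
#' @param seed Integer RNG seed.
#' @return A `target_regions` with the same interval-length multiset.
#' @export
randomize_target <- function(regions, universe, seed) {
  set.seed(seed)
  lens <- sort(regions$end - regions$start, decreasing = TRUE)
  free <- as.data.frame(universe)[, c("transcript_id", "start", "end")]
  placed <- list()
  for (l in lens) {
    cand <- free[free$end - free$start >= l, , drop = FALSE]
    if (!nrow(cand))
      stop("universe too small to place all intervals (need length ", l, ")")
    w <- cand$end - cand$start - l + 1
    pick <- cand[sample.int(nrow(cand), 1, prob = w), , drop = FALSE]
    off <- sample.int(pick$end - pick$start - l + 1, 1) - 1L
    s0 <- pick$start + off
    placed[[length(placed) + 1]] <- data.frame(
      transcript_id = pick$transcript_id, start = s0, end = s0 + l,
      stringsAsFactors = FALSE)
    # split the chosen free segment around the placement, leaving a 1-nt
    # buffer so placed intervals can never be bookended (bookended intervals
    # would merge and change the interval count)
    i <- which(free$transcript_id == pick$transcript_id &
                 free$start == pick$start & free$end == pick$end)[1]
    left <- data.frame(transcript_id = pick$transcript_id,
                       start = pick$start, end = s0 - 1L,
                       stringsAsFactors = FALSE)
    right <- data.frame(transcript_id = pick$transcript_id,
                        start = s0 + l + 1L, end = pick$end,
                        stringsAsFactors = FALSE)
    keep <- rbind(left[left$end > left$start, ], right[right$end > right$start, ])
    free <- rbind(free[-i, , drop = FALSE], keep)
  }
  target_regions(do.call(rbind, placed),
                 label = paste0("randomized(", attr(regions, "label"), ")"))
}
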