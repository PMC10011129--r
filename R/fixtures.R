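#' Specification for a synthetic test fixture
#'
#' Describes a self-contained toy dataset with known ground truth: a
#' stop-free transcriptome, a binder table whose strong binders cover a
#' requested fraction of the CDS, and a mutation cohort drawn from the
#' enumerated single-nucleotide changes with a controllable depletion of
#' ON-target nonsynonymous mutations. With a uniform spectrum and
#' depletion `d`, the expected immune dN/dS of the cohort is `1 - d`.
#'
#' @param n_transcripts Number of toy transcripts (default 10).
#' @param cds_length CDS length in nt, multiple of 3, >= 27 (default 300).
#' @param target_fraction Fraction of the CDS covered by the merged binder
#'   windows (default 0.3).
#' @param n_mutations Mutations drawn before depletion (default 2000).
#' @param depletion Probability an ON-target nonsynonymous draw is removed
#'   (0 = neutral; default 0).
#' @param spectrum `"uniform"` or `"skewed"` (rate concentrated on
#'   C-to-T changes in CpG-like contexts, mimicking real trinucleotide
#'   bias).
#' @param n_samples Number of patient IDs the mutations are spread over
#'   (default 1).
#' @param seed Integer RNG seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_transcripts = 10L, cds_length = 300L,
                         target_fraction = 0.3, n_mutations = 2000L,
                         depletion = 0, spectrum = c("uniform", "skewed"),
                         n_samples = 1L, seed = 1L) {
  stopifnot(cds_length >= 27, cds_length %% 3 == 0,
            depletion >= 0, depletion <= 1,
            target_fraction >= 0, target_fraction <= 1)
  out <- list(n_transcripts = as.integer(n_transcripts),
              cds_length = as.integer(cds_length),
              target_fraction = target_fraction,
              n_mutations = as.integer(n_mutations),
              depletion = depletion, spectrum = match.arg(spectrum),
              n_samples = as.integer(n_samples), seed = as.integer(seed))
  class(out) <- "fixture_spec"
  out
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' Generate a toy stop-free transcriptome
#'
#' Random CDS sequences assembled from sense codons (first codon ATG), so
#' translation in frame never hits a stop. Deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return List: `transcripts` (named character vector) and `universe`
#'   (a `target_regions` covering every full CDS).
#' @export
generate_transcriptome <- function(spec) {
  set.seed(spec$seed)
  n_codons <- spec$cds_length %/% 3L
  codons <- sense_codons()
  ids <- sprintf("TX%04d", seq_len(spec$n_transcripts))
  seqs <- vapply(ids, function(id) {
    paste(c("ATG", sample(codons, n_codons - 1L, replace = TRUE)),
          collapse = "")
  }, "")
  names(seqs) <- ids
  universe <- target_regions(
    data.frame(transcript_id = ids, start = 0L, end = spec$cds_length,
               stringsAsFactors = FALSE),
    label = "universe")
  list(transcripts = seqs, universe = universe)
}

#' Generate a synthetic binder table with known ground truth
#'
#' Samples 9-mer windows across the transcriptome until the merged
#' coverage reaches `target_fraction` of the total CDS (within one window
#' of granularity). Chosen windows get allele A0201 and a percent rank
#' drawn below 0.5, so building the immunopeptidome for an A0201 genotype
#' at threshold 0.5 reproduces the returned ground-truth region set
#' exactly. Decoy records (off-genotype alleles, above-threshold ranks)
#' are added so that filtering logic is actually exercised.
#'
#' @param transcripts Named character vector of CDS sequences.
#' @param spec A [fixture_spec()].
#' @return List: `binders` (a `binder_table`-shaped data frame) and
#'   `truth` (the merged `target_regions` the builder should recover).
#' @export
generate_binder_table <- function(transcripts, spec) {
  set.seed(spec$seed + 1L)
  windows <- do.call(rbind, lapply(names(transcripts), function(tx)
    enumerate_9mers(transcripts[[tx]], tx)))
  goal <- spec$target_fraction * sum(nchar(transcripts))
  chosen <- windows[0, ]
  if (goal > 0 && nrow(windows)) {
    ord <- sample.int(nrow(windows))
    covered_by_tx <- lapply(transcripts, function(s) logical(nchar(s)))
    covered <- 0
    take <- logical(nrow(windows))
    for (i in ord) {
      if (covered >= goal) break
      take[i] <- TRUE
      tx <- windows$transcript_id[i]
      span <- (windows$start[i] + 1L):windows$end[i]
      covered <- covered + sum(!covered_by_tx[[tx]][span])
      covered_by_tx[[tx]][span] <- TRUE
    }
    chosen <- windows[take, , drop = FALSE]
  }
  truth <- target_regions(chosen[, c("transcript_id", "start", "end")],
                          label = "fixture-truth")
  n_hit <- nrow(chosen)
  binders <- data.frame(
    transcript_id = chosen$transcript_id,
    start = chosen$start, end = chosen$end,
    allele = rep("A0201", n_hit),
    percent_rank = stats::runif(n_hit, 0, 0.499),
    peptide = chosen$peptide, stringsAsFactors = FALSE)

  n_decoy <- max(5L, n_hit %/% 4L)
  if (nrow(windows)) {
    decoy_rows <- windows[sample.int(nrow(windows), n_decoy, replace = TRUE), ]
    decoys <- data.frame(
      transcript_id = decoy_rows$transcript_id,
      start = decoy_rows$start, end = decoy_rows$end,
      allele = sample(c("B2705", "C0802"), n_decoy, replace = TRUE),
      percent_rank = stats::runif(n_decoy, 0.5, 10),
      peptide = decoy_rows$peptide, stringsAsFactors = FALSE)
    binders <- rbind(binders, decoys)
  }
  rownames(binders) <- NULL
  attr(binders, "rejects") <- binders[0, , drop = FALSE]
  class(binders) <- c("binder_table", class(binders))
  list(binders = binders, truth = truth)
}

#' Generate a synthetic mutation cohort with known depletion
#'
#' Draws mutations (with replacement) from the enumerated single-nucleotide
#' changes of the transcriptome, uniformly or under a skewed spectrum, then
#' discards each ON-target nonsynonymous draw with probability
#' `spec$depletion`. Because depletion acts on the draw rather than the
#' site model, the estimator is tested against a process it did not
#' assume. Realized per-class counts and the number of removed draws are
#' returned as ground truth.
#'
#' @param transcripts Named character vector of CDS sequences.
#' @param regions ON-target `target_regions` (e.g. the fixture truth set).
#' @param spec A [fixture_spec()].
#' @param enum Optional precomputed [enumerate_transcriptome()] result.
#' @return List: `mutations` (a `mutation_table`), `counts` (realized
#'   `n_N_on`, `n_S_on`, `n_N_off`, `n_S_off`), `n_removed` (ground-truth
#'   removed ON-nonsynonymous draws), `expected_immune`
#'   (`1 - spec$depletion`).
#' @export
generate_mutations <- function(transcripts, regions, spec, enum = NULL) {
  set.seed(spec$seed + 2L)
  if (is.null(enum)) enum <- enumerate_transcriptome(transcripts)
  w <- if (spec$spectrum == "skewed") {
    # concentrate rate on C>T in CpG-like contexts (NCG, alt T)
    ifelse(substr(enum$context, 2, 2) == "C" &
             substr(enum$context, 3, 3) == "G" & enum$alt == "T", 25, 1)
  } else rep(1, nrow(enum))
  idx <- sample.int(nrow(enum), spec$n_mutations, replace = TRUE, prob = w)
  draw <- enum[idx, , drop = FALSE]
  on <- in_regions(draw, regions)
  nonsyn <- draw$impact == "nonsynonymous"
  drop <- on & nonsyn & (stats::runif(nrow(draw)) < spec$depletion)
  n_removed <- sum(drop)
  draw <- draw[!drop, , drop = FALSE]
  on <- on[!drop]
  nonsyn <- nonsyn[!drop]

  consequence <- ifelse(!nonsyn, "synonymous",
                        ifelse(draw$stop_relevant, "stop_gain", "missense"))
  mutations <- data.frame(
    sample_id = sprintf("P%03d",
                        sample.int(spec$n_samples, nrow(draw), replace = TRUE)),
    transcript_id = draw$transcript_id,
    cds_pos = draw$pos, ref = draw$ref, alt = draw$alt,
    consequence = consequence,
    clonality = "unknown", flagged = FALSE,
    stringsAsFactors = FALSE)
  rownames(mutations) <- NULL
  attr(mutations, "rejects") <- mutations[0, , drop = FALSE]
  class(mutations) <- c("mutation_table", class(mutations))

  counts <- c(n_N_on = sum(nonsyn & on), n_S_on = sum(!nonsyn & on),
              n_N_off = sum(nonsyn & !on), n_S_off = sum(!nonsyn & !on))
  list(mutations = mutations, counts = counts, n_removed = n_removed,
       expected_immune = 1 - spec$depletion)
}

#' Write a complete fixture to disk
#'
#' Materializes a [fixture_spec()] as FASTA, BED (truth target), binder
#' TSV, mutation TSV and a ground-truth JSON, so the file readers can be
#' exercised end to end.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects.
#' @export
write_fixture <- function(spec, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  txo <- generate_transcriptome(spec)
  bt <- generate_binder_table(txo$transcripts, spec)
  mut <- generate_mutations(txo$transcripts, bt$truth, spec)
  paths <- list(
    fasta = file.path(outdir, "transcripts.fa"),
    bed = file.path(outdir, "target.bed"),
    binders = file.path(outdir, "binders.tsv"),
    mutations = file.path(outdir, "mutations.tsv"),
    truth_json = file.path(outdir, "truth.json"))
  write_transcript_fasta(txo$transcripts, paths$fasta)
  write_target_regions(bt$truth, paths$bed)
  write_binder_table(bt$binders, paths$binders)
  write_annotated_mutations(mut$mutations, paths$mutations)
  jsonlite::write_json(
    list(spec = unclass(spec), counts = as.list(mut$counts),
         n_removed = mut$n_removed, expected_immune = mut$expected_immune),
    paths$truth_json, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(transcripts = txo$transcripts,
                          universe = txo$universe,
                          binders = bt$binders, truth = bt$truth,
                          mutations = mut$mutations,
                          ground_truth = mut)))
}
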