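# Independent brute-force oracle: classify every single-nucleotide change of
# a CDS (positions 2..L-1) by translating the whole mutated sequence with
# seqinr and comparing protein strings. Deliberately avoids the per-codon
# lookup path used by enumerate_site_classes().
brute_force_change_counts <- function(seq, positions = NULL) {
  L <- nchar(seq)
  if (is.null(positions)) positions <- 2:(L - 1)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  p_ref <- paste(seqinr::translate(tolower(chars)), collapse = "")
  n_syn <- 0L
  n_non <- 0L
  for (pos in positions) {
    ref <- chars[pos]
    for (alt in setdiff(bases, ref)) {
      mutated <- chars
      mutated[pos] <- alt
      p_alt <- paste(seqinr::translate(tolower(mutated)), collapse = "")
      if (p_alt == p_ref) n_syn <- n_syn + 1L else n_non <- n_non + 1L
    }
  }
  c(nonsynonymous = n_non, synonymous = n_syn)
}

# A tiny deterministic mutation table without going through a file.
make_mutations <- function(transcript, cds_pos, consequence,
                           sample_id = "S1", ref = "A", alt = "G") {
  n <- max(length(transcript), length(cds_pos), length(consequence))
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   transcript_id = rep_len(transcript, n),
                   cds_pos = as.integer(rep_len(cds_pos, n)),
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   consequence = rep_len(consequence, n),
                   clonality = "unknown", flagged = FALSE,
                   stringsAsFactors = FALSE)
  class(df) <- c("mutation_table", class(df))
  df
}

# One shared small fixture for engine-level tests (built once per test run).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(n_transcripts = 6, cds_length = 300,
                           target_fraction = 0.4, n_mutations = 2000,
                           depletion = 0, n_samples = 4, seed = 99)
      txo <- generate_transcriptome(spec)
      bt <- generate_binder_table(txo$transcripts, spec)
      mut <- generate_mutations(txo$transcripts, bt$truth, spec)
      cache <<- list(spec = spec, transcripts = txo$transcripts,
                     universe = txo$universe, binders = bt$binders,
                     truth = bt$truth, mutations = mut$mutations,
                     ground = mut,
                     enum = enumerate_transcriptome(txo$transcripts))
    }
    cache
  }
})
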