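uniform_sites <- function(L_N = 1, L_S = 1) {
  structure(list(L_N = L_N, L_S = L_S, mu_ratio = L_N / L_S,
                 degenerate = L_S <= 0), class = "site_counts")
}

test_that("mutations are assigned ON/OFF by half-open interval containment", {
  reg <- target_regions(data.frame(transcript_id = "T1", start = 100L, end = 114L))
  mut <- make_mutations("T1", c(101, 50, 101, 115),
                        c("missense", "synonymous", "stop_gain", "missense"))
  counts <- count_mutations(mut, reg)
  expect_equal(counts$n_N_on, 2)   # missense at 101 (0-based 100) + stop_gain
  expect_equal(counts$n_S_off, 1)
  expect_equal(counts$n_N_off, 1)  # 115 -> 0-based 114 is outside [100,114)
})

test_that("inclusion policy controls which classes count as nonsynonymous", {
  reg <- target_regions(data.frame(transcript_id = "T1", start = 0L, end = 30L))
  mut <- make_mutations("T1", c(5, 10), c("stop_gain", "synonymous"))
  with_trunc <- count_mutations(mut, reg)
  expect_equal(with_trunc$n_N_on, 1)
  missense_only <- count_mutations(mut, reg, nonsyn_classes = "missense")
  expect_equal(missense_only$n_N_on, 0)
  expect_equal(missense_only$n_excluded, 1)
})

test_that("intronic mutations are tallied separately; beyond-CDS rejected", {
  reg <- target_regions(data.frame(transcript_id = "T1", start = 0L, end = 30L))
  mut <- make_mutations("T1", c(5, 10, 400), c("intronic", "missense", "missense"))
  counts <- count_mutations(mut, reg, cds_lengths = c(T1 = 300L))
  expect_equal(counts$n_intronic, 1)
  expect_equal(counts$n_N_on, 1)
  expect_equal(nrow(attr(counts, "rejects")), 1)
})

test_that("dN/dS point estimates follow (n_N/L_N)/(n_S/L_S)", {
  d <- compute_dnds(8, 1, uniform_sites(8, 1))
  expect_equal(d$value, 1)
  zero <- compute_dnds(0, 5, uniform_sites())
  expect_equal(zero$value, 0)
  expect_equal(zero$ci_low, 0)
  expect_true(is.na(zero$ci_high))
  undef <- compute_dnds(5, 0, uniform_sites())
  expect_false(undef$defined)
})

test_that("Katz log-ratio CI matches the closed form and calibrates near 95%", {
  d <- compute_dnds(10, 10, uniform_sites())
  expect_equal(d$value, 1)
  expect_equal(d$ci_low, exp(-1.96 * sqrt(0.2)), tolerance = 1e-10)
  expect_equal(d$ci_high, exp(1.96 * sqrt(0.2)), tolerance = 1e-10)
  expect_equal(round(c(d$ci_low, d$ci_high), 3), c(0.416, 2.403))

  # parametric-bootstrap oracle: Poisson counts at a true ratio of 1
  set.seed(20)
  lam <- 30
  covered <- replicate(400, {
    nN <- stats::rpois(1, lam); nS <- stats::rpois(1, lam)
    if (nN == 0 || nS == 0) return(NA)
    ci <- compute_dnds(nN, nS, uniform_sites())
    ci$ci_low <= 1 && ci$ci_high >= 1
  })
  expect_gt(mean(covered, na.rm = TRUE), 0.90)
})

test_that("immune dN/dS is ON/OFF with all four counts in the CI", {
  on <- compute_dnds(10, 10, uniform_sites())
  off <- compute_dnds(1000, 1000, uniform_sites())
  imm <- compute_immune_dnds(on, off)
  expect_equal(imm$value, 1)
  # identical ON and OFF estimates give exactly 1
  expect_equal(compute_immune_dnds(on, on)$value, 1)
  # the ratio CI is wider than the OFF-only CI and covers the point
  expect_gt(imm$ci_high - imm$ci_low, off$ci_high - off$ci_low)
  expect_true(imm$ci_low <= imm$value && imm$value <= imm$ci_high)
  # scaling: ON 0.6 vs OFF 1.0
  on2 <- compute_dnds(6, 10, uniform_sites())
  expect_equal(compute_immune_dnds(on2, off)$value, 0.6)
  undef <- compute_dnds(5, 0, uniform_sites())
  expect_false(compute_immune_dnds(on, undef)$defined)
})

test_that("intronic correction averages per-base background rates", {
  # OFF synonymous rate 1e-6 vs intronic rate 3e-6 -> averaged 2e-6,
  # so the corrected OFF dN/dS halves
  counts <- structure(list(n_N_on = 0, n_S_on = 0, n_N_off = 100, n_S_off = 10,
                           n_intronic = 30, n_excluded = 0),
                      class = "mutation_counts")
  sites <- uniform_sites(L_N = 1e8, L_S = 1e7)  # syn rate = 10/1e7 = 1e-6
  plain <- compute_dnds(100, 10, sites)
  corr <- apply_intronic_correction(counts, sites, intronic_length = 1e7)
  expect_equal(corr$value, plain$value / 2)
  # n_intronic = 0 halves the background rate, doubling OFF dN/dS
  counts0 <- counts; counts0$n_intronic <- 0
  corr0 <- apply_intronic_correction(counts0, sites, intronic_length = 1e7)
  expect_equal(corr0$value, plain$value * 2)
  # no intronic length and no intronic mutations: identity
  expect_equal(apply_intronic_correction(counts0, sites, 0)$value, plain$value)
  expect_error(apply_intronic_correction(counts, sites, 0), "intronic_length")
})

test_that("exonic-only mode ignores intronic mutations entirely", {
  fx <- small_fixture()
  mut <- fx$mutations
  intr <- make_mutations(names(fx$transcripts)[1], 1:20, "intronic")
  both <- rbind(mut, intr)
  class(both) <- class(mut)
  r1 <- run_cohort(mut, fx$truth, fx$transcripts, enum = fx$enum)
  r2 <- run_cohort(both, fx$truth, fx$transcripts, enum = fx$enum)
  expect_equal(r1$immune$value, r2$immune$value)
  # exonic-intronic mode shifts OFF when the intronic rate differs
  r3 <- run_cohort(both, fx$truth, fx$transcripts,
                   config = dnds_config(mode = "exonic-intronic"),
                   intronic_length = 1e5, enum = fx$enum)
  expect_false(isTRUE(all.equal(r3$off$value, r2$off$value)))
})

test_that("cohort estimates are invariant to how samples are split", {
  fx <- small_fixture()
  mut <- fx$mutations
  relabeled <- mut
  relabeled$sample_id <- "ALL"
  r1 <- run_cohort(mut, fx$truth, fx$transcripts, enum = fx$enum)
  r2 <- run_cohort(relabeled, fx$truth, fx$transcripts, enum = fx$enum)
  expect_equal(r1$immune$value, r2$immune$value)
  expect_equal(r1$counts$n_N_on, r2$counts$n_N_on)
})

test_that("cohorts under the minimum ON-mutation threshold are excluded with a reason", {
  fx <- small_fixture()
  # keep only OFF-target mutations plus too few ON ones
  inside <- immunodnds:::mutation_in_regions(fx$mutations, fx$truth)
  few <- rbind(fx$mutations[!inside, ][1:200, ], fx$mutations[inside, ][1:9, ])
  class(few) <- class(fx$mutations)
  res <- run_cohort(few, fx$truth, fx$transcripts, enum = fx$enum)
  expect_false(res$estimable)
  expect_match(res$reason, "fewer than 10")
})

test_that("driver-gene exclusion removes all mutations of listed transcripts", {
  fx <- small_fixture()
  drop_tx <- names(fx$transcripts)[1]
  cfg <- dnds_config(exclude_transcripts = drop_tx)
  res <- run_cohort(fx$mutations, fx$truth, fx$transcripts, config = cfg,
                    enum = fx$enum)
  kept <- fx$mutations[fx$mutations$transcript_id != drop_tx, , drop = FALSE]
  class(kept) <- class(fx$mutations)
  res2 <- run_cohort(kept, fx$truth, fx$transcripts, enum = fx$enum)
  expect_equal(res$counts$n_N_on, res2$counts$n_N_on)
  expect_equal(res$counts$n_S_off, res2$counts$n_S_off)
})

test_that("patients without enough ON synonymous mutations are not estimable", {
  fx <- small_fixture()
  tab <- run_patient(fx$mutations, fx$truth, fx$transcripts, enum = fx$enum)
  expect_equal(nrow(tab), length(unique(fx$mutations$sample_id)))
  expect_true(all(tab$n_S_on[tab$estimable] >= 1))
  expect_true(all(grepl("edited vs escape", tab$reason[!tab$estimable])))

  # raising the minimum-synonymous threshold can only remove patients
  for (k in 2:4) {
    tabk <- run_patient(fx$mutations, fx$truth, fx$transcripts,
                        config = dnds_config(min_on_synonymous = k),
                        enum = fx$enum)
    expect_true(all(tabk$estimable <= tab$estimable))
    expect_true(all(tabk$n_S_on[tabk$estimable] >= k))
  }
})

test_that("identical patients get identical estimates", {
  fx <- small_fixture()
  m1 <- fx$mutations[fx$mutations$sample_id == "P001", , drop = FALSE]
  m2 <- m1
  m2$sample_id <- "P999"
  both <- rbind(m1, m2)
  class(both) <- class(fx$mutations)
  tab <- run_patient(both, fx$truth, fx$transcripts, enum = fx$enum)
  expect_equal(tab$immune_dnds[1], tab$immune_dnds[2])
})

test_that("bootstrap is seed-deterministic and covers 1 on neutral data", {
  fx <- small_fixture()
  b1 <- bootstrap_resample(fx$mutations, fx$truth, fx$transcripts,
                           B = 50, seed = 7, enum = fx$enum)
  b2 <- bootstrap_resample(fx$mutations, fx$truth, fx$transcripts,
                           B = 50, seed = 7, enum = fx$enum)
  expect_identical(b1$values, b2$values)
  b <- bootstrap_resample(fx$mutations, fx$truth, fx$transcripts,
                          B = 200, seed = 3, enum = fx$enum)
  expect_lte(b$ci_low, 1)
  expect_gte(b$ci_high, 1)
  # patient-level resampling also runs and is finite
  bp <- bootstrap_resample(fx$mutations, fx$truth, fx$transcripts,
                           unit = "patient", B = 20, seed = 5, enum = fx$enum)
  expect_true(all(is.finite(bp$values)))
})

test_that("target randomization conserves interval lengths and is seeded", {
  fx <- small_fixture()
  r1 <- randomize_target(fx$truth, fx$universe, seed = 11)
  r2 <- randomize_target(fx$truth, fx$universe, seed = 11)
  r3 <- randomize_target(fx$truth, fx$universe, seed = 12)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
  expect_equal(region_width(r1), region_width(fx$truth))
  expect_equal(sort(r1$end - r1$start), sort(fx$truth$end - fx$truth$start))
  # placements stay inside the universe
  expect_true(all(r1$end <= 300))
  expect_error(randomize_target(
    fx$truth,
    target_regions(data.frame(transcript_id = "T1", start = 0L, end = 5L)),
    seed = 1), "too small")
})

test_that("neutral data on a randomized target stays near immune dN/dS 1", {
  fx <- small_fixture()
  model <- estimate_context_rates(fx$mutations, fx$transcripts, enum = fx$enum)
  vals <- vapply(1:25, function(s) {
    reg <- randomize_target(fx$truth, fx$universe, seed = 1000 + s)
    run_cohort(fx$mutations, reg, fx$transcripts, model = model,
               enum = fx$enum)$immune$value
  }, numeric(1))
  expect_lt(abs(mean(vals) - 1), 0.1)
})
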