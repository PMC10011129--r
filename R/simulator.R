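#' Configuration for the immune-selection tumor simulator
#'
#' Discrete, synchronous generations: every cell divides, each daughter
#' acquires `Poisson(mu_per_division)` new mutations, each mutation falls
#' in the immunopeptidome with probability `p_on` and is nonsynonymous with
#' probability `p_nonsyn`. A new ON-target nonsynonymous mutation is
#' immune-recognized with probability `p_recognition` (assigned once at
#' birth by default); every generation, a cell carrying at least one
#' recognized mutation is killed with probability `pattack`. The run stops
#' at `max_generations` or as soon as the population exceeds
#' `carrying_capacity` (a stopping rule, not a logistic brake).
#'
#' @param initial_cells Starting population (default 5).
#' @param p_recognition Probability a new ON-target nonsynonymous mutation
#'   is recognized (default 0.1).
#' @param pattack Per-generation kill probability for a cell carrying a
#'   recognized mutation (0 = no immune system, 1 = fully active).
#' @param max_generations Generation cap (default 100).
#' @param carrying_capacity Population size that stops the run when
#'   exceeded (default 2000).
#' @param min_final_cells Cohort-level filter: tumors must end with more
#'   than this many cells to enter the pooled estimate (default 1000).
#' @param freq_threshold Minimum cell fraction for a mutation to be
#'   retained (default 0.01).
#' @param mu_per_division Mean new mutations per daughter cell (default 1).
#' @param p_on Probability a mutation lands in the immunopeptidome
#'   (default 0.1).
#' @param p_nonsyn Probability a mutation is nonsynonymous (default 0.75,
#'   the naive coding expectation).
#' @param recognition `"at-birth"` (default) fixes each mutation's
#'   recognition status once; `"per-generation"` re-draws recognition of
#'   each carried ON-nonsynonymous mutation every generation.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(initial_cells = 5L, p_recognition = 0.1, pattack = 0,
                       max_generations = 100L, carrying_capacity = 2000L,
                       min_final_cells = 1000L, freq_threshold = 0.01,
                       mu_per_division = 1, p_on = 0.1, p_nonsyn = 0.75,
                       recognition = c("at-birth", "per-generation")) {
  probs <- c(p_recognition, pattack, freq_threshold, p_on, p_nonsyn)
  stopifnot(all(probs >= 0 & probs <= 1), initial_cells >= 1,
            carrying_capacity > initial_cells, mu_per_division >= 0)
  out <- list(initial_cells = as.integer(initial_cells),
              p_recognition = p_recognition, pattack = pattack,
              max_generations = as.integer(max_generations),
              carrying_capacity = as.integer(carrying_capacity),
              min_final_cells = as.integer(min_final_cells),
              freq_threshold = freq_threshold,
              mu_per_division = mu_per_division,
              p_on = p_on, p_nonsyn = p_nonsyn,
              recognition = match.arg(recognition))
  class(out) <- "sim_config"
  out
}

#' Simulate one tumor under immune attack
#'
#' Branching-process growth as described in [sim_config()]. Mutations are
#' stored on a genealogy forest so per-mutation cell fractions at the final
#' time point are exact; mutations below `freq_threshold` of the final
#' population are discarded from the retained counts. Extinction
#' (`final_population = 0`) is a valid outcome.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return List of class `simulated_tumor`: `final_population`,
#'   `generations_run`, `mutations` (data frame with `class` in
#'   `on_N`/`on_S`/`off_N`/`off_S`, `recognized`, `generation`,
#'   `cell_fraction`, `retained`) and `retained_counts` (named integer
#'   vector over the four classes).
#' @export
simulate_tumor <- function(config = sim_config(), seed) {
  set.seed(seed)
  per_gen <- config$recognition == "per-generation"

  cell_node <- integer(config$initial_cells)      # 0 = mutation-free root
  cell_attack <- logical(config$initial_cells)    # carries recognized mutation
  cell_n_onN <- integer(config$initial_cells)     # for per-generation mode

  node_parent <- integer(0)
  mut_node <- integer(0)
  mut_on <- logical(0)
  mut_nonsyn <- logical(0)
  mut_recog <- logical(0)
  mut_gen <- integer(0)

  gens <- 0L
  for (g in seq_len(config$max_generations)) {
    pop <- length(cell_node)
    if (pop == 0L) break
    gens <- g
    nd <- 2L * pop
    d_node <- rep(cell_node, each = 2L)
    d_attack <- rep(cell_attack, each = 2L)
    d_n_onN <- rep(cell_n_onN, each = 2L)

    k <- stats::rpois(nd, config$mu_per_division)
    M <- sum(k)
    if (M > 0L) {
      on <- stats::runif(M) < config$p_on
      nonsyn <- stats::runif(M) < config$p_nonsyn
      recog <- on & nonsyn & (stats::runif(M) < config$p_recognition)
      d_of_mut <- rep(seq_len(nd), k)

      has_new <- k > 0L
      new_ids <- length(node_parent) + seq_len(sum(has_new))
      node_parent <- c(node_parent, d_node[has_new])
      node_of_d <- integer(nd)
      node_of_d[has_new] <- new_ids

      any_rec <- logical(nd)
      any_rec[unique(d_of_mut[recog])] <- TRUE
      d_node[has_new] <- new_ids
      d_attack <- d_attack | any_rec
      if (per_gen)
        d_n_onN <- d_n_onN + tabulate(d_of_mut[on & nonsyn], nbins = nd)

      mut_node <- c(mut_node, node_of_d[d_of_mut])
      mut_on <- c(mut_on, on)
      mut_nonsyn <- c(mut_nonsyn, nonsyn)
      mut_recog <- c(mut_recog, recog)
      mut_gen <- c(mut_gen, rep.int(g, M))
    }

    attackable <- if (per_gen) {
      stats::runif(nd) < 1 - (1 - config$p_recognition)^d_n_onN
    } else d_attack
    killed <- attackable & (stats::runif(nd) < config$pattack)
    keep <- !killed
    cell_node <- d_node[keep]
    cell_attack <- d_attack[keep]
    cell_n_onN <- d_n_onN[keep]

    if (length(cell_node) > config$carrying_capacity) break
  }

  final_pop <- length(cell_node)
  n_nodes <- length(node_parent)
  frac <- numeric(length(mut_node))
  if (final_pop > 0L && n_nodes > 0L) {
    cnt <- tabulate(cell_node, nbins = n_nodes)
    for (i in rev(seq_len(n_nodes))) {   # children were created after parents
      p <- node_parent[i]
      if (p > 0L) cnt[p] <- cnt[p] + cnt[i]
    }
    frac <- cnt[mut_node] / final_pop
  }

  cls <- ifelse(mut_on,
                ifelse(mut_nonsyn, "on_N", "on_S"),
                ifelse(mut_nonsyn, "off_N", "off_S"))
  retained <- frac >= config$freq_threshold & frac > 0
  mutations <- data.frame(class = cls, recognized = mut_recog,
                          generation = mut_gen, cell_fraction = frac,
                          retained = retained, stringsAsFactors = FALSE)
  lev <- c("on_N", "on_S", "off_N", "off_S")
  retained_counts <- stats::setNames(
    as.integer(table(factor(cls[retained], levels = lev))), lev)
  out <- list(final_population = final_pop, generations_run = gens,
              mutations = mutations, retained_counts = retained_counts)
  class(out) <- "simulated_tumor"
  out
}

#' Simulate a cohort of tumors and estimate its immune dN/dS
#'
#' Runs `n_tumors` independent tumors, keeps those ending with more than
#' `config$min_final_cells` cells, pools their retained mutation counts,
#' and computes ON-, OFF- and immune dN/dS. Because the simulator emits
#' class labels directly, the neutral nonsynonymous:synonymous expectation
#' is analytic: `mu_ratio = p_nonsyn / (1 - p_nonsyn)` inside and outside
#' the target.
#'
#' @param config A [sim_config()].
#' @param n_tumors Number of tumors (default 1000).
#' @param seed Integer RNG seed; per-tumor seeds are derived from it.
#' @return List of class `simulated_cohort`: `tumors` (one row per tumor),
#'   `n_used`, `pooled_counts`, and `on`, `off`, `immune`
#'   (`dnds_estimate` objects over the pooled counts).
#' @export
simulate_cohort <- function(config = sim_config(), n_tumors = 1000L, seed) {
  stopifnot(n_tumors >= 1)
  set.seed(seed)
  tumor_seeds <- sample.int(.Machine$integer.max, n_tumors)
  lev <- c("on_N", "on_S", "off_N", "off_S")
  counts <- matrix(0L, nrow = n_tumors, ncol = 4,
                   dimnames = list(NULL, lev))
  pops <- integer(n_tumors)
  gens <- integer(n_tumors)
  for (i in seq_len(n_tumors)) {
    tum <- simulate_tumor(config, seed = tumor_seeds[i])
    counts[i, ] <- tum$retained_counts[lev]
    pops[i] <- tum$final_population
    gens[i] <- tum$generations_run
  }
  used <- pops > config$min_final_cells
  if (!any(used))
    stop(sprintf(
      "no simulated tumor exceeded %d cells (%.1f%% survived at all)",
      config$min_final_cells, 100 * mean(pops > 0)))
  pooled <- colSums(counts[used, , drop = FALSE])
  sites <- structure(list(L_N = config$p_nonsyn, L_S = 1 - config$p_nonsyn,
                          mu_ratio = config$p_nonsyn / (1 - config$p_nonsyn),
                          degenerate = FALSE), class = "site_counts")
  on_est <- compute_dnds(pooled[["on_N"]], pooled[["on_S"]], sites)
  off_est <- compute_dnds(pooled[["off_N"]], pooled[["off_S"]], sites)
  immune <- compute_immune_dnds(on_est, off_est)
  out <- list(tumors = data.frame(final_population = pops,
                                  generations_run = gens, counts,
                                  used = used),
              n_used = sum(used), pooled_counts = pooled,
              on = on_est, off = off_est, immune = immune)
  class(out) <- "simulated_cohort"
  out
}
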