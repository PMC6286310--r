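#' The hRPG mutation race model
#'
#' A diploid genome carries `G` genes (2G alleles), `H` of which are
#' haploinsufficient ribosomal protein genes (hRPGs). Random mutations hit
#' alleles uniformly with replacement; a repeat hit on an already-mutated
#' allele changes nothing. The "race" asks which happens first: some hRPG
#' allele is hit (the cell becomes Minute, i.e. hRPG-heterozygous, and in
#' a competitive tissue is eliminated), or some non-hRPG gene accumulates
#' hits on both alleles (homozygous mutant, a potentially dangerous cell
#' that escaped the surveillance).
#'
#' `simulate_race()` runs one trajectory. `race_probability_exact()` is an
#' exact oracle: conditioning on effective (non-repeat) hits, the state is
#' just the number `k` of non-hRPG genes currently heterozygous, and
#' \deqn{P(k) = \frac{2H + 2(G-H-k)\,P(k+1)}{2H + k + 2(G-H-k)},\qquad
#'       P(G-H) = \frac{2H}{2H + (G-H)}}
#' gives the race probability as `P(0)`. No-op repeats cancel from
#' numerator and denominator, so the convention chosen for them cannot
#' change this probability.
#'
#' @param G Number of genes (diploid, so 2G alleles).
#' @param H Number of hRPG genes, `0 <= H <= G`.
#' @param seed Integer seed (single trajectory).
#' @param budget Optional finite mutation budget `M`; `NULL` (default)
#'   runs to absorption.
#' @return `simulate_race()`: a list with `event` (one of
#'   `"HRPG_HET_FIRST"`, `"HOMOZYGOUS_FIRST"`, `"UNRESOLVED"`) and
#'   `mutations_used`. `race_probability_exact()`: a probability.
#' @examples
#' race_probability_exact(2, 1) # 5/6
#' @export
simulate_race <- function(G, H, seed = NULL, budget = NULL) {
  check_gh(G, H)
  run <- function() {
    res <- race_trials_cpp(as.integer(G), as.integer(H), 1L,
                           as.integer(if (is.null(budget)) 0L else budget))
    list(event = c("UNRESOLVED", "HRPG_HET_FIRST",
                   "HOMOZYGOUS_FIRST")[res$event[1] + 1L],
         mutations_used = res$mutations[1])
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' @rdname simulate_race
#' @export
race_probability_exact <- function(G, H) {
  check_gh(G, H)
  if (H == 0) return(0)
  if (H == G) return(1)
  K <- G - H
  p <- 2 * H / (2 * H + K)          # boundary state k = G - H
  for (k in seq(K - 1, 0)) {
    fresh <- 2 * (G - H - k)
    p <- (2 * H + fresh * p) / (2 * H + k + fresh)
  }
  p
}

check_gh <- function(G, H) {
  if (length(G) != 1L || is.na(G) || G < 1)
    stop("config error: G must be a positive integer", call. = FALSE)
  if (length(H) != 1L || is.na(H) || H < 0 || H > G)
    stop("config error: need 0 <= H <= G", call. = FALSE)
  invisible(TRUE)
}

#' Monte-Carlo estimate of the race probability
#'
#' Runs `reps` independent race trajectories under a seeded stream and
#' estimates P(HRPG_HET_FIRST) among resolved runs, with a 95% Wilson
#' score interval (preferred over Wald because the estimate often sits
#' near 0 or 1). When no mutation budget is imposed every run resolves and
#' the exact recursion value is attached for comparison.
#'
#' @inheritParams simulate_race
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Integer seed for the replicate stream.
#' @return An object of class `race_estimate`: `p_hat`, `ci_low`,
#'   `ci_high`, `reps`, `n_resolved`, `exact_p` (NA when a budget is set),
#'   and for budgeted runs the full outcome probabilities
#'   `p_hrpg_het_first`, `p_homozygous_first`, `p_unresolved`.
#' @examples
#' race_probability_mc(2, 1, reps = 5000, seed = 42)
#' @export
race_probability_mc <- function(G, H, reps = 10000L, seed = 1L,
                                budget = NULL) {
  check_gh(G, H)
  stopifnot(reps >= 1)
  bounded <- !is.null(budget)
  if (bounded) stopifnot(budget >= 1)
  res <- withr_seed(seed, race_trials_cpp(as.integer(G), as.integer(H),
                                          as.integer(reps),
                                          as.integer(if (bounded) budget
                                                     else 0L)))
  ev <- res$event
  n_res <- sum(ev != 0L)
  if (n_res == 0L)
    stop("estimate error: all runs UNRESOLVED; increase the mutation ",
         "budget M", call. = FALSE)
  wins <- sum(ev == 1L)
  p_hat <- wins / n_res
  ci <- wilson_ci(wins, n_res)
  out <- list(G = G, H = H, reps = reps,
              n_resolved = n_res,
              p_hat = p_hat, ci_low = ci[1], ci_high = ci[2],
              exact_p = if (bounded) NA_real_
                        else race_probability_exact(G, H),
              budget = if (bounded) budget else NA_integer_,
              p_hrpg_het_first = mean(ev == 1L),
              p_homozygous_first = mean(ev == 2L),
              p_unresolved = mean(ev == 0L),
              mean_mutations = mean(res$mutations))
  class(out) <- "race_estimate"
  out
}

#' @rdname race_probability_mc
#' @param M Finite mutation budget for the bounded variant.
#' @export
race_probability_bounded <- function(G, H, M, reps = 10000L, seed = 1L) {
  stopifnot(length(M) == 1L, M >= 1)
  race_probability_mc(G, H, reps = reps, seed = seed, budget = M)
}

#' @export
print.race_estimate <- function(x, ...) {
  cat(sprintf("race_estimate: G=%d H=%d reps=%d\n", x$G, x$H, x$reps))
  cat(sprintf("  P(hRPG het first) = %.4f  [95%% Wilson %.4f, %.4f]\n",
              x$p_hat, x$ci_low, x$ci_high))
  if (!is.na(x$exact_p))
    cat(sprintf("  exact (recursion) = %.4f\n", x$exact_p))
  if (!is.na(x$budget))
    cat(sprintf("  budget M=%d: P(het)=%.4f P(hom)=%.4f P(unres)=%.4f\n",
                x$budget, x$p_hrpg_het_first, x$p_homozygous_first,
                x$p_unresolved))
  invisible(x)
}

# 95% Wilson score interval for x successes out of n
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Distribution of the number of disturbed genes after M mutations
#'
#' A gene is "disturbed" when both of its alleles have been mutated. This
#' returns the distribution of the number of disturbed genes among `G`
#' genes after `M` uniform-with-replacement allele hits. For small state
#' spaces (`(2G)^M <= enum_limit`) every equally likely hit sequence is
#' enumerated exactly; otherwise the distribution is estimated from
#' `reps` simulated trials. hRPG flags are ignored here: all genes count.
#'
#' @param G Number of genes.
#' @param M Number of mutations.
#' @param reps Simulation replicates (ignored in exact mode).
#' @param seed Integer seed (ignored in exact mode).
#' @param method `"auto"` (default), `"exact"` or `"simulate"`.
#' @param enum_limit Maximum number of sequences for exact enumeration.
#' @return An object of class `disturbed_distribution`: `G`, `M`,
#'   `method`, and `probs`, a named vector over the support
#'   `0..min(G, floor(M/2))` summing to 1.
#' @examples
#' disturbed_count_distribution(1, 2)$probs # P(1 disturbed) = 1/2
#' @export
disturbed_count_distribution <- function(G, M, reps = 20000L, seed = 1L,
                                         method = c("auto", "exact",
                                                    "simulate"),
                                         enum_limit = 1e6) {
  check_gh(G, 0)
  stopifnot(M >= 0)
  method <- match.arg(method)
  n_seq <- (2 * G)^M
  if (method == "auto")
    method <- if (n_seq <= enum_limit) "exact" else "simulate"
  support <- 0:min(G, floor(M / 2))
  if (method == "exact") {
    if (n_seq > enum_limit)
      stop("config error: (2G)^M too large for exact enumeration",
           call. = FALSE)
    counts <- enumerate_disturbed(G, M)
  } else {
    sims <- withr_seed(seed,
                       disturbed_trials_cpp(as.integer(G), as.integer(M),
                                            as.integer(reps)))
    counts <- tabulate(sims + 1L, nbins = length(support))
  }
  probs <- counts / sum(counts)
  names(probs) <- support
  structure(list(G = G, M = M, method = method, probs = probs),
            class = "disturbed_distribution")
}

# exact oracle: depth-first enumeration of all (2G)^M equally likely
# allele-hit sequences, tallying the final disturbed-gene count of each
enumerate_disturbed <- function(G, M) {
  support_len <- min(G, floor(M / 2)) + 1L
  counts <- numeric(support_len)
  hit <- logical(2 * G)
  recurse <- function(depth, disturbed) {
    force(disturbed) # eager: `hit` mutates below, promises must not linger
    if (depth == M) {
      counts[disturbed + 1L] <<- counts[disturbed + 1L] + 1
      return(invisible())
    }
    for (a in seq_len(2 * G)) {
      if (hit[a]) {
        recurse(depth + 1L, disturbed)
      } else {
        partner <- if (a %% 2 == 1) a + 1L else a - 1L
        hit[a] <<- TRUE
        d_next <- disturbed + as.integer(hit[partner])
        recurse(depth + 1L, d_next)
        hit[a] <<- FALSE
      }
    }
  }
  if (M == 0) counts[1] <- 1 else recurse(0L, 0L)
  counts
}

#' @export
print.disturbed_distribution <- function(x, ...) {
  cat(sprintf("disturbed_distribution: G=%d M=%d (%s)\n", x$G, x$M,
              x$method))
  print(round(x$probs, 4))
  invisible(x)
}
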