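#' Per-disc loser/winner clone-area ratios
#'
#' The elimination read-out of a twin-spot experiment: the ratio of the
#' loser clone area (mCherry, hRPG heterozygous) to its wild-type twin's
#' area (GFP 2x) in the same disc. Eliminated losers give ratios close to
#' 0; fully rescued losers give ratios close to 1.
#'
#' @param measurements Data frame with columns `loser_area` (>= 0) and
#'   `winner_area` (> 0), one row per disc.
#' @return Numeric vector of per-disc ratios.
#' @export
per_disc_ratio <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("loser_area", "winner_area") %in% names(measurements)))
  if (any(measurements$winner_area <= 0))
    stop("measurement error: winner_area must be > 0", call. = FALSE)
  if (any(measurements$loser_area < 0))
    stop("measurement error: loser_area must be >= 0", call. = FALSE)
  measurements$loser_area / measurements$winner_area
}

#' Summarise clone ratios per genotype
#'
#' Mean ratio, SEM (sample SD / sqrt(n)) and n per genotype, with no
#' silent filtering: `n` always equals the number of input discs for that
#' genotype.
#'
#' @param measurements Data frame with `genotype`, `loser_area`,
#'   `winner_area`.
#' @return Data frame with one row per genotype: `genotype`,
#'   `mean_ratio`, `sem`, `n`.
#' @export
summarize_genotypes <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            "genotype" %in% names(measurements))
  if (nrow(measurements) == 0)
    stop("input error: no measurements", call. = FALSE)
  ratios <- per_disc_ratio(measurements)
  out <- lapply(split(ratios, measurements$genotype), function(r) {
    n <- length(r)
    data.frame(mean_ratio = mean(r),
               sem = if (n > 1) stats::sd(r) / sqrt(n) else 0,
               n = n)
  })
  res <- do.call(rbind, out)
  res <- cbind(genotype = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's Z_g1, via the
#' Johnson SU transformation) and standardized sample kurtosis (the
#' Anscombe-Glynn Z_g2) into the omnibus statistic K^2 = Z_g1^2 + Z_g2^2,
#' referred to a chi-square distribution with 2 df. Moment definitions
#' and finite-sample corrections match the standard reference
#' implementation to < 1e-6. Requires n >= 8 (the kurtosis normalisation
#' is undefined below).
#'
#' @param x Numeric sample.
#' @return An object of class `normality_result` (and `htest`-like list)
#'   with `statistic` (K^2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @examples
#' dagostino_pearson(rnorm(100))
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("input error: NA in sample", call. = FALSE)
  n <- length(x)
  if (n < 8)
    stop("sample-size error: D'Agostino-Pearson requires n >= 8",
         call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    stop("input error: zero-variance (constant) sample", call. = FALSE)
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness: D'Agostino (1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1 # same convention as the reference implementation
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xs * sqrt(2 / (A - 4))
  term2 <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  z_kurt <- (term1 - term2) / sqrt(2 / (9 * A))

  k2 <- z_skew^2 + z_kurt^2
  structure(list(statistic = k2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 z_skew = z_skew, z_kurt = z_kurt, n = n),
            class = "normality_result")
}

#' @export
print.normality_result <- function(x, ...) {
  cat(sprintf("D'Agostino-Pearson omnibus: K2 = %.4f, p = %.4g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Rank-based group comparison
#'
#' Tie-corrected Kruskal-Wallis test over k >= 2 groups. For k = 2 the
#' Kruskal-Wallis chi-square equals the squared normal approximation of
#' the two-sided Mann-Whitney statistic (no continuity correction), so
#' the two-group case honours the Mann-Whitney contract. If every
#' observation across all groups is identical the test is vacuous and
#' p = 1 by convention.
#'
#' @param groups A list of numeric vectors, one per group (each n >= 1).
#' @return The p-value.
#' @export
rank_group_test <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 1))
    stop("input error: every group needs >= 1 observation", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) return(1)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  stats::kruskal.test(values, g)$p.value
}

#' Two-criterion suppressor call
#'
#' A genuine suppressor of hRPG-mutant cell elimination must (i) increase
#' the loser/winner clone ratio relative to the loser control — tested
#' with a one-sided Mann-Whitney (Wilcoxon rank-sum) test, candidate >
#' control — and (ii) restore a normal distribution of ratios — the
#' D'Agostino-Pearson test on the candidate must NOT reject at
#' `alpha_norm`. Eliminated-loser groups pile up near ratio 0 and are
#' strongly skewed, so criterion (ii) screens out rescues that merely
#' shift a broken distribution.
#'
#' @param candidate,control Numeric ratio vectors (per-disc) or data
#'   frames accepted by [per_disc_ratio()].
#' @param alpha_ratio Significance level of the ratio-increase test.
#' @param alpha_norm Significance level of the normality criterion.
#' @param genotype Optional label for the candidate.
#' @return An object of class `suppressor_call`: `is_suppressor` (logical,
#'   or NA when the call is refused), `ratio_test_p`, `normality_p`,
#'   `alpha_ratio`, `alpha_norm`, `reason`.
#' @export
call_suppressor <- function(candidate, control, alpha_ratio = 0.05,
                            alpha_norm = 0.05, genotype = "candidate") {
  cand <- as_ratios(candidate)
  ctrl <- as_ratios(control)
  if (length(ctrl) < 1)
    stop("input error: empty control group", call. = FALSE)
  out <- list(genotype = genotype, is_suppressor = NA,
              ratio_test_p = NA_real_, normality_p = NA_real_,
              alpha_ratio = alpha_ratio, alpha_norm = alpha_norm,
              n_candidate = length(cand), n_control = length(ctrl),
              reason = NULL)
  class(out) <- "suppressor_call"
  if (length(cand) < 8) {
    out$reason <- "refused: candidate n < 8, normality test undefined"
    return(out)
  }
  out$ratio_test_p <- suppressWarnings(
    stats::wilcox.test(cand, ctrl, alternative = "greater")$p.value)
  norm_res <- tryCatch(dagostino_pearson(cand), error = function(e) NULL)
  if (is.null(norm_res)) {
    out$reason <- "refused: degenerate candidate sample (zero variance)"
    return(out)
  }
  out$normality_p <- norm_res$p_value
  out$is_suppressor <- (out$ratio_test_p < alpha_ratio) &&
    (out$normality_p >= alpha_norm)
  out
}

as_ratios <- function(x) {
  if (is.data.frame(x)) per_disc_ratio(x) else as.numeric(x)
}

#' @export
print.suppressor_call <- function(x, ...) {
  cat(sprintf("suppressor_call [%s]: %s\n", x$genotype,
              if (is.na(x$is_suppressor)) paste("NA -", x$reason)
              else if (x$is_suppressor) "SUPPRESSOR" else "not a suppressor"))
  cat(sprintf("  ratio increase: p = %.4g (alpha = %g, one-sided rank)\n",
              x$ratio_test_p, x$alpha_ratio))
  cat(sprintf("  normality:      p = %.4g (alpha = %g, must NOT reject)\n",
              x$normality_p, x$alpha_norm))
  invisible(x)
}

#' Paired ratio t-test
#'
#' The standard "paired ratio t-test" construction: a two-sided
#' one-sample t-test of the per-pair log ratios `log(treated/control)`
#' against 0. With identical pairs (all log ratios 0) p = 1; with a
#' constant non-unit ratio the t statistic is unbounded, reported as
#' p = 0 with a degeneracy flag.
#'
#' @param treated,control Positive paired measurements (e.g. mean
#'   fluorescence intensities), equal length n >= 2.
#' @return A list with `p_value`, `t`, `df`, `mean_log_ratio`,
#'   `degenerate`.
#' @export
paired_ratio_test <- function(treated, control) {
  treated <- as.numeric(treated); control <- as.numeric(control)
  if (length(treated) != length(control))
    stop("input error: treated/control must be paired", call. = FALSE)
  if (length(treated) < 2)
    stop("input error: need at least 2 pairs", call. = FALSE)
  if (any(treated <= 0) || any(control <= 0))
    stop("input error: intensities must be > 0", call. = FALSE)
  lr <- log(treated / control)
  if (stats::sd(lr) == 0) {
    if (all(lr == 0))
      return(list(p_value = 1, t = 0, df = length(lr) - 1,
                  mean_log_ratio = 0, degenerate = TRUE))
    return(list(p_value = 0, t = sign(lr[1]) * Inf, df = length(lr) - 1,
                mean_log_ratio = mean(lr), degenerate = TRUE))
  }
  tt <- stats::t.test(lr, mu = 0)
  list(p_value = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter), mean_log_ratio = mean(lr),
       degenerate = FALSE)
}
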