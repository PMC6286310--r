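#' Specification of a synthetic genome
#'
#' Parametrises the synthetic diploid genome annotation the pipeline runs
#' on: `n_genes` non-overlapping genes distributed over named arms, with
#' `n_hrpg` of them flagged as haploinsufficient ribosomal protein genes
#' (hRPGs) by uniform sampling without replacement across all genes, so
#' hRPGs end up broadly distributed across arms.
#'
#' @param n_genes Number of genes (>= 0).
#' @param n_hrpg Number of hRPG-flagged genes, `0 <= n_hrpg <= n_genes`.
#' @param arm_names Character vector of arm labels.
#' @param arm_length_bp Numeric vector of arm lengths in bp (recycled or
#'   matched to `arm_names`).
#' @param mean_gene_length_bp Mean generated gene length in bp.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_genes, n_hrpg, arm_names, arm_length_bp,
                        mean_gene_length_bp = 2000L, seed = 1L) {
  stopifnot(length(n_genes) == 1L, n_genes >= 0,
            length(n_hrpg) == 1L, n_hrpg >= 0,
            length(arm_names) >= 1L,
            all(arm_length_bp >= 1),
            length(mean_gene_length_bp) == 1L, mean_gene_length_bp >= 1,
            length(seed) == 1L)
  if (n_hrpg > n_genes)
    stop("spec error: n_hrpg exceeds n_genes", call. = FALSE)
  if (length(arm_length_bp) == 1L)
    arm_length_bp <- rep(arm_length_bp, length(arm_names))
  stopifnot(length(arm_length_bp) == length(arm_names))
  names(arm_length_bp) <- arm_names
  structure(list(n_genes = as.integer(n_genes),
                 n_hrpg = as.integer(n_hrpg),
                 arm_length_bp = arm_length_bp,
                 mean_gene_length_bp = as.numeric(mean_gene_length_bp),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome annotation
#'
#' Genes are apportioned to arms proportionally to arm length (largest
#' remainder), given lognormal lengths with the requested mean (sdlog
#' fixed at 0.75, mimicking the right-skew of real gene lengths), and
#' placed without overlap by distributing the free space of each arm into
#' random inter-gene gaps. Intergenic intervals (the gaps, including arm
#' ends) are recorded so intragenic-fraction computations have inputs.
#'
#' @param spec A [genome_spec()].
#' @return A [genome_annotation()] with exactly `n_genes` genes and
#'   `n_hrpg` hRPG flags.
#' @export
gen_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  arms <- names(spec$arm_length_bp)
  n <- spec$n_genes
  withr_seed(spec$seed, {
    per_arm <- apportion(n, spec$arm_length_bp)
    genes <- vector("list", length(arms))
    gaps <- vector("list", length(arms))
    next_id <- 1L
    for (i in seq_along(arms)) {
      arm <- arms[i]; len <- spec$arm_length_bp[[arm]]; k <- per_arm[i]
      if (k == 0) {
        genes[[i]] <- data.frame(gene_id = character(), arm = character(),
                                 start = numeric(), end = numeric())
        gaps[[i]] <- data.frame(arm = arm, start = 1, end = len)
        next
      }
      sdlog <- 0.75
      meanlog <- log(spec$mean_gene_length_bp) - sdlog^2 / 2
      glen <- pmax(1, round(stats::rlnorm(k, meanlog, sdlog)))
      free <- len - sum(glen)
      if (free < 0)
        stop("spec error: requested gene footprint does not fit on arm ",
             arm, call. = FALSE)
      # split free space into k + 1 gaps (arm ends included)
      gap <- as.numeric(stats::rmultinom(1, free, rep(1, k + 1)))
      start <- cumsum(gap[seq_len(k)] + c(0, glen[-k])) + 1
      end <- start + glen - 1
      ids <- sprintf("g%05d", seq(next_id, next_id + k - 1))
      next_id <- next_id + k
      genes[[i]] <- data.frame(gene_id = ids, arm = arm,
                               start = start, end = end)
      gap_start <- c(1, end + 1)
      gap_end <- c(start - 1, len)
      keep <- gap_end >= gap_start
      gaps[[i]] <- data.frame(arm = arm, start = gap_start[keep],
                              end = gap_end[keep])
    }
    genes <- do.call(rbind, genes)
    genes$is_hrpg <- logical(nrow(genes))
    if (spec$n_hrpg > 0)
      genes$is_hrpg[sample.int(n, spec$n_hrpg)] <- TRUE
    genome_annotation(genes, spec$arm_length_bp,
                      intergenic = do.call(rbind, gaps))
  })
}

# largest-remainder apportionment of n items over weights
apportion <- function(n, weights) {
  if (n == 0) return(integer(length(weights)))
  weights <- as.numeric(weights) # avoid integer overflow in n * weights
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic clone-area dataset
#'
#' Emulates twin-spot clone measurements from wing imaginal discs: per
#' disc, a winner (wild-type twin, GFP 2x) area and a loser (hRPG
#' heterozygous, mCherry) area. The winner area W is lognormal; the loser
#' area is `W * (1 - e) * exp(eps)` with `eps ~ Normal(0, noise_sd)`,
#' truncated at 0. Elimination strength `e = 0` gives loser/winner ratios
#' concentrated near 1 (rescued clones); `e -> 1` gives ratios near 0
#' (eliminated clones), matching the phenomenology of Minute cell
#' competition assays.
#'
#' @param genotype_label Genotype name attached to every disc.
#' @param n_discs Number of discs (>= 1).
#' @param elimination_strength `e` in `[0, 1]`.
#' @param winner_area_log_mean,winner_area_log_sd Lognormal parameters of
#'   the winner twin-spot area (log scale; area in arbitrary units^2).
#' @param noise_sd SD of the multiplicative lognormal measurement noise on
#'   the loser area (log scale).
#' @param seed Integer seed. Each disc draws from its own derived
#'   substream, so increasing `n_discs` extends the dataset without
#'   changing earlier discs.
#' @return An object of class `clone_dataset_spec`.
#' @export
clone_dataset_spec <- function(genotype_label, n_discs,
                               elimination_strength,
                               winner_area_log_mean = log(10000),
                               winner_area_log_sd = 0.35,
                               noise_sd = 0.1, seed = 1L) {
  stopifnot(is.character(genotype_label), length(genotype_label) == 1L,
            length(n_discs) == 1L, n_discs >= 1,
            length(elimination_strength) == 1L,
            elimination_strength >= 0, elimination_strength <= 1,
            noise_sd >= 0, winner_area_log_sd >= 0,
            length(seed) == 1L)
  structure(list(genotype_label = genotype_label,
                 n_discs = as.integer(n_discs),
                 elimination_strength = elimination_strength,
                 winner_area_log_mean = winner_area_log_mean,
                 winner_area_log_sd = winner_area_log_sd,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "clone_dataset_spec")
}

#' Generate synthetic clone-area measurements
#'
#' @param spec A [clone_dataset_spec()].
#' @return Data frame with columns `disc_id`, `genotype`, `loser_area`,
#'   `winner_area`, one row per disc.
#' @export
gen_clone_dataset <- function(spec) {
  stopifnot(inherits(spec, "clone_dataset_spec"))
  n <- spec$n_discs
  W <- numeric(n); L <- numeric(n)
  for (i in seq_len(n)) {
    d <- disc_draw(spec, i)
    W[i] <- d[1]; L[i] <- d[2]
  }
  data.frame(disc_id = sprintf("%s_disc%04d", spec$genotype_label,
                               seq_len(n)),
             genotype = spec$genotype_label,
             loser_area = L,
             winner_area = W)
}

# per-disc substream: a small derived seed keeps earlier discs stable
# when n_discs grows
disc_draw <- function(spec, i) {
  sub <- (as.numeric(spec$seed) * 48271 + i * 16807) %% 2147483647
  withr_seed(as.integer(sub), {
    W <- stats::rlnorm(1, spec$winner_area_log_mean, spec$winner_area_log_sd)
    eps <- if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    L <- max(0, W * (1 - spec$elimination_strength) * exp(eps))
    c(W, L)
  })
}

#' Recover the elimination strength from clone measurements
#'
#' Inverts the generative model's lognormal-noise mean identity
#' `E[L/W] = (1 - e) * exp(noise_sd^2 / 2)`:
#' `e_hat = 1 - mean(L/W) / exp(noise_sd^2 / 2)`.
#'
#' @param measurements Data frame with `loser_area`, `winner_area`.
#' @param noise_sd The generator's noise SD (log scale).
#' @return Estimated elimination strength.
#' @export
estimate_elimination_strength <- function(measurements, noise_sd = 0.1) {
  r <- per_disc_ratio(measurements)
  1 - mean(r) / exp(noise_sd^2 / 2)
}

#' Write clone measurements as CSV
#'
#' @param measurements Data frame from [gen_clone_dataset()] (or rbind of
#'   several).
#' @param path Output CSV path.
#' @export
write_clones_csv <- function(measurements, path) {
  stopifnot(all(c("disc_id", "genotype", "loser_area", "winner_area")
                %in% names(measurements)))
  utils::write.csv(measurements, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clones_csv
#' @export
read_clones_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("disc_id", "genotype", "loser_area", "winner_area")
                %in% names(df)))
  df
}
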