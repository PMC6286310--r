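#' Verify published construct and mapping interval lengths
#'
#' Recomputes, from a bundled table of published coordinate pairs
#' (FlyBase Dmel r6.08 dialect), the genomic-rescue construct lengths,
#' the RpL19 excision-deletion length, the Xrp1 mapping-interval length
#' and the Xrp1 frameshift insertion size, and checks each against its
#' published value at the printed precision.
#'
#' @param path Fixture TSV; defaults to the table shipped with the
#'   package (columns `label`, `kind` (interval/change), `value_text`,
#'   `arm`, `position`, `printed_value`, `unit`, `decimals`).
#' @return Data frame with columns `label`, `printed`, `computed`,
#'   `unit`, `match`. All rows of the bundled fixture must match.
#' @examples
#' verify_reference_intervals()
#' @export
verify_reference_intervals <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_intervals.tsv",
                        package = "caretakeR")
  fx <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(fx) == 0)
    return(data.frame(label = character(), printed = numeric(),
                      computed = numeric(), unit = character(),
                      match = logical()))
  computed <- vapply(seq_len(nrow(fx)), function(i) {
    row <- fx[i, ]
    if (row$kind == "interval") {
      interval_length_kb(parse_flybase_interval(row$value_text),
                         row$decimals)
    } else if (row$kind == "change") {
      net_length_change(parse_sequence_change(row$value_text, row$arm,
                                              row$position))
    } else stop("input error: unknown fixture kind '", row$kind, "'",
                call. = FALSE)
  }, numeric(1))
  data.frame(label = fx$label, printed = fx$printed_value,
             computed = computed, unit = fx$unit,
             match = computed == fx$printed_value)
}

#' Run the full desk-scale pipeline
#'
#' Executes the four stages in order on one set of synthetic inputs:
#' (1) synthetic genome + clone datasets, written as BED/TSV/CSV;
#' (2) binned gene density + intragenic percentage; (3) the Monte-Carlo
#' mutation race with its exact-recursion oracle; (4) genotype summaries
#' and suppressor calls against a named loser control. Deterministic for
#' a fixed config (same config, byte-identical outputs); a failing stage
#' leaves earlier outputs intact and is named in the report.
#'
#' @param config A list as returned by [default_pipeline_config()]:
#'   fields `genome` ([genome_spec()]), `clones` (list of
#'   [clone_dataset_spec()]), `control_genotype`, `mc`
#'   (list `G`, `H`, `reps`, `seed`, optional `budget`), `bin_size_bp`,
#'   `alpha_ratio`, `alpha_norm`.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `run_report`: `ok`, `stages` (status and
#'   output paths per stage), `failed_stage`, `config`. Also written as
#'   `run_report.json` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(ok = TRUE, failed_stage = NULL,
                 stages = list(), config = config_echo(config))
  run_stage <- function(name, fn) {
    if (!report$ok) {
      report$stages[[name]] <<- list(status = "skipped", outputs = list())
      return(invisible())
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      report$ok <<- FALSE
      report$failed_stage <<- name
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     outputs = list())
    } else {
      report$stages[[name]] <<- list(status = "ok", outputs = res)
    }
    invisible()
  }

  annotation <- NULL
  clones <- NULL
  run_stage("synthetic_data", function() {
    annotation <<- gen_genome(config$genome)
    bed <- file.path(out_dir, "genome.bed")
    tsv <- file.path(out_dir, "genome.tsv")
    write_annotation_bed(annotation, bed)
    write_annotation_tsv(annotation, tsv)
    clones <<- do.call(rbind, lapply(config$clones, gen_clone_dataset))
    csv <- file.path(out_dir, "clones.csv")
    write_clones_csv(clones, csv)
    list(genome_bed = bed, genome_tsv = tsv, clones_csv = csv)
  })

  run_stage("genome_intervals", function() {
    dens <- bin_gene_density(annotation, config$bin_size_bp)
    path <- file.path(out_dir, "gene_density.csv")
    utils::write.csv(dens, path, row.names = FALSE, quote = FALSE)
    pct <- intragenic_percentage(sum(annotation$arm_length_bp),
                                 annotation$intergenic)
    jpath <- file.path(out_dir, "genome_map.json")
    jsonlite::write_json(list(intragenic_percent = pct,
                              bin_size_bp = config$bin_size_bp,
                              n_bins = nrow(dens)),
                         jpath, auto_unbox = TRUE, digits = NA)
    list(density_csv = path, genome_map_json = jpath)
  })

  run_stage("caretaker_mc", function() {
    mc <- config$mc
    est <- race_probability_mc(mc$G, mc$H, reps = mc$reps,
                               seed = mc$seed, budget = mc$budget)
    path <- file.path(out_dir, "race.json")
    jsonlite::write_json(unclass(est), path, auto_unbox = TRUE,
                         digits = NA)
    list(race_json = path)
  })

  run_stage("competition_stats", function() {
    if (is.null(clones) || nrow(clones) == 0)
      stop("input error: no clone measurements generated", call. = FALSE)
    summ <- summarize_genotypes(clones)
    spath <- file.path(out_dir, "genotype_summary.csv")
    utils::write.csv(summ, spath, row.names = FALSE, quote = FALSE)
    ctrl <- clones[clones$genotype == config$control_genotype, ,
                   drop = FALSE]
    if (nrow(ctrl) == 0)
      stop("input error: control genotype '", config$control_genotype,
           "' absent from clone data", call. = FALSE)
    calls <- lapply(setdiff(unique(clones$genotype),
                            config$control_genotype), function(g) {
      cand <- clones[clones$genotype == g, , drop = FALSE]
      unclass(call_suppressor(cand, ctrl,
                              alpha_ratio = config$alpha_ratio,
                              alpha_norm = config$alpha_norm,
                              genotype = g))
    })
    cpath <- file.path(out_dir, "suppressor_calls.json")
    jsonlite::write_json(calls, cpath, auto_unbox = TRUE, digits = NA)
    list(summary_csv = spath, calls_json = cpath)
  })

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  report
}

config_echo <- function(config) {
  lapply(config, function(x) {
    if (inherits(x, c("genome_spec", "clone_dataset_spec"))) unclass(x)
    else if (is.list(x) && !is.null(names(x)) &&
             all(vapply(x, inherits, logical(1), "clone_dataset_spec")))
      lapply(x, unclass)
    else if (is.list(x) && is.null(names(x))) lapply(x, function(y)
      if (inherits(y, "clone_dataset_spec")) unclass(y) else y)
    else x
  })
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", if (x$ok) "OK" else paste("FAILED at", x$failed_stage),
      "\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-18s %s", s, st$status))
    if (!is.null(st$error)) cat(" -", st$error)
    cat("\n")
  }
  invisible(x)
}

#' Default demo configuration for [run_pipeline()]
#'
#' A desk-scale stand-in for the experimental design: a two-arm genome
#' with 66 hRPGs among 1000 genes, a loser control at high elimination
#' strength (e = 0.95), a rescued candidate (e = 0.05) and a partial
#' rescue (e = 0.5), group sizes matching the published figure
#' (n = 52, 47, 45), and a Drosophila-scale mutation race
#' (G = 14000, H = 66).
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param reps Monte-Carlo replicates for the race stage.
#' @return A config list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L, reps = 20000L) {
  seed <- as.integer(seed)
  list(genome = genome_spec(n_genes = 1000, n_hrpg = 66,
                            arm_names = c("2L", "2R"),
                            arm_length_bp = c(23e6, 25e6),
                            mean_gene_length_bp = 5000,
                            seed = seed),
       clones = list(
         clone_dataset_spec("loser_control", n_discs = 52,
                            elimination_strength = 0.95,
                            seed = seed + 101L),
         clone_dataset_spec("rescue_candidate", n_discs = 47,
                            elimination_strength = 0.05,
                            seed = seed + 202L),
         clone_dataset_spec("partial_rescue", n_discs = 45,
                            elimination_strength = 0.5,
                            seed = seed + 303L)),
       control_genotype = "loser_control",
       mc = list(G = 14000L, H = 66L, reps = as.integer(reps),
                 seed = seed + 404L, budget = NULL),
       bin_size_bp = 40000L,
       alpha_ratio = 0.05,
       alpha_norm = 0.05)
}
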