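#' Assemble and validate a pipeline configuration
#'
#' @param sim a [simulation_config()] for the cohort stage
#' @param stages character vector of stages to run, in dependency order;
#'   subset of simulate, traits, heritability, ewas, enrich, report
#' @param alpha_lrt twin model-selection LRT level
#' @param threshold heritability classification cut point
#' @param alpha_array family-wise level for the array-wide Bonferroni cutoff
#' @param ewas_subset which heritability class to scan: "low", "high", "all"
#' @param seed master seed (overrides the sim config seed)
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(sim = simulation_config(),
                            stages = c("simulate", "traits", "heritability",
                                       "ewas", "enrich", "report"),
                            alpha_lrt = 0.05, threshold = 0.35,
                            alpha_array = 0.05,
                            ewas_subset = c("low", "high", "all"),
                            seed = NULL) {
  ewas_subset <- match.arg(ewas_subset)
  known <- c("simulate", "traits", "heritability", "ewas", "enrich", "report")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (a in c(alpha_lrt, threshold, alpha_array))
    if (a <= 0 || a >= 1)
      stop("alpha levels and threshold must lie in (0, 1)", call. = FALSE)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, stages = stages, alpha_lrt = alpha_lrt,
                 threshold = threshold, alpha_array = alpha_array,
                 ewas_subset = ewas_subset, seed = sim$seed),
            class = "pipeline_config")
}

#' A small demonstration pipeline configuration
#'
#' 50 MZ + 50 DZ pairs, 200 probes, three planted methylation effects on the
#' low-heritability traits — large enough for the planted effects to be
#' recoverable, small enough to run in seconds.
#'
#' @param seed master seed
#' @return a `pipeline_config`
#' @export
demo_pipeline_config <- function(seed = 1L) {
  sim <- simulation_config(
    n_mz = 50, n_dz = 50,
    methyl_model = list(
      n_probes = 200L, family_var = 0.2,
      planted = data.frame(
        probe = c("cg0000001", "cg0000002", "cg0000003"),
        trait = c("trait_ce", "trait_ce_low", "trait_null"),
        beta = c(0.35, -0.36, 0.30),
        stringsAsFactors = FALSE)),
    seed = seed)
  pipeline_config(sim = sim, seed = seed)
}

stage_log <- function(verbose, ...) if (verbose) message("[twinglyco] ", ...)

#' Run the full twin glycomics pipeline
#'
#' Executes the enabled stages in dependency order — simulate a cohort,
#' derive glycan traits from the peak table, screen heritability, scan the
#' requested heritability class for methylation associations, test
#' enrichment across classes, and render a text report — writing each
#' stage's output as TSV into `out_dir` together with a YAML run manifest
#' (config snapshot, package version, seed, per-file checksums, durations).
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory
#' @param verbose log stage progress
#' @return invisibly, a list with the stage outputs and the manifest
#' @export
run_pipeline <- function(config = demo_pipeline_config(), out_dir,
                         verbose = TRUE) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  manifest <- list(package = "twinglyco",
                   version = as.character(packageVersion("twinglyco")),
                   seed = config$seed,
                   started = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   stages = list())
  out <- list()
  run_stage <- function(name, deps, fn) {
    if (!name %in% stages) return(invisible(NULL))
    missing_dep <- setdiff(deps, names(out))
    if (length(missing_dep))
      stop("stage '", name, "' requires disabled/failed stage(s): ",
           paste(missing_dep, collapse = ", "), call. = FALSE)
    t0 <- Sys.time()
    stage_log(verbose, "stage ", name, " ...")
    res <- tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    files <- attr(res, "files")
    manifest$stages[[name]] <<- list(
      status = "ok",
      duration_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                         2),
      outputs = as.list(setNames(unname(md5sum(files)), basename(files))))
    attr(res, "files") <- NULL
    out[[name]] <<- res
    invisible(NULL)
  }

  run_stage("simulate", character(0), function() {
    cohort <- simulate_cohort(config$sim)
    files <- write_cohort(cohort, out_dir)
    stage_log(verbose, "  ", nrow(cohort$pairs), " pairs, ",
              ncol(cohort$traits), " traits, ", ncol(cohort$methyl),
              " probes")
    structure(cohort, files = unname(files))
  })
  run_stage("traits", "simulate", function() {
    tm <- suppressMessages(compute_all_traits(out$simulate$peaks))
    f <- file.path(out_dir, "glycan_traits.tsv")
    write_tsv(matrix_to_table(tm), f)
    stage_log(verbose, "  ", ncol(tm), " glycan traits from ",
              ncol(out$simulate$peaks), " peaks")
    structure(list(matrix = tm), files = f)
  })
  run_stage("heritability", "simulate", function() {
    her <- heritability_screen(out$simulate$traits, out$simulate$pairs,
                               covariates = out$simulate$covariates,
                               alpha = config$alpha_lrt,
                               threshold = config$threshold)
    f <- file.path(out_dir, "heritability.tsv")
    write_tsv(her, f)
    stage_log(verbose, "  ", nrow(her), " traits screened; ",
              sum(her$class == "low"), " low heritability")
    structure(her, files = f)
  })
  run_stage("ewas", c("simulate", "heritability"), function() {
    her <- out$heritability
    traits <- if (config$ewas_subset == "all") her$trait
              else her$trait[her$class == config$ewas_subset]
    if (!length(traits))
      stop("no traits in requested subset '", config$ewas_subset, "'",
           call. = FALSE)
    methyl <- standardize_probes(out$simulate$methyl)
    bonf <- bonferroni_threshold(config$alpha_array, ncol(methyl))
    assoc <- run_ewas(out$simulate$traits, traits, methyl,
                      covariates = out$simulate$covariates,
                      annotation = out$simulate$methyl_annotation,
                      threshold = bonf$threshold)
    f <- file.path(out_dir, "associations.tsv")
    write_tsv(assoc, f)
    stage_log(verbose, "  ", nrow(assoc), " tests, ",
              sum(assoc$significant), " significant at ",
              format(bonf$reported))
    structure(list(associations = assoc, threshold = bonf), files = f)
  })
  run_stage("enrich", c("heritability", "ewas"), function() {
    cls <- classify_heritability(out$heritability, config$threshold)
    tab <- build_contingency(cls, out$ewas$associations)
    res <- compare_proportions(tab)
    df <- data.frame(class = rownames(tab), hits = tab[, 1],
                     traits = rowSums(tab),
                     percent = res$proportions_report,
                     p_exact = res$p_exact, p_chisq = res$p_chisq,
                     odds_ratio = res$odds_ratio)
    f <- file.path(out_dir, "enrichment.tsv")
    write_tsv(df, f)
    structure(list(table = tab, result = res), files = f)
  })
  run_stage("report", c("heritability", "ewas"), function() {
    lines <- render_report(out$heritability, out$ewas$associations,
                           if ("enrich" %in% names(out)) out$enrich else NULL)
    f <- file.path(out_dir, "report.txt")
    writeLines(lines, f)
    structure(list(lines = lines), files = f)
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$trait_specs <- as.list(as.data.frame(cfg$sim$trait_specs))
  cfg$sim$peak_model$means <- as.list(cfg$sim$peak_model$means)
  cfg$sim$methyl_model$planted <- as.list(cfg$sim$methyl_model$planted)
  manifest$config <- cfg
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  out$manifest <- manifest
  invisible(out)
}

#' Render a plain-text report of the pipeline results
#'
#' Heritability rows are formatted in the conventional twin-table layout
#' (mean (SD), ICC and component estimates as `0.70[0.64,0.75]`); p-values
#' below 1e-4 are printed in scientific `1.19x10^-9` style.
#'
#' @param heritability heritability screen table
#' @param associations association table from [run_ewas()]
#' @param enrichment optional enrich-stage output
#' @return character vector of report lines
#' @export
render_report <- function(heritability, associations, enrichment = NULL) {
  lines <- c("Twin glycomics pipeline report", "")
  lines <- c(lines, "Heritability (best model, standardized shares):")
  hdr <- sprintf("%-14s %-14s %-17s %-14s %-17s %-5s %-17s %-17s %-17s",
                 "Trait", "MZ mean(SD)", "ICC MZ[95%CI]", "DZ mean(SD)",
                 "ICC DZ[95%CI]", "Model", "A[95%CI]", "C[95%CI]",
                 "E[95%CI]")
  lines <- c(lines, hdr)
  comp_fmt <- function(est, lo, hi, absent) {
    if (absent) "" else if (is.na(lo)) sprintf("%.2f", est)
    else format_ci(est, lo, hi)
  }
  for (i in seq_len(nrow(heritability))) {
    h <- heritability[i, ]
    lines <- c(lines, sprintf(
      "%-14s %-14s %-17s %-14s %-17s %-5s %-17s %-17s %-17s",
      h$trait,
      sprintf("%.2f(%.2f)", h$mz_mean, h$mz_sd),
      format_ci(h$icc_mz, h$icc_mz_lo, h$icc_mz_hi),
      sprintf("%.2f(%.2f)", h$dz_mean, h$dz_sd),
      format_ci(h$icc_dz, h$icc_dz_lo, h$icc_dz_hi),
      h$model,
      comp_fmt(h$a2, h$a2_lo, h$a2_hi, h$model %in% c("CE", "E")),
      comp_fmt(h$c2, h$c2_lo, h$c2_hi, h$model %in% c("AE", "E")),
      comp_fmt(h$e2, h$e2_lo, h$e2_hi, FALSE)))
  }
  lines <- c(lines, "", "Array-wide significant associations:")
  sig <- associations[which(associations$significant), , drop = FALSE]
  if (nrow(sig) == 0L) {
    lines <- c(lines, "  zero array-wide hits")
  } else {
    lines <- c(lines, sprintf("%-12s %-4s %-12s %-10s %-24s %6s %6s %-10s",
                              "Probe", "Chr", "Map position", "nearest gene",
                              "Glycan", "Beta", "SE", "P"))
    for (i in seq_len(nrow(sig))) {
      s <- sig[i, ]
      lines <- c(lines, sprintf(
        "%-12s %-4s %-12s %-10s %-24s %6.2f %6.2f %-10s",
        s$probe, as.character(s$chr), as.character(s$position), s$gene,
        s$trait, s$beta, s$se, format_pval(s$p)))
    }
  }
  if (!is.null(enrichment)) {
    res <- enrichment$result
    tab <- enrichment$table
    lines <- c(lines, "", sprintf(
      paste0("Enrichment: %.1f%% of low-heritability traits carry an ",
             "array-wide hit (%d/%d) vs %.1f%% of high-heritability traits ",
             "(%d/%d); one-sided exact p = %s (chi-square p = %s)."),
      res$proportions_report[1], tab[1, 1], sum(tab[1, ]),
      res$proportions_report[2], tab[2, 1], sum(tab[2, ]),
      format_pval(res$p_exact), format_pval(res$p_chisq)))
  }
  lines
}
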