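# One-call orchestration of the analysis stages with deterministic TSV
# outputs and a run log.

.default_pipeline_config <- function() {
  list(
    gene_annotation = NULL, gene_annotation_format = "gtf",
    mirna_annotation = NULL,
    fusion_calls = NULL, fusion_dialect = "generic",
    mirna_expression = NULL, gene_expression = NULL,
    min_tumors = 3, downstream_bp = 2000, same_strand = TRUE,
    biotype_filter = "protein_coding", expressed_min_median = 1,
    fpkm_pseudocount = 0.1, cpm_pseudocount = 1,
    min_fused = 2, direction_filter = TRUE,
    universe = "assigned_hosts", seed = 1L)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are an error; missing keys take the documented defaults
#' (see [run_pipeline()]).
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- .default_pipeline_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(user)] <- user
  cfg
}

.stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  res
}

#' Run the full miRNA-fusion analysis pipeline
#'
#' Executes filter, host assignment, inclusion mapping, recurrence /
#' convergence summaries, enrichment modelling and (when expression
#' matrices are configured) the differential-expression screen, writing
#' one deterministic TSV per result table plus a `run_log.yaml`
#' recording thresholds and per-stage record counts. Any stage error
#' aborts with the stage name in the message.
#'
#' @param config configuration list or path to a YAML file; required
#'   keys are `gene_annotation`, `mirna_annotation` and `fusion_calls`
#'   (file paths). Optional: `mirna_expression`, `gene_expression`,
#'   `fusion_dialect`, `gene_annotation_format`, and the thresholds
#'   `min_tumors` (3), `downstream_bp` (2000), `same_strand`,
#'   `biotype_filter`, `expressed_min_median`, `fpkm_pseudocount`,
#'   `cpm_pseudocount`, `min_fused`, `direction_filter`, `seed`.
#' @param out_dir report directory (created if missing).
#' @return invisible list with every computed object and the log.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  cfg <- .default_pipeline_config()
  cfg[names(config)] <- config
  for (key in c("gene_annotation", "mirna_annotation", "fusion_calls")) {
    if (is.null(cfg[[key]])) stop("config key ", key, " is required")
    if (!file.exists(cfg[[key]])) stop(key, " path not found: ", cfg[[key]])
  }
  stopifnot(cfg$min_tumors >= 1, cfg$downstream_bp >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(thresholds = cfg[c("min_tumors", "downstream_bp", "same_strand",
                                 "biotype_filter", "expressed_min_median",
                                 "min_fused", "seed")],
              counts = list())
  note <- function(k, v) log$counts[[k]] <<- v

  genes <- .stage("read_genes", log,
                  read_gene_annotation(cfg$gene_annotation,
                                       cfg$gene_annotation_format))
  note("genes", length(genes))
  mirnas <- .stage("read_mirnas", log, read_mirna_annotation(cfg$mirna_annotation))
  note("mirnas", length(mirnas))
  calls <- .stage("read_fusions", log,
                  read_fusion_calls(cfg$fusion_calls, cfg$fusion_dialect))
  note("fusion_calls_raw", nrow(calls))
  note("fusion_calls_rejected", nrow(attr(calls, "rejected")))

  filtered <- .stage("filter", log, filter_fusion_calls(calls))
  note("fusion_calls_filtered", nrow(filtered))
  filtered <- dedupe_fusion_calls(filtered)
  note("fusion_calls_deduped", nrow(filtered))

  asg <- .stage("assign_hosts", log,
                assign_hosts(mirnas, genes, downstream_bp = cfg$downstream_bp,
                             same_strand = cfg$same_strand))
  note("hosts_intragenic", sum(asg$relation == "intragenic"))
  note("hosts_downstream2kb", sum(asg$relation == "downstream2kb"))
  write_table(asg, file.path(out_dir, "host_assignments.tsv"))

  events <- .stage("map_fusions", log,
                   map_mirnas_to_fusions(filtered, asg, mirnas, genes,
                                         downstream_bp = cfg$downstream_bp))
  note("events", nrow(events))
  note("events_included", sum(events$included))
  write_table(events, file.path(out_dir, "mirna_fusion_events.tsv"))

  rec <- .stage("recurrence", log,
                recurrence_summary(events, min_tumors = cfg$min_tumors))
  write_table(rec, file.path(out_dir, "recurrence_summary.tsv"))
  census <- recurrence_census(rec, min_tumors = cfg$min_tumors)
  write_table(census, file.path(out_dir, "recurrence_census.tsv"), sort = FALSE)
  conv <- .stage("convergence", log,
                 convergence_table(events, min_tumors = cfg$min_tumors))
  write_table(conv, file.path(out_dir, "convergence_table.tsv"), sort = FALSE)
  note("mirnas_fused_ge1", nrow(rec))
  note("mirnas_recurrent", sum(rec$recurrent_any))

  gene_expr <- if (!is.null(cfg$gene_expression))
    .stage("read_gene_expression", log,
           read_expression_matrix(cfg$gene_expression, "fpkm")) else NULL
  gtab <- .stage("gene_table", log,
                 build_gene_table(genes, asg, filtered, expression = gene_expr,
                                  biotype_filter = cfg$biotype_filter,
                                  min_tumors = cfg$min_tumors,
                                  expressed_min_median = cfg$expressed_min_median))
  note("gene_table_rows", nrow(gtab))
  write_table(gtab, file.path(out_dir, "gene_table.tsv"))

  fits <- .stage("enrichment", log, {
    f1 <- fit_logistic(gtab, with_interaction = FALSE)
    f2 <- fit_logistic(gtab, with_interaction = TRUE)
    f3 <- fit_logistic(gtab, with_interaction = FALSE,
                       outcome = "fused_recurrent")
    f4 <- fit_logistic(gtab, with_interaction = TRUE,
                       outcome = "fused_recurrent")
    list(any = f1, any_interaction = f2, recurrent = f3,
         recurrent_interaction = f4)
  })
  fit_rows <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    or <- if (!f$with_interaction && f$converged)
      size_adjusted_odds_ratio(f) else NULL
    data.frame(model = nm,
               beta0 = f$coefficients[["beta0"]],
               betaH = f$coefficients[["betaH"]],
               betaS = f$coefficients[["betaS"]],
               betaHS = f$coefficients[["betaHS"]],
               se_betaH = f$se[["betaH"]],
               wald_p_betaH = f$wald_p[["betaH"]],
               odds_ratio = if (is.null(or)) NA_real_ else or$odds_ratio,
               or_ci_low = if (is.null(or)) NA_real_ else or$ci_low,
               or_ci_high = if (is.null(or)) NA_real_ else or$ci_high,
               crossover_bp = f$crossover_bp, converged = f$converged,
               stringsAsFactors = FALSE)
  }))
  write_table(fit_rows, file.path(out_dir, "logistic_fits.tsv"), sort = FALSE)

  fractions <- .stage("content_fractions", log,
                      mirna_content_fractions(filtered, asg, mirnas, genes,
                                              downstream_bp = cfg$downstream_bp))
  write_table(fractions, file.path(out_dir, "mirna_content_fractions.tsv"),
              sort = FALSE)
  inframe <- .stage("inframe_analysis", log,
                    inframe_fraction_analysis(filtered, asg, mirnas, genes,
                                              downstream_bp = cfg$downstream_bp))
  write_table(inframe$per_gene, file.path(out_dir, "inframe_per_gene.tsv"))
  write_table(inframe$cdf, file.path(out_dir, "inframe_cdf.tsv"), sort = FALSE)

  de <- NULL
  if (!is.null(cfg$mirna_expression)) {
    cpm <- .stage("read_mirna_expression", log,
                  read_expression_matrix(cfg$mirna_expression, "cpm"))
    de <- .stage("de_screen", log,
                 de_screen(events, mirnas, asg, cpm,
                           min_fused = cfg$min_fused,
                           pseudocount = cfg$cpm_pseudocount,
                           direction_filter = cfg$direction_filter))
    if (!is.null(de)) {
      note("de_tests", nrow(de))
      note("de_significant_bonferroni",
           sum(!de$skipped & de$p_bonferroni < 0.05, na.rm = TRUE))
      write_table(de, file.path(out_dir, "de_results.tsv"), sort = FALSE)
    }
  }

  log$package_version <- as.character(utils::packageVersion("mirfusion"))
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(list(config = cfg, genes = genes, mirnas = mirnas,
                 assignments = asg, calls = filtered, events = events,
                 recurrence = rec, census = census, convergence = conv,
                 gene_table = gtab, fits = fits, fit_table = fit_rows,
                 fractions = fractions, inframe = inframe, de = de,
                 log = log, out_dir = out_dir))
}
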