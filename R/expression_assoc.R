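# Mature-miRNA expression versus host-gene fusion status.

# pooled- or Welch-variance two-sided t test that degrades gracefully when
# both groups are constant
.safe_t_test <- function(x, y, var_equal = TRUE) {
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2L))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                df = length(x) + length(y) - 2L))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Partition tumors by host-gene fusion status for one miRNA
#'
#' Splits the sample set into tumors with at least one included 3'
#' host-gene fusion event for the hairpin (`fused_3p`), tumors with
#' included 5' events only (`fused_5p_only`), and the remainder
#' (`no_host_fusion`). The partition is disjoint and covers `samples`.
#'
#' @param events output of [map_mirnas_to_fusions()].
#' @param mirna_id hairpin identifier.
#' @param samples character vector of all samples with expression data.
#' @param assignments optional host assignments; when given, a hairpin
#'   without an assigned host gene is an error.
#' @return named list of three disjoint character vectors.
#' @export
group_samples_by_fusion_status <- function(events, mirna_id, samples,
                                           assignments = NULL) {
  if (!is.null(assignments)) {
    rel <- assignments$relation[assignments$mirna_id == mirna_id]
    if (length(rel) == 0L || all(rel == "unassigned"))
      stop("miRNA ", mirna_id, " has no assigned host gene")
  }
  ev <- events[events$included & events$mirna_id == mirna_id, , drop = FALSE]
  s3 <- intersect(samples, unique(ev$sample_id[ev$role == "3p"]))
  s5 <- setdiff(intersect(samples, unique(ev$sample_id[ev$role == "5p"])), s3)
  list(fused_3p = sort(s3), fused_5p_only = sort(s5),
       no_host_fusion = sort(setdiff(samples, c(s3, s5))))
}

#' Differential mature-miRNA expression by fusion status
#'
#' Two-sided Student t-test (pooled variance by default; Welch behind
#' `var_equal = FALSE`) on log2(cpm + pseudocount) between tumors with
#' 3' host-gene fusions and a comparison group, for each mature miRNA.
#' Bonferroni adjustment is applied across the tested set. A test whose
#' groups have fewer than 2 samples each is skipped (flagged, not
#' dropped).
#'
#' @param partition output of [group_samples_by_fusion_status()].
#' @param expr cpm matrix (mature miRNAs x samples).
#' @param mature_ids rows to test (default: all rows of `expr`).
#' @param pseudocount added before log2 (default 1).
#' @param compare comparison group: `"no_host_fusion"` (default) or
#'   `"fused_5p_only"`.
#' @param var_equal pooled variance (classic Student) when `TRUE`.
#' @return data frame: `mature_id`, `n_fused`, `n_unfused`,
#'   `mean_fused`, `mean_unfused`, `t_stat`, `p_value`, `p_bonferroni`,
#'   `skipped`.
#' @export
mirna_de_by_fusion_status <- function(partition, expr, mature_ids = NULL,
                                      pseudocount = 1,
                                      compare = c("no_host_fusion",
                                                  "fused_5p_only"),
                                      var_equal = TRUE) {
  compare <- match.arg(compare)
  if (is.null(mature_ids)) mature_ids <- rownames(expr)
  g1 <- intersect(partition$fused_3p, colnames(expr))
  g0 <- intersect(partition[[compare]], colnames(expr))
  rows <- lapply(mature_ids, function(id) {
    if (!id %in% rownames(expr))
      return(data.frame(mature_id = id, n_fused = length(g1),
                        n_unfused = length(g0), mean_fused = NA_real_,
                        mean_unfused = NA_real_, t_stat = NA_real_,
                        p_value = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    x1 <- log2(expr[id, g1] + pseudocount)
    x0 <- log2(expr[id, g0] + pseudocount)
    # too-small groups, or a feature with no variation at all (e.g. zero
    # counts everywhere), cannot be tested
    skipped <- length(x1) < 2L || length(x0) < 2L ||
      stats::sd(c(x1, x0)) == 0
    tt <- if (skipped) list(t = NA_real_, p = NA_real_) else
      .safe_t_test(x1, x0, var_equal = var_equal)
    data.frame(mature_id = id, n_fused = length(x1), n_unfused = length(x0),
               mean_fused = if (length(x1)) mean(x1) else NA_real_,
               mean_unfused = if (length(x0)) mean(x0) else NA_real_,
               t_stat = tt$t, p_value = tt$p, skipped = skipped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * sum(!out$skipped))
  out <- out[, c("mature_id", "n_fused", "n_unfused", "mean_fused",
                 "mean_unfused", "t_stat", "p_value", "p_bonferroni",
                 "skipped")]
  rownames(out) <- NULL
  out
}

#' Cohort-wide screen for fusion-upregulated miRNAs
#'
#' Runs [group_samples_by_fusion_status()] and
#' [mirna_de_by_fusion_status()] for every assigned hairpin with at
#' least `min_fused` expression-profiled tumors carrying an included 3'
#' host-gene fusion, testing the hairpin's mature miRNAs. Bonferroni
#' adjustment spans all computed tests in the screen. With
#' `direction_filter` only upregulated miRNAs
#' (`mean_fused > mean_unfused`) are kept, after adjustment.
#'
#' @param events output of [map_mirnas_to_fusions()].
#' @param mirnas hairpin GRanges (provides `mature_ids`).
#' @param assignments host assignments.
#' @param expr cpm matrix.
#' @param min_fused minimum fused group size (default 2).
#' @param pseudocount log2 pseudocount.
#' @param direction_filter keep upregulated results only (default
#'   `TRUE`).
#' @param var_equal pooled variance (default `TRUE`).
#' @return data frame as from [mirna_de_by_fusion_status()] plus
#'   `mirna_id` and `host_gene_id`, ordered by `p_value`.
#' @export
de_screen <- function(events, mirnas, assignments, expr, min_fused = 2,
                      pseudocount = 1, direction_filter = TRUE,
                      var_equal = TRUE) {
  asg <- assignments[assignments$relation != "unassigned", , drop = FALSE]
  samples <- colnames(expr)
  inc3 <- events[events$included & events$role == "3p" &
                   events$sample_id %in% samples, , drop = FALSE]
  n3 <- tapply(inc3$sample_id, inc3$mirna_id, function(s) length(unique(s)))
  todo <- names(n3)[n3 >= min_fused]
  todo <- todo[todo %in% asg$mirna_id]
  res <- do.call(rbind, lapply(todo, function(mid) {
    part <- group_samples_by_fusion_status(events, mid, samples)
    mat <- unlist(mirnas$mature_ids[match(mid, mirnas$mirna_id)])
    mat <- intersect(mat, rownames(expr))
    if (length(mat) == 0L) return(NULL)
    r <- mirna_de_by_fusion_status(part, expr, mature_ids = mat,
                                   pseudocount = pseudocount,
                                   var_equal = var_equal)
    r$mirna_id <- mid
    r$host_gene_id <- asg$gene_id[match(mid, asg$mirna_id)]
    r
  }))
  if (is.null(res) || nrow(res) == 0L) return(res)
  res$p_bonferroni <- pmin(1, res$p_value * sum(!res$skipped))
  if (direction_filter)
    res <- res[res$skipped | (!is.na(res$mean_fused) &
                                res$mean_fused > res$mean_unfused), ,
               drop = FALSE]
  res <- res[order(res$p_value, res$mature_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
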