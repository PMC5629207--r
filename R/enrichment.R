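# Host-status x gene-size logistic enrichment model, crossover sizes,
# control-element comparisons, and the in-frame / 5'-partner expression
# analyses.

#' Build the per-gene table for enrichment modelling
#'
#' One record per gene passing the biotype and expression filters, with
#' the covariates of the fusion-probability model: host status,
#' log2(gene size), fusion outcome flags, and per-element-class
#' indicator columns. A gene counts as expressed when its median
#' expression across samples is at least `expressed_min_median` (genes
#' absent from the matrix are dropped); pass `expression = NULL` to skip
#' the filter. `fused_recurrent` requires fusions in at least
#' `min_tumors` distinct tumors with the gene in the same (5' or 3')
#' role.
#'
#' @param genes gene GRanges.
#' @param assignments host assignments from [assign_hosts()].
#' @param calls filtered (and ideally deduplicated) fusion calls.
#' @param expression gene expression matrix (FPKM) or `NULL`.
#' @param biotype_filter keep genes of this biotype (default
#'   `protein_coding`; `NULL` keeps all).
#' @param min_tumors recurrence threshold (default 3).
#' @param expressed_min_median median-FPKM floor for the expression
#'   filter (default 1).
#' @param elements optional GRanges of control elements with an
#'   `element_class` column; adds one `element_<class>` indicator per
#'   class (element fully within the gene span).
#' @return data frame: `gene_id`, `is_host`, `log2_size`, `fused_any`,
#'   `fused_recurrent`, `n_tumors_any`, plus element indicator columns.
#' @export
build_gene_table <- function(genes, assignments, calls, expression = NULL,
                             biotype_filter = "protein_coding",
                             min_tumors = 3, expressed_min_median = 1,
                             elements = NULL) {
  keep <- rep(TRUE, length(genes))
  if (!is.null(biotype_filter))
    keep <- keep & !is.na(genes$biotype) & genes$biotype %in% biotype_filter
  if (!is.null(expression)) {
    med <- apply(expression, 1L, stats::median)
    expressed <- names(med)[med >= expressed_min_median]
    keep <- keep & genes$gene_id %in% expressed
  }
  g <- genes[keep]
  if (length(g) == 0L) stop("no genes pass the biotype/expression filters")

  unknown <- setdiff(unique(c(calls$gene5_id, calls$gene3_id)), genes$gene_id)
  unknown <- unknown[!is.na(unknown)]
  if (length(unknown))
    warning(length(unknown), " fusion partner gene(s) absent from the ",
            "annotation are skipped in the gene table")

  host_genes <- unique(assignments$gene_id[assignments$relation != "unassigned"])
  calls <- dedupe_fusion_calls(calls)
  n5 <- tapply(calls$sample_id, calls$gene5_id,
               function(s) length(unique(s)))
  n3 <- tapply(calls$sample_id, calls$gene3_id,
               function(s) length(unique(s)))
  pair <- unique(rbind(
    data.frame(gene_id = calls$gene5_id, sample_id = calls$sample_id,
               stringsAsFactors = FALSE),
    data.frame(gene_id = calls$gene3_id, sample_id = calls$sample_id,
               stringsAsFactors = FALSE)))
  pair <- pair[!is.na(pair$gene_id), , drop = FALSE]
  nany <- tapply(pair$sample_id, pair$gene_id, function(s) length(unique(s)))

  gid <- g$gene_id
  get0 <- function(tab) {
    v <- as.integer(tab[gid]); v[is.na(v)] <- 0L; v
  }
  out <- data.frame(
    gene_id = gid,
    is_host = gid %in% host_genes,
    log2_size = log2(width(g)),
    n_tumors_any = get0(nany),
    stringsAsFactors = FALSE)
  out$fused_any <- out$n_tumors_any >= 1L
  out$fused_recurrent <- pmax(get0(n5), get0(n3)) >= min_tumors

  if (!is.null(elements) && length(elements)) {
    if (is.null(elements$element_class))
      stop("elements need an element_class column")
    ov <- suppressWarnings(findOverlaps(elements, g, type = "within",
                                        ignore.strand = TRUE))
    cls <- as.character(elements$element_class)[queryHits(ov)]
    for (cl in sort(unique(as.character(elements$element_class)))) {
      col <- paste0("element_", cl)
      out[[col]] <- seq_along(g) %in% unique(subjectHits(ov)[cls == cl])
    }
  }
  rownames(out) <- NULL
  out
}

.crossover_bp <- function(betaH, betaHS) {
  if (is.na(betaH) || is.na(betaHS) || betaHS == 0) return(NA_real_)
  if (betaHS >= 0 && betaH >= 0) return(NA_real_)  # host advantage at all sizes
  2^(-betaH / betaHS)
}

#' Fit the fusion-probability logistic model
#'
#' Maximum-likelihood logistic regression of a fusion outcome on a
#' binary gene feature (host status by default) and log2 gene size,
#' optionally with their interaction:
#' `fused ~ feature + log2(size) (+ feature:log2(size))`. Fitting is by
#' iteratively reweighted least squares (tolerance 1e-8, at most 50
#' iterations). Wald p-values use the normal approximation on
#' coefficient / standard error. With the interaction, the crossover
#' size — the gene size at which host and non-host predicted
#' probabilities are equal — is `2^(-betaH/betaHS)`; it is reported
#' absent when the interaction is zero or when `betaH >= 0` and
#' `betaHS >= 0` (host advantage at every size, nothing to extrapolate).
#'
#' @param table gene table from [build_gene_table()].
#' @param with_interaction include the feature-by-size interaction.
#' @param outcome outcome column (default `fused_any`).
#' @param predictor binary feature column (default `is_host`).
#' @param size_col log2-size column (default `log2_size`).
#' @return object of class `logistic_fit`: `coefficients`
#'   (`beta0`, `betaH`, `betaS`, `betaHS`), `se`, `wald_p`, `converged`,
#'   `crossover_bp`, `n`, `with_interaction`, and the underlying `glm`
#'   fit.
#' @export
fit_logistic <- function(table, with_interaction = FALSE,
                         outcome = "fused_any", predictor = "is_host",
                         size_col = "log2_size") {
  df <- data.frame(y = as.integer(as.logical(table[[outcome]])),
                   h = as.numeric(table[[predictor]]),
                   s = as.numeric(table[[size_col]]))
  if (anyNA(df)) stop("missing values in model columns")
  if (length(unique(df$y)) < 2L) stop("outcome has a single class")
  if (length(unique(df$h)) < 2L || length(unique(df$s)) < 2L)
    stop("constant predictor")
  fml <- if (with_interaction) y ~ h * s else y ~ h + s
  fit <- stats::glm(fml, family = binomial(), data = df,
                    control = glm.control(epsilon = 1e-8, maxit = 50))
  sm <- summary(fit)$coefficients
  pick <- function(nm) if (nm %in% rownames(sm)) sm[nm, ] else rep(NA_real_, 4L)
  co <- rbind(beta0 = pick("(Intercept)"), betaH = pick("h"),
              betaS = pick("s"), betaHS = pick("h:s"))
  converged <- isTRUE(fit$converged) &&
    all(abs(co[, 1L]) < 25, na.rm = TRUE) && all(co[, 2L] < 50, na.rm = TRUE)
  crossover <- if (with_interaction)
    .crossover_bp(co["betaH", 1L], co["betaHS", 1L]) else NA_real_
  structure(list(
    coefficients = co[, 1L], se = co[, 2L],
    wald_p = 2 * stats::pnorm(-abs(co[, 1L] / co[, 2L])),
    converged = converged, crossover_bp = crossover,
    with_interaction = with_interaction, n = nrow(df),
    outcome = outcome, predictor = predictor, glm_fit = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit: %s ~ %s + log2(size)%s  (n = %d%s)\n",
              x$outcome, x$predictor,
              if (x$with_interaction) " + interaction" else "", x$n,
              if (x$converged) "" else ", NOT converged"))
  tab <- cbind(estimate = x$coefficients, se = x$se, wald_p = x$wald_p)
  print(round(tab[!is.na(tab[, 1L]), , drop = FALSE], 4L))
  if (!is.na(x$crossover_bp))
    cat(sprintf("crossover size: %.3g kb\n", x$crossover_bp / 1000))
  invisible(x)
}

#' Size-adjusted odds ratio for the binary feature
#'
#' `exp(betaH)` from a no-interaction fit, with the Wald confidence
#' interval `exp(betaH +/- z * se)`.
#'
#' @param fit converged `logistic_fit` without interaction.
#' @param conf_level confidence level (default 0.95).
#' @return named list `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
size_adjusted_odds_ratio <- function(fit, conf_level = 0.95) {
  stopifnot(is(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge")
  bH <- fit$coefficients[["betaH"]]
  se <- fit$se[["betaH"]]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = exp(bH), ci_low = exp(bH - z * se),
       ci_high = exp(bH + z * se), p_value = fit$wald_p[["betaH"]])
}

#' Select control element classes occurring at a miRNA-like rate
#'
#' Given a gene table with `element_<class>` indicator columns, selects
#' the classes whose per-gene occurrence rate lies within a relative
#' tolerance of the target rate (by default the host-gene rate in the
#' table) and refits the logistic model substituting each selected
#' element indicator for host status.
#'
#' @param gene_table output of [build_gene_table()] with element columns.
#' @param target_rate target occurrence rate; default `mean(is_host)`.
#' @param rel_tol relative tolerance (default 0.25).
#' @param outcome outcome column for the refits.
#' @param with_interaction include the size interaction in refits.
#' @return list: `rates` (data frame `class`, `rate`, `selected`),
#'   `target_rate`, and `fits` (named list of `logistic_fit` for the
#'   selected classes).
#' @export
select_control_elements <- function(gene_table, target_rate = NULL,
                                    rel_tol = 0.25, outcome = "fused_any",
                                    with_interaction = TRUE) {
  cols <- grep("^element_", names(gene_table), value = TRUE)
  if (length(cols) == 0L)
    return(list(rates = data.frame(class = character(0), rate = numeric(0),
                                   selected = logical(0)),
                target_rate = target_rate, fits = list()))
  if (is.null(target_rate)) target_rate <- mean(gene_table$is_host)
  rate <- vapply(cols, function(cl) mean(gene_table[[cl]]), numeric(1))
  selected <- abs(rate - target_rate) <= rel_tol * target_rate
  fits <- lapply(cols[selected], function(cl)
    fit_logistic(gene_table, with_interaction = with_interaction,
                 outcome = outcome, predictor = cl))
  names(fits) <- sub("^element_", "", cols[selected])
  list(rates = data.frame(class = sub("^element_", "", cols),
                          rate = unname(rate), selected = unname(selected),
                          stringsAsFactors = FALSE),
       target_rate = target_rate, fits = fits)
}

#' In-frame fusion fraction by miRNA content of the fused segment
#'
#' For every fusion-involved annotated gene and role: the fraction of
#' its fusion transcripts classified in-frame, grouped by whether the
#' fused gene segment contains an included miRNA in at least one call,
#' plus cumulative-distribution points per group for plotting.
#'
#' @param calls filtered fusion calls.
#' @param assignments,mirnas,genes annotation and host assignment.
#' @param downstream_bp downstream rescue window.
#' @return list: `per_gene` (`gene_id`, `role`, `n_fusions`,
#'   `frac_inframe`, `has_mirna`), `group_means`, and `cdf`
#'   (`role`, `has_mirna`, `frac_inframe`, `cum_fraction`).
#' @export
inframe_fraction_analysis <- function(calls, assignments, mirnas, genes,
                                      downstream_bp = 2000) {
  calls <- dedupe_fusion_calls(calls)
  events <- map_mirnas_to_fusions(calls, assignments, mirnas, genes,
                                  downstream_bp = downstream_bp)
  inc <- events[events$included, , drop = FALSE]
  ann <- genes$gene_id
  per_gene <- do.call(rbind, lapply(c("5p", "3p"), function(role) {
    gcol <- if (role == "5p") "gene5_id" else "gene3_id"
    cs <- calls[!is.na(calls[[gcol]]) & calls[[gcol]] %in% ann, , drop = FALSE]
    if (nrow(cs) == 0L) return(NULL)
    sp <- split(cs$frame_class, cs[[gcol]])
    mir_genes <- unique(inc$host_gene_id[inc$role == role])
    data.frame(gene_id = names(sp), role = role,
               n_fusions = lengths(sp),
               frac_inframe = vapply(sp, function(f) mean(f == "in-frame"),
                                     numeric(1)),
               has_mirna = names(sp) %in% mir_genes,
               stringsAsFactors = FALSE)
  }))
  rownames(per_gene) <- NULL
  grp <- aggregate(frac_inframe ~ role + has_mirna, per_gene, mean)
  grp$n_genes <- aggregate(frac_inframe ~ role + has_mirna, per_gene,
                           length)$frac_inframe
  cdf <- do.call(rbind, lapply(split(per_gene,
                                     paste(per_gene$role, per_gene$has_mirna)),
                               function(g) {
    x <- sort(g$frac_inframe)
    data.frame(role = g$role[1L], has_mirna = g$has_mirna[1L],
               frac_inframe = x, cum_fraction = seq_along(x) / length(x),
               stringsAsFactors = FALSE)
  }))
  rownames(cdf) <- NULL
  list(per_gene = per_gene, group_means = grp, cdf = cdf)
}

#' 5' partner expression by 3' partner category
#'
#' Classifies each fusion call by its 3' partner: a miRNA host gene with
#' the miRNA included in the fused segment (`host_mirna_included`), a
#' host gene without the miRNA in the segment (`host_mirna_excluded`),
#' or a non-host gene (`non_host`). For each annotated 5' partner gene
#' and category, the mean log2(FPKM + pseudocount) across the tumors
#' carrying such a fusion is computed; the `no_fusion` baseline is the
#' mean over samples without any fusion involving that gene, for the
#' full 5' partner set. Two-sided pooled-variance t-tests compare the
#' per-gene means between categories.
#'
#' @param calls filtered, deduplicated fusion calls.
#' @param events output of [map_mirnas_to_fusions()] on the same calls.
#' @param gene_expression FPKM matrix (genes x samples).
#' @param pseudocount added before the log2 transform (default 0.1).
#' @return list: `gene_means` (`gene_id`, `category`, `n_samples`,
#'   `mean_log2`) and `tests` (`category_a`, `category_b`, `n_a`, `n_b`,
#'   `mean_diff`, `t_stat`, `p_value`).
#' @export
partner5_expression_by_category <- function(calls, events, gene_expression,
                                            pseudocount = 0.1) {
  calls <- dedupe_fusion_calls(calls)
  lg <- log2(gene_expression + pseudocount)
  ev3 <- events[events$role == "3p", , drop = FALSE]
  inc_calls <- unique(ev3$call_index[ev3$included])
  host_calls <- unique(ev3$call_index)
  category <- ifelse(calls$call_index %in% inc_calls, "host_mirna_included",
                     ifelse(calls$call_index %in% host_calls,
                            "host_mirna_excluded", "non_host"))
  ok <- !is.na(calls$gene5_id) & calls$gene5_id %in% rownames(lg) &
    calls$sample_id %in% colnames(lg)
  cs <- calls[ok, , drop = FALSE]
  category <- category[ok]

  mean_for <- function(gene, samples) mean(lg[gene, unique(samples)])
  sp <- split(seq_len(nrow(cs)), paste(cs$gene5_id, category, sep = "\r"))
  gene_means <- do.call(rbind, lapply(sp, function(i) {
    data.frame(gene_id = cs$gene5_id[i[1L]], category = category[i[1L]],
               n_samples = length(unique(cs$sample_id[i])),
               mean_log2 = mean_for(cs$gene5_id[i[1L]], cs$sample_id[i]),
               stringsAsFactors = FALSE)
  }))

  # no-fusion baseline over the full 5' partner set
  fused_pairs <- unique(rbind(
    data.frame(g = calls$gene5_id, s = calls$sample_id, stringsAsFactors = FALSE),
    data.frame(g = calls$gene3_id, s = calls$sample_id, stringsAsFactors = FALSE)))
  baseline <- do.call(rbind, lapply(unique(cs$gene5_id), function(g) {
    s <- setdiff(colnames(lg), fused_pairs$s[fused_pairs$g %in% g])
    if (length(s) == 0L) return(NULL)
    data.frame(gene_id = g, category = "no_fusion", n_samples = length(s),
               mean_log2 = mean(lg[g, s]), stringsAsFactors = FALSE)
  }))
  gene_means <- rbind(gene_means, baseline)
  gene_means <- gene_means[order(gene_means$category, gene_means$gene_id), ,
                           drop = FALSE]
  rownames(gene_means) <- NULL

  cats <- c("host_mirna_included", "host_mirna_excluded", "non_host", "no_fusion")
  combos <- utils::combn(cats[cats %in% gene_means$category], 2L)
  tests <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
    xa <- gene_means$mean_log2[gene_means$category == combos[1L, k]]
    xb <- gene_means$mean_log2[gene_means$category == combos[2L, k]]
    if (length(xa) < 2L || length(xb) < 2L) {
      warning("category with < 2 genes; t-test skipped for ",
              combos[1L, k], " vs ", combos[2L, k])
      return(data.frame(category_a = combos[1L, k], category_b = combos[2L, k],
                        n_a = length(xa), n_b = length(xb),
                        mean_diff = mean(xa) - mean(xb), t_stat = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    tt <- .safe_t_test(xa, xb, var_equal = TRUE)
    data.frame(category_a = combos[1L, k], category_b = combos[2L, k],
               n_a = length(xa), n_b = length(xb),
               mean_diff = mean(xa) - mean(xb), t_stat = tt$t,
               p_value = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(gene_means = gene_means, tests = tests)
}
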