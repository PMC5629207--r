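# Recurrence and miRNA-convergence summaries, and Fisher exact overlap
# tests against external fusion catalogues.

.included_events <- function(events) {
  ev <- events[events$included, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

.count_tumors <- function(ev) length(unique(ev$sample_id))

#' Per-miRNA recurrence summary
#'
#' Counts, for every hairpin with at least one included event, the
#' distinct tumors in which it is included in a fusion transcript in any
#' role, as part of the 5' partner, and as part of the 3' partner.
#' Recurrence requires at least `min_tumors` tumors with the host gene in
#' the same relative position (role); `recurrent_any` additionally counts
#' hairpins recurrent in either role or in `min_tumors` tumors overall.
#'
#' @param events output of [map_mirnas_to_fusions()]; only
#'   `included = TRUE` rows are used.
#' @param min_tumors recurrence threshold (default 3 tumors).
#' @return data frame: `mirna_id`, `host_gene_id`, `n_tumors_any`,
#'   `n_tumors_5p`, `n_tumors_3p`, `recurrent_5p`, `recurrent_3p`,
#'   `recurrent_any`.
#' @export
recurrence_summary <- function(events, min_tumors = 3) {
  ev <- .included_events(events)
  if (nrow(ev) == 0L)
    return(data.frame(mirna_id = character(0), host_gene_id = character(0),
                      n_tumors_any = integer(0), n_tumors_5p = integer(0),
                      n_tumors_3p = integer(0), recurrent_5p = logical(0),
                      recurrent_3p = logical(0), recurrent_any = logical(0),
                      stringsAsFactors = FALSE))
  sp <- split(ev, ev$mirna_id)
  out <- do.call(rbind, lapply(sp, function(e) {
    data.frame(mirna_id = e$mirna_id[1L], host_gene_id = e$host_gene_id[1L],
               n_tumors_any = .count_tumors(e),
               n_tumors_5p = .count_tumors(e[e$role == "5p", ]),
               n_tumors_3p = .count_tumors(e[e$role == "3p", ]),
               stringsAsFactors = FALSE)
  }))
  out$recurrent_5p <- out$n_tumors_5p >= min_tumors
  out$recurrent_3p <- out$n_tumors_3p >= min_tumors
  out$recurrent_any <- out$recurrent_5p | out$recurrent_3p |
    out$n_tumors_any >= min_tumors
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Census of miRNAs in fusion transcripts by threshold and role
#'
#' Condenses a recurrence summary into counts of hairpins included in
#' fusions in at least one tumor and recurrently (>= `min_tumors`), by
#' host-gene role.
#'
#' @param summary output of [recurrence_summary()].
#' @param min_tumors threshold used when the summary was built.
#' @return data frame with rows `ge1_tumor` and `recurrent` and columns
#'   `any`, `partner5`, `partner3`.
#' @export
recurrence_census <- function(summary, min_tumors = 3) {
  data.frame(
    threshold = c("ge1_tumor", "recurrent"),
    any = c(sum(summary$n_tumors_any >= 1L), sum(summary$recurrent_any)),
    partner5 = c(sum(summary$n_tumors_5p >= 1L), sum(summary$recurrent_5p)),
    partner3 = c(sum(summary$n_tumors_3p >= 1L), sum(summary$recurrent_3p)),
    stringsAsFactors = FALSE)
}

#' miRNA-convergence table
#'
#' For every hairpin included in fusion transcripts with its host gene as
#' the 3' partner: the number of distinct annotated 5' partner genes
#' observed across tumors, the number of tumors carrying fusions with
#' more than one distinct 5' partner, and the number of tumors with any
#' 3' inclusion. Unannotated partners contribute to tumor counts but not
#' to distinct-partner counts. Rows are ordered by decreasing
#' `n_tumors_3p`, then decreasing `n_partner5_genes`, then `mirna_id`,
#' so the most convergent miRNAs come first.
#'
#' @param events output of [map_mirnas_to_fusions()].
#' @param min_tumors recurrence threshold forwarded to
#'   [recurrence_summary()].
#' @return data frame: `mirna_id`, `host_gene_id`, `n_partner5_genes`,
#'   `n_tumors_multi_partner`, `n_tumors_3p`, `n_tumors_5p`,
#'   `n_tumors_any`, `recurrent_5p`, `recurrent_3p`, `recurrent_any`.
#' @export
convergence_table <- function(events, min_tumors = 3) {
  rec <- recurrence_summary(events, min_tumors = min_tumors)
  ev <- .included_events(events)
  ev3 <- ev[ev$role == "3p", , drop = FALSE]
  conv <- do.call(rbind, c(list(
    data.frame(mirna_id = character(0), n_partner5_genes = integer(0),
               n_tumors_multi_partner = integer(0), stringsAsFactors = FALSE)),
    lapply(split(ev3, ev3$mirna_id), function(e) {
      per_tumor <- tapply(e$partner_gene_id, e$sample_id,
                          function(p) length(unique(p[!is.na(p)])))
      data.frame(mirna_id = e$mirna_id[1L],
                 n_partner5_genes = length(unique(e$partner_gene_id[
                   !is.na(e$partner_gene_id)])),
                 n_tumors_multi_partner = sum(per_tumor > 1L),
                 stringsAsFactors = FALSE)
    })))
  out <- merge(rec, conv, by = "mirna_id", all.x = TRUE)
  out$n_partner5_genes[is.na(out$n_partner5_genes)] <- 0L
  out$n_tumors_multi_partner[is.na(out$n_tumors_multi_partner)] <- 0L
  out <- out[, c("mirna_id", "host_gene_id", "n_partner5_genes",
                 "n_tumors_multi_partner", "n_tumors_3p", "n_tumors_5p",
                 "n_tumors_any", "recurrent_5p", "recurrent_3p",
                 "recurrent_any")]
  out <- out[order(-out$n_tumors_3p, -out$n_partner5_genes, out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger
#' than that of the observed table (fixed margins), odds ratio as the
#' conditional maximum-likelihood estimate of the noncentral
#' hypergeometric parameter, and a 95% confidence interval by inverting
#' that distribution. Note the conditional MLE differs slightly from the
#' sample cross-product ratio `ad/bc`. A table with a zero margin has no
#' estimable odds ratio and is returned with `p_value = 1` and
#' `or_undefined = TRUE`.
#'
#' @param a,b,c,d non-negative cell counts (row-wise), or a 2x2 matrix
#'   as `a`.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `fisher_result`: the cells, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `or_undefined`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  res <- list(a = a, b = b, c = c, d = d)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    if (sum(tab) == 0) stop("at least one margin must be positive")
    res <- c(res, list(odds_ratio = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p_value = 1, or_undefined = TRUE))
  } else {
    ft <- stats::fisher.test(tab, conf.level = conf_level)
    res <- c(res, list(odds_ratio = unname(ft$estimate),
                       ci_low = ft$conf.int[1L], ci_high = ft$conf.int[2L],
                       p_value = ft$p.value, or_undefined = FALSE))
  }
  structure(res, class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("2x2 Fisher exact test\n")
  cat(sprintf("  table: [%d %d; %d %d]\n", x$a, x$b, x$c, x$d))
  if (x$or_undefined) {
    cat("  odds ratio undefined (zero margin); p = 1\n")
  } else {
    cat(sprintf("  odds ratio (conditional MLE) = %.4g  95%% CI [%.4g, %.4g]\n",
                x$odds_ratio, x$ci_low, x$ci_high))
    cat(sprintf("  two-sided p = %.4g\n", x$p_value))
  }
  invisible(x)
}

#' Overlap of two miRNA sets over a common universe
#'
#' Builds the 2x2 table of membership in each set over the universe
#' (internal-and-external, internal-only, external-only, neither) and
#' applies [fisher_exact()]. The universe is configurable; by default it
#' should be the set of miRNAs with an assigned host gene, and passing a
#' reduced (single-precursor-per-host) universe is supported by simply
#' intersecting the sets with it.
#'
#' @param internal_mirnas,external_mirnas character vectors (subsets of
#'   `universe`).
#' @param universe character vector of all analyzed miRNAs.
#' @param restrict_to_universe drop set members outside the universe
#'   instead of erroring (default `FALSE`).
#' @return a `fisher_result`.
#' @export
external_overlap <- function(internal_mirnas, external_mirnas, universe,
                             restrict_to_universe = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  internal_mirnas <- unique(internal_mirnas)
  external_mirnas <- unique(external_mirnas)
  if (restrict_to_universe) {
    internal_mirnas <- intersect(internal_mirnas, universe)
    external_mirnas <- intersect(external_mirnas, universe)
  }
  if (!all(internal_mirnas %in% universe) || !all(external_mirnas %in% universe))
    stop("sets must be subsets of the universe")
  a <- length(intersect(internal_mirnas, external_mirnas))
  b <- length(setdiff(internal_mirnas, external_mirnas))
  cc <- length(setdiff(external_mirnas, internal_mirnas))
  d <- length(universe) - a - b - cc
  fisher_exact(a, b, cc, d)
}

#' Match an external fusion catalogue to miRNA host genes
#'
#' In `"coordinates"` mode the catalogue is a fusion-call table (as from
#' [read_fusion_calls()]) and the full inclusion rule is applied: the
#' result is the set of hairpins fully contained in a fused segment. In
#' `"symbols"` mode the catalogue only names partner genes
#' (`gene5_symbol`, `gene3_symbol` columns) and any fusion naming a host
#' gene's symbol counts that host's hairpins — an over-approximation of
#' the coordinate rule, since without breakpoints inclusion cannot be
#' checked.
#'
#' @param catalogue data frame (see Details).
#' @param mode `"coordinates"` or `"symbols"`.
#' @param genes,mirnas,assignments the annotation and host assignment.
#' @param downstream_bp downstream rescue window for coordinates mode.
#' @return sorted character vector of matched hairpin ids.
#' @export
match_external_catalogue <- function(catalogue, mode = c("coordinates", "symbols"),
                                     genes, mirnas, assignments,
                                     downstream_bp = 2000) {
  mode <- match.arg(mode)
  asg <- assignments[assignments$relation != "unassigned", , drop = FALSE]
  if (mode == "symbols") {
    need <- c("gene5_symbol", "gene3_symbol")
    if (!all(need %in% names(catalogue)))
      stop("symbols mode needs columns: ", paste(need, collapse = ", "))
    host_symbol <- genes$symbol[match(asg$gene_id, genes$gene_id)]
    named <- unique(c(catalogue$gene5_symbol, catalogue$gene3_symbol))
    named <- named[!is.na(named)]
    sort(unique(asg$mirna_id[host_symbol %in% named]))
  } else {
    need <- c("gene5_id", "gene3_id", "bp5_pos", "bp3_pos")
    if (!all(need %in% names(catalogue)))
      stop("coordinates mode needs breakpoint columns: ",
           paste(setdiff(need, names(catalogue)), collapse = ", "))
    ev <- map_mirnas_to_fusions(catalogue, assignments, mirnas, genes,
                                downstream_bp = downstream_bp)
    sort(unique(ev$mirna_id[ev$included]))
  }
}

#' Fraction of fusion-involved genes whose fused segment contains a miRNA
#'
#' For all fusions and in-frame fusions only, crossed with partner role
#' (any/5'/3'): the fraction of distinct annotated fusion-involved genes
#' that contain an included miRNA within the fused gene segment in at
#' least one qualifying call.
#'
#' @param calls filtered fusion calls.
#' @param assignments host assignments.
#' @param mirnas,genes annotation.
#' @param downstream_bp downstream rescue window.
#' @return data frame: `scope` (`all`/`in-frame`), `role`
#'   (`any`/`5p`/`3p`), `n_genes`, `n_mirna_genes`, `fraction`.
#' @export
mirna_content_fractions <- function(calls, assignments, mirnas, genes,
                                    downstream_bp = 2000) {
  calls <- dedupe_fusion_calls(calls)
  events <- map_mirnas_to_fusions(calls, assignments, mirnas, genes,
                                  downstream_bp = downstream_bp)
  ann <- genes$gene_id
  scopes <- list(all = calls,
                 `in-frame` = calls[calls$frame_class == "in-frame", , drop = FALSE])
  rows <- list()
  for (sc in names(scopes)) {
    cs <- scopes[[sc]]
    ev <- events[events$included & events$call_index %in% cs$call_index, ,
                 drop = FALSE]
    for (role in c("any", "5p", "3p")) {
      denom <- switch(role,
        any = union(cs$gene5_id, cs$gene3_id),
        `5p` = unique(cs$gene5_id),
        `3p` = unique(cs$gene3_id))
      denom <- denom[!is.na(denom) & denom %in% ann]
      er <- if (role == "any") ev else ev[ev$role == role, , drop = FALSE]
      num <- intersect(denom, unique(er$host_gene_id))
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, role = role, n_genes = length(denom),
        n_mirna_genes = length(num),
        fraction = if (length(denom)) length(num) / length(denom) else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
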