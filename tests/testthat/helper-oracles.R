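# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately share no code with the implementation:
# plain loops, exhaustive enumeration and closed forms only.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

make_genes <- function(chrom, start, end, strand, gene_id = NULL,
                       symbol = NULL, biotype = "protein_coding") {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- sprintf("G%03d", seq_len(n))
  if (is.null(symbol)) symbol <- gene_id
  g <- GRanges(rep(chrom, length.out = n), IRanges(start, end),
               strand = rep(strand, length.out = n),
               gene_id = gene_id, symbol = rep(symbol, length.out = n),
               biotype = rep(biotype, length.out = n))
  names(g) <- gene_id
  g
}

make_mirnas <- function(chrom, start, end, strand, mirna_id = NULL,
                        mature_ids = NULL) {
  n <- length(start)
  if (is.null(mirna_id)) mirna_id <- sprintf("mir-%03d", seq_len(n))
  m <- GRanges(rep(chrom, length.out = n), IRanges(start, end),
               strand = rep(strand, length.out = n), mirna_id = mirna_id)
  if (is.null(mature_ids))
    mature_ids <- lapply(mirna_id, function(id) paste0(id, c("-5p", "-3p")))
  m$mature_ids <- methods::as(mature_ids, "CharacterList")
  names(m) <- mirna_id
  m
}

make_call <- function(sample_id, gene5_id, gene3_id, bp5, bp3,
                      frame_class = "other", flags = "", support = 5L,
                      call_index = 1L) {
  p <- function(x) {
    f <- strsplit(x, ":", fixed = TRUE)[[1]]
    list(chrom = f[1], pos = as.numeric(f[2]), strand = f[3])
  }
  b5 <- p(bp5); b3 <- p(bp3)
  data.frame(sample_id = sample_id, gene5_id = gene5_id, gene3_id = gene3_id,
             bp5_chrom = b5$chrom, bp5_pos = b5$pos, bp5_strand = b5$strand,
             bp3_chrom = b3$chrom, bp3_pos = b3$pos, bp3_strand = b3$strand,
             frame_class = frame_class, flags = flags,
             healthy = flags == "healthy", support = support,
             call_index = call_index, stringsAsFactors = FALSE)
}

make_calls <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, rows)
  out$call_index <- seq_len(nrow(out))
  out
}

# ---- all-pairs host assignment oracle --------------------------------------

bf_assign_hosts <- function(mirnas, genes, downstream_bp = 2000,
                            same_strand = TRUE) {
  mchrom <- as.character(seqnames(mirnas)); mstart <- start(mirnas)
  mend <- end(mirnas); mstr <- as.character(strand(mirnas))
  gchrom <- as.character(seqnames(genes)); gstart <- start(genes)
  gend <- end(genes); gstr <- as.character(strand(genes))
  gid <- genes$gene_id
  out <- data.frame(mirna_id = mirnas$mirna_id, gene_id = NA_character_,
                    relation = "unassigned", distance_bp = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mirnas)) {
    best <- NULL
    for (j in seq_along(genes)) {
      if (mchrom[i] != gchrom[j]) next
      if (same_strand && mstr[i] != gstr[j]) next
      if (mstart[i] >= gstart[j] && mend[i] <= gend[j]) {
        w <- gend[j] - gstart[j] + 1
        if (is.null(best) || w < best$w ||
            (w == best$w && gid[j] < best$id))
          best <- list(id = gid[j], w = w)
      }
    }
    if (!is.null(best)) {
      out$gene_id[i] <- best$id; out$relation[i] <- "intragenic"
      out$distance_bp[i] <- 0
      next
    }
    if (downstream_bp <= 0) next
    bestd <- NULL
    for (j in seq_along(genes)) {
      if (mchrom[i] != gchrom[j]) next
      if (same_strand && mstr[i] != gstr[j]) next
      if (gstr[j] == "+") {
        lo <- gend[j] + 1; hi <- gend[j] + downstream_bp
        gap <- mstart[i] - gend[j]
      } else {
        lo <- gstart[j] - downstream_bp; hi <- gstart[j] - 1
        gap <- gstart[j] - mend[i]
      }
      if (mstart[i] >= lo && mend[i] <= hi) {
        if (is.null(bestd) || gap < bestd$gap ||
            (gap == bestd$gap && gid[j] < bestd$id))
          bestd <- list(id = gid[j], gap = gap)
      }
    }
    if (!is.null(bestd)) {
      out$gene_id[i] <- bestd$id; out$relation[i] <- "downstream2kb"
      out$distance_bp[i] <- bestd$gap
    }
  }
  out[order(out$mirna_id), , drop = FALSE]
}

# scalar miRNA-in-fused-segment oracle; relation is the host relation
bf_included <- function(mstart, mend, gstart, gend, gstrand, bp, role,
                        relation = "intragenic", downstream_bp = 2000) {
  bp <- min(max(bp, gstart), gend)
  ext <- if (role == "3p" && relation == "downstream2kb") downstream_bp else 0
  if (role == "5p") {
    if (gstrand == "+") mstart >= gstart && mend <= bp
    else mstart >= bp && mend <= gend
  } else {
    if (gstrand == "+") mstart >= bp && mend <= gend + ext
    else mstart >= gstart - ext && mend <= bp
  }
}

# ---- Fisher fixed-margin enumeration oracle --------------------------------

# support and probabilities of the (central or noncentral) hypergeometric
# distribution of cell a, given margins
enum_fisher <- function(a, b, cc, d) {
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0L, k - n); hi <- min(k, m)
  supp <- lo:hi
  logw <- lchoose(m, supp) + lchoose(n, k - supp)
  pr <- exp(logw - max(logw)); pr <- pr / sum(pr)
  d_obs <- pr[match(a, supp)]
  p <- sum(pr[pr <= d_obs * (1 + 1e-7)])
  # conditional MLE of the odds ratio, by maximising the noncentral
  # log-likelihood over log(psi)
  or <- if (a == lo && a == hi) NA_real_
  else if (a == lo) 0
  else if (a == hi) Inf
  else {
    ll <- function(t) a * t - (max(logw + supp * t) +
                                 log(sum(exp(logw + supp * t -
                                               max(logw + supp * t)))))
    exp(stats::optimize(ll, c(-36, 36), maximum = TRUE, tol = 1e-10)$maximum)
  }
  list(p = p, or = or, lo = lo, hi = hi)
}

# oracle for the noncentral-hypergeometric CDF, for CI inversion checks
enum_nchg_cdf <- function(a, b, cc, d, psi) {
  m <- a + b; n <- cc + d; k <- a + cc
  supp <- max(0L, k - n):min(k, m)
  logw <- lchoose(m, supp) + lchoose(n, k - supp) + supp * log(psi)
  pr <- exp(logw - max(logw)); pr <- pr / sum(pr)
  c(lower = sum(pr[supp <= a]), upper = sum(pr[supp >= a]))
}

# ---- misc ------------------------------------------------------------------

random_cohort <- function(seed, ...) {
  simulate_cohort(synthetic_config(seed = seed, n_genes = 800,
                                   n_samples = 60, n_expr_samples = 30,
                                   convergent_tumors = c(15, 10, 7, 5, 4),
                                   convergent_partners = c(18, 12, 8, 6, 4),
                                   ...))
}

expect_same_table <- function(a, b) {
  rownames(a) <- NULL; rownames(b) <- NULL
  expect_equal(a, b)
}
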