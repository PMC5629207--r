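# Synthetic cohort generator: gene/miRNA annotation, fusion calls and
# expression matrices with the statistical structure the analysis assumes,
# plus the planted ground truth needed to validate every stage.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the breast-tumor study conditions the analysis is
#' designed for: ~19,000 genes (90% protein coding) with log-normal sizes
#' (log2 mean 14.5, sd 2, i.e. a median gene of ~23 kb), 6.5% of coding
#' genes hosting one or occasionally two intronic hairpins so that ~68% of
#' hairpins are intragenic, ~2.4% lie within 2 kb downstream of a gene and
#' the rest are intergenic; 1552 tumors of which the first 186 carry
#' small-RNA expression data; a gene-level fusion probability following
#' `logit P(fused) = beta0 + betaH*host + betaS*log2(size) +
#' betaHS*host*log2(size)` with a host/non-host crossover planted at
#' 440 kb; frame classes at 8% in-frame / 9% out-of-frame / 83% other with
#' a 0.8 multiplicative in-frame depletion when the 3' segment contains a
#' hairpin; five planted convergent hotspots with tumor/partner counts
#' (155/49/34/29/19 and 338/107/103/38/20) mirroring the most convergent
#' miRNA host genes reported in breast cancer; and a 4-fold cpm increase
#' for mature miRNAs of 3'-included hairpins, negative-binomial dispersion
#' 0.5.
#'
#' @param seed master seed; each generator stage derives its own stream
#'   by a fixed offset.
#' @param n_genes,noncoding_fraction gene count and non-coding fraction.
#' @param host_fraction fraction of protein-coding genes hosting hairpins.
#' @param size_log2_mean,size_log2_sd gene-size distribution (log2 bp).
#' @param n_samples,n_expr_samples cohort size and expression subset.
#' @param beta0,betaH,betaS,betaHS true fusion-model coefficients.
#' @param frame_probs probabilities over in-frame/out-of-frame/other.
#' @param inframe_depletion multiplier on the in-frame probability when
#'   the 3' segment contains a hairpin.
#' @param recurrence_mu,recurrence_size negative-binomial parameters of
#'   the per-fused-gene extra tumor count.
#' @param mirna_downstream_fraction,mirna_intergenic_fraction fractions
#'   of all hairpins placed downstream of a gene or intergenic.
#' @param mirna_cluster_prob probability that a host carries a second
#'   hairpin.
#' @param element_rates named per-gene occurrence rates of control
#'   element classes.
#' @param noise_call_rate fraction of extra calls carrying an exclusion
#'   flag.
#' @param healthy_rate fraction of retained calls flagged `healthy`.
#' @param n_convergent,convergent_tumors,convergent_partners planted
#'   convergent hotspots.
#' @param mirna_fold_change cpm multiplier in tumors with a 3'-included
#'   event.
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion*mu^2`).
#' @param partner5_shift log2-FPKM shift of 5' partners of
#'   miRNA-including fusions in fused tumors.
#' @param downstream_bp downstream rescue window (bp).
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 19000L,
                             noncoding_fraction = 0.10,
                             host_fraction = 0.065,
                             size_log2_mean = 14.5,
                             size_log2_sd = 2.0,
                             n_samples = 1552L,
                             n_expr_samples = 186L,
                             beta0 = -3.22,
                             betaH = 2.8121,
                             betaS = 0.25,
                             betaHS = -0.15,
                             frame_probs = c("in-frame" = 0.08,
                                             "out-of-frame" = 0.09,
                                             "other" = 0.83),
                             inframe_depletion = 0.8,
                             recurrence_mu = 2.2,
                             recurrence_size = 3,
                             mirna_downstream_fraction = 0.024,
                             mirna_intergenic_fraction = 0.298,
                             mirna_cluster_prob = 0.155,
                             element_rates = c(elemA = 0.040, elemB = 0.050,
                                               elemC = 0.055, elemD = 0.060,
                                               elemE = 0.065, elemF = 0.090),
                             noise_call_rate = 0.15,
                             healthy_rate = 0.001,
                             n_convergent = 5L,
                             convergent_tumors = c(155L, 49L, 34L, 29L, 19L),
                             convergent_partners = c(338L, 107L, 103L, 38L, 20L),
                             mirna_fold_change = 4,
                             dispersion = 0.5,
                             partner5_shift = 1,
                             downstream_bp = 2000L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1L, cfg$n_samples >= 1L,
            cfg$n_expr_samples <= cfg$n_samples,
            cfg$host_fraction >= 0, cfg$host_fraction <= 1,
            cfg$noncoding_fraction >= 0, cfg$noncoding_fraction < 1,
            cfg$mirna_downstream_fraction >= 0,
            cfg$mirna_intergenic_fraction >= 0,
            cfg$mirna_downstream_fraction + cfg$mirna_intergenic_fraction < 1,
            all(cfg$frame_probs >= 0), abs(sum(cfg$frame_probs) - 1) < 1e-8,
            cfg$inframe_depletion >= 0, cfg$mirna_fold_change > 0,
            cfg$dispersion >= 0, cfg$downstream_bp >= 0,
            length(cfg$convergent_tumors) >= cfg$n_convergent,
            length(cfg$convergent_partners) >= cfg$n_convergent,
            abs(cfg$seed) < 2^31 - 100)
  names(cfg$frame_probs) <- c("in-frame", "out-of-frame", "other")
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

.sample_ids <- function(n) sprintf("S%04d", seq_len(n))

#' Simulate gene, miRNA and control-element annotation
#'
#' Genes with log-normal sizes are placed non-overlapping on synthetic
#' chromosomes (500 genes per chromosome, gaps of 5-50 kb so that
#' downstream rescue windows never touch a neighbouring gene). Host genes
#' receive one (or, with probability `mirna_cluster_prob`, two) hairpins
#' of 60-110 bp strictly inside their span and on the same strand;
#' further hairpins are planted in downstream rescue windows and in
#' intergenic gaps per the configured fractions. Control elements are
#' planted per class as independent per-gene Bernoulli draws. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return list: `genes`, `mirnas`, `elements` (GRanges) and `truth`
#'   (data frame `mirna_id`, `gene_id`, `relation` of the planted host
#'   map).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(is(cfg, "synthetic_config"))
  set.seed(cfg$seed + 11L)
  n <- cfg$n_genes
  sizes <- pmax(600, round(2^rnorm(n, cfg$size_log2_mean, cfg$size_log2_sd)))
  per_chrom <- 500L
  chrom_i <- (seq_len(n) - 1L) %/% per_chrom + 1L
  chrom <- sprintf("chrS%02d", chrom_i)
  gaps <- round(runif(n, 5000, 50000))
  gstart <- numeric(n)
  for (ci in unique(chrom_i)) {
    i <- which(chrom_i == ci)
    gstart[i] <- 10000 + cumsum(c(0, (sizes[i] + gaps[i])[-length(i)]))
  }
  gend <- gstart + sizes - 1
  gstrand <- sample(c("+", "-"), n, replace = TRUE)
  biotype <- ifelse(runif(n) < cfg$noncoding_fraction, "lincRNA",
                    "protein_coding")
  gene_id <- sprintf("SYNG%05d", seq_len(n))
  genes <- GRanges(chrom, IRanges(gstart, gend), strand = gstrand,
                   gene_id = gene_id, symbol = sprintf("SG%05d", seq_len(n)),
                   biotype = biotype)
  names(genes) <- gene_id

  pc <- which(biotype == "protein_coding")
  n_host <- round(cfg$host_fraction * length(pc))
  host_idx <- if (n_host > 0) sort(sample(pc, n_host)) else integer(0)

  hp <- list(); truth <- list(); hp_count <- 0L
  place_inside <- function(i) {
    len <- round(runif(1, 60, 110))
    s <- round(runif(1, gstart[i] + 150, gend[i] - 150 - len))
    c(s, s + len - 1)
  }
  for (i in host_idx) {
    k <- 1L + (runif(1) < cfg$mirna_cluster_prob)
    for (j in seq_len(k)) {
      hp_count <- hp_count + 1L
      pos <- place_inside(i)
      hp[[hp_count]] <- data.frame(chrom = chrom[i], start = pos[1],
                                   end = pos[2], strand = gstrand[i],
                                   gene_id = gene_id[i],
                                   relation = "intragenic",
                                   stringsAsFactors = FALSE)
    }
  }
  n_intra <- hp_count
  if (n_intra > 0) {
    frac_intra <- 1 - cfg$mirna_downstream_fraction - cfg$mirna_intergenic_fraction
    n_total <- round(n_intra / frac_intra)
    n_down <- round(n_total * cfg$mirna_downstream_fraction)
    n_inter <- max(0L, n_total - n_intra - n_down)
    nonhost <- setdiff(seq_len(n), host_idx)
    down_genes <- sample(nonhost, min(n_down, length(nonhost)))
    for (i in down_genes) {
      hp_count <- hp_count + 1L
      len <- round(runif(1, 60, 110))
      d <- round(runif(1, 50, cfg$downstream_bp - len - 10))
      se <- if (gstrand[i] == "+") c(gend[i] + d, gend[i] + d + len - 1)
            else c(gstart[i] - d - len + 1, gstart[i] - d)
      hp[[hp_count]] <- data.frame(chrom = chrom[i], start = se[1], end = se[2],
                                   strand = gstrand[i], gene_id = gene_id[i],
                                   relation = "downstream2kb",
                                   stringsAsFactors = FALSE)
    }
    inter_genes <- sample(seq_len(n), min(n_inter, n))
    for (i in inter_genes) {
      hp_count <- hp_count + 1L
      len <- round(runif(1, 60, 110))
      hp[[hp_count]] <- data.frame(chrom = chrom[i], start = gend[i] + 2500,
                                   end = gend[i] + 2500 + len - 1,
                                   strand = sample(c("+", "-"), 1),
                                   gene_id = NA_character_,
                                   relation = "unassigned",
                                   stringsAsFactors = FALSE)
    }
  }

  if (hp_count > 0) {
    hpd <- do.call(rbind, hp)
    hpd$mirna_id <- sprintf("hsa-syn-mir-%04d", seq_len(nrow(hpd)))
    mirnas <- GRanges(hpd$chrom, IRanges(hpd$start, hpd$end),
                      strand = hpd$strand, mirna_id = hpd$mirna_id)
    mirnas$mature_ids <- as(lapply(hpd$mirna_id, function(id)
      paste0(sub("mir", "miR", id), c("-5p", "-3p"))), "CharacterList")
    names(mirnas) <- hpd$mirna_id
    truth <- hpd[, c("mirna_id", "gene_id", "relation")]
  } else {
    mirnas <- GRanges(mirna_id = character(0))
    mirnas$mature_ids <- as(list(), "CharacterList")
    truth <- data.frame(mirna_id = character(0), gene_id = character(0),
                        relation = character(0), stringsAsFactors = FALSE)
  }

  el <- list()
  for (cl in names(cfg$element_rates)) {
    pick <- which(runif(n) < cfg$element_rates[[cl]])
    if (length(pick))
      el[[cl]] <- GRanges(chrom[pick],
                          IRanges(gstart[pick] + 50, gstart[pick] + 349),
                          strand = gstrand[pick], element_class = cl)
  }
  elements <- if (length(el)) suppressWarnings(do.call(c, unname(el)))
              else GRanges(element_class = character(0))

  list(genes = genes, mirnas = mirnas, elements = elements, truth = truth)
}

# expand calls x hairpins of the 3' gene and flag calls whose 3' segment
# contains a hairpin (used for the in-frame depletion knob)
.calls_contain_hairpin <- function(g3, bp3, gs, ge, gstrand, hp_by_gene) {
  out <- rep(FALSE, length(g3))
  idx <- which(!is.na(g3) & g3 %in% names(hp_by_gene))
  for (i in idx) {
    h <- hp_by_gene[[g3[i]]]
    out[i] <- if (gstrand[i] == "+")
      any(h$start >= bp3[i] & h$end <= ge[i])
    else any(h$end <= bp3[i] & h$start >= gs[i])
  }
  out
}

#' Simulate a fusion-call cohort
#'
#' The gene-level fused indicator is drawn from the logistic model with
#' the true coefficients; each fused gene then participates in
#' `1 + NB(mu = recurrence_mu, size = recurrence_size)` distinct tumors.
#' Within each tumor the participating genes are paired at random into
#' fusion calls (an odd one out gets an unannotated partner), breakpoints
#' are uniform within each gene span, and frame classes are drawn from
#' `frame_probs` with the in-frame probability multiplied by
#' `inframe_depletion` when the 3' segment contains a hairpin. Convergent
#' hotspots are planted on single-hairpin host genes with breakpoints
#' placed transcript-upstream of the hairpin so every planted call
#' includes it. Extra noise calls carrying exclusion flags (removed by
#' [filter_fusion_calls()]) and rare `healthy` flags complete the table.
#'
#' @param genes gene GRanges from [simulate_annotation()].
#' @param hosts the host map: output of [assign_hosts()] or the `truth`
#'   element of [simulate_annotation()].
#' @param cfg a [synthetic_config()].
#' @param mirnas hairpin GRanges; when `NULL` the in-frame depletion and
#'   convergent planting are skipped.
#' @return fusion-call data frame in the parsed schema of
#'   [read_fusion_calls()], with a `"truth"` attribute (`fused` gene
#'   table and `convergent` planted hotspots).
#' @export
simulate_fusions <- function(genes, hosts, cfg, mirnas = NULL) {
  stopifnot(is(cfg, "synthetic_config"))
  set.seed(cfg$seed + 22L)
  if (is.data.frame(hosts)) {
    host_map <- hosts[hosts$relation != "unassigned", , drop = FALSE]
  } else {
    host_map <- data.frame(mirna_id = NA_character_, gene_id = hosts,
                           relation = "intragenic", stringsAsFactors = FALSE)
  }
  n <- length(genes)
  gid <- genes$gene_id
  gs <- start(genes); ge <- end(genes)
  gchrom <- as.character(seqnames(genes))
  gstrand <- as.character(strand(genes))
  H <- as.integer(gid %in% host_map$gene_id)
  S <- log2(width(genes))
  p <- plogis(cfg$beta0 + cfg$betaH * H + cfg$betaS * S + cfg$betaHS * H * S)
  F_g <- rbinom(n, 1L, p)
  T_g <- ifelse(F_g == 1L,
                pmin(cfg$n_samples,
                     1L + rnbinom(n, size = cfg$recurrence_size,
                                  mu = cfg$recurrence_mu)),
                0L)

  fused <- which(T_g > 0L)
  part_gene <- rep(fused, T_g[fused])
  part_tumor <- unlist(lapply(fused, function(i)
    sample.int(cfg$n_samples, T_g[i])), use.names = FALSE)

  g5 <- integer(0); g3 <- integer(0); tumor <- integer(0)
  if (length(part_gene)) {
    sp <- split(part_gene, part_tumor)
    for (t in names(sp)) {
      idx <- sp[[t]]
      if (length(idx) > 1L) idx <- sample(idx)
      np <- length(idx) %/% 2L
      if (np > 0L) {
        g5 <- c(g5, idx[seq_len(np) * 2L - 1L])
        g3 <- c(g3, idx[seq_len(np) * 2L])
        tumor <- c(tumor, rep(as.integer(t), np))
      }
      if (length(idx) %% 2L == 1L) {      # leftover gets unannotated partner
        last <- idx[length(idx)]
        if (runif(1) < 0.5) {
          g5 <- c(g5, last); g3 <- c(g3, NA_integer_)
        } else {
          g5 <- c(g5, NA_integer_); g3 <- c(g3, last)
        }
        tumor <- c(tumor, as.integer(t))
      }
    }
  }
  rand_bp <- function(i) {
    out <- rep(NA_real_, length(i))
    ok <- !is.na(i)
    out[ok] <- gs[i[ok]] + 5 + floor(runif(sum(ok)) * (ge[i[ok]] - gs[i[ok]] - 10))
    out
  }
  bp5 <- rand_bp(g5); bp3 <- rand_bp(g3)

  # planted convergent hotspots (3' host fusions that always include the
  # hairpin, many distinct 5' partners)
  convergent <- data.frame(mirna_id = character(0), gene_id = character(0),
                           n_tumors = integer(0), n_partners = integer(0),
                           stringsAsFactors = FALSE)
  if (!is.null(mirnas) && cfg$n_convergent > 0L && nrow(host_map) > 0L) {
    intra <- host_map[host_map$relation == "intragenic", , drop = FALSE]
    single <- names(which(table(intra$gene_id) == 1L))
    single <- single[single %in% gid]
    k <- min(cfg$n_convergent, length(single))
    hot_genes <- sample(single, k)
    for (r in seq_len(k)) {
      hg <- hot_genes[r]
      i <- match(hg, gid)
      mid <- intra$mirna_id[intra$gene_id == hg]
      mi <- match(mid, mirnas$mirna_id)
      Tt <- min(cfg$convergent_tumors[r], cfg$n_samples)
      Pp <- min(cfg$convergent_partners[r], n - 1L)
      Pp <- max(Pp, Tt)
      tumors_r <- sample.int(cfg$n_samples, Tt)
      partners_r <- sample(setdiff(seq_len(n), i), Pp)
      tum_r <- tumors_r[((seq_len(Pp) - 1L) %% Tt) + 1L]
      b3 <- if (gstrand[i] == "+")
        round(runif(Pp, gs[i] + 5, start(mirnas)[mi] - 5))
      else round(runif(Pp, end(mirnas)[mi] + 5, ge[i] - 5))
      g5 <- c(g5, partners_r); g3 <- c(g3, rep(i, Pp))
      tumor <- c(tumor, tum_r)
      bp5 <- c(bp5, rand_bp(partners_r)); bp3 <- c(bp3, b3)
      convergent <- rbind(convergent, data.frame(
        mirna_id = mid, gene_id = hg, n_tumors = Tt, n_partners = Pp,
        stringsAsFactors = FALSE))
    }
  }

  n_calls <- length(tumor)
  if (n_calls > 0L) {
    # frame classes, with in-frame depletion when the 3' segment contains
    # a hairpin
    contains <- rep(FALSE, n_calls)
    if (!is.null(mirnas) && length(mirnas) && nrow(host_map)) {
      mi <- match(host_map$mirna_id, mirnas$mirna_id)
      hp_by_gene <- split(data.frame(start = start(mirnas)[mi],
                                     end = end(mirnas)[mi]),
                          host_map$gene_id)
      contains <- .calls_contain_hairpin(
        ifelse(is.na(g3), NA_character_, gid[g3]), bp3,
        ifelse(is.na(g3), NA_real_, gs[g3]),
        ifelse(is.na(g3), NA_real_, ge[g3]),
        ifelse(is.na(g3), "", gstrand[g3]), hp_by_gene)
    }
    p_in <- ifelse(contains, cfg$frame_probs[["in-frame"]] * cfg$inframe_depletion,
                   cfg$frame_probs[["in-frame"]])
    rest <- (1 - p_in) / (1 - cfg$frame_probs[["in-frame"]])
    p_out <- cfg$frame_probs[["out-of-frame"]] * rest
    u <- runif(n_calls)
    frame_class <- ifelse(u < p_in, "in-frame",
                          ifelse(u < p_in + p_out, "out-of-frame", "other"))
    flags <- ifelse(runif(n_calls) < cfg$healthy_rate, "healthy", "")
  } else {
    frame_class <- character(0); flags <- character(0)
  }

  # noise calls carrying exclusion flags
  n_noise <- round(cfg$noise_call_rate * n_calls)
  if (n_noise > 0L) {
    ng5 <- sample.int(n, n_noise, replace = TRUE)
    ng3 <- sample.int(n, n_noise, replace = TRUE)
    g5 <- c(g5, ng5); g3 <- c(g3, ng3)
    tumor <- c(tumor, sample.int(cfg$n_samples, n_noise, replace = TRUE))
    bp5 <- c(bp5, rand_bp(ng5)); bp3 <- c(bp3, rand_bp(ng3))
    u <- runif(n_noise)
    frame_class <- c(frame_class,
                     ifelse(u < cfg$frame_probs[["in-frame"]], "in-frame",
                            ifelse(u < cfg$frame_probs[["in-frame"]] +
                                     cfg$frame_probs[["out-of-frame"]],
                                   "out-of-frame", "other")))
    flags <- c(flags, sample(fusion_exclusion_flags, n_noise, replace = TRUE))
  }

  n_all <- length(tumor)
  col_or <- function(i, v, alt) ifelse(is.na(i), alt, v[ifelse(is.na(i), 1L, i)])
  calls <- data.frame(
    sample_id = .sample_ids(cfg$n_samples)[tumor],
    gene5_id = col_or(g5, gid, NA_character_),
    gene3_id = col_or(g3, gid, NA_character_),
    bp5_chrom = col_or(g5, gchrom, "chrUn"),
    bp5_pos = ifelse(is.na(g5), round(runif(n_all, 1e6, 2e6)), bp5),
    bp5_strand = col_or(g5, gstrand, "+"),
    bp3_chrom = col_or(g3, gchrom, "chrUn"),
    bp3_pos = ifelse(is.na(g3), round(runif(n_all, 1e6, 2e6)), bp3),
    bp3_strand = col_or(g3, gstrand, "+"),
    frame_class = frame_class,
    flags = flags,
    healthy = flags == "healthy",
    support = rpois(n_all, 5) + 1L,
    stringsAsFactors = FALSE)
  calls$call_index <- seq_len(nrow(calls))
  rownames(calls) <- NULL
  attr(calls, "truth") <- list(
    fused = data.frame(gene_id = gid, is_host = H == 1L, log2_size = S,
                       fused = F_g == 1L, n_tumors = T_g,
                       stringsAsFactors = FALSE),
    convergent = convergent)
  calls
}

#' Simulate miRNA cpm and gene FPKM expression matrices
#'
#' Mature-miRNA counts are negative binomial around a log-normal
#' baseline, multiplied by `mirna_fold_change` in tumors carrying an
#' included 3' fusion event for the hairpin, then scaled to counts per
#' million. Gene expression is log-normal FPKM with a
#' `partner5_shift` log2 increase for 5' partners of miRNA-including
#' fusions in the tumors carrying them.
#'
#' @param events output of [map_mirnas_to_fusions()] on the simulated
#'   cohort.
#' @param mirnas hairpin GRanges (provides `mature_ids`).
#' @param genes gene GRanges.
#' @param cfg a [synthetic_config()].
#' @return list: `mirna_cpm` and `gene_fpkm` matrices (columns are the
#'   first `n_expr_samples` cohort samples), each with a `"unit"`
#'   attribute.
#' @export
simulate_expression <- function(events, mirnas, genes, cfg) {
  stopifnot(is(cfg, "synthetic_config"))
  set.seed(cfg$seed + 33L)
  samples <- .sample_ids(cfg$n_samples)[seq_len(cfg$n_expr_samples)]
  ns <- length(samples)

  mats <- unlist(mirnas$mature_ids, use.names = FALSE)
  hp_of <- rep(mirnas$mirna_id, lengths(mirnas$mature_ids))
  nm <- length(mats)
  inc3 <- events[events$included & events$role == "3p" &
                   events$sample_id %in% samples, , drop = FALSE]
  if (nm > 0L) {
    mu <- 2^rnorm(nm, 6, 2)
    mu_mat <- matrix(mu, nm, ns, dimnames = list(mats, samples))
    if (nrow(inc3)) {
      key <- unique(paste(inc3$mirna_id, inc3$sample_id, sep = "\r"))
      idx <- cbind(match(sub("\r.*", "", key), hp_of),
                   match(sub(".*\r", "", key), samples))
      # a hairpin's fold change applies to both of its mature arms
      for (arm_off in 0:1) {
        rows <- idx[, 1L] + arm_off
        ok <- !is.na(rows) & rows <= nm & hp_of[rows] == hp_of[idx[, 1L]]
        mu_mat[cbind(rows[ok], idx[ok, 2L])] <-
          mu_mat[cbind(rows[ok], idx[ok, 2L])] * cfg$mirna_fold_change
      }
    }
    size <- if (cfg$dispersion > 0) 1 / cfg$dispersion else 1e8
    counts <- matrix(rnbinom(nm * ns, mu = as.vector(mu_mat), size = size),
                     nm, ns, dimnames = list(mats, samples))
    tot <- colSums(counts)
    tot[tot == 0] <- 1
    mirna_cpm <- sweep(counts, 2L, tot, "/") * 1e6
  } else {
    mirna_cpm <- matrix(numeric(0), 0L, ns, dimnames = list(NULL, samples))
  }
  attr(mirna_cpm, "unit") <- "cpm"

  gid <- genes$gene_id
  base <- rnorm(length(gid), 3.5, 1.5)
  lmat <- matrix(base, length(gid), ns, dimnames = list(gid, samples)) +
    matrix(rnorm(length(gid) * ns, 0, 0.5), length(gid), ns)
  if (nrow(inc3)) {
    p5 <- inc3[!is.na(inc3$partner_gene_id) & inc3$partner_gene_id %in% gid, ,
               drop = FALSE]
    if (nrow(p5)) {
      at <- unique(cbind(match(p5$partner_gene_id, gid),
                         match(p5$sample_id, samples)))
      lmat[at] <- lmat[at] + cfg$partner5_shift
    }
  }
  gene_fpkm <- 2^lmat
  attr(gene_fpkm, "unit") <- "fpkm"
  list(mirna_cpm = mirna_cpm, gene_fpkm = gene_fpkm)
}

#' Simulate a complete cohort and optionally write it to disk
#'
#' Runs [simulate_annotation()], the real [assign_hosts()] on the
#' simulated annotation, [simulate_fusions()], the filter and inclusion
#' stages, and [simulate_expression()]. With `dir` the cohort is written
#' as `genes.gtf`, `mirnas.gff3`, `fusions.tsv` (generic dialect),
#' `mirna_cpm.tsv`, `gene_fpkm.tsv` and `config.yaml`, so the file
#' readers can be exercised end-to-end.
#'
#' @param cfg a [synthetic_config()].
#' @param dir optional output directory (created if missing).
#' @return list: `config`, `genes`, `mirnas`, `elements`, `truth`,
#'   `assignments`, `calls` (raw), `filtered`, `events`, `expression`,
#'   and `dir` when written.
#' @export
simulate_cohort <- function(cfg = synthetic_config(), dir = NULL) {
  ann <- simulate_annotation(cfg)
  asg <- assign_hosts(ann$mirnas, ann$genes, downstream_bp = cfg$downstream_bp)
  calls <- simulate_fusions(ann$genes, asg, cfg, mirnas = ann$mirnas)
  filtered <- filter_fusion_calls(calls)
  events <- map_mirnas_to_fusions(filtered, asg, ann$mirnas, ann$genes,
                                  downstream_bp = cfg$downstream_bp)
  expr <- simulate_expression(events, ann$mirnas, ann$genes, cfg)
  out <- list(config = cfg, genes = ann$genes, mirnas = ann$mirnas,
              elements = ann$elements,
              truth = c(list(host_map = ann$truth), attr(calls, "truth")),
              assignments = asg, calls = calls, filtered = filtered,
              events = events, expression = expr)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_annotation(ann$genes, file.path(dir, "genes.gtf"), "gtf")
    write_mirna_annotation(ann$mirnas, file.path(dir, "mirnas.gff3"))
    write_fusion_calls(calls, file.path(dir, "fusions.tsv"))
    write_expression_matrix(expr$mirna_cpm, file.path(dir, "mirna_cpm.tsv"))
    write_expression_matrix(expr$gene_fpkm, file.path(dir, "gene_fpkm.tsv"))
    cfg_out <- cfg
    class(cfg_out) <- "list"
    cfg_out$frame_probs <- as.list(cfg_out$frame_probs)
    cfg_out$element_rates <- as.list(cfg_out$element_rates)
    yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
    out$dir <- dir
  }
  out
}
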