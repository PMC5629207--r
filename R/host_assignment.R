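# Host-gene assignment of pre-miRNA hairpins.

#' Assign each pre-miRNA hairpin to a host gene
#'
#' A hairpin is `intragenic` when its span is fully contained in a gene
#' span (strand-matched when `same_strand`); otherwise `downstream2kb`
#' when it is fully contained in the strand-aware window of
#' `downstream_bp` bases immediately 3' of some gene's end; otherwise
#' `unassigned`. The downstream rescue is considered only for hairpins
#' with no intragenic host anywhere. Ties are broken by the smallest
#' enclosing gene span (intragenic) or the smallest gap (downstream),
#' then lexicographic `gene_id`, so results are deterministic.
#'
#' @param mirnas GRanges with a `mirna_id` metadata column.
#' @param genes GRanges with a `gene_id` metadata column.
#' @param downstream_bp size of the downstream rescue window (bp, >= 0).
#' @param same_strand require the hairpin on the same strand as its host.
#' @return data frame with one row per hairpin: `mirna_id`, `gene_id`
#'   (`NA` when unassigned), `relation`
#'   (`intragenic`/`downstream2kb`/`unassigned`), `distance_bp` (0 for
#'   intragenic, gap for downstream, `NA` otherwise), sorted by
#'   `mirna_id`.
#' @export
assign_hosts <- function(mirnas, genes, downstream_bp = 2000, same_strand = TRUE) {
  stopifnot(is(mirnas, "GRanges"), is(genes, "GRanges"), downstream_bp >= 0)
  n <- length(mirnas)
  gene_id <- rep(NA_character_, n)
  relation <- rep("unassigned", n)
  distance <- rep(NA_real_, n)

  off_chrom <- !(as.character(seqnames(mirnas)) %in%
                   unique(as.character(seqnames(genes))))
  if (any(off_chrom))
    warning(sum(off_chrom), " hairpin(s) on chromosomes absent from the ",
            "gene annotation left unassigned")

  gid <- genes$gene_id
  gw <- width(genes)
  pick_best <- function(hits, rank1) {
    # per query, smallest rank1 then lexicographic gene id
    q <- queryHits(hits); s <- subjectHits(hits)
    ord <- order(q, rank1[s], gid[s])
    q <- q[ord]; s <- s[ord]
    keep <- !duplicated(q)
    list(q = q[keep], s = s[keep])
  }

  ov <- suppressWarnings(findOverlaps(mirnas, genes, type = "within",
                                      ignore.strand = !same_strand))
  if (length(ov)) {
    best <- pick_best(ov, rank1 = gw)
    gene_id[best$q] <- gid[best$s]
    relation[best$q] <- "intragenic"
    distance[best$q] <- 0
  }

  un <- which(relation == "unassigned" & !off_chrom)
  if (downstream_bp > 0 && length(un)) {
    dwin <- suppressWarnings(flank(genes, width = downstream_bp, start = FALSE))
    ov2 <- suppressWarnings(findOverlaps(mirnas[un], dwin, type = "within",
                                         ignore.strand = !same_strand))
    if (length(ov2)) {
      s <- subjectHits(ov2)
      q <- un[queryHits(ov2)]
      gap <- ifelse(as.character(strand(genes))[s] == "+",
                    start(mirnas)[q] - end(genes)[s],
                    start(genes)[s] - end(mirnas)[q])
      # rank candidates by gap then gene id, per hairpin
      ord <- order(q, gap, gid[s])
      q <- q[ord]; s <- s[ord]; gap <- gap[ord]
      keep <- !duplicated(q)
      gene_id[q[keep]] <- gid[s[keep]]
      relation[q[keep]] <- "downstream2kb"
      distance[q[keep]] <- gap[keep]
    }
  }

  out <- data.frame(mirna_id = mirnas$mirna_id, gene_id = gene_id,
                    relation = relation, distance_bp = distance,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reduce clustered hairpins to a single precursor per host gene
#'
#' MicroRNAs often occur in genomic clusters inside one host gene, which
#' biases host-level overlap statistics. This keeps, for every distinct
#' host gene, the precursor whose strand-aware 5' end lies most upstream
#' within the host; ties break on lexicographic `mirna_id`. Unassigned
#' hairpins are dropped.
#'
#' @param assignments output of [assign_hosts()].
#' @param mirnas the GRanges the assignments were computed from.
#' @return the reduced assignment data frame (one row per host gene).
#' @export
reduce_to_single_precursor <- function(assignments, mirnas) {
  asg <- assignments[assignments$relation != "unassigned", , drop = FALSE]
  if (nrow(asg) == 0L) return(asg)
  i <- match(asg$mirna_id, mirnas$mirna_id)
  if (anyNA(i)) stop("assignment refers to unknown mirna_id")
  key5 <- ifelse(as.character(strand(mirnas))[i] == "+",
                 start(mirnas)[i], -end(mirnas)[i])
  ord <- order(asg$gene_id, key5, asg$mirna_id)
  asg <- asg[ord, , drop = FALSE]
  out <- asg[!duplicated(asg$gene_id), , drop = FALSE]
  out <- out[order(out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
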