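# Flag-based filtering of fusion calls, fused-segment arithmetic, and the
# miRNA inclusion call.

#' Default exclusion flags for fusion-call filtering
#'
#' FusionCatcher description flags associated with a high false-positive
#' rate; calls carrying any of these are removed by
#' [filter_fusion_calls()]. Calls flagged `healthy` (fusion previously
#' seen in normal tissue) are retained but annotated.
#'
#' @format character vector of 26 flags.
#' @export
fusion_exclusion_flags <- c(
  "banned", "bodymap2", "cacg", "conjoing", "cta_gene", "ctb_gene",
  "ctc_gene", "ctd_gene", "distance1000bp", "ensembl_fully_overlapping",
  "ensembl_same_strand_overlapping", "gtex", "hpa", "mt",
  "pair_pseudo_genes", "paralogs", "readthrough",
  "refseq_fully_overlapping", "refseq_same_strand_overlapping", "rp_gene",
  "rp11_gene", "rrna", "similar_reads", "similar_symbols",
  "ucsc_fully_overlapping", "ucsc_same_strand_overlapping")

#' Filter fusion calls by description flags
#'
#' Removes calls carrying any excluded flag. Idempotent; the number of
#' removed calls is kept in the `"n_excluded"` attribute.
#'
#' @param calls data frame from [read_fusion_calls()].
#' @param exclusion_flags flags that trigger removal (default
#'   [fusion_exclusion_flags]).
#' @return the retained calls, with the `healthy` column updated.
#' @export
filter_fusion_calls <- function(calls, exclusion_flags = fusion_exclusion_flags) {
  fl <- strsplit(calls$flags, ";", fixed = TRUE)
  drop <- vapply(fl, function(f) any(f %in% exclusion_flags), logical(1))
  out <- calls[!drop, , drop = FALSE]
  out$healthy <- vapply(fl[!drop], function(f) "healthy" %in% f, logical(1))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Collapse duplicate fusion calls
#'
#' Multiple transcript isoforms of the same
#' `(sample, gene5, gene3, bp5, bp3)` tuple collapse to one call (the
#' first source row); distinct breakpoints remain distinct calls.
#'
#' @param calls fusion-call data frame.
#' @return deduplicated calls.
#' @export
dedupe_fusion_calls <- function(calls) {
  key <- paste(calls$sample_id, calls$gene5_id, calls$gene3_id,
               calls$bp5_chrom, calls$bp5_pos, calls$bp5_strand,
               calls$bp3_chrom, calls$bp3_pos, calls$bp3_strand, sep = "\r")
  out <- calls[order(key, calls$call_index), , drop = FALSE]
  out <- out[!duplicated(paste(out$sample_id, out$gene5_id, out$gene3_id,
                               out$bp5_chrom, out$bp5_pos, out$bp5_strand,
                               out$bp3_chrom, out$bp3_pos, out$bp3_strand,
                               sep = "\r")), , drop = FALSE]
  out <- out[order(out$call_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# vectorised segment bounds; breakpoints are clipped into the gene span.
# The gene's annotated strand governs which end is 5'; the breakpoint base
# itself belongs to both segments.
.segment_bounds <- function(gs, ge, gstrand, bp, role, ext = 0) {
  clipped <- bp < gs | bp > ge
  bp <- pmin(pmax(bp, gs), ge)
  plus <- gstrand == "+"
  if (role == "5p") {
    lo <- ifelse(plus, gs, bp)
    hi <- ifelse(plus, bp, ge)
  } else {
    lo <- ifelse(plus, bp, gs - ext)
    hi <- ifelse(plus, ge + ext, bp)
  }
  data.frame(lo = lo, hi = hi, clipped = clipped)
}

#' Fused gene segment for one partner of a fusion call
#'
#' For the 5' role the segment runs from the gene's transcription 5' end
#' to the breakpoint; for the 3' role from the breakpoint to the gene's
#' 3' end, optionally extended by `downstream_bp` (used when testing
#' hairpins rescued by the downstream rule). The breakpoint base belongs
#' to both segments. A breakpoint outside the gene span is clipped to the
#' span with a warning. Returns `NULL` when the partner id is absent or
#' unannotated.
#'
#' @param call one-row fusion-call data frame.
#' @param role `"5p"` or `"3p"`: which partner's segment to compute.
#' @param genes gene GRanges (lookup by `gene_id`).
#' @param downstream_bp extension of the 3' end for 3p roles (default 0).
#' @return GRanges of length 1 with `gene_id` and `role` columns, or `NULL`.
#' @export
fused_segment <- function(call, role = c("5p", "3p"), genes, downstream_bp = 0) {
  role <- match.arg(role)
  stopifnot(nrow(call) == 1L)
  gid <- if (role == "5p") call$gene5_id else call$gene3_id
  if (is.na(gid)) return(NULL)
  i <- match(gid, genes$gene_id)
  if (is.na(i)) return(NULL)
  bp <- if (role == "5p") call$bp5_pos else call$bp3_pos
  b <- .segment_bounds(start(genes)[i], end(genes)[i],
                       as.character(strand(genes))[i], bp, role,
                       ext = if (role == "3p") downstream_bp else 0)
  if (b$clipped)
    warning("breakpoint ", bp, " outside span of ", gid, "; clipped")
  GRanges(seqnames(genes)[i], IRanges(b$lo, b$hi), strand = strand(genes)[i],
          gene_id = gid, role = role)
}

#' Call miRNA inclusion in fusion transcripts
#'
#' Emits one event per (hairpin, call, role) where the hairpin's host
#' gene is the 5' or 3' partner of a (deduplicated) fusion call.
#' `included` is `TRUE` when the hairpin lies fully inside the fused
#' segment of its host; for hairpins rescued by the downstream rule the
#' 3p segment is extended by `downstream_bp` (the rescue never applies
#' to 5p roles). A hairpin straddling the breakpoint is by construction
#' never included.
#'
#' @param calls filtered fusion calls.
#' @param assignments output of [assign_hosts()].
#' @param mirnas hairpin GRanges.
#' @param genes gene GRanges.
#' @param downstream_bp downstream rescue window (bp).
#' @return data frame with one row per event: `mirna_id`,
#'   `host_gene_id`, `role`, `sample_id`, `partner_gene_id`, `included`,
#'   `frame_class`, `breakpoint` (`chrom:pos:strand` on the host side),
#'   `bp_pos`, `call_index`.
#' @export
map_mirnas_to_fusions <- function(calls, assignments, mirnas, genes,
                                  downstream_bp = 2000) {
  calls <- dedupe_fusion_calls(calls)
  asg <- assignments[assignments$relation != "unassigned", , drop = FALSE]
  empty <- data.frame(mirna_id = character(0), host_gene_id = character(0),
                      role = character(0), sample_id = character(0),
                      partner_gene_id = character(0), included = logical(0),
                      frame_class = character(0), breakpoint = character(0),
                      bp_pos = numeric(0), call_index = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(asg) == 0L || nrow(calls) == 0L) return(empty)

  mi <- match(asg$mirna_id, mirnas$mirna_id)
  gi <- match(asg$gene_id, genes$gene_id)
  if (anyNA(mi) || anyNA(gi))
    stop("assignments refer to hairpins or genes absent from the annotation")
  hosts <- data.frame(
    gene_id = asg$gene_id, mirna_id = asg$mirna_id, relation = asg$relation,
    m_chrom = as.character(seqnames(mirnas))[mi],
    m_start = start(mirnas)[mi], m_end = end(mirnas)[mi],
    g_start = start(genes)[gi], g_end = end(genes)[gi],
    g_chrom = as.character(seqnames(genes))[gi],
    g_strand = as.character(strand(genes))[gi],
    stringsAsFactors = FALSE)

  n_clipped <- 0L
  one_role <- function(role) {
    host_col <- if (role == "5p") "gene5_id" else "gene3_id"
    partner_col <- if (role == "5p") "gene3_id" else "gene5_id"
    cs <- calls[!is.na(calls[[host_col]]), , drop = FALSE]
    m <- merge(cs, hosts, by.x = host_col, by.y = "gene_id")
    if (nrow(m) == 0L) return(NULL)
    bp_pos <- if (role == "5p") m$bp5_pos else m$bp3_pos
    bp_chrom <- if (role == "5p") m$bp5_chrom else m$bp3_chrom
    bp_strand <- if (role == "5p") m$bp5_strand else m$bp3_strand
    ext <- ifelse(role == "3p" & m$relation == "downstream2kb", downstream_bp, 0)
    b <- .segment_bounds(m$g_start, m$g_end, m$g_strand, bp_pos, role, ext)
    n_clipped <<- n_clipped + sum(b$clipped & bp_chrom == m$g_chrom)
    included <- bp_chrom == m$g_chrom & m$m_chrom == m$g_chrom &
      m$m_start >= b$lo & m$m_end <= b$hi
    data.frame(mirna_id = m$mirna_id, host_gene_id = m[[host_col]],
               role = role, sample_id = m$sample_id,
               partner_gene_id = m[[partner_col]], included = included,
               frame_class = m$frame_class,
               breakpoint = sprintf("%s:%d:%s", bp_chrom, as.integer(bp_pos),
                                    bp_strand),
               bp_pos = bp_pos, call_index = m$call_index,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(one_role("5p"), one_role("3p"))
  if (is.null(ev)) return(empty)
  if (n_clipped > 0L)
    warning(n_clipped, " breakpoint(s) outside the partner gene span were ",
            "clipped to the span")
  ev <- ev[order(ev$sample_id, ev$mirna_id, ev$role, ev$call_index), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
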