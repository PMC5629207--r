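# Readers and writers for the annotation and table formats the pipeline
# touches. Everything genomic becomes a GRanges (1-based closed, strand
# "+"/"-"); everything tabular becomes a plain data frame.

.first_attr <- function(mc, candidates) {
  for (nm in candidates) if (!is.null(mc[[nm]])) return(as.character(mc[[nm]]))
  NULL
}

.check_lines <- function(path, fmt) {
  # called only after rtracklayer fails, to name the offending line
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 8L) stop("malformed ", fmt, " line ", i, " in ", path, call. = FALSE)
  }
}

#' Read gene models from a GTF or GFF3 file
#'
#' Keeps `gene` features only. Gene identifier, symbol and biotype are taken
#' from the `gene_id`/`ID`, `gene_name`/`Name` and
#' `gene_type`/`gene_biotype`/`biotype` attributes (GENCODE dialect).
#' Multiple annotation lines for one `gene_id` on the same chromosome and
#' strand (alternative loci) are collapsed to the widest enclosing span;
#' the same `gene_id` on different chromosomes or strands is an error.
#'
#' @param path file path.
#' @param fmt `"gtf"` or `"gff3"`.
#' @return a [GenomicRanges::GRanges] with metadata columns `gene_id`,
#'   `symbol`, `biotype`; names are gene ids; gene size in bp is
#'   `width()` of the object.
#' @export
read_gene_annotation <- function(path, fmt = c("gtf", "gff3")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) {
                   .check_lines(path, fmt)
                   stop("failed to parse ", path, " as ", fmt, ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", path)
  mc <- mcols(gr)
  gene_id <- .first_attr(mc, c("gene_id", "ID"))
  if (is.null(gene_id) || anyNA(gene_id))
    stop("gene feature without gene_id/ID attribute in ", path)
  symbol <- .first_attr(mc, c("gene_name", "Name")) %||% gene_id
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  biotype <- .first_attr(mc, c("gene_type", "gene_biotype", "biotype")) %||%
    rep(NA_character_, length(gr))
  if (any(as.character(strand(gr)) == "*"))
    stop("gene feature without strand in ", path)

  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr),
                   strand = as.character(strand(gr)),
                   gene_id = gene_id, symbol = symbol, biotype = biotype,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) {
    key <- tapply(paste(df$chrom, df$strand), df$gene_id,
                  function(x) length(unique(x)))
    if (any(key > 1L))
      stop("duplicate gene_id on different chromosome/strand: ",
           paste(names(key)[key > 1L], collapse = ", "))
    df <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
      g$start <- min(g$start); g$end <- max(g$end); g[1L, , drop = FALSE]
    }))
  }
  df <- df[order(df$chrom, df$start, df$end, df$gene_id), , drop = FALSE]
  out <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                 gene_id = df$gene_id, symbol = df$symbol, biotype = df$biotype)
  names(out) <- out$gene_id
  out
}

#' Write gene models as GTF or GFF3
#'
#' Inverse of [read_gene_annotation()]: emits one `gene` feature per record
#' with `gene_id`, `gene_name` and `gene_type` attributes.
#'
#' @param genes GRanges as returned by [read_gene_annotation()].
#' @param path output path.
#' @param fmt `"gtf"` or `"gff3"`.
#' @export
write_gene_annotation <- function(genes, path, fmt = c("gtf", "gff3")) {
  fmt <- match.arg(fmt)
  out <- granges(genes)
  out$source <- "mirfusion"
  out$type <- "gene"
  out$gene_id <- genes$gene_id
  out$gene_name <- genes$symbol
  out$gene_type <- genes$biotype
  if (fmt == "gff3") out$ID <- genes$gene_id
  rtracklayer::export(out, path, format = fmt)
  invisible(path)
}

#' Read pre-miRNA annotation (miRBase GFF3 dialect)
#'
#' One record per `miRNA_primary_transcript` (hairpin) feature; mature
#' `miRNA` features are attached to their hairpin through the
#' `Derives_from` attribute. A mature feature whose parent hairpin is
#' absent is dropped with a warning.
#'
#' @param path GFF3 file path.
#' @return GRanges with metadata columns `mirna_id` (hairpin name) and
#'   `mature_ids` (a CharacterList, possibly empty per hairpin).
#' @export
read_mirna_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   .check_lines(path, "gff3")
                   stop("failed to parse ", path, ": ", conditionMessage(e),
                        call. = FALSE)
                 })
  type <- as.character(gr$type)
  hp <- gr[type == "miRNA_primary_transcript"]
  mt <- gr[type == "miRNA"]
  if (length(hp) == 0L) stop("no miRNA_primary_transcript features in ", path)
  hp_uid <- as.character(hp$ID %||% hp$Name)
  mirna_id <- .first_attr(mcols(hp), c("Name", "ID"))
  if (anyDuplicated(mirna_id))
    stop("duplicate hairpin names in ", path, ": ",
         paste(unique(mirna_id[duplicated(mirna_id)]), collapse = ", "))

  mature_ids <- rep(list(character(0)), length(hp))
  if (length(mt)) {
    der <- mt$Derives_from
    der <- if (is(der, "List")) vapply(der, function(x)
      if (length(x)) x[[1]] else NA_character_, character(1)) else as.character(der)
    mname <- .first_attr(mcols(mt), c("Name", "ID"))
    parent <- match(der, hp_uid)
    orphan <- is.na(parent)
    if (any(orphan))
      warning(sum(orphan), " mature miRNA feature(s) without a parent ",
              "hairpin dropped: ", paste(head(mname[orphan], 5L), collapse = ", "))
    keep <- which(!orphan)
    mature_ids <- unname(split(mname[keep],
                               factor(parent[keep], levels = seq_along(hp))))
  }
  out <- granges(hp)
  out$mirna_id <- mirna_id
  out$mature_ids <- as(mature_ids, "CharacterList")
  names(out) <- mirna_id
  ord <- order(as.character(seqnames(out)), start(out), out$mirna_id)
  out[ord]
}

#' Write pre-miRNA annotation as miRBase-dialect GFF3
#'
#' @param mirnas GRanges as returned by [read_mirna_annotation()].
#' @param path output path.
#' @export
write_mirna_annotation <- function(mirnas, path) {
  hp <- granges(mirnas)
  hp$source <- "mirfusion"
  hp$type <- "miRNA_primary_transcript"
  hp$ID <- mirnas$mirna_id
  hp$Name <- mirnas$mirna_id
  hp$Derives_from <- NA_character_
  n_mat <- lengths(mirnas$mature_ids)
  if (sum(n_mat)) {
    mt <- rep(granges(mirnas), n_mat)
    mt$source <- "mirfusion"
    mt$type <- "miRNA"
    mt$ID <- unlist(mirnas$mature_ids, use.names = FALSE)
    mt$Name <- mt$ID
    mt$Derives_from <- rep(mirnas$mirna_id, n_mat)
    hp <- c(hp, mt)
  }
  rtracklayer::export(hp, path, format = "gff3")
  invisible(path)
}

.parse_breakpoint <- function(x) {
  m <- regmatches(x, regexec("^([^:[:space:]]+):([0-9]+):([+-])$", x))
  bad <- lengths(m) != 4L
  chrom <- pos <- st <- rep(NA_character_, length(x))
  ok <- which(!bad)
  if (length(ok)) {
    mm <- do.call(rbind, m[ok])
    chrom[ok] <- mm[, 2L]; pos[ok] <- mm[, 3L]; st[ok] <- mm[, 4L]
  }
  data.frame(chrom = chrom, pos = as.numeric(pos), strand = st,
             ok = !bad, stringsAsFactors = FALSE)
}

.fc_cols <- c(
  gene5_id = "Gene_1_id(5end_fusion_partner)",
  gene3_id = "Gene_2_id(3end_fusion_partner)",
  bp5 = "Fusion_point_for_gene_1(5end_fusion_partner)",
  bp3 = "Fusion_point_for_gene_2(3end_fusion_partner)",
  flags = "Fusion_description",
  effect = "Predicted_effect")

.map_frame_class <- function(effect) {
  e <- tolower(trimws(effect))
  out <- rep("other", length(e))
  out[e == "in-frame"] <- "in-frame"
  out[e == "out-of-frame"] <- "out-of-frame"
  out
}

.na_gene <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", ".", "NA")] <- NA_character_
  x
}

#' Read fusion calls from a TSV table
#'
#' Two dialects are supported. `"generic"` is an 8-column table
#' (`sample`, `gene5`, `gene3`, `bp5`, `bp3`, `frame`, `flags`, `support`)
#' with breakpoints as `chrom:pos:strand` strings and flags separated by
#' `";"`. `"fusioncatcher"` expects the FusionCatcher candidate-fusion
#' column names plus a `sample` column; flags come from
#' `Fusion_description` (comma separated) and the frame class from
#' `Predicted_effect` (`in-frame` / `out-of-frame` / everything else
#' `other`). Rows with an unparseable breakpoint are rejected with a
#' warning; the rejected row numbers and reasons are kept in the
#' `"rejected"` attribute.
#'
#' @param path TSV path.
#' @param dialect `"fusioncatcher"` or `"generic"`.
#' @return data frame with columns `sample_id`, `gene5_id`, `gene3_id`,
#'   `bp5_chrom`, `bp5_pos`, `bp5_strand`, `bp3_chrom`, `bp3_pos`,
#'   `bp3_strand`, `frame_class`, `flags` (";"-joined), `healthy`,
#'   `support`, `call_index` (source row number).
#' @export
read_fusion_calls <- function(path, dialect = c("fusioncatcher", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", fill = FALSE,
                    stringsAsFactors = FALSE)
  if (dialect == "generic") {
    need <- c("sample", "gene5", "gene3", "bp5", "bp3", "frame", "flags", "support")
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("generic fusion table missing column(s): ",
                           paste(miss, collapse = ", "))
    sample_id <- raw$sample
    gene5 <- .na_gene(raw$gene5); gene3 <- .na_gene(raw$gene3)
    bp5 <- raw$bp5; bp3 <- raw$bp3
    frame_class <- .map_frame_class(raw$frame)
    flags <- gsub("\\s+", "", raw$flags)
    support <- suppressWarnings(as.integer(raw$support))
  } else {
    need <- c("sample", unname(.fc_cols))
    miss <- setdiff(need, names(raw))
    if (length(miss)) stop("fusioncatcher table missing column(s): ",
                           paste(miss, collapse = ", "))
    sample_id <- raw$sample
    gene5 <- .na_gene(raw[[.fc_cols[["gene5_id"]]]])
    gene3 <- .na_gene(raw[[.fc_cols[["gene3_id"]]]])
    bp5 <- raw[[.fc_cols[["bp5"]]]]
    bp3 <- raw[[.fc_cols[["bp3"]]]]
    frame_class <- .map_frame_class(raw[[.fc_cols[["effect"]]]])
    flags <- gsub(",", ";", gsub("\\s+", "", raw[[.fc_cols[["flags"]]]]), fixed = TRUE)
    support <- if ("Spanning_unique_reads" %in% names(raw))
      suppressWarnings(as.integer(raw$Spanning_unique_reads)) else NA_integer_
  }
  p5 <- .parse_breakpoint(bp5)
  p3 <- .parse_breakpoint(bp3)
  ok <- p5$ok & p3$ok
  calls <- data.frame(
    sample_id = sample_id, gene5_id = gene5, gene3_id = gene3,
    bp5_chrom = p5$chrom, bp5_pos = p5$pos, bp5_strand = p5$strand,
    bp3_chrom = p3$chrom, bp3_pos = p3$pos, bp3_strand = p3$strand,
    frame_class = frame_class, flags = flags,
    healthy = vapply(strsplit(flags, ";", fixed = TRUE),
                     function(f) "healthy" %in% f, logical(1)),
    support = support, call_index = seq_len(nrow(raw)),
    stringsAsFactors = FALSE)
  if (any(!ok)) {
    rejected <- data.frame(row = which(!ok),
                           reason = paste0("unparseable breakpoint: ",
                                           ifelse(!p5$ok[!ok], bp5[!ok], bp3[!ok])),
                           stringsAsFactors = FALSE)
    warning(nrow(rejected), " fusion call(s) rejected (unparseable breakpoint)")
  } else {
    rejected <- data.frame(row = integer(0), reason = character(0),
                           stringsAsFactors = FALSE)
  }
  calls <- calls[ok, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "rejected") <- rejected
  calls
}

#' Write fusion calls in the generic 8-column dialect
#'
#' @param calls data frame as returned by [read_fusion_calls()].
#' @param path output path.
#' @export
write_fusion_calls <- function(calls, path) {
  fmt_bp <- function(chrom, pos, strand) sprintf("%s:%d:%s", chrom, as.integer(pos), strand)
  out <- data.frame(
    sample = calls$sample_id,
    gene5 = ifelse(is.na(calls$gene5_id), ".", calls$gene5_id),
    gene3 = ifelse(is.na(calls$gene3_id), ".", calls$gene3_id),
    bp5 = fmt_bp(calls$bp5_chrom, calls$bp5_pos, calls$bp5_strand),
    bp3 = fmt_bp(calls$bp3_chrom, calls$bp3_pos, calls$bp3_strand),
    frame = calls$frame_class,
    flags = ifelse(nzchar(calls$flags), calls$flags, "."),
    support = ifelse(is.na(calls$support), 0L, calls$support),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample expression matrix from TSV
#'
#' First column holds feature identifiers, remaining columns one sample
#' each. Values must be numeric and non-negative; ragged rows and empty
#' files are errors.
#'
#' @param path TSV path.
#' @param unit `"cpm"` (miRNA counts per million) or `"fpkm"` (genes).
#' @return numeric matrix with a `"unit"` attribute.
#' @export
read_expression_matrix <- function(path, unit = c("cpm", "fpkm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.delim(path, header = TRUE, sep = "\t", fill = FALSE,
                            check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) stop("malformed expression matrix ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty expression matrix: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("non-numeric values in expression matrix ", path)
  if (any(m < 0)) stop("negative values in expression matrix ", path)
  rownames(m) <- ids
  attr(m, "unit") <- unit
  m
}

#' Write an expression matrix as TSV
#'
#' @param m numeric matrix with feature row names.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
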