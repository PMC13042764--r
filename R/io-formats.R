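# Readers/writers for the external formats the pipeline touches, plus the
# internal coordinate convention: everything inside the package is 0-based
# half-open. GTF (1-based closed) is converted at the boundary; BED is taken
# verbatim.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,chrom,strand identifiers and location
#' @param exons integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon; rows must be sorted by genomic start and
#'   non-overlapping
#' @param cds_start,cds_end CDS bounds in transcript (mature, 5'->3')
#'   coordinates, 0-based half-open, or `NA` when no CDS is annotated
#' @return object of class `transcript_model`
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript must have at least one exon")
  ord <- order(exons[, 1])
  exons <- exons[ord, , drop = FALSE]
  if (any(exons[, 2] <= exons[, 1]))
    stop("exon end must be > exon start")
  if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    stop("exons overlap in transcript ", transcript_id)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  len <- sum(exons[, 2] - exons[, 1])
  if (!is.na(cds_start)) {
    if (cds_start < 0 || cds_end > len || cds_start >= cds_end)
      stop("CDS bounds outside mature transcript in ", transcript_id)
    if ((cds_end - cds_start) %% 3 != 0)
      stop("CDS length not a multiple of 3 in ", transcript_id)
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
         strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
    class = "transcript_model")
}

#' Mature transcript length
#' @param model a `transcript_model`
#' @return integer, sum of exon lengths
#' @export
transcript_length <- function(model) {
  sum(model$exons[, 2] - model$exons[, 1])
}

#' Introns of a transcript model
#'
#' Gaps between consecutive exons, 0-based half-open, in genomic order.
#'
#' @param model a `transcript_model`
#' @return integer matrix with columns `start`, `end` (0 rows for
#'   single-exon transcripts)
#' @export
transcript_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  matrix(c(ex[-n, 2], ex[-1, 1]), ncol = 2,
         dimnames = list(NULL, c("start", "end")))
}

# map a position in transcript (mature, 5'->3') coordinates to its genomic
# position (0-based); pos may be a vector
transcript_to_genomic <- function(model, pos) {
  lens <- model$exons[, 2] - model$exons[, 1]
  cum <- cumsum(lens)
  total <- cum[length(cum)]
  if (any(pos < 0 | pos >= total)) stop("position outside mature transcript")
  if (model$strand == "-") pos <- total - 1L - pos
  idx <- findInterval(pos, c(0, cum), rightmost.closed = FALSE)
  offset <- pos - c(0, cum)[idx]
  as.integer(model$exons[idx, 1] + offset)
}

# inverse of transcript_to_genomic for a single genomic position; NA if the
# position falls in an intron / outside the transcript
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  lens <- ex[, 2] - ex[, 1]
  cum0 <- c(0, cumsum(lens))
  hit <- which(gpos >= ex[, 1] & gpos < ex[, 2])
  if (length(hit) == 0) return(NA_integer_)
  t <- cum0[hit] + (gpos - ex[hit, 1])
  if (model$strand == "-") t <- sum(lens) - 1L - t
  as.integer(t)
}

gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read gene annotation from GTF
#'
#' Parses `gene`/`transcript`/`exon` (and optionally `CDS`) features,
#' converting 1-based closed GTF coordinates to the internal 0-based
#' half-open convention. Exons are grouped per transcript and sorted by
#' genomic start; CDS features are converted to transcript coordinates.
#' Transcripts with no exon feature are dropped with a warning; an exon
#' outside its declared transcript bounds triggers a warning but is kept.
#'
#' @param path GTF file
#' @return named list of [transcript_model()] objects
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 9)
  if (length(bad) > 0)
    stop("unparseable GTF line ", which(body)[bad[1]], " in ", path,
         ": expected 9 tab-separated fields")
  starts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1]
    stop("unparseable GTF line ", which(body)[bad], " in ", path,
         ": non-numeric coordinates")
  }
  feat <- data.frame(
    seqnames = vapply(fields, `[`, "", 1),
    type = vapply(fields, `[`, "", 3),
    start = starts, end = ends,
    strand = vapply(fields, `[`, "", 7),
    attr = vapply(fields, `[`, "", 9),
    stringsAsFactors = FALSE)
  feat$transcript_id <- gtf_attr(feat$attr, "transcript_id")
  feat$gene_id <- gtf_attr(feat$attr, "gene_id")

  tx_rows <- feat[feat$type == "transcript", , drop = FALSE]
  ex_rows <- feat[feat$type == "exon", , drop = FALSE]
  cds_rows <- feat[feat$type == "CDS", , drop = FALSE]
  tx_ids <- unique(c(tx_rows$transcript_id, ex_rows$transcript_id))
  tx_ids <- tx_ids[!is.na(tx_ids)]

  dropped <- setdiff(tx_ids, unique(ex_rows$transcript_id))
  if (length(dropped) > 0)
    warning("dropping ", length(dropped),
            " transcript(s) with no exons: ",
            paste(head(dropped, 5), collapse = ", "))

  models <- list()
  for (tid in setdiff(tx_ids, dropped)) {
    ex <- ex_rows[ex_rows$transcript_id == tid, , drop = FALSE]
    # GTF 1-based closed -> 0-based half-open
    exons <- cbind(start = ex$start - 1L, end = ex$end)
    decl <- tx_rows[tx_rows$transcript_id == tid, , drop = FALSE]
    if (nrow(decl) == 1 &&
        (min(exons[, 1]) < decl$start - 1L || max(exons[, 2]) > decl$end))
      warning("exon outside declared bounds of transcript ", tid,
              " (kept)")
    m <- transcript_model(tid, ex$gene_id[1], ex$seqnames[1], ex$strand[1],
                          exons)
    cds <- cds_rows[cds_rows$transcript_id == tid, , drop = FALSE]
    if (nrow(cds) > 0) {
      gstarts <- cds$start - 1L
      gends <- cds$end
      tpos <- vapply(gstarts, function(g) genomic_to_transcript(m, g), 0L)
      tpos2 <- vapply(gends - 1L, function(g) genomic_to_transcript(m, g), 0L)
      cs <- min(c(tpos, tpos2))
      ce <- max(c(tpos, tpos2)) + 1L
      m <- transcript_model(tid, m$gene_id, m$chrom, m$strand, m$exons,
                            cds_start = cs, cds_end = ce)
    }
    models[[tid]] <- m
  }
  models
}

#' Write gene annotation to GTF
#'
#' Emits `gene`, `transcript`, `exon` and (when a CDS is present) `CDS`
#' features with 1-based closed coordinates. Output is deterministic:
#' models are written in list order, exons in genomic order.
#'
#' @param models named list of [transcript_model()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gene_annotation <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";',
                       m$gene_id, m$transcript_id)
    attr_gene <- sprintf('gene_id "%s";', m$gene_id)
    lines <- c(lines,
      sprintf("%s\tsplicemark\tgene\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, span[1] + 1L, span[2], m$strand, attr_gene),
      sprintf("%s\tsplicemark\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, span[1] + 1L, span[2], m$strand, attr_tx),
      sprintf("%s\tsplicemark\texon\t%d\t%d\t.\t%s\t.\t%s",
              m$chrom, m$exons[, 1] + 1L, m$exons[, 2], m$strand, attr_tx))
    if (!is.na(m$cds_start)) {
      cds <- transcript_interval_to_genomic(m, m$cds_start, m$cds_end)
      lines <- c(lines,
        sprintf("%s\tsplicemark\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                m$chrom, cds[, 1] + 1L, cds[, 2], m$strand, attr_tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# map a transcript-coordinate interval [tstart, tend) onto genomic exon
# pieces; returns a matrix of 0-based half-open genomic intervals in
# genomic order
transcript_interval_to_genomic <- function(model, tstart, tend) {
  lens <- model$exons[, 2] - model$exons[, 1]
  total <- sum(lens)
  stopifnot(tstart >= 0, tend <= total, tstart < tend)
  if (model$strand == "-") {
    tmp <- total - tend
    tend <- total - tstart
    tstart <- tmp
  }
  cum0 <- c(0, cumsum(lens))
  out <- NULL
  for (i in seq_len(nrow(model$exons))) {
    a <- max(tstart, cum0[i])
    b <- min(tend, cum0[i + 1])
    if (a < b) {
      gs <- model$exons[i, 1] + (a - cum0[i])
      out <- rbind(out, c(gs, gs + (b - a)))
    }
  }
  colnames(out) <- c("start", "end")
  out
}

#' Read a junction count matrix
#'
#' The counts file is tab-delimited with columns `chrom`, `intron_start`,
#' `intron_end`, `strand` followed by one integer column per sample; the
#' companion metadata file maps `sample` to `group`, `tissue` and
#' `tdp_status`. Duplicate junction rows are summed with a warning.
#'
#' @param path counts TSV
#' @param metadata_path sample metadata TSV
#' @param control_label group label treated as control-like
#' @param case_labels allowed case group labels
#' @return object of class `junction_count_matrix`: a list with `junctions`
#'   (data.frame), `counts` (junction x sample integer matrix) and
#'   `metadata` (data.frame)
#' @export
read_junction_counts <- function(path, metadata_path,
                                 control_label = "control",
                                 case_labels = c("ALS", "FTD")) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("counts file needs 4 key columns plus samples")
  key_cols <- c("chrom", "intron_start", "intron_end", "strand")
  if (!identical(colnames(tab)[1:4], key_cols))
    stop("counts file must start with columns: ",
         paste(key_cols, collapse = ", "))
  counts <- as.matrix(tab[, -(1:4), drop = FALSE])
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  jid <- junction_id(tab$chrom, tab$intron_start, tab$intron_end, tab$strand)
  if (anyDuplicated(jid)) {
    warning("summing ", sum(duplicated(jid)), " duplicate junction row(s)")
    counts <- rowsum(counts, group = jid, reorder = FALSE)
    keep <- !duplicated(jid)
    tab <- tab[keep, , drop = FALSE]
    counts <- counts[unique(jid), , drop = FALSE]
    storage.mode(counts) <- "integer"
    jid <- jid[keep]
  }
  junctions <- splice_junctions(tab$chrom, tab$intron_start, tab$intron_end,
                                tab$strand)
  rownames(counts) <- junctions$junction_id
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "tissue")
  if (!all(need %in% colnames(meta)))
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  missing <- setdiff(colnames(counts), meta$sample)
  if (length(missing) > 0)
    stop("samples missing from metadata: ",
         paste(head(missing, 5), collapse = ", "))
  bad <- setdiff(unique(meta$group), c(control_label, case_labels))
  if (length(bad) > 0)
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  junction_count_matrix(junctions, counts, meta)
}

#' Assemble a junction count matrix object
#'
#' @param junctions junction table from [splice_junctions()]
#' @param counts junction x sample integer matrix (rows follow `junctions`)
#' @param metadata data.frame with columns `sample`, `group`, `tissue` and
#'   optionally `tdp_status`
#' @return object of class `junction_count_matrix`
#' @export
junction_count_matrix <- function(junctions, counts, metadata) {
  stopifnot(nrow(junctions) == nrow(counts))
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(junctions$junction_id)) stop("duplicate junctions")
  if (any(counts < 0)) stop("negative counts")
  rownames(counts) <- junctions$junction_id
  metadata <- metadata[match(colnames(counts), metadata$sample), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(junctions = junctions, counts = counts,
                 metadata = metadata),
            class = "junction_count_matrix")
}

#' Write a junction count matrix and its sample metadata
#'
#' Inverse of [read_junction_counts()]; `read(write(x))` reproduces counts,
#' row order and metadata exactly.
#'
#' @param jcm a `junction_count_matrix`
#' @param path counts TSV to write
#' @param metadata_path metadata TSV to write
#' @return `path`, invisibly
#' @export
write_junction_counts <- function(jcm, path, metadata_path) {
  out <- cbind(jcm$junctions[, c("chrom", "intron_start", "intron_end",
                                 "strand")],
               as.data.frame(jcm$counts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(jcm$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an RBP peak set from BED
#'
#' BED3+ with 0-based half-open coordinates, loaded verbatim. The RBP name
#' is taken from the file stem, or from column 4 when `name_from =
#' "column"`.
#'
#' @param path BED file
#' @param name_from `"stem"` or `"column"`
#' @return object of class `rbp_peaks`: list with `rbp_name` and `peaks`
#'   (data.frame `chrom`, `start`, `end`)
#' @export
read_peaks <- function(path, name_from = c("stem", "column")) {
  name_from <- match.arg(name_from)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(rbp_peaks(sub("\\.bed$", "", basename(path)),
                     data.frame(chrom = character(0), start = integer(0),
                                end = integer(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  chrom <- vapply(fields, `[`, "", 1)
  start <- as.integer(vapply(fields, `[`, "", 2))
  end <- as.integer(vapply(fields, `[`, "", 3))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0)
    stop("invalid BED interval at line ", bad[1], " of ", path)
  name <- if (name_from == "column") {
    vapply(fields, function(x) if (length(x) >= 4) x[4] else NA_character_,
           "")[1]
  } else {
    sub("\\.bed$", "", basename(path))
  }
  rbp_peaks(name, data.frame(chrom = chrom, start = start, end = end,
                             stringsAsFactors = FALSE))
}

#' Construct an RBP peak set
#' @param rbp_name RBP name
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based half-open)
#' @return object of class `rbp_peaks`
#' @export
rbp_peaks <- function(rbp_name, peaks) {
  if (nrow(peaks) > 0 && any(peaks$start >= peaks$end))
    stop("peak start must be < end")
  structure(list(rbp_name = rbp_name,
                 peaks = peaks[, c("chrom", "start", "end"), drop = FALSE]),
            class = "rbp_peaks")
}

#' Write an RBP peak set to BED
#' @param ps an `rbp_peaks` object
#' @param path output BED file
#' @return `path`, invisibly
#' @export
write_peaks <- function(ps, path) {
  if (nrow(ps$peaks) == 0) {
    writeLines(character(0), path)
  } else {
    write.table(cbind(ps$peaks, name = ps$rbp_name), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Extract the mature (spliced) transcript sequence
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand transcripts, so the result is always 5'->3' mRNA sense.
#'
#' @param model a `transcript_model`
#' @param genome named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences
#' @return character string, the mature transcript sequence
#' @export
extract_transcript_sequence <- function(model, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!model$chrom %in% names(genome))
    stop("chromosome ", model$chrom, " absent from genome")
  chr <- genome[[model$chrom]]
  if (max(model$exons[, 2]) > length(chr))
    stop("exon beyond chromosome length in ", model$transcript_id)
  pieces <- substring(as.character(chr), model$exons[, 1] + 1L,
                      model$exons[, 2])
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp_chr(s)
  s
}

#' Assign junctions to genes via the annotation
#'
#' A junction belongs to the gene of the first transcript (in annotation
#' order) whose genomic span contains its intron on the same strand;
#' junctions inside no transcript get `NA`.
#'
#' @param junctions junction data.frame
#' @param annotation list of `transcript_model`
#' @return named character vector junction_id -> gene_id
#' @export
assign_junction_genes <- function(junctions, annotation) {
  out <- setNames(rep(NA_character_, nrow(junctions)),
                  junctions$junction_id)
  if (length(annotation) == 0 || nrow(junctions) == 0) return(out)
  tx <- data.frame(
    chrom = vapply(annotation, function(m) m$chrom, ""),
    start = vapply(annotation, function(m) min(m$exons[, 1]), 0),
    end = vapply(annotation, function(m) max(m$exons[, 2]), 0),
    strand = vapply(annotation, function(m) m$strand, ""),
    gene = vapply(annotation, function(m) m$gene_id, ""))
  jg <- GenomicRanges::GRanges(
    junctions$chrom,
    IRanges::IRanges(junctions$intron_start + 1L, junctions$intron_end),
    strand = junctions$strand)
  tg <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end),
    strand = tx$strand)
  hits <- GenomicRanges::findOverlaps(jg, tg, type = "within")
  first <- !duplicated(S4Vectors::queryHits(hits))
  out[S4Vectors::queryHits(hits)[first]] <-
    tx$gene[S4Vectors::subjectHits(hits)[first]]
  out
}

#' Read a genome FASTA
#' @param path FASTA file
#' @return named `DNAStringSet`
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome named `DNAStringSet` or named character vector
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
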