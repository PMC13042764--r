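# Reconstructs aberrant transcripts from splice junctions, enumerates
# open reading frames, predicts premature-termination-codon (PTC) fate
# under the 50-nt NMD boundary rule, and builds the custom peptide
# database (reference proteome + in-silico tryptic digest of novel ORFs)
# for mass-spectrometry search.

#' Reconstruct the aberrant transcript for a junction
#'
#' Starting from the unspliced pre-mRNA span of the canonical transcript,
#' splices out (i) every annotated intron with zero overlap with the
#' aberrant junction's intron interval and (ii) the aberrant intron
#' itself. The retained genomic segments form the exon chain; the mature
#' sequence is extracted in 5'->3' sense. Overlap is >= 1 shared base on
#' half-open intervals. With `junction = NULL` the canonical mature
#' transcript is reproduced; a junction identical to an annotated intron
#' is flagged `annotation_equivalent`.
#'
#' @param model canonical `transcript_model`
#' @param junction one-row junction data.frame, or `NULL`
#' @param genome named `DNAStringSet` or named character vector
#' @return object of class `aberrant_transcript`: list with
#'   `transcript_id`, `junction_id`, `chrom`, `strand`, `exon_chain`
#'   (genomic intervals, genomic order), `mature`, `annotation_equivalent`
#' @export
reconstruct_aberrant_transcript <- function(model, junction, genome) {
  span <- c(min(model$exons[, 1]), max(model$exons[, 2]))
  ann <- transcript_introns(model)
  ann_equiv <- FALSE
  if (is.null(junction)) {
    removed <- ann
    jid <- NA_character_
  } else {
    if (junction$chrom != model$chrom || junction$strand != model$strand)
      stop("junction and transcript differ in chromosome or strand")
    js <- junction$intron_start
    je <- junction$intron_end
    if (js < span[1] || je > span[2])
      stop("junction outside the transcript span")
    overlaps <- ann[, 1] < je & ann[, 2] > js
    ann_equiv <- any(ann[, 1] == js & ann[, 2] == je)
    removed <- rbind(ann[!overlaps, , drop = FALSE], c(js, je))
    removed <- removed[!duplicated(removed), , drop = FALSE]
    jid <- junction_id(junction$chrom, js, je, junction$strand)
  }
  removed <- removed[order(removed[, 1]), , drop = FALSE]
  chain <- interval_complement(span, removed)
  tmp <- transcript_model(paste0(model$transcript_id, ".ab"),
                          model$gene_id, model$chrom, model$strand, chain)
  structure(list(transcript_id = model$transcript_id, junction_id = jid,
                 chrom = model$chrom, strand = model$strand,
                 exon_chain = tmp$exons,
                 mature = extract_transcript_sequence(tmp, genome),
                 annotation_equivalent = ann_equiv),
            class = "aberrant_transcript")
}

# complement of disjoint sorted removed intervals within [span)
interval_complement <- function(span, removed) {
  if (nrow(removed) == 0)
    return(matrix(span, 1, 2, dimnames = list(NULL, c("start", "end"))))
  starts <- c(span[1], removed[, 2])
  ends <- c(removed[, 1], span[2])
  keep <- starts < ends
  matrix(c(starts[keep], ends[keep]), ncol = 2,
         dimnames = list(NULL, c("start", "end")))
}

.CODON_TABLE <- {
  tab <- as.character(Biostrings::GENETIC_CODE)
  names(tab) <- names(Biostrings::GENETIC_CODE)
  tab
}

# translate codons; returns list(peptide, stop_idx) where stop_idx is the
# 0-based codon index of the first stop, NA if none; invalid (N) codons
# before the stop make the frame untranslatable (peptide NA)
translate_frame <- function(seq, from) {
  n <- nchar(seq)
  n_codons <- (n - from) %/% 3
  if (n_codons <= 0) return(list(peptide = "", stop_idx = NA_integer_))
  starts <- from + 3 * (seq_len(n_codons) - 1) + 1
  codons <- substring(seq, starts, starts + 2)
  aa <- unname(.CODON_TABLE[codons])
  stop_at <- which(aa == "*")
  invalid <- which(is.na(aa))
  first_stop <- if (length(stop_at)) stop_at[1] else NA_integer_
  if (length(invalid) && (is.na(first_stop) || invalid[1] < first_stop))
    return(list(peptide = NA_character_, stop_idx = NA_integer_))
  if (is.na(first_stop))
    return(list(peptide = paste(aa, collapse = ""),
                stop_idx = NA_integer_))
  list(peptide = paste(aa[seq_len(first_stop - 1)], collapse = ""),
       stop_idx = first_stop - 1L)
}

#' Enumerate open reading frames
#'
#' Every `ATG ... stop` pair in the three forward frames with no internal
#' stop yields one ORF (nested ATGs each produce their own). ORFs whose
#' peptide is shorter than `min_aa` are dropped; an `N` inside a codon
#' makes that ORF untranslatable and it is skipped.
#'
#' @param sequence nucleotide string (ACGTN)
#' @param min_aa minimum peptide length (default 7)
#' @return data.frame: `start`, `end` (0-based half-open transcript
#'   coordinates; `end - start` is a multiple of 3), `peptide`
#' @export
enumerate_orfs <- function(sequence, min_aa = 7) {
  stopifnot(min_aa >= 1)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains non-ACGTN characters")
  hits <- gregexpr("ATG", sequence, fixed = TRUE)[[1]]
  rows <- list()
  if (hits[1] != -1) {
    for (h in as.integer(hits)) {
      start0 <- h - 1L
      tr <- translate_frame(sequence, start0)
      if (is.na(tr$peptide) || is.na(tr$stop_idx)) next
      pep <- tr$peptide
      if (nchar(pep) < min_aa) next
      end0 <- start0 + 3L * (tr$stop_idx + 1L)
      rows[[length(rows) + 1]] <- data.frame(
        start = start0, end = end0, peptide = pep,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0),
               peptide = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict premature-termination-codon fate
#'
#' Maps the canonical start codon onto the aberrant transcript and
#' translates from there; the transcript carries a PTC when the first
#' in-frame stop ends more than `nmd_nt` nucleotides upstream of the
#' aberrant transcript's last exon-exon junction (strict inequality; the
#' 50-nt NMD boundary rule). `distance` is signed: last-junction position
#' minus stop end.
#'
#' @param aberrant an `aberrant_transcript`
#' @param model the canonical `transcript_model` it was built from (CDS
#'   required)
#' @param nmd_nt NMD boundary (default 50)
#' @return list with `ptc` (TRUE/FALSE/NA), `distance` (nt, signed, NA
#'   when undefined) and `reason` for NA calls
#' @export
predict_ptc <- function(aberrant, model, nmd_nt = 50) {
  if (is.na(model$cds_start))
    stop("canonical transcript has no CDS")
  start_g <- transcript_to_genomic(model, model$cds_start)
  tpos <- chain_genomic_to_transcript(aberrant, start_g)
  if (is.na(tpos))
    return(list(ptc = NA, distance = NA_real_,
                reason = "start codon removed by the event"))
  if (substring(aberrant$mature, tpos + 1, tpos + 3) != "ATG")
    return(list(ptc = NA, distance = NA_real_,
                reason = "start codon disrupted"))
  tr <- translate_frame(aberrant$mature, tpos)
  if (is.na(tr$stop_idx))
    return(list(ptc = NA, distance = NA_real_,
                reason = "no in-frame stop"))
  stop_end <- tpos + 3 * (tr$stop_idx + 1)
  jpos <- chain_junction_positions(aberrant)
  if (length(jpos) == 0)
    return(list(ptc = FALSE, distance = NA_real_,
                reason = "no exon-exon junction"))
  last_j <- max(jpos)
  dist <- last_j - stop_end
  list(ptc = dist > nmd_nt, distance = dist, reason = NA_character_)
}

# transcript-coordinate positions of the exon-exon junctions of an
# aberrant transcript (5'->3')
chain_junction_positions <- function(aberrant) {
  lens <- aberrant$exon_chain[, 2] - aberrant$exon_chain[, 1]
  if (length(lens) < 2) return(numeric(0))
  if (aberrant$strand == "-") lens <- rev(lens)
  cumsum(lens)[seq_len(length(lens) - 1)]
}

# genomic position -> aberrant-transcript coordinate (NA if spliced out)
chain_genomic_to_transcript <- function(aberrant, gpos) {
  m <- list(exons = aberrant$exon_chain, strand = aberrant$strand)
  genomic_to_transcript(m, gpos)
}

#' Fraction of aberrant transcripts with a PTC
#'
#' @param ptc_calls list of [predict_ptc()] results (or logical vector)
#' @return fraction of `TRUE` among defined (non-NA) calls
#' @export
ptc_fraction <- function(ptc_calls) {
  v <- if (is.list(ptc_calls))
    vapply(ptc_calls, function(x) as.logical(x$ptc), NA) else
      as.logical(ptc_calls)
  if (length(v) == 0) stop("empty input")
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no defined PTC calls")
  mean(v)
}

#' In-silico tryptic digest
#'
#' Cleaves after K or R except before P; returns all peptides with up to
#' `missed` missed cleavages whose length lies within `len_range`.
#'
#' @param peptide amino-acid string
#' @param missed maximum missed cleavages (default 2)
#' @param len_range inclusive length bounds (default `c(7, 40)`)
#' @return character vector of digest peptides (may contain duplicates)
#' @export
tryptic_digest <- function(peptide, missed = 2, len_range = c(7, 40)) {
  if (!nzchar(peptide)) return(character(0))
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1, n)] != "P"]
  bounds <- c(0, cut_after, n)
  segs <- substring(peptide, head(bounds, -1) + 1, bounds[-1])
  out <- character(0)
  for (m in 0:missed) {
    if (length(segs) < m + 1) break
    idx <- seq_len(length(segs) - m)
    for (i in idx) out <- c(out, paste(segs[i:(i + m)], collapse = ""))
  }
  out[nchar(out) >= len_range[1] & nchar(out) <= len_range[2]]
}

#' Build the custom peptide database
#'
#' Writes every ORF peptide of the aberrant transcripts to FASTA together
#' with the reference proteome (novel headers
#' `>NOVEL|<junction_id>|<orf_id>`), and computes the in-silico tryptic
#' digest of the novel ORFs; a digest peptide `is_novel` when it is
#' absent from the digest-peptide set of the reference proteome.
#'
#' @param aberrants named list of `aberrant_transcript` objects, each with
#'   an `orfs` element (from [enumerate_orfs()] on its mature sequence)
#' @param proteome named character vector or `AAStringSet` of reference
#'   protein sequences (non-empty)
#' @param missed,len_range digest parameters
#' @param fasta_path optional output FASTA path
#' @return list with `peptides` (data.frame `sequence`, `orf_id`,
#'   `junction_id`, `is_novel`) and `fasta` (named character vector of
#'   all database entries)
#' @export
build_peptide_database <- function(aberrants, proteome, missed = 2,
                                   len_range = c(7, 40),
                                   fasta_path = NULL) {
  if (inherits(proteome, "AAStringSet"))
    proteome <- setNames(as.character(proteome), names(proteome))
  if (length(proteome) == 0) stop("reference proteome is empty")
  ref_digest <- unique(unlist(lapply(proteome, tryptic_digest,
                                     missed = missed,
                                     len_range = len_range)))
  entries <- proteome
  rows <- list()
  n_orfs <- 0
  for (ab in aberrants) {
    orfs <- ab$orfs
    if (is.null(orfs) || nrow(orfs) == 0) next
    for (i in seq_len(nrow(orfs))) {
      n_orfs <- n_orfs + 1
      orf_id <- sprintf("orf%04d", n_orfs)
      header <- paste("NOVEL", ab$junction_id, orf_id, sep = "|")
      entries[header] <- orfs$peptide[i]
      digest <- unique(tryptic_digest(orfs$peptide[i], missed, len_range))
      if (length(digest) > 0)
        rows[[length(rows) + 1]] <- data.frame(
          sequence = digest, orf_id = orf_id,
          junction_id = ab$junction_id,
          is_novel = !(digest %in% ref_digest),
          stringsAsFactors = FALSE)
    }
  }
  if (n_orfs == 0)
    warning("no ORFs supplied; peptide database contains the reference ",
            "proteome only")
  peptides <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), orf_id = character(0),
               junction_id = character(0), is_novel = logical(0),
               stringsAsFactors = FALSE)
  rownames(peptides) <- NULL
  if (!is.null(fasta_path))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(entries), fasta_path, width = 70L)
  list(peptides = peptides, fasta = entries)
}

#' Pick the canonical transcript per gene
#'
#' The annotation's longest-CDS transcript of each gene (ties broken by
#' transcript id).
#'
#' @param annotation list of `transcript_model`
#' @return named list gene_id -> `transcript_model`
#' @export
canonical_transcripts <- function(annotation) {
  by_gene <- split(annotation,
                   vapply(annotation, function(m) m$gene_id, ""))
  lapply(by_gene, function(ms) {
    cds_len <- vapply(ms, function(m)
      if (is.na(m$cds_start)) -1L else m$cds_end - m$cds_start, 0L)
    ids <- vapply(ms, function(m) m$transcript_id, "")
    ms[[order(-cds_len, ids)[1]]]
  })
}
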