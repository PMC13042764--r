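# Fully synthetic toy study: genome, annotation, junction counts,
# single-nucleus expression, per-sample compositions and CLIP-like peaks,
# with a machine-readable truth table. The generator emulates the
# statistical structure the downstream analysis assumes: LSV-structured
# junction counts whose planted aberrant junctions are near-absent in
# controls (PSI << 0.05) and elevated in a carrier subset of patients,
# cell-type expression with planted strictly specific genes, disease-biased
# composition shifts, and peaks enriched near planted splice sites.

#' Cohort design
#'
#' Bundles every knob of the synthetic study. The defaults are the
#' package's reference study conditions: 2 tissues with 12 control / 12 ALS
#' / 12 FTD samples each, 200 multi-exon genes, 30 planted aberrant
#' junctions per disease (control PSI ~ Beta(0.5, 60), case shift
#' `delta_psi` in a `carrier_fraction` subset of patients), 15 normally
#' used up-regulated junctions per disease, 300 null alternative junctions,
#' and Poisson LSV coverage with mean 50.
#'
#' @param seed integer seed; must be supplied explicitly
#' @param n_genes number of genes
#' @param exons_per_gene integer range `c(min, max)` of exons per gene
#' @param exon_len,intron_len sampling ranges (nt) for coding exon and
#'   intron lengths
#' @param utr5_len,utr3_len fixed UTR lengths (nt); the 3'UTR must be long
#'   enough to host planted 3'UTR splice events
#' @param n_chrom chromosomes to pack genes onto
#' @param gene_gap intergenic spacer (nt)
#' @param tissues tissue labels
#' @param n_control,n_ALS,n_FTD samples per group per tissue
#' @param n_aberrant planted aberrant junctions per disease
#' @param event_mix named counts of planted event types per disease
#'   (`cryptic_ss`, `exon_skip`, `utr3`); must sum to `n_aberrant`. The
#'   `utr3` class leaves the CDS intact (PTC-negative); the others
#'   truncate it, so the planted PTC fraction is
#'   `1 - utr3 / n_aberrant`
#' @param delta_psi PSI shift added in carrier patients
#' @param carrier_fraction fraction of patients carrying each aberrant
#'   junction (heterogeneity; in (0, 1])
#' @param control_psi_shape Beta(shape1, shape2) for control PSI of
#'   aberrant junctions, concentrated below 0.02
#' @param n_normal_up planted normally-used up-regulated junctions per
#'   disease
#' @param normal_psi_range control PSI range (uniform) for normal_up
#'   junctions
#' @param normal_shift uniform case shift for normal_up junctions
#' @param n_null_alt planted null alternative junctions (no group effect)
#' @param null_psi_range PSI range for null alternative junctions
#' @param psi_jitter per-sample Gaussian jitter sd for normal/null PSI
#' @param coverage_mean Poisson mean LSV coverage
#' @param cell_types cell-type labels
#' @param biomarker_celltype named map disease -> cell type whose marker
#'   genes host that disease's biomarker junctions
#' @param biomarker_fraction fraction of each disease's aberrant junctions
#'   planted in marker genes of its cell type
#' @param extra_markers named count of additional planted strict markers
#'   per cell type (genes without splice events)
#' @param marker_mu,marker_pct_hi,marker_pct_lo marker expression level and
#'   detection rates in / outside the marker's cell type
#' @param bg_mu,bg_detect background expression level and detection rate
#' @param cells_per_sample nuclei per sample
#' @param composition_control control median cell-type proportions (named,
#'   sums to 1)
#' @param composition_shift named list disease -> named shift vector added
#'   to the control proportions (other types renormalised)
#' @param dirichlet_conc Dirichlet concentration for per-sample
#'   compositions
#' @param sn_tissue tissue whose samples contribute nuclei
#' @param rbp_p_near named vector RBP -> probability of a peak near each
#'   planted aberrant junction
#' @param background_peaks background peaks per RBP across the genome
#' @param peak_width peak width (nt)
#' @param flank_nt splice-site flank (nt) used when placing near-peaks
#' @return object of class `cohort_design`
#' @export
cohort_design <- function(seed,
                          n_genes = 200,
                          exons_per_gene = c(3, 5),
                          exon_len = c(120, 240),
                          intron_len = c(250, 400),
                          utr5_len = 30,
                          utr3_len = 200,
                          n_chrom = 4,
                          gene_gap = 500,
                          tissues = c("frontal_cortex", "temporal_cortex"),
                          n_control = 12, n_ALS = 12, n_FTD = 12,
                          n_aberrant = 30,
                          event_mix = c(cryptic_ss = 20, exon_skip = 4,
                                        utr3 = 6),
                          delta_psi = 0.25,
                          carrier_fraction = 0.6,
                          control_psi_shape = c(0.5, 60),
                          n_normal_up = 15,
                          normal_psi_range = c(0.1, 0.6),
                          normal_shift = 0.2,
                          n_null_alt = 300,
                          null_psi_range = c(0.05, 0.95),
                          psi_jitter = 0.03,
                          coverage_mean = 50,
                          cell_types = c("Neuron", "Oligodendrocyte",
                                         "Astrocyte", "Microglia"),
                          biomarker_celltype = c(ALS = "Oligodendrocyte",
                                                 FTD = "Neuron"),
                          biomarker_fraction = 0.8,
                          extra_markers = c(Neuron = 6,
                                            Oligodendrocyte = 6,
                                            Astrocyte = 5, Microglia = 5),
                          marker_mu = 3,
                          marker_pct_hi = 0.9,
                          marker_pct_lo = 0.02,
                          bg_mu = 1.2,
                          bg_detect = 0.3,
                          cells_per_sample = 200,
                          composition_control = c(Neuron = 0.4,
                                                  Oligodendrocyte = 0.3,
                                                  Astrocyte = 0.2,
                                                  Microglia = 0.1),
                          composition_shift = list(
                            ALS = c(Oligodendrocyte = -0.15),
                            FTD = c(Neuron = -0.10)),
                          dirichlet_conc = 100,
                          sn_tissue = NULL,
                          rbp_p_near = c(TARDBP = 0.9, CELF2 = 0.5,
                                         PTBP1 = 0.5, RBFOX1 = 0.1),
                          background_peaks = 50,
                          peak_width = 30,
                          flank_nt = 150) {
  if (missing(seed)) stop("seed must be supplied explicitly")
  d <- as.list(environment())
  d$sn_tissue <- sn_tissue %||% tissues[1]
  class(d) <- "cohort_design"
  validate_design(d)
  d
}

#' Validate a cohort design
#' @param design a `cohort_design`
#' @return `design`, invisibly; errors on any invalid setting
#' @export
validate_design <- function(design) {
  d <- design
  stopifnot(d$n_genes >= 0, d$n_chrom >= 1, d$coverage_mean > 0,
            d$cells_per_sample > 0)
  if (d$carrier_fraction <= 0 || d$carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  probs <- c(d$rbp_p_near, d$marker_pct_hi, d$marker_pct_lo, d$bg_detect,
             d$biomarker_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (d$marker_pct_lo >= d$marker_pct_hi)
    stop("marker_pct_lo must be < marker_pct_hi")
  if (sum(d$event_mix) != d$n_aberrant)
    stop("event_mix must sum to n_aberrant")
  qhi <- stats::qbeta(0.999, d$control_psi_shape[1], d$control_psi_shape[2])
  if (qhi + d$delta_psi > 1)
    stop("delta_psi pushes aberrant PSI outside [0, 1]")
  if (max(d$normal_psi_range) + d$normal_shift > 1)
    stop("normal_shift pushes normal_up PSI outside [0, 1]")
  if (abs(sum(d$composition_control) - 1) > 1e-9)
    stop("composition_control must sum to 1")
  for (dis in names(d$composition_shift)) {
    sh <- d$composition_shift[[dis]]
    if (any(d$composition_control[names(sh)] + sh <= 0))
      stop("composition_shift drives a proportion below 0")
  }
  if (d$utr3_len < 180)
    stop("utr3_len must be >= 180 to host planted 3'UTR events")
  invisible(design)
}

# deterministic sample metadata for the design
cohort_samples <- function(design) {
  rows <- list()
  for (tis in design$tissues) {
    for (grp in c("control", "ALS", "FTD")) {
      n <- switch(grp, control = design$n_control, ALS = design$n_ALS,
                  FTD = design$n_FTD)
      if (n == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        sample = sprintf("%s.%s.%02d", tis, grp, seq_len(n)),
        group = grp, tissue = tis,
        tdp_status = if (grp == "control") "none" else "TDP",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# sense codons (no stop) used to build clean reading frames
.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

random_cds <- function(n_codons) {
  paste(c("ATG", sample(.SENSE_CODONS, n_codons - 2, replace = TRUE),
          "TAA"), collapse = "")
}

#' Generate the toy genome and annotation
#'
#' Builds random-sequence chromosomes carrying multi-exon genes (one
#' canonical transcript per gene, each with a clean CDS), writes canonical
#' GT/AG dinucleotides at every annotated intron, and plants cryptic
#' splice sites (also GT/AG on the transcribed strand) for the designed
#' aberrant, normal-up and null alternative junctions. Fully deterministic
#' under `design$seed`.
#'
#' Planted event types: `cryptic_ss` retains the 5' part of an intron up to
#' a cryptic donor and carries an in-frame premature stop; `exon_skip`
#' joins the donor of intron i to the acceptor of intron i+1, skipping a
#' frame-shifting exon; `utr3` splices a short segment out of the 3'UTR
#' with its donor within 45 nt of the stop codon (CDS intact).
#'
#' @param design a [cohort_design()]
#' @return list with `genome` (named `DNAStringSet`), `annotation` (list of
#'   [transcript_model()]), `planted` (data.frame of planted junctions with
#'   class/disease/event annotations), `markers` (data.frame gene_id x
#'   cell_type of planted strict markers) and `design`
#' @export
generate_toy_genome <- function(design) {
  validate_design(design)
  d <- design
  set.seed(derive_seed(d$seed, 1))

  if (d$n_genes == 0) {
    return(list(genome = Biostrings::DNAStringSet(
                  setNames(random_dna(1000), "chr1")),
                annotation = list(),
                planted = empty_planted(), markers = data.frame(
                  gene_id = character(0), cell_type = character(0)),
                design = d))
  }

  gene_ids <- sprintf("g%03d", seq_len(d$n_genes))
  diseases <- names(d$biomarker_celltype)

  # --- role planning -------------------------------------------------
  need_event <- (d$n_aberrant + d$n_normal_up) * length(diseases)
  if (need_event > d$n_genes)
    stop("design requires more event genes (", need_event,
         ") than genes available (", d$n_genes, ")")
  pool <- sample(gene_ids)  # random order, deterministic under seed
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  events <- list()
  markers <- list()
  for (dis in diseases) {
    ab_genes <- take(d$n_aberrant)
    etype <- rep(names(d$event_mix), times = d$event_mix)
    n_bio <- round(d$biomarker_fraction * d$n_aberrant)
    is_bio <- seq_along(ab_genes) %in% sample(seq_along(ab_genes), n_bio)
    events[[length(events) + 1]] <- data.frame(
      gene_id = ab_genes, class = paste0("aberrant_up_", dis),
      disease = dis, event_type = etype, is_biomarker = is_bio,
      stringsAsFactors = FALSE)
    markers[[length(markers) + 1]] <- data.frame(
      gene_id = ab_genes[is_bio],
      cell_type = unname(d$biomarker_celltype[[dis]]),
      stringsAsFactors = FALSE)
    nu_genes <- take(d$n_normal_up)
    events[[length(events) + 1]] <- data.frame(
      gene_id = nu_genes, class = "normal_up", disease = dis,
      event_type = "alt_acceptor", is_biomarker = FALSE,
      stringsAsFactors = FALSE)
  }
  for (ct in names(d$extra_markers)) {
    n <- d$extra_markers[[ct]]
    if (n > length(pool))
      stop("not enough genes left for extra markers of ", ct)
    markers[[length(markers) + 1]] <- data.frame(
      gene_id = take(n), cell_type = ct, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, events)
  markers <- do.call(rbind, markers)

  # --- per-gene geometry and sequence -------------------------------
  chrom_of <- setNames(sprintf("chr%d", (seq_len(d$n_genes) - 1) %%
                                 d$n_chrom + 1), gene_ids)
  strand_of <- setNames(sample(c("+", "-"), d$n_genes, replace = TRUE),
                        gene_ids)
  cursor <- setNames(rep(0L, d$n_chrom), sprintf("chr%d", 1:d$n_chrom))
  chrom_parts <- setNames(vector("list", d$n_chrom), names(cursor))

  models <- list()
  planted <- list()
  null_candidates <- list()  # (gene, intron_idx) free for null_alt

  gene_events <- split(events, events$gene_id)

  for (gi in seq_along(gene_ids)) {
    gid <- gene_ids[gi]
    chrom <- unname(chrom_of[gid])
    strand <- unname(strand_of[gid])
    ev <- gene_events[[gid]]
    etype <- if (is.null(ev)) NA_character_ else ev$event_type[1]

    n_ex <- sample(seq(d$exons_per_gene[1], d$exons_per_gene[2]), 1)
    # a skipped exon needs a downstream annotated junction for the
    # frameshift-induced stop to precede, hence >= 4 exons
    if (identical(etype, "exon_skip")) n_ex <- max(n_ex, 4L)
    ex_len <- sample(seq(d$exon_len[1], d$exon_len[2]), n_ex,
                     replace = TRUE)
    in_len <- sample(seq(d$intron_len[1], d$intron_len[2]), n_ex - 1,
                     replace = TRUE)

    skip_idx <- NA_integer_
    if (identical(etype, "exon_skip")) {
      # skip an early internal exon so annotated junctions remain
      # downstream of the frameshift
      skip_idx <- if (n_ex == 4) 2L else sample(2:(n_ex - 2), 1)
      if (ex_len[skip_idx] %% 3 == 0) ex_len[skip_idx] <- ex_len[skip_idx] + 1L
    }

    utr3 <- d$utr3_len
    cds_len <- sum(ex_len) - d$utr5_len
    rem <- cds_len %% 3
    cds_len <- cds_len - rem
    utr3 <- utr3 + rem
    mature <- paste0(random_dna(d$utr5_len), random_cds(cds_len / 3),
                     random_dna(utr3))
    cds_start <- d$utr5_len
    cds_end <- cds_start + cds_len

    # exon boundaries in mature coordinates; last exon carries the 3'UTR
    ex_len_full <- ex_len
    ex_len_full[n_ex] <- ex_len_full[n_ex] + utr3
    mat_bounds <- cumsum(ex_len_full)           # exon ends, mature coords
    junc_pos <- mat_bounds[-n_ex]               # junction positions

    # plant 3'UTR event inside the mature sequence (exonic in genome)
    utr_plant <- NULL
    if (identical(etype, "utr3")) {
      g <- sample(10:45, 1)
      span_ab <- sample(90:120, 1)
      span_p <- sample(40:60, 1)
      donor_m <- cds_end + g
      mature <- plant_motif(mature, donor_m, "GT")
      mature <- plant_motif(mature, donor_m + span_ab - 2, "AG")
      mature <- plant_motif(mature, donor_m + span_p - 2, "AG")
      utr_plant <- list(donor_m = donor_m, span_ab = span_ab,
                        span_p = span_p)
    }

    # intron sequences with planted cryptic elements
    intron_seq <- character(max(n_ex - 1, 0))
    cryptic <- NULL
    cry_target <- if (identical(etype, "cryptic_ss"))
      sample(seq_len(n_ex - 1), 1) else NA_integer_
    for (i in seq_len(n_ex - 1)) {
      s <- paste0("GT", random_dna(in_len[i] - 4), "AG")
      if (identical(i, as.integer(cry_target))) {
        # retained length leaves the embedded stop > 50 nt upstream of
        # the cryptic junction even when this is the gene's last intron
        k <- sample(seq(80, 120, by = 1), 1)
        # in-frame stop inside the retained piece
        p <- junc_pos[i]
        o <- 21 + (3 - (p + 21 - cds_start) %% 3) %% 3
        s <- plant_motif(s, o, "TAA")
        s <- plant_motif(s, k, "GT")
        cryptic <- list(intron = i, k = k)
      }
      intron_seq[i] <- s
    }

    # assemble pre-mRNA and record exon/intron intervals (pre coords)
    mat_cuts0 <- c(0, mat_bounds)
    pre_pieces <- character(0)
    ex_pre <- matrix(0L, n_ex, 2)
    in_pre <- if (n_ex > 1) matrix(0L, n_ex - 1, 2) else
      matrix(integer(0), ncol = 2)
    pos <- 0L
    for (i in seq_len(n_ex)) {
      piece <- substring(mature, mat_cuts0[i] + 1, mat_cuts0[i + 1])
      ex_pre[i, ] <- c(pos, pos + nchar(piece))
      pre_pieces <- c(pre_pieces, piece)
      pos <- pos + nchar(piece)
      if (i < n_ex) {
        in_pre[i, ] <- c(pos, pos + nchar(intron_seq[i]))
        pre_pieces <- c(pre_pieces, intron_seq[i])
        pos <- pos + nchar(intron_seq[i])
      }
    }
    pre_seq <- paste(pre_pieces, collapse = "")
    P <- nchar(pre_seq)

    # place gene on chromosome
    gstart <- unname(cursor[chrom]) + d$gene_gap
    locus <- if (strand == "+") pre_seq else revcomp_chr(pre_seq)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]],
                              random_dna(d$gene_gap), locus)
    cursor[chrom] <- gstart + P

    pre2gen <- function(iv) {
      if (strand == "+") cbind(gstart + iv[, 1], gstart + iv[, 2])
      else cbind(gstart + P - iv[, 2], gstart + P - iv[, 1])
    }
    ex_gen <- pre2gen(ex_pre)
    models[[gid]] <- transcript_model(
      paste0(gid, ".t1"), gid, chrom, strand, ex_gen,
      cds_start = cds_start, cds_end = cds_end)

    add_planted <- function(pre_iv, class, disease, event_type,
                            is_biomarker, ref_pre_iv) {
      g <- pre2gen(matrix(pre_iv, ncol = 2))
      r <- pre2gen(matrix(ref_pre_iv, ncol = 2))
      planted[[length(planted) + 1]] <<- data.frame(
        junction_id = junction_id(chrom, g[1], g[2], strand),
        chrom = chrom, intron_start = g[1], intron_end = g[2],
        strand = strand, gene_id = gid, class = class, disease = disease,
        event_type = event_type, is_biomarker = is_biomarker,
        ref_junction_id = junction_id(chrom, r[1], r[2], strand),
        stringsAsFactors = FALSE)
    }

    used_introns <- integer(0)
    if (!is.null(ev)) {
      if (etype == "cryptic_ss") {
        i <- cryptic$intron
        used_introns <- i
        add_planted(c(in_pre[i, 1] + cryptic$k, in_pre[i, 2]),
                    ev$class, ev$disease, etype, ev$is_biomarker,
                    in_pre[i, ])
      } else if (etype == "exon_skip") {
        i <- skip_idx - 1L  # junction spans introns i and i+1
        used_introns <- c(i, i + 1L)
        add_planted(c(in_pre[i, 1], in_pre[i + 1, 2]),
                    ev$class, ev$disease, etype, ev$is_biomarker,
                    in_pre[i, ])
      } else if (etype == "utr3") {
        # mature 3'UTR position -> pre coords within the last exon
        m2p <- function(m) ex_pre[n_ex, 1] + (m - mat_cuts0[n_ex])
        dn <- m2p(utr_plant$donor_m)
        ab <- c(dn, dn + utr_plant$span_ab)
        pt <- c(dn, dn + utr_plant$span_p)
        g_pt <- pre2gen(matrix(pt, ncol = 2))
        partner_id <- junction_id(chrom, g_pt[1], g_pt[2], strand)
        add_planted(ab, ev$class, ev$disease, etype, ev$is_biomarker, pt)
        planted[[length(planted) + 1]] <- data.frame(
          junction_id = partner_id, chrom = chrom,
          intron_start = g_pt[1], intron_end = g_pt[2], strand = strand,
          gene_id = gid, class = "utr_partner", disease = NA_character_,
          event_type = "utr3_partner", is_biomarker = FALSE,
          ref_junction_id = NA_character_, stringsAsFactors = FALSE)
      } else if (etype == "alt_acceptor") {
        i <- sample(seq_len(n_ex - 1), 1)
        used_introns <- i
        m <- sample(seq(60, in_len[i] - 60), 1)
        # the intron string is already placed on the chromosome, so patch
        # the cryptic acceptor AG into the locus in place
        chrom_parts[[chrom]][[length(chrom_parts[[chrom]])]] <-
          patch_locus(locus, strand, in_pre[i, 1] + m - 2, "AG", P)
        add_planted(c(in_pre[i, 1], in_pre[i, 1] + m),
                    ev$class, ev$disease, etype, FALSE, in_pre[i, ])
      }
    }
    free <- setdiff(seq_len(max(n_ex - 1, 0)), used_introns)
    for (i in free)
      null_candidates[[length(null_candidates) + 1]] <-
        list(gid = gid, intron = i, in_pre = in_pre[i, ], in_len = in_len[i],
             chrom = chrom, strand = strand, gstart = gstart, P = P,
             part_idx = length(chrom_parts[[chrom]]))
  }

  # --- null alternative junctions -----------------------------------
  if (d$n_null_alt > length(null_candidates))
    stop("design requires ", d$n_null_alt,
         " null alternative junctions but only ",
         length(null_candidates), " free introns exist")
  picks <- sample(seq_along(null_candidates), d$n_null_alt)
  for (pk in picks) {
    nc <- null_candidates[[pk]]
    m <- sample(seq(60, nc$in_len - 60), 1)
    apos <- nc$in_pre[1] + m - 2  # pre coords of the AG
    old <- chrom_parts[[nc$chrom]][[nc$part_idx]]
    chrom_parts[[nc$chrom]][[nc$part_idx]] <-
      patch_locus(old, nc$strand, apos, "AG", nc$P)
    iv <- c(nc$in_pre[1], nc$in_pre[1] + m)
    g <- if (nc$strand == "+") nc$gstart + iv else
      c(nc$gstart + nc$P - iv[2], nc$gstart + nc$P - iv[1])
    r <- if (nc$strand == "+") nc$gstart + nc$in_pre else
      c(nc$gstart + nc$P - nc$in_pre[2], nc$gstart + nc$P - nc$in_pre[1])
    planted[[length(planted) + 1]] <- data.frame(
      junction_id = junction_id(nc$chrom, g[1], g[2], nc$strand),
      chrom = nc$chrom, intron_start = g[1], intron_end = g[2],
      strand = nc$strand, gene_id = nc$gid, class = "null",
      disease = NA_character_, event_type = "alt_acceptor",
      is_biomarker = FALSE,
      ref_junction_id = junction_id(nc$chrom, r[1], r[2], nc$strand),
      stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(vapply(
    chrom_parts, function(p) paste(unlist(p), collapse = ""), ""))
  # terminal spacer so no gene abuts a chromosome end
  genome <- Biostrings::DNAStringSet(setNames(
    paste0(as.character(genome), vapply(seq_along(genome),
                                        function(i) random_dna(d$gene_gap),
                                        "")),
    names(chrom_parts)))

  planted <- if (length(planted)) do.call(rbind, planted) else
    empty_planted()
  rownames(planted) <- NULL
  list(genome = genome, annotation = models, planted = planted,
       markers = markers, design = d)
}

empty_planted <- function() {
  data.frame(junction_id = character(0), chrom = character(0),
             intron_start = integer(0), intron_end = integer(0),
             strand = character(0), gene_id = character(0),
             class = character(0), disease = character(0),
             event_type = character(0), is_biomarker = logical(0),
             ref_junction_id = character(0), stringsAsFactors = FALSE)
}

# overwrite positions [at, at + nchar(motif)) (0-based) of a string
plant_motif <- function(s, at, motif) {
  paste0(substring(s, 1, at), motif,
         substring(s, at + nchar(motif) + 1, nchar(s)))
}

# patch a transcription-coordinate motif into the genomic locus string
# (which is the reverse complement of the pre-mRNA for minus-strand genes)
patch_locus <- function(locus, strand, pre_at, motif, P) {
  if (strand == "+") {
    plant_motif(locus, pre_at, motif)
  } else {
    plant_motif(locus, P - pre_at - nchar(motif), revcomp_chr(motif))
  }
}

#' Simulate junction counts for a cohort
#'
#' Draws per-sample junction read counts. Each planted junction is paired
#' with a reference junction into a two-junction LSV; per sample, LSV
#' coverage is Poisson(`coverage_mean`) and the planted junction's count
#' is binomial in its sample-specific PSI. Annotated introns not serving
#' as references are singleton LSVs with Poisson counts. Planted aberrant
#' junctions draw control PSI from the design's Beta and add `delta_psi`
#' in a carrier subset of that disease's patients; normal-up junctions
#' shift all patients uniformly; null alternative junctions have no group
#' effect.
#'
#' @param toy output of [generate_toy_genome()]
#' @param samples optional sample metadata data.frame (`sample`, `group`,
#'   `tissue`); defaults to the design's full cohort
#' @param seed optional seed override (defaults to the design seed)
#' @return list with `counts` (a `junction_count_matrix`) and `truth` (a
#'   data.frame: one row per junction with class, disease, event type,
#'   biomarker flag, true control/case PSI) plus `carriers` (data.frame
#'   junction_id x tissue x sample of planted carriers)
#' @export
simulate_junction_counts <- function(toy, samples = NULL, seed = NULL) {
  d <- toy$design
  set.seed(derive_seed(seed %||% d$seed, 2))
  meta <- samples %||% cohort_samples(d)
  ns <- nrow(meta)

  ann_j <- annotation_junctions(toy$annotation)
  planted <- toy$planted
  ref_ids <- planted$ref_junction_id[!is.na(planted$ref_junction_id)]
  all_j <- rbind(ann_j,
                 planted[, c("junction_id", "chrom", "intron_start",
                             "intron_end", "strand", "gene_id")])
  all_j <- all_j[!duplicated(all_j$junction_id), , drop = FALSE]
  counts <- matrix(0L, nrow(all_j), ns,
                   dimnames = list(all_j$junction_id, meta$sample))

  carriers <- list()
  truth_rows <- list()

  for (i in seq_len(nrow(planted))) {
    pj <- planted[i, ]
    if (pj$class == "utr_partner") next
    cov <- rpois(ns, d$coverage_mean)
    psi <- numeric(ns)
    carrier <- rep(FALSE, ns)
    if (startsWith(pj$class, "aberrant_up")) {
      # one baseline PSI per junction, Beta truncated below the aberrant
      # ceiling (0.02); per-sample variation comes from count sampling
      base <- stats::qbeta(
        runif(1) * stats::pbeta(0.02, d$control_psi_shape[1],
                                d$control_psi_shape[2]),
        d$control_psi_shape[1], d$control_psi_shape[2])
      psi <- rep(base, ns)
      for (tis in unique(meta$tissue)) {
        cases <- which(meta$tissue == tis & meta$group == pj$disease)
        if (length(cases) == 0) next
        k <- max(1L, round(d$carrier_fraction * length(cases)))
        chosen <- sample(cases, k)
        carrier[chosen] <- TRUE
      }
      psi[carrier] <- psi[carrier] + d$delta_psi
      true_control <- base
      true_case <- base + d$delta_psi
    } else if (pj$class == "normal_up") {
      base <- runif(1, d$normal_psi_range[1], d$normal_psi_range[2])
      psi <- clamp(base + rnorm(ns, 0, d$psi_jitter), 0.001, 0.98)
      cases <- meta$group == pj$disease
      psi[cases] <- clamp(psi[cases] + d$normal_shift, 0.001, 0.98)
      carrier[cases] <- TRUE
      true_control <- base
      true_case <- base + d$normal_shift
    } else {  # null
      base <- runif(1, d$null_psi_range[1], d$null_psi_range[2])
      psi <- clamp(base + rnorm(ns, 0, d$psi_jitter), 0.001, 0.98)
      true_control <- base
      true_case <- base
    }
    cj <- rbinom(ns, cov, psi)
    counts[pj$junction_id, ] <- counts[pj$junction_id, ] + cj
    counts[pj$ref_junction_id, ] <- counts[pj$ref_junction_id, ] +
      (cov - cj)
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      junction_id = pj$junction_id, gene_id = pj$gene_id,
      class = pj$class, disease = pj$disease, event_type = pj$event_type,
      is_biomarker = pj$is_biomarker, true_control_psi = true_control,
      true_case_psi = true_case, stringsAsFactors = FALSE)
    if (any(carrier))
      carriers[[length(carriers) + 1]] <- data.frame(
        junction_id = pj$junction_id, tissue = meta$tissue[carrier],
        sample = meta$sample[carrier], stringsAsFactors = FALSE)
  }

  # singleton annotated introns: Poisson coverage, PSI 1 by construction
  singleton <- setdiff(ann_j$junction_id, ref_ids)
  if (length(singleton) > 0) {
    counts[singleton, ] <- matrix(
      rpois(length(singleton) * ns, d$coverage_mean),
      length(singleton), ns)
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else NULL
  jcm <- junction_count_matrix(
    splice_junctions(all_j$chrom, all_j$intron_start, all_j$intron_end,
                     all_j$strand, all_j$gene_id),
    counts, meta)
  list(counts = jcm, truth = truth,
       carriers = if (length(carriers)) do.call(rbind, carriers) else NULL)
}

#' Junction table of all annotated introns
#' @param annotation list of `transcript_model`
#' @return junction data.frame (one row per distinct intron)
#' @export
annotation_junctions <- function(annotation) {
  rows <- lapply(annotation, function(m) {
    iv <- transcript_introns(m)
    if (nrow(iv) == 0) return(NULL)
    data.frame(chrom = m$chrom, intron_start = iv[, 1],
               intron_end = iv[, 2], strand = m$strand,
               gene_id = m$gene_id, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    return(splice_junctions(character(0), integer(0), integer(0),
                            character(0)))
  df <- df[!duplicated(junction_id(df$chrom, df$intron_start,
                                   df$intron_end, df$strand)), ,
           drop = FALSE]
  splice_junctions(df$chrom, df$intron_start, df$intron_end, df$strand,
                   df$gene_id)
}

#' Simulate null junction counts
#'
#' A reduced generator for type-I-error calibration: `n_junctions`
#' two-junction LSVs with per-junction PSI drawn uniformly and no group
#' effect, over `n_a + n_b` samples (groups `A` and `B`).
#'
#' @param n_junctions number of null junctions
#' @param n_a,n_b group sizes
#' @param coverage_mean Poisson LSV coverage
#' @param psi_range per-junction base PSI range
#' @param psi_jitter per-sample jitter sd
#' @param seed integer seed
#' @return a `junction_count_matrix` whose metadata `group` is `"A"`/`"B"`
#' @export
simulate_null_counts <- function(n_junctions, n_a, n_b,
                                 coverage_mean = 50,
                                 psi_range = c(0.05, 0.95),
                                 psi_jitter = 0.03, seed) {
  set.seed(seed)
  ns <- n_a + n_b
  meta <- data.frame(
    sample = sprintf("s%03d", seq_len(ns)),
    group = rep(c("A", "B"), c(n_a, n_b)),
    tissue = "t1", tdp_status = "none", stringsAsFactors = FALSE)
  step <- 2000L
  start <- seq_len(n_junctions) * step
  jdf <- rbind(
    splice_junctions("chrN", start, start + 500L, "+"),
    splice_junctions("chrN", start, start + 900L, "+"))
  counts <- matrix(0L, nrow(jdf), ns,
                   dimnames = list(jdf$junction_id, meta$sample))
  base <- runif(n_junctions, psi_range[1], psi_range[2])
  for (j in seq_len(n_junctions)) {
    cov <- rpois(ns, coverage_mean)
    psi <- clamp(base[j] + rnorm(ns, 0, psi_jitter), 0.001, 0.999)
    cj <- rbinom(ns, cov, psi)
    counts[j, ] <- cj
    counts[n_junctions + j, ] <- cov - cj
  }
  junction_count_matrix(jdf, counts, meta)
}

#' Simulate single-nucleus expression
#'
#' Generates a genes x cells count matrix with planted strictly
#' cell-type-specific markers, per-sample cell counts drawn from
#' composition vectors with the designed disease shift, and shared
#' background genes. Expression is a detection Bernoulli times a shifted
#' Poisson, so detection rates are controlled directly.
#'
#' @param toy output of [generate_toy_genome()]
#' @param seed optional seed override
#' @return list with `expr` (genes x cells integer matrix), `cells`
#'   (data.frame `cell_id`, `cell_type`, `sample`, `group`, `tissue`) and
#'   `compositions` (true per-sample composition vectors)
#' @export
simulate_cell_expression <- function(toy, seed = NULL) {
  d <- toy$design
  set.seed(derive_seed(seed %||% d$seed, 3))
  meta <- cohort_samples(d)
  meta <- meta[meta$tissue == d$sn_tissue, , drop = FALSE]
  if (nrow(meta) == 0) stop("no samples in sn_tissue ", d$sn_tissue)
  genes <- vapply(toy$annotation, function(m) m$gene_id, "")
  genes <- unname(genes)
  if (length(genes) == 0) stop("empty annotation: no genes to express")
  types <- d$cell_types
  marker_of <- setNames(toy$markers$cell_type, toy$markers$gene_id)

  comp_of_group <- function(grp) {
    p <- d$composition_control[types]
    sh <- d$composition_shift[[grp]]
    if (!is.null(sh)) {
      p[names(sh)] <- p[names(sh)] + sh
      others <- setdiff(types, names(sh))
      p[others] <- p[others] * (1 - sum(p[names(sh)])) / sum(p[others])
    }
    p / sum(p)
  }

  cells <- list()
  comps <- list()
  for (si in seq_len(nrow(meta))) {
    p <- comp_of_group(meta$group[si])
    a <- rgamma(length(types), shape = d$dirichlet_conc * p)
    comp <- a / sum(a)
    ncell <- as.vector(rmultinom(1, d$cells_per_sample, comp))
    cells[[si]] <- data.frame(
      cell_type = rep(types, ncell), sample = meta$sample[si],
      group = meta$group[si], tissue = meta$tissue[si],
      stringsAsFactors = FALSE)
    comps[[si]] <- data.frame(sample = meta$sample[si],
                              group = meta$group[si],
                              cell_type = types, proportion = comp,
                              stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
  cells <- cells[, c("cell_id", "cell_type", "sample", "group", "tissue")]

  nc <- nrow(cells)
  expr <- matrix(0L, length(genes), nc,
                 dimnames = list(genes, cells$cell_id))
  for (ct in types) {
    idx <- which(cells$cell_type == ct)
    if (length(idx) == 0) next
    for (g in seq_along(genes)) {
      mt <- marker_of[genes[g]]
      if (!is.na(mt)) {
        pct <- if (mt == ct) d$marker_pct_hi else d$marker_pct_lo
        mu <- d$marker_mu
      } else {
        pct <- d$bg_detect
        mu <- d$bg_mu
      }
      det <- runif(length(idx)) < pct
      v <- integer(length(idx))
      v[det] <- rpois(sum(det), mu) + 1L
      expr[g, idx] <- v
    }
  }
  list(expr = expr, cells = cells, compositions = do.call(rbind, comps))
}

#' Simulate RBP peak sets
#'
#' For each RBP, places a peak within the +/- `flank_nt` window of one
#' splice site of each target junction with probability `p_near`, plus
#' uniform background peaks across the genome.
#'
#' @param junctions junction data.frame (the target set, typically planted
#'   aberrant junctions)
#' @param chrom_lengths named integer vector of chromosome lengths
#' @param rbp_p_near named vector RBP -> per-junction near-peak probability
#' @param background_peaks background peaks per RBP
#' @param peak_width peak width (nt)
#' @param flank_nt splice-site window half-width (nt)
#' @param seed integer seed
#' @return named list of `rbp_peaks`
#' @export
simulate_peaks <- function(junctions, chrom_lengths, rbp_p_near,
                           background_peaks = 50, peak_width = 30,
                           flank_nt = 150, seed) {
  set.seed(seed)
  out <- list()
  for (rbp in names(rbp_p_near)) {
    p <- rbp_p_near[[rbp]]
    rows <- list()
    if (nrow(junctions) > 0 && p > 0) {
      hit <- runif(nrow(junctions)) < p
      for (j in which(hit)) {
        site <- if (runif(1) < 0.5) junctions$intron_start[j] else
          junctions$intron_end[j]
        lo <- max(0L, site - flank_nt)
        hi <- site + flank_nt - peak_width
        s <- if (hi <= lo) lo else sample(seq(lo, hi), 1)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = junctions$chrom[j], start = s, end = s + peak_width,
          stringsAsFactors = FALSE)
      }
    }
    if (background_peaks > 0) {
      chr <- sample(names(chrom_lengths), background_peaks, replace = TRUE)
      s <- vapply(chr, function(cc)
        sample(seq(0, max(1, chrom_lengths[[cc]] - peak_width)), 1), 0)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chr, start = as.integer(s),
        end = as.integer(s + peak_width), stringsAsFactors = FALSE)
    }
    peaks <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0),
                 end = integer(0))
    rownames(peaks) <- NULL
    out[[rbp]] <- rbp_peaks(rbp, peaks)
  }
  out
}

#' Simulate the full synthetic cohort
#'
#' Runs every generator under the design's seed: toy genome + annotation,
#' junction counts with truth table, single-nucleus expression with
#' compositions, and RBP peak sets.
#'
#' @param design a [cohort_design()]
#' @return object of class `splice_cohort`: list with `genome`,
#'   `annotation`, `counts`, `truth`, `carriers`, `expr`, `cells`,
#'   `compositions`, `peaks`, `markers`, `design`
#' @export
simulate_cohort <- function(design) {
  toy <- generate_toy_genome(design)
  jc <- simulate_junction_counts(toy)
  sc <- simulate_cell_expression(toy)
  ab <- toy$planted[startsWith(toy$planted$class, "aberrant_up"), ,
                    drop = FALSE]
  peaks <- simulate_peaks(
    ab, setNames(Biostrings::width(toy$genome), names(toy$genome)),
    design$rbp_p_near, design$background_peaks, design$peak_width,
    design$flank_nt, seed = derive_seed(design$seed, 4))
  structure(list(genome = toy$genome, annotation = toy$annotation,
                 planted = toy$planted, counts = jc$counts,
                 truth = jc$truth, carriers = jc$carriers,
                 expr = sc$expr, cells = sc$cells,
                 compositions = sc$compositions, peaks = peaks,
                 markers = toy$markers, design = design),
            class = "splice_cohort")
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Emits genome FASTA, GTF annotation, junction-count and metadata TSVs,
#' expression and cell-label TSVs, one BED per RBP, and the truth table.
#'
#' @param cohort a `splice_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(cohort$genome, file.path(dir, "genome.fa"))
  write_gene_annotation(cohort$annotation, file.path(dir, "annotation.gtf"))
  write_junction_counts(cohort$counts,
                        file.path(dir, "junction_counts.tsv"),
                        file.path(dir, "sample_metadata.tsv"))
  write.table(cbind(gene_id = rownames(cohort$expr),
                    as.data.frame(cohort$expr, check.names = FALSE)),
              file.path(dir, "expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$cells, file.path(dir, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  for (ps in cohort$peaks)
    write_peaks(ps, file.path(dir, "peaks", paste0(ps$rbp_name, ".bed")))
  write.table(cohort$truth, file.path(dir, "truth_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
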