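# Synthetic genome + annotation generator -----------------------------------
#
# Emulates the kind of data the pipeline analyses: an assembly with
# ambiguity (N) blocks, an automatic annotation of non-overlapping
# multi-exon gene models with configurable exon-count / length / GC
# structure, and an "official gene set" derived from it by curation-like
# perturbation operators plus a de novo fraction, with a provenance map
# and a ground-truth manifest for every step.

round3 <- function(x, minimum = 9L) {
  pmax(as.integer(minimum), as.integer(3L * round(x / 3)))
}

rlnorm_median <- function(n, median, dispersion) {
  stats::rlnorm(n, meanlog = log(median), sdlog = dispersion)
}

#' Synthetic genome configuration
#'
#' @param n_scaffolds number of scaffolds.
#' @param scaffold_length_bp length of each scaffold (bp).
#' @param gc_background target GC content of the background sequence (%).
#' @param n_run_rate expected fraction of each scaffold covered by
#'   ambiguity (N) runs.
#' @param n_run_length length of each N run (bp).
#' @param seed RNG seed for genome generation.
#' @return a `genome_config` list.
#' @export
genome_config <- function(n_scaffolds = 10L, scaffold_length_bp = 1800000L,
                          gc_background = 35, n_run_rate = 0.03,
                          n_run_length = 5000L, seed = 1L) {
  stopifnot(n_scaffolds >= 1L, scaffold_length_bp > 0L,
            gc_background > 0, gc_background < 100,
            n_run_rate >= 0, n_run_rate < 1, n_run_length > 0L)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 scaffold_length_bp = as.integer(scaffold_length_bp),
                 gc_background = gc_background,
                 n_run_rate = n_run_rate,
                 n_run_length = as.integer(n_run_length),
                 seed = as.integer(seed)),
            class = "genome_config")
}

#' Synthetic gene-model configuration
#'
#' Exon counts per transcript are drawn as `1 + NB(size, mu)` (a
#' right-skewed count distribution whose median is configurable through
#' `mu`); exon, intron and intergenic-spacing lengths are log-normal,
#' parameterised by median and dispersion (sdlog). Exon lengths are
#' rounded to multiples of 3 so coding lengths stay divisible by 3 under
#' all downstream perturbations. Exon GC is offset against the genomic
#' background; intron GC follows the background.
#'
#' @param n_genes number of gene models to place.
#' @param exon_count_mu,exon_count_size negative-binomial parameters of
#'   the exon-count distribution (defaults give a median exon count of 5).
#' @param exon_length_median,exon_length_dispersion log-normal exon length
#'   parameters (bp / sdlog).
#' @param intron_length_median,intron_length_dispersion log-normal intron
#'   length parameters.
#' @param intergenic_median,intergenic_dispersion log-normal intergenic
#'   spacing parameters.
#' @param exon_gc_offset exon GC offset over the genomic background (%
#'   points).
#' @param isoform_rate fraction of multi-exon genes receiving a second,
#'   shorter isoform (an internal exon dropped).
#' @param seed RNG seed for annotation generation.
#' @return a `gene_model_config` list.
#' @export
gene_model_config <- function(n_genes = 2000L, exon_count_mu = 5,
                              exon_count_size = 2,
                              exon_length_median = 250,
                              exon_length_dispersion = 0.6,
                              intron_length_median = 400,
                              intron_length_dispersion = 0.9,
                              intergenic_median = 1500,
                              intergenic_dispersion = 0.7,
                              exon_gc_offset = 10,
                              isoform_rate = 0.2,
                              seed = 2L) {
  stopifnot(n_genes >= 1L, exon_count_mu > 0, exon_count_size > 0,
            exon_length_median > 0, intron_length_median > 0,
            intergenic_median > 0, isoform_rate >= 0, isoform_rate <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 exon_count_mu = exon_count_mu,
                 exon_count_size = exon_count_size,
                 exon_length_median = exon_length_median,
                 exon_length_dispersion = exon_length_dispersion,
                 intron_length_median = intron_length_median,
                 intron_length_dispersion = intron_length_dispersion,
                 intergenic_median = intergenic_median,
                 intergenic_dispersion = intergenic_dispersion,
                 exon_gc_offset = exon_gc_offset,
                 isoform_rate = isoform_rate,
                 seed = as.integer(seed)),
            class = "gene_model_config")
}

#' Curation-perturbation configuration
#'
#' A configurable fraction of automatic models is perturbed by operators
#' emulating documented curation actions (boundary shifts at the 3' end,
#' adding/removing a terminal exon, merging adjacent models, splitting a
#' model at an intron), and a small de novo fraction of short,
#' receptor-like models without predecessors is inserted into intergenic
#' space.
#'
#' @param manual_fraction fraction of automatic models perturbed into
#'   MAN-SUB models (default 0.05).
#' @param denovo_fraction de novo models added, as a fraction of the
#'   automatic gene count (default 0.01).
#' @param operator_probs named probabilities of the five operators
#'   (`boundary_shift`, `exon_add`, `exon_remove`, `merge_adjacent`,
#'   `split_model`); must sum to 1.
#' @param shift_median,shift_dispersion log-normal magnitude of boundary
#'   shifts (bp; rounded to multiples of 3). A dispersion of 0 gives a
#'   fixed magnitude.
#' @param shift_extend_prob probability that a boundary shift extends (vs
#'   trims) the model.
#' @param exon_length_median,exon_length_dispersion,intron_length_median,intron_length_dispersion
#'   length distributions for added exons/introns.
#' @param denovo_exon_count_range inclusive range of exon counts of de
#'   novo models (default 1-3: short, receptor-like profile).
#' @param denovo_exon_length_median,denovo_exon_length_dispersion,denovo_intron_length_median,denovo_intron_length_dispersion
#'   length distributions of de novo models.
#' @param seed RNG seed for the perturbation step.
#' @return a `perturbation_config` list.
#' @export
perturbation_config <- function(manual_fraction = 0.05,
                                denovo_fraction = 0.01,
                                operator_probs = c(boundary_shift = 0.55,
                                                   exon_add = 0.15,
                                                   exon_remove = 0.15,
                                                   merge_adjacent = 0.075,
                                                   split_model = 0.075),
                                shift_median = 300,
                                shift_dispersion = 0.5,
                                shift_extend_prob = 0.5,
                                exon_length_median = 250,
                                exon_length_dispersion = 0.6,
                                intron_length_median = 400,
                                intron_length_dispersion = 0.9,
                                denovo_exon_count_range = c(1L, 3L),
                                denovo_exon_length_median = 150,
                                denovo_exon_length_dispersion = 0.4,
                                denovo_intron_length_median = 90,
                                denovo_intron_length_dispersion = 0.4,
                                seed = 3L) {
  ops <- c("boundary_shift", "exon_add", "exon_remove", "merge_adjacent",
           "split_model")
  stopifnot(manual_fraction >= 0, manual_fraction <= 1,
            denovo_fraction >= 0, denovo_fraction <= 1,
            all(ops %in% names(operator_probs)),
            abs(sum(operator_probs) - 1) < 1e-8,
            all(operator_probs >= 0),
            shift_median > 0, shift_extend_prob >= 0, shift_extend_prob <= 1)
  structure(list(manual_fraction = manual_fraction,
                 denovo_fraction = denovo_fraction,
                 operator_probs = operator_probs[ops],
                 shift_median = shift_median,
                 shift_dispersion = shift_dispersion,
                 shift_extend_prob = shift_extend_prob,
                 exon_length_median = exon_length_median,
                 exon_length_dispersion = exon_length_dispersion,
                 intron_length_median = intron_length_median,
                 intron_length_dispersion = intron_length_dispersion,
                 denovo_exon_count_range = as.integer(denovo_exon_count_range),
                 denovo_exon_length_median = denovo_exon_length_median,
                 denovo_exon_length_dispersion = denovo_exon_length_dispersion,
                 denovo_intron_length_median = denovo_intron_length_median,
                 denovo_intron_length_dispersion = denovo_intron_length_dispersion,
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

#' Generate a synthetic genome
#'
#' Background bases are drawn i.i.d. at the configured GC content;
#' ambiguity (N) runs are placed at non-overlapping random positions. The
#' realized GC of the unambiguous sequence is checked against the target
#' (within one percentage point) at generation time.
#'
#' @param config a [genome_config()].
#' @return a `synthetic_genome` list: `assembly` (a `genome_assembly`),
#'   `n_runs` (tibble of N-run intervals, 0-based half-open) and
#'   `manifest` (config echo plus realized composition).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "genome_config"))
  with_seed(config$seed, {
    gc <- config$gc_background / 100
    seq_ids <- sprintf("scf%02d", seq_len(config$n_scaffolds))
    L <- config$scaffold_length_bp
    seqs <- character(config$n_scaffolds)
    run_rows <- list()
    base_codes <- utf8ToInt("ACGTN")
    for (s in seq_len(config$n_scaffolds)) {
      bases <- base_codes[sample.int(4L, L, replace = TRUE,
                                     prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                              (1 - gc) / 2))]
      n_runs <- stats::rpois(1, config$n_run_rate * L / config$n_run_length)
      placed <- integer(0)
      len <- config$n_run_length
      if (n_runs > 0L && L > len) {
        for (k in seq_len(n_runs)) {
          for (try in seq_len(50L)) {
            st <- sample.int(L - len, 1L)
            if (!any(abs(st - placed) < len)) {
              placed <- c(placed, st)
              break
            }
          }
        }
        for (st in placed) bases[st:(st + len - 1L)] <- base_codes[5L]
        if (length(placed) > 0L) {
          run_rows[[length(run_rows) + 1L]] <- tibble::tibble(
            seq_id = seq_ids[s], start = sort(placed) - 1L,
            end = sort(placed) - 1L + len)
        }
      }
      seqs[s] <- intToUtf8(bases)
    }
    assembly <- genome_assembly(stats::setNames(seqs, seq_ids))
    if (abs(assembly$gc_unambiguous - config$gc_background) > 1) {
      stop_annodiff(sprintf(
        "realized GC %.2f%% deviates more than 1 point from target %.1f%%",
        assembly$gc_unambiguous, config$gc_background))
    }
    n_runs_tbl <- if (length(run_rows) > 0L) dplyr::bind_rows(run_rows) else
      tibble::tibble(seq_id = character(0), start = integer(0),
                     end = integer(0))
    structure(list(assembly = assembly, n_runs = n_runs_tbl,
                   manifest = list(config = unclass(config),
                                   realized_gc = assembly$gc_unambiguous,
                                   n_run_count = nrow(n_runs_tbl))),
              class = "synthetic_genome")
  })
}

# draw one gene structure: exon/intron lengths (exons multiples of 3)
draw_gene_structure <- function(config) {
  n_ex <- 1L + stats::rnbinom(1L, size = config$exon_count_size,
                              mu = config$exon_count_mu)
  ex_len <- round3(rlnorm_median(n_ex, config$exon_length_median,
                                 config$exon_length_dispersion))
  in_len <- if (n_ex > 1L) {
    pmax(30L, as.integer(round(rlnorm_median(
      n_ex - 1L, config$intron_length_median,
      config$intron_length_dispersion))))
  } else integer(0)
  list(exon_lengths = ex_len, intron_lengths = in_len,
       span = sum(ex_len) + sum(in_len))
}

# exon start/end offsets (relative to gene start) from a structure
structure_offsets <- function(st) {
  n <- length(st$exon_lengths)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + st$exon_lengths[i]
    if (i < n) pos <- pos + st$intron_lengths[i]
  }
  tibble::tibble(start = starts, end = starts + st$exon_lengths)
}

#' Generate a synthetic automatic annotation
#'
#' Places non-overlapping gene models with the configured structure on the
#' synthetic genome, avoiding ambiguity blocks, and rewrites exonic
#' sequence at the configured GC offset over the background. A fraction of
#' multi-exon genes receives a second, shorter isoform so that
#' longest-transcript selection is exercised. The manifest records the
#' true structural properties of every gene's primary (longest)
#' transcript.
#'
#' @param genome a `synthetic_genome` from [generate_genome()].
#' @param config a [gene_model_config()].
#' @return a `synthetic_annotation` list: `annotation` (a
#'   `gene_annotation`), `assembly` (the updated `genome_assembly`),
#'   `manifest` (per-gene truth tibble) and `config`.
#' @export
generate_auto_annotation <- function(genome, config) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(config, "gene_model_config"))
  assembly <- genome$assembly
  with_seed(config$seed, {
    # free segments per scaffold = complement of N runs
    segments <- list()
    for (sid in names(assembly$sequences)) {
      L <- assembly$seq_lengths[[sid]]
      runs <- genome$n_runs[genome$n_runs$seq_id == sid, ]
      runs <- runs[order(runs$start), ]
      bounds <- c(0L, rbind(runs$start, runs$end), L)
      starts <- bounds[seq(1L, length(bounds), by = 2L)]
      ends <- bounds[seq(2L, length(bounds), by = 2L)]
      keep <- ends > starts
      segments[[length(segments) + 1L]] <- tibble::tibble(
        seq_id = sid, start = starts[keep], end = ends[keep])
    }
    segments <- dplyr::bind_rows(segments)

    exon_rows <- list()
    manifest_rows <- list()
    seg_i <- 1L
    cursor <- segments$start[1L]
    gc_exon <- min(max(assembly$gc_unambiguous + config$exon_gc_offset,
                       1), 99) / 100
    exon_patch <- list()  # per-scaffold replacement intervals + sequences
    for (g in seq_len(config$n_genes)) {
      st <- draw_gene_structure(config)
      spacing <- max(100L, as.integer(round(rlnorm_median(
        1L, config$intergenic_median, config$intergenic_dispersion))))
      placed <- FALSE
      while (!placed) {
        if (seg_i > nrow(segments)) {
          stop_annodiff(sprintf(
            paste0("could not place gene %d of %d; increase scaffold ",
                   "length or count"), g, config$n_genes))
        }
        gene_start <- cursor + spacing
        if (gene_start + st$span <= segments$end[seg_i]) {
          placed <- TRUE
        } else {
          seg_i <- seg_i + 1L
          if (seg_i <= nrow(segments)) cursor <- segments$start[seg_i]
        }
      }
      sid <- segments$seq_id[seg_i]
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("AG%05d", g)
      tx_id <- paste0(gene_id, "-RA")
      off <- structure_offsets(st)
      exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = tx_id, seq_id = sid,
        strand = strand, start = gene_start + off$start,
        end = gene_start + off$end)
      # optional second, shorter isoform: drop one internal exon
      n_ex <- length(st$exon_lengths)
      has_iso <- n_ex >= 3L && stats::runif(1L) < config$isoform_rate
      if (has_iso) {
        drop_i <- sample(2:(n_ex - 1L), 1L)
        exon_rows[[length(exon_rows) + 1L]] <- tibble::tibble(
          gene_id = gene_id, transcript_id = paste0(gene_id, "-RB"),
          seq_id = sid, strand = strand,
          start = gene_start + off$start[-drop_i],
          end = gene_start + off$end[-drop_i])
      }
      manifest_rows[[length(manifest_rows) + 1L]] <- tibble::tibble(
        gene_id = gene_id, transcript_id = tx_id, seq_id = sid,
        strand = strand, gene_start = gene_start,
        gene_end = gene_start + st$span,
        unspliced_length = st$span,
        coding_length = sum(st$exon_lengths),
        intron_total_length = sum(st$intron_lengths),
        protein_length = sum(st$exon_lengths) %/% 3L,
        exon_count = n_ex, intron_count = n_ex - 1L,
        median_exon_length = stats::median(st$exon_lengths),
        median_intron_length = if (n_ex > 1L)
          stats::median(st$intron_lengths) else NA_real_,
        has_second_isoform = has_iso)
      cursor <- gene_start + st$span
    }
    exons <- dplyr::bind_rows(exon_rows)
    manifest <- dplyr::bind_rows(manifest_rows)

    # rewrite exonic sequence at offset GC (union of primary exons)
    seqs <- assembly$sequences
    for (sid in unique(exons$seq_id)) {
      ex <- exons[exons$seq_id == sid & endsWith(exons$transcript_id, "-RA"), ]
      ir <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
      widths <- IRanges::width(ir)
      codes <- utf8ToInt("ACGT")
      repl <- Biostrings::DNAStringSet(vapply(widths, function(w) {
        intToUtf8(codes[sample.int(4L, w, replace = TRUE,
                                   prob = c((1 - gc_exon) / 2, gc_exon / 2,
                                            gc_exon / 2, (1 - gc_exon) / 2))])
      }, character(1)))
      seqs[[sid]] <- Biostrings::replaceAt(seqs[[sid]], ir, repl)
    }
    assembly <- genome_assembly(seqs)
    structure(list(annotation = gene_annotation(exons, assembly),
                   assembly = assembly, manifest = manifest,
                   config = config),
              class = "synthetic_annotation")
  })
}
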