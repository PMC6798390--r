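# Curation-like perturbation of a synthetic automatic annotation ------------

#' Derive a synthetic official gene set by perturbing automatic models
#'
#' Applies curation-like operators to a configured fraction of the
#' automatic gene models (status `manual`, predecessors recorded; a merge
#' produces one OGS model with two predecessors, a split two OGS models
#' sharing one predecessor), inserts a de novo fraction of short models
#' into intergenic space (status `denovo`), and copies all untouched
#' models unchanged. The action manifest records every operator
#' application.
#'
#' @param auto a `synthetic_annotation` from [generate_auto_annotation()].
#' @param config a [perturbation_config()].
#' @return a `synthetic_ogs` list: `annotation` (the OGS
#'   `gene_annotation`), `provenance` (tibble of `manual`/`denovo` rows),
#'   `manifest` (action table) and `config`.
#' @export
perturb_to_ogs <- function(auto, config) {
  stopifnot(inherits(auto, "synthetic_annotation"),
            inherits(config, "perturbation_config"))
  assembly <- auto$assembly
  genes <- dplyr::arrange(auto$manifest, .data$seq_id, .data$gene_start)
  n <- nrow(genes)
  primary_exons <- auto$annotation$exons[
    auto$annotation$exons$transcript_id %in% genes$transcript_id, ]
  exons_by_gene <- split(primary_exons, primary_exons$gene_id)

  with_seed(config$seed, {
    n_manual <- round(config$manual_fraction * n)
    n_denovo <- round(config$denovo_fraction * n)
    chosen <- if (n_manual > 0L) sample(genes$gene_id, n_manual) else character(0)
    consumed <- character(0)
    curated_exons <- list()
    prov_rows <- list()
    action_rows <- list()
    ogs_counter <- 0L

    next_ogs_id <- function() {
      ogs_counter <<- ogs_counter + 1L
      sprintf("OGSM%05d", ogs_counter)
    }
    gene_row <- function(id) genes[genes$gene_id == id, ]

    draw_shift <- function() {
      round3(rlnorm_median(1L, config$shift_median, config$shift_dispersion),
             minimum = 3L)
    }

    apply_boundary_shift <- function(ex, L) {
      delta <- draw_shift()
      extend <- stats::runif(1L) < config$shift_extend_prob
      ex <- ex[order(ex$start), ]
      n_ex <- nrow(ex)
      # transcript 3' end: genomic right on '+', genomic left on '-'
      if (ex$strand[1L] == "+") {
        if (extend) {
          eff <- min(delta, L - ex$end[n_ex])
          ex$end[n_ex] <- ex$end[n_ex] + eff
        } else {
          eff <- min(delta, ex$end[n_ex] - ex$start[n_ex] - 9L)
          eff <- max(eff, 0L)
          ex$end[n_ex] <- ex$end[n_ex] - eff
        }
      } else {
        if (extend) {
          eff <- min(delta, ex$start[1L])
          ex$start[1L] <- ex$start[1L] - eff
        } else {
          eff <- min(delta, ex$end[1L] - ex$start[1L] - 9L)
          eff <- max(eff, 0L)
          ex$start[1L] <- ex$start[1L] + eff
        }
      }
      list(models = list(ex), delta = if (extend) eff else -eff)
    }

    apply_exon_add <- function(ex, L) {
      intron <- max(30L, as.integer(round(rlnorm_median(
        1L, config$intron_length_median, config$intron_length_dispersion))))
      exlen <- round3(rlnorm_median(1L, config$exon_length_median,
                                    config$exon_length_dispersion))
      ex <- ex[order(ex$start), ]
      n_ex <- nrow(ex)
      right_start <- ex$end[n_ex] + intron
      left_start <- ex$start[1L] - intron - exlen
      threeprime_right <- ex$strand[1L] == "+"
      new <- NULL
      sides <- if (threeprime_right) c("right", "left") else c("left", "right")
      for (side in sides) {
        if (side == "right" && right_start + exlen <= L) {
          new <- tibble::tibble(start = right_start, end = right_start + exlen)
          break
        }
        if (side == "left" && left_start >= 0L) {
          new <- tibble::tibble(start = left_start, end = left_start + exlen)
          break
        }
      }
      if (is.null(new)) return(NULL)
      out <- dplyr::bind_rows(ex, tibble::tibble(
        gene_id = ex$gene_id[1L], transcript_id = ex$transcript_id[1L],
        seq_id = ex$seq_id[1L], strand = ex$strand[1L],
        start = new$start, end = new$end))
      list(models = list(out), delta = NA_real_)
    }

    apply_exon_remove <- function(ex) {
      ex <- ex[order(ex$start), ]
      if (nrow(ex) < 2L) return(NULL)
      drop_i <- if (ex$strand[1L] == "+") nrow(ex) else 1L
      list(models = list(ex[-drop_i, ]), delta = NA_real_)
    }

    apply_split <- function(ex) {
      ex <- ex[order(ex$start), ]
      if (nrow(ex) < 2L) return(NULL)
      k <- sample.int(nrow(ex) - 1L, 1L)
      list(models = list(ex[seq_len(k), ], ex[-seq_len(k), ]),
           delta = NA_real_)
    }

    apply_merge <- function(g) {
      same <- genes[genes$seq_id == gene_row(g)$seq_id, ]
      pos <- which(same$gene_id == g)
      cand <- c(if (pos < nrow(same)) same$gene_id[pos + 1L],
                if (pos > 1L) same$gene_id[pos - 1L])
      cand <- setdiff(cand, used)
      if (length(cand) == 0L) return(NULL)
      nb <- cand[1L]
      ex1 <- exons_by_gene[[g]]
      ex2 <- exons_by_gene[[nb]]
      merged <- dplyr::bind_rows(ex1, ex2)
      merged$strand <- ex1$strand[1L]
      merged$gene_id <- ex1$gene_id[1L]
      merged$transcript_id <- ex1$transcript_id[1L]
      list(models = list(merged[order(merged$start), ]), delta = NA_real_,
           extra_pred = nb)
    }

    used <- chosen  # every AUTO model already claimed as a predecessor
    pool <- setdiff(genes$gene_id, chosen)
    for (g in chosen) {
      if (g %in% consumed) {
        # this gene was eaten by an earlier merge; curate another instead
        pool <- setdiff(pool, used)
        if (length(pool) == 0L) next
        g <- sample(pool, 1L)
        pool <- setdiff(pool, g)
        used <- c(used, g)
      }
      ex <- exons_by_gene[[g]]
      L <- assembly$seq_lengths[[ex$seq_id[1L]]]
      res <- NULL
      op <- NA_character_
      for (try in seq_len(10L)) {
        op <- sample(names(config$operator_probs), 1L,
                     prob = config$operator_probs)
        res <- switch(op,
          boundary_shift = apply_boundary_shift(ex, L),
          exon_add = apply_exon_add(ex, L),
          exon_remove = apply_exon_remove(ex),
          merge_adjacent = apply_merge(g),
          split_model = apply_split(ex))
        if (!is.null(res)) break
      }
      if (is.null(res)) {  # fall back to an always-feasible operator
        op <- "boundary_shift"
        res <- apply_boundary_shift(ex, L)
      }
      preds <- c(g, res$extra_pred)
      if (!is.null(res$extra_pred)) {
        consumed <- c(consumed, res$extra_pred)
        used <- c(used, res$extra_pred)
      }
      for (model in res$models) {
        oid <- next_ogs_id()
        model$gene_id <- oid
        model$transcript_id <- paste0(oid, "-RA")
        curated_exons[[length(curated_exons) + 1L]] <- model
        prov_rows[[length(prov_rows) + 1L]] <- tibble::tibble(
          ogs_gene_id = oid, auto_gene_id = paste(preds, collapse = ","),
          status = "manual")
        action_rows[[length(action_rows) + 1L]] <- tibble::tibble(
          ogs_gene_id = oid, operator = op,
          predecessors = paste(preds, collapse = ","),
          delta_bp = res$delta)
      }
    }

    # de novo models in intergenic gaps
    denovo_exons <- list()
    if (n_denovo > 0L) {
      gaps <- list()
      for (sid in unique(genes$seq_id)) {
        gr <- genes[genes$seq_id == sid, ]
        L <- assembly$seq_lengths[[sid]]
        starts <- c(0L, gr$gene_end + 2L)
        ends <- c(gr$gene_start - 2L, L)
        keep <- ends - starts >= 200L
        if (any(keep)) {
          gaps[[length(gaps) + 1L]] <- tibble::tibble(
            seq_id = sid, start = starts[keep], end = ends[keep])
        }
      }
      gaps <- dplyr::bind_rows(gaps)
      for (d in seq_len(n_denovo)) {
        rng <- config$denovo_exon_count_range
        n_ex <- sample(rng[1L]:rng[2L], 1L)
        ex_len <- round3(rlnorm_median(n_ex, config$denovo_exon_length_median,
                                       config$denovo_exon_length_dispersion))
        in_len <- if (n_ex > 1L) pmax(30L, as.integer(round(rlnorm_median(
          n_ex - 1L, config$denovo_intron_length_median,
          config$denovo_intron_length_dispersion)))) else integer(0)
        span <- sum(ex_len) + sum(in_len)
        fit <- which(gaps$end - gaps$start >= span)
        if (length(fit) == 0L) {
          stop_annodiff("no intergenic gap large enough for de novo model")
        }
        gi <- if (length(fit) == 1L) fit else sample(fit, 1L)
        slack <- gaps$end[gi] - gaps$start[gi] - span
        at <- gaps$start[gi] + (if (slack > 0L) sample.int(slack, 1L) else 0L)
        oid <- sprintf("OGSN%05d", d)
        off <- structure_offsets(list(exon_lengths = ex_len,
                                      intron_lengths = in_len))
        denovo_exons[[length(denovo_exons) + 1L]] <- tibble::tibble(
          gene_id = oid, transcript_id = paste0(oid, "-RA"),
          seq_id = gaps$seq_id[gi], strand = sample(c("+", "-"), 1L),
          start = at + off$start, end = at + off$end)
        prov_rows[[length(prov_rows) + 1L]] <- tibble::tibble(
          ogs_gene_id = oid, auto_gene_id = NA_character_, status = "denovo")
        action_rows[[length(action_rows) + 1L]] <- tibble::tibble(
          ogs_gene_id = oid, operator = "denovo_insert",
          predecessors = NA_character_, delta_bp = NA_real_)
        # shrink the used gap so later models cannot overlap this one
        old_end <- gaps$end[gi]
        gaps$end[gi] <- at - 2L
        gaps <- dplyr::bind_rows(gaps, tibble::tibble(
          seq_id = gaps$seq_id[gi], start = at + span + 2L, end = old_end))
        gaps <- gaps[gaps$end - gaps$start >= 200L, ]
      }
    }

    touched <- unique(c(used, consumed))
    unchanged_exons <- auto$annotation$exons[
      !(auto$annotation$exons$gene_id %in% touched), ]
    all_exons <- dplyr::bind_rows(c(list(unchanged_exons), curated_exons,
                                    denovo_exons))
    provenance <- if (length(prov_rows) > 0L) dplyr::bind_rows(prov_rows) else
      tibble::tibble(ogs_gene_id = character(0),
                     auto_gene_id = character(0), status = character(0))
    manifest <- if (length(action_rows) > 0L) dplyr::bind_rows(action_rows) else
      tibble::tibble(ogs_gene_id = character(0), operator = character(0),
                     predecessors = character(0), delta_bp = numeric(0))
    structure(list(annotation = gene_annotation(all_exons, assembly),
                   provenance = provenance, manifest = manifest,
                   config = config),
              class = "synthetic_ogs")
  })
}

#' Generate a complete synthetic data bundle
#'
#' Convenience wrapper chaining [generate_genome()],
#' [generate_auto_annotation()] and [perturb_to_ogs()] under one master
#' seed (sub-seeds for the three stages are derived from it), optionally
#' writing the FASTA, the two GFF3 files, the provenance TSV and a JSON
#' ground-truth manifest to a directory.
#'
#' @param seed master RNG seed.
#' @param out_dir optional output directory; created if missing.
#' @param genome_cfg,gene_cfg,perturb_cfg stage configurations (their
#'   `seed` fields are overridden by sub-seeds derived from `seed`).
#' @return a list with `genome`, `auto`, `ogs`, `assembly`, `provenance`
#'   and, when `out_dir` is given, `paths` (named file paths).
#' @export
simulate_bundle <- function(seed = 1L, out_dir = NULL,
                            genome_cfg = genome_config(),
                            gene_cfg = gene_model_config(),
                            perturb_cfg = perturbation_config()) {
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  genome_cfg$seed <- sub[1L]
  gene_cfg$seed <- sub[2L]
  perturb_cfg$seed <- sub[3L]
  genome <- generate_genome(genome_cfg)
  auto <- generate_auto_annotation(genome, gene_cfg)
  ogs <- perturb_to_ogs(auto, perturb_cfg)
  out <- list(genome = genome, auto = auto, ogs = ogs,
              assembly = auto$assembly, provenance = ogs$provenance)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genome = file.path(out_dir, "genome.fasta"),
               auto = file.path(out_dir, "auto.gff3"),
               ogs = file.path(out_dir, "ogs.gff3"),
               provenance = file.path(out_dir, "provenance.tsv"),
               manifest = file.path(out_dir, "manifest.json"))
    Biostrings::writeXStringSet(auto$assembly$sequences, paths[["genome"]])
    write_annotation_gff3(auto$annotation, paths[["auto"]])
    write_annotation_gff3(ogs$annotation, paths[["ogs"]])
    write_result_table(ogs$provenance, paths[["provenance"]])
    jsonlite::write_json(
      list(seed = seed,
           genome = genome$manifest,
           auto_genes = auto$manifest,
           ogs_actions = ogs$manifest),
      paths[["manifest"]], auto_unbox = TRUE, digits = NA, na = "null")
    out$paths <- paths
  }
  out
}
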