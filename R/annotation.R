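#' Construct a validated gene annotation
#'
#' The in-memory representation of an annotation is a set of three tables
#' (genes, transcripts, exons) with internal coordinates stored 0-based
#' half-open, so interval lengths are simply `end - start`. All reading and
#' writing of GFF3 converts to/from the standard's 1-based inclusive
#' coordinates.
#'
#' @param exons a data frame with columns `gene_id`, `transcript_id`,
#'   `seq_id`, `strand` (`"+"` or `"-"`), `start`, `end` (0-based
#'   half-open). One row per exon.
#' @param assembly optional `genome_assembly`; when supplied, exon
#'   coordinates are checked against sequence bounds.
#' @return a `gene_annotation` object: list of tibbles `genes`,
#'   `transcripts` and `exons` (exons sorted by transcript and start).
#' @export
gene_annotation <- function(exons, assembly = NULL) {
  required <- c("gene_id", "transcript_id", "seq_id", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L) {
    stop_annodiff("exon table lacks column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  exons <- tibble::as_tibble(exons)[required]
  if (nrow(exons) == 0L) stop_annodiff("annotation contains no exons")
  if (!all(exons$strand %in% c("+", "-"))) {
    stop_annodiff("exon strand must be '+' or '-'")
  }
  if (any(exons$start < 0 | exons$start >= exons$end)) {
    stop_annodiff("exon intervals must satisfy 0 <= start < end")
  }
  if (!is.null(assembly)) {
    unknown <- setdiff(unique(exons$seq_id), names(assembly$sequences))
    if (length(unknown) > 0L) {
      stop_annodiff("exon(s) on unknown sequence id(s): ",
                    paste(unknown, collapse = ", "))
    }
    over <- exons$end > assembly$seq_lengths[exons$seq_id]
    if (any(over)) {
      stop_annodiff("exon beyond sequence end for transcript(s): ",
                    paste(unique(exons$transcript_id[over]), collapse = ", "))
    }
  }
  exons <- dplyr::arrange(exons, .data$gene_id, .data$transcript_id,
                          .data$start)
  # one seq_id/strand per transcript; exons pairwise disjoint within it
  by_tx <- dplyr::group_by(exons, .data$transcript_id)
  chk <- dplyr::summarise(
    by_tx,
    gene_id = .data$gene_id[1L],
    seq_id = .data$seq_id[1L],
    strand = .data$strand[1L],
    one_seq = length(unique(.data$seq_id)) == 1L &&
      length(unique(.data$strand)) == 1L &&
      length(unique(.data$gene_id)) == 1L,
    disjoint = dplyr::n() == 1L ||
      all(.data$start[-1L] >= .data$end[-dplyr::n()]),
    .groups = "drop")
  if (!all(chk$one_seq)) {
    stop_annodiff("transcript(s) span several sequences/strands/genes: ",
                  paste(chk$transcript_id[!chk$one_seq], collapse = ", "))
  }
  if (!all(chk$disjoint)) {
    stop_annodiff("overlapping exons within transcript(s): ",
                  paste(chk$transcript_id[!chk$disjoint], collapse = ", "))
  }
  transcripts <- chk[c("transcript_id", "gene_id", "seq_id", "strand")]
  genes <- dplyr::distinct(transcripts[c("gene_id", "seq_id", "strand")],
                           .data$gene_id, .keep_all = TRUE)
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d gene(s), %d transcript(s), %d exon(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

#' Read a GFF3 annotation into gene models
#'
#' Parses a GFF3 file with the usual gene -> mRNA -> exon/CDS hierarchy
#' (linked through `ID`/`Parent` attributes) into a validated
#' [gene_annotation()]. Because untranslated regions are not modelled,
#' exons are taken to coincide with coding sequence: when a transcript has
#' both exon and CDS features and they agree, the exons are used; when they
#' disagree a warning is emitted and the CDS intervals are used (coding
#' structure is what is analysed); when only one of the two feature types
#' is present it is used directly.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @param assembly a `genome_assembly`; features on sequences absent from
#'   the assembly, or extending beyond a sequence end, are errors.
#' @return a `gene_annotation`.
#' @export
read_annotation_gff3 <- function(path, assembly) {
  if (!file.exists(path)) stop_annodiff("GFF3 file does not exist: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- gr$Parent  # CharacterList

  gene_idx <- which(type == "gene")
  mrna_idx <- which(type == "mRNA")
  if (length(gene_idx) == 0L) stop_annodiff("no gene features in ", path)
  gene_ids <- ids[gene_idx]
  if (anyNA(gene_ids)) stop_annodiff("gene feature without ID attribute")
  if (anyDuplicated(gene_ids)) {
    stop_annodiff("duplicate gene ID(s): ",
                  paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }

  mrna_ids <- ids[mrna_idx]
  if (anyNA(mrna_ids)) stop_annodiff("mRNA feature without ID attribute")
  if (anyDuplicated(mrna_ids)) {
    stop_annodiff("duplicate mRNA ID(s): ",
                  paste(unique(mrna_ids[duplicated(mrna_ids)]), collapse = ", "))
  }
  mrna_parent <- vapply(parents[mrna_idx], function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))
  orphan <- is.na(mrna_parent) | !(mrna_parent %in% gene_ids)
  if (any(orphan)) {
    stop_annodiff("mRNA feature(s) without a gene parent: ",
                  paste(mrna_ids[orphan], collapse = ", "))
  }
  tx2gene <- stats::setNames(mrna_parent, mrna_ids)

  collect_children <- function(idx) {
    if (length(idx) == 0L) {
      return(tibble::tibble(transcript_id = character(0), seq_id = character(0),
                            strand = character(0), start = integer(0),
                            end = integer(0)))
    }
    n_par <- lengths(parents[idx])
    if (any(n_par == 0L)) {
      stop_annodiff("exon/CDS feature without Parent attribute")
    }
    rep_idx <- rep(idx, n_par)
    tibble::tibble(
      transcript_id = unlist(parents[idx], use.names = FALSE),
      seq_id = as.character(GenomicRanges::seqnames(gr))[rep_idx],
      strand = as.character(GenomicRanges::strand(gr))[rep_idx],
      # GFF3 1-based inclusive -> internal 0-based half-open
      start = GenomicRanges::start(gr)[rep_idx] - 1L,
      end = GenomicRanges::end(gr)[rep_idx])
  }
  exon_tbl <- collect_children(which(type == "exon"))
  cds_tbl <- collect_children(which(type == "CDS"))
  bad_parent <- setdiff(unique(c(exon_tbl$transcript_id, cds_tbl$transcript_id)),
                        mrna_ids)
  if (length(bad_parent) > 0L) {
    stop_annodiff("exon/CDS Parent(s) not an mRNA: ",
                  paste(bad_parent, collapse = ", "))
  }

  ex_by <- split(seq_len(nrow(exon_tbl)), exon_tbl$transcript_id)
  cd_by <- split(seq_len(nrow(cds_tbl)), cds_tbl$transcript_id)
  empty_child <- exon_tbl[0L, ]
  pick <- function(tx) {
    ex <- if (is.null(ex_by[[tx]])) empty_child else exon_tbl[ex_by[[tx]], ]
    cd <- if (is.null(cd_by[[tx]])) empty_child else cds_tbl[cd_by[[tx]], ]
    if (nrow(ex) > 0L && nrow(cd) > 0L) {
      same <- nrow(ex) == nrow(cd) &&
        identical(sort(ex$start), sort(cd$start)) &&
        identical(sort(ex$end), sort(cd$end))
      if (!same) {
        warning("exon and CDS features differ for transcript '", tx,
                "'; using CDS", call. = FALSE)
        return(cd)
      }
      return(ex)
    }
    if (nrow(ex) > 0L) return(ex)
    if (nrow(cd) > 0L) return(cd)
    stop_annodiff("transcript without exon or CDS features: ", tx)
  }
  exons <- dplyr::bind_rows(lapply(mrna_ids, pick))
  exons$gene_id <- unname(tx2gene[exons$transcript_id])
  genes_without_tx <- setdiff(gene_ids, mrna_parent)
  if (length(genes_without_tx) > 0L) {
    stop_annodiff("gene(s) without any mRNA: ",
                  paste(genes_without_tx, collapse = ", "))
  }
  gene_annotation(exons, assembly)
}

#' Write a gene annotation to GFF3
#'
#' Emits the gene -> mRNA -> exon/CDS hierarchy in standard 1-based
#' inclusive coordinates. Exon and CDS rows are identical by construction.
#'
#' @param annotation a `gene_annotation`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  ex <- annotation$exons
  tx_span <- dplyr::summarise(dplyr::group_by(ex, .data$transcript_id),
                              gene_id = .data$gene_id[1L],
                              seq_id = .data$seq_id[1L],
                              strand = .data$strand[1L],
                              start = min(.data$start), end = max(.data$end),
                              .groups = "drop")
  gene_span <- dplyr::summarise(dplyr::group_by(tx_span, .data$gene_id),
                                seq_id = .data$seq_id[1L],
                                strand = .data$strand[1L],
                                start = min(.data$start), end = max(.data$end),
                                .groups = "drop")
  # CDS phase in transcription order (first codon starts at phase 0)
  phase_of <- function(start, end, strand) {
    o <- order(start, decreasing = strand[1L] == "-")
    w <- (end - start)[o]
    prior <- c(0L, cumsum(w)[-length(w)])
    ph <- (3L - prior %% 3L) %% 3L
    out <- integer(length(ph))
    out[o] <- ph
    out
  }
  ex <- dplyr::mutate(dplyr::group_by(ex, .data$transcript_id),
                      phase = phase_of(.data$start, .data$end, .data$strand))
  ex <- dplyr::ungroup(ex)
  line <- function(df, type, phase, attrs) {
    sprintf("%s\tannodiff\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            df$seq_id, type, df$start + 1L, df$end, df$strand, phase, attrs)
  }
  rows <- tibble::tibble(
    seq_id = c(gene_span$seq_id, tx_span$seq_id, ex$seq_id, ex$seq_id),
    # ordering keys: position of the owning gene, then feature level
    gene_start = c(gene_span$start,
                   gene_span$start[match(tx_span$gene_id, gene_span$gene_id)],
                   gene_span$start[match(ex$gene_id, gene_span$gene_id)],
                   gene_span$start[match(ex$gene_id, gene_span$gene_id)]),
    level = rep(1:4, c(nrow(gene_span), nrow(tx_span), nrow(ex), nrow(ex))),
    start = c(gene_span$start, tx_span$start, ex$start, ex$start),
    text = c(
      line(gene_span, "gene", ".", sprintf("ID=%s", gene_span$gene_id)),
      line(tx_span, "mRNA", ".",
           sprintf("ID=%s;Parent=%s", tx_span$transcript_id, tx_span$gene_id)),
      line(ex, "exon", ".", sprintf("Parent=%s", ex$transcript_id)),
      line(ex, "CDS", as.character(ex$phase),
           sprintf("Parent=%s", ex$transcript_id))))
  rows <- rows[order(rows$seq_id, rows$gene_start, rows$level, rows$start), ]
  writeLines(c("##gff-version 3", rows$text), path)
  invisible(path)
}

#' Read and validate a provenance map
#'
#' The provenance map records, for each gene model of the official gene set
#' (OGS), whether it was manually annotated from an automatic predecessor
#' (`manual`), added de novo by a curator (`denovo`), or carried over
#' unchanged from the automatic annotation (`auto`). It is a 3-column TSV
#' with header `ogs_gene_id`, `auto_gene_id`, `status`. A curated model
#' that replaced several merged predecessors lists them comma-separated in
#' `auto_gene_id`. OGS models absent from the file default to status
#' `auto`.
#'
#' @param path path to the TSV file.
#' @param auto_ids character vector (or `gene_annotation`) of automatic
#'   gene ids; referenced predecessors must be among them.
#' @param ogs_ids character vector (or `gene_annotation`) of OGS gene ids.
#' @return a tibble with columns `ogs_gene_id`, `auto_gene_id` (`NA` for de
#'   novo models; comma-separated for merges) and `status`, covering every
#'   OGS id.
#' @export
read_provenance_tsv <- function(path, auto_ids, ogs_ids) {
  if (!file.exists(path)) stop_annodiff("provenance file does not exist: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA")
  validate_provenance(df, auto_ids, ogs_ids)
}

#' @rdname read_provenance_tsv
#' @param provenance a data frame with the three provenance columns (rows
#'   for `manual`/`denovo` models at least).
#' @export
validate_provenance <- function(provenance, auto_ids, ogs_ids) {
  if (inherits(auto_ids, "gene_annotation")) auto_ids <- auto_ids$genes$gene_id
  if (inherits(ogs_ids, "gene_annotation")) ogs_ids <- ogs_ids$genes$gene_id
  required <- c("ogs_gene_id", "auto_gene_id", "status")
  if (!all(required %in% names(provenance))) {
    stop_annodiff("provenance table must have columns: ",
                  paste(required, collapse = ", "))
  }
  df <- tibble::as_tibble(provenance)[required]
  df$auto_gene_id[!is.na(df$auto_gene_id) & df$auto_gene_id == ""] <- NA_character_
  if (!all(df$status %in% c("manual", "denovo", "auto"))) {
    stop_annodiff("provenance status must be one of manual/denovo/auto")
  }
  if (anyDuplicated(df$ogs_gene_id)) {
    stop_annodiff("duplicate ogs_gene_id in provenance: ",
                  paste(unique(df$ogs_gene_id[duplicated(df$ogs_gene_id)]),
                        collapse = ", "))
  }
  unknown_ogs <- setdiff(df$ogs_gene_id, ogs_ids)
  if (length(unknown_ogs) > 0L) {
    stop_annodiff("provenance ogs_gene_id(s) not in OGS: ",
                  paste(unknown_ogs, collapse = ", "))
  }
  man <- df$status == "manual"
  if (any(is.na(df$auto_gene_id[man]))) {
    stop_annodiff("manual provenance row(s) lack auto_gene_id")
  }
  if (any(!is.na(df$auto_gene_id[df$status == "denovo"]))) {
    stop_annodiff("denovo provenance row(s) must have auto_gene_id = NA")
  }
  preds <- unlist(strsplit(df$auto_gene_id[man], ",", fixed = TRUE))
  unknown_auto <- setdiff(preds, auto_ids)
  if (length(unknown_auto) > 0L) {
    stop_annodiff("predecessor id(s) not in AUTO: ",
                  paste(unknown_auto, collapse = ", "))
  }
  # default all unlisted OGS models to unchanged-automatic
  rest <- setdiff(ogs_ids, df$ogs_gene_id)
  if (length(rest) > 0L) {
    df <- dplyr::bind_rows(df, tibble::tibble(
      ogs_gene_id = rest, auto_gene_id = NA_character_, status = "auto"))
  }
  df
}

#' Write a result table as TSV
#'
#' All tabular outputs are UTF-8 TSV files with a header line, `.` as the
#' decimal separator and the literal string `NA` for undefined values. An
#' empty record set yields a header-only file.
#'
#' @param records a data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_result_table <- function(records, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#'
#' @param path path to a TSV file.
#' @return a tibble.
#' @export
read_result_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      na.strings = "NA"))
}
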