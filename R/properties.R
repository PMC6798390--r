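#' Select the longest transcript of every gene
#'
#' Repertoire-wide property analyses consider a single transcript per gene:
#' the one with the greatest summed exon length (mature coding length), not
#' the greatest genomic span. Ties are broken deterministically by taking
#' the lexicographically smallest transcript id.
#'
#' @param annotation a `gene_annotation`.
#' @return a tibble with one row per gene: `gene_id`, `transcript_id`,
#'   `coding_length` (summed exon bp of the selected transcript).
#' @export
select_longest_transcripts <- function(annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  per_tx <- dplyr::summarise(
    dplyr::group_by(annotation$exons, .data$transcript_id),
    gene_id = .data$gene_id[1L],
    coding_length = sum(.data$end - .data$start),
    .groups = "drop")
  per_tx <- dplyr::arrange(per_tx, .data$gene_id,
                           dplyr::desc(.data$coding_length),
                           .data$transcript_id)
  chosen <- per_tx[!duplicated(per_tx$gene_id), ]
  chosen[c("gene_id", "transcript_id", "coding_length")]
}

#' Derive introns from a transcript's exons
#'
#' Introns are the gaps between consecutive exons of one transcript; a
#' single-exon transcript has none.
#'
#' @param exons data frame of one transcript's exons with columns `seq_id`,
#'   `strand`, `start`, `end` (0-based half-open, sorted, disjoint).
#' @return a tibble of intron intervals with the same columns (possibly
#'   zero rows).
#' @export
derive_introns <- function(exons) {
  exons <- exons[order(exons$start), ]
  n <- nrow(exons)
  if (n <= 1L) {
    return(tibble::tibble(seq_id = character(0), strand = character(0),
                          start = integer(0), end = integer(0)))
  }
  tibble::tibble(seq_id = exons$seq_id[-1L], strand = exons$strand[-1L],
                 start = exons$end[-n], end = exons$start[-1L])
}

#' Per-transcript structural properties
#'
#' Computes, for each selected transcript (by default the longest per gene,
#' see [select_longest_transcripts()]), the per-transcript structural
#' properties: unspliced transcript length (genomic span, bp), protein
#' length (aa, `floor(coding bp / 3)`, optionally minus one for the stop
#' codon), exon and intron counts, the per-transcript median exon and
#' intron lengths (bp), and the per-transcript median exon and intron GC
#' contents (%). Intron-based fields are undefined (`NA`) for single-exon
#' transcripts; GC fields are undefined when every exon (intron) consists
#' entirely of ambiguous bases.
#'
#' @param annotation a `gene_annotation`.
#' @param assembly the matching `genome_assembly`.
#' @param transcripts optional tibble with columns `gene_id`,
#'   `transcript_id` restricting which transcripts are measured; defaults
#'   to the longest transcript per gene.
#' @param subtract_stop_codon if `TRUE`, subtract 1 aa from every protein
#'   length (treat the last codon as the stop). Default `FALSE`.
#' @return a tibble with one row per transcript and columns `gene_id`,
#'   `transcript_id`, `unspliced_length`, `coding_length`,
#'   `intron_total_length`, `protein_length`, `exon_count`, `intron_count`,
#'   `median_exon_length`, `median_intron_length`, `median_exon_gc`,
#'   `median_intron_gc`.
#' @export
transcript_properties <- function(annotation, assembly, transcripts = NULL,
                                  subtract_stop_codon = FALSE) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(assembly, "genome_assembly"))
  if (is.null(transcripts)) transcripts <- select_longest_transcripts(annotation)
  keep <- annotation$exons$transcript_id %in% transcripts$transcript_id
  ex <- annotation$exons[keep, ]
  ex <- dplyr::arrange(ex, .data$transcript_id, .data$start)
  ex$gc <- feature_gc(assembly, ex$seq_id, ex$start, ex$end)

  # introns: gaps between consecutive exons within each transcript
  grp <- dplyr::group_by(ex, .data$transcript_id)
  introns <- dplyr::reframe(grp,
    seq_id = .data$seq_id[-1L],
    intron_start = .data$end[-dplyr::n()],
    intron_end = .data$start[-1L])
  if (nrow(introns) > 0L) {
    introns$gc <- feature_gc(assembly, introns$seq_id, introns$intron_start,
                             introns$intron_end)
  } else {
    introns$gc <- numeric(0)
  }

  per_ex <- dplyr::summarise(grp,
    gene_id = .data$gene_id[1L],
    unspliced_length = max(.data$end) - min(.data$start),
    coding_length = sum(.data$end - .data$start),
    exon_count = dplyr::n(),
    median_exon_length = stats::median(.data$end - .data$start),
    median_exon_gc = median_na(.data$gc),
    .groups = "drop")
  if (any(per_ex$coding_length == 0L)) {
    stop_annodiff("transcript(s) with zero summed exon length")
  }
  per_in <- dplyr::summarise(dplyr::group_by(introns, .data$transcript_id),
    intron_total_length = sum(.data$intron_end - .data$intron_start),
    median_intron_length = stats::median(.data$intron_end -
                                           .data$intron_start),
    median_intron_gc = median_na(.data$gc),
    .groups = "drop")
  out <- dplyr::left_join(per_ex, per_in, by = "transcript_id")
  out$intron_total_length[is.na(out$intron_total_length)] <- 0L
  out$intron_count <- out$exon_count - 1L
  out$protein_length <- out$coding_length %/% 3L -
    (if (subtract_stop_codon) 1L else 0L)
  out <- out[order(out$gene_id), ]
  tibble::as_tibble(out[c("gene_id", "transcript_id", "unspliced_length",
                          "coding_length", "intron_total_length",
                          "protein_length", "exon_count", "intron_count",
                          "median_exon_length", "median_intron_length",
                          "median_exon_gc", "median_intron_gc")])
}

# numeric property columns of a property table
PROPERTY_COLUMNS <- c("unspliced_length", "protein_length", "exon_count",
                      "median_exon_length", "median_intron_length",
                      "median_exon_gc", "median_intron_gc")

#' Set-wide medians of per-transcript properties
#'
#' Computes the set-wide median of each property over a property table
#' (for per-transcript medians such as median exon length this yields the
#' "median of medians"). An even number of records gives the mean of the
#' two central values, so half-values are possible. Undefined
#' per-transcript values (e.g. intron medians of single-exon transcripts)
#' are excluded from that property's median, and the exclusion count is
#' reported.
#'
#' @param props a property table from [transcript_properties()].
#' @param properties which columns to summarise (default: all standard
#'   property columns present).
#' @return a tibble with columns `property`, `median`, `n_used`, `n_na`.
#' @export
set_medians <- function(props, properties = NULL) {
  if (nrow(props) == 0L) stop_annodiff("empty property table")
  if (is.null(properties)) {
    properties <- intersect(PROPERTY_COLUMNS, names(props))
  }
  rows <- lapply(properties, function(p) {
    x <- props[[p]]
    tibble::tibble(property = p, median = median_na(x),
                   n_used = sum(!is.na(x)), n_na = sum(is.na(x)))
  })
  dplyr::bind_rows(rows)
}

#' Repertoire-wide summary metrics for a gene set
#'
#' Summarises a gene (sub)set against its assembly: gene count, total exon
#' count, coding proportion (summed exon lengths of all longest
#' transcripts relative to assembly size, %), intronic proportion
#' (likewise for introns), and the assembly GC content without ambiguity.
#' Gene spans are summed as-is, without merging overlapping models.
#'
#' @param props a property table from [transcript_properties()].
#' @param assembly the `genome_assembly` the properties were computed on.
#' @param set_label label of the set (e.g. `"AUTO"`).
#' @return a one-row tibble with columns `set_label`, `gene_count`,
#'   `total_exon_count`, `coding_proportion`, `intronic_proportion`,
#'   `assembly_gc_unambiguous`.
#' @export
summary_metrics <- function(props, assembly, set_label) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (assembly$assembly_size == 0) stop_annodiff("assembly size is zero")
  tibble::tibble(
    set_label = set_label,
    gene_count = nrow(props),
    total_exon_count = sum(props$exon_count),
    coding_proportion = 100 * sum(props$coding_length) / assembly$assembly_size,
    intronic_proportion = 100 * sum(props$intron_total_length) /
      assembly$assembly_size,
    assembly_gc_unambiguous = assembly$gc_unambiguous)
}
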