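#' Partition gene models into the five comparison (sub)sets
#'
#' From the automatic annotation (AUTO), the official gene set (OGS) and
#' the provenance map, builds the five (sub)sets compared throughout:
#' AUTO, OGS, MAN-SUB (curated models with an automatic predecessor),
#' AUTO-SUB (the distinct predecessors of MAN-SUB models), and MAN-ADD
#' (de novo models without predecessor). OGS models not covered by a
#' manual/denovo provenance row are the unchanged automatic remainder.
#' Split and merge curation actions give many-to-one / one-to-many
#' predecessor links; each predecessor is counted once in AUTO-SUB.
#'
#' @param auto_ids automatic gene ids (character vector or
#'   `gene_annotation`).
#' @param ogs_ids OGS gene ids (character vector or `gene_annotation`).
#' @param provenance a validated provenance table (see
#'   [read_provenance_tsv()]); models absent from it default to status
#'   `auto`.
#' @return a `gene_set_partition`: list with `auto_ids`, `ogs_ids`,
#'   `auto_sub_ids`, `man_sub_ids`, `man_add_ids`, `unchanged_ids` and
#'   `predecessor_map` (tibble `man_sub_id`, `auto_sub_id`, one row per
#'   link).
#' @export
build_partition <- function(auto_ids, ogs_ids, provenance) {
  if (inherits(auto_ids, "gene_annotation")) auto_ids <- auto_ids$genes$gene_id
  if (inherits(ogs_ids, "gene_annotation")) ogs_ids <- ogs_ids$genes$gene_id
  if (anyDuplicated(ogs_ids)) stop_annodiff("duplicate OGS gene id(s)")
  if (anyDuplicated(auto_ids)) stop_annodiff("duplicate AUTO gene id(s)")
  provenance <- validate_provenance(provenance, auto_ids, ogs_ids)

  man <- provenance[provenance$status == "manual", ]
  man_add_ids <- provenance$ogs_gene_id[provenance$status == "denovo"]
  pred_map <- if (nrow(man) > 0L) {
    links <- strsplit(man$auto_gene_id, ",", fixed = TRUE)
    tibble::tibble(man_sub_id = rep(man$ogs_gene_id, lengths(links)),
                   auto_sub_id = unlist(links, use.names = FALSE))
  } else {
    tibble::tibble(man_sub_id = character(0), auto_sub_id = character(0))
  }
  man_sub_ids <- unique(pred_map$man_sub_id)
  auto_sub_ids <- unique(pred_map$auto_sub_id)
  unchanged_ids <- setdiff(ogs_ids, c(man_sub_ids, man_add_ids))
  structure(
    list(auto_ids = auto_ids, ogs_ids = ogs_ids,
         auto_sub_ids = auto_sub_ids, man_sub_ids = man_sub_ids,
         man_add_ids = man_add_ids, unchanged_ids = unchanged_ids,
         predecessor_map = pred_map),
    class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf(paste0("<gene_set_partition> AUTO %d | OGS %d | AUTO-SUB %d | ",
                     "MAN-SUB %d | MAN-ADD %d | unchanged %d\n"),
              length(x$auto_ids), length(x$ogs_ids), length(x$auto_sub_ids),
              length(x$man_sub_ids), length(x$man_add_ids),
              length(x$unchanged_ids)))
  invisible(x)
}

#' Accounting percentages of a gene-set partition
#'
#' Computes the headline accounting of manual annotation effort: the five
#' set sizes and AUTO-SUB as a percentage of AUTO, MAN-SUB and MAN-ADD as
#' percentages of OGS, and MAN-ADD as a percentage of all curator-handled
#' models (MAN-SUB + MAN-ADD, the "de novo burden"). Reported values are
#' rounded to one decimal (half away from zero); unrounded values are kept
#' alongside.
#'
#' @param partition a `gene_set_partition`, or a named list/vector with
#'   counts `n_auto`, `n_ogs`, `n_auto_sub`, `n_man_sub`, `n_man_add`.
#' @return a tibble with columns `quantity`, `value` (unrounded) and
#'   `value_rounded`.
#' @export
partition_accounting <- function(partition) {
  if (inherits(partition, "gene_set_partition")) {
    n <- list(n_auto = length(partition$auto_ids),
              n_ogs = length(partition$ogs_ids),
              n_auto_sub = length(partition$auto_sub_ids),
              n_man_sub = length(partition$man_sub_ids),
              n_man_add = length(partition$man_add_ids))
  } else {
    n <- as.list(partition)
    need <- c("n_auto", "n_ogs", "n_auto_sub", "n_man_sub", "n_man_add")
    if (!all(need %in% names(n))) {
      stop_annodiff("counts must include: ", paste(need, collapse = ", "))
    }
  }
  if (n$n_ogs == 0) stop_annodiff("empty OGS")
  if (n$n_auto == 0) stop_annodiff("empty AUTO")
  handled <- n$n_man_sub + n$n_man_add
  vals <- c(
    n_auto = n$n_auto, n_ogs = n$n_ogs, n_auto_sub = n$n_auto_sub,
    n_man_sub = n$n_man_sub, n_man_add = n$n_man_add,
    auto_sub_pct_of_auto = 100 * n$n_auto_sub / n$n_auto,
    man_sub_pct_of_ogs = 100 * n$n_man_sub / n$n_ogs,
    man_add_pct_of_ogs = 100 * n$n_man_add / n$n_ogs,
    man_add_pct_of_handled = if (handled > 0) 100 * n$n_man_add / handled
                             else 0)
  tibble::tibble(quantity = names(vals), value = unname(vals),
                 value_rounded = round_half_away(unname(vals), 1))
}

#' Property tables of the five (sub)sets
#'
#' Splits the per-transcript property tables of the two annotations into
#' the five comparison sets. AUTO-SUB rows come from the automatic
#' annotation's table; OGS-based sets from the OGS table.
#'
#' @param partition a `gene_set_partition`.
#' @param auto_props property table of the automatic annotation.
#' @param ogs_props property table of the OGS annotation.
#' @return a named list of five tibbles: `AUTO`, `OGS`, `AUTO-SUB`,
#'   `MAN-SUB`, `MAN-ADD` (the latter possibly zero-row).
#' @export
subset_properties <- function(partition, auto_props, ogs_props) {
  stopifnot(inherits(partition, "gene_set_partition"))
  take <- function(props, ids, table_name) {
    missing_ids <- setdiff(ids, props$gene_id)
    if (length(missing_ids) > 0L) {
      stop_annodiff("gene id(s) in partition missing from ", table_name,
                    " property table: ", paste(missing_ids, collapse = ", "))
    }
    props[props$gene_id %in% ids, ]
  }
  list(
    "AUTO" = take(auto_props, partition$auto_ids, "AUTO"),
    "OGS" = take(ogs_props, partition$ogs_ids, "OGS"),
    "AUTO-SUB" = take(auto_props, partition$auto_sub_ids, "AUTO"),
    "MAN-SUB" = take(ogs_props, partition$man_sub_ids, "OGS"),
    "MAN-ADD" = take(ogs_props, partition$man_add_ids, "OGS"))
}
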