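#' Configuration of a full analysis run
#'
#' One invocation analyses one species: a genome, its automatic
#' annotation, its official gene set and the provenance map.
#'
#' @param genome path to the genome FASTA.
#' @param auto path to the automatic annotation GFF3.
#' @param ogs path to the official gene set GFF3.
#' @param provenance path to the provenance TSV.
#' @param out_dir output directory for the report tables (optional; no
#'   files are written when `NULL`).
#' @param seed master RNG seed; all randomness (the resampling procedure)
#'   derives from it.
#' @param n_replicates,n_subsample,interval_mode,percentile_bounds
#'   resampling parameters, see [resampling_config()].
#' @param alpha significance threshold for adjusted p-values.
#' @param test_method method passed to the distribution tests
#'   (`"auto"`, `"exact"` or `"asymptotic"`).
#' @return a `run_config` list.
#' @export
run_config <- function(genome, auto, ogs, provenance, out_dir = NULL,
                       seed = 1L, n_replicates = 1000L, n_subsample = 1000L,
                       interval_mode = "range",
                       percentile_bounds = c(2.5, 97.5), alpha = 0.05,
                       test_method = "auto") {
  for (p in c(genome, auto, ogs, provenance)) {
    if (!file.exists(p)) stop_annodiff("input file does not exist: ", p)
  }
  structure(list(genome = genome, auto = auto, ogs = ogs,
                 provenance = provenance, out_dir = out_dir,
                 seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 n_subsample = as.integer(n_subsample),
                 interval_mode = interval_mode,
                 percentile_bounds = percentile_bounds,
                 alpha = alpha, test_method = test_method),
            class = "run_config")
}

#' Run the full comparison pipeline
#'
#' Executes, in order: parsing of genome/annotations/provenance, the
#' five-set partition with its accounting, per-transcript properties of
#' the longest transcript of every gene, set-wide medians and summary
#' metrics per set, all pairwise KS/Wilcoxon comparisons (Bonferroni
#' corrected), Spearman correlations of the four property pairs, and the
#' subsampling representativeness assessment of AUTO-SUB against AUTO and
#' of MAN-SUB/MAN-ADD against OGS. Deterministic given `config$seed`.
#'
#' When `config$out_dir` is set, every table is also written as TSV
#' (`accounting.tsv`, `properties_<set>.tsv`, `set_medians.tsv`,
#' `summary_metrics.tsv`, `tests.tsv`, `correlations.tsv`,
#' `resampling.tsv`) together with `run_metadata.json`.
#'
#' @param config a [run_config()].
#' @return a `run_report`: list with `accounting`, `sets` (named list of
#'   property tables), `medians` (tibble `set_label`, `property`,
#'   `median`, `n_used`, `n_na`), `summaries`, `tests`, `correlations`,
#'   `resampling` and `metadata`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_annodiff(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  assembly <- stage("parse_genome", read_genome_fasta(config$genome))
  auto <- stage("parse_auto", read_annotation_gff3(config$auto, assembly))
  ogs <- stage("parse_ogs", read_annotation_gff3(config$ogs, assembly))
  provenance <- stage("parse_provenance",
                      read_provenance_tsv(config$provenance, auto, ogs))
  partition <- stage("partition", build_partition(auto, ogs, provenance))
  accounting <- stage("accounting", partition_accounting(partition))

  auto_props <- stage("properties_auto", transcript_properties(auto, assembly))
  ogs_props <- stage("properties_ogs", transcript_properties(ogs, assembly))
  sets <- stage("subset_properties",
                subset_properties(partition, auto_props, ogs_props))
  nonempty <- sets[vapply(sets, nrow, integer(1)) > 0L]

  medians <- stage("set_medians", dplyr::bind_rows(lapply(
    names(nonempty), function(lab) {
      cbind(tibble::tibble(set_label = lab), set_medians(nonempty[[lab]]))
    })))
  summaries <- stage("summary_metrics", dplyr::bind_rows(lapply(
    names(nonempty), function(lab) {
      summary_metrics(nonempty[[lab]], assembly, lab)
    })))
  tests <- stage("compare_all",
                 compare_all(nonempty, method = config$test_method,
                             alpha = config$alpha))
  correlations <- stage("correlate_all", correlate_all(nonempty))

  rs_seeds <- with_seed(config$seed,
                        sample.int(.Machine$integer.max - 1L, 2L))
  mk_rs_cfg <- function(seed) {
    resampling_config(n_replicates = config$n_replicates,
                      n_subsample = config$n_subsample, seed = seed,
                      interval_mode = config$interval_mode,
                      percentile_bounds = config$percentile_bounds)
  }
  resampling <- stage("resampling", dplyr::bind_rows(
    assess_representativeness(
      sets[["AUTO"]], "AUTO", sets["AUTO-SUB"], mk_rs_cfg(rs_seeds[1L])),
    assess_representativeness(
      sets[["OGS"]], "OGS",
      sets[intersect(c("MAN-SUB", "MAN-ADD"), names(nonempty))],
      mk_rs_cfg(rs_seeds[2L]))))

  report <- structure(
    list(accounting = accounting, sets = sets, medians = medians,
         summaries = summaries, tests = tests, correlations = correlations,
         resampling = resampling,
         metadata = list(seed = config$seed,
                         n_replicates = config$n_replicates,
                         n_subsample = config$n_subsample,
                         interval_mode = config$interval_mode,
                         alpha = config$alpha,
                         inputs = config[c("genome", "auto", "ogs",
                                           "provenance")],
                         package_version =
                           as.character(utils::packageVersion("annodiff")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name) {
      write_result_table(df, file.path(config$out_dir, name))
    }
    w(accounting, "accounting.tsv")
    for (lab in names(sets)) {
      w(sets[[lab]], sprintf("properties_%s.tsv",
                             gsub("-", "_", tolower(lab))))
    }
    w(medians, "set_medians.tsv")
    w(summaries, "summary_metrics.tsv")
    w(tests, "tests.tsv")
    w(correlations, "correlations.tsv")
    w(resampling, "resampling.tsv")
    jsonlite::write_json(report$metadata,
                         file.path(config$out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  sets:", paste(sprintf("%s (%d)", names(x$sets),
                               vapply(x$sets, nrow, integer(1))),
                       collapse = ", "), "\n")
  cat("  tests:", nrow(x$tests), "| correlations:", nrow(x$correlations),
      "| resampling rows:", nrow(x$resampling), "\n")
  invisible(x)
}

# coerce a report or a bare medians table to (set_label, property, median)
as_medians_table <- function(x) {
  if (inherits(x, "run_report")) x <- x$medians
  x <- tibble::as_tibble(x)
  need <- c("set_label", "property", "median")
  if (!all(need %in% names(x))) {
    stop_annodiff("medians table must have columns: ",
                  paste(need, collapse = ", "))
  }
  x[need]
}

#' Median differences between gene sets or between runs
#'
#' With one report (or medians table), computes the signed per-property
#' difference of set-wide medians between two of its sets, by default
#' MAN-SUB minus AUTO-SUB — the headline "effect of manual annotation" on
#' each property. With two reports, compares the same set across runs
#' (`report_a` minus `report_b`).
#'
#' @param report_a a `run_report` or a tibble with columns `set_label`,
#'   `property`, `median`.
#' @param report_b optional second report for cross-run comparison.
#' @param set_a,set_b set labels to difference (single-report mode).
#' @param properties optional property subset; properties missing on
#'   either side yield `NA` with a warning.
#' @return a tibble with columns `property`, `value_a`, `value_b`,
#'   `difference`.
#' @export
diff_reports <- function(report_a, report_b = NULL, set_a = "MAN-SUB",
                         set_b = "AUTO-SUB", properties = NULL) {
  ma <- as_medians_table(report_a)
  if (is.null(report_b)) {
    a <- ma[ma$set_label == set_a, ]
    b <- ma[ma$set_label == set_b, ]
  } else {
    mb <- as_medians_table(report_b)
    a <- ma[ma$set_label == set_a, ]
    b <- mb[mb$set_label == set_a, ]
  }
  if (is.null(properties)) properties <- union(a$property, b$property)
  va <- a$median[match(properties, a$property)]
  vb <- b$median[match(properties, b$property)]
  if (anyNA(va) | anyNA(vb)) {
    warning("property missing on one side; difference reported as NA",
            call. = FALSE)
  }
  tibble::tibble(property = properties, value_a = va, value_b = vb,
                 difference = va - vb)
}
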