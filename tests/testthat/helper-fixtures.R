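# Shared fixtures, built in code. Expensive synthetic bundles are memoised
# for reuse across test files within one run.

.fixtures <- new.env(parent = emptyenv())

# a small but complete synthetic bundle (genome + AUTO + OGS + provenance)
small_bundle <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- simulate_bundle(
      seed = 101L,
      genome_cfg = genome_config(n_scaffolds = 4L,
                                 scaffold_length_bp = 400000L,
                                 n_run_rate = 0.02),
      gene_cfg = gene_model_config(n_genes = 200L),
      perturb_cfg = perturbation_config())
  }
  .fixtures$small
}

# same bundle written to disk (for IO / orchestrator tests)
small_bundle_dir <- function() {
  if (is.null(.fixtures$small_dir)) {
    dir <- file.path(tempdir(), "annodiff-small-bundle")
    simulate_bundle(
      seed = 101L, out_dir = dir,
      genome_cfg = genome_config(n_scaffolds = 4L,
                                 scaffold_length_bp = 400000L,
                                 n_run_rate = 0.02),
      gene_cfg = gene_model_config(n_genes = 200L),
      perturb_cfg = perturbation_config())
    .fixtures$small_dir <- dir
  }
  .fixtures$small_dir
}

# tiny hand-built assembly from raw sequence strings
toy_assembly <- function(...) {
  genome_assembly(c(...))
}

# write a FASTA file from named sequences; returns the path
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

# write a GFF3 file from body lines (9 tab-separated columns each)
write_gff3_lines <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_row <- function(seqid, type, start, end, strand = "+", attrs = "",
                    phase = ".") {
  paste(seqid, "test", type, start, end, ".", strand, phase, attrs,
        sep = "\t")
}

# write a provenance TSV; rows is a data frame with the three columns
write_provenance <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}
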