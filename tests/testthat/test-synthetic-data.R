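test_that("generated genomes hit the configured GC and are deterministic", {
  cfg <- genome_config(n_scaffolds = 1, scaffold_length_bp = 100000L,
                       gc_background = 40, n_run_rate = 0, seed = 1)
  g <- generate_genome(cfg)
  expect_gte(g$assembly$gc_unambiguous, 39)
  expect_lte(g$assembly$gc_unambiguous, 41)
  # no ambiguity blocks: determined length equals assembly size
  expect_equal(g$assembly$determined_length, g$assembly$assembly_size)

  g2 <- generate_genome(cfg)
  expect_identical(as.character(g$assembly$sequences),
                   as.character(g2$assembly$sequences))

  withn <- generate_genome(genome_config(n_scaffolds = 2,
                                         scaffold_length_bp = 200000L,
                                         n_run_rate = 0.05, seed = 2))
  expect_gt(nrow(withn$n_runs), 0)
  expect_lt(withn$assembly$determined_length, withn$assembly$assembly_size)
})

test_that("a one-gene single-exon annotation yields one model triple", {
  g <- generate_genome(genome_config(n_scaffolds = 1,
                                     scaffold_length_bp = 50000L,
                                     n_run_rate = 0, seed = 3))
  cfg <- gene_model_config(n_genes = 1, exon_count_mu = 0.0001,
                           isoform_rate = 0, seed = 4)
  a <- generate_auto_annotation(g, cfg)
  expect_equal(nrow(a$annotation$genes), 1)
  expect_equal(nrow(a$annotation$transcripts), 1)
  expect_equal(nrow(a$annotation$exons), 1)
  expect_equal(a$manifest$exon_count, 1)
})

test_that("generator manifest agrees with pipeline-computed properties", {
  b <- small_bundle()
  pr <- transcript_properties(b$auto$annotation, b$assembly)
  m <- dplyr::arrange(b$auto$manifest, gene_id)
  pr <- dplyr::arrange(pr, gene_id)
  expect_equal(pr$transcript_id, m$transcript_id)  # longest = primary
  for (col in c("unspliced_length", "coding_length", "intron_total_length",
                "protein_length", "exon_count", "intron_count",
                "median_exon_length", "median_intron_length")) {
    expect_equal(pr[[col]], m[[col]], label = col, tolerance = 1e-12)
  }
})

test_that("zero perturbation fractions reproduce the automatic set", {
  g <- generate_genome(genome_config(n_scaffolds = 2,
                                     scaffold_length_bp = 300000L,
                                     n_run_rate = 0, seed = 5))
  a <- generate_auto_annotation(g, gene_model_config(n_genes = 60, seed = 6))
  o <- perturb_to_ogs(a, perturbation_config(manual_fraction = 0,
                                             denovo_fraction = 0, seed = 7))
  expect_equal(nrow(o$provenance), 0)
  expect_identical(as.data.frame(o$annotation$exons),
                   as.data.frame(a$annotation$exons))
})

test_that("perturbation fractions are recovered in the partition", {
  b <- small_bundle()  # manual_fraction 0.05, denovo_fraction 0.01, n = 200
  part <- build_partition(b$auto$annotation, b$ogs$annotation, b$provenance)
  acc <- partition_accounting(part)
  man_pct <- acc$value[acc$quantity == "man_sub_pct_of_ogs"]
  add_pct <- acc$value[acc$quantity == "man_add_pct_of_ogs"]
  expect_lt(abs(man_pct - 5), 1.5)   # small n: wider tolerance than at 2000
  expect_lt(abs(add_pct - 1), 1)
})

test_that("a fixed 3' extension shifts curated spans by exactly that amount", {
  g <- generate_genome(genome_config(n_scaffolds = 2,
                                     scaffold_length_bp = 400000L,
                                     n_run_rate = 0, seed = 8))
  a <- generate_auto_annotation(g, gene_model_config(n_genes = 80,
                                                     isoform_rate = 0,
                                                     seed = 9))
  cfg <- perturbation_config(
    manual_fraction = 0.5, denovo_fraction = 0,
    operator_probs = c(boundary_shift = 1, exon_add = 0, exon_remove = 0,
                       merge_adjacent = 0, split_model = 0),
    shift_median = 300, shift_dispersion = 0, shift_extend_prob = 1,
    seed = 10)
  o <- perturb_to_ogs(a, cfg)
  expect_true(all(o$manifest$operator == "boundary_shift"))
  expect_true(all(o$manifest$delta_bp == 300))

  part <- build_partition(a$annotation, o$annotation, o$provenance)
  ap <- transcript_properties(a$annotation, a$assembly)
  op <- transcript_properties(o$annotation, a$assembly)
  sets <- subset_properties(part, ap, op)
  # per-model construction: each curated span = predecessor span + 300
  pred <- part$predecessor_map
  span_auto <- ap$unspliced_length[match(pred$auto_sub_id, ap$gene_id)]
  span_ogs <- op$unspliced_length[match(pred$man_sub_id, op$gene_id)]
  expect_equal(span_ogs, span_auto + 300)
  # and the subset medians differ by exactly +300
  expect_equal(median(sets[["MAN-SUB"]]$unspliced_length) -
                 median(sets[["AUTO-SUB"]]$unspliced_length), 300)
})

test_that("length-decreasing operator mixes reverse the median shift", {
  g <- generate_genome(genome_config(n_scaffolds = 2,
                                     scaffold_length_bp = 400000L,
                                     n_run_rate = 0, seed = 12))
  a <- generate_auto_annotation(g, gene_model_config(n_genes = 80,
                                                     isoform_rate = 0,
                                                     seed = 13))
  trim <- perturbation_config(
    manual_fraction = 0.4, denovo_fraction = 0,
    operator_probs = c(boundary_shift = 1, exon_add = 0, exon_remove = 0,
                       merge_adjacent = 0, split_model = 0),
    shift_median = 120, shift_dispersion = 0.2, shift_extend_prob = 0,
    seed = 14)
  o <- perturb_to_ogs(a, trim)
  part <- build_partition(a$annotation, o$annotation, o$provenance)
  ap <- transcript_properties(a$annotation, a$assembly)
  op <- transcript_properties(o$annotation, a$assembly)
  sets <- subset_properties(part, ap, op)
  expect_lt(median(sets[["MAN-SUB"]]$unspliced_length),
            median(sets[["AUTO-SUB"]]$unspliced_length))
})

test_that("de novo models live in intergenic space with a distinct profile", {
  b <- small_bundle()
  denovo_ids <- b$provenance$ogs_gene_id[b$provenance$status == "denovo"]
  expect_gt(length(denovo_ids), 0)
  ogs_ex <- b$ogs$annotation$exons
  de_ex <- ogs_ex[ogs_ex$gene_id %in% denovo_ids, ]
  # short, few exons
  expect_lte(max(table(de_ex$gene_id)), 3)
  # no overlap with any automatic gene span
  m <- b$auto$manifest
  for (i in seq_len(nrow(de_ex))) {
    same <- m[m$seq_id == de_ex$seq_id[i], ]
    expect_false(any(de_ex$start[i] < same$gene_end &
                       de_ex$end[i] > same$gene_start))
  }
})

test_that("the whole bundle is byte-deterministic under a fixed seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  cfgs <- list(genome_cfg = genome_config(n_scaffolds = 2,
                                          scaffold_length_bp = 300000L),
               gene_cfg = gene_model_config(n_genes = 40))
  do.call(simulate_bundle, c(list(seed = 77L, out_dir = d1), cfgs))
  do.call(simulate_bundle, c(list(seed = 77L, out_dir = d2), cfgs))
  for (f in c("genome.fasta", "auto.gff3", "ogs.gff3", "provenance.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
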