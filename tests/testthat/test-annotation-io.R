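test_that("genome parsing computes size, determined length and GC", {
  p <- write_fasta(list(s1 = "ACGTN"))
  g <- read_genome_fasta(p)
  expect_equal(g$assembly_size, 5)
  expect_equal(g$determined_length, 4)
  expect_equal(g$gc_unambiguous, 50)

  p2 <- write_fasta(list(s1 = "AAAA", s2 = "GGGG"))
  g2 <- read_genome_fasta(p2)
  expect_equal(g2$assembly_size, 8)
  expect_equal(g2$gc_unambiguous, 50)

  # soft-masked lowercase treated as uppercase
  p3 <- write_fasta(list(s1 = "acgtn"))
  expect_equal(read_genome_fasta(p3)$determined_length, 4)
})

test_that("genome totals equal character-count oracle on a random file", {
  set.seed(7)
  n <- 10000
  chars <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                  prob = c(0.22, 0.22, 0.22, 0.22, 0.12))
  p <- write_fasta(list(chr1 = paste(chars, collapse = "")))
  g <- read_genome_fasta(p)
  o <- oracle_fasta_counts(p)
  expect_equal(g$assembly_size, o$total)
  expect_equal(g$determined_length, o$determined)
  expect_equal(g$gc_unambiguous, o$gc)
})

test_that("genome parsing rejects malformed input informatively", {
  expect_error(read_genome_fasta(write_fasta(list(a = "ACGT", a = "ACGT"))),
               "duplicate sequence id")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_genome_fasta(empty), "no sequences")
  err <- expect_error(read_genome_fasta(write_fasta(list(s1 = "ACXGT"))),
                      "non-nucleotide")
  expect_match(conditionMessage(err), "position 3")
  expect_match(conditionMessage(err), "s1")
})

test_that("GFF3 coordinates convert to 0-based half-open", {
  asm <- toy_assembly(chr = strrep("ACGT", 100))
  p <- write_gff3_lines(c(
    gff_row("chr", "gene", 1, 300, "+", "ID=g1"),
    gff_row("chr", "mRNA", 1, 300, "+", "ID=t1;Parent=g1"),
    gff_row("chr", "exon", 1, 100, "+", "Parent=t1"),
    gff_row("chr", "exon", 201, 300, "+", "Parent=t1")))
  ann <- read_annotation_gff3(p, asm)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(ann$exons$start, c(0, 200))
  expect_equal(ann$exons$end, c(100, 300))
})

test_that("CDS-only transcripts adopt CDS intervals as exons", {
  asm <- toy_assembly(chr = strrep("ACGT", 100))
  p <- write_gff3_lines(c(
    gff_row("chr", "gene", 1, 90, "+", "ID=g1"),
    gff_row("chr", "mRNA", 1, 90, "+", "ID=t1;Parent=g1"),
    gff_row("chr", "CDS", 1, 30, "+", "Parent=t1", phase = 0),
    gff_row("chr", "CDS", 61, 90, "+", "Parent=t1", phase = 0)))
  ann <- read_annotation_gff3(p, asm)
  expect_equal(nrow(ann$exons), 2)
  expect_equal(ann$exons$start, c(0, 60))
})

test_that("conflicting exon and CDS features fall back to CDS with warning", {
  asm <- toy_assembly(chr = strrep("ACGT", 100))
  p <- write_gff3_lines(c(
    gff_row("chr", "gene", 1, 90, "+", "ID=g1"),
    gff_row("chr", "mRNA", 1, 90, "+", "ID=t1;Parent=g1"),
    gff_row("chr", "exon", 1, 90, "+", "Parent=t1"),
    gff_row("chr", "CDS", 10, 90, "+", "Parent=t1", phase = 0)))
  expect_warning(ann <- read_annotation_gff3(p, asm), "using CDS")
  expect_equal(ann$exons$start, 9)
})

test_that("GFF3 structural errors are rejected", {
  asm <- toy_assembly(chr = strrep("ACGT", 25))  # 100 bp
  beyond <- write_gff3_lines(c(
    gff_row("chr", "gene", 1, 150, "+", "ID=g1"),
    gff_row("chr", "mRNA", 1, 150, "+", "ID=t1;Parent=g1"),
    gff_row("chr", "exon", 1, 150, "+", "Parent=t1")))
  expect_error(read_annotation_gff3(beyond, asm), "beyond sequence end")

  orphan <- write_gff3_lines(c(
    gff_row("chr", "gene", 1, 50, "+", "ID=g1"),
    gff_row("chr", "mRNA", 1, 50, "+", "ID=t1;Parent=g1"),
    gff_row("chr", "exon", 1, 50, "+", "Parent=t1"),
    gff_row("chr", "mRNA", 1, 50, "+", "ID=t9;Parent=gX"),
    gff_row("chr", "exon", 1, 50, "+", "Parent=t9")))
  expect_error(read_annotation_gff3(orphan, asm), "t9")

  overlap <- write_gff3_lines(c(
    gff_row("chr", "gene", 1, 90, "+", "ID=g1"),
    gff_row("chr", "mRNA", 1, 90, "+", "ID=t1;Parent=g1"),
    gff_row("chr", "exon", 1, 50, "+", "Parent=t1"),
    gff_row("chr", "exon", 40, 90, "+", "Parent=t1")))
  expect_error(read_annotation_gff3(overlap, asm), "[Oo]verlapping")

  unknown <- write_gff3_lines(c(
    gff_row("scaffoldX", "gene", 1, 50, "+", "ID=g1"),
    gff_row("scaffoldX", "mRNA", 1, 50, "+", "ID=t1;Parent=g1"),
    gff_row("scaffoldX", "exon", 1, 50, "+", "Parent=t1")))
  expect_error(read_annotation_gff3(unknown, asm), "unknown sequence")
})

test_that("synthetic GFF3 parses back to the generator's own models", {
  withr::local_seed(11)
  b <- small_bundle()
  dir <- small_bundle_dir()
  asm <- read_genome_fasta(file.path(dir, "genome.fasta"))
  ann <- read_annotation_gff3(file.path(dir, "auto.gff3"), asm)
  expect_equal(nrow(ann$genes), nrow(b$auto$manifest))
  expect_equal(nrow(ann$transcripts), nrow(b$auto$annotation$transcripts))
  # full round-trip: coordinates, strands and ids survive exactly
  a <- as.data.frame(dplyr::arrange(b$auto$annotation$exons,
                                    transcript_id, start))
  b2 <- as.data.frame(dplyr::arrange(ann$exons, transcript_id, start))
  expect_identical(a, b2)
})

test_that("exon length sums never exceed the unspliced span", {
  b <- small_bundle()
  ex <- b$auto$annotation$exons
  spans <- dplyr::summarise(dplyr::group_by(ex, transcript_id),
                            total = sum(end - start),
                            span = max(end) - min(start),
                            n = dplyr::n(), .groups = "drop")
  expect_true(all(spans$total <= spans$span))
  expect_true(all(spans$total[spans$n == 1L] == spans$span[spans$n == 1L]))
  expect_true(all(spans$total[spans$n > 1L] < spans$span[spans$n > 1L]))
})

test_that("provenance validation links, defaults and errors behave", {
  auto <- c("a1", "a2", "a3")
  ogs <- c("g1", "g2", "g3", "g4")
  p <- write_provenance(data.frame(
    ogs_gene_id = c("g1", "g2"),
    auto_gene_id = c("a1", NA),
    status = c("manual", "denovo")))
  prov <- read_provenance_tsv(p, auto, ogs)
  expect_equal(nrow(prov), 4)  # two listed + two defaulted
  expect_equal(prov$status[match(c("g3", "g4"), prov$ogs_gene_id)],
               c("auto", "auto"))
  expect_equal(prov$auto_gene_id[prov$ogs_gene_id == "g1"], "a1")

  expect_error(validate_provenance(data.frame(
    ogs_gene_id = "gX", auto_gene_id = "a1", status = "manual"),
    auto, ogs), "not in OGS")
  expect_error(validate_provenance(data.frame(
    ogs_gene_id = "g1", auto_gene_id = "zz", status = "manual"),
    auto, ogs), "not in AUTO")
  expect_error(validate_provenance(data.frame(
    ogs_gene_id = c("g1", "g1"), auto_gene_id = c("a1", "a2"),
    status = c("manual", "manual")), auto, ogs), "duplicate")
  expect_error(validate_provenance(data.frame(
    ogs_gene_id = "g1", auto_gene_id = NA_character_, status = "manual"),
    auto, ogs), "lack auto_gene_id")
})

test_that("result tables round-trip through TSV including NA cells", {
  df <- tibble::tibble(id = c("x", "y"), value = c(1.5, NA),
                       label = c("ok", "none"))
  p <- tempfile(fileext = ".tsv")
  write_result_table(df, p)
  back <- read_result_table(p)
  expect_equal(as.data.frame(back), as.data.frame(df))
  expect_true(any(grepl("\tNA", readLines(p))))  # literal NA cell

  empty <- df[0, ]
  p2 <- tempfile(fileext = ".tsv")
  write_result_table(empty, p2)
  expect_equal(length(readLines(p2)), 1)  # header only
  expect_equal(names(read_result_table(p2)), names(df))
})
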