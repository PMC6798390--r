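make_annotation <- function(exon_list, seq_len = 100000L) {
  # exon_list: named list transcript -> list(gene, strand, starts, ends)
  rows <- lapply(names(exon_list), function(tid) {
    e <- exon_list[[tid]]
    tibble::tibble(gene_id = e$gene, transcript_id = tid, seq_id = "chr",
                   strand = e$strand %||% "+", start = e$starts,
                   end = e$ends)
  })
  gene_annotation(dplyr::bind_rows(rows))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("longest-transcript selection maximises summed exon length", {
  ann <- make_annotation(list(
    t1 = list(gene = "g1", starts = c(0, 500), ends = c(100, 700)),
    t2 = list(gene = "g1", starts = 0, ends = 250),
    solo = list(gene = "g2", starts = 10, ends = 40)))
  sel <- select_longest_transcripts(ann)
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "t1")  # 300 > 250
  expect_equal(sel$transcript_id[sel$gene_id == "g2"], "solo")

  # tie-break: lexicographically smallest transcript id
  tie <- make_annotation(list(
    b = list(gene = "g", starts = 0, ends = 90),
    a = list(gene = "g", starts = 200, ends = 290)))
  expect_equal(select_longest_transcripts(tie)$transcript_id, "a")
})

test_that("longest-transcript selection agrees with brute force", {
  set.seed(3)
  for (g in 1:20) {
    n_tx <- sample(2:4, 1)
    exon_list <- list()
    for (t in seq_len(n_tx)) {
      n_ex <- sample(1:5, 1)
      lens <- sample(30:250, n_ex, replace = TRUE)
      gaps <- sample(50:300, n_ex, replace = TRUE)
      starts <- cumsum(gaps) + c(0, cumsum(lens[-n_ex]))
      exon_list[[sprintf("t%02d", t)]] <-
        list(gene = "g", starts = starts, ends = starts + lens)
    }
    ann <- make_annotation(exon_list)
    sel <- select_longest_transcripts(ann)
    sums <- vapply(names(exon_list), function(tid) {
      sum(exon_list[[tid]]$ends - exon_list[[tid]]$starts)
    }, numeric(1))
    best <- sort(names(sums)[sums == max(sums)])[1]
    expect_equal(sel$transcript_id, best)
  }
})

test_that("introns are the gaps between consecutive exons", {
  ex <- tibble::tibble(seq_id = "chr", strand = "+",
                       start = c(0, 200), end = c(100, 300))
  intr <- derive_introns(ex)
  expect_equal(nrow(intr), 1)
  expect_equal(intr$start, 100)
  expect_equal(intr$end, 200)

  single <- derive_introns(ex[1, ])
  expect_equal(nrow(single), 0)

  # conservation: gap lengths equal span minus exon sum, random layouts
  set.seed(99)
  for (i in 1:5) {
    n <- sample(2:8, 1)
    lens <- sample(10:200, n, replace = TRUE)
    gaps <- sample(10:300, n, replace = TRUE)
    starts <- cumsum(gaps) + c(0, cumsum(lens[-n]))
    ends <- starts + lens
    ex2 <- tibble::tibble(seq_id = "chr", strand = "+", start = starts,
                          end = ends)
    gaps <- derive_introns(ex2)
    expect_equal(sum(gaps$end - gaps$start),
                 (max(ends) - min(starts)) - sum(ends - starts))
  }
})

test_that("interval GC handles plain, ambiguous and reverse-complement", {
  asm <- toy_assembly(a = "ACGTNNNN", b = "ACGT")
  expect_equal(feature_gc(asm, "a", 0, 4), 50)
  expect_true(is.na(feature_gc(asm, "a", 4, 8)))   # all-N: undefined
  # reverse complement of ACGT is ACGT; GC is strand-insensitive
  rc <- toy_assembly(a = as.character(
    Biostrings::reverseComplement(Biostrings::DNAString("AAGCT"))))
  fwd <- toy_assembly(a = "AAGCT")
  expect_equal(feature_gc(fwd, "a", 0, 5), feature_gc(rc, "a", 0, 5))
  expect_error(feature_gc(asm, "b", 0, 10), "bounds")
  expect_error(feature_gc(asm, "zz", 0, 2), "unknown")
})

test_that("per-transcript properties match the worked example", {
  seqs <- strrep("ACGT", 200)  # 800 bp
  asm <- toy_assembly(chr = seqs)
  ann <- make_annotation(list(
    t1 = list(gene = "g1", starts = c(0, 400), ends = c(300, 700))))
  pr <- transcript_properties(ann, asm)
  expect_equal(pr$unspliced_length, 700)
  expect_equal(pr$exon_count, 2)
  expect_equal(pr$intron_count, 1)
  expect_equal(pr$median_exon_length, 300)
  expect_equal(pr$median_intron_length, 100)
  expect_equal(pr$protein_length, 200)  # 600 coding bp / 3

  # odd-count exon median
  ann3 <- make_annotation(list(
    t1 = list(gene = "g1", starts = c(0, 200, 500),
              ends = c(90, 320, 650))))
  expect_equal(transcript_properties(ann3, asm)$median_exon_length, 120)

  # single-exon transcripts carry undefined intron fields
  s <- make_annotation(list(t1 = list(gene = "g1", starts = 0, ends = 99)))
  ps <- transcript_properties(s, asm)
  expect_true(is.na(ps$median_intron_length))
  expect_true(is.na(ps$median_intron_gc))
  expect_equal(ps$intron_count, 0)
})

test_that("properties equal an independent naive recomputation", {
  b <- small_bundle()
  ann <- b$auto$annotation
  asm <- b$assembly
  pr <- transcript_properties(ann, asm)
  orc <- oracle_transcript_properties(ann, asm)
  pr <- dplyr::arrange(pr, gene_id)
  orc <- dplyr::arrange(orc, gene_id)
  expect_equal(pr$transcript_id, orc$transcript_id)
  for (col in setdiff(names(orc), c("gene_id", "transcript_id"))) {
    expect_equal(pr[[col]], orc[[col]], tolerance = 1e-12, label = col)
  }
  # conservation identity, exact on every transcript
  expect_equal(pr$coding_length + pr$intron_total_length,
               pr$unspliced_length)
})

test_that("set-wide medians follow the even/odd and NA-exclusion rules", {
  one <- tibble::tibble(unspliced_length = 500, protein_length = 100,
                        exon_count = 3, median_exon_length = 100,
                        median_intron_length = 50, median_exon_gc = 40,
                        median_intron_gc = 30)
  m <- set_medians(one)
  expect_equal(m$median[m$property == "unspliced_length"], 500)

  two <- dplyr::bind_rows(one, dplyr::mutate(one, unspliced_length = 504,
                                             median_intron_length = NA))
  m2 <- set_medians(two)
  expect_equal(m2$median[m2$property == "unspliced_length"], 502)  # half-value
  expect_equal(m2$median[m2$property == "median_intron_length"], 50)
  expect_equal(m2$n_na[m2$property == "median_intron_length"], 1)

  set.seed(41)
  many <- tibble::tibble(unspliced_length = sample(1:10000, 101))
  m3 <- set_medians(many, properties = "unspliced_length")
  expect_equal(m3$median, sort(many$unspliced_length)[51])

  expect_error(set_medians(one[0, ]), "empty")
})

test_that("summary metrics compute coding/intronic proportions", {
  asm <- toy_assembly(chr = strrep("A", 10000))
  props <- tibble::tibble(gene_id = "g1", exon_count = 2,
                          coding_length = 1000, intron_total_length = 500)
  s <- summary_metrics(props, asm, "AUTO")
  expect_equal(s$coding_proportion, 10)
  expect_equal(s$intronic_proportion, 5)
  expect_equal(s$gene_count, 1)
  expect_equal(s$total_exon_count, 2)

  intronfree <- dplyr::mutate(props, intron_total_length = 0)
  expect_equal(summary_metrics(intronfree, asm, "x")$intronic_proportion, 0)

  # synthetic annotation: proportions equal manifest sums / assembly size
  b <- small_bundle()
  pr <- transcript_properties(b$auto$annotation, b$assembly)
  sm <- summary_metrics(pr, b$assembly, "AUTO")
  expect_equal(sm$coding_proportion,
               100 * sum(b$auto$manifest$coding_length) /
                 b$assembly$assembly_size)
  expect_equal(sm$intronic_proportion,
               100 * sum(b$auto$manifest$intron_total_length) /
                 b$assembly$assembly_size)
})
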