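# Independent brute-force oracles. These deliberately use naive
# enumeration / straight-line arithmetic, not the package's algorithms.

# ECDF sup-difference of two samples, evaluated at all pooled values
oracle_ks_stat <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(v) mean(x <= v), numeric(1)) -
            vapply(pts, function(v) mean(y <= v), numeric(1))))
}

# exact permutation p-value of the KS statistic by full enumeration
# (ECDF differences evaluated via cumulative sums at tie-group ends)
oracle_ks_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  ord <- order(pooled)
  pos <- integer(N)
  pos[ord] <- seq_len(N)           # position of each element in sorted order
  sorted <- pooled[ord]
  group_end <- which(c(diff(sorted) != 0, TRUE))
  d_of <- function(idx) {
    s <- logical(N)
    s[pos[idx]] <- TRUE
    cumx <- cumsum(s)
    max(abs(cumx[group_end] / n1 -
              (group_end - cumx[group_end]) / n2))
  }
  d_obs <- d_of(seq_len(n1))
  splits <- utils::combn(N, n1)
  d_all <- apply(splits, 2, d_of)
  mean(d_all >= d_obs - 1e-12)
}

# exact two-sided permutation p-value of the rank-sum statistic
oracle_wilcox_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  e <- n1 * (length(pooled) + 1) / 2
  dev_obs <- abs(sum(r[seq_len(n1)]) - e)
  splits <- utils::combn(length(pooled), n1)
  dev_all <- abs(colSums(matrix(r[splits], nrow = n1)) - e)
  mean(dev_all >= dev_obs - 1e-12)
}

# classical tie-corrected Spearman coefficient: Pearson on average ranks,
# written out longhand
oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# character-count composition of a raw FASTA file (oracle for parse_genome)
oracle_fasta_counts <- function(path) {
  lines <- readLines(path)
  seq_chars <- toupper(unlist(strsplit(lines[!startsWith(lines, ">")], "")))
  tab <- table(seq_chars)
  cnt <- function(b) if (b %in% names(tab)) as.integer(tab[[b]]) else 0L
  acgt <- cnt("A") + cnt("C") + cnt("G") + cnt("T")
  list(total = length(seq_chars), determined = acgt,
       gc = 100 * (cnt("G") + cnt("C")) / acgt)
}

# straight-line per-transcript property recomputation from raw intervals
# and raw sequence strings (substring + character counting, no Biostrings)
oracle_transcript_properties <- function(annotation, assembly) {
  seq_strings <- as.character(assembly$sequences)
  gc_of <- function(sid, start, end) {
    chars <- strsplit(substr(seq_strings[[sid]], start + 1, end), "")[[1]]
    det <- sum(chars %in% c("A", "C", "G", "T"))
    if (det == 0) return(NA_real_)
    100 * sum(chars %in% c("G", "C")) / det
  }
  rows <- list()
  for (gid in sort(unique(annotation$exons$gene_id))) {
    gex <- annotation$exons[annotation$exons$gene_id == gid, ]
    # longest transcript: maximal summed exon length, ties -> smallest id
    tx_ids <- sort(unique(gex$transcript_id))
    sums <- vapply(tx_ids, function(tid) {
      e <- gex[gex$transcript_id == tid, ]
      sum(e$end - e$start)
    }, numeric(1))
    tid <- tx_ids[which(sums == max(sums))][1]
    e <- gex[gex$transcript_id == tid, ]
    e <- e[order(e$start), ]
    n <- nrow(e)
    exon_len <- e$end - e$start
    exon_gc <- vapply(seq_len(n), function(i) {
      gc_of(e$seq_id[i], e$start[i], e$end[i])
    }, numeric(1))
    if (n > 1) {
      istart <- e$end[-n]
      iend <- e$start[-1]
      intron_len <- iend - istart
      intron_gc <- vapply(seq_len(n - 1), function(i) {
        gc_of(e$seq_id[i + 1], istart[i], iend[i])
      }, numeric(1))
    } else {
      intron_len <- numeric(0)
      intron_gc <- numeric(0)
    }
    med <- function(v) if (length(v) == 0) NA_real_ else {
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else stats::median(v)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = gid, transcript_id = tid,
      unspliced_length = max(e$end) - min(e$start),
      coding_length = sum(exon_len),
      intron_total_length = sum(intron_len),
      protein_length = floor(sum(exon_len) / 3),
      exon_count = n, intron_count = n - 1,
      median_exon_length = stats::median(exon_len),
      median_intron_length = if (n > 1) stats::median(intron_len) else NA_real_,
      median_exon_gc = med(exon_gc),
      median_intron_gc = med(intron_gc))
  }
  dplyr::bind_rows(rows)
}
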