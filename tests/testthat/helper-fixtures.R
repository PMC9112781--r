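# Fixture builders and independent reference implementations used across the
# suite. Everything is generated in code; no binary fixtures.

# ---- tiny VCF writer ------------------------------------------------------
write_test_vcf <- function(path, chrom, pos, ref, alt, gt,
                           contig_len = 1e6) {
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(chrom), ",length=",
           as.integer(contig_len), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gt, sep = "\t"))
  writeLines(lines, path)
  path
}

# ---- tiny SAM writer ------------------------------------------------------
# reads: data.frame(qname, flag, pos, cigar, seq, mapq?, qual?)
write_test_sam <- function(path, reads, chrom = "chr1", chrom_len = 1e6) {
  if (is.null(reads$mapq)) reads$mapq <- 60L
  if (is.null(reads$qual)) reads$qual <- strrep("I", nchar(reads$seq))
  reads <- reads[order(reads$pos), , drop = FALSE]
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", chrom, "\tLN:", as.integer(chrom_len)),
    paste(reads$qname, reads$flag, chrom, reads$pos, reads$mapq,
          reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, sep = "\t"))
  writeLines(lines, path)
  path
}

# ---- direct H-DAG builders ------------------------------------------------
# Variant table with L SNP levels spaced 100 bp apart.
toy_variants <- function(L, chrom = "chr1", spacing = 100L,
                         ref = NULL, alt = NULL) {
  data.frame(chrom = chrom, pos = seq_len(L) * spacing,
             ref = if (is.null(ref)) rep("A", L) else ref,
             alt = if (is.null(alt)) rep("T", L) else alt,
             level = seq_len(L), kind = "SNP", stringsAsFactors = FALSE)
}

# Set counts/observed on a skeleton directly (for oracle fixtures).
hdag_with_counts <- function(L, counts, observed = NULL) {
  h <- build_skeleton(toy_variants(L))
  h$counts[] <- counts
  if (is.null(observed)) {
    # nodes incident to any counted edge count as read-observed
    obs <- matrix(FALSE, L, 2)
    if (L > 1) {
      for (d in seq_len(L - 1)) for (i in 1:2) for (j in 1:2) {
        if (counts[d, i, j] > 0) { obs[d, i] <- TRUE; obs[d + 1, j] <- TRUE }
      }
    }
    h$observed <- obs
  } else {
    h$observed[] <- observed
  }
  h
}

# Random phaseable block: every adjacent pair keeps >= 1 edge and at least
# one complete start-to-end path exists (resampled until true).
random_block_hdag <- function(L, max_counter = 10L) {
  repeat {
    counts <- array(0L, dim = c(L - 1, 2, 2))
    for (d in seq_len(L - 1)) {
      k <- sample(1:4, 1)
      pick <- sample(1:4, k)
      m <- matrix(0L, 2, 2)
      m[pick] <- sample.int(max_counter, k, replace = TRUE)
      counts[d, , ] <- m
    }
    h <- hdag_with_counts(L, counts)
    if (nrow(brute_force_paths(h, 1L, L)) > 0) return(h)
  }
}

# ---- brute-force path oracle ----------------------------------------------
# All complete start-to-end sibling assignments with finite cost.
brute_force_paths <- function(hdag, first, last) {
  L <- last - first + 1
  w <- compute_weights(hdag)
  grid <- as.matrix(expand.grid(rep(list(1:2), L)))
  res <- list()
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    cost <- 0
    ok <- TRUE
    if (L > 1) for (t in seq_len(L - 1)) {
      d <- first + t - 1
      if (hdag$counts[d, path[t], path[t + 1]] == 0L) { ok <- FALSE; break }
      cost <- cost + w$cost[d, path[t], path[t + 1]]
    }
    if (ok) res[[length(res) + 1]] <- c(path, cost = cost)
  }
  if (!length(res)) {
    return(as.data.frame(matrix(numeric(), ncol = L + 1)))
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c(paste0("l", seq_len(L)), "cost")
  out
}

# ---- independent induction reference ---------------------------------------
# Straightforward recursive rendition of the look-ahead traversal, kept as
# plain edge data frames, used to cross-check induce_edges on small graphs.
naive_induce <- function(hdag, spans) {
  exists_arr <- hdag$counts > 0L
  snap <- hdag$counts > 0L & !hdag$induced   # read-evidence framework
  observed <- hdag$observed
  spans <- spans[order(spans$target_level, -spans$source_level,
                       spans$source_sib, spans$target_sib), , drop = FALSE]
  for (s in seq_len(nrow(spans))) {
    tgt_l <- spans$target_level[s]; tgt_s <- spans$target_sib[s]
    visited <- matrix(FALSE, hdag$L, 2)
    visit <- function(d, i) {
      if (visited[d, i]) return(invisible())
      visited[d, i] <<- TRUE
      if (d == tgt_l) return(invisible())
      sib <- 3 - i
      if (observed[d, sib] && snap[d, sib, 1] && snap[d, sib, 2]) {
        kids <- 1:2
      } else {
        kids <- which(!(snap[d, 1, ] | snap[d, 2, ]))
        if (d + 1 == tgt_l) kids <- kids[kids != 3 - tgt_s]
      }
      for (ch in kids) exists_arr[d, i, ch] <<- TRUE
      for (ch in which(exists_arr[d, i, ])) visit(d + 1, ch)
    }
    visit(spans$source_level[s], spans$source_sib[s])
  }
  exists_arr
}

# Fragment table shortcut: list of (frag, level, allele) triples.
frags <- function(...) {
  m <- do.call(rbind, list(...))
  fragments_from_observations(
    data.frame(frag = m[, 1], level = m[, 2], allele = m[, 3]))
}
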