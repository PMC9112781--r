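#' Simulation configuration for diploid read sets
#'
#' Bundles and validates the parameters of the synthetic diploid data
#' generator. Defaults emulate a human-like short-read regime: heterozygous
#' site density of 1/1000 bp, 316 bp median insert (so paired 100 bp reads
#' leave an unsequenced middle and discontinuous fragments arise), 25-fold
#' coverage, 1% per-base substitution error, and INDELs up to 20 bp making
#' up a tenth of the variants.
#'
#' @param region_length Reference region length, bp.
#' @param het_density Expected heterozygous sites per bp.
#' @param indel_fraction Proportion of variants that are INDELs (1-20 bp).
#' @param read_length Read length, bp (paired-end mode).
#' @param insert_mean,insert_sd Fragment (insert) size distribution, bp.
#' @param long_read_mean_len Mean long-read length, bp (long mode).
#' @param coverage Fold sequencing coverage.
#' @param error_rate Per-base substitution error probability.
#' @param mode `"paired"` or `"long"`.
#' @param chrom Chromosome name used in all outputs.
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(region_length = 1e5, het_density = 1e-3,
                       indel_fraction = 0.1, read_length = 100,
                       insert_mean = 316, insert_sd = 50,
                       long_read_mean_len = 5000, coverage = 25,
                       error_rate = 0.01, mode = c("paired", "long"),
                       chrom = "chr1", seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(region_length > 0, read_length > 0, insert_mean > 0,
            insert_sd >= 0, long_read_mean_len > 0)
  if (coverage <= 0) stop("coverage must be positive")
  if (het_density < 0 || het_density > 1) {
    stop("het_density must be in [0, 1]")
  }
  if (indel_fraction < 0 || indel_fraction > 1) {
    stop("indel_fraction must be in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (region_length < 200) {
    stop("region too short to place variants (need >= 200 bp)")
  }
  structure(list(
    region_length = as.integer(region_length),
    het_density = het_density, indel_fraction = indel_fraction,
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    long_read_mean_len = long_read_mean_len,
    coverage = coverage, error_rate = error_rate, mode = mode,
    chrom = chrom, seed = as.integer(seed)
  ), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Simulate a diploid truth: reference plus phased heterozygous variants
#'
#' Draws a random reference sequence and places heterozygous sites by a
#' Poisson process at the configured density (a minimum spacing of 25 bp
#' keeps variants from overlapping, since INDELs reach 20 bp). Each site is
#' a random substitution or, with probability `indel_fraction`, a 1-20 bp
#' insertion or deletion; each alternate allele is assigned to haplotype 1
#' or 2 at random, which defines the truth phase.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_truth`: list with `config`, `chrom`,
#'   `ref` (character reference sequence) and `variants` (data frame with
#'   `chrom`, `pos`, `ref`, `alt`, `kind`, `alt_hap`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$region_length
  refv <- sample(BASES, L, replace = TRUE)

  margin <- 60L
  n <- stats::rpois(1L, L * config$het_density)
  avail <- seq.int(margin, L - margin)
  n <- min(n, length(avail))
  pos <- sort(sample(avail, n))
  if (length(pos) > 1L) {               # enforce 25 bp spacing greedily
    keep <- logical(length(pos))
    last <- -Inf
    for (k in seq_along(pos)) {
      if (pos[k] - last >= 25L) { keep[k] <- TRUE; last <- pos[k] }
    }
    pos <- pos[keep]
  }
  n <- length(pos)
  ref_al <- character(n); alt_al <- character(n); kind <- character(n)
  is_indel <- stats::runif(n) < config$indel_fraction
  for (k in seq_len(n)) {
    p <- pos[k]
    if (!is_indel[k]) {
      ref_al[k] <- refv[p]
      alt_al[k] <- sample(setdiff(BASES, refv[p]), 1L)
      kind[k] <- "SNP"
    } else if (stats::runif(1) < 0.5) {            # deletion
      len <- sample.int(20L, 1L)
      ref_al[k] <- paste(refv[p:(p + len)], collapse = "")
      alt_al[k] <- refv[p]
      kind[k] <- "INDEL"
    } else {                                       # insertion
      len <- sample.int(20L, 1L)
      ref_al[k] <- refv[p]
      alt_al[k] <- paste(c(refv[p], sample(BASES, len, replace = TRUE)),
                         collapse = "")
      kind[k] <- "INDEL"
    }
  }
  variants <- data.frame(
    chrom = rep(config$chrom, n), pos = pos, ref = ref_al, alt = alt_al,
    kind = kind,
    alt_hap = if (n) sample(1:2, n, replace = TRUE) else integer(),
    stringsAsFactors = FALSE)
  structure(list(config = config, chrom = config$chrom,
                 ref = paste(refv, collapse = ""), variants = variants),
            class = "sim_truth")
}

# Apply a haplotype's alleles to the reference: returns the haplotype
# sequence plus an alignment segment table (M blocks, I and D events) that
# maps haplotype coordinates back to reference coordinates.
build_haplotype <- function(truth, hap) {
  x <- strsplit(truth$ref, "")[[1]]
  v <- truth$variants
  mine <- v[v$alt_hap == hap, , drop = FALSE]
  snps <- mine[mine$kind == "SNP", , drop = FALSE]
  if (nrow(snps)) x[snps$pos] <- snps$alt
  indels <- mine[mine$kind == "INDEL", , drop = FALSE]

  parts <- character(); segs <- list()
  cr <- 1L; chp <- 1L
  add_m <- function(to) {
    mlen <- to - cr + 1L
    if (mlen > 0L) {
      parts[[length(parts) + 1L]] <<- paste(x[cr:to], collapse = "")
      segs[[length(segs) + 1L]] <<- c(type = "M", ref_start = cr,
                                      hap_start = chp, len = mlen)
      cr <<- cr + mlen; chp <<- chp + mlen
    }
  }
  for (k in seq_len(nrow(indels))) {
    p <- indels$pos[k]
    add_m(p)                                       # through the anchor base
    rw <- nchar(indels$ref[k]); aw <- nchar(indels$alt[k])
    if (rw > aw) {                                 # deletion
      dlen <- rw - aw
      segs[[length(segs) + 1L]] <- c(type = "D", ref_start = cr,
                                     hap_start = chp, len = dlen)
      cr <- cr + dlen
    } else {                                       # insertion
      ins <- substring(indels$alt[k], rw + 1L)
      parts[[length(parts) + 1L]] <- ins
      segs[[length(segs) + 1L]] <- c(type = "I", ref_start = cr,
                                     hap_start = chp, len = nchar(ins))
      chp <- chp + nchar(ins)
    }
  }
  add_m(length(x))
  segs <- as.data.frame(do.call(rbind, segs), stringsAsFactors = FALSE)
  segs$ref_start <- as.integer(segs$ref_start)
  segs$hap_start <- as.integer(segs$hap_start)
  segs$len <- as.integer(segs$len)
  list(seq = paste(parts, collapse = ""), segs = segs,
       seg_type = segs$type, seg_ref = segs$ref_start,
       seg_hap = segs$hap_start, seg_len = segs$len,
       hap_len = chp - 1L + 0L)
}

# Alignment (POS + CIGAR) of the haplotype interval [a, b] against the
# reference. Leading/trailing insertions become soft clips; boundary
# deletions are dropped.
hap_alignment <- function(hapmap, a, b) {
  stype <- hapmap$seg_type; sref <- hapmap$seg_ref
  shap <- hapmap$seg_hap; slen <- hapmap$seg_len
  ops <- character(); lens <- integer(); pos <- NA_integer_
  # first segment whose haplotype start could still matter
  k0 <- findInterval(a, shap)
  for (k in max(1L, k0):length(stype)) {
    if (stype[k] == "D") {
      if (shap[k] - 1L >= a && shap[k] <= b) {
        ops <- c(ops, "D"); lens <- c(lens, slen[k])
      }
      next
    }
    he <- shap[k] + slen[k] - 1L
    if (he < a) next
    if (shap[k] > b) break
    o1 <- max(a, shap[k]); o2 <- min(b, he)
    if (o1 > o2) next
    if (stype[k] == "M") {
      if (is.na(pos)) pos <- sref[k] + (o1 - shap[k])
      ops <- c(ops, "M"); lens <- c(lens, o2 - o1 + 1L)
    } else {
      ops <- c(ops, "I"); lens <- c(lens, o2 - o1 + 1L)
    }
  }
  # boundary cleanup
  while (length(ops) && ops[1] %in% c("D")) { ops <- ops[-1]; lens <- lens[-1] }
  while (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  if (length(ops) && ops[1] == "I") ops[1] <- "S"
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  # merge adjacent identical ops
  if (length(ops) > 1L) {
    mo <- character(); ml <- integer()
    for (k in seq_along(ops)) {
      if (length(mo) && mo[length(mo)] == ops[k]) {
        ml[length(ml)] <- ml[length(ml)] + lens[k]
      } else {
        mo <- c(mo, ops[k]); ml <- c(ml, lens[k])
      }
    }
    ops <- mo; lens <- ml
  }
  ref_len <- sum(lens[ops %in% c("M", "D")])
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""),
       ref_len = ref_len)
}

# Substitution errors at the configured rate; returns sequence + positions.
inject_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(list(seq = seq, errors = integer()))
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, error_rate)
  if (k == 0L) return(list(seq = seq, errors = integer()))
  at <- sort(sample.int(n, k))
  for (p in at) {
    substr(seq, p, p) <- sample(setdiff(BASES, substr(seq, p, p)), 1L)
  }
  list(seq = seq, errors = at)
}

#' Simulate aligned reads from a diploid truth
#'
#' Draws DNA fragments uniformly from the two truth haplotypes and writes
#' perfectly placed alignments (the simulator knows the true coordinates, so
#' no mapper is involved): paired-end mode emits two `read_length` reads
#' from the fragment ends with the insert drawn from
#' `Normal(insert_mean, insert_sd)` — when the insert exceeds twice the read
#' length the middle of the fragment is unsequenced and discontinuous
#' fragments arise; long mode emits single reads with exponentially
#' distributed lengths. Substitution errors are applied at `error_rate` and
#' recorded in an optional JSON sidecar (per read: source haplotype, start,
#' error positions).
#'
#' @param config A [sim_config()] object.
#' @param truth The matching [simulate_truth()] result.
#' @param sam_path Output SAM path (text, coordinate-sorted, with header).
#' @param sidecar_path Optional JSON sidecar path.
#' @return Invisibly, a list with `sam`, `sidecar` and `n_reads`.
#' @export
simulate_reads <- function(config, truth, sam_path, sidecar_path = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  hap <- list(build_haplotype(truth, 1L), build_haplotype(truth, 2L))
  L <- config$region_length
  rl <- config$read_length

  recs <- list()   # each: c(qname, flag, pos, cigar, seq, mate fields...)
  side <- list()
  add_read <- function(qname, flag, h, a, b, hapseq) {
    a <- as.integer(a); b <- as.integer(b)
    raw <- substr(hapseq, a, b)
    er <- inject_errors(raw, config$error_rate)
    al <- hap_alignment(hap[[h]], a, b)
    side[[length(side) + 1L]] <<- list(
      qname = qname, mate = if (bitwAnd(flag, 64L) > 0L) 1L
              else if (bitwAnd(flag, 128L) > 0L) 2L else 0L,
      hap = h, hap_start = a, len = b - a + 1L, errors = er$errors)
    list(qname = qname, flag = flag, pos = al$pos, cigar = al$cigar,
         seq = er$seq, ref_len = al$ref_len)
  }

  if (config$mode == "paired") {
    n_frag <- ceiling(config$coverage * L / (2 * rl))
    h <- sample(1:2, n_frag, replace = TRUE)
    flen <- pmax(rl, round(stats::rnorm(n_frag, config$insert_mean,
                                        config$insert_sd)))
    for (i in seq_len(n_frag)) {
      hl <- hap[[h[i]]]$hap_len
      fl <- min(flen[i], hl)
      s <- sample.int(hl - fl + 1L, 1L)
      qn <- sprintf("frag%06d", i)
      lrl <- min(rl, fl)
      left <- add_read(qn, 99L, h[i], s, s + lrl - 1L, hap[[h[i]]]$seq)
      right <- add_read(qn, 147L, h[i], s + fl - lrl, s + fl - 1L,
                        hap[[h[i]]]$seq)
      tl <- right$pos + right$ref_len - left$pos
      left$mpos <- right$pos; left$tlen <- tl
      right$mpos <- left$pos; right$tlen <- -tl
      recs[[length(recs) + 1L]] <- left
      recs[[length(recs) + 1L]] <- right
    }
  } else {
    n_reads <- ceiling(config$coverage * L / config$long_read_mean_len)
    h <- sample(1:2, n_reads, replace = TRUE)
    len <- pmax(200L, round(stats::rexp(n_reads,
                                        1 / config$long_read_mean_len)))
    for (i in seq_len(n_reads)) {
      hl <- hap[[h[i]]]$hap_len
      ln <- min(len[i], hl)
      s <- sample.int(hl - ln + 1L, 1L)
      qn <- sprintf("read%06d", i)
      rd <- add_read(qn, 0L, h[i], s, s + ln - 1L, hap[[h[i]]]$seq)
      rd$mpos <- 0L; rd$tlen <- 0L
      recs[[length(recs) + 1L]] <- rd
    }
  }

  pos <- vapply(recs, function(r) r$pos, integer(1))
  recs <- recs[!is.na(pos)]
  o <- order(pos[!is.na(pos)])
  lines <- vapply(recs[o], function(r) {
    mate <- if (r$mpos > 0L) "=" else "*"
    paste(r$qname, r$flag, config$chrom, r$pos, 60L, r$cigar, mate,
          r$mpos, r$tlen, r$seq, strrep("I", nchar(r$seq)), sep = "\t")
  }, character(1))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", config$chrom, "\tLN:", L))
  writeLines(c(header, lines), sam_path)

  if (!is.null(sidecar_path)) {
    entries <- vapply(side, function(s) {
      sprintf(paste0('{"qname":"%s","mate":%d,"hap":%d,"hap_start":%d,',
                     '"len":%d,"errors":[%s]}'),
              s$qname, s$mate, s$hap, s$hap_start, s$len,
              paste(s$errors, collapse = ","))
    }, character(1))
    writeLines(c("[", paste0(entries, c(rep(",", max(0, length(entries) - 1)),
                                        "")), "]"),
               sidecar_path)
  }
  invisible(list(sam = sam_path, sidecar = sidecar_path,
                 n_reads = length(recs)))
}

write_truth_files <- function(truth, fasta_path, vcf_path) {
  dna <- Biostrings::DNAStringSet(stats::setNames(truth$ref, truth$chrom))
  Biostrings::writeXStringSet(dna, fasta_path)
  v <- truth$variants
  gt <- ifelse(v$alt_hap == 1L, "1|0", "0|1")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", truth$chrom, ",length=",
           truth$config$region_length, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SIM", sep = "\t"))
  if (nrow(v)) {
    lines <- c(lines, paste(v$chrom, v$pos, ".", v$ref, v$alt, ".",
                            "PASS", ".", "GT", gt, sep = "\t"))
  }
  writeLines(lines, vcf_path)
  invisible(vcf_path)
}

#' Generate a complete self-contained simulated dataset
#'
#' Runs [simulate_truth()] and [simulate_reads()] and writes the standard
#' files the phasing pipeline consumes: `ref.fa` (reference), `truth.vcf`
#' (truth-phased variants), `reads.sam` (coordinate-sorted alignments) and
#' `reads.json` (per-read truth haplotype and injected error positions).
#' Outputs are byte-identical across runs with the same configuration.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the four file paths and the in-memory
#'   `truth` object.
#' @export
simulate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config)
  fasta <- file.path(out_dir, "ref.fa")
  vcf <- file.path(out_dir, "truth.vcf")
  sam <- file.path(out_dir, "reads.sam")
  sidecar <- file.path(out_dir, "reads.json")
  write_truth_files(truth, fasta, vcf)
  simulate_reads(config, truth, sam, sidecar)
  invisible(list(fasta = fasta, vcf = vcf, sam = sam, sidecar = sidecar,
                 truth = truth))
}
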