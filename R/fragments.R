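#' Extract per-fragment allele observations from an alignment file
#'
#' Walks the CIGAR alignment of every primary read overlapping the variant
#' levels of one chromosome and records, per DNA fragment (a merged read pair
#' or a single long read), which of the site's two alleles the fragment
#' carries. Bases matching neither allele yield no observation. Fragments
#' with fewer than two observations carry no phase information and are
#' dropped.
#'
#' @param aln_path Coordinate-sorted BAM (indexed, or indexable) or plain SAM
#'   file mapped to the same reference as the VCF. SAM input is converted,
#'   sorted and indexed in a temporary file.
#' @param variants Data frame of heterozygous variants for one chromosome, as
#'   one element of [read_het_variants()].
#' @param min_mapq Minimum mapping quality; reads below contribute nothing.
#' @param min_baseq Minimum Phred base quality for an observation.
#' @return A `haplo_fragments` data frame with columns `frag` (integer
#'   fragment id), `qname`, `level`, `allele` (0 = REF, 1 = ALT), `baseq`,
#'   `source` ("paired-end" or "long-read"), sorted by fragment then level.
#' @details Secondary, supplementary and duplicate alignments are excluded.
#'   Mates sharing a query name are merged into one fragment; if the two
#'   mates disagree at a level, that observation is dropped. A read supports
#'   an INDEL's ALT only when its CIGAR encodes the full insertion/deletion
#'   at the site, and the REF only when one aligned block spans the whole REF
#'   allele with matching bases.
#' @export
extract_fragments <- function(aln_path, variants, min_mapq = 20L,
                              min_baseq = 13L) {
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L)
  chrom <- variants$chrom[1]
  bam <- ensure_indexed_bam(aln_path)

  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chrom %in% names(hdr)) {
    stop("chromosome '", chrom, "' is absent from the alignment header of '",
         aln_path, "' (contig mismatch between VCF and BAM?)")
  }

  rng <- IRanges::IRangesList(IRanges::IRanges(1L, unname(hdr[chrom])))
  names(rng) <- chrom
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, which = rng,
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]

  keep <- !is.na(b$pos) & !is.na(b$cigar) &
    (is.na(b$mapq) | b$mapq >= min_mapq)
  obs <- observations_from_reads(
    qname = b$qname[keep], flag = b$flag[keep], pos = b$pos[keep],
    cigar = b$cigar[keep], seq = as.character(b$seq[keep]),
    qual = as.character(b$qual[keep]),
    variants = variants, min_baseq = min_baseq)

  build_fragments(obs)
}

# Convert SAM to sorted+indexed BAM in tempdir; index a BAM if needed.
ensure_indexed_bam <- function(aln_path) {
  if (!file.exists(aln_path)) stop("alignment file not found: ", aln_path)
  ext <- tolower(tools::file_ext(aln_path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(aln_path, destination = dest, overwrite = TRUE,
                       indexDestination = TRUE),
      error = function(e) stop("could not convert SAM '", aln_path,
                               "' to BAM: ", conditionMessage(e)))
    return(bam)
  }
  bai <- paste0(aln_path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", aln_path)
  if (!file.exists(bai) && !file.exists(bai2)) {
    idx <- tryCatch(Rsamtools::indexBam(aln_path), error = function(e) {
      stop("alignment file '", aln_path, "' is not indexed and could not ",
           "be indexed (is it coordinate-sorted?): ", conditionMessage(e))
    })
  }
  aln_path
}

# Core allele-observation logic over parsed alignment vectors.
observations_from_reads <- function(qname, flag, pos, cigar, seq, qual,
                                    variants, min_baseq) {
  empty <- data.frame(qname = character(), flag = integer(),
                      level = integer(), allele = integer(),
                      baseq = integer(), stringsAsFactors = FALSE)
  if (length(qname) == 0L) return(empty)

  refM <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"))
  qryM <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cigar, ops = c("M", "=", "X"))
  nM <- S4Vectors::elementNROWS(refM)
  read_of_M <- rep(seq_along(cigar), nM)
  refMu <- unlist(refM, use.names = FALSE)
  qryMu <- unlist(qryM, use.names = FALSE)

  out <- list()

  ## --- SNPs: single aligned base must equal REF or ALT -------------------
  snp <- variants[variants$kind == "SNP", , drop = FALSE]
  if (nrow(snp)) {
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(snp$pos, width = 1L), refMu)
    vi <- S4Vectors::queryHits(hits)
    bi <- S4Vectors::subjectHits(hits)
    if (length(vi)) {
      rd <- read_of_M[bi]
      qpos <- IRanges::start(qryMu)[bi] + (snp$pos[vi] -
                                             IRanges::start(refMu)[bi])
      base <- substr(seq[rd], qpos, qpos)
      bq <- qual_at(qual, rd, qpos, qpos)
      allele <- ifelse(base == snp$ref[vi], 0L,
                       ifelse(base == snp$alt[vi], 1L, NA_integer_))
      ok <- !is.na(allele) & bq >= min_baseq
      out$snp <- data.frame(qname = qname[rd[ok]], flag = flag[rd[ok]],
                            level = snp$level[vi[ok]],
                            allele = allele[ok], baseq = bq[ok],
                            stringsAsFactors = FALSE)
    }
  }

  indel <- variants[variants$kind == "INDEL", , drop = FALSE]
  if (nrow(indel)) {
    rw <- nchar(indel$ref)
    aw <- nchar(indel$alt)
    is_del <- rw > aw

    ## --- REF support: one aligned block spans the full REF span ----------
    # deletions: the whole REF allele inside one M block (no D break);
    # insertions: REF plus one base beyond it inside one M block (no I break)
    span_end <- ifelse(is_del, indel$pos + rw - 1L, indel$pos + rw)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(indel$pos, span_end), refMu, type = "within")
    vi <- S4Vectors::queryHits(hits)
    bi <- S4Vectors::subjectHits(hits)
    if (length(vi)) {
      rd <- read_of_M[bi]
      q1 <- IRanges::start(qryMu)[bi] + (indel$pos[vi] -
                                           IRanges::start(refMu)[bi])
      q2 <- q1 + rw[vi] - 1L
      bases <- substr(seq[rd], q1, q2)
      bq <- qual_at(qual, rd, q1, q2)
      ok <- bases == indel$ref[vi] & bq >= min_baseq
      out$indel_ref <- data.frame(qname = qname[rd[ok]], flag = flag[rd[ok]],
                                  level = indel$level[vi[ok]],
                                  allele = 0L, baseq = bq[ok],
                                  stringsAsFactors = FALSE)
    }

    ## --- ALT support for deletions: exact D op at pos + |ALT| ------------
    del <- which(is_del)
    if (length(del)) {
      refD <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cigar, pos = pos, ops = "D")
      read_of_D <- rep(seq_along(cigar), S4Vectors::elementNROWS(refD))
      refDu <- unlist(refD, use.names = FALSE)
      if (length(refDu)) {
        vi <- match(IRanges::start(refDu), indel$pos[del] + aw[del])
        okd <- !is.na(vi) &
          IRanges::width(refDu) == (rw[del] - aw[del])[vi]
        if (any(okd)) {
          rd <- read_of_D[okd]
          vd <- del[vi[okd]]
          # base quality taken at the anchor base preceding the deletion
          anchor <- anchor_qpos(indel$pos[vd], rd, read_of_M, refMu, qryMu)
          keep <- !is.na(anchor)
          rd <- rd[keep]; vd <- vd[keep]; anchor <- anchor[keep]
          bq <- qual_at(qual, rd, anchor, anchor)
          ok <- bq >= min_baseq
          out$del_alt <- data.frame(qname = qname[rd[ok]],
                                    flag = flag[rd[ok]],
                                    level = indel$level[vd[ok]],
                                    allele = 1L, baseq = bq[ok],
                                    stringsAsFactors = FALSE)
        }
      }
    }

    ## --- ALT support for insertions: exact I op after the anchor ---------
    ins <- which(!is_del)
    if (length(ins)) {
      refI <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        cigar, pos = pos, ops = "I")
      qryI <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar, ops = "I")
      read_of_I <- rep(seq_along(cigar), S4Vectors::elementNROWS(refI))
      refIu <- unlist(refI, use.names = FALSE)
      qryIu <- unlist(qryI, use.names = FALSE)
      if (length(refIu)) {
        vi <- match(IRanges::start(refIu), indel$pos[ins] + rw[ins])
        oki <- !is.na(vi) &
          IRanges::width(qryIu) == (aw[ins] - rw[ins])[vi]
        if (any(oki)) {
          rd <- read_of_I[oki]
          vI <- ins[vi[oki]]
          q1 <- IRanges::start(qryIu)[oki]
          q2 <- IRanges::end(qryIu)[oki]
          inserted <- substr(seq[rd], q1, q2)
          want <- substring(indel$alt[vI], rw[vI] + 1L)
          bq <- qual_at(qual, rd, q1, q2)
          ok <- inserted == want & bq >= min_baseq
          out$ins_alt <- data.frame(qname = qname[rd[ok]],
                                    flag = flag[rd[ok]],
                                    level = indel$level[vI[ok]],
                                    allele = 1L, baseq = bq[ok],
                                    stringsAsFactors = FALSE)
        }
      }
    }
  }

  if (!length(out)) return(empty)
  do.call(rbind, unname(out))
}

# Minimum Phred quality over query positions q1..q2 (vectorized per read).
qual_at <- function(qual, rd, q1, q2) {
  if (!length(rd)) return(integer())
  s <- substr(qual[rd], q1, q2)
  vapply(s, function(x) {
    if (nchar(x) == 0L) return(-1L)
    min(as.integer(charToRaw(x))) - 33L
  }, integer(1), USE.NAMES = FALSE)
}

# Query position of the aligned base at reference position p for given reads.
anchor_qpos <- function(p, rd, read_of_M, refMu, qryMu) {
  res <- rep(NA_integer_, length(rd))
  for (k in seq_along(rd)) {
    bi <- which(read_of_M == rd[k] &
                  IRanges::start(refMu) <= p[k] &
                  IRanges::end(refMu) >= p[k])
    if (length(bi)) {
      bi <- bi[1]
      res[k] <- IRanges::start(qryMu)[bi] + (p[k] - IRanges::start(refMu)[bi])
    }
  }
  res
}

# Merge mate observations into fragments; drop intra-fragment conflicts and
# fragments with <2 informative levels.
build_fragments <- function(obs) {
  empty <- structure(
    data.frame(frag = integer(), qname = character(), level = integer(),
               allele = integer(), baseq = integer(), source = character(),
               stringsAsFactors = FALSE),
    class = c("haplo_fragments", "data.frame"), n_fragments = 0L)
  if (nrow(obs) == 0L) return(empty)

  qid <- match(obs$qname, unique(obs$qname))
  key <- paste(qid, obs$level)

  # conflicting alleles within one molecule at one level are uninformative
  pair <- !duplicated(paste(key, obs$allele))
  tabk <- table(key[pair])
  conflict_keys <- names(tabk)[tabk > 1L]
  obs <- obs[!key %in% conflict_keys, , drop = FALSE]
  qid <- qid[!key %in% conflict_keys]
  if (nrow(obs) == 0L) return(empty)

  # duplicate same-allele observations (mate overlap): keep best quality
  o <- order(qid, obs$level, -obs$baseq)
  obs <- obs[o, , drop = FALSE]
  qid <- qid[o]
  dup <- duplicated(paste(qid, obs$level))
  obs <- obs[!dup, , drop = FALSE]
  qid <- qid[!dup]

  nlev <- tabulate(qid)
  keep <- nlev[qid] >= 2L
  obs <- obs[keep, , drop = FALSE]
  qid <- qid[keep]
  if (nrow(obs) == 0L) return(empty)

  frag <- match(qid, unique(qid))
  res <- data.frame(
    frag = frag,
    qname = obs$qname,
    level = obs$level,
    allele = obs$allele,
    baseq = obs$baseq,
    source = ifelse(bitwAnd(obs$flag, 1L) > 0L, "paired-end", "long-read"),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("haplo_fragments", "data.frame"),
            n_fragments = max(frag))
}

#' Build a fragment table from explicit allele observations
#'
#' Constructor used for hand-built graph fixtures and tests: turns a plain
#' data frame of observations into the `haplo_fragments` representation that
#' [build_hdag()] consumes, validating the fragment invariants (levels
#' strictly increasing and unique within a fragment, alleles in 0/1, at least
#' two observations per fragment).
#'
#' @param df Data frame with columns `frag`, `level`, `allele` and optionally
#'   `baseq` (default 40) and `source` (default "paired-end").
#' @return A `haplo_fragments` data frame.
#' @export
fragments_from_observations <- function(df) {
  stopifnot(all(c("frag", "level", "allele") %in% names(df)))
  if (!all(df$allele %in% c(0L, 1L))) {
    stop("allele must be 0 (REF) or 1 (ALT)")
  }
  if (is.null(df$baseq)) df$baseq <- 40L
  if (is.null(df$source)) df$source <- "paired-end"
  if (is.null(df$qname)) df$qname <- sprintf("frag%06d", df$frag)
  df <- df[order(df$frag, df$level), , drop = FALSE]
  for (f in unique(df$frag)) {
    lv <- df$level[df$frag == f]
    if (length(lv) < 2L) stop("fragment ", f, " has <2 observations")
    if (any(diff(lv) <= 0L)) {
      stop("fragment ", f, " has non-increasing or duplicate levels")
    }
  }
  df$frag <- match(df$frag, unique(df$frag))
  res <- df[, c("frag", "qname", "level", "allele", "baseq", "source")]
  rownames(res) <- NULL
  structure(res, class = c("haplo_fragments", "data.frame"),
            n_fragments = max(df$frag))
}
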