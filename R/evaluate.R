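#' Read truth-phased haplotype assignments from a VCF
#'
#' Extracts, for every phased biallelic heterozygous record, which allele
#' (0 = REF, 1 = ALT) lies on the first haplotype, together with its phase
#' set. Records without a `|`-phased genotype are skipped.
#'
#' @param truth_vcf Path to a phased VCF (`a|b` genotypes, optional PS tag;
#'   records without PS fall into one chromosome-wide phase set).
#' @param sample Sample column to use; defaults to the first sample.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `truth_hap1` (0/1) and `ps`.
#' @export
read_truth_haps <- function(truth_vcf, sample = 1L) {
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(truth_vcf, verbose = FALSE)),
    error = function(e) stop("malformed or unreadable truth VCF '",
                             truth_vcf, "': ", conditionMessage(e)))
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      truth_hap1 = integer(), ps = integer()))
  }
  gt <- extract_gt_field(v@gt, sample)
  ps <- extract_ps_field(v@gt, sample)
  het <- !is.na(gt) & gt %in% c("0|1", "1|0") &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  df <- data.frame(
    chrom = fix[het, "CHROM"],
    pos = as.integer(fix[het, "POS"]),
    ref = fix[het, "REF"],
    alt = fix[het, "ALT"],
    truth_hap1 = ifelse(gt[het] == "1|0", 1L, 0L),
    ps = ps[het],
    stringsAsFactors = FALSE)
  df$ps[is.na(df$ps)] <- 0L
  df[order(df$chrom, df$pos), , drop = FALSE]
}

extract_ps_field <- function(gtmat, sample = 1L) {
  fmt <- gtmat[, "FORMAT"]
  val <- gtmat[, 1L + sample]
  ps <- rep(NA_integer_, length(val))
  for (f in unique(fmt)) {
    i <- which(fmt == f)
    pi <- match("PS", strsplit(f, ":", fixed = TRUE)[[1]])
    if (is.na(pi)) next
    parts <- strsplit(val[i], ":", fixed = TRUE)
    ps[i] <- suppressWarnings(as.integer(
      vapply(parts, function(x) if (length(x) >= pi) x[pi]
             else NA_character_, character(1))))
  }
  ps
}

#' Switch errors of predicted haplotypes against a truth phasing
#'
#' For every multi-level predicted block, haplotype 1 is compared to the
#' truth haplotype under both orientation assignments (haplotype labels are
#' arbitrary) and the orientation minimizing the number of discordant levels
#' is kept; the block's error count is the discordance under that
#' orientation. The rate divides total errors by the total phased span of the
#' evaluated blocks, in megabases. Blocks crossing truth phase-set boundaries
#' are evaluated within each truth phase set independently and counted in
#' `split_blocks`. The conventional adjacent-pair switch count (number of
#' relative-phase flips between consecutive levels) is reported alongside as
#' `n_flips`.
#'
#' @param blocks Block table from [read_blocks()] (or the data frame the
#'   block file encodes).
#' @param truth Truth table from [read_truth_haps()].
#' @return A list with `n_errors`, `phased_span_bp`, `rate_per_mb`,
#'   `n_flips`, `excluded_levels` (predicted levels absent from the truth),
#'   `split_blocks`, and `per_block` (one row per evaluated block with its
#'   numerator, denominator and rate).
#' @export
switch_errors <- function(blocks, truth) {
  pb <- blocks[blocks$type == "phased", , drop = FALSE]
  key_t <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
  per <- list()
  excluded <- 0L
  split_blocks <- 0L
  for (b in unique(pb$block)) {
    tb <- pb[pb$block == b, , drop = FALSE]
    hit <- match(paste(tb$chrom, tb$pos, tb$ref, tb$alt), key_t)
    excluded <- excluded + sum(is.na(hit))
    tb <- tb[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
    if (nrow(tb) < 2L) next
    pred <- ifelse(tb$hap1 == tb$alt, 1L, 0L)
    tru <- truth$truth_hap1[hit]
    sets <- truth$ps[hit]
    if (length(unique(sets)) > 1L) split_blocks <- split_blocks + 1L
    for (s in unique(sets)) {
      i <- which(sets == s)
      if (length(i) < 2L) next
      d <- sum(pred[i] != tru[i])
      err <- min(d, length(i) - d)
      rel <- as.integer(pred[i] != tru[i])
      flips <- sum(diff(rel) != 0L)
      span <- max(tb$pos[i]) - min(tb$pos[i]) + 1L
      per[[length(per) + 1L]] <- data.frame(
        chrom = tb$chrom[1], block = b, truth_ps = s,
        n_levels = length(i), span_bp = span, errors = err,
        flips = flips,
        rate_per_mb = err / (span / 1e6),
        stringsAsFactors = FALSE)
    }
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(chrom = character(), block = integer(), truth_ps = integer(),
               n_levels = integer(), span_bp = integer(), errors = integer(),
               flips = integer(), rate_per_mb = numeric())
  span <- sum(per$span_bp)
  errs <- sum(per$errors)
  list(
    n_errors = errs,
    phased_span_bp = span,
    rate_per_mb = if (span > 0) errs / (span / 1e6) else 0,
    n_flips = sum(per$flips),
    excluded_levels = excluded,
    split_blocks = split_blocks,
    per_block = per)
}

#' N50 of a set of block lengths
#'
#' Length of the block at which the cumulative sum of descending-sorted
#' lengths first reaches half of the total length.
#'
#' @param lengths Numeric vector of block lengths (bp).
#' @return The N50, or 0 for an empty input.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' Haplotype block length statistics
#'
#' N50, mean, maximum and total genomic span of the multi-level phased
#' blocks. Block length is the genomic span from the first to the last
#' phased variant of the block (inclusive, bp).
#'
#' @param blocks A `phased_blocks` object or a block table from
#'   [read_blocks()].
#' @return An object of class `phasing_stats`: list with `n_blocks`,
#'   `n_singletons`, `n50`, `mean_len`, `max_len`, `total_phased` (all bp).
#' @export
block_length_stats <- function(blocks) {
  if (inherits(blocks, "phased_blocks")) {
    multi <- !vapply(blocks, function(b) b$singleton, logical(1))
    lens <- vapply(blocks[multi], function(b) as.numeric(b$span_bp),
                   numeric(1))
    nsing <- sum(!multi)
  } else {
    pb <- blocks[blocks$type == "phased", , drop = FALSE]
    lens <- vapply(split(pb$pos, pb$block),
                   function(p) max(p) - min(p) + 1, numeric(1))
    nsing <- length(unique(blocks$block[blocks$type == "singleton"]))
  }
  if (!length(lens)) {
    warning("no multi-level phased blocks; statistics are all zero")
    return(structure(list(n_blocks = 0L, n_singletons = nsing, n50 = 0,
                          mean_len = 0, max_len = 0, total_phased = 0),
                     class = "phasing_stats"))
  }
  structure(list(
    n_blocks = length(lens),
    n_singletons = nsing,
    n50 = n50(lens),
    mean_len = mean(lens),
    max_len = max(lens),
    total_phased = sum(lens)
  ), class = "phasing_stats")
}

#' @export
print.phasing_stats <- function(x, ...) {
  cat("phasing_stats:\n")
  cat(sprintf("  blocks: %d phased (+%d singleton)\n",
              x$n_blocks, x$n_singletons))
  cat(sprintf("  N50: %g bp   mean: %.1f bp   max: %g bp   total: %g bp\n",
              x$n50, x$mean_len, x$max_len, x$total_phased))
  invisible(x)
}

#' Switch-error rates stratified by haplotype length class
#'
#' Assigns every evaluated block to a length class defined by `class_edges`
#' and reports, per class, the block frequency and the switch error rate
#' (class errors over class phased span, per Mb), plus an overall row. The
#' overall rate equals the aggregation of the per-class numerators and
#' denominators.
#'
#' @param blocks Block table from [read_blocks()].
#' @param truth Truth table from [read_truth_haps()].
#' @param class_edges Strictly increasing length boundaries in bp; classes
#'   are `(0, e1], (e1, e2], ..., (ek, Inf)`.
#' @return Data frame with one row per class and a final `overall` row:
#'   `class`, `n_blocks`, `errors`, `span_bp`, `rate_per_mb`.
#' @export
stratified_report <- function(blocks, truth, class_edges) {
  if (is.unsorted(class_edges, strictly = TRUE)) {
    stop("class_edges must be strictly increasing")
  }
  sw <- switch_errors(blocks, truth)
  per <- sw$per_block
  edges <- c(0, class_edges, Inf)
  labs <- paste0("(", edges[-length(edges)], ",", edges[-1L], "]")
  labs[length(labs)] <- paste0(">", class_edges[length(class_edges)])
  cls <- cut(per$span_bp, breaks = edges, labels = labs)
  agg <- data.frame(class = labs, stringsAsFactors = FALSE)
  agg$n_blocks <- as.integer(table(cls)[labs])
  agg$errors <- vapply(labs, function(l) sum(per$errors[cls == l]),
                       numeric(1))
  agg$span_bp <- vapply(labs, function(l) sum(per$span_bp[cls == l]),
                        numeric(1))
  agg$rate_per_mb <- ifelse(agg$span_bp > 0,
                            agg$errors / (agg$span_bp / 1e6), 0)
  overall <- data.frame(class = "overall", n_blocks = nrow(per),
                        errors = sum(per$errors), span_bp = sum(per$span_bp),
                        rate_per_mb = sw$rate_per_mb)
  rownames(agg) <- NULL
  rbind(agg, overall)
}

#' Evaluate a block file against a truth-phased VCF
#'
#' Wrapper over [switch_errors()], [block_length_stats()] and
#' [stratified_report()] that reads both inputs from disk and optionally
#' writes the stratified table as TSV.
#'
#' @param blocks_file Path to a `.blocks.tsv` file.
#' @param truth_vcf Path to the truth-phased VCF.
#' @param class_edges Length class boundaries (bp).
#' @param out_tsv Optional output path for the stratified report.
#' @return List with `stats` (`phasing_stats`), `switch` (result of
#'   [switch_errors()]) and `strata` (stratified report).
#' @export
evaluate_phasing <- function(blocks_file, truth_vcf,
                             class_edges = c(1000, 3000, 10000),
                             out_tsv = NULL) {
  blocks <- read_blocks(blocks_file)
  truth <- read_truth_haps(truth_vcf)
  res <- list(
    stats = block_length_stats(blocks),
    switch = switch_errors(blocks, truth),
    strata = stratified_report(blocks, truth, class_edges))
  if (!is.null(out_tsv)) {
    utils::write.table(res$strata, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}
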