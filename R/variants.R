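#' Read biallelic heterozygous variants from a VCF file
#'
#' Parses a single-sample VCF (plain or bgzipped) and returns, per chromosome,
#' the position-sorted biallelic heterozygous SNPs and INDELs that form the
#' levels of the haplotype DAG. Homozygous, multiallelic, and missing-genotype
#' records are skipped and tallied in a skip report attached to the result.
#'
#' @param vcf_path Path to a VCF file (v4.x, optionally gzipped).
#' @param chrom Optional chromosome name; restricts the result to that
#'   chromosome (an error if the VCF has no records on it).
#' @param sample Sample column to use; defaults to the first sample.
#' @return An object of class `het_variants`: a named list with one
#'   data frame per chromosome (columns `chrom`, `pos`, `ref`, `alt`,
#'   `level`, `kind`), levels numbered 1..L per chromosome in position order.
#'   The skip report is in `attr(x, "skipped")`.
#' @details Only genotypes `0/1`, `1/0`, `0|1`, `1|0` at sites with a single
#'   ALT allele qualify. Two heterozygous records at the same position on one
#'   chromosome are an input error, since a level must carry exactly one
#'   allele pair.
#' @examples
#' \dontrun{
#' vars <- read_het_variants("sample.vcf")
#' attr(vars, "skipped")
#' }
#' @export
read_het_variants <- function(vcf_path, chrom = NULL, sample = 1L) {
  if (!file.exists(vcf_path)) {
    stop("VCF file not found: ", vcf_path)
  }
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(vcf_path, verbose = FALSE)),
    error = function(e) stop("malformed or unreadable VCF '", vcf_path,
                             "': ", conditionMessage(e))
  )
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    res <- structure(list(), class = "het_variants",
                     skipped = empty_skip_report())
    return(res)
  }
  if (ncol(v@gt) < 2L) {
    stop("VCF '", vcf_path, "' has no sample genotype column")
  }
  gt <- extract_gt_field(v@gt, sample)

  chroms <- fix[, "CHROM"]
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bad <- which(is.na(pos) | is.na(ref) | is.na(alt) | ref == "" | alt == "")
  if (length(bad)) {
    stop("malformed VCF record at ", chroms[bad[1]], ":",
         fix[bad[1], "POS"], " in '", vcf_path, "'")
  }

  multi <- grepl(",", alt, fixed = TRUE)
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  missing_gt <- is.na(gt) | grepl("\\.", gt_norm)
  het <- !multi & !missing_gt & gt_norm %in% c("0/1", "1/0")
  hom <- !multi & !missing_gt & gt_norm %in% c("0/0", "1/1")
  # genotypes naming an allele >1 at a biallelic site, or 1/2 etc.
  other <- !multi & !missing_gt & !het & !hom

  skipped <- c(
    homozygous = sum(hom),
    multiallelic = sum(multi),
    missing_genotype = sum(missing_gt & !multi),
    other_genotype = sum(other)
  )

  keep <- which(het)
  out <- list()
  for (cn in unique(chroms[keep])) {
    idx <- keep[chroms[keep] == cn]
    idx <- idx[order(pos[idx])]
    p <- pos[idx]
    if (anyDuplicated(p)) {
      d <- p[duplicated(p)][1]
      stop("two heterozygous records at the same position ", cn, ":", d,
           " in '", vcf_path, "'")
    }
    out[[cn]] <- data.frame(
      chrom = cn,
      pos = p,
      ref = ref[idx],
      alt = alt[idx],
      level = seq_along(idx),
      kind = ifelse(nchar(ref[idx]) == 1L & nchar(alt[idx]) == 1L,
                    "SNP", "INDEL"),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(chrom)) {
    if (!chrom %in% names(out)) {
      stop("no heterozygous variants on chromosome '", chrom, "' in '",
           vcf_path, "'")
    }
    out <- out[chrom]
  }
  structure(out, class = "het_variants", skipped = skipped)
}

empty_skip_report <- function() {
  c(homozygous = 0L, multiallelic = 0L, missing_genotype = 0L,
    other_genotype = 0L)
}

# Pull the GT subfield out of a vcfR @gt matrix for one sample column.
extract_gt_field <- function(gtmat, sample = 1L) {
  fmt <- gtmat[, "FORMAT"]
  val <- gtmat[, 1L + sample]
  # FORMAT is usually constant; handle per unique layout
  gt <- rep(NA_character_, length(val))
  for (f in unique(fmt)) {
    i <- which(fmt == f)
    gi <- match("GT", strsplit(f, ":", fixed = TRUE)[[1]])
    if (is.na(gi)) next
    parts <- strsplit(val[i], ":", fixed = TRUE)
    gt[i] <- vapply(parts, function(x) if (length(x) >= gi) x[gi]
                    else NA_character_, character(1))
  }
  gt
}

#' @export
print.het_variants <- function(x, ...) {
  n <- vapply(x, nrow, integer(1))
  cat("het_variants: ", sum(n), " heterozygous site(s) on ",
      length(x), " chromosome(s)\n", sep = "")
  for (cn in names(x)) cat("  ", cn, ": ", n[[cn]], " site(s)\n", sep = "")
  sk <- attr(x, "skipped")
  if (!is.null(sk) && sum(sk) > 0) {
    cat("skipped:", paste(names(sk), sk, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
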