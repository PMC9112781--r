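#' Write phased haplotypes as a phased VCF and a block file
#'
#' Produces two files: (a) a phased VCF in which every heterozygous genotype
#' belonging to a phased block becomes `a|b` with a `PS` (phase set) tag set
#' to the 1-based position of the block's first variant, written by streaming
#' the input VCF so all other records and fields pass through untouched; and
#' (b) a tab-separated block file, one header line per block followed by one
#' line per variant, consumed by the evaluation functions.
#'
#' @param phased A `phased_blocks` object (or a named list of them, one per
#'   chromosome).
#' @param variants The matching `het_variants` object.
#' @param vcf_in Path to the input VCF the variants came from.
#' @param out_prefix Output path prefix; writes `<prefix>.phased.vcf` and
#'   `<prefix>.blocks.tsv`.
#' @return Invisibly, a list with the two output paths.
#' @section Block file format:
#' Block header lines start with `#BLOCK` and carry: block id, chromosome,
#' type (`phased`/`singleton`), first and last variant position, number of
#' levels, genomic span (bp) and path cost. Variant lines carry: chromosome,
#' block id, level (1-based within chromosome), position, REF, ALT, hap1
#' allele, hap2 allele (`.` for singletons), and the phase set position.
#' @export
write_phased_output <- function(phased, variants, vcf_in, out_prefix) {
  if (inherits(phased, "phased_blocks")) {
    ch <- if (length(phased)) phased[[1]]$chrom else names(variants)[1]
    phased <- stats::setNames(list(phased), ch)
  }
  stopifnot(all(names(phased) %in% names(variants)))

  vcf_out <- paste0(out_prefix, ".phased.vcf")
  blocks_out <- paste0(out_prefix, ".blocks.tsv")

  ## ---- per-variant assignment table ------------------------------------
  rows <- list()
  bid <- 0L
  for (ch in names(phased)) {
    v <- variants[[ch]]
    for (blk in phased[[ch]]) {
      bid <- bid + 1L
      if (any(blk$levels < 1L | blk$levels > nrow(v))) {
        stop("internal consistency error: block references unknown level")
      }
      ps <- v$pos[blk$first_level]
      rows[[bid]] <- data.frame(
        chrom = ch, block = bid,
        type = if (blk$singleton) "singleton" else "phased",
        level = blk$levels, pos = v$pos[blk$levels],
        ref = v$ref[blk$levels], alt = v$alt[blk$levels],
        hap1 = if (blk$singleton) "." else blk$hap1,
        hap2 = if (blk$singleton) "." else blk$hap2,
        ps = ps,
        span_bp = blk$span_bp,
        path_cost = if (blk$singleton) NA_real_ else blk$path_cost,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL

  ## ---- block file ------------------------------------------------------
  con <- file(blocks_out, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("#haplodag blocks v1; columns: chrom block level pos ",
                    "ref alt hap1 hap2 ps"), con)
  if (!is.null(tab)) {
    for (b in unique(tab$block)) {
      tb <- tab[tab$block == b, , drop = FALSE]
      writeLines(sprintf("#BLOCK\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%s",
                         b, tb$chrom[1], tb$type[1], min(tb$pos),
                         max(tb$pos), nrow(tb), tb$span_bp[1],
                         format(tb$path_cost[1], digits = 10)), con)
      writeLines(sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%s\t%s\t%d",
                         tb$chrom, tb$block, tb$level, tb$pos, tb$ref,
                         tb$alt, tb$hap1, tb$hap2, tb$ps), con)
    }
  }

  ## ---- phased VCF ------------------------------------------------------
  write_phased_vcf(tab, vcf_in, vcf_out)
  invisible(list(vcf = vcf_out, blocks = blocks_out))
}

# Stream the input VCF, rewriting GT (a|b) and PS of phased records.
write_phased_vcf <- function(tab, vcf_in, vcf_out) {
  con_in <- if (grepl("\\.gz$", vcf_in)) gzfile(vcf_in, "r")
            else file(vcf_in, "r")
  lines <- readLines(con_in)
  close(con_in)

  phased <- if (is.null(tab)) NULL
            else tab[tab$type == "phased", , drop = FALSE]
  keymap <- if (!is.null(phased) && nrow(phased)) {
    stats::setNames(seq_len(nrow(phased)),
                    paste(phased$chrom, phased$pos, phased$ref, phased$alt))
  } else NULL

  hdr <- grepl("^##", lines)
  chrom_line <- which(grepl("^#CHROM", lines))[1]
  if (is.na(chrom_line)) stop("input VCF lacks a #CHROM header line")
  out <- lines[seq_len(chrom_line - 1L)]
  if (!any(grepl("^##FORMAT=<ID=PS,", lines))) {
    out <- c(out, paste0("##FORMAT=<ID=PS,Number=1,Type=Integer,",
                         "Description=\"Phase set (position of first ",
                         "variant in phased block)\">"))
  }
  out <- c(out, lines[chrom_line])

  body <- lines[seq_len(length(lines)) > chrom_line]
  body <- body[nzchar(body)]
  if (length(body) && !is.null(keymap)) {
    fields <- strsplit(body, "\t", fixed = TRUE)
    body <- vapply(fields, function(fl) {
      key <- paste(fl[1], fl[2], fl[4], fl[5])
      hit <- keymap[key]
      if (is.na(hit)) return(paste(fl, collapse = "\t"))
      p <- phased[hit, ]
      h1 <- if (p$hap1 == p$ref) 0L else 1L
      fmt <- strsplit(fl[9], ":", fixed = TRUE)[[1]]
      smp <- strsplit(fl[10], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fmt)
      smp[gi] <- paste0(h1, "|", 1L - h1)
      pi <- match("PS", fmt)
      if (is.na(pi)) {
        fmt <- c(fmt, "PS")
        smp <- c(smp, as.character(p$ps))
      } else {
        smp[pi] <- as.character(p$ps)
      }
      fl[9] <- paste(fmt, collapse = ":")
      fl[10] <- paste(smp, collapse = ":")
      paste(fl, collapse = "\t")
    }, character(1))
  }
  writeLines(c(out, body), vcf_out)
  invisible(vcf_out)
}

#' Read a haplodag block file
#'
#' @param path Path to a `.blocks.tsv` file written by
#'   [write_phased_output()].
#' @return Data frame with columns `chrom`, `block`, `type`, `level`, `pos`,
#'   `ref`, `alt`, `hap1`, `hap2`, `ps`.
#' @export
read_blocks <- function(path) {
  lines <- readLines(path)
  hdrs <- grepl("^#BLOCK", lines)
  meta <- strsplit(lines[hdrs], "\t", fixed = TRUE)
  types <- stats::setNames(
    vapply(meta, `[`, character(1), 4L),
    vapply(meta, `[`, character(1), 2L))
  data <- lines[!grepl("^#", lines)]
  if (!length(data)) {
    return(data.frame(chrom = character(), block = integer(),
                      type = character(), level = integer(),
                      pos = integer(), ref = character(), alt = character(),
                      hap1 = character(), hap2 = character(),
                      ps = integer(), stringsAsFactors = FALSE))
  }
  fl <- strsplit(data, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(fl, `[`, character(1), 1L),
    block = as.integer(vapply(fl, `[`, character(1), 2L)),
    level = as.integer(vapply(fl, `[`, character(1), 3L)),
    pos = as.integer(vapply(fl, `[`, character(1), 4L)),
    ref = vapply(fl, `[`, character(1), 5L),
    alt = vapply(fl, `[`, character(1), 6L),
    hap1 = vapply(fl, `[`, character(1), 7L),
    hap2 = vapply(fl, `[`, character(1), 8L),
    ps = as.integer(vapply(fl, `[`, character(1), 9L)),
    stringsAsFactors = FALSE)
  df$type <- unname(types[as.character(df$block)])
  df[, c("chrom", "block", "type", "level", "pos", "ref", "alt",
         "hap1", "hap2", "ps")]
}
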