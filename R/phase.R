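#' Convert edge counters to probabilistic weights and costs
#'
#' Each existing directed edge gets the weight
#' \deqn{w_{ij} = n(e_{ij}) / \sum_k n(e_{ik}),}
#' its counter divided by the sum of the counters of all edges emitting from
#' the same source node, and the cost \eqn{-\log w_{ij}} (natural log). A
#' source with a single outgoing edge therefore has weight 1 and cost 0; a
#' pair of freshly induced edges from one parent (both counters at the
#' initial value 1) has weight 0.5 each. Outgoing weights from any source sum
#' to 1 by construction.
#'
#' @param hdag An `hdag` object.
#' @param block Optional block row (from [partition_blocks()]) used only to
#'   validate that the block has at least two levels; weights are local to a
#'   source node, so the arrays are computed for the whole graph.
#' @return A list of arrays shaped like `hdag$counts`: `weight` and `cost`,
#'   `NA` where no edge exists.
#' @export
compute_weights <- function(hdag, block = NULL) {
  if (!is.null(block) && block$n_levels < 2L) {
    stop("edge weights are defined only for blocks with >=2 levels")
  }
  counts <- hdag$counts
  np <- dim(counts)[1]
  weight <- array(NA_real_, dim = dim(counts))
  if (np > 0L) {
    denom <- counts[, , 1L, drop = FALSE] + counts[, , 2L, drop = FALSE]
    denom <- array(rep(denom, 2L), dim = dim(counts))
    weight <- ifelse(counts > 0L, counts / denom, NA_real_)
  }
  list(weight = weight, cost = -log(weight))
}

#' Minimum negative log-likelihood path through one block
#'
#' The likelihood of a start-to-end path through a block is the product of
#' its edge weights; phasing the block means finding the path minimizing the
#' negative log-likelihood, i.e. the sum of edge costs. Dummy start/end nodes
#' connect to both siblings of the boundary levels with zero-cost edges, so
#' the optimization is unconstrained at the block ends. Because edges only
#' join adjacent levels the graph is already topologically sorted by level,
#' and a single forward dynamic-programming sweep with backtracking finds the
#' optimum in time linear in the number of nodes plus edges. Ties are broken
#' deterministically toward the lower sibling index. Haplotype 1 reads the
#' alleles of the path nodes; haplotype 2 takes the sibling allele at every
#' level.
#'
#' @param hdag An `hdag` object.
#' @param block One row of [partition_blocks()] (a multi-level block).
#' @param weights Optional result of [compute_weights()]; computed if absent.
#' @return An object of class `phased_block`: list with `first_level`,
#'   `last_level`, `levels`, `pos`, `path_sib` (1/2 per level), `hap1`,
#'   `hap2` (allele strings), `hap1_index` (0/1 per level), `path_cost` and
#'   `span_bp`.
#' @export
min_weight_path <- function(hdag, block, weights = NULL) {
  f <- block$first_level; l <- block$last_level
  if (l <= f) stop("min_weight_path needs a block with >=2 levels")
  if (is.null(weights)) weights <- compute_weights(hdag)
  cost <- weights$cost

  nlev <- l - f + 1L
  dist <- matrix(Inf, nrow = nlev, ncol = 2L)
  pred <- matrix(NA_integer_, nrow = nlev, ncol = 2L)
  dist[1L, ] <- 0            # zero-cost edges from the start dummy
  for (d in f:(l - 1L)) {
    r <- d - f + 1L
    for (j in 1:2) {
      best <- Inf; arg <- NA_integer_
      for (i in 1:2) {
        if (hdag$counts[d, i, j] > 0L && is.finite(dist[r, i])) {
          cand <- dist[r, i] + cost[d, i, j]
          if (cand < best - 1e-12) { best <- cand; arg <- i }
        }
      }
      dist[r + 1L, j] <- best
      pred[r + 1L, j] <- arg
    }
  }
  endcost <- dist[nlev, ]            # zero-cost edges into the end dummy
  if (!any(is.finite(endcost))) {
    stop("no complete path through block [", f, ", ", l,
         "]: a level has zero incoming edges from the reachable set")
  }
  jend <- if (endcost[1L] <= endcost[2L] + 1e-12) 1L else 2L
  path <- integer(nlev)
  path[nlev] <- jend
  for (r in nlev:2L) path[r - 1L] <- pred[r, path[r]]

  v <- hdag$variants
  lv <- f:l
  hap1 <- ifelse(path == 1L, v$ref[lv], v$alt[lv])
  hap2 <- ifelse(path == 1L, v$alt[lv], v$ref[lv])
  structure(list(
    chrom = hdag$chrom,
    first_level = f, last_level = l, levels = lv,
    pos = v$pos[lv],
    path_sib = path,
    hap1 = hap1, hap2 = hap2,
    hap1_index = path - 1L,
    path_cost = endcost[jend],
    span_bp = v$pos[l] - v$pos[f] + 1L,
    singleton = FALSE
  ), class = "phased_block")
}

#' Phase all blocks of a chromosome
#'
#' Partitions the H-DAG into blocks, optimizes every multi-level block with
#' [min_weight_path()], and passes singleton levels through as unphased
#' single-variant blocks. Blocks are returned in genomic order.
#'
#' @param hdag An `hdag` object with edges constructed.
#' @return A list of `phased_block` objects (class `phased_blocks`);
#'   singleton entries have `singleton = TRUE` and carry no haplotype
#'   assignment.
#' @export
phase_chromosome <- function(hdag) {
  blocks <- partition_blocks(hdag)
  weights <- compute_weights(hdag)
  res <- vector("list", nrow(blocks))
  v <- hdag$variants
  for (b in seq_len(nrow(blocks))) {
    if (blocks$n_levels[b] == 1L) {
      f <- blocks$first_level[b]
      res[[b]] <- structure(list(
        chrom = hdag$chrom,
        first_level = f, last_level = f, levels = f,
        pos = v$pos[f],
        path_sib = NA_integer_,
        hap1 = NA_character_, hap2 = NA_character_,
        hap1_index = NA_integer_,
        path_cost = NA_real_,
        span_bp = 1L,
        singleton = TRUE
      ), class = "phased_block")
    } else {
      res[[b]] <- min_weight_path(hdag, blocks[b, ], weights)
    }
  }
  structure(res, class = "phased_blocks",
            reachability_cuts = attr(blocks, "reachability_cuts"))
}

#' @export
print.phased_blocks <- function(x, ...) {
  multi <- vapply(x, function(b) !b$singleton, logical(1))
  cat("phased_blocks: ", length(x), " block(s), ", sum(multi),
      " phased, ", sum(!multi), " singleton(s)\n", sep = "")
  if (any(multi)) {
    sp <- vapply(x[multi], function(b) b$span_bp, numeric(1))
    cat("  span: total ", sum(sp), " bp, max ", max(sp), " bp, N50 ",
        n50(sp), " bp\n", sep = "")
  }
  invisible(x)
}
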