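#' Build the skeleton haplotype DAG for one chromosome
#'
#' Each heterozygous variant becomes one level holding a sibling pair of
#' nodes. Sibling 1 carries the REF allele and sibling 2 the ALT allele; the
#' phasing result is invariant to this assignment, and a deterministic rule
#' makes runs reproducible. The skeleton has no edges; conceptual dummy cap
#' nodes at both ends enter only during path optimization, with zero-cost
#' edges to both boundary siblings.
#'
#' @param variants Data frame of heterozygous variants for one chromosome
#'   (one element of [read_het_variants()]).
#' @return An object of class `hdag` holding the level table, an edge-counter
#'   array `counts[d, i, j]` for the edge from sibling `i` at level `d` to
#'   sibling `j` at level `d + 1` (0 = edge absent), a parallel `induced`
#'   flag array, and an `observed[level, sibling]` matrix recording which
#'   nodes were covered by continuous read evidence.
#' @export
build_skeleton <- function(variants) {
  if (!is.data.frame(variants) || nrow(variants) == 0L) {
    stop("cannot build an H-DAG from an empty variant list")
  }
  if (any(diff(variants$pos) <= 0L)) {
    stop("variant positions must be strictly increasing")
  }
  L <- nrow(variants)
  np <- max(L - 1L, 0L)
  structure(list(
    chrom = variants$chrom[1],
    variants = variants,
    L = L,
    counts = array(0L, dim = c(np, 2L, 2L)),
    induced = array(FALSE, dim = c(np, 2L, 2L)),
    observed = matrix(FALSE, nrow = L, ncol = 2L),
    unreachable_spans = 0L
  ), class = "hdag")
}

#' @export
print.hdag <- function(x, ...) {
  ne <- sum(x$counts > 0L)
  cat("hdag: ", x$chrom, ", ", x$L, " level(s), ", ne, " edge(s) (",
      sum(x$induced & x$counts > 0L), " induced)\n", sep = "")
  invisible(x)
}

#' Classify a fragment as continuous or discontinuous
#'
#' A fragment is continuous when its observed levels form one consecutive
#' run, and discontinuous otherwise. For discontinuous fragments the maximal
#' consecutive sub-runs are reported along with the gap spans they delimit:
#' each gap span's source node is the last observed node before the gap and
#' its target node the first observed node after it.
#'
#' @param fragment Data frame with columns `level` and `allele` (0/1), levels
#'   strictly increasing — e.g. one fragment's rows of [extract_fragments()].
#' @return A list with `type` ("continuous" or "discontinuous"), `runs` (list
#'   of integer vectors of consecutive levels) and `gaps` (data frame with
#'   `source_level`, `source_sib`, `target_level`, `target_sib`; sibling
#'   indices are 1 = REF, 2 = ALT).
#' @export
classify_fragment <- function(fragment) {
  stopifnot(all(c("level", "allele") %in% names(fragment)))
  lv <- fragment$level
  if (length(lv) < 2L) stop("a fragment needs >=2 observations to classify")
  if (any(diff(lv) <= 0L)) stop("fragment levels must be strictly increasing")
  sib <- fragment$allele + 1L
  run_id <- cumsum(c(1L, diff(lv) != 1L))
  runs <- split(lv, run_id)
  names(runs) <- NULL
  n_runs <- length(runs)
  if (n_runs == 1L) {
    return(list(type = "continuous", runs = runs,
                gaps = empty_gap_spans()))
  }
  last_idx <- cumsum(lengths(runs))
  first_idx <- c(1L, head(last_idx, -1L) + 1L)
  gaps <- data.frame(
    source_level = lv[last_idx[-n_runs]],
    source_sib = sib[last_idx[-n_runs]],
    target_level = lv[first_idx[-1L]],
    target_sib = sib[first_idx[-1L]])
  list(type = "discontinuous", runs = runs, gaps = gaps)
}

empty_gap_spans <- function() {
  data.frame(source_level = integer(), source_sib = integer(),
             target_level = integer(), target_sib = integer())
}

#' Add continuous-fragment evidence to the H-DAG
#'
#' For every adjacent level pair covered by a consecutive run of the
#' fragment, the directed edge from the observed node at the lower level to
#' the observed node at the next level is created if absent (counter starts
#' at 1) and its counter is incremented by 1 for the spanning fragment. Both
#' incident nodes are marked as carrying an observed allele. Accumulated over
#' a fragment set this yields the 2-, 3- or 4-edge in-phase/out-of-phase/
#' ambiguous configurations between adjacent levels.
#'
#' @param hdag An `hdag` object.
#' @param fragment Data frame with `level` and `allele` columns; all maximal
#'   consecutive runs of length >= 2 contribute, so a discontinuous
#'   fragment's sub-runs are handled too (its gaps are ignored here — see
#'   [induce_edges()]).
#' @return The updated `hdag`.
#' @export
add_continuous_evidence <- function(hdag, fragment) {
  lv <- fragment$level
  sib <- fragment$allele + 1L
  if (any(lv < 1L | lv > hdag$L)) {
    stop("fragment level outside the H-DAG level range")
  }
  consec <- which(diff(lv) == 1L)
  if (!length(consec)) return(hdag)
  idx <- cbind(lv[consec], sib[consec], sib[consec + 1L])
  hdag$counts[idx] <- hdag$counts[idx] + 1L + (hdag$counts[idx] == 0L)
  hdag$observed[cbind(lv[consec], sib[consec])] <- TRUE
  hdag$observed[cbind(lv[consec] + 1L, sib[consec + 1L])] <- TRUE
  hdag
}

# Canonical processing order for gap spans: target level ascending, ties by
# source level descending; residual ties by sibling indices for determinism.
order_spans <- function(spans) {
  spans[order(spans$target_level, -spans$source_level,
              spans$source_sib, spans$target_sib), , drop = FALSE]
}

#' Single-level look-ahead edge induction at one parent node
#'
#' The look-ahead step of the discontinuity traversal. Given a parent node at
#' level `d` on the way from a gap's source node toward its target node at
#' level `m`, induces new directed edges to potential children at level
#' `d + 1`: if the parent's sibling has an observed allele and pre-existing
#' edges to both children (full phase ambiguity), the parent gets edges to
#' both children; otherwise the parent gets an edge to each child that has no
#' pre-existing parent edge and, when `d + 1 == m`, is not the sibling of the
#' target node. Pre-existing edges are never duplicated and counters never
#' change: induced edges are created with counter 1, the floor value that
#' gives them minimal (0.5/0.5) weight downstream.
#'
#' @param hdag An `hdag` object.
#' @param parent_level,parent_sib Parent node (level and sibling index 1/2).
#' @param target_level,target_sib Target node of the gap span being bridged.
#' @param snapshot Optional logical array (shaped like `counts`) of the edge
#'   framework against which the branch conditions are evaluated. Defaults to
#'   the continuous-evidence edges (`counts > 0 & !induced`): the conditions
#'   distinguish read-backed evidence from structural induced edges, which
#'   keeps induction idempotent and order-independent while induced edges
#'   still take part in traversal and are never duplicated.
#' @return A list with the updated `hdag` and `children`, the sibling indices
#'   at `parent_level + 1` the parent now connects to (its live out-edges).
#' @export
get_potential_children <- function(hdag, parent_level, parent_sib,
                                   target_level, target_sib,
                                   snapshot = NULL) {
  d <- parent_level
  stopifnot(d >= 1L, d < target_level, target_level <= hdag$L)
  if (is.null(snapshot)) snapshot <- hdag$counts > 0L & !hdag$induced
  sib <- 3L - parent_sib

  branch_a <- hdag$observed[d, sib] &&
    snapshot[d, sib, 1L] && snapshot[d, sib, 2L]
  if (branch_a) {
    targets <- c(1L, 2L)
  } else {
    no_parent <- !(snapshot[d, 1L, ] | snapshot[d, 2L, ])
    targets <- which(no_parent)
    if (d + 1L == target_level) {
      targets <- targets[targets != (3L - target_sib)]
    }
  }
  for (ch in targets) {
    if (hdag$counts[d, parent_sib, ch] == 0L) {
      hdag$counts[d, parent_sib, ch] <- 1L
      hdag$induced[d, parent_sib, ch] <- TRUE
    }
  }
  list(hdag = hdag,
       children = which(hdag$counts[d, parent_sib, ] > 0L))
}

#' Induce directed edges across discontinuities
#'
#' Processes the gap spans of discontinuous fragments in canonical order
#' (target level ascending, ties by source level descending) and bridges each
#' with a look-ahead pre-order depth-first traversal: starting at the span's
#' source node, [get_potential_children()] runs at each visited parent, then
#' each child is visited in turn as a parent until the target level is
#' reached (nodes at the target level are never expanded). Edges induced for
#' one span immediately join the edge framework — later traversals follow
#' them and never duplicate them — while the branch conditions of
#' [get_potential_children()] keep referring to the read-evidence edges, so
#' induction is idempotent and independent of fragment input order. Spans
#' whose traversal cannot reach the target node are counted in
#' `unreachable_spans` on the returned object.
#'
#' @param hdag An `hdag` object with continuous evidence already added.
#' @param spans Data frame of gap spans (`source_level`, `source_sib`,
#'   `target_level`, `target_sib`), e.g. pooled from [classify_fragment()].
#'   Each span must satisfy `target_level - source_level > 1`.
#' @return The updated `hdag`.
#' @export
induce_edges <- function(hdag, spans) {
  if (is.null(spans) || nrow(spans) == 0L) return(hdag)
  if (any(spans$target_level - spans$source_level <= 1L)) {
    stop("gap spans must skip at least one level")
  }
  spans <- order_spans(spans)
  # branch conditions are judged against the read-evidence framework, which
  # induction never changes; compute it once
  snapshot <- hdag$counts > 0L & !hdag$induced
  for (s in seq_len(nrow(spans))) {
    hdag <- bridge_span(hdag, snapshot,
                        spans$source_level[s], spans$source_sib[s],
                        spans$target_level[s], spans$target_sib[s])
  }
  hdag
}

# Depth-first bridge of one gap span.
bridge_span <- function(hdag, snapshot, src_level, src_sib, tgt_level,
                        tgt_sib) {
  visited <- matrix(FALSE, nrow = hdag$L, ncol = 2L)
  stack <- list(c(src_level, src_sib))
  visited[src_level, src_sib] <- TRUE
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    d <- node[1]; i <- node[2]
    if (d == tgt_level) next                    # target level never expanded
    res <- get_potential_children(hdag, d, i, tgt_level, tgt_sib, snapshot)
    hdag <- res$hdag
    # pre-order: push in reverse so sibling 1 is visited before sibling 2
    for (ch in rev(res$children)) {
      if (!visited[d + 1L, ch]) {
        visited[d + 1L, ch] <- TRUE
        stack[[length(stack) + 1L]] <- c(d + 1L, ch)
      }
    }
  }
  if (!visited[tgt_level, tgt_sib]) {
    hdag$unreachable_spans <- hdag$unreachable_spans + 1L
  }
  hdag
}

#' Construct the full H-DAG from variants and fragments
#'
#' Convenience wrapper running the whole graph construction: skeleton, one
#' pass of continuous evidence over every fragment (including the consecutive
#' sub-runs of discontinuous fragments), then edge induction over all pooled
#' gap spans in canonical order.
#'
#' @param variants Data frame of heterozygous variants for one chromosome.
#' @param fragments A `haplo_fragments` data frame (see
#'   [extract_fragments()] / [fragments_from_observations()]).
#' @return An `hdag` object.
#' @export
build_hdag <- function(variants, fragments) {
  hdag <- build_skeleton(variants)
  if (is.null(fragments) || nrow(fragments) == 0L) return(hdag)

  lv_all <- fragments$level
  sib_all <- fragments$allele + 1L
  frag <- fragments$frag
  n <- nrow(fragments)
  starts <- c(1L, which(frag[-1L] != frag[-n]) + 1L)
  ends <- c(starts[-1L] - 1L, n)

  counts <- hdag$counts
  observed <- hdag$observed
  gap_list <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    ii <- starts[k]:ends[k]
    lv <- lv_all[ii]; sib <- sib_all[ii]
    consec <- which(diff(lv) == 1L)
    if (length(consec)) {
      idx <- cbind(lv[consec], sib[consec], sib[consec + 1L])
      counts[idx] <- counts[idx] + 1L + (counts[idx] == 0L)
      observed[cbind(lv[consec], sib[consec])] <- TRUE
      observed[cbind(lv[consec] + 1L, sib[consec + 1L])] <- TRUE
    }
    gap <- which(diff(lv) > 1L)
    if (length(gap)) {
      gap_list[[k]] <- data.frame(
        source_level = lv[gap], source_sib = sib[gap],
        target_level = lv[gap + 1L], target_sib = sib[gap + 1L])
    }
  }
  hdag$counts <- counts
  hdag$observed <- observed
  spans <- do.call(rbind, gap_list[!vapply(gap_list, is.null, logical(1))])
  induce_edges(hdag, spans)
}

#' Partition the H-DAG into phase blocks
#'
#' Splits the level range at every adjacent level pair with zero edges.
#' Levels left with no edge on either side become singleton blocks that are
#' reported but not path-optimized. Multi-level blocks are additionally
#' refined by start-to-end reachability: in rare conflicting-coverage
#' configurations a block can have at least one edge per adjacent pair yet no
#' complete path through it, and such blocks are cut where the forward
#' reachable node set empties (the number of such cuts is recorded in
#' `attr(x, "reachability_cuts")`).
#'
#' @param hdag An `hdag` object with edge construction complete.
#' @return Data frame with columns `block`, `first_level`, `last_level`,
#'   `n_levels`, in genomic order.
#' @export
partition_blocks <- function(hdag) {
  L <- hdag$L
  cuts <- 0L
  if (L == 1L) {
    res <- data.frame(block = 1L, first_level = 1L, last_level = 1L,
                      n_levels = 1L)
    attr(res, "reachability_cuts") <- cuts
    return(res)
  }
  has_edge <- apply(hdag$counts > 0L, 1L, any)
  first <- integer(); last <- integer()
  cur <- 1L
  for (d in seq_len(L - 1L)) {
    if (!has_edge[d]) {
      first <- c(first, cur); last <- c(last, d)
      cur <- d + 1L
    }
  }
  first <- c(first, cur); last <- c(last, L)

  # reachability refinement
  rf <- integer(); rl <- integer()
  for (b in seq_along(first)) {
    f <- first[b]; l <- last[b]
    if (l == f) { rf <- c(rf, f); rl <- c(rl, l); next }
    start <- f
    reach <- c(TRUE, TRUE)
    for (d in f:(l - 1L)) {
      nxt <- c(
        (reach[1L] && hdag$counts[d, 1L, 1L] > 0L) ||
          (reach[2L] && hdag$counts[d, 2L, 1L] > 0L),
        (reach[1L] && hdag$counts[d, 1L, 2L] > 0L) ||
          (reach[2L] && hdag$counts[d, 2L, 2L] > 0L))
      if (!any(nxt)) {
        rf <- c(rf, start); rl <- c(rl, d)
        start <- d + 1L
        reach <- c(TRUE, TRUE)
        cuts <- cuts + 1L
      } else {
        reach <- nxt
      }
    }
    rf <- c(rf, start); rl <- c(rl, l)
  }
  res <- data.frame(block = seq_along(rf), first_level = rf, last_level = rl,
                    n_levels = rl - rf + 1L)
  attr(res, "reachability_cuts") <- cuts
  res
}

#' Export the H-DAG as a DOT graph description
#'
#' Debug aid: renders levels, sibling alleles and counted edges (induced
#' edges dashed) in Graphviz DOT format for visual inspection.
#'
#' @param hdag An `hdag` object.
#' @param file Optional path; when given the DOT text is written there.
#' @return The DOT lines, invisibly when `file` is given.
#' @export
hdag_to_dot <- function(hdag, file = NULL) {
  v <- hdag$variants
  lines <- c("digraph hdag {", "  rankdir=LR;")
  for (l in seq_len(hdag$L)) {
    for (i in 1:2) {
      al <- if (i == 1L) v$ref[l] else v$alt[l]
      lines <- c(lines, sprintf(
        "  n%d_%d [label=\"L%d.%d:%s\"];", l, i, l, i, al))
    }
  }
  if (hdag$L > 1L) {
    for (d in seq_len(hdag$L - 1L)) for (i in 1:2) for (j in 1:2) {
      if (hdag$counts[d, i, j] > 0L) {
        style <- if (hdag$induced[d, i, j]) ", style=dashed" else ""
        lines <- c(lines, sprintf(
          "  n%d_%d -> n%d_%d [label=\"%d\"%s];",
          d, i, d + 1L, j, hdag$counts[d, i, j], style))
      }
    }
  }
  lines <- c(lines, "}")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
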