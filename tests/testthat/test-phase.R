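test_that("edge weights are counter fractions over the source node", {
  # single outgoing edge -> weight exactly 1, cost exactly 0
  h <- hdag_with_counts(2, array(c(5L, 0L, 0L, 0L), c(1, 2, 2)))
  w <- compute_weights(h)
  expect_identical(w$weight[1, 1, 1], 1)
  expect_identical(w$cost[1, 1, 1], 0)

  # two induced edges at initial counter value -> exactly 0.5 each
  h <- build_skeleton(toy_variants(3))
  h <- add_continuous_evidence(h, data.frame(level = 2:3, allele = c(0L, 0L)))
  h <- induce_edges(h, data.frame(source_level = 1L, source_sib = 1L,
                                  target_level = 3L, target_sib = 1L))
  w <- compute_weights(h)
  induced_from_source <- which(h$induced[1, 1, ])
  expect_gte(length(induced_from_source), 1L)
  expect_true(all(w$weight[1, 1, induced_from_source] == 0.5))

  # counters 3 and 1 -> weights 0.75 / 0.25
  h <- hdag_with_counts(2, array(c(3L, 0L, 1L, 0L), c(1, 2, 2)))
  w <- compute_weights(h)
  expect_equal(w$weight[1, 1, 1], 0.75)
  expect_equal(w$weight[1, 1, 2], 0.25)
})

test_that("outgoing weights from every source sum to one", {
  set.seed(11)
  for (rep in 1:25) {
    h <- random_block_hdag(sample(3:8, 1))
    w <- compute_weights(h)
    for (d in seq_len(h$L - 1)) for (i in 1:2) {
      out <- w$weight[d, i, ][h$counts[d, i, ] > 0]
      if (length(out)) expect_equal(sum(out), 1, tolerance = 1e-12)
    }
  }
})

test_that("a block of unambiguous straight edges phases at zero cost", {
  h <- build_skeleton(toy_variants(4))
  for (f in 1:2) {
    al <- if (f == 1) 0L else 1L
    h <- add_continuous_evidence(h, data.frame(level = 1:4, allele = al))
  }
  b <- partition_blocks(h)
  p <- min_weight_path(h, b[1, ])
  expect_equal(p$path_cost, 0)
  expect_equal(p$path_sib, rep(1L, 4))           # lower sibling tie-break
  expect_equal(p$hap1, h$variants$ref)
  expect_equal(p$hap2, h$variants$alt)
})

test_that("the straight path wins over the crossing path at 3:1 counters", {
  counts <- array(0L, c(1, 2, 2))
  counts[1, 1, ] <- c(3L, 1L)
  counts[1, 2, ] <- c(1L, 3L)
  h <- hdag_with_counts(2, counts)
  p <- min_weight_path(h, data.frame(first_level = 1L, last_level = 2L,
                                     n_levels = 2L))
  expect_equal(p$path_sib, c(1L, 1L))
  expect_equal(p$path_cost, -log(0.75), tolerance = 1e-12)
  # hand-enumerated: straight 0.75, crossing 0.25 from either start
  bf <- brute_force_paths(h, 1L, 2L)
  expect_equal(min(bf$cost), p$path_cost, tolerance = 1e-12)
})

test_that("backtracking equals exhaustive path enumeration on random blocks", {
  set.seed(202)
  for (rep in 1:60) {
    L <- sample(2:8, 1)
    h <- random_block_hdag(L)
    bf <- brute_force_paths(h, 1L, L)
    p <- min_weight_path(h, data.frame(first_level = 1L, last_level = L,
                                       n_levels = L))
    best <- min(bf$cost)
    expect_equal(p$path_cost, best, tolerance = 1e-9)
    if (sum(bf$cost < best + 1e-9) == 1L) {
      opt <- unlist(bf[which.min(bf$cost), seq_len(L)])
      expect_equal(p$path_sib, unname(as.integer(opt)))
    }
  }
})

test_that("reinforcing the optimal path never changes it; competitors switch at the threshold", {
  counts <- array(0L, c(1, 2, 2))
  counts[1, 1, ] <- c(4L, 2L)
  h <- hdag_with_counts(2, counts)
  p0 <- min_weight_path(h, data.frame(first_level = 1L, last_level = 2L,
                                      n_levels = 2L))
  expect_equal(p0$path_sib[2], 1L)
  # reinforce the on-path edge: path unchanged
  h$counts[1, 1, 1] <- 40L
  p1 <- min_weight_path(h, data.frame(first_level = 1L, last_level = 2L,
                                      n_levels = 2L))
  expect_equal(p1$path_sib, p0$path_sib)
  # raise the competitor past the on-path counter: path flips
  h$counts[1, 1, 2] <- 41L
  p2 <- min_weight_path(h, data.frame(first_level = 1L, last_level = 2L,
                                      n_levels = 2L))
  expect_equal(p2$path_sib[2], 2L)
})

test_that("phasing is invariant to the skeleton sibling assignment", {
  set.seed(7)
  for (rep in 1:10) {
    L <- sample(3:6, 1)
    h <- random_block_hdag(L)
    p <- min_weight_path(h, data.frame(first_level = 1L, last_level = L,
                                       n_levels = L))
    # flip the sibling order at one level and rewire incident edges
    fl <- sample.int(L, 1)
    h2 <- h
    h2$variants$ref[fl] <- h$variants$alt[fl]
    h2$variants$alt[fl] <- h$variants$ref[fl]
    if (fl > 1) h2$counts[fl - 1, , ] <- h$counts[fl - 1, , 2:1]
    if (fl < L) h2$counts[fl, , ] <- h$counts[fl, 2:1, ]
    h2$observed[fl, ] <- h$observed[fl, 2:1]
    p2 <- min_weight_path(h2, data.frame(first_level = 1L, last_level = L,
                                         n_levels = L))
    # same haplotype pair regardless of labeling
    expect_true(setequal(
      list(paste(p$hap1, collapse = ""), paste(p$hap2, collapse = "")),
      list(paste(p2$hap1, collapse = ""), paste(p2$hap2, collapse = ""))))
    expect_equal(p2$path_cost, p$path_cost, tolerance = 1e-9)
  }
})

test_that("haplotype 2 is the complement of haplotype 1 at every level", {
  set.seed(31)
  for (rep in 1:10) {
    L <- sample(2:7, 1)
    h <- random_block_hdag(L)
    p <- min_weight_path(h, data.frame(first_level = 1L, last_level = L,
                                       n_levels = L))
    for (t in seq_len(L)) {
      expect_true(setequal(c(p$hap1[t], p$hap2[t]),
                           c(h$variants$ref[t], h$variants$alt[t])))
    }
  }
})

test_that("phase_chromosome phases blocks independently and keeps singletons", {
  v <- toy_variants(10)
  h <- build_skeleton(v)
  for (d in c(1:4, 6:9)) h$counts[d, 1, 1] <- 2L  # cut between 5 and 6
  ph <- phase_chromosome(h)
  expect_equal(length(ph), 2L)
  expect_false(any(vapply(ph, function(b) b$singleton, logical(1))))
  expect_equal(ph[[1]]$levels, 1:5)
  expect_equal(ph[[2]]$levels, 6:10)

  h$counts[] <- 0L
  ph <- phase_chromosome(h)
  expect_equal(length(ph), 10L)
  expect_true(all(vapply(ph, function(b) b$singleton, logical(1))))
})
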