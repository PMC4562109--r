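# helper: VariantGraph built directly from an adjacency matrix, with fake
# single-position variants so tie-breaking is well-defined
graph_from_adj <- function(adj, supports = NULL) {
  n <- nrow(adj)
  nodes <- sprintf("SNV:%d:A:C", seq_len(n) * 10L)
  pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(a = nodes[pairs[, 1L]], b = nodes[pairs[, 2L]],
                      support = if (is.null(supports)) rep(1L, nrow(pairs))
                                else supports,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 pool = list(entries = NULL, amp_totals = NULL)),
            class = "VariantGraph")
}

test_that("co-occurrence graph has an edge iff a pooled fragment carries both", {
  v <- sprintf("SNV:%d:A:C", c(10L, 20L, 30L, 40L))
  full <- list(c(0L, 50L))
  frags <- c(list(make_fragment("a", full, v[1:2]),
                  make_fragment("b", full, v[2:3]),
                  make_fragment("c", full, v[c(1, 3)])),
             replicate(3, make_fragment("d", full, v[4]), simplify = FALSE))
  g <- build_cooccurrence_graph(frags, v)
  expect_setequal(g$nodes, v)
  expect_equal(nrow(g$edges), 3L)   # 1-2, 2-3, 1-3; v4 never co-occurs
  expect_false(any(g$edges$a == v[4] | g$edges$b == v[4]))
  # complete graph from all-pairs pool
  frags2 <- lapply(utils::combn(4, 2, simplify = FALSE), function(pr)
    make_fragment(paste(pr, collapse = "_"), full, v[pr]))
  g2 <- build_cooccurrence_graph(frags2, v)
  expect_equal(nrow(g2$edges), 6L)
  # no multi-variant fragment -> edgeless
  g3 <- build_cooccurrence_graph(
    list(make_fragment("a", full, v[1])), v)
  expect_equal(nrow(g3$edges), 0L)
  # cap on selected variants
  many <- sprintf("SNV:%d:A:C", 1:21)
  expect_error(build_cooccurrence_graph(frags, many), "limited to 20")
})

test_that("maximum_clique is exact on random graphs (enumeration oracle)", {
  set.seed(515)
  for (i in 1:60) {
    n <- sample(2:12, 1)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < runif(1, 0.2, 0.8)
    adj <- adj | t(adj)
    g <- graph_from_adj(adj)
    got <- maximum_clique(g)
    expect_equal(length(got), oracle_max_clique_size(adj))
    # returned set really is a clique
    if (length(got) > 1L) {
      idx <- match(got, g$nodes)
      expect_true(all(adj[t(utils::combn(idx, 2L))]))
    }
    # determinism
    expect_identical(maximum_clique(g), got)
  }
  # 4-node graph missing one edge: the unique triangle avoiding it
  adj <- matrix(TRUE, 4, 4); diag(adj) <- FALSE
  adj[1, 2] <- adj[2, 1] <- FALSE
  g <- graph_from_adj(adj)
  expect_setequal(maximum_clique(g),
                  sprintf("SNV:%d:A:C", c(10L, 30L, 40L)))
  # ties: two disjoint triangles, equal support -> smallest position tuple
  adj <- matrix(FALSE, 6, 6)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    adj[pr[1], pr[2]] <- adj[pr[2], pr[1]] <- TRUE
  expect_equal(maximum_clique(graph_from_adj(adj)),
               sprintf("SNV:%d:A:C", c(10L, 20L, 30L)))
  # support tie-break dominates position order
  g <- graph_from_adj(adj, supports = c(1L, 1L, 1L, 5L, 5L, 5L))
  expect_equal(maximum_clique(g), sprintf("SNV:%d:A:C", c(40L, 50L, 60L)))
  expect_equal(maximum_clique(graph_from_adj(matrix(FALSE, 0, 0))),
               character(0))
})

test_that("scattered haplotypes are reconnected on the three-amplicon fixture", {
  fx <- scattered_fixture()
  cfg <- sim_config(reference = fx$reference, design = fx$design,
                    n_fragments = 7L, error_rate = 0, indel_error_rate = 0,
                    seed = 4L)
  sim <- simulate_mixture(fx$truth, cfg)
  frags <- sim_to_fragments(sim, paired = TRUE)
  expect_length(frags, 21L)   # 7 units x (A + B + C-pair merged)

  # default mode: only partial haplotypes, never the full clone
  t_def <- quantify_table(tabulate_haplotypes(frags, fx$variants), frags)
  expect_false(haplotype_id(fx$variants) %in% t_def$rows$id)
  # bare v2 cannot occur either: every fragment covering p2 also covers p1
  # (amplicon A) or p3 (amplicon B), and v2 carriers carry those too
  expect_setequal(
    t_def$rows$id,
    c(fx$variants[c(1, 3)], haplotype_id(fx$variants[c(1, 2)]),
      haplotype_id(fx$variants[c(2, 3)]), haplotype_id(fx$variants[c(1, 3)])))

  # inferred mode: exactly {1,2,3} x 1 unit and {1,3} x 2 units
  t_inf <- infer_scattered(frags, fx$variants, fx$design)
  expect_equal(nrow(t_inf$rows), 2L)
  expect_equal(t_inf$rows$hits[t_inf$rows$id == haplotype_id(fx$variants)],
               1L)
  expect_equal(
    t_inf$rows$hits[t_inf$rows$id == haplotype_id(fx$variants[c(1, 3)])], 2L)
  expect_true(all(t_inf$rows$inferred))
  expect_equal(t_inf$clone_units, 7L)
  q <- quantify_table(t_inf, frags)
  expect_equal(sort(round(q$rows$percentage, 1)), c(14.3, 28.6))
  expect_equal(round(q$wildtype_percentage, 1), 57.1)

  # the exhaustive mixture-enumeration oracle agrees and is unique
  sols <- oracle_mixtures(frags, fx$variants, fx$design, units = 7L)
  expect_length(sols, 1L)
  sol <- sols[[1L]][sols[[1L]] > 0]
  expect_equal(sol[[haplotype_id(fx$variants)]], 1L)
  expect_equal(sol[[haplotype_id(fx$variants[c(1, 3)])]], 2L)
  expect_equal(sol[["<wt>"]], 4L)
})

test_that("inference over a single whole-region amplicon is a no-op", {
  ref <- random_reference(120L, 51L)
  v <- c(snv_at(ref, 20L), snv_at(ref, 60L), snv_at(ref, 100L))
  design <- new_amplicon_design(data.frame(start = 0L, end = 120L,
                                           label = "all"))
  truth <- list(clone_truth(v, 0.3), clone_truth(v[1:2], 0.2),
                clone_truth(v[1], 0.1), clone_truth(character(0), 0.4))
  cfg <- sim_config(reference = ref, design = design, n_fragments = 50L,
                    error_rate = 0, indel_error_rate = 0, seed = 6L)
  frags <- sim_to_fragments(simulate_mixture(truth, cfg))
  t_def <- quantify_table(tabulate_haplotypes(frags, v), frags)
  t_inf <- quantify_table(infer_scattered(frags, v, design), frags)
  o1 <- order(t_def$rows$id); o2 <- order(t_inf$rows$id)
  expect_equal(t_def$rows$id[o1], t_inf$rows$id[o2])
  expect_equal(t_def$rows$hits[o1], t_inf$rows$hits[o2])
  expect_equal(t_def$rows$percentage[o1], t_inf$rows$percentage[o2])
  expect_equal(t_def$wildtype_percentage, t_inf$wildtype_percentage)
})

test_that("noise-free scattered mixtures with distinct clone cliques are recovered", {
  set.seed(2024)
  ref <- random_reference(300L, 77L)
  # overlapping tiling plus one gapped mate-pair amplicon (D) so that every
  # clone's variant pairs co-occur on at least one fragment type -- the
  # precondition for its variant set to form a clique at all
  design <- new_amplicon_design(data.frame(
    start = c(0L, 80L, 160L, 0L, 160L), end = c(140L, 220L, 300L, 80L, 300L),
    label = c("A", "B", "C", "D", "D")))
  for (trial in 1:5) {
    # clones on disjoint positions; each pair covered by A, B, C or D
    pos_pool <- list(c(20L, 100L, 200L), c(50L, 120L), c(90L, 180L),
                     c(230L, 280L), c(30L, 260L))
    n_clones <- sample(2:5, 1)
    picked <- sample(pos_pool, n_clones)
    vars <- lapply(picked, function(p) vapply(p, snv_at, "",
                                              reference = ref))
    units <- sample(2:6, n_clones, replace = TRUE)
    wt <- sample(2:5, 1)
    total <- sum(units) + wt
    truth <- c(lapply(seq_len(n_clones), function(i)
      clone_truth(vars[[i]], units[i] / total)),
      list(clone_truth(character(0), wt / total)))
    cfg <- sim_config(reference = ref, design = design,
                      n_fragments = total, error_rate = 0,
                      indel_error_rate = 0, seed = 100L + trial)
    frags <- sim_to_fragments(simulate_mixture(truth, cfg), paired = TRUE)
    t_inf <- infer_scattered(frags, unlist(vars), design)
    for (i in seq_len(n_clones)) {
      row <- t_inf$rows[t_inf$rows$id == haplotype_id(vars[[i]]), ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$hits, units[i])
    }
  }
})

test_that("inference caps and refusals hold", {
  ref <- random_reference(100L, 61L)
  design <- new_amplicon_design(data.frame(start = 0L, end = 100L,
                                           label = "a"))
  frags <- list(make_fragment("f", list(c(0L, 100L)), "SNV:10:A:C"))
  many <- sprintf("SNV:%d:A:C", 1:21)
  expect_error(infer_scattered(frags, many, design), "limited to 20")
  expect_error(infer_scattered(frags, "SNV:10:A:C", NULL),
               "amplicon design")
  # positional deduction never exceeds observed per-amplicon counts
  fx <- scattered_fixture()
  cfg <- sim_config(reference = fx$reference, design = fx$design,
                    n_fragments = 7L, error_rate = 0, indel_error_rate = 0,
                    seed = 4L)
  frags <- sim_to_fragments(simulate_mixture(fx$truth, cfg), paired = TRUE)
  t_inf <- infer_scattered(frags, fx$variants, fx$design)
  per_amp <- 7L   # 7 units, one fragment per amplicon
  expect_true(all(vapply(seq_along(fx$design$amplicons), function(a) {
    pos <- ampliclone:::amplicon_positions(fx$design$amplicons[[a]])
    contributed <- sum(vapply(seq_len(nrow(t_inf$rows)), function(i) {
      members <- haplotype_members(t_inf$rows$id[i])
      if (length(ampliclone:::restrict_to_amplicon(members, pos)))
        t_inf$rows$hits[i] else 0L
    }, 0L))
    contributed <= per_amp
  }, FALSE)))
})
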