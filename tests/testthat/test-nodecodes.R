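test_that("hand-simulated codes on a chain, a diamond and isolated roots", {
  # chain a -> b -> c
  lab <- assign_nodecodes(sb_dag(data.frame(parent = c("a", "b"),
                                            child = c("b", "c"))))
  expect_identical(lab$nc[["a"]], "0")
  expect_identical(lab$nc[["b"]], "0.0")
  expect_identical(lab$nc[["c"]], "0.0.0")

  # diamond r -> a, r -> b, a -> c, b -> c: two root paths into c
  lab2 <- assign_nodecodes(sb_dag(data.frame(
    parent = c("r", "r", "a", "b"), child = c("a", "b", "c", "c"))))
  expect_length(lab2$nc[["c"]], 2L)
  expect_length(lab2$nc[["r"]], 1L)

  # two isolated roots in lexicographic sibling order under the source
  lab3 <- assign_nodecodes(sb_dag(NULL, nodes = c("q", "p")))
  expect_identical(lab3$nc[["p"]], "0")
  expect_identical(lab3$nc[["q"]], "1")
})

test_that("cyclic input is rejected with a named cycle", {
  expect_error(sb_dag(data.frame(parent = c("a", "b"), child = c("b", "a"))),
               "cycle")
  expect_error(sb_dag(data.frame(parent = "a", child = "a")), "self-loop")
})

test_that("code components are delimiter-separated (safe past 10 children)", {
  n <- 12L
  edges <- data.frame(parent = "root",
                      child = sprintf("leaf%02d", seq_len(n)))
  lab <- assign_nodecodes(sb_dag(edges))
  # child 11 (0-based index 10) must not be a prefix-of/prefixed-by child 1
  expect_identical(lab$nc[["leaf11"]], "0.10")
  expect_identical(lab$nc[["leaf01"]], "0.0")
  expect_false(is_descendant(lab, "leaf01", "leaf11"))
  expect_setequal(descendants_labeled(lab, "root"), edges$child)
})

test_that("strict prefix semantics of is_descendant", {
  lab <- assign_nodecodes(sb_dag(data.frame(
    parent = c("a", "b", "b"), child = c("b", "c", "d"))))
  expect_true(is_descendant(lab, "a", "c"))
  expect_false(is_descendant(lab, "a", "a"))   # strict: never own descendant
  expect_false(is_descendant(lab, "c", "d"))   # siblings
  expect_error(is_descendant(lab, "a", "zzz"), "lookup error")
})

test_that("path-count law: |NC(v)| equals the brute-force root-path count", {
  for (seed in 1:12) {
    n <- 2L + (seed %% 11L)  # n in 2..12
    dag <- generate_random_dag(n, 0.35, seed = seed)
    lab <- assign_nodecodes(dag)
    expect_equal(lengths(lab$nc)[dag$nodes],
                 brute_force_path_counts(dag)[dag$nodes],
                 info = paste("seed", seed))
  }
})

test_that("tree specialization: one code per node, subtree-size descendants", {
  set.seed(3)
  n <- 200L
  nodes <- sprintf("t%03d", seq_len(n))
  parent <- vapply(2:n, function(j) nodes[sample.int(j - 1L, 1L)],
                   character(1))
  dag <- sb_dag(data.frame(parent = parent, child = nodes[2:n]))
  lab <- assign_nodecodes(dag)
  expect_true(all(lengths(lab$nc) == 1L))
  subtree_size <- function(t) length(descendants_iterative(dag, t)) + 1L
  for (t in sample(nodes, 10L)) {
    expect_equal(length(descendants_labeled(lab, t)), subtree_size(t) - 1L)
  }
})

test_that("labeled, iterative and closure methods agree on random DAGs", {
  for (seed in 1:10) {
    n <- sample(c(8L, 20L, 60L), 1L)
    dag <- generate_random_dag(n, 2 / n, seed = seed * 17L)
    lab <- assign_nodecodes(dag)
    closure <- closure_descendants(dag)
    for (t in dag$nodes) {
      dl <- as.character(descendants_labeled(lab, t))
      di <- as.character(descendants_iterative(dag, t))
      expect_identical(dl, di, info = paste("seed", seed, "t", t))
      expect_identical(dl, closure[[t]], info = paste("seed", seed, "t", t))
    }
  }
})

test_that("prefix soundness/completeness: reachability iff is_descendant", {
  dag <- generate_random_dag(40, 0.08, seed = 5)
  lab <- assign_nodecodes(dag)
  closure <- closure_descendants(dag)
  for (u in dag$nodes) {
    reach <- closure[[u]]
    for (v in sample(dag$nodes, 10L)) {
      if (u == v) next
      expect_identical(is_descendant(lab, u, v), v %in% reach,
                       info = paste(u, v))
    }
  }
})

test_that("ancestor queries match the reverse closure", {
  dag <- generate_random_dag(60, 0.06, seed = 9)
  lab <- assign_nodecodes(dag)
  for (t in sample(dag$nodes, 15L)) {
    expect_identical(as.character(ancestors_labeled(lab, t)),
                     as.character(ancestors_iterative(dag, t)), info = t)
  }
})

test_that("selectivity is the descendant fraction over real nodes", {
  chain <- sb_dag(data.frame(parent = c("a", "b", "c"),
                             child = c("b", "c", "d")))
  expect_equal(selectivity(chain, "a"), 0.75)
  expect_equal(selectivity(chain, "d"), 0)
  star <- sb_dag(data.frame(parent = "hub", child = sprintf("l%d", 1:9)))
  expect_equal(selectivity(star, "hub"), 0.9)
  expect_error(selectivity(sb_dag(NULL), "x"), "undefined")
})

test_that("benchmark asserts result equality and reports counters", {
  dag <- generate_random_dag(50, 0.08, seed = 42)
  tbl <- run_query_benchmark(dag, sample(dag$nodes, 5L), reps = 1L)
  expect_setequal(tbl$method, c("NodeCodes", "Iterative"))
  expect_equal(tbl$mean_traversed[tbl$method == "NodeCodes"], 0)
  # each returned node was visited by the traversal
  expect_true(tbl$mean_visited[tbl$method == "Iterative"] >=
                tbl$mean_result_size[tbl$method == "Iterative"])
  expect_equal(nrow(run_query_benchmark(dag, dag$nodes[1], reps = 0L)), 0L)
})

test_that("the explosion guard trips on dense DAGs", {
  # complete layered DAG with multiplying path counts
  layers <- split(sprintf("n%02d", 1:12), rep(1:4, each = 3))
  edges <- do.call(rbind, lapply(1:3, function(i)
    expand.grid(parent = layers[[i]], child = layers[[i + 1]],
                stringsAsFactors = FALSE)))
  expect_error(assign_nodecodes(sb_dag(edges), max_codes = 20),
               "explosion")
})

test_that("edge-list TSV round-trips through labeling export", {
  td <- withr::local_tempdir()
  writeLines(c("child\tparent", "b\ta", "c\tb", "a\t"),
             file.path(td, "dag.tsv"))
  dag <- read_dag_tsv(file.path(td, "dag.tsv"))
  expect_setequal(dag$nodes, c("a", "b", "c"))
  lab <- assign_nodecodes(dag)
  out <- file.path(td, "codes.tsv")
  write_labeling_tsv(lab, out)
  codes <- utils::read.delim(out, colClasses = "character")
  expect_equal(nrow(codes), 3L)
  expect_identical(codes$code[codes$node == "c"], "0.0.0")
})
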