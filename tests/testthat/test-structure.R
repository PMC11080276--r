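test_that("dag constructor enforces acyclicity and edge sanity", {
  expect_error(dag(c("a", "b"), data.frame(from = c("a", "b"),
                                           to = c("b", "a"))), "cyclic")
  expect_error(dag("a", data.frame(from = "a", to = "a")), "self-loop")
  expect_error(dag(c("a", "b"),
                   data.frame(from = c("a", "a"), to = c("b", "b"))),
               "duplicate")
  g <- dag(c("a", "b", "c"), data.frame(from = c("a", "b"),
                                        to = c("b", "c")))
  expect_identical(topo_sort(g), c("a", "b", "c"))
})

test_that("BIC score is decomposable and rewards a real dependency", {
  set.seed(51)
  d <- data.frame(A = sample(0:1, 1000, TRUE))
  d$B <- d$A                              # B deterministically equals A
  d$C <- sample(0:1, 1000, TRUE)
  g0 <- dag(c("A", "B", "C"))
  s0 <- bic_score(g0, d)
  expect_equal(s0$score, sum(s0$family_scores), tolerance = 1e-9)
  g1 <- dag(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  s1 <- bic_score(g1, d)
  expect_gt(s1$score, s0$score)
  # only the B family changed
  expect_equal(s1$family_scores[["A"]], s0$family_scores[["A"]])
  expect_equal(s1$family_scores[["C"]], s0$family_scores[["C"]])
  # empty-graph score equals the sum of marginal family scores computed
  # directly from the multinomial counts
  n <- nrow(d)
  marg <- function(x) {
    cnt <- table(x)
    sum(cnt * log(cnt / n)) - log(n) / 2 * (length(cnt) - 1)
  }
  expect_equal(s0$score, marg(d$A) + marg(d$B) + marg(d$C),
               tolerance = 1e-9)
})

test_that("legal moves enumerate the single-edge neighborhood", {
  g2 <- dag(c("a", "b"))
  mv <- legal_moves(g2)
  expect_identical(nrow(mv), 2L)
  expect_true(all(mv$type == "add"))

  g3 <- dag(c("a", "b", "c"))
  expect_identical(nrow(legal_moves(g3)), 6L)

  # the cycle-closing addition is excluded
  tri <- dag(c("a", "b", "c"), data.frame(from = c("a", "b"),
                                          to = c("b", "c")))
  mv3 <- legal_moves(tri)
  expect_false(any(mv3$type == "add" & mv3$from == "c" & mv3$to == "a"))
  expect_true(any(mv3$type == "add" & mv3$from == "a" & mv3$to == "c"))
  # deterministic ordering: types sorted, then source, then target
  expect_identical(mv3$type, sort(mv3$type))
})

test_that("constraints are validated and honored by the neighborhood", {
  expect_error(edge_constraints(whitelist = data.frame(from = "a", to = "b"),
                                blacklist = data.frame(from = "a", to = "b")),
               "overlap")
  expect_error(edge_constraints(whitelist = data.frame(
    from = c("a", "b"), to = c("b", "a"))), "cyclic")

  cs <- edge_constraints(whitelist = data.frame(from = "a", to = "b"),
                         blacklist = data.frame(from = "c", to = "a"))
  g <- dag(c("a", "b", "c"), data.frame(from = "a", to = "b"))
  mv <- legal_moves(g, cs)
  expect_false(any(mv$type == "delete" & mv$from == "a" & mv$to == "b"))
  expect_false(any(mv$type == "reverse" & mv$from == "a" & mv$to == "b"))
  expect_false(any(mv$type == "add" & mv$from == "c" & mv$to == "a"))

  dc <- default_constraints(c("age", "sex", "smoke", "T2DM"))
  expect_true(all(c("age", "sex") %in% dc$blacklist$to))
  expect_false("smoke" %in% dc$blacklist$to)
})

test_that("tabu search recovers small structures up to Markov equivalence", {
  d_chain <- generate_from_bn(chain_net(), 5000, seed = 52)
  got <- tabu_search(d_chain)
  expect_true(cpdag(got$dag) == cpdag(bn_dag(chain_net())))

  d_v <- generate_from_bn(vstruct_net(), 5000, seed = 53)
  got_v <- tabu_search(d_v)
  expect_true(cpdag(got_v$dag) == cpdag(bn_dag(vstruct_net())))
  # the v-structure itself is identifiable, so the arcs must match exactly
  e <- dag_edges(got_v$dag)
  expect_setequal(paste(e$from, e$to), c("A C", "B C"))

  set.seed(54)
  d_ind <- data.frame(A = sample(0:1, 5000, TRUE),
                      B = sample(0:1, 5000, TRUE),
                      C = sample(0:1, 5000, TRUE))
  expect_identical(nrow(dag_edges(tabu_search(d_ind)$dag)), 0L)
})

test_that("tabu search attains the exhaustive BIC optimum on 3 nodes", {
  dags <- all_dags(c("A", "B", "C"))
  expect_length(dags, 25L)
  d <- generate_from_bn(chain_net(), 2000, seed = 55)
  best_exhaustive <- max(vapply(dags, function(g) bic_score(g, d)$score,
                                numeric(1)))
  got <- tabu_search(d)
  expect_equal(got$score, best_exhaustive, tolerance = 1e-9)
  # the reported score is consistent with an independent rescore
  expect_equal(got$score, bic_score(got$dag, d)$score, tolerance = 1e-9)
})

test_that("search respects constraints and improves on its start", {
  d <- generate_from_bn(strong8_net(), 2000, seed = 56)
  cs <- edge_constraints(blacklist = data.frame(from = "C", to = "D"))
  got <- tabu_search(d, constraints = cs)
  e <- dag_edges(got$dag)
  expect_false(any(e$from == "C" & e$to == "D"))
  expect_false(is.null(topo_sort(got$dag)))
  empty_score <- bic_score(dag(names(d)), d)$score
  expect_gte(got$score, empty_score)

  wl <- edge_constraints(whitelist = data.frame(from = "A", to = "H"))
  got_wl <- tabu_search(d, constraints = wl,
                        params = search_params(max_iter = 40))
  ewl <- dag_edges(got_wl$dag)
  expect_true(any(ewl$from == "A" & ewl$to == "H"))
})

test_that("stratified split has exact floor sizes and partitions rows", {
  coh <- generate_case_control(reference_profiles(), seed = 57)
  sub <- coh[coh$group %in% c("control", "T2DM"), ]
  sp <- train_test_split(sub, 0.7, seed = 58)
  expect_identical(sum(sp$train$group == "control"), 822L)
  expect_identical(sum(sp$train$group == "T2DM"), 814L)
  expect_identical(sum(sp$test$group == "control"), 353L)
  expect_identical(sum(sp$test$group == "T2DM"), 349L)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(sub))
  # disjoint and exhaustive by row identity
  key <- function(d) do.call(paste, c(d, sep = "\r"))
  expect_identical(sort(c(rownames(sp$train), rownames(sp$test))),
                   sort(rownames(sub)))
  sp2 <- train_test_split(sub, 0.7, seed = 58)
  expect_identical(sp$train, sp2$train)
  expect_error(train_test_split(data.frame(group = "only"), 0.7, 1),
               "fewer than 2")
})

test_that("CPDAGs identify Markov equivalence classes exactly", {
  # chains collapse to an undirected skeleton, v-structures stay directed
  ch <- cpdag(dag(c("A", "B", "C"),
                  data.frame(from = c("A", "B"), to = c("B", "C"))))
  expect_identical(nrow(ch$directed), 0L)
  expect_identical(nrow(ch$undirected), 2L)
  vs <- cpdag(dag(c("A", "B", "C"),
                  data.frame(from = c("A", "B"), to = c("C", "C"))))
  expect_identical(nrow(vs$directed), 2L)
  expect_identical(nrow(vs$undirected), 0L)

  # exhaustive: on 3 nodes, two DAGs share a CPDAG iff they share skeleton
  # and v-structure set (the classical characterization as oracle)
  sig <- function(g) {
    e <- dag_edges(g)
    skel <- sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
    vstr <- character()
    for (nd in g$nodes) {
      pa <- g$parents[[nd]]
      if (length(pa) == 2L &&
          !(pa[1] %in% g$parents[[pa[2]]]) &&
          !(pa[2] %in% g$parents[[pa[1]]]))
        vstr <- c(vstr, paste(sort(pa)[1], nd, sort(pa)[2]))
    }
    paste(c(skel, "|", sort(vstr)), collapse = ";")
  }
  dags <- all_dags(c("A", "B", "C"))
  sigs <- vapply(dags, sig, character(1))
  keys <- vapply(dags, function(g) cpdag(g)$key, character(1))
  for (s in unique(sigs))
    expect_length(unique(keys[sigs == s]), 1L)
  expect_identical(length(unique(keys)), length(unique(sigs)))

  # the strong 8-node truth is fully compelled
  cp8 <- cpdag(bn_dag(strong8_net()))
  expect_identical(nrow(cp8$undirected), 0L)
  expect_identical(nrow(cp8$directed), 7L)
})
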