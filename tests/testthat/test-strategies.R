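# helper: state with a prescribed partition, built by replaying merges
state_with_partition <- function(g, groups) {
  st <- init_singletons(g)
  for (grp in groups) {
    idx <- match(as.character(grp), g$nodes)
    for (k in seq_along(idx)[-1]) {
      apply_merge(st, st$memb[idx[1]], st$memb[idx[k]])
    }
  }
  st
}

test_that("node selection honours each strategy's candidate rule", {
  jt <- joined_triangles()

  # all singletons: nothing eligible under any strategy
  st <- init_singletons(jt)
  for (s in c("random", "weak", "low_embeddedness", "non_triad")) {
    expect_null(select_node(st, s))
  }

  # one six-node community: every node has k_int >= 2 > k_ext, so no weak node
  st6 <- state_with_partition(jt, list(as.character(1:6)))
  set.seed(1)
  expect_null(select_node(st6, "weak"))

  # low embeddedness picks a bridge endpoint of the two-triangle split
  st2 <- state_with_partition(jt, list(c("1", "2", "3"), c("4", "5", "6")))
  set.seed(1)
  sel <- select_node(st2, "low_embeddedness")
  expect_true(jt$nodes[sel$node] %in% c("3", "4"))

  # random: any node of an eligible community
  set.seed(2)
  sel2 <- select_node(st2, "random")
  expect_true(st2$csize[sel2$community] > 1L)
  expect_equal(st2$memb[sel2$node], sel2$community)
})

test_that("non-triad node selection requires communities above size four", {
  # triangle a-b-c with pendant p; x completes a second triangle with a, b
  g <- dgm_graph(edges_chr("a", "b", "b", "c", "c", "a", "c", "p",
                           "x", "a", "x", "b"))
  st4 <- state_with_partition(g, list(c("a", "b", "c", "p")))
  set.seed(1)
  expect_null(select_node(st4, "non_triad"))  # |C| = 4 is below threshold

  st5 <- state_with_partition(g, list(c("a", "b", "c", "p", "x")))
  set.seed(1)
  sel <- select_node(st5, "non_triad")
  expect_equal(g$nodes[sel$node], "p")        # only p sits in no triangle
})

test_that("community selection honours each strategy's score", {
  # triangle {1,2,3} and path {4,5,6} with no edges between them
  g <- dgm_graph(edges_chr(1, 2, 2, 3, 3, 1, 4, 5, 5, 6))
  st <- state_with_partition(g, list(c("1", "2", "3"), c("4", "5", "6")))
  path_id <- st$memb[match("4", g$nodes)]

  set.seed(1)
  expect_equal(select_community(st, "low_density"), path_id)  # 2/3 < 1
  expect_equal(select_community(st, "low_tpr"), path_id)      # 0 < 1
  expect_equal(select_community(st, "weak"), path_id)         # 2 < 3

  # all singletons: nothing eligible
  st0 <- init_singletons(g)
  for (s in c("random", "weak", "low_density", "low_tpr", "high_conductance")) {
    expect_null(select_community(st0, s))
  }

  # high conductance prefers the leakier community
  jt <- joined_triangles()
  g2 <- dgm_graph(rbind(cbind(jt$nodes[jt$edges[, 1]], jt$nodes[jt$edges[, 2]]),
                        c("2", "5")), nodes = jt$nodes)
  st2 <- state_with_partition(g2, list(c("1", "2", "3"), c("4", "5", "6")))
  set.seed(1)
  cid <- select_community(st2, "high_conductance")
  expect_true(st2$csize[cid] == 3L)  # tie between the triangles is fine
})

test_that("selection is reproducible under a fixed seed", {
  fx <- load_fixture("karate")
  st <- state_with_partition(fx$graph, list(as.character(1:17), as.character(18:34)))
  for (s in c("random", "weak", "low_embeddedness")) {
    set.seed(42)
    a <- select_node(st, s)
    set.seed(42)
    b <- select_node(st, s)
    expect_identical(a, b)
  }
  set.seed(42)
  ca <- select_community(st, "random")
  set.seed(42)
  cb <- select_community(st, "random")
  expect_identical(ca, cb)
})

test_that("node disassembly splits the remainder into components", {
  e <- single_edge()
  st <- state_with_partition(e, list(c("a", "b")))
  mv <- disassemble_node(st, st$memb[1], 1L)
  expect_equal(sum(st$active), 2L)
  expect_equal(mv$kind, "node")
  expect_equal(st$q, state_scratch_q(st), tolerance = 1e-12)

  # removing the star centre leaves three singleton leaves
  s4 <- star4()
  st2 <- state_with_partition(s4, list(s4$nodes))
  centre <- match("c", s4$nodes)
  disassemble_node(st2, st2$memb[centre], centre)
  expect_equal(sum(st2$active), 4L)
  expect_true(all(st2$csize[st2$active] == 1L))

  # created components have no edges between them inside the old community
  set.seed(9)
  for (i in 1:10) {
    g <- random_connected_graph(sample(8:16, 1), runif(1, 0.2, 0.4))
    st3 <- state_with_partition(g, list(g$nodes))
    v <- sample.int(g$n, 1)
    mv <- disassemble_node(st3, st3$memb[v], v)
    comp_ids <- setdiff(mv$created_communities, st3$memb[v])
    for (a in comp_ids) {
      for (b in setdiff(comp_ids, a)) {
        expect_equal(st3$M[a, b], 0)
      }
    }
    expect_equal(st3$q, state_scratch_q(st3), tolerance = 1e-9)
  }
})

test_that("community disassembly returns every member to a singleton", {
  g <- k3()
  st <- state_with_partition(g, list(c("1", "2", "3")))
  q0 <- st$q
  disassemble_community(st, st$memb[1])
  expect_equal(sum(st$active), 3L)
  expect_lt(st$q, q0)
  expect_equal(st$q, state_scratch_q(st), tolerance = 1e-12)

  # for a two-node community the two moves coincide
  e <- single_edge()
  st1 <- state_with_partition(e, list(c("a", "b")))
  st2 <- state_with_partition(e, list(c("a", "b")))
  disassemble_community(st1, st1$memb[1])
  disassemble_node(st2, st2$memb[1], 1L)
  expect_equal(state_partition(st1)$membership, state_partition(st2)$membership)

  expect_error(disassemble_community(st1, st1$memb[1]), "singleton")
})

test_that("states stay internally consistent under random move sequences", {
  set.seed(123)
  for (i in 1:8) {
    g <- random_connected_graph(sample(10:25, 1), runif(1, 0.15, 0.35))
    st <- init_singletons(g)
    for (k in 1:40) {
      u <- runif(1)
      if (u < 0.5) {
        bm <- best_merge(st, positive_only = FALSE)
        if (!is.null(bm)) apply_merge(st, bm$i, bm$j)
      } else if (u < 0.75) {
        cid <- select_community(st, "random")
        if (!is.null(cid)) disassemble_community(st, cid)
      } else {
        sel <- select_node(st, "random")
        if (!is.null(sel)) disassemble_node(st, sel$community, sel$node)
      }
      # partition validity: cover, disjoint, no empty community
      memb <- st$memb
      expect_true(all(st$active[memb]))
      expect_equal(sort(unique(memb)), which(st$active))
      expect_equal(tabulate(memb, nbins = length(st$active))[st$active],
                   st$csize[st$active])
      # tallies match a from-scratch recount
      expect_equal(st$q, state_scratch_q(st), tolerance = 1e-9)
      recount <- community_stats(st$g, state_partition(st))
      act <- sort(unique(memb))  # internal id act[k] carries label k
      rec_lc <- recount$l_c[match(as.character(seq_along(act)), recount$community)]
      rec_kc <- recount$k_c[match(as.character(seq_along(act)), recount$community)]
      expect_equal(unname(diag(st$M)[act]), as.numeric(rec_lc))
      expect_equal(unname(st$kc[act]), as.numeric(rec_kc))
    }
  }
})
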