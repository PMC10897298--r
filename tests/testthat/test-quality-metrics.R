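test_that("modularity matches hand-derived and published values", {
  g <- k3()
  expect_equal(modularity_q(g, partition_of(g, list(c(1, 2, 3)))), 0)
  expect_equal(modularity_q(g, partition_of(g, list(1, 2, 3))), -1 / 3)

  fx <- load_fixture("karate")
  expect_equal(round(modularity_q(fx$graph, fx$reference), 4), 0.3582)

  empty <- dgm_graph(matrix(character(0), 0, 2), nodes = c("a", "b"))
  p <- dgm_partition(c(a = "1", b = "1"))
  expect_error(modularity_q(empty, p), "empty graph")
})

test_that("modularity agrees with the igraph implementation", {
  set.seed(21)
  for (i in 1:15) {
    g <- random_connected_graph(sample(6:25, 1), runif(1, 0.15, 0.5))
    p <- random_partition(g, sample(2:5, 1))
    expect_equal(modularity_q(g, p), igraph_modularity(g, p), tolerance = 1e-12)
    q <- modularity_q(g, p)
    expect_gte(q, -0.5)
    expect_lt(q, 1)
  }
})

test_that("degree splits, embeddedness and weak-node rule are exact", {
  g <- k3()
  one <- partition_of(g, list(c(1, 2, 3)))
  s <- degree_split(g, one, "1")
  expect_equal(s[c("k_int", "k_ext")], list(k_int = 2L, k_ext = 0L))
  expect_false(is_weak_node(s))
  expect_equal(embeddedness(g, one, "1"), 1)

  e <- single_edge()
  apart <- partition_of(e, list("a", "b"))
  s2 <- degree_split(e, apart, "a")
  expect_equal(s2$k_int, 0L)
  expect_equal(s2$k_ext, 1L)
  expect_true(is_weak_node(s2))
  expect_equal(embeddedness(e, apart, "a"), 0)

  jt <- joined_triangles()
  tri <- partition_of(jt, list(c(1, 2, 3), c(4, 5, 6)))
  s3 <- degree_split(jt, tri, "3")
  expect_equal(s3$k_int, 2L)
  expect_equal(s3$k_ext, 1L)
  expect_false(is_weak_node(s3))
  expect_equal(embeddedness(jt, tri, "3"), 2 / 3)

  # boundary case: equality counts as weak
  expect_true(is_weak_node(list(k_int = 1L, k_ext = 1L)))
  expect_error(degree_split(g, one, "zz"), "unknown node")
})

test_that("triad detection finds exactly the triangle members", {
  expect_setequal(triad_nodes(k3(), c("1", "2", "3")), c("1", "2", "3"))
  expect_length(triad_nodes(path3(), path3()$nodes), 0L)
  jt <- joined_triangles()
  expect_setequal(triad_nodes(jt, jt$nodes), as.character(1:6))
  # restricting to one triangle plus the bridge endpoint keeps the triangle
  expect_setequal(triad_nodes(jt, c("1", "2", "3", "4")), c("1", "2", "3"))
})

test_that("adding edges never shrinks the triad set", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:10, 1)
    g <- random_connected_graph(n, runif(1, 0.25, 0.5))
    before <- triad_nodes(g, g$nodes)
    pool <- t(utils::combn(g$nodes, 2))
    have <- paste(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]])
    extra <- pool[!(paste(pool[, 1], pool[, 2]) %in% have), , drop = FALSE]
    if (!nrow(extra)) next
    add <- extra[sample.int(nrow(extra), 1), , drop = FALSE]
    g2 <- dgm_graph(rbind(cbind(g$nodes[g$edges[, 1]], g$nodes[g$edges[, 2]]), add),
                    nodes = g$nodes)
    expect_true(all(before %in% triad_nodes(g2, g2$nodes)))
  }
})

test_that("community-level metrics follow their closed forms", {
  expect_equal(internal_edge_density(list(n_s = 3, l_c = 3)), 1)
  expect_equal(internal_edge_density(list(n_s = 3, l_c = 1)), 1 / 3)
  expect_equal(internal_edge_density(list(n_s = 17, l_c = 33)), 33 / 136)
  expect_error(internal_edge_density(list(n_s = 1, l_c = 0)), "undefined")

  expect_equal(triad_participation_ratio(k3(), c("1", "2", "3")), 1)
  st <- star4()
  expect_equal(triad_participation_ratio(st, st$nodes), 0)
  tp <- dgm_graph(edges_chr(1, 2, 2, 3, 3, 1, 3, 4))  # triangle plus pendant
  expect_equal(triad_participation_ratio(tp, tp$nodes), 0.75)
  expect_error(triad_participation_ratio(st, character(0)), "empty")

  expect_equal(conductance(list(l_c = 7, m_out = 0)), 0)
  expect_equal(conductance(list(l_c = 0, m_out = 3)), 1)
  expect_equal(conductance(list(l_c = 3, m_out = 1)), 1 / 7)
  expect_error(conductance(list(l_c = 0, m_out = 0)), "undefined")

  expect_equal(community_edge_balance(list(l_c = 12, m_out = 0)), 12)
  expect_equal(community_edge_balance(list(l_c = 3, m_out = 1)), 2)
  expect_equal(community_edge_balance(list(l_c = 0, m_out = 3)), -3)
})

test_that("mean internal density averages non-singleton communities", {
  two_tri <- dgm_graph(edges_chr(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4))
  p <- partition_of(two_tri, list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mean_internal_density(two_tri, p), 1)

  fx <- load_fixture("karate")
  expect_equal(round(mean_internal_density(fx$graph, fx$reference), 4), 0.2463)

  mix <- dgm_graph(edges_chr(1, 2, 2, 3, 3, 1, 4, 5, 5, 6))
  pm <- partition_of(mix, list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(mean_internal_density(mix, pm), 5 / 6)

  singles <- partition_of(k3(), list(1, 2, 3))
  expect_error(mean_internal_density(k3(), singles), "singleton")
})

test_that("community stats satisfy the degree identity on random graphs", {
  set.seed(55)
  for (i in 1:10) {
    g <- random_connected_graph(sample(8:30, 1), runif(1, 0.15, 0.4))
    p <- random_partition(g, sample(2:5, 1))
    st <- community_stats(g, p)
    expect_true(all(st$k_c == 2 * st$l_c + st$m_out))
    expect_true(all(st$l_c >= 0 & st$m_out >= 0))
    expect_true(all(st$l_c <= st$n_s * (st$n_s - 1) / 2))
    inter <- sum(st$m_out) / 2
    expect_equal(sum(st$l_c) + inter, g$m)
  }
})

test_that("the metrics table is consistent with the scalar functions", {
  jt <- joined_triangles()
  p <- partition_of(jt, list(c(1, 2, 3), c(4, 5, 6)))
  tab <- community_metrics(jt, p)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$density, c(1, 1))
  expect_equal(tab$tpr, c(1, 1))
  expect_equal(tab$conductance, c(1 / 7, 1 / 7))
  expect_equal(tab$balance, c(2, 2))
})
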