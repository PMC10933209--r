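test_that("contact edges respect the inclusive cutoff boundary", {
  map <- molecule_map(c(1, 2), c("C", "C"))
  box <- cubic_box(50)
  near <- rbind(c(0, 0, 0), c(2.9, 0, 0))
  far <- rbind(c(0, 0, 0), c(3.01, 0, 0))
  at <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  expect_equal(nrow(find_contacts(near, map, box, cutoff = 3)$edges), 1)
  expect_equal(nrow(find_contacts(far, map, box, cutoff = 3)$edges), 0)
  # "within" is inclusive
  expect_equal(nrow(find_contacts(at, map, box, cutoff = 3)$edges), 1)
})

test_that("contacts can be restricted to heavy atoms or multiple pairs", {
  # molecules whose only close approach is via a hydrogen
  map <- molecule_map(c(1, 1, 2), c("C", "H", "C"))
  box <- cubic_box(50)
  co <- rbind(c(0, 0, 0), c(4, 0, 0), c(6, 0, 0))
  expect_equal(nrow(find_contacts(co, map, box, cutoff = 3)$edges), 1)
  expect_equal(nrow(find_contacts(co, map, box, cutoff = 3,
                                  contact_atoms = "heavy")$edges), 0)
  # min_contacts = 2 needs two qualifying atom pairs
  map2 <- molecule_map(c(1, 1, 2, 2), rep("C", 4))
  co2 <- rbind(c(0, 0, 0), c(0, 1.5, 0), c(2, 0, 0), c(20, 20, 20))
  expect_equal(nrow(find_contacts(co2, map2, box, cutoff = 3)$edges), 1)
  expect_equal(nrow(find_contacts(co2, map2, box, cutoff = 3,
                                  min_contacts = 2)$edges), 1)
  expect_equal(nrow(find_contacts(co2, map2, box, cutoff = 3,
                                  min_contacts = 3)$edges), 0)
})

test_that("contacts reach across periodic boundaries", {
  map <- molecule_map(c(1, 2), c("C", "C"))
  co <- rbind(c(0.5, 5, 5), c(19.5, 5, 5))  # 1 A apart through the wall
  for (meth in c("brute", "cell_list")) {
    g <- find_contacts(co, map, cubic_box(20), cutoff = 3, method = meth)
    expect_equal(nrow(g$edges), 1)
  }
})

test_that("cell-list refuses cutoffs too large for the box", {
  map <- molecule_map(c(1, 2), c("C", "C"))
  co <- rbind(c(1, 1, 1), c(5, 5, 5))
  expect_error(find_contacts(co, map, cubic_box(10), cutoff = 4,
                             method = "cell_list"), "brute")
  # auto falls back to brute silently
  g <- find_contacts(co, map, cubic_box(10), cutoff = 4, method = "auto")
  expect_equal(g$method, "brute")
})

test_that("union-find components match spec examples", {
  expect_equal(connected_components(matrix(integer(0), 0, 2), 11)$n_clusters,
               11)  # fully dispersed: all molecules separate
  cc <- connected_components(matrix(c(1, 2, 2, 3), ncol = 2, byrow = TRUE), 11)
  expect_equal(cc$n_clusters, 9)
  expect_equal(cc$sizes, c(3, rep(1, 8)))
  expect_equal(sum(cc$sizes), 11)
  expect_error(connected_components(matrix(c(1, 12), 1, 2), 11), "beyond")
})

test_that("union-find matches a DFS component oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:30, 1)
    m <- sample(0:40, 1)
    edges <- if (m == 0) matrix(integer(0), 0, 2) else
      cbind(sample(n, m, TRUE), sample(n, m, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    cc <- connected_components(edges, n)
    expect_equal(cc$n_clusters, oracle_n_components(edges, n))
    expect_equal(max(cc$labels), cc$n_clusters)
    expect_equal(sum(cc$sizes), n)
  }
})

test_that("cell-list and brute-force graphs match a pure-R 27-image oracle", {
  set.seed(21)
  boxes <- list(cubic_box(22), truncated_octahedron_box(26),
                orthorhombic_box(20, 26, 31))
  for (i in 1:30) {
    box <- boxes[[(i %% 3) + 1]]
    fr <- make_random_frame(sample(3:8, 1), max_atoms = 6, box = box)
    cutoff <- stats::runif(1, 2, 6)
    want <- sort_edges(oracle_contact_edges(fr$coords, fr$map$mol_id, box,
                                            cutoff))
    for (meth in c("brute", "cell_list")) {
      got <- find_contacts(fr$coords, fr$map, box, cutoff = cutoff,
                           method = meth)$edges
      expect_equal(sort_edges(got), want)
    }
    # heavy-atom restriction agrees with the oracle too
    want_h <- sort_edges(oracle_contact_edges(fr$coords, fr$map$mol_id, box,
                                              cutoff, fr$map$element,
                                              heavy_only = TRUE))
    got_h <- find_contacts(fr$coords, fr$map, box, cutoff = cutoff,
                           contact_atoms = "heavy")$edges
    expect_equal(sort_edges(got_h), want_h)
  }
})

test_that("N_c is non-increasing in the cutoff", {
  set.seed(31)
  for (i in 1:10) {
    fr <- make_random_frame(10, max_atoms = 4, box = cubic_box(25))
    nc <- sapply(seq(2, 6, by = 0.5), function(ct) {
      connected_components(find_contacts(fr$coords, fr$map, fr$box,
                                         cutoff = ct))$n_clusters
    })
    expect_true(all(diff(nc) <= 0))
  }
})

test_that("the contact graph is invariant under lattice translations", {
  set.seed(41)
  box <- truncated_octahedron_box(28)
  fr <- make_random_frame(8, max_atoms = 5, box = box)
  g0 <- sort_edges(find_contacts(fr$coords, fr$map, box, cutoff = 4)$edges)
  shift <- colSums(box$vectors * c(1, -2, 1))
  g1 <- sort_edges(find_contacts(sweep(fr$coords, 2, shift, `+`), fr$map,
                                 box, cutoff = 4)$edges)
  expect_equal(g1, g0)
})

test_that("cluster_trajectory reproduces constructed limiting series", {
  box <- cubic_box(60)
  n <- 6
  fused <- matrix(rep(c(10, 10, 10), each = n), ncol = 3) +
    cbind(seq(0, by = 2.5, length.out = n), 0, 0)
  dispersed <- cbind(seq(5, 55, length.out = n), 30, 30)
  mk <- function(...) list(...)
  traj_f <- make_point_trajectory(mk(fused, fused, fused), box)
  traj_d <- make_point_trajectory(mk(dispersed, dispersed), box)
  traj_a <- make_point_trajectory(mk(fused, dispersed, fused, dispersed), box)
  expect_equal(cluster_trajectory(traj_f, cutoff = 3)$n_clusters, rep(1L, 3))
  expect_equal(cluster_trajectory(traj_d, cutoff = 3)$n_clusters, rep(6L, 2))
  s <- cluster_trajectory(traj_a, cutoff = 3, n_frames = 4)
  expect_equal(s$n_clusters, c(1L, 6L, 1L, 6L))
  expect_equal(s$largest_cluster_size, c(6L, 1L, 6L, 1L))
  expect_equal(attr(s, "n_mol"), 6)
})
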