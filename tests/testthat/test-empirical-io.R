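test_that("edge-list reader deduplicates, drops self-loops and validates", {
  path <- withr::local_tempfile()
  writeLines(c("# comment", "1 2", "2\t1", "3 3", "4 5"), path)
  expect_message(e <- read_edge_list(path), "1 self-loop")
  expect_equal(e, rbind(c(1L, 2L), c(4L, 5L)), ignore_attr = TRUE)

  bad <- withr::local_tempfile()
  writeLines(c("1 2", "7 eight"), bad)
  expect_error(read_edge_list(bad), "malformed edge line 2")
})

test_that("community files round-trip and tolerate empty lines", {
  path <- withr::local_tempfile()
  writeLines(c("1 2 3", "", "3 4 5"), path)
  expect_message(cm <- read_communities(path), "1 empty line")
  expect_identical(cm, list(c(1L, 2L, 3L), c(3L, 4L, 5L)))

  out <- withr::local_tempfile()
  write_communities(cm, out)
  expect_identical(read_communities(out), cm)

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_identical(read_communities(empty), list())
})

test_that("pair selection balances connectivity against size", {
  # B is larger than C, but only the (A, C) pair is connected enough
  comms <- list(1:10, 11:19, 20:26)
  edges <- rbind(cbind(1:5, 20:24),  # A-C: 5 inter edges
                 c(11, 12), c(1, 2), c(20, 21),
                 c(10, 11))          # single A-B edge
  pick <- select_community_pair(edges, comms, min_inter_edges = 3)
  expect_identical(pick$indices, c(1L, 3L))
  expect_identical(pick$inter_edges, 5L)

  expect_error(select_community_pair(edges, comms, min_inter_edges = 50),
               "no community pair")
})

test_that("biased overlap assignment balances sizes greedily", {
  # 6 exclusive + 4 shared vs 2 exclusive: all 4 go to the smaller side
  a <- 1:10
  b <- c(7:10, 11, 12)
  out <- assign_overlaps(a, b, "biased")
  expect_identical(out$a, 1:6)
  expect_identical(out$b, c(7:10, 11:12))
  expect_length(intersect(out$a, out$b), 0)

  set.seed(2); r1 <- assign_overlaps(a, b, "random")
  set.seed(2); r2 <- assign_overlaps(a, b, "random")
  expect_identical(r1, r2)
  expect_identical(sort(c(r1$a, r1$b)), 1:12)

  no_overlap <- assign_overlaps(1:3, 4:6, "biased")
  expect_identical(no_overlap, list(a = 1:3, b = 4:6))
})

test_that("subnetwork statistics match hand counts", {
  # two triangles plus one bridge, via the ID-level pipeline
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                 c(3, 4), c(6, 99)) # edge out of the pair is dropped
  sub <- extract_subnetwork(edges, a = 1:3, b = 4:6)
  st <- empirical_stats(sub)
  expect_identical(st$N, 6L)
  expect_equal(st$mu, 1 / 7)
  expect_equal(st$z_A, 2)
  expect_equal(st$z_B, 2)
  expect_error(extract_subnetwork(edges, 1:3, 3:6), "disjoint")

  bip <- modular_network(rbind(c(1, 3), c(2, 4)), c(1, 1, 2, 2))
  stb <- empirical_stats(bip)
  expect_equal(stb$mu, 1)
  expect_equal(stb$z_A, 0)
})

test_that("fixtures are reproducible and carry their planted truth", {
  dir <- withr::local_tempdir()
  set.seed(11)
  fx <- make_snap_fixture(file.path(dir, "a"), sizes = c(60, 50),
                          p_intra = 0.2, p_inter = 0.05, overlap = 5)
  comms <- read_communities(fx$communities)
  expect_length(comms, 2 + fx$truth$n_extra)
  expect_identical(lengths(comms)[1:2], c(60L, 50L))
  expect_identical(intersect(comms[[1]], comms[[2]]), fx$truth$shared_ids)
  expect_length(fx$truth$shared_ids, 5)

  set.seed(11)
  fx2 <- make_snap_fixture(file.path(dir, "b"), sizes = c(60, 50),
                           p_intra = 0.2, p_inter = 0.05, overlap = 5)
  expect_identical(readLines(fx$edges), readLines(fx2$edges))
  expect_identical(readLines(fx$communities), readLines(fx2$communities))

  # planted pair is recovered by the selector
  edges <- read_edge_list(fx$edges)
  pick <- select_community_pair(edges, comms, min_inter_edges = 5)
  expect_identical(pick$indices, c(1L, 2L))
})

test_that("a bipartite planted pair reads back with mu = 1", {
  dir <- withr::local_tempdir()
  set.seed(6)
  fx <- make_snap_fixture(dir, sizes = c(20, 20), p_intra = 0,
                          p_inter = 0.5, overlap = 0, n_extra = 0)
  edges <- read_edge_list(fx$edges)
  sub <- extract_subnetwork(edges, 1:20, 21:40)
  expect_equal(empirical_stats(sub)$mu, 1)
})
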