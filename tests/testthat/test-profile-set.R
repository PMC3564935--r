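pair_vocab <- function()
  mesh_vocabulary(c("T1", "T2", "T3"), c("one", "two", "three"),
                  list("A", "B", "C"))

test_that("shared policy keeps the common terms, union zero-fills", {
  v <- pair_vocab()
  m1 <- fake_meshop(c("T1", "T2"), c(1e-4, 1e-2), v, "e1")
  m2 <- fake_meshop(c("T1", "T2", "T3"), c(1e-3, 1e-2, 1e-1), v, "e2")
  ps <- profile_set(list(m1, m2), "shared")
  expect_equal(ps$term_ids, c("T1", "T2"))
  expect_equal(dim(ps), c(2L, 2L))

  pu <- profile_set(list(m1, m2), "union")
  expect_equal(pu$term_ids, c("T1", "T2", "T3"))
  expect_equal(unname(pu$weights["e1", "T3"]), 0)
  expect_equal(unname(pu$weights["e2", "T3"]), 1)
})

test_that("weights are capped -log10 p-values", {
  v <- pair_vocab()
  m1 <- fake_meshop(c("T1", "T2"), c(1e-40, 1e-4), v, "e1")
  m2 <- fake_meshop(c("T1", "T2"), c(1e-2, 1), v, "e2")
  ps <- profile_set(list(m1, m2), "shared", cap = 1e-30)
  expect_equal(unname(ps$weights["e1", "T1"]), 30)  # capped from 40
  expect_equal(unname(ps$weights["e1", "T2"]), 4)
  expect_equal(unname(ps$weights["e2", "T2"]), 0)   # p = 1
})

test_that("disjoint profiles under shared policy advise union", {
  v <- pair_vocab()
  m1 <- fake_meshop("T1", 1e-4, v, "e1")
  m2 <- fake_meshop("T2", 1e-4, v, "e2")
  expect_error(profile_set(list(m1, m2), "shared"), "union")
})

test_that("euclidean distance matches hand computation and brute force", {
  v <- pair_vocab()
  m1 <- fake_meshop(c("T1", "T2"), c(1e-4, 1e-2), v, "e1")
  m2 <- fake_meshop(c("T1", "T2"), c(1e-6, 1e-2), v, "e2")
  ps <- profile_set(list(m1, m2), "shared")
  # rows are (4, 2) and (6, 2): distance 2
  expect_equal(euclidean_distance(ps, 1, 2), 2)
  expect_equal(euclidean_distance(ps, "e1", "e2"), 2)
  expect_equal(euclidean_distance(ps, 1, 1), 0)
  expect_error(euclidean_distance(ps, 1, 3), "out of range")

  set.seed(4)
  w <- matrix(stats::runif(40, 0, 30), nrow = 4)
  ps$weights <- w
  ps$entity_ids <- paste0("x", 1:4)
  for (i in 1:4) for (j in 1:4)
    expect_equal(euclidean_distance(ps, i, j),
                 sqrt(sum((w[i, ] - w[j, ])^2)))
})

test_that("profile distances satisfy the metric axioms", {
  set.seed(8)
  v <- make_toy_vocab(2, 3)
  ms <- lapply(1:5, function(i) {
    ids <- sample(v$term_id, 6)
    fake_meshop(ids, stats::runif(6, 1e-20, 1), v, paste0("e", i))
  })
  ps <- profile_set(ms, "union")
  d <- as.matrix(profile_dist(ps))
  expect_true(all(d >= 0))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("complete linkage merges nearest entities first", {
  v <- pair_vocab()
  # collinear weights 0, 1, 10 on a single shared term
  ms <- list(fake_meshop("T1", 1, v, "a"),
             fake_meshop("T1", 1e-1, v, "b"),
             fake_meshop("T1", 1e-10, v, "c"))
  hc <- cluster_complete(profile_set(ms, "shared"))
  expect_equal(sort(hc$merge[1L, ]), c(-2L, -1L))  # a and b first
  expect_equal(hc$height, c(1, 10))
  expect_true(all(diff(hc$height) >= 0))
})

test_that("entity relabeling permutes but preserves merge heights", {
  set.seed(21)
  v <- make_toy_vocab(2, 3)
  ms <- lapply(1:6, function(i)
    fake_meshop(v$term_id, stats::runif(length(v$term_id), 1e-12, 1),
                v, paste0("e", i)))
  ps <- profile_set(ms, "union")
  hc1 <- cluster_complete(ps)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  hc2 <- cluster_complete(profile_set(ms[perm], "union"))
  expect_equal(sort(hc1$height), sort(hc2$height))
})

test_that("two planted groups are recovered by cutting at k = 2", {
  v <- make_toy_vocab(3, 3)
  syn <- generate_corpus(two_group_spec(17), v)
  ms <- lapply(syn$bibliographies, function(b)
    meshop(b, syn$corpus, v))
  hc <- cluster_complete(profile_set(ms, "union"))
  cut <- stats::cutree(hc, k = 2)
  groups <- substr(names(cut), 1, 1)
  expect_equal(length(unique(cut[groups == "A"])), 1L)
  expect_equal(length(unique(cut[groups == "B"])), 1L)
  expect_false(cut[groups == "A"][1L] == cut[groups == "B"][1L])
})

test_that("clustering needs at least two entities", {
  v <- pair_vocab()
  ps <- profile_set(list(fake_meshop("T1", 0.1, v, "a"),
                         fake_meshop("T1", 0.2, v, "b")), "shared")
  ps$weights <- ps$weights[1, , drop = FALSE]
  expect_error(cluster_complete(ps), "at least 2")
})

test_that("cooccurrence submatrix restricts to the requested panel", {
  v <- make_toy_vocab(2, 3)
  ms <- lapply(1:3, function(i)
    fake_meshop(v$term_id[1:6], stats::runif(6, 1e-8, 0.5), v,
                paste0("e", i)))
  panel <- v$term_id[c(2, 4, 9)]   # term 9 occurs in no profile
  ps <- cooccurrence_submatrix(ms, panel)
  expect_equal(ps$term_ids, panel)
  expect_equal(dim(ps), c(3L, 3L))
  expect_true(all(ps$weights[, 3] == 0))   # absent term: zero column
  expect_error(cooccurrence_submatrix(ms, v$term_id[9]), "none")
  one <- cooccurrence_submatrix(ms, v$term_id[2])
  expect_equal(dim(one), c(3L, 1L))
})

test_that("distance and merge tables write as documented TSV", {
  v <- pair_vocab()
  ms <- list(fake_meshop(c("T1", "T2"), c(1e-4, 1e-2), v, "e1"),
             fake_meshop(c("T1", "T2"), c(1e-6, 1e-2), v, "e2"),
             fake_meshop(c("T1", "T2"), c(1e-2, 1e-1), v, "e3"))
  ps <- profile_set(ms, "shared")
  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_dist_tsv(profile_dist(ps), dpath)
  d <- utils::read.delim(dpath, row.names = 1)
  expect_equal(unname(as.matrix(d)), unname(as.matrix(profile_dist(ps))),
               tolerance = 1e-9)
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_merges_tsv(cluster_complete(ps), mpath)
  mg <- utils::read.delim(mpath)
  expect_equal(nrow(mg), 2L)
  expect_equal(mg$size, c(2L, 3L))
})
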