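test_that("fisher_greater matches enumeration on the worked table", {
  # foreground {1,2} both with the term, one of four remaining background
  # articles with it: C(3,2)*C(3,0)/C(6,2) = 3/15
  expect_equal(fisher_greater(2, 0, 1, 3), 0.2)
  expect_equal(fisher_greater(2, 0, 1, 3), hyper_tail_oracle(2, 0, 1, 3))
})

test_that("degenerate tables hit the boundary values", {
  expect_equal(fisher_greater(0, 5, 3, 7), 1)       # P(X >= 0) = 1
  expect_equal(fisher_greater(0, 0, 0, 0), 1)
  # term on every background article: X is identically the draw count
  expect_equal(fisher_greater(4, 0, 6, 0), 1)
  expect_error(fisher_greater(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_greater agrees with the brute-force tail on small tables", {
  set.seed(1)
  for (rep in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:40, 1), rep(1, 4)))
    expect_equal(fisher_greater(cells[1], cells[2], cells[3], cells[4]),
                 hyper_tail_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("p-values decrease strictly in a with margins fixed", {
  # population 40, successes 15, draws 10
  K <- 15; n <- 10; N <- 40
  p <- vapply(0:10, function(a)
    fisher_greater(a, n - a, K - a, N - K - (n - a)), 0.0)
  expect_true(all(diff(p) < 0))
})

test_that("extreme tables stay representable and positive", {
  p <- fisher_greater(250, 0, 250, 4500)
  expect_gt(p, 0)
  expect_lt(p, 1e-280)
  expect_equal(log(p), log(hyper_tail_oracle(250, 0, 250, 4500)),
               tolerance = 1e-9)
})

test_that("meshop reproduces the worked 6-article example", {
  wf <- worked_fixture()
  m <- meshop(wf$fg, wf$corpus, wf$vocab)
  expect_s3_class(m, "meshop")
  expect_equal(m$fg_size, 2L)
  expect_equal(m$background$size, 6L)
  row <- m$scores[m$scores$term_id == "TT", ]
  expect_equal(row$a, 2L)
  expect_equal(row$k, 3L)
  expect_equal(row$p_value, 0.2)
  # UU never occurs in the foreground, so it is absent
  expect_false("UU" %in% m$scores$term_id)
})

test_that("a term on every background article scores p = 1", {
  v <- mesh_vocabulary(c("E", "R"), c("Everywhere", "Rare"),
                       list("A", "B"))
  corp <- mesh_corpus(1:8, rep(2000L, 8),
                      c(rep(list(c("E", "R")), 2), rep(list("E"), 6)), v)
  m <- meshop(bibliography("x", 1:2), corp, v)
  expect_equal(m$scores$p_value[m$scores$term_id == "E"], 1)
  expect_lt(m$scores$p_value[m$scores$term_id == "R"], 1)
})

test_that("profile ordering is ascending p with term_id tie-break", {
  v <- make_toy_vocab(2, 3)
  syn <- generate_corpus(synthetic_spec(seed = 5,
                                        n_background_articles = 100L,
    entities = list(list(entity_id = "e", n_articles = 15L,
                         planted = numeric(0)))), v)
  m <- meshop(syn$bibliographies[["e"]], syn$corpus, v)
  s <- m$scores
  expect_true(all(diff(s$p_value) >= 0))
  ties <- which(diff(s$p_value) == 0)
  if (length(ties))
    expect_true(all(s$term_id[ties] < s$term_id[ties + 1L]))
  expect_true(all(s$a >= 1L))
})

test_that("foreground outside the background or empty is an error", {
  wf <- worked_fixture()
  expect_error(meshop(bibliography("x", c(1L, 2L)), wf$corpus, wf$vocab,
                      background = c(1L, 3:6)),
               "outside the background")
  expect_error(meshop(bibliography("x", 999L), wf$corpus, wf$vocab),
               "empty foreground")
})

test_that("unresolvable foreground articles are dropped with a count", {
  wf <- worked_fixture()
  m <- meshop(bibliography("x", c(1L, 2L, 777L)), wf$corpus, wf$vocab)
  expect_equal(m$n_dropped, 1L)
  expect_equal(m$fg_size, 2L)
})

test_that("min_count prunes low-support terms", {
  wf <- worked_fixture()
  corp <- mesh_corpus(1:6, rep(2000L, 6),
                      list("TT", c("TT", "UU"), "TT", "UU", "UU", "UU"),
                      wf$vocab)
  m1 <- meshop(bibliography("x", 1:2), corp, wf$vocab, min_count = 1L)
  m2 <- meshop(bibliography("x", 1:2), corp, wf$vocab, min_count = 2L)
  expect_true("UU" %in% m1$scores$term_id)
  expect_false("UU" %in% m2$scores$term_id)
  expect_error(meshop(bibliography("x", 1:2), corp, wf$vocab,
                      min_count = 0L))
})

test_that("bonferroni multiplies, caps, and preserves order", {
  wf <- worked_fixture()
  m <- meshop(wf$fg, wf$corpus, wf$vocab)
  expect_equal(bonferroni(m, 1)$scores$p_bonferroni,
               m$scores$p_value)
  expect_equal(bonferroni(m, 10)$scores$p_bonferroni[
    m$scores$term_id == "TT"], 1)  # 0.2 * 10 capped
  fm <- fake_meshop("TT", 1e-5, wf$vocab)
  expect_equal(bonferroni(fm, 4411)$scores$p_bonferroni, 4.411e-2)
  expect_error(bonferroni(m, 0), ">= 1")
})

test_that("planted enrichment attains the minimum p in the profile", {
  v <- make_toy_vocab(3, 3)
  syn <- generate_corpus(recovery_spec(101), v)
  m <- meshop(syn$bibliographies[[1L]], syn$corpus, v)
  expect_equal(m$scores$term_id[1L], syn$ground_truth$term_id[1L])
  expect_lt(m$scores$p_value[1L], 0.05)
})

test_that("class-enriched terms lose significance under class background", {
  # a term common in the class literature but at the class rate in the
  # member's own articles: strongly enriched vs the universal background,
  # unremarkable vs the class background
  v <- mesh_vocabulary(c("TT", "FF"), c("Class trait", "Filler"),
                       list("A", "B"))
  terms <- c(rep(list(c("TT", "FF")), 5), rep(list("FF"), 5),   # member
             rep(list(c("TT", "FF")), 15), rep(list("FF"), 15), # class rest
             rep(list(c("TT", "FF")), 6), rep(list("FF"), 54))  # outside
  corp <- mesh_corpus(1:100, rep(2000L, 100), terms, v)
  member <- bibliography("m", 1:10)
  class_members <- list(member, bibliography("others", 11:40))
  m_univ <- meshop(member, corp, v, background = "universal")
  m_class <- meshop(member, corp, v, background = "class",
                    members = class_members)
  p_univ <- m_univ$scores$p_value[m_univ$scores$term_id == "TT"]
  p_class <- m_class$scores$p_value[m_class$scores$term_id == "TT"]
  expect_lt(p_univ, p_class)
})

test_that("profiles round-trip through the TSV dialect", {
  v <- make_toy_vocab(3, 2)
  syn <- generate_corpus(recovery_spec(7, v), v)
  m <- bonferroni(meshop(syn$bibliographies[[1L]], syn$corpus, v), 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(m, path)
  m2 <- read_profile_tsv(path)
  expect_equal(m2$entity_id, m$entity_id)
  expect_equal(m2$scores$term_id, m$scores$term_id)
  expect_equal(m2$scores$p_value, m$scores$p_value, tolerance = 1e-12)
  expect_equal(m2$scores$a, m$scores$a)
  expect_equal(m2$background$size, m$background$size)
})
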