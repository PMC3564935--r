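# Independent brute-force oracle for the hypergeometric upper tail:
# direct summation of the point masses over the support, via log binomial
# coefficients.  Deliberately avoids phyper.
hyper_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c   # successes in the population
  n <- a + b   # draws
  if (a <= max(0, n + K - N)) return(1)
  xs <- a:min(n, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# brute-force ancestor scan over all tree-number pairs
ancestors_brute <- function(vocab, id) {
  mine <- vocab$tree_numbers[[match(id, vocab$term_id)]]
  out <- character(0)
  for (j in seq_along(vocab$term_id)) {
    other <- vocab$term_id[j]
    if (other == id) next
    for (p in vocab$tree_numbers[[j]])
      for (q in mine)
        if (startsWith(q, paste0(p, "."))) out <- c(out, other)
  }
  unique(out)
}

# the 6-article worked corpus: term TT on articles 1-3, UU on 4-6,
# foreground {1, 2}; the table for TT is (a=2, b=0, c=1, d=3), p = 3/15
worked_fixture <- function() {
  vocab <- mesh_vocabulary(c("TT", "UU"), c("Term T", "Term U"),
                           list("A", "B"))
  corpus <- mesh_corpus(1:6, rep(2000L, 6),
                        list("TT", "TT", "TT", "UU", "UU", "UU"), vocab)
  list(vocab = vocab, corpus = corpus,
       fg = bibliography("demo", c(1L, 2L)))
}

# write the worked corpus in the on-disk dialects for CLI tests
write_worked_files <- function(dir) {
  wf <- worked_fixture()
  write_vocab_tsv(wf$vocab, file.path(dir, "vocab.tsv"))
  write_annotations(wf$corpus, file.path(dir, "annotations.tsv"))
  writeLines(c("# demo foreground", "1", "2"),
             file.path(dir, "fg.pmids"))
  invisible(dir)
}

# a profile object with prescribed terms and p-values, for post-processing
# tests that need full control of the scores
fake_meshop <- function(term_ids, p, vocab, entity_id = "fake") {
  ord <- order(p, term_ids)
  n <- length(term_ids)
  scores <- data.frame(term_id = term_ids[ord],
                       term_name = term_names(vocab, term_ids[ord]),
                       a = rep(1L, n), fg_size = rep(10L, n),
                       k = rep(5L, n), bg_size = rep(100L, n),
                       p_value = p[ord], stringsAsFactors = FALSE)
  structure(list(entity_id = entity_id, scores = scores, fg_size = 10L,
                 n_dropped = 0L,
                 background = list(mode = "universal", size = 100L)),
            class = "meshop")
}
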