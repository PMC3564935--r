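#' Build a complete toy vocabulary tree
#'
#' Generates a full tree of the given depth and branching factor with
#' deterministic IDs: the node reached by branch indices `i1, i2, ...` has
#' tree position `"i1.i2..."` and term ID `"Ni1_i2_..."`.  Total terms are
#' `sum(branching^(1:depth))`.  Useful as a stand-in hierarchy for tests
#' and simulations.
#'
#' @param depth tree depth (>= 1).
#' @param branching children per node (>= 1).
#' @return A [mesh_vocabulary()].
#' @export
make_toy_vocab <- function(depth, branching) {
  if (depth < 1L || branching < 1L)
    stop("depth and branching must be >= 1")
  positions <- character(0)
  frontier <- as.character(seq_len(branching))
  for (lev in seq_len(depth)) {
    positions <- c(positions, frontier)
    if (lev < depth)
      frontier <- as.vector(t(outer(frontier, seq_len(branching),
                                    paste, sep = ".")))
  }
  ids <- paste0("N", gsub(".", "_", positions, fixed = TRUE))
  mesh_vocabulary(ids, paste("Toy term", ids), as.list(positions))
}

#' Specification of a synthetic annotated corpus
#'
#' Describes a corpus drawn under the null model of independent random term
#' assignment, optionally with planted over-representation signal for named
#' entities.  Background articles receive each *leaf* term independently
#' with `base_term_probability`; ancestors arrive only through the upward
#' closure, mirroring curation practice of assigning the most specific
#' relevant terms.  Each entity contributes `n_articles` additional
#' articles in which its planted leaf terms appear at their stated
#' foreground probabilities and all other leaves at the background rate.
#'
#' @param seed integer seed governing all draws.
#' @param n_background_articles number of background (non-entity) articles.
#' @param base_term_probability per-leaf assignment probability.
#' @param entities list of entities; each is a list with `entity_id`
#'   (string), `n_articles` (count >= 1), and `planted` (named numeric
#'   vector: leaf term ID -> foreground probability; may be empty).
#' @param year_range integer vector `c(first, last)` publication year.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_background_articles = 500L,
                           base_term_probability = 0.05,
                           entities = list(),
                           year_range = c(1990L, 2010L)) {
  stopifnot(n_background_articles >= 0L,
            base_term_probability >= 0, base_term_probability <= 1,
            length(year_range) == 2L, year_range[1L] <= year_range[2L])
  for (e in entities) {
    stopifnot(is.list(e), !is.null(e$entity_id), e$n_articles >= 1L)
    if (length(e$planted)) {
      stopifnot(!is.null(names(e$planted)),
                all(e$planted >= 0), all(e$planted <= 1))
    }
  }
  structure(list(seed = as.integer(seed),
                 n_background_articles = as.integer(n_background_articles),
                 base_term_probability = base_term_probability,
                 entities = entities,
                 year_range = as.integer(year_range)),
            class = "synthetic_spec")
}

# leaves = occupied positions that are not a proper prefix of any other
.leaf_terms <- function(vocab) {
  pos <- names(vocab$position_index)
  has_child <- vapply(pos, function(p)
    any(startsWith(pos, paste0(p, "."))), TRUE)
  unique(unname(vocab$position_index[!has_child]))
}

# deterministic substream seed from (seed, entity label); < 2^31
.substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Draw a synthetic corpus with planted enrichment
#'
#' Realizes a [synthetic_spec()] against a vocabulary.  All randomness
#' comes from the spec's seed; entity draws use substreams derived from
#' `(seed, entity_id)`, so runs are reproducible and entities do not
#' perturb each other's draws.
#'
#' @param spec a [synthetic_spec()].
#' @param vocab a [mesh_vocabulary()]; planted terms must be leaves of it.
#' @return List with `corpus` (a [mesh_corpus()]), `bibliographies` (named
#'   list of [bibliography()], one per entity) and `ground_truth` (data
#'   frame: `entity_id`, `term_id`, `foreground_probability`).
#' @export
generate_corpus <- function(spec, vocab) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(vocab, "mesh_vocab"))
  leaves <- .leaf_terms(vocab)
  for (e in spec$entities) {
    bad <- setdiff(names(e$planted), vocab$term_id)
    if (length(bad))
      stop("planted term not in vocabulary: ", paste(bad, collapse = ", "))
  }

  draw_articles <- function(n, probs) {
    # probs: named vector over all leaves
    hits <- matrix(stats::runif(n * length(probs)) < rep(probs, each = n),
                   nrow = n)
    lapply(seq_len(n), function(i) leaves[hits[i, ]])
  }
  draw_years <- function(n) {
    yrs <- seq(spec$year_range[1L], spec$year_range[2L])
    yrs[sample.int(length(yrs), n, replace = TRUE)]
  }

  base_probs <- stats::setNames(
    rep(spec$base_term_probability, length(leaves)), leaves)

  set.seed(spec$seed)
  n_bg <- spec$n_background_articles
  bg_terms <- draw_articles(n_bg, base_probs)
  bg_years <- draw_years(n_bg)

  next_id <- n_bg
  all_terms <- bg_terms
  all_years <- bg_years
  bibs <- list()
  gt <- list()
  for (e in spec$entities) {
    set.seed(.substream_seed(spec$seed, e$entity_id))
    probs <- base_probs
    probs[names(e$planted)] <- e$planted
    ids <- next_id + seq_len(e$n_articles)
    next_id <- next_id + e$n_articles
    all_terms <- c(all_terms, draw_articles(e$n_articles, probs))
    all_years <- c(all_years, draw_years(e$n_articles))
    bibs[[e$entity_id]] <- bibliography(e$entity_id, ids)
    if (length(e$planted))
      gt[[length(gt) + 1L]] <- data.frame(
        entity_id = e$entity_id, term_id = names(e$planted),
        foreground_probability = unname(e$planted),
        stringsAsFactors = FALSE)
  }
  ground_truth <- if (length(gt)) do.call(rbind, gt) else
    data.frame(entity_id = character(0), term_id = character(0),
               foreground_probability = numeric(0))

  n_total <- n_bg + sum(vapply(spec$entities,
                               function(e) e$n_articles, 0L))
  corpus <- mesh_corpus(seq_len(n_total), all_years, all_terms, vocab)
  list(corpus = corpus, bibliographies = bibs, ground_truth = ground_truth)
}

#' Canonical single-entity signal-recovery scenario
#'
#' 500 background articles; one entity with 30 articles in which the first
#' leaf of the tree is planted at foreground probability 0.5 against a base
#' rate of 0.05.  Used to check that the planted term attains the smallest
#' p-value in the entity's profile.
#'
#' @param seed integer seed.
#' @param vocab vocabulary to plant in (default a depth-3, branching-3
#'   toy tree).
#' @return A [synthetic_spec()].
#' @export
recovery_spec <- function(seed, vocab = make_toy_vocab(3, 3)) {
  leaf <- .leaf_terms(vocab)[1L]
  synthetic_spec(
    seed = seed, n_background_articles = 500L,
    base_term_probability = 0.05,
    entities = list(list(entity_id = "entity1", n_articles = 30L,
                         planted = stats::setNames(0.5, leaf))))
}

#' Canonical two-group clustering scenario
#'
#' Two groups of five entities each, 25 articles per entity.  Each group
#' carries a disjoint signature of three planted leaf terms at foreground
#' probability 0.5 against base 0.05, emulating a class of entities that
#' share several topical terms; members of different groups share none.
#' A multi-term signature keeps the group signal stable across the
#' binomial sampling noise of any single term, so complete-linkage
#' clustering of the resulting profiles cut at k = 2 recovers the groups.
#'
#' @inheritParams recovery_spec
#' @return A [synthetic_spec()].
#' @export
two_group_spec <- function(seed, vocab = make_toy_vocab(3, 3)) {
  leaves <- .leaf_terms(vocab)
  stopifnot(length(leaves) >= 6L)
  ent <- function(id, sig)
    list(entity_id = id, n_articles = 25L,
         planted = stats::setNames(rep(0.5, length(sig)), sig))
  entities <- c(
    lapply(1:5, function(i) ent(paste0("A", i), leaves[1:3])),
    lapply(1:5, function(i) ent(paste0("B", i), leaves[4:6])))
  synthetic_spec(seed = seed, n_background_articles = 300L,
                 base_term_probability = 0.05, entities = entities)
}

#' Write a synthetic data set as the package's TSV dialects
#'
#' Writes `vocab.tsv`, `annotations.tsv`, one `<entity>.pmids` file per
#' entity, and `ground_truth.tsv` into a directory, in exactly the formats
#' the readers consume.
#'
#' @param syn result of [generate_corpus()].
#' @param vocab the vocabulary used.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(syn, vocab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vocab_tsv(vocab, file.path(dir, "vocab.tsv"))
  write_annotations(syn$corpus, file.path(dir, "annotations.tsv"))
  for (b in syn$bibliographies)
    writeLines(as.character(b$article_ids),
               file.path(dir, paste0(b$entity_id, ".pmids")))
  gt <- syn$ground_truth
  writeLines(c("entity_id\tterm_id\tforeground_probability",
               if (nrow(gt)) paste(gt$entity_id, gt$term_id,
                                   gt$foreground_probability, sep = "\t")),
             file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
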