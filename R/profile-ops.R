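#' Reduce a profile to its most specific significant terms
#'
#' First restricts the profile to terms with `p <= alpha`, then removes every
#' retained term that is a hierarchy ancestor of another retained term.  The
#' result is an antichain under the tree order: no surviving term implies any
#' other, so general terms carried along only because a specific descendant
#' is enriched (e.g. a broad disease category above a specific disease)
#' disappear.  The significance threshold is applied before the antichain
#' reduction, so an insignificant descendant cannot shield its significant
#' ancestor.  Idempotent.
#'
#' @param object a [meshop()].
#' @param vocab the vocabulary defining the hierarchy.
#' @param alpha significance threshold in (0, 1].
#' @return The filtered profile (ordering preserved).
#' @export
filter_most_specific <- function(object, vocab, alpha = 0.05) {
  stopifnot(inherits(object, "meshop"), inherits(vocab, "mesh_vocab"),
            alpha > 0, alpha <= 1)
  s <- object$scores
  s <- s[s$p_value <= alpha, , drop = FALSE]
  if (nrow(s) > 1L) {
    present <- s$term_id
    # a term is dropped iff it is an ancestor of some other retained term
    anc_of_present <- unique(unlist(vocab$ancestor_ids[present],
                                    use.names = FALSE))
    s <- s[!(s$term_id %in% anc_of_present), , drop = FALSE]
  }
  rownames(s) <- NULL
  object$scores <- s
  object
}

#' Remove a term and its ancestors from a profile
#'
#' When a bibliography is selected *by* a query term (e.g. profiling the
#' literature of a topic term), that term and everything above it are
#' trivially enriched; this drops them so the profile shows only what the
#' articles say beyond the query itself.
#'
#' @inheritParams filter_most_specific
#' @param term_id single term ID present in `vocab`.
#' @return The profile without `term_id` and its ancestors.
#' @export
exclude_term_family <- function(object, vocab, term_id) {
  stopifnot(inherits(object, "meshop"), length(term_id) == 1L)
  .check_terms(vocab, term_id)
  drop <- c(term_id, ancestors(vocab, term_id))
  s <- object$scores[!(object$scores$term_id %in% drop), , drop = FALSE]
  rownames(s) <- NULL
  object$scores <- s
  object
}

#' Most recent articles of a bibliography up to a year
#'
#' Represents the state of a field at a time point by the `n` most recent
#' articles published in or before `year`.  Articles without a known year
#' are excluded.  Ties within a year break by descending article ID so the
#' slice is deterministic; if fewer than `n` articles qualify, all of them
#' are returned.
#'
#' @param bib a [bibliography()].
#' @param corpus a [mesh_corpus()] providing publication years.
#' @param year calendar year (inclusive upper bound).
#' @param n number of articles to keep (default 50).
#' @return A [bibliography()] (possibly empty).
#' @export
temporal_slice <- function(bib, corpus, year, n = 50L) {
  stopifnot(inherits(bib, "bibliography"), inherits(corpus, "mesh_corpus"),
            n >= 1L)
  pos <- match(bib$article_ids, corpus$article_id)
  ok <- !is.na(pos)
  ids <- bib$article_ids[ok]
  yrs <- corpus$year[pos[ok]]
  sel <- !is.na(yrs) & yrs <= year
  ids <- ids[sel]; yrs <- yrs[sel]
  ord <- order(-yrs, -ids)
  bibliography(bib$entity_id, ids[ord][seq_len(min(n, length(ids)))])
}
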