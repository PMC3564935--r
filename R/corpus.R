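#' Construct an annotated article corpus
#'
#' Holds articles with their publication year and directly assigned term IDs.
#' At construction each article's annotation is closed upward through the
#' vocabulary (an article annotated with a term counts as annotated with all
#' of that term's ancestors), and an inverted index from term to article IDs
#' is built; every downstream count works on the closed sets.  Term IDs not
#' present in the vocabulary are dropped and counted in `dropped_terms`.
#' Articles left with no resolvable term are retained but flagged; they are
#' excluded from every background.
#'
#' @param article_id integer vector of unique positive article IDs (PMIDs).
#' @param year integer vector of publication years (NA for unknown).
#' @param direct_terms list of character vectors of directly assigned term
#'   IDs, one element per article.
#' @param vocab a [mesh_vocabulary()] used to resolve terms and compute the
#'   upward closure.
#' @return An object of class `mesh_corpus`.
#' @export
mesh_corpus <- function(article_id, year, direct_terms, vocab) {
  stopifnot(inherits(vocab, "mesh_vocab"),
            length(article_id) == length(year),
            length(article_id) == length(direct_terms))
  article_id <- as.integer(article_id)
  if (anyNA(article_id) || any(article_id <= 0L))
    stop("article_id must be positive integers")
  if (anyDuplicated(article_id))
    stop("duplicate article_id: ", article_id[duplicated(article_id)][1L])
  year <- as.integer(year)

  dropped <- 0L
  known <- vocab$term_id
  direct_terms <- lapply(direct_terms, function(tt) {
    tt <- unique(as.character(tt))
    tt <- tt[nzchar(tt)]
    keep <- tt %in% known
    dropped <<- dropped + sum(!keep)
    tt[keep]
  })
  closed_terms <- lapply(direct_terms, function(tt) close_upward(vocab, tt))
  term_free <- lengths(closed_terms) == 0L

  # inverted index: term id -> sorted positions (row indices) of the
  # articles whose closed annotation contains it
  pairs_term <- unlist(closed_terms, use.names = FALSE)
  pairs_pos <- rep(seq_along(article_id), lengths(closed_terms))
  term_index <- split(pairs_pos, pairs_term)

  structure(
    list(article_id = article_id, year = year,
         direct_terms = direct_terms, closed_terms = closed_terms,
         term_free = term_free, term_index = term_index,
         dropped_terms = dropped),
    class = "mesh_corpus")
}

#' @export
print.mesh_corpus <- function(x, ...) {
  cat("Annotated corpus:", length(x$article_id), "articles (",
      sum(x$term_free), "term-free ),",
      length(x$term_index), "distinct closed terms\n")
  if (x$dropped_terms > 0L)
    cat("  dropped", x$dropped_terms, "unresolvable term references\n")
  invisible(x)
}

#' @export
length.mesh_corpus <- function(x) length(x$article_id)

#' Read an annotated corpus from tab-separated text
#'
#' Expects columns `article_id<TAB>year<TAB>terms` (header optional), with
#' term IDs semicolon-joined and the year field possibly empty.  Rows whose
#' article ID is not a positive integer are rejected with their line number.
#'
#' @param path path to a TSV file (or a connection).
#' @inheritParams mesh_corpus
#' @return A [mesh_corpus()].
#' @export
read_annotations <- function(path, vocab) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(sub("\t.*", "", lines[1L]), "article_id"))
    lines <- lines[-1L]
  if (length(lines) == 0L)
    return(mesh_corpus(integer(0), integer(0), list(), vocab))
  fields <- lapply(strsplit(lines, "\t", fixed = TRUE),
                   function(f) c(f, "", "")[1:3])
  m <- do.call(rbind, fields)
  id <- suppressWarnings(as.integer(m[, 1L]))
  bad <- which(is.na(id) | id <= 0L)
  if (length(bad))
    stop("non-integer article_id at line ", bad[1L], ": ", m[bad[1L], 1L])
  yr <- suppressWarnings(as.integer(m[, 2L]))
  tt <- lapply(strsplit(m[, 3L], ";", fixed = TRUE),
               function(x) x[nzchar(x)])
  mesh_corpus(id, yr, tt, vocab)
}

#' Write an annotated corpus as tab-separated text
#'
#' Inverse of [read_annotations()]; only direct (unclosed) annotations are
#' written, the closure being recomputed on read.
#'
#' @param corpus a [mesh_corpus()].
#' @param path output file path.
#' @export
write_annotations <- function(corpus, path) {
  stopifnot(inherits(corpus, "mesh_corpus"))
  yr <- ifelse(is.na(corpus$year), "", as.character(corpus$year))
  tt <- vapply(corpus$direct_terms, paste, "", collapse = ";")
  writeLines(c("article_id\tyear\tterms",
               paste(corpus$article_id, yr, tt, sep = "\t")),
             path)
  invisible(path)
}

#' Construct an entity bibliography
#'
#' A bibliography is the set of articles linked to one entity (a gene, a
#' disease, a chemical, a topic); it is the foreground set from which a
#' profile is computed.
#'
#' @param entity_id single identifier string.
#' @param article_ids integer vector of article IDs; duplicates collapsed.
#' @return An object of class `bibliography`.
#' @export
bibliography <- function(entity_id, article_ids) {
  stopifnot(length(entity_id) == 1L)
  structure(list(entity_id = as.character(entity_id),
                 article_ids = sort(unique(as.integer(article_ids)))),
            class = "bibliography")
}

#' @export
print.bibliography <- function(x, ...) {
  cat("Bibliography '", x$entity_id, "': ", length(x$article_ids),
      " articles\n", sep = "")
  invisible(x)
}

#' @export
length.bibliography <- function(x) length(x$article_ids)

#' Read gene-to-article links in the NCBI gene2pubmed dialect
#'
#' Tab-separated columns `tax_id`, `GeneID`, `PubMed_ID`, one link per line;
#' lines starting with `#` are comments.  Duplicated links collapse.
#'
#' @param path path to the file (or a connection).
#' @param taxon_filter optional taxon ID; only rows with this `tax_id` are
#'   kept.
#' @return Named list of [bibliography()] objects, one per gene.
#' @export
read_gene2pubmed <- function(path, taxon_filter = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("malformed gene2pubmed line ", lineno[bad[1L]])
  m <- do.call(rbind, fields)
  tax <- suppressWarnings(as.integer(m[, 1L]))
  pmid <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(tax) | is.na(pmid))
  if (length(bad))
    stop("malformed gene2pubmed line ", lineno[bad[1L]])
  if (!is.null(taxon_filter)) {
    sel <- tax == as.integer(taxon_filter)
    m <- m[sel, , drop = FALSE]; pmid <- pmid[sel]
  }
  if (nrow(m) == 0L) return(list())
  by_gene <- split(pmid, m[, 2L])
  stats::setNames(
    lapply(names(by_gene), function(g) bibliography(g, by_gene[[g]])),
    names(by_gene))
}

#' Read gene-to-article links in the GeneRIF basic dialect
#'
#' Tab-separated columns `tax_id`, `GeneID`, comma-joined PMIDs, timestamp,
#' free text (ignored).  Rows with an empty PMID field contribute nothing
#' (with a warning).
#'
#' @inheritParams read_gene2pubmed
#' @return Named list of [bibliography()] objects, one per gene.
#' @export
read_generif <- function(path, taxon_filter = NULL) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GeneRIF line ", lineno[bad[1L]])
  m <- do.call(rbind, lapply(fields, function(f) f[1:3]))
  tax <- suppressWarnings(as.integer(m[, 1L]))
  if (anyNA(tax))
    stop("malformed GeneRIF line ", lineno[which(is.na(tax))[1L]])
  if (!is.null(taxon_filter)) {
    sel <- tax == as.integer(taxon_filter)
    m <- m[sel, , drop = FALSE]; lineno <- lineno[sel]
  }
  if (nrow(m) == 0L) return(list())
  pmids <- lapply(strsplit(m[, 3L], ",", fixed = TRUE),
                  function(x) {
                    x <- suppressWarnings(as.integer(x[nzchar(x)]))
                    x[!is.na(x)]
                  })
  empty <- lengths(pmids) == 0L
  if (any(empty))
    warning(sum(empty), " GeneRIF row(s) with empty PMID list skipped")
  by_gene <- split(unlist(pmids, use.names = FALSE),
                   rep(m[, 2L], lengths(pmids)))
  stats::setNames(
    lapply(names(by_gene), function(g) bibliography(g, by_gene[[g]])),
    names(by_gene))
}

#' Read a plain list of article identifiers
#'
#' One positive integer per line; `#` comments and blank lines allowed.
#'
#' @inheritParams read_gene2pubmed
#' @param entity_id identifier to attach to the resulting bibliography.
#' @return A [bibliography()].
#' @export
read_pmid_list <- function(path, entity_id = "entity") {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  ids <- suppressWarnings(as.integer(lines))
  if (anyNA(ids))
    stop("non-integer PMID: ", lines[which(is.na(ids))[1L]])
  bibliography(entity_id, ids)
}

#' Bibliography of a vocabulary term
#'
#' Collects every article whose closed annotation contains the term; this is
#' how disease and chemical entities, which are themselves vocabulary terms,
#' obtain their bibliographies.
#'
#' @param corpus a [mesh_corpus()].
#' @param vocab the vocabulary the corpus was built against.
#' @param term_id a single term ID.
#' @return A [bibliography()] with `entity_id = term_id`.
#' @export
bibliography_from_term <- function(corpus, vocab, term_id) {
  stopifnot(inherits(corpus, "mesh_corpus"), length(term_id) == 1L)
  .check_terms(vocab, term_id)
  pos <- corpus$term_index[[term_id]]
  bibliography(term_id,
               if (is.null(pos)) integer(0) else corpus$article_id[pos])
}

#' Resolve a background article set
#'
#' The universal background is every article in the corpus carrying at least
#' one resolvable term.  A class background is the union of the articles of a
#' set of member bibliographies (for example, all articles addressing at
#' least one gene of the studied organism), again restricted to term-bearing
#' articles in the corpus; member articles absent from the corpus are
#' dropped.
#'
#' @param corpus a [mesh_corpus()].
#' @param mode `"universal"` or `"class"`.
#' @param members list of [bibliography()] objects (required for `"class"`).
#' @return Sorted integer vector of article IDs.
#' @export
resolve_background <- function(corpus, mode = c("universal", "class"),
                               members = NULL) {
  stopifnot(inherits(corpus, "mesh_corpus"))
  mode <- match.arg(mode)
  term_bearing <- corpus$article_id[!corpus$term_free]
  if (mode == "universal") return(sort(term_bearing))
  if (is.null(members) || length(members) == 0L)
    stop("class background requires a non-empty set of member bibliographies")
  ids <- unique(unlist(lapply(members, function(b) b$article_ids),
                       use.names = FALSE))
  sort(intersect(ids, term_bearing))
}
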