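#' Construct a hierarchical term vocabulary
#'
#' A `mesh_vocab` holds a set of annotation terms, each identified by a unique
#' ID and placed at zero or more positions in a hierarchy.  Positions are
#' dot-delimited tree numbers (e.g. `"C10.228.140"`): a term whose tree number
#' is a proper dot-prefix of another term's tree number is an ancestor of that
#' term.  One term may occupy several tree positions, in which case its
#' ancestors are collected from every branch.  Terms with no tree number
#' (supplementary concepts, typically chemicals) are flat: they have no
#' ancestors and are never ancestors of anything.
#'
#' @param term_id character vector of unique term identifiers.
#' @param name character vector of display names, same length as `term_id`.
#' @param tree_numbers list of character vectors, one per term; each element
#'   holds that term's tree positions (may be empty).
#' @return An object of class `mesh_vocab` with components `term_id`, `name`,
#'   `tree_numbers`, `is_supplementary`, `position_index` (named character
#'   vector mapping tree number to term ID) and `ancestor_ids` (precomputed
#'   ancestor sets, one per term).
#' @seealso [read_vocab_tsv()], [read_mesh_ascii()], [ancestors()]
#' @export
mesh_vocabulary <- function(term_id, name, tree_numbers) {
  term_id <- as.character(term_id)
  name <- as.character(name)
  stopifnot(length(term_id) == length(name),
            length(term_id) == length(tree_numbers))
  if (anyDuplicated(term_id))
    stop("duplicate term_id: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  tree_numbers <- lapply(tree_numbers, function(tn) {
    tn <- as.character(tn)
    tn <- tn[nzchar(tn)]
    if (anyDuplicated(tn)) tn <- unique(tn)
    bad <- grepl("^\\.|\\.$|\\.\\.", tn) | grepl("^$", tn)
    if (any(bad)) stop("malformed tree number: ", tn[bad][1L])
    tn
  })
  all_pos <- unlist(tree_numbers, use.names = FALSE)
  if (anyDuplicated(all_pos))
    stop("tree position occupied by more than one term: ",
         all_pos[duplicated(all_pos)][1L])
  position_index <- stats::setNames(
    rep(term_id, lengths(tree_numbers)), all_pos)

  vocab <- structure(
    list(term_id = term_id, name = name, tree_numbers = tree_numbers,
         is_supplementary = lengths(tree_numbers) == 0L,
         position_index = position_index),
    class = "mesh_vocab")
  vocab$ancestor_ids <- lapply(seq_along(term_id), function(i)
    .ancestors_of_positions(vocab, tree_numbers[[i]], term_id[i]))
  names(vocab$ancestor_ids) <- term_id
  vocab
}

# all proper dot-prefixes of one tree number, e.g. "A.B.C" -> c("A", "A.B")
.proper_prefixes <- function(tn) {
  parts <- strsplit(tn, ".", fixed = TRUE)[[1L]]
  n <- length(parts)
  if (n <= 1L) return(character(0))
  vapply(seq_len(n - 1L),
         function(k) paste(parts[seq_len(k)], collapse = "."), "")
}

# Positions absent from the vocabulary (gaps in a subset) are skipped.
.ancestors_of_positions <- function(vocab, positions, self_id) {
  if (length(positions) == 0L) return(character(0))
  pref <- unique(unlist(lapply(positions, .proper_prefixes),
                        use.names = FALSE))
  ids <- unname(vocab$position_index[pref])
  ids <- ids[!is.na(ids)]
  unique(ids[ids != self_id])
}

.check_terms <- function(vocab, term_ids) {
  miss <- setdiff(term_ids, vocab$term_id)
  if (length(miss))
    stop("unknown term_id: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Ancestors of a term
#'
#' Returns the IDs of every term occupying a proper dot-prefix of any of the
#' term's tree positions.  Prefix positions not present in the vocabulary are
#' skipped, so the result is well defined on vocabulary subsets.  Flat
#' (supplementary) terms have no ancestors.
#'
#' @param vocab a [mesh_vocabulary()].
#' @param term_id a single term ID present in `vocab`.
#' @return Character vector of ancestor term IDs (never contains `term_id`).
#' @export
ancestors <- function(vocab, term_id) {
  stopifnot(inherits(vocab, "mesh_vocab"), length(term_id) == 1L)
  .check_terms(vocab, term_id)
  vocab$ancestor_ids[[term_id]]
}

#' Upward closure of a term set
#'
#' Adds to `term_ids` every ancestor of every member.  The operation is
#' idempotent and monotone; an article annotated with a term is treated
#' downstream as annotated with its whole closure, so that specific
#' annotations also count toward every more general term above them.
#'
#' @inheritParams ancestors
#' @param term_ids character vector of term IDs, all present in `vocab`.
#' @return Character vector: `term_ids` united with all their ancestors.
#' @export
close_upward <- function(vocab, term_ids) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  if (length(term_ids) == 0L) return(character(0))
  term_ids <- unique(as.character(term_ids))
  .check_terms(vocab, term_ids)
  unique(c(term_ids,
           unlist(vocab$ancestor_ids[term_ids], use.names = FALSE)))
}

#' Test the ancestor relation between two terms
#'
#' `TRUE` iff some tree position of `a` is a proper dot-prefix of some tree
#' position of `b`.  A term is never its own ancestor, and flat supplementary
#' terms are unrelated to everything.
#'
#' @inheritParams ancestors
#' @param a,b single term IDs present in `vocab`.
#' @export
is_ancestor <- function(vocab, a, b) {
  stopifnot(inherits(vocab, "mesh_vocab"),
            length(a) == 1L, length(b) == 1L)
  .check_terms(vocab, c(a, b))
  a %in% vocab$ancestor_ids[[b]]
}

#' @export
print.mesh_vocab <- function(x, ...) {
  cat("Term vocabulary:", length(x$term_id), "terms,",
      length(x$position_index), "tree positions,",
      sum(x$is_supplementary), "supplementary (flat)\n")
  invisible(x)
}

#' @export
length.mesh_vocab <- function(x) length(x$term_id)

#' Display names for term IDs
#'
#' @inheritParams ancestors
#' @param term_ids character vector of term IDs.
#' @return Character vector of names; unknown IDs are returned unchanged.
#' @export
term_names <- function(vocab, term_ids) {
  i <- match(term_ids, vocab$term_id)
  out <- vocab$name[i]
  out[is.na(i)] <- term_ids[is.na(i)]
  out
}

#' Read a vocabulary from tab-separated text
#'
#' Expects a header line `term_id<TAB>name<TAB>tree_numbers` with tree numbers
#' semicolon-joined; an empty third column yields a flat supplementary-style
#' term.
#'
#' @param path path to a TSV file (or a connection).
#' @return A [mesh_vocabulary()].
#' @export
read_vocab_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L)
    return(mesh_vocabulary(character(0), character(0), list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # a trailing empty tree_numbers column is dropped by strsplit
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop("expected 3 tab-separated columns at line ", bad[1L])
  fields <- lapply(fields, function(f) c(f, "", "")[1:3])
  m <- do.call(rbind, fields)
  hdr <- 1L
  if (!identical(m[1L, 1L], "term_id"))
    hdr <- 0L  # tolerate a missing header
  if (nrow(m) <= hdr)
    return(mesh_vocabulary(character(0), character(0), list()))
  body <- m[(hdr + 1L):nrow(m), , drop = FALSE]
  tn <- lapply(strsplit(body[, 3L], ";", fixed = TRUE),
               function(x) x[nzchar(x)])
  mesh_vocabulary(body[, 1L], body[, 2L], tn)
}

#' Write a vocabulary as tab-separated text
#'
#' Inverse of [read_vocab_tsv()].
#'
#' @inheritParams ancestors
#' @param path output file path.
#' @export
write_vocab_tsv <- function(vocab, path) {
  stopifnot(inherits(vocab, "mesh_vocab"))
  tn <- vapply(vocab$tree_numbers, paste, "", collapse = ";")
  writeLines(c("term_id\tname\ttree_numbers",
               paste(vocab$term_id, vocab$name, tn, sep = "\t")),
             path)
  invisible(path)
}

#' Read a vocabulary from the NLM descriptor ASCII format
#'
#' Parses the plain-text descriptor dialect in which records start with a
#' `*NEWRECORD` line and carry `UI = `, `MH = ` and `MN = ` fields (one tree
#' number per `MN` line).  All other field codes are ignored.
#'
#' @param path path to the descriptor file (or a connection).
#' @return A [mesh_vocabulary()].
#' @export
read_mesh_ascii <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\*NEWRECORD\\s*$", lines)
  if (length(starts) == 0L)
    return(mesh_vocabulary(character(0), character(0), list()))
  ends <- c(starts[-1L] - 1L, length(lines))
  recs <- Map(function(s, e) lines[seq(s, e)], starts, ends)
  get_field <- function(rec, code) {
    pat <- paste0("^", code, " = ")
    sub(pat, "", rec[grepl(pat, rec)])
  }
  ui <- character(length(recs)); mh <- character(length(recs))
  mn <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    u <- get_field(recs[[i]], "UI")
    h <- get_field(recs[[i]], "MH")
    if (length(u) != 1L)
      stop("record ", i, " must have exactly one UI field")
    if (length(h) != 1L)
      stop("record ", i, " (UI ", u, ") must have exactly one MH field")
    ui[i] <- u; mh[i] <- h
    mn[[i]] <- get_field(recs[[i]], "MN")
  }
  if (anyDuplicated(ui))
    stop("duplicate UI across records: ", ui[duplicated(ui)][1L])
  mesh_vocabulary(ui, mh, mn)
}
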