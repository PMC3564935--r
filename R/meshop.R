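#' One-sided Fisher's exact test for over-representation
#'
#' Upper-tail probability of the 2x2 table with cells `a` (foreground
#' articles carrying the term), `b` (foreground without it), `c`
#' (background-only articles carrying it) and `d` (the remainder): the
#' chance that a term this prevalent or more would appear in an
#' equally sized article set drawn uniformly at random from the background.
#' Computed as the hypergeometric tail P(X >= a) with population
#' `a+b+c+d`, `a+c` successes and `a+b` draws, evaluated in log space so
#' p-values down to the smallest representable double survive.
#'
#' All arguments are vectorized and recycled.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisher_greater <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0, na.rm = TRUE))
    stop("contingency cells must be non-negative")
  # P(X >= a) = 1 when a == 0; phyper handles the boundary correctly
  p <- stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  pmin(p, 1)
}

#' Compute a term over-representation profile (MeSHOP)
#'
#' Fits the profile of one entity: for every vocabulary term occurring in
#' the entity's articles (after upward closure of the annotations), builds
#' the 2x2 contingency table of the term against the background and scores
#' it with a one-sided Fisher's exact test.  Terms counted once per article
#' regardless of how many descendants implied them.  The result is a vector
#' of (term, p-value) pairs ordered by ascending p-value, ties broken by
#' term ID, so profiles are reproducible byte for byte.
#'
#' Foreground articles absent from the corpus, or carrying no resolvable
#' term, are dropped (their count is recorded in `n_dropped`); the
#' remaining foreground must be a subset of the background.
#'
#' @param foreground a [bibliography()], or an integer vector of article IDs.
#' @param corpus a [mesh_corpus()].
#' @param vocab the vocabulary the corpus was built against.
#' @param background `"universal"` (default), `"class"`, or an integer
#'   vector of article IDs to use directly.
#' @param members list of member bibliographies, required when
#'   `background = "class"` (see [resolve_background()]).
#' @param min_count minimum foreground occurrence count for a term to be
#'   scored (default 1: every occurring term is reported; significance
#'   thresholds belong downstream).
#' @return An object of class `meshop`: a list with `entity_id`, `scores`
#'   (data frame with columns `term_id`, `term_name`, `a`, `fg_size`, `k`,
#'   `bg_size`, `p_value`), `fg_size`, `n_dropped` (foreground articles not
#'   in the corpus) and `background` (mode and size).
#' @examples
#' vocab <- make_toy_vocab(depth = 2, branching = 2)
#' syn <- generate_corpus(synthetic_spec(seed = 1, n_background_articles = 50,
#'   entities = list(list(entity_id = "g1", n_articles = 10,
#'                        planted = c(N1_1 = 0.8)))), vocab)
#' m <- meshop(syn$bibliographies[["g1"]], syn$corpus, vocab)
#' head(as.data.frame(m))
#' @export
meshop <- function(foreground, corpus, vocab,
                   background = "universal", members = NULL,
                   min_count = 1L) {
  stopifnot(inherits(corpus, "mesh_corpus"), inherits(vocab, "mesh_vocab"),
            min_count >= 1L)
  if (inherits(foreground, "bibliography")) {
    entity_id <- foreground$entity_id
    fg_ids <- foreground$article_ids
  } else {
    entity_id <- "entity"
    fg_ids <- sort(unique(as.integer(foreground)))
  }
  if (is.character(background)) {
    bg_mode <- match.arg(background, c("universal", "class"))
    bg_ids <- resolve_background(corpus, bg_mode, members)
  } else {
    bg_mode <- "explicit"
    # explicit backgrounds are restricted to term-bearing corpus articles,
    # the universe over which term counts are defined
    bg_ids <- sort(intersect(unique(as.integer(background)),
                             corpus$article_id[!corpus$term_free]))
  }

  # foreground articles absent from the corpus or carrying no resolvable
  # term cannot enter the test universe; drop them with a count
  pos0 <- match(fg_ids, corpus$article_id)
  usable <- !is.na(pos0) & !corpus$term_free[ifelse(is.na(pos0), 1L, pos0)]
  n_dropped <- sum(!usable)
  fg_ids <- fg_ids[usable]
  if (length(fg_ids) == 0L)
    stop("empty foreground after resolving against the corpus")
  outside <- setdiff(fg_ids, bg_ids)
  if (length(outside))
    stop("foreground articles outside the background: ",
         paste(utils::head(outside, 5L), collapse = ", "),
         if (length(outside) > 5L) " ..." else "")

  fg_size <- length(fg_ids)
  bg_size <- length(bg_ids)

  pos <- match(fg_ids, corpus$article_id)
  fg_terms <- unlist(corpus$closed_terms[pos], use.names = FALSE)
  a_tab <- table(fg_terms)
  a <- as.integer(a_tab)
  tid <- names(a_tab)
  keep <- a >= min_count
  a <- a[keep]; tid <- tid[keep]

  if (length(tid) == 0L) {
    scores <- data.frame(term_id = character(0), term_name = character(0),
                         a = integer(0), fg_size = integer(0),
                         k = integer(0), bg_size = integer(0),
                         p_value = numeric(0), stringsAsFactors = FALSE)
  } else {
    bg_mask <- logical(length(corpus$article_id))
    bg_mask[match(bg_ids, corpus$article_id)] <- TRUE
    k <- vapply(tid, function(t)
      sum(bg_mask[corpus$term_index[[t]]]), 0L)
    b <- fg_size - a
    cc <- k - a
    d <- bg_size - fg_size - cc
    p <- fisher_greater(a, b, cc, d)
    ord <- order(p, tid)
    scores <- data.frame(term_id = tid, term_name = term_names(vocab, tid),
                         a = a, fg_size = fg_size, k = as.integer(k),
                         bg_size = bg_size, p_value = p,
                         stringsAsFactors = FALSE)[ord, ]
    rownames(scores) <- NULL
  }

  structure(
    list(entity_id = entity_id, scores = scores, fg_size = fg_size,
         n_dropped = n_dropped,
         background = list(mode = bg_mode, size = bg_size)),
    class = "meshop")
}

#' Bonferroni correction across entities
#'
#' Multiplies every p-value in the profile by the number of entities
#' profiled in the same family (e.g. the number of diseases) and caps at 1.
#' The uncorrected p-values are kept alongside in `p_value`; the corrected
#' ones are added as `p_bonferroni`.  Ordering is unchanged.
#'
#' @param object a [meshop()].
#' @param n number of entities in the family (>= 1).
#' @return The profile with a `p_bonferroni` column added.
#' @export
bonferroni <- function(object, n) {
  stopifnot(inherits(object, "meshop"))
  if (n < 1) stop("n must be >= 1")
  object$scores$p_bonferroni <- pmin(object$scores$p_value * n, 1)
  object
}

#' @export
print.meshop <- function(x, n = 10L, ...) {
  cat("Term over-representation profile for '", x$entity_id, "'\n", sep = "")
  cat("  foreground:", x$fg_size, "articles",
      if (x$n_dropped > 0L) paste0("(", x$n_dropped, " dropped)") else "",
      "\n")
  cat("  background:", x$background$mode, "(", x$background$size,
      "articles )\n")
  cat("  terms scored:", nrow(x$scores), "\n")
  if (nrow(x$scores)) {
    cat("  top terms:\n")
    top <- utils::head(x$scores, n)
    print(data.frame(term = top$term_name, a = top$a, k = top$k,
                     p = signif(top$p_value, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.meshop <- function(object, alpha = 0.05, ...) {
  s <- object$scores
  out <- list(entity_id = object$entity_id, fg_size = object$fg_size,
              background = object$background, n_terms = nrow(s),
              n_significant = sum(s$p_value <= alpha), alpha = alpha,
              min_p = if (nrow(s)) min(s$p_value) else NA_real_)
  class(out) <- "summary.meshop"
  out
}

#' @export
print.summary.meshop <- function(x, ...) {
  cat("Profile '", x$entity_id, "': ", x$n_terms, " terms over ",
      x$fg_size, " articles (", x$background$mode, " background, ",
      x$background$size, " articles)\n", sep = "")
  cat("  ", x$n_significant, " terms at p <= ", x$alpha,
      "; smallest p = ", signif(x$min_p, 3), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.meshop <- function(x, ...) x$scores

#' Bar plot of the strongest terms in a profile
#'
#' @param x a [meshop()].
#' @param top_k number of terms to show.
#' @param cap floor applied to p-values before the -log10 transform.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.meshop <- function(x, top_k = 20L, cap = 1e-30, ...) {
  s <- utils::head(x$scores, top_k)
  if (nrow(s) == 0L) {
    warning("empty profile; nothing to plot")
    return(invisible(x))
  }
  w <- rev(-log10(pmax(s$p_value, cap)))
  graphics::barplot(w, names.arg = rev(s$term_name), horiz = TRUE,
                    las = 1, xlab = expression(-log[10](p)),
                    main = x$entity_id, ...)
  invisible(x)
}

#' Write a profile as tab-separated text
#'
#' Columns: `term_id`, `term_name`, `a`, `fg_size`, `k`, `bg_size`,
#' `p_value`, `p_bonferroni` (empty if not computed), `neg_log10_p`;
#' rows in profile order.
#'
#' @param object a [meshop()].
#' @param path output file path.
#' @export
write_profile_tsv <- function(object, path) {
  stopifnot(inherits(object, "meshop"))
  s <- object$scores
  pb <- if ("p_bonferroni" %in% names(s))
    formatC(s$p_bonferroni, digits = 15, format = "g") else
    rep("", nrow(s))
  lines <- c(
    paste0("# entity_id=", object$entity_id,
           " fg_size=", object$fg_size,
           " background=", object$background$mode,
           " bg_size=", object$background$size),
    paste("term_id", "term_name", "a", "fg_size", "k", "bg_size",
          "p_value", "p_bonferroni", "neg_log10_p", sep = "\t"))
  if (nrow(s))
    lines <- c(lines, paste(
      s$term_id, s$term_name, s$a, s$fg_size, s$k, s$bg_size,
      formatC(s$p_value, digits = 15, format = "g"), pb,
      formatC(-log10(s$p_value), digits = 10, format = "g"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a profile written by [write_profile_tsv()]
#'
#' @param path path to the TSV file.
#' @return A [meshop()].
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  meta <- list(entity_id = "entity", fg_size = 0L,
               mode = "explicit", bg_size = 0L)
  if (length(lines) && startsWith(lines[1L], "#")) {
    kv <- regmatches(lines[1L],
                     gregexpr("[A-Za-z_]+=[^ ]+", lines[1L]))[[1L]]
    for (p in kv) {
      key <- sub("=.*", "", p); val <- sub("^[^=]+=", "", p)
      if (key == "entity_id") meta$entity_id <- val
      if (key == "fg_size") meta$fg_size <- as.integer(val)
      if (key == "background") meta$mode <- val
      if (key == "bg_size") meta$bg_size <- as.integer(val)
    }
    lines <- lines[-1L]
  }
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE,
                          colClasses = c(term_id = "character"))
  scores <- data.frame(term_id = as.character(df$term_id),
                       term_name = as.character(df$term_name),
                       a = as.integer(df$a),
                       fg_size = as.integer(df$fg_size),
                       k = as.integer(df$k),
                       bg_size = as.integer(df$bg_size),
                       p_value = as.numeric(df$p_value),
                       stringsAsFactors = FALSE)
  if ("p_bonferroni" %in% names(df) && !all(is.na(df$p_bonferroni)))
    scores$p_bonferroni <- as.numeric(df$p_bonferroni)
  structure(
    list(entity_id = meta$entity_id, scores = scores,
         fg_size = if (nrow(scores)) scores$fg_size[1L] else meta$fg_size,
         n_dropped = 0L,
         background = list(mode = meta$mode,
                           size = if (nrow(scores)) scores$bg_size[1L]
                                  else meta$bg_size)),
    class = "meshop")
}
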