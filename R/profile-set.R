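#' Assemble profiles into a weight matrix for comparison
#'
#' Stacks several entity profiles into an entities x terms matrix of
#' transformed p-values, the representation used for distances and
#' clustering.  Weights are `-log10(max(p, cap))`: the cap keeps one
#' extremely studied term from dominating every distance.  Under the
#' `"shared"` policy the columns are the terms present in every profile
#' (the default comparison); under `"union"` all terms appear and an entity
#' missing a term gets weight 0, i.e. is treated as if the term had p = 1.
#'
#' @param meshops list of two or more [meshop()] objects.
#' @param term_policy `"shared"` or `"union"`.
#' @param log_base base of the logarithm for the weight transform.
#' @param cap p-value floor in (0, 1), default `1e-30`.
#' @return An object of class `profile_set`: list with `entity_ids`,
#'   `term_ids`, `weights` (matrix, rows = entities) and the transform
#'   parameters.
#' @export
profile_set <- function(meshops, term_policy = c("shared", "union"),
                        log_base = 10, cap = 1e-30) {
  term_policy <- match.arg(term_policy)
  stopifnot(length(meshops) >= 2L, cap > 0, cap < 1)
  lapply(meshops, function(m) stopifnot(inherits(m, "meshop")))
  entity_ids <- vapply(meshops, function(m) m$entity_id, "")
  if (anyDuplicated(entity_ids))
    entity_ids <- make.unique(entity_ids)
  term_lists <- lapply(meshops, function(m) m$scores$term_id)
  term_ids <- if (term_policy == "shared")
    Reduce(intersect, term_lists) else
    Reduce(union, term_lists)
  if (length(term_ids) == 0L) {
    if (term_policy == "shared")
      stop("profiles share no terms; use term_policy = \"union\"")
    stop("no terms in any profile")
  }
  term_ids <- sort(term_ids)
  w <- matrix(0, nrow = length(meshops), ncol = length(term_ids),
              dimnames = list(entity_ids, term_ids))
  for (i in seq_along(meshops)) {
    s <- meshops[[i]]$scores
    j <- match(s$term_id, term_ids)
    ok <- !is.na(j)
    w[i, j[ok]] <- -log(pmax(s$p_value[ok], cap), base = log_base)
  }
  structure(list(entity_ids = entity_ids, term_ids = term_ids, weights = w,
                 term_policy = term_policy, log_base = log_base, cap = cap),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat("Profile set:", length(x$entity_ids), "entities x",
      length(x$term_ids), "terms (", x$term_policy, "policy, -log base",
      x$log_base, ", cap", format(x$cap), ")\n")
  invisible(x)
}

#' @export
dim.profile_set <- function(x) dim(x$weights)

#' Euclidean distance between two entities of a profile set
#'
#' Standard Euclidean distance between the two entities' rows of transformed
#' p-values.
#'
#' @param ps a [profile_set()].
#' @param i,j entity indices (integer) or entity IDs (character).
#' @return A single non-negative number.
#' @seealso [profile_dist()] for the full distance matrix.
#' @export
euclidean_distance <- function(ps, i, j) {
  stopifnot(inherits(ps, "profile_set"))
  ij <- c(i, j)
  if (is.character(ij)) ij <- match(ij, ps$entity_ids)
  if (anyNA(ij) || any(ij < 1L) || any(ij > nrow(ps$weights)))
    stop("entity index out of range")
  sqrt(sum((ps$weights[ij[1L], ] - ps$weights[ij[2L], ])^2))
}

#' Pairwise Euclidean distances of a profile set
#'
#' @param ps a [profile_set()].
#' @return A [stats::dist] object over the entities.
#' @export
profile_dist <- function(ps) {
  stopifnot(inherits(ps, "profile_set"))
  stats::dist(ps$weights, method = "euclidean")
}

#' Complete-linkage clustering of entity profiles
#'
#' Agglomerative hierarchical clustering of the entities using complete
#' linkage on the pairwise Euclidean distances of the transformed p-value
#' vectors.  Complete linkage guarantees monotone merge heights.  The result
#' is a standard [stats::hclust] tree, so [stats::cutree()] and `plot()`
#' apply directly.
#'
#' @param ps a [profile_set()] with at least two entities.
#' @return An object of class `hclust`.
#' @export
cluster_complete <- function(ps) {
  stopifnot(inherits(ps, "profile_set"))
  if (nrow(ps$weights) < 2L) stop("need at least 2 entities to cluster")
  stats::hclust(profile_dist(ps), method = "complete")
}

#' Restrict profiles to a named term panel
#'
#' Builds a profile set over exactly the named terms (union policy: an
#' entity lacking a term gets weight 0).  This supports entity-vs-entity
#' views such as scoring each vitamin's profile against the panel of all
#' vitamin terms.
#'
#' @inheritParams profile_set
#' @param term_ids non-empty character vector of term IDs to keep, in the
#'   requested column order.
#' @return A [profile_set()] whose columns are exactly `term_ids`.
#' @export
cooccurrence_submatrix <- function(meshops, term_ids, log_base = 10,
                                   cap = 1e-30) {
  stopifnot(length(term_ids) >= 1L)
  term_ids <- as.character(term_ids)
  present <- unique(unlist(lapply(meshops, function(m) m$scores$term_id),
                           use.names = FALSE))
  if (!any(term_ids %in% present))
    stop("none of the requested terms occurs in any profile")
  ps <- profile_set(meshops, term_policy = "union", log_base = log_base,
                    cap = cap)
  w <- matrix(0, nrow = length(ps$entity_ids), ncol = length(term_ids),
              dimnames = list(ps$entity_ids, term_ids))
  j <- match(term_ids, ps$term_ids)
  ok <- !is.na(j)
  w[, ok] <- ps$weights[, j[ok], drop = FALSE]
  ps$term_ids <- term_ids
  ps$weights <- w
  ps
}

#' Write a square distance matrix as tab-separated text
#'
#' @param d a [stats::dist] object (as from [profile_dist()]).
#' @param path output file path.
#' @export
write_dist_tsv <- function(d, path) {
  m <- as.matrix(d)
  lines <- c(paste(c("entity_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i],
                       formatC(m[i, ], digits = 10, format = "g")),
                     collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write a dendrogram merge table as tab-separated text
#'
#' One row per merge with the two merged clusters (negative numbers are
#' leaves, positive numbers earlier merges, as in [stats::hclust]), the
#' merge height, and the size of the resulting cluster.
#'
#' @param hc an `hclust` object.
#' @param path output file path.
#' @export
write_merges_tsv <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  sizes <- integer(nrow(hc$merge))
  size_of <- function(x) if (x < 0) 1L else sizes[x]
  for (i in seq_len(nrow(hc$merge)))
    sizes[i] <- size_of(hc$merge[i, 1L]) + size_of(hc$merge[i, 2L])
  lines <- c("cluster1\tcluster2\theight\tsize",
             paste(hc$merge[, 1L], hc$merge[, 2L],
                   formatC(hc$height, digits = 10, format = "g"),
                   sizes, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
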