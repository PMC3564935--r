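#' Convert a profile to word-cloud entries
#'
#' Takes the `top_k` strongest terms (profile order, i.e. ascending p with
#' deterministic term-ID tie-break) and maps each p-value to the weight
#' `-log10(max(p, cap))`, the font-size weight of tag-cloud renderers.  With
#' the default cap of `1e-30` weights lie in [0, 30].  Entries whose weight
#' is 0 (p = 1) are dropped.  Multi-word term names are kept intact
#' downstream by a non-breaking join (see [write_tagcloud()]).
#'
#' @param object a [meshop()].
#' @param top_k maximum number of entries (default 150).
#' @param cap p-value floor in (0, 1), default `1e-30`.
#' @return Data frame of class `cloud_entries` with columns `label` and
#'   `weight`, ordered as in the profile.
#' @export
to_cloud <- function(object, top_k = 150L, cap = 1e-30) {
  stopifnot(inherits(object, "meshop"), top_k >= 1L, cap > 0, cap < 1)
  s <- utils::head(object$scores, top_k)
  w <- -log10(pmax(s$p_value, cap))
  keep <- w > 0
  out <- data.frame(label = s$term_name[keep], weight = w[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("cloud_entries", "data.frame")
  out
}

# non-breaking space keeps multi-word labels as one cloud token
.NBSP <- "\u00a0"

#' Write word-cloud entries in the advanced tag-cloud text format
#'
#' One `label:weight` line per entry, suitable for pasting into tag-cloud
#' tools that accept weighted words.  Internal whitespace in labels is
#' replaced by non-breaking spaces so layout engines treat each term as a
#' single token.  Weights are printed with 4 significant digits.
#'
#' @param entries as returned by [to_cloud()].
#' @param path output file path (or a connection).
#' @export
write_tagcloud <- function(entries, path) {
  labels <- gsub("[ \t]+", .NBSP, entries$label)
  if (any(!nzchar(labels))) stop("empty label")
  lines <- if (length(labels) == 0L) character(0) else
    paste0(labels, ":",
           trimws(formatC(entries$weight, digits = 4, format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' Read tag-cloud text written by [write_tagcloud()]
#'
#' @param path path to the file (or a connection).
#' @return Data frame with columns `label` and `weight`.
#' @export
read_tagcloud <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(label = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    label <- sub(":[^:]*$", "", lines)
    weight <- as.numeric(sub(".*:", "", lines))
    out <- data.frame(label = gsub(.NBSP, " ", label), weight = weight,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("cloud_entries", "data.frame")
  out
}
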