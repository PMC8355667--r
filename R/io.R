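#' Read a hypergraph from a text or JSON file
#'
#' Two on-disk dialects are supported.
#'
#' * `"text"`: one hyperedge per line, whitespace-separated node labels,
#'   optionally followed by a trailing `#k` token giving the hyperedge's
#'   category. Blank lines and lines starting with `%` are skipped. Node
#'   labels are mapped to internal indices in order of first appearance.
#' * `"json"`: an object with fields `n`, `nodes` (labels), `hyperedges`
#'   (each `{"nodes": [...], "category": k}`), as written by
#'   [write_hypergraph()].
#'
#' Writing then reading reproduces node count, hyperedges and categories.
#' Hyperedges of size 1 are tolerated with a warning (they contribute only
#' diagonal co-membership weight).
#'
#' @param path input file.
#' @param format `"auto"` (by file extension), `"text"` or `"json"`.
#' @return a `hypergraph`.
#' @export
read_hypergraph <- function(path, format = c("auto", "text", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "text"
  if (format == "json") read_hypergraph_json(path) else
    read_hypergraph_text(path)
}

read_hypergraph_text <- function(path) {
  lines <- readLines(path)
  labels <- character(0)
  edges <- list()
  category <- integer(0)
  any_cat <- FALSE
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "%")) next
    toks <- strsplit(raw, "[[:space:]]+")[[1]]
    k <- NA_integer_
    last <- toks[length(toks)]
    if (startsWith(last, "#")) {
      k <- suppressWarnings(as.integer(sub("^#", "", last)))
      if (is.na(k) || k < 1L)
        stop("line ", ln, ": malformed category token '", last, "'")
      toks <- toks[-length(toks)]
      any_cat <- TRUE
    }
    if (length(toks) == 0L)
      stop("line ", ln, ": hyperedge has no nodes")
    if (anyDuplicated(toks))
      stop("line ", ln, ": duplicate node in hyperedge ('",
           toks[anyDuplicated(toks)], "')")
    if (length(toks) == 1L)
      warning("line ", ln, ": hyperedge of size 1 (diagonal weight only)")
    new <- setdiff(toks, labels)
    labels <- c(labels, new)
    edges[[length(edges) + 1L]] <- match(toks, labels)
    category <- c(category, k)
  }
  if (any_cat && anyNA(category))
    stop("some hyperedges have a category token and some do not")
  hypergraph(edges, n = length(labels),
             category = if (any_cat) category else NULL,
             labels = if (length(labels)) labels else NULL)
}

read_hypergraph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$n)) stop("JSON hypergraph is missing field 'n'")
  he <- obj$hyperedges
  if (is.null(he)) he <- list()
  nodes_of <- if (is.data.frame(he)) he$nodes else
    lapply(he, function(e) e$nodes)
  cats <- if (is.data.frame(he)) he$category else
    vapply(he, function(e) e$category %||% NA_integer_, numeric(1))
  labels <- obj$nodes
  edges <- lapply(nodes_of, function(nd) {
    if (!is.null(labels)) match(as.character(nd), labels) else as.integer(nd)
  })
  has_cat <- length(cats) > 0 && !all(is.na(cats))
  hypergraph(edges, n = as.integer(obj$n),
             category = if (has_cat) as.integer(cats) else NULL,
             K = if (has_cat && !is.null(obj$K)) as.integer(obj$K) else NULL,
             labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a hypergraph to a text or JSON file
#'
#' @param H a `hypergraph`.
#' @param path output file.
#' @param format `"auto"` (by extension), `"text"` or `"json"`; see
#'   [read_hypergraph()] for the dialects.
#' @export
write_hypergraph <- function(H, path, format = c("auto", "text", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "text"
  labels <- H$labels %||% as.character(seq_len(H$n))
  if (format == "text") {
    lines <- vapply(seq_along(H$edges), function(h) {
      s <- paste(labels[H$edges[[h]]], collapse = " ")
      if (!is.null(H$category)) s <- paste0(s, " #", H$category[h])
      s
    }, character(1))
    writeLines(lines, path)
  } else {
    he <- lapply(seq_along(H$edges), function(h) {
      e <- list(nodes = labels[H$edges[[h]]])
      if (!is.null(H$category)) e$category <- H$category[h]
      e
    })
    jsonlite::write_json(
      list(n = H$n, K = if (!is.null(H$category)) H$K else NULL,
           nodes = labels, hyperedges = he),
      path, auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}
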