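#' Construct a terminology graph
#'
#' A minimal stand-in for a licensed clinical vocabulary: a set of concept
#' identifiers with preferred terms, a many-to-one map from normalized
#' surface terms to concepts (synonyms such as "structure of heart" and
#' "cardiac" share one concept), and is-a edges. Edges are traversed
#' undirected for shortest paths — the path measure walks the hierarchy both
#' up and down. The graph may be disconnected.
#'
#' @param concepts Tibble or data.frame with columns `id`, `preferred_term`.
#' @param term_map Named character vector: `names()` are normalized surface
#'   terms, values are concept ids.
#' @param edges Two-column matrix/data.frame of concept-id pairs (is-a
#'   child, parent); may have zero rows.
#' @return A `terminology_graph` object.
#' @export
terminology_graph <- function(concepts, term_map, edges = NULL) {
  concepts <- tibble::as_tibble(concepts)
  stopifnot(all(c("id", "preferred_term") %in% names(concepts)))
  concepts$id <- as.character(concepts$id)
  if (anyDuplicated(concepts$id)) {
    stop("duplicate concept id(s) in terminology", call. = FALSE)
  }
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(as.data.frame(edges)[, 1:2])
    storage.mode(edges) <- "character"
  }
  undeclared <- setdiff(unique(as.vector(edges)), concepts$id)
  if (length(undeclared) > 0) {
    stop("edge endpoint(s) not declared as concepts: ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  term_map <- unlist(term_map)
  if (length(term_map) > 0) {
    names(term_map) <- normalize_term(names(term_map))
    bad <- setdiff(unique(term_map), concepts$id)
    if (length(bad) > 0) {
      stop("term_map target(s) not declared as concepts: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(names(term_map))) {
      stop("term_map must be many-to-one: duplicate surface term(s) ",
           paste(unique(names(term_map)[duplicated(names(term_map))]),
                 collapse = ", "), call. = FALSE)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(concepts), name = concepts$id)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  structure(
    list(concepts = concepts, term_map = term_map, edges = edges, graph = g),
    class = "terminology_graph")
}

#' @export
print.terminology_graph <- function(x, ...) {
  cat("<terminology_graph: ", nrow(x$concepts), " concepts, ",
      nrow(x$edges), " is-a edges, ", length(x$term_map),
      " surface terms>\n", sep = "")
  invisible(x)
}

#' Read a terminology file
#'
#' UTF-8 tab-separated with three record kinds:
#' `CONCEPT <id> <preferred term>`, `ISA <child id> <parent id>`, and
#' `TERM <surface term> <id>`.
#'
#' @param path File to read.
#' @return A [terminology_graph()].
#' @export
read_terminology <- function(path) {
  if (!file.exists(path)) stop("terminology file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1)
  bad <- setdiff(unique(kind), c("CONCEPT", "ISA", "TERM"))
  if (length(bad) > 0) {
    stop("unknown terminology record kind(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  get2 <- function(p) p[[2]]
  get3 <- function(p) p[[3]]
  cp <- parts[kind == "CONCEPT"]
  concepts <- tibble::tibble(
    id = vapply(cp, get2, character(1)),
    preferred_term = vapply(cp, get3, character(1)))
  ip <- parts[kind == "ISA"]
  edges <- if (length(ip) > 0) {
    cbind(vapply(ip, get2, character(1)), vapply(ip, get3, character(1)))
  } else NULL
  tp <- parts[kind == "TERM"]
  term_map <- if (length(tp) > 0) {
    setNames(vapply(tp, get3, character(1)), vapply(tp, get2, character(1)))
  } else character(0)
  terminology_graph(concepts, term_map, edges)
}

#' Write a terminology file
#'
#' @param tg A [terminology_graph()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_terminology <- function(tg, path) {
  lines <- c(
    paste("CONCEPT", tg$concepts$id, tg$concepts$preferred_term, sep = "\t"),
    if (nrow(tg$edges) > 0)
      paste("ISA", tg$edges[, 1], tg$edges[, 2], sep = "\t"),
    if (length(tg$term_map) > 0)
      paste("TERM", names(tg$term_map), unname(tg$term_map), sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Map a surface term to its concept
#'
#' Exact-string lookup (after canonical normalization) in the term map.
#'
#' @param tg A [terminology_graph()].
#' @param term Character vector of surface terms.
#' @return Character vector of concept ids, `NA` where unknown.
#' @export
map_term <- function(tg, term) {
  unname(tg$term_map[normalize_term(term)])
}

#' Shortest-path node count between two concepts
#'
#' Counts the NODES on the shortest undirected path, inclusive of both
#' endpoints: identical concepts give 1, a parent and child give 2,
#' siblings with no direct edge give 3. `NA` when no path exists.
#'
#' @param tg A [terminology_graph()].
#' @param a,b Concept ids (vectors are paired elementwise).
#' @return Integer vector of node counts, `NA` where disconnected.
#' @export
path_length <- function(tg, a, b) {
  known <- tg$concepts$id
  bad <- setdiff(unique(c(a, b)), known)
  if (length(bad) > 0) {
    stop("undeclared concept id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ua <- unique(a)
  ub <- unique(b)
  d <- igraph::distances(tg$graph, v = ua, to = ub)
  out <- d[cbind(match(a, ua), match(b, ub))]
  out[is.infinite(out)] <- NA
  as.integer(out) + 1L
}

#' Path-measure similarity between two surface terms
#'
#' Maps both terms to concepts and returns `1 / l` where `l` is the
#' shortest-path node count ([path_length()]). Identical concepts give 1.
#' If either term is unmapped, or the two concepts lie in different
#' components, the sentinel −1 is returned; the score is therefore always
#' in (0, 1] or exactly −1, never 0. Note that an unmapped term scores −1
#' even against itself: similarity is defined on the terminology, not on
#' strings.
#'
#' @param tg A [terminology_graph()].
#' @param term_a,term_b Character vectors of surface terms, paired
#'   elementwise.
#' @return Numeric vector of similarities.
#' @export
path_similarity <- function(tg, term_a, term_b) {
  ca <- map_term(tg, term_a)
  cb <- map_term(tg, term_b)
  out <- rep(-1, length(ca))
  ok <- !is.na(ca) & !is.na(cb)
  if (any(ok)) {
    l <- path_length(tg, ca[ok], cb[ok])
    sim <- 1 / l
    sim[is.na(l)] <- -1
    out[ok] <- sim
  }
  out
}

# All-pairs similarity between two term vectors; rows = terms_a, cols =
# terms_b. Computes concept-level distances once per unique concept pair.
term_similarity_matrix <- function(tg, terms_a, terms_b) {
  ca <- map_term(tg, terms_a)
  cb <- map_term(tg, terms_b)
  out <- matrix(-1, nrow = length(terms_a), ncol = length(terms_b),
                dimnames = list(terms_a, terms_b))
  ua <- unique(ca[!is.na(ca)])
  ub <- unique(cb[!is.na(cb)])
  if (length(ua) == 0 || length(ub) == 0) return(out)
  d <- igraph::distances(tg$graph, v = ua, to = ub) + 1
  sim <- 1 / d
  sim[is.infinite(d)] <- -1
  ia <- match(ca, ua)
  ib <- match(cb, ub)
  ok_a <- which(!is.na(ia))
  ok_b <- which(!is.na(ib))
  out[ok_a, ok_b] <- sim[ia[ok_a], ib[ok_b], drop = FALSE]
  out
}
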