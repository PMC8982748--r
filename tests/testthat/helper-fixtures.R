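# Row builder for annotation records.
ann_row <- function(patient = "P0001", doc = "CN-P0001-1", corpus = "CN",
                    date = "2016-03-10", section = "Diagnosis",
                    term = "chest pain", group = "FIND",
                    experiencer = "Patient", cui = "", assertion = "Present") {
  tibble::tibble(
    patient_id = patient, document_id = doc, corpus_tag = corpus,
    note_date = as.Date(date), section = section, term = term, cui = cui,
    semantic_group = group, experiencer = experiencer, assertion = assertion)
}

ann_rows <- function(...) dplyr::bind_rows(...)

# Hand-built toy terminology:
#
#        heart (K1)
#        /        \
#   valve (K2)   muscle (K3)
#      |
#   mitral (K4)        island (K9, disconnected)
toy_graph <- function() {
  terminology_graph(
    concepts = tibble::tibble(
      id = c("K1", "K2", "K3", "K4", "K9"),
      preferred_term = c("heart", "heart valve", "heart muscle",
                         "mitral valve", "island concept")),
    term_map = c("heart" = "K1", "structure of heart" = "K1",
                 "cardiac" = "K1", "heart valve" = "K2",
                 "heart muscle" = "K3", "mitral valve" = "K4",
                 "island concept" = "K9"),
    edges = rbind(c("K2", "K1"), c("K3", "K1"), c("K4", "K2")))
}

# Exhaustive minimum-node-count path search over an undirected edge list,
# independent of the package's graph machinery. Nodes are integers 1..n.
oracle_path_nodes <- function(n, edges, a, b) {
  adj <- vector("list", n)
  if (NROW(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  best <- Inf
  visited <- rep(FALSE, n)
  recurse <- function(node, len) {
    if (len >= best) return(invisible())
    if (node == b) { best <<- len; return(invisible()) }
    for (nb in adj[[node]]) {
      if (!visited[nb]) {
        visited[nb] <<- TRUE
        recurse(nb, len + 1L)
        visited[nb] <<- FALSE
      }
    }
  }
  visited[a] <- TRUE
  recurse(a, 1L)
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

# Random terminology over <= n_max nodes with full surface-term coverage
# ("term i" -> node i); returns the graph plus its raw edge list.
random_terminology <- function(n_max = 12, p_edge = 0.25) {
  n <- sample(2:n_max, 1)
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- pairs[keep, , drop = FALSE]
  ids <- sprintf("K%02d", seq_len(n))
  tg <- terminology_graph(
    concepts = tibble::tibble(id = ids, preferred_term = paste("term", seq_len(n))),
    term_map = stats::setNames(ids, paste("term", seq_len(n))),
    edges = if (nrow(edges) > 0) cbind(ids[edges[, 1]], ids[edges[, 2]]) else NULL)
  list(tg = tg, n = n, edges = edges)
}

# Brute-force Venn-region classifier over rendered keys: every key in the
# union is assigned by direct membership lookup against the three sets.
brute_force_regions <- function(omr_keys, icn_keys, fcn_keys) {
  keys <- unique(c(omr_keys, icn_keys, fcn_keys))
  out <- lapply(stats::setNames(nm = c("A", "B", "C", "D", "E", "F", "G")),
                function(r) character(0))
  for (k in keys) {
    o <- k %in% omr_keys; i <- k %in% icn_keys; f <- k %in% fcn_keys
    r <- if (o && i && f) "A" else if (o && i) "B" else if (o && f) "C"
    else if (i && f) "D" else if (i) "E" else if (f) "F" else "G"
    out[[r]] <- c(out[[r]], k)
  }
  out
}

# Small end-to-end synthetic study shared by several tests.
small_spec <- function(seed = 42, ...) {
  args <- list(...)
  if (is.null(args$n_terminology_concepts)) {
    args$n_terminology_concepts <- 100
  }
  do.call(synthetic_spec, c(list(
    seed = seed, n_patients = 20,
    region_cardinalities = c(A = 10, B = 20, C = 8, D = 6, E = 30, F = 15,
                             G = 50)), args))
}
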