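#' Read gene-set collections and ontologies
#'
#' `read_gmt()` reads a GMT gene-set file (via [fgsea::gmtPathways()])
#' and wraps it into a pathway database: named member sets plus a
#' source label and a universe (the union of members unless supplied).
#' `read_ontology_edges()` reads a two-column (plus optional `type`)
#' child-parent edge TSV; `read_obo()` extracts `is_a` and
#' `relationship: part_of` edges from an OBO file. Both return an
#' `ontology_graph` used by [wang_sim()].
#'
#' @param path file path.
#' @param source database label (`"GO"`, `"KEGG"`, `"Reactome"`,
#'   `"custom"`).
#' @param universe optional character vector of annotatable features.
#' @return `read_gmt()`: a `pathway_db` list with `sets`, `source`,
#'   `universe`.
#' @export
read_gmt <- function(path, source = "custom", universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  pathway_db(sets, source = source, universe = universe)
}

#' Construct a pathway database from a list of member sets
#'
#' @param sets named list of character vectors (no empty set).
#' @inheritParams read_gmt
#' @export
pathway_db <- function(sets, source = "custom", universe = NULL) {
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0)) stop("empty pathway in database")
  universe <- universe %||% unique(unlist(sets, use.names = FALSE))
  extra <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(extra)) stop("pathway members outside the universe: ",
                          paste(head(extra, 3), collapse = ", "), " ...")
  structure(list(sets = sets,
                 source = stats::setNames(rep(source, length(sets)),
                                          names(sets)),
                 universe = universe),
            class = "pathway_db")
}

#' @rdname read_gmt
#' @param weights edge-type contribution weights in (0, 1).
#' @export
read_ontology_edges <- function(path, weights = c(is_a = 0.8,
                                                  part_of = 0.6)) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("child", "parent") %in% names(df)))
    stop("edge table needs 'child' and 'parent' columns")
  if (is.null(df$type)) df$type <- "is_a"
  ontology_graph(df, weights)
}

#' @rdname read_gmt
#' @export
read_obo <- function(path, weights = c(is_a = 0.8, part_of = 0.6)) {
  lines <- readLines(path)
  term_starts <- which(lines == "[Term]")
  edges <- list()
  for (s in term_starts) {
    e <- s + 1
    while (e <= length(lines) && !startsWith(lines[e], "[")) e <- e + 1
    block <- lines[s:(e - 1)]
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE)[1])
    if (any(grepl("^is_obsolete: true", block))) next
    isa <- sub(" !.*$", "", sub("^is_a: *", "",
                                grep("^is_a: ", block, value = TRUE)))
    po <- sub(" !.*$", "", sub("^relationship: part_of *", "",
              grep("^relationship: part_of ", block, value = TRUE)))
    if (length(isa))
      edges[[length(edges) + 1]] <- data.frame(child = id, parent = isa,
                                               type = "is_a")
    if (length(po))
      edges[[length(edges) + 1]] <- data.frame(child = id, parent = po,
                                               type = "part_of")
    if (!length(isa) && !length(po))
      edges[[length(edges) + 1]] <- data.frame(child = id,
                                               parent = NA_character_,
                                               type = "root")
  }
  ontology_graph(do.call(rbind, edges), weights)
}

#' Build an ontology graph from an edge table
#'
#' @param edges data.frame `child`, `parent`, `type` (rows with `NA`
#'   parent only register the term).
#' @param weights named edge-type weights in (0, 1).
#' @return an `ontology_graph`: `parents` (list keyed by term of
#'   data.frames `parent`, `w`), `terms`.
#' @export
ontology_graph <- function(edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(all(weights > 0), all(weights < 1))
  real <- edges[!is.na(edges$parent), , drop = FALSE]
  bad <- setdiff(unique(real$type), names(weights))
  if (length(bad)) stop("no weight for edge type(s): ",
                        paste(bad, collapse = ", "))
  terms <- unique(c(edges$child, real$parent))
  parents <- split(data.frame(parent = real$parent,
                              w = unname(weights[real$type]),
                              stringsAsFactors = FALSE),
                   factor(real$child, levels = terms))
  g <- igraph::graph_from_data_frame(real[, c("child", "parent")],
                                     vertices = terms)
  if (!igraph::is_dag(g)) stop("ontology contains a cycle")
  structure(list(parents = parents, terms = terms), class = "ontology_graph")
}

# S-values of a term's ancestor closure: S_t(t) = 1 and the
# contribution decays by the edge weight along each upward step, taking
# the best path (max) when several exist.
.s_values <- function(term, ont) {
  if (!term %in% ont$terms) stop("term not in ontology: ", term)
  s <- c(stats::setNames(1, term))
  queue <- term
  while (length(queue)) {
    t0 <- queue[1]; queue <- queue[-1]
    ps <- ont$parents[[t0]]
    if (is.null(ps) || nrow(ps) == 0) next
    for (i in seq_len(nrow(ps))) {
      cand <- ps$w[i] * s[[t0]]
      prev <- s[ps$parent[i]]
      if (is.na(prev) || cand > prev) {
        s[ps$parent[i]] <- cand
        queue <- c(queue, ps$parent[i])
      }
    }
  }
  s
}

#' Wang semantic similarity between two ontology terms
#'
#' Downward-weight propagation of S-values over each term's ancestor
#' closure (the term itself included):
#' `sim = sum over shared ancestors of (S_1 + S_2) / (SV(t1) + SV(t2))`
#' where `SV(t)` is the sum of the term's S-values. Terms in disjoint
#' components have similarity 0; `wang_sim(t, t) = 1`.
#'
#' @param t1,t2 term identifiers.
#' @param ont an [ontology_graph()].
#' @return similarity in `[0, 1]`.
#' @export
wang_sim <- function(t1, t2, ont) {
  s1 <- .s_values(t1, ont)
  s2 <- .s_values(t2, ont)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Jaccard similarity of two sets
#'
#' @param a,b character vectors (at least one non-empty).
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard_sim <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop("both sets empty")
  length(intersect(a, b)) / u
}

#' Hypergeometric over-representation test
#'
#' For each pathway the one-sided upper tail
#' `P(X >= overlap)` of the hypergeometric distribution with the
#' database universe as population is computed, then BH-adjusted across
#' the tested pathways. Query features outside the universe are dropped
#' with a message.
#'
#' @param query character vector of features of interest.
#' @param db a `pathway_db`.
#' @param alpha significance threshold on the adjusted p.
#' @return data.frame of class `enrichment_table`: `pathway_id`,
#'   `source`, `overlap`, `pathway_size`, `query_size`,
#'   `universe_size`, `p`, `p_adj`, `significant`.
#' @export
hypergeom_enrich <- function(query, db, alpha = 0.05) {
  stopifnot(inherits(db, "pathway_db"))
  query <- unique(query)
  if (!length(query)) stop("empty query")
  out <- setdiff(query, db$universe)
  if (length(out)) {
    msg(length(out), " query feature(s) outside the universe dropped")
    query <- intersect(query, db$universe)
    if (!length(query)) stop("no query features left in the universe")
  }
  N <- length(db$universe); n <- length(query)
  res <- do.call(rbind, lapply(names(db$sets), function(pw) {
    K <- length(db$sets[[pw]])
    k <- length(intersect(query, db$sets[[pw]]))
    data.frame(pathway_id = pw, source = unname(db$source[pw]),
               overlap = k, pathway_size = K, query_size = n,
               universe_size = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_adjust(res$p)
  res$significant <- res$p_adj < alpha
  class(res) <- c("enrichment_table", class(res))
  res
}

#' Build a pathway similarity network
#'
#' Nodes are the given pathways (isolates retained); undirected edges
#' connect pairs whose similarity exceeds `cutoff`.
#'
#' @param ids pathway/term identifiers.
#' @param sim_fn function of two ids returning a similarity, or a
#'   precomputed symmetric similarity matrix with matching dimnames.
#' @param cutoff edge threshold (strictly greater).
#' @return an [igraph::graph] with vertex attribute `name`.
#' @export
build_similarity_network <- function(ids, sim_fn, cutoff) {
  stopifnot(length(ids) >= 1)
  n <- length(ids)
  if (is.matrix(sim_fn)) {
    sim <- sim_fn[ids, ids, drop = FALSE]
  } else {
    sim <- matrix(1, n, n, dimnames = list(ids, ids))
    if (n > 1)
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        sim[i, j] <- sim[j, i] <- sim_fn(ids[i], ids[j])
  }
  adj <- sim > cutoff
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Edge-betweenness (Girvan-Newman) community detection
#'
#' Edges with the highest betweenness are removed iteratively; the
#' resulting dendrogram is cut at the partition with maximum modularity
#' (isolated vertices become singleton modules).
#'
#' @param graph an undirected [igraph::graph].
#' @return named integer vector: module id per vertex.
#' @export
edge_betweenness_modules <- function(graph) {
  if (igraph::ecount(graph) == 0) {
    m <- seq_len(igraph::vcount(graph))
    names(m) <- igraph::V(graph)$name
    return(m)
  }
  comm <- suppressWarnings(
    igraph::cluster_edge_betweenness(graph, directed = FALSE))
  igraph::membership(comm)
}

#' Collapse significant pathway enrichments into functional modules
#'
#' Within each source database a similarity network over the
#' significant pathways is built (Wang similarity on the ontology for
#' GO when `ont` is supplied, Jaccard on member sets otherwise), cut by
#' the source-specific threshold (0.7 for Wang, 0.5 for Jaccard), and
#' partitioned by edge-betweenness communities; each module is
#' represented by its smallest-adjusted-p pathway. The surviving
#' modules from all sources are then merged across databases by
#' Jaccard similarity of their member-feature unions with the same
#' community procedure, and final representatives are chosen the same
#' way.
#'
#' @param enrichment an `enrichment_table` (or rbind of several).
#' @param db a `pathway_db` covering the enriched pathways (or a named
#'   list of them, keyed by source).
#' @param ont optional [ontology_graph()] for the GO source.
#' @param wang_cutoff,jaccard_cutoff,cross_cutoff similarity thresholds.
#' @return data.frame of class `functional_modules`: one row per final
#'   module with `module_id`, `representative`, `rep_p_adj`,
#'   `n_pathways`, `sources`, and list-columns `members` and
#'   `features`.
#' @export
collapse_to_modules <- function(enrichment, db, ont = NULL,
                                wang_cutoff = 0.7, jaccard_cutoff = 0.5,
                                cross_cutoff = 0.5) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  empty <- data.frame(module_id = integer(0), representative = character(0),
                      rep_p_adj = numeric(0), n_pathways = integer(0),
                      sources = character(0))
  if (nrow(sig) == 0) {
    empty$members <- list(); empty$features <- list()
    class(empty) <- c("functional_modules", class(empty))
    return(empty)
  }
  sets <- if (inherits(db, "pathway_db")) db$sets else
    do.call(c, unname(lapply(db, function(d) d$sets)))
  missing_sets <- setdiff(sig$pathway_id, names(sets))
  if (length(missing_sets)) stop("pathways absent from the database: ",
                                 paste(head(missing_sets, 3), collapse = ", "))
  # stage 1: per-source redundancy collapse
  stage1 <- list()
  for (src in unique(sig$source)) {
    rows <- sig[sig$source == src, , drop = FALSE]
    ids <- rows$pathway_id
    use_wang <- identical(src, "GO") && !is.null(ont)
    sim_fn <- if (use_wang) function(a, b) wang_sim(a, b, ont) else
      function(a, b) jaccard_sim(sets[[a]], sets[[b]])
    cutoff <- if (use_wang) wang_cutoff else jaccard_cutoff
    g <- build_similarity_network(ids, sim_fn, cutoff)
    mem <- edge_betweenness_modules(g)
    for (mod in unique(mem)) {
      ids_m <- names(mem)[mem == mod]
      padj <- rows$p_adj[match(ids_m, rows$pathway_id)]
      # ties on adjusted p broken lexicographically for determinism
      best <- ids_m[order(padj, ids_m)][1]
      stage1[[length(stage1) + 1]] <- list(
        members = ids_m, representative = best,
        rep_p_adj = min(padj), source = src,
        features = unique(unlist(sets[ids_m], use.names = FALSE)))
    }
  }
  # stage 2: cross-database merge on member-feature unions
  ids2 <- sprintf("m%03d", seq_along(stage1))
  feats2 <- lapply(stage1, `[[`, "features")
  names(feats2) <- ids2
  g2 <- build_similarity_network(
    ids2, function(a, b) jaccard_sim(feats2[[a]], feats2[[b]]), cross_cutoff)
  mem2 <- edge_betweenness_modules(g2)
  out <- lapply(unique(mem2), function(mod) {
    parts <- stage1[match(names(mem2)[mem2 == mod], ids2)]
    padj <- vapply(parts, `[[`, numeric(1), "rep_p_adj")
    reps <- vapply(parts, `[[`, character(1), "representative")
    best <- parts[[order(padj, reps)[1]]]
    members <- unique(unlist(lapply(parts, `[[`, "members")))
    data.frame(representative = best$representative,
               rep_p_adj = min(padj), n_pathways = length(members),
               sources = paste(sort(unique(vapply(parts, `[[`, character(1),
                                                  "source"))),
                               collapse = "+"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(module_id = seq_len(nrow(res)), res)
  res$members <- lapply(unique(mem2), function(mod)
    unique(unlist(lapply(stage1[match(names(mem2)[mem2 == mod], ids2)],
                         `[[`, "members"))))
  res$features <- lapply(unique(mem2), function(mod)
    unique(unlist(lapply(stage1[match(names(mem2)[mem2 == mod], ids2)],
                         `[[`, "features"))))
  res <- res[order(res$rep_p_adj), , drop = FALSE]
  res$module_id <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("functional_modules", class(res))
  res
}
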