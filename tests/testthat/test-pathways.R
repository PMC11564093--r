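test_that("hypergeometric enrichment matches exact tail sums", {
  genes <- sprintf("g%02d", 1:20)
  db <- pathway_db(list(pw = genes[1:5]), source = "custom",
                   universe = genes)
  res <- hypergeom_enrich(genes[1:5], db)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, tail_sum_hyper(5, 5, 20, 5), tolerance = 1e-15)
  # zero overlap and pathway == universe are both p = 1
  expect_equal(hypergeom_enrich(genes[6:10], db)$p, 1)
  db2 <- pathway_db(list(all = genes), universe = genes)
  expect_equal(hypergeom_enrich(genes[1:7], db2)$p, 1)
  expect_error(hypergeom_enrich(character(0), db), "empty")
  # random configurations against the naive tail sum
  set.seed(71)
  for (i in 1:25) {
    N <- sample(20:60, 1); K <- sample(3:10, 1); n <- sample(5:15, 1)
    uni <- sprintf("u%03d", 1:N)
    dbr <- pathway_db(list(pw = sample(uni, K)), universe = uni)
    q <- sample(uni, n)
    k <- length(intersect(q, dbr$sets$pw))
    expect_equal(hypergeom_enrich(q, dbr)$p, tail_sum_hyper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("jaccard similarity counts overlaps correctly", {
  expect_equal(jaccard_sim(letters[1:3], letters[1:3]), 1)
  expect_equal(jaccard_sim(letters[1:3], letters[4:6]), 0)
  expect_equal(jaccard_sim(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_error(jaccard_sim(character(0), character(0)), "empty")
})

test_that("Wang similarity propagates S-values as specified", {
  # two-term chain with is_a weight 0.8: sim = 1.8 / 2.8
  ont <- ontology_graph(data.frame(child = "c", parent = "p",
                                   type = "is_a"))
  expect_equal(wang_sim("c", "p", ont), 1.8 / 2.8, tolerance = 1e-12)
  expect_equal(wang_sim("c", "c", ont), 1)
  expect_equal(wang_sim("p", "p", ont), 1)
  # disjoint components share no ancestors
  ont2 <- ontology_graph(data.frame(child = c("a", "x"),
                                    parent = c("b", "y"), type = "is_a"))
  expect_equal(wang_sim("a", "x", ont2), 0)
  # part_of weight 0.6
  ont3 <- ontology_graph(data.frame(child = "c", parent = "p",
                                    type = "part_of"))
  expect_equal(wang_sim("c", "p", ont3), 1.6 / 2.6, tolerance = 1e-12)
  expect_error(wang_sim("zz", "p", ont), "not in ontology")
})

test_that("Wang similarity is symmetric with unit diagonal on random DAGs", {
  set.seed(72)
  for (rep in 1:5) {
    n <- 12
    terms <- sprintf("t%02d", 1:n)
    # random DAG: edges only from later to earlier terms
    edges <- do.call(rbind, lapply(2:n, function(i) {
      k <- sample(1:min(2, i - 1), 1)
      data.frame(child = terms[i],
                 parent = sample(terms[seq_len(i - 1)], k),
                 type = sample(c("is_a", "part_of"), k, TRUE))
    }))
    ont <- ontology_graph(edges)
    picks <- matrix(sample(terms, 10, TRUE), ncol = 2)
    for (r in seq_len(nrow(picks))) {
      s12 <- wang_sim(picks[r, 1], picks[r, 2], ont)
      expect_equal(s12, wang_sim(picks[r, 2], picks[r, 1], ont),
                   tolerance = 1e-12)
      expect_gte(s12, 0); expect_lte(s12, 1)
    }
    for (t in sample(terms, 3)) expect_equal(wang_sim(t, t, ont), 1)
  }
})

test_that("similarity networks threshold edges and keep isolates", {
  sets <- list(a = letters[1:4], b = letters[2:5], c = letters[3:6],
               d = letters[10:12])
  simf <- function(x, y) jaccard_sim(sets[[x]], sets[[y]])
  g <- build_similarity_network(names(sets), simf, cutoff = 0.5)
  expect_setequal(igraph::V(g)$name, names(sets))
  ed <- apply(igraph::as_edgelist(g), 1, function(r)
    paste(sort(r), collapse = "-"))
  expect_setequal(ed, c("a-b", "b-c")) # jaccard 3/5 = 0.6 adjacent only
  expect_equal(igraph::ecount(build_similarity_network(
    names(sets), simf, cutoff = 1.1)), 0)
  g2 <- build_similarity_network(c("p1", "p2"), function(...) 1, 0.9)
  expect_equal(igraph::ecount(g2), 1)
})

test_that("edge-betweenness modules split the bridge graph correctly", {
  # two triangles joined by one bridge
  el <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
              c("d", "e"), c("e", "f"), c("d", "f"),
              c("c", "d"))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  eb <- brute_force_edge_betweenness(g)
  bridge <- igraph::get_edge_ids(g, c("c", "d"))
  expect_equal(which.max(eb), bridge)
  expect_equal(max(igraph::edge_betweenness(g, directed = FALSE)),
               eb[bridge])
  mods <- edge_betweenness_modules(g)
  expect_equal(length(unique(mods)), 2)
  expect_equal(length(unique(mods[c("a", "b", "c")])), 1)
  expect_equal(length(unique(mods[c("d", "e", "f")])), 1)
  # K3 is one module; the empty graph is all singletons
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("x", "y", "z")
  expect_equal(length(unique(edge_betweenness_modules(k3))), 1)
  e0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(e0)$name <- letters[1:4]
  expect_equal(unname(edge_betweenness_modules(e0)), 1:4)
})

test_that("Girvan-Newman never beats, and here matches, brute force", {
  graphs <- list(
    bridge = igraph::graph_from_edgelist(
      rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("d", "e"),
            c("e", "f"), c("d", "f"), c("c", "d")), directed = FALSE),
    two_k4 = local({
      g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
      g <- igraph::add_edges(g, c(1, 5))
      igraph::V(g)$name <- letters[1:8]
      g
    }),
    star = local({
      g <- igraph::make_star(6, mode = "undirected")
      igraph::V(g)$name <- letters[1:6]
      g
    }))
  for (nm in names(graphs)) {
    g <- graphs[[nm]]
    gn <- edge_betweenness_modules(g)
    bf <- brute_force_modularity(g)
    gn_mod <- igraph::modularity(g, gn)
    expect_lte(gn_mod, bf$modularity + 1e-12)
    expect_equal(gn_mod, bf$modularity, tolerance = 1e-9,
                 info = paste("graph", nm))
  }
  # on random community graphs the dendrogram cut can miss the global
  # optimum, but must never exceed it
  set.seed(73)
  for (s in 1:5) {
    g <- igraph::sample_sbm(8, matrix(c(0.9, 0.15, 0.15, 0.9), 2),
                            c(4, 4))
    igraph::V(g)$name <- letters[1:8]
    if (igraph::ecount(g) == 0) next
    expect_lte(igraph::modularity(g, edge_betweenness_modules(g)),
               brute_force_modularity(g)$modularity + 1e-12)
  }
})

test_that("module collapse merges the planted-topic fixture to 4 modules", {
  fx <- enrichment_fixture()
  enr <- fixture_enrichment_tables(fx)
  expect_true(all(enr$significant))
  mods <- collapse_to_modules(enr, db = list(fx$go_db, fx$kegg_db),
                              ont = fx$ont)
  expect_equal(nrow(mods), 4)
  # topic A (GO) absorbed KEGG topic D through shared genes
  big <- mods[vapply(mods$members, function(m) any(grepl("^KEGG:D", m)),
                     logical(1)), ]
  expect_equal(nrow(big), 1)
  expect_true(any(grepl("^GO:A", big$members[[1]])))
  # every significant pathway lands in exactly one module
  all_members <- unlist(mods$members)
  expect_setequal(all_members, enr$pathway_id)
  expect_equal(anyDuplicated(all_members), 0)
  # representatives carry the module-minimum adjusted p
  for (i in seq_len(nrow(mods))) {
    ps <- enr$p_adj[match(mods$members[[i]], enr$pathway_id)]
    expect_equal(mods$rep_p_adj[i], min(ps))
    expect_true(mods$representative[i] %in% mods$members[[i]])
  }
  # input order invariance
  mods2 <- collapse_to_modules(enr[sample(nrow(enr)), ],
                               db = list(fx$go_db, fx$kegg_db),
                               ont = fx$ont)
  expect_equal(nrow(mods2), 4)
  expect_setequal(mods2$representative, mods$representative)
})

test_that("degenerate collapse inputs behave", {
  genes <- sprintf("g%02d", 1:30)
  db <- pathway_db(list(p1 = genes[1:10], p2 = genes[1:10]),
                   universe = genes)
  enr <- hypergeom_enrich(genes[1:10], db)
  enr$p_adj <- c(0.01, 0.001)
  enr$significant <- TRUE
  mods <- collapse_to_modules(enr, db)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$rep_p_adj, 0.001)
  one <- enr[1, ]
  m1 <- collapse_to_modules(one, db)
  expect_equal(m1$representative, "p1")
  none <- enr; none$significant <- FALSE
  expect_equal(nrow(collapse_to_modules(none, db)), 0)
})

test_that("GMT, OBO and edge-list readers round-trip the fixtures", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdescA\tg1\tg2\tg3", "pwB\tdescB\tg3\tg4"), gmt)
  db <- read_gmt(gmt, source = "KEGG")
  expect_setequal(names(db$sets), c("pwA", "pwB"))
  expect_equal(db$sets$pwA, c("g1", "g2", "g3"))
  expect_setequal(db$universe, paste0("g", 1:4))
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "",
    "[Term]", "id: GO:2", "name: mid", "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: leaf",
    "relationship: part_of GO:2 ! mid", ""), obo)
  ont <- read_obo(obo)
  expect_equal(wang_sim("GO:2", "GO:1", ont), 1.8 / 2.8, tolerance = 1e-12)
  # GO:3 -part_of-> GO:2 -is_a-> GO:1: S_3 = {1, 0.6, 0.48}, S_2 = {1, 0.8};
  # shared {GO:2, GO:1} -> (0.6+1) + (0.48+0.8) over (2.08 + 1.8)
  expect_equal(wang_sim("GO:3", "GO:2", ont), 2.88 / 3.88, tolerance = 1e-12)
  edg <- tempfile(fileext = ".tsv")
  writeLines(c("child\tparent\ttype", "GO:2\tGO:1\tis_a"), edg)
  ont2 <- read_ontology_edges(edg)
  expect_equal(wang_sim("GO:2", "GO:1", ont2), 1.8 / 2.8, tolerance = 1e-12)
})
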