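# Programmatic fixtures shared across test files.

# Small cohort wrapper with sensible test-scale defaults.
tiny_cohort <- function(n = 40, feats = c(proteomics = 30), arch = NULL,
                        seed = 1, ...) {
  simulate_cohort(cohort_config(n_participants = n, n_features = feats,
                                archetypes = arch, seed = seed, ...))
}

# Hand-built cross-sectional matrix (bypasses the simulator).
manual_csm <- function(values, age, omics = NULL, adjusted = TRUE) {
  if (is.null(omics))
    omics <- stats::setNames(rep("assay", nrow(values)), rownames(values))
  structure(list(values = values, age = age, omics = omics,
                 metadata = NULL, adjusted = adjusted),
            class = "cross_sectional")
}

# Planted-topic enrichment fixture: three GO "topics" of four
# near-duplicate terms each (chained in the ontology), two KEGG topics
# of two near-duplicate pathways, one KEGG topic sharing most of its
# genes with GO topic A. Hand analysis: per-source collapse may split a
# topic (the similarity chains are cut by the community step), but the
# cross-database Jaccard merge reunites fragments of one topic and
# joins KEGG topic D onto GO topic A, giving final modules
# {A+D}, {B}, {C}, {E} -> 4.
enrichment_fixture <- function() {
  genes <- sprintf("g%03d", 1:100)
  topic_genes <- list(A = genes[1:10], B = genes[21:30], C = genes[41:50])
  go_sets <- list()
  for (tp in names(topic_genes)) {
    gs <- topic_genes[[tp]]
    go_sets[[paste0("GO:", tp, "1")]] <- gs
    go_sets[[paste0("GO:", tp, "2")]] <- gs[1:9]
    go_sets[[paste0("GO:", tp, "3")]] <- gs[2:10]
    go_sets[[paste0("GO:", tp, "4")]] <- gs[c(1:4, 6:10)]
  }
  kegg_sets <- list(
    "KEGG:D1" = c(topic_genes$A[1:8], genes[61:62]),
    "KEGG:D2" = c(topic_genes$A[1:8], genes[61:63]),
    "KEGG:E1" = genes[71:80],
    "KEGG:E2" = genes[c(71:79, 81)])
  # ontology: per topic a 4-term is_a chain under a topic root
  edges <- do.call(rbind, lapply(names(topic_genes), function(tp) {
    terms <- paste0("GO:", tp, 1:4)
    rbind(data.frame(child = terms[2:4], parent = terms[1:3], type = "is_a"),
          data.frame(child = terms[1], parent = paste0("GO:root", tp),
                     type = "is_a"),
          data.frame(child = paste0("GO:root", tp), parent = "GO:root",
                     type = "is_a"))
  }))
  list(
    go_db = pathway_db(go_sets, source = "GO", universe = genes),
    kegg_db = pathway_db(kegg_sets, source = "KEGG", universe = genes),
    ont = ontology_graph(edges),
    genes = genes,
    query = unique(c(topic_genes$A, topic_genes$B, topic_genes$C,
                     genes[71:80], genes[61:63], genes[81])))
}

# Merge two enrichment tables and a db pair for collapse_to_modules.
fixture_enrichment_tables <- function(fx, alpha = 0.05) {
  go <- hypergeom_enrich(fx$query, fx$go_db, alpha = alpha)
  kegg <- hypergeom_enrich(fx$query, fx$kegg_db, alpha = alpha)
  rbind(go, kegg)
}
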