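make_long <- function(df, meta = NULL) {
  structure(list(samples = data.table::as.data.table(df), metadata = meta,
                 truth = NULL, taxonomy = NULL, config = NULL),
            class = "aging_cohort")
}

test_that("healthy-visit averaging follows the stated rules", {
  df <- data.frame(
    participant_id = c("P1", "P1", "P1", "P1", "P2"),
    visit_age = c(50, 50.5, 51, 50.2, 60),
    healthy = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    omics = "assay", feature_id = "f1",
    value = c(1, 2, 3, 100, 7))
  csm <- aggregate_participants(make_long(df))
  expect_equal(unname(csm$values["f1", "P1"]), 2) # unhealthy visit excluded
  expect_equal(unname(csm$values["f1", "P2"]), 7) # single visit: identity
  # participant age = mean over all collection time points
  expect_equal(unname(csm$age["P1"]), mean(c(50, 50.5, 51, 50.2)))
  df2 <- df[1:2, ]; df2$visit_age <- c(50, 51)
  expect_equal(unname(aggregate_participants(make_long(df2))$age["P1"]), 50.5)
})

test_that("participants with no healthy visit are dropped with a message", {
  df <- data.frame(participant_id = c("P1", "P2"), visit_age = c(50, 60),
                   healthy = c(TRUE, FALSE), omics = "assay",
                   feature_id = "f1", value = c(1, 2))
  expect_message(csm <- aggregate_participants(make_long(df)), "dropping")
  expect_equal(colnames(csm$values), "P1")
  expect_error(aggregate_participants(make_long(df[0, ])), "empty")
})

test_that("genus collapse conserves abundance and leaves other omics alone", {
  df <- data.frame(
    participant_id = "P1", visit_age = 50, healthy = TRUE,
    omics = c(rep("gut_microbiome", 3), "proteomics"),
    feature_id = c("t1", "t2", "t3", "prot1"),
    value = c(0.1, 0.2, 0.7, 5))
  tax <- data.frame(feature_id = c("t1", "t2", "t3"),
                    genus = c("gA", "gA", "gB"))
  coh <- collapse_microbiome_to_genus(make_long(df), tax)
  s <- coh$samples
  expect_equal(s$value[s$feature_id == "gA"], 0.3)
  expect_equal(s$value[s$feature_id == "gB"], 0.7) # single-taxon identity
  expect_equal(s$value[s$feature_id == "prot1"], 5)
  # per-sample conservation at machine precision
  expect_equal(sum(s$value[grepl("^g", s$feature_id)]), 1, tolerance = 1e-12)
  # missing taxonomy entry -> unclassified, with a message
  tax2 <- tax[1:2, ]
  expect_message(c2 <- collapse_microbiome_to_genus(make_long(df), tax2),
                 "unclassified")
  expect_true(any(grepl("unclassified", c2$samples$feature_id)))
})

test_that("confounder adjustment returns OLS residuals", {
  set.seed(4)
  n <- 60
  meta <- data.frame(
    participant_id = sprintf("P%02d", 1:n),
    sex = sample(c("F", "M"), n, TRUE),
    ethnicity = sample(c("a", "b"), n, TRUE),
    bmi = rnorm(n, 28, 4),
    iris_class = sample(c("IS", "IR", "unknown"), n, TRUE))
  vals <- rbind(f_bmi = 2 * meta$bmi,                  # exact confounder fit
                f_ind = rnorm(n))                      # independent of design
  colnames(vals) <- meta$participant_id
  csm <- manual_csm(vals, stats::setNames(runif(n, 30, 70),
                                          meta$participant_id),
                    adjusted = FALSE)
  csm$metadata <- meta
  adj <- adjust_confounders(csm)
  expect_true(adj$adjusted)
  expect_lt(max(abs(adj$values["f_bmi", ])), 1e-9)
  # independent feature: residuals are close to the centered values
  cent <- vals["f_ind", ] - mean(vals["f_ind", ])
  expect_gt(cor(adj$values["f_ind", ], cent), 0.9)
  expect_equal(mean(adj$values["f_ind", ]), 0, tolerance = 1e-10)
  # idempotence: adjusting twice equals adjusting once
  adj2 <- adjust_confounders(adj)
  expect_equal(adj2$values, adj$values, tolerance = 1e-8)
})

test_that("aggregation after a single-visit simulation is the identity", {
  cfg <- cohort_config(n_participants = 10, n_features = c(assay = 5),
                       follow_up_meanlog = log(0.01), follow_up_sdlog = 0.01,
                       follow_up_max = 0.02, healthy_prob = 1, seed = 8)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$samples), 10 * 5) # one visit each
  csm <- aggregate_participants(coh)
  s <- coh$samples
  for (i in seq_len(nrow(s)))
    expect_equal(unname(csm$values[s$feature_id[i], s$participant_id[i]]),
                 s$value[i])
})

test_that("participant column order never changes scan results", {
  set.seed(11)
  vals <- matrix(rnorm(20 * 40), 20,
                 dimnames = list(sprintf("f%02d", 1:20),
                                 sprintf("P%02d", 1:40)))
  age <- stats::setNames(runif(40, 25, 75), colnames(vals))
  csm <- manual_csm(vals, age)
  perm <- sample(40)
  csm2 <- manual_csm(vals[, perm], age[perm])
  r1 <- scan_linear(csm, min_n = 10)
  r2 <- scan_linear(csm2, min_n = 10)
  expect_equal(r1$spearman_rho, r2$spearman_rho)
  expect_equal(r1$p_value, r2$p_value)
  s1 <- deswan_scan(csm, min_n = 5)
  s2 <- deswan_scan(csm2, min_n = 5)
  expect_equal(s1$counts, s2$counts)
})
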