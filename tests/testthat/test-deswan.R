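test_that("window construction follows the parcel conventions", {
  set.seed(61)
  ages <- runif(300, 25, 75)
  w <- build_windows(ages, width = 20)
  expect_equal(w$center, 40:65)
  first <- w[1, ]
  expect_equal(c(first$left_lo, first$left_hi), c(min(ages), 40))
  expect_equal(c(first$right_lo, first$right_hi), c(40, 50))
  mid <- w[w$center == 45, ]
  expect_equal(c(mid$left_lo, mid$left_hi, mid$right_lo, mid$right_hi),
               c(35, 45, 45, 55))
  # young cohort: centers stop where the full older parcel still fits
  young <- runif(300, 25, 55)
  wy <- build_windows(young, width = 20)
  expect_lte(max(wy$center), 45)
  expect_error(build_windows(runif(50, 25, 35), width = 20), "")
})

test_that("null counts are low and flat; counts are monotone in q", {
  set.seed(62)
  n <- 108
  age <- stats::setNames(runif(n, 25, 75), sprintf("P%03d", 1:n))
  vals <- matrix(rnorm(300 * n), 300,
                 dimnames = list(sprintf("f%03d", 1:300), names(age)))
  sc <- deswan_scan(manual_csm(vals, age))
  expect_true(all(sc$counts[, "1e-04"] <= sc$counts[, "0.05"]))
  expect_lt(max(sc$counts[, "0.05"]), 0.05 * 300)
  expect_true(all(sc$q >= sc$p, na.rm = TRUE))
})

test_that("a planted step produces a count peak at its transition age", {
  set.seed(63)
  n <- 108
  age <- stats::setNames(runif(n, 25, 75), sprintf("P%03d", 1:n))
  shift <- 2 / (1 + exp(-(age - 50)))
  sig <- t(sapply(1:150, function(i) shift + rnorm(n)))
  noise <- matrix(rnorm(350 * n), 350)
  vals <- rbind(sig, noise)
  dimnames(vals) <- list(sprintf("f%03d", 1:500), names(age))
  sc <- deswan_scan(manual_csm(vals, age))
  peak <- sc$centers[which.max(sc$counts[, "0.05"])]
  expect_lte(abs(peak - 50), 2)
})

test_that("crest detection applies the local-max and envelope rules", {
  counts <- stats::setNames(c(1, 5, 2, 8, 3), 40:44)
  cr <- detect_crests(counts, envelope = rep(1, 5) - 0.5, radius = 1)
  expect_equal(cr$age, c(41, 43))
  # monotone counts: single crest at the right end, flagged as edge
  mono <- stats::setNames(1:6, 40:45)
  cr2 <- detect_crests(mono, envelope = rep(0, 6), radius = 2)
  expect_equal(cr2$age, 45)
  expect_true(cr2$edge)
  # counts entirely inside the envelope: nothing
  cr3 <- detect_crests(counts, envelope = rep(100, 5), radius = 1)
  expect_equal(nrow(cr3), 0)
  # plateau resolves to its midpoint (rounded down)
  plat <- stats::setNames(c(0, 7, 7, 7, 0), 40:44)
  cr4 <- detect_crests(plat, envelope = rep(0, 5), radius = 1)
  expect_equal(cr4$age, 42)
})

test_that("the permutation envelope is reproducible and calibrated", {
  set.seed(64)
  n <- 108
  age <- stats::setNames(runif(n, 25, 75), sprintf("P%03d", 1:n))
  vals <- matrix(rnorm(150 * n), 150,
                 dimnames = list(sprintf("f%03d", 1:150), names(age)))
  csm <- manual_csm(vals, age)
  e1 <- age_permutation_null(csm, n_perm = 20, seed = 5)
  e2 <- age_permutation_null(csm, n_perm = 20, seed = 5)
  expect_identical(e1$quantiles, e2$quantiles)
  # null data: the observed curve stays inside the envelope
  sc <- deswan_scan(csm)
  expect_equal(nrow(detect_crests(sc, envelope = e1)), 0)
})

test_that("a width-only grid reduces to the plain scan, deterministically", {
  set.seed(65)
  n <- 80
  age <- stats::setNames(runif(n, 25, 75), sprintf("P%02d", 1:n))
  vals <- matrix(rnorm(100 * n), 100,
                 dimnames = list(sprintf("f%03d", 1:100), names(age)))
  csm <- manual_csm(vals, age)
  g <- robustness_grid(csm, widths = 20, n_perm = 0)
  sc <- deswan_scan(csm)
  expect_equal(g$scans[["20"]]$counts, sc$counts)
  g2 <- robustness_grid(csm, widths = 20, n_perm = 0)
  expect_identical(g$crests, g2$crests)
})

test_that("per-omics scans localize planted effects to their stratum", {
  set.seed(66)
  n <- 108
  age <- stats::setNames(runif(n, 25, 75), sprintf("P%03d", 1:n))
  shift <- 1.5 / (1 + exp(-(age - 50)))
  prot <- t(sapply(1:100, function(i) shift + rnorm(n)))
  metab <- matrix(rnorm(100 * n), 100)
  vals <- rbind(prot, metab)
  dimnames(vals) <- list(c(sprintf("p%03d", 1:100), sprintf("m%03d", 1:100)),
                         names(age))
  omics <- stats::setNames(rep(c("proteomics", "metabolomics"), each = 100),
                           rownames(vals))
  csm <- manual_csm(vals, age, omics = omics)
  waves <- per_omics_waves(csm)
  expect_setequal(names(waves), c("proteomics", "metabolomics"))
  expect_gt(max(waves$proteomics$counts[, "0.05"]), 50)
  expect_lt(max(waves$metabolomics$counts[, "0.05"]), 10)
  # per-stratum monotonicity in the cutoff
  for (w in waves)
    expect_true(all(w$counts[, "1e-04"] <= w$counts[, "0.05"]))
  # a tiny stratum is skipped with a message
  omics2 <- omics; omics2[1:3] <- "tiny"
  csm2 <- csm; csm2$omics <- omics2
  expect_message(w2 <- per_omics_waves(csm2), "skipped")
  expect_false("tiny" %in% names(w2))
})
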