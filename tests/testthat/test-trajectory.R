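test_that("LOESS reproduces polynomials and constants exactly", {
  set.seed(51)
  ages <- runif(60, 25, 75)
  grid <- seq(30, 70, 0.5)
  lin <- loess_fit_predict(ages, 2 * ages - 7, age_grid = grid, seed = 1)
  expect_lt(max(abs(lin$predictions - (2 * lin$age_grid - 7))), 1e-6)
  const <- loess_fit_predict(ages, rep(3, 60), age_grid = grid, seed = 1)
  expect_lt(max(abs(const$predictions - 3)), 1e-8)
  expect_error(loess_fit_predict(1:5, 1:5), ">= 10")
})

test_that("cross-validated span beats the widest span on wiggly signal", {
  wins <- vapply(1:5, function(s) {
    set.seed(500 + s)
    ages <- sort(runif(108, 25, 75))
    truth <- sin((ages - 25) / 6)
    values <- truth + rnorm(108, 0, 0.4)
    grid <- seq(26, 74, 0.5)
    cvfit <- loess_fit_predict(ages, values, age_grid = grid, seed = s)
    fix1 <- loess_fit_predict(ages, values, age_grid = grid,
                              span_grid = 1, seed = s)
    truth_grid <- sin((grid - 25) / 6)
    err <- function(f) mean((f$predictions -
                               truth_grid[match(f$age_grid, grid)])^2)
    err(cvfit) <= err(fix1)
  }, logical(1))
  expect_gte(sum(wins), 4)
})

test_that("autoscale standardizes, ignores affine shifts, is idempotent", {
  set.seed(52)
  x <- matrix(rnorm(40), 4, dimnames = list(letters[1:4], NULL))
  z <- autoscale(x)
  expect_equal(unname(rowMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 4), tolerance = 1e-12)
  expect_equal(autoscale(5 * x + 3), z, tolerance = 1e-12)
  expect_equal(autoscale(z), z, tolerance = 1e-12)
  xc <- rbind(x, flat = rep(2, 10))
  expect_message(z2 <- autoscale(xc), "zero-variance")
  expect_equal(nrow(z2), 4)
})

test_that("fuzzy c-means matches symmetry and a reference implementation", {
  one <- fuzzy_cmeans(matrix(rnorm(40), 10), k = 1)
  expect_true(all(one$memberships == 1))
  expect_equal(as.vector(one$centers), colMeans(matrix(one$centers, 1)))
  # symmetric point between two tight clouds: membership (0.5, 0.5)
  pts <- rbind(matrix(rep(c(-10, 0), each = 5), 5) +
                 matrix(rnorm(10, 0, 1e-3), 5),
               matrix(rep(c(10, 0), each = 5), 5) +
                 matrix(rnorm(10, 0, 1e-3), 5),
               c(0, 0))
  fit <- fuzzy_cmeans(pts, k = 2, seed = 4)
  expect_equal(unname(fit$memberships[11, ]), c(0.5, 0.5), tolerance = 0.01)
  # two well-separated clouds: crisp membership, centers at cloud means,
  # agreeing with a naive alternating-update reference
  set.seed(53)
  cloud1 <- matrix(rnorm(100, 0, 0.5), 50, 2)
  cloud2 <- matrix(rnorm(100, 0, 0.5), 50, 2) + 10
  x <- rbind(cloud1, cloud2)
  fit2 <- fuzzy_cmeans(x, k = 2, m = 2, seed = 9)
  own <- apply(fit2$memberships, 1, max)
  expect_true(all(own > 0.95))
  got <- fit2$centers[order(fit2$centers[, 1]), ]
  want <- rbind(colMeans(cloud1), colMeans(cloud2))
  expect_lt(max(abs(got - want)), 0.1)
  ref <- reference_cmeans(x, centers0 = rbind(x[1, ], x[51, ]), m = 2)
  refc <- ref$centers[order(ref$centers[, 1]), ]
  expect_lt(max(abs(got - refc)), 1e-3)
})

test_that("the Dmin curve recovers planted cluster counts", {
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    x <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 3),
               matrix(rnorm(60, 8, 0.3), ncol = 3),
               matrix(rnorm(60, c(0, 12, 20), 0.3), ncol = 3, byrow = TRUE))
    sel <- select_k(x, k_grid = 2:8, seed = s)
    drop34 <- (sel$dmin_curve["3"] - sel$dmin_curve["4"]) /
      sel$dmin_curve["3"]
    sel$k_selected == 3 && drop34 > 0.5
  }, logical(1))
  expect_gte(sum(hits), 9)
  # degenerate grid and property checks
  x <- matrix(rnorm(200), 20)
  expect_equal(select_k(x, k_grid = 2, seed = 1)$k_selected, 2)
  dm <- select_k(x, k_grid = 2:6, seed = 2)$dmin_curve
  expect_true(all(diff(dm) < 0.05 * head(dm, -1) + 1e-9))
})

test_that("cluster merging is transitive and respects thresholds", {
  grid <- seq(0, 1, length.out = 20)
  base <- sin(2 * pi * grid)
  centers <- rbind(A = base, B = base + rnorm(20, 0, 0.05),
                   C = -base, D = grid)
  u <- matrix(0.05, 40, 4, dimnames = list(sprintf("f%02d", 1:40), NULL))
  for (i in 1:40) u[i, ((i - 1) %/% 10) + 1] <- 0.85
  u[40, ] <- c(0.4, 0.3, 0.2, 0.1) # low-confidence feature
  fit <- list(centers = centers, memberships = u / rowSums(u) * 1, k = 4L)
  fit$memberships <- u / rowSums(u)
  fit$memberships[1:39, ] <- u[1:39, ] / rowSums(u[1:39, ])
  model <- merge_and_retain(fit)
  # A and B merge (cor ~ 1); C and D stay apart
  expect_equal(model$merge_map[["A"]], model$merge_map[["B"]])
  expect_equal(model$n_clusters, 3)
  expect_false("f40" %in% model$retained) # membership below 0.5 dropped
  # all-identical centers collapse to one cluster
  fit2 <- list(centers = rbind(A = base, B = base),
               memberships = matrix(0.5, 10, 2,
                                    dimnames = list(letters[1:10], NULL)))
  expect_equal(merge_and_retain(fit2)$n_clusters, 1)
  # transitive chain: cor(A,B) = cor(B,C) ~ 0.84, cor(A,C) = 0.4 -> the
  # connected-component rule merges all three through B
  t <- seq(0, 2 * pi, length.out = 32)[-32]
  e1 <- sin(t); e2 <- cos(t) # orthogonal, zero-mean
  A <- e1
  C <- 0.4 * e1 + sqrt(1 - 0.4^2) * e2
  B <- A + C
  cors <- cor(cbind(A, B, C))
  expect_gt(min(cors[1, 2], cors[2, 3]), 0.8)
  expect_lt(cors[1, 3], 0.8)
  fit3 <- list(centers = rbind(A = A, B = B, C = C),
               memberships = matrix(1 / 3, 6, 3,
                                    dimnames = list(letters[1:6], NULL)))
  expect_equal(merge_and_retain(fit3)$n_clusters, 1)
})
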