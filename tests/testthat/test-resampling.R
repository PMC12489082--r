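# ADASYN oversampling, augmentation and leakage-safe splitting.

test_that("ADASYN allocation matches a brute-force neighbor oracle", {
  minority <- rbind(c(0, 0), c(0, 1))
  majority <- rbind(c(5, 5), c(5, 6), c(6, 5), c(6, 6))
  k <- 3
  syn <- adasyn(minority, majority, k = k, beta = 1, seed = 4)
  expect_equal(nrow(syn), round(1 * (4 - 2)))

  # brute-force Delta_i: k nearest in the combined set, counting majority
  combined <- rbind(minority, majority)
  delta <- vapply(1:2, function(i) {
    d <- sqrt(rowSums((combined - matrix(minority[i, ], 6, 2,
                                         byrow = TRUE))^2))
    d[i] <- Inf
    sum(order(d)[1:k] > 2)
  }, 0)
  # each minority point has its sibling plus 2 majority points among its 3 NN
  expect_equal(delta, c(2, 2))
  # equal ratios -> largest remainder assigns one synthetic point each
  expect_equal(attr(syn, "allocation"), c(1L, 1L))

  # every synthetic point lies on the segment between the two minority points
  expect_true(all(syn[, 1] == 0))
  expect_true(all(syn[, 2] >= 0 & syn[, 2] <= 1))
})

test_that("ADASYN totals are exact and synthetic points are convex combinations", {
  set.seed(12)
  for (m in c(5, 26)) {
    for (M in c(40, 134)) {
      for (beta in c(0.5, 1)) {
        minority <- matrix(rnorm(m * 6), m)
        majority <- matrix(rnorm(M * 6, 2), M)
        syn <- adasyn(minority, majority, k = 5, beta = beta, seed = 99)
        G <- round(beta * (M - m))
        expect_equal(nrow(syn), G)
        expect_equal(sum(attr(syn, "allocation")), G)
        # collinearity: s = x_i + lambda (x_z - x_i) for some minority z
        par <- attr(syn, "parent")
        for (q in seq_len(min(nrow(syn), 20))) {
          xi <- minority[par[q], ]
          v <- syn[q, ] - xi
          ok <- FALSE
          for (z in seq_len(m)) {
            if (z == par[q]) next
            u <- minority[z, ] - xi
            lam <- sum(v * u) / sum(u * u)
            if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
                sqrt(sum((v - lam * u)^2)) < 1e-9) { ok <- TRUE; break }
          }
          expect_true(ok)
        }
      }
    }
  }
  expect_equal(nrow(adasyn(matrix(rnorm(20), 10), matrix(rnorm(20), 10),
                           seed = 1)), 0)
  expect_error(adasyn(matrix(1, 1, 2), matrix(rnorm(20), 10)),
               class = "mwi_validation_error")
})

test_that("balancing a 26/134 table yields 134/134", {
  set.seed(0)
  x <- rbind(matrix(rnorm(26 * 128), 26), matrix(rnorm(134 * 128, 4), 134))
  tab <- labeled_table(x, c(rep(0, 26), rep(1, 134)),
                       sprintf("c%03d", 1:160))
  bal <- balance_dataset(tab, k = 5, seed = 2)
  expect_equal(nrow(bal$x), 268)
  expect_equal(as.vector(table(bal$label)), c(134, 134))
  expect_equal(sum(bal$provenance == "synthetic"), 108)
  expect_true(all(bal$parent_id[bal$provenance == "synthetic"] %in%
                    tab$case_id[tab$label == 0]))

  expect_identical(balance_dataset(bal), bal)
  one <- labeled_table(x[1:10, ], rep(1, 10), sprintf("d%02d", 1:10))
  expect_error(balance_dataset(one), class = "mwi_validation_error")

  # row count arithmetic across designs
  for (m in c(4, 9)) for (M in c(12, 30)) for (beta in c(0.5, 1)) {
    t2 <- labeled_table(matrix(rnorm((m + M) * 3), m + M),
                        c(rep(0, m), rep(1, M)),
                        sprintf("e%03d", seq_len(m + M)))
    b2 <- balance_dataset(t2, k = 3, beta = beta, seed = 5)
    expect_equal(nrow(b2$x), m + M + round(beta * (M - m)))
  }
})

test_that("flip augmentation quadruples the set with involutive operators", {
  set.seed(8)
  imgs <- lapply(1:6, function(i) array(runif(5 * 4 * 3), c(5, 4, 3)))
  set <- image_set(imgs, label = seq(2, 12, 2), case_id = paste0("i", 1:6))
  aug <- augment_images(set)
  expect_equal(length(aug$images), 24)
  expect_equal(sum(aug$provenance == "augmented"), 18)
  expect_equal(aug$label, rep(set$label, 4))
  expect_equal(aug$parent_id, rep(set$case_id, 4))

  a <- imgs[[1]]
  expect_identical(flip_horizontal(flip_horizontal(a)), a)
  expect_identical(flip_vertical(flip_vertical(a)), a)
  expect_identical(rotate_180(rotate_180(a)), a)
  expect_identical(rotate_180(a), flip_vertical(flip_horizontal(a)))
  expect_identical(rotate_180(a), flip_horizontal(flip_vertical(a)))
  # the stored augmented instances match the operators pixel-exactly
  expect_identical(aug$images[[7]], flip_horizontal(imgs[[1]]))
  expect_identical(aug$images[[19]], rotate_180(imgs[[1]]))
})

test_that("leakage-safe splitting removes held-out descendants from training", {
  set.seed(3)
  imgs <- lapply(1:140, function(i) array(runif(4 * 4 * 3), c(4, 4, 3)))
  set <- image_set(imgs, label = runif(140), case_id = sprintf("t%03d", 1:140))
  aug <- augment_images(set)
  expect_equal(length(aug$images), 560)
  test_ids <- sprintf("t%03d", 1:10)
  sp <- leakage_safe_split(aug, test_ids, 0.8, seed = 6)
  expect_equal(length(sp$train$images) + length(sp$validation$images), 520)
  expect_equal(length(sp$test$images), 10)
  expect_true(all(sp$test$provenance == "original"))
  expect_length(intersect(sp$train$parent_id, sp$test$parent_id), 0)
  expect_length(intersect(sp$train$parent_id, sp$validation$parent_id), 0)
  expect_length(intersect(sp$validation$parent_id, sp$test$parent_id), 0)

  # determinism and the empty-test edge
  sp2 <- leakage_safe_split(aug, test_ids, 0.8, seed = 6)
  expect_identical(sp$train$case_id, sp2$train$case_id)
  sp0 <- leakage_safe_split(aug, character(0), 0.8, seed = 6)
  expect_equal(length(sp0$test$images), 0)
  expect_equal(length(sp0$train$images) + length(sp0$validation$images), 560)
  expect_error(leakage_safe_split(aug, "nope", 0.8),
               class = "mwi_validation_error")
})
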