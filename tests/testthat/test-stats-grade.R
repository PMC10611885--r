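test_that("exact rank-sum p-values: worked case, degenerate cases, invariances", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4, 5))
  expect_equal(w$p_two_sided, 0.2)   # observed rank sum is the minimum of 10 arrangements
  expect_equal(w$method, "exact")

  # location shift of both groups leaves ranks, hence p, unchanged
  w2 <- wilcoxon_rank_sum(c(1, 2) + 17.3, c(3, 4, 5) + 17.3)
  expect_equal(w2$p_two_sided, w$p_two_sided)

  # identical tied groups: maximal p
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_two_sided, 1.0)
  # singleton groups: only 2 arrangements
  expect_equal(wilcoxon_rank_sum(1, 2)$p_two_sided, 1.0)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact enumeration matches the oracle and base R for all n+m <= 10", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    x <- round(rnorm(n), 1)   # rounding induces occasional ties
    y <- round(rnorm(m), 1)
    p_pkg <- wilcoxon_rank_sum(x, y, method = "exact")$p_two_sided
    expect_equal(p_pkg, enum_ranksum_p(x, y), tolerance = 1e-12)
    # tie-free cases also agree with stats::wilcox.test's exact p
    if (!anyDuplicated(c(x, y))) {
      p_base <- wilcox.test(x, y, exact = TRUE)$p.value
      expect_equal(p_pkg, p_base, tolerance = 1e-9)
    }
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(8)
  for (rep in 1:20) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 2))
    pe <- wilcoxon_rank_sum(x, y, method = "exact")$p_two_sided
    pn <- wilcoxon_rank_sum(x, y, method = "normal_approx")$p_two_sided
    expect_lt(abs(pe - pn), 0.05)
  }
})

test_that("pairwise group comparison assembles the right cells", {
  tbl <- tibble::tibble(
    who_grade = rep(c(2, 3, 4), times = c(3, 3, 4)),
    grade_label = ifelse(rep(c(2, 3, 4), times = c(3, 3, 4)) == 2, "LGG", "HGG"),
    ki = c(1, 2, 3, 11, 12, 13, 21, 22, 23, 24)
  )
  res <- group_compare(tbl, "ki", by = "who_grade")
  expect_equal(nrow(res), 3)                 # 2v3, 2v4, 3v4
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  # fully separated groups get the minimal achievable exact p
  p23 <- res$p_value[res$group1 == "2" & res$group2 == "3"]
  expect_equal(p23, 2 / choose(6, 3))
  res_bh <- group_compare(tbl, "ki", by = "who_grade", p_adjust = "BH")
  expect_true(all(res_bh$p_adjusted >= res_bh$p_value))
})

test_that("lasso in the orthonormal linear design reduces to soft thresholding", {
  set.seed(4)
  n <- 40; p <- 5
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))    # orthonormal columns: X'X = I
  beta <- c(3, -2, 1.5, 0, 0)
  y <- drop(Q %*% beta)                         # noiseless
  b_ols <- drop(crossprod(Q, y))
  lam <- 0.8                                    # glmnet objective: RSS/(2n) + lam |b|
  tbl <- tibble::as_tibble(as.data.frame(Q))
  fit <- lasso_classify(tbl, family = "gaussian", response = y, standardize = FALSE,
                        intercept = FALSE, seed = 2,
                        lambda = exp(seq(log(2), log(1e-4), length.out = 80)))
  # glmnet solves RSS/(2n) + s|b|; with X'X = I the solution is S(b_ols, n*s),
  # so querying the path at s = lam/n must give the soft threshold at lam
  cf_at <- as.matrix(glmnet::coef.glmnet(fit$cv_fit$glmnet.fit, s = lam / n,
                                         exact = TRUE, x = Q, y = y))
  soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
  expect_lt(max(abs(cf_at[-1] - soft)), 1e-6)
})

test_that("penalised grade classification is reproducible and sparsifies with lambda", {
  set.seed(55)
  n <- 30
  tbl <- tibble::tibble(
    grade_label = rep(c("LGG", "HGG"), each = n / 2),
    f1 = rnorm(n, mean = rep(c(0, 2), each = n / 2)),
    f2 = rnorm(n, mean = rep(c(0, 1.5), each = n / 2)),
    f3 = rnorm(n), f4 = rnorm(n)
  )
  fit1 <- lasso_classify(tbl, seed = 9)
  fit2 <- lasso_classify(tbl, seed = 9)
  expect_equal(fit1$lambda_min, fit2$lambda_min)
  expect_equal(fit1$coefficients, fit2$coefficients)
  expect_true(all(c("f1") %in% fit1$selected))

  # sparsity is monotone along the path for an orthonormal design
  Q <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6)))
  yq <- drop(Q %*% c(3, -2, 1, 0.5, 0, 0))
  fitq <- lasso_classify(tibble::as_tibble(as.data.frame(Q)), family = "gaussian",
                         response = yq, standardize = FALSE, intercept = FALSE, seed = 1)
  path <- fitq$cv_fit$glmnet.fit
  nnz <- colSums(as.matrix(path$beta) != 0)
  expect_true(all(diff(nnz[order(path$lambda, decreasing = TRUE)]) >= 0))

  # degenerate inputs
  one_class <- tbl[tbl$grade_label == "LGG", ]
  expect_error(lasso_classify(one_class), "both classes")
  # folds capped at the smallest class size for logistic loss
  small <- tibble::tibble(grade_label = rep(c("LGG", "HGG"), c(4, 4)),
                          f1 = c(0, 0.1, -0.1, 0.2, 3, 3.2, 2.9, 3.1),
                          f2 = rnorm(8))
  w <- capture_warnings(lasso_classify(small, folds = 5, seed = 3))
  expect_true(any(grepl("reducing folds", w)))
  # a 2-member class cannot support logistic CV: auto falls back to
  # penalised least squares on the 0/1 labels
  tiny <- tibble::tibble(grade_label = c("LGG", "LGG", "HGG", "HGG", "HGG"),
                         f1 = c(0, 0.1, 3, 3.2, 2.9), f2 = rnorm(5))
  w2 <- capture_warnings(fit_tiny <- lasso_classify(tiny, seed = 3))
  expect_true(any(grepl("least-squares", w2)))
  expect_equal(fit_tiny$family, "gaussian")
  expect_error(lasso_classify(tiny, family = "binomial"), "at least 3")
})

test_that("paired signed-rank wrapper detects a consistent within-patient shift", {
  set.seed(2)
  cwm <- rnorm(10, 1, 0.05)
  lesion <- cwm + runif(10, 0.3, 0.7)
  p <- wilcoxon_signed_rank(lesion, cwm)$p_two_sided
  expect_lt(p, 0.01)
})
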