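#' Wilcoxon rank-sum test with exact mid-rank enumeration
#'
#' Two-sided unpaired rank-sum test. For small samples (`n + m <= max_exact`)
#' the null distribution of the rank sum is obtained by full enumeration of
#' all `choose(n+m, n)` assignments of the observed (mid-)ranks, which is
#' exact also in the presence of ties; the two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`. Larger samples use the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param method `"auto"` (exact when feasible), `"exact"`, `"normal_approx"`.
#' @param max_exact Enumeration limit on `n + m` for `"auto"` (default 12).
#' @return A one-row tibble: `statistic` (rank sum of `x`), `p_two_sided`,
#'   `method`, `n_x`, `n_y`.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "exact", "normal_approx"),
                              max_exact = 12) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  if (method == "auto") {
    method <- if (N <= max_exact) "exact" else "normal_approx"
  }
  if (method == "exact") {
    if (N > 20) stop("exact enumeration limited to n + m <= 20", call. = FALSE)
    combos <- utils::combn(N, n)
    sums <- colSums(matrix(r[combos], nrow = n))
    eps <- 1e-9
    p_le <- mean(sums <= w + eps)
    p_ge <- mean(sums >= w - eps)
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (N + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n * m / 12 * ((N + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  tibble::tibble(statistic = w, p_two_sided = p, method = method, n_x = n, n_y = m)
}

#' Pairwise group comparison of a feature
#'
#' Applies [wilcoxon_rank_sum()] to every pair of groups. No multiplicity
#' correction is applied by default; set `p_adjust = "BH"` for
#' Benjamini-Hochberg adjusted values in an extra column.
#'
#' @param table A feature table (tibble), one row per patient.
#' @param feature Name of the feature column (string).
#' @param by Grouping column, e.g. `"grade_label"` or `"who_grade"`.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return Tibble with `group1`, `group2`, `n1`, `n2`, `statistic`, `p_value`
#'   (and `p_adjusted` when requested).
#' @export
group_compare <- function(table, feature, by = "grade_label", p_adjust = "none") {
  stopifnot(feature %in% names(table), by %in% names(table))
  groups <- sort(unique(table[[by]]))
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  pairs <- utils::combn(as.character(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- table[[feature]][as.character(table[[by]]) == g1]
    y <- table[[feature]][as.character(table[[by]]) == g2]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    wt <- wilcoxon_rank_sum(x, y)
    tibble::tibble(group1 = g1, group2 = g2, n1 = length(x), n2 = length(y),
                   statistic = wt$statistic, p_value = wt$p_two_sided)
  })
  if (p_adjust != "none") res$p_adjusted <- stats::p.adjust(res$p_value, p_adjust)
  res
}

#' Paired Wilcoxon signed-rank comparison (lesion vs reference region)
#'
#' Thin wrapper over [stats::wilcox.test()] with `paired = TRUE`, used for
#' within-patient comparisons such as lesion versus contralateral white
#' matter.
#'
#' @param x,y Paired numeric vectors.
#' @return One-row tibble: `statistic`, `p_two_sided`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  ht <- stats::wilcox.test(x, y, paired = TRUE, exact = NULL)
  tibble::tibble(statistic = unname(ht$statistic), p_two_sided = ht$p.value)
}

#' L1-penalised grade classification
#'
#' LASSO over a per-patient feature matrix to discriminate lower-grade (LGG)
#' from higher-grade (HGG) tumours. Features are z-scored column-wise, the
#' penalised model is fitted over a log-spaced lambda path, and lambda is
#' selected by stratified k-fold cross-validation at the minimum mean CV
#' error (`lambda.min`). The default family is binomial (logistic loss, CV
#' deviance); `family = "gaussian"` gives the penalised-least-squares shape
#' on a numeric response.
#'
#' @param table Feature table: tibble with a `grade_label` column
#'   (`"LGG"`/`"HGG"`) plus numeric feature columns (non-numeric and label
#'   columns are ignored as predictors).
#' @param folds Number of CV folds (default 5; reduced with a warning if a
#'   class has fewer members than folds).
#' @param seed Seed controlling fold assignment (default 1).
#' @param standardize Z-score the feature columns (default `TRUE`).
#' @param family `"auto"`, `"binomial"` or `"gaussian"`. Logistic loss needs
#'   at least 3 members per class for valid cross-validation splits; `"auto"`
#'   (the default) picks logistic when that holds and otherwise falls back to
#'   penalised least squares on 0/1 class labels — the configuration that
#'   remains well defined for very small cohorts.
#' @param response Optional numeric response for `family = "gaussian"`;
#'   when omitted the 0/1 encoding of `grade_label` is used.
#' @param intercept Fit an intercept (default `TRUE`).
#' @param lambda Optional lambda path to use instead of glmnet's default.
#' @return Object of class `lasso_fit`: list with `lambda_grid`, `cv_mean`,
#'   `cv_sd`, `lambda_min`, `coefficients` (tibble `term`, `estimate`),
#'   `selected` (nonzero terms), `seed`, `family`, and the underlying
#'   `cv.glmnet` object.
#' @export
lasso_classify <- function(table, folds = 5, seed = 1, standardize = TRUE,
                           family = c("auto", "binomial", "gaussian"),
                           response = NULL, intercept = TRUE, lambda = NULL) {
  family <- match.arg(family)
  drop_cols <- c("patient_id", "grade_label", "who_grade")
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  feat_cols <- setdiff(num_cols, drop_cols)
  if (length(feat_cols) < 1) stop("no numeric feature columns found", call. = FALSE)
  X <- as.matrix(table[feat_cols])
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (standardize) X <- scale(X)

  y <- NULL
  if (family != "gaussian" || is.null(response)) {
    if (!"grade_label" %in% names(table)) stop("grade_label column required", call. = FALSE)
    y <- factor(table$grade_label, levels = c("LGG", "HGG"))
    if (length(unique(y)) < 2) stop("need both classes present", call. = FALSE)
  }
  if (family == "auto") {
    n_min <- min(table(y))
    if (n_min >= 3) {
      family <- "binomial"
    } else {
      warning("smallest class has ", n_min, " member(s): using penalised ",
              "least-squares classification on 0/1 labels")
      family <- "gaussian"
    }
  }

  # class-sorted cyclic assignment: every fold is used and classes are spread
  # across folds as evenly as their sizes allow
  stratified_folds <- function(y, folds) {
    n <- length(y)
    ord <- order(as.integer(y), sample(n))
    foldid <- integer(n)
    foldid[ord] <- rep_len(seq_len(folds), n)
    foldid
  }

  if (family == "binomial") {
    n_min <- min(table(y))
    if (n_min < 3) stop("logistic loss needs at least 3 members per class; ",
                        "use family = 'auto' or 'gaussian'", call. = FALSE)
    if (folds > n_min) {
      warning("reducing folds from ", folds, " to ", n_min, " (smallest class size)")
      folds <- n_min
    }
    old <- get_rng_state(); set.seed(seed)
    foldid <- stratified_folds(y, folds)
    restore_rng_state(old)
    cv <- do.call(glmnet::cv.glmnet,
                  list(X, y, family = "binomial", foldid = foldid,
                       standardize = FALSE, intercept = intercept,
                       lambda = lambda, type.measure = "deviance",
                       grouped = nrow(X) >= 3 * folds))
  } else {
    if (is.null(response)) response <- as.numeric(y == "HGG")
    folds <- max(3, min(folds, length(response)))
    old <- get_rng_state(); set.seed(seed)
    foldid <- if (!is.null(y)) stratified_folds(y, folds)
              else sample(rep_len(seq_len(folds), length(response)))
    restore_rng_state(old)
    cv <- do.call(glmnet::cv.glmnet,
                  list(X, response, family = "gaussian", foldid = foldid,
                       standardize = FALSE, intercept = intercept,
                       lambda = lambda, thresh = 1e-12,
                       grouped = length(response) >= 3 * folds))
  }
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))
  coefs <- tibble::tibble(term = rownames(cf), estimate = cf[, 1])
  structure(
    list(lambda_grid = cv$lambda, cv_mean = cv$cvm, cv_sd = cv$cvsd,
         lambda_min = cv$lambda.min,
         coefficients = coefs,
         selected = coefs$term[coefs$term != "(Intercept)" & abs(coefs$estimate) > 0],
         seed = seed, family = family, cv_fit = cv),
    class = "lasso_fit"
  )
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("<lasso_fit> family=", x$family, ", lambda_min=", signif(x$lambda_min, 4),
      ", selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}
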