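new_association_result <- function(statistic, estimate, p_value, n,
                                   detail = NULL) {
  structure(list(statistic = statistic, estimate = estimate,
                 p_value = p_value, n = n, detail = detail),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, two-sided p = %.4g (n = %d%s)\n",
              x$statistic, x$estimate, x$p_value, x$n,
              if (is.null(x$detail)) "" else paste0("; ", x$detail)))
  invisible(x)
}

## all permutations of 1..n as an (n! x n) matrix, built iteratively;
## intended for the exact small-n tests only
all_permutations <- function(n) {
  perms <- matrix(1L, 1, 1)
  if (n == 1) return(perms)
  for (m in 2:n) {
    nm <- nrow(perms)
    out <- matrix(0L, nm * m, m)
    for (pos in seq_len(m)) {
      rows <- (pos - 1L) * nm + seq_len(nm)
      out[rows, pos] <- m
      out[rows, -pos] <- perms
    }
    perms <- out
  }
  perms
}

## sum(rx[perm] * ry) over all permutations of rx; chunked by the first
## slot for n > 8 to keep the permutation matrix small
enumerate_perm_sums <- function(rx, ry) {
  n <- length(rx)
  if (n <= 8) {
    P <- all_permutations(n)
    return(as.vector(matrix(rx[P], nrow(P), n) %*% ry))
  }
  Pm <- all_permutations(n - 1)
  unlist(lapply(seq_len(n), function(first) {
    rest <- rx[-first]
    as.vector(matrix(rest[Pm], nrow(Pm), n - 1) %*% ry[-1]) +
      rx[first] * ry[1]
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Spearman's rho with average ranks for ties.  For n <= 10 the two-sided
#' p-value is computed by exhaustive enumeration of all n! rank
#' permutations (`P(|rho_perm| >= |rho_obs|)`); for larger n the usual t
#' approximation `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of
#' freedom is used.
#'
#' @param scores,covariate paired numeric vectors (>= 3 pairs after
#'   dropping incomplete pairs).
#' @return an `association_result` with statistic `"spearman_rho"`.
#' @export
rank_correlation <- function(scores, covariate) {
  keep <- stats::complete.cases(scores, covariate)
  x <- scores[keep]; y <- covariate[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    ## rho is linear in S = sum(rx[perm] * ry): permuting rx leaves its
    ## mean and sd unchanged, so enumerate S for all n! permutations
    S <- enumerate_perm_sums(rx, ry)
    rho_null <- (S - n * mean(rx) * mean(ry)) / (n - 1) /
      (stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    detail <- "exact permutation enumeration"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    detail <- "t approximation"
  }
  new_association_result("spearman_rho", rho, p, n, detail)
}

## rank sum of the case group, with average ranks
rank_sum <- function(pooled_ranks, is_case) sum(pooled_ranks[is_case])

#' Two-sided Wilcoxon rank-sum test for a case-control score difference
#'
#' The statistic is the sum of pooled (average) ranks of the case group.
#' When both groups have at most 8 members the two-sided p-value is exact:
#' all `choose(n, n_case)` assignments of the pooled ranks are enumerated
#' and `p = min(1, 2 * min(P(W <= w), P(W >= w)))`.  Otherwise a normal
#' approximation with the usual tie correction on the variance is used
#' (no continuity correction).
#'
#' @param scores numeric vector of donor scores.
#' @param labels case-control labels: logical, or values in
#'   `c("case", "control")`, or 0/1 (1 = case).
#' @return an `association_result` with statistic `"rank_sum_W"`.
#' @export
case_control_test <- function(scores, labels) {
  is_case <- if (is.logical(labels)) labels
             else if (is.numeric(labels)) labels == 1
             else labels == "case"
  keep <- stats::complete.cases(scores, is_case)
  x <- scores[keep]; g <- is_case[keep]
  n1 <- sum(g); n2 <- sum(!g); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  r <- rank(x)
  w <- rank_sum(r, g)
  if (n1 <= 8 && n2 <= 8) {
    combos <- utils::combn(n, n1)
    w_null <- colSums(matrix(r[combos], nrow = n1))
    p <- min(1, 2 * min(mean(w_null <= w + 1e-12),
                        mean(w_null >= w - 1e-12)))
    detail <- "exact enumeration"
  } else {
    ew <- n1 * (n + 1) / 2
    ties <- table(r)
    vw <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - ew) / sqrt(vw)
    p <- 2 * stats::pnorm(-abs(z))
    detail <- "normal approximation with tie correction"
  }
  new_association_result("rank_sum_W", w, p, n, detail)
}

#' Joint regression of donor scores on age, sex and case status
#'
#' Ordinary least squares of `scores ~ age + sex + status` with sex coded
#' as an indicator for the second level (reported in the term name) and
#' status coded case = 1.  Tests whether age and disease status have
#' independent effects on a factor's donor expression.
#'
#' @param scores numeric vector of donor scores.
#' @param age numeric ages (years).
#' @param sex binary labels (factor, character or 0/1).
#' @param status case-control labels as in [case_control_test()].
#' @return data frame of class `joint_regression` with one row per term
#'   (`age`, `sex`, `status`): estimate, t statistic (`regression_t`),
#'   two-sided p, n.
#' @export
joint_regression <- function(scores, age, sex, status) {
  is_case <- if (is.logical(status)) status
             else if (is.numeric(status)) status == 1
             else status == "case"
  sexf <- factor(sex)
  if (nlevels(sexf) > 2) stop("sex must be binary")
  dat <- data.frame(scores = scores, age = age,
                    sex = as.numeric(sexf) - 1,
                    status = as.numeric(is_case))
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) <= 4) stop("too few complete observations")
  mm <- stats::model.matrix(~ age + sex + status, dat)
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    sds <- apply(mm[, -1, drop = FALSE], 2, stats::sd)
    stop("rank-deficient design; constant or collinear term(s): ",
         paste(names(sds)[sds == 0], collapse = ", "))
  }
  fit <- stats::lm(scores ~ age + sex + status, dat)
  cf <- summary(fit)$coefficients
  terms <- c("age", "sex", "status")
  out <- data.frame(term = terms,
                    estimate = cf[terms, 1],
                    statistic = cf[terms, 3],
                    p_value = cf[terms, 4],
                    n = nrow(dat), row.names = NULL)
  attr(out, "sex_coding") <- paste0(levels(sexf)[2], " = 1")
  attr(out, "residual_ss") <- sum(stats::residuals(fit)^2)
  class(out) <- c("joint_regression", "data.frame")
  out
}
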