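#' Concatenate per-cell-type pseudobulk matrices into one donor x feature matrix
#'
#' Each cell type's residual pseudobulk is filtered to the top
#' `top_fraction` of expressed genes (ranked by raw feature counts scaled
#' to 100,000 transcripts per donor), its gene names suffixed with the cell
#' type (`ACAP3` becomes `ACAP3_astrocyte`), and the blocks column-bound so
#' that each donor row carries expression from every cell type.  Donors
#' missing any cell type are dropped with a warning.
#'
#' @param residual_pbs list of `residual_sum` pseudobulk objects.
#' @param raw_pbs matching list of `raw_sum` pseudobulk objects used for
#'   the expression ranking.
#' @param top_fraction fraction of genes kept per cell type (default 0.5).
#' @return donor x feature numeric matrix with feature names
#'   `"GENE_celltype"`; attribute `"celltype"` maps features to cell types.
#' @export
concatenate_celltypes <- function(residual_pbs, raw_pbs, top_fraction = 0.5) {
  if (length(residual_pbs) == 0) stop("empty pseudobulk list")
  stopifnot(length(residual_pbs) == length(raw_pbs),
            top_fraction > 0, top_fraction <= 1)
  donor_sets <- lapply(residual_pbs, function(p) colnames(p$matrix))
  donors <- Reduce(intersect, donor_sets)
  dropped <- setdiff(unique(unlist(donor_sets)), donors)
  if (length(dropped))
    warning("donors missing a cell type, dropped: ",
            paste(dropped, collapse = ", "))
  blocks <- list(); ct_of <- character(0)
  for (i in seq_along(residual_pbs)) {
    res <- residual_pbs[[i]]; raw <- raw_pbs[[i]]
    if (res$mode != "residual_sum" || raw$mode != "raw_sum")
      stop("expected residual_sum + raw_sum pseudobulk pairs")
    stopifnot(identical(rownames(res$matrix), rownames(raw$matrix)))
    m_raw <- raw$matrix[, donors, drop = FALSE]
    scaled <- sweep(m_raw, 2, pmax(colSums(m_raw), 1), "/") * 1e5
    expr <- rowSums(scaled)
    n_keep <- max(1L, ceiling(top_fraction * nrow(m_raw)))
    keep <- order(expr, decreasing = TRUE)[seq_len(n_keep)]
    keep <- sort(keep)
    block <- t(res$matrix[keep, donors, drop = FALSE])
    colnames(block) <- paste(rownames(res$matrix)[keep], res$cell_type,
                             sep = "_")
    blocks[[i]] <- block
    ct_of <- c(ct_of, rep(res$cell_type, n_keep))
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- donors
  if (anyDuplicated(colnames(out))) stop("duplicate features after suffixing")
  attr(out, "celltype") <- ct_of
  out
}

#' Fit a cross-cell-type latent factor model
#'
#' Models a donor x (gene, cell type) expression matrix as
#' `X ~ scores %*% t(loadings) + noise`.  The default engine (`"vb_ard"`)
#' is coordinate-ascent variational Bayes for a Gaussian factor model with
#' automatic-relevance-determination (ARD) priors on the factor loadings
#' and per-feature noise precisions: surplus factors are shrunk away, so
#' the requested `k` is an upper bound rather than a hard model choice.
#' `"pca"` returns truncated principal components — an exact, deterministic
#' oracle for noiseless low-rank input.
#'
#' Each factor is oriented so that its largest-|loading| feature has a
#' positive loading (a global sign convention; factor signs are otherwise
#' arbitrary).
#'
#' @param x donor x feature numeric matrix (e.g. from
#'   [concatenate_celltypes()]).
#' @param k number of factors, `1 <= k < min(dim(x))`.
#' @param method `"vb_ard"` or `"pca"`.
#' @param tol relative change in the evidence lower bound below which the
#'   VB iteration stops (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @param seed integer seed for the VB initialisation jitter.
#' @param center center features before fitting (default TRUE; residual
#'   inputs are already variance-stabilised so no scaling is applied).
#' @return object of class `latent_factor_fit`: `scores` (donor x k),
#'   `loadings` (feature x k), `relevance` (per-factor share of explained
#'   score variance), `tau` (feature noise precisions, VB only), `alpha`
#'   (ARD precisions, VB only), `elbo` (trace), `converged`, `method`,
#'   `center`, `sigma_s` (posterior score covariance, VB only).
#' @export
fit_latent_factors <- function(x, k = 10, method = c("vb_ard", "pca"),
                               tol = 1e-6, max_iter = 1000, seed = 1L,
                               center = TRUE) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (k < 1 || k >= min(n, p))
    stop("k must satisfy 1 <= k < min(donors, features)")
  if (anyNA(x)) stop("matrix must be complete; drop donors missing a cell type")
  mu <- if (center) colMeans(x) else rep(0, p)
  xc <- sweep(x, 2, mu)
  fit <- if (method == "pca") fit_pca(xc, k) else
    fit_vb_ard(xc, k, tol = tol, max_iter = max_iter, seed = seed)
  fit$center <- mu
  fit$method <- method
  fit$k <- k
  ## sign convention: top-|loading| feature positive per factor
  for (j in seq_len(k)) {
    top <- which.max(abs(fit$loadings[, j]))
    if (fit$loadings[top, j] < 0) {
      fit$loadings[, j] <- -fit$loadings[, j]
      fit$scores[, j] <- -fit$scores[, j]
    }
  }
  dimnames(fit$scores) <- list(rownames(x), paste0("LF", seq_len(k)))
  dimnames(fit$loadings) <- list(colnames(x), paste0("LF", seq_len(k)))
  sv <- apply(fit$scores, 2, stats::var) *
    colSums(fit$loadings^2)
  fit$relevance <- sv / sum(sv)
  fit$celltype <- attr(x, "celltype")
  class(fit) <- "latent_factor_fit"
  fit
}

fit_pca <- function(xc, k) {
  sv <- svd(xc, nu = k, nv = k)
  list(scores = sv$u %*% diag(sv$d[seq_len(k)], k),
       loadings = sv$v,
       elbo = numeric(0), converged = TRUE,
       tau = NULL, alpha = NULL, sigma_s = NULL)
}

## Variational Bayes Gaussian factor model with ARD priors.
## X (n x p) = S L' + E;  s_i ~ N(0, I);  l_jk ~ N(0, 1/alpha_k);
## alpha_k ~ Gamma(a0, b0);  noise x_ij ~ N(s_i.l_j, 1/tau_j);
## tau_j ~ Gamma(c0, d0).  Mean-field q(S) q(L) q(alpha) q(tau).
fit_vb_ard <- function(xc, k, tol = 1e-6, max_iter = 1000, seed = 1L,
                       a0 = 1e-3, b0 = 1e-3, c0 = 1e-3, d0 = 1e-3) {
  n <- nrow(xc); p <- ncol(xc)
  set.seed(seed)
  ## initialise loadings from truncated SVD plus jitter to break symmetry
  sv <- svd(xc, nu = k, nv = k)
  Lmu <- sv$v %*% diag(sv$d[seq_len(k)] / sqrt(n), k) +
    matrix(stats::rnorm(p * k, 0, 1e-3), p, k)
  Lsig <- array(0, c(k, k, p))   # per-feature loading covariance
  for (j in seq_len(p)) Lsig[, , j] <- diag(1e-2, k)
  Etau <- rep(1, p)
  Ealpha <- rep(1, k)
  col_ss <- colSums(xc^2)
  elbo <- numeric(0)
  a_alpha <- a0 + p / 2
  c_tau <- c0 + n / 2
  converged <- FALSE
  M <- matrix(0, n, k); Ssig <- diag(1, k)
  b_alpha <- rep(b0, k); d_tau <- rep(d0, p)
  for (it in seq_len(max_iter)) {
    ## --- q(S): shared covariance, posterior means M
    ElLt <- matrix(0, k, k)       # sum_j Etau_j E[l_j l_j']
    for (j in seq_len(p))
      ElLt <- ElLt + Etau[j] * (tcrossprod(Lmu[j, ]) + Lsig[, , j])
    Ssig <- chol2inv(chol(diag(1, k) + ElLt))
    M <- (sweep(xc, 2, Etau, "*") %*% Lmu) %*% Ssig
    SS <- crossprod(M) + n * Ssig  # sum_i E[s_i s_i']
    ## --- q(L)
    XtM <- crossprod(xc, M)        # p x k
    El2 <- matrix(0, p, k)         # E[l_jk^2]
    for (j in seq_len(p)) {
      Sig_j <- chol2inv(chol(diag(Ealpha, k) + Etau[j] * SS))
      Lsig[, , j] <- Sig_j
      Lmu[j, ] <- Etau[j] * as.vector(Sig_j %*% XtM[j, ])
      El2[j, ] <- Lmu[j, ]^2 + diag(Sig_j)
    }
    ## --- q(alpha)
    b_alpha <- b0 + colSums(El2) / 2
    Ealpha <- a_alpha / b_alpha
    ## --- q(tau): expected residual sum of squares per feature
    Eres2 <- vapply(seq_len(p), function(j) {
      col_ss[j] - 2 * sum(XtM[j, ] * Lmu[j, ]) +
        sum(SS * (tcrossprod(Lmu[j, ]) + Lsig[, , j]))
    }, 0)
    d_tau <- d0 + Eres2 / 2
    Etau <- c_tau / d_tau
    ## --- evidence lower bound
    Eln_tau <- digamma(c_tau) - log(d_tau)
    Eln_alpha <- digamma(a_alpha) - log(b_alpha)
    ll <- sum(n / 2 * (Eln_tau - log(2 * pi)) - Etau * Eres2 / 2)
    lpS <- -n * k / 2 * log(2 * pi) - 0.5 * (sum(M^2) + n * sum(diag(Ssig)))
    lpL <- p / 2 * sum(Eln_alpha) - p * k / 2 * log(2 * pi) -
      0.5 * sum(sweep(El2, 2, Ealpha, "*"))
    lpA <- sum(a0 * log(b0) - lgamma(a0) + (a0 - 1) * Eln_alpha -
                 b0 * Ealpha)
    lpT <- sum(c0 * log(d0) - lgamma(c0) + (c0 - 1) * Eln_tau - d0 * Etau)
    hS <- n / 2 * (k * (1 + log(2 * pi)) +
                     as.numeric(determinant(Ssig)$modulus))
    hL <- sum(vapply(seq_len(p), function(j)
      0.5 * (k * (1 + log(2 * pi)) +
               as.numeric(determinant(matrix(Lsig[, , j], k, k))$modulus)),
      0))
    hA <- sum(a_alpha - log(b_alpha) + lgamma(a_alpha) +
                (1 - a_alpha) * digamma(a_alpha))
    hT <- sum(c_tau - log(d_tau) + lgamma(c_tau) +
                (1 - c_tau) * digamma(c_tau))
    elbo[it] <- ll + lpS + lpL + lpA + lpT + hS + hL + hA + hT
    if (it > 1) {
      rel <- abs(elbo[it] - elbo[it - 1]) / (abs(elbo[it - 1]) + 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("vb_ard did not converge in ", max_iter, " iterations")
  list(scores = M, loadings = Lmu, elbo = elbo, converged = converged,
       tau = Etau, alpha = Ealpha, sigma_s = Ssig)
}

#' @export
print.latent_factor_fit <- function(x, ...) {
  cat(sprintf("latent factor fit (%s): %d donors, %d features, k = %d\n",
              x$method, nrow(x$scores), nrow(x$loadings), x$k))
  if (length(x$elbo))
    cat(sprintf("  %d iterations, %sconverged; final ELBO %.2f\n",
                length(x$elbo), if (x$converged) "" else "NOT ", max(x$elbo)))
  cat("  factor relevance (share of explained score variance):\n  ")
  cat(sprintf("%.3f", x$relevance), sep = " ")
  cat("\n")
  invisible(x)
}

#' @export
coef.latent_factor_fit <- function(object, ...) object$loadings

#' @export
fitted.latent_factor_fit <- function(object, ...) {
  sweep(object$scores %*% t(object$loadings), 2, object$center, "+")
}

#' @export
residuals.latent_factor_fit <- function(object, x, ...) {
  if (missing(x)) stop("supply the fitted matrix x to compute residuals")
  as.matrix(x) - fitted(object)
}

#' Project new donors onto fitted factors
#'
#' @param object a `latent_factor_fit`.
#' @param newdata donor x feature matrix with the same features.
#' @param ... unused.
#' @return donor x k score matrix (posterior means for `vb_ard`,
#'   least-squares projections for `pca`).
#' @export
predict.latent_factor_fit <- function(object, newdata, ...) {
  xc <- sweep(as.matrix(newdata), 2, object$center)
  L <- object$loadings
  if (object$method == "vb_ard" && !is.null(object$sigma_s)) {
    (sweep(xc, 2, object$tau, "*") %*% L) %*% object$sigma_s
  } else {
    xc %*% L %*% solve(crossprod(L))
  }
}

#' @export
plot.latent_factor_fit <- function(x, which = c("relevance", "elbo"), ...) {
  which <- match.arg(which)
  if (which == "elbo" && length(x$elbo)) {
    graphics::plot(x$elbo, type = "l", xlab = "iteration", ylab = "ELBO", ...)
  } else {
    graphics::barplot(x$relevance, names.arg = colnames(x$scores),
                      ylab = "relevance", las = 2, ...)
  }
  invisible(x)
}

#' Summarise a latent factor fit
#'
#' Reports total and per-factor variance explained (fraction of the
#' centered matrix's sum of squares), pairwise score and loading
#' correlations, and the cell-type composition of each factor's top-`top_n`
#' features by |loading| (rows sum to 1).
#'
#' @param object a `latent_factor_fit`.
#' @param x the matrix the model was fitted on.
#' @param top_n features per factor for the composition table
#'   (default 1000; clamped to the feature count with a warning).
#' @param ... unused.
#' @return object of class `factor_summary`: `total_ve`, `factor_ve`,
#'   `score_cor`, `loading_cor`, `composition`.
#' @export
summary.latent_factor_fit <- function(object, x, top_n = 1000, ...) {
  if (missing(x)) stop("supply the fitted matrix x")
  xc <- sweep(as.matrix(x), 2, object$center)
  tss <- sum(xc^2)
  recon <- object$scores %*% t(object$loadings)
  total_ve <- 1 - sum((xc - recon)^2) / tss
  k <- object$k
  factor_ve <- vapply(seq_len(k), function(j) {
    r1 <- tcrossprod(object$scores[, j], object$loadings[, j])
    1 - sum((xc - r1)^2) / tss
  }, 0)
  names(factor_ve) <- colnames(object$scores)
  ct <- object$celltype
  composition <- NULL
  if (!is.null(ct)) {
    if (top_n > nrow(object$loadings)) {
      warning("top_n clamped to feature count")
      top_n <- nrow(object$loadings)
    }
    types <- sort(unique(ct))
    composition <- t(vapply(seq_len(k), function(j) {
      top <- order(abs(object$loadings[, j]), decreasing = TRUE)[seq_len(top_n)]
      tab <- table(factor(ct[top], types))
      as.vector(tab / sum(tab))
    }, numeric(length(types))))
    dimnames(composition) <- list(colnames(object$scores), types)
  }
  structure(list(total_ve = total_ve, factor_ve = factor_ve,
                 score_cor = stats::cor(object$scores),
                 loading_cor = stats::cor(object$loadings),
                 composition = composition, k = k),
            class = "factor_summary")
}

#' @export
print.factor_summary <- function(x, ...) {
  cat(sprintf("factor summary: k = %d, total variance explained %.3f\n",
              x$k, x$total_ve))
  cat("per-factor variance explained:\n")
  print(round(x$factor_ve, 4))
  if (!is.null(x$composition)) {
    cat("cell-type composition of top-loading features:\n")
    print(round(x$composition, 3))
  }
  invisible(x)
}

#' Rank-based quantile normalisation to standard normal scores
#'
#' `qnorm(rank(x) / (length(x) + 1))` with average ranks for ties: a
#' monotone map of the observed values onto evenly spaced standard-normal
#' quantiles, used to make donor factor scores comparable across factors
#' without changing any rank-based statistic.
#'
#' @param x numeric vector.
#' @return numeric vector of normal scores.
#' @export
quantile_normalize <- function(x) {
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

#' Adjust donor scores for age
#'
#' Residuals from an ordinary least squares regression of the scores on
#' age (with intercept): removes the linear age trend so that remaining
#' variation can be tested against other covariates.
#'
#' @param scores numeric vector of donor scores.
#' @param ages numeric vector of donor ages (years).
#' @return residual scores.
#' @export
adjust_for_age <- function(scores, ages) {
  stopifnot(length(scores) == length(ages), length(scores) >= 3)
  if (stats::var(ages) == 0) stop("age not identifiable (constant ages)")
  stats::residuals(stats::lm(scores ~ ages))
}
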