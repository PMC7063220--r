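#' Unit-variance autoscaling
#'
#' Centers every column to mean zero and scales it to unit variance, the
#' conventional preprocessing for spectra-like physiological index matrices
#' before latent-variable modelling. [unscale()] inverts it exactly.
#'
#' @param x Numeric matrix (rows = animals, columns = indices).
#' @return The scaled matrix with `"scaled:center"` / `"scaled:scale"`
#'   attributes (as [base::scale()]).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  const <- which(sds == 0 | is.na(sds))
  if (length(const)) {
    nm <- colnames(x)[const] %||% as.character(const)
    stop("constant column(s) cannot be autoscaled: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  scale(x, center = TRUE, scale = TRUE)
}

#' @rdname autoscale
#' @param xs A matrix produced by [autoscale()].
#' @export
unscale <- function(xs) {
  ctr <- attr(xs, "scaled:center")
  scl <- attr(xs, "scaled:scale")
  if (is.null(ctr) || is.null(scl)) {
    stop("xs does not carry scaling attributes", call. = FALSE)
  }
  out <- sweep(sweep(unclass(xs), 2, scl, "*"), 2, ctr, "+")
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

# Venetian-blind fold assignment: row i -> fold ((i-1) mod folds) + 1.
.venetian_folds <- function(n, folds) {
  folds <- max(2L, min(as.integer(folds), n))
  ((seq_len(n) - 1L) %% folds) + 1L
}

# Scale columns by supplied center/scale; zero scales fall back to 1 so a
# dummy column constant within a training fold does not blow up.
.apply_scaling <- function(x, ctr, scl) {
  scl[scl == 0] <- 1
  sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
}

#' Principal component analysis with cross-validated Q2
#'
#' PCA on the autoscaled matrix via singular value decomposition, reporting
#' per-component and cumulative explained variance (R2X) and a
#' cross-validated Q2 from venetian-blind row folds: held-out rows are
#' projected onto the training loadings and the reconstruction PRESS is
#' accumulated.
#'
#' @param x Numeric matrix.
#' @param n_components Number of components. Default 2.
#' @param cv_folds Folds for Q2 (default 7); `0` skips cross-validation.
#' @param scale Autoscale `x` first (default `TRUE`; otherwise only
#'   mean-centering is applied).
#' @return Object of class `pca_model`: `scores`, `loadings` (orthonormal
#'   columns), `r2x` (per component), `r2x_cum`, `q2`.
#' @export
pca_fit <- function(x, n_components = 2, cv_folds = 7, scale = TRUE) {
  x <- as.matrix(x)
  if (n_components > min(nrow(x) - 1L, ncol(x))) {
    stop("n_components exceeds min(rows - 1, cols)", call. = FALSE)
  }
  xs <- if (scale) autoscale(x) else base::scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xs)
  if (all(sv$d < 1e-12)) stop("degenerate (all-zero) matrix", call. = FALSE)
  a <- n_components
  scores <- sv$u[, seq_len(a), drop = FALSE] %*% diag(sv$d[seq_len(a)], a)
  loadings <- sv$v[, seq_len(a), drop = FALSE]
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("comp", seq_len(a))
  r2x <- sv$d[seq_len(a)]^2 / sum(sv$d^2)

  q2 <- NA_real_
  if (cv_folds >= 2 && nrow(x) >= 4) {
    fold <- .venetian_folds(nrow(x), cv_folds)
    press <- 0; ss <- 0
    for (f in unique(fold)) {
      tr <- x[fold != f, , drop = FALSE]
      te <- x[fold == f, , drop = FALSE]
      ctr <- colMeans(tr)
      scl <- if (scale) apply(tr, 2, stats::sd) else rep(1, ncol(tr))
      trs <- .apply_scaling(tr, ctr, scl)
      tes <- .apply_scaling(te, ctr, scl)
      v <- svd(trs)$v[, seq_len(min(a, ncol(tr), nrow(trs) - 1L)), drop = FALSE]
      rec <- tes %*% v %*% t(v)
      press <- press + sum((tes - rec)^2)
      ss <- ss + sum(tes^2)
    }
    q2 <- 1 - press / ss
  }
  structure(list(scores = scores, loadings = loadings,
                 r2x = r2x, r2x_cum = cumsum(r2x), q2 = q2,
                 n_components = a),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA: %d components, R2X(cum) = %.3f, Q2 = %s\n",
              x$n_components, x$r2x_cum[x$n_components],
              ifelse(is.na(x$q2), "NA", sprintf("%.3f", x$q2))))
  invisible(x)
}

# NIPALS PLS2 on preprocessed X (n x p) and Y (n x g). Returns scores T,
# weights W (unit columns), X-loadings P, Y-loadings C, and per-component
# explained sums of squares.
.pls2_nipals <- function(X, Y, a, tol = 1e-10, max_iter = 500) {
  n <- nrow(X); p <- ncol(X); g <- ncol(Y)
  Tm <- matrix(0, n, a); W <- matrix(0, p, a)
  P <- matrix(0, p, a); C <- matrix(0, g, a)
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  ssx <- ssy <- numeric(a)
  for (comp in seq_len(a)) {
    if (sum(X^2) < 1e-12 * max(ssx0, 1)) break
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (sum(u^2) < 1e-12) u <- X[, which.max(apply(X, 2, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_scr <- X %*% w
      cc <- crossprod(Y, t_scr) / sum(t_scr^2)
      if (sum(cc^2) > 1e-12) u <- Y %*% cc / sum(cc^2)
      if (sqrt(sum((t_scr - t_old)^2)) < tol * sqrt(sum(t_scr^2))) break
      t_old <- t_scr
    }
    p_load <- crossprod(X, t_scr) / sum(t_scr^2)
    X <- X - t_scr %*% t(p_load)
    Y <- Y - t_scr %*% t(cc)
    Tm[, comp] <- t_scr; W[, comp] <- w; P[, comp] <- p_load; C[, comp] <- cc
    ssx[comp] <- sum(t_scr^2) * sum(p_load^2)
    ssy[comp] <- sum(t_scr^2) * sum(cc^2)
  }
  list(T = Tm, W = W, P = P, C = C, ssx = ssx, ssy = ssy,
       ssx_total = ssx0, ssy_total = ssy0)
}

# Regression coefficients B (p x g) of a fitted NIPALS PLS2 on the scaled
# metric: Yhat_scaled = X_scaled %*% B.
.pls2_coef <- function(fit) {
  PW <- crossprod(fit$P, fit$W)
  fit$W %*% solve(PW) %*% t(fit$C)
}

.dummy_matrix <- function(groups) {
  groups <- factor(groups)
  Y <- stats::model.matrix(~ groups - 1)
  colnames(Y) <- levels(groups)
  attr(Y, "assign") <- NULL
  attr(Y, "contrasts") <- NULL
  Y
}

#' Partial least-squares discriminant analysis (NIPALS PLS2)
#'
#' Fits a PLS2 model of the autoscaled index matrix against the one-hot
#' (dummy) class matrix by the NIPALS algorithm, with successive deflation.
#' Reports per-component and cumulative explained variance of X (R2X) and of
#' the class matrix (R2Y), and the cross-validated predictive ability Q2
#' from venetian-blind folds (default 7): each fold is held out, the model is
#' refit on the remainder and the held-out class matrix predicted; Q2 =
#' 1 - PRESS/SS.
#'
#' @param x Numeric matrix (rows = animals, columns = indices).
#' @param groups Class label per row; every class needs at least 2 members.
#' @param n_components Number of latent components. Default 2.
#' @param cv_folds Folds for Q2 (default 7); `0` skips cross-validation.
#' @param scale Autoscale `x` (default `TRUE`).
#' @return Object of class `plsda_model` with `scores`, `weights`,
#'   `loadings`, `y_loadings`, `r2x`, `r2y` (per component), `r2x_cum`,
#'   `r2y_cum`, `q2`, plus the scaling parameters and class levels needed for
#'   prediction.
#' @export
plsda <- function(x, groups, n_components = 2, cv_folds = 7, scale = TRUE) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("every group needs at least 2 members", call. = FALSE)
  }
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (nrow(x) != length(groups)) stop("x rows and groups differ", call. = FALSE)

  xs <- if (scale) autoscale(x) else base::scale(x, center = TRUE, scale = FALSE)
  Y <- .dummy_matrix(groups)
  y_ctr <- colMeans(Y)
  y_scl <- apply(Y, 2, stats::sd)
  Ys <- .apply_scaling(Y, y_ctr, y_scl)

  fit <- .pls2_nipals(unclass(xs), Ys, n_components)
  r2x <- fit$ssx / fit$ssx_total
  r2y <- fit$ssy / fit$ssy_total

  q2 <- NA_real_
  if (cv_folds >= 2 && nrow(x) >= 4) {
    fold <- .venetian_folds(nrow(x), cv_folds)
    press <- 0; ss <- 0
    for (f in unique(fold)) {
      tr_i <- fold != f
      xtr <- x[tr_i, , drop = FALSE]; xte <- x[!tr_i, , drop = FALSE]
      ytr <- Y[tr_i, , drop = FALSE]; yte <- Y[!tr_i, , drop = FALSE]
      x_ctr <- colMeans(xtr)
      x_scl <- if (scale) apply(xtr, 2, stats::sd) else rep(1, ncol(xtr))
      yc <- colMeans(ytr); ysd <- apply(ytr, 2, stats::sd)
      f_fit <- .pls2_nipals(.apply_scaling(xtr, x_ctr, x_scl),
                            .apply_scaling(ytr, yc, ysd), n_components)
      B <- .pls2_coef(f_fit)
      yhat <- .apply_scaling(xte, x_ctr, x_scl) %*% B
      ytes <- .apply_scaling(yte, yc, ysd)
      press <- press + sum((ytes - yhat)^2)
      ss <- ss + sum(ytes^2)
    }
    q2 <- 1 - press / ss
  }

  scores <- fit$T
  colnames(scores) <- paste0("comp", seq_len(n_components))
  rownames(fit$W) <- rownames(fit$P) <- colnames(x)
  rownames(fit$C) <- colnames(Y)
  structure(list(scores = scores, weights = fit$W, loadings = fit$P,
                 y_loadings = fit$C,
                 r2x = r2x, r2y = r2y,
                 r2x_cum = cumsum(r2x), r2y_cum = cumsum(r2y),
                 q2 = q2, ssy = fit$ssy,
                 n_components = n_components, groups = groups,
                 levels = colnames(Y),
                 x_center = attr(xs, "scaled:center"),
                 x_scale = attr(xs, "scaled:scale") %||% rep(1, ncol(x)),
                 y_center = y_ctr, y_scale = y_scl,
                 cv_folds = cv_folds, scaled = scale),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf(
    "PLS-DA: %d components over %d groups\n  R2X = %.3f, R2Y = %.3f, Q2 = %s\n",
    x$n_components, nlevels(x$groups),
    x$r2x_cum[x$n_components], x$r2y_cum[x$n_components],
    ifelse(is.na(x$q2), "NA", sprintf("%.3f", x$q2))))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP score of variable j over the A fitted components:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' where `p` is the number of variables, `w` the unit-norm NIPALS weights and
#' `SSY_a` the class-matrix variance explained by component `a`. Squared VIP
#' scores average to 1, so VIP > 1 marks variables contributing more than
#' average to class separation.
#'
#' @param model A fitted [plsda()] model.
#' @return Named numeric vector of VIP scores, one per variable, in column
#'   order.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W <- model$weights
  ssy <- model$ssy
  if (sum(ssy) <= 0) {
    stop("model explains no class variance; VIP undefined", call. = FALSE)
  }
  p <- nrow(W)
  scores <- sqrt(p * as.numeric(W^2 %*% ssy) / sum(ssy))
  stats::setNames(scores, rownames(W))
}

#' Permutation validation of a PLS-DA model
#'
#' Refits the model `n_perm` times with randomly permuted class labels and
#' compares the permuted R2Y and Q2 with the real model's. The model is
#' declared valid when every permuted R2Y and Q2 falls below the real values.
#' Intercepts of the permuted statistics at zero label correlation are
#' estimated by linear regression of the permuted values (plus the real
#' model at correlation 1) on the absolute correlation between permuted and
#' original dummy matrices; a negative Q2 intercept is the classical sign of
#' a non-overfitted model.
#'
#' @param x,groups Data as in [plsda()].
#' @param model The fitted model being validated (supplies `n_components`,
#'   `cv_folds`, scaling choice).
#' @param n_perm Number of permutations. Default 200.
#' @param seed Integer seed controlling the permutation sequence.
#' @return List: `r2y`, `q2` (real model), `perm_r2y`, `perm_q2` (vectors),
#'   `r2_intercept`, `q2_intercept`, `valid`.
#' @export
permutation_validate <- function(x, groups, model, n_perm = 200, seed = 1) {
  stopifnot(inherits(model, "plsda_model"))
  if (n_perm < 10) warning("fewer than 10 permutations give an unstable null")
  x <- as.matrix(x)
  groups <- factor(groups)
  Y0 <- .dummy_matrix(groups)
  set.seed(seed)
  perm_r2y <- perm_q2 <- perm_cor <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    gp <- sample(groups)
    m <- plsda(x, gp, n_components = model$n_components,
               cv_folds = model$cv_folds, scale = model$scaled)
    perm_r2y[i] <- m$r2y_cum[model$n_components]
    perm_q2[i] <- m$q2
    perm_cor[i] <- abs(stats::cor(as.vector(.dummy_matrix(gp)), as.vector(Y0)))
  }
  r2y0 <- model$r2y_cum[model$n_components]
  q20 <- model$q2
  cors <- c(perm_cor, 1)
  r2_int <- unname(stats::coef(stats::lm(c(perm_r2y, r2y0) ~ cors))[1])
  q2_int <- unname(stats::coef(stats::lm(c(perm_q2, q20) ~ cors))[1])
  list(r2y = r2y0, q2 = q20,
       perm_r2y = perm_r2y, perm_q2 = perm_q2,
       r2_intercept = r2_int, q2_intercept = q2_int,
       valid = all(perm_r2y < r2y0) && all(perm_q2 < q20))
}

#' Rank treatment groups by score-space distance to a reference
#'
#' Computes the centroid of each group in latent-score space and the
#' Euclidean distance of every non-reference centroid to the reference
#' (typically the healthy control): the closer a treated group sits to
#' normality, the better its pharmacodynamic effect.
#'
#' @param scores Numeric matrix of component scores (rows = animals).
#' @param groups Class label per row.
#' @param reference_group Label of the reference group.
#' @return Data frame `group`, `distance`, sorted ascending by distance.
#' @export
group_distance_ranking <- function(scores, groups, reference_group) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  if (!reference_group %in% groups) {
    stop("reference group '", reference_group, "' absent", call. = FALSE)
  }
  centroids <- do.call(rbind, lapply(split(seq_along(groups), groups),
                                     function(i) colMeans(scores[i, , drop = FALSE])))
  ref <- centroids[reference_group, ]
  others <- setdiff(rownames(centroids), reference_group)
  d <- vapply(others, function(g) sqrt(sum((centroids[g, ] - ref)^2)), numeric(1))
  out <- data.frame(group = others, distance = unname(d), stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA and pairwise comparisons from summary statistics
#'
#' Reconstructs, per index, the one-way ANOVA F test from group means,
#' standard deviations and sizes (between/within sums of squares), plus
#' pairwise Welch t tests of every group against a control and a model
#' reference — the comparisons behind the usual `+`/`++` and `*`/`**` table
#' footnotes at p < 0.05 / p < 0.01.
#'
#' @param group_means Matrix or data frame, groups x indices.
#' @param group_sds Matrix of the same shape, positive.
#' @param group_ns Integer vector of group sizes (>= 2).
#' @param control,model_group Row names of the two reference groups; either
#'   may be `NULL` to skip that comparison family.
#' @return List with `anova` (index, F, p) and `pairwise` (index, group,
#'   reference, t, df, p, sig05, sig01), Welch-corrected.
#' @export
summary_anova <- function(group_means, group_sds, group_ns,
                          control = "control", model_group = "model") {
  m <- as.matrix(group_means); s <- as.matrix(group_sds)
  ns <- as.numeric(group_ns)
  if (!all(dim(m) == dim(s))) stop("means/sds shapes differ", call. = FALSE)
  if (length(ns) != nrow(m)) stop("one n per group required", call. = FALSE)
  if (any(ns < 2)) stop("group sizes must be >= 2", call. = FALSE)
  if (any(s <= 0)) stop("standard deviations must be positive", call. = FALSE)
  g <- nrow(m); idx <- colnames(m) %||% paste0("x", seq_len(ncol(m)))
  groups <- rownames(m) %||% paste0("g", seq_len(g))
  rownames(m) <- rownames(s) <- groups
  N <- sum(ns)

  anova_rows <- lapply(seq_len(ncol(m)), function(j) {
    gm <- sum(ns * m[, j]) / N
    ssb <- sum(ns * (m[, j] - gm)^2)
    ssw <- sum((ns - 1) * s[, j]^2)
    Fst <- (ssb / (g - 1)) / (ssw / (N - g))
    data.frame(index = idx[j], F = Fst,
               p = stats::pf(Fst, g - 1, N - g, lower.tail = FALSE))
  })

  welch <- function(j, a, b) {
    se2 <- s[a, j]^2 / ns[which(groups == a)] + s[b, j]^2 / ns[which(groups == b)]
    tst <- (m[a, j] - m[b, j]) / sqrt(se2)
    df <- se2^2 / (
      (s[a, j]^2 / ns[which(groups == a)])^2 / (ns[which(groups == a)] - 1) +
      (s[b, j]^2 / ns[which(groups == b)])^2 / (ns[which(groups == b)] - 1))
    p <- 2 * stats::pt(abs(tst), df, lower.tail = FALSE)
    data.frame(index = idx[j], group = a, reference = b,
               t = tst, df = df, p = p,
               sig05 = p < 0.05, sig01 = p < 0.01, stringsAsFactors = FALSE)
  }
  pair_rows <- list()
  for (j in seq_len(ncol(m))) {
    for (ref in c(control, model_group)) {
      if (is.null(ref) || !ref %in% groups) next
      for (a in setdiff(groups, ref)) {
        pair_rows[[length(pair_rows) + 1L]] <- welch(j, a, ref)
      }
    }
  }
  list(anova = do.call(rbind, anova_rows),
       pairwise = if (length(pair_rows)) do.call(rbind, pair_rows) else NULL)
}
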