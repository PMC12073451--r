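#' Fit a sparse PLS discriminant analysis model
#'
#' From-scratch sparse partial least squares discriminant analysis. Class
#' labels are one-hot encoded and column-centred; X columns are centred
#' (scaling is expected upstream, see [preprocess()]). Each component is
#' extracted by the NIPALS iteration with an X-weight sparsity step: the
#' Y-side score is initialized from the dominant (largest-variance) column
#' of Y, then the loop `w <- soft-threshold(X'u)` (keeping the `keepX`
#' largest absolute entries, renormalized to unit norm), `t <- Xw`,
#' `a <- Y't` (normalized), `u <- Ya` runs to convergence. X and Y are then
#' deflated by regression on the score `t`, which makes scores orthogonal
#' across components. The fit is deterministic: no random initialization.
#'
#' @param X Numeric matrix, samples x features (already scaled).
#' @param y Class labels (factor or character), at least two classes.
#' @param ncomp Number of components H (>= 1, <= min(n - 1, p)).
#' @param keepX Number of non-zero weights per component; scalar or vector
#'   of length `ncomp`. `keepX` equal to the feature count disables
#'   sparsity, recovering dense PLS-DA.
#' @param tol Convergence tolerance on the weight update (default 1e-9,
#'   comfortably below the 1e-6 agreement checked against a dense oracle).
#' @param max_iter Iteration cap per component (default 1000).
#' @return An `splsda_model`: list with `weights` (p x H), `loadings`
#'   (p x H), `scores` (n x H), `y_loadings`, `levels`, `x_center`,
#'   `centroids` (class centroids in score space), `explained_variance`
#'   (per-component fraction of centred X variance), `keepX`, `ncomp`,
#'   plus the training `X` and `y` for downstream feature ranking.
#' @export
fit_splsda <- function(X, y, ncomp = 2L, keepX = 30L, tol = 1e-9,
                       max_iter = 1000L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("y must contain at least two classes",
                            call. = FALSE)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (ncomp < 1L) stop("ncomp must be >= 1", call. = FALSE)
  if (ncomp > min(n - 1L, p)) {
    stop("ncomp must be <= min(samples - 1, features)", call. = FALSE)
  }
  keepX <- rep(as.integer(keepX), length.out = ncomp)
  if (any(keepX < 1L) || any(keepX > p)) {
    stop("keepX must be between 1 and the feature count", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))

  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  Yc <- sweep(Y, 2, colMeans(Y))
  ssx_total <- sum(Xc^2)

  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, ncomp)
  Q <- matrix(0, ncol(Y), ncomp, dimnames = list(levels(y), NULL))
  expl <- numeric(ncomp)

  soft_keep <- function(v, k) {
    if (k >= length(v)) return(v)
    thr <- sort(abs(v), decreasing = TRUE)[k + 1L]
    sign(v) * pmax(abs(v) - thr, 0)
  }

  for (h in seq_len(ncomp)) {
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    w_old <- rep(0, p)
    for (iter in seq_len(max_iter)) {
      w <- soft_keep(drop(crossprod(Xc, u)), keepX[h])
      nw <- sqrt(sum(w^2))
      if (nw == 0) stop("degenerate component: all weights thresholded out",
                        call. = FALSE)
      w <- w / nw
      tt <- drop(Xc %*% w)
      a <- drop(crossprod(Yc, tt))
      a <- a / sqrt(sum(a^2))
      u <- drop(Yc %*% a)
      if (max(abs(w - w_old)) < tol) break
      w_old <- w
    }
    tsq <- sum(tt^2)
    pl <- drop(crossprod(Xc, tt)) / tsq
    ql <- drop(crossprod(Yc, tt)) / tsq
    Xc <- Xc - tcrossprod(tt, pl)
    Yc <- Yc - tcrossprod(tt, ql)
    W[, h] <- w; P[, h] <- pl; Tm[, h] <- tt; Q[, h] <- ql
    expl[h] <- tsq * sum(pl^2) / ssx_total
  }

  centroids <- do.call(rbind, lapply(levels(y), function(g) {
    colMeans(Tm[y == g, , drop = FALSE])
  }))
  rownames(centroids) <- levels(y)

  structure(list(
    weights = W, loadings = P, scores = Tm, y_loadings = Q,
    levels = levels(y), x_center = x_center, centroids = centroids,
    explained_variance = expl, keepX = keepX, ncomp = ncomp,
    X = X, y = y
  ), class = "splsda_model")
}

#' Project new samples into the score space of a fitted model
#'
#' @param model An `splsda_model`.
#' @param newX Matrix of new samples (same feature columns as training).
#' @param ncomp Number of components to use (default all).
#' @return Matrix of scores (rows = samples, columns = components).
#' @export
splsda_scores <- function(model, newX, ncomp = model$ncomp) {
  if (is.null(dim(newX))) newX <- matrix(newX, nrow = 1L)
  newX <- as.matrix(newX)
  if (ncol(newX) != length(model$x_center)) {
    stop("newX must have the training feature columns", call. = FALSE)
  }
  Xc <- sweep(newX, 2, model$x_center)
  out <- matrix(0, nrow(Xc), ncomp)
  for (h in seq_len(ncomp)) {
    tt <- drop(Xc %*% model$weights[, h])
    Xc <- Xc - tcrossprod(tt, model$loadings[, h])
    out[, h] <- tt
  }
  out
}

#' Predict class membership by nearest centroid in score space
#'
#' @param model An `splsda_model`.
#' @param newX New samples.
#' @param ncomp Components used for the distance (default all).
#' @return Character vector of predicted class labels.
#' @export
predict_splsda <- function(model, newX, ncomp = model$ncomp) {
  sc <- splsda_scores(model, newX, ncomp)
  ctr <- model$centroids[, seq_len(ncomp), drop = FALSE]
  apply(sc, 1, function(s) {
    rownames(ctr)[which.min(colSums((t(ctr) - s)^2))]
  })
}

balanced_error_rate <- function(truth, predicted) {
  truth <- factor(truth)
  per_class <- vapply(levels(truth), function(g) {
    mean(predicted[truth == g] != g)
  }, numeric(1))
  mean(per_class)
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin with a running cursor so fold sizes stay as even as possible
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  cursor <- 0L
  for (g in levels(factor(y))) {
    ix <- sample(which(y == g))
    assign[ix] <- ((cursor + seq_along(ix) - 1L) %% folds) + 1L
    cursor <- cursor + length(ix)
  }
  assign
}

#' Select the number of sPLS-DA components by stratified cross-validation
#'
#' Splits samples into stratified folds (each fold's class proportions as
#' close as integer arithmetic allows; the fold count is capped at the
#' sample size, so "10-fold" degenerates toward leave-one-out at small n).
#' For each candidate component count H, the model is refitted on each
#' training split and held-out samples are classified by nearest centroid in
#' score space; predictions are pooled over folds and summarized as the
#' balanced error rate (BER: classification error averaged over classes).
#' The chosen H is the smallest one attaining the minimum BER. If a fold's
#' training split lacks a class, folds are reshuffled once before erroring.
#'
#' @param X Matrix, samples x features: the globally scaled matrix with
#'   `rescale = FALSE` (default, mirroring tools that scale once before
#'   cross-validating), or the unscaled (log-transformed) matrix with
#'   `rescale = TRUE`.
#' @param y Class labels.
#' @param max_comp Largest component count to evaluate (default 3).
#' @param folds Requested fold count (default 10; >= 2).
#' @param keepX Sparsity per component (as in [fit_splsda()]).
#' @param seed Integer seed for the fold shuffle.
#' @param rescale Re-estimate per-feature autoscaling on each training
#'   split and apply it to the held-out samples. At small n, scaling across
#'   all samples before cross-validation couples the held-out sample to the
#'   training set (centred rows make it the negative sum of the training
#'   rows), which distorts error estimates; within-fold rescaling removes
#'   that coupling.
#' @return list with `ber` (named numeric, one entry per H), `chosen`
#'   (selected H), `fold_assignment`, `predictions` (pooled, for the chosen
#'   H).
#' @export
cross_validate <- function(X, y, max_comp = 3L, folds = 10L, keepX = 30L,
                           seed = 1L, rescale = FALSE) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  folds <- as.integer(min(folds, n))
  max_comp <- min(max_comp, n - max(table(y)) - 1L, ncol(X))
  if (max_comp < 1L) stop("too few samples for cross-validation",
                          call. = FALSE)
  set.seed(seed)
  assign <- stratified_folds(y, folds)
  ok <- function(a) all(vapply(seq_len(folds), function(f) {
    length(unique(y[a != f])) == nlevels(y)
  }, logical(1)))
  if (!ok(assign)) {
    assign <- stratified_folds(y, folds)
    if (!ok(assign)) {
      stop("a training split lacks a class even after reshuffling",
           call. = FALSE)
    }
  }

  pred <- matrix(NA_character_, n, max_comp)
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    if (!length(test)) next
    train <- setdiff(seq_len(n), test)
    Xtr <- X[train, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    if (rescale) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
    }
    hmax <- min(max_comp, length(train) - 1L)
    model <- fit_splsda(Xtr, y[train], ncomp = hmax,
                        keepX = pmin(keepX, ncol(X)))
    for (h in seq_len(hmax)) {
      pred[test, h] <- predict_splsda(model, Xte, ncomp = h)
    }
  }
  ber <- vapply(seq_len(max_comp), function(h) {
    balanced_error_rate(y, pred[, h])
  }, numeric(1))
  names(ber) <- paste0("comp", seq_len(max_comp))
  chosen <- which(ber == min(ber))[1]
  list(ber = ber, chosen = chosen, fold_assignment = assign,
       predictions = pred[, chosen])
}

#' Rank features by discriminative influence
#'
#' Orders features by the absolute component-1 weight of the fitted model
#' (descending; ties broken by feature name), optionally by the VIP score
#' instead. Each reported feature carries the group of its maximal mean
#' scaled abundance as a signed association readout. When fewer non-zero
#' weights than `top_n` exist, all non-zero features are returned and the
#' shortfall is noted in the `shortfall` attribute.
#'
#' @param model An `splsda_model`.
#' @param top_n Number of features to report (default 30).
#' @param ranking `"weight"` (default, |component-1 weight|) or `"vip"`.
#' @return data.frame `feature`, `weight`, `influence`, `group`, ordered by
#'   decreasing influence.
#' @export
rank_features <- function(model, top_n = 30L, ranking = c("weight", "vip")) {
  ranking <- match.arg(ranking)
  top_n <- as.integer(top_n)
  w1 <- model$weights[, 1]
  infl <- if (ranking == "weight") abs(w1) else splsda_vip(model)
  nz <- which(if (ranking == "weight") w1 != 0 else infl > 0)
  shortfall <- max(0L, top_n - length(nz))
  ord <- nz[order(-infl[nz], names(infl)[nz] %||% nz)]
  sel <- ord[seq_len(min(top_n, length(ord)))]
  feats <- colnames(model$X)[sel]
  group <- vapply(sel, function(j) {
    mu <- tapply(model$X[, j], model$y, mean)
    names(mu)[which.max(mu)]
  }, character(1))
  out <- data.frame(feature = feats, weight = w1[sel],
                    influence = infl[sel], group = group,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfall
  out
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP over the fitted components, weighting each component's
#' squared weights by the Y-variance it explains.
#'
#' @param model An `splsda_model`.
#' @return Numeric vector of VIP scores, one per feature.
#' @export
splsda_vip <- function(model) {
  p <- nrow(model$weights)
  tsq <- colSums(model$scores^2)
  ssy <- tsq * colSums(model$y_loadings^2)
  vip2 <- p * (model$weights^2 %*% ssy) / sum(ssy)
  stats::setNames(sqrt(drop(vip2)), rownames(model$weights))
}

#' Balanced error rate under label permutation
#'
#' Repeats cross-validation with randomly shuffled class labels; the
#' resulting BER distribution is the permutation null (chance level is
#' 1 - 1/k for k classes, since for label-independent predictions the
#' class-balanced error averages to exactly that). The BER is evaluated at
#' a fixed component count -- selecting the best of several H inside the
#' null would bias it optimistically -- and, by default, with within-fold
#' rescaling (see [cross_validate()]): global pre-scaling couples held-out
#' samples to the training split, and at two or more components overfitting
#' to shuffled labels makes cross-validated error sit above chance, a known
#' small-sample property of permutation nulls.
#'
#' @inheritParams cross_validate
#' @param ncomp Fixed component count for the null (default 1).
#' @param n_perm Number of label shuffles (default 50).
#' @return Numeric vector of BERs, one per permutation.
#' @export
permutation_ber <- function(X, y, n_perm = 50L, ncomp = 1L, folds = 10L,
                            keepX = 30L, seed = 1L, rescale = TRUE) {
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  cv_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  vapply(seq_len(n_perm), function(i) {
    set.seed(perm_seeds[i])
    ys <- sample(y)
    cv <- cross_validate(X, ys, max_comp = ncomp, folds = folds,
                         keepX = keepX, seed = cv_seeds[i],
                         rescale = rescale)
    unname(cv$ber[ncomp])
  }, numeric(1))
}
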