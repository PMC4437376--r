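#' Fit G-BLUP by REML
#'
#' Mixed model `y = X b + g + e` with `g ~ N(0, G sigma2_g)` and
#' `e ~ N(0, I sigma2_e)`, where `G` is a genomic relationship matrix.
#' Variance components are estimated by REML: after one eigendecomposition
#' of the training block of `G`, the restricted log-likelihood is profiled
#' down to the single variance ratio `lambda = sigma2_g / sigma2_e`, which is
#' maximised by 1-D optimisation (tolerance 1e-6 on the ratio).  BLUPs are
#' then computed for every individual in the GRM through the mixed-model
#' equations, so individuals outside the training set are predicted through
#' their genomic relationships with the training individuals.
#'
#' @param grm a `gp_grm` covering at least the training individuals (and any
#'   individuals to be predicted).
#' @param phenotype named numeric vector (names = sample ids).
#' @param covariates optional numeric matrix/data frame of fixed covariates
#'   (e.g. ancestry PCs), row names = sample ids.  An intercept is always
#'   included.
#' @param train_ids ids used to estimate the model; default: all GRM ids with
#'   a non-missing phenotype.
#' @param fix optional `c(sigma2_g, sigma2_e)` to skip REML and compute BLUPs
#'   at fixed variances (used e.g. to check the ridge-regression equivalence).
#' @param ridge_eps jitter added to the training-block diagonal (default
#'   1e-8) to absorb numerically semi-definite GRMs; recorded in the fit.
#' @return An object of class `gblup_fit` with elements `sigma2_g`,
#'   `sigma2_e`, `h2_hat`, `fixed_effects`, `blups` (all GRM individuals),
#'   `alpha` (the solution `V^{-1}(y - X b)`, the quantity any cross-GRM can
#'   be multiplied with to predict new individuals), `train_ids`, `loglik`,
#'   `converged`.
#' @export
fit_gblup <- function(grm, phenotype, covariates = NULL, train_ids = NULL,
                      fix = NULL, ridge_eps = 1e-8) {
  stopifnot(inherits(grm, "gp_grm"))
  if (is.null(train_ids)) {
    train_ids <- intersect(grm$sample_ids,
                           names(phenotype)[!is.na(phenotype)])
  }
  if (!all(train_ids %in% grm$sample_ids)) {
    stop("train_ids must all be present in the GRM")
  }
  y <- phenotype[train_ids]
  if (anyNA(y)) stop("missing phenotypes among train_ids")
  if (sd(y) == 0) stop("phenotype is constant in the training set")
  n <- length(y)
  X <- build_design(covariates, train_ids)
  p <- ncol(X)

  Gtt <- grm$matrix[train_ids, train_ids]
  e <- eigen(Gtt + diag(ridge_eps, n), symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values))) {
    stop("GRM is not positive semi-definite beyond tolerance; ",
         "consider a larger ridge_eps")
  }
  d <- pmax(e$values, 0)
  U <- e$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  reml <- function(loglambda) {
    lambda <- exp(loglambda)
    v <- lambda * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - drop(Xs %*% beta)
    rss <- sum(w * r^2)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(s2e) + sum(log(v)) +
                    determinant(XtWX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), beta = drop(beta), s2e = s2e, lambda = lambda)
  }

  if (is.null(fix)) {
    opt <- optimize(function(t) -reml(t)$ll, interval = c(-14, 14),
                    tol = 1e-8)
    sol <- reml(opt$minimum)
    sigma2_e <- sol$s2e
    sigma2_g <- sol$lambda * sigma2_e
    ## honest convergence: interior optimum (not pinned to the search edge)
    converged <- opt$minimum > -13.9 && opt$minimum < 13.9
    loglik <- sol$ll
    beta <- sol$beta
  } else {
    stopifnot(length(fix) == 2, all(fix >= 0), fix[2] > 0)
    sigma2_g <- fix[1]; sigma2_e <- fix[2]
    sol <- reml(log(max(sigma2_g, 1e-12) / sigma2_e))
    loglik <- sol$ll
    beta <- sol$beta
    converged <- TRUE
  }

  vinv_diag <- 1 / (sigma2_g * d + sigma2_e)
  r_raw <- y - drop(X %*% beta)
  alpha <- drop(U %*% (crossprod(U, r_raw) * vinv_diag))
  names(alpha) <- train_ids
  blups <- sigma2_g * drop(grm$matrix[, train_ids, drop = FALSE] %*% alpha)
  names(blups) <- grm$sample_ids
  h2_hat <- sigma2_g / (sigma2_g + sigma2_e)

  structure(
    list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, h2_hat = h2_hat,
         fixed_effects = setNames(beta, colnames(X)), blups = blups,
         alpha = alpha, train_ids = train_ids, loglik = loglik,
         converged = converged, ridge_eps = ridge_eps,
         covariate_names = colnames(X)),
    class = "gblup_fit"
  )
}

build_design <- function(covariates, ids) {
  if (is.null(covariates)) {
    X <- matrix(1, length(ids), 1, dimnames = list(ids, "(Intercept)"))
  } else {
    Z <- as.matrix(covariates)
    if (is.null(rownames(Z))) stop("covariates must have sample-id row names")
    miss <- setdiff(ids, rownames(Z))
    if (length(miss) > 0) stop("covariates missing for: ",
                               paste(head(miss, 5), collapse = ", "))
    Z <- Z[ids, , drop = FALSE]
    X <- cbind("(Intercept)" = 1, Z)
  }
  X
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "gblup_fit: n_train = %d, sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f\n",
    length(x$train_ids), x$sigma2_g, x$sigma2_e, x$h2_hat))
  invisible(x)
}

#' Predict genetic values from a G-BLUP fit
#'
#' Predictions are the BLUPs of the genetic effect; fixed-covariate (PC)
#' contributions are deliberately excluded so the prediction reflects genomic
#' information only.  For individuals already in the fitted GRM the stored
#' BLUPs are returned; for new individuals supply their relationship rows to
#' the training set via `grm_cross` (see [grm_cross()]).
#'
#' @param object a `gblup_fit`.
#' @param test_ids ids to predict (must be in the fitted GRM unless
#'   `grm_cross` is given).
#' @param grm_cross optional matrix of relationships, rows = new individuals,
#'   columns = training individuals (in any order; matched by name).
#' @param ... unused.
#' @return named numeric vector of predicted genetic values.
#' @export
predict.gblup_fit <- function(object, test_ids = NULL, grm_cross = NULL,
                              ...) {
  if (!is.null(grm_cross)) {
    stopifnot(all(object$train_ids %in% colnames(grm_cross)))
    K <- grm_cross[, object$train_ids, drop = FALSE]
    pred <- object$sigma2_g * drop(K %*% object$alpha)
    names(pred) <- rownames(grm_cross)
    if (!is.null(test_ids)) pred <- pred[test_ids]
    return(pred)
  }
  if (is.null(test_ids)) return(object$blups)
  miss <- setdiff(test_ids, names(object$blups))
  if (length(miss) > 0) {
    stop("individuals absent from the fitted GRM: ",
         paste(head(miss, 5), collapse = ", "))
  }
  object$blups[test_ids]
}
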