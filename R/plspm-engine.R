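## Generic PLS path-modeling estimator (Lohmoeller-style alternating
## outer/inner weight iteration with centroid, factorial or path scheme).

#' Column-standardize a data matrix
#'
#' Centers each column to mean 0 and scales to sample variance 1
#' (denominator n - 1), the convention used throughout the engine so
#' correlations and standardized OLS agree.
#'
#' @param X numeric matrix or data.frame with unique column names.
#' @return A numeric matrix of the same shape.
#' @examples
#' standardizeColumns(cbind(a = c(1, 2, 3)))   # -1, 0, 1
#' @export
standardizeColumns <- function(X) {
  X <- .asDataMatrix(X)
  s <- apply(X, 2L, sd)
  zero <- !is.finite(s) | s == 0
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  sweep(sweep(X, 2L, colMeans(X)), 2L, s, "/")
}

## internal: coerce + validate the numeric substrate
.asDataMatrix <- function(X, minRows = 1L) {
  if (is.data.frame(X)) {
    if (!is.null(X$patient_id)) {
      rn <- as.character(X$patient_id)
      X <- X[, setdiff(names(X), "patient_id"), drop = FALSE]
      rownames(X) <- rn
    }
    X <- as.matrix(X)
  }
  if (!is.numeric(X)) stop("data must be numeric")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("data must have unique column names")
  if (anyNA(X) || any(!is.finite(X))) stop("data must be complete and finite")
  if (nrow(X) < minRows) stop("too few rows (need at least ", minRows, ")")
  X
}

#' Fit a PLS path model
#'
#' Iterative estimation of the outer (measurement) and inner (structural)
#' model.  Outer weights start at 1; each LV is the standardized weighted
#' sum of its MVs; the inner proxy of an LV is the weighted sum of all
#' adjacent LV scores (either edge direction) with weights given by the
#' scheme -- sign of the score correlation (`centroid`), the correlation
#' itself (`factorial`), or regression coefficients for predecessors and
#' correlations for successors (`path`).  Reflective blocks update
#' weights by MV--proxy correlation (Mode A); formative blocks by
#' within-block least squares of the proxy on the MVs (Mode B).
#' Iteration stops when the largest absolute change of any normalized
#' outer weight drops below `tol`.
#'
#' After convergence each LV is oriented so the MV with the largest
#' absolute loading in its block loads positively; the applied signs are
#' recorded in the result so scores can be flipped back.  Path
#' coefficients and R-squared are obtained by standardized OLS of each
#' endogenous LV score on its predecessor scores (full-precision scores,
#' never a rounded correlation matrix).
#'
#' @param X patients x MVs numeric matrix or data.frame (a `patient_id`
#'   column is used as row names).  Complete, at least 3 rows, unique
#'   column names, every used column with nonzero variance.
#' @param blocks list of [BlockSpec-class] objects; the same column may
#'   appear in several blocks.
#' @param inner an [InnerSpec-class] over exactly the blocks' LVs.
#' @param scheme inner weighting scheme.
#' @param tol convergence tolerance on outer weights.
#' @param maxIter maximum number of iterations; non-convergence yields a
#'   warning and `isConverged(result) == FALSE`.
#' @param gofVariant which blocks contribute communalities to the
#'   goodness-of-fit: all of them, or only blocks with more than one MV
#'   (single-MV blocks have communality 1 by construction and carry no
#'   measurement information).
#' @return A [PLSPMResult-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.8 * x + rnorm(50, sd = 0.6)
#' fit <- plsFit(cbind(x = x, y = y),
#'               list(blockSpec("X", "x", "reflective"),
#'                    blockSpec("Y", "y", "reflective")),
#'               innerSpec(c("X", "Y"), list(c("X", "Y"))))
#' pathCoefficients(fit)$Y   # equals cor(x, y)
#' @export
plsFit <- function(X, blocks, inner,
                   scheme = c("centroid", "factorial", "path"),
                   tol = 1e-6, maxIter = 300L,
                   gofVariant = c("multi_mv_blocks", "all_mvs")) {
  scheme <- match.arg(scheme)
  gofVariant <- match.arg(gofVariant)
  stopifnot(tol > 0, maxIter >= 1L)
  blocks <- lapply(blocks, function(b) { validObject(b); b })
  validObject(inner)
  lvs <- vapply(blocks, function(b) b@lvName, "")
  if (anyDuplicated(lvs)) stop("duplicate block LV names")
  if (!setequal(lvs, inner@lvNames))
    stop("block LVs and inner 'lvNames' must coincide")
  ## reporting order follows inner@lvNames
  blocks <- blocks[match(inner@lvNames, lvs)]
  lvs <- inner@lvNames
  J <- length(lvs)

  allMVs <- unique(unlist(lapply(blocks, function(b) b@mvNames)))
  X <- .asDataMatrix(X, minRows = 3L)
  missing <- setdiff(allMVs, colnames(X))
  if (length(missing))
    stop("columns missing from data: ", paste(missing, collapse = ", "))
  n <- nrow(X)
  for (b in blocks)
    if (b@mode == "formative" && n <= length(b@mvNames))
      stop(sprintf("block '%s': need more rows (%d) than formative MVs (%d)",
                   b@lvName, n, length(b@mvNames)))
  Xs <- standardizeColumns(X[, allMVs, drop = FALSE])
  Xb <- lapply(blocks, function(b) Xs[, b@mvNames, drop = FALSE])
  names(Xb) <- lvs

  ## adjacency (either direction)
  adj <- matrix(FALSE, J, J, dimnames = list(lvs, lvs))
  for (i in seq_len(nrow(inner@edges))) {
    adj[inner@edges[i, 1L], inner@edges[i, 2L]] <- TRUE
    adj[inner@edges[i, 2L], inner@edges[i, 1L]] <- TRUE
  }
  preds <- lapply(lvs, function(lv) predecessorsOf(inner, lv))
  names(preds) <- lvs
  succs <- lapply(lvs, function(lv)
    inner@lvNames[inner@lvNames %in% inner@edges[inner@edges[, 1L] == lv, 2L]])
  names(succs) <- lvs

  normScore <- function(xb, w, lv) {
    y <- drop(xb %*% w)
    s <- sd(y)
    if (!is.finite(s) || s < .Machine$double.eps^0.5)
      stop(sprintf("degenerate (zero-variance) score for LV '%s'", lv))
    list(w = w / s, y = y / s)
  }

  W <- Y <- vector("list", J); names(W) <- names(Y) <- lvs
  for (j in seq_len(J)) {
    ns <- normScore(Xb[[j]], rep(1, ncol(Xb[[j]])), lvs[j])
    W[[j]] <- setNames(ns$w, blocks[[j]]@mvNames); Y[[j]] <- ns$y
  }

  iter <- 0L; converged <- FALSE
  while (iter < maxIter) {
    iter <- iter + 1L
    Ym <- do.call(cbind, Y); colnames(Ym) <- lvs
    C <- cor(Ym)
    E <- matrix(0, J, J, dimnames = list(lvs, lvs))  # E[k, j]: weight of Y_k in Z_j
    for (j in seq_len(J)) {
      a <- which(adj[, j])
      if (!length(a)) next
      if (scheme == "centroid") {
        E[a, j] <- sign(C[a, j])
      } else if (scheme == "factorial") {
        E[a, j] <- C[a, j]
      } else {
        p <- preds[[lvs[j]]]
        if (length(p)) {
          Rpp <- C[p, p, drop = FALSE]
          if (rcond(Rpp) < 1e-12)
            stop(sprintf("collinear predecessor LVs for '%s': %s",
                         lvs[j], paste(p, collapse = ", ")))
          E[p, j] <- solve(Rpp, C[p, j])
        }
        s <- succs[[lvs[j]]]
        if (length(s)) E[s, j] <- C[s, j]
      }
    }
    Z <- Ym %*% E

    Wnew <- W
    for (j in seq_len(J)) {
      xb <- Xb[[j]]
      if (blocks[[j]]@mode == "reflective") {
        w <- drop(crossprod(xb, Z[, j])) / (n - 1)
      } else {
        G <- crossprod(xb)
        if (rcond(G) < 1e-12)
          stop(sprintf(
            "singular within-block covariance in formative block '%s'",
            lvs[j]))
        w <- drop(solve(G, crossprod(xb, Z[, j])))
      }
      ns <- normScore(xb, w, lvs[j])
      Wnew[[j]] <- setNames(ns$w, blocks[[j]]@mvNames); Y[[j]] <- ns$y
    }
    delta <- max(abs(unlist(Wnew) - unlist(W)))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("PLS-PM did not converge in %d iterations", maxIter))

  ## loadings + sign canonicalization
  orient <- setNames(rep(1, J), lvs)
  L <- vector("list", J); names(L) <- lvs
  for (j in seq_len(J)) {
    l <- drop(crossprod(Xb[[j]], Y[[j]])) / (n - 1)
    k <- which.max(abs(l))
    if (l[k] < 0) {
      orient[j] <- -1
      W[[j]] <- -W[[j]]; Y[[j]] <- -Y[[j]]; l <- -l
    }
    L[[j]] <- setNames(pmin(1, pmax(-1, l)), blocks[[j]]@mvNames)
  }
  scores <- do.call(cbind, Y)
  dimnames(scores) <- list(rownames(X), lvs)

  lvCor <- lvCorrelationMatrix(scores)
  pc <- plsPathCoefficients(scores, inner)
  r2 <- pc$rSquared

  comm <- lapply(L, function(l) l^2)
  red <- vector("list", J); names(red) <- lvs
  for (j in seq_len(J)) {
    rj <- if (lvs[j] %in% names(r2)) r2[[lvs[j]]] else 0
    red[[j]] <- comm[[j]] * rj
  }

  multi <- vapply(blocks, function(b) length(b@mvNames) > 1L, TRUE)
  gofBoth <- c(
    all_mvs = goodnessOfFit(unlist(comm), r2),
    multi_mv_blocks = if (any(multi))
      goodnessOfFit(unlist(comm[multi]), r2) else NA_real_)
  gof <- unname(gofBoth[[gofVariant]])

  new("PLSPMResult",
      outerWeights = W, mvLoadings = L, communalities = comm,
      redundancies = red, lvScores = scores, lvCorrelations = lvCor,
      pathCoefficients = pc$coefficients, rSquared = r2,
      gof = gof, gofVariant = gofVariant, gofBoth = gofBoth,
      iterations = iter, converged = converged, orientation = orient,
      scheme = scheme, blocks = blocks, inner = inner)
}

#' Standardized inner-model OLS on LV scores
#'
#' For each endogenous LV, regresses its standardized score on its
#' predecessor scores.  With standardized variables the intercept is 0
#' by construction and the coefficients solve the correlation normal
#' equations at full precision.
#'
#' @param scores patients x LVs matrix of standardized scores (columns
#'   named by LV).
#' @param inner an [InnerSpec-class].
#' @return List with `coefficients` (named list per endogenous LV) and
#'   `rSquared` (named numeric).
#' @export
plsPathCoefficients <- function(scores, inner) {
  validObject(inner)
  stopifnot(is.matrix(scores), all(inner@lvNames %in% colnames(scores)))
  C <- cor(scores)
  endo <- endogenousLVs(inner)
  coefs <- vector("list", length(endo)); names(coefs) <- endo
  r2 <- setNames(numeric(length(endo)), endo)
  for (lv in endo) {
    p <- predecessorsOf(inner, lv)
    Rpp <- C[p, p, drop = FALSE]
    if (rcond(Rpp) < 1e-12)
      stop(sprintf("rank-deficient predecessors for '%s': collinear LVs %s",
                   lv, paste(p, collapse = ", ")))
    b <- drop(solve(Rpp, C[p, lv]))
    coefs[[lv]] <- setNames(b, p)
    r2[[lv]] <- sum(b * C[p, lv])
  }
  list(coefficients = coefs, rSquared = r2)
}

#' Standardized OLS from a correlation matrix
#'
#' Solves the normal equations `R_xx beta = r_xy` for printed or otherwise
#' pre-computed correlation matrices, returning the condition number of
#' `R_xx` so callers can judge whether individual coefficients are
#' numerically meaningful (with near-collinear predictors they are not,
#' even though the implied R-squared is stable).
#'
#' @param corr symmetric correlation matrix with unit diagonal and
#'   dimnames.
#' @param response response variable name.
#' @param predictors ordered predictor names.
#' @return List with `coefficients`, `rSquared` and `conditionNumber`.
#' @examples
#' R <- diag(2); dimnames(R) <- list(c("x", "y"), c("x", "y"))
#' R["x", "y"] <- R["y", "x"] <- 0.6
#' olsFromCorrelation(R, "y", "x")$rSquared   # 0.36
#' @export
olsFromCorrelation <- function(corr, response, predictors) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("'corr' must be a square matrix")
  if (is.null(rownames(corr))) stop("'corr' must have dimnames")
  if (max(abs(corr - t(corr))) > 1e-8) stop("'corr' must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("'corr' must have a unit diagonal")
  stopifnot(length(response) == 1L, response %in% rownames(corr),
            all(predictors %in% rownames(corr)),
            !response %in% predictors, length(predictors) >= 1L)
  Rxx <- corr[predictors, predictors, drop = FALSE]
  rxy <- corr[predictors, response]
  if (rcond(Rxx) < 1e-12)
    stop("singular predictor correlation matrix")
  beta <- drop(solve(Rxx, rxy))
  list(coefficients = setNames(beta, predictors),
       rSquared = sum(beta * rxy),
       conditionNumber = kappa(Rxx, exact = TRUE))
}

#' Goodness-of-fit criterion
#'
#' The global PLS-PM fit criterion: the square root of mean communality
#' times mean R-squared.  When `communalities` is a per-block list the
#' `variant` chooses whether single-MV blocks (communality 1 by
#' construction) contribute.
#'
#' @param communalities numeric vector, or per-block list of numeric
#'   vectors, of MV communalities in `[0, 1]`.
#' @param rSquared numeric vector of endogenous-LV R-squared values.
#' @param variant block filter applied when `communalities` is a list.
#' @return The scalar goodness-of-fit.
#' @examples
#' goodnessOfFit(rep(0.25, 4), c(1, 1))   # 0.5
#' @export
goodnessOfFit <- function(communalities, rSquared,
                          variant = c("multi_mv_blocks", "all_mvs")) {
  variant <- match.arg(variant)
  if (is.list(communalities)) {
    if (variant == "multi_mv_blocks")
      communalities <- communalities[vapply(communalities, length, 1L) > 1L]
    communalities <- unlist(communalities)
  }
  communalities <- as.numeric(communalities)
  rSquared <- as.numeric(rSquared)
  if (!length(communalities) || !length(rSquared))
    stop("'communalities' and 'rSquared' must be non-empty")
  if (any(communalities < -1e-12 | communalities > 1 + 1e-12) ||
      any(rSquared < -1e-12 | rSquared > 1 + 1e-12))
    stop("communalities and R-squared values must lie in [0, 1]")
  sqrt(mean(communalities) * mean(rSquared))
}

#' Communality and redundancy indices
#'
#' Recomputes the per-MV quality indices from a fitted model:
#' communality is the squared MV--LV loading; redundancy is communality
#' times the R-squared of the MV's own LV (zero for exogenous LVs).
#'
#' @param result a [PLSPMResult-class].
#' @return List with per-block `communalities` and `redundancies`.
#' @export
qualityIndices <- function(result) {
  stopifnot(is(result, "PLSPMResult"))
  r2 <- rSquared(result)
  comm <- lapply(mvLoadings(result), function(l) l^2)
  red <- comm
  for (lv in names(red))
    red[[lv]] <- comm[[lv]] * (if (lv %in% names(r2)) r2[[lv]] else 0)
  list(communalities = comm, redundancies = red)
}

#' LV score correlation matrix
#'
#' @param scores patients x LVs matrix of standardized scores.
#' @return Symmetric Pearson correlation matrix with unit diagonal,
#'   labelled by the score column names.
#' @export
lvCorrelationMatrix <- function(scores) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  C <- cor(scores)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}
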