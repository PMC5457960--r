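#' @import methods
#' @importFrom stats cor sd rnorm runif var setNames coef
NULL

## ---------------------------------------------------------------------------
## BlockSpec: one measurement (outer-model) block
## ---------------------------------------------------------------------------

#' Measurement block specification
#'
#' A block ties one latent variable (LV) to its manifest variables (MVs).
#' In a \emph{formative} block the MVs are taken to cause the LV and outer
#' weights are estimated by within-block regression (Mode B); in a
#' \emph{reflective} block the LV causes the MVs and weights follow the
#' MV--proxy correlations (Mode A).  The same data column may appear in
#' several blocks; each block then treats it as its own indicator.
#'
#' @slot lvName name of the latent variable.
#' @slot mvNames ordered manifest-variable (column) names; non-empty and
#'   unique within the block.
#' @slot mode `"formative"` or `"reflective"`.
#' @export
setClass("BlockSpec",
         slots = c(lvName = "character", mvNames = "character",
                   mode = "character"))

setValidity("BlockSpec", function(object) {
  msg <- character()
  if (length(object@lvName) != 1L || !nzchar(object@lvName))
    msg <- c(msg, "'lvName' must be a single non-empty string")
  if (length(object@mvNames) < 1L || any(!nzchar(object@mvNames)))
    msg <- c(msg, "'mvNames' must be a non-empty character vector")
  if (anyDuplicated(object@mvNames))
    msg <- c(msg, "'mvNames' must be unique within a block")
  if (length(object@mode) != 1L ||
      !object@mode %in% c("formative", "reflective"))
    msg <- c(msg, "'mode' must be \"formative\" or \"reflective\"")
  if (length(msg)) msg else TRUE
})

#' Create a measurement block
#'
#' @param lvName latent variable name.
#' @param mvNames manifest variable (column) names.
#' @param mode `"formative"` or `"reflective"`.
#' @return A [BlockSpec-class] object.
#' @examples
#' blockSpec("LV_10", c("B_s_10", "Me_s_10"), "formative")
#' @export
blockSpec <- function(lvName, mvNames, mode = c("formative", "reflective")) {
  mode <- match.arg(mode)
  new("BlockSpec", lvName = as.character(lvName),
      mvNames = as.character(mvNames), mode = mode)
}

setMethod("show", "BlockSpec", function(object) {
  cat(sprintf("BlockSpec '%s' (%s): %s\n", object@lvName, object@mode,
              paste(object@mvNames, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## InnerSpec: the structural (inner) model
## ---------------------------------------------------------------------------

#' Structural (inner) model specification
#'
#' A directed acyclic graph over the latent variables.  Any LV with at
#' least one incoming edge is \emph{endogenous}; the remainder are
#' exogenous.
#'
#' @slot lvNames latent variable names, fixing the reporting order.
#' @slot edges two-column character matrix (`from`, `to`) of directed edges.
#' @export
setClass("InnerSpec",
         slots = c(lvNames = "character", edges = "matrix"))

setValidity("InnerSpec", function(object) {
  msg <- character()
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("'edges' must be a two-column character matrix")
  if (anyDuplicated(object@lvNames))
    msg <- c(msg, "'lvNames' must be unique")
  if (nrow(e)) {
    if (!all(e %in% object@lvNames))
      msg <- c(msg, "all edge endpoints must be in 'lvNames'")
    if (any(e[, 1L] == e[, 2L]))
      msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (is.null(.topoSort(object@lvNames, e)))
    msg <- c(msg, "the inner graph must be acyclic")
  if (nrow(e) == 0L)
    msg <- c(msg, "at least one endogenous LV (incoming edge) is required")
  if (length(msg)) msg else TRUE
})

#' Create a structural model
#'
#' @param lvNames latent variable names.
#' @param edges directed edges, either a two-column matrix/data.frame of
#'   (from, to) pairs or a list of length-2 character vectors.
#' @return An [InnerSpec-class] object.
#' @examples
#' innerSpec(c("A", "B"), list(c("A", "B")))
#' @export
innerSpec <- function(lvNames, edges) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (nrow(edges)) storage.mode(edges) <- "character"
  dimnames(edges) <- list(NULL, c("from", "to"))
  new("InnerSpec", lvNames = as.character(lvNames), edges = edges)
}

## internal: topological order or NULL if cyclic
.topoSort <- function(lvNames, edges) {
  n <- length(lvNames)
  indeg <- setNames(integer(n), lvNames)
  if (nrow(edges))
    for (i in seq_len(nrow(edges)))
      indeg[edges[i, 2L]] <- indeg[edges[i, 2L]] + 1L
  order <- character(0)
  avail <- lvNames[indeg == 0L]
  indeg2 <- indeg
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    if (nrow(edges)) {
      outs <- edges[edges[, 1L] == v, 2L]
      for (w in outs) {
        indeg2[w] <- indeg2[w] - 1L
        if (indeg2[w] == 0L) avail <- c(avail, w)
      }
    }
  }
  if (length(order) == n) order else NULL
}

#' Endogenous latent variables of an inner model
#'
#' @param inner an [InnerSpec-class].
#' @return Character vector of LVs with at least one incoming edge, in
#'   `lvNames` order.
#' @export
endogenousLVs <- function(inner) {
  stopifnot(is(inner, "InnerSpec"))
  inner@lvNames[inner@lvNames %in% inner@edges[, 2L]]
}

#' Direct predecessors of a latent variable
#'
#' @param inner an [InnerSpec-class].
#' @param lv latent variable name.
#' @return Character vector of LVs with an edge into `lv`, in `lvNames`
#'   order.
#' @export
predecessorsOf <- function(inner, lv) {
  stopifnot(is(inner, "InnerSpec"), lv %in% inner@lvNames)
  p <- inner@edges[inner@edges[, 2L] == lv, 1L]
  inner@lvNames[inner@lvNames %in% p]
}

setMethod("show", "InnerSpec", function(object) {
  cat(sprintf("InnerSpec with %d LVs: %s\n", length(object@lvNames),
              paste(object@lvNames, collapse = ", ")))
  if (nrow(object@edges))
    cat("  ", paste(object@edges[, 1L], "->", object@edges[, 2L],
                    collapse = "; "), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## PLSPMResult
## ---------------------------------------------------------------------------

#' Fitted PLS path model
#'
#' Holds everything a fitted PLS path model reports: per-block outer
#' weights and loadings (MV--LV correlations), communalities (loading
#' squared) and redundancies (communality times the own LV's R-squared,
#' zero for exogenous LVs), standardized LV scores, the LV correlation
#' matrix, standardized inner path coefficients with their R-squared,
#' and the goodness-of-fit criterion.
#'
#' @slot outerWeights,mvLoadings,communalities,redundancies named lists
#'   (one element per block, in model order) of named numeric vectors over
#'   the block's MVs.
#' @slot lvScores numeric matrix, patients x LVs; each column has sample
#'   mean 0 and variance 1 (n-1 denominator).
#' @slot lvCorrelations symmetric LV correlation matrix with unit diagonal.
#' @slot pathCoefficients named list per endogenous LV of standardized OLS
#'   coefficients on its inner predecessors.
#' @slot rSquared named numeric, one entry per endogenous LV.
#' @slot gof goodness-of-fit under the selected variant.
#' @slot gofVariant `"multi_mv_blocks"` or `"all_mvs"`.
#' @slot gofBoth both variants, named.
#' @slot iterations,converged iteration count and convergence flag.
#' @slot orientation +1/-1 per LV recording the sign canonicalization
#'   applied after convergence (the MV with the largest absolute loading
#'   in each block is oriented positive).
#' @slot scheme inner weighting scheme used.
#' @slot blocks,inner the model specification that was fitted.
#' @export
setClass("PLSPMResult",
         slots = c(outerWeights = "list", mvLoadings = "list",
                   communalities = "list", redundancies = "list",
                   lvScores = "matrix", lvCorrelations = "matrix",
                   pathCoefficients = "list", rSquared = "numeric",
                   gof = "numeric", gofVariant = "character",
                   gofBoth = "numeric",
                   iterations = "integer", converged = "logical",
                   orientation = "numeric", scheme = "character",
                   blocks = "list", inner = "InnerSpec"))

setValidity("PLSPMResult", function(object) {
  msg <- character()
  sc <- object@lvScores
  if (ncol(sc)) {
    m <- colMeans(sc)
    v <- apply(sc, 2L, var)
    if (any(abs(m) > 1e-8) || any(abs(v - 1) > 1e-8))
      msg <- c(msg, "LV scores must be standardized (mean 0, variance 1)")
  }
  for (b in names(object@mvLoadings)) {
    l <- object@mvLoadings[[b]]
    if (any(abs(l) > 1 + 1e-8))
      msg <- c(msg, sprintf("|loading| > 1 in block '%s'", b))
    if (any(abs(object@communalities[[b]] - l^2) > 1e-12))
      msg <- c(msg, sprintf("communality != loading^2 in block '%s'", b))
  }
  d <- diag(object@lvCorrelations)
  if (length(d) && any(abs(d - 1) > 1e-10))
    msg <- c(msg, "diag(lvCorrelations) must be 1")
  if (any(object@rSquared < -1e-12 | object@rSquared > 1 + 1e-8))
    msg <- c(msg, "R-squared values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PLSPMResult", function(object) {
  cat(sprintf("PLSPMResult: %d LVs, %d patients, scheme '%s'\n",
              ncol(object@lvScores), nrow(object@lvScores), object@scheme))
  cat(sprintf("  converged: %s after %d iterations\n",
              if (object@converged) "yes" else "NO", object@iterations))
  for (lv in names(object@pathCoefficients)) {
    b <- object@pathCoefficients[[lv]]
    cat(sprintf("  %s ~ %s   (R2 = %.4f)\n", lv,
                paste(sprintf("%+.4f %s", b, names(b)), collapse = " "),
                object@rSquared[[lv]]))
  }
  cat(sprintf("  GoF (%s) = %.4f\n", object@gofVariant, object@gof))
})

## ---------------------------------------------------------------------------
## ReferenceFrame
## ---------------------------------------------------------------------------

#' Cephalometric reference frame
#'
#' Two-dimensional orthonormal frame anchored at Sella: `fhAxis` runs
#' along the Frankfort-horizontal direction (posterior to anterior,
#' anterior positive) and `sperpAxis` is its perpendicular through Sella
#' (inferior positive).
#'
#' @slot origin Sella coordinates (mm).
#' @slot fhAxis,sperpAxis orthonormal unit vectors.
#' @export
setClass("ReferenceFrame",
         slots = c(origin = "numeric", fhAxis = "numeric",
                   sperpAxis = "numeric"))

setValidity("ReferenceFrame", function(object) {
  msg <- character()
  if (length(object@origin) != 2L || length(object@fhAxis) != 2L ||
      length(object@sperpAxis) != 2L)
    msg <- c(msg, "origin and axes must be length-2 numeric vectors")
  else {
    if (abs(sum(object@fhAxis^2) - 1) > 1e-8 ||
        abs(sum(object@sperpAxis^2) - 1) > 1e-8)
      msg <- c(msg, "axes must be unit vectors")
    if (abs(sum(object@fhAxis * object@sperpAxis)) > 1e-8)
      msg <- c(msg, "axes must be orthogonal")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReferenceFrame", function(object) {
  cat(sprintf(
    "ReferenceFrame: origin (%.2f, %.2f), FH (%.3f, %.3f), S-perp (%.3f, %.3f)\n",
    object@origin[1L], object@origin[2L], object@fhAxis[1L],
    object@fhAxis[2L], object@sperpAxis[1L], object@sperpAxis[2L]))
})

## ---------------------------------------------------------------------------
## Simulation specifications
## ---------------------------------------------------------------------------

#' Latent-structured simulation specification
#'
#' Describes a generating PLS path model: the structural graph with true
#' path coefficients, one measurement block per LV (reflective blocks
#' with loading targets, formative blocks with an intra-block MV
#' correlation and composite weights), per-endogenous-LV residual
#' standard deviations, sample size and seed.  Residual SDs may be left
#' empty, in which case each endogenous LV's residual variance is set so
#' the LV has unit population variance and the supplied paths are its
#' population standardized coefficients.
#'
#' @slot blocks list of per-LV lists with elements `lvName`, `mvNames`,
#'   `mode`, and either `lambda` (reflective loadings) or `rho` and
#'   `weights` (formative).
#' @slot inner an [InnerSpec-class].
#' @slot paths named numeric, names `"from->to"` for every inner edge.
#' @slot residualSD named numeric over endogenous LVs (possibly empty =
#'   automatic unit-variance residuals).
#' @slot n,seed sample size and RNG seed.
#' @export
setClass("LatentSimSpec",
         slots = c(blocks = "list", inner = "InnerSpec", paths = "numeric",
                   residualSD = "numeric", n = "integer", seed = "integer"))

setValidity("LatentSimSpec", function(object) {
  msg <- character()
  lvs <- vapply(object@blocks, `[[`, "", "lvName")
  if (!setequal(lvs, object@inner@lvNames))
    msg <- c(msg, "block LVs must match inner 'lvNames'")
  mvs <- unlist(lapply(object@blocks, `[[`, "mvNames"))
  if (anyDuplicated(mvs))
    msg <- c(msg, "blocks must use disjoint MV names")
  ek <- paste0(object@inner@edges[, 1L], "->", object@inner@edges[, 2L])
  if (!setequal(names(object@paths), ek))
    msg <- c(msg, "'paths' must name every inner edge as \"from->to\"")
  for (b in object@blocks) {
    if (identical(b$mode, "reflective")) {
      if (is.null(b$lambda) || length(b$lambda) != length(b$mvNames) ||
          any(abs(b$lambda) > 1))
        msg <- c(msg, sprintf("block '%s': 'lambda' must give one loading in [-1,1] per MV",
                              b$lvName))
    } else {
      if (is.null(b$weights) || length(b$weights) != length(b$mvNames))
        msg <- c(msg, sprintf("block '%s': 'weights' must give one weight per MV",
                              b$lvName))
      if (is.null(b$rho) || b$rho <= -1 || b$rho >= 1)
        msg <- c(msg, sprintf("block '%s': 'rho' must lie in (-1, 1)", b$lvName))
    }
  }
  if (object@n < 3L) msg <- c(msg, "'n' must be at least 3")
  if (length(msg)) msg else TRUE
})

#' Create a latent simulation specification
#'
#' @param blocks list of per-LV block descriptions (see
#'   [LatentSimSpec-class]).
#' @param inner an [InnerSpec-class].
#' @param paths named numeric of true path coefficients (`"from->to"`).
#' @param residualSD named numeric of residual SDs per endogenous LV, or
#'   `NULL` for automatic unit-variance residuals.
#' @param n sample size.
#' @param seed RNG seed.
#' @return A [LatentSimSpec-class] object.
#' @export
latentSimSpec <- function(blocks, inner, paths, residualSD = NULL,
                          n = 200L, seed = 1L) {
  if (is.null(residualSD)) residualSD <- numeric(0)
  new("LatentSimSpec", blocks = blocks, inner = inner,
      paths = paths, residualSD = residualSD,
      n = as.integer(n), seed = as.integer(seed))
}

setMethod("show", "LatentSimSpec", function(object) {
  cat(sprintf("LatentSimSpec: %d LVs, %d MVs, n = %d, seed = %d\n",
              length(object@blocks),
              length(unlist(lapply(object@blocks, `[[`, "mvNames"))),
              object@n, object@seed))
})

#' Cephalometric cohort simulation specification
#'
#' Moment-calibrated multivariate-normal generator for a three-timepoint
#' cephalometric cohort.  Per-variable means and SDs at T0/T1/T2 come
#' from the variable roster; the correlation structure is the Kronecker
#' product of a between-variable matrix (exchangeable within the
#' distal-segment block, a lower constant elsewhere) and a
#' between-timepoint matrix (constant correlation), which keeps the
#' joint matrix positive definite while emulating the strong
#' within-segment collinearity of mandibular measurements.
#'
#' @slot roster data.frame with columns `variable`, `mean_T0`, `mean_T1`,
#'   `mean_T2`, `sd_T0`, `sd_T1`, `sd_T2`.
#' @slot distalBlock variables forming the highly collinear
#'   distal-segment block.
#' @slot rhoWithin,rhoBetween,rhoTime correlations within the distal
#'   block, between all other variable pairs, and between timepoints of
#'   the same variable.
#' @slot n,seed cohort size and RNG seed.
#' @export
setClass("CohortSpec",
         slots = c(roster = "data.frame", distalBlock = "character",
                   rhoWithin = "numeric", rhoBetween = "numeric",
                   rhoTime = "numeric", n = "integer", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  need <- c("variable", "mean_T0", "mean_T1", "mean_T2",
            "sd_T0", "sd_T1", "sd_T2")
  if (!all(need %in% names(object@roster)))
    msg <- c(msg, "roster must have columns variable, mean_T*, sd_T*")
  else if (any(as.matrix(object@roster[, c("sd_T0", "sd_T1", "sd_T2")]) < 0))
    msg <- c(msg, "SDs must be non-negative")
  if (!all(object@distalBlock %in% object@roster$variable))
    msg <- c(msg, "distalBlock must be a subset of roster variables")
  for (r in c(object@rhoWithin, object@rhoBetween, object@rhoTime))
    if (r <= -1 || r >= 1) msg <- c(msg, "correlations must lie in (-1, 1)")
  if (object@n < 1L) msg <- c(msg, "'n' must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d variables x 3 timepoints, n = %d, seed = %d\n",
              nrow(object@roster), object@n, object@seed))
  cat(sprintf("  rhoWithin = %.2f, rhoBetween = %.2f, rhoTime = %.2f\n",
              object@rhoWithin, object@rhoBetween, object@rhoTime))
})
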