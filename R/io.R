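## CSV dialects and JSON serialization.
##
## Landmark CSV (long): patient_id, timepoint, landmark, x_mm, y_mm.
## Measurement CSV (wide): patient_id first, then numeric columns named
## <base>_<s|f>_<t> with timepoint suffixes 0/1/2 and increment suffixes
## 10/21/20 (e.g. B_s_10, VD_10, B_s_20).

#' Read a landmark CSV
#'
#' @param path file path.
#' @return Validated long-format landmark data.frame.  Malformed rows
#'   raise an error naming file, line and column; landmark names outside
#'   the documented set raise a warning listing them.
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "landmark", "x_mm", "y_mm")
  if (!identical(names(df)[seq_along(need)], need))
    stop(sprintf("%s: malformed header; expected columns %s",
                 path, paste(need, collapse = ", ")))
  for (col in c("x_mm", "y_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("%s: line %d, column '%s': non-numeric value",
                   path, bad[1L] + 1L, col))
    df[[col]] <- v
  }
  bad <- which(!df$timepoint %in% .TIMEPOINTS)
  if (length(bad))
    stop(sprintf("%s: line %d, column 'timepoint': expected T0/T1/T2",
                 path, bad[1L] + 1L))
  unknown <- setdiff(unique(df$landmark), .KNOWN_LANDMARKS)
  if (length(unknown))
    warning("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  df
}

#' Write a landmark CSV
#'
#' @param landmarks long-format landmark data.frame.
#' @param path file path.
#' @export
writeLandmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement CSV
#'
#' @param path file path.
#' @return Wide measurement data.frame with `patient_id` first.
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "patient_id")
    stop(sprintf("%s: malformed header; first column must be patient_id",
                 path))
  for (col in names(df)[-1L]) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: line %d, column '%s': non-numeric value",
                   path, bad[1L] + 1L, col))
    df[[col]] <- v
  }
  df
}

#' Write a measurement CSV
#'
#' @param rows wide measurement data.frame.
#' @param path file path.
#' @export
writeMeasurements <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a fitted model to a plain list
#'
#' Nested structure: `blocks` (per block, per MV: weight, loading,
#' communality, redundancy), `inner` (per endogenous LV: paths, r2),
#' `lv_correlations`, and `global` (gof, variant, both variants,
#' iterations, converged, scheme, orientation).
#'
#' @param result a [PLSPMResult-class].
#' @return A list suitable for JSON serialization.
#' @export
resultToList <- function(result) {
  stopifnot(is(result, "PLSPMResult"))
  blocks <- lapply(names(outerWeights(result)), function(lv) {
    w <- outerWeights(result)[[lv]]
    l <- mvLoadings(result)[[lv]]
    cm <- communalities(result)[[lv]]
    rd <- redundancies(result)[[lv]]
    mvs <- lapply(names(w), function(mv)
      list(weight = unname(w[[mv]]), loading = unname(l[[mv]]),
           communality = unname(cm[[mv]]), redundancy = unname(rd[[mv]])))
    names(mvs) <- names(w)
    mvs
  })
  names(blocks) <- names(outerWeights(result))
  inner <- lapply(names(pathCoefficients(result)), function(lv)
    list(paths = as.list(pathCoefficients(result)[[lv]]),
         r2 = unname(rSquared(result)[[lv]])))
  names(inner) <- names(pathCoefficients(result))
  list(blocks = blocks, inner = inner,
       lv_correlations = result@lvCorrelations,
       global = list(gof = gofValue(result),
                     gof_variant = result@gofVariant,
                     gof_all_mvs = unname(result@gofBoth[["all_mvs"]]),
                     gof_multi_mv_blocks =
                       unname(result@gofBoth[["multi_mv_blocks"]]),
                     iterations = result@iterations,
                     converged = isConverged(result),
                     scheme = result@scheme,
                     orientation = as.list(orientation(result))))
}

#' Write a fitted model as JSON
#'
#' @param result a [PLSPMResult-class].
#' @param path output file path.
#' @export
writeResult <- function(result, path) {
  jsonlite::write_json(resultToList(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
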