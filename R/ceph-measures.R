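## Cephalometric measurement layer: reference frame, signed distances,
## occlusal vertical dimension, timepoint increments.
##
## Coordinates are Cartesian mm with y increasing upward (digitizer
## convention); all geometry is 2-D, the lateral-cephalogram reduction in
## which the Frankfort-horizontal (FH) and Sella-perpendicular (S-perp)
## planes become lines.

.TIMEPOINTS <- c("T0", "T1", "T2")
.TP_SUFFIX <- c(T0 = "0", T1 = "1", T2 = "2")
## landmarks whose inferior position orients the vertical axis
.GNATHIC <- c("Me", "B", "Pog", "Gn")
.KNOWN_LANDMARKS <- c("Po", "Or", "S", "Na", "Ba", "Cd", "Cp", "A", "B",
                      "Pog", "Me", "Gn", "PNS", "U1", "U1r", "L1", "L1r",
                      "U1t", "L1t", "U6", "L6", "U6mc", "L6mc")

#' Build the cephalometric reference frame
#'
#' The FH axis is the unit vector from Porion to Orbitale (posterior to
#' anterior, so anterior distances are positive); the S-perp axis is its
#' perpendicular through Sella, oriented inferior-positive.  Orientation
#' is resolved by an inferior witness point (any gnathic landmark): the
#' axis is flipped so the witness gets a positive vertical coordinate.
#' Without a witness, the y-up coordinate convention is assumed and the
#' clockwise perpendicular is used.
#'
#' @param Po,Or,S landmark coordinates, length-2 numeric (mm).
#' @param inferior optional witness point known to lie inferior to Sella.
#' @return A [ReferenceFrame-class].
#' @examples
#' buildFrame(Po = c(0, 0), Or = c(10, 0), S = c(2, 5))
#' @export
buildFrame <- function(Po, Or, S, inferior = NULL) {
  Po <- as.numeric(Po); Or <- as.numeric(Or); S <- as.numeric(S)
  stopifnot(length(Po) == 2L, length(Or) == 2L, length(S) == 2L,
            all(is.finite(c(Po, Or, S))))
  d <- Or - Po
  len <- sqrt(sum(d^2))
  if (len < 1e-9) stop("Po and Or coincide; FH line undefined")
  fh <- d / len
  sperp <- c(fh[2L], -fh[1L])   # clockwise: inferior for y-up inputs
  if (!is.null(inferior)) {
    proj <- sum((as.numeric(inferior) - S) * sperp)
    if (abs(proj) > 1e-9 && proj < 0) sperp <- -sperp
  }
  new("ReferenceFrame", origin = S, fhAxis = fh, sperpAxis = sperp)
}

#' Signed horizontal distance (to the S-perpendicular line)
#'
#' Component of `p - Sella` along the FH axis; anterior positive,
#' posterior (e.g. Condylion) negative.
#'
#' @param p point, length-2 numeric (mm).
#' @param frame a [ReferenceFrame-class].
#' @return Signed distance in mm.
#' @export
horizDist <- function(p, frame) {
  stopifnot(is(frame, "ReferenceFrame"))
  sum((as.numeric(p) - frame@origin) * frame@fhAxis)
}

#' Signed vertical distance (to the FH line)
#'
#' Component of `p - Sella` along the S-perp axis; inferior positive.
#'
#' @inheritParams horizDist
#' @return Signed distance in mm.
#' @export
vertDist <- function(p, frame) {
  stopifnot(is(frame, "ReferenceFrame"))
  sum((as.numeric(p) - frame@origin) * frame@sperpAxis)
}

#' Occlusal vertical dimension
#'
#' Distance between the mesial contact points of the upper and lower
#' first molars as projected onto the S-perp direction: the absolute
#' difference of their vertical distances.
#'
#' @param U6mc,L6mc molar mesial contact points, length-2 numeric (mm).
#' @param frame a [ReferenceFrame-class].
#' @return Non-negative distance in mm.
#' @export
occlusalVD <- function(U6mc, L6mc, frame) {
  abs(vertDist(L6mc, frame) - vertDist(U6mc, frame))
}

## internal: landmark long data.frame -> named list of 2-vectors for one
## patient/timepoint
.pointsOf <- function(landmarks, pid, tp) {
  sel <- landmarks$patient_id == pid & landmarks$timepoint == tp
  pts <- landmarks[sel, , drop = FALSE]
  out <- lapply(seq_len(nrow(pts)),
                function(i) c(pts$x_mm[i], pts$y_mm[i]))
  names(out) <- pts$landmark
  out
}

#' Derive measurement rows from landmark coordinates
#'
#' For each patient and timepoint, builds the reference frame from Po,
#' Or and Sella and computes the signed horizontal (`<L>_s_<t>`) and
#' vertical (`<L>_f_<t>`) distance of every other digitized landmark,
#' plus the occlusal vertical dimension `VD_<t>` when both molar mesial
#' contacts are present.  Timepoint suffixes are 0/1/2; increments are
#' appended for every measured quantity as `_10` (T1 - T0) and `_21`
#' (T2 - T1), plus the T0-to-T2 change of the B-point horizontal
#' position, `B_s_20`.
#'
#' @param landmarks long-format data.frame with columns `patient_id`,
#'   `timepoint` (T0/T1/T2), `landmark`, `x_mm`, `y_mm`.
#' @return Wide data.frame, one row per patient, first column
#'   `patient_id`.
#' @export
deriveMeasurements <- function(landmarks) {
  need <- c("patient_id", "timepoint", "landmark", "x_mm", "y_mm")
  if (!all(need %in% names(landmarks)))
    stop("landmark table must have columns ",
         paste(need, collapse = ", "))
  if (!all(landmarks$timepoint %in% .TIMEPOINTS))
    stop("timepoints must be one of ", paste(.TIMEPOINTS, collapse = ", "))
  pids <- unique(landmarks$patient_id)
  rows <- lapply(pids, function(pid) {
    vals <- list(patient_id = pid)
    for (tp in .TIMEPOINTS) {
      pts <- .pointsOf(landmarks, pid, tp)
      for (lm in c("Po", "Or", "S"))
        if (is.null(pts[[lm]]))
          stop(sprintf("patient '%s', timepoint %s: missing landmark '%s'",
                       pid, tp, lm))
      wit <- intersect(.GNATHIC, names(pts))
      frame <- buildFrame(pts$Po, pts$Or, pts$S,
                          inferior = if (length(wit)) pts[[wit[1L]]])
      sfx <- .TP_SUFFIX[[tp]]
      for (lm in setdiff(names(pts), c("Po", "Or", "S"))) {
        vals[[paste0(lm, "_s_", sfx)]] <- horizDist(pts[[lm]], frame)
        vals[[paste0(lm, "_f_", sfx)]] <- vertDist(pts[[lm]], frame)
      }
      if (!is.null(pts$U6mc) && !is.null(pts$L6mc))
        vals[[paste0("VD_", sfx)]] <- occlusalVD(pts$U6mc, pts$L6mc, frame)
    }
    as.data.frame(vals, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  addIncrements(out)
}

#' Append timepoint increments to a measurement table
#'
#' Adds `X_10 = X_1 - X_0` and `X_21 = X_2 - X_1` for every base
#' quantity `X` measured at the required timepoints, and
#' `B_s_20 = B_s_2 - B_s_0`.  Existing increment columns are recomputed.
#'
#' @param rows wide measurement data.frame with `patient_id` and
#'   timepoint-suffixed columns (`_0`, `_1`, `_2`).
#' @return The table with increment columns appended.
#' @export
addIncrements <- function(rows) {
  bases <- unique(sub("_[012]$", "",
                      grep("_[012]$", names(rows), value = TRUE)))
  for (b in bases) {
    c0 <- paste0(b, "_0"); c1 <- paste0(b, "_1"); c2 <- paste0(b, "_2")
    if (all(c(c0, c1) %in% names(rows)))
      rows[[paste0(b, "_10")]] <- rows[[c1]] - rows[[c0]]
    if (all(c(c1, c2) %in% names(rows)))
      rows[[paste0(b, "_21")]] <- rows[[c2]] - rows[[c1]]
  }
  if (all(c("B_s_0", "B_s_2") %in% names(rows)))
    rows[["B_s_20"]] <- rows[["B_s_2"]] - rows[["B_s_0"]]
  rows
}

#' Extract the model's manifest-variable matrix
#'
#' Selects the manifest variables of the setback path model -- surgical
#' setback of B point and Menton (`B_s_10`, `Me_s_10`), postsurgical
#' A-point and coronoid positions (`A_s_1`, `Cp_f_1`), the occlusal
#' vertical dimension change (`VD_10`) and the final setback
#' (`B_s_20`) -- as a patients x MVs numeric matrix.
#'
#' @param rows wide measurement data.frame (see [deriveMeasurements()]).
#' @param extra additional column names to include (e.g. `"Pog_f_10"`).
#' @return Numeric matrix with patient ids as row names.
#' @export
extractMVTable <- function(rows, extra = character()) {
  cols <- c("B_s_10", "Me_s_10", "A_s_1", "Cp_f_1", "VD_10", "B_s_20",
            extra)
  missing <- setdiff(cols, names(rows))
  if (length(missing))
    stop("incomplete measurement rows; missing: ",
         paste(missing, collapse = ", "))
  if (anyNA(rows[, cols]))
    stop("incomplete measurement rows: NA values in model columns")
  m <- as.matrix(rows[, cols, drop = FALSE])
  rownames(m) <- as.character(rows$patient_id)
  m
}
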