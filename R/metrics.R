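#' Dice similarity coefficient
#'
#' \eqn{DSC(P, T) = 2|P \cap T| / (|P| + |T|)} between a predicted and a
#' reference mask; defined as 1 when both are empty.
#'
#' @param P,T \code{\linkS4class{BrainMask}} objects (or 0/1 arrays) of the
#'   same shape.
#' @return Proportion in [0, 1].
#' @examples
#' a <- array(c(1, 0), c(2, 2, 2))
#' dsc(brainMask(a), brainMask(a))  # 1
#' @export
dsc <- function(P, T) {
  p <- if (is(P, "BrainVolume")) P@data else P
  t <- if (is(T, "BrainVolume")) T@data else T
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  denom <- sum(p > 0) + sum(t > 0)
  if (denom == 0) return(1)
  2 * sum(p > 0 & t > 0) / denom
}

#' Voxel-level confusion counts
#'
#' Counts of true/false positive/negative voxels over the full grid, with
#' the prediction P against the reference T.
#'
#' @inheritParams dsc
#' @return List of class \code{"confusionCounts"} with elements
#'   \code{TP, FP, FN, TN}.
#' @export
confusionCounts <- function(P, T) {
  p <- if (is(P, "BrainVolume")) P@data else P
  t <- if (is(T, "BrainVolume")) T@data else T
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  p <- p > 0; t <- t > 0
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusionCounts")
}

#' Combine confusion counts
#'
#' @param ... \code{confusionCounts} objects to pool (voxelwise sums).
#' @return A pooled \code{confusionCounts}.
#' @export
poolCounts <- function(...) {
  cs <- list(...)
  if (length(cs) == 1 && is.list(cs[[1]]) && !inherits(cs[[1]], "confusionCounts"))
    cs <- cs[[1]]
  structure(list(TP = sum(vapply(cs, `[[`, numeric(1), "TP")),
                 FP = sum(vapply(cs, `[[`, numeric(1), "FP")),
                 FN = sum(vapply(cs, `[[`, numeric(1), "FN")),
                 TN = sum(vapply(cs, `[[`, numeric(1), "TN"))),
            class = "confusionCounts")
}

waldCI <- function(p, n) {
  if (n == 0 || !is.finite(p)) return(c(NA_real_, NA_real_))
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Sensitivity, specificity and predictive values with Wald intervals
#'
#' The four voxel-level proportions Se = TP/(TP+FN), Sp = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), each with a 95\% normal-approximation
#' (Wald) confidence interval \eqn{p \pm 1.96\sqrt{p(1-p)/n}} clipped to
#' [0, 1], where n is the metric's own denominator. A metric whose
#' denominator is zero is returned as \code{NA} and flagged.
#'
#' @param counts a \code{\link{confusionCounts}}.
#' @param ci compute confidence intervals (default \code{TRUE}).
#' @return List of class \code{"voxelMetrics"}: \code{Se, Sp, PPV, NPV},
#'   \code{ci95} (named list of \code{c(lo, hi)}), and \code{undefined}
#'   (character vector of flagged metrics).
#' @examples
#' vm <- voxelMetrics(structure(list(TP = 10478, FP = 3025, FN = 1426,
#'                                   TN = 1787261), class = "confusionCounts"))
#' round(vm$Se, 2)  # 0.88
#' @export
voxelMetrics <- function(counts, ci = TRUE) {
  stopifnot(inherits(counts, "confusionCounts"))
  den <- with(counts, list(Se = TP + FN, Sp = TN + FP,
                           PPV = TP + FP, NPV = TN + FN))
  num <- with(counts, list(Se = TP, Sp = TN, PPV = TP, NPV = TN))
  vals <- lapply(names(den), function(k)
    if (den[[k]] > 0) num[[k]] / den[[k]] else NA_real_)
  names(vals) <- names(den)
  out <- vals
  out$ci95 <- if (ci) lapply(names(den), function(k)
    waldCI(vals[[k]], den[[k]])) else NULL
  if (ci) names(out$ci95) <- names(den)
  out$undefined <- names(den)[vapply(den, function(d) d == 0, logical(1))]
  class(out) <- "voxelMetrics"
  out
}

#' Lesion-level detection analysis
#'
#' Labels the connected components of the prediction under
#' 26-connectivity; a reference lesion counts as detected when any
#' component overlaps it by at least one voxel, and components overlapping
#' no lesion count as false-positive detections.
#'
#' @param P predicted \code{BrainMask}.
#' @param truthLesions list of reference lesion \code{BrainMask}s on the
#'   same grid (one per lesion).
#' @return List of class \code{"detectionResult"}: \code{nLesions},
#'   \code{nDetected}, \code{nFalsePositiveComponents},
#'   \code{detectionSensitivity}, \code{detected} (logical per lesion).
#' @export
detectLesions <- function(P, truthLesions) {
  stopifnot(is(P, "BrainMask"))
  if (is(truthLesions, "BrainMask")) truthLesions <- list(truthLesions)
  d <- dim(P@data)
  lab <- array(cpp_label26(as.integer(P@data), d), d)
  nComp <- max(lab)
  hitComps <- integer(0)
  detected <- logical(length(truthLesions))
  for (i in seq_along(truthLesions)) {
    t <- truthLesions[[i]]@data
    if (!identical(dim(t), d)) stop("lesion mask grid mismatch")
    overl <- unique(lab[t > 0 & lab > 0])
    detected[i] <- length(overl) > 0
    hitComps <- union(hitComps, overl)
  }
  nFP <- nComp - length(hitComps)
  structure(list(nLesions = length(truthLesions), nDetected = sum(detected),
                 nFalsePositiveComponents = nFP,
                 detectionSensitivity = if (length(detected))
                   mean(detected) else NA_real_,
                 detected = detected),
            class = "detectionResult")
}
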