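#' Generative parameters for synthetic dynamic FET-PET subjects
#'
#' Describes the statistical structure of a simulated amino-acid PET brain
#' study: low uniform background uptake inside an ellipsoidal brain
#' support, a few physiologic hot structures (venous sinuses, peri-orbital
#' fat, a thin peri-cranial rim), one heterogeneous hyperintense lesion per
#' positive subject, a Gaussian point-spread blur standing in for the
#' reconstruction post-filter, and additive Gaussian noise. Ranges are
#' sampled uniformly per subject.
#'
#' @param gridShape integer(3) grid, default the MNI-like 2 mm grid
#'   (91, 109, 91). The left-right axis is the first axis.
#' @param spacing mm per voxel, default 2 mm isotropic.
#' @param backgroundUptake mean brain background activity (a.u.).
#' @param sinusUptakeFactor range of hot-structure contrast vs background.
#' @param lesionContrast range of peak lesion/background ratio; the lower
#'   bound must exceed 1.3 so the reference thresholding regime is
#'   non-degenerate.
#' @param lesionRadiusMm range of lesion component radius in mm.
#' @param lesionHeterogeneity relative sd of the smooth intra-lesion
#'   activity modulation.
#' @param psfFwhmMm full width at half maximum of the isotropic Gaussian
#'   point-spread blur, in mm.
#' @param noiseSd additive Gaussian noise sd relative to background.
#' @param nFrames,frameDurationMin dynamic protocol (default 10 x 5 min).
#' @param tacSlope range of the per-frame linear trend of lesion activity
#'   (positive = increasing time-activity curve).
#' @return A validated list of class \code{"phantomSpec"}.
#' @examples
#' spec <- phantomSpec(gridShape = c(41, 49, 41))
#' @export
phantomSpec <- function(gridShape = c(91, 109, 91), spacing = c(2, 2, 2),
                        backgroundUptake = 1.0,
                        sinusUptakeFactor = c(1.5, 2.0),
                        lesionContrast = c(2, 4),
                        lesionRadiusMm = c(8, 25),
                        lesionHeterogeneity = 0.2,
                        psfFwhmMm = 5.0, noiseSd = 0.05,
                        nFrames = 10L, frameDurationMin = 5,
                        tacSlope = c(-0.03, 0.05)) {
  rng2 <- function(x) if (length(x) == 1) c(x, x) else as.numeric(x)
  spec <- list(gridShape = as.integer(gridShape), spacing = as.numeric(spacing),
               backgroundUptake = backgroundUptake,
               sinusUptakeFactor = rng2(sinusUptakeFactor),
               lesionContrast = rng2(lesionContrast),
               lesionRadiusMm = rng2(lesionRadiusMm),
               lesionHeterogeneity = lesionHeterogeneity,
               psfFwhmMm = psfFwhmMm, noiseSd = noiseSd,
               nFrames = as.integer(nFrames),
               frameDurationMin = frameDurationMin,
               tacSlope = rng2(tacSlope))
  stopifnot(length(spec$gridShape) == 3, all(spec$gridShape >= 8),
            all(spec$spacing > 0), spec$backgroundUptake > 0,
            spec$lesionContrast[1] > 1.3,
            diff(spec$lesionContrast) >= 0, diff(spec$lesionRadiusMm) >= 0,
            spec$psfFwhmMm >= 0, spec$noiseSd >= 0,
            spec$lesionHeterogeneity >= 0, spec$nFrames >= 1)
  class(spec) <- "phantomSpec"
  spec
}

# Voxel-index coordinate arrays (1-based) for a grid.
gridCoords <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

# Logical ellipsoid support |(p - centre) / semi|^2 <= 1 (voxel units).
ellipsoidMask <- function(co, centre, semi) {
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

# Tube of given radius (voxels) around a polyline given as a matrix of
# voxel coordinates; realized as a union of spheres at dense samples.
tubeMask <- function(co, pts, radius) {
  m <- array(FALSE, dim(co$x))
  for (i in seq_len(nrow(pts)))
    m <- m | ellipsoidMask(co, pts[i, ], rep(radius, 3))
  m
}

# Midline venous structures and peri-cranial rim, all symmetric about the
# left-right midline so that a lesion-free, noise-free phantom is exactly
# mirror-symmetric. Returns the background activity image (zero outside
# the head) and the brain support.
phantomBackground <- function(spec, co, nStruct, sinusFactors) {
  d <- spec$gridShape
  ctr <- (d + 1) / 2
  semi <- d / 3
  brain <- ellipsoidMask(co, ctr, semi)
  img <- array(0, d)
  img[brain] <- spec$backgroundUptake
  # thin peri-cranial rim at ~1.3x background
  rim <- ellipsoidMask(co, ctr, semi * 1.10) & !ellipsoidMask(co, ctr, semi * 1.03)
  img[rim] <- 1.3 * spec$backgroundUptake
  # candidate structures, added in order up to nStruct
  t <- seq(-0.75, 0.75, length.out = 24)
  structs <- list(
    # superior sagittal sinus: midline arc hugging the top of the brain
    cbind(ctr[1], ctr[2] + t * semi[2], ctr[3] + 0.85 * semi[3] * sqrt(pmax(1 - t^2 / 0.85^2, 0))),
    # straight/inferior sagittal sinus: midline posterior run
    cbind(ctr[1], ctr[2] - (0.2 + 0.5 * (t + 0.75) / 1.5) * semi[2],
          ctr[3] + (0.1 + 0.4 * (t + 0.75) / 1.5) * semi[3]),
    # transverse sinuses: symmetric left/right posterior pair
    rbind(cbind(ctr[1] + t * 0.7 * semi[1], ctr[2] - 0.8 * semi[2], ctr[3] - 0.1 * semi[3]),
          cbind(ctr[1] - t * 0.7 * semi[1], ctr[2] - 0.8 * semi[2], ctr[3] - 0.1 * semi[3])),
    # peri-orbital fat: symmetric anterior-inferior blobs
    rbind(cbind(ctr[1] + 0.45 * semi[1], ctr[2] + 0.95 * semi[2], ctr[3] - 0.45 * semi[3]),
          cbind(ctr[1] - 0.45 * semi[1], ctr[2] + 0.95 * semi[2], ctr[3] - 0.45 * semi[3])))
  radii <- c(1.8, 1.5, 1.8, 3.0)
  for (s in seq_len(nStruct)) {
    m <- tubeMask(co, structs[[s]], radii[s])
    img[m] <- sinusFactors[s] * spec$backgroundUptake
  }
  list(img = img, brain = brain)
}

# Smooth zero-mean heterogeneity field over the lesion bounding box.
heterogeneityField <- function(d, support, sdRel) {
  if (sdRel <= 0) return(array(0, d))
  noise <- array(rnorm(prod(d)), d)
  sm <- array(cpp_gaussian_blur3d(as.numeric(noise), d, c(3, 3, 3)), d)
  vals <- sm[support]
  if (sd(vals) == 0) return(array(0, d))
  (sm - mean(vals)) / sd(vals) * sdRel
}

#' Generate one synthetic dynamic FET-PET subject
#'
#' Builds the brain background with physiologic hot structures, places one
#' lesion (a union of 1-3 overlapping ellipsoids modulated by a smooth
#' heterogeneity field) in a single hemisphere, scales lesion activity
#' linearly across frames, then blurs each frame with the point-spread
#' Gaussian and adds noise. Deterministic for a fixed (spec, seed).
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed integer seed.
#' @param side force the lesion hemisphere ("left" = lower indices of the
#'   left-right axis); sampled at random when \code{NULL}.
#' @param lesion set \code{FALSE} for a lesion-free (negative) subject.
#' @return A \code{\linkS4class{PhantomSubject}}.
#' @examples
#' s <- generateSubject(phantomSpec(gridShape = c(41, 49, 41)), seed = 1)
#' @export
generateSubject <- function(spec, seed, side = NULL, lesion = TRUE) {
  stopifnot(inherits(spec, "phantomSpec"))
  seed <- as.integer(seed)
  withSeed(seed, function() {
    d <- spec$gridShape
    sx <- spec$spacing
    co <- gridCoords(d)
    ctr <- (d + 1) / 2
    semi <- d / 3
    nStruct <- sample(2:4, 1)
    sinusFactors <- runif(4, spec$sinusUptakeFactor[1], spec$sinusUptakeFactor[2])
    bg <- phantomBackground(spec, co, nStruct, sinusFactors)

    support <- array(FALSE, d)
    params <- list(nStruct = nStruct, sinusFactors = sinusFactors[seq_len(nStruct)])
    if (lesion) {
      if (is.null(side)) side <- sample(c("left", "right"), 1)
      contrast <- runif(1, spec$lesionContrast[1], spec$lesionContrast[2])
      baseR <- runif(1, spec$lesionRadiusMm[1], spec$lesionRadiusMm[2])
      nell <- sample(1:3, 1)
      placed <- FALSE
      for (try in 1:100) {
        # candidate centre deep inside the brain, clear of the midline
        off <- c(runif(1, 0.25, 0.75), runif(1, -0.55, 0.55), runif(1, -0.55, 0.55))
        if (side == "left") off[1] <- -off[1]
        cen <- ctr + off * semi
        if (abs(cen[1] - ctr[1]) * sx[1] <= baseR + 2 * sx[1]) next
        if (sum(((cen - ctr) / semi)^2) > 0.6) next
        m <- array(FALSE, d)
        cens <- list()
        for (j in seq_len(nell)) {
          cj <- if (j == 1) cen else cen + runif(3, -0.5, 0.5) * baseR / sx
          semj <- runif(3, 0.55, 1.0) * baseR / sx
          m <- m | ellipsoidMask(co, cj, semj)
          cens[[j]] <- cj
        }
        inBrain <- !any(m & !bg$brain)
        oneHemi <- if (side == "left") !any(m & co$x > ctr[1]) else !any(m & co$x < ctr[1])
        if (inBrain && oneHemi && sum(m) > 0) {
          support <- m
          params <- c(params, list(lesionContrast = contrast, baseRadiusMm = baseR,
                                   nEllipsoids = nell, centres = cens))
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place a lesion inside the brain support (seed ",
                        seed, ")")
    } else side <- if (is.null(side)) "none" else side

    het <- if (lesion) heterogeneityField(d, support, spec$lesionHeterogeneity)
           else array(0, d)
    tacSlope <- runif(1, spec$tacSlope[1], spec$tacSlope[2])
    lesionAct <- array(0, d)
    if (lesion) {
      lesionAct[support] <- params$lesionContrast * spec$backgroundUptake *
        (1 + het[support])
      params$tacSlope <- tacSlope
      params$maxLesionActivity <- max(lesionAct)
    }

    sigmaVox <- (spec$psfFwhmMm / (2 * sqrt(2 * log(2)))) / sx
    frames <- vector("list", spec$nFrames)
    for (f in seq_len(spec$nFrames)) {
      img <- bg$img
      if (lesion) img[support] <- lesionAct[support] * (1 + tacSlope * (f - 1))
      if (spec$psfFwhmMm > 0)
        img <- array(cpp_gaussian_blur3d(as.numeric(img), d, sigmaVox), d)
      if (spec$noiseSd > 0)
        img <- img + array(rnorm(prod(d), 0, spec$noiseSd * spec$backgroundUptake), d)
      frames[[f]] <- brainVolume(img, spacing = sx)
    }
    series <- dynamicSeries(frames, frameDurationMin = spec$frameDurationMin)
    summ <- sumFrames(series, 20, 40)
    new("PhantomSubject", series = series, summation = summ,
        truthLesion = brainMask(support * 1, spacing = sx),
        lesionSide = side, spec = unclass(spec), seed = seed, params = params)
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject seeds are derived deterministically from the master seed and
#' lesion sides are balanced to within one subject.
#'
#' @param n number of subjects.
#' @param spec a \code{\link{phantomSpec}}.
#' @param seed master seed.
#' @param transform optional function applied to each subject as it is
#'   generated (e.g. to extract the summation image and drop the dynamic
#'   frames, keeping cohort memory bounded).
#' @return List of \code{\linkS4class{PhantomSubject}} (or of
#'   \code{transform}'s results).
#' @export
generateCohort <- function(n, spec = phantomSpec(), seed = 1L,
                           transform = identity) {
  stopifnot(n >= 1)
  sides <- withSeed(seed, function()
    sample(rep_len(c("left", "right"), n)))
  lapply(seq_len(n), function(i) {
    tryCatch(
      transform(generateSubject(spec, deriveSeed(seed, i), side = sides[i])),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e)))
  })
}
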