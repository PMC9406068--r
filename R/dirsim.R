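# Simulated multi-algorithm DIR contour propagation. The registrations
# themselves are not re-implemented: each "algorithm" is emulated as a
# systematic bias displacement field plus an independent random field, both
# smooth, applied to the ground-truth contours of the daily anatomy. The
# bias term reproduces the observation that intensity-based DIR algorithms
# tend to be systematically closer to each other than to clinical contours.

#' DIR contour-propagation noise model
#'
#' @param nAlgorithms Number of emulated DIR algorithms (`>= 2`).
#' @param biasAmpMM Per-algorithm systematic field amplitude (mm); recycled.
#' @param randomAmpMM Per-algorithm random field amplitude (mm); recycled.
#' @param correlationLengthMM Smoothness scale of both fields (mm).
#' @param targetDiceBand Acceptance band `(low, high)` for the Dice
#'   coefficient of every simulated structure against the clinical contour;
#'   `0 < low < high <= 1`.
#' @param maxRetries Bounded number of re-draws with a perturbed seed when a
#'   simulated set falls outside the Dice band.
#' @param seed Integer seed.
#' @return A validated list of class `"DirNoiseModel"`.
#' @export
dirNoiseModel <- function(nAlgorithms = 3L,
                          biasAmpMM = 2,
                          randomAmpMM = 1,
                          correlationLengthMM = 20,
                          targetDiceBand = c(0.70, 0.995),
                          maxRetries = 8L,
                          seed = 1L) {
  nAlgorithms <- as.integer(nAlgorithms)
  if (nAlgorithms < 2L) stop("nAlgorithms must be >= 2")
  biasAmpMM <- rep_len(biasAmpMM, nAlgorithms)
  randomAmpMM <- rep_len(randomAmpMM, nAlgorithms)
  if (any(biasAmpMM < 0) || any(randomAmpMM < 0)) stop("amplitudes must be >= 0")
  if (correlationLengthMM <= 0) stop("correlationLengthMM must be > 0")
  if (!(targetDiceBand[1] > 0 && targetDiceBand[1] < targetDiceBand[2] &&
        targetDiceBand[2] <= 1)) {
    stop("targetDiceBand must satisfy 0 < low < high <= 1")
  }
  structure(list(
    nAlgorithms = nAlgorithms, biasAmpMM = biasAmpMM, randomAmpMM = randomAmpMM,
    correlationLengthMM = correlationLengthMM, targetDiceBand = targetDiceBand,
    maxRetries = as.integer(maxRetries), seed = as.integer(seed)
  ), class = "DirNoiseModel")
}

#' Simulate DIR-propagated contour ensembles
#'
#' Produces `nAlgorithms` structure sets on the daily grid by warping each
#' ground-truth contour with a per-algorithm displacement field (systematic
#' bias plus random component). Every simulated structure must agree with
#' the clinical contour within the configured Dice band; an algorithm whose
#' draw falls outside the band is re-drawn with a perturbed seed up to
#' `maxRetries` times, after which an error names the offending structure
#' and the band. With all amplitudes zero every simulated set equals the
#' clinical set. The external contour is not propagated (it is assumed
#' observable on the daily image) and is copied from the clinical set.
#'
#' @param daily A daily [Phantom-class] whose structures are ground truth.
#' @param noise A [dirNoiseModel()].
#' @return List of `nAlgorithms` [StructureSet-class] objects.
#' @export
simulateDirSets <- function(daily, noise) {
  stopifnot(is(daily, "Phantom"), inherits(noise, "DirNoiseModel"))
  ss <- daily@structures
  gd <- gridShape(daily); sp <- voxelSpacing(daily)
  propNames <- names(ss@masks)[structureRoles(ss) != "external"]
  out <- vector("list", noise$nAlgorithms)
  for (k in seq_len(noise$nAlgorithms)) {
    zeroAmp <- noise$biasAmpMM[k] == 0 && noise$randomAmpMM[k] == 0
    accepted <- FALSE
    lastBad <- NULL
    for (try in 0:noise$maxRetries) {
      kseed <- noise$seed + 1009L * k + 131L * try
      if (zeroAmp) {
        masks <- ss@masks
        accepted <- TRUE
      } else {
        bias <- smoothRandomField(gd, sp, noise$biasAmpMM[k],
                                  noise$correlationLengthMM, seed = kseed)
        rand <- smoothRandomField(gd, sp, noise$randomAmpMM[k],
                                  noise$correlationLengthMM, seed = kseed + 50000L)
        field <- addFields(bias, rand)
        masks <- ss@masks
        ok <- TRUE
        for (nm in propNames) {
          w <- warpMask(ss@masks[[nm]], field)
          masks[[nm]] <- w
          dc <- diceCoefficient(ss@masks[[nm]], w)
          if (!any(w) || dc < noise$targetDiceBand[1] || dc > noise$targetDiceBand[2]) {
            ok <- FALSE
            lastBad <- sprintf("structure '%s' Dice %.3f outside band [%.3f, %.3f]",
                               nm, dc, noise$targetDiceBand[1], noise$targetDiceBand[2])
            break
          }
        }
        accepted <- ok
      }
      if (accepted) break
    }
    if (!accepted) {
      stop("simulated DIR set ", k, " failed the Dice acceptance band after ",
           noise$maxRetries, " retries: ", lastBad)
    }
    out[[k]] <- structureSet(masks, ss@roles, ss@priorityMode, sp)
  }
  out
}
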