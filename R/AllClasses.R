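#' @include AllGenerics.R
NULL

#' PullbackTrace: a sampled QFR-versus-position curve for one vessel
#'
#' The QFR virtual pullback of a single coronary vessel: the QFR value
#' ("index QFR") sampled at increasing positions along the vessel, measured in
#' millimetres from the proximal landmark (ostium, position 0). The last
#' position is the total analysed vessel length (TVL).
#'
#' @slot vesselId single character, opaque vessel identifier.
#' @slot positions numeric, strictly increasing, first element 0; mm from the
#'   proximal landmark.
#' @slot qfr numeric, same length as `positions`; QFR in (0, 1.05] (values
#'   slightly above 1 are tolerated for measurement noise only).
#' @slot phase `"pre_pci"` or `"post_pci"`.
#'
#' @examples
#' tr <- PullbackTrace("V001", c(0, 40, 80), c(1.00, 0.90, 0.75))
#' totalVesselLength(tr)
#' indexQFR(tr, 60)
#' @export
setClass("PullbackTrace",
         representation(vesselId = "character",
                        positions = "numeric",
                        qfr = "numeric",
                        phase = "character"))

setValidity("PullbackTrace", function(object) {
  msg <- character(0)
  if (length(object@vesselId) != 1L || is.na(object@vesselId))
    msg <- c(msg, "vesselId must be a single non-NA string")
  n <- length(object@positions)
  if (n < 2L || length(object@qfr) != n)
    msg <- c(msg, "positions and qfr must have equal length >= 2")
  if (n >= 1L && (is.na(object@positions[1L]) || abs(object@positions[1L]) > 1e-9))
    msg <- c(msg, "first position must be 0 (proximal landmark)")
  if (n >= 2L && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (any(!is.finite(object@qfr)) || any(object@qfr <= 0) || any(object@qfr > 1.05))
    msg <- c(msg, "qfr values must be finite and in (0, 1.05]")
  if (length(object@phase) != 1L || !object@phase %in% c("pre_pci", "post_pci"))
    msg <- c(msg, "phase must be \"pre_pci\" or \"post_pci\"")
  if (length(msg)) msg else TRUE
})

#' Construct a PullbackTrace
#'
#' @param vesselId vessel identifier.
#' @param positions numeric positions in mm, strictly increasing, starting at 0.
#' @param qfr QFR values at `positions`, in (0, 1.05].
#' @param phase `"pre_pci"` (default) or `"post_pci"`.
#' @return A [PullbackTrace-class] object.
#' @export
PullbackTrace <- function(vesselId, positions, qfr, phase = "pre_pci") {
  new("PullbackTrace", vesselId = as.character(vesselId),
      positions = as.numeric(positions), qfr = as.numeric(qfr),
      phase = as.character(phase))
}

#' @describeIn PullbackTrace vessel identifier
#' @param x a `PullbackTrace`
#' @export
setMethod("vesselId", "PullbackTrace", function(x) x@vesselId)

#' @describeIn PullbackTrace measurement phase
#' @export
setMethod("phase", "PullbackTrace", function(x) x@phase)

#' @describeIn PullbackTrace sampling positions (mm)
#' @export
setMethod("tracePositions", "PullbackTrace", function(x) x@positions)

#' @describeIn PullbackTrace QFR values at the sampling positions
#' @export
setMethod("qfrValues", "PullbackTrace", function(x) x@qfr)

#' @describeIn PullbackTrace total analysed vessel length (mm, last position)
#' @export
setMethod("totalVesselLength", "PullbackTrace",
          function(x) x@positions[length(x@positions)])

setMethod("show", "PullbackTrace", function(object) {
  cat(sprintf("PullbackTrace %s [%s]\n", object@vesselId, object@phase))
  cat(sprintf("  %d samples over %.1f mm; QFR %.3f (ostium) -> %.3f (distal)\n",
              length(object@positions), totalVesselLength(object),
              object@qfr[1L], object@qfr[length(object@qfr)]))
})

setClassUnion("PullbackTraceOrNULL", c("PullbackTrace", "NULL"))

#' CohortSpec: parameters of the synthetic pullback cohort
#'
#' Describes the study conditions emulated by the synthetic-data generator:
#' number of vessels, mixture of functional CAD patterns, total-vessel-length
#' and distal pre-PCI QFR ranges, trace noise, and the mandatory seed.
#'
#' @slot nVessels number of vessels to generate.
#' @slot patternMix named probabilities over `focal`, `serial_lesions`,
#'   `diffuse`, `combination`; must sum to 1.
#' @slot tvlRangeMm uniform range of total vessel length (mm).
#' @slot distalQfrRange target range of the distal pre-PCI QFR.
#' @slot noiseSd standard deviation of i.i.d. Gaussian trace noise (QFR units).
#' @slot seed integer seed (mandatory, for reproducibility).
#' @slot multiVesselFrac fraction of vessels sharing a patient with another
#'   vessel (second vessels of multi-vessel patients).
#' @slot stepMm sampling step of the generated traces (mm).
#' @export
setClass("CohortSpec",
         representation(nVessels = "integer",
                        patternMix = "numeric",
                        tvlRangeMm = "numeric",
                        distalQfrRange = "numeric",
                        noiseSd = "numeric",
                        seed = "integer",
                        multiVesselFrac = "numeric",
                        stepMm = "numeric"))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (object@nVessels < 1L) msg <- c(msg, "nVessels must be >= 1")
  if (!identical(sort(names(object@patternMix)), sort(patternLevels())))
    msg <- c(msg, "patternMix must be named with the four pattern levels")
  if (abs(sum(object@patternMix) - 1) > 1e-8 || any(object@patternMix < 0))
    msg <- c(msg, "patternMix must be non-negative and sum to 1")
  if (length(object@tvlRangeMm) != 2L || diff(object@tvlRangeMm) < 0 ||
      object@tvlRangeMm[1L] < 25)
    msg <- c(msg, "tvlRangeMm must be an increasing range >= 25 mm")
  if (length(object@distalQfrRange) != 2L || diff(object@distalQfrRange) < 0 ||
      object@distalQfrRange[1L] <= 0 || object@distalQfrRange[2L] >= 1)
    msg <- c(msg, "distalQfrRange must be an increasing range within (0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (is.na(object@seed)) msg <- c(msg, "seed is mandatory")
  if (object@multiVesselFrac < 0 || object@multiVesselFrac > 0.5)
    msg <- c(msg, "multiVesselFrac must be in [0, 0.5]")
  if (object@stepMm <= 0 || object@stepMm > 5)
    msg <- c(msg, "stepMm must be in (0, 5] mm")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults reproduce the emulated study conditions: 120 vessels, pattern mix
#' 43/17/12/28% (focal / serial lesions / diffuse / combination), total vessel
#' length uniform on 55-80 mm, distal pre-PCI QFR targeted to 0.70-0.77, and
#' trace noise of 0.005 QFR units.
#'
#' @param nVessels number of vessels.
#' @param patternMix named pattern probabilities (sums to 1).
#' @param tvlRangeMm total vessel length range (mm).
#' @param distalQfrRange distal pre-PCI QFR target range.
#' @param noiseSd trace noise SD (QFR units).
#' @param seed integer seed (mandatory).
#' @param multiVesselFrac fraction of vessels that are a patient's second
#'   vessel (0 disables clustering; the emulated cohort had 120 vessels in 111
#'   patients, i.e. about 0.075).
#' @param stepMm trace sampling step (mm).
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nVessels = 120,
                       patternMix = c(focal = 0.43, serial_lesions = 0.17,
                                      diffuse = 0.12, combination = 0.28),
                       tvlRangeMm = c(55, 80),
                       distalQfrRange = c(0.70, 0.77),
                       noiseSd = 0.005,
                       seed,
                       multiVesselFrac = 0,
                       stepMm = 0.5) {
  qvpAssert(!missing(seed), "invalidParameter", "cohortSpec() requires a seed")
  new("CohortSpec", nVessels = as.integer(nVessels),
      patternMix = patternMix[patternLevels()],
      tvlRangeMm = as.numeric(tvlRangeMm),
      distalQfrRange = as.numeric(distalQfrRange),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed),
      multiVesselFrac = as.numeric(multiVesselFrac),
      stepMm = as.numeric(stepMm))
}

#' @describeIn CohortSpec number of vessels
#' @param x a `CohortSpec`
#' @export
setMethod("nVessels", "CohortSpec", function(x) x@nVessels)

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d vessels, seed %d, noise SD %.3f\n",
              object@nVessels, object@seed, object@noiseSd))
  cat("  pattern mix:",
      paste(sprintf("%s %.0f%%", names(object@patternMix),
                    100 * object@patternMix), collapse = ", "), "\n")
  cat(sprintf("  TVL %.0f-%.0f mm, distal QFR %.2f-%.2f, step %.2f mm\n",
              object@tvlRangeMm[1L], object@tvlRangeMm[2L],
              object@distalQfrRange[1L], object@distalQfrRange[2L],
              object@stepMm))
})

#' SyntheticVessel: generated vessel with ground truth and PCI outcome
#'
#' A synthetic vessel: its pre-PCI pullback trace, the lesion components the
#' trace was built from (ground truth), the generating functional pattern, and
#' - once [simulatePCI()] has run - the stented intervals, post-PCI trace and
#' post-PCI QFR.
#'
#' @slot vesselId vessel identifier.
#' @slot patientId patient identifier (vessels of one patient cluster).
#' @slot tracePre pre-PCI [PullbackTrace-class].
#' @slot tracePost post-PCI trace, or `NULL` before [simulatePCI()].
#' @slot components data.frame of lesion components (kind, startMm, endMm,
#'   centerMm, dropQfr, scaleMm).
#' @slot truePattern generating pattern label.
#' @slot ostialQfr noise-free QFR at the ostium.
#' @slot postQfr distal QFR of the post-PCI trace (NA before PCI).
#' @slot stentedIntervals 2-column matrix of stented [start, end) intervals.
#' @export
setClass("SyntheticVessel",
         representation(vesselId = "character",
                        patientId = "character",
                        tracePre = "PullbackTrace",
                        tracePost = "PullbackTraceOrNULL",
                        components = "data.frame",
                        truePattern = "character",
                        ostialQfr = "numeric",
                        postQfr = "numeric",
                        stentedIntervals = "matrix"))

setValidity("SyntheticVessel", function(object) {
  msg <- character(0)
  if (!object@truePattern %in% patternLevels())
    msg <- c(msg, "truePattern must be one of the four pattern levels")
  if (nrow(object@components) < 1L)
    msg <- c(msg, "a synthetic vessel needs at least one lesion component")
  need <- c("kind", "startMm", "endMm", "dropQfr")
  if (!all(need %in% names(object@components)))
    msg <- c(msg, "components must have kind/startMm/endMm/dropQfr columns")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticVessel vessel identifier
#' @param x a `SyntheticVessel`
#' @export
setMethod("vesselId", "SyntheticVessel", function(x) x@vesselId)

#' @describeIn SyntheticVessel patient identifier
#' @export
setMethod("patientId", "SyntheticVessel", function(x) x@patientId)

#' @describeIn SyntheticVessel pre-PCI trace
#' @export
setMethod("tracePre", "SyntheticVessel", function(x) x@tracePre)

#' @describeIn SyntheticVessel post-PCI trace (or NULL)
#' @export
setMethod("tracePost", "SyntheticVessel", function(x) x@tracePost)

#' @describeIn SyntheticVessel ground-truth lesion components
#' @export
setMethod("lesionComponents", "SyntheticVessel", function(x) x@components)

#' @describeIn SyntheticVessel generating pattern label
#' @export
setMethod("truePattern", "SyntheticVessel", function(x) x@truePattern)

#' @describeIn SyntheticVessel distal post-PCI QFR
#' @export
setMethod("postQFR", "SyntheticVessel", function(x) x@postQfr)

#' @describeIn SyntheticVessel stented intervals (mm)
#' @export
setMethod("stentedIntervals", "SyntheticVessel", function(x) x@stentedIntervals)

setMethod("show", "SyntheticVessel", function(object) {
  cat(sprintf("SyntheticVessel %s (patient %s): %s pattern, %d component(s)\n",
              object@vesselId, object@patientId, object@truePattern,
              nrow(object@components)))
  cat(sprintf("  pre-PCI distal QFR %.3f",
              qfrValues(object@tracePre)[length(qfrValues(object@tracePre))]))
  if (!is.null(object@tracePost))
    cat(sprintf("; post-PCI QFR %.3f (%d stent(s))",
                object@postQfr, nrow(object@stentedIntervals)))
  cat("\n")
})

#' PullbackCohort: a generated cohort of synthetic vessels
#'
#' @slot vessels list of [SyntheticVessel-class] objects.
#' @slot spec the [CohortSpec-class] the cohort was generated from.
#' @export
setClass("PullbackCohort",
         representation(vessels = "list", spec = "CohortSpec"))

setValidity("PullbackCohort", function(object) {
  if (!all(vapply(object@vessels, is, logical(1L), "SyntheticVessel")))
    return("all cohort members must be SyntheticVessel objects")
  TRUE
})

#' @describeIn PullbackCohort list of member vessels
#' @param x a `PullbackCohort`
#' @export
setMethod("vessels", "PullbackCohort", function(x) x@vessels)

#' @describeIn PullbackCohort number of vessels
#' @export
setMethod("nVessels", "PullbackCohort", function(x) length(x@vessels))

#' @describeIn PullbackCohort per-vessel manifest table (patient, pattern,
#'   distal pre/post QFR, stented length)
#' @export
setMethod("cohortManifest", "PullbackCohort", function(x) {
  rows <- lapply(x@vessels, function(v) {
    qPre <- qfrValues(tracePre(v))
    data.frame(vessel_id = vesselId(v),
               patient_id = patientId(v),
               true_pattern = truePattern(v),
               tvl_mm = totalVesselLength(tracePre(v)),
               pre_pci_qfr = qPre[length(qPre)],
               post_pci_qfr = postQFR(v),
               stented_mm = if (nrow(stentedIntervals(v)))
                 sum(stentedIntervals(v)[, 2L] - stentedIntervals(v)[, 1L]) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
})

setMethod("show", "PullbackCohort", function(object) {
  counts <- table(factor(vapply(object@vessels, truePattern, character(1L)),
                         levels = patternLevels()))
  cat(sprintf("PullbackCohort: %d vessels (seed %d)\n",
              length(object@vessels), object@spec@seed))
  cat("  realized mix:",
      paste(sprintf("%s %d", names(counts), as.integer(counts)),
            collapse = ", "), "\n")
})
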