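#' Default green/yellow/red zone scheme for the four geometric parameters
#'
#' Encodes the published traffic-light thresholds: asynclitism degree (AD)
#' is green below 65.5 mm, yellow in the 65.5-70.5 mm cut-off band and red
#' at or above 70.5 mm; angle of progression (AoP) is green in
#' \[101.5, 144.5) degrees and red on either side; head-symphysis distance
#' (HSD) is red at or above 19.5 mm. The midline-angle (MLA) red threshold
#' was not published with the other cut-offs (it is inherited from the
#' antecedent AIDA study), so it is configurable; the default of 45 degrees
#' is the conventional midline-angle cutoff for clinically significant
#' malrotation.
#'
#' Intervals follow a half-open `[lo, hi)` convention with the topmost
#' interval closed, so a red threshold `t` printed as ">= t" maps value `t`
#' itself to RED.
#'
#' @param mla_red MLA red threshold in degrees (default 45).
#' @param ad_green_hi,ad_red_lo AD yellow-band bounds in mm.
#' @param aop_green_lo,aop_green_hi AoP green-band bounds in degrees.
#' @param hsd_red_lo HSD red threshold in mm.
#' @return An object of class `zone_scheme`: a named list (one element per
#'   parameter) of data frames with columns `label`, `lo`, `hi`.
#' @examples
#' sch <- default_zone_scheme()
#' zone_of(72, "ad_mm", sch)   # RED
#' zone_of(68, "ad_mm", sch)   # YELLOW
#' zone_of(120, "aop_deg", sch) # GREEN
#' @export
default_zone_scheme <- function(mla_red = 45,
                                ad_green_hi = 65.5, ad_red_lo = 70.5,
                                aop_green_lo = 101.5, aop_green_hi = 144.5,
                                hsd_red_lo = 19.5) {
  stopifnot(ad_green_hi <= ad_red_lo, aop_green_lo < aop_green_hi)
  scheme <- list(
    ad_mm = data.frame(
      label = c("GREEN", "YELLOW", "RED"),
      lo = c(0, ad_green_hi, ad_red_lo),
      hi = c(ad_green_hi, ad_red_lo, Inf)),
    aop_deg = data.frame(
      label = c("RED", "GREEN", "RED"),
      lo = c(0, aop_green_lo, aop_green_hi),
      hi = c(aop_green_lo, aop_green_hi, 360)),
    hsd_mm = data.frame(
      label = c("GREEN", "RED"),
      lo = c(0, hsd_red_lo),
      hi = c(hsd_red_lo, Inf)),
    mla_deg = data.frame(
      label = c("GREEN", "RED"),
      lo = c(0, mla_red),
      hi = c(mla_red, 360))
  )
  # observed study ranges; values outside are zoned with a warning
  attr(scheme, "evidence_range") <- list(
    ad_mm = c(4, 95), aop_deg = c(72, 192),
    hsd_mm = c(10, 51), mla_deg = c(26, 90))
  class(scheme) <- "zone_scheme"
  validate_zone_scheme(scheme)
  scheme
}

validate_zone_scheme <- function(scheme) {
  stopifnot(all(GEOMETRY_PARAMS %in% names(scheme)))
  for (p in GEOMETRY_PARAMS) {
    iv <- scheme[[p]]
    stopifnot(all(c("label", "lo", "hi") %in% names(iv)),
              all(iv$label %in% ZONE_LEVELS))
    iv <- iv[order(iv$lo), ]
    if (any(iv$lo >= iv$hi & !(iv$lo == iv$hi))) {
      stop("zone scheme for ", p, " has an empty or inverted interval")
    }
    # intervals must tile the admissible range without gap or overlap
    if (nrow(iv) > 1 && any(abs(iv$hi[-nrow(iv)] - iv$lo[-1]) > 1e-9)) {
      stop("zone scheme for ", p, " has gaps or overlaps")
    }
  }
  invisible(scheme)
}

#' Zone label of a measurement under a zone scheme
#'
#' @param value numeric vector of measurements.
#' @param parameter one of `"ad_mm"`, `"aop_deg"`, `"hsd_mm"`, `"mla_deg"`.
#' @param scheme a [default_zone_scheme()]-style `zone_scheme`.
#' @param warn_outside_evidence warn (once per call) when values fall
#'   outside the observed study range; they are still zoned.
#' @return factor with levels GREEN, YELLOW, RED.
#' @export
zone_of <- function(value, parameter, scheme = default_zone_scheme(),
                    warn_outside_evidence = TRUE) {
  parameter <- match.arg(parameter, GEOMETRY_PARAMS)
  iv <- scheme[[parameter]]
  if (any(!is.finite(value))) stop("non-finite ", parameter, " value")
  lo_all <- min(iv$lo)
  hi_all <- max(iv$hi)
  if (any(value < lo_all | value > hi_all)) {
    stop(parameter, " value outside the admissible range [",
         lo_all, ", ", hi_all, "]")
  }
  ev <- attr(scheme, "evidence_range")[[parameter]]
  if (warn_outside_evidence && !is.null(ev)) {
    n_out <- sum(value < ev[1] | value > ev[2])
    if (n_out > 0) {
      warning(n_out, " ", parameter, " value(s) outside the observed study ",
              "range [", ev[1], ", ", ev[2], "]; zoned anyway", call. = FALSE)
    }
  }
  idx <- rep(NA_integer_, length(value))
  for (i in seq_len(nrow(iv))) {
    top <- i == which.max(iv$hi)
    hit <- value >= iv$lo[i] & (value < iv$hi[i] | (top & value <= iv$hi[i]))
    idx[hit & is.na(idx)] <- i
  }
  factor(iv$label[idx], levels = ZONE_LEVELS)
}

#' AIDA class from four zone labels
#'
#' The AIDA class counts how many of the four parameters are outside their
#' green zone: 0 (all green, low risk) through 4 (none green, high risk).
#'
#' @param zones character/factor vector of 4 labels, or a data frame /
#'   matrix with one row per patient and 4 zone columns.
#' @return integer vector of classes in 0..4.
#' @export
aida_class <- function(zones) {
  if (is.data.frame(zones) || is.matrix(zones)) {
    z <- as.matrix(as.data.frame(lapply(as.data.frame(zones), as.character)))
    stopifnot(ncol(z) == 4, all(z %in% ZONE_LEVELS))
    return(as.integer(rowSums(z != "GREEN")))
  }
  zones <- as.character(zones)
  stopifnot(length(zones) == 4, all(zones %in% ZONE_LEVELS))
  as.integer(sum(zones != "GREEN"))
}

#' Zone profile and AIDA class for a cohort
#'
#' Applies [zone_of()] to each of the four geometric parameters of each
#' patient and appends the AIDA class.
#'
#' @param cohort data frame with columns `ad_mm`, `aop_deg`, `hsd_mm`,
#'   `mla_deg` (a full patient-record cohort is accepted).
#' @inheritParams zone_of
#' @return data frame with `zone_ad`, `zone_aop`, `zone_hsd`, `zone_mla`
#'   and `aida_class` (plus `patient_id` when present in the input).
#' @export
zone_profile <- function(cohort, scheme = default_zone_scheme(),
                         warn_outside_evidence = TRUE) {
  stopifnot(all(GEOMETRY_PARAMS %in% names(cohort)))
  out <- data.frame(
    zone_ad  = zone_of(cohort$ad_mm, "ad_mm", scheme, warn_outside_evidence),
    zone_aop = zone_of(cohort$aop_deg, "aop_deg", scheme, warn_outside_evidence),
    zone_hsd = zone_of(cohort$hsd_mm, "hsd_mm", scheme, warn_outside_evidence),
    zone_mla = zone_of(cohort$mla_deg, "mla_deg", scheme, warn_outside_evidence)
  )
  out$aida_class <- as.integer(rowSums(out != "GREEN"))
  if (!is.null(cohort$patient_id)) {
    out <- cbind(patient_id = cohort$patient_id, out)
  }
  out
}
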