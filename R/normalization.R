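#' Normalization and filtering configuration
#'
#' The distal seed coat (DSC) is a much larger tissue than the funiculus
#' (FUN) or chalazal seed coat (CSC); under the assumption of equal RNA
#' isolation efficiency and fixed section thickness, the relative in-vivo
#' mRNA concentration is the microarray signal divided by tissue area.  FUN
#' and CSC have approximately equal areas while the DSC area is about 26.8
#' times larger, so the DSC signal is divided by \code{area_ratio} before any
#' correlation analysis.  Genes whose raw FUN and CSC signals are both below
#' \code{low_signal_threshold} are treated as likely false positives and
#' dropped before grouping.
#'
#' @param area_ratio positive real; DSC area relative to FUN (= CSC) area.
#' @param low_signal_threshold non-negative real; strict-less-than cutoff
#'   applied to the raw FUN and CSC signals jointly.
#' @return a list of class \code{"normalization_config"}.
#' @export
normalization_config <- function(area_ratio = 26.8, low_signal_threshold = 10) {
  if (!is.numeric(area_ratio) || length(area_ratio) != 1L ||
      is.na(area_ratio) || area_ratio <= 0)
    stop("area_ratio must be a positive number")
  if (!is.numeric(low_signal_threshold) || length(low_signal_threshold) != 1L ||
      is.na(low_signal_threshold) || low_signal_threshold < 0)
    stop("low_signal_threshold must be non-negative")
  structure(list(area_ratio = area_ratio,
                 low_signal_threshold = low_signal_threshold),
            class = "normalization_config")
}

#' Area-normalize the DSC signal
#'
#' Sets \code{dsc_norm = dsc_raw / area_ratio} on every profile; FUN and CSC
#' signals are left untouched.  The normalized DSC value is what enters every
#' downstream three-point profile.
#'
#' @param profiles an \code{"expression_profiles"} data frame.
#' @param config a [normalization_config()].
#' @return the profiles with \code{dsc_norm} filled in.
#' @export
normalize_dsc <- function(profiles, config = normalization_config()) {
  stopifnot(inherits(config, "normalization_config"))
  if (anyNA(profiles$dsc_raw)) stop("dsc_raw missing on some profiles")
  profiles$dsc_norm <- profiles$dsc_raw / config$area_ratio
  profiles
}

#' Drop genes with low signal in both FUN and CSC
#'
#' A gene is dropped iff its raw FUN signal AND its raw CSC signal are both
#' strictly below the threshold; the DSC signal is not consulted.  The
#' comparison is on raw, not normalized, signals.
#'
#' @param profiles an \code{"expression_profiles"} data frame.
#' @param config a [normalization_config()].
#' @return list with elements \code{kept} and \code{dropped}, a partition of
#'   the input rows.
#' @export
filter_low_signal <- function(profiles, config = normalization_config()) {
  stopifnot(inherits(config, "normalization_config"))
  thr <- config$low_signal_threshold
  drop <- profiles$fun < thr & profiles$csc < thr
  list(kept = profiles[!drop, , drop = FALSE],
       dropped = profiles[drop, , drop = FALSE])
}
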