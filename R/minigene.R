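#' Inclusion/exclusion (In/Ex) index of a gel lane
#'
#' Ratio of inclusion-isoform to exclusion-isoform band intensity from an
#' RT-PCR or minigene gel, with a small pseudo-intensity so
#' detection-limited zero bands give a finite, strictly positive index.
#' The pseudo-intensity is \code{epsilon_frac} times the lane's maximum
#' intensity, so the index is scale-invariant for intensities well above
#' the detection limit.
#'
#' @param inclusion_intensity,exclusion_intensity non-negative band
#'   intensities (arbitrary units); vectorised.
#' @param epsilon_frac pseudo-intensity as a fraction of the lane maximum
#'   (default 1e-6).
#' @return the In/Ex index, strictly positive and finite.
#' @examples
#' in_ex_index(200, 100)  # 2.0
#' @export
in_ex_index <- function(inclusion_intensity, exclusion_intensity,
                        epsilon_frac = 1e-6) {
  if (any(inclusion_intensity < 0) || any(exclusion_intensity < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  mx <- pmax(inclusion_intensity, exclusion_intensity)
  if (any(mx == 0))
    stop("both band intensities are zero in at least one lane", call. = FALSE)
  eps <- epsilon_frac * mx
  (inclusion_intensity + eps) / (exclusion_intensity + eps)
}

#' Classify a construct's splicing response to splicing-factor perturbation
#'
#' Computes the fold response of the In/Ex index between a control lane and
#' a perturbed lane of the same minigene construct, oriented so that the
#' expected direction of an inclusion-promoting factor gives a fold above
#' one: for a knockdown the fold is In/Ex(control) / In/Ex(perturbed), for
#' an overexpression it is In/Ex(perturbed) / In/Ex(control). A construct is
#' responsive when the fold reaches \code{min_fold} (inclusive) — deletion
#' mutants that lose the factor's binding site drop below it.
#'
#' @param control_lane,perturbed_lane lists or one-row data.frames with
#'   \code{condition} ("control", "knockdown" or "overexpression"),
#'   \code{construct}, \code{inclusion_intensity}, \code{exclusion_intensity}.
#' @param min_fold responsiveness threshold (default 2), inclusive.
#' @param epsilon_frac passed to \code{\link{in_ex_index}}.
#' @return data.frame: \code{construct}, \code{in_ex_control},
#'   \code{in_ex_perturbed}, \code{fold_response}, \code{responsive}.
#' @export
classify_response <- function(control_lane, perturbed_lane, min_fold = 2,
                              epsilon_frac = 1e-6) {
  if (!identical(control_lane$construct, perturbed_lane$construct))
    stop("lanes must assay the same construct", call. = FALSE)
  if (identical(control_lane$condition, perturbed_lane$condition))
    stop("lanes must differ in condition", call. = FALSE)
  if (!identical(as.character(control_lane$condition), "control"))
    stop("control_lane must have condition 'control'", call. = FALSE)
  pert <- as.character(perturbed_lane$condition)
  if (!pert %in% c("knockdown", "overexpression"))
    stop("perturbed condition must be 'knockdown' or 'overexpression'",
         call. = FALSE)
  ie_c <- in_ex_index(control_lane$inclusion_intensity,
                      control_lane$exclusion_intensity, epsilon_frac)
  ie_p <- in_ex_index(perturbed_lane$inclusion_intensity,
                      perturbed_lane$exclusion_intensity, epsilon_frac)
  fold <- if (pert == "knockdown") ie_c / ie_p else ie_p / ie_c
  # inclusive threshold, up to the pseudo-intensity regularisation error
  responsive <- fold >= min_fold * (1 - 4 * epsilon_frac)
  data.frame(construct = as.character(control_lane$construct),
             in_ex_control = ie_c, in_ex_perturbed = ie_p,
             fold_response = fold, responsive = responsive,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantify a whole minigene lane table
#'
#' Pairs each construct's control lane with its perturbed lane and runs
#' \code{\link{classify_response}} on every construct.
#'
#' @param lanes data.frame with columns \code{sample_id}, \code{condition},
#'   \code{construct}, \code{inclusion_intensity}, \code{exclusion_intensity}.
#' @param min_fold,epsilon_frac see \code{\link{classify_response}}.
#' @return data.frame with one row per construct.
#' @export
minigene_responses <- function(lanes, min_fold = 2, epsilon_frac = 1e-6) {
  out <- lapply(unique(lanes$construct), function(cn) {
    sub <- lanes[lanes$construct == cn, ]
    ctrl <- sub[sub$condition == "control", ][1, ]
    pert <- sub[sub$condition != "control", ][1, ]
    if (any(is.na(ctrl$sample_id)) || any(is.na(pert$sample_id)))
      stop("construct ", cn, " lacks a control or perturbed lane",
           call. = FALSE)
    classify_response(ctrl, pert, min_fold, epsilon_frac)
  })
  do.call(rbind, out)
}
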