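#' Percent-spliced-in from inclusion/exclusion junction counts
#'
#' PSI is the estimated fraction of transcripts that include the alternative
#' segment. With \code{normalize = FALSE} (the default) it is the raw
#' junction-read ratio inclusion / (inclusion + exclusion). With
#' \code{normalize = TRUE} the counts are first divided by the number of
#' junction forms supporting each isoform (effective lengths), the usual
#' correction for skipped exons where two junctions support inclusion but
#' only one supports exclusion.
#'
#' Events with zero total reads get \code{NA} PSI, never 0/0; events below
#' \code{min_reads} total are flagged, not dropped — filtering is the
#' screen's concern, not the estimator's.
#'
#' @param counts data.frame with columns \code{event_id}, \code{condition},
#'   \code{inclusion}, \code{exclusion}; optional \code{inclusion_eff_len},
#'   \code{exclusion_eff_len} (default 1). Replicates of one
#'   event/condition are pooled.
#' @param normalize divide counts by effective junction lengths first.
#' @param min_reads coverage below which \code{low_coverage} is set.
#' @return data.frame: \code{event_id}, \code{condition}, \code{psi},
#'   \code{total_reads}, \code{low_coverage}.
#' @examples
#' compute_psi(data.frame(event_id = "e1", condition = "control",
#'                        inclusion = 50, exclusion = 50))
#' @export
compute_psi <- function(counts, normalize = FALSE, min_reads = 10) {
  need <- c("event_id", "condition", "inclusion", "exclusion")
  if (!all(need %in% names(counts)))
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(counts$inclusion < 0) || any(counts$exclusion < 0))
    stop("negative junction counts", call. = FALSE)
  if (is.null(counts$inclusion_eff_len)) counts$inclusion_eff_len <- 1
  if (is.null(counts$exclusion_eff_len)) counts$exclusion_eff_len <- 1
  if (any(counts$inclusion_eff_len < 1) || any(counts$exclusion_eff_len < 1))
    stop("effective lengths must be >= 1", call. = FALSE)
  key <- interaction(counts$event_id, counts$condition, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, sum))
  first <- function(v) as.numeric(tapply(v, key, function(x) x[1]))
  incl <- agg(counts$inclusion); excl <- agg(counts$exclusion)
  il <- first(counts$inclusion_eff_len); el <- first(counts$exclusion_eff_len)
  total <- incl + excl
  psi <- if (normalize) {
    ifelse(total > 0, (incl / il) / (incl / il + excl / el), NA_real_)
  } else {
    ifelse(total > 0, incl / total, NA_real_)
  }
  ids <- tapply(as.character(counts$event_id), key, function(x) x[1])
  cond <- tapply(as.character(counts$condition), key, function(x) x[1])
  out <- data.frame(event_id = as.character(ids),
                    condition = as.character(cond),
                    psi = psi, total_reads = as.integer(total),
                    low_coverage = total < min_reads,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$event_id, out$condition), , drop = FALSE]
}
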