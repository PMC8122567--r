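#' Immunohistochemistry H-score
#'
#' H-score = sum(PI x I) over staining bins, where PI is the percent of
#' positive pixel area (0-100) in a bin and I is the intensity grade
#' (0-3); the score therefore ranges 0-300.
#'
#' @param pi_percent percent positive area per bin, each in [0,100],
#'   summing to at most 100.
#' @param intensity intensity grades per bin, integers in 0..3.
#' @return the H-score in [0, 300].
#' @examples
#' h_score(c(50, 25, 25), c(1, 2, 3))  # 175
#' @export
h_score <- function(pi_percent, intensity) {
  stopifnot(length(pi_percent) == length(intensity))
  if (any(pi_percent < 0) || any(pi_percent > 100))
    stop("PI values must be percentages in [0,100]", call. = FALSE)
  if (sum(pi_percent) > 100 + 1e-9)
    stop("PI values sum to more than 100", call. = FALSE)
  if (any(!intensity %in% 0:3))
    stop("intensity grades must be in {0,1,2,3}", call. = FALSE)
  sum(pi_percent * intensity)
}

#' Xenograft tumor volume
#'
#' volume = length x width^2 / 2, in mm^3 when the calipers read mm. By
#' convention length is the larger axis; reversed inputs are swapped with a
#' warning.
#'
#' @param length,width caliper measurements (non-negative); vectorised.
#' @return tumor volume(s).
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("measurements must be non-negative", call. = FALSE)
  swap <- width > length
  if (any(swap)) {
    warning("width exceeded length; axes swapped")
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Relative wound-closure (migration) area
#'
#' Percent of the initial wound area closed at a later time point:
#' (W0 - Wt) / W0 x 100.
#'
#' @param w0 initial wounded area (> 0).
#' @param wt wounded area at the later time point (>= 0); vectorised.
#' @return closure percentage.
#' @examples
#' relative_migration_area(100, 60)  # 40
#' @export
relative_migration_area <- function(w0, wt) {
  if (any(w0 <= 0)) stop("initial wound area must be positive", call. = FALSE)
  if (any(wt < 0)) stop("wound areas must be non-negative", call. = FALSE)
  (w0 - wt) / w0 * 100
}

#' Assign PSI + expression median-cutoff risk groups
#'
#' High risk = PSI below its cutoff AND expression above its cutoff (low
#' inclusion of the protective isoform, high splicing-factor expression);
#' low risk = PSI above AND expression below. Patients with mixed profiles,
#' or whose value ties a cutoff, belong to neither extreme group and are
#' excluded. Cutoffs default to the medians of the analysed cohort.
#'
#' @param records data.frame with \code{psi} and \code{expression}
#'   (and any survival columns, carried through).
#' @param psi_cutoff,expr_cutoff numeric cutoffs; \code{NULL} (default)
#'   uses the cohort median.
#' @return \code{records} with a \code{risk_group} column
#'   (\code{"high"}, \code{"low"} or \code{"excluded"}) and the cutoffs as
#'   attributes.
#' @export
assign_risk_groups <- function(records, psi_cutoff = NULL, expr_cutoff = NULL) {
  ok <- !is.na(records$psi) & !is.na(records$expression)
  if (sum(ok) < 2) stop("need >= 2 records with psi and expression",
                        call. = FALSE)
  if (is.null(psi_cutoff)) psi_cutoff <- stats::median(records$psi[ok])
  if (is.null(expr_cutoff)) expr_cutoff <- stats::median(records$expression[ok])
  grp <- rep("excluded", nrow(records))
  grp[ok & records$psi < psi_cutoff & records$expression > expr_cutoff] <- "high"
  grp[ok & records$psi > psi_cutoff & records$expression < expr_cutoff] <- "low"
  if (all(grp == "excluded"))
    warning("no patient fell in either extreme risk group")
  records$risk_group <- grp
  attr(records, "psi_cutoff") <- psi_cutoff
  attr(records, "expr_cutoff") <- expr_cutoff
  records
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' Right-continuous survival step function starting at 1; censored subjects
#' leave the risk set without contributing events.
#'
#' @param time follow-up times (>= 0).
#' @param event event indicators (1 = death, 0 = censored).
#' @return an object of class \code{km_fit}: data.frame with one row per
#'   distinct event time: \code{time}, \code{n_risk}, \code{n_event},
#'   \code{survival}.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times", call. = FALSE)
  stopifnot(length(time) == length(event), length(time) >= 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], survival = fit$surv[keep])
  class(out) <- c("km_fit", "data.frame")
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate:", nrow(x), "event times\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Two-group log-rank test
#'
#' At each event time the observed events in the first group are compared
#' with their hypergeometric expectation given the risk sets; the squared
#' standardised sum is chi-square with 1 df. For small cohorts a
#' permutation p-value (random relabelling of group membership) is
#' available.
#'
#' @param time,event follow-up times and event indicators.
#' @param group two-level group labels.
#' @param permutations if > 0, also compute a permutation p-value with this
#'   many resamples (seeded by \code{perm_seed}).
#' @param perm_seed seed for the permutation resampling.
#' @return list: \code{chi_square}, \code{p_value} (asymptotic),
#'   \code{p_permutation} (NA unless requested), \code{n_events}.
#' @export
logrank_test <- function(time, event, group, permutations = 0,
                         perm_seed = 1L) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("need exactly two groups", call. = FALSE)
  if (sum(event) == 0) {
    warning("no events observed; log-rank undefined")
    return(list(chi_square = NA_real_, p_value = NA_real_,
                p_permutation = NA_real_, n_events = 0L))
  }
  stat <- function(g) {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
    sd_$chisq
  }
  chisq <- stat(group)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  p_perm <- NA_real_
  if (permutations > 0) {
    set.seed(perm_seed)
    obs <- chisq
    hits <- 0L
    for (b in seq_len(permutations)) {
      gs <- sample(group)
      s <- tryCatch(stat(gs), error = function(e) NA_real_)
      if (!is.na(s) && s >= obs - 1e-12) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (permutations + 1)
  }
  list(chi_square = chisq, p_value = p, p_permutation = p_perm,
       n_events = sum(event))
}

#' Risk stratification with survival comparison
#'
#' Assigns median-cutoff risk groups, fits Kaplan-Meier curves per group
#' and compares them with the log-rank test — the full survival surface of
#' the pipeline.
#'
#' @param cohort data.frame with \code{time}, \code{event}, \code{psi},
#'   \code{expression}.
#' @param psi_cutoff,expr_cutoff passed to \code{\link{assign_risk_groups}}.
#' @param permutations passed to \code{\link{logrank_test}}.
#' @return list: \code{records} (with risk groups), \code{km} (named list of
#'   \code{km_fit} per group), \code{logrank}, \code{n_high}, \code{n_low}.
#' @export
risk_stratify <- function(cohort, psi_cutoff = NULL, expr_cutoff = NULL,
                          permutations = 0) {
  rec <- assign_risk_groups(cohort, psi_cutoff, expr_cutoff)
  hi <- rec[rec$risk_group == "high", ]
  lo <- rec[rec$risk_group == "low", ]
  km <- list(high = if (nrow(hi)) km_estimate(hi$time, hi$event) else NULL,
             low = if (nrow(lo)) km_estimate(lo$time, lo$event) else NULL)
  lr <- if (nrow(hi) && nrow(lo)) {
    sub <- rec[rec$risk_group != "excluded", ]
    logrank_test(sub$time, sub$event, sub$risk_group,
                 permutations = permutations)
  } else NULL
  list(records = rec, km = km, logrank = lr,
       n_high = nrow(hi), n_low = nrow(lo))
}
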