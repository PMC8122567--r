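#' Per-event test for differential splicing between two conditions
#'
#' With a single library per condition, junction counts are compared with a
#' two-sided Fisher's exact test on the 2x2 table
#' \code{[[incl_ctrl, excl_ctrl], [incl_kd, excl_kd]]}. An event with zero
#' total reads in either condition gets \code{NA}. A binomial
#' likelihood-ratio test is available as a lighter asymptotic alternative.
#'
#' @param incl_control,excl_control,incl_kd,excl_kd junction count vectors,
#'   one entry per event.
#' @param method \code{"fisher"} (exact, default) or \code{"lrt"}
#'   (binomial likelihood ratio, chi-square with 1 df).
#' @return numeric vector of two-sided p-values in (0, 1], \code{NA} where a
#'   condition had no reads.
#' @export
test_event <- function(incl_control, excl_control, incl_kd, excl_kd,
                       method = c("fisher", "lrt")) {
  method <- match.arg(method)
  n <- length(incl_control)
  stopifnot(length(excl_control) == n, length(incl_kd) == n,
            length(excl_kd) == n)
  tot_c <- incl_control + excl_control
  tot_k <- incl_kd + excl_kd
  p <- rep(NA_real_, n)
  ok <- tot_c > 0 & tot_k > 0
  if (method == "fisher") {
    for (i in which(ok)) {
      tab <- matrix(c(incl_control[i], excl_control[i],
                      incl_kd[i], excl_kd[i]), 2, 2, byrow = TRUE)
      p[i] <- stats::fisher.test(tab)$p.value
    }
  } else {
    ll <- function(x, n, pr) stats::dbinom(x, n, pr, log = TRUE)
    for (i in which(ok)) {
      x1 <- incl_control[i]; n1 <- tot_c[i]
      x2 <- incl_kd[i]; n2 <- tot_k[i]
      p0 <- (x1 + x2) / (n1 + n2)
      lr <- 2 * (ll(x1, n1, x1 / n1) + ll(x2, n2, x2 / n2) -
                   ll(x1, n1, p0) - ll(x2, n2, p0))
      p[i] <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    }
  }
  pmin(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values controlling the false discovery rate; order-preserving
#' and bounded by 1. \code{NA} p-values propagate to \code{NA} q-values.
#'
#' @param p_values numeric vector of p-values.
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Screen and classify splicing-factor-regulated events
#'
#' Applies the screening rule FDR < \code{alpha} and |delta PSI| >=
#' \code{min_delta} (both thresholds inclusive at the delta boundary, strict
#' at alpha) and assigns a direction. Delta PSI is knockdown minus control,
#' so events whose inclusion the factor activates move negative under
#' knockdown.
#'
#' @param psi_table output of \code{\link{compute_psi}} with conditions
#'   \code{"control"} and \code{"knockdown"}, or a data.frame already
#'   carrying \code{psi_control}/\code{psi_knockdown} per event.
#' @param counts raw counts (as for \code{\link{compute_psi}}); used for the
#'   per-event test. Replicates are pooled.
#' @param alpha FDR threshold (default 0.05).
#' @param min_delta minimum |delta PSI| (default 0.1), inclusive.
#' @param method test passed to \code{\link{test_event}}.
#' @param events optional event catalog; adds the \code{category} column.
#' @return an object of class \code{splice_screen}: a data.frame with
#'   \code{event_id}, \code{psi_control}, \code{psi_knockdown},
#'   \code{delta_psi}, \code{p_value}, \code{q_value}, \code{direction}
#'   (activated / repressed / unchanged), plus screen parameters as
#'   attributes. Events untestable for zero coverage are kept with
#'   \code{NA} statistics and direction \code{"unchanged"}.
#' @export
screen_events <- function(counts, alpha = 0.05, min_delta = 0.1,
                          method = "fisher", events = NULL) {
  pooled <- stats::aggregate(cbind(inclusion, exclusion) ~ event_id + condition,
                             data = counts, FUN = sum)
  ctrl <- pooled[pooled$condition == "control", ]
  kd <- pooled[pooled$condition == "knockdown", ]
  ids <- sort(intersect(ctrl$event_id, kd$event_id))
  ctrl <- ctrl[match(ids, ctrl$event_id), ]
  kd <- kd[match(ids, kd$event_id), ]
  psi_c <- ifelse(ctrl$inclusion + ctrl$exclusion > 0,
                  ctrl$inclusion / (ctrl$inclusion + ctrl$exclusion), NA_real_)
  psi_k <- ifelse(kd$inclusion + kd$exclusion > 0,
                  kd$inclusion / (kd$inclusion + kd$exclusion), NA_real_)
  p <- test_event(ctrl$inclusion, ctrl$exclusion, kd$inclusion, kd$exclusion,
                  method = method)
  q <- adjust_fdr(p)
  res <- data.frame(event_id = ids, psi_control = psi_c,
                    psi_knockdown = psi_k, delta_psi = psi_k - psi_c,
                    p_value = p, q_value = q, stringsAsFactors = FALSE)
  res <- screen_and_classify(res, alpha = alpha, min_delta = min_delta)
  if (!is.null(events))
    res$category <- events$category[match(res$event_id, events$event_id)]
  attr(res, "alpha") <- alpha
  attr(res, "min_delta") <- min_delta
  attr(res, "method") <- method
  class(res) <- c("splice_screen", "data.frame")
  res
}

#' Apply the screening thresholds and direction calls to test results
#'
#' @param results data.frame with \code{delta_psi} and \code{q_value}.
#' @param alpha FDR threshold (strict).
#' @param min_delta |delta PSI| threshold (inclusive).
#' @return \code{results} with a \code{direction} column: \code{"activated"}
#'   when q < alpha and delta_psi <= -min_delta (knockdown reduces inclusion,
#'   so the factor activates it), \code{"repressed"} when q < alpha and
#'   delta_psi >= +min_delta, else \code{"unchanged"}.
#' @export
screen_and_classify <- function(results, alpha = 0.05, min_delta = 0.1) {
  stopifnot(all(c("delta_psi", "q_value") %in% names(results)))
  d <- results$delta_psi; q <- results$q_value
  dir <- rep("unchanged", nrow(results))
  sig <- !is.na(q) & !is.na(d) & q < alpha
  dir[sig & d <= -min_delta] <- "activated"
  dir[sig & d >= min_delta] <- "repressed"
  results$direction <- dir
  results
}

#' @export
print.splice_screen <- function(x, ...) {
  cat("Differential splicing screen:", nrow(x), "events tested\n")
  cat("  thresholds: FDR <", attr(x, "alpha"), ", |dPSI| >=",
      attr(x, "min_delta"), "(", attr(x, "method"), "test )\n")
  print(table(direction = x$direction))
  invisible(x)
}

#' @export
summary.splice_screen <- function(object, ...) {
  tab <- table(object$direction)
  reg <- sum(object$direction != "unchanged")
  out <- list(
    n_events = nrow(object),
    n_regulated = reg,
    n_activated = sum(object$direction == "activated"),
    n_repressed = sum(object$direction == "repressed"),
    by_category = if (!is.null(object$category))
      table(object$category[object$direction != "unchanged"]) else NULL,
    alpha = attr(object, "alpha"), min_delta = attr(object, "min_delta"))
  class(out) <- "summary.splice_screen"
  out
}

#' @export
print.summary.splice_screen <- function(x, ...) {
  cat(x$n_regulated, "of", x$n_events, "events called regulated (",
      x$n_activated, "activated,", x$n_repressed, "repressed ) at FDR <",
      x$alpha, "and |dPSI| >=", x$min_delta, "\n")
  if (!is.null(x$by_category)) {
    cat("regulated events by category:\n")
    print(x$by_category)
  }
  invisible(x)
}

#' Simple threshold screen for differential gene expression
#'
#' Log2 fold change of group means (with a pseudocount) plus a Welch
#' two-sample t-test on log2-transformed values, BH-adjusted; a gene passes
#' when |log2 FC| exceeds \code{log_fc_threshold} and q < \code{alpha}
#' (the classic volcano-plot rule, e.g. |log2FC| > 1, FDR < 0.05).
#'
#' @param expr_a,expr_b non-negative expression matrices (genes x samples)
#'   with matching rownames for the two groups.
#' @param log_fc_threshold |log2 fold change| cutoff (strict).
#' @param alpha FDR cutoff (strict).
#' @param pseudocount added before taking logs (default 1).
#' @return data.frame: \code{gene}, \code{log_fc} (group B over group A),
#'   \code{p_value}, \code{q_value}, \code{passes}.
#' @export
expression_screen <- function(expr_a, expr_b, log_fc_threshold = 1,
                              alpha = 0.05, pseudocount = 1) {
  expr_a <- as.matrix(expr_a); expr_b <- as.matrix(expr_b)
  stopifnot(nrow(expr_a) == nrow(expr_b))
  if (any(expr_a < 0) || any(expr_b < 0))
    stop("expression values must be non-negative", call. = FALSE)
  genes <- if (!is.null(rownames(expr_a))) rownames(expr_a)
           else sprintf("gene%05d", seq_len(nrow(expr_a)))
  ma <- rowMeans(expr_a); mb <- rowMeans(expr_b)
  log_fc <- log2(mb + pseudocount) - log2(ma + pseudocount)
  log_fc[ma == 0 & mb == 0] <- 0  # constant-zero genes carry no signal
  la <- log2(expr_a + pseudocount); lb <- log2(expr_b + pseudocount)
  p <- rep(NA_real_, nrow(expr_a))
  for (i in seq_len(nrow(expr_a))) {
    a <- la[i, ]; b <- lb[i, ]
    if (length(unique(a)) == 1 && length(unique(b)) == 1) {
      p[i] <- if (identical(a[1], b[1])) 1 else 0
    } else {
      p[i] <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    }
  }
  q <- adjust_fdr(p)
  passes <- !is.na(q) & abs(log_fc) > log_fc_threshold & q < alpha
  data.frame(gene = genes, log_fc = log_fc, p_value = p, q_value = q,
             passes = passes, stringsAsFactors = FALSE, row.names = NULL)
}
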