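AS_CATEGORIES <- c("SE", "RI", "A5SS", "A3SS", "MXE")
REGIONS <- c("upstream_flank", "cassette", "downstream_flank")
REGULATION_LABELS <- c("activated", "repressed", "unchanged")

#' Simulation configuration for a synthetic splicing study
#'
#' Builds and validates the configuration object consumed by the
#' synthetic-data generators. The defaults emulate a two-condition
#' (control vs splicing-factor knockdown) RNA-seq screen: five
#' alternative-splicing categories, binomial junction counts around true PSI
#' values, a knockdown-induced PSI shift for a designated subset of events,
#' and hexamer motifs planted position-dependently (cassette exon for
#' factor-activated events, a flanking constitutive exon for
#' factor-repressed events).
#'
#' @param n_events number of AS events to simulate.
#' @param category_mix named non-negative proportions over
#'   \code{c("SE","RI","A5SS","A3SS","MXE")}; normalised to sum to 1.
#' @param frac_activated fraction of events whose inclusion the factor
#'   activates (knockdown decreases PSI).
#' @param frac_repressed fraction of events whose inclusion the factor
#'   represses (knockdown increases PSI).
#' @param true_delta_psi magnitude of the true knockdown-induced PSI shift.
#' @param coverage mean total junction reads per event and condition.
#' @param planted_motif hexamer planted in the cassette exon of activated
#'   events.
#' @param planted_motif_repressed hexamer planted in a flanking constitutive
#'   exon of repressed events.
#' @param exon_len,flank_len cassette and flanking exon lengths (bases).
#' @param base_comp background base composition (A,C,G,T), i.i.d. model.
#' @param replicates libraries per condition.
#' @param overdispersion if non-NULL, total counts are negative binomial with
#'   this dispersion (variance = mu + disp * mu^2) instead of Poisson.
#' @param seed integer seed giving full determinism.
#' @return an object of class \code{sim_config} (a validated list).
#' @examples
#' cfg <- sim_config(n_events = 50, seed = 1)
#' @export
sim_config <- function(n_events = 2000,
                       category_mix = c(SE = 5038, RI = 121, A5SS = 354,
                                        A3SS = 345, MXE = 841) / 6699,
                       frac_activated = 0.1,
                       frac_repressed = 0.1,
                       true_delta_psi = 0.4,
                       coverage = 100,
                       planted_motif = "GCAGGG",
                       planted_motif_repressed = "GCTGGA",
                       exon_len = 120,
                       flank_len = 120,
                       base_comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       replicates = 1,
                       overdispersion = NULL,
                       seed = 1L) {
  if (length(n_events) != 1L || is.na(n_events) || n_events < 1)
    stop("invalid config: n_events must be >= 1", call. = FALSE)
  if (length(category_mix) != 5L)
    stop("invalid config: category_mix must have five entries", call. = FALSE)
  if (is.null(names(category_mix))) names(category_mix) <- AS_CATEGORIES
  if (!setequal(names(category_mix), AS_CATEGORIES))
    stop("invalid config: category_mix names must be SE/RI/A5SS/A3SS/MXE",
         call. = FALSE)
  category_mix <- category_mix[AS_CATEGORIES]
  if (any(category_mix < 0) || sum(category_mix) <= 0)
    stop("invalid config: category_mix entries must be non-negative with positive sum",
         call. = FALSE)
  category_mix <- category_mix / sum(category_mix)
  stopifnot(abs(sum(category_mix) - 1) < 1e-9)
  if (frac_activated < 0 || frac_repressed < 0 ||
      frac_activated + frac_repressed > 1)
    stop("invalid config: frac_activated + frac_repressed must be <= 1",
         call. = FALSE)
  if (abs(true_delta_psi) > 1)
    stop("invalid config: |true_delta_psi| must be <= 1", call. = FALSE)
  if (coverage <= 0) stop("invalid config: coverage must be positive", call. = FALSE)
  for (m in c(planted_motif, planted_motif_repressed)) {
    if (nchar(m) != 6L || grepl("[^ACGT]", m))
      stop("invalid config: planted motifs must be hexamers over {A,C,G,T}",
           call. = FALSE)
  }
  if (exon_len < nchar(planted_motif) || flank_len < nchar(planted_motif))
    stop("invalid config: exon shorter than motif width", call. = FALSE)
  if (length(base_comp) != 4L || any(base_comp < 0) || sum(base_comp) <= 0)
    stop("invalid config: base_comp must be four non-negative proportions",
         call. = FALSE)
  names(base_comp) <- c("A", "C", "G", "T")
  base_comp <- base_comp / sum(base_comp)
  structure(list(
    n_events = as.integer(n_events), category_mix = category_mix,
    frac_activated = frac_activated, frac_repressed = frac_repressed,
    true_delta_psi = true_delta_psi, coverage = coverage,
    planted_motif = planted_motif,
    planted_motif_repressed = planted_motif_repressed,
    exon_len = as.integer(exon_len), flank_len = as.integer(flank_len),
    base_comp = base_comp, replicates = as.integer(replicates),
    overdispersion = overdispersion, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Splicing simulation config:", x$n_events, "events, coverage",
      x$coverage, "\n")
  cat("  category mix:",
      paste(sprintf("%s=%.3f", names(x$category_mix), x$category_mix),
            collapse = " "), "\n")
  cat("  activated/repressed fractions:", x$frac_activated, "/",
      x$frac_repressed, "; true |dPSI| =", x$true_delta_psi, "\n")
  cat("  planted motifs:", x$planted_motif, "(cassette, activated) /",
      x$planted_motif_repressed, "(flank, repressed)\n")
  invisible(x)
}

# Largest-remainder (Hamilton) apportionment of n among proportions p.
largest_remainder <- function(n, p) {
  quota <- n * p / sum(p)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties in remainder broken by position order
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a synthetic catalog of alternative-splicing events
#'
#' Allocates \code{n_events} across the five AS categories by
#' largest-remainder rounding of \code{category_mix} and lays out 0-based,
#' half-open coordinates for the upstream flanking exon, the alternative
#' (cassette) region and the downstream flanking exon of each event, with
#' non-overlapping regions separated by introns.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a data.frame with one row per event: \code{event_id},
#'   \code{category}, \code{gene}, \code{chrom}, \code{strand} and
#'   start/end columns for the three regions.
#' @export
generate_event_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_events
  counts <- largest_remainder(n, config$category_mix)
  category <- rep(AS_CATEGORIES, counts)
  ids <- sprintf("ev%06d", seq_len(n))
  intron_len <- 300L
  # lay events end to end on synthetic chromosomes, 20 per chromosome
  per_chrom <- 20L
  slot <- (seq_len(n) - 1L) %% per_chrom
  chrom <- sprintf("chr%d", ((seq_len(n) - 1L) %/% per_chrom) + 1L)
  span <- config$flank_len * 2L + config$exon_len + 2L * intron_len + 500L
  up_start <- slot * span + 100L
  up_end <- up_start + config$flank_len
  cas_start <- up_end + intron_len
  cas_end <- cas_start + config$exon_len
  dn_start <- cas_end + intron_len
  dn_end <- dn_start + config$flank_len
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(
    event_id = ids, category = category,
    gene = sprintf("GENE%05d", seq_len(n)),
    chrom = chrom, strand = strand,
    upstream_start = up_start, upstream_end = up_end,
    cassette_start = cas_start, cassette_end = cas_end,
    downstream_start = dn_start, downstream_end = dn_end,
    stringsAsFactors = FALSE
  )
}

random_seq <- function(len, base_comp) {
  paste(sample(names(base_comp), len, replace = TRUE, prob = base_comp),
        collapse = "")
}

# i.i.d. background sequence guaranteed to contain none of `forbidden`
background_seq <- function(len, base_comp, forbidden) {
  repeat {
    s <- random_seq(len, base_comp)
    if (!any(vapply(forbidden, function(m) grepl(m, s, fixed = TRUE), TRUE)))
      return(s)
  }
}

# plant `motif` once at a random position, rejecting layouts that create
# extra copies of any forbidden word
plant_once <- function(len, base_comp, motif, forbidden) {
  w <- nchar(motif)
  repeat {
    s <- background_seq(len, base_comp, forbidden)
    pos <- sample.int(len - w + 1L, 1L)
    s2 <- paste0(substr(s, 1L, pos - 1L), motif, substr(s, pos + w, len))
    hits <- count_kmer_hits(motif, s2)
    others <- setdiff(forbidden, motif)
    clean <- !any(vapply(others, function(m) grepl(m, s2, fixed = TRUE), TRUE))
    if (hits >= 1L && clean) return(s2)
  }
}

#' Plant hexamer motifs position-dependently into event region sequences
#'
#' Generates i.i.d. background sequences for the three regions of every
#' event and plants the configured hexamers according to the regulation
#' label: activated events carry at least one copy of the activated motif
#' inside the cassette exon and no planted copies elsewhere; repressed
#' events carry at least one copy of the repressed motif inside one flanking
#' constitutive exon and none in the cassette; unchanged events carry no
#' planted copies at all. Background windows that spell a planted word by
#' chance are rejected and re-sampled, so the planted signal is the unique
#' ground truth.
#'
#' @param events event catalog from \code{\link{generate_event_catalog}}.
#' @param truth_labels character vector (one per event) over
#'   \code{c("activated","repressed","unchanged")}.
#' @param config a \code{\link{sim_config}}.
#' @return a data.frame with columns \code{event_id}, \code{region},
#'   \code{seq} (sense-strand sequence).
#' @export
plant_motifs <- function(events, truth_labels, config) {
  stopifnot(inherits(config, "sim_config"),
            nrow(events) == length(truth_labels),
            all(truth_labels %in% REGULATION_LABELS))
  set.seed(config$seed + 1L)
  forbidden <- unique(c(config$planted_motif, config$planted_motif_repressed))
  lens <- c(upstream_flank = config$flank_len, cassette = config$exon_len,
            downstream_flank = config$flank_len)
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    lab <- truth_labels[i]
    seqs <- c(upstream_flank = NA_character_, cassette = NA_character_,
              downstream_flank = NA_character_)
    if (lab == "activated") {
      target <- "cassette"
    } else if (lab == "repressed") {
      target <- sample(c("upstream_flank", "downstream_flank"), 1L)
    } else target <- NA_character_
    motif <- switch(lab, activated = config$planted_motif,
                    repressed = config$planted_motif_repressed, NA_character_)
    for (r in REGIONS) {
      seqs[[r]] <- if (!is.na(target) && r == target)
        plant_once(lens[[r]], config$base_comp, motif, forbidden)
      else background_seq(lens[[r]], config$base_comp, forbidden)
    }
    out[[i]] <- data.frame(event_id = events$event_id[i], region = REGIONS,
                           seq = unname(seqs), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Per-event ground truth: regulation label and true PSI in each condition.
make_truth <- function(events, config) {
  set.seed(config$seed + 2L)
  n <- nrow(events)
  n_act <- round(config$frac_activated * n)
  n_rep <- round(config$frac_repressed * n)
  if (n_act + n_rep > n) n_rep <- n - n_act
  labels <- sample(rep(REGULATION_LABELS, c(n_act, n_rep, n - n_act - n_rep)))
  d <- abs(config$true_delta_psi)
  psi_c <- numeric(n); psi_k <- numeric(n)
  act <- labels == "activated"; rep_ <- labels == "repressed"
  unc <- labels == "unchanged"
  lo <- 0.05; hi <- 0.95
  # keep control PSI where the full shift fits, so the true effect size is d
  psi_c[act] <- stats::runif(sum(act), min(hi, lo + d), hi)
  psi_c[rep_] <- stats::runif(sum(rep_), lo, max(lo, hi - d))
  psi_c[unc] <- stats::runif(sum(unc), lo, hi)
  psi_k[act] <- pmin(1, pmax(0, psi_c[act] - d))
  psi_k[rep_] <- pmin(1, pmax(0, psi_c[rep_] + d))
  psi_k[unc] <- psi_c[unc]
  data.frame(event_id = events$event_id, label = labels,
             psi_control = psi_c, psi_knockdown = psi_k,
             motif_region = ifelse(act, "cassette",
                                   ifelse(rep_, "flank", "none")),
             stringsAsFactors = FALSE)
}

#' Simulate inclusion/exclusion junction counts under two conditions
#'
#' For each event, condition and replicate, the total junction read count is
#' Poisson with mean \code{coverage} (negative binomial when
#' \code{overdispersion} is set) and the inclusion-supporting count is
#' binomial with the condition's true PSI as success probability.
#'
#' @param truth truth table with \code{event_id}, \code{psi_control},
#'   \code{psi_knockdown} (as built by \code{\link{simulate_splicing_dataset}}).
#' @param config a \code{\link{sim_config}}.
#' @return a data.frame with columns \code{event_id}, \code{condition},
#'   \code{replicate}, \code{inclusion}, \code{exclusion}.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"),
            all(truth$psi_control >= 0 & truth$psi_control <= 1),
            all(truth$psi_knockdown >= 0 & truth$psi_knockdown <= 1))
  set.seed(config$seed + 3L)
  n <- nrow(truth)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      condition = c("control", "knockdown"),
                      idx = seq_len(n), stringsAsFactors = FALSE)
  psi <- ifelse(grid$condition == "control",
                truth$psi_control[grid$idx], truth$psi_knockdown[grid$idx])
  m <- nrow(grid)
  total <- if (is.null(config$overdispersion)) {
    stats::rpois(m, config$coverage)
  } else {
    stats::rnbinom(m, size = 1 / config$overdispersion, mu = config$coverage)
  }
  incl <- stats::rbinom(m, total, psi)
  data.frame(event_id = truth$event_id[grid$idx],
             condition = grid$condition, replicate = grid$replicate,
             inclusion = incl, exclusion = total - incl,
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic splicing dataset
#'
#' Runs catalog generation, truth assignment, motif planting and count
#' simulation under one seed, returning everything downstream stages need.
#'
#' @param config a \code{\link{sim_config}}.
#' @param sequences generate region sequences with planted motifs
#'   (set \code{FALSE} to skip the slowest step when only counts are needed).
#' @return an object of class \code{splice_dataset}: a list with
#'   \code{events}, \code{truth}, \code{sequences} (or NULL), \code{counts}
#'   and \code{config}.
#' @examples
#' ds <- simulate_splicing_dataset(sim_config(n_events = 30, seed = 7))
#' table(ds$truth$label)
#' @export
simulate_splicing_dataset <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  events <- generate_event_catalog(config)
  truth <- make_truth(events, config)
  seqs <- if (sequences) plant_motifs(events, truth$label, config) else NULL
  counts <- simulate_counts(truth, config)
  structure(list(events = events, truth = truth, sequences = seqs,
                 counts = counts, config = config),
            class = "splice_dataset")
}

#' @export
print.splice_dataset <- function(x, ...) {
  cat("Synthetic splicing dataset:", nrow(x$events), "events\n")
  print(table(category = x$events$category))
  print(table(regulation = x$truth$label))
  invisible(x)
}

#' Simulate a survival cohort with a latent PSI/expression risk structure
#'
#' Event times are exponential with a per-group hazard; censoring is an
#' independent exponential calibrated so the expected censored fraction is
#' \code{censor_rate}. PSI and expression values are drawn so that the
#' latent group matches the median-cutoff risk definition (high risk = low
#' PSI and high expression) up to \code{label_noise}, the probability that a
#' subject's PSI/expression profile is swapped across the cutoffs.
#'
#' @param n cohort size (>= 2).
#' @param group_hazards named positive hazards \code{c(high=, low=)}.
#' @param censor_rate expected fraction censored, in [0,1).
#' @param label_noise probability of a discordant PSI/expression profile.
#' @param seed integer seed.
#' @return a data.frame of survival records: \code{patient_id}, \code{time},
#'   \code{event} (1 = death, 0 = censored), \code{psi}, \code{expression},
#'   \code{latent_group}.
#' @export
simulate_survival_cohort <- function(n, group_hazards = c(high = 0.06, low = 0.02),
                                     censor_rate = 0.2, label_noise = 0,
                                     seed = 1L) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (any(group_hazards <= 0)) stop("hazards must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0,1)", call. = FALSE)
  set.seed(seed)
  group <- sample(rep(c("high", "low"), length.out = n))
  lam <- group_hazards[group]
  t_event <- stats::rexp(n, rate = lam)
  if (censor_rate > 0) {
    mu <- lam * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(n, rate = mu)
  } else t_cens <- rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  flip <- stats::runif(n) < label_noise
  eff <- ifelse(flip, ifelse(group == "high", "low", "high"), group)
  psi <- ifelse(eff == "high", stats::runif(n, 0.0, 0.45),
                stats::runif(n, 0.55, 1.0))
  expr <- ifelse(eff == "high", stats::runif(n, 55, 100),
                 stats::runif(n, 0, 45))
  data.frame(patient_id = sprintf("pt%04d", seq_len(n)),
             time = time, event = event, psi = psi, expression = expr,
             latent_group = group, stringsAsFactors = FALSE)
}
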