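#' Enumerate GA-rich k-mers
#'
#' Returns every word over {A,C,G,T} of length \code{k} containing at least
#' \code{min_G} Gs, at least \code{min_A} As and with a G+A fraction of at
#' least \code{min_GA_fraction} — the candidate serine/arginine-rich
#' splicing-factor binding-site class. At the hexamer defaults this catalog
#' has 2222 members and contains both GCAGGG and GCTGGA.
#'
#' @param k word length (default 6).
#' @param min_G,min_A minimum counts of G and A.
#' @param min_GA_fraction minimum (G+A)/k.
#' @return an object of class \code{kmer_catalog}: a character vector,
#'   sorted lexicographically, with the filter stored as attributes.
#' @examples
#' cat6 <- enumerate_filtered_kmers()
#' length(cat6)
#' @export
enumerate_filtered_kmers <- function(k = 6, min_G = 1, min_A = 1,
                                     min_GA_fraction = 0.5) {
  stopifnot(k >= 1)
  if (min_G + min_A > k) {
    warning("infeasible filter: min_G + min_A > k; returning empty catalog")
    return(structure(character(0), class = "kmer_catalog",
                     k = k, min_G = min_G, min_A = min_A,
                     min_GA_fraction = min_GA_fraction))
  }
  bases <- c("A", "C", "G", "T")
  words <- do.call(paste0, rev(expand.grid(rep(list(bases), k),
                                           stringsAsFactors = FALSE)))
  mat <- matrix(unlist(strsplit(words, "")), ncol = k, byrow = TRUE)
  nG <- rowSums(mat == "G"); nA <- rowSums(mat == "A")
  keep <- nG >= min_G & nA >= min_A & (nG + nA) / k >= min_GA_fraction
  structure(sort(words[keep]), class = "kmer_catalog",
            k = k, min_G = min_G, min_A = min_A,
            min_GA_fraction = min_GA_fraction)
}

#' @export
print.kmer_catalog <- function(x, ...) {
  cat("k-mer catalog:", length(x), "words of length", attr(x, "k"),
      sprintf("(>=%dG, >=%dA, GA fraction >= %g)\n",
              attr(x, "min_G"), attr(x, "min_A"), attr(x, "min_GA_fraction")))
  invisible(x)
}

# overlapping occurrences of one word in one sequence (sliding window)
count_kmer_hits <- function(kmer, seq) {
  w <- nchar(kmer); L <- nchar(seq)
  if (L < w) return(0L)
  starts <- seq_len(L - w + 1L)
  sum(substring(seq, starts, starts + w - 1L) == kmer)
}

#' Count k-mer occurrences in region sequences
#'
#' Overlapping sliding-window counts of each catalog word in each sequence;
#' positions containing N (or any non-ACGT letter) never match. Densities
#' are per kilobase of scanned sequence.
#'
#' @param kmers character vector of words (e.g. a
#'   \code{\link{enumerate_filtered_kmers}} catalog).
#' @param sequences named character vector of uppercase sense-strand
#'   sequences.
#' @param overlapping count overlapping occurrences (default TRUE; when
#'   FALSE, non-overlapping greedy left-to-right counting).
#' @return matrix of counts, kmers x sequences, with a
#'   \code{"scanned_kb"} attribute (total kilobases scanned).
#' @export
count_occurrences <- function(kmers, sequences, overlapping = TRUE) {
  kmers <- as.character(kmers)
  sequences <- toupper(as.character(sequences))
  w <- nchar(kmers[1])
  # index every window once, then tabulate against the catalog
  out <- matrix(0L, nrow = length(kmers), ncol = length(sequences),
                dimnames = list(kmers, names(sequences)))
  for (j in seq_along(sequences)) {
    s <- sequences[j]; L <- nchar(s)
    if (L < w) next
    if (overlapping) {
      starts <- seq_len(L - w + 1L)
      wins <- substring(s, starts, starts + w - 1L)
      tab <- table(factor(wins, levels = kmers))
      out[, j] <- as.integer(tab)
    } else {
      for (i in seq_along(kmers)) {
        out[i, j] <- length(gregexpr(kmers[i], s, fixed = TRUE)[[1]][
          gregexpr(kmers[i], s, fixed = TRUE)[[1]] > 0])
      }
    }
  }
  attr(out, "scanned_kb") <- sum(pmax(nchar(sequences) - w + 1, 0)) / 1000
  out
}

#' Select the top activated and repressed skipped-exon event sets
#'
#' Restricts to SE-category events, ranks each direction by q-value
#' ascending with ties broken by |delta PSI| descending and then by
#' event_id, and takes the top \code{n_per_set} of each — the event sets
#' used for motif discovery.
#'
#' @param results a \code{\link{screen_events}} result (needs
#'   \code{category}, \code{direction}, \code{q_value}, \code{delta_psi}).
#' @param n_per_set events per direction (default 50).
#' @return list with character vectors \code{activated} and
#'   \code{repressed} of event ids.
#' @export
select_event_sets <- function(results, n_per_set = 50) {
  stopifnot(!is.null(results$category))
  pick <- function(dir) {
    sub <- results[results$direction == dir & results$category == "SE", ]
    if (nrow(sub) < n_per_set)
      warning(sprintf("only %d %s SE events available (requested %d)",
                      nrow(sub), dir, n_per_set))
    ord <- order(sub$q_value, -abs(sub$delta_psi), sub$event_id)
    utils::head(sub$event_id[ord], n_per_set)
  }
  list(activated = pick("activated"), repressed = pick("repressed"))
}

#' K-mer enrichment of foreground over background regions
#'
#' For each catalog word, compares its occurrence frequency (hits per
#' scanned window) in the foreground sequences against the background with
#' a binomial z-score under the background frequency, two-sided normal
#' p-values and BH q-values. Background words never observed get a
#' pseudo-frequency of one occurrence over the total background windows.
#'
#' @param foreground,background character vectors of sequences.
#' @param kmers word catalog.
#' @return data.frame ranked by z descending: \code{kmer},
#'   \code{foreground_freq}, \code{background_freq} (per kilobase),
#'   \code{z_score}, \code{p_value}, \code{q_value}.
#' @export
kmer_enrichment <- function(foreground, background, kmers) {
  if (length(foreground) == 0 || length(background) == 0)
    stop("foreground and background must be non-empty", call. = FALSE)
  fg <- count_occurrences(kmers, foreground)
  bg <- count_occurrences(kmers, background)
  w <- nchar(as.character(kmers)[1])
  n_fg <- sum(pmax(nchar(foreground) - w + 1, 0))
  n_bg <- sum(pmax(nchar(background) - w + 1, 0))
  x_fg <- rowSums(fg); x_bg <- rowSums(bg)
  p0 <- x_bg / n_bg
  p0[p0 == 0] <- 1 / n_bg  # pseudo-frequency for unseen background words
  p0 <- pmin(p0, 1)
  z <- (x_fg - n_fg * p0) / sqrt(n_fg * p0 * (1 - p0))
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(kmer = as.character(kmers),
                    foreground_freq = x_fg / n_fg * 1000,
                    background_freq = x_bg / n_bg * 1000,
                    z_score = z, p_value = p, q_value = adjust_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$z_score, out$kmer), , drop = FALSE]
}

#' Positional preference of candidate binding words
#'
#' Computes hit densities (hits per kilobase) of a k-mer catalog in the
#' cassette exon, upstream flank and downstream flank of the activated and
#' repressed event sets, and calls the preferred region of each set. The
#' two flanks are additionally pooled into a single "flank" density so the
#' cassette-versus-flank contrast is read off directly.
#'
#' @param sequences region sequence table (\code{event_id}, \code{region},
#'   \code{seq}) as produced by \code{\link{plant_motifs}}.
#' @param activated_ids,repressed_ids event ids of the two sets.
#' @param kmers words to scan — typically the top enriched candidates from
#'   \code{\link{kmer_enrichment}}; scanning the full GA-rich catalog buries
#'   any positional signal under background hits.
#' @return an object of class \code{positional_profile}: data.frame of
#'   densities (set x region) with attributes \code{preference} (named
#'   character: "cassette" or "flank" per set, NA when no hits) and
#'   \code{density_ratio} (cassette / flank density per set).
#' @export
positional_preference <- function(sequences, activated_ids, repressed_ids,
                                  kmers) {
  dens <- function(ids, region_set) {
    sub <- sequences[sequences$event_id %in% ids &
                       sequences$region %in% region_set, ]
    if (nrow(sub) == 0) return(c(hits = 0, kb = 0))
    cts <- count_occurrences(kmers, sub$seq)
    c(hits = sum(cts), kb = attr(cts, "scanned_kb"))
  }
  sets <- list(activated = activated_ids, repressed = repressed_ids)
  regions <- list(cassette = "cassette", upstream_flank = "upstream_flank",
                  downstream_flank = "downstream_flank",
                  flank = c("upstream_flank", "downstream_flank"))
  prof <- do.call(rbind, lapply(names(sets), function(s) {
    hv <- vapply(regions, function(r) {
      d <- dens(sets[[s]], r); if (d["kb"] > 0) d["hits"] / d["kb"] else 0
    }, numeric(1))
    data.frame(set = s, region = names(regions), density = unname(hv),
               stringsAsFactors = FALSE)
  }))
  pref <- vapply(names(sets), function(s) {
    sub <- prof[prof$set == s & prof$region %in%
                  c("cassette", "flank"), ]
    if (all(sub$density == 0)) return(NA_character_)
    sub$region[which.max(sub$density)]
  }, character(1))
  ratio <- vapply(names(sets), function(s) {
    cassette <- prof$density[prof$set == s & prof$region == "cassette"]
    flank <- prof$density[prof$set == s & prof$region == "flank"]
    if (flank == 0) Inf else cassette / flank
  }, numeric(1))
  structure(prof, class = c("positional_profile", "data.frame"),
            preference = pref, density_ratio = ratio)
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("Positional k-mer hit densities (per kb):\n")
  print.data.frame(x, row.names = FALSE)
  pref <- attr(x, "preference")
  for (s in names(pref))
    cat(sprintf("  %s set prefers: %s (cassette/flank ratio %.2f)\n",
                s, ifelse(is.na(pref[s]), "undefined (no hits)", pref[s]),
                attr(x, "density_ratio")[s]))
  invisible(x)
}

#' Elicit a position weight matrix motif by expectation-maximisation
#'
#' Fits a one-occurrence-per-sequence (OOPS) motif model with a uniform
#' background by EM: the E-step computes the posterior over start positions
#' in each sequence, the M-step re-estimates the PWM from posterior-weighted
#' base counts with a Dirichlet pseudocount. Initialisation is
#' deterministic, from \code{init_kmer} (by default the most enriched word
#' should be supplied). The recorded objective is the observed-data
#' log-likelihood plus the pseudocount prior term, which EM never decreases.
#'
#' @param sequences character vector (>= 2) of sequences, each at least
#'   \code{width} long.
#' @param width motif width (default 6).
#' @param init_kmer word of length \code{width} used to seed the PWM
#'   (its bases get probability 0.7, the rest 0.1).
#' @param pseudocount Dirichlet pseudocount per base (default 0.1).
#' @param max_iter,tol stopping rule: at most \code{max_iter} iterations or
#'   objective improvement below \code{tol}.
#' @return an object of class \code{motif_model}: list with \code{pwm}
#'   (4 x width probability matrix, columns sum to 1), \code{consensus}
#'   (per-column argmax word), \code{loglik_trace}, \code{width},
#'   \code{pseudocount}, \code{n_iter}, \code{converged}.
#' @examples
#' seqs <- paste0(strrep("CT", 10), "GCAGGG", strrep("TC", 10))
#' m <- elicit_motif(rep(seqs, 5), init_kmer = "GCAGGG")
#' m$consensus
#' @export
elicit_motif <- function(sequences, width = 6, init_kmer = NULL,
                         pseudocount = 0.1, max_iter = 200, tol = 1e-6) {
  sequences <- toupper(as.character(sequences))
  if (length(sequences) < 2) stop("need at least 2 sequences", call. = FALSE)
  short <- which(nchar(sequences) < width)
  if (length(short))
    stop("sequence ", short[1], " is shorter than the motif width",
         call. = FALSE)
  bases <- c("A", "C", "G", "T")
  enc <- lapply(sequences, function(s)
    match(strsplit(s, "")[[1]], bases))  # NA for non-ACGT
  if (is.null(init_kmer)) init_kmer <- paste(rep("A", width), collapse = "")
  stopifnot(nchar(init_kmer) == width)
  pwm <- matrix(0.1, 4, width, dimnames = list(bases, NULL))
  init <- match(strsplit(init_kmer, "")[[1]], bases)
  for (j in seq_len(width)) pwm[init[j], j] <- 0.7
  pwm <- sweep(pwm, 2, colSums(pwm), "/")

  log_bg <- log(0.25)
  obj <- function(pwm) {
    lp <- log(pwm)
    ll <- 0
    for (e in enc) {
      m <- length(e) - width + 1L
      lw <- vapply(seq_len(m), function(pos) {
        idx <- e[pos:(pos + width - 1L)]
        if (anyNA(idx)) -Inf else sum(lp[cbind(idx, seq_len(width))])
      }, numeric(1))
      # uniform prior over starts; background covers the rest of the sequence
      ll <- ll + (length(e) - width) * log_bg +
        log(mean(exp(lw - max(lw)))) + max(lw)
    }
    ll + pseudocount * sum(log(pwm))  # Dirichlet prior term
  }

  trace <- obj(pwm)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    counts <- matrix(pseudocount, 4, width, dimnames = list(bases, NULL))
    lp <- log(pwm)
    for (e in enc) {
      m <- length(e) - width + 1L
      lw <- vapply(seq_len(m), function(pos) {
        idx <- e[pos:(pos + width - 1L)]
        if (anyNA(idx)) -Inf else sum(lp[cbind(idx, seq_len(width))])
      }, numeric(1))
      post <- exp(lw - max(lw)); post <- post / sum(post)
      for (pos in which(post > 1e-12)) {
        idx <- e[pos:(pos + width - 1L)]
        counts[cbind(idx, seq_len(width))] <-
          counts[cbind(idx, seq_len(width))] + post[pos]
      }
    }
    pwm <- sweep(counts, 2, colSums(counts), "/")
    trace <- c(trace, obj(pwm))
    k <- length(trace)
    if (trace[k] - trace[k - 1] < tol) { converged <- TRUE; break }
  }
  consensus <- paste(bases[apply(pwm, 2, which.max)], collapse = "")
  structure(list(pwm = pwm, consensus = consensus, loglik_trace = trace,
                 width = width, pseudocount = pseudocount,
                 n_iter = length(trace) - 1L, converged = converged),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("PWM motif model, width", x$width, "- consensus", x$consensus, "\n")
  cat("  EM iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  print(round(x$pwm, 3))
  invisible(x)
}

#' @export
plot.motif_model <- function(x, ...) {
  graphics::barplot(x$pwm, beside = TRUE, names.arg = seq_len(x$width),
                    legend.text = rownames(x$pwm),
                    xlab = "motif position", ylab = "base probability",
                    main = paste("Motif consensus:", x$consensus), ...)
  invisible(x)
}

#' Write a motif in minimal MEME text format
#'
#' Emits the version line, alphabet, strand line and the letter-probability
#' matrix so the model can be consumed by standard motif tooling.
#'
#' @param motif a \code{\link{elicit_motif}} model.
#' @param path output file.
#' @param name motif name in the file.
#' @param nsites number of contributing sites recorded in the header.
#' @return \code{path}, invisibly.
#' @export
write_meme <- function(motif, path, name = motif$consensus, nsites = 20) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       motif$width, nsites)), con)
  for (j in seq_len(motif$width))
    writeLines(paste(sprintf("%.6f", motif$pwm[, j]), collapse = " "), con)
  invisible(path)
}

#' Locate motif hits and report them as BED intervals
#'
#' Scans sequences for exact matches of a word and returns 0-based,
#' half-open intervals relative to each sequence.
#'
#' @param kmer word to locate.
#' @param sequences named character vector.
#' @return data.frame in BED column order: \code{chrom} (sequence name),
#'   \code{start}, \code{end}, \code{name} (the word).
#' @export
locate_hits <- function(kmer, sequences) {
  rows <- lapply(seq_along(sequences), function(j) {
    s <- sequences[j]; w <- nchar(kmer); L <- nchar(s)
    if (L < w) return(NULL)
    starts <- seq_len(L - w + 1L)
    hits <- starts[substring(s, starts, starts + w - 1L) == kmer]
    if (!length(hits)) return(NULL)
    data.frame(chrom = names(sequences)[j] %||% sprintf("seq%d", j),
               start = hits - 1L, end = hits - 1L + nchar(kmer),
               name = kmer, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
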