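test_that("GA-rich hexamer catalog equals brute-force enumeration", {
  cat6 <- enumerate_filtered_kmers()
  bases <- c("A", "C", "G", "T")
  words <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases,
                                       bases, stringsAsFactors = FALSE))
  nG <- vapply(strsplit(words, ""), function(x) sum(x == "G"), 1L)
  nA <- vapply(strsplit(words, ""), function(x) sum(x == "A"), 1L)
  brute <- sort(words[nG >= 1 & nA >= 1 & (nG + nA) / 6 >= 0.5])
  expect_identical(as.character(cat6), brute)
  expect_length(cat6, 2222)
})

test_that("catalog membership follows the GA-rich predicate", {
  cat6 <- enumerate_filtered_kmers()
  expect_true("GAGAGA" %in% cat6)
  expect_true("GCAGGG" %in% cat6)   # activated-set consensus word
  expect_true("GCTGGA" %in% cat6)   # repressed-set consensus word
  expect_false("GGGGGG" %in% cat6)  # no A
  expect_false("AAAAAA" %in% cat6)  # no G
  expect_false("GACTTT" %in% cat6)  # GA fraction 2/6
  expect_warning(empty <- enumerate_filtered_kmers(k = 2, min_G = 2, min_A = 2),
                 "infeasible")
  expect_length(empty, 0)
})

test_that("occurrence counting is overlapping and oracle-consistent", {
  expect_equal(as.integer(count_occurrences("GAGAGA", c(s = "GAGAGAGA"))), 2L)
  expect_equal(as.integer(count_occurrences("GAGAGA",
                                            c(s = strrep("C", 30)))), 0L)
  expect_equal(as.integer(count_occurrences("GAGAGA", c(s = "GAG"))), 0L)
  # N-containing windows never match
  expect_equal(as.integer(count_occurrences("GAGAGA", c(s = "GAGNGA"))), 0L)

  set.seed(4)
  seqs <- vapply(1:15, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""), "")
  kmers <- enumerate_filtered_kmers()[sample(2222, 40)]
  counted <- count_occurrences(kmers, seqs)
  for (k in kmers) {
    oracle <- vapply(seqs, scan_count_oracle, 0L, kmer = k)
    expect_equal(as.integer(counted[k, ]), unname(oracle))
  }
})

test_that("event-set selection ranks by q, then |dPSI|, then id, SE only", {
  res <- data.frame(
    event_id = c("e1", "e2", "e3", "e4", "e5", "e6"),
    category = c("SE", "SE", "SE", "MXE", "SE", "SE"),
    direction = c("activated", "activated", "activated", "activated",
                  "activated", "repressed"),
    q_value = c(0.01, 0.01, 0.001, 1e-5, 0.01, 0.02),
    delta_psi = c(-0.5, -0.3, -0.2, -0.9, -0.5, 0.4))
  class(res) <- c("splice_screen", "data.frame")
  expect_warning(sets <- select_event_sets(res, n_per_set = 3), "repressed")
  # e4 excluded (MXE); e3 leads on q; e1/e5 tie on q and |dPSI|, id breaks it
  expect_equal(sets$activated, c("e3", "e1", "e5"))
  expect_equal(sets$repressed, "e6")
})

test_that("enrichment statistics behave and recover a planted word", {
  kmers <- enumerate_filtered_kmers()
  set.seed(10)
  bg <- vapply(1:30, function(i)
    paste(sample(c("C", "T"), 80, TRUE, prob = c(0.5, 0.5)), collapse = ""), "")
  # foreground = background (same generator): z-scores hover near zero
  fg0 <- vapply(1:30, function(i)
    paste(sample(c("C", "T"), 80, TRUE), collapse = ""), "")
  e0 <- kmer_enrichment(fg0, bg, kmers)
  expect_lt(max(abs(e0$z_score)), 4)

  # plant GCAGGG in every foreground sequence
  fg <- vapply(fg0, function(s) paste0(substr(s, 1, 30), "GCAGGG",
                                       substr(s, 37, 80)), "")
  e1 <- kmer_enrichment(fg, bg, kmers)
  expect_equal(e1$kmer[1], "GCAGGG")
  expect_gt(e1$z_score[1], 5)
  # z sign flips under foreground/background swap
  e2 <- kmer_enrichment(bg, fg, kmers)
  expect_lt(e2$z_score[e2$kmer == "GCAGGG"], 0)
  expect_error(kmer_enrichment(character(0), bg, kmers), "non-empty")
})

test_that("positional preference recovers the planting region", {
  cfg <- tiny_config(60, frac_activated = 0.3, frac_repressed = 0.3, seed = 14)
  ds <- simulate_splicing_dataset(cfg)
  act <- ds$truth$event_id[ds$truth$label == "activated"]
  rep_ <- ds$truth$event_id[ds$truth$label == "repressed"]
  prof <- positional_preference(ds$sequences, act, rep_,
                                c(cfg$planted_motif,
                                  cfg$planted_motif_repressed))
  pref <- attr(prof, "preference")
  expect_equal(unname(pref["activated"]), "cassette")
  expect_equal(unname(pref["repressed"]), "flank")
  expect_gt(attr(prof, "density_ratio")["activated"], 1)
  expect_lt(attr(prof, "density_ratio")["repressed"], 1)

  # no hits anywhere: densities zero, preference undefined
  noseq <- data.frame(event_id = "x", region = c("upstream_flank", "cassette",
                                                 "downstream_flank"),
                      seq = strrep("C", 50))
  p0 <- positional_preference(noseq, "x", "x", "GAGAGA")
  expect_true(all(p0$density == 0))
  expect_true(all(is.na(attr(p0, "preference"))))
})

test_that("EM elicitor recovers a planted consensus with monotone objective", {
  set.seed(6)
  seqs <- vapply(1:20, function(i) {
    bg <- sample(c("C", "T"), 50, TRUE)
    pos <- sample(1:(50 - 5), 1)
    bg[pos:(pos + 5)] <- strsplit("GCAGGG", "")[[1]]
    paste(bg, collapse = "")
  }, "")
  m <- elicit_motif(seqs, init_kmer = "GCAGGG")
  expect_equal(m$consensus, "GCAGGG")
  expect_true(all(diff(m$loglik_trace) >= -1e-8))
  expect_true(all(abs(colSums(m$pwm) - 1) < 1e-9))
  expect_lte(m$n_iter, 200)

  # recovery also works from a cold (uninformative) start
  m2 <- elicit_motif(seqs, init_kmer = "ACGTAC")
  expect_true(all(diff(m2$loglik_trace) >= -1e-8))

  # identical sequences: consensus must be a substring of the repeated word
  w <- "GATTACAGATTACA"
  m3 <- elicit_motif(rep(w, 5), init_kmer = "GATTAC")
  subs <- substring(w, 1:(nchar(w) - 5), 6:nchar(w))
  expect_true(m3$consensus %in% subs)

  expect_error(elicit_motif("ACGTACGT"), "at least 2")
  expect_error(elicit_motif(c("ACGTACGT", "ACG")), "shorter")
})

test_that("MEME writer emits a parseable letter-probability matrix", {
  m <- elicit_motif(c(strrep("GCAGGGCT", 4), strrep("CTGCAGGG", 4)),
                    init_kmer = "GCAGGG")
  path <- tempfile(fileext = ".meme")
  write_meme(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^letter-probability matrix", lines)))
  mat_start <- grep("^letter-probability", lines) + 1
  mat <- read.table(text = lines[mat_start:(mat_start + 5)])
  expect_equal(unname(rowSums(mat)), rep(1, 6), tolerance = 1e-4)
})

test_that("hit locations are 0-based half-open and overlap-aware", {
  hits <- locate_hits("GAGAGA", c(a = "GAGAGAGA", b = strrep("C", 10)))
  expect_equal(hits$chrom, c("a", "a"))
  expect_equal(hits$start, c(0L, 2L))
  expect_equal(hits$end, c(6L, 8L))
})
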