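# shared fixture germline database (deterministic) and small helpers

fixture_db <- simulate_germline_db(n_v = 12, n_d = 12, n_j = 5, seed = 42)
fixture_db_inv <- add_inverted_d(fixture_db)

# independent run-based scorer used as the oracle for the alignment score:
# given the forgiven subset explicitly, fuse flanking runs through forgiven
# positions (string/run based, no shared code with the C++ path)
oracle_run_score <- function(pattern_int, forgiven = integer(0)) {
  sym <- ifelse(pattern_int == 1L, "M", "x")
  sym[forgiven] <- "F"
  rl <- rle(sym == "x")
  score <- 0
  idx <- 1L
  for (k in seq_along(rl$lengths)) {
    len <- rl$lengths[k]
    block <- sym[idx:(idx + len - 1L)]
    if (rl$values[k]) {
      score <- score - len^2
    } else {
      score <- score + sum(block == "M")^2
    }
    idx <- idx + len
  }
  score
}

# forgivable isolated mismatches of a pattern (mismatch runs of length 1,
# excluding unforgivable codes)
isolated_mismatches <- function(pattern_int) {
  n <- length(pattern_int)
  which(vapply(seq_len(n), function(i) {
    pattern_int[i] == 0L &&
      (i == 1L || pattern_int[i - 1L] == 1L) &&
      (i == n || pattern_int[i + 1L] == 1L)
  }, logical(1)))
}

# documented greedy semantics, via the oracle: forgive the 5'-most
# min(budget, #isolated) isolated mismatches
oracle_greedy_score <- function(pattern_int, budget) {
  iso <- isolated_mismatches(pattern_int)
  oracle_run_score(pattern_int, utils::head(iso, budget))
}

# naive exhaustive best ungapped placement (R reference implementation)
oracle_best_alignment <- function(read, gene, budget, window, min_overlap) {
  best <- NULL
  lg <- nchar(gene)
  for (o in (window[1] - lg + min_overlap):(window[2] - min_overlap + 1L)) {
    rs <- max(o, window[1]); re <- min(o + lg - 1L, window[2])
    ov <- re - rs + 1L
    if (ov < min_overlap) next
    r <- strsplit(substr(read, rs, re), "")[[1]]
    g <- strsplit(substr(gene, rs - o + 1L, re - o + 1L), "")[[1]]
    p <- as.integer(r == g)
    sc <- oracle_greedy_score(p, budget)
    cand <- list(score = sc, overlap = ov, offset = o)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && ov > best$overlap) ||
        (sc == best$score && ov == best$overlap && o < best$offset)) {
      best <- cand
    }
  }
  best
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# small simulated repertoire + its annotations, shared across test files
sim_small <- local({
  set.seed(202)
  simulate_repertoire(fixture_db, sim_config(n_germline = 6, n_rounds = 2))
})
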