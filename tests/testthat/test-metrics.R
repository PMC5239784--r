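test_that("exact and degenerate gene matching behave as specified", {
  db <- germline_db(dplyr::bind_rows(
    new_gene_rows(c("IGHD1-1*01", "IGHD1-1*02"), "D",
                  c("ATTAACTA", "ATTAACTA")),
    new_gene_rows(c("IGHD2-1*01", "IGHD2-1*02"), "D",
                  c("GGGGCCCC", "GGGGCCCA"))
  ))
  # same name: both modes true
  expect_true(gene_match("IGHD1-1*01", "IGHD1-1*01", db, "exact"))
  # identical sequences under different allele names: degenerate only
  expect_false(gene_match("IGHD1-1*02", "IGHD1-1*01", db, "exact"))
  expect_true(gene_match("IGHD1-1*02", "IGHD1-1*01", db, "degenerate"))
  # 8-nt alleles differing at one nt: 87.5% < 98%
  expect_false(gene_match("IGHD2-1*01", "IGHD2-1*02", db, "degenerate"))
  expect_error(gene_match("IGHD9-9*01", "IGHD1-1*01", db, "degenerate"),
               "unknown")
})

test_that("degenerate matching is symmetric and handles length differences", {
  db <- germline_db(new_gene_rows(
    c("IGHD3-1*01", "IGHD3-2*01"), "D",
    c("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC", # 50 nt
      "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT")))  # its 48-nt prefix
  expect_true(gene_match("IGHD3-1*01", "IGHD3-2*01", db, "degenerate"))
  expect_true(gene_match("IGHD3-2*01", "IGHD3-1*01", db, "degenerate"))
})

test_that("confusion counts split positions into TP/TN/FP/FN", {
  c1 <- shm_confusion(predicted_positions = c(3, 5, 9, 11, 15),
                      truth_positions = c(3, 5, 9, 11, 15),
                      region = c(1, 20))
  expect_equal(unlist(c1), c(tp = 5L, tn = 15L, fp = 0L, fn = 0L))
  # germline read: nothing mutated, nothing called
  c2 <- shm_confusion(integer(0), integer(0), c(1, 30))
  expect_equal(unlist(c2), c(tp = 0L, tn = 30L, fp = 0L, fn = 0L))
  # counts always sum to the region width
  c3 <- shm_confusion(c(2, 4), c(4, 6), c(1, 10))
  expect_equal(sum(unlist(c3)), 10L)
  expect_equal(c3$tp, 1L); expect_equal(c3$fp, 1L); expect_equal(c3$fn, 1L)
})

test_that("accuracy and PPR reproduce printed spot checks", {
  # heavily mutated row: 1230/50072/629/644 -> 0.98 / 0.66
  r <- accuracy_ppr(tibble::tibble(tp = 1230, tn = 50072, fp = 629,
                                   fn = 644))
  expect_equal(round(r$acc, 2), 0.98)
  expect_equal(round(r$ppr, 2), 0.66)
  # germline rows: no true or called positives -> PPR defined as 0
  r0 <- accuracy_ppr(tibble::tibble(tp = 0, tn = 100, fp = 0, fn = 0))
  expect_equal(r0$ppr, 0)
  expect_equal(accuracy_ppr(tibble::tibble(tp = 5, tn = 15, fp = 0,
                                           fn = 0))$acc, 1)
})

prop_pairs <- function(parent, child, len = NULL) {
  len <- len %||% nchar(parent)
  tibble::tibble(parent_seq = parent, child_seq = child,
                 v_end = 4L, d_start = 6L, d_end = 8L,
                 j_start = 10L)
}

test_that("propensity matrices count parent-to-child substitutions", {
  # single A->G inside the V segment
  p <- propensity_matrix(prop_pairs("AAAACCGGTTTT", "AGAACCGGTTTT"),
                         scope = "V")
  expect_equal(sum(p$count), 1L)
  expect_equal(p$freq[p$from == "A" & p$to == "G"], 1)
  # rows with counts normalize to 1
  sums <- tapply(p$freq, p$from, sum)
  expect_true(all(is.na(sums) | abs(sums - 1) < 1e-12))
  # N-region positions (5 and 9 here) are excluded
  p2 <- propensity_matrix(prop_pairs("AAAACCGGTTTT", "AAAAGCGGTTTT"),
                          scope = "all")
  expect_equal(sum(p2$count), 0L)
  expect_true(attr(p2, "empty"))
})

test_that("chain edges are counted once per inheritance", {
  # g -> c1 mutates position 2; c1 -> c2 inherits it and adds position 11
  g  <- "AAAACCGGTTTT"
  c1 <- "ACAACCGGTTTT"
  c2 <- "ACAACCGGTTGT"
  pairs <- dplyr::bind_rows(prop_pairs(g, c1), prop_pairs(c1, c2))
  p <- propensity_matrix(pairs, scope = "all")
  expect_equal(sum(p$count), 2L) # not 3: the inherited A>C is not re-counted
})

test_that("V-vs-DJ propensity correlation has closed-form behaviour", {
  nts <- c("A", "C", "G", "T")
  grid <- tidyr::expand_grid(from = nts, to = nts) |>
    dplyr::filter(from != to)
  set.seed(701)
  v <- grid |> dplyr::mutate(freq = {
    x <- stats::runif(12); unlist(tapply(x, from, function(g) g / sum(g)))
  })
  identical <- v_dj_correlation(v, v)
  expect_equal(identical$r_corr, 1)
  expect_equal(identical$slope, 1)
  # dj = 0.5 * v + shift -> slope 0.5, r 1
  dj <- v |> dplyr::mutate(freq = 0.5 * freq + 1 / 6)
  scaled <- v_dj_correlation(v, dj)
  expect_equal(scaled$slope, 0.5, tolerance = 1e-12)
  expect_equal(scaled$r_corr, 1, tolerance = 1e-12)
  # anti-correlated toy
  anti <- v |> dplyr::mutate(freq = max(freq) - freq)
  expect_lt(v_dj_correlation(v, anti)$r_corr, 0)
  # zero variance errors
  flat <- v |> dplyr::mutate(freq = 1 / 3)
  expect_error(v_dj_correlation(v, flat), "variance")
})

test_that("propensities on simulator output recover the substitution matrix", {
  set.seed(702)
  truth <- simulate_repertoire(fixture_db,
                               sim_config(n_germline = 40, n_rounds = 2))
  kids <- truth[truth$generation > 0, ]
  pairs <- tibble::tibble(
    parent_seq = truth$sequence[match(kids$parent_id, truth$id)],
    child_seq = kids$sequence,
    v_end = kids$v_end, d_start = kids$d_start, d_end = kids$d_end,
    j_start = kids$j_start)
  p <- propensity_matrix(pairs, scope = "all")
  cfg <- default_substitution()
  for (i in seq_len(nrow(p))) {
    expected <- cfg[p$from[i], p$to[i]]
    n_row <- sum(p$count[p$from == p$from[i]])
    # binomial 3-sigma envelope around the configured probability
    expect_lt(abs(p$freq[i] - expected),
              3 * sqrt(expected * (1 - expected) / n_row) + 0.02)
  }
})

test_that("hot-spot profiles expose planted motifs against the background", {
  # mutations planted only at the C of "AGC": offset -1 should be G-rich
  set.seed(703)
  parents <- character(30); children <- character(30)
  for (i in 1:30) {
    s <- random_nt(60)
    pos <- 20 + (i %% 10)
    substr(s, pos - 2, pos) <- "AGC"
    child <- s
    substr(child, pos, pos) <- "T"
    parents[i] <- s; children[i] <- child
  }
  pairs <- tibble::tibble(parent_seq = parents, child_seq = children,
                          v_end = 60L, d_start = NA_integer_,
                          d_end = NA_integer_, j_start = NA_integer_)
  prof <- hotspot_profile(pairs, k = 2, scope = "V")
  mut <- prof[prof$center == "mutated", ]
  expect_equal(mut$nt[mut$offset == 0][which.max(mut$freq[mut$offset == 0])],
               "C")
  g_at_m1 <- mut$freq[mut$offset == -1 & mut$nt == "G"]
  expect_gt(g_at_m1, 0.9)
  bg <- prof[prof$center == "all" & prof$offset == -1 & prof$nt == "G", ]
  expect_lt(bg$freq, 0.5) # background not G-enriched
  # k = 0 gives the composition of mutated nts themselves
  prof0 <- hotspot_profile(pairs, k = 0, scope = "V")
  m0 <- prof0[prof0$center == "mutated", ]
  expect_equal(m0$freq[m0$nt == "C"], 1)
})

test_that("background composition of uniform sequence is about uniform", {
  set.seed(704)
  pairs <- tibble::tibble(parent_seq = random_nt(4000),
                          child_seq = random_nt(4000),
                          v_end = 4000L, d_start = NA_integer_,
                          d_end = NA_integer_, j_start = NA_integer_)
  prof <- hotspot_profile(pairs, k = 1, scope = "V")
  bg <- prof[prof$center == "all", ]
  expect_true(all(abs(bg$freq - 0.25) < 0.03))
})

test_that("usage tables count families, pairs, and inverted D separately", {
  ann <- tibble::tibble(
    v_name = rep("IGHV1-2*01", 10),
    d_name = c(rep("IGHD2-1*01", 9), "rIGHD2-1*01"),
    j_name = rep("IGHJ4*01", 10))
  u <- usage_frequencies(ann)
  fam <- u$family
  expect_equal(fam$freq[fam$segment == "V"], 1)
  expect_setequal(fam$family[fam$segment == "D"], c("IGHD2", "rIGHD2"))
  expect_equal(sum(fam$freq[fam$segment == "D"]), 1)
  expect_equal(nrow(u$vd_pairs), 2L) # (V1, D2) and (V1, rD2)
  expect_equal(sum(u$vd_pairs$freq), 1)
  expect_equal(sum(u$dj_pairs$freq), 1)
})

test_that("Vframe and CDR3 mutation loads are reported per sequence", {
  set.seed(705)
  truth <- simulate_repertoire(fixture_db,
                               sim_config(n_germline = 4, n_rounds = 1))
  reads <- tibble::tibble(id = truth$id, sequence = truth$sequence)
  cl <- build_lineages(annotate_reads(reads, fixture_db_inv),
                       fixture_db_inv)
  res <- vframe_vs_cdr3(cl)
  expect_equal(nrow(res$per_sequence), nrow(truth))
  expect_true(all(res$per_sequence$vframe_mutations >= 0, na.rm = TRUE))
  # all-germline repertoire: zero loads everywhere, correlation undefined
  g0 <- truth[truth$generation == 0, ]
  cl0 <- build_lineages(
    annotate_reads(tibble::tibble(id = g0$id, sequence = g0$sequence),
                   fixture_db_inv), fixture_db_inv)
  res0 <- vframe_vs_cdr3(cl0)
  expect_true(is.na(res0$correlation))
})
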