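# build a read with known structure from fixture genes
make_read <- function(v_idx = 1, d_idx = 1, j_idx = 1, n_vd = "", n_dj = "",
                      v_del = 0, d_del5 = 0, d_del3 = 0, j_del5 = 0,
                      read_length = 125L, db = fixture_db, full_j = FALSE) {
  v <- db[db$segment_class == "V", ][v_idx, ]
  d <- db[db$segment_class == "D", ][d_idx, ]
  j <- db[db$segment_class == "J", ][j_idx, ]
  v_seq <- substr(v$sequence, 1, nchar(v$sequence) - v_del)
  d_seq <- substr(d$sequence, 1 + d_del5, nchar(d$sequence) - d_del3)
  j_end <- if (full_j) nchar(j$sequence) else j$anchor_pos + 2
  j_seq <- substr(j$sequence, 1 + j_del5, j_end)
  full <- paste0(v_seq, n_vd, d_seq, n_dj, j_seq)
  trim <- max(0L, nchar(full) - read_length)
  list(read = substr(full, trim + 1, nchar(full)),
       v = v, d = d, j = j, trim = trim,
       v_end = nchar(v_seq) - trim,
       d_start = nchar(v_seq) + nchar(n_vd) + 1 - trim,
       d_end = nchar(v_seq) + nchar(n_vd) + nchar(d_seq) - trim,
       j_start = nchar(full) - nchar(j_seq) + 1 - trim)
}

test_that("V matching reserves the last 9 nt of the read", {
  rd <- make_read(n_vd = "GG", n_dj = "GGA")
  v <- annotate_v(rd$read, fixture_db)
  expect_equal(v$gene, rd$v$name)
  expect_lte(v$read_end, nchar(rd$read) - 9L) # 125-nt read: first 116 only
  expect_equal(v$n_mismatch, 0L)
})

test_that("a read equal to a V prefix plus 9 nt recovers that V exactly", {
  v <- fixture_db[fixture_db$segment_class == "V", ][3, ]
  read <- paste0(substr(v$sequence, 1, 80), "ACGTACGTA")
  a <- annotate_v(read, fixture_db)
  expect_equal(a$gene, v$name)
  expect_equal(a$n_mismatch, 0L)
  expect_equal(a$read_end, 80L)
})

test_that("too-short reads take the failure path, not an error", {
  out <- annotate_sequence("short", "ACGTACGTACGT", fixture_db)
  expect_equal(out$status, "too_short")
  out2 <- annotate_sequence("empty", "", fixture_db)
  expect_equal(out2$status, "empty")
  out3 <- annotate_sequence("bad", strrep("ACGX", 30), fixture_db)
  expect_equal(out3$status, "ambiguous_chars")
})

test_that("J matching starts after the 3-nt reservation", {
  rd <- make_read(n_vd = "GGT", n_dj = "AG")
  j <- annotate_j(rd$read, fixture_db, v_end = rd$v_end)
  expect_equal(j$gene, rd$j$name)
  expect_gte(j$read_start, rd$v_end + 4L)
  # v_end = 121 on a 125-nt read leaves no J window
  jf <- annotate_j(rd$read, fixture_db, v_end = 121L)
  expect_identical(jf$score, -Inf)
})

test_that("D matching searches the inter-segment window, inverted included", {
  d <- fixture_db[fixture_db$segment_class == "D", ][5, ]
  len <- nchar(d$sequence)
  rd <- make_read(d_idx = 5, n_vd = "GG", n_dj = "AGG")
  a <- annotate_d(rd$read, fixture_db_inv, rd$v_end, rd$j_start)
  expect_equal(a$gene, d$name)
  expect_equal(a$score, len^2) # exact full-length match
  expect_equal(substr(rd$read, a$read_start, a$read_end), d$sequence)
})

test_that("inverted D genes are found and can be disallowed", {
  d <- fixture_db[fixture_db$segment_class == "D", ][2, ]
  rc <- vdjlineage:::revcomp(d$sequence)
  # plant the reverse complement of a D gene in the junction
  rd <- make_read(d_idx = 2, n_vd = "", n_dj = "")
  read <- paste0(substr(rd$read, 1, rd$d_start - 1), rc,
                 substr(rd$read, rd$d_end + 1, nchar(rd$read)))
  window_end <- rd$d_end + 1 + (nchar(read) - nchar(rd$read))
  a <- annotate_d(read, fixture_db_inv, rd$d_start - 1, window_end)
  expect_equal(a$gene, paste0("r", d$name))
  b <- annotate_d(read, fixture_db_inv, rd$d_start - 1, window_end,
                  allow_inverted = FALSE)
  expect_false(grepl("^r", b$gene))
})

test_that("N-region assignment is verbatim and respects absent D", {
  read <- "AAACCCGGGTTT"
  nr <- assign_n_regions(read, v_end = 3, d_start = 7, d_end = 9,
                         j_start = 12)
  expect_equal(nr$n_vd, "CCC")
  expect_equal(nr$n_dj, "TT")
  nr2 <- assign_n_regions(read, v_end = 3, d_start = 4, d_end = 9,
                          j_start = 10)
  expect_equal(nr2$n_vd, "")
  expect_equal(nr2$n_dj, "")
  nr3 <- assign_n_regions(read, v_end = 3, d_start = NA, d_end = NA,
                          j_start = 10)
  expect_equal(nr3$n_vd, "CCCGGG")
})

test_that("CDR3 spans the Cys codon through the Trp codon at the read end", {
  # pick an in-frame, stop-free junction among the fixture D genes
  found <- NULL
  for (d_idx in 1:12) {
    for (b in 0:2) { # pad N_DJ until the anchors share a frame
      rd <- make_read(d_idx = d_idx, n_vd = "G", n_dj = strrep("A", b))
      ann <- annotate_sequence("r1", rd$read, fixture_db)
      if (isTRUE(ann$productive)) { found <- list(rd = rd, ann = ann); break }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  rd <- found$rd; ann <- found$ann
  expect_equal(ann$status, "ok")
  # data convention: the last 3 nt code the conserved 118Trp
  expect_equal(ann$cdr3_end, nchar(rd$read))
  expect_equal(substr(rd$read, ann$cdr3_end - 2, ann$cdr3_end), "TGG")
  expect_equal(substr(rd$read, ann$cdr3_start, ann$cdr3_start + 2),
               substr(rd$v$sequence, rd$v$anchor_pos, rd$v$anchor_pos + 2))
})

test_that("stop codons and frameshifts make the junction non-productive", {
  #            1234 567 890 123 456 7890
  clean   <- "AAAATGTGCAGCATGGAAAA" # Cys at 5, Trp at 14, span 9 (in frame)
  ok <- locate_cdr3(clean, v_offset = 1, v_anchor = 5,
                    j_offset = 14, j_anchor = 1)
  expect_true(ok$productive)
  expect_equal(ok$cdr3_start, 5L)
  expect_equal(ok$cdr3_end, 16L)
  expect_equal(ok$cdr3_nt, "TGTGCAGCATGG")
  # in-frame TAA inside the junction
  stopry <- "AAAATGTTAAGCATGGAAAA"
  bad <- locate_cdr3(stopry, v_offset = 1, v_anchor = 5,
                     j_offset = 14, j_anchor = 1)
  expect_false(bad$productive)
  # anchors out of frame by one
  off <- locate_cdr3(clean, v_offset = 1, v_anchor = 5,
                     j_offset = 13, j_anchor = 1)
  expect_false(off$productive)
  # anchor mapping outside the read: no CDR3, not productive
  out <- locate_cdr3(clean, v_offset = 1, v_anchor = 5,
                     j_offset = 19, j_anchor = 1)
  expect_false(out$ok)
  expect_true(is.na(out$cdr3_start))
})

test_that("segments tile every annotated read end to end", {
  reads <- tibble::tibble(id = sim_small$id, sequence = sim_small$sequence)
  ann <- annotate_reads(reads, fixture_db_inv)
  ok <- ann[ann$status %in% c("ok", "no_cdr3"), ]
  expect_gt(nrow(ok), 0)
  with_d <- !is.na(ok$d_start)
  expect_true(all(ok$v_end >= 1))
  expect_true(all(ok$d_start[with_d] > ok$v_end[with_d]))
  expect_true(all(ok$d_end[with_d] >= ok$d_start[with_d]))
  expect_true(all(ok$j_start[with_d] > ok$d_end[with_d]))
  expect_true(all(ok$j_start <= ok$read_length))
  expect_equal(nchar(ok$n_vd[with_d]),
               ok$d_start[with_d] - ok$v_end[with_d] - 1L)
  expect_equal(nchar(ok$n_dj[with_d]),
               ok$j_start[with_d] - ok$d_end[with_d] - 1L)
  # preservation at the matching stage: J never intrudes on the 3 reserved nt
  expect_true(all(ok$j_start >= ok$v_end + 4L))
})

test_that("unmutated fixture reads recover their generating genes", {
  g0 <- sim_small[sim_small$generation == 0, ]
  reads <- tibble::tibble(id = g0$id, sequence = g0$sequence)
  ann <- annotate_reads(reads, fixture_db_inv)
  m <- match(g0$id, ann$read_id)
  expect_true(all(gene_match(ann$v_name[m], g0$v_name, fixture_db_inv,
                             "degenerate")))
  expect_true(all(gene_match(ann$j_name[m], g0$j_name, fixture_db_inv,
                             "degenerate")))
  expect_gte(mean(gene_match(ann$d_name[m], g0$d_name, fixture_db_inv,
                             "degenerate")), 0.5)
})

test_that("mutations are recorded at their planted positions", {
  g0 <- sim_small[sim_small$generation == 0, ][1, ]
  read <- g0$sequence
  base <- annotate_sequence("m0", read, fixture_db_inv)
  # plant 3 substitutions inside the V frame, away from segment edges
  pos <- c(10L, 25L, 40L)
  for (p in pos) {
    old <- substr(read, p, p)
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  ann <- annotate_sequence("m1", read, fixture_db_inv)
  expect_equal(ann$v_name, base$v_name)
  expect_true(all(pos %in% ann$v_mismatches[[1]]))
  expect_gte(ann$shm_vframe, 3L)
})

test_that("constant-region overhang is trimmed back to the J end", {
  rd <- make_read(full_j = TRUE, read_length = 150L)
  withC <- paste0(rd$read, "CATCATCATCATCATCATCA") # 20 nt constant
  trimmed <- trim_constant_region(withC, fixture_db)
  expect_equal(trimmed, rd$read)
  expect_equal(trim_constant_region(rd$read, fixture_db), rd$read)
})
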