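#' Annotation configuration
#'
#' Tunable parameters of the segmentation pipeline. Defaults reflect the
#' study conditions: 15% V-segment mismatch leniency, the observed V
#' mutation fraction propagated to D/J leniency, a 9-nt 3' reservation
#' before V matching and a 3-nt reservation after the V segment before J
#' matching, minimum overlaps of 10 nt (V/J) and 3 nt (D), inverted D genes
#' allowed, and V-indel correction accepting up to 2 single-nt edits each
#' gaining more than 4 score units.
#'
#' @param v_leniency_fraction Forgivable mismatch fraction for V matching.
#' @param min_overlap_v,min_overlap_j,min_overlap_d Minimum aligned overlaps.
#' @param allow_inverted_d Search reverse-complement D genes.
#' @param indel_margin,max_indel_edits V indel-correction controls.
#' @param preserve_v3,preserve_after_v Reserved nt counts (9-nt read tail
#'   before V matching; 3 nt after V before J matching).
#' @param trim_constant Trim 3' constant-region overhang past the best J
#'   before annotating (for reads not pre-trimmed to the 118Trp).
#' @returns A list of class `annotate_config`.
#' @export
annotate_config <- function(v_leniency_fraction = 0.15,
                            min_overlap_v = 10L, min_overlap_j = 10L,
                            min_overlap_d = 3L, allow_inverted_d = TRUE,
                            indel_margin = 4, max_indel_edits = 2L,
                            preserve_v3 = 9L, preserve_after_v = 3L,
                            trim_constant = FALSE) {
  structure(list(v_leniency_fraction = v_leniency_fraction,
                 min_overlap_v = as.integer(min_overlap_v),
                 min_overlap_j = as.integer(min_overlap_j),
                 min_overlap_d = as.integer(min_overlap_d),
                 allow_inverted_d = allow_inverted_d,
                 indel_margin = indel_margin,
                 max_indel_edits = as.integer(max_indel_edits),
                 preserve_v3 = as.integer(preserve_v3),
                 preserve_after_v = as.integer(preserve_after_v),
                 trim_constant = trim_constant),
            class = "annotate_config")
}

db_class <- function(db, cls) db[db$segment_class == cls, , drop = FALSE]

# outermost matching read position of an aligned overlap (side "3p" = last
# match, "5p" = first match); falls back to the overlap end when nothing
# matches (degenerate, keeps downstream windows well-defined)
match_trimmed_end <- function(read, gene_seq, offset, rs, re, side) {
  mm <- alignment_mismatch_positions(read, gene_seq, offset, rs, re)
  matches <- setdiff(rs:re, mm)
  if (length(matches) == 0L) {
    return(if (side == "3p") as.integer(re) else as.integer(rs))
  }
  if (side == "3p") as.integer(max(matches)) else as.integer(min(matches))
}

#' Match the V gene over the read with a 3' reservation
#'
#' The last `preserve_v3` nt of the read (default 9) are withheld from V
#' matching so that the D and J genes can still be resolved: for a 125-nt
#' read only the first 116 nt are used to determine the V gene.
#'
#' @param read Read sequence.
#' @param db Germline database.
#' @param config An [annotate_config()].
#' @returns One-row alignment tibble (score `-Inf` on failure).
#' @export
annotate_v <- function(read, db, config = annotate_config()) {
  len <- nchar(read)
  window <- c(1L, len - config$preserve_v3)
  align_to_db(read, db_class(db, "V"),
              leniency_policy(fraction = config$v_leniency_fraction),
              window, config$min_overlap_v)
}

#' Match the J gene 3' of the V segment with a 3-nt reservation
#'
#' The `preserve_after_v` nt (default 3) immediately right of the V segment
#' are withheld, so with V ending at read position 100 of 125, positions
#' 101-103 are preserved and the last 22 nt are used to match J.
#'
#' @param read Read sequence.
#' @param db Germline database.
#' @param v_end Read position of the V segment 3' end.
#' @param v_mut_fraction Observed V mutation fraction; sets the J leniency
#'   budget (`ceiling(fraction * overlap)`).
#' @param config An [annotate_config()].
#' @returns One-row alignment tibble.
#' @export
annotate_j <- function(read, db, v_end, v_mut_fraction = 0,
                       config = annotate_config()) {
  len <- nchar(read)
  window <- c(v_end + config$preserve_after_v + 1L, len)
  align_to_db(read, db_class(db, "J"),
              leniency_policy(fraction = v_mut_fraction),
              window, config$min_overlap_j)
}

#' Match the D gene between the V and J segments
#'
#' All nts strictly between the V 3' end and the J 5' start are searched,
#' including inverted (reverse-complement, `"r"`-prefixed) D genes when
#' allowed.
#'
#' @inheritParams annotate_j
#' @param j_start Read position of the J segment 5' start.
#' @param allow_inverted Include inverted D genes (default from `config`).
#' @returns One-row alignment tibble.
#' @export
annotate_d <- function(read, db, v_end, j_start, v_mut_fraction = 0,
                       config = annotate_config(),
                       allow_inverted = config$allow_inverted_d) {
  genes <- db_class(db, "D")
  if (!allow_inverted) genes <- genes[!genes$is_inverted, , drop = FALSE]
  window <- c(v_end + 1L, j_start - 1L)
  if (window[2] < window[1]) return(no_alignment_result())
  align_to_db(read, genes, leniency_policy(fraction = v_mut_fraction),
              window, config$min_overlap_d)
}

#' Assign N regions between segment boundaries
#'
#' @param read Read sequence.
#' @param v_end,d_start,d_end,j_start Boundary positions; `d_start`/`d_end`
#'   may be `NA` (no D), in which case the whole gap is N_VD.
#' @returns List with `n_vd` and `n_dj` nt strings (possibly empty).
#' @export
assign_n_regions <- function(read, v_end, d_start, d_end, j_start) {
  sub_or_empty <- function(a, b) {
    if (is.na(a) || is.na(b) || b < a) "" else substr(read, a, b)
  }
  if (is.na(d_start)) {
    list(n_vd = sub_or_empty(v_end + 1L, j_start - 1L), n_dj = "")
  } else {
    list(n_vd = sub_or_empty(v_end + 1L, d_start - 1L),
         n_dj = sub_or_empty(d_end + 1L, j_start - 1L))
  }
}

#' Locate the CDR3 and call junction productivity
#'
#' Maps the V gene's 104Cys anchor and the J gene's 118Trp anchor through
#' the alignment offsets into read coordinates. The CDR3 spans the Cys
#' codon start through the Trp codon end. The junction is productive when
#' both anchors map inside the read, they share a reading frame (span
#' divisible by 3), and no stop codon occurs in that frame across the
#' junction.
#'
#' @param read Read sequence.
#' @param v_offset,j_offset Read coordinate of gene position 1 for V and J.
#' @param v_anchor,j_anchor Germline anchor positions (may be `NA`).
#' @returns List: `cdr3_start`, `cdr3_end`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, `ok` (whether a CDR3 could be placed).
#' @export
locate_cdr3 <- function(read, v_offset, v_anchor, j_offset, j_anchor) {
  fail <- list(cdr3_start = NA_integer_, cdr3_end = NA_integer_,
               cdr3_nt = NA_character_, cdr3_aa = NA_character_,
               productive = FALSE, ok = FALSE)
  if (is.na(v_anchor) || is.na(j_anchor) ||
      is.na(v_offset) || is.na(j_offset)) {
    return(fail)
  }
  len <- nchar(read)
  cys <- v_offset + v_anchor - 1L
  trp <- j_offset + j_anchor - 1L
  if (cys < 1L || trp + 2L > len || trp <= cys) return(fail)
  cdr3_start <- cys
  cdr3_end <- trp + 2L
  cdr3_nt <- substr(read, cdr3_start, cdr3_end)
  in_frame <- (trp - cys) %% 3L == 0L
  has_stop <- FALSE
  if (in_frame) {
    starts <- seq.int(cys, trp, by = 3L)
    has_stop <- any(substring(read, starts, starts + 2L) %in% STOP_CODONS)
  }
  list(cdr3_start = cdr3_start, cdr3_end = cdr3_end, cdr3_nt = cdr3_nt,
       cdr3_aa = if (in_frame) translate_nt(cdr3_nt) else NA_character_,
       productive = in_frame && !has_stop, ok = TRUE)
}

#' Trim a 3' constant-region overhang
#'
#' If the read extends 3' past the end of the best full-length J alignment,
#' the overhang is removed before annotation.
#'
#' @param read Read sequence.
#' @param db Germline database.
#' @param config An [annotate_config()].
#' @returns The (possibly trimmed) read.
#' @export
trim_constant_region <- function(read, db, config = annotate_config()) {
  j <- align_to_db(read, db_class(db, "J"),
                   leniency_policy(fraction = config$v_leniency_fraction),
                   c(1L, nchar(read)), config$min_overlap_j)
  if (j$score == -Inf) return(read)
  gene_len <- nchar(db$sequence[match(j$gene, db$name)])
  if (!is.na(j$gene_end) && j$gene_end == gene_len &&
      j$read_end < nchar(read)) {
    read <- substr(read, 1L, j$read_end)
  }
  read
}

empty_annotation <- function(read_id, sequence, status) {
  tibble(
    read_id = read_id, sequence = sequence,
    read_length = nchar(sequence), status = status, productive = FALSE,
    v_name = NA_character_, v_tied = list(character(0)), v_score = NA_real_,
    v_offset = NA_integer_, v_read_start = NA_integer_, v_end = NA_integer_,
    v_mut_fraction = NA_real_,
    d_name = NA_character_, d_tied = list(character(0)), d_score = NA_real_,
    d_offset = NA_integer_, d_start = NA_integer_, d_end = NA_integer_,
    j_name = NA_character_, j_tied = list(character(0)), j_score = NA_real_,
    j_offset = NA_integer_, j_start = NA_integer_,
    n_vd = NA_character_, n_dj = NA_character_,
    cdr3_start = NA_integer_, cdr3_end = NA_integer_,
    cdr3_nt = NA_character_, cdr3_aa = NA_character_,
    v_mismatches = list(integer(0)), d_mismatches = list(integer(0)),
    j_mismatches = list(integer(0)),
    shm_vframe = NA_integer_, shm_cdr3 = NA_integer_,
    indel_log = list(tibble(position = integer(0), type = character(0),
                            nt = character(0)))
  )
}

#' Annotate a single read (segmentation orchestrator)
#'
#' Runs V matching, V-indel correction (with one re-alignment), J matching,
#' D matching, N-region assignment, and CDR3 localization. Failures at any
#' stage yield an annotation row with a `status` reason (`no_v`, `no_j`,
#' `no_d`, `no_cdr3`, `too_short`, `ambiguous_chars`, `empty`) rather than a
#' dropped read.
#'
#' @param read_id Identifier.
#' @param sequence Read nt string.
#' @param db Germline database with anchors assigned.
#' @param config An [annotate_config()].
#' @returns One-row annotation tibble.
#' @export
annotate_sequence <- function(read_id, sequence, db,
                              config = annotate_config()) {
  sequence <- toupper(sequence)
  if (is.na(sequence) || !nzchar(sequence)) {
    return(empty_annotation(read_id, "", "empty"))
  }
  if (grepl("[^ACGTN]", sequence)) {
    return(empty_annotation(read_id, sequence, "ambiguous_chars"))
  }
  if (config$trim_constant) {
    sequence <- trim_constant_region(sequence, db, config)
  }
  len <- nchar(sequence)
  if (len <= config$preserve_v3 + config$min_overlap_v) {
    return(empty_annotation(read_id, sequence, "too_short"))
  }

  v <- annotate_v(sequence, db, config)
  if (v$score == -Inf) return(empty_annotation(read_id, sequence, "no_v"))
  v_gene <- db[match(v$gene, db$name), , drop = FALSE]

  corr <- correct_v_indels(sequence, v, v_gene,
                           leniency_policy(fraction = config$v_leniency_fraction),
                           margin = config$indel_margin,
                           max_edits = config$max_indel_edits)
  sequence <- corr$read
  v <- corr$v_result
  len <- nchar(sequence)

  out <- empty_annotation(read_id, sequence, "ok")
  out$v_name <- v$gene; out$v_tied <- v$tied; out$v_score <- v$score
  out$v_offset <- v$offset; out$v_read_start <- v$read_start
  out$v_mut_fraction <- v$mutation_fraction
  out$indel_log <- list(corr$log)

  # segment boundaries end at the outermost MATCHING position of the
  # aligned overlap: a mismatch run hanging off a segment tip is junction
  # material (deleted germline tail or N nts), not segment
  v_end <- match_trimmed_end(sequence, v_gene$sequence, v$offset,
                             v$read_start, v$read_end, "3p")
  out$v_end <- v_end

  j <- annotate_j(sequence, db, v_end, v$mutation_fraction, config)
  if (j$score == -Inf) { out$status <- "no_j"; return(out) }
  j_gene <- db[match(j$gene, db$name), , drop = FALSE]
  j_start <- match_trimmed_end(sequence, j_gene$sequence, j$offset,
                               j$read_start, j$read_end, "5p")
  out$j_name <- j$gene; out$j_tied <- j$tied; out$j_score <- j$score
  out$j_offset <- j$offset; out$j_start <- j_start

  d <- annotate_d(sequence, db, v_end, j_start,
                  v$mutation_fraction, config)
  if (d$score > -Inf) {
    d_gene_seq <- db$sequence[match(d$gene, db$name)]
    out$d_name <- d$gene; out$d_tied <- d$tied; out$d_score <- d$score
    out$d_offset <- d$offset
    out$d_start <- match_trimmed_end(sequence, d_gene_seq, d$offset,
                                     d$read_start, d$read_end, "5p")
    out$d_end <- match_trimmed_end(sequence, d_gene_seq, d$offset,
                                   d$read_start, d$read_end, "3p")
  } else {
    out$status <- "no_d"
  }

  nreg <- assign_n_regions(sequence, v_end, out$d_start, out$d_end,
                           j_start)
  out$n_vd <- nreg$n_vd; out$n_dj <- nreg$n_dj

  cdr3 <- locate_cdr3(sequence, v$offset, v_gene$anchor_pos,
                      j$offset, j_gene$anchor_pos)
  out$cdr3_start <- cdr3$cdr3_start; out$cdr3_end <- cdr3$cdr3_end
  out$cdr3_nt <- cdr3$cdr3_nt; out$cdr3_aa <- cdr3$cdr3_aa
  out$productive <- cdr3$productive
  if (!cdr3$ok && out$status == "ok") out$status <- "no_cdr3"

  recompute_mismatches(out, db)
}

# per-segment mismatch positions and SHM counts against the row's own
# gene calls; also used after cluster unification
recompute_mismatches <- function(ann, db) {
  for (i in seq_len(nrow(ann))) {
    seqn <- ann$sequence[i]
    mm <- function(gene_name, offset, rs, re) {
      if (is.na(gene_name) || is.na(offset) || is.na(rs) || is.na(re)) {
        return(integer(0))
      }
      gseq <- db$sequence[match(gene_name, db$name)]
      # clamp to the span covered by both the read and the gene
      rs <- max(rs, offset, 1L)
      re <- min(re, offset + nchar(gseq) - 1L, nchar(seqn))
      if (re < rs) return(integer(0))
      alignment_mismatch_positions(seqn, gseq, offset, rs, re)
    }
    vm <- mm(ann$v_name[i], ann$v_offset[i], ann$v_read_start[i], ann$v_end[i])
    dm <- mm(ann$d_name[i], ann$d_offset[i], ann$d_start[i], ann$d_end[i])
    jm <- mm(ann$j_name[i], ann$j_offset[i], ann$j_start[i],
             ann$read_length[i])
    ann$v_mismatches[[i]] <- vm
    ann$d_mismatches[[i]] <- dm
    ann$j_mismatches[[i]] <- jm
    if (!is.na(ann$cdr3_start[i])) {
      all_mm <- c(vm, dm, jm)
      ann$shm_vframe[i] <- sum(vm < ann$cdr3_start[i])
      ann$shm_cdr3[i] <- sum(all_mm >= ann$cdr3_start[i] &
                               all_mm <= ann$cdr3_end[i])
    } else {
      ann$shm_vframe[i] <- length(vm)
      ann$shm_cdr3[i] <- NA_integer_
    }
  }
  ann
}

#' Annotate a table of reads
#'
#' @param reads Tibble with columns `id`, `sequence`, and optionally
#'   `template_count` (default 1), e.g. from [read_sequences()].
#' @param db Germline database with anchors assigned (see
#'   [load_germline_db()] / [simulate_germline_db()]).
#' @param config An [annotate_config()].
#' @returns Annotation tibble, one row per input read (failures included
#'   with a `status` reason), with a `template_count` column.
#' @export
annotate_reads <- function(reads, db, config = annotate_config()) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  tc <- if ("template_count" %in% names(reads)) reads$template_count else 1L
  out <- purrr::map2(reads$id, reads$sequence, annotate_sequence,
                     db = db, config = config)
  out <- dplyr::bind_rows(out)
  out$template_count <- rep_len(as.integer(tc), nrow(out))
  dplyr::relocate(out, "template_count", .after = "sequence")
}
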