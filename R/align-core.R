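#' Mismatch-leniency policy for the run-based alignment score
#'
#' The alignment score sums squared lengths of consecutively matched runs
#' and subtracts squared lengths of consecutively mismatched runs. Under
#' leniency, isolated point mismatches (runs of length exactly 1) may be
#' "forgiven": the forgiven position contributes 0 while its flanking match
#' runs fuse into one, scored as a single squared length. Forgiveness is
#' applied greedily from the 5' end, reflecting the higher frequency of
#' hypermutation near the 5' end of these amplicons. Runs of two or more
#' consecutive mismatches are never forgiven, and neither are ambiguous
#' (`N`) positions.
#'
#' The budget may be a fixed `count`, or a `fraction` of the aligned overlap
#' length (budget `ceiling(fraction * overlap)`), which is how the V segment
#' is scored (fraction 0.15) and how the observed V mutation fraction is
#' propagated to D and J matching.
#'
#' @param count Fixed number of forgivable isolated mismatches, or `NULL`.
#' @param fraction Forgivable fraction of the overlap length, or `NULL`.
#'   Exactly one of `count`/`fraction` should be given; both `NULL` means no
#'   leniency.
#' @returns A `leniency_policy` list.
#' @export
leniency_policy <- function(count = NULL, fraction = NULL) {
  if (!is.null(count) && !is.null(fraction)) {
    abort("give either `count` or `fraction`, not both")
  }
  if (!is.null(count)) stopifnot(count >= 0)
  if (!is.null(fraction)) stopifnot(fraction >= 0)
  structure(list(count = count, fraction = fraction),
            class = "leniency_policy")
}

policy_budget <- function(policy, overlap) {
  if (is.null(policy)) return(0L)
  if (!is.null(policy$count)) return(as.integer(policy$count))
  if (!is.null(policy$fraction)) return(as.integer(ceiling(policy$fraction * overlap)))
  0L
}

# Accepts a logical vector (TRUE = match), an integer vector
# (1/0/-1 = match/forgivable mismatch/unforgivable), or a single string in
# which lowercase letters mark mismatches (e.g. "AGtTTcC").
as_pattern_int <- function(pattern) {
  if (is.character(pattern) && length(pattern) == 1L) {
    ch <- seq_chars(pattern)
    out <- ifelse(ch == toupper(ch), 1L, 0L)
    out[toupper(ch) == "N"] <- -1L
    return(as.integer(out))
  }
  if (is.logical(pattern)) return(ifelse(pattern, 1L, 0L))
  as.integer(pattern)
}

#' Score a match/mismatch pattern with the consecutive-run rule
#'
#' @param pattern Logical vector (`TRUE` = match), integer vector
#'   (1 match / 0 mismatch / -1 unforgivable mismatch), or a single aligned
#'   string with lowercase mismatches, e.g. `"AGtTTcC"`.
#' @param leniency A [leniency_policy()], or a plain non-negative integer
#'   taken as a fixed forgiveness count.
#' @returns The alignment score (a number).
#' @examples
#' score_match_pattern("AGtTTcC")              # 2^2 - 1 + 2^2 - 1 + 1 = 7
#' score_match_pattern("AGtTTcC", leniency = 1) # (2+0+2)^2 - 1 + 1 = 16
#' @export
score_match_pattern <- function(pattern, leniency = 0) {
  p <- as_pattern_int(pattern)
  if (length(p) == 0L) abort("pattern must be non-empty")
  if (is.numeric(leniency)) leniency <- leniency_policy(count = leniency)
  score_pattern_cpp(p, policy_budget(leniency, length(p)))
}

no_alignment_result <- function(gene = NA_character_) {
  tibble(gene = gene, score = -Inf, offset = NA_integer_,
         read_start = NA_integer_, read_end = NA_integer_,
         gene_start = NA_integer_, gene_end = NA_integer_,
         overlap = 0L, n_mismatch = NA_integer_,
         mutation_fraction = NA_real_, tied = list(character(0)))
}

#' Best ungapped placement of a germline gene against a read
#'
#' Evaluates every ungapped offset of `gene_seq` against the read restricted
#' to `window` (partial overhangs at the window edges allowed) and returns
#' the placement maximizing [score_match_pattern()]. Ties are broken by
#' longer overlap, then smaller offset.
#'
#' @param read Read sequence (uppercase nt string; `N` allowed, always
#'   scored as an unforgivable mismatch).
#' @param gene_seq Germline gene sequence.
#' @param leniency A [leniency_policy()] or fixed count.
#' @param window 1-based inclusive read interval to align within.
#' @param min_overlap Minimum aligned overlap; below it a no-alignment
#'   sentinel with score `-Inf` is returned.
#' @param gene_name Optional name copied into the result.
#' @returns One-row tibble: `gene`, `score`, `offset` (read coordinate of
#'   gene position 1), `read_start`/`read_end`, `gene_start`/`gene_end`,
#'   `overlap`, `n_mismatch`, `mutation_fraction`.
#' @export
best_ungapped_alignment <- function(read, gene_seq, leniency = 0,
                                    window = c(1L, nchar(read)),
                                    min_overlap = 10L,
                                    gene_name = NA_character_) {
  if (is.numeric(leniency)) leniency <- leniency_policy(count = leniency)
  ws <- as.integer(window[1]); we <- as.integer(window[2])
  if (we - ws + 1L < min_overlap || nchar(gene_seq) < 1L) {
    return(no_alignment_result(gene_name))
  }
  cand <- enumerate_offsets_cpp(read, gene_seq, ws, we, as.integer(min_overlap),
                                leniency$fraction %||% -1,
                                if (is.null(leniency$count)) -1L
                                else as.integer(leniency$count))
  if (nrow(cand) == 0L) return(no_alignment_result(gene_name))
  ord <- order(-cand$score, -cand$overlap, cand$offset)
  b <- cand[ord[1L], ]
  tibble(gene = gene_name, score = b$score, offset = as.integer(b$offset),
         read_start = as.integer(b$read_start),
         read_end = as.integer(b$read_end),
         gene_start = as.integer(b$read_start - b$offset + 1L),
         gene_end = as.integer(b$read_end - b$offset + 1L),
         overlap = as.integer(b$overlap),
         n_mismatch = as.integer(b$n_mismatch),
         mutation_fraction = b$n_mismatch / b$overlap,
         tied = list(character(0)))
}

# Best gene over a database subset; ties across genes broken by score,
# overlap, offset, then lexicographic gene name. The full tied-name list is
# kept; pseudogenes are dropped from it when a functional tie exists.
align_to_db <- function(read, genes, leniency, window, min_overlap) {
  if (nrow(genes) == 0L) return(no_alignment_result())
  res <- purrr::map2(genes$sequence, genes$name, function(s, nm) {
    best_ungapped_alignment(read, s, leniency, window, min_overlap,
                            gene_name = nm)
  })
  res <- dplyr::bind_rows(res)
  if (all(res$score == -Inf)) return(no_alignment_result())
  ord <- order(-res$score, -res$overlap, res$offset, res$gene)
  best <- res[ord[1L], ]
  tied <- sort(res$gene[res$score == best$score & res$overlap == best$overlap])
  if (length(tied) > 1L) {
    pseudo <- genes$is_pseudogene[match(tied, genes$name)]
    if (any(!pseudo)) tied <- tied[!pseudo]
    if (!best$gene %in% tied) {
      best <- res[res$gene == tied[1L], ][1L, ]
    }
  }
  best$tied <- list(tied)
  best
}

# read positions (within the aligned overlap) that mismatch the gene
alignment_mismatch_positions <- function(read, gene_seq, offset,
                                         read_start, read_end) {
  if (is.na(read_start) || read_end < read_start) return(integer(0))
  r <- seq_chars(substr(read, read_start, read_end))
  g <- seq_chars(substr(gene_seq, read_start - offset + 1L,
                        read_end - offset + 1L))
  which(r != g) + read_start - 1L
}

#' Correct V-segment indels upstream of the 104Cys
#'
#' Single-nucleotide insertion/deletion sequencing errors in the V framework
#' (strictly 5' of the 104Cys anchor) are repaired when an edit raises the
#' V alignment score by more than `margin`. The CDR3 (at/after the anchor)
#' is never edited, since indels there can be genuine recombination events.
#' At most `max_edits` edits are applied, best-first.
#'
#' @param read Read sequence.
#' @param v_result One-row alignment tibble from [best_ungapped_alignment()]
#'   for the chosen V gene.
#' @param v_gene One-row tibble for the V gene (needs `sequence`,
#'   `anchor_pos`).
#' @param leniency Leniency policy used for re-scoring (default: the V rule,
#'   fraction 0.15).
#' @param margin Minimum strict score gain per accepted edit (default 4).
#' @param max_edits Maximum number of edits (default 2).
#' @returns List with `read` (possibly edited), `log` (tibble of
#'   `position`, `type`, `nt`), and `v_result` re-aligned against the edited
#'   read.
#' @export
correct_v_indels <- function(read, v_result, v_gene,
                             leniency = leniency_policy(fraction = 0.15),
                             margin = 4, max_edits = 2L) {
  log <- tibble(position = integer(0), type = character(0), nt = character(0))
  if (is.na(v_result$score) || v_result$score == -Inf ||
      is.na(v_gene$anchor_pos)) {
    return(list(read = read, log = log, v_result = v_result))
  }
  realign <- function(rd) {
    best_ungapped_alignment(rd, v_gene$sequence, leniency,
                            window = c(1L, max(nchar(rd) - 9L, 1L)),
                            min_overlap = 10L, gene_name = v_gene$name)
  }
  # cheap gate: a genuine single-nt indel frameshifts the alignment tail,
  # producing runs of consecutive mismatches; isolated SHM does not. Skip
  # the (expensive) edit search unless such a run exists 5' of the anchor.
  has_frameshift_signature <- function(aln) {
    mm <- alignment_mismatch_positions(read, v_gene$sequence, aln$offset,
                                       aln$read_start, aln$read_end)
    mm <- mm[mm < aln$offset + v_gene$anchor_pos - 1L]
    if (length(mm) < 3L) return(FALSE)
    runs <- rle(diff(mm) == 1L)
    any(runs$lengths[runs$values] >= 2L) # run of >= 3 positions
  }
  if (!has_frameshift_signature(v_result)) {
    return(list(read = read, log = log, v_result = v_result))
  }
  cur <- v_result
  cur_read <- read
  for (k in seq_len(max_edits)) {
    anchor_read <- cur$offset + v_gene$anchor_pos - 1L
    lo <- cur$read_start
    hi <- min(anchor_read - 1L, cur$read_end)
    if (is.na(hi) || hi < lo) break
    best_gain <- -Inf; best_edit <- NULL
    # an edit must both clear the score margin and strictly reduce the
    # mismatch count: a real single-nt indel leaves a frameshifted,
    # mismatch-rich tail that the repair resolves, whereas edits that
    # merely grow the aligned overlap at the read edge do not
    for (p in max(lo, cur$read_start + 1L):hi) {
      # deletion of read nt p
      rd <- paste0(substr(cur_read, 1L, p - 1L),
                   substr(cur_read, p + 1L, nchar(cur_read)))
      a <- realign(rd)
      gain <- a$score - cur$score
      if (a$n_mismatch < cur$n_mismatch && gain > best_gain) {
        best_gain <- gain
        best_edit <- list(read = rd, type = "deletion", pos = p,
                          nt = substr(cur_read, p, p), aln = a)
      }
      # insertion of the germline nt aligned at p: under a 5'-anchored
      # placement the new nt pairs with gene position p - offset + 1, under
      # a 3'-anchored placement with p - offset, so both are tried
      for (g_pos in unique(c(p - cur$offset + 1L, p - cur$offset))) {
        if (g_pos < 1L || g_pos > nchar(v_gene$sequence)) next
        ins <- substr(v_gene$sequence, g_pos, g_pos)
        rd <- paste0(substr(cur_read, 1L, p - 1L), ins,
                     substr(cur_read, p, nchar(cur_read)))
        a <- realign(rd)
        gain <- a$score - cur$score
        if (a$n_mismatch < cur$n_mismatch && gain > best_gain) {
          best_gain <- gain
          best_edit <- list(read = rd, type = "insertion", pos = p,
                            nt = ins, aln = a)
        }
      }
    }
    if (is.null(best_edit) || best_gain <= margin) break
    vl_log("V indel corrected: ", best_edit$type, " at read position ",
           best_edit$pos, " (score +", round(best_gain, 1), ")")
    cur_read <- best_edit$read
    cur <- best_edit$aln
    log <- dplyr::bind_rows(log, tibble(position = best_edit$pos,
                                        type = best_edit$type,
                                        nt = best_edit$nt))
  }
  list(read = cur_read, log = log, v_result = cur)
}
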