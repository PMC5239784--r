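#' TDT N-region insertion model
#'
#' Terminal deoxynucleotidyl transferase (TDT) inserts non-templated
#' nucleotides with a strong G/A bias on the elongated strand. The model
#' holds the per-nt insertion probabilities used to judge whether a
#' candidate N region looks TDT-made rather than random; defaults are the
#' mouse estimates P_A = 0.25, P_C = 0.08, P_G = 0.60, P_T = 0.07, against
#' a uniform 0.25-per-nt background.
#'
#' @param p_a,p_c,p_g,p_t Insertion probabilities (must sum to 1).
#' @param baseline Background per-nt probability (default 0.25).
#' @returns A `tdt_model` list with `p_insert` (named numeric) and
#'   `baseline`.
#' @export
tdt_model <- function(p_a = 0.25, p_c = 0.08, p_g = 0.60, p_t = 0.07,
                      baseline = 0.25) {
  p <- c(A = p_a, C = p_c, G = p_g, T = p_t)
  if (abs(sum(p) - 1) > 1e-8) abort("insertion probabilities must sum to 1")
  if (any(p <= 0) || any(p >= 1)) abort("insertion probabilities must lie in (0,1)")
  structure(list(p_insert = p, baseline = baseline), class = "tdt_model")
}

p_tdt_one_strand <- function(n_seq, model) {
  if (!nzchar(n_seq)) return(0.5)
  p <- model$p_insert[seq_chars(n_seq)]
  prod_p <- prod(p)
  prod_p / (model$baseline^nchar(n_seq) + prod_p)
}

#' Probability that an N region was created by TDT
#'
#' Relative to purely random insertion: `prod(P_X) / (0.25^L + prod(P_X))`.
#' Because TDT may act on either DNA strand, the value is the maximum over
#' the sequence and its element-wise complement (no reversal). The empty
#' region returns the neutral value 0.5.
#'
#' @param n_seq N-region nt string (may be empty); vectorized.
#' @param model A [tdt_model()].
#' @returns Probability in (0, 1).
#' @examples
#' round(p_tdt("GGG"), 2)    # 0.93
#' round(p_tdt("TATC"), 2)   # 0.40 (via the complement ATAG)
#' round(p_tdt("GGGCCC"), 2) # 0.31
#' @export
p_tdt <- function(n_seq, model = tdt_model()) {
  vapply(toupper(n_seq), function(s) {
    max(p_tdt_one_strand(s, model),
        p_tdt_one_strand(complement_nt(s), model))
  }, numeric(1), USE.NAMES = FALSE)
}

#' N-region likelihood score
#'
#' `Nscore = (P_TDT * L)^2` with `L` the N-region length; the two-strand
#' maximum of [p_tdt()] is used and the empty region scores 0.
#'
#' @inheritParams p_tdt
#' @returns Non-negative score; vectorized.
#' @export
nscore <- function(n_seq, model = tdt_model()) {
  ifelse(nzchar(n_seq), (p_tdt(n_seq, model) * nchar(n_seq))^2, 0)
}

#' Consensus mismatches of a cluster
#'
#' Positions at which every member of a cluster mismatches the predicted
#' germline sequence — the signature of a suboptimal junction annotation
#' (when confined to the CDR3) or of an early real mutation (when present
#' in the V framework). Positions are reported in root coordinates and
#' labelled `Vframe` (5' of the CDR3), `CDR3`, or `other`.
#'
#' @param clusters A `clone_clusters` object.
#' @param cluster_id Optional single cluster id; default all clusters.
#' @returns Tibble with `cluster_id`, `position`, `region`.
#' @export
find_consensus_mismatches <- function(clusters, cluster_id = NULL) {
  ann <- clusters$annotations
  ids <- cluster_id %||% unique(ann$cluster_id)
  out <- list()
  for (cid in ids) {
    idx <- which(ann$cluster_id == cid)
    germline <- clusters$germlines$germline[
      match(cid, clusters$germlines$cluster_id)]
    if (is.na(germline)) next
    sub <- ann[idx, , drop = FALSE]
    win <- group_windows(sub)
    wlen <- nchar(win[1])
    gwin <- substr(germline, nchar(germline) - wlen + 1L, nchar(germline))
    gch <- seq_chars(gwin)
    consensus <- rep(TRUE, wlen)
    for (s in win) consensus <- consensus & (seq_chars(s) != gch)
    pos_win <- which(consensus)
    if (length(pos_win) == 0L) next
    ri <- cluster_root_index(ann, idx)
    # window is right-anchored: map back to root coordinates
    pos <- pos_win + ann$read_length[ri] - wlen
    region <- dplyr::case_when(
      is.na(ann$cdr3_start[ri]) ~ "other",
      pos < ann$cdr3_start[ri] ~ "Vframe",
      pos <= ann$cdr3_end[ri] ~ "CDR3",
      TRUE ~ "other"
    )
    out[[cid]] <- tibble(cluster_id = cid, position = pos, region = region)
  }
  if (length(out) == 0L) {
    return(tibble(cluster_id = character(0), position = integer(0),
                  region = character(0)))
  }
  dplyr::bind_rows(out)
}

# objective used to accept a D re-annotation
d_objective <- function(v_score, d_score, j_score, n_vd, n_dj, model) {
  sum(v_score, d_score, j_score, na.rm = TRUE) +
    nscore(n_vd, model) + nscore(n_dj, model)
}

#' Refine D-gene annotations within clusters (Step 3)
#'
#' For clusters showing at least one CDR3 consensus mismatch and none in
#' the V framework (a framework consensus mismatch indicates the CDR3 ones
#' are real SHM by-products, so such clusters are skipped), the D alignment
#' is re-run on the root over all D genes (including inverted copies) and
#' all placements. An alternative is accepted only if it strictly
#' increases the sum of the V, D, and J alignment scores plus the Nscores
#' of both N regions. On acceptance the cluster is re-unified.
#'
#' Consensus mismatches sitting within a few nt of a segment tip are a
#' symptom of N-region demarcation error, which the edge rules of
#' [refine_n_edges()] own; D re-annotation is attempted only when an
#' interior CDR3 consensus mismatch (farther than `edge_window` nt from
#' every segment tip) implicates the D gene choice itself.
#'
#' @param clusters A `clone_clusters` object.
#' @param model A [tdt_model()].
#' @param edge_window Tip distance within which a consensus mismatch is
#'   considered a demarcation artefact (default 3, matching
#'   [refine_n_edges()]).
#' @returns The (possibly updated) object.
#' @export
refine_d_gene <- function(clusters, model = tdt_model(), edge_window = 3L) {
  ann <- clusters$annotations
  db <- clusters$db
  cm <- find_consensus_mismatches(clusters)
  changed <- FALSE
  for (cid in unique(cm$cluster_id)) {
    sub <- cm[cm$cluster_id == cid, , drop = FALSE]
    if (!any(sub$region == "CDR3") || any(sub$region == "Vframe")) next
    idx <- which(ann$cluster_id == cid)
    ri <- cluster_root_index(ann, idx)
    root <- ann[ri, , drop = FALSE]
    tips <- c(root$v_end, root$d_start, root$d_end, root$j_start)
    tips <- tips[!is.na(tips)]
    interior <- vapply(sub$position[sub$region == "CDR3"], function(p) {
      all(abs(p - tips) > edge_window)
    }, logical(1))
    if (!any(interior)) next
    if (is.na(root$v_end) || is.na(root$j_start)) next
    ws <- root$v_end + 1L; we <- root$j_start - 1L
    if (we < ws) next
    lp <- leniency_policy(fraction = root$v_mut_fraction %||% 0)
    genes <- db_class(db, "D")
    cur_obj <- d_objective(root$v_score, root$d_score %||% 0, root$j_score,
                           root$n_vd, root$n_dj, model)
    best <- NULL
    for (k in seq_len(nrow(genes))) {
      cand <- enumerate_offsets_cpp(root$sequence, genes$sequence[k],
                                    ws, we, 3L,
                                    root$v_mut_fraction %||% 0, -1L)
      if (nrow(cand) == 0L) next
      for (r in seq_len(nrow(cand))) {
        n_vd <- if (cand$read_start[r] > ws)
          substr(root$sequence, ws, cand$read_start[r] - 1L) else ""
        n_dj <- if (cand$read_end[r] < we)
          substr(root$sequence, cand$read_end[r] + 1L, we) else ""
        obj <- d_objective(root$v_score, cand$score[r], root$j_score,
                           n_vd, n_dj, model)
        if (is.null(best) || obj > best$obj ||
            (obj == best$obj && genes$name[k] < best$gene)) {
          best <- list(obj = obj, gene = genes$name[k],
                       offset = cand$offset[r],
                       read_start = cand$read_start[r],
                       read_end = cand$read_end[r],
                       score = cand$score[r], n_vd = n_vd, n_dj = n_dj)
        }
      }
    }
    if (!is.null(best) && best$obj > cur_obj &&
        !identical(best$gene, root$d_name)) {
      vl_log("cluster ", cid, ": D gene re-annotated ",
             root$d_name %||% "<none>", " -> ", best$gene,
             " (objective ", round(cur_obj, 2), " -> ",
             round(best$obj, 2), ")")
      ann$d_name[ri] <- best$gene
      ann$d_tied[[ri]] <- best$gene
      ann$d_score[ri] <- best$score
      ann$d_offset[ri] <- as.integer(best$offset)
      ann$d_start[ri] <- as.integer(best$read_start)
      ann$d_end[ri] <- as.integer(best$read_end)
      ann$n_vd[ri] <- best$n_vd
      ann$n_dj[ri] <- best$n_dj
      changed <- TRUE
    }
  }
  if (changed) {
    clusters$annotations <- ann
    clusters <- unify_annotations(clusters)
  }
  clusters
}

# one segment edge for refine_n_edges: returns the updated root row or NULL
refine_one_edge <- function(root, db, model, edge, edge_window, run_gap) {
  seqn <- root$sequence
  get_mm <- function(col) root[[col]][[1]]
  spec <- switch(edge,
    v3 = list(tip = root$v_end, dir = "3p", mm = get_mm("v_mismatches"),
              n = root$n_vd, n_side = "after",
              lo = if (!is.na(root$cdr3_start)) root$cdr3_start + 2L else root$v_read_start),
    d5 = list(tip = root$d_start, dir = "5p", mm = get_mm("d_mismatches"),
              n = root$n_vd, n_side = "before", hi = root$d_end - 1L),
    d3 = list(tip = root$d_end, dir = "3p", mm = get_mm("d_mismatches"),
              n = root$n_dj, n_side = "after", lo = root$d_start + 1L),
    j5 = list(tip = root$j_start, dir = "5p", mm = get_mm("j_mismatches"),
              n = root$n_dj, n_side = "before",
              hi = if (!is.na(root$cdr3_end)) root$cdr3_end - 3L else root$read_length)
  )
  if (is.na(spec$tip) || length(spec$mm) == 0L) return(NULL)
  mm <- sort(spec$mm)
  if (spec$dir == "3p") {
    dist <- spec$tip - mm
  } else {
    dist <- mm - spec$tip
  }
  k <- 0L
  # rule A: a run of >= 3 consecutive mismatches whose near end lies within
  # run_gap nts of the tip moves unconditionally, together with the
  # intervening matching nts
  runs <- split(mm, cumsum(c(1L, diff(mm) != 1L)))
  for (run in runs) {
    near <- if (spec$dir == "3p") spec$tip - max(run) else min(run) - spec$tip
    if (length(run) >= 3L && near <= run_gap) {
      k <- if (spec$dir == "3p") spec$tip - min(run) + 1L
           else max(run) - spec$tip + 1L
      break
    }
  }
  rule_a <- k > 0L
  if (!rule_a) {
    # rules B/C: TDT-composition test on the edge nts from the outermost
    # near-tip mismatch through the tip
    near_mm <- mm[dist <= edge_window & dist >= 0L]
    if (length(near_mm) == 0L) return(NULL)
    k <- if (spec$dir == "3p") spec$tip - min(near_mm) + 1L
         else max(near_mm) - spec$tip + 1L
  }
  # respect segment bounds (keep the Cys/Trp codons and >= 1 nt of D)
  if (spec$dir == "3p") {
    if (!is.null(spec$lo) && !is.na(spec$lo)) {
      k <- min(k, spec$tip - spec$lo)
    }
    if (k < 1L) return(NULL)
    cand <- substr(seqn, spec$tip - k + 1L, spec$tip)
  } else {
    if (!is.null(spec$hi) && !is.na(spec$hi)) {
      k <- min(k, spec$hi - spec$tip)
    }
    if (k < 1L) return(NULL)
    cand <- substr(seqn, spec$tip, spec$tip + k - 1L)
  }
  if (!rule_a) {
    combined <- if (spec$n_side == "after") paste0(cand, spec$n)
                else paste0(spec$n, cand)
    ok <- if (!nzchar(spec$n)) {
      p_tdt(cand, model) > 0.5 # rule B: trimming creates an N region
    } else {
      p_tdt(combined, model) > p_tdt(cand, model) # rule C: extension helps
    }
    if (!ok) return(NULL)
  }
  list(edge = edge, k = k)
}

apply_edge_trim <- function(root, trim) {
  k <- trim$k
  s <- root$sequence
  switch(trim$edge,
    v3 = {
      root$n_vd <- paste0(substr(s, root$v_end - k + 1L, root$v_end),
                          root$n_vd)
      root$v_end <- root$v_end - k
    },
    d5 = {
      root$n_vd <- paste0(root$n_vd,
                          substr(s, root$d_start, root$d_start + k - 1L))
      root$d_start <- root$d_start + k
    },
    d3 = {
      root$n_dj <- paste0(substr(s, root$d_end - k + 1L, root$d_end),
                          root$n_dj)
      root$d_end <- root$d_end - k
    },
    j5 = {
      root$n_dj <- paste0(root$n_dj,
                          substr(s, root$j_start, root$j_start + k - 1L))
      root$j_start <- root$j_start + k
    }
  )
  root
}

#' Refine N-region demarcations within clusters (Step 4)
#'
#' For each segment edge abutting an N region (V 3', D 5', D 3', J 5', in
#' that order) on the unified root: (rule A) a run of three or more
#' consecutive mismatches at the edge is moved into the adjacent N region
#' unconditionally, together with any germline-matching nts between the run
#' and the segment tip; (rule B) where no N region exists, edge mismatch
#' nts (plus the nts between them and the tip) are trimmed into a new N
#' region iff their `p_tdt` exceeds 0.50; (rule C) where an N region
#' exists, the edge nts extend it iff `p_tdt` of the combined region
#' strictly exceeds that of the edge nts alone. One pass over the four
#' edges, then one re-unification.
#'
#' @param clusters A `clone_clusters` object.
#' @param model A [tdt_model()].
#' @param edge_window Mismatches at most this many nt from the segment tip
#'   trigger the rule B/C tests (default 3).
#' @param run_gap Maximum number of matching nts between a rule-A mismatch
#'   run and the tip (default 2).
#' @returns The (possibly updated) object.
#' @export
refine_n_edges <- function(clusters, model = tdt_model(),
                           edge_window = 3L, run_gap = 2L) {
  ann <- clusters$annotations
  db <- clusters$db
  changed <- FALSE
  for (cid in unique(ann$cluster_id)) {
    idx <- which(ann$cluster_id == cid)
    ri <- cluster_root_index(ann, idx)
    root <- ann[ri, , drop = FALSE]
    if (is.na(root$v_end) || is.na(root$j_start)) next
    edited <- FALSE
    for (edge in c("v3", "d5", "d3", "j5")) {
      if (edge %in% c("d5", "d3") && is.na(root$d_start)) next
      trim <- refine_one_edge(root, db, model, edge, edge_window, run_gap)
      if (!is.null(trim)) {
        vl_log("cluster ", cid, ": ", trim$k, " nt moved from the ", edge,
               " segment edge into the N region")
        root <- apply_edge_trim(root, trim)
        root <- recompute_mismatches(root, db)
        edited <- TRUE
      }
    }
    if (edited) {
      for (col in names(root)) ann[[col]][ri] <- root[[col]]
      changed <- TRUE
    }
  }
  if (changed) {
    clusters$annotations <- ann
    clusters <- unify_annotations(clusters)
  }
  clusters
}

#' Run the D-gene and N-region refinement stages
#'
#' Applies [refine_d_gene()] then [refine_n_edges()], at most `max_iter`
#' times (default 2), stopping early when a pass changes nothing.
#'
#' @param clusters A `clone_clusters` object.
#' @param model A [tdt_model()].
#' @param max_iter Maximum Step3+Step4 passes.
#' @returns The refined object.
#' @export
refine_junctions <- function(clusters, model = tdt_model(), max_iter = 2L) {
  for (i in seq_len(max_iter)) {
    before <- clusters$annotations[c("d_name", "v_end", "d_start", "d_end",
                                     "j_start")]
    clusters <- refine_d_gene(clusters, model)
    clusters <- refine_n_edges(clusters, model)
    after <- clusters$annotations[c("d_name", "v_end", "d_start", "d_end",
                                    "j_start")]
    if (identical(before, after)) break
  }
  finalize_clusters(clusters)
}
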