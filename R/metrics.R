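#' Gene-call match against truth
#'
#' `exact` mode requires full allele-name equality (up to the allele
#' number). `degenerate` mode counts a call correct when the called
#' allele's germline sequence is at least `threshold` (default 98%)
#' identical to the truth allele's sequence over the best ungapped
#' placement of the shorter sequence within the longer; it is symmetric in
#' its two arguments.
#'
#' @param predicted,truth Allele names (vectorized, equal length).
#' @param db Germline database resolving both names.
#' @param mode `"exact"` or `"degenerate"`.
#' @param threshold Identity threshold for degenerate matching.
#' @returns Logical vector.
#' @export
gene_match <- function(predicted, truth, db,
                       mode = c("exact", "degenerate"), threshold = 0.98) {
  mode <- match.arg(mode)
  purrr::map2_lgl(predicted, truth, function(p, t) {
    if (is.na(p) || is.na(t)) return(FALSE)
    if (p == t) return(TRUE)
    if (mode == "exact") return(FALSE)
    ps <- db$sequence[match(p, db$name)]
    ts <- db$sequence[match(t, db$name)]
    if (is.na(ps) || is.na(ts)) abort(paste0("unknown gene name: ",
                                             if (is.na(ps)) p else t))
    if (nchar(ps) > nchar(ts)) { tmp <- ps; ps <- ts; ts <- tmp }
    short <- seq_chars(ps); long <- seq_chars(ts)
    ls <- length(short); ll <- length(long)
    best <- 0L
    for (o in 0:(ll - ls)) {
      best <- max(best, sum(short == long[(o + 1):(o + ls)]))
    }
    best / ls >= threshold
  })
}

#' Per-position SHM confusion counts
#'
#' Compares predicted mutation calls with truth per position of a region:
#' TP = mutated in truth and called, TN = unmutated and uncalled, FP =
#' called but not mutated, FN = mutated but uncalled.
#'
#' @param predicted_positions,truth_positions Integer vectors of called /
#'   true mutated read positions.
#' @param region Inclusive 1-based interval `c(start, end)` to evaluate.
#' @returns Tibble with `tp`, `tn`, `fp`, `fn` (summing to the region
#'   width).
#' @export
shm_confusion <- function(predicted_positions, truth_positions, region) {
  pos <- seq.int(region[1], region[2])
  p <- pos %in% predicted_positions
  t <- pos %in% truth_positions
  tibble(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t),
         fn = sum(!p & t))
}

#' Accuracy and positive prediction rate
#'
#' `acc = (tp + tn) / (tp + tn + fp + fn)`; `ppr = tp / (tp + fp)`,
#' defined as 0 when no positives were called.
#'
#' @param counts Tibble or list with `tp`, `tn`, `fp`, `fn` (vectorized).
#' @returns Tibble with `acc` and `ppr`.
#' @export
accuracy_ppr <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  stopifnot(all(tot > 0))
  called <- counts$tp + counts$fp
  tibble(acc = (counts$tp + counts$tn) / tot,
         ppr = ifelse(called == 0, 0, counts$tp / called))
}

# differing positions of a parent/child pair restricted to an interval set
pair_mutations <- function(parent, child, keep) {
  p <- seq_chars(parent); c <- seq_chars(child)
  i <- which(p != c)
  i <- i[keep[i]]
  tibble(from = p[i], to = c[i])
}

segment_mask <- function(row, scope, len) {
  keep <- rep(FALSE, len)
  mark <- function(a, b) {
    if (!is.na(a) && !is.na(b) && b >= a) keep[a:b] <<- TRUE
  }
  if (scope %in% c("V", "all")) mark(1L, row$v_end)
  if (scope %in% c("DJ", "all")) {
    mark(row$d_start, row$d_end)
    mark(row$j_start, len)
  }
  keep
}

#' SHM propensity matrix from parent-child pairs
#'
#' Counts the 12 ordered X0 -> X1 substitutions over differing positions
#' of parent-child sequence pairs (parent strand supplies the context and
#' X0) within the chosen scope — V segment, D+J segments, or all three —
#' always excluding N regions; rows are then normalized so that, e.g.,
#' P(A->T) + P(A->C) + P(A->G) = 1.
#'
#' @param pairs Tibble with `parent_seq`, `child_seq` and boundary columns
#'   `v_end`, `d_start`, `d_end`, `j_start` (see [lineage_pairs()]).
#' @param scope `"V"`, `"DJ"`, or `"all"`.
#' @returns A `propensity_matrix` tibble: `from`, `to`, `count`, `freq`,
#'   with the scope as attribute; zero-count matrices carry `empty = TRUE`.
#' @export
propensity_matrix <- function(pairs, scope = c("all", "V", "DJ")) {
  scope <- match.arg(scope)
  nts <- c("A", "C", "G", "T")
  muts <- purrr::pmap(
    pairs[c("parent_seq", "child_seq", "v_end", "d_start", "d_end",
            "j_start")],
    function(parent_seq, child_seq, v_end, d_start, d_end, j_start) {
      row <- list(v_end = v_end, d_start = d_start, d_end = d_end,
                  j_start = j_start)
      keep <- segment_mask(row, scope, nchar(parent_seq))
      pair_mutations(parent_seq, child_seq, keep)
    })
  muts <- dplyr::bind_rows(muts)
  grid <- tidyr::expand_grid(from = nts, to = nts) |>
    dplyr::filter(.data$from != .data$to)
  counts <- muts |>
    dplyr::count(.data$from, .data$to, name = "count") |>
    dplyr::right_join(grid, by = c("from", "to")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::arrange(.data$from, .data$to) |>
    dplyr::group_by(.data$from) |>
    dplyr::mutate(freq = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else NA_real_) |>
    dplyr::ungroup()
  out <- structure(counts, scope = scope, empty = sum(counts$count) == 0)
  class(out) <- unique(c("propensity_matrix", class(out)))
  out
}

#' Parent-child sequence pairs from clonal clusters
#'
#' One row per lineage edge, carrying the parent and child sequences and
#' the unified segment boundaries, ready for [propensity_matrix()] and
#' [hotspot_profile()].
#'
#' @param clusters A `clone_clusters` object.
#' @returns Tibble with `parent_seq`, `child_seq`, and boundary columns.
#' @export
lineage_pairs <- function(clusters) {
  ann <- clusters$annotations
  child <- ann[!is.na(ann$parent_id), , drop = FALSE]
  pidx <- match(child$parent_id, ann$read_id)
  tibble(parent_id = child$parent_id, child_id = child$read_id,
         parent_seq = ann$sequence[pidx], child_seq = child$sequence,
         v_end = child$v_end, d_start = child$d_start,
         d_end = child$d_end, j_start = child$j_start)
}

#' Correlation between V- and DJ-segment SHM propensities
#'
#' Pearson correlation and least-squares slope (DJ on V) over the 12
#' normalized substitution frequencies; a proxy for annotation quality
#' since the mutational machinery does not discriminate between segments.
#'
#' @param v,dj `propensity_matrix` tibbles.
#' @returns One-row tibble with `r_corr` and `slope`.
#' @export
v_dj_correlation <- function(v, dj) {
  m <- dplyr::inner_join(as_tibble(v)[c("from", "to", "freq")],
                         as_tibble(dj)[c("from", "to", "freq")],
                         by = c("from", "to"),
                         suffix = c("_v", "_dj"))
  m <- m[stats::complete.cases(m$freq_v, m$freq_dj), , drop = FALSE]
  if (nrow(m) < 3L || stats::sd(m$freq_v) == 0 || stats::sd(m$freq_dj) == 0) {
    abort("propensity frequencies have zero variance; correlation undefined")
  }
  fit <- stats::lm(m$freq_dj ~ m$freq_v)
  tibble(r_corr = stats::cor(m$freq_v, m$freq_dj),
         slope = unname(stats::coef(fit)[2]))
}

#' Nucleotide composition around mutated positions (hot-spot profile)
#'
#' For offsets -k..k around each mutated position (and, as the background,
#' around every position), tallies the parent-strand nt composition; the
#' two tables together let motif enrichment be judged against the
#' intrinsic positional background.
#'
#' @param pairs Tibble as for [propensity_matrix()].
#' @param k Window half-width (default 3).
#' @param scope Segment scope, as in [propensity_matrix()].
#' @returns Tibble: `center` (`"mutated"`/`"all"`), `offset`, `nt`,
#'   `count`, `freq` (normalized per center x offset).
#' @export
hotspot_profile <- function(pairs, k = 3L, scope = "all") {
  tallies <- list()
  add <- function(center, offset, nt) {
    tallies[[length(tallies) + 1L]] <<- tibble(center = center,
                                               offset = offset, nt = nt)
  }
  for (i in seq_len(nrow(pairs))) {
    p <- seq_chars(pairs$parent_seq[i])
    len <- length(p)
    keep <- segment_mask(pairs[i, ], scope, len)
    c_ch <- seq_chars(pairs$child_seq[i])
    centers_mut <- which(p != c_ch & keep)
    centers_all <- which(keep)
    for (off in -k:k) {
      at <- centers_mut + off
      ok <- at >= 1L & at <= len
      if (any(ok)) add("mutated", off, p[at[ok]])
      at <- centers_all + off
      ok <- at >= 1L & at <= len
      if (any(ok)) add("all", off, p[at[ok]])
    }
  }
  dplyr::bind_rows(tallies) |>
    dplyr::count(.data$center, .data$offset, .data$nt, name = "count") |>
    tidyr::complete(center = c("mutated", "all"), offset = -k:k,
                    nt = c("A", "C", "G", "T"),
                    fill = list(count = 0L)) |>
    dplyr::group_by(.data$center, .data$offset) |>
    dplyr::mutate(freq = if (sum(.data$count) > 0)
      .data$count / sum(.data$count) else NA_real_) |>
    dplyr::ungroup()
}

#' V/D/J gene-family usage frequencies
#'
#' Family-level usage for each segment class (inverted D families tallied
#' under their `"r"`-prefixed label) and pair frequencies for (V family,
#' D family) and (D family, J family).
#'
#' @param ann Annotation tibble (productive rows are conventionally passed).
#' @returns List of tibbles: `family` (segment, family, count, freq),
#'   `vd_pairs`, `dj_pairs`.
#' @export
usage_frequencies <- function(ann) {
  fam <- function(x) parse_gene_family(x)$family
  tab <- tibble(v = fam(ann$v_name), d = fam(ann$d_name),
                j = fam(ann$j_name))
  one <- function(col, segment) {
    tab |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::count(family = .data[[col]], name = "count") |>
      dplyr::mutate(segment = segment, freq = .data$count / sum(.data$count)) |>
      dplyr::relocate("segment")
  }
  pair <- function(a, b) {
    tab |>
      dplyr::filter(!is.na(.data[[a]]), !is.na(.data[[b]])) |>
      dplyr::count(.data[[a]], .data[[b]], name = "count") |>
      dplyr::mutate(freq = .data$count / sum(.data$count))
  }
  list(family = dplyr::bind_rows(one("v", "V"), one("d", "D"), one("j", "J")),
       vd_pairs = pair("v", "d"), dj_pairs = pair("d", "j"))
}

#' V-framework versus CDR3 mutation loads
#'
#' Per sequence, the mismatch counts against the cluster germline split
#' into the V framework (5' of the CDR3) and the CDR3, plus their Pearson
#' correlation across sequences (flagged `NA` when degenerate, e.g. an
#' all-germline repertoire).
#'
#' @param clusters A `clone_clusters` object.
#' @returns List with `per_sequence` (read_id, vframe_mutations,
#'   cdr3_mutations) and `correlation` (possibly `NA`).
#' @export
vframe_vs_cdr3 <- function(clusters) {
  ann <- clusters$annotations
  per <- tibble(read_id = ann$read_id,
                vframe_mutations = ann$shm_vframe,
                cdr3_mutations = ann$shm_cdr3)
  ok <- stats::complete.cases(per$vframe_mutations, per$cdr3_mutations)
  corr <- NA_real_
  if (sum(ok) >= 3L && stats::sd(per$vframe_mutations[ok]) > 0 &&
      stats::sd(per$cdr3_mutations[ok]) > 0) {
    corr <- stats::cor(per$vframe_mutations[ok], per$cdr3_mutations[ok])
  }
  list(per_sequence = per, correlation = corr)
}
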