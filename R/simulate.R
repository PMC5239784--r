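#' Simulator configuration
#'
#' Defaults follow the benchmark design: 1,000 unmutated recombination
#' events ("germlines"), each seeding a 5-generation chain in which every
#' generation mutates 5 nt at never-before-mutated positions of the
#' lineage, reads of 125 nt ending on the 118Trp codon, uniform 0-5 nt
#' exonuclease deletions per gene end, uniform 0-8 nt N-region lengths
#' with TDT-biased composition, and a substitution matrix qualitatively
#' matching AID/strand-bias observations (C->T and G->A dominant; A
#' mutations more frequent than T mutations, with A->G > A->T > A->C).
#'
#' @param n_germline Number of germline recombination events.
#' @param n_rounds Generations of hypermutation per germline.
#' @param mutations_per_descendant New mutations per generation.
#' @param read_length Output read length (nt).
#' @param del_max Maximum deletion per gene end (3'V, 5'D, 3'D, 5'J).
#' @param n_max Maximum N-region length.
#' @param substitution Named 4x4 row-stochastic matrix (rows = parent nt,
#'   zero diagonal).
#' @param tdt A [tdt_model()] controlling N-region composition.
#' @returns A `sim_config` list.
#' @export
sim_config <- function(n_germline = 1000L, n_rounds = 5L,
                       mutations_per_descendant = 5L, read_length = 125L,
                       del_max = 5L, n_max = 8L,
                       substitution = default_substitution(),
                       tdt = tdt_model()) {
  stopifnot(n_germline >= 1L, n_rounds >= 0L, read_length >= 50L,
            all(abs(rowSums(substitution) - 1) < 1e-8),
            all(diag(substitution) == 0))
  structure(list(n_germline = as.integer(n_germline),
                 n_rounds = as.integer(n_rounds),
                 mutations_per_descendant = as.integer(mutations_per_descendant),
                 read_length = as.integer(read_length),
                 del_max = as.integer(del_max), n_max = as.integer(n_max),
                 substitution = substitution, tdt = tdt),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_substitution <- function() {
  nts <- c("A", "C", "G", "T")
  m <- matrix(0, 4, 4, dimnames = list(nts, nts))
  m["A", c("C", "G", "T")] <- c(0.2, 0.5, 0.3)
  m["C", c("A", "G", "T")] <- c(0.2, 0.2, 0.6)
  m["G", c("A", "C", "T")] <- c(0.6, 0.2, 0.2)
  m["T", c("A", "C", "G")] <- c(0.25, 0.25, 0.5)
  m
}

#' Synthesize a TDT-biased N region
#'
#' Draws nts i.i.d. from the TDT insertion probabilities; with probability
#' `flip_prob` the element-wise complement is emitted instead, modelling
#' TDT elongating either the coding or the non-coding strand.
#'
#' @param length Region length (>= 0).
#' @param model A [tdt_model()].
#' @param flip_prob Probability of emitting the complement strand.
#' @returns An nt string (empty for `length = 0`).
#' @export
synthesize_n_region <- function(length, model = tdt_model(),
                                flip_prob = 0.5) {
  if (length == 0L) return("")
  s <- paste(sample(names(model$p_insert), length, replace = TRUE,
                    prob = model$p_insert), collapse = "")
  if (stats::runif(1) < flip_prob) s <- complement_nt(s) else s
}

#' Sample one productive recombination event
#'
#' Uniformly samples V, D, and J genes (gene usage is deliberately not
#' modelled: uniform sampling exercises more VDJ combinations), applies
#' uniform end deletions, synthesizes both N regions, assembles the
#' sequence, and trims it 5' to `read_length` nt keeping the 118Trp codon
#' as the final 3 nt. Non-productive junctions (anchors out of frame or a
#' stop codon across the junction) are rejected and resampled.
#'
#' @param db Germline database with anchors (non-inverted genes are used).
#' @param config A [sim_config()].
#' @param max_tries Resampling budget before erroring (default 1000).
#' @returns One-row truth tibble (generation 0).
#' @export
sample_recombination_event <- function(db, config = sim_config(),
                                       max_tries = 1000L) {
  vs <- db[db$segment_class == "V" & !is.na(db$anchor_pos), , drop = FALSE]
  ds <- db[db$segment_class == "D" & !db$is_inverted, , drop = FALSE]
  js <- db[db$segment_class == "J" & !is.na(db$anchor_pos), , drop = FALSE]
  if (nrow(vs) == 0L || nrow(ds) == 0L || nrow(js) == 0L) {
    abort("database lacks usable V, D, or J genes with anchors")
  }
  for (try in seq_len(max_tries)) {
    v <- vs[sample.int(nrow(vs), 1L), ]
    d <- ds[sample.int(nrow(ds), 1L), ]
    j <- js[sample.int(nrow(js), 1L), ]
    del <- sample.int(config$del_max + 1L, 4L, replace = TRUE) - 1L
    v_seq <- substr(v$sequence, 1L, nchar(v$sequence) - del[1])
    if (v$anchor_pos + 2L > nchar(v_seq)) next # Cys clipped
    d_len <- nchar(d$sequence) - del[2] - del[3]
    if (d_len < 1L) next
    d_seq <- substr(d$sequence, del[2] + 1L, del[2] + d_len)
    j_trp <- j$anchor_pos
    if (del[4] + 1L > j_trp) next # Trp clipped by 5' deletion
    j_seq <- substr(j$sequence, del[4] + 1L, j_trp + 2L)
    n_vd <- synthesize_n_region(sample.int(config$n_max + 1L, 1L) - 1L,
                                config$tdt)
    n_dj <- synthesize_n_region(sample.int(config$n_max + 1L, 1L) - 1L,
                                config$tdt)
    full <- paste0(v_seq, n_vd, d_seq, n_dj, j_seq)
    if (nchar(full) < config$read_length) next
    trim <- nchar(full) - config$read_length
    read <- substr(full, trim + 1L, nchar(full))
    # boundaries in read coordinates
    v_end <- nchar(v_seq) - trim
    if (v_end < 20L) next # keep a matchable V segment
    d_start <- v_end + nchar(n_vd) + 1L
    d_end <- d_start + nchar(d_seq) - 1L
    j_start <- d_end + nchar(n_dj) + 1L
    cys <- v$anchor_pos - trim
    trp <- j_start + (j_trp - del[4] - 1L)
    if (cys < 1L || (trp - cys) %% 3L != 0L) next
    starts <- seq.int(cys, trp, by = 3L)
    if (any(substring(read, starts, starts + 2L) %in% STOP_CODONS)) next
    return(tibble(
      sequence = read, v_name = v$name, d_name = d$name, j_name = j$name,
      v_end = v_end, d_start = d_start, d_end = d_end, j_start = j_start,
      n_vd = n_vd, n_dj = n_dj, cdr3_start = cys, cdr3_end = trp + 2L
    ))
  }
  abort("could not generate a productive junction; fixture database inadequate")
}

#' Apply one round of somatic hypermutation
#'
#' Mutates `mutations_per_descendant` positions chosen uniformly among the
#' positions never mutated before anywhere in the lineage, substituting
#' per the configured conditional matrix.
#'
#' @param sequence Parent sequence.
#' @param used_positions Positions already mutated in the lineage.
#' @param config A [sim_config()].
#' @returns List with `sequence`, `positions`, and `substitutions`
#'   (`"pos:from>to"` strings).
#' @export
apply_shm_round <- function(sequence, used_positions, config = sim_config()) {
  fresh <- setdiff(seq_len(nchar(sequence)), used_positions)
  k <- config$mutations_per_descendant
  if (length(fresh) < k) {
    abort("not enough never-mutated positions left in the lineage")
  }
  pos <- sort(sample(fresh, k))
  ch <- seq_chars(sequence)
  subs <- character(k)
  for (i in seq_along(pos)) {
    from <- ch[pos[i]]
    to <- sample(colnames(config$substitution), 1L,
                 prob = config$substitution[from, ])
    ch[pos[i]] <- to
    subs[i] <- paste0(pos[i], ":", from, ">", to)
  }
  list(sequence = paste(ch, collapse = ""), positions = pos,
       substitutions = subs)
}

#' Simulate a truth-annotated BCR repertoire
#'
#' Generates `n_germline` productive recombination events and, for each, a
#' chain of `n_rounds` descendants (each generation mutating the previous
#' one at fresh positions), for `n_germline * (1 + n_rounds)` sequences at
#' defaults. All randomness comes from R's RNG: call `set.seed()` first
#' for reproducibility.
#'
#' @param db Germline database with anchors.
#' @param config A [sim_config()].
#' @returns Truth tibble: `id`, `germline_id`, `generation` (0 =
#'   germline), `parent_id`, `sequence`, gene names, boundaries, N
#'   regions, CDR3 interval, and `mutated_positions` (`"pos:from>to"`,
#'   semicolon-separated, cumulative within the row's own round).
#' @export
simulate_repertoire <- function(db, config = sim_config()) {
  out <- vector("list", config$n_germline * (config$n_rounds + 1L))
  k <- 0L
  for (g in seq_len(config$n_germline)) {
    ev <- sample_recombination_event(db, config)
    gid <- sprintf("G%04d", g)
    ev$id <- gid
    ev$germline_id <- gid
    ev$generation <- 0L
    ev$parent_id <- NA_character_
    ev$mutated_positions <- ""
    k <- k + 1L
    out[[k]] <- ev
    parent <- ev
    used <- integer(0)
    for (r in seq_len(config$n_rounds)) {
      mut <- apply_shm_round(parent$sequence, used, config)
      used <- c(used, mut$positions)
      child <- parent
      child$sequence <- mut$sequence
      child$id <- sprintf("%s.%d", gid, r)
      child$generation <- r
      child$parent_id <- parent$id
      child$mutated_positions <- paste(mut$substitutions, collapse = ";")
      k <- k + 1L
      out[[k]] <- child
      parent <- child
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::relocate("id", "germline_id", "generation", "parent_id")
}

#' Write simulator output as FASTA plus a truth TSV
#'
#' @param truth Tibble from [simulate_repertoire()].
#' @param fasta_path,truth_path Output paths.
#' @returns `truth_path`, invisibly.
#' @export
write_simulated_repertoire <- function(truth, fasta_path, truth_path) {
  writeLines(paste0(">", truth$id, "\n", truth$sequence), fasta_path)
  readr::write_tsv(
    truth[c("id", "generation", "v_name", "d_name", "j_name", "v_end",
            "d_start", "d_end", "j_start", "n_vd", "n_dj",
            "mutated_positions")],
    truth_path)
  invisible(truth_path)
}
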