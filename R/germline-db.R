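#' Germline V/D/J gene databases
#'
#' A germline database is a tibble with one row per allele and columns
#' `name`, `segment_class` (`"V"`, `"D"`, `"J"`), `sequence`, `family`,
#' `family_number`, `strain`, `is_pseudogene`, `is_inverted`, `frame`, and
#' `anchor_pos`. `anchor_pos` is the 1-based start of the conserved 104Cys
#' codon (V genes) or 118Trp codon (J genes); it is `NA` until
#' [find_anchor_positions()] is run, or when no in-frame anchor exists (such
#' genes are kept but unusable for CDR3 calls).
#'
#' @param genes Tibble of gene rows, e.g. the output of
#'   [read_germline_fasta()] for each segment class bound together.
#' @param species Species label stored as an attribute.
#' @returns A `germline_db` tibble.
#' @export
germline_db <- function(genes, species = "mouse") {
  genes <- as_tibble(genes)
  dup <- genes$name[duplicated(genes$name)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate gene names in database: ",
                 paste(unique(dup), collapse = ", ")))
  }
  attr(genes, "species") <- species
  class(genes) <- unique(c("germline_db", class(genes)))
  genes
}

new_gene_rows <- function(name, segment_class, sequence, strain = NA_character_,
                          is_pseudogene = FALSE, is_inverted = FALSE,
                          frame = 1L) {
  fam <- parse_gene_family(name)
  tibble(
    name = name, segment_class = segment_class, sequence = sequence,
    family = fam$family, family_number = fam$family_number,
    strain = strain, is_pseudogene = is_pseudogene,
    is_inverted = is_inverted, frame = as.integer(frame),
    anchor_pos = NA_integer_
  )
}

parse_fasta_header <- function(header) {
  fields <- strsplit(header, "|", fixed = TRUE)[[1]]
  fields <- trimws(fields)
  if (length(fields) >= 2L && grepl("*", fields[2], fixed = TRUE)) {
    # IMGT dialect: accession | allele | species[_strain] | functionality | ...
    name <- fields[2]
    strain <- if (length(fields) >= 3L && grepl("_", fields[3], fixed = TRUE)) {
      sub("^[^_]*_", "", fields[3])
    } else {
      NA_character_
    }
    func <- if (length(fields) >= 4L) fields[4] else NA_character_
  } else {
    # simplified fixture dialect: NAME | STRAIN | FUNCTIONALITY
    name <- fields[1]
    strain <- if (length(fields) >= 2L && nzchar(fields[2])) fields[2] else NA_character_
    func <- if (length(fields) >= 3L && nzchar(fields[3])) fields[3] else NA_character_
  }
  pseudo <- !is.na(func) &&
    (func %in% c("P", "(P)") || grepl("pseudo", func, ignore.case = TRUE))
  list(name = name, strain = strain, is_pseudogene = pseudo)
}

#' Load germline genes from a FASTA file
#'
#' Reads an IMGT-style germline FASTA (description fields separated by `|`;
#' allele name in field 2 by IMGT convention, or a simplified
#' `>NAME|STRAIN|FUNCTIONALITY` dialect). IMGT alignment gaps (`.`) are
#' removed and sequences are uppercased; any residual non-ACGT character is a
#' parse error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @param segment_class One of `"V"`, `"D"`, `"J"`.
#' @returns A tibble of gene rows (see [germline_db()]); anchors unassigned.
#' @export
read_germline_fasta <- function(path, segment_class = c("V", "D", "J")) {
  segment_class <- match.arg(segment_class)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(dss) == 0L) abort(paste0("empty FASTA file: ", path))
  seqs <- unname(toupper(gsub(".", "", as.character(dss), fixed = TRUE)))
  headers <- names(dss)
  rows <- purrr::map2(headers, seqs, function(h, s) {
    info <- parse_fasta_header(h)
    if (!nzchar(s)) {
      abort(paste0("empty sequence for record '", info$name, "'"))
    }
    if (grepl("[^ACGT]", s)) {
      abort(paste0("non-ACGT characters in record '", info$name, "'"))
    }
    new_gene_rows(info$name, segment_class, s, strain = info$strain,
                  is_pseudogene = info$is_pseudogene)
  })
  dplyr::bind_rows(rows)
}

#' Write a germline database to FASTA (simplified dialect)
#'
#' @param db A `germline_db` tibble or compatible gene tibble.
#' @param path Output file path.
#' @returns `path`, invisibly.
#' @export
write_germline_fasta <- function(db, path) {
  strain <- ifelse(is.na(db$strain), "", db$strain)
  func <- ifelse(db$is_pseudogene, "P", "F")
  writeLines(paste0(">", db$name, "|", strain, "|", func, "\n", db$sequence),
             path)
  invisible(path)
}

#' Filter a germline database by mouse strain
#'
#' Genes whose `strain` annotation differs from `strain` are removed;
#' unannotated genes (missing `strain`) are kept by default.
#'
#' @param db A `germline_db` tibble.
#' @param strain Strain label, e.g. `"C57BL/6"`.
#' @param keep_unannotated Keep genes without a strain annotation
#'   (default `TRUE`).
#' @returns The filtered database. Errors if the filter leaves any segment
#'   class (present in the input) empty, since annotation would be impossible.
#' @export
filter_by_strain <- function(db, strain, keep_unannotated = TRUE) {
  stopifnot(is.character(strain), nzchar(strain))
  keep <- db$strain == strain
  keep[is.na(keep)] <- keep_unannotated
  out <- db[keep, , drop = FALSE]
  for (cls in intersect(c("V", "D", "J"), unique(db$segment_class))) {
    if (!any(out$segment_class == cls)) {
      abort(paste0("strain filter '", strain, "' removed every ", cls,
                   " gene; annotation impossible"))
    }
  }
  attr(out, "strain_filter") <- strain
  out
}

#' Add inverted (reverse-complement) D genes
#'
#' For every non-inverted D gene, appends a reverse-complement copy named
#' with an `"r"` prefix (e.g. `rIGHD1-1*01`) and `is_inverted = TRUE`.
#' Idempotent: genes whose inverted counterpart already exists are skipped.
#'
#' @param db A `germline_db` tibble (may contain V/J rows; only D rows are
#'   augmented).
#' @returns The augmented database.
#' @export
add_inverted_d <- function(db) {
  cand <- db[db$segment_class == "D" & !db$is_inverted, , drop = FALSE]
  if (nrow(cand) == 0L) return(db)
  cand <- cand[!paste0("r", cand$name) %in% db$name, , drop = FALSE]
  if (nrow(cand) == 0L) return(db)
  inv <- new_gene_rows(paste0("r", cand$name), "D", revcomp(cand$sequence),
                       strain = cand$strain,
                       is_pseudogene = cand$is_pseudogene,
                       is_inverted = TRUE)
  out <- dplyr::bind_rows(as_tibble(db), inv)
  germline_db(out, species = attr(db, "species") %||% "unknown")
}

#' Locate conserved CDR3 anchor codons in V and J genes
#'
#' V genes: the start of the in-frame Cys codon (`TGT`/`TGC`) nearest the 3'
#' end (the 104Cys). J genes: the start of the first in-frame Trp codon
#' (`TGG`, the 118Trp). The reading frame is taken from the `frame` column
#' (default 1). Genes with no in-frame anchor keep `anchor_pos = NA` and are
#' flagged unusable for CDR3 calls, not dropped.
#'
#' @param db A `germline_db` tibble.
#' @returns The database with `anchor_pos` filled for V and J rows.
#' @export
find_anchor_positions <- function(db) {
  anchor_one <- function(seq, cls, frame) {
    starts <- codon_starts(nchar(seq), frame)
    if (length(starts) == 0L) return(NA_integer_)
    codons <- substring(seq, starts, starts + 2L)
    if (cls == "V") {
      hit <- starts[codons %in% c("TGT", "TGC")]
      if (length(hit) == 0L) NA_integer_ else max(hit)
    } else if (cls == "J") {
      hit <- starts[codons == "TGG"]
      if (length(hit) == 0L) NA_integer_ else min(hit)
    } else {
      NA_integer_
    }
  }
  db$anchor_pos <- as.integer(purrr::pmap_int(
    list(db$sequence, db$segment_class, db$frame),
    function(s, c, f) {
      v <- anchor_one(s, c, f)
      if (is.na(v)) NA_integer_ else as.integer(v)
    }
  ))
  db
}

#' Load a complete germline database from FASTA files
#'
#' Convenience wrapper: reads V/D/J FASTA files, optionally filters by
#' strain and drops pseudogenes, appends inverted D genes, and assigns CDR3
#' anchor positions.
#'
#' @param v_path,d_path,j_path FASTA paths for each segment class.
#' @param species Species label.
#' @param strain Optional strain filter (see [filter_by_strain()]).
#' @param include_inverted_d Append reverse-complement D genes
#'   (default `TRUE`).
#' @param include_pseudogenes Keep pseudogene alleles (default `TRUE`);
#'   pseudogene-only suggestions are dropped downstream and junctions with
#'   stops are flagged non-productive regardless.
#' @param keep_unannotated Passed to [filter_by_strain()].
#' @returns A `germline_db` tibble ready for annotation.
#' @export
load_germline_db <- function(v_path, d_path, j_path, species = "mouse",
                             strain = NULL, include_inverted_d = TRUE,
                             include_pseudogenes = TRUE,
                             keep_unannotated = TRUE) {
  genes <- dplyr::bind_rows(
    read_germline_fasta(v_path, "V"),
    read_germline_fasta(d_path, "D"),
    read_germline_fasta(j_path, "J")
  )
  db <- germline_db(genes, species = species)
  if (!include_pseudogenes) db <- db[!db$is_pseudogene, , drop = FALSE]
  if (!is.null(strain)) db <- filter_by_strain(db, strain, keep_unannotated)
  if (include_inverted_d) db <- add_inverted_d(db)
  find_anchor_positions(db)
}

#' Generate a synthetic germline database fixture
#'
#' Emits a small, deterministic (under `seed`) database that mimics the
#' structure of a mouse heavy-chain locus: V genes of ~300 nt whose 3'-most
#' in-frame Cys codon sits 9 nt before the gene end, short D genes (9-18 nt,
#' the mouse D length range), and J genes of 48 nt carrying one in-frame Trp
#' codon. Genes within a class are pairwise >= 2 nt distinct so that
#' recovery benchmarks are well-posed. Headers use the simplified
#' `>NAME|STRAIN|F` dialect with C57BL/6 strain tags.
#'
#' @param n_v,n_d,n_j Number of genes per class.
#' @param seed Optional integer seed.
#' @param strain Strain tag applied to every gene.
#' @returns A `germline_db` tibble with anchors assigned.
#' @export
simulate_germline_db <- function(n_v = 12, n_d = 12, n_j = 5, seed = NULL,
                                 strain = "C57BL/6") {
  if (!is.null(seed)) set.seed(seed)
  rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
  strip_codon <- function(seq, starts, bad) {
    # replace unwanted in-frame codons so the designed anchor is unique
    for (s in starts) {
      if (substring(seq, s, s + 2L) %in% bad) {
        substr(seq, s, s + 2L) <- "AAA"
      }
    }
    seq
  }
  min_pair_dist <- function(seqs) {
    if (length(seqs) < 2L) return(Inf)
    d <- Inf
    for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
      if (i >= j || nchar(seqs[i]) != nchar(seqs[j])) next
      d <- min(d, sum(seq_chars(seqs[i]) != seq_chars(seqs[j])))
    }
    d
  }
  make_class <- function(n, gen_one) {
    seqs <- character(0)
    while (length(seqs) < n) {
      cand <- gen_one()
      if (min_pair_dist(c(seqs, cand)) >= 2) seqs <- c(seqs, cand)
    }
    seqs
  }

  v_len <- 300L
  v_anchor <- v_len - 11L # 289, in frame 1; 9 nt follow the Cys codon
  v_seqs <- make_class(n_v, function() {
    s <- rand_nt(v_len)
    substr(s, v_anchor, v_anchor + 2L) <- "TGT"
    after <- codon_starts(v_len)[codon_starts(v_len) > v_anchor]
    strip_codon(s, after, c("TGT", "TGC"))
  })
  v_names <- sprintf("IGHV%d-%d*01",
                     rep_len(1:4, n_v),
                     stats::ave(seq_len(n_v), rep_len(1:4, n_v),
                                FUN = seq_along))

  d_seqs <- make_class(n_d, function() rand_nt(sample(9:18, 1)))
  d_names <- sprintf("IGHD%d-%d*01",
                     rep_len(1:4, n_d),
                     stats::ave(seq_len(n_d), rep_len(1:4, n_d),
                                FUN = seq_along))

  j_len <- 48L
  j_anchor <- 22L # in frame 1
  j_seqs <- make_class(n_j, function() {
    s <- rand_nt(j_len)
    substr(s, j_anchor, j_anchor + 2L) <- "TGG"
    other <- setdiff(codon_starts(j_len), j_anchor)
    strip_codon(s, other, "TGG")
  })
  j_names <- sprintf("IGHJ%d*01", seq_len(n_j))

  genes <- dplyr::bind_rows(
    new_gene_rows(v_names, "V", v_seqs, strain = strain),
    new_gene_rows(d_names, "D", d_seqs, strain = strain),
    new_gene_rows(j_names, "J", j_seqs, strain = strain)
  )
  find_anchor_positions(germline_db(genes, species = "mouse"))
}
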