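#' Read BCR sequence records
#'
#' Accepts FASTA, FASTQ (qualities ignored), or delimited tables with
#' columns `id`, `sequence`, and optionally `template_count` (default 1).
#' Sequences are uppercased. Records containing characters outside
#' `ACGTN` are rejected with a warning and reported in the `rejected`
#' attribute (tibble of `id`, `reason`) so callers can carry them into the
#' output table; duplicate ids are an error listing the offenders.
#'
#' @param path Input file.
#' @param format `"fasta"`, `"fastq"`, `"csv"`, or `"tsv"`; guessed from
#'   the extension when `NULL`.
#' @returns Tibble with `id`, `sequence`, `template_count`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fa = , fna = , fasta = "fasta",
                     fq = , fastq = "fastq", csv = "csv",
                     tsv = , txt = "tsv",
                     abort(paste0("cannot guess format from extension: ", ext)))
  }
  if (format %in% c("fasta", "fastq")) {
    ss <- Biostrings::readBStringSet(path, format = format)
    ids <- sub("\\s.*$", "", names(ss))
    recs <- tibble(id = unname(ids), sequence = unname(toupper(as.character(ss))),
                   template_count = 1L)
  } else {
    reader <- if (format == "csv") readr::read_csv else readr::read_tsv
    tab <- reader(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("id", "sequence") %in% names(tab))) {
      abort("tabular input needs `id` and `sequence` columns")
    }
    recs <- tibble(id = as.character(tab$id),
                   sequence = toupper(tab$sequence),
                   template_count = if ("template_count" %in% names(tab))
                     as.integer(tab$template_count) else 1L)
  }
  dup <- unique(recs$id[duplicated(recs$id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sequence ids: ", paste(dup, collapse = ", ")))
  }
  bad <- grepl("[^ACGTN]", recs$sequence) | !nzchar(recs$sequence)
  rejected <- tibble(id = recs$id[bad], reason = "ambiguous_chars")
  if (any(bad)) {
    warn(paste0(sum(bad), " record(s) rejected for non-ACGTN characters: ",
                paste(utils::head(recs$id[bad], 5L), collapse = ", ")))
  }
  out <- recs[!bad, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Flatten clonal clusters to the output annotation table
#'
#' One row per input sequence (failed reads included, with their status),
#' with tied-allele lists collapsed to semicolon-separated strings.
#'
#' @param clusters A `clone_clusters` object.
#' @returns A plain tibble.
#' @export
as_annotation_table <- function(clusters) {
  ann <- clusters$annotations
  collapse <- function(x) vapply(x, paste, character(1), collapse = ";")
  germ <- clusters$germlines
  tibble(
    id = ann$read_id, template_count = ann$template_count,
    cluster_id = ann$cluster_id, parent_id = ann$parent_id,
    distance_to_parent = ann$distance_to_parent,
    n_descendants = ann$n_descendants,
    v_name = ann$v_name, d_name = ann$d_name, j_name = ann$j_name,
    tied_alleles = paste(collapse(ann$v_tied), collapse(ann$d_tied),
                         collapse(ann$j_tied), sep = "|"),
    v_end = ann$v_end, d_start = ann$d_start, d_end = ann$d_end,
    j_start = ann$j_start, n_vd = ann$n_vd, n_dj = ann$n_dj,
    cdr3_nt = ann$cdr3_nt, cdr3_aa = ann$cdr3_aa,
    shm_count_vframe = ann$shm_vframe, shm_count_cdr3 = ann$shm_cdr3,
    germline_seq = if (!is.null(germ))
      germ$germline[match(ann$cluster_id, germ$cluster_id)] else NA_character_,
    sequence = ann$sequence,
    productive = ann$productive, status = ann$status
  )
}

#' Write the annotation table to TSV
#'
#' @param clusters A `clone_clusters` object.
#' @param path Output path.
#' @param extra_rows Optional tibble of `id`/`status` rows (e.g. rejected
#'   inputs) appended so that every input id appears exactly once.
#' @returns `path`, invisibly.
#' @export
write_annotation_table <- function(clusters, path, extra_rows = NULL) {
  tab <- as_annotation_table(clusters)
  if (!is.null(extra_rows) && nrow(extra_rows) > 0L) {
    tab <- dplyr::bind_rows(tab, tibble(id = extra_rows$id,
                                        status = extra_rows$reason))
  }
  readr::write_tsv(tab, path)
  invisible(path)
}

tree_edges <- function(clusters, cluster_id) {
  ann <- clusters$annotations
  sub <- ann[ann$cluster_id == cluster_id, , drop = FALSE]
  if (nrow(sub) == 0L) abort(paste0("no such cluster: ", cluster_id))
  tibble(child_id = sub$read_id, parent_id = sub$parent_id,
         distance = sub$distance_to_parent,
         template_count = sub$template_count, cdr3 = sub$cdr3_nt)
}

newick_node <- function(id, edges) {
  kids <- edges$child_id[!is.na(edges$parent_id) & edges$parent_id == id]
  kids <- sort(kids)
  label <- gsub("[,;:()\\s]", "_", id)
  if (length(kids) == 0L) return(label)
  inner <- vapply(kids, function(k) {
    d <- edges$distance[edges$child_id == k]
    paste0(newick_node(k, edges), ":", format(d, trim = TRUE))
  }, character(1))
  paste0("(", paste(inner, collapse = ","), ")", label)
}

#' Export one lineage tree
#'
#' Newick output uses sequence ids as (internal and tip) labels and SHM
#' distances as branch lengths; a single-member cluster serializes as
#' `"id;"`. Tabular output is a parent-child edge list that reconstructs
#' the tree exactly.
#'
#' @param clusters A `clone_clusters` object.
#' @param cluster_id Cluster to export.
#' @param format `"newick"` or `"tabular"`.
#' @returns A newick string, or a tibble of
#'   `(child_id, parent_id, distance, template_count, cdr3)`.
#' @export
export_tree <- function(clusters, cluster_id,
                        format = c("newick", "tabular")) {
  format <- match.arg(format)
  edges <- tree_edges(clusters, cluster_id)
  if (format == "tabular") return(edges)
  root <- edges$child_id[is.na(edges$parent_id)][1]
  paste0(newick_node(root, edges), ";")
}
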