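#' Run the full annotation pipeline on a read table
#'
#' Segments every read ([annotate_reads()]), builds clonal clusters and
#' lineage trees ([build_lineages()]), and refines D genes and N regions
#' within each cluster ([refine_junctions()]).
#'
#' @param reads Tibble with `id`, `sequence`, optional `template_count`.
#' @param db Germline database with anchors assigned.
#' @param config An [annotate_config()].
#' @param cutoff_fraction SHM distance cutoff fraction (default 0.03).
#' @param params An [shm_params()].
#' @param model A [tdt_model()].
#' @returns A `clone_clusters` object.
#' @export
annotate_repertoire <- function(reads, db, config = annotate_config(),
                                cutoff_fraction = 0.03,
                                params = shm_params(),
                                model = tdt_model()) {
  ann <- annotate_reads(reads, db, config)
  clusters <- build_lineages(ann, db, cutoff_fraction, params)
  refine_junctions(clusters, model)
}

#' @export
print.clone_clusters <- function(x, ...) {
  ann <- x$annotations
  cat("<clone_clusters>\n")
  cat("  sequences: ", nrow(ann), "\n", sep = "")
  cat("  clusters:  ", length(unique(ann$cluster_id)), "\n", sep = "")
  cat("  productive:", sum(ann$productive), "\n")
  cat("  cutoff fraction:", x$cutoff_fraction, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clonal clustering result
#'
#' @param x A `clone_clusters` object.
#' @param ... Unused.
#' @returns The flat annotation table (see [as_annotation_table()]).
#' @method tidy clone_clusters
#' @export
tidy.clone_clusters <- function(x, ...) {
  as_annotation_table(x)
}

#' One-row summary of a clonal clustering result
#'
#' @param x A `clone_clusters` object.
#' @param ... Unused.
#' @returns Tibble with sequence/cluster counts, largest cluster size,
#'   productive fraction, and mean parent-child SHM distance.
#' @method glance clone_clusters
#' @export
glance.clone_clusters <- function(x, ...) {
  ann <- x$annotations
  sizes <- table(ann$cluster_id)
  tibble(
    n_sequences = nrow(ann),
    n_clusters = length(sizes),
    largest_cluster = max(sizes),
    prop_productive = mean(ann$productive),
    mean_edge_distance = mean(ann$distance_to_parent, na.rm = TRUE)
  )
}
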