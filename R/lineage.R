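#' SHM distance parameters
#'
#' The somatic-hypermutation distance resembles a Hamming distance with two
#' adjustments: a maximal run of M consecutive mismatches contributes M^2
#' (separating clonally unrelated sequences with similar genes but
#' different N regions), and each individual mismatch adds a weight that
#' depends on the parent-to-child substitution: the frequently observed
#' C->T, G->A, A->G, and A->T mutations subtract 0.5 each, the less
#' frequent T->C and A->C have no effect, and all rarer mutations add 0.5.
#' The per-mutation weights make the distance asymmetric, which is what
#' lets parent-child direction be inferred.
#'
#' @param favored,neutral Character vectors of `"X>Y"` substitutions.
#' @param favored_weight,neutral_weight,other_weight Per-mutation weights.
#' @returns List with the 4x4 `weight` matrix (rows = parent nt,
#'   cols = child nt, order ACGT).
#' @export
shm_params <- function(favored = c("C>T", "G>A", "A>G", "A>T"),
                       neutral = c("T>C", "A>C"),
                       favored_weight = -0.5, neutral_weight = 0,
                       other_weight = 0.5) {
  nts <- c("A", "C", "G", "T")
  w <- matrix(other_weight, 4, 4, dimnames = list(nts, nts))
  diag(w) <- 0
  for (s in favored) {
    p <- strsplit(s, ">", fixed = TRUE)[[1]]
    w[p[1], p[2]] <- favored_weight
  }
  for (s in neutral) {
    p <- strsplit(s, ">", fixed = TRUE)[[1]]
    w[p[1], p[2]] <- neutral_weight
  }
  structure(list(weight = w), class = "shm_params")
}

#' Asymmetric SHM distance between equal-length sequences
#'
#' @param parent,child Equal-length nt strings over ACGT.
#' @param params An [shm_params()].
#' @returns The distance (a number); asymmetric in general.
#' @examples
#' shm_distance("ACGCTT", "ATTGTT") # 3^2 + (-0.5 + 0.5 + 0.5) = 9.5
#' shm_distance("ATTGTT", "ACGCTT") # 3^2 + ( 0   + 0.5 + 0.5) = 10
#' @export
shm_distance <- function(parent, child, params = shm_params()) {
  parent <- toupper(parent); child <- toupper(child)
  if (nchar(parent) != nchar(child)) {
    abort("parent and child must have equal length (compare only within a CDR3-length group)")
  }
  shm_dist_cpp(parent, child, params$weight)
}

#' Coarse clustering key: CDR3 length and V/J family numbers
#'
#' Adds `v_family_number`, `j_family_number`, `cdr3_length`, and a
#' `group_id` column partitioning the annotations; rows without a CDR3 (or
#' failed reads) get `group_id = NA` and are carried as singleton rejects.
#'
#' @param ann Annotation tibble from [annotate_reads()].
#' @returns The annotated tibble with grouping columns.
#' @export
coarse_group <- function(ann) {
  ann$v_family_number <- parse_gene_family(ann$v_name)$family_number
  ann$j_family_number <- parse_gene_family(ann$j_name)$family_number
  ann$cdr3_length <- ifelse(is.na(ann$cdr3_start), NA_integer_,
                            ann$cdr3_end - ann$cdr3_start + 1L)
  key <- paste(ann$cdr3_length, ann$v_family_number, ann$j_family_number,
               sep = "_")
  key[is.na(ann$cdr3_length) | is.na(ann$v_family_number) |
        is.na(ann$j_family_number)] <- NA
  ann$group_id <- key
  ann
}

# distance-comparison windows, right-anchored at the 118Trp codon end so
# that variable-length members are compared over their common aligned span
group_windows <- function(ann) {
  anchor <- ifelse(is.na(ann$cdr3_end), ann$read_length, ann$cdr3_end)
  left <- min(anchor)
  right <- min(ann$read_length - anchor)
  substr(ann$sequence, anchor - left + 1L, anchor + right)
}

# nearest-neighbour linkage + cycle-root resolution for one coarse group;
# returns parent index (NA = root), distance, and local cluster label
link_group <- function(ann, params, cutoff_fraction) {
  n <- nrow(ann)
  parent <- rep(NA_integer_, n)
  dist_to_parent <- rep(NA_real_, n)
  comp <- seq_len(n)
  if (n == 1L) {
    return(list(parent = parent, distance = dist_to_parent, comp = comp))
  }
  win <- group_windows(ann)
  D <- shm_dist_matrix_cpp(win, params$weight)
  cutoff <- cutoff_fraction * nchar(win[1])
  tc <- ann$template_count %||% rep(1L, n)
  aln_score <- rowSums(cbind(ann$v_score, ann$d_score, ann$j_score),
                       na.rm = TRUE)

  # nearest neighbour of each node under the symmetrized distance;
  # ties: higher template count, then sequence id. Linkage is
  # unconditional within the coarse group (the cutoff governs tree
  # merging, not the initial nearest-distance linkage) — except that a
  # sequence whose nearest neighbour is farther than the larger of the
  # cutoff and `link_slack` SHM-distance units stays its own root, which
  # keeps clonally unrelated singletons that merely share a coarse group
  # from being chained together
  link_slack <- 3 * cutoff
  nn <- integer(n)
  linked <- logical(n)
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), i)
    m <- pmin(D[i, js], D[js, i])
    ord <- order(m, -tc[js], ann$read_id[js])
    nn[i] <- js[ord[1L]]
    linked[i] <- m[ord[1L]] <= max(cutoff, link_slack)
  }

  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(linked)) {
    g <- igraph::add_edges(g, c(rbind(which(linked), nn[linked])))
  }
  comp <- igraph::components(g)$membership

  for (cid in unique(comp)) {
    members <- which(comp == cid)
    if (length(members) == 1L) next
    # the functional graph i -> nn[i] has exactly one cycle per component
    seen <- integer(0)
    cur <- members[1L]
    while (!cur %in% seen) { seen <- c(seen, cur); cur <- nn[cur] }
    cycle <- seen[which(seen == cur):length(seen)]
    tot <- vapply(cycle, function(r) sum(D[r, setdiff(members, r)]),
                  numeric(1))
    ord <- order(tot, -aln_score[cycle], ann$read_id[cycle])
    root <- cycle[ord[1L]]
    # orient edges away from the root by BFS over the undirected linkage
    bfs <- igraph::bfs(g, root = root, mode = "all", unreachable = FALSE,
                       father = TRUE, dist = FALSE)
    f <- as.integer(bfs$father)
    for (m in members) {
      if (m != root && !is.na(f[m])) {
        parent[m] <- f[m]
        dist_to_parent[m] <- D[f[m], m]
      }
    }
  }

  # iterative merging: each root seeks its nearest sequence in another
  # tree; merges (root becomes a child) applied in ascending best-merge
  # distance while the distance stays within the cutoff
  repeat {
    roots <- which(is.na(parent))
    if (length(roots) < 2L) break
    best <- NULL
    for (r in roots) {
      others <- which(comp != comp[r])
      if (length(others) == 0L) next
      d <- D[others, r]
      k <- order(d, ann$read_id[others])[1L]
      if (d[k] <= cutoff &&
          (is.null(best) || d[k] < best$d ||
             (d[k] == best$d && ann$read_id[r] < ann$read_id[best$r]))) {
        best <- list(r = r, s = others[k], d = d[k])
      }
    }
    if (is.null(best)) break
    parent[best$r] <- best$s
    dist_to_parent[best$r] <- best$d
    comp[comp == comp[best$r]] <- comp[best$s]
  }

  list(parent = parent, distance = dist_to_parent, comp = comp)
}

#' Build clonal clusters and lineage trees from annotations
#'
#' Within each coarse group ([coarse_group()]), every sequence links to its
#' nearest neighbour under the asymmetric SHM distance; the cyclic
#' dependencies this creates are resolved by taking as root, per connected
#' component, the cycle member with the smallest total SHM distance to all
#' other members (ties: highest total VDJ alignment score). Small trees are
#' then merged iteratively while a root lies within the SHM distance cutoff
#' (default 3% of the compared length) of a sequence in another tree.
#' Finally the annotations of each cluster are unified to the root's
#' ([unify_annotations()]) and the tree is rerooted if another member lies
#' strictly closer to the predicted germline ([reroot_clusters()]).
#'
#' @param ann Annotation tibble from [annotate_reads()].
#' @param db Germline database used for unification.
#' @param cutoff_fraction SHM distance cutoff as a fraction of the compared
#'   sequence length (default 0.03; 0 disables merging).
#' @param params An [shm_params()].
#' @returns A `clone_clusters` object: list with `annotations` (the input
#'   plus `cluster_id`, `parent_id`, `distance_to_parent`,
#'   `n_descendants`), `germlines` (per-cluster predicted unmutated
#'   sequence), and the parameters used.
#' @export
build_lineages <- function(ann, db, cutoff_fraction = 0.03,
                           params = shm_params()) {
  if (anyDuplicated(ann$read_id)) abort("read ids must be unique")
  ann <- coarse_group(ann)
  ann$cluster_id <- NA_character_
  ann$parent_id <- NA_character_
  ann$distance_to_parent <- NA_real_

  groups <- unique(ann$group_id[!is.na(ann$group_id)])
  for (gid in groups) {
    idx <- which(ann$group_id == gid)
    res <- link_group(ann[idx, , drop = FALSE], params, cutoff_fraction)
    roots <- which(is.na(res$parent))
    # cluster label: id of the member's tree root
    root_of <- integer(length(idx))
    for (i in seq_along(idx)) {
      cur <- i
      while (!is.na(res$parent[cur])) cur <- res$parent[cur]
      root_of[i] <- cur
    }
    ann$cluster_id[idx] <- paste0(gid, ":", ann$read_id[idx][root_of])
    ann$parent_id[idx] <- ifelse(is.na(res$parent), NA_character_,
                                 ann$read_id[idx][res$parent])
    ann$distance_to_parent[idx] <- res$distance
  }
  rejects <- is.na(ann$group_id)
  ann$cluster_id[rejects] <- paste0("reject:", ann$read_id[rejects])

  cl <- new_clone_clusters(ann, db, params, cutoff_fraction)
  original <- cl$annotations
  cl <- unify_annotations(cl)
  # annotations follow the root: after rerooting toward the predicted
  # germline, each new root recovers its own pre-unification annotation
  # and the cluster is re-unified so every member inherits the
  # (least-mutated) root's gene calls; the germline prediction changes
  # with the root, so the cycle runs until the rooting is stable
  for (i in 1:3) {
    parents_before <- cl$annotations$parent_id
    cl <- reroot_clusters(cl)
    if (identical(cl$annotations$parent_id, parents_before)) break
    cl <- restore_root_annotations(cl, original)
    cl <- unify_annotations(cl)
  }
  finalize_clusters(cl)
}

new_clone_clusters <- function(ann, db, params, cutoff_fraction) {
  structure(list(annotations = ann, germlines = NULL, db = db,
                 params = params, cutoff_fraction = cutoff_fraction),
            class = "clone_clusters")
}

unified_columns <- c("v_name", "v_tied", "v_score", "v_offset",
                     "v_read_start", "v_end", "v_mut_fraction", "d_name",
                     "d_tied", "d_score", "d_offset", "d_start", "d_end",
                     "j_name", "j_tied", "j_score", "j_offset", "j_start",
                     "n_vd", "n_dj", "cdr3_start", "cdr3_end", "cdr3_nt",
                     "cdr3_aa")

# give every current root back its own per-read annotation (as produced by
# annotate_reads) so unification propagates the root's calls, not a stale
# previous root's
restore_root_annotations <- function(clusters, original) {
  ann <- clusters$annotations
  for (cid in unique(ann$cluster_id)) {
    idx <- which(ann$cluster_id == cid)
    ri <- cluster_root_index(ann, idx)
    oi <- match(ann$read_id[ri], original$read_id)
    for (col in unified_columns) ann[[col]][ri] <- original[[col]][oi]
  }
  clusters$annotations <- ann
  clusters
}

cluster_root_index <- function(ann, idx) {
  r <- idx[is.na(ann$parent_id[idx])]
  if (length(r) == 0L) idx[1L] else r[1L]
}

# predicted unmutated sequence for a cluster: the root read with germline
# nts substituted over the aligned V, D, and J intervals (N regions keep
# the root's nts)
predict_germline <- function(root_row, db) {
  g <- root_row$sequence
  paste_in <- function(g, gene, offset, rs, re) {
    if (is.na(gene) || is.na(offset) || is.na(rs) || is.na(re)) return(g)
    gseq <- db$sequence[match(gene, db$name)]
    # substitute only over the span the gene actually covers
    rs <- max(rs, offset, 1L)
    re <- min(re, offset + nchar(gseq) - 1L, nchar(g))
    if (re < rs) return(g)
    sub <- substr(gseq, rs - offset + 1L, re - offset + 1L)
    paste0(substr(g, 1L, rs - 1L), sub, substr(g, re + 1L, nchar(g)))
  }
  g <- paste_in(g, root_row$v_name, root_row$v_offset,
                max(root_row$v_read_start, 1L), root_row$v_end)
  g <- paste_in(g, root_row$d_name, root_row$d_offset,
                root_row$d_start, root_row$d_end)
  paste_in(g, root_row$j_name, root_row$j_offset,
           root_row$j_start, root_row$read_length)
}

# mismatch count of each member against the cluster germline over the
# right-anchored common window
germline_mismatch_counts <- function(ann_idx, germline) {
  win <- group_windows(ann_idx)
  anchor_g <- nchar(germline)
  vapply(win, function(s) {
    gs <- substr(germline, anchor_g - nchar(s) + 1L, anchor_g)
    sum(seq_chars(s) != seq_chars(gs))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Unify annotations within each cluster to the root's
#'
#' Every member's V/D/J gene calls, boundary intervals, N-region
#' demarcations, and CDR3 interval are replaced by the root's (shifted by
#' the 3'-anchored length offset when member lengths differ), the
#' per-cluster germline prediction is rebuilt, and per-member mismatch sets
#' are recomputed against the unified germlines. Idempotent.
#'
#' @param clusters A `clone_clusters` object.
#' @returns The updated object with `germlines` filled.
#' @export
unify_annotations <- function(clusters) {
  ann <- clusters$annotations
  db <- clusters$db
  copy_cols <- unified_columns
  shift_cols <- c("v_offset", "v_read_start", "v_end", "d_offset", "d_start",
                  "d_end", "j_offset", "j_start", "cdr3_start", "cdr3_end")
  germ <- list()
  for (cid in unique(ann$cluster_id)) {
    idx <- which(ann$cluster_id == cid)
    ri <- cluster_root_index(ann, idx)
    root <- ann[ri, , drop = FALSE]
    for (i in idx) {
      delta <- ann$read_length[i] - root$read_length
      for (col in copy_cols) ann[[col]][i] <- root[[col]]
      if (delta != 0L) {
        for (col in shift_cols) {
          if (!is.na(ann[[col]][i])) ann[[col]][i] <- ann[[col]][i] + delta
        }
      }
    }
    germ[[cid]] <- predict_germline(ann[ri, , drop = FALSE], db)
  }
  ann <- recompute_mismatches(ann, db)
  clusters$annotations <- ann
  clusters$germlines <- tibble(cluster_id = names(germ),
                               germline = unlist(germ, use.names = FALSE))
  clusters
}

#' Reroot clusters toward the predicted germline
#'
#' A cluster is rerooted only when a non-root member has strictly fewer
#' mismatches to the predicted germline sequence than the current root
#' (raw mismatch count; ties leave the tree unchanged). Edges re-orient
#' away from the new root and parent-child distances are recomputed.
#' Idempotent.
#'
#' @param clusters A `clone_clusters` object (after [unify_annotations()]).
#' @returns The updated object.
#' @export
reroot_clusters <- function(clusters) {
  ann <- clusters$annotations
  for (cid in unique(ann$cluster_id)) {
    idx <- which(ann$cluster_id == cid)
    if (length(idx) < 2L) next
    ri <- cluster_root_index(ann, idx)
    germline <- clusters$germlines$germline[
      match(cid, clusters$germlines$cluster_id)]
    mmc <- germline_mismatch_counts(ann[idx, , drop = FALSE], germline)
    root_pos <- match(ri, idx)
    best <- order(mmc, -(ann$template_count[idx] %||% rep(1L, length(idx))),
                  ann$read_id[idx])[1L]
    if (best == root_pos || mmc[best] >= mmc[root_pos]) next
    # re-orient: BFS from the new root over the undirected tree edges
    edges <- cbind(match(ann$parent_id[idx], ann$read_id[idx]),
                   seq_along(idx))
    edges <- edges[!is.na(edges[, 1L]), , drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    bfs <- igraph::bfs(g, root = best, mode = "all", unreachable = FALSE,
                       father = TRUE)
    f <- as.integer(bfs$father)
    win <- group_windows(ann[idx, , drop = FALSE])
    for (m in seq_along(idx)) {
      i <- idx[m]
      if (m == best || is.na(f[m])) {
        ann$parent_id[i] <- NA_character_
        ann$distance_to_parent[i] <- NA_real_
      } else {
        ann$parent_id[i] <- ann$read_id[idx[f[m]]]
        ann$distance_to_parent[i] <- shm_dist_cpp(win[f[m]], win[m],
                                                  clusters$params$weight)
      }
    }
  }
  clusters$annotations <- ann
  clusters
}

# descendant counts and column ordering
finalize_clusters <- function(clusters) {
  ann <- clusters$annotations
  ann$n_descendants <- 0L
  for (cid in unique(ann$cluster_id)) {
    idx <- which(ann$cluster_id == cid)
    ids <- ann$read_id[idx]
    parents <- ann$parent_id[idx]
    nd <- integer(length(idx))
    for (m in seq_along(idx)) {
      cur <- parents[m]
      while (!is.na(cur)) {
        k <- match(cur, ids)
        nd[k] <- nd[k] + 1L
        cur <- parents[k]
      }
    }
    ann$n_descendants[idx] <- nd
  }
  clusters$annotations <- ann
  clusters
}
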