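#' Voronoi-density cluster analysis of one cell
#'
#' Simplified re-implementation of Voronoi-tessellation cluster
#' detection for single-molecule data (the SR-Tesseler approach): the
#' molecule positions of one cell are tessellated and clipped to the
#' cell polygon, each molecule's local density is its rank-`rank`
#' Voronoi density (the molecule and its Voronoi neighbourhood up to
#' `rank` rings, count over summed tile areas), molecules whose density
#' reaches `density_factor` times the reference density are marked
#' dense, and clusters are connected components of dense molecules
#' under Voronoi-neighbor adjacency. Components smaller than
#' `min_molecules` are discarded, and surviving clusters are then
#' optionally grown (see `grow`) to reclaim their rim.
#'
#' The reference density is, by default, the cell-wide average
#' `n / area(cell polygon)` (`mean_density = "global"`, the SR-Tesseler
#' convention); `"local"` uses the mean of the per-molecule Voronoi
#' densities instead. Exact duplicate positions are deterministically
#' jittered by 0.1 nm and logged. Because the parameters of the original
#' SR-Tesseler analyses are unpublished, this implementation makes no
#' claim of numeric equivalence with SR-Tesseler itself.
#'
#' @param mols Molecule tibble of one cell (`x_nm`, `y_nm`).
#' @param polygon Cell outline tibble (`x_nm`, `y_nm`) used to clip
#'   boundary Voronoi regions.
#' @param density_factor Density threshold relative to the reference
#'   density (default 2).
#' @param min_molecules Minimum molecules per cluster (default 5).
#' @param mean_density `"global"` (default) or `"local"`, see Details.
#' @param rank Voronoi neighbourhood rank of the local density estimate
#'   (0, 1 or 2; default 2).
#' @param grow If `TRUE` (default), detected clusters absorb adjacent
#'   molecules whose bare tile density clears the threshold
#'   (hysteresis) and then one ring of immediate Voronoi neighbours;
#'   see Details.
#' @return List with `clusters` (tibble: `cluster`, `n_molecules`,
#'   `centroid_x_nm`, `centroid_y_nm`, `mean_density`) and `members`
#'   (tibble: `mol`, `cluster`, `density`, `dense`). Zero clusters is a
#'   valid result.
#' @export
cluster_voronoi <- function(mols, polygon, density_factor = 2,
                            min_molecules = 5,
                            mean_density = c("global", "local"),
                            rank = 2L, grow = TRUE) {
  mean_density <- match.arg(mean_density)
  stopifnot(rank %in% 0:2)
  empty <- list(
    clusters = tibble(cluster = integer(), n_molecules = integer(),
                      centroid_x_nm = numeric(), centroid_y_nm = numeric(),
                      mean_density = numeric()),
    members = tibble(mol = integer(), cluster = integer(),
                     density = numeric(), dense = logical()))
  n <- nrow(mols)
  if (n < 3L) {
    warn("cluster_voronoi: fewer than 3 molecules; no clusters")
    return(empty)
  }
  x <- mols$x_nm; y <- mols$y_nm
  # deterministic 0.1 nm jitter for exact duplicates
  dup <- duplicated(cbind(x, y))
  if (any(dup)) {
    inform(paste0("cluster_voronoi: jittering ", sum(dup),
                  " duplicate positions by 0.1 nm"))
    k <- seq_len(sum(dup))
    ang <- 2.39996322972865 * k   # golden angle, deterministic
    x[dup] <- x[dup] + 0.1 * cos(ang)
    y[dup] <- y[dup] + 0.1 * sin(ang)
  }
  if (abs(polygon_signed_area(x, y)) < 1e-9 &&
      max(abs((x - x[1]) * (y[2] - y[1]) - (y - y[1]) * (x[2] - x[1]))) < 1e-9) {
    warn("cluster_voronoi: collinear molecules; no clusters")
    return(empty)
  }

  poly <- list(x = polygon$x_nm, y = polygon$y_nm)
  # window margin scales with the data so the tessellation is
  # scale-equivariant
  rx <- range(c(x, poly$x)); ry <- range(c(y, poly$y))
  mar <- 0.01 * max(diff(rx), diff(ry), 1)
  dd <- tryCatch(deldir::deldir(x, y, rw = c(rx + c(-mar, mar),
                                             ry + c(-mar, mar))),
                 error = function(e) NULL)
  if (is.null(dd)) {
    warn("cluster_voronoi: tessellation failed; no clusters")
    return(empty)
  }
  tiles <- deldir::tile.list(dd)
  area <- vapply(tiles, function(tl) {
    clipped <- polyclip::polyclip(list(x = tl$x, y = tl$y), poly, "intersection")
    if (!length(clipped)) return(NA_real_)
    sum(vapply(clipped, function(p) polygon_area(p$x, p$y), numeric(1)))
  }, numeric(1))
  # molecules whose tile misses the polygon entirely: fall back to the
  # unclipped tile area
  raw_area <- vapply(tiles, function(tl) polygon_area(tl$x, tl$y), numeric(1))
  area[is.na(area) | area <= 0] <- raw_area[is.na(area) | area <= 0]

  # rank-k local density: the molecule and its Voronoi neighbourhood up
  # to `rank` rings, count over summed tile areas. Rank 0 is the bare
  # inverse tile area; higher ranks smooth the heavy tail that complete
  # spatial randomness produces in single-tile densities and keep rim
  # molecules of a genuine cluster (whose own tiles leak into empty
  # space) attached to it.
  nb_edges <- dd$delsgs[, c("ind1", "ind2")]
  nb_list <- vector("list", n)
  for (r in seq_len(nrow(nb_edges))) {
    i1 <- nb_edges$ind1[r]; i2 <- nb_edges$ind2[r]
    nb_list[[i1]] <- c(nb_list[[i1]], i2)
    nb_list[[i2]] <- c(nb_list[[i2]], i1)
  }
  dens <- vapply(seq_len(n), function(i) {
    idx <- i
    ring <- i
    for (k in seq_len(rank)) {
      ring <- setdiff(unique(unlist(nb_list[ring])), idx)
      if (!length(ring)) break
      idx <- c(idx, ring)
    }
    length(idx) / sum(area[idx])
  }, numeric(1))

  ref <- if (mean_density == "global") {
    n / polygon_area(poly$x, poly$y)
  } else {
    mean(1 / area)
  }
  dense <- dens >= density_factor * ref

  members <- tibble(mol = seq_len(n), cluster = NA_integer_,
                    density = dens, dense = dense)
  if (sum(dense) >= min_molecules) {
    keep <- dense[nb_edges$ind1] & dense[nb_edges$ind2]
    edges <- nb_edges[keep, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$ind1), to = as.character(edges$ind2)),
      directed = FALSE,
      vertices = data.frame(name = as.character(which(dense))))
    comp <- igraph::components(g)$membership
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes >= min_molecules])
    cl_ids <- stats::setNames(seq_along(big), big)
    mol_idx <- as.integer(names(comp))
    assigned <- comp %in% big
    members$cluster[mol_idx[assigned]] <-
      as.integer(cl_ids[as.character(comp[assigned])])

    if (grow && any(!is.na(members$cluster))) {
      # Growth: the smoothed detection density deliberately excludes a
      # genuine cluster's rim, whose tiles open into the empty cell body.
      # (a) hysteresis — unassigned molecules whose bare tile density
      # clears the threshold join an adjacent cluster, iteratively;
      # (b) one final ring of immediate Voronoi neighbours is absorbed.
      # Clusters are never merged: a candidate joins the cluster most
      # common among its neighbours. Absent any detected cluster,
      # growth can create none.
      own_dense <- (1 / area) >= density_factor * ref
      absorb <- function(eligible) {
        cand <- which(is.na(members$cluster) & eligible)
        did <- FALSE
        for (i in cand) {
          cl <- members$cluster[nb_list[[i]]]
          cl <- cl[!is.na(cl)]
          if (length(cl)) {
            members$cluster[i] <<- as.integer(names(which.max(table(cl))))
            did <- TRUE
          }
        }
        did
      }
      while (absorb(own_dense)) NULL
      absorb(rep(TRUE, n))
    }
  }

  clusters <- members %>%
    filter(!is.na(.data$cluster)) %>%
    group_by(.data$cluster) %>%
    summarise(n_molecules = n(),
              centroid_x_nm = mean(x[.data$mol]),
              centroid_y_nm = mean(y[.data$mol]),
              mean_density = mean(.data$density), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_molecules)) %>%
    mutate(rank = row_number())
  list(clusters = clusters, members = members)
}

#' Summarise clusters across cells
#'
#' Population view of per-cell cluster results: a contingency table of
#' cell length class (below/above the mean cell length) by number of
#' clusters (1, 2, 3+), plus per-cluster molecule counts with the
#' largest cluster of each multi-cluster cell flagged and the skew ratio
#' (largest / second-largest) reported.
#'
#' @param cell_clusters Tibble with one row per cluster: `cell_id`,
#'   `n_molecules` (cells with zero clusters may be listed with
#'   `n_molecules = NA`).
#' @param cell_lengths Tibble `cell_id`, `length_nm`.
#' @param mean_length_nm Length splitting "younger" from "older" cells;
#'   default the mean of `cell_lengths$length_nm`.
#' @return List with `contingency` (tibble `length_class`, `n_clusters`,
#'   `n_cells`), `per_cluster` (input rows plus `is_largest`), and
#'   `skew` (tibble `cell_id`, `skew_ratio` for cells with >= 2
#'   clusters).
#' @export
cluster_summary <- function(cell_clusters, cell_lengths,
                            mean_length_nm = NULL) {
  mean_length_nm <- mean_length_nm %||% mean(cell_lengths$length_nm)
  per_cluster <- cell_clusters %>%
    filter(!is.na(.data$n_molecules)) %>%
    group_by(.data$cell_id) %>%
    mutate(is_largest = .data$n_molecules == max(.data$n_molecules) &
             n() > 1L) %>%
    ungroup()
  counts <- cell_clusters %>%
    group_by(.data$cell_id) %>%
    summarise(k = sum(!is.na(.data$n_molecules)), .groups = "drop") %>%
    left_join(cell_lengths, by = "cell_id") %>%
    mutate(length_class = if_else(.data$length_nm < mean_length_nm,
                                  "below_mean", "above_mean"),
           n_clusters = case_when(.data$k >= 3 ~ "3+",
                                  TRUE ~ as.character(.data$k)))
  contingency <- counts %>%
    count(.data$length_class, .data$n_clusters, name = "n_cells")
  skew <- per_cluster %>%
    group_by(.data$cell_id) %>%
    filter(n() >= 2L) %>%
    summarise(skew_ratio = {
      srt <- sort(.data$n_molecules, decreasing = TRUE)
      srt[1] / srt[2]
    }, .groups = "drop")
  list(contingency = contingency, per_cluster = per_cluster, skew = skew,
       mean_length_nm = mean_length_nm)
}
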