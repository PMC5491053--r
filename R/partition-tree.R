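#' Binary partition tree on diffusion coordinates
#'
#' Recursive dyadic bipartition of a point set organized by its diffusion
#' geometry. Each node is split by 2-means on the diffusion coordinates; the
#' split falls back to a balanced median split along the first non-trivial
#' eigenvector when 2-means degenerates or would leave a child too small to
#' sustain the remaining levels of refinement, so a feasible request always
#' yields exactly `2^depth` leaves. Splits are seeded from `seed` plus a hash
#' of the node's path, and the child containing the lexicographically smallest
#' member id is always the left child, making trees reproducible.
#'
#' @param g A `diffusion_geometry` (from [diffusion_embed()]).
#' @param depth Number of dyadic levels (leaves = 2^depth).
#' @param seed Integer seed for the 2-means splits.
#' @param strict If `TRUE` (default), a node that cannot be split at a level
#'   requiring a split is an error; if `FALSE`, it becomes an early leaf.
#' @return A `partition_tree` object; nodes carry `id` (path string, root
#'   "r"), `level` (root 0), `members` (ids), and 0 or 2 `children`.
#' @export
build_partition_tree <- function(g, depth, seed = 1L, strict = TRUE) {
  stopifnot(depth >= 1)
  coords <- diffusion_coords(g)
  ids <- g$ids

  split_node <- function(member_idx, level, path) {
    node <- list(id = path, level = level, members = ids[member_idx])
    if (level == depth) {
      node$children <- NULL
      return(node)
    }
    n <- length(member_idx)
    # strict mode reserves enough members per child for full refinement;
    # otherwise children only need to be nonempty (early leaves are allowed)
    need <- if (strict) 2^(depth - level - 1) else 1
    if (n < 2) {
      if (strict) stop("insufficient entities for requested depth ", depth,
                       call. = FALSE)
      node$children <- NULL
      return(node)
    }
    xs <- coords[member_idx, , drop = FALSE]
    assign_left <- NULL
    km <- tryCatch(
      with_seed((seed + str_hash(path)) %% .Machine$integer.max, {
        stats::kmeans(xs, centers = 2, nstart = 5)
      }),
      error = function(e) NULL
    )
    if (!is.null(km)) {
      sizes <- tabulate(km$cluster, 2)
      if (min(sizes) >= max(1, need)) assign_left <- km$cluster == 1
    }
    if (is.null(assign_left)) {
      # balanced fallback: order along first diffusion coordinate, ties by id
      ord <- order(xs[, 1], ids[member_idx])
      half <- floor(n / 2)
      assign_left <- logical(n)
      assign_left[ord[seq_len(half)]] <- TRUE
      if (half < max(1, need) || (n - half) < max(1, need)) {
        if (strict) stop("insufficient entities for requested depth ", depth,
                         call. = FALSE)
        node$children <- NULL
        return(node)
      }
    }
    left_idx <- member_idx[assign_left]
    right_idx <- member_idx[!assign_left]
    # left child holds the lexicographically smallest member id
    if (min(ids[right_idx]) < min(ids[left_idx])) {
      tmp <- left_idx; left_idx <- right_idx; right_idx <- tmp
    }
    node$children <- list(
      split_node(left_idx, level + 1, paste0(path, "0")),
      split_node(right_idx, level + 1, paste0(path, "1"))
    )
    node
  }

  root <- split_node(seq_along(ids), 0L, "r")
  structure(list(root = root, depth = depth, ids = ids),
            class = "partition_tree")
}

# Flatten all nodes of a tree into a list, depth-first.
tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node[c("id", "level", "members")]
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' Leaves of a partition tree
#'
#' @param tree A `partition_tree`.
#' @return A named list mapping leaf id to its member ids, in depth-first
#'   (left-to-right) order.
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (is.null(node$children)) {
      out[[node$id]] <<- node$members
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  out
}

#' Cut a partition tree at a level
#'
#' Nodes at `level` (plus any leaves above it) partition the full point set.
#'
#' @param tree A `partition_tree`.
#' @param level Level to cut at (root = 0).
#' @return Named character vector mapping member id to the id of its node at
#'   the cut.
#' @export
tree_cut <- function(tree, level) {
  out <- character(0)
  walk <- function(node) {
    if (node$level == level || is.null(node$children)) {
      out[node$members] <<- node$id
    } else {
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree$root)
  out[tree$ids]
}

#' @export
print.partition_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  cat(sprintf("<partition_tree> depth %d, %d leaves over %d points\n",
              x$depth, length(lv), length(x$ids)))
  cat("  leaf sizes:", paste(lengths(lv), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a partition tree into a flat membership table
#'
#' @param x A `partition_tree`.
#' @param ... Unused.
#' @return Tibble with columns `id` (member), `leaf_id`, and `path` (the
#'   level-by-level branch string below the root).
#' @export
tidy.partition_tree <- function(x, ...) {
  lv <- tree_leaves(x)
  purrr::imap_dfr(lv, function(members, leaf_id) {
    tibble::tibble(id = members, leaf_id = leaf_id,
                   path = sub("^r", "", leaf_id))
  }) |> dplyr::arrange(.data$id)
}

#' Export a partition tree as nested JSON
#'
#' @param tree A `partition_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  strip <- function(node) {
    out <- list(id = node$id, level = node$level, members = node$members)
    if (!is.null(node$children)) out$children <- lapply(node$children, strip)
    out
  }
  jsonlite::write_json(strip(tree$root), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
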