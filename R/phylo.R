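#' p-distance matrix from an amino-acid alignment
#'
#' Proportion of mismatching residues over pairwise-compared columns;
#' columns where either sequence carries a gap are ignored for that pair
#' (pairwise deletion). A pair with no comparable column is an error.
#'
#' @param alignment Aligned FASTA path, `AAStringSet`, or named character
#'   vector of equal-length sequences.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   labels.
#' @export
p_distance <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L && file.exists(alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  labels <- names(alignment)
  seqs <- as.character(alignment)
  if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(labels)) stop("duplicate sequence labels")
  if (length(unique(nchar(seqs))) != 1L) stop("ragged alignment")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  gap <- m == "-" | m == "."
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      if (!any(comp))
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     labels[i], labels[j]))
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

# internal recursive tree node: leaf = list(label=), internal =
# list(children = list(list(node=, length=), ...)); min_label caches the
# lexicographically smallest descendant tip for deterministic ordering.
nj_leaf <- function(label) list(label = label, min_label = label)
nj_join <- function(parts) {
  # parts: list of list(node=, length=)
  list(children = parts,
       min_label = min(vapply(parts, function(p) p$node$min_label, character(1))))
}

needs_quote <- function(label) grepl("[][ \t():;,']", label)

newick_label <- function(label) {
  if (needs_quote(label))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

newick_node <- function(node) {
  if (!is.null(node$label)) return(newick_label(node$label))
  kids <- node$children
  ord <- order(vapply(kids, function(p) p$node$min_label, character(1)))
  inner <- vapply(kids[ord], function(p) {
    paste0(newick_node(p$node), ":", as.character(signif(p$length, 6)))
  }, character(1))
  paste0("(", paste(inner, collapse = ","), ")")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (R = row sums over active nodes) is
#' joined, limb lengths follow the standard formulas with negative limbs
#' clamped to zero, and ties are broken by the lexicographically smallest
#' label pair so the output is deterministic. The result is an unrooted tree
#' returned with a trifurcating root.
#'
#' @param d Symmetric distance matrix with labelled rows/columns (e.g. from
#'   [p_distance()]), at least 3 taxa.
#' @return An [ape] `"phylo"` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n0 <- nrow(d)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n0))
  if (anyDuplicated(labels)) stop("duplicate labels")
  nodes <- lapply(labels, nj_leaf)
  reps <- labels                       # tie-break representative per node
  D <- d
  while (length(nodes) > 3L) {
    n <- length(nodes)
    R <- rowSums(D)
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * D[i, j] - R[i] - R[j]
        pair <- sort(c(reps[i], reps[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(q = q, i = i, j = j, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- nj_join(list(list(node = nodes[[i]], length = li),
                             list(node = nodes[[j]], length = lj)))
    others <- setdiff(seq_len(n), c(i, j))
    new_d <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D2 <- rbind(cbind(D[others, others, drop = FALSE], new_d),
                c(new_d, 0))
    nodes <- c(nodes[others], list(new_node))
    reps <- c(reps[others], new_node$min_label)
    D <- D2
  }
  # final trifurcation
  x1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  x2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  x3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  root <- nj_join(list(list(node = nodes[[1]], length = x1),
                       list(node = nodes[[2]], length = x2),
                       list(node = nodes[[3]], length = x3)))
  nodes_to_phylo(root)
}

# convert the internal nested representation into an ape "phylo" object
# (preorder edge list, root trifurcation preserved)
nodes_to_phylo <- function(root) {
  tips <- character(0)
  n_internal <- 0L
  collect <- function(node) {
    if (!is.null(node$label)) tips <<- c(tips, node$label)
    else {
      n_internal <<- n_internal + 1L
      for (p in node$children) collect(p$node)
    }
  }
  collect(root)
  n_tip <- length(tips)
  tip_idx <- setNames(seq_len(n_tip), tips)
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  next_internal <- n_tip + 1L
  walk <- function(node, up, len) {
    my <- if (!is.null(node$label)) tip_idx[[node$label]] else {
      id <- next_internal
      next_internal <<- next_internal + 1L
      id
    }
    if (!is.na(up)) {
      parent <<- c(parent, up); child <<- c(child, my); elen <<- c(elen, len)
    }
    if (is.null(node$label))
      for (p in node$children) walk(p$node, my, p$length)
  }
  walk(root, NA_integer_, NA_real_)
  structure(list(edge = cbind(parent, child, deparse.level = 0),
                 edge.length = elen, tip.label = tips, Nnode = n_internal),
            class = "phylo", order = "cladewise")
}

phylo_to_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  build <- function(node) {
    kids_idx <- which(tree$edge[, 1] == node)
    if (length(kids_idx) == 0L) return(nj_leaf(tree$tip.label[node]))
    parts <- lapply(kids_idx, function(e) {
      list(node = build(tree$edge[e, 2]),
           length = if (is.null(tree$edge.length)) 0 else tree$edge.length[e])
    })
    nj_join(parts)
  }
  build(root)
}

#' Serialize a tree as a deterministic Newick string
#'
#' Branch lengths are written with 6 significant digits; at every internal
#' node children are ordered by their lexicographically smallest descendant
#' tip label, so topologically identical trees serialize identically. Labels
#' needing quoting are single-quoted per the Newick convention.
#'
#' @param tree An ape `"phylo"` object.
#' @return Newick string terminated by `";"`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  paste0(newick_node(phylo_to_nodes(tree)), ";")
}
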