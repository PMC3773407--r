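#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion `Q_ij = (N - 2) d_ij - r_i - r_j` is joined, limb lengths are
#' `l_i = d_ij / 2 + (r_i - r_j) / (2 (N - 2))`, and distances to the joined
#' node are `(d_ik + d_jk - d_ij) / 2`. Taxa are ordered lexicographically
#' and ties in Q are broken by the first pair in scan order, so the result is
#' deterministic. Exact on additive matrices (topology and branch lengths).
#'
#' CGCD matrices may contain negative dissimilarities; NJ operates on
#' arbitrary real input and negative estimated branch lengths are kept as
#' computed (use `clamp_negative = TRUE` for the common zero-clamp
#' alternative).
#'
#' @param dm Symmetric numeric matrix with zero diagonal and taxon dimnames
#'   (e.g. a `cgc_dist`).
#' @param clamp_negative Clamp negative branch lengths to zero.
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm, clamp_negative = FALSE) {
  dm <- unclass(dm)
  if (nrow(dm) < 3L) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) abort("distance matrix is not symmetric")
  ord <- order(rownames(dm))
  d <- dm[ord, ord, drop = FALSE]
  # each active node carries a newick fragment
  frag <- vapply(rownames(d), quote_newick_label, "")
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(d) > 3L) {
    nn <- nrow(d)
    r <- rowSums(d)
    q <- (nn - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    q[lower.tri(q)] <- Inf
    best <- which(q == min(q), arr.ind = TRUE)[1, ]
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    if (clamp_negative) {
      li <- max(li, 0); lj <- max(lj, 0)
    }
    new_frag <- paste0("(", frag[i], ":", fmt(li), ",",
                       frag[j], ":", fmt(lj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    rownames(d2) <- colnames(d2) <- c(rownames(d)[keep], "joined")
    d <- d2
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clamp_negative) {
    la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  }
  txt <- paste0("(", frag[1], ":", fmt(la), ",", frag[2], ":", fmt(lb), ",",
                frag[3], ":", fmt(lc), ");")
  tree <- ape::read.tree(text = txt)
  if (!clamp_negative && any(tree$edge.length < 0)) {
    message("neighbor_joining: ", sum(tree$edge.length < 0),
            " negative branch length(s) kept as computed")
  }
  tree
}

# Quote a label for Newick output when it contains structural characters.
quote_newick_label <- function(x) {
  if (grepl("[][ \t(),:;']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else {
    x
  }
}

# Undo Newick label quoting after parsing.
unquote_newick_label <- function(x) {
  quoted <- grepl("^'.*'$", x)
  x[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[quoted]))
  x
}

#' Write a tree in Newick format
#'
#' Labels containing whitespace or Newick structural characters are quoted;
#' branch lengths are written with 6 decimals, so a write/read round trip
#' preserves topology, labels and lengths to that precision.
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  has_len <- !is.null(tree$edge.length)
  node_str <- function(node) {
    if (node <= n_tip) return(quote_newick_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(r) {
      child <- tree$edge[r, 2]
      s <- node_str(child)
      if (has_len) paste0(s, ":", sprintf("%.6f", tree$edge.length[r])) else s
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  writeLines(paste0(node_str(root), ";"), path)
  invisible(path)
}

#' Read a Newick tree
#' @param path File path.
#' @return An `ape::phylo`.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) abort(paste0("malformed Newick in ", path))
  tree$tip.label <- unquote_newick_label(tree$tip.label)
  if (!is.null(tree$node.label)) {
    tree$node.label <- unquote_newick_label(tree$node.label)
  }
  tree
}
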