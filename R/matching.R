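# Internal matching solvers for the ortholog-assignment objective:
#   maximize  sum_{chosen pairs} w_ij
#           - b * (# distinct operon units of genome B touched)
#           - c * (# distinct operon units of genome A touched)
# subject to each gene appearing in at most one chosen pair.
#
# The candidate graph decomposes: two candidate pairs interact only if they
# share a gene or their genes share an operon unit. Components are solved
# independently (operon units never span components), exactly by
# branch-and-bound when small, otherwise by an exact similarity-only
# assignment (Hungarian algorithm) refined with local search over the
# penalty terms.

# Union-find -----------------------------------------------------------------
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

# Component labels for candidate pairs. `cand` has columns gene_a, gene_b,
# op_a, op_b (operon unit ids, singletons already expanded).
match_components <- function(cand) {
  keys <- c(paste0("A\r", cand$gene_a), paste0("B\r", cand$gene_b),
            paste0("OA\r", cand$op_a), paste0("OB\r", cand$op_b))
  ids <- unique(keys)
  lk <- match(keys, ids)
  n <- length(ids)
  parent <- uf_new(n)
  m <- nrow(cand)
  node <- matrix(lk, nrow = m)
  for (r in seq_len(m)) {
    base <- node[r, 1]
    for (cix in 2:4) {
      ra <- uf_find(parent, base)
      rb <- uf_find(parent, node[r, cix])
      if (ra != rb) parent[rb] <- ra
      base <- ra
    }
  }
  roots <- vapply(node[, 1], function(i) uf_find(parent, i), 1L)
  match(roots, unique(roots))
}

# Objective of a chosen subset (logical index into cand).
matching_objective <- function(cand, chosen, b, c) {
  if (!any(chosen)) return(0)
  sum(cand$w[chosen]) -
    b * length(unique(cand$op_b[chosen])) -
    c * length(unique(cand$op_a[chosen]))
}

# Exact branch-and-bound over one component's candidate list. Pairs are
# explored in a fixed order (decreasing weight, then lexicographic ids);
# the bound ignores future penalties, which only overestimates.
solve_exact <- function(cand, b, c) {
  ord <- order(-cand$w, cand$gene_a, cand$gene_b)
  cand <- cand[ord, , drop = FALSE]
  m <- nrow(cand)
  suffix_w <- rev(cumsum(rev(cand$w)))
  best <- list(obj = 0, chosen = rep(FALSE, m))
  state <- new.env(parent = emptyenv())
  state$best <- best
  recurse <- function(i, chosen, used_a, used_b, ops_a, ops_b, obj) {
    if (obj > state$best$obj + 1e-12) {
      state$best <- list(obj = obj, chosen = chosen)
    }
    if (i > m) return(invisible())
    if (obj + suffix_w[i] <= state$best$obj + 1e-12) return(invisible())
    ga <- cand$gene_a[i]; gb <- cand$gene_b[i]
    if (!(ga %in% used_a) && !(gb %in% used_b)) {
      d <- cand$w[i] -
        (if (cand$op_b[i] %in% ops_b) 0 else b) -
        (if (cand$op_a[i] %in% ops_a) 0 else c)
      ch <- chosen; ch[i] <- TRUE
      recurse(i + 1L, ch, c(used_a, ga), c(used_b, gb),
              union(ops_a, cand$op_a[i]), union(ops_b, cand$op_b[i]),
              obj + d)
    }
    recurse(i + 1L, chosen, used_a, used_b, ops_a, ops_b, obj)
  }
  recurse(1L, rep(FALSE, m), character(0), character(0),
          character(0), character(0), 0)
  res <- rep(FALSE, m)
  res[ord] <- state$best$chosen
  res
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths) for
# a square cost matrix, minimizing. Returns for each column the assigned row.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)     # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx] <- cur[upd]
        way[idx + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedc <- which(used)            # 1-based positions = column + 1
      u[p[usedc]] <- u[p[usedc]] + delta
      v[usedc] <- v[usedc] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}

# Maximum-weight bipartite matching on a sparse candidate list via Hungarian
# assignment on the padded dense matrix. Returns logical vector over rows of
# `cand`: pairs in the optimal similarity-only matching.
match_similarity_only <- function(cand) {
  ga <- sort(unique(cand$gene_a))
  gb <- sort(unique(cand$gene_b))
  n <- max(length(ga), length(gb))
  w <- matrix(0, n, n)
  ia <- match(cand$gene_a, ga)
  ib <- match(cand$gene_b, gb)
  for (r in seq_len(nrow(cand))) {
    w[ia[r], ib[r]] <- max(w[ia[r], ib[r]], cand$w[r])
  }
  assign_rows <- hungarian_min(max(w) - w)  # column j -> row
  chosen <- rep(FALSE, nrow(cand))
  for (j in seq_len(n)) {
    i <- assign_rows[j]
    if (i <= length(ga) && j <= length(gb) && w[i, j] > 0) {
      hit <- which(ia == i & ib == j & cand$w == w[i, j])[1]
      chosen[hit] <- TRUE
    }
  }
  chosen
}

# Local search refinement under operon penalties: deterministic passes of
# drop / add / swap moves until no improvement (capped).
refine_matching <- function(cand, chosen, b, c, max_pass = 50L) {
  obj <- matching_objective(cand, chosen, b, c)
  m <- nrow(cand)
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(m)) {
      if (chosen[i]) {
        trial <- chosen; trial[i] <- FALSE
        o <- matching_objective(cand, trial, b, c)
        if (o > obj + 1e-12) {
          chosen <- trial; obj <- o; improved <- TRUE
        }
      } else {
        conflict <- chosen &
          (cand$gene_a == cand$gene_a[i] | cand$gene_b == cand$gene_b[i])
        trial <- chosen
        trial[conflict] <- FALSE
        trial[i] <- TRUE
        o <- matching_objective(cand, trial, b, c)
        if (o > obj + 1e-12) {
          chosen <- trial; obj <- o; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  chosen
}

# Solve the full instance: split into components, exact where small.
solve_matching <- function(cand, b, c, exact_limit = 22L) {
  if (nrow(cand) == 0) return(logical(0))
  comp <- match_components(cand)
  chosen <- rep(FALSE, nrow(cand))
  for (cc in sort(unique(comp))) {
    rows <- which(comp == cc)
    sub <- cand[rows, , drop = FALSE]
    if (length(rows) <= exact_limit) {
      chosen[rows] <- solve_exact(sub, b, c)
    } else {
      base <- match_similarity_only(sub)
      chosen[rows] <- refine_matching(sub, base, b, c)
    }
  }
  chosen
}
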