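#' Parameters of conserved-cluster detection
#'
#' A conserved orthologous gene cluster is a chain of ortholog pairs whose
#' gene indices advance consecutively in both genomes, either in the same
#' direction (forward) or in strictly opposite directions (inverted). A
#' bounded number of insertion/deletion events is tolerated: at most
#' `max_gap_events` times per cluster, one genome's index may jump over up to
#' `max_gap_len` skipped genes while the other remains consecutive. Chains
#' shorter than `min_cluster_size` pairs are discarded.
#'
#' @param max_gap_len Maximum consecutive skipped genes per gap event
#'   (default 2).
#' @param max_gap_events Maximum gap events per cluster (default 1).
#' @param min_cluster_size Minimum pairs per cluster (default 2).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(max_gap_len = 2L, max_gap_events = 1L,
                           min_cluster_size = 2L) {
  stopifnot(max_gap_len >= 0, max_gap_events >= 0, min_cluster_size >= 1)
  structure(list(max_gap_len = as.integer(max_gap_len),
                 max_gap_events = as.integer(max_gap_events),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

# Longest valid chain extension from each start over pairs sorted by A-index.
# Returns reach[s] = largest t such that pairs s..t form one valid cluster.
chain_reach <- function(ai, bi, params) {
  n <- length(ai)
  reach <- integer(n)
  for (s in seq_len(n)) {
    t <- s
    ori <- 0L
    events <- 0L
    while (t < n) {
      da <- ai[t + 1L] - ai[t]
      db <- bi[t + 1L] - bi[t]
      s_db <- sign(db)
      if (ori != 0L && s_db != ori) break
      adb <- abs(db)
      if (da == 1L && adb == 1L) {
        # consecutive step
      } else if (da == 1L && adb >= 2L && adb <= params$max_gap_len + 1L) {
        if (events >= params$max_gap_events) break
        events <- events + 1L
      } else if (adb == 1L && da >= 2L && da <= params$max_gap_len + 1L) {
        if (events >= params$max_gap_events) break
        events <- events + 1L
      } else {
        break
      }
      if (ori == 0L) ori <- s_db
      t <- t + 1L
    }
    reach[s] <- t
  }
  reach
}

#' Detect conserved orthologous gene clusters between two genomes
#'
#' Pairs are ordered by their gene index in genome A and partitioned into
#' chains that maximise the total number of ortholog pairs covered by valid
#' clusters (see [cluster_params()]); pairs that fit no cluster are left
#' uncovered. The partition is computed by dynamic programming with
#' deterministic tie-breaking (the longest admissible cluster ending at each
#' position is preferred), so swapping the roles of the two genomes leaves
#' the covered pair count unchanged.
#'
#' @param map An `ortholog_map` (one-to-one).
#' @param genome_a,genome_b The two genomes the map refers to.
#' @param params A [cluster_params()].
#' @return Tibble with one row per cluster: `cluster`, `orientation`
#'   (`"forward"`/`"inverted"`), `n_pairs`, `gap_events` and a list-column
#'   `pairs` of (`gene_a`, `gene_b`, `a_index`, `b_index`) tibbles.
#' @export
conserved_clusters <- function(map, genome_a, genome_b,
                               params = cluster_params()) {
  empty <- tibble(cluster = integer(0), orientation = character(0),
                  n_pairs = integer(0), gap_events = integer(0),
                  pairs = list())
  if (nrow(map$pairs) == 0) return(empty)
  # canonical orientation: chain over the lexicographically smaller genome,
  # so swapping the roles of the two genomes yields the same clusters
  if (genome_a$id > genome_b$id) {
    sw_pairs <- map$pairs
    sw_pairs$gene_a <- map$pairs$gene_b
    sw_pairs$gene_b <- map$pairs$gene_a
    swapped <- structure(
      list(genome_a = map$genome_b, genome_b = map$genome_a,
           pairs = sw_pairs, objective = map$objective),
      class = "ortholog_map")
    out <- conserved_clusters(swapped, genome_b, genome_a, params)
    out$pairs <- lapply(out$pairs, function(p) {
      tibble(gene_a = p$gene_b, gene_b = p$gene_a,
             a_index = p$b_index, b_index = p$a_index)
    })
    return(out)
  }
  ia <- setNames(genome_a$genes$index, genome_a$genes$gene_id)
  ib <- setNames(genome_b$genes$index, genome_b$genes$gene_id)
  pr <- tibble(gene_a = map$pairs$gene_a, gene_b = map$pairs$gene_b,
               a_index = unname(ia[map$pairs$gene_a]),
               b_index = unname(ib[map$pairs$gene_b]))
  if (anyNA(pr$a_index) || anyNA(pr$b_index)) {
    abort("ortholog map references genes absent from the supplied genomes")
  }
  pr <- arrange(pr, .data$a_index)
  n <- nrow(pr)
  reach <- chain_reach(pr$a_index, pr$b_index, params)
  msz <- params$min_cluster_size
  f <- numeric(n + 1L)           # f[t + 1] = best coverage over pairs 1..t
  for (t in seq_len(n)) {
    best <- f[t]                 # drop pair t
    for (s in seq_len(t)) {
      if (reach[s] >= t && t - s + 1L >= msz) {
        cand <- f[s] + (t - s + 1L)
        if (cand > best) best <- cand
      }
    }
    f[t + 1L] <- best
  }
  # backtrack: prefer taking a cluster, and the longest (smallest s) on ties
  segs <- list()
  t <- n
  while (t > 0L) {
    taken <- FALSE
    for (s in seq_len(t)) {
      if (reach[s] >= t && t - s + 1L >= msz &&
          f[s] + (t - s + 1L) == f[t + 1L]) {
        segs[[length(segs) + 1L]] <- c(s, t)
        t <- s - 1L
        taken <- TRUE
        break
      }
    }
    if (!taken) t <- t - 1L
  }
  segs <- rev(segs)
  if (length(segs) == 0) return(empty)
  bind_rows(lapply(seq_along(segs), function(k) {
    sg <- segs[[k]]
    chunk <- pr[sg[1]:sg[2], , drop = FALSE]
    db <- diff(chunk$b_index)
    da <- diff(chunk$a_index)
    ori <- if (length(db) == 0 || db[1] > 0) "forward" else "inverted"
    events <- if (length(db) == 0) 0L else sum(da > 1L | abs(db) > 1L)
    tibble(cluster = k, orientation = ori,
           n_pairs = nrow(chunk), gap_events = as.integer(events),
           pairs = list(chunk))
  }))
}

#' Total orthologous genes in conserved clusters
#' @param clusters Output of [conserved_clusters()].
#' @return Integer: sum of cluster sizes (pair count).
#' @export
n_cgc <- function(clusters) {
  if (nrow(clusters) == 0) return(0L)
  as.integer(sum(clusters$n_pairs))
}

#' Conserved gene cluster distance
#'
#' `D_cgc = -log10(N_cgc)`: more shared clustered orthologs give a more
#' negative (smaller) distance. `N_cgc = 0` is undefined under the log and is
#' mapped to a configurable sentinel (default +1, one log-decade beyond a
#' single shared gene), ranking such pairs as maximally distant.
#'
#' @param n Number of orthologous genes in conserved clusters.
#' @param sentinel Distance returned when `n = 0`.
#' @return The distance (may be negative).
#' @export
#' @examples
#' cgcd(14)  # -1.1461
cgcd <- function(n, sentinel = 1.0) {
  if (any(n < 0)) abort("negative cluster gene count")
  ifelse(n == 0, sentinel, -log10(n))
}

#' CGCD distance matrix over a panel
#'
#' Runs cluster detection once per unordered genome pair on the (filtered)
#' ortholog maps and fills a symmetric matrix of CGCD values with zero
#' diagonal. With `use_clusters = FALSE` the distance degenerates to
#' `-log10` of the raw ortholog-pair count (every ortholog its own cluster),
#' which is the stage-1-only ablation arm.
#'
#' @param panel Named list of [annotated_genome()]s.
#' @param maps `ortholog_map`s for all unordered pairs.
#' @param params A [cluster_params()].
#' @param sentinel Distance for pairs with no clustered orthologs.
#' @param use_clusters Apply cluster detection (default TRUE).
#' @return A `cgc_dist` matrix (symmetric, zero diagonal, ids as dimnames).
#' @export
distance_matrix <- function(panel, maps, params = cluster_params(),
                            sentinel = 1.0, use_clusters = TRUE) {
  ids <- sort(vapply(panel, function(g) g$id, ""))
  by_id <- setNames(panel, vapply(panel, function(g) g$id, ""))
  d <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  seen <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  diag(seen) <- TRUE
  for (mp in maps) {
    if (!(mp$genome_a %in% ids) || !(mp$genome_b %in% ids)) next
    nn <- if (use_clusters) {
      n_cgc(conserved_clusters(mp, by_id[[mp$genome_a]], by_id[[mp$genome_b]],
                               params))
    } else {
      nrow(mp$pairs)
    }
    v <- cgcd(nn, sentinel)
    d[mp$genome_a, mp$genome_b] <- v
    d[mp$genome_b, mp$genome_a] <- v
    seen[mp$genome_a, mp$genome_b] <- TRUE
    seen[mp$genome_b, mp$genome_a] <- TRUE
  }
  if (!all(seen)) {
    miss <- which(!seen, arr.ind = TRUE)[1, ]
    abort(paste0("missing ortholog map for pair ", ids[miss[1]], " vs ",
                 ids[miss[2]]))
  }
  structure(d, class = c("cgc_dist", class(d)))
}

#' @export
print.cgc_dist <- function(x, ...) {
  cat("<cgc_dist> ", nrow(x), " taxa; range [",
      format(min(x[upper.tri(x)]), digits = 5), ", ",
      format(max(x[upper.tri(x)]), digits = 5), "]\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cgc_dist <- function(x, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(taxon_a = ids[ut[, 1]], taxon_b = ids[ut[, 2]],
         distance = x[ut])
}

#' Plot a CGCD distance matrix
#' @param object A `cgc_dist` matrix.
#' @param ... Unused.
#' @return A ggplot heat map of pairwise distances.
#' @exportS3Method ggplot2::autoplot
autoplot.cgc_dist <- function(object, ...) {
  ids <- rownames(object)
  dat <- tidyr::expand_grid(taxon_a = ids, taxon_b = ids)
  dat$distance <- as.numeric(object[cbind(dat$taxon_a, dat$taxon_b)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                    fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "CGCD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write / read a Phylip square distance matrix
#'
#' The classic dialect pads or truncates taxon names to 10 characters;
#' `relaxed = TRUE` writes full names followed by whitespace.
#'
#' @param d A square distance matrix with taxon dimnames.
#' @param path File path.
#' @param relaxed Use relaxed (long-name) format.
#' @return `path` invisibly; `read_phylip()` returns the matrix.
#' @export
write_phylip <- function(d, path, relaxed = FALSE) {
  ids <- rownames(d)
  names_out <- if (relaxed) {
    paste0(ids, "  ")
  } else {
    # classic 10-column name field, plus a separator for 10-char names
    sprintf("%-11s", substr(ids, 1, 10))
  }
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(names_out[i],
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  ids <- vapply(rows, `[`, "", 1)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(ids, ids)
  d
}
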