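#' Weights of the ortholog-assignment objective
#'
#' The assignment maximises summed (scaled) sequence similarity of the chosen
#' ortholog pairs minus operon-parsimony penalties: `b` per distinct operon
#' touched in genome B and `c` per distinct operon touched in genome A, so
#' that orthologs concentrate in as few operons as possible. The defaults
#' (`a = 1`, `b = 0.5`, `c = 0.5`) apply to raw bit-score-like scores
#' (hundreds per gene), so sequence similarity dominates and the operon
#' terms act as structural tie-breakers.
#'
#' @param a Similarity scaling factor.
#' @param b,c Operon penalty factors for genome B and genome A.
#' @param score_scale `"raw"` (default) uses the bit score as-is, so with
#'   the default weights the operon terms are tie-breakers, as in the tool
#'   this objective descends from; `"normalized"` divides each hit's score
#'   by the maximum score among the genome pair's candidates, which makes
#'   the penalties comparable to whole genes (useful for studying the
#'   operon terms in isolation).
#' @return An `ortho_weights` list.
#' @export
ortho_weights <- function(a = 1.0, b = 0.5, c = 0.5,
                          score_scale = c("raw", "normalized")) {
  stopifnot(a > 0, b >= 0, c >= 0)
  structure(list(a = a, b = b, c = c,
                 score_scale = match.arg(score_scale)),
            class = "ortho_weights")
}

#' Read tabular similarity hits
#'
#' Reads the common tabular alignment dialect (columns `qseqid`, `sseqid`,
#' `bitscore`, `evalue`, `pident`; a header line is detected and skipped).
#' The candidate E-value filter (`evalue <= 1e-3`) is applied at read time and
#' only the best-scoring hit per ordered gene pair is kept.
#'
#' @param path TSV path.
#' @param max_evalue E-value cutoff applied at read time.
#' @return Tibble with columns `gene_a`, `gene_b`, `score`, `evalue`,
#'   `identity`.
#' @export
read_similarity <- function(path, max_evalue = 1e-3) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L && grepl("qseqid", first, fixed = TRUE)
  tab <- readr::read_tsv(
    path, skip = if (has_header) 1L else 0L,
    col_names = c("gene_a", "gene_b", "score", "evalue", "identity"),
    col_types = "ccddd")
  tab |>
    filter(.data$evalue <= max_evalue) |>
    group_by(.data$gene_a, .data$gene_b) |>
    arrange(dplyr::desc(.data$score)) |>
    dplyr::slice(1) |>
    ungroup() |>
    arrange(.data$gene_a, .data$gene_b)
}

#' Write similarity hits
#' @param hits Tibble as returned by [read_similarity()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(hits, path) {
  readr::write_tsv(
    select(hits, qseqid = "gene_a", sseqid = "gene_b", bitscore = "score",
           evalue = "evalue", pident = "identity"),
    path)
  invisible(path)
}

#' Filter similarity hits to candidate ortholog pairs
#'
#' Keeps hits with `evalue <= 1e-3` and `identity > 30`, then drops hits whose
#' two genes carry COG functional categories that are both annotated and
#' unequal; genes lacking COG annotation pass the COG filter. Hits referencing
#' genes absent from either genome are an error.
#'
#' @param hits Tibble of hits (`gene_a`, `gene_b`, `score`, `evalue`,
#'   `identity`).
#' @param genome_a,genome_b The two [annotated_genome()]s (`gene_a` ids belong
#'   to `genome_a`).
#' @param max_evalue,min_identity Thresholds; set `min_identity = 0` to
#'   disable the identity filter.
#' @param cog_filter Apply the COG-compatibility filter (default TRUE).
#' @return The filtered hit tibble (possibly empty).
#' @export
candidate_hits <- function(hits, genome_a, genome_b, max_evalue = 1e-3,
                           min_identity = 30, cog_filter = TRUE) {
  hits <- as_tibble(hits)
  unknown_a <- setdiff(hits$gene_a, genome_a$genes$gene_id)
  unknown_b <- setdiff(hits$gene_b, genome_b$genes$gene_id)
  if (length(unknown_a) > 0 || length(unknown_b) > 0) {
    abort(paste0("similarity hits reference unknown gene: ",
                 c(unknown_a, unknown_b)[1]))
  }
  hits <- filter(hits, .data$evalue <= max_evalue,
                 .data$identity > min_identity)
  if (cog_filter && nrow(hits) > 0) {
    cog_a <- setNames(genome_a$genes$cog, genome_a$genes$gene_id)
    cog_b <- setNames(genome_b$genes$cog, genome_b$genes$gene_id)
    ca <- unname(cog_a[hits$gene_a])
    cb <- unname(cog_b[hits$gene_b])
    hits <- hits[is.na(ca) | is.na(cb) | ca == cb, , drop = FALSE]
  }
  arrange(hits, .data$gene_a, .data$gene_b)
}

# Candidate table augmented with solver weights and operon units. Genes not
# declared in any operon count as singleton operon units, so every gene has
# exactly one unit.
prepare_candidates <- function(cand, genome_a, genome_b, weights) {
  op_a <- setNames(genome_a$genes$operon_id, genome_a$genes$gene_id)
  op_b <- setNames(genome_b$genes$operon_id, genome_b$genes$gene_id)
  unit <- function(ops, ids) {
    u <- unname(ops[ids])
    ifelse(is.na(u), paste0("__singleton__", ids), u)
  }
  cand$op_a <- unit(op_a, cand$gene_a)
  cand$op_b <- unit(op_b, cand$gene_b)
  norm <- if (weights$score_scale == "normalized" && nrow(cand) > 0) {
    cand$score / max(cand$score)
  } else {
    cand$score
  }
  cand$norm_score <- norm
  cand$w <- weights$a * norm
  cand
}

new_ortholog_map <- function(genome_a, genome_b, pairs, objective) {
  structure(
    list(genome_a = genome_a$id, genome_b = genome_b$id,
         pairs = pairs, objective = objective),
    class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("<ortholog_map> ", x$genome_a, " vs ", x$genome_b, ": ",
      nrow(x$pairs), " pairs, objective ", format(x$objective, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ortholog_map <- function(x, ...) {
  mutate(x$pairs, genome_a = x$genome_a, genome_b = x$genome_b,
         .before = 1)
}

#' @exportS3Method generics::glance
glance.ortholog_map <- function(x, ...) {
  tibble(genome_a = x$genome_a, genome_b = x$genome_b,
         n_pairs = nrow(x$pairs), objective = x$objective)
}

#' Assign one-to-one orthologs between two genomes
#'
#' Finds the one-to-one gene matching maximising
#' `sum(a * scaled_score) - b * (# operons touched in B) - c * (# operons
#' touched in A)` over the candidate hits. The candidate graph splits into
#' independent components (pairs interact only through shared genes or shared
#' operons); small components are solved exactly by branch-and-bound, larger
#' ones by exact maximum-weight bipartite matching on similarity refined with
#' deterministic local search over the operon penalties.
#'
#' @param candidates Output of [candidate_hits()].
#' @param genome_a,genome_b The two genomes.
#' @param weights An [ortho_weights()].
#' @return An `ortholog_map`: genome ids, a `pairs` tibble (`gene_a`,
#'   `gene_b`, `score`, `evalue`, `identity`, `norm_score`), and the achieved
#'   `objective`.
#' @export
assign_orthologs <- function(candidates, genome_a, genome_b,
                             weights = ortho_weights()) {
  empty <- tibble(gene_a = character(0), gene_b = character(0),
                  score = numeric(0), evalue = numeric(0),
                  identity = numeric(0), norm_score = numeric(0))
  if (nrow(candidates) == 0) {
    return(new_ortholog_map(genome_a, genome_b, empty, 0))
  }
  cand <- prepare_candidates(candidates, genome_a, genome_b, weights)
  chosen <- solve_matching(cand, weights$b, weights$c)
  pairs <- cand[chosen, c("gene_a", "gene_b", "score", "evalue",
                          "identity", "norm_score")]
  pairs <- arrange(as_tibble(pairs), .data$gene_a, .data$gene_b)
  new_ortholog_map(genome_a, genome_b, pairs,
                   matching_objective(cand, chosen, weights$b, weights$c))
}

#' Exhaustive ortholog assignment (test oracle)
#'
#' Enumerates every subset of candidate hits that forms a one-to-one matching
#' and returns the objective-optimal one. Guarded to small instances; used to
#' validate [assign_orthologs()].
#'
#' @inheritParams assign_orthologs
#' @param max_genes Per-genome gene-count guard (default 8).
#' @return An `ortholog_map`.
#' @export
brute_force_orthologs <- function(candidates, genome_a, genome_b,
                                  weights = ortho_weights(), max_genes = 8L) {
  if (n_genes(genome_a) > max_genes || n_genes(genome_b) > max_genes) {
    abort(paste0("instance too large for exhaustive enumeration (> ",
                 max_genes, " genes per genome)"))
  }
  empty <- tibble(gene_a = character(0), gene_b = character(0),
                  score = numeric(0), evalue = numeric(0),
                  identity = numeric(0), norm_score = numeric(0))
  if (nrow(candidates) == 0) {
    return(new_ortholog_map(genome_a, genome_b, empty, 0))
  }
  cand <- prepare_candidates(candidates, genome_a, genome_b, weights)
  m <- nrow(cand)
  best_obj <- 0
  best <- rep(FALSE, m)
  enumerate <- function(i, chosen, used_a, used_b) {
    if (i > m) {
      o <- matching_objective(cand, chosen, weights$b, weights$c)
      if (o > best_obj + 1e-12) {
        best_obj <<- o
        best <<- chosen
      }
      return(invisible())
    }
    enumerate(i + 1L, chosen, used_a, used_b)
    if (!(cand$gene_a[i] %in% used_a) && !(cand$gene_b[i] %in% used_b)) {
      ch <- chosen; ch[i] <- TRUE
      enumerate(i + 1L, ch, c(used_a, cand$gene_a[i]),
                c(used_b, cand$gene_b[i]))
    }
  }
  enumerate(1L, rep(FALSE, m), character(0), character(0))
  pairs <- cand[best, c("gene_a", "gene_b", "score", "evalue",
                        "identity", "norm_score")]
  pairs <- arrange(as_tibble(pairs), .data$gene_a, .data$gene_b)
  new_ortholog_map(genome_a, genome_b, pairs, best_obj)
}

#' Per-gene ortholog occurrence counts over a panel
#'
#' For each gene of each panel genome, the number of other panel genomes in
#' which it has an assigned ortholog. Highly conserved genes (orthologous in
#' the overwhelming majority of species) have counts near `panel size - 1`.
#'
#' @param panel Named list of [annotated_genome()]s.
#' @param maps List of `ortholog_map`s covering every unordered genome pair.
#' @return Tibble with columns `genome_id`, `gene_id`, `n_ortholog`.
#' @export
ortholog_count_table <- function(panel, maps) {
  ids <- vapply(panel, function(g) g$id, "")
  want <- combn(sort(ids), 2)
  have <- vapply(maps, function(m) {
    paste(sort(c(m$genome_a, m$genome_b)), collapse = "\r")
  }, "")
  missing <- setdiff(apply(want, 2, paste, collapse = "\r"), have)
  if (length(missing) > 0) {
    abort(paste0("missing ortholog map for pair: ",
                 gsub("\r", " vs ", missing[1])))
  }
  base <- bind_rows(lapply(panel, function(g) {
    tibble(genome_id = g$id, gene_id = g$genes$gene_id)
  }))
  in_panel <- vapply(maps, function(m) {
    m$genome_a %in% ids && m$genome_b %in% ids
  }, TRUE)
  occ <- bind_rows(lapply(maps[in_panel], function(m) {
    bind_rows(
      tibble(genome_id = m$genome_a, gene_id = m$pairs$gene_a),
      tibble(genome_id = m$genome_b, gene_id = m$pairs$gene_b))
  }))
  counts <- occ |>
    group_by(.data$genome_id, .data$gene_id) |>
    summarise(n_ortholog = dplyr::n(), .groups = "drop")
  base |>
    left_join(counts, by = c("genome_id", "gene_id")) |>
    mutate(n_ortholog = ifelse(is.na(.data$n_ortholog), 0L,
                               as.integer(.data$n_ortholog))) |>
    arrange(.data$genome_id, .data$gene_id)
}

#' Export an ortholog map as TSV
#' @param map An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(map, path) {
  readr::write_tsv(select(map$pairs, "gene_a", "gene_b", "score"), path)
  invisible(path)
}
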