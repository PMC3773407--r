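# Small programmatic fixtures shared across the suite.

# A minimal genome: n adjacent genes of gene_len bp on the + strand.
make_genome <- function(id, n, gene_len = 100, cogs = NULL, operons = NULL,
                        sequence = NULL) {
  genes <- tibble::tibble(
    gene_id = sprintf("%s_g%02d", tolower(id), seq_len(n)),
    start = (seq_len(n) - 1) * gene_len + 1,
    end = seq_len(n) * gene_len,
    strand = "+")
  if (!is.null(cogs)) genes$cog <- cogs
  annotated_genome(id, genes, sequence = sequence, operons = operons)
}

# Perfect self-hit table between two equally sized genomes (gene i <-> gene i).
identity_hits <- function(ga, gb, score = 500) {
  tibble::tibble(gene_a = ga$genes$gene_id, gene_b = gb$genes$gene_id,
                 score = score, evalue = 0, identity = 100)
}

# The 16-gene worked example: two genomes with 14 ortholog pairs laid out as
# one collinear run, one inverted run, and two runs interrupted by an
# insertion (in B) and a deletion (in A).
worked_example <- function() {
  x <- make_genome("X", 16)
  y <- make_genome("Y", 16)
  pairs <- tibble::tibble(
    gene_a = x$genes$gene_id[c(1:13, 16)],
    gene_b = y$genes$gene_id[c(1:4, 7, 6, 5, 8, 9, 12, 13, 14, 15, 16)],
    score = 500, evalue = 0, identity = 100, norm_score = 1)
  map <- structure(
    list(genome_a = "X", genome_b = "Y", pairs = pairs, objective = 14),
    class = "ortholog_map")
  list(x = x, y = y, map = map)
}

# Random ortho instance with operons and COGs for solver/oracle comparisons.
random_instance <- function(seed, max_genes = 6) {
  set.seed(seed)
  mk <- function(id) {
    n <- sample(3:max_genes, 1)
    g <- make_genome(id, n, cogs = sample(c("J", "K", NA), n, replace = TRUE))
    cuts <- sort(sample(seq_len(n), size = max(1, n %/% 2)))
    op <- cumsum(seq_len(n) %in% cuts)
    set_operons(g, tibble::tibble(operon_id = paste0(tolower(id), "_o", op),
                                  gene_id = g$genes$gene_id))
  }
  ga <- mk("A")
  gb <- mk("B")
  nh <- sample(2:10, 1)
  hits <- tibble::tibble(
    gene_a = sample(ga$genes$gene_id, nh, replace = TRUE),
    gene_b = sample(gb$genes$gene_id, nh, replace = TRUE),
    score = round(stats::runif(nh, 10, 100), 1),
    evalue = 1e-9,
    identity = stats::runif(nh, 35, 99))
  hits <- hits[!duplicated(paste(hits$gene_a, hits$gene_b)), ]
  weights <- ortho_weights(b = stats::runif(1, 0, 1),
                           c = stats::runif(1, 0, 1),
                           score_scale = "normalized")
  list(ga = ga, gb = gb,
       cand = candidate_hits(hits, ga, gb), weights = weights)
}

# All-pairs synthetic hits for a generated clade.
clade_hits <- function(clade, spurious_fraction = 0) {
  ids <- sort(names(clade$genomes))
  hits <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        key <- paste(c(ids[i], ids[j]), collapse = "||")
        hits[[key]] <- similarity_hits(clade$genomes[[ids[i]]],
                                       clade$genomes[[ids[j]]],
                                       clade$truth, spurious_fraction)
      }
    }
  }
  hits
}
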