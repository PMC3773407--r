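test_that("the 16-gene worked example yields four clusters covering 14 genes", {
  wx <- worked_example()
  cl <- conserved_clusters(wx$map, wx$x, wx$y)
  expect_equal(nrow(cl), 4)
  expect_equal(n_cgc(cl), 14L)
  expect_setequal(cl$orientation[cl$n_pairs == 2 | cl$cluster == 2],
                  c("inverted"))
  expect_equal(cgcd(n_cgc(cl)), -1.1461, tolerance = 1e-4)
})

test_that("degenerate cluster inputs behave", {
  ga <- make_genome("A", 6)
  gb <- make_genome("B", 6)
  empty_map <- structure(list(genome_a = "A", genome_b = "B",
                              pairs = tibble::tibble(gene_a = character(0),
                                                     gene_b = character(0)),
                              objective = 0), class = "ortholog_map")
  expect_equal(nrow(conserved_clusters(empty_map, ga, gb)), 0)
  expect_equal(n_cgc(conserved_clusters(empty_map, ga, gb)), 0L)

  full <- assign_orthologs(identity_hits(ga, gb), ga, gb)
  cl <- conserved_clusters(full, ga, gb)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$orientation, "forward")
  expect_equal(cl$n_pairs, 6L)
})

test_that("gap tolerance follows the configured limits", {
  ga <- make_genome("A", 12)
  gb <- make_genome("B", 12)
  mk_map <- function(ai, bi) {
    structure(list(genome_a = "A", genome_b = "B",
                   pairs = tibble::tibble(gene_a = ga$genes$gene_id[ai],
                                          gene_b = gb$genes$gene_id[bi]),
                   objective = 0), class = "ortholog_map")
  }
  # one 2-gene gap on B: allowed by default (one event, gap length 2)
  m1 <- mk_map(1:4, c(1, 2, 5, 6))
  expect_equal(n_cgc(conserved_clusters(m1, ga, gb)), 4L)
  # a 3-gene jump exceeds max_gap_len = 2: chain breaks
  m2 <- mk_map(1:4, c(1, 2, 6, 7))
  expect_equal(max(conserved_clusters(m2, ga, gb)$n_pairs), 2L)
  # two gap events in one chain break it under max_gap_events = 1
  m3 <- mk_map(1:6, c(1, 2, 5, 6, 9, 10))
  cl3 <- conserved_clusters(m3, ga, gb)
  expect_equal(max(cl3$n_pairs), 4L)
  # ... but pass when two events are allowed
  cl3b <- conserved_clusters(m3, ga, gb, cluster_params(max_gap_events = 2))
  expect_equal(n_cgc(cl3b), 6L)
})

test_that("cgcd follows the log10 rule with its zero sentinel", {
  expect_equal(cgcd(1), 0)
  expect_equal(cgcd(1000), -3)
  expect_equal(cgcd(14), -log10(14))
  expect_equal(cgcd(0), 1)
  expect_equal(cgcd(0, sentinel = 2.5), 2.5)
  expect_error(cgcd(-1), "negative")
  n <- c(1, 2, 5, 14, 100, 1000)
  expect_true(all(diff(cgcd(n)) < 0))   # strictly decreasing in n
})

test_that("cluster coverage is symmetric under swapping the two genomes", {
  for (seed in 1:12) {
    set.seed(seed)
    n <- 15
    ga <- make_genome("A", n)
    gb <- make_genome("B", n)
    k <- sample(6:12, 1)
    ai <- sort(sample(seq_len(n), k))
    bi <- sample(seq_len(n), k)
    map_ab <- structure(list(genome_a = "A", genome_b = "B",
                             pairs = tibble::tibble(
                               gene_a = ga$genes$gene_id[ai],
                               gene_b = gb$genes$gene_id[bi]),
                             objective = 0), class = "ortholog_map")
    map_ba <- structure(list(genome_a = "B", genome_b = "A",
                             pairs = tibble::tibble(
                               gene_a = gb$genes$gene_id[bi],
                               gene_b = ga$genes$gene_id[ai]),
                             objective = 0), class = "ortholog_map")
    n_ab <- n_cgc(conserved_clusters(map_ab, ga, gb))
    n_ba <- n_cgc(conserved_clusters(map_ba, gb, ga))
    expect_equal(n_ab, n_ba, label = paste("seed", seed))
    expect_lte(n_ab, k)      # never more clustered genes than pairs
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  panel <- list(A = make_genome("A", 8), B = make_genome("B", 8),
                C = make_genome("C", 8))
  maps <- list(
    assign_orthologs(identity_hits(panel$A, panel$B), panel$A, panel$B),
    assign_orthologs(identity_hits(panel$A, panel$C), panel$A, panel$C),
    assign_orthologs(identity_hits(panel$B, panel$C), panel$B, panel$C))
  d <- distance_matrix(panel, maps)
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(unname(d["A", "B"]), -log10(8))
  expect_error(distance_matrix(panel, maps[1:2]), "missing")

  d_raw <- distance_matrix(panel, maps, use_clusters = FALSE)
  expect_equal(unname(d_raw["A", "B"]), -log10(8))
})

test_that("Phylip distance files round-trip in both dialects", {
  d <- matrix(c(0, -1.25, -1.25, 0), 2, 2,
              dimnames = list(c("NC_000916", "NC_007716"),
                              c("NC_000916", "NC_007716")))
  tmp <- withr::local_tempfile(fileext = ".phylip")
  write_phylip(d, tmp)
  back <- read_phylip(tmp)
  expect_equal(unname(back), unname(d), tolerance = 1e-6)
  expect_equal(rownames(back), rownames(d))

  long <- matrix(0, 2, 2, dimnames = list(
    c("averylonggenomename_x", "averylonggenomename_y"),
    c("averylonggenomename_x", "averylonggenomename_y")))
  write_phylip(long, tmp)
  expect_equal(nchar(strsplit(readLines(tmp)[2], " ")[[1]][1]), 10)
  write_phylip(long, tmp, relaxed = TRUE)
  expect_equal(rownames(read_phylip(tmp)), rownames(long))
})
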