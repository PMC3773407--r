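small_params <- function(...) {
  clade_params(n_leaves = 6, n_genes = 60, gene_len_bp = 250, ...)
}

test_that("generation is byte-identical under one seed", {
  a <- generate_clade(small_params(seed = 4, hgt_insert_rate = 2,
                                   loss_rate = 0.1, inversion_rate = 0.3,
                                   indel_rate = 0.3))
  b <- generate_clade(small_params(seed = 4, hgt_insert_rate = 2,
                                   loss_rate = 0.1, inversion_rate = 0.3,
                                   indel_rate = 0.3))
  expect_identical(lapply(a$genomes, function(g) g$sequence),
                   lapply(b$genomes, function(g) g$sequence))
  expect_identical(lapply(a$genomes, function(g) g$genes),
                   lapply(b$genomes, function(g) g$genes))
  c_ <- generate_clade(small_params(seed = 5))
  expect_false(identical(a$genomes[[1]]$sequence, c_$genomes[[1]]$sequence))
})

test_that("with zero event rates all leaves share gene order and orthology", {
  cl <- generate_clade(small_params(seed = 2))
  lin <- lapply(cl$truth$provenance, function(t) t$lineage)
  for (l in lin[-1]) expect_identical(l, lin[[1]])
  ids <- names(cl$genomes)
  tp <- true_pairs(cl$truth, ids[1], ids[2])
  expect_equal(nrow(tp), 60)
  expect_error(true_pairs(cl$truth, ids[1], "not_here"), "not in this clade")
})

test_that("similarity hits reduce to true pairs without spurious additions", {
  cl <- generate_clade(small_params(seed = 3))
  ids <- sort(names(cl$genomes))
  h <- similarity_hits(cl$genomes[[ids[1]]], cl$genomes[[ids[2]]],
                       cl$truth, spurious_fraction = 0)
  tp <- true_pairs(cl$truth, ids[1], ids[2])
  # every emitted hit is a true pair (some true pairs may fall below the
  # emission floor at large divergence)
  expect_true(all(paste(h$gene_a, h$gene_b) %in%
                    paste(tp$gene_a, tp$gene_b)))
  expect_gt(nrow(h), 0)

  # swapping the genomes transposes the very same hit set
  h_rev <- similarity_hits(cl$genomes[[ids[2]]], cl$genomes[[ids[1]]],
                           cl$truth, spurious_fraction = 0)
  expect_setequal(paste(h$gene_a, h$gene_b),
                  paste(h_rev$gene_b, h_rev$gene_a))
  expect_error(similarity_hits(cl$genomes[[ids[1]]],
                               make_genome("Z", 4), cl$truth),
               "unknown truth")
})

test_that("a zero-length branch pair gets identity 100 and E-value 0", {
  tree <- ape::read.tree(text = "((tA:0,tB:0):1,(tC:0.5,tD:0.5):0.5);")
  cl <- generate_clade(clade_params(tree = tree, n_genes = 40,
                                    gene_len_bp = 200, seed = 6))
  h <- similarity_hits(cl$genomes$tA, cl$genomes$tB, cl$truth,
                       spurious_fraction = 0)
  expect_true(all(h$identity == 100))
  expect_true(all(h$evalue == 0))
})

test_that("spurious hit counts follow the configured binomial fraction", {
  cl <- generate_clade(small_params(seed = 9))
  ids <- sort(names(cl$genomes))
  extra <- vapply(1:10, function(i) {
    cl_i <- generate_clade(small_params(seed = 100 + i))
    ids_i <- sort(names(cl_i$genomes))
    h0 <- similarity_hits(cl_i$genomes[[ids_i[1]]], cl_i$genomes[[ids_i[2]]],
                          cl_i$truth, spurious_fraction = 0)
    h2 <- similarity_hits(cl_i$genomes[[ids_i[1]]], cl_i$genomes[[ids_i[2]]],
                          cl_i$truth, spurious_fraction = 0.2)
    nrow(h2) - nrow(h0)
  }, 1)
  # Binomial(n_true, 0.2) spread around 12 for 60 true pairs
  expect_gt(mean(extra), 4)
  expect_lt(mean(extra), 20)
})

test_that("planted foreign segments carry the barcode anomaly", {
  hits_frac <- vapply(1:10, function(i) {
    cl <- generate_clade(clade_params(
      n_leaves = 5, n_genes = 80, gene_len_bp = 500, seed = 300 + i,
      hgt_insert_rate = 3, hgt_leaf_fraction = 0.4,
      foreign_gc_shift = 0.25))
    rec <- names(Filter(length, cl$truth$hgt_genes))[1]
    g <- cl$genomes[[rec]]
    prof <- anomaly_profile(compute_barcode(g, L = 1000))
    flagged <- eliminate_barcode_genes(g, prof, "sss", frac = 0.2)$gene_id
    foreign <- cl$truth$hgt_genes[[rec]]
    precision <- mean(flagged %in% foreign)
    baseline <- length(foreign) / n_genes(g)
    c(precision / baseline)
  }, 1)
  # planted genes are strongly enriched among barcode-flagged genes
  expect_gt(min(hits_frac), 2)
  expect_true(mean(hits_frac) > 3)
})

test_that("clades round-trip through the on-disk bundle and manifest", {
  dir <- withr::local_tempdir()
  cl <- generate_clade(clade_params(n_leaves = 4, n_genes = 30,
                                    gene_len_bp = 200, seed = 12))
  manifest <- write_clade(cl, dir, spurious_fraction = 0)
  loaded <- read_manifest(manifest)
  expect_setequal(names(loaded$genomes), names(cl$genomes))
  gid <- names(cl$genomes)[1]
  expect_equal(loaded$genomes[[gid]]$sequence, cl$genomes[[gid]]$sequence)
  expect_equal(loaded$genomes[[gid]]$genes$gene_id,
               cl$genomes[[gid]]$genes$gene_id)
  expect_equal(loaded$genomes[[gid]]$genes$operon_id,
               cl$genomes[[gid]]$genes$operon_id)
  expect_equal(length(loaded$hits), choose(4, 2))
  tr <- read_newick(file.path(dir, "truth_tree.nwk"))
  expect_setequal(tr$tip.label, names(cl$genomes))
})
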