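test_that("rog evaluates the orthologous-gene ratio with its bounds", {
  expect_equal(rog(100, 100, 100), 1)
  expect_equal(rog(0, 10, 20), 0)
  expect_equal(rog(50, 100, 150), 0.4)
  expect_equal(rog(50, 150, 100), 0.4)          # symmetric
  expect_error(rog(1, 0, 10), "zero-size")
  expect_error(rog(20, 10, 15))                 # n_orth > min(n_g, n_h)
})

test_that("rog matrices assemble from maps and flag missing pairs", {
  panel <- list(A = make_genome("A", 4), B = make_genome("B", 4),
                C = make_genome("C", 4))
  maps <- list(
    assign_orthologs(identity_hits(panel$A, panel$B), panel$A, panel$B),
    assign_orthologs(identity_hits(panel$A, panel$C), panel$A, panel$C),
    assign_orthologs(identity_hits(panel$B, panel$C), panel$B, panel$C))
  rm <- rog_matrix(panel, maps)
  expect_true(isSymmetric(rm))
  expect_equal(unname(rm["A", "B"]), 1)
  expect_equal(mean_rog_set(rm, c("A", "B", "C")), 1)
  expect_error(rog_matrix(panel, maps[1:2]), "missing ortholog map")
})

test_that("calibration is seeded, collapses for constant statistics, and is
           Monte-Carlo consistent", {
  panel <- list(A = make_genome("A", 4), B = make_genome("B", 4),
                C = make_genome("C", 4), D = make_genome("D", 4))
  ids <- names(panel)
  maps <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    maps[[length(maps) + 1]] <- assign_orthologs(
      identity_hits(panel[[ids[i]]], panel[[ids[j]]]),
      panel[[ids[i]]], panel[[ids[j]]])
  }
  cal <- calibrate(panel, maps = maps, statistic = "mean_rog", m = 50,
                   set_size = 3, seed = 9)
  expect_equal(cal$mu, 1)
  expect_equal(cal$sigma, 0)      # identical genomes: statistic is constant
  cal2 <- calibrate(panel, maps = maps, statistic = "mean_rog", m = 50,
                    set_size = 3, seed = 9)
  expect_identical(cal$mu, cal2$mu)

  # std_rge path on a heterogeneous panel: two m values agree within
  # Monte-Carlo error of the subset-statistic mean
  withr::with_seed(42, {
    rge <- stats::setNames(runif(12, 0.5, 0.9), sprintf("g%02d", 1:12))
  })
  big_panel <- lapply(names(rge), function(id) make_genome(id, 2))
  names(big_panel) <- names(rge)
  c1 <- calibrate(big_panel, profiles = rge, statistic = "std_rge",
                  m = 400, set_size = 5, seed = 1)
  c2 <- calibrate(big_panel, profiles = rge, statistic = "std_rge",
                  m = 2000, set_size = 5, seed = 2)
  expect_lt(abs(c1$mu - c2$mu), 3 * c2$sigma / sqrt(400))
  expect_error(calibrate(big_panel, profiles = rge, statistic = "std_rge",
                         m = 100, set_size = 20, seed = 1), "set_size")
})

test_that("three-sigma classification is boundary-inclusive and one-sided
           for the genomic-evolution statistic", {
  cal <- structure(list(mu = 0.5, sigma = 0.01, tail = "two_sided"),
                   class = "calibration")
  expect_equal(classify_set(0.5, cal), "oss")
  expect_equal(classify_set(0.5 + 3 * 0.01, cal), "oss")   # closed interval
  expect_equal(classify_set(0.5 - 3 * 0.01, cal), "oss")
  expect_equal(classify_set(0.5 + 3.0001 * 0.01, cal), "sss")
  expect_equal(classify_set(0.5 - 3.0001 * 0.01, cal), "sss")

  cal_up <- structure(list(mu = 0.04, sigma = 0.002, tail = "upper"),
                      class = "calibration")
  expect_equal(classify_set(0.04, cal_up), "oss")
  expect_equal(classify_set(0.04 + 4 * 0.002, cal_up), "sss")
  expect_equal(classify_set(0.04 - 4 * 0.002, cal_up), "oss")  # lower tail
})

test_that("highly conserved genes are eliminated by the 85% occurrence rule", {
  counts <- tibble::tibble(
    genome_id = "G1",
    gene_id = c("g1", "g2", "g3"),
    n_ortholog = c(9L, 8L, 0L))
  out <- eliminate_conserved(counts, n_as = 10, set_class = "oss")
  expect_equal(out$gene_id, "g1")     # 9 >= 8.5 goes, 8 < 8.5 stays
  expect_equal(out$reason, "conserved")
  expect_equal(nrow(eliminate_conserved(counts, 10, "sss")), 0)
  expect_error(eliminate_conserved(counts, 10, "oss", frac = 1.2),
               "frac")
})

test_that("abnormal-barcode elimination takes exactly the capped gene count,
           walking fragments by anomaly rank", {
  # 20 genes x 500 bp = 10 kb = 10 fragments; genes 5,6 (fragment index 2)
  # sit on a GC-shifted segment
  withr::with_seed(5, {
    host <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                         prob = c(.25, .25, .25, .25)), collapse = "")
  })
  withr::with_seed(6, {
    foreign <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE,
                            prob = c(.1, .4, .4, .1)), collapse = "")
  })
  seq <- paste0(substr(host, 1, 2000), foreign, substr(host, 3001, 10000))
  g <- make_genome("G", 20, gene_len = 500, sequence = seq)
  prof <- anomaly_profile(compute_barcode(g, L = 1000))

  expect_equal(nrow(eliminate_barcode_genes(g, prof, "oss")), 0)
  out <- eliminate_barcode_genes(g, prof, "sss", frac = 0.2)
  expect_equal(nrow(out), 4)                  # floor(0.2 * 20)
  expect_true(all(c("g_g05", "g_g06") %in% out$gene_id))
  # cap is honoured exactly even when the last fragment overshoots
  out2 <- eliminate_barcode_genes(g, prof, "sss", frac = 0.15)
  expect_equal(nrow(out2), 3)
})

test_that("applying eliminations filters pairs and preserves one-to-one
           structure", {
  ga <- make_genome("A", 5)
  gb <- make_genome("B", 5)
  maps <- list(assign_orthologs(identity_hits(ga, gb), ga, gb))

  same <- apply_elimination(maps, tibble::tibble(genome_id = character(0),
                                                 gene_id = character(0)))
  expect_equal(nrow(same[[1]]$pairs), 5)

  gone_all <- apply_elimination(maps, tibble::tibble(
    genome_id = "A", gene_id = ga$genes$gene_id))
  expect_equal(nrow(gone_all[[1]]$pairs), 0)

  gone2 <- apply_elimination(maps, tibble::tibble(
    genome_id = c("A", "B"), gene_id = c("a_g01", "b_g03")))
  p <- gone2[[1]]$pairs
  expect_equal(nrow(p), 3)
  expect_false(any(duplicated(p$gene_a)) || any(duplicated(p$gene_b)))
})

test_that("calibrations round-trip through their key-value file", {
  cal <- structure(list(mu = 0.61234, sigma = 0.00456, m = 1000L,
                        set_size = 10L, seed = 7L, statistic = "mean_rog",
                        tail = "two_sided"),
                   class = "calibration")
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cal, tmp)
  back <- read_calibration(tmp)
  expect_equal(back$mu, cal$mu)
  expect_equal(back$sigma, cal$sigma)
  expect_equal(back$statistic, "mean_rog")
  expect_equal(back$tail, "two_sided")
})
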