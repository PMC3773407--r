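test_that("candidate filter enforces E-value, identity, and COG thresholds", {
  ga <- make_genome("A", 3, cogs = c("J", "J", NA))
  gb <- make_genome("B", 3, cogs = c("J", "K", NA))
  hit <- function(i, j, evalue = 1e-5, identity = 40) {
    tibble::tibble(gene_a = ga$genes$gene_id[i], gene_b = gb$genes$gene_id[j],
                   score = 100, evalue = evalue, identity = identity)
  }
  expect_equal(nrow(candidate_hits(hit(1, 1, evalue = 1e-2), ga, gb)), 0)
  expect_equal(nrow(candidate_hits(hit(1, 1), ga, gb)), 1)       # J vs J
  expect_equal(nrow(candidate_hits(hit(1, 2), ga, gb)), 0)       # J vs K
  expect_equal(nrow(candidate_hits(hit(3, 2), ga, gb)), 1)       # NA passes
  expect_equal(nrow(candidate_hits(hit(1, 1, identity = 30), ga, gb)), 0)
  expect_equal(nrow(candidate_hits(hit(1, 1, identity = 30), ga, gb,
                                   min_identity = 0)), 1)
  expect_equal(nrow(candidate_hits(hit(1, 2), ga, gb, cog_filter = FALSE)), 1)
  expect_error(candidate_hits(
    tibble::tibble(gene_a = "zz", gene_b = gb$genes$gene_id[1], score = 1,
                   evalue = 0, identity = 99), ga, gb), "unknown gene")
})

test_that("similarity TSV IO filters at read time and keeps best per pair", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tbitscore\tevalue\tpident",
               "a1\tb1\t200\t1e-10\t80",
               "a1\tb1\t150\t1e-08\t70",
               "a2\tb2\t90\t0.5\t60"), tmp)
  h <- read_similarity(tmp)
  expect_equal(nrow(h), 1)            # a2 hit fails the E-value filter
  expect_equal(h$score, 200)          # best-scoring duplicate retained

  out <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(h, out)
  expect_equal(read_similarity(out), h)
})

test_that("trivial assignments behave: identity matching and single hits", {
  ga <- make_genome("A", 4)
  gb <- make_genome("B", 4)
  m <- assign_orthologs(identity_hits(ga, gb), ga, gb)
  expect_equal(nrow(m$pairs), 4)
  expect_equal(m$pairs$gene_b, gb$genes$gene_id[match(
    m$pairs$gene_a, ga$genes$gene_id)])

  one <- candidate_hits(tibble::tibble(
    gene_a = ga$genes$gene_id[2], gene_b = gb$genes$gene_id[3],
    score = 50, evalue = 1e-9, identity = 55), ga, gb)
  m1 <- assign_orthologs(one, ga, gb)
  expect_equal(nrow(m1$pairs), 1)

  m0 <- assign_orthologs(one[0, ], ga, gb)
  expect_equal(nrow(m0$pairs), 0)
  expect_equal(m0$objective, 0)
})

test_that("operon parsimony can override raw similarity", {
  # a2 could take the higher-scoring b3 hit, but that opens a second operon
  # in B; with normalized scores and heavy penalties the operon-coherent
  # matching wins, and the solver agrees with exhaustive enumeration
  ga <- set_operons(make_genome("A", 2),
                    tibble::tibble(operon_id = "oa", gene_id = c("a_g01", "a_g02")))
  gb <- set_operons(make_genome("B", 4),
                    tibble::tibble(operon_id = c("ob1", "ob1", "ob2", "ob2"),
                                   gene_id = paste0("b_g0", 1:4)))
  hits <- tibble::tibble(
    gene_a = c("a_g01", "a_g02", "a_g02"),
    gene_b = c("b_g01", "b_g02", "b_g03"),
    score = c(100, 80, 95), evalue = 1e-9, identity = 90)
  w <- ortho_weights(b = 0.4, c = 0.4, score_scale = "normalized")
  cand <- candidate_hits(hits, ga, gb)
  m <- assign_orthologs(cand, ga, gb, w)
  expect_setequal(m$pairs$gene_b, c("b_g01", "b_g02"))
  bf <- brute_force_orthologs(cand, ga, gb, w)
  expect_equal(m$objective, bf$objective)
  # with negligible penalties the higher-scoring hit wins instead
  m2 <- assign_orthologs(cand, ga, gb,
                         ortho_weights(b = 0.01, c = 0.01,
                                       score_scale = "normalized"))
  expect_setequal(m2$pairs$gene_b, c("b_g01", "b_g03"))
})

test_that("solver equals the exhaustive oracle on seeded random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    m <- assign_orthologs(inst$cand, inst$ga, inst$gb, inst$weights)
    bf <- brute_force_orthologs(inst$cand, inst$ga, inst$gb, inst$weights)
    expect_equal(m$objective, bf$objective, tolerance = 1e-9,
                 label = paste("objective, seed", seed))
  }
})

test_that("role swap with equal operon weights yields the same pair set", {
  for (seed in 101:115) {
    inst <- random_instance(seed)
    w <- ortho_weights(b = 0.3, c = 0.3, score_scale = "normalized")
    m_ab <- assign_orthologs(inst$cand, inst$ga, inst$gb, w)
    swapped <- dplyr::select(inst$cand, gene_a = "gene_b", gene_b = "gene_a",
                             "score", "evalue", "identity")
    m_ba <- assign_orthologs(swapped, inst$gb, inst$ga, w)
    expect_setequal(paste(m_ab$pairs$gene_a, m_ab$pairs$gene_b),
                    paste(m_ba$pairs$gene_b, m_ba$pairs$gene_a))
  }
})

test_that("raising the operon penalties never touches more operons", {
  touched <- function(m, inst) {
    ops <- stats::setNames(inst$ga$genes$operon_id, inst$ga$genes$gene_id)
    opb <- stats::setNames(inst$gb$genes$operon_id, inst$gb$genes$gene_id)
    length(unique(ops[m$pairs$gene_a])) + length(unique(opb[m$pairs$gene_b]))
  }
  for (seed in 201:212) {
    inst <- random_instance(seed)
    prev <- Inf
    for (bc in c(0, 0.2, 0.5, 1)) {
      m <- assign_orthologs(inst$cand, inst$ga, inst$gb,
                            ortho_weights(b = bc, c = bc,
                                          score_scale = "normalized"))
      now <- touched(m, inst)
      expect_lte(now, prev)
      prev <- now
    }
  }
})

test_that("ortholog occurrence counts tally panel-wide presence", {
  panel <- list(make_genome("A", 3), make_genome("B", 3), make_genome("C", 3))
  names(panel) <- c("A", "B", "C")
  maps <- list(
    assign_orthologs(identity_hits(panel$A, panel$B), panel$A, panel$B),
    assign_orthologs(identity_hits(panel$A, panel$C), panel$A, panel$C),
    assign_orthologs(identity_hits(panel$B, panel$C), panel$B, panel$C))
  counts <- ortholog_count_table(panel, maps)
  expect_true(all(counts$n_ortholog == 2))

  # a gene with no hits anywhere counts zero
  maps2 <- maps
  maps2[[1]]$pairs <- maps2[[1]]$pairs[-1, ]
  maps2[[2]]$pairs <- maps2[[2]]$pairs[-1, ]
  counts2 <- ortholog_count_table(panel, maps2)
  expect_equal(counts2$n_ortholog[counts2$genome_id == "A" &
                                    counts2$gene_id == "a_g01"], 0L)

  expect_error(ortholog_count_table(panel, maps[1:2]), "missing ortholog map")
})

test_that("large components fall back to Hungarian + refinement correctly", {
  # dense instance forced through the non-exact path must match enumeration
  for (seed in 301:306) {
    inst <- random_instance(seed)
    cand <- inst$cand
    if (nrow(cand) == 0) next
    prep <- cgcphy:::prepare_candidates(cand, inst$ga, inst$gb, inst$weights)
    exact <- cgcphy:::solve_matching(prep, inst$weights$b, inst$weights$c,
                                     exact_limit = 50L)
    heur <- cgcphy:::solve_matching(prep, inst$weights$b, inst$weights$c,
                                    exact_limit = 0L)
    obj_e <- cgcphy:::matching_objective(prep, exact, inst$weights$b,
                                         inst$weights$c)
    obj_h <- cgcphy:::matching_objective(prep, heur, inst$weights$b,
                                         inst$weights$c)
    expect_equal(obj_h, obj_e, tolerance = 1e-9,
                 label = paste("heuristic path, seed", seed))
  }
})
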