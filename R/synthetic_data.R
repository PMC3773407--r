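#' Simulate an ultrametric clade tree
#'
#' Random topology built by successive joins of two uniformly chosen
#' lineages, with the n - 1 join heights geometrically spaced from
#' `depth / 10` up to `depth` (recent joins denser, as in coalescent
#' genealogies). Geometric spacing keeps every pair of adjacent node depths
#' separated by the same ratio, so pairwise divergences stay well apart on
#' the log scale at which similarity thresholds operate — the clean
#' test-bed regime for the pipeline.
#'
#' @param n_leaves Number of leaves (>= 3).
#' @param depth Total tree height (expected-divergence units).
#' @param seed RNG seed.
#' @return An ultrametric `ape::phylo` with tips `t01`, `t02`, ...
#' @export
sim_clade_tree <- function(n_leaves, depth = 1, seed = 1L) {
  stopifnot(n_leaves >= 3)
  labels <- sprintf("t%02d", seq_len(n_leaves))
  with_seed(seed, {
    frag <- labels
    height <- rep(0, n_leaves)
    join_h <- depth * 10^(-(n_leaves - 1L - seq_len(n_leaves - 1L)) /
                            max(n_leaves - 2L, 1L))
    for (k in seq_len(n_leaves - 1L)) {
      pick <- sort(sample.int(length(frag), 2L))
      i <- pick[1]; j <- pick[2]
      h <- join_h[k]
      new_frag <- paste0("(", frag[i], ":", sprintf("%.10f", h - height[i]),
                         ",", frag[j], ":", sprintf("%.10f", h - height[j]),
                         ")")
      frag <- c(frag[-pick], new_frag)
      height <- c(height[-pick], h)
    }
    ape::read.tree(text = paste0(frag, ";"))
  })
}

#' Parameters of the synthetic clade generator
#'
#' The generator evolves an annotated ancestral genome along a known tree.
#' Sequence evolution is modelled at the level of per-gene similarity decay
#' (downstream stages consume similarity hits, not alignments); nucleotide
#' composition matters only to the barcode stage, so chromosome sequence is
#' drawn i.i.d. with per-region GC content. Horizontal transfer is planted by
#' inserting segments from a GC-shifted donor pool shared across recipient
#' lineages, which creates both the compositional anomaly and the spurious
#' cross-clade similarity that the filter stages are meant to remove.
#'
#' @param n_leaves Leaves of the generated tree (used when `tree` is NULL).
#' @param tree Optional `ape::phylo` with branch lengths (divergence units).
#' @param n_genes Ancestral gene count (>= 4).
#' @param mean_operon_len Mean genes per operon (default 3).
#' @param gene_len_bp Gene length in bp (default 500; genes are adjacent, so
#'   the chromosome is `n_genes * gene_len_bp` long).
#' @param loss_rate Per-gene, per-unit-branch-length loss probability rate.
#' @param inversion_rate,indel_rate Per-unit-branch-length segmental event
#'   rates.
#' @param hgt_insert_rate Expected number of foreign-segment insertions per
#'   susceptible lineage (recent transfers on terminal branches).
#' @param hgt_leaf_fraction Fraction of lineages susceptible to horizontal
#'   transfer (default 0.3); concentrating transfer in a subset of genomes
#'   mirrors the heterogeneity that makes a species set "special".
#' @param foreign_gc_shift GC offset of foreign segments in [-0.3, 0.3].
#' @param gc_host Host background GC content.
#' @param rate_range Range of per-gene similarity decay rates; rates are
#'   evenly log-spaced across genes so divergence thresholds are crossed
#'   gene by gene.
#' @param noise_sd Identity noise (percentage points) added per gene pair.
#' @param rate_jitter_sd Lognormal sd of per-genome, per-gene rate
#'   multipliers (lineage rate variation). Jitter breaks the strict
#'   nestedness of gene presence across divergence depths, as in real
#'   panels where a slowly evolving gene can be detectable in a distant
#'   relative yet missed in a closer one.
#' @param hgt_identity Percent identity between copies of one donor-pool
#'   gene acquired by different lineages (recent transfer, hence high).
#' @param n_donor_pool Genes in the shared foreign donor pool.
#' @param seed RNG seed; the whole clade is reproducible from it.
#' @return A `clade_params` list.
#' @export
clade_params <- function(n_leaves = 8L, tree = NULL, n_genes = 180L,
                         mean_operon_len = 3, gene_len_bp = 500L,
                         loss_rate = 0, inversion_rate = 0, indel_rate = 0,
                         hgt_insert_rate = 0, hgt_leaf_fraction = 0.3,
                         foreign_gc_shift = 0.25,
                         gc_host = 0.5, rate_range = c(0.4, 10),
                         noise_sd = 0.25, rate_jitter_sd = 0.08,
                         hgt_identity = 95, n_donor_pool = 20L, seed = 1L) {
  stopifnot(n_genes >= 4, mean_operon_len > 0, gene_len_bp > 0,
            loss_rate >= 0, inversion_rate >= 0, indel_rate >= 0,
            hgt_insert_rate >= 0,
            foreign_gc_shift >= -0.3, foreign_gc_shift <= 0.3,
            rate_range[1] > 0, rate_range[2] > rate_range[1])
  structure(
    list(n_leaves = as.integer(n_leaves), tree = tree,
         n_genes = as.integer(n_genes), mean_operon_len = mean_operon_len,
         gene_len_bp = as.integer(gene_len_bp), loss_rate = loss_rate,
         inversion_rate = inversion_rate, indel_rate = indel_rate,
         hgt_insert_rate = hgt_insert_rate,
         hgt_leaf_fraction = hgt_leaf_fraction,
         foreign_gc_shift = foreign_gc_shift, gc_host = gc_host,
         rate_range = rate_range, noise_sd = noise_sd,
         rate_jitter_sd = rate_jitter_sd, hgt_identity = hgt_identity,
         n_donor_pool = as.integer(n_donor_pool),
         seed = as.integer(seed)),
    class = "clade_params")
}

# Draw an i.i.d. nucleotide string of length n with the given GC content.
draw_sequence <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Geometric-ish segment length >= 1 with the given mean.
seg_len <- function(mean_len) 1L + rpois(1L, max(mean_len - 1, 0))

#' Generate a clade of annotated genomes along a known tree
#'
#' Evolves gene content (loss, segmental inversion, insertion/deletion) and
#' plants horizontal transfer from a GC-shifted donor pool along each branch,
#' then assembles one [annotated_genome()] per leaf with coordinates, strand,
#' COG labels (inherited through vertical descent, random for foreign genes),
#' operon annotation (contiguous runs of the ancestral operon structure) and
#' chromosome sequence. All randomness flows from one seeded stream, so the
#' same parameters give byte-identical output.
#'
#' @param params A [clade_params()].
#' @return List with `genomes` (named list of [annotated_genome()]s),
#'   `truth` (a `truth_record`: `tree`, per-genome gene provenance tables,
#'   `hgt_genes`, and the params) — see [true_pairs()].
#' @export
generate_clade <- function(params = clade_params()) {
  tree <- params$tree
  if (is.null(tree)) {
    tree <- sim_clade_tree(params$n_leaves, depth = 1,
                           seed = derive_seed(params$seed, "tree"))
  }
  if (length(tree$tip.label) <= 2L) {
    abort("degenerate tree: need more than 2 leaves")
  }
  with_seed(params$seed, {
    ng <- params$n_genes
    cogs <- sample(strsplit("JKLMNOPQRSTUVCEFGHI", "")[[1]], ng,
                   replace = TRUE)
    # ancestral operon partition: contiguous blocks
    op_id <- integer(0)
    k <- 0L
    while (length(op_id) < ng) {
      k <- k + 1L
      len <- 2L + rpois(1L, max(params$mean_operon_len - 2, 0))
      op_id <- c(op_id, rep(k, len))
    }
    op_id <- op_id[seq_len(ng)]
    # one divergence rate per operon (co-transcribed genes evolve at a
    # shared rate), evenly log-spaced so every divergence depth keeps some
    # intact slow operons; shuffled so rate is independent of position
    n_op <- max(op_id)
    op_rates <- exp(seq(log(params$rate_range[1]),
                        log(params$rate_range[2]), length.out = n_op))
    op_rates <- sample(op_rates)
    rates <- op_rates[op_id]
    ancestor <- tibble(
      lineage = sprintf("g%03d", seq_len(ng)),
      source = sprintf("g%03d", seq_len(ng)),
      rate = rates, cog = cogs, foreign = FALSE,
      strand = "+", operon = sprintf("op%03d", op_id))
    pool <- tibble(
      source = sprintf("hgtP%02d", seq_len(params$n_donor_pool)),
      rate = stats::runif(params$n_donor_pool, 0.2, 1),
      cog = sample(strsplit("JKLMNOPQRSTUVCEFGHI", "")[[1]],
                   params$n_donor_pool, replace = TRUE))
    hgt_event <- 0L
    ins_event <- 0L
    evolve_branch <- function(genes, bl) {
      # gene loss
      if (params$loss_rate > 0 && nrow(genes) > 0) {
        p_loss <- 1 - exp(-params$loss_rate * bl)
        keep <- stats::runif(nrow(genes)) >= p_loss
        if (sum(keep) >= 4) genes <- genes[keep, , drop = FALSE]
      }
      # segmental inversions
      n_inv <- rpois(1L, params$inversion_rate * bl)
      for (i in seq_len(n_inv)) {
        if (nrow(genes) < 2) break
        len <- min(seg_len(4), nrow(genes))
        s <- sample.int(nrow(genes) - len + 1L, 1L)
        seg <- s:(s + len - 1L)
        inv <- genes[rev(seg), , drop = FALSE]
        inv$strand <- ifelse(inv$strand == "+", "-", "+")
        genes[seg, ] <- inv
      }
      # indels: novel insertions and segmental deletions
      n_ind <- rpois(1L, params$indel_rate * bl)
      for (i in seq_len(n_ind)) {
        if (stats::runif(1) < 0.5 && nrow(genes) > 6) {
          len <- min(seg_len(2), nrow(genes) - 4L)
          s <- sample.int(nrow(genes) - len + 1L, 1L)
          genes <- genes[-(s:(s + len - 1L)), , drop = FALSE]
        } else {
          ins_event <<- ins_event + 1L
          len <- seg_len(2)
          new <- tibble(
            lineage = sprintf("ins%03d_%02d", ins_event, seq_len(len)),
            source = sprintf("ins%03d_%02d", ins_event, seq_len(len)),
            rate = stats::runif(len, 0.2, 2),
            cog = sample(strsplit("JKLMNOPQRSTUV", "")[[1]], len,
                         replace = TRUE),
            foreign = FALSE, strand = "+",
            operon = sprintf("insop%03d", ins_event))
          s <- sample.int(nrow(genes) + 1L, 1L)
          genes <- bind_rows(
            genes[seq_len(s - 1L), , drop = FALSE], new,
            genes[seq(s, length.out = nrow(genes) - s + 1L), , drop = FALSE])
        }
      }
      genes
    }
    # horizontal transfer: recent acquisitions from the shared donor pool
    # into a susceptible subset of lineages (terminal branches), so the
    # planted signal is concentrated in some genomes and shared across
    # unrelated recipients
    plant_hgt <- function(genes) {
      n_ev <- rpois(1L, params$hgt_insert_rate)
      for (i in seq_len(n_ev)) {
        hgt_event <<- hgt_event + 1L
        len <- min(3L + rpois(1L, 2L), nrow(pool))
        s <- sample.int(nrow(pool) - len + 1L, 1L)
        seg <- pool[s:(s + len - 1L), , drop = FALSE]
        # a lineage acquires each donor gene at most once
        seg <- seg[!seg$source %in% genes$source, , drop = FALSE]
        if (nrow(seg) == 0L) next
        new <- tibble(
          lineage = paste0("h", hgt_event, "_", seg$source),
          source = seg$source, rate = seg$rate, cog = seg$cog,
          foreign = TRUE, strand = "+",
          operon = sprintf("hgtop%03d", hgt_event))
        at <- sample.int(nrow(genes) + 1L, 1L)
        genes <- bind_rows(
          genes[seq_len(at - 1L), , drop = FALSE], new,
          genes[seq(at, length.out = nrow(genes) - at + 1L), , drop = FALSE])
      }
      genes
    }
    # preorder traversal from the root
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    state <- vector("list", n_tip + tree$Nnode)
    state[[root]] <- ancestor
    leaf_tables <- vector("list", n_tip)
    edges <- tree$edge[order(tree$edge[, 1], tree$edge[, 2]), , drop = FALSE]
    lens <- tree$edge.length[order(tree$edge[, 1], tree$edge[, 2])]
    walk <- function(node) {
      rows <- which(edges[, 1] == node)
      for (r in rows) {
        child <- edges[r, 2]
        state[[child]] <<- evolve_branch(state[[node]], lens[r])
        if (child <= n_tip) {
          leaf_tables[[child]] <<- state[[child]]
        } else {
          walk(child)
        }
      }
    }
    walk(root)
    susceptible <- rep(FALSE, n_tip)
    if (params$hgt_insert_rate > 0) {
      n_sus <- max(1L, round(params$hgt_leaf_fraction * n_tip))
      susceptible[sample.int(n_tip, n_sus)] <- TRUE
    }
    for (leaf in seq_len(n_tip)) {
      if (susceptible[leaf]) {
        leaf_tables[[leaf]] <- plant_hgt(leaf_tables[[leaf]])
      }
    }
    genomes <- list()
    provenance <- list()
    for (leaf in seq_len(n_tip)) {
      gid <- tree$tip.label[leaf]
      tab <- leaf_tables[[leaf]]
      tab$gene_id <- make.unique(tab$lineage, sep = "_d")
      tab$rate_mult <- if (params$rate_jitter_sd > 0) {
        exp(rnorm(nrow(tab), 0, params$rate_jitter_sd))
      } else {
        rep(1, nrow(tab))
      }
      m <- nrow(tab)
      gl <- params$gene_len_bp
      gc <- ifelse(tab$foreign, params$gc_host + params$foreign_gc_shift,
                   params$gc_host)
      seqs <- vapply(gc, function(g) draw_sequence(gl, g), "")
      genes <- tibble(
        gene_id = tab$gene_id,
        start = (seq_len(m) - 1L) * gl + 1L,
        end = seq_len(m) * gl,
        strand = tab$strand, cog = tab$cog)
      # operons: maximal contiguous runs of the inherited operon label
      run <- cumsum(c(1L, tab$operon[-1] != tab$operon[-m]))
      operons <- tibble(operon_id = paste0(gid, "_", tab$operon, "_", run),
                        gene_id = tab$gene_id)
      genomes[[gid]] <- annotated_genome(
        gid, genes, sequence = paste(seqs, collapse = ""),
        operons = operons)
      provenance[[gid]] <- tab
    }
    truth <- structure(
      list(tree = tree, provenance = provenance,
           hgt_genes = lapply(provenance, function(t) {
             t$gene_id[t$foreign]
           }),
           params = params),
      class = "truth_record")
    list(genomes = genomes, truth = truth)
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> ", length(x$provenance), " genomes on a ",
      length(x$tree$tip.label), "-leaf tree; ",
      sum(lengths(x$hgt_genes)), " planted HGT genes\n", sep = "")
  invisible(x)
}

#' True ortholog pairs between two generated genomes
#'
#' Genes descending from the same ancestral gene copy (identical lineage
#' identifier) — vertical orthologs. Copies of one donor-pool gene acquired
#' through different transfer events are *not* true pairs even though they
#' are highly similar.
#'
#' @param truth A `truth_record` from [generate_clade()].
#' @param id_a,id_b Leaf genome ids.
#' @return Tibble with columns `gene_a`, `gene_b`.
#' @export
true_pairs <- function(truth, id_a, id_b) {
  ta <- truth$provenance[[id_a]]
  tb <- truth$provenance[[id_b]]
  if (is.null(ta) || is.null(tb)) abort("genome not in this clade's truth")
  shared <- intersect(ta$lineage, tb$lineage)
  tibble(gene_a = ta$gene_id[match(shared, ta$lineage)],
         gene_b = tb$gene_id[match(shared, tb$lineage)]) |>
    arrange(.data$gene_a)
}

#' Synthetic similarity hits between two generated genomes
#'
#' Stands in for an all-against-all sequence search: true ortholog pairs get
#' identity decaying exponentially with tree path length at each gene's own
#' rate (plus seeded noise), copies of one donor-pool gene acquired by
#' different lineages get high fixed identity (recent transfer), and a
#' configurable fraction of spurious paralog-like hits is added. Output uses
#' the same column layout [read_similarity()] accepts. Hits are canonical in
#' the unordered genome pair: calling with the genomes swapped yields the
#' same pairs with columns exchanged.
#'
#' @param genome_a,genome_b Leaf [annotated_genome()]s from one clade.
#' @param truth The clade's `truth_record`.
#' @param spurious_fraction Expected spurious hits per true pair.
#' @return Tibble with `gene_a`, `gene_b`, `score`, `evalue`, `identity`.
#' @export
similarity_hits <- function(genome_a, genome_b, truth,
                            spurious_fraction = 0.05) {
  id_a <- genome_a$id
  id_b <- genome_b$id
  if (is.null(truth$provenance[[id_a]]) ||
      is.null(truth$provenance[[id_b]])) {
    abort("genomes are not from this clade (unknown truth)")
  }
  flip <- id_a > id_b
  if (flip) {
    tmp <- id_a; id_a <- id_b; id_b <- tmp
  }
  ta <- truth$provenance[[id_a]]
  tb <- truth$provenance[[id_b]]
  dmat <- ape::cophenetic.phylo(truth$tree)
  d <- dmat[id_a, id_b]
  gl <- truth$params$gene_len_bp
  hits <- with_seed(derive_seed(truth$params$seed,
                                paste0("hits|", id_a, "|", id_b)), {
    vert <- intersect(ta$lineage, tb$lineage)
    ia <- match(vert, ta$lineage)
    ib <- match(vert, tb$lineage)
    ident <- 100 * exp(-ta$rate[ia] *
                         sqrt(ta$rate_mult[ia] * tb$rate_mult[ib]) * d)
    if (d > 0 && truth$params$noise_sd > 0) {
      ident <- ident + rnorm(length(ident), 0, truth$params$noise_sd)
    }
    ident <- pmin(100, pmax(0, ident))
    out <- tibble(gene_a = ta$gene_id[ia], gene_b = tb$gene_id[ib],
                  identity = ident)
    # donor-pool copies acquired through different transfer events
    fa <- ta[ta$foreign, , drop = FALSE]
    fb <- tb[tb$foreign, , drop = FALSE]
    if (nrow(fa) > 0 && nrow(fb) > 0) {
      cross <- merge(fa[, c("gene_id", "lineage", "source")],
                     fb[, c("gene_id", "lineage", "source")],
                     by = "source")
      cross <- cross[cross$lineage.x != cross$lineage.y, , drop = FALSE]
      if (nrow(cross) > 0) {
        hi <- truth$params$hgt_identity +
          rnorm(nrow(cross), 0, truth$params$noise_sd)
        out <- bind_rows(out, tibble(gene_a = cross$gene_id.x,
                                     gene_b = cross$gene_id.y,
                                     identity = pmin(100, hi)))
      }
    }
    out <- out[out$identity >= 20, , drop = FALSE]
    # spurious paralog-like hits
    n_true <- sum(!is.na(match(vert, ta$lineage)))
    n_spur <- rbinom(1L, n_true, min(1, spurious_fraction))
    if (n_spur > 0) {
      sp <- tibble(
        gene_a = sample(ta$gene_id, n_spur, replace = TRUE),
        gene_b = sample(tb$gene_id, n_spur, replace = TRUE),
        identity = stats::runif(n_spur, 31, 55))
      key <- paste0(out$gene_a, "\r", out$gene_b)
      sp <- sp[!paste0(sp$gene_a, "\r", sp$gene_b) %in% key, , drop = FALSE]
      sp <- sp[!duplicated(paste0(sp$gene_a, "\r", sp$gene_b)), ,
               drop = FALSE]
      out <- bind_rows(out, sp)
    }
    out
  })
  hits$score <- round(2 * gl * hits$identity / 100, 1)
  hits$evalue <- ifelse(hits$identity >= 100 & d == 0, 0,
                        10^(-hits$identity / 3))
  hits <- select(hits, "gene_a", "gene_b", "score", "evalue", "identity")
  if (flip) {
    hits <- select(hits, gene_a = "gene_b", gene_b = "gene_a",
                   "score", "evalue", "identity")
  }
  arrange(hits, .data$gene_a, .data$gene_b)
}

#' Write a generated clade to disk
#'
#' Exports the same FASTA/TSV bundle the readers accept: per genome a FASTA,
#' a gene table and an operon table; similarity hits for every unordered
#' pair; the generating tree (Newick) and per-pair true ortholog pairs
#' (TSV); and a manifest consumable by [run_pipeline()].
#'
#' @param clade Output of [generate_clade()].
#' @param dir Output directory (created if needed).
#' @param spurious_fraction Passed to [similarity_hits()].
#' @return The manifest path, invisibly.
#' @export
write_clade <- function(clade, dir, spurious_fraction = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sort(names(clade$genomes))
  rows <- character(0)
  for (gid in ids) {
    g <- clade$genomes[[gid]]
    fa <- file.path(dir, paste0(gid, ".fasta"))
    gt <- file.path(dir, paste0(gid, "_genes.tsv"))
    ot <- file.path(dir, paste0(gid, "_operons.tsv"))
    write_genome_fasta(g, fa)
    write_gene_table(g, gt)
    write_operon_table(g, ot)
    rows <- c(rows, paste(gid, fa, gt, ot,
                          file.path(dir, paste0("hits_", gid, "__*.tsv")),
                          sep = "\t"))
  }
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        h <- similarity_hits(clade$genomes[[ids[i]]], clade$genomes[[ids[j]]],
                             clade$truth, spurious_fraction)
        write_similarity(
          h, file.path(dir, paste0("hits_", ids[i], "__", ids[j], ".tsv")))
        tp <- true_pairs(clade$truth, ids[i], ids[j])
        readr::write_tsv(
          tp, file.path(dir, paste0("truth_", ids[i], "__", ids[j], ".tsv")))
      }
    }
  }
  write_newick(clade$truth$tree, file.path(dir, "truth_tree.nwk"))
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(c("genome_id\tfasta\tgene_table\toperon_table\thits_glob",
               rows), manifest)
  invisible(manifest)
}
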