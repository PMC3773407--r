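pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "||")

#' Pipeline stage options
#'
#' Bundles every tunable of the four pipeline stages. The two HGT-filter
#' toggles reproduce the stage-ablation design: `rog_filter` controls the
#' highly-conserved-gene elimination, `barcode_filter` the abnormal-barcode
#' elimination, and `use_clusters` switches between the conserved-cluster
#' distance and the degenerate raw ortholog-count distance.
#'
#' @param weights [ortho_weights()] for the assignment stage.
#' @param clusters [cluster_params()] for the distance stage.
#' @param rog_filter,barcode_filter Enable the two elimination stages.
#' @param use_clusters Use conserved clusters for the distance (default
#'   TRUE).
#' @param min_identity,cog_filter Candidate-filter settings (see
#'   [candidate_hits()]).
#' @param conserved_frac,barcode_frac Elimination fractions (defaults 0.15
#'   and 0.2).
#' @param calib_m Random sets drawn per calibration (default 1000; raise to
#'   10000 for production-size panels).
#' @param calib_set_size Species per random set; default the analysis-set
#'   size (capped at the calibration panel size).
#' @param barcode_L Barcode fragment length in bp (default 1000).
#' @param sentinel Distance for pairs with no clustered orthologs.
#' @param clamp_negative Clamp negative NJ branch lengths.
#' @return A `pipeline_options` list.
#' @export
pipeline_options <- function(weights = ortho_weights(),
                             clusters = cluster_params(),
                             rog_filter = TRUE, barcode_filter = TRUE,
                             use_clusters = TRUE,
                             min_identity = 30, cog_filter = TRUE,
                             conserved_frac = 0.15, barcode_frac = 0.2,
                             calib_m = 1000L, calib_set_size = NULL,
                             barcode_L = 1000L, sentinel = 1.0,
                             clamp_negative = FALSE) {
  structure(
    list(weights = weights, clusters = clusters, rog_filter = rog_filter,
         barcode_filter = barcode_filter, use_clusters = use_clusters,
         min_identity = min_identity, cog_filter = cog_filter,
         conserved_frac = conserved_frac, barcode_frac = barcode_frac,
         calib_m = as.integer(calib_m), calib_set_size = calib_set_size,
         barcode_L = as.integer(barcode_L), sentinel = sentinel,
         clamp_negative = clamp_negative),
    class = "pipeline_options")
}

# Assign orthologs for every unordered pair of `ids`, reusing `hits` keyed by
# pair_key(). Returns a list keyed the same way.
compute_maps <- function(genomes, hits, ids, opts) {
  maps <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      key <- pair_key(ids[i], ids[j])
      h <- hits[[key]]
      if (is.null(h)) {
        abort(paste0("no similarity hits supplied for pair ", ids[i], " vs ",
                     ids[j]))
      }
      ga <- genomes[[ids[i]]]
      gb <- genomes[[ids[j]]]
      cand <- candidate_hits(h, ga, gb, min_identity = opts$min_identity,
                             cog_filter = opts$cog_filter)
      maps[[key]] <- assign_orthologs(cand, ga, gb, opts$weights)
    }
  }
  maps
}

#' Run the whole-genome phylogeny pipeline
#'
#' Executes the four stages in order: (1) candidate filtering and
#' one-to-one ortholog assignment for every genome pair; (2) optional HGT
#' elimination — three-sigma classification of the analysis set against a
#' calibration panel, then removal of highly conserved genes (ordinary sets)
#' and of genes on abnormal-barcode fragments (special sets); (3) conserved
#' gene cluster detection and the CGCD distance matrix; (4) neighbor-joining
#' tree construction, plus optional quartet scoring against a reference.
#'
#' @param genomes Named list of [annotated_genome()]s (the analysis set).
#' @param hits Named list of similarity-hit tibbles keyed
#'   `"<idA>||<idB>"` with ids sorted (see [similarity_hits()] /
#'   [read_similarity()]).
#' @param opts A [pipeline_options()].
#' @param calibration_genomes,calibration_hits Optional larger calibration
#'   universe (and its hits, covering all its pairs); defaults to the
#'   analysis set. Also used as the reference panel for ortholog occurrence
#'   counts.
#' @param reference Optional reference for quartet scoring: an `ape::phylo`
#'   or a taxonomy tibble (`taxon`, `code`).
#' @param seed Seed for the calibrations and any sampled quartet mode.
#' @param out_dir Optional output directory; intermediates are written there.
#' @return A `cgcphy_result` list: `maps` (raw), `filtered_maps`,
#'   `eliminated`, `classification`, `calibrations`, `distance`, `tree`,
#'   `quartets` (or NULL), `log` (per-stage counts tibble).
#' @export
run_pipeline <- function(genomes, hits, opts = pipeline_options(),
                         calibration_genomes = NULL,
                         calibration_hits = NULL,
                         reference = NULL, seed = 1L, out_dir = NULL) {
  ids <- sort(names(genomes))
  if (length(ids) < 3) abort("pipeline needs at least 3 genomes")
  self_cal <- is.null(calibration_genomes)
  cal_genomes <- if (self_cal) genomes else calibration_genomes
  cal_hits <- if (self_cal) hits else calibration_hits
  cal_ids <- sort(names(cal_genomes))
  log <- list()
  # stage 1: orthologs over the union of analysis + calibration pairs
  maps <- compute_maps(cal_genomes, cal_hits, cal_ids, opts)
  if (!self_cal) {
    extra <- setdiff(ids, cal_ids)
    if (length(extra) > 0) {
      abort("analysis genomes must be part of the calibration panel")
    }
  }
  analysis_maps <- maps[vapply(maps, function(m) {
    m$genome_a %in% ids && m$genome_b %in% ids
  }, TRUE)]
  log$orthologs <- bind_rows(lapply(analysis_maps, glance))
  eliminated <- tibble(genome_id = character(0), gene_id = character(0),
                       reason = character(0))
  classification <- list(rog = NA_character_, barcode = NA_character_)
  calibrations <- list()
  set_size <- opts$calib_set_size
  if (is.null(set_size)) set_size <- min(length(ids), length(cal_ids))
  # stage 2a: highly conserved gene elimination
  if (opts$rog_filter) {
    cal_rog <- calibrate(cal_genomes, maps = maps, statistic = "mean_rog",
                         m = opts$calib_m, set_size = set_size,
                         seed = derive_seed(seed, "rog"))
    stat <- mean_rog_set(cal_rog$rogm, ids)
    classification$rog <- classify_set(stat, cal_rog)
    calibrations$rog <- cal_rog
    counts <- ortholog_count_table(cal_genomes, maps)
    elim_cons <- eliminate_conserved(counts, length(cal_ids),
                                     classification$rog,
                                     frac = opts$conserved_frac)
    eliminated <- bind_rows(eliminated,
                            filter(elim_cons, .data$genome_id %in% ids))
  }
  # stage 2b: abnormal genome barcode gene elimination
  if (opts$barcode_filter) {
    profiles <- lapply(cal_genomes, function(g) {
      anomaly_profile(compute_barcode(g, L = opts$barcode_L))
    })
    cal_rge <- calibrate(cal_genomes, profiles = profiles,
                         statistic = "std_rge", m = opts$calib_m,
                         set_size = set_size,
                         seed = derive_seed(seed, "rge"))
    rge <- setNames(vapply(profiles, function(p) p$r_ge, 1),
                    vapply(profiles, function(p) p$genome_id, ""))
    stat <- std_rge_set(rge, ids)
    classification$barcode <- classify_set(stat, cal_rge)
    calibrations$barcode <- cal_rge
    elim_bar <- bind_rows(lapply(ids, function(gid) {
      eliminate_barcode_genes(genomes[[gid]], profiles[[gid]],
                              classification$barcode,
                              frac = opts$barcode_frac)
    }))
    eliminated <- bind_rows(eliminated, elim_bar)
  }
  eliminated <- distinct(eliminated, .data$genome_id, .data$gene_id,
                         .keep_all = TRUE)
  filtered <- apply_elimination(analysis_maps, eliminated)
  log$eliminated <- eliminated |>
    group_by(.data$genome_id, .data$reason) |>
    summarise(n = dplyr::n(), .groups = "drop")
  # stage 3: conserved gene cluster distance
  dm <- distance_matrix(genomes, filtered, params = opts$clusters,
                        sentinel = opts$sentinel,
                        use_clusters = opts$use_clusters)
  # stage 4: neighbor joining (+ optional quartet scoring)
  tree <- neighbor_joining(dm, clamp_negative = opts$clamp_negative)
  quartets <- NULL
  if (!is.null(reference)) {
    ref_tree <- if (inherits(reference, "phylo")) {
      reference
    } else {
      taxonomy_tree(reference)
    }
    keep <- intersect(ref_tree$tip.label, ids)
    if (length(keep) < length(ids)) {
      abort("reference does not cover all analysis genomes")
    }
    quartets <- quartet_accuracy(tree, ref_tree, seed = derive_seed(seed, "q"))
  }
  res <- structure(
    list(maps = analysis_maps, filtered_maps = filtered,
         eliminated = eliminated, classification = classification,
         calibrations = calibrations, distance = dm, tree = tree,
         quartets = quartets, log = log, opts = opts, seed = seed),
    class = "cgcphy_result")
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

#' @export
print.cgcphy_result <- function(x, ...) {
  cat("<cgcphy_result> ", nrow(x$distance), " genomes; ",
      nrow(x$eliminated), " genes eliminated (rog: ",
      x$classification$rog, ", barcode: ", x$classification$barcode, ")\n",
      sep = "")
  if (!is.null(x$quartets)) print(x$quartets)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cgcphy_result <- function(x, ...) {
  tibble(n_genomes = nrow(x$distance),
         n_pairs = length(x$maps),
         n_eliminated = nrow(x$eliminated),
         rog_class = x$classification$rog,
         barcode_class = x$classification$barcode,
         quartet_accuracy = if (is.null(x$quartets)) NA_real_ else
           x$quartets$accuracy)
}

#' Write pipeline outputs to a directory
#' @param res A `cgcphy_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_phylip(res$distance, file.path(dir, "distance.phylip"))
  write_newick(res$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(res$eliminated, file.path(dir, "eliminated_genes.tsv"))
  for (key in names(res$filtered_maps)) {
    write_ortholog_map(
      res$filtered_maps[[key]],
      file.path(dir, paste0("orthologs_", gsub("\\|\\|", "__", key), ".tsv")))
  }
  for (nm in names(res$calibrations)) {
    write_calibration(res$calibrations[[nm]],
                      file.path(dir, paste0("calibration_", nm, ".txt")))
  }
  if (!is.null(res$quartets)) {
    write_quartet_report(res$quartets, file.path(dir, "quartets.json"))
  }
  readr::write_tsv(bind_rows(res$log$orthologs),
                   file.path(dir, "log_orthologs.tsv"))
  readr::write_tsv(res$log$eliminated, file.path(dir, "log_eliminated.tsv"))
  invisible(dir)
}

#' Stage-ablation experiment
#'
#' Runs the pipeline under combinations of its stages on the same input and
#' seed: arm `"1"` is ortholog identification only (no HGT filter, distance
#' `-log10` of the raw ortholog count), `"1+2"` adds the HGT eliminations,
#' `"1+3"` adds conserved-cluster distances without elimination, and
#' `"1+2+3"` is the full pipeline.
#'
#' @inheritParams run_pipeline
#' @param arms Subset of `c("1", "1+2", "1+3", "1+2+3")`.
#' @param reference Required: reference tree or taxonomy for scoring.
#' @return Tibble with one row per arm: `arm`, `accuracy`, `n_effective`,
#'   `n_eliminated`.
#' @export
run_ablation <- function(genomes, hits, reference,
                         arms = c("1", "1+2", "1+3", "1+2+3"),
                         opts = pipeline_options(),
                         calibration_genomes = NULL,
                         calibration_hits = NULL, seed = 1L) {
  if (is.null(reference)) abort("ablation needs a reference taxonomy/tree")
  arms <- match.arg(arms, several.ok = TRUE)
  bind_rows(lapply(arms, function(arm) {
    o <- opts
    o$rog_filter <- arm %in% c("1+2", "1+2+3")
    o$barcode_filter <- arm %in% c("1+2", "1+2+3")
    o$use_clusters <- arm %in% c("1+3", "1+2+3")
    res <- run_pipeline(genomes, hits, o,
                        calibration_genomes = calibration_genomes,
                        calibration_hits = calibration_hits,
                        reference = reference, seed = seed)
    tibble(arm = arm, accuracy = res$quartets$accuracy,
           n_effective = res$quartets$n_effective,
           n_eliminated = nrow(res$eliminated))
  }))
}

#' Read a pipeline manifest
#'
#' Tab-separated with header: `genome_id`, `fasta`, `gene_table`,
#' `operon_table`, `hits_glob`. Relative paths are resolved against the
#' manifest's directory. Hit files must be named so that the glob expands to
#' `hits_<idA>__<idB>.tsv` for genome pairs.
#'
#' @param path Manifest path.
#' @return List with `genomes` (named list) and `hits` (named list keyed
#'   `"<idA>||<idB>"`).
#' @export
read_manifest <- function(path) {
  base <- dirname(path)
  tab <- readr::read_tsv(path, col_types = "ccccc")
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base, basename(p)))
  }
  genomes <- list()
  for (i in seq_len(nrow(tab))) {
    gid <- tab$genome_id[i]
    g <- read_gene_table(resolve(tab$gene_table[i]), gid,
                         sequence = read_genome_fasta(resolve(tab$fasta[i])))
    if (!is.na(tab$operon_table[i]) && nzchar(tab$operon_table[i])) {
      g <- read_operon_table(resolve(tab$operon_table[i]), g)
    }
    genomes[[gid]] <- g
  }
  hits <- list()
  ids <- sort(names(genomes))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      row <- which(tab$genome_id == ids[i])
      pat <- gsub("\\*", paste0(ids[j]), basename(tab$hits_glob[row]))
      f <- resolve(file.path(dirname(tab$hits_glob[row]), pat))
      if (!file.exists(f)) {
        # try the swapped naming
        row2 <- which(tab$genome_id == ids[j])
        pat2 <- gsub("\\*", paste0(ids[i]), basename(tab$hits_glob[row2]))
        f <- resolve(file.path(dirname(tab$hits_glob[row2]), pat2))
      }
      if (!file.exists(f)) {
        abort(paste0("no hits file found for pair ", ids[i], " vs ", ids[j]))
      }
      h <- read_similarity(f)
      if (basename(f) == paste0("hits_", ids[j], "__", ids[i], ".tsv")) {
        h <- select(h, gene_a = "gene_b", gene_b = "gene_a", "score",
                    "evalue", "identity")
      }
      hits[[pair_key(ids[i], ids[j])]] <- h
    }
  }
  list(genomes = genomes, hits = hits)
}
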