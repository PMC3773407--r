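#' Ratio of orthologous genes (ROG) between two genomes
#'
#' `rog = 2 * n_orth / (n_g + n_h)`: the fraction of genes of the two genomes
#' that are in ortholog pairs, a pairwise genome similarity in `[0, 1]`.
#'
#' @param n_orth Number of ortholog pairs between the genomes.
#' @param n_g,n_h Gene counts of the two genomes.
#' @return ROG value in `[0, 1]`.
#' @export
#' @examples
#' rog(50, 100, 150)  # 0.4
rog <- function(n_orth, n_g, n_h) {
  if (any(n_g <= 0) || any(n_h <= 0)) abort("zero-size genome in rog()")
  stopifnot(all(n_orth <= pmin(n_g, n_h)))
  2 * n_orth / (n_g + n_h)
}

#' Pairwise ROG matrix over a panel
#'
#' @param panel Named list of [annotated_genome()]s.
#' @param maps List of `ortholog_map`s covering every unordered pair.
#' @return Symmetric matrix of ROG values with genome ids as dimnames
#'   (diagonal 1).
#' @export
rog_matrix <- function(panel, maps) {
  ids <- sort(vapply(panel, function(g) g$id, ""))
  sizes <- setNames(vapply(panel, n_genes, 1L),
                    vapply(panel, function(g) g$id, ""))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  for (mp in maps) {
    if (!(mp$genome_a %in% ids) || !(mp$genome_b %in% ids)) next
    v <- rog(nrow(mp$pairs), sizes[mp$genome_a], sizes[mp$genome_b])
    m[mp$genome_a, mp$genome_b] <- v
    m[mp$genome_b, mp$genome_a] <- v
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(paste0("missing ortholog map for pair ", ids[miss[1]], " vs ",
                 ids[miss[2]]))
  }
  m
}

#' Set-level statistics for species-set classification
#'
#' `mean_rog_set` averages the pairwise ROG over the `n(n-1)/2` unordered
#' pairs of a species set; `std_rge_set` is the sample standard deviation of
#' the per-genome genomic-evolution values over the set.
#'
#' @param rogm ROG matrix from [rog_matrix()].
#' @param ids Genome ids of the set.
#' @return Scalar statistic.
#' @export
mean_rog_set <- function(rogm, ids) {
  sub <- rogm[ids, ids, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' @rdname mean_rog_set
#' @param rge Named numeric vector of per-genome `r_ge` values (see
#'   [anomaly_profile()]).
#' @export
std_rge_set <- function(rge, ids) {
  sd(rge[ids])
}

#' Three-sigma calibration of a set-level statistic
#'
#' Draws `m` random species sets of `set_size` genomes (without replacement
#' within a set) from the calibration panel, computes the chosen statistic for
#' each, and records the mean and sample standard deviation of the `m`
#' values. A species set is later called *special* (sss) when its statistic
#' falls outside three sigmas of this calibration (see [classify_set()]).
#'
#' @param panel Named list of [annotated_genome()]s (the calibration
#'   universe).
#' @param maps `ortholog_map`s over the panel (required for
#'   `statistic = "mean_rog"`).
#' @param profiles List of [anomaly_profile()]s, or a named numeric vector of
#'   `r_ge` values (required for `statistic = "std_rge"`).
#' @param statistic `"mean_rog"` (two-sided classification) or `"std_rge"`
#'   (upper tail only).
#' @param m Number of random sets (default 10000).
#' @param set_size Species per random set.
#' @param seed RNG seed; the calibration is fully reproducible.
#' @return A `calibration` object: `mu`, `sigma`, `m`, `set_size`, `seed`,
#'   `statistic`, `tail`, plus the panel statistic inputs needed to classify
#'   new sets (`rogm` or `rge`).
#' @export
calibrate <- function(panel, maps = NULL, profiles = NULL,
                      statistic = c("mean_rog", "std_rge"),
                      m = 10000L, set_size = 10L, seed = 1L) {
  statistic <- match.arg(statistic)
  ids <- sort(vapply(panel, function(g) g$id, ""))
  if (set_size > length(ids)) {
    abort(paste0("set_size (", set_size, ") exceeds panel size (",
                 length(ids), ")"))
  }
  if (m < 2) abort("calibration needs m >= 2 random sets")
  if (statistic == "mean_rog") {
    if (is.null(maps)) abort("mean_rog calibration needs ortholog maps")
    rogm <- rog_matrix(panel, maps)
    stat_fun <- function(s) mean_rog_set(rogm, s)
    data <- list(rogm = rogm)
    tail <- "two_sided"
  } else {
    if (is.null(profiles)) abort("std_rge calibration needs anomaly profiles")
    rge <- if (is.numeric(profiles)) {
      profiles
    } else {
      setNames(vapply(profiles, function(p) p$r_ge, 1),
               vapply(profiles, function(p) p$genome_id, ""))
    }
    if (!all(ids %in% names(rge))) abort("r_ge missing for some panel genomes")
    stat_fun <- function(s) std_rge_set(rge, s)
    data <- list(rge = rge[ids])
    tail <- "upper"
  }
  vals <- with_seed(seed, {
    vapply(seq_len(m), function(i) {
      stat_fun(sample(ids, set_size))
    }, 1)
  })
  structure(
    c(list(mu = mean(vals), sigma = sd(vals), m = as.integer(m),
           set_size = as.integer(set_size), seed = as.integer(seed),
           statistic = statistic, tail = tail), data),
    class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration> ", x$statistic, ": mu = ", format(x$mu, digits = 5),
      ", sigma = ", format(x$sigma, digits = 5), " (m = ", x$m,
      ", set_size = ", x$set_size, ", seed = ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Classify a species set as ordinary or special
#'
#' Applies the three-sigma rule to a set-level statistic. For `mean_rog` the
#' ordinary interval is the closed two-sided band `[mu - 3 sigma, mu + 3
#' sigma]`; for `std_rge` only the upper tail is special: a set is ordinary
#' whenever its statistic is `<= mu + 3 sigma`.
#'
#' @param stat_value The set's statistic (e.g. from [mean_rog_set()]).
#' @param cal A [calibrate()] result.
#' @return `"oss"` (ordinary species set) or `"sss"` (special species set).
#' @export
classify_set <- function(stat_value, cal) {
  upper <- cal$mu + 3 * cal$sigma
  lower <- cal$mu - 3 * cal$sigma
  special <- if (cal$tail == "upper") {
    stat_value > upper
  } else {
    stat_value < lower || stat_value > upper
  }
  if (special) "sss" else "oss"
}

#' Eliminate highly conserved orthologous genes
#'
#' In an ordinary species set, genes orthologous in the overwhelming majority
#' of panel species are putative horizontal-transfer carriers (mostly COG
#' category J) and are eliminated: a gene goes when its ortholog occurrence
#' count is at least `(1 - frac)` of the panel size. In a special species set
#' (e.g. one phylum only) conservation reflects vertical descent and nothing
#' is eliminated.
#'
#' @param counts Occurrence tibble from [ortholog_count_table()].
#' @param n_as Panel size (number of species the counts were computed over).
#' @param set_class `"oss"` or `"sss"` from [classify_set()].
#' @param frac Elimination threshold fraction (default 0.15).
#' @return Tibble with columns `genome_id`, `gene_id`, `reason`
#'   (`"conserved"`); empty for sss sets.
#' @export
eliminate_conserved <- function(counts, n_as, set_class, frac = 0.15) {
  if (frac <= 0 || frac >= 1) abort("frac must be in (0, 1)")
  empty <- tibble(genome_id = character(0), gene_id = character(0),
                  reason = character(0))
  if (identical(set_class, "sss")) return(empty)
  hit <- filter(counts, .data$n_ortholog >= (1 - frac) * n_as)
  if (nrow(hit) == 0) return(empty)
  mutate(select(hit, "genome_id", "gene_id"), reason = "conserved")
}

# Genes overlapping a 0-based fragment index by at least one bp.
genes_on_fragment <- function(genome, frag, L) {
  lo <- frag * L + 1
  hi <- (frag + 1) * L
  genome$genes$gene_id[genome$genes$start <= hi & genome$genes$end >= lo]
}

#' Eliminate genes on abnormal-barcode fragments
#'
#' For a special species set, walks the genome's fragments in decreasing
#' barcode-anomaly order, collecting every gene overlapping each fragment by
#' at least one bp, until `floor(frac * n_genes)` genes are collected. When
#' the last fragment overshoots the cap, its genes are admitted in ascending
#' gene-index order until the cap is exact, so the eliminated set is
#' deterministic. Ordinary species sets eliminate nothing.
#'
#' @param genome An [annotated_genome()] with sequence.
#' @param profile Its [anomaly_profile()].
#' @param set_class `"oss"` or `"sss"`.
#' @param frac Fraction of genes to eliminate when special (default 0.2).
#' @return Tibble with `genome_id`, `gene_id`, `reason` (`"barcode"`).
#' @export
eliminate_barcode_genes <- function(genome, profile, set_class, frac = 0.2) {
  empty <- tibble(genome_id = character(0), gene_id = character(0),
                  reason = character(0))
  if (identical(set_class, "oss")) return(empty)
  if (is.null(genome$sequence)) {
    abort(paste0("genome ", genome$id, " has no sequence"))
  }
  cap <- floor(frac * n_genes(genome))
  if (cap < 1) return(empty)
  L <- profile$L
  idx <- setNames(genome$genes$index, genome$genes$gene_id)
  collected <- character(0)
  for (frag in abnormal_fragments(profile)) {
    new <- setdiff(genes_on_fragment(genome, frag, L), collected)
    new <- new[order(idx[new])]
    room <- cap - length(collected)
    if (length(new) >= room) {
      collected <- c(collected, new[seq_len(room)])
      break
    }
    collected <- c(collected, new)
  }
  tibble(genome_id = genome$id, gene_id = collected, reason = "barcode")
}

#' Remove eliminated genes from ortholog maps
#'
#' Drops every ortholog pair touching an eliminated gene. Pair counts are
#' monotonically non-increasing and the one-to-one structure is preserved.
#'
#' @param maps List of `ortholog_map`s.
#' @param eliminated Tibble with columns `genome_id`, `gene_id` (e.g. the
#'   union of [eliminate_conserved()] and [eliminate_barcode_genes()]
#'   output).
#' @return The filtered list of maps.
#' @export
apply_elimination <- function(maps, eliminated) {
  if (is.null(eliminated) || nrow(eliminated) == 0) return(maps)
  gone <- split(eliminated$gene_id, eliminated$genome_id)
  lapply(maps, function(m) {
    drop_a <- gone[[m$genome_a]]
    drop_b <- gone[[m$genome_b]]
    keep <- !(m$pairs$gene_a %in% drop_a) & !(m$pairs$gene_b %in% drop_b)
    m$pairs <- m$pairs[keep, , drop = FALSE]
    m
  })
}

#' Write / read a calibration as a key-value text file
#' @param cal A [calibrate()] result.
#' @param path File path.
#' @return `path` invisibly; `read_calibration()` returns a `calibration`
#'   (without the panel statistic inputs).
#' @export
write_calibration <- function(cal, path) {
  writeLines(c(
    paste0("statistic\t", cal$statistic),
    paste0("tail\t", cal$tail),
    paste0("mu\t", format(cal$mu, digits = 17)),
    paste0("sigma\t", format(cal$sigma, digits = 17)),
    paste0("m\t", cal$m),
    paste0("set_size\t", cal$set_size),
    paste0("seed\t", cal$seed)), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  kv <- strsplit(readLines(path), "\t", fixed = TRUE)
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  structure(
    list(mu = as.numeric(vals[["mu"]]), sigma = as.numeric(vals[["sigma"]]),
         m = as.integer(vals[["m"]]),
         set_size = as.integer(vals[["set_size"]]),
         seed = as.integer(vals[["seed"]]),
         statistic = vals[["statistic"]], tail = vals[["tail"]]),
    class = "calibration")
}
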