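#' Build the reference taxonomy tree from Bergey codes
#'
#' Turns a list of rank-coded taxa into a rooted, generally multifurcating
#' rank trie: one internal node per code prefix shared by more than one
#' lineage, leaves labelled by taxon. Taxa with identical full codes become
#' siblings under one node (they contribute no resolved quartets among
#' themselves). Unit branch lengths are attached so that quartet topologies
#' can be read off path distances.
#'
#' @param codes Tibble with columns `taxon` and `code` (as from
#'   [read_taxonomy()]), or a named character vector of codes.
#' @return An `ape::phylo`, possibly multifurcating.
#' @export
taxonomy_tree <- function(codes) {
  if (is.character(codes)) {
    codes <- tibble(taxon = names(codes), code = unname(codes))
  }
  if (anyDuplicated(codes$taxon)) abort("duplicate taxon in taxonomy")
  if (nrow(codes) < 2) abort("taxonomy tree needs at least 2 taxa")
  keys <- lapply(codes$code, function(cd) {
    p <- parse_bergey(cd)
    c(p$domain_tag, as.character(p$ranks))
  })
  labels <- vapply(codes$taxon, quote_newick_label, "")
  build <- function(keys, labels) {
    if (length(labels) == 1L) return(labels)
    done <- lengths(keys) == 0L
    if (all(done)) {
      return(paste0("(", paste(labels, collapse = ","), ")"))
    }
    heads <- vapply(keys[!done], `[`, "", 1)
    groups <- split(seq_along(keys)[!done], heads)
    if (!any(done) && length(groups) == 1L) {
      return(build(lapply(keys, `[`, -1), labels))
    }
    parts <- c(
      labels[done],
      vapply(groups, function(ix) {
        build(lapply(keys[ix], `[`, -1), labels[ix])
      }, ""))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- build(keys, labels)
  tree <- ape::read.tree(text = paste0(txt, ";"))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

# Pairwise path distances under unit branch lengths (topology only).
unit_cophenetic <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  stats::cophenetic(t2)
}

# Topology codes for columns of a 4 x m index matrix against a distance
# matrix: 1 = ab|cd, 2 = ac|bd, 3 = ad|bc, 0 = unresolved (star).
quartet_codes <- function(D, quads) {
  a <- quads[1, ]; b <- quads[2, ]; cc <- quads[3, ]; d <- quads[4, ]
  s1 <- D[cbind(a, b)] + D[cbind(cc, d)]
  s2 <- D[cbind(a, cc)] + D[cbind(b, d)]
  s3 <- D[cbind(a, d)] + D[cbind(b, cc)]
  mn <- pmin(s1, s2, s3)
  eps <- 1e-9
  ties <- (s1 - mn < eps) + (s2 - mn < eps) + (s3 - mn < eps)
  code <- max.col(-cbind(s1, s2, s3), ties.method = "first")
  code[ties > 1L] <- 0L
  code
}

#' Induced quartet topology of four taxa
#'
#' The unrooted shape a tree induces on four leaves: `"ab|cd"` when the first
#' two supplied taxa pair against the last two, similarly `"ac|bd"` and
#' `"ad|bc"`, or `"unresolved"` when the induced subtree is a star (possible
#' only in a multifurcating reference).
#'
#' @param tree An `ape::phylo`.
#' @param taxa Character vector of four leaf labels.
#' @return One of `"ab|cd"`, `"ac|bd"`, `"ad|bc"`, `"unresolved"`.
#' @export
quartet_topology <- function(tree, taxa) {
  stopifnot(length(taxa) == 4L)
  missing_taxa <- setdiff(taxa, tree$tip.label)
  if (length(missing_taxa) > 0) {
    abort(paste0("unknown taxon: ", missing_taxa[1]))
  }
  D <- unit_cophenetic(tree)
  code <- quartet_codes(D[taxa, taxa], matrix(1:4, ncol = 1))
  c("unresolved", "ab|cd", "ac|bd", "ad|bc")[code + 1L]
}

#' Quartet-topology agreement between two trees
#'
#' The fraction of *effective* quartets — those the reference resolves — on
#' which the inferred tree induces the same topology. Exact mode enumerates
#' all `choose(n, 4)` quartets (guarded to `n <= max_exact_n`); sampled mode
#' draws quartets uniformly with a seeded RNG, excluding unresolved reference
#' quartets from the denominator.
#'
#' @param inferred Binary `ape::phylo`.
#' @param reference `ape::phylo` with the same leaf set (may be
#'   multifurcating, e.g. from [taxonomy_tree()]).
#' @param mode `"exact"` or `"sampled"`; `"auto"` (default) picks exact up to
#'   `max_exact_n` leaves.
#' @param n_sampled Quartets to draw in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @param max_exact_n Leaf-count guard for exact enumeration.
#' @return A `quartet_result`: `n_effective`, `n_agreed`, `accuracy`
#'   (`NA` when no quartet is effective), `mode`, and `n_sampled`/`seed`
#'   when sampled.
#' @export
quartet_accuracy <- function(inferred, reference,
                             mode = c("auto", "exact", "sampled"),
                             n_sampled = 20000L, seed = 1L,
                             max_exact_n = 60L) {
  mode <- match.arg(mode)
  taxa <- sort(inferred$tip.label)
  if (!identical(taxa, sort(reference$tip.label))) {
    abort("inferred and reference trees have different leaf sets")
  }
  n <- length(taxa)
  if (n < 4) abort("quartet accuracy needs at least 4 taxa")
  if (mode == "auto") mode <- if (n <= max_exact_n) "exact" else "sampled"
  if (mode == "exact" && n > max_exact_n) {
    abort(paste0("exact enumeration guarded to ", max_exact_n,
                 " taxa; use mode = 'sampled'"))
  }
  Di <- unit_cophenetic(inferred)[taxa, taxa]
  Dr <- unit_cophenetic(reference)[taxa, taxa]
  if (mode == "exact") {
    quads <- combn(n, 4L)
  } else {
    quads <- with_seed(seed, {
      vapply(seq_len(n_sampled), function(i) sort(sample.int(n, 4L)),
             integer(4))
    })
  }
  ref_code <- quartet_codes(Dr, quads)
  inf_code <- quartet_codes(Di, quads)
  eff <- ref_code != 0L
  n_eff <- sum(eff)
  n_agree <- sum(ref_code[eff] == inf_code[eff])
  structure(
    list(n_effective = n_eff, n_agreed = n_agree,
         accuracy = if (n_eff == 0) NA_real_ else n_agree / n_eff,
         mode = mode,
         n_sampled = if (mode == "sampled") as.integer(n_sampled) else NA_integer_,
         seed = if (mode == "sampled") as.integer(seed) else NA_integer_),
    class = "quartet_result")
}

#' @export
print.quartet_result <- function(x, ...) {
  cat("<quartet_result> ", x$n_agreed, "/", x$n_effective,
      " effective quartets agree (accuracy ",
      if (is.na(x$accuracy)) "undefined" else format(x$accuracy, digits = 4),
      ", ", x$mode, ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.quartet_result <- function(x, ...) glance(x)

#' @exportS3Method generics::glance
glance.quartet_result <- function(x, ...) {
  tibble(n_effective = x$n_effective, n_agreed = x$n_agreed,
         accuracy = x$accuracy, mode = x$mode,
         n_sampled = x$n_sampled, seed = x$seed)
}

#' Write a quartet result as JSON
#' @param result A `quartet_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quartet_report <- function(result, path) {
  jsonlite::write_json(
    list(n_effective = result$n_effective, n_agreed = result$n_agreed,
         accuracy = result$accuracy, mode = result$mode,
         n_sampled = result$n_sampled, seed = result$seed),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
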