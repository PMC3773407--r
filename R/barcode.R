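#' Canonical k-mer classes
#'
#' A genome barcode pools each k-mer with its reverse complement, so for
#' k = 4 the 256 words collapse to 136 classes: 120 two-member classes plus
#' 16 palindromic words that are their own reverse complement. Classes are
#' keyed by the lexicographically smaller member and ordered alphabetically,
#' which fixes the column order of every barcode matrix.
#'
#' @param k Word size (default 4).
#' @return Tibble with columns `label` (e.g. `"AAAA|TTTT"`, palindromes keep a
#'   single word), `key`, and a list-column `members` of the words in the
#'   class.
#' @export
kmer_classes <- function(k = 4L) {
  words <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)[, k:1],
                      1, paste, collapse = ""))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  key <- pmin(words, rc)
  keys <- sort(unique(key))
  members <- lapply(keys, function(x) sort(unique(c(x, rc[words == x]))))
  label <- vapply(members, paste, "", collapse = "|")
  tibble(label = label, key = keys, members = members)
}

#' Compute the 4-mer barcode matrix of a genome
#'
#' The chromosome is cut into non-overlapping fragments of `L` bp (the
#' trailing partial fragment is discarded, so there are `N = floor(M/L)`
#' fragments for a genome of `M` bp). Row i, column c is the combined
#' frequency of class-c words (a k-mer pooled with its reverse complement)
#' among the `L - k + 1` windows of fragment i, normalised by the number of
#' unambiguous windows; windows containing non-ACGT characters are excluded
#' from both numerator and denominator.
#'
#' @param genome An [annotated_genome()] with sequence, or a raw sequence
#'   string.
#' @param L Fragment length in bp (default 1000).
#' @param k Word size (default 4).
#' @return A `barcode_matrix`: an N x 136 numeric matrix (for k = 4) with
#'   class labels as column names and attributes `genome_id`, `L`, `k`.
#' @export
compute_barcode <- function(genome, L = 1000L, k = 4L) {
  if (inherits(genome, "annotated_genome")) {
    if (is.null(genome$sequence)) {
      abort(paste0("genome ", genome$id, " has no sequence"))
    }
    seq <- genome$sequence
    gid <- genome$id
  } else {
    seq <- genome
    gid <- NA_character_
  }
  m <- nchar(seq)
  n_frag <- m %/% L
  if (n_frag < 1L) {
    abort(paste0("sequence length ", m, " is shorter than one fragment (L = ",
                 L, ")"))
  }
  starts <- (seq_len(n_frag) - 1L) * L + 1L
  frags <- Biostrings::DNAStringSet(
    substring(seq, starts, starts + L - 1L))
  counts <- Biostrings::oligonucleotideFrequency(frags, width = k, step = 1L)
  cls <- kmer_classes(k)
  word_key <- rep(cls$key, lengths(cls$members))
  names(word_key) <- unlist(cls$members)
  grp <- factor(word_key[colnames(counts)], levels = cls$key)
  pooled <- t(rowsum(t(counts), grp))
  denom <- rowSums(pooled)
  vals <- pooled / ifelse(denom == 0, 1, denom)
  colnames(vals) <- cls$label
  rownames(vals) <- NULL
  structure(vals, genome_id = gid, L = as.integer(L), k = as.integer(k),
            class = c("barcode_matrix", class(vals)))
}

#' @export
print.barcode_matrix <- function(x, ...) {
  cat("<barcode_matrix> ", attr(x, "genome_id"), ": ", nrow(x),
      " fragments of ", attr(x, "L"), " bp, ", ncol(x),
      " canonical ", attr(x, "k"), "-mer classes\n", sep = "")
  invisible(x)
}

#' Write a barcode matrix as TSV
#' @param bm A `barcode_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode <- function(bm, path) {
  tab <- as_tibble(unclass(bm))
  tab <- dplyr::bind_cols(tibble(fragment = seq_len(nrow(bm)) - 1L), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Fragment anomaly profile and genomic-evolution value
#'
#' The average barcode is the column-mean vector over all fragments;
#' `dis[i]` is the Euclidean distance between fragment i's barcode row and
#' the average; the genomic-evolution value is
#' `r_ge = mean(dis) + 3 * sd(dis)` (sample standard deviation). Fragments
#' far above the bulk of `dis` are compositionally abnormal and are the
#' candidates for foreign (horizontally transferred) segments.
#'
#' @param bm A `barcode_matrix` with at least two fragments.
#' @return An `anomaly_profile`: list with `genome_id`, `avg_barcode`
#'   (136-vector), `dis` (per-fragment distances) and `r_ge`.
#' @export
anomaly_profile <- function(bm) {
  if (nrow(bm) < 2L) {
    abort("anomaly profile needs at least 2 fragments (sd undefined)")
  }
  avg <- colMeans(bm)
  dis <- sqrt(rowSums(sweep(unclass(bm), 2, avg)^2))
  structure(
    list(genome_id = attr(bm, "genome_id"), avg_barcode = avg,
         dis = as.numeric(dis), r_ge = mean(dis) + 3 * sd(dis),
         L = attr(bm, "L")),
    class = "anomaly_profile")
}

#' @export
print.anomaly_profile <- function(x, ...) {
  cat("<anomaly_profile> ", x$genome_id, ": ", length(x$dis),
      " fragments, r_ge = ", format(x$r_ge, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.anomaly_profile <- function(x, ...) {
  tibble(genome_id = x$genome_id,
         fragment = seq_along(x$dis) - 1L,
         dis = x$dis)
}

#' @exportS3Method generics::glance
glance.anomaly_profile <- function(x, ...) {
  tibble(genome_id = x$genome_id, n_fragments = length(x$dis),
         mean_dis = mean(x$dis), sd_dis = sd(x$dis), r_ge = x$r_ge)
}

#' Rank fragments by barcode anomaly
#'
#' @param profile An [anomaly_profile()].
#' @return Integer vector of 0-based fragment indices sorted by decreasing
#'   anomaly distance; ties broken by ascending index.
#' @export
abnormal_fragments <- function(profile) {
  ord <- order(-profile$dis, seq_along(profile$dis))
  as.integer(ord - 1L)
}

#' Plot a fragment anomaly profile
#'
#' @param object An [anomaly_profile()].
#' @param ... Unused.
#' @return A ggplot: anomaly distance per fragment with the `r_ge` line.
#' @exportS3Method ggplot2::autoplot
autoplot.anomaly_profile <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fragment, y = .data$dis)) +
    ggplot2::geom_col(width = 1, fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$r_ge, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "fragment (0-based)", y = "distance to average barcode",
                  title = object$genome_id,
                  subtitle = paste0("r_ge = mean + 3·sd = ",
                                    format(object$r_ge, digits = 4))) +
    ggplot2::theme_minimal()
}
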