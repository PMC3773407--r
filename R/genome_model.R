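#' Annotated genome objects
#'
#' An `annotated_genome` bundles what the pipeline needs to know about one
#' single-chromosome prokaryotic genome: an ordered gene table, operon
#' membership, optionally the chromosome sequence, and optionally a Bergey-style
#' taxonomy code. Genes are kept sorted by start coordinate and carry a 0-based
#' `index` equal to their rank along the chromosome; that index is what the
#' operon-parsimony and gene-cluster stages reason about.
#'
#' @param id Genome identifier (accession-like, e.g. `"NC_000916"`).
#' @param genes A data frame with columns `gene_id`, `start`, `end`, `strand`
#'   and optionally `cog` (single-letter COG functional category) and `seq`.
#'   Coordinates are 1-based inclusive on the forward strand.
#' @param sequence Optional chromosome sequence as a single character string.
#' @param operons Optional data frame with columns `operon_id`, `gene_id`
#'   (one row per member gene) or a list as produced by [read_operon_table()].
#' @param name Human-readable name; defaults to `id`.
#' @param bergey_code Optional taxonomy code string (see [parse_bergey()]).
#'
#' @return An object of class `annotated_genome`: a list with elements `id`,
#'   `name`, `sequence`, `genes` (tibble, sorted by `start`, with `index` and
#'   `operon_id` columns) and `bergey_code`.
#' @export
#' @examples
#' g <- annotated_genome("G1", tibble::tibble(
#'   gene_id = c("a", "b"), start = c(1, 501), end = c(500, 1000),
#'   strand = c("+", "-")))
#' n_genes(g)
annotated_genome <- function(id, genes, sequence = NULL, operons = NULL,
                             name = id, bergey_code = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  genes <- as_tibble(genes)
  required <- c("gene_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table for ", id, " lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene id in genome ", id, ": ",
                 genes$gene_id[duplicated(genes$gene_id)][1]))
  }
  bad <- which(genes$end < genes$start)
  if (length(bad) > 0) {
    abort(paste0("gene table row ", bad[1], " (", genes$gene_id[bad[1]],
                 "): end < start"))
  }
  bad_strand <- which(!genes$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("gene table row ", bad_strand[1], ": unknown strand symbol '",
                 genes$strand[bad_strand[1]], "'"))
  }
  if (!"cog" %in% names(genes)) genes$cog <- NA_character_
  if (!"seq" %in% names(genes)) genes$seq <- NA_character_
  genes$cog[genes$cog %in% c("", "-", ".")] <- NA_character_
  genes <- arrange(genes, .data$start, .data$gene_id)
  genes$index <- seq_len(nrow(genes)) - 1L
  genes$operon_id <- NA_character_
  genes <- select(genes, "gene_id", "index", "start", "end", "strand",
                  "cog", "operon_id", "seq")
  if (!is.null(sequence)) {
    stopifnot(is.character(sequence), length(sequence) == 1L)
    m <- nchar(sequence)
    if (nrow(genes) > 0 && max(genes$end) > m) {
      abort(paste0("genome ", id, ": gene coordinates exceed sequence length ",
                   m))
    }
  }
  g <- structure(
    list(id = id, name = name, sequence = sequence, genes = genes,
         bergey_code = bergey_code),
    class = "annotated_genome")
  if (!is.null(operons)) g <- set_operons(g, operons)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  m <- if (is.null(x$sequence)) "no sequence" else
    paste0(format(nchar(x$sequence), big.mark = ","), " bp")
  n_op <- length(unique(stats::na.omit(x$genes$operon_id)))
  cat("<annotated_genome> ", x$id, " (", m, ", ", nrow(x$genes), " genes, ",
      n_op, " operons)\n", sep = "")
  invisible(x)
}

#' Number of genes in a genome
#' @param genome An [annotated_genome()].
#' @return Integer gene count.
#' @export
n_genes <- function(genome) nrow(genome$genes)

#' Read an ordered gene table
#'
#' Parses a tab-separated gene table with a header line and columns
#' `gene_id`, `start`, `end`, `strand` and optionally `cog` and `seq`.
#' Rows may appear in any order; genes are sorted by start coordinate and
#' indexed. Parsing is strict: a malformed row aborts with its row number.
#'
#' @param path Path to the TSV file.
#' @param genome_id Identifier for the resulting genome.
#' @inheritParams annotated_genome
#' @return An [annotated_genome()] without operon annotation.
#' @export
read_gene_table <- function(path, genome_id, sequence = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    strand = readr::col_character(), .default = readr::col_character()))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0("malformed gene table ", path, ": row ", probs$row[1], ", ",
                 probs$expected[1]))
  }
  if (any(is.na(tab$start) | is.na(tab$end))) {
    bad <- which(is.na(tab$start) | is.na(tab$end))[1]
    abort(paste0("malformed gene table ", path, ": row ", bad,
                 " has non-numeric coordinates"))
  }
  annotated_genome(genome_id, tab, sequence = sequence)
}

#' Write a gene table
#'
#' Inverse of [read_gene_table()]: the written file reads back to the same
#' gene list.
#'
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genome, path) {
  readr::write_tsv(select(genome$genes, "gene_id", "start", "end", "strand",
                          "cog", "seq"), path)
  invisible(path)
}

#' Attach operon membership to a genome
#'
#' Operon members must be contiguous along the chromosome. Declarations whose
#' members are not contiguous (as happens when an operon call straddles
#' re-annotated genes) are split into maximal contiguous runs with a warning;
#' split parts are suffixed `.1`, `.2`, ... Genes absent from every operon stay
#' unannotated and are treated as singleton operon units by the orthology
#' stage.
#'
#' @param genome An [annotated_genome()].
#' @param operons Data frame with columns `operon_id` and `gene_id`.
#' @return The genome with `operon_id` stamped onto its gene table.
#' @export
set_operons <- function(genome, operons) {
  operons <- as_tibble(operons)
  stopifnot(all(c("operon_id", "gene_id") %in% names(operons)))
  unknown <- setdiff(operons$gene_id, genome$genes$gene_id)
  if (length(unknown) > 0) {
    abort(paste0("operon table for ", genome$id,
                 " references unknown gene: ", unknown[1]))
  }
  if (anyDuplicated(operons$gene_id)) {
    dup <- operons$gene_id[duplicated(operons$gene_id)][1]
    abort(paste0("gene ", dup, " declared in two operons"))
  }
  idx <- setNames(genome$genes$index, genome$genes$gene_id)
  assign_col <- setNames(rep(NA_character_, nrow(genome$genes)),
                         genome$genes$gene_id)
  split_any <- FALSE
  for (op in unique(operons$operon_id)) {
    members <- operons$gene_id[operons$operon_id == op]
    members <- members[order(idx[members])]
    runs <- cumsum(c(1L, diff(idx[members]) != 1L))
    if (max(runs) > 1L) split_any <- TRUE
    for (r in unique(runs)) {
      part <- members[runs == r]
      part_id <- if (max(runs) == 1L) op else paste0(op, ".", r)
      assign_col[part] <- part_id
    }
  }
  if (split_any) {
    warn(paste0("genome ", genome$id,
                ": non-contiguous operon declaration(s) split into",
                " maximal contiguous runs"))
  }
  genome$genes$operon_id <- unname(assign_col[genome$genes$gene_id])
  genome
}

#' Read an operon table
#'
#' Tab-separated file without header: `operon_id<TAB>gene1,gene2,...`.
#' An empty file leaves the genome unchanged.
#'
#' @param path Path to the operon TSV.
#' @param genome An [annotated_genome()].
#' @return The genome with operon membership stamped on (see [set_operons()]).
#' @export
read_operon_table <- function(path, genome) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(genome)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0) {
    abort(paste0("malformed operon table ", path, ": line ", bad[1]))
  }
  tab <- bind_rows(lapply(parts, function(p) {
    tibble(operon_id = p[1],
           gene_id = strsplit(p[2], ",", fixed = TRUE)[[1]])
  }))
  set_operons(genome, tab)
}

#' Write an operon table
#' @param genome An [annotated_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_operon_table <- function(genome, path) {
  g <- filter(genome$genes, !is.na(.data$operon_id))
  if (nrow(g) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  by_op <- split(g$gene_id[order(g$index)], g$operon_id[order(g$index)])
  writeLines(paste0(names(by_op), "\t",
                    vapply(by_op, paste, "", collapse = ",")), path)
  invisible(path)
}

#' Read a genome sequence from FASTA
#'
#' One record per genome; multi-record files are rejected because the pipeline
#' is scoped to single-chromosome genomes.
#'
#' @param path FASTA path.
#' @return Character string with the sequence.
#' @export
read_genome_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (length(s) != 1L) {
    abort(paste0(path, " holds ", length(s), " records; the pipeline handles",
                 " single-chromosome genomes only"))
  }
  as.character(s[[1]])
}

#' Write a genome sequence to FASTA
#' @param genome An [annotated_genome()] with sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) abort(paste0(genome$id, " has no sequence"))
  s <- Biostrings::DNAStringSet(genome$sequence)
  names(s) <- genome$id
  Biostrings::writeXStringSet(s, path)
  invisible(path)
}

#' Parse a Bergey-style taxonomy code
#'
#' Bergey's Manual abbreviates a lineage as a dotted rank path, e.g.
#' `"B12.2.3.1.3"` for domain Bacteria, Phylum XII, Class II, Order III,
#' Family I, Genus III. The leading letter is the domain tag (`A` archaea,
#' `B` bacteria); the dotted integers are successive rank indices.
#'
#' @param code Code string matching `[AB]\\d+(\\.\\d+)*`.
#' @return A `bergey_code` object with fields `raw`, `domain_tag`, `ranks`.
#' @export
#' @examples
#' parse_bergey("B12.2.3.1.3")
parse_bergey <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!grepl("^[AB][0-9]+(\\.[0-9]+)*$", code)) {
    abort(paste0("malformed Bergey code: '", code, "'"))
  }
  structure(
    list(raw = code,
         domain_tag = substr(code, 1, 1),
         ranks = as.integer(strsplit(substr(code, 2, nchar(code)),
                                     ".", fixed = TRUE)[[1]])),
    class = "bergey_code")
}

#' @export
print.bergey_code <- function(x, ...) {
  cat("<bergey_code> ", x$raw, " (domain ", x$domain_tag, ", ",
      length(x$ranks), " ranks)\n", sep = "")
  invisible(x)
}

#' @export
format.bergey_code <- function(x, ...) x$raw

#' Shared lineage depth of two Bergey codes
#'
#' Length of the longest common prefix of `(domain, rank1, rank2, ...)`.
#' Two codes in different domains share depth 0; identical codes share
#' `1 + length(ranks)`.
#'
#' @param c1,c2 `bergey_code` objects or code strings.
#' @return Integer shared depth.
#' @export
shared_depth <- function(c1, c2) {
  if (is.character(c1)) c1 <- parse_bergey(c1)
  if (is.character(c2)) c2 <- parse_bergey(c2)
  if (c1$domain_tag != c2$domain_tag) return(0L)
  k <- min(length(c1$ranks), length(c2$ranks))
  same <- c1$ranks[seq_len(k)] == c2$ranks[seq_len(k)]
  1L + if (all(same)) k else which(!same)[1] - 1L
}

#' Read a taxonomy file
#'
#' One line per taxon: `genome_id<TAB>bergey_code`.
#'
#' @param path Path to the taxonomy TSV.
#' @return Tibble with columns `taxon` and `code`; codes are validated.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("taxon", "code"),
                         col_types = "cc")
  for (cd in tab$code) parse_bergey(cd)
  if (anyDuplicated(tab$taxon)) {
    abort(paste0("duplicate taxon in ", path))
  }
  tab
}
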