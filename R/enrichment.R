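#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated member
#' symbols. Members are deduplicated within a set, case preserved.
#'
#' @param path File path.
#' @return A `gene_set_collection`: long tibble with `set`,
#'   `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- purrr::imap_dfr(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields (need name, description, members)", i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(sprintf("GMT line %d ('%s') has an empty member list", i, fields[1]))
    }
    tibble(set = fields[1], description = fields[2], gene = genes)
  })
  class(out) <- c("gene_set_collection", class(out))
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided enrichment p-value is the exact
#' upper tail `P(X >= k)` of `Hypergeometric(N, K, n)`: `N` universe
#' genes, `K` of them in the set, `n` query genes drawn, `k` observed
#' in the set. Sets are restricted to the universe before testing;
#' query genes outside the universe are dropped with a warning.
#' Benjamini-Hochberg adjustment is applied across sets.
#'
#' @param query Character vector of query gene symbols (e.g. the
#'   unique nearest genes of a kME-limited module).
#' @param gene_sets A `gene_set_collection` from [read_gmt()] (or any
#'   tibble with `set` and `gene`).
#' @param universe Character vector of background gene symbols
#'   (typically the unique nearest genes of all post-QC probes).
#' @return Tibble sorted by p-value: `set`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`.
#' @export
hypergeometric_enrichment <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("dropping %d query gene(s) not in the universe", length(outside)))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  sets <- split(gene_sets$gene, gene_sets$set)
  out <- purrr::imap_dfr(sets, function(members, name) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = name, k = k, K = K, n = n, N = N, p_value = p)
  })
  out$q_value <- bh_adjust(out$p_value)
  dplyr::arrange(out, .data$p_value)
}

#' Enrichment of a kME-limited module
#'
#' Maps the limited module's probes to their nearest genes,
#' deduplicates to a gene query, and tests it against the collection
#' with the universe defaulting to all unique nearest genes in the
#' annotation (the post-QC background).
#'
#' @param limited Tibble from [limit_module()] (needs `probe_id`).
#' @param annotation Probe annotation tibble with `nearest_gene`.
#' @param gene_sets A `gene_set_collection`.
#' @param universe Background gene symbols; defaults to the unique
#'   nearest genes of the annotation.
#' @return See [hypergeometric_enrichment()].
#' @export
module_enrichment <- function(limited, annotation, gene_sets,
                              universe = NULL) {
  genes <- annotation$nearest_gene[match(limited$probe_id, annotation$probe_id)]
  genes <- unique(genes[!is.na(genes) & genes != "NA"])
  universe <- universe %||%
    unique(annotation$nearest_gene[!is.na(annotation$nearest_gene) &
                                     annotation$nearest_gene != "NA"])
  hypergeometric_enrichment(genes, gene_sets, universe)
}
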