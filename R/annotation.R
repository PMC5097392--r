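#' Assign each probe its nearest gene
#'
#' Probes use 1-based coordinates; gene intervals use BED half-open
#' `[start, end)` (0-based), so an interval covers 1-based positions
#' `start + 1 .. end`. Distance is 0 for a probe inside the interval,
#' otherwise the gap to the closer boundary. Ties are broken
#' alphabetically by gene symbol; assignment never crosses chromosomes,
#' and a probe on a chromosome without genes is assigned `NA`.
#'
#' @param probes Tibble with columns `probe_id`, `chromosome`, `position`.
#' @param genes Tibble with columns `chromosome`, `start`, `end`, `gene`
#'   (as from [read_gene_bed()]).
#' @return The `probes` tibble with `nearest_gene` and `gene_distance`
#'   columns appended.
#' @export
nearest_gene <- function(probes, genes) {
  stopifnot(all(c("probe_id", "chromosome", "position") %in% names(probes)),
            all(c("chromosome", "start", "end", "gene") %in% names(genes)))
  genes <- dplyr::arrange(genes, .data$gene)  # alphabetical tie-break by order
  by_chr <- split(genes, genes$chromosome)
  n <- nrow(probes)
  out_gene <- rep(NA_character_, n)
  out_dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- by_chr[[probes$chromosome[i]]]
    if (is.null(g) || nrow(g) == 0) next
    p <- probes$position[i]
    lo <- g$start + 1  # first 1-based position covered
    hi <- g$end        # last 1-based position covered
    d <- pmax(0, pmax(lo - p, p - hi))
    j <- which.min(d)  # first minimum = alphabetical winner
    out_gene[i] <- g$gene[j]
    out_dist[i] <- d[j]
  }
  dplyr::mutate(probes, nearest_gene = out_gene, gene_distance = out_dist)
}
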