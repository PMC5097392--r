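#' Read and write intensity matrices
#'
#' `read_intensity_data()` ingests either a directory holding four
#' co-indexed tab-delimited matrices (`meth.tsv`, `unmeth.tsv`,
#' `detection_p.tsv`, `beadcount.tsv`; header row of sample ids, first
#' column of probe ids) or a single long-format table with columns
#' `probe_id, sample_id, meth, unmeth, detection_p, beadcount`.
#' `write_intensity_data()` writes the four-matrix layout.
#' Row and column order are preserved from file (first appearance for
#' long format).
#'
#' @param path Directory of matrix files, or a long-format TSV file.
#' @return An [intensity_data] object.
#' @export
read_intensity_data <- function(path) {
  if (dir.exists(path)) {
    mats <- lapply(c("meth", "unmeth", "detection_p", "beadcount"),
                   function(nm) {
                     f <- file.path(path, paste0(nm, ".tsv"))
                     if (!file.exists(f)) abort(sprintf("missing matrix file '%s'", f))
                     read_matrix_tsv(f)
                   })
    names(mats) <- c("meth", "unmeth", "detection_p", "beadcount")
    for (nm in names(mats)[-1]) {
      if (!identical(dimnames(mats[[nm]]), dimnames(mats$meth))) {
        abort(sprintf("matrix '%s' is not co-indexed with 'meth' (ids or order differ)", nm))
      }
    }
    return(intensity_data(mats$meth, mats$unmeth, mats$detection_p, mats$beadcount))
  }
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probe_id", "sample_id", "meth", "unmeth", "detection_p", "beadcount")
  miss <- setdiff(need, names(long))
  if (length(miss) > 0) {
    abort(sprintf("long-format table is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  probes <- unique(long$probe_id)
  samples <- unique(long$sample_id)
  if (anyDuplicated(paste(long$probe_id, long$sample_id))) {
    abort("duplicated (probe, sample) record in long-format table")
  }
  build <- function(col) {
    m <- matrix(NA_real_, length(probes), length(samples),
                dimnames = list(probes, samples))
    m[cbind(match(long$probe_id, probes), match(long$sample_id, samples))] <- long[[col]]
    if (anyNA(m)) abort("long-format table does not cover every (probe, sample) cell")
    m
  }
  intensity_data(build("meth"), build("unmeth"),
                 build("detection_p"), build("beadcount"))
}

#' @rdname read_intensity_data
#' @param x An [intensity_data] object.
#' @export
write_intensity_data <- function(x, path) {
  stopifnot(inherits(x, "intensity_data"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (nm in c("meth", "unmeth", "detection_p", "beadcount")) {
    write_matrix_tsv(x[[nm]], file.path(path, paste0(nm, ".tsv")))
  }
  invisible(path)
}

read_matrix_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- d[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate probe id '%s' in %s",
                  ids[duplicated(ids)][1], basename(path)))
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

write_matrix_tsv <- function(m, path) {
  d <- tibble::as_tibble(m, rownames = "probe_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Tab-delimited, mandatory columns `probe_id`, `chromosome`,
#' `position`, `nearest_gene`, `snp_within_5bp`, `repeat_region`.
#' Boolean columns are parsed from `{0, 1, true, false}`
#' (case-insensitive). Chromosomes are kept as labels; `X`/`Y` mark the
#' sex chromosomes.
#'
#' @param path File path.
#' @return A tibble, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("probe_id", "chromosome", "position", "nearest_gene",
            "snp_within_5bp", "repeat_region")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(sprintf("annotation is missing mandatory column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  out <- tibble(
    probe_id = d$probe_id,
    chromosome = gsub("^chr", "", d$chromosome),
    position = as.integer(d$position),
    nearest_gene = d$nearest_gene,
    snp_within_5bp = parse_boolean(d$snp_within_5bp, "snp_within_5bp"),
    repeat_region = parse_boolean(d$repeat_region, "repeat_region")
  )
  if (anyDuplicated(out$probe_id)) {
    abort(sprintf("duplicate probe id '%s' in annotation",
                  out$probe_id[duplicated(out$probe_id)][1]))
  }
  if (any(!is.na(out$position) & out$position < 1)) {
    abort("annotation positions must be >= 1 (1-based coordinates)")
  }
  out
}

#' Read a sample sheet
#'
#' Tab-delimited, mandatory columns `sample_id`, `copd_case`, `age`,
#' `gender`, `pack_years`, `batch`; optional `cohort` and
#' `replicate_of`. Missing covariates are preserved as `NA` (never
#' imputed) and summarised in the derived `covariates_complete` column,
#' which subject-level QC uses for removal.
#'
#' @param path File path.
#' @return A tibble, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()),
                       na = c("", "NA"))
  need <- c("sample_id", "copd_case", "age", "gender", "pack_years", "batch")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(sprintf("sample sheet is missing mandatory column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  out <- tibble(
    sample_id = d$sample_id,
    copd_case = parse_boolean(d$copd_case, "copd_case"),
    age = as.numeric(d$age),
    gender = tolower(d$gender),
    pack_years = as.numeric(d$pack_years),
    batch = d$batch,
    cohort = if ("cohort" %in% names(d)) d$cohort else NA_character_,
    replicate_of = if ("replicate_of" %in% names(d)) d$replicate_of else NA_character_
  )
  validate_sample_sheet(out)
}

validate_sample_sheet <- function(out) {
  if (anyDuplicated(out$sample_id)) {
    abort(sprintf("duplicate sample id '%s' in sample sheet",
                  out$sample_id[duplicated(out$sample_id)][1]))
  }
  bad_g <- setdiff(unique(out$gender[!is.na(out$gender)]), c("male", "female"))
  if (length(bad_g) > 0) {
    abort(sprintf("gender must be male/female; found: %s",
                  paste(bad_g, collapse = ", ")))
  }
  if (any(!is.na(out$age) & out$age <= 0)) abort("age must be > 0")
  if (any(!is.na(out$pack_years) & out$pack_years < 0)) abort("pack_years must be >= 0")
  bad_rep <- setdiff(out$replicate_of[!is.na(out$replicate_of)], out$sample_id)
  if (length(bad_rep) > 0) {
    abort(sprintf("replicate_of refers to unknown sample id(s): %s",
                  paste(bad_rep, collapse = ", ")))
  }
  out$covariates_complete <-
    !is.na(out$copd_case) & !is.na(out$age) & !is.na(out$gender) &
    !is.na(out$pack_years) & !is.na(out$batch)
  out
}

parse_boolean <- function(x, label) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true")] <- TRUE
  out[v %in% c("0", "false")] <- FALSE
  bad <- !is.na(v) & v != "" & is.na(out)
  if (any(bad)) {
    abort(sprintf("column '%s': cannot parse '%s' as boolean (expect 0/1/true/false)",
                  label, v[bad][1]))
  }
  out
}

#' Read gene intervals from a BED file
#'
#' BED semantics: 0-based, half-open `[start, end)`; at least four
#' columns (chrom, start, end, name), no header.
#'
#' @param path File path.
#' @return Tibble with columns `chromosome`, `start`, `end`, `gene`.
#' @export
read_gene_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE, comment = "#")
  if (ncol(d) < 4) abort("BED file must have at least 4 columns (chrom, start, end, name)")
  tibble(chromosome = gsub("^chr", "", as.character(d[[1]])),
         start = as.numeric(d[[2]]), end = as.numeric(d[[3]]),
         gene = as.character(d[[4]]))
}

#' Write a results table
#'
#' Tab-delimited output with stable column order and full-precision
#' numerics; `digits` optionally applies fixed-decimal rounding to
#' numeric columns (ids and counts excepted where integer).
#'
#' @param results Any of the pipeline's result tibbles.
#' @param path Output file.
#' @param digits Optional number of decimal places for numeric columns.
#' @export
write_results_table <- function(results, path, digits = NULL) {
  out <- as_tibble(results)
  if (!is.null(digits)) {
    num <- vapply(out, function(c) is.numeric(c) && !is.integer(c), logical(1))
    out[num] <- lapply(out[num], function(c) formatC(c, digits = digits, format = "f"))
  }
  readr::write_tsv(out, path)
  invisible(path)
}
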