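#' Methylation array intensity container
#'
#' Bundles the four co-indexed probes-by-samples matrices a 27K-style
#' methylation array produces: methylated and unmethylated fluorescence
#' intensities, per-measurement detection p-values, and beadcounts.
#' All downstream stages (QC, beta/M transforms, deconvolution, EWAS,
#' network analysis) consume this container.
#'
#' @param meth,unmeth Nonnegative numeric matrices (probes x samples) of
#'   methylated / unmethylated bead-type intensities, with probe ids as
#'   rownames and sample ids as colnames.
#' @param detection_p Matrix of detection p-values in `[0, 1]`, same
#'   shape and dimnames.
#' @param beadcount Nonnegative integer matrix of bead counts, same
#'   shape and dimnames.
#'
#' @return An object of class `intensity_data`: a list of the four
#'   matrices with validated, shared dimnames.
#' @export
intensity_data <- function(meth, unmeth, detection_p, beadcount) {
  mats <- list(meth = meth, unmeth = unmeth,
               detection_p = detection_p, beadcount = beadcount)
  for (nm in names(mats)) {
    if (!is.matrix(mats[[nm]])) mats[[nm]] <- as.matrix(mats[[nm]])
  }
  ref_dim <- dim(mats$meth)
  for (nm in names(mats)) {
    if (!identical(dim(mats[[nm]]), ref_dim)) {
      abort(sprintf("matrix '%s' has shape %s, expected %s", nm,
                    paste(dim(mats[[nm]]), collapse = "x"),
                    paste(ref_dim, collapse = "x")))
    }
  }
  probes <- rownames(mats$meth)
  samples <- colnames(mats$meth)
  if (is.null(probes) || is.null(samples)) {
    abort("meth matrix must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(probes)) {
    abort(sprintf("duplicate probe id(s): %s",
                  paste(unique(probes[duplicated(probes)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  for (nm in names(mats)) dimnames(mats[[nm]]) <- list(probes, samples)

  check_nonneg <- function(m, label) {
    bad <- which(m < 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(sprintf("negative %s at probe '%s', sample '%s'", label,
                    probes[bad[1, 1]], samples[bad[1, 2]]))
    }
  }
  check_nonneg(mats$meth, "meth intensity")
  check_nonneg(mats$unmeth, "unmeth intensity")
  check_nonneg(mats$beadcount, "beadcount")
  if (any(mats$detection_p < 0 | mats$detection_p > 1)) {
    abort("detection_p values must lie in [0, 1]")
  }
  structure(mats, class = "intensity_data")
}

#' @export
print.intensity_data <- function(x, ...) {
  cat(sprintf("<intensity_data> %d probes x %d samples\n",
              nrow(x$meth), ncol(x$meth)))
  cat("  matrices: meth, unmeth, detection_p, beadcount\n")
  invisible(x)
}

#' @export
dim.intensity_data <- function(x) dim(x$meth)

#' Probe and sample ids of an intensity container
#' @param x An `intensity_data` object.
#' @return Character vector of ids.
#' @export
probe_ids <- function(x) rownames(x$meth)

#' @rdname probe_ids
#' @export
sample_ids <- function(x) colnames(x$meth)

#' Subset an intensity container
#'
#' Subsets all four matrices jointly, by probe and/or sample (index,
#' logical, or id character vectors).
#'
#' @param x An `intensity_data` object.
#' @param i Probe selector.
#' @param j Sample selector.
#' @param ... Ignored.
#' @export
`[.intensity_data` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$meth))
  if (missing(j)) j <- seq_len(ncol(x$meth))
  intensity_data(x$meth[i, j, drop = FALSE],
                 x$unmeth[i, j, drop = FALSE],
                 x$detection_p[i, j, drop = FALSE],
                 x$beadcount[i, j, drop = FALSE])
}
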