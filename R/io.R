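#' @title File formats
#' @description Tab-delimited dialects for peak tables (GeneMapper-export
#'   style), sample truth / genotype-call tables, and run manifests.  All
#'   formats are plain text, UTF-8, tab-separated, with `.` for missing
#'   values.
#' @name io
NULL

#' Write peak tables to TSV
#'
#' Sized mode writes `sample  dye  size  height`; raw mode writes
#' `sample  dye  raw  height` plus a sidecar ladder TSV (`raw  size`) so the
#' reader must perform size calling.
#'
#' @param peak_tables list of `lg_peak_table`.
#' @param path output TSV path.
#' @param mode `"sized"` or `"raw"`.
#' @param ladder_path ladder sidecar path (raw mode); default
#'   `<path>.ladder.tsv`.
#' @return `path`, invisibly.
#' @export
write_peaks_tsv <- function(peak_tables, path, mode = c("sized", "raw"),
                            ladder_path = paste0(path, ".ladder.tsv")) {
  mode <- match.arg(mode)
  if (inherits(peak_tables, "lg_peak_table")) peak_tables <- list(peak_tables)
  rows <- lapply(peak_tables, function(pt) {
    p <- pt$peaks
    if (nrow(p) == 0) return(NULL)
    if (mode == "sized")
      data.frame(sample = pt$sample_id, dye = p$dye, size = p$size,
                 height = p$height, stringsAsFactors = FALSE)
    else
      data.frame(sample = pt$sample_id, dye = p$dye, raw = p$raw,
                 height = p$height, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (mode == "raw") {
    utils::write.table(peak_tables[[1]]$ladder, ladder_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read peak tables from TSV
#'
#' Accepts both dialects written by [write_peaks_tsv()]; raw mode requires
#' the ladder sidecar.
#'
#' @param path peaks TSV path.
#' @param ladder_path ladder sidecar TSV (`raw  size`); required when the
#'   peaks file is in raw mode.
#' @return list of `lg_peak_table`, one per distinct sample, in file order.
#' @export
read_peaks_tsv <- function(path, ladder_path = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no peaks in ", path)
  need <- c("sample", "dye", "height")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  raw_mode <- "raw" %in% names(tab) && !"size" %in% names(tab)
  if (!raw_mode && !"size" %in% names(tab))
    stop(path, ": needs a 'size' or 'raw' column")
  bad <- which(!tab$dye %in% .DYES)
  if (length(bad) > 0)
    stop(path, ": line ", bad[1] + 1, ": unknown dye '", tab$dye[bad[1]], "'")
  bad <- which(!is.finite(tab$height) | tab$height <= 0)
  if (length(bad) > 0)
    stop(path, ": line ", bad[1] + 1, ": non-positive peak height")
  ladder <- NULL
  if (raw_mode) {
    if (is.null(ladder_path))
      stop(path, " is in raw-migration mode; a ladder TSV is required")
    ladder <- utils::read.table(ladder_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    if (!all(c("raw", "size") %in% names(ladder)))
      stop(ladder_path, ": ladder needs columns 'raw' and 'size'")
  }
  ids <- unique(tab$sample)
  lapply(ids, function(id) {
    p <- tab[tab$sample == id, , drop = FALSE]
    peaks <- data.frame(dye = p$dye,
                        raw = if ("raw" %in% names(p)) p$raw else NA_real_,
                        size = if ("size" %in% names(p)) p$size else NA_real_,
                        height = p$height, stringsAsFactors = FALSE)
    structure(list(sample_id = id, peaks = peaks, ladder = ladder),
              class = "lg_peak_table")
  })
}

#' Write sample truths to TSV
#'
#' Format: `sample  variant  gt  mt_fraction` with VCF-style genotype
#' strings; only non-reference genotypes are written, plus one `.` row for
#' variant-free samples so the sample roster is preserved.
#'
#' @param truths list of [sample_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truths, path) {
  rows <- lapply(truths, function(t) {
    if (length(t$genotypes) == 0)
      return(data.frame(sample = t$sample_id, variant = ".", gt = ".",
                        mt_fraction = ".", stringsAsFactors = FALSE))
    do.call(rbind, lapply(names(t$genotypes), function(v) {
      g <- t$genotypes[[v]]
      if (is.numeric(g))
        data.frame(sample = t$sample_id, variant = v,
                   gt = if (g >= 0.95) "1/1" else if (g <= 0.05) "0/0" else "0/1",
                   mt_fraction = format(g), stringsAsFactors = FALSE)
      else
        data.frame(sample = t$sample_id, variant = v,
                   gt = c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[[g]],
                   mt_fraction = ".", stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample truths from TSV
#'
#' @param path TSV written by [write_truth_tsv()].
#' @param panel an `lg_panel` (used to recognize mitochondrial loci).
#' @return list of [sample_truth()].
#' @export
read_truth_tsv <- function(path, panel) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("sample", "variant", "gt") %in% names(tab)))
    stop(path, ": needs columns sample, variant, gt")
  mt_vars <- panel$variants$name[panel$variants$inheritance == "MT"]
  ids <- unique(tab$sample)
  lapply(ids, function(id) {
    rows <- tab[tab$sample == id & tab$variant != ".", , drop = FALSE]
    g <- list()
    for (i in seq_len(nrow(rows))) {
      v <- rows$variant[i]
      if (v %in% mt_vars) {
        g[[v]] <- if (!is.null(rows$mt_fraction) && rows$mt_fraction[i] != ".")
          as.numeric(rows$mt_fraction[i])
        else c(`0/0` = 0, `0/1` = 0.5, `1/1` = 1)[[rows$gt[i]]]
      } else {
        g[[v]] <- c(`0/0` = "hom_ref", `0/1` = "het", `1/1` = "hom_alt")[[rows$gt[i]]]
      }
    }
    sample_truth(id, g)
  })
}

#' Write a genotype call matrix to TSV
#'
#' Long format `sample  variant  gt  mt_fraction` covering every
#' (sample, variant) cell.
#'
#' @param calls genotype matrix from [call_batch()] or [truth_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  mt <- attr(calls, "mt_fraction")
  rows <- expand.grid(sample = rownames(calls), variant = colnames(calls),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$gt <- calls[cbind(rows$sample, rows$variant)]
  rows$mt_fraction <- if (is.null(mt)) "." else {
    x <- mt[cbind(rows$sample, rows$variant)]
    ifelse(is.na(x), ".", format(x))
  }
  rows <- rows[order(match(rows$sample, rownames(calls)),
                     match(rows$variant, colnames(calls))), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype call matrix from TSV
#'
#' @param path TSV written by [write_calls_tsv()].
#' @return genotype matrix with `mt_fraction` attribute.
#' @export
read_calls_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("sample", "variant", "gt") %in% names(tab)))
    stop(path, ": needs columns sample, variant, gt")
  ids <- unique(tab$sample); vars <- unique(tab$variant)
  m <- matrix("./.", nrow = length(ids), ncol = length(vars),
              dimnames = list(ids, vars))
  mt <- matrix(NA_real_, nrow = length(ids), ncol = length(vars),
               dimnames = dimnames(m))
  m[cbind(tab$sample, tab$variant)] <- tab$gt
  if ("mt_fraction" %in% names(tab)) {
    keep <- tab$mt_fraction != "."
    mt[cbind(tab$sample[keep], tab$variant[keep])] <-
      as.numeric(tab$mt_fraction[keep])
  }
  attr(m, "mt_fraction") <- mt
  m
}

#' Write a JSON run manifest
#'
#' Records inputs, outputs, seeds and package version so that a pipeline run
#' can be reproduced byte-identically.
#'
#' @param path manifest path.
#' @param command subcommand name.
#' @param inputs,outputs named lists of file paths.
#' @param seed integer seed(s) used.
#' @param extra optional named list of additional settings.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, inputs = list(), outputs = list(),
                           seed = NULL, extra = list()) {
  obj <- c(list(tool = "ligatyper",
                version = as.character(utils::packageVersion("ligatyper")),
                command = command, inputs = inputs, outputs = outputs,
                seed = seed), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
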