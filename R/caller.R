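#' @title Genotype calling from peak tables
#' @description Decoding pipeline: ladder-based size calling (local Southern
#'   with linear fallback), peak-to-product matching in the dye/size plane,
#'   allele-ratio zygosity calling, batch calling, and truth concordance.
#' @name caller
NULL

#' Calling thresholds
#'
#' @param min_height minimum peak height (RFU) for a peak to enter calling;
#'   sub-threshold peaks are treated as baseline and ignored.
#' @param het_band allele-ratio interval (alt / (ref + alt)) called
#'   heterozygous.
#' @param hom_override ratios below the first element call the majority
#'   homozygote hom_ref, above the second hom_alt; ratios between the
#'   override bounds and the het band are ambiguous no-calls.
#' @param mt_homoplasmy_min homoplasmy fraction at or above which a
#'   mitochondrial locus is reported homoplasmic-alt (and `1 -` it,
#'   homoplasmic-ref).
#' @param size_tolerance half-width (nt) of the product matching window;
#'   `NULL` uses the panel's declared tolerance.
#' @return list of class `lg_thresholds`.
#' @export
call_thresholds <- function(min_height = 100, het_band = c(0.25, 0.75),
                            hom_override = c(0.1, 0.9),
                            mt_homoplasmy_min = 0.95, size_tolerance = NULL) {
  stopifnot(min_height > 0, length(het_band) == 2, het_band[1] < het_band[2],
            length(hom_override) == 2,
            hom_override[1] <= het_band[1], hom_override[2] >= het_band[2],
            mt_homoplasmy_min > 0.5, mt_homoplasmy_min <= 1)
  structure(list(min_height = min_height, het_band = het_band,
                 hom_override = hom_override,
                 mt_homoplasmy_min = mt_homoplasmy_min,
                 size_tolerance = size_tolerance),
            class = "lg_thresholds")
}

# -------------------------------------------------------------------------
# Size calling
# -------------------------------------------------------------------------

# fit size = c + a / (m - b) through three (m, L) ladder points; returns the
# evaluator or NULL when the triplet is (near-)collinear or the pole falls
# inside the migration interval
.southern_fit <- function(m, L) {
  r <- (L[1] - L[3]) / (L[1] - L[2])
  den <- (m[3] - m[1]) - r * (m[2] - m[1])
  if (!is.finite(den) || abs(den) < 1e-9 * abs(m[3] - m[1])) return(NULL)
  b <- ((m[3] - m[1]) * m[2] - r * (m[2] - m[1]) * m[3]) / den
  if (b >= min(m) && b <= max(m)) return(NULL)
  a <- (L[1] - L[2]) * (m[1] - b) * (m[2] - b) / (m[2] - m[1])
  cc <- L[1] - a / (m[1] - b)
  function(x) cc + a / (x - b)
}

.linear_interp <- function(x, m1, m2, L1, L2) L1 + (x - m1) * (L2 - L1) / (m2 - m1)

#' Convert raw migration units to fragment sizes against a ladder
#'
#' Local Southern sizing: for a peak between ladder points i and i+1, the
#' reciprocal curve `L = c + a/(m - b)` is fitted through each bracketing
#' triplet (i-1, i, i+1) and (i, i+1, i+2) and the two estimates averaged
#' (one triplet at the ladder ends).  Collinear triplets degenerate to
#' linear interpolation.  Peaks outside the ladder span are sized by linear
#' extrapolation from the terminal pair and flagged `off_size`.
#'
#' @param raw numeric vector of raw migration units.
#' @param ladder data.frame with columns `raw`, `size`, >= 4 points, strictly
#'   increasing in both.
#' @return data.frame with columns `raw`, `size`, `off_size` (logical); the
#'   raw -> size mapping is strictly monotone.
#' @export
size_call <- function(raw, ladder) {
  stopifnot(all(c("raw", "size") %in% names(ladder)))
  if (nrow(ladder) < 4)
    stop("ladder must have at least 4 points")
  if (any(diff(ladder$raw) <= 0) || any(diff(ladder$size) <= 0))
    stop("ladder must be strictly increasing in raw units and size")
  m <- ladder$raw; L <- ladder$size; n <- nrow(ladder)
  one <- function(x) {
    if (x < m[1] || x > m[n]) {
      idx <- if (x < m[1]) c(1, 2) else c(n - 1, n)
      return(c(.linear_interp(x, m[idx[1]], m[idx[2]], L[idx[1]], L[idx[2]]), TRUE))
    }
    i <- findInterval(x, m, rightmost.closed = TRUE)  # m[i] <= x <= m[i+1]
    ests <- numeric(0)
    for (tri in list(if (i >= 2) (i - 1):(i + 1), if (i + 2 <= n) i:(i + 2))) {
      if (is.null(tri)) next
      f <- .southern_fit(m[tri], L[tri])
      ests <- c(ests, if (is.null(f))
        .linear_interp(x, m[i], m[i + 1], L[i], L[i + 1]) else f(x))
    }
    c(mean(ests), FALSE)
  }
  res <- t(vapply(raw, one, numeric(2)))
  data.frame(raw = raw, size = res[, 1], off_size = as.logical(res[, 2]))
}

# -------------------------------------------------------------------------
# Product matching
# -------------------------------------------------------------------------

#' Match sized peaks to panel ligation products
#'
#' Each peak is assigned to the product sharing its dye whose expected size
#' lies within `size_tolerance`; by the panel layout invariant at most one
#' product can match.  When several peaks match one product the tallest is
#' kept and the locus is flagged `ambiguous`.
#'
#' @param panel an `lg_panel`.
#' @param peaks data.frame with columns `dye`, `size`, `height`.
#' @param size_tolerance matching half-window (nt); default panel tolerance.
#' @return named list (by variant name): `heights` named numeric per allele
#'   (`ref`, `alt`, optionally `alt2`; 0 when absent) and `flags` character.
#' @export
match_products <- function(panel, peaks, size_tolerance = panel$tolerance) {
  pr <- panel$products
  out <- list()
  for (v in panel$variants$name) {
    alleles <- pr$allele[pr$variant == v]
    out[[v]] <- list(heights = stats::setNames(numeric(length(alleles)), alleles),
                     flags = character())
  }
  if (nrow(peaks) > 0) {
    for (j in seq_len(nrow(pr))) {
      hit <- peaks$dye == pr$dye[j] &
        abs(peaks$size - pr$size[j]) <= size_tolerance + 1e-9
      if (!any(hit)) next
      hs <- peaks$height[hit]
      v <- pr$variant[j]; al <- pr$allele[j]
      out[[v]]$heights[[al]] <- max(hs)
      if (sum(hit) > 1)
        out[[v]]$flags <- union(out[[v]]$flags, "ambiguous")
    }
  }
  out
}

# -------------------------------------------------------------------------
# Locus calling
# -------------------------------------------------------------------------

#' Call zygosity at one locus from matched allele peak heights
#'
#' Nuclear loci: with no above-threshold peak the locus is a `no_call`
#' (`low_signal`); a single-allele signal calls the corresponding homozygote;
#' with both alleles present the allele ratio `alt/(ref+alt)` calls het
#' inside the het band, the majority homozygote beyond the override bounds,
#' and an ambiguous no-call in between.  Mitochondrial loci report the
#' homoplasmy fraction: `>= mt_homoplasmy_min` homoplasmic alt (genotype
#' `1/1`), `<= 1 - mt_homoplasmy_min` reference, else heteroplasmic (`0/1`).
#' Tri-allelic loci are called ref against the strongest alt allele.
#'
#' @param variant one row of a panel's variant table (needs `name`,
#'   `inheritance`).
#' @param heights named numeric: per-allele matched peak heights (RFU).
#' @param thresholds an [call_thresholds()] object.
#' @param flags carried-over matching flags.
#' @return one-row data.frame: `variant`, `call`, `gt`, `ref_height`,
#'   `alt_height`, `allele_ratio`, `mt_fraction`, `which_alt`, `flags`.
#' @export
call_locus <- function(variant, heights, thresholds = call_thresholds(),
                       flags = character()) {
  r <- if ("ref" %in% names(heights)) heights[["ref"]] else 0
  alt_names <- setdiff(names(heights), "ref")
  alts <- heights[alt_names]
  if (length(alts) == 0) alts <- c(alt = 0)
  # sub-threshold peaks are baseline: drop them before ratio computation
  r <- if (r >= thresholds$min_height) r else 0
  alts[alts < thresholds$min_height] <- 0
  which_alt <- if (all(alts == 0)) "alt" else names(alts)[which.max(alts)]
  a <- max(alts)
  is_mt <- identical(variant$inheritance, "MT")
  ratio <- if (r + a > 0) a / (r + a) else NA_real_
  mt_fraction <- if (is_mt) ratio else NA_real_
  if (r == 0 && a == 0) {
    call <- "no_call"; flags <- union(flags, "low_signal")
  } else if (is_mt) {
    call <- if (ratio >= thresholds$mt_homoplasmy_min) "hom_alt"
    else if (ratio <= 1 - thresholds$mt_homoplasmy_min) "hom_ref"
    else "het"
  } else if (a == 0) {
    call <- "hom_ref"
  } else if (r == 0) {
    call <- "hom_alt"
  } else if (ratio >= thresholds$het_band[1] && ratio <= thresholds$het_band[2]) {
    call <- "het"
  } else if (ratio < thresholds$hom_override[1]) {
    call <- "hom_ref"
  } else if (ratio > thresholds$hom_override[2]) {
    call <- "hom_alt"
  } else {
    call <- "no_call"; flags <- union(flags, "ambiguous")
  }
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", no_call = "./.")[[call]]
  data.frame(variant = variant$name, call = call, gt = gt,
             ref_height = r, alt_height = a,
             allele_ratio = ratio, mt_fraction = mt_fraction,
             which_alt = which_alt,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Call all panel loci for one sample
#'
#' Runs the full decoding pipeline: size calling (when the peak table is in
#' raw migration units and carries a ladder), product matching, and per-locus
#' zygosity calling.
#'
#' @param panel an `lg_panel`.
#' @param peak_table an `lg_peak_table` (from [simulate_sample()] or
#'   [read_peaks_tsv()]).
#' @param thresholds an [call_thresholds()] object.
#' @return data.frame of class `lg_calls`, one row per panel variant.
#' @export
call_sample <- function(panel, peak_table, thresholds = call_thresholds()) {
  stopifnot(inherits(peak_table, "lg_peak_table"))
  tol <- if (is.null(thresholds$size_tolerance)) panel$tolerance
         else thresholds$size_tolerance
  peaks <- peak_table$peaks
  need_sizing <- (!"size" %in% names(peaks)) ||
    (nrow(peaks) > 0 && all(is.na(peaks$size)))
  if (need_sizing) {
    if (is.null(peak_table$ladder) || nrow(peak_table$ladder) == 0)
      stop("peak table has raw units only and no ladder; cannot size-call")
    sized <- size_call(peaks$raw, peak_table$ladder)
    peaks$size <- sized$size
    peaks <- peaks[!sized$off_size, , drop = FALSE]
  }
  matched <- match_products(panel, peaks, tol)
  rows <- lapply(seq_len(nrow(panel$variants)), function(i) {
    v <- panel$variants[i, ]
    m <- matched[[v$name]]
    call_locus(v, m$heights, thresholds, m$flags)
  })
  out <- do.call(rbind, rows)
  attr(out, "sample_id") <- peak_table$sample_id
  class(out) <- c("lg_calls", class(out))
  out
}

#' Call a batch of peak tables into a genotype matrix
#'
#' @param panel an `lg_panel`.
#' @param peak_tables list of `lg_peak_table`.
#' @param thresholds an [call_thresholds()] object.
#' @return character matrix (samples x variants) of genotype strings with
#'   attribute `mt_fraction` (numeric matrix of homoplasmy fractions at
#'   mitochondrial loci).
#' @export
call_batch <- function(panel, peak_tables, thresholds = call_thresholds()) {
  vars <- panel$variants$name
  ids <- vapply(peak_tables, `[[`, "", "sample_id")
  m <- matrix("./.", nrow = length(peak_tables), ncol = length(vars),
              dimnames = list(ids, vars))
  mt <- matrix(NA_real_, nrow = length(peak_tables), ncol = length(vars),
               dimnames = dimnames(m))
  for (i in seq_along(peak_tables)) {
    calls <- call_sample(panel, peak_tables[[i]], thresholds)
    m[i, calls$variant] <- calls$gt
    mt[i, calls$variant] <- calls$mt_fraction
  }
  attr(m, "mt_fraction") <- mt
  m
}

# -------------------------------------------------------------------------
# Concordance
# -------------------------------------------------------------------------

#' Concordance of called genotypes against truth
#'
#' Evaluated per (sample, locus) cell.  Sensitivity is the fraction of
#' truth-positive cells (truth genotype not `0/0`) called with exactly the
#' true zygosity; an exact zygosity mismatch (e.g. het called homozygous)
#' counts as discordant.  Specificity is the fraction of truth-negative
#' cells called `0/0`.
#'
#' @param truth,calls character genotype matrices with matching dimnames
#'   (see [truth_matrix()], [call_batch()]).
#' @return list of class `lg_concordance`: `sensitivity`, `specificity`
#'   (percent), `n_positive`, `n_negative`, `discordant` (data.frame), and a
#'   per-variant confusion table.
#' @export
concordance <- function(truth, calls) {
  if (!identical(dim(truth), dim(calls)) ||
      !identical(dimnames(truth), dimnames(calls)))
    stop("truth and call matrices must share sample/variant axes")
  pos <- truth != "0/0"
  exact <- calls == truth
  n_pos <- sum(pos); n_neg <- sum(!pos)
  sens <- if (n_pos > 0) 100 * sum(exact & pos) / n_pos else NA_real_
  spec <- if (n_neg > 0) 100 * sum(exact & !pos) / n_neg else NA_real_
  bad <- which(!exact, arr.ind = TRUE)
  discordant <- data.frame(
    sample = rownames(truth)[bad[, 1]],
    variant = colnames(truth)[bad[, 2]],
    truth = truth[bad], called = calls[bad],
    stringsAsFactors = FALSE)
  per_variant <- lapply(colnames(truth), function(v)
    table(truth = truth[, v], called = calls[, v]))
  names(per_variant) <- colnames(truth)
  structure(list(sensitivity = sens, specificity = spec,
                 n_positive = n_pos, n_negative = n_neg,
                 discordant = discordant, per_variant = per_variant),
            class = "lg_concordance")
}

#' @export
print.lg_concordance <- function(x, ...) {
  cat(sprintf("Concordance over %d positive and %d negative (sample, locus) cells\n",
              x$n_positive, x$n_negative))
  cat(sprintf("  sensitivity: %.2f%%   specificity: %.2f%%\n",
              x$sensitivity, x$specificity))
  if (nrow(x$discordant) > 0) {
    cat("  discordant cells:\n")
    print(utils::head(x$discordant, 20))
  }
  invisible(x)
}
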