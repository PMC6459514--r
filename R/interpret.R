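#' @title Inheritance-aware interpretation
#' @description Per-sample diagnostic classification under gene-specific
#'   inheritance modes, and cohort summary statistics (per-variant
#'   frequencies, per-gene burdens, compound-heterozygote table, detection
#'   rate and diagnostic yield).
#' @name interpret
NULL

.CATEGORIES <- c("confirmed_homozygous", "confirmed_mt",
                 "possible_compound_het_phase_unknown", "ad_positive",
                 "xl_positive", "carrier_monoallelic", "negative")

#' Classify one sample's genotype vector into a diagnostic category
#'
#' Precedence (first match wins):
#' homozygous alt at any autosomal-recessive locus -> `confirmed_homozygous`;
#' homoplasmic mitochondrial alt -> `confirmed_mt`; two heterozygous calls in
#' the same AR gene -> `possible_compound_het_phase_unknown` (phase unknown
#' without parental data, so not counted as confirmed); any alt call at an
#' autosomal-dominant locus -> `ad_positive`; any alt at an X-linked locus ->
#' `xl_positive`; any remaining alt finding (a single AR het, or a
#' heteroplasmic mitochondrial call) -> `carrier_monoallelic`; otherwise
#' `negative`.
#'
#' @param gts named character vector of genotype strings (`0/0`, `0/1`,
#'   `1/1`, `./.`), one per panel variant, or an `lg_calls` data.frame.
#' @param panel an `lg_panel`.
#' @return list of class `lg_report`: `category` and `supporting` (data.frame
#'   of the variants behind the call).
#' @export
classify_sample <- function(gts, panel) {
  if (inherits(gts, "lg_calls"))
    gts <- stats::setNames(gts$gt, gts$variant)
  vs <- panel$variants
  missing <- setdiff(vs$name, names(gts))
  if (length(missing) > 0)
    stop("missing call(s) for panel loci: ", paste(missing, collapse = ", "))
  gts <- gts[vs$name]
  carried <- gts %in% c("0/1", "1/1")
  sup <- function(idx) data.frame(variant = vs$name[idx], gene = vs$gene[idx],
                                  gt = unname(gts[idx]),
                                  stringsAsFactors = FALSE)
  done <- function(category, idx)
    structure(list(category = category, supporting = sup(idx)),
              class = "lg_report")

  ar_hom <- vs$inheritance == "AR" & gts == "1/1"
  if (any(ar_hom)) return(done("confirmed_homozygous", which(ar_hom)))
  mt_hom <- vs$inheritance == "MT" & gts == "1/1"
  if (any(mt_hom)) return(done("confirmed_mt", which(mt_hom)))
  ar_het <- vs$inheritance == "AR" & gts == "0/1"
  if (any(ar_het)) {
    by_gene <- table(vs$gene[ar_het])
    cg <- names(by_gene)[by_gene >= 2]
    if (length(cg) > 0)
      return(done("possible_compound_het_phase_unknown",
                  which(ar_het & vs$gene %in% cg)))
  }
  ad <- vs$inheritance == "AD" & carried
  if (any(ad)) return(done("ad_positive", which(ad)))
  xl <- vs$inheritance == "XL" & carried
  if (any(xl)) return(done("xl_positive", which(xl)))
  other <- carried | (vs$inheritance == "MT" & gts == "0/1")
  if (any(other)) return(done("carrier_monoallelic", which(other)))
  done("negative", integer(0))
}

#' @export
print.lg_report <- function(x, ...) {
  cat("Diagnostic category:", x$category, "\n")
  if (nrow(x$supporting) > 0) {
    cat("Supporting variants:\n")
    print(x$supporting)
  }
  invisible(x)
}

#' Tabulate same-gene dual-heterozygote (possible compound het) pairs
#'
#' Counts samples heterozygous at both members of every same-gene variant
#' pair; a sample het at k variants of one gene contributes to all
#' `choose(k, 2)` pairs.
#'
#' @param calls genotype matrix (samples x variants).
#' @param panel an `lg_panel`.
#' @return data.frame `variant_a`, `variant_b`, `gene`, `n`, sorted by gene
#'   then descending count; zero rows when no dual-het sample exists.
#' @export
compound_het_table <- function(calls, panel) {
  vs <- panel$variants
  res <- list()
  for (g in unique(vs$gene)) {
    vnames <- vs$name[vs$gene == g & vs$inheritance != "MT"]
    if (length(vnames) < 2) next
    for (i in seq_len(length(vnames) - 1)) for (j in seq(i + 1, length(vnames))) {
      n <- sum(calls[, vnames[i]] == "0/1" & calls[, vnames[j]] == "0/1")
      if (n > 0)
        res[[length(res) + 1]] <- data.frame(
          variant_a = vnames[i], variant_b = vnames[j], gene = g, n = n,
          stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(variant_a = character(), variant_b = character(),
                      gene = character(), n = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(out$gene, -out$n, out$variant_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a cohort's genotype matrix
#'
#' Per-variant homozygous/heterozygous counts and carrier frequency
#' `(hom + het) / n`, per-gene entry counts, the compound-het pair table,
#' and the cohort rates.  "Entry" counting treats each variant-carrier
#' occurrence as one finding, so a dual-variant sample contributes two
#' entries; `detection_rate` is total entries / n, which is how the source
#' cohort's 57/171 detection figure is defined.  A deduplicated patient-level
#' carrier rate is reported alongside.  `diagnostic_yield` is the fraction
#' of samples classified `confirmed_homozygous` or `confirmed_mt` by
#' [classify_sample()] (phase-unknown compound hets are not confirmed).
#'
#' @param calls genotype matrix (samples x variants), e.g. from
#'   [call_batch()] or [truth_matrix()].
#' @param panel an `lg_panel`.
#' @return list of class `lg_cohort_summary` with fields `n`, `per_variant`,
#'   `per_gene`, `pairs`, `detection_rate`, `carrier_rate`,
#'   `diagnostic_yield`, `het_entry_rate`, `hom_entry_rate`, `categories`.
#' @export
summarize_cohort <- function(calls, panel) {
  if (nrow(calls) == 0) stop("empty cohort")
  vs <- panel$variants
  stopifnot(all(vs$name %in% colnames(calls)))
  n <- nrow(calls)
  hom <- colSums(calls[, vs$name, drop = FALSE] == "1/1")
  het <- colSums(calls[, vs$name, drop = FALSE] == "0/1")
  per_variant <- data.frame(
    gene = vs$gene, chrom = vs$chrom, variant = vs$name,
    hom = as.integer(hom), het = as.integer(het),
    frequency = 100 * (hom + het) / n,
    stringsAsFactors = FALSE)
  entries <- per_variant$hom + per_variant$het
  per_gene <- stats::aggregate(entries, by = list(gene = per_variant$gene), sum)
  names(per_gene)[2] <- "entries"
  per_gene$frequency <- 100 * per_gene$entries / n
  per_gene <- per_gene[order(match(per_gene$gene, unique(vs$gene))), ,
                       drop = FALSE]
  rownames(per_gene) <- NULL
  categories <- vapply(seq_len(n), function(i)
    classify_sample(calls[i, ], panel)$category, character(1))
  names(categories) <- rownames(calls)
  carrier <- apply(calls[, vs$name, drop = FALSE], 1,
                   function(r) any(r %in% c("0/1", "1/1")))
  structure(list(
    n = n,
    per_variant = per_variant,
    per_gene = per_gene,
    pairs = compound_het_table(calls, panel),
    detection_rate = 100 * sum(entries) / n,
    carrier_rate = 100 * sum(carrier) / n,
    diagnostic_yield = 100 * mean(categories %in%
                                    c("confirmed_homozygous", "confirmed_mt")),
    het_entry_rate = 100 * sum(per_variant$het) / n,
    hom_entry_rate = 100 * sum(per_variant$hom) / n,
    categories = categories),
    class = "lg_cohort_summary")
}

#' @export
print.lg_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  pv <- x$per_variant[x$per_variant$hom + x$per_variant$het > 0, , drop = FALSE]
  if (nrow(pv) > 0) {
    pv$frequency <- sprintf("%.2f%%", pv$frequency)
    print(pv, row.names = FALSE)
  } else cat("  no variants detected\n")
  cat(sprintf("Detection rate (entries/n): %.2f%%  (carrier samples: %.2f%%)\n",
              x$detection_rate, x$carrier_rate))
  cat(sprintf("Heterozygous entries: %.2f%%   Homozygous entries: %.2f%%\n",
              x$het_entry_rate, x$hom_entry_rate))
  cat(sprintf("Diagnostic yield (confirmed by inheritance mode): %.2f%%\n",
              x$diagnostic_yield))
  if (nrow(x$pairs) > 0) {
    cat("Possible compound heterozygotes (phase unknown):\n")
    print(x$pairs, row.names = FALSE)
  }
  invisible(x)
}

#' Share of a gene's variant entries attributable to one variant
#'
#' @param summary an `lg_cohort_summary`.
#' @param gene gene symbol.
#' @param variant variant name within that gene.
#' @return percentage of the gene's (hom + het) entries carried by `variant`.
#' @export
gene_share <- function(summary, gene, variant) {
  stopifnot(inherits(summary, "lg_cohort_summary"))
  pv <- summary$per_variant
  gene_total <- sum(pv$hom[pv$gene == gene] + pv$het[pv$gene == gene])
  if (gene_total == 0) stop("gene ", gene, " has no variant entries")
  row <- pv[pv$gene == gene & pv$variant == variant, , drop = FALSE]
  if (nrow(row) == 0) stop("variant ", variant, " not found in gene ", gene)
  100 * (row$hom + row$het) / gene_total
}

#' Write a cohort summary as a five-column variant report TSV
#'
#' Mirrors the classic per-variant report layout: Gene, Chromosome,
#' Nucleotide change, Homozygous, Heterozygous, Frequency.
#'
#' @param summary an `lg_cohort_summary`.
#' @param path output TSV path.
#' @param all_variants include variants with zero carriers.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path, all_variants = FALSE) {
  pv <- summary$per_variant
  if (!all_variants) pv <- pv[pv$hom + pv$het > 0, , drop = FALSE]
  out <- data.frame(Gene = pv$gene, Chromosome = pv$chrom,
                    Nucleotide_change = pv$variant,
                    Homozygous = pv$hom, Heterozygous = pv$het,
                    Frequency = sprintf("%.2f%%", pv$frequency),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the full cohort report as JSON
#'
#' @param summary an `lg_cohort_summary`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  obj <- list(
    n = summary$n,
    detection_rate = summary$detection_rate,
    carrier_rate = summary$carrier_rate,
    diagnostic_yield = summary$diagnostic_yield,
    het_entry_rate = summary$het_entry_rate,
    hom_entry_rate = summary$hom_entry_rate,
    per_variant = summary$per_variant,
    per_gene = summary$per_gene,
    compound_het_pairs = summary$pairs,
    categories = as.list(summary$categories))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
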