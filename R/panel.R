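#' @title Ligation genotyping panels
#' @description Domain model for a multiplex ligation-detection (MLDR) SNP
#'   genotyping panel: a set of target variants, each decoded by two (or, for a
#'   tri-allelic locus, three) dye-labeled ligation products at characteristic
#'   electrophoretic sizes, plus the multiplex PCR amplicon grouping.
#' @name panel
NULL

.DYES <- c("B", "G", "Y", "R")
.INHERITANCE <- c("AR", "AD", "XL", "MT")

#' Construct a ligation genotyping panel
#'
#' A panel couples an ordered variant table to a dye-by-size product layout.
#' Each variant contributes one product per allele; ref and alt products of a
#' locus carry different dyes so that alleles are separated in the dye
#' dimension even when they co-migrate (same-size products on different dyes
#' are a legal, indeed canonical, layout).
#'
#' @param name panel name.
#' @param variants data.frame with columns `gene`, `chrom`, `name`, `ref`,
#'   `alt`, optional `alt2` (tri-allelic loci), `rs`, `inheritance`
#'   (one of `"AR"`, `"AD"`, `"XL"`, `"MT"`), `amplicon`.
#' @param products data.frame with columns `variant`, `allele`
#'   (`"ref"`/`"alt"`/`"alt2"`), `dye` (`"B"`,`"G"`,`"Y"`,`"R"`), `size` (nt).
#' @param size_range numeric length 2, electrophoretic window in nt.
#' @param tolerance half-width (nt) of the size-matching window; same-dye
#'   products must be at least `2 * tolerance` apart to be decodable.
#' @param probesets optional list of probe sets (see [design_probe_set()]);
#'   the built-in panel has none because its probe sequences are proprietary.
#' @param notes character vector of free-text annotations.
#' @return an object of class `lg_panel`.
#' @export
lg_panel <- function(name, variants, products, size_range = c(80, 260),
                     tolerance = 1.5, probesets = NULL, notes = character()) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  products <- as.data.frame(products, stringsAsFactors = FALSE)
  if (!"alt2" %in% names(variants)) variants$alt2 <- NA_character_
  if (!"rs" %in% names(variants)) variants$rs <- NA_character_
  if (!"amplicon" %in% names(variants)) variants$amplicon <- NA_character_
  req <- c("gene", "chrom", "name", "ref", "alt", "inheritance")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0)
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$name))
    stop("duplicate variant name(s): ",
         paste(unique(variants$name[duplicated(variants$name)]), collapse = ", "))
  if (any(variants$ref == variants$alt))
    stop("ref and alt allele identical for: ",
         paste(variants$name[variants$ref == variants$alt], collapse = ", "))
  bad_inh <- !variants$inheritance %in% .INHERITANCE
  if (any(bad_inh))
    stop("invalid inheritance code(s): ",
         paste(unique(variants$inheritance[bad_inh]), collapse = ", "))
  mt_mismatch <- xor(variants$chrom == "mtDNA", variants$inheritance == "MT")
  if (any(mt_mismatch))
    stop("chromosome 'mtDNA' and inheritance 'MT' must co-occur; offending: ",
         paste(variants$name[mt_mismatch], collapse = ", "))
  if (!all(products$variant %in% variants$name))
    stop("products reference unknown variant(s)")
  if (!all(products$dye %in% .DYES))
    stop("products carry unknown dye label(s)")
  out_of_range <- products$size < size_range[1] | products$size > size_range[2]
  if (any(out_of_range))
    stop("product size outside panel size range for: ",
         paste(products$variant[out_of_range], collapse = ", "))
  # one product per allele present on each variant
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    want <- c("ref", "alt", if (!is.na(v$alt2)) "alt2")
    have <- sort(products$allele[products$variant == v$name])
    if (!identical(sort(want), have))
      stop("variant ", v$name, " must have exactly one product per allele (",
           paste(want, collapse = ", "), ")")
    dyes_here <- products$dye[products$variant == v$name]
    if (anyDuplicated(dyes_here))
      stop("ref/alt products of ", v$name, " must carry distinct dyes")
  }
  structure(
    list(name = name, variants = variants, products = products,
         size_range = as.numeric(size_range), tolerance = tolerance,
         dyes = .DYES, probesets = probesets, notes = as.character(notes)),
    class = "lg_panel")
}

#' @export
print.lg_panel <- function(x, ...) {
  cat("Ligation genotyping panel:", x$name, "\n")
  cat(sprintf("  %d variants in %d genes; %d ligation products\n",
              nrow(x$variants), length(unique(x$variants$gene)),
              nrow(x$products)))
  cat(sprintf("  size window %.0f-%.0f nt, matching tolerance +/-%.1f nt, dyes %s\n",
              x$size_range[1], x$size_range[2], x$tolerance,
              paste(x$dyes, collapse = "/")))
  amp <- x$variants$amplicon
  if (!all(is.na(amp)))
    cat(sprintf("  %d multiplex PCR amplicon groups\n", length(unique(amp))))
  coll <- validate_layout(x)
  cat(if (nrow(coll) == 0) "  layout: collision-free\n"
      else sprintf("  layout: %d same-dye collision(s)!\n", nrow(coll)))
  invisible(x)
}

#' Amplicon grouping of a panel
#'
#' @param panel an `lg_panel`.
#' @return named list mapping amplicon id to the variant names it covers.
#' @export
amplicons <- function(panel) {
  stopifnot(inherits(panel, "lg_panel"))
  split(panel$variants$name, panel$variants$amplicon)
}

#' Check a panel layout for same-dye size collisions
#'
#' Two ligation products sharing a dye channel are only distinguishable if
#' their expected sizes differ by at least twice the size-matching tolerance;
#' closer pairs are collisions and make the layout undecodable.
#'
#' @param panel an `lg_panel`.
#' @param size_tolerance half-width of the matching window in nt; defaults to
#'   the panel's declared tolerance.
#' @return data.frame with one row per colliding pair (columns `variant_a`,
#'   `allele_a`, `variant_b`, `allele_b`, `dye`, `size_a`, `size_b`, `delta`);
#'   zero rows iff the layout is decodable at this tolerance.
#' @export
validate_layout <- function(panel, size_tolerance = panel$tolerance) {
  stopifnot(inherits(panel, "lg_panel"))
  pr <- panel$products
  out_of_range <- pr$size < panel$size_range[1] | pr$size > panel$size_range[2]
  if (any(out_of_range))
    stop("product(s) outside panel size range: ",
         paste(pr$variant[out_of_range], collapse = ", "))
  res <- list()
  min_sep <- 2 * size_tolerance
  for (dye in unique(pr$dye)) {
    d <- pr[pr$dye == dye, , drop = FALSE]
    if (nrow(d) < 2) next
    d <- d[order(d$size), , drop = FALSE]
    for (i in seq_len(nrow(d) - 1)) {
      for (j in seq(i + 1, nrow(d))) {
        delta <- d$size[j] - d$size[i]
        if (delta >= min_sep) break  # sorted: later j only larger
        res[[length(res) + 1]] <- data.frame(
          variant_a = d$variant[i], allele_a = d$allele[i],
          variant_b = d$variant[j], allele_b = d$allele[j],
          dye = dye, size_a = d$size[i], size_b = d$size[j], delta = delta,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(variant_a = character(), allele_a = character(),
                      variant_b = character(), allele_b = character(),
                      dye = character(), size_a = numeric(),
                      size_b = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Expected ligation products of one variant
#'
#' @param panel an `lg_panel`.
#' @param variant_name variant name as listed in the panel.
#' @return data.frame of the variant's products (ref first, then alt / alt2),
#'   columns `variant`, `allele`, `dye`, `size`.
#' @export
expected_products <- function(panel, variant_name) {
  stopifnot(inherits(panel, "lg_panel"))
  if (!variant_name %in% panel$variants$name)
    stop("unknown variant name: ", variant_name)
  pr <- panel$products[panel$products$variant == variant_name, , drop = FALSE]
  ord <- match(pr$allele, c("ref", "alt", "alt2"))
  pr <- pr[order(ord), , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

# size shift of an allele product relative to the ref product: a deletion
# shortens the allele-specific probe arm by the number of deleted bases
.allele_size_delta <- function(ref, alt) {
  n_alt <- if (identical(alt, "-")) 0L else nchar(alt)
  n_alt - nchar(ref)
}

# -------------------------------------------------------------------------
# Built-in 32-variant hereditary hearing loss panel
# -------------------------------------------------------------------------

# The 32 targets most frequently implicated in hereditary hearing loss in the
# Chinese population: 28 nonsyndromic variants plus 4 Waardenburg-syndrome
# variants, across 10 genes.  GJB2/GJB3/SLC26A4 are autosomal recessive,
# MT-RNR1 maternally inherited, POU3F4 X-linked, the remainder autosomal
# dominant.  The COCH c.1625 locus is tri-allelic (G>A and G>T at one site)
# and is modeled as a single variant with two alt alleles and three products.
.hl32_variant_table <- function() {
  v <- function(gene, chrom, name, ref, alt, rs, inh, amp, alt2 = NA_character_) {
    data.frame(gene = gene, chrom = chrom, name = name, ref = ref, alt = alt,
               alt2 = alt2, rs = rs, inheritance = inh, amplicon = amp,
               stringsAsFactors = FALSE)
  }
  rbind(
    v("GJB2", "13", "IVS1+1G>A",        "G", "A", "rs80338940",  "AR", "A01"),
    v("GJB2", "13", "c.35delG",         "G", "-", "rs80338939",  "AR", "A02"),
    v("GJB2", "13", "c.71G>A",          "G", "A", "rs104894396", "AR", "A02"),
    v("GJB2", "13", "c.139G>T",         "G", "T", "rs104894398", "AR", "A02"),
    v("GJB2", "13", "c.167delT",        "T", "-", "rs80338942",  "AR", "A02"),
    v("GJB2", "13", "c.176_191del16",   "GCTGCAAGAACGTGTG", "-", NA, "AR", "A02"),
    v("GJB2", "13", "c.235delC",        "C", "-", "rs80338943",  "AR", "A02"),
    v("GJB2", "13", "c.299_300delAT",   "AT", "-", NA,           "AR", "A02"),
    v("GJB2", "13", "c.571T>G",         "T", "G", NA,            "AR", "A03"),
    v("GJB2", "13", "c.596C>T",         "C", "T", NA,            "AR", "A03"),
    v("GJB3", "1",  "c.538C>T",         "C", "T", "rs74315319",  "AR", "A04"),
    v("GJB3", "1",  "c.547G>A",         "G", "A", NA,            "AR", "A04"),
    v("GJB3", "1",  "c.580G>A",         "G", "A", "rs121908852", "AR", "A04"),
    v("SLC26A4", "7", "c.281C>T",       "C", "T", NA,            "AR", "A05"),
    v("SLC26A4", "7", "IVS7-2A>G",      "A", "G", NA,            "AR", "A06"),
    v("SLC26A4", "7", "c.1174A>T",      "A", "T", NA,            "AR", "A07"),
    v("SLC26A4", "7", "c.1226G>A",      "G", "A", NA,            "AR", "A08"),
    v("SLC26A4", "7", "c.1229C>T",      "C", "T", NA,            "AR", "A08"),
    v("SLC26A4", "7", "IVS15+5G>A",     "G", "A", NA,            "AR", "A09"),
    v("SLC26A4", "7", "c.2027T>A",      "T", "A", NA,            "AR", "A10"),
    v("SLC26A4", "7", "c.2168A>G",      "A", "G", "rs121908362", "AR", "A10"),
    v("MT-RNR1", "mtDNA", "c.1494C>T",  "C", "T", NA,            "MT", "A11"),
    v("MT-RNR1", "mtDNA", "c.1555A>G",  "A", "G", NA,            "MT", "A11"),
    v("COCH", "14", "c.151C>T",         "C", "T", "rs28938175",  "AD", "A12"),
    v("COCH", "14", "c.1625G>A,c.1625G>T", "G", "A", "rs121908933", "AD", "A13",
      alt2 = "T"),
    v("POU3F4", "X", "c.967C>G",        "C", "G", "rs104894924", "XL", "A14"),
    v("PAX3", "2",  "c.812G>A",         "G", "A", NA,            "AD", "A15"),
    v("MITF", "3",  "c.650G>T",         "G", "T", NA,            "AD", "A16"),
    v("MITF", "3",  "c.648_650delAAG",  "AAG", "-", NA,          "AD", "A16"),
    v("SOX10", "22", "c.113delG",       "G", "-", NA,            "AD", "A17"),
    v("CEACAM16", "19", "c.505G>A",     "G", "A", NA,            "AD", "A18"),
    v("CEACAM16", "19", "c.418A>C",     "A", "C", NA,            "AD", "A18"))
}

.panel_cache <- new.env(parent = emptyenv())

#' The built-in 32-variant hereditary hearing loss panel
#'
#' Thirty-two mutations in ten genes (GJB2, GJB3, SLC26A4, MT-RNR1, COCH,
#' POU3F4, PAX3, MITF, SOX10, CEACAM16) covering the variants most frequently
#' responsible for nonsyndromic and syndromic sensorineural hearing loss in
#' the Chinese population, grouped into 18 multiplex PCR amplicons.  The
#' dye/size layout is computed once by [assign_layout()] under the default
#' parameters and is fully deterministic, so repeated calls return an
#' identical object.
#'
#' Notes: the c.571T>G entry is listed in the source table with allelic change
#' "T/C", contradicting its name; the panel uses T>G per the name and records
#' the discrepancy in `notes`.  The COCH c.1625 site carries two alternate
#' alleles (A and T) and is modeled as one tri-allelic locus with three
#' products.
#'
#' @return an `lg_panel` of 32 variants (65 ligation products).
#' @export
builtin_panel_hl32 <- function() {
  if (!is.null(.panel_cache$hl32)) return(.panel_cache$hl32)
  variants <- .hl32_variant_table()
  layout <- assign_layout(variants, design_params())
  panel <- lg_panel(
    name = "HL32", variants = variants, products = layout,
    size_range = c(80, 260), tolerance = 1.5,
    notes = c(paste("c.571T>G: source table prints allelic change T/C;",
                    "the variant name (used consistently elsewhere) implies",
                    "T>G, which this panel adopts."),
              paste("COCH c.1625G>A,c.1625G>T: one tri-allelic locus with",
                    "three ligation products (ref, altA, altT).")))
  .panel_cache$hl32 <- panel
  panel
}

# -------------------------------------------------------------------------
# Panel JSON round trip
# -------------------------------------------------------------------------

#' Write a panel to JSON
#'
#' @param panel an `lg_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "lg_panel"))
  vs <- panel$variants
  prod_of <- function(nm, allele, col) {
    p <- panel$products
    x <- p[[col]][p$variant == nm & p$allele == allele]
    if (length(x) == 0) NA else x
  }
  variants <- lapply(seq_len(nrow(vs)), function(i) {
    v <- as.list(vs[i, ])
    rec <- list(gene = v$gene, chrom = v$chrom, name = v$name, ref = v$ref,
                alt = v$alt, rs = v$rs, inheritance = v$inheritance,
                dye_ref = prod_of(v$name, "ref", "dye"),
                dye_alt = prod_of(v$name, "alt", "dye"),
                size_ref = prod_of(v$name, "ref", "size"),
                size_alt = prod_of(v$name, "alt", "size"),
                amplicon = v$amplicon)
    if (!is.na(v$alt2)) {
      rec$alt2 <- v$alt2
      rec$dye_alt2 <- prod_of(v$name, "alt2", "dye")
      rec$size_alt2 <- prod_of(v$name, "alt2", "size")
    }
    rec
  })
  obj <- list(name = panel$name,
              size_range = panel$size_range,
              tolerance = panel$tolerance,
              dyes = panel$dyes,
              variants = variants,
              notes = panel$notes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a panel from JSON
#'
#' Validates all panel invariants on load: unique variant names, products
#' inside the size window, and a collision-free layout at the declared
#' tolerance.
#'
#' @param path JSON file written by [write_panel()] (schema documented there).
#' @return an `lg_panel`.
#' @export
load_panel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("name", "size_range", "tolerance", "variants"))
    if (is.null(obj[[f]])) stop("panel JSON lacks required field '", f, "'")
  get_chr <- function(v, f) {
    x <- v[[f]]
    if (is.null(x) || length(x) == 0 || (length(x) == 1 && is.list(x) &&
                                         length(x[[1]]) == 0))
      NA_character_
    else as.character(unlist(x))
  }
  vs <- do.call(rbind, lapply(obj$variants, function(v) {
    data.frame(gene = get_chr(v, "gene"), chrom = get_chr(v, "chrom"),
               name = get_chr(v, "name"), ref = get_chr(v, "ref"),
               alt = get_chr(v, "alt"), alt2 = get_chr(v, "alt2"),
               rs = get_chr(v, "rs"), inheritance = get_chr(v, "inheritance"),
               amplicon = get_chr(v, "amplicon"), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(vs$name))
    stop("panel JSON contains duplicate variant name(s): ",
         paste(unique(vs$name[duplicated(vs$name)]), collapse = ", "))
  prods <- do.call(rbind, lapply(obj$variants, function(v) {
    rows <- data.frame(variant = as.character(v$name),
                       allele = c("ref", "alt"),
                       dye = c(as.character(v$dye_ref), as.character(v$dye_alt)),
                       size = c(as.numeric(v$size_ref), as.numeric(v$size_alt)),
                       stringsAsFactors = FALSE)
    if (!is.null(v$alt2))
      rows <- rbind(rows, data.frame(variant = as.character(v$name),
                                     allele = "alt2",
                                     dye = as.character(v$dye_alt2),
                                     size = as.numeric(v$size_alt2),
                                     stringsAsFactors = FALSE))
    rows
  }))
  panel <- lg_panel(name = as.character(obj$name), variants = vs,
                    products = prods,
                    size_range = as.numeric(unlist(obj$size_range)),
                    tolerance = as.numeric(obj$tolerance),
                    notes = as.character(unlist(obj$notes)))
  coll <- validate_layout(panel)
  if (nrow(coll) > 0)
    stop("panel layout has ", nrow(coll),
         " same-dye size collision(s) at tolerance ", panel$tolerance)
  panel
}

#' Export the variant table in the classic five-column report format
#'
#' @param panel an `lg_panel`.
#' @param path optional TSV output path; when `NULL` the data.frame is
#'   returned only.
#' @return data.frame with columns Gene, Chromosome, Nucleotide_change,
#'   Allelic_change, dbSNP_rs.
#' @export
panel_variant_table <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "lg_panel"))
  vs <- panel$variants
  allelic <- ifelse(is.na(vs$alt2),
                    paste0(vs$ref, "/", vs$alt),
                    paste0(vs$ref, "/", vs$alt, ";", vs$ref, "/", vs$alt2))
  out <- data.frame(Gene = vs$gene, Chromosome = vs$chrom,
                    Nucleotide_change = vs$name, Allelic_change = allelic,
                    dbSNP_rs = ifelse(is.na(vs$rs), "", vs$rs),
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
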