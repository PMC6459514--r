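#' @title Probe-set design and multiplex layout assignment
#' @description Construction of allele-specific ligation probe sets from
#'   flanking sequence under a nearest-neighbor melting-temperature model, and
#'   the dye/stuffer layout solver that places every ligation product at a
#'   collision-free (dye, size) address.
#' @name design
NULL

#' Design parameters
#'
#' @param target_tm target annealing temperature, degrees C.
#' @param tm_window half-width of the acceptable Tm window, degrees C.
#' @param min_probe_len,max_probe_len allowed annealing-arm lengths, nt.
#' @param dye_tag_seqs named character vector of four distinct 12-nt 5' tag
#'   sequences, one per dye channel B/G/Y/R; the tag recruits the dye-labeled
#'   oligo in the labeling ligation and does not hybridize to the target.
#' @param stuffer_step quantization (nt) of stuffer lengths appended to the
#'   common 3' probe to shift a locus's products along the size axis.
#' @param size_range electrophoretic size window, nt.
#' @param min_separation minimum same-dye product separation, nt (twice the
#'   size-matching tolerance).
#' @param na_mM monovalent salt concentration used by the Tm model, mM.
#' @param oligo_nM total oligo concentration used by the Tm model, nM.
#' @param rng_seed seed reserved for randomized fallbacks of the layout
#'   search; the default greedy solver is deterministic and does not use it.
#' @return list of class `lg_design_params`.
#' @export
design_params <- function(target_tm = 62, tm_window = 3,
                          min_probe_len = 18, max_probe_len = 35,
                          dye_tag_seqs = c(B = "ACGGTACTGCAT",
                                           G = "TCCAGTGACGTA",
                                           Y = "GGATCACGTTCA",
                                           R = "CATGGTCAAGCT"),
                          stuffer_step = 2,
                          size_range = c(80, 260), min_separation = 3,
                          na_mM = 50, oligo_nM = 250, rng_seed = 1L) {
  stopifnot(min_probe_len >= 8, max_probe_len >= min_probe_len,
            stuffer_step >= 1, min_separation > 0,
            length(size_range) == 2, size_range[2] > size_range[1])
  if (length(dye_tag_seqs) != 4 || anyDuplicated(dye_tag_seqs) ||
      !all(sort(names(dye_tag_seqs)) == sort(.DYES)))
    stop("dye_tag_seqs must be 4 distinct tags named B, G, Y, R")
  structure(list(target_tm = target_tm, tm_window = tm_window,
                 min_probe_len = min_probe_len, max_probe_len = max_probe_len,
                 dye_tag_seqs = dye_tag_seqs, stuffer_step = stuffer_step,
                 size_range = as.numeric(size_range),
                 min_separation = min_separation,
                 na_mM = na_mM, oligo_nM = oligo_nM,
                 rng_seed = as.integer(rng_seed)),
            class = "lg_design_params")
}

# -------------------------------------------------------------------------
# Nearest-neighbor melting temperature
# -------------------------------------------------------------------------

# Unified nearest-neighbor duplex parameters (SantaLucia unified set):
# dH kcal/mol, dS cal/(mol K), 1 M NaCl reference.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

.revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Nearest-neighbor melting temperature of a DNA duplex
#'
#' Two-state nearest-neighbor model with the unified duplex parameter set,
#' duplex-initiation terms for terminal A:T / G:C pairs, a symmetry correction
#' for self-complementary sequences, and the entropic monovalent-salt
#' correction `dS + 0.368 (N-1) ln[Na+]`.  Tm is evaluated at total strand
#' concentration `CT` as `1000 dH / (dS + R ln(CT/x)) - 273.15` with `x = 4`
#' for non-self-complementary duplexes (`x = 1` otherwise).
#'
#' @param seq DNA string over ACGT, length >= 8.
#' @param na_mM monovalent cation concentration, mM.
#' @param oligo_nM total strand concentration, nM.
#' @return melting temperature in degrees C.
#' @export
melting_temperature <- function(seq, na_mM = 50, oligo_nM = 250) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq))
    stop("sequence contains characters outside ACGT")
  n <- nchar(seq)
  if (n < 8)
    stop("sequence too short for the nearest-neighbor model (need >= 8 nt)")
  bases <- strsplit(seq, "")[[1]]
  steps <- paste0(bases[-n], bases[-1])
  dH <- sum(.NN_DH[steps])
  dS <- sum(.NN_DS[steps])
  for (term in c(bases[1], bases[n])) {
    if (term %in% c("G", "C")) { dH <- dH + 0.1; dS <- dS - 2.8 }
    else                       { dH <- dH + 2.3; dS <- dS + 4.1 }
  }
  selfcomp <- identical(seq, .revcomp(seq))
  x <- 4
  if (selfcomp) { dS <- dS - 1.4; x <- 1 }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  ct <- oligo_nM * 1e-9
  1000 * dH / (dS + 1.987 * log(ct / x)) - 273.15
}

# -------------------------------------------------------------------------
# Probe-set construction
# -------------------------------------------------------------------------

.check_dna <- function(seq, what) {
  if (!grepl("^[ACGT]+$", toupper(seq)))
    stop(what, " contains characters outside ACGT")
  toupper(seq)
}

# pick the shortest 5'-arm length for which the annealing Tm of every given
# candidate sequence-builder falls inside the window; builders map arm length
# to annealing sequence
.fit_arm <- function(builders, params) {
  achieved <- c(Inf, -Inf)
  for (len in seq(params$min_probe_len, params$max_probe_len)) {
    seqs <- lapply(builders, function(b) b(len))
    if (any(vapply(seqs, is.null, logical(1)))) next
    tms <- vapply(seqs, melting_temperature, numeric(1),
                  na_mM = params$na_mM, oligo_nM = params$oligo_nM)
    achieved <- c(min(achieved[1], min(tms)), max(achieved[2], max(tms)))
    if (all(abs(tms - params$target_tm) <= params$tm_window))
      return(list(len = len, seqs = seqs, tms = tms))
  }
  stop(sprintf(
    "no arm length in [%d, %d] nt reaches Tm %.1f +/- %.1f C (achieved %.1f-%.1f C)",
    params$min_probe_len, params$max_probe_len, params$target_tm,
    params$tm_window, achieved[1], achieved[2]))
}

#' Design an allele-specific ligation probe set for one variant
#'
#' Builds the two (dye-tagged) allele-specific 5' probes and the common 3'
#' probe for a variant from its flanking sequence.  The two 5' probes share
#' their upstream arm and differ only at the 3'-terminal allele base(s) — the
#' position the ligase proofreads.  Deletion alleles are probed across the
#' deletion junction: the alt probe's 3' terminus reads into the sequence
#' that follows the deleted bases.  Arm lengths are chosen (deterministically,
#' shortest first) so that every annealing region's Tm falls inside
#' `target_tm +/- tm_window`.
#'
#' @param flank5 upstream flanking sequence, ending immediately 5' of the
#'   variant site.
#' @param flank3 downstream flanking sequence, beginning immediately 3' of
#'   the variant site.
#' @param variant one-row data.frame (or list) with fields `name`, `ref`,
#'   `alt` (use `"-"` for a deletion allele), optional `amplicon`.
#' @param params an [design_params()] object.
#' @return object of class `lg_probe_set`: probe sequences, annealing Tms,
#'   provisional dyes (finalized by [assign_layout()]) and product lengths.
#' @export
design_probe_set <- function(flank5, flank3, variant, params = design_params()) {
  flank5 <- .check_dna(flank5, "flank5")
  flank3 <- .check_dna(flank3, "flank3")
  variant <- as.list(variant)
  ref <- .check_dna(variant$ref, "ref allele")
  is_del <- identical(variant$alt, "-")
  alt <- if (is_del) "-" else .check_dna(variant$alt, "alt allele")
  if (!is.null(variant$alt2) && !is.na(variant$alt2))
    stop("tri-allelic loci are not supported by sequence-level design")
  if (is_del && nchar(flank3) < params$min_probe_len)
    stop("deletion variant needs >= min_probe_len nt of 3' flank for the ",
         "junction-spanning probe")
  junction_bases <- 2L  # alt 3' terminus read-through for deletion alleles

  tail5 <- function(n) if (n > nchar(flank5)) NULL else
    substr(flank5, nchar(flank5) - n + 1, nchar(flank5))
  head3 <- function(n) if (n > nchar(flank3)) NULL else substr(flank3, 1, n)

  # 5' probes: arm length counts the full annealing region incl. allele bases
  build_ref <- function(len) {
    arm <- len - nchar(ref)
    if (arm < 1) return(NULL)
    t5 <- tail5(arm); if (is.null(t5)) return(NULL)
    paste0(t5, ref)
  }
  build_alt <- if (is_del) {
    function(len) {
      arm <- len - junction_bases
      if (arm < 1) return(NULL)
      t5 <- tail5(arm); if (is.null(t5)) return(NULL)
      h3 <- head3(junction_bases); if (is.null(h3)) return(NULL)
      paste0(t5, h3)
    }
  } else {
    function(len) {
      arm <- len - nchar(alt)
      if (arm < 1) return(NULL)
      t5 <- tail5(arm); if (is.null(t5)) return(NULL)
      paste0(t5, alt)
    }
  }
  fit5 <- .fit_arm(list(ref = build_ref, alt = build_alt), params)
  fit3 <- .fit_arm(list(common = head3), params)

  p5_ref <- fit5$seqs$ref
  p5_alt <- fit5$seqs$alt
  if (identical(p5_ref, p5_alt))
    stop("ref and alt probes are identical; flanks inconsistent with alleles")
  tag_len <- nchar(params$dye_tag_seqs[[1]])
  structure(list(
    variant = variant$name,
    ref = ref, alt = variant$alt,
    probe5_ref = list(dye = "B", dye_tag_seq = unname(params$dye_tag_seqs["B"]),
                      allele_specific_seq = p5_ref),
    probe5_alt = list(dye = "G", dye_tag_seq = unname(params$dye_tag_seqs["G"]),
                      allele_specific_seq = p5_alt),
    probe3_common = list(anneal_seq = fit3$seqs$common, stuffer_len = 0L),
    amplicon_id = if (is.null(variant$amplicon)) NA_character_ else variant$amplicon,
    tm = c(ref = unname(fit5$tms["ref"]), alt = unname(fit5$tms["alt"]),
           common = unname(fit3$tms["common"])),
    product_len = c(ref = tag_len + nchar(p5_ref) + nchar(fit3$seqs$common),
                    alt = tag_len + nchar(p5_alt) + nchar(fit3$seqs$common))),
    class = "lg_probe_set")
}

# -------------------------------------------------------------------------
# Dye / stuffer layout assignment
# -------------------------------------------------------------------------

# normalize layout input into one record per locus:
#   name, alleles, base (minimum product size before stuffer, per allele)
.layout_loci <- function(x, params) {
  if (is.data.frame(x)) {            # abstract layout from a variant table
    if (!"alt2" %in% names(x)) x$alt2 <- NA_character_
    lapply(seq_len(nrow(x)), function(i) {
      v <- x[i, ]
      alleles <- c("ref", "alt", if (!is.na(v$alt2)) "alt2")
      deltas <- c(0,
                  .allele_size_delta(v$ref, v$alt),
                  if (!is.na(v$alt2)) .allele_size_delta(v$ref, v$alt2))
      list(name = v$name, alleles = alleles,
           base = params$size_range[1] + deltas - min(deltas, 0))
    })
  } else {                           # designed probe sets
    lapply(x, function(ps) {
      stopifnot(inherits(ps, "lg_probe_set"))
      list(name = ps$variant, alleles = c("ref", "alt"),
           base = unname(ps$product_len))
    })
  }
}

#' Assign a collision-free dye/stuffer layout to a set of loci
#'
#' Places every ligation product at a (dye, size) address such that products
#' sharing a dye are at least `min_separation` nt apart and the alleles of
#' one locus always ride different dyes.  Sizes are the locus's base product
#' length plus a per-locus stuffer quantized to `stuffer_step` (the stuffer
#' sits on the shared 3' probe, so allele size offsets within a locus are
#' fixed by allele length differences).  The solver is a deterministic greedy
#' first-fit over stuffer slots and dye combinations in B<G<Y<R order; on
#' failure it retries with loci reordered by descending product count before
#' declaring the instance infeasible.
#'
#' @param x either a panel variant data.frame (abstract layout; base sizes
#'   start at the bottom of the size window) or a list of
#'   [design_probe_set()] objects (base sizes from real probe lengths).
#' @param params an [design_params()] object.
#' @return data.frame with columns `variant`, `allele`, `dye`, `size`,
#'   `stuffer` — the panel `products` table.
#' @export
assign_layout <- function(x, params = design_params()) {
  loci <- .layout_loci(x, params)
  n_products <- sum(vapply(loci, function(l) length(l$alleles), integer(1)))
  slots_per_dye <- floor(diff(params$size_range) / params$min_separation) + 1
  if (n_products > 4 * slots_per_dye)
    stop(sprintf("layout infeasible: %d products but only %d (dye, size) slots",
                 n_products, 4 * slots_per_dye))

  try_order <- function(ord) {
    occupied <- stats::setNames(vector("list", 4), .DYES)
    rows <- list()
    free_at <- function(dye, size)
      length(occupied[[dye]]) == 0 ||
        all(abs(occupied[[dye]] - size) >= params$min_separation - 1e-9)
    for (li in ord) {
      loc <- loci[[li]]
      k <- length(loc$alleles)
      offs <- loc$base - min(loc$base)       # per-allele offsets from locus base
      placed <- FALSE
      stuffer <- 0
      while (min(loc$base) + stuffer + max(offs) <= params$size_range[2] + 1e-9) {
        sizes <- min(loc$base) + stuffer + offs
        if (all(sizes >= params$size_range[1] - 1e-9)) {
          dyesets <- .dye_combinations(k)
          for (ds in dyesets) {
            if (all(mapply(free_at, ds, sizes))) {
              rows[[length(rows) + 1]] <- data.frame(
                variant = loc$name, allele = loc$alleles, dye = ds,
                size = sizes, stuffer = stuffer, stringsAsFactors = FALSE)
              for (j in seq_len(k))
                occupied[[ds[j]]] <- c(occupied[[ds[j]]], sizes[j])
              placed <- TRUE
              break
            }
          }
        }
        if (placed) break
        stuffer <- stuffer + params$stuffer_step
      }
      if (!placed) return(NULL)
    }
    out <- do.call(rbind, rows)
    out[order(match(out$variant, vapply(loci, `[[`, "", "name")),
              match(out$allele, c("ref", "alt", "alt2"))), , drop = FALSE]
  }

  res <- try_order(seq_along(loci))
  if (is.null(res)) {
    ord <- order(-vapply(loci, function(l) length(l$alleles), integer(1)),
                 vapply(loci, function(l) min(l$base), numeric(1)))
    res <- try_order(ord)
  }
  if (is.null(res))
    stop(sprintf(
      "layout infeasible for %d products in window %.0f-%.0f nt at %g nt separation",
      n_products, params$size_range[1], params$size_range[2],
      params$min_separation))
  rownames(res) <- NULL
  res
}

# ordered distinct-dye tuples, lexicographic in B<G<Y<R
.dye_combinations <- function(k) {
  if (k == 2) {
    out <- list()
    for (a in .DYES) for (b in .DYES) if (a != b) out[[length(out) + 1]] <- c(a, b)
    out
  } else if (k == 3) {
    out <- list()
    for (a in .DYES) for (b in .DYES) for (c in .DYES)
      if (length(unique(c(a, b, c))) == 3) out[[length(out) + 1]] <- c(a, b, c)
    out
  } else {
    stop("loci must have 2 or 3 allele products")
  }
}

# -------------------------------------------------------------------------
# Multiplex PCR amplicon grouping
# -------------------------------------------------------------------------

#' Group variants into multiplex PCR amplicons
#'
#' Variants on the same contig are chained into one amplicon whenever
#' consecutive sites are within `max_amplicon_len` of each other
#' (single-linkage); a sorted greedy sweep yields the minimum number of
#' groups for this connectivity rule.
#'
#' @param positions data.frame with columns `variant`, `contig`, `offset`
#'   (non-negative integer position on the contig).
#' @param max_amplicon_len maximum linking distance, nt.
#' @return named list: amplicon id (`"A01"`, `"A02"`, ...) to character
#'   vector of variant names; ids ordered by contig then offset.
#' @export
group_amplicons <- function(positions, max_amplicon_len = 600) {
  stopifnot(all(c("variant", "contig", "offset") %in% names(positions)),
            all(positions$offset >= 0))
  groups <- list()
  for (ctg in unique(positions$contig)) {
    p <- positions[positions$contig == ctg, , drop = FALSE]
    p <- p[order(p$offset, p$variant), , drop = FALSE]
    brk <- c(0, cumsum(diff(p$offset) > max_amplicon_len))
    for (g in split(p$variant, brk)) groups[[length(groups) + 1]] <- g
  }
  stats::setNames(groups, sprintf("A%02d", seq_along(groups)))
}

# -------------------------------------------------------------------------
# Flanking-sequence FASTA
# -------------------------------------------------------------------------

#' Read variant flanking sequences from FASTA
#'
#' Each record holds the variant's neighborhood with the site marked inline
#' by a bracketed allele token, e.g. `ACGT[C/-]TTAA` (ref C deleted in alt).
#' The record id is the variant name, optionally extended as
#' `name|gene|chrom|inheritance` to carry panel metadata.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `name`, `gene`, `chrom`, `inheritance`,
#'   `flank5`, `ref`, `alt`, `flank3`.
#' @export
read_flanks_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no records in ", path)
  recs <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    s <- toupper(as.character(seqs[[i]]))
    m <- regexec("^([ACGT]*)\\[([ACGT]+)/([ACGT]+|-)\\]([ACGT]*)$", s)[[1]]
    if (m[1] == -1)
      stop("record ", i, " ('", id, "'): expected '<flank5>[REF/ALT]<flank3>'")
    parts <- regmatches(s, regexec("^([ACGT]*)\\[([ACGT]+)/([ACGT]+|-)\\]([ACGT]*)$", s))[[1]]
    meta <- strsplit(id, "|", fixed = TRUE)[[1]]
    data.frame(name = meta[1],
               gene = if (length(meta) >= 2) meta[2] else meta[1],
               chrom = if (length(meta) >= 3) meta[3] else "1",
               inheritance = if (length(meta) >= 4) meta[4] else "AR",
               flank5 = parts[2], ref = parts[3], alt = parts[4],
               flank3 = parts[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Design a complete panel from flanking sequences
#'
#' Convenience wrapper: reads or accepts a flank table, designs a probe set
#' per variant, solves the layout, and assembles an `lg_panel`.
#'
#' @param flanks path to a flanks FASTA (see [read_flanks_fasta()]) or an
#'   equivalent data.frame.
#' @param params an [design_params()] object.
#' @param name panel name.
#' @return an `lg_panel` with `probesets` attached.
#' @export
design_panel <- function(flanks, params = design_params(), name = "designed") {
  ft <- if (is.character(flanks)) read_flanks_fasta(flanks) else flanks
  probesets <- lapply(seq_len(nrow(ft)), function(i) {
    r <- ft[i, ]
    design_probe_set(r$flank5, r$flank3,
                     list(name = r$name, ref = r$ref, alt = r$alt), params)
  })
  layout <- assign_layout(probesets, params)
  # write the solved dyes/stuffers back onto the probe sets
  for (i in seq_along(probesets)) {
    ps <- probesets[[i]]
    lay <- layout[layout$variant == ps$variant, ]
    ps$probe5_ref$dye <- lay$dye[lay$allele == "ref"]
    ps$probe5_ref$dye_tag_seq <- unname(params$dye_tag_seqs[ps$probe5_ref$dye])
    ps$probe5_alt$dye <- lay$dye[lay$allele == "alt"]
    ps$probe5_alt$dye_tag_seq <- unname(params$dye_tag_seqs[ps$probe5_alt$dye])
    ps$probe3_common$stuffer_len <- unique(lay$stuffer)
    probesets[[i]] <- ps
  }
  variants <- data.frame(gene = ft$gene, chrom = ft$chrom, name = ft$name,
                         ref = ft$ref, alt = ft$alt, alt2 = NA_character_,
                         rs = NA_character_, inheritance = ft$inheritance,
                         amplicon = NA_character_, stringsAsFactors = FALSE)
  lg_panel(name = name, variants = variants, products = layout,
           size_range = params$size_range,
           tolerance = params$min_separation / 2, probesets = probesets)
}
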