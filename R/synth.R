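#' @title Synthetic cohorts and peak-table simulation
#' @description Generators for the study's genotype fixtures (validation
#'   cases, healthy controls, patient cohort) reconstructed from their printed
#'   zygosity counts, and a capillary-electrophoresis peak simulator that
#'   turns any genotyped sample into a dye/size/height peak table.
#' @name synth
NULL

#' Sample truth
#'
#' @param sample_id sample identifier.
#' @param genotypes named list/vector: variant name to `"hom_ref"`, `"het"`
#'   or `"hom_alt"` for nuclear loci, or a numeric homoplasmy fraction in
#'   \[0, 1\] for mitochondrial loci.  Omitted panel variants are `hom_ref`.
#' @return list of class `lg_truth`.
#' @export
sample_truth <- function(sample_id, genotypes = list()) {
  genotypes <- as.list(genotypes)
  for (g in genotypes) {
    ok <- (is.character(g) && g %in% c("hom_ref", "het", "hom_alt")) ||
      (is.numeric(g) && g >= 0 && g <= 1)
    if (!ok) stop("invalid genotype value for sample ", sample_id)
  }
  structure(list(sample_id = sample_id, genotypes = genotypes),
            class = "lg_truth")
}

.check_truth_panel <- function(truths, panel) {
  vars <- panel$variants$name
  for (t in truths) {
    unknown <- setdiff(names(t$genotypes), vars)
    if (length(unknown) > 0)
      stop("sample ", t$sample_id, " carries variant(s) not in panel: ",
           paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Truth genotype matrix
#'
#' @param truths list of [sample_truth()] objects.
#' @param panel an `lg_panel`.
#' @return character matrix (samples x variants) of VCF-style genotype
#'   strings `0/0`, `0/1`, `1/1`; mitochondrial loci are mapped through the
#'   default homoplasmy cutoffs (fraction >= 0.95 -> `1/1`, <= 0.05 ->
#'   `0/0`, else `0/1`) with the raw fractions attached as attribute
#'   `mt_fraction`.
#' @export
truth_matrix <- function(truths, panel) {
  .check_truth_panel(truths, panel)
  vars <- panel$variants$name
  is_mt <- panel$variants$inheritance == "MT"
  m <- matrix("0/0", nrow = length(truths), ncol = length(vars),
              dimnames = list(vapply(truths, `[[`, "", "sample_id"), vars))
  mt <- matrix(NA_real_, nrow = length(truths), ncol = length(vars),
               dimnames = dimnames(m))
  mt[, is_mt] <- 0
  for (i in seq_along(truths)) {
    for (v in names(truths[[i]]$genotypes)) {
      g <- truths[[i]]$genotypes[[v]]
      if (is.numeric(g)) {
        mt[i, v] <- g
        m[i, v] <- if (g >= 0.95) "1/1" else if (g <= 0.05) "0/0" else "0/1"
      } else {
        m[i, v] <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[[g]]
      }
    }
  }
  attr(m, "mt_fraction") <- mt
  m
}

# -------------------------------------------------------------------------
# Cohorts from printed zygosity counts
# -------------------------------------------------------------------------

#' Build a cohort of sample truths from per-variant zygosity counts
#'
#' Reconstructs a cohort whose per-variant marginal counts equal the inputs.
#' Compound pairs (two variants carried heterozygously by the same sample)
#' are realized first, drawing those het occurrences from the per-variant het
#' budgets; remaining het and all hom occurrences are placed in otherwise
#' variant-free samples; everything else is reference.  Mitochondrial `hom`
#' counts are realized as homoplasmic (fraction 1), `het` counts as
#' heteroplasmic (fraction 0.5).
#'
#' In `mode = "strict"` a pair demand exceeding a variant's het budget is an
#' error; in `mode = "reconcile"` pairs are processed in input order and each
#' pair's count is capped at the remaining budget, with a warning.  Marginal
#' counts are preserved exactly in both modes.
#'
#' @param panel an `lg_panel`.
#' @param counts data.frame with columns `variant`, `hom`, `het`.
#' @param pairs optional data.frame with columns `variant_a`, `variant_b`,
#'   `n`: number of samples het for both.
#' @param n_total cohort size.
#' @param seed integer seed; used only to shuffle the final sample order, so
#'   the generator is a pure function of `(panel, counts, pairs, seed)`.
#' @param mode `"strict"` or `"reconcile"` (see above).
#' @return list of `n_total` [sample_truth()] objects.
#' @export
cohort_from_counts <- function(panel, counts, pairs = NULL, n_total,
                               seed = 1L, mode = c("strict", "reconcile")) {
  mode <- match.arg(mode)
  stopifnot(all(c("variant", "hom", "het") %in% names(counts)))
  unknown <- setdiff(counts$variant, panel$variants$name)
  if (length(unknown) > 0)
    stop("counts reference variant(s) not in panel: ",
         paste(unknown, collapse = ", "))
  is_mt <- function(v)
    panel$variants$inheritance[panel$variants$name == v] == "MT"
  het_left <- stats::setNames(as.integer(counts$het), counts$variant)
  hom_left <- stats::setNames(as.integer(counts$hom), counts$variant)

  genos <- list()  # list of named lists, one per carrier sample
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$variant_a[i]; b <- pairs$variant_b[i]
      k <- as.integer(pairs$n[i])
      for (v in c(a, b)) if (!v %in% names(het_left))
        stop("pair references variant without het count: ", v)
      avail <- min(het_left[[a]], het_left[[b]])
      if (k > avail) {
        if (mode == "strict")
          stop(sprintf(
            "infeasible pair %s/%s: demands %d dual-het samples but only %d het %s remain",
            a, b, k, avail, if (het_left[[a]] < het_left[[b]]) a else b))
        warning(sprintf("pair %s/%s capped at %d (demand %d exceeds het budget)",
                        a, b, avail, k))
        k <- avail
      }
      het_left[[a]] <- het_left[[a]] - k
      het_left[[b]] <- het_left[[b]] - k
      if (k > 0) for (j in seq_len(k)) {
        g <- list()
        g[[a]] <- if (is_mt(a)) 0.5 else "het"
        g[[b]] <- if (is_mt(b)) 0.5 else "het"
        genos[[length(genos) + 1]] <- g
      }
    }
  }
  for (v in counts$variant) {
    if (het_left[[v]] > 0) for (j in seq_len(het_left[[v]])) {
      g <- list(); g[[v]] <- if (is_mt(v)) 0.5 else "het"
      genos[[length(genos) + 1]] <- g
    }
    if (hom_left[[v]] > 0) for (j in seq_len(hom_left[[v]])) {
      g <- list(); g[[v]] <- if (is_mt(v)) 1.0 else "hom_alt"
      genos[[length(genos) + 1]] <- g
    }
  }
  if (length(genos) > n_total)
    stop(sprintf("infeasible counts: %d carrier samples required but n_total = %d",
                 length(genos), n_total))
  while (length(genos) < n_total) genos[[length(genos) + 1]] <- list()
  old <- .seed_swap(seed)
  ord <- sample.int(length(genos))
  .seed_restore(old)
  truths <- lapply(seq_along(ord), function(i)
    sample_truth(sprintf("S%03d", i), genos[[ord[i]]]))
  .check_truth_panel(truths, panel)
  truths
}

# run code under a private RNG state
.seed_swap <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Validation cohort: 49 positive cases with Sanger-confirmed genotypes.
# Primary findings (variant, het count, hom count), one entry per patient.
.table1_counts <- function() {
  read.table(text = "
variant het hom
c.139G>T 2 0
c.176_191del16 1 0
c.235delC 10 6
c.299_300delAT 2 0
c.571T>G 1 0
IVS7-2A>G 3 3
c.1174A>T 1 0
c.1229C>T 2 0
c.2168A>G 3 0
c.1555A>G 0 11
c.580G>A 1 0
c.812G>A 1 0
c.650G>T 1 0
c.505G>A 1 0
", header = TRUE, stringsAsFactors = FALSE)
}

# Dual-variant findings among the 49 positive cases: (first listed variant is
# the primary carrier the second is added to, count of samples)
.table3_pairs <- function() {
  read.table(text = "
variant_a	variant_b	n
IVS7-2A>G	c.2168A>G	1
c.235delC	c.299_300delAT	2
c.235delC	c.1555A>G	1
c.235delC	IVS7-2A>G	1
c.580G>A	c.1555A>G	1
c.571T>G	c.1174A>T	1
c.1229C>T	c.2168A>G	2
", header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' The 49-sample validation cohort
#'
#' Forty-nine positive cases with known genotypes: 29 heterozygous and 20
#' homozygous primary findings (11 of them homoplasmic mitochondrial
#' c.1555A>G), plus nine dual-variant samples realized by adding the second
#' variant of each reported pair on top of a sample already carrying the
#' first.  Same-gene dual-het samples are the reported compound
#' heterozygotes; cross-gene pairs (e.g. a GJB2 het plus homoplasmic
#' MT-RNR1 c.1555A>G) are dual-gene findings.
#'
#' @param panel an `lg_panel` (the built-in panel by default).
#' @param seed unused placeholder for API symmetry; the construction is fully
#'   deterministic.
#' @return list of 49 [sample_truth()] objects (ids `V01`..`V49`).
#' @export
validation_samples_table1 <- function(panel = builtin_panel_hl32(), seed = 1L) {
  counts <- .table1_counts()
  is_mt <- function(v)
    panel$variants$inheritance[panel$variants$name == v] == "MT"
  genos <- list()
  primary <- character()
  for (i in seq_len(nrow(counts))) {
    v <- counts$variant[i]
    if (counts$het[i] > 0) for (j in seq_len(counts$het[i])) {
      g <- list(); g[[v]] <- "het"
      genos[[length(genos) + 1]] <- g; primary <- c(primary, paste0(v, ":het"))
    }
    if (counts$hom[i] > 0) for (j in seq_len(counts$hom[i])) {
      g <- list(); g[[v]] <- if (is_mt(v)) 1.0 else "hom_alt"
      genos[[length(genos) + 1]] <- g; primary <- c(primary, paste0(v, ":hom"))
    }
  }
  pairs <- .table3_pairs()
  taken <- rep(FALSE, length(genos))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$variant_a[i]; b <- pairs$variant_b[i]
    for (j in seq_len(pairs$n[i])) {
      idx <- which(primary == paste0(a, ":het") & !taken)[1]
      if (is.na(idx))
        stop("no free heterozygous ", a, " sample to host pair with ", b)
      genos[[idx]][[b]] <- if (is_mt(b)) 1.0 else "het"
      taken[idx] <- TRUE
    }
  }
  truths <- lapply(seq_along(genos), function(i)
    sample_truth(sprintf("V%02d", i), genos[[i]]))
  .check_truth_panel(truths, panel)
  truths
}

#' The 50-sample healthy control cohort
#'
#' Five carriers among 50 controls: one heterozygote each for GJB2
#' c.176_191del16, c.235delC and c.299_300delAT, and two heterozygotes for
#' SLC26A4 IVS7-2A>G, in five distinct samples; the remaining 45 samples are
#' variant-free.
#'
#' @inheritParams validation_samples_table1
#' @return list of 50 [sample_truth()] objects (ids `C01`..`C50`).
#' @export
control_samples_table4 <- function(panel = builtin_panel_hl32(), seed = 1L) {
  carriers <- c("c.176_191del16", "c.235delC", "c.299_300delAT",
                "IVS7-2A>G", "IVS7-2A>G")
  truths <- lapply(seq_len(50), function(i) {
    g <- list()
    if (i <= length(carriers)) g[[carriers[i]]] <- "het"
    sample_truth(sprintf("C%02d", i), g)
  })
  .check_truth_panel(truths, panel)
  truths
}

# Patient cohort marginals: per-variant (hom, het) counts among 171 patients
.table5_counts <- function() {
  read.table(text = "
variant hom het
c.176_191del16 0 1
c.235delC 12 4
c.299_300delAT 2 9
c.571T>G 0 2
c.538C>T 0 1
c.580G>A 0 6
IVS7-2A>G 2 4
c.1229C>T 0 4
IVS15+5G>A 0 1
c.2168A>G 0 3
c.1494C>T 1 0
c.1555A>G 5 0
", header = TRUE, stringsAsFactors = FALSE)
}

.table6_pairs <- function() {
  read.table(text = "
variant_a	variant_b	n
IVS7-2A>G	c.1229C>T	1
IVS7-2A>G	c.2168A>G	1
c.235delC	c.176_191del16	1
c.235delC	c.299_300delAT	6
", header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' The 171-patient SNHL cohort
#'
#' Built by [cohort_from_counts()] from the patient cohort's per-variant
#' zygosity marginals (22 homozygous and 35 heterozygous entries, 57 in all)
#' and its compound-heterozygote table.  The printed pair counts over-demand
#' the c.235delC het budget, so the default mode is `"reconcile"`: pairs are
#' capped at the remaining budget (with a warning) and all marginal counts
#' are preserved exactly.
#'
#' @inheritParams cohort_from_counts
#' @param panel an `lg_panel`.
#' @return list of 171 [sample_truth()] objects.
#' @export
cohort_samples_table5 <- function(panel = builtin_panel_hl32(), seed = 1L,
                                  mode = "reconcile") {
  cohort_from_counts(panel, .table5_counts(), .table6_pairs(),
                     n_total = 171L, seed = seed, mode = mode)
}

# -------------------------------------------------------------------------
# Peak simulation
# -------------------------------------------------------------------------

#' Instrument noise model for peak simulation
#'
#' @param size_sd standard deviation (nt) of measured peak size around the
#'   expected product size.
#' @param height_mean_log,height_sd_log log-normal peak-height parameters
#'   (RFU scale).
#' @param het_imbalance_sd jitter (SD) of the alt-allele height fraction
#'   around 0.5 at heterozygous loci.
#' @param baseline_rate expected number of spurious baseline peaks per
#'   sample (Poisson); baseline peaks fall below the calling threshold
#'   (heights in `baseline_height`).
#' @param baseline_height low/high bounds (RFU) for baseline peak heights.
#' @param dropout_prob per-allele probability of complete peak dropout.
#' @return list of class `lg_noise`.
#' @export
noise_model <- function(size_sd = 0.15, height_mean_log = log(2000),
                        height_sd_log = 0.35, het_imbalance_sd = 0.05,
                        baseline_rate = 2, baseline_height = c(20, 80),
                        dropout_prob = 0) {
  stopifnot(size_sd >= 0, height_sd_log >= 0, het_imbalance_sd >= 0,
            baseline_rate >= 0, dropout_prob >= 0, dropout_prob < 1)
  structure(list(size_sd = size_sd, height_mean_log = height_mean_log,
                 height_sd_log = height_sd_log,
                 het_imbalance_sd = het_imbalance_sd,
                 baseline_rate = baseline_rate,
                 baseline_height = baseline_height,
                 dropout_prob = dropout_prob),
            class = "lg_noise")
}

#' Noise-free instrument model
#'
#' Deterministic read-out: exact product sizes, fixed peak heights, no
#' baseline peaks, no dropout.  Useful for encode/decode identity checks.
#' @return an [noise_model()] object with all stochastic terms zeroed.
#' @export
noise_none <- function() {
  noise_model(size_sd = 0, height_sd_log = 0, het_imbalance_sd = 0,
              baseline_rate = 0, dropout_prob = 0)
}

# default size standard co-electrophoresed with every sample
.ladder_sizes <- function(panel) {
  lo <- floor(panel$size_range[1] / 20) * 20 - 20
  hi <- ceiling(panel$size_range[2] / 20) * 20 + 20
  seq(max(lo, 20), hi, by = 20)
}

# migration model: raw scanpoint units as a smooth monotone function of size
.migration <- function(size) 2000 + 12 * size + 0.01 * size^2

#' Simulate one sample's capillary electropherogram peak table
#'
#' Emits one peak per allele present: at the product's expected size plus
#' Gaussian sizing noise, on the product's dye, with log-normal height.
#' Heterozygous loci split the locus signal between both allele peaks with a
#' jittered 50/50 ratio; mitochondrial loci split it by the homoplasmy
#' fraction.  Poisson-distributed spurious baseline peaks (below the calling
#' threshold) are added at uniform sizes and dyes, and the size-standard
#' ladder is appended in raw migration units.
#'
#' @param panel an `lg_panel`.
#' @param truth a [sample_truth()].
#' @param noise an [noise_model()].
#' @param seed integer seed for this sample's random draws.
#' @return object of class `lg_peak_table`: `sample_id`, `peaks` data.frame
#'   (`dye`, `raw`, `size`, `height`), `ladder` data.frame (`raw`, `size`).
#' @export
simulate_sample <- function(panel, truth, noise = noise_model(), seed = 1L) {
  .check_truth_panel(list(truth), panel)
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  vs <- panel$variants
  peaks <- list()
  emit <- function(variant, allele, h) {
    pr <- panel$products
    row <- pr[pr$variant == variant & pr$allele == allele, ]
    if (h <= 0) return()
    if (noise$dropout_prob > 0 && stats::runif(1) < noise$dropout_prob) return()
    size <- row$size + stats::rnorm(1, 0, noise$size_sd)
    peaks[[length(peaks) + 1]] <<- data.frame(
      dye = row$dye, raw = .migration(size), size = size, height = h,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(vs))) {
    v <- vs$name[i]
    g <- truth$genotypes[[v]]
    if (is.null(g)) g <- if (vs$inheritance[i] == "MT") 0 else "hom_ref"
    # one locus-level signal, partitioned between the allele products
    h_locus <- exp(stats::rnorm(1, noise$height_mean_log, noise$height_sd_log))
    if (is.numeric(g)) {                       # mitochondrial: fraction
      if (g < 1) emit(v, "ref", h_locus * (1 - g))
      if (g > 0) emit(v, "alt", h_locus * g)
    } else if (g == "hom_ref") {
      emit(v, "ref", h_locus)
    } else if (g == "hom_alt") {
      emit(v, "alt", h_locus)
    } else {                                   # het: split with ratio jitter
      p <- 0.5 + stats::rnorm(1, 0, noise$het_imbalance_sd)
      p <- min(max(p, 0.05), 0.95)
      emit(v, "ref", h_locus * (1 - p))
      emit(v, "alt", h_locus * p)
    }
  }
  n_spur <- if (noise$baseline_rate > 0) stats::rpois(1, noise$baseline_rate) else 0L
  if (n_spur > 0) for (j in seq_len(n_spur)) {
    size <- stats::runif(1, panel$size_range[1], panel$size_range[2])
    peaks[[length(peaks) + 1]] <- data.frame(
      dye = sample(.DYES, 1), raw = .migration(size), size = size,
      height = stats::runif(1, noise$baseline_height[1],
                            noise$baseline_height[2]),
      stringsAsFactors = FALSE)
  }
  peaks <- if (length(peaks) > 0) do.call(rbind, peaks) else
    data.frame(dye = character(), raw = numeric(), size = numeric(),
               height = numeric(), stringsAsFactors = FALSE)
  ladder_nt <- .ladder_sizes(panel)
  structure(list(sample_id = truth$sample_id, peaks = peaks,
                 ladder = data.frame(raw = .migration(ladder_nt),
                                     size = ladder_nt)),
            class = "lg_peak_table")
}

#' @export
print.lg_peak_table <- function(x, ...) {
  cat("Peak table for sample", x$sample_id, "-", nrow(x$peaks), "peaks,",
      nrow(x$ladder), "ladder points\n")
  invisible(x)
}

#' Simulate a cohort of peak tables
#'
#' Maps [simulate_sample()] over a truth list with per-sample seeds derived
#' from `seed`, so output is order-stable and reproducible.
#'
#' @param panel an `lg_panel`.
#' @param truths list of [sample_truth()] objects.
#' @param noise an [noise_model()].
#' @param seed integer base seed.
#' @return list of `lg_peak_table`, one per truth, in order.
#' @export
simulate_cohort <- function(panel, truths, noise = noise_model(), seed = 1L) {
  lapply(seq_along(truths), function(i) {
    simulate_sample(panel, truths[[i]], noise,
                    seed = (as.integer(seed) %% 59999L) * 30011L + i)
  })
}
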