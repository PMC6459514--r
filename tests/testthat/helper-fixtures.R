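# shared test fixtures, all generated in code

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# small abstract-layout panel with random SNV / deletion variants
random_panel <- function(n_loci, seed, p_del = 0.3, n_mt = 0) {
  set.seed(seed)
  vs <- do.call(rbind, lapply(seq_len(n_loci), function(i) {
    if (runif(1) < p_del) {
      ref <- rand_dna(sample(1:4, 1)); alt <- "-"
    } else {
      ref <- rand_dna(1); alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    }
    is_mt <- i <= n_mt
    data.frame(gene = paste0("G", (i + 1) %/% 2),
               chrom = if (is_mt) "mtDNA" else "1",
               name = paste0("v", i), ref = ref, alt = alt,
               alt2 = NA_character_, rs = NA_character_,
               inheritance = if (is_mt) "MT" else "AR",
               amplicon = NA_character_, stringsAsFactors = FALSE)
  }))
  lay <- assign_layout(vs, design_params())
  lg_panel(paste0("toy", n_loci), vs, lay)
}

# random truth set over a panel
random_truths <- function(panel, n_samples, seed) {
  set.seed(seed)
  nuclear <- panel$variants$name[panel$variants$inheritance != "MT"]
  mt <- panel$variants$name[panel$variants$inheritance == "MT"]
  lapply(seq_len(n_samples), function(i) {
    g <- list()
    for (v in nuclear) {
      z <- sample(c("hom_ref", "het", "hom_alt"), 1, prob = c(0.5, 0.3, 0.2))
      if (z != "hom_ref") g[[v]] <- z
    }
    for (v in mt) {
      f <- sample(c(0, 1), 1)
      if (f > 0) g[[v]] <- f
    }
    sample_truth(sprintf("R%03d", i), g)
  })
}

# independent brute-force all-pairs collision check (oracle for validate_layout)
brute_force_collisions <- function(panel, tol) {
  pr <- panel$products
  hits <- 0
  n <- nrow(pr)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (pr$dye[i] == pr$dye[j] && abs(pr$size[i] - pr$size[j]) < 2 * tol)
      hits <- hits + 1
  }
  hits
}

# table 5/6 patient fixture, with the expected reconciliation warning muffled
quiet_table5 <- function(panel = builtin_panel_hl32(), seed = 1) {
  suppressWarnings(cohort_samples_table5(panel, seed))
}
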