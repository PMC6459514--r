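test_that("validation cohort fixture realizes the printed primary-finding counts", {
  p <- builtin_panel_hl32()
  t1 <- validation_samples_table1(p)
  expect_length(t1, 49)
  gt_of <- function(v) vapply(t1, function(t) {
    g <- t$genotypes[[v]]
    if (is.null(g)) "" else if (is.numeric(g)) as.character(g) else g
  }, "")
  # primary counts: only samples whose SOLE origin is the variant, plus pair hosts
  z235 <- gt_of("c.235delC")
  expect_equal(sum(z235 == "het"), 10)
  expect_equal(sum(z235 == "hom_alt"), 6)
  # 11 homoplasmic mitochondrial primaries + 2 added as pair second variants
  z1555 <- gt_of("c.1555A>G")
  expect_equal(sum(z1555 == "1"), 13)
  # het / hom primary totals: 29 + 20 = 49 one-per-patient findings
  n_primary_hom <- sum(vapply(t1, function(t) {
    g <- t$genotypes[[1]]  # first entry is the primary finding
    is.numeric(g) || identical(g, "hom_alt")
  }, logical(1)))
  expect_equal(n_primary_hom, 20)
  # dual-variant samples: exactly the nine reported pairs
  n_dual <- sum(vapply(t1, function(t) length(t$genotypes) >= 2, logical(1)))
  expect_equal(n_dual, 9)
  # the SLC26A4 compound het pair is present
  has_pair <- any(vapply(t1, function(t)
    identical(t$genotypes[["IVS7-2A>G"]], "het") &&
      identical(t$genotypes[["c.2168A>G"]], "het"), logical(1)))
  expect_true(has_pair)
  # fully deterministic
  expect_identical(t1, validation_samples_table1(p))
})

test_that("control cohort fixture has 5 carriers among 50, all heterozygous", {
  p <- builtin_panel_hl32()
  t4 <- control_samples_table4(p)
  expect_length(t4, 50)
  n_ivs7 <- sum(vapply(t4, function(t)
    identical(t$genotypes[["IVS7-2A>G"]], "het"), logical(1)))
  expect_equal(n_ivs7, 2)
  n_free <- sum(vapply(t4, function(t) length(t$genotypes) == 0, logical(1)))
  expect_equal(n_free, 45)
  any_hom <- any(vapply(t4, function(t)
    any(vapply(t$genotypes, identical, logical(1), "hom_alt")), logical(1)))
  expect_false(any_hom)
  # each carrier is a distinct sample
  n_carrier <- sum(vapply(t4, function(t) length(t$genotypes) > 0, logical(1)))
  expect_equal(n_carrier, 5)
})

test_that("cohort_from_counts reproduces marginals exactly in strict mode", {
  p <- builtin_panel_hl32()
  counts <- data.frame(variant = c("c.235delC", "IVS7-2A>G", "c.1555A>G"),
                       hom = c(3, 1, 2), het = c(5, 4, 0))
  pairs <- data.frame(variant_a = "c.235delC", variant_b = "IVS7-2A>G", n = 2)
  truths <- cohort_from_counts(p, counts, pairs, n_total = 30, seed = 9,
                               mode = "strict")
  expect_length(truths, 30)
  m <- truth_matrix(truths, p)
  expect_equal(sum(m[, "c.235delC"] == "1/1"), 3)
  expect_equal(sum(m[, "c.235delC"] == "0/1"), 5)
  expect_equal(sum(m[, "IVS7-2A>G"] == "0/1"), 4)
  expect_equal(sum(m[, "c.1555A>G"] == "1/1"), 2)
  expect_equal(sum(m[, "c.235delC"] == "0/1" & m[, "IVS7-2A>G"] == "0/1"), 2)
  # deterministic given seed
  expect_identical(truths, cohort_from_counts(p, counts, pairs, 30, seed = 9,
                                              mode = "strict"))
  expect_false(identical(truths, cohort_from_counts(p, counts, pairs, 30,
                                                    seed = 10, mode = "strict")))
})

test_that("infeasible pair demand errors in strict mode and caps with warning otherwise", {
  p <- builtin_panel_hl32()
  counts <- data.frame(variant = c("c.235delC", "c.299_300delAT"),
                       hom = c(0, 0), het = c(4, 9))
  pairs <- data.frame(variant_a = "c.235delC", variant_b = "c.299_300delAT",
                      n = 6)
  expect_error(cohort_from_counts(p, counts, pairs, 20, mode = "strict"),
               "infeasible pair")
  expect_warning(
    truths <- cohort_from_counts(p, counts, pairs, 20, mode = "reconcile"),
    "capped at 4")
  m <- truth_matrix(truths, p)
  # marginals still exact after capping
  expect_equal(sum(m[, "c.235delC"] == "0/1"), 4)
  expect_equal(sum(m[, "c.299_300delAT"] == "0/1"), 9)
  expect_equal(sum(m[, "c.235delC"] == "0/1" & m[, "c.299_300delAT"] == "0/1"), 4)
})

test_that("all-zero counts give a variant-free cohort", {
  p <- builtin_panel_hl32()
  counts <- data.frame(variant = "c.235delC", hom = 0, het = 0)
  truths <- cohort_from_counts(p, counts, NULL, 10, mode = "strict")
  expect_length(truths, 10)
  expect_true(all(vapply(truths, function(t) length(t$genotypes) == 0,
                         logical(1))))
})

test_that("patient cohort fixture preserves every printed marginal", {
  p <- builtin_panel_hl32()
  t5 <- quiet_table5(p)
  expect_length(t5, 171)
  m <- truth_matrix(t5, p)
  expected <- list(
    c("c.176_191del16", 0, 1), c("c.235delC", 12, 4),
    c("c.299_300delAT", 2, 9), c("c.571T>G", 0, 2),
    c("c.538C>T", 0, 1), c("c.580G>A", 0, 6),
    c("IVS7-2A>G", 2, 4), c("c.1229C>T", 0, 4),
    c("IVS15+5G>A", 0, 1), c("c.2168A>G", 0, 3),
    c("c.1494C>T", 1, 0), c("c.1555A>G", 5, 0))
  for (e in expected) {
    expect_equal(sum(m[, e[1]] == "1/1"), as.integer(e[2]), info = e[1])
    expect_equal(sum(m[, e[1]] == "0/1"), as.integer(e[3]), info = e[1])
  }
  # mitochondrial homozygotes are homoplasmic
  mt <- attr(m, "mt_fraction")
  expect_true(all(mt[m[, "c.1555A>G"] == "1/1", "c.1555A>G"] == 1))
})

test_that("zero-noise simulation emits exact allele peaks", {
  p <- builtin_panel_hl32()
  # all reference: one peak per locus at the exact ref product size
  pt <- simulate_sample(p, sample_truth("s", list()), noise_none(), seed = 1)
  expect_equal(nrow(pt$peaks), nrow(p$variants))
  ref_sizes <- p$products$size[p$products$allele == "ref"]
  expect_equal(sort(pt$peaks$size), sort(ref_sizes))
  # homozygous alt: alt peak present, ref peak absent at that locus
  pt2 <- simulate_sample(p, sample_truth("s2", list(c.235delC = "hom_alt")),
                         noise_none(), seed = 1)
  epr <- expected_products(p, "c.235delC")
  at <- function(pt, row) any(pt$peaks$dye == row$dye &
                                abs(pt$peaks$size - row$size) < 1e-9)
  expect_true(at(pt2, epr[epr$allele == "alt", ]))
  expect_false(at(pt2, epr[epr$allele == "ref", ]))
  # heterozygous: both peaks, equal heights at zero imbalance
  pt3 <- simulate_sample(p, sample_truth("s3", list(c.235delC = "het")),
                         noise_none(), seed = 1)
  h <- pt3$peaks$height[pt3$peaks$dye %in% epr$dye &
                          (abs(pt3$peaks$size - epr$size[1]) < 1e-9 |
                             abs(pt3$peaks$size - epr$size[2]) < 1e-9)]
  expect_equal(length(h), 2)
  expect_equal(h[1], h[2])
})

test_that("size noise keeps nearly all peaks within half a nucleotide", {
  tp <- random_panel(3, seed = 5)
  truths <- rep(list(sample_truth("s", list())), 400)
  for (i in seq_along(truths)) truths[[i]]$sample_id <- paste0("s", i)
  pts <- simulate_cohort(tp, truths, noise_model(), seed = 77)
  errs <- unlist(lapply(pts, function(pt) {
    ref <- tp$products[tp$products$allele == "ref", ]
    vapply(seq_len(nrow(ref)), function(j) {
      cand <- pt$peaks$size[pt$peaks$dye == ref$dye[j]]
      min(abs(cand - ref$size[j]))
    }, numeric(1))
  }))
  # size_sd = 0.15 nt: 0.5 nt is a 3.3 sigma excursion
  expect_gt(mean(errs <= 0.5), 0.99)
})

test_that("cohort simulation is seed-deterministic and order-stable", {
  p <- builtin_panel_hl32()
  t4 <- control_samples_table4(p)[1:6]
  a <- simulate_cohort(p, t4, noise_model(), seed = 3)
  b <- simulate_cohort(p, t4, noise_model(), seed = 3)
  expect_identical(a, b)
  c <- simulate_cohort(p, t4, noise_model(), seed = 4)
  expect_false(identical(a, c))
  expect_equal(vapply(a, `[[`, "", "sample_id"),
               vapply(t4, `[[`, "", "sample_id"))
  expect_identical(simulate_cohort(p, list(), noise_model(), seed = 1), list())
})
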