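test_that("size calling is exact at ladder points and linear between collinear points", {
  lad <- data.frame(raw = seq(100, 900, 100), size = seq(50, 450, 50))
  at_points <- size_call(lad$raw, lad)
  expect_equal(at_points$size, lad$size)
  # perfectly linear ladder: midway peak sizes to the arithmetic mean
  mid <- size_call(c(150, 450), lad)
  expect_equal(mid$size, c(75, 225))
  expect_false(any(mid$off_size))
})

test_that("local Southern sizing inverts a reciprocal migration curve exactly", {
  # ladder generated from L = c + a/(m - b); the fit must recover any L
  a <- -30000; b <- 12000; cc <- 400
  L <- c(50, 75, 100, 139, 150, 200, 250, 300, 340)
  lad <- data.frame(raw = b + a / (L - cc), size = L)
  x <- c(51.3, 62.3, 88.8, 141.77, 199.99, 260.5, 339.1)
  res <- size_call(b + a / (x - cc), lad)
  expect_equal(res$size, x, tolerance = 1e-9)
  expect_false(any(res$off_size))
})

test_that("size calling is strictly monotone and flags off-ladder peaks", {
  set.seed(13)
  sz <- seq(60, 300, 20)
  lad <- data.frame(raw = 2000 + 12 * sz + 0.01 * sz^2, size = sz)
  raws <- sort(runif(50, min(lad$raw) - 200, max(lad$raw) + 200))
  res <- size_call(raws, lad)
  expect_true(all(diff(res$size) > 0))
  expect_true(all(res$off_size == (raws < min(lad$raw) | raws > max(lad$raw))))
  expect_error(size_call(1, lad[1:3, ]), "at least 4")
  bad <- lad; bad$raw[2] <- bad$raw[4]
  expect_error(size_call(1, bad), "increasing")
})

test_that("peaks match the unique same-dye product within tolerance", {
  p <- builtin_panel_hl32()
  pt <- simulate_sample(p, sample_truth("s", list()), noise_none(), seed = 1)
  matched <- match_products(p, pt$peaks)
  for (v in p$variants$name) {
    h <- matched[[v]]$heights
    expect_gt(h[["ref"]], 0)
    expect_true(all(h[setdiff(names(h), "ref")] == 0))
  }
  # a spurious peak >= 7 nt from every same-dye product stays unassigned
  epr <- expected_products(p, "c.235delC")
  ref <- epr[epr$allele == "ref", ]
  same_dye <- p$products$size[p$products$dye == ref$dye]
  spur_size <- ref$size + 7
  while (min(abs(same_dye - spur_size)) < 7) spur_size <- spur_size + 1
  spur <- data.frame(dye = ref$dye, size = spur_size, height = 5000)
  m2 <- match_products(p, spur)
  expect_true(all(vapply(m2, function(x) all(x$heights == 0), logical(1))))
  # two peaks inside one product window: tallest kept, ambiguous flag
  two <- data.frame(dye = ref$dye, size = c(ref$size - 0.5, ref$size + 0.5),
                    height = c(800, 1500))
  m3 <- match_products(p, two)
  expect_equal(m3[["c.235delC"]]$heights[["ref"]], 1500)
  expect_true("ambiguous" %in% m3[["c.235delC"]]$flags)
})

test_that("allele-ratio zygosity rules cover all regimes", {
  thr <- call_thresholds()
  nuc <- list(name = "x", inheritance = "AR")
  call_of <- function(r, a, v = nuc)
    call_locus(v, c(ref = r, alt = a), thr)
  expect_equal(call_of(1200, 0)$call, "hom_ref")
  expect_equal(call_of(0, 1400)$call, "hom_alt")
  res <- call_of(1000, 950)
  expect_equal(res$call, "het")
  expect_equal(res$allele_ratio, 950 / 1950, tolerance = 1e-12)
  # ratio in the dead zone between het band and homozygote override
  expect_equal(call_of(1000, 200)$call, "no_call")   # ratio 0.167
  expect_match(call_of(1000, 200)$flags, "ambiguous")
  expect_equal(call_of(1000, 90)$call, "hom_ref")    # ratio 0.083 < 0.1 (and < min_height)
  expect_equal(call_of(1000, 105)$call, "hom_ref")   # ratio 0.095 < 0.1
  expect_equal(call_of(80, 1000)$call, "hom_alt")    # ref below threshold
  nores <- call_of(0, 0)
  expect_equal(nores$call, "no_call")
  expect_match(nores$flags, "low_signal")
  # sub-threshold peaks are invisible to calling
  expect_equal(call_of(60, 70)$call, "no_call")
})

test_that("mitochondrial loci report homoplasmy fraction with the 0.95 cutoff", {
  thr <- call_thresholds()
  mt <- list(name = "m", inheritance = "MT")
  only_alt <- call_locus(mt, c(ref = 0, alt = 2000), thr)
  expect_equal(only_alt$call, "hom_alt")      # homoplasmic alt
  expect_equal(only_alt$mt_fraction, 1)
  hetero <- call_locus(mt, c(ref = 600, alt = 1400), thr)
  expect_equal(hetero$call, "het")            # heteroplasmic
  expect_equal(hetero$mt_fraction, 0.7)
  near_ref <- call_locus(mt, c(ref = 2000, alt = 101), thr)
  expect_equal(near_ref$call, "hom_ref")      # fraction 0.048 <= 0.05
})

test_that("no-call rate is monotone non-decreasing in the height threshold", {
  p <- builtin_panel_hl32()
  t1 <- validation_samples_table1(p)[1:10]
  pts <- simulate_cohort(p, t1, noise_model(), seed = 5)
  rates <- vapply(c(100, 1000, 2000, 4000), function(mh) {
    cm <- call_batch(p, pts, call_thresholds(min_height = mh))
    mean(cm == "./.")
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[length(rates)], rates[1])
})

test_that("batch calling produces one call per sample and locus", {
  p <- builtin_panel_hl32()
  t4 <- control_samples_table4(p)[1:7]
  pts <- simulate_cohort(p, t4, noise_model(), seed = 2)
  cm <- call_batch(p, pts)
  expect_equal(dim(cm), c(7, 32))
  expect_equal(rownames(cm), vapply(t4, `[[`, "", "sample_id"))
  expect_true(all(cm %in% c("0/0", "0/1", "1/1", "./.")))
  # zero-noise single-het sample: that locus het, everything else hom_ref
  tr <- sample_truth("z", list(c.299_300delAT = "het"))
  cz <- call_sample(p, simulate_sample(p, tr, noise_none(), seed = 1))
  expect_equal(cz$gt[cz$variant == "c.299_300delAT"], "0/1")
  expect_true(all(cz$gt[cz$variant != "c.299_300delAT"] == "0/0"))
})

test_that("concordance scores exact zygosity agreement per cell", {
  m <- matrix("0/0", 2, 2, dimnames = list(c("s1", "s2"), c("v1", "v2")))
  t <- m; t["s1", "v1"] <- "0/1"
  c1 <- concordance(t, t)
  expect_equal(c1$sensitivity, 100)
  expect_equal(c1$specificity, 100)
  # one false negative among positives
  tt <- matrix("0/1", 10, 10,
               dimnames = list(paste0("s", 1:10), paste0("v", 1:10)))
  cc <- tt; cc[1, 1] <- "0/0"
  c2 <- concordance(tt, cc)
  expect_equal(c2$sensitivity, 99.0)
  expect_equal(nrow(c2$discordant), 1)
  # zygosity mismatch counts as discordant even though the variant was seen
  cz <- tt; cz[1, 1] <- "1/1"
  expect_equal(concordance(tt, cz)$sensitivity, 99.0)
  expect_error(concordance(tt, cc[, 1:5]), "axes")
})

test_that("raw-unit peak tables are size-called through the ladder before matching", {
  p <- builtin_panel_hl32()
  tr <- sample_truth("r", list(c.235delC = "het", `c.1555A>G` = 1.0))
  pt <- simulate_sample(p, tr, noise_model(), seed = 8)
  pt$peaks$size <- NA_real_  # raw mode: force ladder-based sizing
  calls <- call_sample(p, pt)
  expect_equal(calls$gt[calls$variant == "c.235delC"], "0/1")
  expect_equal(calls$gt[calls$variant == "c.1555A>G"], "1/1")
  expect_equal(calls$mt_fraction[calls$variant == "c.1555A>G"], 1)
  pt$ladder <- NULL
  expect_error(call_sample(p, pt), "ladder")
})
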