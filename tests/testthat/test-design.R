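test_that("nearest-neighbor Tm matches independent oracle computations", {
  # values computed independently by summing published unified NN dH/dS
  # terms with the entropic salt correction (frozen oracle outputs)
  expect_equal(melting_temperature("AGCTGACCTGAAGCATTGCA", 50, 250),
               56.616587, tolerance = 0.5 / 56)
  expect_equal(melting_temperature("TTGACTGGAGCAATCGGATCGT", 50, 250),
               58.179532, tolerance = 0.5 / 58)
  expect_equal(melting_temperature("AGCTGACCTGAAGCATTGCA", 100, 100),
               58.762971, tolerance = 0.5 / 58)
  # self-complementary duplex: symmetry correction applies
  expect_equal(melting_temperature("CGCGCGCGATATCGCGCGCG", 50, 250),
               69.986789, tolerance = 0.5 / 70)
})

test_that("Tm is duplex-symmetric and rejects invalid input", {
  revcomp <- function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  set.seed(7)
  for (i in 1:10) {
    s <- rand_dna(sample(10:30, 1))
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)),
                 info = s)
  }
  expect_error(melting_temperature("ACGT"), "short")
  expect_error(melting_temperature("ACGTACGNACGT"), "ACGT")
})

test_that("designed probe arms hit the Tm window and encode the allele at the 3' end", {
  set.seed(21)
  params <- design_params()
  for (i in 1:8) {
    f5 <- rand_dna(60); f3 <- rand_dna(60)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ps <- design_probe_set(f5, f3, list(name = "v", ref = ref, alt = alt), params)
    expect_true(all(abs(ps$tm - params$target_tm) <= params$tm_window))
    pr <- ps$probe5_ref$allele_specific_seq
    pa <- ps$probe5_alt$allele_specific_seq
    expect_equal(nchar(pr), nchar(pa))
    expect_equal(substr(pr, 1, nchar(pr) - 1), substr(pa, 1, nchar(pa) - 1))
    expect_equal(substr(pr, nchar(pr), nchar(pr)), ref)
    expect_equal(substr(pa, nchar(pa), nchar(pa)), alt)
    expect_true(startsWith(f3, ps$probe3_common$anneal_seq))
  }
})

test_that("deletion alleles are probed across the deletion junction", {
  set.seed(22)
  f5 <- rand_dna(60); f3 <- rand_dna(60)
  ps <- design_probe_set(f5, f3, list(name = "d", ref = "ACGT", alt = "-"))
  pa <- ps$probe5_alt$allele_specific_seq
  # alt probe = 5' arm + first bases of the 3' flank (deleted bases skipped)
  expect_true(endsWith(pa, substr(f3, 1, 2)))
  arm <- substr(pa, 1, nchar(pa) - 2)
  expect_true(endsWith(f5, arm))
  # ref probe ends in the (retained) ref bases
  expect_true(endsWith(ps$probe5_ref$allele_specific_seq, "ACGT"))
})

test_that("unreachable Tm windows are reported with the achieved range", {
  err <- tryCatch(
    design_probe_set(strrep("A", 60), strrep("A", 60),
                     list(name = "pa", ref = "G", alt = "A")),
    error = conditionMessage)
  expect_match(err, "achieved")
  # poly-A arms top out far below the 59 C window floor
  expect_lt(melting_temperature(strrep("A", 35)), 59)
})

test_that("layout assignment places every locus collision-free with distinct allele dyes", {
  # single locus
  vs1 <- data.frame(gene = "G", chrom = "1", name = "x", ref = "A", alt = "C",
                    inheritance = "AR", stringsAsFactors = FALSE)
  lay <- assign_layout(vs1, design_params())
  expect_equal(nrow(lay), 2)
  expect_false(lay$dye[1] == lay$dye[2])
  expect_true(all(lay$size >= 80 & lay$size <= 260))

  # 33 loci (66 products) in a 100-250 nt window at 3 nt separation: feasible
  vs33 <- do.call(rbind, lapply(1:33, function(i) {
    data.frame(gene = "G", chrom = "1", name = paste0("v", i),
               ref = "A", alt = "C", inheritance = "AR",
               stringsAsFactors = FALSE)
  }))
  p33 <- design_params(size_range = c(100, 250))
  lay33 <- assign_layout(vs33, p33)
  expect_equal(nrow(lay33), 66)
  pan33 <- lg_panel("t33", vs33, lay33, size_range = c(100, 250))
  expect_equal(brute_force_collisions(pan33, 1.5), 0)

  # random panels with deletions: always collision-free by the oracle
  for (seed in 1:6) {
    tp <- random_panel(8, seed)
    expect_equal(brute_force_collisions(tp, tp$tolerance), 0,
                 info = paste("seed", seed))
  }
})

test_that("layout feasibility is monotone in window size and separation", {
  vs <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(gene = "G", chrom = "1", name = paste0("v", i),
               ref = "A", alt = "C", stringsAsFactors = FALSE)
  }))
  tight <- design_params(size_range = c(100, 128), min_separation = 3,
                         stuffer_step = 3)
  lay <- assign_layout(vs, tight)            # 40 products, 40 slots: feasible
  expect_equal(nrow(lay), 40)
  # enlarging the window keeps it feasible
  wide <- design_params(size_range = c(100, 200), min_separation = 3,
                        stuffer_step = 3)
  expect_equal(nrow(assign_layout(vs, wide)), 40)
  # reducing separation keeps it feasible
  finer <- design_params(size_range = c(100, 128), min_separation = 2,
                         stuffer_step = 3)
  expect_equal(nrow(assign_layout(vs, finer)), 40)
  # an infeasible instance errors with a slot accounting
  too_small <- design_params(size_range = c(100, 110), min_separation = 3,
                             stuffer_step = 3)
  expect_error(assign_layout(vs, too_small), "infeasible")
})

test_that("amplicon grouping is single-linkage and achieves the minimum group count", {
  pos2 <- data.frame(variant = c("a", "b"), contig = "c1", offset = c(0, 50))
  expect_equal(length(group_amplicons(pos2, 600)), 1)
  pos2$offset <- c(0, 10000)
  expect_equal(length(group_amplicons(pos2, 600)), 2)

  # brute force over set partitions: a grouping is valid if every group is
  # chain-connected at the linking distance; minimal count must match greedy
  min_groups_brute <- function(offsets, maxlen) {
    n <- length(offsets)
    best <- n
    assign_next <- function(labels, i, k) {
      if (i > n) {
        for (g in seq_len(k)) {
          o <- sort(offsets[labels[1:n] == g])
          if (length(o) > 1 && any(diff(o) > maxlen)) return(invisible())
        }
        best <<- min(best, k)
        return(invisible())
      }
      for (g in seq_len(min(k + 1, n))) {
        labels[i] <- g
        assign_next(labels, i + 1, max(k, g))
      }
    }
    assign_next(integer(n), 1, 0)
    best
  }
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    offsets <- sort(sample(0:4000, n))
    pos <- data.frame(variant = paste0("v", 1:n), contig = "c", offset = offsets)
    greedy <- length(group_amplicons(pos, 600))
    expect_equal(greedy, min_groups_brute(offsets, 600),
                 info = paste(offsets, collapse = ","))
  }
})

test_that("flanks FASTA reader parses bracketed allele tokens and metadata", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">snv1|GENE1|13|AR", "ACGTACGT[C/T]GGATCCAA",
               ">del1", "TTTTCCCC[AG/-]AAGGTTCC"), f)
  ft <- read_flanks_fasta(f)
  expect_equal(nrow(ft), 2)
  expect_equal(ft$gene[1], "GENE1")
  expect_equal(ft$ref, c("C", "AG"))
  expect_equal(ft$alt, c("T", "-"))
  expect_equal(ft$flank5[2], "TTTTCCCC")
  expect_equal(ft$flank3[2], "AAGGTTCC")
  writeLines(c(">bad", "ACGTACGTGGATCCAA"), f)
  expect_error(read_flanks_fasta(f), "REF/ALT")
})

test_that("full sequence-level design round trip decodes genotypes exactly", {
  set.seed(31)
  ft <- do.call(rbind, lapply(1:5, function(i) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    data.frame(name = paste0("v", i), gene = paste0("g", i), chrom = "1",
               inheritance = "AR", flank5 = rand_dna(60), ref = ref,
               alt = alt, flank3 = rand_dna(60), stringsAsFactors = FALSE)
  }))
  pan <- design_panel(ft, name = "seqtoy")
  expect_equal(nrow(validate_layout(pan)), 0)
  truths <- list(sample_truth("s1", list(v1 = "het", v4 = "hom_alt")),
                 sample_truth("s2", list(v2 = "het", v3 = "het")))
  pts <- simulate_cohort(pan, truths, noise_none(), seed = 1)
  cm <- call_batch(pan, pts)
  cc <- concordance(truth_matrix(truths, pan), cm)
  expect_equal(cc$sensitivity, 100)
  expect_equal(cc$specificity, 100)
})
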