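test_that("pipeline CSV round trip is the identity", {
  sim <- simulate_population(simulation_config(n_groups = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(sim$dataset, path)
  back <- read_genotypes(path, "csv")
  expect_equal(back$calls, sim$dataset$calls)
  expect_equal(back$meta$id, sim$dataset$meta$id)
  expect_equal(back$meta$status, sim$dataset$meta$status)
  # second round trip is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("packaged 3-individual fixture parses to the hand-written table", {
  ds <- read_genotypes(system.file("extdata", "mini_genotypes.csv",
                                   package = "kinrecon"), "csv")
  expect_equal(ds$loci, c("LocA", "LocB"))
  expect_equal(ds$meta$id, c("f1", "f2", "o1"))
  expect_equal(unname(ds$calls["f1", ]), c(101, 103, 202, 204))
  expect_equal(unname(ds$calls["o1", c("LocA_1", "LocA_2")]), c(103, 105))
  expect_true(all(is.na(ds$calls["o1", c("LocB_1", "LocB_2")])))
  expect_equal(ds$meta$sl_mm, c(55, 44, 12))
})

test_that("GenePop import handles Pop blocks and 0000 missing codes", {
  gp <- c("Title line", "LocA", "LocB", "Pop",
          "ind1 , 0101 0203", "ind2 , 0102 0000",
          "Pop", "ind3 , 0303 0104")
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(gp, path)
  ds <- read_genotypes(path, "genepop")
  expect_equal(ds$meta$population, c("pop1", "pop1", "pop2"))
  expect_equal(unname(ds$calls["ind1", ]), c(1, 1, 2, 3))
  expect_true(all(is.na(ds$calls["ind2", c("LocB_1", "LocB_2")])))
  expect_equal(unname(ds$calls["ind3", c("LocA_1", "LocA_2")]), c(3, 3))
})

test_that("dataset validation rejects malformed input", {
  calls <- matrix(c(1, 2), 1, 2, dimnames = list(NULL, c("L1_1", "L1_2")))
  expect_error(genotype_dataset(rbind(calls, calls),
                                data.frame(id = c("a", "a"))), "duplicate")
  expect_error(genotype_dataset(matrix(1, 1, 3), data.frame(id = "a")),
               "even")
  expect_error(genotype_dataset(calls, data.frame(id = "a", status = "king")),
               "unknown status")
  m2 <- data.frame(id = c("a", "b"), group = c("G1", "G2"),
                   subgroup = c("S1", "S1"))
  expect_error(genotype_dataset(rbind(calls, calls), m2),
               "more than one group")
})

test_that("naive allele frequencies count alleles; floor is bounded", {
  calls <- matrix(c(1, 1, 1, 2), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("L1_1", "L1_2")))
  ds <- genotype_dataset(calls, data.frame(id = c("a", "b")))
  f <- estimate_allele_frequencies(ds, "naive", floor = FALSE)
  expect_equal(unname(f$L1), c(0.75, 0.25))
  # floor changes no frequency by more than the floor value 1/(2N+1)
  sim <- simulate_population(simulation_config(n_groups = 2, seed = 9))
  n <- n_individuals(sim$dataset)
  f0 <- estimate_allele_frequencies(sim$dataset, "naive", floor = FALSE)
  f1 <- estimate_allele_frequencies(sim$dataset, "naive", floor = TRUE)
  for (l in names(f0))
    expect_lt(max(abs(f0[[l]] - f1[[l]])), 1 / (2 * n + 1) + 1e-12)
})

test_that("relatedness correction: no-op on unrelateds, helps with families", {
  fb <- uniform_block(8, 8)
  # unrelated HWE sample: corrected ~ naive
  un <- family_dataset(fb, integer(0), n_unrelated = 60, seed = 2)$dataset
  fn <- estimate_allele_frequencies(un, "naive", floor = FALSE)
  fc <- estimate_allele_frequencies(un, "corrected", floor = FALSE)
  for (l in names(fn))
    expect_lt(max(abs(fc[[l]][names(fn[[l]])] - fn[[l]])), 1e-3)
  # one large family + few unrelateds: corrected closer to founder truth
  fam <- family_dataset(fb, fam_sizes = 30, n_unrelated = 6, seed = 5)$dataset
  fn2 <- estimate_allele_frequencies(fam, "naive", floor = FALSE)
  fc2 <- estimate_allele_frequencies(fam, "corrected", floor = FALSE)
  l1 <- function(est) sum(vapply(names(fb), function(l) {
    truth <- fb[[l]]
    e <- est[[l]][names(truth)]
    e[is.na(e)] <- 0
    sum(abs(e - truth))
  }, numeric(1)))
  expect_lt(l1(fc2), l1(fn2))
})

test_that("zero-call locus is reported, not dropped", {
  calls <- matrix(c(1, 2, NA, NA), 1, 4,
                  dimnames = list(NULL, c("L1_1", "L1_2", "L2_1", "L2_2")))
  ds <- genotype_dataset(calls, data.frame(id = "a"))
  expect_error(estimate_allele_frequencies(ds, "naive"), "L2")
})

test_that("HWE Monte-Carlo test: modal table, excess heterozygotes, mono", {
  mk <- function(n_aa, n_ab, n_bb) {
    a1 <- c(rep(1, n_aa), rep(1, n_ab), rep(2, n_bb))
    a2 <- c(rep(1, n_aa), rep(2, n_ab), rep(2, n_bb))
    calls <- cbind(L1_1 = a1, L1_2 = a2)
    genotype_dataset(calls, data.frame(id = sprintf("i%d", seq_len(nrow(calls)))))
  }
  expect_gte(hwe_test(mk(25, 50, 25), "L1", n_mc = 2000, seed = 1), 0.99)
  expect_lt(hwe_test(mk(0, 50, 0), "L1", n_mc = 10000, seed = 1), 0.01)
  expect_warning(p <- hwe_test(mk(10, 0, 0), "L1", n_mc = 100, seed = 1),
                 "monomorphic")
  expect_equal(p, 1)
  expect_error(hwe_test(mk(2, 1, 0), "L1", n_mc = 100, seed = 1), ">= 5")
})

test_that("HWE test holds its type-I error on simulated HWE loci", {
  # 400 replicates at n_mc = 400 (scaled down from the 1000-replicate
  # calibration for runtime; binomial SE ~ 0.011 keeps [0.03, 0.07] sharp)
  set.seed(31)
  p <- replicate(400, {
    a <- sample(1:6, 100, TRUE)
    calls <- matrix(a, 50, 2, dimnames = list(NULL, c("L1_1", "L1_2")))
    ds <- genotype_dataset(calls, data.frame(id = sprintf("i%d", 1:50)))
    hwe_test(ds, "L1", n_mc = 400, seed = sample.int(1e6, 1))
  })
  rej <- mean(p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
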