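mk_partition <- function(clusters) {
  assignment <- integer(0)
  for (k in seq_along(clusters))
    assignment <- c(assignment,
                    stats::setNames(rep(k, length(clusters[[k]])),
                                    clusters[[k]]))
  structure(list(assignment = assignment, clusters = clusters),
            class = "kin_partition")
}
mk_parentage <- function(offspring = character(), parent = character(),
                         role = character()) {
  n <- length(offspring)
  data.frame(offspring = offspring, parent = parent, sex_role = role,
             mismatches = rep(0L, n), age_feasible = rep(TRUE, n),
             lr_po_u = rep(5, n), accepted = rep(TRUE, n),
             stringsAsFactors = FALSE)
}

test_that("immigrant classes follow the kin-link and kin-group rules", {
  ages <- c(a = 100, b = 400, c = 380, d = 50, e = 60, f = 200)
  # a has an accepted parent (b) in the group -> non-immigrant
  part <- mk_partition(list(c("a"), c("b", "c"), c("d", "e"), c("f")))
  par <- mk_parentage("a", "b", "father")
  expect_equal(classify_immigrant("a", part, par, ages), "non-immigrant")
  # f: unique genotype; older cluster (b,c) and younger cluster (d,e)
  expect_equal(classify_immigrant("f", part, mk_parentage(), ages),
               "immigrant")
  # singleton with only an older kin-group -> possible immigrant
  part2 <- mk_partition(list(c("b", "c"), c("f")))
  expect_equal(classify_immigrant("f", part2, mk_parentage(),
                                  ages[c("b", "c", "f")]),
               "possible immigrant")
  # cluster co-membership (lateral kin) -> non-immigrant
  expect_equal(classify_immigrant("d", part, mk_parentage(), ages),
               "non-immigrant")
  # own offspring do not confer philopatry
  ages2 <- c(ages, g = 30)
  part3 <- mk_partition(list(c("f", "d"), c("b", "c"), c("e", "g")))
  par3 <- mk_parentage("d", "f", "mother")
  expect_equal(classify_immigrant("f", part3, par3, ages2), "immigrant")
  # missing age degrades to possible immigrant with a warning
  ages_na <- ages; ages_na["f"] <- NA
  expect_warning(cls <- classify_immigrant("f", part, mk_parentage(), ages_na),
                 "no age")
  expect_equal(cls, "possible immigrant")
})

test_that("classes are exhaustive and exclusive on random partitions", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    ids <- letters[seq_len(n)]
    k <- sample(seq_len(n), 1)
    part <- mk_partition(split(ids, sort(rep_len(seq_len(k), n))))
    ages <- stats::setNames(sample(50:500, n), ids)
    cls <- vapply(ids, function(i)
      classify_immigrant(i, part, mk_parentage(), ages), character(1))
    expect_true(all(cls %in% c("non-immigrant", "possible immigrant",
                               "immigrant")))
  }
})

test_that("inheritance detection: parent present, sibs, or nothing", {
  meta <- data.frame(id = c("bf", "dad", "sib", "x"),
                     status = c("breeder female", "breeder male",
                                "helper", "helper"),
                     sex = c("F", "M", "F", "M"), stringsAsFactors = FALSE)
  ages <- c(bf = 400, dad = 900, sib = 430, x = 100)
  links0 <- data.frame(id1 = character(), id2 = character(),
                       best = character(), significant = logical())
  # accepted other-sex parent in group
  res <- detect_inheritance("bf", meta, mk_parentage("bf", "dad", "father"),
                            links0, ages)
  expect_true(res$inherited); expect_equal(res$label, "MLI")
  # similar-aged full sib
  links <- data.frame(id1 = "bf", id2 = "sib", best = "FS",
                      significant = TRUE, stringsAsFactors = FALSE)
  res2 <- detect_inheritance("bf", meta, mk_parentage(), links, ages,
                             similar_age_window = 90)
  expect_true(res2$inherited)
  # same sib outside the age window
  ages2 <- ages; ages2["sib"] <- 800
  expect_false(detect_inheritance("bf", meta, mk_parentage(), links,
                                  ages2, 90)$inherited)
  # no kin in group
  expect_false(detect_inheritance("bf", meta, mk_parentage(), links0,
                                  ages)$inherited)
  expect_error(detect_inheritance("x", meta, mk_parentage(), links0, ages),
               "breeders only")
})

test_that("tenure bounds follow the min/max construction", {
  meta <- data.frame(id = c("bf", "o1", "o2", "older", "imm"),
                     stringsAsFactors = FALSE)
  ages <- c(bf = 600, o1 = 100, o2 = 40, older = 300, imm = 350)
  cls <- c(bf = "non-immigrant", o1 = "non-immigrant", o2 = "non-immigrant",
           older = "non-immigrant", imm = "immigrant")
  par <- mk_parentage(c("o1", "o2"), c("bf", "bf"), c("mother", "mother"))
  ten <- estimate_tenure("bf", meta, par, cls, ages)
  expect_equal(ten$t_min, 100)           # oldest own offspring
  expect_equal(ten$t_max, 300)           # next older non-immigrant
  expect_equal(ten$tenure, 200)
  expect_false(ten$censored)
  # immigrants never bound the maximum; with no qualifying elder: censored
  cls2 <- cls; cls2["older"] <- "immigrant"
  ten2 <- estimate_tenure("bf", meta, par, cls2, ages)
  expect_true(ten2$censored)
  expect_equal(ten2$tenure, 100)
  # no offspring and no older non-immigrant -> t_min 0, censored
  meta3 <- data.frame(id = "bf", stringsAsFactors = FALSE)
  ten3 <- estimate_tenure("bf", meta3, mk_parentage(),
                          c(bf = "non-immigrant"), c(bf = 600))
  expect_equal(ten3$t_min, 0)
  expect_true(ten3$censored)
})

test_that("female-biased inheritance is recovered directionally", {
  # scaled down from the 30-group example for runtime; the direction
  # (MLI detected more often than PLI) is the assertion
  cfg <- simulation_config(n_groups = 12, p_inherit_female = 1,
                           p_inherit_male = 0, seed = 19)
  sim <- simulate_population(cfg)
  fb <- estimate_allele_frequencies(sim$dataset, "naive")
  dem <- demography_report(sim$dataset, fb, parentage = NULL,
                           n_null = 500, seed = 19)
  mli <- mean(dem$inherited[dem$status == "breeder female"], na.rm = TRUE)
  pli <- mean(dem$inherited[dem$status == "breeder male"], na.rm = TRUE)
  expect_gt(mli, pli)
})
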