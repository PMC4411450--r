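# The factorial expansion engine: expansion order, counting, deselection,
# registration, derivation.

test_that("expand_tier orders parents outermost, replicates innermost", {
  parents <- expand_tier(NULL, list(factor_def("Phenotype",
                                               c("black", "yellow"))), 1)
  expect_length(parents, 2)
  kids <- expand_tier(parents,
                      list(factor_def("growth medium",
                                      c("control", "tyrosin-"))), 1,
                      type = "Q_BIOLOGICAL_SAMPLE")
  expect_length(kids, 4)
  expect_identical(vapply(kids, `[[`, 0L, "parent_index"), c(1L, 1L, 2L, 2L))
  expect_identical(vapply(kids, function(s) to_condensed(s$factor_values), ""),
                   c("Phenotype: black; growth medium: control",
                     "Phenotype: black; growth medium: tyrosin-",
                     "Phenotype: yellow; growth medium: control",
                     "Phenotype: yellow; growth medium: tyrosin-"))
  reps <- expand_tier(kids, list(), 2, type = "Q_TEST_SAMPLE")
  expect_length(reps, 8)
  expect_identical(vapply(reps, `[[`, 0L, "parent_index"),
                   rep(1:4, each = 2L))
})

test_that("two factors expand with the first factor slowest", {
  out <- expand_tier(NULL, list(factor_def("a", c("1", "2")),
                                factor_def("b", c("x", "y", "z"))), 1)
  expect_identical(vapply(out, function(s) to_condensed(s$factor_values), ""),
                   c("a: 1; b: x", "a: 1; b: y", "a: 1; b: z",
                     "a: 2; b: x", "a: 2; b: y", "a: 2; b: z"))
})

test_that("identity expansion passes factor values through", {
  p <- expand_tier(NULL, list(factor_def("f", "only")), 1)
  out <- expand_tier(p, list(), 1, type = "Q_BIOLOGICAL_SAMPLE")
  expect_length(out, 1)
  expect_identical(to_condensed(out[[1]]$factor_values), "f: only")
  expect_error(expand_tier(p, list(), 0), ">= 1")
})

test_that("build_design obeys the tier-size count law on the worked example", {
  expect_identical(tier_sizes(build_design(qmela_spec())), c(2L, 4L, 8L))
})

test_that("a factorless spec with unit replicates is minimal", {
  spec <- design_spec("QTEST", list(
    tier_spec(1, organism = "human"),
    tier_spec(2, tissue = "Blood"),
    tier_spec(3, analyte = "DNA")))
  expect_identical(tier_sizes(build_design(spec)), c(1L, 1L, 1L))
})

test_that("count law: (3x2 levels, replicates 2,1,3) gives tiers 6/12/36", {
  spec <- design_spec("QTEST", list(
    tier_spec(1, factors = list(factor_def("geno", c("wt", "ko", "het"))),
              replicates = 2, organism = "mouse"),
    tier_spec(2, factors = list(factor_def("diet", c("chow", "hfd"))),
              replicates = 1, tissue = "Liver"),
    tier_spec(3, replicates = 3, analyte = "RNA")))
  expect_identical(tier_sizes(build_design(spec)), c(6L, 12L, 36L))
})

test_that("count law holds on random specs", {
  set.seed(303)
  for (i in 1:60) {
    spec <- random_design_spec()
    d <- build_design(spec)
    n_prev <- 1L
    for (k in 1:3) {
      ts <- spec$tiers[[k]]
      expected <- n_prev * ts$replicates *
        prod(vapply(ts$factors, function(f) length(f$levels), 0))
      expect_identical(length(d$tiers[[k]]), as.integer(expected))
      n_prev <- expected
    }
  }
})

test_that("factor values accumulate down the hierarchy", {
  set.seed(304)
  for (i in 1:20) {
    spec <- random_design_spec()
    d <- register_design(build_design(spec))
    for (k in 2:3) {
      for (s in d$tiers[[k]]) {
        parent <- Filter(function(p) p$identifier == s$parents,
                         d$tiers[[k - 1]])[[1]]
        n_par <- length(parent$factor_values)
        expect_identical(condensed_list(s$factor_values[seq_len(n_par)]),
                         condensed_list(parent$factor_values))
      }
    }
    # symmetric design: each full combination appears equally often at tier 3
    combos <- table(vapply(d$tiers[[3]],
                           function(s) to_condensed(s$factor_values), ""))
    expect_length(unique(as.integer(combos)), 1L)
  }
})

test_that("deselection removes descendants transitively", {
  d <- deselect(build_design(qmela_spec()), 2, 2)
  expect_identical(tier_sizes(d), c(2L, 3L, 6L))
  d0 <- deselect(build_design(qmela_spec()), 1, 1:2)
  expect_identical(tier_sizes(d0), c(0L, 0L, 0L))
  unchanged <- deselect(build_design(qmela_spec()), 2, integer(0))
  expect_identical(tier_sizes(unchanged), c(2L, 4L, 8L))
})

test_that("deselect validates its inputs", {
  d <- build_design(qmela_spec())
  expect_error(deselect(d, 2, 99), "out of range")
  expect_error(deselect(register_design(d), 2, 1), "registered")
})

test_that("deselect-then-expand equals expand-then-prune", {
  set.seed(305)
  for (i in 1:40) {
    spec <- random_design_spec()
    full <- build_design(spec)
    n2 <- length(full$tiers[[2]])
    if (n2 < 2) next
    pos <- sample.int(n2, sample.int(min(3L, n2 - 1L), 1L))
    # route 1: prune the fully expanded design
    pruned <- deselect(full, 2, pos)
    # route 2: expand tier 3 only beneath the surviving extracts
    survivors <- full$tiers[[2]][-pos]
    ts3 <- spec$tiers[[3]]
    reexpanded <- expand_tier(survivors, ts3$factors, ts3$replicates,
                              type = "Q_TEST_SAMPLE",
                              properties = ts3$properties)
    expect_identical(
      vapply(pruned$tiers[[3]], function(s) to_condensed(s$factor_values), ""),
      vapply(reexpanded, function(s) to_condensed(s$factor_values), ""))
    expect_identical(
      vapply(pruned$tiers[[3]], `[[`, 0L, "parent_index"),
      vapply(reexpanded, `[[`, 0L, "parent_index"))
  }
})

test_that("registration yields exactly the printed identifiers in order", {
  d <- qmela_design()
  expect_identical(vapply(d$tiers[[1]], `[[`, "", "identifier"),
                   GOLDEN_ENTITY_IDS)
  expect_identical(vapply(design_samples(d, 2:3), `[[`, "", "identifier"),
                   GOLDEN_SAMPLE_IDS)
  parents3 <- vapply(d$tiers[[3]], `[[`, "", "parents")
  expect_identical(parents3, rep(GOLDEN_SAMPLE_IDS[1:4], each = 2))
})

test_that("registration is gap-free after deselection and order-stable", {
  d <- register_design(deselect(build_design(qmela_spec()), 2, 2))
  ids <- vapply(design_samples(d, 2:3), `[[`, "", "identifier")
  counters <- vapply(ids, function(id) parse_id(id)$counter, 0L)
  expect_identical(unname(counters), seq_along(ids))
})

test_that("a design cannot be registered twice", {
  expect_error(register_design(qmela_design()), "already registered")
})

test_that("group letters wrap after Z and test samples inherit them", {
  spec <- design_spec("QBIGX", list(
    tier_spec(1, organism = "human"),
    tier_spec(2, replicates = 30, tissue = "Blood"),
    tier_spec(3, analyte = "DNA")))
  d <- register_design(build_design(spec))
  letters2 <- vapply(d$tiers[[2]],
                     function(s) parse_id(s$identifier)$group_char, "")
  expect_identical(letters2, c(LETTERS, LETTERS[1:4]))
  letters3 <- vapply(d$tiers[[3]],
                     function(s) parse_id(s$identifier)$group_char, "")
  expect_identical(letters3, letters2)
})

test_that("counter exhaustion is a capacity error", {
  spec <- design_spec("QFULL", list(
    tier_spec(1, organism = "human"),
    tier_spec(2, replicates = 400, tissue = "Blood"),
    tier_spec(3, replicates = 2, analyte = "DNA")))
  expect_error(register_design(build_design(spec)), "exhausted")
})

test_that("derive_from_existing continues counters beneath known samples", {
  d <- qmela_design()
  der <- derive_from_existing(d$tiers[[2]],
                              tier_spec(3, analyte = "Proteins",
                                        replicates = 1),
                              known = design_samples(d))
  der <- register_design(der)
  ids <- vapply(der$tiers[[3]], `[[`, "", "identifier")
  expect_length(ids, 4)
  expect_identical(vapply(ids, function(i) parse_id(i)$counter, 0L,
                          USE.NAMES = FALSE), 13:16)
  expect_identical(vapply(der$tiers[[3]], `[[`, "", "parents"),
                   GOLDEN_SAMPLE_IDS[1:4])
  # inherited group letters and factor values
  expect_identical(vapply(ids, function(i) parse_id(i)$group_char, "",
                          USE.NAMES = FALSE), c("A", "B", "C", "D"))
  expect_identical(to_condensed(der$tiers[[3]][[1]]$factor_values),
                   "Phenotype: black; growth medium: control")
})

test_that("derive validates parent tiers", {
  d <- qmela_design()
  expect_error(derive_from_existing(d$tiers[[1]],
                                    tier_spec(3, analyte = "Proteins")),
               "contiguous|below tier")
  mixed <- c(d$tiers[[1]][1], d$tiers[[2]][1])
  expect_error(derive_from_existing(mixed, tier_spec(3, analyte = "DNA")),
               "same tier")
  one <- derive_from_existing(d$tiers[[2]][1],
                              tier_spec(3, analyte = "Proteins",
                                        replicates = 2),
                              known = design_samples(d))
  one <- register_design(one)
  expect_length(one$tiers[[3]], 2)
  expect_identical(unique(vapply(one$tiers[[3]], `[[`, "", "parents")),
                   "QMELA001AK")
})
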