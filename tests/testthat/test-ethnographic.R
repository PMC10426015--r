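toy_path <- system.file("extdata", "toy_coding.csv", package = "punishr")

test_that("the shipped toy coding table reads and validates", {
  dat <- suppressMessages(read_coding_table(toy_path))
  expect_s3_class(dat$evidence, "evidence_matrix")
  expect_equal(length(dat$evidence$society_id), 6)
  expect_equal(sum(is.na(dat$socio[socio_predictors()])), 4)
  expect_equal(nrow(dat$docs), 6)
})

test_that("invariant breaches and malformed tables are rejected with context", {
  dat <- utils::read.csv(toy_path)
  bad <- dat
  bad$c_rape_material[2] <- 1  # cell without violation or punishment flag
  f <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f, row.names = FALSE)
  expect_error(suppressMessages(read_coding_table(f)), "rape|inconsistent")

  bad2 <- dat
  bad2$v_adultery[1] <- 2
  utils::write.csv(bad2, f, row.names = FALSE)
  expect_error(suppressMessages(read_coding_table(f)), "v_adultery.*rows 1")

  bad3 <- dat
  bad3$mystery <- 1
  utils::write.csv(bad3, f, row.names = FALSE)
  expect_error(suppressMessages(read_coding_table(f)), "unknown columns: mystery")

  # cell flag without its violation flag must fail containment
  bad4 <- dat
  bad4$c_food_physical[1] <- 1
  bad4$p_physical[1] <- 1
  utils::write.csv(bad4, f, row.names = FALSE)
  expect_error(suppressMessages(read_coding_table(f)), "containment")
})

test_that("prevalence matches hand counts and is permutation invariant", {
  dat <- suppressMessages(read_coding_table(toy_path))
  em <- dat$evidence
  expect_equal(prevalence(em, "adultery"), 3 / 6)
  expect_equal(prevalence(em, "material"), 2 / 6)
  expect_equal(prevalence(em, "any_violation"), 5 / 6)
  expect_equal(prevalence(em, "any_punishment"), 4 / 6)
  expect_error(prevalence(em, "witchcraft"), "unknown")

  perm <- sample(seq_along(em$society_id))
  em2 <- evidence_matrix(em$society_id[perm], em$violations[perm, ],
                         em$punishments[perm, ], em$cells[perm, ])
  for (v in c(violation_domains(), punishment_types())) {
    expect_equal(prevalence(em2, v), prevalence(em, v))
  }

  ones <- evidence_matrix(
    c("a", "b"), matrix(1L, 2, 5), matrix(1L, 2, 4), matrix(1L, 2, 20)
  )
  for (v in c(violation_domains(), punishment_types())) {
    expect_equal(prevalence(ones, v), 1)
  }
})

test_that("co-occurrence stats reproduce the hand-worked 2x2 table", {
  # violation = [1,1,0,0], any-punishment = [1,0,0,0]:
  # a=1, b=1, c=0, d=2 -> phi = (ad-bc)/sqrt((a+b)(c+d)(a+c)(b+d)) = 1/sqrt(3)
  v <- matrix(0L, 4, 5, dimnames = list(NULL, violation_domains()))
  v[, "adultery"] <- c(1L, 1L, 0L, 0L)
  cl <- matrix(0L, 4, 20, dimnames = list(NULL, cell_names()))
  cl[1, "adultery.material"] <- 1L
  p <- matrix(0L, 4, 4, dimnames = list(NULL, punishment_types()))
  p[1, "material"] <- 1L
  em <- evidence_matrix(paste0("s", 1:4), v, p, cl)
  co <- cooccurrence_stats(em)
  row <- co$per_domain[co$per_domain$domain == "adultery", ]
  expect_equal(row$jaccard, 0.5)
  expect_equal(row$phi, 1 / sqrt(3), tolerance = 1e-12)
  # all-zero domains: correlation undefined but flagged, not an error
  expect_false(any(co$per_domain$phi_defined[co$per_domain$domain != "adultery"]))
})

test_that("identical violation/punishment vectors give phi = jaccard = 1", {
  v <- matrix(0L, 5, 5, dimnames = list(NULL, violation_domains()))
  v[, "food"] <- c(1L, 0L, 1L, 0L, 1L)
  cl <- matrix(0L, 5, 20, dimnames = list(NULL, cell_names()))
  cl[c(1, 3, 5), "food.execution"] <- 1L
  p <- matrix(0L, 5, 4, dimnames = list(NULL, punishment_types()))
  p[c(1, 3, 5), "execution"] <- 1L
  em <- evidence_matrix(paste0("s", 1:5), v, p, cl)
  row <- cooccurrence_stats(em)$per_domain
  food <- row[row$domain == "food", ]
  expect_equal(food$phi, 1)
  expect_equal(food$jaccard, 1)
})

test_that("crosstab counts cells and respects the violation bound", {
  zero <- evidence_matrix(c("a", "b"), matrix(0L, 2, 5), matrix(0L, 2, 4),
                          matrix(0L, 2, 20))
  expect_true(all(crosstab_counts(zero) == 0))

  dat <- suppressMessages(read_coding_table(toy_path))
  xt <- crosstab_counts(dat$evidence)
  expect_equal(xt["adultery", "physical"], 1)
  expect_equal(xt["war_cowardice", "reputational"], 1)
  expect_equal(sum(xt), 5)

  # each cell count is bounded by the count of societies with that violation
  set.seed(4)
  fx <- make_study_fixture(seed = 88, n = 40)
  xt2 <- crosstab_counts(fx$evidence)
  vc <- colSums(fx$evidence$violations)
  for (d in violation_domains()) {
    expect_true(all(xt2[d, ] <= vc[d]))
  }
})
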