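test_that("phantom generation is seeded, aligned and defect-aware", {
  spec <- phantom_spec(seed = 4)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$dose$values, ph2$dose$values)
  expect_identical(ph1$q_activity$values, ph2$q_activity$values)
  expect_identical(ph1$v_activity$values, ph2$v_activity$values)

  for (vol in ph1[c("dose", "q_activity", "v_activity")]) {
    expect_true(validate_alignment(vol, ph1$lung))
    expect_true(all(vol$values >= 0))
  }
  expect_equal(max(ph1$dose$values), 62, tolerance = 1e-6)
  # different seed changes the activity noise
  ph3 <- generate_phantom(phantom_spec(seed = 5))
  expect_false(identical(ph1$q_activity$values, ph3$q_activity$values))
})

test_that("noise-free defect-free phantoms degrade to uniform functional lung", {
  spec <- phantom_spec(q_activity = list(baseline = 50, noise_cv = 0, defects = list()),
                       v_activity = list(baseline = 50, noise_cv = 0, defects = list()))
  ph <- generate_phantom(spec)
  inside <- ph$q_activity$values[ph$lung$values]
  expect_true(all(abs(inside - 50) < 1e-12))
  fm <- segment_functional(ph$q_activity, ph$lung, 0.3, "perfusion")
  expect_identical(fm$mask$values, ph$lung$values)
})

test_that("a ventilation-only defect shows up as perfusion-only mismatch", {
  defect <- list(center = c(50, 80, 75), radii = c(18, 20, 24), residual = 0.05)
  spec <- phantom_spec(
    q_activity = list(baseline = 100, noise_cv = 0, defects = list()),
    v_activity = list(baseline = 100, noise_cv = 0, defects = list(defect)),
    seed = 8
  )
  ph <- generate_phantom(spec)
  q <- segment_functional(ph$q_activity, ph$lung, 0.3, "perfusion")
  v <- segment_functional(ph$v_activity, ph$lung, 0.3, "ventilation")
  rep <- mismatch_report(q, v)

  # defect volume by brute-force voxel count
  sp <- spec$spacing
  ctr <- which(ph$lung$values, arr.ind = TRUE)
  world <- sweep(sweep(ctr - 1, 2, sp, `*`), 2, spec$origin, `+`)
  ins <- rowSums(sweep(sweep(world, 2, defect$center, `-`), 2,
                       defect$radii, `/`)^2) <= 1
  defect_cm3 <- sum(ins) * prod(sp) / 1000

  expect_equal(rep$volume_cm3[rep$region == "q_only"], defect_cm3)
  expect_equal(rep$volume_cm3[rep$region == "v_only"], 0)

  # defect outside the lung is an error
  bad <- phantom_spec(v_activity = list(baseline = 100, noise_cv = 0,
                                        defects = list(list(center = c(5, 5, 5),
                                                            radii = c(10, 10, 10),
                                                            residual = 0))))
  expect_error(generate_phantom(bad), "outside the lung")
  expect_error(phantom_spec(q_activity = list(baseline = 1, noise_cv = 0,
                                              defects = list(list(center = c(0, 0, 0),
                                                                  radii = c(1, 1, 1),
                                                                  residual = 1)))),
               "residual")
})

test_that("worked-example fixture reproduces its six percentages through the pipeline", {
  fx <- figure1_fixture()
  for (case in names(fx)) {
    b <- fx[[case]]
    q <- segment_functional(b$q_activity, b$lung, 0.30, "perfusion")
    v <- segment_functional(b$v_activity, b$lung, 0.30, "ventilation")
    mt <- compute_metrics(b$dose, b$lung, q, v)
    expect_identical(mt$V20, 25)

    # segmentation recovers the constructed two-level regions exactly
    expect_identical(q$mask$values,
                     array(b$q_activity$values == 1, dim = dim(b$q_activity$values)))
    expect_identical(v$mask$values,
                     array(b$v_activity$values == 1, dim = dim(b$v_activity$values)))
  }
  rilt <- analyze_bundle(fx$rilt_case)$metrics
  ctrl <- analyze_bundle(fx$non_rilt_case)$metrics
  expect_identical(c(rilt$Q_V20, rilt$V_V20), c(35, 33))
  expect_identical(c(ctrl$Q_V20, ctrl$V_V20), c(20, 22))
})

test_that("cohort simulation is seeded and matches its margins", {
  co1 <- simulate_cohort(cohort_spec(), seed = 10)
  co2 <- simulate_cohort(cohort_spec(), seed = 10)
  expect_identical(co1, co2)
  expect_false(identical(co1$V20, simulate_cohort(cohort_spec(), seed = 11)$V20))

  m <- default_cohort_margins()
  expect_equal(nrow(co1), 57)
  expect_equal(as.numeric(table(co1$copd)[c("yes", "no")]), c(20, 37))
  expect_equal(sort(as.numeric(table(co1$chemo))), sort(as.numeric(m$chemo)))
  expect_true(all(co1$age_years[co1$age_group == "<70"] < 70))
  expect_true(all(co1$V20 >= 10 & co1$V20 <= 45))
  expect_true(all(co1$MLD >= 8 & co1$MLD <= 25))

  expect_error(cohort_spec(rho = c(CT = 0.3, Q = 1, V = 0.7)), "\\(-1, 1\\)")
  expect_error(
    cohort_spec(margins = utils::modifyList(default_cohort_margins(),
                                            list(copd = c(yes = 10L, no = 10L)))),
    "infeasible"
  )
})

test_that("achieved rank correlation converges to the copula target at large n", {
  sp <- cohort_spec(n = 5000)
  co <- simulate_cohort(sp, seed = 12)
  z <- attr(co, "latent_z")
  for (fam in c("CT", "Q", "V")) {
    target <- target_rank_correlation(sp$rho[[fam]])
    mcol <- c(CT = "V20", Q = "Q_V20", V = "V_V20")[[fam]]
    achieved <- spearman_cor(co[[mcol]], z)$r
    expect_lt(abs(achieved - target), 0.02)
  }
})

test_that("null simulator plants no association", {
  sp <- cohort_spec(rho = c(CT = 0, Q = 0, V = 0))
  r_abs <- vapply(1:50, function(i) {
    co <- simulate_cohort(sp, seed = 100 + i)
    abs(spearman_cor(co$Q_V20, rilt_event(co$rilt_grade))$r)
  }, numeric(1))
  expect_lt(mean(r_abs), 0.15)
})

test_that("fixture cohort reproduces every printed characteristics cell", {
  co <- table1_fixture()
  ev <- rilt_event(co$rilt_grade)
  expect_equal(sum(ev), 15)
  expect_equal(sum(1 - ev), 42)

  cells <- list(
    sex = list(c(male = 11, female = 4), c(male = 32, female = 10)),
    age_group = list(c(`<70` = 8, `>70` = 7), c(`<70` = 31, `>70` = 11)),
    histology = list(c(squamous = 11, adenocarcinoma = 4),
                     c(squamous = 29, adenocarcinoma = 13)),
    stage = list(c(I = 2, II = 4, III = 9), c(I = 4, II = 5, III = 33)),
    location = list(c(central = 8, peripheral = 7),
                    c(central = 24, peripheral = 18)),
    copd = list(c(yes = 7, no = 8), c(yes = 13, no = 29)),
    pft = list(c(worse = 5, good = 10), c(worse = 10, good = 32)),
    chemo = list(c(none = 7, docetaxel_platinum = 2,
                   pemetrexed_platinum = 2, gemcitabine_platinum = 4),
                 c(none = 24, docetaxel_platinum = 9,
                   pemetrexed_platinum = 4, gemcitabine_platinum = 5))
  )
  for (cv in names(cells)) {
    for (grp in 1:2) {
      want <- cells[[cv]][[grp]]
      got <- table(co[[cv]][ev == (2 - grp)])
      expect_equal(as.numeric(got[names(want)]), as.numeric(want),
                   label = paste(cv, "group", grp))
    }
  }
  # deterministic given default seed
  expect_identical(table1_fixture(), table1_fixture())
})
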