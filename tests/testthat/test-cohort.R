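test_that("load_cohort round-trips write_cohort output exactly", {
  skip_if_not_installed("linchim")
  for (seed in c(1, 2)) {
    co <- generate_cohort(sim_params(n_transplants = 25, seed = seed))
    tp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
    write_cohort(co, tp, mp)
    back <- load_cohort(tp, mp)
    expect_equal(back$transplants, co$transplants)
    expect_equal(back$measurements, co$measurements)
  }
  # CSV dialect
  co <- generate_cohort(sim_params(n_transplants = 5, seed = 3))
  tp <- tempfile(); mp <- tempfile()
  write_cohort(co, tp, mp, sep = ",")
  expect_equal(load_cohort(tp, mp, sep = ",")$measurements, co$measurements)
})

test_that("all eight (compartment, lineage) strata survive a round-trip", {
  tr <- make_transplants("t1")
  me <- rbind(make_measurements("t1", 50, "blood", c("CD3", "CD19", "CD33"), 1:3),
              make_measurements("t1", 50, "marrow",
                                c("CD3", "CD19", "CD33", "CD34"), 4:7))
  co <- cohort(tr, me)
  tp <- tempfile(); mp <- tempfile()
  write_cohort(co, tp, mp)
  back <- load_cohort(tp, mp)
  strata <- unique(paste(back$measurements$compartment, back$measurements$lineage))
  expect_length(strata, 7) # blood carries 3 lineages, marrow 4
  expect_equal(back$measurements, co$measurements)
})

test_that("empty cohort writes header-only files that load back", {
  co <- cohort(make_transplants(character(0)),
               make_measurements(character(0), integer(0)))
  tp <- tempfile(); mp <- tempfile()
  write_cohort(co, tp, mp)
  expect_length(readLines(mp), 1)
  back <- load_cohort(tp, mp)
  expect_equal(nrow(back$transplants), 0)
  expect_equal(nrow(back$measurements), 0)
})

test_that("validation rejects bad rows with row-numbered diagnostics", {
  tr <- make_transplants("t1")
  expect_error(cohort(tr, make_measurements("t1", 10, percent = 101)),
               "percent_recipient.*row\\(s\\) 1")
  expect_error(cohort(tr, make_measurements("t2", 10)), "unknown transplant_id")
  expect_error(cohort(tr, make_measurements("t1", -5)), "negative day")
  expect_error(cohort(tr, make_measurements("t1", 10, compartment = "blood",
                                            lineage = "CD34")),
               "CD34 outside marrow")
  expect_error(cohort(rbind(tr, tr), make_measurements("t1", 10)),
               "duplicated transplant_id")
  expect_error(cohort(tr[, -3], make_measurements("t1", 10)),
               "missing required column")
  expect_error(load_cohort(tempfile(), tempfile()), "file not found")
})

test_that("paired_samples pairs same-day blood/marrow and excludes replicates", {
  tr <- make_transplants(c("t1", "t2"))
  me <- rbind(
    make_measurements("t1", 100, "blood", "CD3", 0.5),
    make_measurements("t1", 100, "marrow", "CD3", 1.0),   # pair
    make_measurements("t1", 200, "blood", "CD3", 0.2),
    make_measurements("t1", 201, "marrow", "CD3", 0.4),   # off by a day: no pair
    make_measurements("t2", 50, "blood", "CD3", c(0.1, 0.3)), # replicate blood
    make_measurements("t2", 50, "marrow", "CD3", 0.2)
  )
  co <- cohort(tr, me)
  expect_warning(pairs <- paired_samples(co, "CD3"), "replicate")
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$blood_percent, 0.5)
  expect_equal(pairs$marrow_percent, 1.0)
  # other lineages unaffected
  expect_equal(nrow(paired_samples(co, "CD19")), 0)
})

test_that("paired_samples output is bounded by the smaller compartment", {
  co <- generate_cohort(sim_params(n_transplants = 40, seed = 5))
  pairs <- suppressWarnings(paired_samples(co, "CD3"))
  m <- co$measurements[co$measurements$lineage == "CD3", ]
  expect_lte(nrow(pairs), min(sum(m$compartment == "blood"),
                              sum(m$compartment == "marrow")))
})

test_that("paired_correlation matches the product-moment formula", {
  set.seed(42)
  x <- rlnorm(20); y <- 0.8 * x + rnorm(20, sd = 0.3)
  pairs <- data.frame(transplant_id = paste0("t", 1:20), day = 1, lineage = "CD3",
                      blood_percent = x, marrow_percent = pmax(y, 0))
  r <- paired_correlation(pairs)$r
  xb <- pairs$blood_percent; yb <- pairs$marrow_percent
  oracle <- sum((xb - mean(xb)) * (yb - mean(yb))) /
    sqrt(sum((xb - mean(xb))^2) * sum((yb - mean(yb))^2))
  expect_equal(r, oracle, tolerance = 1e-12)
  # collinear cases
  lin <- data.frame(blood_percent = 1:5, marrow_percent = 2 * (1:5) + 1)
  expect_equal(paired_correlation(lin)$r, 1.0)
  lin$marrow_percent <- -2 * (1:5) + 20
  expect_equal(paired_correlation(lin)$r, -1.0)
  # symmetry and positive-affine invariance
  sw <- pairs; sw$blood_percent <- pairs$marrow_percent
  sw$marrow_percent <- pairs$blood_percent
  expect_equal(paired_correlation(sw)$r, r)
  sc <- pairs; sc$blood_percent <- 3 * pairs$blood_percent + 7
  expect_equal(paired_correlation(sc)$r, r, tolerance = 1e-12)
  # degenerate inputs
  expect_error(paired_correlation(pairs[1:2, ]), "at least 3")
  cst <- pairs; cst$blood_percent <- 1
  expect_error(paired_correlation(cst), "degenerate variance")
})
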