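test_that("config invariants are enforced", {
  expect_error(sim_config(category_mix = c(NONE = 0.5, LIGHT = 0.5,
                                           MODERATE = 0, HEAVY = 0.1,
                                           PAST = 0, UNKNOWN = 0)),
               "sum to 1")
  expect_error(sim_config(p_document_base = 1.4), "\\[0, 1\\]")
  expect_error(sim_config(n_providers = 0), "n_providers")
  expect_error(simulate_extract(sim_config(n_patients = 0)), "empty")
})

test_that("a JSON config file round-trips through the generator", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_patients = 300, n_providers = 6, seed = 13,
                            p_document_base = 0.25,
                            doc_logit_effects = list(male = 0.2)),
                       path, auto_unbox = TRUE, digits = NA)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$n_patients, 300L)
  expect_identical(cfg$doc_logit_effects, c(male = 0.2))
  ref <- sim_config(n_patients = 300, n_providers = 6, seed = 13,
                    p_document_base = 0.25,
                    doc_logit_effects = c(male = 0.2))
  expect_identical(simulate_extract(cfg)$truth,
                   simulate_extract(ref)$truth)
  # seed is mandatory; unknown fields are refused
  jsonlite::write_json(list(n_patients = 10), path, auto_unbox = TRUE)
  expect_error(read_sim_config(path), "seed is mandatory")
  jsonlite::write_json(list(seed = 1, frobnicate = 2), path,
                       auto_unbox = TRUE)
  expect_error(read_sim_config(path), "unknown config fields")
})

test_that("same seed and config give identical extracts", {
  cfg <- sim_config(n_patients = 800, n_providers = 10, seed = 99)
  a <- simulate_extract(cfg)
  b <- simulate_extract(cfg)
  for (nm in c("patients", "providers", "encounters", "conditions",
               "riskfactor", "truth")) {
    expect_identical(a[[nm]], b[[nm]], label = nm)
  }
})

test_that("truth table couples documentation and rendered text", {
  ex <- simulate_extract(sim_config(n_patients = 2000, n_providers = 20,
                                    seed = 5))
  tr <- ex$truth
  expect_true(all(nzchar(tr$rendered_text[tr$documented])))
  expect_true(all(!nzchar(tr$rendered_text[!tr$documented])))
  expect_identical(sort(ex$riskfactor$patient_id),
                   tr$patient_id[tr$documented])
  # every foreign key resolves
  expect_true(all(ex$encounters$patient_id %in% ex$patients$patient_id))
  expect_true(all(ex$patients$provider_id %in% ex$providers$provider_id))
})

test_that("degenerate documentation probabilities behave", {
  ex0 <- simulate_extract(sim_config(n_patients = 500, n_providers = 5,
                                     seed = 3, p_document_base = 0))
  expect_identical(nrow(ex0$riskfactor), 0L)
  ex1 <- simulate_extract(sim_config(n_patients = 500, n_providers = 5,
                                     seed = 3, p_document_base = 1))
  expect_identical(nrow(ex1$riskfactor), 500L)
})

test_that("marginals calibrate to the configured targets", {
  n <- 20000
  cfg <- sim_config(n_patients = n, n_providers = 40, seed = 12)
  ex <- simulate_extract(cfg)
  p_doc <- mean(ex$truth$documented)
  se <- sqrt(0.406 * (1 - 0.406) / n)
  expect_lt(abs(p_doc - 0.406), 3 * se)
  urb <- mean(ex$patients$cma_population >= 1e5)
  expect_lt(abs(urb - cfg$p_urban), 3 * sqrt(cfg$p_urban *
                                               (1 - cfg$p_urban) / n))
  mix <- prop.table(table(ex$truth$true_category[ex$truth$documented]))
  nd <- sum(ex$truth$documented)
  for (k in alcohol_categories()) {
    pk <- cfg$category_mix[[k]]
    expect_lt(abs(mix[[k]] - pk), 3 * sqrt(pk * (1 - pk) / nd),
              label = paste("mix", k))
  }
})

test_that("patients per provider match the configured mean", {
  ex <- simulate_extract(sim_config(n_patients = 1000, n_providers = 40,
                                    seed = 8))
  sizes <- table(ex$patients$provider_id)
  expect_identical(length(sizes), 40L)
  expect_equal(mean(sizes), 25)
  expect_lte(max(sizes) - min(sizes), 1)  # near-uniform by design
})

test_that("a configured male effect reproduces the crude odds ratio", {
  # single nonzero effect: marginal and conditional OR coincide, so the
  # crude cross-product is its own closed-form oracle
  cfg <- sim_config(n_patients = 150000, n_providers = 100, seed = 21,
                    doc_logit_effects = c(male = log(1.09)),
                    risk_logit_effects = c(male = 0))
  ex <- simulate_extract(cfg)
  male <- ex$patients$sex == "M"
  doc <- ex$truth$documented
  tab <- table(male, doc)
  or <- crude_odds_ratio(tab["TRUE", "TRUE"], tab["FALSE", "TRUE"],
                         tab["TRUE", "FALSE"], tab["FALSE", "FALSE"])
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or$or) - log(1.09)), 3 * se)
})

test_that("render_note enforces band-quantity coherence", {
  expect_error(render_note("LIGHT", 5), "inconsistent")
  expect_error(render_note("HEAVY", 2), "inconsistent")
  expect_error(render_note("MODERATE", NA), "quantity")
  expect_error(render_note("BINGE", 2), "unknown category")
  set.seed(2)
  expect_match(render_note("PAST"),
               "alcoholics anonymous|recover|past|quit|sober")
  expect_match(render_note("NONE"), "non-drinker|denies|never|no etoh|does not")
  expect_true(nzchar(render_note("UNKNOWN")))
})

test_that("text noise garbles notes without touching the truth labels", {
  cfg <- sim_config(n_patients = 4000, n_providers = 10, seed = 77,
                    text_noise_rate = 0.5)
  ex <- simulate_extract(cfg)
  cls <- classify_table(ex$riskfactor)
  tr <- ex$truth[ex$truth$documented, ]
  acc <- mean(cls$label == tr$true_category[match(cls$patient_id,
                                                  tr$patient_id)])
  expect_lt(acc, 0.9)   # noise hurts the classifier
  expect_true(all(tr$true_category %in% alcohol_categories()))
})
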