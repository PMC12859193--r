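test_that("an empty catalog request yields empty but valid outputs", {
  cfg <- sim_config(seed = 1, n_pvs = 0, n_ancient = 0, n_african = 0,
                    n_nonafrican = 0)
  dir <- withr::local_tempdir()
  sim <- simulate_run(cfg, dir)
  expect_equal(nrow(sim$catalog), 0)
  expect_equal(nrow(sim$carriers), 0)
  expect_true(all(file.exists(unlist(sim$paths))))
  expect_equal(nrow(read_catalog(sim$paths$catalog)), 0)
})

test_that("the same seed reproduces every output byte for byte", {
  cfg <- sim_config(seed = 33, n_pvs = 40, n_genes = 10, n_ancient = 20,
                    n_african = 25, n_nonafrican = 30)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_run(cfg, d1)
  simulate_run(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  d3 <- withr::local_tempdir()
  cfg2 <- sim_config(seed = 34, n_pvs = 40, n_genes = 10, n_ancient = 20,
                     n_african = 25, n_nonafrican = 30)
  simulate_run(cfg2, d3)
  expect_false(identical(readLines(file.path(d1, "catalog.tsv")),
                         readLines(file.path(d3, "catalog.tsv"))))
})

test_that("cohort generation recovers the configured sharing propensities", {
  cfg <- sim_config(seed = 17, n_pvs = 400, n_genes = 40, n_ancient = 50,
                    n_african = 4000, n_nonafrican = 4000)
  sim_cat <- simulate_catalog(cfg)
  cohorts <- simulate_cohorts(cfg, sim_cat)
  anc_set <- sim_cat$truth$pv_id[sim_cat$truth$ancient_present]
  df <- as.data.frame(cohorts$carriers)
  for (cohort in c("modern_african", "modern_nonafrican")) {
    rows <- df[df$cohort == cohort, ]
    p_hat <- mean(rows$pv_id %in% anc_set)
    p <- cfg$propensity[[cohort]]
    se <- sqrt(p * (1 - p) / nrow(rows))
    expect_lt(abs(p_hat - p), 3 * se + 0.01)
  }
  # carriage: zero-truncated Poisson mean
  for (cohort in c("modern_african", "modern_nonafrican")) {
    rows <- df[df$cohort == cohort, ]
    k <- table(rows$ind_id)
    lambda <- cfg$carriage[[cohort]]
    mu <- lambda / (1 - exp(-lambda))
    expect_lt(abs(mean(k) - mu), 3 * sqrt(stats::var(as.numeric(k)) / length(k)) + 0.02)
  }
  # nearly all carriers heterozygous
  expect_gt(mean(df$zygosity == "het"), 0.95)
})

test_that("ancient dates follow the bulk range with an undated fraction", {
  cfg <- sim_config(seed = 23, n_pvs = 100, n_ancient = 2000,
                    n_african = 0, n_nonafrican = 0)
  sim_cat <- simulate_catalog(cfg)
  cohorts <- simulate_cohorts(cfg, sim_cat)
  inds <- cohorts$individuals
  frac_undated <- mean(is.na(inds$date_bp))
  se <- sqrt(cfg$undated_frac * (1 - cfg$undated_frac) / nrow(inds))
  expect_lt(abs(frac_undated - cfg$undated_frac), 3 * se + 0.005)
  dated <- inds$date_bp[!is.na(inds$date_bp)]
  expect_true(all(dated >= cfg$date_bulk[1] - 0.5))
  expect_true(all(dated <= cfg$date_tail_max + 0.5))
  in_bulk <- mean(dated <= cfg$date_bulk[2])
  expect_gt(in_bulk, 0.9)  # tail fraction is 5%
})

test_that("a zero deamination rate on a hom-ref site yields no alternate reads", {
  cfg <- sim_config(seed = 3, read_model = list(
    deamination_rate = 0, seq_error_rate = 0, depth_mean = 30,
    depth_min = 10))
  pv <- as.data.frame(make_catalog(1, ref = "C", alt = "T"))[1, ]
  set.seed(10)
  for (i in 1:20) {
    obs <- simulate_reads(cfg, "I1", pv, "ref/ref")
    expect_equal(sum(obs$base == "T"), 0)
  }
})

test_that("strong terminal deamination creates only damage-consistent alt reads", {
  cfg <- sim_config(seed = 3, read_model = list(
    deamination_rate = 0.5, deamination_decay = 0.001,
    seq_error_rate = 0, depth_mean = 50, depth_min = 30))
  pv <- as.data.frame(make_catalog(1, ref = "C", alt = "T"))[1, ]
  set.seed(11)
  obs <- do.call(rbind, lapply(1:10, function(i) {
    simulate_reads(cfg, "I1", pv, "ref/ref")
  }))
  alt <- obs[obs$base == "T", ]
  expect_gt(nrow(alt), 0)
  expect_true(all(is_damage_consistent("C", "T", alt$strand)))
})

test_that("het sites draw alleles at one half on average", {
  cfg <- sim_config(seed = 3, read_model = list(
    deamination_rate = 0, seq_error_rate = 0, depth_mean = 30,
    depth_min = 30, duplicate_rate = 0))
  pv <- as.data.frame(make_catalog(1))[1, ]  # A>G
  set.seed(12)
  n_sim <- 1000
  fracs <- vapply(seq_len(n_sim), function(i) {
    obs <- simulate_reads(cfg, "I1", pv, "het")
    mean(obs$base == "G")
  }, 1.0)
  se <- stats::sd(fracs) / sqrt(n_sim)
  expect_lt(abs(mean(fracs) - 0.5), 3 * se)
})

test_that("species sharing decays toward Primate when configured to decay", {
  cfg <- sim_config(seed = 29, n_pvs = 1500, n_genes = 50,
                    clade_share_prob = c(Fish = 0.08, Sarcopterygii = 0.06,
                                         Aves = 0.045, Mammalia = 0.03,
                                         Afrotheria = 0.02,
                                         Laurasiatheria = 0.012,
                                         Euarchontoglires = 0.006,
                                         Primate = 0.002))
  sim_cat <- simulate_catalog(cfg)
  tab <- simulate_species_table(cfg, sim_cat$catalog)
  mat <- project_and_match(sim_cat$catalog, tab)
  summ <- clade_summary(mat)
  rate <- summ$per_clade$species_hits /
    (summ$per_clade$n_species * summ$n_pvs)
  # per-species sharing rate increases with clade rank (distance from human)
  expect_true(all(diff(rate[order(summ$per_clade$clade_rank)]) > 0))
})

test_that("simulated founder and selection tables honor their configured shapes", {
  cfg <- sim_config(seed = 41)
  ft <- simulate_founder_table(cfg)
  expect_equal(nrow(ft), cfg$n_founder)
  expect_true(all(ft$age_bp <= 9100))
  st <- simulate_selection_table(cfg)
  expect_equal(nrow(st), cfg$n_selection_genes)
  means <- tapply(st$pv_count, st$class, mean)
  expect_gt(means[["positive"]], means[["negative"]])
})
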