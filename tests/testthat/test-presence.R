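test_that("duplicates sharing a fragment key collapse to the best read", {
  obs <- make_obs(3, base_qual = c(30L, 38L, 34L),
                  frag_start = rep(1000L, 3), frag_end = rep(1059L, 3))
  out <- filter_observations(obs, caller_config(terminal_trim = 2))
  expect_equal(nrow(out), 1)
  expect_equal(out$base_qual, 38L)
})

test_that("terminal bases are excluded", {
  obs <- make_obs(1, dist5 = 1L)
  expect_equal(nrow(filter_observations(obs, caller_config(terminal_trim = 2))), 0)
  expect_equal(nrow(filter_observations(obs, caller_config(terminal_trim = 1))), 1)
  obs3 <- make_obs(1, dist3 = 0L)
  expect_equal(nrow(filter_observations(obs3, caller_config(terminal_trim = 2))), 0)
})

test_that("the filter agrees with an independent re-implementation", {
  cfgs <- list(caller_config(),
               caller_config(terminal_trim = 5, min_base_qual = 30,
                             min_map_qual = 40))
  for (seed in 1:3) {
    obs <- random_obs(200, seed)
    for (cfg in cfgs) {
      got <- filter_observations(obs, cfg)
      want <- oracle_filter(obs, cfg)
      expect_equal(got$read_id, want$read_id)
    }
  }
})

test_that("damage consistency covers exactly the two deamination signatures", {
  expect_true(is_damage_consistent("C", "T", "+"))
  expect_true(is_damage_consistent("G", "A", "-"))
  expect_false(is_damage_consistent("C", "T", "-"))
  expect_false(is_damage_consistent("G", "A", "+"))
  expect_false(is_damage_consistent("A", "G", "+"))
  expect_false(is_damage_consistent("A", "G", "-"))
})

test_that("zero surviving observations are uncallable", {
  pv <- as.data.frame(make_catalog(1))
  call <- call_presence(pv, make_obs(0), caller_config())
  expect_equal(call$call, "uncallable")
  expect_equal(call$zygosity, "na")
})

test_that("clean double-allele support calls a heterozygote", {
  pv <- as.data.frame(make_catalog(1))  # A>G
  obs <- make_obs(5, base = c("G", "G", "G", "A", "A"),
                  frag_start = 1000L + 1:5)
  call <- call_presence(pv, obs, caller_config())
  expect_equal(call$call, "present")
  expect_equal(call$zygosity, "het")
  expect_equal(call$n_alt_support, 3)
  expect_equal(call$n_ref_support, 2)
  expect_false(call$damage_flagged)
})

test_that("bases matching neither allele are excluded from both supports", {
  pv <- as.data.frame(make_catalog(1))  # A>G
  obs <- make_obs(4, base = c("G", "G", "T", "C"), frag_start = 1000L + 1:4)
  call <- call_presence(pv, obs, caller_config())
  expect_equal(call$n_alt_support, 2)
  expect_equal(call$n_ref_support, 0)
  expect_equal(call$n_other, 2)
  expect_equal(call$zygosity, "hom")
})

test_that("pure single-strand deamination-consistent support needs the stricter threshold", {
  pv <- as.data.frame(make_catalog(1, ref = "C", alt = "T"))
  one_plus <- make_obs(1, base = "T", strand = "+")
  call <- call_presence(pv, one_plus, caller_config())
  expect_equal(call$call, "uncallable")
  expect_true(call$damage_flagged)
  # the same single alt read on the reverse strand cannot be deamination
  one_minus <- make_obs(1, base = "T", strand = "-")
  call2 <- call_presence(pv, one_minus, caller_config())
  expect_equal(call2$call, "present")
  expect_false(call2$damage_flagged)
  # double-stranded alt support overrides the damage penalty
  two_strands <- make_obs(2, base = "T", strand = c("+", "-"),
                          frag_start = c(1000L, 1001L))
  call3 <- call_presence(pv, two_strands, caller_config())
  expect_equal(call3$call, "present")
  expect_false(call3$damage_flagged)
})

test_that("raising quality thresholds never converts absent to present", {
  pv <- as.data.frame(make_catalog(1, ref = "C", alt = "T"))
  base_cfg <- caller_config()
  stricter <- list(caller_config(min_base_qual = 30),
                   caller_config(min_map_qual = 50),
                   caller_config(terminal_trim = 6),
                   caller_config(min_alt_reads = 2, min_alt_reads_damage = 3))
  for (seed in 1:20) {
    obs <- random_obs(12, seed + 100)
    before <- call_presence(pv, obs, base_cfg)$call
    if (before != "absent") next
    for (cfg in stricter) {
      expect_false(call_presence(pv, obs, cfg)$call == "present")
    }
  }
})

test_that("calls are invariant to observation order and read ids", {
  pv <- as.data.frame(make_catalog(1))
  obs <- random_obs(30, 7)
  shuffled <- obs[sample(nrow(obs)), ]
  shuffled$read_id <- sprintf("zzz%02d", seq_len(nrow(shuffled)))
  a <- call_presence(pv, obs, caller_config())
  b <- call_presence(pv, shuffled, caller_config())
  expect_equal(a[, -1][, setdiff(names(a), c("ind_id"))],
               b[, setdiff(names(b), c("ind_id"))])
})

test_that("with no damage and deep coverage every planted genotype is recovered", {
  cfg <- sim_config(seed = 11, read_model = list(
    deamination_rate = 0, depth_mean = 40, depth_min = 30,
    low_qual_rate = 0, low_map_rate = 0, seq_error_rate = 0,
    duplicate_rate = 0.1))
  catalog <- make_catalog(6, ref = rep(c("C", "G", "A"), 2),
                          alt = rep(c("T", "A", "G"), 2))
  genotypes <- c("ref/ref", "het", "hom")
  set.seed(5)
  for (g in genotypes) {
    for (i in seq_len(nrow(catalog))) {
      pv <- as.data.frame(catalog)[i, ]
      obs <- simulate_reads(cfg, "IND1", pv, g)
      call <- call_presence(pv, obs, caller_config())
      expect_equal(call$call, if (g == "ref/ref") "absent" else "present")
      if (g != "ref/ref") {
        expect_equal(call$zygosity, if (g == "het") "het" else "hom")
      }
    }
  }
})

test_that("call_presence_all groups a mixed pileup per individual and site", {
  catalog <- make_catalog(2, ref = c("A", "C"), alt = c("G", "T"))
  obs <- rbind(
    make_obs(3, base = "G", ind_id = "I1", pv_id = "pv001",
             frag_start = 1000L + 1:3),
    make_obs(2, base = "C", ind_id = "I1", pv_id = "pv002",
             frag_start = 2000L + 1:2),
    make_obs(2, base = "G", ind_id = "I2", pv_id = "pv001",
             frag_start = 3000L + 1:2))
  calls <- call_presence_all(pileup_table(obs), catalog)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$call[calls$ind_id == "I1" & calls$pv_id == "pv001"],
               "present")
  expect_equal(calls$call[calls$ind_id == "I1" & calls$pv_id == "pv002"],
               "absent")
  bad <- make_obs(1, pv_id = "pv999")
  expect_error(call_presence_all(pileup_table(bad), catalog), "pv999")
})
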