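make_species_table <- function(catalog, species, clade, allele_fun) {
  rows <- do.call(rbind, lapply(seq_along(species), function(j) {
    data.frame(pv_id = catalog$pv_id, species = species[j],
               clade = clade[j],
               allele = allele_fun(as.data.frame(catalog), species[j]),
               stringsAsFactors = FALSE)
  }))
  species_allele_table(rows)
}

test_that("reference alleles everywhere give zero sharing", {
  catalog <- make_catalog(5)
  tab <- make_species_table(catalog, c("fish1", "prim1"),
                            c("Fish", "Primate"),
                            function(cat, sp) cat$ref)
  mat <- project_and_match(catalog, tab)
  expect_equal(sum(mat$shared), 0)
  expect_true(all(is.na(mat$nearest_clade)))
  summ <- clade_summary(mat)
  expect_equal(summ$n_absent, 5)
  expect_equal(summ$absent_percent, 100)
})

test_that("a single alt-carrying species sets the nearest shared clade", {
  catalog <- make_catalog(3)
  tab <- make_species_table(catalog, c("fish1", "mouse1"),
                            c("Fish", "Euarchontoglires"),
                            function(cat, sp) {
                              a <- cat$ref
                              if (sp == "mouse1") a[2] <- cat$alt[2]
                              a
                            })
  mat <- project_and_match(catalog, tab)
  expect_equal(unname(mat$nearest_clade[catalog$pv_id[2]]),
               "Euarchontoglires")
  expect_true(is.na(mat$nearest_clade[catalog$pv_id[1]]))
})

test_that("the nearest clade is the minimum rank among sharing species", {
  catalog <- make_catalog(1)
  tab <- make_species_table(catalog, c("fish1", "bird1", "prim1"),
                            c("Fish", "Aves", "Primate"),
                            function(cat, sp) {
                              if (sp == "prim1") cat$ref else cat$alt
                            })
  mat <- project_and_match(catalog, tab)
  expect_equal(unname(mat$nearest_clade[1]), "Aves")
})

test_that("missing orthology is tracked apart from reference presence", {
  catalog <- make_catalog(2)
  tab <- species_allele_table(data.frame(
    pv_id = rep(catalog$pv_id, 2),
    species = rep(c("sp1", "sp2"), each = 2),
    clade = rep(c("Fish", "Aves"), each = 2),
    allele = c(".", as.data.frame(catalog)$ref[2], "",
               as.data.frame(catalog)$alt[2])))
  mat <- project_and_match(catalog, tab)
  expect_true(mat$missing["pv001", "sp1"])
  expect_false(mat$missing["pv002", "sp1"])
  expect_false(mat$shared["pv001", "sp1"])
  expect_true(mat$shared["pv002", "sp2"])
})

test_that("projection matches a brute-force double loop on random tables", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 50
    catalog <- make_catalog(n,
                            ref = sample(c("A", "C", "G", "T"), n, TRUE),
                            alt = rep("N", n))
    # rebuild with valid distinct alts
    df <- as.data.frame(catalog)
    df$alt <- vapply(df$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    catalog <- pv_catalog(df)
    clades <- names(DEFAULT_CLADE_RANKS)
    species <- sprintf("sp%02d", 1:10)
    sp_clade <- sample(clades, 10, replace = TRUE)
    rows <- do.call(rbind, lapply(1:10, function(j) {
      data.frame(pv_id = df$pv_id, species = species[j],
                 clade = sp_clade[j],
                 allele = sample(c("A", "C", "G", "T", "."), n,
                                 replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    tab <- species_allele_table(rows)
    mat <- project_and_match(catalog, tab)
    want <- oracle_project(catalog, tab)
    got_pairs <- which(mat$shared, arr.ind = TRUE)
    got <- lapply(seq_len(nrow(got_pairs)), function(k) {
      c(rownames(mat$shared)[got_pairs[k, 1]],
        colnames(mat$shared)[got_pairs[k, 2]])
    })
    key <- function(p) paste(p[1], p[2])
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("sharing is invariant to species order and totals are conserved", {
  set.seed(12)
  catalog <- make_catalog(20)
  rows <- do.call(rbind, lapply(1:6, function(j) {
    data.frame(pv_id = catalog$pv_id, species = sprintf("sp%d", j),
               clade = sample(names(DEFAULT_CLADE_RANKS), 1),
               allele = sample(c("A", "G", "."), 20, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  tab1 <- species_allele_table(rows)
  tab2 <- species_allele_table(rows[sample(nrow(rows)), ])
  m1 <- project_and_match(catalog, tab1)
  m2 <- project_and_match(catalog, tab2)
  expect_equal(m1$shared[, colnames(m2$shared)], m2$shared)
  summ <- clade_summary(m1)
  expect_equal(sum(summ$per_clade$species_hits), sum(m1$shared))
  expect_equal(summ$n_absent + summ$n_shared, summ$n_pvs)
  expect_equal(sum(summ$per_clade$pvs_nearest), summ$n_shared)
})

test_that("clade summary percentages follow the half-up convention", {
  # 37 of 43 PVs absent -> 86.0%; focal-clade species percentages over
  # the clade's shared PV count
  catalog <- make_catalog(43)
  shared_ids <- catalog$pv_id[1:6]
  rows <- rbind(
    data.frame(pv_id = catalog$pv_id, species = "prim1", clade = "Primate",
               allele = ifelse(catalog$pv_id %in% shared_ids, "G", "A")),
    data.frame(pv_id = catalog$pv_id, species = "prim2", clade = "Primate",
               allele = ifelse(catalog$pv_id %in% shared_ids[1:3], "G", "A")))
  mat <- project_and_match(catalog, species_allele_table(rows))
  summ <- clade_summary(mat)
  expect_equal(summ$n_absent, 37)
  expect_equal(summ$absent_percent, 86)
  rep <- clade_species_report(mat, "Primate")
  expect_equal(attr(rep, "clade_shared"), 6)
  expect_equal(rep$percent_of_clade_shared[rep$species == "prim2"], 50)
  expect_equal(rep$n_shared[rep$species == "prim1"], 6)
  expect_error(clade_species_report(mat, "Fish"), "no species")
})

test_that("unknown species-table keys warn and are dropped", {
  catalog <- make_catalog(2)
  rows <- data.frame(pv_id = c(catalog$pv_id, "pv999"),
                     species = "sp1", clade = "Fish",
                     allele = "G")
  expect_warning(mat <- project_and_match(catalog,
                                          species_allele_table(rows)),
                 "pv999")
  expect_equal(nrow(mat$shared), 2)
})
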