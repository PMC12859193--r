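with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The defaults emulate the
#' statistical structure of the real study inputs at desk scale: sparse,
#' almost entirely heterozygous PV carriage; ancient dates concentrated
#' between 5,000 and 1,000 years BP with a thin tail to 40,000 BP and an
#' undated fraction of 110/1,266; a higher ancient-sharing propensity in
#' the carried PVs of non-Africans (0.5) than Africans (0.17);
#' cross-species sharing probabilities that decay from the most distal
#' clade (Fish) toward Primate; and an ancient-DNA read model with
#' terminal C->T / G->A deamination and PCR duplicates.
#'
#' @param seed root seed; every generator output is a deterministic
#'   function of it.
#' @param n_pvs,n_genes catalog size.
#' @param n_ancient,n_african,n_nonafrican cohort sizes.
#' @param carriage mean number of distinct carried PVs per individual
#'   (named: ancient, modern_african, modern_nonafrican); draws are
#'   zero-truncated Poisson so every simulated individual is a carrier.
#' @param propensity probability that a carried PV of a modern
#'   individual is one that is present in ancient humans.
#' @param p_ancient fraction of catalogued PVs present in the ancient
#'   gene pool.
#' @param p_het probability a carried PV is heterozygous.
#' @param date_bulk,date_tail_max bulk uniform date range and tail
#'   maximum (years BP); \code{date_tail_frac} of dated individuals fall
#'   uniformly between the bulk upper bound and the tail maximum.
#' @param undated_frac fraction of ancient individuals without dates.
#' @param read_model list: \code{depth_mean, depth_min, read_length,
#'   deamination_rate, deamination_decay, duplicate_rate,
#'   base_qual_mean, base_qual_sd, low_qual_rate, low_map_rate,
#'   seq_error_rate}.
#' @param species_per_clade named integer vector (99 species over the 8
#'   clades by default).
#' @param clade_share_prob named per-clade probability that a species of
#'   that clade carries the human alternate allele; decays toward
#'   Primate.
#' @param p_missing_orthology probability the orthologous position is
#'   absent in a species.
#' @param n_founder,founder_age_mean founder-table size and mean of the
#'   (exponential) age distribution.
#' @param n_selection_genes,selection_means,selection_props selection
#'   table size, per-class mean PV counts and class proportions.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_pvs = 200L, n_genes = 40L,
                       n_ancient = 250L, n_african = 300L,
                       n_nonafrican = 600L,
                       carriage = c(ancient = 1.5, modern_african = 1.2,
                                    modern_nonafrican = 1.2),
                       propensity = c(modern_african = 0.17,
                                      modern_nonafrican = 0.5),
                       p_ancient = 0.4,
                       p_het = 0.98,
                       date_bulk = c(1000, 5000),
                       date_tail_max = 40000,
                       date_tail_frac = 0.05,
                       undated_frac = 110 / 1266,
                       read_model = list(),
                       species_per_clade = c(Fish = 25L, Sarcopterygii = 6L,
                                             Aves = 20L, Mammalia = 20L,
                                             Afrotheria = 4L,
                                             Laurasiatheria = 12L,
                                             Euarchontoglires = 6L,
                                             Primate = 6L),
                       clade_share_prob = c(Fish = 0.006,
                                            Sarcopterygii = 0.005,
                                            Aves = 0.003, Mammalia = 0.002,
                                            Afrotheria = 0.0015,
                                            Laurasiatheria = 0.001,
                                            Euarchontoglires = 0.0006,
                                            Primate = 0.0003),
                       p_missing_orthology = 0.15,
                       n_founder = 50L, founder_age_mean = 1200,
                       n_selection_genes = 45L,
                       selection_means = c(positive = 30, neutral = 10,
                                           negative = 4),
                       selection_props = c(positive = 1 / 3,
                                           neutral = 1 / 3,
                                           negative = 1 / 3)) {
  rm_defaults <- list(depth_mean = 8, depth_min = 1L, read_length = 60L,
                      deamination_rate = 0.2, deamination_decay = 0.3,
                      duplicate_rate = 0.1, base_qual_mean = 37,
                      base_qual_sd = 3, low_qual_rate = 0.05,
                      low_map_rate = 0.05, seq_error_rate = 0.001)
  rm_defaults[names(read_model)] <- read_model
  probs <- c(propensity, p_ancient, p_het, undated_frac, date_tail_frac,
             clade_share_prob, p_missing_orthology, selection_props,
             rm_defaults$deamination_rate, rm_defaults$duplicate_rate,
             rm_defaults$low_qual_rate, rm_defaults$low_map_rate,
             rm_defaults$seq_error_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  cfg <- list(seed = as.integer(seed), n_pvs = as.integer(n_pvs),
              n_genes = as.integer(n_genes),
              n_ancient = as.integer(n_ancient),
              n_african = as.integer(n_african),
              n_nonafrican = as.integer(n_nonafrican),
              carriage = carriage, propensity = propensity,
              p_ancient = p_ancient, p_het = p_het,
              date_bulk = date_bulk, date_tail_max = date_tail_max,
              date_tail_frac = date_tail_frac,
              undated_frac = undated_frac, read_model = rm_defaults,
              species_per_clade = species_per_clade,
              clade_share_prob = clade_share_prob,
              p_missing_orthology = p_missing_orthology,
              n_founder = as.integer(n_founder),
              founder_age_mean = founder_age_mean,
              n_selection_genes = as.integer(n_selection_genes),
              selection_means = selection_means,
              selection_props = selection_props)
  class(cfg) <- "sim_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

#' Simulate a PV catalog with planted truth
#'
#' Draws \code{n_pvs} pathogenic variants over \code{n_genes} synthetic
#' genes. C>T and G>A substitutions are over-represented (as in real
#' ClinVar pathogenic SNVs) so the deamination logic downstream is
#' exercised. Each gene gets 1-3 DDR pathway codes; each PV gets an
#' ancient-present flag with probability \code{p_ancient} -- the planted
#' truth against which cohort sharing and rarefaction are evaluated.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{catalog} (a \code{\link{pv_catalog}}) and
#'   \code{truth} (data frame \code{pv_id, ancient_present}).
#' @export
simulate_catalog <- function(cfg) {
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_pvs
    if (n == 0) {
      cat_df <- stats::setNames(
        as.data.frame(matrix(character(0), ncol = length(CATALOG_COLUMNS))),
        CATALOG_COLUMNS)
      return(list(catalog = pv_catalog(cat_df),
                  truth = data.frame(pv_id = character(0),
                                     ancient_present = logical(0))))
    }
    genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
    gene_pathways <- vapply(genes, function(g) {
      k <- sample(1:3, 1, prob = c(0.6, 0.3, 0.1))
      paste(sample(PATHWAY_CODES, k), collapse = "|")
    }, "")
    pv_gene <- sample(genes, n, replace = TRUE)
    mut_class <- sample(c("CT", "GA", "other"), n, replace = TRUE,
                        prob = c(0.3, 0.15, 0.55))
    ref <- character(n); alt <- character(n)
    for (i in seq_len(n)) {
      if (mut_class[i] == "CT") { ref[i] <- "C"; alt[i] <- "T" }
      else if (mut_class[i] == "GA") { ref[i] <- "G"; alt[i] <- "A" }
      else {
        ref[i] <- sample(BASES, 1)
        alt[i] <- sample(setdiff(BASES, ref[i]), 1)
      }
    }
    df <- data.frame(
      pv_id = sprintf("pv%04d", seq_len(n)),
      gene = pv_gene,
      cdna = sprintf("c.%d%s>%s", sample.int(9000, n, replace = TRUE),
                     ref, alt),
      protein = sprintf("p.X%dY", sample.int(3000, n, replace = TRUE)),
      chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
      pos = sample.int(5e7, n),
      ref = ref, alt = alt,
      pathways = unname(gene_pathways[pv_gene]),
      classification = sample(c("Pathogenic", "LikelyPathogenic"), n,
                              replace = TRUE, prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
    truth <- data.frame(pv_id = df$pv_id,
                        ancient_present = stats::runif(n) < cfg$p_ancient)
    list(catalog = pv_catalog(df), truth = truth)
  })
}

rztpois <- function(n, lambda) {
  # zero-truncated Poisson via inverse-CDF on the shifted uniform
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate ancient and modern carrier cohorts
#'
#' Every individual draws a zero-truncated Poisson number of distinct
#' carried PVs. Ancient individuals draw from the ancient-present pool
#' only (they define it); each carried PV of a modern individual is
#' ancient-present with that cohort's propensity (defaults 0.5 for
#' non-Africans, 0.17 for Africans). Zygosity is heterozygous with
#' probability \code{p_het}. Ancient dates follow the configured
#' bulk/tail mixture and a fraction are undated.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param catalog_sim output of \code{\link{simulate_catalog}}.
#' @return list: \code{carriers} (a \code{carrier_table} over all three
#'   cohorts), \code{individuals} (data frame \code{ind_id, cohort,
#'   date_bp, region} including individuals for whom no PV row exists).
#' @export
simulate_cohorts <- function(cfg, catalog_sim) {
  with_seed(cfg$seed + 2L, {
    truth <- catalog_sim$truth
    pool_anc <- truth$pv_id[truth$ancient_present]
    pool_non <- truth$pv_id[!truth$ancient_present]
    regions <- c("WestEurasia", "EastAsia", "Steppe", "Levant", "Oceania",
                 "SouthAsia")
    draw_carried <- function(k, prop) {
      if (length(pool_anc) == 0 && length(pool_non) == 0) return(character(0))
      n_anc <- stats::rbinom(1, k, prop)
      ids <- c(if (length(pool_anc) > 0) sample(pool_anc, min(n_anc, length(pool_anc))),
               if (length(pool_non) > 0) sample(pool_non, min(k - n_anc, length(pool_non))))
      unique(ids)
    }
    make_cohort <- function(prefix, n, cohort, carriage, prop, dated) {
      if (n == 0) {
        return(list(rows = NULL,
                    inds = data.frame(ind_id = character(0), cohort = character(0),
                                      date_bp = numeric(0), region = character(0))))
      }
      ind_id <- sprintf("%s%05d", prefix, seq_len(n))
      date_bp <- rep(NA_real_, n)
      if (dated) {
        has_date <- stats::runif(n) >= cfg$undated_frac
        tail_draw <- stats::runif(n) < cfg$date_tail_frac
        d_bulk <- stats::runif(n, cfg$date_bulk[1], cfg$date_bulk[2])
        d_tail <- stats::runif(n, cfg$date_bulk[2], cfg$date_tail_max)
        date_bp[has_date] <- round(ifelse(tail_draw, d_tail, d_bulk))[has_date]
      }
      region <- sample(regions, n, replace = TRUE)
      ks <- rztpois(n, carriage)
      rows <- lapply(seq_len(n), function(i) {
        carried <- if (cohort == "ancient") {
          if (length(pool_anc) == 0) character(0)
          else unique(sample(pool_anc, min(ks[i], length(pool_anc)),
                             replace = FALSE))
        } else {
          draw_carried(ks[i], prop)
        }
        if (length(carried) == 0) return(NULL)
        data.frame(ind_id = ind_id[i], cohort = cohort,
                   date_bp = date_bp[i], region = region[i],
                   pv_id = carried,
                   zygosity = ifelse(stats::runif(length(carried)) < cfg$p_het,
                                     "het", "hom"),
                   stringsAsFactors = FALSE)
      })
      list(rows = do.call(rbind, rows),
           inds = data.frame(ind_id = ind_id, cohort = cohort,
                             date_bp = date_bp, region = region,
                             stringsAsFactors = FALSE))
    }
    anc <- make_cohort("ANC", cfg$n_ancient, "ancient",
                       cfg$carriage[["ancient"]], NA, dated = TRUE)
    afr <- make_cohort("AFR", cfg$n_african, "modern_african",
                       cfg$carriage[["modern_african"]],
                       cfg$propensity[["modern_african"]], dated = FALSE)
    nonafr <- make_cohort("NAF", cfg$n_nonafrican, "modern_nonafrican",
                          cfg$carriage[["modern_nonafrican"]],
                          cfg$propensity[["modern_nonafrican"]],
                          dated = FALSE)
    rows <- do.call(rbind, Filter(Negate(is.null),
                                  list(anc$rows, afr$rows, nonafr$rows)))
    if (is.null(rows)) {
      rows <- data.frame(ind_id = character(0), cohort = character(0),
                         date_bp = numeric(0), region = character(0),
                         pv_id = character(0), zygosity = character(0))
    }
    list(carriers = carrier_table(rows),
         individuals = rbind(anc$inds, afr$inds, nonafr$inds))
  })
}

#' Per-individual carried-PV sets for a cohort
#'
#' Builds the named list (\code{ind_id} -> character vector of carried
#' \code{pv_id}s) that \code{\link{rarefy}} consumes. Passing the
#' \code{individuals} roster adds empty sets for individuals with no
#' carrier rows, so subsampling respects the true cohort size.
#'
#' @param carriers a \code{carrier_table}.
#' @param cohort optional cohort label to filter on.
#' @param individuals optional roster data frame with \code{ind_id} (and
#'   \code{cohort}).
#' @return named list of character vectors.
#' @export
cohort_pv_sets <- function(carriers, cohort = NULL, individuals = NULL) {
  df <- as.data.frame(carriers)
  if (!is.null(cohort)) df <- df[df$cohort == cohort, , drop = FALSE]
  sets <- split(as.character(df$pv_id), as.character(df$ind_id))
  if (!is.null(individuals)) {
    roster <- individuals
    if (!is.null(cohort) && "cohort" %in% names(roster)) {
      roster <- roster[roster$cohort == cohort, , drop = FALSE]
    }
    missing_ids <- setdiff(roster$ind_id, names(sets))
    sets <- c(sets, stats::setNames(
      rep(list(character(0)), length(missing_ids)), missing_ids))
    sets <- sets[order(names(sets))]
  }
  sets
}

#' Simulate ancient-DNA read observations at one PV site
#'
#' Draws a read depth, assigns each read a true allele from the planted
#' genotype (heterozygotes are binomial 0.5), places the site uniformly
#' along the read, and injects the deamination artifact: a true C on a
#' forward-strand read becomes T with probability
#' \code{deamination_rate * exp(-deamination_decay * dist5)}, and a true
#' G on a reverse-strand read becomes A with the mirrored probability in
#' \code{dist3}. A generic sequencing-error rate, low-quality reads and
#' PCR duplicates (same fragment key, fresh read id) complete the model.
#'
#' @param cfg a \code{\link{sim_config}} (its \code{read_model} is used).
#' @param ind_id,pv individual id and single-row catalog slice.
#' @param genotype \code{"ref/ref"}, \code{"het"} or \code{"hom"}.
#' @return data frame in the pileup layout (possibly zero rows).
#' @export
simulate_reads <- function(cfg, ind_id, pv, genotype = c("ref/ref", "het",
                                                         "hom")) {
  genotype <- match.arg(genotype)
  rm <- cfg$read_model
  depth <- max(rm$depth_min, stats::rpois(1, rm$depth_mean))
  if (depth == 0) {
    return(stats::setNames(as.data.frame(matrix(character(0), ncol =
                                                  length(PILEUP_COLUMNS))),
                           PILEUP_COLUMNS))
  }
  true_base <- switch(genotype,
                      "ref/ref" = rep(pv$ref, depth),
                      "hom" = rep(pv$alt, depth),
                      "het" = ifelse(stats::runif(depth) < 0.5, pv$alt, pv$ref))
  strand <- sample(c("+", "-"), depth, replace = TRUE)
  len <- rm$read_length
  dist5 <- sample.int(len, depth, replace = TRUE) - 1L
  dist3 <- len - 1L - dist5
  base <- true_base
  p_deam5 <- rm$deamination_rate * exp(-rm$deamination_decay * dist5)
  p_deam3 <- rm$deamination_rate * exp(-rm$deamination_decay * dist3)
  hit5 <- base == "C" & strand == "+" & stats::runif(depth) < p_deam5
  hit3 <- base == "G" & strand == "-" & stats::runif(depth) < p_deam3
  base[hit5] <- "T"
  base[hit3] <- "A"
  err <- stats::runif(depth) < rm$seq_error_rate & nchar(base) == 1
  if (any(err)) {
    base[err] <- vapply(base[err],
                        function(b) sample(setdiff(BASES, b), 1), "")
  }
  base_qual <- as.integer(pmax(2, pmin(41, round(
    stats::rnorm(depth, rm$base_qual_mean, rm$base_qual_sd)))))
  lowq <- stats::runif(depth) < rm$low_qual_rate
  base_qual[lowq] <- sample(2:19, sum(lowq), replace = TRUE)
  map_qual <- rep(60L, depth)
  lowm <- stats::runif(depth) < rm$low_map_rate
  map_qual[lowm] <- sample(0:29, sum(lowm), replace = TRUE)
  frag_start <- ifelse(strand == "+", pv$pos - dist5, pv$pos - dist3)
  frag_end <- frag_start + len - 1L
  df <- data.frame(ind_id = ind_id, pv_id = pv$pv_id,
                   read_id = sprintf("%s_%s_r%03d", ind_id, pv$pv_id,
                                     seq_len(depth)),
                   base = base, base_qual = base_qual, map_qual = map_qual,
                   dist5 = dist5, dist3 = dist3, strand = strand,
                   frag_start = as.integer(frag_start),
                   frag_end = as.integer(frag_end),
                   stringsAsFactors = FALSE)
  dup <- stats::runif(depth) < rm$duplicate_rate
  if (any(dup)) {
    dups <- df[dup, , drop = FALSE]
    dups$read_id <- paste0(dups$read_id, "_dup")
    dups$base_qual <- pmax(2L, dups$base_qual -
                             sample(0:3, nrow(dups), replace = TRUE))
    df <- rbind(df, dups)
  }
  rownames(df) <- NULL
  df
}

#' Simulate pileups for an ancient cohort with planted genotypes
#'
#' Generates read observations for every (ancient individual, carried
#' PV) pair -- planted \code{het}/\code{hom} per the carrier table --
#' plus \code{n_ref_sites} uncarried catalog PVs per individual planted
#' \code{ref/ref}, so the caller's absent path is exercised too.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param catalog a \code{\link{pv_catalog}}.
#' @param carriers a \code{carrier_table}; only \code{ancient} rows are
#'   used.
#' @param n_ref_sites uncarried sites per individual.
#' @return list: \code{pileup} (a \code{\link{pileup_table}}) and
#'   \code{truth} (data frame \code{ind_id, pv_id, genotype}).
#' @export
simulate_pileups <- function(cfg, catalog, carriers, n_ref_sites = 3L) {
  with_seed(cfg$seed + 6L, {
    df <- as.data.frame(carriers)
    df <- df[df$cohort == "ancient", , drop = FALSE]
    cat_df <- as.data.frame(catalog)
    truth_rows <- list(); pile_rows <- list(); k <- 0L
    for (ind in unique(df$ind_id)) {
      carried <- df[df$ind_id == ind, , drop = FALSE]
      uncarried <- setdiff(cat_df$pv_id, carried$pv_id)
      ref_sites <- if (length(uncarried) > 0) {
        sample(uncarried, min(n_ref_sites, length(uncarried)))
      } else character(0)
      plan <- rbind(
        data.frame(pv_id = carried$pv_id,
                   genotype = ifelse(carried$zygosity == "hom", "hom", "het"),
                   stringsAsFactors = FALSE),
        if (length(ref_sites) > 0) {
          data.frame(pv_id = ref_sites, genotype = "ref/ref",
                     stringsAsFactors = FALSE)
        })
      for (i in seq_len(nrow(plan))) {
        pv <- cat_df[match(plan$pv_id[i], cat_df$pv_id), ]
        k <- k + 1L
        pile_rows[[k]] <- simulate_reads(cfg, ind, pv, plan$genotype[i])
      }
      plan$ind_id <- ind
      truth_rows[[length(truth_rows) + 1L]] <- plan
    }
    pile <- do.call(rbind, pile_rows)
    if (is.null(pile)) {
      pile <- stats::setNames(as.data.frame(matrix(character(0), ncol =
                                                     length(PILEUP_COLUMNS))),
                              PILEUP_COLUMNS)
      for (col in c("base_qual", "map_qual", "dist5", "dist3",
                    "frag_start", "frag_end")) pile[[col]] <- integer(0)
      pile$strand <- character(0)
    }
    truth <- do.call(rbind, truth_rows)
    truth <- if (is.null(truth)) {
      data.frame(ind_id = character(0), pv_id = character(0),
                 genotype = character(0))
    } else truth[, c("ind_id", "pv_id", "genotype")]
    list(pileup = pileup_table(pile), truth = truth)
  })
}

#' Simulate a species allele table
#'
#' Each species of each clade carries the human alternate allele at a
#' PV's orthologous position with its clade's sharing probability
#' (decaying from Fish toward Primate by default), lacks the orthologous
#' position with probability \code{p_missing_orthology}, and otherwise
#' shows the human reference allele.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param catalog a \code{\link{pv_catalog}}.
#' @return a \code{\link{species_allele_table}}.
#' @export
simulate_species_table <- function(cfg, catalog) {
  with_seed(cfg$seed + 3L, {
    cat_df <- as.data.frame(catalog)
    rows <- list()
    for (clade in names(cfg$species_per_clade)) {
      n_sp <- cfg$species_per_clade[[clade]]
      p_share <- cfg$clade_share_prob[[clade]]
      for (s in seq_len(n_sp)) {
        sp <- sprintf("%s_sp%02d", clade, s)
        n <- nrow(cat_df)
        if (n == 0) next
        u <- stats::runif(n)
        allele <- ifelse(u < cfg$p_missing_orthology, ".",
                         ifelse(u < cfg$p_missing_orthology + p_share *
                                  (1 - cfg$p_missing_orthology),
                                cat_df$alt, cat_df$ref))
        rows[[length(rows) + 1L]] <- data.frame(
          pv_id = cat_df$pv_id, species = sp, clade = clade,
          allele = allele, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    if (is.null(df)) {
      df <- data.frame(pv_id = character(0), species = character(0),
                       clade = character(0), allele = character(0))
    }
    species_allele_table(df)
  })
}

#' Simulate a founder-variant age table
#'
#' Ages are exponential with the configured mean, truncated at 9,000
#' BP; most fall within the recent 4,000 years. A mix of point, range
#' and bounded specifications (with thousands separators) exercises the
#' age parser.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{\link{founder_table}}.
#' @export
simulate_founder_table <- function(cfg) {
  with_seed(cfg$seed + 4L, {
    n <- cfg$n_founder
    genes <- sample(c("BRCA1", "BRCA2", "MLH1", "MSH2", "MSH6", "MUTYH",
                      "TP53"), n, replace = TRUE,
                    prob = c(0.35, 0.3, 0.08, 0.08, 0.05, 0.07, 0.07))
    age <- round(pmin(stats::rexp(n, 1 / cfg$founder_age_mean), 9000)) + 100
    kind <- sample(c("point", "range", "lower", "upper"), n, replace = TRUE,
                   prob = c(0.7, 0.15, 0.08, 0.07))
    fmt_thousands <- function(x) format(x, big.mark = ",", trim = TRUE,
                                        scientific = FALSE)
    years_bp <- vapply(seq_len(n), function(i) {
      switch(kind[i],
             point = fmt_thousands(age[i]),
             range = paste0(fmt_thousands(age[i]), "-",
                            fmt_thousands(round(age[i] * stats::runif(1, 0.4, 0.9)))),
             lower = paste0(">", fmt_thousands(age[i])),
             upper = paste0("<", fmt_thousands(age[i])))
    }, "")
    founder_table(data.frame(
      gene = genes,
      cdna = sprintf("c.%ddel", sample.int(9000, n)),
      protein = sprintf("p.X%dfs", sample.int(3000, n)),
      pubmed_id = sprintf("9%07d", sample.int(9999999, n)),
      population = sample(c("Ashkenazi Jewish", "Finnish", "Icelandic",
                            "Portuguese", "Spanish", "Italian", "Dutch"),
                          n, replace = TRUE),
      years_bp = years_bp, stringsAsFactors = FALSE))
  })
}

#' Simulate a per-gene selection-class table
#'
#' Genes are assigned to positive/neutral/negative selection classes
#' with the configured proportions; per-gene PV counts are Poisson with
#' the class mean, so classes differ in location on the log2 scale.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a \code{\link{selection_table}}.
#' @export
simulate_selection_table <- function(cfg) {
  with_seed(cfg$seed + 5L, {
    n <- cfg$n_selection_genes
    cls <- sample(names(cfg$selection_props), n, replace = TRUE,
                  prob = cfg$selection_props)
    selection_table(data.frame(
      gene = sprintf("SELGENE%03d", seq_len(n)),
      class = cls,
      pv_count = stats::rpois(n, cfg$selection_means[cls]),
      stringsAsFactors = FALSE))
  })
}

#' Simulate a complete run directory
#'
#' Writes every input the pipeline consumes -- catalog, carrier and
#' roster tables, ancient pileups, species allele table, synthetic
#' founder table, selection table -- plus a \code{truth.json} with the
#' planted structure. Byte-identical for a fixed config.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return (invisibly) list of generated objects and file paths.
#' @export
simulate_run <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cat_sim <- simulate_catalog(cfg)
  cohorts <- simulate_cohorts(cfg, cat_sim)
  pile_sim <- simulate_pileups(cfg, cat_sim$catalog, cohorts$carriers)
  species <- simulate_species_table(cfg, cat_sim$catalog)
  founders <- simulate_founder_table(cfg)
  selection <- simulate_selection_table(cfg)
  paths <- list(
    catalog = file.path(dir, "catalog.tsv"),
    carriers = file.path(dir, "carriers.tsv"),
    individuals = file.path(dir, "individuals.tsv"),
    pileup = file.path(dir, "pileup.tsv"),
    species = file.path(dir, "species_alleles.tsv"),
    founders = file.path(dir, "founder_ages_synthetic.tsv"),
    selection = file.path(dir, "selection_classes.tsv"),
    truth = file.path(dir, "truth.json"))
  write_catalog(cat_sim$catalog, paths$catalog)
  write_carriers(cohorts$carriers, paths$carriers)
  utils::write.table(cohorts$individuals, paths$individuals, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(pile_sim$pileup), paths$pileup,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(species), paths$species, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(founders)[, c("gene", "cdna", "protein",
                                                 "pubmed_id", "population",
                                                 "years_bp")],
                     paths$founders, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(selection), paths$selection, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(seed = cfg$seed,
                ancient_present = cat_sim$truth$pv_id[cat_sim$truth$ancient_present],
                genotypes = pile_sim$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(config = cfg, catalog = cat_sim$catalog,
                 truth = cat_sim$truth, carriers = cohorts$carriers,
                 individuals = cohorts$individuals,
                 pileup = pile_sim$pileup,
                 genotype_truth = pile_sim$truth, species = species,
                 founders = founders, selection = selection,
                 paths = paths))
}
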