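#' Run the full analysis chain and assemble a report
#'
#' Executes catalog reading, damage-aware presence calling, cohort
#' sharing (Venn partition, load comparison, temporal profile),
#' rarefaction of both modern cohorts against the ancient PV set,
#' cross-species projection, the selection-class bootstrap and the
#' founder-table summaries, and assembles one JSON-serializable report.
#' The ancient PV set is taken from presence calls when a pileup is
#' given, otherwise from the ancient carrier rows.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   \code{catalog} (path), \code{carriers} (path), optional
#'   \code{individuals}, \code{pileup}, \code{species}, \code{founders},
#'   \code{selection} paths; \code{seed}; optional parameter blocks
#'   \code{caller} (arguments to \code{\link{caller_config}}),
#'   \code{rarefaction} (\code{sizes}, \code{n_reps}), \code{bin_width},
#'   \code{n_boot}; optional \code{out_dir} to write \code{report.json}
#'   and the stage TSVs.
#' @return list of class \code{paleo_report} with one element per stage
#'   plus \code{meta} (seed and config hash).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  report <- list(meta = list(seed = seed,
                             config_hash = config_hash(config),
                             n_records = list()))

  catalog <- stage("catalog", read_catalog(config$catalog))
  report$meta$n_records$catalog <- nrow(catalog)

  carriers <- stage("carriers", read_carriers(config$carriers, catalog))
  individuals <- if (!is.null(config$individuals)) {
    utils::read.delim(config$individuals, check.names = FALSE)
  } else NULL
  report$meta$n_records$carriers <- nrow(carriers)

  ancient_carriers <- carriers[carriers$cohort == "ancient", , drop = FALSE]
  if (!is.null(config$pileup)) {
    cfg_caller <- do.call(caller_config, as.list(config$caller))
    pile <- stage("presence", read_pileup(config$pileup))
    calls <- stage("presence", call_presence_all(pile, catalog, cfg_caller))
    report$presence <- list(
      n_sites = nrow(calls),
      n_present = sum(calls$call == "present"),
      n_absent = sum(calls$call == "absent"),
      n_uncallable = sum(calls$call == "uncallable"),
      calls = calls)
    ancient_pvs <- sort(unique(calls$pv_id[calls$call == "present"]))
  } else {
    ancient_pvs <- sort(unique(ancient_carriers$pv_id))
  }

  african_pvs <- unique(carriers$pv_id[carriers$cohort == "modern_african"])
  nonafrican_pvs <- unique(carriers$pv_id[carriers$cohort == "modern_nonafrican"])

  report$sharing <- stage("sharing", {
    venn <- venn_partition(ancient_pvs, african_pvs, nonafrican_pvs)
    anc_counts <- count_by_gene_and_pathway(catalog, restrict_to =
                                              intersect(ancient_pvs, catalog$pv_id))
    mod_counts <- count_by_gene_and_pathway(catalog, restrict_to =
                                              intersect(union(african_pvs, nonafrican_pvs),
                                                        catalog$pv_id))
    bin_width <- if (is.null(config$bin_width)) 1000 else config$bin_width
    list(venn = venn,
         ancient_share_percent = sharing_percentage(length(ancient_pvs),
                                                    nrow(catalog), 1),
         load = load_comparison(anc_counts, mod_counts),
         temporal = temporal_profile(ancient_carriers, catalog, bin_width))
  })

  report$rarefaction <- stage("rarefaction", {
    rcfg <- config$rarefaction
    sets_afr <- cohort_pv_sets(carriers, "modern_african", individuals)
    sets_naf <- cohort_pv_sets(carriers, "modern_nonafrican", individuals)
    max_n <- min(length(sets_afr), length(sets_naf))
    design <- rarefaction_design(
      sizes = rcfg$sizes,
      n_reps = if (is.null(rcfg$n_reps)) 200L else rcfg$n_reps,
      seed = seed,
      min_size = max(2L, ceiling(max_n / 20)),
      max_size = max_n,
      n_sizes = if (is.null(rcfg$n_sizes)) 8L else rcfg$n_sizes)
    res_afr <- rarefy(sets_afr, ancient_pvs, design)
    res_naf <- rarefy(sets_naf, ancient_pvs, design)
    list(african = res_afr$summary, nonafrican = res_naf$summary,
         comparison = compare_curves(res_naf, res_afr))
  })

  if (!is.null(config$species)) {
    report$phylo <- stage("phylo", {
      tab <- read_species_alleles(config$species)
      mat <- project_and_match(catalog, tab)
      clade_summary(mat)
    })
  }

  if (!is.null(config$selection)) {
    report$selection <- stage("selection", {
      st <- read_selection_table(config$selection)
      bt <- bootstrap_group_test(
        st, n_boot = if (is.null(config$n_boot)) 10000L else config$n_boot,
        seed = seed)
      bt[c("mean_a", "mean_b", "diff_obs", "p_value", "group_a", "group_b",
           "n_boot", "transform")]
    })
  }

  if (!is.null(config$founders)) {
    report$founder <- stage("founder", {
      ft <- read_founder_table(config$founders)
      oldest <- oldest_founder(ft)
      parts <- filter_by_age(ft, 4000)
      list(n_records = nrow(ft),
           oldest = list(gene = oldest$record$gene,
                         cdna = oldest$record$cdna,
                         age_bp = oldest$age_bp),
           n_within_4000 = nrow(parts$within),
           n_exceeding_4000 = nrow(parts$exceeding))
    })
  }

  class(report) <- "paleo_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_hash <- function(config) {
  # order-insensitive structural hash; no external digest dependency
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      paste0("{", paste(names(x), vapply(x, canon, ""), sep = ":",
                        collapse = ","), "}")
    } else {
      paste(format(x), collapse = ",")
    }
  }
  s <- canon(config)
  v <- utf8ToInt(s)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 1024))) {
    h <- sum(h * 33^(rev(seq_along(chunk)) %% 7), chunk) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Write a pipeline report to disk
#'
#' Serializes the report to \code{report.json} (data frames as column
#' objects) under \code{dir}.
#'
#' @param report a \code{paleo_report}.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ser <- rapply(unclass(report), f = function(x) x, how = "replace")
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  invisible(file.path(dir, "report.json"))
}
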