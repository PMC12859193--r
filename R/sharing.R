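#' Sharing percentage with half-up rounding
#'
#' Percentage of catalogued PVs shared between two cohorts, rounded
#' half-up (so 70.5 -> 71 at 0 digits, matching how such percentages are
#' conventionally printed rather than banker's rounding).
#'
#' @param shared_count,total_count non-negative counts,
#'   \code{shared_count <= total_count}, \code{total_count > 0}.
#' @param digits decimals to keep.
#' @return numeric percentage.
#' @export
sharing_percentage <- function(shared_count, total_count, digits = 1L) {
  if (total_count <= 0) stop("total_count must be positive")
  if (shared_count > total_count) stop("shared_count exceeds total_count")
  if (shared_count < 0) stop("shared_count must be non-negative")
  round_half_up(100 * shared_count / total_count, digits)
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Partition ancient PVs by sharing with modern cohorts
#'
#' Splits the set of PVs observed in ancient individuals into four
#' disjoint classes by membership in the modern African and non-African
#' PV sets: shared with non-Africans only, with both, with Africans only,
#' or with neither modern cohort. Fractions are reported on two bases:
#' \code{fractions} over the shared PVs only (ancient PVs found in at
#' least one modern cohort) and \code{fractions_all} over all ancient
#' PVs; when no ancient PV is shared with either cohort the shared-base
#' fractions are undefined and flagged \code{NA} with a warning.
#'
#' @param ancient_pvs,african_pvs,nonafrican_pvs character vectors of
#'   \code{pv_id}s (treated as sets).
#' @return list of class \code{venn_partition} with the four id sets and
#'   both fraction vectors (\code{only_nonafrican, both, only_african}).
#' @export
venn_partition <- function(ancient_pvs, african_pvs, nonafrican_pvs) {
  ancient_pvs <- unique(as.character(ancient_pvs))
  in_afr <- ancient_pvs %in% african_pvs
  in_nonafr <- ancient_pvs %in% nonafrican_pvs
  out <- list(
    only_nonafrican = ancient_pvs[!in_afr & in_nonafr],
    both            = ancient_pvs[in_afr & in_nonafr],
    only_african    = ancient_pvs[in_afr & !in_nonafr],
    neither         = ancient_pvs[!in_afr & !in_nonafr])
  shared_n <- length(out$only_nonafrican) + length(out$both) +
    length(out$only_african)
  frac_names <- c("only_nonafrican", "both", "only_african")
  if (shared_n == 0) {
    warning("no ancient PV is shared with either modern cohort; ",
            "shared-base fractions undefined")
    out$fractions <- stats::setNames(rep(NA_real_, 3), frac_names)
  } else {
    out$fractions <- stats::setNames(
      c(length(out$only_nonafrican), length(out$both),
        length(out$only_african)) / shared_n, frac_names)
  }
  total_n <- length(ancient_pvs)
  out$fractions_all <- if (total_n == 0) {
    stats::setNames(rep(NA_real_, 3), frac_names)
  } else {
    stats::setNames(c(length(out$only_nonafrican), length(out$both),
                      length(out$only_african)) / total_n, frac_names)
  }
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Ancient-PV sharing partition\n")
  cat(sprintf("  non-African only: %d (%.1f%%)\n", length(x$only_nonafrican),
              100 * x$fractions[["only_nonafrican"]]))
  cat(sprintf("  both cohorts:     %d (%.1f%%)\n", length(x$both),
              100 * x$fractions[["both"]]))
  cat(sprintf("  African only:     %d (%.1f%%)\n", length(x$only_african),
              100 * x$fractions[["only_african"]]))
  cat(sprintf("  neither (excluded from %% base): %d\n", length(x$neither)))
  invisible(x)
}

#' Compare per-gene PV load between two cohorts
#'
#' Each cohort's per-gene count is normalized to a share of that cohort's
#' nonredundant total, so cohorts of very different sizes become
#' comparable; the discordance score is ancient share minus modern share
#' and genes are ranked by its magnitude. A gene absent from one cohort
#' contributes share 0 on that side.
#'
#' @param ancient_counts,modern_counts \code{pv_count_table}s from
#'   \code{\link{count_by_gene_and_pathway}}; both must be nonempty.
#' @return data frame \code{gene, ancient_share, modern_share,
#'   discordance}, ordered by decreasing \code{|discordance|}.
#' @export
load_comparison <- function(ancient_counts, modern_counts) {
  if (ancient_counts$total_nonredundant == 0 ||
      modern_counts$total_nonredundant == 0) {
    stop("both count tables must be nonempty")
  }
  genes <- union(names(ancient_counts$per_gene), names(modern_counts$per_gene))
  a <- ancient_counts$per_gene[genes]
  m <- modern_counts$per_gene[genes]
  a[is.na(a)] <- 0L
  m[is.na(m)] <- 0L
  out <- data.frame(gene = genes,
                    ancient_share = as.numeric(a) / ancient_counts$total_nonredundant,
                    modern_share = as.numeric(m) / modern_counts$total_nonredundant,
                    stringsAsFactors = FALSE)
  out$discordance <- out$ancient_share - out$modern_share
  out <- out[order(-abs(out$discordance), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Temporal profile of dated ancient PV carriers
#'
#' Bins dated carrier occurrences into half-open intervals
#' \code{[start, end)} in years BP, descending in time; undated carriers
#' are excluded from the bins and counted separately. Also reports, per
#' gene, the oldest dated carrier (the first appearance of a PV in that
#' gene within the sampled record) and the overall oldest and youngest
#' dated (pv_id, date) pairs.
#'
#' Two counting modes: \code{"carrier_occurrence"} (default) counts one
#' per (individual, carried PV) so an individual carrying two PVs
#' contributes twice; \code{"individual"} counts each dated individual
#' once (bins and oldest/youngest then use each individual's full PV
#' list for gene attribution but a single date contribution per person).
#'
#' @param carriers a \code{carrier_table} (ancient cohort rows).
#' @param catalog a \code{\link{pv_catalog}} supplying the gene of each PV.
#' @param bin_width bin width in years; default 1000.
#' @param mode counting mode, see above.
#' @return list of class \code{temporal_profile}: \code{bins} (data frame
#'   \code{start_bp, end_bp, carrier_count}), \code{first_occurrence}
#'   (named numeric, per gene), \code{oldest}, \code{youngest},
#'   \code{n_undated}.
#' @export
temporal_profile <- function(carriers, catalog, bin_width = 1000,
                             mode = c("carrier_occurrence", "individual")) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0)
  df <- as.data.frame(carriers)
  df$gene <- as.data.frame(catalog)$gene[match(df$pv_id, catalog$pv_id)]
  dated <- df[!is.na(df$date_bp), , drop = FALSE]
  undated <- df[is.na(df$date_bp), , drop = FALSE]
  n_undated <- if (mode == "individual") {
    length(setdiff(unique(undated$ind_id), unique(dated$ind_id)))
  } else {
    nrow(undated)
  }
  events <- if (mode == "individual") {
    dated[!duplicated(dated$ind_id), , drop = FALSE]
  } else {
    dated
  }
  if (nrow(events) == 0) {
    bins <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                       carrier_count = integer(0))
  } else {
    top <- ceiling(max(events$date_bp) / bin_width + 1e-12) * bin_width
    top <- max(top, bin_width)
    starts <- seq(top, bin_width, by = -bin_width)
    counts <- vapply(starts, function(s) {
      sum(events$date_bp < s & events$date_bp >= (s - bin_width))
    }, 1L)
    bins <- data.frame(start_bp = starts, end_bp = starts - bin_width,
                       carrier_count = counts)
  }
  first_occurrence <- if (nrow(dated) == 0) {
    stats::setNames(numeric(0), character(0))
  } else {
    vapply(split(dated$date_bp, dated$gene), max, 1.0)
  }
  pick <- function(which_fun) {
    if (nrow(dated) == 0) return(list(pv_id = NA_character_, date_bp = NA_real_))
    i <- which_fun(dated$date_bp)
    list(pv_id = dated$pv_id[i], date_bp = dated$date_bp[i])
  }
  out <- list(bins = bins, first_occurrence = first_occurrence,
              oldest = pick(which.max), youngest = pick(which.min),
              n_undated = n_undated, mode = mode, bin_width = bin_width)
  class(out) <- "temporal_profile"
  out
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat("Temporal profile (", x$mode, " counting, ", x$bin_width,
      "-year bins)\n", sep = "")
  if (!is.na(x$oldest$date_bp)) {
    cat(sprintf("  oldest: %s at %s BP; youngest: %s at %s BP\n",
                x$oldest$pv_id, format(x$oldest$date_bp, big.mark = ","),
                x$youngest$pv_id, format(x$youngest$date_bp, big.mark = ",")))
  }
  cat("  undated carriers:", x$n_undated, "\n")
  occupied <- x$bins[x$bins$carrier_count > 0, , drop = FALSE]
  print(utils::head(occupied, 12), row.names = FALSE)
  invisible(x)
}
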