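#' Rarefaction design
#'
#' Subsampling plan used to equalize cohort sizes: the list of subgroup
#' sizes, the number of replicate draws per size, and the root seed. When
#' \code{sizes} is omitted, \code{n_sizes} sizes are interpolated evenly
#' on a log scale between \code{min_size} and \code{max_size} (the
#' default mirrors the 15-subgroup, 1,000-replicate design used to
#' compare a 222,342-person cohort down to a 28,872-person one).
#'
#' @param sizes ascending integer vector of subgroup sizes, or NULL.
#' @param n_reps replicate subsamples per size.
#' @param seed root seed; every random draw derives from it.
#' @param min_size,max_size,n_sizes log-scale interpolation bounds used
#'   when \code{sizes} is NULL.
#' @return list of class \code{rarefaction_design}.
#' @export
rarefaction_design <- function(sizes = NULL, n_reps = 1000L, seed = 1L,
                               min_size = 1000L, max_size = 28872L,
                               n_sizes = 15L) {
  if (is.null(sizes)) {
    sizes <- unique(round(exp(seq(log(min_size), log(max_size),
                                  length.out = n_sizes))))
  }
  sizes <- sort(unique(as.integer(sizes)))
  if (length(sizes) == 0 || any(sizes < 1)) stop("sizes must be >= 1")
  if (n_reps < 1) stop("n_reps must be >= 1")
  out <- list(sizes = sizes, n_reps = as.integer(n_reps),
              seed = as.integer(seed))
  class(out) <- "rarefaction_design"
  out
}

carrier_sets <- function(cohort) {
  if (inherits(cohort, "data.frame")) {
    split(as.character(cohort$pv_id), as.character(cohort$ind_id))
  } else if (is.list(cohort)) {
    cohort
  } else {
    stop("cohort must be a carrier table or a named list of pv_id sets")
  }
}

#' Rarefaction resampling of ancient-PV sharing
#'
#' For each subgroup size n and each replicate, draws n individuals from
#' the cohort without replacement, takes the union of their carried PVs
#' ("discovered" PVs), and records the proportion of discovered PVs that
#' are also present in ancient humans. Replicates that discover zero PVs
#' are flagged and excluded from the summaries. The per-(size, replicate)
#' random streams are derived from the design's root seed up front, so
#' results are bitwise reproducible and independent of execution order.
#'
#' @param cohort a \code{carrier_table} (or named list mapping
#'   \code{ind_id} to a character vector of carried \code{pv_id}s).
#' @param ancient_pvs character vector: the PVs observed in ancient
#'   individuals.
#' @param design a \code{\link{rarefaction_design}}; every size must be
#'   at most the cohort size.
#' @return list of class \code{rarefaction_result}: \code{proportions}
#'   (size x rep matrix, NA where discovery was empty),
#'   \code{discovered_counts} (same shape), \code{summary} (data frame
#'   \code{size, median, q5, q95, n_zero_discovery}), and the design.
#' @export
rarefy <- function(cohort, ancient_pvs, design) {
  stopifnot(inherits(design, "rarefaction_design"))
  sets <- carrier_sets(cohort)
  n_ind <- length(sets)
  too_big <- design$sizes[design$sizes > n_ind]
  if (length(too_big) > 0) {
    stop("subgroup size(s) exceed cohort size (", n_ind, "): ",
         paste(too_big, collapse = ", "))
  }
  ancient_pvs <- unique(as.character(ancient_pvs))
  n_sizes <- length(design$sizes)
  sub_seeds <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(design$seed)
    matrix(sample.int(.Machine$integer.max - 1L, n_sizes * design$n_reps),
           nrow = n_sizes)
  })
  props <- matrix(NA_real_, n_sizes, design$n_reps)
  disc <- matrix(NA_integer_, n_sizes, design$n_reps)
  for (i in seq_len(n_sizes)) {
    n <- design$sizes[i]
    for (j in seq_len(design$n_reps)) {
      set.seed(sub_seeds[i, j])
      idx <- sample.int(n_ind, n)
      discovered <- unique(unlist(sets[idx], use.names = FALSE))
      disc[i, j] <- length(discovered)
      if (length(discovered) > 0) {
        props[i, j] <- sum(discovered %in% ancient_pvs) / length(discovered)
      }
    }
  }
  summ <- data.frame(
    size = design$sizes,
    median = apply(props, 1, stats::median, na.rm = TRUE),
    q5 = apply(props, 1, stats::quantile, probs = 0.05, na.rm = TRUE,
               names = FALSE),
    q95 = apply(props, 1, stats::quantile, probs = 0.95, na.rm = TRUE,
                names = FALSE),
    n_zero_discovery = apply(props, 1, function(x) sum(is.na(x))))
  out <- list(proportions = props, discovered_counts = disc,
              summary = summ, design = design)
  class(out) <- "rarefaction_result"
  out
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat("Rarefaction result:", length(x$design$sizes), "sizes x",
      x$design$n_reps, "replicates (seed", x$design$seed, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Compare two rarefaction curves size by size
#'
#' Per-size difference of median ancient-sharing proportions between two
#' cohorts resampled under the same design, with an indicator of whether
#' the [5th, 95th] percentile bands overlap at that size (non-overlap is
#' the separation evidence the curves are meant to display).
#'
#' @param result_a,result_b \code{rarefaction_result}s produced under an
#'   identical design (sizes and replicate count).
#' @return data frame \code{size, median_a, median_b, diff,
#'   bands_overlap}.
#' @export
compare_curves <- function(result_a, result_b) {
  da <- result_a$design; db <- result_b$design
  if (!identical(da$sizes, db$sizes) || da$n_reps != db$n_reps) {
    stop("rarefaction designs differ (sizes or replicate count)")
  }
  sa <- result_a$summary; sb <- result_b$summary
  data.frame(size = da$sizes,
             median_a = sa$median, median_b = sb$median,
             diff = sa$median - sb$median,
             bands_overlap = sa$q5 <= sb$q95 & sb$q5 <= sa$q95)
}

#' Write rarefaction output tables
#'
#' Writes the per-size summary TSV and a long-format per-replicate TSV
#' (\code{size rep proportion discovered}).
#'
#' @param result a \code{rarefaction_result}.
#' @param summary_path,long_path output files (either may be NULL).
#' @export
write_rarefaction <- function(result, summary_path = NULL, long_path = NULL) {
  if (!is.null(summary_path)) {
    utils::write.table(result$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(long_path)) {
    long <- data.frame(
      size = rep(result$design$sizes, times = result$design$n_reps),
      rep = rep(seq_len(result$design$n_reps), each = length(result$design$sizes)),
      proportion = as.vector(result$proportions),
      discovered = as.vector(result$discovered_counts))
    long <- long[order(long$size, long$rep), ]
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result)
}
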