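#' Read a per-gene selection-class table
#'
#' TSV \code{gene class pv_count}: each DDR gene's selection regime
#' (\code{positive}, \code{neutral} or \code{negative}, classified
#' upstream, e.g. by dN/dS) and its pathogenic-variant count.
#'
#' @param path input TSV.
#' @return data frame of class \code{selection_table}.
#' @export
read_selection_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  selection_table(df)
}

#' @rdname read_selection_table
#' @param df data frame in the selection-table layout.
#' @export
selection_table <- function(df) {
  required <- c("gene", "class", "pv_count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("selection table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required]
  df$gene <- as.character(df$gene)
  df$class <- as.character(df$class)
  df$pv_count <- as.integer(df$pv_count)
  bad <- setdiff(unique(df$class), c("positive", "neutral", "negative"))
  if (length(bad) > 0) stop("unknown selection class(es): ",
                            paste(bad, collapse = ", "))
  if (any(df$pv_count < 0)) stop("negative pv_count")
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0) stop("duplicate gene(s): ", paste(dup, collapse = ", "))
  class(df) <- c("selection_table", "data.frame")
  df
}

#' Bootstrap comparison of per-gene PV counts between selection classes
#'
#' Tests whether genes under one selection regime carry more pathogenic
#' variants than genes under another. Counts are transformed
#' (default \code{log2(count + 1)}, which admits zero-PV genes), genes
#' are resampled with replacement within each class \code{n_boot} times,
#' and the statistic is the difference of transformed-group means
#' (\code{group_a - group_b}). The two-sided p-value is
#' \code{2 * min(Pr(diff <= 0), Pr(diff >= 0))} over the bootstrap
#' distribution, with a \code{+1/(n_boot+1)} continuity correction so p
#' is never exactly 0, capped at 1.
#'
#' @param table a \code{\link{selection_table}}.
#' @param group_a,group_b the two classes to compare; each needs at
#'   least 2 genes.
#' @param n_boot bootstrap replicates (>= 1000).
#' @param seed integer seed.
#' @param transform \code{"log2p1"} (default), \code{"log2"} (drops
#'   zero-count genes), or \code{"none"}.
#' @return list of class \code{bootstrap_test}: \code{mean_a},
#'   \code{mean_b} (transformed-scale observed means), \code{diff_obs},
#'   \code{p_value}, \code{boot_means_a}, \code{boot_means_b},
#'   \code{boot_diffs}, plus the settings.
#' @export
bootstrap_group_test <- function(table, group_a = "positive",
                                 group_b = "negative", n_boot = 10000L,
                                 seed = 1L,
                                 transform = c("log2p1", "log2", "none")) {
  transform <- match.arg(transform)
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  df <- as.data.frame(table)
  xa <- df$pv_count[df$class == group_a]
  xb <- df$pv_count[df$class == group_b]
  if (length(xa) == 0 || length(xb) == 0) {
    stop("empty selection class: ",
         if (length(xa) == 0) group_a else group_b)
  }
  if (length(xa) < 2 || length(xb) < 2) {
    stop("each class needs >= 2 genes for resampling")
  }
  tf <- switch(transform,
               log2p1 = function(x) log2(x + 1),
               log2 = function(x) log2(x[x > 0]),
               none = identity)
  ta <- tf(xa); tb <- tf(xb)
  if (length(ta) < 2 || length(tb) < 2) {
    stop("fewer than 2 usable genes after transform")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  ia <- matrix(sample.int(length(ta), n_boot * length(ta), replace = TRUE),
               nrow = n_boot)
  ib <- matrix(sample.int(length(tb), n_boot * length(tb), replace = TRUE),
               nrow = n_boot)
  boot_a <- rowMeans(matrix(ta[ia], nrow = n_boot))
  boot_b <- rowMeans(matrix(tb[ib], nrow = n_boot))
  diffs <- boot_a - boot_b
  p_le <- (sum(diffs <= 0) + 1) / (n_boot + 1)
  p_ge <- (sum(diffs >= 0) + 1) / (n_boot + 1)
  out <- list(mean_a = mean(ta), mean_b = mean(tb),
              diff_obs = mean(ta) - mean(tb),
              p_value = min(1, 2 * min(p_le, p_ge)),
              boot_means_a = boot_a, boot_means_b = boot_b,
              boot_diffs = diffs,
              group_a = group_a, group_b = group_b,
              n_boot = as.integer(n_boot), seed = as.integer(seed),
              transform = transform)
  class(out) <- "bootstrap_test"
  out
}

#' @export
print.bootstrap_test <- function(x, ...) {
  cat(sprintf("Bootstrap group test (%s scale, %d resamples, seed %d)\n",
              x$transform, x$n_boot, x$seed))
  cat(sprintf("  mean(%s) = %.3f, mean(%s) = %.3f, diff = %.3f\n",
              x$group_a, x$mean_a, x$group_b, x$mean_b, x$diff_obs))
  cat(sprintf("  two-sided bootstrap P = %.4g\n", x$p_value))
  invisible(x)
}
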