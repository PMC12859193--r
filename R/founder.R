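#' Parse a founder-variant age specification
#'
#' Haplotype-dated founder-variant ages come in four shapes: a point
#' estimate ("8,675"), a range ("1,500-750", older bound first), a lower
#' bound (">250", i.e. older than 250 BP) or an upper bound ("<200").
#' Thousands separators and en-dashes are normalized before parsing. All
#' values are years before present.
#'
#' @param text character scalar.
#' @return list of class \code{age_spec} with \code{kind} (one of
#'   \code{point, range, lower_bound, upper_bound}) and either
#'   \code{value} or \code{older}/\code{younger}.
#' @export
parse_age <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    stop("empty age specification")
  }
  raw <- text
  s <- trimws(text)
  s <- gsub(",", "", s, fixed = TRUE)
  s <- gsub("–|—", "-", s)        # en/em dash -> hyphen
  num <- "[0-9]+(?:\\.[0-9]+)?"
  spec <- if (grepl(paste0("^>\\s*", num, "$"), s)) {
    list(kind = "lower_bound",
         value = as.numeric(sub("^>\\s*", "", s)))
  } else if (grepl(paste0("^<\\s*", num, "$"), s)) {
    list(kind = "upper_bound",
         value = as.numeric(sub("^<\\s*", "", s)))
  } else if (grepl(paste0("^", num, "\\s*-\\s*", num, "$"), s)) {
    parts <- as.numeric(strsplit(s, "\\s*-\\s*")[[1]])
    if (parts[1] < parts[2]) {
      stop("range must list the older bound first: '", raw, "'")
    }
    list(kind = "range", older = parts[1], younger = parts[2])
  } else if (grepl(paste0("^", num, "$"), s)) {
    list(kind = "point", value = as.numeric(s))
  } else {
    stop("unparseable age specification: '", raw, "'")
  }
  class(spec) <- "age_spec"
  spec
}

#' Format an age specification back to text
#'
#' Inverse of \code{\link{parse_age}} (round-trips for all four kinds);
#' no thousands separators are emitted.
#'
#' @param spec an \code{age_spec}.
#' @return character scalar.
#' @export
format_age <- function(spec) {
  stopifnot(inherits(spec, "age_spec"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  switch(spec$kind,
         point = fmt(spec$value),
         range = paste0(fmt(spec$older), "-", fmt(spec$younger)),
         lower_bound = paste0(">", fmt(spec$value)),
         upper_bound = paste0("<", fmt(spec$value)))
}

#' Representative age of an age specification
#'
#' Single number used for ordering and thresholding: the point value, a
#' range's older bound, or the stated bound for ">x"/"<x". This is the
#' conservative "no younger than stated" reading; \code{midpoint = TRUE}
#' switches ranges to their midpoint for summary statistics.
#'
#' @param spec an \code{age_spec}.
#' @param midpoint use the midpoint of ranges instead of the older bound.
#' @return numeric years BP.
#' @export
representative_age <- function(spec, midpoint = FALSE) {
  stopifnot(inherits(spec, "age_spec"))
  if (spec$kind == "range") {
    if (midpoint) (spec$older + spec$younger) / 2 else spec$older
  } else {
    spec$value
  }
}

#' Read a founder-variant age table
#'
#' TSV with columns \code{gene cdna protein pubmed_id population
#' years_bp}; the \code{years_bp} column holds age specifications in the
#' \code{\link{parse_age}} dialect. The package ships a compiled
#' literature table of haplotype-dated DDR founder variants as
#' \code{system.file("extdata", "founder_ages.tsv", package =
#' "paleoPV")}, read by default.
#'
#' @param path input TSV; default the packaged table.
#' @return data frame of class \code{founder_table} with an added
#'   \code{age_bp} column of representative ages.
#' @export
read_founder_table <- function(path = system.file("extdata",
                                                  "founder_ages.tsv",
                                                  package = "paleoPV")) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  founder_table(df)
}

#' @rdname read_founder_table
#' @param df data frame in the founder-table layout.
#' @export
founder_table <- function(df) {
  required <- c("gene", "cdna", "protein", "pubmed_id", "population",
                "years_bp")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("founder table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required]
  if (any(!nzchar(trimws(df$gene)))) stop("empty gene symbol in founder table")
  specs <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(parse_age(df$years_bp[i]),
             error = function(e) stop("founder record ", i, " (",
                                      df$gene[i], " ", df$cdna[i], "): ",
                                      conditionMessage(e), call. = FALSE))
  })
  df$age_bp <- vapply(specs, representative_age, 1.0)
  attr(df, "age_specs") <- specs
  class(df) <- c("founder_table", "data.frame")
  df
}

#' Oldest founder variant
#'
#' Returns the record with the largest representative age (older bound
#' for ranges, stated bound for one-sided specifications) and that age.
#'
#' @param records a \code{\link{founder_table}}.
#' @return list with \code{record} (one-row data frame) and
#'   \code{age_bp}.
#' @export
oldest_founder <- function(records) {
  df <- as.data.frame(records)
  if (nrow(df) == 0) stop("empty founder table")
  i <- which.max(df$age_bp)
  list(record = df[i, , drop = FALSE], age_bp = df$age_bp[i])
}

#' Partition founder variants by age threshold
#'
#' @param records a \code{\link{founder_table}}.
#' @param threshold_bp positive years BP.
#' @return list with \code{within} (representative age <= threshold) and
#'   \code{exceeding} data frames; the two partition the input.
#' @export
filter_by_age <- function(records, threshold_bp) {
  if (threshold_bp <= 0) stop("threshold_bp must be positive")
  df <- as.data.frame(records)
  within <- df$age_bp <= threshold_bp
  list(within = df[within, , drop = FALSE],
       exceeding = df[!within, , drop = FALSE])
}

#' Intersect a cohort's PVs with population founder lists
#'
#' Counts, per source population, how many of the cohort's PVs are known
#' founder variants of that population, with a per-gene breakdown and a
#' nonredundant grand total (a PV matched in several populations counts
#' once in the total).
#'
#' @param cohort_pvs character vector of \code{pv_id}s carried in the
#'   cohort of interest.
#' @param founder_lists named list: source population -> character
#'   vector of founder \code{pv_id}s.
#' @param gene_map optional named character vector \code{pv_id -> gene}
#'   enabling the per-gene breakdown.
#' @return list of class \code{founder_intersection}: \code{per_population}
#'   (data frame \code{population, n_match}), \code{per_gene} (data frame
#'   \code{gene, n_match}, NULL without \code{gene_map}), \code{matched}
#'   (nonredundant matched ids), \code{total}.
#' @export
founder_intersection <- function(cohort_pvs, founder_lists,
                                 gene_map = NULL) {
  cohort_pvs <- unique(as.character(cohort_pvs))
  if (is.null(names(founder_lists)) && length(founder_lists) > 0) {
    stop("founder_lists must be a named list (population -> pv_id set)")
  }
  per_pop <- data.frame(
    population = names(founder_lists),
    n_match = vapply(founder_lists,
                     function(s) length(intersect(cohort_pvs, s)), 1L),
    row.names = NULL)
  matched <- intersect(cohort_pvs,
                       unique(unlist(founder_lists, use.names = FALSE)))
  per_gene <- NULL
  if (!is.null(gene_map) && length(matched) > 0) {
    genes <- gene_map[matched]
    tab <- table(genes, useNA = "no")
    per_gene <- data.frame(gene = names(tab), n_match = as.integer(tab),
                           row.names = NULL)
    per_gene <- per_gene[order(-per_gene$n_match, per_gene$gene), ,
                         drop = FALSE]
    rownames(per_gene) <- NULL
  } else if (!is.null(gene_map)) {
    per_gene <- data.frame(gene = character(0), n_match = integer(0))
  }
  out <- list(per_population = per_pop, per_gene = per_gene,
              matched = matched, total = length(matched))
  class(out) <- "founder_intersection"
  out
}

#' @export
print.founder_intersection <- function(x, ...) {
  cat("Founder-PV intersection:", x$total, "nonredundant matched PVs\n")
  print(x$per_population, row.names = FALSE)
  if (!is.null(x$per_gene) && nrow(x$per_gene) > 0) {
    cat("By gene:\n")
    print(x$per_gene, row.names = FALSE)
  }
  invisible(x)
}
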