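PATHWAY_CODES <- c("FA", "HR", "MMR", "NER", "NHEJ", "DDR", "BER", "DR")

CLINVAR_CLASSES <- c("Pathogenic", "LikelyPathogenic", "VUS",
                     "LikelyBenign", "Benign")

PATHOGENIC_CLASSES <- c("Pathogenic", "LikelyPathogenic")

CATALOG_COLUMNS <- c("pv_id", "gene", "cdna", "protein", "chrom", "pos",
                     "ref", "alt", "pathways", "classification")

#' Construct a pathogenic-variant catalog
#'
#' A catalog is a data frame with one row per catalogued pathogenic variant
#' (PV): its opaque identifier, gene symbol, HGVS c./p. labels (carried as
#' opaque strings, never parsed), 1-based forward-strand coordinates, the
#' reference and alternate alleles, the set of DNA damage repair (DDR)
#' pathways the gene belongs to, and its clinical classification. Pathway
#' membership is many-to-many: a gene may sit in several pathways, so the
#' \code{pathways} column is a \code{|}-separated string of codes from
#' \code{FA, HR, MMR, NER, NHEJ, DDR, BER, DR}.
#'
#' @param df data frame with columns \code{pv_id, gene, cdna, protein,
#'   chrom, pos, ref, alt, pathways, classification}.
#' @return the validated data frame with class \code{pv_catalog}.
#' @export
pv_catalog <- function(df) {
  missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("catalog is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, CATALOG_COLUMNS]
  for (col in setdiff(CATALOG_COLUMNS, "pos")) df[[col]] <- as.character(df[[col]])
  df$pos <- as.integer(df$pos)
  validate_catalog(df)
  class(df) <- c("pv_catalog", "data.frame")
  df
}

validate_catalog <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  dup <- unique(df$pv_id[duplicated(df$pv_id)])
  if (length(dup) > 0) {
    stop("duplicate pv_id in catalog: ", paste(dup, collapse = ", "))
  }
  issues <- character(0)
  for (i in seq_len(nrow(df))) {
    row_issues <- character(0)
    if (is.na(df$pos[i]) || df$pos[i] < 1) {
      row_issues <- c(row_issues, "pos must be >= 1")
    }
    if (!nzchar(df$ref[i]) || !nzchar(df$alt[i])) {
      row_issues <- c(row_issues, "empty allele")
    } else {
      if (df$ref[i] == df$alt[i]) {
        row_issues <- c(row_issues, "ref equals alt")
      }
      if (grepl("[^ACGTN-]", df$ref[i]) || grepl("[^ACGTN-]", df$alt[i])) {
        row_issues <- c(row_issues, "non-nucleotide allele characters")
      }
    }
    if (!df$classification[i] %in% CLINVAR_CLASSES) {
      row_issues <- c(row_issues,
                      paste0("unknown classification '", df$classification[i], "'"))
    }
    codes <- pathway_codes(df$pathways[i])
    if (length(codes) == 0) {
      row_issues <- c(row_issues, "empty pathway set")
    } else if (!all(codes %in% PATHWAY_CODES)) {
      row_issues <- c(row_issues,
                      paste0("unknown pathway code(s): ",
                             paste(setdiff(codes, PATHWAY_CODES), collapse = ",")))
    }
    if (length(row_issues) > 0) {
      issues <- c(issues, paste0("record ", i, " (", df$pv_id[i], "): ",
                                 paste(row_issues, collapse = "; ")))
    }
  }
  if (length(issues) > 0) {
    stop("malformed catalog record(s):\n  ", paste(issues, collapse = "\n  "))
  }
  invisible(df)
}

pathway_codes <- function(x) {
  codes <- strsplit(x, "|", fixed = TRUE)[[1]]
  codes[nzchar(codes)]
}

#' Read a PV catalog from TSV or VCF
#'
#' The TSV dialect has header \code{pv_id gene cdna protein chrom pos ref
#' alt pathways classification} with \code{|}-separated pathway codes. The
#' VCF dialect carries \code{GENE}, \code{PATHWAYS} and \code{CLNSIG} INFO
#' keys and uses the VCF ID column as \code{pv_id}. Coordinates are 1-based
#' on the forward strand in both dialects.
#'
#' By default only records classified \code{Pathogenic} or
#' \code{LikelyPathogenic} are retained, in file order.
#'
#' @param path input file.
#' @param format \code{"tsv"} or \code{"vcf"}; guessed from the extension
#'   when omitted.
#' @param keep_all_classes retain benign/VUS records too.
#' @return a \code{\link{pv_catalog}}.
#' @export
read_catalog <- function(path, format = c("auto", "tsv", "vcf"),
                         keep_all_classes = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  df <- if (format == "vcf") read_catalog_vcf(path) else read_catalog_tsv(path)
  if (!keep_all_classes && nrow(df) > 0) {
    df <- df[df$classification %in% PATHOGENIC_CLASSES, , drop = FALSE]
    rownames(df) <- NULL
  }
  pv_catalog(df)
}

read_catalog_tsv <- function(path) {
  utils::read.delim(path, colClasses = "character", check.names = FALSE)
}

read_catalog_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(stats::setNames(
      as.data.frame(matrix(character(0), ncol = length(CATALOG_COLUMNS))),
      CATALOG_COLUMNS))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 8)
  if (length(bad) > 0) {
    stop("malformed VCF record at data line ", bad[1],
         ": fewer than 8 columns")
  }
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
    if (length(m) < 2) "" else m[2]
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    info <- f[8]
    data.frame(pv_id = f[3], gene = info_get(info, "GENE"),
               cdna = info_get(info, "CDNA"),
               protein = info_get(info, "PROTEIN"),
               chrom = f[1], pos = f[2], ref = f[4], alt = f[5],
               pathways = info_get(info, "PATHWAYS"),
               classification = info_get(info, "CLNSIG"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a PV catalog
#'
#' Writes the catalog TSV dialect (or the VCF dialect with GENE/PATHWAYS/
#' CLNSIG INFO keys). \code{read_catalog(write_catalog(x), keep_all_classes
#' = TRUE)} reproduces the records field for field.
#'
#' @param catalog a \code{\link{pv_catalog}}.
#' @param path output file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @export
write_catalog <- function(catalog, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(catalog)[, CATALOG_COLUMNS], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    header <- c("##fileformat=VCFv4.2",
                "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
                "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS c.\">",
                "##INFO=<ID=PROTEIN,Number=1,Type=String,Description=\"HGVS p.\">",
                "##INFO=<ID=PATHWAYS,Number=1,Type=String,Description=\"Pipe-separated pathway codes\">",
                "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"Clinical classification\">",
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- paste0("GENE=", catalog$gene, ";CDNA=", catalog$cdna,
                   ";PROTEIN=", catalog$protein,
                   ";PATHWAYS=", catalog$pathways,
                   ";CLNSIG=", catalog$classification)
    body <- paste(catalog$chrom, catalog$pos, catalog$pv_id, catalog$ref,
                  catalog$alt, ".", ".", info, sep = "\t")
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Read a cohort carrier table
#'
#' Long-format TSV with one row per (individual, carried PV): columns
#' \code{ind_id cohort date_bp region pv_id zygosity}. \code{date_bp} is
#' years before present and may be empty (undated individuals); zygosity is
#' \code{het}, \code{hom} or \code{present_unknown}.
#'
#' @param path input TSV.
#' @param catalog optional \code{\link{pv_catalog}}; if given, carried
#'   \code{pv_id}s absent from the catalog are a hard error.
#' @return data frame of class \code{carrier_table}.
#' @export
read_carriers <- function(path, catalog = NULL) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  carrier_table(df, catalog = catalog)
}

#' @rdname read_carriers
#' @param df data frame in the carrier-table layout.
#' @export
carrier_table <- function(df, catalog = NULL) {
  required <- c("ind_id", "cohort", "date_bp", "region", "pv_id", "zygosity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("carrier table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required]
  df$date_bp <- suppressWarnings(as.numeric(df$date_bp))
  bad_cohort <- setdiff(unique(df$cohort),
                        c("ancient", "neanderthal", "denisovan",
                          "modern_african", "modern_nonafrican"))
  if (length(bad_cohort) > 0) {
    stop("unknown cohort label(s): ", paste(bad_cohort, collapse = ", "))
  }
  bad_zyg <- setdiff(unique(df$zygosity), c("het", "hom", "present_unknown"))
  if (length(bad_zyg) > 0) {
    stop("unknown zygosity value(s): ", paste(bad_zyg, collapse = ", "))
  }
  if (any(!is.na(df$date_bp) & df$date_bp < 0)) {
    stop("negative date_bp in carrier table")
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(df$pv_id), catalog$pv_id)
    if (length(unknown) > 0) {
      stop("carried pv_id(s) not in catalog: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  class(df) <- c("carrier_table", "data.frame")
  df
}

#' Write a carrier table
#' @param carriers a \code{carrier_table}.
#' @param path output TSV.
#' @export
write_carriers <- function(carriers, path) {
  df <- as.data.frame(carriers)
  df$date_bp <- ifelse(is.na(df$date_bp), "", format(df$date_bp, trim = TRUE,
                                                     scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count PVs per gene and per pathway
#'
#' Produces the nonredundant per-gene counts and the per-pathway rollup. A
#' PV belongs to exactly one gene, but a gene may belong to several
#' pathways, so a PV is counted once per pathway it belongs to and pathway
#' totals may exceed the nonredundant total.
#'
#' @param catalog a \code{\link{pv_catalog}}.
#' @param restrict_to optional character vector of \code{pv_id}s to count
#'   (e.g. the set observed in a cohort); must be a subset of the catalog.
#' @return list of class \code{pv_count_table} with \code{per_gene} (named
#'   integer vector), \code{per_pathway} (data frame \code{pathway,
#'   genes_with_pv, pv_count}) and \code{total_nonredundant}.
#' @export
count_by_gene_and_pathway <- function(catalog, restrict_to = NULL) {
  stopifnot(inherits(catalog, "pv_catalog"))
  df <- as.data.frame(catalog)
  if (!is.null(restrict_to)) {
    extra <- setdiff(restrict_to, df$pv_id)
    if (length(extra) > 0) {
      stop("restrict_to contains pv_id(s) not in catalog: ",
           paste(utils::head(extra, 5), collapse = ", "))
    }
    df <- df[df$pv_id %in% restrict_to, , drop = FALSE]
  }
  per_gene <- if (nrow(df) == 0) {
    stats::setNames(integer(0), character(0))
  } else {
    tab <- table(df$gene)
    stats::setNames(as.integer(tab), names(tab))
  }
  rows <- lapply(PATHWAY_CODES, function(pw) {
    if (nrow(df) == 0) {
      return(data.frame(pathway = pw, genes_with_pv = 0L, pv_count = 0L))
    }
    in_pw <- vapply(df$pathways, function(p) pw %in% pathway_codes(p), TRUE)
    data.frame(pathway = pw,
               genes_with_pv = length(unique(df$gene[in_pw])),
               pv_count = sum(in_pw))
  })
  out <- list(per_gene = per_gene,
              per_pathway = do.call(rbind, rows),
              total_nonredundant = nrow(df))
  class(out) <- "pv_count_table"
  out
}

#' @export
print.pv_count_table <- function(x, ...) {
  cat("PV count table:", x$total_nonredundant, "nonredundant PVs in",
      length(x$per_gene), "genes\n")
  print(x$per_pathway, row.names = FALSE)
  invisible(x)
}
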