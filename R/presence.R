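#' Presence-caller configuration
#'
#' Thresholds for the ancient-DNA damage-aware presence caller. Ancient
#' libraries are low coverage, so the defaults are deliberately permissive
#' on depth while guarding against the two dominant aDNA artifacts:
#' post-mortem deamination (C->T on the forward strand, G->A on the
#' reverse, concentrated at fragment ends) and PCR duplicates.
#'
#' @param terminal_trim drop observations within this many bases of either
#'   read end (deamination is concentrated there).
#' @param min_base_qual,min_map_qual Phred thresholds.
#' @param min_alt_reads alternate-allele reads required to call a PV
#'   present when the support cannot be a deamination artifact.
#' @param min_alt_reads_damage stricter requirement applied when all
#'   alternate support is damage-consistent on its strand.
#' @param min_depth surviving depth required to call a site absent.
#' @param min_zyg_reads per-allele reads required to assign zygosity.
#' @param auto_filter run \code{\link{filter_observations}} inside
#'   \code{\link{call_presence}}.
#' @return list of class \code{caller_config}.
#' @export
caller_config <- function(terminal_trim = 2L, min_base_qual = 20L,
                          min_map_qual = 30L, min_alt_reads = 1L,
                          min_alt_reads_damage = 2L, min_depth = 1L,
                          min_zyg_reads = 2L, auto_filter = TRUE) {
  cfg <- list(terminal_trim = as.integer(terminal_trim),
              min_base_qual = as.integer(min_base_qual),
              min_map_qual = as.integer(min_map_qual),
              min_alt_reads = as.integer(min_alt_reads),
              min_alt_reads_damage = as.integer(min_alt_reads_damage),
              min_depth = as.integer(min_depth),
              min_zyg_reads = as.integer(min_zyg_reads),
              auto_filter = isTRUE(auto_filter))
  stopifnot(all(vapply(cfg[1:7], function(x) x >= 0, TRUE)))
  class(cfg) <- "caller_config"
  cfg
}

PILEUP_COLUMNS <- c("ind_id", "pv_id", "read_id", "base", "base_qual",
                    "map_qual", "dist5", "dist3", "strand",
                    "frag_start", "frag_end")

#' Read a pileup table of read observations at PV sites
#'
#' TSV dialect: \code{ind_id pv_id read_id base base_qual map_qual dist5
#' dist3 strand frag_start frag_end}. One row per read overlapping a PV
#' site; \code{dist5}/\code{dist3} are 0-based distances of the site from
#' the read's 5' and 3' ends, and (\code{frag_start}, \code{frag_end},
#' \code{strand}) identify the source fragment for duplicate collapse
#' (aDNA libraries have no UMIs). For indel PVs \code{base} carries the
#' full observed allele string.
#'
#' @param path input TSV.
#' @return data frame of class \code{pileup_table}.
#' @export
read_pileup <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  pileup_table(df)
}

#' @rdname read_pileup
#' @param df data frame in the pileup layout.
#' @export
pileup_table <- function(df) {
  missing_cols <- setdiff(PILEUP_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("pileup missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, PILEUP_COLUMNS]
  for (col in c("base_qual", "map_qual", "dist5", "dist3",
                "frag_start", "frag_end")) {
    df[[col]] <- as.integer(df[[col]])
  }
  if (any(df$dist5 < 0 | df$dist3 < 0, na.rm = TRUE)) {
    stop("negative read-end distances in pileup")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("pileup_table", "data.frame")
  df
}

#' Quality-filter read observations at a PV site
#'
#' Applies the standard aDNA quality steps: excludes terminal bases
#' (within \code{terminal_trim} of either read end), drops observations
#' below the base/mapping quality thresholds, and collapses duplicates
#' sharing a (fragment start, fragment end, strand) key, keeping the
#' highest base quality (first occurrence on ties). Output order follows
#' input order.
#'
#' @param site data frame of observations (pileup layout, one site).
#' @param cfg a \code{\link{caller_config}}.
#' @return the surviving observations.
#' @export
filter_observations <- function(site, cfg = caller_config()) {
  df <- as.data.frame(site)
  if (nrow(df) == 0) return(df)
  keep <- df$dist5 >= cfg$terminal_trim & df$dist3 >= cfg$terminal_trim &
    df$base_qual >= cfg$min_base_qual & df$map_qual >= cfg$min_map_qual
  df <- df[keep, , drop = FALSE]
  if (nrow(df) <= 1) { rownames(df) <- NULL; return(df) }
  key <- paste(df$frag_start, df$frag_end, df$strand, sep = ":")
  best <- rep(FALSE, nrow(df))
  for (k in unique(key)) {
    idx <- which(key == k)
    best[idx[which.max(df$base_qual[idx])]] <- TRUE
  }
  df <- df[best, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Could an alternate-allele observation be a deamination artifact?
#'
#' Post-mortem cytosine deamination produces apparent C->T substitutions
#' on the strand carrying the C, observed as C->T on forward-strand reads
#' and G->A on reverse-strand reads. An alternate-supporting read is
#' damage-consistent when its (ref, alt, strand) combination matches one
#' of those two signatures; only SNVs are eligible.
#'
#' @param ref,alt reference and alternate alleles of the PV.
#' @param strand read strand, \code{"+"} or \code{"-"} (vectorized).
#' @return logical vector.
#' @export
is_damage_consistent <- function(ref, alt, strand) {
  (ref == "C" & alt == "T" & strand == "+") |
    (ref == "G" & alt == "A" & strand == "-")
}

#' Call PV presence in one ancient individual from read evidence
#'
#' Decides present / absent / uncallable for a known pathogenic variant
#' from the surviving read observations, instead of de-novo genotyping:
#' the catalog supplies the expected ref and alt alleles and the caller
#' only asks whether the alternate allele is credibly observed.
#'
#' A site is \code{present} when alternate support reaches
#' \code{min_alt_reads} -- or \code{min_alt_reads_damage} when every
#' alternate read is deamination-consistent on its strand (alternate
#' support on both strands can never be pure deamination, so
#' double-stranded support always counts as real evidence);
#' \code{absent} when surviving depth reaches \code{min_depth} with zero
#' alternate support; \code{uncallable} otherwise. Observations matching
#' neither allele are excluded from both supports and reported in
#' \code{n_other}. Zygosity (for present calls): \code{het} when both
#' alleles have \code{min_zyg_reads} support, \code{hom} when only the
#' alternate does and the reference has none, else
#' \code{present_unknown}.
#'
#' @param pv single-row \code{\link{pv_catalog}} slice (or list with
#'   \code{pv_id}, \code{ref}, \code{alt}).
#' @param site observations for one (individual, PV site).
#' @param cfg a \code{\link{caller_config}}.
#' @return one-row data frame: \code{ind_id pv_id call zygosity n_alt
#'   n_ref n_other damage_flagged}.
#' @export
call_presence <- function(pv, site, cfg = caller_config()) {
  df <- as.data.frame(site)
  ind_id <- if (nrow(df) > 0) df$ind_id[1] else NA_character_
  if (cfg$auto_filter) df <- filter_observations(df, cfg)
  n_alt <- sum(df$base == pv$alt)
  n_ref <- sum(df$base == pv$ref)
  n_other <- nrow(df) - n_alt - n_ref
  depth <- n_alt + n_ref
  alt_obs <- df[df$base == pv$alt, , drop = FALSE]
  damage_flagged <- n_alt > 0 &&
    all(is_damage_consistent(pv$ref, pv$alt, alt_obs$strand))
  required_alt <- if (damage_flagged) cfg$min_alt_reads_damage else cfg$min_alt_reads
  if (n_alt >= required_alt && n_alt > 0) {
    call <- "present"
    zygosity <- if (n_alt >= cfg$min_zyg_reads && n_ref >= cfg$min_zyg_reads) {
      "het"
    } else if (n_alt >= cfg$min_zyg_reads && n_ref == 0) {
      "hom"
    } else {
      "present_unknown"
    }
  } else if (depth >= cfg$min_depth && n_alt == 0) {
    call <- "absent"
    zygosity <- "na"
  } else {
    call <- "uncallable"
    zygosity <- "na"
  }
  data.frame(ind_id = ind_id, pv_id = pv$pv_id, call = call,
             zygosity = zygosity, n_alt_support = n_alt,
             n_ref_support = n_ref, n_other = n_other,
             damage_flagged = damage_flagged, stringsAsFactors = FALSE)
}

#' Call presence for every (individual, PV) pair in a pileup
#'
#' @param pileup a \code{\link{pileup_table}} covering any number of
#'   individuals and sites.
#' @param catalog a \code{\link{pv_catalog}}; every \code{pv_id} in the
#'   pileup must be catalogued.
#' @param cfg a \code{\link{caller_config}}.
#' @return data frame of presence calls, one row per (ind_id, pv_id) seen.
#' @export
call_presence_all <- function(pileup, catalog, cfg = caller_config()) {
  df <- as.data.frame(pileup)
  unknown <- setdiff(unique(df$pv_id), catalog$pv_id)
  if (length(unknown) > 0) {
    stop("pileup pv_id(s) not in catalog: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  key <- paste(df$ind_id, df$pv_id, sep = "\r")
  groups <- split(seq_len(nrow(df)), key)
  calls <- lapply(groups, function(idx) {
    site <- df[idx, , drop = FALSE]
    pv <- as.data.frame(catalog)[match(site$pv_id[1], catalog$pv_id), ]
    call_presence(pv, site, cfg)
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$ind_id, out$pv_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write presence calls to TSV
#' @param calls output of \code{\link{call_presence_all}}.
#' @param path output file.
#' @export
write_presence_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
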