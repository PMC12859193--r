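#' Default clade ordering, closest to most distal from humans
#'
#' The eight vertebrate clades used to summarize cross-species sharing,
#' ranked by divergence from humans: rank 1 is Primate (closest), rank 8
#' is Fish (most distal). Overridable wherever a clade ranking is taken.
#' @export
DEFAULT_CLADE_RANKS <- c(Primate = 1L, Euarchontoglires = 2L,
                         Laurasiatheria = 3L, Afrotheria = 4L,
                         Mammalia = 5L, Aves = 6L, Sarcopterygii = 7L,
                         Fish = 8L)

#' Read a species allele table
#'
#' TSV with columns \code{pv_id species clade allele}: the allele
#' observed in each species at the position orthologous to each human
#' PV. A missing orthologous position (gene or alignment absent in that
#' species) is encoded as \code{.} or an empty allele.
#'
#' @param path input TSV.
#' @return data frame with class \code{species_allele_table}.
#' @export
read_species_alleles <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  species_allele_table(df)
}

#' @rdname read_species_alleles
#' @param df data frame in the species-allele layout.
#' @export
species_allele_table <- function(df) {
  required <- c("pv_id", "species", "clade", "allele")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("species allele table missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, required]
  sp_clades <- unique(df[, c("species", "clade")])
  dup_sp <- unique(sp_clades$species[duplicated(sp_clades$species)])
  if (length(dup_sp) > 0) {
    stop("species assigned to more than one clade: ",
         paste(dup_sp, collapse = ", "))
  }
  class(df) <- c("species_allele_table", "data.frame")
  df
}

#' Project human PVs onto species and match alleles
#'
#' A human PV is shared with a species when that species' observed allele
#' at the orthologous position equals the human alternate (pathogenic)
#' allele. A missing allele scores "not shared" but is tracked separately,
#' so absence of data is distinguishable from presence of the reference
#' allele. For each PV the nearest shared clade is the minimum clade rank
#' (closest to humans) among the species sharing it.
#'
#' @param catalog a \code{\link{pv_catalog}}.
#' @param table a \code{\link{species_allele_table}}; keys outside the
#'   catalog raise a warning and are dropped.
#' @param clade_ranks named integer vector ordering clades by divergence
#'   from humans (1 = closest); defaults to
#'   \code{\link{DEFAULT_CLADE_RANKS}}.
#' @return list of class \code{sharing_matrix}: \code{shared} and
#'   \code{missing} logical PV x species matrices, \code{species} (data
#'   frame \code{species, clade, clade_rank}), \code{nearest_clade}
#'   (character, per PV, NA when unshared), and \code{clade_ranks}.
#' @export
project_and_match <- function(catalog, table,
                              clade_ranks = DEFAULT_CLADE_RANKS) {
  stopifnot(inherits(catalog, "pv_catalog"))
  tab <- as.data.frame(table)
  unknown <- setdiff(unique(tab$pv_id), catalog$pv_id)
  if (length(unknown) > 0) {
    warning("species table keys not in catalog (dropped): ",
            paste(utils::head(unknown, 5), collapse = ", "))
    tab <- tab[tab$pv_id %in% catalog$pv_id, , drop = FALSE]
  }
  unknown_clade <- setdiff(unique(tab$clade), names(clade_ranks))
  if (length(unknown_clade) > 0) {
    stop("clade(s) without a rank: ", paste(unknown_clade, collapse = ", "))
  }
  pv_ids <- catalog$pv_id
  sp_info <- unique(tab[, c("species", "clade")])
  sp_info <- sp_info[order(clade_ranks[sp_info$clade], sp_info$species), ,
                     drop = FALSE]
  sp_info$clade_rank <- as.integer(clade_ranks[sp_info$clade])
  rownames(sp_info) <- NULL
  species <- sp_info$species
  shared <- matrix(FALSE, length(pv_ids), length(species),
                   dimnames = list(pv_ids, species))
  miss <- matrix(TRUE, length(pv_ids), length(species),
                 dimnames = list(pv_ids, species))
  if (nrow(tab) > 0) {
    i <- match(tab$pv_id, pv_ids)
    j <- match(tab$species, species)
    has_allele <- nzchar(tab$allele) & tab$allele != "."
    miss[cbind(i, j)] <- !has_allele
    alt <- catalog$alt[i]
    shared[cbind(i, j)] <- has_allele & tab$allele == alt
  }
  nearest <- apply(shared, 1, function(row) {
    hit <- which(row)
    if (length(hit) == 0) return(NA_character_)
    sp_info$clade[hit[which.min(sp_info$clade_rank[hit])]]
  })
  out <- list(shared = shared, missing = miss, species = sp_info,
              nearest_clade = nearest, clade_ranks = clade_ranks)
  class(out) <- "sharing_matrix"
  out
}

#' Summarize cross-species sharing by clade
#'
#' Reports how many human PVs are absent from every surveyed species (and
#' the percentage), how many are shared with at least one, the per-clade
#' species-hit totals and per-clade counts of PVs whose nearest shared
#' clade it is, plus per-species shared counts.
#'
#' @param matrix a \code{sharing_matrix} from
#'   \code{\link{project_and_match}}.
#' @return list of class \code{clade_summary}: \code{n_pvs},
#'   \code{n_absent}, \code{absent_percent}, \code{n_shared},
#'   \code{per_clade} (data frame \code{clade, clade_rank, n_species,
#'   species_hits, pvs_shared, pvs_nearest}), \code{per_species} (data
#'   frame \code{species, clade, n_shared}).
#' @export
clade_summary <- function(matrix) {
  stopifnot(inherits(matrix, "sharing_matrix"))
  if (nrow(matrix$shared) == 0) stop("empty sharing matrix")
  any_shared <- rowSums(matrix$shared) > 0
  n_pvs <- nrow(matrix$shared)
  n_absent <- sum(!any_shared)
  sp <- matrix$species
  per_species <- data.frame(species = sp$species, clade = sp$clade,
                            n_shared = colSums(matrix$shared),
                            row.names = NULL)
  clades <- unique(sp$clade)
  per_clade <- do.call(rbind, lapply(clades, function(cl) {
    cols <- sp$species[sp$clade == cl]
    sub <- matrix$shared[, cols, drop = FALSE]
    data.frame(clade = cl,
               clade_rank = as.integer(matrix$clade_ranks[cl]),
               n_species = length(cols),
               species_hits = sum(sub),
               pvs_shared = sum(rowSums(sub) > 0),
               pvs_nearest = sum(matrix$nearest_clade == cl, na.rm = TRUE))
  }))
  per_clade <- per_clade[order(per_clade$clade_rank), , drop = FALSE]
  rownames(per_clade) <- NULL
  out <- list(n_pvs = n_pvs, n_absent = n_absent,
              absent_percent = round_half_up(100 * n_absent / n_pvs, 1),
              n_shared = n_pvs - n_absent,
              per_clade = per_clade, per_species = per_species)
  class(out) <- "clade_summary"
  out
}

#' @export
print.clade_summary <- function(x, ...) {
  cat(sprintf("Cross-species sharing: %d PVs, %d (%.1f%%) absent in all species, %d shared\n",
              x$n_pvs, x$n_absent, x$absent_percent, x$n_shared))
  print(x$per_clade, row.names = FALSE)
  invisible(x)
}

#' Per-species sharing report within one clade
#'
#' For a focal clade (e.g. Primate), reports each species' shared-PV
#' count as count and percentage of the PVs shared with any species of
#' that clade.
#'
#' @param matrix a \code{sharing_matrix}.
#' @param clade clade name.
#' @return data frame \code{species, n_shared, percent_of_clade_shared},
#'   plus attribute \code{clade_shared} (PVs shared with >= 1 species of
#'   the clade).
#' @export
clade_species_report <- function(matrix, clade) {
  sp <- matrix$species
  cols <- sp$species[sp$clade == clade]
  if (length(cols) == 0) stop("no species in clade: ", clade)
  sub <- matrix$shared[, cols, drop = FALSE]
  clade_shared <- sum(rowSums(sub) > 0)
  out <- data.frame(species = cols, n_shared = colSums(sub),
                    row.names = NULL)
  out$percent_of_clade_shared <- if (clade_shared > 0) {
    round_half_up(100 * out$n_shared / clade_shared, 1)
  } else {
    NA_real_
  }
  attr(out, "clade_shared") <- clade_shared
  out
}
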