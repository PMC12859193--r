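# Independent brute-force re-implementations used as oracles. These are
# deliberately written as plain loops over definitions, sharing no code
# with the package internals they check.

oracle_filter <- function(obs, cfg) {
  survivors <- list()
  seen_keys <- character(0)
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, ]
    if (o$dist5 < cfg$terminal_trim) next
    if (o$dist3 < cfg$terminal_trim) next
    if (o$base_qual < cfg$min_base_qual) next
    if (o$map_qual < cfg$min_map_qual) next
    survivors[[length(survivors) + 1]] <- o
  }
  if (length(survivors) == 0) return(obs[0, ])
  surv <- do.call(rbind, survivors)
  keep <- rep(TRUE, nrow(surv))
  key <- paste(surv$frag_start, surv$frag_end, surv$strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      best <- idx[1]
      for (j in idx) if (surv$base_qual[j] > surv$base_qual[best]) best <- j
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  out <- surv[keep, ]
  rownames(out) <- NULL
  out
}

oracle_venn <- function(ancient, african, nonafrican) {
  res <- list(only_nonafrican = character(0), both = character(0),
              only_african = character(0), neither = character(0))
  for (pv in unique(ancient)) {
    a <- FALSE; n <- FALSE
    for (x in african) if (x == pv) a <- TRUE
    for (x in nonafrican) if (x == pv) n <- TRUE
    slot <- if (a && n) "both" else if (n) "only_nonafrican"
            else if (a) "only_african" else "neither"
    res[[slot]] <- c(res[[slot]], pv)
  }
  res
}

oracle_count_table <- function(catalog, restrict_to = NULL) {
  df <- as.data.frame(catalog)
  if (!is.null(restrict_to)) df <- df[df$pv_id %in% restrict_to, ]
  genes <- sort(unique(df$gene))
  per_gene <- integer(0)
  for (g in genes) per_gene[g] <- sum(df$gene == g)
  pw_counts <- list()
  for (pw in c("FA", "HR", "MMR", "NER", "NHEJ", "DDR", "BER", "DR")) {
    n_pv <- 0; gset <- character(0)
    for (i in seq_len(nrow(df))) {
      codes <- strsplit(df$pathways[i], "|", fixed = TRUE)[[1]]
      if (pw %in% codes) {
        n_pv <- n_pv + 1
        gset <- union(gset, df$gene[i])
      }
    }
    pw_counts[[pw]] <- c(genes = length(gset), pvs = n_pv)
  }
  list(per_gene = per_gene, per_pathway = pw_counts, total = nrow(df))
}

oracle_project <- function(catalog, table) {
  tab <- as.data.frame(table)
  shared <- list()
  for (i in seq_len(nrow(catalog))) {
    for (j in seq_len(nrow(tab))) {
      if (tab$pv_id[j] == catalog$pv_id[i] &&
          nzchar(tab$allele[j]) && tab$allele[j] != "." &&
          tab$allele[j] == catalog$alt[i]) {
        shared[[length(shared) + 1]] <- c(catalog$pv_id[i], tab$species[j])
      }
    }
  }
  shared
}

oracle_oldest <- function(df) {
  best <- 1
  for (i in seq_len(nrow(df))) {
    if (df$age_bp[i] > df$age_bp[best]) best <- i
  }
  best
}

oracle_intersection <- function(cohort, lists) {
  per_pop <- integer(0)
  matched <- character(0)
  for (pop in names(lists)) {
    n <- 0
    for (pv in unique(cohort)) {
      if (pv %in% lists[[pop]]) {
        n <- n + 1
        matched <- union(matched, pv)
      }
    }
    per_pop[pop] <- n
  }
  list(per_pop = per_pop, total = length(matched))
}
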