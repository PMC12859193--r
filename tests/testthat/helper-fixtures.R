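# Small in-code fixture builders shared across the suite.

make_catalog <- function(n = 6, genes = NULL, pathways = NULL,
                         ref = NULL, alt = NULL, classification = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", ((seq_len(n) - 1) %% 3) + 1)
  if (is.null(pathways)) pathways <- rep("HR", n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(classification)) classification <- rep("Pathogenic", n)
  pv_catalog(data.frame(
    pv_id = sprintf("pv%03d", seq_len(n)),
    gene = genes,
    cdna = sprintf("c.%d%s>%s", seq_len(n) * 10, ref, alt),
    protein = sprintf("p.X%dY", seq_len(n)),
    chrom = "chr1",
    pos = seq_len(n) * 100,
    ref = ref, alt = alt,
    pathways = pathways,
    classification = classification,
    stringsAsFactors = FALSE))
}

make_obs <- function(n = 1, base = "G", base_qual = 35L, map_qual = 60L,
                     dist5 = 10L, dist3 = 10L, strand = "+",
                     frag_start = NULL, frag_end = NULL,
                     ind_id = "IND1", pv_id = "pv001") {
  if (n == 0) {
    return(make_obs(1)[0, ])
  }
  if (is.null(frag_start)) frag_start <- 1000L + seq_len(n)
  if (is.null(frag_end)) frag_end <- frag_start + 59L
  data.frame(ind_id = ind_id, pv_id = pv_id,
             read_id = sprintf("r%03d", seq_len(n)),
             base = base, base_qual = as.integer(base_qual),
             map_qual = as.integer(map_qual),
             dist5 = as.integer(dist5), dist3 = as.integer(dist3),
             strand = strand, frag_start = as.integer(frag_start),
             frag_end = as.integer(frag_end),
             stringsAsFactors = FALSE)
}

make_carriers <- function(ind_id, pv_id, date_bp = NA_real_,
                          cohort = "ancient", zygosity = "het",
                          region = "TestRegion") {
  carrier_table(data.frame(ind_id = ind_id, cohort = cohort,
                           date_bp = date_bp, region = region,
                           pv_id = pv_id, zygosity = zygosity,
                           stringsAsFactors = FALSE))
}

random_obs <- function(n, seed) {
  set.seed(seed)
  make_obs(n,
           base = sample(c("A", "C", "G", "T"), n, replace = TRUE),
           base_qual = sample(2:41, n, replace = TRUE),
           map_qual = sample(0:60, n, replace = TRUE),
           dist5 = sample(0:30, n, replace = TRUE),
           dist3 = sample(0:30, n, replace = TRUE),
           strand = sample(c("+", "-"), n, replace = TRUE),
           frag_start = sample(1000:1010, n, replace = TRUE),
           frag_end = sample(1060:1070, n, replace = TRUE))
}
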