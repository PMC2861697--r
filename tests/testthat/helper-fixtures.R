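# In-code fixture builders shared across the test files.

# TSS table from parallel vectors.
make_tss <- function(gene_id, pos, strand = "+", chrom = "chr1") {
  data.frame(gene_id = gene_id, chrom = chrom, tss_pos = as.integer(pos),
             strand = rep_len(strand, length(gene_id)), stringsAsFactors = FALSE)
}

# Site table; `mid` gives 1-based midpoints, sites are 201 bp wide so the
# midpoint convention floor((start+end)/2)+1 lands exactly on `mid`.
make_sites <- function(mid, chrom = "chr1", tissue = "liver", id = NULL,
                       regulators = NULL, enrichment = NA_real_,
                       conservation = NA_real_) {
  n <- length(mid)
  df <- data.frame(site_id = id %||% sprintf("s%03d", seq_len(n)),
                   chrom = rep_len(chrom, n),
                   start = as.integer(mid - 101L), end = as.integer(mid + 100L),
                   tissue = rep_len(tissue, n),
                   enrichment = rep_len(enrichment, n),
                   conservation = rep_len(conservation, n),
                   stringsAsFactors = FALSE)
  df$regulators <- regulators %||% rep(list(character()), n)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small synthetic study reused by several files.
small_study <- function(n_genes = 300, seed = 11, ...) {
  spec <- synthetic_spec(n_genes = n_genes, ...)
  simulate_study(spec, seed = seed)
}

# Dense conservation track from a per-base score vector starting at base 1.
make_track <- function(scores, chrom = "chr1") {
  structure(list(scores = stats::setNames(list(as.numeric(scores)), chrom),
                 offset = stats::setNames(1L, chrom)),
            class = "conservation_track")
}
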