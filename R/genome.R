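# Genome-side domain objects and geometry.
#
# Coordinate conventions (used everywhere in the package):
#   * binding sites are BED-style 0-based half-open intervals [start, end);
#   * TSS positions are 1-based base positions;
#   * a site's reference point is its midpoint, floor((start + end) / 2) in
#     0-based coordinates, converted to 1-based by adding 1;
#   * signed distance d = (midpoint - tss) in transcription direction:
#     negative upstream of the TSS, positive downstream; on the - strand the
#     genomic difference is negated.

site_midpoint <- function(start, end) as.integer(floor((start + end) / 2) + 1L)

validate_tss <- function(tss) {
  req <- c("gene_id", "chrom", "tss_pos", "strand")
  miss <- setdiff(req, names(tss))
  if (length(miss)) stopf("TSS table missing column(s): %s", paste(miss, collapse = ", "))
  if (anyNA(tss$tss_pos) || any(tss$tss_pos < 1))
    stopf("tss_pos must be integer >= 1")
  bad <- !tss$strand %in% c("+", "-")
  if (any(bad)) stopf("invalid strand value(s): %s", paste(unique(tss$strand[bad]), collapse = ", "))
  dup <- tss$gene_id[duplicated(tss$gene_id)]
  if (length(dup)) stopf("duplicate gene_id: %s", paste(unique(dup), collapse = ", "))
  tss
}

validate_sites <- function(sites) {
  req <- c("site_id", "chrom", "start", "end", "tissue")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stopf("site table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(sites$start >= sites$end))
    stopf("binding site with start >= end: %s",
          paste(sites$site_id[sites$start >= sites$end], collapse = ", "))
  if (!is.null(sites$enrichment) && any(!is.na(sites$enrichment) & sites$enrichment <= 0))
    stopf("enrichment must be > 0 when present")
  if (!is.null(sites$conservation)) {
    cs <- sites$conservation
    if (any(!is.na(cs) & (cs < 0 | cs > 1))) stopf("conservation must lie in [0, 1]")
  }
  sites
}

# Canonical empty site table; regulators is a list column of character vectors.
empty_sites <- function() {
  df <- data.frame(site_id = character(), chrom = character(),
                   start = integer(), end = integer(), tissue = character(),
                   enrichment = numeric(), conservation = numeric(),
                   stringsAsFactors = FALSE)
  df$regulators <- list()
  df
}

#' Read a TSS annotation table
#'
#' Reads a tab-separated file with header columns \code{gene_id},
#' \code{chrom}, \code{pos} (1-based TSS position) and \code{strand}
#' (\code{+}/\code{-}). Each \code{gene_id} (typically one array probe set,
#' treated as an independent gene) must be unique.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss_pos}, \code{strand}.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  req <- c("gene_id", "chrom", "pos", "strand")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stopf("TSS table missing column(s): %s", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$pos))
  if (nrow(tab) && anyNA(pos)) stopf("non-integer TSS position in %s", path)
  validate_tss(data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                          tss_pos = pos, strand = tab$strand,
                          stringsAsFactors = FALSE))
}

#' Write a TSS annotation table
#' @param tss TSS data frame as returned by [read_tss_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  validate_tss(tss)
  out <- data.frame(gene_id = tss$gene_id, chrom = tss$chrom,
                    pos = tss$tss_pos, strand = tss$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binding sites from a BED-like file
#'
#' Reads a BED3+ file of binding sites. Columns beyond the first three are
#' optional and interpreted as: 4 = site id, 5 = comma-separated regulator
#' names, 6 = ChIP enrichment ratio, 7 = conservation score in \[0, 1\].
#' Intervals are 0-based half-open and preserved exactly. Absent optional
#' fields are left absent (\code{NA} / empty regulator set).
#'
#' @param path Path to the BED file (whitespace-separated, no header).
#' @param tissue Tissue label attached to every site.
#' @return A site data frame with columns \code{site_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{tissue}, \code{enrichment},
#'   \code{conservation} and a list column \code{regulators}.
#' @export
read_sites_bed <- function(path, tissue) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_sites())
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 3)) stopf("BED line with fewer than 3 fields")
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get_col(2)))
  end <- suppressWarnings(as.integer(get_col(3)))
  if (anyNA(start) || anyNA(end)) stopf("non-integer start/end in %s", path)
  enr <- get_col(6)
  enrichment <- suppressWarnings(as.numeric(enr))
  if (any(!is.na(enr) & is.na(enrichment) & enr != ".")) stopf("non-numeric enrichment in %s", path)
  enrichment[enr == "."] <- NA_real_
  cons <- get_col(7)
  conservation <- suppressWarnings(as.numeric(cons))
  conservation[cons == "."] <- NA_real_
  ids <- get_col(4)
  ids[is.na(ids) | ids == "."] <- paste0("site_", seq_along(lines))[is.na(ids) | ids == "."]
  regs <- get_col(5)
  reg_list <- lapply(regs, function(r) {
    if (is.na(r) || r == "." || r == "") character() else strsplit(r, ",", fixed = TRUE)[[1]]
  })
  df <- data.frame(site_id = ids, chrom = get_col(1), start = start, end = end,
                   tissue = tissue, enrichment = enrichment,
                   conservation = conservation, stringsAsFactors = FALSE)
  df$regulators <- reg_list
  validate_sites(df)
}

#' Write binding sites to a BED-like file
#'
#' Inverse of [read_sites_bed()]: writes 7 columns (chrom, start, end, id,
#' comma-joined regulators, enrichment, conservation) with \code{.} for
#' absent values, so that a read/write round trip preserves all fields.
#'
#' @param sites Site data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  validate_sites(sites)
  regs <- vapply(sites$regulators, function(r) if (length(r)) paste(r, collapse = ",") else ".", "")
  fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))  # exact double round-trip
  out <- paste(sites$chrom, sites$start, sites$end, sites$site_id, regs,
               fmt_num(sites$enrichment), fmt_num(sites$conservation), sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Define putative regulatory regions from per-regulator peak sets
#'
#' Merges ChIP peak sets from one tissue into maximal intervals and keeps
#' those satisfying the combinatorial-binding rule: a region qualifies if it
#' overlaps a p300 peak, or overlaps peaks of at least two distinct
#' non-p300 regulators. When \code{p300_name} is \code{NULL} (the
#' promoter-array mode, where any peak of the single profiled coregulator
#' defines a region) every merged interval is kept. Overlap means >= 1 bp
#' interval intersection. The output region's regulator set is the union of
#' contributing peak sets and its enrichment the maximum over contributing
#' peaks.
#'
#' @param peak_sets Named list mapping regulator name to a site data frame
#'   (as from [read_sites_bed()]) from a single tissue.
#' @param p300_name Name of the p300 entry in \code{peak_sets}, or
#'   \code{NULL}.
#' @return A site data frame of merged regulatory regions.
#' @export
define_regulatory_regions <- function(peak_sets, p300_name = NULL) {
  if (!length(peak_sets) || is.null(names(peak_sets)) || any(!nzchar(names(peak_sets))))
    stopf("peak_sets must be a non-empty named list")
  if (!is.null(p300_name) && !p300_name %in% names(peak_sets))
    stopf("unknown p300_name '%s'", p300_name)
  pooled <- do.call(rbind, lapply(names(peak_sets), function(r) {
    s <- validate_sites(peak_sets[[r]])
    if (!nrow(s)) return(NULL)
    data.frame(chrom = s$chrom, start = s$start, end = s$end, regulator = r,
               enrichment = s$enrichment, tissue = s$tissue,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || !nrow(pooled)) return(empty_sites())
  res <- lapply(split(pooled, pooled$chrom), function(pk) {
    ir <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)  # 1-based closed
    merged <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, merged)
    cl <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    regs <- split(pk$regulator, cl)
    enrs <- split(pk$enrichment, cl)
    keep <- vapply(seq_along(merged), function(i) {
      r <- unique(regs[[as.character(i)]])
      if (is.null(p300_name)) return(TRUE)
      p300_name %in% r || length(setdiff(r, p300_name)) >= 2L
    }, logical(1))
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    df <- data.frame(site_id = NA_character_, chrom = pk$chrom[1],
                     start = IRanges::start(merged)[idx] - 1L,
                     end = IRanges::end(merged)[idx],
                     tissue = pk$tissue[1],
                     enrichment = vapply(idx, function(i) {
                       e <- enrs[[as.character(i)]]
                       if (all(is.na(e))) NA_real_ else max(e, na.rm = TRUE)
                     }, numeric(1)),
                     conservation = NA_real_, stringsAsFactors = FALSE)
    df$regulators <- lapply(idx, function(i) sort(unique(regs[[as.character(i)]])))
    df
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) return(empty_sites())
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$site_id <- sprintf("rr_%s_%d", out$chrom, stats::ave(out$start, out$chrom, FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Signed distance from binding sites to a TSS
#'
#' Distance is measured from the site midpoint to the TSS position, signed
#' in the gene's transcription direction: negative upstream, positive
#' downstream. On the \code{-} strand the genomic difference is negated.
#'
#' @param sites Site data frame (one or more rows).
#' @param tss A single-row TSS data frame (or a list with fields
#'   \code{chrom}, \code{tss_pos}, \code{strand}).
#' @return Integer vector of signed distances in bp.
#' @export
signed_distance <- function(sites, tss) {
  if (length(tss$chrom) != 1L) stopf("signed_distance expects a single TSS")
  if (any(sites$chrom != tss$chrom))
    stopf("site and TSS on different chromosomes; filter by chromosome first")
  mid <- site_midpoint(sites$start, sites$end)
  d <- mid - as.integer(tss$tss_pos)
  if (tss$strand == "-") d <- -d
  as.integer(d)
}

# All (site, gene) pairs with |signed distance| <= cutoff, as a data frame.
# The inclusive boundary is the association convention used throughout.
site_gene_pairs <- function(tss, sites, cutoff) {
  validate_tss(tss); validate_sites(sites)
  if (cutoff <= 0) stopf("cutoff must be positive")
  out <- list()
  for (chr in intersect(unique(tss$chrom), unique(sites$chrom))) {
    g <- tss[tss$chrom == chr, , drop = FALSE]
    s <- sites[sites$chrom == chr, , drop = FALSE]
    mid <- site_midpoint(s$start, s$end)
    q <- IRanges::IRanges(start = mid, width = 1L)
    subj <- IRanges::IRanges(start = g$tss_pos - as.integer(cutoff),
                             end = g$tss_pos + as.integer(cutoff))
    hits <- IRanges::findOverlaps(q, subj)
    si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
    if (!length(si)) next
    d <- mid[si] - g$tss_pos[gi]
    d <- ifelse(g$strand[gi] == "-", -d, d)
    out[[chr]] <- data.frame(gene_id = g$gene_id[gi], site_row = which(sites$chrom == chr)[si],
                             distance = as.integer(d), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_id = character(), site_row = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Assemble binding_profiles from a pair table. Every gene in `tss` is
# retained; unbound genes get an empty entry table.
build_profiles <- function(tss, sites, pairs, cutoff, tissue = NULL) {
  # entry tables are assembled with a no-copy constructor: profile building
  # is the hot path when associating thousands of sites with 100 kb windows
  entry_frame <- function(site_id, distance, alpha, conservation, enrichment,
                          regulators) {
    structure(list(site_id = site_id, distance = distance, alpha = alpha,
                   conservation = conservation, enrichment = enrichment,
                   regulators = regulators),
              class = "data.frame",
              row.names = c(NA_integer_, -length(site_id)))
  }
  empty <- entry_frame(character(), integer(), numeric(), numeric(),
                       numeric(), list())
  profiles <- rep(list(empty), nrow(tss))
  names(profiles) <- tss$gene_id
  if (nrow(pairs)) {
    gidx <- match(pairs$gene_id, tss$gene_id)
    sid <- sites$site_id[pairs$site_row]
    ord <- order(gidx, pairs$distance, sid)
    gidx <- gidx[ord]
    sid <- sid[ord]
    dist <- pairs$distance[ord]
    cons <- sites$conservation[pairs$site_row[ord]]
    enr <- sites$enrichment[pairs$site_row[ord]]
    regs <- sites$regulators[pairs$site_row[ord]]
    for (grp in split(seq_along(gidx), gidx)) {
      profiles[[gidx[grp[1]]]] <-
        entry_frame(sid[grp], dist[grp], rep(1, length(grp)), cons[grp],
                    enr[grp], regs[grp])
    }
  }
  structure(profiles, cutoff = cutoff,
            tissue = tissue %||% (if (nrow(sites)) sites$tissue[1] else NA_character_),
            class = "binding_profiles")
}

#' Associate binding sites with genes (multi-gene model)
#'
#' Builds per-gene binding profiles: every site whose midpoint lies within
#' \code{cutoff} bp of a gene's TSS (boundary inclusive) enters that gene's
#' profile with its signed distance and a default modifier \code{alpha = 1}.
#' A site may appear in many profiles. Genes with no associated site are
#' retained with an empty profile.
#'
#' @param tss TSS data frame.
#' @param sites Site data frame.
#' @param cutoff Association cutoff in bp (positive).
#' @return A \code{binding_profiles} object: a named list (by gene) of entry
#'   data frames with columns \code{site_id}, \code{distance}, \code{alpha},
#'   \code{conservation}, \code{enrichment}, \code{regulators}.
#' @export
associate_sites <- function(tss, sites, cutoff) {
  pairs <- site_gene_pairs(tss, sites, cutoff)
  build_profiles(tss, sites, pairs, cutoff)
}

#' Associate binding sites with their nearest gene only
#'
#' As [associate_sites()], but each site is assigned to exactly one gene:
#' the gene with minimum absolute signed distance, ties broken by
#' lexicographically smallest \code{gene_id}. Sites beyond \code{cutoff}
#' from every gene are dropped.
#'
#' @inheritParams associate_sites
#' @return A \code{binding_profiles} object.
#' @export
nearest_gene_assignment <- function(tss, sites, cutoff) {
  pairs <- site_gene_pairs(tss, sites, cutoff)
  if (nrow(pairs)) {
    ord <- order(pairs$site_row, abs(pairs$distance), pairs$gene_id)
    pairs <- pairs[ord, , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$site_row), , drop = FALSE]
  }
  build_profiles(tss, sites, pairs, cutoff)
}

#' Is a site proximal to any TSS?
#'
#' A site is proximal when its midpoint lies within the window of
#' \code{2 * half_window + 1} bp centered on some TSS
#' (i.e. |midpoint - tss| <= half_window, boundary inclusive).
#'
#' @param sites Site data frame.
#' @param tss TSS data frame.
#' @param half_window Half-width of the proximal window in bp (default 250,
#'   i.e. a 500 bp window).
#' @return Logical vector, one element per site.
#' @export
classify_proximal <- function(sites, tss, half_window = 250) {
  validate_tss(tss); validate_sites(sites)
  mid <- site_midpoint(sites$start, sites$end)
  vapply(seq_len(nrow(sites)), function(i) {
    g <- tss[tss$chrom == sites$chrom[i], , drop = FALSE]
    nrow(g) > 0 && any(abs(mid[i] - g$tss_pos) <= half_window)
  }, logical(1))
}

#' @export
print.binding_profiles <- function(x, ...) {
  n_entries <- vapply(x, nrow, integer(1))
  cat(sprintf("binding_profiles: %d genes (%d bound), %d site-gene entries, cutoff %s bp\n",
              length(x), sum(n_entries > 0), sum(n_entries),
              format(attr(x, "cutoff"), big.mark = ",")))
  invisible(x)
}

# Number of entries per gene; used by the uniform variant and filters.
profile_sizes <- function(profiles) vapply(profiles, nrow, integer(1))

# Restrict a profile set to sites passing a predicate on the entry table.
filter_profiles <- function(profiles, keep_fun) {
  out <- lapply(profiles, function(e) {
    k <- keep_fun(e)
    e[k, , drop = FALSE]
  })
  attributes(out) <- attributes(profiles)
  out
}
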