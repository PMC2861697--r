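# Sequence-conservation scoring of bound regions.
#
# A region's conservation score is the maximum over a sliding window of the
# windowed mean of per-base scores (PhastCons-style, values in [0, 1]).
# Uncovered bases score 0, following the convention that bases missing from
# the alignment are unconserved.

#' Read a per-base conservation track
#'
#' Reads a bedGraph or fixed-step wiggle file into dense per-base arrays,
#' one per chromosome. Bases not covered by any interval score 0. Scores
#' must lie in \[0, 1\] and intervals must not overlap.
#'
#' @param path Path to a \code{.bedGraph}/\code{.bg} or \code{.wig} file.
#' @param format Format override; guessed from the extension by default.
#' @return A \code{conservation_track}: list with \code{scores} (named list
#'   chrom -> numeric vector) and \code{offset} (named integer vector,
#'   1-based genomic position of each array's first element).
#' @export
read_track <- function(path, format = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bg = , bedgraph = "bedGraph", wig = "wig",
                     stopf("cannot guess track format from extension '%s'", ext))
  }
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)  # 1-based closed start/end, score column
  if (!nrow(df)) stopf("empty conservation track: %s", path)
  if (any(df$score < 0 | df$score > 1))
    stopf("conservation score outside [0, 1] in %s", path)
  scores <- list(); offset <- integer()
  for (chr in unique(as.character(df$seqnames))) {
    d <- df[as.character(df$seqnames) == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stopf("overlapping intervals on %s in %s", chr, path)
    off <- min(d$start)
    arr <- numeric(max(d$end) - off + 1L)
    for (i in seq_len(nrow(d)))
      arr[(d$start[i] - off + 1L):(d$end[i] - off + 1L)] <- d$score[i]
    scores[[chr]] <- arr
    offset[[chr]] <- as.integer(off)
  }
  structure(list(scores = scores, offset = offset), class = "conservation_track")
}

# Per-base scores over 1-based positions from..to; 0 outside the stored array.
track_slice <- function(track, chrom, from, to) {
  if (!chrom %in% names(track$scores))
    stopf("chromosome '%s' absent from conservation track", chrom)
  arr <- track$scores[[chrom]]
  off <- track$offset[[chrom]]
  idx <- (from:to) - off + 1L
  out <- numeric(length(idx))
  ok <- idx >= 1L & idx <= length(arr)
  out[ok] <- arr[idx[ok]]
  out
}

#' Conservation score of a bound region
#'
#' Computes the moving average of per-base scores over windows of
#' \code{window} bp fully contained in the site, and returns the maximum
#' windowed mean. Sites shorter than the window are scored by the mean over
#' the whole site.
#'
#' @param site One-row site data frame (0-based half-open interval).
#' @param track A \code{conservation_track} from [read_track()].
#' @param window Moving-average window in bp (default 100).
#' @return Conservation score in \[0, 1\].
#' @export
region_conservation <- function(site, track, window = 100) {
  if (nrow(site) != 1L) stopf("region_conservation scores one site at a time")
  if (window < 1) stopf("window must be >= 1")
  len <- site$end - site$start
  if (len < 1) stopf("site length must be >= 1")
  x <- track_slice(track, site$chrom, site$start + 1L, site$end)
  if (len < window) return(mean(x))
  cs <- cumsum(c(0, x))
  max((cs[(window + 1):(len + 1)] - cs[1:(len - window + 1)]) / window)
}

#' Score many sites against a conservation track
#'
#' Vectorized convenience wrapper around [region_conservation()]; fills the
#' site table's \code{conservation} column.
#'
#' @param sites Site data frame.
#' @inheritParams region_conservation
#' @return `sites` with the \code{conservation} column populated.
#' @export
score_sites <- function(sites, track, window = 100) {
  sites$conservation <- vapply(seq_len(nrow(sites)), function(i)
    region_conservation(sites[i, , drop = FALSE], track, window), numeric(1))
  sites
}

#' Data-driven conservation threshold
#'
#' Selects the threshold t that best separates bound-region scores from
#' background (random sequence) scores, maximizing
#' \code{mean(bound > t) + mean(background <= t)} (equivalently Youden's J
#' plus 1). Candidate thresholds are the midpoints of adjacent sorted
#' unique pooled scores; ties are broken toward the smallest t.
#'
#' @param bound_scores Numeric vector of bound-region scores.
#' @param background_scores Numeric vector of background scores.
#' @param objective Separation objective: \code{"accuracy_sum"} (default,
#'   the sum of the two correct-classification fractions) or \code{"ks"}
#'   (Kolmogorov-Smirnov distance, which selects the same maximizer when
#'   the two samples have equal weight).
#' @return The selected threshold.
#' @export
select_threshold <- function(bound_scores, background_scores,
                             objective = c("accuracy_sum", "ks")) {
  objective <- match.arg(objective)
  if (!length(bound_scores) || !length(background_scores))
    stopf("both score lists must be non-empty")
  u <- sort(unique(c(bound_scores, background_scores)))
  if (length(u) == 1L) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  obj <- vapply(cand, function(t) {
    a <- mean(bound_scores > t); b <- mean(background_scores <= t)
    if (objective == "ks") abs(a + b - 1) else a + b
  }, numeric(1))
  cand[which.max(obj)]  # which.max takes the first, i.e. smallest t, on ties
}

#' Partition sites by conservation
#'
#' Splits sites into conserved (score strictly above the threshold) and
#' non-conserved (score at or below it).
#'
#' @param sites Site data frame; every site must carry a conservation score.
#' @param threshold Conservation threshold.
#' @return List with elements \code{conserved} and \code{nonconserved}.
#' @export
partition_conserved <- function(sites, threshold) {
  if (anyNA(sites$conservation))
    stopf("site(s) missing conservation score: %s",
          paste(sites$site_id[is.na(sites$conservation)], collapse = ", "))
  keep <- sites$conservation > threshold
  list(conserved = sites[keep, , drop = FALSE],
       nonconserved = sites[!keep, , drop = FALSE])
}
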