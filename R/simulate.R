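# Synthetic-data generator: genomes, tissue-specific binding sites and
# expression with the exact statistical structure the influence model
# assumes, so every pipeline stage can be tested and parameter recovery
# measured against a known truth.

#' Specification of a synthetic study
#'
#' Collects the generator's parameters with defaults chosen to emulate the
#' statistical structure of tissue-specific ChIP binding and microarray
#' expression data: genes on one linear chromosome, a Poisson number of
#' binding sites per gene scattered up to \code{distance_max} from the TSS
#' (a mixture of a TSS-proximal component and a uniform background, so most
#' sites fall outside the proximal promoter and single sites often lie
#' within range of several genes), partial sharing of sites between two
#' tissues, regulator labels with true influence weights, conservation
#' scores drawn from a low/high beta mixture independent of true influence,
#' log-normal ChIP enrichment ratios, and Gaussian expression noise.
#'
#' @param n_genes Number of genes (default 2000).
#' @param sites_per_gene_mean Poisson mean number of generated sites per
#'   gene (default 3).
#' @param distance_max Maximum |signed distance| of generated sites from
#'   their gene's TSS, in bp (default 1e5).
#' @param proximal_fraction Mixture weight of the TSS-proximal distance
#'   component (default 0.4).
#' @param proximal_sd Standard deviation (bp) of the proximal component
#'   (default 5000).
#' @param min_spacing Minimum TSS spacing in bp (default 2000).
#' @param chrom_length Chromosome length; defaults to
#'   \code{n_genes * 20000 + 2 * (distance_max + 1000)}, giving a mean TSS
#'   spacing of about 20 kb so that sites commonly fall within
#'   \code{distance_max} of multiple genes.
#' @param tissue_unique_fraction Fraction of sites present in only one of
#'   the two tissues (default 0.5); the rest are shared.
#' @param tissues Tissue labels (exactly two).
#' @param regulators Named numeric vector of true per-regulator influence
#'   weights; site labels are drawn uniformly from its names.
#' @param regs_per_site Number of regulator labels per site (default 1).
#' @param influence_preset True influence function name, see
#'   [true_influence_presets()].
#' @param cons_high_fraction Mixture weight of the high-conservation beta
#'   component (default 0.5).
#' @param cons_beta_low,cons_beta_high Shape parameters of the two beta
#'   components (defaults Beta(1, 8) and Beta(6, 2)).
#' @param enrichment_meanlog,enrichment_sdlog Log-normal enrichment
#'   parameters (defaults 2 and 0.5).
#' @param noise_sd Gaussian expression noise standard deviation
#'   (default 0.5).
#' @param combine Rule combining multiple regulator weights at one site.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_genes = 2000, sites_per_gene_mean = 3,
                           distance_max = 1e5, proximal_fraction = 0.4,
                           proximal_sd = 5000, min_spacing = 2000,
                           chrom_length = NULL, tissue_unique_fraction = 0.5,
                           tissues = c("tissueA", "tissueB"),
                           regulators = c(TF1 = 1), regs_per_site = 1,
                           influence_preset = "linear_decay_50kb",
                           cons_high_fraction = 0.5,
                           cons_beta_low = c(1, 8), cons_beta_high = c(6, 2),
                           enrichment_meanlog = 2, enrichment_sdlog = 0.5,
                           noise_sd = 0.5, combine = "mean") {
  if (is.null(chrom_length)) chrom_length <- n_genes * 20000 + 2 * (distance_max + 1000)
  stopifnot(n_genes >= 1, sites_per_gene_mean > 0, distance_max > 0,
            proximal_fraction >= 0, proximal_fraction <= 1,
            tissue_unique_fraction >= 0, tissue_unique_fraction <= 1,
            noise_sd >= 0, length(tissues) == 2, length(regulators) >= 1,
            !is.null(names(regulators)), all(regulators > 0))
  structure(as.list(environment()), class = "synthetic_spec")
}

#' True influence-function presets
#'
#' Named ground-truth influence functions used by the generator:
#' \describe{
#'   \item{linear_decay_50kb}{\code{f(d) = max(0, 1 - |d| / 50000)}: an
#'     approximately linear falloff vanishing beyond 50 kb.}
#'   \item{asymmetric_upstream}{the linear decay with the upstream side
#'     (d < 0) multiplied by 1.2, mirroring a somewhat greater effect of
#'     upstream regions.}
#'   \item{flat}{constant 1 within +/- 100 kb: position-independent
#'     influence.}
#'   \item{conservation_only}{influence equal to the site's conservation
#'     score, independent of position (within +/- 100 kb).}
#' }
#'
#' @param name Preset name.
#' @return A function \code{f(d, conservation = NULL)} vectorized over
#'   sites.
#' @export
true_influence_presets <- function(name = c("linear_decay_50kb", "asymmetric_upstream",
                                            "flat", "conservation_only")) {
  name <- match.arg(name)
  switch(name,
    linear_decay_50kb = function(d, conservation = NULL) pmax(0, 1 - abs(d) / 5e4),
    asymmetric_upstream = function(d, conservation = NULL)
      pmax(0, 1 - abs(d) / 5e4) * ifelse(d < 0, 1.2, 1),
    flat = function(d, conservation = NULL) as.numeric(abs(d) <= 1e5),
    conservation_only = function(d, conservation = NULL) {
      if (is.null(conservation)) stopf("conservation_only preset needs conservation scores")
      conservation * (abs(d) <= 1e5)
    })
}

#' Generate a synthetic genome (TSS annotation)
#'
#' Places \code{n_genes} TSSs uniformly at random on one chromosome with a
#' minimum spacing, keeping a margin of \code{distance_max + 300} bp from
#' the chromosome ends so generated sites never fall off the chromosome.
#' Strands are assigned independently with probability 1/2.
#'
#' @param spec A \code{synthetic_spec}.
#' @param seed Integer seed.
#' @return A TSS data frame.
#' @export
generate_genome <- function(spec, seed) {
  n <- spec$n_genes; s <- spec$min_spacing
  margin <- spec$distance_max + 300
  lo <- 1 + margin; hi <- spec$chrom_length - margin
  if (hi - lo < (n - 1) * s)
    stopf("%d genes with %d bp spacing do not fit on a %d bp chromosome",
          n, s, spec$chrom_length)
  with_seed(seed, {
    u <- sort(round(stats::runif(n, lo, hi - (n - 1) * s)))
    pos <- u + (seq_len(n) - 1L) * s
    validate_tss(data.frame(
      gene_id = sprintf("g%05d", seq_len(n)), chrom = "chrS",
      tss_pos = as.integer(pos),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE))
  })
}

#' Generate tissue-specific binding sites
#'
#' For each gene, draws a Poisson number of 201 bp sites whose signed
#' distances follow the spec's proximal/uniform mixture (relative to the
#' gene's strand). Each site is shared between the two tissues with
#' probability \code{1 - tissue_unique_fraction}, otherwise assigned to a
#' single random tissue. Regulator labels, conservation scores and
#' enrichment ratios are drawn per site; shared sites carry identical
#' attributes in both tissues. Because genes are closely spaced, sites
#' routinely fall within the association cutoff of several genes.
#'
#' @param genome TSS data frame from [generate_genome()].
#' @param spec A \code{synthetic_spec}.
#' @param seed Integer seed.
#' @return Named list (by tissue) of site data frames.
#' @export
generate_sites <- function(genome, spec, seed) {
  with_seed(seed, {
    k <- stats::rpois(nrow(genome), spec$sites_per_gene_mean)
    total <- sum(k)
    gene_row <- rep(seq_len(nrow(genome)), k)
    prox <- stats::runif(total) < spec$proximal_fraction
    d <- numeric(total)
    d[prox] <- pmax(pmin(stats::rnorm(sum(prox), 0, spec$proximal_sd),
                         spec$distance_max), -spec$distance_max)
    d[!prox] <- stats::runif(sum(!prox), -spec$distance_max, spec$distance_max)
    d <- as.integer(round(d))
    genomic_offset <- ifelse(genome$strand[gene_row] == "-", -d, d)
    pos <- genome$tss_pos[gene_row] + genomic_offset
    regs <- if (spec$regs_per_site == 1) {
      as.list(sample(names(spec$regulators), total, replace = TRUE))
    } else {
      replicate(total, sample(names(spec$regulators), spec$regs_per_site),
                simplify = FALSE)
    }
    high <- stats::runif(total) < spec$cons_high_fraction
    conservation <- ifelse(high,
                           stats::rbeta(total, spec$cons_beta_high[1], spec$cons_beta_high[2]),
                           stats::rbeta(total, spec$cons_beta_low[1], spec$cons_beta_low[2]))
    enrichment <- stats::rlnorm(total, spec$enrichment_meanlog, spec$enrichment_sdlog)
    shared <- stats::runif(total) >= spec$tissue_unique_fraction
    home <- sample(spec$tissues, total, replace = TRUE)
    base <- data.frame(site_id = sprintf("s%06d", seq_len(total)),
                       chrom = "chrS", start = as.integer(pos - 101L),
                       end = as.integer(pos + 100L), tissue = NA_character_,
                       enrichment = enrichment, conservation = conservation,
                       stringsAsFactors = FALSE)
    base$regulators <- regs
    out <- lapply(spec$tissues, function(t) {
      keep <- shared | home == t
      s <- base[keep, , drop = FALSE]
      s$tissue <- t
      rownames(s) <- NULL
      validate_sites(s)
    })
    names(out) <- spec$tissues
    out
  })
}

#' Generate expression from binding sites and a true influence function
#'
#' Per tissue, a gene's log expression is the sum over all sites within
#' \code{distance_max} of its TSS of
#' \code{a(regulators) * f_true(d, conservation)} plus
#' \code{Normal(0, noise_sd)} noise, where \code{a} combines the spec's
#' true regulator weights. With \code{noise_sd = 0} the table equals the
#' noiseless model predictions exactly. Genes whose site sets differ
#' between the two tissues are flagged \code{differential}.
#'
#' @param genome TSS data frame.
#' @param sites Named list of per-tissue site data frames.
#' @param spec A \code{synthetic_spec}.
#' @param seed Integer seed (noise only).
#' @return List with \code{expression} (data frame: gene_id, one column
#'   per tissue, \code{differential}) and \code{truth} (true influence
#'   function, weights, per-tissue profiles and noiseless means).
#' @export
generate_expression <- function(genome, sites, spec, seed) {
  f <- true_influence_presets(spec$influence_preset)
  profiles <- lapply(sites, function(s) associate_sites(genome, s, spec$distance_max))
  mu <- lapply(profiles, function(pp) {
    # flatten all entries once: much faster than per-gene sums at scale
    sizes <- vapply(pp, nrow, integer(1))
    gi <- rep(seq_along(pp), sizes)
    d <- unlist(lapply(pp, `[[`, "distance"), use.names = FALSE)
    al <- unlist(lapply(pp, `[[`, "alpha"), use.names = FALSE)
    cons <- unlist(lapply(pp, `[[`, "conservation"), use.names = FALSE)
    regs <- do.call(c, lapply(pp, `[[`, "regulators"))
    out <- stats::setNames(numeric(length(pp)), names(pp))
    if (length(d)) {
      a <- combine_weights(spec$regulators, regs, spec$combine)
      agg <- rowsum(a * al * f(d, cons), gi)
      out[as.integer(rownames(agg))] <- agg
    }
    out
  })
  noise <- with_seed(seed, lapply(seq_along(mu), function(i)
    stats::rnorm(nrow(genome), 0, spec$noise_sd)))
  expr <- data.frame(gene_id = genome$gene_id, stringsAsFactors = FALSE)
  for (i in seq_along(spec$tissues))
    expr[[spec$tissues[i]]] <- mu[[i]] + noise[[i]]
  ids <- lapply(profiles, function(pp) lapply(pp, function(e) sort(e$site_id)))
  expr$differential <- !mapply(identical, ids[[1]], ids[[2]])
  list(expression = expr,
       truth = list(influence = f, weights = spec$regulators,
                    profiles = profiles, mu = mu))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_genome()], [generate_sites()] and
#' [generate_expression()] with sub-seeds derived from one seed.
#'
#' @param spec A \code{synthetic_spec}.
#' @param seed Integer seed.
#' @return List with \code{tss}, \code{sites} (per tissue),
#'   \code{expression}, \code{truth}, \code{spec}, \code{seed}.
#' @export
simulate_study <- function(spec, seed) {
  seeds <- derive_seeds(seed, 3)
  tss <- generate_genome(spec, seeds[1])
  sites <- generate_sites(tss, spec, seeds[2])
  ge <- generate_expression(tss, sites, spec, seeds[3])
  list(tss = tss, sites = sites, expression = ge$expression,
       truth = ge$truth, spec = spec, seed = seed)
}
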