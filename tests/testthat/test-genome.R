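test_that("TSS table parsing validates rows and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tpos\tstrand", "g1\tchr1\t1000\t+"), f)
  tss <- read_tss_table(f)
  expect_equal(tss, make_tss("g1", 1000))

  writeLines("gene_id\tchrom\tpos\tstrand", f)
  expect_equal(nrow(read_tss_table(f)), 0L)

  writeLines(c("gene_id\tchrom\tpos\tstrand", "g1\tchr1\t1000\t*"), f)
  expect_error(read_tss_table(f), "strand")

  writeLines(c("gene_id\tchrom\tpos\tstrand", "g1\tchr1\tabc\t+"), f)
  expect_error(read_tss_table(f), "non-integer")

  writeLines(c("gene_id\tchrom\tpos\tstrand",
               "g1\tchr1\t1000\t+", "g1\tchr2\t5\t-"), f)
  expect_error(read_tss_table(f), "g1")

  writeLines(c("gene_id\tchrom\tpos", "g1\tchr1\t1000"), f)
  expect_error(read_tss_table(f), "strand")
  expect_error(read_tss_table(file.path(tempdir(), "no_such_file.tsv")), "not found")
})

test_that("BED site parsing preserves intervals and optional columns", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t900\ts1\tp300,CEBPA\t12.5\t0.4", f)
  s <- read_sites_bed(f, tissue = "liver")
  expect_equal(s$start, 500L)
  expect_equal(s$end, 900L)
  expect_equal(s$regulators[[1]], c("p300", "CEBPA"))
  expect_equal(s$enrichment, 12.5)
  expect_equal(s$conservation, 0.4)
  expect_equal(s$tissue, "liver")

  writeLines("chr1\t100\t300", f)
  s3 <- read_sites_bed(f, "liver")
  expect_equal(s3$regulators[[1]], character())
  expect_true(is.na(s3$enrichment))

  writeLines("chr1\t900\t500", f)
  expect_error(read_sites_bed(f, "liver"), "start >= end")

  writeLines("chr1\t100\t300\ts1\tp300\tnot_a_number", f)
  expect_error(read_sites_bed(f, "liver"), "enrichment")
})

test_that("site BED write/read round trip preserves all fields exactly", {
  st <- small_study(n_genes = 50, regulators = c(p300 = 1, CEBPA = 0.7),
                    regs_per_site = 1)
  sites <- st$sites$tissueA
  f <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, f)
  back <- read_sites_bed(f, tissue = "tissueA")
  rownames(sites) <- rownames(back) <- NULL
  expect_identical(back$start, sites$start)
  expect_identical(back$end, sites$end)
  expect_identical(back$site_id, sites$site_id)
  expect_identical(back$regulators, sites$regulators)
  expect_identical(back$enrichment, sites$enrichment)
  expect_identical(back$conservation, sites$conservation)
})

test_that("regulatory-region definition applies the combinatorial rule", {
  p300 <- make_sites(1000, id = "p1")
  cebpa <- make_sites(5000, id = "c1")
  # one p300 peak, nothing else -> one region carrying p300
  rr <- define_regulatory_regions(list(p300 = p300), p300_name = "p300")
  expect_equal(nrow(rr), 1L)
  expect_equal(rr$regulators[[1]], "p300")
  # one non-p300 peak alone -> nothing
  rr2 <- define_regulatory_regions(list(p300 = p300[0, ], CEBPA = cebpa),
                                   p300_name = "p300")
  expect_equal(nrow(rr2), 0L)
  # two overlapping non-p300 factors -> one merged region with both
  foxa1 <- make_sites(5050, id = "f1")
  rr3 <- define_regulatory_regions(list(CEBPA = cebpa, FOXA1 = foxa1, p300 = p300[0, ]),
                                   p300_name = "p300")
  expect_equal(nrow(rr3), 1L)
  expect_setequal(rr3$regulators[[1]], c("CEBPA", "FOXA1"))
  expect_equal(rr3$start, min(cebpa$start, foxa1$start))
  expect_equal(rr3$end, max(cebpa$end, foxa1$end))
  # enrichment = max over contributing peaks
  a <- make_sites(2000, id = "a", enrichment = 3)
  b <- make_sites(2050, id = "b", enrichment = 9)
  rr4 <- define_regulatory_regions(list(X = a, Y = b), p300_name = NULL)
  expect_equal(rr4$enrichment, 9)
  expect_error(define_regulatory_regions(list(X = a), p300_name = "p300"), "unknown")
})

test_that("regulatory-region definition is idempotent", {
  peaks <- list(p300 = make_sites(c(1000, 1150, 9000)),
                CEBPA = make_sites(c(5000, 20000)),
                FOXA1 = make_sites(c(5080, 40000)))
  rr <- define_regulatory_regions(peaks, p300_name = "p300")
  again <- define_regulatory_regions(list(p300 = rr), p300_name = "p300")
  expect_equal(again[, c("chrom", "start", "end")], rr[, c("chrom", "start", "end")])
})

test_that("signed distance follows the strand-aware midpoint convention", {
  tss_plus <- make_tss("g", 10000, "+")
  expect_equal(signed_distance(make_sites(9500), tss_plus), -500L)
  expect_equal(signed_distance(make_sites(10000), tss_plus), 0L)
  expect_equal(signed_distance(make_sites(10500), tss_plus), 500L)
  tss_minus <- make_tss("g", 10000, "-")
  expect_equal(signed_distance(make_sites(10500), tss_minus), -500L)
  expect_equal(signed_distance(make_sites(9500), tss_minus), 500L)
  expect_error(signed_distance(make_sites(9500, chrom = "chr2"), tss_plus),
               "chromosome")
})

test_that("strand flip with mirrored positions negates nothing (symmetry)", {
  # mirroring a site about the TSS and flipping strand leaves d unchanged;
  # flipping strand alone negates d
  tss_p <- make_tss("g", 50000, "+")
  tss_m <- make_tss("g", 50000, "-")
  for (off in c(-20000L, -3L, 7L, 12345L)) {
    d_p <- signed_distance(make_sites(50000 + off), tss_p)
    expect_equal(signed_distance(make_sites(50000 + off), tss_m), -d_p)
    expect_equal(signed_distance(make_sites(50000 - off), tss_m), d_p)
  }
})

test_that("multi-gene association is inclusive at the cutoff and keeps unbound genes", {
  tss <- make_tss(c("g1", "g2"), c(100000, 170000))
  site <- make_sites(140000, id = "s1")  # 40 kb from g1, 30 kb from g2
  prof <- associate_sites(tss, site, cutoff = 50000)
  expect_equal(nrow(prof$g1), 1L)
  expect_equal(nrow(prof$g2), 1L)
  expect_equal(prof$g1$distance, 40000L)
  expect_equal(prof$g2$distance, -30000L)

  prof10 <- associate_sites(tss, site, cutoff = 10000)
  expect_equal(sum(profile_sizes <- vapply(prof10, nrow, integer(1))), 0L)
  expect_named(prof10, c("g1", "g2"))  # unbound genes retained

  exact <- associate_sites(tss, make_sites(150000), cutoff = 50000)
  expect_equal(nrow(exact$g1), 1L)  # |d| == cutoff is included
})

test_that("nearest-gene assignment picks the closest gene with deterministic ties", {
  tss <- make_tss(c("g1", "g2"), c(10000, 35000))
  s <- make_sites(15000)  # 5 kb from g1, 20 kb from g2
  pn <- nearest_gene_assignment(tss, s, cutoff = 50000)
  expect_equal(nrow(pn$g1), 1L)
  expect_equal(nrow(pn$g2), 0L)

  tie <- make_sites(22500)  # 12.5 kb from both
  pt <- nearest_gene_assignment(tss, tie, cutoff = 50000)
  expect_equal(nrow(pt$g1), 1L)  # lexicographic tie-break
  expect_equal(nrow(pt$g2), 0L)

  far <- make_sites(500000)
  pf <- nearest_gene_assignment(tss, far, cutoff = 50000)
  expect_equal(sum(vapply(pf, nrow, integer(1))), 0L)
})

test_that("nearest-gene output refines the multi-gene association", {
  st <- small_study(n_genes = 120, seed = 5)
  multi <- associate_sites(st$tss, st$sites$tissueA, cutoff = 6e4)
  near <- nearest_gene_assignment(st$tss, st$sites$tissueA, cutoff = 6e4)
  pairs <- function(p) unlist(lapply(names(p), function(g)
    if (nrow(p[[g]])) paste(g, p[[g]]$site_id) else character()))
  expect_true(all(pairs(near) %in% pairs(multi)))
  # every site lands in exactly one nearest profile
  ids_near <- unlist(lapply(near, function(e) e$site_id))
  expect_false(any(duplicated(ids_near)))
})

test_that("proximal classification uses the inclusive half-window", {
  tss <- make_tss("g1", 10000)
  expect_true(classify_proximal(make_sites(10200), tss))
  expect_true(classify_proximal(make_sites(10250), tss))
  expect_false(classify_proximal(make_sites(10251), tss))
  expect_false(classify_proximal(make_sites(10200, chrom = "chr9"), tss))
})
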