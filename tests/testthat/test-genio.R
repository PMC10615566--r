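test_that("VCF write/read round trip restores the panel", {
  sim <- sim_small(seed = 2)
  dir <- withr::local_tempdir()
  paths <- emit_dataset(sim$panel, sim$truth, dir)
  anc <- read_ancestral_table(paths[["ancestral"]])
  map <- read_genetic_map(paths[["map"]])
  back <- read_phased_vcf(paths[["vcf"]], ancestral = anc, map = map)
  expect_identical(back$haplotypes, sim$panel$haplotypes)
  expect_equal(back$variants$bp, sim$panel$variants$bp)
  expect_equal(back$variants$cM, sim$panel$variants$cM, tolerance = 1e-12)
  expect_identical(back$samples$sample_id, sim$panel$samples$sample_id)
})

test_that("ALT-dosage coding and ancestral polarity are honoured", {
  # 2 samples, 3 phased sites; ancestral = REF everywhere
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|0\t0|0",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0|0\t0|1"), vcf)
  anc <- tibble::tibble(chrom = "chr1", bp = c(100, 200, 300),
                        ancestral_allele = c("A", "C", "G"))
  p <- read_phased_vcf(vcf, ancestral = anc)
  expect_equal(dim(p$haplotypes), c(4L, 3L))
  expect_equal(p$haplotypes[, 1], c(0L, 1L, 1L, 1L))
  expect_equal(p$haplotypes[, 2], c(1L, 0L, 0L, 0L))
  expect_false(any(p$variants$ancestral_missing))

  # ancestral = ALT at one site -> that column is bit-flipped
  anc2 <- anc
  anc2$ancestral_allele[2] <- "T"
  p2 <- read_phased_vcf(vcf, ancestral = anc2)
  expect_equal(p2$haplotypes[, 2], 1L - p$haplotypes[, 2])
  expect_false(p2$variants$ancestral_is_ref[2])

  # undetermined ancestral state -> flagged, coding kept
  anc3 <- anc
  anc3$ancestral_allele[3] <- "N"
  p3 <- read_phased_vcf(vcf, ancestral = anc3)
  expect_true(p3$variants$ancestral_missing[3])
  expect_equal(p3$haplotypes[, 3], p$haplotypes[, 3])
})

test_that("unphased genotypes are rejected naming the first offender", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "u.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1"), vcf)
  expect_error(read_phased_vcf(vcf), "chr1:200")
})

test_that("multiallelic and indel records are dropped with a counted warning", {
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "m.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "chr1\t150\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1",
    "chr1\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0|1"), vcf)
  expect_warning(p <- read_phased_vcf(vcf), "2 non-biallelic")
  expect_equal(n_variants(p), 1L)
})

test_that("genetic map interpolation follows the piecewise-linear rule", {
  map <- genetic_map(tibble::tibble(chrom = "chr1",
                                    bp = c(1e6, 2e6, 3e6),
                                    cM = c(1, 2, 2)))
  expect_equal(interpolate_cM(map, "chr1", 1.5e6), 1.5)
  expect_equal(interpolate_cM(map, "chr1", 2e6), 2)        # exact knot
  expect_equal(interpolate_cM(map, "chr1", 2.5e6), 2)      # flat segment
  # extrapolation from terminal rate, floored at zero
  expect_equal(interpolate_cM(map, "chr1", 3.5e6), 2)      # flat right end
  expect_equal(interpolate_cM(map, "chr1", 0.5e6), 0.5)
  steep <- genetic_map(tibble::tibble(chrom = "chr1", bp = c(1e6, 2e6),
                                      cM = c(0.5, 2)))
  expect_equal(interpolate_cM(steep, "chr1", 5e5), 0)      # floored at 0
  expect_error(interpolate_cM(map, "chr2", 1e6), "absent")
})

test_that("map written then interpolated at each variant recovers knots", {
  sim <- sim_small(seed = 8)
  dir <- withr::local_tempdir()
  paths <- emit_dataset(sim$panel, sim$truth, dir)
  map <- read_genetic_map(paths[["map"]])
  got <- interpolate_cM(map, "chr1", sim$panel$variants$bp)
  expect_equal(got, sim$panel$variants$cM, tolerance = 1e-9)
})

test_that("SV BED parsing follows the 0-based half-open convention", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "sv.bed")
  writeLines("chr1\t1000\t21000\tAF=0.05", bed)
  sv <- read_sv_bed(bed)
  expect_equal(sv$sv_length, 20000)
  expect_equal(sv$af, 0.05)

  writeLines(character(0), file.path(dir, "empty.bed"))
  expect_equal(nrow(read_sv_bed(file.path(dir, "empty.bed"))), 0L)

  writeLines("chr1\t-5\t100\tAF=0.5", bed)
  expect_error(read_sv_bed(bed), "negative")
})

test_that("scan tables round trip losslessly", {
  tab <- tibble::tibble(chrom = "chr1", bp = c(1L, 5L), p = c(0.1, 1e-12),
                        flag = c(TRUE, FALSE))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "scan.tsv")
  write_scan_table(tab, path)
  expect_equal(as.data.frame(read_scan_table(path)), as.data.frame(tab))
})

test_that("derived-allele recoding is an involution", {
  sim <- sim_small(seed = 4)
  h <- sim$panel$haplotypes
  flip <- !sim$panel$variants$ancestral_is_ref
  h2 <- h
  h2[, flip] <- 1L - h2[, flip]
  h2[, flip] <- 1L - h2[, flip]
  expect_identical(h2, h)
})
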