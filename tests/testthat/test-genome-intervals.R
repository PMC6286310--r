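test_that("published construct coordinates reproduce their printed lengths", {
  cases <- list(
    list(text = "2R:24967017..24970096 Dmel_r6.08", dec = 2, kb = 3.08),
    list(text = "3R:18911505..18927381 Dmel_r6.08", dec = 2, kb = 15.88),
    list(text = "2R:24968426..24969517 Dmel_r6.08", dec = 2, kb = 1.09),
    list(text = "3R:18872668..18979166 Dmel_r6.08", dec = 1, kb = 106.5))
  for (cs in cases) {
    iv <- parse_flybase_interval(cs$text)
    expect_equal(interval_length_kb(iv, cs$dec), cs$kb, info = cs$text)
  }
  # single-base interval
  expect_equal(interval_length_kb(genomic_interval("X", 5, 5), 3), 0.001)
})

test_that("FlyBase interval parsing validates its input", {
  iv <- parse_flybase_interval("2R:24968426..24969517 Dmel_r6.08")
  expect_s3_class(iv, "genomic_interval")
  expect_equal(c(iv$start, iv$end), c(24968426, 24969517))
  expect_equal(parse_flybase_interval("X:1..1")$arm, "X")
  expect_error(parse_flybase_interval("X:10..5"), "start")
  expect_error(parse_flybase_interval("not-an-interval"), "parse error")
  expect_error(genomic_interval("X", 0, 5), "1-based")
})

test_that("sequence changes parse, measure and frameshift-call correctly", {
  ins <- parse_sequence_change("C > GATCCC", "3R", 18925226)
  expect_equal(net_length_change(ins), 5)
  expect_true(is_frameshift(ins)) # +5 bp shifts the frame (5 mod 3 = 2)
  snv <- parse_sequence_change("T > A", "3R", 18921364)
  expect_equal(net_length_change(snv), 0)
  expect_false(is_frameshift(snv))
  indel <- parse_sequence_change("TC > ACA", "3R", 18925609)
  expect_equal(net_length_change(indel), 1)
  expect_true(is_frameshift(indel))
  expect_error(parse_sequence_change("C > C", "3R", 1), "identical")
  expect_error(parse_sequence_change("C > GAXCC", "3R", 1), "non-DNA")
})

test_that("midpoints are exact reals", {
  expect_equal(gene_midpoint(1, 3), 2)
  expect_equal(gene_midpoint(10, 11), 10.5)
  expect_equal(gene_midpoint(24967017, 24970096), 24968556.5)
})

test_that("BED conversion round-trips and shifts the convention", {
  expect_equal(to_bed(genomic_interval("2R", 1, 1)),
               list(chrom = "2R", start = 0, end = 1))
  iv <- from_bed("2R", 24967016, 24970096)
  expect_equal(c(iv$start, iv$end), c(24967017, 24970096))
  expect_error(from_bed("2R", -1, 5), "BED start")
  # property: round trip is the identity on random intervals
  set.seed(11)
  for (i in 1:50) {
    s <- sample.int(1e7, 1)
    e <- s + sample.int(1e5, 1) - 1
    x <- genomic_interval("3L", s, e)
    b <- to_bed(x)
    expect_identical(from_bed(b$chrom, b$start, b$end), x)
  }
})

test_that("gene density bins by midpoint with floor((mid-1)/bin)", {
  ann <- make_annotation(simple_genes(c(10000, 50000, 90000)))
  ann$arm_length_bp[] <- 120000
  dens <- bin_gene_density(ann, 40000)
  expect_equal(dens$count, c(1, 1, 1))
  expect_equal(dens$bin_start_bp, c(1, 40001, 80001))
  # boundary: midpoint exactly 40000 stays in bin 0; 40001 goes to bin 1
  ann2 <- make_annotation(simple_genes(c(40000, 40001)))
  ann2$arm_length_bp[] <- 80000
  expect_equal(bin_gene_density(ann2, 40000)$count, c(1, 1))
  # empty annotation: all-zero counts, bins still tiled
  empty <- genome_annotation(
    data.frame(gene_id = character(), arm = character(),
               start = numeric(), end = numeric(), is_hrpg = logical()),
    c(`2L` = 100000))
  expect_equal(sum(bin_gene_density(empty, 40000)$count), 0)
})

test_that("bin counts conserve gene counts per arm at any bin size", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    mids <- sort(sample.int(2e6, n))
    ann <- make_annotation(simple_genes(mids, arm = sample(c("2L", "3R"), 1)))
    for (bs in c(1000, 40000, 1e6)) {
      dens <- bin_gene_density(ann, bs)
      expect_equal(sum(dens$count), n, info = sprintf("bin %d", bs))
    }
  }
})

test_that("intragenic percentage is the complement of intergenic cover", {
  expect_equal(intragenic_percentage(1000, NULL), 100)
  one <- data.frame(arm = "2L", start = 1, end = 1000)
  expect_equal(intragenic_percentage(1000, one), 0)
  two <- data.frame(arm = c("2L", "2L"), start = c(1, 50001),
                    end = c(20000, 70000))
  expect_equal(intragenic_percentage(100000, two), 60)
  bad <- data.frame(arm = "2L", start = c(1, 100), end = c(200, 300))
  expect_error(intragenic_percentage(1000, bad), "overlapping")
  expect_error(intragenic_percentage(100, one), "exceeds genome size")
})

test_that("annotation BED writer round-trips through its reader", {
  ann <- make_annotation(simple_genes(c(500, 1500, 2500), width = 101))
  ann$genes$is_hrpg[2] <- TRUE
  path <- withr::local_tempfile(fileext = ".bed")
  write_annotation_bed(ann, path)
  back <- read_annotation_bed(path)
  expect_equal(back$start, ann$genes$start)
  expect_equal(back$end, ann$genes$end)
  expect_equal(back$is_hrpg, ann$genes$is_hrpg)
  # cross-check the file against an independent BED reader if available
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    expect_equal(GenomicRanges::start(gr), ann$genes$start)
    expect_equal(GenomicRanges::end(gr), ann$genes$end)
  }
})
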