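# Reading, validation and conversion of the two STR data modes.

test_that("frequency tables validate sums, alleles and duplicates", {
  ok <- data.frame(population = "A", locus = "TH01",
                   allele = c(9, 9.3, 10), frequency = c(0.4, 0.2, 0.4),
                   n_copies = 100)
  ft <- freq_table(ok)
  expect_s3_class(ft, "freq_table")
  expect_true(9.3 %in% ft$allele)  # imperfect allele kept verbatim

  bad_sum <- data.frame(population = "A", locus = "L1",
                        allele = c(8, 10), frequency = c(0.6, 0.6),
                        n_copies = 100)
  expect_error(freq_table(bad_sum), "sum to 1.2")

  dup <- data.frame(population = "A", locus = "L1",
                    allele = c(8, 8), frequency = c(0.5, 0.5),
                    n_copies = 100)
  expect_error(freq_table(dup), "duplicate allele")

  neg <- data.frame(population = "A", locus = "L1",
                    allele = c(-2, 8), frequency = c(0.5, 0.5),
                    n_copies = 100)
  expect_error(freq_table(neg), "nonnegative")
})

test_that("frequency table files round-trip and drop zero frequencies", {
  df <- data.frame(population = rep(c("A", "B"), each = 3),
                   locus = "D5S818",
                   allele = c(8, 10, 11, 8, 10, 12),
                   frequency = c(0.5, 0.5, 0, 0.25, 0.5, 0.25),
                   n_copies = c(100, 100, 100, 40, 40, 40))
  path <- withr::local_tempfile(fileext = ".tsv")
  ft <- freq_table(df)
  expect_equal(nrow(ft), 5L)  # zero-frequency row dropped
  write_frequency_table(ft, path)
  back <- read_frequency_table(path)
  expect_equal(back$frequency, ft$frequency, tolerance = 1e-6)
  expect_identical(back$allele, ft$allele)
  expect_identical(back$n_copies, ft$n_copies)
})

test_that("GenePop files round-trip, including decimal microvariants", {
  g <- gt_from_copies(list(A = c(8, 8, 9.3, 10, 10, 11),
                           B = c(8, 10, 10, 10, 12, 12)), locus = "TH01")
  path <- withr::local_tempfile(fileext = ".gen")
  write_genotypes_genepop(g, path)
  back <- read_genotypes_genepop(path)
  expect_equal(length(back$populations), 2L)
  expect_equal(nrow(back$genotypes), nrow(g))
  expect_equal(sort(c(back$genotypes$allele1, back$genotypes$allele2)),
               sort(c(g$allele1, g$allele2)))
})

test_that("GenePop reading drops individuals with missing calls", {
  lines <- c("toy", "L1", "L2", "POP",
             "a1 , 008008 010010",
             "a2 , 008010 000010",  # missing call -> dropped
             "a3 , 010010 010012",
             "POP",
             "b1 , 012012 010010",
             "b2 , 012010 012012",
             "b3 , 010008 012010")
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(lines, path)
  res <- read_genotypes_genepop(path)
  expect_equal(length(attr(res$genotypes, "individuals")), 5L)
  expect_equal(nrow(res$dropped), 1L)
  expect_equal(res$dropped$individual, "a2")
  expect_error(suppressWarnings(read_genotypes_genepop(
    withr::local_tempfile(fileext = ".gen"))))
})

test_that("genotype-to-frequency conversion counts copies exactly", {
  g <- gt_from_copies(list(A = c(8, 8, 8, 10)))
  ft <- frequencies_from_genotypes(g)
  expect_equal(ft$frequency[ft$allele == 8], 0.75)
  expect_equal(ft$frequency[ft$allele == 10], 0.25)
  expect_equal(unique(ft$n_copies), 4L)

  mono <- frequencies_from_genotypes(gt_from_copies(list(A = c(9, 9, 9, 9))))
  expect_equal(mono$frequency, 1)

  # conservation on random tables
  set.seed(1)
  for (i in 1:5) {
    cp <- lapply(stats::setNames(1:3, c("A", "B", "C")),
                 function(.) sample(7:12, 8, replace = TRUE))
    f <- frequencies_from_genotypes(gt_from_copies(cp))
    sums <- tapply(f$frequency, f$population, sum)
    expect_equal(as.vector(sums), rep(1, 3))
  }
})

test_that("copy-count reconstruction inverts frequencies", {
  # counts -> frequencies -> largest-remainder reconstruction is identity
  set.seed(2)
  for (i in 1:10) {
    cnt <- as.vector(stats::rmultinom(1, 50, c(0.4, 0.3, 0.2, 0.1)))
    cnt <- cnt[cnt > 0]
    rec <- strpopgen:::.largest_remainder(cnt / sum(cnt), sum(cnt))
    expect_identical(rec, as.integer(cnt))
  }
})

test_that("complex-repeat loci can be dropped for robustness runs", {
  df <- expand.grid(population = "A",
                    locus = c("TH01", "FGA", "D21S11", "VWA"),
                    stringsAsFactors = FALSE)
  df$allele <- 8; df$frequency <- 1; df$n_copies <- 50
  ft <- freq_table(df)
  out <- drop_complex_loci(ft)
  expect_identical(loci(out), "VWA")
  expect_error(drop_complex_loci(ft, drop = unique(df$locus)))
})

test_that("metadata validation enforces coordinates and labels", {
  md <- data.frame(population = c("A", "B"), group = c("EUR", "EAS"),
                   lat = c(48, 35), lon = c(2, 139),
                   region = c("EUR", "EAS"), well_defined = c(TRUE, FALSE))
  meta <- pop_metadata(md)
  expect_s3_class(meta, "pop_metadata")
  md$lat[1] <- 99
  expect_error(pop_metadata(md), "latitude")
  h <- hierarchy_config(meta)
  expect_identical(unname(unclass(h)["A"]), "EUR")
  expect_error(hierarchy_config(c("A", "A"), c("x", "y")), "exactly once")
})
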