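miso_fixture <- function() {
  tibble::tibble(
    event_name = c("ev1@chr1:100:200:+", "ev2@chr2:5:50:-", "ev3@chr3:7:9:+"),
    sample1_psi_mean = c(0.8, 0.5, 0.2),
    sample2_psi_mean = c(0.6, 0.5, 0.4),
    diff = c(0.2, 0.0, -0.2),
    bayes_factor = c(12.5, 0.4, 3.3),
    sample1_inc = c(40, 10, 4), sample1_exc = c(10, 10, 16),
    sample2_inc = c(30, 10, 8), sample2_exc = c(20, 10, 12)
  )
}

test_that("MISO comparison files round-trip field-for-field", {
  f <- withr::local_tempfile(fileext = ".miso_bf")
  recs <- miso_fixture()
  write_miso_comparison(recs, f)
  got <- read_miso_comparison(f)
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_skipped"), 0L)
  attr(got, "n_skipped") <- NULL
  expect_equal(as.data.frame(got), as.data.frame(recs))
  # a second round trip reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".miso_bf")
  write_miso_comparison(got, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("rows with non-numeric Bayes factors are skipped with a count", {
  f <- withr::local_tempfile(fileext = ".miso_bf")
  recs <- miso_fixture()
  recs$bayes_factor <- as.character(recs$bayes_factor)
  recs$bayes_factor[2] <- "NA"
  readr::write_tsv(recs, f)
  expect_warning(got <- read_miso_comparison(f), "Skipped 1 row")
  expect_equal(nrow(got), 2)
  expect_equal(attr(got, "n_skipped"), 1)
})

test_that("missing required columns are reported by name", {
  f <- withr::local_tempfile(fileext = ".miso_bf")
  readr::write_tsv(dplyr::select(miso_fixture(), -bayes_factor), f)
  expect_error(read_miso_comparison(f), "bayes_factor")
})

test_that("footprint BED parsing honors the BED6+ layout", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t110\tM054_0.6\t0.995\t+", f)
  got <- read_footprints_bed(f)
  expect_equal(got$start, 100)
  expect_equal(got$end, 110)
  expect_equal(got$motif_id, "M054_0.6")
  expect_equal(got$posterior, 0.995)
  expect_equal(got$strand, "+")
})

test_that("footprint BED edge cases: empty file, missing posterior, bad interval", {
  f <- withr::local_tempfile(fileext = ".bed")
  file.create(f)
  expect_equal(nrow(read_footprints_bed(f)), 0)

  writeLines("chr1\t100\t110\tM054_0.6", f)
  expect_warning(got <- read_footprints_bed(f), "posterior")
  expect_equal(got$posterior, 1)

  writeLines("chr1\t110\t100\tM054_0.6\t0.99\t+", f)
  expect_error(read_footprints_bed(f), "start >= end")
})

test_that("footprint BED round-trips through the writer", {
  f <- withr::local_tempfile(fileext = ".bed")
  fp <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(5, 100),
                       end = c(17, 160), motif_id = c("M1", "M2"),
                       posterior = c(0.995, 1), strand = c("+", "."),
                       binding_effect = c("affecting", "neutral"))
  write_footprints_bed(fp, f)
  got <- read_footprints_bed(f)
  expect_equal(as.data.frame(got), as.data.frame(fp))
})

test_that("event GFF conversion is 1-based on disk, 0-based internally", {
  f <- withr::local_tempfile(fileext = ".gff3")
  # plus-strand AFE with first exons starting at 1-based 1001 and 2001
  ann <- tibble::tibble(
    event_id = "afe1", gene_id = "G1", event_type = "AFE",
    chrom = "chr1", strand = "+",
    iso1_start = 1000, iso1_end = 1200, iso2_start = 2000, iso2_end = 2200
  )
  write_event_gff(ann, f)
  raw <- readLines(f)
  exon_starts <- as.integer(sub("\t.*", "", sub("^\\S+\t\\S+\texon\t", "",
                                 grep("\texon\t", raw, value = TRUE))))
  expect_setequal(exon_starts, c(1001, 2001))
  got <- read_event_gff(f)
  expect_equal(got$iso1_start, 1000)
  expect_equal(got$iso2_start, 2000)
  tss <- afe_tss(got)
  expect_equal(tss$tss_upstream, 1000)
  expect_equal(tss$tss_downstream, 2000)
})

test_that("minus-strand AFE: the upstream TSS is the larger coordinate", {
  f <- withr::local_tempfile(fileext = ".gff3")
  ann <- tibble::tibble(
    event_id = "afe2", gene_id = "G2", event_type = "AFE",
    chrom = "chr1", strand = "-",
    iso1_start = 1000, iso1_end = 1200, iso2_start = 2000, iso2_end = 2200
  )
  write_event_gff(ann, f)
  tss <- afe_tss(read_event_gff(f))
  expect_equal(tss$tss_upstream, 2199)   # last base of the 3'-most exon
  expect_equal(tss$tss_downstream, 1199)
})

test_that("annotation round-trips through GFF for a mixed fixture", {
  f <- withr::local_tempfile(fileext = ".gff3")
  ann <- fixture_annotation()
  write_event_gff(ann, f)
  got <- read_event_gff(f) %>% dplyr::arrange(event_id)
  want <- ann %>%
    dplyr::select(event_id, gene_id, event_type, chrom, strand,
                  iso1_start, iso1_end, iso2_start, iso2_end) %>%
    dplyr::arrange(event_id)
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("malformed event GFFs are rejected", {
  f <- withr::local_tempfile(fileext = ".gff3")
  lines <- c(
    "##gff-version 3",
    "chr1\t.\tgene\t1001\t2200\t.\t+\t.\tID=e1;event_type=XX",
    "chr1\t.\tmRNA\t1001\t1200\t.\t+\t.\tID=e1.iso1;Parent=e1",
    "chr1\t.\texon\t1001\t1200\t.\t+\t.\tID=e1.iso1.exon;Parent=e1.iso1",
    "chr1\t.\tmRNA\t2001\t2200\t.\t+\t.\tID=e1.iso2;Parent=e1",
    "chr1\t.\texon\t2001\t2200\t.\t+\t.\tID=e1.iso2.exon;Parent=e1.iso2"
  )
  writeLines(lines, f)
  expect_error(read_event_gff(f), "Unknown event type")

  lines2 <- c(
    "##gff-version 3",
    "chr1\t.\tgene\t1001\t2200\t.\t+\t.\tID=e1;event_type=AFE",
    "chr1\t.\tmRNA\t1001\t1200\t.\t+\t.\tID=e1.iso1;Parent=e1",
    "chr1\t.\texon\t1001\t1200\t.\t+\t.\tID=e1.iso1.exon;Parent=e1.iso1"
  )
  writeLines(lines2, f)
  expect_error(read_event_gff(f), "isoform")
})
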