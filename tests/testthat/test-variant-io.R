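test_that("sync lines parse to ref/alt counts with the majority alternate base", {
  f <- tempfile(fileext = ".sync")
  writeLines(c("chr1\t100\tA\t10:0:0:0:0:0\t8:2:0:0:0:0",
               "chr1\t200\tC\t0:0:0:0:0:0\t5:0:7:0:0:0"), f)
  rec <- read_sync(f)
  expect_equal(rec$ref[1], "A")
  expect_equal(rec$alt[1], "T")
  expect_equal(unlist(rec[1, c("ref1", "alt1", "ref2", "alt2")], use.names = FALSE),
               c(10L, 0L, 8L, 2L))
  # all-zero sextet kept with zero depth in that pool
  expect_equal(rec$ref1[2] + rec$alt1[2], 0L)
  expect_equal(rec$ref2[2], 7L)  # ref C
  expect_equal(rec$alt2[2], 5L)  # alt A (majority non-ref)
})

test_that("malformed sync input raises parse errors naming the line", {
  f <- tempfile(fileext = ".sync")
  writeLines(c("chr1\t100\tA\t10:0:0:0:0:0\t8:2:0:0:0:0",
               "chr1\t200\tA\t1:2:3\t1:1:1:1:1:1"), f)
  expect_error(read_sync(f), "line 2")
  writeLines("chr1\t100\tA\t10:0:0:0:0:0", f)
  expect_error(read_sync(f), "column")
})

test_that("sync writing and reading round-trips counts and indel typing", {
  sim <- small_sim()
  f <- tempfile(fileext = ".sync")
  write_sync(sim$records, f)
  back <- read_sync(f)
  expect_equal(nrow(back), nrow(sim$records))
  expect_equal(back$pos, sim$records$pos)
  for (col in c("ref1", "alt1", "ref2", "alt2")) {
    expect_equal(back[[col]], sim$records[[col]], ignore_attr = TRUE)
  }
  expect_equal(back$type, sim$records$type)
})

test_that("VCF writing and reading round-trips counts, quality, and type", {
  sim <- small_sim()
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$records, f, pools = sim$config$pools)
  back <- read_vcf_counts(f)
  expect_equal(nrow(back), nrow(sim$records))
  for (col in c("ref1", "alt1", "ref2", "alt2")) {
    expect_equal(back[[col]], sim$records[[col]], ignore_attr = TRUE)
  }
  expect_equal(back$qual, sim$records$qual, tolerance = 1e-8)
  expect_equal(back$type, sim$records$type)
})

test_that("VCF allelic depths are extracted and indels typed by length", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t50\t.\t.\tAD\t12,3\t20,0",
    "chr1\t200\t.\tA\tAT\t40\t.\t.\tAD\t9,9\t10,2",
    "chr1\t300\t.\tC\tG,T\t30\t.\t.\tAD\t5,1,8\t6,2,9"), f)
  rec <- read_vcf_counts(f)
  expect_equal(unlist(rec[1, c("ref1", "alt1", "ref2", "alt2")], use.names = FALSE),
               c(12L, 3L, 20L, 0L))
  expect_equal(rec$type[2], "indel")
  # multiallelic: keeps the higher-depth alternate (T: 8+9 vs G: 5+2... 1+2)
  expect_equal(rec$alt[3], "T")
  expect_equal(rec$alt1[3], 8L)
  expect_equal(attr(rec, "multiallelic"), 1L)
})

test_that("a VCF without allelic depths is rejected", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t50\t.\t.\tGT\t0/1\t0/0"), f)
  expect_error(read_vcf_counts(f), "AD")
})

test_that("GFF3 gene features are read with symbol fallback to the id", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=g1;Name=MYGENE",
               "chr1\tsrc\tgene\t5000\t6000\t.\t-\t.\tID=ENSCAFG000001",
               "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=t1;Parent=g1"), f)
  g <- read_gff3(f)
  expect_equal(nrow(g), 2L)
  expect_equal(g$symbol, c("MYGENE", "ENSCAFG000001"))
  expect_equal(g$start[1], 1000L)
  expect_equal(g$end[1], 2000L)
})

test_that("a GFF3 with no gene features yields an empty table with a warning", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=t1",
               "chr1\tsrc\texon\t1000\t1500\t.\t+\t.\tID=e1"), f)
  expect_warning(g <- read_gff3(f), "gene")
  expect_equal(nrow(g), 0L)
})

test_that("gene annotations written as GFF3 round-trip", {
  sim <- small_sim()
  genes <- toy_gene_annotation(sim)
  f <- tempfile(fileext = ".gff3")
  write_gff3(genes, f)
  back <- read_gff3(f)
  expect_equal(back$symbol, genes$symbol)
  expect_equal(back$start, as.integer(genes$start))
  expect_equal(back$end, as.integer(genes$end))
})

test_that("the MAF boundary is strict and the indel distance inclusive", {
  tab <- variant_table(
    snp_row(pos = 100, ref1 = 57, alt1 = 3, ref2 = 38, alt2 = 2),   # MAF = 5/100: retained
    snp_row(pos = 200, ref1 = 58, alt1 = 2, ref2 = 38, alt2 = 2),   # MAF = 4/100: discarded
    snp_row(pos = 1000, ref = "AT", alt = "A", type = "indel"),
    snp_row(pos = 1015, ref1 = 20, alt1 = 20, ref2 = 20, alt2 = 20), # 15 bp: discarded
    snp_row(pos = 1016, ref1 = 20, alt1 = 20, ref2 = 20, alt2 = 20)  # 16 bp: retained
  )
  out <- apply_filters(tab)
  expect_setequal(out$records$pos, c(100, 1016))
  expect_equal(out$report$discarded$maf, 1L)
  expect_equal(out$report$discarded$indel_proximity, 1L)
  expect_equal(out$report$discarded$indel_records, 1L)
})

test_that("depth and quality rules and the per-pool/combined switch behave", {
  tab <- variant_table(
    snp_row(pos = 10, ref1 = 5, alt1 = 4, ref2 = 20, alt2 = 10),  # pool1 depth 9
    snp_row(pos = 20, qual = 19.9),                               # quality
    snp_row(pos = 30, qual = 20)                                  # boundary: kept
  )
  out <- apply_filters(tab)
  expect_equal(out$records$pos, 30)
  # combined depth mode: 9 + 30 = 39 >= 10 passes
  out2 <- apply_filters(tab, filter_config(depth_mode = "combined"))
  expect_setequal(out2$records$pos, c(10, 30))
  # missing quality (sync input) passes the quality rule; the low-depth
  # record at pos 10 is still removed by the depth rule
  tab$qual <- NA_real_
  out3 <- apply_filters(tab)
  expect_setequal(out3$records$pos, c(20, 30))
})

test_that("filtering is idempotent and the report always balances", {
  for (seed in 1:5) {
    tab <- random_variant_table(n = 80, seed = seed)
    out <- apply_filters(tab)
    expect_equal(out$report$retained + out$report$discarded_unique,
                 out$report$input)
    again <- apply_filters(out$records)
    expect_identical(again$records, out$records)
    expect_equal(again$report$discarded_unique, 0L)
  }
})

test_that("unsorted input is rejected", {
  tab <- rbind(snp_row(pos = 200), snp_row(pos = 100))
  expect_error(apply_filters(tab), "sorted")
})

test_that("Ts/Tv counts transitions against transversions with a division guard", {
  tab <- variant_table(
    snp_row(pos = 1, ref = "A", alt = "G"),
    snp_row(pos = 2, ref = "A", alt = "G"),
    snp_row(pos = 3, ref = "A", alt = "C")
  )
  expect_equal(compute_tstv(tab)$ratio, 2)
  only_ts <- variant_table(snp_row(pos = 1, ref = "C", alt = "T"))
  expect_warning(r <- compute_tstv(only_ts), "undefined")
  expect_true(is.na(r$ratio))
  sym <- variant_table(snp_row(pos = 1, ref = "A", alt = "G"),
                       snp_row(pos = 2, ref = "A", alt = "T"))
  expect_equal(compute_tstv(sym)$ratio, 1)
  # per-pool restriction counts only sites with alternate reads in that pool
  mix <- variant_table(snp_row(pos = 1, ref = "A", alt = "G", alt1 = 0),
                       snp_row(pos = 2, ref = "A", alt = "C", alt1 = 3))
  expect_equal(compute_tstv(mix, pool = 1)$transversions, 1L)
  expect_equal(compute_tstv(mix, pool = 1)$transitions, 0L)
})
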