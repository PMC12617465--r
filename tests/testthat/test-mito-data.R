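test_that("FASTA reading parses, normalises case and rejects ragged records", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGTACGTAC", ">s2 extra header words", "acgtacgtac",
               ">s3", "ACGTACGTAG"), f)
  aln <- readMitoFasta(f)
  expect_equal(nSamples(aln), 3L)
  expect_equal(nSites(aln), 10L)
  expect_equal(sampleIds(aln), c("s1", "s2", "s3"))
  expect_equal(paste(alignmentMatrix(aln)["s2", ], collapse = ""), "ACGTACGTAC")

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTA"), f2)
  expect_error(readMitoFasta(f2), "not aligned")

  f3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f3)
  expect_error(readMitoFasta(f3), "empty")

  f4 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACRTACGTAC", ">b", "ACGTACGTAC"), f4)  # IUPAC R
  expect_warning(aln4 <- readMitoFasta(f4), "mapped to N")
  expect_equal(unname(alignmentMatrix(aln4)["a", 3]), "N")
})

test_that("alignments round-trip through FASTA", {
  set.seed(41)
  aln <- randomAlignment(6, 40)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeMitoFasta(aln, f)
  back <- readMitoFasta(f)
  expect_identical(alignmentMatrix(back), alignmentMatrix(aln))
})

test_that("the default hotspot mask covers exactly the documented positions", {
  pol <- defaultMask()
  pos <- excludedPositions(pol)
  expect_true(16519L %in% pos)
  expect_true(all(303:315 %in% pos))
  expect_true(all(16182:16194 %in% pos))
  expect_length(pos, 1 + 13 + 13)
  expect_false(16181L %in% pos)
  expect_false(302L %in% pos)
  expect_false(16195L %in% pos)
  expect_true(pol@excludeIndels)
})

test_that("masking drops hotspot and indel columns and keeps coordinates", {
  L <- 16569L
  base <- rep("A", L)
  s1 <- base; s2 <- base
  s2[16519] <- "G"                      # only difference is the hotspot
  s1[100] <- "-"                        # indel column
  m <- rbind(s1 = s1, s2 = s2)
  aln <- MitoAlignment(m)
  masked <- applyMask(aln, defaultMask())
  expect_false(16519L %in% sitePositions(masked))
  expect_false(100L %in% sitePositions(masked))
  expect_equal(sum(alignmentMatrix(masked)["s1", ] != alignmentMatrix(masked)["s2", ]), 0L)
  expect_equal(nSites(masked), L - 27L - 1L)

  ## empty mask is the identity
  same <- applyMask(aln, maskPolicy(integer(0), excludeIndels = FALSE))
  expect_identical(alignmentMatrix(same), alignmentMatrix(aln))

  expect_error(applyMask(MitoAlignment(c(a = "ACGT", b = "ACGT")), defaultMask()),
               "exceed")
})

test_that("haplotype collapsing groups identical unmasked sequences", {
  aln <- generateToy("paleolithic_hd")     # 12 sequences, one duplicated pair
  tab <- collapseHaplotypes(aln)
  expect_length(tab@counts, 11L)
  expect_equal(sort(tab@counts, decreasing = TRUE), c(2L, rep(1L, 10)))
  expect_equal(tab@counts[1], 2L)          # sorted by descending count

  all_same <- MitoAlignment(setNames(rep("ACGTACGT", 5), paste0("x", 1:5)))
  expect_length(collapseHaplotypes(all_same)@counts, 1L)

  set.seed(7)
  distinct <- randomAlignment(8, 60)
  expect_length(collapseHaplotypes(distinct)@counts, 8L)

  ## masking then collapsing is idempotent
  set.seed(8)
  x <- randomAlignment(10, 50)
  pol <- maskPolicy(c(3L, 17L), excludeIndels = TRUE)
  once <- collapseHaplotypes(applyMask(x, pol))
  twice <- collapseHaplotypes(applyMask(applyMask(x, pol), pol))
  expect_identical(haplotypeCounts(once), haplotypeCounts(twice))
})

test_that("haplotype diversity matches its draw-probability definition", {
  expect_equal(round(haplotypeDiversity(c(rep(1, 10), 2)), 2), 0.98)
  expect_equal(round(haplotypeDiversity(c(rep(1, 15), 2)), 2), 0.99)
  expect_equal(haplotypeDiversity(c(5)), 0)
  expect_equal(haplotypeDiversity(rep(1, 4)), 1)
  expect_error(haplotypeDiversity(c(1)), "n < 2")

  set.seed(11)
  for (i in 1:200) {
    counts <- rpois(sample(2:8, 1), 2) + 1L
    if (sum(counts) < 2) next
    expect_equal(haplotypeDiversity(counts), bruteHd(counts), tolerance = 1e-12)
    p <- counts / sum(counts)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("haplogroup frequency tables collapse prefixes and report dropped samples", {
  md <- data.frame(
    sample_id = sprintf("u%02d", 1:10),
    group = c(rep("MesolithicUzzo", 8), "NeolithicUzzo", "NeolithicUzzo"),
    geogroup = "", age_bp = 9000, age_low = 8500, age_high = 9500,
    haplogroup = c(rep("U5b2b", 7), "U2e1", "K1a3", NA),
    stringsAsFactors = FALSE)
  pm <- c(U5 = "U5", U2 = "U2-U3-U4", K = "U8b/K", U8 = "U8b/K")
  tab <- haplogroupFrequencyTable(md, "group", prefixMap = pm)
  expect_equal(tab["MesolithicUzzo", "U5"], 7L)
  expect_equal(tab["MesolithicUzzo", "U5"] / sum(tab["MesolithicUzzo", ]), 0.875)
  expect_equal(attr(tab, "dropped"), "u10")

  empty <- haplogroupFrequencyTable(md[0, ], "group")
  expect_equal(dim(empty), c(0L, 0L))

  ## longest prefix wins; unmatched labels pass through
  expect_equal(macroHaplogroup(c("U5b2b1", "U8b1b1", "HV0"), pm),
               c("U5", "U8b/K", "HV0"))
  expect_equal(macroHaplogroup(c("HG01", "HG02")), c("HG01", "HG02"))
})

test_that("metadata validation enforces id uniqueness and age brackets", {
  md <- data.frame(sample_id = c("a", "b"), group = "g", geogroup = "",
                   age_bp = c(0, 5000), age_low = c(0, 4800),
                   age_high = c(0, 5200), haplogroup = NA,
                   stringsAsFactors = FALSE)
  expect_true(validateSampleMetadata(md))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSampleMetadata(md, f)
  expect_equal(readSampleMetadata(f)$age_bp, c(0, 5000))

  bad <- md; bad$age_low[2] <- 5100
  expect_error(validateSampleMetadata(bad), "age_low")
  dup <- md; dup$sample_id[2] <- "a"
  expect_error(validateSampleMetadata(dup), "unique")
})
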