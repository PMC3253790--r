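test_that("FASTA reading distinguishes aligned and unaligned input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "ACGT", ">t2", "ACGA"), f)
  aln <- readFasta(f, "nt")
  expect_s4_class(aln, "PartitionedAlignment")
  expect_equal(dim(alignmentMatrix(aln)), c(2L, 4L))
  expect_equal(taxonNames(aln), c("t1", "t2"))

  writeLines(c(">sp1|c1", "ACGT", ">sp1|c2", "ACG", ">sp2", "AC"), f)
  gs <- readFasta(f, "nt")
  expect_s4_class(gs, "GeneSequenceSet")
  expect_setequal(taxonNames(gs), c("sp1", "sp2"))

  writeLines(c(">t1", "AC-N", ">t2", "ACGA"), f)
  aln <- readFasta(f, "nt")
  expect_equal(unname(alignmentMatrix(aln)["t1", 3:4]), c("-", "N"))

  writeLines(c(">t1", "ACGT", ">t1", "ACGA"), f)
  expect_error(readFasta(f, "nt"), "duplicate")

  writeLines(c(">t1", "AC!T"), f)
  expect_error(readFasta(f, "nt"), "illegal character")
})

test_that("FASTA write/read round-trips the matrix", {
  aln <- partitionedAlignment(c(a = "MKL-W", b = "MKLVW"), "aa")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(aln, f)
  back <- readFasta(f, "aa")
  expect_identical(alignmentMatrix(back), alignmentMatrix(aln))
})

test_that("NEXUS charsets convert 1-based inclusive to half-open intervals", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin data;",
               "dimensions ntax=3 nchar=10;",
               "format datatype=dna missing=? gap=-;", "matrix",
               "t1 ACGTACGTAC", "t2 ACGAACGTAC", "t3 AGGAACGTAC", ";",
               "end;", "begin sets;", "charset gene1 = 1-6;",
               "charset gene2 = 7-10;", "end;"), f)
  aln <- readNexusAlignment(f)
  p <- partitionScheme(aln)
  expect_equal(p$start, c(0L, 6L))
  expect_equal(p$end, c(6L, 10L))
  expect_equal(p$name, c("gene1", "gene2"))
})

test_that("interleaved and sequential NEXUS dialects parse identically", {
  f1 <- withr::local_tempfile(fileext = ".nex")
  f2 <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin data;",
               "dimensions ntax=2 nchar=8;",
               "format datatype=dna gap=-;", "matrix",
               "t1 ACGTTGCA", "t2 ACGATGCA", ";", "end;"), f1)
  writeLines(c("#NEXUS", "begin data;",
               "dimensions ntax=2 nchar=8;",
               "format datatype=dna gap=- interleave;", "matrix",
               "t1 ACGT", "t2 ACGA", "", "t1 TGCA", "t2 TGCA", ";",
               "end;"), f2)
  expect_identical(alignmentMatrix(readNexusAlignment(f1)),
                   alignmentMatrix(readNexusAlignment(f2)))
})

test_that("NEXUS dimension mismatches are rejected", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "begin data;",
               "dimensions ntax=2 nchar=10;",
               "format datatype=dna gap=-;", "matrix",
               "t1 ACGTACGTA", "t2 ACGAACGTA", ";", "end;"), f)
  expect_error(readNexusAlignment(f))
})

test_that("Newick parsing keeps shape; writer is canonical and stable", {
  t1 <- parseNewick("((A:1,B:2):0.5,C:3);")
  expect_equal(length(t1$tip.label), 3L)
  expect_true(ape::is.rooted(t1))
  t2 <- parseNewick("(A:1,B:2,C:3);")
  expect_false(ape::is.rooted(t2))
  expect_error(parseNewick("((A:1,A:2):0.5,C:3);"), "duplicate")

  # canonical writer: child order independent of input rotation
  a <- parseNewick("((B:2,A:1):0.5,C:3);")
  b <- parseNewick("((A:1,B:2):0.5,C:3);")
  expect_identical(writeNewick(a), writeNewick(b))
  expect_match(writeNewick(a, digits = 3), "A:1\\.000")

  # support labels emitted after the closing parenthesis
  s <- parseNewick("((A:1,B:2)94:0.5,C:3);")
  expect_match(writeNewick(s), "\\)94:")
})

test_that("Newick round-trip preserves bipartitions and lengths", {
  set.seed(7)
  for (i in 1:5) {
    phy <- ape::rtree(20, br = function(n) round(runif(n, 0.01, 1), 6))
    back <- parseNewick(writeNewick(phy, digits = 6))
    expect_equal(bipartitionDistance(phy, back), 0)
    expect_equal(sort(back$edge.length), sort(phy$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("representative selection policies and tie-breaking", {
  gs <- new("GeneSequenceSet", gene = "g",
            sequences = c(x1 = "MKLVW", b = "MKL--", a = "MK---"),
            taxa = c(x1 = "sp1", b = "sp2", a = "sp2"))
  expect_equal(selectRepresentatives(gs)[["sp1"]], "x1")
  expect_equal(selectRepresentatives(gs)[["sp2"]], "b")   # more ungapped
  gs2 <- new("GeneSequenceSet", gene = "g",
             sequences = c(b = "MKL", a = "MKV"),
             taxa = c(b = "sp1", a = "sp1"))
  expect_equal(selectRepresentatives(gs2)[["sp1"]], "a")  # lexicographic tie
  expect_equal(selectRepresentatives(
    gs, policy = "explicit",
    mapping = c(sp1 = "x1", sp2 = "a"))[["sp2"]], "a")
  expect_error(selectRepresentatives(gs, policy = "explicit",
                                     mapping = c(sp1 = "zz", sp2 = "a")),
               "absent record")
})

test_that("concatenation builds the supermatrix with missing-data padding", {
  set.seed(2)
  mk <- function(taxa, w, alphabet = "nt") {
    states <- if (alphabet == "nt") c("A", "C", "G", "T") else c("M", "K")
    m <- matrix(sample(states, length(taxa) * w, TRUE),
                nrow = length(taxa), dimnames = list(taxa, NULL))
    partitionedAlignment(m, alphabet)
  }
  # the study's four-gene supermatrix geometry: 278 + 280 + 274 + 1338
  genes <- list(GAPDH = mk(c("s1", "s2"), 278, "aa"),
                actin = mk(c("s1", "s2", "s3"), 280, "aa"),
                EF1a  = mk(c("s1", "s3"), 274, "aa"),
                SSU   = mk(c("s1", "s2", "s3"), 1338, "nt"))
  sup <- concatenatePartitions(genes)
  expect_equal(nSites(sup), 2170L)
  expect_equal(nrow(partitionScheme(sup)), 4L)
  expect_equal(partitionScheme(sup)$end - partitionScheme(sup)$start,
               c(278L, 280L, 274L, 1338L))
  # s2 missing from EF1a -> all-gap block there
  expect_true(all(alignmentMatrix(sup)["s2", 559:832] == "-"))
  # non-missing counts conserved
  expect_equal(sum(alignmentMatrix(sup)["s3", ] != "-"), 280L + 274L + 1338L)
  expect_error(concatenatePartitions(genes, roster = c("s1", "s4")),
               "absent from every gene")
})

test_that("site masks drop columns and re-index partitions", {
  aln <- partitionedAlignment(c(a = "ACGTACGTAC", b = "ACGAACGTAC"), "nt",
    partitions = data.frame(name = c("g1", "g2"), alphabet = "nt",
                            start = c(0L, 6L), end = c(6L, 10L),
                            model = "GTR+G4"))
  m1 <- applySiteMask(aln, list(c(0, 5)))
  expect_equal(nSites(m1), 5L)
  expect_equal(nrow(partitionScheme(m1)), 1L)
  m2 <- applySiteMask(aln, list(c(0, 10)))
  expect_identical(alignmentMatrix(m2), alignmentMatrix(aln))
  m3 <- applySiteMask(aln, list(c(0, 6)))          # removes g2 entirely
  expect_equal(partitionScheme(m3)$name, "g1")
  expect_error(applySiteMask(aln, list(c(0, 5), c(4, 8))), "overlap")
  expect_error(applySiteMask(aln, list(c(0, 11))), "out of range")
})
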