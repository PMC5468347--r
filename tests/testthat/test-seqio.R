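# Sequence input, windows, identity and redundancy reduction.

test_that("read_fasta parses entries in order, upper-cases and strips stops", {
  path <- write_tmp_fasta(c("a", "b"), c("MKT", "ACD"))
  recs <- read_fasta(path)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$seq, c("MKT", "ACD"))
  expect_equal(recs$label, c("unknown", "unknown"))

  path2 <- write_tmp_fasta("a", "mkt*")
  expect_equal(read_fasta(path2)$seq, "MKT")

  long <- paste(rep("ACDEFGHIKL", 13), collapse = "")
  path3 <- write_tmp_fasta("w", long, wrap = TRUE)
  expect_equal(read_fasta(path3)$seq, long)
})

test_that("read_fasta rejects malformed and empty files", {
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKT", ">a", "ACD"), bad)
  expect_error(read_fasta(bad), "malformed FASTA")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty))
})

test_that("read_labels attaches labels and cleavage positions by id", {
  path <- write_tmp_fasta(c("p1", "c1"), c(strrep("MK", 30), strrep("AC", 30)))
  recs <- read_fasta(path)
  lab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel\tcleavage_pos", "p1\tsecretory\t21",
               "c1\tcytoplasmic\t"), lab)
  out <- read_labels(lab, recs)
  expect_equal(out$label, c("secretory", "cytoplasmic"))
  expect_equal(out$cleavage_pos, c(21L, NA_integer_))
})

test_that("read_labels rejects bad tokens, duplicates, and reports orphans", {
  path <- write_tmp_fasta("p2", strrep("MK", 30))
  recs <- read_fasta(path)
  lab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlabel\tcleavage_pos", "p2\tsecreted\t20"), lab)
  expect_error(read_labels(lab, recs), "unknown label token")

  writeLines(c("id\tlabel\tcleavage_pos", "p2\tsecretory\t20",
               "p2\tsecretory\t21"), lab)
  expect_error(read_labels(lab, recs), "duplicate")

  writeLines(c("id\tlabel\tcleavage_pos", "p2\tsecretory\t20",
               "ghost\tcytoplasmic\t"), lab)
  expect_warning(read_labels(lab, recs), "ghost")
})

test_that("seq_set enforces label and cleavage invariants", {
  expect_error(seq_set("a", "MKT", "cytoplasmic", 2L), "cytoplasmic")
  expect_error(seq_set("a", "MKT", "secretory", 3L), "out of range")
  expect_error(seq_set(c("a", "a"), c("MK", "MT")), "duplicate")
})

test_that("extract_window follows the coordinate convention", {
  recs <- seq_set("p", random_seq(120), "secretory", 21L)
  w <- extract_window(recs, "mature", W = 80)
  expect_equal(w$start_pos, 24L)
  expect_equal(w$residues, substr(recs$seq, 24, 103))
  expect_false(w$short)

  wp <- extract_window(seq_set("s", "MKT"), "preprotein", W = 5)
  expect_equal(wp$residues, "MKT--")
  expect_true(wp$short)

  cyt <- seq_set("c", random_seq(50), "cytoplasmic")
  expect_error(extract_window(cyt, "mature"), "cleavage")
})

test_that("windows are length-exact with padding only as a suffix", {
  set.seed(42)
  for (i in 1:20) {
    len <- sample(25:150, 1)
    cp <- sample(18:24, 1)
    recs <- seq_set("x", random_seq(len), "secretory", cp)
    for (kind in c("preprotein", "mature")) {
      W <- sample(c(30, 80, 84), 1)
      w <- extract_window(recs, kind, W = W)
      expect_equal(nchar(w$residues), W)
      expect_match(w$residues, "^[A-Z]*-*$")  # gaps only as contiguous suffix
    }
  }
})

test_that("pairwise identity matches hand counts and is symmetric", {
  s <- random_seq(50)
  expect_equal(pairwise_identity(s, s), 100)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV"), 90)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  set.seed(7)
  for (i in 1:10) {
    a <- random_seq(sample(30:120, 1))
    b <- random_seq(sample(30:120, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "ACD"), "empty")
})

test_that("identity is computed over the first span residues only", {
  a <- paste0(strrep("A", 50), strrep("C", 100))
  b <- paste0(strrep("A", 50), strrep("D", 100))
  expect_equal(pairwise_identity(a, b, span = 50), 100)
  expect_lt(pairwise_identity(a, b, span = 100), 100)
})

test_that("hobohm2 resolves the worked three-sequence example", {
  # A and B nearly identical (> cutoff); C unrelated. A has 1 neighbor, B has
  # 1: tie, the later index (B) is removed, so {A, C} is retained.
  base <- random_seq(60)
  bvar <- paste0(substr(base, 1, 55), "CCCCC")
  recs <- seq_set(c("A", "B", "C"), c(base, bvar, strrep("GH", 30)))
  red <- hobohm2_reduce(recs, cutoff = 40)
  expect_equal(red$id, c("A", "C"))
})

test_that("hobohm2 keeps dissimilar sets unchanged and is idempotent", {
  set.seed(13)
  recs <- seq_set(paste0("s", 1:6), replicate(6, random_seq(80)))
  red <- hobohm2_reduce(recs, cutoff = 40)
  expect_equal(red$id, recs$id)
  # cluster of similar sequences: reduce, then reduce the output again
  core <- random_seq(90)
  clones <- vapply(1:4, function(i) {
    s <- strsplit(core, "")[[1]]
    mut <- sample(90, 20)
    s[mut] <- sample(secmature:::AA_STANDARD, 20, replace = TRUE)
    paste(s, collapse = "")
  }, "")
  recs2 <- seq_set(paste0("m", 1:5), c(core, clones))
  red2 <- hobohm2_reduce(recs2, cutoff = 40)
  expect_identical(hobohm2_reduce(red2, cutoff = 40)$id, red2$id)
})

test_that("no retained pair exceeds the cutoff and classes reduce separately", {
  set.seed(99)
  core <- random_seq(100)
  mutate <- function(k) {
    s <- strsplit(core, "")[[1]]
    i <- sample(100, k)
    s[i] <- sample(secmature:::AA_STANDARD, k, replace = TRUE)
    paste(s, collapse = "")
  }
  seqs <- c(core, mutate(10), mutate(30), mutate(70), random_seq(100), core)
  recs <- seq_set(paste0("q", 1:6), seqs,
                  label = c(rep("secretory", 5), "cytoplasmic"),
                  cleavage_pos = c(rep(20L, 5), NA))
  red <- hobohm2_reduce(recs, cutoff = 40)
  ids <- red$id
  for (grp in unique(red$label)) {
    sub <- red[red$label == grp, ]
    if (nrow(sub) > 1) {
      for (i in 1:(nrow(sub) - 1)) {
        for (j in (i + 1):nrow(sub)) {
          expect_lte(pairwise_identity(sub$seq[i], sub$seq[j]), 40)
        }
      }
    }
  }
  # the cytoplasmic copy of the secretory core survives: classes are separate
  expect_true("q6" %in% ids)
})
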