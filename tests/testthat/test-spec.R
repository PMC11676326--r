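test_that("spec labels parse, validate, and round-trip", {
  s <- parse_spec("2_30_15")
  expect_equal(s$n_copies, 2L)
  expect_equal(s$window_length, 30L)
  expect_equal(s$overlap, 15L)
  expect_equal(parse_spec(format(s))[], s[])

  expect_equal(parse_spec("1_10_0")[c("n_copies", "window_length", "overlap")],
               list(n_copies = 1L, window_length = 10L, overlap = 0L))
  # boundary of the O <= L - 1 constraint
  expect_equal(parse_spec("3_50_49")$overlap, 49L)
  expect_error(parse_spec("3_50_50"), "overlap")
  expect_error(parse_spec("2-30-15"), "malformed")
  expect_error(parse_spec("2_30_x"), "'x'")
  expect_error(fragment_spec(0, 10, 0), "n_copies")
  expect_error(fragment_spec(2, 10, 3, flank = "B@D"), "flank")
})

test_that("windows tile the sequence with C-terminal window-length priority", {
  s <- fragment_spec(2, 50, 25)
  expect_equal(make_windows(100, s),
               data.frame(start = c(0L, 25L, 50L), end = c(50L, 75L, 100L)))
  # last fragment keeps length L; its overlap grows from 25 to 35
  expect_equal(make_windows(90, s),
               data.frame(start = c(0L, 25L, 40L), end = c(50L, 75L, 90L)))
  expect_equal(make_windows(50, s), data.frame(start = 0L, end = 50L))
  expect_warning(w <- make_windows(30, s), "single full-sequence window")
  expect_equal(w, data.frame(start = 0L, end = 30L))
})

test_that("windowing matches a brute-force enumerator on random cases", {
  set.seed(42)
  for (rep in 1:200) {
    L <- sample(2:80, 1)
    O <- sample(0:(L - 1), 1)
    len <- L + sample(0:300, 1)
    w <- make_windows(len, fragment_spec(1, L, O))
    expect_equal(w, brute_windows(len, L, O),
                 info = sprintf("len=%d L=%d O=%d", len, L, O))
    # tiling and shape properties
    cov <- integer(len)
    for (i in seq_len(nrow(w))) {
      expect_equal(w$end[i] - w$start[i], L)
      cov[(w$start[i] + 1):w$end[i]] <- cov[(w$start[i] + 1):w$end[i]] + 1L
    }
    expect_true(all(cov >= 1))
    if (nrow(w) > 1) {
      shared <- w$end[-nrow(w)] - w$start[-1]
      expect_true(all(shared[-length(shared)] == O))
      expect_gte(shared[length(shared)], O)
    }
  }
})

test_that("dividing writes queries, constructs, and parameters that round-trip", {
  seqc <- paste(rep("ACDEFGHIKL", 10), collapse = "")
  out <- withr::local_tempdir()
  man <- divide_sequence(seqc, parse_spec("2_50_25"), out, seq_id = "toy")
  expect_equal(nrow(man), 3L)
  expect_true(file.exists(file.path(out, "parameters.json")))
  qfiles <- list.files(file.path(out, "queries"))
  expect_equal(sort(qfiles), sort(man$query_file))
  expect_false(anyDuplicated(qfiles) > 0)

  # dimer query in the colon dialect: one record, chain repeated twice
  q <- Biostrings::readBStringSet(file.path(out, "queries", man$query_file[1]))
  parts <- strsplit(as.character(q[[1]]), ":", fixed = TRUE)[[1]]
  expect_length(parts, 2)
  expect_equal(parts[1], parts[2])
  expect_equal(parts[1], substr(seqc, 1, 50))

  # windows reconstructed from the written constructs equal the in-memory ones
  back <- read_manifest(out)
  expect_equal(back$manifest, man)
  expect_equal(back$params$sequence, seqc)

  # core slice invariant
  for (i in seq_len(nrow(man)))
    expect_equal(man$core_length[i], man$end[i] - man$start[i])
})

test_that("flanks extend each query chain symmetrically", {
  seqc <- paste(rep("MKLVNEAQRS", 6), collapse = "")
  flank <- "RMKQLEDKVEELLSK"
  out <- withr::local_tempdir()
  man <- divide_sequence(seqc, parse_spec("2_20_10", flank = flank), out)
  q <- Biostrings::readBStringSet(file.path(out, "queries", man$query_file[1]))
  chain <- strsplit(as.character(q[[1]]), ":", fixed = TRUE)[[1]][1]
  expect_equal(nchar(chain), 20 + 2 * nchar(flank))
  expect_equal(substr(chain, 1, 15), flank)
  expect_equal(substr(chain, 36, 50), flank)
  expect_equal(unique(man$flank_length), 15L)
})

test_that("two specs share windows but not files; output is deterministic", {
  seqc <- paste(rep("ACDEFGHIKL", 9), collapse = "")
  specs <- list(parse_spec("2_30_15"), parse_spec("3_30_15"))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  m1 <- divide_sequence(seqc, specs, out1)
  m2 <- divide_sequence(seqc, specs, out2)
  a <- m1[m1$spec_label == "2_30_15", c("start", "end")]
  b <- m1[m1$spec_label == "3_30_15", c("start", "end")]
  expect_equal(a, b, ignore_attr = TRUE)
  expect_length(intersect(m1$query_file[m1$spec_label == "2_30_15"],
                          m1$query_file[m1$spec_label == "3_30_15"]), 0)

  # byte-identical across runs
  f1 <- list.files(out1, recursive = TRUE)
  expect_equal(f1, list.files(out2, recursive = TRUE))
  for (f in f1)
    expect_equal(unname(tools::md5sum(file.path(out1, f))),
                 unname(tools::md5sum(file.path(out2, f))),
                 info = f)

  # one record per chain copy in the "records" dialect
  out3 <- withr::local_tempdir()
  m3 <- divide_sequence(seqc, parse_spec("3_30_15"), out3,
                        multimer_dialect = "records")
  q <- Biostrings::readBStringSet(file.path(out3, "queries", m3$query_file[1]))
  expect_length(q, 3)
})

test_that("invalid sequences are rejected with offending positions", {
  expect_error(divide_sequence("", parse_spec("1_5_0"), tempfile()), "empty")
  expect_error(divide_sequence("ACDEJGHZ", parse_spec("1_5_0"), tempfile()),
               "position\\(s\\) 5, 8")
})
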