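test_that("length filter keeps exactly the transcripts at or above the cutoff", {
  set.seed(11)
  tx <- c(short = random_dna_str(249), exact = random_dna_str(250),
          long = random_dna_str(400))
  expect_identical(names(filter_transcripts(tx)), c("exact", "long"))
  expect_identical(filter_transcripts(character(0)), character(0))
  expect_identical(filter_transcripts(tx[2:3]), tx[2:3])
  expect_identical(names(filter_transcripts(tx, min_len = 100)),
                   names(tx))
})

test_that("overlap clustering links chains of shared substrings and nothing else", {
  set.seed(21)
  # A-B share 60 bp, B-C share a different 60 bp, A-C share nothing
  a <- random_dna_str(300)
  mid <- random_dna_str(180)
  b <- paste0(substr(a, 241, 300), mid)          # 60 bp from A's tail
  c_ <- paste0(substr(b, 181, 240), random_dna_str(240))
  tx <- c(A = a, B = b, C = c_)
  cl <- cluster_transcripts(tx)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$member_ids, c("A", "B", "C"))

  # unrelated sequences stay apart; identical sequences merge
  tx2 <- c(X = random_dna_str(300), Y = random_dna_str(300))
  expect_length(cluster_transcripts(tx2), 2)
  tx3 <- c(P = a, Q = a)
  expect_length(cluster_transcripts(tx3), 1)
})

test_that("reverse-complement overlaps link transcripts unless disabled", {
  set.seed(22)
  a <- random_dna_str(300)
  b <- paste0(rc(substr(a, 1, 60)), random_dna_str(200))
  tx <- c(A = a, B = b)
  expect_length(cluster_transcripts(tx), 1)
  expect_length(cluster_transcripts(tx, both_strands = FALSE), 2)
})

test_that("clustering matches the brute-force all-pairs oracle on random instances", {
  for (s in 1:4) {
    set.seed(100 + s)
    g <- gen_transcript_clusters(n_clusters = sample(3:6, 1),
                                 members_per_cluster = sample(1:4, 1),
                                 member_len = 300, overlap_len = 60,
                                 seed = 200 + s)
    # pad with unrelated singletons up to ~20 transcripts
    extra <- stats::setNames(replicate(6, random_dna_str(300)),
                             paste0("lone", 1:6))
    tx <- c(g$transcripts, extra)
    perm <- sample(length(tx))
    got <- as_partition(cluster_transcripts(tx[perm]))
    expect_same_partition(got, oracle_cluster(tx))
  }
})

test_that("cluster assignment is invariant to input order", {
  g <- gen_transcript_clusters(4, 3, seed = 77)
  p1 <- as_partition(cluster_transcripts(g$transcripts))
  set.seed(1)
  p2 <- as_partition(cluster_transcripts(
    g$transcripts[sample(length(g$transcripts))]))
  expect_same_partition(p1, p2)
})

test_that("nominal length adds only the non-overlapping sequence", {
  set.seed(31)
  long <- random_dna_str(300)
  # singleton
  expect_identical(nominal_length(c(A = long)), 300L)
  # full containment
  inner <- substr(long, 101, 250)
  expect_identical(nominal_length(c(A = long, B = inner)), 300L)
  # 60 bp suffix/prefix overlap: 300 + (200 - 60)
  second <- paste0(substr(long, 241, 300), random_dna_str(140))
  expect_identical(nominal_length(c(A = long, B = second)), 440L)
})

test_that("nominal length equals the interval-union oracle on planted layouts", {
  for (s in 1:6) {
    set.seed(300 + s)
    master <- random_dna_str(3000)
    m <- sample(2:5, 1)
    widths <- sample(200:500, m, replace = TRUE)
    starts <- integer(m); starts[1] <- sample(1:200, 1)
    for (i in seq_len(m - 1)) {
      ov <- sample(50:150, 1)          # chain overlaps of >= 50 bp
      starts[i + 1] <- starts[i] + widths[i] - ov
    }
    members <- stats::setNames(
      substring(master, starts, starts + widths - 1),
      paste0("m", seq_len(m)))
    expected <- oracle_union_length(starts, widths)
    got <- nominal_length(members)
    expect_identical(got, as.integer(expected))
    expect_gte(got, max(widths))
    expect_lte(got, sum(widths))
  }
})

test_that("expression values follow the per-kilobase per-million formula", {
  C <- matrix(c(10, 0, 5, 990000, 999990, 99995), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  # make column sums exactly 1e6 and 1e5
  C[, 1] <- c(10, 0, 999990)
  C[, 2] <- c(0, 5, 99995)
  ct <- count_table(C)
  E <- compute_expression(ct, c(g1 = 1000, g2 = 500, g3 = 2000))
  expect_equal(E["g1", "s1"], 10)             # 10 / 1kb / 1M reads
  expect_equal(E["g2", "s1"], 0)
  expect_equal(E["g2", "s2"], 5 / 0.5 / 0.1)
  expect_identical(E == 0, C == 0)            # zero iff zero count
})

test_that("expression is invariant to per-sample count scaling", {
  set.seed(41)
  C <- matrix(rpois(60, 50), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  L <- stats::setNames(sample(300:3000, 10), rownames(C))
  E1 <- compute_expression(count_table(C), L)
  C2 <- C; C2[, 3] <- C[, 3] * 7L
  E2 <- compute_expression(count_table(C2), L)
  expect_equal(E1, E2)
})

test_that("a counted gene without a nominal length is a hard error naming it", {
  C <- matrix(1:4, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(compute_expression(count_table(C), c(gA = 500)), "gB")
})

test_that("expression call needs the threshold in enough replicates", {
  expect_true(is_expressed(c(0, 0, 12)))
  expect_false(is_expressed(c(0, 0, 0)))
  expect_false(is_expressed(c(11.9, 11.9, 11.9)))
  expect_true(is_expressed(c(15, 20, 0), min_reps = 2))
  expect_false(is_expressed(c(15, 11, 0), min_reps = 2))
  expect_error(is_expressed(numeric(0)), "at least one")
})

test_that("FASTA and count-table I/O round-trip through quantify", {
  g <- gen_transcript_clusters(3, 2, seed = 5)
  fa <- tempfile(fileext = ".fa")
  write_transcripts(g$transcripts, fa)
  tx <- read_transcripts(fa)
  expect_identical(tx, g$transcripts)

  q <- quantify(tx)
  expect_identical(unname(q$lengths[order(names(q$lengths))]),
                   unname(g$nominal_lengths))

  C <- matrix(rpois(6, 100), 3, 2,
              dimnames = list(names(q$lengths), c("s1", "s2")))
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(C), C),
                     tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  ct <- read_count_table(tsv)
  expect_identical(ct$counts, C)
  q2 <- quantify(tx, counts = ct)
  expect_equal(dim(q2$expression), dim(C))
})
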