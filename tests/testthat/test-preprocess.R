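test_that("adapter trimming finds the leftmost valid adapter start", {
  ad <- ADAPTER3
  r <- trim_adapter(paste0("ACGTACGT", ad))
  expect_equal(r$insert, "ACGTACGT")
  expect_true(r$trimmed)
  ## adapter absent: whole read, flagged untrimmed
  r <- trim_adapter("ACGTACGTACGTACGTACGTACGT")
  expect_equal(r$insert, "ACGTACGTACGTACGTACGTACGT")
  expect_false(r$trimmed)
  ## empty read
  r <- trim_adapter("")
  expect_equal(r$insert, "")
  expect_false(r$trimmed)
  expect_error(trim_adapter("ACGT", min_overlap = 3), ">= 5")
})

test_that("truncated adapters are recovered iff >= min_overlap bases remain", {
  ad <- ADAPTER3
  insert <- "TGTGTTCCCAGCTCGACCCCG"
  for (keep in 0:12) {
    read <- paste0(insert, substr(ad, 1, keep))
    got <- trim_adapter(read, ad, min_overlap = 5)
    want <- brute_trim(read, ad, 5)
    expect_equal(got$insert, want$insert, info = paste("keep =", keep))
    expect_equal(got$trimmed, want$trimmed)
    if (keep >= 5) expect_equal(got$insert, insert)
  }
})

test_that("trimming equals the brute-force leftmost-prefix scan on random reads", {
  set.seed(11)
  ad <- ADAPTER3
  reads <- vapply(1:300, function(i) {
    ins <- rand_seq(sample(5:30, 1))
    body <- switch(sample(3, 1),
                   paste0(ins, ad, strrep("A", 10)),   # full adapter
                   paste0(ins, substr(ad, 1, sample(0:12, 1))),  # truncated
                   rand_seq(40))                        # random
    substr(body, 1, 50)
  }, character(1))
  got <- trim_adapter(reads, ad, 5)
  for (i in seq_along(reads)) {
    want <- brute_trim(reads[i], ad, 5)
    expect_equal(got$insert[i], want$insert, info = reads[i])
    expect_equal(got$trimmed[i], want$trimmed, info = reads[i])
  }
})

test_that("size selection keeps exactly the 18-24 nt inserts, in order", {
  ins <- vapply(c(17, 18, 24, 25), rand_seq, character(1))
  expect_equal(size_select(ins), ins[c(2, 3)])
  expect_equal(size_select(character(0)), character(0))
  set.seed(12)
  many <- vapply(sample(10:40, 1000, replace = TRUE), rand_seq, character(1))
  sel <- size_select(many)
  expect_equal(length(sel), sum(nchar(many) >= 18 & nchar(many) <= 24))
  expect_equal(sel, many[nchar(many) >= 18 & nchar(many) <= 24])
})

test_that("collapsing counts multiplicities and names tags stably", {
  des <- data.frame(library_id = c("A", "B"), treatment = "control",
                    replicate = 1:2, time_dat = 0L)
  s1 <- strrep("A", 18)
  s2 <- strrep("C", 18)
  tags <- collapse_and_name(list(A = rep(s1, 3), B = c(rep(s1, 2), s2)), des)
  i1 <- match(s1, tags$sequence)
  i2 <- match(s2, tags$sequence)
  expect_equal(unname(tags$counts[i1, ]), c(3L, 2L))
  expect_equal(unname(tags$counts[i2, ]), c(0L, 1L))
  ## permuting library order permutes count columns only, not tag ids
  des2 <- des[2:1, ]
  tags2 <- collapse_and_name(list(A = rep(s1, 3), B = c(rep(s1, 2), s2)), des2)
  expect_equal(tags2$tag_id, tags$tag_id)
  expect_equal(tags2$sequence, tags$sequence)
  expect_equal(tags2$counts[, c("A", "B")], tags$counts[, c("A", "B")])
  ## conservation: column sums equal input read numbers
  set.seed(13)
  ins <- list(A = replicate(500, rand_seq(sample(18:24, 1))),
              B = replicate(400, rand_seq(sample(18:24, 1))))
  t3 <- collapse_and_name(ins, des)
  expect_equal(unname(colSums(t3$counts)), c(500L, 400L))
})

test_that("RPM is counts over retained reads times one million", {
  des <- data.frame(library_id = "L1", treatment = "control",
                    replicate = 1L, time_dat = 0L)
  tags <- collapse_and_name(list(L1 = rep(strrep("G", 20), 5)), des)
  tags <- compute_rpm(tags, c(L1 = 500000L))
  expect_equal(unname(tags$rpm[1, 1]), 10)
  ## normalization identity: denominators equal to column sums give 1e6
  set.seed(14)
  ins <- list(L1 = replicate(800, rand_seq(sample(18:24, 1))))
  tags <- compute_rpm(collapse_and_name(ins, des))
  expect_equal(unname(colSums(tags$rpm)), 1e6)
  ## brute recomputation on a random matrix
  des2 <- data.frame(library_id = c("A", "B"), treatment = "control",
                     replicate = 1:2, time_dat = 0L)
  ins2 <- list(A = replicate(300, rand_seq(sample(18:24, 1))),
               B = replicate(200, rand_seq(sample(18:24, 1))))
  t2 <- compute_rpm(collapse_and_name(ins2, des2))
  for (i in seq_along(t2$sequence)) {
    for (j in 1:2) {
      expect_equal(t2$rpm[i, j], t2$counts[i, j] / c(300, 200)[j] * 1e6)
    }
  }
  ## zero denominator with nonzero counts is a hard error
  expect_error(compute_rpm(collapse_and_name(ins2, des2), c(A = 0L, B = 200L)),
               "denominator")
})

test_that("decoy removal is exact substring matching on both strands", {
  ref <- c(rRNA1 = rand_seq(200))
  inside <- substr(ref, 50, 70)                       # 21-mer inside the decoy
  mism <- inside
  substr(mism, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                  substr(inside, 11, 11))[1]
  rc <- revcomp(substr(ref, 100, 121))
  des <- data.frame(library_id = "L1", treatment = "control",
                    replicate = 1L, time_dat = 0L)
  tags <- collapse_and_name(list(L1 = c(inside, mism, rc)), des)
  flt <- filter_known_ncRNA(tags, ref)
  expect_setequal(flt$removed$sequence, c(inside, rc))
  expect_setequal(flt$retained$sequence, mism)
  ## partition equals a brute-force substring scan on random inputs
  set.seed(15)
  refs <- stats::setNames(vapply(1:20, function(i) rand_seq(150), character(1)),
                          paste0("d", 1:20))
  pool <- c(replicate(60, rand_seq(sample(18:24, 1))),
            vapply(1:40, function(i) {
              r <- refs[[sample(20, 1)]]
              s <- sample(120, 1)
              substr(r, s, s + 20)
            }, character(1)))
  tgs <- collapse_and_name(list(L1 = pool), des)
  f2 <- filter_known_ncRNA(tgs, refs)
  hay <- paste(c(refs, revcomp(refs)), collapse = "#")
  want_removed <- tgs$sequence[stringi::stri_detect_fixed(hay, tgs$sequence)]
  expect_setequal(f2$removed$sequence, want_removed)
  expect_equal(length(f2$removed$sequence) + length(f2$retained$sequence),
               length(tgs$sequence))
})

test_that("the minimum-RPM filter is inclusive at the threshold", {
  des <- data.frame(library_id = c("A", "B"), treatment = "control",
                    replicate = 1:2, time_dat = 0L)
  tags <- collapse_and_name(list(A = character(0), B = character(0)), des)
  t <- structure(list(tag_id = c("t1", "t2", "t3"),
                      sequence = c(strrep("A", 18), strrep("C", 18), strrep("G", 18)),
                      counts = matrix(1L, 3, 2, dimnames = list(NULL, c("A", "B"))),
                      rpm = matrix(c(9.99, 10.0, 50.0, 9.99, 3.0, 5.0), 3, 2,
                                   dimnames = list(NULL, c("A", "B"))),
                      retained_reads = NULL),
                 class = "distinct_tags")
  kept <- filter_min_rpm(t, 10)
  expect_setequal(kept$tag_id, c("t2", "t3"))
  ## random matrix equals the brute-force max scan
  set.seed(16)
  t$rpm <- matrix(runif(6, 0, 20), 3, 2, dimnames = list(NULL, c("A", "B")))
  kept <- filter_min_rpm(t, 10)
  expect_equal(kept$tag_id, t$tag_id[apply(t$rpm, 1, max) >= 10])
})

test_that("size distributions count reads weighted and tags unweighted", {
  des <- data.frame(library_id = c("A", "B"), treatment = c("control", "heat"),
                    replicate = 1L, time_dat = 0L)
  s21 <- rand_seq(21)
  tags <- collapse_and_name(list(A = rep(s21, 10), B = character(0)), des)
  sd <- size_distribution(tags, des)
  expect_equal(sd$reads[sd$treatment == "control" & sd$size == 21], 10)
  expect_equal(sd$tags[sd$treatment == "control" & sd$size == 21], 1)
  expect_equal(sum(sd$reads[sd$treatment == "heat"]), 0)
  ## identical inputs across treatments give identical rows
  tags2 <- collapse_and_name(list(A = rep(s21, 4), B = rep(s21, 4)), des)
  sd2 <- size_distribution(tags2, des)
  expect_equal(sd2$reads[sd2$treatment == "control"],
               sd2$reads[sd2$treatment == "heat"])
  ## random input equals a brute-force histogram
  set.seed(17)
  ins <- list(A = replicate(300, rand_seq(sample(18:24, 1))),
              B = replicate(250, rand_seq(sample(18:24, 1))))
  t3 <- collapse_and_name(ins, des)
  sd3 <- size_distribution(t3, des)
  for (s in 18:24) {
    expect_equal(sd3$reads[sd3$treatment == "control" & sd3$size == s],
                 sum(nchar(ins$A) == s))
  }
})

test_that("tag tables round-trip through TSV", {
  des <- data.frame(library_id = c("A", "B"), treatment = "control",
                    replicate = 1:2, time_dat = 0L)
  ins <- list(A = replicate(50, rand_seq(20)), B = replicate(30, rand_seq(20)))
  tags <- compute_rpm(collapse_and_name(ins, des))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tags(tags, path)
  back <- read_tags(path)
  expect_equal(back$tag_id, tags$tag_id)
  expect_equal(back$sequence, tags$sequence)
  expect_equal(back$counts, tags$counts)
  expect_equal(back$rpm, tags$rpm, tolerance = 1e-9)
})
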