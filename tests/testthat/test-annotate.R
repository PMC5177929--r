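mk_tags <- function(seqs, counts = NULL) {
  des <- data.frame(library_id = c("A", "B"), treatment = "control",
                    replicate = 1:2, time_dat = 0L)
  if (is.null(counts)) counts <- lapply(seqs, function(s) c(2L, 1L))
  ins <- list(A = rep(seqs, vapply(counts, `[`, integer(1), 1)),
              B = rep(seqs, vapply(counts, `[`, integer(1), 2)))
  compute_rpm(collapse_and_name(ins, des))
}

test_that("precursor mapping reports every exact occurrence", {
  set.seed(31)
  h <- build_hairpin(rand_seq(22), loop_len = 10)
  prec <- c(locusA = h$precursor)
  tags <- mk_tags(c(h$mature, rand_seq(20)))
  hits <- map_to_precursors(tags, prec)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$locus_id, "locusA")
  expect_equal(c(hits$start, hits$end), c(1L, 22L))
  ## a tag absent from all precursors yields no hit
  expect_false(rand_seq(20) %in% hits$sequence)
  ## empty precursor set: empty result with a warning
  expect_warning(h0 <- map_to_precursors(tags, character(0)), "empty")
  expect_equal(nrow(h0), 0)
})

test_that("mapping equals the naive all-positions scan on random inputs", {
  set.seed(32)
  precs <- stats::setNames(vapply(1:15, function(i) rand_seq(sample(60:120, 1)),
                                  character(1)), paste0("L", 1:15))
  pool <- c(replicate(30, rand_seq(sample(18:24, 1))),
            vapply(1:30, function(i) {    # planted substrings
              p <- precs[[sample(15, 1)]]
              s <- sample(nchar(p) - 21, 1)
              substr(p, s, s + 20)
            }, character(1)))
  tags <- mk_tags(unique(pool))
  hits <- map_to_precursors(tags, precs)
  want <- naive_hits(tags$sequence, precs)
  got_keys <- sort(paste(hits$sequence, hits$locus_id, hits$start))
  want_keys <- sort(paste(tags$sequence[want$tag], want$locus, want$start))
  expect_equal(got_keys, want_keys)
})

test_that("a mature placed in the hairpin loop yields no star", {
  ## hairpin with a large loop; query an interval inside the loop
  set.seed(33)
  h <- build_hairpin(rand_seq(21), loop_len = 24)
  s <- fold_mfe(h$precursor)
  sp <- predict_star(s, 23, 42)   # inside the 24-nt loop region
  expect_false(sp$ok)
  expect_equal(sp$reason, "spans_loop")
})

test_that("poorly paired matures are rejected with a reason code", {
  ## an unstructured sequence has no pairing to anchor a star
  s <- fold_mfe(paste0(strrep("A", 30), strrep("C", 20)))
  sp <- predict_star(s, 1, 21)
  expect_false(sp$ok)
  expect_true(sp$reason %in% c("low_pairing", "spans_loop"))
})

test_that("star expression check is exact membership with nonzero counts", {
  set.seed(34)
  h <- build_hairpin(rand_seq(21), loop_len = 12)
  tags_with <- mk_tags(c(h$mature, h$star_seq))
  tags_without <- mk_tags(c(h$mature, rand_seq(20)))
  expect_true(check_star_expression(h$star_seq, tags_with))
  expect_false(check_star_expression(h$star_seq, tags_without))
  ## randomized table equals brute membership
  pool <- unique(replicate(50, rand_seq(sample(18:24, 1))))
  tg <- mk_tags(pool)
  for (q in c(pool[1:5], replicate(5, rand_seq(20)))) {
    expect_equal(check_star_expression(q, tg), q %in% tg$sequence)
  }
})

test_that("classification requires precursor, stable hairpin and star geometry", {
  set.seed(35)
  h <- build_hairpin(rand_seq(21), loop_len = 12)
  sirna <- rand_seq(24)
  ## weak locus: the mature occurs but the 'precursor' cannot fold
  weak_mature <- rand_seq(20)
  weak_prec <- paste0(weak_mature, strrep("A", 30))
  tags <- mk_tags(c(h$mature, h$star_seq, sirna, weak_mature))
  ann <- classify_mirna(tags, list(c(locus1 = h$precursor, weak = weak_prec)))
  acc <- ann$annotations
  expect_true(h$mature %in% acc$sequence)
  expect_true(acc$star_supported[acc$sequence == h$mature])
  expect_equal(acc$accepted_strict[acc$sequence == h$mature], TRUE)
  rej <- ann$rejections
  expect_equal(rej$reason[rej$sequence == sirna], "no_precursor")
  expect_equal(rej$reason[rej$sequence == weak_mature], "mfe_gate")
})

test_that("star support is recorded but not required for the lenient verdict", {
  set.seed(36)
  h <- build_hairpin(rand_seq(21), loop_len = 12)
  tags <- mk_tags(c(h$mature, rand_seq(19)))   # star reads never emitted
  ann <- classify_mirna(tags, c(locus1 = h$precursor))
  acc <- ann$annotations
  expect_true(h$mature %in% acc$sequence)
  row <- acc[acc$sequence == h$mature, ]
  expect_false(row$star_supported)
  expect_true(row$accepted)
  expect_false(row$accepted_strict)
})

test_that("family assignment handles exact, mismatch, ambiguous and empty cases", {
  cat398 <- "TGTGTTCCCAGCTCGACCCCG"
  catalog <- c(`tae-miR398a` = cat398,
               `tae-miR169b` = "CAGCCAAGGATGACTTGCCGG",
               `tae-miR399c` = "CAGCCAAGGATGACTTGCCTA")
  expect_equal(assign_family(cat398, catalog), "miR398")
  ## two mismatches outside the seed still match the family
  v <- cat398
  substr(v, 15, 15) <- "A"
  substr(v, 20, 20) <- "T"
  expect_equal(assign_family(v, catalog), "miR398")
  ## a seed mismatch breaks the relaxed rule
  v2 <- cat398
  substr(v2, 3, 3) <- "A"
  expect_equal(assign_family(v2, catalog), "UNASSIGNED")
  ## a tag matching entries of two families is ambiguous: the miR169b /
  ## miR399c entries share the seed and differ at two 3' positions
  mid <- "CAGCCAAGGATGACTTGCCGA"
  expect_equal(assign_family(mid, catalog), "AMBIGUOUS")
  ## empty catalog
  expect_equal(assign_family(c(cat398, v), character(0)),
               c("UNASSIGNED", "UNASSIGNED"))
})

test_that("family assignment equals the brute-force all-pairs rule", {
  set.seed(37)
  catalog <- stats::setNames(replicate(25, rand_seq(21)),
                             sprintf("tae-miR%d%s", rep(101:105, each = 5),
                                     letters[rep(1:5, 5)]))
  queries <- c(catalog[1:10],
               vapply(catalog[11:20], function(s) {
                 p <- sample(9:21, 1)
                 substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
                 s
               }, character(1), USE.NAMES = FALSE),
               replicate(20, rand_seq(21)))
  got <- assign_family(queries, catalog, max_mismatch = 2)
  fam <- sub("^tae-(miR[0-9]+).*$", "\\1", names(catalog))
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    hitfams <- character(0)
    for (ci in seq_along(catalog)) {
      cs <- catalog[[ci]]
      if (nchar(cs) != nchar(q)) next
      mm <- sum(strsplit(cs, "")[[1]] != strsplit(q, "")[[1]])
      seed_same <- substr(cs, 2, 8) == substr(q, 2, 8)
      if (cs == q || (mm <= 2 && seed_same)) hitfams <- c(hitfams, fam[ci])
    }
    hitfams <- unique(hitfams)
    want <- if (length(hitfams) == 0) "UNASSIGNED"
            else if (length(hitfams) > 1) "AMBIGUOUS" else hitfams
    expect_equal(got[qi], want, info = q)
  }
})

test_that("family summaries count members and size classes", {
  a <- data.frame(family = c("miR398", "miR398", "miR398", "miR156"),
                  size_class = c(20L, 21L, 21L, 22L))
  fs <- family_summary(a)
  r <- fs[fs$family == "miR398", ]
  expect_equal(r$n_members, 3L)
  expect_equal(r$len20, 1L)
  expect_equal(r$len21, 2L)
  expect_equal(r$len22, 0L)
  ## empty annotation
  e <- family_summary(data.frame(family = character(0), size_class = integer(0)))
  expect_equal(nrow(e), 0)
  ## random annotations equal a brute group-by
  set.seed(38)
  a2 <- data.frame(family = sample(c("f1", "f2", "f3"), 50, replace = TRUE),
                   size_class = sample(18:24, 50, replace = TRUE))
  fs2 <- family_summary(a2)
  for (f in unique(a2$family)) {
    expect_equal(fs2$n_members[fs2$family == f], sum(a2$family == f))
    for (s in 18:24) {
      expect_equal(fs2[[paste0("len", s)]][fs2$family == f],
                   sum(a2$family == f & a2$size_class == s))
    }
  }
})
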